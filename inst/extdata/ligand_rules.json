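{
  "_comment": "Editable AND-of-OR capability rules over KEGG orthologs. A capability is satisfied when every entry of 'groups' intersects the taxon's KO set and, where 'routes' is present, at least one route block is fully satisfied. KO lists are curated defaults for the named KEGG maps and are meant to be edited for a given catalog version.",
  "flagellin": {
    "map": "map02040",
    "groups": [["K02406"]]
  },
  "lps_core": {
    "map": "map00540",
    "groups": [
      ["K00677"],
      ["K02535"],
      ["K02536"],
      ["K03269"],
      ["K00748"],
      ["K00912"],
      ["K02527"]
    ]
  },
  "lps_hexa_extension": {
    "map": "map00540",
    "groups": [
      ["K02517"],
      ["K02560"]
    ]
  },
  "butyrate": {
    "map": "map00650",
    "groups": [["K00634", "K00929", "K01034", "K01035"]],
    "routes": [
      [["K00626"], ["K00074"], ["K01715"], ["K00248"]],
      [["K18120"], ["K18122"], ["K14534"], ["K00248"]],
      [["K14534"], ["K00248"]],
      [["K01615"], ["K01715"], ["K00248"]],
      [["K04072"]]
    ]
  }
}
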