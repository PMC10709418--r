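## Fixed taxonomy vocabulary used by the synthetic cohort generator and the
## family-level summaries. The closed set of 22 common human gut bacterial
## families keeps family rollups comparable across simulated cohorts.

#' Catalog of gut bacterial families used by the simulator
#'
#' Returns the closed vocabulary of 22 bacterial families (with phylum) from
#' which synthetic ASVs draw their taxonomy, together with the relative
#' weight each family receives when ASVs are assigned and a typical mean
#' relative abundance in bulk feces. Weights reflect the usual dominance of
#' Lachnospiraceae and Ruminococcaceae among gut ASVs; they are generator
#' defaults, not estimates from any particular cohort.
#'
#' @return A `data.frame` with columns `family`, `phylum`, `asv_weight`
#'   (probability an ASV belongs to the family) and `mean_abundance`
#'   (expected bulk relative abundance of the whole family).
#' @export
#' @examples
#' head(gut_family_catalog())
gut_family_catalog <- function() {
  fam <- data.frame(
    family = c(
      "Lachnospiraceae", "Ruminococcaceae", "Peptostreptococcaceae",
      "Clostridiaceae", "Christensenellaceae", "ClostridialesFamilyXIII",
      "Peptococcaceae", "Veillonellaceae", "Streptococcaceae",
      "Lactobacillaceae", "Erysipelotrichaceae",
      "Bacteroidaceae", "Prevotellaceae", "Rikenellaceae", "Tannerellaceae",
      "Enterobacteriaceae", "Desulfovibrionaceae", "Sutterellaceae",
      "Bifidobacteriaceae", "Eggerthellaceae", "Actinomycetaceae",
      "Akkermansiaceae"
    ),
    phylum = c(
      rep("Firmicutes", 11),
      rep("Bacteroidetes", 4),
      rep("Proteobacteria", 3),
      rep("Actinobacteria", 3),
      "Verrucomicrobia"
    ),
    asv_weight = c(
      0.33, 0.18, 0.05,
      0.03, 0.025, 0.01,
      0.01, 0.025, 0.02,
      0.02, 0.03,
      0.09, 0.04, 0.025, 0.02,
      0.025, 0.015, 0.01,
      0.03, 0.015, 0.005,
      0.02
    ),
    mean_abundance = c(
      0.28, 0.18, 0.004,
      0.02, 0.01, 0.002,
      0.005, 0.03, 0.015,
      0.01, 0.02,
      0.17, 0.06, 0.02, 0.015,
      0.02, 0.006, 0.005,
      0.05, 0.008, 0.002,
      0.04
    ),
    stringsAsFactors = FALSE
  )
  fam$asv_weight <- fam$asv_weight / sum(fam$asv_weight)
  fam$mean_abundance <- fam$mean_abundance / sum(fam$mean_abundance)
  fam
}

# Families whose members can plausibly carry each genetic capability; used
# only by the synthetic KO-profile generator (editable there).
capability_families <- function() {
  list(
    flagellin = c("Clostridiaceae", "Lachnospiraceae", "Peptostreptococcaceae",
                  "Ruminococcaceae", "Desulfovibrionaceae",
                  "Enterobacteriaceae"),
    lps = c("Bacteroidaceae", "Prevotellaceae", "Rikenellaceae",
            "Tannerellaceae", "Enterobacteriaceae", "Desulfovibrionaceae",
            "Sutterellaceae", "Akkermansiaceae", "Veillonellaceae"),
    lps_hexa = "Enterobacteriaceae",
    butyrate = c("Lachnospiraceae", "Ruminococcaceae", "Clostridiaceae",
                 "Erysipelotrichaceae", "Christensenellaceae",
                 "Peptostreptococcaceae")
  )
}
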