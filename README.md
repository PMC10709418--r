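# igcoat

Quantitative analysis of multi-immunoglobulin (IgA, IgM, IgG and IgG1–4)
coating of intestinal bacteria, for cohorts of IgA-deficient subjects
paired with IgA-sufficient household members.

Secretory antibodies bind gut bacteria, and flow cytometry of fecal
suspensions stained with anti-isotype antibodies can count how many
bacteria carry each isotype — alone or in combination — while FACS
sorting of the gated fractions followed by 16S amplicon sequencing tells
*which* bacteria are coated. `igcoat` implements the full analysis
around that design:

* **Flow quantification** (`derive_thresholds`, `classify_events`,
  `absolute_load`, `combo_loads`). Gates are set at an empirical
  quantile (default 0.999, nearest-rank) of fluorescence-minus-one (FMO)
  control intensities; DAPI⁺ non-bead events are partitioned into the
  2ᵏ Boolean isotype combinations (k = 3 for the IgA/IgM/IgG panel,
  k = 4 for IgG1–4). Counting beads convert events to absolute loads:

  ```
  load (bacteria/g) = (cell events / bead events) × beads added × dilution / sample mass
  ```

* **Sorted-fraction ASV pipeline** (`remove_control_asvs`,
  `prevalence_abundance_filter`, `preprocess_counts`). ASVs appearing in
  any negative control (pre-sorting fluid, extraction blank, PCR blank)
  are removed everywhere; ASVs with *both* low prevalence and low
  abundance are then filtered (conjunctive rule).

* **Coating classification** (`presence_matrix`, `classify_asvs`,
  `summarize_categories`, `fraction_prevalence`). An ASV present in a
  coated sort of an IgA⁺ subject and in an IgM-based coated sort of an
  IgA⁻ subject is *shared*; presence on only one side gives *IgA-only*
  or *IgM-only*; ASVs seen only in non-coated sorts are *strictly
  non-coated*.

* **Coated-load conversion** (`taxon_coated_load`,
  `family_coating_frequency`, `family_coating_summary`, `fold_ratio`,
  `pseudocount_ratio`). Sorted-fraction compositions times flow-derived
  coated loads give bacteria/g per taxon or family; dividing by the bulk
  family load gives the family's coating frequency.

* **Ligand capability calls** (`load_ligand_rules`, `call_ligands`,
  `producer_coating_summary`). An editable AND-of-OR rule engine over
  KEGG orthologs calls flagellin, penta- vs hexa-acylated LPS (Raetz
  pathway core plus secondary acyltransferases) and butyrate production
  per taxon, and joins the calls to coated loads.

* **Statistics** (`paired_wilcoxon`, `spearman`, `fisher_exact`,
  `fdr_adjust`, `adjust_results`). Paired Wilcoxon signed-rank across
  household pairs, Spearman correlations, Fisher's exact test, and
  Benjamini–Hochberg FDR with the significance convention
  *p* < 0.05 and *q* < 0.1.

* **Synthetic cohorts** (`cohort_config`, `generate_cohort`,
  `simulate_flow_events`, `simulate_sorted_counts`). A generator that
  emulates the whole design — household pairs, per-ASV coating
  probabilities with IgA exactly absent in IgA⁻ subjects, bead-spiked
  acquisitions, sort purity, contaminant pools shared with the negative
  controls, multinomial read counts — and returns the latent ground
  truth, so every stage is testable without subject-level data.

## Worked example

```r
library(igcoat)

cfg    <- cohort_config(n_pairs = 16, seed = 7)   # 16 household pairs
cohort <- generate_cohort(cfg)
report <- run_cohort_analysis(cohort$bundle)
report
#> Multi-Ig coating cohort report
#>   subjects: 32 (16 pairs)
#>   median coated %: IgA+ 7.07, IgA- 3.84 (fold 1.84)
#> Coated ASVs: 396
#>   shared                 384 (97%)
#>   iga_only                 4 (1%)
#>   igm_only                 8 (2%)
#>   strictly_non_coated      2
#> ...
#> Paired tests:
#>        label                      method statistic ...            p
#> 2 pct_any_ig paired Wilcoxon signed-rank       136     3.051758e-05
```

The IgA⁺ members carry a median 7.07 % Ig-coated bacteria against
3.84 % in their IgA-deficient partners — a highly significant paired
difference — and at the default 95 % sort purity the carry-over of bulk
community into the sorted gates makes most detected ASVs look shared
(decontamination and the `min_count` presence threshold exist precisely
to counter this; with pure sorts the classification recovers the true
category of every detectable ASV).

Bead calibration on its own:

```r
absolute_load(cell_events = 48000, bead_events = 360, beads_added = 1e5,
              dilution_factor = 150, sample_mass = 0.1)
#> absolute_load: 2e+10 bacteria/g (48000 cells / 360 beads, 100000 beads added, 150x dilution, 0.1 g)

fold_ratio(7.2, 2.0)   # fold difference of two median coated fractions
#> [1] 3.6
```

## Vignette

`vignettes/multi-ig-coating.Rmd` describes the model and its
assumptions, the generator's design and what it does and does not
emulate, numerical conventions (gating ties, rounding of printed
percentages, pseudocounts), and known limitations.
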