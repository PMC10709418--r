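---
title: "Methods: quantifying multi-immunoglobulin coating of gut bacteria"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying multi-immunoglobulin coating of gut bacteria}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(igcoat)
```

`igcoat` analyses immunoglobulin coating of intestinal bacteria in
cohorts where each IgA-deficient (IgA−) subject is paired with an
IgA-sufficient (IgA+) member of the same household. Pairing controls
for the strong household effect on gut microbiota composition, so that
differences in coating can be attributed to the antibody repertoire
rather than to lifestyle. This vignette explains the models and
conventions behind each stage, the choices made where the design was
genuinely open, and what the synthetic-data tests do and do not show
about real data.

## Flow-cytometry quantification

An acquisition is a table of events with fluorescence intensities for
DAPI and each stained isotype channel, plus a flag for counting beads.
Two conventions matter:

* **Gating.** Positivity thresholds come from fluorescence-minus-one
  (FMO) controls: the threshold for a channel is the nearest-rank
  empirical quantile (default 0.999) of that channel's FMO intensities.
  The nearest-rank rule keeps thresholds at observed intensity values.
  Positivity is *strict* (`intensity > threshold`): an event tied with
  the gate is negative, the conservative choice. By construction a
  0.999-quantile gate lets roughly 0.1 % of truly negative events
  through; on simulated data this appears as a small (≈2–3 %) upward
  relative bias in recovered coating fractions, which is a property of
  quantile-based FMO gating itself, not of the implementation.

* **Bead calibration.** With a known number of beads spiked into the
  tube, the absolute load is
  `(cell events / bead events) × beads added × dilution / mass`.
  The formula is pinned here, with every component retained in the
  result for audit; bead product and beads-per-tube are user inputs.
  The worked default geometry is a 150× dilution of a 100 mg/mL fecal
  homogenate. Zero observed bead events is a calibration error, never a
  division by zero.

Counts over the 2^k Boolean isotype combinations are reported relative
to DAPI⁺ non-bead events. The IgG1–4 subtype panel reuses the same
machinery at k = 4; panels are separate stains and are never joined at
event level. Combination loads are `total load × combination count /
gated total`, so they sum to the total load exactly.

## Sorted-fraction pre-processing

Reads from FACS-sorted fractions are decontaminated and filtered in a
fixed order:

1. **Control-based removal.** Any ASV reaching `control_min_count`
   reads (default 1 — the strictest reading of "appeared in a
   control") in any of the pre-sorting fluid, extraction blank or PCR
   control samples is removed from all samples.
2. **Joint prevalence/abundance filter.** An ASV is removed only when
   it *both* occurs in fewer than `min_prevalence` samples (default 2)
   *and* never exceeds `min_rel_abund` (default 10⁻⁴) relative
   abundance. The conjunction means a rare-but-abundant ASV (one
   sample, 20 %) survives, while a one-read singleton does not. The
   published analyses state the rule but not the numbers; the defaults
   here are deliberately conservative and surfaced in the run report.

Both steps are contractions: rows are dropped, counts are never
altered, and no rarefaction is performed — quantification later uses
flow-derived loads, not read depth.

## Coating categories

After pre-processing, an ASV's category is a set-theoretic statement
about where it was ever detected (`min_count` reads in at least one
sample, default 1):

* coated-in-IgA+ — any coated sorted fraction of any IgA+ subject;
* coated-in-IgA− — likewise via the IgM-based sorts of IgA− subjects;
* **shared** = both; **IgA-only** / **IgM-only** = exactly one;
* **strictly non-coated** = seen in a non-coated (triple-negative)
  fraction and in no coated fraction of any subject;
* **unobserved** otherwise.

Classification is cohort-level by default (an ASV coated in *any* IgA+
subject counts), matching how cohort totals are reported; a per-pair
classification is also available (`classify_asvs_per_pair`) for
prevalence-style analyses. Whether category membership should require
presence in more than one subject is not settled; the default is ≥ 1,
configurable via `min_count` and by filtering the presence matrix.
The implementation is checked against an exhaustive truth-table oracle
over all presence patterns.

Printed percentages follow the reporting convention of rounding to
whole percent at ≥ 10 % and one decimal below 10 % (`round_pct`), so
tests about printed values are well defined.

## From compositions to coated loads

The sorted fraction tells composition, the flow panel tells magnitude:
a taxon's coated load is its relative abundance among sorted coated
reads times the flow-derived load of the matching gate (the "any IgA"
marginal for IgA+ subjects, "any IgM" for IgA−). Dividing a family's
coated load by its bulk load (bulk relative abundance × total load)
gives the family coating frequency. Two conventions:

* Because numerator and denominator are independent estimates, noise
  can push a frequency above 1; such values are capped at 1 with a
  warning and counted, never silently.
* Per-subject averages include subjects where the family was undetected
  in the sorted fraction (zeros included); the alternative mean over
  detected subjects only is available by flag. For *cohort-level*
  family frequencies, `family_coating_summary` uses the ratio of
  average loads rather than the average of per-subject ratios: for
  sparse families the per-subject denominator can be a handful of
  reads, making the mean-of-ratios estimator unstable and upward
  biased, while the ratio-of-means pools reads across subjects.

Ratios between groups use either a plain fold ratio of positive
quantities or, for coated producer vs non-producer loads, the
pseudocount rule `t(v) = 1 if v = 0 else v + 1` applied to both sides,
which removes zero denominators while leaving large loads essentially
unchanged.

## Ligand and butyrate capability rules

Capabilities are called from per-taxon KEGG-ortholog (KO) sets with an
AND-of-OR rule engine: a capability holds when every requirement group
is hit by at least one of its alternative KOs. LPS is three-valued:
*none* without the complete Raetz core (UDP-GlcNAc → KDO₂-lipid A),
*penta* with the core alone, *hexa* when the secondary acyltransferase
extension is also present — so a hexa call always implies a satisfied
core. Butyrate additionally requires at least one complete precursor
route (succinate semialdehyde / acetoacetyl-CoA / vinylacetyl-CoA /
glutaconyl-CoA / butanal) plus a terminal butyrate-forming group.

The KEGG maps behind the rules are recorded (`map02040`, `map00540`,
`map00650`), but the exact KO membership is configuration data shipped
as an editable JSON table (`inst/extdata/ligand_rules.json`), not an
asserted fact: users mapping against a specific KEGG release should
review and edit the lists. The engine itself is validated against
brute-force enumeration over small KO universes.

## Statistics

All tests are nonparametric. Comparisons between household partners use
the Wilcoxon signed-rank test on pair differences — the standard
reading of a "paired Wilcoxon rank-sum" — with zero differences dropped
before testing so the exact null distribution (used up to 25
informative pairs without ties) remains available; above that, the
tie-corrected normal approximation with continuity correction.
Degenerate input (all differences zero) returns *p* = 1 with a message.
Spearman correlations use exact permutation p-values for n ≤ 10 without
ties and the t approximation otherwise; constant input yields a missing
coefficient. Fisher's exact test sums hypergeometric point
probabilities. FDR control is Benjamini–Hochberg, applied within
declared test families (one per analysis panel), and the significance
convention is *p* < 0.05 **and** *q* < 0.1.

## The synthetic cohort generator

`generate_cohort` emulates the study design so the whole pipeline can
be exercised end to end with known truth:

* **ASVs and taxonomy.** A fixed vocabulary of 22 common gut bacterial
  families (with phyla) so family-level summaries are comparable across
  runs; one Enterobacteriaceae ASV is flagged as an *Escherichia
  coli*-like taxon. Baseline composition splits family-level mean
  abundances log-normally across members; each subject's bulk
  composition is a Dirichlet-like perturbation of the baseline.
* **Coating structure.** Each ASV has a true category — shared,
  IgA-only, IgM-only or non-coated — with default probabilities chosen
  so roughly half of ASVs are coated and the coated half splits about
  evenly, mirroring reported cohort proportions. Coating probabilities
  of coated ASVs are Beta-distributed (defaults: IgA Beta(2, 8), IgM
  Beta(2, 20), IgG Beta(1.5, 15)); these values place the aggregate
  coated fractions near the scale reported for real cohorts (IgA ≈ 9 %
  of bacteria in IgA+ subjects, IgM ≈ 2 % in IgA−, IgG ≈ 1–2 % in
  both). In IgA− subjects the IgA coating probability is exactly zero;
  for shared ASVs a configurable fraction of it (default 0.25 to IgM,
  0.05 extra to IgG) reappears on the compensating isotypes.
* **Flow events.** The expected cell:bead event ratio inverts the bead
  formula, so calibration recovers the true load in expectation.
  Isotype states are independent Bernoulli per event by default; an
  optional copula parameter induces IgM/IgG co-coating. Intensities
  come from two log-normal components (negative around 30, positive
  around 5000 units, σ = 0.5 on the log scale), cleanly separable, and
  FMO tables are the negative component only.
* **Sorted reads.** A sorted sample is one multinomial draw whose
  source distribution mixes the true gated composition (weight =
  `sort_purity`, default 0.95), bulk carry-over (the remainder) and a
  contaminant pool (weight = `contamination_rate`, default 0.02). The
  pool is disjoint from the community by default — so control-based
  removal is unambiguous at truth level — with an overlap mode for
  stress tests; the same pool feeds the three negative controls at
  `seq_depth × contamination_rate` reads. The study does not report
  sort purity or control depths; these defaults are stated here as
  generator configuration, not inferred values.
* **KO profiles** are constructed per family from the shipped rule
  table: carrier taxa receive a complete requirement set, non-carriers
  within capable families an incomplete one, plus decoy KOs.

Everything is a pure function of the configuration seed; identical
configurations give byte-identical bundles.

### What the recovery tests show — problem sizes

The test suite and the acceptance script run the generator at the
study's conditions: 16 household pairs, 50,000 flow events per
acquisition, 20,000 reads per sorted sample, over 10–20 generator
seeds, with pure sorts (purity 1, contamination 0) for recovery
checks. Under those conditions classification recovers the true
category of every ASV whose expected coated read count is at least 5,
bead-calibrated loads land within a few percent of truth, and
cohort-level family coating frequencies (families with ≥ 20 expected
coated reads per sample) recover truth within 10 % relative error. The
null rejection rate of the paired Wilcoxon stays at its nominal level
over 1000 simulated null cohorts.

What this does *not* show: the generator draws independent isotype
states per event (real co-coating is correlated), uses cleanly
separable fluorescence components (no spillover, autofluorescence or
doublets), a contaminant pool disjoint from the community (real
reagent contamination overlaps it), and no sequencing error or chimera
structure. Passing tests therefore validate the *analysis logic* under
the stated statistical model, not instrument- or chemistry-level
robustness. At realistic sort purity (0.95) the cohort-level
classification is dominated by bulk carry-over — most detected ASVs
appear "shared" — which is exactly why the decontamination step, the
`min_count` presence threshold and per-pair classification exist; real
analyses should raise `min_count` when library cross-talk or impure
sorts are suspected.

## Known limitations

* Vendor FCS parsing, spectral compensation and doublet discrimination
  are out of scope; event tables must be pre-exported.
* ASV inference, taxonomy assignment and phylogenetics are upstream;
  the pipeline consumes count tables with taxonomy attached.
* The KO lists in the default rule table are a curated reconstruction
  of the named pathways and should be reviewed against the KEGG
  release in use.
* Coating frequencies compare two independent estimates; they are
  ratio statistics and inherit ratio-estimator bias for sparsely
  sequenced families (mitigated, not eliminated, by
  `family_coating_summary`).
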