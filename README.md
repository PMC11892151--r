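# PanScreen

Analysis pipeline for high-throughput screens of secreted heterologous
enzyme production across large *Saccharomyces cerevisiae* strain
libraries, and for the genomic and proteomic characterization of the
producer strains such screens identify.

A production screen of this kind assays hundreds of transformed strains by
a colorimetric enzyme assay in microplates — for a laccase, oxidation of
ABTS followed at 420 nm — and then asks which strains secrete
significantly more active enzyme than the laboratory reference strain
(BY4741), and what in their genomes and proteomes explains it. PanScreen
implements every downstream computational stage of that workflow:

1. **Kinetics** (`trimToLinear`, `activityFromFit`, `quantifyPlate`):
   each well's progress curve is trimmed to its linear range by an
   exhaustive longest-window search (window accepted when the
   least-squares fit reaches R² ≥ 0.999 over at least 10 readings), and
   the slope is converted to enzyme Units by the Beer–Lambert law,

   *U* = slope / (ε·l) × V(L) × 10⁶,

   with ε = 36 000 M⁻¹cm⁻¹ for oxidized ABTS and 1 U = 1 µmol substrate
   oxidized per minute.
2. **Hit calling** (`madValue`, `callPrimaryHits`, `secondaryScreen`,
   `combineDualScreen`): primary hits are strains whose activity exceeds
   median + 3·MAD over all screened strains, with
   MAD = 1.4826·median(|xᵢ − median(x)|); confirmed hits beat the
   reference strain in a replicated one-sided Welch test; two-enzyme
   screens are combined with per-strain categories and the Pearson
   correlation of activities.
3. **Pan-genome enrichment** (`retainVariableOrfs`, `fisherEnrichment`,
   `classifyCompensation`): ORFs whose presence differs between hits and
   the reference are tested hits-vs-rest with the two-sided Fisher exact
   test; depleted ORFs with a close enriched homolog (≥ 73% amino-acid
   identity by default) are relabeled *compensated*.
4. **Phylogeny** (`njTree`, `rootAtOutgroup`, `writeNewick`):
   neighbour-joining tree from a SNP distance matrix, rooted at the
   midpoint of a chosen outgroup's pendant edge, exported as Newick.
5. **qPCR** (`relativeExpression`, `activityPerMrna`): comparative-Ct
   (ΔΔCt) relative transcript levels against an internal reference gene
   and calibrator strain, and activity-per-mRNA ratios that separate
   transcriptional from post-transcriptional effects.
6. **Proteomics** (`replicateQC`, `medianNormalize`, `imputeMinProb`,
   `differentialAbundance`, `recurrenceFilter`, `cvProfile`,
   `pcaSamples`): post-quantification analysis of DIA protein intensity
   matrices — replicate exclusion below R² 0.85, median-scaling
   normalization, left-censored bottom-5% imputation with positive-draw
   sigma tuning, per-strain Welch tests versus the reference with
   two-fold / p ≤ 0.05 calls, and an at-least-50%-of-strains recurrence
   filter.
7. **Synthetic data** (`simulateScreen`, `simulatePangenome`,
   `simulateDistances`, `simulateProteomes`, `simulateQpcr`,
   `simulateSecondaryScreen`): seeded generators for every input format
   with planted ground truth, so each stage's recovery can be measured.

`runPipeline()` orchestrates the stages over plain CSV/TSV/Newick files
with a JSON run report; all randomness flows from one seed, and reruns
are byte-identical.

## Worked example

```r
library(PanScreen)

sim <- simulateScreen(nStrains = 600, nHits = 30, effectSize = 2, seed = 1)
act <- quantifyPlate(sim$kinetics, sim$layout,
                     KineticsParams(pathLength = 1))
perStrain <- tapply(act$activity_U, act$strain_id, mean)
hits <- callPrimaryHits(setNames(as.numeric(perStrain), names(perStrain)))
sum(hits$is_hit)
#> [1] 30
all(sim$truth$planted_hits %in% hits$strain_id[hits$is_hit])
#> [1] TRUE
signif(unique(hits$threshold_U), 3)
#> [1] 0.000193
```

The 30 planted 2× producers all clear the median + 3·MAD threshold of
1.93 × 10⁻⁴ U (the baseline strain activity is 2 × 10⁻⁴ U; measured
values sit slightly lower because the fitted linear window averages over
the gently saturating part of the curve), and no non-producer is called.
The same closed-form conversion underlies it: a slope of 0.036 AU/min at
ε = 36 000 M⁻¹cm⁻¹, a 1 cm path and 200 µL reaction is exactly
2.0 × 10⁻⁴ U.

The whole synthetic study, end to end:

```r
cfg <- pipelineConfig(seed = 1, outDir = "panscreen_run")
report <- runPipeline(cfg)
report$counts$n_primary_hits            # 30
report$counts$enrichment_classes        # enriched/compensated/depleted
report$counts$n_recurrent_up            # proteins up in >= 50% of hits
```

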