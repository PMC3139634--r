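# DecayCoupling

Comparative analysis of mRNA degradation and transcription between two yeast
species (*S. cerevisiae* and *S. paradoxus*) and their interspecific hybrid.

mRNA levels are set by the balance of transcription and degradation,
`TR = D × L` at steady state, where `D` is the first-order decay constant
(here the absolute slope of log2 abundance vs time, in log2 units/min;
half-life `= 1/D` min) and `L` the steady-state level. After chemical
transcriptional arrest, abundance is sampled at 0/20/40/60 min; because equal
amounts of total RNA are hybridized at each time point, the global decay is
masked and must be restored by re-anchoring each time point to an assumed
genome-wide half-life of 25 min (log2 abundance then falls 0.8 units per
20-min interval). Per-probe log-linear fits gated at R² ≥ 0.94 and aggregated
as the absolute median slope give per-gene rates; differential degradation
requires a median probe-level t-test p < 0.05 and a rate ratio above 1.4-fold,
differential expression a level ratio above 1.5-fold. Because
`log2(TR_cer/TR_par) = log2(D_cer/D_par) + log2(L_cer/L_par)`, divergence in
transcription is estimated from the other two. The package quantifies
*opposite coupling* — the species with faster degradation also transcribing
more, so the two changes partly cancel in mRNA level — classifies each
divergence as *cis* or *trans* from hybrid allele-specific data (cis effects
persist between alleles sharing a nucleus, trans effects are equalized),
tests regulator target-set enrichment of coupled genes, and calls diverged
transcription-factor binding sites in orthologous promoters by PSSM log-odds
scanning with asymmetric thresholds.

Everything runs on a first-class synthetic-data generator that emulates the
study design (probe-level two-species + hybrid microarray time courses with
known ground truth), so the whole pipeline is testable without any external
download. The methods vignette (`vignettes/decay-coupling-methods.Rmd`)
documents the model, the generator, and every numerical choice.

Who this is for: computational biologists studying post-transcriptional
regulation, regulatory evolution, or allele-specific expression who want a
tested, reusable implementation of decay-rate estimation from shut-off time
courses and of the coupling/cis-trans analyses built on it.

## Worked example

```r
library(DecayCoupling)

params <- simParams(nGenes = 1000, fracDivergedDecay = 0.11,
                    fracCoupledOpposite = 0.05, fracDivergedExpression = 0.5,
                    noiseSd = 0.05, seed = 1)
truth <- simulateGroundTruth(params)
de    <- globalScale(simulateTimecourse(truth))   # undo total-RNA masking
fits  <- fitDecay(de)                             # per-probe OLS, R² gate
div   <- divergenceTable(de, fits)                # D, L and TR divergence
rec   <- quadrantClassify(div)
c(n_sig_decay = sum(rec$sig_decay),
  n_coupled   = sum(rec$coupled_conservative))
#> n_sig_decay   n_coupled
#>         110          50

ct <- cisTransTable(de, fits, div)                # hybrid allele analysis
table(ct$label[ct$measure == "decay"])
#>  cis trans
#>   66    44
```

At this noise level recovery is essentially perfect: all 110 planted
differential-degradation genes are called (p < 0.05 and >1.4-fold), all 50
planted coupled-opposite genes are recovered under the conservative
definition, and the hybrid allele data classify the significant decay
differences into 66 cis and 44 trans — exactly the planted mechanisms, with
none excluded. `runPipeline(params)` runs
every stage — including target-set enrichment and diverged-motif calling on
simulated promoters — and returns one bundle with a config-hashed summary.

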