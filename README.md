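# detrem

Cell-type deconvolution of bulk RNA-seq against a single-nuclei RNA-seq
signature, with correction for the systematic per-gene capture differences
between the two technologies.

## The problem and who this is for

Bulk RNA-seq of a tissue sample measures a mixture: the average expression
of all cell types present, weighted by their abundance. Given a labelled
single-cell or single-nuclei reference, deconvolution estimates the
fraction *p<sub>k</sub>* of each cell type *k* in every bulk sample. For
tissues like frozen human brain, single-*nuclei* RNA-seq (snRNA-seq) is
the only practical reference — but nuclear sequencing captures genes
differently from whole-tissue sequencing, and deconvolution methods that
ignore this inherit the discrepancy as structured error, often calling
whole cell types absent. This package is for researchers with a labelled
snRNA-seq reference and a bulk RNA-seq cohort who want per-sample
cell-type fractions they can trust, plus the simulation and evaluation
machinery to verify that trust.

## The method

The estimator is an iterated weighted non-negative least squares (NNLS) in
the MuSiC family. From a multi-subject reference it builds a signature:
per-type relative mean expression θ<sub>kg</sub>, cross-subject variance
σ<sub>kg</sub>, and cell-size factors S<sub>k</sub>. Each bulk vector *y*
is modelled as

> y<sub>g</sub> = r<sub>g</sub> + Σ<sub>k</sub> p<sub>k</sub> S<sub>k</sub> θ<sub>kg</sub>

and solved by NNLS iterated with gene weights

> w<sub>g</sub> = 1 / (σ<sub>g</sub> + r<sub>g</sub>² + ν),  σ<sub>g</sub> = Σ<sub>k</sub> (S<sub>k</sub>θ<sub>kg</sub>)² σ<sub>kg</sub>

until proportions stabilize. The DeTREM extension measures each gene's
*capture quotient* Q<sub>g</sub> — the ratio of its normalized total
expression in the target bulk dataset to that in the reference — and
divides every iteration's weight by

> D<sub>g</sub> = max(1, 10·|log₂ Q<sub>g</sub>|),

so genes captured very differently by the two technologies lose influence
while concordant genes are untouched. With Q<sub>g</sub> ≡ 1 the method
reduces exactly to plain MuSiC-style weighting (`method = "music"`).

Also included: a pseudo-bulk simulator with known ground-truth fractions
and gamma- or quotient-derived capture bias; a fully synthetic
multi-subject snRNA-seq reference generator (so everything is testable
with no downloads); and an evaluation suite (Lin's CCC, Pearson r, RMSE,
exact-zero calls, min–max-scaled concordance with IHC / marker / density
measurements, neuron aggregation). See `vignettes/detrem-methods.Rmd` for
the full model and design notes.

## Worked example

Generate a synthetic reference, a capture-biased "real bulk" companion,
simulate a biased cohort from the measured quotient, and compare the base
weighting with the capture-penalized one:

```r
library(detrem)

spec <- synthetic_reference_spec()            # 5 types, 1000 genes, 4 subjects
ref  <- make_reference(spec, seed = 1)
sig  <- build_signature(ref)

companion <- make_biased_bulk_companion(spec, ref, n_samples = 24, seed = 3)
Q     <- quotient_bias(ref, companion$counts)
sim_b <- simulate_bulk(sig, synthetic_ranges(spec), n_samples = 50,
                       depth_range = c(1e5, 1e5), bias = bias_quotient(Q), seed = 4)

fit_m <- deconvolute(sim_b, sig, deconv_config("music"))
fit_d <- deconvolute(sim_b, sig, deconv_config("detrem"), reference = ref)
fit_d
#> <deconv_result> method: detrem | 50 samples x 5 cell types | 1000 genes
#>   converged: 50/50 samples
#> # A tibble: 5 × 6
#>   sample    AST     GAB   GLU    MIC    ODC
#>   <chr>   <dbl>   <dbl> <dbl>  <dbl>  <dbl>
#> 1 S1     0.0620 0.0119  0.926 0      0
#> 2 S2     0.114  0       0.886 0      0
#> 3 S3     0.158  0       0.829 0.0128 0
#> 4 S4     0.193  0.00410 0.700 0.0794 0.0229
#> 5 S5     0.166  0.0603  0.774 0      0

glance(evaluate_deconvolution(fit_m, sim_b$true_proportions))
#>   mean_ccc mean_r mean_rmse n_types total_zero_calls
#> 1    0.209  0.826     0.153       5               85
glance(evaluate_deconvolution(fit_d, sim_b$true_proportions))
#>   mean_ccc mean_r mean_rmse n_types total_zero_calls
#> 1    0.292  0.902     0.134       5               65
```

Each proportion row sums to one; zeros are exact (NNLS active set), so the
`total_zero_calls` column counts "cell type called absent" events. On this
capture-biased cohort the quotient penalty raises mean concordance (CCC
0.29 vs 0.21, r 0.90 vs 0.83), lowers error (RMSE 0.13 vs 0.15) and calls
fewer cell types absent (65 vs 85). On the matching *unbiased* cohort both
methods recover truth nearly perfectly (mean CCC 0.994, zero absent
calls) — the penalty only matters when capture differs.

Results are tibbles throughout and pipe into `tidy()`, `glance()`,
`autoplot()` and `plot_concordance(fit, truth)`.

A command-line interface covering the pipeline
(`synth | signature | simulate | deconv | evaluate`) is installed at
`inst/cli/detrem`; see `?detrem_cli`.

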