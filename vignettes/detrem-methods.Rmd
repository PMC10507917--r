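---
title: "Capture-bias-corrected cell-type deconvolution: model and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Capture-bias-corrected cell-type deconvolution: model and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Bulk RNA-seq measures the average expression of a tissue sample: a mixture
of the transcriptomes of its constituent cell types. Given a labelled
single-nuclei RNA-seq (snRNA-seq) reference for the same tissue,
deconvolution estimates the fraction of each cell type in every bulk
sample. In human brain, snRNA-seq is the practical reference technology
(nuclei can be isolated from frozen tissue where whole cells cannot), but
nuclear and whole-tissue sequencing capture genes differently: genes
enriched in cytoplasmic RNA are under-represented in the nuclear reference,
and vice versa. A deconvolution model fit across all genes inherits these
systematic capture differences as structured error, which in practice
drives estimates of whole cell types to zero.

`detrem` implements the DeTREM weighting scheme: an iterated weighted
non-negative least-squares (NNLS) estimator in the MuSiC family whose gene
weights are additionally penalized by a per-gene *capture quotient*
measuring how differently each gene is captured by the reference and
target technologies.

## Signature construction

From a gene-by-cell count matrix with per-cell `cell_type` and `subject`
labels (`reference_counts()`), `build_signature()` computes for every cell
type $k$ and gene $g$:

* $\theta_{kg}$ — the cross-subject mean of subject-level relative
  expression. Per subject $j$: the mean count over that subject's type-$k$
  cells, normalized to sum to one over genes. Subjects missing a
  (subject, type) combination are skipped.
* $\sigma_{kg}$ — the cross-subject variance of the same quantity,
  with the population ($1/n$) denominator so a single subject gives
  $\sigma = 0$ rather than `NA`.
* $S_k$ — the cell-size factor: the mean over subjects of the mean
  per-cell library size of type-$k$ cells. $S_k$ converts relative
  expression into each type's absolute RNA contribution.

`build_pooled_profile()` separately pools all cells of a type
($X_{kg} = \sum_{c \in C_k} X_{cg}$) and normalizes rows to one
($X'_{kg}$); this pooled profile is the mixing basis of the simulator.
Whether $X_{kg}$ is a per-type sum or mean is immaterial: the constant is
absorbed by the row normalization, and the sum is used. Genes with zero
counts in every cell are dropped at construction with a logged count; they
carry no signal and make downstream capture quotients undefined.

## The estimator

For one bulk vector $y$ (library-size normalized by default so bulk and
signature are on comparable relative scales), the model is
$y_g = r_g + \sum_k p_k\, S_k\, \theta_{kg}$, fit by iterating:

1. Solve NNLS on the $\sqrt{w}$-scaled system with design
   $D_{gk} = S_k \theta_{kg}$; proportions are the coefficients normalized
   to sum to one. NNLS is the Lawson–Hanson active-set algorithm
   (`pracma::lsqnonneg`), so inactive cell types get *exact* zeros — which
   is what makes "absent cell type" calls countable.
2. Compute residuals $r_g = y_g - \sum_k b_k S_k \theta_{kg}$ on the
   original (unweighted) scale.
3. Update weights $w_g = 1/(\sigma_g + r_g^2 + \nu)$ with
   $\sigma_g = \sum_k (S_k\theta_{kg})^2 \sigma_{kg}$: genes that are
   cross-subject-variable where they are most expressed, or that fit
   poorly, lose weight. $\nu$ (default $10^{-4}$) guards the denominator
   and caps weights at $1/\nu$.
4. Under `method = "detrem"`, divide $w_g$ by the capture penalty $D_g$
   (below).
5. Stop when no estimated proportion moves by more than `eps`
   (default 0.01) or after `max_iter` (default 1000) iterations.

The first pass is unweighted ($w \equiv 1$). On noiseless inputs drawn
from the model itself the first weighted solve reproduces the first
solution and the iteration is an immediate fixed point.

Two optional working-scale variants mirror the "C" and "N" switches of the
base method: `center` subtracts the mean of each working vector (the
weighted $y$ and each weighted design column) before every solve, and
`normalize` divides each by its standard deviation. Both are applied
per-vector immediately before the solve; negative entries produced by
centering are legitimate NNLS inputs (the constraint is on coefficients,
not data).

### The capture quotient and penalty

`quotient_bias()` sums expression per gene in the reference and in the
*whole* target bulk dataset, normalizes each total vector to sum to one
over the shared genes, and forms $Q_g = Y'_g / X'_g$ — the per-gene ratio
of normalized bulk capture to normalized single-nuclei capture. The
quotient is computed once per dataset and shared by all samples; genes
absent or unexpressed on either side are dropped from the working set with
a logged count.

The penalty is $D_g = \max(1,\; c\,|\log_2 Q_g|)$ with scale $c = 10$
(configurable as `penalty_scale`), and each iteration's weights become
$w'_g = w_g / D_g$. Genes captured similarly by both technologies
($|\log_2 Q_g| < 1/c$, i.e. within about 7% at the default scale) are
untouched; discordant genes lose weight in proportion to the log magnitude
of their capture difference. No gene weight is ever increased.

The published description of the clamp can also be read literally as
"keep $c|\log_2 Q|$ when it is below 1, else set it to 1, then divide" —
which would *divide by numbers smaller than one*, amplifying concordant
genes' weights without bound as $Q \to 1$ and contradicting the stated
objective that no gene weight be increased. The objective-consistent form
above is the default; the literal form is retained behind
`literal_clamp = TRUE` for auditability. With $Q_g \equiv 1$ the penalty
is identically 1 and `detrem` reduces *bit-for-bit* to `music`, which the
test suite asserts.

### Numerical choices and degenerate inputs

* Deconvolution is per sample; the residual of the published formulation
  sums over subjects, but with one sample per solve the two coincide, and
  per-sample estimates are what every downstream evaluation uses.
* Convergence is measured as the maximum absolute change in any
  proportion; defaults `eps = 0.01`, `max_iter = 1000`.
* Extreme weights can concentrate effective mass on fewer genes than cell
  types and make the weighted design rank-deficient (more likely under
  `center`); the solver then falls back to a ridge augmentation with a
  vanishingly small $\lambda$ scaled to the design.
* An all-zero bulk vector is an error (named by sample). An all-zero NNLS
  solution flags the sample non-converged and reports an `NA` proportion
  row rather than imputing a uniform — silent imputation would corrupt
  zero-call statistics.
* The dataset-level working gene set is the intersection of
  signature-expressed and bulk-expressed genes, in signature order, so
  results are invariant to bulk gene order.

## The pseudo-bulk simulator

`simulate_bulk()` draws, per sample: cell-type proportions $P_k$ uniform
on configurable ranges with one residual type set to $1 - \sum_k P_k$
(whole vectors with a negative residual are rejected and redrawn, which
preserves the uniform marginals conditional on feasibility; a
`max_attempts` guard errors on persistently infeasible ranges); a read
depth uniform on 8–12 million reads (configurable); and gene counts as a
single multinomial draw over the mixed relative abundances
$R_g \propto \sum_k P_k X'_{kg}$. One multinomial per sample is exactly
equivalent to assigning reads one at a time and far faster. Identical
seeds give bit-identical datasets.

Three bias models skew the mixing profile before row renormalization:
`bias_none()`; `bias_gamma(shape, rate)` with
$B_g = \log_2(\Gamma(a, x) + 1)$, the three benchmark parameterizations
being (0.25, 0.025), (0.75, 0.25) and (1.0, 0.5); and `bias_quotient(Q)`
which uses a capture quotient — typically measured from a real bulk
dataset against the reference — as the per-gene factor. Proportion ranges
are a required input; `brain_proportion_ranges()` ships plausible
human-cortex defaults (astrocytes 5–25%, endothelial 1–8%, microglia
2–12%, oligodendrocytes 10–40%, OPCs 1–8%, GABAergic neurons 5–20%,
glutamatergic neurons residual) that are package defaults, not cohort
estimates.

## The synthetic reference generator

`synthetic_reference_spec()` + `make_reference()` generate the labelled
multi-subject snRNA-seq reference every other module is tested against:
log-normal baseline gene means; a disjoint marker block per type whose
genes are folded up (default 8x) in that type only; multiplicative
log-normal per-subject gene effects (default log-SD 0.15) that create
genuine cross-subject variance in relative profiles — the quantity
$\sigma_{kg}$ estimates; log-normal per-cell library sizes (mean 2000,
log-SD 0.3) shared across types so cell-size factors are comparable; and
Poisson counts, with optional gamma-Poisson overdispersion
(`nb_dispersion`) since cross-subject variance estimation benefits from
realistic overdispersion. Poisson is the default because it keeps
brute-force oracles exact and simple.

`make_biased_bulk_companion()` emulates the "real bulk" dataset that
defines a capture quotient: pseudo-bulk from the reference's pooled
profiles at known proportions, with a planted per-gene capture factor
applied before read sampling. Most genes keep factor 1 and a minority
(default 25%) receive log-normal factors (log-SD 1.5), giving the
structure observed when real bulk capture is compared with a nuclear
reference: most genes relatively unchanged, roughly equal numbers shifted
up and down, a heavy tail of strongly discordant genes. The planted
factors are returned as ground truth so quotient estimates can be checked
against them.

Default sizes — 5 cell types, 1000 genes, 4 subjects, 100 cells per
subject-type, 50 bulk samples at depth $10^5$ — are the package's chosen
study conditions for end-to-end checks; full 8–12M-read depths are a
parameter away. What the generator does *not* emulate: transcript-length
and UMI effects, ambient RNA, doublets, batch structure, or
condition-dependent expression shifts. Passing end-to-end tests therefore
demonstrates correctness of the estimator under its own model assumptions
plus capture bias, not performance on any particular tissue or cohort.

## Evaluation

`evaluate_deconvolution()` scores estimates against ground truth per cell
type with Lin's concordance correlation coefficient
$\mathrm{CCC} = 2\,\mathrm{cov}(x,y) / (\mathrm{var}\,x + \mathrm{var}\,y
+ (\bar x - \bar y)^2)$ using population ($1/n$) moments (the sample-
variance alternative differs by $O(1/n)$), Pearson's $r$, and RMSE, plus
exact-zero counts. CCC is the headline metric for truth comparisons
because it penalizes location and scale shifts that $r$ forgives; CCC is
scale-dependent between percentages and fractions only if the two vectors
are rescaled differently, and fractions are used throughout.
`scaled_concordance()` compares estimates with an external per-sample
measurement (IHC fraction, marker expression, cell density): zero-estimate
samples are excluded first (configurable), then both retained vectors are
min–max scaled to $[0,1]$ and correlated; fewer than three retained pairs
reports `NA` with the reason. Exclusion precedes scaling so the scale is
that of the retained samples. `aggregate_neurons()` sums GABAergic and
glutamatergic estimates into a total-neuron column for pan-neuronal
markers such as NeuN. Mean CCCs across types are unweighted arithmetic
means skipping `NA` cells.

## Known limitations

* The quotient conflates technology capture differences with composition
  differences between the reference mix and the target tissue; strongly
  cell-type-specific genes can acquire $Q_g \neq 1$ without any capture
  bias, and the penalty will down-weight them too.
* When capture bias affects essentially every gene there is no concordant
  gene set left to favor, and the penalty cannot help; its advantage is
  largest when discordance is sparse.
* Per-type renormalization of a biased profile changes each type's
  normalizing constant, so even a perfectly fit biased dataset recovers
  proportions distorted by those constants; this affects any method fit to
  a biased mixture and bounds attainable CCC below one.
* The estimator assumes the reference types span the tissue; an absent or
  extra type biases all proportions.
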