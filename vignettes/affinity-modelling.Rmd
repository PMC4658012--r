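---
title: "Total binding affinity: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Total binding affinity: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(affinityscan)
```

This vignette is the package's own account of the science it implements:
the scoring model and its assumptions, the parameters that matter, what the
synthetic benchmarks do and do not emulate, and the numerical and design
decisions taken where more than one reasonable choice existed.

## The scoring model

A PWM `w` of length `l` assigns each window `r_i..r_{i+l-1}` of a sequence
a likelihood ratio against a background base-frequency model `b`, in both
strand orientations; the window's score is the natural log of the larger of
the two. Three sequence-level summaries are built from the window scores:

* **TBA** — `log` of the sum of `exp(score)` over all `L - l + 1` windows.
  This is a thermodynamically motivated quantity: each window contributes
  in proportion to its relative affinity, so weak sites are downweighted
  smoothly, never discarded.
* **Occupancy at cutoff C** — the same sum restricted to windows with
  `score >= C * S_max`, where `S_max` is the maximum score the PWM can
  achieve. At high `C` this is the classical discrete-binding-site view; as
  `C` decreases it converges to TBA exactly (once every window passes).
* **Sum of scores at cutoff C** — the arithmetic sum of the passing *log*
  scores, the whole-sequence score a site-enumeration tool produces. It
  weights sites on the wrong (log) scale, which is precisely why it is
  kept: as a baseline.

Assumptions inherited from this model family: positions within a site
contribute independently (the PWM factorization), a single mononucleotide
background describes non-site sequence, and the two strands are scanned
symmetrically with no orientation preference.

The expression model is log-linear: for gene `g`,
`e_g = sum_i c_i a_g(i) + b + r_g`, with `a_g(i)` the affinity of gene
`g`'s regulatory region for PWM `i`. Its assumptions are deliberately
strong — a common basal level, additive PWM contributions, no
activator/repressor context switching, no cooperativity — because its
purpose is measuring *variance explained*, which is invariant under any
invertible change of basis of the predictors (tested property), not
interpreting individual coefficients.

## Parameters and defaults

| Parameter | Default | Units | Why |
|---|---|---|---|
| promoter `up` / `down` | 1500 / 500 | bp around TSS | the standard proximal-promoter window for single-TSS genes |
| cutoff grid | 0.1 .. 1.0, step 0.1 | fraction of `S_max` | ten equally spaced cutoffs plus TBA give the 11-value sweep |
| count-matrix zeros | replaced by 1 | counts | keeps probabilities strictly positive without disturbing observed counts |
| probability-matrix pseudocount | 1e-6 | probability | below the smallest nonzero probability of typical collections; a warning fires if not |
| background | uniform 0.25 | frequency | well-defined scores without a genome; estimate from intergenic FASTA (`background_from_fasta`) for genome work |
| expression pseudo-count | smallest nonzero value, per table | expression units | makes `log2` defined at 0 while preserving order |
| CV folds | 10 | — | standard; fold assignment is seeded and reproducible |
| lasso penalty | CV-error minimizing (`lambda.min`) | — | the stated selection rule; deliberately liberal, see below |

## Numerical choices

* **All windows, half-open coordinates.** Every one of the `L - l + 1`
  full-length windows is scored (an index bound of `L - l` would silently
  drop the last window). Genomic intervals are 0-based half-open (BED).
  The minus-strand promoter is the mirrored window `[tss-down, tss+up)`.
* **Cutoff comparison.** The threshold test is `score >= C*S_max - tol`
  with `tol = 1e-9 * max(1, |S_max|)`. A strict `>` would make occupancy at
  `C = 1` empty even at a perfect consensus site; the relative tolerance
  guarantees the top site always passes at `C = 1` despite floating-point
  rounding.
* **`S_max` with asymmetric backgrounds.** Because the reverse-orientation
  ratio divides by the background of the *plus-strand* base, the forward
  per-position maximum does not bound reverse-orientation scores when the
  background is not strand-symmetric (`P(A) != P(T)`). `s_max()` therefore
  maximizes each orientation separately and takes the larger, which is the
  true maximum (verified by exhaustive enumeration in the tests). For
  strand-symmetric backgrounds the two coincide.
* **Empty occupancy is `-Inf`, not an error.** "No site above the cutoff"
  is a legitimate, lowest-possible prediction: `-Inf` values rank below all
  finite scores in ROC analysis (ties among themselves count 1/2) and are
  serialized as `-inf` in TSV output. A sequence with *no scorable window
  at all* (too short, all N/masked) is the genuinely distinct error case,
  and becomes a reported missing cell in `score_matrix()`.
* **Log-sum-exp.** TBA sums are computed with the max-shifted log-sum-exp
  to avoid overflow; all logs are natural. AUCs are rank-based and
  unaffected by the log base; regression coefficients simply scale.
* **Masked windows.** Windows covering an N or masked base are skipped
  entirely. Multi-interval regions are concatenated with one masked
  junction base so no window spans a gap, making the region's TBA exactly
  the (affinity-scale) sum of its intervals' TBAs — one value per gene,
  consistent with masking semantics.
* **Negative `S_max`.** For a PWM worse than background everywhere,
  `C * S_max` *rises* toward 0 as `C` grows, so higher cutoffs admit more
  windows. The formula is applied literally; such PWMs are pathological
  and the behavior is documented rather than special-cased.
* **Cross-validated R².** Per fold, `1 - RSS/TSS` on the held-out genes
  (TSS around the held-out mean), averaged over folds. Rank-deficient
  training folds fall back to a pivoted least-squares fit with the aliased
  coefficients at zero.

## Open design decisions, and how they were settled

* **Renormalization after the 1e-6 pseudocount** on probability matrices:
  applied, so every emitted PWM satisfies the strictly-positive,
  column-sums-to-1 invariant that the rest of the package (and its tests)
  rely on. At 1e-6 the effect on scores is negligible.
* **Fully closed promoters** (every base in a closed chromatin state):
  the gene is dropped from the expression model and reported, rather than
  assigned zero affinity — a zero would be an arbitrary point on the
  affinity scale, while dropping keeps the fitted model interpretable.
  `extract_sequences()` and the pipelines list the affected genes.
* **Genes with `-Inf` occupancy** in a design matrix are likewise dropped
  listwise by `fit_linear()` (with the gene ids recorded on the fit), since
  OLS cannot consume infinities and any finite substitute would be a tuning
  knob.
* **Lasso standardization**: predictors are standardized inside the lasso
  only (coefficients reported on the original scale); OLS is fitted
  unstandardized. The penalty follows the plain CV-minimum rule, not the
  1-SE rule — `lambda.min` keeps more weakly-supported predictors, which is
  the stated selection criterion, and the tests treat its liberality as
  expected behavior (full true support recovered; some nulls retained).
* **Per-table expression pseudo-counts**: each cell line's table gets its
  own smallest-nonzero pseudo-count; genes at zero in one line but not
  others are retained (the pseudo-count handles them).
* **Paired AUC comparisons** use the exact signed-rank distribution up to
  25 pairs and the tie-corrected normal approximation above; all-tied
  inputs return p = 1 rather than NaN.

## What the synthetic benchmarks emulate — and what they do not

The generators reproduce the *statistical structure* of the real analyses:
planted-motif positives vs background negatives stand in for ChIP-seq
peaks vs control peaks; expression is simulated forward from the log-linear
model; segmentations use the 15-label state vocabulary with two closed
states. Defaults chosen once and used throughout the tests and the
acceptance script:

* **Binding benchmark** (`make_binding_benchmark`): 300 positives and 300
  negatives of 500 bp. For the cutoff-sweep comparison the planted motifs
  are 18 bp at ~0.55 bits/position with 5 sites per positive, sampled
  *faithfully* from the PWM (`site_strength = 1`). Faithful sampling from a
  long, moderate-information matrix yields a broad mixture of weak and
  occasionally strong sites — the regime where transient low-affinity
  binding carries the signal, and the regime that separates TBA from
  high-cutoff occupancy. Shorter or sharper motifs move the AUC collapse
  to higher cutoffs.
* **Expression recovery**: 2000 genes, 25 random 8-bp PWMs on 200-bp
  regions, residual noise matched to the signal standard deviation
  (signal-to-noise 1), so the expected fraction of variance explained is
  0.5 analytically and estimated coefficients should sit within their
  standard errors.
* **Chromatin refinement**: 40 genes with consensus sites planted 2-3 kb
  upstream of the TSS — outside the fixed promoter but inside the open
  segment that the refined region extends into — with expression driven by
  the planted-site count.

What passing these benchmarks does **not** show about real data: real
peak sets have length distributions, composition biases and positional site
enrichment that i.i.d. background sequences lack; real PWM collections are
redundant and correlated; real expression has heavy tails, batch structure
and biological covariates outside any sequence model; and real chromatin
segmentations have state-specific length distributions rather than
exponential tiles. The benchmarks validate the machinery and the *direction*
of the documented effects, not the published effect sizes, which depend on
genome-scale data.

## Known limitations

* Mononucleotide background only; no dinucleotide or higher-order models.
* One PWM at a time; no site competition, cooperativity or TF-TF
  interaction terms, and no principal-component or interaction variants of
  the expression model.
* Regions assume single-TSS genes; callers must pre-filter multi-TSS
  genes.
* The scanner is vectorized base R, adequate for promoter-scale inputs
  (thousands of regions times hundreds of PWMs); chromosome-scale scans
  would want a compiled backend.
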