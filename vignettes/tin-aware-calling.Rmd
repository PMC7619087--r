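---
title: "Somatic variant calling with a contaminated matched normal"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Somatic variant calling with a contaminated matched normal}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tincaller)
```

## The problem

Somatic variant calling contrasts a tumour sample against a matched
"normal" sample: variants present in both are filtered as germline. In
haematological malignancies this logic breaks down, because the matched
normal — purified T cells, buccal swabs — frequently carries a fraction of
the malignant clone itself (tumour-in-normal contamination, TiN). A
genuine somatic variant then shows a small but real alt-read signal in the
normal sample and is discarded as germline. At TiN levels of 10–20%, a
conventional caller can silently lose a large share of the true somatic
call set.

`tincaller` treats the matched normal the same way as the tumour sample:
each carries its own *aberrant cell fraction* — `alpha_t` for the tumour
(its purity) and `alpha_n` for the normal (the TiN level) — and the
likelihood of both samples is evaluated jointly over every genotype
configuration the local copy-number state allows.

## The model

At a biallelic site, a *genotype pair* `(k_g, k_t)` specifies how many
chromosomal copies carry the mutant allele in a normal cell
(`k_g` of `cn_normal`) and in a tumour cell (`k_t` of `cn_tumour`).
Pairs are labelled `REF` (`k_g = k_t = 0`), `SOMATIC` (`k_g = 0`,
`k_t >= 1`) and `GERMLINE` (`k_g >= 1`). The full
`(cn_normal + 1) x (cn_tumour + 1)` grid is enumerated with no
evolutionary constraint linking the two — loss of heterozygosity can
remove germline alleles from the tumour genome, so no pair is ruled out
a priori.

For a sample with aberrant cell fraction $\alpha$, a read at the site
originates from a tumour cell with probability

$$\pi = \frac{\alpha\,c_t}{\alpha\,c_t + (1-\alpha)\,c_n},$$

where $c_t, c_n$ are the tumour- and normal-cell copy numbers; the cell
classes contribute in proportion to cell fraction *times* local copy
number. Given the pair, the mutant-allele fractions are $f_t = k_t/c_t$
and $f_g = k_g/c_n$, and the probability of observing the alt base on one
read, under a uniform four-base error model with miscall probability $e$,
is

$$P(\text{alt}) = \pi\left[f_t(1-e) + (1-f_t)\tfrac{e}{3}\right] +
  (1-\pi)\left[f_g(1-e) + (1-f_g)\tfrac{e}{3}\right].$$

The sample likelihood is the product over its reads; the tumour sample is
evaluated at $\alpha_t$ and the normal sample at $\alpha_n$ with the same
machinery. The posterior over pairs combines both likelihoods with a
prior that places `1 - prior_snp - prior_somatic` on the reference pair
and splits `prior_snp` and `prior_somatic` equally over the germline and
somatic pairs respectively. A site is called `SOMATIC` when the aggregate
somatic posterior reaches `somatic_threshold`, then `GERMLINE`, then
`REF`, else `UNCLASSIFIED`.

```{r}
p <- tin_params(alpha_t = 0.8, alpha_n = 0.10)
site_posterior(list(t_depth = 40, t_alt = 16, n_depth = 40, n_alt = 2),
               list(cn_normal = 2, cn_tumour = 2), p)
```

Two alt reads in forty is exactly what 10% TiN predicts for this
heterozygous somatic variant, so the TiN-aware posterior stays somatic; a
caller assuming a clean normal must instead explain those reads as either
error or germline signal, and loses confidence as the count grows.

## Parameters and defaults

* `alpha_t` — tumour purity, taken as given (from a copy-number/purity
  tool or study design); default 1.0 (pure tumour) as the neutral choice.
* `alpha_n` — TiN level; default 0.10. In contaminated haematological
  cohorts observed TiN spans roughly 0–18%, and a fixed 10% assumption is
  usually sufficient to recover genuine variants, making it a sensible
  production default when estimation is not wanted. `alpha_n` and
  `alpha_t` are independent; no ordering is imposed.
* `base_error` — per-read miscall probability in counts mode, default
  0.01 (Phred 20); per-read qualities override it when supplied.
* `prior_snp = 1e-4`, `prior_somatic = 6e-6` — conventional whole-genome
  caller priors (about one het SNP per 10 kb; somatic rate orders of
  magnitude lower).
* `somatic_threshold = 0.95` — posterior mass required to classify.

All likelihood work is in log space with max-subtraction normalisation;
a site where every pair has zero likelihood (possible only with
error-free per-read qualities and contradictory reads) falls back to a
uniform posterior flagged `UNCLASSIFIED` rather than erroring.

## Estimating the TiN level

`estimate_tin()` profiles the total log marginal likelihood of candidate
sites over a grid of `alpha_n` values (default step 0.005 up to 0.5),
summing genotype pairs out at each site. A grid search was chosen over EM
because the problem is one-dimensional and bounded, and every grid value
is exactly checkable against direct summation. Candidate sites are gated
deterministically (tumour VAF ≥ 0.10, normal VAF ≤ 0.35, both depths
≥ 10) to enrich for somatic variants, whose normal-sample alt counts are
what carry information about `alpha_n`; fewer than 50 survivors flags the
estimate low-confidence. Ties break toward smaller `alpha_n`, and the
interval reported collects grid values within 1.92 log-units of the
maximum. Whether to estimate `alpha_n` jointly with `alpha_t` was an open
design choice; conditioning on a given `alpha_t` keeps the estimator
exact, fast and auditable, and matches how purity is obtained in practice
(from copy-number tools).

```{r}
co <- simulate_cohort(500, tin_grid = 0.10,
                      params = tin_params(alpha_t = 0.8), seed = 1,
                      t_depth = 60, n_depth = 60, classes = "SOMATIC")
estimate_tin(co$sites, NULL, tin_params(alpha_t = 0.8))
```

## Indel rescue by germline log odds

Indel callers flag candidates "present in matched normal" and discard
them; under TiN those flags are often wrong. `glod_score()` contrasts two
binomial models of the normal-sample alt count: germline-heterozygous
(success probability `0.5 * xi`, with `xi = 0.9` absorbing the
systematic underestimation of indel VAFs) versus TiN-consistent somatic
(expected normal VAF = tumour VAF scaled by `alpha_n / alpha_t`, clamped
to `[1e-3, 0.5]`). `rescue_indels()` recovers a flagged candidate when
the log10 odds fall below 0. This functional form is a reconstruction of
a previously described filtering step whose formulas are not public;
every constant is configurable, and the gate is deliberately the entire
indel treatment — indel error profiles differ enough from SNVs that
re-running the full genotype model would suggest more precision than the
data support.

## CCF and clone trajectories

`variant_ccf()` converts VAF to cancer cell fraction with the standard
purity/copy-number/multiplicity correction, estimating multiplicity by
rounding `vaf * (alpha_t*cn_t + (1-alpha_t)*cn_n) / alpha_t` into
`[1, cn_t]` — the usual subclonal-reconstruction convention.
`clone_ccf()` implements the convention that makes whole-genome and
targeted timepoints commensurable on one fishplot: clone CCF is double
the median VAF of its diploid autosomal member SNVs, capped at 1.

`coordination_check()` encodes the longitudinal quality requirement that
a clone's member variants move together over time. Thresholds are
reconstructions of an unquantified requirement: a consecutive-timepoint
shift is informative when the median VAF change — or the median change
*magnitude*, so that symmetric anti-coordination cannot hide behind a
zero median — exceeds twice the pooled binomial standard error, and an
informative shift requires 80% of members to agree with the majority
direction. Clones with fewer than 3 members or 2 timepoints are reported
`UNSCORED` rather than judged.

`export_fishplot_table()` emits the long-format (clone, parent,
timepoint, CCF) table for fishplot-style rendering after nesting repair.
Constraints (child ≤ parent; siblings sum ≤ parent; top-level clones
under an implicit root of CCF 1) are enforced *exactly* on output —
downstream renderers reject even tiny violations — while only repairs
exceeding 0.05 CCF, the range attributable to sampling noise at typical
depths, are reported as genuine repairs. Cyclic parent relations are a
hard error.

## The simulator and what the benchmark shows

`simulate_cohort()` draws per-site alt counts binomially with expected
alt probabilities computed by the *same* per-read model used for
calling: truth classes `REF` (0,0), `GERMLINE_HET` (1,1) and `SOMATIC`
(0, m) with multiplicity uniform on `1..cn_tumour`. Defaults mirror the
benchmark's study conditions: tumour purity 0.8, tumour depth 80, normal
depth 40, error 0.01, TiN grid {0, 0.05, 0.10, 0.20} spanning the 0–18%
range seen in contaminated cohorts. A master seed drives a counter-based
substream per site, so any subset regenerates identically.

Because generator and model share the read-level formula, the benchmark
isolates the effect of the TiN assumption itself: `run_benchmark()`
scores sensitivity, specificity, and the fraction of baseline-missed
somatic sites (missed when assuming `alpha_n = 0`) that each TiN-aware
configuration recovers. At true TiN 0.10–0.20 the matched configuration
recovers essentially all baseline misses while leaving germline
heterozygotes untouched. What passing this benchmark does *not* show:
real data add mapping artefacts, strand and position biases, non-uniform
error profiles, subclonal tumour structure and copy-number
mis-specification, none of which the simulator emulates. The benchmark
validates the statistical engine, not an end-to-end pipeline on real
reads.

Problem sizes throughout the test-suite and the reproduction script —
1,000 sites per class and TiN level for calling benchmarks, 500-site
cohorts at depth 60 across 10 replicate seeds for estimator recovery —
were chosen as the smallest sizes at which the binomial sampling noise of
the reported rates is comfortably below the margins being tested.

## Known limitations

* Biallelic sites only; multi-allelic records must be split upstream.
* Counts mode collapses the four-base error model onto ref/alt; the two
  unobserved bases are not tracked.
* Timepoints are called independently; no joint multi-timepoint
  likelihood.
* `alpha_n` is genome-wide; per-chromosome TiN is out of scope.
* The simulator does not generate indels, LOH germline sites (available
  behind `classes=` composition choices only as REF/het/somatic), or
  read-level artefacts.
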