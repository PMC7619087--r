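#' Simulate one site's paired read observations with known truth
#'
#' Draws tumour and normal alt counts binomially with expected alt
#' probabilities computed by the *same* per-read observation model used
#' for calling ([read_prob()]): the generator and the likelihood agree by
#' construction, so discrepancies in benchmarks reflect the caller, not
#' the simulator. Somatic sites use the pair `(0, m)` with multiplicity
#' `m` drawn uniformly from `1..cn_tumour`; germline heterozygotes use
#' `(1, 1)`; reference sites `(0, 0)` (alt reads then arise only from
#' sequencing error).
#'
#' @param true_class `"REF"`, `"GERMLINE_HET"` or `"SOMATIC"`.
#' @param params A [tin_params()] supplying the *true* `alpha_t`,
#'   `alpha_n` and `base_error`.
#' @param t_depth,n_depth Read depths for the two samples.
#' @param cn_normal,cn_tumour Locus copy numbers (default diploid).
#' @param seed Substream seed for this site (see [simulate_cohort()]).
#' @return A list with `site` (a one-row data frame in count-table
#'   layout) and `truth` (a one-row truth record).
#' @export
simulate_site <- function(true_class, params, t_depth, n_depth,
                          cn_normal = 2, cn_tumour = 2, seed = 1L) {
  stopifnot(t_depth >= 1, n_depth >= 1,
            true_class %in% c("REF", "GERMLINE_HET", "SOMATIC"))
  params <- as_tin_params(params)
  set.seed(seed)
  k <- switch(true_class,
              REF = c(0L, 0L),
              GERMLINE_HET = c(1L, 1L),
              SOMATIC = c(0L, sample.int(max(cn_tumour, 1L), 1L)))
  e <- params$base_error
  f_t <- if (cn_tumour > 0) k[2L] / cn_tumour else 0
  f_g <- if (cn_normal > 0) k[1L] / cn_normal else 0
  p_t <- read_prob(TRUE, e, f_t, f_g,
                   tumour_read_fraction(params$alpha_t, cn_tumour,
                                        cn_normal))
  p_n <- read_prob(TRUE, e, f_t, f_g,
                   tumour_read_fraction(params$alpha_n, cn_tumour,
                                        cn_normal))
  t_alt <- stats::rbinom(1L, t_depth, p_t)
  n_alt <- stats::rbinom(1L, n_depth, p_n)
  site <- data.frame(chrom = "1", pos = NA_integer_, ref = "A", alt = "T",
                     t_depth = t_depth, t_alt = t_alt,
                     n_depth = n_depth, n_alt = n_alt,
                     stringsAsFactors = FALSE)
  truth <- data.frame(chrom = "1", pos = NA_integer_,
                      true_class = true_class,
                      k_g = k[1L], k_t = k[2L],
                      true_alpha_t = params$alpha_t,
                      true_alpha_n = params$alpha_n,
                      expected_t_vaf = p_t, expected_n_vaf = p_n,
                      t_depth = t_depth, n_depth = n_depth,
                      error = e, site_seed = seed,
                      stringsAsFactors = FALSE)
  list(site = site, truth = truth)
}

# Per-site substream seed derived from the master seed; keeps every site
# independently reproducible and all values below 2^31.
site_substream <- function(seed, index) {
  as.integer((as.double(seed) * 1000003 + as.double(index) * 7919) %%
               2147483629)
}

#' Simulate a benchmarking cohort across TiN levels
#'
#' For each TiN level in `tin_grid`, generates `n_per_class` sites of
#' each requested class at the given depths. A single master seed drives
#' a counter-based substream per site, so any subset of sites is
#' reproducible independently of the rest. The output count table feeds
#' [call_snvs()] unchanged.
#'
#' @param n_per_class Sites per class per TiN level.
#' @param tin_grid True `alpha_n` levels to simulate (default spans the
#'   0-20% range typical of contaminated haematological cohorts).
#' @param params A [tin_params()]; its `alpha_t` and `base_error` are the
#'   simulation truth (`alpha_n` is overridden per grid level).
#' @param seed Master integer seed.
#' @param t_depth,n_depth Read depths (default 80 tumour / 40 normal).
#' @param classes Which truth classes to generate.
#' @param cn_normal,cn_tumour Locus copy numbers (default diploid).
#' @return A list with `sites` (count-table data frame) and `truth`
#'   (matching truth records including `true_tin`).
#' @examples
#' cohort <- simulate_cohort(5, tin_grid = c(0, 0.1),
#'                           params = tin_params(alpha_t = 0.8), seed = 1)
#' table(cohort$truth$true_class, cohort$truth$true_tin)
#' @export
simulate_cohort <- function(n_per_class, tin_grid = c(0, 0.05, 0.10, 0.20),
                            params = tin_params(alpha_t = 0.8),
                            seed = 1L, t_depth = 80, n_depth = 40,
                            classes = c("REF", "GERMLINE_HET", "SOMATIC"),
                            cn_normal = 2, cn_tumour = 2) {
  params <- as_tin_params(params)
  sites <- list()
  truths <- list()
  idx <- 0L
  for (tin in tin_grid) {
    p <- tin_params(alpha_t = params$alpha_t, alpha_n = tin,
                    base_error = params$base_error,
                    prior_snp = params$prior_snp,
                    prior_somatic = params$prior_somatic,
                    somatic_threshold = params$somatic_threshold)
    for (cls in classes) {
      for (i in seq_len(n_per_class)) {
        idx <- idx + 1L
        sim <- simulate_site(cls, p, t_depth, n_depth,
                             cn_normal, cn_tumour,
                             seed = site_substream(seed, idx))
        sim$site$pos <- idx
        sim$truth$pos <- idx
        sim$truth$true_tin <- tin
        sites[[idx]] <- sim$site
        truths[[idx]] <- sim$truth
      }
    }
  }
  if (idx == 0L) {
    return(list(sites = data.frame(), truth = data.frame()))
  }
  list(sites = do.call(rbind, sites), truth = do.call(rbind, truths))
}

#' Benchmark TiN-aware calling against the simulation truth
#'
#' Calls every simulated site under each assumed `alpha_n` configuration
#' and scores, per true TiN level: sensitivity (true somatic sites
#' classified somatic), specificity (germline-het and reference sites
#' *not* classified somatic), and the rescued fraction — among true
#' somatic sites missed by the `alpha_n = 0` baseline (the conventional
#' caller that assumes a clean normal), the fraction recovered by each
#' TiN-aware configuration. The baseline is always computed internally,
#' whether or not 0 is among the requested configurations. Undefined
#' rates (empty denominators) are reported as `NA`, never 0.
#'
#' @param cohort Output of [simulate_cohort()] (or a compatible
#'   `list(sites, truth)`).
#' @param assumed_alpha_n Caller configurations to evaluate.
#' @param params Calling parameters; `alpha_t` should match the cohort's
#'   truth, `alpha_n` is overridden per configuration.
#' @return A data frame with one row per (true TiN, assumed `alpha_n`):
#'   `sensitivity`, `specificity`, `rescued_fraction` and the counts
#'   behind them.
#' @export
run_benchmark <- function(cohort,
                          assumed_alpha_n = c(0, 0.05, 0.10, 0.20),
                          params = tin_params(alpha_t = 0.8)) {
  params <- as_tin_params(params)
  sites <- cohort$sites
  truth <- cohort$truth
  stopifnot(nrow(sites) == nrow(truth))
  out <- list()
  if (nrow(sites) == 0L) {
    return(data.frame(true_tin = numeric(0), assumed_tin = numeric(0),
                      sensitivity = numeric(0), specificity = numeric(0),
                      rescued_fraction = numeric(0),
                      n_somatic = integer(0), n_non_somatic = integer(0),
                      n_missed_baseline = integer(0)))
  }
  call_with <- function(idx, a) {
    p <- tin_params(alpha_t = params$alpha_t, alpha_n = a,
                    base_error = params$base_error,
                    prior_snp = params$prior_snp,
                    prior_somatic = params$prior_somatic,
                    somatic_threshold = params$somatic_threshold)
    call_snvs(sites[idx, , drop = FALSE], NULL, p)$classification
  }
  for (tin in unique(truth$true_tin)) {
    idx <- which(truth$true_tin == tin)
    is_som <- truth$true_class[idx] == "SOMATIC"
    baseline <- call_with(idx, 0)
    missed <- is_som & baseline != "SOMATIC"
    for (a in assumed_alpha_n) {
      cls <- if (a == 0) baseline else call_with(idx, a)
      sens <- if (any(is_som)) mean(cls[is_som] == "SOMATIC") else NA_real_
      spec <- if (any(!is_som)) mean(cls[!is_som] != "SOMATIC")
              else NA_real_
      resc <- if (any(missed)) mean(cls[missed] == "SOMATIC")
              else NA_real_
      out[[length(out) + 1L]] <- data.frame(
        true_tin = tin, assumed_tin = a,
        sensitivity = sens, specificity = spec,
        rescued_fraction = resc,
        n_somatic = sum(is_som), n_non_somatic = sum(!is_som),
        n_missed_baseline = sum(missed))
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Reshape a benchmark result into a long summary table
#'
#' One row per (true TiN, assumed `alpha_n`, metric), with the count the
#' metric was estimated from; deterministic ordering, round-trippable at
#' 6 decimals.
#'
#' @param result Output of [run_benchmark()].
#' @param path Optional TSV output path.
#' @return The long-format data frame
#'   (`true_tin`, `assumed_tin`, `metric`, `value`, `n`).
#' @export
summarize_recovery <- function(result, path = NULL) {
  metrics <- c(sensitivity = "n_somatic",
               specificity = "n_non_somatic",
               rescued_fraction = "n_missed_baseline")
  rows <- list()
  if (!is.null(result) && nrow(result)) {
    result <- result[order(result$true_tin, result$assumed_tin), ,
                     drop = FALSE]
    for (i in seq_len(nrow(result))) {
      for (m in names(metrics)) {
        rows[[length(rows) + 1L]] <- data.frame(
          true_tin = result$true_tin[i],
          assumed_tin = result$assumed_tin[i],
          metric = m,
          value = round(result[[m]][i], 6),
          n = result[[metrics[[m]]]][i])
      }
    }
  }
  long <- if (length(rows)) do.call(rbind, rows) else
    data.frame(true_tin = numeric(0), assumed_tin = numeric(0),
               metric = character(0), value = numeric(0), n = integer(0))
  rownames(long) <- NULL
  if (!is.null(path)) {
    utils::write.table(long, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  long
}
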