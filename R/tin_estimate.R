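#' Select candidate sites for TiN estimation
#'
#' Keeps sites whose read evidence is informative about the normal
#' sample's aberrant cell fraction: a clear somatic-like signal in the
#' tumour (alt fraction at least `vaf_min`), a normal alt fraction below
#' the germline-heterozygote range, and adequate depth in both samples.
#' Selection is deterministic given its inputs.
#'
#' @param sites Data frame of site observations.
#' @param vaf_min Minimum tumour alt fraction (default 0.10).
#' @param normal_vaf_max Maximum normal alt fraction (default 0.35).
#' @param min_depth Minimum depth in each sample (default 10).
#' @param min_sites Below this survivor count a warning is issued and the
#'   `low_confidence` attribute set (default 50).
#' @return The surviving rows, with attribute `low_confidence`.
#' @export
select_candidate_sites <- function(sites, vaf_min = 0.10,
                                   normal_vaf_max = 0.35,
                                   min_depth = 10, min_sites = 50) {
  keep <- sites$t_depth >= min_depth & sites$n_depth >= min_depth
  tvaf <- ifelse(sites$t_depth > 0, sites$t_alt / sites$t_depth, 0)
  nvaf <- ifelse(sites$n_depth > 0, sites$n_alt / sites$n_depth, 0)
  keep <- keep & tvaf >= vaf_min & nvaf <= normal_vaf_max
  out <- sites[keep, , drop = FALSE]
  low <- nrow(out) < min_sites
  if (low)
    warning("only ", nrow(out), " candidate sites survive filtering ",
            "(< ", min_sites, "); TiN estimate will be low-confidence")
  attr(out, "low_confidence") <- low
  out
}

#' Profile log-likelihood of the data at a fixed TiN level
#'
#' The total log marginal likelihood of the candidate sites with the
#' normal-sample aberrant cell fraction pinned at `alpha_n`: at each site
#' the genotype pair is summed out,
#' \eqn{\log \sum_{pairs} prior \cdot \exp(L_t + L_n(\alpha_n))},
#' and sites are summed. An empty candidate set scores 0.
#'
#' @param sites Candidate sites (see [select_candidate_sites()]).
#' @param segments Copy-number segments or `NULL` for all-diploid.
#' @param params A [tin_params()] object; its `alpha_n` is ignored in
#'   favour of the `alpha_n` argument.
#' @param alpha_n The TiN level to score.
#' @return The total log marginal likelihood.
#' @export
tin_profile_log_likelihood <- function(sites, segments, params, alpha_n) {
  params <- as_tin_params(params)
  if (is.null(sites) || nrow(sites) == 0L) return(0)
  p <- tin_params(alpha_t = params$alpha_t, alpha_n = alpha_n,
                  base_error = params$base_error,
                  prior_snp = params$prior_snp,
                  prior_somatic = params$prior_somatic,
                  somatic_threshold = params$somatic_threshold)
  cn <- assign_segments(sites, segments)
  key <- paste(cn$cn_normal, cn$cn_tumour, sep = "/")
  total <- 0
  for (k in unique(key)) {
    i <- which(key == k)
    cnn <- cn$cn_normal[i[1L]]
    cnt <- cn$cn_tumour[i[1L]]
    pairs <- enumerate_genotype_pairs(cnn, cnt)
    prior <- pair_priors(pairs, p)
    e <- p$base_error
    pt <- pair_read_probs(pairs, cnn, cnt, p$alpha_t, e)
    pn <- pair_read_probs(pairs, cnn, cnt, p$alpha_n, e)
    ll <- xlogp(sites$t_alt[i], log(pt$alt)) +
      xlogp(sites$t_depth[i] - sites$t_alt[i], log(pt$ref)) +
      xlogp(sites$n_alt[i], log(pn$alt)) +
      xlogp(sites$n_depth[i] - sites$n_alt[i], log(pn$ref))
    lp <- sweep(ll, 2L, log(prior), "+")
    mx <- apply(lp, 1L, max)
    site_ll <- ifelse(is.finite(mx),
                      mx + log(rowSums(exp(lp - ifelse(is.finite(mx),
                                                       mx, 0)))),
                      -Inf)
    total <- total + sum(site_ll)
  }
  total
}

#' Estimate the tumour-in-normal level by profile-likelihood grid search
#'
#' Maximises [tin_profile_log_likelihood()] over a grid
#' `{0, grid_step, ..., alpha_max}`. Ties break toward the smaller
#' `alpha_n`. The confidence interval collects grid values within 1.92
#' log-units of the maximum (the asymptotic 95% profile-likelihood cut
#' for one parameter). A flat profile (spread below `1e-6`) returns 0 and
#' is flagged uninformative.
#'
#' @param sites Site observations; filtered through
#'   [select_candidate_sites()] unless `prefiltered = TRUE`.
#' @param segments Copy-number segments or `NULL` for all-diploid.
#' @param params A [tin_params()] object (`alpha_t` is taken as given,
#'   e.g. from an upstream purity estimate).
#' @param grid_step Grid resolution (default 0.005).
#' @param alpha_max Upper bound of the search (default 0.5).
#' @param prefiltered Set `TRUE` when `sites` are already candidates.
#' @return An object of class `tin_estimate`: `alpha_n_hat`, `ci_low`,
#'   `ci_high`, `n_sites_used`, the full `profile` (data frame `alpha_n`,
#'   `log_lik`), and flags `uninformative`, `low_confidence`.
#' @examples
#' \donttest{
#' cohort <- simulate_cohort(100, tin_grid = 0.1,
#'                           params = tin_params(alpha_t = 0.8),
#'                           seed = 1, classes = "SOMATIC")
#' estimate_tin(cohort$sites, NULL,
#'              tin_params(alpha_t = 0.8))$alpha_n_hat
#' }
#' @export
estimate_tin <- function(sites, segments = NULL, params = tin_params(),
                         grid_step = 0.005, alpha_max = 0.5,
                         prefiltered = FALSE) {
  stopifnot(grid_step > 0, alpha_max <= 0.5, alpha_max > 0)
  params <- as_tin_params(params)
  cand <- if (prefiltered) sites else select_candidate_sites(sites)
  low_confidence <- isTRUE(attr(cand, "low_confidence"))
  grid <- seq(0, alpha_max, by = grid_step)
  ll <- vapply(grid, function(a)
    tin_profile_log_likelihood(cand, segments, params, a), numeric(1))
  profile <- data.frame(alpha_n = grid, log_lik = ll)
  uninformative <- (max(ll) - min(ll)) < 1e-6
  if (uninformative) {
    hat <- 0
    ci <- c(0, alpha_max)
  } else {
    hat <- grid[which.max(ll)]  # first max = smallest alpha on ties
    inside <- grid[ll >= max(ll) - 1.92]
    ci <- range(inside)
  }
  structure(
    list(alpha_n_hat = hat, ci_low = ci[1L], ci_high = ci[2L],
         n_sites_used = nrow(cand), profile = profile,
         uninformative = uninformative, low_confidence = low_confidence),
    class = "tin_estimate"
  )
}

#' @export
print.tin_estimate <- function(x, ...) {
  cat(sprintf("TiN estimate: alpha_n = %.3f (95%% CI %.3f-%.3f), %d sites\n",
              x$alpha_n_hat, x$ci_low, x$ci_high, x$n_sites_used))
  if (x$uninformative) cat("  [flat profile: uninformative]\n")
  if (x$low_confidence) cat("  [low confidence: few candidate sites]\n")
  invisible(x)
}
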