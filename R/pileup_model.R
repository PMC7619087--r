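#' Probability that a read arose from an aberrant (tumour) cell
#'
#' At a locus where tumour cells carry `cn_tumour` copies and normal cells
#' `cn_normal` copies, a sample with aberrant cell fraction `alpha`
#' contributes reads from the two cell classes in proportion to cell
#' fraction times local copy number:
#' \deqn{\pi = \frac{\alpha\,c_t}{\alpha\,c_t + (1-\alpha)\,c_n}}
#'
#' @param alpha Aberrant cell fraction of the sample, in `[0, 1]`.
#' @param cn_tumour Total copy number of the locus in tumour cells.
#' @param cn_normal Total copy number of the locus in normal cells.
#' @return The fraction of reads expected to originate from tumour cells.
#' @examples
#' tumour_read_fraction(0.5, 2, 2)  # 0.5
#' tumour_read_fraction(0.5, 4, 2)  # 2/3: the gained locus over-contributes
#' @export
tumour_read_fraction <- function(alpha, cn_tumour, cn_normal) {
  stopifnot(all(alpha >= 0 & alpha <= 1),
            all(cn_tumour >= 0), all(cn_normal >= 0),
            all(cn_tumour + cn_normal >= 1))
  denom <- alpha * cn_tumour + (1 - alpha) * cn_normal
  if (any(denom == 0)) {
    stop("degenerate locus: no cell class contributes reads ",
         "(alpha = 1 with cn_tumour = 0, or alpha = 0 with cn_normal = 0)")
  }
  alpha * cn_tumour / denom
}

#' Per-read observation probability under a genotype pair
#'
#' The probability of observing the alternate (or reference) base on a
#' single read, marginalising over which cell class the read came from and
#' allowing for sequencing error under a uniform four-base miscall model:
#' a mutant chromosome yields the alt base with probability `1 - e` and
#' the ref base with probability `e/3` (the remaining error mass goes to
#' the two unobserved bases, which counts mode collapses onto ref).
#'
#' @param is_alt_observed Logical; `TRUE` for an alt base call, `FALSE`
#'   for reference.
#' @param error Per-read miscall probability.
#' @param f_t Mutant-allele fraction of the tumour-cell genotype
#'   (`k_t / cn_tumour`; pass 0 when `cn_tumour` is 0 — the class then
#'   contributes no reads via `pi`).
#' @param f_g Mutant-allele fraction of the normal-cell genotype
#'   (`k_g / cn_normal`).
#' @param pi Fraction of reads from tumour cells
#'   (see [tumour_read_fraction()]).
#' @return The observation probability; vectorised over all arguments.
#' @examples
#' read_prob(TRUE, 0.01, 0, 0, 0.5)    # pure sequencing error: e/3
#' read_prob(TRUE, 0, 0.5, 0, 0.2)     # 0.2 * 0.5 = 0.1
#' @export
read_prob <- function(is_alt_observed, error, f_t, f_g, pi) {
  qa <- function(f) f * (1 - error) + (1 - f) * error / 3
  qr <- function(f) (1 - f) * (1 - error) + f * error / 3
  p_alt <- pi * qa(f_t) + (1 - pi) * qa(f_g)
  p_ref <- pi * qr(f_t) + (1 - pi) * qr(f_g)
  n <- max(length(p_alt), length(is_alt_observed))
  ifelse(rep_len(is_alt_observed, n), rep_len(p_alt, n), rep_len(p_ref, n))
}

#' Enumerate all genotype pairs consistent with a copy-number state
#'
#' A genotype pair `(k_g, k_t)` gives the number of mutant-allele copies in
#' a normal cell (`k_g`, 0..`cn_normal`) and in a tumour cell (`k_t`,
#' 0..`cn_tumour`). Every combination on the grid is enumerated — no
#' evolutionary consistency between the two is imposed, since loss of
#' heterozygosity can delete germline alleles from the tumour genome.
#' Labels: `REF` when both are zero, `SOMATIC` when mutant copies exist
#' only in tumour cells, `GERMLINE` whenever the normal-cell genome carries
#' the mutant allele.
#'
#' @param cn_normal Normal-cell total copy number (>= 0).
#' @param cn_tumour Tumour-cell total copy number (>= 0); not both zero.
#' @return A data frame with columns `k_g`, `k_t`, `label`, one row per
#'   pair; `(cn_normal + 1) * (cn_tumour + 1)` rows.
#' @examples
#' enumerate_genotype_pairs(2, 2)  # 9 pairs: 1 REF, 2 SOMATIC, 6 GERMLINE
#' @export
enumerate_genotype_pairs <- function(cn_normal, cn_tumour) {
  stopifnot(length(cn_normal) == 1L, length(cn_tumour) == 1L,
            cn_normal >= 0, cn_tumour >= 0, cn_normal + cn_tumour >= 1)
  g <- expand.grid(k_g = 0:cn_normal, k_t = 0:cn_tumour,
                   KEEP.OUT.ATTRS = FALSE)
  g$label <- ifelse(g$k_g >= 1L, "GERMLINE",
                    ifelse(g$k_t >= 1L, "SOMATIC", "REF"))
  g
}

# Prior over genotype pairs: REF mass, prior_snp split across GERMLINE
# pairs, prior_somatic split across SOMATIC pairs; renormalised in case a
# class is empty (e.g. cn_tumour = 0 leaves no SOMATIC pair).
pair_priors <- function(pairs, params) {
  pr <- numeric(nrow(pairs))
  is_germ <- pairs$label == "GERMLINE"
  is_som <- pairs$label == "SOMATIC"
  pr[pairs$label == "REF"] <- 1 - params$prior_snp - params$prior_somatic
  if (any(is_germ)) pr[is_germ] <- params$prior_snp / sum(is_germ)
  if (any(is_som)) pr[is_som] <- params$prior_somatic / sum(is_som)
  pr / sum(pr)
}

# Alt/ref read probabilities for every genotype pair, for one sample.
pair_read_probs <- function(pairs, cn_normal, cn_tumour, alpha, error) {
  pi <- tumour_read_fraction(alpha, cn_tumour, cn_normal)
  f_t <- if (cn_tumour > 0) pairs$k_t / cn_tumour else rep(0, nrow(pairs))
  f_g <- if (cn_normal > 0) pairs$k_g / cn_normal else rep(0, nrow(pairs))
  list(alt = read_prob(TRUE, error, f_t, f_g, pi),
       ref = read_prob(FALSE, error, f_t, f_g, pi))
}

# n * log(p) with the 0 * log(0) = 0 convention (empty product).
xlogp <- function(n, logp) {
  m <- n %o% logp
  if (any(n == 0)) m[n == 0, ] <- 0
  m
}

#' Log-likelihood of one sample's reads under a genotype pair
#'
#' The site likelihood is the product over reads of [read_prob()]. In
#' counts mode (no per-read qualities) every non-alt read is treated as the
#' reference base and a single error rate applies; with per-read qualities,
#' each read's error is derived from its Phred score
#' (`e = 10^(-Q/10)`).
#'
#' @param depth,alt Read counts for the sample at the site.
#' @param k_g,k_t Genotype pair: mutant copies in normal cells / tumour
#'   cells.
#' @param cn_normal,cn_tumour Locus copy number in the two cell classes.
#' @param alpha Aberrant cell fraction of this sample (`alpha_t` for the
#'   tumour sample, `alpha_n` for the matched normal).
#' @param error Fixed per-read error probability (counts mode).
#' @param quals Optional data frame with columns `is_alt` (logical) and
#'   `qual` (numeric Phred score), one row per read; overrides counts mode.
#' @return The log-likelihood (`<= 0`); `-Inf` when the data are impossible
#'   under the pair, never an error.
#' @examples
#' sample_log_likelihood(10, 10, 0, 0, 2, 2, alpha = 0.5, error = 0.01)
#' # = 10 * log(0.01/3): all-alt reads explained by error alone
#' @export
sample_log_likelihood <- function(depth, alt, k_g, k_t, cn_normal, cn_tumour,
                                  alpha, error = 0.01, quals = NULL) {
  stopifnot(depth >= 0, alt >= 0, alt <= depth,
            k_g >= 0, k_g <= cn_normal, k_t >= 0, k_t <= cn_tumour)
  pi <- tumour_read_fraction(alpha, cn_tumour, cn_normal)
  f_t <- if (cn_tumour > 0) k_t / cn_tumour else 0
  f_g <- if (cn_normal > 0) k_g / cn_normal else 0
  if (!is.null(quals)) {
    stopifnot(nrow(quals) == depth, sum(quals$is_alt) == alt)
    e <- 10^(-quals$qual / 10)
    p <- read_prob(quals$is_alt, e, f_t, f_g, pi)
    return(sum(log(p)))
  }
  if (depth == 0) return(0)
  p_alt <- read_prob(TRUE, error, f_t, f_g, pi)
  p_ref <- read_prob(FALSE, error, f_t, f_g, pi)
  term <- function(n, p) if (n == 0) 0 else n * log(p)
  term(alt, p_alt) + term(depth - alt, p_ref)
}

# Vectorised posterior over genotype pairs for many sites sharing one
# copy-number state (counts mode). Returns a list with the pair grid,
# the posterior matrix (sites x pairs) and a per-site degenerate flag.
posterior_matrix <- function(t_alt, t_depth, n_alt, n_depth,
                             cn_normal, cn_tumour, params) {
  pairs <- enumerate_genotype_pairs(cn_normal, cn_tumour)
  prior <- pair_priors(pairs, params)
  e <- params$base_error
  pt <- pair_read_probs(pairs, cn_normal, cn_tumour, params$alpha_t, e)
  pn <- pair_read_probs(pairs, cn_normal, cn_tumour, params$alpha_n, e)
  ll <- xlogp(t_alt, log(pt$alt)) + xlogp(t_depth - t_alt, log(pt$ref)) +
    xlogp(n_alt, log(pn$alt)) + xlogp(n_depth - n_alt, log(pn$ref))
  lp <- sweep(ll, 2L, log(prior), "+")
  mx <- apply(lp, 1L, max)
  degenerate <- !is.finite(mx)
  w <- exp(lp - ifelse(is.finite(mx), mx, 0))
  if (any(degenerate)) w[degenerate, ] <- 1  # uniform fallback
  post <- w / rowSums(w)
  list(pairs = pairs, prior = prior, posterior = post,
       degenerate = degenerate)
}

#' Posterior over genotype pairs at one site
#'
#' Combines the tumour-sample likelihood (at `alpha_t`) and the
#' normal-sample likelihood (at `alpha_n` — the matched normal is treated
#' exactly like a tumour sample with its own aberrant cell fraction) with
#' the genotype-pair prior, exhaustively over every pair consistent with
#' the locus copy-number state. All computation is in log space with
#' max-subtraction normalisation.
#'
#' @param site A list or one-row data frame with `t_depth`, `t_alt`,
#'   `n_depth`, `n_alt`; optional elements `tumour_quals` and
#'   `normal_quals` (data frames with `is_alt`, `qual`) switch the
#'   corresponding sample to per-read mode.
#' @param cn A list or one-row data frame with `cn_normal` and `cn_tumour`
#'   (see [assign_copy_number()]).
#' @param params A [tin_params()] object.
#' @return An object of class `site_posterior`: a list with `pairs` (the
#'   pair grid with a `posterior` column), `p_somatic`, `p_germline`,
#'   `map_pair`, `classification`, and `degenerate` (all-pair zero
#'   likelihood fallback, classified `UNCLASSIFIED`).
#' @examples
#' p <- tin_params(alpha_t = 0.8, alpha_n = 0.1)
#' sp <- site_posterior(list(t_depth = 40, t_alt = 16,
#'                           n_depth = 40, n_alt = 2),
#'                      list(cn_normal = 2, cn_tumour = 2), p)
#' sp$classification
#' @export
site_posterior <- function(site, cn, params) {
  params <- as_tin_params(params)
  cn_normal <- as.integer(cn$cn_normal)
  cn_tumour <- as.integer(cn$cn_tumour)
  has_quals <- !is.null(site$tumour_quals) || !is.null(site$normal_quals)
  if (!has_quals) {
    pm <- posterior_matrix(site$t_alt, site$t_depth, site$n_alt,
                           site$n_depth, cn_normal, cn_tumour, params)
    pairs <- pm$pairs
    pairs$posterior <- as.numeric(pm$posterior[1L, ])
    degenerate <- pm$degenerate[1L]
  } else {
    pairs <- enumerate_genotype_pairs(cn_normal, cn_tumour)
    prior <- pair_priors(pairs, params)
    ll <- vapply(seq_len(nrow(pairs)), function(i) {
      sample_log_likelihood(site$t_depth, site$t_alt,
                            pairs$k_g[i], pairs$k_t[i],
                            cn_normal, cn_tumour,
                            params$alpha_t, params$base_error,
                            quals = site$tumour_quals) +
        sample_log_likelihood(site$n_depth, site$n_alt,
                              pairs$k_g[i], pairs$k_t[i],
                              cn_normal, cn_tumour,
                              params$alpha_n, params$base_error,
                              quals = site$normal_quals)
    }, numeric(1))
    lp <- ll + log(prior)
    mx <- max(lp)
    degenerate <- !is.finite(mx)
    w <- if (degenerate) rep(1, length(lp)) else exp(lp - mx)
    pairs$posterior <- w / sum(w)
  }
  p_somatic <- sum(pairs$posterior[pairs$label == "SOMATIC"])
  p_germline <- sum(pairs$posterior[pairs$label == "GERMLINE"])
  map_i <- which.max(pairs$posterior)
  out <- structure(
    list(pairs = pairs,
         p_somatic = p_somatic,
         p_germline = p_germline,
         map_pair = pairs[map_i, c("k_g", "k_t", "label")],
         degenerate = degenerate,
         classification = NA_character_),
    class = "site_posterior"
  )
  out$classification <- if (degenerate) "UNCLASSIFIED" else
    classify_site(out, params$somatic_threshold)
  out
}

#' Classify a site from its genotype-pair posterior
#'
#' The decision rule on the posterior: `SOMATIC` if the aggregate somatic
#' probability reaches the threshold, otherwise `GERMLINE` if the germline
#' mass does, otherwise `REF` if the reference pair does, otherwise
#' `UNCLASSIFIED`.
#'
#' @param posterior A `site_posterior` object.
#' @param threshold Posterior probability cut-off in `(0, 1)`.
#' @return One of `"SOMATIC"`, `"GERMLINE"`, `"REF"`, `"UNCLASSIFIED"`.
#' @export
classify_site <- function(posterior, threshold) {
  stopifnot(threshold > 0, threshold < 1)
  if (isTRUE(posterior$degenerate)) return("UNCLASSIFIED")
  p_ref <- sum(posterior$pairs$posterior[posterior$pairs$label == "REF"])
  if (posterior$p_somatic >= threshold) "SOMATIC"
  else if (posterior$p_germline >= threshold) "GERMLINE"
  else if (p_ref >= threshold) "REF"
  else "UNCLASSIFIED"
}

#' @export
print.site_posterior <- function(x, ...) {
  cat(sprintf("Site posterior: %s (P[somatic] = %.4f, P[germline] = %.4f)\n",
              x$classification, x$p_somatic, x$p_germline))
  cat(sprintf("MAP genotype pair: k_g = %d, k_t = %d (%s)\n",
              x$map_pair$k_g, x$map_pair$k_t, x$map_pair$label))
  invisible(x)
}
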