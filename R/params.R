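#' Model parameters for TiN-aware genotype-pair calling
#'
#' Bundles the tunable parameters of the genotype-pair likelihood model.
#' Both samples of a tumour/normal pair carry their own aberrant cell
#' fraction: `alpha_t` for the tumour sample (its purity) and `alpha_n` for
#' the matched normal (the tumour-in-normal level). The two are independent
#' parameters; `alpha_n <= alpha_t` is not required.
#'
#' The prior over genotype pairs factorises as: the reference pair gets
#' `1 - prior_snp - prior_somatic`; `prior_snp` is split equally across
#' germline pairs (any pair with mutant copies in the normal-cell genome);
#' `prior_somatic` is split equally across somatic pairs (mutant copies in
#' tumour cells only). Defaults mirror conventional whole-genome caller
#' priors: roughly one heterozygous SNP per 10 kb and a somatic rate orders
#' of magnitude below it.
#'
#' @param alpha_t Aberrant (tumour) cell fraction of the tumour sample,
#'   in `[0, 1]`.
#' @param alpha_n Aberrant cell fraction of the matched normal sample
#'   (the TiN level), in `[0, 1]`. The production default of 0.10 reflects
#'   the observation that a fixed 10% level is sufficient to recover
#'   genuine variants across typical contaminated cohorts.
#' @param base_error Per-read base miscall probability used in counts mode,
#'   in `(0, 0.75)`. Per-read Phred qualities override this when present.
#' @param prior_snp Prior probability that the site is a germline variant.
#' @param prior_somatic Prior probability that the site carries a somatic
#'   mutation.
#' @param somatic_threshold Posterior probability above which a site is
#'   classified, in `(0, 1)`.
#' @return An object of class `tin_params` (a validated list).
#' @examples
#' p <- tin_params(alpha_t = 0.8, alpha_n = 0.1)
#' p$somatic_threshold
#' @export
tin_params <- function(alpha_t = 1.0, alpha_n = 0.10, base_error = 0.01,
                       prior_snp = 1e-4, prior_somatic = 6e-6,
                       somatic_threshold = 0.95) {
  stopifnot(
    is.numeric(alpha_t), length(alpha_t) == 1L, alpha_t >= 0, alpha_t <= 1,
    is.numeric(alpha_n), length(alpha_n) == 1L, alpha_n >= 0, alpha_n <= 1,
    is.numeric(base_error), base_error > 0, base_error < 0.75,
    prior_snp >= 0, prior_somatic >= 0,
    prior_snp + prior_somatic < 1,
    somatic_threshold > 0, somatic_threshold < 1
  )
  structure(
    list(alpha_t = alpha_t, alpha_n = alpha_n, base_error = base_error,
         prior_snp = prior_snp, prior_somatic = prior_somatic,
         somatic_threshold = somatic_threshold),
    class = "tin_params"
  )
}

#' @export
print.tin_params <- function(x, ...) {
  cat("TiN-aware calling parameters\n")
  cat(sprintf("  alpha_t (tumour purity):      %.3f\n", x$alpha_t))
  cat(sprintf("  alpha_n (tumour-in-normal):   %.3f\n", x$alpha_n))
  cat(sprintf("  base error:                   %.4g\n", x$base_error))
  cat(sprintf("  prior SNP / somatic:          %.3g / %.3g\n",
              x$prior_snp, x$prior_somatic))
  cat(sprintf("  classification threshold:     %.3f\n", x$somatic_threshold))
  invisible(x)
}

as_tin_params <- function(x) {
  if (inherits(x, "tin_params")) return(x)
  do.call(tin_params, as.list(x))
}
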