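#' Look up the copy-number segment covering a site
#'
#' Returns the unique segment whose interval (1-based, inclusive) contains
#' the site's position on the matching chromosome. Sites falling in gaps
#' between segments, or on chromosomes absent from the segment table, get
#' the default diploid state (`cn_normal = 2`, `cn_tumour = 2`); callers
#' that need to count these fallbacks can inspect the `gap` attribute.
#'
#' @param site A `site_observation` or any list with `chrom` and `pos`.
#' @param segments Segment data frame (see [read_segments()]), sorted and
#'   non-overlapping per chromosome.
#' @return A one-row data frame with `cn_normal`, `cn_tumour` (and
#'   `cn_major` if present); attribute `gap` is `TRUE` when the diploid
#'   fallback was used.
#' @export
assign_copy_number <- function(site, segments) {
  hit <- segments$chrom == site$chrom &
    segments$start <= site$pos & segments$end >= site$pos
  if (any(hit)) {
    out <- segments[which(hit)[1L], , drop = FALSE]
    attr(out, "gap") <- FALSE
  } else {
    out <- data.frame(chrom = site$chrom, start = site$pos, end = site$pos,
                      cn_normal = 2L, cn_tumour = 2L)
    attr(out, "gap") <- TRUE
  }
  out
}

# Vectorised segment lookup: returns per-site cn_normal / cn_tumour with
# the diploid fallback, plus the number of gap fallbacks.
assign_segments <- function(sites, segments) {
  n <- nrow(sites)
  cn_normal <- rep(2L, n)
  cn_tumour <- rep(2L, n)
  gap <- rep(TRUE, n)
  if (!is.null(segments) && nrow(segments)) {
    for (ch in unique(segments$chrom)) {
      seg <- segments[segments$chrom == ch, , drop = FALSE]
      seg <- seg[order(seg$start), , drop = FALSE]
      i <- which(sites$chrom == ch)
      if (!length(i)) next
      j <- findInterval(sites$pos[i], seg$start)
      inside <- j >= 1L & sites$pos[i] <= seg$end[pmax(j, 1L)]
      hit <- i[inside]
      cn_normal[hit] <- as.integer(seg$cn_normal[j[inside]])
      cn_tumour[hit] <- as.integer(seg$cn_tumour[j[inside]])
      gap[hit] <- FALSE
    }
  }
  list(cn_normal = cn_normal, cn_tumour = cn_tumour, gap = gap,
       n_gap = sum(gap))
}

#' Call somatic SNVs on a table of paired site observations
#'
#' Runs the genotype-pair posterior at every site: each site is matched to
#' its copy-number segment, the tumour and normal likelihoods are combined
#' under `alpha_t` and `alpha_n`, and the site is classified at the
#' configured posterior threshold. Sites are grouped by copy-number state
#' and processed with a vectorised likelihood kernel, so whole-genome-sized
#' tables are practical.
#'
#' Malformed rows (missing counts, alt exceeding depth, negative values)
#' are skipped; their number is reported via a message and the `n_skipped`
#' attribute, never silently.
#'
#' @param sites Data frame of sites (columns of [read_count_table()]).
#' @param segments Copy-number segments, or `NULL` for all-diploid.
#' @param params A [tin_params()] object.
#' @return A data frame of calls: site identity, `classification`,
#'   `p_somatic`, `p_germline`, MAP genotype pair (`map_k_g`, `map_k_t`),
#'   the copy-number state used and `alpha_n`. Attributes: `n_skipped`,
#'   `n_cn_gap`.
#' @examples
#' p <- tin_params(alpha_t = 0.8, alpha_n = 0.1)
#' sites <- data.frame(chrom = "1", pos = 100, ref = "A", alt = "T",
#'                     t_depth = 40, t_alt = 16, n_depth = 40, n_alt = 2)
#' call_snvs(sites, NULL, p)$classification
#' @export
call_snvs <- function(sites, segments = NULL, params = tin_params()) {
  params <- as_tin_params(params)
  if (is.null(sites) || nrow(sites) == 0L) {
    out <- empty_calls()
    attr(out, "n_skipped") <- 0L
    attr(out, "n_cn_gap") <- 0L
    return(out)
  }
  num <- c("pos", "t_depth", "t_alt", "n_depth", "n_alt")
  bad <- rep(FALSE, nrow(sites))
  for (cl in num) bad <- bad | !is.finite(as.numeric(sites[[cl]]))
  ok <- !bad
  ok[ok] <- with(sites[ok, , drop = FALSE],
                 t_alt >= 0 & n_alt >= 0 & t_alt <= t_depth &
                   n_alt <= n_depth & t_depth >= 0 & n_depth >= 0)
  n_skipped <- sum(!ok)
  if (n_skipped > 0L)
    message("call_snvs: skipped ", n_skipped, " malformed row(s)")
  sites <- sites[ok, , drop = FALSE]
  cn <- assign_segments(sites, segments)
  key <- paste(cn$cn_normal, cn$cn_tumour, sep = "/")
  out <- vector("list", length(unique(key)))
  names(out) <- unique(key)
  for (k in unique(key)) {
    i <- which(key == k)
    cnn <- cn$cn_normal[i[1L]]
    cnt <- cn$cn_tumour[i[1L]]
    pm <- posterior_matrix(sites$t_alt[i], sites$t_depth[i],
                           sites$n_alt[i], sites$n_depth[i],
                           cnn, cnt, params)
    post <- pm$posterior
    is_som <- pm$pairs$label == "SOMATIC"
    is_germ <- pm$pairs$label == "GERMLINE"
    is_ref <- pm$pairs$label == "REF"
    p_som <- rowSums(post[, is_som, drop = FALSE])
    p_germ <- rowSums(post[, is_germ, drop = FALSE])
    p_ref <- rowSums(post[, is_ref, drop = FALSE])
    map_i <- max.col(post, ties.method = "first")
    thr <- params$somatic_threshold
    cls <- ifelse(pm$degenerate, "UNCLASSIFIED",
                  ifelse(p_som >= thr, "SOMATIC",
                         ifelse(p_germ >= thr, "GERMLINE",
                                ifelse(p_ref >= thr, "REF",
                                       "UNCLASSIFIED"))))
    out[[k]] <- data.frame(
      row = i,
      chrom = as.character(sites$chrom[i]),
      pos = sites$pos[i],
      ref = sites$ref[i],
      alt = sites$alt[i],
      classification = cls,
      p_somatic = p_som,
      p_germline = p_germ,
      map_k_g = pm$pairs$k_g[map_i],
      map_k_t = pm$pairs$k_t[map_i],
      cn_normal = cnn,
      cn_tumour = cnt,
      alpha_n = params$alpha_n,
      stringsAsFactors = FALSE
    )
  }
  calls <- do.call(rbind, out)
  calls <- calls[order(calls$row), setdiff(names(calls), "row"),
                 drop = FALSE]
  rownames(calls) <- NULL
  attr(calls, "n_skipped") <- n_skipped
  attr(calls, "n_cn_gap") <- cn$n_gap
  calls
}

empty_calls <- function() {
  data.frame(chrom = character(), pos = integer(), ref = character(),
             alt = character(), classification = character(),
             p_somatic = numeric(), p_germline = numeric(),
             map_k_g = integer(), map_k_t = integer(),
             cn_normal = integer(), cn_tumour = integer(),
             alpha_n = numeric(), stringsAsFactors = FALSE)
}

#' Germline log-odds (GLOD) score for an indel candidate
#'
#' Contrasts two binomial explanations of the alt reads seen in the
#' matched normal: a germline-heterozygous model with success probability
#' `0.5 * xi` (`xi < 1` absorbs the systematic underestimation of indel
#' VAFs by alignment) against a TiN-consistent somatic model whose
#' expected normal VAF scales the tumour VAF by `alpha_n / alpha_t`,
#' clamped to `[1e-3, 0.5]`. Positive scores favour the germline model.
#'
#' \deqn{GLOD = \log_{10} B(a; d, 0.5\xi) - \log_{10} B(a; d, p_{som})}
#'
#' @param normal_alt,normal_depth Alt and total read counts in the normal.
#' @param tumour_vaf Variant allele fraction observed in the tumour.
#' @param alpha_t,alpha_n Aberrant cell fractions of tumour and normal.
#' @param xi Detection-efficiency factor in `(0, 1]`, default 0.9.
#' @return The log10 odds; vectorised. Exactly 0 when the two models
#'   coincide.
#' @export
glod_score <- function(normal_alt, normal_depth, tumour_vaf,
                       alpha_t, alpha_n, xi = 0.9) {
  stopifnot(all(normal_depth >= 1), all(xi > 0), all(xi <= 1),
            all(normal_alt >= 0), all(normal_alt <= normal_depth))
  p_germ <- 0.5 * xi
  p_som <- pmin(pmax(tumour_vaf * alpha_n / pmax(alpha_t, 0.01), 1e-3), 0.5)
  out <- (stats::dbinom(normal_alt, normal_depth, p_germ, log = TRUE) -
            stats::dbinom(normal_alt, normal_depth, p_som, log = TRUE)) /
    log(10)
  out[p_som == p_germ] <- 0
  out
}

#' Rescue indels flagged as present in the matched normal
#'
#' Indel callers running against a contaminated normal reject genuine
#' somatic indels because the contaminating tumour cells place alt reads
#' in the normal sample (the "present in matched normal" / F015-style
#' rejection). This gate recovers such candidates when their GLOD score
#' indicates the normal-sample evidence is better explained by
#' tumour-in-normal leakage than by a germline heterozygote: a flagged
#' candidate is rescued iff `glod < glod_threshold`. Unflagged candidates
#' pass through untouched.
#'
#' @param candidates Data frame with columns `flagged_in_normal`
#'   (logical), `tumour_vaf`, `normal_alt`, `normal_depth`; a precomputed
#'   `glod` column is honoured, otherwise scores are computed via
#'   [glod_score()].
#' @param params A [tin_params()] object supplying `alpha_t`, `alpha_n`.
#' @param glod_threshold Rescue cut-off on the log10 odds (default 0).
#' @param xi Detection-efficiency factor passed to [glod_score()].
#' @return The candidates with `glod` and logical `rescued` columns.
#' @export
rescue_indels <- function(candidates, params = tin_params(),
                          glod_threshold = 0, xi = 0.9) {
  params <- as_tin_params(params)
  if (is.null(candidates) || nrow(candidates) == 0L) {
    candidates$glod <- numeric(0)
    candidates$rescued <- logical(0)
    return(candidates)
  }
  if (is.null(candidates$glod)) {
    candidates$glod <- glod_score(candidates$normal_alt,
                                  candidates$normal_depth,
                                  candidates$tumour_vaf,
                                  params$alpha_t, params$alpha_n, xi)
  }
  candidates$rescued <- candidates$flagged_in_normal &
    candidates$glod < glod_threshold
  candidates
}
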