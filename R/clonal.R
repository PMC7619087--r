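#' Copy-number-corrected cancer cell fraction of a variant
#'
#' Converts a variant allele fraction to the fraction of tumour cells
#' carrying the mutation. With tumour purity `alpha_t` and locus copy
#' numbers `cn_tumour` (tumour cells) / `cn_normal` (normal cells), the
#' total allele dose at the locus is
#' `D = alpha_t * cn_tumour + (1 - alpha_t) * cn_normal`, the mutation
#' multiplicity is estimated by rounding `vaf * D / alpha_t` into
#' `[1, max(cn_tumour, 1)]`, and
#' \deqn{CCF = \frac{VAF \cdot D}{\alpha_t \cdot m}}
#' CCF may slightly exceed 1 from sampling noise; values are clamped at
#' 1.5 with a flag.
#'
#' @param vaf Variant allele fraction in `[0, 1]`; vectorised.
#' @param alpha_t Tumour purity in `(0, 1]`.
#' @param cn_normal,cn_tumour Locus total copy number in normal / tumour
#'   cells (default diploid).
#' @return A data frame with `vaf`, `multiplicity`, `ccf`, `clamped`.
#' @examples
#' variant_ccf(0.25, 0.5)          # clonal het at 50% purity: CCF 1
#' variant_ccf(0.10, 0.8)          # subclonal: CCF 0.25
#' @export
variant_ccf <- function(vaf, alpha_t, cn_normal = 2, cn_tumour = 2) {
  if (any(alpha_t <= 0)) stop("CCF undefined at alpha_t = 0")
  stopifnot(all(vaf >= 0), all(vaf <= 1), all(alpha_t <= 1))
  dose <- alpha_t * cn_tumour + (1 - alpha_t) * cn_normal
  m_raw <- vaf * dose / alpha_t
  m <- pmin(pmax(round(m_raw), 1), pmax(cn_tumour, 1))
  ccf <- vaf * dose / (alpha_t * m)
  clamped <- ccf > 1.5
  ccf <- pmin(ccf, 1.5)
  data.frame(vaf = vaf, multiplicity = as.integer(m), ccf = ccf,
             clamped = clamped)
}

#' Clone-level CCF from member variant VAFs
#'
#' The fishplot convention for longitudinal tracking across whole-genome
#' and targeted timepoints: a clone's CCF at a timepoint is double the
#' median VAF of its diploid autosomal member SNVs, capped at 1 (with an
#' overflow flag). When no diploid autosomal members are available the
#' mean of the supplied per-variant CCFs is used instead, with a
#' provenance flag.
#'
#' @param diploid_vafs VAFs of the clone's diploid autosomal member SNVs
#'   at one timepoint; may be empty.
#' @param fallback_ccf Optional per-variant CCFs (e.g. from
#'   [variant_ccf()]) used when `diploid_vafs` is empty.
#' @return A length-one numeric with attributes `overflow` (capped at 1)
#'   and `source` (`"diploid_vaf"` or `"mean_ccf"`).
#' @examples
#' clone_ccf(c(0.2, 0.25, 0.3))  # 0.5
#' @export
clone_ccf <- function(diploid_vafs, fallback_ccf = NULL) {
  if (length(diploid_vafs) >= 1L) {
    raw <- 2 * stats::median(diploid_vafs)
    src <- "diploid_vaf"
  } else if (length(fallback_ccf) >= 1L) {
    raw <- mean(fallback_ccf)
    src <- "mean_ccf"
  } else {
    stop("clone has no member VAFs and no fallback CCFs")
  }
  out <- min(raw, 1)
  attr(out, "overflow") <- raw > 1
  attr(out, "source") <- src
  out
}

#' Coordinated-VAF check for a clone across timepoints
#'
#' Variants genuinely belonging to one clone must move together over
#' time. For each consecutive timepoint pair the median VAF change is
#' compared against a binomial noise floor (twice the pooled standard
#' error of a VAF difference at the observed depths); when the shift is
#' informative (the median change, or the median change magnitude,
#' exceeds the floor), at least `min_agreement` of member variants must
#' change in the majority direction. The clone passes iff every
#' informative pair passes; the score is the minimum agreeing fraction.
#' Clones with fewer than 3 members or fewer than 2 timepoints are
#' `UNSCORED`.
#'
#' @param vaf A members x timepoints matrix of VAFs (timepoints in
#'   chronological order).
#' @param depth A matrix of matching dimensions with read depths, or a
#'   single depth applied throughout.
#' @param min_agreement Required fraction of members moving with the
#'   median (default 0.8).
#' @return A list: `status` (`"pass"`, `"fail"`, `"UNSCORED"`), `score`
#'   (minimum agreeing fraction over informative pairs; `NA` if none),
#'   and per-pair details in `pairs`.
#' @export
coordination_check <- function(vaf, depth, min_agreement = 0.8) {
  vaf <- as.matrix(vaf)
  if (length(depth) == 1L)
    depth <- matrix(depth, nrow(vaf), ncol(vaf))
  depth <- as.matrix(depth)
  stopifnot(all(dim(vaf) == dim(depth)))
  if (nrow(vaf) < 3L || ncol(vaf) < 2L) {
    return(list(status = "UNSCORED", score = NA_real_,
                pairs = data.frame()))
  }
  pairs <- data.frame(from = integer(0), to = integer(0),
                      delta = numeric(0), noise_floor = numeric(0),
                      informative = logical(0), agreement = numeric(0),
                      pass = logical(0))
  for (j in seq_len(ncol(vaf) - 1L)) {
    d <- vaf[, j + 1L] - vaf[, j]
    delta <- stats::median(d)
    pbar <- mean(c(vaf[, j], vaf[, j + 1L]))
    se <- sqrt(pbar * (1 - pbar) *
                 mean(1 / depth[, j] + 1 / depth[, j + 1L]))
    # informative if the clone moves, or if members move individually but
    # cancel (anti-coordination must not hide behind a zero median)
    informative <- abs(delta) > 2 * se || stats::median(abs(d)) > 2 * se
    agreement <- if (!informative) NA_real_
    else if (abs(delta) > 0) mean(sign(d) == sign(delta))
    else max(mean(sign(d) == 1), mean(sign(d) == -1))
    pairs <- rbind(pairs, data.frame(
      from = j, to = j + 1L, delta = delta, noise_floor = 2 * se,
      informative = informative, agreement = agreement,
      pass = !informative || agreement >= min_agreement))
  }
  informative <- pairs$informative
  score <- if (any(informative)) min(pairs$agreement[informative])
           else NA_real_
  status <- if (all(pairs$pass)) "pass" else "fail"
  list(status = status, score = score, pairs = pairs)
}

#' Export clone trajectories as a nested fishplot table
#'
#' Produces the long-format table (`clone`, `parent`, `timepoint`, `ccf`)
#' consumed by fishplot-style renderers, after repairing violations of
#' the nesting constraints that sampling noise introduces: a child's CCF
#' may not exceed its parent's, and siblings may not jointly exceed their
#' parent. Children exceeding the parent are reduced to it; sibling sets
#' summing above the parent are rescaled proportionally to it. Top-level
#' clones are nested under an implicit root of CCF 1. Constraints hold
#' exactly on output; repairs larger than `tolerance` (the range
#' attributable to sampling noise) are reported in the `repairs`
#' attribute and via messages.
#'
#' @param clones Data frame with columns `clone`, `parent` (`NA` for
#'   top-level clones), `timepoint`, `ccf`.
#' @param tolerance CCF exceedance above which a repair is logged
#'   (default 0.05).
#' @return The repaired long-format data frame, ordered by timepoint then
#'   clone, with attribute `repairs`.
#' @examples
#' cl <- data.frame(clone = c("A", "B"), parent = c(NA, "A"),
#'                  timepoint = 1, ccf = c(0.5, 0.6))
#' export_fishplot_table(cl)  # child B reduced to 0.5
#' @export
export_fishplot_table <- function(clones, tolerance = 0.05) {
  stopifnot(all(c("clone", "parent", "timepoint", "ccf") %in%
                  names(clones)))
  ids <- unique(as.character(clones$clone))
  parent_of <- vapply(ids, function(id) {
    p <- unique(as.character(clones$parent[clones$clone == id]))
    if (length(p) > 1L) stop("clone ", id, " has conflicting parents")
    p
  }, character(1))
  # cycle detection by walking each clone's ancestry
  for (id in ids) {
    seen <- character(0)
    cur <- id
    while (!is.na(parent_of[[cur]])) {
      if (parent_of[[cur]] %in% c(seen, cur))
        stop("cyclic parent relation involving clone ", cur)
      seen <- c(seen, cur)
      cur <- parent_of[[cur]]
      if (!cur %in% ids) break  # unknown parent treated as root
    }
  }
  # topological order: parents before children
  ordered <- character(0)
  remaining <- ids
  while (length(remaining)) {
    ready <- remaining[vapply(remaining, function(id) {
      p <- parent_of[[id]]
      is.na(p) || !(p %in% remaining)
    }, logical(1))]
    ordered <- c(ordered, ready)
    remaining <- setdiff(remaining, ready)
  }
  repairs <- data.frame(clone = character(0), timepoint = numeric(0),
                        rule = character(0), from = numeric(0),
                        to = numeric(0))
  out <- clones
  out$clone <- as.character(out$clone)
  out$parent <- as.character(out$parent)
  for (tp in unique(out$timepoint)) {
    at <- function(id) {
      v <- out$ccf[out$clone == id & out$timepoint == tp]
      if (length(v)) v[1L] else NA_real_
    }
    set <- function(id, value) {
      out$ccf[out$clone == id & out$timepoint == tp] <<- value
    }
    parent_ccf <- function(id) {
      p <- parent_of[[id]]
      if (is.na(p) || !(p %in% ids)) 1 else at(p)
    }
    # one sweep parents-first: clamp children to the parent's final CCF,
    # then rescale each sibling set; later groups see repaired values
    groups <- split(ids, vapply(ids, function(id) {
      p <- parent_of[[id]]
      if (is.na(p) || !(p %in% ids)) "<root>" else p
    }, character(1)))
    for (p in c("<root>", ordered)) {
      sibs <- groups[[p]]
      if (is.null(sibs)) next
      cap <- if (p == "<root>") 1 else at(p)
      if (is.na(cap)) cap <- 1
      for (id in sibs) {  # child <= parent
        v <- at(id)
        if (is.na(v) || v <= cap) next
        if (v - cap > tolerance) {
          repairs <- rbind(repairs, data.frame(
            clone = id, timepoint = tp, rule = "nesting",
            from = v, to = cap))
          message(sprintf(
            "fishplot repair (t=%s): clone %s CCF %.3f > parent %.3f; reduced",
            format(tp), id, v, cap))
        }
        set(id, cap)
      }
      vals <- vapply(sibs, at, numeric(1))
      present <- !is.na(vals)
      if (!any(present)) next
      total <- sum(vals[present])
      if (total > cap && total > 0) {  # sibling sum <= parent
        scale <- cap / total
        if (total - cap > tolerance) {
          for (s in sibs[present]) {
            repairs <- rbind(repairs, data.frame(
              clone = s, timepoint = tp, rule = "sibling_sum",
              from = at(s), to = at(s) * scale))
          }
          message(sprintf(
            "fishplot repair (t=%s): siblings under %s sum %.3f > %.3f; rescaled",
            format(tp), p, total, cap))
        }
        for (s in sibs[present]) set(s, at(s) * scale)
      }
    }
  }
  out <- out[order(out$timepoint, out$clone),
             c("clone", "parent", "timepoint", "ccf")]
  rownames(out) <- NULL
  attr(out, "repairs") <- repairs
  out
}

#' Write a fishplot table to TSV
#' @param table Output of [export_fishplot_table()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fishplot_table <- function(table, path) {
  utils::write.table(table, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
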