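#' Construct a validated site observation
#'
#' One genomic site's paired read evidence: tumour and normal depths and
#' alt counts, optionally with per-read base qualities. Coordinates are
#' 1-based. Sites are biallelic; multi-allelic sites should be split into
#' separate records upstream with the highest-count non-reference base as
#' alt.
#'
#' @param chrom Chromosome name.
#' @param pos 1-based position.
#' @param ref,alt Single reference / alternate bases (must differ).
#' @param t_depth,t_alt Tumour depth and alt read count.
#' @param n_depth,n_alt Normal depth and alt read count.
#' @param tumour_quals,normal_quals Optional per-read data frames with
#'   columns `is_alt` (logical) and `qual` (Phred); row counts must equal
#'   the depths and alt-flag sums the alt counts.
#' @return A list of class `site_observation`.
#' @export
site_observation <- function(chrom, pos, ref, alt, t_depth, t_alt,
                             n_depth, n_alt,
                             tumour_quals = NULL, normal_quals = NULL) {
  stopifnot(nchar(ref) == 1L, nchar(alt) == 1L, ref != alt,
            t_depth >= 0, n_depth >= 0,
            t_alt >= 0, t_alt <= t_depth,
            n_alt >= 0, n_alt <= n_depth)
  check_quals <- function(q, depth, altc, what) {
    if (is.null(q)) return(invisible())
    if (nrow(q) != depth || sum(q$is_alt) != altc)
      stop(what, " per-read qualities inconsistent with counts")
  }
  check_quals(tumour_quals, t_depth, t_alt, "tumour")
  check_quals(normal_quals, n_depth, n_alt, "normal")
  structure(list(chrom = as.character(chrom), pos = as.integer(pos),
                 ref = ref, alt = alt,
                 t_depth = as.integer(t_depth), t_alt = as.integer(t_alt),
                 n_depth = as.integer(n_depth), n_alt = as.integer(n_alt),
                 tumour_quals = tumour_quals, normal_quals = normal_quals),
            class = "site_observation")
}

#' Read a per-site count table
#'
#' Tab-separated, one row per site, columns `chrom`, `pos`, `ref`, `alt`,
#' `t_depth`, `t_alt`, `n_depth`, `n_alt`.
#'
#' @param path Path to the TSV file.
#' @return A data frame of sites.
#' @export
read_count_table <- function(path) {
  # ref/alt must never be sniffed as logical (an all-"T" column would be)
  x <- utils::read.delim(path, stringsAsFactors = FALSE,
                         colClasses = c(chrom = "character",
                                        ref = "character",
                                        alt = "character"))
  needed <- c("chrom", "pos", "ref", "alt",
              "t_depth", "t_alt", "n_depth", "n_alt")
  missing <- setdiff(needed, names(x))
  if (length(missing))
    stop("count table missing columns: ", paste(missing, collapse = ", "))
  x
}

#' Write a per-site count table
#' @param sites Data frame of sites (see [read_count_table()] for columns).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_count_table <- function(sites, path) {
  utils::write.table(sites, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read allele-specific copy-number segments
#'
#' Tab-separated intervals with 1-based inclusive coordinates: `chrom`,
#' `start`, `end`, `cn_normal` (normal-cell total copies), `cn_tumour`
#' (tumour-cell total copies) and optionally `cn_major` (major-allele
#' copies, `<= cn_tumour`). Segment files from allele-specific
#' copy-number tools can be reshaped to this format upstream; segments are
#' consumed as given, never estimated here.
#'
#' @param path Path to the TSV file.
#' @return A data frame of segments, sorted by chromosome and start.
#' @export
read_segments <- function(path) {
  x <- utils::read.delim(path, stringsAsFactors = FALSE,
                         colClasses = c(chrom = "character"))
  needed <- c("chrom", "start", "end", "cn_normal", "cn_tumour")
  missing <- setdiff(needed, names(x))
  if (length(missing))
    stop("segment table missing columns: ", paste(missing, collapse = ", "))
  validate_segments(x)
  x[order(x$chrom, x$start), , drop = FALSE]
}

validate_segments <- function(seg) {
  stopifnot(all(seg$start <= seg$end),
            all(seg$cn_normal >= 0), all(seg$cn_tumour >= 0),
            all(seg$cn_normal + seg$cn_tumour >= 1))
  if ("cn_major" %in% names(seg)) {
    ok <- is.na(seg$cn_major) | seg$cn_major <= seg$cn_tumour
    stopifnot(all(ok))
  }
  for (ch in unique(seg$chrom)) {
    s <- seg[seg$chrom == ch, , drop = FALSE]
    s <- s[order(s$start), , drop = FALSE]
    if (nrow(s) > 1L && any(s$start[-1L] <= s$end[-nrow(s)]))
      stop("overlapping segments on chromosome ", ch)
  }
  invisible(seg)
}
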