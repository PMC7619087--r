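#' Write calls (and rescued indels) to a VCF 4.2 file
#'
#' Emits a sites-only VCF. SNV records carry INFO keys `PSOM` (somatic
#' posterior, 4 decimals), `TIN` (the `alpha_n` used) and `MAPGT` (MAP
#' genotype pair as `k_g/k_t`); indel records additionally carry `GLOD`.
#' FILTER encodes the classification: `PASS` for somatic calls,
#' `GERMLINE`, `REF`, `UNCLASSIFIED`, and `RESCUED_TIN` for indels
#' recovered by the GLOD gate (non-rescued flagged indels keep
#' `GERMLINE`; unflagged indels are `PASS`). The header records the full
#' parameter set, and output is byte-identical across reruns on identical
#' input.
#'
#' @param calls SNV calls from [call_snvs()], sorted by chromosome then
#'   position (unsorted input is a hard error).
#' @param path Output path.
#' @param params The [tin_params()] used for calling.
#' @param rescued Optional indel candidates from [rescue_indels()], with
#'   site identity columns `chrom`, `pos`, `ref`, `alt`.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(calls, path, params = tin_params(), rescued = NULL) {
  params <- as_tin_params(params)
  check_sorted <- function(x, what) {
    if (is.null(x) || nrow(x) < 2L) return(invisible())
    blocks <- rle(as.character(x$chrom))$values
    if (anyDuplicated(blocks))
      stop(what, " not sorted: chromosome blocks interleaved")
    if (any(unlist(tapply(x$pos, factor(x$chrom, levels = blocks),
                          function(p) diff(p) < 0))))
      stop(what, " not sorted by position")
  }
  check_sorted(calls, "calls")
  check_sorted(rescued, "rescued indels")

  filter_of <- function(cls) {
    c(SOMATIC = "PASS", GERMLINE = "GERMLINE", REF = "REF",
      UNCLASSIFIED = "UNCLASSIFIED")[cls]
  }
  recs <- character(0)
  if (!is.null(calls) && nrow(calls)) {
    info <- sprintf("PSOM=%.4f;TIN=%.4f;MAPGT=%d/%d",
                    calls$p_somatic, calls$alpha_n,
                    calls$map_k_g, calls$map_k_t)
    recs <- c(recs, sprintf("%s\t%d\t.\t%s\t%s\t.\t%s\t%s",
                            calls$chrom, as.integer(calls$pos),
                            calls$ref, calls$alt,
                            filter_of(calls$classification), info))
  }
  if (!is.null(rescued) && nrow(rescued)) {
    filt <- ifelse(rescued$rescued, "RESCUED_TIN",
                   ifelse(rescued$flagged_in_normal, "GERMLINE", "PASS"))
    info <- sprintf("TIN=%.4f;GLOD=%.4f", params$alpha_n, rescued$glod)
    recs <- c(recs, sprintf("%s\t%d\t.\t%s\t%s\t.\t%s\t%s",
                            rescued$chrom, as.integer(rescued$pos),
                            rescued$ref, rescued$alt, filt, info))
  }
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=tincaller",
    sprintf(paste0("##tincaller_params=alpha_t=%g,alpha_n=%g,",
                   "base_error=%g,prior_snp=%g,prior_somatic=%g,",
                   "somatic_threshold=%g"),
            params$alpha_t, params$alpha_n, params$base_error,
            params$prior_snp, params$prior_somatic,
            params$somatic_threshold),
    "##FILTER=<ID=GERMLINE,Description=\"Classified germline\">",
    "##FILTER=<ID=REF,Description=\"Classified reference\">",
    "##FILTER=<ID=UNCLASSIFIED,Description=\"No class reached the posterior threshold\">",
    "##FILTER=<ID=RESCUED_TIN,Description=\"Indel flagged in matched normal, recovered by GLOD under tumour-in-normal\">",
    "##INFO=<ID=PSOM,Number=1,Type=Float,Description=\"Posterior probability the site is somatic\">",
    "##INFO=<ID=TIN,Number=1,Type=Float,Description=\"Aberrant cell fraction assumed for the matched normal (alpha_n)\">",
    "##INFO=<ID=MAPGT,Number=1,Type=String,Description=\"MAP genotype pair k_g/k_t (mutant copies in normal/tumour cells)\">",
    "##INFO=<ID=GLOD,Number=1,Type=Float,Description=\"Germline log10 odds for indel candidates\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"
  )
  con <- file(path, open = "wb")  # fixed \n line endings on any platform
  on.exit(close(con))
  writeLines(c(header, recs), con, sep = "\n")
  invisible(path)
}
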