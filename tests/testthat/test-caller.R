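segfix <- data.frame(chrom = c("1", "1", "2"),
                     start = c(100L, 500L, 1L),
                     end = c(200L, 500L, 1000L),
                     cn_normal = c(2L, 2L, 2L),
                     cn_tumour = c(3L, 1L, 2L),
                     stringsAsFactors = FALSE)

test_that("copy-number lookup honours inclusive bounds and the diploid fallback", {
  hit <- assign_copy_number(list(chrom = "1", pos = 500), segfix)
  expect_equal(hit$cn_tumour, 1L)
  expect_false(attr(hit, "gap"))
  edge <- assign_copy_number(list(chrom = "1", pos = 200), segfix)
  expect_equal(edge$cn_tumour, 3L)
  gap <- assign_copy_number(list(chrom = "1", pos = 300), segfix)
  expect_true(attr(gap, "gap"))
  expect_equal(gap$cn_normal, 2L)
  expect_equal(gap$cn_tumour, 2L)
  off <- assign_copy_number(list(chrom = "X", pos = 50), segfix)
  expect_true(attr(off, "gap"))
})

test_that("calling a table reproduces single-site posteriors", {
  p <- tin_params(alpha_t = 0.8, alpha_n = 0.10)
  sites <- data.frame(chrom = rep("1", 3), pos = c(10L, 20L, 30L),
                      ref = "A", alt = "T",
                      t_depth = c(40, 40, 40), t_alt = c(0, 18, 16),
                      n_depth = c(40, 40, 40), n_alt = c(0, 20, 2),
                      stringsAsFactors = FALSE)
  calls <- call_snvs(sites, NULL, p)
  expect_equal(calls$classification, c("REF", "GERMLINE", "SOMATIC"))
  for (i in 1:3) {
    sp <- site_posterior(as.list(sites[i, ]),
                         list(cn_normal = 2, cn_tumour = 2), p)
    expect_equal(calls$p_somatic[i], sp$p_somatic, tolerance = 1e-12)
    o <- oracle_posterior(sites$t_depth[i], sites$t_alt[i],
                          sites$n_depth[i], sites$n_alt[i], 2, 2, p)
    expect_equal(calls$p_somatic[i], sum(o$posterior[o$label == "SOMATIC"]),
                 tolerance = 1e-10)
  }
  expect_equal(nrow(call_snvs(sites[0, ], NULL, p)), 0L)
})

test_that("a copy-neutral LOH site with high tumour VAF is called somatic", {
  p <- tin_params(alpha_t = 0.9, alpha_n = 0.10)
  site <- data.frame(chrom = "9", pos = 100L, ref = "C", alt = "T",
                     t_depth = 48, t_alt = 40, n_depth = 40, n_alt = 4,
                     stringsAsFactors = FALSE)
  seg <- data.frame(chrom = "9", start = 1L, end = 1000L,
                    cn_normal = 2L, cn_tumour = 2L, cn_major = 2L)
  call <- call_snvs(site, seg, p)
  expect_equal(call$classification, "SOMATIC")
  o <- oracle_posterior(48, 40, 40, 4, 2, 2, p)
  expect_equal(call$p_somatic, sum(o$posterior[o$label == "SOMATIC"]),
               tolerance = 1e-10)
  # both-copies-mutant pair dominates
  expect_equal(call$map_k_t, 2L)
})

test_that("malformed rows are skipped and counted, never silent", {
  p <- tin_params(alpha_t = 0.8)
  sites <- data.frame(chrom = rep("1", 3), pos = c(1L, 2L, 3L),
                      ref = "A", alt = "T",
                      t_depth = c(40, 40, 40), t_alt = c(10, 50, NA),
                      n_depth = c(40, 40, 40), n_alt = c(0, 0, 0),
                      stringsAsFactors = FALSE)
  expect_message(calls <- call_snvs(sites, NULL, p), "skipped 2")
  expect_equal(nrow(calls), 1L)
  expect_equal(attr(calls, "n_skipped"), 2L)
})

test_that("GLOD separates germline-level from TiN-level normal evidence", {
  expect_gt(glod_score(18, 40, 0.45, 0.9, 0.10, 0.9), 0)
  expect_lt(glod_score(2, 40, 0.45, 0.9, 0.10, 0.9), 0)
  # when the two binomial models coincide the odds are exactly zero
  expect_identical(glod_score(7, 40, 0.45, 0.5, 0.5, 0.9), 0)
})

test_that("GLOD matches a first-principles binomial computation on a random grid", {
  set.seed(99)
  for (i in 1:100) {
    nd <- sample(10:120, 1)
    na <- sample(0:nd, 1)
    tv <- runif(1)
    at <- runif(1, 0.1, 1)
    an <- runif(1, 0, 0.3)
    xi <- runif(1, 0.5, 1)
    expect_equal(glod_score(na, nd, tv, at, an, xi),
                 oracle_glod(na, nd, tv, at, an, xi),
                 tolerance = 1e-10)
  }
})

test_that("indel rescue honours the flag precondition and the threshold", {
  p <- tin_params(alpha_t = 0.9, alpha_n = 0.10)
  cand <- data.frame(chrom = "1", pos = c(10L, 20L, 30L),
                     ref = "AT", alt = "A",
                     flagged_in_normal = c(TRUE, TRUE, FALSE),
                     tumour_vaf = 0.45,
                     normal_alt = c(2, 18, 2), normal_depth = 40,
                     stringsAsFactors = FALSE)
  out <- rescue_indels(cand, p)
  expect_true(out$rescued[1])     # flagged, GLOD < 0
  expect_false(out$rescued[2])    # flagged, germline-level evidence
  expect_false(out$rescued[3])    # unflagged passes through untouched
  expect_true(all(out$rescued <= out$flagged_in_normal))
  # precomputed GLOD column is honoured
  forced <- cand
  forced$glod <- c(-3.2, 4.0, -5)
  out2 <- rescue_indels(forced, p)
  expect_equal(out2$rescued, c(TRUE, FALSE, FALSE))
})

test_that("VCF output is standards-compliant and round-trips", {
  skip_if_not_installed("vcfR")
  p <- tin_params(alpha_t = 0.8, alpha_n = 0.10)
  sites <- data.frame(chrom = rep(c("1", "2"), each = 2),
                      pos = c(10L, 20L, 5L, 15L), ref = "A", alt = "T",
                      t_depth = 40, t_alt = c(16, 0, 18, 20),
                      n_depth = 40, n_alt = c(2, 0, 20, 3),
                      stringsAsFactors = FALSE)
  calls <- call_snvs(sites, NULL, p)
  rescued <- rescue_indels(
    data.frame(chrom = "3", pos = 7L, ref = "CA", alt = "C",
               flagged_in_normal = TRUE, tumour_vaf = 0.45,
               normal_alt = 2, normal_depth = 40,
               stringsAsFactors = FALSE), p)
  path <- withr::local_tempfile(fileext = ".vcf")
  write_vcf(calls, path, p, rescued = rescued)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  expect_equal(nrow(v@fix), 5L)
  filt <- v@fix[, "FILTER"]
  expect_equal(unname(filt[1:4]),
               c("PASS", "REF", "GERMLINE", "PASS"))
  expect_equal(unname(filt[5]), "RESCUED_TIN")
  psom <- as.numeric(sub(".*PSOM=([0-9.]+).*", "\\1",
                         v@fix[1:4, "INFO"]))
  expect_equal(psom, calls$p_somatic, tolerance = 1e-4)
  # re-derived classification from FILTER agrees
  expect_equal(unname(ifelse(filt[1:4] == "PASS", "SOMATIC", filt[1:4])),
               ifelse(calls$classification == "SOMATIC", "SOMATIC",
                      calls$classification))
})

test_that("VCF writing is deterministic and rejects unsorted input", {
  p <- tin_params(alpha_t = 0.8, alpha_n = 0.10)
  sites <- data.frame(chrom = "1", pos = c(10L, 20L), ref = "A", alt = "T",
                      t_depth = 40, t_alt = c(16, 0),
                      n_depth = 40, n_alt = c(2, 0),
                      stringsAsFactors = FALSE)
  calls <- call_snvs(sites, NULL, p)
  f1 <- withr::local_tempfile(fileext = ".vcf")
  f2 <- withr::local_tempfile(fileext = ".vcf")
  write_vcf(calls, f1, p)
  write_vcf(calls, f2, p)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
  unsorted <- calls[c(2, 1), ]
  expect_error(write_vcf(unsorted, f1, p), "not sorted")
  interleaved <- rbind(calls, calls)
  interleaved$chrom <- c("1", "2", "1", "2")
  expect_error(write_vcf(interleaved, f1, p), "interleaved")
  # empty call set -> valid header-only VCF
  f3 <- withr::local_tempfile(fileext = ".vcf")
  write_vcf(calls[0, ], f3, p)
  lines <- readLines(f3)
  expect_true(startsWith(lines[1], "##fileformat=VCFv4.2"))
  expect_true(startsWith(lines[length(lines)], "#CHROM"))
})

test_that("count tables and segments survive a disk round-trip", {
  sites <- data.frame(chrom = c("1", "X"), pos = c(10L, 99L),
                      ref = c("A", "G"), alt = c("T", "C"),
                      t_depth = c(40L, 30L), t_alt = c(16L, 2L),
                      n_depth = c(40L, 28L), n_alt = c(2L, 0L),
                      stringsAsFactors = FALSE)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_count_table(sites, f)
  expect_equal(read_count_table(f), sites)
  seg <- withr::local_tempfile(fileext = ".tsv")
  utils::write.table(segfix, seg, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  expect_equal(read_segments(seg), segfix)
  bad <- segfix
  bad$end[1] <- 600L  # overlaps the second segment on chrom 1
  utils::write.table(bad, seg, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  expect_error(read_segments(seg), "overlapping")
})
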