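test_that("global alignment matches the scoring arithmetic on simple cases", {
  a <- align_global("ACGTACGT", "ACGTACGT")
  expect_equal(a$score, 16)
  expect_false(grepl("-", a$aligned_read, fixed = TRUE))
  b <- align_global("ACGT", "AGT")
  expect_equal(b$score, 4)  # 3 matches + one 1-base gap: 2*3 - 2
  expect_equal(nchar(b$aligned_read), 4)
  expect_error(align_global("ACGX", "ACGT"), "only A, C, G, T, N")
  expect_error(align_global("", "ACGT"), "empty")
})

test_that("alignment scores equal the brute-force oracle on all short pairs", {
  for (la in 1:4) for (lb in 1:4) {
    for (a in all_seqs(la)) for (b in all_seqs(lb)) {
      expect_equal(align_global(a, b)$score, brute_nw_score(a, b),
                   info = paste(a, b))
    }
  }
  # a sample of longer pairs over {A,C} up to length 6
  set.seed(42)
  s6 <- all_seqs(6)
  for (k in 1:40) {
    a <- sample(s6, 1); b <- sample(s6, 1)
    expect_equal(align_global(a, b)$score, brute_nw_score(a, b),
                 info = paste(a, b))
  }
})

test_that("paired reads merge at the best overlap with quality resolution", {
  dir <- withr::local_tempdir()
  base <- paste(sample(c("A", "C", "G", "T"), 150, TRUE), collapse = "")
  r1 <- substr(base, 1, 100)
  r2 <- substr(base, 51, 150)
  rc <- function(s) chartr("ACGT", "TGCA",
                           paste(rev(strsplit(s, "")[[1]]), collapse = ""))
  writeLines(c("@p1", r1, "+", strrep("I", 100)), file.path(dir, "r1.fq"))
  writeLines(c("@p1", rc(r2), "+", strrep("I", 100)), file.path(dir, "r2.fq"))
  m <- merge_pairs(file.path(dir, "r1.fq"), file.path(dir, "r2.fq"))
  expect_equal(m$merged, base)
  expect_equal(m$n_dropped, 0L)

  # overlap below min_overlap: pair dropped
  m2 <- merge_pairs(file.path(dir, "r1.fq"), file.path(dir, "r2.fq"),
                    min_overlap = 60L)
  expect_equal(m2$n_dropped, 1L)
  expect_length(m2$merged, 0)

  # disagreeing overlap base resolved toward the higher-quality mate (mate 2)
  r1x <- r1
  substr(r1x, 80, 80) <- if (substr(r1, 80, 80) == "A") "C" else "A"
  q1 <- paste0(strrep("I", 79), "#", strrep("I", 20))   # low qual at the lie
  writeLines(c("@p1", r1x, "+", q1), file.path(dir, "r1b.fq"))
  m3 <- merge_pairs(file.path(dir, "r1b.fq"), file.path(dir, "r2.fq"))
  expect_equal(m3$merged, base)

  # unpaired mates error
  writeLines(c("@zz", r1, "+", strrep("I", 100)), file.path(dir, "r1c.fq"))
  expect_error(merge_pairs(file.path(dir, "r1c.fq"), file.path(dir, "r2.fq")),
               "not paired")
})

test_that("read classification applies the HDR-marker gating rule", {
  d <- demo_design()
  ref <- d$reference_seq
  put <- function(s, pos, base) { substr(s, pos + 1, pos + 1) <- base; s }
  with_marker <- put(ref, 64, "T")

  expect_equal(classify_read(ref, d)$category, "WT")
  # marker + a codon change inside the target region -> that HDR variant
  r <- put(with_marker, 50, "G")
  cl <- classify_read(r, d)
  expect_equal(cl$category, "HDR_variant")
  expect_equal(cl$hgvs_c, "c.169T>G")
  # marker + full codon replacement TAC -> GAT
  r2 <- put(put(put(with_marker, 50, "G"), 51, "A"), 52, "T")
  cl2 <- classify_read(r2, d)
  expect_equal(cl2$category, "HDR_variant")
  expect_equal(cl2$hgvs_c, "c.169T>G;171C>T")  # middle base unchanged
  # marker only -> the wildtype-codon-with-marker key
  expect_equal(classify_read(with_marker, d)$hgvs_c, "WT_marker")
  # marker + an extra substitution outside the target region -> rejected
  r3 <- put(with_marker, 100, "A")
  expect_equal(classify_read(r3, d)$category, "rejected_other")
  # variant without the marker -> rejected (gating)
  expect_equal(classify_read(put(ref, 50, "G"), d)$category,
               "rejected_other")
  # marker + a 1-bp deletion -> indel, never HDR
  rdel <- paste0(substr(with_marker, 1, 60), substr(with_marker, 62, 220))
  cl4 <- classify_read(rdel, d)
  expect_equal(cl4$category, "indel")
  expect_equal(unname(cl4$indel["size"]), -1)
  # reads containing N are removed
  expect_equal(classify_read(put(ref, 10, "N"), d)$category, "rejected_N")
  # garbage read is an alignment failure
  expect_equal(classify_read(strrep("A", 220), d)$category,
               "alignment_failure")
})

test_that("classification is a partition and counts are conserved", {
  d <- demo_design()
  lib <- enumerate_codon_library(d, 58)
  cfg <- sim_config(error_rate = 0, hdr_rate = 0.3, indel_rate = 0.1,
                    depth_per_sample = 1000)
  tr <- simulate_ground_truth(lib, cfg, seed = 11)
  dir <- withr::local_tempdir()
  tc <- simulate_reads(tr, d, cfg, file.path(dir, "r1.fq"),
                       file.path(dir, "r2.fq"), n_reads = 400, seed = 12)
  m <- merge_pairs(file.path(dir, "r1.fq"), file.path(dir, "r2.fq"))
  cs <- call_sample(m$merged, d)
  expect_equal(sum(cs$tally), length(m$merged))        # partition
  expect_equal(cs$total, sum(cs$tally) - cs$tally[["alignment_failure"]])
  # noiseless HDR/WT counts round-trip exactly to the ground truth
  truth_counts <- setNames(tc$true_count, tc$key)
  hdr_keys <- names(cs$counts)[!grepl("^indel:", names(cs$counts))]
  expect_true(all(hdr_keys %in% names(truth_counts)))
  expect_equal(cs$counts[hdr_keys], truth_counts[hdr_keys])
  # all simulated indel reads are called as indels
  expect_equal(sum(cs$counts[grepl("^indel:", names(cs$counts))]),
               sum(truth_counts[grepl("^indel:", names(truth_counts))]))
})

test_that("reads with injected N bases are dropped downstream", {
  d <- demo_design()
  lib <- enumerate_codon_library(d, 57)[1:5]
  cfg <- sim_config(error_rate = 0, n_frac = 0.3, hdr_rate = 0.5,
                    indel_rate = 0)
  tr <- simulate_ground_truth(lib, cfg, seed = 5)
  dir <- withr::local_tempdir()
  simulate_reads(tr, d, cfg, file.path(dir, "r1.fq"), file.path(dir, "r2.fq"),
                 n_reads = 100, seed = 6)
  m <- merge_pairs(file.path(dir, "r1.fq"), file.path(dir, "r2.fq"))
  cs <- call_sample(m$merged, d)
  expect_gt(cs$tally[["rejected_N"]], 0)
})

test_that("indel spectra and editing summaries follow their definitions", {
  rows <- data.frame(key = c("c.169T>G", "WT", "indel:-1:0", "indel:2:3"),
                     type = c("variant", "WT", "indel", "indel"),
                     hgvs_c = c("c.169T>G", NA, NA, NA),
                     consequence = c("missense", NA, NA, NA),
                     position = c(50L, NA, 0L, 3L))
  samples <- data.frame(sample = c("d3_r1", "d3_r2"), day = 3L,
                        condition = "pre", replicate = 1:2)
  cnt <- matrix(c(10000, 979000, 10000, 1000,
                  10000, 978000, 11000, 1000), ncol = 2,
                dimnames = list(rows$key, samples$sample))
  ct <- count_table(cnt, rows, samples, totals = c(1e6, 1e6))
  es <- compute_editing_summary(ct)
  expect_equal(es$pct_hdr, c(1.0, 1.0))
  expect_equal(es$pct_indel, c(1.1, 1.2))
  sp <- compute_indel_spectrum(ct)
  expect_equal(unname(sp$size_freq["-1", ]), c(0.01, 0.011))
  expect_equal(unname(sp$pos_freq["0", ]), c(0.01, 0.011))
  # equal frequencies across samples -> z = 0 (SD guard)
  expect_equal(unname(sp$size_z["2", ]), c(0, 0))
  # all-WT sample
  ct0 <- count_table(matrix(c(0, 100, 0, 0), ncol = 1,
                            dimnames = list(rows$key, "d3_r1")),
                     rows, samples[1, ], totals = 100)
  es0 <- compute_editing_summary(ct0)
  expect_equal(es0$pct_hdr, 0)
  expect_equal(es0$pct_indel, 0)
})

test_that("count tables survive a TSV round trip", {
  d <- demo_design()
  lib <- enumerate_codon_library(d, 57)[1:10]
  tr <- simulate_ground_truth(lib, sim_config(depth_per_sample = 5000),
                              seed = 7)
  ct <- simulate_counts(tr, seed = 8)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_count_table(ct, path)
  ct2 <- read_count_table(path)
  expect_equal(unname(ct2$counts), unname(ct$counts))
  expect_equal(ct2$totals, ct$totals)
  expect_equal(ct2$samples$condition, ct$samples$condition)
})
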