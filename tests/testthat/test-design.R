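test_that("amplicon positions map to HGVS c. coordinates and back", {
  d <- demo_design()
  # anchor: first exonic base
  expect_identical(map_position(d, 50L), list(cdna = 169L, offset = 0L))
  expect_equal(cdna_label(d, 50L), "169")
  # 12 bases upstream of the exon start
  expect_equal(cdna_label(d, 38L), "169-12")
  # 7 bases past the exon end (last exonic base is c.288 at position 169)
  expect_equal(cdna_label(d, 176L), "288+7")
  # round-trip over every exonic and near-intronic position
  for (p in c(30:49, 50:169, 170:190)) {
    m <- map_position(d, p)
    expect_identical(cdna_to_pos(d, m$cdna, m$offset), p)
  }
  expect_error(map_position(d, 220L), "outside")
  expect_error(map_position(d, -1L), "outside")
})

test_that("multi-exon designs anchor intron offsets to the nearer exon", {
  d <- two_exon_design()
  expect_equal(cdna_label(d, 5L), "1")
  expect_equal(cdna_label(d, 12L), "8")
  expect_equal(cdna_label(d, 19L), "9")     # c. numbering continues
  expect_equal(cdna_label(d, 13L), "8+1")   # first intronic base
  expect_equal(cdna_label(d, 18L), "9-1")   # last intronic base
  expect_equal(cdna_label(d, 15L), "8+3")   # tie anchors to preceding exon
  for (p in 0:32) {
    m <- map_position(d, p)
    expect_identical(cdna_to_pos(d, m$cdna, m$offset), p)
  }
})

test_that("consequences follow the codon table in the declared frame", {
  d <- demo_design()
  # TAC -> TAA at residue 57 is the classic nonsense control
  k <- variant_key(d, data.frame(pos = "c.171", ref = "C", alt = "A"))
  expect_equal(k$consequence$kind, "nonsense")
  expect_equal(k$hgvs_p, "p.Tyr57*")
  expect_equal(k$hgvs_c, "c.171C>A")
  # CTG -> CCG is Leu -> Pro (residue 61, c.182T>C)
  k2 <- variant_key(d, data.frame(pos = "c.182", ref = "T", alt = "C"),
                    check_marker = FALSE)
  expect_equal(k2$consequence$kind, "missense")
  expect_equal(k2$consequence$aa_ref, "L")
  expect_equal(k2$consequence$aa_alt, "P")
  expect_equal(k2$hgvs_p, "p.Leu61Pro")
  # synonymous third-base change: GGT -> GGC at residue 60 (c.180)
  k3 <- variant_key(d, data.frame(pos = "c.180", ref = "T", alt = "C"))
  expect_equal(k3$consequence$kind, "synonymous")
  # multi-base codon replacement translated as a unit: TAC -> GCT (Ala)
  k4 <- variant_key(d, data.frame(pos = c(50L, 51L, 52L),
                                  ref = c("T", "A", "C"),
                                  alt = c("G", "C", "T")))
  expect_equal(k4$consequence$kind, "missense")
  expect_equal(k4$consequence$aa_alt, "A")
  # ref mismatch is an error
  expect_error(variant_key(d, data.frame(pos = 50L, ref = "G", alt = "A")),
               "do not match")
})

test_that("intronic and splice-region edits are labelled as such", {
  d <- demo_design()
  k_spl <- variant_key(d, data.frame(pos = 48L, ref = "T", alt = "A"))
  expect_equal(k_spl$consequence$kind, "splice_region")
  expect_equal(k_spl$hgvs_p, "")
  k_int <- variant_key(d, data.frame(pos = 40L, ref = "T", alt = "C"))
  expect_equal(k_int$consequence$kind, "intronic")
  k_don <- variant_key(d, data.frame(pos = 170L, ref = "G", alt = "C"))
  expect_equal(k_don$consequence$kind, "splice_region")
})

test_that("codon libraries carry 63 keys partitioned like brute-force translation", {
  d <- demo_design()
  for (res in c(57L, 58L)) {
    lib <- enumerate_codon_library(d, res)
    expect_length(lib, 63)
    tab <- library_table(lib)
    expect_false(any(duplicated(tab$hgvs_c)))
    # oracle: translate all 64 codons directly
    bases <- c("A", "C", "G", "T")
    wt <- substring(d$reference_seq, (3 * res - 2):(3 * res) - 168 + 50,
                    (3 * res - 2):(3 * res) - 168 + 50)
    codons <- expand.grid(bases, bases, bases, stringsAsFactors = FALSE)
    codons <- codons[!(codons[, 1] == wt[1] & codons[, 2] == wt[2] &
                         codons[, 3] == wt[3]), ]
    aas <- apply(codons, 1, function(b)
      as.character(Biostrings::GENETIC_CODE[paste(b, collapse = "")]))
    wt_aa <- as.character(Biostrings::GENETIC_CODE[paste(wt, collapse = "")])
    expect_equal(sum(tab$consequence == "nonsense"), sum(aas == "*"))
    expect_equal(sum(tab$consequence == "synonymous"),
                 sum(aas == wt_aa & aas != "*"))
    expect_equal(sum(tab$consequence == "missense"),
                 sum(aas != wt_aa & aas != "*"))
  }
  # WT codon TAC has exactly the 3 stop codons among its 63 replacements
  expect_equal(sum(library_table(enumerate_codon_library(d, 57))$consequence
                   == "nonsense"), 3)
})

test_that("SNV libraries hold 3 variants per position", {
  d <- demo_design()
  lib <- enumerate_snv_library(d, 50L, 59L)
  expect_length(lib, 30)
  lib1 <- enumerate_snv_library(d, "c.171", "c.171")
  expect_length(lib1, 3)
  expect_setequal(vapply(lib1, `[[`, character(1), "hgvs_c"),
                  c("c.171C>A", "c.171C>G", "c.171C>T"))
  expect_error(enumerate_snv_library(d, 59L, 50L), "inverted")
})

test_that("designs validate their invariants", {
  expect_error(amplicon_design("x", "ACGTACGTAC", rbind(c(2L, 8L)), 0L, 5L,
                               data.frame(pos = 3L, ref = "T", alt = "G"),
                               c(2L, 8L)),
               "not synonymous")
  expect_error(amplicon_design("x", "ACGTNCGT", rbind(c(0L, 8L)), 0L, 4L,
                               data.frame(pos = 0L, ref = "A", alt = "G"),
                               c(0L, 8L)),
               "only A, C, G, T")
  expect_error(amplicon_design("x", "ACGTACGT", rbind(c(0L, 8L)), 0L, 40L,
                               data.frame(pos = 2L, ref = "G", alt = "A"),
                               c(0L, 8L)),
               "cut site")
})

test_that("design YAML round-trips through read_amplicon_design", {
  d <- demo_design()
  dir <- withr::local_tempdir()
  writeLines(c(">demo_exon", d$reference_seq), file.path(dir, "ref.fa"))
  yaml::write_yaml(list(
    amplicon_id = d$amplicon_id,
    reference_fasta = "ref.fa",
    exon_intervals = list(as.integer(d$exon_intervals[1, ])),
    cdna_offset = d$cdna_offset,
    cut_sites = d$cut_sites,
    marker_edits = list(list(pos = 64L, ref = "G", alt = "T")),
    target_region = c(50L, 59L)), file.path(dir, "design.yaml"))
  d2 <- read_amplicon_design(file.path(dir, "design.yaml"))
  expect_equal(d2$reference_seq, d$reference_seq)
  expect_equal(d2$cdna_offset, d$cdna_offset)
  expect_equal(cdna_label(d2, 38L), "169-12")
})
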