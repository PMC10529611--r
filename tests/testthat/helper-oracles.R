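# Brute-force oracles kept deliberately independent of the implementation.

# exhaustive global-alignment score by recursion over all edit paths
brute_nw_score <- function(a, b, match = 2, mismatch = -1, gap = -2) {
  memo <- new.env(hash = TRUE)
  rec <- function(i, j) {
    if (i == 0 && j == 0) return(0)
    key <- paste(i, j)
    if (!is.null(memo[[key]])) return(memo[[key]])
    best <- -Inf
    if (i > 0 && j > 0)
      best <- max(best, rec(i - 1, j - 1) +
                    if (substr(a, i, i) == substr(b, j, j)) match else mismatch)
    if (i > 0) best <- max(best, rec(i - 1, j) + gap)
    if (j > 0) best <- max(best, rec(i, j - 1) + gap)
    memo[[key]] <- best
    best
  }
  rec(nchar(a), nchar(b))
}

# all sequences of a given length over an alphabet
all_seqs <- function(len, alphabet = c("A", "C")) {
  if (len == 0) return("")
  apply(do.call(expand.grid, rep(list(alphabet), len)), 1, paste,
        collapse = "")
}

# naive confusion-table metrics calculator
brute_metrics <- function(tp, fn, tn, fp) {
  sens <- 100 * tp / (tp + fn)
  spec <- 100 * tn / (tn + fp)
  list(sens = sens, spec = spec,
       lr_plus = sens / (100 - spec),
       lr_minus = (100 - sens) / spec)
}

# a two-exon design for intron/coordinate tests: 8-base exon 1, 6-base
# intron, 9-base exon 2 inside a 33-base amplicon
two_exon_design <- function() {
  ref <- paste0("ACGTA",        # intron-side flank, positions 0-4
                "ATGGCTAC",     # exon 1, positions 5-12  (c.1-8)
                "GTTTAG",       # intron, positions 13-18
                "ACCGGTTAA",    # exon 2, positions 19-27 (c.9-17)
                "CCGGA")        # flank, positions 28-32
  amplicon_design(
    amplicon_id = "two_exon",
    reference_seq = ref,
    exon_intervals = rbind(c(5L, 13L), c(19L, 28L)),
    cdna_offset = 0L,
    cut_sites = 10L,
    marker_edits = data.frame(pos = 2L, ref = "G", alt = "A"),  # intronic
    target_region = c(5L, 13L))
}
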