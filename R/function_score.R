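#' Pseudocounted frequency normalization
#'
#' Every cell gets a pseudocount of 1 and is divided by the per-sample total
#' of aligned reads (the library total, not the per-variant sum), so
#' frequencies are strictly positive and a variant absent at day 14 still has
#' a finite dropout score.
#'
#' @param ct an `sge_counts` object.
#' @return object of class `sge_freq`: list with `freq` matrix, `rows`,
#'   `samples`, `counts`, `totals`.
#' @export
normalize_frequencies <- function(ct) {
  stopifnot(inherits(ct, "sge_counts"))
  if (any(ct$totals <= 0)) stop("per-sample totals must be positive")
  freq <- sweep(ct$counts + 1, 2, ct$totals, "/")
  structure(list(freq = freq, rows = ct$rows, samples = ct$samples,
                 counts = ct$counts, totals = ct$totals),
            class = "sge_freq")
}

day3_cols <- function(x, replicate = NULL) {
  i <- x$samples$day == 3
  if (!is.null(replicate)) i <- i & x$samples$replicate == replicate
  x$samples$sample[i]
}

day14_col <- function(x, condition, replicate) {
  x$samples$sample[x$samples$day == 14 & x$samples$condition == condition &
                     x$samples$replicate == replicate]
}

#' Function scores from a frequency table
#'
#' The function score (FS) of a variant in an arm is the log2 ratio of its
#' day-14 frequency to its day-3 frequency, per replicate (matched replicate
#' pairing) and averaged over the two replicates. The untransformed post/pre
#' ratios per condition (and their replicate mean) are carried along for the
#' exon-wide scoring path.
#'
#' @param fq an [normalize_frequencies()] result.
#' @return data.frame of class `sge_fs`: one row per HDR variant with
#'   `fs_<cond>_r<k>`, `fs_<cond>` (replicate mean), `ratio_<cond>_r<k>` and
#'   `ratio_<cond>` columns.
#' @export
compute_fs <- function(fq) {
  stopifnot(inherits(fq, "sge_freq"))
  conds <- unique(fq$samples$condition[fq$samples$day == 14])
  reps <- sort(unique(fq$samples$replicate))
  vi <- fq$rows$type == "variant"
  out <- fq$rows[vi, c("key", "hgvs_c", "consequence", "position")]
  f <- fq$freq[vi, , drop = FALSE]
  for (cond in conds) {
    fs_reps <- ratio_reps <- NULL
    for (r in reps) {
      ratio <- f[, day14_col(fq, cond, r)] / f[, day3_cols(fq, r)]
      out[[paste0("ratio_", cond, "_r", r)]] <- ratio
      out[[paste0("fs_", cond, "_r", r)]] <- log2(ratio)
      ratio_reps <- cbind(ratio_reps, ratio)
      fs_reps <- cbind(fs_reps, log2(ratio))
    }
    out[[paste0("ratio_", cond)]] <- rowMeans(ratio_reps)
    out[[paste0("fs_", cond)]] <- rowMeans(fs_reps)
  }
  class(out) <- c("sge_fs", "data.frame")
  out
}

#' Day-3 abundance filter for the degenerate-codon libraries
#'
#' A variant is retained only when its day-3 frequency exceeds 1 in 1e5 in
#' both replicates; a frequency at or below the threshold in any one replicate
#' flags the variant `low_freq` and removes it (the boundary case is resolved
#' as excluded: keeping requires strictly "more than" the threshold).
#'
#' @param fq an [normalize_frequencies()] result.
#' @param threshold day-3 frequency threshold (default 1e-5).
#' @return list of class `sge_filter`: `keep` (named logical over variant
#'   keys), `flags` (per-variant character), `report` (per-filter removal
#'   counts and surviving count).
#' @export
apply_codon_filters <- function(fq, threshold = 1e-5) {
  stopifnot(inherits(fq, "sge_freq"))
  vi <- fq$rows$type == "variant"
  d3 <- fq$freq[vi, day3_cols(fq), drop = FALSE]
  low <- apply(d3 <= threshold, 1, any)
  keep <- setNames(!low, fq$rows$key[vi])
  flags <- setNames(ifelse(low, "low_freq", ""), fq$rows$key[vi])
  structure(list(keep = keep, flags = flags,
                 report = data.frame(filter = "low_freq",
                                     removed = sum(low),
                                     surviving = sum(!low))),
            class = "sge_filter")
}

#' @export
print.sge_filter <- function(x, ...) {
  print(x$report); invisible(x)
}

fold_diff <- function(a, b) pmax(a, b) / pmin(a, b)

prelim_class_calls <- function(fs, conds, reps) {
  # per (condition, replicate) two-class call against the midpoint of the
  # synonymous and nonsense control medians of the replicate's log2 ratios
  calls <- list()
  for (cond in conds) for (r in reps) {
    v <- fs[[paste0("fs_", cond, "_r", r)]]
    syn <- median(v[fs$consequence == "synonymous"])
    non <- median(v[fs$consequence == "nonsense"])
    mid <- (syn + non) / 2
    calls[[paste0(cond, "_r", r)]] <-
      ifelse(v < mid, "non_functional", "functional")
  }
  calls
}

#' Read-count and replicate-concordance filters for the SNV-saturation path
#'
#' Removes variants with a day-3 read count below `min_day3_count` or day-3
#' frequency at or below `freq_threshold` in any replicate; variants whose two
#' DMSO post/pre ratios differ by more than `ratio_diff` *and* whose
#' per-replicate preliminary class calls diverge; and variants failing that
#' same two-part test in two or more conditions.
#'
#' "Differ by more than 2" is interpreted as a fold difference (max/min of the
#' two ratios) by default, these being multiplicative quantities; set
#' `diff_mode = "arithmetic"` for an absolute difference.
#'
#' @param fq an [normalize_frequencies()] result.
#' @param fs the matching [compute_fs()] table.
#' @param min_day3_count minimum day-3 read count (default 10).
#' @param freq_threshold day-3 frequency threshold (default 1e-5).
#' @param ratio_diff replicate post/pre ratio discordance bound (default 2).
#' @param diff_mode `"fold"` or `"arithmetic"`.
#' @return an `sge_filter` object (see [apply_codon_filters()]).
#' @export
apply_exon13_filters <- function(fq, fs, min_day3_count = 10,
                                 freq_threshold = 1e-5, ratio_diff = 2,
                                 diff_mode = c("fold", "arithmetic")) {
  diff_mode <- match.arg(diff_mode)
  stopifnot(inherits(fq, "sge_freq"), inherits(fs, "sge_fs"))
  vi <- fq$rows$type == "variant"
  keys <- fq$rows$key[vi]
  stopifnot(identical(keys, fs$key))
  d3f <- fq$freq[vi, day3_cols(fq), drop = FALSE]
  d3c <- fq$counts[vi, day3_cols(fq), drop = FALSE]
  low_count <- apply(d3c < min_day3_count, 1, any)
  low_freq <- apply(d3f <= freq_threshold, 1, any)
  conds <- unique(fq$samples$condition[fq$samples$day == 14])
  reps <- sort(unique(fq$samples$replicate))
  calls <- prelim_class_calls(fs, conds, reps)
  discord <- sapply(conds, function(cond) {
    r1 <- fs[[paste0("ratio_", cond, "_r", reps[1])]]
    r2 <- fs[[paste0("ratio_", cond, "_r", reps[2])]]
    big <- if (diff_mode == "fold") fold_diff(r1, r2) > ratio_diff
           else abs(r1 - r2) > ratio_diff
    divergent <- calls[[paste0(cond, "_r", reps[1])]] !=
      calls[[paste0(cond, "_r", reps[2])]]
    big & divergent
  })
  dmso_discord <- discord[, "DMSO"]
  multi_discord <- rowSums(discord) >= 2
  flags <- ifelse(low_count, "low_day3_count",
                  ifelse(low_freq, "low_freq",
                         ifelse(dmso_discord | multi_discord,
                                "replicate_discordant", "")))
  keep <- setNames(flags == "", keys)
  report <- data.frame(
    filter = c("low_day3_count", "low_freq", "replicate_discordant"),
    removed = c(sum(low_count), sum(low_freq & !low_count),
                sum((dmso_discord | multi_discord) & !low_count & !low_freq)),
    surviving = sum(keep))
  structure(list(keep = keep, flags = setNames(flags, keys), report = report),
            class = "sge_filter")
}

#' Weighted global post/pre ratio
#'
#' The per-variant global ratio is the weighted mean of the per-condition
#' mean post/pre ratios (default weights 0.4 for DMSO and 0.25 for each drug
#' arm), normalized by the weight sum (0.9, since the stated weights do not
#' sum to 1). Its log2 feeds the exon-wide scoring and mixture classifier.
#'
#' @param fs a [compute_fs()] table.
#' @param weights named condition weights.
#' @return numeric vector of per-variant global ratios.
#' @export
compute_global_ratio <- function(fs, weights = c(DMSO = 0.4, cisplatin = 0.25,
                                                 olaparib = 0.25)) {
  cols <- paste0("ratio_", names(weights))
  if (!all(cols %in% names(fs)))
    stop("missing condition ratio column(s): ",
         paste(setdiff(cols, names(fs)), collapse = ", "))
  m <- as.matrix(fs[, cols])
  as.numeric(m %*% weights) / sum(weights)
}
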