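#' Construct a per-variant, per-sample count table
#'
#' Rows are HDR variant keys plus the pseudo-keys `WT` and `indel:size:offset`;
#' columns are samples (day 3 pre-selection replicates and day 14 per
#' condition/replicate). `totals` are per-sample totals of aligned reads,
#' which may exceed the column sums when some aligned categories are not
#' tabulated.
#'
#' @param counts integer matrix, alleles x samples.
#' @param rows data.frame with `key`, `type` (variant/WT/indel), `hgvs_c`,
#'   `consequence`, `position`.
#' @param samples data.frame with `sample`, `day`, `condition`, `replicate`.
#' @param totals per-sample total aligned reads.
#' @return object of class `sge_counts`.
#' @export
count_table <- function(counts, rows, samples, totals) {
  counts <- as.matrix(counts)
  stopifnot(nrow(counts) == nrow(rows), ncol(counts) == nrow(samples),
            length(totals) == ncol(counts), all(counts >= 0),
            all(totals >= colSums(counts) - 1e-9))
  dimnames(counts) <- list(rows$key, samples$sample)
  names(totals) <- samples$sample
  structure(list(counts = counts, rows = rows, samples = samples,
                 totals = totals), class = "sge_counts")
}

#' @export
print.sge_counts <- function(x, ...) {
  cat("SGE count table: ", sum(x$rows$type == "variant"), " variants, ",
      sum(x$rows$type == "indel"), " indel alleles, ",
      ncol(x$counts), " samples, median depth ",
      format(median(x$totals), big.mark = ","), "\n", sep = "")
  invisible(x)
}

read_fastq_pairs <- function(r1_path, r2_path) {
  r1 <- suppressWarnings(Biostrings::readQualityScaledDNAStringSet(r1_path))
  r2 <- suppressWarnings(Biostrings::readQualityScaledDNAStringSet(r2_path))
  id1 <- sub("[/ ].*$", "", names(r1))
  id2 <- sub("[/ ].*$", "", names(r2))
  if (length(r1) != length(r2) || !setequal(id1, id2))
    stop("R1 and R2 mates are not paired by ID")
  r2 <- suppressWarnings(r2[match(id1, id2)])
  list(id = id1,
       s1 = as.character(r1), q1 = as.character(Biostrings::quality(r1)),
       s2 = as.character(r2), q2 = as.character(Biostrings::quality(r2)))
}

merge_one_pair <- function(s1, q1, s2rc, q2rc, min_overlap, max_mismatch_frac) {
  b1 <- strsplit(s1, "")[[1]]; b2 <- strsplit(s2rc, "")[[1]]
  n1 <- length(b1); n2 <- length(b2)
  if (min(n1, n2) < min_overlap) return(NULL)
  best_frac <- Inf; best_v <- 0L
  for (v in seq(min(n1, n2), min_overlap)) {
    ov1 <- b1[(n1 - v + 1):n1]; ov2 <- b2[1:v]
    mm <- sum(ov1 != ov2)
    frac <- mm / v
    if (frac <= max_mismatch_frac &&
        (frac < best_frac - 1e-12 ||
         (abs(frac - best_frac) <= 1e-12 && v > best_v))) {
      best_frac <- frac; best_v <- v
      if (frac == 0) break   # no smaller overlap can beat a perfect one
    }
  }
  if (best_v == 0L) return(NULL)
  v <- best_v
  ov1 <- b1[(n1 - v + 1):n1]; ov2 <- b2[1:v]
  qv1 <- strsplit(q1, "")[[1]][(n1 - v + 1):n1]
  qv2 <- strsplit(q2rc, "")[[1]][1:v]
  take2 <- ov1 != ov2 & utf8ToInt(paste(qv2, collapse = "")) >
    utf8ToInt(paste(qv1, collapse = ""))
  ov <- ov1; ov[take2] <- ov2[take2]
  paste0(paste(b1[seq_len(n1 - v)], collapse = ""),
         paste(ov, collapse = ""),
         paste(b2[seq.int(v + 1, length.out = n2 - v)], collapse = ""))
}

#' Merge overlapping paired-end reads
#'
#' For each pair, the reverse-complemented mate 2 is overlapped against mate 1
#' at every offset with overlap at least `min_overlap`; the overlap with the
#' lowest mismatch fraction (ties: longest) not exceeding `max_mismatch_frac`
#' is used. Disagreeing overlap bases are resolved in favour of the mate with
#' the higher base quality. Unmergeable pairs are dropped and counted.
#'
#' @param r1_path,r2_path FASTQ files (gzip allowed), mates paired by ID.
#' @param min_overlap minimum overlap length (default 10).
#' @param max_mismatch_frac maximum mismatch fraction in the overlap
#'   (default 0.25).
#' @return list with `id`, `merged` (character vector of merged sequences)
#'   and `n_dropped`.
#' @export
merge_pairs <- function(r1_path, r2_path, min_overlap = 10L,
                        max_mismatch_frac = 0.25) {
  p <- read_fastq_pairs(r1_path, r2_path)
  s2rc <- revcomp(p$s2)
  q2rc <- vapply(p$q2, function(q) paste(rev(strsplit(q, "")[[1]]),
                                         collapse = ""),
                 character(1), USE.NAMES = FALSE)
  merged <- character(0); ids <- character(0); dropped <- 0L
  for (i in seq_along(p$s1)) {
    m <- merge_one_pair(p$s1[i], p$q1[i], s2rc[i], q2rc[i],
                        min_overlap, max_mismatch_frac)
    if (is.null(m)) dropped <- dropped + 1L
    else { merged <- c(merged, m); ids <- c(ids, p$id[i]) }
  }
  list(id = ids, merged = merged, n_dropped = dropped)
}

#' Global (Needleman-Wunsch) alignment of a read to the reference amplicon
#'
#' Optimal global alignment under linear scoring (defaults: match +2,
#' mismatch -1, gap -2) with deterministic tie-breaking: a substitution is
#' preferred over a gap, and a gap in the read over a gap in the reference.
#' Gap runs are subsequently left-aligned so indel positions are reproducible.
#'
#' @param read,reference sequences over A, C, G, T, N.
#' @param match,mismatch,gap scoring parameters.
#' @return list with `aligned_read`, `aligned_ref`, `score`.
#' @export
align_global <- function(read, reference, match = 2, mismatch = -1, gap = -2) {
  read <- toupper(read); reference <- toupper(reference)
  if (!nzchar(read) || !nzchar(reference)) stop("empty sequence")
  if (grepl("[^ACGTN]", read) || grepl("[^ACGTN]", reference))
    stop("sequences must contain only A, C, G, T, N")
  aln <- .nw_align_cpp(read, reference, match, mismatch, gap)
  left_align_gaps(aln)
}

# shift every gap run as far left as the flanking sequence allows; the score
# is unchanged because only equal bases are exchanged across the gap.
left_align_gaps <- function(aln) {
  for (which in c("aligned_read", "aligned_ref")) {
    g <- strsplit(aln[[which]], "")[[1]]
    other_name <- setdiff(c("aligned_read", "aligned_ref"), which)
    o <- strsplit(aln[[other_name]], "")[[1]]
    repeat {
      moved <- FALSE
      r <- rle(g == "-")
      ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1
      for (k in which(r$values)) {
        s <- starts[k]; e <- ends[k]
        while (s > 1 && g[s - 1] != "-" && o[s - 1] != "-" &&
               g[s - 1] == o[e]) {
          # move the non-gap base rightwards across the gap
          g[e] <- g[s - 1]; g[s - 1] <- "-"
          s <- s - 1; e <- e - 1
          moved <- TRUE
        }
      }
      if (!moved) break
    }
    aln[[which]] <- paste(g, collapse = "")
  }
  aln
}

#' Classify one merged read against the amplicon design
#'
#' Applies the HDR-marker gating rule: reads containing `N` are rejected; any
#' alignment gap makes the read an indel (signed size and leftmost-gap-edge
#' offset from the cut site, after left-alignment); otherwise a read is
#' counted as an HDR variant only when all marker edits are present and every
#' remaining substitution lies inside the target region (a marker-only read
#' maps to the wildtype-codon-with-marker key `WT_marker`); reads identical to
#' the reference are `WT`; anything else is `rejected_other`.
#'
#' @param read merged read sequence.
#' @param design an [amplicon_design()].
#' @param min_score_frac reads scoring below this fraction of the perfect
#'   alignment score are excluded as alignment failures.
#' @param ... scoring parameters passed to [align_global()].
#' @return list with `category`, `hgvs_c`, `edits`, `indel`.
#' @export
classify_read <- function(read, design, min_score_frac = 0.6, ...) {
  out <- list(category = "rejected_other", hgvs_c = NA_character_,
              edits = NULL, indel = NULL)
  if (grepl("N", read, fixed = TRUE)) {
    out$category <- "rejected_N"; return(out)
  }
  ref <- design$reference_seq
  aln <- align_global(read, ref, ...)
  if (aln$score < min_score_frac * 2 * nchar(ref)) {
    out$category <- "alignment_failure"; return(out)
  }
  gr <- strsplit(aln$aligned_read, "")[[1]]
  gz <- strsplit(aln$aligned_ref, "")[[1]]
  refpos <- cumsum(gz != "-") - 1L        # 0-based ref position per column
  if (any(gr == "-") || any(gz == "-")) {
    isgap <- gr == "-" | gz == "-"
    first <- which(isgap)[1]
    run_end <- first
    while (run_end < length(gr) && isgap[run_end + 1]) run_end <- run_end + 1
    size <- if (gr[first] == "-") -(run_end - first + 1L)
            else (run_end - first + 1L)
    at <- if (gz[first] == "-") refpos[first] + 1L else refpos[first]
    out$category <- "indel"
    out$indel <- c(size = size, offset = at - design$cut_sites[1])
    return(out)
  }
  subs <- which(gr != gz)
  sub_pos <- refpos[subs]; sub_alt <- gr[subs]
  mk <- design$marker_edits
  marker_ok <- all(mk$pos %in% sub_pos &
                     sub_alt[match(mk$pos, sub_pos)] == mk$alt)
  nonmk <- !(sub_pos %in% mk$pos)
  if (length(subs) == 0) { out$category <- "WT"; return(out) }
  if (marker_ok) {
    extra_pos <- sub_pos[nonmk]; extra_alt <- sub_alt[nonmk]
    if (length(extra_pos) == 0) {
      out$category <- "HDR_variant"; out$hgvs_c <- "WT_marker"
      return(out)
    }
    if (all(extra_pos >= design$target_region[1] &
            extra_pos < design$target_region[2])) {
      ed <- data.frame(pos = extra_pos,
                       ref = substring(ref, extra_pos + 1, extra_pos + 1),
                       alt = extra_alt)
      key <- variant_key(design, ed)
      out$category <- "HDR_variant"; out$hgvs_c <- key$hgvs_c
      out$edits <- ed
      return(out)
    }
  }
  out
}

#' Call and tabulate merged reads for one sample
#'
#' @param merged character vector of merged reads.
#' @param design an [amplicon_design()].
#' @param ... passed to [classify_read()].
#' @return list with per-key `counts` (named integer vector over HDR variant
#'   keys, `WT` and `indel:size:offset` pseudo-keys), category `tally`, and
#'   `total` aligned reads (all categories except alignment failures).
#' @export
call_sample <- function(merged, design, ...) {
  cls <- lapply(merged, classify_read, design = design, ...)
  cat_ <- vapply(cls, `[[`, character(1), "category")
  keys <- character(length(cls))
  keys[cat_ == "HDR_variant"] <-
    vapply(cls[cat_ == "HDR_variant"], `[[`, character(1), "hgvs_c")
  keys[cat_ == "WT"] <- "WT"
  keys[cat_ == "indel"] <- vapply(cls[cat_ == "indel"], function(x)
    paste0("indel:", x$indel["size"], ":", x$indel["offset"]), character(1))
  tab <- table(keys[nzchar(keys)])
  list(counts = setNames(as.integer(tab), names(tab)),
       tally = table(factor(cat_, levels = c(
         "WT", "HDR_variant", "indel", "rejected_N", "rejected_other",
         "alignment_failure"))),
       total = sum(cat_ != "alignment_failure"))
}

#' Assemble per-sample calls into an `sge_counts` table
#'
#' @param calls named list of [call_sample()] results, one per sample.
#' @param samples data.frame describing the samples (`sample`, `day`,
#'   `condition`, `replicate`), rows matching `names(calls)`.
#' @param design the [amplicon_design()] used for calling.
#' @return an `sge_counts` object.
#' @export
count_variants <- function(calls, samples, design) {
  keys <- sort(unique(unlist(lapply(calls, function(x) names(x$counts)))))
  cnt <- sapply(calls, function(x) {
    v <- setNames(integer(length(keys)), keys)
    v[names(x$counts)] <- x$counts
    v
  })
  cnt <- matrix(cnt, nrow = length(keys),
                dimnames = list(keys, samples$sample))
  type <- ifelse(keys == "WT", "WT",
                 ifelse(grepl("^indel:", keys), "indel", "variant"))
  pos <- rep(NA_integer_, length(keys))
  pos[type == "indel"] <- as.integer(sub("^indel:[^:]+:", "", keys[type == "indel"]))
  cons <- rep(NA_character_, length(keys))
  cons[keys == "WT_marker"] <- "synonymous"
  idx <- which(type == "variant" & keys != "WT_marker")
  for (i in idx) {
    ed <- parse_hgvs_edits(design, keys[i])
    k <- variant_key(design, ed)
    cons[i] <- k$consequence$kind
    pos[i] <- k$edits$pos[1]
  }
  rows <- data.frame(key = keys, type = type, hgvs_c = ifelse(
    type == "variant", keys, NA), consequence = cons, position = pos,
    stringsAsFactors = FALSE)
  count_table(cnt, rows, samples,
              totals = vapply(calls, `[[`, numeric(1), "total"))
}

parse_hgvs_edits <- function(design, hgvs) {
  parts <- strsplit(sub("^c\\.", "", hgvs), ";")[[1]]
  ed <- list()
  for (p in parts) {
    m <- regmatches(p, regexec(
      "^(\\d+[+-]?\\d*)(?:_(\\d+[+-]?\\d*))?([ACGT]+)>([ACGT]+)$", p))[[1]]
    if (length(m) == 0) stop("cannot parse variant label: ", hgvs)
    start <- resolve_position(design, m[2])
    refs <- strsplit(m[4], "")[[1]]; alts <- strsplit(m[5], "")[[1]]
    for (k in seq_along(refs)) {
      if (refs[k] != alts[k])
        ed[[length(ed) + 1]] <- data.frame(pos = start + k - 1L,
                                           ref = refs[k], alt = alts[k])
    }
  }
  do.call(rbind, ed)
}

#' Indel size and position spectra from a count table
#'
#' Per-sample frequencies of each indel allele (count over total aligned
#' reads), aggregated by signed size and by position offset from the cut
#' site, plus a z-score view per size bin across samples (zero SD gives z=0).
#'
#' @param ct an `sge_counts` object.
#' @return list with `size_freq`, `pos_freq`, `size_z` matrices.
#' @export
compute_indel_spectrum <- function(ct) {
  if (any(ct$totals == 0)) stop("zero per-sample total; frequency undefined")
  idx <- ct$rows$type == "indel"
  if (!any(idx)) stop("count table has no indel pseudo-keys")
  keys <- ct$rows$key[idx]
  size <- as.integer(sub("^indel:([^:]+):.*$", "\\1", keys))
  offset <- as.integer(sub("^indel:[^:]+:", "", keys))
  freq <- sweep(ct$counts[idx, , drop = FALSE], 2, ct$totals, "/")
  size_freq <- rowsum(freq, size)
  pos_freq <- rowsum(freq, offset)
  size_z <- t(apply(size_freq, 1, function(f) {
    s <- sd(f)
    if (is.na(s) || s == 0) rep(0, length(f)) else (f - mean(f)) / s
  }))
  dimnames(size_z) <- dimnames(size_freq)
  list(size_freq = size_freq, pos_freq = pos_freq, size_z = size_z)
}

#' Per-sample editing summary
#'
#' @param ct an `sge_counts` object.
#' @return data.frame with per-sample `pct_hdr` and `pct_indel` (percent of
#'   total aligned reads).
#' @export
compute_editing_summary <- function(ct) {
  stopifnot(all(ct$totals > 0))
  hdr <- colSums(ct$counts[ct$rows$type == "variant", , drop = FALSE])
  ind <- colSums(ct$counts[ct$rows$type == "indel", , drop = FALSE])
  data.frame(sample = ct$samples$sample,
             pct_hdr = 100 * hdr / ct$totals,
             pct_indel = 100 * ind / ct$totals,
             row.names = NULL)
}

#' Write / read an `sge_counts` table as TSV
#'
#' The layout is one row per allele with its metadata columns followed by one
#' column per sample, plus a `__total__` row carrying per-sample totals; the
#' sample descriptors are recycled from the column names (`d3_r1`,
#' `d14_DMSO_r2`, ...).
#'
#' @param ct an `sge_counts` object.
#' @param path output TSV path.
#' @export
write_count_table <- function(ct, path) {
  df <- cbind(ct$rows, as.data.frame(ct$counts, check.names = FALSE))
  tot <- df[1, ]; tot[] <- NA
  tot$key <- "__total__"; tot$type <- "total"
  tot[, ct$samples$sample] <- ct$totals
  write.table(rbind(df, tot), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
}

#' @rdname write_count_table
#' @return `read_count_table()` returns an `sge_counts` object.
#' @export
read_count_table <- function(path) {
  df <- read.delim(path, check.names = FALSE)
  meta_cols <- c("key", "type", "hgvs_c", "consequence", "position")
  samp_cols <- setdiff(names(df), meta_cols)
  tot_row <- df$key == "__total__"
  totals <- as.numeric(df[tot_row, samp_cols])
  df <- df[!tot_row, ]
  parse_sample <- function(s) {
    p <- strsplit(s, "_")[[1]]
    if (p[1] == "d3") data.frame(sample = s, day = 3L, condition = "pre",
                                 replicate = as.integer(sub("r", "", p[2])))
    else data.frame(sample = s, day = 14L, condition = p[2],
                    replicate = as.integer(sub("r", "", p[3])))
  }
  samples <- do.call(rbind, lapply(samp_cols, parse_sample))
  count_table(as.matrix(df[, samp_cols]), df[, meta_cols], samples, totals)
}
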