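#' Simulation settings for a synthetic SGE experiment
#'
#' Defaults emulate the study conditions of a saturation-genome-editing drug
#' assay in mouse ES cells: 2 million reads per sample, HDR knock-in rates
#' around 1% (observed range 0.3-2.3%), an NHEJ indel spectrum centred on the
#' cut site, day-3 to day-14 selection across DMSO, cisplatin and olaparib
#' arms in two replicates, and a bimodal function-score structure (functional
#' variants around 0 log2 units, non-functional around -3) plus a small
#' hypomorph class sensitive only in the drug arms.
#'
#' @param depth_per_sample reads per sample (default 2e6).
#' @param hdr_rate fraction of day-3 reads carrying an HDR variant allele.
#' @param indel_rate fraction of day-3 reads carrying an NHEJ indel allele.
#' @param error_rate per-base sequencing substitution error rate (reads only).
#' @param n_frac fraction of simulated reads given an 'N' base.
#' @param read_length paired-end read length.
#' @param fs_mean_functional,fs_sd_functional true log2 fold-change
#'   distribution of functional variants (all arms).
#' @param fs_mean_nonfunctional,fs_sd_nonfunctional likewise for
#'   non-functional variants.
#' @param fs_mean_hypomorph_drug,fs_sd_hypomorph hypomorphs are ~0 in DMSO
#'   and negative (default -2) in the drug arms.
#' @param prop_non_functional,prop_hypomorph class proportions among
#'   experimental (non-control) variants; the remainder are functional.
#' @param replicate_noise_sd SD of per-replicate log2 noise added to the true
#'   fold change.
#' @param position_bias_amplitude amplitude (log2 units) of a smooth
#'   positional editing-rate bias across the library; 0 disables it.
#' @param day3_concentration Dirichlet concentration of per-variant day-3
#'   abundances (smaller = more dispersed).
#' @param indel_sizes,indel_weights,indel_offsets the fixed NHEJ allele set:
#'   signed sizes, their relative day-3 weights and position offsets from the
#'   cut site.
#' @param conditions,n_replicates day-14 arms and replicates per arm.
#' @return list of class `sge_sim_config`.
#' @export
sim_config <- function(depth_per_sample = 2e6,
                       hdr_rate = 0.01,
                       indel_rate = 0.05,
                       error_rate = 0.001,
                       n_frac = 0,
                       read_length = 150L,
                       fs_mean_functional = 0, fs_sd_functional = 0.3,
                       fs_mean_nonfunctional = -3, fs_sd_nonfunctional = 0.5,
                       fs_mean_hypomorph_drug = -2, fs_sd_hypomorph = 0.4,
                       prop_non_functional = 0.45, prop_hypomorph = 0.05,
                       replicate_noise_sd = 0.1,
                       position_bias_amplitude = 0,
                       day3_concentration = 50,
                       indel_sizes = c(-1L, 1L, -2L, 2L, -3L, -4L, 3L, -6L),
                       indel_weights = c(30, 20, 15, 10, 9, 8, 5, 3),
                       indel_offsets = c(0L, 0L, -1L, 1L, 0L, -2L, 2L, 0L),
                       conditions = c("DMSO", "cisplatin", "olaparib"),
                       n_replicates = 2L) {
  cfg <- as.list(environment())
  stopifnot(hdr_rate >= 0, hdr_rate <= 1, indel_rate >= 0,
            hdr_rate + indel_rate < 1, depth_per_sample > 0,
            error_rate >= 0, error_rate <= 1, n_frac >= 0, n_frac <= 1,
            prop_non_functional + prop_hypomorph <= 1,
            fs_sd_functional >= 0, fs_sd_nonfunctional >= 0,
            replicate_noise_sd >= 0, day3_concentration > 0,
            length(indel_sizes) == length(indel_weights),
            length(indel_sizes) == length(indel_offsets))
  structure(cfg, class = "sge_sim_config")
}

#' Assign ground-truth classes and effects to a variant library
#'
#' Synonymous variants are forced functional and nonsense variants forced
#' non-functional (they are the assay's internal controls); other variants are
#' assigned functional / non-functional / hypomorph per the configured
#' proportions. Each variant receives a true per-arm log2 fold change drawn
#' from its class distribution (hypomorphs: ~0 in DMSO, negative in drug
#' arms) and a day-3 abundance (Dirichlet) summing to the HDR fraction.
#'
#' @param library list of [variant_key()] objects.
#' @param config a [sim_config()].
#' @param seed integer seed; all simulator randomness flows from it.
#' @return object of class `sge_truth`.
#' @export
simulate_ground_truth <- function(library, config = sim_config(), seed = 1L) {
  stopifnot(length(library) > 0)
  set.seed(seed)
  tab <- library_table(library)
  n <- nrow(tab)
  class <- character(n)
  class[tab$consequence == "synonymous"] <- "functional"
  class[tab$consequence %in% c("nonsense", "splice_region")] <- "non_functional"
  open <- which(class == "")
  if (length(open)) {
    p <- c(non_functional = config$prop_non_functional,
           hypomorph = config$prop_hypomorph)
    u <- runif(length(open))
    class[open] <- ifelse(u < p[1], "non_functional",
                          ifelse(u < p[1] + p[2], "hypomorph", "functional"))
  }
  conds <- config$conditions
  lfc <- matrix(0, n, length(conds), dimnames = list(NULL, conds))
  for (k in seq_len(n)) {
    lfc[k, ] <- switch(class[k],
      functional = rnorm(length(conds), config$fs_mean_functional,
                         config$fs_sd_functional),
      non_functional = rnorm(length(conds), config$fs_mean_nonfunctional,
                             config$fs_sd_nonfunctional),
      hypomorph = c(rnorm(1, 0, config$fs_sd_hypomorph),
                    rnorm(length(conds) - 1, config$fs_mean_hypomorph_drug,
                          config$fs_sd_hypomorph)))
  }
  ab <- rgamma(n, shape = config$day3_concentration)
  ab <- ab / sum(ab) * config$hdr_rate
  ni <- length(config$indel_sizes)
  iab <- config$indel_weights / sum(config$indel_weights) * config$indel_rate
  indels <- data.frame(size = config$indel_sizes,
                       offset = config$indel_offsets,
                       day3_abund = iab,
                       lethal = config$indel_sizes %% 3L != 0L)
  ilfc <- matrix(0, ni, length(conds), dimnames = list(NULL, conds))
  ilfc[indels$lethal, ] <- config$fs_mean_nonfunctional
  structure(list(
    variants = data.frame(tab, class = class, day3_abund = ab,
                          position = vapply(library, function(k) k$edits$pos[1],
                                            integer(1)),
                          stringsAsFactors = FALSE),
    lfc = lfc, indels = indels, indel_lfc = ilfc,
    wt_abund = 1 - config$hdr_rate - config$indel_rate,
    library = library, config = config, seed = seed),
    class = "sge_truth")
}

#' @export
print.sge_truth <- function(x, ...) {
  cat("SGE ground truth: ", nrow(x$variants), " variants (",
      paste(names(table(x$variants$class)), table(x$variants$class),
            sep = "=", collapse = ", "),
      "), ", nrow(x$indels), " indel alleles, WT fraction ",
      signif(x$wt_abund, 3), "\n", sep = "")
  invisible(x)
}

allele_keys <- function(truth) {
  c(truth$variants$hgvs_c, "WT",
    paste0("indel:", truth$indels$size, ":", truth$indels$offset))
}

position_bias_term <- function(truth, amplitude) {
  if (amplitude == 0) return(rep(0, nrow(truth$variants)))
  pos <- truth$variants$position
  rng <- range(pos)
  if (diff(rng) == 0) return(rep(0, length(pos)))
  amplitude * sin(2 * pi * (pos - rng[1]) / diff(rng))
}

#' Draw multinomial count tables from a ground truth
#'
#' Day-3 counts are multinomial over WT, HDR-variant and indel alleles at the
#' configured rates; per (condition, replicate), day-14 expected frequencies
#' are the day-3 frequencies times `2^(true log2FC + replicate noise +
#' position bias)`, renormalized and multinomially sampled. Per-sample totals
#' are exact (fixed sequencing depth).
#'
#' @param truth an [simulate_ground_truth()] result.
#' @param config a [sim_config()]; defaults to the one inside `truth`.
#' @param seed integer seed.
#' @return an `sge_counts` object (see [count_table()]).
#' @export
simulate_counts <- function(truth, config = truth$config, seed = truth$seed + 1L) {
  set.seed(seed)
  nv <- nrow(truth$variants); ni <- nrow(truth$indels)
  keys <- allele_keys(truth)
  p3 <- c(truth$variants$day3_abund, truth$wt_abund, truth$indels$day3_abund)
  depth <- config$depth_per_sample
  conds <- config$conditions; nr <- config$n_replicates
  bias <- position_bias_term(truth, config$position_bias_amplitude)
  samples <- data.frame(sample = paste0("d3_r", seq_len(nr)),
                        day = 3L, condition = "pre", replicate = seq_len(nr))
  cnt <- sapply(seq_len(nr), function(r) rmultinom(1, depth, p3)[, 1])
  for (cond in conds) for (r in seq_len(nr)) {
    lfc <- c(truth$lfc[, cond] + bias +
               rnorm(nv, 0, config$replicate_noise_sd),
             0,
             truth$indel_lfc[, cond])
    p14 <- p3 * 2^lfc
    p14 <- p14 / sum(p14)
    cnt <- cbind(cnt, rmultinom(1, depth, p14)[, 1])
    samples <- rbind(samples, data.frame(
      sample = paste0("d14_", cond, "_r", r), day = 14L,
      condition = cond, replicate = r))
  }
  rows <- data.frame(
    key = keys,
    type = c(rep("variant", nv), "WT", rep("indel", ni)),
    hgvs_c = c(truth$variants$hgvs_c, NA, rep(NA, ni)),
    consequence = c(truth$variants$consequence, NA, rep(NA, ni)),
    position = c(truth$variants$position, NA_integer_,
                 truth$indels$offset),
    stringsAsFactors = FALSE)
  count_table(cnt, rows, samples, totals = rep(depth, ncol(cnt)))
}

revcomp <- function(x) {
  chartr("ACGTN", "TGCAN", vapply(x, function(s)
    paste(rev(strsplit(s, "")[[1]]), collapse = ""), character(1),
    USE.NAMES = FALSE))
}

allele_sequence <- function(truth, design, i) {
  ref <- design$reference_seq
  nv <- nrow(truth$variants)
  if (i <= nv) {               # HDR variant: marker edits plus variant edits
    ed <- rbind(design$marker_edits[, c("pos", "alt")],
                truth$library[[i]]$edits[, c("pos", "alt")])
    s <- strsplit(ref, "")[[1]]
    s[ed$pos + 1] <- ed$alt
    paste(s, collapse = "")
  } else if (i == nv + 1) {    # WT
    ref
  } else {                     # NHEJ indel around the cut site
    idl <- truth$indels[i - nv - 1, ]
    at <- design$cut_sites[1] + idl$offset
    if (idl$size < 0) {
      paste0(substr(ref, 1, at), substr(ref, at + 1 - idl$size, nchar(ref)))
    } else {
      ins <- paste(rep("A", idl$size), collapse = "")
      paste0(substr(ref, 1, at), ins, substr(ref, at + 1, nchar(ref)))
    }
  }
}

write_fastq <- function(names, seqs, quals, path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  writeLines(paste0("@", names, "\n", seqs, "\n+\n", quals), con)
}

#' Emit paired FASTQ reads for one simulated sample
#'
#' Reads are drawn from the day-3 allele frequencies of the ground truth
#' (WT, HDR variants carrying the marker, and indel alleles), as overlapping
#' read pairs from the two amplicon ends, with optional flat per-base
#' substitution error and optional 'N' injection. The true allele is recorded
#' in each read name after the last `|`, which lets tests assert exact
#' round-trips.
#'
#' @param truth an [simulate_ground_truth()] result.
#' @param design the [amplicon_design()].
#' @param config a [sim_config()]; `read_length`, `error_rate` and `n_frac`
#'   are honoured. `depth_per_sample` is overridden by `n_reads`.
#' @param r1_path,r2_path output FASTQ paths (gzip if ending in .gz).
#' @param n_reads number of read pairs.
#' @param seed integer seed.
#' @return invisibly, a table of true allele counts.
#' @export
simulate_reads <- function(truth, design, config = truth$config,
                           r1_path, r2_path,
                           n_reads = 2000L, seed = truth$seed + 2L) {
  set.seed(seed)
  keys <- allele_keys(truth)
  p3 <- c(truth$variants$day3_abund, truth$wt_abund, truth$indels$day3_abund)
  draws <- rmultinom(1, n_reads, p3)[, 1]
  alleles <- rep(seq_along(keys), draws)
  alleles <- sample(alleles)               # shuffle read order
  L <- config$read_length
  seqs <- vapply(seq_along(keys), allele_sequence, character(1),
                 truth = truth, design = design)
  full <- seqs[alleles]
  add_errors <- function(s) {
    if (config$error_rate == 0) return(s)
    vapply(s, function(x) {
      b <- strsplit(x, "")[[1]]
      hit <- which(runif(length(b)) < config$error_rate)
      if (length(hit))
        b[hit] <- vapply(hit, function(h)
          sample(setdiff(c("A", "C", "G", "T"), b[h]), 1), character(1))
      paste(b, collapse = "")
    }, character(1), USE.NAMES = FALSE)
  }
  r1 <- add_errors(substr(full, 1, L))
  r2 <- add_errors(revcomp(substring(full, pmax(1, nchar(full) - L + 1))))
  if (config$n_frac > 0) {
    hit <- which(runif(length(r1)) < config$n_frac)
    for (h in hit) {
      at <- sample(nchar(r1[h]), 1)
      substr(r1[h], at, at) <- "N"
    }
  }
  nm <- paste0("sim_", seq_along(alleles), "|", keys[alleles])
  q1 <- strrep("I", nchar(r1)); q2 <- strrep("I", nchar(r2))
  write_fastq(nm, r1, q1, r1_path)
  write_fastq(nm, r2, q2, r2_path)
  invisible(data.frame(key = keys, true_count = draws))
}
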