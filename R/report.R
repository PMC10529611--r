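#' Join external annotations onto a result table
#'
#' Left join on the canonical `hgvs_c` key, preserving every result row;
#' unmatched rows keep NA annotations and are reported, never dropped.
#' A `splice_flag` is set where the SpliceAI maximum delta score exceeds 0.2
#' (strictly greater, as stated).
#'
#' @param results data.frame with an `hgvs_c` column.
#' @param annotations data.frame with `hgvs_c` plus any of `clinvar`, `cadd`,
#'   `bayesdel`, `prior_class`, `spliceai`.
#' @param spliceai_cutoff splice-flag cutoff (default 0.2, strict `>`).
#' @return `results` with annotation columns and `splice_flag` appended; the
#'   number of unmatched rows is attached as attribute `n_unmatched`.
#' @export
join_annotations <- function(results, annotations,
                             spliceai_cutoff = 0.2) {
  stopifnot("hgvs_c" %in% names(results))
  if (nrow(annotations) == 0 || !"hgvs_c" %in% names(annotations)) {
    results$splice_flag <- FALSE
    attr(results, "n_unmatched") <- nrow(results)
    return(results)
  }
  dup <- annotations$hgvs_c[duplicated(annotations$hgvs_c)]
  if (length(dup))
    stop("duplicate annotation keys: ", paste(unique(dup), collapse = ", "))
  out <- merge(results, annotations, by = "hgvs_c", all.x = TRUE,
               sort = FALSE)
  out <- out[match(results$hgvs_c, out$hgvs_c), ]
  rownames(out) <- NULL
  out$splice_flag <- !is.na(out$spliceai) & out$spliceai > spliceai_cutoff
  attr(out, "n_unmatched") <- sum(!results$hgvs_c %in% annotations$hgvs_c)
  out
}

#' Pairwise correlation report
#'
#' Rank (Spearman, default) or linear (Pearson) correlations between the
#' named numeric columns, pairwise-complete, with the paired n reported;
#' constant columns yield NA flagged as undefined.
#'
#' @param data data.frame.
#' @param columns character vector of numeric column names (default: all
#'   numeric columns).
#' @param method `"spearman"` or `"pearson"`.
#' @return data.frame with `var1`, `var2`, `rho`, `n`, `undefined`.
#' @export
correlation_report <- function(data, columns = NULL,
                               method = c("spearman", "pearson")) {
  method <- match.arg(method)
  if (is.null(columns))
    columns <- names(data)[vapply(data, is.numeric, logical(1))]
  stopifnot(length(columns) >= 2)
  out <- NULL
  for (i in seq_len(length(columns) - 1)) for (j in (i + 1):length(columns)) {
    x <- data[[columns[i]]]; y <- data[[columns[j]]]
    ok <- complete.cases(x, y)
    n <- sum(ok)
    if (n < 3) stop("fewer than 3 paired observations for ",
                    columns[i], " vs ", columns[j])
    undef <- sd(x[ok]) == 0 || sd(y[ok]) == 0
    rho <- if (undef) NA_real_ else cor(x[ok], y[ok], method = method)
    out <- rbind(out, data.frame(var1 = columns[i], var2 = columns[j],
                                 rho = rho, n = n, undefined = undef))
  }
  out
}

#' Sequence-function map
#'
#' Per-position grid of the SNV library: the reference base, each of the 3
#' non-wildtype alternatives, the assigned category and flags, with excluded
#' (filtered) variants carried as their own category so that every library
#' variant appears exactly once and category counts reconcile with the
#' classifier output.
#'
#' @param results data.frame with `hgvs_c` and `category` columns (category
#'   `excluded` for filtered variants); optional logical flag columns
#'   `clinvar_flag`, `splice_flag`.
#' @param design the [amplicon_design()].
#' @return list of class `sge_map`: `grid` data.frame and `counts` by
#'   category.
#' @export
sequence_function_map <- function(results, design) {
  stopifnot(all(c("hgvs_c", "category") %in% names(results)))
  if (anyDuplicated(results$hgvs_c))
    stop("duplicate variant keys in results")
  grid <- NULL
  for (i in seq_len(nrow(results))) {
    ed <- parse_hgvs_edits(design, results$hgvs_c[i])
    grid <- rbind(grid, data.frame(
      position = ed$pos[1],
      cdna = cdna_label(design, ed$pos[1]),
      ref = ed$ref[1], alt = ed$alt[1],
      hgvs_c = results$hgvs_c[i],
      category = results$category[i],
      clinvar_flag = if ("clinvar_flag" %in% names(results))
        isTRUE(results$clinvar_flag[i]) else FALSE,
      splice_flag = if ("splice_flag" %in% names(results))
        isTRUE(results$splice_flag[i]) else FALSE))
  }
  grid <- grid[order(grid$position, grid$alt), ]
  rownames(grid) <- NULL
  structure(list(grid = grid,
                 counts = table(grid$category)),
            class = "sge_map")
}

#' @export
print.sge_map <- function(x, ...) {
  cat("Sequence-function map: ", nrow(x$grid), " variants across ",
      length(unique(x$grid$position)), " positions\n", sep = "")
  print(x$counts)
  invisible(x)
}

default_snv_region <- function(design) {
  # saturate the exon plus two intronic flanking bases on each side,
  # skipping the marker codon (handled inside enumerate_snv_library)
  iv <- design$exon_intervals
  c(max(0L, iv[1, 1] - 2L),
    min(nchar(design$reference_seq) - 1L, iv[nrow(iv), 2] + 1L))
}

#' Run the full SGE analysis on a simulated experiment
#'
#' Generates a ground-truthed experiment, produces count tables, function
#' scores and filters, and applies the requested classifier: `"pif"` runs the
#' degenerate-codon path (three-assay probit on synonymous/nonsense
#' controls), `"gmm"` runs the SNV-saturation path (weighted global ratio,
#' loess positional-bias correction, control anchoring, Gaussian mixture).
#'
#' @param design an [amplicon_design()] (default [demo_design()]).
#' @param config a [sim_config()].
#' @param seed integer master seed.
#' @param mode `"pif"` or `"gmm"`.
#' @param library variant library; defaults to the design's codon library
#'   (pif) or SNV library across the exon and 2-bp intron flanks (gmm).
#' @param n_sims_ci perturbation simulations for PIF confidence intervals
#'   (0 skips them).
#' @return list with the truth, counts, function scores, filter report,
#'   fitted model, per-variant results and evaluation metrics.
#' @export
run_sge_pipeline <- function(design = demo_design(), config = sim_config(),
                             seed = 1L, mode = c("pif", "gmm"),
                             library = NULL, n_sims_ci = 0L) {
  mode <- match.arg(mode)
  if (is.null(library)) {
    library <- if (mode == "pif") {
      codons <- unique(ceiling((map_position(design, design$target_region[1])$cdna:
        map_position(design, design$target_region[2] - 1L)$cdna) / 3))
      do.call(c, lapply(codons, enumerate_codon_library, design = design))
    } else {
      r <- default_snv_region(design)
      enumerate_snv_library(design, r[1], r[2])
    }
  }
  truth <- simulate_ground_truth(library, config, seed = seed)
  ct <- simulate_counts(truth, config, seed = seed + 1L)
  fq <- normalize_frequencies(ct)
  fs <- compute_fs(fq)
  truth_class <- truth$variants$class[match(fs$key, truth$variants$hgvs_c)]
  if (mode == "pif") {
    flt <- apply_codon_filters(fq)
    kept <- fs[flt$keep[fs$key], ]
    ctrl <- kept$consequence %in% c("synonymous", "nonsense")
    xcols <- paste0("fs_", config$conditions)
    xtr <- as.matrix(kept[ctrl, xcols])
    ytr <- ifelse(kept$consequence[ctrl] == "nonsense",
                  "non_functional", "functional")
    model <- pif_probit(xtr, ytr)
    pif <- compute_pif(model, as.matrix(kept[, xcols]))
    results <- data.frame(kept[, c("key", "hgvs_c", "consequence")],
                          pif = pif, category = categorize_pif(pif))
    if (n_sims_ci > 0) {
      ci <- pif_confidence_intervals(model, as.matrix(kept[, xcols]),
                                     n_sims = n_sims_ci, seed = seed + 2L)
      results$ci_low <- ci$ci_low; results$ci_high <- ci$ci_high
    }
    tc <- truth_class[flt$keep[fs$key]]
    eval_idx <- tc != "hypomorph"
    metrics <- recovery_metrics(results$category[eval_idx],
                                tc[eval_idx],
                                pathogenic_label = "non_functional")
  } else {
    flt <- apply_exon13_filters(fq, fs)
    kept <- fs[flt$keep[fs$key], ]
    gr <- compute_global_ratio(kept)
    raw <- log2(gr)
    pos <- kept$position
    bias_model <- fit_position_bias(pos, raw)
    corrected <- correct_scores(raw, bias_model, pos)
    normed <- normalize_across_exons(corrected, rep("exon", length(corrected)),
                                     kept$consequence)
    score <- normed$scores
    ctrl <- kept$consequence %in% c("synonymous", "nonsense")
    model <- gmm_classify(score[ctrl],
                          ifelse(kept$consequence[ctrl] == "nonsense",
                                 "non_functional", "functional"))
    post <- posterior_pathogenic(model, score)
    results <- data.frame(kept[, c("key", "hgvs_c", "consequence")],
                          score = score, posterior = post,
                          category = categorize_gmm(post))
    tc <- truth_class[flt$keep[fs$key]]
    eval_idx <- tc != "hypomorph"
    metrics <- recovery_metrics(results$category[eval_idx], tc[eval_idx],
                                pathogenic_label = "pathogenic")
    results$bias_model <- NULL
    metrics$control_metrics <- classifier_metrics(post[ctrl],
      ifelse(kept$consequence[ctrl] == "nonsense", "non_functional",
             "functional"))
  }
  list(truth = truth, counts = ct, fs = fs, filter = flt, model = model,
       results = results, metrics = metrics, seed = seed, mode = mode)
}

recovery_metrics <- function(category, truth_class, pathogenic_label) {
  y <- truth_class == "non_functional"
  pred_path <- category %in% c("non_functional", "pathogenic")
  pred_fun <- category %in% c("functional", "benign")
  list(sensitivity = 100 * sum(pred_path & y) / sum(y),
       specificity = 100 * sum(pred_fun & !y) / sum(!y),
       accuracy = 100 * mean((pred_path & y) | (pred_fun & !y)),
       n = length(category))
}

cli_log <- function(...) {
  message("[sgescore ", as.character(utils::packageVersion("sgescore")),
          " ", format(Sys.time(), "%H:%M:%S"), "] ", ...)
}

parse_flags <- function(args) {
  out <- list()
  i <- 1
  while (i <= length(args)) {
    a <- args[i]
    if (!startsWith(a, "--")) stop("unexpected argument: ", a)
    key <- sub("^--", "", a)
    if (i == length(args) || startsWith(args[i + 1], "--")) {
      out[[key]] <- TRUE; i <- i + 1
    } else {
      out[[key]] <- args[i + 1]; i <- i + 2
    }
  }
  out
}

#' Command-line entry point
#'
#' A thin shell over the package functions; subcommands: `simulate` (design
#' YAML -> count/truth TSV), `call` (FASTQ pair -> single-sample counts),
#' `score` (counts TSV -> function-score TSV), `classify-pif`,
#' `classify-gmm`, `report` (annotate + sequence-function map) and
#' `run-all` (simulate + score + classify on one seed). Every run logs the
#' package version and seed; outputs are deterministic under a fixed seed.
#' An `Rscript` wrapper lives in `inst/cli/sge.R`.
#'
#' @param args character vector (default: the command line).
#' @return exit status, invisibly (0 on success).
#' @export
sge_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (length(args) == 0) {
    message("usage: sge <simulate|call|score|classify-pif|classify-gmm|",
            "report|run-all> [--flags]")
    return(invisible(1L))
  }
  cmd <- args[1]
  fl <- parse_flags(args[-1])
  need <- function(k) {
    if (is.null(fl[[k]])) stop("missing required flag --", k)
    fl[[k]]
  }
  seed <- as.integer(fl[["seed"]] %||% 1L)
  status <- tryCatch({
    switch(cmd,
      "simulate" = {
        design <- read_amplicon_design(need("design"))
        cli_log("simulate: seed ", seed)
        res <- run_sge_pipeline(design, seed = seed,
                                mode = fl[["mode"]] %||% "pif")
        write_count_table(res$counts, need("out"))
        if (!is.null(fl[["truth"]]))
          write.table(res$truth$variants, fl[["truth"]], sep = "\t",
                      quote = FALSE, row.names = FALSE)
        0L
      },
      "call" = {
        design <- read_amplicon_design(need("design"))
        m <- merge_pairs(need("r1"), need("r2"))
        cli_log("call: ", length(m$merged), " merged, ", m$n_dropped,
                " dropped")
        cs <- call_sample(m$merged, design)
        write.table(data.frame(key = names(cs$counts), count = cs$counts,
                               total = cs$total),
                    need("out"), sep = "\t", quote = FALSE,
                    row.names = FALSE)
        0L
      },
      "score" = {
        ct <- read_count_table(need("counts"))
        fs <- compute_fs(normalize_frequencies(ct))
        fs$global_ratio <- tryCatch(compute_global_ratio(fs),
                                    error = function(e) NA_real_)
        write.table(fs, need("out"), sep = "\t", quote = FALSE,
                    row.names = FALSE)
        0L
      },
      "classify-pif" = {
        fs <- read.delim(need("scores"))
        ctrl <- fs$consequence %in% c("synonymous", "nonsense")
        xc <- grep("^fs_[^_]+$", names(fs), value = TRUE)
        fit <- pif_probit(as.matrix(fs[ctrl, xc]),
                          ifelse(fs$consequence[ctrl] == "nonsense",
                                 "non_functional", "functional"))
        pif <- compute_pif(fit, as.matrix(fs[, xc]))
        out <- data.frame(hgvs_c = fs$hgvs_c, pif = pif,
                          category = categorize_pif(pif))
        write.table(out, need("out"), sep = "\t", quote = FALSE,
                    row.names = FALSE)
        0L
      },
      "classify-gmm" = {
        fs <- read.delim(need("scores"))
        score <- log2(fs$global_ratio)
        ctrl <- fs$consequence %in% c("synonymous", "nonsense")
        fit <- gmm_classify(score[ctrl],
                            ifelse(fs$consequence[ctrl] == "nonsense",
                                   "non_functional", "functional"))
        post <- posterior_pathogenic(fit, score)
        out <- data.frame(hgvs_c = fs$hgvs_c, score = score,
                          posterior = post,
                          category = categorize_gmm(post))
        write.table(out, need("out"), sep = "\t", quote = FALSE,
                    row.names = FALSE)
        0L
      },
      "report" = {
        res <- read.delim(need("results"))
        if (!is.null(fl[["annotations"]]))
          res <- join_annotations(res, read.delim(fl[["annotations"]]))
        write.table(res, need("out"), sep = "\t", quote = FALSE,
                    row.names = FALSE)
        0L
      },
      "run-all" = {
        design <- if (is.null(fl[["design"]])) demo_design()
                  else read_amplicon_design(fl[["design"]])
        outdir <- need("outdir")
        dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
        cli_log("run-all: seed ", seed)
        res <- run_sge_pipeline(design, seed = seed,
                                mode = fl[["mode"]] %||% "pif")
        write_count_table(res$counts, file.path(outdir, "counts.tsv"))
        write.table(res$fs, file.path(outdir, "function_scores.tsv"),
                    sep = "\t", quote = FALSE, row.names = FALSE)
        write.table(res$results, file.path(outdir, "classified.tsv"),
                    sep = "\t", quote = FALSE, row.names = FALSE)
        cli_log("recovery: sensitivity ",
                round(res$metrics$sensitivity, 1), "%, specificity ",
                round(res$metrics$specificity, 1), "%")
        0L
      },
      { message("unknown subcommand: ", cmd); 1L })
  }, error = function(e) { message("error: ", conditionMessage(e)); 1L })
  invisible(status)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
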