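#' Model positional editing-rate bias with a loess smoother
#'
#' Editing (and hence day-14/day-3 ratio) varies smoothly with distance from
#' the cut site. The bias is modelled by locally weighted linear regression
#' (tricube weights, degree 1) of the log2 post/pre ratio on position, fitted
#' only on the near-neutral variants so that real biological effects do not
#' leak into the correction: by default the variants within `threshold`-fold
#' of no change, i.e. `|log2 ratio| <= log2(threshold)`. A one-sided
#' alternative (`ratio >= threshold`) is available behind `side`.
#'
#' @param position per-variant position (amplicon or chromosomal; any
#'   monotone coordinate).
#' @param log2_ratio per-variant log2 post/pre ratio.
#' @param span loess span (default 0.75).
#' @param threshold inclusion bound on the ratio scale (default 1.25).
#' @param side `"within"` (default; within `threshold`-fold of 1) or
#'   `"at_least"` (ratio >= threshold).
#' @param min_points minimum number of included variants (default 10).
#' @return object of class `sge_loess` with a `predict()` method; predictions
#'   outside the fitted range take the nearest fitted value.
#' @export
fit_position_bias <- function(position, log2_ratio, span = 0.75,
                              threshold = 1.25,
                              side = c("within", "at_least"),
                              min_points = 10L) {
  side <- match.arg(side)
  stopifnot(length(position) == length(log2_ratio))
  ok <- is.finite(position) & is.finite(log2_ratio)
  inc <- ok & if (side == "within") abs(log2_ratio) <= log2(threshold)
              else 2^log2_ratio >= threshold
  if (sum(inc) < min_points)
    stop("only ", sum(inc), " variants pass the |log2 ratio| <= log2(",
         threshold, ") inclusion rule; need at least ", min_points)
  fit <- loess(y ~ x, data = data.frame(x = position[inc],
                                        y = log2_ratio[inc]),
               span = span, degree = 1,
               family = "gaussian",
               control = loess.control(surface = "direct"))
  structure(list(fit = fit, span = span, threshold = threshold, side = side,
                 range = range(position[inc]), n_used = sum(inc)),
            class = "sge_loess")
}

#' @export
predict.sge_loess <- function(object, newdata, ...) {
  x <- pmin(pmax(newdata, object$range[1]), object$range[2])
  as.numeric(predict(object$fit, data.frame(x = x)))
}

#' @export
print.sge_loess <- function(x, ...) {
  cat("Positional bias model: loess (degree 1, span ", x$span, "), fit on ",
      x$n_used, " near-neutral variants over positions [", x$range[1], ", ",
      x$range[2], "]\n", sep = "")
  invisible(x)
}

#' Export a fitted bias curve as a (position, fitted value) TSV
#' @param model an [fit_position_bias()] model.
#' @param positions positions to evaluate.
#' @param path output TSV path.
#' @export
export_bias_curve <- function(model, positions, path) {
  write.table(data.frame(position = positions,
                         fitted = predict(model, positions)),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Subtract the fitted positional bias from raw scores
#'
#' @param log2_ratio raw per-variant log2 post/pre ratios.
#' @param model an [fit_position_bias()] model.
#' @param position per-variant positions.
#' @return corrected log2 ratios (`raw - fitted(position)`).
#' @export
correct_scores <- function(log2_ratio, model, position) {
  log2_ratio - predict(model, position)
}

#' Two-point affine anchoring of an exon's scores onto global control medians
#'
#' The affine map sends the exon's median synonymous score to the global
#' median synonymous score and the exon's median nonsense score to the global
#' median nonsense score, and is applied to every variant of the exon.
#' Monotone by construction, so within-exon rankings are preserved.
#'
#' @param scores the exon's corrected scores.
#' @param exon_anchors,global_anchors numeric `c(syn, nonsense)` medians.
#' @return rescaled scores.
#' @export
scale_within_exon <- function(scores, exon_anchors, global_anchors) {
  es <- exon_anchors[1]; en <- exon_anchors[2]
  gs <- global_anchors[1]; gn <- global_anchors[2]
  if (!is.finite(es) || !is.finite(en) || es <= en)
    stop("degenerate anchors: synonymous median (", es,
         ") must exceed nonsense median (", en, ")")
  gn + (scores - en) * (gs - gn) / (es - en)
}

#' Normalize scores across exons onto common control anchors
#'
#' Applies [scale_within_exon()] per exon with the global anchors defined as
#' the medians of the synonymous and nonsense controls pooled over all exons,
#' so that after normalization every exon's synonymous median equals the
#' global synonymous median and likewise for nonsense. With a single exon the
#' map is the identity.
#'
#' @param scores per-variant corrected scores.
#' @param exon per-variant exon labels.
#' @param consequence per-variant consequence (controls are `synonymous` and
#'   `nonsense`).
#' @return list with `scores` (normalized), `anchors` (per-exon and global
#'   medians).
#' @export
normalize_across_exons <- function(scores, exon, consequence) {
  stopifnot(length(scores) == length(exon),
            length(scores) == length(consequence))
  gsyn <- median(scores[consequence == "synonymous"])
  gnon <- median(scores[consequence == "nonsense"])
  out <- scores
  anchors <- list(global = c(synonymous = gsyn, nonsense = gnon))
  for (e in unique(exon)) {
    i <- exon == e
    es <- median(scores[i & consequence == "synonymous"])
    en <- median(scores[i & consequence == "nonsense"])
    if (sum(i & consequence == "synonymous") < 3 ||
        sum(i & consequence == "nonsense") < 1)
      stop("exon ", e, " lacks control variants for anchoring")
    out[i] <- scale_within_exon(scores[i], c(es, en), c(gsyn, gnon))
    anchors[[as.character(e)]] <- c(synonymous = es, nonsense = en)
  }
  list(scores = out, anchors = anchors)
}
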