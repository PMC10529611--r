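#' Supervised Gaussian-mixture classifier on a single function score
#'
#' Fits class-conditional Gaussians (model-based discriminant analysis) to
#' the normalized function scores of labelled control variants: the
#' functional class (synonymous plus ClinVar benign/likely-benign) and the
#' non-functional class (nonsense plus ClinVar pathogenic/likely-pathogenic).
#' Each class gets its own mean and SD by default (`pooled_var = TRUE` shares
#' one SD); priors are the training proportions unless `equal_priors`.
#' The posterior probability of pathogenicity of a score s is
#' `p = pi_nf phi_nf(s) / (pi_nf phi_nf(s) + pi_f phi_f(s))`.
#'
#' @param score numeric function scores of the training controls.
#' @param labels `functional` / `non_functional` (or 0/1).
#' @param equal_priors use priors (0.5, 0.5) regardless of class sizes.
#' @param pooled_var share a pooled SD between the classes.
#' @return object of class `sge_gmm` with `print`, `summary`, `coef`,
#'   `predict` and `plot` methods.
#' @export
gmm_classify <- function(score, labels, equal_priors = FALSE,
                         pooled_var = FALSE) {
  y <- encode_labels(labels)
  score <- as.numeric(score)
  stopifnot(length(score) == length(y))
  if (length(unique(y)) < 2 || min(table(y)) < 2)
    stop("both classes need at least 2 training members")
  mu <- c(functional = mean(score[y == 0]),
          non_functional = mean(score[y == 1]))
  if (pooled_var) {
    s2 <- sum((score - mu[y + 1])^2) / (length(score) - 2)
    sdv <- c(functional = sqrt(s2), non_functional = sqrt(s2))
  } else {
    sdv <- c(functional = sd(score[y == 0]),
             non_functional = sd(score[y == 1]))
  }
  if (any(sdv == 0))
    stop("a class has zero variance; consider pooled_var = TRUE")
  priors <- if (equal_priors) c(functional = 0.5, non_functional = 0.5)
            else c(functional = mean(y == 0), non_functional = mean(y == 1))
  structure(list(mean = mu, sd = sdv, priors = priors,
                 n = c(functional = sum(y == 0),
                       non_functional = sum(y == 1)),
                 score = score, y = y),
            class = "sge_gmm")
}

#' Posterior probability of pathogenicity under a fitted mixture
#'
#' @param model a fitted [gmm_classify()] model.
#' @param score numeric scores.
#' @return posterior probabilities in `[0, 1]`.
#' @export
posterior_pathogenic <- function(model, score) {
  lnf <- log(model$priors["non_functional"]) +
    dnorm(score, model$mean["non_functional"], model$sd["non_functional"],
          log = TRUE)
  lf <- log(model$priors["functional"]) +
    dnorm(score, model$mean["functional"], model$sd["functional"],
          log = TRUE)
  unname(1 / (1 + exp(lf - lnf)))
}

#' @export
predict.sge_gmm <- function(object, newdata = object$score,
                            type = c("posterior", "category"), ...) {
  type <- match.arg(type)
  p <- posterior_pathogenic(object, newdata)
  if (type == "posterior") p else categorize_gmm(p)
}

#' @export
coef.sge_gmm <- function(object, ...) {
  rbind(mean = object$mean, sd = object$sd, prior = object$priors)
}

#' @export
print.sge_gmm <- function(x, ...) {
  cat("Gaussian mixture classifier (", x$n["functional"], " functional / ",
      x$n["non_functional"], " non-functional controls)\n", sep = "")
  print(signif(coef(x), 4))
  invisible(x)
}

#' @export
summary.sge_gmm <- function(object, ...) {
  print(object)
  post <- posterior_pathogenic(object, object$score)
  acc <- mean((post > 0.5) == (object$y == 1))
  cat("training accuracy at 0.5:", round(100 * acc, 1), "%\n")
  invisible(list(accuracy = 100 * acc))
}

#' @export
plot.sge_gmm <- function(x, newdata = x$score, ...) {
  s <- seq(min(newdata) - 1, max(newdata) + 1, length.out = 200)
  graphics::hist(newdata, breaks = 30, freq = FALSE, main = "",
                 xlab = "function score", ...)
  graphics::lines(s, x$priors[1] * dnorm(s, x$mean[1], x$sd[1]), col = 4)
  graphics::lines(s, x$priors[2] * dnorm(s, x$mean[2], x$sd[2]), col = 2)
  invisible(x)
}

#' Three-way posterior categorization
#'
#' Posterior `> 0.99` is pathogenic, `< 0.05` benign, anything in between
#' (both boundaries included) intermediate.
#'
#' @param posterior numeric vector in `[0, 1]`.
#' @return character vector.
#' @export
categorize_gmm <- function(posterior) {
  if (any(!is.finite(posterior)) || any(posterior < 0 | posterior > 1))
    stop("posterior values must lie in [0, 1]")
  ifelse(posterior > 0.99, "pathogenic",
         ifelse(posterior < 0.05, "benign", "intermediate"))
}

#' Sensitivity and specificity of a categorical prediction
#'
#' Sensitivity is the percentage of non-functional (pathogenic) labels
#' predicted pathogenic; specificity the percentage of functional (benign)
#' labels predicted benign. Intermediates count against their true class by
#' default (conservative); `intermediates = "exclude"` drops them first.
#'
#' @param predicted categories (`pathogenic` / `benign` / `intermediate`).
#' @param labels true binary labels (`functional` / `non_functional` or 0/1).
#' @param intermediates `"against"` (default) or `"exclude"`.
#' @return list with `sensitivity`, `specificity` (percent) and `confusion`
#'   counts (TP, FN, TN, FP).
#' @export
compute_sensitivity_specificity <- function(predicted, labels,
                                            intermediates = c("against",
                                                              "exclude")) {
  intermediates <- match.arg(intermediates)
  y <- encode_labels(labels)
  if (intermediates == "exclude") {
    keep <- predicted != "intermediate"
    predicted <- predicted[keep]; y <- y[keep]
  }
  if (!any(y == 1) || !any(y == 0))
    stop("both classes must be present to compute sensitivity/specificity")
  tp <- sum(y == 1 & predicted == "pathogenic")
  fn <- sum(y == 1 & predicted != "pathogenic")
  tn <- sum(y == 0 & predicted == "benign")
  fp <- sum(y == 0 & predicted != "benign")
  list(sensitivity = 100 * tp / (tp + fn),
       specificity = 100 * tn / (tn + fp),
       confusion = c(TP = tp, FN = fn, TN = tn, FP = fp))
}

#' Positive and negative likelihood ratios
#'
#' `LR+ = sensitivity / (100 - specificity)` and
#' `LR- = (100 - sensitivity) / specificity`, both on the percent scale as
#' printed; a zero denominator yields `Inf` (flagged by the caller's
#' context, not an error).
#'
#' @param sensitivity,specificity percentages in `[0, 100]`.
#' @return list with `lr_plus` and `lr_minus`.
#' @export
compute_likelihood_ratios <- function(sensitivity, specificity) {
  stopifnot(sensitivity >= 0, sensitivity <= 100,
            specificity >= 0, specificity <= 100)
  list(lr_plus = if (specificity == 100) Inf
       else sensitivity / (100 - specificity),
       lr_minus = if (specificity == 0) Inf
       else (100 - sensitivity) / specificity)
}

# OddsPath -> ACMG evidence strength (Bayesian adaptation of the
# PS3/BS3 recommendations)
oddspath_strength <- function(op, side = c("pathogenic", "benign")) {
  side <- match.arg(side)
  if (side == "pathogenic") {
    if (op > 350) "PS3_very_strong"
    else if (op > 18.7) "PS3_strong"
    else if (op > 4.3) "PS3_moderate"
    else if (op > 2.1) "PS3_supporting"
    else "indeterminate"
  } else {
    if (op < 0.0029) "BS3_very_strong"
    else if (op < 0.053) "BS3_strong"
    else if (op < 0.23) "BS3_moderate"
    else if (op < 0.48) "BS3_supporting"
    else "indeterminate"
  }
}

#' Odds of pathogenicity (OddsPath) for PS3/BS3 evidence calibration
#'
#' From the composition of the control set and the classifier's prediction
#' counts: `P1` is the proportion of pathogenic controls;
#' `P2_pathogenic = n_pred_pathogenic / (n_pred_pathogenic + 1)`;
#' `P2_benign = 1 / (n_pred_benign + 1)`;
#' `OP = (P2 (1 - P1)) / ((1 - P2) P1)` for each side. The OddsPath values
#' are mapped to ACMG evidence-strength labels.
#'
#' @param n_pathogenic_controls,n_total_controls control-set composition.
#' @param n_pred_pathogenic,n_pred_benign prediction counts among controls.
#' @return list with `P1`, `P2_pathogenic`, `P2_benign`, `OP_pathogenic`,
#'   `OP_benign`, `strength_pathogenic`, `strength_benign`.
#' @export
compute_oddspath <- function(n_pathogenic_controls, n_total_controls,
                             n_pred_pathogenic, n_pred_benign) {
  stopifnot(n_total_controls > 0, n_pathogenic_controls >= 0,
            n_pred_pathogenic >= 0, n_pred_benign >= 0)
  p1 <- n_pathogenic_controls / n_total_controls
  if (p1 %in% c(0, 1))
    stop("OddsPath undefined when the control set is single-class (P1 = ",
         p1, ")")
  p2p <- n_pred_pathogenic / (n_pred_pathogenic + 1)
  p2b <- 1 / (n_pred_benign + 1)
  opp <- (p2p * (1 - p1)) / ((1 - p2p) * p1)
  opb <- (p2b * (1 - p1)) / ((1 - p2b) * p1)
  list(P1 = p1, P2_pathogenic = p2p, P2_benign = p2b,
       OP_pathogenic = opp, OP_benign = opb,
       strength_pathogenic = oddspath_strength(opp, "pathogenic"),
       strength_benign = oddspath_strength(opb, "benign"))
}

#' ROC curve and AUC by threshold sweep
#'
#' Sweeps every observed posterior as a threshold and reports (1-specificity,
#' sensitivity) points; the AUC is computed by the rank (Mann-Whitney)
#' statistic with average ranks for ties, equivalent to the trapezoidal area
#' under the empirical ROC.
#'
#' @param posteriors numeric scores (higher = more pathogenic).
#' @param labels true binary labels.
#' @return list with `roc` (data.frame threshold, fpr, tpr) and `auc`.
#' @export
compute_roc_auc <- function(posteriors, labels) {
  y <- encode_labels(labels)
  if (!any(y == 1) || !any(y == 0)) stop("need both classes for a ROC curve")
  thr <- c(Inf, sort(unique(posteriors), decreasing = TRUE))
  roc <- t(vapply(thr, function(t) {
    pred <- posteriors >= t
    c(fpr = sum(pred & y == 0) / sum(y == 0),
      tpr = sum(pred & y == 1) / sum(y == 1))
  }, c(fpr = 0, tpr = 0)))
  r <- rank(posteriors)
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  auc <- (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  list(roc = data.frame(threshold = thr, fpr = roc[, "fpr"],
                        tpr = roc[, "tpr"]),
       auc = auc)
}

#' Full metric panel for a fitted classifier on labelled controls
#'
#' @param posteriors posterior probabilities for the labelled variants.
#' @param labels true binary labels.
#' @param intermediates passed to [compute_sensitivity_specificity()].
#' @return list of class `sge_metrics`: sensitivity, specificity, LR+/-,
#'   OddsPath panel, AUC and confusion counts.
#' @export
classifier_metrics <- function(posteriors, labels,
                               intermediates = "against") {
  cat_ <- categorize_gmm(posteriors)
  ss <- compute_sensitivity_specificity(cat_, labels, intermediates)
  lr <- compute_likelihood_ratios(ss$sensitivity, ss$specificity)
  y <- encode_labels(labels)
  op <- tryCatch(
    compute_oddspath(sum(y == 1), length(y),
                     sum(cat_ == "pathogenic"), sum(cat_ == "benign")),
    error = function(e) NULL)
  auc <- compute_roc_auc(posteriors, labels)$auc
  structure(c(ss, lr, list(oddspath = op, auc = auc)),
            class = "sge_metrics")
}

#' @export
print.sge_metrics <- function(x, ...) {
  cat("sensitivity ", round(x$sensitivity, 2), "%, specificity ",
      round(x$specificity, 2), "%\nLR+ ", signif(x$lr_plus, 4), ", LR- ",
      signif(x$lr_minus, 4), ", AUC ", signif(x$auc, 4), "\n", sep = "")
  if (!is.null(x$oddspath))
    cat("OddsPath pathogenic ", signif(x$oddspath$OP_pathogenic, 4), " (",
        x$oddspath$strength_pathogenic, "), benign ",
        signif(x$oddspath$OP_benign, 4), " (", x$oddspath$strength_benign,
        ")\n", sep = "")
  invisible(x)
}
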