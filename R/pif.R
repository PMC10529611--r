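#' Probability-of-impact-on-function probit classifier
#'
#' Fits a linear probit regression of the binary phenotype (functional = 0,
#' non-functional = 1) on one or more function-score predictors — in the
#' three-assay form, the DMSO, cisplatin and olaparib function scores of the
#' synonymous and nonsense control variants. The probability of impact on
#' function (PIF) of a variant is the fitted probability of being
#' non-functional, `PIF = pnorm(intercept + beta . FS)`.
#'
#' Well-separated control sets (the usual case: nonsense controls deplete by
#' several log2 units) make the unpenalized maximum-likelihood fit diverge
#' (quasi-separation). When separation is detected the model is refit with a
#' small quadratic (ridge) penalty on the slopes, default `1e-4`, and the
#' `separation` flag is set; fitted PIFs remain finite and training accuracy
#' is unaffected.
#'
#' @param x matrix or data.frame of function-score predictors (rows =
#'   training variants).
#' @param labels binary phenotype: 0/1, logical, or a factor/character with
#'   levels `functional` / `non_functional`.
#' @param penalty ridge penalty always applied (default 0).
#' @param separation_penalty penalty used for the stabilized refit.
#' @param coef_limit coefficient magnitude beyond which the fit is declared
#'   separated.
#' @return object of class `sge_pif` with `print`, `summary`, `coef`,
#'   `fitted`, `residuals`, `predict` and `plot` methods.
#' @export
pif_probit <- function(x, labels, penalty = 0, separation_penalty = 1e-4,
                       coef_limit = 15) {
  x <- as.matrix(x)
  if (is.null(colnames(x))) colnames(x) <- paste0("fs", seq_len(ncol(x)))
  y <- encode_labels(labels)
  if (length(unique(y)) < 2) stop("training labels contain a single class")
  if (min(table(y)) < 2) stop("need at least 2 training examples per class")
  stopifnot(nrow(x) == length(y))
  fit <- probit_ml(x, y, penalty)
  # under quasi-separation the likelihood supremum is 1 (nll -> 0) and the
  # coefficients diverge; either signature triggers the stabilized refit
  separation <- !fit$converged || max(abs(fit$coef[-1])) > coef_limit ||
    fit$value - penalty * sum(fit$coef[-1]^2) < 1e-3
  if (separation && penalty < separation_penalty) {
    fit <- probit_ml(x, y, separation_penalty)
    penalty <- separation_penalty
  }
  structure(list(coefficients = fit$coef, converged = fit$converged,
                 separation = separation, penalty = penalty,
                 x = x, y = y, logLik = -fit$value),
            class = "sge_pif")
}

encode_labels <- function(labels) {
  if (is.logical(labels)) return(as.integer(labels))
  if (is.numeric(labels)) {
    stopifnot(all(labels %in% c(0, 1)))
    return(as.integer(labels))
  }
  lv <- as.character(labels)
  bad <- !lv %in% c("functional", "non_functional")
  if (any(bad)) stop("labels must be functional / non_functional (or 0/1)")
  as.integer(lv == "non_functional")
}

probit_ml <- function(x, y, lambda) {
  X <- cbind(intercept = 1, x)
  nll <- function(b) {
    eta <- drop(X %*% b)
    -sum(ifelse(y == 1, pnorm(eta, log.p = TRUE),
                pnorm(-eta, log.p = TRUE))) + lambda * sum(b[-1]^2)
  }
  grad <- function(b) {
    eta <- drop(X %*% b)
    g <- ifelse(y == 1, exp(dnorm(eta, log = TRUE) - pnorm(eta, log.p = TRUE)),
                -exp(dnorm(eta, log = TRUE) - pnorm(-eta, log.p = TRUE)))
    drop(-crossprod(X, g)) + 2 * lambda * c(0, b[-1])
  }
  start <- c(qnorm(pmin(pmax(mean(y), 0.05), 0.95)), rep(0, ncol(x)))
  opt <- optim(start, nll, grad, method = "BFGS",
               control = list(maxit = 500, reltol = 1e-12))
  list(coef = setNames(opt$par, colnames(X)), converged = opt$convergence == 0,
       value = opt$value)
}

#' @export
coef.sge_pif <- function(object, ...) object$coefficients

#' @export
fitted.sge_pif <- function(object, ...) {
  compute_pif(object, object$x)
}

#' @export
residuals.sge_pif <- function(object, ...) object$y - fitted(object)

#' Compute PIFs for new function scores
#'
#' @param model a fitted [pif_probit()] model.
#' @param newdata matrix/data.frame with the model's predictor columns.
#' @return numeric vector of PIFs in `[0, 1]`.
#' @export
compute_pif <- function(model, newdata) {
  newdata <- as.matrix(newdata)
  vars <- names(model$coefficients)[-1]
  if (!is.null(colnames(newdata)) && all(vars %in% colnames(newdata)))
    newdata <- newdata[, vars, drop = FALSE]
  if (ncol(newdata) != length(vars)) stop("missing predictor column(s)")
  if (anyNA(newdata)) stop("missing predictor value(s)")
  pnorm(drop(cbind(1, newdata) %*% model$coefficients))
}

#' @export
predict.sge_pif <- function(object, newdata = object$x,
                            type = c("pif", "category", "link"), ...) {
  type <- match.arg(type)
  pif <- compute_pif(object, newdata)
  switch(type,
         pif = pif,
         category = categorize_pif(pif),
         link = qnorm(pif))
}

#' @export
print.sge_pif <- function(x, ...) {
  cat("Probit PIF model (", length(x$coefficients) - 1, " predictor(s))\n",
      sep = "")
  print(signif(x$coefficients, 4))
  if (x$separation)
    cat("note: quasi-separation detected; ridge-stabilized fit (penalty ",
        x$penalty, ")\n", sep = "")
  invisible(x)
}

#' @export
summary.sge_pif <- function(object, cutoff = 0.5, ...) {
  pif <- fitted(object)
  acc <- mean((pif > cutoff) == (object$y == 1))
  cat("Probit PIF model\n  predictors: ",
      paste(names(object$coefficients)[-1], collapse = ", "),
      "\n  training: ", sum(object$y == 0), " functional, ",
      sum(object$y == 1), " non-functional\n  model-fit accuracy at ",
      cutoff, " cutoff: ", round(100 * acc, 1), "%\n", sep = "")
  if (object$separation) cat("  quasi-separation: ridge-stabilized fit\n")
  invisible(list(accuracy = 100 * acc, coefficients = object$coefficients,
                 separation = object$separation))
}

#' @export
plot.sge_pif <- function(x, newdata = x$x, ci = NULL, ...) {
  pif <- compute_pif(x, newdata)
  o <- order(pif)
  plot(seq_along(pif), pif[o], pch = 16, cex = 0.6,
       xlab = "variant (ordered)", ylab = "PIF", ylim = c(0, 1), ...)
  if (!is.null(ci))
    segments(seq_along(pif), ci$ci_low[o], seq_along(pif), ci$ci_high[o],
             col = "grey60")
  graphics::abline(h = c(0.05, 0.99), lty = 2)
  invisible(x)
}

#' Three-way PIF categorization
#'
#' `PIF <= 0.05` is functional, `PIF > 0.99` non-functional, anything in
#' between intermediate (both boundaries as stated: 0.05 is functional,
#' 0.99 is intermediate).
#'
#' @param pif numeric vector in `[0, 1]`.
#' @return character vector of categories.
#' @export
categorize_pif <- function(pif) {
  if (any(!is.finite(pif)) || any(pif < 0 | pif > 1))
    stop("PIF values must lie in [0, 1]")
  ifelse(pif <= 0.05, "functional",
         ifelse(pif > 0.99, "non_functional", "intermediate"))
}

#' K-fold cross-validation of the probit PIF model
#'
#' Random (unstratified by default) assignment into K folds whose sizes
#' differ by at most one; each fold is predicted by a model trained on the
#' other K-1 folds at the given probability cutoff. Accuracy is the
#' unweighted mean of per-fold accuracies; sensitivity (non-functional
#' predicted correctly) and specificity (functional predicted correctly) are
#' averaged over the folds that contain the respective class.
#'
#' @param x,labels training predictors and phenotype labels.
#' @param K number of folds (`K = n` is leave-one-out).
#' @param seed integer seed controlling the fold assignment.
#' @param cutoff class-assignment probability cutoff (default 0.5).
#' @param stratified assign folds within each class.
#' @param ... passed to [pif_probit()].
#' @return list of class `sge_cv` with per-fold and overall metrics (in %).
#' @export
kfold_cv <- function(x, labels, K, seed = 1L, cutoff = 0.5,
                     stratified = FALSE, ...) {
  x <- as.matrix(x); y <- encode_labels(labels)
  n <- length(y)
  if (K < 2 || K > n) stop("K must be between 2 and n")
  set.seed(seed)
  fold <- if (stratified) {
    f <- integer(n)
    for (cl in unique(y)) {
      i <- which(y == cl)
      f[i] <- sample(rep_len(seq_len(K), length(i)))
    }
    f
  } else sample(rep_len(seq_len(K), n))
  acc <- sens <- spec <- rep(NA_real_, K)
  for (k in seq_len(K)) {
    tr <- fold != k; te <- !tr
    fit <- pif_probit(x[tr, , drop = FALSE], y[tr], ...)
    pred <- as.integer(compute_pif(fit, x[te, , drop = FALSE]) > cutoff)
    truth <- y[te]
    acc[k] <- mean(pred == truth)
    if (any(truth == 1)) sens[k] <- mean(pred[truth == 1] == 1)
    if (any(truth == 0)) spec[k] <- mean(pred[truth == 0] == 0)
  }
  structure(list(K = K, seed = seed, fold = fold,
                 fold_accuracy = 100 * acc,
                 accuracy = 100 * mean(acc),
                 sensitivity = 100 * mean(sens, na.rm = TRUE),
                 specificity = 100 * mean(spec, na.rm = TRUE)),
            class = "sge_cv")
}

#' @export
print.sge_cv <- function(x, ...) {
  cat("K-fold cross-validation (K = ", x$K, "): accuracy ",
      round(x$accuracy, 1), "%, sensitivity ", round(x$sensitivity, 1),
      "%, specificity ", round(x$specificity, 1), "%\n", sep = "")
  invisible(x)
}

#' Perturbation 95% confidence intervals for PIFs
#'
#' Repeatedly perturbs every training predictor value by independent
#' `Normal(0, noise_sd)` noise, refits the probit model, and recomputes the
#' PIF of every variant in `newdata`; per-variant confidence bounds are the
#' percentile-method quantiles of the simulated PIFs. Extreme variants (large
#' absolute linear predictor) get near-zero widths; variants near the
#' decision boundary get the widest intervals.
#'
#' @param model a fitted [pif_probit()] model.
#' @param newdata function-score table to compute CIs for.
#' @param n_sims number of perturbation refits (default 10000).
#' @param noise_sd perturbation SD (default 0.05).
#' @param seed integer seed.
#' @param level confidence level (default 0.95).
#' @return data.frame with `pif`, `ci_low`, `ci_high`, `category`.
#' @export
pif_confidence_intervals <- function(model, newdata = model$x,
                                     n_sims = 10000L, noise_sd = 0.05,
                                     seed = 1L, level = 0.95) {
  newdata <- as.matrix(newdata)
  set.seed(seed)
  sims <- matrix(NA_real_, n_sims, nrow(newdata))
  failures <- 0L
  for (s in seq_len(n_sims)) {
    xp <- model$x + matrix(rnorm(length(model$x), 0, noise_sd),
                           nrow(model$x))
    fit <- tryCatch(pif_probit(xp, model$y, penalty = model$penalty),
                    error = function(e) NULL)
    if (is.null(fit)) { failures <- failures + 1L; next }
    sims[s, ] <- compute_pif(fit, newdata)
  }
  if (failures > 0.01 * n_sims)
    warning(failures, " of ", n_sims, " perturbation fits failed")
  a <- (1 - level) / 2
  ci <- t(apply(sims, 2, quantile, probs = c(a, 1 - a), na.rm = TRUE))
  pif <- compute_pif(model, newdata)
  data.frame(pif = pif, ci_low = ci[, 1], ci_high = ci[, 2],
             category = categorize_pif(pif))
}

#' Fit the three one-variable probit models alongside the full model
#'
#' Each single-assay model uses one function-score column of the training
#' set; comparing their model-fit accuracies with the full three-variable
#' model quantifies what the drug arms add (hypomorphs separate only there).
#'
#' @param x training predictor matrix (one column per assay).
#' @param labels phenotype labels.
#' @param newdata table to compute per-model PIFs for (default training).
#' @param cutoff accuracy cutoff (default 0.5).
#' @return list per predictor: `model`, `pif`, `category`, `accuracy` (%).
#' @export
one_variable_models <- function(x, labels, newdata = NULL, cutoff = 0.5) {
  x <- as.matrix(x)
  if (is.null(newdata)) newdata <- x
  newdata <- as.matrix(newdata)
  y <- encode_labels(labels)
  out <- list()
  for (j in seq_len(ncol(x))) {
    nm <- colnames(x)[j]
    fit <- pif_probit(x[, j, drop = FALSE], y)
    pif <- compute_pif(fit, newdata[, j, drop = FALSE])
    out[[nm]] <- list(model = fit, pif = pif,
                      category = categorize_pif(pif),
                      accuracy = 100 * mean((fitted(fit) > cutoff) == (y == 1)))
  }
  out
}
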