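test_that("the posterior equals the closed-form Gaussian ratio", {
  m <- structure(list(mean = c(functional = 2, non_functional = 0),
                      sd = c(functional = 1, non_functional = 1),
                      priors = c(functional = 0.5, non_functional = 0.5)),
                 class = "sge_gmm")
  # symmetric point between the two means
  expect_equal(posterior_pathogenic(m, 1), 0.5)
  # at the non-functional mean: e^-2 / (1 + e^-2)
  expect_equal(posterior_pathogenic(m, 2), exp(-2) / (1 + exp(-2)),
               tolerance = 1e-10)
  expect_equal(posterior_pathogenic(m, 2), 0.1192, tolerance = 1e-4)
  # limits take the nearer class's label
  expect_equal(posterior_pathogenic(m, -50), 1)
  expect_equal(posterior_pathogenic(m, 50), 0)
})

test_that("the supervised fit recovers class parameters", {
  set.seed(15)
  s <- c(rnorm(200, 1, 0.2), rnorm(200, -1, 0.2))
  y <- rep(c("functional", "non_functional"), each = 200)
  fit <- gmm_classify(s, y)
  se <- 0.2 / sqrt(200)
  expect_lt(abs(fit$mean["functional"] - 1), 3 * se)
  expect_lt(abs(fit$mean["non_functional"] + 1), 3 * se)
  expect_equal(unname(fit$priors), c(0.5, 0.5))
  # unequal class sizes give proportional priors unless equal_priors
  s2 <- c(rnorm(300, 1, 0.2), rnorm(50, -1, 0.2))
  y2 <- rep(c("functional", "non_functional"), c(300, 50))
  fit2 <- gmm_classify(s2, y2)
  expect_equal(unname(fit2$priors["functional"]), 300 / 350)
  fit3 <- gmm_classify(s2, y2, equal_priors = TRUE)
  expect_equal(unname(fit3$priors), c(0.5, 0.5))
  expect_error(gmm_classify(c(1, 2, 3), c(0, 0, 1)), "at least 2")
  expect_error(gmm_classify(c(1, 1, 2, 3), c(0, 0, 1, 1)), "zero variance")
})

test_that("the supervised fit matches mclust discriminant analysis", {
  skip_if_not_installed("mclust")
  withr::local_package("mclust")
  set.seed(16)
  s <- c(rnorm(60, 0.5, 0.3), rnorm(25, -2, 0.5))
  y <- rep(c(0, 1), c(60, 25))
  fit <- gmm_classify(s, y)
  da <- mclust::MclustDA(s, y, modelType = "MclustDA",
                         modelNames = "V", G = 1, verbose = FALSE)
  post <- predict(da, newdata = s)$z[, "1"]
  expect_equal(posterior_pathogenic(fit, s), unname(post), tolerance = 0.02)
})

test_that("posterior categorization uses strict 0.99 / 0.05 boundaries", {
  expect_equal(categorize_gmm(c(0.995, 0.05, 0.3, 0.99, 0.049)),
               c("pathogenic", "intermediate", "intermediate",
                 "intermediate", "benign"))
  expect_error(categorize_gmm(-0.1), "0, 1")
})

test_that("sensitivity/specificity and likelihood ratios match hand arithmetic", {
  # confusion (TP 8, FN 0, TN 42, FP 2): 100% and 95.4545..%
  pred <- c(rep("pathogenic", 8), rep("benign", 42), rep("pathogenic", 2))
  lab <- c(rep(1, 8), rep(0, 44))
  ss <- compute_sensitivity_specificity(pred, lab)
  expect_equal(ss$sensitivity, 100)
  expect_equal(ss$specificity, 100 * 42 / 44)
  expect_equal(unname(ss$confusion), c(8, 0, 42, 2))
  lr <- compute_likelihood_ratios(ss$sensitivity, ss$specificity)
  expect_equal(lr$lr_plus, 100 / (100 - 100 * 42 / 44))
  expect_equal(round(lr$lr_plus), 22)
  expect_equal(lr$lr_minus, 0)
  expect_equal(compute_likelihood_ratios(50, 50)$lr_plus, 1)
  expect_identical(compute_likelihood_ratios(100, 100)$lr_plus, Inf)
  # intermediates count against their class by default, not when excluded
  pred2 <- c(rep("pathogenic", 7), "intermediate", rep("benign", 44))
  ss2 <- compute_sensitivity_specificity(pred2, lab)
  expect_equal(ss2$sensitivity, 100 * 7 / 8)
  ss3 <- compute_sensitivity_specificity(pred2, lab,
                                         intermediates = "exclude")
  expect_equal(ss3$sensitivity, 100)
  # all-pathogenic predictions have zero specificity
  expect_equal(compute_sensitivity_specificity(
    rep("pathogenic", 52), lab)$specificity, 0)
})

test_that("metric formulas agree with a brute-force calculator on random tables", {
  set.seed(17)
  for (k in 1:25) {
    tp <- sample(0:20, 1); fn <- sample(0:20, 1)
    tn <- sample(0:20, 1); fp <- sample(0:20, 1)
    if (tp + fn == 0 || tn + fp == 0) next
    pred <- c(rep("pathogenic", tp), rep("benign", fn),
              rep("benign", tn), rep("pathogenic", fp))
    lab <- rep(c(1, 0), c(tp + fn, tn + fp))
    ss <- compute_sensitivity_specificity(pred, lab)
    o <- brute_metrics(tp, fn, tn, fp)
    expect_equal(ss$sensitivity, o$sens)
    expect_equal(ss$specificity, o$spec)
    if (o$spec < 100 && o$spec > 0) {
      lr <- compute_likelihood_ratios(ss$sensitivity, ss$specificity)
      expect_equal(lr$lr_plus, o$lr_plus)
      expect_equal(lr$lr_minus, o$lr_minus)
    }
  }
})

test_that("OddsPath follows the printed formulas and strength bands", {
  op <- compute_oddspath(10, 20, 9, 0)
  expect_equal(op$P1, 0.5)
  expect_equal(op$P2_pathogenic, 0.9)
  expect_equal(op$OP_pathogenic, 9)
  expect_equal(op$strength_pathogenic, "PS3_moderate")
  op2 <- compute_oddspath(10, 20, 0, 9)
  expect_equal(op2$P2_benign, 0.1)
  expect_equal(op2$OP_benign, 1 / 9, tolerance = 1e-4)
  expect_equal(op2$strength_benign, "BS3_moderate")
  # P2 = P1 means no evidence
  op3 <- compute_oddspath(10, 20, 1, 1)
  expect_equal(op3$OP_pathogenic, 1)
  expect_error(compute_oddspath(0, 20, 1, 1), "single-class")
})

test_that("ROC/AUC equals the Mann-Whitney statistic", {
  # perfectly separated posteriors
  expect_equal(compute_roc_auc(c(0.1, 0.2, 0.8, 0.9),
                               c(0, 0, 1, 1))$auc, 1)
  set.seed(18)
  for (k in 1:10) {
    p <- round(runif(40), 2)          # ties on purpose
    y <- rbinom(40, 1, 0.4)
    if (sum(y) %in% c(0, 40)) next
    auc <- compute_roc_auc(p, y)$auc
    w <- wilcox.test(p[y == 1], p[y == 0], exact = FALSE)$statistic
    expect_equal(auc, unname(w) / (sum(y) * sum(1 - y)))
  }
  # large-n label-independent posteriors give AUC near 0.5
  set.seed(19)
  p <- runif(4000); y <- rbinom(4000, 1, 0.5)
  expect_lt(abs(compute_roc_auc(p, y)$auc - 0.5), 0.03)
  expect_error(compute_roc_auc(c(0.1, 0.9), c(1, 1)), "both classes")
})

test_that("AUC matches the pROC reference implementation", {
  skip_if_not_installed("pROC")
  set.seed(20)
  p <- rnorm(60); y <- rbinom(60, 1, plogis(p))
  if (length(unique(y)) == 2) {
    ref <- suppressMessages(as.numeric(pROC::auc(y, p)))
    expect_equal(compute_roc_auc(p, y)$auc, ref)
  }
})

test_that("the classifier recovers exon-wide simulated classes", {
  # control composition mirroring the SNV-saturation study (42 functional,
  # 12 non-functional) at the generator's default effect sizes (3 log2
  # units between class means, SD ~0.4)
  set.seed(21)
  ctrl_s <- c(rnorm(42, 0, 0.4), rnorm(12, -3, 0.4))
  ctrl_y <- rep(c(0, 1), c(42, 12))
  fit <- gmm_classify(ctrl_s, ctrl_y)
  post <- posterior_pathogenic(fit, ctrl_s)
  mets <- classifier_metrics(post, ctrl_y)
  expect_gte(mets$sensitivity, 95)
  expect_gte(mets$specificity, 90)
  expect_gte(mets$auc, 0.95)
})
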