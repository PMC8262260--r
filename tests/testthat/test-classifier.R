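# features table with the classifier's covariate schema from raw columns
fake_features <- function(n, clr_n_umi = rnorm(n), clr_n_genes = rnorm(n),
                          clr_n_umi_vdj = rnorm(n),
                          mito_ribo_ratio = runif(n)) {
  data.frame(barcode = sprintf("b%05d", seq_len(n)),
             sample_id = "s1",
             mito_ribo_ratio = mito_ribo_ratio,
             clr_n_umi = clr_n_umi, clr_n_genes = clr_n_genes,
             clr_n_umi_vdj = clr_n_umi_vdj,
             stringsAsFactors = FALSE)
}

test_that("training sets are unions of sources with remainder negatives", {
  universe <- paste0("b", 1:6)
  ts <- build_training_set(universe, vdj = c("b1", "b2"),
                           cite = c("b2", "b3"))
  expect_setequal(ts$positives, c("b1", "b2", "b3"))
  expect_setequal(ts$negatives, c("b4", "b5", "b6"))
  expect_named(ts$sources, c("vdj", "cite"))

  single <- build_training_set(universe, vdj = c("b1", "b5"))
  expect_setequal(single$positives, c("b1", "b5"))

  expect_error(build_training_set(universe, vdj = character(0)),
               "no identified doublets")
  expect_error(build_training_set(universe, vdj = universe),
               "no negatives")
})

test_that("the 2-SD trim keeps central values and removes outliers", {
  n <- 200
  set.seed(40)
  feats <- fake_features(n)
  feats$clr_n_umi <- rnorm(n)
  feats$clr_n_umi[1] <- mean(feats$clr_n_umi[-1])  # near the group mean
  trimmed <- trim_2sd(feats, feats$barcode)
  expect_true(feats$barcode[1] %in% trimmed)

  feats$clr_n_genes[2] <- mean(feats$clr_n_genes) +
    3.5 * sd(feats$clr_n_genes)
  expect_false(feats$barcode[2] %in% trim_2sd(feats, feats$barcode))

  # a constant variable alone cannot trim anything away
  feats$mito_ribo_ratio <- 0.2
  expect_length(trim_2sd(feats, feats$barcode, vars = "mito_ribo_ratio"),
                nrow(feats))
})

test_that("the trim retains the normal-tail fraction on Gaussian features", {
  set.seed(1234)
  n <- 1e5
  feats <- fake_features(n, mito_ribo_ratio = rnorm(n))
  kept <- trim_2sd(feats, feats$barcode)
  # four independent N(0,1) variables: P(all within 2 SD) ~ 0.9545^4
  expect_equal(length(kept) / n, 0.9545^4, tolerance = 0.01)
})

test_that("logistic coefficients are recovered on a well-specified simulation", {
  set.seed(77)
  n <- 1e4
  feats <- fake_features(n, mito_ribo_ratio = rnorm(n))
  eta <- -2 + 1.5 * feats$clr_n_umi
  y <- runif(n) < plogis(eta)
  training <- build_training_set(feats$barcode,
                                 sim = feats$barcode[y])
  fit <- mltiplet(feats, training, trim = FALSE,
                  covariates = c("mito_ribo_ratio", "clr_n_umi",
                                 "clr_n_genes", "clr_n_umi_vdj"))
  expect_false(fit$ridge)
  beta <- coef(fit)
  se <- summary(fit$glm)$coefficients[, "Std. Error"]
  names(se) <- names(beta)
  expect_lt(abs(beta[["clr_n_umi"]] - 1.5), 0.15)
  expect_lt(abs(beta[["clr_n_umi"]] - 1.5), 2 * se[["clr_n_umi"]])
  expect_lt(abs(beta[["(Intercept)"]] + 2), 2 * se[["(Intercept)"]])
  # the null covariates' confidence intervals cover zero
  for (v in c("clr_n_genes", "clr_n_umi_vdj", "mito_ribo_ratio"))
    expect_lt(abs(beta[[v]]), 2 * se[[v]])

  # probabilities rank the truth at the model's attainable discrimination:
  # for logit -2 + 1.5 z the population AUROC is 0.822 (rank-statistic
  # oracle at n = 2e6)
  pred <- predict(fit, feats)
  auc <- as.numeric(pROC::auc(pROC::roc(y, pred$probability,
                                        quiet = TRUE)))
  expect_equal(auc, 0.822, tolerance = 0.02)
})

test_that("labels independent of features give slopes indistinguishable from zero", {
  set.seed(99)
  n <- 4000
  feats <- fake_features(n, mito_ribo_ratio = rnorm(n))
  y <- runif(n) < 0.1
  fit <- mltiplet(feats, build_training_set(feats$barcode,
                                            src = feats$barcode[y]),
                  trim = FALSE,
                  covariates = c("mito_ribo_ratio", "clr_n_umi",
                                 "clr_n_genes", "clr_n_umi_vdj"))
  sm <- summary(fit$glm)$coefficients
  slopes <- sm[-1, ]
  expect_true(all(abs(slopes[, "Estimate"]) < 2.5 * slopes[, "Std. Error"]))
})

test_that("duplicating every row leaves the coefficients unchanged", {
  set.seed(55)
  n <- 800
  feats <- fake_features(n)
  y <- runif(n) < plogis(-1 + feats$clr_n_umi)
  fit1 <- mltiplet(feats, build_training_set(feats$barcode,
                                             s = feats$barcode[y]),
                   trim = FALSE)
  feats2 <- rbind(feats, transform(feats, barcode = paste0(barcode, "x")))
  pos2 <- c(feats$barcode[y], paste0(feats$barcode[y], "x"))
  fit2 <- mltiplet(feats2, build_training_set(feats2$barcode, s = pos2),
                   trim = FALSE)
  expect_equal(coef(fit1), coef(fit2), tolerance = 1e-6)
})

test_that("prediction applies the inverse logit with a strict cutoff", {
  model <- structure(list(
    coefficients = c(`(Intercept)` = 0, mito_ribo_ratio = 0,
                     clr_n_umi = 1, clr_n_genes = 0, clr_n_umi_vdj = 0),
    feature_names = c("mito_ribo_ratio", "clr_n_umi", "clr_n_genes",
                      "clr_n_umi_vdj"),
    cutoff = 0.5, training = list(positives = character(0)),
    trimmed = list(), trim = FALSE, covariates = NULL, ridge = FALSE,
    glm = NULL), class = "mltiplet")
  feats <- fake_features(3, clr_n_umi = c(0, 2, -2))
  pred <- predict(model, feats)
  expect_equal(pred$probability, plogis(c(0, 2, -2)))
  expect_equal(pred$call, c(FALSE, TRUE, FALSE))  # 0.5 is not called

  # all-zero slopes: every probability equals the inverse-logit intercept
  model$coefficients[] <- 0
  model$coefficients[["(Intercept)"]] <- -1
  pred0 <- predict(model, feats)
  expect_true(all(pred0$probability == plogis(-1)))

  # training positives are always reported as doublets
  model$training$positives <- feats$barcode[1]
  predt <- predict(model, feats)
  expect_true(predt$call[1] & predt$training[1])

  feats_bad <- feats[, setdiff(names(feats), "clr_n_umi_vdj")]
  expect_error(predict(model, feats_bad), "missing")
})

test_that("perfect separation falls back to a ridge-stabilised fit", {
  set.seed(13)
  n <- 500
  feats <- fake_features(n)
  y <- feats$clr_n_umi > 0
  expect_warning(
    fit <- mltiplet(feats, build_training_set(feats$barcode,
                                              s = feats$barcode[y]),
                    trim = FALSE),
    "ridge-stabilised")
  expect_true(fit$ridge)
  pred <- predict(fit, feats)
  expect_gt(mean(pred$call == y), 0.98)
})

test_that("the estimated proportion counts calls and is monotone in the cutoff", {
  calls <- data.frame(barcode = paste0("b", 1:1000),
                      call = c(rep(TRUE, 50), rep(FALSE, 950)))
  expect_equal(estimate_doublet_proportion(calls), 0.05)
  expect_equal(estimate_doublet_proportion(calls[calls$call == FALSE, ]), 0)

  set.seed(2)
  feats <- fake_features(500)
  y <- runif(500) < plogis(feats$clr_n_umi)
  fit <- mltiplet(feats, build_training_set(feats$barcode,
                                            s = feats$barcode[y]),
                  trim = FALSE)
  props <- vapply(c(0.9, 0.5, 0.2, 0.05), function(ct)
    estimate_doublet_proportion(predict(fit, feats, cutoff = ct)),
    numeric(1))
  expect_true(all(diff(props) >= 0))
})

test_that("model JSON persistence round-trips predictions", {
  set.seed(3)
  feats <- fake_features(300)
  y <- runif(300) < plogis(feats$clr_n_umi - 1)
  fit <- mltiplet(feats, build_training_set(feats$barcode,
                                            s = feats$barcode[y]),
                  trim = FALSE)
  path <- withr::local_tempfile(fileext = ".json")
  write_model(fit, path)
  restored <- read_model(path)
  expect_equal(predict(restored, feats)$probability,
               predict(fit, feats)$probability, tolerance = 1e-12)
})
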