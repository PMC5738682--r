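test_that("intercept-only fit has the closed-form null deviance", {
  fit <- fit_logistic(matrix(nrow = 4, ncol = 0), c(1, 1, 0, 0))
  expect_equal(fit$intercept, 0, tolerance = 1e-8)
  expect_equal(fit$deviance, 8 * log(2), tolerance = 1e-8)
  expect_equal(fit$deviance, fit$null_deviance, tolerance = 1e-10)
})

test_that("fit_logistic recovers generating coefficients on large samples", {
  set.seed(77)
  n <- 2000
  X <- cbind(f1 = rnorm(n), f2 = rnorm(n))
  eta <- 0.3 + 1.5 * X[, 1] - 0.8 * X[, 2]
  y <- rbinom(n, 1, plogis(eta))
  fit <- fit_logistic(X, y)
  expect_true(fit$converged)
  expect_false(fit$separation_detected)
  expect_lt(abs(fit$intercept - 0.3), 0.15)
  expect_lt(abs(fit$coefficients[["f1"]] - 1.5), 0.15)
  expect_lt(abs(fit$coefficients[["f2"]] + 0.8), 0.15)
  # agrees with glm to numerical precision
  ref <- glm(y ~ X, family = binomial())
  expect_equal(unname(fit$coefficients), unname(coef(ref)[-1]), tolerance = 1e-6)
  expect_equal(fit$deviance, ref$deviance, tolerance = 1e-8)
})

test_that("fit_logistic guards its input contracts", {
  X <- matrix(rnorm(20), 10, 2)
  expect_error(fit_logistic(X, rep(1, 10)), "both classes")
  expect_error(fit_logistic(X, c(rep(0.5, 10))), "0/1")
  Xna <- X; Xna[1, 1] <- NA
  expect_error(fit_logistic(Xna, rep(c(0, 1), 5)), "missing")
  Xcol <- cbind(a = X[, 1], b = X[, 1])  # exactly collinear
  expect_error(fit_logistic(Xcol, rep(c(0, 1), 5)), "collinear")
})

test_that("perfect separation is detected and flagged", {
  X <- matrix(c(1:5, 11:15), ncol = 1)
  y <- rep(c(0, 1), each = 5)
  fit <- suppressWarnings(fit_logistic(X, y))
  expect_true(fit$separation_detected)
  # ridge stabilisation bounds the coefficients
  rfit <- fit_logistic(X, y, ridge = 0.1)
  expect_false(rfit$separation_detected)
  expect_lt(abs(rfit$coefficients[[1]]), 15)
})

test_that("likelihood-ratio test follows the chi-square tail", {
  mk <- function(features, deviance, n = 50) {
    structure(list(features = features, deviance = deviance,
                   null_deviance = 70, n = n), class = "panel_logit")
  }
  same <- likelihood_ratio_test(mk("a", 10), mk("a", 10))
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)
  lrt <- likelihood_ratio_test(mk(c("a", "b"), 10), mk("a", 20.83))
  expect_equal(lrt$df, 1)
  expect_equal(lrt$statistic, 10.83)
  expect_equal(lrt$p_value, pchisq(10.83, 1, lower.tail = FALSE))
  expect_equal(lrt$p_value, 0.001, tolerance = 0.01)
  expect_error(likelihood_ratio_test(mk("a", 10), mk("z", 12)), "nested")
})

test_that("dropping a null feature is usually insignificant, an informative one is not", {
  res <- vapply(1:20, function(s) {
    set.seed(400 + s)
    n <- 600
    X <- cbind(inf = rnorm(n), nul = rnorm(n))
    y <- rbinom(n, 1, plogis(1.2 * X[, "inf"]))
    full <- fit_logistic(X, y)
    drop_null <- likelihood_ratio_test(full, fit_logistic(X[, "inf", drop = FALSE], y))
    drop_inf <- likelihood_ratio_test(full, fit_logistic(X[, "nul", drop = FALSE], y))
    c(null_p = drop_null$p_value, inf_p = drop_inf$p_value)
  }, numeric(2))
  expect_gte(mean(res["null_p", ] > 0.05), 0.8)
  expect_true(all(res["inf_p", ] < 0.01))
})

test_that("deviance is monotone under nesting", {
  set.seed(21)
  n <- 120
  X <- matrix(rnorm(n * 3), n, dimnames = list(NULL, c("a", "b", "c")))
  y <- rbinom(n, 1, plogis(0.5 * X[, 1]))
  devs <- vapply(1:3, function(k) {
    fit_logistic(X[, seq_len(k), drop = FALSE], y)$deviance
  }, numeric(1))
  expect_true(all(diff(devs) <= 1e-8))
})

test_that("predict_prob is the logistic of the linear predictor", {
  m0 <- structure(list(features = c("a", "b"), intercept = 0,
                       coefficients = c(a = 0, b = 0), n = 3),
                  class = "panel_logit")
  X <- data.frame(a = c(-1, 0, 5), b = c(2, 0, -3))
  expect_equal(predict_prob(m0, X), rep(0.5, 3))
  m1 <- structure(list(features = "a", intercept = 50,
                       coefficients = c(a = 0), n = 3), class = "panel_logit")
  expect_equal(predict_prob(m1, X), rep(1, 3), tolerance = 1e-10)
  m2 <- structure(list(features = "a", intercept = -1,
                       coefficients = c(a = 2), n = 3), class = "panel_logit")
  expect_equal(predict_prob(m2, data.frame(a = 0.5)), 0.5)
  expect_error(predict_prob(m2, data.frame(b = 1)))
})

test_that("training-set mean predicted probability equals prevalence", {
  set.seed(31)
  n <- 300
  X <- matrix(rnorm(n * 2), n, dimnames = list(NULL, c("a", "b")))
  y <- rbinom(n, 1, plogis(0.4 + X[, 1]))
  fit <- fit_logistic(X, y)
  expect_equal(mean(predict_prob(fit, X)), mean(y), tolerance = 1e-6)
})

test_that("rank_models orders by deviance with deterministic tie-breaks", {
  set.seed(41)
  n <- 80
  m <- rbind(
    inf1 = plogis(rnorm(n, rep(c(-2, 2), each = n / 2), 1)),
    inf2 = plogis(rnorm(n, rep(c(-2, 2), each = n / 2), 1)),
    nul1 = runif(n), nul2 = runif(n)
  )
  colnames(m) <- sprintf("s%02d", seq_len(n))
  beta <- matrix_to_beta(m)
  labels <- rep(c(0, 1), each = n / 2)
  cands <- tibble::tibble(
    set_id = c("set001", "set002", "set003"),
    probes = list(c("inf1", "inf2"), c("nul1", "nul2"), c("inf1", "inf2")),
    provenance = list(c("t", "t"), c("t", "t"), c("t", "t")),
    size = c(2L, 2L, 2L)
  )
  rm_ <- suppressWarnings(rank_models(cands, beta, labels, top = 1))
  expect_equal(nrow(rm_), 3)
  # informative sets first; identical rosters keep a stable order
  expect_setequal(rm_$set_id[1:2], c("set001", "set003"))
  expect_equal(rm_$set_id[3], "set002")
  expect_true(rm_$selected[1])
  expect_false(any(rm_$selected[-1]))
  expect_equal(rm_$deviance[1], rm_$deviance[2], tolerance = 1e-8)
  # tidy/glance surface the fitted panel
  td <- tidy(rm_$model[[1]])
  expect_equal(td$term, c("(Intercept)", rm_$probes[[1]]))
  gl <- glance(rm_$model[[1]])
  expect_equal(gl$df, 2)
  expect_equal(gl$n, n)
})

test_that("informative candidate outranks a null candidate across seeds", {
  wins <- vapply(1:8, function(s) {
    ch <- simulate_cohort(quick_config(), seed = 500 + s)
    planted <- ch$truth$diff_probe_ids[1:3]
    nulls <- setdiff(ch$beta$probe_id,
                     c(ch$truth$diff_probe_ids, ch$truth$age_probe_ids))[1:3]
    cands <- tibble::tibble(
      set_id = c("planted", "null"),
      probes = list(planted, nulls),
      provenance = list(rep("t", 3), rep("t", 3)),
      size = c(3L, 3L)
    )
    tissue <- ch$samples[ch$samples$specimen_type %in%
                           c("tumor_tissue", "normal_tissue"), ]
    beta <- ch$beta[, c("probe_id", tissue$sample_id)]
    rm_ <- suppressWarnings(rank_models(
      cands, beta, as.integer(tissue$specimen_type == "tumor_tissue")))
    rm_$set_id[1] == "planted"
  }, logical(1))
  expect_gte(mean(wins), 0.95)
})
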