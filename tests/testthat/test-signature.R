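# small synthetic feature/survival set with planted signal
make_screening_data <- function(n = 300, p_noise = 5, beta = 1, seed = 1) {
  set.seed(seed)
  risk <- rnorm(n)
  X <- cbind(risk = risk,
             matrix(rnorm(n * p_noise), n,
                    dimnames = list(NULL, paste0("noise", seq_len(p_noise)))))
  u <- runif(n)
  time <- 5 * (-log(u) * exp(-beta * risk))
  list(X = X, time = time, event = rep(1L, n))
}

test_that("univariate screening keeps planted signal and excludes degenerate features", {
  d <- make_screening_data(n = 300, beta = 1, seed = 2)
  X <- cbind(d$X, flat = rep(3, nrow(d$X)))
  scr <- univariate_screen(X, d$time, d$event)
  expect_true(scr$kept[scr$id == "risk"])
  expect_equal(scr$reason[scr$id == "flat"], "degenerate")
  expect_false(scr$kept[scr$id == "flat"])
  expect_true(all(scr$p >= 0 & scr$p <= 1, na.rm = TRUE))
  expect_error(univariate_screen(d$X, d$time, rep(0L, length(d$time))), "event")
})

test_that("screening of pure-noise features retains about the nominal 5 percent", {
  set.seed(42)
  n <- 150
  X <- matrix(rnorm(n * 1000), n, dimnames = list(NULL, paste0("f", 1:1000)))
  time <- rexp(n, 0.2)
  scr <- univariate_screen(X, time, rep(1L, n))
  expect_lt(abs(mean(scr$kept) - 0.05), 0.02)
})

test_that("LASSO-Cox at vanishing penalty matches the unpenalised Cox fit", {
  d <- make_screening_data(n = 500, p_noise = 2, beta = 0.8, seed = 3)
  m <- fit_lasso_cox(d$X, d$time, d$event, lambda = 1e-5)
  z <- scale(d$X)
  fit <- survival::coxph(survival::Surv(d$time, d$event) ~ z, ties = "efron")
  ref <- coef(fit)[paste0("z", m$feature_ids)]
  expect_equal(length(m$feature_ids), 3L)
  expect_lt(max(abs(m$weights - ref) / abs(ref)), 1e-3)
})

test_that("an over-penalised model raises the empty-model error", {
  d <- make_screening_data(n = 100, p_noise = 2, seed = 4)
  expect_error(fit_lasso_cox(d$X, d$time, d$event, lambda = 100), "smaller lambda")
})

test_that("LASSO selection is deterministic given the seed", {
  d <- make_screening_data(n = 150, p_noise = 10, beta = 0.7, seed = 5)
  m1 <- fit_lasso_cox(d$X, d$time, d$event, seed = 99)
  m2 <- fit_lasso_cox(d$X, d$time, d$event, seed = 99)
  expect_identical(m1$feature_ids, m2$feature_ids)
  expect_identical(m1$weights, m2$weights)
  expect_identical(m1$lambda, m2$lambda)
})

test_that("LASSO recovers most planted support across seeds", {
  hits <- vapply(1:50, function(s) {
    set.seed(s)
    n <- 400
    Xs <- matrix(rnorm(n * 5), n, dimnames = list(NULL, paste0("sig", 1:5)))
    Xn <- matrix(rnorm(n * 95), n, dimnames = list(NULL, paste0("noise", 1:95)))
    lp <- Xs %*% rep(0.6, 5)
    time <- 5 * (-log(runif(n)) * exp(-lp))
    m <- tryCatch(fit_lasso_cox(cbind(Xs, Xn), time, rep(1L, n),
                                lambda_rule = "min", seed = s),
                  error = function(e) NULL)
    if (is.null(m)) 0L else sum(paste0("sig", 1:5) %in% m$feature_ids)
  }, integer(1))
  expect_gte(mean(hits >= 4), 0.80)
})

test_that("signature scoring is an exact dot product with named-feature lookup", {
  m <- structure(list(feature_ids = c("a", "b", "c"), weights = c(2, -1, 0.5),
                      center = c(0, 0, 0), scale = c(1, 1, 1), cutoff = NA,
                      reference_flag = FALSE), class = "signature_model")
  expect_equal(score_signature(m, c(a = 0, b = 0, c = 0)), 0)
  expect_equal(score_signature(m, c(a = 1, b = 0, c = 0)), 2)
  set.seed(6)
  for (i in 1:20) {
    v <- setNames(rnorm(3), c("a", "b", "c"))
    expect_equal(score_signature(m, v), sum(c(2, -1, 0.5) * v))
  }
  expect_error(score_signature(m, c(a = 1, b = 2)), "c")
})

test_that("the shipped reference signature loads with its published weights and cut-off", {
  ref <- reference_signature()
  expect_true(ref$reference_flag)
  expect_length(ref$weights, 8)
  expect_equal(ref$cutoff, -1.117)
  expect_equal(ref$weights[3], -1.980131e+01)
  # unit vector on one feature scores its weight
  v <- setNames(rep(0, 8), ref$feature_ids); v[1] <- 1
  expect_equal(score_signature(ref, v), ref$weights[1])
})

test_that("signature models round-trip through JSON", {
  d <- make_screening_data(n = 120, p_noise = 3, seed = 8)
  m <- fit_lasso_cox(d$X, d$time, d$event, lambda = 0.01, cutoff = 0.3)
  f <- tempfile(fileext = ".json")
  write_signature_model(m, f)
  m2 <- read_signature_model(f)
  expect_equal(m2$feature_ids, m$feature_ids)
  expect_equal(m2$weights, m$weights)
  expect_equal(m2$cutoff, m$cutoff)
})

test_that("cut-point search equals the brute-force survdiff scan", {
  for (s in c(1, 2, 3, 7, 11)) {
    n <- c(40, 80, 120, 200, 60)[match(s, c(1, 2, 3, 7, 11))]
    d <- random_surv(n, seed = s)
    res <- find_optimal_cutpoint(d$scores, d$time, d$event)
    orac <- oracle_cutpoint(d$scores, d$time, d$event)
    expect_equal(res$cutoff, orac$cut)
    expect_equal(res$statistic, orac$stat, tolerance = 1e-8)
    expect_gte(min(res$group_sizes), 0.1 * n)
  }
  expect_error(find_optimal_cutpoint(rep(1, 30), rexp(30), rep(1, 30)), "equal")
})

test_that("cut-point search separates two planted risk clusters", {
  set.seed(10)
  n <- 200
  grp <- rep(c(-2, 2), each = n / 2)
  time <- 5 * (-log(runif(n)) * exp(-log(3) * (grp > 0)))
  res <- find_optimal_cutpoint(grp + rnorm(n, 0, 0.1), time, rep(1L, n))
  expect_gt(res$cutoff, -2)
  expect_lt(res$cutoff, 2)
})

test_that("the naive p-value at the selected cut-point is anti-conservative under the null", {
  rej <- vapply(1:200, function(s) {
    d <- random_surv(60, seed = 1000 + s, cens = 0.2)
    find_optimal_cutpoint(d$scores, d$time, d$event)$naive_p < 0.05
  }, logical(1))
  # selection inflates the type-I error well above the nominal 5%
  expect_gt(mean(rej), 0.05)
})

test_that("signature stratification follows the boundary convention and direction", {
  lab <- stratify_by_signature(c(-2, -1.117, -1, 0), cutoff = -1.117)
  expect_equal(as.character(lab), c("good-TTP", "good-TTP", "poor-TTP", "poor-TTP"))
  # permuting patients permutes labels consistently
  sc <- rnorm(20)
  p <- sample(20)
  expect_identical(stratify_by_signature(sc, 0)[p],
                   stratify_by_signature(sc[p], 0))
})
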