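test_that("Kaplan-Meier / log-rank recovers planted group structure", {
  # identical duplicated groups: zero log-rank statistic
  set.seed(1)
  t0 <- rexp(40, 0.2); e0 <- rep(1L, 40)
  km0 <- km_logrank(rep(c("a", "b"), each = 40), c(t0, t0), c(e0, e0))
  expect_lt(km0$logrank_chisq, 1e-10)

  # planted HR = 2.57 recovered at n = 1000
  set.seed(2)
  g <- rep(0:1, each = 500)
  tt <- 5 * (-log(runif(1000)) * exp(-log(2.57) * g))
  km1 <- km_logrank(factor(g), tt, rep(1L, 1000))
  expect_gt(km1$hr_table$hr, 2.2)
  expect_lt(km1$hr_table$hr, 3.0)
  expect_true(km1$hr_table$lower < 2.57 && 2.57 < km1$hr_table$upper)

  # exponential median within 5% of s * ln 2 at n = 5000
  set.seed(3)
  km2 <- km_logrank(factor(rep(c("x", "y"), each = 2500)),
                    rexp(5000, 1 / 8), rep(1L, 5000))
  expect_lt(abs(km2$medians[["x"]] - 8 * log(2)) / (8 * log(2)), 0.05)

  expect_error(km_logrank(factor(rep("a", 10)), rexp(10), rep(1, 10)), "groups")
})

test_that("the concordance index matches its defining pair enumeration", {
  expect_equal(c_index(c(3, 2, 1), c(1, 2, 3), c(1, 1, 1))$c_index, 1.0)
  expect_equal(c_index(rep(1, 10), rexp(10) + 0.1, rep(1, 10))$c_index, 0.5)
  for (s in 1:10) {
    d <- random_surv(30, seed = 200 + s)
    d$time <- round(d$time)  # force ties in time too
    expect_equal(c_index(d$scores, d$time, d$event)$c_index,
                 oracle_c_index(d$scores, d$time, d$event))
  }
  expect_error(c_index(1:3, c(5, 5, 5), c(0, 0, 0)), "comparable")
})

test_that("the concordance index agrees with survival::concordance on untied data", {
  set.seed(9)
  n <- 80
  tt <- rexp(n); sc <- rnorm(n); ev <- as.integer(runif(n) > 0.3)
  ours <- c_index(sc, tt, ev)$c_index
  ref <- survival::concordance(survival::Surv(tt, ev) ~ sc, reverse = TRUE)$concordance
  expect_equal(ours, ref, tolerance = 1e-12)
})

test_that("the concordance index is invariant to monotone score transforms and its bootstrap is seeded", {
  d <- random_surv(60, seed = 5)
  a <- c_index(d$scores, d$time, d$event, ci = TRUE, n_boot = 200, seed = 7)
  b <- c_index(exp(d$scores), d$time, d$event, ci = TRUE, n_boot = 200, seed = 7)
  expect_equal(a$c_index, b$c_index)
  expect_equal(a$lower, b$lower)
  a2 <- c_index(d$scores, d$time, d$event, ci = TRUE, n_boot = 200, seed = 7)
  expect_identical(a, a2)
  expect_true(a$lower <= a$c_index && a$c_index <= a$upper)
})

test_that("NRI and IDI match the hand-computed six-patient fixture and vanish for identical models", {
  time <- c(2, 3, 8, 9, 4, 10)
  event <- rep(1L, 6)
  new <- c(0.9, 0.8, 0.3, 0.2, 0.6, 0.1)
  old <- c(0.7, 0.85, 0.4, 0.3, 0.5, 0.2)
  r <- nri_idi(new, old, time, event, horizon = 6, n_boot = 200, seed = 1)
  expect_equal(r$nri, 4 / 3, tolerance = 1e-12)
  expect_equal(r$idi, 0.5666667 - 0.3833333, tolerance = 1e-6)

  r0 <- nri_idi(new, new, time, event, horizon = 6, n_boot = 100, seed = 1)
  expect_equal(r0$nri, 0)
  expect_equal(r0$idi, 0)

  expect_error(nri_idi(new, old, time, event, horizon = 99), "horizon")
})

test_that("adding pure noise to a model keeps the NRI centred at zero", {
  base <- random_surv(120, seed = 11, cens = 0.2)
  risk <- stats::plogis(base$scores)
  vals <- vapply(1:100, function(s) {
    set.seed(3000 + s)
    noisy <- stats::plogis(base$scores + rnorm(120, 0, 0.5))
    nri_idi(noisy, risk, base$time, base$event, horizon = 3,
            n_boot = 0, seed = 1)$nri
  }, numeric(1))
  expect_lt(abs(mean(vals)), 0.1)
})

test_that("net benefit reproduces the defining formula and its reference curves", {
  # 100 patients, 20 TP, 10 FP at a fixed policy
  outcome <- rep(c(1L, 0L), c(25, 75))
  flag <- c(rep(TRUE, 20), rep(FALSE, 5), rep(TRUE, 10), rep(FALSE, 65))
  nb <- net_benefit(flag, outcome, thresholds = 0.25)
  expect_equal(nb$nb, 0.2 - 0.1 * (0.25 / 0.75), tolerance = 1e-12)
  expect_equal(nb$nb_none, 0)

  # Pt -> 0 limit equals TP/n
  nb0 <- net_benefit(flag, outcome, thresholds = 1e-6)
  expect_equal(nb0$nb, 0.2, tolerance = 1e-5)

  # treat-all identity on random data
  set.seed(12)
  o <- rbinom(200, 1, 0.3)
  p <- runif(200)
  grid <- seq(0.05, 0.6, by = 0.05)
  nb2 <- net_benefit(p, o, grid)
  prev <- mean(o)
  expect_equal(nb2$nb_all, prev - (1 - prev) * grid / (1 - grid), tolerance = 1e-12)
  expect_true(all(nb2$nb <= prev + 1e-12))
  # thresholds at 1 are excluded
  expect_error(net_benefit(p, o, thresholds = 1), "empty")
})

test_that("clinical impact curves behave for perfect and degenerate predictors", {
  outcome <- rep(c(1L, 0L), c(30, 70))
  perfect <- as.numeric(outcome)
  ci <- clinical_impact(perfect, outcome, thresholds = c(0.1, 0.2), n_boot = 50)
  expect_equal(ci$n_high, ci$n_high_event)
  none <- rep(0, 100)
  ci0 <- clinical_impact(none, outcome, thresholds = c(0.5), n_boot = 50)
  expect_equal(ci0$n_high, 0)

  # bootstrap CI width grows as n shrinks
  width <- vapply(c(400, 100, 25), function(n) {
    set.seed(5)
    o <- rbinom(n, 1, 0.3)
    p <- stats::plogis(rnorm(n) + o)
    x <- clinical_impact(p, o, thresholds = 0.3, n_boot = 200, seed = 2)
    x$n_high_upper - x$n_high_lower
  }, numeric(1))
  expect_true(width[1] < width[2] && width[2] < width[3])
})

test_that("a well-specified model is calibrated and a negated one is not", {
  set.seed(13)
  n <- 2000
  x <- rnorm(n)
  tt <- 6 * (-log(runif(n)) * exp(-0.8 * x))
  ev <- rep(1L, n)
  h <- 4
  pred <- exp(-(h / 6) * exp(0.8 * x))   # true exponential-PH survival
  cal <- calibration(pred, tt, ev, horizon = h, bins = 5)
  expect_lt(max(abs(cal$predicted - cal$observed)), 0.05)

  bad <- exp(-(h / 6) * exp(-0.8 * x))   # negated linear predictor
  cal2 <- calibration(bad, tt, ev, horizon = h, bins = 5)
  expect_gt(max(abs(cal2$predicted - cal2$observed)), 0.15)

  cal1 <- calibration(pred, tt, ev, horizon = h, bins = 1)
  km <- survival::survfit(survival::Surv(tt, ev) ~ 1)
  expect_equal(cal1$observed, summary(km, times = h)$surv)
})

test_that("the Kruskal-Wallis balance check is calibrated and powered", {
  strata <- factor(rep(c("low", "mid", "high"), each = 30))
  rej <- vapply(1:500, function(s) {
    set.seed(s)
    kruskal_wallis_balance(data.frame(x = rnorm(90)), strata)$p < 0.05
  }, logical(1))
  expect_lt(abs(mean(rej) - 0.05), 0.03)

  set.seed(1)
  shifted <- c(rnorm(30), rnorm(30), rnorm(30) + 3)
  expect_lt(kruskal_wallis_balance(data.frame(x = shifted), strata)$p, 0.01)

  # two strata: agrees with the rank-sum test
  set.seed(2)
  x <- rnorm(60); g2 <- factor(rep(c("a", "b"), each = 30))
  p_kw <- kruskal_wallis_balance(data.frame(x = x), g2)$p
  p_ks <- kruskal.test(x, g2)$p.value
  expect_equal(p_kw, p_ks)
  expect_equal(kruskal_wallis_balance(data.frame(c_ = rep(1, 60)), g2)$p, 1)
})

test_that("stratum risk mapping reproduces per-stratum Kaplan-Meier event fractions", {
  set.seed(14)
  g <- factor(rep(c("low", "high"), each = 50))
  tt <- ifelse(g == "high", rexp(100, 1 / 3), rexp(100, 1 / 9))
  p <- stratum_event_probability(g, tt, rep(1L, 100), horizon = 6)
  expect_length(unique(p), 2)
  expect_gt(mean(p[g == "high"]), mean(p[g == "low"]))
  expect_true(all(p >= 0 & p <= 1))
})
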