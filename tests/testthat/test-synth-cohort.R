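test_that("phantom generation is deterministic and honours the zero-noise limit", {
  p1 <- generate_tumor_phantom(texture_params(), shape = c(12, 12, 12), seed = 42)
  p2 <- generate_tumor_phantom(texture_params(), shape = c(12, 12, 12), seed = 42)
  expect_identical(p1$volume, p2$volume)
  expect_identical(p1$mask, p2$mask)
  expect_true(any(p1$mask))
  expect_identical(dim(p1$mask), dim(p1$volume))

  p0 <- generate_tumor_phantom(texture_params(noise_sd = 0),
                               shape = c(12, 12, 12), seed = 1)
  expect_equal(diff(range(p0$volume[p0$mask])), 0)
  expect_equal(unique(p0$volume[p0$mask]), p0$params$mean_intensity)

  expect_error(generate_tumor_phantom(texture_params(), shape = c(4, 12, 12)),
               "shape")
})

test_that("longer correlation length raises the lag-1 autocorrelation", {
  lag1 <- function(len, seed) {
    p <- generate_tumor_phantom(texture_params(correlation_length = len),
                                shape = c(20, 20, 20), seed = seed)
    v <- p$volume
    a <- v[1:19, , ][p$mask[1:19, , ] & p$mask[2:20, , ]]
    b <- v[2:20, , ][p$mask[1:19, , ] & p$mask[2:20, , ]]
    cor(a, b)
  }
  for (s in 1:3) expect_gt(lag1(8, s), lag1(1, s))
})

test_that("endpoint simulation matches the exponential closed form and recovers a planted HR", {
  s <- 5
  ep <- simulate_endpoints(rep(0, 10000), list(shape = 1, scale = s),
                           censor_rate_os = 0, seed = 3)
  expect_lt(abs(median(ep$ttp_months) - s * log(2)) / (s * log(2)), 0.03)
  expect_true(all(ep$os_event == 1))
  expect_true(all(ep$ttp_months > 0))
  expect_true(all(ep$os_months >= ep$ttp_months))

  # two groups at log-HR = log(2.45): Cox recovery at n = 2000
  g <- rep(0:1, each = 1000)
  ep2 <- simulate_endpoints(log(2.45) * g, list(shape = 1, scale = s),
                            censor_rate_os = 0, seed = 4)
  fit <- survival::coxph(survival::Surv(ep2$ttp_months, ep2$ttp_event) ~ g)
  expect_gt(exp(coef(fit)), 2.0)
  expect_lt(exp(coef(fit)), 3.0)

  expect_error(simulate_endpoints(0, list(shape = 1, scale = 1), 1), "censor")
})

test_that("planted log-hazard ratios are recovered within 3 SE at n = 2000", {
  for (beta in c(0, 0.5, 1.0)) {
    g <- rep(0:1, each = 1000)
    ep <- simulate_endpoints(beta * g, list(shape = 1.2, scale = 6),
                             censor_rate_os = 0, seed = 100 + round(10 * beta))
    fit <- survival::coxph(survival::Surv(ep$ttp_months, ep$ttp_event) ~ g)
    se <- sqrt(fit$var[1, 1])
    expect_lt(abs(coef(fit) - beta), 3 * se)
  }
})

test_that("OS censoring rate is approximately the configured fraction", {
  ep <- simulate_endpoints(rep(0, 500), list(shape = 1, scale = 5),
                           censor_rate_os = 0.2, seed = 9)
  expect_lt(abs(mean(ep$os_event == 0) - 0.2), 0.03)
  # censored records sit at the administrative horizon
  tau <- max(ep$os_months[ep$os_event == 0])
  expect_true(all(ep$os_months[ep$os_event == 0] == tau))
  expect_true(all(ep$os_months[ep$os_event == 1] <= tau))
})

test_that("default cohort has the study arm sizes and response margins", {
  cc <- cohort_config(include_images = FALSE, seed = 7)
  x <- generate_cohort(cc)
  co <- x$cohort
  expect_equal(sum(co$arm == "chemo"), 96)
  expect_equal(sum(co$arm == "tki"), 14)
  expect_equal(unname(table(co$response)[c("PR", "SD", "PD")]),
               c(27L, 56L, 13L), ignore_attr = TRUE)
  expect_true(all(is.na(co$response[co$arm == "tki"])))
  expect_true(all(clinical_variables() %in% colnames(co)))
  expect_length(clinical_variables(), 24)
  expect_true(all(co$ttp_months > 0))
  expect_true(all(co$ttp_event %in% 0:1))
  expect_true(all(co$os_event %in% 0:1))
  obs <- co$ttp_event == 1 & co$os_event == 1
  expect_true(all(co$ttp_months[obs] <= co$os_months[obs]))
})

test_that("cohort generation and CSV export are reproducible from the seed", {
  cc <- cohort_config(n_chemo = 20, n_tki = 4, include_images = FALSE, seed = 33)
  x1 <- generate_cohort(cc)
  x2 <- generate_cohort(cc)
  expect_identical(x1$cohort, x2$cohort)
  d1 <- file.path(tempdir(), "coh1"); d2 <- file.path(tempdir(), "coh2")
  write_cohort(x1, d1); write_cohort(x2, d2)
  expect_identical(readLines(file.path(d1, "cohort.csv")),
                   readLines(file.path(d2, "cohort.csv")))
})

test_that("null hazard coefficients give calibrated log-rank rejection across replicates", {
  cc0 <- cohort_config(n_chemo = 60, n_tki = 0, include_images = FALSE,
                       hazard_coefs = list(beta_signature = 0, beta_ast = 0))
  rej <- vapply(1:200, function(s) {
    cc0$seed <- s
    co <- generate_cohort(cc0)$cohort
    if (length(unique(co$latent_risk)) < 2) return(NA)
    sd_ <- survival::survdiff(survival::Surv(co$ttp_months, co$ttp_event) ~
                                co$latent_risk)
    stats::pchisq(sd_$chisq, 1, lower.tail = FALSE) < 0.05
  }, logical(1))
  expect_lt(abs(mean(rej, na.rm = TRUE) - 0.05), 0.045)
})

test_that("phantom NIfTI round-trips through RNifti with its spacing", {
  p <- generate_tumor_phantom(texture_params(), shape = c(10, 10, 10), seed = 2)
  vp <- tempfile(fileext = ".nii.gz"); mp <- tempfile(fileext = ".nii.gz")
  write_phantom_nifti(p, vp, mp)
  v <- RNifti::readNifti(vp)
  expect_equal(as.array(v), p$volume, ignore_attr = TRUE, tolerance = 1e-6)
  expect_equal(unname(RNifti::pixdim(v)), p$voxel_spacing)
  m <- as.array(RNifti::readNifti(mp)) > 0
  expect_equal(unname(sum(m)), sum(p$mask))
})
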