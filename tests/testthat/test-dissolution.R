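test_that("noiseless Weibull and Hill parameters are recovered to 4 decimals", {
  tt <- diss_times()
  pw <- dissolution_profile("W", tt, 1 - exp(-(tt / 6)^1.2))
  fw <- fit_dissolution(pw, "weibull")
  expect_equal(fw$mdt, 6, tolerance = 1e-5)
  expect_equal(fw$b, 1.2, tolerance = 1e-5)

  ph <- dissolution_profile("H", tt, tt^1.4 / (5^1.4 + tt^1.4))
  fh <- fit_dissolution(ph, "hill")
  expect_equal(fh$mdt, 5, tolerance = 1e-5)
  expect_equal(fh$b, 1.4, tolerance = 1e-5)
})

test_that("characteristic release points: Hill half release and Weibull 63.2% at MDT", {
  f_hill <- fit_dissolution(
    dissolution_profile("H", diss_times(),
                        diss_times()^1.4 / (5^1.4 + diss_times()^1.4)),
    "hill")
  expect_equal(predict(f_hill, f_hill$mdt), 0.5, tolerance = 1e-8)
  f_wei <- make_weibull_fit(6, 1.2)
  expect_equal(predict(f_wei, 6), 1 - exp(-1), tolerance = 1e-12)
})

test_that("AIC model selection identifies the generating family", {
  tt <- diss_times()
  set.seed(101)
  n_wei <- n_hill <- 0L
  for (r in 1:100) {
    yw <- pmin(pmax(1 - exp(-(tt / 6)^1.2) + rnorm(11, 0, 0.005), 0), 1.05)
    yw[1] <- 0
    fw <- fit_dissolution(dissolution_profile("W", tt, yw), "auto")
    if (fw$model == "weibull") n_wei <- n_wei + 1L
    yh <- pmin(pmax(tt^1.4 / (5^1.4 + tt^1.4) + rnorm(11, 0, 0.005), 0), 1.05)
    yh[1] <- 0
    fh <- fit_dissolution(dissolution_profile("H", tt, yh), "auto")
    if (fh$model == "hill") n_hill <- n_hill + 1L
  }
  expect_gte(n_wei, 95L)
  expect_gte(n_hill, 95L)
})

test_that("the selected model never has the larger AIC and curves are monotone", {
  tt <- diss_times()
  set.seed(7)
  for (r in 1:5) {
    y <- pmin(pmax(1 - exp(-(tt / (4 + r))^1.1) + rnorm(11, 0, 0.01), 0), 1.05)
    y[1] <- 0
    fit <- fit_dissolution(dissolution_profile("X", tt, y), "auto")
    expect_lte(fit$aic, fit$aic_other)
    dense <- predict(fit, seq(0, 48, length.out = 400))
    expect_true(all(diff(dense) >= -1e-12))
    expect_true(all(dense <= fit$finf + 1e-9))
  }
})

test_that("replicate profiles are averaged before fitting", {
  tt <- diss_times()
  y <- 1 - exp(-(tt / 6)^1.2)
  r1 <- dissolution_profile("X", tt, pmin(y + 0.01, 1.05), replicate_id = "1")
  r1$fraction_dissolved[1] <- 0
  r2 <- dissolution_profile("X", tt, pmax(y - 0.01, 0), replicate_id = "2")
  fit <- fit_dissolution(list(r1, r2), "weibull")
  single <- fit_dissolution(dissolution_profile("X", tt,
    (r1$fraction_dissolved + r2$fraction_dissolved) / 2), "weibull")
  expect_equal(fit$mdt, single$mdt, tolerance = 1e-8)
  expect_error(fit_dissolution(list(r1, dissolution_profile("Y", tt, y))),
               "different formulations")
})

test_that("f2 similarity matches its closed forms", {
  tt <- diss_times()
  y <- c(0, 12, 20, 30, 40, 48, 55, 62, 70, 76, 82) / 100
  ref <- dissolution_profile("R", tt, y)
  expect_equal(f2_similarity(ref, ref), 100)

  # uniform 10-percent and 2-percent offsets (reference stays below 85%)
  test10 <- dissolution_profile("T", tt, c(0, y[-1] - 0.10))
  expect_equal(f2_similarity(ref, test10), 50 * log10(100 / sqrt(101)),
               tolerance = 1e-10)
  test2 <- dissolution_profile("T", tt, c(0, y[-1] - 0.02))
  expect_equal(f2_similarity(ref, test2), 50 * log10(100 / sqrt(5)),
               tolerance = 1e-10)
})

test_that("f2 ignores points more than one past 85% reference dissolution", {
  tt <- c(0, 1, 2, 4, 6, 8, 10)
  yref <- c(0, .30, .55, .80, .90, .95, .99)
  ytest1 <- c(0, .25, .50, .75, .85, .90, .94)
  ytest2 <- ytest1
  ytest2[6:7] <- c(0.40, 0.20)  # wildly different only beyond the cutoff
  ytest2 <- pmax(ytest2, 0)
  r <- dissolution_profile("R", tt, yref)
  f1 <- f2_similarity(r, dissolution_profile("T", tt, ytest1))
  # reference exceeds 85% at 6 h; points after 8 h (cutoff + 1) are ignored,
  # so corrupting them cannot change f2 -- construct monotone variant
  ytest3 <- ytest1
  ytest3[7] <- 0.999
  f3 <- f2_similarity(r, dissolution_profile("T", tt, ytest3))
  expect_equal(f1, f3)
  expect_error(f2_similarity(
    dissolution_profile("R", c(0, 1, 2), c(0, .9, .95)),
    dissolution_profile("T", c(0, 1, 2), c(0, .9, .95))), "3 usable")
})

test_that("f2 is invariant to a common offset and decreasing in the gap", {
  tt <- diss_times()
  y <- c(0, 5, 10, 20, 30, 40, 48, 55, 65, 72, 80) / 100
  ref <- dissolution_profile("R", tt, y)
  shifted_ref <- ref; shifted_test <- ref
  gaps <- seq(0.02, 0.12, by = 0.02)
  f2s <- vapply(gaps, function(g) {
    te <- ref
    te$fraction_dissolved[-1] <- y[-1] - g
    f2_similarity(ref, te)
  }, numeric(1))
  expect_true(all(diff(f2s) < 0))
  # adding the same constant to both leaves f2 unchanged (both references
  # stay below the 85% truncation threshold)
  a <- ref; b <- ref
  a$fraction_dissolved[-1] <- y[-1] + 0.02
  b$fraction_dissolved[-1] <- y[-1] + 0.02 - 0.04
  plain <- ref
  plain$fraction_dissolved[-1] <- y[-1] - 0.04
  expect_equal(f2_similarity(a, b), f2_similarity(ref, plain))
})
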