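test_that("deconvolution inverts the forward convolution exactly for in-class inputs", {
  tt <- study_times()
  u <- make_uir(A = c(120, 40), alpha = c(0.8, 0.06), ka = 3, dose = 24)
  # piecewise-linear input rate (the default basis): ramp up, plateau, off
  rates <- c(0, 2, 4, 4, 3, 2, 1.5, 1, 0.6, 0.3, 0.15, 0.08, 0.02,
             0, 0, 0, 0)
  amounts <- ivivcr:::cum_from_rates(tt, rates)
  conc <- as.vector(ivivcr:::conv_matrix_linear(u, tt, tt[-1]) %*% rates)
  er <- pk_profile("S1", 2, "C", 30, tt, c(0, conc), lloq = 0)
  dec <- deconvolve(er, u)
  expect_equal(dec$fa, amounts / 30, tolerance = 1e-8)
  # convolve back: round trip closes to solver precision
  back <- convolve_predict(dec, u, 30, tt)
  expect_equal(back$concentrations[-1], conc, tolerance = 1e-6)
})

test_that("the step basis round-trips a piecewise-constant ramp exactly", {
  tt <- study_times()
  u <- make_uir(A = 80, alpha = 0.1, ka = 1.5, dose = 24)
  fa_true <- pmin(tt / 12, 1)
  fa_obj <- make_fa(tt, fa_true, formulation = "C", dose = 30)
  fa_obj$amounts <- 30 * diff(fa_true)
  fa_obj$basis <- "step"
  cp <- convolve_predict(fa_obj, u, 30, tt)
  er <- pk_profile("S1", 2, "C", 30, tt, cp$concentrations, lloq = 0)
  dec <- deconvolve(er, u, basis = "step")
  expect_equal(dec$fa, fa_true, tolerance = 1e-9)
  back <- convolve_predict(dec, u, 30, tt)
  expect_equal(back$concentrations, cp$concentrations, tolerance = 1e-8)
})

test_that("deconvolving the scaled UIR itself returns an immediate unit input", {
  tt <- study_times()
  u <- make_uir(A = c(120, 40), alpha = c(0.8, 0.06), ka = 3, dose = 24)
  conc <- 30 * uir_eval(u, tt)
  er <- pk_profile("S1", 2, "C", 30, tt, conc, lloq = 0)
  dec <- deconvolve(er, u)
  # the bolus is recovered within the first two grid cells
  expect_gt(dec$fa[3], 0.95)
  expect_lt(abs(dec$fa[length(dec$fa)] - 1), 0.05)
  dec_step <- deconvolve(er, u, basis = "step")
  expect_gt(dec_step$fa[2], 0.9)
})

test_that("deconvolution is equivariant to a common dose and concentration scale", {
  tt <- study_times()
  u <- make_uir(A = c(120, 40), alpha = c(0.8, 0.06), ka = 3, dose = 24)
  rates <- c(0, 1, 3, 4, 3.5, 2.5, 1.8, 1.2, 0.7, 0.35, 0.2, 0.1, 0.03,
             0, 0, 0, 0)
  conc <- as.vector(ivivcr:::conv_matrix_linear(u, tt, tt[-1]) %*% rates)
  er1 <- pk_profile("S1", 2, "C", 30, tt, c(0, conc), lloq = 0)
  er2 <- pk_profile("S1", 2, "C", 60, tt, c(0, 2 * conc), lloq = 0)
  expect_equal(deconvolve(er2, u)$fa, deconvolve(er1, u)$fa,
               tolerance = 1e-10)
})

test_that("recovered fa is nondecreasing, starts at zero, and guards apply", {
  ds <- simulate_study(study_spec(n_subjects = 2), seed = 17)
  irs <- dataset_profiles(ds, regimen = "IR")
  u <- suppressWarnings(fit_uir(irs[[1]]))
  er <- dataset_profiles(ds, regimen = "C",
                         subject = irs[[1]]$subject_id)[[1]]
  dec <- deconvolve(er, u)
  expect_equal(dec$fa[1], 0)
  expect_true(all(diff(dec$fa) >= -1e-12))
  # mismatched subjects are rejected
  other <- dataset_profiles(ds, regimen = "C",
                            subject = irs[[2]]$subject_id)[[1]]
  expect_error(deconvolve(other, u), "different subjects")
  # a grid not covering the observations is rejected
  expect_error(deconvolve(er, u, grid = c(0, 1, 2, 4)), "span")
  # near-duplicate grid nodes make the system ill-conditioned
  bad_grid <- sort(c(er$times[er$times > 0], 24 - 1e-10, 24 + 1e-10, 0))
  expect_error(deconvolve(er, u, grid = bad_grid), "ill-conditioned")
})

test_that("mean absorption profile averages pointwise and checks inputs", {
  a <- make_fa(c(0, 1, 2), c(0, 0.5, 1.0), formulation = "C")
  b <- make_fa(c(0, 1, 2), c(0, 0.3, 0.9), formulation = "C", subject = "S2")
  m <- mean_absorption_profile(list(a, b))
  expect_equal(m$fa, c(0, 0.4, 0.95))
  expect_identical(mean_absorption_profile(list(a, a))$fa, a$fa)
  d <- make_fa(c(0, 1, 2), c(0, 0.2, 0.8), formulation = "D")
  expect_error(mean_absorption_profile(list(a, d)), "mix formulations")
})

test_that("two-stage generator input yields a biphasic deconvolved profile", {
  sp <- study_spec(n_subjects = 3, absorption = "two_stage",
                   residual_cv = 0.05)
  ds <- simulate_study(sp, seed = 2)
  fit <- suppressWarnings(ivivc(ds, control = ivivc_control(refine = FALSE)))
  fm <- fit$fa_mean[["C"]]
  rate_early <- (fm$fa[fm$times == 4] - fm$fa[fm$times == 1]) / 3
  rate_late <- (fm$fa[fm$times == 10] - fm$fa[fm$times == 6]) / 4
  expect_gt(rate_early, 2 * rate_late)  # change point at 4.5 h
})

test_that("convolution prediction scales the UIR and handles edge inputs", {
  tt <- study_times()
  u <- make_uir(A = 24, alpha = 0.1, ka = 2, dose = 24)  # UIR = 1*exp(-0.1t)
  # near-instantaneous complete input reproduces the scaled kernel
  fa_bolus <- make_fa(c(0, 1e-6, tt[-1]), c(0, 1, rep(1, 16)))
  cp <- convolve_predict(fa_bolus, u, 30, tt)
  expect_equal(cp$concentrations[-1], 30 * exp(-0.1 * tt[-1]),
               tolerance = 1e-4)
  # zero input gives a zero profile
  fa0 <- make_fa(tt, rep(0, 17))
  expect_true(all(convolve_predict(fa0, u, 30, tt)$concentrations == 0))
  # beyond the fa grid the input is held at plateau: pure washout
  fa_short <- make_fa(c(0, 2, 4), c(0, 0.6, 1), dose = 30)
  fa_short$dose_mg <- NA_real_
  cp2 <- convolve_predict(fa_short, u, 30, c(0, 2, 4, 8, 16, 32))
  tail_conc <- cp2$concentrations[4:6]
  expect_true(all(diff(tail_conc) < 0))
  expect_equal(tail_conc[3] / tail_conc[2], exp(-0.1 * 16), tolerance = 1e-6)
  expect_error(convolve_predict(make_fa(c(0, 1, 2), c(0, .5, .4)), u, 30, tt),
               "nondecreasing")
})
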