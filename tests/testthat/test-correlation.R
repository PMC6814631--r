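test_that("the Emax time map reproduces its closed-form values and clamps", {
  m <- c(11.6, 2.66, 3.49)
  expect_equal(map_time(m, 2), 11.6 * 2 / 4.66 - 3.49, tolerance = 1e-12)
  expect_equal(map_time(m, 2), 1.488541, tolerance = 1e-6)
  expect_equal(map_time(m, 1e9), 11.6 - 3.49, tolerance = 1e-5)
  root <- 2.66 * 3.49 / (11.6 - 3.49)
  expect_equal(map_time(m, root), 0)
  expect_equal(map_time(m, root / 2), 0)  # clamped below the onset
  expect_error(map_time(m, -1), "nonnegative")
  # nondecreasing on a dense grid
  tv <- seq(0, 80, length.out = 2000)
  expect_true(all(diff(map_time(m, tv)) >= 0))
})

test_that("a noiseless self-consistent fixture is recovered exactly", {
  dfit <- make_weibull_fit(6.73, 1.2, "C")
  grid <- study_times()
  truth <- c(11.6, 2.66, 3.49)
  fa <- make_fa(grid, predict(dfit, map_time(truth, grid)), formulation = "C")
  expect_warning(fit <- fit_emax_timescale(list(C = fa), list(C = dfit)),
                 "single formulation")
  expect_lt(fit$sse, 1e-10)
  expect_equal(unname(coef(fit)), truth, tolerance = 1e-4)
})

test_that("the fit converges to one optimum from both conventional start sets", {
  dfits <- list(A = make_weibull_fit(4.04, 1.2, "A"),
                C = make_weibull_fit(6.73, 1.2, "C"),
                D = make_weibull_fit(10.76, 1.2, "D"))
  grid <- study_times()
  truth <- c(11.6, 2.66, 3.49)
  fas <- lapply(names(dfits), function(f)
    make_fa(grid, predict(dfits[[f]], map_time(truth, grid)), formulation = f))
  names(fas) <- names(dfits)
  f1 <- fit_emax_timescale(fas, dfits, starts = rbind(c(15, 5, 8)))
  f2 <- fit_emax_timescale(fas, dfits, starts = rbind(c(16, 6, 10)))
  expect_equal(coef(f1), coef(f2), tolerance = 1e-5)
  expect_equal(unname(coef(f1)), truth, tolerance = 1e-4)
})

test_that("fitting is invariant to the ordering of formulations", {
  fit <- small_fit()
  fa <- fit$fa_mean[c("A", "C", "D")]
  fa <- lapply(fa, ivivcr:::truncate_absorption, t_limit = 24)
  f_fwd <- fit_emax_timescale(fa, fit$dissolution_fits)
  f_rev <- fit_emax_timescale(rev(fa), fit$dissolution_fits)
  expect_equal(coef(f_fwd), coef(f_rev), tolerance = 1e-7)
})

test_that("linear correlation variants recover identity and pure time scaling", {
  dfit <- make_weibull_fit(6, 1.2, "C")
  grid <- study_times()
  fa_id <- make_fa(grid, predict(dfit, grid), formulation = "C")
  f_id <- fit_linear_ivivc(list(C = fa_id), list(C = dfit),
                           variant = "abs-scale+scale+shift")
  expect_equal(f_id$abs_scale, 1, tolerance = 1e-5)
  expect_equal(f_id$time_scale, 1, tolerance = 1e-5)
  expect_equal(f_id$time_shift, 0, tolerance = 1e-4)
  fa_2x <- make_fa(grid, predict(dfit, 2 * grid), formulation = "C")
  f_2x <- fit_linear_ivivc(list(C = fa_2x), list(C = dfit), variant = "scale")
  expect_equal(f_2x$time_scale, 2, tolerance = 1e-5)
})

test_that("predicted fa is zero at time zero and plateaus at the mapped asymptote", {
  dfit <- make_weibull_fit(6.73, 1.2, "C")
  m <- structure(list(A1 = 11.6, A2 = 2.66, B2 = 3.49,
                      se = c(A1 = NA, A2 = NA, B2 = NA), sse = 0,
                      n_obs = 0L, formulations = "C"),
                 class = "timescale_fit")
  fa <- predict_fa(m, dfit, c(0, 1, 2, 6, 24, 1e5))
  expect_equal(fa$fa[1], 0)
  expect_equal(fa$fa[length(fa$fa)], predict(dfit, 11.6 - 3.49),
               tolerance = 1e-3)
  expect_true(all(diff(fa$fa) >= -1e-12))
})

test_that("pooled absorbed-vs-dissolved relation is nearly linear on study-like data", {
  fit <- small_fit()
  pooled <- do.call(rbind, lapply(c("A", "C", "D"), function(f) {
    fm <- fit$fa_mean[[f]]
    keep <- fm$times > 0 & fm$times <= 24
    data.frame(fa = fm$fa[keep],
               fd = predict(fit$dissolution_fits[[f]], fm$times[keep]))
  }))
  r2 <- summary(lm(fa ~ fd, data = pooled))$r.squared
  expect_gte(r2, 0.9)
})

test_that("linear models under-predict Cmax where the true time scale is nonlinear", {
  sp <- study_spec(n_subjects = 2, bsv_cv = 0.1, residual_cv = 0,
                   dissolution_sd = 0)
  ds <- simulate_study(sp, seed = 5)
  f_emax <- suppressWarnings(ivivc(ds))
  f_lin <- suppressWarnings(ivivc(ds, correlation = "linear"))
  cmax_pe <- function(fit) {
    r <- fit$validation$records
    r$pe_pct[r$parameter == "cmax" & r$role == "internal"]
  }
  expect_true(all(cmax_pe(f_lin) < 0))             # systematic under-prediction
  expect_gt(mean(abs(cmax_pe(f_lin))), mean(abs(cmax_pe(f_emax))))
})
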