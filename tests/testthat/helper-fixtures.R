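# shared fixtures; everything is generated in code, nothing is read from disk

study_times <- function() c(0, 0.25, 0.5, 1, 1.5, 2, 3, 4, 6, 8, 10, 12, 16,
                            24, 36, 48, 72)

diss_times <- function() c(0, 1, 2, 4, 6, 8, 10, 12, 16, 20, 24)

# a uir_fit object with known coefficients (bypasses fitting)
make_uir <- function(A, alpha, ka = 3, t_lag = 0, dose = 24, subject = "S1") {
  ord <- order(alpha, decreasing = TRUE)
  structure(list(subject_id = subject, coefficients = A[ord],
                 rates = alpha[ord], n_exp = length(A), ka = ka,
                 t_lag = t_lag, dose_ref = dose, sse = 0, aic = NA_real_,
                 phi = 1 - sum(A / ka) / sum(A / alpha), r_squared = 1),
            class = "uir_fit")
}

# a dissolution_fit object with known Weibull parameters
make_weibull_fit <- function(mdt, b, formulation = "X", finf = 1) {
  structure(list(model = "weibull", formulation_id = formulation,
                 finf = finf, mdt = mdt, b = b, sse = 0, aic = NA_real_,
                 n = 11L),
            class = "dissolution_fit")
}

# an absorption_profile with plain fa values (no rate representation)
make_fa <- function(times, fa, formulation = "X", subject = "S1",
                    dose = 30) {
  structure(list(subject_id = subject, formulation_id = formulation,
                 times = times, fa = fa, dose_mg = dose, basis = NULL,
                 rates = NULL, amounts = NULL, residual_sse = NULL),
            class = "absorption_profile")
}

# Bateman (one-compartment, first-order absorption) IR profile
bateman_profile <- function(A = 80, ka = 1.5, ke = 0.1, dose = 24,
                            subject = "S1", times = study_times(),
                            lloq = 0) {
  tpos <- times[times > 0]
  conc <- c(0, A * (exp(-ke * tpos) - exp(-ka * tpos)))
  pk_profile(subject, 1L, "IR", dose, times, conc, lloq = lloq)
}

# small noisy study fitted once and memoised across tests
.fixture_env <- new.env(parent = emptyenv())

small_fit <- function() {
  if (is.null(.fixture_env$fit)) {
    ds <- simulate_study(study_spec(n_subjects = 4), seed = 11)
    .fixture_env$ds <- ds
    .fixture_env$fit <- suppressWarnings(ivivc(ds))
  }
  .fixture_env$fit
}

small_study <- function() {
  small_fit()
  .fixture_env$ds
}
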