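test_that("dissolution CSV reading converts percent and enforces invariants", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("formulation,time_h,pct_dissolved",
               "X,0,0", "X,1,50", "X,2,100"), path)
  profs <- read_dissolution(path)
  expect_length(profs, 1L)
  expect_equal(profs[[1]]$fraction_dissolved, c(0, 0.5, 1.0))

  # duplicate time within one formulation is a validation error
  writeLines(c("formulation,time_h,pct_dissolved",
               "X,0,0", "X,1,50", "X,1,60", "X,2,100"), path)
  expect_error(read_dissolution(path), "duplicate time")

  # a missing column is a schema error naming the column
  writeLines(c("formulation,hours,pct_dissolved", "X,0,0"), path)
  expect_error(read_dissolution(path), "time_h")

  # the full 11-point in vitro schedule reads into an 11-point profile
  tt <- diss_times()
  y <- round(100 * (1 - exp(-(tt / 6)^1.2)), 3)
  writeLines(c("formulation,time_h,pct_dissolved",
               paste("C", tt, y, sep = ",")), path)
  prof <- read_dissolution(path)[[1]]
  expect_length(prof$times, 11L)
  expect_equal(prof$times, tt)
})

test_that("dissolution profile invariants are enforced at construction", {
  expect_error(dissolution_profile("X", c(0, 2, 1), c(0, .2, .4)),
               "strictly increasing")
  expect_error(dissolution_profile("X", c(1, 2, 3), c(0, .2, .4)),
               "start at 0")
  expect_error(dissolution_profile("X", c(0, 1, 2), c(0.2, .5, .8)),
               "t = 0")
  expect_error(dissolution_profile("X", c(0, 1, 2), c(0, .5, 1.2)),
               "1.05")
})

test_that("concentration reading flags BLQ without dropping values", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("subject,period,regimen,dose_mg,time_h,conc_ng_ml",
               "S1,1,IR,24,0,0", "S1,1,IR,24,1,12", "S1,1,IR,24,2,0.03",
               "S1,2,A,30,0,0", "S1,2,A,30,1,5", "S1,2,A,30,2,4"), path)
  ds <- read_concentrations(path, reference_regimen = "IR", lloq = 0.05)
  expect_length(ds$profiles, 2L)
  ir <- dataset_profiles(ds, regimen = "IR")[[1]]
  # 0.03 < LLOQ 0.05: flagged, numeric value preserved
  expect_true(ir$blq[3])
  expect_identical(ir$concentrations[3], 0.03)
  expect_false(ir$blq[2])
})

test_that("dataset invariants: orphan ER arms and duplicate reference arms", {
  p_ir <- bateman_profile(subject = "S1")
  p_er <- pk_profile("S2", 2, "A", 30, c(0, 1, 2), c(0, 5, 4))
  expect_error(study_dataset(list(p_ir, p_er), reference_regimen = "IR"),
               "S2")
  p_ir2 <- bateman_profile(subject = "S1")
  p_ir2$period <- 2L
  expect_error(study_dataset(list(p_ir, p_ir2), reference_regimen = "IR"),
               "more than once")
})

test_that("a simulated crossover has 20 x 5 profiles and round-trips through CSV", {
  ds <- simulate_study(study_spec(), seed = 4)
  expect_length(ds$profiles, 100L)
  expect_true(all(vapply(ds$profiles, function(p) length(p$times), 1L) == 17L))

  conc_path <- withr::local_tempfile(fileext = ".csv")
  diss_path <- withr::local_tempfile(fileext = ".csv")
  write_study(ds, conc_path, diss_path)
  ds2 <- read_concentrations(conc_path, reference_regimen = "IR",
                             lloq = 0.05,
                             dissolution = read_dissolution(diss_path),
                             internal = ds$internal_formulations,
                             external = ds$external_formulations)
  expect_length(ds2$profiles, 100L)
  key <- function(d) vapply(d$profiles, function(p)
    paste(p$subject_id, p$regimen), character(1))
  ord1 <- order(key(ds)); ord2 <- order(key(ds2))
  for (i in seq_along(ord1)) {
    a <- ds$profiles[[ord1[i]]]; b <- ds2$profiles[[ord2[i]]]
    expect_equal(b$concentrations, a$concentrations, tolerance = 0)
    expect_equal(b$blq, a$blq)
  }
  d1 <- ds$dissolution[[1]]; d2 <- ds2$dissolution[[1]]
  # the interchange format stores percent; fractions return to within one ulp
  expect_equal(d2$fraction_dissolved, d1$fraction_dissolved,
               tolerance = 1e-15)
})

test_that("validation report files have the contracted layout and are deterministic", {
  fit <- small_fit()
  # internal-only report: 3 parameters x formulations + 3 average rows
  val <- validate_ivivc(small_study(), fit$model, fit$dissolution_fits,
                        fit$uirs, internal = c("A", "C", "D"),
                        external = character(0))
  path <- withr::local_tempfile(fileext = ".csv")
  write_report(val, path)
  tab <- utils::read.csv(path)
  expect_equal(nrow(tab), 3 * 3 + 3)
  expect_named(tab, c("formulation", "parameter", "observed", "predicted",
                      "pe_pct", "criterion", "pass"))
  expect_equal(sum(tab$formulation == "average_internal"), 3L)
  expect_true(file.exists(sub("\\.csv$", ".txt", path)))
  bytes1 <- readBin(path, "raw", file.size(path))
  write_report(val, path)
  expect_identical(readBin(path, "raw", file.size(path)), bytes1)
})
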