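test_that("terminal slope is recovered exactly from mono-exponential data", {
  tt <- 1:8
  prof <- conc_time_profile(tt, 100 * exp(-0.5 * tt), dose = 1, route = "iv_bolus")
  lz <- estimate_lambda_z(prof)
  expect_false(lz$failed)
  expect_equal(lz$lambda_z, 0.5, tolerance = 1e-10)
  expect_gt(lz$r2_adj, 0.999999)
})

test_that("terminal slope of a biexponential profile is recovered at late sampling", {
  truth <- ground_truth_pk("two_compartment",
                           list(cl = 1000, v1 = 1000, q = 500, v2 = 3000),
                           "iv_bolus", dose = 1)
  # independent terminal eigenvalue of the micro-constant rate matrix
  k10 <- 1; k12 <- 0.5; k21 <- 500 / 3000
  beta <- min(abs(eigen(matrix(c(-(k10 + k12), k21, k12, -k21), 2, 2))$values))
  tt <- c(0.25, 0.5, 1, 2, 4, seq(8, 48, by = 4))
  prof <- generate_profile(truth, tt, noise_cv = 0, seed = 1)
  lz <- estimate_lambda_z(prof)
  expect_rel(lz$lambda_z, beta, 0.02)
})

test_that("profiles without a decaying terminal phase flag estimation failure", {
  prof <- conc_time_profile(1:5, c(1, 2, 4, 8, 16), dose = 1, route = "oral")
  lz <- estimate_lambda_z(prof)
  expect_true(lz$failed)
  res <- compute_nca(prof)
  expect_true(res$infinite_auc_flag)
  expect_true(is.na(res$auc_0_inf))
  expect_null(res$cl_total)
})

test_that("NCA recovers one-compartment parameters from noiseless profiles", {
  # iv bolus: Dose 1 mg/kg, V 2000 mL/kg, k 0.5/h -> CL 1000 mL/h/kg
  truth <- ground_truth_pk("one_compartment", list(cl = 1000, v = 2000),
                           "iv_bolus", dose = 1)
  tt <- seq(0.25, 10, by = 0.25)  # dense sampling to 5 half-lives
  res <- compute_nca(generate_profile(truth, tt, noise_cv = 0, seed = 1))
  expect_rel(res$cl_total, 1000, 0.005)
  expect_rel(res$vd_ss, 2000, 0.005)
  expect_rel(res$t_half, log(2) / 0.5, 0.005)
  expect_lt(res$extrapolated_fraction, 1)

  # oral with ka >> k recovers CL/F within 5%
  truth_po <- ground_truth_pk("one_compartment", list(cl = 1000, v = 2000, ka = 15),
                              "oral", dose = 1)
  res_po <- compute_nca(generate_profile(truth_po, c(0.1, 0.25, 0.5, 1, 2, 4, 8, 12, 16),
                                         noise_cv = 0, seed = 1))
  expect_rel(res_po$cl_total, 1000, 0.05)
})

test_that("profiles with fewer than 3 quantifiable points cannot be analysed", {
  prof <- conc_time_profile(1:5, rep(0, 5), dose = 1, route = "iv_bolus")
  expect_error(compute_nca(prof), "3 quantifiable")
})

test_that("adding a later quantifiable timepoint never decreases AUC_0-t", {
  set.seed(42)
  for (rep in 1:20) {
    tt <- sort(runif(8, 0.1, 24))
    cc <- exp(rnorm(8, 3, 1))
    p_full <- conc_time_profile(tt, cc, dose = 1, route = "oral")
    p_trunc <- conc_time_profile(tt[1:7], cc[1:7], dose = 1, route = "oral")
    expect_gte(compute_nca(p_full)$auc_0_t, compute_nca(p_trunc)$auc_0_t)
  }
})

test_that("bioavailability is the dose-normalised AUC ratio", {
  mk <- function(auc_like, route) {
    structure(list(auc_0_inf = auc_like, dose = 1, route = route),
              class = "nca_result")
  }
  # rat: AUC po 355 vs iv 762 at 1 mg/kg
  expect_rel(bioavailability(mk(355, "oral"), mk(762, "iv_bolus")), 0.466, 0.01)
  # dog: 307 vs 664 at equal doses
  expect_rel(bioavailability(mk(307, "oral"), mk(664, "iv_bolus")), 0.462, 0.01)
  expect_equal(bioavailability(mk(500, "oral"), mk(500, "iv_bolus")), 1)
  expect_error(bioavailability(mk(-1, "oral"), mk(500, "iv_bolus")), "finite and positive")
})

test_that("renal clearance is urinary recovery times total clearance", {
  expect_rel(renal_clearance(0.046, 1330), 61.2, 0.005)
  expect_rel(renal_clearance(0.020, 785), 15.7, 0.005)
  expect_equal(renal_clearance(0, 1330), 0)
  expect_error(renal_clearance(1.2, 100), "\\[0, 1\\]")
})
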