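#' Concentration-time profile
#'
#' Container for a single-subject (or mean) concentration-time course after
#' a single dose. Trailing below-LOQ observations are dropped; embedded
#' below-LOQ observations are treated as missing.
#'
#' @param times sampling times (h), strictly increasing, nonnegative.
#' @param concentrations plasma concentrations (ng/mL); values below `lloq`
#'   are flagged as unquantifiable.
#' @param dose administered dose (mg/kg unless `dose_unit = "mg"`).
#' @param route `"iv_bolus"` or `"oral"`.
#' @param lloq lower limit of quantification (ng/mL).
#' @param dose_unit `"mg/kg"` (default) or `"mg"`.
#' @return an object of class `conc_time_profile`.
#' @export
conc_time_profile <- function(times, concentrations, dose,
                              route = c("iv_bolus", "oral"), lloq = 0,
                              dose_unit = c("mg/kg", "mg")) {
  route <- match.arg(route)
  dose_unit <- match.arg(dose_unit)
  stopifnot(length(times) == length(concentrations),
            all(times >= 0), !is.unsorted(times, strictly = TRUE),
            dose >= 0, lloq >= 0)
  quantifiable <- !is.na(concentrations) & concentrations >= lloq &
    concentrations > 0
  structure(list(times = times, concentrations = concentrations,
                 quantifiable = quantifiable, dose = dose, route = route,
                 lloq = lloq, dose_unit = dose_unit),
            class = "conc_time_profile")
}

# quantifiable observations with trailing BLQ dropped and embedded BLQ removed;
# NCA needs at least 3 quantifiable points
.nca_points <- function(profile) {
  q <- profile$quantifiable
  if (sum(q) < 3) stop("NCA requires at least 3 quantifiable points", call. = FALSE)
  last <- max(which(q))
  keep <- which(q[seq_len(last)])
  list(t = profile$times[keep], c = profile$concentrations[keep])
}

#' Terminal slope estimation
#'
#' Fits log-linear regressions to candidate terminal subsets (the latest
#' `k >= 3` quantifiable points, excluding the observed Cmax for oral data)
#' and keeps the subset maximising adjusted R-squared. Returns the terminal
#' rate constant lambda_z, the number of points used and the adjusted
#' R-squared of the winning fit.
#'
#' @param profile a [conc_time_profile()].
#' @return list with `lambda_z` (1/h), `points_used`, `r2_adj`, `intercept`
#'   (log-scale at t = 0), or an object with `failed = TRUE` when no subset
#'   shows positive decay.
#' @export
estimate_lambda_z <- function(profile) {
  pts <- .nca_points(profile)
  i_max <- which.max(pts$c)
  # exclude Cmax itself for oral data (absorption-phase contamination)
  first_ok <- if (profile$route == "oral") i_max + 1L else i_max
  idx <- seq(first_ok, length(pts$t))
  if (length(idx) < 3) return(list(failed = TRUE, reason = "fewer than 3 post-Cmax points"))
  t <- pts$t[idx]; lc <- log(pts$c[idx])
  best <- NULL
  for (k in 3:length(t)) {
    sel <- seq(length(t) - k + 1, length(t))
    fit <- stats::lm.fit(cbind(1, t[sel]), lc[sel])
    slope <- fit$coefficients[2]
    if (!is.finite(slope) || slope >= 0) next
    rss <- sum(fit$residuals^2)
    tss <- sum((lc[sel] - mean(lc[sel]))^2)
    r2 <- if (tss > 0) 1 - rss / tss else 1
    r2_adj <- if (k > 2) 1 - (1 - r2) * (k - 1) / (k - 2) else r2
    if (is.null(best) || r2_adj > best$r2_adj + 1e-12) {
      best <- list(lambda_z = unname(-slope), points_used = k, r2_adj = r2_adj,
                   intercept = unname(fit$coefficients[1]), failed = FALSE)
    }
  }
  if (is.null(best)) return(list(failed = TRUE, reason = "no decaying terminal subset"))
  best
}

# linear-up/log-down trapezoid for one interval; returns c(auc, aumc)
.trapz_seg <- function(t1, t2, c1, c2) {
  dt <- t2 - t1
  if (c2 < c1 && c1 > 0 && c2 > 0) {
    lam <- log(c1 / c2) / dt
    auc <- (c1 - c2) / lam
    aumc <- (t1 * c1 - t2 * c2) / lam + (c1 - c2) / lam^2
  } else {
    auc <- dt * (c1 + c2) / 2
    aumc <- dt * (t1 * c1 + t2 * c2) / 2
  }
  c(auc, aumc)
}

#' Non-compartmental analysis
#'
#' Computes the standard single-dose NCA parameter set: AUC by the
#' linear-up/log-down trapezoid rule, extrapolation to infinity through the
#' terminal slope, Cmax/tmax, clearance, mean residence time and the
#' steady-state and terminal-phase distribution volumes. For iv bolus data
#' the concentration at time zero is back-extrapolated log-linearly from the
#' first two points. Clearances and volumes are body-weight normalised
#' (mL/h/kg, mL/kg) when the dose is mg/kg, absolute (mL/h, mL) when mg;
#' after oral dosing they are apparent (CL/F, Vdz/F).
#'
#' @param profile a [conc_time_profile()].
#' @return an object of class `nca_result`: list with `auc_0_t`, `auc_0_inf`,
#'   `aumc_0_inf`, `lambda_z`, `t_half`, `cmax`, `tmax`, `cl_total`, `vd_ss`
#'   (iv bolus only), `vd_z`, `mrt`, `extrapolated_fraction`, `lambda_z_fit`.
#' @export
compute_nca <- function(profile) {
  pts <- .nca_points(profile)
  t <- pts$t; c <- pts$c
  cmax <- max(c); tmax <- t[which.max(c)]
  if (profile$route == "iv_bolus" && t[1] > 0) {
    # back-extrapolate C0 from the first two points when they decay
    c0 <- if (length(c) >= 2 && c[1] > c[2]) {
      exp(log(c[1]) - t[1] * (log(c[2]) - log(c[1])) / (t[2] - t[1]))
    } else c[1]
    t <- c(0, t); c <- c(c0, c)
  } else if (t[1] > 0) {
    t <- c(0, t); c <- c(0, c)  # oral: zero baseline
  }
  segs <- vapply(seq_len(length(t) - 1),
                 function(i) .trapz_seg(t[i], t[i + 1], c[i], c[i + 1]),
                 numeric(2))
  auc_0_t <- sum(segs[1, ]); aumc_0_t <- sum(segs[2, ])
  lz <- estimate_lambda_z(profile)
  dose_ng_per_ref <- profile$dose * 1e6  # mg -> ng (per kg or absolute)
  res <- list(auc_0_t = auc_0_t, cmax = cmax, tmax = tmax,
              route = profile$route, dose = profile$dose,
              dose_unit = profile$dose_unit, lambda_z_fit = lz)
  if (isTRUE(lz$failed)) {
    res$auc_0_inf <- NA_real_
    res$infinite_auc_flag <- TRUE
    class(res) <- "nca_result"
    return(res)
  }
  clast <- c[length(c)]; tlast <- t[length(t)]
  auc_extra <- clast / lz$lambda_z
  aumc_extra <- clast * tlast / lz$lambda_z + clast / lz$lambda_z^2
  res$lambda_z <- lz$lambda_z
  res$t_half <- log(2) / lz$lambda_z
  res$auc_0_inf <- auc_0_t + auc_extra
  res$aumc_0_inf <- aumc_0_t + aumc_extra
  res$extrapolated_fraction <- auc_extra / res$auc_0_inf
  res$mrt <- res$aumc_0_inf / res$auc_0_inf
  res$cl_total <- dose_ng_per_ref / res$auc_0_inf
  res$vd_z <- res$cl_total / lz$lambda_z
  if (profile$route == "iv_bolus") res$vd_ss <- res$cl_total * res$mrt
  class(res) <- "nca_result"
  res
}

#' Oral bioavailability from dose-normalised AUC ratio
#'
#' @param nca_oral,nca_iv [compute_nca()] results for the oral and iv arms.
#' @return absolute bioavailability F (fraction).
#' @export
bioavailability <- function(nca_oral, nca_iv) {
  if (!is.finite(nca_oral$auc_0_inf) || !is.finite(nca_iv$auc_0_inf) ||
      nca_oral$auc_0_inf <= 0 || nca_iv$auc_0_inf <= 0) {
    stop("bioavailability: both AUC_0-inf must be finite and positive")
  }
  (nca_oral$auc_0_inf / nca_oral$dose) / (nca_iv$auc_0_inf / nca_iv$dose)
}

#' Renal clearance from urinary recovery
#'
#' CL_renal = fraction of the dose excreted unchanged in urine x CL_total.
#'
#' @param fe_urine fraction of dose excreted unchanged in urine, in `[0, 1]`.
#' @param cl_total total clearance (mL/h/kg).
#' @return renal clearance (mL/h/kg).
#' @export
renal_clearance <- function(fe_urine, cl_total) {
  if (fe_urine < 0 || fe_urine > 1) {
    stop("renal_clearance: fe_urine must be in [0, 1]")
  }
  fe_urine * cl_total
}
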