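#' Two-species allometric fit of whole-body clearance
#'
#' Regresses log10 whole-body clearance (mL/h) on log10 body weight (kg)
#' for exactly two species; the intercept at 1 kg is the allometric
#' coefficient `a` and the slope the exponent `b`.
#'
#' @param cl_by_species named numeric, body-weight-normalised clearance
#'   (mL/h/kg) per species.
#' @param bw named numeric, body weight (kg) for the same species.
#' @return list of class `allometric_fit` with `coefficient_a` (mL/h at
#'   1 kg), `coefficient_a_ml_min`, `exponent_b`, `species_used`.
#' @export
fit_two_species_allometry <- function(cl_by_species, bw) {
  sp <- intersect(names(cl_by_species), names(bw))
  if (length(sp) != 2) stop("fit_two_species_allometry: exactly two species required")
  cl_whole <- cl_by_species[sp] * bw[sp]            # mL/h
  if (any(cl_whole <= 0) || any(bw[sp] <= 0)) stop("clearances and weights must be positive")
  if (abs(diff(log10(bw[sp]))) < 1e-12) stop("singular fit: identical body weights")
  b <- diff(log10(cl_whole)) / diff(log10(bw[sp]))
  log_a <- log10(cl_whole[1]) - b * log10(bw[sp][1])
  structure(list(coefficient_a = unname(10^log_a),
                 coefficient_a_ml_min = unname(10^log_a) / 60,
                 exponent_b = unname(b), species_used = sp),
            class = "allometric_fit")
}

#' Human clearance by two-species allometry with a fixed exponent
#'
#' CL_human(mL/h) = a x BW^0.628; returned body-weight normalised
#' (divided by BW). The 0.628 exponent is the published fixed-exponent
#' variant of two-species (rat-dog) simple allometry.
#'
#' @param fit an [fit_two_species_allometry()] result.
#' @param human_bw human body weight (kg).
#' @param fixed_exponent allometric exponent applied at extrapolation.
#' @return predicted human CL_total (mL/h/kg).
#' @export
predict_cl_allometry <- function(fit, human_bw = 70, fixed_exponent = 0.628) {
  stopifnot(human_bw > 0, fit$coefficient_a > 0)
  fit$coefficient_a * human_bw^fixed_exponent / human_bw
}

#' Human clearance by the fu-corrected intercept method (FCIM)
#'
#' CL_human(mL/min) = 33.35 x (a / Rfu)^0.77 with `a` the allometric
#' coefficient in mL/min and Rfu = fu_rat / fu_human; converted to mL/h/kg.
#'
#' @param fit an [fit_two_species_allometry()] result.
#' @param fu_rat,fu_human unbound plasma fractions, in (0, 1].
#' @param human_bw human body weight (kg).
#' @return predicted human CL_total (mL/h/kg).
#' @export
predict_cl_fcim <- function(fit, fu_rat, fu_human, human_bw = 70) {
  stopifnot(fu_rat > 0, fu_rat <= 1, fu_human > 0, fu_human <= 1, human_bw > 0)
  r_fu <- fu_rat / fu_human
  cl_ml_min <- 33.35 * (fit$coefficient_a_ml_min / r_fu)^0.77
  convert_units(cl_ml_min / human_bw, "mL/min/kg", "mL/h/kg")
}

#' Scale microsomal intrinsic clearance to whole-body units
#'
#' clint (uL/min/mg) x MPPGL (mg/g) x liver weight (g/kg) x 60/1000
#' -> mL/h/kg, without unbound-fraction correction.
#'
#' @param clint microsomal intrinsic clearance (uL/min/mg protein).
#' @param physiology a [species_physiology()].
#' @return scaled intrinsic clearance (mL/h/kg).
#' @export
scale_clint <- function(clint, physiology) {
  stopifnot(clint >= 0)
  clint * physiology$mppgl * physiology$liver_weight_per_bw * 60 / 1000
}

#' Human clearance by well-stirred IVIVE
#'
#' Hepatic clearance from the well-stirred liver model in its plasma-based
#' published form, with the microsomal-binding-corrected intrinsic
#' clearance X = CLint_scaled / fu_mic:
#' CL_h = QH * fu * X / (QH + (fu / Rb) * X), plus renal clearance.
#'
#' @param clint_scaled whole-body scaled intrinsic clearance (mL/h/kg),
#'   see [scale_clint()].
#' @param fu plasma unbound fraction (0, 1].
#' @param fu_mic microsomal unbound fraction (0, 1].
#' @param rb blood:plasma ratio.
#' @param qh hepatic blood flow (mL/h/kg).
#' @param cl_renal renal clearance (mL/h/kg).
#' @return predicted CL_total (mL/h/kg).
#' @export
predict_cl_ivive <- function(clint_scaled, fu, fu_mic, rb, qh, cl_renal = 0) {
  stopifnot(fu > 0, fu <= 1, fu_mic > 0, fu_mic <= 1, rb > 0, qh > 0,
            clint_scaled >= 0, cl_renal >= 0)
  x <- clint_scaled / fu_mic
  qh * fu * x / (qh + (fu / rb) * x) + cl_renal
}

#' Renal clearance assuming glomerular filtration only
#'
#' @param fu plasma unbound fraction (0, 1].
#' @param gfr glomerular filtration rate (mL/h/kg).
#' @return renal clearance (mL/h/kg).
#' @export
predict_cl_renal_gfr <- function(fu, gfr) {
  stopifnot(fu > 0, fu <= 1, gfr > 0)
  fu * gfr
}

#' Back-calculate in vivo intrinsic clearance
#'
#' Inverts the well-stirred hepatic term of [predict_cl_ivive()] to recover
#' the unbound intrinsic clearance consistent with an observed in vivo
#' hepatic clearance CL_h = CL_total - CL_renal:
#' X = CL_h * QH / (fu * (QH - CL_h / Rb)).
#'
#' @param cl_total observed total clearance (mL/h/kg).
#' @param cl_renal renal clearance (mL/h/kg).
#' @param fu plasma unbound fraction.
#' @param rb blood:plasma ratio.
#' @param qh hepatic blood flow (mL/h/kg).
#' @return in vivo unbound intrinsic clearance (mL/h/kg).
#' @export
backcalc_in_vivo_clint <- function(cl_total, cl_renal, fu, rb, qh) {
  cl_h <- cl_total - cl_renal
  stopifnot(cl_h >= 0)
  if (cl_h / rb >= qh) {
    stop("backcalc_in_vivo_clint: hepatic clearance at or above the flow limit; inversion infeasible")
  }
  cl_h * qh / (fu * (qh - cl_h / rb))
}

#' Microsomal unbound fraction from lipophilicity
#'
#' Lipophilicity-based prediction of the fraction unbound in a microsomal
#' incubation at protein concentration C (mg/mL), using the quadratic
#' log-binding relation logK = 0.072 logP^2 + 0.067 logP - 1.126 and
#' fu_mic = 1 / (1 + C x 10^logK).
#'
#' @param log_p octanol-water logP (for bases, logP; for acids logD7.4 is
#'   conventionally used and should be supplied by the caller).
#' @param protein_conc microsomal protein concentration in the incubation
#'   (mg/mL).
#' @return predicted fu_mic, in (0, 1].
#' @export
fu_mic_lipophilicity <- function(log_p, protein_conc) {
  stopifnot(protein_conc > 0)
  log_k <- 0.072 * log_p^2 + 0.067 * log_p - 1.126
  1 / (1 + protein_conc * 10^log_k)
}

#' Empirical scaling factor
#'
#' Ratio of the back-calculated in vivo unbound intrinsic clearance to the
#' scaled unbound in vitro intrinsic clearance for one species.
#'
#' @param in_vivo_clint in vivo unbound intrinsic clearance (mL/h/kg),
#'   see [backcalc_in_vivo_clint()].
#' @param in_vitro_clint_unbound scaled, microsomal-binding-corrected in
#'   vitro intrinsic clearance (mL/h/kg).
#' @return unitless scaling factor.
#' @export
empirical_scaling_factor <- function(in_vivo_clint, in_vitro_clint_unbound) {
  stopifnot(in_vivo_clint > 0, in_vitro_clint_unbound > 0)
  in_vivo_clint / in_vitro_clint_unbound
}

#' Average per-species empirical scaling factors
#'
#' @param esf numeric vector of per-species scaling factors.
#' @return their arithmetic mean.
#' @export
average_esf <- function(esf) mean(esf)

#' Fraction metabolised from selective inhibition
#'
#' fm = 1 - CLint(with inhibitor) / CLint(control), per enzyme, clipped to
#' `[0, 1]` (assay noise can push the ratio outside the unit interval).
#'
#' @param clint_control control intrinsic clearance (uL/min/mg).
#' @param clint_with_inhibitor named numeric, intrinsic clearance in the
#'   presence of each selective inhibitor (uL/min/mg).
#' @return named numeric of per-enzyme metabolised fractions.
#' @export
fm_from_inhibition <- function(clint_control, clint_with_inhibitor) {
  stopifnot(clint_control > 0)
  pmin(pmax(1 - clint_with_inhibitor / clint_control, 0), 1)
}

#' Human Vdss by single-species (rat) scaling
#'
#' Assumes the unbound steady-state volume is conserved across species:
#' Vdss_human = (Vdss_rat / fu_rat) x fu_human.
#'
#' @param vdss_rat rat Vdss (mL/kg).
#' @param fu_rat,fu_human plasma unbound fractions.
#' @return predicted human Vdss (mL/kg).
#' @export
predict_vd_single_species <- function(vdss_rat, fu_rat, fu_human) {
  stopifnot(vdss_rat > 0, fu_rat > 0, fu_human > 0)
  vdss_rat / fu_rat * fu_human
}

#' Human Vdss by the rat-dog-human proportionality equation
#'
#' log10(Vdss_human) = 0.07714 log10(Vdss_rat) log10(Vdss_dog)
#' + 0.5147 log10(Vdss_dog) + 0.586, all volumes in mL/kg.
#'
#' @param vdss_rat,vdss_dog animal Vdss (mL/kg).
#' @return predicted human Vdss (mL/kg).
#' @export
predict_vd_wajima <- function(vdss_rat, vdss_dog) {
  stopifnot(vdss_rat > 0, vdss_dog > 0)
  10^(0.07714 * log10(vdss_rat) * log10(vdss_dog) +
        0.5147 * log10(vdss_dog) + 0.586)
}

# Oie-Tozer steady-state volume (L/kg) given fu and tissue unbound fraction
.oie_tozer_forward <- function(fu, fu_t, phys) {
  phys$vp * (1 + phys$re_i) +
    phys$vp * fu * (phys$ve / phys$vp - phys$re_i) +
    phys$vr * fu / fu_t
}

# invert for fu_t given an observed Vdss (L/kg)
.oie_tozer_invert <- function(vdss_l_kg, fu, phys) {
  denom <- vdss_l_kg - phys$vp * (1 + phys$re_i) -
    phys$vp * fu * (phys$ve / phys$vp - phys$re_i)
  if (denom <= 0) {
    stop("Oie-Tozer inversion infeasible: Vdss does not exceed the plasma and extracellular terms")
  }
  phys$vr * fu / denom
}

#' Human Vdss by the Oie-Tozer method
#'
#' Inverts the Oie-Tozer steady-state volume equation
#' Vdss = Vp (1 + RE/I) + Vp fu (Ve/Vp - RE/I) + Vr fu / fu_t
#' for the tissue unbound fraction fu_t in each animal species, averages
#' fu_t arithmetically, and evaluates the equation forward for human.
#'
#' @param vdss_animals named numeric, animal Vdss (mL/kg).
#' @param fu named numeric, plasma unbound fractions; must include every
#'   animal species and `"human"`.
#' @param physiologies named list of [species_physiology()] including
#'   `human`; see [default_physiologies()].
#' @return list with `vdss_human` (mL/kg), `fu_t` (per animal), `fu_t_mean`.
#' @export
predict_vd_oie_tozer <- function(vdss_animals, fu, physiologies = default_physiologies()) {
  sp <- names(vdss_animals)
  stopifnot(length(sp) >= 1, all(sp %in% names(fu)), all(sp %in% names(physiologies)),
            "human" %in% names(fu), "human" %in% names(physiologies))
  fu_t <- vapply(sp, function(s) {
    .oie_tozer_invert(vdss_animals[[s]] / 1000, fu[[s]], physiologies[[s]])
  }, numeric(1))
  fu_t_mean <- mean(fu_t)
  vd_h <- .oie_tozer_forward(fu[["human"]], fu_t_mean, physiologies$human) * 1000
  list(vdss_human = vd_h, fu_t = fu_t, fu_t_mean = fu_t_mean)
}

#' Full human CL and Vdss prediction suite
#'
#' Runs all six interspecies extrapolation methods on one compound: FCIM
#' and two-species allometry from the animal iv clearances; well-stirred
#' IVIVE from HLM intrinsic clearance without and with the averaged
#' rat/dog empirical scaling factor; single-species (rat) scaling, the
#' rat-dog-human proportionality equation and the Oie-Tozer method for
#' Vdss. Methods whose inputs are missing are skipped with a warning.
#'
#' @param compound a [compound_profile()].
#' @param physiologies named list of [species_physiology()].
#' @param animal_pk per-species list with `cl_total` (mL/h/kg), `vdss`
#'   (mL/kg) and `fe_urine` (fraction), as in [thy1773_inputs()].
#' @param esf_protein_conc microsomal protein concentrations (mg/mL) of the
#'   animal assays, used for the lipophilicity-based fu_mic entering the
#'   empirical scaling factor chain.
#' @param esf_override optional named numeric of per-species empirical
#'   scaling factors to apply instead of the internally computed chain
#'   (e.g. values reported alongside the in vivo study); the internal
#'   chain is still computed and reported for comparison.
#' @return data.frame of prediction records: `parameter` (`cl_total` /
#'   `vd_ss`), `method`, `predicted_value` (mL/h/kg or mL/kg), plus an
#'   `esf` attribute carrying the per-species and averaged scaling factors
#'   and the ESF-adjusted CLint (uL/min/mg).
#' @export
cl_vd_prediction_suite <- function(compound, physiologies = default_physiologies(),
                                   animal_pk, esf_protein_conc = c(rat = 0.25, dog = 0.25),
                                   esf_override = NULL) {
  human <- physiologies$human
  fu <- compound$fu_plasma
  rb <- compound$blood_plasma_ratio
  records <- list()
  add <- function(parameter, method, value) {
    records[[length(records) + 1]] <<- data.frame(
      parameter = parameter, method = method, predicted_value = value,
      stringsAsFactors = FALSE)
  }
  animals <- intersect(names(animal_pk), c("rat", "dog"))
  if (length(animals) == 2) {
    cl_sp <- vapply(animals, function(s) animal_pk[[s]]$cl_total, numeric(1))
    bw_sp <- vapply(animals, function(s) physiologies[[s]]$body_weight, numeric(1))
    fit <- fit_two_species_allometry(cl_sp, bw_sp)
    add("cl_total", "fcim",
        predict_cl_fcim(fit, fu[["rat"]], fu[["human"]], human$body_weight))
    add("cl_total", "allometry_2sp",
        predict_cl_allometry(fit, human$body_weight))
  } else {
    warning("two-species allometry and FCIM skipped: need rat and dog iv clearance")
  }

  cl_renal_h <- predict_cl_renal_gfr(fu[["human"]], human$gfr)
  clint_h <- compound$clint_microsomal[["human"]]
  add("cl_total", "ivive_no_esf",
      predict_cl_ivive(scale_clint(clint_h, human), fu[["human"]],
                       compound$fu_mic, rb[["human"]],
                       human$hepatic_blood_flow, cl_renal_h))

  esf_info <- NULL
  if (length(animals) >= 1 &&
      all(vapply(animals, function(s) !is.null(animal_pk[[s]]$fe_urine), logical(1)))) {
    esf <- vapply(animals, function(s) {
      phys <- physiologies[[s]]
      pk <- animal_pk[[s]]
      cl_ren <- renal_clearance(pk$fe_urine, pk$cl_total)
      in_vivo <- backcalc_in_vivo_clint(pk$cl_total, cl_ren, fu[[s]], rb[[s]],
                                        phys$hepatic_blood_flow)
      fu_mic_s <- fu_mic_lipophilicity(compound$log_p, esf_protein_conc[[s]])
      in_vitro <- scale_clint(compound$clint_microsomal[[s]], phys) / fu_mic_s
      empirical_scaling_factor(in_vivo, in_vitro)
    }, numeric(1))
    applied <- if (!is.null(esf_override)) esf_override else esf
    esf_mean <- average_esf(applied)
    clint_esf <- clint_h * esf_mean
    add("cl_total", "ivive_with_esf",
        predict_cl_ivive(scale_clint(clint_esf, human), fu[["human"]],
                         compound$fu_mic, rb[["human"]],
                         human$hepatic_blood_flow, cl_renal_h))
    esf_info <- list(applied = applied, mean = esf_mean,
                     clint_adjusted = clint_esf,
                     computed_chain = esf)
  } else {
    warning("IVIVE with ESF skipped: animal iv clearance and urinary recovery required")
  }

  if ("rat" %in% animals) {
    add("vd_ss", "single_species_rat",
        predict_vd_single_species(animal_pk$rat$vdss, fu[["rat"]], fu[["human"]]))
  }
  if (length(animals) == 2) {
    add("vd_ss", "wajima",
        predict_vd_wajima(animal_pk$rat$vdss, animal_pk$dog$vdss))
  }
  if (length(animals) >= 1) {
    vd_an <- vapply(animals, function(s) animal_pk[[s]]$vdss, numeric(1))
    ot <- predict_vd_oie_tozer(vd_an, fu, physiologies)
    add("vd_ss", "oie_tozer", ot$vdss_human)
  }
  out <- if (length(records)) do.call(rbind, records) else
    data.frame(parameter = character(), method = character(),
               predicted_value = numeric(), stringsAsFactors = FALSE)
  attr(out, "esf") <- esf_info
  out
}
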