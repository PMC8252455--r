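#' Ground-truth PK model for synthetic profiles
#'
#' Known-parameter compartmental model used to generate test data with an
#' exact closed-form solution. Supported models: `"one_compartment"`
#' (parameters `cl` mL/h/kg, `v` mL/kg; oral additionally `ka` 1/h and
#' optionally `f`) and `"two_compartment"` (iv only; `cl`, `v1`, `q`, `v2`
#' in mL/h/kg and mL/kg).
#'
#' @param model model name.
#' @param parameters named list of parameters (units above).
#' @param route `"iv_bolus"` or `"oral"`.
#' @param dose dose (mg/kg).
#' @return object of class `ground_truth_pk`.
#' @export
ground_truth_pk <- function(model = c("one_compartment", "two_compartment"),
                            parameters, route = c("iv_bolus", "oral"), dose) {
  model <- match.arg(model)
  route <- match.arg(route)
  p <- parameters
  stopifnot(dose > 0, all(unlist(p) > 0))
  if (model == "one_compartment") {
    stopifnot(!is.null(p$cl), !is.null(p$v))
    if (route == "oral") stopifnot(!is.null(p$ka))
    if (is.null(p$f)) p$f <- 1
  } else {
    stopifnot(route == "iv_bolus", !is.null(p$cl), !is.null(p$v1),
              !is.null(p$q), !is.null(p$v2))
  }
  structure(list(model = model, parameters = p, route = route, dose = dose),
            class = "ground_truth_pk")
}

#' Closed-form concentrations for a ground-truth model
#'
#' @param truth a [ground_truth_pk()].
#' @param times sampling times (h).
#' @return concentrations (ng/mL).
#' @export
closed_form_conc <- function(truth, times) {
  p <- truth$parameters
  dose_ng_kg <- truth$dose * 1e6
  if (truth$model == "one_compartment") {
    k <- p$cl / p$v
    if (truth$route == "iv_bolus") {
      dose_ng_kg / p$v * exp(-k * times)
    } else {
      if (abs(p$ka - k) < 1e-9) stop("closed_form_conc: ka must differ from k")
      p$f * dose_ng_kg * p$ka / (p$v * (p$ka - k)) *
        (exp(-k * times) - exp(-p$ka * times))
    }
  } else {
    # two-compartment iv bolus: macro constants from micro rate constants
    k10 <- p$cl / p$v1; k12 <- p$q / p$v1; k21 <- p$q / p$v2
    s <- k10 + k12 + k21
    alpha <- (s + sqrt(s^2 - 4 * k10 * k21)) / 2
    beta <- (s - sqrt(s^2 - 4 * k10 * k21)) / 2
    a <- dose_ng_kg / p$v1 * (alpha - k21) / (alpha - beta)
    b <- dose_ng_kg / p$v1 * (k21 - beta) / (alpha - beta)
    a * exp(-alpha * times) + b * exp(-beta * times)
  }
}

#' Generate a noisy concentration-time profile
#'
#' Closed-form concentrations multiplied by lognormal unit-mean error
#' (standard multiplicative residual model for bioanalytical PK data);
#' values below the LOQ are flagged unquantifiable. Reproducible under the
#' mandatory seed.
#'
#' @param truth a [ground_truth_pk()].
#' @param sampling_times sampling times (h).
#' @param noise_cv residual coefficient of variation (fraction; 0 = exact).
#' @param lloq lower limit of quantification (ng/mL).
#' @param seed integer random seed.
#' @return a [conc_time_profile()].
#' @export
generate_profile <- function(truth, sampling_times, noise_cv = 0, lloq = 0,
                             seed) {
  stopifnot(noise_cv >= 0, !missing(seed))
  conc <- closed_form_conc(truth, sampling_times)
  if (noise_cv > 0) {
    set.seed(seed)
    sdlog <- sqrt(log(1 + noise_cv^2))
    conc <- conc * stats::rlnorm(length(conc), -sdlog^2 / 2, sdlog)
  }
  conc_time_profile(times = sampling_times, concentrations = conc,
                    dose = truth$dose, route = truth$route, lloq = lloq)
}

#' Generate a random, internally consistent virtual compound
#'
#' Draws physicochemistry, per-species binding and intrinsic clearance
#' uniformly from plausible ranges. Cross-species consistency of the
#' unbound steady-state volume is enforced by construction (one unbound
#' volume is drawn and each species' Vdss is fu-scaled from it), so
#' single-species Vdss scaling is exact on these compounds; the generating
#' values are attached as the `"truth"` attribute.
#'
#' @param seed integer random seed.
#' @param ranges list of ranges: `fu` (unbound fraction), `log_p`, `clint`
#'   (uL/min/mg), `vdss_u` (unbound Vdss, L/kg).
#' @return a [compound_profile()] with a `"truth"` attribute carrying
#'   `vdss_u_l_kg` and per-species `vdss_ml_kg`.
#' @export
generate_virtual_compound <- function(seed,
                                      ranges = list(fu = c(0.005, 1),
                                                    log_p = c(0, 5),
                                                    clint = c(1, 200),
                                                    vdss_u = c(1, 50))) {
  set.seed(seed)
  runif1 <- function(r) stats::runif(1, r[1], r[2])
  species <- c("rat", "dog", "human")
  fu <- stats::setNames(stats::runif(3, ranges$fu[1], ranges$fu[2]), species)
  vdss_u <- runif1(ranges$vdss_u)                     # L/kg, unbound
  vdss <- vdss_u * fu * 1000                          # mL/kg per species
  cmpd <- compound_profile(
    name = sprintf("VIRT%04d", seed %% 10000),
    molecular_weight = stats::runif(1, 250, 600),
    log_p = runif1(ranges$log_p),
    pka = stats::runif(1, 3, 6.9),
    compound_type = sample(c("monoprotic_base", "monoprotic_acid", "neutral"), 1),
    fu_plasma = fu,
    blood_plasma_ratio = stats::setNames(stats::runif(3, 0.5, 1.5), species),
    clint_microsomal = stats::setNames(stats::runif(3, ranges$clint[1], ranges$clint[2]), species),
    fu_mic = stats::runif(1, 0.3, 1),
    fm_by_enzyme = c(CYP3A4 = 0.7, CYP2D6 = 0.2),
    ec50_free = stats::runif(1, 0.5, 50),
    emax = 100, ka = stats::runif(1, 0.5, 4), fa = stats::runif(1, 0.5, 1),
    fu_gut = 1
  )
  attr(cmpd, "truth") <- list(vdss_u_l_kg = vdss_u, vdss_ml_kg = vdss)
  cmpd
}

#' Generate a virtual population
#'
#' Per-subject lognormal draws of body weight and of multiplicative
#' intrinsic-clearance and unbound-fraction factors (unit mean), laid out
#' by trial.
#'
#' @param population a [virtual_population_spec()].
#' @return data.frame with columns `trial`, `subject`, `body_weight_kg`,
#'   `clint_mult`, `fu_mult`.
#' @export
generate_population <- function(population) {
  stopifnot(inherits(population, "virtual_population_spec"))
  n <- population$n_trials * population$n_subjects_per_trial
  draw <- function(mean, cv) {
    if (cv == 0) return(rep(mean, n))
    sdlog <- sqrt(log(1 + cv^2))
    stats::rlnorm(n, log(mean) - sdlog^2 / 2, sdlog)
  }
  set.seed(population$seed)
  data.frame(
    trial = rep(seq_len(population$n_trials), each = population$n_subjects_per_trial),
    subject = seq_len(n),
    body_weight_kg = draw(population$weight_mean, population$weight_cv),
    clint_mult = draw(1, population$clint_cv),
    fu_mult = draw(1, population$fu_cv)
  )
}
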