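#' Compound parameter record
#'
#' Constructs and validates the compound-specific parameter set consumed by
#' every downstream stage: physicochemistry (MW, logP, pKa, ionisation
#' class), per-species plasma binding and blood partitioning, microsomal
#' intrinsic clearance with its unbound fraction and CYP split, the
#' occupancy model constants, and the oral absorption constants.
#'
#' @param name compound label.
#' @param molecular_weight g/mol.
#' @param log_p octanol-water log partition coefficient.
#' @param pka acid dissociation constant of the ionisable centre.
#' @param compound_type one of `"monoprotic_base"`, `"monoprotic_acid"`,
#'   `"neutral"`.
#' @param fu_plasma named numeric, unbound plasma fraction per species (0, 1].
#' @param blood_plasma_ratio named numeric, blood:plasma ratio per species.
#' @param clint_microsomal named numeric, microsomal intrinsic clearance per
#'   species (uL/min/mg microsomal protein).
#' @param fu_mic unbound fraction in the microsomal incubation (0, 1].
#' @param fm_by_enzyme named numeric, fraction metabolised per enzyme;
#'   must sum to at most 1.
#' @param ec50_free free plasma concentration at half-maximal occupancy
#'   (nmol/L).
#' @param emax maximal receptor occupancy (%, in (0, 100]).
#' @param ka first-order absorption rate constant (1/h).
#' @param fa fraction absorbed (0, 1].
#' @param fu_gut unbound fraction in enterocytes (0, 1].
#' @return an object of class `compound_profile` (a validated list).
#' @export
compound_profile <- function(name, molecular_weight, log_p, pka, compound_type,
                             fu_plasma, blood_plasma_ratio, clint_microsomal,
                             fu_mic, fm_by_enzyme, ec50_free, emax = 100,
                             ka = NA_real_, fa = NA_real_, fu_gut = 1) {
  obj <- list(
    name = as.character(name), molecular_weight = molecular_weight,
    log_p = log_p, pka = pka, compound_type = compound_type,
    fu_plasma = unlist(fu_plasma), blood_plasma_ratio = unlist(blood_plasma_ratio),
    clint_microsomal = unlist(clint_microsomal), fu_mic = fu_mic,
    fm_by_enzyme = unlist(fm_by_enzyme), ec50_free = ec50_free, emax = emax,
    ka = ka, fa = fa, fu_gut = fu_gut
  )
  class(obj) <- "compound_profile"
  validate_compound_profile(obj)
}

#' @rdname compound_profile
#' @param x object to validate.
#' @export
validate_compound_profile <- function(x) {
  chk <- function(cond, msg) if (!isTRUE(all(cond))) stop("compound_profile: ", msg, call. = FALSE)
  chk(x$molecular_weight > 0, "molecular_weight must be positive")
  chk(x$compound_type %in% c("monoprotic_base", "monoprotic_acid", "neutral"),
      "compound_type must be monoprotic_base, monoprotic_acid or neutral")
  frac_in_01 <- function(v) all(v > 0 & v <= 1)
  chk(frac_in_01(x$fu_plasma), "fu_plasma values must be in (0, 1]")
  chk(all(x$blood_plasma_ratio > 0), "blood_plasma_ratio must be positive")
  chk(all(x$clint_microsomal >= 0), "clint_microsomal must be nonnegative")
  chk(frac_in_01(x$fu_mic), "fu_mic must be in (0, 1]")
  chk(all(x$fm_by_enzyme >= 0) && sum(x$fm_by_enzyme) <= 1 + 1e-9,
      "fm_by_enzyme values must be nonnegative and sum to <= 1")
  chk(x$ec50_free > 0, "ec50_free must be positive")
  chk(x$emax > 0 && x$emax <= 100, "emax must be in (0, 100]")
  if (!is.na(x$fa)) chk(frac_in_01(x$fa), "fa must be in (0, 1]")
  chk(frac_in_01(x$fu_gut), "fu_gut must be in (0, 1]")
  x
}

#' Species physiology record
#'
#' Per-species physiological constants used for in vitro-in vivo
#' extrapolation and the Oie-Tozer distribution model: body weight, liver
#' weight per body weight, microsomal protein per gram liver (MPPGL),
#' hepatic blood flow, glomerular filtration rate, and the plasma /
#' extracellular / remainder fluid volumes with the extracellular-to-plasma
#' binding-protein ratio.
#'
#' @param species species label.
#' @param body_weight kg.
#' @param liver_weight_per_bw g liver / kg body weight.
#' @param mppgl mg microsomal protein / g liver.
#' @param hepatic_blood_flow mL/h/kg.
#' @param gfr glomerular filtration rate, mL/h/kg.
#' @param vp,ve,vr plasma, extracellular and remainder fluid volumes, L/kg.
#' @param re_i ratio of binding protein in extracellular fluid to plasma.
#' @return an object of class `species_physiology`.
#' @export
species_physiology <- function(species, body_weight, liver_weight_per_bw, mppgl,
                               hepatic_blood_flow, gfr, vp, ve, vr, re_i = 1.4) {
  obj <- list(species = species, body_weight = body_weight,
              liver_weight_per_bw = liver_weight_per_bw, mppgl = mppgl,
              hepatic_blood_flow = hepatic_blood_flow, gfr = gfr,
              vp = vp, ve = ve, vr = vr, re_i = re_i)
  num <- unlist(obj[-1])
  if (!all(is.finite(num) & num > 0)) {
    stop("species_physiology: all physical quantities must be strictly positive",
         call. = FALSE)
  }
  class(obj) <- "species_physiology"
  obj
}

#' Bundled default physiologies for rat, dog and human
#'
#' Liver weight, MPPGL, hepatic blood flow and GFR follow the standard
#' scaling-factor compilations used for IVIVE; the Oie-Tozer fluid volumes
#' and the extracellular binding-protein ratio are the standard published
#' values. Body weights default to 0.25 kg (young adult SD rat), 10 kg
#' (adult beagle) and 70 kg (reference human); all fields can be overridden
#' through the configuration file.
#'
#' @return named list of [species_physiology()] objects (`rat`, `dog`,
#'   `human`).
#' @export
default_physiologies <- function() {
  list(
    rat = species_physiology("rat", body_weight = 0.25,
                             liver_weight_per_bw = 40, mppgl = 45,
                             hepatic_blood_flow = 4200, gfr = 312,
                             vp = 0.0313, ve = 0.265, vr = 0.364),
    dog = species_physiology("dog", body_weight = 10,
                             liver_weight_per_bw = 32, mppgl = 45,
                             hepatic_blood_flow = 2400, gfr = 192,
                             vp = 0.0515, ve = 0.216, vr = 0.450),
    human = species_physiology("human", body_weight = 70,
                               liver_weight_per_bw = 21, mppgl = 40,
                               hepatic_blood_flow = 1242, gfr = 108,
                               vp = 0.0436, ve = 0.151, vr = 0.380)
  )
}

#' Observed human PK record
#'
#' Observed oral clearance and terminal-phase volume (apparent, i.e. over
#' bioavailability F), consumed by the fold-error evaluation.
#'
#' @param cl_over_f observed CL/F, mL/h/kg.
#' @param vdz_over_f observed Vdz/F, mL/kg.
#' @param reference_body_weight kg used for body-weight normalisation of the
#'   observed values.
#' @return an object of class `observed_human_pk`.
#' @export
observed_human_pk <- function(cl_over_f, vdz_over_f, reference_body_weight = 70) {
  stopifnot(cl_over_f > 0, vdz_over_f > 0, reference_body_weight > 0)
  structure(list(cl_over_f = cl_over_f, vdz_over_f = vdz_over_f,
                 reference_body_weight = reference_body_weight),
            class = "observed_human_pk")
}

#' Bundled THY1773 study inputs
#'
#' The complete published parameter set for THY1773, the V1B receptor
#' antagonist whose first-in-human dose prediction this package
#' re-implements: physicochemistry, per-species binding, microsomal
#' intrinsic clearances, the phenotyping (selective inhibition) data, the
#' single-dose animal iv PK summary, the absorption constants and the
#' occupancy model constants.
#'
#' @return list with elements `compound` ([compound_profile()]),
#'   `phenotyping` (control and inhibited HLM CLint, uL/min/mg),
#'   `animal_pk` (per-species iv CL, Vdss, urinary excreted fraction),
#'   `esf` (per-species empirical scaling factors reported with the study),
#'   `observed_human` ([observed_human_pk()]).
#' @export
thy1773_inputs <- function() {
  compound <- compound_profile(
    name = "THY1773",
    molecular_weight = 483.99, log_p = 3.17, pka = 6.85,
    compound_type = "monoprotic_base",
    fu_plasma = c(rat = 0.108, dog = 0.104, human = 0.017),
    blood_plasma_ratio = c(rat = 0.822, dog = 0.846, human = 0.55),
    clint_microsomal = c(rat = 22.0, dog = 32.2, human = 11.2),
    fu_mic = 0.714,
    fm_by_enzyme = c(CYP3A4 = 0.911, CYP2D6 = 0.089),
    ec50_free = 3.51, emax = 100,
    ka = 3.10, fa = 0.998, fu_gut = 1
  )
  list(
    compound = compound,
    phenotyping = list(
      clint_control = 11.2,
      clint_with_inhibitor = c(CYP3A = 0.961, CYP2D6 = 10.2)
    ),
    animal_pk = list(
      rat = list(cl_total = 1330, vdss = 2220, fe_urine = 0.046),
      dog = list(cl_total = 785, vdss = 2020, fe_urine = 0.020)
    ),
    # empirical scaling factors reported with the in vivo study
    esf = c(rat = 6.5, dog = 3.6),
    observed_human = observed_human_pk(cl_over_f = 17.2, vdz_over_f = 528,
                                       reference_body_weight = 70)
  )
}

#' Load a study configuration file
#'
#' Reads a YAML or JSON configuration describing a compound, optional
#' species-physiology overrides, optional animal PK summaries and optional
#' observed human PK. Missing physiology blocks are filled with the bundled
#' defaults ([default_physiologies()]); all type invariants are validated.
#'
#' @param path path to a `.yaml`/`.yml` or `.json` file.
#' @return list with `compound`, `physiologies`, and (when present in the
#'   file) `phenotyping`, `animal_pk`, `observed_human`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("configuration file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  raw <- tryCatch(
    switch(ext,
           yaml = , yml = yaml::read_yaml(path),
           json = jsonlite::read_json(path, simplifyVector = TRUE),
           stop("unsupported configuration format: .", ext)),
    error = function(e) stop("configuration parse failure in '", path, "': ",
                             conditionMessage(e), call. = FALSE)
  )
  if (is.null(raw$compound)) stop("configuration error: missing 'compound' block")
  cp <- raw$compound
  compound <- compound_profile(
    name = cp$name, molecular_weight = cp$molecular_weight, log_p = cp$log_p,
    pka = cp$pka, compound_type = cp$compound_type,
    fu_plasma = cp$fu_plasma, blood_plasma_ratio = cp$blood_plasma_ratio,
    clint_microsomal = cp$clint_microsomal, fu_mic = cp$fu_mic,
    fm_by_enzyme = cp$fm_by_enzyme, ec50_free = cp$ec50_free,
    emax = if (is.null(cp$emax)) 100 else cp$emax,
    ka = if (is.null(cp$ka)) NA_real_ else cp$ka,
    fa = if (is.null(cp$fa)) NA_real_ else cp$fa,
    fu_gut = if (is.null(cp$fu_gut)) 1 else cp$fu_gut
  )
  phys <- default_physiologies()
  for (sp in names(raw$physiology)) {
    base <- phys[[sp]]
    if (is.null(base)) base <- phys$human
    over <- raw$physiology[[sp]]
    args <- utils::modifyList(unclass(base)[-1], over)
    phys[[sp]] <- do.call(species_physiology, c(list(species = sp), args))
  }
  out <- list(compound = compound, physiologies = phys)
  if (!is.null(raw$phenotyping)) {
    ph <- raw$phenotyping
    out$phenotyping <- list(clint_control = ph$clint_control,
                            clint_with_inhibitor = unlist(ph$clint_with_inhibitor))
  }
  if (!is.null(raw$animal_pk)) out$animal_pk <- raw$animal_pk
  if (!is.null(raw$esf)) out$esf <- unlist(raw$esf)
  if (!is.null(raw$observed_human)) {
    oh <- raw$observed_human
    out$observed_human <- observed_human_pk(
      cl_over_f = oh$cl_over_f, vdz_over_f = oh$vdz_over_f,
      reference_body_weight = if (is.null(oh$reference_body_weight)) 70
                              else oh$reference_body_weight)
  }
  out
}
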