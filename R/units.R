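#' Unit conversion
#'
#' Small multiplicative unit registry for the quantities used throughout the
#' pipeline. Canonical internal units are: time h, volume mL, mass ng,
#' body-weight-normalised clearances mL/h/kg, concentrations ng/mL (with a
#' helper to free nmol/L). A compound unit is written with `/` separators,
#' e.g. `"mL/min/kg"` or `"uL/min/mg"`; each token must be a registered
#' simple unit and the token-wise dimensions of `from_unit` and `to_unit`
#' must match.
#'
#' @param value numeric vector to convert.
#' @param from_unit,to_unit unit strings, e.g. `"mL/min/kg"`.
#' @return `value` expressed in `to_unit`.
#' @examples
#' convert_units(1, "mL/min/kg", "mL/h/kg") # 60
#' @export
convert_units <- function(value, from_unit, to_unit) {
  f <- .unit_parse(from_unit)
  t <- .unit_parse(to_unit)
  if (!identical(f$dims, t$dims)) {
    stop("incompatible dimensions: '", from_unit, "' (", paste(f$dims, collapse = "/"),
         ") vs '", to_unit, "' (", paste(t$dims, collapse = "/"), ")")
  }
  value * f$factor / t$factor
}

# simple units: factor to the canonical unit of their dimension
.unit_table <- local({
  u <- list(
    # volume (canonical mL)
    L = c("volume", 1e3), mL = c("volume", 1), uL = c("volume", 1e-3),
    # time (canonical h)
    h = c("time", 1), min = c("time", 1 / 60), s = c("time", 1 / 3600),
    d = c("time", 24),
    # mass (canonical ng)
    kg = c("mass", 1e12), g = c("mass", 1e9), mg = c("mass", 1e6),
    ug = c("mass", 1e3), ng = c("mass", 1), pg = c("mass", 1e-3),
    # amount (canonical nmol)
    mol = c("amount", 1e9), mmol = c("amount", 1e6), umol = c("amount", 1e3),
    nmol = c("amount", 1), pmol = c("amount", 1e-3)
  )
  data.frame(unit = names(u),
             dim = vapply(u, `[`, "", 1),
             factor = as.numeric(vapply(u, `[`, "", 2)))
})

.unit_parse <- function(unit) {
  stopifnot(is.character(unit), length(unit) == 1L)
  tokens <- strsplit(unit, "/", fixed = TRUE)[[1]]
  # accept some common spellings
  tokens <- sub("^ml$", "mL", tokens)
  tokens <- sub("^l$", "L", tokens)
  tokens <- sub("^µL$", "uL", tokens)
  tokens <- sub("^hr$", "h", tokens)
  idx <- match(tokens, .unit_table$unit)
  if (anyNA(idx)) stop("unknown unit token: ", tokens[is.na(idx)][1])
  factor <- .unit_table$factor[idx[1]]
  if (length(idx) > 1) factor <- factor / prod(.unit_table$factor[idx[-1]])
  list(dims = .unit_table$dim[idx], factor = factor)
}

#' Total plasma concentration to free molar concentration
#'
#' Converts a total plasma concentration in ng/mL to the unbound molar
#' concentration in nmol/L using the plasma unbound fraction and the
#' molecular weight: `free_nM = conc * fu / MW * 1000`.
#'
#' @param conc_ng_ml total plasma concentration (ng/mL).
#' @param fu unbound fraction in plasma (0, 1].
#' @param mw molecular weight (g/mol).
#' @return free concentration (nmol/L).
#' @export
free_nM <- function(conc_ng_ml, fu, mw) {
  stopifnot(fu > 0, fu <= 1, mw > 0)
  conc_ng_ml * fu / mw * 1000
}
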