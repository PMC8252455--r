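#' Full human PK prediction and accuracy evaluation for one study bundle
#'
#' Convenience driver over the whole desk-scale chain: runs the
#' six-method clearance and volume prediction suite
#' ([cl_vd_prediction_suite()]), derives the metabolised fractions from the
#' phenotyping data ([fm_from_inhibition()]), and (when observed human PK
#' is available) builds the retrospective fold-error report
#' ([fold_error_report()]).
#'
#' @param inputs a study bundle as returned by [thy1773_inputs()] or
#'   [load_config()]: list with `compound`, optional `physiologies`,
#'   `animal_pk`, `phenotyping`, `observed_human`.
#' @return list with `predictions` (data.frame incl. the `esf` attribute),
#'   `fm` (named fractions, when phenotyping data present), `report`
#'   (fold-error report, when observed data present).
#' @export
predict_human_pk <- function(inputs = thy1773_inputs()) {
  phys <- if (!is.null(inputs$physiologies)) inputs$physiologies else default_physiologies()
  out <- list(
    predictions = cl_vd_prediction_suite(inputs$compound, phys, inputs$animal_pk,
                                         esf_override = inputs$esf)
  )
  if (!is.null(inputs$phenotyping)) {
    out$fm <- fm_from_inhibition(inputs$phenotyping$clint_control,
                                 inputs$phenotyping$clint_with_inhibitor)
  }
  if (!is.null(inputs$observed_human)) {
    out$report <- fold_error_report(out$predictions, inputs$observed_human)
  }
  out
}
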