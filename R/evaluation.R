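#' Fold error of a prediction
#'
#' Predicted divided by observed; values above 1 are overpredictions.
#'
#' @param predicted,observed positive quantities in the same units.
#' @return fold error (unitless).
#' @export
fold_error <- function(predicted, observed) {
  if (any(predicted <= 0) || any(observed <= 0)) {
    stop("fold_error: predicted and observed must be positive")
  }
  predicted / observed
}

#' Retrospective prediction-accuracy report
#'
#' Pairs every prediction record with the observed human value of the same
#' parameter and computes fold errors with 2-fold and 3-fold accuracy
#' flags. The observed comparators are the oral CL_total/F and Vdz/F;
#' the comparison therefore assumes complete bioavailability (F = 100%)
#' and Vdz comparable to Vdss, which is recorded in the report.
#'
#' @param predictions data.frame of prediction records (`parameter`,
#'   `method`, `predicted_value`), e.g. from [cl_vd_prediction_suite()].
#' @param observed an [observed_human_pk()].
#' @return object of class `fold_error_report`: data.frame with columns
#'   `parameter`, `method`, `predicted`, `observed`, `fold_error`,
#'   `within_2fold`, `within_3fold`; assumption note in the
#'   `"assumptions"` attribute and display-rounded fold errors in
#'   `fold_error_display`.
#' @export
fold_error_report <- function(predictions, observed) {
  stopifnot(inherits(observed, "observed_human_pk"))
  if (nrow(predictions) == 0) {
    out <- data.frame(parameter = character(), method = character(),
                      predicted = numeric(), observed = numeric(),
                      fold_error = numeric(), within_2fold = logical(),
                      within_3fold = logical())
    class(out) <- c("fold_error_report", class(out))
    return(out)
  }
  obs_for <- c(cl_total = observed$cl_over_f, vd_ss = observed$vdz_over_f)
  if (!all(predictions$parameter %in% names(obs_for))) {
    stop("fold_error_report: no observed comparator for parameter(s): ",
         paste(setdiff(predictions$parameter, names(obs_for)), collapse = ", "))
  }
  fe <- fold_error(predictions$predicted_value, obs_for[predictions$parameter])
  out <- data.frame(
    parameter = predictions$parameter, method = predictions$method,
    predicted = predictions$predicted_value,
    observed = unname(obs_for[predictions$parameter]),
    fold_error = unname(fe),
    within_2fold = unname(fe >= 0.5 & fe <= 2),
    within_3fold = unname(fe >= 1 / 3 & fe <= 3)
  )
  # display convention: 2 significant figures at >= 1, 2 decimals below 1
  out$fold_error_display <- ifelse(out$fold_error >= 1,
                                   signif(out$fold_error, 2),
                                   round(out$fold_error, 2))
  attr(out, "assumptions") <-
    "observed comparators are oral CL/F and Vdz/F; F assumed 100%, Vdz ~ Vdss"
  class(out) <- c("fold_error_report", class(out))
  out
}
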