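# Small derived effect summaries used to report perturbation outcomes
# (e.g. flow-cytometry S-phase fractions, densitometry ratios). The means
# are taken as inputs; acquisition and gating are upstream of this package.

#' Relative percent reduction of a treated mean versus a control mean
#'
#' `(1 - treated_mean / control_mean) * 100`. Used, for example, to express
#' the reduction of the S-phase cell fraction in a knockdown line relative
#' to a scrambled-control line.
#'
#' @param treated_mean Non-negative mean under treatment.
#' @param control_mean Positive control mean.
#' @return Percent reduction in `(-Inf, 100]` (0 when equal, 100 when the
#'   treated mean is zero; negative when treatment increases the quantity).
#' @export
#' @examples
#' relative_percent_reduction(36, 50)  # 28
relative_percent_reduction <- function(treated_mean, control_mean) {
  check_scalar_number(treated_mean, "treated_mean", lower = 0)
  check_scalar_number(control_mean, "control_mean")
  if (control_mean <= 0) stop_validation("control_mean must be positive")
  (1 - treated_mean / control_mean) * 100
}

#' Ratio of two quantities normalized to a reference ratio
#'
#' `(numerator / denominator) / reference_ratio`, e.g. a Bax/Bcl-2 protein
#' ratio expressed relative to the same ratio in control cells.
#'
#' @param numerator Non-negative numerator.
#' @param denominator Positive denominator.
#' @param reference_ratio Positive reference ratio.
#' @return The relative difference (1 means equal to the reference).
#' @export
normalized_ratio <- function(numerator, denominator, reference_ratio) {
  check_scalar_number(numerator, "numerator", lower = 0)
  check_scalar_number(denominator, "denominator")
  check_scalar_number(reference_ratio, "reference_ratio")
  if (denominator <= 0) stop_validation("denominator must be positive")
  if (reference_ratio <= 0) stop_validation("reference_ratio must be positive")
  (numerator / denominator) / reference_ratio
}

#' Summarize a table of condition means against a control condition
#'
#' Applies [relative_percent_reduction()] to every non-control row of a
#' (condition, mean) table.
#'
#' @param means Data.frame with `condition` and `mean` columns.
#' @param control Name of the control condition (a row of `means`).
#' @return Data.frame (condition, control, metric, value).
#' @export
summarize_effects <- function(means, control) {
  i <- match(control, means$condition)
  if (is.na(i)) stop_validation("control condition not found: ", control)
  treated <- means[-i, , drop = FALSE]
  data.frame(
    condition = treated$condition,
    control = control,
    metric = "relative_percent_reduction",
    value = vapply(treated$mean, relative_percent_reduction, 0,
                   control_mean = means$mean[i]),
    stringsAsFactors = FALSE
  )
}
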