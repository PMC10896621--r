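#' Paired device measurements
#'
#' Per-subject, per-trait pairs of a reference-device and a test-device
#' value. Subjects present on only one side are dropped with a warning and
#' enumerated in the `dropped` attribute.
#'
#' @param subject_id,trait,value_reference,value_test vectors of equal
#'   length; alternatively `value_test` rows may come from a second call.
#' @return a `paired_measurements` data.frame.
#' @export
paired_measurements <- function(subject_id, trait, value_reference,
                                value_test) {
  df <- data.frame(subject_id = as.character(subject_id),
                   trait = as.character(trait),
                   value_reference = as.numeric(value_reference),
                   value_test = as.numeric(value_test),
                   stringsAsFactors = FALSE)
  unpaired <- !is.finite(df$value_reference) | !is.finite(df$value_test)
  dropped <- df$subject_id[unpaired]
  if (any(unpaired)) {
    warning(sprintf("dropping %d unpaired record(s): %s", sum(unpaired),
                    paste(unique(dropped), collapse = ", ")))
    df <- df[!unpaired, , drop = FALSE]
  }
  if (any(df$value_reference <= 0) || any(df$value_test <= 0))
    warning("non-positive measurement values present")
  structure(df, class = c("paired_measurements", "data.frame"),
            dropped = unique(dropped))
}

#' Per-trait mean differences between two devices
#'
#' For each trait: reference and test means, absolute difference of the
#' means and relative difference in percent of the reference mean.
#'
#' @param pm a [paired_measurements()].
#' @return data.frame with one row per trait (`mean_reference`,
#'   `mean_test`, `abs_difference`, `rel_difference_percent`, `n`).
#' @export
paired_differences <- function(pm) {
  traits <- unique(pm$trait)
  rows <- lapply(traits, function(tr) {
    d <- pm[pm$trait == tr, ]
    if (nrow(d) < 2)
      stop("need at least 2 paired subjects for trait ", tr)
    mr <- mean(d$value_reference)
    mt <- mean(d$value_test)
    data.frame(trait = tr, mean_reference = mr, mean_test = mt,
               abs_difference = abs(mr - mt),
               rel_difference_percent = 100 * abs(mr - mt) / mr,
               n = nrow(d), stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Ordinary least squares regression of test on reference device
#'
#' @param pm a [paired_measurements()].
#' @param trait trait to regress.
#' @return list with `slope`, `intercept`, `r_squared`, `n` and
#'   `negative_slope` flag.
#' @export
regress_devices <- function(pm, trait) {
  d <- pm[pm$trait == trait, ]
  if (nrow(d) < 3) stop("need at least 3 pairs for regression")
  if (stats::var(d$value_reference) <= 0)
    stop("zero variance on the reference side")
  fit <- stats::lm(value_test ~ value_reference, data = d)
  co <- stats::coef(fit)
  r2 <- stats::cor(d$value_reference, d$value_test)^2
  neg <- unname(co[2]) < 0
  if (neg) warning("negative device slope for trait ", trait)
  list(slope = unname(co[2]), intercept = unname(co[1]), r_squared = r2,
       n = nrow(d), negative_slope = neg)
}

#' Validate body-weight predictions against scale weights
#'
#' Regression of scale weight on predicted weight plus the root mean
#' squared prediction error.
#'
#' @param predicted,scale paired weight vectors in kg (n >= 3).
#' @return list with `slope`, `intercept`, `r_squared`, `rmse`, `n`.
#' @export
validate_bw <- function(predicted, scale) {
  if (length(predicted) != length(scale)) stop("length mismatch")
  if (length(predicted) < 3) stop("need at least 3 animals")
  if (stats::var(predicted) <= 0)
    stop("zero variance in predicted weights")
  fit <- stats::lm(scale ~ predicted)
  co <- stats::coef(fit)
  list(slope = unname(co[2]), intercept = unname(co[1]),
       r_squared = stats::cor(predicted, scale)^2,
       rmse = sqrt(mean((scale - predicted)^2)), n = length(predicted))
}
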