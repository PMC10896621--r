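#' Long-format measurement tables
#'
#' Records of repeated trait measurements: one row per (subject, session,
#' repeat, trait). This is the input of the repeatability/reproducibility
#' statistics.
#'
#' @param subject_id,session,rep,trait,value,unit vectors of equal length
#'   (recycled where scalar).
#' @return a `measurement_table` (data.frame).
#' @export
measurement_table <- function(subject_id, session, rep, trait, value,
                              unit = "") {
  df <- data.frame(subject_id = as.character(subject_id),
                   session = as.integer(session),
                   rep = as.integer(rep),
                   trait = as.character(trait),
                   value = as.numeric(value),
                   unit = as.character(unit),
                   stringsAsFactors = FALSE)
  u <- tapply(df$unit, df$trait, function(x) length(unique(x)))
  if (any(u > 1)) stop("inconsistent units within a trait")
  class(df) <- c("measurement_table", "data.frame")
  df
}

#' Residual standard deviation of the one-way ANOVA with subject as factor
#'
#' Pooled within-subject SD: the residual SD of `value ~ subject`, i.e.
#' `sqrt(sum((x - subject_mean)^2) / (N - k))` with N records and k
#' subjects. The subject factor removes morphological variation between
#' animals, leaving measurement variability.
#'
#' @param table a [measurement_table()].
#' @param trait trait name to analyse.
#' @return list with `sigma`, `df` (N - k), `mean` (grand mean),
#'   `n_records`, `n_subjects`.
#' @export
residual_sd <- function(table, trait) {
  d <- table[table$trait == trait, , drop = FALSE]
  if (nrow(d) == 0) stop("no records for trait ", trait)
  d <- d[is.finite(d$value), , drop = FALSE]
  k <- length(unique(d$subject_id))
  n <- nrow(d)
  if (n - k < 1)
    stop("fewer than 1 residual degree of freedom for trait ", trait)
  fit <- if (k > 1) stats::lm(value ~ factor(subject_id), data = d)
         else stats::lm(value ~ 1, data = d)
  sigma <- sqrt(sum(stats::residuals(fit)^2) / (n - k))
  list(sigma = sigma, df = n - k, mean = mean(d$value),
       n_records = n, n_subjects = k)
}

#' Coefficient of variation in percent
#'
#' @param sigma residual SD in trait units (non-negative).
#' @param mean population mean of the trait (positive).
#' @return `100 * sigma / mean`.
#' @export
cv_percent <- function(sigma, mean) {
  if (any(mean <= 0)) stop("mean must be positive")
  if (any(sigma < 0)) stop("sigma must be non-negative")
  100 * sigma / mean
}

#' Measurement error implied by a CV and a mean
#'
#' Back-converts a coefficient of variation to trait units:
#' `cv/100 * mean`. Used to express table CVs as concrete errors for an
#' average animal.
#'
#' @param cv coefficient of variation in percent.
#' @param mean trait mean in trait units.
#' @return error in trait units.
#' @export
error_from_cv <- function(cv, mean) {
  if (any(cv < 0)) stop("cv must be non-negative")
  if (any(mean <= 0)) stop("mean must be positive")
  cv / 100 * mean
}

#' 95% repeatability/reproducibility limit
#'
#' The value below which the absolute difference of two determinations
#' falls with 95% probability, assuming Gaussian errors:
#' r = qnorm(0.975) * sqrt(2) * sigma = 2.7718 * sigma.
#'
#' @param sigma residual SD in trait units.
#' @return limit in trait units.
#' @export
limit_95 <- function(sigma) {
  if (any(sigma < 0)) stop("sigma must be non-negative")
  stats::qnorm(0.975) * sqrt(2) * sigma
}

#' Repeatability/reproducibility assessment of a measurement table
#'
#' One row per trait: ANOVA-residual sigma, mean, CV percent, error
#' (reported as sigma itself, matching how table errors relate to the
#' printed CVs and means), the 95% limit and the below-4%-CV quality
#' verdict.
#'
#' @param table a [measurement_table()].
#' @param cv_threshold CV quality threshold in percent (default 4).
#' @return data.frame of class `variability_result`.
#' @export
assess <- function(table, cv_threshold = 4) {
  traits <- unique(table$trait)
  rows <- lapply(traits, function(tr) {
    r <- residual_sd(table, tr)
    cv <- cv_percent(r$sigma, r$mean)
    data.frame(trait = tr, sigma = r$sigma, mean = r$mean,
               cv_percent = cv, error = r$sigma,
               limit_r = limit_95(r$sigma),
               n_subjects = r$n_subjects, n_records = r$n_records,
               df = r$df, verdict_below_4pct = cv < cv_threshold,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("variability_result", "data.frame")
  out
}
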