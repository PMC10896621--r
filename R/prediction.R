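#' Published prediction equations
#'
#' Linear equations converting partial to total measurements and predicting
#' body weight from morphological traits, with the published coefficients
#' as immutable defaults:
#' \deqn{TV = 1.0704 \, PV + 0.015 \quad (m^3)}
#' \deqn{TS = 1.07 \, PS + 0.94 \quad (m^2)}
#' \deqn{BW = 644 \, TV + 408 \, HW + 271 \, WB - 199 \quad (kg)}
#' All equation math is in SI units (m^3, m^2, m, kg); volumes in liters
#' are converted at the reporting layer (1 m^3 = 1000 L). In the body
#' weight equation HW is hip width (not withers height).
#'
#' @param tv_slope,tv_intercept_m3 total-volume equation coefficients.
#' @param ts_slope,ts_intercept_m2 total-surface equation coefficients.
#' @param bw_coeff_tv,bw_coeff_hw,bw_coeff_wb,bw_intercept body-weight
#'   equation coefficients (kg per m^3, kg per m, kg per m, kg).
#' @return a `prediction_config` object.
#' @export
prediction_config <- function(tv_slope = 1.0704, tv_intercept_m3 = 0.015,
                              ts_slope = 1.07, ts_intercept_m2 = 0.94,
                              bw_coeff_tv = 644, bw_coeff_hw = 408,
                              bw_coeff_wb = 271, bw_intercept = -199) {
  cfg <- list(tv_slope = tv_slope, tv_intercept_m3 = tv_intercept_m3,
              ts_slope = ts_slope, ts_intercept_m2 = ts_intercept_m2,
              bw_coeff_tv = bw_coeff_tv, bw_coeff_hw = bw_coeff_hw,
              bw_coeff_wb = bw_coeff_wb, bw_intercept = bw_intercept)
  default <- list(tv_slope = 1.0704, tv_intercept_m3 = 0.015,
                  ts_slope = 1.07, ts_intercept_m2 = 0.94,
                  bw_coeff_tv = 644, bw_coeff_hw = 408,
                  bw_coeff_wb = 271, bw_intercept = -199)
  changed <- names(cfg)[!mapply(identical, cfg, default)]
  if (length(changed) > 0) {
    message("prediction_config: non-default coefficients: ",
            paste(changed, collapse = ", "))
  }
  structure(cfg, class = "prediction_config", non_default = changed)
}

#' Total volume from partial volume
#'
#' @param pv partial volume (shoulder/rump cutoff) in m^3, non-negative.
#' @param config a [prediction_config()].
#' @return total volume in m^3.
#' @export
total_volume_from_partial <- function(pv, config = prediction_config()) {
  if (any(pv < 0)) stop("partial volume must be non-negative")
  config$tv_slope * pv + config$tv_intercept_m3
}

#' Total surface from partial surface
#'
#' @param ps partial surface area in m^2, non-negative.
#' @param config a [prediction_config()].
#' @return total surface area in m^2.
#' @export
total_surface_from_partial <- function(ps, config = prediction_config()) {
  if (any(ps < 0)) stop("partial surface must be non-negative")
  config$ts_slope * ps + config$ts_intercept_m2
}

# Twice the adult trait envelope; inputs outside it are implausible for
# a standing animal and trigger a warning (never an error).
bw_plausible_range <- list(tv = c(0.25, 1.6), hw = c(0.2, 1.2),
                           wb = c(0.2, 1.2))

#' Predict body weight from total volume, hip width and buttocks width
#'
#' @param tv total volume in m^3.
#' @param hw hip width in m (distance between hip landmarks, not withers
#'   height).
#' @param wb buttocks width in m.
#' @param config a [prediction_config()].
#' @return predicted body weight in kg.
#' @export
predict_bw <- function(tv, hw, wb, config = prediction_config()) {
  if (any(c(tv, hw, wb) < 0)) stop("inputs must be non-negative")
  implausible <- any(tv < bw_plausible_range$tv[1] | tv > bw_plausible_range$tv[2] |
                     hw < bw_plausible_range$hw[1] | hw > bw_plausible_range$hw[2] |
                     wb < bw_plausible_range$wb[1] | wb > bw_plausible_range$wb[2])
  if (implausible)
    warning("inputs outside the plausible adult-cattle envelope; ",
            "prediction may be meaningless")
  config$bw_coeff_tv * tv + config$bw_coeff_hw * hw +
    config$bw_coeff_wb * wb + config$bw_intercept
}

#' Convert between cubic meters and liters
#' @param m3 volume in cubic meters.
#' @return volume in liters.
#' @export
m3_to_liters <- function(m3) 1000 * m3

#' @rdname m3_to_liters
#' @param liters volume in liters.
#' @export
liters_to_m3 <- function(liters) liters / 1000
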