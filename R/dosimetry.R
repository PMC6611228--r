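# Internal canonical units: hours, MBq, Gy. S-values are accepted in the
# conventional cGy MBq^-1 d^-1 of monolayer dosimetry tables and converted
# at the boundary (1 cGy/d = 0.01/24 Gy/h).

Y90_HALF_LIFE_H <- 64.1

#' Physical decay parameters
#'
#' The decay constant is always derived from the half-life, never stored
#' independently, so the pair can never fall out of step.
#'
#' @param T_phys Physical half-life in hours. Default is the Y-90 value,
#'   64.1 h.
#' @return A list with components `T_phys` (hours) and `lambda` (per hour).
#' @examples
#' decay_params()$lambda * 64.1 / log(2)  # exactly 1
#' @export
decay_params <- function(T_phys = Y90_HALF_LIFE_H) {
  stopifnot(is.numeric(T_phys), length(T_phys) == 1L, T_phys > 0)
  list(T_phys = T_phys, lambda = log(2) / T_phys)
}

#' Describe a Y-90 exposure scenario
#'
#' Bundles initial activity, the start/end S-values of the monolayer (the
#' S-value drifts linearly over the exposure as medium evaporates), the
#' exposure duration and the decay parameters.
#'
#' @param A0 Initial activity, MBq.
#' @param s_initial,s_final S-value at the start and end of the exposure,
#'   cGy MBq^-1 d^-1.
#' @param T Exposure duration, hours.
#' @param decay A list from [decay_params()].
#' @return An object of class `exposure_config`.
#' @export
exposure_config <- function(A0, s_initial, s_final = s_initial, T,
                            decay = decay_params()) {
  stopifnot(is.numeric(A0), length(A0) == 1L, is.numeric(T), length(T) == 1L)
  if (A0 < 0) stop("initial activity must be non-negative")
  if (T < 0) stop("exposure duration must be non-negative")
  if (s_initial < 0 || s_final < 0) stop("S-values must be non-negative")
  structure(
    list(A0 = A0, s_initial = s_initial, s_final = s_final, T = T,
         decay = decay),
    class = "exposure_config"
  )
}

#' Linearly interpolated S-value during an exposure
#'
#' @param s_initial,s_final S-values bracketing the exposure,
#'   cGy MBq^-1 d^-1.
#' @param t Time since the start of the exposure, hours (vectorised).
#' @param T Exposure duration, hours.
#' @return S-value(s) at `t`, cGy MBq^-1 d^-1.
#' @examples
#' s_value_at(40, 60, t = 36, T = 72)  # 50, the midpoint
#' @export
s_value_at <- function(s_initial, s_final, t, T) {
  stopifnot(T >= 0)
  if (any(t < 0 | t > T)) stop("t must lie within the exposure window [0, T]")
  if (T == 0) return(rep_len(s_initial, length(t)))
  s_initial + (s_final - s_initial) * t / T
}

# (1 - (1 + x) e^-x) / x, the protracted-decay shape factor of the
# evaporation term; series branch avoids cancellation for small x.
.decay_drift_factor <- function(x) {
  ifelse(x < 1e-6,
         x / 2 - x^2 / 3 + x^3 / 8,
         (1 - (1 + x) * exp(-x)) / x)
}

.s_cgy_day_to_gy_hour <- function(s) s * 0.01 / 24

#' Cumulated absorbed dose for a decaying source with evaporating medium
#'
#' Closed form of the integral of activity times S-value,
#' \deqn{D(T) = \int_0^T A_0 e^{-\lambda t} S(t)\, dt,}
#' where S(t) is interpolated linearly between the start and end of the
#' exposure. Reduces to the unmodified constant-S MIRD cumulated-activity
#' formula when `s_final == s_initial`.
#'
#' @param cfg An [exposure_config()].
#' @return Cumulated dose in Gy.
#' @examples
#' cfg <- exposure_config(A0 = 20, s_initial = 47.3, T = 144)
#' cumulated_dose(cfg)  # about 28.8 Gy over a 6 d exposure
#' @export
cumulated_dose <- function(cfg) {
  stopifnot(inherits(cfg, "exposure_config"))
  if (cfg$T == 0) return(0)
  lam <- cfg$decay$lambda
  si <- .s_cgy_day_to_gy_hour(cfg$s_initial)
  sf <- .s_cgy_day_to_gy_hour(cfg$s_final)
  x <- lam * cfg$T
  (cfg$A0 / lam) * ((sf - si) * .decay_drift_factor(x) + si * (-expm1(-x)))
}

#' Instantaneous dose rate during an exposure
#'
#' @param cfg An [exposure_config()].
#' @param t Time since the start of the exposure, hours (vectorised).
#' @return Dose rate in Gy per minute.
#' @export
dose_rate <- function(cfg, t) {
  stopifnot(inherits(cfg, "exposure_config"))
  if (any(t < 0 | t > cfg$T)) stop("t must lie within the exposure window [0, T]")
  s <- s_value_at(cfg$s_initial, cfg$s_final, t, cfg$T)
  cfg$A0 * exp(-cfg$decay$lambda * t) * .s_cgy_day_to_gy_hour(s) / 60
}

#' Monolayer S-values by dish position and Y-90 formulation
#'
#' Monte Carlo calculated start-of-exposure S-values for a 15 um cell
#' monolayer at each treatment-dish position of the irradiation stack,
#' for free Y-90 chloride and chelated Y-90 DOTATATE. The source
#' non-uniformity of each formulation is already embedded in these
#' constants.
#'
#' @return A data frame with columns `formulation`, `position` and
#'   `s_initial` (cGy MBq^-1 d^-1).
#' @export
s_value_reference <- function() {
  data.frame(
    formulation = rep(c("YCl3", "DOTATATE"), each = 4L),
    position    = rep(c("+2", "+1", "-1", "-2"), 2L),
    s_initial   = c(6.26, 37.9, 31.4, 3.01,
                    8.40, 47.3, 24.3, 2.06),
    stringsAsFactors = FALSE
  )
}

#' Cumulated dose at every dish position of an irradiation stack
#'
#' End-of-exposure S-values are not tabulated; they are expressed as a
#' multiple of the start value through `evaporation_factor` (medium loss
#' of up to a third thins the absorbing layer and raises the S-value).
#'
#' @param A0 Initial activity, MBq.
#' @param formulation `"YCl3"` or `"DOTATATE"`.
#' @param T Exposure duration, hours (default 144, a 6 d exposure).
#' @param evaporation_factor Ratio `s_final / s_initial`, default 1.2.
#' @param decay A list from [decay_params()].
#' @return A data frame with columns `position`, `s_initial`, `s_final`
#'   and `dose_Gy`.
#' @examples
#' dish_dose_table(A0 = 20, formulation = "DOTATATE")
#' @export
dish_dose_table <- function(A0, formulation, T = 144,
                            evaporation_factor = 1.2,
                            decay = decay_params()) {
  if (evaporation_factor < 0) stop("evaporation_factor must be non-negative")
  sv <- s_value_reference()
  sv <- sv[sv$formulation == formulation, ]
  if (nrow(sv) == 0L) {
    stop("unknown formulation: ", formulation,
         " (expected 'YCl3' or 'DOTATATE')")
  }
  s_final <- sv$s_initial * evaporation_factor
  dose <- vapply(seq_len(nrow(sv)), function(i) {
    cumulated_dose(exposure_config(A0, sv$s_initial[i], s_final[i], T, decay))
  }, numeric(1))
  data.frame(position = sv$position, s_initial = sv$s_initial,
             s_final = s_final, dose_Gy = dose, stringsAsFactors = FALSE)
}

#' Read an exposure scenario from a YAML config file
#'
#' Expected keys: `activity_MBq`, `formulation`, `position`, `duration_h`,
#' and optionally `evaporation_factor` (default 1.2) and `T_phys_h`
#' (default 64.1).
#'
#' @param path Path to the YAML file.
#' @return An [exposure_config()].
#' @export
read_exposure_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  needed <- c("activity_MBq", "formulation", "position", "duration_h")
  missing <- setdiff(needed, names(cfg))
  if (length(missing)) {
    stop("exposure config is missing keys: ", paste(missing, collapse = ", "))
  }
  ef <- if (is.null(cfg$evaporation_factor)) 1.2 else cfg$evaporation_factor
  dec <- decay_params(if (is.null(cfg$T_phys_h)) Y90_HALF_LIFE_H else cfg$T_phys_h)
  sv <- s_value_reference()
  row <- sv[sv$formulation == cfg$formulation & sv$position == cfg$position, ]
  if (nrow(row) != 1L) {
    stop("no S-value for formulation '", cfg$formulation,
         "' at position '", cfg$position, "'")
  }
  exposure_config(cfg$activity_MBq, row$s_initial, row$s_initial * ef,
                  cfg$duration_h, dec)
}
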