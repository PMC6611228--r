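# BED and equivalent fractionated-dose conversion between protracted
# Y-90 exposure and external-beam radiotherapy.

#' Parameters of the Y-90 / EBRT equivalence
#'
#' @param rbe_max Maximum RBE at zero dose, alpha_Y90 / alpha_EBRT.
#' @param g_inf Fully-decayed Lea-Catcheside factor, in [0, 1].
#' @param ab_ebrt External-beam alpha/beta ratio, Gy.
#' @param d Fraction size of the reference EBRT schedule, Gy.
#' @return An object of class `equivalence_params`.
#' @export
equivalence_params <- function(rbe_max, g_inf, ab_ebrt, d = 2) {
  stopifnot(ab_ebrt > 0, d >= 0, g_inf >= 0, g_inf <= 1)
  structure(list(rbe_max = rbe_max, g_inf = g_inf, ab_ebrt = ab_ebrt, d = d),
            class = "equivalence_params")
}

#' Biologically effective dose of a fractionated EBRT schedule
#'
#' \eqn{BED = nd(1 + d/(\alpha/\beta))}, with no repopulation term.
#'
#' @param n Number of fractions.
#' @param d Dose per fraction, Gy.
#' @param ab_ebrt Tissue alpha/beta ratio, Gy.
#' @return BED in Gy.
#' @examples
#' bed_fractionated(30, 2, 14.4)
#' @export
bed_fractionated <- function(n, d, ab_ebrt) {
  stopifnot(all(n >= 0), all(d >= 0), all(ab_ebrt > 0))
  n * d * (1 + d / ab_ebrt)
}

#' Biologically effective dose of a Y-90 absorbed dose
#'
#' BED referenced to the external-beam alpha/beta, with the intrinsic
#' effectiveness difference carried by RBE_max and the dose-rate effect
#' by the fully-decayed protraction factor:
#' \eqn{BED = D(RBE_{max} + G_\infty D / (\alpha/\beta)_{EBRT})}.
#'
#' @param D Y-90 absorbed dose, Gy (vectorised).
#' @param params An [equivalence_params()].
#' @return BED in Gy.
#' @export
bed_y90 <- function(D, params) {
  stopifnot(inherits(params, "equivalence_params"), all(D >= 0))
  D * (params$rbe_max + params$g_inf * D / params$ab_ebrt)
}

#' Equivalent fractionated EBRT dose of a Y-90 absorbed dose
#'
#' The EBRT dose, delivered in fractions of size `d`, with the same BED
#' as the Y-90 exposure:
#' \eqn{EQD = D(RBE_{max} + G_\infty D/(\alpha/\beta)) / (1 + d/(\alpha/\beta))}.
#'
#' @inheritParams bed_y90
#' @return EQD in Gy.
#' @examples
#' p <- equivalence_params(rbe_max = 0.388, g_inf = 0.0377, ab_ebrt = 14.4)
#' eqd(60, p)  # about 28.7 Gy in 2 Gy fractions
#' @export
eqd <- function(D, params) {
  bed_y90(D, params) / (1 + params$d / params$ab_ebrt)
}

#' Y-90 dose producing a given level of cell kill
#'
#' Inverts the linear-quadratic effect \eqn{E = \alpha D + \beta D^2}
#' for the dose, taking the positive root (or the linear solution when
#' beta is zero).
#'
#' @param effect Effect level E, in -ln(survival) units; non-negative.
#' @param alpha_y Linear coefficient, per Gy; positive.
#' @param beta_y Quadratic coefficient, per Gy^2; non-negative.
#' @return Dose in Gy.
#' @examples
#' equivalent_y90_dose(2.58, alpha_y = 0.129, beta_y = 0)  # 20 Gy
#' @export
equivalent_y90_dose <- function(effect, alpha_y, beta_y = 0) {
  stopifnot(effect >= 0, alpha_y > 0, beta_y >= 0)
  if (beta_y == 0) return(effect / alpha_y)
  disc <- alpha_y^2 + 4 * beta_y * effect
  root <- (-alpha_y + sqrt(disc)) / (2 * beta_y)
  if (root < 0) stop("no non-negative dose solves the effect equation")
  root
}

#' EQD over a grid of Y-90 doses
#'
#' Doses beyond the 32 Gy ceiling of the clonogenic measurements are
#' flagged as extrapolated.
#'
#' @param D_grid Y-90 absorbed doses, Gy.
#' @param params An [equivalence_params()].
#' @param measured_max Largest dose backed by measurement, Gy.
#' @return A data frame with columns `D`, `eqd` and `extrapolated`.
#' @export
eqd_curve <- function(D_grid, params, measured_max = 32) {
  if (length(D_grid) == 0L) {
    return(data.frame(D = numeric(0), eqd = numeric(0),
                      extrapolated = logical(0)))
  }
  stopifnot(all(D_grid >= 0))
  data.frame(D = D_grid, eqd = eqd(D_grid, params),
             extrapolated = D_grid > measured_max)
}
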