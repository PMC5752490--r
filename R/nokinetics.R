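# First-order NONOate decomposition model. A NONOate donor (e.g. DETA/NO)
# decays exponentially in aqueous medium, releasing `yield` mol NO per mol
# donor (2 for DETA/NO; half-life ~24 h at pH 7.4, 37 C). Free NO is
# consumed by medium and cells; modelling that consumption as a single
# first-order sink with rate k_c gives a quasi-steady NO concentration
#
#   [NO]ss = yield * k_d * D0 / k_c,   k_d = ln 2 / t_half,
#
# which is linear in the donor dose D0. k_c is not derivable from first
# principles here; it is calibrated from one measured (donor, NO) reference
# pair. The quasi-steady approximation holds for times short relative to the
# donor half-life.

#' Construct a NONOate donor model
#'
#' @param d0_um initial donor concentration, uM (>= 0).
#' @param half_life_h donor half-life, hours (> 0); ~24 h for DETA/NO at
#'   pH 7.4 and 37 C.
#' @param yield mol NO released per mol donor (2 for DETA/NO).
#' @param k_c first-order NO consumption rate, per hour; usually set via
#'   [calibrate_kc()].
#' @return object of class `donor_model`.
#' @export
donor_model <- function(d0_um, half_life_h = 24, yield = 2, k_c = NA_real_) {
  if (d0_um < 0) stop("'d0_um' must be >= 0")
  if (half_life_h <= 0) stop("'half_life_h' must be > 0")
  if (yield <= 0) stop("'yield' must be > 0")
  structure(list(d0_um = d0_um, half_life_h = half_life_h, yield = yield,
                 k_d = log(2) / half_life_h, k_c = k_c),
            class = "donor_model")
}

#' @export
print.donor_model <- function(x, ...) {
  cat(sprintf("donor_model: D0 = %g uM, t1/2 = %g h, yield = %g, k_c = %s /h\n",
              x$d0_um, x$half_life_h, x$yield,
              if (is.na(x$k_c)) "uncalibrated" else format(x$k_c)))
  invisible(x)
}

#' Remaining donor concentration
#'
#' `D(t) = D0 * 2^(-t / t_half)`.
#'
#' @param model a [donor_model()].
#' @param t_h time, hours (>= 0; vectorized).
#' @return donor concentration, uM.
#' @examples
#' donor_remaining(donor_model(100), 24) # 50 uM after one half-life
#' @export
donor_remaining <- function(model, t_h) {
  stopifnot(inherits(model, "donor_model"))
  if (any(t_h < 0)) stop("'t_h' must be >= 0")
  model$d0_um * 2^(-t_h / model$half_life_h)
}

#' Cumulative NO released by time t
#'
#' Mass accounting: every decomposed donor molecule yields `yield` NO, so
#' the cumulative release is `yield * (D0 - D(t))`, uM.
#'
#' @inheritParams donor_remaining
#' @return cumulative NO released, uM.
#' @export
cumulative_no <- function(model, t_h) {
  model$yield * (model$d0_um - donor_remaining(model, t_h))
}

#' Calibrate the NO consumption rate from a reference measurement
#'
#' Fixes `k_c` so that the model reproduces one measured steady-state pair:
#' a donor dose `d_ref_um` observed to sustain `no_ref_nm` of NO. With the
#' quasi-steady relation `[NO]ss = yield * k_d * D0 / k_c` this gives
#' `k_c = 1000 * yield * k_d * d_ref_um / no_ref_nm` (the factor 1000
#' converts the donor's uM to the NO's nM scale).
#'
#' @param model a [donor_model()].
#' @param d_ref_um reference donor dose, uM (> 0).
#' @param no_ref_nm measured steady-state NO at that dose, nM (> 0).
#' @return the model with `k_c` set.
#' @examples
#' m <- calibrate_kc(donor_model(1), 100, 100)
#' steady_state_no(m) # 1 nM at 1 uM donor
#' @export
calibrate_kc <- function(model, d_ref_um, no_ref_nm) {
  stopifnot(inherits(model, "donor_model"))
  if (d_ref_um <= 0 || no_ref_nm <= 0)
    stop("reference donor and NO values must be > 0")
  model$k_c <- 1000 * model$yield * model$k_d * d_ref_um / no_ref_nm
  model
}

#' Quasi-steady-state NO concentration
#'
#' `[NO]ss = 1000 * yield * k_d * D0 / k_c` (nM); exactly linear in the
#' donor dose for fixed `k_c`. Valid for exposure times short relative to
#' the donor half-life, over which the release rate is approximately
#' constant.
#'
#' @param model a calibrated [donor_model()].
#' @param d0_um donor dose, uM; defaults to the model's `d0_um`.
#' @return steady-state NO, nM.
#' @export
steady_state_no <- function(model, d0_um = model$d0_um) {
  stopifnot(inherits(model, "donor_model"))
  if (is.na(model$k_c) || model$k_c <= 0)
    stop("'k_c' must be calibrated and > 0; see calibrate_kc()")
  1000 * model$yield * model$k_d * d0_um / model$k_c
}
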