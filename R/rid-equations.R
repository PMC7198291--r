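## The RID prediction equations and the model-derived coefficients.

#' Olson isotope-dilution equation for total liver reserves
#'
#' The classical single-sample prediction
#' `TLR = F * dose * S * a * (H:D - 1)`, where `F` is the fraction of the
#' oral dose absorbed and retained, `a` corrects for catabolic loss of the
#' retained dose by sampling time, `S` is the plasma-to-liver
#' specific-activity ratio, and `H:D` is the plasma hydrogen-to-deuterium
#' ratio (the reciprocal of the tracer-to-tracee ratio).  The `- 1` removes
#' the contribution of the dose itself to the measured pool.
#'
#' @param f_abs_retained Fraction of the dose absorbed and retained (F).
#' @param a_catabolism Catabolic correction factor (a).
#' @param s_ratio Plasma-to-stores specific-activity ratio (S).
#' @param dose Tracer dose, µmol.
#' @param h_to_d Hydrogen-to-deuterium ratio; values <= 1 mean the dose has
#'   not yet diluted and give a flagged non-positive result with a warning.
#' @return Estimated total liver reserves, µmol.
#' @export
#' @examples
#' olson_tlr(0.50, 0.90, 0.65, 100, 11)  # 292.5 umol
olson_tlr <- function(f_abs_retained, a_catabolism, s_ratio, dose, h_to_d) {
  stopifnot(f_abs_retained > 0, a_catabolism > 0, s_ratio > 0, dose > 0,
            is.finite(h_to_d))
  if (h_to_d <= 1)
    warning("h_to_d <= 1: dose not yet diluted; returning a non-positive reserve",
            call. = FALSE)
  f_abs_retained * dose * s_ratio * a_catabolism * (h_to_d - 1)
}

#' Modified isotope-dilution equation for total body stores
#'
#' `TBS = Fa * S / SA_p`: `Fa` is the fraction of the dose absorbed and
#' present in stores at sampling time, `S` the plasma-to-stores
#' specific-activity ratio at that time, and `SA_p` the measured plasma
#' retinol specific activity in fraction of dose per µmol.
#'
#' @param fa Fraction of dose in stores (0-1).
#' @param s Plasma-to-stores specific-activity ratio.
#' @param sa_p Plasma specific activity, fraction of dose per µmol (> 0).
#' @return Total body stores, µmol.  Vectorized over its arguments.
#' @export
#' @examples
#' modified_tbs(0.72, 4.1, 0.01)
modified_tbs <- function(fa, s, sa_p) {
  if (any(!is.finite(sa_p)) || any(sa_p <= 0))
    stop("sa_p must be > 0", call. = FALSE)
  fa * s / sa_p
}

#' Model-derived RID coefficient curves
#'
#' Evaluates the time-varying RID coefficients from a simulated tracer
#' trajectory and the tracee steady-state masses:
#' `Fa(t) = f_6 + f_7` (fraction of dose in stores),
#' `S(t) = (f_5/m_5) / ((f_6+f_7)/(m_6+m_7))` (plasma-to-stores SA ratio,
#' undefined while the stores hold no tracer), and the composite coefficient
#' `FaS(t) = (f_5/m_5) * (m_6+m_7)`, the product `Fa(t) * S(t)` computed
#' without the indeterminate 0/0 at time zero.  Dividing `FaS` by a measured
#' plasma specific activity gives total body stores.
#'
#' @param traj A [tracer_trajectory][simulate_tracer()].
#' @param masses An [rid_masses][steady_state()] from the same parameter set
#'   (checked when the trajectory carries its parameters).
#' @param s_eq Optional equilibrium S value to attach; defaults to
#'   [s_equilibrium()] of the trajectory's parameters when the dietary
#'   intake is positive.
#' @return Object of class `rid_curve`: list with `times`, `fa`, `s` (NA
#'   where undefined), `fas`, and `s_eq` (NA when unavailable).
#' @export
#' @examples
#' p <- example_params()
#' cur <- rid_coefficients(simulate_tracer(p), steady_state(p))
#' cur$s_eq
rid_coefficients <- function(traj, masses, s_eq = NULL) {
  stopifnot(inherits(traj, "tracer_trajectory"), inherits(masses, "rid_masses"))
  if (masses$m_5 <= 0 || (masses$m_6 + masses$m_7) <= 0)
    stop("zero plasma or store mass: RID coefficients undefined", call. = FALSE)
  if (!is.null(traj$params) && !is.null(masses$params)) {
    own <- steady_state(traj$params)
    if (abs(own$tbs - masses$tbs) > 1e-8 * max(own$tbs, 1) ||
        abs(own$m_5 - masses$m_5) > 1e-8 * max(own$m_5, 1))
      stop("masses do not match the trajectory's parameter set", call. = FALSE)
  }
  fa <- traj$f_6 + traj$f_7
  sa_p <- traj$f_5 / masses$m_5
  sa_s <- fa / (masses$m_6 + masses$m_7)
  s <- ifelse(sa_s > 0, sa_p / sa_s, NA_real_)
  fas <- sa_p * (masses$m_6 + masses$m_7)
  if (is.null(s_eq)) {
    s_eq <- if (!is.null(traj$params) && traj$params$dietary_intake > 0)
      s_equilibrium(traj$params, masses) else NA_real_
  }
  structure(list(times = traj$times, fa = fa, s = s, fas = fas, s_eq = s_eq),
            class = "rid_curve")
}

#' @export
print.rid_curve <- function(x, ...) {
  cat(sprintf("RID coefficient curves: %d times over %.3g-%.3g d (S_eq = %.4g)\n",
              length(x$times), min(x$times), max(x$times), x$s_eq))
  show <- x$times %in% c(4, 7, 14, 21)
  if (any(show))
    print(data.frame(time_d = x$times[show], fa = signif(x$fa[show], 4),
                     s = signif(x$s[show], 4), fas = signif(x$fas[show], 4)),
          row.names = FALSE)
  invisible(x)
}

#' @export
as.data.frame.rid_curve <- function(x, ...) {
  data.frame(time_d = x$times, fa = x$fa, s = x$s, fas = x$fas, s_eq = x$s_eq)
}

#' Equilibrium plasma-to-stores specific-activity ratio
#'
#' Long after dosing, with dietary intake constant, the plasma-to-stores SA
#' ratio settles at
#' `S_eq = R(5,6) / (R(5,4) + R(5,6))`,
#' where `R(5,6) = l_5_6 * m_6` is the plasma inflow recycled from the large
#' store and `R(5,4)` the plasma inflow originating from (unlabeled) diet,
#' equal to `absorption_efficiency * dietary_intake` at steady state.  The
#' more dietary vitamin A dilutes plasma retinol, the farther below 1 the
#' plateau; with no intake (and stores frozen at their pre-dose values) the
#' ratio is 1.
#'
#' @param params A [rid_params] object.
#' @param masses Tracee masses defining the store size; defaults to the
#'   steady state of `params`, which then requires positive dietary intake.
#' @return The dimensionless equilibrium ratio.
#' @export
#' @examples
#' s_equilibrium(example_params())  # 0.8 for the packaged parameter set
s_equilibrium <- function(params, masses = steady_state(params)) {
  stopifnot(inherits(params, "rid_params"), inherits(masses, "rid_masses"))
  r54 <- params$absorption_efficiency * params$dietary_intake
  r56 <- params$l_5_6 * masses$m_6
  if (r54 + r56 <= 0)
    stop("equilibrium S undefined: no plasma inflow from diet or stores ",
         "(all masses zero?)", call. = FALSE)
  r56 / (r54 + r56)
}

# Monotone cubic interpolation of a coefficient curve at arbitrary times.
interp_curve <- function(times, values, at) {
  if (any(at < min(times)) || any(at > max(times)))
    stop("requested time outside the simulated grid (",
         min(times), "-", max(times), " d)", call. = FALSE)
  ok <- !is.na(values)
  ord <- order(times[ok])
  x <- times[ok][ord]; y <- values[ok][ord]
  hit <- match(at, x)
  if (!anyNA(hit)) return(y[hit])  # exact grid times need no interpolation
  if (length(x) < 2L)
    stop("curve has fewer than 2 defined points; cannot interpolate", call. = FALSE)
  stats::splinefun(x, y, method = "monoH.FC")(at)
}

#' Predict total body stores from one plasma sample
#'
#' Applies the derived-coefficient prediction
#' `TBS = FaS(t) / SA_p(t)`: the composite coefficient is interpolated on
#' the curve's grid (monotone cubic interpolation) at the sampling time and
#' divided by the measured plasma specific activity.  Sampling before day 4
#' is permitted but flagged with a warning, since the dose may not yet have
#' mixed with stores.
#'
#' @param curve An [rid_curve][rid_coefficients()]: the subject's own curve
#'   or a population-derived one.
#' @param time Sampling time, days (within the curve's grid).
#' @param sa_p Measured plasma specific activity, fraction of dose per µmol.
#' @param subject_id Optional label.
#' @param coefficient_source One of `"population"`, `"individual"`,
#'   `"literature"`; recorded in the result.
#' @return Object of class `tbs_prediction`: one-row data frame with
#'   `subject_id`, `time`, `sa_p`, `tbs` (µmol), `coefficient_source`.
#' @export
#' @examples
#' p <- example_params()
#' cur <- rid_coefficients(simulate_tracer(p), steady_state(p))
#' sa4 <- specific_activity(simulate_tracer(p, c(0, 4)), steady_state(p))
#' predict_tbs(cur, 4, sa4$sa_plasma[2], coefficient_source = "individual")
predict_tbs <- function(curve, time, sa_p, subject_id = NA_character_,
                        coefficient_source = c("population", "individual", "literature")) {
  stopifnot(inherits(curve, "rid_curve"), length(time) == 1L, length(sa_p) == 1L)
  coefficient_source <- match.arg(coefficient_source)
  if (!is.finite(sa_p) || sa_p <= 0)
    stop("sa_p must be > 0", call. = FALSE)
  if (time < 4)
    warning("sampling at ", time, " d is before the 4-d mixing window; ",
            "the prediction may be unreliable", call. = FALSE)
  fas <- interp_curve(curve$times, curve$fas, time)
  out <- data.frame(subject_id = subject_id, time = time, sa_p = sa_p,
                    tbs = fas / sa_p, coefficient_source = coefficient_source,
                    stringsAsFactors = FALSE)
  class(out) <- c("tbs_prediction", "data.frame")
  out
}

#' Ratio of derived-coefficient to individual TBS predictions
#'
#' For a subject sampled at time t, the prediction made with
#' population-derived coefficients relates to the subject's true stores by
#' `TBS_d / TBS_i = (Fa_d * S_d) / (Fa_i * S_i)`; the measured specific
#' activity cancels.
#'
#' @param fa_derived,s_derived Population (derived) coefficients at t.
#' @param fa_individual,s_individual The subject's own coefficients at t.
#' @return The dimensionless prediction ratio.
#' @export
tbs_ratio <- function(fa_derived, s_derived, fa_individual, s_individual) {
  vals <- c(fa_derived, s_derived, fa_individual, s_individual)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("all four coefficients must be positive", call. = FALSE)
  (fa_derived * s_derived) / (fa_individual * s_individual)
}
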