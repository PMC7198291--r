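## Composite ("super-person") fitting of pooled plasma tracer observations.

# Forward model: plasma SA (fraction of dose per umol) at the given times.
model_sa <- function(params, times, n_delay_stages = 25L) {
  grid <- sort(unique(c(0, times)))
  masses <- steady_state(params)
  traj <- simulate_tracer(params, grid, n_delay_stages)
  sa <- specific_activity(traj, masses)
  sa$sa_plasma[match(times, grid)]
}

check_observations <- function(observations) {
  need <- c("subject_id", "time", "sa_p")
  if (!is.data.frame(observations) || !all(need %in% names(observations)))
    stop("observations must be a data frame with columns subject_id, time, sa_p",
         call. = FALSE)
  if (anyNA(observations[need]))
    stop("observations contain missing values", call. = FALSE)
  if (any(observations$time < 0) || any(observations$sa_p < 0))
    stop("observation times and sa_p must be >= 0", call. = FALSE)
  observations
}

# Restore the caller's RNG state after seeded internal draws.
with_local_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Fit the kinetic model to pooled plasma observations
#'
#' Minimizes the relative-error weighted sum of squares
#' `sum(((model(t_i) - sa_i) / max(sa_i, floor))^2)` over the free kinetic
#' parameters, treating all pooled observations as one composite
#' ("super-person") dataset.  Parameters are optimized in log space, which
#' enforces positivity across the orders of magnitude that fractional
#' transfer coefficients span; optimization uses Levenberg-Marquardt
#' ([minpack.lm::nls.lm]) with seeded random multi-start around the initial
#' values.
#'
#' Absorption efficiency cannot be identified from plasma specific activity
#' alone and must be held fixed (from outside information), as must the
#' dose, since specific activity is expressed per unit dose.  The transit
#' delay and dietary intake are fixed by default because sparse post-dose
#' sampling carries little information about them.
#'
#' @param observations Data frame with columns `subject_id`, `time` (days)
#'   and `sa_p` (fraction of dose per µmol), e.g. from
#'   [read_observations()] or [observe_subject()].
#' @param init A [rid_params] object with starting values; fixed parameters
#'   keep these values.
#' @param fixed Character vector of parameter names held fixed.  Must
#'   include `absorption_efficiency` and `dose`.  The default additionally
#'   fixes the transit delay, the dietary intake, the chylomicron clearance
#'   `l_5_4` (too fast to resolve without absorption-phase samples) and the
#'   store output `l_0_6` (its split against plasma catabolism only affects
#'   the slow tail beyond a 28-42 d study), leaving the five plasma-store
#'   exchange and catabolism rates free — a set that is practically
#'   identifiable from post-dose plasma specific activity.
#' @param known_intake Optional dietary intake (µmol/d) overriding
#'   `init$dietary_intake`, e.g. from a dietary survey.
#' @param weight_floor Floor applied to the observed SA in the relative
#'   weights, guarding against division by near-zero values.
#' @param n_starts Number of multi-start initializations (the first is
#'   `init` itself; the rest perturb the free parameters lognormally with
#'   sdlog 0.25).  Best final objective wins; ties keep the first found.
#' @param seed Seed for the multi-start perturbations.
#' @param pre_average If `TRUE`, observations are first collapsed to the
#'   geometric mean of `sa_p` at each distinct time and the fit minimizes
#'   log-scale residuals weighted by the number of samples contributing at
#'   each time (geometric means are the natural center of a constant-CV
#'   error model and live on the log scale).  By default all observations
#'   are pooled unaveraged and the relative-error objective above is used.
#' @param n_delay_stages Stages of the Erlang delay chain in the forward
#'   model.
#' @return Object of class `rid_fit`: list with the fitted `params`, the
#'   `free` and `fixed` names, weighted `residuals`, `fcv` (fractional
#'   standard deviation of each free parameter, from the Jacobian at the
#'   optimum), `converged`, `objective` (final weighted SSQ), `rsstrace`
#'   (objective per accepted iteration of the winning start), and `n_obs`.
#' @export
fit_composite <- function(observations, init,
                          fixed = c("absorption_efficiency", "delay_time",
                                    "dietary_intake", "dose", "l_5_4", "l_0_6"),
                          known_intake = NULL,
                          weight_floor = 1e-12,
                          n_starts = 5L, seed = 1L,
                          pre_average = FALSE,
                          n_delay_stages = 25L) {
  observations <- check_observations(observations)
  stopifnot(inherits(init, "rid_params"))
  bad <- setdiff(fixed, .param_fields)
  if (length(bad))
    stop("unknown parameter name(s) in fixed: ", paste(bad, collapse = ", "),
         call. = FALSE)
  if (!"absorption_efficiency" %in% fixed)
    stop("absorption_efficiency is not identifiable from plasma SA alone ",
         "and must be fixed from outside information", call. = FALSE)
  if (!"dose" %in% fixed)
    stop("dose must be fixed: specific activity is expressed per unit dose",
         call. = FALSE)
  if (!is.null(known_intake)) {
    stopifnot(is.numeric(known_intake), known_intake >= 0)
    init$dietary_intake <- known_intake
  }
  if (pre_average) {
    sp <- split(observations$sa_p, observations$time)
    observations <- data.frame(
      subject_id = "geometric_mean",
      time = as.numeric(names(sp)),
      sa_p = vapply(sp, function(v) exp(mean(log(pmax(v, weight_floor)))), 0),
      n = lengths(sp)
    )
  }
  if (length(unique(observations$time)) < 2L)
    stop("need observations at >= 2 distinct times", call. = FALSE)
  free <- setdiff(.param_fields, fixed)
  if (length(free) == 0L) {
    res <- fit_residuals(numeric(0), character(0), init, observations,
                         weight_floor, n_delay_stages)
    return(structure(
      list(params = init, free = free, fixed = fixed, residuals = res,
           fcv = numeric(0), converged = TRUE, objective = sum(res^2),
           rsstrace = sum(res^2), n_obs = nrow(observations)),
      class = "rid_fit"))
  }
  if (nrow(observations) < length(free))
    stop("fewer observations (", nrow(observations), ") than free parameters (",
         length(free), ")", call. = FALSE)
  if (any(unlist(init[free]) <= 0))
    stop("initial values of free parameters must be > 0 (log-scale fit)",
         call. = FALSE)

  start0 <- log(unlist(init[free]))
  starts <- with_local_seed(seed, {
    lapply(seq_len(max(1L, n_starts)), function(i) {
      if (i == 1L) start0 else start0 + stats::rnorm(length(start0), 0, 0.25)
    })
  })
  best <- NULL
  for (st in starts) {
    fit <- tryCatch(
      minpack.lm::nls.lm(
        par = st,
        fn = function(lp) fit_residuals(lp, free, init, observations,
                                        weight_floor, n_delay_stages),
        control = minpack.lm::nls.lm.control(maxiter = 200)
      ),
      error = function(e) NULL
    )
    if (is.null(fit)) next
    if (is.null(best) || fit$deviance < best$deviance) best <- fit
  }
  if (is.null(best))
    stop("all optimization starts failed", call. = FALSE)

  params <- init
  params[free] <- as.list(exp(best$par))
  params <- validate_rid_params(params)
  converged <- best$info %in% 1:4
  n <- length(best$fvec); p <- length(free)
  fcv <- rep(NA_real_, p); names(fcv) <- free
  if (n > p) {
    resvar <- best$deviance / (n - p)
    covar <- tryCatch(solve(best$hessian), error = function(e) NULL)
    # log-scale standard error is the fractional SD of the parameter itself
    if (!is.null(covar)) fcv <- sqrt(pmax(diag(covar), 0) * resvar)
    names(fcv) <- free
  }
  structure(
    list(params = params, free = free, fixed = fixed,
         residuals = best$fvec, fcv = fcv, converged = converged,
         objective = best$deviance, info = best$info,
         message = best$message, rsstrace = best$rsstrace,
         n_obs = nrow(observations)),
    class = "rid_fit"
  )
}

fit_residuals <- function(log_free, free, init, observations,
                          weight_floor, n_delay_stages) {
  tryCatch({
    params <- init
    if (length(free)) params[free] <- as.list(exp(log_free))
    params <- validate_rid_params(params)
    pred <- suppressWarnings(model_sa(params, observations$time, n_delay_stages))
    if (length(pred) != nrow(observations) || anyNA(pred))
      stop("integration failed")
    if (is.null(observations$n)) {
      # pooled observations: relative (constant-CV) error model
      (pred - observations$sa_p) / pmax(observations$sa_p, weight_floor)
    } else {
      # geometric means live on the log scale; each carries the precision of
      # the n samples it summarizes
      (log(pmax(pred, weight_floor)) - log(pmax(observations$sa_p, weight_floor))) *
        sqrt(observations$n)
    }
  }, error = function(e) rep(1e6, nrow(observations)))  # repel the optimizer
}

#' @export
print.rid_fit <- function(x, ...) {
  cat(sprintf("Composite RID model fit: %d observations, %d free parameters\n",
              x$n_obs, length(x$free)))
  cat(sprintf("  converged: %s   weighted SSQ: %.6g\n", x$converged, x$objective))
  if (length(x$free)) {
    est <- unlist(x$params[x$free])
    print(data.frame(parameter = x$free, estimate = signif(est, 5),
                     fcv = signif(x$fcv, 3)), row.names = FALSE)
  }
  cat(sprintf("  fitted total body stores: %.4g umol\n", steady_state(x$params)$tbs))
  invisible(x)
}

#' Population RID coefficients from a composite fit
#'
#' Runs the fitted parameter set forward (steady state plus tracer
#' simulation) and returns the RID coefficient curve evaluated at the
#' requested times; these are the group-level (derived) coefficients used to
#' predict total body stores for individual subjects.
#'
#' @param fit An [rid_fit][fit_composite()]; must have converged.
#' @param times Times (days) at which to evaluate the coefficients.
#' @param n_delay_stages Stages of the Erlang delay chain.
#' @return An [rid_curve][rid_coefficients()] on `times`.
#' @export
derive_population_coefficients <- function(fit, times, n_delay_stages = 25L) {
  stopifnot(inherits(fit, "rid_fit"))
  if (!isTRUE(fit$converged))
    stop("composite fit did not converge; coefficients withheld", call. = FALSE)
  if (any(times < 0)) stop("times must be >= 0", call. = FALSE)
  grid <- sort(unique(c(0, times)))
  masses <- steady_state(fit$params)
  traj <- simulate_tracer(fit$params, grid, n_delay_stages)
  cur <- rid_coefficients(traj, masses)
  keep <- match(times, grid)
  structure(list(times = times, fa = cur$fa[keep], s = cur$s[keep],
                 fas = cur$fas[keep], s_eq = cur$s_eq),
            class = "rid_curve")
}
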