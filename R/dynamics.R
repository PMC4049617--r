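# Transient simulation: stiff (BDF) integration of the ODE model, the glucose
# pulse protocol, and response-time measurement.

#' Integrate the model through time
#'
#' Stiff BDF integration (deSolve, vode) of the mass-balance ODEs under a
#' constant or time-varying external glucose profile, with the environment
#' otherwise fixed.
#'
#' @param model a \code{glyc_model} (full model).
#' @param init initial state: named or positional concentrations (mM).
#' @param t_end simulation horizon (h).
#' @param glucose_profile either NULL (constant glucose from the model), a
#'   single number, or a function of time (h) returning glucose (mM).
#' @param dt output time step (h, default 0.1).
#' @param rtol,atol integrator tolerances.
#' @return object of class \code{glyc_trajectory}: data.frame \code{states}
#'   (time + concentrations), matrix of instantaneous fluxes, and the
#'   glucose profile evaluated on the grid.
#' @export
simulate_model <- function(model, init, t_end = 500, glucose_profile = NULL,
                           dt = 0.1, rtol = 1e-8, atol = 1e-10) {
  stopifnot(inherits(model, "glyc_model"))
  if (model$kind != "full")
    stop("simulate_model expects the full glycolysis model", call. = FALSE)
  if (!is.null(names(init))) init <- init[species_names()]
  init <- unname(init)
  stopifnot(length(init) == model$dim, all(is.finite(init)), all(init >= 0))

  gfun <- if (is.null(glucose_profile)) {
    g0 <- model$control_value
    function(t) g0
  } else if (is.numeric(glucose_profile)) {
    g0 <- glucose_profile
    function(t) g0
  } else glucose_profile

  cfg <- model$config
  base_pars <- model$pars
  # pre-resolve the glucose-dependent entry of the compiled parameters
  Km_glut <- cfg$constants$glut$Km
  derivs <- function(t, y, parms) {
    p <- base_pars
    g <- gfun(t)
    p$glut_ext <- g / (Km_glut + g)
    list(deriv_from_flux(flux_vector(pmax(y, 0), p)))
  }
  times <- seq(0, t_end, by = dt)
  sol <- deSolve::ode(y = init, times = times, func = derivs, parms = NULL,
                      method = "vode", rtol = rtol, atol = atol,
                      maxsteps = 50000)
  if (attr(sol, "istate")[1] < 0)
    stop("integration failed at t = ", max(sol[, 1]), " h", call. = FALSE)
  st <- as.data.frame(sol)
  names(st) <- c("time", species_names())
  fl <- t(apply(as.matrix(st[, -1]), 1, function(y)
    flux_vector(pmax(y, 0), base_pars)))
  colnames(fl) <- flux_names()
  # fluxes must reflect the instantaneous glucose
  fl[, "GLUT"] <- vapply(seq_len(nrow(st)), function(i) {
    p <- base_pars
    g <- gfun(st$time[i])
    p$glut_ext <- g / (Km_glut + g)
    flux_vector(pmax(as.numeric(st[i, -1]), 0), p)[1]
  }, 0)
  structure(list(states = st, fluxes = fl,
                 glucose = vapply(st$time, gfun, 0),
                 model = model),
            class = "glyc_trajectory")
}

#' @export
print.glyc_trajectory <- function(x, ...) {
  n <- nrow(x$states)
  cat(sprintf("Trajectory: %.1f h in %d steps; terminal J_PFK = %.4f mM/h\n",
              max(x$states$time), n, x$fluxes[n, "PFK"]))
  invisible(x)
}

#' @export
plot.glyc_trajectory <- function(x, what = "PFK", ...) {
  graphics::plot(x$states$time, x$fluxes[, what], type = "l",
                 xlab = "time (h)", ylab = paste0("J_", what, " (mM/h)"), ...)
  invisible(x)
}

# settle: integrate from y0 at constant glucose until approximately steady
settle <- function(model, y0, t_end = 500, rtol = 1e-8, atol = 1e-10) {
  tr <- simulate_model(model, y0, t_end = t_end, dt = t_end / 50,
                       rtol = rtol, atol = atol)
  pmax(as.numeric(tr$states[nrow(tr$states), -1]), 0)
}

#' Glucose pulse protocol
#'
#' Reproduces the transient switch experiment: the system is initialized
#' on the low-flux branch at \code{base_glucose} (inside the bistable
#' window), a rectangular glucose pulse of amplitude \code{pulse_glucose}
#' is applied at \code{t0} for \code{duration} hours, and the run
#' continues until \code{t_end} to see whether the system settles on the
#' high branch (switched) or falls back to the low branch.  PFKFB level
#' does not move the steady states, but it sets the response time of the
#' F26BP pool, so low PFKFB levels fail to switch within a short pulse.
#'
#' @param config a \code{glyc_config}.
#' @param pfkfb_level PFKFB expression level (fraction of reference).
#' @param base_glucose resting glucose (mM), inside the bistable window.
#' @param pulse_glucose glucose during the pulse (mM), above the
#'   switch-up concentration.  Default: base + 3 mM, which for the
#'   reference Loop-2 configuration is about 2 mM above its switch-up
#'   concentration.
#' @param t0 pulse onset (h).
#' @param duration pulse length (h).
#' @param t_end total horizon (h, >= 500 recommended).
#' @param seed seed for the steady-state initialization.
#' @return object of class \code{glyc_pulse}: fields \code{switched},
#'   \code{settle_time}, \code{final_flux}, \code{trajectory} and the
#'   protocol parameters.
#' @export
pulse_protocol <- function(config, pfkfb_level = 1, base_glucose = 5,
                           pulse_glucose = NULL, t0 = 50, duration = 1.5,
                           t_end = 550, seed = 1) {
  stopifnot(inherits(config, "glyc_config"))
  cfg <- set_parameter(config, "level:PFKFB", pfkfb_level)
  m <- glycolysis_model(cfg, glucose = base_glucose)
  ss <- find_steady_states(m, n_starts = 120, seed = seed)
  lab <- vapply(ss$solutions, function(s) s$stability, "")
  stable <- ss$solutions[lab == "stable"]
  if (length(stable) < 2)
    stop("base_glucose is not inside a bistable window for this config",
         call. = FALSE)
  low <- stable[[1]]
  high <- stable[[length(stable)]]
  if (is.null(pulse_glucose)) pulse_glucose <- base_glucose + 3

  prof <- function(t) ifelse(t >= t0 & t < t0 + duration,
                             pulse_glucose, base_glucose)
  tr <- simulate_model(m, unname(low$state), t_end = t_end,
                       glucose_profile = prof)
  Jend <- tr$fluxes[nrow(tr$fluxes), "PFK"]
  switched <- abs(Jend - high$J) < abs(Jend - low$J)
  # settling time: first time after pulse at which flux stays within 1% of
  # its terminal value
  Jt <- tr$fluxes[, "PFK"]
  tt <- tr$states$time
  idx <- which(tt >= t0)
  rel <- abs(Jt[idx] - Jend) / max(abs(Jend), 1e-12)
  settled <- idx[which(rev(cummax(rev(rel))) < 0.01)]
  settle_time <- if (length(settled)) tt[settled[1]] - t0 else NA_real_
  structure(list(switched = switched, settle_time = settle_time,
                 final_flux = Jend, low_flux = low$J, high_flux = high$J,
                 pfkfb_level = pfkfb_level, base_glucose = base_glucose,
                 pulse_glucose = pulse_glucose, t0 = t0,
                 duration = duration, trajectory = tr),
            class = "glyc_pulse")
}

#' @export
print.glyc_pulse <- function(x, ...) {
  cat(sprintf(paste0("Glucose pulse (%g -> %g mM at t = %g h for %g h), ",
                     "PFKFB level %g%%:\n"),
              x$base_glucose, x$pulse_glucose, x$t0, x$duration,
              100 * x$pfkfb_level))
  cat(sprintf("  %s (final J = %.3f; low branch %.3f, high branch %.3f)\n",
              if (x$switched) "switched to the high-flux state"
              else "returned to the low-flux state",
              x$final_flux, x$low_flux, x$high_flux))
  invisible(x)
}

#' Response time of a flux transition
#'
#' First time at which the PFK flux crosses a given fraction (default 0.9)
#' of the gap between its initial and target values.
#'
#' @param trajectory a \code{glyc_trajectory}.
#' @param target_flux target flux (mM/h); default the terminal flux.
#' @param fraction crossing fraction in (0, 1].
#' @return time in hours, or NA if the flux never crosses.
#' @export
response_time <- function(trajectory, target_flux = NULL, fraction = 0.9) {
  stopifnot(inherits(trajectory, "glyc_trajectory"), fraction > 0,
            fraction <= 1)
  Jt <- trajectory$fluxes[, "PFK"]
  if (is.null(target_flux)) target_flux <- Jt[length(Jt)]
  J0 <- Jt[1]
  if (abs(target_flux - J0) < 1e-12) return(NA_real_)
  thr <- J0 + fraction * (target_flux - J0)
  hit <- if (target_flux > J0) which(Jt >= thr) else which(Jt <= thr)
  if (!length(hit)) return(NA_real_)
  trajectory$states$time[hit[1]]
}
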