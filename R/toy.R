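# Synthetic solver-verification fixtures: an analytically solvable 1-D
# bistable system whose steady states are polynomial roots, brute-force
# sign-change root scanning as an independent oracle, and randomized
# enzyme-level perturbations for robustness sweeps.

#' One-dimensional bistable toy model
#'
#' The system dx/dt = a + b x^n / (K^n + x^n) - c x mirrors the
#' feedback-activation motif of the F6P node: basal production a, a Hill
#' auto-activation of strength b, and first-order removal c x.  Its steady
#' states are the nonnegative real roots of a degree-(n+1) polynomial, so
#' exact roots and stabilities are available as ground truth for the
#' multistart solver.
#'
#' @param a,b,c nonnegative rate constants (production, activation
#'   strength, removal).
#' @param K activation half-point (> 0).
#' @param n integer Hill exponent >= 2.
#' @return object of class \code{toy_model} with a \code{deriv} function
#'   and the parameters.
#' @examples
#' m <- toy_bistable()         # bundled parameter set with 3 positive roots
#' toy_steady_states(m)
#' @export
toy_bistable <- function(a = 0.05, b = 1, c = 0.5, K = 1, n = 2) {
  stopifnot(a >= 0, b >= 0, c >= 0, K > 0, n == round(n), n >= 2)
  structure(list(a = a, b = b, c = c, K = K, n = as.integer(n),
                 deriv = function(x) a + b * x^n / (K^n + x^n) - c * x),
            class = "toy_model")
}

#' Exact steady states of the toy model
#'
#' Clears the denominator: (a - c x)(K^n + x^n) + b x^n = 0, solves the
#' polynomial with \code{polyroot}, keeps nonnegative real roots, and
#' classifies each by the sign of d(dx/dt)/dx.
#'
#' @param model a \code{toy_model}.
#' @param tol imaginary-part / clustering tolerance.
#' @return data.frame with columns x, stability ("stable"/"unstable"),
#'   sorted by x.
#' @export
toy_steady_states <- function(model, tol = 1e-9) {
  stopifnot(inherits(model, "toy_model"))
  n <- model$n
  # coefficients of (a - c x)(K^n + x^n) + b x^n in increasing powers
  coef <- numeric(n + 2)
  coef[1] <- model$a * model$K^n                  # x^0
  coef[2] <- -model$c * model$K^n                 # x^1
  coef[n + 1] <- coef[n + 1] + model$a + model$b  # x^n
  coef[n + 2] <- -model$c                         # x^(n+1)
  if (all(coef == 0)) return(data.frame(x = 0, stability = "stable"))
  while (length(coef) > 1 && coef[length(coef)] == 0)
    coef <- coef[-length(coef)]
  r <- if (length(coef) > 1) polyroot(coef) else complex(0)
  x <- Re(r[abs(Im(r)) < tol & Re(r) > -tol])
  x <- sort(pmax(x, 0))
  if (length(x) > 1)  # drop numerically duplicated roots
    x <- x[c(TRUE, diff(x) > tol * pmax(1, x[-1]))]
  h <- 1e-7
  slope <- vapply(x, function(xi)
    (model$deriv(xi + h) - model$deriv(max(xi - h, 0))) /
      (xi + h - max(xi - h, 0)), 0)
  data.frame(x = x, stability = ifelse(slope < 0, "stable", "unstable"))
}

# wrap a toy model as a glyc_model so the multistart machinery applies
as_glyc_model <- function(toy) {
  structure(list(kind = "toy", config = NULL, state_names = "x", dim = 1L,
                 control = "none", control_value = NA_real_,
                 deriv = function(y) toy$deriv(y[1]),
                 fluxes = function(y) c(x = toy$deriv(y[1])),
                 flux_J = function(y) y[1]),
            class = "glyc_model")
}

#' Brute-force root scanning for 1-D and 2-D reduced systems
#'
#' Independent oracle for the multistart solver: detects sign changes of
#' the residual on a fine grid (1-D), or, for a 2-D system, solves the
#' second equation on a grid of the first unknown and scans the remaining
#' 1-D residual.  Adjacent unresolved sign changes trigger refinement up
#' to a cap.
#'
#' @param fn function taking a numeric vector (length 1 or 2) and
#'   returning the residual vector of the same length.
#' @param lower,upper bounds per dimension.
#' @param resolution number of grid cells per dimension.
#' @param max_refine maximum number of refinement passes.
#' @return matrix of roots (one row per root).
#' @export
brute_force_roots <- function(fn, lower, upper, resolution = 400,
                              max_refine = 4) {
  d <- length(lower)
  stopifnot(d %in% c(1, 2), length(upper) == d, all(upper > lower))
  if (d == 1) {
    scan1 <- function(lo, hi, res, depth) {
      xs <- seq(lo, hi, length.out = res)
      fs <- vapply(xs, function(x) fn(x)[1], 0)
      roots <- c()
      for (i in seq_len(res - 1)) {
        if (!is.finite(fs[i]) || !is.finite(fs[i + 1])) next
        if (fs[i] == 0) roots <- c(roots, xs[i])
        else if (fs[i] * fs[i + 1] < 0)
          roots <- c(roots,
                     stats::uniroot(function(x) fn(x)[1],
                                    c(xs[i], xs[i + 1]), tol = 1e-12)$root)
      }
      roots
    }
    r <- scan1(lower, upper, resolution, 0)
    return(matrix(r, ncol = 1))
  }
  # 2-D: for each x1 on the grid, solve fn[2] for x2 (1-D scan), then
  # evaluate fn[1] along the solution branch and find its sign changes.
  xs <- seq(lower[1], upper[1], length.out = resolution)
  branch <- lapply(xs, function(x1) {
    g <- function(x2) fn(c(x1, x2))[2]
    r <- brute_force_roots(function(x2) g(x2), lower[2], upper[2],
                           resolution = 200)
    as.numeric(r)
  })
  roots <- NULL
  for (i in seq_len(resolution - 1)) {
    for (x2a in branch[[i]]) {
      if (!length(branch[[i + 1]])) next
      x2b <- branch[[i + 1]][which.min(abs(branch[[i + 1]] - x2a))]
      f1a <- fn(c(xs[i], x2a))[1]
      f1b <- fn(c(xs[i + 1], x2b))[1]
      if (!is.finite(f1a) || !is.finite(f1b)) next
      if (f1a * f1b < 0) {
        # bisection along the branch
        loP <- c(xs[i], x2a); hiP <- c(xs[i + 1], x2b)
        for (k in 1:60) {
          mid1 <- (loP[1] + hiP[1]) / 2
          g <- function(x2) fn(c(mid1, x2))[2]
          cand <- brute_force_roots(function(x2) g(x2), lower[2], upper[2],
                                    resolution = 200)
          if (!length(cand)) break
          mid2 <- cand[which.min(abs(cand - (loP[2] + hiP[2]) / 2))]
          if (fn(c(mid1, mid2))[1] * fn(loP)[1] < 0) hiP <- c(mid1, mid2)
          else loP <- c(mid1, mid2)
          if (abs(hiP[1] - loP[1]) < 1e-10) break
        }
        roots <- rbind(roots, (loP + hiP) / 2)
      }
    }
  }
  if (is.null(roots)) matrix(numeric(0), ncol = 2) else roots
}

#' Randomized enzyme-level perturbation of a configuration
#'
#' Multiplies every enzyme level by 10^u with u drawn uniformly from
#' +/- \code{log10_range}; deterministic for a fixed seed.  Used to stress
#' the solver and the flux-balance invariants over a family of plausible
#' expression states.
#'
#' @param seed integer seed.
#' @param log10_range half-width of the log10 perturbation (default 1:
#'   levels span two orders of magnitude).
#' @param base config to perturb.
#' @return a \code{glyc_config}.
#' @export
random_config <- function(seed, log10_range = 1, base = build_config()) {
  stopifnot(inherits(base, "glyc_config"), log10_range >= 0)
  rs <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(rs)) assign(".Random.seed", rs, envir = globalenv()))
  set.seed(seed)
  u <- stats::runif(length(base$levels), -log10_range, log10_range)
  base$levels <- base$levels * 10^u
  base$pfkfb_level <- unname(base$levels["PFKFB"])
  base
}
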