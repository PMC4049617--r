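# Multistart steady-state enumeration with eigenvalue stability analysis.
#
# Roots of the balance equations are found by damped Newton iteration in
# log-concentration space (which enforces positivity and handles the
# decade-spanning magnitudes of the intermediates), started from
# pseudorandom initial guesses.  Each converged root is deduplicated,
# checked against the residual bound, and classified by the eigenvalues of
# a finite-difference Jacobian.

# Finite-difference Jacobian in concentration space (central differences).
#' Numerical Jacobian of the model right-hand side
#'
#' Central finite differences with a relative step, evaluated at a state.
#'
#' @param model a \code{glyc_model}.
#' @param state positive state vector (length \code{model$dim}).
#' @param rel_step relative perturbation (default 1e-6).
#' @return square matrix of dimension \code{model$dim}.
#' @export
jacobian <- function(model, state, rel_step = 1e-6) {
  n <- length(state)
  J <- matrix(0, n, n)
  for (j in seq_len(n)) {
    h <- rel_step * max(abs(state[j]), 1e-8)
    yp <- state; yp[j] <- yp[j] + h
    ym <- state; ym[j] <- max(ym[j] - h, 0)
    J[, j] <- (model$deriv(yp) - model$deriv(ym)) / (yp[j] - ym[j])
  }
  if (any(!is.finite(J))) {
    bad <- unique(ceiling(which(!is.finite(J)) / n))
    stop("non-finite Jacobian entries for state variable(s): ",
         paste(model$state_names[bad], collapse = ", "), call. = FALSE)
  }
  J
}

# Damped Newton in u = log(y).  Returns list(root, residual, converged).
newton_log <- function(deriv, u0, tol = 1e-8, maxit = 80) {
  u <- u0
  f <- tryCatch(deriv(exp(u)), error = function(e) NULL)
  if (is.null(f) || any(!is.finite(f))) return(list(converged = FALSE))
  nf <- max(abs(f))
  n <- length(u)
  for (it in seq_len(maxit)) {
    if (nf < tol) return(list(root = exp(u), residual = nf, converged = TRUE))
    # forward-difference Jacobian w.r.t. u
    J <- matrix(0, n, n)
    for (j in seq_len(n)) {
      h <- 1e-7 * max(1, abs(u[j]))
      u2 <- u; u2[j] <- u2[j] + h
      f2 <- deriv(exp(u2))
      J[, j] <- (f2 - f) / h
    }
    step <- tryCatch(solve(J, -f), error = function(e) NULL)
    if (is.null(step) || any(!is.finite(step))) return(list(converged = FALSE))
    smax <- max(abs(step))
    if (smax > 4) step <- step * (4 / smax)   # trust region in log units
    lam <- 1
    for (k in 1:14) {
      un <- u + lam * step
      fn <- tryCatch(deriv(exp(un)), error = function(e) NULL)
      if (!is.null(fn) && all(is.finite(fn)) && max(abs(fn)) < nf) break
      lam <- lam / 2
      fn <- NULL
    }
    if (is.null(fn)) {
      # accept a full step once in a while to escape flat regions
      un <- u + step
      fn <- tryCatch(deriv(exp(un)), error = function(e) NULL)
      if (is.null(fn) || any(!is.finite(fn)) || max(abs(fn)) > 1e6 * nf)
        return(list(converged = FALSE))
    }
    u <- un; f <- fn; nf <- max(abs(f))
    # divergence bail-out: concentrations beyond any physical scale
    if (max(u) > 12) return(list(converged = FALSE))
  }
  if (nf < tol) list(root = exp(u), residual = nf, converged = TRUE)
  else list(converged = FALSE)
}

#' Merge near-identical roots
#'
#' Two roots are merged when their maximum relative component difference is
#' below \code{rel_tol}; the representative with the lowest residual is
#' kept.
#'
#' @param roots list of numeric vectors (equal length).
#' @param residuals numeric vector of residual norms (same length).
#' @param rel_tol relative tolerance (default 1e-4).
#' @return integer indices of the surviving roots.
#' @export
dedupe_roots <- function(roots, residuals = rep(0, length(roots)),
                         rel_tol = 1e-4) {
  keep <- integer(0)
  ord <- order(residuals)
  for (i in ord) {
    dup <- FALSE
    for (j in keep) {
      d <- max(abs(roots[[i]] - roots[[j]]) /
                 pmax(abs(roots[[i]]), abs(roots[[j]]), 1e-9))
      if (d < rel_tol) { dup <- TRUE; break }
    }
    if (!dup) keep <- c(keep, i)
  }
  sort(keep)
}

#' Stability label from eigenvalues
#'
#' Stable iff every eigenvalue real part is below \code{-eps_stab};
#' unstable iff some real part exceeds \code{+eps_stab}; otherwise
#' "marginal" (which bifurcation scans treat as a refinement trigger).
#'
#' @param eigenvalues complex vector.
#' @param eps_stab stability margin (1/h, default 1e-9).
#' @return "stable", "unstable" or "marginal".
#' @export
classify_stability <- function(eigenvalues, eps_stab = 1e-9) {
  mre <- max(Re(eigenvalues))
  if (mre < -eps_stab) "stable"
  else if (mre > eps_stab) "unstable"
  else "marginal"
}

#' Enumerate the steady states of a model
#'
#' Multistart search for all positive real roots of the balance equations:
#' pseudorandom initial guesses (log-uniform over [1e-4, 10] mM by default;
#' a standard-uniform mode over (0, 10] mM is available) are polished by a
#' damped Newton iteration in log-concentration space, deduplicated, and
#' classified by Jacobian eigenvalues.
#'
#' @param model a \code{glyc_model}.
#' @param n_starts number of random starts (>= 1).
#' @param seed integer seed; identical inputs give identical output.
#' @param tol residual bound on max |d/dt| (mM/h).
#' @param rel_tol dedupe tolerance.
#' @param eps_stab stability margin for classification.
#' @param extra_starts optional matrix (rows = states) of additional
#'   deterministic starts, e.g. roots from a neighbouring scan point.
#' @param sampling "log" (default) or "uniform" initial-guess distribution.
#' @return object of class \code{glyc_steady_states}: a list of solutions
#'   sorted by increasing flux, each with fields \code{state},
#'   \code{fluxes}, \code{J} (PFK flux, mM/h), \code{eigenvalues},
#'   \code{stability}, \code{residual} and \code{start}.
#' @export
find_steady_states <- function(model, n_starts = 200, seed = 1,
                               tol = 1e-8, rel_tol = 1e-4, eps_stab = 1e-9,
                               extra_starts = NULL, sampling = c("log", "uniform")) {
  stopifnot(inherits(model, "glyc_model"), n_starts >= 1)
  sampling <- match.arg(sampling)
  n <- model$dim
  rs <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(rs)) assign(".Random.seed", rs, envir = globalenv()))
  set.seed(seed)
  starts <- if (sampling == "log")
    matrix(10^stats::runif(n_starts * n, -4, 1), n_starts, n)
  else matrix(pmax(stats::runif(n_starts * n) * 10, 1e-8), n_starts, n)
  if (!is.null(extra_starts)) {
    extra_starts <- rbind(extra_starts)
    starts <- rbind(as.matrix(extra_starts), starts)
  }

  roots <- list(); resids <- c(); origin <- c()
  for (i in seq_len(nrow(starts))) {
    res <- newton_log(model$deriv, log(pmax(starts[i, ], 1e-12)), tol = tol)
    if (isTRUE(res$converged)) {
      roots[[length(roots) + 1L]] <- res$root
      resids <- c(resids, res$residual)
      origin <- c(origin, i)
    }
  }
  if (!length(roots))
    stop(sprintf(paste0("no steady state converged (%d starts, control %s = %g);",
                        " consider more starts"),
                 nrow(starts), model$control, model$control_value),
         call. = FALSE)
  keep <- dedupe_roots(roots, resids, rel_tol)
  sols <- lapply(keep, function(i) {
    y <- roots[[i]]
    ev <- eigen(jacobian(model, y), only.values = TRUE)$values
    list(state = stats::setNames(y, model$state_names),
         fluxes = model$fluxes(y),
         J = model$flux_J(y),
         eigenvalues = ev,
         stability = classify_stability(ev, eps_stab),
         residual = resids[i], start = origin[i])
  })
  sols <- sols[order(vapply(sols, function(s) s$J, 0))]
  structure(list(solutions = sols, model = model,
                 control = model$control,
                 control_value = model$control_value,
                 n_starts = n_starts, seed = seed),
            class = "glyc_steady_states")
}

#' @export
print.glyc_steady_states <- function(x, ...) {
  cat(sprintf("Steady states at %s = %g mM: %d found\n",
              x$control, x$control_value, length(x$solutions)))
  for (s in x$solutions)
    cat(sprintf("  J_PFK = %10.4f mM/h  [%s]  max Re(eig) = %.3g  resid = %.2g\n",
                s$J, s$stability, max(Re(s$eigenvalues)), s$residual))
  invisible(x)
}

#' @export
as.data.frame.glyc_steady_states <- function(x, ...) {
  do.call(rbind, lapply(x$solutions, function(s) {
    df <- as.data.frame(t(s$state))
    df$J <- s$J
    df$max_re_eig <- max(Re(s$eigenvalues))
    df$stability <- s$stability
    df$residual <- s$residual
    df[[x$control]] <- x$control_value
    df
  }))
}

# counts of stable / unstable / total
state_counts <- function(ss) {
  lab <- vapply(ss$solutions, function(s) s$stability, "")
  c(stable = sum(lab == "stable"), unstable = sum(lab == "unstable"),
    marginal = sum(lab == "marginal"), total = length(lab))
}
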