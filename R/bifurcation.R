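# Quasi-static bifurcation scans: steady states versus a control parameter,
# switch-point detection, bistable-region characterization, and the
# enzyme-level / environment sensitivity analyses built on top of them.

# Build a model for a (config, parameter, value) triple.  "F6P" scans the
# reduced node; everything else scans the full model.
model_at <- function(config, parameter, value, node = c("none", "two", "three")) {
  node <- match.arg(node)
  if (parameter == "F6P") {
    if (node == "none") node <- "three"
    return(f6p_node_model(config, enzymes = node, f6p = value))
  }
  cfg <- if (parameter == "glucose") config else set_parameter(config, parameter, value)
  if (node != "none")
    f6p_node_model(cfg, enzymes = node,
                   f6p = if (node == "two") 0.1 else 0.1)
  else glycolysis_model(cfg, glucose = if (parameter == "glucose") value
                        else unname(cfg$env["GLC_ext"]))
}

#' Quasi-static steady-state scan over a control parameter
#'
#' Enumerates all steady states at every grid value of the control
#' parameter.  Roots found at one grid point seed the solver at the next
#' (nearest-neighbour continuation), in addition to the pseudorandom
#' multistart, so branches are tracked reliably with moderate start counts.
#'
#' @param config a \code{glyc_config}.
#' @param parameter one of "glucose", "F6P" (reduced F6P-node scan), "kp",
#'   "NAD_ratio", "LAC", "ALA", or "level:<ENZYME>".
#' @param grid sorted numeric vector of parameter values.
#' @param node for "F6P" scans, "two" or "three" enzyme node; otherwise
#'   "none" (full model).
#' @param n_starts,seed multistart controls (per point; the point seed is
#'   derived deterministically from \code{seed} and the grid index).
#' @param ... passed to [find_steady_states()].
#' @return object of class \code{glyc_bifurcation}: per-point solution
#'   sets, counts, and the grid.
#' @export
scan_bifurcation <- function(config, parameter = "glucose", grid,
                             node = c("none", "two", "three"),
                             n_starts = 60, seed = 1, ...) {
  stopifnot(inherits(config, "glyc_config"))
  node <- match.arg(node)
  if (is.unsorted(grid)) stop("grid must be sorted", call. = FALSE)
  if (!length(grid))
    return(structure(list(parameter = parameter, grid = numeric(0),
                          points = list(), config = config, node = node,
                          n_starts = n_starts, seed = seed),
                     class = "glyc_bifurcation"))
  prev <- NULL
  points <- vector("list", length(grid))
  for (i in seq_along(grid)) {
    m <- model_at(config, parameter, grid[i], node)
    ss <- tryCatch(find_steady_states(m, n_starts = n_starts,
                                      seed = seed + 7919L * (i - 1L),
                                      extra_starts = prev, ...),
                   error = function(e) NULL)
    # a missed point retries once with a denser multistart before failing
    if (is.null(ss))
      ss <- find_steady_states(m, n_starts = 4L * n_starts,
                               seed = seed + 7919L * (i - 1L) + 13L,
                               extra_starts = prev, ...)
    prev <- do.call(rbind, lapply(ss$solutions, function(s) unname(s$state)))
    points[[i]] <- ss
  }
  structure(list(parameter = parameter, grid = grid, points = points,
                 config = config, node = node, n_starts = n_starts,
                 seed = seed),
            class = "glyc_bifurcation")
}

#' @export
print.glyc_bifurcation <- function(x, ...) {
  cat(sprintf("Bifurcation scan over %s (%d points, %g to %g)\n",
              x$parameter, length(x$grid), min(x$grid), max(x$grid)))
  cnt <- count_table(x)
  mb <- cnt[cnt$stable >= 2, , drop = FALSE]
  if (nrow(mb))
    cat(sprintf("  multistable for %s in [%g, %g]; max %d stable / %d total\n",
                x$parameter, min(mb[[1]]), max(mb[[1]]),
                max(cnt$stable), max(cnt$total)))
  else cat("  monostable over the whole grid\n")
  invisible(x)
}

#' Per-grid-point state counts of a scan
#'
#' @param diagram a \code{glyc_bifurcation}.
#' @return data.frame with the parameter value, stable/unstable/total
#'   counts, and the flux range.
#' @export
count_table <- function(diagram) {
  stopifnot(inherits(diagram, "glyc_bifurcation"))
  do.call(rbind, lapply(seq_along(diagram$grid), function(i) {
    ss <- diagram$points[[i]]
    cc <- state_counts(ss)
    Js <- vapply(ss$solutions, function(s) s$J, 0)
    out <- data.frame(value = diagram$grid[i], stable = cc[["stable"]],
                      unstable = cc[["unstable"]], total = cc[["total"]],
                      J_min = min(Js), J_max = max(Js))
    names(out)[1] <- diagram$parameter
    out
  }))
}

#' Long-format data frame of a scan (one row per steady state)
#'
#' @param x a \code{glyc_bifurcation}.
#' @param ... unused.
#' @return data.frame with parameter value, branch label, concentrations,
#'   flux and stability.
#' @export
as.data.frame.glyc_bifurcation <- function(x, ...) {
  do.call(rbind, lapply(seq_along(x$grid), function(i) {
    ss <- x$points[[i]]
    df <- as.data.frame(ss)
    df[[x$parameter]] <- x$grid[i]
    nst <- sum(df$stability == "stable")
    df$branch <- branch_labels(df$J, df$stability)
    df
  }))
}

# low / intermediate / high by flux ordering among stable states;
# unstable states get "unstable".
branch_labels <- function(J, stability) {
  lab <- rep("unstable", length(J))
  st <- which(stability == "stable")
  st <- st[order(J[st])]
  if (length(st) == 1) lab[st] <- "low"
  else if (length(st) == 2) lab[st] <- c("low", "high")
  else if (length(st) >= 3)
    lab[st] <- c("low", rep("intermediate", length(st) - 2), "high")
  lab
}

# stable-branch existence helpers -------------------------------------

low_exists <- function(ss) {
  # the low branch exists when more than one stable state coexists, or when
  # the unique state is the continuation of the low branch; scans decide by
  # multistability, so here: >= 2 stable states.
  sum(vapply(ss$solutions, function(s) s$stability, "") == "stable") >= 2
}

#' Switch-up and switch-down concentrations of a scan
#'
#' The switch-up concentration is the largest parameter value at which the
#' low branch still exists (the supremum of the multistable region); the
#' switch-down concentration is the smallest value at which the high
#' branch exists (its infimum).  Both edges are refined by bisection,
#' re-solving at midpoints with branch-continuation starts.
#'
#' @param diagram a \code{glyc_bifurcation}.
#' @param refine_to parameter resolution of the bisection (default 0.005
#'   for F6P scans, 0.05 otherwise).
#' @return list with numeric \code{switch_up} and \code{switch_down}
#'   (both \code{NA} for a monostable diagram).
#' @export
switch_points <- function(diagram,
                          refine_to = if (diagram$parameter == "F6P") 0.005 else 0.05) {
  stopifnot(inherits(diagram, "glyc_bifurcation"))
  cnt <- count_table(diagram)
  multi <- cnt$stable >= 2
  if (!any(multi)) return(list(switch_up = NA_real_, switch_down = NA_real_))
  g <- diagram$grid
  i_lo <- min(which(multi)); i_hi <- max(which(multi))

  solve_multi <- function(value, starts) {
    m <- model_at(diagram$config, diagram$parameter, value, diagram$node)
    ss <- tryCatch(find_steady_states(m, n_starts = diagram$n_starts,
                                      seed = diagram$seed,
                                      extra_starts = starts),
                   error = function(e) NULL)
    if (is.null(ss)) FALSE else low_exists(ss)
  }
  starts_at <- function(i) do.call(rbind, lapply(diagram$points[[i]]$solutions,
                                                 function(s) unname(s$state)))

  # switch-up: last parameter with 2 stable branches, refined upward
  lo <- g[i_hi]
  hi <- if (i_hi < length(g)) g[i_hi + 1] else g[i_hi]
  st <- starts_at(i_hi)
  while (hi - lo > refine_to) {
    mid <- (lo + hi) / 2
    if (solve_multi(mid, st)) lo <- mid else hi <- mid
  }
  switch_up <- (lo + hi) / 2

  # switch-down: first parameter with 2 stable branches, refined downward
  hi2 <- g[i_lo]
  lo2 <- if (i_lo > 1) g[i_lo - 1] else g[i_lo]
  st2 <- starts_at(i_lo)
  while (hi2 - lo2 > refine_to) {
    mid <- (lo2 + hi2) / 2
    if (solve_multi(mid, st2)) hi2 <- mid else lo2 <- mid
  }
  switch_down <- (lo2 + hi2) / 2
  list(switch_up = switch_up, switch_down = switch_down)
}

#' Bistable interval of a configuration along a parameter
#'
#' Scans the parameter over \code{bounds} and returns the refined
#' [switch-down, switch-up] interval when at least two stable branches
#' coexist somewhere, or \code{NULL} when the diagram is monostable.
#'
#' @param config a \code{glyc_config}.
#' @param parameter scan parameter (see [scan_bifurcation()]).
#' @param bounds length-2 numeric, finite.
#' @param n_grid number of grid points.
#' @param node node mode for F6P scans.
#' @param ... passed to [scan_bifurcation()].
#' @return list(switch_down, switch_up, diagram) or NULL.
#' @export
bistability_region <- function(config, parameter = "glucose",
                               bounds = c(0.1, 25), n_grid = 40,
                               node = c("none", "two", "three"), ...) {
  stopifnot(is.finite(bounds), length(bounds) == 2)
  node <- match.arg(node)
  grid <- seq(bounds[1], bounds[2], length.out = n_grid)
  d <- scan_bifurcation(config, parameter, grid, node = node, ...)
  sp <- switch_points(d)
  if (is.na(sp$switch_up)) return(NULL)
  list(switch_down = sp$switch_down, switch_up = sp$switch_up, diagram = d)
}

#' Enzyme-level range preserving multistability
#'
#' Varies one enzyme's level over \code{fold_range} (two orders of
#' magnitude by default, centred on the reference level) and reports, per
#' level, whether the glucose diagram is multistable and where its switch
#' points lie.
#'
#' @param config a \code{glyc_config}.
#' @param enzyme_id name from \code{names(enzyme_level_defaults())}.
#' @param levels explicit level multipliers to test (default: 9 points
#'   log-spaced over \code{fold_range}).
#' @param fold_range length-2 multiplier range (default c(0.1, 10)).
#' @param glucose_bounds glucose range scanned per level.
#' @param n_grid glucose grid size per level.
#' @param ... passed to [scan_bifurcation()].
#' @return data.frame with level, bistable flag, switch points.
#' @export
enzyme_sensitivity <- function(config, enzyme_id, levels = NULL,
                               fold_range = c(0.1, 10),
                               glucose_bounds = c(0.25, 20), n_grid = 25,
                               ...) {
  if (is.null(levels))
    levels <- 10^seq(log10(fold_range[1]), log10(fold_range[2]),
                     length.out = 9)
  out <- lapply(levels, function(lv) {
    cfg <- set_parameter(config, paste0("level:", enzyme_id), lv)
    reg <- tryCatch(bistability_region(cfg, "glucose", glucose_bounds,
                                       n_grid = n_grid, ...),
                    error = function(e) NULL)
    data.frame(level = lv, bistable = !is.null(reg),
               switch_down = if (is.null(reg)) NA_real_ else reg$switch_down,
               switch_up = if (is.null(reg)) NA_real_ else reg$switch_up)
  })
  do.call(rbind, out)
}

#' Sensitivity of the steady-state picture to the fixed environment
#'
#' Scans one clamped environment quantity -- the NAD+/NADH ratio, the
#' extracellular lactate concentration or the alanine concentration (with
#' mitochondrial pyruvate held at its default 0.1 mM) -- and tabulates the
#' maximum number of coexisting states and the glucose switch points at
#' each value.
#'
#' @param config a \code{glyc_config}.
#' @param which "NAD_ratio", "LAC" or "ALA".
#' @param values environment values to test.
#' @param glucose_bounds,n_grid glucose scan per value.
#' @param ... passed to [scan_bifurcation()].
#' @return data.frame with value, max stable, max total, switch points.
#' @export
environment_sensitivity <- function(config, which = c("NAD_ratio", "LAC", "ALA"),
                                    values, glucose_bounds = c(0.25, 20),
                                    n_grid = 25, ...) {
  which <- match.arg(which)
  out <- lapply(values, function(v) {
    cfg <- set_parameter(config, which, v)
    grid <- seq(glucose_bounds[1], glucose_bounds[2], length.out = n_grid)
    d <- scan_bifurcation(cfg, "glucose", grid, ...)
    cnt <- count_table(d)
    sp <- switch_points(d)
    data.frame(value = v, max_stable = max(cnt$stable),
               max_total = max(cnt$total),
               switch_down = sp$switch_down, switch_up = sp$switch_up)
  })
  do.call(rbind, out)
}

#' Hysteresis loop along a quasi-static parameter sweep
#'
#' Tracks a single branch continuously: the up-sweep starts from the
#' steady state at the lowest parameter value and follows it as the
#' parameter increases (jumping only when the branch loses existence); the
#' down-sweep mirrors this from the highest value.  Inside a bistable
#' window the two sweeps occupy different branches; outside they coincide.
#'
#' @param config a \code{glyc_config}.
#' @param parameter,grid as in [scan_bifurcation()].
#' @param node node mode.
#' @param n_starts starts used only at the two endpoint initializations.
#' @param seed integer seed.
#' @return data.frame with parameter value, up-sweep flux, down-sweep flux.
#' @export
hysteresis_scan <- function(config, parameter = "glucose", grid,
                            node = c("none", "two", "three"),
                            n_starts = 60, seed = 1) {
  node <- match.arg(node)
  follow <- function(values, from_low) {
    m0 <- model_at(config, parameter, values[1], node)
    ss0 <- find_steady_states(m0, n_starts = n_starts, seed = seed)
    sols <- ss0$solutions
    cur <- if (from_low) sols[[1]] else sols[[length(sols)]]
    y <- unname(cur$state)
    J <- numeric(length(values))
    for (i in seq_along(values)) {
      m <- model_at(config, parameter, values[i], node)
      res <- newton_log(m$deriv, log(pmax(y, 1e-12)))
      if (!isTRUE(res$converged)) {
        ss <- find_steady_states(m, n_starts = n_starts, seed = seed)
        # branch lost: jump to the nearest remaining attractor
        dst <- vapply(ss$solutions,
                      function(s) sum((log(pmax(s$state, 1e-12)) -
                                         log(pmax(y, 1e-12)))^2), 0)
        res <- list(root = unname(ss$solutions[[which.min(dst)]]$state))
      } else {
        # if the Newton polish slid to an unstable root, re-settle by a
        # short integration
        ev <- eigen(jacobian(m, res$root), only.values = TRUE)$values
        if (classify_stability(ev) != "stable") {
          y2 <- settle(m, res$root * (1 + 1e-3), t_end = 200)
          res <- list(root = y2)
        }
      }
      y <- res$root
      J[i] <- m$flux_J(y)
    }
    J
  }
  up <- follow(grid, from_low = TRUE)
  down <- rev(follow(rev(grid), from_low = FALSE))
  out <- data.frame(value = grid, J_up = up, J_down = down)
  names(out)[1] <- parameter
  out
}
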