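# Scripted, parameterized reproductions of the figure-level analyses:
# steady-state diagrams per isozyme set, K/P modulation, pulse transients,
# the in-silico hysteresis protocol, isozyme mixtures, and the
# lactate-to-glucose flux ratio.

#' Reference configuration used by the figure-level experiments
#'
#' The HeLa-like default activates both regulatory loops (PFKL + PKM2)
#' with a PFKFB K/P ratio of 8; its bistable glucose window brackets the
#' 2--4.5 mM range probed by the hysteresis protocol.
#'
#' @return a \code{glyc_config}.
#' @export
hela_config <- function() build_config("PFKL", "PKM2", kp = 8)

experiment_registry <- function() {
  list(
    fig1b  = "two-enzyme F6P node (PFKL): flux vs F6P with switch points",
    fig1d  = "three-enzyme F6P node: bistable window vs PFKFB K/P",
    fig2a  = "full model, PFKP + PKM1 (no loop): flux vs glucose",
    fig2b  = "full model, PFKL + PKM1 (Loop 1): flux vs glucose",
    fig2c  = "full model, PFKP + PKM2 (Loop 2): flux vs glucose",
    fig2d  = "full model, PFKL + PKM2 (both loops): flux vs glucose",
    fig2e  = "full model, PFKL + PKM2: window vs K/P",
    fig4   = "glucose pulse at PFKFB levels 100/50/20/10%",
    figS1  = "two-enzyme node with PFKP: monostable at all K/P",
    figS2  = "full model PFKP + PKM1: monostable at several K/P",
    figS3  = "enzyme-level sensitivity of multistability",
    figS4  = "environment sensitivity: NAD/NADH, lactate, alanine",
    figS5  = "PFK isozyme mixtures",
    figS7  = "lactate-to-glucose flux ratio along the diagram"
  )
}

#' Reproduce a figure-level analysis
#'
#' Runs one registered experiment end-to-end and returns its data tables
#' and derived summary (switch points, state counts, outcome flags).
#' Grids are chosen to finish in seconds to a few minutes each.
#'
#' @param id experiment id; see names of the registry in the error message
#'   of an unknown id.
#' @param seed master seed.
#' @param overrides named list of arguments overriding experiment defaults
#'   (e.g. \code{list(grid = ...)}).
#' @return object of class \code{glyc_experiment} with fields \code{id},
#'   \code{tables} (named list of data frames), \code{summary} (list).
#' @export
reproduce <- function(id, seed = 1, overrides = list()) {
  reg <- experiment_registry()
  if (!id %in% names(reg))
    stop("unknown experiment id; registered: ",
         paste(names(reg), collapse = ", "), call. = FALSE)
  args <- list(seed = seed)
  args[names(overrides)] <- overrides
  res <- switch(id,
    fig1b = exp_node_scan("two", kp = 10, seed = seed),
    fig1d = exp_node_kp(seed = seed),
    fig2a = exp_full_scan("PFKP", "PKM1", seed = seed),
    fig2b = exp_full_scan("PFKL", "PKM1", seed = seed),
    fig2c = exp_full_scan("PFKP", "PKM2", seed = seed),
    fig2d = exp_full_scan("PFKL", "PKM2", seed = seed),
    fig2e = exp_full_kp(seed = seed),
    fig4  = exp_pulse(seed = seed),
    figS1 = exp_node_scan("two", pfk = "PFKP", kp = 10, seed = seed),
    figS2 = exp_fullS2(seed = seed),
    figS3 = exp_enzyme_sens(seed = seed),
    figS4 = exp_env_sens(seed = seed),
    figS5 = exp_mixtures(seed = seed),
    figS7 = exp_dldg(seed = seed))
  structure(c(list(id = id, description = reg[[id]]), res),
            class = "glyc_experiment")
}

#' @export
print.glyc_experiment <- function(x, ...) {
  cat("Experiment ", x$id, ": ", x$description, "\n", sep = "")
  utils::str(x$summary, max.level = 2, give.attr = FALSE)
  invisible(x)
}

exp_node_scan <- function(enzymes, pfk = "PFKL", kp = 10, seed = 1) {
  cfg <- build_config(pfk, "PKM1", kp = kp)
  # PFK capacity exceeds the ALDO asymptote above ~0.42 mM F6P, where
  # the node has no steady state; scan below that.
  grid <- seq(0.01, 0.40, by = 0.005)
  d <- scan_bifurcation(cfg, "F6P", grid, node = enzymes,
                        n_starts = 25, seed = seed)
  sp <- switch_points(d, refine_to = 0.005)
  list(tables = list(diagram = as.data.frame(d), counts = count_table(d)),
       summary = list(switch_up = sp$switch_up, switch_down = sp$switch_down,
                      bistable = !is.na(sp$switch_up)),
       diagram = d)
}

exp_node_kp <- function(kps = c(0.4, 1, 2, 5, 10, 20, 50), seed = 1) {
  rows <- lapply(kps, function(kp) {
    r <- exp_node_scan("three", kp = kp, seed = seed)
    data.frame(kp = kp, bistable = r$summary$bistable,
               switch_down = r$summary$switch_down,
               switch_up = r$summary$switch_up)
  })
  tab <- do.call(rbind, rows)
  list(tables = list(kp_table = tab),
       summary = list(bistable_kps = tab$kp[tab$bistable],
                      monostable_kps = tab$kp[!tab$bistable]))
}

full_glucose_grid <- function() c(seq(0.5, 8, by = 0.5), 9, 10, 12, 16, 20, 25)

exp_full_scan <- function(pfk, pk, kp = 10, seed = 1, grid = full_glucose_grid(),
                          n_starts = 50) {
  cfg <- build_config(pfk, pk, kp = kp)
  d <- scan_bifurcation(cfg, "glucose", grid, n_starts = n_starts, seed = seed)
  cnt <- count_table(d)
  sp <- switch_points(d, refine_to = 0.1)
  list(tables = list(diagram = as.data.frame(d), counts = cnt),
       summary = list(max_stable = max(cnt$stable),
                      max_total = max(cnt$total),
                      monostable = all(cnt$stable == 1),
                      switch_down = sp$switch_down, switch_up = sp$switch_up),
       diagram = d)
}

exp_full_kp <- function(kps = c(2, 5, 8, 10, 20, 50), seed = 1) {
  rows <- lapply(kps, function(kp) {
    r <- exp_full_scan("PFKL", "PKM2", kp = kp, seed = seed)
    data.frame(kp = kp, max_stable = r$summary$max_stable,
               switch_down = r$summary$switch_down,
               switch_up = r$summary$switch_up)
  })
  tab <- do.call(rbind, rows)
  list(tables = list(kp_table = tab),
       summary = list(kp_with_multistability = tab$kp[tab$max_stable >= 2]))
}

exp_fullS2 <- function(kps = c(5, 10, 50, 100), seed = 1) {
  rows <- lapply(kps, function(kp) {
    r <- exp_full_scan("PFKP", "PKM1", kp = kp, seed = seed)
    data.frame(kp = kp, monostable = r$summary$monostable)
  })
  tab <- do.call(rbind, rows)
  list(tables = list(kp_table = tab),
       summary = list(all_monostable = all(tab$monostable)))
}

exp_pulse <- function(levels = c(1, 0.5, 0.2, 0.1), base_glucose = 5,
                      pulse_glucose = 8, seed = 1) {
  cfg <- build_config("PFKP", "PKM2", kp = 10)
  rows <- lapply(levels, function(lv) {
    p <- pulse_protocol(cfg, pfkfb_level = lv, base_glucose = base_glucose,
                        pulse_glucose = pulse_glucose, seed = seed)
    data.frame(level = lv, switched = p$switched,
               final_flux = p$final_flux, settle_time = p$settle_time)
  })
  tab <- do.call(rbind, rows)
  list(tables = list(pulse_table = tab),
       summary = list(switched_levels = tab$level[tab$switched],
                      returned_levels = tab$level[!tab$switched],
                      base_glucose = base_glucose,
                      pulse_glucose = pulse_glucose))
}

exp_enzyme_sens <- function(enzymes = c("HK", "PFK", "PK", "GLUT"), seed = 1) {
  cfg <- build_config("PFKL", "PKM1", kp = 10)
  tabs <- lapply(enzymes, function(e)
    cbind(enzyme = e,
          enzyme_sensitivity(cfg, e, levels = 10^seq(-1, 1, length.out = 5),
                             glucose_bounds = c(0.5, 16), n_grid = 12,
                             n_starts = 40, seed = seed)))
  tab <- do.call(rbind, tabs)
  wid <- vapply(split(tab, tab$enzyme), function(d) sum(d$bistable), 0)
  list(tables = list(sensitivity = tab),
       summary = list(bistable_levels_per_enzyme = wid))
}

exp_env_sens <- function(seed = 1) {
  cfg <- build_config("PFKL", "PKM2", kp = 10)
  nad <- environment_sensitivity(cfg, "NAD_ratio", c(0.5, 1, 9, 100),
                                 glucose_bounds = c(0.5, 10), n_grid = 12,
                                 n_starts = 40, seed = seed)
  lac <- environment_sensitivity(cfg, "LAC", c(0.5, 5, 30),
                                 glucose_bounds = c(0.5, 10), n_grid = 12,
                                 n_starts = 40, seed = seed)
  ala <- environment_sensitivity(cfg, "ALA", c(0.1, 2, 20),
                                 glucose_bounds = c(0.5, 10), n_grid = 12,
                                 n_starts = 40, seed = seed)
  list(tables = list(NAD_ratio = nad, LAC = lac, ALA = ala),
       summary = list(
         nad_counts = stats::setNames(nad$max_total, nad$value),
         lac_invariant = length(unique(round(lac$switch_up, 1))) == 1,
         ala_shift = ala$switch_up[nrow(ala)] - ala$switch_up[1]))
}

#' Steady-state diagrams for PFK isozyme mixtures
#'
#' Scans the glucose diagram for pure PFK isoforms and mixtures on a
#' simplex grid, with PKM2 as the PK isoform; reports per mixture whether
#' the diagram is multistable and where its switch points lie.
#'
#' @param mixtures list of named weight vectors over PFKM/PFKL/PFKP.
#' @param kp PFKFB K/P ratio.
#' @param seed master seed.
#' @param grid glucose grid.
#' @return data.frame with one row per mixture.
#' @export
isozyme_mixture_scan <- function(mixtures = list(c(PFKM = 1), c(PFKL = 1),
                                                 c(PFKP = 1),
                                                 c(PFKL = 0.7, PFKP = 0.3),
                                                 c(PFKM = 0.5, PFKL = 0.5)),
                                 kp = 10, seed = 1,
                                 grid = full_glucose_grid()) {
  rows <- lapply(mixtures, function(w) {
    cfg <- build_config(pfk = w, pk = "PKM2", kp = kp)
    d <- scan_bifurcation(cfg, "glucose", grid, n_starts = 50, seed = seed)
    cnt <- count_table(d)
    sp <- switch_points(d, refine_to = 0.1)
    data.frame(mixture = paste(sprintf("%s:%.2g", names(w), w),
                               collapse = "+"),
               bistable = max(cnt$stable) >= 2,
               switch_down = sp$switch_down, switch_up = sp$switch_up)
  })
  do.call(rbind, rows)
}

exp_mixtures <- function(seed = 1) {
  tab <- isozyme_mixture_scan(seed = seed)
  list(tables = list(mixtures = tab),
       summary = list(bistable = stats::setNames(tab$bistable, tab$mixture)))
}

#' Lactate-to-glucose flux ratio along a diagram
#'
#' For every steady state of a glucose scan, the ratio of the lactate
#' production flux to the glucose uptake flux.  Stoichiometry bounds the
#' ratio by 2 (two lactate per glucose).
#'
#' @param diagram a \code{glyc_bifurcation} over glucose.
#' @return data.frame with glucose, branch, J_GLUT, J_LDH and the ratio
#'   (NA where the glucose flux is zero).
#' @export
delta_L_over_delta_G <- function(diagram) {
  stopifnot(inherits(diagram, "glyc_bifurcation"))
  do.call(rbind, lapply(seq_along(diagram$grid), function(i) {
    ss <- diagram$points[[i]]
    do.call(rbind, lapply(ss$solutions, function(s) {
      jg <- unname(s$fluxes["GLUT"])
      jl <- unname(s$fluxes["LDH"])
      data.frame(glucose = diagram$grid[i], stability = s$stability,
                 J_GLUT = jg, J_LDH = jl,
                 ratio = if (abs(jg) < 1e-12) NA_real_ else jl / jg)
    }))
  }))
}

exp_dldg <- function(seed = 1) {
  cfg <- hela_config()
  d <- scan_bifurcation(cfg, "glucose", full_glucose_grid(),
                        n_starts = 50, seed = seed)
  tab <- delta_L_over_delta_G(d)
  st <- tab[tab$stability == "stable" & !is.na(tab$ratio), ]
  bist <- split(st, st$glucose)
  per_g <- do.call(rbind, lapply(bist, function(d2)
    data.frame(glucose = d2$glucose[1], low = min(d2$ratio),
               high = max(d2$ratio), n = nrow(d2))))
  list(tables = list(ratio = tab, per_glucose = per_g),
       summary = list(max_ratio = max(st$ratio),
                      high_exceeds_low = all(per_g$high >= per_g$low)))
}

#' Flux conversion from intracellular to cell-specific units
#'
#' Converts mM/h to mmol per 1e9 cells per hour using the configured cell
#' volume (picolitres).
#'
#' @param flux_mM_h numeric flux in mM/h.
#' @param cell_volume_pl cell volume (pL).
#' @return flux in mmol/1e9 cells/h.
#' @export
cell_specific_flux <- function(flux_mM_h, cell_volume_pl = 16) {
  # 1e9 cells * V pL = V * 1e-3 L; mM/h * L = mmol/h
  flux_mM_h * cell_volume_pl * 1e-3
}

#' In-silico analogue of the cultured-cell hysteresis protocol
#'
#' Cells are preconditioned for 12 h at low (0.6 mM) or high (25 mM)
#' glucose, then transferred to test glucose concentrations for a 6 h
#' assay window; the quasi-steady glucose-uptake and lactate fluxes over
#' the assay are reported per (history, test glucose) pair.  Inside the
#' bistable window the realized flux depends on the preconditioning
#' history; at the extremes it does not.
#'
#' @param config a bistable \code{glyc_config} whose switch-down lies
#'   below 2 mM and switch-up above 4.5 mM (default [hela_config()]).
#' @param preconditioning named vector c(LG =, HG =) glucose (mM).
#' @param test_glucose test concentrations (mM).
#' @param precondition_h,assay_h protocol windows (h).
#' @param seed seed for the steady-state initialization.
#' @return data.frame with history, glucose, glucose-uptake and lactate
#'   fluxes (mM/h and mmol/1e9 cells/h).
#' @export
hela_hysteresis_insilico <- function(config = hela_config(),
                                     preconditioning = c(LG = 0.6, HG = 25),
                                     test_glucose = c(0.6, 2, 3, 4.5, 25),
                                     precondition_h = 12, assay_h = 6,
                                     seed = 1) {
  stopifnot(inherits(config, "glyc_config"))
  # verify the required bistable window
  m2 <- glycolysis_model(config, glucose = 2)
  m45 <- glycolysis_model(config, glucose = 4.5)
  ok <- function(m) sum(vapply(find_steady_states(m, n_starts = 80,
                                                  seed = seed)$solutions,
                               function(s) s$stability, "") == "stable") >= 2
  if (!ok(m2) || !ok(m45))
    stop("config is not bistable across the 2-4.5 mM test window",
         call. = FALSE)

  start_state <- function(glucose) {
    m <- glycolysis_model(config, glucose = glucose)
    ss <- find_steady_states(m, n_starts = 80, seed = seed)
    lab <- vapply(ss$solutions, function(s) s$stability, "")
    st <- ss$solutions[lab == "stable"]
    # preconditioning picks the branch the protocol would reach from a
    # fresh culture: the unique state at the extreme glucose
    y0 <- unname(st[[if (glucose <= 1) 1 else length(st)]]$state)
    settle(m, y0, t_end = precondition_h)
  }
  rows <- list()
  for (h in names(preconditioning)) {
    y0 <- start_state(preconditioning[[h]])
    for (g in test_glucose) {
      m <- glycolysis_model(config, glucose = g)
      tr <- simulate_model(m, y0, t_end = assay_h, dt = 0.25)
      n <- nrow(tr$fluxes)
      jg <- mean(tr$fluxes[(n - 8):n, "GLUT"])
      jl <- mean(tr$fluxes[(n - 8):n, "LDH"])
      rows[[length(rows) + 1L]] <- data.frame(
        history = h, glucose = g, J_glc = jg, J_lac = jl,
        q_glc = cell_specific_flux(jg, config$cell_volume_pl),
        q_lac = cell_specific_flux(jl, config$cell_volume_pl))
    }
  }
  do.call(rbind, rows)
}
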