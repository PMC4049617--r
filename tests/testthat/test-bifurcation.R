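# Scans, switch-point detection, hysteresis, and the structural properties
# of the diagrams (fold pairing, count parity).

test_that("empty grid yields an empty diagram", {
  d <- scan_bifurcation(build_config(), "glucose", numeric(0))
  expect_s3_class(d, "glyc_bifurcation")
  expect_equal(length(d$grid), 0)
})

test_that("the no-loop configuration scans to a single saturating branch", {
  cfg <- build_config("PFKP", "PKM1", kp = 10)
  grid <- c(0.5, 1, 2, 4, 8, 16, 25)
  d <- scan_bifurcation(cfg, "glucose", grid, n_starts = 30, seed = 3)
  cnt <- count_table(d)
  expect_true(all(cnt$total == 1))
  expect_true(all(diff(cnt$J_max) > 0))          # monotone nondecreasing flux
  expect_lt(cnt$J_max[7] - cnt$J_max[6], cnt$J_max[2] - cnt$J_max[1]) # saturating
  sp <- switch_points(d)
  expect_true(is.na(sp$switch_up) && is.na(sp$switch_down))
  expect_null(bistability_region(cfg, "glucose", c(0.5, 10), n_grid = 8,
                                 n_starts = 30, seed = 3))
})

test_that("two-enzyme node scan: switch points, parity, branch labels", {
  cfg <- build_config("PFKL", "PKM1", kp = 10)
  grid <- seq(0.02, 0.4, by = 0.01)
  d <- scan_bifurcation(cfg, "F6P", grid, node = "two", n_starts = 20,
                        seed = 2)
  cnt <- count_table(d)
  # counts change by +/-2 across folds (stable/unstable pair creation)
  expect_true(all(diff(cnt$total) %in% c(-2, 0, 2)))
  expect_equal(max(cnt$total), 3)
  sp <- switch_points(d, refine_to = 0.005)
  expect_lt(sp$switch_down, sp$switch_up)
  # branch labels: the middle branch of the bistable region is unstable
  df <- as.data.frame(d)
  tri <- df[df$F6P %in% cnt$F6P[cnt$total == 3], ]
  for (v in unique(tri$F6P)) {
    sub <- tri[tri$F6P == v, ]
    sub <- sub[order(sub$J), ]
    expect_equal(sub$stability, c("stable", "unstable", "stable"))
    expect_equal(sub$branch, c("low", "unstable", "high"))
  }
})

test_that("hysteresis: up and down sweeps split inside the window only", {
  cfg <- build_config("PFKL", "PKM1", kp = 10)
  grid <- seq(0.02, 0.38, by = 0.02)
  h <- hysteresis_scan(cfg, "F6P", grid, node = "two", n_starts = 20,
                       seed = 2)
  d <- scan_bifurcation(cfg, "F6P", grid, node = "two", n_starts = 20,
                        seed = 2)
  sp <- switch_points(d, refine_to = 0.005)
  inside <- h$F6P > sp$switch_down + 0.02 & h$F6P < sp$switch_up - 0.02
  outside <- h$F6P < sp$switch_down - 0.02 | h$F6P > sp$switch_up + 0.02
  reldiff <- abs(h$J_up - h$J_down) / pmax(h$J_up, h$J_down)
  expect_true(all(reldiff[inside] > 0.2))   # distinct branches
  expect_true(all(reldiff[outside] < 1e-6)) # coincide
})

test_that("K/P shifts the node window monotonically and removes it when high", {
  cfg <- function(kp) build_config("PFKL", "PKM1", kp = kp)
  win <- function(kp) {
    grid <- seq(0.02, 0.4, by = 0.01)
    d <- scan_bifurcation(cfg(kp), "F6P", grid, node = "three",
                          n_starts = 20, seed = 2)
    switch_points(d, refine_to = 0.005)
  }
  w1 <- win(1); w5 <- win(5); w50 <- win(50)
  expect_false(is.na(w1$switch_up))
  expect_false(is.na(w5$switch_up))
  expect_true(is.na(w50$switch_up))       # bistability gone at very high K/P
  expect_gt(w1$switch_up, w5$switch_up)   # window at higher F6P for lower K/P
})

test_that("enzyme sensitivity: degenerate range gives a single evaluation", {
  cfg <- build_config("PFKL", "PKM1", kp = 10)
  tab <- enzyme_sensitivity(cfg, "PFK", levels = 1,
                            glucose_bounds = c(1.5, 6), n_grid = 5,
                            n_starts = 30, seed = 3)
  expect_equal(nrow(tab), 1)
  expect_true(tab$bistable)
})

test_that("PFKFB level leaves the steady-state diagram unchanged", {
  cfg <- build_config("PFKL", "PKM2", kp = 10)
  ref <- NULL
  for (lev in c(1, 0.5, 0.2, 0.1)) {
    m <- glycolysis_model(set_parameter(cfg, "level:PFKFB", lev), glucose = 2)
    ss <- find_steady_states(m, n_starts = 50, seed = 4)
    states <- do.call(rbind, lapply(ss$solutions, function(s) unname(s$state)))
    states <- states[order(states[, 3]), , drop = FALSE]
    if (is.null(ref)) ref <- states
    else {
      expect_equal(dim(states), dim(ref))
      expect_lt(max(abs(states - ref) / pmax(abs(ref), 1e-9)), 1e-6)
    }
  }
})
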