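# Multistart solver, numerical Jacobian, stability classification and
# deduplication, validated against the analytic toy oracle and against
# the model's own balance structure.

toy_as_model <- glycoswitch:::as_glyc_model

test_that("jacobian recovers the matrix of a linear system", {
  A <- matrix(c(-2, 1, 0.5, -1), 2, 2)
  lin <- structure(list(kind = "toy", dim = 2L, state_names = c("x", "y"),
                        deriv = function(y) as.numeric(A %*% y)),
                   class = "glyc_model")
  J <- jacobian(lin, c(0.3, 0.7))
  expect_equal(J, A, tolerance = 1e-6)
  # step-size robustness on a full-model steady state
  m <- glycolysis_model(build_config("PFKP", "PKM1", 10), glucose = 5)
  ss <- find_steady_states(m, n_starts = 40, seed = 1)
  y <- unname(ss$solutions[[1]]$state)
  J1 <- jacobian(m, y, rel_step = 1e-5)
  J2 <- jacobian(m, y, rel_step = 1e-7)
  expect_lt(max(abs(J1 - J2)) / max(abs(J1)), 1e-3)
})

test_that("stability labels follow the eigenvalue sign definition", {
  expect_equal(classify_stability(c(-1, -0.2 + 3i, -0.2 - 3i)), "stable")
  expect_equal(classify_stability(c(-1, 0.5)), "unstable")
  expect_equal(classify_stability(c(-1, 1e-12)), "marginal")
})

test_that("dedupe merges jittered copies and keeps distinct roots", {
  set.seed(1)
  true_roots <- list(c(0.1, 1), c(0.5, 2), c(3, 0.02))
  jittered <- lapply(1:50, function(i) {
    r <- true_roots[[(i %% 3) + 1]]
    r * (1 + rnorm(2, sd = 1e-7))
  })
  keep <- dedupe_roots(jittered, rel_tol = 1e-4)
  expect_equal(length(keep), 3)
  # 10% difference in one component is kept separate
  two <- list(c(1, 1), c(1, 1.1))
  expect_equal(length(dedupe_roots(two)), 2)
  expect_equal(length(dedupe_roots(list(c(1, 1), c(1, 1)))), 1)
})

test_that("multistart roots coincide with the polynomial oracle on 100 toy instances", {
  set.seed(99)
  misses <- 0; spurious <- 0
  for (i in 1:100) {
    m <- toy_bistable(a = runif(1, 0, 0.3), b = runif(1, 0.5, 2),
                      c = runif(1, 0.3, 1), K = runif(1, 0.5, 2))
    exact <- toy_steady_states(m)
    exact <- exact[exact$x > 1e-8, ]
    gm <- toy_as_model(m)
    ss <- find_steady_states(gm, n_starts = 40, seed = i)
    found <- vapply(ss$solutions, function(s) unname(s$state), 0)
    for (x in exact$x)
      if (!any(abs(found - x) / max(x, 1e-6) < 1e-6)) misses <- misses + 1
    for (x in found)
      if (!any(abs(exact$x - x) / max(x, 1e-6) < 1e-6)) spurious <- spurious + 1
    # analytic stability agrees with the eigenvalue labels
    if (nrow(exact) == length(found))
      expect_equal(vapply(ss$solutions, function(s) s$stability, ""),
                   exact$stability)
  }
  expect_equal(misses, 0)
  expect_equal(spurious, 0)
})

test_that("solver output is deterministic and satisfies the residual bound", {
  m <- glycolysis_model(build_config("PFKL", "PKM2", 10), glucose = 3)
  s1 <- find_steady_states(m, n_starts = 60, seed = 5)
  s2 <- find_steady_states(m, n_starts = 60, seed = 5)
  expect_identical(lapply(s1$solutions, `[[`, "state"),
                   lapply(s2$solutions, `[[`, "state"))
  for (s in s1$solutions) {
    expect_lt(s$residual, 1e-8)
    expect_lt(max(abs(m$deriv(unname(s$state)))), 1e-8)
    expect_true(all(s$state > 0))
  }
  # sorted by flux
  J <- vapply(s1$solutions, function(s) s$J, 0)
  expect_true(!is.unsorted(J))
})

test_that("flux balance holds at every root of the full model", {
  m <- glycolysis_model(build_config("PFKL", "PKM2", 10), glucose = 3)
  ss <- find_steady_states(m, n_starts = 60, seed = 5)
  for (s in ss$solutions) {
    fl <- s$fluxes
    relequal <- function(a, b) expect_lt(abs(a - b) / max(abs(a), 1e-9), 1e-6)
    relequal(fl[["GLUT"]], fl[["HK"]])
    relequal(fl[["HK"]], fl[["PGI"]])
    relequal(fl[["PGI"]], fl[["PFK"]])
    relequal(fl[["PFK"]], fl[["ALDO"]])
    relequal(fl[["PFKFB_K"]], fl[["PFKFB_P"]])  # net PFKFB flux is zero
    relequal(fl[["GAPDH"]], 2 * fl[["PFK"]])
    relequal(fl[["PK"]], fl[["GAPDH"]])
    relequal(fl[["PK"]], fl[["LDH"]] + fl[["MITO"]] + fl[["ALA"]])
  }
})

test_that("node multistart agrees with 1-D brute-force scanning", {
  cfg <- build_config("PFKL", "PKM1", 10)
  for (f6p in c(0.06, 0.15, 0.35)) {  # mono, bistable, mono
    m <- f6p_node_model(cfg, "two", f6p = f6p)
    ss <- find_steady_states(m, n_starts = 30, seed = 2)
    bf <- sort(as.numeric(brute_force_roots(function(x) m$deriv(x),
                                            1e-6, 30, resolution = 3000)))
    found <- sort(vapply(ss$solutions, function(s) unname(s$state), 0))
    expect_equal(length(found), length(bf))
    expect_equal(found, bf, tolerance = 1e-3)
    if (f6p == 0.15) expect_equal(length(found), 3)
    else expect_equal(length(found), 1)
  }
})

test_that("no-root failure reports diagnostics", {
  # the two-enzyme node has no steady state once PFK capacity exceeds the
  # ALDO asymptote
  m <- f6p_node_model(build_config("PFKL", "PKM1", 10), "two", f6p = 0.6)
  expect_error(find_steady_states(m, n_starts = 20, seed = 1),
               "no steady state converged")
})

test_that("an independent general-purpose solver confirms a model root", {
  skip_if_not_installed("pracma")
  m <- glycolysis_model(build_config("PFKP", "PKM1", 10), glucose = 5)
  ss <- find_steady_states(m, n_starts = 30, seed = 1)
  y <- unname(ss$solutions[[1]]$state)
  alt <- pracma::fsolve(function(v) m$deriv(v), y * 1.05)$x
  expect_equal(alt, y, tolerance = 1e-5)
})
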