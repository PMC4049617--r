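# Rate laws: trivial zeros, monotonicity, isoform contrasts from the
# catalog, and regression pins against independently hand-coded formulas.

test_that("substrate-free rates vanish and negative inputs error", {
  expect_equal(rate_pfk(0, 3, 1, 0.01, 0.2), 0)
  expect_equal(rate_pk(0, 0.8, 1, 3), 0)
  expect_equal(rate_hk(0, 3, 0.1), 0)
  expect_error(rate_pfk(-1, 3), "nonnegative")
  expect_error(rate_pk(0.1, -0.5), "nonnegative")
  expect_error(rate_pfk(0.1, 3, iso = "PFKQ"), "unknown")
  expect_error(rate_chain("FOO", c(F6P = 0.1)), "unknown enzyme_id")
})

test_that("PFK activation: isoform contrast and monotone effectors", {
  # stronger F16BP activation constant (PFKM 0.35 vs PFKL 0.65) gives the
  # larger rate at identical state
  st <- list(F6P = 0.2, ATP = 3, F16BP = 0.5, F26BP = 0.002, AMP = 0.2)
  rM <- do.call(rate_pfk, c(st, iso = "PFKM"))
  rL <- do.call(rate_pfk, c(st, iso = "PFKL"))
  rP <- do.call(rate_pfk, c(st, iso = "PFKP"))
  expect_gte(rM, rL)
  expect_gte(rL, rP)       # PFKP has no F16BP term at all
  # strictly increasing in F26BP (every isoform) and in F16BP (PFKL)
  f26 <- seq(0, 0.05, by = 0.005)
  rf26 <- vapply(f26, function(x) rate_pfk(0.2, 3, 0.2, x, 0.2, "PFKP"), 0)
  expect_true(all(diff(rf26) > 0))
  f16 <- seq(0, 3, by = 0.25)
  rf16 <- vapply(f16, function(x) rate_pfk(0.2, 3, x, 0, 0.2, "PFKL"), 0)
  expect_true(all(diff(rf16) > 0))
  # PFKP is structurally independent of F16BP
  expect_equal(rate_pfk(0.2, 3, 0, 0.002, 0.2, "PFKP"),
               rate_pfk(0.2, 3, 5, 0.002, 0.2, "PFKP"))
})

test_that("PFK activation fold at F16BP = 10 Ka matches the hand-coded law", {
  r <- rate_pfk(0.2, 3, 6.5, 0, 0.2, "PFKL") / rate_pfk(0.2, 3, 0, 0, 0.2, "PFKL")
  expect_equal(r, 9.48182561987147, tolerance = 1e-12)
})

test_that("PK law: isoform Km contrast, ATP inhibition, activation pin", {
  # PKM1 (Km 0.08) reaches half its maximum at lower PEP than PKM2 (0.4)
  # with F16BP = 0
  vmax1 <- rate_pk(500, 0.8, 0, 3, iso = "PKM1")
  vmax2 <- rate_pk(500, 0.8, 0, 3, iso = "PKM2")
  half_pep <- function(iso, vmax) {
    stats::uniroot(function(p) rate_pk(p, 0.8, 0, 3, iso = iso) - vmax / 2,
                   c(1e-6, 10))$root
  }
  expect_lt(half_pep("PKM1", vmax1), half_pep("PKM2", vmax2))
  # increasing ATP decreases the rate; increasing F16BP increases it (PKM2)
  expect_gt(rate_pk(0.1, 0.8, 0.5, 1), rate_pk(0.1, 0.8, 0.5, 5))
  expect_gt(rate_pk(0.1, 0.8, 1, 3), rate_pk(0.1, 0.8, 0.01, 3))
  # PKM1 carries no F16BP activation
  expect_equal(rate_pk(0.1, 0.8, 0, 3, iso = "PKM1"),
               rate_pk(0.1, 0.8, 2, 3, iso = "PKM1"))
  # pinned against the independent evaluation at F16BP = Ka = 0.04
  expect_equal(rate_pk(0.1, 0.8, 0.04, 3, PYR = 0.1, iso = "PKM2"),
               23.3796054691577, tolerance = 1e-12)
})

test_that("HK is monotone nonincreasing in G6P with half-inhibition at Ki", {
  g6p <- seq(0, 5, by = 0.25)
  r <- vapply(g6p, function(x) rate_hk(5, 3, x), 0)
  expect_true(all(diff(r) <= 0))
  ki <- kinetic_defaults()$hk$Ki_g6p
  expect_equal(rate_hk(5, 3, ki), rate_hk(5, 3, 0) / 2, tolerance = 1e-12)
})

test_that("PFKFB net rate: unique internal zero, level-invariant, K/P-monotone", {
  # pure phosphatase limit: net < 0 whenever F26BP > 0
  expect_lt(rate_pfkfb_net(0.2, 3, 0.01, 0, kp = 1e-9), 0)
  # the zero of net() is independent of expression level
  zero_at <- function(level, kp) {
    stats::uniroot(function(x) rate_pfkfb_net(0.2, 3, x, 0.02, kp, level),
                   c(1e-9, 4.9), tol = 1e-13)$root
  }
  z <- vapply(c(1, 0.5, 0.2, 0.1), zero_at, 0, kp = 10)
  expect_equal(max(z) - min(z), 0, tolerance = 1e-10)
  # frozen bisection values and monotone K/P effect
  expect_equal(zero_at(1, 1), 0.000317480475, tolerance = 1e-6)
  expect_equal(zero_at(1, 10), 0.003176620076, tolerance = 1e-6)
  expect_gt(zero_at(1, 10), zero_at(1, 1))
})

test_that("chain enzymes: cofactor dependence, reversibility, ALDO pin", {
  env <- environment_defaults()
  # GAPDH forward requires NAD; with no product present the rate is zero
  env0 <- env; env0["NAD"] <- 0
  expect_equal(rate_chain("GAPDH", c(GAP = 0.1, BPG13 = 0), env0), 0)
  # LDH net rate flips sign across its equilibrium pyruvate
  k <- kinetic_defaults()$ldh
  pyr_eq <- env[["LAC"]] * env[["NAD"]] / (k$Keq * env[["NADH"]])
  expect_lt(rate_chain("LDH", c(PYR = pyr_eq * 0.5), env), 0)
  expect_gt(rate_chain("LDH", c(PYR = pyr_eq * 2), env), 0)
  expect_equal(rate_chain("LDH", c(PYR = pyr_eq), env), 0, tolerance = 1e-12)
  # ALDO at the clamped triose concentrations, pinned vs the hand-coded law
  expect_equal(rate_chain("ALDO", c(F16BP = 0.5, DHAP = 0.04, GAP = 0.02)),
               7.39055793991416, tolerance = 1e-12)
  # ALDO is zero exactly at its equilibrium
  keq <- kinetic_defaults()$aldo$Keq
  expect_equal(rate_chain("ALDO", c(F16BP = 0.04 * 0.02 / keq,
                                    DHAP = 0.04, GAP = 0.02)),
               0, tolerance = 1e-12)
})

test_that("isoform mixtures: degenerate, convex, pinned", {
  st <- list(F6P = 0.2, ATP = 3, F16BP = 0.8, F26BP = 0.005, AMP = 0.2)
  pureL <- do.call(rate_pfk, c(st, iso = "PFKL"))
  pureP <- do.call(rate_pfk, c(st, iso = "PFKP"))
  expect_equal(do.call(mixture_rate_pfk, c(list(c(PFKL = 1)), st)), pureL)
  half <- do.call(mixture_rate_pfk, c(list(c(PFKL = 0.5, PFKP = 0.5)), st))
  expect_gte(half, min(pureL, pureP))
  expect_lte(half, max(pureL, pureP))
  expect_equal(do.call(mixture_rate_pfk, c(list(c(PFKL = 0.8, PFKP = 0.2)), st)),
               15.858671421543, tolerance = 1e-12)
  expect_error(mixture_rate_pfk(c(PFKL = 0.6, PFKP = 0.6), 0.2, 3),
               "sum to 1")
})

test_that("rhs is a stoichiometric balance and zero on the empty pathway", {
  cfg <- build_config("PFKL", "PKM2", kp = 10, env = c(GLC_ext = 0, LAC = 0,
                                                       PYR_m = 0, ALA = 0))
  d <- rhs(stats::setNames(rep(0, 12), species_names()), config = cfg)
  expect_true(all(abs(d) < 1e-12))
  # finite random state: derivatives equal producing-minus-consuming sums
  m <- glycolysis_model(build_config(), glucose = 5)
  y <- c(2, 0.5, 0.2, 0.8, 0.005, 0.05, 0.02, 0.001, 0.1, 0.02, 0.05, 0.1)
  fl <- m$fluxes(y)
  d2 <- m$deriv(y)
  expect_equal(d2[4], unname(fl["PFK"] - fl["ALDO"]))
  expect_equal(d2[7], unname(fl["ALDO"] + fl["TPI"] - fl["GAPDH"]))
  expect_equal(d2[12], unname(fl["PK"] - fl["LDH"] - fl["MITO"] - fl["ALA"]))
})
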