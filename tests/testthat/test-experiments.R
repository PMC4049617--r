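# Figure-level experiments, the hysteresis protocol, mixtures, the
# lactate-to-glucose ratio, and the CLI dispatcher.

test_that("experiment registry rejects unknown ids", {
  expect_error(reproduce("fig99"), "unknown experiment id")
})

test_that("PFKP-only node is monostable at every K/P (saturation kinetics)", {
  for (kp in c(0.5, 10, 50)) {
    cfg <- build_config("PFKP", "PKM1", kp = kp)
    grid <- seq(0.02, 0.4, by = 0.02)
    d <- scan_bifurcation(cfg, "F6P", grid, node = "two", n_starts = 15,
                          seed = 2)
    expect_true(all(count_table(d)$total == 1))
  }
})

test_that("isozyme mixtures: dominant isoform shapes the diagram", {
  tab <- isozyme_mixture_scan(mixtures = list(c(PFKL = 1),
                                              c(PFKL = 0.7, PFKP = 0.3),
                                              c(PFKP = 1)),
                              kp = 10, seed = 2,
                              grid = c(0.5, 1, 2, 3, 4, 5, 6, 8))
  expect_true(tab$bistable[1])           # pure PFKL: Loop-1 window
  expect_true(tab$bistable[2])           # PFKL-dominant mixture stays bistable
  # mixture switch points move relative to the pure isoform
  expect_false(isTRUE(all.equal(tab$switch_up[1], tab$switch_up[2],
                                tolerance = 1e-3)))
})

test_that("pure-mixture diagram is identical to the single-isoform diagram", {
  grid <- c(1, 2, 3)
  d1 <- scan_bifurcation(build_config("PFKL", "PKM2", 10), "glucose", grid,
                         n_starts = 30, seed = 5)
  d2 <- scan_bifurcation(build_config(c(PFKL = 1), "PKM2", 10), "glucose",
                         grid, n_starts = 30, seed = 5)
  expect_equal(as.data.frame(d1), as.data.frame(d2), tolerance = 1e-12)
})

test_that("lactate-to-glucose ratio is stoichiometrically bounded and ordered", {
  cfg <- hela_config()
  d <- scan_bifurcation(cfg, "glucose", c(1.5, 2, 3, 4), n_starts = 40,
                        seed = 3)
  tab <- delta_L_over_delta_G(d)
  ok <- !is.na(tab$ratio)
  expect_true(all(tab$ratio[ok] <= 2))
  # the high-flux branch produces relatively more lactate than the low one
  st <- tab[tab$stability == "stable" & ok, ]
  for (g in unique(st$glucose)) {
    sub <- st[st$glucose == g, ]
    if (nrow(sub) >= 2)
      expect_gt(sub$ratio[which.max(sub$J_GLUT)],
                sub$ratio[which.min(sub$J_GLUT)])
  }
  # pinned recomputation from the raw fluxes
  expect_equal(tab$ratio, tab$J_LDH / tab$J_GLUT, tolerance = 1e-12)
})

test_that("cell-specific flux conversion is linear in the cell volume", {
  expect_equal(cell_specific_flux(100, 3), 0.3)
  expect_equal(cell_specific_flux(0, 3), 0)
})

test_that("hysteresis protocol rejects a non-bistable configuration", {
  expect_error(hela_hysteresis_insilico(build_config("PFKP", "PKM1", 10)),
               "not bistable")
})

test_that("CLI: catalog and steady-states round trip through files", {
  out <- tempfile(fileext = ".csv")
  expect_equal(glyc_main(c("catalog", "--out", out)), 0L)
  tab <- utils::read.csv(out)
  expect_true("PKM2" %in% tab$isoform)
  out2 <- tempfile(fileext = ".csv")
  cfgf <- tempfile(fileext = ".yaml")
  write_config(build_config("PFKP", "PKM1", 10), cfgf)
  expect_equal(glyc_main(c("steady-states", "--config", cfgf,
                           "--glucose", "5", "--seed", "1",
                           "--n-starts", "30", "--out", out2)), 0L)
  ss <- utils::read.csv(out2)
  expect_equal(nrow(ss), 1)
  expect_equal(ss$stability, "stable")
  # identical invocation reproduces the file bit-for-bit
  out3 <- tempfile(fileext = ".csv")
  glyc_main(c("steady-states", "--config", cfgf, "--glucose", "5",
              "--seed", "1", "--n-starts", "30", "--out", out3))
  expect_identical(readLines(out2), readLines(out3))
  expect_equal(glyc_main(character(0)), 2L)
  unlink(c(out, out2, out3, cfgf))
})

test_that("export and manifest write well-formed files", {
  m <- glycolysis_model(build_config("PFKP", "PKM1", 10), glucose = 5)
  ss <- find_steady_states(m, n_starts = 20, seed = 1)
  f <- tempfile(fileext = ".csv")
  export_csv(ss, f)
  expect_true(file.exists(f))
  dir <- tempfile(); dir.create(dir)
  mf <- write_manifest(dir, "test", build_config(), 1, "x.csv")
  j <- jsonlite::read_json(mf)
  expect_equal(j$seed, 1)
  expect_true(nzchar(j$version))
  unlink(c(f, dir), recursive = TRUE)
})
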