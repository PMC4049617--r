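# Independent hand-coded rate evaluations used as oracles for the package's
# rate laws, written directly from the model definitions (not by calling
# package internals), plus small scan utilities shared across test files.

oracle_pfk <- function(F6P, ATP, F16BP, F26BP, AMP, Ka_f16bp = 0.65,
                       level = 1) {
  k <- kinetic_defaults()$pfk
  w <- (F26BP / k$Ka_f26bp)^k$n_f26 + AMP / k$Ka_amp
  if (!is.na(Ka_f16bp)) w <- w + (F16BP / Ka_f16bp)^k$n_fbp
  act <- (k$eps + w) / (1 + w)
  sub <- F6P / (k$Km_f6p + F6P)
  atp <- ATP / (k$Km_atp + ATP) / (1 + (ATP / k$Ki_atp)^2)
  level * k$Vmax * sub * atp * act
}

oracle_pk_pkm2 <- function(PEP, ADP, F16BP, ATP, PYR = 0, level = 1) {
  k <- kinetic_defaults()$pk
  Km <- 0.4 / (1 + F16BP / 0.04)
  level * k$Vmax * PEP^2 / (Km^2 + PEP^2) * ADP / (k$Km_adp + ADP) /
    (1 + ATP / 3.5) / (1 + PYR / k$Ki_pyr)
}

oracle_aldo <- function(F16BP, DHAP, GAP, level = 1) {
  k <- kinetic_defaults()$aldo
  level * k$Vmax * (F16BP - DHAP * GAP / k$Keq) /
    (k$Km_fbp * (1 + F16BP / k$Km_fbp + DHAP / k$Km_dhap + GAP / k$Km_gap))
}

# all steady states of a model over a sorted grid, with continuation
scan_counts <- function(config, grid, parameter = "glucose", node = "none",
                        n_starts = 40, seed = 7) {
  d <- scan_bifurcation(config, parameter, grid, node = node,
                        n_starts = n_starts, seed = seed)
  list(diagram = d, counts = count_table(d))
}
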