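# Rate laws.
#
# Allosteric activation of PFK is modelled as a single saturable activation
# factor A = (eps + w)/(1 + w) where w pools the Hill terms of all bound
# activators (F16BP for PFKM/PFKL, F26BP for every isoform, AMP).  eps is the
# basal activity of the unactivated enzyme; the factor rises monotonically to
# 1 as any activator accumulates, so saturating F26BP occludes the F16BP
# feedback -- the mechanism by which a high PFKFB K/P ratio abolishes
# F6P-node bistability.  Structural absences (no F16BP term for PFKP, none
# for PKM1) are implemented by omitting the term, not by a sentinel constant.

check_nonneg <- function(...) {
  v <- c(...)
  if (any(!is.finite(v)) || any(v < 0))
    stop("concentrations must be finite and nonnegative", call. = FALSE)
}

pfk_activation <- function(F16BP, F26BP, AMP, Ka_f16bp, k) {
  w <- (F26BP / k$Ka_f26bp)^k$n_f26 + AMP / k$Ka_amp
  if (!is.null(Ka_f16bp)) w <- w + (F16BP / Ka_f16bp)^k$n_fbp
  (k$eps + w) / (1 + w)
}

pfk_substrate <- function(F6P, ATP, k) {
  F6P^k$h_f6p / (k$Km_f6p^k$h_f6p + F6P^k$h_f6p) *
    ATP / (k$Km_atp + ATP) / (1 + (ATP / k$Ki_atp)^k$h_iatp)
}

#' Phosphofructokinase rate
#'
#' Isozyme-aware PFK rate law: cooperative F6P saturation, ATP as substrate
#' with high-ATP inhibition, and a pooled saturable activation factor fed by
#' F16BP (PFKM and PFKL only), F26BP (all isoforms) and AMP.
#'
#' @param F6P,ATP,F16BP,F26BP,AMP concentrations (mM).
#' @param iso isoform name ("PFKM", "PFKL", "PFKP").
#' @param level dimensionless multiplier on the reference Vmax.
#' @param constants shared kinetic constants (defaults from
#'   \code{kinetic_defaults()$pfk}).
#' @return rate in mM/h.
#' @export
rate_pfk <- function(F6P, ATP, F16BP = 0, F26BP = 0, AMP = 0,
                     iso = "PFKL", level = 1,
                     constants = kinetic_defaults()$pfk) {
  check_nonneg(F6P, ATP, F16BP, F26BP, AMP)
  cat <- table1_catalog()$PFK
  if (!iso %in% names(cat))
    stop("unknown PFK isoform: ", iso, call. = FALSE)
  Ka <- cat[[iso]]$Ka_f16bp  # NULL for PFKP
  level * constants$Vmax * pfk_substrate(F6P, ATP, constants) *
    pfk_activation(F16BP, F26BP, AMP, Ka, constants)
}

#' PFK rate for an isoform mixture
#'
#' Weighted sum of the isoform rates with the total enzyme level conserved:
#' each isoform contributes \code{weight * rate} at the common level.
#'
#' @param fractions named nonnegative weights over PFKM/PFKL/PFKP summing
#'   to 1 (tolerance 1e-9).
#' @inheritParams rate_pfk
#' @return rate in mM/h.
#' @export
mixture_rate_pfk <- function(fractions, F6P, ATP, F16BP = 0, F26BP = 0,
                             AMP = 0, level = 1,
                             constants = kinetic_defaults()$pfk) {
  if (any(fractions < 0) || abs(sum(fractions) - 1) > 1e-9)
    stop("mixture weights must be nonnegative and sum to 1", call. = FALSE)
  s <- 0
  for (iso in names(fractions)) {
    if (fractions[[iso]] == 0) next
    s <- s + fractions[[iso]] *
      rate_pfk(F6P, ATP, F16BP, F26BP, AMP, iso, level, constants)
  }
  s
}

#' Net PFKFB (F26BP production) rate
#'
#' The bifunctional enzyme's kinase domain synthesizes F26BP from F6P and
#' ATP and is competitively inhibited by PEP; the bisphosphatase domain
#' hydrolyzes F26BP.  The K/P activity ratio multiplies the kinase maximal
#' rate relative to the bisphosphatase, while \code{level} scales both
#' domains equally -- so the internal zero of the net rate (the steady-state
#' F26BP concentration) depends on K/P but not on level.
#'
#' @param F6P,ATP,F26BP,PEP concentrations (mM).
#' @param kp kinase-to-bisphosphatase activity ratio (> 0).
#' @param level PFKFB expression level (scales both domains).
#' @param constants kinetic constants (\code{kinetic_defaults()$pfkfb}).
#' @return net F26BP production rate (kinase - phosphatase), mM/h.
#' @export
rate_pfkfb_net <- function(F6P, ATP, F26BP, PEP = 0, kp = 10, level = 1,
                           constants = kinetic_defaults()$pfkfb) {
  check_nonneg(F6P, ATP, F26BP, PEP)
  if (!(kp > 0)) stop("K/P ratio must be > 0", call. = FALSE)
  k <- constants
  vk <- level * kp * k$kin_unit * k$Vph *
    F6P / (k$Km_f6p + F6P) * ATP / (k$Km_atp + ATP) /
    (1 + (PEP / k$Ki_pep)^k$h_ipep)
  vp <- level * k$Vph * F26BP / (k$Km_f26bp + F26BP)
  vk - vp
}

#' Pyruvate kinase rate
#'
#' Cooperative PEP saturation with the apparent PEP half-saturation lowered
#' by F16BP (feed-forward activation; absent for PKM1), ADP as co-substrate,
#' and ATP inhibition with the isoform-specific Ki.
#'
#' @param PEP,ADP,F16BP,ATP,PYR concentrations (mM); PYR exerts mild
#'   product inhibition.
#' @param iso isoform name: "PKM1", "PKM2", "PKL", "PKR".
#' @param level multiplier on the reference Vmax.
#' @param constants shared constants (\code{kinetic_defaults()$pk}).
#' @return rate in mM/h.
#' @export
rate_pk <- function(PEP, ADP, F16BP = 0, ATP = 0, PYR = 0, iso = "PKM2",
                    level = 1, constants = kinetic_defaults()$pk) {
  check_nonneg(PEP, ADP, F16BP, ATP, PYR)
  cat <- table1_catalog()$PK
  if (!iso %in% names(cat))
    stop("unknown PK isoform: ", iso, call. = FALSE)
  ic <- cat[[iso]]
  Km_app <- if (is.null(ic$Ka_f16bp)) ic$Km_pep
            else ic$Km_pep / (1 + F16BP / ic$Ka_f16bp)
  h <- constants$h_pep
  level * constants$Vmax * PEP^h / (Km_app^h + PEP^h) *
    ADP / (constants$Km_adp + ADP) / (1 + ATP / ic$Ki_atp) /
    (1 + PYR / constants$Ki_pyr)
}

#' Hexokinase rate
#'
#' Michaelis-Menten in intracellular glucose and ATP with product (G6P)
#' feedback inhibition, which is kept active in every configuration.
#'
#' @param GLC_in,ATP,G6P concentrations (mM).
#' @param level multiplier on the reference Vmax.
#' @param constants kinetic constants (\code{kinetic_defaults()$hk}).
#' @return rate in mM/h.
#' @export
rate_hk <- function(GLC_in, ATP, G6P = 0, level = 1,
                    constants = kinetic_defaults()$hk) {
  check_nonneg(GLC_in, ATP, G6P)
  k <- constants
  level * k$Vmax * GLC_in / (k$Km_glc + GLC_in) *
    ATP / (k$Km_atp + ATP) / (1 + (G6P / k$Ki_g6p)^k$h_g6p)
}

#' Rate of a (reversible) chain enzyme
#'
#' Evaluates the rate law of one of the non-allosteric steps: glucose
#' transport (GLUT), PGI, ALDO, TPI, GAPDH, PGK, PGAM, ENO, LDH,
#' mitochondrial pyruvate transport (MITO) or the alanine-linked pyruvate
#' exchange (ALA).  Reversible laws return negative rates beyond their
#' equilibrium point and zero exactly at equilibrium.
#'
#' @param enzyme_id one of "GLUT", "PGI", "ALDO", "TPI", "GAPDH", "PGK",
#'   "PGAM", "ENO", "LDH", "MITO", "ALA".
#' @param state named numeric vector with (a subset of) the species of
#'   [species_names()]; missing species default to 0.
#' @param env named environment vector (see \code{environment_defaults()}).
#' @param config a \code{glyc_config} supplying constants and levels
#'   (default configuration if omitted).
#' @return rate in mM/h.
#' @export
rate_chain <- function(enzyme_id, state, env = environment_defaults(),
                       config = build_config()) {
  full <- stats::setNames(numeric(12), species_names())
  full[names(state)] <- state
  check_nonneg(full, env)
  k <- config$constants
  lv <- config$levels
  y <- full
  switch(enzyme_id,
    GLUT = lv["GLUT"] * k$glut$Vmax *
      (env["GLC_ext"] / (k$glut$Km + env["GLC_ext"]) -
         y["GLC"] / (k$glut$Km + y["GLC"])),
    PGI = lv["PGI"] * k$pgi$Vmax * (y["G6P"] - y["F6P"] / k$pgi$Keq) /
      (k$pgi$Km_g6p * (1 + y["G6P"] / k$pgi$Km_g6p + y["F6P"] / k$pgi$Km_f6p)),
    ALDO = lv["ALDO"] * k$aldo$Vmax *
      (y["F16BP"] - y["DHAP"] * y["GAP"] / k$aldo$Keq) /
      (k$aldo$Km_fbp * (1 + y["F16BP"] / k$aldo$Km_fbp +
                          y["DHAP"] / k$aldo$Km_dhap +
                          y["GAP"] / k$aldo$Km_gap)),
    TPI = lv["TPI"] * k$tpi$Vmax * (y["DHAP"] - y["GAP"] / k$tpi$Keq) /
      (k$tpi$Km_dhap * (1 + y["DHAP"] / k$tpi$Km_dhap +
                          y["GAP"] / k$tpi$Km_gap)),
    GAPDH = lv["GAPDH"] * k$gapdh$Vmax *
      (y["GAP"] * env["NAD"] - y["BPG13"] * env["NADH"] / k$gapdh$Keq) /
      ((k$gapdh$Km_gap + y["GAP"]) * (k$gapdh$Km_nad + env["NAD"])),
    PGK = lv["PGK"] * k$pgk$Vmax *
      (y["BPG13"] * env["ADP"] - y["PG3"] * env["ATP"] / k$pgk$Keq) /
      ((k$pgk$Km_bpg + y["BPG13"]) * (k$pgk$Km_adp + env["ADP"])),
    PGAM = lv["PGAM"] * k$pgam$Vmax * (y["PG3"] - y["PG2"] / k$pgam$Keq) /
      (k$pgam$Km_3pg + y["PG3"] + y["PG2"]),
    ENO = lv["ENO"] * k$eno$Vmax * (y["PG2"] - y["PEP"] / k$eno$Keq) /
      (k$eno$Km_2pg + y["PG2"] + y["PEP"]),
    LDH = lv["LDH"] * k$ldh$Vmax *
      (y["PYR"] * env["NADH"] - env["LAC"] * env["NAD"] / k$ldh$Keq) /
      ((k$ldh$Km_pyr + y["PYR"]) * (k$ldh$Km_nadh + env["NADH"])),
    MITO = lv["MITO"] * k$mito$Vmax *
      (y["PYR"] / (k$mito$Km + y["PYR"]) -
         env["PYR_m"] / (k$mito$Km + env["PYR_m"])),
    ALA = lv["ALA"] * k$ala$Vmax * (y["PYR"] - env["ALA"] / k$ala$Keq) /
      (k$ala$Km_pyr + y["PYR"] + env["ALA"]),
    stop("unknown enzyme_id: ", enzyme_id, call. = FALSE)
  ) |> unname()
}

# ---- compiled fast path -----------------------------------------------
# compile_pars() flattens a config into a plain list with the constant
# environment factors pre-multiplied, so the inner Newton/ODE loops do no
# list traversal or name lookup.

compile_pars <- function(config) {
  stopifnot(inherits(config, "glyc_config"))
  k <- config$constants
  lv <- config$levels
  ev <- config$env
  cat <- config$catalog

  # PFK: per-isoform weights and F16BP constants
  w <- config$pfk_weights
  pfk_Ka <- lapply(names(w), function(i) cat$PFK[[i]]$Ka_f16bp)
  pfk_c <- lv[["PFK"]] * k$pfk$Vmax *
    ev[["ATP"]] / (k$pfk$Km_atp + ev[["ATP"]]) /
    (1 + (ev[["ATP"]] / k$pfk$Ki_atp)^k$pfk$h_iatp)

  pkc <- cat$PK[[config$pk]]
  pk_c <- lv[["PK"]] * k$pk$Vmax *
    ev[["ADP"]] / (k$pk$Km_adp + ev[["ADP"]]) /
    (1 + ev[["ATP"]] / pkc$Ki_atp)

  kinase_c <- lv[["PFKFB"]] * config$kp * k$pfkfb$kin_unit * k$pfkfb$Vph *
    ev[["ATP"]] / (k$pfkfb$Km_atp + ev[["ATP"]])

  list(
    glut_V = lv[["GLUT"]] * k$glut$Vmax, glut_Km = k$glut$Km,
    glut_ext = ev[["GLC_ext"]] / (k$glut$Km + ev[["GLC_ext"]]),
    hk_c = lv[["HK"]] * k$hk$Vmax * ev[["ATP"]] / (k$hk$Km_atp + ev[["ATP"]]),
    hk_Km = k$hk$Km_glc, hk_Ki = k$hk$Ki_g6p, hk_h = k$hk$h_g6p,
    pgi_c = lv[["PGI"]] * k$pgi$Vmax, pgi_Kg = k$pgi$Km_g6p,
    pgi_Kf = k$pgi$Km_f6p, pgi_Keq = k$pgi$Keq,
    pfk_c = pfk_c, pfk_w = unname(w), pfk_Ka = pfk_Ka,
    pfk_Km = k$pfk$Km_f6p, pfk_h = k$pfk$h_f6p, pfk_eps = k$pfk$eps,
    pfk_n = k$pfk$n_fbp, pfk_K26 = k$pfk$Ka_f26bp, pfk_n26 = k$pfk$n_f26,
    pfk_amp = ev[["AMP"]] / k$pfk$Ka_amp,
    kin_c = kinase_c, kin_Kf6p = k$pfkfb$Km_f6p, kin_Kipep = k$pfkfb$Ki_pep,
    kin_hpep = k$pfkfb$h_ipep,
    ph_c = lv[["PFKFB"]] * k$pfkfb$Vph, ph_Km = k$pfkfb$Km_f26bp,
    aldo_c = lv[["ALDO"]] * k$aldo$Vmax, aldo_Kf = k$aldo$Km_fbp,
    aldo_Kd = k$aldo$Km_dhap, aldo_Kg = k$aldo$Km_gap, aldo_Keq = k$aldo$Keq,
    tpi_c = lv[["TPI"]] * k$tpi$Vmax, tpi_Kd = k$tpi$Km_dhap,
    tpi_Kg = k$tpi$Km_gap, tpi_Keq = k$tpi$Keq,
    gap_c = lv[["GAPDH"]] * k$gapdh$Vmax / (k$gapdh$Km_nad + ev[["NAD"]]),
    gap_Km = k$gapdh$Km_gap, gap_NAD = ev[["NAD"]], gap_NADH = ev[["NADH"]],
    gap_Keq = k$gapdh$Keq,
    pgk_c = lv[["PGK"]] * k$pgk$Vmax / (k$pgk$Km_adp + ev[["ADP"]]),
    pgk_Km = k$pgk$Km_bpg, pgk_ADP = ev[["ADP"]], pgk_ATP = ev[["ATP"]],
    pgk_Keq = k$pgk$Keq,
    pgam_c = lv[["PGAM"]] * k$pgam$Vmax, pgam_Km = k$pgam$Km_3pg,
    pgam_Keq = k$pgam$Keq,
    eno_c = lv[["ENO"]] * k$eno$Vmax, eno_Km = k$eno$Km_2pg,
    eno_Keq = k$eno$Keq,
    pk_c = pk_c, pk_Km = pkc$Km_pep, pk_Ka = pkc$Ka_f16bp,
    pk_h = k$pk$h_pep, pk_Kipyr = k$pk$Ki_pyr,
    ldh_c = lv[["LDH"]] * k$ldh$Vmax / (k$ldh$Km_nadh + ev[["NADH"]]),
    ldh_Km = k$ldh$Km_pyr, ldh_NADH = ev[["NADH"]],
    ldh_back = ev[["LAC"]] * ev[["NAD"]] / k$ldh$Keq,
    mito_V = lv[["MITO"]] * k$mito$Vmax, mito_Km = k$mito$Km,
    mito_back = ev[["PYR_m"]] / (k$mito$Km + ev[["PYR_m"]]),
    ala_V = lv[["ALA"]] * k$ala$Vmax, ala_Km = k$ala$Km_pyr,
    ala_ALA = ev[["ALA"]], ala_Keq = k$ala$Keq
  )
}

flux_names <- function() {
  c("GLUT", "HK", "PGI", "PFK", "PFKFB_K", "PFKFB_P", "ALDO", "TPI",
    "GAPDH", "PGK", "PGAM", "ENO", "PK", "LDH", "MITO", "ALA")
}

# y: positional state (order of species_names()); p: compile_pars() output.
# Returns unnamed 16-vector in flux_names() order.
flux_vector <- function(y, p) {
  GLC <- y[1]; G6P <- y[2]; F6P <- y[3]; F16BP <- y[4]; F26BP <- y[5]
  DHAP <- y[6]; GAP <- y[7]; BPG <- y[8]; PG3 <- y[9]; PG2 <- y[10]
  PEP <- y[11]; PYR <- y[12]

  v_glut <- p$glut_V * (p$glut_ext - GLC / (p$glut_Km + GLC))
  v_hk <- p$hk_c * GLC / (p$hk_Km + GLC) / (1 + (G6P / p$hk_Ki)^p$hk_h)
  v_pgi <- p$pgi_c * (G6P - F6P / p$pgi_Keq) /
    (p$pgi_Kg * (1 + G6P / p$pgi_Kg + F6P / p$pgi_Kf))

  w0 <- (F26BP / p$pfk_K26)^p$pfk_n26 + p$pfk_amp
  sub <- F6P^p$pfk_h / (p$pfk_Km^p$pfk_h + F6P^p$pfk_h)
  v_pfk <- 0
  for (i in seq_along(p$pfk_w)) {
    Ka <- p$pfk_Ka[[i]]
    w <- if (is.null(Ka)) w0 else w0 + (F16BP / Ka)^p$pfk_n
    v_pfk <- v_pfk + p$pfk_w[i] * (p$pfk_eps + w) / (1 + w)
  }
  v_pfk <- p$pfk_c * sub * v_pfk

  v_kin <- p$kin_c * F6P / (p$kin_Kf6p + F6P) /
    (1 + (PEP / p$kin_Kipep)^p$kin_hpep)
  v_ph <- p$ph_c * F26BP / (p$ph_Km + F26BP)

  v_aldo <- p$aldo_c * (F16BP - DHAP * GAP / p$aldo_Keq) /
    (p$aldo_Kf * (1 + F16BP / p$aldo_Kf + DHAP / p$aldo_Kd +
                    GAP / p$aldo_Kg))
  v_tpi <- p$tpi_c * (DHAP - GAP / p$tpi_Keq) /
    (p$tpi_Kd * (1 + DHAP / p$tpi_Kd + GAP / p$tpi_Kg))
  v_gap <- p$gap_c * (GAP * p$gap_NAD - BPG * p$gap_NADH / p$gap_Keq) /
    (p$gap_Km + GAP)
  v_pgk <- p$pgk_c * (BPG * p$pgk_ADP - PG3 * p$pgk_ATP / p$pgk_Keq) /
    (p$pgk_Km + BPG)
  v_pgam <- p$pgam_c * (PG3 - PG2 / p$pgam_Keq) / (p$pgam_Km + PG3 + PG2)
  v_eno <- p$eno_c * (PG2 - PEP / p$eno_Keq) / (p$eno_Km + PG2 + PEP)

  Km_pep <- if (is.null(p$pk_Ka)) p$pk_Km else p$pk_Km / (1 + F16BP / p$pk_Ka)
  v_pk <- p$pk_c * PEP^p$pk_h / (Km_pep^p$pk_h + PEP^p$pk_h) /
    (1 + PYR / p$pk_Kipyr)

  v_ldh <- p$ldh_c * (PYR * p$ldh_NADH - p$ldh_back) / (p$ldh_Km + PYR)
  v_mito <- p$mito_V * (PYR / (p$mito_Km + PYR) - p$mito_back)
  v_ala <- p$ala_V * (PYR - p$ala_ALA / p$ala_Keq) /
    (p$ala_Km + PYR + p$ala_ALA)

  c(v_glut, v_hk, v_pgi, v_pfk, v_kin, v_ph, v_aldo, v_tpi, v_gap,
    v_pgk, v_pgam, v_eno, v_pk, v_ldh, v_mito, v_ala)
}

deriv_from_flux <- function(fl) {
  c(fl[1] - fl[2],                    # GLC
    fl[2] - fl[3],                    # G6P
    fl[3] - fl[4] - fl[5] + fl[6],    # F6P
    fl[4] - fl[7],                    # F16BP
    fl[5] - fl[6],                    # F26BP
    fl[7] - fl[8],                    # DHAP
    fl[7] + fl[8] - fl[9],            # GAP
    fl[9] - fl[10],                   # BPG13
    fl[10] - fl[11],                  # PG3
    fl[11] - fl[12],                  # PG2
    fl[12] - fl[13],                  # PEP
    fl[13] - fl[14] - fl[15] - fl[16] # PYR
  )
}
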