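#' Catalog of isozyme-specific allosteric constants
#'
#' Kinetic properties of the mammalian isozymes of phosphofructokinase (PFK),
#' pyruvate kinase (PK) and the bifunctional
#' 6-phosphofructo-2-kinase/fructose-2,6-bisphosphatase (PFKFB).  Constants
#' with literature provenance are the isozyme-discriminating ones: the F16BP
#' activation constant of PFKM/PFKL (PFKP carries no F16BP activation term at
#' all), the ATP inhibition / F16BP activation / PEP half-saturation constants
#' of the four PK isoforms (PKM1 carries no F16BP activation term), and the
#' tissue-specific kinase-to-bisphosphatase (K/P) activity ratios of PFKFB.
#' All remaining constants are shared across isoforms and were calibrated so
#' that the two-enzyme F6P node reproduces its characteristic switch-up /
#' switch-down concentrations (see the package vignette).
#'
#' @return A list with components \code{PFK}, \code{PK} and \code{PFKFB}.
#'   \code{PFK} and \code{PK} map isoform names to lists of constants (mM);
#'   \code{PFKFB} maps tissue presets to K/P activity ratios and stores the
#'   liver range metadata.  Entries that are structurally absent (e.g. no
#'   F16BP activation of PFKP) are absent from the list, not set to a
#'   sentinel value.
#' @examples
#' cat <- table1_catalog()
#' cat$PK$PKM2$Ki_atp    # 3.5 mM
#' "Ka_f16bp" %in% names(cat$PFK$PFKP)  # FALSE: no F16BP activation
#' @export
table1_catalog <- function() {
  list(
    PFK = list(
      PFKM = list(Ka_f16bp = 0.35, provenance = "literature"),
      PFKL = list(Ka_f16bp = 0.65, provenance = "literature"),
      PFKP = list(provenance = "literature (no F16BP activation)")
    ),
    PK = list(
      PKL  = list(Ki_atp = 0.05, Ka_f16bp = 0.01, Km_pep = 0.6,
                  provenance = "literature"),
      PKR  = list(Ki_atp = 0.12, Ka_f16bp = 0.04, Km_pep = 1.2,
                  provenance = "literature"),
      PKM1 = list(Ki_atp = 2.5,  Km_pep = 0.08,
                  provenance = "literature (no F16BP activation)"),
      PKM2 = list(Ki_atp = 3.5,  Ka_f16bp = 0.04, Km_pep = 0.4,
                  provenance = "literature")
    ),
    PFKFB = list(
      PFKFB1_liver      = list(KP = 2.0, KP_range = c(1.5, 2.5)),
      PFKFB1_muscle     = list(KP = 0.4),
      PFKFB2_heart      = list(KP = 1.8),
      PFKFB3_ubiquitous = list(KP = 3.1),
      PFKFB3_inducible  = list(KP = 710),
      PFKFB4_testis     = list(KP = 4.1)
    )
  )
}

#' Export the isozyme catalog as a data frame
#'
#' Flat, CSV-ready view of [table1_catalog()].
#'
#' @return A data.frame with columns enzyme, isoform, constant, value.
#' @export
catalog_table <- function() {
  cat <- table1_catalog()
  rows <- list()
  for (enz in names(cat)) {
    for (iso in names(cat[[enz]])) {
      cons <- cat[[enz]][[iso]]
      for (nm in names(cons)) {
        if (!is.numeric(cons[[nm]]) || length(cons[[nm]]) != 1L) next
        rows[[length(rows) + 1L]] <- data.frame(
          enzyme = enz, isoform = iso, constant = nm,
          value = cons[[nm]], stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, rows)
}

# Shared (non-isoform-discriminating) kinetic constants.  Scale constants of
# PFK and ALDO are calibrated against the F6P-node switch concentrations;
# the remainder are physiologically plausible choices (see vignette).
kinetic_defaults <- function() {
  list(
    glut  = list(Vmax = 110, Km = 10),
    hk    = list(Vmax = 400, Km_glc = 4.0, Km_atp = 0.30, Ki_g6p = 0.15,
                 h_g6p = 2.5),
    pgi   = list(Vmax = 800, Km_g6p = 0.50, Km_f6p = 0.15, Keq = 0.30),
    pfk   = list(Vmax = 190, Km_f6p = 0.36, h_f6p = 1, Km_atp = 0.15,
                 Ki_atp = 2.5, h_iatp = 2, eps = 0.016, n_fbp = 4,
                 Ka_f26bp = 0.011, n_f26 = 4, Ka_amp = 2.0),
    pfkfb = list(Vph = 120, kin_unit = 0.0005, Km_f6p = 0.10, Km_atp = 0.15,
                 Km_f26bp = 5.0, Ki_pep = 0.01, h_ipep = 2),
    aldo  = list(Vmax = 40, Km_fbp = 1.0, Km_dhap = 0.035, Km_gap = 1.0,
                 Keq = 0.1),
    tpi   = list(Vmax = 1000, Km_dhap = 0.6, Km_gap = 0.4, Keq = 0.5),
    gapdh = list(Vmax = 92, Km_gap = 0.2, Km_nad = 0.05, Keq = 0.08),
    pgk   = list(Vmax = 2000, Km_bpg = 0.05, Km_adp = 0.2, Keq = 1800),
    pgam  = list(Vmax = 1500, Km_3pg = 0.2, Keq = 0.15),
    eno   = list(Vmax = 1200, Km_2pg = 0.1, Keq = 5),
    pk    = list(Vmax = 300, h_pep = 2, Km_adp = 0.3, Ki_pyr = 20),
    ldh   = list(Vmax = 130, Km_pyr = 8, Km_nadh = 0.05, Keq = 25000),
    mito  = list(Vmax = 8, Km = 0.15),
    ala   = list(Vmax = 4, Km_pyr = 0.5, Keq = 5)
  )
}

# Fixed-environment defaults (mM).  Nucleotides, redox couple, ions and the
# pyruvate/lactate/alanine pools are clamped during any single solve or run.
environment_defaults <- function() {
  c(ATP = 3.0, ADP = 0.8, AMP = 0.2, NAD = 1.0, NADH = 0.1,
    MG = 0.5, K = 140, CA = 1e-4,
    PYR_m = 0.1, LAC = 1.5, ALA = 0.5, GLC_ext = 5.0)
}

# Reference relative enzyme levels (dimensionless multipliers on Vmax).
enzyme_level_defaults <- function() {
  c(GLUT = 1, HK = 1, PGI = 1, PFK = 1, PFKFB = 1, ALDO = 1, TPI = 1,
    GAPDH = 1, PGK = 1, PGAM = 1, ENO = 1, PK = 1, LDH = 1, MITO = 1,
    ALA = 1)
}

#' Names of the balanced glycolytic intermediates
#'
#' The twelve species whose mass balances constitute the ODE model:
#' intracellular glucose, G6P, F6P, F16BP, F26BP, DHAP, GAP,
#' 1,3-bisphosphoglycerate, 3PG, 2PG, PEP and cytosolic pyruvate.
#'
#' @return Character vector of length 12.
#' @export
species_names <- function() {
  c("GLC", "G6P", "F6P", "F16BP", "F26BP", "DHAP", "GAP",
    "BPG13", "PG3", "PG2", "PEP", "PYR")
}
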