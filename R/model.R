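#' Construct the full glycolysis ODE model
#'
#' Builds the mass-balance model for the twelve glycolytic intermediates
#' (see [species_names()]) under a fixed environment, with external glucose
#' as the control input.  The returned object carries the right-hand side
#' and flux evaluators consumed by the steady-state, bifurcation and
#' dynamics machinery.
#'
#' @param config a \code{glyc_config} from [build_config()].
#' @param glucose optional external glucose concentration (mM) overriding
#'   the configuration's environment value.
#' @return An object of class \code{glyc_model}.
#' @examples
#' m <- glycolysis_model(build_config("PFKP", "PKM1", kp = 10), glucose = 5)
#' m$deriv(rep(0.1, 12))
#' @export
glycolysis_model <- function(config = build_config(), glucose = NULL) {
  stopifnot(inherits(config, "glyc_config"))
  if (!is.null(glucose)) {
    stopifnot(glucose >= 0)
    config$env["GLC_ext"] <- glucose
  }
  p <- compile_pars(config)
  structure(list(
    kind = "full", config = config, pars = p,
    state_names = species_names(), dim = 12L,
    control = "glucose", control_value = unname(config$env["GLC_ext"]),
    deriv = function(y) deriv_from_flux(flux_vector(y, p)),
    fluxes = function(y) stats::setNames(flux_vector(y, p), flux_names()),
    flux_J = function(y) flux_vector(y, p)[4]   # J_PFK
  ), class = "glyc_model")
}

# shared node helpers: PFK and ALDO rates against fixed trioses
node_pfk <- function(F6P, F16BP, F26BP, p) {
  w0 <- (F26BP / p$pfk_K26)^p$pfk_n26 + p$pfk_amp
  sub <- F6P^p$pfk_h / (p$pfk_Km^p$pfk_h + F6P^p$pfk_h)
  v <- 0
  for (i in seq_along(p$pfk_w)) {
    Ka <- p$pfk_Ka[[i]]
    w <- if (is.null(Ka)) w0 else w0 + (F16BP / Ka)^p$pfk_n
    v <- v + p$pfk_w[i] * (p$pfk_eps + w) / (1 + w)
  }
  p$pfk_c * sub * v
}

node_aldo <- function(F16BP, p, DHAP, GAP) {
  p$aldo_c * (F16BP - DHAP * GAP / p$aldo_Keq) /
    (p$aldo_Kf * (1 + F16BP / p$aldo_Kf + DHAP / p$aldo_Kd + GAP / p$aldo_Kg))
}

#' Construct the reduced F6P-node model
#'
#' The F6P node is the subsystem around fructose-6-phosphate: PFK plus ALDO
#' (two-enzyme form), optionally with the bifunctional PFKFB (three-enzyme
#' form).  F6P is the control parameter and the triose products of ALDO are
#' clamped (DHAP 0.04 mM, GAP 0.02 mM).  The two-enzyme node balances
#' F16BP only; the three-enzyme node balances F16BP and F26BP.  PEP is
#' absent from the node, so the PFKFB kinase runs uninhibited.
#'
#' @param config a \code{glyc_config} (PFK isoform/mixture and K/P are
#'   taken from it).
#' @param enzymes "two" (PFK + ALDO) or "three" (PFK + ALDO + PFKFB).
#' @param f6p F6P concentration (mM), the node's control parameter.
#' @param dhap,gap clamped triose concentrations (mM).
#' @return An object of class \code{glyc_model}.
#' @export
f6p_node_model <- function(config = build_config(), enzymes = c("two", "three"),
                           f6p = 0.1, dhap = 0.04, gap = 0.02) {
  stopifnot(inherits(config, "glyc_config"), f6p >= 0)
  enzymes <- match.arg(enzymes)
  p <- compile_pars(config)
  if (enzymes == "two") {
    deriv <- function(y) node_pfk(f6p, y[1], 0, p) - node_aldo(y[1], p, dhap, gap)
    fluxes <- function(y) c(PFK = node_pfk(f6p, y[1], 0, p),
                            ALDO = node_aldo(y[1], p, dhap, gap))
    st <- "F16BP"; d <- 1L
  } else {
    deriv <- function(y) {
      vk <- p$kin_c * f6p / (p$kin_Kf6p + f6p)   # PEP = 0 in the node
      vp <- p$ph_c * y[2] / (p$ph_Km + y[2])
      c(node_pfk(f6p, y[1], y[2], p) - node_aldo(y[1], p, dhap, gap),
        vk - vp)
    }
    fluxes <- function(y) c(PFK = node_pfk(f6p, y[1], y[2], p),
                            ALDO = node_aldo(y[1], p, dhap, gap),
                            PFKFB_K = p$kin_c * f6p / (p$kin_Kf6p + f6p),
                            PFKFB_P = p$ph_c * y[2] / (p$ph_Km + y[2]))
    st <- c("F16BP", "F26BP"); d <- 2L
  }
  structure(list(kind = paste0("node_", enzymes), config = config, pars = p,
                 state_names = st, dim = d,
                 control = "F6P", control_value = f6p,
                 deriv = deriv, fluxes = fluxes,
                 flux_J = function(y) unname(fluxes(y)["PFK"])),
            class = "glyc_model")
}

# Rebuild a model of the same kind with a new control value.
set_control <- function(model, value) {
  if (model$kind == "full") glycolysis_model(model$config, glucose = value)
  else f6p_node_model(model$config,
                      enzymes = sub("node_", "", model$kind), f6p = value)
}

#' Time derivatives of the balanced intermediates
#'
#' Evaluates the stoichiometric right-hand side of the model: for each
#' intermediate, producing minus consuming rates.  ALDO splits one F16BP
#' into DHAP + GAP, so the triose pool feeds GAPDH at twice the upper
#' glycolytic carbon flux; the pyruvate balance is PK minus LDH,
#' mitochondrial transport and the alanine-linked sink.
#'
#' @param state named or positional concentrations of the 12 intermediates
#'   (mM, order of [species_names()]).
#' @param env named environment vector (defaults from config).
#' @param config a \code{glyc_config}.
#' @return named vector of derivatives (mM/h).
#' @export
rhs <- function(state, env = NULL, config = build_config()) {
  if (!is.null(env)) config$env[names(env)] <- env
  if (!is.null(names(state))) state <- state[species_names()]
  check_nonneg(state)
  p <- compile_pars(config)
  fl <- flux_vector(unname(state), p)
  if (any(!is.finite(fl)))
    stop("non-finite rate for enzyme(s): ",
         paste(flux_names()[!is.finite(fl)], collapse = ", "), call. = FALSE)
  stats::setNames(deriv_from_flux(fl), species_names())
}

#' @export
print.glyc_model <- function(x, ...) {
  cat("Glycolysis kinetic model (", x$kind, "), ",
      x$dim, " balanced species\n", sep = "")
  cat("  control: ", x$control, " = ", format(x$control_value), " mM\n",
      sep = "")
  print(x$config)
  invisible(x)
}
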