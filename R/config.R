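#' Assemble a full model configuration
#'
#' A configuration fixes the PFK isoform (or mixture), the PK isoform, the
#' PFKFB kinase/bisphosphatase activity ratio (K/P) and expression level,
#' the relative levels of every enzyme, the fixed environment, and all
#' kinetic constants.  Everything downstream (steady-state enumeration,
#' bifurcation scans, transient simulation) consumes a config.
#'
#' @param pfk PFK isoform name ("PFKM", "PFKL", "PFKP") or a named numeric
#'   vector of mixture weights over those isoforms (weights must be
#'   nonnegative and sum to 1).
#' @param pk PK isoform name: "PKM1", "PKM2", "PKL" or "PKR".
#' @param kp PFKFB kinase-to-bisphosphatase activity ratio (dimensionless,
#'   > 0), or the name of a tissue preset from the catalog
#'   (e.g. "PFKFB3_inducible").
#' @param pfkfb_level PFKFB expression level as a fraction of the reference
#'   (0 < level <= 10).  Scales kinase and bisphosphatase domains equally,
#'   so it leaves every steady state unchanged and only affects dynamics.
#' @param levels optional named vector overriding relative enzyme levels
#'   (names among \code{names(enzyme_level_defaults())}, values > 0).
#' @param env optional named vector overriding fixed-environment
#'   concentrations (mM).
#' @param constants optional nested list overriding kinetic constants, e.g.
#'   \code{list(pfk = list(Km_f6p = 0.4))}.
#' @param cell_volume_pl cell volume in picolitres used to convert
#'   intracellular fluxes (mM/h) to cell-specific rates (mmol/1e9 cells/h).
#' @return An object of class \code{glyc_config}.
#' @examples
#' cfg <- build_config("PFKL", "PKM2", kp = 10)
#' loop_status(cfg)
#' @export
build_config <- function(pfk = "PFKL", pk = "PKM2", kp = 10,
                         pfkfb_level = 1, levels = NULL, env = NULL,
                         constants = NULL, cell_volume_pl = 16) {
  cat <- table1_catalog()

  if (is.character(pfk)) {
    if (length(pfk) != 1L || !pfk %in% names(cat$PFK))
      stop("unknown PFK isoform; valid: ",
           paste(names(cat$PFK), collapse = ", "), call. = FALSE)
    w <- stats::setNames(1, pfk)
  } else {
    w <- pfk
    if (is.null(names(w)) || !all(names(w) %in% names(cat$PFK)))
      stop("PFK mixture weights must be named with: ",
           paste(names(cat$PFK), collapse = ", "), call. = FALSE)
    if (any(w < 0)) stop("PFK mixture weights must be nonnegative",
                         call. = FALSE)
    if (abs(sum(w) - 1) > 1e-9)
      stop("PFK mixture weights must sum to 1 (got ", sum(w), ")",
           call. = FALSE)
    w <- w[w > 0]
  }

  if (length(pk) != 1L || !pk %in% names(cat$PK))
    stop("unknown PK isoform; valid: ",
         paste(names(cat$PK), collapse = ", "), call. = FALSE)

  if (is.character(kp)) {
    if (!kp %in% names(cat$PFKFB))
      stop("unknown PFKFB preset; valid: ",
           paste(names(cat$PFKFB), collapse = ", "), call. = FALSE)
    kp <- cat$PFKFB[[kp]]$KP
  }
  stopifnot(is.numeric(kp), length(kp) == 1L, kp > 0)
  if (!(pfkfb_level > 0 && pfkfb_level <= 10))
    stop("pfkfb_level must satisfy 0 < level <= 10", call. = FALSE)

  lv <- enzyme_level_defaults()
  if (!is.null(levels)) {
    bad <- setdiff(names(levels), names(lv))
    if (length(bad)) stop("unknown enzyme level name(s): ",
                          paste(bad, collapse = ", "), call. = FALSE)
    if (any(levels <= 0)) stop("enzyme levels must be > 0", call. = FALSE)
    lv[names(levels)] <- levels
  }
  lv["PFKFB"] <- pfkfb_level

  ev <- environment_defaults()
  if (!is.null(env)) {
    bad <- setdiff(names(env), names(ev))
    if (length(bad)) stop("unknown environment name(s): ",
                          paste(bad, collapse = ", "), call. = FALSE)
    if (any(env < 0)) stop("environment concentrations must be >= 0",
                           call. = FALSE)
    ev[names(env)] <- env
  }

  kc <- kinetic_defaults()
  if (!is.null(constants)) {
    bad <- setdiff(names(constants), names(kc))
    if (length(bad)) stop("unknown constants section(s): ",
                          paste(bad, collapse = ", "), call. = FALSE)
    for (sec in names(constants)) {
      badf <- setdiff(names(constants[[sec]]), names(kc[[sec]]))
      if (length(badf)) stop("unknown constant(s) in ", sec, ": ",
                             paste(badf, collapse = ", "), call. = FALSE)
      kc[[sec]][names(constants[[sec]])] <- constants[[sec]]
    }
  }

  structure(list(pfk_weights = w, pk = pk, kp = kp,
                 pfkfb_level = pfkfb_level, levels = lv, env = ev,
                 constants = kc, catalog = cat,
                 cell_volume_pl = cell_volume_pl),
            class = "glyc_config")
}

#' Which regulatory loops does a configuration activate?
#'
#' Loop 1 is the feedback activation of PFK by F16BP (plus F26BP activation
#' of PFK); it is active whenever the PFK mixture puts positive weight on
#' PFKM or PFKL.  Loop 2 is the composite positive loop of PK activation by
#' F16BP, PEP inhibition of the PFKFB kinase and F26BP activation of PFK;
#' it is active with PKM2, PKL or PKR (not PKM1).
#'
#' @param config a \code{glyc_config}.
#' @return list with logical fields \code{loop1} and \code{loop2}.
#' @export
loop_status <- function(config) {
  stopifnot(inherits(config, "glyc_config"))
  w <- config$pfk_weights
  list(loop1 = any(names(w) %in% c("PFKM", "PFKL") & w > 0),
       loop2 = config$pk %in% c("PKM2", "PKL", "PKR"))
}

#' @export
print.glyc_config <- function(x, ...) {
  ls <- loop_status(x)
  wt <- paste(sprintf("%s:%.2g", names(x$pfk_weights), x$pfk_weights),
              collapse = " ")
  cat("Glycolysis model configuration\n")
  cat("  PFK: ", wt, "   PK: ", x$pk, "\n", sep = "")
  cat(sprintf("  PFKFB K/P = %g, level = %g\n", x$kp, x$pfkfb_level))
  cat(sprintf("  Loop 1 %s, Loop 2 %s\n",
              if (ls$loop1) "active" else "inactive",
              if (ls$loop2) "active" else "inactive"))
  cat("  Non-default enzyme levels:",
      { d <- x$levels[x$levels != 1]
        if (length(d)) paste(sprintf("%s=%.3g", names(d), d),
                             collapse = " ") else "none" }, "\n")
  invisible(x)
}

# Apply a scan parameter to a config.  Understood names:
#   "glucose" (external), "kp", "NAD_ratio" (NAD/NADH with NADH fixed),
#   "LAC", "ALA", or "level:<ENZYME>".
set_parameter <- function(config, name, value) {
  stopifnot(inherits(config, "glyc_config"))
  if (name == "glucose") config$env["GLC_ext"] <- value
  else if (name == "kp") config$kp <- value
  else if (name == "NAD_ratio") config$env["NAD"] <- value * config$env["NADH"]
  else if (name %in% c("LAC", "ALA")) config$env[name] <- value
  else if (startsWith(name, "level:")) {
    enz <- sub("^level:", "", name)
    if (!enz %in% names(config$levels))
      stop("unknown enzyme in level parameter: ", enz, call. = FALSE)
    config$levels[enz] <- value
    if (enz == "PFKFB") config$pfkfb_level <- value
  } else stop("unknown scan parameter: ", name, call. = FALSE)
  config
}

#' Write / read a configuration as YAML
#'
#' Round-trips all numeric content of a config; reloading yields identical
#' rate evaluations.
#'
#' @param config a \code{glyc_config}.
#' @param path file path (".yaml"/".yml" or ".json").
#' @return \code{write_config} returns the path invisibly;
#'   \code{read_config} returns a \code{glyc_config}.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "glyc_config"))
  obj <- list(
    isozymes = list(pfk = as.list(config$pfk_weights), pk = config$pk,
                    pfkfb = list(kp = config$kp,
                                 level = config$pfkfb_level)),
    enzyme_levels = as.list(config$levels),
    environment = as.list(config$env),
    allosteric_constants = config$constants,
    cell_volume_pl = config$cell_volume_pl)
  if (grepl("\\.json$", path))
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  else yaml::write_yaml(obj, path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  obj <- if (grepl("\\.json$", path)) jsonlite::read_json(path,
                                                          simplifyVector = TRUE)
         else yaml::read_yaml(path)
  w <- unlist(obj$isozymes$pfk)
  build_config(pfk = w / sum(w), pk = obj$isozymes$pk,
               kp = obj$isozymes$pfkfb$kp,
               pfkfb_level = obj$isozymes$pfkfb$level,
               levels = unlist(obj$enzyme_levels),
               env = unlist(obj$environment),
               constants = obj$allosteric_constants,
               cell_volume_pl = obj$cell_volume_pl)
}
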