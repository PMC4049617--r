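# Result serialization and the command-line dispatcher.

fmt_num <- function(x) formatC(x, digits = 12, format = "g")

#' Export steady states or a bifurcation diagram as CSV
#'
#' One row per steady state: control value, concentrations, flux, maximum
#' eigenvalue real part and stability label, with 12 significant digits so
#' regression comparisons are stable.
#'
#' @param x a \code{glyc_steady_states} or \code{glyc_bifurcation}.
#' @param path output file.
#' @return the path, invisibly.
#' @export
export_csv <- function(x, path) {
  df <- as.data.frame(x)
  num <- vapply(df, is.numeric, TRUE)
  df[num] <- lapply(df[num], fmt_num)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a run manifest
#'
#' Records the command, a digest of the configuration, the master seed,
#' package version and timestamp next to a run's outputs.
#'
#' @param dir output directory.
#' @param command character description of the run.
#' @param config the \code{glyc_config} used.
#' @param seed master seed.
#' @param outputs character vector of output paths.
#' @return manifest path, invisibly.
#' @export
write_manifest <- function(dir, command, config, seed, outputs = character()) {
  cfg_file <- tempfile(fileext = ".yaml")
  write_config(config, cfg_file)
  digest <- sum(utf8ToInt(paste(readLines(cfg_file), collapse = "\n")) *
                  seq_along(utf8ToInt(paste(readLines(cfg_file),
                                            collapse = "\n")))) %% 2^31
  unlink(cfg_file)
  obj <- list(command = command, config_digest = digest, seed = seed,
              version = as.character(utils::packageVersion("glycoswitch")),
              timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
              outputs = outputs)
  path <- file.path(dir, "manifest.json")
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Command-line entry point
#'
#' Dispatcher behind the \code{inst/cli/glyc} script.  Subcommands:
#' \describe{
#'   \item{catalog}{print the isozyme constant catalog as CSV}
#'   \item{steady-states}{enumerate steady states at one glucose value}
#'   \item{scan}{glucose bifurcation scan}
#'   \item{simulate}{transient run, optionally with a glucose pulse}
#'   \item{reproduce}{run a registered figure-level experiment}
#' }
#'
#' @param argv character vector of command-line arguments.
#' @return integer exit status (0 success, 2 usage error), invisibly.
#' @export
glyc_main <- function(argv = commandArgs(trailingOnly = TRUE)) {
  usage <- paste(
    "usage: glyc <command> [options]",
    "  catalog",
    "  steady-states [--config F] [--glucose G] [--seed S] [--out F.csv]",
    "  scan          [--config F] [--from A --to B --by H] [--seed S] [--out F.csv]",
    "  simulate      [--config F] [--glucose G] [--t-end T] [--pulse t0=..,dur=..,glc=..] [--out F.csv]",
    "  reproduce <id> [--seed S] [--out DIR]", sep = "\n")
  if (!length(argv)) { message(usage); return(invisible(2L)) }
  cmd <- argv[1]
  opts <- list()
  i <- 2
  pos <- character()
  while (i <= length(argv)) {
    a <- argv[i]
    if (startsWith(a, "--")) {
      opts[[sub("^--", "", a)]] <- if (i < length(argv)) argv[i + 1] else ""
      i <- i + 2
    } else { pos <- c(pos, a); i <- i + 1 }
  }
  getn <- function(name, default) if (is.null(opts[[name]])) default
                                  else as.numeric(opts[[name]])
  cfg <- if (!is.null(opts$config)) read_config(opts$config) else build_config()
  seed <- as.integer(getn("seed", 1))

  status <- tryCatch({
    if (cmd == "catalog") {
      utils::write.csv(catalog_table(), if (is.null(opts$out)) stdout()
                       else opts$out, row.names = FALSE, quote = FALSE)
    } else if (cmd == "steady-states") {
      m <- glycolysis_model(cfg, glucose = getn("glucose", 5))
      ss <- find_steady_states(m, n_starts = as.integer(getn("n-starts", 100)),
                               seed = seed)
      if (is.null(opts$out)) print(ss) else export_csv(ss, opts$out)
    } else if (cmd == "scan") {
      grid <- seq(getn("from", 0.5), getn("to", 25), by = getn("by", 0.5))
      d <- scan_bifurcation(cfg, "glucose", grid,
                            n_starts = as.integer(getn("n-starts", 50)),
                            seed = seed)
      if (is.null(opts$out)) print(d) else export_csv(d, opts$out)
    } else if (cmd == "simulate") {
      m <- glycolysis_model(cfg, glucose = getn("glucose", 5))
      ss <- find_steady_states(m, n_starts = 80, seed = seed)
      init <- unname(ss$solutions[[1]]$state)
      prof <- NULL
      if (!is.null(opts$pulse)) {
        kv <- strsplit(strsplit(opts$pulse, ",")[[1]], "=")
        pv <- stats::setNames(as.numeric(vapply(kv, `[`, "", 2)),
                              vapply(kv, `[`, "", 1))
        base <- getn("glucose", 5)
        prof <- function(t) ifelse(t >= pv[["t0"]] &
                                     t < pv[["t0"]] + pv[["dur"]],
                                   pv[["glc"]], base)
      }
      tr <- simulate_model(m, init, t_end = getn("t-end", 500),
                           glucose_profile = prof)
      out <- cbind(tr$states, tr$fluxes)
      if (is.null(opts$out)) print(tr)
      else utils::write.csv(out, opts$out, row.names = FALSE)
    } else if (cmd == "reproduce") {
      if (!length(pos)) stop("reproduce needs an experiment id")
      r <- reproduce(pos[1], seed = seed)
      if (!is.null(opts$out)) {
        dir.create(opts$out, showWarnings = FALSE, recursive = TRUE)
        for (nm in names(r$tables))
          utils::write.csv(r$tables[[nm]],
                           file.path(opts$out, paste0(nm, ".csv")),
                           row.names = FALSE)
        jsonlite::write_json(r$summary,
                             file.path(opts$out, "summary.json"),
                             auto_unbox = TRUE, digits = NA)
        write_manifest(opts$out, paste("reproduce", pos[1]),
                       hela_config(), seed,
                       list.files(opts$out))
      } else print(r)
    } else {
      message(usage); return(invisible(2L))
    }
    0L
  }, error = function(e) {
    message("error: ", conditionMessage(e))
    1L
  })
  invisible(status)
}
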