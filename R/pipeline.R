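# End-to-end orchestration: for each binding mode (a pair of chain sets) run
# the potential solve, the separation force scan and, when an ensemble is
# supplied, the contact-occupancy analysis; then rank the modes. Outputs are
# deterministic for a fixed config + seed (no timestamps in numerical files).

#' Assemble a pipeline run configuration
#'
#' @param input path to a PQR file (or a charged [struct3d()]).
#' @param modes list of binding modes, each a list with `name`, `chains_a`,
#'   `chains_b` (e.g. the four tubulin-style modes alpha/alpha, beta/beta,
#'   alpha/beta, beta/alpha).
#' @param settings a [solver_settings()].
#' @param criteria a [contact_criteria()].
#' @param ensemble optional multi-model PDB path or [ensemble3d()] for the
#'   contact analysis.
#' @param scan list with `d_min`, `d_max`, `step` (Angstrom).
#' @param outdir output directory.
#' @param seed integer seed recorded in the manifest and set before the run.
#' @param contact_kinds kinds to analyse when an ensemble is present.
#' @param heavy_only passed to [detect_hbonds()] (hydrogen-free input).
#' @return a `run_config` list.
#' @export
run_config <- function(input, modes, settings = solver_settings(),
                       criteria = contact_criteria(), ensemble = NULL,
                       scan = list(d_min = 14, d_max = 40, step = 2),
                       outdir = tempfile("ifacelec_run_"), seed = 1,
                       contact_kinds = c("hbond", "saltbridge"),
                       heavy_only = FALSE) {
  stopifnot(length(modes) >= 1)
  for (m in modes)
    if (is.null(m$name) || is.null(m$chains_a) || is.null(m$chains_b))
      stop("each mode needs name, chains_a, chains_b")
  structure(list(input = input, modes = modes, settings = settings,
                 criteria = criteria, ensemble = ensemble, scan = scan,
                 outdir = outdir, seed = as.integer(seed),
                 contact_kinds = contact_kinds, heavy_only = heavy_only),
            class = "run_config")
}

#' Load a run configuration from YAML
#'
#' Top-level keys mirror [run_config()] arguments; `settings` and
#' `criteria` sub-maps mirror [solver_settings()] / [contact_criteria()]
#' field names (with `salt_mM` and `cation_valence` convenience keys for the
#' ion set).
#'
#' @param path YAML file.
#' @return a `run_config`.
#' @export
load_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  st <- y$settings %||% list()
  if (!is.null(st$salt_mM)) {
    st$ions <- salt_ions(st$salt_mM / 1000,
                         z_plus = st$cation_valence %||% 1)
    st$salt_mM <- NULL; st$cation_valence <- NULL
  }
  settings <- do.call(solver_settings, st)
  criteria <- do.call(contact_criteria, y$criteria %||% list())
  modes <- lapply(y$modes, function(m)
    list(name = m$name, chains_a = m$chains_a, chains_b = m$chains_b))
  run_config(input = y$input, modes = modes, settings = settings,
             criteria = criteria, ensemble = y$ensemble,
             scan = y$scan %||% list(d_min = 14, d_max = 40, step = 2),
             outdir = y$outdir %||% tempfile("ifacelec_run_"),
             seed = y$seed %||% 1,
             contact_kinds = y$contact_kinds %||% c("hbond", "saltbridge"),
             heavy_only = isTRUE(y$heavy_only))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.config_hash <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  dump_cfg <- config
  dump_cfg$outdir <- NULL  # output location must not change the hash
  writeLines(paste(deparse(dump_cfg), collapse = "\n"), tmp)
  unname(tools::md5sum(tmp))
}

.run_mode <- function(config, mode, structure, ens, mode_dir) {
  dir.create(mode_dir, recursive = TRUE, showWarnings = FALSE)
  settings <- config$settings
  sa <- chain_subset(structure, mode$chains_a)
  sb <- chain_subset(structure, mode$chains_b)
  complex <- combine_structs(sa, sb)
  sol <- solve_potential(complex, settings)
  write_dx(sol$phi, file.path(mode_dir, "potential.dx"))
  sp <- surface_potential(complex, sol$phi, clamp = TRUE)
  write.csv(data.frame(serial = complex$atoms$serial, chain = complex$atoms$chain,
                       resid = complex$atoms$resid, name = complex$atoms$name,
                       potential_kT_per_e = sprintf("%.6f", sp)),
            file.path(mode_dir, "surface_potential.csv"),
            row.names = FALSE, quote = FALSE)
  prof <- run_separation_scan(sa, sb, settings,
                              d_min = config$scan$d_min,
                              d_max = config$scan$d_max,
                              step = config$scan$step)
  write_force_table(prof, file.path(mode_dir, "force_scan.csv"))
  summary <- list(
    mode = mode$name,
    chains_a = paste(mode$chains_a, collapse = ""),
    chains_b = paste(mode$chains_b, collapse = ""),
    force_at_dmin = prof$magnitude[1],
    classification_at_dmin = prof$classification[1],
    n_attractive_points = sum(prof$classification == "attractive"),
    n_scan_points = nrow(prof))
  if (!is.null(ens)) {
    for (kind in config$contact_kinds) {
      occ <- if (kind == "hbond")
        compute_occupancy(ens, mode$chains_a, mode$chains_b, "hbond",
                          config$criteria, heavy_only = config$heavy_only)
      else
        compute_occupancy(ens, mode$chains_a, mode$chains_b, "saltbridge",
                          config$criteria)
      write_contact_report(occ, file.path(mode_dir, paste0(kind, "_occupancy")))
      if (kind == "hbond") summary$n_hbonds <- nrow(occ$pairs)
      else summary$n_saltbridges <- nrow(occ$pairs)
    }
  }
  summary
}

#' Run the full interface-electrostatics pipeline
#'
#' Per binding mode: potential map (OpenDX), per-atom surface potential
#' samples (CSV, clamped to +/-1 kT/e), force-scan table (CSV) and, when an
#' ensemble is configured, hydrogen-bond and salt-bridge occupancy reports
#' (TSV + JSON). A `summary.json` ranks the modes ([compare_modes()]) and a
#' `manifest.json` records the config hash, seed and package version. A
#' mode that fails is recorded and the other modes still run.
#'
#' @param config a [run_config()] or path to a YAML config.
#' @return the run directory path, invisibly; attribute `failures` lists
#'   failed modes (empty character vector if none).
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- load_run_config(config)
  stopifnot(inherits(config, "run_config"))
  set.seed(config$seed)
  outdir <- config$outdir
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  structure <- if (inherits(config$input, "struct3d")) config$input
               else read_pqr(config$input)
  ens <- NULL
  if (!is.null(config$ensemble)) {
    ens <- if (inherits(config$ensemble, "ensemble3d")) config$ensemble
           else read_ensemble(config$ensemble, topology = structure)
  }
  summaries <- list(); failures <- character(0)
  for (mode in config$modes) {
    mode_dir <- file.path(outdir, mode$name)
    res <- tryCatch(.run_mode(config, mode, structure, ens, mode_dir),
                    error = function(e) e)
    if (inherits(res, "error")) {
      failures <- c(failures, mode$name)
      message(sprintf("mode %s failed: %s", mode$name, conditionMessage(res)))
      writeLines(conditionMessage(res), file.path(outdir, paste0(mode$name, ".error")))
    } else {
      summaries[[mode$name]] <- res
    }
  }
  ranking <- if (length(summaries) >= 1) compare_modes(summaries) else NULL
  jsonlite::write_json(list(modes = summaries, ranking = ranking,
                            failed_modes = as.list(failures)),
                       file.path(outdir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  jsonlite::write_json(list(config_hash = .config_hash(config),
                            seed = config$seed,
                            package_version = as.character(utils::packageVersion("ifacelec"))),
                       file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE)
  attr(outdir, "failures") <- failures
  invisible(outdir)
}

#' Rank binding modes
#'
#' Sorts mode summaries by: attractive before repulsive, then attractive
#' force magnitude at the smallest separation (descending), then retained
#' hydrogen-bond count, then retained salt-bridge count (both descending).
#' Ties preserve input order (stable sort).
#'
#' @param summaries list of per-mode summaries as produced by
#'   [run_pipeline()] (fields `mode`, `force_at_dmin`,
#'   `classification_at_dmin`, optional `n_hbonds`, `n_saltbridges`).
#' @return data.frame ranking with one row per mode.
#' @export
compare_modes <- function(summaries) {
  stopifnot(length(summaries) >= 1)
  df <- do.call(rbind, lapply(summaries, function(s) data.frame(
    mode = s$mode,
    classification = s$classification_at_dmin,
    force_at_dmin = s$force_at_dmin,
    n_hbonds = s$n_hbonds %||% NA_integer_,
    n_saltbridges = s$n_saltbridges %||% NA_integer_,
    stringsAsFactors = FALSE)))
  attract <- df$classification == "attractive"
  ord <- order(!attract,
               -ifelse(attract, df$force_at_dmin, 0),
               -ifelse(is.na(df$n_hbonds), 0, df$n_hbonds),
               -ifelse(is.na(df$n_saltbridges), 0, df$n_saltbridges))
  out <- df[ord, , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}
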