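#' Scenario configurations and the deterministic runner
#'
#' A scenario bundles one of the tool's workflows with its inputs and is
#' executed by [run_scenario()], which writes TSV tables and a run
#' manifest into an output directory.  Everything is deterministic: the
#' tool contains no randomness, and all numeric output uses fixed
#' formatting, so re-running a scenario reproduces its files
#' byte-identically.
#'
#' Commands:
#' * `steady`: one steady run per temperature; writes per-temperature
#'   trajectory, spike, burst and ISI-histogram tables plus a summary of
#'   mean SB / mean BP versus temperature.
#' * `transition`: one transient run per `(Ti_eff, Tf_eff)` pair (with
#'   the default exponential width law unless a constant `a` is given);
#'   same per-run tables plus a summary.
#' * `calibrate-params`: endpoint calibration of the tanh constants from
#'   the linear set.
#' * `calibrate-matching`: matching-condition search for the width
#'   parameter of one transition.
#' * `fit-width`: matching search over several transitions followed by
#'   the exponential fit.
#' * `analyze`: spike/burst/ISI analytics of an existing spike-time
#'   table.
#'
#' @param command one of `steady`, `transition`, `calibrate-params`,
#'   `calibrate-matching`, `fit-width`, `analyze`.
#' @param pset parameter set (defaults to [default_tanh_params()]), or a
#'   path to a parameter config file.
#' @param temperatures numeric vector of steady temperatures, degC.
#' @param transitions data frame with columns `Ti_eff`, `Tf_eff` (degC).
#' @param a constant width parameter (ms^-1) or a [width_fit()];
#'   `NULL` uses [default_width_fit()] for transient runs.
#' @param spikes_file path to a single-column spike-time TSV
#'   (`analyze` only).
#' @param cfg a [simulation_config()].
#' @param bin_width ISI histogram bin width, ms.
#' @return `scenario_config()` returns a `scenario_config` object.
#' @export
scenario_config <- function(command = c("steady", "transition",
                                        "calibrate-params",
                                        "calibrate-matching",
                                        "fit-width", "analyze"),
                            pset = default_tanh_params(),
                            temperatures = NULL, transitions = NULL,
                            a = NULL, spikes_file = NULL,
                            cfg = simulation_config(), bin_width = 2) {
  command <- match.arg(command)
  if (is.character(pset)) {
    if (!file.exists(pset))
      stop("scenario_config: parameter file not found: ", pset,
           call. = FALSE)
    pset <- read_param_config(pset)
  }
  if (!is.null(temperatures) &&
      (!is.numeric(temperatures) || any(!is.finite(temperatures))))
    stop("scenario_config: temperatures must be finite numeric",
         call. = FALSE)
  if (!is.null(spikes_file) && !file.exists(spikes_file))
    stop("scenario_config: spikes_file not found: ", spikes_file,
         call. = FALSE)
  structure(list(command = command, pset = pset,
                 temperatures = temperatures, transitions = transitions,
                 a = a, spikes_file = spikes_file, cfg = cfg,
                 bin_width = bin_width),
            class = "scenario_config")
}

#' Bundled scenario presets
#'
#' Ready-made scenarios covering the tool's standard runs:
#' * `steady_sweep`: steady temperatures 15, 20, 25, 30, 35, 40 degC;
#' * `transition_sweep`: transitions 40 degC to 35, 30, 25, 20, 15 degC;
#' * `step_sequence`: the staircase 35->30, 30->25, 25->20, 20->15 degC.
#'
#' @param name preset name; omit to list available names.
#' @return A `scenario_config`, or the preset names.
#' @export
scenario_preset <- function(name = NULL) {
  presets <- list(
    steady_sweep = function() scenario_config(
      "steady", temperatures = seq(15, 40, by = 5)),
    transition_sweep = function() scenario_config(
      "transition",
      transitions = data.frame(Ti_eff = 40, Tf_eff = c(35, 30, 25, 20, 15))),
    step_sequence = function() scenario_config(
      "transition",
      transitions = data.frame(Ti_eff = c(35, 30, 25, 20),
                               Tf_eff = c(30, 25, 20, 15))))
  if (is.null(name)) return(names(presets))
  if (!name %in% names(presets))
    stop("unknown preset '", name, "'; available: ",
         paste(names(presets), collapse = ", "), call. = FALSE)
  presets[[name]]()
}

scenario_log <- function(verbose, ...) {
  if (verbose) message(sprintf(...))
}

write_manifest <- function(path, cfg, extra = character(0)) {
  lines <- c(sprintf("package = coldburst %s",
                     as.character(utils::packageVersion("coldburst"))),
             sprintf("command = %s", cfg$command),
             sprintf("dt = %g", cfg$cfg$dt),
             sprintf("theta0 = %g", cfg$cfg$theta0),
             sprintf("phase_mode = %s", cfg$cfg$phase_mode),
             sprintf("record_stride = %d", cfg$cfg$record_stride),
             extra)
  writeLines(lines, path)
}

analyze_train <- function(spikes, windows, out_dir, tag, bin_width,
                          verbose) {
  bursts <- segment_bursts(spikes, windows)
  h <- isi_histogram(spikes, bin_width)
  write_spike_times(spikes, file.path(out_dir,
                                      sprintf("spikes_%s.tsv", tag)))
  write_burst_summary(bursts, file.path(out_dir,
                                        sprintf("bursts_%s.tsv", tag)))
  write_isi_histogram(h, file.path(out_dir,
                                   sprintf("isih_%s.tsv", tag)))
  scenario_log(verbose, "  %s: %d spikes, %d bursts", tag,
               length(spikes), nrow(bursts$bursts))
  bursts
}

#' Run a scenario
#'
#' Executes a [scenario_config()] and writes its outputs (TSV tables and
#' a `manifest.txt`) under `out_dir`.
#'
#' @param cfg a `scenario_config`, a preset name (see
#'   [scenario_preset()]) or a path to a key-value config file with at
#'   least a `command` key.
#' @param out_dir output directory, created if missing.
#' @param verbose emit progress messages to standard error.
#' @return Invisibly, a list of the in-memory results.
#' @export
run_scenario <- function(cfg, out_dir, verbose = FALSE) {
  if (is.character(cfg)) {
    cfg <- if (cfg %in% scenario_preset()) scenario_preset(cfg)
           else scenario_config_from_file(cfg)
  }
  stopifnot(inherits(cfg, "scenario_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  scenario_log(verbose, "running scenario '%s' -> %s", cfg$command,
               out_dir)
  res <- switch(
    cfg$command,
    "steady" = run_steady_scenario(cfg, out_dir, verbose),
    "transition" = run_transition_scenario(cfg, out_dir, verbose),
    "calibrate-params" = {
      rep <- calibrate_tanh_endpoints(roper_linear_params(), 15, 40)
      write_calibration_report(rep, file.path(out_dir,
                                              "calibrated_params.cfg"))
      list(report = rep)
    },
    "calibrate-matching" = {
      tr <- cfg$transitions
      if (is.null(tr) || nrow(tr) != 1L)
        stop("calibrate-matching needs exactly one transition",
             call. = FALSE)
      spec <- make_transition(tr$Ti_eff[1], tr$Tf_eff[1])
      mr <- find_matching_a(cfg$pset, spec)
      write_match_result(mr, file.path(out_dir, "match_result.cfg"))
      list(match = mr)
    },
    "fit-width" = {
      tr <- cfg$transitions
      if (is.null(tr) || nrow(tr) < 2L)
        stop("fit-width needs at least two transitions", call. = FALSE)
      samples <- lapply(seq_len(nrow(tr)), function(i) {
        spec <- make_transition(tr$Ti_eff[i], tr$Tf_eff[i])
        mr <- find_matching_a(cfg$pset, spec)
        scenario_log(verbose, "  %g->%g: a = %.5g", tr$Ti_eff[i],
                     tr$Tf_eff[i], mr$a)
        list(spec = spec, a = mr$a)
      })
      fit <- fit_width_function(samples)
      writeLines(c(sprintf("a0 = %.10g", fit$a0),
                   sprintf("alpha = %.10g", fit$alpha)),
                 file.path(out_dir, "width_fit.cfg"))
      list(fit = fit, samples = samples)
    },
    "analyze" = {
      spikes <- read_spike_times(cfg$spikes_file)
      h <- isi_histogram(spikes, cfg$bin_width)
      write_isi_histogram(h, file.path(out_dir, "isih.tsv"))
      cl <- isi_clusters(spikes)
      writeLines(c("isi_cluster_ms", sprintf("%.6f", cl)),
                 file.path(out_dir, "isi_clusters.tsv"))
      list(histogram = h, clusters = cl)
    })
  write_manifest(file.path(out_dir, "manifest.txt"), cfg)
  invisible(res)
}

run_steady_scenario <- function(cfg, out_dir, verbose) {
  temps <- cfg$temperatures
  if (is.null(temps)) stop("steady scenario needs temperatures",
                           call. = FALSE)
  rows <- list()
  out <- list()
  for (Te in temps) {
    tag <- sprintf("T%g", Te)
    st <- steady_burst_stats(cfg$pset, Te, cfg$cfg)
    write_trajectory(st$trajectory,
                     file.path(out_dir, sprintf("trajectory_%s.tsv", tag)))
    analyze_train(st$spikes, st$windows, out_dir, tag, cfg$bin_width,
                  verbose)
    rows[[tag]] <- data.frame(Teff = Te, mean_SB = st$mean_SB,
                              mean_BP = st$mean_BP,
                              delta = attr(st$windows, "delta"))
    out[[tag]] <- st
  }
  summary <- do.call(rbind, rows)
  writeLines(c("Teff_C\tmean_SB\tmean_BP_ms\tdelta_ms",
               sprintf("%.6f\t%.6f\t%.6f\t%.6f", summary$Teff,
                       summary$mean_SB, summary$mean_BP, summary$delta)),
             file.path(out_dir, "steady_summary.tsv"))
  c(out, list(summary = summary))
}

run_transition_scenario <- function(cfg, out_dir, verbose) {
  tr <- cfg$transitions
  if (is.null(tr) || !nrow(tr))
    stop("transition scenario needs transitions", call. = FALSE)
  a <- if (is.null(cfg$a)) default_width_fit() else cfg$a
  rows <- list()
  out <- list()
  for (i in seq_len(nrow(tr))) {
    spec <- make_transition(tr$Ti_eff[i], tr$Tf_eff[i])
    tag <- sprintf("T%g_to_T%g", spec$Ti_eff, spec$Tf_eff)
    traj <- simulate_transition(cfg$pset, spec, a, cfg$cfg)
    write_trajectory(traj,
                     file.path(out_dir, sprintf("trajectory_%s.tsv", tag)))
    spikes <- detect_spikes(traj)
    windows <- overlap_windows(traj)
    bursts <- analyze_train(spikes, windows, out_dir, tag, cfg$bin_width,
                            verbose)
    rows[[tag]] <- data.frame(
      Ti_eff = spec$Ti_eff, Tf_eff = spec$Tf_eff,
      n_spikes = length(spikes), n_bursts = nrow(bursts$bursts),
      max_SB = if (length(bursts$SB)) max(bursts$SB) else 0L,
      mean_BP = if (length(bursts$BP)) mean(bursts$BP) else NA_real_)
    out[[tag]] <- list(trajectory = traj, spikes = spikes,
                       windows = windows, bursts = bursts)
  }
  summary <- do.call(rbind, rows)
  writeLines(c("Ti_eff_C\tTf_eff_C\tn_spikes\tn_bursts\tmax_SB\tmean_BP_ms",
               sprintf("%.6f\t%.6f\t%d\t%d\t%d\t%.6f", summary$Ti_eff,
                       summary$Tf_eff, summary$n_spikes,
                       summary$n_bursts, summary$max_SB,
                       summary$mean_BP)),
             file.path(out_dir, "transition_summary.tsv"))
  c(out, list(summary = summary))
}

scenario_config_from_file <- function(path) {
  if (!file.exists(path))
    stop("scenario config not found: ", path, call. = FALSE)
  kv <- read_keyvals(path)
  if (is.null(kv$command))
    stop("scenario config needs a 'command' key", call. = FALSE)
  num <- function(key, default = NULL)
    if (is.null(kv[[key]])) default else parse_config_number(kv[[key]])
  temps <- if (!is.null(kv$temperatures))
    as.numeric(strsplit(kv$temperatures, ",")[[1]]) else NULL
  transitions <- if (!is.null(kv$transitions)) {
    pairs <- strsplit(strsplit(kv$transitions, ",")[[1]], "->")
    data.frame(Ti_eff = as.numeric(vapply(pairs, `[[`, "", 1L)),
               Tf_eff = as.numeric(vapply(pairs, `[[`, "", 2L)))
  } else NULL
  scenario_config(
    command = kv$command,
    pset = if (!is.null(kv$params)) kv$params else default_tanh_params(),
    temperatures = temps, transitions = transitions,
    a = num("a"), spikes_file = kv$spikes_file,
    cfg = simulation_config(
      dt = num("dt", 0.01) , t_end = num("t_end"),
      theta0 = num("theta0", 0),
      phase_mode = if (!is.null(kv$phase_mode)) kv$phase_mode
                   else "integrated",
      record_stride = num("record_stride", 1)),
    bin_width = num("bin_width", 2))
}

#' Command-line entry point
#'
#' Thin wrapper so the tool can be driven from `Rscript`:
#' ```
#' Rscript -e 'coldburst::coldburst_cli()' preset steady_sweep --out out/
#' Rscript -e 'coldburst::coldburst_cli()' run scenario.cfg --out out/
#' ```
#' The first positional argument is `preset` or `run`; the second is the
#' preset name or config path.  `--out DIR` (required) sets the output
#' directory, `--quiet` suppresses progress logging.  Invalid input
#' raises an error (non-zero exit under `Rscript`).
#'
#' @param args character vector of CLI arguments; defaults to the real
#'   command line.
#' @return Invisibly, the scenario result list.
#' @export
coldburst_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- paste(
    "usage: coldburst (preset <name> | run <config>) --out <dir>",
    "[--quiet]")
  out <- NULL
  quiet <- FALSE
  pos <- character(0)
  i <- 1L
  while (i <= length(args)) {
    a <- args[i]
    if (a == "--out") {
      if (i == length(args)) stop(usage, call. = FALSE)
      out <- args[i + 1L]; i <- i + 2L
    } else if (a == "--quiet") {
      quiet <- TRUE; i <- i + 1L
    } else {
      pos <- c(pos, a); i <- i + 1L
    }
  }
  if (length(pos) != 2L || is.null(out)) stop(usage, call. = FALSE)
  cfg <- switch(pos[1],
                preset = scenario_preset(pos[2]),
                run = scenario_config_from_file(pos[2]),
                stop(usage, call. = FALSE))
  run_scenario(cfg, out, verbose = !quiet)
}
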