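# End-to-end orchestration: synthetic environment and tracks (or user CSV
# inputs) -> ingest -> movement model -> control ensemble -> covariates ->
# Monte Carlo stepwise RSF -> report. One master seed fans out
# deterministically to per-stage, per-animal, per-replicate streams.

#' Pipeline configuration
#'
#' Houses the analysis constants: the Bering Sea boundary parallel
#' (65 deg 45 min N), the 10% ice-edge level with its 50 km minimum
#' contour, the 1000 m shelf-break isobath, 20 control replicates and
#' alpha = 0.05, plus movement-model and synthetic-world knobs. A bare
#' config therefore reproduces the canonical settings.
#'
#' @param seed Master RNG seed.
#' @param n_rep Control replicates (>= 2).
#' @param alpha Stepwise significance-to-stay level, in (0, 1).
#' @param boundary_lat Bering Sea boundary latitude.
#' @param ice_edge_level Ice-edge concentration, %.
#' @param min_contour_km Minimum retained ice-edge contour length, km.
#' @param isobath_m Shelf-break isobath, m.
#' @param max_speed_kmh Speed cap for the movement model.
#' @param n_bearing_bins,n_speed_bins Movement-model bin counts.
#' @param max_gap_h Fit-exclusion threshold for long gaps, hours.
#' @param min_steps Minimum pooled steps for the movement fit.
#' @param n_animals,n_steps Synthetic-mode cohort size and track length.
#' @param truth Named truth coefficients for the synthetic generator.
#' @param argos_error Add Argos-style error to synthetic tracks.
#' @param env_cfg An [env_config()] for synthetic mode.
#' @param initial_terms Initial RSF terms.
#' @param tracks_csv,metadata_csv Optional paths to user location and
#'   metadata tables (CSV); when given they replace the synthetic tracks.
#' @param out_dir Optional output directory for stage artifacts.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1L, n_rep = 20, alpha = 0.05,
                            boundary_lat = 65.75, ice_edge_level = 10,
                            min_contour_km = 50, isobath_m = 1000,
                            max_speed_kmh = 8, n_bearing_bins = 36,
                            n_speed_bins = 20, max_gap_h = 72,
                            min_steps = 100, n_animals = 17, n_steps = 60,
                            truth = c("sqrt(d2ice)" = -0.3,
                                      "ice_conc" = 0.05,
                                      "ice_conc^2" = -3e-4),
                            argos_error = FALSE, env_cfg = env_config(),
                            initial_terms = rsf_initial_terms(),
                            tracks_csv = NULL, metadata_csv = NULL,
                            out_dir = NULL) {
  if (n_rep < 2) stop("invalid config: n_rep must be >= 2")
  if (alpha <= 0 || alpha >= 1) stop("invalid config: alpha must be in (0,1)")
  for (p in c(tracks_csv, metadata_csv))
    if (!is.null(p) && !file.exists(p))
      stop(sprintf("invalid config: path does not exist: %s", p))
  structure(as.list(environment()), class = "pipeline_config")
}

read_csv_tracks <- function(path) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  raw$timestamp <- as.POSIXct(raw$timestamp, tz = "UTC")
  raw$animal_id <- as.character(raw$animal_id)
  raw
}

#' Run the full pipeline
#'
#' Synthetic mode (default): build the environment, generate selective
#' tracks from the configured truth, then ingest, fit the null movement
#' model, simulate the matched control ensemble, attach covariates, and
#' run the Monte Carlo stepwise RSF. With `tracks_csv`/`metadata_csv` set,
#' observed tracks are read instead of generated. Stage outputs are
#' written under `out_dir` when configured; reruns with the same config
#' are identical.
#'
#' @param cfg A [pipeline_config()].
#' @param quiet Suppress progress messages.
#' @return List with `env`, `tracks` (included only), `inclusion`,
#'   `summary`, `model`, `controls`, `rows`, `result`, `manifest`.
#' @export
run_pipeline <- function(cfg = pipeline_config(), quiet = FALSE) {
  stopifnot(inherits(cfg, "pipeline_config"))
  say <- function(stage, ...) if (!quiet)
    message(jsonlite::toJSON(list(stage = stage, msg = paste0(...),
                                  time = format(Sys.time(), tz = "UTC")),
                             auto_unbox = TRUE))
  stage <- function(name, expr) {
    say(name, "start")
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE))
  }

  env <- stage("environment", {
    ec <- cfg$env_cfg
    ec$seed <- derive_seed(cfg$seed, 1L)
    make_environment(ec)
  })

  raw_tracks <- stage("tracks", {
    if (!is.null(cfg$tracks_csv)) {
      raw <- read_csv_tracks(cfg$tracks_csv)
      meta <- utils::read.csv(cfg$metadata_csv, stringsAsFactors = FALSE)
      meta$animal_id <- as.character(meta$animal_id)
      ingest_tracks(raw, meta, env)
    } else {
      trs <- make_selective_tracks(env, truth = cfg$truth,
                                   n_animals = cfg$n_animals,
                                   n_steps = cfg$n_steps,
                                   seed = derive_seed(cfg$seed, 2L))
      if (cfg$argos_error)
        trs <- lapply(trs, function(tr) {
          e <- add_argos_error(tr, seed = derive_seed(
            cfg$seed, 3L, sum(utf8ToInt(tr$animal_id[1]))))
          attr(e, "sex") <- attr(tr, "sex")
          class(e) <- class(tr)
          e
        })
      lapply(trs, function(tr) {
        f <- filter_locations(as.data.frame(tr)[, c("animal_id", "timestamp",
                                                    "lon", "lat", "lq")],
                              env, sex = attr(tr, "sex"))
        f
      })
    }
  })

  inclusion <- stage("inclusion", {
    lapply(raw_tracks, include_for_rsf, boundary_lat = cfg$boundary_lat)
  })
  tracks <- raw_tracks[vapply(inclusion, `[[`, logical(1), "include")]
  if (length(tracks) == 0) stop("pipeline: no track passed the inclusion rule")
  say("inclusion", sprintf("%d of %d tracks included", length(tracks),
                           length(raw_tracks)))
  summary_tbl <- summarize_tracks(raw_tracks, cfg$boundary_lat)

  model <- stage("movement_fit", {
    steps <- do.call(rbind, lapply(tracks, decompose_steps))
    fit_movement_model(steps, n_bearing_bins = cfg$n_bearing_bins,
                       n_speed_bins = cfg$n_speed_bins,
                       max_speed_kmh = cfg$max_speed_kmh,
                       max_gap_h = cfg$max_gap_h, min_steps = cfg$min_steps)
  })

  controls <- stage("simulate_null", {
    simulate_ensemble(model, tracks, env, n_rep = cfg$n_rep,
                      seed = derive_seed(cfg$seed, 4L))
  })

  rows <- stage("covariates", {
    build_covariate_table(tracks, controls, env,
                          edge_level = cfg$ice_edge_level,
                          edge_min_km = cfg$min_contour_km,
                          isobath_m = cfg$isobath_m)
  })

  result <- stage("rsf", {
    stepwise_eliminate(rows, initial = cfg$initial_terms, alpha = cfg$alpha)
  })

  manifest <- list(
    seed = cfg$seed, n_rep = cfg$n_rep, alpha = cfg$alpha,
    n_tracks_in = length(raw_tracks), n_tracks_included = length(tracks),
    n_controls = length(controls), n_rows = nrow(rows),
    n_rows_incomplete = attr(rows, "n_incomplete"),
    replicates_converged = vapply(result$fits, function(f)
      isTRUE(f$converged), logical(1)),
    final_terms = result$terms,
    config_hash = config_hash(cfg)
  )

  run <- list(env = env, tracks = tracks, inclusion = inclusion,
              summary = summary_tbl, model = model, controls = controls,
              rows = rows, result = result, manifest = manifest)
  if (!is.null(cfg$out_dir)) write_outputs(run, cfg)
  run
}

# stable short hash of the configuration (djb2 over its deparse)
config_hash <- function(cfg) {
  s <- paste(deparse(cfg[setdiff(names(cfg), "out_dir")]), collapse = "")
  h <- 5381
  for (v in utf8ToInt(s)) h <- (h * 33 + v) %% 2147483647
  sprintf("%08x", h)
}

write_outputs <- function(run, cfg) {
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  hdr <- sprintf("# config_hash=%s seed=%d", run$manifest$config_hash,
                 cfg$seed)
  wcsv <- function(df, file) {
    path <- file.path(cfg$out_dir, file)
    writeLines(hdr, path)
    suppressWarnings(utils::write.table(df, path, sep = ",", append = TRUE,
                                        row.names = FALSE, qmethod = "double"))
  }
  wcsv(run$result$final, "final_model.csv")
  wcsv(run$result$trace, "elimination_trace.csv")
  wcsv(run$summary$per_animal, "track_summary.csv")
  rows_out <- run$rows
  rows_out$timestamp <- format(rows_out$timestamp, tz = "UTC")
  wcsv(rows_out, "covariates.csv")
  jsonlite::write_json(run$manifest, file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  jsonlite::write_json(
    list(bearing_edges = run$model$bearing_edges,
         bearing_trans = run$model$bearing_trans,
         speed_edges = run$model$speed_edges,
         speed_marg = run$model$speed_marg,
         transform = run$model$transform, meta = run$model$meta),
    file.path(cfg$out_dir, "movement_model.json"),
    auto_unbox = TRUE, digits = NA)
  invisible(NULL)
}

#' Render a plain-text run report
#'
#' Markdown summary of a completed run: inclusion and QC counts, the
#' elimination trace, the final coefficient table, and (when the ice terms
#' survived) the selection curves with availability weighting.
#'
#' @param run A [run_pipeline()] result.
#' @return Character vector of markdown lines.
#' @export
render_report <- function(run) {
  if (is.null(run$result)) stop("report error: missing stage output 'rsf'")
  mc <- run$result$final
  lines <- c(
    "# Habitat selection run report",
    "",
    sprintf("Config hash: %s; seed: %d; replicates: %d",
            run$manifest$config_hash, run$manifest$seed,
            run$manifest$n_rep),
    sprintf("Tracks: %d ingested, %d included; covariate rows: %d (%d incomplete, excluded)",
            run$manifest$n_tracks_in, run$manifest$n_tracks_included,
            run$manifest$n_rows, run$manifest$n_rows_incomplete),
    "",
    "## Eliminated terms (in order)",
    ""
  )
  if (nrow(run$result$trace) == 0) {
    lines <- c(lines, "(none: all initial terms retained)")
  } else {
    lines <- c(lines, sprintf("%d. %s (p = %.4f)", run$result$trace$step,
                              run$result$trace$term, run$result$trace$p))
  }
  lines <- c(lines, "", "## Final model", "",
             sprintf("%-28s %10s %10s %8s %10s", "term", "estimate", "SE",
                     "z", "p"),
             sprintf("%-28s %10.4f %10.4f %8.3f %10.4g", mc$term,
                     mc$estimate, mc$se, mc$z, mc$p))
  habitat_terms <- setdiff(run$result$terms, "(Intercept)")
  if (length(habitat_terms) == 0)
    lines <- c(lines, "", "no habitat terms retained")
  if (all(c("ice_conc", "ice_conc^2") %in% run$result$terms)) {
    pk <- peak_ice_concentration(run$result)
    lines <- c(lines, "", "## Selection curves", "",
               sprintf("Selection peaks at %.1f%% ice concentration.", pk))
    curve <- odds_of_selection(
      run$result,
      profile = list(sex = "F", sea_ice = "yes", d2ice = 10, d2coast = 100,
                     depth_m = 60, d21kiso = 300),
      vary = "ice_conc", grid = seq(0, 100, by = 10), rows = run$rows)
    lines <- c(lines, "",
               sprintf("%6s %10s %12s", "conc", "odds", "availability"),
               sprintf("%6.0f %10.3f %12.3f", curve$value, curve$odds,
                       curve$availability))
  }
  lines
}

#' Read a flat key = value config file
#'
#' Text lines `key = value` (comments with `#`); numeric values are
#' converted, `truth.<term>` entries collect into the truth vector.
#'
#' @param path File path.
#' @return A [pipeline_config()].
#' @export
read_config <- function(path) {
  ln <- readLines(path, warn = FALSE)
  ln <- sub("#.*$", "", ln)
  ln <- trimws(ln)
  ln <- ln[nzchar(ln)]
  kv <- strsplit(ln, "\\s*=\\s*")
  keys <- vapply(kv, `[`, character(1), 1)
  vals <- vapply(kv, `[`, character(1), 2)
  num <- suppressWarnings(as.numeric(vals))
  args <- stats::setNames(
    lapply(seq_along(keys), function(i)
      if (is.na(num[i])) vals[i] else num[i]), keys)
  tr <- grepl("^truth\\.", keys)
  truth <- unlist(args[tr])
  names(truth) <- sub("^truth\\.", "", names(truth))
  args <- args[!tr]
  if (length(truth)) args$truth <- truth
  if (!is.null(args$seed)) args$seed <- as.integer(args$seed)
  do.call(pipeline_config, args)
}

#' Command-line entry point
#'
#' `sealrsf_main(c("run-all", "--seed", "7", "--out", "outdir"))` runs the
#' synthetic end-to-end pipeline and writes stage outputs plus
#' `report.md`; the `report` subcommand re-renders the report for an
#' existing output directory is not supported offline and simply reruns.
#'
#' @param args Character vector of CLI arguments (default
#'   `commandArgs(trailingOnly = TRUE)`).
#' @return Invisibly, the run object.
#' @export
sealrsf_main <- function(args = commandArgs(trailingOnly = TRUE)) {
  get_opt <- function(flag, default = NULL) {
    i <- which(args == flag)
    if (length(i)) args[i[1] + 1L] else default
  }
  cmd <- if (length(args) && !startsWith(args[1], "--")) args[1] else "run-all"
  cfg_path <- get_opt("--config")
  cfg <- if (!is.null(cfg_path)) read_config(cfg_path) else pipeline_config()
  seed <- get_opt("--seed")
  if (!is.null(seed)) cfg$seed <- as.integer(seed)
  n_rep <- get_opt("--n-rep")
  if (!is.null(n_rep)) cfg$n_rep <- as.integer(n_rep)
  cfg$out_dir <- get_opt("--out", cfg$out_dir)
  quiet <- identical(get_opt("--log-level", "info"), "quiet")
  if (!cmd %in% c("run-all", "report"))
    stop(sprintf("unknown subcommand '%s'", cmd))
  run <- run_pipeline(cfg, quiet = quiet)
  rep_lines <- render_report(run)
  if (!is.null(cfg$out_dir))
    writeLines(rep_lines, file.path(cfg$out_dir, "report.md"))
  else cat(rep_lines, sep = "\n")
  invisible(run)
}
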