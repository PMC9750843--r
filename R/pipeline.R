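default_config <- function() {
  list(
    layout = list(n_positions = 470L, n_cols = 24L, dx = 1, dy = 1.5,
                  n_dead = 22L),
    layout_file = NULL,
    params_file = NULL,
    spec_file = NULL,
    distances = default_distance_grid(),
    n_draws = 2000L,
    noise_mode = "independent",
    seed = 1L,
    out_dir = "gardensim-output",
    band_levels = c(0.68, 0.95),
    r_threshold = 0.99,
    band_level = 0.68,
    size_median = 0.05,
    size_gsd = 1.6,
    cutoff_radius = Inf,
    write_results = TRUE
  )
}

#' Validate a pipeline configuration
#'
#' Accepts a named list or a path to a flat YAML/JSON key-value file, applies
#' defaults (which mirror the reference study: 470 positions, 22 dead, 15
#' distances from 0.5 to 4 m, 2000 draws), rejects unknown keys, and range-
#' checks every value.
#'
#' @param raw Named list, or path to a `.yaml`/`.yml`/`.json` config file.
#'   An empty list yields the full default configuration.
#' @return A validated `run_config` list.
#' @export
#' @examples
#' cfg <- validate_config(list(n_draws = 10, distances = c(0.5, 4)))
#' cfg$n_draws
validate_config <- function(raw = list()) {
  if (is.character(raw) && length(raw) == 1) {
    if (!file.exists(raw)) {
      rlang::abort(sprintf("config file not found: %s", raw),
                   class = "gardensim_error_config")
    }
    raw <- if (grepl("\\.json$", raw, ignore.case = TRUE)) {
      jsonlite::read_json(raw, simplifyVector = TRUE)
    } else {
      yaml::read_yaml(raw)
    }
    raw <- raw %||% list()
  }
  if (!is.list(raw)) {
    rlang::abort("config must be a named list or a file path.",
                 class = "gardensim_error_config")
  }
  defaults <- default_config()
  unknown <- setdiff(names(raw), names(defaults))
  if (length(unknown) > 0) {
    rlang::abort(paste("unknown config key(s):", paste(unknown, collapse = ", ")),
                 class = "gardensim_error_config")
  }
  cfg <- utils::modifyList(defaults, raw, keep.null = TRUE)
  if ("layout" %in% names(raw)) {
    bad <- setdiff(names(raw$layout), names(defaults$layout))
    if (length(bad) > 0) {
      rlang::abort(paste("unknown layout key(s):", paste(bad, collapse = ", ")),
                   class = "gardensim_error_config")
    }
    cfg$layout <- utils::modifyList(defaults$layout, raw$layout)
  }

  # YAML sequences of mixed int/float arrive as lists; flatten numeric keys
  for (f in c("distances", "band_levels")) {
    if (is.list(cfg[[f]]) && all(vapply(cfg[[f]], is.numeric, logical(1)))) {
      cfg[[f]] <- as.numeric(unlist(cfg[[f]]))
    }
  }

  check_range <- function(ok, what) {
    if (!isTRUE(ok)) {
      rlang::abort(paste("config value out of range:", what),
                   class = "gardensim_error_config_range")
    }
  }
  check_range(is.numeric(cfg$distances) && length(cfg$distances) > 0 &&
                all(is.finite(cfg$distances)) && all(cfg$distances > 0) &&
                !is.unsorted(cfg$distances),
              "distances must be positive and sorted ascending")
  check_range(is.numeric(cfg$n_draws) && length(cfg$n_draws) == 1 &&
                cfg$n_draws >= 1, "n_draws must be >= 1")
  check_range(is.character(cfg$noise_mode) &&
                cfg$noise_mode %in% c("independent", "common", "none"),
              "noise_mode must be independent, common or none")
  check_range(is.numeric(cfg$seed) && length(cfg$seed) == 1 &&
                cfg$seed == round(cfg$seed), "seed must be an integer")
  check_range(all(cfg$band_levels > 0 & cfg$band_levels < 1),
              "band_levels must lie in (0, 1)")
  check_range(cfg$band_level > 0 && cfg$band_level < 1,
              "band_level must lie in (0, 1)")
  check_range(cfg$r_threshold > 0 && cfg$r_threshold <= 1,
              "r_threshold must lie in (0, 1]")
  check_range(cfg$size_median > 0 && cfg$size_gsd >= 1,
              "size distribution needs median > 0 and gsd >= 1")
  check_range(is.numeric(cfg$cutoff_radius) && cfg$cutoff_radius > 0,
              "cutoff_radius must be positive")
  lay <- cfg$layout
  check_range(lay$n_positions >= 1 && lay$n_cols >= 1 &&
                lay$dx > 0 && lay$dy > 0 &&
                lay$n_dead >= 0 && lay$n_dead < lay$n_positions,
              "layout geometry/mortality")
  for (f in c("layout_file", "params_file", "spec_file")) {
    if (!is.null(cfg[[f]]) && !file.exists(cfg[[f]])) {
      rlang::abort(sprintf("config file reference does not exist: %s = %s",
                           f, cfg[[f]]),
                   class = "gardensim_error_config")
    }
  }
  cfg$n_draws <- as.integer(cfg$n_draws)
  cfg$seed <- as.integer(cfg$seed)
  structure(cfg, class = "run_config")
}

#' Run the full crowding-bias pipeline
#'
#' Layout generation (or load) -> posterior draws (or load) -> two distance
#' sweeps (independent-noise for the F analysis, deterministic for the
#' correlation analysis) -> bias summaries -> minimum-distance
#' recommendation, with all tables written to `out_dir`:
#' `layout.csv`, `results.csv` and `results_deterministic.csv` (optional,
#' long format), `bias_summary.csv`, `group_means.csv`,
#' `recommendation.json`, `run_log.txt`, and `manifest.json`. Output is a
#' pure function of `(config, seed)`.
#'
#' @param config A list, config file path, or `run_config` from
#'   [validate_config()].
#' @return Invisibly, a list with `layout`, `draws`, `summary`
#'   (a [bias_summary()]), `recommendation`, `config`, and `files`.
#' @export
run_pipeline <- function(config = list()) {
  cfg <- if (inherits(config, "run_config")) config else validate_config(config)
  t0 <- Sys.time()
  dir_ok <- dir.exists(cfg$out_dir) || dir.create(cfg$out_dir, recursive = TRUE)
  if (!dir_ok) {
    rlang::abort(sprintf("cannot create output directory: %s", cfg$out_dir),
                 class = "gardensim_error_io")
  }

  # derive independent sub-seeds (< 2^31) for each stochastic stage
  set.seed(cfg$seed)
  sub <- sample.int(2147483646L, 4)

  layout <- if (!is.null(cfg$layout_file)) {
    read_garden_layout(cfg$layout_file)
  } else {
    make_grid_layout(n_positions = cfg$layout$n_positions,
                     n_cols = cfg$layout$n_cols,
                     dx = cfg$layout$dx, dy = cfg$layout$dy,
                     n_dead = cfg$layout$n_dead, seed = sub[1])
  }
  if (!"size" %in% names(layout)) {
    size_spec <- tibble::tibble(group = unique(as.character(layout$group)),
                                median = cfg$size_median, gsd = cfg$size_gsd)
    layout <- make_initial_sizes(layout, size_spec, seed = sub[2])
  }

  draws <- if (!is.null(cfg$params_file)) {
    as_posterior_draws(list(read_growth_params(cfg$params_file)))
  } else {
    spec <- if (!is.null(cfg$spec_file)) read_group_spec(cfg$spec_file)
            else default_group_spec()
    make_posterior_draws(spec, n_draws = cfg$n_draws, seed = sub[3])
  }

  log_lines <- c(
    sprintf("gardensim %s", as.character(utils::packageVersion("gardensim"))),
    sprintf("R %s", paste(R.version$major, R.version$minor, sep = ".")),
    sprintf("seed: %d", cfg$seed),
    sprintf("positions: %d (alive %d)", nrow(layout), sum(layout$alive)),
    sprintf("distances: %s", paste(cfg$distances, collapse = ", ")),
    sprintf("draws: %d", n_draws(draws)),
    sprintf("noise_mode (F analysis): %s", cfg$noise_mode)
  )

  res_noise <- run_sweep(layout, draws, distances = cfg$distances,
                         noise_mode = cfg$noise_mode, seed = sub[4],
                         cutoff_radius = cfg$cutoff_radius)
  res_det <- run_sweep(layout, draws, distances = cfg$distances,
                       noise_mode = "none", seed = sub[4],
                       cutoff_radius = cfg$cutoff_radius)
  summary <- bias_summary(res_noise, res_det, levels = cfg$band_levels,
                          r_threshold = cfg$r_threshold,
                          band_level = cfg$band_level)

  files <- c(layout = file.path(cfg$out_dir, "layout.csv"),
             bias = file.path(cfg$out_dir, "bias_summary.csv"),
             groups = file.path(cfg$out_dir, "group_means.csv"),
             rec = file.path(cfg$out_dir, "recommendation.json"),
             log = file.path(cfg$out_dir, "run_log.txt"),
             manifest = file.path(cfg$out_dir, "manifest.json"))
  write_garden_layout(layout, files[["layout"]])
  readr::write_csv(tidy(summary), files[["bias"]])
  gm <- summary$group_means
  gm$group <- as.character(gm$group)
  readr::write_csv(gm, files[["groups"]])
  jsonlite::write_json(
    list(recommended_min_distance_m = summary$recommendation,
         r_threshold = cfg$r_threshold, band_level = cfg$band_level,
         qualifying = !is.na(summary$recommendation)),
    files[["rec"]], digits = NA, auto_unbox = TRUE, null = "null"
  )
  if (isTRUE(cfg$write_results)) {
    files[["results"]] <- file.path(cfg$out_dir, "results.csv")
    files[["results_det"]] <- file.path(cfg$out_dir, "results_deterministic.csv")
    write_scenario_results(res_noise, files[["results"]])
    write_scenario_results(res_det, files[["results_det"]])
  }

  elapsed <- as.numeric(difftime(Sys.time(), t0, units = "secs"))
  log_lines <- c(log_lines,
                 sprintf("simulations: %d", length(cfg$distances) * n_draws(draws)),
                 sprintf("recommended min distance: %s",
                         if (is.na(summary$recommendation)) "none"
                         else sprintf("%g m", summary$recommendation)),
                 sprintf("wall time: %.1f s", elapsed))
  writeLines(log_lines, files[["log"]])
  cfg_out <- unclass(cfg)[setdiff(names(cfg), "layout")]
  if (!is.finite(cfg_out$cutoff_radius)) cfg_out$cutoff_radius <- "Inf"
  manifest <- list(config = cfg_out,
                   layout = cfg$layout,
                   config_hash = rlang::hash(unclass(cfg)),
                   n_simulations = length(cfg$distances) * n_draws(draws))
  jsonlite::write_json(manifest, files[["manifest"]], digits = NA,
                       auto_unbox = TRUE, null = "null", force = TRUE)

  invisible(list(layout = layout, draws = draws, summary = summary,
                 recommendation = summary$recommendation,
                 config = cfg, files = files))
}
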