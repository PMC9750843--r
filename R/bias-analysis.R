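# columnwise one-way F statistics for a matrix of responses (one column per
# draw) under a fixed grouping; conventions: zero between-group SS -> F = 0,
# zero within-group SS with nonzero between -> +Inf
f_stat_cols <- function(Y, g) {
  if (!is.matrix(Y)) Y <- matrix(Y, ncol = 1)
  g <- as.integer(factor(g))
  n <- length(g)
  k <- max(g)
  cnt <- tabulate(g, k)
  gs <- rowsum(Y, g, reorder = TRUE)       # k x m group sums
  gm <- colSums(Y) / n                     # grand means
  M <- gs / cnt                            # group means
  ssb <- colSums(cnt * (M - rep(gm, each = k))^2)
  sst <- colSums(Y^2) - n * gm^2
  ssw <- pmax(sst - ssb, 0)
  tolb <- 1e-12 * pmax(sst, .Machine$double.eps)
  f <- (ssb / (k - 1)) / (ssw / (n - k))
  f[ssw <= tolb & ssb > tolb] <- Inf
  f[ssb <= tolb] <- 0
  f
}

#' One-way ANOVA F statistic
#'
#' Classical between/within mean-square ratio with degrees of freedom
#' (k - 1, n - k). Two continuity conventions beyond the textbook formula:
#' a response with zero between-group sum of squares returns F = 0, and one
#' with zero within-group variance but non-zero between-group variance
#' returns `Inf`.
#'
#' @param response Numeric response, one value per plant.
#' @param groups Group labels, one per plant; at least two distinct groups.
#' @return A one-row tibble with `f_value`, `df1`, `df2`.
#' @export
#' @examples
#' one_way_f(c(1, 2, 3, 4), c("A", "A", "B", "B")) # F = 8, df (1, 2)
one_way_f <- function(response, groups) {
  if (length(response) != length(groups)) {
    rlang::abort("`response` and `groups` must have equal length.",
                 class = "gardensim_error_shape")
  }
  gf <- factor(groups)
  gf <- droplevels(gf)
  k <- nlevels(gf)
  n <- length(response)
  if (k < 2) {
    rlang::abort("ANOVA needs at least two groups.",
                 class = "gardensim_error_degenerate_design")
  }
  if (n <= k) {
    rlang::abort("ANOVA needs more observations than groups.",
                 class = "gardensim_error_degenerate_design")
  }
  tibble::tibble(f_value = f_stat_cols(matrix(response, ncol = 1), gf),
                 df1 = k - 1L, df2 = n - as.integer(k))
}

# reshape one-distance results into per-draw matrices (plants x draws)
results_matrices <- function(results) {
  results <- dplyr::arrange(tibble::as_tibble(results), .data$draw,
                            .data$plant_id)
  dr <- unique(results$draw)
  n <- nrow(results) / length(dr)
  if (n != round(n)) {
    rlang::abort("results are unbalanced across draws.",
                 class = "gardensim_error_shape")
  }
  list(
    draws = dr,
    groups = results$group[seq_len(n)],
    full = matrix(results$mu_full, nrow = n),
    base = matrix(results$mu_base, nrow = n)
  )
}

#' Relativized F samples at one planting distance
#'
#' For each posterior draw, computes the one-way F statistic of the
#' full-minus-base growth difference `mu_full - mu_base` across groups, and
#' relativizes it by the average base-model F over draws:
#' `F(mu_full - mu_base) / mean_draws F(mu_base)`. A value near zero means
#' the spatial term adds nothing to group separation; a value near one means
#' crowding generates group differences as large as the intrinsic growth
#' rates do.
#'
#' @param results A `scenario_results` tibble filtered to a single distance.
#' @return A tibble with columns `draw`, `rel_f`.
#' @export
relative_f <- function(results) {
  if (dplyr::n_distinct(results$distance) != 1) {
    rlang::abort("`relative_f()` expects results at a single distance.",
                 class = "gardensim_error_shape")
  }
  m <- results_matrices(results)
  f_diff <- f_stat_cols(m$full - m$base, m$groups)
  f_base <- mean(f_stat_cols(m$base, m$groups))
  if (!is.finite(f_base) || f_base == 0) {
    rlang::abort("mean base-model F is zero; relativized F undefined.",
                 class = "gardensim_error_undefined_relativization")
  }
  tibble::tibble(draw = m$draws, rel_f = f_diff / f_base)
}

#' Relativized-F curve across the distance grid
#'
#' Applies [relative_f()] at every distance in the results and summarizes
#' the per-draw samples with their mean and central percentile bands.
#'
#' @param results A `scenario_results` tibble covering one or more distances
#'   (typically generated with `noise_mode = "independent"`).
#' @param levels Band coverage levels (defaults 0.68 and 0.95).
#' @return A `rel_f_curve` tibble with one row per distance: `rel_f_mean`,
#'   band edge columns `rel_f_lo_*` / `rel_f_hi_*`, and a `samples`
#'   list-column of the per-draw values.
#' @export
relative_f_curve <- function(results, levels = c(0.68, 0.95)) {
  per_d <- lapply(split(tibble::as_tibble(results), results$distance),
                  relative_f)
  out <- tibble::tibble(
    distance = as.numeric(names(per_d)),
    rel_f_mean = unname(vapply(per_d, function(x) mean(x$rel_f), numeric(1))),
    samples = unname(lapply(per_d, function(x) x$rel_f))
  )
  out <- add_band_cols(out, "rel_f", levels)
  out <- out[order(out$distance), ]
  tibble::new_tibble(out, band_levels = levels, class = "rel_f_curve",
                     nrow = nrow(out))
}

add_band_cols <- function(curve, prefix, levels) {
  for (lv in levels) {
    bands <- vapply(curve$samples, percentile_band, numeric(2), level = lv)
    tag <- formatC(round(100 * lv), width = 2, flag = "0")
    curve[[paste0(prefix, "_lo_", tag)]] <- bands[1, ]
    curve[[paste0(prefix, "_hi_", tag)]] <- bands[2, ]
  }
  curve
}

#' Full/base correlation-convergence curve
#'
#' For each (distance, draw) pair, the Pearson correlation between the full
#' and base predicted growth vectors across plants; per distance, the mean
#' over draws and central percentile bands. Low r at tight spacing means the
#' two models disagree plant-by-plant; r approaching 1 with distance marks
#' spacings at which neighborhood interactions stop affecting inference.
#' Intended for deterministic (`noise_mode = "none"`) sweeps, so uncertainty
#' is propagated only through the posterior means.
#'
#' @param results A `scenario_results` tibble across distances.
#' @param levels Band coverage levels (defaults 0.68 and 0.95).
#' @return A `cor_curve` tibble with one row per distance: `r_mean`, band
#'   edges `r_lo_*` / `r_hi_*`, and a `samples` list-column.
#' @export
correlation_curve <- function(results, levels = c(0.68, 0.95)) {
  nm <- attr(results, "noise_mode")
  if (!is.null(nm) && !is.na(nm) && nm != "none") {
    rlang::warn("correlation_curve() expects a deterministic (noise_mode = 'none') sweep.")
  }
  per_d <- lapply(split(tibble::as_tibble(results), results$distance),
                  correlation_samples)
  out <- tibble::tibble(
    distance = as.numeric(names(per_d)),
    r_mean = unname(vapply(per_d, mean, numeric(1))),
    samples = unname(per_d)
  )
  out <- add_band_cols(out, "r", levels)
  out <- out[order(out$distance), ]
  tibble::new_tibble(out, band_levels = levels, class = "cor_curve",
                     nrow = nrow(out))
}

correlation_samples <- function(results) {
  m <- results_matrices(results)
  vapply(seq_along(m$draws), function(j) {
    x <- m$full[, j]
    y <- m$base[, j]
    if (stats::sd(x) == 0 || stats::sd(y) == 0) {
      if (isTRUE(all.equal(x, y))) return(1)
      rlang::abort("constant prediction vector: correlation undefined.",
                   class = "gardensim_error_undefined_correlation")
    }
    stats::cor(x, y)
  }, numeric(1))
}

#' Central empirical percentile band
#'
#' The central quantile interval `[(1 - level)/2, (1 + level)/2]`, with
#' linear interpolation between order statistics (`stats::quantile` type 7).
#'
#' @param samples Numeric samples (non-empty).
#' @param level Coverage in (0, 1).
#' @return Length-2 numeric `(low, high)`.
#' @export
#' @examples
#' percentile_band(1:100, 0.95)
percentile_band <- function(samples, level) {
  if (length(samples) == 0) {
    rlang::abort("no samples.", class = "gardensim_error_no_data")
  }
  if (!is.numeric(level) || length(level) != 1 || level <= 0 || level >= 1) {
    rlang::abort("`level` must be in (0, 1).",
                 class = "gardensim_error_no_data")
  }
  unname(stats::quantile(samples, c((1 - level) / 2, (1 + level) / 2),
                         names = FALSE, type = 7))
}

#' Recommend a minimum planting distance
#'
#' The smallest distance on the grid at which the lower edge of the
#' `band_level` percentile band of the full/base correlation exceeds
#' `r_threshold` — i.e. the tightest spacing at which, across posterior
#' uncertainty, neighborhood interactions are unlikely to affect inference
#' on group means. Returns `NA` (an explicit "no recommendation" sentinel,
#' not an error) when no distance qualifies.
#'
#' @param curve A [correlation_curve()] result.
#' @param r_threshold Correlation threshold (default 0.99).
#' @param band_level Band used for the lower bound (default 0.68, the 1-SD
#'   band; the 95% band is the conservative alternative).
#' @return A single distance in meters, or `NA_real_`.
#' @export
recommend_min_distance <- function(curve, r_threshold = 0.99,
                                   band_level = 0.68) {
  lower <- vapply(curve$samples, function(s) percentile_band(s, band_level)[1],
                  numeric(1))
  ok <- lower > r_threshold
  if (!any(ok)) return(NA_real_)
  min(curve$distance[ok])
}

#' Per-group growth summary at one distance
#'
#' Group means of full-model predicted growth pooled over plants and draws,
#' the SD of the per-draw group means (posterior + residual spread), and the
#' resulting performance ranking (1 = fastest).
#'
#' @param results A `scenario_results` tibble at a single distance.
#' @return A tibble with columns `group`, `mean_growth`, `sd_growth`,
#'   `n_plants`, `rank`.
#' @export
group_summary <- function(results) {
  if (dplyr::n_distinct(results$distance) != 1) {
    rlang::abort("`group_summary()` expects results at a single distance.",
                 class = "gardensim_error_shape")
  }
  per_draw <- dplyr::summarise(
    dplyr::group_by(tibble::as_tibble(results), .data$group, .data$draw),
    m = mean(.data$mu_full), n_plants = dplyr::n(), .groups = "drop"
  )
  out <- dplyr::summarise(
    dplyr::group_by(per_draw, .data$group),
    mean_growth = mean(.data$m),
    sd_growth = stats::sd(.data$m),
    n_plants = .data$n_plants[1],
    .groups = "drop"
  )
  out$rank <- rank(-out$mean_growth, ties.method = "min")
  out
}

#' Summarize crowding bias across a distance sweep
#'
#' Convenience wrapper joining the relativized-F curve (from an
#' independent-noise sweep), the correlation-convergence curve (from a
#' deterministic sweep), per-group means at the two extreme distances, and
#' the minimum-distance recommendation.
#'
#' @param results_noise `scenario_results` with `noise_mode = "independent"`.
#' @param results_det `scenario_results` with `noise_mode = "none"`.
#' @param levels Band coverage levels (defaults 0.68 and 0.95).
#' @param r_threshold,band_level Passed to [recommend_min_distance()].
#' @return A `bias_summary` list with elements `rel_f`, `correlation`,
#'   `group_means` (at min and max distance), `recommendation`,
#'   `r_threshold`, `band_level`.
#' @export
bias_summary <- function(results_noise, results_det,
                         levels = c(0.68, 0.95),
                         r_threshold = 0.99, band_level = 0.68) {
  relf <- relative_f_curve(results_noise, levels = levels)
  corc <- correlation_curve(results_det, levels = levels)
  dlo <- min(results_noise$distance)
  dhi <- max(results_noise$distance)
  gm <- dplyr::bind_rows(
    dplyr::mutate(group_summary(results_noise[results_noise$distance == dlo, ]),
                  distance = dlo, .before = 1),
    dplyr::mutate(group_summary(results_noise[results_noise$distance == dhi, ]),
                  distance = dhi, .before = 1)
  )
  structure(
    list(rel_f = relf, correlation = corc, group_means = gm,
         recommendation = recommend_min_distance(corc, r_threshold, band_level),
         r_threshold = r_threshold, band_level = band_level),
    class = "bias_summary"
  )
}

#' @export
print.bias_summary <- function(x, ...) {
  cat("<bias_summary>\n")
  cat(sprintf("  distances: %g to %g m (%d scenarios), %d draws\n",
              min(x$rel_f$distance), max(x$rel_f$distance),
              nrow(x$rel_f), length(x$rel_f$samples[[1]])))
  cat(sprintf("  mean relativized F: %.3f at %g m -> %.3f at %g m\n",
              x$rel_f$rel_f_mean[1], x$rel_f$distance[1],
              x$rel_f$rel_f_mean[nrow(x$rel_f)],
              x$rel_f$distance[nrow(x$rel_f)]))
  cat(sprintf("  mean full/base correlation: %.3f -> %.3f\n",
              x$correlation$r_mean[1],
              x$correlation$r_mean[nrow(x$correlation)]))
  rec <- if (is.na(x$recommendation)) "none on this grid"
         else sprintf("%g m", x$recommendation)
  cat(sprintf("  recommended minimum distance (r > %.2f, %.0f%% band): %s\n",
              x$r_threshold, 100 * x$band_level, rec))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
tidy.bias_summary <- function(x, ...) {
  relf <- x$rel_f[, setdiff(names(x$rel_f), "samples")]
  corc <- x$correlation[, setdiff(names(x$correlation), "samples")]
  dplyr::left_join(tibble::as_tibble(relf), tibble::as_tibble(corc),
                   by = "distance")
}

#' @importFrom generics glance
#' @export
glance.bias_summary <- function(x, ...) {
  tibble::tibble(
    n_distances = nrow(x$rel_f),
    n_draws = length(x$rel_f$samples[[1]]),
    rel_f_at_min = x$rel_f$rel_f_mean[1],
    rel_f_at_max = x$rel_f$rel_f_mean[nrow(x$rel_f)],
    r_at_min = x$correlation$r_mean[1],
    r_at_max = x$correlation$r_mean[nrow(x$correlation)],
    recommended_distance = x$recommendation
  )
}
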