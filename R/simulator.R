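#' Default distance-scenario grid
#'
#' Fifteen equally spaced planting distances from 0.5 to 4.0 m (0.25 m step),
#' the sweep over which crowding bias is evaluated.
#'
#' @return Numeric vector of 15 distances (meters).
#' @export
default_distance_grid <- function() {
  seq(0.5, 4, length.out = 15)
}

# deterministic per-(distance, draw) substream seeds: results are
# order-independent and identical regardless of which scenarios are run
substream_seeds <- function(seed, n_dist, n_draw) {
  set.seed(seed)
  matrix(sample.int(2147483646L, n_dist * n_draw, replace = TRUE),
         nrow = n_dist)
}

# posterior draws as per-parameter matrices (n_draws x k) for fast indexing
draws_matrices <- function(draws) {
  glab <- draw_groups(draws)
  k <- length(glab)
  nd <- n_draws(draws)
  d <- dplyr::arrange(tibble::as_tibble(draws), .data$draw,
                      match(as.character(.data$group), glab))
  stopifnot(nrow(d) == nd * k)
  list(
    A = matrix(d$alpha, nrow = nd, ncol = k, byrow = TRUE),
    B = matrix(d$beta, nrow = nd, ncol = k, byrow = TRUE),
    G = matrix(d$gamma, nrow = nd, ncol = k, byrow = TRUE),
    C = matrix(d$c, nrow = nd, ncol = k, byrow = TRUE),
    b = d$b[seq(1, nrow(d), by = k)],
    sigma = d$sigma[seq(1, nrow(d), by = k)],
    groups = glab, n_draws = nd, k = k
  )
}

#' Sweep distance scenarios across posterior draws
#'
#' For every (distance, draw) pair: rescales the garden to a uniform square
#' lattice at that distance, recomputes the crowding index, and evaluates the
#' full (with crowding) and base (without) growth predictions. Residual noise
#' is controlled by `noise_mode`:
#'
#' * `"independent"` — full and base each get their own `sigma * z` vector
#'   (the two models as written, each with its own residual draw);
#' * `"common"` — one shared `sigma * z` vector, so `mu_full - mu_base`
#'   equals the pure crowding term `gamma * phi`;
#' * `"none"` — deterministic means (`sigma^2 = 0`), used for the
#'   correlation-convergence analysis.
#'
#' Each run consumes a substream seeded deterministically from
#' `(seed, distance index, draw index)`, so output does not depend on
#' evaluation order.
#'
#' @param layout A `garden_layout`; dead plants are excluded from both the
#'   response and the neighbor sums.
#' @param draws A `posterior_draws` tibble (or a single [growth_params()]).
#' @param distances Planting distances in meters
#'   (default [default_distance_grid()]).
#' @param noise_mode One of `"independent"`, `"common"`, `"none"`.
#' @param seed Integer master seed.
#' @param sizes Optional initial sizes for live plants; defaults to the
#'   layout's `size` column (see [make_initial_sizes()]).
#' @param cutoff_radius Optional kernel truncation radius in meters
#'   (default `Inf`).
#' @return A `scenario_results` tibble with one row per
#'   (distance, draw, live plant): columns `distance`, `draw`, `plant_id`,
#'   `group`, `phi`, `mu_full`, `mu_base`.
#' @export
#' @examples
#' g <- make_initial_sizes(make_grid_layout(seed = 1), seed = 2)
#' d <- make_posterior_draws(n_draws = 3, seed = 3)
#' res <- run_sweep(g, d, distances = c(0.5, 4), noise_mode = "none", seed = 4)
#' dplyr::count(res, distance)
run_sweep <- function(layout, draws, distances = default_distance_grid(),
                      noise_mode = c("independent", "common", "none"),
                      seed = 1L, sizes = NULL, cutoff_radius = Inf) {
  noise_mode <- match.arg(noise_mode)
  validate_garden_layout(layout)
  draws <- as_posterior_draws(draws)
  if (n_draws(draws) < 1) {
    rlang::abort("`draws` must contain at least one parameter set.",
                 class = "gardensim_error_no_parameters")
  }
  if (length(distances) == 0 || any(distances <= 0)) {
    rlang::abort("`distances` must be a non-empty vector of positive meters.",
                 class = "gardensim_error_invalid_distance")
  }

  live <- layout[layout$alive, , drop = FALSE]
  n <- nrow(live)
  if (is.null(sizes)) {
    if (!"size" %in% names(layout)) {
      rlang::abort("no sizes: supply `sizes` or run make_initial_sizes() first.",
                   class = "gardensim_error_shape")
    }
    sizes <- live$size
  }
  if (length(sizes) != n || any(sizes <= 0)) {
    rlang::abort("`sizes` must be positive with one entry per live plant.",
                 class = "gardensim_error_shape")
  }

  pm <- draws_matrices(draws)
  g <- match(as.character(live$group), pm$groups)
  if (anyNA(g)) {
    rlang::abort("layout contains groups absent from the parameter draws.",
                 class = "gardensim_error_unknown_group")
  }

  nd <- length(distances)
  ndr <- pm$n_draws
  seeds <- substream_seeds(seed, nd, ndr)

  # unit-lattice squared distances; scenario d scales them by d^2
  ij <- lattice_indices(live)
  d2u <- as.matrix(stats::dist(ij))^2
  diag(d2u) <- Inf

  nrun <- nd * ndr
  phi_out <- numeric(n * nrun)
  mu_full <- numeric(n * nrun)
  mu_base <- numeric(n * nrun)
  off <- 0L

  for (di in seq_len(nd)) {
    d2 <- distances[di]^2 * d2u
    if (is.finite(cutoff_radius)) d2[d2 > cutoff_radius^2] <- Inf
    for (dr in seq_len(ndr)) {
      w <- pm$C[dr, g] * sizes
      phi <- as.vector(exp(pm$b[dr] * d2) %*% w)
      mb <- pm$A[dr, g] + pm$B[dr, g] * sizes
      mf <- mb + pm$G[dr, g] * phi
      if (noise_mode != "none") {
        set.seed(seeds[di, dr])
        if (noise_mode == "independent") {
          mf <- mf + pm$sigma[dr] * stats::rnorm(n)
          mb <- mb + pm$sigma[dr] * stats::rnorm(n)
        } else {
          z <- pm$sigma[dr] * stats::rnorm(n)
          mf <- mf + z
          mb <- mb + z
        }
      }
      idx <- off + seq_len(n)
      phi_out[idx] <- phi
      mu_full[idx] <- mf
      mu_base[idx] <- mb
      off <- off + n
    }
  }

  out <- tibble::tibble(
    distance = rep(distances, each = n * ndr),
    draw = rep(rep(seq_len(ndr), each = n), times = nd),
    plant_id = rep(live$plant_id, times = nrun),
    group = rep(live$group, times = nrun),
    phi = phi_out,
    mu_full = mu_full,
    mu_base = mu_base
  )
  tibble::new_tibble(out, noise_mode = noise_mode, n_live = n,
                     class = "scenario_results", nrow = nrow(out))
}

#' Write/read sweep results as long-format CSV
#'
#' Columns `distance, draw, plant_id, group, phi, mu_full, mu_base`.
#'
#' @param results A `scenario_results` tibble.
#' @param path File path.
#' @export
write_scenario_results <- function(results, path) {
  out <- tibble::as_tibble(results)
  out$group <- as.character(out$group)
  readr::write_csv(out, path)
  invisible(path)
}

#' @rdname write_scenario_results
#' @export
read_scenario_results <- function(path) {
  df <- strip_readr_attrs(readr::read_csv(path, show_col_types = FALSE))
  df$group <- factor(df$group, levels = csv_group_levels(df$group))
  n_live <- nrow(df[df$distance == df$distance[1] & df$draw == df$draw[1], ])
  tibble::new_tibble(df, noise_mode = NA_character_, n_live = n_live,
                     class = "scenario_results", nrow = nrow(df))
}
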