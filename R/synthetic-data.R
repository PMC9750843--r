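#' Default synthetic posterior specification
#'
#' The empirical posterior for the motivating sagebrush garden is not printed
#' in any public table, so the package ships a synthetic specification that
#' reproduces its documented structure:
#'
#' * intrinsic growth `alpha` ordered tridentata-2x (fastest) down to
#'   arbuscula (slowest);
#' * tetraploid groups more conservative (lower `alpha`) and more
#'   neighbor-tolerant (smaller `|gamma|`) than their diploid counterparts;
#' * `gamma` negative in the mean (crowding suppresses growth);
#' * mean kernel decay `b = -0.5` m^-2, so the kernel weight at 2.5 m is
#'   `exp(-0.5 * 2.5^2)` = 4.4% of its value at the plant — a near-negligible
#'   effect beyond 2.5 m;
#' * crowding at 0.5 m spacing of the same order as intrinsic group
#'   differences, the regime in which dense plantings distort group
#'   comparisons.
#'
#' All values are synthetic and configurable; see the package vignette for
#' the reasoning behind the magnitudes.
#'
#' @return A `group_spec` object: a list with a per-group tibble (`groups`)
#'   of means/SDs for `alpha`, `beta`, `gamma`, `c`, scalars `b_mean`,
#'   `b_sd`, `sigma_mean`, `sigma_sd`, and an optional `correlation` matrix
#'   among (alpha, beta, gamma) draws.
#' @export
#' @examples
#' default_group_spec()
default_group_spec <- function() {
  groups <- tibble::tibble(
    group = garden_groups(),
    alpha_mean = c(0.12, 0.09, 0.08, 0.06, 0.05, 0.03),
    alpha_sd = rep(0.010, 6),
    beta_mean = c(1.00, 0.90, 0.95, 0.85, 0.80, 0.90),
    beta_sd = rep(0.08, 6),
    gamma_mean = c(-0.20, -0.08, -0.15, -0.06, -0.05, -0.10),
    gamma_sd = rep(0.02, 6),
    c_mean = c(1.0, 0.8, 1.0, 0.8, 0.8, 0.9),
    c_sd = rep(0.10, 6)
  )
  group_spec(groups, b_mean = -0.5, b_sd = 0.05,
             sigma_mean = 0.05, sigma_sd = 0.005)
}

#' Construct a posterior specification
#'
#' @param groups Tibble with columns `group` and `<par>_mean` / `<par>_sd`
#'   for `alpha`, `beta`, `gamma`, `c`.
#' @param b_mean,b_sd Mean (< 0) and SD of the shared kernel decay.
#' @param sigma_mean,sigma_sd Mean (>= 0) and SD of the residual SD.
#' @param correlation Optional 3x3 correlation matrix applied to the
#'   (alpha, beta, gamma) draws within each group; `NULL` for independence.
#' @return A `group_spec` object.
#' @export
group_spec <- function(groups, b_mean, b_sd, sigma_mean, sigma_sd,
                       correlation = NULL) {
  groups <- tibble::as_tibble(groups)
  req <- c("group", paste0(rep(c("alpha", "beta", "gamma", "c"), each = 2),
                           c("_mean", "_sd")))
  if (!all(req %in% names(groups)) || nrow(groups) < 1 || nrow(groups) > 6) {
    rlang::abort("invalid group table in posterior spec.",
                 class = "gardensim_error_invalid_spec")
  }
  sds <- c(groups$alpha_sd, groups$beta_sd, groups$gamma_sd, groups$c_sd,
           b_sd, sigma_sd)
  if (any(sds < 0) || any(groups$c_mean < 0) || b_mean >= 0 || sigma_mean < 0) {
    rlang::abort("posterior spec violates sign constraints (SDs >= 0, c >= 0, b < 0, sigma >= 0).",
                 class = "gardensim_error_invalid_spec")
  }
  if (!is.null(correlation)) {
    if (!is.matrix(correlation) || any(dim(correlation) != 3) ||
        !isSymmetric(correlation) || any(abs(diag(correlation) - 1) > 1e-12)) {
      rlang::abort("`correlation` must be a symmetric 3x3 correlation matrix.",
                   class = "gardensim_error_invalid_spec")
    }
  }
  structure(list(groups = groups, b_mean = b_mean, b_sd = b_sd,
                 sigma_mean = sigma_mean, sigma_sd = sigma_sd,
                 correlation = correlation),
            class = "group_spec")
}

#' @export
print.group_spec <- function(x, ...) {
  cat(sprintf("<group_spec: %d groups, b ~ %.3g (sd %.3g), sigma ~ %.3g (sd %.3g)>\n",
              nrow(x$groups), x$b_mean, x$b_sd, x$sigma_mean, x$sigma_sd))
  print(x$groups)
  invisible(x)
}

#' Read/write a posterior specification as JSON
#'
#' @param spec A `group_spec` object.
#' @param path File path.
#' @export
write_group_spec <- function(spec, path) {
  stopifnot(inherits(spec, "group_spec"))
  jsonlite::write_json(
    list(groups = spec$groups, b_mean = spec$b_mean, b_sd = spec$b_sd,
         sigma_mean = spec$sigma_mean, sigma_sd = spec$sigma_sd,
         correlation = spec$correlation),
    path, digits = NA, auto_unbox = TRUE
  )
  invisible(path)
}

#' @rdname write_group_spec
#' @export
read_group_spec <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  corr <- x$correlation
  corr <- if (length(corr) == 0) NULL else as.matrix(corr)
  group_spec(x$groups, b_mean = x$b_mean, b_sd = x$b_sd,
             sigma_mean = x$sigma_mean, sigma_sd = x$sigma_sd,
             correlation = corr)
}

# lognormal draws moment-matched to a given mean and SD
rlnorm_meansd <- function(n, mean, sd) {
  if (mean == 0) return(rep(0, n))
  if (sd == 0) return(rep(mean, n))
  sdlog <- sqrt(log1p((sd / mean)^2))
  stats::rlnorm(n, meanlog = log(mean) - sdlog^2 / 2, sdlog = sdlog)
}

#' Draw synthetic posterior parameter samples
#'
#' Generates `n_draws` parameter sets from the specification: normal draws
#' for `alpha`, `beta`, `gamma` (optionally correlated within group),
#' lognormal draws (moment-matched to the stated mean/SD) for `c`, `-b`, and
#' `sigma` to preserve their signs.
#'
#' @param spec A [group_spec()]; default [default_group_spec()].
#' @param n_draws Number of posterior samples (default 2000).
#' @param seed Integer seed.
#' @return A `posterior_draws` tibble with columns `draw`, `group`, `alpha`,
#'   `beta`, `gamma`, `c`, `b`, `sigma` (the scalars repeated within draw),
#'   rows ordered by draw then group.
#' @export
#' @examples
#' d <- make_posterior_draws(n_draws = 10, seed = 1)
#' dplyr::count(d, group)
make_posterior_draws <- function(spec = default_group_spec(), n_draws = 2000L,
                                 seed = 1L) {
  if (!inherits(spec, "group_spec")) {
    rlang::abort("`spec` must be a group_spec object.",
                 class = "gardensim_error_invalid_spec")
  }
  if (n_draws < 1) {
    rlang::abort("`n_draws` must be >= 1.",
                 class = "gardensim_error_invalid_spec")
  }
  n_draws <- as.integer(n_draws)
  g <- spec$groups
  k <- nrow(g)
  set.seed(seed)

  L <- if (is.null(spec$correlation)) NULL else chol(spec$correlation)
  per_group <- lapply(seq_len(k), function(i) {
    z <- matrix(stats::rnorm(3 * n_draws), ncol = 3)
    if (!is.null(L)) z <- z %*% L
    tibble::tibble(
      draw = seq_len(n_draws),
      group = g$group[i],
      alpha = g$alpha_mean[i] + g$alpha_sd[i] * z[, 1],
      beta = g$beta_mean[i] + g$beta_sd[i] * z[, 2],
      gamma = g$gamma_mean[i] + g$gamma_sd[i] * z[, 3],
      c = rlnorm_meansd(n_draws, g$c_mean[i], g$c_sd[i])
    )
  })
  b <- -rlnorm_meansd(n_draws, -spec$b_mean, spec$b_sd)
  sigma <- rlnorm_meansd(n_draws, spec$sigma_mean, spec$sigma_sd)

  out <- dplyr::arrange(dplyr::bind_rows(per_group), .data$draw)
  out$group <- factor(out$group, levels = g$group)
  out$b <- rep(b, each = k)
  out$sigma <- rep(sigma, each = k)
  tibble::new_tibble(out, n_draws = n_draws, group_levels = as.character(g$group),
                     class = "posterior_draws", nrow = nrow(out))
}

#' Number of draws / group levels of a posterior sample
#' @param draws A `posterior_draws` tibble.
#' @return `n_draws()`: integer count; `draw_groups()`: character labels.
#' @export
n_draws <- function(draws) {
  attr(draws, "n_draws") %||% dplyr::n_distinct(draws$draw)
}

#' @rdname n_draws
#' @export
draw_groups <- function(draws) {
  attr(draws, "group_levels") %||% as.character(unique(draws$group))
}

#' Extract one draw as a parameter set
#'
#' @param draws A `posterior_draws` tibble.
#' @param i Draw index.
#' @return A [growth_params()] object.
#' @export
param_set <- function(draws, i) {
  d <- draws[draws$draw == i, , drop = FALSE]
  if (nrow(d) == 0) {
    rlang::abort(sprintf("draw %s not found.", i),
                 class = "gardensim_error_invalid_spec")
  }
  d <- d[match(draw_groups(draws), as.character(d$group)), , drop = FALSE]
  growth_params(alpha = d$alpha, beta = d$beta, gamma = d$gamma, c = d$c,
                b = d$b[1], sigma = d$sigma[1],
                groups = as.character(d$group))
}

#' Wrap parameter sets as posterior draws
#'
#' @param params A `growth_params` or list of them (all over the same groups).
#' @return A `posterior_draws` tibble.
#' @export
as_posterior_draws <- function(params) {
  if (inherits(params, "posterior_draws")) return(params)
  if (inherits(params, "growth_params")) params <- list(params)
  if (length(params) == 0) {
    rlang::abort("no parameter sets supplied.",
                 class = "gardensim_error_no_parameters")
  }
  rows <- lapply(seq_along(params), function(i) {
    p <- params[[i]]
    tibble::tibble(draw = i, group = p$groups, alpha = unname(p$alpha),
                   beta = unname(p$beta), gamma = unname(p$gamma),
                   c = unname(p$c), b = p$b, sigma = p$sigma)
  })
  out <- dplyr::bind_rows(rows)
  out$group <- factor(out$group, levels = params[[1]]$groups)
  tibble::new_tibble(out, n_draws = length(params),
                     group_levels = params[[1]]$groups,
                     class = "posterior_draws", nrow = nrow(out))
}

#' Attach initial crown-volume sizes to a layout
#'
#' Draws strictly positive initial sizes (m^3) from a per-group lognormal:
#' `median` is the group's median crown volume and `gsd` its geometric SD.
#' Sizes stand in for a pre-census size survey; every position gets a size,
#' but only live plants enter the growth model.
#'
#' @param layout A `garden_layout`.
#' @param size_spec Either `NULL` (defaults: median 0.05 m^3, geometric SD
#'   1.6 for every group) or a data frame with columns `group`, `median`,
#'   `gsd`.
#' @param seed Integer seed.
#' @return The layout with a `size` column appended.
#' @export
#' @examples
#' g <- make_initial_sizes(make_grid_layout(seed = 1), seed = 2)
#' range(g$size)
make_initial_sizes <- function(layout, size_spec = NULL, seed = 1L) {
  validate_garden_layout(layout)
  if (is.null(size_spec)) {
    size_spec <- tibble::tibble(group = unique(as.character(layout$group)),
                                median = 0.05, gsd = 1.6)
  }
  size_spec <- tibble::as_tibble(size_spec)
  if (any(size_spec$median <= 0) || any(size_spec$gsd < 1)) {
    rlang::abort("size distribution needs `median` > 0 and `gsd` >= 1.",
                 class = "gardensim_error_invalid_spec")
  }
  i <- match(as.character(layout$group), size_spec$group)
  if (anyNA(i)) {
    rlang::abort("`size_spec` must cover every group in the layout.",
                 class = "gardensim_error_invalid_spec")
  }
  set.seed(seed)
  n <- nrow(layout)
  out <- layout
  out$size <- size_spec$median[i] *
    exp(log(size_spec$gsd[i]) * stats::rnorm(n))
  sp <- layout_spacing(layout)
  new_garden_layout(out, dx = sp[["dx"]], dy = sp[["dy"]])
}
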