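#' Neighborhood crowding index
#'
#' For each plant i, the crowding index is the sum over live neighbors j of
#' `c[group_j] * size_j * exp(b * D_ij^2)`: cumulative neighbor crown volume
#' weighted by a Gaussian-shaped distance-decay kernel. The kernel scale `c`
#' is indexed by the neighbor's group (a neighbor's competitive effect scales
#' its own size); set `c_by = "target"` to index by the focal plant instead.
#'
#' @param sizes Positive crown volumes (m^3), one per live plant.
#' @param groups Group labels, one per live plant.
#' @param dist Symmetric distance matrix (m) with zero diagonal, as from
#'   [pairwise_distances()].
#' @param params A [growth_params()] set supplying `c` and `b`.
#' @param cutoff_radius Optional truncation radius (m); neighbor pairs beyond
#'   it contribute exactly zero. Default `Inf` (no truncation).
#' @param c_by Whether `c` is indexed by the `"neighbor"` (default) or the
#'   `"target"` group.
#' @return Numeric vector of crowding indices (>= 0), one per plant.
#' @export
#' @examples
#' p <- growth_params(alpha = 0, beta = 0, gamma = 0, c = 1, b = -1,
#'                    sigma = 0, groups = "g")
#' crowding_index(c(1, 1), c("g", "g"), rbind(c(0, 1), c(1, 0)), p)
crowding_index <- function(sizes, groups, dist, params,
                           cutoff_radius = Inf,
                           c_by = c("neighbor", "target")) {
  c_by <- match.arg(c_by)
  n <- length(sizes)
  if (length(groups) != n || !is.matrix(dist) ||
      nrow(dist) != n || ncol(dist) != n) {
    rlang::abort("`sizes`, `groups` and `dist` must agree in dimension.",
                 class = "gardensim_error_shape")
  }
  if (any(sizes <= 0)) {
    rlang::abort("`sizes` must be strictly positive.",
                 class = "gardensim_error_shape")
  }
  g <- group_index(groups, params)
  d2 <- dist^2
  diag(d2) <- Inf # excludes self: exp(b * Inf) = 0 for b < 0
  if (is.finite(cutoff_radius)) d2[dist > cutoff_radius] <- Inf
  w <- exp(params$b * d2)
  if (c_by == "neighbor") {
    as.vector(w %*% (params$c[g] * sizes))
  } else {
    params$c[g] * as.vector(w %*% sizes)
  }
}

#' Predicted growth with and without neighborhood effects
#'
#' The *full* model predicts growth of plant i in group s as
#' `alpha_s + beta_s * size_i + gamma_s * phi_i + noise_i`; the *base* model
#' drops the crowding term. `noise` is a pre-drawn residual vector (typically
#' `sigma * z`), or 0 for the deterministic mean.
#'
#' @param state A data frame with columns `size`, `group`, and (for the full
#'   model) `phi`, one row per live plant.
#' @param params A [growth_params()] set.
#' @param noise Residual vector (recycled scalar 0 allowed).
#' @return Numeric vector of predicted growth, one per plant.
#' @export
#' @examples
#' p <- growth_params(alpha = 1, beta = 0.5, gamma = -0.4, c = 1, b = -1,
#'                    sigma = 0, groups = "g")
#' st <- tibble::tibble(size = 2, group = "g", phi = 0.5)
#' predict_growth_full(st, p) # 1 + 1 - 0.2 = 1.8
#' predict_growth_base(st, p) # 2
predict_growth_full <- function(state, params, noise = 0) {
  g <- group_index(state$group, params)
  check_noise(noise, nrow(state))
  unname(params$alpha[g] + params$beta[g] * state$size +
           params$gamma[g] * state$phi + noise)
}

#' @rdname predict_growth_full
#' @export
predict_growth_base <- function(state, params, noise = 0) {
  g <- group_index(state$group, params)
  check_noise(noise, nrow(state))
  unname(params$alpha[g] + params$beta[g] * state$size + noise)
}

check_noise <- function(noise, n) {
  if (!(length(noise) %in% c(1L, n))) {
    rlang::abort("`noise` must have one entry per plant (or be scalar).",
                 class = "gardensim_error_shape")
  }
  invisible(noise)
}
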