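# shared fixtures: small gardens, toy parameter sets, and independent oracles

`%||%` <- rlang::`%||%`

tiny_layout <- function(n = 12L, n_cols = 4L, dx = 1, dy = 1, n_dead = 2L,
                        seed = 1L) {
  make_grid_layout(n_positions = n, n_cols = n_cols, dx = dx, dy = dy,
                   n_dead = n_dead, seed = seed)
}

toy_params <- function(groups = c("a", "b"), gamma = NULL, alpha = NULL,
                       beta = NULL, c = NULL, b = -0.5, sigma = 0.1) {
  k <- length(groups)
  growth_params(alpha = alpha %||% seq_len(k), beta = beta %||% rep(0.5, k),
                gamma = gamma %||% (-0.2 / seq_len(k)), c = c %||% rep(1, k),
                b = b, sigma = sigma, groups = groups)
}

# arbitrary (non-lattice) positions wrapped as a layout-shaped tibble
manual_layout <- function(x, y, group = rep("a", length(x)),
                          alive = rep(TRUE, length(x))) {
  tibble::tibble(plant_id = seq_along(x), x = x, y = y, alive = alive,
                 population = seq_along(x), group = factor(group))
}

# scalar double-loop evaluation of the crowding index
phi_oracle <- function(sizes, groups, dist, params) {
  g <- match(as.character(groups), params$groups)
  n <- length(sizes)
  phi <- numeric(n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (j != i) {
        phi[i] <- phi[i] +
          params$c[g[j]] * sizes[j] * exp(params$b * dist[i, j]^2)
      }
    }
  }
  phi
}

# textbook one-way ANOVA oracle via the fitted linear model
f_oracle <- function(y, g) {
  stats::anova(stats::lm(y ~ factor(g)))$`F value`[1]
}

# hand-assembled scenario_results table for analysis-stage unit tests
manual_results <- function(distance, mu_full, mu_base, groups,
                           noise_mode = "independent") {
  n_draw <- length(mu_full)
  n <- length(mu_full[[1]])
  out <- tibble::tibble(
    distance = rep(distance, n_draw * n),
    draw = rep(seq_len(n_draw), each = n),
    plant_id = rep(seq_len(n), n_draw),
    group = factor(rep(groups, n_draw)),
    phi = 0,
    mu_full = unlist(mu_full),
    mu_base = unlist(mu_base)
  )
  tibble::new_tibble(out, noise_mode = noise_mode, n_live = n,
                     class = "scenario_results", nrow = nrow(out))
}

default_mean_params <- function(sigma = 0) {
  spec <- default_group_spec()
  growth_params(alpha = spec$groups$alpha_mean, beta = spec$groups$beta_mean,
                gamma = spec$groups$gamma_mean, c = spec$groups$c_mean,
                b = spec$b_mean, sigma = sigma, groups = spec$groups$group)
}
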