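test_that("one-way F reproduces hand calculations and conventions", {
  r <- one_way_f(c(1, 2, 3, 4), c("A", "A", "B", "B"))
  expect_equal(r$f_value, 8)
  expect_equal(r$df1, 1L)
  expect_equal(r$df2, 2L)
  # constant response: no between-group variance -> F = 0
  expect_equal(one_way_f(rep(2, 6), rep(c("A", "B"), 3))$f_value, 0)
  # zero within-group variance with real separation -> +Inf sentinel
  expect_equal(one_way_f(c(1, 1, 5, 5), c("A", "A", "B", "B"))$f_value, Inf)
  # the default garden gives the census ANOVA dimensions
  g <- make_grid_layout(seed = 1)
  live <- g[g$alive, ]
  set.seed(2)
  r448 <- one_way_f(stats::rnorm(448), live$group)
  expect_equal(c(r448$df1, r448$df2), c(5L, 442L))
})

test_that("one-way F agrees with the fitted-linear-model oracle", {
  set.seed(31)
  for (i in 1:40) {
    k <- sample(2:5, 1)
    n <- sample((k + 2):40, 1)
    gl <- c(letters[seq_len(k)], sample(letters[seq_len(k)], n - k, TRUE))
    y <- stats::rnorm(n, mean = as.integer(factor(gl)) * stats::runif(1, 0, 2))
    expect_equal(one_way_f(y, gl)$f_value, f_oracle(y, gl),
                 tolerance = 1e-10)
  }
})

test_that("one-way F is invariant to shift and positive scaling", {
  set.seed(17)
  y <- stats::rnorm(30)
  gl <- rep(c("A", "B", "C"), 10)
  f0 <- one_way_f(y, gl)$f_value
  expect_equal(one_way_f(y + 7.3, gl)$f_value, f0, tolerance = 1e-10)
  expect_equal(one_way_f(2.9 * y, gl)$f_value, f0, tolerance = 1e-10)
  expect_equal(one_way_f(2.9 * y - 1.1, gl)$f_value, f0, tolerance = 1e-10)
})

test_that("degenerate ANOVA designs are rejected", {
  expect_error(one_way_f(1:4, rep("A", 4)),
               class = "gardensim_error_degenerate_design")
  expect_error(one_way_f(1:2, c("A", "B")),
               class = "gardensim_error_degenerate_design")
  expect_error(one_way_f(1:4, c("A", "B")), class = "gardensim_error_shape")
})

test_that("relativized F matches an explicit two-ANOVA oracle", {
  set.seed(5)
  gl <- rep(c("A", "A", "B", "B", "C", "C"), 2)
  mu_base <- lapply(1:3, function(i) stats::rnorm(12, as.integer(factor(gl))))
  mu_full <- lapply(1:3, function(i) mu_base[[i]] + stats::rnorm(12, 0, 0.5))
  res <- manual_results(0.5, mu_full, mu_base, gl)
  got <- relative_f(res)
  f_base_mean <- mean(vapply(mu_base, f_oracle, numeric(1), g = gl))
  want <- vapply(seq_len(3),
                 function(i) f_oracle(mu_full[[i]] - mu_base[[i]], gl),
                 numeric(1)) / f_base_mean
  expect_equal(got$rel_f, want, tolerance = 1e-10)
})

test_that("relativized F is identically zero when full equals base", {
  gl <- rep(c("A", "B"), 4)
  mu_base <- lapply(1:4, function(i) stats::rnorm(8, as.integer(factor(gl))))
  res <- manual_results(1, mu_base, mu_base, gl, noise_mode = "common")
  expect_equal(relative_f(res)$rel_f, rep(0, 4))
})

test_that("relativization is undefined when the base model separates nothing", {
  gl <- rep(c("A", "B"), 4)
  flat <- lapply(1:2, function(i) rep(1, 8))
  res <- manual_results(1, lapply(1:2, function(i) stats::rnorm(8)), flat, gl)
  expect_error(relative_f(res),
               class = "gardensim_error_undefined_relativization")
})

test_that("correlation samples match the textbook Pearson formula", {
  gl <- c("A", "B", "A")
  res <- manual_results(2, list(c(1.1, 1.9, 3.0)), list(c(1, 2, 3)), gl,
                        noise_mode = "none")
  curve <- correlation_curve(res)
  x <- c(1.1, 1.9, 3.0); y <- c(1, 2, 3)
  r_hand <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(curve$r_mean, r_hand)
  expect_equal(curve$samples[[1]], r_hand)
})

test_that("identical constant vectors give r = 1; mismatched ones error", {
  gl <- c("A", "B", "A")
  same <- manual_results(1, list(rep(2, 3)), list(rep(2, 3)), gl, "none")
  expect_equal(correlation_curve(same)$r_mean, 1)
  diffc <- manual_results(1, list(rep(2, 3)), list(c(1, 2, 3)), gl, "none")
  expect_error(correlation_curve(diffc),
               class = "gardensim_error_undefined_correlation")
})

test_that("gamma = 0 gives perfect full/base correlation at every distance", {
  g <- make_initial_sizes(tiny_layout(n = 30, n_cols = 6, n_dead = 2), seed = 1)
  p0 <- toy_params(groups = garden_groups(),
                   alpha = c(6, 5, 4, 3, 2, 1) / 10,
                   beta = rep(1, 6), gamma = rep(0, 6), c = rep(1, 6),
                   b = -0.5, sigma = 0.05)
  res <- run_sweep(g, p0, distances = c(0.5, 2, 4), noise_mode = "none",
                   seed = 3)
  expect_equal(correlation_curve(res)$r_mean, rep(1, 3))
})

test_that("percentile bands are central, interpolated, and nested", {
  expect_equal(percentile_band(rep(3.5, 10), 0.68), c(3.5, 3.5))
  set.seed(8)
  z <- stats::rnorm(1e5)
  expect_equal(percentile_band(z, 0.95), c(-1.96, 1.96), tolerance = 0.03)
  for (seed in 1:5) {
    set.seed(seed)
    s <- stats::rlnorm(200)
    b68 <- percentile_band(s, 0.68)
    b95 <- percentile_band(s, 0.95)
    expect_gte(b68[1], b95[1])
    expect_lte(b68[2], b95[2])
  }
  expect_error(percentile_band(numeric(0), 0.5),
               class = "gardensim_error_no_data")
  expect_error(percentile_band(1:3, 1.2), class = "gardensim_error_no_data")
})

test_that("minimum-distance recommendation follows the band lower bound", {
  curve <- tibble::tibble(
    distance = c(0.5, 1, 2),
    samples = list(rep(1, 10), rep(1, 10), rep(1, 10))
  )
  expect_equal(recommend_min_distance(curve), 0.5)
  low <- tibble::tibble(distance = c(0.5, 1),
                        samples = list(stats::runif(20, 0, 0.5),
                                       stats::runif(20, 0, 0.5)))
  expect_identical(recommend_min_distance(low), NA_real_)
  mixed <- tibble::tibble(distance = c(0.5, 1, 2),
                          samples = list(rep(0.5, 10), rep(0.995, 10),
                                         rep(0.999, 10)))
  expect_equal(recommend_min_distance(mixed), 1)
  # a stricter band can withdraw the recommendation
  spread <- tibble::tibble(distance = 1,
                           samples = list(c(rep(0.999, 80), rep(0.5, 20))))
  expect_equal(recommend_min_distance(spread, band_level = 0.5), 1)
  expect_identical(recommend_min_distance(spread, band_level = 0.95), NA_real_)
})

test_that("group summaries tie when groups are exchangeable and rank otherwise", {
  gl <- rep(c("A", "B"), 6)
  same <- manual_results(1, list(rep(2, 12)), list(rep(2, 12)), gl)
  gs <- group_summary(same)
  expect_equal(gs$mean_growth, rep(2, 2))
  expect_equal(gs$rank, rep(1L, 2))
  ranked <- manual_results(1, list(c(rep(3, 6), rep(1, 6))),
                           list(rep(0, 12)), rep(c("A", "B"), each = 6))
  gr <- group_summary(ranked)
  expect_equal(gr$rank[gr$group == "A"], 1L)
  expect_equal(gr$rank[gr$group == "B"], 2L)
})

test_that("crowding can reorder group performance between densities", {
  # gamma ordering opposes alpha ordering: the faster-growing group is the
  # more competition-sensitive one, so dense planting flips the ranking
  p <- toy_params(groups = c("fast_sensitive", "slow_tolerant"),
                  alpha = c(0.12, 0.09), beta = c(1, 1),
                  gamma = c(-0.25, -0.02), c = c(1, 1), b = -0.5,
                  sigma = 0.01)
  g <- make_initial_sizes(
    make_grid_layout(n_positions = 100, n_cols = 10, n_dead = 5,
                     group_spec = tibble::tibble(population = 1:2,
                                                 group = c("fast_sensitive",
                                                           "slow_tolerant")),
                     seed = 2), seed = 3)
  res <- run_sweep(g, as_posterior_draws(rep(list(p), 5)),
                   distances = c(0.5, 4), seed = 4)
  lo <- group_summary(res[res$distance == 0.5, ])
  hi <- group_summary(res[res$distance == 4, ])
  expect_equal(hi$rank[hi$group == "fast_sensitive"], 1L)
  expect_equal(lo$rank[lo$group == "fast_sensitive"], 2L)
})

test_that("bias_summary assembles nested bands and a recommendation", {
  g <- make_initial_sizes(make_grid_layout(n_positions = 80, n_cols = 10,
                                           n_dead = 6, seed = 1), seed = 2)
  draws <- make_posterior_draws(n_draws = 30, seed = 3)
  rn <- run_sweep(g, draws, distances = c(0.5, 1.5, 3, 4), seed = 4)
  rd <- run_sweep(g, draws, distances = c(0.5, 1.5, 3, 4),
                  noise_mode = "none", seed = 4)
  bs <- bias_summary(rn, rd)
  expect_s3_class(bs, "bias_summary")
  expect_equal(nrow(bs$rel_f), 4)
  expect_true(all(bs$rel_f$rel_f_lo_68 >= bs$rel_f$rel_f_lo_95))
  expect_true(all(bs$rel_f$rel_f_hi_68 <= bs$rel_f$rel_f_hi_95))
  expect_true(all(vapply(bs$correlation$samples,
                         function(s) all(s >= -1 & s <= 1), logical(1))))
  td <- tidy(bs)
  expect_equal(nrow(td), 4)
  expect_true(all(c("rel_f_mean", "r_mean") %in% names(td)))
  gl <- glance(bs)
  expect_equal(gl$n_draws, 30)
})
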