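test_that("crowding index matches closed forms on minimal neighborhoods", {
  p1 <- toy_params(groups = "g", gamma = 0, alpha = 0, beta = 0, c = 1, b = -1)
  # a lone plant has an empty neighbor sum
  expect_equal(crowding_index(2, "g", matrix(0, 1, 1), p1), 0)
  # two unit-size plants 1 m apart with c = 1, b = -1: phi = e^-1
  dm <- rbind(c(0, 1), c(1, 0))
  expect_equal(crowding_index(c(1, 1), c("g", "g"), dm, p1),
               rep(exp(-1), 2))
})

test_that("vectorized crowding index equals the scalar double-loop oracle", {
  params <- toy_params(groups = c("a", "b", "c"), gamma = c(-1, -1, -1),
                       alpha = c(0, 0, 0), beta = c(0, 0, 0),
                       c = c(1.2, 0.7, 1.0), b = -0.8)
  for (seed in 1:10) {
    set.seed(seed)
    n <- sample(3:20, 1)
    lay <- manual_layout(stats::runif(n, 0, 5), stats::runif(n, 0, 5),
                         group = sample(c("a", "b", "c"), n, replace = TRUE))
    sizes <- stats::rlnorm(n, log(0.05), 0.5)
    dm <- as.matrix(stats::dist(cbind(lay$x, lay$y)))
    phi <- crowding_index(sizes, lay$group, dm, params)
    expect_equal(phi, phi_oracle(sizes, lay$group, dm, params),
                 tolerance = 1e-10)
  }
})

test_that("crowding index is homogeneous in sizes and decays with distance", {
  params <- toy_params(groups = c("a", "b"), c = c(1, 0.5), b = -0.6)
  set.seed(42)
  lay <- manual_layout(stats::runif(8), stats::runif(8),
                       group = rep(c("a", "b"), 4))
  sizes <- stats::rlnorm(8, log(0.05), 0.4)
  dm <- as.matrix(stats::dist(cbind(lay$x, lay$y)))
  # homogeneity of degree 1 in neighbor sizes
  expect_equal(crowding_index(2 * sizes, lay$group, dm, params),
               2 * crowding_index(sizes, lay$group, dm, params))
  # strictly decreasing in any single pairwise distance (b < 0)
  dm2 <- dm
  dm2[1, 2] <- dm2[2, 1] <- dm[1, 2] + 0.1
  phi <- crowding_index(sizes, lay$group, dm, params)
  phi2 <- crowding_index(sizes, lay$group, dm2, params)
  expect_lt(phi2[1], phi[1])
  expect_lt(phi2[2], phi[2])
  expect_equal(phi2[-(1:2)], phi[-(1:2)])
})

test_that("truncation radius zeroes far neighbors only", {
  params <- toy_params(groups = "g", c = 1, b = -0.1)
  lay <- manual_layout(c(0, 1, 10), c(0, 0, 0), group = rep("g", 3))
  dm <- as.matrix(stats::dist(cbind(lay$x, lay$y)))
  sizes <- c(1, 1, 1)
  phi <- crowding_index(sizes, lay$group, dm, params, cutoff_radius = 4)
  expect_equal(phi[1], exp(-0.1)) # the 10 m neighbor is cut off
  expect_equal(phi[3], 0)
})

test_that("full and base predictions follow the model arithmetic", {
  p <- growth_params(alpha = 1, beta = 0.5, gamma = -0.4, c = 1, b = -1,
                     sigma = 0, groups = "g")
  st <- tibble::tibble(size = 2, group = "g", phi = 0.5)
  expect_equal(predict_growth_full(st, p), 1.8)
  expect_equal(predict_growth_base(st, p), 2.0)
  # intercept-only limit
  st0 <- tibble::tibble(size = 1e-12, group = "g", phi = 0)
  expect_equal(predict_growth_base(st0, p), 1, tolerance = 1e-9)
  # gamma = 0 collapses full onto base
  p0 <- growth_params(alpha = 1, beta = 0.5, gamma = 0, c = 1, b = -1,
                      sigma = 0, groups = "g")
  expect_equal(predict_growth_full(st, p0), predict_growth_base(st, p0))
})

test_that("full minus base equals gamma * phi under identical noise", {
  params <- toy_params(gamma = c(-0.3, -0.1))
  set.seed(1)
  st <- tibble::tibble(size = stats::rlnorm(10, log(0.05), 0.4),
                       group = rep(c("a", "b"), 5),
                       phi = stats::runif(10))
  noise <- stats::rnorm(10, 0, 0.1)
  g <- match(st$group, params$groups)
  expect_equal(predict_growth_full(st, params, noise) -
                 predict_growth_base(st, params, noise),
               unname(params$gamma[g] * st$phi))
})

test_that("stochastic predictions are centered on the deterministic mean", {
  p <- growth_params(alpha = 1, beta = 0.5, gamma = -0.4, c = 1, b = -1,
                     sigma = 0.3, groups = "g")
  st <- tibble::tibble(size = 2, group = "g", phi = 0.5)
  set.seed(99)
  reps <- vapply(seq_len(10000),
                 function(i) predict_growth_full(st, p, p$sigma * stats::rnorm(1)),
                 numeric(1))
  se <- 0.3 / sqrt(10000)
  expect_lt(abs(mean(reps) - 1.8), 3 * se)
})

test_that("model inputs are validated", {
  p <- toy_params()
  expect_error(crowding_index(c(1, 2), c("a", "b", "b"), matrix(0, 2, 2), p),
               class = "gardensim_error_shape")
  expect_error(crowding_index(c(-1, 2), c("a", "b"),
                              rbind(c(0, 1), c(1, 0)), p),
               class = "gardensim_error_shape")
  st <- tibble::tibble(size = 1, group = "zebra", phi = 0)
  expect_error(predict_growth_full(st, p),
               class = "gardensim_error_unknown_group")
  expect_error(growth_params(alpha = 1, beta = 1, gamma = 0, c = 1,
                             b = 0.5, sigma = 0, groups = "g"),
               class = "gardensim_error_invalid_params")
  expect_error(growth_params(alpha = 1, beta = 1, gamma = 0, c = -1,
                             b = -0.5, sigma = 0, groups = "g"),
               class = "gardensim_error_invalid_params")
})

test_that("growth parameters round-trip through JSON", {
  p <- toy_params(groups = c("a", "b"), gamma = c(-0.25, -0.05),
                  b = -0.47, sigma = 0.04)
  path <- withr::local_tempfile(fileext = ".json")
  write_growth_params(p, path)
  p2 <- read_growth_params(path)
  expect_equal(p2, p)
})
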