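#' Least-squares recovery of growth parameters
#'
#' Validation fitter for the forward model: minimizes the residual sum of
#' squares of observed growth against the full-model prediction over
#' `(alpha, beta, gamma, c, b)`. Used to close the simulate-fit-recover loop,
#' not as a replacement for the hierarchical Bayesian estimation the
#' empirical parameters came from.
#'
#' The kernel is only identified up to a multiplicative trade-off between
#' `c` and `gamma` (scaling all `c` by t and all `gamma` by 1/t leaves
#' predictions unchanged), so `c` of `reference_group` is fixed at its value
#' in `init`. Remaining `c` entries and `-b` are optimized on the log scale;
#' for any candidate kernel, `(alpha, beta, gamma)` are profiled out by
#' per-group linear least squares.
#'
#' @param growth Observed growth, one value per live plant.
#' @param sizes Initial sizes (m^3), one per live plant.
#' @param groups Group labels, one per live plant.
#' @param dist Distance matrix among the same plants.
#' @param init A [growth_params()] starting point (also fixes the reference
#'   kernel scale).
#' @param reference_group Group whose `c` is held fixed (default: first
#'   group of `init`).
#' @param control Passed to [stats::optim()] (BFGS); sensible defaults.
#' @return A `growth_fit` list: `params` (estimates as [growth_params()]),
#'   `rss`, `fitted`, `converged`, `kernel_identifiable`, `n`.
#' @export
fit_growth_params <- function(growth, sizes, groups, dist, init,
                              reference_group = NULL, control = list()) {
  stopifnot(inherits(init, "growth_params"))
  n <- length(growth)
  if (length(sizes) != n || length(groups) != n ||
      !is.matrix(dist) || nrow(dist) != n || ncol(dist) != n) {
    rlang::abort("`growth`, `sizes`, `groups`, `dist` must agree in dimension.",
                 class = "gardensim_error_shape")
  }
  glab <- init$groups
  g <- group_index(groups, init)
  if (!all(seq_along(glab) %in% g)) {
    glab <- glab[sort(unique(g))]
    init <- growth_params(init$alpha[glab], init$beta[glab], init$gamma[glab],
                          init$c[glab], init$b, init$sigma, groups = glab)
    g <- group_index(groups, init)
  }
  k <- length(glab)
  gf <- factor(glab[g], levels = glab)

  d2 <- dist^2
  diag(d2) <- Inf
  phi_of <- function(cvec, b) as.vector(exp(b * d2) %*% (cvec[g] * sizes))

  # design for the profiled linear stage: per-group intercept, size, phi
  Gm <- stats::model.matrix(~ 0 + gf)
  linfit <- function(phi) {
    X <- cbind(Gm, Gm * sizes, Gm * phi)
    stats::lm.fit(X, growth)
  }

  # identifiability probe: if no plant feels any neighbor at the init kernel,
  # gamma/c/b cannot be estimated
  if (max(phi_of(init$c, init$b)) < 1e-10) {
    fit0 <- stats::lm.fit(cbind(Gm, Gm * sizes), growth)
    cf <- fit0$coefficients
    est <- growth_params(alpha = cf[seq_len(k)], beta = cf[k + seq_len(k)],
                         gamma = rep(0, k), c = init$c, b = init$b,
                         sigma = sqrt(sum(fit0$residuals^2) / max(n - 2 * k, 1)),
                         groups = glab)
    return(structure(list(params = est, rss = sum(fit0$residuals^2),
                          fitted = fit0$fitted.values, converged = TRUE,
                          kernel_identifiable = FALSE, n = n),
                     class = "growth_fit"))
  }

  ref <- reference_group %||% glab[1]
  ref_i <- match(ref, glab)
  if (is.na(ref_i)) {
    rlang::abort("`reference_group` is not a group of `init`.",
                 class = "gardensim_error_unknown_group")
  }
  free_i <- setdiff(seq_len(k), ref_i)
  c_ref <- init$c[ref_i]
  if (c_ref <= 0) c_ref <- 1

  unpack <- function(theta) {
    cvec <- numeric(k)
    cvec[ref_i] <- c_ref
    cvec[free_i] <- exp(theta[seq_along(free_i)])
    list(c = cvec, b = -exp(theta[length(theta)]))
  }
  objective <- function(theta) {
    p <- unpack(theta)
    sum(linfit(phi_of(p$c, p$b))$residuals^2)
  }

  theta0 <- c(log(pmax(init$c[free_i], 1e-6)), log(-init$b))
  ctrl <- utils::modifyList(list(maxit = 500, reltol = 1e-14), control)
  opt <- stats::optim(theta0, objective, method = "BFGS", control = ctrl)
  # polish: BFGS from the Nelder-Mead-free solution is usually enough, but a
  # second start guards against a flat first line search
  opt2 <- stats::optim(opt$par, objective, method = "Nelder-Mead",
                       control = list(maxit = 2000, reltol = 1e-14))
  if (opt2$value < opt$value) opt <- opt2

  p <- unpack(opt$par)
  phi <- phi_of(p$c, p$b)
  lf <- linfit(phi)
  cf <- lf$coefficients
  rss <- sum(lf$residuals^2)
  est <- growth_params(alpha = cf[seq_len(k)], beta = cf[k + seq_len(k)],
                       gamma = cf[2 * k + seq_len(k)], c = p$c, b = p$b,
                       sigma = sqrt(rss / max(n - 3 * k - length(free_i) - 1, 1)),
                       groups = glab)
  structure(list(params = est, rss = rss, fitted = lf$fitted.values,
                 converged = opt$convergence == 0, kernel_identifiable = TRUE,
                 n = n),
            class = "growth_fit")
}

#' @export
print.growth_fit <- function(x, ...) {
  cat(sprintf("<growth_fit: n = %d, rss = %.4g, kernel %sidentifiable>\n",
              x$n, x$rss, if (x$kernel_identifiable) "" else "NOT "))
  print(x$params)
  invisible(x)
}

#' Tidy a growth-model fit
#'
#' @param x A `growth_fit` from [fit_growth_params()].
#' @param ... Unused.
#' @return `tidy()`: one row per (term, group) estimate; `glance()`: a
#'   one-row fit summary.
#' @export
tidy.growth_fit <- function(x, ...) {
  p <- x$params
  k <- length(p$groups)
  tibble::tibble(
    term = c(rep(c("alpha", "beta", "gamma", "c"), each = k), "b", "sigma"),
    group = c(rep(p$groups, 4), NA, NA),
    estimate = c(unname(p$alpha), unname(p$beta), unname(p$gamma),
                 unname(p$c), p$b, p$sigma)
  )
}

#' @rdname tidy.growth_fit
#' @export
glance.growth_fit <- function(x, ...) {
  tibble::tibble(rss = x$rss, n = x$n, converged = x$converged,
                 kernel_identifiable = x$kernel_identifiable)
}
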