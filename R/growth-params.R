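#' Construct a growth parameter set
#'
#' One parameter set of the spatial growth model: per-group intercepts
#' (intrinsic growth rate `alpha`), size slopes `beta`, crowding responses
#' `gamma`, kernel scales `c`, plus the shared kernel decay `b` and the
#' residual standard deviation `sigma`. Units follow crown volume in m^3 per
#' census interval; `b` is in m^-2 and must be negative so the kernel
#' `c * Size * exp(b * D^2)` decays with distance.
#'
#' @param alpha,beta,gamma,c Numeric vectors, one entry per group. `c` must
#'   be non-negative.
#' @param b Shared kernel decay (scalar, < 0).
#' @param sigma Residual SD (scalar, >= 0).
#' @param groups Group labels; defaults to `names(alpha)`.
#' @return A `growth_params` object.
#' @export
#' @examples
#' growth_params(alpha = c(a = 1, b = 2), beta = c(0.5, 0.5),
#'               gamma = c(-0.1, -0.2), c = c(1, 1), b = -0.5, sigma = 0.1)
growth_params <- function(alpha, beta, gamma, c, b, sigma,
                          groups = names(alpha)) {
  if (is.null(groups)) groups <- as.character(seq_along(alpha))
  k <- length(groups)
  vecs <- list(alpha = alpha, beta = beta, gamma = gamma, c = c)
  for (nm in names(vecs)) {
    v <- vecs[[nm]]
    if (length(v) != k || !is.numeric(v) || !all(is.finite(v))) {
      rlang::abort(sprintf("`%s` must be finite numeric with one value per group.", nm),
                   class = "gardensim_error_invalid_params")
    }
  }
  if (k > 6) {
    rlang::abort("at most 6 groups are supported.",
                 class = "gardensim_error_invalid_params")
  }
  if (any(c < 0)) {
    rlang::abort("`c` must be non-negative.",
                 class = "gardensim_error_invalid_params")
  }
  if (!is.numeric(b) || length(b) != 1 || !is.finite(b) || b >= 0) {
    rlang::abort("`b` must be a single negative decay rate (m^-2).",
                 class = "gardensim_error_invalid_params")
  }
  if (!is.numeric(sigma) || length(sigma) != 1 || !is.finite(sigma) || sigma < 0) {
    rlang::abort("`sigma` must be a single non-negative SD.",
                 class = "gardensim_error_invalid_params")
  }
  out <- list(
    alpha = stats::setNames(as.numeric(alpha), groups),
    beta = stats::setNames(as.numeric(beta), groups),
    gamma = stats::setNames(as.numeric(gamma), groups),
    c = stats::setNames(as.numeric(c), groups),
    b = as.numeric(b),
    sigma = as.numeric(sigma),
    groups = as.character(groups)
  )
  structure(out, class = "growth_params")
}

#' @export
print.growth_params <- function(x, ...) {
  cat(sprintf("<growth_params: %d groups, b = %.4g m^-2, sigma = %.4g>\n",
              length(x$groups), x$b, x$sigma))
  print(tibble::tibble(group = x$groups, alpha = unname(x$alpha),
                       beta = unname(x$beta), gamma = unname(x$gamma),
                       c = unname(x$c)))
  invisible(x)
}

#' Read/write growth parameters as JSON
#'
#' Flat JSON with keys `groups`, `alpha`, `beta`, `gamma`, `c` (arrays by
#' group) and scalars `b`, `sigma`.
#'
#' @param params A `growth_params` object.
#' @param path File path.
#' @return `write_growth_params()` returns `path` invisibly;
#'   `read_growth_params()` returns a `growth_params`.
#' @export
write_growth_params <- function(params, path) {
  stopifnot(inherits(params, "growth_params"))
  jsonlite::write_json(
    list(groups = params$groups, alpha = unname(params$alpha),
         beta = unname(params$beta), gamma = unname(params$gamma),
         c = unname(params$c), b = params$b, sigma = params$sigma),
    path, digits = NA, auto_unbox = TRUE
  )
  invisible(path)
}

#' @rdname write_growth_params
#' @export
read_growth_params <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  growth_params(alpha = x$alpha, beta = x$beta, gamma = x$gamma, c = x$c,
                b = x$b, sigma = x$sigma, groups = x$groups)
}

# map plant group labels to positions in a parameter vector
group_index <- function(groups, params) {
  g <- match(as.character(groups), params$groups)
  if (anyNA(g)) {
    rlang::abort(
      paste("unknown group(s):",
            paste(unique(as.character(groups)[is.na(g)]), collapse = ", ")),
      class = "gardensim_error_unknown_group"
    )
  }
  g
}
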