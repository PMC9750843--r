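#' Default population-to-group roster
#'
#' The default garden hosts 56 source populations mapped onto six taxonomic
#' groups: five *Artemisia tridentata* subspecies-cytotype categories (11
#' populations each) plus a single *A. arbuscula* population. Group sample
#' sizes per population at the real site are unpublished, so populations are
#' spread as evenly as possible.
#'
#' @return A tibble with columns `population` (integer) and `group` (factor
#'   over the six group labels).
#' @export
#' @examples
#' default_population_groups()
default_population_groups <- function() {
  tibble::tibble(
    population = 1:56,
    group = factor(
      c(rep(garden_groups()[1:5], each = 11), garden_groups()[6]),
      levels = garden_groups()
    )
  )
}

#' Canonical group labels
#'
#' Five *A. tridentata* subspecies-cytotypes plus *A. arbuscula*, ordered by
#' convention (diploid before tetraploid within subspecies).
#'
#' @return Character vector of length 6.
#' @export
garden_groups <- function() {
  c("tridentata-2x", "tridentata-4x", "vaseyana-2x", "vaseyana-4x",
    "wyomingensis-4x", "arbuscula")
}

#' Generate a grid common-garden layout
#'
#' Builds a rectangular lattice of planting positions filled row-major over
#' `n_cols` columns, marks `n_dead` positions as mortalities (uniformly at
#' random), and assigns source populations to positions by randomly permuting
#' a balanced roster. Defaults emulate the motivating garden: 470 positions
#' at 1 m x 1.5 m spacing, 22 dead, 56 populations in 6 groups.
#'
#' @param n_positions Total planted positions (default 470).
#' @param n_cols Columns in the lattice; rows are added as needed (default 24,
#'   giving a near-square plot).
#' @param dx,dy Axis spacings in meters (defaults 1 and 1.5).
#' @param n_dead Number of mortality gaps (default 22).
#' @param group_spec Data frame mapping `population` to `group`
#'   (default [default_population_groups()]).
#' @param seed Integer seed controlling mortality placement and the
#'   population permutation.
#' @return A `garden_layout` tibble with columns `plant_id`, `x`, `y`,
#'   `alive`, `population`, `group`, and spacing attributes `dx`, `dy`.
#' @export
#' @examples
#' g <- make_grid_layout(seed = 1)
#' sum(g$alive)
make_grid_layout <- function(n_positions = 470L, n_cols = 24L, dx = 1, dy = 1.5,
                             n_dead = 22L, group_spec = default_population_groups(),
                             seed = 1L) {
  if (n_positions < 1 || n_cols < 1) {
    rlang::abort("`n_positions` and `n_cols` must be >= 1.",
                 class = "gardensim_error_invalid_layout")
  }
  if (dx <= 0 || dy <= 0) {
    rlang::abort("`dx` and `dy` must be positive.",
                 class = "gardensim_error_invalid_distance")
  }
  if (n_dead < 0 || n_dead >= n_positions) {
    rlang::abort("`n_dead` must satisfy 0 <= n_dead < n_positions.",
                 class = "gardensim_error_invalid_mortality")
  }
  group_spec <- tibble::as_tibble(group_spec)
  if (nrow(group_spec) == 0 || !all(c("population", "group") %in% names(group_spec))) {
    rlang::abort("`group_spec` must be a non-empty population -> group table.",
                 class = "gardensim_error_invalid_roster")
  }
  if (anyDuplicated(group_spec$population) > 0) {
    rlang::abort("each population must map to exactly one group.",
                 class = "gardensim_error_invalid_roster")
  }

  # balanced roster: each population planted floor(n/p) or ceiling(n/p) times
  p <- nrow(group_spec)
  counts <- rep(n_positions %/% p, p)
  extra <- n_positions %% p
  if (extra > 0) counts[seq_len(extra)] <- counts[seq_len(extra)] + 1L
  roster <- rep(group_spec$population, times = counts)

  set.seed(seed)
  dead <- sample.int(n_positions, n_dead)
  pops <- sample(roster)

  idx <- seq_len(n_positions) - 1L
  col <- idx %% n_cols
  row <- idx %/% n_cols
  grp <- group_spec$group[match(pops, group_spec$population)]

  out <- tibble::tibble(
    plant_id = seq_len(n_positions),
    x = col * dx,
    y = row * dy,
    alive = !(seq_len(n_positions) %in% dead),
    population = pops,
    group = grp
  )
  new_garden_layout(out, dx = dx, dy = dy)
}

new_garden_layout <- function(df, dx, dy) {
  out <- tibble::new_tibble(df, dx = dx, dy = dy,
                            class = "garden_layout", nrow = nrow(df))
  validate_garden_layout(out)
  out
}

#' @export
print.garden_layout <- function(x, ...) {
  cat(sprintf("<garden_layout: %d positions (%d alive), spacing %g x %g m>\n",
              nrow(x), sum(x$alive), attr(x, "dx"), attr(x, "dy")))
  NextMethod()
}

validate_garden_layout <- function(layout) {
  req <- c("plant_id", "x", "y", "alive", "population", "group")
  if (!all(req %in% names(layout))) {
    rlang::abort(paste("layout is missing columns:",
                       paste(setdiff(req, names(layout)), collapse = ", ")),
                 class = "gardensim_error_invalid_layout")
  }
  if (anyDuplicated(cbind(layout$x, layout$y)) > 0) {
    rlang::abort("layout coordinates must be distinct.",
                 class = "gardensim_error_invalid_layout")
  }
  map <- unique(tibble::tibble(population = layout$population,
                               group = as.character(layout$group)))
  if (anyDuplicated(map$population) > 0) {
    rlang::abort("every population must map to exactly one group.",
                 class = "gardensim_error_invalid_layout")
  }
  if (dplyr::n_distinct(layout$group) > 6) {
    rlang::abort("at most 6 groups are supported.",
                 class = "gardensim_error_invalid_layout")
  }
  invisible(layout)
}

layout_spacing <- function(layout) {
  dx <- attr(layout, "dx")
  dy <- attr(layout, "dy")
  if (is.null(dx) || is.null(dy)) {
    # infer from the lattice: smallest positive coordinate differences
    ux <- sort(unique(layout$x)); uy <- sort(unique(layout$y))
    dx <- if (length(ux) > 1) min(diff(ux)) else 1
    dy <- if (length(uy) > 1) min(diff(uy)) else 1
  }
  c(dx = dx, dy = dy)
}

strip_readr_attrs <- function(df) {
  attr(df, "spec") <- NULL
  attr(df, "problems") <- NULL
  df
}

# stored group labels come back as character; recover canonical level order
# (all six garden groups when the labels are a subset of them)
csv_group_levels <- function(groups) {
  u <- unique(groups)
  if (all(u %in% garden_groups())) garden_groups() else sort(u)
}

lattice_indices <- function(layout) {
  sp <- layout_spacing(layout)
  cbind(col = round(layout$x / sp[["dx"]]), row = round(layout$y / sp[["dy"]]))
}

#' Rescale a layout to a uniform planting distance
#'
#' Keeps the lattice topology, occupancy, and all labels, and sets both axis
#' spacings to `d` (a uniform square lattice). This is the distance-scenario
#' operation: the same garden, planted wider or tighter.
#'
#' @param layout A `garden_layout`.
#' @param d Planting distance in meters (> 0).
#' @return A `garden_layout` at spacing `d` on both axes.
#' @export
#' @examples
#' g <- make_grid_layout(seed = 1)
#' g05 <- rescale_layout(g, 0.5)
rescale_layout <- function(layout, d) {
  if (!is.numeric(d) || length(d) != 1 || !is.finite(d) || d <= 0) {
    rlang::abort("`d` must be a single positive distance in meters.",
                 class = "gardensim_error_invalid_distance")
  }
  validate_garden_layout(layout)
  ij <- lattice_indices(layout)
  out <- layout
  out$x <- ij[, "col"] * d
  out$y <- ij[, "row"] * d
  new_garden_layout(out, dx = d, dy = d)
}

#' Spatially perturb a layout
#'
#' Randomly permutes the plant tuples (alive flag, population, group, and an
#' attached `size` column if present) across the fixed lattice positions.
#' Used to check that results do not hinge on pre-existing spatial pattern in
#' mortality or plant arrangement.
#'
#' @param layout A `garden_layout`.
#' @param seed Integer seed for the permutation.
#' @return A `garden_layout` with permuted labels on the same positions.
#' @export
perturb_layout <- function(layout, seed = 1L) {
  validate_garden_layout(layout)
  set.seed(seed)
  perm <- sample.int(nrow(layout))
  out <- layout
  movable <- intersect(c("alive", "population", "group", "size"), names(layout))
  for (cl in movable) out[[cl]] <- layout[[cl]][perm]
  sp <- layout_spacing(layout)
  new_garden_layout(out, dx = sp[["dx"]], dy = sp[["dy"]])
}

#' Pairwise distances among live plants
#'
#' @param layout A `garden_layout`.
#' @return A symmetric matrix of Euclidean distances (meters) among live
#'   plants, zero diagonal, dimnames set to `plant_id`.
#' @export
pairwise_distances <- function(layout) {
  validate_garden_layout(layout)
  live <- layout[layout$alive, , drop = FALSE]
  m <- as.matrix(stats::dist(cbind(live$x, live$y)))
  dimnames(m) <- list(live$plant_id, live$plant_id)
  m
}

#' Read/write a garden layout as CSV
#'
#' Plain CSV with columns `plant_id, x, y, alive, population, group`; the
#' alive flag is stored as 0/1. Spacings are re-inferred from the lattice on
#' read (or can be supplied).
#'
#' @param layout A `garden_layout`.
#' @param path File path.
#' @param dx,dy Optional spacings to attach on read; inferred if `NULL`.
#' @return `write_garden_layout()` returns `path` invisibly;
#'   `read_garden_layout()` returns a `garden_layout`.
#' @export
write_garden_layout <- function(layout, path) {
  validate_garden_layout(layout)
  out <- tibble::as_tibble(layout)
  out$alive <- as.integer(out$alive)
  out$group <- as.character(out$group)
  keep <- c("plant_id", "x", "y", "alive", "population", "group",
            intersect("size", names(out)))
  readr::write_csv(out[, keep], path)
  invisible(path)
}

#' @rdname write_garden_layout
#' @export
read_garden_layout <- function(path, dx = NULL, dy = NULL) {
  df <- strip_readr_attrs(readr::read_csv(path, show_col_types = FALSE))
  df$alive <- as.logical(df$alive)
  df$group <- factor(df$group, levels = csv_group_levels(df$group))
  sp <- layout_spacing(df)
  new_garden_layout(df, dx = dx %||% sp[["dx"]], dy = dy %||% sp[["dy"]])
}
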