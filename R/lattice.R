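#' Periodic lattice landscape
#'
#' Creates an `L x L` toroidal landscape with every site in a single state.
#' A landscape is an integer matrix with entries in `{-1, 0, 1, 2}` (see
#' [cell_states()]); all package functions treat it with periodic boundary
#' conditions in both axes.
#'
#' @param L Lattice side length (>= 4).
#' @param fill State for every site: a name (`"vacant"`, `"destroyed"`, `"nc"`,
#'   `"exploiter"`) or an integer code.
#' @return An integer matrix of class `landscape`.
#' @examples
#' g <- landscape(8, "nc")
#' state_fractions(g)
#' @export
landscape <- function(L, fill = "vacant") {
  L <- .check_L(L)
  code <- .state_codes(fill)
  if (length(code) != 1) stop("'fill' must be a single state")
  structure(matrix(code, L, L), class = c("landscape", "matrix", "array"))
}

.check_L <- function(L) {
  if (length(L) != 1 || !is.finite(L) || L < 3 || L != round(L)) {
    stop("'L' must be a single integer >= 3")
  }
  as.integer(L)
}

.as_landscape <- function(grid) {
  if (!is.matrix(grid) || nrow(grid) != ncol(grid)) {
    stop("a landscape must be a square matrix")
  }
  storage.mode(grid) <- "integer"
  if (!all(grid %in% c(.S_DES, .S_VAC, .S_NC, .S_EX))) {
    stop("landscape entries must be state codes in {-1, 0, 1, 2}")
  }
  class(grid) <- c("landscape", "matrix", "array")
  grid
}

#' @export
print.landscape <- function(x, ...) {
  fr <- state_fractions(x)
  cat(sprintf(
    "<landscape %dx%d (toroidal)>  p-: %.3f  p0: %.3f  p+: %.3f  p++: %.3f\n",
    nrow(x), ncol(x), fr["p_minus"], fr["p_vacant"], fr["p_nc"], fr["p_ex"]
  ))
  invisible(x)
}

#' Global state fractions of a landscape
#'
#' @param grid A landscape matrix.
#' @return Named numeric vector `(p_minus, p_vacant, p_nc, p_ex)`; the four
#'   fractions sum to 1.
#' @export
state_fractions <- function(grid) {
  n <- length(grid)
  c(
    p_minus = sum(grid == .S_DES) / n,
    p_vacant = sum(grid == .S_VAC) / n,
    p_nc = sum(grid == .S_NC) / n,
    p_ex = sum(grid == .S_EX) / n
  )
}

#' Interaction-neighborhood offsets (Hamming ball)
#'
#' Enumerates the displacement vectors of the Hamming (Manhattan / von
#' Neumann) neighborhood of range `r`: all `(dr, dc)` with
#' `1 <= |dr| + |dc| <= r`, the focal site excluded. The neighborhood size is
#' `2 r (r + 1)`; for `r = 1` it is the four nearest neighbors N, E, S, W.
#'
#' @param r Interaction range, a positive integer.
#' @return An object of class `neighborhood_spec`: a list with `range` and
#'   `offsets` (a two-column integer matrix of row/column displacements).
#' @examples
#' nrow(neighborhood_offsets(1)$offsets) # 4
#' nrow(neighborhood_offsets(2)$offsets) # 12
#' @export
neighborhood_offsets <- function(r) {
  if (length(r) != 1 || !is.finite(r) || r < 1 || r != round(r)) {
    stop("'r' must be a single integer >= 1")
  }
  r <- as.integer(r)
  dr <- rep(-r:r, times = 2L * (r - abs(-r:r)) + 1L)
  dc <- unlist(lapply(-r:r, function(d) {
    rem <- r - abs(d)
    -rem:rem
  }))
  keep <- !(dr == 0L & dc == 0L)
  structure(
    list(range = r, offsets = cbind(dr = dr[keep], dc = dc[keep])),
    class = "neighborhood_spec"
  )
}

#' @export
print.neighborhood_spec <- function(x, ...) {
  cat(sprintf(
    "<neighborhood_spec> Hamming range %d, %d offsets\n",
    x$range, nrow(x$offsets)
  ))
  invisible(x)
}

#' Count neighbors in a given state
#'
#' Counts the sites at the toroidal offsets of `spec` around `site` whose state
#' equals `target`. Distances use the minimum-image convention on the torus, so
#' wrap-around neighbors are counted; on small lattices several offsets may map
#' to the same physical site and are then counted once per offset, matching the
#' simulator's per-offset colonization attempts.
#'
#' @param grid A landscape matrix.
#' @param site Integer vector `c(row, col)`, 1-based.
#' @param spec A [neighborhood_offsets()] object.
#' @param target State name or code to count.
#' @return Non-negative integer count, at most `nrow(spec$offsets)`.
#' @export
count_neighbors <- function(grid, site, spec, target) {
  L <- nrow(grid)
  if (length(site) != 2 || any(site < 1) || any(site > L)) {
    stop("'site' must be c(row, col) within the grid")
  }
  code <- .state_codes(target)
  rr <- ((site[1] - 1 + spec$offsets[, "dr"]) %% L) + 1
  cc <- ((site[2] - 1 + spec$offsets[, "dc"]) %% L) + 1
  sum(grid[cbind(rr, cc)] == code)
}

#' Connected clusters of occupied (or other) sites
#'
#' Labels the connected components of all sites in the target states under
#' 4-connectivity (von Neumann adjacency), with toroidal wrap by default.
#' Cluster connectivity is fixed at range 1 regardless of the model's
#' construction range: contiguity is defined by the colonization graph.
#'
#' @param grid A landscape matrix (or any integer matrix of state codes).
#' @param targets States forming clusters; default both occupied strategies.
#' @param wrap Use periodic boundaries (default `TRUE`).
#' @return An object of class `cluster_stats`: list with `cluster_sizes`
#'   (decreasing), `n_clusters`, `largest_fraction` (largest component size
#'   over total target sites; `NA` if none), and `labels` (matrix of component
#'   ids, 0 for non-target sites).
#' @examples
#' g <- landscape(6, "vacant")
#' g[1, 1] <- g[1, 2] <- g[4, 5] <- 1L
#' connected_clusters(g, "nc")$n_clusters # 2
#' @export
connected_clusters <- function(grid, targets = c("nc", "exploiter"), wrap = TRUE) {
  codes <- .state_codes(targets)
  if (nrow(grid) != ncol(grid) && wrap) {
    # wrapped components are defined for any rectangle; keep it general
  }
  res <- clusters_cpp(as.integer(grid), nrow(grid), ncol(grid), codes, wrap)
  sizes <- sort(res$sizes, decreasing = TRUE)
  structure(
    list(
      cluster_sizes = sizes,
      n_clusters = length(sizes),
      largest_fraction = if (length(sizes)) sizes[1] / sum(sizes) else NA_real_,
      labels = matrix(res$labels, nrow(grid), ncol(grid))
    ),
    class = "cluster_stats"
  )
}

#' @export
print.cluster_stats <- function(x, ...) {
  cat(sprintf(
    "<cluster_stats> %d cluster(s), largest fraction %.3f\n",
    x$n_clusters, x$largest_fraction
  ))
  invisible(x)
}

#' Write / read a landscape as integer-coded CSV
#'
#' Plain-text serialization of a lattice snapshot: one CSV row per lattice row,
#' entries `-1` destroyed, `0` vacant, `1` NC, `2` exploiter, no header.
#'
#' @param grid A landscape matrix.
#' @param path Output file path.
#' @return `write_landscape_csv` returns `path` invisibly;
#'   `read_landscape_csv` returns a `landscape` matrix.
#' @export
write_landscape_csv <- function(grid, path) {
  utils::write.table(unclass(grid), path,
    sep = ",", row.names = FALSE,
    col.names = FALSE
  )
  invisible(path)
}

#' @rdname write_landscape_csv
#' @export
read_landscape_csv <- function(path) {
  m <- as.matrix(utils::read.table(path, sep = ",", header = FALSE))
  dimnames(m) <- NULL
  .as_landscape(m)
}

#' Write a PNG snapshot of a landscape
#'
#' Renders the lattice with the conventional palette: green = NC (occupied),
#' white = vacant, black = destroyed, red = exploiter.
#'
#' @param grid A landscape matrix.
#' @param path Output PNG path.
#' @param pixel_size Pixels per lattice site.
#' @return `path`, invisibly.
#' @export
write_snapshot_png <- function(grid, path, pixel_size = 2) {
  L <- nrow(grid)
  pal <- c("black", "white", "forestgreen", "red3") # codes -1, 0, 1, 2
  grDevices::png(path, width = L * pixel_size, height = L * pixel_size)
  op <- graphics::par(mar = c(0, 0, 0, 0))
  on.exit({
    graphics::par(op)
    grDevices::dev.off()
  })
  # image() draws column j of z at x = j: transpose so the plot matches the
  # matrix orientation (row 1 at the top).
  z <- t(unclass(grid))[, L:1, drop = FALSE]
  graphics::image(
    seq_len(L), seq_len(L), z,
    col = pal, breaks = c(-1.5, -0.5, 0.5, 1.5, 2.5),
    axes = FALSE, xlab = "", ylab = "", useRaster = TRUE
  )
  invisible(path)
}
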