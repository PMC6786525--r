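# Density rasters over the triangle of biomedicine: point-light accumulation,
# separable Gaussian smoothing, ratio maps, and pseudocolour rendering.

TRI_XLIM <- c(-sqrt(3) / 2, sqrt(3) / 2)
TRI_YLIM <- c(-0.5, 1)

# Inverse of the trilinear transform; used for the inside-triangle test.
.tri_barycentric <- function(x, y) {
  h <- (y + 0.5) / 1.5
  a <- ((1 - h) + 2 * x / sqrt(3)) / 2
  mc <- 1 - h - a
  cbind(h = h, a = a, mc = mc)
}

#' Accumulate article coordinates into a density grid
#'
#' Each article is a point light source at its trilinear coordinates; articles
#' landing on the same pixel sum their weights (ten articles at the Animal
#' vertex give that pixel the value ten). Nearest-pixel binning conserves the
#' total weight exactly.
#'
#' @param x,y Trilinear coordinates (must lie inside or on the triangle, up to
#'   a small tolerance).
#' @param weights Per-article weights (recycled; default 1).
#' @param grid_size Raster side length in pixels.
#' @return A `density_grid`: list with `values` (`grid_size x grid_size`
#'   matrix, rows = x, columns = y), `grid_size`, `xlim`, `ylim`.
#' @export
triangle_accumulate <- function(x, y, weights = 1, grid_size = 512L) {
  stopifnot(length(x) == length(y), grid_size >= 2L)
  weights <- rep_len(weights, length(x))
  if (length(x) > 0L) {
    b <- .tri_barycentric(x, y)
    if (any(b < -1e-9)) stop("coordinate(s) outside the triangle")
  }
  values <- matrix(0, nrow = grid_size, ncol = grid_size)
  if (length(x) > 0L) {
    px <- pmin(grid_size, pmax(1L, 1L + round((x - TRI_XLIM[1L]) /
                                                diff(TRI_XLIM) * (grid_size - 1L))))
    py <- pmin(grid_size, pmax(1L, 1L + round((y - TRI_YLIM[1L]) /
                                                diff(TRI_YLIM) * (grid_size - 1L))))
    idx <- (py - 1L) * grid_size + px
    acc <- tapply(weights, idx, sum)
    values[as.integer(names(acc))] <- as.numeric(acc)
  }
  structure(list(values = values, grid_size = as.integer(grid_size),
                 xlim = TRI_XLIM, ylim = TRI_YLIM),
            class = "density_grid")
}

# 1-D convolution of the columns of m with kernel k, zero-padded.
.conv_cols <- function(m, k) {
  r <- (length(k) - 1L) %/% 2L
  n <- nrow(m)
  out <- matrix(0, nrow = n, ncol = ncol(m))
  for (j in seq_along(k)) {
    shift <- j - r - 1L
    src <- seq_len(n) + shift
    ok <- src >= 1L & src <= n
    out[ok, ] <- out[ok, ] + k[j] * m[src[ok], ]
  }
  out
}

#' Gaussian smoothing of a density grid
#'
#' Separable Gaussian blur with standard deviation `sigma` in pixels;
#' `sigma = 0` is the identity. Zero padding at the raster edge, so total
#' weight is conserved except for mass blurred past the boundary.
#'
#' @param grid A `density_grid`.
#' @param sigma Blur standard deviation in pixels (`>= 0`).
#' @return A smoothed `density_grid`.
#' @export
triangle_smooth <- function(grid, sigma) {
  stopifnot(inherits(grid, "density_grid"), sigma >= 0)
  if (sigma == 0) return(grid)
  r <- ceiling(3 * sigma)
  k <- stats::dnorm(seq(-r, r), sd = sigma)
  k <- k / sum(k)
  v <- .conv_cols(grid$values, k)      # along x
  v <- t(.conv_cols(t(v), k))          # along y
  grid$values <- v
  grid
}

#' Ratio of two density grids
#'
#' Pixel-wise `numerator / denominator` after optional smoothing of both, with
#' zero-denominator pixels masked to `NA` — e.g. the fraction of articles on
#' each triangle pixel that were clinically cited.
#'
#' @param numerator,denominator `density_grid`s on the same raster.
#' @param sigma Smoothing applied to both before division (default 0).
#' @return A `density_grid` of ratios with `NA` where the denominator is zero.
#' @export
triangle_ratio <- function(numerator, denominator, sigma = 0) {
  stopifnot(inherits(numerator, "density_grid"),
            inherits(denominator, "density_grid"),
            numerator$grid_size == denominator$grid_size)
  num <- triangle_smooth(numerator, sigma)
  den <- triangle_smooth(denominator, sigma)
  out <- num
  v <- num$values / den$values
  v[den$values == 0] <- NA_real_
  out$values <- v
  out
}

#' Render a density grid
#'
#' Pseudocolours the raster with a perceptually uniform palette, draws the
#' triangle outline and vertex labels, and optionally writes a PNG. Rendering
#' is deterministic.
#'
#' @param grid A `density_grid`.
#' @param palette Function `n -> colours` (default viridis via
#'   [grDevices::hcl.colors()]).
#' @param file Optional PNG output path.
#' @param n_colors Number of palette steps.
#' @param main Plot title.
#' @param width,height Device size in pixels when writing a file.
#' @return The colour legend (value breaks and colours), invisibly.
#' @export
plot_triangle <- function(grid, palette = function(n) grDevices::hcl.colors(n, "viridis"),
                          file = NULL, n_colors = 64L, main = "",
                          width = 800L, height = 800L) {
  stopifnot(inherits(grid, "density_grid"))
  if (!is.null(file)) {
    grDevices::png(file, width = width, height = height)
    on.exit(grDevices::dev.off(), add = TRUE)
  }
  cols <- palette(n_colors)
  rng <- range(grid$values, na.rm = TRUE)
  if (diff(rng) == 0) rng <- rng + c(0, 1e-12)
  breaks <- seq(rng[1L], rng[2L], length.out = n_colors + 1L)
  xs <- seq(grid$xlim[1L], grid$xlim[2L], length.out = grid$grid_size)
  ys <- seq(grid$ylim[1L], grid$ylim[2L], length.out = grid$grid_size)
  graphics::image(xs, ys, grid$values, col = cols, breaks = breaks,
                  asp = 1, xlab = "", ylab = "", axes = FALSE, main = main)
  s <- sqrt(3) / 2
  graphics::polygon(c(0, s, -s), c(1, -0.5, -0.5), border = "grey30")
  graphics::text(c(0, s, -s), c(1.06, -0.58, -0.58),
                 labels = c("Human", "Animal", "Mol./Cell."), cex = 0.9)
  invisible(list(breaks = breaks, colors = cols))
}

#' Write / read a density grid as TSV
#'
#' Plain-text raster exchange format for regression tests and downstream
#' tools: one row per raster row, tab-separated.
#'
#' @param grid A `density_grid`.
#' @param path File path.
#' @return `write_grid_tsv()`: `path` invisibly; `read_grid_tsv()`: a
#'   `density_grid`.
#' @export
write_grid_tsv <- function(grid, path) {
  stopifnot(inherits(grid, "density_grid"))
  utils::write.table(grid$values, path, sep = "\t", row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' @rdname write_grid_tsv
#' @export
read_grid_tsv <- function(path) {
  values <- as.matrix(utils::read.table(path, sep = "\t", header = FALSE))
  dimnames(values) <- NULL
  stopifnot(nrow(values) == ncol(values))
  structure(list(values = values, grid_size = nrow(values),
                 xlim = TRI_XLIM, ylim = TRI_YLIM),
            class = "density_grid")
}
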