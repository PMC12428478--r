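#' Surface and radar visualisation
#'
#' The nine primary scores of a policy arranged row-major in a 3x3 grid
#' make the surface diagram: an interpolated 3-D sheet whose concave
#' regions mark weak dimensions. The radar chart plots the per-primary
#' column means on nine axes scaled \[0, 1\].
#'
#' @name pmc_plots
NULL

#' 3x3 surface matrix of one policy's primary scores
#'
#' Row-major placement: first row X1 X2 X3, second X4 X5 X6, third
#' X7 X8 X9. A pure reshaping — no smoothing, exact score values.
#'
#' @param scores a `pmc_scores` object, or a named numeric vector of the
#'   nine primary scores.
#' @param code policy code (required when `scores` is a `pmc_scores`).
#' @return 3x3 numeric matrix.
#' @export
#' @examples
#' sc <- score_policies(integration_policies()$coding)
#' surface_matrix(sc, "P22")
surface_matrix <- function(scores, code = NULL) {
  ids <- paste0("X", 1:9)
  if (inherits(scores, "pmc_scores")) {
    if (is.null(code) || !code %in% scores$results$code) {
      abort_pmc("supply a policy code present in the results",
                "pmc_plot_error")
    }
    v <- scores$exact$num[code, ids] / scores$exact$den[code, ids]
  } else {
    v <- scores[ids]
  }
  if (anyNA(v)) {
    abort_pmc("all nine scored primaries X1..X9 are required",
              "pmc_plot_error")
  }
  if (any(v < 0 | v > 1)) {
    abort_pmc("primary scores must lie in [0, 1]", "pmc_plot_error")
  }
  matrix(as.numeric(v), nrow = 3, byrow = TRUE)
}

# Bilinear interpolation of a small grid up to n x n (cosmetic
# smoothing of the plotted sheet only; scores are never interpolated).
interp_bilinear <- function(grid, n = 30) {
  nr <- nrow(grid); nc <- ncol(grid)
  xs <- seq(1, nc, length.out = n)
  ys <- seq(1, nr, length.out = n)
  out <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    y <- ys[i]; x <- xs[j]
    y0 <- floor(y); x0 <- floor(x)
    y1 <- min(y0 + 1, nr); x1 <- min(x0 + 1, nc)
    fy <- y - y0; fx <- x - x0
    out[i, j] <- grid[y0, x0] * (1 - fy) * (1 - fx) +
      grid[y1, x0] * fy * (1 - fx) +
      grid[y0, x1] * (1 - fy) * fx +
      grid[y1, x1] * fy * fx
  }
  out
}

open_device <- function(path, width = 5, height = 5) {
  if (grepl("\\.svg$", path, ignore.case = TRUE)) {
    grDevices::svg(path, width = width, height = height)
  } else {
    grDevices::png(path, width = width * 96, height = height * 96)
  }
}

#' Render a policy surface diagram
#'
#' Draws the bilinearly interpolated 3-D sheet over the 3x3 score grid
#' with fixed perspective settings, so repeated renders of the same
#' input are byte-identical.
#'
#' @param mat 3x3 matrix from [surface_matrix()].
#' @param path output `.png` or `.svg` path; `NULL` draws on the current
#'   device.
#' @param title plot title.
#' @param resolution interpolation grid size (cosmetic).
#' @return `path`, invisibly.
#' @export
render_surface <- function(mat, path = NULL, title = "", resolution = 30) {
  z <- interp_bilinear(mat, resolution)
  draw <- function() {
    graphics::persp(seq_len(nrow(z)), seq_len(ncol(z)), z,
                    zlim = c(0, 1), theta = 40, phi = 25, expand = 0.6,
                    col = "lightsteelblue", shade = 0.4, border = NA,
                    xlab = "", ylab = "", zlab = "score",
                    ticktype = "simple", main = title)
  }
  if (is.null(path)) {
    draw()
  } else {
    open_device(path)
    on.exit(grDevices::dev.off())
    draw()
  }
  invisible(path)
}

#' Render the mean radar chart
#'
#' Nine axes in X1..X9 order, values on \[0, 1\], no renormalisation.
#'
#' @param means named numeric vector containing `X1`..`X9` (e.g.
#'   `column_means` of a `pmc_scores`).
#' @param path output `.png` or `.svg` path; `NULL` draws on the
#'   current device.
#' @param title plot title.
#' @return `path`, invisibly.
#' @export
render_radar <- function(means, path = NULL, title = "Mean primary scores") {
  ids <- paste0("X", 1:9)
  v <- as.numeric(means[ids])
  if (anyNA(v)) {
    abort_pmc("means must contain X1..X9", "pmc_plot_error")
  }
  ang <- pi / 2 - 2 * pi * (seq_along(ids) - 1) / length(ids)
  draw <- function() {
    graphics::par(mar = c(1, 1, 3, 1))
    graphics::plot(NA, xlim = c(-1.3, 1.3), ylim = c(-1.3, 1.3),
                   axes = FALSE, xlab = "", ylab = "", asp = 1,
                   main = title)
    for (r in c(0.25, 0.5, 0.75, 1)) {
      graphics::polygon(r * cos(ang), r * sin(ang), border = "grey80")
    }
    graphics::segments(0, 0, cos(ang), sin(ang), col = "grey80")
    graphics::polygon(v * cos(ang), v * sin(ang),
                      border = "steelblue", col = grDevices::adjustcolor(
                        "steelblue", alpha.f = 0.35), lwd = 2)
    graphics::text(1.18 * cos(ang), 1.18 * sin(ang), ids, cex = 0.9)
  }
  if (is.null(path)) {
    draw()
  } else {
    open_device(path)
    on.exit(grDevices::dev.off())
    draw()
  }
  invisible(path)
}

#' Batch-render surfaces for a scored policy set
#'
#' Writes one file per policy in ranking order (left-to-right,
#' top-to-bottom reading order of the composite), named
#' `NN_<code>.<format>`, plus a composite contact sheet
#' `surfaces_all.png`.
#'
#' @param scores a `pmc_scores`.
#' @param dir output directory (created if absent).
#' @param format `"png"` or `"svg"` for the per-policy files.
#' @return character vector of written per-policy paths, invisibly.
#' @export
render_surfaces <- function(scores, dir, format = c("png", "svg")) {
  format <- match.arg(format)
  stopifnot(inherits(scores, "pmc_scores"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  codes <- scores$results$code
  paths <- character(length(codes))
  for (i in seq_along(codes)) {
    paths[i] <- file.path(dir, sprintf("%02d_%s.%s", i, codes[i], format))
    render_surface(surface_matrix(scores, codes[i]), paths[i],
                   title = codes[i])
  }
  sheet <- file.path(dir, "surfaces_all.png")
  nc <- ceiling(sqrt(length(codes)))
  nr <- ceiling(length(codes) / nc)
  grDevices::png(sheet, width = nc * 220, height = nr * 220)
  graphics::par(mfrow = c(nr, nc), mar = c(0.5, 0.5, 1.5, 0.5))
  for (i in seq_along(codes)) {
    render_surface(surface_matrix(scores, codes[i]), path = NULL,
                   title = codes[i])
  }
  grDevices::dev.off()
  invisible(paths)
}
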