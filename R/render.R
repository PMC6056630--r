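# Rendering is presentation-only: a symmetric maroon-to-blue diverging scale
# for portraits, sequential scales for variance/prognostic maps. Never part
# of correctness tests.

portrait_palette <- function(n = 101) {
  grDevices::colorRampPalette(c("midnightblue", "steelblue", "white",
                                "indianred", "maroon"))(n)
}

draw_map <- function(mat, col, main = "", zlim = NULL) {
  mat <- mat[rev(seq_len(nrow(mat))), , drop = FALSE]  # row 0 on top
  if (is.null(zlim)) zlim <- suppressWarnings(range(mat, finite = TRUE))
  if (!all(is.finite(zlim))) zlim <- c(0, 1)
  if (diff(zlim) == 0) zlim <- zlim + c(-1, 1) * max(1e-6, abs(zlim[1]) / 100)
  graphics::image(t(mat), col = col, axes = FALSE, main = main, zlim = zlim,
                  useRaster = TRUE)
  graphics::box()
}

#' Render a portrait (or any per-metagene map) to PNG
#'
#' @param p Per-metagene vector (portrait, variance map, ...).
#' @param path Output PNG path.
#' @param grid `c(rows, cols)`; taken from the portrait attribute if absent.
#' @param main Plot title.
#' @param diverging Symmetric maroon-to-blue scale around zero (portraits);
#'   otherwise a sequential scale (variance maps).
#' @return Invisibly, the path.
#' @export
render_portrait_png <- function(p, path, grid = attr(p, "grid"), main = "",
                                diverging = TRUE) {
  mat <- portrait_matrix(p, grid)
  grDevices::png(path, width = 480, height = 480)
  on.exit(grDevices::dev.off())
  if (diverging) {
    lim <- max(abs(mat), na.rm = TRUE)
    if (lim == 0) lim <- 1
    draw_map(mat, portrait_palette(), main, zlim = c(-lim, lim))
  } else {
    draw_map(mat, grDevices::hcl.colors(101, "YlOrBr", rev = TRUE), main)
  }
  invisible(path)
}

#' Render a spot segmentation overlay to PNG
#'
#' @param seg A `spot_segmentation`.
#' @param path Output PNG path.
#' @return Invisibly, the path.
#' @export
render_segmentation_png <- function(seg, path) {
  n <- prod(seg$grid)
  lab <- rep(0L, n)
  for (i in seq_along(seg$spots)) lab[seg$spots[[i]]$pixels] <- i
  mat <- portrait_matrix(lab, seg$grid)
  grDevices::png(path, width = 480, height = 480)
  on.exit(grDevices::dev.off())
  cols <- c("grey92", grDevices::hcl.colors(max(1, length(seg$spots)), "Dark 3"))
  draw_map(mat, cols, main = "spot segmentation")
  invisible(path)
}

#' Render a prognostic map to PNG (masked pixels white)
#'
#' @param pm A `prognostic_map`.
#' @param path Output PNG path.
#' @return Invisibly, the path.
#' @export
render_prognostic_png <- function(pm, path) {
  mat <- portrait_matrix(as.numeric(pm$pct), pm$grid)
  grDevices::png(path, width = 480, height = 480)
  on.exit(grDevices::dev.off())
  draw_map(mat, grDevices::hcl.colors(101, "RdYlGn"),
           main = "28-day survivor percentage", zlim = c(0, 100))
  invisible(path)
}
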