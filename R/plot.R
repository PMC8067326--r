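# Base-graphics views of meshes and fields (2D). ParaView via the VTU
# snapshots is the intended tool for 3D output.

#' @export
plot.ch_domain <- function(x, ...) {
  if (x$dim != 2L) stop("plot method supports 2D domains; export a VTU snapshot for 3D")
  graphics::plot(x$nodes, type = "n", asp = 1, xlab = "x", ylab = "y",
                 main = sprintf("%s mesh (%d elements)", x$shape, nrow(x$elements)), ...)
  e <- x$elements
  graphics::segments(x$nodes[e[, 1], 1], x$nodes[e[, 1], 2],
                     x$nodes[e[, 2], 1], x$nodes[e[, 2], 2], col = "grey70")
  graphics::segments(x$nodes[e[, 2], 1], x$nodes[e[, 2], 2],
                     x$nodes[e[, 3], 1], x$nodes[e[, 3], 2], col = "grey70")
  graphics::segments(x$nodes[e[, 3], 1], x$nodes[e[, 3], 2],
                     x$nodes[e[, 1], 1], x$nodes[e[, 1], 2], col = "grey70")
  f <- x$facets
  cols <- ifelse(x$facet_tag == 0L, "black", "orange")
  graphics::segments(x$nodes[f[, 1], 1], x$nodes[f[, 1], 2],
                     x$nodes[f[, 2], 1], x$nodes[f[, 2], 2], col = cols, lwd = 2)
  invisible(x)
}

#' Filled-element plot of a 2D phase field
#'
#' Membrane phase (psi < 0) in blue, matrix phase (psi > 0) in red, the
#' transition region whitening towards psi = 0.
#'
#' @param d A 2D \code{ch_domain}.
#' @param psi Nodal order parameter.
#' @param ... Passed to \code{plot}.
#' @export
plot_field <- function(d, psi, ...) {
  stopifnot(inherits(d, "ch_domain"), d$dim == 2L)
  check_field(d, psi, "psi")
  pal <- grDevices::colorRampPalette(c("#2166ac", "#f7f7f7", "#b2182b"))(101)
  cv <- pmin(pmax(rowMeans(element_values(d, psi)), -1), 1)
  col <- pal[round((cv + 1) * 50) + 1L]
  graphics::plot(d$nodes, type = "n", asp = 1, xlab = "x", ylab = "y", ...)
  e <- d$elements
  xs <- rbind(d$nodes[e[, 1], 1], d$nodes[e[, 2], 1], d$nodes[e[, 3], 1], NA)
  ys <- rbind(d$nodes[e[, 1], 2], d$nodes[e[, 2], 2], d$nodes[e[, 3], 2], NA)
  graphics::polygon(as.vector(xs), as.vector(ys), col = col, border = NA)
  invisible(d)
}
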