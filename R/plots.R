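## Rendering of FU matrices and causal network diagrams (base graphics).

#' Heat map of an FU matrix or correlation grid
#'
#' @param m square matrix (`fu_matrix` or a Pearson r grid).
#' @param main plot title.
#' @param ... forwarded to [graphics::image()].
#' @return invisibly, the matrix.
#' @export
plot_fu_matrix <- function(m, main = "FU counts per second", ...) {
  n <- nrow(m)
  pal <- grDevices::hcl.colors(64, "YlOrRd", rev = TRUE)
  graphics::image(seq_len(n), seq_len(n), t(unclass(m))[, n:1, drop = FALSE],
                  col = pal, axes = FALSE, xlab = "source at t+1",
                  ylab = "source at t", main = main, ...)
  nm <- rownames(m) %||% as.character(seq_len(n))
  graphics::axis(1, at = seq_len(n), labels = nm, las = 2, cex.axis = 0.5)
  graphics::axis(2, at = seq_len(n), labels = rev(nm), las = 2, cex.axis = 0.5)
  graphics::box()
  invisible(m)
}

#' Draw a causal network diagram
#'
#' Sources are placed on a circle; uni-directional edges are drawn as
#' arrows, bi-directional ones as double-headed arrows; positive
#' correlations in red, negative in blue.
#'
#' @param edges a [build_cnd()] result.
#' @param sources source labels giving the node order; defaults to the
#'   labels occurring in the edge set.
#' @param main plot title.
#' @return invisibly, the edge set.
#' @export
plot_cnd <- function(edges, sources = NULL, main = "Causal network diagram") {
  if (is.null(sources)) {
    sources <- sort(unique(c(edges$from, edges$to)))
  }
  n <- length(sources)
  th <- seq(0, 2 * pi, length.out = n + 1)[-1]
  xs <- cos(th); ys <- sin(th)
  graphics::plot(xs, ys, pch = 19, cex = 0.6, axes = FALSE, xlab = "",
                 ylab = "", main = main, xlim = c(-1.3, 1.3),
                 ylim = c(-1.3, 1.3), asp = 1)
  graphics::text(1.15 * xs, 1.15 * ys, sources, cex = 0.6)
  for (k in seq_len(nrow(edges))) {
    i <- match(edges$from[k], sources); j <- match(edges$to[k], sources)
    if (is.na(i) || is.na(j)) next
    col <- if (edges$sign[k] == "+") "firebrick" else "steelblue"
    code <- if (edges$directionality[k] == "bi") 3 else 2
    graphics::arrows(xs[i], ys[i], xs[j], ys[j], col = col, length = 0.08,
                     code = code, lwd = 1.2)
  }
  invisible(edges)
}
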