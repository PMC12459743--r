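#' Render a directed connectivity graph as SVG
#'
#' Draws one node per cluster at its (projected) centroid and a directed
#' arrow per non-zero off-diagonal connection. Arrow thickness is
#' proportional to the connectivity value; the printed label is the value
#' multiplied by 100 and rounded to two decimals, following the convention
#' of scaling small connectivity values for readability. Arrows are solid
#' where the significance mask is TRUE and dashed otherwise. Output is a
#' pure function of the inputs: rendering twice gives byte-identical files.
#'
#' @param nodes data frame with columns `label`, `x`, `y` (mm or arbitrary
#'   units), one row per node, in matrix order.
#' @param values M x M non-negative matrix, entry `[j, i]` = connection
#'   i -> j.
#' @param mask optional M x M logical matrix (same orientation); TRUE =
#'   drawn solid. Default: all dashed.
#' @param out_path output file path (`.svg`).
#' @param title optional figure title.
#' @param color stroke color for the arrows (default steel blue).
#' @param value_scale factor applied to values for the printed labels
#'   (default 100).
#' @return invisibly, `out_path`.
#' @export
render_connectivity_graph <- function(nodes, values, mask = NULL, out_path,
                                      title = "", color = "#3465a4",
                                      value_scale = 100) {
  M <- nrow(values)
  stopifnot(is.data.frame(nodes), nrow(nodes) == M, ncol(values) == M,
            all(c("label", "x", "y") %in% names(nodes)))
  if (is.null(mask)) mask <- matrix(FALSE, M, M)
  if (!all(dim(mask) == c(M, M))) stop("mask size does not match values")

  W <- 640; Hh <- 640; margin <- 90; r_node <- 26
  rng <- function(v) if (diff(range(v)) < 1e-9) c(v[1] - 1, v[1] + 1) else range(v)
  rx <- rng(nodes$x); ry <- rng(nodes$y)
  px <- margin + (nodes$x - rx[1]) / (rx[2] - rx[1]) * (W - 2 * margin)
  py <- Hh - margin - (nodes$y - ry[1]) / (ry[2] - ry[1]) * (Hh - 2 * margin)

  fmt <- function(z) sprintf("%.2f", z)
  lines <- c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    sprintf('<svg xmlns="http://www.w3.org/2000/svg" width="%d" height="%d" viewBox="0 0 %d %d">',
            W, Hh, W, Hh),
    sprintf('<rect width="%d" height="%d" fill="white"/>', W, Hh))
  if (nzchar(title))
    lines <- c(lines, sprintf(
      '<text x="%s" y="30" font-family="sans-serif" font-size="18" text-anchor="middle">%s</text>',
      fmt(W / 2), title))

  vmax <- max(values[row(values) != col(values)], 0)
  for (j in seq_len(M)) for (i in seq_len(M)) {
    if (i == j || values[j, i] <= 0) next
    dx <- px[j] - px[i]; dy <- py[j] - py[i]
    len <- sqrt(dx^2 + dy^2); if (len < 1e-9) next
    ux <- dx / len; uy <- dy / len
    ox <- -uy * 9; oy <- ux * 9                 # perpendicular offset
    x1 <- px[i] + ux * r_node + ox; y1 <- py[i] + uy * r_node + oy
    x2 <- px[j] - ux * (r_node + 12) + ox; y2 <- py[j] - uy * (r_node + 12) + oy
    wdt <- 1 + 5 * values[j, i] / max(vmax, 1e-12)
    dash <- if (isTRUE(mask[j, i])) '' else ' stroke-dasharray="7,5"'
    lines <- c(lines, sprintf(
      '<line x1="%s" y1="%s" x2="%s" y2="%s" stroke="%s" stroke-width="%s"%s/>',
      fmt(x1), fmt(y1), fmt(x2), fmt(y2), color, fmt(wdt), dash))
    ah <- 6 + 1.5 * wdt                          # arrowhead scales with width
    hx <- x2 + ux * 10; hy <- y2 + uy * 10
    lines <- c(lines, sprintf(
      '<polygon points="%s,%s %s,%s %s,%s" fill="%s"/>',
      fmt(hx), fmt(hy),
      fmt(hx - ux * ah - uy * ah * 0.6), fmt(hy - uy * ah + ux * ah * 0.6),
      fmt(hx - ux * ah + uy * ah * 0.6), fmt(hy - uy * ah - ux * ah * 0.6),
      color))
    mx <- (x1 + x2) / 2 + ox * 1.4; my <- (y1 + y2) / 2 + oy * 1.4
    lines <- c(lines, sprintf(
      '<text x="%s" y="%s" font-family="sans-serif" font-size="13" text-anchor="middle">%s</text>',
      fmt(mx), fmt(my), fmt(values[j, i] * value_scale)))
  }

  for (k in seq_len(M)) {
    lines <- c(lines, sprintf(
      '<circle cx="%s" cy="%s" r="%d" fill="#f4f4f4" stroke="black" stroke-width="1.5"/>',
      fmt(px[k]), fmt(py[k]), r_node))
    lines <- c(lines, sprintf(
      '<text x="%s" y="%s" font-family="sans-serif" font-size="13" text-anchor="middle">%s</text>',
      fmt(px[k]), fmt(py[k] + 4), nodes$label[k]))
  }
  lines <- c(lines, '</svg>')
  writeLines(lines, out_path)
  invisible(out_path)
}
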