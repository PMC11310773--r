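# Parametric microplot grids: rotated rectangular plots, numbering schemes,
# margin trimming. Geometry is kept in world coordinates (m, projected CRS).

#' Specify a rectangular microplot grid
#'
#' The headless equivalent of drawing a plot grid on screen: a rotated
#' lattice of identical rectangles anchored at a world coordinate.
#' In the grid's local frame, plot (r, c) has its lower-left corner at
#' (c * (plot_width + col_gap), r * (plot_length + row_gap)); the layout is
#' then rotated by `angle` about the anchor and translated to it.
#'
#' @param anchor_x,anchor_y world coordinates (m) of the first plot's corner.
#' @param angle grid rotation, degrees counterclockwise from east.
#' @param plot_length,plot_width plot dimensions (m), length along the
#'   local y axis.
#' @param n_rows,n_cols number of plot rows/columns.
#' @param row_gap,col_gap spacing between adjacent plots (m).
#' @param numbering one of `"row_major"`, `"column_major"`,
#'   `"serpentine_rows"`.
#' @param start_number first plot id.
#' @return a `grid_spec`.
#' @export
grid_spec <- function(anchor_x, anchor_y, angle = 0, plot_length, plot_width,
                      n_rows = 1L, n_cols = 1L, row_gap = 0, col_gap = 0,
                      numbering = c("row_major", "column_major",
                                    "serpentine_rows"),
                      start_number = 1L) {
  numbering <- match.arg(numbering)
  if (plot_length <= 0 || plot_width <= 0) {
    stop_plotpheno("bad_spec", "plot dimensions must be positive")
  }
  if (n_rows < 1L || n_cols < 1L) {
    stop_plotpheno("bad_spec", "plot counts must be at least 1")
  }
  if (row_gap < 0 || col_gap < 0) {
    stop_plotpheno("bad_spec", "gaps must be non-negative")
  }
  structure(list(anchor_x = anchor_x, anchor_y = anchor_y,
                 angle = angle %% 360, plot_length = plot_length,
                 plot_width = plot_width, n_rows = as.integer(n_rows),
                 n_cols = as.integer(n_cols), row_gap = row_gap,
                 col_gap = col_gap, numbering = numbering,
                 start_number = as.integer(start_number)),
            class = "grid_spec")
}

#' Construct a microplot
#'
#' @param plot_id integer plot id, unique within a set.
#' @param polygon 4-vertex ring of world coordinates (m); the closing
#'   vertex may be omitted.
#' @param row,col optional 0-based grid position (set by
#'   [generate_grid()]; needed by [renumber()]).
#' @return a `microplot`.
#' @export
microplot <- function(plot_id, polygon, row = NA_integer_, col = NA_integer_) {
  polygon <- as.matrix(polygon)
  colnames(polygon) <- c("x", "y")
  structure(list(plot_id = as.integer(plot_id),
                 polygon = polygon,
                 row = as.integer(row), col = as.integer(col)),
            class = "microplot")
}

plot_ids <- function(spec) {
  # id for grid position (r, c), 0-based, per the numbering scheme
  r <- rep(seq_len(spec$n_rows) - 1L, each = spec$n_cols)
  c <- rep(seq_len(spec$n_cols) - 1L, times = spec$n_rows)
  ord <- switch(spec$numbering,
    row_major = r * spec$n_cols + c,
    column_major = c * spec$n_rows + r,
    serpentine_rows = r * spec$n_cols +
      ifelse(r %% 2L == 0L, c, spec$n_cols - 1L - c))
  matrix(spec$start_number + ord, nrow = spec$n_rows, byrow = TRUE)
}

rotate_about <- function(xy, angle_deg, cx = 0, cy = 0) {
  th <- angle_deg * pi / 180
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2L)
  sweep(sweep(xy, 2L, c(cx, cy)) %*% t(R), 2L, c(cx, cy), `+`)
}

#' Generate the microplot polygons of a grid specification
#'
#' @param spec a `grid_spec`.
#' @return a list of `microplot` objects (length `n_rows * n_cols`).
#' @export
generate_grid <- function(spec) {
  stopifnot(inherits(spec, "grid_spec"))
  ids <- plot_ids(spec)
  plots <- vector("list", spec$n_rows * spec$n_cols)
  k <- 1L
  for (r in seq_len(spec$n_rows) - 1L) {
    for (c in seq_len(spec$n_cols) - 1L) {
      x0 <- c * (spec$plot_width + spec$col_gap)
      y0 <- r * (spec$plot_length + spec$row_gap)
      corners <- cbind(
        x = x0 + c(0, spec$plot_width, spec$plot_width, 0),
        y = y0 + c(0, 0, spec$plot_length, spec$plot_length))
      world <- rotate_about(corners, spec$angle)
      world[, 1L] <- world[, 1L] + spec$anchor_x
      world[, 2L] <- world[, 2L] + spec$anchor_y
      plots[[k]] <- microplot(ids[r + 1L, c + 1L], world, row = r, col = c)
      k <- k + 1L
    }
  }
  plots[order(vapply(plots, function(p) p$plot_id, 1L))]
}

#' Reassign plot ids under a numbering scheme
#'
#' Geometry is untouched; ids are recomputed from each plot's grid position.
#'
#' @param plots list of `microplot`s generated from a grid (they carry their
#'   row/column position).
#' @param numbering numbering scheme (see [grid_spec()]).
#' @param start_number first id.
#' @return the plots with new ids, sorted by id.
#' @export
renumber <- function(plots, numbering = c("row_major", "column_major",
                                          "serpentine_rows"),
                     start_number = 1L) {
  numbering <- match.arg(numbering)
  rows <- vapply(plots, function(p) p$row, 1L)
  cols <- vapply(plots, function(p) p$col, 1L)
  if (anyNA(rows) || anyNA(cols)) {
    stop_plotpheno("bad_plots", "plots lack grid positions; cannot renumber")
  }
  n_rows <- max(rows) + 1L
  n_cols <- max(cols) + 1L
  ord <- switch(numbering,
    row_major = rows * n_cols + cols,
    column_major = cols * n_rows + rows,
    serpentine_rows = rows * n_cols +
      ifelse(rows %% 2L == 0L, cols, n_cols - 1L - cols))
  out <- Map(function(p, id) { p$plot_id <- as.integer(id); p },
             plots, start_number + ord)
  out[order(start_number + ord)]
}

plot_center <- function(plot) colMeans(plot$polygon[1:4, , drop = FALSE])

#' Shrink a plot concentrically
#'
#' Returns a rectangle with the selected dimension(s) scaled by
#' `1 - fraction`, keeping the center and orientation. `fraction` is the
#' total proportion removed (split equally between the two sides), e.g.
#' trimming 20% off the width turns a 9 x 1.2 m plot into 9 x 0.96 m.
#' Used to drop plot edges compacted by machinery wheels.
#'
#' @param plot a `microplot`.
#' @param fraction proportion removed, in `[0, 1)`.
#' @param side which dimension to trim: `"width"` (the default; the first
#'   polygon edge), `"length"`, or `"both"`.
#' @return the trimmed `microplot`.
#' @export
trim_margin <- function(plot, fraction, side = c("width", "length", "both")) {
  side <- match.arg(side)
  if (!is.finite(fraction) || fraction < 0 || fraction >= 1) {
    stop_plotpheno("bad_fraction", "trim fraction must be in [0, 1)")
  }
  if (fraction == 0) return(plot)
  ctr <- plot_center(plot)
  p <- plot$polygon[1:4, , drop = FALSE]
  # local axes from the rectangle's edges: u along width (v1->v2), v along
  # length (v2->v3)
  u <- p[2L, ] - p[1L, ]
  v <- p[3L, ] - p[2L, ]
  su <- if (side %in% c("width", "both")) 1 - fraction else 1
  sv <- if (side %in% c("length", "both")) 1 - fraction else 1
  lu <- sqrt(sum(u^2)); lv <- sqrt(sum(v^2))
  uh <- u / lu; vh <- v / lv
  du <- sweep(p, 2L, ctr) %*% uh   # signed coords along u about the center
  dv <- sweep(p, 2L, ctr) %*% vh
  newp <- cbind(ctr[1L] + su * du * uh[1L] + sv * dv * vh[1L],
                ctr[2L] + su * du * uh[2L] + sv * dv * vh[2L])
  colnames(newp) <- c("x", "y")
  microplot(plot$plot_id, newp, plot$row, plot$col)
}
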