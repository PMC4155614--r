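#' Node grid for the diagram
#'
#' Positions are laid out left to right at `column_spacing` intervals; residue
#' rows run top to bottom in the scheme's total order, `row_spacing` apart
#' within a functional group and `row_spacing + group_gap` across group
#' boundaries, so the grouping is visible as horizontal bands. Deterministic:
#' the same scheme, column count and geometry always give the same grid.
#'
#' @param scheme An [alphabet_scheme()].
#' @param n_columns Number of alignment columns (>= 2).
#' @param config A [diagram_config()] (only the geometry fields are used).
#' @return A list with `x` (numeric vector, one per column) and `rows` (data
#'   frame with `residue`, `group`, `y`).
#' @export
compute_grid <- function(scheme, n_columns, config = diagram_config()) {
  stopifnot(inherits(scheme, "alphabet_scheme"),
            inherits(config, "diagram_config"))
  if (n_columns < 2) {
    sdd_error("a diagram needs at least 2 columns", "sdd_invalid_alignment")
  }
  rows <- scheme_rows(scheme)
  step <- c(0, ifelse(rows$group[-1] == rows$group[-nrow(rows)],
                      config$row_spacing,
                      config$row_spacing + config$group_gap))
  rows$y <- cumsum(step)
  list(
    x = stats::setNames((seq_len(n_columns) - 1) * config$column_spacing,
                        seq_len(n_columns)),
    rows = rows
  )
}

#' Ribbon geometry from filtered transition tables
#'
#' Turns each surviving (group, i, a, b) pair into one ribbon: a cubic
#' S-curve with horizontal tangents from node (i, a) to node (i+1, b), with
#' stroke width `max_ribbon_weight * pair frequency` constant along the whole
#' path (the Sankey convention — constant line width between axes avoids the
#' line-width illusion of tapered bands). Ribbons touching a masked position
#' are suppressed. Draw order is group-major (the order of `tables`), then
#' ascending weight within a group, so each sample's dominant flows are drawn
#' on top of its minor ones.
#'
#' @param tables Named list of (typically filtered) `transition_table`s, one
#'   per sample, in the intended drawing order.
#' @param grid A [compute_grid()] result covering every residue in `tables`.
#' @param config A [diagram_config()].
#' @param colors Named colors per group label; `NULL` uses the config colors
#'   or the default palette.
#' @return An object of class `diagram_layout`: list with `nodes` (the grid),
#'   `ribbons` (data frame: `group`, `column`, `from`, `to`, `count`, `freq`,
#'   `weight`, `x0`, `y0`, `x1`, `y1`, `cx`, `color`), `extents`
#'   (xmin/xmax/ymin/ymax), `position_labels`, `masked`, `n_columns`.
#' @export
compute_ribbons <- function(tables, grid, config = diagram_config(),
                            colors = NULL) {
  stopifnot(is.list(tables), length(tables) > 0,
            all(vapply(tables, inherits, logical(1), "transition_table")))
  labels <- vapply(tables, `[[`, character(1), "label")
  names(tables) <- labels
  ncols <- vapply(tables, `[[`, integer(1), "n_columns")
  if (length(unique(ncols)) != 1) {
    sdd_error("incompatible alignments: transition tables differ in column count",
              "sdd_incompatible_alignments")
  }
  n_columns <- ncols[1]
  if (n_columns != length(grid$x)) {
    sdd_error("grid does not match the tables' column count",
              "sdd_incompatible_alignments")
  }
  if (is.null(colors)) {
    colors <- config$group_colors %||%
      stats::setNames(default_group_colors(length(tables)), labels)
  }
  if (is.null(names(colors))) names(colors) <- labels

  y_of <- stats::setNames(grid$rows$y, grid$rows$residue)
  masked <- config$masked_positions

  per_group <- lapply(labels, function(lab) {
    p <- tables[[lab]]$pairs
    if (nrow(p) == 0) return(NULL)
    drop <- p$column %in% masked | (p$column + 1L) %in% masked
    p <- p[!drop, , drop = FALSE]
    if (nrow(p) == 0) return(NULL)
    unmapped <- setdiff(unique(c(p$from, p$to)), names(y_of))
    if (length(unmapped) > 0) {
      sdd_error(sprintf("unmapped residue(s) not in scheme: %s",
                        paste(unmapped, collapse = ", ")),
                "sdd_bad_config")
    }
    p <- p[order(p$freq, p$column, p$from, p$to), , drop = FALSE]
    data.frame(
      group = lab, p,
      weight = config$max_ribbon_weight * p$freq,
      x0 = unname(grid$x[p$column]),
      y0 = unname(y_of[p$from]),
      x1 = unname(grid$x[p$column + 1L]),
      y1 = unname(y_of[p$to]),
      cx = unname((grid$x[p$column] + grid$x[p$column + 1L]) / 2),
      color = unname(colors[lab]),
      stringsAsFactors = FALSE
    )
  })
  ribbons <- do.call(rbind, per_group) %||%
    data.frame(group = character(), column = integer(), from = character(),
               to = character(), count = integer(), freq = numeric(),
               weight = numeric(), x0 = numeric(), y0 = numeric(),
               x1 = numeric(), y1 = numeric(), cx = numeric(),
               color = character())
  rownames(ribbons) <- NULL
  structure(
    list(
      nodes = grid,
      ribbons = ribbons,
      extents = c(xmin = 0, xmax = max(grid$x),
                  ymin = 0, ymax = max(grid$rows$y)),
      position_labels = stats::setNames(seq_len(n_columns), seq_len(n_columns)),
      masked = masked,
      n_columns = n_columns,
      group_labels = labels,
      group_colors = colors[labels]
    ),
    class = "diagram_layout"
  )
}

#' @export
print.diagram_layout <- function(x, ...) {
  cat(sprintf("<diagram_layout: %d ribbons, %d groups, %d columns x %d rows>\n",
              nrow(x$ribbons), length(x$group_labels), x$n_columns,
              nrow(x$nodes$rows)))
  invisible(x)
}
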