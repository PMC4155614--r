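# SVG serialization and PNG/PDF export.
#
# The SVG is assembled as plain text with fixed-precision coordinates and no
# timestamps, so identical inputs give byte-identical output. One <path> of
# class "ribbon" per layout ribbon; residue and group labels on the left;
# 1-based position labels along the top, kept even for masked positions.

SVG_MARGIN_LEFT <- 70
SVG_MARGIN_TOP <- 40
SVG_MARGIN_RIGHT <- 25
SVG_MARGIN_BOTTOM <- 20
SVG_FONT <- "Helvetica"

num <- function(x) sub("\\.?0+$", "", sprintf("%.3f", x))

# "#RRGGBB" or "#RRGGBBAA" -> list(hex = "#RRGGBB", alpha = fraction)
split_rgba <- function(color) {
  if (!grepl("^#[0-9A-Fa-f]{6}([0-9A-Fa-f]{2})?$", color)) {
    sdd_error(sprintf("invalid color '%s' (use #RRGGBB or #RRGGBBAA)", color),
              "sdd_bad_config")
  }
  if (nchar(color) == 9) {
    list(hex = substr(color, 1, 7),
         alpha = strtoi(substr(color, 8, 9), 16L) / 255)
  } else {
    list(hex = color, alpha = 1)
  }
}

#' Render a diagram layout to SVG
#'
#' Serializes a [compute_ribbons()] layout to an SVG 1.1 document. Each ribbon
#' is one `<path>` element stroked in its sample's color with the color's
#' alpha as `stroke-opacity`, so overlapping ribbons of different samples
#' blend optically in the viewer (semi-transparent red over blue reads as
#' purple). Rendering is pure: the same layout and config always produce
#' byte-identical text.
#'
#' @param layout A [compute_ribbons()] result with at least one ribbon.
#' @param scheme The [alphabet_scheme()] the layout was built from (optional;
#'   row and group placement is already resolved in the layout).
#' @param config A [diagram_config()].
#' @return The SVG document as a single character string.
#' @export
render_svg <- function(layout, scheme = NULL, config = diagram_config()) {
  stopifnot(inherits(layout, "diagram_layout"))
  if (nrow(layout$ribbons) == 0) {
    sdd_error("nothing to draw: no ribbons survive filtering/masking",
              "sdd_invalid_alignment")
  }
  ox <- SVG_MARGIN_LEFT
  oy <- SVG_MARGIN_TOP
  width <- layout$extents[["xmax"]] + ox + SVG_MARGIN_RIGHT
  height <- layout$extents[["ymax"]] + oy + SVG_MARGIN_BOTTOM +
    20 * length(layout$group_labels)

  out <- c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    sprintf('<svg xmlns="http://www.w3.org/2000/svg" version="1.1" width="%s" height="%s" viewBox="0 0 %s %s">',
            num(width), num(height), num(width), num(height)),
    sprintf('<desc>Sequence Diversity Diagram: %s</desc>',
            paste(layout$group_labels, collapse = " vs "))
  )

  # position labels (1-based), retained for masked positions
  for (i in seq_len(layout$n_columns)) {
    out <- c(out, sprintf(
      '<text class="poslabel" x="%s" y="%s" font-family="%s" font-size="9" text-anchor="middle">%d</text>',
      num(ox + layout$nodes$x[i]), num(oy - 14), SVG_FONT, i))
  }

  # residue row labels and group labels
  rows <- layout$nodes$rows
  for (r in seq_len(nrow(rows))) {
    out <- c(out, sprintf(
      '<text class="rowlabel" x="%s" y="%s" font-family="%s" font-size="9" text-anchor="end">%s</text>',
      num(ox - 10), num(oy + rows$y[r] + 3), SVG_FONT, rows$residue[r]))
  }
  for (g in unique(rows$group)) {
    yg <- mean(rows$y[rows$group == g])
    out <- c(out, sprintf(
      '<text class="grouplabel" x="%s" y="%s" font-family="%s" font-size="8" text-anchor="end" transform="rotate(-90 %s %s)">%s</text>',
      num(ox - 45), num(oy + yg + 2), SVG_FONT,
      num(ox - 45), num(oy + yg + 2), g))
  }

  # ribbons: cubic S-curves with horizontal tangents, constant stroke width
  rb <- layout$ribbons
  for (k in seq_len(nrow(rb))) {
    col <- split_rgba(rb$color[k])
    out <- c(out, sprintf(
      '<path class="ribbon" data-group="%s" data-column="%d" data-from="%s" data-to="%s" d="M %s %s C %s %s %s %s %s %s" fill="none" stroke="%s" stroke-opacity="%s" stroke-width="%s" stroke-linecap="butt"/>',
      rb$group[k], rb$column[k], rb$from[k], rb$to[k],
      num(ox + rb$x0[k]), num(oy + rb$y0[k]),
      num(ox + rb$cx[k]), num(oy + rb$y0[k]),
      num(ox + rb$cx[k]), num(oy + rb$y1[k]),
      num(ox + rb$x1[k]), num(oy + rb$y1[k]),
      col$hex, num(col$alpha), num(rb$weight[k])))
  }

  # sample legend below the grid
  ly <- oy + layout$extents[["ymax"]] + SVG_MARGIN_BOTTOM
  for (j in seq_along(layout$group_labels)) {
    col <- split_rgba(layout$group_colors[j])
    out <- c(out, sprintf(
      '<rect class="legend" x="%s" y="%s" width="18" height="8" fill="%s" fill-opacity="%s"/>',
      num(ox), num(ly + 20 * (j - 1)), col$hex, num(col$alpha)))
    out <- c(out, sprintf(
      '<text class="legendlabel" x="%s" y="%s" font-family="%s" font-size="10">%s</text>',
      num(ox + 24), num(ly + 20 * (j - 1) + 8), SVG_FONT,
      layout$group_labels[j]))
  }

  paste0(paste(out, collapse = "\n"), "\n</svg>\n")
}

# Evaluate the ribbon cubic Bezier (horizontal tangents) at parameter t.
bezier_xy <- function(x0, y0, cx, x1, y1, t) {
  mt <- 1 - t
  list(
    x = mt^3 * x0 + 3 * mt^2 * t * cx + 3 * mt * t^2 * cx + t^3 * x1,
    y = mt^3 * y0 + 3 * mt^2 * t * y0 + 3 * mt * t^2 * y1 + t^3 * y1
  )
}

# Draw a layout on the current graphics device (used by plot.seqdiv and by
# the PNG/PDF export, which share the SVG's geometry source).
draw_layout <- function(layout, main = NULL) {
  stopifnot(inherits(layout, "diagram_layout"))
  if (nrow(layout$ribbons) == 0) {
    sdd_error("nothing to draw: no ribbons survive filtering/masking",
              "sdd_invalid_alignment")
  }
  rows <- layout$nodes$rows
  op <- graphics::par(mar = c(1, 5, 3, 1))
  on.exit(graphics::par(op))
  graphics::plot.new()
  graphics::plot.window(
    xlim = c(-10, layout$extents[["xmax"]] + 10),
    ylim = c(layout$extents[["ymax"]] + 30, -10)  # y grows downward
  )
  graphics::axis(3, at = layout$nodes$x, labels = names(layout$nodes$x),
                 cex.axis = 0.6, lwd = 0, lwd.ticks = 0.5, padj = 1)
  graphics::axis(2, at = rows$y, labels = rows$residue, las = 2,
                 cex.axis = 0.6, lwd = 0)
  t <- seq(0, 1, length.out = 41)
  rb <- layout$ribbons
  for (k in seq_len(nrow(rb))) {
    col <- split_rgba(rb$color[k])
    pts <- bezier_xy(rb$x0[k], rb$y0[k], rb$cx[k], rb$x1[k], rb$y1[k], t)
    graphics::lines(pts$x, pts$y,
                    col = grDevices::adjustcolor(col$hex, alpha.f = col$alpha),
                    lwd = max(rb$weight[k], 0.1), lend = 1)
  }
  graphics::legend(
    "bottomleft",
    legend = layout$group_labels,
    col = vapply(layout$group_colors, function(co) {
      s <- split_rgba(co)
      grDevices::adjustcolor(s$hex, alpha.f = s$alpha)
    }, character(1)),
    lwd = 4, bty = "n", cex = 0.7
  )
  if (!is.null(main)) graphics::title(main = main)
  invisible(layout)
}

#' Export a diagram to SVG, PNG or PDF
#'
#' SVG output writes the [render_svg()] document verbatim (the source of
#' truth). PNG and PDF draw the identical layout geometry through the
#' corresponding graphics device; PNG pixel dimensions are the figure extents
#' scaled by `dpi` (the SVG's abstract units are points, 72 per inch).
#'
#' @param layout A [compute_ribbons()] result (or a [seqdiv()] object, whose
#'   layout is used).
#' @param path Output file path.
#' @param format `"svg"`, `"png"` or `"pdf"`; default from the file extension.
#' @param scheme,config Passed to [render_svg()] for SVG output.
#' @param dpi Raster resolution for PNG. Default 96.
#' @return `path`, invisibly.
#' @export
export_diagram <- function(layout, path, format = NULL,
                           scheme = NULL, config = diagram_config(),
                           dpi = 96) {
  if (inherits(layout, "seqdiv")) {
    scheme <- scheme %||% layout$scheme
    config <- layout$config
    layout <- layout$layout
  }
  stopifnot(inherits(layout, "diagram_layout"))
  format <- tolower(format %||% tools::file_ext(path))
  if (!format %in% c("svg", "png", "pdf")) {
    sdd_error(sprintf("unknown output format '%s' (use svg, png or pdf)",
                      format), "sdd_bad_config")
  }
  w_units <- layout$extents[["xmax"]] + SVG_MARGIN_LEFT + SVG_MARGIN_RIGHT
  h_units <- layout$extents[["ymax"]] + SVG_MARGIN_TOP + SVG_MARGIN_BOTTOM +
    20 * length(layout$group_labels)
  if (format == "svg") {
    svg <- render_svg(layout, scheme, config)
    con <- file(path, open = "wb")
    on.exit(close(con))
    writeBin(charToRaw(svg), con)
  } else if (format == "png") {
    grDevices::png(path, width = w_units / 72 * dpi, height = h_units / 72 * dpi,
                   res = dpi, type = "cairo")
    on.exit(grDevices::dev.off())
    draw_layout(layout)
  } else {
    grDevices::pdf(path, width = w_units / 72, height = h_units / 72)
    on.exit(grDevices::dev.off())
    draw_layout(layout)
  }
  invisible(path)
}
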