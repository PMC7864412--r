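#' @title Static excess-mortality figures
#' @name plotting
#' @description Renders the target-year curve against its reference level
#'   with shaded excess/deficit polygons and an optional light-gray overlay
#'   of all other years, to PNG (raster) or SVG (deterministic vector).
NULL

.palettes <- list(
  classic = list(excess = "#D7301F", deficit = "#2B8CBE", observed = "#000000",
                 reference = "#636363", other = "#D9D9D9"),
  viridis = list(excess = "#FDE725", deficit = "#440154", observed = "#21908C",
                 reference = "#3B528B", other = "#DDDDDD")
)

.figure_palette <- function(palette) {
  if (is.list(palette)) return(palette)
  if (!palette %in% names(.palettes)) {
    stop_validation("unknown palette '%s'; available: %s", palette,
                    paste(names(.palettes), collapse = ", "))
  }
  .palettes[[palette]]
}

# Everything both backends need: ranges, curves, polygon outlines, legend.
.figure_geometry <- function(result, show_other_years) {
  series <- result$series
  other <- NULL
  if (isTRUE(show_other_years)) {
    yrs <- setdiff(series$years, result$target_year)
    if (length(yrs)) {
      other <- lapply(yrs, function(y) {
        v <- .series_year(series, y)
        list(year = y, week = as.integer(names(v)), value = as.numeric(v))
      })
    }
  }
  xs <- result$weeks
  ys <- c(result$observed, result$reference)
  for (o in other) { xs <- c(xs, o$week); ys <- c(ys, o$value) }
  polys <- list()
  if (nrow(result$polygons)) {
    for (p in seq_len(nrow(result$polygons))) {
      run <- result$weeks >= result$polygons$start_week[p] &
             result$weeks <= result$polygons$end_week[p]
      polys[[p]] <- list(
        sign = result$polygons$sign[p],
        x = c(result$weeks[run], rev(result$weeks[run])),
        y = c(result$observed[run], rev(result$reference[run]))
      )
    }
  }
  list(
    xlim = range(xs), ylim = range(ys), other = other, polygons = polys,
    legend = sprintf("Target %d vs %s (reference %d-%d)",
                     result$target_year, gsub("_", " ", result$method),
                     min(result$period), max(result$period)),
    ylab = sprintf("%s (%s)", result$measure,
                   if (result$measure_kind == "count") "weekly deaths"
                   else "deaths per person-week")
  )
}

#' Plot an excess-mortality fit
#'
#' @param x an \code{excess_mort}.
#' @param show_other_years overlay all non-target years in light gray.
#' @param palette palette name (\code{"classic"}, \code{"viridis"}) or a
#'   named list of colors.
#' @param ... passed to \code{plot.default}.
#' @return \code{x}, invisibly.
#' @export
plot.excess_mort <- function(x, show_other_years = FALSE, palette = "classic", ...) {
  pal <- .figure_palette(palette)
  g <- .figure_geometry(x, show_other_years)
  graphics::plot(NA, xlim = g$xlim, ylim = g$ylim, xlab = "Week", ylab = g$ylab,
                 main = g$legend, ...)
  for (o in g$other) graphics::lines(o$week, o$value, col = pal$other)
  for (p in g$polygons) {
    graphics::polygon(p$x, p$y, border = NA,
                      col = grDevices::adjustcolor(
                        if (p$sign == "excess") pal$excess else pal$deficit, 0.5))
  }
  graphics::lines(x$weeks, x$reference, col = pal$reference, lty = 2, lwd = 2)
  graphics::lines(x$weeks, x$observed, col = pal$observed, lwd = 2)
  graphics::legend("topright", bty = "n", lwd = 2, lty = c(1, 2),
                   col = c(pal$observed, pal$reference),
                   legend = c(sprintf("observed %d", x$target_year), "reference"))
  invisible(x)
}

# Minimal deterministic SVG emitter; shaded regions carry the CSS classes
# "polygon excess" / "polygon deficit" so they can be counted downstream.
.render_svg <- function(result, show_other_years, pal, out_path,
                        width, height) {
  g <- .figure_geometry(result, show_other_years)
  mar <- c(left = 70, right = 20, top = 40, bottom = 45)
  pw <- width - mar["left"] - mar["right"]
  ph <- height - mar["top"] - mar["bottom"]
  pad <- function(r) if (diff(r) == 0) r + c(-1, 1) else r + c(-1, 1) * 0.04 * diff(r)
  xr <- pad(g$xlim); yr <- pad(g$ylim)
  sx <- function(w) mar["left"] + (w - xr[1]) / diff(xr) * pw
  sy <- function(v) mar["top"] + (yr[2] - v) / diff(yr) * ph
  pts <- function(xs, ys) paste(sprintf("%.2f,%.2f", sx(xs), sy(ys)), collapse = " ")
  out <- c(
    sprintf('<svg xmlns="http://www.w3.org/2000/svg" width="%d" height="%d" viewBox="0 0 %d %d">',
            width, height, width, height),
    sprintf('<rect width="%d" height="%d" fill="#FFFFFF"/>', width, height)
  )
  for (o in g$other) {
    out <- c(out, sprintf('<polyline class="other-year" points="%s" fill="none" stroke="%s" stroke-width="1"/>',
                          pts(o$week, o$value), pal$other))
  }
  for (p in g$polygons) {
    out <- c(out, sprintf('<path class="polygon %s" d="M %s Z" fill="%s" fill-opacity="0.5" stroke="none"/>',
                          p$sign,
                          paste(sprintf("%.2f %.2f", sx(p$x), sy(p$y)), collapse = " L "),
                          if (p$sign == "excess") pal$excess else pal$deficit))
  }
  out <- c(out,
    sprintf('<polyline class="reference" points="%s" fill="none" stroke="%s" stroke-width="2" stroke-dasharray="6,4"/>',
            pts(result$weeks, result$reference), pal$reference),
    sprintf('<polyline class="observed" points="%s" fill="none" stroke="%s" stroke-width="2"/>',
            pts(result$weeks, result$observed), pal$observed))
  # axes
  out <- c(out, sprintf('<line x1="%.2f" y1="%.2f" x2="%.2f" y2="%.2f" stroke="#000000"/>',
                        mar["left"], mar["top"] + ph, mar["left"] + pw, mar["top"] + ph),
           sprintf('<line x1="%.2f" y1="%.2f" x2="%.2f" y2="%.2f" stroke="#000000"/>',
                   mar["left"], mar["top"], mar["left"], mar["top"] + ph))
  for (t in pretty(xr, 8)) {
    if (t < xr[1] || t > xr[2]) next
    out <- c(out, sprintf('<text class="tick" x="%.2f" y="%.2f" font-size="11" text-anchor="middle">%s</text>',
                          sx(t), mar["top"] + ph + 16, format(t)))
  }
  for (t in pretty(yr, 6)) {
    if (t < yr[1] || t > yr[2]) next
    out <- c(out, sprintf('<text class="tick" x="%.2f" y="%.2f" font-size="11" text-anchor="end">%s</text>',
                          mar["left"] - 6, sy(t) + 4, format(t)))
  }
  out <- c(out,
    sprintf('<text class="legend" x="%.2f" y="%.2f" font-size="13" text-anchor="middle">%s</text>',
            mar["left"] + pw / 2, 22, g$legend),
    sprintf('<text class="xlab" x="%.2f" y="%.2f" font-size="12" text-anchor="middle">Week</text>',
            mar["left"] + pw / 2, height - 8),
    sprintf('<text class="ylab" x="14" y="%.2f" font-size="12" text-anchor="middle" transform="rotate(-90 14 %.2f)">%s</text>',
            mar["top"] + ph / 2, mar["top"] + ph / 2, g$ylab),
    '</svg>')
  con <- file(out_path, open = "wb")
  on.exit(close(con))
  writeLines(out, con)
}

#' Render an excess-mortality figure to PNG or SVG
#'
#' The format follows the file extension of \code{out_path}. SVG output is
#' byte-deterministic for fixed inputs and annotates each shaded excess or
#' deficit region with the CSS class \code{"polygon excess"} or
#' \code{"polygon deficit"}.
#'
#' @param result an \code{excess_mort}.
#' @param show_other_years overlay all non-target years in light gray.
#' @param palette palette name or named color list; affects colors only.
#' @param out_path output path ending in \code{.png} or \code{.svg}.
#' @param width,height figure size in pixels.
#' @param dpi raster resolution for PNG output.
#' @return \code{out_path}, invisibly.
#' @export
render_excess_figure <- function(result, show_other_years = FALSE,
                                 palette = "classic", out_path,
                                 width = 800, height = 500, dpi = 96) {
  stopifnot(inherits(result, "excess_mort"))
  if (!nrow(as.data.frame(result))) stop_precondition("result is empty")
  pal <- .figure_palette(palette)
  ext <- tolower(tools::file_ext(out_path))
  if (ext == "svg") {
    .render_svg(result, show_other_years, pal, out_path, width, height)
  } else if (ext == "png") {
    grDevices::png(out_path, width = width, height = height, res = dpi)
    on.exit(grDevices::dev.off())
    plot(result, show_other_years = show_other_years, palette = pal)
  } else {
    stop_validation("unsupported figure extension '.%s' (use .png or .svg)", ext)
  }
  invisible(out_path)
}
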