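# Matrisome composition charts. Each chart is first built as a
# renderer-independent chart_spec (labels, values, geometry hints, fixed
# palette), then rendered to a ggplot and optionally to PDF/PNG. Keeping
# spec and rendering separate makes the chart geometry testable without a
# graphics device and serializable for golden-file comparison.

#' The fixed matrisome chart palette
#'
#' One color per division, per category and for non-matrisome, constant
#' across charts, datasets and species — composition is comparable between
#' figures because a category always has the same hue.
#'
#' @return Named character vector of hex colors.
#' @export
matrisome_palette <- function() {
  c(
    "Core matrisome"           = "#1F5FA8",
    "Matrisome-associated"     = "#E8861A",
    "Non-matrisome"            = "#B3B3B3",
    "ECM Glycoproteins"        = "#13334C",
    "Collagens"                = "#0587BC",
    "Proteoglycans"            = "#59B0DD",
    "ECM-affiliated Proteins"  = "#F4A127",
    "ECM Regulators"           = "#E8671B",
    "Secreted Factors"         = "#C53A28",
    "Non-matrisome (category)" = "#B3B3B3"
  )
}

new_chart_spec <- function(kind, groups, hints = list(), title = "",
                           subtitle = "") {
  pal <- matrisome_palette()
  labs <- if (kind == "matriflow") unique(groups$target) else groups$label
  # labels outside the fixed map (e.g. flow sources) are rendered neutral grey
  palette <- pal[intersect(names(pal), labs)]
  structure(list(kind = kind, groups = groups, palette = palette,
                 title = title, subtitle = subtitle, hints = hints),
            class = "chart_spec")
}

#' Bar chart of matrisome molecule counts (matribar)
#'
#' Two groups of bars — molecule counts per division and per category —
#' summarizing the composition of an annotated dataset.
#'
#' @param summary A `count_summary` from [summary_counts()].
#' @param title Chart title.
#' @return A `chart_spec` of kind `"matribar"`.
#' @export
matribar <- function(summary, title = "Matrisome composition") {
  stopifnot(inherits(summary, "count_summary"))
  groups <- data.frame(
    panel = c(rep("Divisions", length(summary$divisions)),
              rep("Categories", length(summary$categories))),
    label = c(names(summary$divisions), names(summary$categories)),
    value = c(unname(summary$divisions), unname(summary$categories)),
    stringsAsFactors = FALSE)
  new_chart_spec("matribar", groups, title = title)
}

#' Donut chart of matrisome composition (matriring)
#'
#' Angular fraction of each division (or category) equals its molecule
#' count divided by the total, so the fractions of the non-zero groups sum
#' to 1.
#'
#' @param summary A `count_summary`.
#' @param level `"divisions"` or `"categories"`.
#' @param title Chart title.
#' @return A `chart_spec` of kind `"matriring"` with per-group angular
#'   fractions in `hints$fraction`.
#' @export
matriring <- function(summary, level = c("divisions", "categories"),
                      title = "Matrisome composition") {
  stopifnot(inherits(summary, "count_summary"))
  level <- match.arg(level)
  counts <- summary[[level]]
  total <- sum(counts)
  if (total == 0) {
    stop("all counts are zero; nothing to draw", call. = FALSE)
  }
  groups <- data.frame(label = names(counts), value = unname(counts),
                       stringsAsFactors = FALSE)
  new_chart_spec("matriring", groups,
                 hints = list(fraction = unname(counts) / total),
                 title = title)
}

#' Polar bar chart of per-category aggregates (matristar)
#'
#' Each category is one angular segment: the angular width of the segment
#' is proportional to the category's molecule count, and the radial height
#' of its bar is proportional to the category's aggregate value (for
#' example the mean expression of its genes in one cell cluster). Both are
#' normalized per chart — widths to fractions of the full circle over
#' non-zero categories, heights linearly to the unit radius — and the
#' normalization constants are recorded in the spec. Zero-count categories
#' have no angular extent and are dropped from rendering.
#'
#' @param values Named numeric vector: per-category aggregate (non-negative).
#' @param counts Named integer vector, same names: per-category molecule
#'   counts.
#' @param title Chart title.
#' @return A `chart_spec` of kind `"matristar"` with `hints$width_fraction`
#'   and `hints$height` (unit-scaled), plus the normalization constants.
#' @export
matristar <- function(values, counts, title = "Matrisome categories") {
  if (is.null(names(values)) || is.null(names(counts)) ||
      !setequal(names(values), names(counts))) {
    stop("values and counts must be named by the same categories",
         call. = FALSE)
  }
  allowed <- c(.matriomics_categories, .non_matrisome,
               "Non-matrisome (category)")
  bad <- setdiff(names(values), allowed)
  if (length(bad)) {
    stop("unknown categories: ", paste(bad, collapse = ", "), call. = FALSE)
  }
  counts <- counts[names(values)]
  if (any(values < 0)) {
    stop("aggregate values must be non-negative", call. = FALSE)
  }
  keep <- counts > 0
  if (!any(keep)) stop("all counts are zero; nothing to draw", call. = FALSE)
  lab <- names(values)[keep]
  val <- unname(values[keep]); cnt <- unname(counts[keep])
  vmax <- max(val)
  groups <- data.frame(label = lab, value = val, count = cnt,
                       stringsAsFactors = FALSE)
  new_chart_spec("matristar", groups,
                 hints = list(
                   width_fraction = cnt / sum(cnt),
                   height = if (vmax > 0) val / vmax else rep(0, length(val)),
                   width_norm = sum(cnt), height_norm = vmax),
                 title = title)
}

#' Alluvial chart of sample groups flowing into matrisome categories
#'
#' Cross-tabulates a grouping column of an annotated table (for example a
#' sample, cluster or condition label) against the matrisome category, and
#' describes one flow ribbon per (group, category) pair weighted by its row
#' count. Flow weights out of each group sum to that group's row count.
#'
#' @param annotated An `annotated_table`.
#' @param grouping Header name of the grouping column.
#' @param title Chart title.
#' @return A `chart_spec` of kind `"matriflow"` whose `groups` are
#'   (source, target, weight) triples.
#' @export
matriflow <- function(annotated, grouping,
                      title = "Matrisome category flows") {
  stopifnot(inherits(annotated, "annotated_table"))
  if (!grouping %in% names(annotated)) {
    stop("grouping column '", grouping, "' is not a column of the table",
         call. = FALSE)
  }
  cat_levels <- c(.matriomics_categories, .non_matrisome)
  tab <- table(source = annotated[[grouping]],
               target = factor(annotated[[.cat_col]], levels = cat_levels))
  triples <- as.data.frame(tab, stringsAsFactors = FALSE)
  names(triples) <- c("source", "target", "weight")
  triples <- triples[triples$weight > 0, , drop = FALSE]
  triples <- triples[order(triples$source,
                           match(triples$target, cat_levels)), , drop = FALSE]
  rownames(triples) <- NULL
  new_chart_spec("matriflow", triples, title = title)
}

#' Serialize a chart spec to JSON
#'
#' Stable JSON representation of a `chart_spec` (kind, groups, palette,
#' hints), suitable for golden-file comparison of chart geometry.
#'
#' @param spec A `chart_spec`.
#' @return A JSON string.
#' @export
chart_spec_json <- function(spec) {
  stopifnot(inherits(spec, "chart_spec"))
  jsonlite::toJSON(unclass(spec), dataframe = "columns", digits = NA,
                   auto_unbox = TRUE, pretty = TRUE)
}

# Build the ggplot for a chart spec.
chart_ggplot <- function(spec) {
  stopifnot(inherits(spec, "chart_spec"))
  pal <- matrisome_palette()
  g <- spec$groups
  fill_scale <- function(labels) {
    cols <- ifelse(labels %in% names(pal), pal[labels], "#808080")
    ggplot2::scale_fill_manual(values = stats::setNames(cols, labels))
  }
  p <- switch(spec$kind,
    matribar = {
      g$label <- factor(g$label, levels = unique(g$label))
      g$panel <- factor(g$panel, levels = c("Divisions", "Categories"))
      ggplot2::ggplot(g, ggplot2::aes(x = .data$label, y = .data$value,
                                      fill = .data$label)) +
        ggplot2::geom_col(show.legend = FALSE) +
        ggplot2::facet_wrap(~panel, scales = "free_x") +
        fill_scale(levels(g$label)) +
        ggplot2::labs(x = NULL, y = "Molecules") +
        ggplot2::theme_minimal(base_size = 10) +
        ggplot2::theme(axis.text.x =
          ggplot2::element_text(angle = 45, hjust = 1))
    },
    matriring = {
      keep <- g$value > 0
      g <- g[keep, , drop = FALSE]
      frac <- spec$hints$fraction[keep]
      g$xmax <- cumsum(frac); g$xmin <- g$xmax - frac
      g$label <- factor(g$label, levels = g$label)
      ggplot2::ggplot(g) +
        ggplot2::geom_rect(ggplot2::aes(xmin = .data$xmin, xmax = .data$xmax,
                                        ymin = 2, ymax = 3,
                                        fill = .data$label)) +
        ggplot2::coord_polar(theta = "x") +
        ggplot2::xlim(0, 1) + ggplot2::ylim(0, 3) +
        fill_scale(levels(g$label)) +
        ggplot2::theme_void(base_size = 10) +
        ggplot2::labs(fill = NULL)
    },
    matristar = {
      w <- spec$hints$width_fraction
      g$xmax <- cumsum(w); g$xmin <- g$xmax - w
      g$height <- spec$hints$height
      g$label <- factor(g$label, levels = g$label)
      ggplot2::ggplot(g) +
        ggplot2::geom_rect(ggplot2::aes(xmin = .data$xmin, xmax = .data$xmax,
                                        ymin = 0, ymax = .data$height,
                                        fill = .data$label)) +
        ggplot2::coord_polar(theta = "x") +
        ggplot2::xlim(0, 1) + ggplot2::ylim(0, 1) +
        fill_scale(levels(g$label)) +
        ggplot2::theme_void(base_size = 10) +
        ggplot2::labs(fill = NULL)
    },
    matriflow = {
      # two-pillar alluvial: groups on the left, categories on the right,
      # one ribbon per flow, drawn with straight-edged polygons
      src_levels <- unique(g$source)
      tgt_levels <- unique(g$target)
      src_tot <- tapply(g$weight, factor(g$source, src_levels), sum)
      tgt_tot <- tapply(g$weight, factor(g$target, tgt_levels), sum)
      total <- sum(g$weight)
      gap <- 0.02 * total
      stack_pos <- function(levels, totals) {
        top <- cumsum(unname(totals) + gap) - gap
        data.frame(label = levels, y1 = top - unname(totals), y2 = top,
                   stringsAsFactors = FALSE)
      }
      sp <- stack_pos(src_levels, src_tot)
      tp <- stack_pos(tgt_levels, tgt_tot)
      src_off <- stats::setNames(sp$y1, sp$label)
      tgt_off <- stats::setNames(tp$y1, tp$label)
      polys <- lapply(seq_len(nrow(g)), function(i) {
        s <- g$source[i]; t <- g$target[i]; wgt <- g$weight[i]
        ys <- src_off[[s]]; yt <- tgt_off[[t]]
        src_off[[s]] <<- ys + wgt
        tgt_off[[t]] <<- yt + wgt
        data.frame(id = i, target = t,
                   x = c(1.05, 1.95, 1.95, 1.05),
                   y = c(ys, yt, yt + wgt, ys + wgt),
                   stringsAsFactors = FALSE)
      })
      ribbons <- do.call(rbind, polys)
      pillars <- rbind(
        data.frame(x1 = 0.9, x2 = 1.05, y1 = sp$y1, y2 = sp$y2,
                   label = sp$label, stringsAsFactors = FALSE),
        data.frame(x1 = 1.95, x2 = 2.1, y1 = tp$y1, y2 = tp$y2,
                   label = tp$label, stringsAsFactors = FALSE))
      all_labels <- unique(c(ribbons$target, pillars$label))
      ggplot2::ggplot() +
        ggplot2::geom_polygon(
          data = ribbons,
          ggplot2::aes(x = .data$x, y = .data$y, group = .data$id,
                       fill = .data$target),
          alpha = 0.5, show.legend = FALSE) +
        ggplot2::geom_rect(
          data = pillars,
          ggplot2::aes(xmin = .data$x1, xmax = .data$x2,
                       ymin = .data$y1, ymax = .data$y2,
                       fill = .data$label),
          show.legend = FALSE) +
        fill_scale(all_labels) +
        ggplot2::geom_text(
          data = pillars,
          ggplot2::aes(x = (.data$x1 + .data$x2) / 2,
                       y = (.data$y1 + .data$y2) / 2, label = .data$label),
          size = 2.5) +
        ggplot2::theme_void(base_size = 10)
    },
    stop("unknown chart kind: ", spec$kind, call. = FALSE)
  )
  p + ggplot2::ggtitle(spec$title,
                       subtitle = if (nzchar(spec$subtitle)) spec$subtitle)
}

#' Render a chart spec to PDF or PNG
#'
#' With `show = FALSE` the underlying ggplot object is returned and nothing
#' is written, allowing further customization; with `show = TRUE` the chart
#' is written to `path`. Rendering uses fixed size and resolution (7 x 5 in,
#' 150 dpi, cairo devices) so a given spec always produces the same file.
#'
#' @param spec A `chart_spec`.
#' @param path Output path (required when `show = TRUE`).
#' @param format `"pdf"` or `"png"`.
#' @param show Write the file (TRUE) or return the ggplot object (FALSE).
#' @return The ggplot object, invisibly when a file is written.
#' @export
render_chart <- function(spec, path = NULL, format = c("pdf", "png"),
                         show = TRUE) {
  format <- match.arg(format)
  p <- chart_ggplot(spec)
  if (!show) return(p)
  if (is.null(path)) stop("path is required when show = TRUE", call. = FALSE)
  dev <- if (format == "pdf") grDevices::cairo_pdf else {
    function(filename, width, height, ...) {
      grDevices::png(filename, width = width, height = height,
                     units = "in", res = 150, type = "cairo")
    }
  }
  ok <- tryCatch({
    dev(path, width = 7, height = 5)
    print(p)
    grDevices::dev.off()
    TRUE
  }, error = function(e) {
    try(grDevices::dev.off(), silent = TRUE)
    stop("cannot render chart to ", path, ": ", conditionMessage(e),
         call. = FALSE)
  })
  invisible(p)
}

#' @export
print.chart_spec <- function(x, ...) {
  cat("Chart spec: ", x$kind, " (", nrow(x$groups), " groups)\n", sep = "")
  print.data.frame(x$groups)
  invisible(x)
}
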