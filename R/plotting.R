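#' Static scatter with polygon overlay
#'
#' Renders all cells on the requested axes (embedding or feature scatter),
#' optionally coloured by a gene's expression or an annotation column, with
#' every polygon drawn closed on top. Alongside the image a sidecar JSON
#' (`<out>.json`) records the plotted polygon coordinates, so the session
#' travels with the figure.
#'
#' @param ds a `CellDataset`.
#' @param axes an [embedding_axes()] or [scatter_axes()] context.
#' @param polys optional [polygon_set()] to overlay.
#' @param color_by optional gene id or annotation column name.
#' @param out output image path (extension chooses the device, e.g. `.png`).
#' @param point_size scatter point size.
#' @return `out`, invisibly.
#' @export
render_overlay <- function(ds, axes, polys = NULL, color_by = NULL,
                           out, point_size = 0.5) {
  coords <- if (axes$kind == "embedding") {
    get_embedding(ds, axes$embedding_name)
  } else {
    scatter_coords(ds, axes)
  }
  df <- data.frame(x = coords[, 1], y = coords[, 2])
  lab <- if (axes$kind == "embedding") {
    c(paste0(axes$embedding_name, " 1"), paste0(axes$embedding_name, " 2"))
  } else {
    c(axes$x_feature, axes$y_feature)
  }
  p <- ggplot2::ggplot(df, ggplot2::aes(x = x, y = y))
  if (!is.null(color_by)) {
    if (color_by %in% colnames(ds$annotations)) {
      df$col <- as.character(get_annotation(ds, color_by))
      p <- ggplot2::ggplot(df, ggplot2::aes(x = x, y = y,
                                            colour = col)) +
        ggplot2::labs(colour = color_by)
    } else if (color_by %in% ds$gene_ids) {
      df$col <- feature_values(ds, color_by, "raw")
      p <- ggplot2::ggplot(df, ggplot2::aes(x = x, y = y,
                                            colour = col)) +
        ggplot2::scale_colour_viridis_c() +
        ggplot2::labs(colour = color_by)
    } else {
      stop("color_by '", color_by,
           "' is neither a gene nor an annotation", call. = FALSE)
    }
  }
  p <- p + ggplot2::geom_point(size = point_size) +
    ggplot2::labs(x = lab[1], y = lab[2]) +
    ggplot2::theme_classic()
  if (!is.null(polys)) {
    for (poly in polys$polygons) {
      v <- as.data.frame(poly$vertices)
      p <- p + ggplot2::geom_polygon(
        data = v, ggplot2::aes(x = x, y = y),
        inherit.aes = FALSE, fill = NA, colour = "black",
        linewidth = 0.6)
    }
  }
  ggplot2::ggsave(out, p, width = 6, height = 5, dpi = 150)
  if (!is.null(polys)) {
    write_polygon_set(polys, paste0(out, ".json"))
  }
  invisible(out)
}

utils::globalVariables(c("x", "y", "col"))
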