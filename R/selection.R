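#' Display-space coordinates for scatter gating
#'
#' Maps each cell to the (x, y) position it would occupy on a scatter plot of
#' two features: values are taken from the requested layer and, under a
#' `log10` axis scale, log10-transformed so that polygons drawn in the
#' displayed coordinate system apply directly. Zero values under `log10` are
#' placed at `log10(zero_offset)` (half a count by default) so they remain
#' visible and gateable; negative values are a domain error.
#'
#' @param ds a `CellDataset`.
#' @param axes a [scatter_axes()] context.
#' @param zero_offset pseudo-count used to place zeros on a log10 axis.
#' @return numeric n x 2 matrix of display coordinates.
#' @export
scatter_coords <- function(ds, axes, zero_offset = 0.5) {
  stopifnot(inherits(axes, "axes_context"), axes$kind == "scatter")
  x <- feature_values(ds, axes$x_feature, axes$layer)
  y <- feature_values(ds, axes$y_feature, axes$layer)
  cbind(apply_axis_scale(x, axes$x_scale, zero_offset),
        apply_axis_scale(y, axes$y_scale, zero_offset))
}

apply_axis_scale <- function(v, scale, zero_offset = 0.5) {
  if (scale == "linear") return(v)
  if (any(v < 0)) {
    stop("log10 axis scale requires non-negative values", call. = FALSE)
  }
  out <- v
  out[v == 0] <- zero_offset
  log10(out)
}

new_selection_result <- function(key, labels, membership, polys) {
  structure(list(key = key, labels = labels, membership = membership,
                 polygon_set = polys),
            class = "SelectionResult")
}

#' @export
print.SelectionResult <- function(x, ...) {
  cat("SelectionResult '", x$key, "': ", length(x$labels), " cells, ",
      ncol(x$membership), " polygons\n", sep = "")
  print(table(x$labels))
  invisible(x)
}

apply_polygons <- function(ds, coords, polys, key) {
  m <- membership_matrix(coords, polys)
  labels <- labels_from_membership(m, polygon_names(polys))
  if (key %in% colnames(ds$annotations)) {
    message("overwriting existing annotation '", key, "'")
  }
  ds <- set_annotation(ds, key, labels)
  ds$polygon_store[[key]] <- polys
  res <- new_selection_result(key, labels, m, polys)
  res$dataset <- ds
  res
}

#' Select cells by polygons on an embedding
#'
#' Applies every polygon of the set to the named embedding's coordinates,
#' writes the comma-joined labels as annotation column `key` (overwriting
#' any previous column of that name), and stores the polygon set in the
#' dataset's session store under `key` for later saving or re-plotting.
#'
#' @param ds a `CellDataset`.
#' @param embedding_name name of a registered embedding.
#' @param polys a [polygon_set()] whose axes context is the same embedding.
#' @param key annotation column name to write.
#' @return a `SelectionResult` with fields `key`, `labels`, `membership`,
#'   `polygon_set`, and `dataset` (the updated dataset).
#' @export
#' @examples
#' ds <- simulate_dataset(sim_spec(n_cells = 200, seed = 1))
#' gate <- reference_polygon(sim_spec(n_cells = 200, seed = 1), cluster = 1)
#' polys <- polygon_set(list(gate), embedding_axes("umap"))
#' res <- select_on_embedding(ds, "umap", polys, key = "sel")
#' table(res$labels)
select_on_embedding <- function(ds, embedding_name, polys, key) {
  stopifnot(inherits(polys, "polygon_set"))
  coords <- get_embedding(ds, embedding_name)
  ax <- polys$axes
  if (ax$kind != "embedding") {
    stop("polygon set was drawn on ", ax$kind,
         " axes, not on an embedding", call. = FALSE)
  }
  if (!is.null(ax$embedding_name) && ax$embedding_name != embedding_name) {
    stop("polygon set was drawn on embedding '", ax$embedding_name,
         "', not '", embedding_name, "'", call. = FALSE)
  }
  apply_polygons(ds, coords, polys, key)
}

#' Select cells by polygons on a two-feature scatter
#'
#' Gates cells in the displayed coordinate system of a feature-vs-feature
#' scatter plot (see [scatter_coords()]); polygons drawn on a log10 axis are
#' interpreted in log10 space. The normalized layer is computed on the fly
#' when requested but absent.
#'
#' @param ds a `CellDataset`.
#' @param polys a [polygon_set()] with a [scatter_axes()] context.
#' @param key annotation column name to write.
#' @param zero_offset pseudo-count for zeros under log10 (see
#'   [scatter_coords()]).
#' @return a `SelectionResult` (see [select_on_embedding()]).
#' @export
select_on_scatter <- function(ds, polys, key, zero_offset = 0.5) {
  stopifnot(inherits(polys, "polygon_set"))
  ax <- polys$axes
  if (ax$kind != "scatter") {
    stop("polygon set was drawn on ", ax$kind, " axes, not on a scatter",
         call. = FALSE)
  }
  coords <- scatter_coords(ds, ax, zero_offset)
  apply_polygons(ds, coords, polys, key)
}

#' Apply a polygon session to a dataset
#'
#' Dispatches on the set's axes context: embedding sessions are applied to
#' the embedding they were drawn on (an error if the dataset lacks it),
#' scatter sessions to the recorded feature pair, layer and scales.
#'
#' @param ds a `CellDataset`.
#' @param polys a [polygon_set()], e.g. from [load_session()].
#' @param key annotation column name to write.
#' @param ... passed on to [select_on_scatter()].
#' @return a `SelectionResult`.
#' @export
apply_session <- function(ds, polys, key, ...) {
  if (polys$axes$kind == "embedding") {
    select_on_embedding(ds, polys$axes$embedding_name, polys, key)
  } else {
    select_on_scatter(ds, polys, key, ...)
  }
}

#' Rename selection labels
#'
#' Replaces the default integer polygon names stored in an annotation column
#' with custom names. Composite comma-joined labels are treated as whole
#' strings: to rename `"0,1"` supply it as a mapping key itself.
#'
#' @param ds a `CellDataset`.
#' @param key annotation column to edit.
#' @param mapping named character vector, `c(old = "new", ...)`.
#' @return the updated dataset.
#' @export
#' @examples
#' \dontrun{
#' ds <- rename_labels(ds, "sel", c("0" = "TH1", "1" = "TH17"))
#' }
rename_labels <- function(ds, key, mapping) {
  labels <- as.character(get_annotation(ds, key))
  if (length(mapping) == 0L) return(ds)
  old <- names(mapping)
  missing <- setdiff(old, unique(labels))
  if (length(missing)) {
    stop("labels not present under '", key, "': ",
         paste(missing, collapse = ", "), "; valid labels: ",
         paste(sort(unique(labels)), collapse = ", "), call. = FALSE)
  }
  new <- as.character(mapping)
  merged <- intersect(new, c(setdiff(unique(labels), old), new[duplicated(new)]))
  if (length(merged)) {
    warning("renaming merges previously distinct labels: ",
            paste(unique(merged), collapse = ", "), call. = FALSE)
  }
  hit <- match(labels, old)
  labels[!is.na(hit)] <- new[hit[!is.na(hit)]]
  set_annotation(ds, key, labels)
}

# ---- session JSON ----------------------------------------------------------

axes_to_list <- function(ax) unclass(ax)

axes_from_list <- function(lst) {
  if (lst$kind == "embedding") {
    embedding_axes(lst$embedding_name)
  } else {
    scatter_axes(lst$x_feature, lst$y_feature, lst$layer,
                 lst$x_scale, lst$y_scale)
  }
}

#' Serialize a polygon set to JSON
#'
#' Schema:
#' `{"axes": {...}, "polygons": [{"name": "...", "vertices": [[x, y], ...]}]}`.
#' Vertices are written at full precision (`digits = NA`) so the round trip
#' is exact for decimal representations.
#'
#' @param polys a [polygon_set()].
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_polygon_set <- function(polys, path) {
  obj <- list(
    axes = axes_to_list(polys$axes),
    polygons = lapply(polys$polygons, function(p) {
      list(name = p$name,
           vertices = lapply(seq_len(nrow(p$vertices)),
                             function(i) as.numeric(p$vertices[i, ])))
    }))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = I(17))
  invisible(path)
}

#' @rdname write_polygon_set
#' @export
read_polygon_set <- function(path) {
  obj <- jsonlite::read_json(path)
  if (is.null(obj$axes) || is.null(obj$polygons)) {
    stop("not a polygon session file (missing 'axes' or 'polygons'): ",
         path, call. = FALSE)
  }
  polys <- lapply(obj$polygons, function(p) {
    verts <- do.call(rbind, lapply(p$vertices, function(v) {
      as.numeric(unlist(v))
    }))
    gate_polygon(verts, name = p$name)
  })
  polygon_set(polys, axes_from_list(obj$axes))
}

#' Save / load a gate session
#'
#' `save_session` writes the polygon set stored under annotation `key` (the
#' session created by a selection call) to JSON; `load_session` reads one
#' back. Loading then re-applying with [apply_session()] reproduces the
#' original labels exactly.
#'
#' @param ds a `CellDataset`.
#' @param key annotation key whose session to save.
#' @param path JSON path.
#' @return `save_session`: `path` invisibly; `load_session`: a
#'   [polygon_set()].
#' @export
save_session <- function(ds, key, path) {
  if (!key %in% names(ds$polygon_store)) {
    stop("no polygon session stored under key '", key, "'", call. = FALSE)
  }
  write_polygon_set(ds$polygon_store[[key]], path)
}

#' @rdname save_session
#' @export
load_session <- function(path) {
  read_polygon_set(path)
}
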