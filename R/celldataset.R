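#' cellgate: polygon gating and region statistics for single-cell data
#'
#' Headless manual cell selection on 2-D representations of cell-by-gene
#' UMI count matrices, with per-region statistics (percent of cells, percent
#' expressing, TPM, fold-enrichment), Gaussian-mixture grouping, a synthetic
#' data generator, and a command-line interface.
#'
#' @keywords internal
"_PACKAGE"

#' Construct a cell-by-gene dataset
#'
#' The central container: a raw UMI count matrix (cells in rows, genes in
#' columns) plus optional normalized layer, per-cell annotation columns,
#' named 2-D embeddings, and a store of polygon gate sessions. Cell order is
#' the canonical index: all matrices, embeddings and annotations align
#' positionally, and `cell_id` is used only when joining files.
#'
#' @param counts matrix or sparse Matrix of non-negative integer UMI counts,
#'   cells x genes.
#' @param cell_ids character vector of unique cell identifiers; defaults to
#'   `rownames(counts)`.
#' @param gene_ids character vector of unique gene/feature identifiers;
#'   defaults to `colnames(counts)`.
#' @param normalized optional matrix of the same shape with non-negative
#'   normalized expression values. When absent and requested (e.g. by
#'   [select_on_scatter()] with `layer = "normalized"`), it is computed by
#'   [normalized_layer()].
#' @param annotations optional data.frame of per-cell columns (one row per
#'   cell, in cell order).
#' @return An object of class `CellDataset`.
#' @seealso [validate_dataset()], [attach_embedding()], [read_mtx_dataset()]
#' @export
#' @examples
#' counts <- matrix(c(5L, 0L, 0L, 1L, 2L, 0L), nrow = 3, byrow = TRUE,
#'                  dimnames = list(paste0("cell", 1:3), c("CCR7", "SELL")))
#' ds <- CellDataset(counts)
#' n_cells(ds)
CellDataset <- function(counts, cell_ids = rownames(counts),
                        gene_ids = colnames(counts), normalized = NULL,
                        annotations = NULL) {
  counts <- as_count_matrix(counts)
  if (is.null(cell_ids)) {
    cell_ids <- paste0("cell", seq_len(nrow(counts)))
  }
  if (is.null(gene_ids)) {
    gene_ids <- paste0("gene", seq_len(ncol(counts)))
  }
  if (anyDuplicated(cell_ids)) {
    stop("cell_ids contain duplicates", call. = FALSE)
  }
  if (anyDuplicated(gene_ids)) {
    stop("gene_ids contain duplicates", call. = FALSE)
  }
  rownames(counts) <- cell_ids
  colnames(counts) <- gene_ids
  if (is.null(annotations)) {
    annotations <- data.frame(row.names = cell_ids)
  } else {
    annotations <- as.data.frame(annotations, row.names = cell_ids)
  }
  ds <- structure(
    list(counts = counts, normalized = normalized,
         cell_ids = as.character(cell_ids), gene_ids = as.character(gene_ids),
         annotations = annotations, embeddings = list(),
         polygon_store = list()),
    class = "CellDataset")
  validate_dataset(ds)
  ds
}

# Coerce to a sparse integer-valued count matrix, rejecting bad values.
as_count_matrix <- function(counts) {
  if (!methods::is(counts, "Matrix")) {
    counts <- Matrix::Matrix(as.matrix(counts), sparse = TRUE)
  }
  counts <- methods::as(methods::as(counts, "dMatrix"), "CsparseMatrix")
  v <- counts@x
  if (any(v < 0)) {
    stop("count matrix contains negative entries", call. = FALSE)
  }
  if (any(v != round(v))) {
    stop("count matrix contains non-integer entries", call. = FALSE)
  }
  counts
}

#' Validate the structural invariants of a dataset
#'
#' Checks dimension agreement between counts, identifiers, annotations and
#' embeddings, uniqueness of identifiers, and 2-D/finiteness of embeddings.
#' Raises an error on the first violation; returns the dataset invisibly
#' otherwise.
#'
#' @param ds a `CellDataset`.
#' @return `ds`, invisibly.
#' @export
validate_dataset <- function(ds) {
  stopifnot(inherits(ds, "CellDataset"))
  nc <- nrow(ds$counts)
  ng <- ncol(ds$counts)
  if (length(ds$cell_ids) != nc) {
    stop("counts has ", nc, " rows but there are ", length(ds$cell_ids),
         " cell_ids", call. = FALSE)
  }
  if (length(ds$gene_ids) != ng) {
    stop("counts has ", ng, " columns but there are ", length(ds$gene_ids),
         " gene_ids", call. = FALSE)
  }
  if (anyDuplicated(ds$cell_ids)) {
    stop("cell_ids contain duplicates", call. = FALSE)
  }
  if (anyDuplicated(ds$gene_ids)) {
    stop("gene_ids contain duplicates", call. = FALSE)
  }
  if (!is.null(ds$normalized) &&
      !identical(dim(ds$normalized), dim(ds$counts))) {
    stop("normalized layer shape differs from counts", call. = FALSE)
  }
  if (nrow(ds$annotations) != nc) {
    stop("annotations have ", nrow(ds$annotations), " rows for ", nc,
         " cells", call. = FALSE)
  }
  for (nm in names(ds$embeddings)) {
    emb <- ds$embeddings[[nm]]
    if (ncol(emb) != 2L) {
      stop("embedding '", nm, "': embeddings limited to 2 dimensions",
           call. = FALSE)
    }
    if (nrow(emb) != nc) {
      stop("embedding '", nm, "' has ", nrow(emb), " rows for ", nc,
           " cells", call. = FALSE)
    }
    if (!all(is.finite(emb))) {
      stop("embedding '", nm, "' contains non-finite coordinates",
           call. = FALSE)
    }
  }
  invisible(ds)
}

#' @export
print.CellDataset <- function(x, ...) {
  cat("CellDataset:", nrow(x$counts), "cells x", ncol(x$counts), "genes\n")
  cat("  normalized layer:", if (is.null(x$normalized)) "absent" else
    "present", "\n")
  if (ncol(x$annotations)) {
    cat("  annotations:", paste(colnames(x$annotations), collapse = ", "),
        "\n")
  }
  if (length(x$embeddings)) {
    cat("  embeddings:", paste(names(x$embeddings), collapse = ", "), "\n")
  }
  if (length(x$polygon_store)) {
    cat("  gate sessions:", paste(names(x$polygon_store), collapse = ", "),
        "\n")
  }
  invisible(x)
}

#' Number of cells / genes in a dataset
#' @param ds a `CellDataset`.
#' @return integer count.
#' @export
n_cells <- function(ds) nrow(ds$counts)

#' @rdname n_cells
#' @export
n_genes <- function(ds) ncol(ds$counts)

#' Register a 2-D embedding
#'
#' Embeddings (UMAP, t-SNE, PCA, ...) are inputs, never computed here, and
#' are limited to exactly two dimensions because gates are planar polygons.
#'
#' @param ds a `CellDataset`.
#' @param name embedding name, e.g. `"umap"`.
#' @param coords numeric matrix with one row per cell and exactly 2 columns.
#' @return the updated dataset.
#' @export
attach_embedding <- function(ds, name, coords) {
  stopifnot(inherits(ds, "CellDataset"), is.character(name),
            length(name) == 1L)
  coords <- as.matrix(coords)
  if (ncol(coords) != 2L) {
    stop("embeddings limited to 2 dimensions (got ", ncol(coords),
         " columns)", call. = FALSE)
  }
  if (nrow(coords) != n_cells(ds)) {
    stop("embedding has ", nrow(coords), " rows but dataset has ",
         n_cells(ds), " cells", call. = FALSE)
  }
  if (!all(is.finite(coords))) {
    stop("embedding coordinates must be finite", call. = FALSE)
  }
  storage.mode(coords) <- "double"
  dimnames(coords) <- list(ds$cell_ids, c("dim1", "dim2"))
  ds$embeddings[[name]] <- coords
  ds
}

#' Retrieve an embedding by name
#' @param ds a `CellDataset`.
#' @param name embedding name.
#' @return n_cells x 2 numeric matrix.
#' @export
get_embedding <- function(ds, name) {
  if (!name %in% names(ds$embeddings)) {
    stop("unknown embedding '", name, "'; available: ",
         paste(names(ds$embeddings), collapse = ", "), call. = FALSE)
  }
  ds$embeddings[[name]]
}

#' Default normalized expression layer
#'
#' When a dataset carries no normalized layer, one is derived from the raw
#' counts by the dominant single-cell convention: each cell's counts are
#' scaled to the median total UMI count across cells, then log1p-transformed.
#' Region statistics ([tpm()], [enrichment()]) never use this layer; it
#' exists for scatter gating and mixture modelling on a variance-stabilized
#' scale.
#'
#' @param ds a `CellDataset`.
#' @return dense numeric matrix, cells x genes.
#' @export
normalized_layer <- function(ds) {
  if (!is.null(ds$normalized)) {
    return(as.matrix(ds$normalized))
  }
  tot <- Matrix::rowSums(ds$counts)
  target <- stats::median(tot)
  sf <- ifelse(tot > 0, target / tot, 0)
  log1p(as.matrix(ds$counts * sf))
}

#' Per-cell values of one feature
#'
#' @param ds a `CellDataset`.
#' @param feature a gene or antibody-capture feature id.
#' @param layer `"raw"` (UMI counts) or `"normalized"`.
#' @return numeric vector of length `n_cells(ds)`.
#' @export
feature_values <- function(ds, feature, layer = c("raw", "normalized")) {
  layer <- match.arg(layer)
  j <- match(feature, ds$gene_ids)
  if (is.na(j)) {
    stop("unknown feature '", feature, "'", call. = FALSE)
  }
  if (layer == "raw") {
    as.numeric(ds$counts[, j])
  } else {
    as.numeric(normalized_layer(ds)[, j])
  }
}

#' Fetch an annotation column
#' @param ds a `CellDataset`.
#' @param key annotation column name.
#' @return the column (usually character labels).
#' @export
get_annotation <- function(ds, key) {
  if (!key %in% colnames(ds$annotations)) {
    stop("unknown annotation key '", key, "'; available: ",
         paste(colnames(ds$annotations), collapse = ", "), call. = FALSE)
  }
  ds$annotations[[key]]
}

#' Set an annotation column
#' @param ds a `CellDataset`.
#' @param key annotation column name; an existing column is overwritten.
#' @param values vector with one entry per cell, in cell order.
#' @return the updated dataset.
#' @export
set_annotation <- function(ds, key, values) {
  if (length(values) != n_cells(ds)) {
    stop("annotation '", key, "' has ", length(values), " values for ",
         n_cells(ds), " cells", call. = FALSE)
  }
  ds$annotations[[key]] <- values
  ds
}

#' Subset a dataset to selected cells
#'
#' Counts, normalized layer, annotations and embeddings are subset in lock
#' step; the polygon session store is carried over unchanged so sessions can
#' be re-applied to the remaining cells.
#'
#' @param ds a `CellDataset`.
#' @param keep logical vector, integer indices, or cell ids.
#' @return the reduced dataset.
#' @export
filter_cells <- function(ds, keep) {
  if (is.character(keep)) {
    idx <- match(keep, ds$cell_ids)
    if (anyNA(idx)) {
      stop("unknown cell ids: ", paste(keep[is.na(idx)], collapse = ", "),
           call. = FALSE)
    }
  } else if (is.logical(keep)) {
    stopifnot(length(keep) == n_cells(ds))
    idx <- which(keep)
  } else {
    idx <- as.integer(keep)
  }
  ds$counts <- ds$counts[idx, , drop = FALSE]
  if (!is.null(ds$normalized)) {
    ds$normalized <- ds$normalized[idx, , drop = FALSE]
  }
  ds$cell_ids <- ds$cell_ids[idx]
  ds$annotations <- ds$annotations[idx, , drop = FALSE]
  ds$embeddings <- lapply(ds$embeddings, function(e) e[idx, , drop = FALSE])
  validate_dataset(ds)
  ds
}

#' Drop all cells carrying a label
#'
#' Negative selection: removes every cell whose label under `key` equals one
#' of `labels` (string-exact match, so the composite label `"A,B"` removes
#' exactly the cells inside both polygon A and polygon B).
#'
#' @param ds a `CellDataset`.
#' @param key annotation column written by a selection.
#' @param labels character vector of labels to drop.
#' @return the reduced dataset.
#' @export
drop_label <- function(ds, key, labels) {
  lab <- get_annotation(ds, key)
  filter_cells(ds, !(lab %in% labels))
}
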