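#' Read a Matrix Market dataset
#'
#' Loads a sparse UMI matrix with its barcode and feature sidecar files.
#' Because both orientations circulate (CellRanger writes genes-by-cells),
#' the orientation must be stated explicitly; genes-by-cells input is
#' transposed so the in-memory convention is always cells-by-genes.
#'
#' @param matrix_path path to the `.mtx` file.
#' @param barcodes_path path to a TSV with one cell barcode per line.
#' @param features_path path to a TSV with one feature per line; lines may
#'   carry 2-3 tab-separated fields, of which the first is used as gene id.
#' @param orientation `"cells-by-genes"` or `"genes-by-cells"`.
#' @return a [CellDataset()].
#' @export
read_mtx_dataset <- function(matrix_path, barcodes_path, features_path,
                             orientation = c("cells-by-genes",
                                             "genes-by-cells")) {
  orientation <- match.arg(orientation)
  for (p in c(matrix_path, barcodes_path, features_path)) {
    if (!file.exists(p)) stop("file not found: ", p, call. = FALSE)
  }
  m <- Matrix::readMM(matrix_path)
  barcodes <- readLines(barcodes_path)
  barcodes <- barcodes[nzchar(barcodes)]
  feat_lines <- readLines(features_path)
  feat_lines <- feat_lines[nzchar(feat_lines)]
  features <- vapply(strsplit(feat_lines, "\t", fixed = TRUE), `[[`, "", 1L)
  if (orientation == "genes-by-cells") {
    m <- Matrix::t(m)
  }
  if (nrow(m) != length(barcodes)) {
    stop("dimension mismatch: matrix implies ", nrow(m), " cells but ",
         barcodes_path, " has ", length(barcodes), " barcodes",
         call. = FALSE)
  }
  if (ncol(m) != length(features)) {
    stop("dimension mismatch: matrix implies ", ncol(m), " features but ",
         features_path, " has ", length(features), " features",
         call. = FALSE)
  }
  CellDataset(m, cell_ids = barcodes, gene_ids = features)
}

#' Write a dataset as Matrix Market plus sidecar TSVs
#'
#' Emits `matrix.mtx` (genes-by-cells, the CellRanger convention),
#' `barcodes.tsv` and `features.tsv` into `dir`, plus one CSV per embedding
#' (`embedding_<name>.csv`) and `annotations.csv` when annotations exist.
#'
#' @param ds a `CellDataset`.
#' @param dir output directory, created if missing.
#' @return `dir`, invisibly.
#' @export
write_mtx_dataset <- function(ds, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  m <- methods::as(Matrix::t(ds$counts), "generalMatrix")
  Matrix::writeMM(m, file.path(dir, "matrix.mtx"))
  writeLines(ds$cell_ids, file.path(dir, "barcodes.tsv"))
  writeLines(ds$gene_ids, file.path(dir, "features.tsv"))
  for (nm in names(ds$embeddings)) {
    emb <- ds$embeddings[[nm]]
    utils::write.csv(
      data.frame(cell_id = ds$cell_ids, dim1 = emb[, 1], dim2 = emb[, 2]),
      file.path(dir, paste0("embedding_", nm, ".csv")), row.names = FALSE)
  }
  if (ncol(ds$annotations)) {
    write_annotations(ds, file.path(dir, "annotations.csv"))
  }
  invisible(dir)
}

#' Read a dense CSV count matrix
#'
#' Toy-data reader: first column `cell_id`, header row of gene ids, integer
#' entries.
#'
#' @param path CSV path.
#' @return a [CellDataset()].
#' @export
read_csv_dataset <- function(path) {
  tab <- utils::read.csv(path, check.names = FALSE)
  cell_ids <- as.character(tab[[1]])
  m <- as.matrix(tab[, -1, drop = FALSE])
  rownames(m) <- cell_ids
  CellDataset(m)
}

#' Read embedding coordinates from CSV
#'
#' Expects columns `cell_id, dim1, dim2`; rows are joined to the dataset by
#' `cell_id` and must cover every cell exactly once.
#'
#' @param ds a `CellDataset`.
#' @param path CSV path.
#' @param name name under which to register the embedding.
#' @return the updated dataset.
#' @export
read_embedding_csv <- function(ds, path, name) {
  tab <- utils::read.csv(path)
  idx <- match(ds$cell_ids, as.character(tab$cell_id))
  if (anyNA(idx)) {
    stop("embedding CSV is missing ", sum(is.na(idx)), " cell ids",
         call. = FALSE)
  }
  attach_embedding(ds, name, cbind(tab$dim1[idx], tab$dim2[idx]))
}

#' Write / read per-cell annotations as CSV
#'
#' The CSV has a `cell_id` column plus one column per annotation. The round
#' trip preserves column names and values; rows are joined by `cell_id` so
#' file order need not match cell order. A `cell_id` unknown to the dataset
#' is an error.
#'
#' @param ds a `CellDataset`.
#' @param path CSV path.
#' @return `write_annotations`: `path` invisibly; `read_annotations`: the
#'   updated dataset.
#' @export
write_annotations <- function(ds, path) {
  tab <- cbind(data.frame(cell_id = ds$cell_ids), ds$annotations)
  rownames(tab) <- NULL
  utils::write.csv(tab, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_annotations
#' @export
read_annotations <- function(ds, path) {
  tab <- utils::read.csv(path, check.names = FALSE,
                         colClasses = c(cell_id = "character"))
  idx <- match(as.character(tab$cell_id), ds$cell_ids)
  if (anyNA(idx)) {
    stop("annotation CSV contains cell ids absent from the dataset: ",
         paste(utils::head(tab$cell_id[is.na(idx)], 5), collapse = ", "),
         call. = FALSE)
  }
  for (col in setdiff(colnames(tab), "cell_id")) {
    values <- rep(NA, n_cells(ds))
    values[idx] <- tab[[col]]
    ds <- set_annotation(ds, col, values)
  }
  ds
}
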