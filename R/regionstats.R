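#' Percentage of cells per region
#'
#' For every distinct label of an annotation column (a gate selection, a
#' clustering, any categorical), the share of all cells carrying it:
#' `100 * n_label / n_total`. Values over all labels sum to 100.
#'
#' @param ds a `CellDataset`.
#' @param key annotation column name.
#' @return named numeric vector, percent per label.
#' @export
pct_cells <- function(ds, key) {
  if (n_cells(ds) == 0L) stop("dataset has no cells", call. = FALSE)
  labels <- as.character(get_annotation(ds, key))
  tab <- table(labels)
  out <- 100 * as.numeric(tab) / length(labels)
  names(out) <- names(tab)
  out
}

#' Percentage of cells expressing a gene, per region
#'
#' A cell "expresses" a gene when its raw UMI count reaches `threshold`
#' (default 1, i.e. at least one captured transcript).
#'
#' @param ds a `CellDataset`.
#' @param key annotation column name.
#' @param gene gene id.
#' @param threshold minimum raw count to call a cell expressing.
#' @return named numeric vector, percent per label.
#' @export
pct_expressing <- function(ds, key, gene, threshold = 1) {
  labels <- as.character(get_annotation(ds, key))
  v <- feature_values(ds, gene, "raw")
  expressed <- v >= threshold
  out <- vapply(split(expressed, labels), function(e) 100 * mean(e), 0)
  out
}

region_mask <- function(ds, cells) {
  if (is.logical(cells)) {
    stopifnot(length(cells) == n_cells(ds))
    cells
  } else if (is.character(cells)) {
    idx <- match(cells, ds$cell_ids)
    if (anyNA(idx)) stop("unknown cell ids in region", call. = FALSE)
    seq_len(n_cells(ds)) %in% idx
  } else {
    seq_len(n_cells(ds)) %in% as.integer(cells)
  }
}

#' Transcripts per million of a gene in a cell population
#'
#' One UMI is taken to represent one detected mRNA transcript, so TPM is the
#' gene's share of all UMIs in the population, scaled to one million:
#' `sum(UMI_gene) / sum(UMI_all) * 1e6`, always computed on the raw counts
#' (never the normalized layer).
#'
#' @param ds a `CellDataset`.
#' @param cells region cell set: logical mask, integer indices, or cell ids.
#' @param gene gene id.
#' @return TPM (numeric); `NaN` with a warning when the region has zero
#'   total UMIs.
#' @export
tpm <- function(ds, cells, gene) {
  mask <- region_mask(ds, cells)
  if (!any(mask)) stop("region is empty", call. = FALSE)
  j <- match(gene, ds$gene_ids)
  if (is.na(j)) stop("unknown gene '", gene, "'", call. = FALSE)
  total <- sum(ds$counts[mask, , drop = FALSE])
  if (total == 0) {
    warning("region has zero total UMIs; TPM undefined", call. = FALSE)
    return(NaN)
  }
  g <- sum(ds$counts[mask, j])
  g / total * 1e6
}

#' Fold-enrichment of a gene inside a labelled region
#'
#' The ratio of the gene's TPM within the region to its TPM among all cells
#' outside it. Labels are matched string-exactly, so the composite label
#' `"A,B"` is its own region; use [label_has_polygon()] to pool cells at the
#' polygon level instead.
#'
#' @param ds a `CellDataset`.
#' @param key annotation column name.
#' @param label region label (or, for `combined_enrichment`, several labels
#'   pooled into one region).
#' @param gene gene id.
#' @return fold enrichment (numeric); `Inf` with a warning when the gene is
#'   detected only inside the region, `NaN` when undetected everywhere.
#' @export
enrichment <- function(ds, key, label, gene) {
  labels <- as.character(get_annotation(ds, key))
  mask <- labels %in% label
  enrichment_mask(ds, mask, gene)
}

#' @rdname enrichment
#' @param labels labels whose union forms the pooled region.
#' @export
combined_enrichment <- function(ds, key, labels, gene) {
  all_labels <- as.character(get_annotation(ds, key))
  mask <- all_labels %in% labels
  enrichment_mask(ds, mask, gene)
}

enrichment_mask <- function(ds, mask, gene) {
  if (!any(mask)) stop("region is empty", call. = FALSE)
  if (all(mask)) {
    stop("region covers every cell; enrichment needs a non-empty complement",
         call. = FALSE)
  }
  t_in <- tpm(ds, mask, gene)
  t_out <- tpm(ds, !mask, gene)
  if (is.nan(t_in) || is.nan(t_out)) return(NaN)
  if (t_out == 0) {
    if (t_in == 0) return(NaN)
    warning("gene detected only inside the region; enrichment is infinite",
            call. = FALSE)
    return(Inf)
  }
  t_in / t_out
}

#' Does a (possibly composite) label include a polygon name?
#'
#' Comma-joined labels are atomic strings for the statistics above; this
#' predicate splits them so cells labelled `"CCR7,SELL"` can be pooled with
#' `"CCR7"` cells on demand.
#'
#' @param labels character vector of labels.
#' @param polygon_name single polygon name.
#' @param sep label separator.
#' @return logical vector.
#' @export
label_has_polygon <- function(labels, polygon_name, sep = ",") {
  vapply(strsplit(as.character(labels), sep, fixed = TRUE),
         function(parts) polygon_name %in% parts, NA)
}

#' Region statistics table
#'
#' One row per distinct label of the annotation column with the number of
#' cells, percent of all cells, and for each requested gene: percent of
#' cells expressing it, its TPM, and its fold-enrichment versus all other
#' cells. Percentages are unrounded; format at print time.
#'
#' @param ds a `CellDataset`.
#' @param key annotation column name.
#' @param genes character vector of gene ids (may be empty).
#' @param threshold expression-call threshold for percent expressing.
#' @return data.frame with one row per label.
#' @export
region_stats <- function(ds, key, genes = character(), threshold = 1) {
  labels <- as.character(get_annotation(ds, key))
  lvls <- sort(unique(labels))
  pc <- pct_cells(ds, key)
  tab <- data.frame(region = lvls,
                    n_cells = as.integer(table(labels)[lvls]),
                    pct_cells = as.numeric(pc[lvls]),
                    stringsAsFactors = FALSE)
  for (g in genes) {
    pe <- pct_expressing(ds, key, g, threshold)
    tab[[paste0("pct_expressing_", g)]] <- as.numeric(pe[lvls])
    tab[[paste0("tpm_", g)]] <-
      vapply(lvls, function(l) tpm(ds, labels == l, g), 0)
    tab[[paste0("enrichment_", g)]] <- vapply(lvls, function(l) {
      if (all(labels == l)) NA_real_ else
        suppressWarnings(enrichment(ds, key, l, g))
    }, 0)
  }
  rownames(tab) <- NULL
  tab
}
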