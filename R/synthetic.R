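# Synthetic single-cell fixtures: clustered 2-D embeddings, negative-binomial
# UMI counts with subset-elevated marker genes and dropout, and log-normal
# antibody-capture features spanning orders of magnitude — the statistical
# structure gating assumes, generated deterministically per seed.

#' Specification of a synthetic dataset
#'
#' Defaults describe a small but realistic droplet-style experiment: a few
#' well-separated clusters on a 2-D embedding, negative-binomial
#' (overdispersed) UMI counts, one up-regulated marker gene per cluster, and
#' moderate dropout.
#'
#' @param n_cells number of cells.
#' @param n_genes number of mRNA genes (capture features are extra columns).
#' @param n_clusters number of ground-truth clusters.
#' @param cluster_weights cluster mixing proportions (sum to 1); uniform by
#'   default.
#' @param embedding_centers n_clusters x 2 matrix of cluster centres in the
#'   embedding; defaults to points on a circle of radius `5 * embedding_sd *
#'   n_clusters / pi`, giving ~10-sd nearest-neighbour separation.
#' @param embedding_sd isotropic within-cluster standard deviation.
#' @param marker_table data.frame with columns `gene` (id), `clusters`
#'   (comma-separated 1-based cluster indices) and `fold` (> 1, mean
#'   multiplier); defaults to one marker per cluster (`markerK`) at fold 10.
#' @param baseline_mean negative-binomial mean of a non-marker gene.
#' @param nb_dispersion NB dispersion (variance = mu + dispersion * mu^2).
#' @param dropout_rate probability that any expressed count is zeroed.
#' @param capture_features optional data.frame of antibody-capture features
#'   with columns `name`, `pos_clusters` (comma-separated indices),
#'   `meanlog_pos`, `meanlog_neg`, `sdlog`; counts are rounded log-normals.
#' @param seed RNG seed; the same spec yields the same dataset.
#' @return an object of class `sim_spec`.
#' @export
sim_spec <- function(n_cells = 2000L, n_genes = 100L, n_clusters = 3L,
                     cluster_weights = NULL, embedding_centers = NULL,
                     embedding_sd = 1, marker_table = NULL,
                     baseline_mean = 2, nb_dispersion = 0.5,
                     dropout_rate = 0.1, capture_features = NULL,
                     seed = 1L) {
  if (is.null(cluster_weights)) {
    cluster_weights <- rep(1 / n_clusters, n_clusters)
  }
  if (abs(sum(cluster_weights) - 1) > 1e-8) {
    stop("cluster_weights must sum to 1", call. = FALSE)
  }
  if (length(cluster_weights) != n_clusters) {
    stop("need one weight per cluster", call. = FALSE)
  }
  if (is.null(embedding_centers)) {
    r <- 5 * embedding_sd * n_clusters / pi
    th <- 2 * pi * (seq_len(n_clusters) - 1) / n_clusters
    embedding_centers <- cbind(r * cos(th), r * sin(th))
  }
  embedding_centers <- as.matrix(embedding_centers)
  if (!identical(dim(embedding_centers), c(as.integer(n_clusters), 2L))) {
    stop("embedding_centers must be n_clusters x 2", call. = FALSE)
  }
  if (is.null(marker_table)) {
    marker_table <- data.frame(
      gene = paste0("marker", seq_len(n_clusters)),
      clusters = as.character(seq_len(n_clusters)),
      fold = rep(10, n_clusters), stringsAsFactors = FALSE)
  }
  if (any(marker_table$fold <= 1)) {
    stop("marker folds must exceed 1", call. = FALSE)
  }
  if (nb_dispersion <= 0) stop("nb_dispersion must be positive", call. = FALSE)
  if (dropout_rate < 0 || dropout_rate >= 1) {
    stop("dropout_rate must lie in [0, 1)", call. = FALSE)
  }
  structure(list(n_cells = as.integer(n_cells),
                 n_genes = as.integer(n_genes),
                 n_clusters = as.integer(n_clusters),
                 cluster_weights = cluster_weights,
                 embedding_centers = embedding_centers,
                 embedding_sd = embedding_sd, marker_table = marker_table,
                 baseline_mean = baseline_mean,
                 nb_dispersion = nb_dispersion, dropout_rate = dropout_rate,
                 capture_features = capture_features,
                 seed = as.integer(seed)),
            class = "sim_spec")
}

parse_cluster_field <- function(s) {
  as.integer(strsplit(as.character(s), ",", fixed = TRUE)[[1]])
}

#' Simulate a dataset from a specification
#'
#' Each cell draws a ground-truth cluster from the weights, an embedding
#' coordinate from an isotropic Gaussian at its cluster centre, and UMI
#' counts from a negative binomial whose mean is `baseline_mean` times the
#' marker fold where applicable; counts are then zeroed independently with
#' probability `dropout_rate`. Antibody-capture features (when specified)
#' are rounded log-normal counts with cluster-dependent location, appended
#' as extra count columns. The true cluster (1-based index as string) is
#' stored in annotation `"true_cluster"`, the embedding under `"umap"`.
#'
#' @param spec a [sim_spec()].
#' @return a [CellDataset()].
#' @export
simulate_dataset <- function(spec) {
  stopifnot(inherits(spec, "sim_spec"))
  set.seed(spec$seed)
  n <- spec$n_cells
  g <- spec$n_genes
  cl <- sample.int(spec$n_clusters, n, replace = TRUE,
                   prob = spec$cluster_weights)
  emb <- spec$embedding_centers[cl, , drop = FALSE] +
    matrix(stats::rnorm(2 * n, sd = spec$embedding_sd), n, 2)

  gene_ids <- paste0("gene", seq_len(g))
  marker_idx <- integer(0)
  if (nrow(spec$marker_table)) {
    # markers replace the leading genes so ids match the marker table
    marker_idx <- seq_len(nrow(spec$marker_table))
    gene_ids[marker_idx] <- spec$marker_table$gene
  }
  mu <- matrix(spec$baseline_mean, n, g)
  for (i in seq_along(marker_idx)) {
    in_cl <- cl %in% parse_cluster_field(spec$marker_table$clusters[i])
    mu[in_cl, marker_idx[i]] <- spec$baseline_mean * spec$marker_table$fold[i]
  }
  size <- 1 / spec$nb_dispersion
  counts <- matrix(stats::rnbinom(n * g, size = size, mu = mu), n, g)
  if (spec$dropout_rate > 0) {
    keep <- matrix(stats::runif(n * g) >= spec$dropout_rate, n, g)
    counts <- counts * keep
  }

  if (!is.null(spec$capture_features)) {
    cf <- spec$capture_features
    cap <- matrix(0L, n, nrow(cf))
    for (i in seq_len(nrow(cf))) {
      pos <- cl %in% parse_cluster_field(cf$pos_clusters[i])
      meanlog <- ifelse(pos, cf$meanlog_pos[i], cf$meanlog_neg[i])
      cap[, i] <- as.integer(round(stats::rlnorm(n, meanlog, cf$sdlog[i])))
    }
    counts <- cbind(counts, cap)
    gene_ids <- c(gene_ids, cf$name)
  }

  dimnames(counts) <- list(sprintf("cell%05d", seq_len(n)), gene_ids)
  ds <- CellDataset(counts)
  ds <- set_annotation(ds, "true_cluster", as.character(cl))
  ds <- attach_embedding(ds, "umap", emb)
  ds
}

#' Analytic reference gate for a simulated cluster
#'
#' A convex regular polygon centred on the cluster's embedding centre whose
#' circumscribed radius is the `q`-quantile radius of the cluster's
#' isotropic 2-D Gaussian (`sd * sqrt(qchisq(q, 2))`), so the expected
#' fraction of the cluster's cells inside is slightly below `q` (the polygon
#' is inscribed in the quantile circle).
#'
#' @param spec the [sim_spec()] that generated the dataset.
#' @param cluster 1-based cluster index.
#' @param q coverage quantile in (0, 1); default 0.95.
#' @param n_vertices number of polygon vertices; default 16.
#' @param name optional polygon name.
#' @return a [gate_polygon()].
#' @export
reference_polygon <- function(spec, cluster, q = 0.95, n_vertices = 16L,
                              name = NULL) {
  stopifnot(inherits(spec, "sim_spec"), cluster >= 1,
            cluster <= spec$n_clusters, q > 0, q < 1)
  centre <- spec$embedding_centers[cluster, ]
  r <- spec$embedding_sd * sqrt(stats::qchisq(q, df = 2))
  th <- 2 * pi * (seq_len(n_vertices) - 1) / n_vertices
  gate_polygon(cbind(centre[1] + r * cos(th), centre[2] + r * sin(th)),
               name = name)
}

#' Read / write a simulation spec as JSON
#' @param spec a [sim_spec()].
#' @param path JSON path.
#' @return `write_sim_spec`: `path` invisibly; `read_sim_spec`: a
#'   [sim_spec()].
#' @export
write_sim_spec <- function(spec, path) {
  obj <- unclass(spec)
  obj$embedding_centers <- apply(spec$embedding_centers, 1, as.numeric,
                                 simplify = FALSE)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = I(17),
                       dataframe = "rows")
  invisible(path)
}

#' @rdname write_sim_spec
#' @export
read_sim_spec <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  centers <- obj$embedding_centers
  if (!is.null(centers) && !is.matrix(centers)) {
    centers <- do.call(rbind, lapply(centers, as.numeric))
  }
  cf <- obj$capture_features
  if (!is.data.frame(cf) || nrow(cf) == 0L) cf <- NULL
  sim_spec(n_cells = obj$n_cells, n_genes = obj$n_genes,
           n_clusters = obj$n_clusters,
           cluster_weights = obj$cluster_weights,
           embedding_centers = centers,
           embedding_sd = obj$embedding_sd,
           marker_table = obj$marker_table,
           baseline_mean = obj$baseline_mean,
           nb_dispersion = obj$nb_dispersion,
           dropout_rate = obj$dropout_rate,
           capture_features = cf,
           seed = obj$seed)
}
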