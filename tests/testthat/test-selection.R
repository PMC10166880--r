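test_that("embedding selection labels cells inside the gate, rest outside", {
  spec <- sim_spec(n_cells = 800, n_clusters = 2, seed = 21)
  ds <- simulate_dataset(spec)
  gate <- reference_polygon(spec, 1, q = 0.95)
  polys <- polygon_set(list(gate), embedding_axes("umap"))
  res <- select_on_embedding(ds, "umap", polys, "sel")

  set.seed(99)
  want <- oracle_pip(get_embedding(ds, "umap"), gate$vertices)
  off <- dist_to_boundary(get_embedding(ds, "umap"), gate$vertices) > 1e-7
  expect_identical(res$membership[off, 1], want[off])
  expect_identical(res$labels, ifelse(res$membership[, 1], "0", "rest"))
  expect_identical(get_annotation(res$dataset, "sel"), res$labels)
  expect_identical(names(res$dataset$polygon_store), "sel")

  # most of cluster 1 is inside, almost none of cluster 2
  cl <- get_annotation(ds, "true_cluster")
  expect_gt(mean(res$membership[cl == "1", 1]), 0.9)
  expect_lt(mean(res$membership[cl == "2", 1]), 0.01)
})

test_that("a gate far from all cells selects nothing", {
  spec <- sim_spec(n_cells = 100, seed = 5)
  ds <- simulate_dataset(spec)
  far <- gate_polygon(rbind(c(900, 900), c(901, 900), c(901, 901)))
  res <- select_on_embedding(ds, "umap",
                             polygon_set(list(far), embedding_axes("umap")),
                             "sel")
  expect_true(all(res$labels == "rest"))
  expect_false(any(res$membership))
})

test_that("re-running a selection under the same key is idempotent", {
  spec <- sim_spec(n_cells = 200, seed = 8)
  ds <- simulate_dataset(spec)
  polys <- polygon_set(list(reference_polygon(spec, 1)),
                       embedding_axes("umap"))
  r1 <- select_on_embedding(ds, "umap", polys, "sel")
  expect_message(r2 <- select_on_embedding(r1$dataset, "umap", polys, "sel"),
                 "overwriting")
  expect_identical(r2$labels, r1$labels)
  expect_identical(colnames(r2$dataset$annotations),
                   colnames(r1$dataset$annotations))
})

test_that("axes-context mismatches are rejected", {
  spec <- sim_spec(n_cells = 50, seed = 2)
  ds <- simulate_dataset(spec)
  polys <- polygon_set(list(reference_polygon(spec, 1)),
                       embedding_axes("tsne"))
  expect_error(select_on_embedding(ds, "umap", polys, "k"),
               "drawn on embedding 'tsne'")
  expect_error(select_on_embedding(ds, "tsne", polys, "k"),
               "unknown embedding")
  sc <- polygon_set(list(unit_square()), scatter_axes("gene1", "gene2"))
  expect_error(select_on_embedding(ds, "umap", sc, "k"), "scatter")
  expect_error(select_on_scatter(ds, polys, "k"), "embedding")
})

test_that("scatter gating in log10 space reproduces the four CD4/CD8 gates", {
  counts <- rbind(c(100L, 1L), c(1L, 100L), c(50L, 50L), c(0L, 0L))
  colnames(counts) <- c("CD4", "CD8")
  ds <- CellDataset(cbind(counts, other = rep(1L, 4)))
  rect <- function(x0, x1, y0, y1, name) {
    gate_polygon(rbind(c(x0, y0), c(x1, y0), c(x1, y1), c(x0, y1)), name)
  }
  # gates drawn in the displayed (log10) coordinate system; 10 counts = 1.0
  polys <- polygon_set(
    list(rect(1, 3, -1, 1, "CD4"), rect(-1, 1, 1, 3, "CD8"),
         rect(1, 3, 1, 3, "DP")),
    scatter_axes("CD4", "CD8", x_scale = "log10", y_scale = "log10"))
  res <- select_on_scatter(ds, polys, "gate")
  expect_identical(res$labels, c("CD4", "CD8", "DP", "rest"))

  # a log-space gate containing (log10 100, log10 1) = (2, 0)
  lg <- polygon_set(list(rect(1, 3, -0.5, 0.5, "hit")),
                    scatter_axes("CD4", "CD8", x_scale = "log10",
                                 y_scale = "log10"))
  expect_identical(select_on_scatter(ds, lg, "k2")$labels[1], "hit")
})

test_that("log10 display gating equals gating log10 values linearly", {
  spec <- sim_spec(n_cells = 500, seed = 31,
                   capture_features = data.frame(
                     name = c("CD4", "CD8"), pos_clusters = c("1", "2"),
                     meanlog_pos = log(300), meanlog_neg = log(3),
                     sdlog = 0.6))
  ds <- simulate_dataset(spec)
  verts <- rbind(c(1, -1), c(4, -1), c(4, 1.5), c(1, 1.5))
  log_polys <- polygon_set(list(gate_polygon(verts, "g")),
                           scatter_axes("CD4", "CD8", x_scale = "log10",
                                        y_scale = "log10"))
  res_log <- select_on_scatter(ds, log_polys, "a")

  x <- feature_values(ds, "CD4"); y <- feature_values(ds, "CD8")
  pos <- x > 0 & y > 0
  lin <- point_in_polygon(cbind(log10(x[pos]), log10(y[pos])),
                          gate_polygon(verts, "g"))
  expect_identical(res_log$membership[pos, 1], lin)

  # zero counts sit at log10(zero_offset), so they are gateable
  zero_gate <- polygon_set(
    list(gate_polygon(rbind(c(-0.5, -0.5), c(-0.1, -0.5), c(-0.1, -0.1),
                            c(-0.5, -0.1)), "z")),
    scatter_axes("CD4", "CD8", x_scale = "log10", y_scale = "log10"))
  rz <- select_on_scatter(ds, zero_gate, "z")
  expect_identical(rz$membership[, 1], x == 0 & y == 0)
  # and the pseudo-position follows zero_offset
  sc <- scatter_coords(ds, zero_gate$axes, zero_offset = 0.25)
  expect_equal(sc[x == 0, 1], rep(log10(0.25), sum(x == 0)))
})

test_that("negative values are a domain error under log10 scale", {
  ds <- CellDataset(matrix(c(1L, 2L, 3L, 4L), 2,
                           dimnames = list(NULL, c("a", "b"))))
  ds$normalized <- matrix(c(-1, 1, 1, 1), 2)
  ax <- scatter_axes("a", "b", layer = "normalized", x_scale = "log10")
  expect_error(scatter_coords(ds, ax), "non-negative")
})

test_that("normalized layer is computed on the fly for scatter gating", {
  counts <- matrix(c(0L, 10L, 4L, 6L), 2,
                   dimnames = list(NULL, c("CCR7", "SELL")))
  ds <- CellDataset(counts)
  ax <- scatter_axes("CCR7", "SELL", layer = "normalized")
  expect_identical(scatter_coords(ds, ax),
                   unname(normalized_layer(ds)[, 1:2]))
})

test_that("rename_labels rewrites whole labels and validates sources", {
  ds <- CellDataset(matrix(1L, 6, 2))
  ds <- set_annotation(ds, "sel", c("0", "1", "rest", "0", "0,1", "1"))
  out <- rename_labels(ds, "sel", c("0" = "TH1", "1" = "TH17"))
  expect_identical(get_annotation(out, "sel"),
                   c("TH1", "TH17", "rest", "TH1", "0,1", "TH17"))
  # composite labels rename as whole strings
  out2 <- rename_labels(out, "sel", c("0,1" = "TH1/17"))
  expect_identical(get_annotation(out2, "sel")[5], "TH1/17")
  expect_identical(get_annotation(rename_labels(ds, "sel", character()),
                                  "sel"),
                   get_annotation(ds, "sel"))
  expect_error(rename_labels(ds, "sel", c("2" = "X")), "valid labels")
  expect_warning(rename_labels(ds, "sel", c("0" = "1")), "merges")
})

test_that("sessions survive the JSON round trip and re-apply identically", {
  spec <- sim_spec(n_cells = 400, n_clusters = 3, seed = 13)
  ds <- simulate_dataset(spec)
  polys <- polygon_set(list(reference_polygon(spec, 1),
                            reference_polygon(spec, 2)),
                       embedding_axes("umap"))
  res <- select_on_embedding(ds, "umap", polys, "sel")
  path <- tempfile(fileext = ".json")
  save_session(res$dataset, "sel", path)
  loaded <- load_session(path)
  expect_identical(lapply(loaded$polygons, `[[`, "vertices"),
                   lapply(polys$polygons, `[[`, "vertices"))
  res2 <- apply_session(ds, loaded, "sel2")
  expect_identical(res2$labels, res$labels)
  expect_error(save_session(ds, "nope", tempfile()), "no polygon session")

  # a session bound to an embedding the dataset lacks is a context error
  other <- CellDataset(matrix(0L, 5, 2))
  expect_error(apply_session(other, loaded, "x"), "unknown embedding")
})

test_that("subset consistency: labels survive removal of other cells", {
  spec <- sim_spec(n_cells = 600, n_clusters = 2, seed = 17)
  ds <- simulate_dataset(spec)
  polys <- polygon_set(list(reference_polygon(spec, 1)),
                       embedding_axes("umap"))
  res <- select_on_embedding(ds, "umap", polys, "sel")
  kept <- drop_label(res$dataset, "sel", "rest")
  res2 <- select_on_embedding(kept, "umap", polys, "sel2")
  expect_identical(res2$labels, get_annotation(kept, "sel"))
})

test_that("dropping a composite label removes exactly the intersection", {
  spec <- sim_spec(n_cells = 1000, n_clusters = 2, seed = 19,
                   embedding_centers = rbind(c(0, 0), c(3, 0)))
  ds <- simulate_dataset(spec)
  a <- reference_polygon(spec, 1, q = 0.9, name = "A")
  b <- reference_polygon(spec, 2, q = 0.9, name = "B")
  res <- select_on_embedding(ds, "umap",
                             polygon_set(list(a, b), embedding_axes("umap")),
                             "sel")
  inter <- res$membership[, "A"] & res$membership[, "B"]
  expect_gt(sum(inter), 0)  # the scenario needs a real overlap
  reduced <- drop_label(res$dataset, "sel", "A,B")
  expect_identical(n_cells(reduced), n_cells(ds) - sum(inter))
  expect_identical(reduced$cell_ids, ds$cell_ids[!inter])
})
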