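#' Polygon gate
#'
#' An ordered list of at least three vertices; the polygon is implicitly
#' closed (last vertex joins the first). Convexity and non-self-intersection
#' are not required: hand-drawn gates can self-intersect, and membership is
#' resolved by the even-odd rule. A zero-area polygon is accepted with a
#' warning and matches only points on its boundary.
#'
#' @param vertices numeric matrix (m x 2) or list of `c(x, y)` pairs, m >= 3.
#' @param name optional polygon name; when `NULL` a default decimal-integer
#'   name is assigned by [polygon_set()] in drawing order starting at "0".
#' @return an object of class `gate_polygon`.
#' @export
#' @examples
#' sq <- gate_polygon(rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1)))
#' point_in_polygon(c(0.5, 0.5), sq)
gate_polygon <- function(vertices, name = NULL) {
  if (is.list(vertices)) {
    vertices <- do.call(rbind, lapply(vertices, as.numeric))
  }
  vertices <- as.matrix(vertices)
  if (ncol(vertices) != 2L) {
    stop("polygon vertices must be (x, y) pairs", call. = FALSE)
  }
  if (nrow(vertices) < 3L) {
    stop("a polygon needs at least 3 vertices", call. = FALSE)
  }
  if (!all(is.finite(vertices))) {
    stop("polygon vertices must be finite", call. = FALSE)
  }
  storage.mode(vertices) <- "double"
  colnames(vertices) <- c("x", "y")
  if (polygon_degenerate(vertices)) {
    warning("polygon has zero area; it will match only boundary points",
            call. = FALSE)
  }
  structure(list(name = name, vertices = vertices), class = "gate_polygon")
}

# All vertices collinear (the ring encloses no area). The shoelace sum is
# not used here because opposite windings of a self-intersecting ring can
# cancel to zero while still enclosing area.
polygon_degenerate <- function(v) {
  a <- v[1, ]
  d <- sweep(v[-1, , drop = FALSE], 2, a)
  ref <- d[which.max(rowSums(d^2)), ]
  all(abs(d[, 1] * ref[2] - d[, 2] * ref[1]) < 1e-12)
}

#' Axes context for a polygon set
#'
#' Gates are only meaningful in the coordinate system they were drawn in.
#' `embedding_axes` binds a set to a named 2-D embedding; `scatter_axes`
#' binds it to a pair of features under a layer and per-axis scales. Under a
#' `log10` scale the polygon vertices live in the displayed (log-transformed)
#' coordinate system.
#'
#' @param embedding_name embedding name, e.g. `"umap"`.
#' @return an object of class `axes_context`.
#' @export
embedding_axes <- function(embedding_name) {
  structure(list(kind = "embedding", embedding_name = embedding_name),
            class = "axes_context")
}

#' @rdname embedding_axes
#' @param x_feature,y_feature gene or antibody-capture feature ids.
#' @param layer `"raw"` or `"normalized"`.
#' @param x_scale,y_scale `"linear"` or `"log10"`.
#' @export
scatter_axes <- function(x_feature, y_feature, layer = c("raw", "normalized"),
                         x_scale = c("linear", "log10"),
                         y_scale = c("linear", "log10")) {
  structure(list(kind = "scatter", x_feature = x_feature,
                 y_feature = y_feature, layer = match.arg(layer),
                 x_scale = match.arg(x_scale), y_scale = match.arg(y_scale)),
            class = "axes_context")
}

#' A named, ordered collection of polygons bound to an axes context
#'
#' Polygons without an explicit name receive the default decimal-integer
#' names `"0", "1", ...` in drawing (list) order, mirroring gate numbering in
#' interactive use. Names must be unique within the set.
#'
#' @param polygons a list of [gate_polygon()] objects (bare vertex matrices
#'   are accepted and wrapped).
#' @param axes an [embedding_axes()] or [scatter_axes()] context.
#' @return an object of class `polygon_set`.
#' @export
polygon_set <- function(polygons, axes) {
  stopifnot(inherits(axes, "axes_context"))
  if (inherits(polygons, "gate_polygon")) polygons <- list(polygons)
  polygons <- lapply(polygons, function(p) {
    if (inherits(p, "gate_polygon")) p else gate_polygon(p)
  })
  next_default <- 0L
  for (i in seq_along(polygons)) {
    if (is.null(polygons[[i]]$name)) {
      polygons[[i]]$name <- as.character(next_default)
      next_default <- next_default + 1L
    }
  }
  nms <- vapply(polygons, `[[`, "", "name")
  if (anyDuplicated(nms)) {
    stop("polygon names must be unique within a set: ",
         paste(nms[duplicated(nms)], collapse = ", "), call. = FALSE)
  }
  structure(list(axes = axes, polygons = polygons), class = "polygon_set")
}

#' Polygon names of a set, in drawing order
#' @param polys a `polygon_set`.
#' @return character vector.
#' @export
polygon_names <- function(polys) {
  vapply(polys$polygons, `[[`, "", "name")
}

#' Even-odd point-in-polygon test
#'
#' Crossing-number (even-odd) rule: a point is inside iff a horizontal ray
#' from it crosses the polygon boundary an odd number of times. This is
#' well-defined for self-intersecting polygons. Points within `tol` of an
#' edge or vertex count as inside, making gates closed sets as in flow
#' cytometry.
#'
#' @param p numeric `c(x, y)` pair, or an n x 2 matrix of points.
#' @param poly a [gate_polygon()].
#' @param tol boundary tolerance (absolute distance).
#' @return logical scalar (or vector of length n for a matrix of points).
#' @export
point_in_polygon <- function(p, poly, tol = 1e-9) {
  stopifnot(inherits(poly, "gate_polygon"))
  pts <- if (is.matrix(p)) p else matrix(p, ncol = 2)
  pip_batch(pts, poly$vertices, tol)
}

# Vectorized even-odd test of n points against one vertex ring.
# Loops over edges (few) with vectorized work over points (many).
pip_batch <- function(pts, v, tol = 1e-9) {
  px <- pts[, 1]; py <- pts[, 2]
  n <- length(px)
  m <- nrow(v)
  inside <- logical(n)
  boundary <- logical(n)
  j <- m
  for (i in seq_len(m)) {
    xi <- v[i, 1]; yi <- v[i, 2]
    xj <- v[j, 1]; yj <- v[j, 2]
    # crossing test on the half-open edge
    crosses <- ((yi > py) != (yj > py))
    if (any(crosses)) {
      xint <- xi + (py[crosses] - yi) * (xj - xi) / (yj - yi)
      flip <- which(crosses)[px[crosses] < xint]
      inside[flip] <- !inside[flip]
    }
    # distance from each point to segment (xi,yi)-(xj,yj)
    dx <- xj - xi; dy <- yj - yi
    len2 <- dx * dx + dy * dy
    if (len2 == 0) {
      d2 <- (px - xi)^2 + (py - yi)^2
    } else {
      t <- pmin(1, pmax(0, ((px - xi) * dx + (py - yi) * dy) / len2))
      d2 <- (px - (xi + t * dx))^2 + (py - (yi + t * dy))^2
    }
    boundary <- boundary | d2 <= tol^2
    j <- i
  }
  inside | boundary
}

#' Boolean membership of points in every polygon of a set
#'
#' @param points numeric n x 2 matrix of finite coordinates.
#' @param polys a [polygon_set()] with at least one polygon.
#' @param tol boundary tolerance passed to [point_in_polygon()].
#' @return logical n x k matrix; column j is membership in the j-th polygon,
#'   columns named and ordered as the polygons in the set.
#' @export
membership_matrix <- function(points, polys, tol = 1e-9) {
  stopifnot(inherits(polys, "polygon_set"))
  if (length(polys$polygons) == 0L) {
    stop("polygon set is empty: nothing to select", call. = FALSE)
  }
  points <- as.matrix(points)
  if (!all(is.finite(points))) {
    stop("points must be finite", call. = FALSE)
  }
  m <- vapply(polys$polygons,
              function(p) pip_batch(points, p$vertices, tol),
              logical(nrow(points)))
  m <- matrix(m, nrow = nrow(points))
  colnames(m) <- polygon_names(polys)
  m
}

#' Collapse a membership matrix to one label per cell
#'
#' Each cell's label is the comma-joined names of every polygon containing
#' it, in polygon drawing order (so a cell inside both the CCR7 and SELL
#' gates is labelled `"CCR7,SELL"`); cells inside no polygon receive
#' `outside_label`.
#'
#' @param m logical n x k membership matrix.
#' @param names character vector of k unique polygon names.
#' @param outside_label label for cells in no polygon; default `"rest"`.
#' @param sep label separator; default `","`.
#' @return character vector of n labels.
#' @export
labels_from_membership <- function(m, names = colnames(m),
                                   outside_label = "rest", sep = ",") {
  m <- as.matrix(m)
  if (length(names) != ncol(m)) {
    stop("need one name per membership column", call. = FALSE)
  }
  if (anyDuplicated(names)) {
    stop("polygon names must be unique", call. = FALSE)
  }
  labels <- apply(m, 1L, function(row) {
    if (any(row)) paste(names[row], collapse = sep) else outside_label
  })
  as.character(labels)
}
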