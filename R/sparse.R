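#' Sparse samples: lists, k-d trees, extrapolation
#'
#' Sparsely and irregularly sampled data are held either as a plain sample
#' list or in a k-d tree; both implement the same search interface
#' (nearest neighbour, k nearest, radius), so the linear scan over the list
#' doubles as the reference the tree is validated against. A
#' nearest-neighbour field turns either structure into a continuous
#' (piecewise-constant, Voronoi) image defined on all of real space.
#'
#' The metric is Euclidean; distance ties are broken by insertion order,
#' which makes every search deterministic across platforms.
#'
#' @name sparse
NULL

#' A list of sample points
#' @param coords an N x n matrix of finite real coordinates
#' @param values a vector (or list) of N sample values
#' @return an object of class `nd_points`
#' @export
nd_points <- function(coords, values) {
  coords <- as.matrix(coords)
  if (nrow(coords) < 1) nd_stop("at least one sample point is required")
  if (!all(is.finite(coords))) nd_stop("sample coordinates must be finite")
  if (length(values) != nrow(coords))
    nd_stop("need exactly one value per sample point")
  structure(list(coords = coords, values = values, n = ncol(coords)),
            class = "nd_points")
}

#' @export
print.nd_points <- function(x, ...) {
  cat("<nd_points> ", nrow(x$coords), " points in ", x$n, "-D\n", sep = "")
  invisible(x)
}

check_query <- function(obj, q) {
  if (length(q) != obj$n)
    nd_stop("query dimensionality ", length(q),
            " does not match the stored points (", obj$n, "-D)")
  if (!all(is.finite(q))) nd_stop("query coordinates must be finite")
}

dist2_to_all <- function(coords, q) {
  d2 <- numeric(nrow(coords))
  for (d in seq_len(ncol(coords))) d2 <- d2 + (coords[, d] - q[d])^2
  d2
}

# scalar twin of dist2_to_all with the same accumulation order, so tree
# and scan produce bitwise-identical distances
dist2_one <- function(p, q) {
  d2 <- 0
  for (d in seq_along(p)) d2 <- d2 + (p[d] - q[d])^2
  d2
}

## ---- k-d tree --------------------------------------------------------------

#' Build a balanced k-d tree
#'
#' Split dimension cycles with depth; each node takes the lower median of a
#' stable sort along the split dimension, so the left subtree holds
#' coordinates `<=` the node's, the right subtree `>=`, and the depth is at
#' most `ceil(log2(N)) + 1`.
#' @param points an [nd_points()], or an N x n coordinate matrix
#' @param values sample values when `points` is a matrix
#' @return an object of class `nd_kdtree`
#' @export
build_kdtree <- function(points, values = NULL) {
  if (!inherits(points, "nd_points")) points <- nd_points(points, values)
  coords <- points$coords
  n <- ncol(coords)
  build <- function(idx, depth) {
    if (length(idx) == 0) return(NULL)
    dim <- (depth %% n) + 1
    ord <- idx[order(coords[idx, dim], idx)]
    m <- (length(ord) + 1) %/% 2
    list(idx = ord[m], dim = dim,
         left = build(ord[seq_len(m - 1)], depth + 1),
         right = build(ord[seq_len(length(ord) - m) + m], depth + 1))
  }
  structure(list(coords = coords, values = points$values, n = n,
                 root = build(seq_len(nrow(coords)), 0)),
            class = "nd_kdtree")
}

#' @rdname build_kdtree
#' @param tree an `nd_kdtree`
#' @return `kdtree_depth`: number of levels; `kdtree_indices`: the stored
#'   point indices from an in-order traversal
#' @export
kdtree_depth <- function(tree) {
  depth <- function(node) if (is.null(node)) 0
    else 1 + max(depth(node$left), depth(node$right))
  depth(tree$root)
}

#' @rdname build_kdtree
#' @export
kdtree_indices <- function(tree) {
  walk <- function(node) {
    if (is.null(node)) return(numeric(0))
    c(walk(node$left), node$idx, walk(node$right))
  }
  walk(tree$root)
}

## ---- searches --------------------------------------------------------------

search_result <- function(obj, idx, d2) {
  idx <- as.integer(idx)
  list(index = idx, coords = obj$coords[idx, ], value = obj$values[[idx]],
       dist = sqrt(d2))
}

search_results <- function(obj, idx, d2) {
  idx <- as.integer(idx)
  list(index = idx, coords = obj$coords[idx, , drop = FALSE],
       values = obj$values[idx], dist = sqrt(d2))
}

#' Nearest-neighbour, k-NN and radius search
#'
#' Dispatches on the storage: the k-d tree uses branch-and-bound, the
#' sample list a linear scan; the two agree exactly (including
#' tie-breaking by insertion order). `knn_search` returns the k nearest in
#' non-decreasing distance order; `radius_search` all points within `r`,
#' sorted the same way.
#' @param x an `nd_kdtree` or `nd_points`
#' @param q a finite query coordinate of matching dimensionality
#' @return `nn_search`: `list(index, coords, value, dist)`; the others:
#'   `list(index, coords, values, dist)` with one entry per hit
#' @export
nn_search <- function(x, q) UseMethod("nn_search")

#' @export
nn_search.nd_points <- function(x, q) {
  check_query(x, q)
  d2 <- dist2_to_all(x$coords, q)
  best <- which(d2 == min(d2))[1]   # earliest insertion among ties
  search_result(x, best, d2[best])
}

#' @export
nn_search.nd_kdtree <- function(x, q) {
  check_query(x, q)
  best_idx <- NA_real_
  best_d2 <- Inf
  coords <- x$coords
  descend <- function(node) {
    if (is.null(node)) return(invisible(NULL))
    p <- coords[node$idx, ]
    d2 <- dist2_one(p, q)
    if (d2 < best_d2 || (d2 == best_d2 && node$idx < best_idx)) {
      best_d2 <<- d2
      best_idx <<- node$idx
    }
    delta <- q[node$dim] - p[node$dim]
    first <- if (delta <= 0) node$left else node$right
    second <- if (delta <= 0) node$right else node$left
    descend(first)
    if (delta^2 <= best_d2) descend(second)
  }
  descend(x$root)
  search_result(x, best_idx, best_d2)
}

#' @rdname nn_search
#' @param k number of neighbours, `1 <= k <= N`
#' @export
knn_search <- function(x, q, k) UseMethod("knn_search")

check_k <- function(x, k) {
  if (k < 1 || k > nrow(x$coords))
    nd_stop("k must be between 1 and the number of stored points (",
            nrow(x$coords), ")")
}

#' @export
knn_search.nd_points <- function(x, q, k) {
  check_query(x, q); check_k(x, k)
  d2 <- dist2_to_all(x$coords, q)
  ord <- order(d2, seq_along(d2))[seq_len(k)]
  search_results(x, ord, d2[ord])
}

#' @export
knn_search.nd_kdtree <- function(x, q, k) {
  check_query(x, q); check_k(x, k)
  coords <- x$coords
  cand_idx <- numeric(0)
  cand_d2 <- numeric(0)
  worst <- function() if (length(cand_d2) < k) Inf else cand_d2[k]
  descend <- function(node) {
    if (is.null(node)) return(invisible(NULL))
    p <- coords[node$idx, ]
    d2 <- dist2_one(p, q)
    if (d2 < worst() ||
        (d2 == worst() && length(cand_d2) == k && node$idx < cand_idx[k])) {
      ord <- order(c(cand_d2, d2), c(cand_idx, node$idx))
      cand_idx <<- c(cand_idx, node$idx)[ord][seq_len(min(k, length(ord)))]
      cand_d2 <<- c(cand_d2, d2)[ord][seq_len(min(k, length(ord)))]
    }
    delta <- q[node$dim] - p[node$dim]
    first <- if (delta <= 0) node$left else node$right
    second <- if (delta <= 0) node$right else node$left
    descend(first)
    if (delta^2 <= worst()) descend(second)
  }
  descend(x$root)
  search_results(x, cand_idx, cand_d2)
}

#' @rdname nn_search
#' @param r search radius, `r >= 0`
#' @export
radius_search <- function(x, q, r) UseMethod("radius_search")

#' @export
radius_search.nd_points <- function(x, q, r) {
  check_query(x, q)
  if (r < 0) nd_stop("radius must be >= 0")
  d2 <- dist2_to_all(x$coords, q)
  hit <- which(d2 <= r^2)
  hit <- hit[order(d2[hit], hit)]
  search_results(x, hit, d2[hit])
}

#' @export
radius_search.nd_kdtree <- function(x, q, r) {
  check_query(x, q)
  if (r < 0) nd_stop("radius must be >= 0")
  r2 <- r^2
  coords <- x$coords
  hit_idx <- numeric(0)
  hit_d2 <- numeric(0)
  descend <- function(node) {
    if (is.null(node)) return(invisible(NULL))
    p <- coords[node$idx, ]
    d2 <- dist2_one(p, q)
    if (d2 <= r2) {
      hit_idx <<- c(hit_idx, node$idx)
      hit_d2 <<- c(hit_d2, d2)
    }
    delta <- q[node$dim] - p[node$dim]
    if (delta <= 0 || delta^2 <= r2) descend(node$left)
    if (delta >= 0 || delta^2 <= r2) descend(node$right)
  }
  descend(x$root)
  ord <- order(hit_d2, hit_idx)
  search_results(x, hit_idx[ord], hit_d2[ord])
}

## ---- extrapolation ---------------------------------------------------------

#' Extrapolate sparse samples into a continuous image
#'
#' The resulting unbounded continuous image returns, at every real
#' coordinate, the value of the nearest stored sample — a piecewise
#' constant Voronoi field. Combine with [rasterize()] and [window()] to
#' sample it onto a grid.
#' @param points an [nd_points()] or prebuilt [build_kdtree()] index
#' @export
nn_extrapolate <- function(points) {
  tree <- if (inherits(points, "nd_kdtree")) points else build_kdtree(points)
  structure(list(tree = tree, n = tree$n),
            class = c("nd_nnfield", "nd_real"))
}

#' @export
real_get_many.nd_nnfield <- function(rimg, X) {
  out <- vector(mode(rimg$tree$values), nrow(X))
  for (i in seq_len(nrow(X)))
    out[[i]] <- nn_search(rimg$tree, X[i, ])$value
  out
}

## ---- CSV interchange -------------------------------------------------------

#' Read / write sparse samples as CSV
#'
#' One row per point: n coordinate columns named `x0, x1, ...` followed by
#' one `value` column; the header row is required.
#' @param path file path
#' @export
read_points_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  cols <- names(df)
  if (cols[length(cols)] != "value" ||
      !all(grepl("^x[0-9]+$", cols[-length(cols)])))
    nd_stop("'", path, "': expected header x0,x1,...,value; found: ",
            paste(cols, collapse = ","))
  nd_points(as.matrix(df[, -length(cols), drop = FALSE]), df$value)
}

#' @rdname read_points_csv
#' @param points an [nd_points()]
#' @export
write_points_csv <- function(points, path) {
  df <- as.data.frame(points$coords)
  names(df) <- paste0("x", seq_len(points$n) - 1)
  df$value <- points$values
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
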