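#' Generic n-dimensional algorithms
#'
#' Every algorithm here is written against the generic access layer only:
#' samples are read through the image's accessors (including any view
#' composition and out-of-bounds extension) and results are written through
#' a factory. The same call therefore produces identical output whether the
#' input lives in an array, cell or list backend, at any dimensionality,
#' and whether it is a raw image or a translated/permuted/extended view.
#'
#' @name algorithms
NULL

# read the (extension-folded) samples of img over its interval grown by
# `margin` per dimension into a plain array
materialize_grown <- function(img, margin, extension) {
  iv <- img_interval(img)
  grown <- nd_interval(iv$min - margin, iv$max + margin)
  materialize(extend(img, extension), grown)
}

# correlation along dimension d of array A, consuming a margin of h:
# out(p) = sum_t k[t+h+1] * A(p + t), t = -h..h
correlate_1d <- function(A, d, k) {
  h <- (length(k) - 1) / 2
  dims <- dim(A)
  if (is.null(dims)) dims <- length(A)
  n <- length(dims)
  perm <- c(d, seq_len(n)[-d])
  M <- aperm(array(A, dims), perm)
  dm <- dim(M)
  M <- matrix(M, nrow = dm[1])
  len_out <- dm[1] - 2 * h
  out <- matrix(0, len_out, ncol(M))
  for (t in seq_along(k)) {
    if (k[t] == 0) next
    out <- out + k[t] * M[(t - 1) + seq_len(len_out), , drop = FALSE]
  }
  out <- array(out, c(len_out, dm[-1]))
  aperm(out, order(perm))
}

finish_image <- function(arr, factory, min) {
  out <- image_from_array(arr, factory)
  if (any(min != 0)) out <- translate(out, min)
  out
}

#' Sampled Gaussian kernel
#'
#' Truncated at `max(2, ceiling(3 * sigma))` samples each side and
#' normalized to sum exactly 1; `sigma = 0` yields the identity kernel.
#' @param sigma standard deviation in pixels, `>= 0`
#' @export
gaussian_kernel <- function(sigma) {
  if (sigma < 0) nd_stop("sigma must be >= 0")
  if (sigma == 0) return(1)
  h <- max(2, ceiling(3 * sigma))
  w <- exp(-(-h:h)^2 / (2 * sigma^2))
  w / sum(w)
}

#' Separable correlation with per-dimension kernels
#'
#' One 1-D pass per dimension; boundary samples are generated by the given
#' extension strategy. Kernels use correlation orientation:
#' `out(p) = sum_t k[t] * in(p + t)`.
#' @param img a bounded image or view
#' @param kernels list of odd-length numeric kernels, one per dimension
#' @param extension out-of-bounds strategy (kind string or
#'   [extension_strategy()])
#' @param factory output backend/type
#' @export
separable_convolve <- function(img, kernels,
                               extension = "mirror_single",
                               factory = image_factory("array", "f64")) {
  n <- img_ndim(img)
  stopifnot(length(kernels) == n)
  h <- vapply(kernels, function(k) (length(k) - 1) / 2, numeric(1))
  A <- materialize_grown(img, h, extension)
  for (d in seq_len(n)) if (h[d] > 0) A <- correlate_1d(A, d, kernels[[d]])
  finish_image(A, factory, img_interval(img)$min)
}

#' Gaussian convolution
#'
#' Separable convolution with per-dimension sampled Gaussian kernels (see
#' [gaussian_kernel()]); out-of-bounds samples come from `extension`
#' (mirroring without border repetition by default).
#' @param img a bounded image or view
#' @param sigmas standard deviations, recycled over dimensions
#' @inheritParams separable_convolve
#' @export
gaussian_convolve <- function(img, sigmas,
                              extension = "mirror_single",
                              factory = image_factory("array", "f64")) {
  n <- img_ndim(img)
  sigmas <- rep_len(sigmas, n)
  if (any(sigmas < 0)) nd_stop("sigma must be >= 0")
  separable_convolve(img, lapply(sigmas, gaussian_kernel),
                     extension, factory)
}

#' Sobel gradients
#'
#' For each dimension `d`: derivative kernel `(-1, 0, 1)` along `d`
#' (so `out = in(p+1) - in(p-1)`, positive along increasing coordinates)
#' and smoothing kernel `(1, 2, 1)` along every other dimension. On a unit
#' ramp along `d` the interior response is `2 * 4^(n-1)` (derivative gain 2
#' times the smoothing mass per remaining dimension).
#' @inheritParams separable_convolve
#' @return a list of gradient images, one per dimension
#' @export
sobel <- function(img, extension = "mirror_single",
                  factory = image_factory("array", "f64")) {
  n <- img_ndim(img)
  lapply(seq_len(n), function(d) {
    kernels <- rep(list(c(1, 2, 1)), n)
    kernels[[d]] <- c(-1, 0, 1)
    separable_convolve(img, kernels, extension, factory)
  })
}

## ---- difference-of-Gaussians interest points ------------------------------

# strict local extrema of array A over the full 3^n - 1 neighborhood;
# only pixels whose whole neighborhood lies inside are candidates
local_extrema <- function(A) {
  dims <- dim(A)
  if (is.null(dims)) dims <- length(A)
  n <- length(dims)
  inner <- interval_from_dims(dims - 2)
  P <- sweep(interval_coords(inner), 2, rep(1, n), `+`)  # 0-based interior
  idx <- linear_index_many(P, dims) + 1
  v <- A[idx]
  strides <- cumprod(c(1, dims[-n]))
  offs <- interval_coords(nd_interval(rep(-1, n), rep(1, n)))
  is_max <- rep(TRUE, length(idx))
  is_min <- rep(TRUE, length(idx))
  for (i in seq_len(nrow(offs))) {
    if (all(offs[i, ] == 0)) next
    nv <- A[idx + sum(offs[i, ] * strides)]
    is_max <- is_max & v > nv
    is_min <- is_min & v < nv
  }
  list(coords = P, value = v, is_max = is_max, is_min = is_min)
}

#' Difference-of-Gaussians interest points
#'
#' The response is `gaussian(sigma2) - gaussian(sigma1)` (raw difference,
#' no `1/(sigma2-sigma1)` normalization, so the threshold applies to the
#' raw band-pass response). Detections are the strict local extrema of the
#' response over the full `3^n - 1` neighborhood (plateaus yield no
#' detections) with `|response| >= threshold`, sorted by `|response|`
#' descending. The reported scale is the geometric mean
#' `sqrt(sigma1 * sigma2)`.
#' @param img a bounded image or view
#' @param sigma1,sigma2 scales with `0 < sigma1 < sigma2`
#' @param threshold minimum absolute response
#' @inheritParams separable_convolve
#' @return a data.frame with one coordinate column per dimension
#'   (`x1, x2, ...`), plus `scale` and `response`
#' @export
dog_detect <- function(img, sigma1, sigma2, threshold,
                       extension = "mirror_single") {
  if (!(sigma1 > 0 && sigma2 > sigma1))
    nd_stop("need 0 < sigma1 < sigma2")
  g1 <- materialize(zero_min(gaussian_convolve(img, sigma1,
                                               extension = extension)))
  g2 <- materialize(zero_min(gaussian_convolve(img, sigma2,
                                               extension = extension)))
  resp <- g2 - g1
  ex <- local_extrema(resp)
  keep <- (ex$is_max | ex$is_min) & abs(ex$value) >= threshold
  P <- ex$coords[keep, , drop = FALSE]
  P <- sweep(P, 2, img_interval(img)$min, `+`)
  out <- as.data.frame(P)
  names(out) <- paste0("x", seq_len(ncol(P)))
  out$scale <- rep(sqrt(sigma1 * sigma2), nrow(P))
  out$response <- ex$value[keep]
  out[order(-abs(out$response)), , drop = FALSE]
}

## ---- component trees and MSER ---------------------------------------------

neighbors_of <- function(pos, dims) {
  n <- length(dims)
  out <- matrix(rep(pos, 2 * n), ncol = n, byrow = TRUE)
  for (d in seq_len(n)) {
    out[2 * d - 1, d] <- pos[d] - 1
    out[2 * d, d] <- pos[d] + 1
  }
  ok <- rep(TRUE, 2 * n)
  for (d in seq_len(n)) ok <- ok & out[, d] >= 0 & out[, d] < dims[d]
  out[ok, , drop = FALSE]
}

# connected components (2n-face connectivity) of the pixels flagged in
# `mask` (logical vector over raster order); returns integer labels, 0 = off
flood_label <- function(mask, dims) {
  n <- length(dims)
  strides <- cumprod(c(1, dims[-n]))
  labels <- integer(length(mask))
  nextlab <- 0
  P <- interval_coords(interval_from_dims(dims))
  for (start in which(mask)) {
    if (labels[start] != 0) next
    nextlab <- nextlab + 1
    queue <- start
    labels[start] <- nextlab
    while (length(queue)) {
      cur <- queue[length(queue)]
      queue <- queue[-length(queue)]
      nb <- neighbors_of(P[cur, ], dims)
      if (nrow(nb) == 0) next
      nbi <- linear_index_many(nb, dims) + 1
      nbi <- nbi[mask[nbi] & labels[nbi] == 0]
      labels[nbi] <- nextlab
      queue <- c(queue, nbi)
    }
  }
  labels
}

#' Build the max-tree (component tree) of a scalar image
#'
#' The max-tree nests the connected components of the upper threshold sets
#' `{p : I(p) >= g}` over all gray levels `g` present in the image
#' (bright components; obtain a min-tree by inverting values through a
#' converter). Connectivity is 2n-face. Each node carries its gray level,
#' pixel set, size and parent; the root is the whole image at the global
#' minimum level.
#' @param img a bounded image or view with an ordered scalar value type
#' @return an object of class `nd_comptree` with elements `nodes` (list),
#'   `dims`, `min` (interval minimum) and `root` (node id)
#' @export
build_component_tree <- function(img) {
  if (!type_is_ordered(img_type(img)))
    nd_stop("component trees require an ordered scalar value type, not '",
            img_type(img), "'")
  A <- materialize(img)
  dims <- dim(A)
  if (is.null(dims)) dims <- length(A)
  v <- as.vector(A)
  levels <- sort(unique(v), decreasing = TRUE)
  nodes <- list()
  comp_node <- integer(length(v))   # deepest node covering each pixel so far
  for (g in levels) {
    mask <- v >= g
    labels <- flood_label(mask, dims)
    for (lab in seq_len(max(labels, 0))) {
      pix <- which(labels == lab)
      if (!any(v[pix] == g)) next   # identical to an existing node
      id <- length(nodes) + 1
      children <- setdiff(unique(comp_node[pix]), 0)
      nodes[[id]] <- list(id = id, level = g, pixels = pix,
                          size = length(pix), parent = NA_integer_,
                          children = children)
      for (ch in children) nodes[[ch]]$parent <- id
      comp_node[pix] <- id
    }
  }
  structure(list(nodes = nodes, dims = dims, min = img_interval(img)$min,
                 root = length(nodes)),
            class = "nd_comptree")
}

#' Pixel coordinates of a component-tree node
#' @param tree an `nd_comptree`
#' @param id node id
#' @return 0-based coordinates (k x n matrix) in the source image frame
#' @export
component_coords <- function(tree, id) {
  pix <- tree$nodes[[id]]$pixels
  P <- matrix(0, length(pix), length(tree$dims))
  idx <- pix - 1
  for (d in seq_along(tree$dims)) {
    P[, d] <- idx %% tree$dims[d]
    idx <- idx %/% tree$dims[d]
  }
  sweep(P, 2, tree$min, `+`)
}

# component size at threshold level g along a root-to-leaf path:
# the first node on the path (from the root) with level >= g; clamped to
# the root below the root level and to the leaf above the leaf level
path_size_at <- function(nodes, path, g) {
  for (id in path) if (nodes[[id]]$level >= g) return(nodes[[id]]$size)
  nodes[[path[length(path)]]]$size
}

#' Maximally stable extremal regions
#'
#' Along every root-to-leaf branch of the max-tree, each node `i` at gray
#' level `g` is scored with the stability rate
#' `q(i) = (|Q_{g-delta}| - |Q_{g+delta}|) / |Q_g|`, where `Q_l` is the
#' branch's component at threshold level `l` (clamped to the root/leaf
#' where no component exists at `l`). A node is selected iff `q` is a
#' (non-strict) local minimum along some branch, `q <= max_rate` and
#' `min_size <= |Q_g| <= max_size`. The root (the whole image) is never a
#' region.
#' @param tree an `nd_comptree` from [build_component_tree()]
#' @param delta stability window in gray-level units, `>= 1`
#' @param min_size,max_size region size bounds in pixels
#' @param max_rate maximum admissible stability rate
#' @return a data.frame with columns `id`, `level`, `size`, `rate`,
#'   ordered by increasing rate
#' @export
mser_detect <- function(tree, delta, min_size = 1, max_size = Inf,
                        max_rate = 1) {
  if (delta < 1) nd_stop("delta must be >= 1")
  nodes <- tree$nodes
  leaves <- Filter(function(nd) length(nd$children) == 0, nodes)
  sel <- new.env(parent = emptyenv())
  for (leaf in leaves) {
    path <- leaf$id
    while (!is.na(nodes[[path[1]]]$parent))
      path <- c(nodes[[path[1]]]$parent, path)
    q <- vapply(path, function(id) {
      nd <- nodes[[id]]
      (path_size_at(nodes, path, nd$level - delta) -
         path_size_at(nodes, path, nd$level + delta)) / nd$size
    }, numeric(1))
    m <- length(path)
    for (j in seq_len(m)) {
      if (path[j] == tree$root) next   # the whole image is not a region
      if ((j == 1 || q[j] <= q[j - 1]) && (j == m || q[j] <= q[j + 1]) &&
          q[j] <= max_rate &&
          nodes[[path[j]]]$size >= min_size &&
          nodes[[path[j]]]$size <= max_size) {
        key <- as.character(path[j])
        prev <- sel[[key]]
        if (is.null(prev) || q[j] < prev) sel[[key]] <- q[j]
      }
    }
  }
  ids <- as.integer(ls(sel))
  rate <- vapply(as.character(ids), function(k) sel[[k]], numeric(1))
  out <- data.frame(id = ids,
                    level = vapply(ids, function(i) nodes[[i]]$level,
                                   numeric(1)),
                    size = vapply(ids, function(i) nodes[[i]]$size,
                                  numeric(1)),
                    rate = unname(rate))
  out[order(out$rate, out$id), , drop = FALSE]
}

## ---- anisotropic diffusion -------------------------------------------------

shift_replicate <- function(A, d, by) {
  dims <- dim(A)
  if (is.null(dims)) dims <- length(A)
  idx <- lapply(dims, seq_len)
  L <- dims[d]
  idx[[d]] <- if (by == 1) c(2:L, L) else c(1, 1:(L - 1))
  if (L == 1) idx[[d]] <- 1
  do.call(`[`, c(list(array(A, dims)), idx, list(drop = FALSE)))
}

#' Perona-Malik anisotropic diffusion
#'
#' Explicit scheme: per iteration
#' `I <- I + lam * sum_d [ g(D+d) * D+d + g(D-d) * D-d ]` with forward and
#' backward differences `D+-d` along each dimension and conductance
#' `g(s) = exp(-(s/kappa)^2)` (or the rational variant
#' `1 / (1 + (s/kappa)^2)`). The boundary repeats the border sample
#' (gradient zero across the boundary), so the total image mass is
#' conserved exactly. Stability of the explicit scheme requires
#' `0 < lam <= 1/(2n)`.
#' @param img a bounded image or view
#' @param n_iter number of iterations, `>= 0`
#' @param kappa conductance scale (gray-level units), `> 0`
#' @param lam time step; must satisfy `0 < lam <= 1/(2n)`
#' @param conductance `"exponential"` (default) or `"rational"`
#' @inheritParams separable_convolve
#' @export
anisotropic_diffusion <- function(img, n_iter, kappa, lam,
                                  conductance = c("exponential", "rational"),
                                  factory = image_factory("array", "f64")) {
  conductance <- match.arg(conductance)
  n <- img_ndim(img)
  if (n_iter < 0) nd_stop("n_iter must be >= 0")
  if (kappa <= 0) nd_stop("kappa must be > 0")
  if (!(lam > 0 && lam <= 1 / (2 * n)))
    nd_stop("lam = ", lam, " outside the stability range (0, ",
            format(1 / (2 * n)), "] for ", n, " dimensions")
  g <- if (conductance == "exponential")
    function(s) exp(-(s / kappa)^2)
  else
    function(s) 1 / (1 + (s / kappa)^2)
  A <- materialize(img)
  dims <- dim(A)
  if (is.null(dims)) dims <- length(A)
  A <- array(as.double(A), dims)
  for (it in seq_len(n_iter)) {
    acc <- array(0, dims)
    for (d in seq_len(n)) {
      dp <- shift_replicate(A, d, 1) - A
      dm <- shift_replicate(A, d, -1) - A
      acc <- acc + g(dp) * dp + g(dm) * dm
    }
    A <- A + lam * acc
  }
  finish_image(A, factory, img_interval(img)$min)
}
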