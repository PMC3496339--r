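#' Lazy integer-coordinate views
#'
#' Views transform coordinates on the fly without copying pixel data:
#' translation, axis permutation, 90-degree rotation, axis inversion,
#' hyperslicing, windowing and out-of-bounds extension. Views accept any
#' accessible as source — including other views — and act both as input and
#' output (writes through an invertible view propagate to its source).
#'
#' Consecutive integer-transform views are fused at construction into a
#' single composed transform, so access through a deep chain costs one
#' coordinate mapping; set `options(ndimg.simplify = FALSE)` to keep chains
#' unfused (used by the equality tests against the sequential oracle).
#'
#' @name views
NULL

#' Composed integer coordinate transform
#'
#' Represents the access map of a view: for a view coordinate `q`, the
#' source coordinate is `p[d] = off[d] + sign[d] * q[comp[d]]` per source
#' dimension `d`; `comp[d] = NA` pins the source dimension to the constant
#' `off[d]` (slicing). Any composition of permutations, axis inversions,
#' translations and slices has this form, and composing two such maps
#' yields another one — the basis of view-chain simplification.
#'
#' @param n_view dimensionality of the view (transform input)
#' @param comp per source dimension: which view dimension it reads (1-based)
#'   or `NA` for a constant
#' @param sign per source dimension: +1 or -1 (axis inversion)
#' @param off per source dimension: integer offset (or the pinned constant)
#' @return an object of class `nd_transform`
#' @export
nd_mixed_transform <- function(n_view, comp, sign, off) {
  stopifnot(length(comp) == length(sign), length(sign) == length(off))
  structure(list(n_view = n_view, n_source = length(comp),
                 comp = comp, sign = sign, off = off),
            class = "nd_transform")
}

transform_identity <- function(n) {
  nd_mixed_transform(n, seq_len(n), rep(1, n), rep(0, n))
}

#' @rdname nd_mixed_transform
#' @param t an `nd_transform`
#' @param q a view coordinate vector
#' @return `transform_apply`: the source coordinate vector
#' @export
transform_apply <- function(t, q) {
  p <- t$off
  live <- !is.na(t$comp)
  p[live] <- p[live] + t$sign[live] * q[t$comp[live]]
  p
}

transform_apply_many <- function(t, Q) {
  P <- matrix(rep(t$off, each = nrow(Q)), nrow(Q), t$n_source)
  for (d in which(!is.na(t$comp)))
    P[, d] <- t$off[d] + t$sign[d] * Q[, t$comp[d]]
  P
}

#' Compose two transforms
#'
#' `transform_chain(inner, outer)` is the access map of a view (with map
#' `inner`) stacked on a view (with map `outer`): coordinates pass through
#' `inner` first, then `outer`.
#' @param inner,outer `nd_transform` objects; `inner$n_source` must equal
#'   `outer$n_view`
#' @export
transform_chain <- function(inner, outer) {
  stopifnot(inner$n_source == outer$n_view)
  comp <- sign <- off <- numeric(outer$n_source)
  for (d in seq_len(outer$n_source)) {
    j <- outer$comp[d]
    if (is.na(j)) {
      comp[d] <- NA; sign[d] <- 1; off[d] <- outer$off[d]
    } else if (is.na(inner$comp[j])) {
      comp[d] <- NA; sign[d] <- 1
      off[d] <- outer$off[d] + outer$sign[d] * inner$off[j]
    } else {
      comp[d] <- inner$comp[j]
      sign[d] <- outer$sign[d] * inner$sign[j]
      off[d] <- outer$off[d] + outer$sign[d] * inner$off[j]
    }
  }
  nd_mixed_transform(inner$n_view, comp, sign, off)
}

#' Invert a square, non-slicing transform
#' @param t an `nd_transform` with no constant components and equal
#'   dimensionalities
#' @export
transform_inverse <- function(t) {
  if (t$n_view != t$n_source || anyNA(t$comp))
    nd_stop("transform is not invertible (slicing or non-square)")
  comp <- sign <- off <- numeric(t$n_view)
  for (d in seq_len(t$n_source)) {
    j <- t$comp[d]
    comp[j] <- d
    sign[j] <- t$sign[d]
    off[j] <- -t$sign[d] * t$off[d]
  }
  nd_mixed_transform(t$n_source, comp, sign, off)
}

## ---- the mixed view --------------------------------------------------------

new_mixed_view <- function(source, transform, interval) {
  if (inherits(source, "nd_mixed_view") && nd_simplify_enabled()) {
    transform <- transform_chain(transform, source$transform)
    source <- source$source
  }
  img <- structure(list(interval = interval, type = img_type(source),
                        source = source, transform = transform),
                   class = c("nd_mixed_view", "nd_img"))
  img$n <- if (!is.null(interval)) interval_ndim(interval) else transform$n_view
  img
}

#' @export
img_get.nd_mixed_view <- function(img, pos) {
  check_pos(img, pos)
  img_get(img$source, transform_apply(img$transform, pos))
}

#' @export
img_set.nd_mixed_view <- function(img, pos, value) {
  check_pos(img, pos)
  img_set(img$source, transform_apply(img$transform, pos), value)
}

#' @export
img_get_many.nd_mixed_view <- function(img, P) {
  img_get_many(img$source, transform_apply_many(img$transform, P))
}

#' Depth of a view chain
#'
#' Number of stacked view nodes above the backing image; a fused chain of
#' integer transforms has depth 1.
#' @param img an image or view
#' @export
view_depth <- function(img) {
  if (inherits(img, c("nd_mixed_view", "nd_extended", "nd_converted")))
    1 + view_depth(img$source)
  else 0
}

#' Fuse runs of integer-transform views in a chain
#'
#' Returns an equivalent view in which every maximal run of consecutive
#' integer-transform nodes is collapsed into a single composed transform.
#' Extension and conversion nodes are preserved in place (their semantics
#' are not coordinate-affine). With the default
#' `options(ndimg.simplify = TRUE)` chains are already fused at
#' construction and this is the identity.
#' @param img an image or view
#' @export
simplify <- function(img) {
  if (inherits(img, "nd_mixed_view")) {
    s <- simplify(img$source)
    if (inherits(s, "nd_mixed_view")) {
      new <- structure(list(interval = img$interval, type = img$type,
                            source = s$source,
                            transform = transform_chain(img$transform,
                                                        s$transform)),
                       class = c("nd_mixed_view", "nd_img"))
      new$n <- img$n
      return(new)
    }
    new <- img; new$source <- s
    return(new)
  }
  if (inherits(img, c("nd_extended", "nd_converted"))) {
    img$source <- simplify(img$source)
    return(img)
  }
  img
}

## ---- view constructors -----------------------------------------------------

#' Translate, permute, rotate and mirror views
#'
#' All constructors are lazy: no pixel data is copied, and
#' `img_get(view, p)` equals `img_get(img, Tinv(p))` for the respective
#' coordinate transform.
#'
#' `rotate90(img, from_d, to_d)` rotates the `(from_d, to_d)` plane by 90
#' degrees: the new coordinate along `to_d` is the old `from_d` coordinate,
#' and the new `from_d` coordinate is `max_to - old to_d` — a permutation
#' followed by one axis inversion, so four applications are the identity.
#' For a 2x3 image with values `v(x,y)`, `rotate90(img, 1, 2)` is a 3x2
#' image `w` with `w(x, y) = v(y, 2 - x)`.
#'
#' @param img an image or view (any accessible)
#' @param offset integer translation vector
#' @return a lazy view (class `nd_mixed_view`)
#' @export
translate <- function(img, offset) {
  n <- img_ndim(img)
  stopifnot(length(offset) == n)
  t <- nd_mixed_transform(n, seq_len(n), rep(1, n), -as.numeric(offset))
  iv <- if (img_is_bounded(img))
    nd_interval(img_interval(img)$min + offset, img_interval(img)$max + offset)
  new_mixed_view(img, t, iv)
}

#' @rdname translate
#' @param d1,d2 the two dimensions (1-based) to swap
#' @export
permute <- function(img, d1, d2) {
  n <- img_ndim(img)
  comp <- seq_len(n); comp[d1] <- d2; comp[d2] <- d1
  t <- nd_mixed_transform(n, comp, rep(1, n), rep(0, n))
  iv <- NULL
  if (img_is_bounded(img)) {
    mn <- img_interval(img)$min; mx <- img_interval(img)$max
    mn2 <- mn; mx2 <- mx
    mn2[d1] <- mn[d2]; mn2[d2] <- mn[d1]
    mx2[d1] <- mx[d2]; mx2[d2] <- mx[d1]
    iv <- nd_interval(mn2, mx2)
  }
  new_mixed_view(img, t, iv)
}

#' @rdname translate
#' @param d dimension whose axis to invert
#' @export
invert_axis <- function(img, d) {
  n <- img_ndim(img)
  sgn <- rep(1, n); sgn[d] <- -1
  t <- nd_mixed_transform(n, seq_len(n), sgn, rep(0, n))
  iv <- NULL
  if (img_is_bounded(img)) {
    mn <- img_interval(img)$min; mx <- img_interval(img)$max
    mn2 <- mn; mx2 <- mx
    mn2[d] <- -mx[d]; mx2[d] <- -mn[d]
    iv <- nd_interval(mn2, mx2)
  }
  new_mixed_view(img, t, iv)
}

#' @rdname translate
#' @param from_d,to_d the rotation plane (distinct dimensions, 1-based)
#' @export
rotate90 <- function(img, from_d, to_d) {
  if (from_d == to_d) nd_stop("rotate90: from_d and to_d must differ")
  n <- img_ndim(img)
  if (!img_is_bounded(img))
    nd_stop("rotate90 requires a bounded source (the pivot uses max)")
  mn <- img_interval(img)$min; mx <- img_interval(img)$max
  comp <- seq_len(n); sgn <- rep(1, n); off <- rep(0, n)
  # access map view -> source: p[from] = q[to]; p[to] = max_to - q[from]
  comp[from_d] <- to_d
  comp[to_d] <- from_d; sgn[to_d] <- -1; off[to_d] <- mx[to_d]
  t <- nd_mixed_transform(n, comp, sgn, off)
  mn2 <- mn; mx2 <- mx
  mn2[to_d] <- mn[from_d]; mx2[to_d] <- mx[from_d]
  mn2[from_d] <- mx[to_d] - mx[to_d]; mx2[from_d] <- mx[to_d] - mn[to_d]
  new_mixed_view(img, t, nd_interval(mn2, mx2))
}

#' Hyperslice: fix one dimension
#'
#' Returns an (n-1)-dimensional view; `img_get(view, p)` reads the source
#' at `p` with `fixed_pos` inserted at `fixed_dim`. Writes propagate to the
#' sliced plane of the source.
#' @param img an image or view
#' @param fixed_dim dimension to fix (1-based)
#' @param fixed_pos coordinate along `fixed_dim`
#' @export
hyperslice <- function(img, fixed_dim, fixed_pos) {
  n <- img_ndim(img)
  if (img_is_bounded(img)) {
    iv <- img_interval(img)
    if (fixed_pos < iv$min[fixed_dim] || fixed_pos > iv$max[fixed_dim])
      nd_stop("hyperslice: fixed_pos ", fixed_pos,
              " outside interval of dimension ", fixed_dim)
  }
  keep <- setdiff(seq_len(n), fixed_dim)
  comp <- sign <- off <- numeric(n)
  comp[keep] <- seq_len(n - 1)
  sign[keep] <- 1
  comp[fixed_dim] <- NA; sign[fixed_dim] <- 1; off[fixed_dim] <- fixed_pos
  t <- nd_mixed_transform(n - 1, comp, sign, off)
  iv <- NULL
  if (img_is_bounded(img)) {
    src <- img_interval(img)
    iv <- nd_interval(src$min[keep], src$max[keep])
  }
  new_mixed_view(img, t, iv)
}

#' Window and zero-min views
#'
#' `window` restricts a source to a sub-interval without changing
#' coordinates; `zero_min` translates a bounded image so its minimum is the
#' origin.
#' @param img an image or view
#' @param interval an `nd_interval`; for a bounded, unextended source it
#'   must be contained in the source interval
#' @export
window <- function(img, interval) {
  if (img_is_bounded(img) &&
      !interval_contains_interval(img_interval(img), interval))
    nd_stop("window: interval not contained in the source interval; ",
            "extend() the source first to sample outside")
  n <- interval_ndim(interval)
  new_mixed_view(img, transform_identity(n), interval)
}

#' @rdname window
#' @export
zero_min <- function(img) translate(img, -img_interval(img)$min)

## ---- out-of-bounds extension ----------------------------------------------

#' Out-of-bounds extension strategies
#'
#' A strategy generates values for coordinates outside a bounded image:
#' \describe{
#'   \item{mirror_single}{fold at the boundary without repeating the border
#'     sample: `..., v2, v1, | v0, v1, v2 |, v1, v0, ...`}
#'   \item{mirror_double}{fold repeating the border sample:
#'     `..., v1, v0, | v0, v1, v2 |, v2, v1, ...`}
#'   \item{periodic}{wrap modulo the side length (mathematical modulo, so
#'     negative coordinates wrap correctly)}
#'   \item{constant}{a fixed fill value}
#' }
#' @param kind one of `"mirror_single"`, `"mirror_double"`, `"periodic"`,
#'   `"constant"`
#' @param constant_value fill value for the constant strategy
#' @return an object of class `nd_extension`
#' @export
extension_strategy <- function(kind = c("mirror_single", "mirror_double",
                                        "periodic", "constant"),
                               constant_value = 0) {
  kind <- match.arg(kind)
  structure(list(kind = kind, constant_value = constant_value),
            class = "nd_extension")
}

# fold a vector of coordinates along one dimension into [m, M]
fold_coords <- function(p, m, M, kind) {
  L <- M - m + 1
  q <- p - m
  switch(kind,
    periodic = m + (q %% L),
    mirror_single = {
      if (L == 1) rep(m, length(p))
      else {
        r <- q %% (2 * L - 2)
        r[r >= L] <- 2 * L - 2 - r[r >= L]
        m + r
      }
    },
    mirror_double = {
      r <- q %% (2 * L)
      r[r >= L] <- 2 * L - 1 - r[r >= L]
      m + r
    },
    nd_stop("fold_coords: unsupported kind ", kind))
}

#' Extend a bounded image beyond its interval
#'
#' The result is unbounded: `img_get` is defined for every integer
#' coordinate, equals the source inside its interval, and applies the
#' strategy's folding rule (or constant) outside. Unbounded images cannot
#' be iterated; window them first.
#' @param img a bounded image or view
#' @param strategy an [extension_strategy()], or a kind string
#' @export
extend <- function(img, strategy = "mirror_single") {
  if (!img_is_bounded(img)) nd_stop("extend: source must be bounded")
  if (is.character(strategy)) strategy <- extension_strategy(strategy)
  v <- structure(list(interval = NULL, type = img_type(img), source = img,
                      strategy = strategy,
                      source_interval = img_interval(img),
                      n = img_ndim(img)),
                 class = c("nd_extended", "nd_img"))
  v
}

#' @export
img_get.nd_extended <- function(img, pos) {
  iv <- img$source_interval
  if (interval_contains(iv, pos)) return(img_get(img$source, pos))
  if (img$strategy$kind == "constant") return(img$strategy$constant_value)
  p <- pos
  for (d in seq_along(p))
    p[d] <- fold_coords(p[d], iv$min[d], iv$max[d], img$strategy$kind)
  img_get(img$source, p)
}

#' @export
img_set.nd_extended <- function(img, pos, value) {
  if (!interval_contains(img$source_interval, pos))
    nd_stop("cannot write outside the source interval of an extended view")
  img_set(img$source, pos, value)
}

#' @export
img_get_many.nd_extended <- function(img, P) {
  iv <- img$source_interval
  if (img$strategy$kind == "constant") {
    inside <- interval_contains_many(iv, P)
    out <- rep(type_wrap(img$type, img$strategy$constant_value), nrow(P))
    if (any(inside))
      out[inside] <- img_get_many(img$source, P[inside, , drop = FALSE])
    return(out)
  }
  for (d in seq_len(ncol(P)))
    P[, d] <- fold_coords(P[, d], iv$min[d], iv$max[d], img$strategy$kind)
  img_get_many(img$source, P)
}

## ---- converted views -------------------------------------------------------

#' Lazily convert the values of an image
#'
#' Every access applies the converter's mapping on the fly; no pixel data
#' is copied. Writing requires an inverse mapping in the converter.
#' @param img an image or view whose type equals `conv$source`
#' @param conv an [nd_converter()]
#' @export
convert_view <- function(img, conv) {
  if (!identical(img_type(img), conv$source))
    nd_stop("convert_view: image type '", img_type(img),
            "' does not match converter source '", conv$source, "'")
  v <- structure(list(interval = img$interval, type = conv$target,
                      source = img, conv = conv, n = img_ndim(img)),
                 class = c("nd_converted", "nd_img"))
  v
}

#' @export
img_get.nd_converted <- function(img, pos) {
  type_wrap(img$type, img$conv$fn(img_get(img$source, pos)))
}

#' @export
img_set.nd_converted <- function(img, pos, value) {
  if (is.null(img$conv$inv))
    nd_stop("cannot write through a one-way converter (no inverse mapping)")
  if (inherits(value, "nd_value")) value <- value$value
  img_set(img$source, pos, img$conv$inv(value))
}

#' @export
img_get_many.nd_converted <- function(img, P) {
  type_wrap(img$type, img$conv$fn(img_get_many(img$source, P)))
}
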