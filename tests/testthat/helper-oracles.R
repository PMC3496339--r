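# Independent reference implementations ("oracles") that the package is
# validated against. These deliberately use the most naive formulation
# available — correctness over speed — and share no code with the package
# internals they check.

runif_seeded <- function(n, seed = 1, min = 0, max = 1) {
  set.seed(seed)
  stats::runif(n, min, max)
}

# -- out-of-bounds index folding ---------------------------------------------
# Fold a single 0-based index i into [0, L-1] under each strategy.
oracle_fold <- function(i, L, strategy) {
  switch(strategy,
    periodic = i %% L,
    mirror_single = {            # edge samples not repeated: period 2L - 2
      if (L == 1) return(0)
      p <- i %% (2 * L - 2)
      if (p >= L) 2 * L - 2 - p else p
    },
    mirror_double = {            # edge samples repeated: period 2L
      p <- i %% (2 * L)
      if (p >= L) 2 * L - 1 - p else p
    },
    stop("oracle_fold does not handle: ", strategy))
}

# Value of the extended image at a (possibly out-of-bounds) coordinate.
oracle_extended_get <- function(A, pos, strategy, fill = 0) {
  dims <- dim(A)
  if (is.null(dims)) dims <- length(A)
  if (strategy == "constant") {
    if (any(pos < 0 | pos >= dims)) return(fill)
    folded <- pos
  } else {
    folded <- mapply(oracle_fold, pos, dims,
                     MoreArgs = list(strategy = strategy))
  }
  do.call(`[`, c(list(array(A, dims)), as.list(folded + 1)))
}

# -- dense n-D correlation ----------------------------------------------------
# Correlate A with the dense outer product of 1-D kernels, sampling
# out-of-bounds pixels through oracle_extended_get. kernels[[d]] is the
# 1-D kernel along dimension d, odd length, centered.
oracle_dense_correlate <- function(A, kernels, strategy = "mirror_single") {
  dims <- dim(A)
  if (is.null(dims)) dims <- length(A)
  n <- length(dims)
  half <- vapply(kernels, function(k) (length(k) - 1) / 2, numeric(1))
  offs <- as.matrix(expand.grid(lapply(half, function(h) -h:h)))
  w <- apply(offs, 1, function(o)
    prod(vapply(seq_len(n), function(d) kernels[[d]][o[d] + half[d] + 1],
                numeric(1))))
  out <- array(0, dims)
  coords <- as.matrix(expand.grid(lapply(dims, function(d) 0:(d - 1))))
  for (i in seq_len(nrow(coords))) {
    s <- 0
    for (j in seq_len(nrow(offs)))
      s <- s + w[j] * oracle_extended_get(A, coords[i, ] + offs[j, ], strategy)
    out[i] <- s
  }
  out
}

# -- per-level threshold partitions ------------------------------------------
# For every gray level g in A, label the connected components (face
# connectivity) of {v >= g} with a breadth-first search and return the
# partition as a sorted list of sorted pixel-index sets.
oracle_level_partition <- function(A) {
  dims <- dim(A)
  if (is.null(dims)) dims <- length(A)
  v <- as.vector(A)
  n <- length(dims)
  stride <- cumprod(c(1, dims[-n]))
  neighbors <- function(i) {            # 1-based linear index
    idx0 <- i - 1
    out <- integer(0)
    for (d in seq_len(n)) {
      c_d <- (idx0 %/% stride[d]) %% dims[d]
      if (c_d > 0) out <- c(out, i - stride[d])
      if (c_d < dims[d] - 1) out <- c(out, i + stride[d])
    }
    out
  }
  parts <- list()
  for (g in sort(unique(v))) {
    inset <- v >= g
    seen <- !inset
    for (s in which(inset)) {
      if (seen[s]) next
      comp <- integer(0)
      queue <- s
      seen[s] <- TRUE
      while (length(queue)) {
        cur <- queue[1]; queue <- queue[-1]
        comp <- c(comp, cur)
        for (nb in neighbors(cur)) {
          if (!seen[nb]) { seen[nb] <- TRUE; queue <- c(queue, nb) }
        }
      }
      # canonical components only: a node exists at level g iff some pixel
      # attains exactly g (otherwise the same pixel set reappears at a
      # higher level and is that node instead)
      if (any(v[comp] == g))
        parts[[length(parts) + 1]] <- list(level = g, pixels = sort(comp))
    }
  }
  parts
}

# Order-independent canonical keys for a list(level=, pixels=) partition,
# robust against integer/double storage differences.
partition_keys <- function(parts) {
  sort(vapply(parts, function(p)
    paste0(format(as.numeric(p$level)), ":",
           paste(as.integer(p$pixels), collapse = ",")), character(1)))
}

# -- random view chains -------------------------------------------------------
# Apply a random chain of integer view operations twice: once fused
# (default) and once with simplification disabled, which evaluates the
# chain node by node. Returns both views plus bookkeeping.
random_view_chain <- function(img, depth) {
  ops <- list()
  build <- function(v) {
    for (k in seq_len(depth)) {
      n <- img_ndim(v)
      choice <- sample(c("translate", "invert", if (n > 1) "permute",
                         if (n > 1) "hyperslice", if (n > 1) "rotate"), 1)
      # local() gives every closure its own copy of the drawn parameters
      op <- switch(choice,
        translate = local({
          t <- sample(-3:3, n, replace = TRUE)
          list(f = function(x) translate(x, t))
        }),
        permute = local({
          d <- sample(n, 2)
          list(f = function(x) permute(x, d[1], d[2]))
        }),
        invert = local({
          d <- sample(n, 1)
          list(f = function(x) invert_axis(x, d))
        }),
        hyperslice = local({
          d <- sample(n, 1)
          iv <- img_interval(v)
          p <- sample(iv$min[d]:iv$max[d], 1)
          list(f = function(x) hyperslice(x, d, p))
        }),
        rotate = local({
          d <- sample(n, 2)
          list(f = function(x) rotate90(x, d[1], d[2]))
        }))
      v <- op$f(v)
      ops[[length(ops) + 1]] <<- op$f
    }
    v
  }
  fused <- build(img)
  seq_v <- img
  old <- options(ndimg.simplify = FALSE)
  on.exit(options(old))
  for (f in ops) seq_v <- f(seq_v)
  list(fused = fused, sequential = seq_v)
}

# Read every sample of a bounded image/view as a named vector in a
# canonical (raster) order, independent of the object's own iteration.
all_samples <- function(v) {
  iv <- img_interval(v)
  P <- interval_coords(iv)
  img_get_many(v, P)
}
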