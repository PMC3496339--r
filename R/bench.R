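#' Benchmark harness: generic access versus direct buffers
#'
#' Compares the package's generic access layer against special-purpose
#' implementations that reach straight into the flat buffer of an array
#' image, on three tasks:
#' \describe{
#'   \item{pixel_sum}{sum of all samples}
#'   \item{per_pixel_op}{a per-pixel multiply-add (`v * 2 + 1`)}
#'   \item{nd_inner_loop}{mean over the 3^n box neighborhood (mirror
#'     boundary) — the inner loop runs over a dimensionality unknown to the
#'     generic code, while the direct variant is written for the concrete
#'     dimensionality at hand}
#' }
#' The two variants of each task are first verified to produce identical
#' numbers (disagreement aborts the benchmark); only then are they timed.
#' Timing ratios are reported, never asserted — they are properties of the
#' machine and runtime, not of the code's correctness.
#'
#' @param tasks subset of `c("pixel_sum", "per_pixel_op", "nd_inner_loop")`
#' @param dims_list list of dimension vectors to benchmark on
#' @param reps repetitions; the median time is reported
#' @param seed seed for the pseudorandom test pattern
#' @return a data.frame with one row per (task, dims, variant): columns
#'   `task`, `dims`, `variant`, `median_s`, and `ratio`
#'   (generic / direct, repeated on both rows of a pair)
#' @export
run_benchmark <- function(tasks = c("pixel_sum", "per_pixel_op",
                                    "nd_inner_loop"),
                          dims_list = list(c(256, 256), c(32, 32, 16)),
                          reps = 3, seed = 42) {
  tasks <- match.arg(tasks, several.ok = TRUE)
  rows <- list()
  for (dims in dims_list) {
    img <- generate_fixture("uniform_noise", dims,
                            factory = image_factory("array", "f64"),
                            seed = seed, range = c(0, 255))
    buf <- img$e$data
    for (task in tasks) {
      fns <- bench_task(task, img, buf, dims)
      r_gen <- fns$generic(); r_dir <- fns$direct()
      if (!isTRUE(all.equal(r_gen, r_dir, tolerance = 1e-12)))
        nd_stop("benchmark '", task, "' on ", paste(dims, collapse = "x"),
                ": generic and direct variants disagree; aborting")
      t_gen <- stats::median(vapply(seq_len(reps), function(i)
        system.time(fns$generic())[["elapsed"]], numeric(1)))
      t_dir <- stats::median(vapply(seq_len(reps), function(i)
        system.time(fns$direct())[["elapsed"]], numeric(1)))
      ratio <- if (t_dir > 0) t_gen / t_dir else NA_real_
      d <- paste(dims, collapse = "x")
      rows[[length(rows) + 1]] <- data.frame(
        task = task, dims = d, variant = c("generic_iterate",
                                           "direct_buffer"),
        median_s = c(t_gen, t_dir), ratio = ratio)
    }
  }
  do.call(rbind, rows)
}

bench_task <- function(task, img, buf, dims) {
  n <- length(dims)
  switch(task,
    pixel_sum = list(
      generic = function() sum(img_values(img)),
      direct = function() sum(buf)),
    per_pixel_op = list(
      generic = function() img_get_many(img, img_coords(img)) * 2 + 1,
      direct = function() buf * 2 + 1),
    nd_inner_loop = list(
      generic = function() {
        ext <- extend(img, "mirror_double")
        P <- img_coords(img)
        acc <- numeric(nrow(P))
        offs <- interval_coords(nd_interval(rep(-1, n), rep(1, n)))
        for (i in seq_len(nrow(offs)))
          acc <- acc + img_get_many(ext, sweep(P, 2, offs[i, ], `+`))
        acc / nrow(offs)
      },
      direct = function() bench_box_direct(buf, dims)))
}

# dimensionality-specialized box mean on the raw buffer (mirror_double)
bench_box_direct <- function(buf, dims) {
  clamp_idx <- function(i, L) pmin(pmax(i, 1), L)
  if (length(dims) == 2) {
    A <- array(buf, dims)
    acc <- array(0, dims)
    for (dx in -1:1) for (dy in -1:1)
      acc <- acc + A[clamp_idx(seq_len(dims[1]) + dx, dims[1]),
                     clamp_idx(seq_len(dims[2]) + dy, dims[2])]
    as.vector(acc / 9)
  } else if (length(dims) == 3) {
    A <- array(buf, dims)
    acc <- array(0, dims)
    for (dx in -1:1) for (dy in -1:1) for (dz in -1:1)
      acc <- acc + A[clamp_idx(seq_len(dims[1]) + dx, dims[1]),
                     clamp_idx(seq_len(dims[2]) + dy, dims[2]),
                     clamp_idx(seq_len(dims[3]) + dz, dims[3])]
    as.vector(acc / 27)
  } else {
    nd_stop("the direct box-mean variant is written per dimensionality and ",
            "supports 2-D and 3-D only - which is the point of the exercise")
  }
}
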