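#' End-to-end capability demo
#'
#' Renders three panels from one deterministic synthetic scene, exercising
#' the whole stack:
#' \describe{
#'   \item{panel a}{the scene extended by mirroring, with four algorithms
#'     applied to sub-windows of the extended view: anisotropic diffusion,
#'     MSER (as a region label image plus region table), Sobel filtering
#'     and Gaussian convolution}
#'   \item{panel b}{2,000 points randomly sampled from a window of the
#'     scene, indexed in a k-d tree, nearest-neighbour extrapolated to a
#'     continuous field and rasterized back onto the grid}
#'   \item{panel c}{an n-linearly interpolated, affine-rotated view of a
#'     tilted window, rasterized}
#' }
#' All outputs are written as 8-bit TIFF (linearly rescaled to the 0..255
#' range), the sampled points as CSV, and every parameter as a JSON file
#' next to the images. A fixed seed makes each run bit-identical.
#'
#' The algorithm settings are illustrative defaults, not reproductions of
#' any particular published figure.
#'
#' @param seed RNG seed for the scene noise and the point sampling
#' @param out_dir output directory (created if missing)
#' @param size side length of the square scene
#' @param n_points number of sparse samples for panel b
#' @return invisibly, a named list of the files written
#' @export
demo_figure1 <- function(seed = 42, out_dir = "demo_out", size = 96,
                         n_points = 2000) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list()
  emit <- function(name, img) {
    p <- file.path(out_dir, name)
    write_image(to_u8(img), p)
    paths[[name]] <<- p
    p
  }

  # --- scene: blob + nested squares + noise, in [0, 255] -------------------
  fac <- image_factory("array", "f64")
  blob <- materialize(generate_fixture("gaussian_blob", c(size, size),
                                       factory = fac, amplitude = 150,
                                       sigma = size / 6))
  sq <- materialize(generate_fixture("squares", c(size, size), factory = fac,
                                     levels = c(20, 70, 120),
                                     inset = round(size / 6)))
  noise <- materialize(generate_fixture("uniform_noise", c(size, size),
                                        factory = fac, seed = seed,
                                        range = c(0, 30)))
  scene <- image_from_array(pmin(blob + sq + noise, 255), fac)
  emit("scene.tif", scene)

  # --- panel a: mirror-extended scene, four algorithms on sub-windows ------
  ext <- extend(scene, "mirror_single")
  m <- round(size / 8)
  win <- window(ext, nd_interval(c(-m, -m), c(size - 1 + m, size - 1 + m)))
  emit("panel_a_extended.tif", win)
  q <- round((size + 2 * m) / 4)
  sub <- function(i) window(ext, nd_interval(c(-m + (i - 1) * q, -m),
                                             c(-m + i * q - 1, size - 1 + m)))
  emit("panel_a_diffusion.tif",
       anisotropic_diffusion(sub(1), n_iter = 10, kappa = 20, lam = 0.2))
  tree <- build_component_tree(to_u8(sub(2)))
  regions <- mser_detect(tree, delta = 5, min_size = 30,
                         max_size = num_elements(img_interval(sub(2))) / 2,
                         max_rate = 1)
  label <- create_image(image_factory("array", "u8"),
                        interval_dims(img_interval(sub(2))))
  if (nrow(regions)) {
    shade <- round(seq(255, 80, length.out = nrow(regions)))
    for (i in seq_len(nrow(regions))) {
      P <- component_coords(tree, regions$id[i])
      for (j in seq_len(nrow(P))) img_set(label, P[j, ], shade[i])
    }
  }
  emit("panel_a_mser_labels.tif", label)
  utils::write.csv(regions, file.path(out_dir, "panel_a_mser_regions.csv"),
                   row.names = FALSE)
  paths[["panel_a_mser_regions.csv"]] <-
    file.path(out_dir, "panel_a_mser_regions.csv")
  grad <- sobel(sub(3))
  gmag <- sqrt(materialize(zero_min(grad[[1]]))^2 +
                 materialize(zero_min(grad[[2]]))^2)
  emit("panel_a_sobel.tif", image_from_array(gmag, fac))
  emit("panel_a_gauss.tif", gaussian_convolve(sub(4), sigmas = 3))

  # --- panel b: sparse sampling, k-d tree, NN extrapolation ----------------
  pts <- with_seed(seed + 1, {
    X <- cbind(stats::runif(n_points, 0, size - 1),
               stats::runif(n_points, 0, size - 1))
    vals <- real_get_many(interpolate(ext, "nlinear"), X)
    nd_points(X, vals)
  })
  write_points_csv(pts, file.path(out_dir, "panel_b_points.csv"))
  paths[["panel_b_points.csv"]] <- file.path(out_dir, "panel_b_points.csv")
  field <- nn_extrapolate(build_kdtree(pts))
  emit("panel_b_extrapolated.tif",
       rasterize(field, interval_from_dims(c(size, size)), fac))

  # --- panel c: interpolated + affine-rotated tilted window ----------------
  ctr <- (size - 1) / 2
  rot <- affine_compose(
    nd_affine(diag(2), c(ctr, ctr)),
    affine_compose(affine_rotation2d(pi / 8),
                   nd_affine(diag(2), c(-ctr, -ctr))))
  cimg <- affine_view(interpolate(ext, "nlinear"), rot)
  emit("panel_c_affine.tif",
       rasterize(cimg, interval_from_dims(c(size, size)), fac))

  params <- list(seed = seed, size = size, n_points = n_points,
                 panel_a = list(extension = "mirror_single",
                                diffusion = list(n_iter = 10, kappa = 20,
                                                 lam = 0.2),
                                mser = list(delta = 5, min_size = 30,
                                            max_rate = 1),
                                gauss_sigma = 3),
                 panel_b = list(interpolation = "nlinear",
                                extrapolation = "nearest_neighbor"),
                 panel_c = list(interpolation = "nlinear",
                                rotation_rad = pi / 8))
  jsonlite::write_json(params, file.path(out_dir, "params.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  paths[["params.json"]] <- file.path(out_dir, "params.json")
  invisible(paths)
}

# rescale any real image linearly onto 0..255 and convert to u8 (identity
# for u8 inputs); deterministic, used for demo output rendering
to_u8 <- function(img) {
  if (img_type(img) == "u8") return(img)
  A <- materialize(img)
  rng <- range(A)
  scaled <- if (rng[2] > rng[1]) (A - rng[1]) / (rng[2] - rng[1]) * 255
    else A * 0
  image_from_array(round(scaled), image_factory("array", "u8"))
}
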