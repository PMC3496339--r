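test_that("gaussian kernels are normalized and shrink with sigma", {
  for (s in c(0.5, 1, 2.7)) {
    k <- gaussian_kernel(s)
    expect_equal(sum(k), 1, tolerance = 1e-14)
    expect_length(k, 2 * max(2, ceiling(3 * s)) + 1)
    expect_true(all(diff(k[1:((length(k) + 1) / 2)]) >= 0))  # unimodal rise
  }
  expect_identical(gaussian_kernel(0), 1)
  expect_error(gaussian_kernel(-1), ">= 0")
})

test_that("separable convolution matches the dense oracle in 2-D", {
  img <- generate_fixture("uniform_noise", c(7, 6), seed = 3)
  kx <- gaussian_kernel(0.8)
  ky <- c(0.25, 0.5, 0.25)
  got <- materialize(separable_convolve(img, list(kx, ky)))
  want <- oracle_dense_correlate(materialize(img), list(kx, ky))
  expect_equal(got, want, tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("gaussian convolution preserves the mean under periodic boundary", {
  img <- generate_fixture("uniform_noise", c(12, 12), seed = 4)
  out <- gaussian_convolve(img, 1.5, extension = "periodic")
  expect_equal(mean(materialize(out)), mean(materialize(img)),
               tolerance = 1e-12)
})

test_that("sobel responds 2*4^(n-1) on a unit ramp, zero across it", {
  img <- generate_fixture("ramp", c(8, 8), coeffs = c(1, 0))
  g <- sobel(img)
  gx <- materialize(g[[1]]); gy <- materialize(g[[2]])
  expect_equal(gx[3:6, 3:6], array(8, c(4, 4)), ignore_attr = TRUE)
  expect_equal(gy[3:6, 3:6], array(0, c(4, 4)), ignore_attr = TRUE)
})

test_that("difference of gaussians finds an isolated blob at its center", {
  img <- generate_fixture("gaussian_blob", c(21, 21), sigma = 2,
                          amplitude = 100)
  det <- dog_detect(img, sigma1 = 1, sigma2 = 3, threshold = 1)
  expect_gte(nrow(det), 1)
  expect_equal(unlist(det[1, c("x1", "x2")]), c(10, 10),
               ignore_attr = TRUE)
  expect_equal(det$scale[1], sqrt(3))
  expect_error(dog_detect(img, 2, 1, 0), "sigma")
})

test_that("a constant image yields no DoG detections (strict extrema)", {
  img <- create_image(image_factory("array", "f64"), c(9, 9))
  img_write_values(img, rep(5, 81))
  expect_equal(nrow(dog_detect(img, 1, 2, 0)), 0)
})

test_that("the component tree matches per-level flood-fill partitions", {
  img <- create_image(image_factory("array", "f64"), 5)
  img_write_values(img, c(0, 2, 0, 3, 0))
  tree <- build_component_tree(img)
  sizes <- t(vapply(tree$nodes, function(n) c(n$level, n$size),
                    numeric(2)))
  expect_equal(sizes[order(sizes[, 1], sizes[, 2]), ],
               rbind(c(0, 5), c(2, 1), c(3, 1)), ignore_attr = TRUE)
  # node pixel sets equal the oracle's threshold components
  want <- oracle_level_partition(materialize(img))
  got <- lapply(tree$nodes, function(n)
    list(level = n$level, pixels = sort(n$pixels)))
  expect_identical(partition_keys(got), partition_keys(want))
})

test_that("random images: tree components equal the flood-fill oracle", {
  set.seed(31)
  for (rep in 1:8) {
    dims <- sample(3:5, sample(1:2, 1), replace = TRUE)
    img <- create_image(image_factory("array", "u8"), dims)
    img_write_values(img, sample(0:3, prod(dims), replace = TRUE))
    got <- lapply(build_component_tree(img)$nodes, function(n)
      list(level = n$level, pixels = sort(n$pixels)))
    expect_identical(partition_keys(got),
                     partition_keys(oracle_level_partition(materialize(img))))
  }
})

test_that("MSER finds exactly the bright square on a nested-squares scene", {
  img <- generate_fixture("squares", c(24, 24), levels = c(0, 60, 200),
                          inset = 4)
  tree <- build_component_tree(img)
  r <- mser_detect(tree, delta = 5)
  expect_equal(nrow(r), 1)
  expect_equal(r$level, 200)
  expect_equal(r$size, 8 * 8)        # two insets of 4 per side from 24
  expect_equal(r$rate, 0)
  # the region's pixels really are the inner square
  P <- component_coords(tree, r$id)
  expect_true(all(P >= 8 & P <= 15))
})

test_that("MSER returns nothing on a constant image", {
  img <- create_image(image_factory("array", "u8"), c(6, 6))
  img_write_values(img, rep(7, 36))
  expect_equal(nrow(mser_detect(build_component_tree(img), delta = 2)), 0)
})

test_that("anisotropic diffusion conserves mass and smooths edges", {
  img <- generate_fixture("squares", c(16, 16), levels = c(0, 100))
  out <- anisotropic_diffusion(img, n_iter = 20, kappa = 30, lam = 0.25)
  A <- materialize(img); B <- materialize(out)
  expect_equal(sum(B), sum(A), tolerance = 1e-9)
  expect_lt(max(abs(diff(B[, 8]))), max(abs(diff(A[, 8]))))  # softer edge
  expect_error(anisotropic_diffusion(img, 1, 30, 0.3), "stability")
  expect_error(anisotropic_diffusion(img, 1, 0, 0.1), "kappa")
})

test_that("diffusion with huge kappa approaches linear smoothing", {
  img <- generate_fixture("impulse", c(9, 9))
  out <- materialize(anisotropic_diffusion(img, 1, kappa = 1e9, lam = 0.25))
  # one explicit heat step: center loses 4*lam, each face neighbour gains lam
  expect_equal(out[5, 5], 1 - 4 * 0.25)
  expect_equal(out[4, 5], 0.25)
  expect_equal(out[5, 4], 0.25)
})
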