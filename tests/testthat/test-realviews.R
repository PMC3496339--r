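test_that("nearest-neighbour interpolation rounds half toward +inf", {
  line <- create_image(image_factory("array", "f64"), 4)
  img_write_values(line, c(0, 10, 20, 30))
  nn <- interpolate(line, "nearest")
  expect_equal(real_get(nn, 1.49), 10)
  expect_equal(real_get(nn, 1.5), 20)
  expect_equal(real_get(nn, 2), 20)
})

test_that("n-linear interpolation blends the surrounding grid samples", {
  line <- create_image(image_factory("array", "f64"), 2)
  img_write_values(line, c(0, 10))
  li <- interpolate(line, "nlinear")
  expect_equal(real_get(li, 0.25), 2.5)
  expect_equal(real_get(li, 0.5), 5)
  expect_equal(real_get(li, 1), 10)   # exact at grid points
})

test_that("n-linear interpolation reproduces affine ramps exactly", {
  for (dims in list(7, c(5, 6), c(4, 4, 4))) {
    n <- length(dims)
    coeffs <- seq_len(n) + 0.5
    img <- generate_fixture("ramp", dims, coeffs = coeffs, intercept = 3)
    li <- interpolate(img, "nlinear")
    set.seed(11 + n)
    X <- sapply(dims, function(d) runif(50, 0, d - 1))
    if (n == 1) X <- matrix(X, ncol = 1)
    got <- real_get_many(li, X)
    want <- as.vector(X %*% coeffs) + 3
    expect_equal(got, want, tolerance = 1e-12, info = paste0(n, "D"))
  }
})

test_that("procedural continuous images evaluate their closed form", {
  f <- real_procedural(function(X) sin(X[, 1]) + X[, 2], 2)
  expect_equal(real_ndim(f), 2)
  expect_equal(real_get(f, c(pi / 2, 1)), 2)
})

test_that("affine transforms compose, invert and apply consistently", {
  A <- nd_affine(matrix(c(2, 0, 0, 3), 2, 2), c(1, -1))
  B <- affine_rotation2d(pi / 2)
  x <- c(1, 2)
  expect_equal(affine_apply(A, rbind(x))[1, ], c(3, 5))
  # compose applies B first
  expect_equal(affine_apply(affine_compose(A, B), rbind(x))[1, ],
               affine_apply(A, affine_apply(B, rbind(x)))[1, ])
  AI <- affine_inverse(A)
  expect_equal(affine_apply(AI, affine_apply(A, rbind(x)))[1, ], x)
  expect_error(affine_inverse(nd_affine(matrix(0, 2, 2))), "determinant")
})

test_that("an identity affine view rasterizes back to the source", {
  img <- generate_fixture("gaussian_blob", c(9, 9))
  cimg <- affine_view(interpolate(extend(img, "mirror_single")),
                      nd_affine(diag(2)))
  out <- rasterize(cimg, img_interval(img))
  expect_equal(materialize(out), materialize(img), tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("a quarter rotation about the center permutes the samples", {
  img <- create_image(image_factory("array", "f64"), c(5, 5))
  img_write_values(img, seq_len(25))
  ctr <- c(2, 2)
  # view(x) = source(R^{-1}(x - c) + c): rotating the image by +90 deg
  rot <- affine_compose(nd_affine(diag(2), ctr),
                        affine_compose(affine_rotation2d(pi / 2),
                                       nd_affine(diag(2), -ctr)))
  cimg <- affine_view(interpolate(extend(img, "periodic")), rot)
  out <- materialize(rasterize(cimg, img_interval(img)))
  # the rasterized rotation must be a permutation of the original samples
  expect_equal(sort(as.vector(out)), 1:25)
  expect_false(identical(as.vector(out), as.numeric(1:25)))
})

test_that("rasterize honours output intervals with non-zero minimum", {
  img <- generate_fixture("ramp", c(6, 6), coeffs = c(1, 10))
  cimg <- interpolate(extend(img, "mirror_single"))
  iv <- nd_interval(c(2, 3), c(4, 5))
  out <- rasterize(cimg, iv)
  expect_equal(img_interval(out), iv)
  expect_equal(materialize(out), materialize(img)[3:5, 4:6],
               ignore_attr = TRUE)
})
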