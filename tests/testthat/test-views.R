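ramp_img <- function(dims, backend = "array") {
  img <- create_image(image_factory(backend, "f64", cell_dims = 3), dims)
  img_write_values(img, seq_len(prod(dims)))
  img
}

test_that("translate shifts the domain without touching the data", {
  img <- ramp_img(c(3, 3))
  v <- translate(img, c(5, -2))
  expect_equal(img_interval(v)$min, c(5, -2))
  expect_equal(img_get(v, c(5, -2)), img_get(img, c(0, 0)))
  expect_equal(img_get(v, c(7, 0)), img_get(img, c(2, 2)))
})

test_that("permute swaps two dimensions; applying it twice is the identity", {
  img <- ramp_img(c(3, 4))
  p <- permute(img, 1, 2)
  expect_equal(interval_dims(img_interval(p)), c(4, 3))
  expect_equal(img_get(p, c(3, 2)), img_get(img, c(2, 3)))
  pp <- permute(p, 1, 2)
  expect_equal(materialize(pp), materialize(img), ignore_attr = TRUE)
})

test_that("invert_axis mirrors one dimension and is an involution", {
  img <- ramp_img(c(4, 2))
  f <- invert_axis(img, 1)
  expect_equal(img_get(f, c(0, 0)), img_get(img, c(-0, 0)))
  expect_equal(materialize(invert_axis(f, 1)), materialize(img),
               ignore_attr = TRUE)
  # values reverse along dimension 1
  expect_equal(materialize(zero_min(f))[, 1], rev(materialize(img)[, 1]))
})

test_that("rotate90 turns the plane; four turns compose to the identity", {
  img <- ramp_img(c(5, 4))
  r <- img
  for (k in 1:4) r <- rotate90(r, 1, 2)
  expect_equal(img_interval(r), img_interval(img))
  expect_equal(materialize(r), materialize(img), ignore_attr = TRUE)
  # one turn: the new first row is the old last column
  w <- rotate90(img, 1, 2)
  wz <- zero_min(w)
  expect_equal(materialize(wz)[1, ], materialize(img)[, 4])
})

test_that("hyperslice fixes one dimension of a 3-D image", {
  img <- ramp_img(c(4, 3, 2))
  s <- hyperslice(img, 3, 1)
  expect_equal(img_ndim(s), 2)
  expect_equal(materialize(s), materialize(img)[, , 2], ignore_attr = TRUE)
  s2 <- hyperslice(img, 1, 2)
  expect_equal(materialize(s2), materialize(img)[3, , ], ignore_attr = TRUE)
})

test_that("window restricts the domain and checks containment", {
  img <- ramp_img(c(5, 5))
  w <- window(img, nd_interval(c(1, 2), c(3, 4)))
  expect_equal(materialize(w), materialize(img)[2:4, 3:5],
               ignore_attr = TRUE)
  expect_error(window(img, nd_interval(c(0, 0), c(5, 2))), "contain")
})

test_that("views are writable and write through to the source buffer", {
  for (backend in c("array", "cell", "list")) {
    img <- ramp_img(c(4, 4), backend)
    v <- rotate90(translate(img, c(2, 2)), 1, 2)
    P <- interval_coords(img_interval(v))
    img_set(v, P[1, ], 999)
    expect_equal(sum(materialize(img) == 999), 1, info = backend)
  }
})

test_that("view construction allocates no pixel buffers", {
  img <- ramp_img(c(6, 6))
  nd_pixel_alloc_reset()
  v <- rotate90(invert_axis(translate(img, c(1, 1)), 2), 1, 2)
  v <- extend(v, "periodic")
  expect_equal(nd_pixel_alloc_count(), 0)
  invisible(materialize(v, nd_interval(c(0, 0), c(5, 5))))
  expect_equal(nd_pixel_alloc_count(), 0)  # reading still copies lazily
})

test_that("chained integer views fuse into a single transform node", {
  img <- ramp_img(c(4, 4))
  v <- translate(permute(translate(img, c(1, 2)), 1, 2), c(-1, -1))
  expect_equal(view_depth(v), 1)
  old <- options(ndimg.simplify = FALSE)
  u <- translate(permute(translate(img, c(1, 2)), 1, 2), c(-1, -1))
  options(old)
  expect_equal(view_depth(u), 3)
  expect_equal(materialize(v), materialize(u), ignore_attr = TRUE)
  expect_equal(view_depth(simplify(u)), 1)
  expect_equal(materialize(simplify(u)), materialize(v),
               ignore_attr = TRUE)
})

test_that("simplify fuses across runs but preserves extension nodes", {
  img <- ramp_img(c(3, 3))
  old <- options(ndimg.simplify = FALSE)
  v <- translate(extend(translate(img, c(1, 1)), "periodic"), c(2, 2))
  options(old)
  s <- simplify(v)
  w <- window(s, nd_interval(c(3, 3), c(5, 5)))
  expect_equal(materialize(w), materialize(img), ignore_attr = TRUE)
})

test_that("mixed transforms compose and invert correctly", {
  t1 <- nd_mixed_transform(2, comp = c(2, 1), sign = c(1, -1),
                           off = c(3, 0))
  q <- c(4, 5)
  p <- transform_apply(t1, q)
  expect_equal(p, c(3 + q[2], -q[1]))
  t2 <- transform_inverse(t1)
  expect_equal(transform_apply(t2, p), q)
  chain <- transform_chain(t1, t2)   # p -> q -> p
  expect_equal(transform_apply(chain, p), p)
})

test_that("all four extension strategies match the folding oracle", {
  line <- create_image(image_factory("array", "f64"), 3)
  img_write_values(line, c(10, 20, 30))
  probe <- -5:7
  for (kind in c("mirror_single", "mirror_double", "periodic")) {
    ext <- extend(line, kind)
    got <- vapply(probe, function(i) img_get(ext, i), numeric(1))
    want <- vapply(probe, function(i)
      oracle_extended_get(c(10, 20, 30), i, kind), numeric(1))
    expect_equal(got, want, info = kind)
  }
  cst <- extend(line, extension_strategy("constant", constant_value = -1))
  expect_equal(img_get(cst, -1), -1)
  expect_equal(img_get(cst, 3), -1)
  expect_equal(img_get(cst, 2), 30)
})

test_that("the documented 1-D extension examples hold exactly", {
  line <- create_image(image_factory("array", "f64"), 3)
  img_write_values(line, c(10, 20, 30))
  read <- function(kind, at) img_get(extend(line, kind), at)
  # mirror without border repetition: ..., 30, 20, | 10 20 30 |, 20, 10, ...
  expect_equal(vapply(-2:4, function(i) read("mirror_single", i),
                      numeric(1)), c(30, 20, 10, 20, 30, 20, 10))
  # mirror with border repetition: ..., 20, 10, | 10 20 30 |, 30, 20, ...
  expect_equal(vapply(-2:4, function(i) read("mirror_double", i),
                      numeric(1)), c(20, 10, 10, 20, 30, 30, 20))
  expect_equal(vapply(-2:4, function(i) read("periodic", i),
                      numeric(1)), c(20, 30, 10, 20, 30, 10, 20))
})

test_that("writes into the in-bounds part of an extended view pass through", {
  img <- ramp_img(c(3, 3))
  ext <- extend(img, "mirror_single")
  img_set(ext, c(1, 1), -4)
  expect_equal(img_get(img, c(1, 1)), -4)
  expect_error(img_set(ext, c(-1, 0), 5), "outside")
})

test_that("converted views apply the converter on read and invert on write", {
  img <- create_image(image_factory("array", "f64"), c(2, 2))
  img_write_values(img, c(0.1, 0.5, 1.2, -0.3))
  halved <- convert_view(img, nd_converter(function(v) v * 2,
                                           "f64", "f64",
                                           inv = function(v) v / 2))
  expect_equal(materialize(halved), 2 * materialize(img),
               ignore_attr = TRUE)
  img_set(halved, c(0, 0), 10)
  expect_equal(img_get(img, c(0, 0)), 5)
  ro <- convert_view(img, clamp_u8_converter())
  expect_error(img_set(ro, c(0, 0), 1), "invert|read-only|inverse")
})

test_that("random view chains: fused equals node-by-node evaluation", {
  set.seed(7)
  img <- create_image(image_factory("array", "f64"), c(4, 3, 3))
  img_write_values(img, runif(36))
  for (rep in 1:10) {
    ch <- random_view_chain(img, depth = sample(1:5, 1))
    expect_equal(all_samples(ch$fused), all_samples(ch$sequential))
    expect_equal(img_interval(ch$fused), img_interval(ch$sequential))
  }
})
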