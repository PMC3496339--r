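test_that("random access reads and writes through a reusable handle", {
  img <- create_image(image_factory("array", "f64"), c(4, 4))
  ra <- random_access(img)
  ra_set_pos(ra, c(2, 3))
  ra_set(ra, 7.5)
  expect_equal(ra_get(ra), 7.5)
  expect_equal(img_get(img, c(2, 3)), 7.5)
  ra_set_pos(ra, c(0, 0))
  expect_equal(ra_get(ra), 0)
})

test_that("bounds checking is on by default and can be disabled", {
  img <- create_image(image_factory("array", "f64"), c(3, 3))
  expect_error(img_get(img, c(3, 0)), "outside|bounds")
  old <- options(ndimg.checked = FALSE)
  on.exit(options(old))
  # unchecked access into the flat buffer does not raise the interval error
  expect_silent(img_get(img, c(1, 1)))
})

test_that("cursors visit every sample exactly once on all backends", {
  for (backend in c("array", "cell", "list")) {
    img <- create_image(image_factory(backend, "f64", cell_dims = 2),
                        c(3, 4))
    v <- seq_len(12) + 0.25
    img_write_values(img, v)
    cur <- cursor(img)
    seen <- list()
    while (cursor_has_next(cur)) {
      cursor_fwd(cur)
      seen[[length(seen) + 1]] <- list(pos = cursor_localize(cur),
                                       val = cursor_value(cur))
    }
    expect_length(seen, 12)
    P <- do.call(rbind, lapply(seen, `[[`, "pos"))
    expect_equal(nrow(unique(P)), 12, info = backend)  # no coordinate twice
    for (s in seen)
      expect_equal(img_get(img, s$pos), s$val, info = backend)
  }
})

test_that("cell images iterate cell by cell, flat images in raster order", {
  a <- create_image(image_factory("array", "u8"), c(4, 4))
  c4 <- create_image(image_factory("cell", "u8", cell_dims = 2), c(4, 4))
  expect_false(iteration_order_equal(a, c4))
  expect_true(iteration_order_equal(a, a))
  it <- iterate(c4)
  # same sample set, different order
  expect_equal(nrow(unique(it$coords)), 16)
  expect_false(identical(it$coords, iterate(a)$coords))
})

test_that("a cursor reuses one proxy instead of allocating per sample", {
  img <- create_image(image_factory("array", "f64"), c(8, 8))
  cur <- cursor(img)
  nd_alloc_reset()
  total <- 0
  while (cursor_has_next(cur)) {
    cursor_fwd(cur)
    total <- total + proxy_value(cursor_proxy(cur))
  }
  expect_equal(nd_alloc_count(), 0)   # the scan allocated no value objects
  # a snapshot is the explicit way to materialize a value object
  cur2 <- cursor(img)
  cursor_fwd(cur2)
  invisible(proxy_snapshot(cursor_proxy(cur2)))
  expect_equal(nd_alloc_count(), 1)
})

test_that("proxies are live handles: writes elsewhere show through them", {
  img <- create_image(image_factory("list", "f64"), c(3, 3))
  ra <- random_access(img)
  ra_set_pos(ra, c(1, 1))
  expect_equal(ra_get(ra), 0)
  img_set(img, c(1, 1), 42)
  expect_equal(ra_get(ra), 42)   # same storage, not a copy
})

test_that("cursor_set writes at the cursor position", {
  img <- create_image(image_factory("cell", "u8", cell_dims = 2), c(3, 3))
  cur <- cursor(img)
  while (cursor_has_next(cur)) {
    cursor_fwd(cur)
    p <- cursor_localize(cur)
    cursor_set(cur, (p[1] + p[2]) %% 256)
  }
  expect_equal(img_get(img, c(2, 2)), 4)
  expect_equal(img_get(img, c(0, 0)), 0)
})

test_that("materialize returns the dense array and honours sub-intervals", {
  img <- image_from_array(array(1:24, c(2, 3, 4)))
  A <- materialize(img)
  expect_equal(A, array(1:24, c(2, 3, 4)), ignore_attr = TRUE)
  sub <- materialize(img, nd_interval(c(0, 1, 1), c(1, 2, 2)))
  expect_equal(sub, array(1:24, c(2, 3, 4))[1:2, 2:3, 2:3],
               ignore_attr = TRUE)
})

test_that("image_from_array round-trips through every backend", {
  A <- array(runif_seeded(60), c(3, 4, 5))
  for (backend in c("array", "cell", "list")) {
    img <- image_from_array(A, image_factory(backend, "f64", cell_dims = 2))
    expect_equal(materialize(img), A, ignore_attr = TRUE, info = backend)
  }
})
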