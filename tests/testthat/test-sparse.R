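test_that("the k-d tree balances 1-D points with the lower median", {
  # 7 points on a line, inserted in shuffled order
  coords <- matrix(c(3, 0, 6, 1, 5, 2, 4), ncol = 1)
  tree <- build_kdtree(coords, values = 1:7)
  expect_equal(kdtree_depth(tree), 3)
  # in-order traversal recovers the sorted coordinate order
  expect_equal(coords[kdtree_indices(tree), 1], 0:6)
})

test_that("tree searches equal the linear scan, including ties", {
  set.seed(21)
  for (n in c(2, 3)) {
    C <- matrix(runif(80 * n, 0, 10), ncol = n)
    C[41:45, ] <- C[1:5, ]          # exact duplicates force distance ties
    pts <- nd_points(C, seq_len(80))
    tree <- build_kdtree(pts)
    for (rep in 1:40) {
      q <- runif(n, -1, 11)
      expect_identical(nn_search(tree, q), nn_search(pts, q))
      k <- sample(1:10, 1)
      expect_identical(knn_search(tree, q, k), knn_search(pts, q, k))
      r <- runif(1, 0, 6)
      expect_identical(radius_search(tree, q, r), radius_search(pts, q, r))
    }
  }
})

test_that("distance ties resolve to the earliest inserted point", {
  C <- rbind(c(0, 0), c(2, 0), c(2, 0))
  pts <- nd_points(C, c("a", "b", "c"))
  tree <- build_kdtree(pts)
  got <- nn_search(tree, c(2, 0))
  expect_equal(got$index, 2L)       # not 3, despite equal distance
  expect_equal(nn_search(pts, c(2, 0))$index, 2L)
})

test_that("knn returns neighbours in non-decreasing distance order", {
  set.seed(5)
  C <- matrix(runif(60), ncol = 2)
  tree <- build_kdtree(C, values = 1:30)
  res <- knn_search(tree, c(0.5, 0.5), 7)
  expect_length(res$index, 7)
  expect_true(all(diff(res$dist) >= 0))
})

test_that("searches validate their arguments", {
  pts <- nd_points(cbind(1:3, 1:3), 1:3)
  expect_error(nn_search(pts, c(1, 2, 3)), "dimension")
  expect_error(knn_search(pts, c(0, 0), 4), "between")
  expect_error(radius_search(pts, c(0, 0), -1), ">= 0")
  expect_error(nd_points(cbind(NA, 1), 1), "finite")
})

test_that("nearest-neighbour extrapolation is the Voronoi partition", {
  set.seed(9)
  C <- matrix(runif(24, 0, 8), ncol = 2)
  vals <- rnorm(12)
  field <- nn_extrapolate(nd_points(C, vals))
  out <- materialize(rasterize(field, interval_from_dims(c(8, 8))))
  P <- interval_coords(interval_from_dims(c(8, 8)))
  for (i in seq_len(nrow(P))) {
    d2 <- rowSums(sweep(C, 2, P[i, ])^2)
    expect_equal(out[i], vals[which(d2 == min(d2))[1]])
  }
})

test_that("points survive a CSV round trip and headers are validated", {
  pts <- nd_points(cbind(c(0.5, 1.5), c(2, 3), c(4, 5)), c(7.5, -1))
  path <- tempfile(fileext = ".csv")
  bad <- tempfile(fileext = ".csv")
  on.exit(unlink(c(path, bad)), add = TRUE)
  write_points_csv(pts, path)
  back <- read_points_csv(path)
  expect_equal(back$coords, pts$coords, ignore_attr = TRUE)
  expect_equal(back$values, pts$values)
  writeLines(c("a,b,value", "1,2,3"), bad)
  expect_error(read_points_csv(bad), "header")
})
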