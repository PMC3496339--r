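proxy_free_value <- function(v) v$value

test_that("integer types wrap modulo their bit width", {
  expect_equal(type_wrap("u8", 300), 44)
  expect_equal(type_wrap("u8", -1), 255)
  expect_equal(type_wrap("u16", 65536 + 7), 7)
  expect_equal(type_wrap("i16", 32768), -32768)
  expect_equal(type_wrap("i32", 2^31), -2^31)
  expect_equal(type_wrap("bit", 5), 1)
  expect_equal(type_wrap("bit", 0), 0)
})

test_that("typed arithmetic wraps like fixed-width hardware", {
  a <- nd_value(200, "u8")
  b <- nd_value(100, "u8")
  expect_equal(proxy_free_value(numeric_add(a, b)), 44)
  expect_equal(proxy_free_value(numeric_sub(b, a)), 156)
  expect_equal(proxy_free_value(numeric_mul(nd_value(16, "u8"),
                                            nd_value(16, "u8"))), 0)
})

test_that("integer division truncates and rejects zero divisors", {
  expect_equal(proxy_free_value(numeric_div(nd_value(7, "i32"),
                                            nd_value(2, "i32"))), 3)
  expect_equal(proxy_free_value(numeric_div(nd_value(-7, "i32"),
                                            nd_value(2, "i32"))), -3)
  expect_error(numeric_div(nd_value(1, "u8"), nd_value(0, "u8")),
               "zero")
})

test_that("f32 stores true single-precision values", {
  v <- nd_value(1 / 3, "f32")$value
  expect_false(identical(v, 1 / 3))              # quantized
  expect_identical(type_wrap("f32", v), v)       # idempotent
  expect_identical(type_wrap("f32", c(-2.5, 0, 1e6)), c(-2.5, 0, 1e6))
})

test_that("complex arithmetic works and comparison is refused", {
  s <- numeric_add(nd_value(1 + 2i, "cf32"), nd_value(3 - 2i, "cf32"))
  expect_equal(s$value, 4 + 0i)
  p <- numeric_mul(nd_value(1 + 1i, "cf32"), nd_value(1 - 1i, "cf32"))
  expect_equal(p$value, 2 + 0i)
  expect_false(type_is_ordered("cf32"))
  expect_error(numeric_compare(nd_value(1i, "cf32"), nd_value(2i, "cf32")),
               "ordered|compar")
})

test_that("ARGB packs four 8-bit channels into one sample", {
  p <- argb_pack(255, 10, 20, 30)
  ch <- argb_unpack(p)
  expect_equal(unlist(ch[c("a", "r", "g", "b")]), c(255, 10, 20, 30),
               ignore_attr = TRUE)
  # per-channel clamped arithmetic
  s <- numeric_add(nd_value(argb_pack(200, 250, 100, 0), "argb"),
                   nd_value(argb_pack(100, 10, 100, 5), "argb"))
  expect_equal(unlist(argb_unpack(s$value)[c("a", "r", "g", "b")]),
               c(255, 255, 200, 5), ignore_attr = TRUE)
})

test_that("converters map samples on the fly", {
  conv <- clamp_u8_converter()
  expect_equal(conv$fn(c(0.4, 254.6, 300, -5)), c(0, 255, 255, 0))
  id <- identity_converter("u8")
  expect_equal(id$fn(77), 77)
})

test_that("value allocations are observable", {
  nd_alloc_reset()
  invisible(nd_value(1, "u8"))
  invisible(nd_value(2, "u8"))
  expect_equal(nd_alloc_count(), 2)
})
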