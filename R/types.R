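#' Value types
#'
#' The pixel algebra is defined over a closed registry of sample types,
#' keyed by short string tags:
#' \describe{
#'   \item{`"bit"`}{binary \{0,1\}}
#'   \item{`"u8"`}{unsigned byte, 0..255}
#'   \item{`"i16"`, `"u16"`, `"i32"`}{signed/unsigned integers}
#'   \item{`"f32"`, `"f64"`}{IEEE reals; `f32` values are quantized to
#'     single precision on every write, so buffers hold exactly what a
#'     32-bit float file would hold}
#'   \item{`"cf32"`}{complex (real, imaginary) pair}
#'   \item{`"argb"`}{four 8-bit channels packed into one 32-bit word}
#' }
#' Integer types wrap modulo 2^bits on overflow (raw-byte storage
#' semantics); clamping is available as an explicit converter instead.
#' Integer division truncates toward zero and raises an error on a zero
#' divisor; real division follows IEEE (inf/nan). ARGB arithmetic operates
#' per channel with clamping at 255, since arithmetic on the packed word is
#' meaningless. Complex values are not ordered; comparison is unsupported.
#'
#' @name value-types
NULL

# quantize doubles to IEEE single precision (exact float32 semantics)
float32_quantize <- function(v) {
  if (length(v) == 0) return(v)
  b <- writeBin(as.double(v), raw(), size = 4L)
  readBin(b, "double", n = length(v), size = 4L)
}

wrap_unsigned <- function(v, bits) v %% 2^bits
wrap_signed <- function(v, bits) {
  h <- 2^(bits - 1)
  ((v + h) %% 2^bits) - h
}

clamp255 <- function(v) pmin(pmax(round(v), 0), 255)

int_div <- function(a, b, wrap) {
  if (any(b == 0)) nd_stop("integer division by zero")
  wrap(trunc(a / b))
}

argb_channel_op <- function(a, b, op) {
  ca <- argb_unpack_many(a)
  cb <- argb_unpack_many(b)
  argb_pack_many(clamp255(op(ca$a, cb$a)), clamp255(op(ca$r, cb$r)),
                 clamp255(op(ca$g, cb$g)), clamp255(op(ca$b, cb$b)))
}

# one registry entry per tag; `wrap` canonicalizes any written value into
# the type's storage semantics, arithmetic is defined on canonical values
.nd_types <- list()

nd_register_type <- function(tag, storage, ordered, wrap, add, sub, mul, div,
                             zero) {
  .nd_types[[tag]] <<- list(tag = tag, storage = storage, ordered = ordered,
                            wrap = wrap, add = add, sub = sub, mul = mul,
                            div = div, zero = zero)
}

local({
  int_type <- function(tag, bits, signed) {
    wrap <- if (signed) function(v) wrap_signed(v, bits)
            else function(v) wrap_unsigned(v, bits)
    nd_register_type(tag, "double", ordered = TRUE, wrap = wrap,
      add = function(a, b) wrap(a + b),
      sub = function(a, b) wrap(a - b),
      mul = function(a, b) wrap(a * b),
      div = function(a, b) int_div(a, b, wrap),
      zero = 0)
  }
  nd_register_type("bit", "double", ordered = TRUE,
    wrap = function(v) as.numeric(v != 0),
    add = function(a, b) (a + b) %% 2,
    sub = function(a, b) (a - b) %% 2,
    mul = function(a, b) a * b,
    div = function(a, b) int_div(a, b, function(v) v %% 2),
    zero = 0)
  int_type("u8", 8, FALSE)
  int_type("i16", 16, TRUE)
  int_type("u16", 16, FALSE)
  int_type("i32", 32, TRUE)
  nd_register_type("f32", "double", ordered = TRUE,
    wrap = float32_quantize,
    add = function(a, b) float32_quantize(a + b),
    sub = function(a, b) float32_quantize(a - b),
    mul = function(a, b) float32_quantize(a * b),
    div = function(a, b) float32_quantize(a / b),
    zero = 0)
  nd_register_type("f64", "double", ordered = TRUE,
    wrap = as.double,
    add = `+`, sub = `-`, mul = `*`, div = `/`,
    zero = 0)
  nd_register_type("cf32", "complex", ordered = FALSE,
    wrap = function(v) complex(real = float32_quantize(Re(v)),
                               imaginary = float32_quantize(Im(v))),
    add = `+`, sub = `-`, mul = `*`,
    div = function(a, b) a / b,
    zero = 0 + 0i)
  nd_register_type("argb", "double", ordered = FALSE,
    wrap = function(v) v %% 2^32,
    add = function(a, b) argb_channel_op(a, b, `+`),
    sub = function(a, b) argb_channel_op(a, b, `-`),
    mul = function(a, b) argb_channel_op(a, b, `*`),
    div = function(a, b) {
      cb <- argb_unpack_many(b)
      if (any(cb$a == 0) || any(cb$r == 0) || any(cb$g == 0) ||
          any(cb$b == 0)) nd_stop("integer division by zero")
      argb_channel_op(a, b, function(x, y) trunc(x / y))
    },
    zero = 0)
})

#' List the registered value-type tags
#' @return character vector of tags
#' @export
nd_types <- function() names(.nd_types)

nd_type_info <- function(tag) {
  info <- .nd_types[[tag]]
  if (is.null(info)) nd_stop("unknown value type tag: '", tag, "'")
  info
}

#' Canonicalize a raw value into a type's storage semantics
#'
#' Writes into any backend pass through this: unsigned integers wrap modulo
#' 2^bits, `f32` is quantized to single precision, `bit` collapses to 0/1.
#' @param tag a type tag (see [nd_types()])
#' @param v numeric (or complex) vector
#' @export
type_wrap <- function(tag, v) nd_type_info(tag)$wrap(v)

#' Is a type ordered (supports comparison)?
#' @param tag a type tag
#' @export
type_is_ordered <- function(tag) nd_type_info(tag)$ordered

#' Boxed sample values
#'
#' `nd_value` boxes one raw sample together with its type tag; the arithmetic
#' helpers check that operands share a tag and apply the type's storage
#' semantics. Boxed values are snapshots: unlike proxies, they do not change
#' when an accessor moves. Each construction is counted by the allocation
#' accounting (see [nd_alloc_count()]).
#'
#' @param value a raw sample (numeric, or complex for `"cf32"`)
#' @param type a type tag
#' @return an object of class `nd_value`
#' @export
nd_value <- function(value, type) {
  info <- nd_type_info(type)
  nd_count_alloc()
  structure(list(value = info$wrap(value), type = type), class = "nd_value")
}

#' @export
print.nd_value <- function(x, ...) {
  cat("<nd_value ", x$type, "> ", format(x$value), "\n", sep = "")
  invisible(x)
}

check_same_type <- function(a, b) {
  if (!identical(a$type, b$type))
    nd_stop("type mismatch: '", a$type, "' vs '", b$type, "'")
}

#' Arithmetic on boxed values
#'
#' Both operands must carry the same type tag; the result follows the
#' type's storage semantics (wrap-around for unsigned integers, IEEE for
#' reals, componentwise for complex, per-channel clamped for ARGB).
#' @param a,b `nd_value` objects of the same type
#' @return an `nd_value` of the same type
#' @export
numeric_add <- function(a, b) {
  check_same_type(a, b)
  nd_value(nd_type_info(a$type)$add(a$value, b$value), a$type)
}

#' @rdname numeric_add
#' @export
numeric_sub <- function(a, b) {
  check_same_type(a, b)
  nd_value(nd_type_info(a$type)$sub(a$value, b$value), a$type)
}

#' @rdname numeric_add
#' @export
numeric_mul <- function(a, b) {
  check_same_type(a, b)
  nd_value(nd_type_info(a$type)$mul(a$value, b$value), a$type)
}

#' @rdname numeric_add
#' @export
numeric_div <- function(a, b) {
  check_same_type(a, b)
  nd_value(nd_type_info(a$type)$div(a$value, b$value), a$type)
}

#' Compare two boxed values of an ordered type
#' @param a,b `nd_value` objects of the same ordered type
#' @return -1, 0 or 1
#' @export
numeric_compare <- function(a, b) {
  check_same_type(a, b)
  if (!type_is_ordered(a$type))
    nd_stop("type '", a$type, "' is not ordered; comparison is undefined")
  sign(as.numeric(a$value - b$value))
}

## ---- ARGB packing ---------------------------------------------------------

#' Pack/unpack ARGB channel quadruples
#'
#' Channels occupy bits 31-24 (alpha), 23-16 (red), 15-8 (green), 7-0
#' (blue) of one 32-bit word, carried in a double so the full unsigned
#' range is representable. `argb_unpack` inverts `argb_pack` exactly.
#' @param a,r,g,b channel values in 0..255
#' @return `argb_pack`: the packed word; `argb_unpack`: a named list of
#'   the four channels
#' @examples
#' argb_pack(255, 0, 0, 0) == 0xFF000000
#' argb_unpack(argb_pack(17, 34, 51, 68))
#' @export
argb_pack <- function(a, r, g, b) {
  ch <- c(a, r, g, b)
  if (any(ch < 0) || any(ch > 255) || any(ch != floor(ch)))
    nd_stop("argb_pack: channels must be integers in 0..255")
  a * 2^24 + r * 2^16 + g * 2^8 + b
}

#' @rdname argb_pack
#' @param packed a packed 32-bit ARGB word
#' @export
argb_unpack <- function(packed) argb_unpack_many(packed)

argb_pack_many <- function(a, r, g, b) a * 2^24 + r * 2^16 + g * 2^8 + b

argb_unpack_many <- function(packed) {
  packed <- packed %% 2^32
  list(a = packed %/% 2^24,
       r = (packed %/% 2^16) %% 256,
       g = (packed %/% 2^8) %% 256,
       b = packed %% 256)
}

## ---- Converters -----------------------------------------------------------

#' Value converters
#'
#' A converter is a pure mapping from one value type to another, applied on
#' access and never materialized. Supplying an inverse makes a converted
#' view writable. `fn` and `inv` must accept vectors (they are applied to
#' whole batches of samples during bulk access).
#'
#' @param fn vectorized function raw-source-values -> raw-target-values
#' @param source,target type tags
#' @param inv optional vectorized inverse (target -> source); required for
#'   writing through a converted view
#' @return an object of class `nd_converter`
#' @examples
#' # address a float image as bytes, clamped and rounded
#' conv <- nd_converter(function(v) pmin(pmax(round(v), 0), 255),
#'                      "f64", "u8")
#' @export
nd_converter <- function(fn, source, target, inv = NULL) {
  nd_type_info(source); nd_type_info(target)
  structure(list(fn = fn, inv = inv, source = source, target = target),
            class = "nd_converter")
}

#' Identity converter for a type
#' @param tag a type tag
#' @export
identity_converter <- function(tag) {
  nd_converter(identity, tag, tag, inv = identity)
}

#' Clamping converter from a real type to an unsigned-byte view
#' @param source source type tag (a real type)
#' @export
clamp_u8_converter <- function(source = "f64") {
  nd_converter(function(v) pmin(pmax(round(v), 0), 255), source, "u8")
}
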