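#' Deterministic synthetic fixtures
#'
#' Programmatically generated test imagery with documented closed forms:
#' \describe{
#'   \item{impulse}{zeros with a single 1 (default: domain center)}
#'   \item{ramp}{`I(p) = sum_d coeffs[d] * p[d] + intercept`}
#'   \item{gaussian_blob}{`I(p) = amplitude * exp(-|p - center|^2 /
#'     (2 sigma^2))` on a constant background}
#'   \item{squares}{nested axis-aligned constant regions: `levels[1]`
#'     fills the domain, each further level fills a centered box shrunk by
#'     `inset` pixels per side relative to the previous one}
#'   \item{uniform_noise}{i.i.d. uniform draws on `range`, from a private
#'     RNG stream seeded with `seed` — the same spec and seed reproduce the
#'     image bit for bit}
#' }
#' @param kind fixture kind (see above)
#' @param dims side lengths
#' @param factory output backend/type
#' @param seed RNG seed (uniform_noise only)
#' @param center,coeffs,intercept,amplitude,sigma,background,levels,inset,range
#'   kind-specific parameters with sensible defaults
#' @return an image
#' @examples
#' generate_fixture("ramp", c(4, 4), coeffs = c(1, 0))
#' @export
generate_fixture <- function(kind = c("impulse", "ramp", "gaussian_blob",
                                      "squares", "uniform_noise"),
                             dims,
                             factory = image_factory("array", "f64"),
                             seed = 42,
                             center = NULL, coeffs = NULL, intercept = 0,
                             amplitude = 1, sigma = NULL, background = 0,
                             levels = c(0, 1), inset = NULL,
                             range = c(0, 1)) {
  kind <- match.arg(kind)
  dims <- as.numeric(dims)
  if (length(dims) < 1 || any(dims < 1))
    nd_stop("dims must be positive")
  n <- length(dims)
  P <- interval_coords(interval_from_dims(dims))
  v <- switch(kind,
    impulse = {
      if (is.null(center)) center <- floor((dims - 1) / 2)
      as.numeric(apply(P, 1, function(p) all(p == center)))
    },
    ramp = {
      if (is.null(coeffs)) coeffs <- c(1, rep(0, n - 1))
      as.vector(P %*% coeffs) + intercept
    },
    gaussian_blob = {
      if (is.null(center)) center <- (dims - 1) / 2
      if (is.null(sigma)) sigma <- max(dims) / 8
      d2 <- rowSums(sweep(P, 2, center)^2)
      background + amplitude * exp(-d2 / (2 * sigma^2))
    },
    squares = {
      if (is.null(inset)) inset <- floor(min(dims) / (2 * length(levels)))
      v <- rep(levels[1], nrow(P))
      lo <- rep(0, n); hi <- dims - 1
      for (i in seq_along(levels)[-1]) {
        lo <- lo + inset; hi <- hi - inset
        if (any(hi < lo)) break
        inside <- rep(TRUE, nrow(P))
        for (d in seq_len(n))
          inside <- inside & P[, d] >= lo[d] & P[, d] <= hi[d]
        v[inside] <- levels[i]
      }
      v
    },
    uniform_noise = with_seed(seed, {
      stats::runif(nrow(P), range[1], range[2])
    }))
  img <- create_image(factory, dims)
  write_raster_values(img, v)
  img
}
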