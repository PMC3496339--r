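---
title: "ndimg: methods and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{ndimg: methods and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ndimg)
```

This vignette records the design of `ndimg` and the numerical and
semantic choices behind it, at the level of detail needed to reimplement
the package or to interpret its test oracles.

# The separation of concerns

A single algorithm implementation in `ndimg` must produce identical
samples on every storage backend and through every lazy view. This is
achieved by a strict three-way split:

* **Containers** own sample memory and expose only a factory-level
  contract: dimensions, value type, and the ability to hand out
  accessors. `image_factory(backend, type, ...)` captures a storage
  strategy so that algorithms can create outputs "like" their inputs
  without knowing the backend.
* **Accessors** are the only way to touch samples.
  `random_access(img)` positions and reads/writes at arbitrary
  coordinates; `cursor(img)` traverses every sample exactly once in the
  container's preferred order. Both hand out a single mutable *proxy*
  that is repositioned in place; tests assert with allocation counters
  (`nd_alloc_count()`, `nd_pixel_alloc_count()`) that scanning an image
  allocates zero proxies beyond the first.
* **Value types** define what a sample means. Integer types use
  wrap-around modular arithmetic (e.g. `u8`: 200 + 100 = 44); `f32` is
  stored in doubles but every write is quantized through a genuine
  IEEE-754 single-precision round trip (`writeBin`/`readBin` at
  `size = 4`), so `f32` semantics are exact, not approximated; `argb`
  packs four 8-bit channels into one sample with per-channel *clamped*
  arithmetic; `cf32` is complex and deliberately unordered.

## Coordinates and intervals

Pixel coordinates are **0-based** and intervals are min/max-inclusive
(`nd_interval(min, max)`), which keeps view arithmetic free of ±1
corrections. Dimension *numbers* passed to the API (`hyperslice(img,
d, pos)`, `permute(img, d1, d2)`, CLI flags) are **1-based**, matching
R convention. This asymmetry is intentional: coordinates are data,
dimension numbers are R-level arguments.

## Iteration order

Flat (`array`) and `list` containers iterate in raster order
(dimension 1 fastest). The `cell` container iterates cell-by-cell, each
cell in raster order — the order that is cache-friendly for its layout.
`iteration_order()` reifies the order and `iteration_order_equal()`
gates sample-aligned co-iteration; algorithms that co-iterate two
images either check it or address by coordinates. Bulk helpers
distinguish the two conventions explicitly: `img_write_values()` fills
in iteration order; raster-order vectors (arrays read from R, decoded
image files) go through an internal raster-to-iteration permutation.

# Capacity arithmetic

A flat buffer addressed by a 31-bit signed index holds `2^31` samples.
`max_square_side(n)` returns the largest `s` with `s^2 <= n`, computed
with an integer-safe bound rather than `floor(sqrt(n))` (which is
vulnerable to double rounding at large `n`); `max_square_side(2^31)`
is exactly 46340. The cell container's addressable capacity is the
number of cells times per-cell capacity, capped at `2^63`;
`cell_capacity_pixels()` reports at least `2^62`. Constructors enforce
the caps: requesting an image beyond a backend's capacity is an error
that names the cell backend as the remedy.

# View algebra

Every integer view is one *mixed transform* mapping a view coordinate
`q` to a source coordinate `p`:

```
p[d] = off[d] + sign[d] * q[comp[d]]        (comp[d] = NA ⇒ constant)
```

This one form expresses translation, axis permutation, axis inversion,
quarter rotations (permute + invert), and dimension-dropping slices
(the `NA` component). Mixed transforms are closed under composition,
so a chain of views fuses into a **single** transform node; `ndimg`
fuses automatically on construction (`view_depth()` stays 1) unless
`options(ndimg.simplify = FALSE)` is set, which the test suite uses to
build the unfused "sequential" twin of every random chain and compare
sample-for-sample. Views are writable wherever the transform is
invertible on its image, and are lazy: constructing a view allocates
no pixels.

## Out-of-bounds extension

`extend(img, strategy)` makes a bounded image unbounded by folding
coordinates into the source interval. With `L` the extent of an axis
and `i` a 0-based offset from the axis minimum:

* `periodic`: `i mod L`;
* `mirror_single`: period `2L − 2`, the boundary sample is **not**
  repeated (fold `p = i mod (2L−2)`; if `p ≥ L` then `2L−2−p`);
* `mirror_double`: period `2L`, the boundary sample **is** repeated
  (fold `p = i mod 2L`; if `p ≥ L` then `2L−1−p`), which equals
  border replication at offsets ±1;
* `constant`: a fixed fill value outside.

Axes of extent 1 fold to 0 under every mirror rule. The tests compare
all strategies against these closed-form folds over a margin of 10 in
1-D, 2-D and 3-D.

# Real-valued access

`interpolate(img, method)` lifts a (usually extended) discrete image to
real coordinates. `nlinear` is separable linear interpolation over the
`2^n` surrounding grid points with weights `∏ (1 − |x_d − p_d|)`; it
reproduces affine functions `a·x + b` exactly up to double rounding,
which the acceptance checks exploit (ramp fixtures, error `< 1e−9`,
observed `~1e−15`). `affine_view()` composes an affine matrix with a
continuous image by mapping target to source coordinates (the inverse
transform), and `rasterize()` samples any continuous image onto an
integer interval, closing the loop back to containers.

# Sparse data

`nd_points` stores coordinates and values; `build_kdtree()` builds a
balanced k-d tree by splitting on the **lower median** along the axis
cycling with depth. Searches (`nn_search`, `knn_search`,
`radius_search`) are exact, with ties broken toward the
earliest-inserted point and k-NN output sorted by non-decreasing
distance then insertion index.

A subtle determinism choice: the linear-scan reference computes
squared distances column-wise in double precision, and R's `sum()`
accumulates in extended precision, which can differ from a sequential
double-precision loop in the last ulp. The tree therefore uses a
scalar distance routine with the *same accumulation order* as the scan
(`dist2_one`), so tree and scan results are `identical()`, not merely
close. `nn_extrapolate()` exposes the Voronoi nearest-neighbour field
as a continuous image.

# Algorithms

All algorithms read through accessors and write through a factory, so
they are backend- and view-agnostic by construction; the test suite
re-runs each one across backends and through permuted/translated views
and requires bitwise-equal output arrays.

* **Gaussian / separable convolution.** `gaussian_kernel(sigma)` is a
  sampled, normalized Gaussian with half-width
  `max(2, ceiling(3*sigma))`; normalization makes the kernel mass
  exactly 1 up to rounding (`< 1e−12` asserted, `~1e−16` observed).
  `separable_convolve()` applies one 1-D correlation per axis over a
  `mirror_single` extension by default; separability is validated
  against a dense n-D correlation oracle (`< 1e−6` asserted, `~1e−15`
  observed). Symmetric kernels make correlation equal convolution.
* **Sobel** returns one gradient image per axis (smoothing kernel
  `[1,2,1]/4` on the other axes, derivative `[−1,0,1]/2` on the axis).
* **Difference of Gaussians** subtracts two Gaussian scales and
  reports local extrema of the *raw* response above a threshold, each
  tagged with the geometric mean scale `sqrt(sigma1*sigma2)`.
* **Anisotropic diffusion** (Perona–Malik, exponential conductance
  `exp(−(|∇|/kappa)^2)`) uses border-replicate boundaries and requires
  the explicit-scheme stability bound `lam ∈ (0, 1/(2n)]`; a constant
  image is a fixed point and total mass is conserved under replicate
  boundaries.

## Component trees and MSER

`build_component_tree()` is a max-tree over upper level sets with
4-/2n-connectivity. Nodes are **canonical**: a node exists at level `g`
only if its component contains a pixel whose value is exactly `g`. The
per-level partition implied by the tree is validated against an
independent breadth-first flood fill of every threshold set.

`mser_detect(tree, delta, ...)` scores each node `Q_g` with the
stability rate `q(g) = (|Q_{g−delta}| − |Q_{g+delta}|) / |Q_g|`,
clamping `g ± delta` at branch ends, and selects non-strict local
minima of `q` along every root-to-leaf path. The root itself is never
returned, but its rate participates as a neighbour in the comparison.
One consequence worth knowing: a **binary** image (a single threshold
transition) has two-node paths on which the leaf can never be a local
minimum, so MSER detects nothing — a degenerate input for the method,
not a bug. Detection fixtures therefore use multi-level scenes (e.g.
nested squares at levels 0/60/200, where exactly the bright inner
square is returned with rate 0).

# I/O

TIFF is the interchange format. Reading uses the `tiff` package and
dispatches on bits-per-sample (8 → `u8`, 16 → `u16`, 32 → `f32`);
multi-page files map to 3-D images. `u8`/`u16` writing also uses the
`tiff` package. Floating-point pages are a different matter: no
installed package can *write* IEEE-float TIFF (the `tiff` package's
32-bit mode emits scaled unsigned integers restricted to [0, 1]), so
`ndimg` includes a small hand-written baseline TIFF writer
(`write_tiff_f32`) — little-endian header, one uncompressed strip per
page, `SampleFormat = 3`, chained IFDs for multi-page. It is a minimal
single-purpose writer, described as exactly that; its output is read
back bit-exactly by `tiff::readTIFF`, which is how the round-trip
tests validate it. `f64` images quantize to float32 on write. PNG
(via the `png` package) covers 2-D `u8`/`u16` grayscale and `argb`.
Sparse points serialize as CSV with a validated `x1,...,xn,value`
header.

# Study sizes and reproducibility

The property suites use fixed study sizes chosen to exercise every
code path while keeping the whole suite inside a few minutes of
interpreter time: 50 random backend-equivalence patterns, 100 random
view chains of depth ≤ 5, extension margins of 10, 1,000 interpolation
points per dimensionality, 1,000 queries against 200 points (with
forced duplicates) in 2/3/5-D, 20 random component-tree images, and
9×9 / 7×7×5 dense-convolution fixtures. `scripts/acceptance.R` re-runs
the same computations against the installed package from a single
`--seed` and writes every headline quantity to JSON;
`demo_figure1(seed)` is bit-reproducible, verified by running it twice
and comparing every output file byte-for-byte.
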