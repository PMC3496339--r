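Package: ndimg
Title: Generic N-Dimensional Image Containers, Lazy Views and Algorithms
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: An n-dimensional image processing toolkit that decouples pixel
    algebra, data access and data representation. Images of any
    dimensionality and of several value types (bit, unsigned byte, signed
    and unsigned integers, 32/64-bit reals, complex, packed ARGB) are stored
    behind interchangeable backends (single flat buffer, chunked cell grid,
    object-per-pixel list) selected through factories. Lazy views provide
    slicing, windowing, axis permutation, 90-degree rotation, translation
    and out-of-bounds extension without copying pixel data; consecutive
    integer transforms are fused into a single composed transform.
    Continuous-coordinate access is provided by nearest-neighbour and
    n-linear interpolation, n-dimensional affine views and rasterization.
    Sparse point samples are indexed in a k-d tree supporting
    nearest-neighbour, k-nearest and radius queries, and extrapolated into
    continuous Voronoi images. A set of generic algorithms (separable
    Gaussian convolution, Sobel gradients, difference-of-Gaussians interest
    points, max-tree component analysis with MSER selection, Perona-Malik
    anisotropic diffusion) runs unchanged over any backend, dimensionality
    and view composition. TIFF and PNG input/output, deterministic synthetic
    fixtures, a benchmark harness and a command-line front end are included.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    tiff,
    png,
    jsonlite,
    utils,
    stats
Suggests:
    testthat (>= 3.0.0),
    optparse,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
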