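#' @keywords internal
"_PACKAGE"

#' @importFrom stats dnorm rnorm runif rbinom fft sd var coef lm pnorm
#'   quantile optim setNames aggregate complete.cases
#' @importFrom utils head write.csv read.csv
NULL

# Evaluate `expr` under a fixed RNG seed without disturbing the caller's
# RNG stream.
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(expr)
}

#' Read an image as an RGB array in [0, 1]
#'
#' Reads a PNG file and returns an `H x W x 3` numeric array with values in
#' `[0, 1]`. Grayscale images are replicated across the three channels; an
#' alpha channel, if present, is dropped.
#'
#' @param path Path to a PNG file.
#' @return Numeric array of dimension `H x W x 3`.
#' @export
read_image <- function(path) {
  x <- png::readPNG(path)
  as_rgb(x)
}

#' Write an RGB array to a PNG file
#'
#' @param image `H x W x 3` array with values in `[0, 1]`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_image <- function(image, path) {
  image <- clamp01(as_rgb(image))
  png::writePNG(image, path)
  invisible(path)
}

# Coerce matrix / RGBA / RGB input to H x W x 3 in [0,1].
as_rgb <- function(x) {
  if (is.matrix(x)) x <- array(rep(x, 3L), dim = c(dim(x), 3L))
  if (length(dim(x)) != 3L) stop("image must be an H x W x C array")
  if (dim(x)[3] == 4L) x <- x[, , 1:3, drop = FALSE]
  if (dim(x)[3] == 1L) x <- array(rep(x[, , 1L], 3L), dim = c(dim(x)[1:2], 3L))
  if (dim(x)[3] != 3L) stop("image must have 1, 3 or 4 channels")
  storage.mode(x) <- "double"
  x
}

clamp01 <- function(x) pmin(pmax(x, 0), 1)

#' Convert an RGB image to luminance
#'
#' Rec. 709 luma weights (0.2126, 0.7152, 0.0722).
#'
#' @param image `H x W x 3` array.
#' @return `H x W` numeric matrix.
#' @export
luminance <- function(image) {
  image <- as_rgb(image)
  0.2126 * image[, , 1] + 0.7152 * image[, , 2] + 0.0722 * image[, , 3]
}

# Reflect-pad a matrix by `k` pixels on every side (mirror about the edge
# pixel centers, edge row not repeated).
reflect_pad <- function(x, k) {
  n <- nrow(x); m <- ncol(x)
  if (k == 0) return(x)
  ri <- reflect_index(seq_len(n + 2 * k) - 1 - k, n) + 1
  ci <- reflect_index(seq_len(m + 2 * k) - 1 - k, m) + 1
  x[ri, ci, drop = FALSE]
}

# Fold 0-based coordinates into [0, n-1] by mirror reflection about the
# first/last pixel centers (triangle wave of period 2(n-1)).
reflect_index <- function(i, n) {
  if (n == 1) return(rep(0, length(i)))
  p <- 2 * (n - 1)
  i <- i %% p
  i <- ifelse(i < 0, i + p, i)
  ifelse(i >= n, p - i, i)
}

gaussian_kernel <- function(sigma, truncate = 4) {
  r <- max(1L, ceiling(truncate * sigma))
  k <- dnorm(seq(-r, r), sd = sigma)
  k / sum(k)
}

# Separable 2-D convolution with reflected boundaries. `kx` runs along
# columns (x / width), `ky` along rows.
sep_filter <- function(x, ky, kx = ky) {
  rk <- (length(ky) - 1L) %/% 2L
  ck <- (length(kx) - 1L) %/% 2L
  n <- nrow(x); m <- ncol(x)
  xp <- reflect_pad(x, max(rk, ck))
  off <- max(rk, ck)
  # rows
  out <- matrix(0, n, ncol(xp))
  for (j in seq_along(ky))
    out <- out + ky[j] * xp[(off - rk + j - 1) + seq_len(n), , drop = FALSE]
  # columns
  res <- matrix(0, n, m)
  for (j in seq_along(kx))
    res <- res + kx[j] * out[, (off - ck + j - 1) + seq_len(m), drop = FALSE]
  res
}

# Gaussian smoothing, truncated at `truncate` standard deviations.
gaussian_blur <- function(x, sigma, truncate = 4) {
  k <- gaussian_kernel(sigma, truncate)
  sep_filter(x, k, k)
}
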