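#' Eidolon distortion parameters
#'
#' Bundle the two parameters of the scale-free Eidolon disarray together
#' with the seed that fixes the random displacement field.
#'
#' @param grain Positive number, pixels. Gaussian smoothing scale of the
#'   displacement field; larger grain gives lower-spatial-frequency disarray.
#' @param reach Non-negative number, pixels. Root-mean-square displacement;
#'   the intensity of the distortion.
#' @param seed Integer seed fixing the random field.
#' @return An object of class `"eidolon_params"`.
#' @export
eidolon_params <- function(grain, reach, seed = 1L) {
  if (!is.numeric(grain) || length(grain) != 1L || !is.finite(grain) || grain <= 0)
    stop("`grain` must be a single positive number")
  if (!is.numeric(reach) || length(reach) != 1L || !is.finite(reach) || reach < 0)
    stop("`reach` must be a single non-negative number")
  structure(list(grain = grain, reach = reach, seed = as.integer(seed)),
            class = "eidolon_params")
}

#' @export
print.eidolon_params <- function(x, ...) {
  cat(sprintf("Eidolon parameters: grain = %g px, reach = %g px, seed = %d\n",
              x$grain, x$reach, x$seed))
  invisible(x)
}

#' Build a smoothed Gaussian random displacement field
#'
#' Two independent displacement maps (`dx`, `dy`) are built by drawing
#' i.i.d. standard-normal noise, low-pass filtering it with a Gaussian of
#' standard deviation `grain` (truncated at 4 sigma), renormalizing by the
#' filtered field's own empirical standard deviation, and scaling by
#' `reach`. The empirical per-realization standard deviation of each map is
#' therefore exactly `reach`.
#'
#' @param shape Integer vector `c(H, W)`.
#' @param params An [eidolon_params()] object.
#' @return A list of class `"disarray_field"` with `H x W` matrices `dx`
#'   and `dy` (pixels).
#' @export
build_disarray_field <- function(shape, params) {
  stopifnot(inherits(params, "eidolon_params"))
  shape <- as.integer(shape)
  if (length(shape) != 2L || any(shape < 1L))
    stop("`shape` must be c(H, W) with H, W >= 1")
  if (prod(shape) < 4L)
    stop("field renormalization is undefined for fewer than 4 pixels")
  h <- shape[1]; w <- shape[2]
  field <- with_seed(params$seed, {
    mk <- function() {
      z <- matrix(rnorm(h * w), h, w)
      f <- gaussian_blur(z, params$grain)
      s <- sd(as.vector(f))
      if (s == 0) stop("degenerate displacement field (zero variance)")
      f / s * params$reach
    }
    list(dx = mk(), dy = mk())
  })
  structure(field, class = "disarray_field")
}

#' Warp an image along a displacement field
#'
#' Backward warp: output pixel `(r, c)` samples the input at
#' `(r + dy[r, c], c + dx[r, c])` (0-based, pixel centers at integers).
#' One field is shared across the three channels. Coordinates falling
#' outside the image are folded back by mirror reflection, and the result
#' is clipped to `[0, 1]`.
#'
#' @param image `H x W x 3` array in `[0, 1]`.
#' @param field A `"disarray_field"` whose maps match the image size.
#' @param interp `"bilinear"` (default) or `"nearest"`.
#' @return Warped image, same dimensions.
#' @export
apply_disarray <- function(image, field, interp = c("bilinear", "nearest")) {
  interp <- match.arg(interp)
  image <- as_rgb(image)
  h <- dim(image)[1]; w <- dim(image)[2]
  if (!identical(dim(field$dx), c(h, w)) || !identical(dim(field$dy), c(h, w)))
    stop("image and field shapes disagree")
  rr <- matrix(seq_len(h) - 1, h, w) + field$dy
  cc <- matrix(rep(seq_len(w) - 1, each = h), h, w) + field$dx
  out <- array(0, dim(image))
  if (interp == "nearest") {
    ri <- reflect_index(round(rr), h) + 1
    ci <- reflect_index(round(cc), w) + 1
    idx <- cbind(as.vector(ri), as.vector(ci))
    for (ch in 1:3) {
      pl <- image[, , ch]
      out[, , ch] <- matrix(pl[idx], h, w)
    }
  } else {
    r0 <- floor(rr); c0 <- floor(cc)
    fr <- rr - r0; fc <- cc - c0
    i00 <- cbind(as.vector(reflect_index(r0, h) + 1),
                 as.vector(reflect_index(c0, w) + 1))
    i01 <- cbind(as.vector(reflect_index(r0, h) + 1),
                 as.vector(reflect_index(c0 + 1, w) + 1))
    i10 <- cbind(as.vector(reflect_index(r0 + 1, h) + 1),
                 as.vector(reflect_index(c0, w) + 1))
    i11 <- cbind(as.vector(reflect_index(r0 + 1, h) + 1),
                 as.vector(reflect_index(c0 + 1, w) + 1))
    w00 <- as.vector((1 - fr) * (1 - fc)); w01 <- as.vector((1 - fr) * fc)
    w10 <- as.vector(fr * (1 - fc));       w11 <- as.vector(fr * fc)
    for (ch in 1:3) {
      pl <- image[, , ch]
      out[, , ch] <- matrix(pl[i00] * w00 + pl[i01] * w01 +
                            pl[i10] * w10 + pl[i11] * w11, h, w)
    }
  }
  clamp01(out)
}

#' Apply an Eidolon distortion to an image
#'
#' Convenience composition of [build_disarray_field()] and
#' [apply_disarray()]: deterministic given the seed carried in `params`.
#' At `reach = 0` the output is bit-identical to the input.
#'
#' @inheritParams apply_disarray
#' @param params An [eidolon_params()] object.
#' @return Distorted image.
#' @export
eidolon_distort <- function(image, params, interp = c("bilinear", "nearest")) {
  image <- as_rgb(image)
  if (params$reach == 0) return(image)
  field <- build_disarray_field(dim(image)[1:2], params)
  apply_disarray(image, field, interp = match.arg(interp))
}
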