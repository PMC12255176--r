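#' Local contrast map of an image
#'
#' Converts the image to luminance (Rec. 709) and computes the gradient
#' magnitude of the Gaussian-derivative-filtered luminance at scale
#' `sigma`: the response of a pair of first-order derivative-of-Gaussian
#' filters, combined as `sqrt(gx^2 + gy^2)`. This is the local contrast
#' measure underlying the CE/SC statistics.
#'
#' @param image `H x W x 3` array in `[0, 1]` (or a luminance matrix).
#' @param sigma Positive filter scale in pixels.
#' @return `H x W` non-negative matrix.
#' @export
local_contrast_map <- function(image, sigma = 1.5) {
  if (!is.numeric(sigma) || sigma <= 0) stop("`sigma` must be positive")
  y <- if (is.matrix(image)) image else luminance(image)
  g <- gaussian_kernel(sigma)
  r <- (length(g) - 1L) %/% 2L
  t <- seq(-r, r)
  dg <- -(t / sigma^2) * dnorm(t, sd = sigma)
  dg <- dg / sum(t * dg) * (-1)   # unit response to a unit ramp
  gx <- sep_filter(y, ky = g, kx = dg)
  gy <- sep_filter(y, ky = dg, kx = g)
  m <- sqrt(gx^2 + gy^2)
  # roundoff-level responses in flat regions are not contrast
  m[m < 1e-10] <- 0
  m
}

#' Maximum-likelihood Weibull fit to a contrast distribution
#'
#' Fits a two-parameter Weibull distribution to the strictly positive
#' values of a local-contrast map by maximum likelihood (zeros are
#' dropped; there is no location parameter). The shape parameter is found
#' by solving the profile-likelihood score equation, the scale follows in
#' closed form, so the fit is deterministic.
#'
#' @param contrast Non-negative numeric matrix or vector.
#' @return Named numeric vector `c(scale = ..., shape = ...)`.
#' @export
weibull_contrast_fit <- function(contrast) {
  x <- as.vector(contrast)
  x <- x[is.finite(x) & x > 0]
  if (length(unique(x)) < 2L)
    stop("degenerate contrast distribution: need at least 2 distinct positive values")
  lx <- log(x)
  mlx <- mean(lx)
  score <- function(k) {
    xk <- exp(k * (lx - max(lx)))          # rescaled for overflow safety
    sum(xk * lx) / sum(xk) - 1 / k - mlx
  }
  lo <- 1e-3; hi <- 1
  while (score(hi) < 0 && hi < 1e4) hi <- hi * 2
  k <- stats::uniroot(score, c(lo, hi), tol = 1e-10)$root
  scale <- mean(x^k)^(1 / k)
  c(scale = scale, shape = k)
}

#' Contrast energy (CE) and spatial coherence (SC) of an image
#'
#' CE is the fitted Weibull scale and SC the fitted Weibull shape of the
#' image's local-contrast distribution: a narrow contrast distribution
#' (low CE) means edges of similar strength, while SC tracks the edge
#' density of the image.
#'
#' @inheritParams local_contrast_map
#' @param sigma Contrast filter scale in pixels (default 1.5).
#' @return Named numeric vector `c(ce = ..., sc = ...)`.
#' @export
compute_ce_sc <- function(image, sigma = 1.5) {
  fit <- weibull_contrast_fit(local_contrast_map(image, sigma = sigma))
  c(ce = unname(fit["scale"]), sc = unname(fit["shape"]))
}

#' Train the linear scene-versus-texture classifier
#'
#' Soft-margin linear support vector machine on standardized (CE, SC)
#' features (cost 1), as used to split a stimulus set into scene-like
#' (high CE, high SC) and texture-like (low CE, low SC) populations.
#'
#' @param points Numeric matrix with columns `(ce, sc)`.
#' @param labels Vector of class labels, `"scene"` or `"texture"`.
#' @return An object of class `"linear_boundary"`: weight vector `w`,
#'   bias `b` (decision rule `w . x + b >= 0` maps to `"scene"`), and the
#'   in-sample `accuracy`.
#' @export
train_scene_texture_classifier <- function(points, labels) {
  points <- as.matrix(points)
  labels <- as.character(labels)
  if (ncol(points) != 2L) stop("`points` must have two columns (ce, sc)")
  if (length(unique(labels)) < 2L) stop("need at least two classes to train")
  if (min(table(labels)) < 2L) stop("need at least 2 points per class")
  y <- factor(labels, levels = c("scene", "texture"))
  fit <- e1071::svm(points, y, kernel = "linear", cost = 1, scale = TRUE)
  w_sc <- drop(t(fit$coefs) %*% fit$SV)
  ctr <- fit$x.scale$`scaled:center`
  scl <- fit$x.scale$`scaled:scale`
  w <- w_sc / scl
  b <- -fit$rho - sum(w_sc * ctr / scl)
  # libsvm orients the decision function by order of appearance; align the
  # sign rule with the fitted model's own predictions
  pred_rule <- ifelse(drop(points %*% w) + b >= 0, "scene", "texture")
  pred_fit <- as.character(predict(fit, points))
  if (mean(pred_rule == pred_fit) < 0.5) { w <- -w; b <- -b
    pred_rule <- ifelse(drop(points %*% w) + b >= 0, "scene", "texture") }
  structure(list(w = unname(w), b = unname(b),
                 accuracy = mean(pred_rule == labels)),
            class = "linear_boundary")
}

#' @export
print.linear_boundary <- function(x, ...) {
  cat(sprintf("Linear scene/texture boundary: %.4f*CE + %.4f*SC + %.4f >= 0 -> scene\n",
              x$w[1], x$w[2], x$b))
  cat(sprintf("In-sample accuracy: %.1f%%\n", 100 * x$accuracy))
  invisible(x)
}

#' Classify (CE, SC) points with a linear boundary
#'
#' Points exactly on the boundary are assigned `"scene"`.
#'
#' @param points Numeric matrix with columns `(ce, sc)`.
#' @param boundary A `"linear_boundary"` object.
#' @return Character vector of `"scene"` / `"texture"` labels.
#' @export
classify <- function(points, boundary) {
  stopifnot(inherits(boundary, "linear_boundary"))
  points <- as.matrix(points)
  ifelse(drop(points %*% boundary$w) + boundary$b >= 0, "scene", "texture")
}
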