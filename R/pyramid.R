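# Complex steerable pyramid (frequency-domain construction) and the
# texture-statistic vector computed from it: marginal pixel statistics,
# band-magnitude autocorrelations, lowpass autocorrelations,
# cross-orientation and cross-scale magnitude correlations, and
# phase-doubled cross-scale (real-part) correlations.

fft2 <- function(x) fft(x)
ifft2 <- function(x) fft(x, inverse = TRUE) / length(x)

# log2 radial frequency (Nyquist at 0) and orientation grids for an n x m
# spectrum in standard (unshifted) FFT layout.
freq_grids <- function(n, m) {
  fy <- ((seq_len(n) - 1 + n %/% 2) %% n - n %/% 2) / (n / 2)
  fx <- ((seq_len(m) - 1 + m %/% 2) %% m - m %/% 2) / (m / 2)
  FY <- matrix(fy, n, m)
  FX <- matrix(fx, n, m, byrow = TRUE)
  r <- sqrt(FX^2 + FY^2)
  r[1, 1] <- .Machine$double.eps
  list(log_rad = log2(r), angle = atan2(FY, FX))
}

# raised-cosine highpass/lowpass pair, one-octave transition ending at
# log_rad = shift (energy complementary: hi^2 + lo^2 = 1)
rc_hi <- function(log_rad, shift = 0) {
  t <- pmin(pmax(-(log_rad - shift), 0), 1)
  cos(pi / 2 * t)
}
rc_lo <- function(log_rad, shift = 0) {
  t <- pmin(pmax(-(log_rad - shift), 0), 1)
  sin(pi / 2 * t)
}

# single-sided angular mask for orientation k of K (analytic bands)
angle_mask <- function(angle, k, K) {
  d <- atan2(sin(angle - pi * (k - 1) / K), cos(angle - pi * (k - 1) / K))
  out <- ifelse(abs(d) < pi / 2, cos(d)^(K - 1), 0)
  2 * out
}

# crop the centre half of a spectrum (downsample by 2 in space)
spectrum_downsample <- function(ft) {
  n <- nrow(ft); m <- ncol(ft)
  sh <- ft[c((n %/% 2 + 1):n, 1:(n %/% 2)), c((m %/% 2 + 1):m, 1:(m %/% 2))]
  ctr <- sh[(n %/% 4 + 1):(n %/% 4 + n %/% 2), (m %/% 4 + 1):(m %/% 4 + m %/% 2)]
  n2 <- n %/% 2; m2 <- m %/% 2
  ctr[c((n2 %/% 2 + 1):n2, 1:(n2 %/% 2)), c((m2 %/% 2 + 1):m2, 1:(m2 %/% 2))] / 4
}

# Build the pyramid: highpass residual, S x K complex oriented bands,
# and the lowpass image retained after each scale.
build_csp <- function(y, n_scales, n_orient) {
  ft <- fft2(y)
  g <- freq_grids(nrow(y), ncol(y))
  hi0 <- Re(ifft2(ft * rc_hi(g$log_rad)))
  lodft <- ft * rc_lo(g$log_rad)
  bands <- vector("list", n_scales)
  lows <- vector("list", n_scales)
  for (s in seq_len(n_scales)) {
    gs <- freq_grids(nrow(lodft), ncol(lodft))
    bmask <- rc_hi(gs$log_rad, shift = 0)
    bands[[s]] <- lapply(seq_len(n_orient), function(k)
      ifft2(lodft * bmask * angle_mask(gs$angle, k, n_orient)))
    lodft <- spectrum_downsample(lodft * rc_lo(gs$log_rad, shift = 0))
    lows[[s]] <- Re(ifft2(lodft))
  }
  list(highpass = hi0, bands = bands, lowpass = lows)
}

# central Na x Na window of the circular autocovariance of x
central_autocorr <- function(x, width) {
  x <- x - mean(x)
  a <- Re(ifft2(Mod(fft2(x))^2)) / length(x)
  h <- (width - 1L) %/% 2L
  idx <- function(n) ((-h:h) %% n) + 1
  a[idx(nrow(a)), idx(ncol(a))]
}

skewness <- function(x) { m <- mean(x); s <- sd(x); if (s == 0) 0 else mean((x - m)^3) / s^3 }
kurtosis <- function(x) { m <- mean(x); s <- sd(x); if (s == 0) 0 else mean((x - m)^4) / s^4 }

upsample2 <- function(x) x[rep(seq_len(nrow(x)), each = 2), rep(seq_len(ncol(x)), each = 2)]

safe_cor <- function(a, b) {
  sa <- sd(a); sb <- sd(b)
  if (sa == 0 || sb == 0) return(0)
  mean((a - mean(a)) * (b - mean(b))) / (sa * sb)
}

#' Steerable-pyramid texture statistics of an image
#'
#' Decomposes the luminance image with a complex steerable pyramid
#' (`n_scales` scales, `n_orientations` orientations, frequency-domain
#' filters) and assembles the texture-statistic vector: marginal pixel
#' statistics (mean, variance, skewness, kurtosis, min, max), highpass
#' residual variance, per-scale lowpass skew/kurtosis and central
#' autocorrelations, band-magnitude means and central autocorrelations,
#' within-scale cross-orientation magnitude correlations, cross-scale
#' magnitude correlations, and phase-doubled cross-scale real-part
#' correlations. The vector length is a fixed function of the
#' configuration, so vectors from any two images of valid size are
#' directly comparable.
#'
#' @param image `H x W x 3` array in `[0, 1]` or a luminance matrix.
#'   Side lengths are center-cropped/reflect-padded to a multiple of
#'   `2^n_scales`.
#' @param n_scales Number of pyramid scales (default 4).
#' @param n_orientations Number of orientation bands per scale (default 4).
#' @param corr_width Odd width of the central autocorrelation windows
#'   (default 9).
#' @return Named numeric vector; attribute `"config"` records the
#'   configuration.
#' @export
ps_statistics <- function(image, n_scales = 4, n_orientations = 4, corr_width = 9) {
  if (corr_width %% 2 != 1) stop("`corr_width` must be odd")
  y <- if (is.matrix(image)) image else luminance(image)
  blk <- 2^n_scales
  tgt <- (dim(y) %/% blk) * blk
  if (any(tgt == 0)) tgt <- ceiling(dim(y) / blk) * blk
  y <- fit_to_size(y, tgt)
  if (min(dim(y)) < blk * corr_width)
    stop(sprintf("image side %d too small for %d scales with corr_width %d (need >= %d)",
                 min(dim(y)), n_scales, corr_width, blk * corr_width))
  pyr <- build_csp(y, n_scales, n_orientations)
  K <- n_orientations
  out <- c(mean = mean(y), var = var(as.vector(y)), skew = skewness(y),
           kurt = kurtosis(y), min = min(y), max = max(y),
           hp_var = var(as.vector(pyr$highpass)))
  mags <- lapply(pyr$bands, function(sc) lapply(sc, Mod))
  for (s in seq_len(n_scales)) {
    lp <- pyr$lowpass[[s]]
    out <- c(out, setNames(c(skewness(lp), kurtosis(lp)),
                           paste0(c("lp_skew_s", "lp_kurt_s"), s)))
    ac <- central_autocorr(lp, corr_width)
    out <- c(out, setNames(as.vector(ac),
                           paste0("lp_ac_s", s, "_", seq_along(ac))))
    for (k in seq_len(K)) {
      m <- mags[[s]][[k]]
      out <- c(out, setNames(mean(m), paste0("mag_mean_s", s, "o", k)))
      ac <- central_autocorr(m, corr_width)
      out <- c(out, setNames(as.vector(ac),
                             paste0("mag_ac_s", s, "o", k, "_", seq_along(ac))))
    }
    for (k1 in seq_len(K - 1)) for (k2 in (k1 + 1):K)
      out <- c(out, setNames(safe_cor(mags[[s]][[k1]], mags[[s]][[k2]]),
                             paste0("xori_s", s, "_", k1, k2)))
  }
  if (n_scales > 1) for (s in seq_len(n_scales - 1)) {
    for (k1 in seq_len(K)) {
      par_m <- upsample2(mags[[s + 1]][[k1]])
      parent <- upsample2(pyr$bands[[s + 1]][[k1]])
      p2 <- parent^2 / pmax(Mod(parent), .Machine$double.eps)  # phase doubled
      for (k2 in seq_len(K)) {
        out <- c(out, setNames(safe_cor(mags[[s]][[k2]], par_m),
                               paste0("xscl_mag_s", s, "_", k1, k2)))
        out <- c(out, setNames(safe_cor(Re(pyr$bands[[s]][[k2]]), Re(p2)),
                               paste0("xscl_re_s", s, "_", k1, k2)))
        out <- c(out, setNames(safe_cor(Re(pyr$bands[[s]][[k2]]), Im(p2)),
                               paste0("xscl_im_s", s, "_", k1, k2)))
      }
    }
  }
  attr(out, "config") <- c(n_scales = n_scales, n_orientations = n_orientations,
                           corr_width = corr_width)
  out
}

# center-crop or reflect-pad a matrix to target size
fit_to_size <- function(x, tgt) {
  n <- nrow(x); m <- ncol(x)
  if (n > tgt[1]) { o <- (n - tgt[1]) %/% 2; x <- x[(o + 1):(o + tgt[1]), , drop = FALSE] }
  if (ncol(x) > tgt[2]) { o <- (ncol(x) - tgt[2]) %/% 2; x <- x[, (o + 1):(o + tgt[2]), drop = FALSE] }
  if (nrow(x) < tgt[1] || ncol(x) < tgt[2]) {
    k <- max(tgt[1] - nrow(x), tgt[2] - ncol(x))
    xp <- reflect_pad(x, ceiling(k / 2) + 1)
    o1 <- (nrow(xp) - tgt[1]) %/% 2; o2 <- (ncol(xp) - tgt[2]) %/% 2
    x <- xp[(o1 + 1):(o1 + tgt[1]), (o2 + 1):(o2 + tgt[2]), drop = FALSE]
  }
  x
}

#' Distance between two texture-statistic vectors
#'
#' Euclidean mode gives the L2 distance; cosine mode gives the cosine
#' similarity minus one, so that identical vectors score 0 and
#' anti-parallel vectors score -2.
#'
#' @param a,b Numeric vectors of equal length.
#' @param mode `"euclidean"` or `"cosine"`.
#' @return A single number.
#' @export
ps_distance <- function(a, b, mode = c("euclidean", "cosine")) {
  mode <- match.arg(mode)
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) != length(b)) stop("statistic vectors differ in length")
  if (mode == "euclidean") return(sqrt(sum((a - b)^2)))
  sum(a * b) / (sqrt(sum(a^2)) * sqrt(sum(b^2))) - 1
}
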