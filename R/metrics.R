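#' Mean squared error between two images
#'
#' Mean over all pixels and channels of the squared difference.
#'
#' @param a,b `H x W x 3` arrays of equal dimension.
#' @return Non-negative number.
#' @export
mse <- function(a, b) {
  a <- as_rgb(a); b <- as_rgb(b)
  if (!identical(dim(a), dim(b))) stop("image dimensions differ")
  mean((a - b)^2)
}

#' Opponent-channel means of an image
#'
#' `rg = mean(R) - mean(G)`; `yb = mean((R+G)/2) - mean(B)`.
#'
#' @param image `H x W x 3` array.
#' @return Named vector `c(rg = ..., yb = ...)`.
#' @export
opponent_means <- function(image) {
  image <- as_rgb(image)
  mr <- mean(image[, , 1]); mg <- mean(image[, , 2]); mb <- mean(image[, , 3])
  c(rg = mr - mg, yb = (mr + mg) / 2 - mb)
}

# 2-D power spectrum of the luminance image (|FFT|^2, unnormalized)
power_spectrum <- function(image) {
  y <- if (is.matrix(image)) image else luminance(image)
  Mod(fft(y))^2
}

#' Manhattan distance between two power spectra
#'
#' L1 distance between the 2-D power spectra of the two luminance images,
#' with the DC component excluded. Because the power spectrum is
#' shift-invariant, circularly shifted copies of an image score 0.
#'
#' @param a,b Images (or luminance matrices) of equal size.
#' @return Non-negative number.
#' @export
power_spectrum_distance <- function(a, b) {
  pa <- power_spectrum(a); pb <- power_spectrum(b)
  if (!identical(dim(pa), dim(pb))) stop("image dimensions differ")
  pa[1, 1] <- 0; pb[1, 1] <- 0
  sum(abs(pa - pb))
}

# radially averaged power spectrum: mean power in integer-rounded
# radial-frequency bins (cycles/image), DC excluded
radial_average <- function(p) {
  n <- nrow(p); m <- ncol(p)
  fy <- ((seq_len(n) - 1 + n %/% 2) %% n - n %/% 2)
  fx <- ((seq_len(m) - 1 + m %/% 2) %% m - m %/% 2)
  r <- round(sqrt(outer(fy^2, fx^2, "+")))
  keep <- r >= 1 & r <= floor(0.9 * min(n, m) / 2)
  agg <- tapply(p[keep], r[keep], mean)
  list(freq = as.numeric(names(agg)), power = as.numeric(agg))
}

#' Log-log slope and intercept of the radial power spectrum
#'
#' Ordinary least squares fit of `log10(radially averaged power)` on
#' `log10(radial frequency in cycles/image)`. The DC bin and frequencies
#' above 0.9 of Nyquist are excluded.
#'
#' @param image Image or luminance matrix.
#' @return Named vector `c(fs = slope, fi = intercept)`.
#' @export
fourier_slope_intercept <- function(image) {
  ra <- radial_average(power_spectrum(image))
  ok <- ra$power > 0
  if (sum(ok) < 2) stop("degenerate spectrum: cannot fit a slope")
  fit <- lm(log10(ra$power[ok]) ~ log10(ra$freq[ok]))
  c(fs = unname(coef(fit)[2]), fi = unname(coef(fit)[1]))
}

#' Euclidean distance between two (CE, SC) statistic pairs
#'
#' @param a,b Numeric vectors `c(ce, sc)` (as from [compute_ce_sc()]).
#' @return Non-negative number.
#' @export
lgn_distance <- function(a, b) sqrt(sum((as.numeric(a) - as.numeric(b))^2))

#' Shift an external JOD quality score to a zero-at-equality difference
#'
#' JOD scores rate 10 as "identical images"; subtracting 10 expresses
#' them on the same zero-means-no-difference scale as the other metrics.
#'
#' @param score Numeric JOD score(s).
#' @return `score - 10`.
#' @export
jod_adapter <- function(score) score - 10

#' Relative (normalized) variant of a difference metric
#'
#' The direct difference divided by the statistic's value on the original
#' image.
#'
#' @param direct Direct difference value.
#' @param original_stat Statistic of the original image; must be non-zero.
#' @return `direct / original_stat`.
#' @export
normalized_variant <- function(direct, original_stat) {
  if (any(original_stat == 0))
    stop("normalization undefined: original-image statistic is zero")
  direct / original_stat
}

#' Metrics of the difference battery
#'
#' Named logical vector: one entry per metric in the battery, `TRUE` if
#' the metric admits a relative (normalized-by-original) variant. `mse`,
#' `ps_cosine` and `jod` do not.
#'
#' @return Named logical vector of the 12 battery metrics.
#' @export
battery_metrics <- function() {
  c(mse = FALSE, rg_mean = TRUE, yb_mean = TRUE, spectrum_manhattan = TRUE,
    fourier_intercept = TRUE, fourier_slope = TRUE, lgn_euclidean = TRUE,
    ce_diff = TRUE, sc_diff = TRUE, ps_euclidean = TRUE, ps_cosine = FALSE,
    jod = FALSE)
}

#' Metric specification for the difference battery
#'
#' @param name Metric name; one of `mse`, `rg_mean`, `yb_mean`,
#'   `spectrum_manhattan`, `fourier_intercept`, `fourier_slope`,
#'   `lgn_euclidean`, `ce_diff`, `sc_diff`, `ps_euclidean`, `ps_cosine`,
#'   `jod`.
#' @param normalized Logical; request the relative variant. `mse`, `jod`
#'   and `ps_cosine` admit no normalized variant.
#' @return Object of class `"metric_spec"`.
#' @export
metric_spec <- function(name, normalized = FALSE) {
  known <- battery_metrics()
  if (!name %in% names(known)) stop("unknown metric: ", name)
  if (normalized && !known[[name]])
    stop("metric `", name, "` has no normalized variant")
  structure(list(name = name, normalized = normalized), class = "metric_spec")
}

#' Transform a metric series into a difficulty predictor
#'
#' Applies `log(|value| + 1e-12)` and then z-scores across all rows of the
#' series (mean 0, SD 1), producing the regressor used by the metric-based
#' response models. A monotone transform for positive inputs.
#'
#' @param values Numeric vector of metric values.
#' @return Numeric vector of the same length, mean 0 and SD 1.
#' @export
difficulty_transform <- function(values) {
  if (!length(values)) stop("empty metric series")
  x <- log(abs(values) + 1e-12)
  s <- sd(x)
  if (!is.finite(s) || s == 0)
    stop("degenerate metric series: zero variance after transform")
  (x - mean(x)) / s
}

#' Deterministic seed for a distorted stimulus instance
#'
#' Hashes `(image_id, grain, reach)` to a 31-bit integer so that every
#' design cell maps to one fixed distorted instance without storing
#' images.
#'
#' @param image_id Character id of the original image.
#' @param grain,reach Distortion parameters.
#' @return Integer seed.
#' @export
stimulus_seed <- function(image_id, grain, reach) {
  s <- paste(image_id, grain, reach, sep = "|")
  h <- 0
  for (v in utf8ToInt(s)) h <- (h * 131 + v) %% 2147483647
  as.integer(h)
}

# per-image statistics needed by the battery, computed once
image_battery_stats <- function(image, ps_config, sigma_ce = 1.5) {
  list(op = opponent_means(image),
       fsfi = fourier_slope_intercept(image),
       cesc = compute_ce_sc(image, sigma = sigma_ce),
       ps = do.call(ps_statistics, c(list(image), as.list(ps_config))),
       spec = { p <- power_spectrum(image); p[1, 1] <- 0; p })
}

#' Compute the metric battery over a distortion grid
#'
#' For every combination of original image, grain, and reach, a single
#' distorted instance is generated with a seed derived deterministically
#' from `(image_id, grain, reach)`, and every requested difference metric
#' (plus its relative variant where defined) is evaluated. Signed
#' difference metrics follow the original-minus-distorted convention.
#'
#' @param originals Named list of images (names are image ids).
#' @param grains,reaches Numeric vectors of Eidolon parameters.
#' @param metrics Character vector of metric names (default: all
#'   image-computable metrics; `jod` is external and joined separately).
#' @param ps_config Named list/vector for [ps_statistics()]
#'   (`n_scales`, `n_orientations`, `corr_width`).
#' @param jod_table Optional data frame `(image_id, grain, reach, jod)` of
#'   external JOD scores; if supplied, the shifted `jod` metric is added.
#' @param interp Warp interpolation passed to [eidolon_distort()].
#' @return Data frame with columns `image_id, grain, reach, metric,
#'   normalized, value`.
#' @export
compute_battery <- function(originals, grains, reaches,
                            metrics = setdiff(names(battery_metrics()), "jod"),
                            ps_config = list(n_scales = 3, n_orientations = 4,
                                             corr_width = 7),
                            jod_table = NULL,
                            interp = "bilinear") {
  stopifnot(length(names(originals)) == length(originals))
  norm_ok <- battery_metrics()
  bad <- setdiff(metrics, names(norm_ok))
  if (length(bad)) stop("unknown metrics: ", paste(bad, collapse = ", "))
  need_ps <- any(c("ps_euclidean", "ps_cosine") %in% metrics)
  need_ce <- any(c("lgn_euclidean", "ce_diff", "sc_diff") %in% metrics)
  rows <- list()
  add <- function(id, g, r, metric, normalized, value)
    rows[[length(rows) + 1L]] <<- data.frame(
      image_id = id, grain = g, reach = r, metric = metric,
      normalized = normalized, value = value, stringsAsFactors = FALSE)
  for (id in names(originals)) {
    orig <- as_rgb(originals[[id]])
    ostat <- image_battery_stats(orig, ps_config)
    for (g in grains) for (r in reaches) {
      dist <- eidolon_distort(orig, eidolon_params(g, r, stimulus_seed(id, g, r)),
                              interp = interp)
      dstat <- image_battery_stats(dist, ps_config)
      direct <- list(
        mse = mse(orig, dist),
        rg_mean = ostat$op["rg"] - dstat$op["rg"],
        yb_mean = ostat$op["yb"] - dstat$op["yb"],
        spectrum_manhattan = sum(abs(ostat$spec - dstat$spec)),
        fourier_intercept = ostat$fsfi["fi"] - dstat$fsfi["fi"],
        fourier_slope = ostat$fsfi["fs"] - dstat$fsfi["fs"],
        lgn_euclidean = if (need_ce) lgn_distance(ostat$cesc, dstat$cesc),
        ce_diff = if (need_ce) ostat$cesc["ce"] - dstat$cesc["ce"],
        sc_diff = if (need_ce) ostat$cesc["sc"] - dstat$cesc["sc"],
        ps_euclidean = if (need_ps) ps_distance(ostat$ps, dstat$ps, "euclidean"),
        ps_cosine = if (need_ps) ps_distance(ostat$ps, dstat$ps, "cosine"))
      orig_ref <- list(
        rg_mean = ostat$op["rg"], yb_mean = ostat$op["yb"],
        spectrum_manhattan = sum(abs(ostat$spec)),
        fourier_intercept = ostat$fsfi["fi"], fourier_slope = ostat$fsfi["fs"],
        lgn_euclidean = sqrt(sum(ostat$cesc^2)),
        ce_diff = ostat$cesc["ce"], sc_diff = ostat$cesc["sc"],
        ps_euclidean = sqrt(sum(ostat$ps^2)))
      for (mname in metrics) {
        v <- unname(direct[[mname]])
        add(id, g, r, mname, FALSE, v)
        if (norm_ok[[mname]])
          add(id, g, r, mname, TRUE, unname(normalized_variant(v, orig_ref[[mname]])))
      }
    }
  }
  out <- do.call(rbind, rows)
  if (!is.null(jod_table)) {
    if (!all(c("image_id", "grain", "reach", "jod") %in% names(jod_table))) {
      warning("jod table lacks required columns; jod metric skipped")
    } else {
      out <- rbind(out, data.frame(
        image_id = jod_table$image_id, grain = jod_table$grain,
        reach = jod_table$reach, metric = "jod", normalized = FALSE,
        value = jod_adapter(jod_table$jod), stringsAsFactors = FALSE))
    }
  }
  rownames(out) <- NULL
  out
}
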