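# Per-metric hierarchical probit regression of trial correctness on the
# transformed metric value, with participant-level weights.

#' Probit response probability of the metric-based model
#'
#' `S(x) = gamma + (1 - gamma) * pnorm(b0 + b1 * x)`. The lapse rate is
#' fixed at zero: with a lapse the weights of an uninformative metric
#' become unidentifiable.
#'
#' @param x Transformed metric value.
#' @param b0,b1 Intercept and slope.
#' @param gamma Chance level (default 1/3).
#' @return Probability in `(gamma, 1)`.
#' @export
regression_prob <- function(x, b0, b1, gamma = 1 / 3) {
  gamma + (1 - gamma) * pnorm(b0 + b1 * x)
}

metric_model_string <- "
model {
  for (t in 1:N) {
    prob[t] <- gam + (1 - gam) * (1e-6 + (1 - 2e-6) * phi(b0[p[t]] + b1[p[t]] * x[t]))
    y[t] ~ dbern(prob[t])
  }
  for (j in 1:P) {
    b0[j] ~ dnorm(mu_b0, tau_b0)
    b1[j] ~ dnorm(mu_b1, tau_b1)
  }
  mu_b0 ~ dnorm(0, 0.25)
  mu_b1 ~ dnorm(0, 1)
  sig_b0 ~ dlnorm(0, 1); tau_b0 <- pow(sig_b0, -2)
  sig_b1 ~ dlnorm(0, 1); tau_b1 <- pow(sig_b1, -2)
}"

# join trials to metric values by (image_id, grain, reach)
join_metric <- function(trials, series) {
  key <- function(d) paste(d$image_id, d$grain, d$reach, sep = "|")
  sk <- key(series)
  if (anyDuplicated(sk)) stop("metric series has duplicate (image, grain, reach) rows")
  idx <- match(key(trials), sk)
  if (any(is.na(idx))) {
    bad <- unique(key(trials)[is.na(idx)])
    stop("trials without a matching metric value: ",
         paste(head(bad, 5), collapse = ", "),
         if (length(bad) > 5) sprintf(" (and %d more)", length(bad) - 5) else "")
  }
  series$value[idx]
}

#' Fit a metric-based hierarchical probit model
#'
#' Predicts trial correctness from a single transformed metric value via
#' `S(x) = gamma + (1 - gamma) * pnorm(b0_p + b1_p * x)` with
#' participant-level weights partially pooled toward population means.
#' Priors: `mu_b0 ~ N(0, 2)`, `mu_b1 ~ N(0, 1)` (standard deviations),
#' scales `logN(0, 1)`. The regressor `x` is the z-scored log-absolute
#' metric value; if `transform = TRUE` (default) the transform is applied
#' here via [difficulty_transform()].
#'
#' @param trials Trial table (see [fit_oracle()]).
#' @param series Data frame with columns `image_id`, `grain`, `reach`,
#'   `value`: one metric value per distorted instance. Each trial must
#'   join to exactly one row.
#' @param transform Apply the log-absolute z-score difficulty transform
#'   to the joined values (default `TRUE`; set `FALSE` if `series$value`
#'   is already transformed).
#' @param gamma Chance level (default 1/3).
#' @param chains,warmup,samples,seed MCMC settings.
#' @return Object of class `"metric_fit"` with posterior draws,
#'   pointwise log-likelihood, split R-hat and convergence flag.
#' @export
fit_metric <- function(trials, series, transform = TRUE, gamma = 1 / 3,
                       chains = 4, warmup = 500, samples = 500, seed = 0) {
  prep <- prepare_trials(trials)
  x <- join_metric(trials, series)
  if (transform) x <- difficulty_transform(x)
  if (sd(x) == 0) stop("degenerate metric regressor: zero variance")
  P <- length(prep$p_labels); N <- nrow(trials)
  data <- list(N = N, P = P, y = as.integer(trials$correct), x = x,
               p = prep$p, gam = gamma)
  inits_fn <- function(ch) list(mu_b0 = 0, mu_b1 = 0, sig_b0 = 1, sig_b1 = 1,
                                b0 = rep(0, P), b1 = rep(0, P))
  res <- run_jags(metric_model_string, data,
                  c("mu_b0", "mu_b1", "sig_b0", "sig_b1", "b0", "b1", "prob"),
                  chains, warmup, samples, seed, inits_fn)
  draws <- res$draws
  pcols <- grep("^prob\\[", colnames(draws))
  pm <- pmin(pmax(draws[, pcols, drop = FALSE], 1e-12), 1 - 1e-12)
  yrep <- matrix(data$y, nrow(pm), N, byrow = TRUE)
  ll <- yrep * log(pm) + (1 - yrep) * log(1 - pm)
  colnames(ll) <- NULL
  draws <- draws[, -pcols, drop = FALSE]
  rhat <- res$rhat[!grepl("^prob\\[", names(res$rhat))]
  converged <- is.null(rhat) || all(rhat < 1.05, na.rm = TRUE)
  if (!converged)
    warning(sprintf("convergence warning: max split-Rhat = %.3f",
                    max(rhat, na.rm = TRUE)))
  structure(list(draws = draws, loglik = ll, rhat = rhat,
                 converged = converged, gamma = gamma, n_trials = N,
                 participant_labels = prep$p_labels,
                 mcmc = list(chains = chains, warmup = warmup,
                             samples = samples, seed = seed)),
            class = "metric_fit")
}

#' @export
print.metric_fit <- function(x, ...) {
  cat("Hierarchical probit metric model\n")
  cat(sprintf("  %d trials, %d participants; chance level %.3f\n",
              x$n_trials, length(x$participant_labels), x$gamma))
  cat(sprintf("  posterior mean mu_b1 = %.3f (sd %.3f); converged: %s\n",
              mean(x$draws[, "mu_b1"]), sd(x$draws[, "mu_b1"]),
              ifelse(x$converged, "yes", "NO")))
  invisible(x)
}

#' @export
coef.metric_fit <- function(object, ...) {
  c(mu_b0 = mean(object$draws[, "mu_b0"]),
    mu_b1 = mean(object$draws[, "mu_b1"]))
}

#' @export
summary.metric_fit <- function(object, mass = 0.95, ...) {
  d <- object$draws[, c("mu_b0", "mu_b1", "sig_b0", "sig_b1")]
  tab <- data.frame(parameter = colnames(d), mean = colMeans(d),
                    sd = apply(d, 2, sd),
                    hpdi_lo = apply(d, 2, function(v) hpdi(v, mass)[1]),
                    hpdi_hi = apply(d, 2, function(v) hpdi(v, mass)[2]),
                    row.names = NULL)
  tab
}

#' Posterior-mean response probability at new metric values
#'
#' Population-level prediction (participant weights at their population
#' means).
#'
#' @param object A `"metric_fit"`.
#' @param newdata Data frame with a column `x` of transformed metric
#'   values (or a numeric vector).
#' @param ... Unused.
#' @return Numeric vector of probabilities.
#' @export
predict.metric_fit <- function(object, newdata, ...) {
  x <- if (is.data.frame(newdata)) newdata$x else as.numeric(newdata)
  b0 <- object$draws[, "mu_b0"]; b1 <- object$draws[, "mu_b1"]
  vapply(x, function(xi) mean(regression_prob(xi, b0, b1, object$gamma)),
         numeric(1))
}
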