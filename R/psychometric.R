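# Hierarchical Bayesian Weibull psychometric model for odd-one-out
# discrimination data, fit with JAGS.

#' Weibull psychometric function on the log-stimulus axis
#'
#' `F(x) = 1 - exp(log(0.5) * exp(c * (log(x) - m) / w))`, strictly
#' increasing in `x`, with `F(exp(m)) = 0.5`. The constant `c` is chosen
#' so that `w` is the log-stimulus distance between the 0.05 and 0.95
#' quantiles of `F`.
#'
#' @param x Positive stimulus intensity (reach).
#' @param m Threshold on the log-stimulus axis.
#' @param w Positive width.
#' @param cc Parametrization constant; default [weibull_c()].
#' @return Value in (0, 1).
#' @export
weibull_F <- function(x, m, w, cc = weibull_c()) {
  if (any(x <= 0)) stop("stimulus intensity must be positive")
  if (any(w <= 0)) stop("width must be positive")
  1 - exp(log(0.5) * exp(cc * (log(x) - m) / w))
}

#' Width-normalizing constant of the Weibull parametrization
#'
#' `c = log(-log(0.05)) - log(-log(0.95))`, which makes the width `w` the
#' log-stimulus span between the 5% and 95% points of the function.
#'
#' @return A single number (about 4.55).
#' @export
weibull_c <- function() log(-log(0.05)) - log(-log(0.95))

#' Probability of a correct response
#'
#' `S(x) = gamma + (1 - gamma - lambda) * F(x)`: chance-corrected and
#' lapse-limited success probability, bounded in `[gamma, 1 - lambda]`.
#'
#' @inheritParams weibull_F
#' @param lambda Lapse rate in `[0, 0.2]`.
#' @param gamma Chance level (1/3 for odd-one-out, 1/2 for 2IFC).
#' @return Probability.
#' @export
success_prob <- function(x, m, w, lambda = 0, gamma = 1 / 3, cc = weibull_c()) {
  stopifnot(all(lambda >= 0), all(lambda <= 0.2), gamma > 0, gamma < 1)
  gamma + (1 - gamma - lambda) * weibull_F(x, m, w, cc)
}

# validate a trial table and attach integer indices
prepare_trials <- function(trials) {
  need <- c("participant_id", "image_id", "image_type", "grain", "reach", "correct")
  miss <- setdiff(need, names(trials))
  if (length(miss)) stop("trial table lacks columns: ", paste(miss, collapse = ", "))
  if (any(!trials$image_type %in% c("scene", "texture")))
    stop("image_type must be 'scene' or 'texture'")
  if (any(trials$reach <= 0)) stop("reach must be positive")
  if (any(!trials$correct %in% c(0, 1))) stop("correct must be 0/1")
  if (any(!complete.cases(trials[need]))) stop("trial table contains missing values")
  cond <- interaction(trials$image_type, trials$grain, drop = TRUE, sep = ":")
  list(trials = trials,
       cond = as.integer(cond), cond_labels = levels(cond),
       p = as.integer(factor(trials$participant_id)),
       p_labels = levels(factor(trials$participant_id)),
       i = as.integer(factor(trials$image_id)),
       i_labels = levels(factor(trials$image_id)))
}

oracle_model_string <- "
model {
  for (t in 1:N) {
    m[t] <- mc[cond[t]] + dmp[p[t]] + dmi[img[t]]
    w[t] <- max(wc[cond[t]] + dwp[p[t]] + dwi[img[t]], 0.001)
    eta[t] <- min(cc * (lx[t] - m[t]) / w[t], 30)
    FW[t] <- 1 - exp(log(0.5) * exp(eta[t]))
    prob[t] <- gam + (1 - gam - lam[p[t]]) * FW[t]
    y[t] ~ dbern(prob[t])
  }
  for (c in 1:C) {
    mc[c] ~ dnorm(1, 1)
    wc[c] ~ dnorm(1, 1)
  }
  for (j in 1:P) {
    dmp[j] ~ dnorm(0, tau_mp)
    dwp[j] ~ dnorm(0, tau_wp)
    lam[j] ~ dnorm(mu_lam, tau_lam) T(0, 0.2)
  }
  for (k in 1:I) {
    dmi[k] ~ dnorm(0, tau_mi)
    dwi[k] ~ dnorm(0, tau_wi)
  }
  sig_mp ~ dlnorm(-1, 1); tau_mp <- pow(sig_mp, -2)
  sig_wp ~ dlnorm(-1, 1); tau_wp <- pow(sig_wp, -2)
  sig_mi ~ dlnorm(-1, 1); tau_mi <- pow(sig_mi, -2)
  sig_wi ~ dlnorm(-1, 1); tau_wi <- pow(sig_wi, -2)
  mu_lam ~ dbeta(1, 10)
  sig_lam ~ dlnorm(-1, 1); tau_lam <- pow(sig_lam, -2)
}"

# run a JAGS model, return merged draws matrix plus split-Rhat per monitor
run_jags <- function(model_string, data, monitors, chains, warmup, samples,
                     seed, inits_fn = NULL) {
  inits <- lapply(seq_len(chains), function(ch) {
    ini <- if (is.null(inits_fn)) list() else inits_fn(ch)
    c(ini, list(.RNG.name = "base::Mersenne-Twister",
                .RNG.seed = as.integer(seed) + ch))
  })
  model <- rjags::jags.model(textConnection(model_string), data = data,
                             inits = inits, n.chains = chains, quiet = TRUE)
  update(model, warmup, progress.bar = "none")
  mcmc <- rjags::coda.samples(model, monitors, n.iter = samples,
                              progress.bar = "none")
  draws <- do.call(rbind, lapply(mcmc, as.matrix))
  rhat <- tryCatch({
    m1 <- as.matrix(mcmc[[1]])
    keep <- apply(m1, 2, function(v) var(v) > 0) & !grepl("^prob\\[", colnames(m1))
    g <- coda::gelman.diag(mcmc[, keep, drop = FALSE], multivariate = FALSE,
                           autoburnin = FALSE)
    setNames(g$psrf[, 1], rownames(g$psrf))
  }, error = function(e) NULL)
  list(draws = draws, rhat = rhat, mcmc = mcmc)
}

#' Fit the experiment-based (oracle) psychometric model
#'
#' Hierarchical Bayesian model of odd-one-out correctness: a Weibull
#' psychometric function of log reach per condition (image type x grain),
#' with zero-mean participant and image offsets on both threshold and
#' width, participant lapse rates drawn from a truncated normal with a
#' Beta(1,10) prior on the mean lapse, and a Bernoulli likelihood per
#' trial. Priors: condition means N(1,1); offset scales logN(-1,1);
#' lapse scale logN(-1,1). Sampled with JAGS.
#'
#' @param trials Data frame with columns `participant_id`, `image_id`,
#'   `image_type` (`"scene"`/`"texture"`), `grain`, `reach`, `correct`.
#' @param gamma Chance level; 1/3 (odd-one-out, default) or 1/2 (2IFC).
#' @param chains,warmup,samples MCMC settings (default 4 chains,
#'   1000 + 1000).
#' @param seed Integer seed; fixed seed gives identical draws.
#' @param loglik Keep the pointwise log-likelihood matrix (needed for
#'   WAIC; default `TRUE`).
#' @return Object of class `"oracle_fit"`: posterior draws for condition
#'   thresholds/widths (`mc`, `wc`, labelled by condition), offset scales,
#'   lapse parameters, the draws-by-trials log-likelihood matrix, split
#'   R-hat values, and a `converged` flag (all R-hat < 1.05).
#' @seealso [threshold_contrast()], [waic()], [simulate_experiment()]
#' @export
fit_oracle <- function(trials, gamma = 1 / 3, chains = 4, warmup = 1000,
                       samples = 1000, seed = 0, loglik = TRUE) {
  prep <- prepare_trials(trials)
  C <- length(prep$cond_labels); P <- length(prep$p_labels)
  I <- length(prep$i_labels); N <- nrow(trials)
  data <- list(N = N, C = C, P = P, I = I,
               y = as.integer(trials$correct), lx = log(trials$reach),
               cond = prep$cond, p = prep$p, img = prep$i,
               gam = gamma, cc = weibull_c())
  inits_fn <- function(ch) list(mc = rep(1, C), wc = rep(1, C),
                                sig_mp = 0.2, sig_wp = 0.2, sig_mi = 0.2,
                                sig_wi = 0.2, sig_lam = 0.05, mu_lam = 0.05,
                                lam = rep(0.05, P))
  monitors <- c("mc", "wc", "sig_mp", "sig_wp", "sig_mi", "sig_wi",
                "mu_lam", "sig_lam", "lam", if (loglik) "prob")
  res <- run_jags(oracle_model_string, data, monitors, chains, warmup,
                  samples, seed, inits_fn)
  draws <- res$draws
  ll <- NULL
  if (loglik) {
    pcols <- grep("^prob\\[", colnames(draws))
    pm <- draws[, pcols, drop = FALSE]
    pm <- pmin(pmax(pm, 1e-12), 1 - 1e-12)
    yrep <- matrix(data$y, nrow(pm), N, byrow = TRUE)
    ll <- yrep * log(pm) + (1 - yrep) * log(1 - pm)
    colnames(ll) <- NULL
    draws <- draws[, -pcols, drop = FALSE]
  }
  rhat <- res$rhat[!grepl("^prob\\[", names(res$rhat))]
  converged <- is.null(rhat) || all(rhat < 1.05, na.rm = TRUE)
  if (!converged)
    warning(sprintf("convergence warning: max split-Rhat = %.3f",
                    max(rhat, na.rm = TRUE)))
  structure(list(draws = draws, loglik = ll, rhat = rhat,
                 converged = converged,
                 cond_labels = prep$cond_labels,
                 participant_labels = prep$p_labels,
                 image_labels = prep$i_labels,
                 gamma = gamma, n_trials = N,
                 mcmc = list(chains = chains, warmup = warmup,
                             samples = samples, seed = seed)),
            class = "oracle_fit")
}

#' Highest posterior density interval
#'
#' Narrowest contiguous interval containing the requested posterior mass
#' of a sample of draws.
#'
#' @param samples Numeric vector of posterior draws.
#' @param mass Probability mass (default 0.95).
#' @return Numeric vector `c(lower, upper)`.
#' @export
hpdi <- function(samples, mass = 0.95) {
  x <- sort(samples[is.finite(samples)])
  n <- length(x)
  if (n == 0) stop("no finite draws")
  k <- max(1L, ceiling(mass * n))
  if (k >= n) return(c(x[1], x[n]))
  widths <- x[(k + 1):n] - x[1:(n - k)]
  j <- which.min(widths)
  c(x[j], x[j + k])
}

#' Posterior contrast between two condition thresholds
#'
#' Elementwise difference of the posterior threshold draws of two
#' conditions, with its HPDI and a credible-difference flag (zero outside
#' the interval).
#'
#' @param fit An `"oracle_fit"`.
#' @param condition_a,condition_b Condition labels as in
#'   `fit$cond_labels` (format `"<image_type>:<grain>"`).
#' @param mass HPDI mass (default 0.95).
#' @return List with `draws`, `hpdi`, and logical `credible`.
#' @export
threshold_contrast <- function(fit, condition_a, condition_b, mass = 0.95) {
  stopifnot(inherits(fit, "oracle_fit"))
  ia <- match(condition_a, fit$cond_labels)
  ib <- match(condition_b, fit$cond_labels)
  if (is.na(ia) || is.na(ib)) stop("unknown condition label")
  d <- fit$draws[, paste0("mc[", ia, "]")] - fit$draws[, paste0("mc[", ib, "]")]
  h <- hpdi(d, mass)
  list(draws = d, hpdi = h, credible = !(h[1] <= 0 && 0 <= h[2]))
}

#' @export
print.oracle_fit <- function(x, ...) {
  cat("Hierarchical Weibull psychometric model (experiment-based oracle)\n")
  cat(sprintf("  %d trials, %d conditions, %d participants, %d images\n",
              x$n_trials, length(x$cond_labels), length(x$participant_labels),
              length(x$image_labels)))
  cat(sprintf("  chance level %.3f; %d chains x %d draws; converged: %s\n",
              x$gamma, x$mcmc$chains, x$mcmc$samples,
              ifelse(x$converged, "yes", "NO (max Rhat >= 1.05)")))
  invisible(x)
}

#' @export
coef.oracle_fit <- function(object, ...) {
  idx <- seq_along(object$cond_labels)
  data.frame(condition = object$cond_labels,
             m = colMeans(object$draws[, paste0("mc[", idx, "]"), drop = FALSE]),
             w = colMeans(object$draws[, paste0("wc[", idx, "]"), drop = FALSE]),
             row.names = NULL)
}

#' @export
summary.oracle_fit <- function(object, mass = 0.95, ...) {
  d <- object$draws
  tab <- data.frame(parameter = colnames(d),
                    mean = colMeans(d),
                    sd = apply(d, 2, sd),
                    hpdi_lo = apply(d, 2, function(v) hpdi(v, mass)[1]),
                    hpdi_hi = apply(d, 2, function(v) hpdi(v, mass)[2]),
                    rhat = if (is.null(object$rhat)) NA_real_
                           else unname(object$rhat[colnames(d)]),
                    row.names = NULL)
  idx <- seq_along(object$cond_labels)
  tab$parameter[match(paste0("mc[", idx, "]"), tab$parameter)] <-
    paste0("m[", object$cond_labels, "]")
  tab$parameter[match(paste0("wc[", idx, "]"), tab$parameter)] <-
    paste0("w[", object$cond_labels, "]")
  structure(list(table = tab, fit = object), class = "summary.oracle_fit")
}

#' @export
print.summary.oracle_fit <- function(x, ...) {
  print(x$fit)
  tab <- x$table
  tab[-1] <- lapply(tab[-1], round, 3)
  print(head(tab, 25), row.names = FALSE)
  if (nrow(tab) > 25) cat("  ...", nrow(tab) - 25, "more rows\n")
  invisible(x)
}

#' Predicted success probability from a fitted oracle model
#'
#' Posterior-mean success probability at new reach values for a given
#' condition (population level: random-effect offsets at zero, lapse at
#' the posterior mean of `mu_lam`).
#'
#' @param object An `"oracle_fit"`.
#' @param newdata Data frame with columns `reach` and `condition`
#'   (labels as in `object$cond_labels`).
#' @param ... Unused.
#' @return Numeric vector of probabilities.
#' @export
predict.oracle_fit <- function(object, newdata, ...) {
  ic <- match(newdata$condition, object$cond_labels)
  if (any(is.na(ic))) stop("unknown condition label in newdata")
  mu_lam <- mean(object$draws[, "mu_lam"])
  vapply(seq_len(nrow(newdata)), function(j) {
    md <- object$draws[, paste0("mc[", ic[j], "]")]
    wd <- pmax(object$draws[, paste0("wc[", ic[j], "]")], 1e-3)
    mean(success_prob(newdata$reach[j], md, wd, lambda = mu_lam,
                      gamma = object$gamma))
  }, numeric(1))
}
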