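# WAIC / ELPD model comparison and the final metric ranking against the
# experiment-based oracle model.

#' Widely applicable information criterion from a log-likelihood matrix
#'
#' `lppd = sum_i log mean_s exp(ll[s, i])`, effective parameter count
#' `p_waic = sum_i var_s(ll[s, i])`, `elpd = lppd - p_waic`, and
#' `se = sqrt(n * var_i(elpd_i))` over the pointwise elpd contributions.
#' Approximates leave-one-out expected log predictive density.
#'
#' @param loglik Draws-by-points matrix of pointwise log-likelihoods.
#' @return Object of class `"waic_result"` with fields `elpd`, `se`,
#'   `p_waic`, `lppd`, `n_points`, and the `pointwise` elpd vector.
#' @export
waic <- function(loglik) {
  loglik <- as.matrix(loglik)
  if (nrow(loglik) < 2) stop("need at least 2 posterior draws")
  mx <- apply(loglik, 2, max)
  lppd_i <- mx + log(colMeans(exp(sweep(loglik, 2, mx))))
  p_i <- apply(loglik, 2, var)
  elpd_i <- lppd_i - p_i
  n <- ncol(loglik)
  structure(list(elpd = sum(elpd_i), se = sqrt(n * var(elpd_i)),
                 p_waic = sum(p_i), lppd = sum(lppd_i), n_points = n,
                 pointwise = elpd_i),
            class = "waic_result")
}

#' @export
print.waic_result <- function(x, ...) {
  cat(sprintf("WAIC: elpd = %.2f (se %.2f), p_waic = %.2f, n = %d\n",
              x$elpd, x$se, x$p_waic, x$n_points))
  invisible(x)
}

#' Choose between the direct and normalized variant of a metric
#'
#' The variant with the higher elpd wins; an exact tie goes to the direct
#' variant.
#'
#' @param result_direct,result_normalized `"waic_result"` objects.
#' @return `"direct"` or `"normalized"`.
#' @export
select_variant <- function(result_direct, result_normalized) {
  stopifnot(inherits(result_direct, "waic_result"),
            inherits(result_normalized, "waic_result"))
  if (result_normalized$elpd > result_direct$elpd) "normalized" else "direct"
}

#' Final model comparison table
#'
#' Ranks the metric-based models and the experiment-based oracle by elpd
#' (descending) and reports each model's elpd difference to the oracle
#' with the standard error of that difference computed on the pointwise
#' elpd contributions.
#'
#' @param oracle `"waic_result"` of the experiment-based model.
#' @param metric_results Named list of `"waic_result"` objects, one per
#'   metric model (after per-metric variant selection).
#' @return Data frame with columns `model`, `elpd`, `se`, `p_waic`,
#'   `delta_elpd_vs_oracle`, `delta_se`, sorted by `elpd` descending.
#' @export
final_comparison <- function(oracle, metric_results) {
  stopifnot(inherits(oracle, "waic_result"), length(names(metric_results)) ==
              length(metric_results))
  all_res <- c(list(oracle = oracle), metric_results)
  delta <- vapply(all_res, function(r) r$elpd - oracle$elpd, numeric(1))
  dse <- vapply(all_res, function(r) {
    if (r$n_points != oracle$n_points) return(NA_real_)
    d <- r$pointwise - oracle$pointwise
    sqrt(r$n_points * var(d))
  }, numeric(1))
  tab <- data.frame(model = names(all_res),
                    elpd = vapply(all_res, `[[`, numeric(1), "elpd"),
                    se = vapply(all_res, `[[`, numeric(1), "se"),
                    p_waic = vapply(all_res, `[[`, numeric(1), "p_waic"),
                    delta_elpd_vs_oracle = delta, delta_se = dse,
                    row.names = NULL)
  tab[order(-tab$elpd), , drop = FALSE]
}

#' Run variant selection over a battery of fitted metric models
#'
#' Given WAIC results for every fitted variant (named
#' `"<metric>"` for direct and `"<metric>_norm"` for normalized), keeps
#' one result per metric by [select_variant()].
#'
#' @param results Named list of `"waic_result"` objects.
#' @return Named list with one `"waic_result"` per metric; attribute
#'   `"chosen"` records which variant won.
#' @export
select_all_variants <- function(results) {
  base <- grep("_norm$", names(results), value = TRUE, invert = TRUE)
  out <- list(); chosen <- character(0)
  for (m in base) {
    nm <- paste0(m, "_norm")
    if (nm %in% names(results)) {
      pick <- select_variant(results[[m]], results[[nm]])
      out[[m]] <- if (pick == "normalized") results[[nm]] else results[[m]]
      chosen[m] <- pick
    } else {
      out[[m]] <- results[[m]]
      chosen[m] <- "direct"
    }
  }
  attr(out, "chosen") <- chosen
  out
}
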