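#' @export
print.trio_model <- function(x, ...) {
  cat("Two-locus trio log-linear model (variant ", x$spec$variant, ")\n", sep = "")
  ds <- x$data_summary
  cat("  families: ", ds$n_families,
      " (complete: ", ds$n_complete,
      if (ds$n_excluded > 0) paste0("; excluded for missing mother: ", ds$n_excluded),
      ")\n", sep = "")
  if (x$em)
    cat("  fitted by EM (", x$em_info$n_em_iter, " iterations, observed-data ",
        "log-likelihood ", format(x$log_likelihood), ")\n", sep = "")
  else
    cat("  log-likelihood ", format(x$log_likelihood), "\n", sep = "")
  if (!x$converged) cat("  WARNING: fit did not converge\n")
  if (length(x$not_estimable))
    cat("  not estimable: ", paste(x$not_estimable, collapse = ", "), "\n", sep = "")
  cat("\nCoefficients (log relative risks):\n")
  print(round(x$coefficients, 4))
  invisible(x)
}

#' @export
coef.trio_model <- function(object, ...) object$coefficients

#' @export
vcov.trio_model <- function(object, ...) object$vcov

#' @export
logLik.trio_model <- function(object, ...) {
  structure(object$log_likelihood, df = length(object$coefficients),
            class = "logLik")
}

#' @export
confint.trio_model <- function(object, parm, level = 0.95, ...) {
  b <- object$coefficients
  se <- sqrt(diag(object$vcov))
  z <- stats::qnorm(1 - (1 - level) / 2)
  ci <- cbind(b - z * se, b + z * se)
  colnames(ci) <- paste(format(100 * c((1 - level) / 2, 1 - (1 - level) / 2)), "%")
  if (!missing(parm)) ci <- ci[parm, , drop = FALSE]
  ci
}

#' @export
predict.trio_model <- function(object, type = c("response", "link"), ...) {
  type <- match.arg(type)
  out <- object$design$cells
  out$fitted <- object$fitted
  if (type == "link") out$fitted <- ifelse(object$fitted > 0, log(object$fitted), -Inf)
  out
}

#' @export
residuals.trio_model <- function(object, type = c("pearson", "deviance"), ...) {
  type <- match.arg(type)
  y <- object$counts; mu <- object$fitted
  kc <- object$keep_cells
  r <- numeric(length(y))
  if (type == "pearson") {
    r[kc] <- (y[kc] - mu[kc]) / sqrt(mu[kc])
  } else {
    d <- 2 * (ifelse(y[kc] > 0, y[kc] * log(y[kc] / mu[kc]), 0) - (y[kc] - mu[kc]))
    r[kc] <- sign(y[kc] - mu[kc]) * sqrt(pmax(d, 0))
  }
  r
}

#' @export
plot.trio_model <- function(x, ...) {
  y <- x$counts; mu <- x$fitted
  graphics::plot(mu, y, xlab = "fitted cell count", ylab = "observed cell count",
                 main = "Trio log-linear model fit", ...)
  graphics::abline(0, 1, lty = 2)
  invisible(x)
}

#' Simulate complete-trio datasets from a fitted model
#'
#' Draws `nsim` datasets of complete case-parent trios by multinomial
#' sampling over the fitted cell means (normalized to probabilities), with
#' the same number of families as the fitted data.
#'
#' @param object a fitted `trio_model`.
#' @param nsim number of datasets.
#' @param seed optional integer seed.
#' @param ... unused.
#' @return A list of `nsim` trio data frames.
#' @export
simulate.trio_model <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  pr <- object$fitted / sum(object$fitted)
  n <- round(object$data_summary$n_families)
  cells <- object$design$cells
  two_locus <- object$spec$variant != "eq3"
  lapply(seq_len(nsim), function(i) {
    k <- stats::rmultinom(1, n, pr)[, 1]
    idx <- rep(seq_along(k), k)
    data.frame(family_id = as.character(seq_along(idx)),
               mother_locus1 = cells$M[idx],
               father_locus1 = cells$F[idx],
               child_locus1 = cells$C[idx],
               mother_locus2 = if (two_locus) cells$M2[idx] else NA_integer_)
  })
}

#' Summarize a trio model fit
#'
#' Produces the per-effect inference table: relative-risk estimates with
#' Wald 95% confidence intervals, and the likelihood-ratio test of each
#' fitted effect (the canonical test of this framework).
#'
#' @param object a fitted `trio_model`.
#' @param level confidence level for the relative-risk intervals.
#' @param ... unused.
#' @return An object of class `summary.trio_model` containing the fit and
#'   an `effects` data frame.
#' @export
summary.trio_model <- function(object, level = 0.95, ...) {
  b <- object$coefficients
  se <- sqrt(diag(object$vcov))
  z <- stats::qnorm(1 - (1 - level) / 2)
  rows <- list()
  for (e in object$spec$effects) {
    lrt <- if (e == "locus2") suppressWarnings(trio_lrt(object, e))
           else trio_lrt(object, e)
    for (cn in object$design$effect_cols[[e]]) {
      if (cn %in% names(b)) {
        rows[[length(rows) + 1]] <- data.frame(
          effect = e, parameter = cn, rr = exp(b[cn]),
          lower = exp(b[cn] - z * se[cn]), upper = exp(b[cn] + z * se[cn]),
          lrt_stat = lrt$statistic, lrt_df = lrt$df, p_value = lrt$p_value)
      } else {
        rows[[length(rows) + 1]] <- data.frame(
          effect = e, parameter = cn, rr = NA_real_, lower = NA_real_,
          upper = NA_real_, lrt_stat = NA_real_, lrt_df = NA_integer_,
          p_value = NA_real_)
      }
    }
  }
  eff <- do.call(rbind, rows)
  rownames(eff) <- NULL
  structure(list(fit = object, effects = eff, level = level),
            class = "summary.trio_model")
}

#' @export
print.summary.trio_model <- function(x, ...) {
  print(x$fit)
  cat("\nEffect estimates (relative-risk scale) and likelihood-ratio tests:\n")
  eff <- x$effects
  eff$rr <- round(eff$rr, 3); eff$lower <- round(eff$lower, 3)
  eff$upper <- round(eff$upper, 3); eff$lrt_stat <- round(eff$lrt_stat, 3)
  eff$p_value <- signif(eff$p_value, 3)
  print(eff, row.names = FALSE)
  if ("locus2" %in% x$fit$spec$effects &&
      x$fit$spec$variant %in% c("eq1", "eq1_hwe"))
    cat("\nNote: the locus-2 main-effect test is valid only if the specified\n",
        "genotype frequencies are correct; the interaction tests are not\n",
        "sensitive to that specification.\n", sep = "")
  invisible(x)
}
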