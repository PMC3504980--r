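#' Likelihood-ratio test of a model effect
#'
#' Tests one effect of a fitted trio log-linear model by refitting the
#' model without that effect's free parameters (all other terms and
#' offsets identical) and referring twice the log-likelihood difference to
#' a chi-square distribution.  For models fitted by EM the observed-data
#' log-likelihoods are compared, with the reduced model run through the
#' same EM on the same families.
#'
#' Testing `"locus2"` (the locus-2 maternal main effect) is only valid
#' when the specified genotype frequencies `p` are correct; a small
#' deviation from the correct frequencies can severely inflate this test,
#' while the interaction tests are unaffected.  A warning is issued.
#'
#' @param object a [trio_model()] fit whose specification includes `effect`.
#' @param effect one of the fitted effects (`"maternal"`, `"child"`,
#'   `"locus2"`, `"mxm"`, `"mxo"`, `"rho"`).
#' @return An object of class `trio_lrt`: list with `statistic`, `df`,
#'   `p_value`, `effect`, and `estimable` (`FALSE` when the effect's
#'   parameters could not be estimated from these data, in which case
#'   `statistic` and `p_value` are `NA`).
#' @export
trio_lrt <- function(object, effect) {
  stopifnot(inherits(object, "trio_model"))
  spec <- object$spec
  if (!effect %in% spec$effects)
    stop("effect '", effect, "' is not part of the fitted model")
  if (effect == "locus2")
    warning("the locus-2 main-effect test is valid only if the specified ",
            "genotype frequencies are correct", call. = FALSE)
  cols <- object$design$effect_cols[[effect]]
  bad <- intersect(cols, object$not_estimable)
  est_cols <- setdiff(cols, object$not_estimable)
  if (length(est_cols) == 0)
    return(structure(list(statistic = NA_real_, df = 0L, p_value = NA_real_,
                          effect = effect, estimable = FALSE,
                          not_estimable = bad), class = "trio_lrt"))
  reduced <- spec
  reduced$effects <- setdiff(spec$effects, effect)
  reduced$coding <- spec$coding[reduced$effects]
  if (object$em) {
    ed <- object$em_info$em_data
    red_fit <- em_fit_cells(ed$y0, ed$patterns, reduced,
                            allow_aliased = TRUE, compute_vcov = FALSE)
    ll_red <- red_fit$core$log_likelihood
  } else {
    red_fit <- fit_cells(object$counts, reduced, allow_aliased = TRUE)
    ll_red <- red_fit$log_likelihood
  }
  stat <- 2 * (object$log_likelihood - ll_red)
  if (stat < -1e-6)
    stop("negative likelihood-ratio statistic (", format(stat),
         "): optimization failure")
  stat <- max(stat, 0)
  df <- length(est_cols)
  structure(list(statistic = stat, df = df,
                 p_value = stats::pchisq(stat, df, lower.tail = FALSE),
                 effect = effect, estimable = TRUE,
                 not_estimable = bad), class = "trio_lrt")
}

#' @export
print.trio_lrt <- function(x, ...) {
  cat("Likelihood-ratio test:", x$effect, "\n")
  if (!x$estimable) {
    cat("  not estimable from these data (parameters: ",
        paste(x$not_estimable, collapse = ", "), ")\n", sep = "")
  } else {
    cat(sprintf("  chi-square = %.4f, df = %d, p = %.4g\n",
                x$statistic, x$df, x$p_value))
  }
  invisible(x)
}

#' Compare two nested trio model fits
#'
#' @param object,... two `trio_model` fits of nested specifications on the
#'   same data (larger model either first or second).
#' @return A data frame with the chi-square statistic, degrees of freedom
#'   and p-value of the likelihood-ratio comparison.
#' @export
anova.trio_model <- function(object, ...) {
  others <- list(...)
  if (length(others) != 1 || !inherits(others[[1]], "trio_model"))
    stop("anova() for trio models compares exactly two fits")
  m2 <- others[[1]]
  if (object$em != m2$em)
    stop("cannot compare a complete-data fit with an EM fit")
  if (!object$em && !isTRUE(all.equal(object$counts, m2$counts)))
    stop("the two fits are not on the same counts")
  stat <- 2 * abs(object$log_likelihood - m2$log_likelihood)
  df <- abs(length(object$coefficients) - length(m2$coefficients))
  if (df == 0) stop("models have the same number of parameters; not nested")
  data.frame(statistic = stat, df = df,
             p_value = stats::pchisq(stat, df, lower.tail = FALSE))
}
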