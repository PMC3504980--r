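# Poisson family without the AIC term: EM allocations are fractional, and
# dpois() on non-integer counts floods the fit with warnings; the AIC slot
# is never used here (log-likelihoods are computed directly).
quiet_poisson <- local({
  fam <- NULL
  function() {
    if (is.null(fam)) {
      f <- stats::poisson()
      f$aic <- function(y, n, mu, wt, dev) 0
      fam <<- f
    }
    fam
  }
})

# Core Poisson ML fitting on the trio cell table.
#
# Zero-support indicator columns (every cell carrying the column has zero
# count) have their MLE at -Inf; the likelihood limit is attained by
# excluding those cells (their contribution tends to 0) and dropping the
# column.  That limit is what fit_cells() computes when allow_aliased is
# TRUE; by default such parameters raise an identifiability error.

diagnose_design <- function(X, y) {
  binary <- apply(X, 2, function(v) all(v %in% c(0, 1)))
  keep_cells <- rep(TRUE, nrow(X))
  dropped <- character(0)
  repeat {
    support_y <- as.numeric(t(X[keep_cells, , drop = FALSE] != 0) %*%
                              y[keep_cells])
    cand <- colnames(X)[support_y == 0 & !(colnames(X) %in% dropped)]
    cand <- setdiff(cand, dropped)
    if (!length(cand)) break
    nonbin <- cand[!binary[cand]]
    if (length(nonbin))
      stop("model degenerate: non-indicator column(s) with no observed support: ",
           paste(nonbin, collapse = ", "))
    for (cn in cand) keep_cells <- keep_cells & (X[, cn] == 0)
    dropped <- c(dropped, cand)
  }
  keep_cols <- setdiff(colnames(X), dropped)
  Xk <- X[keep_cells, keep_cols, drop = FALSE]
  qr_x <- qr(Xk)
  aliased <- character(0)
  if (qr_x$rank < ncol(Xk)) {
    aliased <- colnames(Xk)[qr_x$pivot[seq(qr_x$rank + 1, ncol(Xk))]]
    keep_cols <- setdiff(keep_cols, aliased)
  }
  list(keep_cells = keep_cells, keep_cols = keep_cols,
       zero_support = dropped, aliased = aliased)
}

fit_cells <- function(counts, spec, allow_aliased = FALSE,
                      epsilon = 1e-12, maxit = 100, design = NULL,
                      start = NULL) {
  des <- design %||% trio_design(spec)
  X <- des$X
  if (length(counts) != nrow(X))
    stop("'counts' must have one value per cell (", nrow(X), " for variant '",
         spec$variant, "')")
  if (any(counts < 0) || anyNA(counts)) stop("cell counts must be nonnegative")
  if (sum(counts) == 0) stop("all cell counts are zero")
  y <- as.numeric(counts)
  dg <- diagnose_design(X, y)
  not_estimable <- c(dg$zero_support, dg$aliased)
  if (length(not_estimable) && !allow_aliased)
    stop("model not identifiable from these counts; non-estimable parameter(s): ",
         paste(not_estimable, collapse = ", "))
  kc <- dg$keep_cells
  Xk <- X[kc, dg$keep_cols, drop = FALSE]
  offk <- des$offset[kc]
  st <- NULL
  if (!is.null(start) && all(colnames(Xk) %in% names(start)))
    st <- start[colnames(Xk)]
  fit <- suppressWarnings(stats::glm.fit(
    x = Xk, y = y[kc], offset = offk, family = quiet_poisson(),
    start = st,
    control = stats::glm.control(epsilon = epsilon, maxit = maxit)))
  beta <- fit$coefficients
  eta <- drop(Xk %*% beta) + offk
  mu <- exp(eta)
  fitted <- numeric(length(y))
  fitted[kc] <- mu
  w <- mu
  info <- crossprod(Xk, Xk * w)
  vc <- tryCatch(solve(info), error = function(e) matrix(NA_real_, ncol(Xk), ncol(Xk)))
  dimnames(vc) <- list(names(beta), names(beta))
  ll <- sum(y[kc] * eta - mu - lgamma(y[kc] + 1))
  score <- drop(crossprod(Xk, y[kc] - mu))
  list(coefficients = beta, vcov = vc, log_likelihood = ll,
       fitted = fitted, converged = fit$converged, n_iterations = fit$iter,
       score_norm = max(abs(score)), not_estimable = not_estimable,
       keep_cells = kc, spec = spec, design = des, counts = y)
}

#' Fit a trio log-linear model to complete-trio cell counts
#'
#' Maximum-likelihood Poisson fit of the model described by a
#' [trio_spec()] to a vector of (possibly fractional) cell counts aligned
#' with [cell_index_table()].  This is the complete-data workhorse behind
#' [trio_model()]; use it directly when the data are already tabulated.
#'
#' @param counts nonnegative cell counts, length 45 (two-locus variants) or
#'   15 (`eq3`).
#' @param spec a [trio_spec()].
#' @param allow_aliased if `FALSE` (default), parameters that cannot be
#'   estimated from these counts (no observed support, or linear aliasing)
#'   raise an error naming them; if `TRUE` they are dropped, recorded in
#'   the result, and tests involving them are reported as not estimable.
#' @return A `trio_model` object.
#' @export
fit_trio_counts <- function(counts, spec, allow_aliased = FALSE) {
  core <- fit_cells(counts, spec, allow_aliased = allow_aliased)
  new_trio_model(core, em = FALSE, data_summary = list(
    n_families = sum(counts), n_complete = sum(counts), n_excluded = 0L))
}

new_trio_model <- function(core, em, data_summary, em_info = NULL,
                           families = NULL, allow_aliased = FALSE) {
  structure(list(
    coefficients = core$coefficients, vcov = core$vcov,
    log_likelihood = core$log_likelihood, fitted = core$fitted,
    converged = core$converged, n_iterations = core$n_iterations,
    score_norm = core$score_norm, not_estimable = core$not_estimable,
    keep_cells = core$keep_cells, spec = core$spec, design = core$design,
    counts = core$counts, em = em, em_info = em_info, families = families,
    data_summary = data_summary, allow_aliased = allow_aliased),
    class = "trio_model")
}

#' Fit a two-locus trio log-linear model
#'
#' The main fitting interface.  Accepts either a trio data frame (columns
#' `mother_locus1`, `father_locus1`, `child_locus1`, `mother_locus2`,
#' optionally `family_id`; genotypes coded 0/1/2 with `NA` for missing) or
#' a vector of tabulated cell counts.  Complete trios are tabulated into
#' the 45-cell (or 15-cell, for `variant = "eq3"`) table and fitted by
#' Poisson maximum likelihood; when incompletely genotyped trios are
#' present the model is fitted with an EM algorithm maximizing the
#' observed-data likelihood.
#'
#' Case-father pairs (mother missing) and case-only records are excluded
#' by default because missing mothers remove all locus-2 information and
#' can inflate the type-I error of the interaction tests; missing fathers
#' are handled fully.
#'
#' @param data trio data frame or cell count vector.
#' @param variant,effects,coding,p,mating passed to [trio_spec()].
#' @param keep_case_father,keep_case_only retain families with a missing
#'   mother (and both-parent-missing families) in the EM instead of
#'   dropping them.
#' @param allow_aliased see [fit_trio_counts()].
#' @param em_control list with elements `tol` (convergence tolerance on
#'   the observed-data log-likelihood, default 1e-8) and `max_iter`
#'   (default 500).
#' @return An object of class `trio_model`, with methods `print`,
#'   `summary`, `coef`, `vcov`, `logLik`, `confint`, `predict`,
#'   `residuals`, `simulate`, `plot` and `anova`.  Effects are tested with
#'   [trio_lrt()].
#' @examples
#' sc <- trio_scenario("model3", n_families = 300, seed = 1)
#' trios <- simulate_trios(sc)
#' fit <- trio_model(trios, variant = "eq1", coding = "dominant",
#'                   p = hwe_genotype_freq(0.3))
#' trio_lrt(fit, "mxm")
#' @export
trio_model <- function(data, variant = c("eq1", "eq2", "eq1_hwe", "eq3"),
                       effects = NULL, coding = "codominant", p = NULL,
                       mating = c("types", "intercept"),
                       keep_case_father = FALSE, keep_case_only = FALSE,
                       allow_aliased = FALSE,
                       em_control = list(tol = 1e-8, max_iter = 500)) {
  variant <- match.arg(variant)
  if (is.null(effects))
    effects <- if (variant == "eq3") c("maternal", "child", "rho")
               else if (variant == "eq2") c("maternal", "child", "mxm", "mxo")
               else c("maternal", "child", "locus2", "mxm", "mxo")
  spec <- trio_spec(variant, effects, coding, p, mating = mating)
  if (is.numeric(data) && is.null(dim(data)))
    return(fit_trio_counts(data, spec, allow_aliased = allow_aliased))
  fam <- validate_trios(as.data.frame(data))
  fam$class <- classify_families(fam)
  excl <- fam$class %in% c(if (!keep_case_father) "CASE_FATHER",
                           if (!keep_case_only) "CASE_ONLY")
  n_excl <- sum(excl)
  if (n_excl > 0)
    warning(n_excl, " famil", if (n_excl == 1) "y" else "ies",
            " with missing maternal genotypes excluded (see 'keep_case_father')")
  fam_used <- fam[!excl, , drop = FALSE]
  if (nrow(fam_used) == 0) stop("no usable families")
  agg <- aggregate_families(fam_used, variant)
  ds <- list(n_families = nrow(fam_used),
             n_complete = sum(agg$complete_counts),
             n_excluded = n_excl)
  if (length(agg$patterns) == 0) {
    core <- fit_cells(agg$complete_counts, spec, allow_aliased = allow_aliased)
    return(new_trio_model(core, em = FALSE, data_summary = ds,
                          families = fam_used, allow_aliased = allow_aliased))
  }
  em <- em_fit_cells(agg$complete_counts, agg$patterns, spec,
                     allow_aliased = allow_aliased,
                     tol = em_control$tol %||% 1e-8,
                     max_iter = em_control$max_iter %||% 500)
  new_trio_model(em$core, em = TRUE, data_summary = ds,
                 em_info = em$info, families = fam_used,
                 allow_aliased = allow_aliased)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# tabulate complete trios into cell counts; incomplete families into
# compatible-cell patterns keyed by their observed genotypes (families with
# the same observed pattern share one E-step allocation)
aggregate_families <- function(fam, variant) {
  cells <- cell_index_table(variant)
  n_cells <- nrow(cells)
  two_locus <- variant != "eq3"
  M2 <- if (two_locus) fam$mother_locus2 else rep(NA_integer_, nrow(fam))
  key <- paste(fam$mother_locus1, fam$father_locus1, fam$child_locus1, M2)
  y0 <- numeric(n_cells)
  patterns <- list()
  tab <- table(key)
  for (k in names(tab)) {
    g <- strsplit(k, " ", fixed = TRUE)[[1]]
    g <- suppressWarnings(as.integer(g))  # "NA" -> NA
    idx <- compatible_cells(g[1], g[2], g[3], g[4], variant = variant)
    if (length(idx) == 0)
      stop("family '", fam$family_id[match(k, key)],
           "': genotypes are Mendelian-inconsistent")
    n_k <- as.integer(tab[[k]])
    if (length(idx) == 1) y0[idx] <- y0[idx] + n_k
    else patterns[[length(patterns) + 1]] <- list(cells = idx, n = n_k)
  }
  list(complete_counts = y0, patterns = patterns)
}
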