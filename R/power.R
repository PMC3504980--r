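#' Monte-Carlo type-I error and power study
#'
#' Replicate engine: simulates datasets under a scenario, analyses each
#' with the requested model, tests the requested effects by likelihood
#' ratio, and tabulates rejection fractions at the nominal level together
#' with Monte-Carlo standard errors and mean parameter estimates.
#' Replicate `r` uses seed `base_seed + r`, so a study is fully
#' reproducible from its design.  Datasets with missing genotypes are
#' analysed by EM automatically; replicates whose fit fails or does not
#' converge are counted and excluded (with a warning if they exceed 1%),
#' and tests whose parameters are not estimable in a replicate count as
#' non-rejections.
#'
#' @param scenario a [trio_scenario()].
#' @param variant,effects,coding,p,mating the analysis model, as in
#'   [trio_model()].
#' @param effects_to_test effects whose LRT rejection fraction is
#'   recorded; defaults to the interaction effects present in the analysis
#'   model.
#' @param n_replicates number of simulated datasets.
#' @param alpha nominal significance level; a replicate counts as a
#'   rejection when its p-value is strictly below `alpha`.
#' @param base_seed integer; replicate `r` is simulated with seed
#'   `base_seed + r`.
#' @return An object of class `trio_power`: a list with `results` (one row
#'   per tested effect: rejections, rejection fraction, Monte-Carlo SE,
#'   mean and SD of each parameter estimate on the log scale, counts of
#'   not-estimable tests), `n_failed`, and the design.
#' @examples
#' sc <- trio_scenario("model1", n_families = 300)
#' trio_power_study(sc, variant = "eq1", coding = "dominant",
#'                  p = hwe_genotype_freq(0.3), n_replicates = 20,
#'                  base_seed = 42)
#' @export
trio_power_study <- function(scenario, variant = "eq1", effects = NULL,
                             coding = "dominant", p = NULL,
                             mating = c("types", "intercept"),
                             effects_to_test = NULL, n_replicates = 1000,
                             alpha = 0.05, base_seed = 1) {
  stopifnot(inherits(scenario, "trio_scenario"))
  if (n_replicates < 1) stop("'n_replicates' must be at least 1")
  if (alpha <= 0 || alpha > 1) stop("'alpha' must be in (0, 1]")
  mating <- match.arg(mating)
  if (is.null(effects))
    effects <- if (variant == "eq3") c("maternal", "child", "rho")
               else if (variant == "eq2") c("maternal", "child", "mxm", "mxo")
               else c("maternal", "child", "locus2", "mxm", "mxo")
  spec <- trio_spec(variant, effects, coding, p, mating = mating)
  if (is.null(effects_to_test))
    effects_to_test <- intersect(c("mxm", "mxo", "rho"), spec$effects)
  stopifnot(all(effects_to_test %in% spec$effects))
  has_missing <- scenario$missing_father_rate > 0 ||
    scenario$missing_mother_rate > 0
  pvals <- matrix(NA_real_, n_replicates, length(effects_to_test),
                  dimnames = list(NULL, effects_to_test))
  estimable <- matrix(NA, n_replicates, length(effects_to_test),
                      dimnames = list(NULL, effects_to_test))
  est_sums <- list(); est_sq <- list(); est_n <- list()
  n_failed <- 0L
  for (r in seq_len(n_replicates)) {
    s <- scenario
    s$seed <- base_seed + r
    fit <- tryCatch({
      if (!has_missing) {
        set.seed(s$seed)
        counts <- simulate_cell_counts(s)
        if (variant == "eq3") counts <- rowSums(matrix(counts, 15, 3))
        fit_trio_counts(counts, spec, allow_aliased = TRUE)
      } else {
        trios <- simulate_trios(s)
        suppressWarnings(trio_model(trios, variant = variant,
                                    effects = effects, coding = coding,
                                    p = p, mating = mating,
                                    allow_aliased = TRUE))
      }
    }, error = function(e) e)
    if (inherits(fit, "error") || !fit$converged) {
      n_failed <- n_failed + 1L
      next
    }
    for (e in effects_to_test) {
      lrt <- tryCatch(suppressWarnings(trio_lrt(fit, e)),
                      error = function(err) NULL)
      if (is.null(lrt)) { estimable[r, e] <- FALSE; next }
      estimable[r, e] <- lrt$estimable
      if (lrt$estimable) pvals[r, e] <- lrt$p_value
      cols <- intersect(fit$design$effect_cols[[e]], names(fit$coefficients))
      for (cn in cols) {
        est_sums[[cn]] <- (est_sums[[cn]] %||% 0) + fit$coefficients[[cn]]
        est_sq[[cn]] <- (est_sq[[cn]] %||% 0) + fit$coefficients[[cn]]^2
        est_n[[cn]] <- (est_n[[cn]] %||% 0L) + 1L
      }
    }
  }
  if (n_failed > 0.01 * n_replicates)
    warning(n_failed, " of ", n_replicates,
            " replicates failed to fit or converge and were excluded")
  n_used <- n_replicates - n_failed
  res <- lapply(effects_to_test, function(e) {
    ne <- sum(!is.na(estimable[, e]) & !estimable[, e])
    pv <- pvals[, e]
    rej <- sum(pv < alpha, na.rm = TRUE)  # not-estimable => non-rejection
    frac <- if (n_used > 0) rej / n_used else NA_real_
    data.frame(effect = e, n_replicates = n_used, rejections = rej,
               rejection_fraction = frac,
               mc_se = sqrt(frac * (1 - frac) / max(n_used, 1)),
               n_not_estimable = ne)
  })
  est <- lapply(names(est_sums), function(cn) {
    n <- est_n[[cn]]
    m <- est_sums[[cn]] / n
    v <- est_sq[[cn]] / n - m^2
    data.frame(parameter = cn, mean_log = m, sd_log = sqrt(max(v, 0) * n / max(n - 1, 1)),
               mean_rr = exp(m), n = n)
  })
  structure(list(results = do.call(rbind, res),
                 estimates = if (length(est)) do.call(rbind, est) else NULL,
                 n_failed = n_failed, alpha = alpha,
                 scenario = scenario, spec = spec,
                 n_replicates = n_replicates, base_seed = base_seed,
                 pvals = pvals),
            class = "trio_power")
}

#' @export
print.trio_power <- function(x, ...) {
  cat("Monte-Carlo study: ", x$n_replicates, " replicates of ",
      x$scenario$n_families, " families",
      if (!is.null(x$scenario$model)) paste0(" (", x$scenario$model, ")"),
      ", alpha = ", x$alpha, "\n", sep = "")
  out <- x$results
  out$rejection_pct <- round(100 * out$rejection_fraction, 1)
  out$mc_se_pct <- round(100 * out$mc_se, 2)
  print(out[, c("effect", "n_replicates", "rejections", "rejection_pct",
                "mc_se_pct", "n_not_estimable")], row.names = FALSE)
  if (x$n_failed > 0) cat("failed replicates:", x$n_failed, "\n")
  invisible(x)
}
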