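#' Model specification for the trio log-linear model
#'
#' Describes which model variant is fitted, which effects are included, and
#' the genetic coding of each effect.
#'
#' Variants:
#' \describe{
#'   \item{`eq1`}{two-locus model with the locus-2 genotype frequencies
#'     `p` specified in the offset and a 2-parameter locus-2 main effect
#'     (`delta`) available.}
#'   \item{`eq2`}{two-locus model estimating the locus-2 genotype
#'     frequencies through free nuisance parameters `lambda_k = ln(p_k/p_0)`;
#'     the locus-2 main effect is absorbed and cannot be estimated.}
#'   \item{`eq1_hwe`}{as `eq1`, but the six mating-type parameters are
#'     replaced by an intercept plus a parents' allele-count column whose
#'     coefficient is `logit` of the locus-1 allele frequency, the
#'     Hardy-Weinberg constraint.}
#'   \item{`eq3`}{single-locus model on the 15 trio configurations with the
#'     same-locus maternal-by-offspring interaction `rho`.}
#' }
#'
#' @param variant one of `"eq1"`, `"eq2"`, `"eq1_hwe"`, `"eq3"`.
#' @param effects character vector drawn from `"maternal"` (maternal locus-1
#'   main effect S), `"child"` (child locus-1 main effect R), `"locus2"`
#'   (locus-2 maternal main effect, `eq1`/`eq1_hwe` only), `"mxm"`
#'   (two-locus maternal-by-maternal interaction theta), `"mxo"` (two-locus
#'   maternal-by-offspring interaction phi), `"rho"` (single-locus
#'   interaction, `eq3` only).
#' @param coding a single coding for all effects, or a named list with one
#'   entry per effect.  Codings: `"dominant"` (one parameter, carriers),
#'   `"codominant"`/`"unconstrained"` (free parameter per genotype level),
#'   `"multiplicative"` (log-risk linear in allele count; main effects
#'   only).  The locus-2 main effect is always fitted with its two free
#'   parameters.
#' @param p locus-2 genotype frequencies (p0, p1, p2), required for `eq1`
#'   and `eq1_hwe`.
#' @param mating `"types"` (default) fits one stratum parameter per mating
#'   type; `"intercept"` replaces the six stratum parameters with a single
#'   constant.  Because the same mating-type factor multiplies all three
#'   locus-2 strata of a configuration, the interaction tests are invariant
#'   to this choice when the main effects are retained.  Ignored by
#'   `eq1_hwe`, which has its own allele-frequency parameterization.
#' @return An object of class `trio_spec`.
#' @export
trio_spec <- function(variant = c("eq1", "eq2", "eq1_hwe", "eq3"),
                      effects = c("maternal", "child", "locus2", "mxm", "mxo"),
                      coding = "codominant", p = NULL,
                      mating = c("types", "intercept")) {
  variant <- match.arg(variant)
  mating <- match.arg(mating)
  all_effects <- c("maternal", "child", "locus2", "mxm", "mxo", "rho")
  effects <- unique(match.arg(effects, all_effects, several.ok = TRUE))
  if (variant == "eq2" && "locus2" %in% effects)
    stop("variant 'eq2' estimates the locus-2 frequencies; its main effect cannot be included")
  if (variant == "eq3" && any(effects %in% c("locus2", "mxm", "mxo")))
    stop("variant 'eq3' is single-locus; allowed effects are 'maternal', 'child', 'rho'")
  if (variant != "eq3" && "rho" %in% effects)
    stop("'rho' (single-locus interaction) is only available with variant 'eq3'")
  if (variant %in% c("eq1", "eq1_hwe")) {
    if (is.null(p)) stop("variant '", variant, "' requires specified locus-2 frequencies 'p'")
    check_p(p)
    if (any(p == 0)) stop("specified locus-2 frequencies must be strictly positive")
  } else if (!is.null(p)) {
    stop("'p' must not be supplied with variant '", variant, "'")
  }
  codings <- c("dominant", "codominant", "unconstrained", "multiplicative")
  if (!is.list(coding)) {
    coding <- match.arg(coding, codings)
    coding <- stats::setNames(as.list(rep(coding, length(effects))), effects)
  } else {
    if (!all(effects %in% names(coding)))
      coding[setdiff(effects, names(coding))] <- "codominant"
    coding <- lapply(coding, match.arg, choices = codings)
  }
  coding <- lapply(coding, function(cd) if (cd == "unconstrained") "codominant" else cd)
  for (e in intersect(effects, c("mxm", "mxo", "rho")))
    if (coding[[e]] == "multiplicative")
      stop("multiplicative coding is only supported for main effects")
  structure(list(variant = variant, effects = effects,
                 coding = coding[effects],
                 p = if (is.null(p)) NULL else as.numeric(p),
                 mating = mating),
            class = "trio_spec")
}

#' @export
print.trio_spec <- function(x, ...) {
  cat("trio log-linear model specification\n")
  cat("  variant:", x$variant, "\n")
  cat("  effects:", paste(sprintf("%s (%s)", x$effects, unlist(x$coding)),
                          collapse = ", "), "\n")
  if (!is.null(x$p))
    cat("  specified locus-2 frequencies:", paste(format(x$p), collapse = "/"), "\n")
  invisible(x)
}

# columns for a genotype-indexed effect: g is the indexing genotype vector
effect_columns <- function(g, coding, prefix) {
  switch(coding,
    dominant = {
      m <- matrix(as.numeric(g >= 1), ncol = 1)
      colnames(m) <- prefix
      m
    },
    codominant = {
      m <- cbind(as.numeric(g == 1), as.numeric(g == 2))
      colnames(m) <- paste0(prefix, 1:2)
      m
    },
    multiplicative = {
      m <- matrix(as.numeric(g), ncol = 1)
      colnames(m) <- paste0(prefix, "_add")
      m
    })
}

interaction_columns <- function(g1, g2, coding, prefix) {
  if (coding == "dominant") {
    m <- matrix(as.numeric(g1 >= 1 & g2 >= 1), ncol = 1)
    colnames(m) <- prefix
    return(m)
  }
  cols <- lapply(1:2, function(i) lapply(1:2, function(k)
    as.numeric(g1 == i & g2 == k)))
  m <- do.call(cbind, unlist(cols, recursive = FALSE))
  colnames(m) <- paste0(prefix, rep(1:2, each = 2), rep(1:2, 2))
  m
}

#' Design matrix of a trio log-linear model
#'
#' Linearizes the trio-type table on the log scale: for every admissible
#' coefficient vector, `exp(X %*% beta + offset)` reproduces the expected
#' cell counts cell by cell.  Mating-type stratum parameters come first
#' (six indicators, or intercept plus parents' allele count for the
#' Hardy-Weinberg-constrained variant), followed by the requested effects.
#'
#' @param spec a [trio_spec()].
#' @return A list with components `X` (cells x parameters matrix), `offset`
#'   (see [cell_offsets()]), `cells` (the cell index table), and
#'   `effect_cols`, a named list mapping each effect to its column names
#'   (the free parameters removed when that effect is tested).
#' @export
trio_design <- function(spec) {
  stopifnot(inherits(spec, "trio_spec"))
  cells <- cell_index_table(spec$variant)
  if (spec$variant == "eq1_hwe") {
    X <- cbind("(Intercept)" = rep(1, nrow(cells)),
               "a" = mating_allele_count()[cells$m])
  } else if (identical(spec$mating, "intercept")) {
    X <- cbind("(Intercept)" = rep(1, nrow(cells)))
  } else {
    X <- sapply(1:6, function(mm) as.numeric(cells$m == mm))
    colnames(X) <- paste0("mu", 1:6)
  }
  effect_cols <- list()
  add <- function(X, block, effect) {
    effect_cols[[effect]] <<- colnames(block)
    cbind(X, block)
  }
  if (spec$variant == "eq2") {
    lam <- cbind(lambda1 = as.numeric(cells$M2 == 1),
                 lambda2 = as.numeric(cells$M2 == 2))
    X <- cbind(X, lam)
  }
  for (e in spec$effects) {
    cd <- spec$coding[[e]]
    block <- switch(e,
      maternal = effect_columns(cells$M, cd, "S"),
      child    = effect_columns(cells$C, cd, "R"),
      locus2   = {
        b <- cbind(delta1 = as.numeric(cells$M2 == 1),
                   delta2 = as.numeric(cells$M2 == 2))
        b
      },
      mxm = interaction_columns(cells$M, cells$M2, cd, "theta"),
      mxo = interaction_columns(cells$C, cells$M2, cd, "phi"),
      rho = interaction_columns(cells$M, cells$C, cd, "rho"))
    X <- add(X, block, e)
  }
  list(X = X, offset = cell_offsets(spec$variant, spec$p),
       cells = cells, effect_cols = effect_cols)
}
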