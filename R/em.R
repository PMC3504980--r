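# EM for incompletely genotyped trios.
#
# A family with missing genotypes is compatible with a set of cells; the
# observed-data likelihood (Poisson total-count formulation, families
# independent) is
#   sum_fam ln( sum_{cells compatible with fam} mu_cell ) - sum_cells mu.
# The E-step distributes each incomplete family over its compatible cells
# proportionally to the current fitted means (offsets included, so locus-2
# frequency information enters for families missing the mother's locus-2
# genotype); the M-step refits the Poisson model on the fractional table.

#' Cells compatible with a partially observed family
#'
#' Returns the indices (rows of [cell_index_table()]) of every cell whose
#' mother/father/child locus-1 and mother locus-2 genotypes agree with the
#' observed entries, applying Mendelian rules through the enumeration of
#' consistent configurations.  Fully observed families map to exactly one
#' cell; an empty result means the observed genotypes are
#' Mendelian-inconsistent.
#'
#' @param M,F,C,M2 genotypes (0, 1, 2) or `NA` when missing.
#' @param variant model variant; `"eq3"` uses the 15-cell single-locus
#'   table and ignores `M2`.
#' @return Integer vector of compatible cell indices (possibly empty).
#' @export
compatible_cells <- function(M, F, C, M2 = NA,
                             variant = c("eq1", "eq2", "eq1_hwe", "eq3")) {
  variant <- match.arg(variant)
  cells <- cell_index_table(variant)
  ok <- rep(TRUE, nrow(cells))
  if (!is.na(M)) ok <- ok & cells$M == M
  if (!is.na(F)) ok <- ok & cells$F == F
  if (!is.na(C)) ok <- ok & cells$C == C
  if (variant != "eq3" && !is.na(M2)) ok <- ok & cells$M2 == M2
  which(ok)
}

classify_families <- function(fam) {
  m_miss <- is.na(fam$mother_locus1)
  f_miss <- is.na(fam$father_locus1)
  ifelse(m_miss & f_miss, "CASE_ONLY",
         ifelse(m_miss, "CASE_FATHER",
                ifelse(f_miss, "CASE_MOTHER", "FULL")))
}

validate_trios <- function(fam) {
  need <- c("mother_locus1", "father_locus1", "child_locus1", "mother_locus2")
  if (!all(need %in% names(fam)))
    stop("trio data must have columns ", paste(need, collapse = ", "))
  if (!"family_id" %in% names(fam))
    fam$family_id <- as.character(seq_len(nrow(fam)))
  for (cn in need) {
    v <- fam[[cn]]
    if (!all(is.na(v) | v %in% 0:2))
      stop("column '", cn, "' must contain genotypes 0, 1, 2 or NA")
  }
  if (anyNA(fam$child_locus1))
    stop("missing child genotypes are not supported")
  if (anyDuplicated(fam$family_id))
    stop("duplicate family_id values: ",
         paste(unique(fam$family_id[duplicated(fam$family_id)]), collapse = ", "))
  fam
}

obs_loglik <- function(beta, Xk, offk, y0k, pat_k) {
  mu <- exp(drop(Xk %*% beta) + offk)
  ll <- sum(y0k[y0k > 0] * log(mu[y0k > 0])) - sum(mu)
  for (p in pat_k) {
    s <- sum(mu[p$cells])
    if (s <= 0) return(-Inf)
    ll <- ll + p$n * log(s)
  }
  ll
}

em_fit_cells <- function(y0, patterns, spec, allow_aliased = FALSE,
                         tol = 1e-8, max_iter = 500, compute_vcov = TRUE) {
  if (length(patterns) == 0) {
    core <- fit_cells(y0, spec, allow_aliased = allow_aliased)
    core$log_likelihood <- core$log_likelihood +
      sum(lgamma(y0 + 1))  # drop the tabulation constant: per-family form
    return(list(core = core,
                info = list(n_em_iter = 0L, converged = TRUE,
                            obs_loglik_trace = core$log_likelihood)))
  }
  n_cells <- length(y0)
  # initial allocation: uniform over compatible cells
  y <- y0
  for (p in patterns) y[p$cells] <- y[p$cells] + p$n / length(p$cells)
  ll_old <- -Inf
  trace <- numeric(0)
  monotone <- TRUE
  core <- NULL
  des <- trio_design(spec)
  beta_prev <- NULL
  for (it in seq_len(max_iter)) {
    core <- fit_cells(y, spec, allow_aliased = allow_aliased,
                      design = des, start = beta_prev)
    beta_prev <- core$coefficients
    mu <- core$fitted
    ll <- sum(y0[y0 > 0] * log(mu[y0 > 0])) - sum(mu)
    for (p in patterns) {
      s <- sum(mu[p$cells])
      if (s <= 0) stop("EM degenerate: a family's compatible cells all have zero fitted mean")
      ll <- ll + p$n * log(s)
    }
    trace <- c(trace, ll)
    if (ll < ll_old - 1e-7) monotone <- FALSE
    done <- abs(ll - ll_old) < tol
    ll_old <- ll
    if (done) break
    # E-step
    y <- y0
    for (p in patterns) {
      w <- mu[p$cells] / sum(mu[p$cells])
      y[p$cells] <- y[p$cells] + p$n * w
    }
  }
  converged <- (it < max_iter) ||
    (length(trace) >= 2 && abs(diff(utils::tail(trace, 2))) < tol)
  if (compute_vcov) {
    # observed-data information, central differences on the observed log-lik
    kc <- core$keep_cells
    Xk <- core$design$X[kc, names(core$coefficients), drop = FALSE]
    offk <- core$design$offset[kc]
    idx_map <- cumsum(kc)
    pat_k <- lapply(patterns, function(p) {
      cl <- p$cells[kc[p$cells]]
      list(cells = idx_map[cl], n = p$n)
    })
    y0k <- y0[kc]
    beta <- core$coefficients
    d <- length(beta)
    H <- matrix(NA_real_, d, d, dimnames = list(names(beta), names(beta)))
    h <- 1e-4 * pmax(1, abs(beta))
    f0 <- obs_loglik(beta, Xk, offk, y0k, pat_k)
    for (a in seq_len(d)) for (b in seq_len(a)) {
      ea <- eb <- numeric(d); ea[a] <- h[a]; eb[b] <- h[b]
      if (a == b) {
        H[a, a] <- (obs_loglik(beta + ea, Xk, offk, y0k, pat_k) - 2 * f0 +
                      obs_loglik(beta - ea, Xk, offk, y0k, pat_k)) / h[a]^2
      } else {
        H[a, b] <- H[b, a] <-
          (obs_loglik(beta + ea + eb, Xk, offk, y0k, pat_k) -
             obs_loglik(beta + ea - eb, Xk, offk, y0k, pat_k) -
             obs_loglik(beta - ea + eb, Xk, offk, y0k, pat_k) +
             obs_loglik(beta - ea - eb, Xk, offk, y0k, pat_k)) / (4 * h[a] * h[b])
      }
    }
    vc <- tryCatch(solve(-H), error = function(e) matrix(NA_real_, d, d))
    dimnames(vc) <- dimnames(H)
    core$vcov <- vc
  }
  core$log_likelihood <- ll_old
  core$converged <- core$converged && converged
  list(core = core,
       info = list(n_em_iter = it, converged = converged,
                   obs_loglik_trace = trace, monotone = monotone,
                   em_data = list(y0 = y0, patterns = patterns)))
}
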