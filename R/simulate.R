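# Ascertained case-parent trio simulator.
#
# Sampling is prospective in distribution: a trio's probability of entering
# the study is proportional to
#   P(M) P(F) P(C | M, F) P(M2) x penetrance(M, C, M2),
# penetrance = baseline * S_i R_j theta_ik phi_jk tau_k (and rho_ij for
# single-locus scenarios).  Under symmetric Hardy-Weinberg mating this
# reduces exactly to the theoretical trio-type table.  Two interchangeable
# samplers are provided: a multinomial draw over the 45 ordered cells
# (primary, exact under the model) and an individual-level rejection
# sampler that accepts a simulated family with probability equal to the
# child's disease risk (cross-validation oracle).

# P(child = c | mother = m, father = f) by Mendelian transmission
mendelian_transmission <- function(m, f, c) {
  pa <- function(g, a) if (a == 1) g / 2 else 1 - g / 2
  pa(m, 0) * pa(f, 0) * (c == 0) +
    (pa(m, 1) * pa(f, 0) + pa(m, 0) * pa(f, 1)) * (c == 1) +
    pa(m, 1) * pa(f, 1) * (c == 2)
}

risk_product <- function(risk, i, j, k, include_rho = FALSE) {
  v <- rr_at(risk$S, i) * rr_at(risk$R, j) * rr_at(risk$tau, k) *
    rr_at2(risk$theta, i, k) * rr_at2(risk$phi, j, k)
  if (include_rho) v <- v * rr_at2(risk$rho, i, j)
  v
}

father_genotype_freq <- function(pop) {
  rm <- pop$raf1_male
  if (is.data.frame(rm)) {
    f <- rep(0, 3)
    for (s in seq_len(nrow(rm)))
      f <- f + rm$weight[s] * hwe_genotype_freq(rm$raf[s])
    f
  } else hwe_genotype_freq(rm)
}

#' Simulation scenario for ascertained trio data
#'
#' Constructs a simulation scenario, either from a named preset
#' (`"model1"` .. `"model14"`, `"model11a"` .. `"model14a"`) or from
#' explicit `risk`/`pop` components.  Presets share the common study
#' conditions: baseline disease incidence 0.1, Hardy-Weinberg equilibrium
#' at both loci, risk-allele frequency 0.3 at both loci.  Presets 1-10 are
#' dominant (a single relative risk applies to carriers); 11-14 are
#' codominant with per-genotype risks; the `a` variants add parental
#' mating asymmetry (father genotypes drawn from an equal mixture of
#' Hardy-Weinberg strata with allele frequencies 0.1 and 0.5, overall
#' allele frequency still 0.3).
#'
#' @param model preset name, or `NULL` when `risk` and `pop` are given.
#' @param n_families number of ascertained trios per dataset.
#' @param risk a [risk_model()] (ignored when `model` is a preset name).
#' @param pop a [pop_params()] (ignored when `model` is a preset name).
#' @param missing_father_rate,missing_mother_rate probabilities that a
#'   family's father genotype, or mother genotypes at both loci, are set
#'   missing (completely at random, mutually exclusive per family).
#' @param seed integer seed used by the samplers; `NULL` leaves the RNG
#'   state untouched.
#' @return An object of class `trio_scenario`.
#' @export
trio_scenario <- function(model = NULL, n_families = 1000, risk = NULL,
                          pop = NULL, missing_father_rate = 0,
                          missing_mother_rate = 0, seed = NULL) {
  include_rho <- FALSE
  if (!is.null(model)) {
    pre <- scenario_preset(model)
    risk <- pre$risk; pop <- pre$pop; include_rho <- pre$include_rho
  }
  if (is.null(risk) || is.null(pop))
    stop("supply either a preset 'model' name or both 'risk' and 'pop'")
  stopifnot(inherits(risk, "risk_model"), inherits(pop, "pop_params"))
  if (n_families < 1) stop("'n_families' must be at least 1")
  if (missing_father_rate < 0 || missing_mother_rate < 0 ||
      missing_father_rate + missing_mother_rate > 1)
    stop("missingness rates must be nonnegative with sum at most 1")
  # penetrance validity: the largest cell disease risk must not exceed 1
  combos <- expand.grid(i = 0:2, j = 0:2, k = 0:2)
  max_risk <- risk$baseline *
    max(risk_product(risk, combos$i, combos$j, combos$k, include_rho = TRUE))
  if (max_risk > 1)
    stop("invalid scenario: maximum cell disease risk ", format(max_risk),
         " exceeds 1; lower the baseline incidence or the relative risks")
  structure(list(model = model, risk = risk, pop = pop,
                 n_families = n_families, include_rho = include_rho,
                 missing_father_rate = missing_father_rate,
                 missing_mother_rate = missing_mother_rate, seed = seed),
            class = "trio_scenario")
}

scenario_preset <- function(model) {
  asym <- grepl("a$", model)
  base <- sub("a$", "", model)
  num <- suppressWarnings(as.integer(sub("^model", "", base)))
  if (is.na(num) || !grepl("^model", base) ||
      !(num %in% 1:14) || (asym && !(num %in% 11:14)))
    stop("unknown scenario preset '", model, "'")
  male <- if (asym) data.frame(raf = c(0.1, 0.5), weight = c(0.5, 0.5)) else 0.3
  pop <- pop_params(raf1_female = 0.3, raf1_male = male, raf2 = 0.3)
  include_rho <- num %in% c(9, 10)
  risk <- switch(as.character(num),
    "1" = risk_model_dominant(),
    "2" = risk_model_dominant(theta1 = 1.5),
    "3" = risk_model_dominant(theta1 = 2),
    "4" = risk_model_dominant(phi1 = 1.5),
    "5" = risk_model_dominant(phi1 = 2),
    "6" = risk_model_dominant(S1 = 1.5, R1 = 1.5),
    "7" = risk_model_dominant(theta1 = 1.5, phi1 = 1.5),
    "8" = risk_model_dominant(theta1 = 2, phi1 = 2),
    "9" = risk_model_dominant(rho1 = 1.5),
    "10" = risk_model_dominant(rho1 = 2),
    "11" = risk_model(phi = c(1.3, 1.69, 1.69, 2.197)),
    "12" = risk_model(theta = c(1.4, 1.96, 1.96, 2.744)),
    "13" = risk_model(theta = c(1.4, 1.96, 1.96, 2.744),
                      phi = c(1.3, 1.69, 1.69, 2.197)),
    "14" = risk_model(R = c(1.3, 1.69), S = c(1.4, 1.96)))
  list(risk = risk, pop = pop, include_rho = include_rho)
}

#' Ascertained sampling probabilities over the ordered cell space
#'
#' The probability that an ascertained trio falls in each of the 45
#' ordered cells (15 ordered Mendelian configurations at locus 1 times
#' 3 maternal locus-2 genotypes), proportional to parental genotype
#' frequencies, Mendelian transmission, the locus-2 genotype frequency and
#' the cell's disease risk.  Under symmetric Hardy-Weinberg mating this is
#' the normalized theoretical trio-type table.
#'
#' @param s a [trio_scenario()].
#' @return [cell_index_table()] plus a `prob` column summing to 1.
#' @export
cell_sampling_probabilities <- function(s) {
  stopifnot(inherits(s, "trio_scenario"))
  cells <- cell_index_table("eq1")
  pm <- hwe_genotype_freq(s$pop$raf1_female)
  pf <- father_genotype_freq(s$pop)
  pr <- pm[cells$M + 1] * pf[cells$F + 1] *
    mendelian_transmission(cells$M, cells$F, cells$C) *
    s$pop$p[cells$M2 + 1] *
    s$risk$baseline *
    risk_product(s$risk, cells$M, cells$C, cells$M2, s$include_rho)
  cells$prob <- pr / sum(pr)
  cells
}

apply_missingness <- function(df, s) {
  n <- nrow(df)
  if (s$missing_father_rate == 0 && s$missing_mother_rate == 0) return(df)
  u <- stats::runif(n)
  f_miss <- u < s$missing_father_rate
  m_miss <- !f_miss & u < s$missing_father_rate + s$missing_mother_rate
  df$father_locus1[f_miss] <- NA_integer_
  df$mother_locus1[m_miss] <- NA_integer_
  df$mother_locus2[m_miss] <- NA_integer_
  df
}

cells_to_trios <- function(idx) {
  cells <- cell_index_table("eq1")
  data.frame(family_id = as.character(seq_along(idx)),
             mother_locus1 = cells$M[idx],
             father_locus1 = cells$F[idx],
             child_locus1 = cells$C[idx],
             mother_locus2 = cells$M2[idx])
}

# multinomial draw over cells; returns the 45-cell count vector
simulate_cell_counts <- function(s) {
  pr <- cell_sampling_probabilities(s)$prob
  stats::rmultinom(1, s$n_families, pr)[, 1]
}

#' Simulate an ascertained trio dataset (multinomial cell sampler)
#'
#' Draws `n_families` trios by multinomial sampling over the ascertained
#' cell probabilities, then applies completely-at-random missingness
#' (father, or mother at both loci).  Deterministic given the scenario
#' seed.
#'
#' @param s a [trio_scenario()].
#' @return A trio data frame (`family_id`, `mother_locus1`,
#'   `father_locus1`, `child_locus1`, `mother_locus2`).
#' @export
simulate_trios <- function(s) {
  stopifnot(inherits(s, "trio_scenario"))
  if (!is.null(s$seed)) set.seed(s$seed)
  counts <- simulate_cell_counts(s)
  df <- cells_to_trios(rep(seq_along(counts), counts))
  # randomize family order so missingness patterns are exchangeable
  df <- df[sample.int(nrow(df)), ]
  df$family_id <- as.character(seq_len(nrow(df)))
  rownames(df) <- NULL
  apply_missingness(df, s)
}

#' Simulate an ascertained trio dataset (individual-level rejection sampler)
#'
#' Independent oracle for [simulate_trios()]: parents are drawn from their
#' sex-specific genotype distributions, the child by Mendelian
#' transmission, the mother's locus-2 genotype from its population
#' distribution, and the family is accepted with probability equal to the
#' child's disease risk.  Distributionally equivalent to the multinomial
#' sampler.
#'
#' @param s a [trio_scenario()].
#' @param max_batches safety limit on the number of candidate batches.
#' @return A trio data frame, as [simulate_trios()].
#' @export
simulate_trios_rejection <- function(s, max_batches = 1000) {
  stopifnot(inherits(s, "trio_scenario"))
  if (!is.null(s$seed)) set.seed(s$seed)
  pm <- hwe_genotype_freq(s$pop$raf1_female)
  pf <- father_genotype_freq(s$pop)
  need <- s$n_families
  batch <- max(1000, ceiling(need / max(s$risk$baseline, 1e-3)))
  acc <- list(); got <- 0; tried <- 0; accepted_total <- 0
  for (b in seq_len(max_batches)) {
    M <- sample(0:2, batch, replace = TRUE, prob = pm)
    F <- sample(0:2, batch, replace = TRUE, prob = pf)
    tm <- stats::rbinom(batch, 1, M / 2)
    tf <- stats::rbinom(batch, 1, F / 2)
    C <- tm + tf
    M2 <- sample(0:2, batch, replace = TRUE, prob = s$pop$p)
    risk <- s$risk$baseline * risk_product(s$risk, M, C, M2, s$include_rho)
    keep <- stats::runif(batch) < risk
    tried <- tried + batch
    accepted_total <- accepted_total + sum(keep)
    if (any(keep))
      acc[[length(acc) + 1]] <- data.frame(mother_locus1 = M[keep],
                                           father_locus1 = F[keep],
                                           child_locus1 = C[keep],
                                           mother_locus2 = M2[keep])
    got <- accepted_total
    if (tried >= 1e5 && accepted_total / tried < 1e-6)
      stop("rejection sampler acceptance rate below 1e-6; check the scenario")
    if (got >= need) break
  }
  if (got < need) stop("rejection sampler failed to accept ", need, " families")
  df <- do.call(rbind, acc)[seq_len(need), ]
  df <- cbind(family_id = as.character(seq_len(need)), df)
  attr(df, "acceptance_rate") <- accepted_total / tried
  rownames(df) <- NULL
  apply_missingness(df, s)
}
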