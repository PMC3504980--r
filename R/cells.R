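#' Trio configurations at the first locus
#'
#' Enumerates the 15 Mendelian-consistent ordered genotype configurations
#' (mother, father, child) of a biallelic locus, grouped into the six
#' mating types defined under mating symmetry.  Genotypes are coded as the
#' number of risk alleles (0, 1, 2).  Configuration 9 (all three members
#' heterozygous) arises from two equally likely transmissions and carries a
#' Mendelian multiplicity of 2; all others have multiplicity 1.
#'
#' @return A data frame with one row per configuration and columns
#'   `config` (1..15), `m` (mating type 1..6), `M`, `F`, `C` (risk-allele
#'   counts of mother, father, child) and `mult` (Mendelian multiplicity).
#' @examples
#' trio_configurations()
#' @export
trio_configurations <- function() {
  data.frame(
    config = 1:15,
    m    = c(1, 2, 2, 2, 2, 3, 3, 4, 4, 4, 5, 5, 5, 5, 6),
    M    = c(2, 2, 2, 1, 1, 2, 0, 1, 1, 1, 1, 1, 0, 0, 0),
    F    = c(2, 1, 1, 2, 2, 0, 2, 1, 1, 1, 0, 0, 1, 1, 0),
    C    = c(2, 2, 1, 2, 1, 1, 1, 2, 1, 0, 1, 0, 1, 0, 0),
    mult = c(1, 1, 1, 1, 1, 1, 1, 1, 2, 1, 1, 1, 1, 1, 1)
  )
}

# parents' total risk-allele count per mating type 1..6
mating_allele_count <- function() c(4L, 3L, 2L, 2L, 1L, 0L)

#' Cell index table
#'
#' The cell space of the log-linear model: the 15 trio configurations,
#' stratified (for the two-locus variants) by the mother's genotype at the
#' second locus.
#'
#' @param variant model variant; the single-locus variant `"eq3"` has 15
#'   cells, all others 45 (15 configurations x 3 second-locus strata).
#' @return A data frame with columns `config`, `m`, `M`, `F`, `C`, `mult`
#'   and, for two-locus variants, `M2` in 0..2.  Row order is configuration
#'   1..15 within `M2` = 0, then 1, then 2.
#' @export
cell_index_table <- local({
  cache <- list()
  function(variant = c("eq1", "eq2", "eq1_hwe", "eq3")) {
    variant <- match.arg(variant)
    key <- if (variant == "eq3") "single" else "two"
    if (is.null(cache[[key]])) {
      cfg <- trio_configurations()
      if (key == "single") {
        cache[[key]] <<- cfg
      } else {
        out <- cfg[rep(seq_len(15), times = 3), ]
        out$M2 <- rep(0:2, each = 15)
        rownames(out) <- NULL
        cache[[key]] <<- out
      }
    }
    cache[[key]]
  }
})

#' Relative-risk parameter set
#'
#' Bundles all relative risks of the two-locus trio model: maternal main
#' effects `S` at locus 1, child main effects `R` at locus 1, the
#' two-locus maternal-by-maternal interaction `theta[i, k]`, the two-locus
#' maternal-by-offspring interaction `phi[j, k]`, the maternal main effect
#' `tau` at locus 2, and the single-locus maternal-by-offspring interaction
#' `rho[i, j]` (used only by the single-locus variant and the simulator).
#' Index 0 parameters are fixed at 1 by construction and never stored.
#'
#' @param S,R length-2 vectors of relative risks for 1 and 2 copies of the
#'   risk allele in mother and child, respectively.
#' @param theta,phi,rho 2 x 2 matrices of interaction relative risks; rows
#'   index the first subscript (1, 2 risk alleles), columns the second.
#'   Scalars are recycled.
#' @param tau length-2 vector of locus-2 maternal main-effect relative risks.
#' @param baseline baseline disease incidence for the all-zero genotype
#'   category (used by the simulator's penetrance model).
#' @return An object of class `risk_model`.
#' @seealso [risk_model_dominant()] for the common dominant shorthand.
#' @export
risk_model <- function(S = c(1, 1), R = c(1, 1), theta = 1, phi = 1,
                       tau = c(1, 1), rho = 1, baseline = 0.1) {
  as_mat <- function(x, nm) {
    if (length(x) == 1) x <- matrix(x, 2, 2) else x <- matrix(x, 2, 2)
    if (any(x <= 0)) stop("relative risks in '", nm, "' must be positive")
    dimnames(x) <- list(c("1", "2"), c("1", "2"))
    x
  }
  S <- rep(S, length.out = 2); R <- rep(R, length.out = 2)
  tau <- rep(tau, length.out = 2)
  if (any(c(S, R, tau) <= 0)) stop("relative risks must be positive")
  if (baseline <= 0 || baseline > 1) stop("'baseline' must be in (0, 1]")
  structure(list(S = S, R = R, theta = as_mat(theta, "theta"),
                 phi = as_mat(phi, "phi"), tau = tau,
                 rho = as_mat(rho, "rho"), baseline = baseline),
            class = "risk_model")
}

#' @rdname risk_model
#' @param S1,R1,theta1,phi1,rho1,tau1 single dominant relative risks: the
#'   same value applies to carriers of one or two risk alleles.
#' @export
risk_model_dominant <- function(S1 = 1, R1 = 1, theta1 = 1, phi1 = 1,
                                tau1 = 1, rho1 = 1, baseline = 0.1) {
  risk_model(S = c(S1, S1), R = c(R1, R1), theta = theta1, phi = phi1,
             tau = c(tau1, tau1), rho = rho1, baseline = baseline)
}

#' Population parameters for the two-locus trio model
#'
#' @param raf1_female risk-allele frequency at locus 1 in females.
#' @param raf1_male risk-allele frequency at locus 1 in males; either a
#'   single frequency (mating symmetry when equal to `raf1_female`) or a
#'   data frame / list with components `raf` and `weight` describing a
#'   mixture of Hardy-Weinberg strata (mating asymmetry).
#' @param raf2 risk-allele frequency at locus 2 (mothers).
#' @param p optional genotype frequency triple (p0, p1, p2) of the mother's
#'   locus-2 genotype; defaults to Hardy-Weinberg proportions from `raf2`.
#' @param mu optional vector of six ordered-pair mating-type frequencies
#'   mu_1..mu_6; defaults to the Hardy-Weinberg values
#'   `q^a (1-q)^(4-a)`, a = (4,3,2,2,1,0), with `q = raf1_female`.
#' @return An object of class `pop_params`.
#' @export
pop_params <- function(raf1_female = 0.3, raf1_male = raf1_female,
                       raf2 = 0.3, p = NULL, mu = NULL) {
  stopifnot(raf1_female > 0, raf1_female < 1, raf2 > 0, raf2 < 1)
  if (is.null(p)) p <- hwe_genotype_freq(raf2)
  check_p(p)
  if (is.null(mu)) mu <- hwe_mating_freq(raf1_female)
  if (length(mu) != 6 || any(mu < 0)) stop("'mu' must be 6 nonnegative frequencies")
  if (is.list(raf1_male)) {
    raf1_male <- as.data.frame(raf1_male)
    stopifnot(all(c("raf", "weight") %in% names(raf1_male)))
    if (abs(sum(raf1_male$weight) - 1) > 1e-8)
      stop("male stratum weights must sum to 1")
  }
  structure(list(raf1_female = raf1_female, raf1_male = raf1_male,
                 raf2 = raf2, p = as.numeric(p), mu = as.numeric(mu)),
            class = "pop_params")
}

check_p <- function(p) {
  if (length(p) != 3 || any(p < 0) || abs(sum(p) - 1) > 1e-12)
    stop("locus-2 genotype frequencies 'p' must be 3 nonnegative values summing to 1")
  invisible(p)
}

#' Hardy-Weinberg genotype frequencies
#'
#' @param q risk-allele frequency.
#' @return `c((1-q)^2, 2q(1-q), q^2)`, the frequencies of 0, 1, 2 copies.
#' @export
hwe_genotype_freq <- function(q) c((1 - q)^2, 2 * q * (1 - q), q^2)

#' Hardy-Weinberg ordered mating-type frequencies
#'
#' The per-ordered-parental-pair cell frequency of each mating type under
#' Hardy-Weinberg equilibrium with allele frequency `q`:
#' `mu_m = q^a_m (1-q)^(4-a_m)` where `a_m` is the parents' total
#' risk-allele count (4, 3, 2, 2, 1, 0 for m = 1..6).  The heterozygote
#' factor 2 in the genotype frequency cancels against the 1/2 transmission
#' probability, so these values multiply each Table-row cell directly.
#'
#' @param q risk-allele frequency at locus 1.
#' @return Numeric vector mu_1..mu_6.
#' @export
hwe_mating_freq <- function(q) {
  a <- mating_allele_count()
  q^a * (1 - q)^(4 - a)
}

# look up a relative risk with 0-index meaning 1
rr_at <- function(v, i) ifelse(i == 0, 1, v[pmax(i, 1)])
rr_at2 <- function(m, i, k) ifelse(i == 0 | k == 0, 1, m[cbind(pmax(i, 1), pmax(k, 1))])

#' Expected cell proportions of the two-locus trio table
#'
#' Builds the 45-cell table of theoretical trio-type proportions: each cell
#' `(configuration, M2 = k)` carries
#' `mult * p_k * tau_k * theta_{ik} * phi_{jk} * S_i * R_j * mu_m`,
#' where `i`, `j` are the mother's and child's locus-1 risk-allele counts
#' and index-0 factors equal 1.  The table is not normalized in general; it
#' sums to 1 under an all-null risk model with `mu` taken as true ordered
#' mating-type frequencies.
#'
#' @param risk a [risk_model()].
#' @param pop a [pop_params()].
#' @param include_rho include the single-locus maternal-by-offspring
#'   interaction `rho[i, j]` in the product (used by the simulator for
#'   single-locus scenarios); default `FALSE`.
#' @return A data frame: [cell_index_table()] plus a `value` column.
#' @export
expected_cell_proportions <- function(risk, pop, include_rho = FALSE) {
  stopifnot(inherits(risk, "risk_model"), inherits(pop, "pop_params"))
  check_p(pop$p)
  cells <- cell_index_table("eq1")
  i <- cells$M; j <- cells$C; k <- cells$M2
  v <- cells$mult *
    pop$p[k + 1] *
    rr_at(risk$tau, k) *
    rr_at2(risk$theta, i, k) *
    rr_at2(risk$phi, j, k) *
    rr_at(risk$S, i) *
    rr_at(risk$R, j) *
    pop$mu[cells$m]
  if (include_rho) v <- v * rr_at2(risk$rho, i, j)
  cells$value <- v
  cells
}

#' Log-linear offsets per cell
#'
#' Fixed additive terms of the log-linear predictor.  All variants carry
#' `ln 2` for configuration 9 (the double-heterozygote Mendelian
#' multiplicity).  The variants with specified locus-2 genotype frequencies
#' (`eq1`, `eq1_hwe`) additionally carry `ln p_k`; the variant that
#' estimates the frequencies (`eq2`) and the single-locus variant (`eq3`)
#' do not.
#'
#' @param variant model variant.
#' @param p locus-2 genotype frequencies (p0, p1, p2); required (and all
#'   strictly positive) for `eq1` and `eq1_hwe`, ignored otherwise.
#' @return Numeric offset vector aligned with [cell_index_table()].
#' @export
cell_offsets <- function(variant = c("eq1", "eq2", "eq1_hwe", "eq3"), p = NULL) {
  variant <- match.arg(variant)
  cells <- cell_index_table(variant)
  off <- log(2) * (cells$config == 9)
  if (variant %in% c("eq1", "eq1_hwe")) {
    if (is.null(p)) stop("variant '", variant, "' requires specified locus-2 frequencies 'p'")
    check_p(p)
    if (any(p == 0)) stop("specified locus-2 frequencies must be strictly positive")
    off <- off + log(p)[cells$M2 + 1]
  }
  off
}
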