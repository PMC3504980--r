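test_that("the 15 trio configurations enumerate the published table rows", {
  cfg <- trio_configurations()
  expect_equal(nrow(cfg), 15)
  expect_equal(length(unique(cfg$m)), 6)
  # frozen row-by-row oracle: (mating type, M, F, C, multiplicity)
  oracle <- rbind(
    c(1, 2, 2, 2, 1), c(2, 2, 1, 2, 1), c(2, 2, 1, 1, 1), c(2, 1, 2, 2, 1),
    c(2, 1, 2, 1, 1), c(3, 2, 0, 1, 1), c(3, 0, 2, 1, 1), c(4, 1, 1, 2, 1),
    c(4, 1, 1, 1, 2), c(4, 1, 1, 0, 1), c(5, 1, 0, 1, 1), c(5, 1, 0, 0, 1),
    c(5, 0, 1, 1, 1), c(5, 0, 1, 0, 1), c(6, 0, 0, 0, 1))
  expect_equal(unname(as.matrix(cfg[, c("m", "M", "F", "C", "mult")])),
               unname(oracle))
  # every row is Mendelian-consistent and the double-het is the only mult-2
  for (r in seq_len(15)) {
    pt <- function(g) c(1 - g / 2, g / 2)
    pm <- pt(cfg$M[r]); pf <- pt(cfg$F[r])
    pc <- c(pm[1] * pf[1], pm[1] * pf[2] + pm[2] * pf[1], pm[2] * pf[2])
    expect_gt(pc[cfg$C[r] + 1], 0)
  }
  expect_equal(which(cfg$mult == 2), 9L)
  expect_true(all(cfg$M[cfg$config == 9] == 1 & cfg$F[cfg$config == 9] == 1 &
                    cfg$C[cfg$config == 9] == 1))
})

test_that("expected cell proportions reproduce the theoretical table", {
  # literal cell-by-cell oracle under a fully asymmetric parameter set
  tab <- expected_cell_proportions(fixture_risk(), fixture_pop())
  expect_equal(tab$value, fixture_table_oracle(), tolerance = 1e-14)

  # all-null model with true HWE mating frequencies is a distribution
  null_tab <- expected_cell_proportions(risk_model_dominant(), pop_params())
  expect_equal(sum(null_tab$value), 1, tolerance = 1e-12)

  # direct product: configuration 1, M2 = 2, only S2 = 2 active
  rk <- risk_model(S = c(1, 2))
  pp <- pop_params(p = c(0.4, 0.3, 0.3), mu = c(0.1, rep(0.18, 5)))
  tab1 <- expected_cell_proportions(rk, pp)
  expect_equal(tab1$value[tab1$config == 1 & tab1$M2 == 2], 0.3 * 2 * 0.1)

  # dominant M-by-M risk 2: stratum ratio within configuration 6
  rk3 <- risk_model_dominant(theta1 = 2)
  pp3 <- pop_params(p = p_true)
  tab3 <- expected_cell_proportions(rk3, pp3)
  r1 <- tab3$value[tab3$config == 6 & tab3$M2 == 1]
  r0 <- tab3$value[tab3$config == 6 & tab3$M2 == 0]
  expect_equal(r1 / r0, 2 * 0.42 / 0.49, tolerance = 1e-12)

  # invalid frequency specifications are rejected
  expect_error(pop_params(p = c(0.5, 0.4, 0.2)), "summing to 1")
  expect_error(pop_params(p = c(0.6, 0.5, -0.1)), "nonnegative|summing")
})

test_that("Hardy-Weinberg mating frequencies close the null table", {
  q <- 0.3
  mu <- hwe_mating_freq(q)
  # ordered-pair frequencies times transmission recover each mu exactly
  expect_equal(mu, q^c(4, 3, 2, 2, 1, 0) * (1 - q)^c(0, 1, 2, 2, 3, 4))
  expect_equal(hwe_genotype_freq(q), c(0.49, 0.42, 0.09))
  # null proportions sum to 1 for any allele frequency
  for (qq in c(0.1, 0.3, 0.5, 0.8)) {
    tab <- expected_cell_proportions(
      risk_model_dominant(),
      pop_params(raf1_female = qq, raf2 = qq))
    expect_equal(sum(tab$value), 1, tolerance = 1e-12)
  }
})

test_that("offsets carry the genotype frequencies and the double-het weight", {
  off1 <- cell_offsets("eq1", p_true)
  cells <- cell_index_table("eq1")
  expect_equal(off1[cells$config == 9 & cells$M2 == 1], log(0.42) + log(2))
  expect_equal(off1[cells$config == 15 & cells$M2 == 0], log(0.49))
  off2 <- cell_offsets("eq2")
  expect_equal(off2[cells$config == 3 & cells$M2 == 0], 0)
  expect_equal(off2, log(2) * (cells$config == 9))
  off3 <- cell_offsets("eq3")
  expect_equal(length(off3), 15)
  expect_equal(off3, log(2) * (trio_configurations()$config == 9))
  expect_error(cell_offsets("eq1"), "requires")
  expect_error(cell_offsets("eq1", c(0.82, 0.18, 0)), "strictly positive")
})

test_that("the design matrix linearizes the cell table exactly", {
  risk <- fixture_risk(); pop <- fixture_pop()
  tab <- expected_cell_proportions(risk, pop)
  spec <- trio_spec("eq1", coding = "codominant", p = pop$p)
  d <- trio_design(spec)
  beta <- fixture_beta(risk, pop)
  expect_equal(drop(exp(d$X %*% beta + d$offset)), tab$value,
               tolerance = 1e-12)

  # dominant constraint: one parameter per effect reproduces dominant tables
  rkd <- risk_model_dominant(S1 = 1.5, R1 = 1.2, theta1 = 1.7, phi1 = 0.8,
                             tau1 = 1.3)
  tabd <- expected_cell_proportions(rkd, pop)
  specd <- trio_spec("eq1", coding = "dominant", p = pop$p)
  dd <- trio_design(specd)
  betad <- c(log(pop$mu), log(1.5), log(1.2), log(1.3), log(1.3),
             log(1.7), log(0.8))
  expect_equal(drop(exp(dd$X %*% betad + dd$offset)), tabd$value,
               tolerance = 1e-12)
})

test_that("free-parameter counts match the model variants", {
  expect_equal(ncol(trio_design(trio_spec("eq1", coding = "dominant",
                                          p = p_true))$X), 12)
  expect_equal(ncol(trio_design(trio_spec("eq1", coding = "codominant",
                                          p = p_true))$X), 20)
  expect_equal(ncol(trio_design(trio_spec(
    "eq3", effects = c("maternal", "child", "rho"),
    coding = "codominant"))$X), 14)
  d <- trio_design(trio_spec("eq1_hwe", coding = "codominant", p = p_true))
  expect_equal(ncol(d$X), 2 + 2 + 2 + 2 + 4 + 4)
  expect_equal(colnames(d$X)[1:2], c("(Intercept)", "a"))
})

test_that("specification rules are enforced", {
  expect_error(trio_spec("eq2", effects = c("locus2", "mxm")), "eq2")
  expect_error(trio_spec("eq3", effects = c("maternal", "mxm")), "single-locus")
  expect_error(trio_spec("eq1", effects = c("maternal", "rho"), p = p_true),
               "rho")
  expect_error(trio_spec("eq1", coding = "dominant"), "requires")
  expect_error(trio_spec("eq2", coding = "dominant", p = p_true), "eq2")
  expect_error(trio_spec("eq1", coding = list(mxm = "multiplicative"),
                         p = p_true), "multiplicative")
})
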