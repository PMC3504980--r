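test_that("fitting exact expected counts recovers the generating log-risks", {
  risk <- fixture_risk(); pop <- fixture_pop()
  tab <- expected_cell_proportions(risk, pop)
  spec <- trio_spec("eq1", coding = "codominant", p = pop$p)
  beta <- fixture_beta(risk, pop)
  for (N in c(200, 5000)) {
    fit <- fit_trio_counts(tab$value * N, spec)
    est <- coef(fit)
    # effect coefficients are recovered exactly; mating-type parameters
    # absorb the arbitrary scale N
    eff <- setdiff(names(est), paste0("mu", 1:6))
    expect_equal(unname(est[eff]), unname(beta[eff]), tolerance = 1e-6)
    expect_equal(unname(est[paste0("mu", 1:6)] - log(N)),
                 unname(log(pop$mu)), tolerance = 1e-6)
    expect_true(fit$converged)
    # sufficient statistics preserved at the MLE
    d <- fit$design
    expect_lt(max(abs(crossprod(d$X, fit$counts - fit$fitted))), 1e-6)
  }
})

test_that("LRT on null-proportional counts is zero with p-value 1", {
  tab <- expected_cell_proportions(risk_model_dominant(), pop_params())
  fit <- trio_model(tab$value * 400, "eq1", coding = "dominant", p = p_true)
  for (e in c("mxm", "mxo", "maternal", "child")) {
    l <- trio_lrt(fit, e)
    expect_lt(l$statistic, 1e-6)
    expect_gt(l$p_value, 1 - 1e-4)
  }
})

test_that("specified-frequency and estimated-frequency variants give identical
           interaction tests", {
  # algebraic identity: the offset difference lies in the span of the
  # mating-type and locus-2 columns, so interaction LRTs agree exactly
  set.seed(421)
  for (i in 1:20) {
    y <- rpois(45, 15) + (i %% 3 == 0)  # vary sparsity a little
    p_any <- prop.table(runif(3) + 0.05)
    f1 <- trio_model(y, "eq1", coding = "dominant", p = p_any,
                     allow_aliased = TRUE)
    f2 <- trio_model(y, "eq2", coding = "dominant", allow_aliased = TRUE)
    for (e in c("mxm", "mxo")) {
      l1 <- trio_lrt(f1, e); l2 <- trio_lrt(f2, e)
      expect_equal(l1$statistic, l2$statistic, tolerance = 1e-6)
    }
  }
})

test_that("interaction estimates and tests are invariant to the specified
           locus-2 frequencies when the main effect is in the model", {
  set.seed(77)
  y <- rpois(45, 12)
  ref <- trio_model(y, "eq1", coding = "codominant", p = p_true)
  for (p in list(p_false1, p_false2, c(0.2, 0.3, 0.5))) {
    alt <- trio_model(y, "eq1", coding = "codominant", p = p)
    for (e in c("mxm", "mxo")) {
      expect_equal(trio_lrt(ref, e)$statistic, trio_lrt(alt, e)$statistic,
                   tolerance = 1e-8)
    }
    nm <- c(paste0("theta", c(11, 12, 21, 22)), paste0("phi", c(11, 12, 21, 22)))
    expect_equal(coef(ref)[nm], coef(alt)[nm], tolerance = 1e-8)
  }
})

test_that("single-locus interaction LRT equals the conditional multinomial
           test", {
  # oracle: maximize the within-mating-type multinomial likelihood directly
  cfg <- trio_configurations()
  mult <- cfg$mult
  multinom_lrt <- function(y, with_rho) {
    nll <- function(par) {
      alpha <- par[1]; beta <- par[2]; rho <- if (with_rho) par[3] else 0
      w <- mult * exp(alpha * (cfg$M >= 1) + beta * (cfg$C >= 1) +
                        rho * (cfg$M >= 1 & cfg$C >= 1))
      ll <- 0
      for (m in 1:6) {
        idx <- cfg$m == m
        pr <- w[idx] / sum(w[idx])
        ll <- ll + sum(y[idx] * log(pr))
      }
      -ll
    }
    npar <- if (with_rho) 3 else 2
    opt <- stats::optim(rep(0, npar), nll, method = "BFGS",
                        control = list(reltol = 1e-14, maxit = 500))
    -opt$value
  }
  set.seed(99)
  for (i in 1:10) {
    y <- rpois(15, 25) + 1
    fit <- trio_model(y, "eq3", coding = "dominant")
    l <- trio_lrt(fit, "rho")
    oracle_stat <- 2 * (multinom_lrt(y, TRUE) - multinom_lrt(y, FALSE))
    expect_equal(l$statistic, oracle_stat, tolerance = 1e-6)
  }
})

test_that("an empty locus-2 stratum raises an identifiability error naming
           the affected parameters", {
  tab <- expected_cell_proportions(risk_model_dominant(),
                                   pop_params(p = c(0.6, 0.4, 0)))
  y <- round(tab$value * 600)
  err <- tryCatch(
    trio_model(y, "eq1", coding = "codominant", p = p_true),
    error = function(e) conditionMessage(e))
  expect_match(err, "delta2")
  expect_match(err, "theta12"); expect_match(err, "theta22")
  expect_match(err, "phi12"); expect_match(err, "phi22")
  # with allow_aliased the fit proceeds, tests get reduced df, and the
  # dropped parameters are reported
  fit <- trio_model(y, "eq1", coding = "codominant", p = p_true,
                    allow_aliased = TRUE)
  expect_true(all(c("delta2", "theta12", "theta22", "phi12", "phi22")
                  %in% fit$not_estimable))
  l <- trio_lrt(fit, "mxm")
  expect_true(l$estimable)
  expect_equal(l$df, 2)
})

test_that("a fully missing effect support returns a not-estimable test", {
  # no mothers carrying the risk allele at locus 1 in the M2 > 0 strata
  y <- numeric(45)
  cells <- cell_index_table("eq1")
  y[cells$M == 0] <- 5
  y[cells$M > 0 & cells$M2 == 0] <- 5
  fit <- trio_model(y, "eq1", coding = "dominant", p = p_true,
                    allow_aliased = TRUE)
  l <- trio_lrt(fit, "mxm")
  expect_false(l$estimable)
  expect_true(is.na(l$p_value))
})

test_that("the locus-2 main-effect test warns and is sensitive to frequency
           misspecification, unlike the interaction tests", {
  sc <- trio_scenario("model1", n_families = 500)
  n_rep <- 120
  rej <- c(correct = 0, wrong = 0)
  rej_int <- 0
  for (r in seq_len(n_rep)) {
    s <- sc; s$seed <- 7000 + r
    set.seed(s$seed)
    y <- triolog:::simulate_cell_counts(s)
    f_ok <- trio_model(y, "eq1", coding = "dominant", p = p_true,
                       allow_aliased = TRUE)
    f_bad <- trio_model(y, "eq1", coding = "dominant", p = p_false1,
                        allow_aliased = TRUE)
    expect_warning(l_ok <- trio_lrt(f_ok, "locus2"), "valid only")
    l_bad <- suppressWarnings(trio_lrt(f_bad, "locus2"))
    rej["correct"] <- rej["correct"] + (l_ok$p_value < 0.05)
    rej["wrong"] <- rej["wrong"] + (l_bad$p_value < 0.05)
    rej_int <- rej_int + (trio_lrt(f_bad, "mxm")$p_value < 0.05)
  }
  # correct frequencies: calibrated near 5%; misspecified: grossly inflated
  expect_lt(rej[["correct"]] / n_rep, 0.12)
  expect_gt(rej[["wrong"]] / n_rep, 0.5)
  # the interaction test on the same misspecified fits stays calibrated
  expect_lt(rej_int / n_rep, 0.12)
})

test_that("multiplicative main-effect coding constrains the second copy to
           twice the log-risk of the first", {
  rk <- risk_model(S = c(1.4, 1.4^2), R = c(1.2, 1.2^2))
  pop <- pop_params()
  tab <- expected_cell_proportions(rk, pop)
  fit <- trio_model(tab$value * 300, "eq1",
                    coding = list(maternal = "multiplicative",
                                  child = "multiplicative",
                                  locus2 = "codominant",
                                  mxm = "dominant", mxo = "dominant"),
                    p = p_true)
  expect_equal(unname(coef(fit)["S_add"]), log(1.4), tolerance = 1e-6)
  expect_equal(unname(coef(fit)["R_add"]), log(1.2), tolerance = 1e-6)
})
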