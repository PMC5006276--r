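test_that("penalized log-likelihood evaluates known closed forms", {
  set.seed(1)
  V <- matrix(rbinom(60, 1, 0.5), 20, 3)
  psi0 <- dda_params(h = rep(0, 3), model = "dominant")
  expect_equal(penalized_loglik(psi0, V, lambda = 0), -20 * 3 * log(2))
  # Bernoulli oracle at the single-SNP optimum
  k <- 19; n <- 100
  V1 <- cbind(c(rep(1, k), rep(0, n - k)))
  psi1 <- dda_params(h = qlogis(0.19), model = "dominant")
  expect_equal(penalized_loglik(psi1, V1, lambda = 0),
               n * (0.19 * log(0.19) + 0.81 * log(0.81)), tolerance = 1e-12)
  # the penalty is linear in lambda and touches J only
  J <- matrix(c(0, 0.3, 0.3, 0), 2)
  psi2 <- dda_params(h = c(0.1, -0.2), J = J, model = "dominant")
  V2 <- matrix(rbinom(40, 1, 0.5), 20, 2)
  l1 <- penalized_loglik(psi2, V2, lambda = 1)
  l2 <- penalized_loglik(psi2, V2, lambda = 2)
  expect_equal(l1 - l2, 20 * 0.5 * 0.3^2)
})

test_that("independent-SNP analytics: log odds ratios and boundaries", {
  # 2x2 log odds ratio oracle: carriers 40/100 cases vs 30/100 controls
  ec <- enc_from_carriers(30, 100, 40, 100)
  f <- fit_independent(ec$V, ec$labels, model = "dominant")
  beta <- f$psi1$H - f$psi0$H
  expect_equal(beta, log(40 * 70 / (60 * 30)), tolerance = 1e-12)
  # symmetric frequencies give zero fields
  ec2 <- enc_from_carriers(50, 100, 50, 100)
  f2 <- fit_independent(ec2$V, ec2$labels, model = "dominant")
  expect_equal(f2$psi0$H, 0)
  expect_equal(f2$psi1$H, 0)
  # boundary frequency: pseudo-count keeps fields finite and is logged
  ec3 <- enc_from_carriers(0, 50, 10, 50)
  expect_message(f3 <- fit_independent(ec3$V, ec3$labels, model = "dominant"),
                 "pseudo-count")
  expect_true(all(is.finite(f3$psi0$H)))
  # genotypic fields are log frequency ratios against the reference level
  V <- matrix(c(rep(0, 50), rep(1, 30), rep(2, 20)), ncol = 1)
  lb <- rep(c(0L, 1L), 50)
  fg <- fit_independent(V, lb, model = "genotypic")
  expect_equal(fg$psi_pooled$H, c(log(30 / 50), log(20 / 50)),
               tolerance = 1e-12)
})

test_that("independent-SNP power agrees with a simulated LR test", {
  expect_equal(power_independent(0.3, 0.3, 1000), 0.05)
  ns <- c(50, 100, 400, 1000)
  pw <- sapply(ns, function(n) power_independent(0.19, 0.4375, n))
  expect_true(all(diff(pw) > 0))
  expect_error(power_independent(0.2, 0.3, 100, alpha_level = 1.2), "alpha")
  # Monte-Carlo oracle: vectorized G tests on simulated 2x2 tables
  sim_power <- function(f0, f1, n, reps = 10000, seed = 77) {
    set.seed(seed)
    n0 <- n / 2; n1 <- n / 2
    k0 <- rbinom(reps, n0, f0); k1 <- rbinom(reps, n1, f1)
    term <- function(k, nn, fbar) {
      f <- k / nn
      out <- ifelse(k > 0, k * log(f / fbar), 0)
      out + ifelse(k < nn, (nn - k) * log((1 - f) / (1 - fbar)), 0)
    }
    fbar <- (k0 + k1) / n
    ok <- fbar > 0 & fbar < 1
    g <- 2 * (term(k0, n0, fbar) + term(k1, n1, fbar))
    mean(ok & g > qchisq(0.95, 1))
  }
  for (n in c(40, 1000)) {
    mc <- sim_power(0.19, 0.4375, n)
    se <- sqrt(mc * (1 - mc) / 10000)
    expect_lt(abs(power_independent(0.19, 0.4375, n) - mc),
              2 * se + 0.005)
  }
})

test_that("exact enumeration recovers the saturated 2-SNP closed form", {
  V <- enc_2snp_counts(40, 20, 20, 20)
  psi <- fit_ee(V, lambda = 0, model = "dominant", tol = 1e-9)
  expect_equal(psi$H, c(log(0.5), log(0.5)), tolerance = 1e-6)
  expect_equal(psi$Jbig[1, 2], log(20 * 40 / (20 * 20)), tolerance = 1e-6)
  expect_true(attr(psi, "converged"))
  # uniform state counts give the uniform model
  psi_u <- fit_ee(enc_2snp_counts(25, 25, 25, 25), lambda = 0,
                  model = "dominant")
  expect_equal(max(abs(c(psi_u$H, psi_u$Jbig))), 0, tolerance = 1e-6)
  # strong penalty drives couplings to zero and fields to the analytic limit
  set.seed(5)
  sim <- simulate_cohort(simulation_spec(m = 4, n0 = 500, n1 = 500, seed = 5))
  psi_pen <- fit_ee(sim$enc, sim$labels, lambda = 1e3, group = "case")
  ind <- fit_independent(sim$enc, sim$labels)
  expect_lt(max(abs(psi_pen$Jbig)), 1e-2)
  expect_lt(max(abs(psi_pen$H - ind$psi1$H)), 1e-2)
})

test_that("pseudo-likelihood agrees with exact enumeration and its limits", {
  V <- enc_2snp_counts(40, 20, 20, 20)
  ee <- fit_ee(V, lambda = 1e-4, model = "dominant")
  pl <- fit_pl(V, lambda = 1e-4, model = "dominant")
  expect_lt(max(abs(c(ee$H - pl$H, ee$Jbig - pl$Jbig))), 0.05)
  set.seed(6)
  sim <- simulate_cohort(simulation_spec(m = 4, n0 = 2000, n1 = 2000,
                                         seed = 6))
  pl3 <- fit_pl(sim$enc, sim$labels, lambda = 1e3, group = "control")
  ind <- fit_independent(sim$enc, sim$labels)
  expect_lt(max(abs(pl3$Jbig)), 1e-2)
  expect_lt(max(abs(pl3$H - ind$psi0$H)), 1e-2)
  expect_error(fit_pl(cbind(c(0, 1)), model = "dominant"), "m >= 2")
})

test_that("pseudo-likelihood recovers generating couplings at large n", {
  spec <- simulation_spec(m = 10, n0 = 50000, n1 = 50000, hbar = c(-1, -0.3),
                          jbar = c(0, 0.1), sigma_h = 0.2, sigma_j = 0.2,
                          seed = 13)
  sim <- simulate_cohort(spec)
  cv <- cross_validate(sim$enc, sim$labels, method = "PL",
                       grid = c(1e-4, 1e-3, 1e-2), folds = 3, seed = 2)
  psi1 <- fit_pl(sim$enc, sim$labels, lambda = cv$best_penalizer,
                 group = "case")
  lay <- ddagwas:::theta_layout(10, 1)
  j_hat <- psi1$Jbig[cbind(lay$r_idx, lay$s_idx)]
  j_true <- sim$psi1$Jbig[cbind(lay$r_idx, lay$s_idx)]
  expect_gt(cor(j_hat, j_true), 0.9)
})

test_that("mean field matches its independent and weak-coupling limits", {
  set.seed(8)
  sim <- simulate_cohort(simulation_spec(m = 4, n0 = 3000, n1 = 3000,
                                         seed = 8))
  mf0 <- fit_mf(sim$enc, sim$labels, epsilon = 0, group = "control")
  ind <- fit_independent(sim$enc, sim$labels)
  expect_equal(mf0$Jbig, matrix(0, 4, 4))
  expect_equal(mf0$H, ind$psi0$H, tolerance = 1e-12)
  # weak couplings: inversion is within 25% of the exact fit
  spec_w <- simulation_spec(m = 2, n0 = 50000, n1 = 50000, hbar = c(-0.5, -0.5),
                            jbar = c(0.08, 0.08), sigma_h = 0.1, sigma_j = 0.01,
                            seed = 14)
  sw <- simulate_cohort(spec_w)
  ee <- fit_ee(sw$enc, sw$labels, lambda = 0, group = "case")
  mf <- fit_mf(sw$enc, sw$labels, epsilon = 1, group = "case")
  expect_lt(abs(mf$Jbig[1, 2] - ee$Jbig[1, 2]) / abs(ee$Jbig[1, 2]), 0.25)
  # exactly independent columns give zero couplings at any epsilon
  V <- as.matrix(expand.grid(0:1, 0:1))[rep(1:4, 25), ]
  mfi <- fit_mf(V, epsilon = 0.7, model = "dominant")
  expect_equal(max(abs(mfi$Jbig)), 0, tolerance = 1e-10)
})

test_that("identical case and control samples collapse to the pooled fit", {
  set.seed(10)
  half <- matrix(rbinom(300, 1, 0.4), 100, 3)
  V <- rbind(half, half)
  labels <- c(rep(0L, 100), rep(1L, 100))
  for (meth in c("EE", "PL", "MF", "independent")) {
    f <- dda_fit(V, labels, method = meth, penalizer = 0.1,
                 model = "dominant")
    expect_lt(max(abs(f$psi0$H - f$psi1$H)), 1e-4)
    expect_lt(max(abs(f$psi0$Jbig - f$psi1$Jbig)), 1e-4)
    expect_lt(max(abs(f$psi0$H - f$psi_pooled$H)), 1e-4)
  }
})
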