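test_that("log-space Stirling ledger matches exact integers and identities", {
  led <- log_stirling_first(10)
  s <- stirling_exact(10)
  for (n in 1:10) {
    expect_equal(exp(led[[n]]), s[n, 1:n], tolerance = 1e-12)
    # boundary rows: s(n, 1) = (n-1)!, s(n, n) = 1
    expect_equal(led[[n]][1], lgamma(n), tolerance = 1e-12)
    expect_equal(led[[n]][n], 0)
    # row sums: sum_a s(n, a) = n!
    expect_equal(sum(exp(led[[n]])), factorial(n), tolerance = 1e-10)
  }
  expect_equal(exp(led[[4]][2]), 11, tolerance = 1e-12)
  expect_error(log_stirling_first(0), "n_max")
})

test_that("ancestry weights K(D, A) agree with brute-force enumeration", {
  for (abund in list(c(3L), c(2L, 1L), c(3L, 2L), c(4L, 2L, 1L), c(2L, 2L, 2L),
                     c(5L, 1L, 1L), c(3L, 3L, 2L, 1L))) {
    S <- length(abund)
    J <- sum(abund)
    logK <- microneutral:::logK_DA_cpp(abund)
    for (A in S:J)
      expect_equal(exp(logK[A - S + 1]), brute_force_K(abund, A),
                   tolerance = 1e-10,
                   label = paste0("K((", paste(abund, collapse = ","), "), ", A, ")"))
  }
})

test_that("two-individual community probability matches the urn history tree", {
  # D=(1,1): histories -> second individual immigrates (I/(I+1)) AND its
  # ancestor founds a new species (theta/(theta+1))
  for (theta in c(0.5, 1, 7)) for (I in c(0.5, 1, 20)) {
    expect_equal(exp(etienne_log_likelihood(community_sad(c(1, 1)), theta, I)),
                 (I / (I + 1)) * (theta / (theta + 1)), tolerance = 1e-12)
    expect_equal(exp(etienne_log_likelihood(community_sad(c(2)), theta, I)),
                 1 - (I / (I + 1)) * (theta / (theta + 1)), tolerance = 1e-12)
  }
  # a single individual is certainly one species
  expect_equal(etienne_log_likelihood(community_sad(1L), 3.2, 0.7), 0)
})

test_that("probabilities sum to one over all partitions of J", {
  for (J in c(4, 6)) {
    parts <- partitions_of(J)
    for (theta in c(0.5, 5)) for (I in c(0.5, 5)) {
      tot <- sum(vapply(parts, function(d)
        exp(etienne_log_likelihood(community_sad(d), theta, I)), numeric(1)))
      expect_equal(tot, 1, tolerance = 1e-10)
    }
  }
})

test_that("dispersal-unlimited limit reproduces the Ewens sampling formula", {
  set.seed(31)
  for (k in 1:10) {
    sad <- community_sad(microneutral:::sim_crp_cpp(runif(1, 2, 30),
                                                    sample(20:200, 1)))
    theta <- runif(1, 1, 50)
    le <- etienne_log_likelihood(sad, theta, I = 1e9)
    lw <- ewens_log_likelihood(sad, theta)
    expect_lt(abs(le - lw) / abs(lw), 1e-5)
  }
})

test_that("log-likelihood stays finite and <= 0 on overflow-prone inputs", {
  sad <- community_sad(c(1500L, rep(10L, 20), rep(1L, 60)))
  for (pars in list(c(1e-3, 1e-3), c(1e4, 1e8), c(50, 1e12))) {
    ll <- etienne_log_likelihood(sad, pars[1], pars[2])
    expect_true(is.finite(ll))
    expect_lte(ll, 0)
  }
  expect_error(etienne_log_likelihood(sad, -1, 1), "positive")
})

test_that("m and I conversions invert each other", {
  for (m in c(1e-6, 0.1, 0.5, 0.9, 1 - 1e-6)) for (J in c(10, 1676)) {
    expect_equal(m_from_I(I_from_m(m, J), J), m, tolerance = 1e-12)
  }
})

test_that("urn simulator matches exact partition probabilities at J = 3", {
  set.seed(5)
  draws <- replicate(20000,
    paste(microneutral:::sim_etienne_cpp(1, 1, 3), collapse = ","))
  obs <- table(factor(draws, levels = c("3", "2,1", "1,1,1")))
  # exact values from the likelihood (cross-validated by hand enumeration):
  # P(3) = 23/36, P(2,1) = 12/36, P(1,1,1) = 1/36
  expect_equal(
    vapply(list(3L, c(2L, 1L), c(1L, 1L, 1L)), function(d)
      exp(etienne_log_likelihood(community_sad(d), 1, 1)), numeric(1)),
    c(23, 12, 1) / 36, tolerance = 1e-12)
  gof <- chisq.test(as.numeric(obs), p = c(23, 12, 1) / 36)
  expect_gt(gof$p.value, 0.01)

  expect_equal(simulate_etienne_sample(5, 2, 1)$abundances, 1L)
  s1 <- simulate_etienne_sample(8, 10, 500, seed = 99)
  s2 <- simulate_etienne_sample(8, 10, 500, seed = 99)
  expect_identical(s1$abundances, s2$abundances)
})

test_that("mean species count increases with theta", {
  set.seed(8)
  meanS <- vapply(c(2, 20, 200), function(theta)
    mean(replicate(40, simulate_etienne_sample(theta, 50, 300)$S)), numeric(1))
  expect_true(all(diff(meanS) > 0))
})

test_that("MLE recovers theta from simulated communities and beats grid probes", {
  set.seed(21)
  th <- replicate(8, {
    sad <- simulate_etienne_sample(40, I_from_m(0.9, 2000), 2000)
    fit_etienne_mle(sad)$theta
  })
  expect_lt(abs(median(th) - 40) / 40, 0.5)

  set.seed(22)
  sad <- simulate_etienne_sample(30, I_from_m(0.9, 800), 800)
  fit <- fit_etienne_mle(sad)
  expect_lte(fit$logL, 0)
  for (theta in c(5, 30, 100)) for (m in c(0.2, 0.9)) {
    expect_gte(fit$logL + 1e-9,
               etienne_log_likelihood(sad, theta, I_from_m(m, sad$J)))
  }
})

test_that("maximized logL is invariant to the optimization parameterization", {
  set.seed(23)
  sad <- simulate_etienne_sample(20, I_from_m(0.8, 400), 400)
  fit <- fit_etienne_mle(sad)
  # independent optimization over (log theta, log I) of the same objective
  obj <- function(par) -etienne_log_likelihood(sad, exp(par[1]), exp(par[2]))
  alt <- optim(c(log(20), log(10)), obj, method = "Nelder-Mead",
               control = list(reltol = 1e-12, maxit = 3000))
  alt2 <- optim(c(log(5), log(1000)), obj, method = "Nelder-Mead",
                control = list(reltol = 1e-12, maxit = 3000))
  expect_lt(abs(fit$logL - max(-alt$value, -alt2$value)), 1e-4)
})

test_that("boundary communities are flagged", {
  expect_warning(fit_etienne_mle(community_sad(c(9L))), "S = 1")
  expect_warning(fit_etienne_mle(community_sad(rep(1L, 6))), "singleton")
})

test_that("deviation statistic reproduces worked values and behaves monotonely", {
  d1 <- deviation_statistic(-86.334, -85.809)
  expect_equal(d1$q, 1.050, tolerance = 1e-9)
  expect_equal(d1$p, pchisq(1.050, 1, lower.tail = FALSE))
  d2 <- deviation_statistic(-110.238, -108.549)
  expect_equal(d2$q, 3.378, tolerance = 1e-9)
  dd <- deviation_statistic(-4.2, -4.2)
  expect_equal(dd$q, 0)
  expect_equal(dd$p, 1)
  qs <- seq(0, 10, by = 0.5)
  ps <- pchisq(qs, 1, lower.tail = FALSE)
  expect_true(all(diff(ps) < 0))
  expect_error(deviation_statistic(NA, -1), "finite")
})

test_that("exact neutrality test is reproducible and internally consistent", {
  set.seed(77)
  sad <- simulate_etienne_sample(15, I_from_m(0.7, 300), 300)
  r1 <- exact_neutrality_test(sad, n_sim = 25, seed = 123)
  r2 <- exact_neutrality_test(sad, n_sim = 25, seed = 123)
  expect_identical(r1$sim_logL, r2$sim_logL)
  expect_identical(r1$p, r2$p)
  expect_equal(r1$q, 2 * abs(r1$logL1 - r1$logL0))
  expect_equal(r1$logL1, mean(r1$sim_logL))
  # the arithmetic-mean-likelihood variant dominates the log mean
  expect_gte(r1$logL1_arith, r1$logL1)
  expect_identical(r1$pass, r1$p > 0.05)
  expect_error(exact_neutrality_test(sad, n_sim = 1), "n_sim")
})
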