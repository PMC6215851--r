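test_that("transition probabilities sum to one and obey boundary cases", {
  grid <- expand.grid(N_i = c(0, 1, 7, 100, 199, 200), N_T = 200,
                      m = c(0, 0.1, 0.5, 1), p_i = c(0, 0.3, 1))
  pr <- transition_probabilities(grid$N_i, grid$N_T, grid$m, grid$p_i)
  expect_true(all(pr$up >= 0 & pr$up <= 1))
  expect_true(all(pr$down >= 0 & pr$down <= 1))
  expect_true(all(pr$stay >= 0 & pr$stay <= 1))
  expect_equal(pr$up + pr$stay + pr$down, rep(1, nrow(grid)))

  at0 <- transition_probabilities(0, 150, 0.2, 0.4)
  expect_equal(at0$down, 0)
  expect_equal(at0$up, 0.2 * 0.4 * (150 / 150))
  atN <- transition_probabilities(150, 150, 0.2, 0.4)
  expect_equal(atN$up, 0)
  expect_error(transition_probabilities(-1, 100, 0.5, 0.5), "N_i")
})

test_that("abundance chain is seeded-reproducible and immigration-dominated at m = 1", {
  t1 <- simulate_sloan_dynamics(100, 0.3, 0.2, 5000, seed = 4)
  t2 <- simulate_sloan_dynamics(100, 0.3, 0.2, 5000, seed = 4)
  expect_identical(t1, t2)

  # pure immigration: x concentrates at p_i
  tr <- simulate_sloan_dynamics(100, 1, 0.35, 2e5, seed = 9)
  x <- tr[5e4:2e5] / 100
  se <- sd(x) / sqrt(length(x) / 100)  # generous effective-n correction
  expect_lt(abs(mean(x) - 0.35), 3 * max(se, 0.005))
})

test_that("chain stationary distribution matches the beta law", {
  traj <- simulate_sloan_dynamics(200, 0.1, 0.3, 1.2e6, seed = 42)
  idx <- seq(2e5 + 1, 1.2e6, by = 1e4)  # thinned past the relaxation time
  set.seed(42)
  x <- (traj[idx] + runif(length(idx)) - 0.5) / 200  # dither the lattice
  ks <- ks.test(x, function(q) pbeta(q, 200 * 0.1 * 0.3, 200 * 0.1 * 0.7))
  expect_gt(ks$p.value, 0.01)
})

test_that("stationary beta density is a proper, correctly-shaped density", {
  f <- function(x) beta_density(x, N_T = 100, m = 0.2, p_i = 0.2)
  expect_equal(integrate(f, 0, 1)$value, 1, tolerance = 1e-8)
  expect_equal(integrate(function(x) x * f(x), 0, 1)$value, 0.2,
               tolerance = 1e-6)
  xs <- seq(0.05, 0.45, by = 0.05)
  sym <- beta_density(xs, 50, 0.3, 0.5) - beta_density(1 - xs, 50, 0.3, 0.5)
  expect_equal(sym, rep(0, length(xs)), tolerance = 1e-10)
  expect_error(beta_density(0.5, 100, 0, 0.5), "positive")
})

test_that("occurrence statistics implement the n/N definition", {
  counts <- rbind(c(10L, 0L, 5L), c(8L, 1L, 0L), c(12L, 2L, 0L))
  tab <- otu_table(matrix(counts, 3, dimnames = list(paste0("d", 1:3),
                                                     c("t1", "t2", "t3"))))
  st <- occurrence_stats(tab, source_samples = rownames(tab),
                         dest_samples = rownames(tab))
  expect_equal(unname(st$x[["t1"]]), 1)       # present everywhere
  expect_equal(unname(st$x[["t2"]]), 2 / 3)   # detected in 2 of 3
  expect_equal(unname(st$x[["t3"]]), 1 / 3)
  expect_equal(st$N_T, as.integer(round(mean(rowSums(counts)))))
  expect_equal(sum(st$p), 1, tolerance = 1e-12)
  expect_error(occurrence_stats(tab, character(0), rownames(tab)), "non-empty")
})

test_that("fit_sloan recovers an exactly model-generated occurrence curve", {
  N_T <- 800
  d <- 1 / N_T
  p <- exp(seq(log(1e-4), log(0.2), length.out = 80))
  p <- p / sum(p)
  m_star <- 0.2
  x <- pbeta(d, N_T * m_star * p, N_T * m_star * (1 - p), lower.tail = FALSE)
  fit <- fit_sloan(p, x, N_T, n_dest_samples = 50, detection_threshold = d)
  expect_lt(abs(fit$m_hat - m_star), 1e-4)
  expect_equal(fit$R2, 1, tolerance = 1e-6)
  expect_equal(fit$pct_neutral, 100)

  # objective at m_hat beats a grid audit
  sse <- function(m) sum((x - pbeta(d, N_T * m * p, N_T * m * (1 - p),
                                    lower.tail = FALSE))^2)
  for (m in seq(0.05, 0.95, by = 0.1))
    expect_lte(sse(fit$m_hat), sse(m) + 1e-12)
})

test_that("classification is total, exclusive and order-invariant", {
  set.seed(14)
  des <- synthetic_design(n_groups = 1, samples_per_group = 30, J = 500,
                          mode = "sloan_neutral", theta = 20, m = 0.2, seed = 14)
  dat <- generate_neutral_dataset(des)
  ids <- rownames(dat$table)
  st <- occurrence_stats(dat$table, ids, ids)
  fit <- fit_sloan(st$p, st$x, st$N_T, st$n_dest,
                   detection_threshold = st$detection_threshold)
  expect_true(all(fit$species$classification %in% c("neutral", "above", "below")))
  expect_equal(fit$pct_neutral + fit$pct_above + fit$pct_below, 100,
               tolerance = 1e-9)
  expect_true(all(fit$species$ci_low <= fit$species$predicted_freq &
                  fit$species$predicted_freq <= fit$species$ci_high))
  # permuting taxa does not change the percentages
  perm <- sample(length(st$p))
  fit2 <- fit_sloan(st$p[perm], st$x[perm], st$N_T, st$n_dest,
                    detection_threshold = st$detection_threshold)
  expect_equal(fit2$pct_neutral, fit$pct_neutral)
  expect_equal(fit2$m_hat, fit$m_hat, tolerance = 1e-9)

  expect_warning(fit_sloan(c(0.4, 0.6), c(1, 1), 100, 10), "identical")
})

test_that("resampled analysis is seed-stable and degenerates sensibly at 1 repeat", {
  set.seed(3)
  des <- synthetic_design(n_groups = 2, samples_per_group = 20, J = 400,
                          mode = "sloan_neutral", theta = 15, m = 0.2, seed = 3)
  dat <- generate_neutral_dataset(des)
  a <- resampled_sloan_analysis(dat$table, dat$groups, "lean", "obese",
                                n_per_group = 12, n_repeats = 3, seed = 7)
  b <- resampled_sloan_analysis(dat$table, dat$groups, "lean", "obese",
                                n_per_group = 12, n_repeats = 3, seed = 7)
  expect_identical(a$summary, b$summary)
  expect_identical(a$repeats, b$repeats)

  one <- resampled_sloan_analysis(dat$table, dat$groups, "lean", "lean",
                                  n_per_group = 12, n_repeats = 1, seed = 7)
  expect_equal(one$summary$m_sd, 0)
  expect_equal(one$summary$pct_neutral_sd, 0)
  expect_error(
    resampled_sloan_analysis(dat$table, dat$groups, "martian", "lean",
                             n_per_group = 5, n_repeats = 1, seed = 1),
    "source group")
})
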