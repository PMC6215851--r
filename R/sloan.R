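#' One-step transition probabilities of the local-community birth/death chain
#'
#' In the continuous neutral model the local (destination) community is
#' saturated at N_T individuals; at each expected death the focal species
#' with current abundance N_i gains one individual, stays, or loses one:
#' \deqn{P_{up} = \frac{N_T - N_i}{N_T}\left[m p_i + (1-m)\frac{N_i}{N_T-1}\right]}
#' \deqn{P_{down} = \frac{N_i}{N_T}\left[m (1-p_i) + (1-m)\frac{N_T-N_i}{N_T-1}\right]}
#' with \eqn{P_{stay} = 1 - P_{up} - P_{down}} so the three always sum to one.
#' p_i is the species' relative abundance in the source community and m the
#' immigration probability. All arguments are vectorized.
#'
#' @param N_i Current abundance of the focal species, 0..N_T.
#' @param N_T Local community size (>= 2).
#' @param m Immigration probability in [0, 1].
#' @param p_i Source relative abundance in [0, 1].
#' @return List with numeric vectors `up`, `stay`, `down`.
#' @export
transition_probabilities <- function(N_i, N_T, m, p_i) {
  if (any(N_i < 0 | N_i > N_T)) stop("N_i must lie in [0, N_T]")
  if (any(N_T < 2)) stop("N_T must be >= 2")
  if (any(m < 0 | m > 1) || any(p_i < 0 | p_i > 1))
    stop("m and p_i must lie in [0, 1]")
  up <- ((N_T - N_i) / N_T) * (m * p_i + (1 - m) * N_i / (N_T - 1))
  down <- (N_i / N_T) * (m * (1 - p_i) + (1 - m) * (N_T - N_i) / (N_T - 1))
  list(up = up, stay = 1 - up - down, down = down)
}

#' Simulate the local-community abundance chain for one species
#'
#' Markov chain on N_i in {0, ..., N_T} with the transition kernel of
#' [transition_probabilities], one step per expected death (time unit
#' 1/delta; the death rate only sets the clock and is irrelevant at
#' stationarity). At stationarity the relative abundance x = N_i/N_T follows
#' Beta(N_T m p_i, N_T m (1 - p_i)).
#'
#' @param N_T Local community size.
#' @param m Immigration probability.
#' @param p_i Source relative abundance of the focal species.
#' @param n_steps Number of steps.
#' @param N0 Initial abundance (default: round(N_T p_i)).
#' @param seed Optional integer seed.
#' @return Integer vector of abundances after each step.
#' @export
simulate_sloan_dynamics <- function(N_T, m, p_i, n_steps,
                                    N0 = round(N_T * p_i), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  sim_sloan_chain_cpp(as.integer(N0), as.integer(N_T), m, p_i,
                      as.integer(n_steps))
}

#' Stationary beta density of the relative abundance
#'
#' Density of x = N_i/N_T at stationarity of the birth/death/immigration
#' chain: Beta(N_T m p_i, N_T m (1 - p_i)).
#'
#' @param x Relative abundance in (0, 1).
#' @inheritParams transition_probabilities
#' @return Density values.
#' @export
beta_density <- function(x, N_T, m, p_i) {
  a <- N_T * m * p_i
  b <- N_T * m * (1 - p_i)
  if (any(a <= 0) || any(b <= 0)) stop("beta shape parameters must be positive")
  stats::dbeta(x, a, b)
}

#' Source abundances and destination occurrence frequencies
#'
#' For a source -> destination design: p_i is the mean relative abundance of
#' taxon i across the source samples; x_i is the fraction of destination
#' samples in which taxon i's relative abundance reaches the detection
#' threshold d; N_T is the rounded mean read depth of the destination
#' samples. Taxa absent from both sample sets are dropped.
#'
#' @param table An [otu_table].
#' @param source_samples,dest_samples Character vectors of sample ids.
#' @param detection_threshold Relative-abundance detection limit d in
#'   [0, 1); default `NULL` means 1/N_T (one read in an average-depth
#'   sample). Detection is `relative abundance >= d`.
#' @return List with `p`, `x` (named numeric vectors over retained taxa),
#'   `N_T`, `detection_threshold`, `n_dest` (number of destination samples),
#'   `taxon_ids`.
#' @export
occurrence_stats <- function(table, source_samples, dest_samples,
                             detection_threshold = NULL) {
  stopifnot(inherits(table, "otu_table"))
  if (!length(source_samples) || !length(dest_samples))
    stop("source and destination sample sets must be non-empty")
  missing <- setdiff(c(source_samples, dest_samples), rownames(table))
  if (length(missing))
    stop("unknown samples: ", paste(utils::head(missing, 5), collapse = ", "))
  cnt <- unclass(table)
  src <- cnt[source_samples, , drop = FALSE]
  dst <- cnt[dest_samples, , drop = FALSE]
  src_rel <- src / rowSums(src)
  dst_rel <- dst / rowSums(dst)
  N_T <- as.integer(round(mean(rowSums(dst))))
  d <- if (is.null(detection_threshold)) 1 / N_T else detection_threshold
  if (d < 0 || d >= 1) stop("detection_threshold must lie in [0, 1)")
  keep <- colSums(src) > 0 | colSums(dst) > 0
  p <- colMeans(src_rel)[keep]
  x <- colMeans(dst_rel[, keep, drop = FALSE] >= d)
  list(p = p, x = x, N_T = N_T, detection_threshold = d,
       n_dest = length(dest_samples), taxon_ids = colnames(cnt)[keep])
}

wilson_interval <- function(f, n, conf = 0.95) {
  z <- stats::qnorm(1 - (1 - conf) / 2)
  den <- 1 + z^2 / n
  center <- (f + z^2 / (2 * n)) / den
  half <- (z / den) * sqrt(f * (1 - f) / n + z^2 / (4 * n^2))
  list(low = pmax(0, center - half), high = pmin(1, center + half))
}

exact_binomial_interval <- function(f, n, conf = 0.95) {
  a <- (1 - conf) / 2
  k <- f * n
  low <- ifelse(k <= 0, 0, stats::qbeta(a, k, n - k + 1))
  high <- ifelse(k >= n, 1, stats::qbeta(1 - a, k + 1, n - k))
  list(low = low, high = high)
}

#' Fit the continuous neutral model to occurrence frequencies
#'
#' The model predicts the probability that taxon i is detected (relative
#' abundance >= d) in a destination sample as the upper tail of its
#' stationary beta law: F_i(m) = 1 - BetaCDF(d; N_T m p_i, N_T m (1 - p_i)).
#' The single migration parameter m is fitted by bounded least squares
#' against the observed occurrence frequencies x_i; R^2 is the coefficient
#' of determination of the fitted curve. Each taxon is then classified as
#' neutral / above / below according to whether x_i falls inside a 95%
#' sampling interval around its predicted frequency (binomial over the
#' n destination samples; Wilson score interval by default).
#'
#' @param p Named vector of source relative abundances.
#' @param x Named vector of observed destination occurrence frequencies,
#'   aligned with `p`.
#' @param N_T Destination community size (mean reads per sample).
#' @param n_dest_samples Number of destination samples behind each x_i.
#' @param detection_threshold Relative-abundance detection limit d; default
#'   1/N_T.
#' @param ci_method `"wilson"` (default) or `"exact"` binomial intervals.
#' @param conf Interval coverage (default 0.95).
#' @return A `sloan_fit`: list with `m_hat`, `R2`, `N_T`,
#'   `detection_threshold`, `species` (tibble: taxon_id, p_i, x_i,
#'   predicted_freq, ci_low, ci_high, classification), `pct_neutral`,
#'   `pct_above`, `pct_below`, `n_species_total`, `converged`.
#' @export
fit_sloan <- function(p, x, N_T, n_dest_samples,
                      detection_threshold = NULL,
                      ci_method = c("wilson", "exact"), conf = 0.95) {
  ci_method <- match.arg(ci_method)
  if (length(p) != length(x)) stop("p and x must be aligned")
  d <- if (is.null(detection_threshold)) 1 / N_T else detection_threshold
  usable <- p > 0
  pu <- p[usable]
  xu <- x[usable]
  pred_freq <- function(m) {
    stats::pbeta(d, N_T * m * pu, N_T * m * (1 - pu), lower.tail = FALSE)
  }
  sse <- function(m) sum((xu - pred_freq(m))^2)
  opt <- stats::optimize(sse, interval = c(1e-6, 1 - 1e-6), tol = 1e-8)
  m_hat <- opt$minimum
  fitted <- pred_freq(m_hat)
  ss_tot <- sum((xu - mean(xu))^2)
  if (ss_tot == 0) {
    warning("all occurrence frequencies identical; R^2 undefined")
    R2 <- NaN
  } else {
    R2 <- 1 - opt$objective / ss_tot
  }
  ci <- switch(ci_method,
               wilson = wilson_interval(fitted, n_dest_samples, conf),
               exact = exact_binomial_interval(fitted, n_dest_samples, conf))
  cls <- ifelse(xu > ci$high, "above", ifelse(xu < ci$low, "below", "neutral"))
  species <- tibble::tibble(
    taxon_id = if (is.null(names(pu))) as.character(seq_along(pu)) else names(pu),
    p_i = unname(pu),
    x_i = unname(xu),
    predicted_freq = unname(fitted),
    ci_low = unname(ci$low),
    ci_high = unname(ci$high),
    classification = unname(cls))
  n_tot <- nrow(species)
  structure(list(m_hat = m_hat,
                 R2 = R2,
                 N_T = N_T,
                 detection_threshold = d,
                 species = species,
                 pct_neutral = 100 * mean(cls == "neutral"),
                 pct_above = 100 * mean(cls == "above"),
                 pct_below = 100 * mean(cls == "below"),
                 n_species_total = n_tot,
                 ci_method = ci_method,
                 converged = TRUE),
            class = "sloan_fit")
}

#' @export
print.sloan_fit <- function(x, ...) {
  cat(sprintf(
    "Continuous neutral-model fit: m = %.4f, R2 = %.3f, N_T = %d, %d taxa\n",
    x$m_hat, x$R2, x$N_T, x$n_species_total))
  cat(sprintf("  neutral %.1f%% | above %.1f%% | below %.1f%%  (d = %.3g, %s CI)\n",
              x$pct_neutral, x$pct_above, x$pct_below,
              x$detection_threshold, x$ci_method))
  invisible(x)
}

#' Balanced resampled species-level neutrality analysis
#'
#' Repeats the source -> destination occurrence fit on random balanced
#' subsamples: each repeat draws `n_per_group` samples from the source group
#' and (for cross-group designs) `n_per_group` from the destination group,
#' runs [occurrence_stats] and [fit_sloan], and the per-repeat results are
#' averaged. For a same-group design (source == destination) the single draw
#' serves as both source and destination. Per-repeat seeds are derived
#' deterministically from the master seed.
#'
#' @param table An [otu_table].
#' @param groups Group map (data frame: `sample_id`, `group`).
#' @param source_label,dest_label Group labels.
#' @param n_per_group Samples drawn per group per repeat (default 50). If a
#'   group has fewer samples, sampling is with replacement and flagged.
#' @param n_repeats Number of repeats (default 30).
#' @param seed Master seed.
#' @param detection_threshold,ci_method Passed to [fit_sloan].
#' @return A `sloan_resample`: list with `summary` (one-row tibble: source,
#'   dest, N, m, R2, total, pct_neutral, pct_nonneutral and their SDs),
#'   `repeats` (per-repeat tibble), `last_fit` (the final repeat's
#'   `sloan_fit`, for per-taxon inspection).
#' @export
resampled_sloan_analysis <- function(table, groups, source_label, dest_label,
                                     n_per_group = 50, n_repeats = 30,
                                     seed = NULL,
                                     detection_threshold = NULL,
                                     ci_method = "wilson") {
  groups <- validate_group_map(groups, table)
  src_pool <- groups$sample_id[groups$group == source_label]
  dst_pool <- groups$sample_id[groups$group == dest_label]
  if (!length(src_pool)) stop("unknown or empty source group '", source_label, "'")
  if (!length(dst_pool)) stop("unknown or empty destination group '", dest_label, "'")
  same_group <- identical(source_label, dest_label)
  replace_src <- length(src_pool) < n_per_group
  replace_dst <- length(dst_pool) < n_per_group
  if (replace_src || replace_dst)
    warning("group smaller than n_per_group; sampling with replacement")
  if (is.null(seed)) seed <- sample.int(1e6, 1)
  reps <- vector("list", n_repeats)
  last_fit <- NULL
  for (r in seq_len(n_repeats)) {
    set.seed(seed + r)
    src <- sample(src_pool, n_per_group, replace = replace_src)
    dst <- if (same_group) src
           else sample(dst_pool, n_per_group, replace = replace_dst)
    st <- occurrence_stats(table, src, dst, detection_threshold)
    fit <- fit_sloan(st$p, st$x, st$N_T, st$n_dest,
                     detection_threshold = st$detection_threshold,
                     ci_method = ci_method)
    last_fit <- fit
    reps[[r]] <- tibble::tibble(
      repeat_id = r, N = st$N_T, m = fit$m_hat, R2 = fit$R2,
      total = fit$n_species_total,
      pct_neutral = fit$pct_neutral,
      pct_nonneutral = fit$pct_above + fit$pct_below)
  }
  reps <- do.call(rbind, reps)
  sd0 <- function(v) if (n_repeats > 1) stats::sd(v) else 0
  summary <- tibble::tibble(
    source = source_label, dest = dest_label,
    N = mean(reps$N), m = mean(reps$m), R2 = mean(reps$R2),
    total = mean(reps$total),
    pct_neutral = mean(reps$pct_neutral),
    pct_nonneutral = mean(reps$pct_nonneutral),
    N_sd = sd0(reps$N), m_sd = sd0(reps$m), R2_sd = sd0(reps$R2),
    total_sd = sd0(reps$total),
    pct_neutral_sd = sd0(reps$pct_neutral),
    pct_nonneutral_sd = sd0(reps$pct_nonneutral))
  structure(list(summary = summary, repeats = reps, last_fit = last_fit,
                 seed = seed, n_per_group = n_per_group,
                 n_repeats = n_repeats),
            class = "sloan_resample")
}

#' @export
print.sloan_resample <- function(x, ...) {
  s <- x$summary
  cat(sprintf("%s -> %s (%d repeats x %d samples/group):\n",
              s$source, s$dest, x$n_repeats, x$n_per_group))
  cat(sprintf("  N = %.0f, m = %.4f +- %.4f, R2 = %.3f, neutral %.1f%% +- %.1f%%\n",
              s$N, s$m, s$m_sd, s$R2, s$pct_neutral, s$pct_neutral_sd))
  invisible(x)
}

#' Compare the neutral-species percentage between two resampled designs
#'
#' Unpaired t-test on the per-repeat percentages of neutral taxa from two
#' [resampled_sloan_analysis] runs (e.g. lean->lean vs obese->obese). A
#' large p-value means no detectable difference in species-level neutrality
#' between the designs.
#'
#' @param a,b `sloan_resample` objects.
#' @return An object of class `htest` from [stats::t.test].
#' @export
pct_neutral_ttest <- function(a, b) {
  stopifnot(inherits(a, "sloan_resample"), inherits(b, "sloan_resample"))
  stats::t.test(a$repeats$pct_neutral, b$repeats$pct_neutral)
}
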