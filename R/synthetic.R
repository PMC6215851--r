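#' Draw a log-series-like metacommunity from the neutral point process
#'
#' Samples a metacommunity of `J_meta` individuals by the Ewens/Chinese-
#' restaurant urn with fundamental biodiversity number theta (each arrival
#' founds a new species with probability theta/(theta + j - 1)) and returns
#' the normalized relative abundances. For large J_meta the abundance
#' distribution approaches the log-series that neutral theory predicts for
#' the regional pool.
#'
#' @param theta Fundamental biodiversity number, > 0.
#' @param J_meta Metacommunity size in individuals (default 1e5).
#' @param seed Optional integer seed.
#' @return Named numeric vector of relative abundances (sums to 1), named
#'   `mtaxon_1`, ... in decreasing order.
#' @export
logseries_metacommunity <- function(theta, J_meta = 1e5, seed = NULL) {
  if (!(theta > 0) || J_meta < 1) stop("theta > 0 and J_meta >= 1 required")
  if (!is.null(seed)) set.seed(seed)
  counts <- sim_crp_cpp(theta, as.integer(J_meta))
  p <- counts / sum(counts)
  names(p) <- paste0("mtaxon_", seq_along(p))
  p
}

#' Describe a synthetic multi-sample study design
#'
#' Ground-truth parameters for a generated two-group OTU dataset emulating a
#' human gut 16S study: tens of samples per group, per-sample read depths in
#' the thousands, one to a few hundred taxa. Three generative modes:
#' `"etienne_neutral"` (each sample an independent draw of the
#' dispersal-limited urn), `"sloan_neutral"` (per-taxon beta-distributed
#' relative abundances around a shared source pool, multinomial reads) and
#' `"niche"` (deterministic per-taxon environmental responses plus an
#' optional group-level composition shift).
#'
#' @param n_groups Number of host groups (default 2).
#' @param samples_per_group Samples per group (default 30).
#' @param J Nominal reads per sample (default 1000).
#' @param depth_variation `"uniform"` (depths drawn uniformly from
#'   [0.5 J, 1.5 J], emulating real depth heterogeneity) or `"fixed"`.
#' @param mode Generative mode (see above).
#' @param theta Fundamental biodiversity number of the pool (default 30).
#' @param m Immigration probability (default 0.9 — high, as fitted gut
#'   communities are barely dispersal-limited).
#' @param metacommunity Optional relative-abundance vector for the source
#'   pool; default drawn by [logseries_metacommunity] at `theta`.
#' @param selection_strength Niche mode: scale of the per-taxon-by-sample
#'   environmental response (0 reduces to neutral multinomial sampling).
#' @param group_effect Niche mode: optional list
#'   `list(taxa = <ids or count>, factor = <multiplier>, group = <label>)`
#'   multiplying a taxon subset's weights in one group (a
#'   Firmicutes/Bacteroidetes-ratio-style shift).
#' @param group_labels Labels, default `c("lean", "obese", "overweight")`
#'   truncated to `n_groups`.
#' @param seed Integer seed; every generator is a pure function of
#'   (design, seed).
#' @return A `synthetic_design` list.
#' @export
synthetic_design <- function(n_groups = 2, samples_per_group = 30, J = 1000,
                             depth_variation = c("uniform", "fixed"),
                             mode = c("etienne_neutral", "sloan_neutral", "niche"),
                             theta = 30, m = 0.9,
                             metacommunity = NULL,
                             selection_strength = 0,
                             group_effect = NULL,
                             group_labels = c("lean", "obese", "overweight"),
                             seed = 1L) {
  mode <- match.arg(mode)
  depth_variation <- match.arg(depth_variation)
  stopifnot(n_groups >= 1, samples_per_group >= 1, J >= 1,
            theta > 0, m > 0, m < 1, selection_strength >= 0)
  if (!is.null(metacommunity)) {
    if (abs(sum(metacommunity) - 1) > 1e-8)
      stop("metacommunity must sum to 1")
  }
  structure(list(n_groups = n_groups,
                 samples_per_group = samples_per_group,
                 J = J,
                 depth_variation = depth_variation,
                 mode = mode,
                 theta = theta,
                 m = m,
                 metacommunity = metacommunity,
                 selection_strength = selection_strength,
                 group_effect = group_effect,
                 group_labels = rep_len(group_labels, n_groups),
                 seed = as.integer(seed)),
            class = "synthetic_design")
}

design_depths <- function(design, n) {
  if (design$depth_variation == "fixed") rep(as.integer(design$J), n)
  else as.integer(round(stats::runif(n, 0.5 * design$J, 1.5 * design$J)))
}

design_groups <- function(design) {
  labels <- design$group_labels
  tibble::tibble(
    sample_id = paste0("s", seq_len(design$n_groups * design$samples_per_group)),
    group = rep(labels, each = design$samples_per_group))
}

design_metacommunity <- function(design) {
  if (!is.null(design$metacommunity)) return(design$metacommunity)
  logseries_metacommunity(design$theta, 1e5)
}

#' Generate a neutral multi-sample OTU dataset with known ground truth
#'
#' Two routes, each the matched positive control for one neutrality test:
#' \describe{
#'   \item{etienne_neutral}{every sample is an independent draw of the
#'     sequential urn at (theta, I(m, J_s), J_s); species of each draw are
#'     mapped onto a shared taxon pool (a weighted draw without replacement
#'     from the metacommunity) so samples share taxon identifiers. The SAD
#'     of each sample is exactly Etienne-distributed.}
#'   \item{sloan_neutral}{each taxon's per-sample relative abundance is
#'     drawn from its stationary law Beta(N_T m p_i, N_T m (1 - p_i)) with
#'     N_T = J, then reads are multinomial at the sample depth.}
#' }
#'
#' @param design A [synthetic_design] with a neutral `mode`.
#' @return List with `table` ([otu_table]), `groups` (tibble), `truth`
#'   (list of the generative parameters, including the metacommunity).
#' @export
generate_neutral_dataset <- function(design) {
  stopifnot(inherits(design, "synthetic_design"))
  if (!design$mode %in% c("etienne_neutral", "sloan_neutral"))
    stop("design mode must be etienne_neutral or sloan_neutral")
  set.seed(design$seed)
  groups <- design_groups(design)
  n <- nrow(groups)
  depths <- design_depths(design, n)
  p <- design_metacommunity(design)
  if (design$mode == "etienne_neutral") {
    sads <- vector("list", n)
    taxa_per_sample <- vector("list", n)
    for (s in seq_len(n)) {
      I <- I_from_m(design$m, depths[s])
      ab <- sim_etienne_cpp(design$theta, I, depths[s])
      sads[[s]] <- ab
      # label species by a weighted draw without replacement from the pool;
      # labelling only — the per-sample SAD is untouched
      if (length(ab) > length(p))
        stop("metacommunity has fewer taxa than a sample's species count; ",
             "supply a larger metacommunity")
      taxa_per_sample[[s]] <- sample(names(p), length(ab), prob = p)
    }
    all_taxa <- sort(unique(unlist(taxa_per_sample)))
    counts <- matrix(0L, n, length(all_taxa),
                     dimnames = list(groups$sample_id, all_taxa))
    for (s in seq_len(n))
      counts[s, taxa_per_sample[[s]]] <- sads[[s]]
  } else {
    N_T <- design$J
    a <- N_T * design$m * p
    b <- N_T * design$m * (1 - p)
    counts <- matrix(0L, n, length(p),
                     dimnames = list(groups$sample_id, names(p)))
    for (s in seq_len(n)) {
      xs <- stats::rbeta(length(p), a, b)
      counts[s, ] <- as.integer(stats::rmultinom(1, depths[s], xs / sum(xs)))
    }
  }
  keep <- colSums(counts) > 0
  table <- otu_table(counts[, keep, drop = FALSE])
  list(table = table, groups = groups,
       truth = list(mode = design$mode, theta = design$theta, m = design$m,
                    J = design$J, metacommunity = p, seed = design$seed))
}

#' Generate a niche-structured (non-neutral) OTU dataset
#'
#' Deterministic assembly negative control: per-sample taxon weights are
#' `metacommunity * exp(selection_strength * r_i * e_s)` with fixed
#' per-taxon environmental responses r_i ~ N(0,1) and per-sample
#' environments e_s ~ N(0,1), optionally multiplied by a group-specific
#' factor on a designated taxon subset; reads are multinomial at the sample
#' depth. With `selection_strength = 0` and no group effect this reduces to
#' plain multinomial sampling of the shared pool.
#'
#' @param design A [synthetic_design] with `mode = "niche"`.
#' @return As [generate_neutral_dataset]; `truth` additionally records the
#'   responses, environments and group effect.
#' @export
generate_niche_dataset <- function(design) {
  stopifnot(inherits(design, "synthetic_design"))
  if (design$mode != "niche") stop("design mode must be 'niche'")
  set.seed(design$seed)
  groups <- design_groups(design)
  n <- nrow(groups)
  depths <- design_depths(design, n)
  p <- design_metacommunity(design)
  S <- length(p)
  r <- stats::rnorm(S)
  e <- stats::rnorm(n)
  ge <- design$group_effect
  ge_taxa <- character(0)
  if (!is.null(ge)) {
    ge_taxa <- if (is.numeric(ge$taxa) && length(ge$taxa) == 1)
      names(p)[seq_len(min(ge$taxa, S))] else intersect(as.character(ge$taxa), names(p))
    if (!length(ge_taxa)) stop("group_effect taxa not found in metacommunity")
  }
  counts <- matrix(0L, n, S, dimnames = list(groups$sample_id, names(p)))
  for (s in seq_len(n)) {
    w <- p * exp(design$selection_strength * r * e[s])
    if (length(ge_taxa) && groups$group[s] == ge$group)
      w[ge_taxa] <- w[ge_taxa] * ge$factor
    counts[s, ] <- as.integer(stats::rmultinom(1, depths[s], w / sum(w)))
  }
  keep <- colSums(counts) > 0
  table <- otu_table(counts[, keep, drop = FALSE])
  list(table = table, groups = groups,
       truth = list(mode = "niche", theta = design$theta,
                    selection_strength = design$selection_strength,
                    responses = r, environments = e,
                    group_effect = ge, group_effect_taxa = ge_taxa,
                    metacommunity = p, seed = design$seed))
}
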