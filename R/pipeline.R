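#' Configuration for the cross-scale neutrality analysis
#'
#' Bundles data paths (or in-memory objects), the community-scale and
#' species-scale settings and the master seed. Every threshold the analysis
#' uses is visible here with the canonical defaults: alpha = 0.05 for the
#' exact community test, 100 artificial communities per test, 50 samples per
#' group x 30 repeats for the species-scale resampling, and an R^2 pass
#' threshold of 0.5 for the continuous-model fit.
#'
#' @param table An [otu_table], or a path to read one from.
#' @param groups Group map (data frame or path), required for the
#'   species-scale stage.
#' @param community List: `enabled`, `n_sim`, `alpha`, `max_samples`
#'   (optional cap on the number of samples tested).
#' @param species List: `designs` (list of `c(source, dest)` pairs;
#'   default all same-group designs plus lean->obese when both exist,
#'   excluding any "overweight" group), `n_per_group`, `n_repeats`,
#'   `detection_threshold`, `R2_pass`, `ci_method`.
#' @param seed Master seed.
#' @param out_dir Output directory for [run_analysis].
#' @return An `analysis_config` list.
#' @export
analysis_config <- function(table, groups = NULL,
                            community = list(),
                            species = list(),
                            seed = 1L, out_dir = NULL) {
  if (is.character(table)) table <- read_otu_table(table)
  if (is.character(groups)) groups <- read_group_map(groups, table)
  if (!is.null(groups)) groups <- validate_group_map(groups, table)
  community <- utils::modifyList(
    list(enabled = TRUE, n_sim = 100, alpha = 0.05, max_samples = NULL),
    community)
  species <- utils::modifyList(
    list(designs = NULL, n_per_group = 50, n_repeats = 30,
         detection_threshold = NULL, R2_pass = 0.5, ci_method = "wilson"),
    species)
  stopifnot(community$alpha > 0, community$alpha < 1)
  if (is.null(species$designs) && !is.null(groups)) {
    labs <- setdiff(unique(groups$group), "overweight")
    designs <- lapply(labs, function(g) c(g, g))
    if (all(c("lean", "obese") %in% labs))
      designs <- c(designs, list(c("lean", "obese")))
    species$designs <- designs
  }
  if (!is.null(groups))
    for (d in species$designs)
      if (!all(d %in% groups$group))
        stop("design references undeclared group: ", paste(d, collapse = " -> "))
  structure(list(table = table, groups = groups, community = community,
                 species = species, seed = as.integer(seed),
                 out_dir = out_dir),
            class = "analysis_config")
}

#' Community-scale neutrality report
#'
#' Runs the exact neutrality test on every sample of the OTU table and
#' returns a per-sample report: sample id, reads J, species S, fitted theta
#' and m, the observed and neutral-reference log-likelihoods, the deviation
#' q, its chi-squared p-value and the pass flag (p > alpha means the sample
#' is consistent with neutral assembly). Samples are independent, so any
#' execution order yields identical rows; per-sample seeds are derived from
#' the master seed. Per-sample failures are logged, not fatal.
#'
#' @param config An [analysis_config].
#' @return Tibble, one row per tested sample, with attribute `n_pass`.
#' @export
run_community_scale <- function(config) {
  stopifnot(inherits(config, "analysis_config"))
  tab <- config$table
  ids <- rownames(tab)
  cap <- config$community$max_samples
  if (!is.null(cap)) ids <- utils::head(ids, cap)
  rows <- vector("list", length(ids))
  for (k in seq_along(ids)) {
    id <- ids[k]
    rows[[k]] <- tryCatch({
      sad <- sample_to_sad(tab, id)
      res <- exact_neutrality_test(sad, n_sim = config$community$n_sim,
                                   seed = config$seed + k,
                                   alpha = config$community$alpha)
      tibble::tibble(sample_id = id, J = sad$J, S = sad$S,
                     theta = res$fit$theta, m = res$fit$m,
                     logL0 = res$logL0, logL1 = res$logL1,
                     q = res$q, p = res$p, pass = res$pass)
    }, error = function(e) {
      message("sample ", id, " failed: ", conditionMessage(e))
      tibble::tibble(sample_id = id, J = NA_integer_, S = NA_integer_,
                     theta = NA_real_, m = NA_real_, logL0 = NA_real_,
                     logL1 = NA_real_, q = NA_real_, p = NA_real_, pass = NA)
    })
  }
  out <- do.call(rbind, rows)
  attr(out, "n_pass") <- sum(out$pass, na.rm = TRUE)
  out
}

#' Species-scale neutrality report
#'
#' Runs the balanced resampled species-level analysis for each
#' source -> destination design and returns one summary row per design
#' (mean and SD over repeats of N, m, R^2, total taxa, percent neutral and
#' non-neutral), with designs whose mean R^2 falls below the pass threshold
#' flagged. When at least two designs are present, an unpaired t-test
#' compares the per-repeat neutral percentages of the first two (the
#' no-group-difference check) and is attached as attribute `ttest`.
#'
#' @param config An [analysis_config] with `groups` set.
#' @return Tibble, one row per design, with attributes `resamples` (the
#'   underlying `sloan_resample` objects) and `ttest`.
#' @export
run_species_scale <- function(config) {
  stopifnot(inherits(config, "analysis_config"))
  if (is.null(config$groups)) stop("species-scale analysis needs a group map")
  sp <- config$species
  if (!length(sp$designs)) stop("no designs configured")
  resamples <- vector("list", length(sp$designs))
  rows <- vector("list", length(sp$designs))
  for (k in seq_along(sp$designs)) {
    d <- sp$designs[[k]]
    rs <- resampled_sloan_analysis(
      config$table, config$groups, d[1], d[2],
      n_per_group = sp$n_per_group, n_repeats = sp$n_repeats,
      seed = config$seed + 1000L * k,
      detection_threshold = sp$detection_threshold,
      ci_method = sp$ci_method)
    resamples[[k]] <- rs
    rows[[k]] <- tibble::as_tibble(
      cbind(rs$summary, tibble::tibble(R2_pass = rs$summary$R2 >= sp$R2_pass)))
  }
  out <- do.call(rbind, rows)
  attr(out, "resamples") <- resamples
  if (length(resamples) >= 2)
    attr(out, "ttest") <- pct_neutral_ttest(resamples[[1]], resamples[[2]])
  out
}

#' Rank-abundance export for observed vs simulated communities
#'
#' Long-format table of log-abundance against abundance rank for the
#' observed community and `n_sim` neutral communities simulated at the
#' fitted parameters — the data behind the classic observed-vs-neutral
#' rank-abundance comparison plot.
#'
#' @param sad A `community_sad`.
#' @param fit An `etienne_fit` (or list with `theta` and `I`).
#' @param n_sim Number of simulated curves (0 = observed only).
#' @param seed Optional integer seed.
#' @return Tibble with columns `curve` ("observed", "sim_1", ...), `rank`,
#'   `abundance`, `log_abundance` (natural log).
#' @export
export_rank_abundance <- function(sad, fit, n_sim = 10, seed = NULL) {
  stopifnot(inherits(sad, "community_sad"))
  if (!is.null(seed)) set.seed(seed)
  curves <- list(tibble::tibble(curve = "observed",
                                rank = seq_len(sad$S),
                                abundance = sad$abundances))
  for (i in seq_len(n_sim)) {
    ab <- sim_etienne_cpp(fit$theta, fit$I, sad$J)
    curves[[i + 1]] <- tibble::tibble(curve = paste0("sim_", i),
                                      rank = seq_along(ab), abundance = ab)
  }
  out <- do.call(rbind, curves)
  out$log_abundance <- log(out$abundance)
  out
}

#' Run the full cross-scale analysis and write report files
#'
#' Executes the community-scale exact tests and the species-scale resampled
#' fits per the configuration and writes `table1.tsv` (per-sample community
#' report), `table2.tsv` (per-design species report), `rank_abundance.tsv`
#' (curves for every passing community, or the first sample if none pass)
#' and `species_classification.tsv` (per-taxon classification of the last
#' repeat of the first design) into `out_dir`. Each file carries a
#' provenance comment header (package version, seed, config hash), and the
#' whole run is a deterministic function of (config, seed).
#'
#' @param config An [analysis_config] with `out_dir` set.
#' @return Invisibly, a list with the in-memory reports.
#' @export
run_analysis <- function(config) {
  stopifnot(inherits(config, "analysis_config"))
  if (is.null(config$out_dir)) stop("config$out_dir must be set")
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  prov <- c(
    paste0("package: microneutral ",
           as.character(utils::packageVersion("microneutral"))),
    paste0("seed: ", config$seed),
    paste0("config_hash: ", rlang::hash(config[c("community", "species", "seed")])))
  out <- list()
  if (isTRUE(config$community$enabled)) {
    t1 <- run_community_scale(config)
    write_results_table(t1, file.path(config$out_dir, "table1.tsv"),
                        comments = c(prov, paste0("passing: ", attr(t1, "n_pass"),
                                                  " of ", nrow(t1))))
    out$table1 <- t1
    show <- t1$sample_id[which(t1$pass)]
    if (!length(show)) show <- t1$sample_id[1]
    ra <- lapply(show, function(id) {
      sad <- sample_to_sad(config$table, id)
      row <- t1[t1$sample_id == id, ]
      fit <- list(theta = row$theta, I = I_from_m(row$m, sad$J))
      cbind(sample_id = id,
            export_rank_abundance(sad, fit, n_sim = 10, seed = config$seed))
    })
    write_results_table(do.call(rbind, ra),
                        file.path(config$out_dir, "rank_abundance.tsv"),
                        comments = prov)
    out$rank_abundance <- ra
  }
  if (!is.null(config$groups) && length(config$species$designs)) {
    t2 <- run_species_scale(config)
    tt <- attr(t2, "ttest")
    cm <- prov
    if (!is.null(tt))
      cm <- c(cm, sprintf("pct_neutral t-test (%s->%s vs %s->%s): p = %.4g",
                          t2$source[1], t2$dest[1], t2$source[2], t2$dest[2],
                          tt$p.value))
    write_results_table(t2, file.path(config$out_dir, "table2.tsv"),
                        comments = cm)
    write_results_table(attr(t2, "resamples")[[1]]$last_fit$species,
                        file.path(config$out_dir, "species_classification.tsv"),
                        comments = prov)
    out$table2 <- t2
  }
  invisible(out)
}
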