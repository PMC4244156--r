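#' Deletion genotyping benchmark on simulated data
#'
#' Runs the package's standard simulation study: a random reference with
#' planted deletions (lengths log-uniform in `length_range`), a cohort
#' simulated at the given coverage with per-site allele frequencies
#' uniform in `af_range`, feature extraction from truth-placement
#' alignments, and `rounds` repetitions of a random train/test split of
#' the individuals with full grid-search training. Library insert
#' statistics are estimated from the simulated alignments, not assumed.
#'
#' @param seed Master seed; all randomness (sites, cohort, splits, CV
#'   folds) derives from it.
#' @param n_sites,n_individuals,coverage,ref_length,length_range,af_range
#'   Study dimensions; defaults are the package's standard conditions
#'   (60 deletions of 50–5000 bp on 1 Mbp, 20 individuals at 6x, allele
#'   frequencies uniform on (0, 0.5)).
#' @param rounds Train/test rounds (default 10).
#' @param n_train Individuals in each training split (default 15).
#' @param folds,cost_grid,gamma_grid Passed to [train_genotyper()].
#' @return A list: `accuracy` (per-stratum accuracy averaged over rounds,
#'   plus pooled counts), `per_round` (per-round stratified tables),
#'   `features` (labeled feature tibble), `sim` (the cohort), `lib`, and
#'   `last_model`.
#' @export
deletion_benchmark <- function(seed = 1L, n_sites = 60L, n_individuals = 20L,
                               coverage = 6, ref_length = 1e6,
                               length_range = c(50, 5000),
                               af_range = c(0, 0.5), rounds = 10L,
                               n_train = 15L, folds = 10L,
                               cost_grid = default_cost_grid(),
                               gamma_grid = default_gamma_grid()) {
  sites <- sim_sites(n_sites, ref_length, length_range = length_range,
                     seed = seed)
  cfg <- sim_config(coverage = coverage, n_individuals = n_individuals,
                    seed = seed + 1L)
  af <- withr::with_seed(seed + 2L,
                         runif(n_sites, af_range[1], af_range[2]))
  sim <- simulate_cohort(sites, cfg, ref_length = ref_length,
                         allele_freq = af)
  lib <- estimate_library_stats(sim$alignments)
  feat <- extract_features(sim$alignments, sites, lib)
  labeled <- feat %>%
    left_join(rename(sim$truth, label = "genotype"),
              by = c("sample", "site_id"))
  smps <- sample_names(n_individuals)
  per_round <- vector("list", rounds)
  model <- NULL
  for (r in seq_len(rounds)) {
    tr_smp <- withr::with_seed(seed + 100L + r, sample(smps, n_train))
    tr <- labeled %>% filter(.data$sample %in% tr_smp)
    te <- labeled %>% filter(!.data$sample %in% tr_smp)
    model <- train_genotyper(tr, folds = folds, cost_grid = cost_grid,
                             gamma_grid = gamma_grid, seed = seed + 200L + r)
    calls <- call_genotypes(model, te)
    truth_te <- sim$truth %>%
      dplyr::semi_join(te, by = c("sample", "site_id"))
    per_round[[r]] <- stratified_accuracy(calls, truth_te, sites,
                                          strata = "length") %>%
      mutate(round = r)
  }
  per_round <- bind_rows(per_round)
  accuracy <- per_round %>%
    group_by(.data$stratum) %>%
    summarise(n_sites = .data$n_sites[1],
              n_genotypes = sum(.data$n_genotypes),
              accuracy = mean(.data$accuracy, na.rm = TRUE),
              .groups = "drop")
  list(accuracy = accuracy, per_round = per_round, features = labeled,
       sim = sim, lib = lib, last_model = model)
}

#' Feature-ablation comparison
#'
#' Trains the genotyper on subsets of the five deletion features over the
#' same training data, split and CV folds, reporting each subset's
#' cross-validated accuracy. Feature subsets are given by name
#' (`discordant`, `concordant`, `split`, `full`, `depth`).
#'
#' @param labeled Labeled feature tibble (e.g.
#'   `deletion_benchmark()$features`), single indel kind.
#' @param subsets Named list of feature-name vectors; the default compares
#'   all five against the pair-only, span-only and depth-only sets.
#' @param folds,cost_grid,gamma_grid,seed Passed to [train_genotyper()].
#' @return A tibble: `subset`, `features`, `cv_accuracy`.
#' @export
feature_ablation <- function(labeled,
                             subsets = list(
                               all = del_feature_names,
                               pairs = c("discordant", "concordant"),
                               span = c("split", "full"),
                               depth = "depth"),
                             folds = 10L,
                             cost_grid = default_cost_grid(),
                             gamma_grid = default_gamma_grid(),
                             seed = 1L) {
  kind <- unique(labeled$kind) %||% "DEL"
  if (base::length(kind) > 1) abort("ablation expects a single indel kind")
  fnames <- feature_names_for(kind)
  x_all <- as.matrix(labeled[, feature_cols])
  colnames(x_all) <- fnames
  y <- labeled$label
  map_dfr(names(subsets), function(nm) {
    cols <- subsets[[nm]]
    bad <- setdiff(cols, fnames)
    if (base::length(bad) > 0)
      abort(paste0("unknown feature name(s): ", paste(bad, collapse = ", ")))
    m <- train_genotyper(x_all[, cols, drop = FALSE], labels = y,
                         kind = kind, folds = folds, cost_grid = cost_grid,
                         gamma_grid = gamma_grid, seed = seed)
    tibble(subset = nm, features = paste(cols, collapse = "+"),
           cv_accuracy = m$cv_accuracy)
  })
}

#' Downsampling consistency benchmark
#'
#' Simulates the standard deletion cohort at a higher baseline coverage,
#' trains on a split of individuals, then calls genotypes twice — on the
#' full alignments and on a random template fraction
#' ([downsample_reads()]) — and reports the fraction of genotypes that
#' change. Because features are normalized by local coverage, calls should
#' be largely stable under downsampling.
#'
#' @param seed Master seed.
#' @param coverage Baseline fold coverage (default 12).
#' @param fraction Template keep fraction for the downsampled pass
#'   (default 0.25).
#' @param n_sites,n_individuals,ref_length,length_range,af_range,n_train
#'   Study dimensions as in [deletion_benchmark()].
#' @param folds,cost_grid,gamma_grid Passed to [train_genotyper()].
#' @return A list: `changed` (from [changed_genotypes()]), `full_calls`,
#'   `reduced_calls`, `truth`.
#' @export
downsampling_benchmark <- function(seed = 1L, coverage = 12, fraction = 0.25,
                                   n_sites = 60L, n_individuals = 20L,
                                   ref_length = 1e6,
                                   length_range = c(50, 5000),
                                   af_range = c(0, 0.5), n_train = 15L,
                                   folds = 10L,
                                   cost_grid = default_cost_grid(),
                                   gamma_grid = default_gamma_grid()) {
  sites <- sim_sites(n_sites, ref_length, length_range = length_range,
                     seed = seed)
  cfg <- sim_config(coverage = coverage, n_individuals = n_individuals,
                    seed = seed + 1L)
  af <- withr::with_seed(seed + 2L,
                         runif(n_sites, af_range[1], af_range[2]))
  sim <- simulate_cohort(sites, cfg, ref_length = ref_length,
                         allele_freq = af)
  lib <- estimate_library_stats(sim$alignments)
  feat_full <- extract_features(sim$alignments, sites, lib)
  labeled <- feat_full %>%
    left_join(rename(sim$truth, label = "genotype"),
              by = c("sample", "site_id"))
  tr_smp <- withr::with_seed(seed + 100L,
                             sample(sample_names(n_individuals), n_train))
  model <- train_genotyper(labeled %>% filter(.data$sample %in% tr_smp),
                           folds = folds, cost_grid = cost_grid,
                           gamma_grid = gamma_grid, seed = seed + 200L)
  reduced <- downsample_reads(sim$alignments, fraction, seed = seed + 300L)
  feat_red <- extract_features(reduced, sites, lib)
  full_calls <- call_genotypes(model, feat_full)
  reduced_calls <- call_genotypes(model, feat_red)
  list(changed = changed_genotypes(full_calls, reduced_calls),
       full_calls = full_calls, reduced_calls = reduced_calls,
       truth = sim$truth)
}
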