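calls_of <- function(truth, flip = integer(0)) {
  out <- truth %>% dplyr::select(sample, site_id, genotype)
  out$genotype[flip] <- (out$genotype[flip] + 1L) %% 3L
  out
}

toy_truth <- function() {
  tidyr::expand_grid(sample = c("S01", "S02"),
                     site_id = c("a", "b")) %>%
    dplyr::mutate(genotype = c(0L, 1L, 2L, 0L))
}

test_that("accuracy counts correct genotypes per stratum", {
  truth <- toy_truth()
  acc <- stratified_accuracy(calls_of(truth, flip = 1), truth,
                             strata = "none")
  expect_equal(acc$accuracy, 0.75)
  expect_equal(acc$n_genotypes, 4L)

  perfect <- stratified_accuracy(calls_of(truth), truth, strata = "none")
  expect_equal(perfect$accuracy, 1.0)

  orphan <- calls_of(truth) %>%
    dplyr::mutate(site_id = replace(site_id, 1, "zzz"))
  expect_error(stratified_accuracy(orphan, truth), "no matching truth")
})

test_that("length strata split sites on the standard bins", {
  sites <- indel_sites("ref", p1 = c(1000L, 5000L, 9000L),
                       p2 = c(1100L, 5300L, 11000L), kind = "DEL")
  truth <- tidyr::expand_grid(sample = c("S01", "S02"),
                              site_id = sites$site_id) %>%
    dplyr::mutate(genotype = c(0L, 1L, 2L, 1L, 0L, 2L))
  acc <- stratified_accuracy(calls_of(truth, flip = 2), truth, sites,
                             strata = "length")
  expect_setequal(acc$stratum, c("50-200", "200-400", ">1500", "overall"))
  expect_equal(acc$accuracy[acc$stratum == "200-400"], 0.5)
  expect_equal(acc$accuracy[acc$stratum == "overall"], 5 / 6)
  # overall equals the genotype-weighted mean of the strata
  strat <- acc %>% dplyr::filter(stratum != "overall")
  expect_equal(weighted.mean(strat$accuracy, strat$n_genotypes),
               acc$accuracy[acc$stratum == "overall"])
})

test_that("frequency strata come from truth carriers, missing calls are split out", {
  co <- small_cohort()
  truth <- co$sim$truth
  calls <- truth %>% dplyr::select(sample, site_id, genotype) %>%
    dplyr::slice(-(1:5))  # five genotypes uncalled
  acc <- stratified_accuracy(calls, truth, co$sites, strata = "frequency")
  ov <- acc[acc$stratum == "overall", ]
  expect_equal(ov$n_missing, 5L)
  expect_equal(ov$accuracy, 1.0)  # the called ones are all correct
  expect_equal(ov$n_genotypes + ov$n_missing, nrow(truth))
})

test_that("the eight Mendelian-impossible triples match brute force", {
  grid <- tidyr::expand_grid(father = 0:2, mother = 0:2, child = 0:2)
  res <- trio_discordance(grid)
  brute <- purrr::pmap_lgl(grid, function(father, mother, child)
    !mendel_possible(father, mother, child))
  expect_equal(res$per_site$discordant, brute)
  # as unordered parent pairs: exactly the eight cases
  impossible <- res$per_site %>% dplyr::filter(discordant) %>%
    dplyr::mutate(key = paste(pmin(father, mother),
                              pmax(father, mother), child)) %>%
    dplyr::distinct(key)
  expect_equal(nrow(impossible), 8L)
  expect_setequal(impossible$key,
                  c("0 0 1", "0 0 2", "0 1 2", "0 2 0", "0 2 2", "1 2 0",
                    "2 2 0", "2 2 1"))
})

test_that("trio metrics count specific cases and tolerate missing calls", {
  trios <- tibble::tibble(father = c(0L, 0L, 1L, 2L, NA),
                          mother = c(0L, 0L, 1L, 2L, 1L),
                          child = c(1L, 0L, 1L, 2L, 0L))
  res <- trio_discordance(trios)
  expect_equal(res$n_discordant, 1L)  # (0,0,1)
  expect_equal(res$n_all_zero, 1L)    # (0,0,0)
  expect_equal(res$n_missing, 1L)
  expect_equal(res$n_total, 4L)
  expect_error(trio_discordance(tibble::tibble(father = 5L, mother = 0L,
                                               child = 0L)),
               "must be 0, 1, 2")
})

test_that("downsampling keeps templates atomically at the right rate", {
  co <- small_cohort()
  one <- co$sim$alignments %>% dplyr::filter(sample == "S01")
  expect_identical(downsample_reads(one, 1, seed = 1), one)
  expect_equal(nrow(downsample_reads(one, 0, seed = 1)), 0L)

  half <- downsample_reads(one, 0.5, seed = 2)
  n0 <- dplyr::n_distinct(one$qname)
  nk <- dplyr::n_distinct(half$qname)
  expect_lt(abs(nk - 0.5 * n0), 3 * sqrt(0.25 * n0))
  # mates stay together
  per_template <- half %>% dplyr::count(qname)
  orig <- one %>% dplyr::count(qname)
  expect_equal(per_template$n,
               orig$n[match(per_template$qname, orig$qname)])

  expect_identical(downsample_reads(one, 0.5, seed = 2), half)
  expect_error(downsample_reads(one, 1.5), "fraction")
})

test_that("sequential downsampling composes multiplicatively", {
  co <- small_cohort()
  one <- co$sim$alignments %>% dplyr::filter(sample == "S02")
  n0 <- dplyr::n_distinct(one$qname)
  twice <- downsample_reads(downsample_reads(one, 0.6, seed = 3), 0.5,
                            seed = 4)
  nk <- dplyr::n_distinct(twice$qname)
  p <- 0.3
  expect_lt(abs(nk - p * n0), 3 * sqrt(p * (1 - p) * n0))
})

test_that("changed genotypes count differences and dropouts", {
  full <- toy_truth() %>% dplyr::select(sample, site_id, genotype)
  expect_equal(changed_genotypes(full, full),
               list(n_changed = 0L, n_total = 4L, fraction = 0))
  one_diff <- full %>%
    dplyr::mutate(genotype = replace(genotype, 2, 2L))
  expect_equal(changed_genotypes(full, one_diff)$n_changed, 1L)
  dropped <- full %>% dplyr::slice(-3)
  res <- changed_genotypes(full, dropped)
  expect_equal(res$n_changed, 1L)
  expect_equal(res$n_total, 4L)
})
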