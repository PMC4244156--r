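test_that("truth genotypes follow the configured frequencies", {
  sites <- sim_sites(100, 2e6, length_range = c(50, 500), seed = 1)
  cfg <- sim_config(n_individuals = 100, seed = 2)  # freqs 0.7/0.2/0.1
  tr <- assign_truth_genotypes(sites, cfg)
  n <- nrow(tr)
  expect_equal(n, 10000L)
  p <- c(0.7, 0.2, 0.1)
  for (g in 0:2) {
    tol <- 3 * sqrt(p[g + 1] * (1 - p[g + 1]) / n)
    expect_lt(abs(mean(tr$genotype == g) - p[g + 1]), tol)
  }
  # heterozygotes carry a haplotype assignment, homozygotes do not
  expect_true(all(!is.na(tr$hap[tr$genotype == 1])))
  expect_true(all(is.na(tr$hap[tr$genotype != 1])))

  all0 <- assign_truth_genotypes(sites, sim_config(
    n_individuals = 5, genotype_freqs = c(1, 0, 0), seed = 3))
  expect_true(all(all0$genotype == 0L))

  expect_identical(assign_truth_genotypes(sites, cfg),
                   assign_truth_genotypes(sites, cfg))
  expect_error(sim_config(genotype_freqs = c(0.5, 0.4, 0.2)), "sum to 1")
})

test_that("hardy-weinberg draws respect per-site allele frequencies", {
  sites <- sim_sites(3, 5e4, length_range = c(100, 200), seed = 4)
  cfg <- sim_config(n_individuals = 2000, seed = 5)
  tr <- assign_truth_genotypes(sites, cfg, allele_freq = c(0, 0.5, 1))
  by_site <- split(tr$genotype, tr$site_id)[sites$site_id]
  expect_true(all(by_site[[1]] == 0L))
  expect_true(all(by_site[[3]] == 2L))
  expect_equal(mean(by_site[[2]]) / 2, 0.5, tolerance = 0.05)
})

test_that("haplotype surgery matches hand-built strings", {
  ref <- "AAAACCCCGGGG"
  del <- indel_sites("ref", 4L, 8L, "DEL")
  g2 <- tibble::tibble(sample = "S01", site_id = del$site_id,
                       genotype = 2L, hap = NA_integer_)
  h <- build_haplotypes(ref, del, g2)
  expect_equal(c(h$h1, h$h2), c("AAAAGGGG", "AAAAGGGG"))

  g1 <- dplyr::mutate(g2, genotype = 1L, hap = 2L)
  h1 <- build_haplotypes(ref, del, g1)
  expect_equal(c(h1$h1, h1$h2), c("AAAACCCCGGGG", "AAAAGGGG"))

  ins <- indel_sites("ref", 4L, 4L, "INS", length = 3L)
  hi <- build_haplotypes(ref, ins, dplyr::mutate(g2, site_id = ins$site_id),
                         ins_seqs = stats::setNames("TTT", ins$site_id))
  expect_equal(hi$h1, "AAAATTTCCCCGGGG")

  overlap <- indel_sites("ref", c(2L, 4L), c(6L, 8L), "DEL")
  truth2 <- tibble::tibble(sample = "S01", site_id = overlap$site_id,
                           genotype = 2L, hap = NA_integer_)
  expect_error(build_haplotypes(ref, overlap, truth2), "overlapping sites")
})

test_that("pair count follows coverage and reads mirror the haplotype", {
  cfg <- sim_config(coverage = 10, read_len = 100, n_individuals = 1,
                    error_rate = 0, seed = 6)
  org <- simulate_paired_reads(c(1e5, 1e5), 1e5, cfg, seed = 7)
  expect_equal(nrow(org), 5000L)  # c*G/(2l) = 10*1e5/200
  expect_true(all(org$frag_len >= 200L))
  expect_true(all(org$frag_start >= 0 &
                    org$frag_start + org$frag_len <= 1e5))

  # with no errors, every read is a substring of its haplotype (mate 2
  # after reverse complement)
  ref <- random_reference(5000, seed = 8)
  cfg2 <- sim_config(coverage = 3, n_individuals = 1, error_rate = 0,
                     seed = 9)
  org2 <- simulate_paired_reads(c(5000L, 5000L), 5000L, cfg2, seed = 10)
  seqs <- read_sequences(org2, list(h1 = ref$seq, h2 = ref$seq), cfg2,
                         seed = 11)
  expect_true(all(vapply(seqs$seq1, grepl, logical(1), x = ref$seq,
                         fixed = TRUE)))
  rc2 <- indelgt:::revcomp(seqs$seq2)
  expect_true(all(vapply(rc2, grepl, logical(1), x = ref$seq,
                         fixed = TRUE)))
})

test_that("base errors hit at about the configured rate", {
  ref <- random_reference(20000, seed = 12)
  cfg <- sim_config(coverage = 5, n_individuals = 1, error_rate = 0.02,
                    seed = 13)
  org <- simulate_paired_reads(c(20000L, 20000L), 20000L, cfg, seed = 14)
  clean <- read_sequences(org, list(h1 = ref$seq, h2 = ref$seq),
                          sim_config(coverage = 5, n_individuals = 1,
                                     error_rate = 0, seed = 13), seed = 15)
  noisy <- read_sequences(org, list(h1 = ref$seq, h2 = ref$seq), cfg,
                          seed = 15)
  mm <- function(a, b) sum(utf8ToInt(paste(a, collapse = "")) !=
                             utf8ToInt(paste(b, collapse = "")))
  total <- 2 * nrow(org) * cfg$read_len
  rate <- (mm(clean$seq1, noisy$seq1) + mm(clean$seq2, noisy$seq2)) / total
  expect_equal(rate, 0.02, tolerance = 0.15)
})

test_that("identical seeds give byte-identical FASTQ", {
  ref <- random_reference(3000, seed = 16)
  cfg <- sim_config(coverage = 4, n_individuals = 1, seed = 17)
  fq <- function() {
    org <- simulate_paired_reads(c(3000L, 3000L), 3000L, cfg, seed = 18)
    seqs <- read_sequences(org, list(h1 = ref$seq, h2 = ref$seq), cfg,
                           seed = 19)
    prefix <- tempfile()
    paths <- write_sim_fastq(seqs, prefix)
    lapply(paths, readLines)
  }
  expect_identical(fq(), fq())
})

test_that("realized depth tracks the configured coverage", {
  co <- small_cohort()  # 10 individuals at 8x
  cov <- coverage_profiles(co$sim$alignments)
  # an indel-free 10 kb window well away from any site
  gaps <- co$sites$p1[-1] - co$sites$p2[-nrow(co$sites)]
  i <- which.max(gaps)
  w0 <- co$sites$p2[i] + 2000; w1 <- w0 + 10000
  depths <- vapply(cov, function(s)
    indelgt:::rle_region_mean(s$ref, w0, w1), numeric(1))
  expect_true(all(abs(depths - 8) / 8 < 0.10))
})

test_that("deletion genotypes shape the interval depth as expected", {
  co <- small_cohort()
  cov <- coverage_profiles(co$sim$alignments)
  long <- co$sites %>% dplyr::filter(length >= 800)
  cases <- co$sim$truth %>%
    dplyr::inner_join(long, by = "site_id") %>%
    dplyr::mutate(
      dep = purrr::pmap_dbl(list(sample, p1, p2), function(smp, a, b)
        indelgt:::rle_region_mean(cov[[smp]]$ref, a, b)),
      flank = purrr::pmap_dbl(list(sample, p1, p2), function(smp, a, b)
        mean(c(indelgt:::rle_region_mean(cov[[smp]]$ref, a - 1000, a),
               indelgt:::rle_region_mean(cov[[smp]]$ref, b, b + 1000)))))
  hom <- cases %>% dplyr::filter(genotype == 2)
  het <- cases %>% dplyr::filter(genotype == 1)
  # reads overhang breakpoints, so a trickle of clipped-through coverage
  # remains; homozygous intervals must still be nearly empty
  expect_lt(mean(hom$dep) / mean(hom$flank), 0.15)
  expect_equal(mean(het$dep) / mean(het$flank), 0.5, tolerance = 0.25)
})

test_that("trio construction is Mendelian-consistent by design", {
  sites <- sim_sites(200, 2e6, length_range = c(50, 500), seed = 20)
  cfg <- sim_config(n_individuals = 3, genotype_freqs = c(0.4, 0.3, 0.3),
                    seed = 21)
  trio <- simulate_trio_truth(sites, cfg)
  res <- trio_discordance(trio)
  expect_equal(res$n_discordant, 0L)
  expect_gt(res$n_total, 0L)
})

test_that("cohort simulation is reproducible end to end", {
  sites <- sim_sites(5, 5e4, length_range = c(100, 800), seed = 22)
  cfg <- sim_config(coverage = 4, n_individuals = 2, seed = 23)
  s1 <- simulate_cohort(sites, cfg, ref_length = 5e4)
  s2 <- simulate_cohort(sites, cfg, ref_length = 5e4)
  expect_identical(s1$truth, s2$truth)
  expect_identical(s1$alignments, s2$alignments)
})
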