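test_that("region depth is the per-base mean", {
  expect_equal(mean_region_depth(c(2, 2, 2, 2)), 2.0)
  expect_equal(mean_region_depth(c(0, 1, 2, 3)), 1.5)
  expect_error(mean_region_depth(numeric(0)), "empty region")
})

test_that("local coverage averages the two flank means", {
  lib <- toy_lib(); cfg <- evidence_config()  # w = 650
  del <- toy_del_site()[1, ]                  # p1 10000, p2 10400
  # uniform depth 10 over both flanks
  unif <- purrr::map_dfr(seq(8000, 12000, by = 10), function(s)
    aln(paste0("u", s), s, s + 100L, mate_mapped = FALSE))
  cov <- coverage_profiles(unif)[["S01"]]
  expect_equal(local_coverage(del, cov, lib, cfg), 10, tolerance = 0.05)

  # left flank ~8, right flank ~12 -> 10
  uneven <- dplyr::bind_rows(
    purrr::map_dfr(seq(8000, 9999, by = 25), function(s)
      aln(paste0("l", s), s, s + 200L, mate_mapped = FALSE)),
    purrr::map_dfr(seq(10400, 12000, by = 25), function(s)
      aln(paste0("r", s), s, s + 300L, mate_mapped = FALSE)))
  cov2 <- coverage_profiles(uneven)[["S01"]]
  l <- indelgt:::rle_region_mean(cov2$ref, 10000 - 650, 10000)
  r <- indelgt:::rle_region_mean(cov2$ref, 10400, 10400 + 650)
  expect_equal(local_coverage(del, cov2, lib, cfg), mean(c(l, r)))

  # site at the contig start: the left flank is empty, the right one
  # carries the estimate alone
  edge <- indel_sites("ref", 0L, 200L, "DEL")[1, ]
  right_only <- purrr::map_dfr(seq(200, 1200, by = 20), function(s)
    aln(paste0("e", s), s, s + 100L, mate_mapped = FALSE))
  cov3 <- coverage_profiles(right_only)[["S01"]]
  expect_equal(local_coverage(edge, cov3, lib, cfg),
               indelgt:::rle_region_mean(cov3$ref, 200, 850))
})

test_that("feature vectors assemble in the fixed per-kind order", {
  cnt <- list(n_discordant = 4, n_concordant = 2, n_single_end_mapped = 3,
              n_split = 5, n_partial = 7, n_full = 1)
  del <- build_feature_vector(cnt, depth = 6.2, kind = "DEL")
  expect_equal(unname(del), c(4, 2, 5, 1, 6.2))
  expect_equal(names(del), c("discordant", "concordant", "split", "full",
                             "depth"))
  ins <- build_feature_vector(cnt, kind = "INS")
  expect_equal(unname(ins), c(4, 2, 3, 7, 1))
  expect_equal(names(ins), c("discordant", "concordant",
                             "single_end_mapped", "partial", "full"))
  expect_error(build_feature_vector(cnt, kind = "DUP"), "unknown indel kind")
})

test_that("normalization divides by local coverage with a fallback", {
  v <- c(4, 2, 6, 1, 3)
  nv <- normalize_vector(v, lambda = 2)
  expect_equal(as.numeric(nv), c(2, 1, 3, 0.5, 1.5))
  expect_equal(attr(nv, "lambda"), 2)

  fb <- normalize_vector(v, lambda = 0, fallback_cov = 4)
  expect_equal(as.numeric(fb), v / 4)
  expect_equal(attr(fb, "lambda"), 4)

  expect_error(normalize_vector(v, lambda = 0), "no usable fallback")
  expect_error(normalize_vector(v, lambda = NA), "no usable fallback")
})

test_that("duplicating every read leaves normalized features unchanged", {
  co <- small_cohort()
  one <- co$sim$alignments %>% dplyr::filter(sample == "S01")
  dup <- dplyr::bind_rows(one, one %>%
                            dplyr::mutate(qname = paste0(qname, "_dup")))
  f1 <- extract_features(one, co$sites, co$lib)
  f2 <- extract_features(dup, co$sites, co$lib)
  for (cc in c("f1", "f2", "f3", "f4", "f5")) {
    base <- f1[[cc]]; doubled <- f2[[cc]]
    nz <- base > 0
    expect_lt(mean(abs(doubled[nz] - base[nz]) / base[nz]), 0.10)
  }
  expect_equal(f2$lambda, 2 * f1$lambda, tolerance = 1e-8)
})

test_that("normalized depth orders the three deletion genotypes", {
  co <- small_cohort()
  by_g <- co$feat %>%
    dplyr::inner_join(co$sim$truth, by = c("sample", "site_id")) %>%
    dplyr::group_by(genotype) %>%
    dplyr::summarise(depth = mean(f5), discordant = mean(f1))
  expect_true(by_g$depth[by_g$genotype == 2] <
                by_g$depth[by_g$genotype == 1])
  expect_true(by_g$depth[by_g$genotype == 1] <
                by_g$depth[by_g$genotype == 0])
  # discordant support runs the other way
  expect_true(by_g$discordant[by_g$genotype == 2] >
                by_g$discordant[by_g$genotype == 0])
})

test_that("feature tables survive the TSV round trip", {
  co <- small_cohort()
  f <- co$feat %>% head(20) %>%
    dplyr::mutate(label = rep_len(0:2, 20))
  path <- tempfile(fileext = ".tsv")
  write_features(f, path)
  back <- read_features(path)
  expect_equal(as.data.frame(back), as.data.frame(f[, names(back)]),
               tolerance = 1e-12)
  expect_error(read_features(write_sites(toy_del_site(),
                                         tempfile(fileext = ".tsv"))),
               "missing column")
})
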