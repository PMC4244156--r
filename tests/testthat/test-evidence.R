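test_that("relevant region extends the site by one maximal insert", {
  lib <- toy_lib()  # mu 500, sigma 50 -> D = 650
  del <- toy_del_site()
  r <- relevant_region(del[1, ], lib)
  expect_equal(r[c("start", "end")], list(start = 9350L, end = 11050L))

  ins <- indel_sites("ref", 10000L, 10000L, "INS", length = 200L)
  ri <- relevant_region(ins[1, ], lib)
  expect_equal(ri[c("start", "end")], list(start = 9350L, end = 10650L))

  edge <- indel_sites("ref", 100L, 500L, "DEL")
  expect_equal(relevant_region(edge[1, ], lib)$start, 0L)
})

pair_summary <- function(n_mapped = 2L, insert = NA, outer_start = NA,
                         outer_end = NA, innie = TRUE) {
  tibble::tibble(n_mapped = n_mapped, insert = as.numeric(insert),
                 outer_start = as.numeric(outer_start),
                 outer_end = as.numeric(outer_end), innie = innie)
}

enc_pair <- function(insert) # encompasses p1 = 10000 of the toy site
  pair_summary(insert = insert, outer_start = 10000 - insert + 150,
               outer_end = 10150)

test_that("pair classes follow the indel-adjusted insert-size windows", {
  del <- toy_del_site()[1, ]; lib <- toy_lib(); cfg <- evidence_config()
  # |905 - 500 - 400| = 5 <= 150
  expect_equal(classify_pair(enc_pair(905), del, lib, cfg),
               "DISCORDANT_SUPPORT")
  # |510 - 500| <= 150
  expect_equal(classify_pair(enc_pair(510), del, lib, cfg), "CONCORDANT")
  # beyond both windows: discarded as wrongly mapped
  expect_equal(classify_pair(enc_pair(5000), del, lib, cfg), "INVALID")
  # between the windows (700: 200 over mu, 200 under mu+L): no class
  expect_equal(classify_pair(enc_pair(700), del, lib, cfg), "UNINFORMATIVE")
  # not encompassing any breakpoint
  expect_equal(classify_pair(
    pair_summary(insert = 500, outer_start = 9000, outer_end = 9500),
    del, lib, cfg), "UNINFORMATIVE")
  # wrong orientation
  expect_equal(classify_pair(
    pair_summary(insert = 905, outer_start = 9245, outer_end = 10150,
                 innie = FALSE), del, lib, cfg), "UNINFORMATIVE")

  ins <- indel_sites("ref", 10000L, 10000L, "INS", length = 400L)[1, ]
  # one mapped mate: insertion evidence, meaningless for deletions
  expect_equal(classify_pair(pair_summary(n_mapped = 1L), ins, lib, cfg),
               "SINGLE_END_MAPPED")
  expect_equal(classify_pair(pair_summary(n_mapped = 1L), del, lib, cfg),
               "UNINFORMATIVE")
  # insertion-adjusted window: insert ~ mu - L
  expect_equal(classify_pair(
    pair_summary(insert = 110, outer_start = 9950, outer_end = 10060),
    ins, lib, cfg), "DISCORDANT_SUPPORT")

  expect_error(classify_pair(tibble::tibble(insert = 1), del, lib, cfg),
               "missing column")
})

seg <- function(start, end, clip_left = 0L, clip_right = 0L)
  tibble::tibble(start = start, end = end, clip_left = clip_left,
                 clip_right = clip_right)

test_that("spanning-read classes honor the clip slack at breakpoints", {
  del <- toy_del_site()[1, ]  # p1 10000, p2 10400
  cfg <- evidence_config()    # clip slack 15

  # two segments with inner edges within 15 bp of p1 and p2
  expect_equal(classify_spanning_read(
    dplyr::bind_rows(seg(9933, 10003, clip_right = 30L),
                     seg(10398, 10468, clip_left = 70L)), del, cfg), "SPLIT")
  # soft clip 12 bp from p1
  expect_equal(classify_spanning_read(
    seg(9930, 10012, clip_right = 18L), del, cfg), "PARTIAL")
  # mapped end-to-end across p1
  expect_equal(classify_spanning_read(seg(9950, 10050), del, cfg), "FULL")
  # clip 20 bp from the breakpoint: outside the slack, and the clip also
  # disqualifies the read from FULL
  expect_equal(classify_spanning_read(
    seg(9940, 10020, clip_right = 20L), del, cfg), "NONE")
  # read nowhere near a breakpoint
  expect_equal(classify_spanning_read(seg(9500, 9600), del, cfg), "NONE")

  # split segments are not insertion evidence
  ins <- indel_sites("ref", 10000L, 10000L, "INS", length = 400L)[1, ]
  expect_equal(classify_spanning_read(
    dplyr::bind_rows(seg(9930, 10000, clip_right = 30L),
                     seg(10400, 10470, clip_left = 70L)), ins, cfg),
    "PARTIAL")
})

test_that("evidence tallies on the crafted toy match hand classification", {
  counts <- collect_evidence(toy_del_alignments(), toy_del_site(),
                             toy_lib())
  expect_equal(counts, expected_toy_counts())
})

test_that("a pair with both mates at MAPQ 0 contributes to no category", {
  low <- pair_aln("F", 9800L, 905L, mapq = 0L)  # would be discordant
  counts <- collect_evidence(low, toy_del_site(), toy_lib())
  expect_true(all(counts[, -(1:2)] == 0L))
  # one well-mapped mate rescues the template
  mixed <- pair_aln("M", 9800L, 905L)
  mixed$mapq[2] <- 0L
  counts2 <- collect_evidence(mixed, toy_del_site(), toy_lib())
  expect_equal(counts2$n_discordant, 1L)
})

test_that("a region with no reads yields all-zero counts", {
  far <- pair_aln("Z", 100L, 500L)
  counts <- collect_evidence(far, toy_del_site(), toy_lib())
  expect_true(all(counts[, -(1:2)] == 0L))
})

test_that("adding records never decreases any evidence count", {
  base <- toy_del_alignments()
  extra <- list(aln("N1", 9950L, 10050L, mate_mapped = FALSE),   # full
                pair_aln("N2", 9400L, 905L),                      # discordant
                aln("N3", 9935L, 10005L, clip_right = 30L,
                    mate_mapped = FALSE))                          # partial
  counts0 <- collect_evidence(base, toy_del_site(), toy_lib())
  for (e in extra) {
    counts1 <- collect_evidence(dplyr::bind_rows(base, e), toy_del_site(),
                                toy_lib())
    expect_true(all(as.matrix(counts1[, -(1:2)]) >=
                      as.matrix(counts0[, -(1:2)])))
  }
})

test_that("multi-aligned templates count once per category per site", {
  dup <- dplyr::bind_rows(
    pair_aln("A", 9400L, 905L),
    pair_aln("A", 9400L, 905L) %>% dplyr::mutate(primary = FALSE))
  counts <- collect_evidence(dup, toy_del_site(), toy_lib())
  expect_equal(counts$n_discordant, 1L)
})

test_that("collect_evidence is deterministic", {
  a <- collect_evidence(toy_del_alignments(), toy_del_site(), toy_lib())
  b <- collect_evidence(toy_del_alignments(), toy_del_site(), toy_lib())
  expect_identical(a, b)
})

test_that("vectorized tallies agree with per-record rule application", {
  del <- toy_del_site()[1, ]; lib <- toy_lib(); cfg <- evidence_config()
  for (sd in 1:5) {
    recs <- withr::with_seed(sd, {
      n <- 25L
      start <- sample(9300:11000, n)
      ins <- sample(c(300:1100, 5000), n, replace = TRUE)
      clip <- sample(c(0L, 0L, 0L, 20L, 30L), n, replace = TRUE)
      purrr::map_dfr(seq_len(n), function(i) {
        if (i %% 3 == 0) {
          aln(paste0("r", i), start[i], start[i] + 100L - clip[i],
              clip_right = clip[i], mate_mapped = FALSE)
        } else {
          pair_aln(paste0("r", i), start[i], ins[i])
        }
      })
    })
    got <- collect_evidence(recs, del, lib, cfg)
    # independent tally: apply the exported single-read rules per template
    templates <- split(recs, recs$qname)
    pc <- sc <- character(0)
    for (tm in templates) {
      if (all(tm$mapq < cfg$mapq_min)) next
      fwd <- tm[tm$tlen > 0, ]
      ps <- if (any(!tm$mate_mapped)) pair_summary(n_mapped = 1L)
            else pair_summary(insert = fwd$tlen, outer_start = fwd$start,
                              outer_end = fwd$start + fwd$tlen)
      pc <- c(pc, classify_pair(ps, del, lib, cfg))
      for (m in unique(tm$mate))
        sc <- c(sc, classify_spanning_read(tm[tm$mate == m, ], del, cfg))
    }
    expect_equal(
      unlist(got[, -(1:2)], use.names = FALSE),
      c(sum(pc == "DISCORDANT_SUPPORT"), sum(pc == "CONCORDANT"),
        sum(pc == "SINGLE_END_MAPPED"), sum(sc == "SPLIT"),
        sum(sc == "PARTIAL"), sum(sc == "FULL")))
  }
})
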