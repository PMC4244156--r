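# shared fixture builders: crafted alignment records and small cohorts

# one alignment record with sensible defaults (100 bp read, well mapped)
aln <- function(qname, start, end = start + 100L, mate = 1L, sample = "S01",
                chrom = "ref", clip_left = 0L, clip_right = 0L, mapq = 60L,
                strand = "+", primary = TRUE, mate_mapped = TRUE,
                mate_strand = if (mate_mapped) (if (strand == "+") "-" else "+")
                              else NA_character_,
                tlen = 0L) {
  tibble::tibble(sample = sample, qname = qname, mate = as.integer(mate),
                 chrom = chrom, start = as.integer(start),
                 end = as.integer(end), clip_left = as.integer(clip_left),
                 clip_right = as.integer(clip_right), mapq = as.integer(mapq),
                 strand = strand, primary = primary,
                 mate_mapped = mate_mapped, mate_strand = mate_strand,
                 tlen = as.integer(tlen))
}

# a forward-reverse both-mapped pair with the given outer span
pair_aln <- function(qname, outer_start, insert, read_len = 100L, ...) {
  dplyr::bind_rows(
    aln(qname, outer_start, outer_start + read_len, mate = 1L,
        strand = "+", tlen = insert, ...),
    aln(qname, outer_start + insert - read_len, outer_start + insert,
        mate = 2L, strand = "-", tlen = -insert, ...))
}

# the crafted deletion toy: DEL p1=10000 p2=10400 (L=400), mu=500 sigma=50;
# 2 discordant pairs, 3 concordant pairs, 1 split read, 2 fully mapped
# spanning reads, plus one pair with both mates at MAPQ 0 (must be dropped).
# Same records as inst/extdata/toy.sam.
toy_del_site <- function() indel_sites("ref", 10000L, 10400L, "DEL")

toy_del_alignments <- function() {
  dplyr::bind_rows(
    pair_aln("A", 9400L, 905L),   # |905-500-400| = 5   -> discordant
    pair_aln("G", 9350L, 900L),   # |900-900|      = 0  -> discordant
    pair_aln("B", 9700L, 510L),   # |510-500|     = 10  -> concordant
    pair_aln("H", 9650L, 480L),   # |480-500|     = 20  -> concordant
    pair_aln("I", 10290L, 520L),  # encompasses p2      -> concordant
    # split read: segments end at p1 and start at p2, mate unmapped
    aln("C", 9930L, 10000L, clip_right = 30L, mate_mapped = FALSE),
    aln("C", 10400L, 10430L, clip_left = 70L, primary = FALSE,
        mate_mapped = FALSE),
    # fully mapped spanning reads over p1 and p2, mates unmapped
    aln("D", 9950L, 10050L, mate_mapped = FALSE),
    aln("E", 10350L, 10450L, mate_mapped = FALSE),
    # both mates of F are MAPQ 0: the whole template is discarded
    pair_aln("F", 9800L, 500L, mapq = 0L))
}

toy_lib <- function() library_stats(mu = 500, sigma = 50, read_len = 100)

expected_toy_counts <- function() {
  tibble::tibble(sample = "S01", site_id = toy_del_site()$site_id,
                 n_discordant = 2L, n_concordant = 3L,
                 n_single_end_mapped = 0L, n_split = 1L, n_partial = 0L,
                 n_full = 2L)
}

# small simulated deletion cohort, memoised per test run
small_cohort <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      sites <- sim_sites(30, 4e5, length_range = c(200, 2000), seed = 42)
      cfg <- sim_config(coverage = 8, n_individuals = 10,
                        genotype_freqs = c(0.4, 0.3, 0.3), seed = 42)
      sim <- simulate_cohort(sites, cfg, ref_length = 4e5)
      lib <- library_stats(500, 50, 100)
      feat <- extract_features(sim$alignments, sites, lib)
      cache <<- list(sites = sites, cfg = cfg, sim = sim, lib = lib,
                     feat = feat)
    }
    cache
  }
})

# brute-force Mendelian checker: can the child genotype arise from one
# allele of each parent?
mendel_possible <- function(father, mother, child) {
  alleles <- function(g) switch(as.character(g), `0` = 0L, `1` = 0:1, `2` = 1L)
  child %in% as.vector(outer(alleles(father), alleles(mother), "+"))
}
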