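#' Simulation configuration
#'
#' Parameters of the diploid paired-end read simulator used to generate
#' labeled training data. Defaults follow the study conditions the
#' package's models are calibrated on: 100 bp reads, mean insert 500 bp
#' (SD 50 bp), 2% per-base substitution error, and population genotype
#' frequencies of 70% homozygous wild-type, 20% heterozygous, 10%
#' homozygous indel.
#'
#' @param coverage Fold coverage per individual.
#' @param read_len Read length, bp.
#' @param insert_mean,insert_sd Insert-size (outer distance) mean and SD, bp.
#' @param error_rate Per-base substitution probability (applied when read
#'   sequences are materialized; truth placements are error-independent).
#' @param genotype_freqs Probabilities of genotypes (0, 1, 2).
#' @param n_individuals Number of diploid individuals.
#' @param seed Master seed; all randomness in the simulator derives from it.
#' @return A `sim_config` list.
#' @examples
#' sim_config(coverage = 6, n_individuals = 20, seed = 1)
#' @export
sim_config <- function(coverage = 6, read_len = 100L, insert_mean = 500,
                       insert_sd = 50, error_rate = 0.02,
                       genotype_freqs = c(0.7, 0.2, 0.1),
                       n_individuals = 10L, seed = 1L) {
  if (abs(sum(genotype_freqs) - 1) > 1e-9)
    abort("genotype_freqs must sum to 1")
  stopifnot(coverage > 0, read_len > 0, error_rate >= 0, error_rate < 1,
            insert_mean > 2 * read_len, insert_sd >= 0, n_individuals >= 1)
  structure(list(coverage = coverage, read_len = as.integer(read_len),
                 insert_mean = insert_mean, insert_sd = insert_sd,
                 error_rate = error_rate, genotype_freqs = genotype_freqs,
                 n_individuals = as.integer(n_individuals),
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf(paste0("<sim_config> %d individuals at %.1fx, reads %d bp, ",
                     "insert %.0f +/- %.0f bp, error %.1f%%, ",
                     "genotype freqs (%.2f, %.2f, %.2f), seed %d\n"),
              x$n_individuals, x$coverage, x$read_len, x$insert_mean,
              x$insert_sd, 100 * x$error_rate, x$genotype_freqs[1],
              x$genotype_freqs[2], x$genotype_freqs[3], x$seed))
  invisible(x)
}

#' Generate a random reference sequence
#'
#' i.i.d. uniform A/C/G/T, seed-stable. A desk-scale stand-in for a real
#' chromosome when only coordinates and coverage matter.
#'
#' @param length Reference length, bp.
#' @param seed Integer seed.
#' @param name Sequence name.
#' @return A list with `name`, `seq` (single character string) and
#'   `length`.
#' @export
random_reference <- function(length = 1e6, seed = 1L, name = "ref") {
  seq <- withr::with_seed(seed,
    paste(sample(c("A", "C", "G", "T"), length, replace = TRUE),
          collapse = ""))
  list(name = name, seq = seq, length = as.integer(length))
}

#' Draw non-overlapping indel sites on a reference
#'
#' Plants `n` indel sites with lengths log-uniform in `length_range`,
#' uniformly positioned subject to a minimum gap (so that the evidence
#' windows of neighbouring sites do not entangle) and an edge margin.
#'
#' @param n Number of sites.
#' @param ref_length Reference length, bp.
#' @param kind `"DEL"` or `"INS"` (scalar or length-`n`).
#' @param length_range Min/max indel length, bp.
#' @param min_gap Minimum distance between consecutive sites' breakpoints
#'   (default 2000, comfortably above insert mean + 3 SD).
#' @param margin Keep-out distance from the reference ends.
#' @param chrom Sequence name.
#' @param seed Integer seed.
#' @return A site tibble ([indel_sites()]).
#' @export
sim_sites <- function(n, ref_length, kind = "DEL",
                      length_range = c(50, 5000), min_gap = 2000,
                      margin = 2000, chrom = "ref", seed = 1L) {
  kind <- rep_len(kind, n)
  withr::with_seed(seed, {
    lens <- round(exp(runif(n, log(length_range[1]), log(length_range[2]))))
    extent <- ifelse(kind == "DEL", lens, 0L)
    # stick-breaking placement: distribute the free space between sites,
    # so the min_gap spacing holds by construction
    free <- ref_length - 2 * margin - sum(extent) - (n - 1) * min_gap
    if (free < 0)
      abort("could not place sites: reference too short for n/min_gap")
    cuts <- sort(runif(n, 0, free))
    p1 <- round(margin + cuts + (seq_len(n) - 1) * min_gap +
                  cumsum(c(0, extent[-n])))
    p2 <- ifelse(kind == "DEL", p1 + lens, p1)
    indel_sites(chrom, p1, p2, kind,
                length = lens,
                id = sprintf("%s_%03d", tolower(kind), seq_len(n)))
  })
}

sample_names <- function(n) sprintf("S%02d", seq_len(n))

#' Assign truth genotypes to a cohort
#'
#' Draws a genotype in \{0, 1, 2\} for every (individual, site) pair.
#' By default draws are i.i.d. from `cfg$genotype_freqs`; when
#' `allele_freq` is given (one value per site), genotypes are drawn
#' binomially from the per-site indel allele frequency
#' (`g ~ Binomial(2, af)`), which produces frequency-stratified cohorts.
#' Heterozygous carriers get a seed-deterministic haplotype assignment for
#' the single indel copy.
#'
#' @param sites Site tibble.
#' @param cfg [sim_config()].
#' @param allele_freq Optional per-site indel allele frequencies.
#' @return A truth tibble: `sample`, `site_id`, `genotype`, `hap`
#'   (1 or 2 for heterozygotes, `NA` otherwise).
#' @export
assign_truth_genotypes <- function(sites, cfg, allele_freq = NULL) {
  n <- cfg$n_individuals
  m <- nrow(sites)
  withr::with_seed(cfg$seed, {
    if (is.null(allele_freq)) {
      g <- sample(0:2, n * m, replace = TRUE, prob = cfg$genotype_freqs)
    } else {
      stopifnot(base::length(allele_freq) == m,
                all(allele_freq >= 0 & allele_freq <= 1))
      af <- rep(allele_freq, times = n)  # site-major within each sample
      g <- rbinom(n * m, 2L, af)
    }
    hap <- ifelse(g == 1L, sample(1:2, n * m, replace = TRUE), NA_integer_)
  })
  tibble(sample = rep(sample_names(n), each = m),
         site_id = rep(sites$site_id, times = n),
         genotype = as.integer(g), hap = as.integer(hap))
}

# --- haplotype coordinate maps -------------------------------------------

# blocks of one haplotype: tibble(hap_start, hap_end, ref_start, ref_end,
# ins_site) in 0-based half-open coords; ref_* are NA inside an inserted
# block, ins_site anchors it to the site's breakpoint
haplotype_map <- function(ref_length, applied_sites) {
  s <- applied_sites[order(applied_sites$p1), , drop = FALSE]
  blocks <- list()
  ref_cur <- 0L; hap_cur <- 0L; k <- 0L
  add <- function(hs, he, rs, re, ins) {
    k <<- k + 1L
    blocks[[k]] <<- tibble(hap_start = hs, hap_end = he, ref_start = rs,
                           ref_end = re, ins_site = ins)
  }
  for (i in seq_len(nrow(s))) {
    w <- s$p1[i] - ref_cur
    if (w > 0) add(hap_cur, hap_cur + w, ref_cur, s$p1[i], NA_character_)
    hap_cur <- hap_cur + w
    if (s$kind[i] == "DEL") {
      ref_cur <- s$p2[i]
    } else {
      add(hap_cur, hap_cur + s$length[i], NA_integer_, NA_integer_,
          s$site_id[i])
      hap_cur <- hap_cur + s$length[i]
      ref_cur <- s$p1[i]
    }
  }
  if (ref_length > ref_cur)
    add(hap_cur, hap_cur + (ref_length - ref_cur), ref_cur,
        as.integer(ref_length), NA_character_)
  m <- bind_rows(blocks)
  attr(m, "hap_length") <- if (nrow(m) > 0) max(m$hap_end) else 0L
  m
}

applied_for <- function(sites, truth_one, hap) {
  gt <- truth_one[match(sites$site_id, truth_one$site_id), ]
  keep <- gt$genotype == 2L | (gt$genotype == 1L & gt$hap == hap)
  sites[keep, , drop = FALSE]
}

#' Build the two haplotype sequences of one individual
#'
#' Applies the individual's indel genotypes to the reference by string
#' surgery: genotype 2 modifies both haplotypes, genotype 1 the assigned
#' one. A deletion removes `[p1, p2)`; an insertion inserts the site's
#' allele sequence at `p1` (a seed-stable random sequence per site unless
#' supplied). Sites must not overlap.
#'
#' @param reference A [random_reference()] list, or a character string.
#' @param sites Site tibble.
#' @param truth_one Truth rows ([assign_truth_genotypes()]) of one sample.
#' @param ins_seqs Named character vector of insertion allele sequences
#'   (names = site ids); generated with `seed` when missing.
#' @param seed Seed for generated insertion sequences.
#' @return A list with `h1`, `h2` (sequences), `map1`, `map2` (coordinate
#'   maps used for truth placements).
#' @export
build_haplotypes <- function(reference, sites, truth_one, ins_seqs = NULL,
                             seed = 1L) {
  refseq <- if (is.list(reference)) reference$seq else reference
  ref_len <- nchar(refseq)
  check_no_overlap(sites)
  ins_seqs <- ins_seqs %||% make_ins_seqs(sites, seed)
  surgery <- function(hap) {
    app <- applied_for(sites, truth_one, hap)
    if (nrow(app) == 0) return(refseq)
    app <- app[order(-app$p1), , drop = FALSE]  # right to left
    s <- refseq
    for (i in seq_len(nrow(app))) {
      if (app$kind[i] == "DEL") {
        s <- paste0(substr(s, 1, app$p1[i]), substr(s, app$p2[i] + 1, nchar(s)))
      } else {
        s <- paste0(substr(s, 1, app$p1[i]), ins_seqs[[app$site_id[i]]],
                    substr(s, app$p1[i] + 1, nchar(s)))
      }
    }
    s
  }
  list(h1 = surgery(1L), h2 = surgery(2L),
       map1 = haplotype_map(ref_len, applied_for(sites, truth_one, 1L)),
       map2 = haplotype_map(ref_len, applied_for(sites, truth_one, 2L)))
}

check_no_overlap <- function(sites) {
  for (ch in unique(sites$chrom)) {
    s <- sites %>% filter(.data$chrom == ch) %>% arrange(.data$p1)
    if (nrow(s) < 2) next
    ends <- pmax(s$p2, s$p1)
    clash <- which(s$p1[-1] < ends[-nrow(s)])
    if (base::length(clash) > 0)
      abort(paste0("overlapping sites: ",
                   paste(s$site_id[clash], s$site_id[clash + 1],
                         sep = " / ", collapse = "; ")))
  }
  invisible(sites)
}

make_ins_seqs <- function(sites, seed) {
  ins <- sites %>% filter(.data$kind == "INS")
  if (nrow(ins) == 0) return(character())
  withr::with_seed(seed, {
    setNames(vapply(ins$length, function(L)
      paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = ""),
      character(1)), ins$site_id)
  })
}

# --- fragment sampling ----------------------------------------------------

#' Simulate paired-end fragment placements for one individual
#'
#' Draws `round(coverage * G / (2 * read_len))` fragments (G = reference
#' length), split binomially between the two haplotypes, with lengths
#' Normal(`insert_mean`, `insert_sd`) truncated at `2 * read_len`, and
#' uniform starts. Mates are the first and last `read_len` bases of the
#' fragment (the second reverse-complemented when sequences are
#' materialized). Placements are independent of the base error process.
#'
#' @param hap_lengths Lengths of the two haplotypes.
#' @param ref_length Reference length G used for the pair count.
#' @param cfg [sim_config()].
#' @param seed Seed (one individual's stream).
#' @param sample Sample name stamped into read names.
#' @return An origin tibble: `qname`, `hap`, `frag_start` (0-based on the
#'   haplotype), `frag_len`.
#' @export
simulate_paired_reads <- function(hap_lengths, ref_length, cfg, seed,
                                  sample = "S01") {
  l <- cfg$read_len
  min_hap <- cfg$insert_mean + 6 * cfg$insert_sd
  if (any(hap_lengths <= min_hap))
    abort("haplotype too short for the insert-size distribution")
  n_pairs <- round(cfg$coverage * ref_length / (2 * l))
  withr::with_seed(seed, {
    hap <- rbinom(n_pairs, 1L, 0.5) + 1L
    frag <- pmax(2L * l, round(rnorm(n_pairs, cfg$insert_mean, cfg$insert_sd)))
    start <- floor(runif(n_pairs) * (hap_lengths[hap] - frag + 1))
    tibble(qname = sprintf("%s_p%06d", sample, seq_len(n_pairs)),
           hap = hap, frag_start = as.integer(start),
           frag_len = as.integer(frag))
  })
}

# --- truth placements -----------------------------------------------------

# lift read intervals [a, b) in haplotype coords through a haplotype map;
# returns a segment table (read = input index) in reference coords.
# Fast path: reads inside one reference block (the vast majority);
# junction-crossing reads are resolved one at a time.
lift_reads <- function(a, b, map, min_seg = 20L) {
  n <- base::length(a)
  bi_a <- findInterval(a, map$hap_start)
  bi_b <- findInterval(b - 1L, map$hap_start)
  ref_block <- !is.na(map$ref_start)
  same <- bi_a == bi_b
  easy <- same & ref_block[bi_a]
  res_easy <- if (any(easy)) {
    j <- bi_a[easy]
    data.frame(read = which(easy),
               start = map$ref_start[j] + (a[easy] - map$hap_start[j]),
               end = map$ref_start[j] + (b[easy] - map$hap_start[j]),
               clip_left = 0L, clip_right = 0L, primary = TRUE)
  } else NULL
  hard <- which(!same)  # reads inside an inserted block map nowhere
  res_hard <- vector("list", base::length(hard))
  for (h in seq_along(hard)) {
    i <- hard[h]
    segs <- NULL
    for (j in bi_a[i]:bi_b[i]) {
      lo <- max(a[i], map$hap_start[j]); hi <- min(b[i], map$hap_end[j])
      if (hi <= lo || !ref_block[j]) next
      segs <- rbind(segs, c(read_off = lo - a[i], len = hi - lo,
                            ref_start = map$ref_start[j] + (lo - map$hap_start[j])))
    }
    if (is.null(segs)) next
    l <- b[i] - a[i]
    segs <- segs[order(segs[, "ref_start"]), , drop = FALSE]
    if (nrow(segs) == 2 && all(segs[, "len"] >= min_seg) &&
        sum(segs[, "len"]) == l) {
      # clean deletion junction: split-mapped read, two segments
      prim <- which.max(segs[, "len"])
      res_hard[[h]] <- data.frame(
        read = i, start = segs[, "ref_start"],
        end = segs[, "ref_start"] + segs[, "len"],
        clip_left = segs[, "read_off"],
        clip_right = l - segs[, "read_off"] - segs[, "len"],
        primary = seq_len(2) == prim)
    } else {
      k <- which.max(segs[, "len"])
      res_hard[[h]] <- data.frame(
        read = i, start = segs[k, "ref_start"],
        end = segs[k, "ref_start"] + segs[k, "len"],
        clip_left = segs[k, "read_off"],
        clip_right = l - segs[k, "read_off"] - segs[k, "len"],
        primary = TRUE)
    }
  }
  out <- bind_rows(c(list(res_easy), res_hard))
  if (nrow(out) == 0)
    out <- data.frame(read = integer(), start = integer(), end = integer(),
                      clip_left = integer(), clip_right = integer(),
                      primary = logical())
  out
}

#' Truth-placement alignments for one individual
#'
#' Converts simulated fragment origins into the alignment records an ideal
#' soft-clipping aligner would produce, by lifting each mate's haplotype
#' interval back to reference coordinates: reads crossing a deletion
#' junction become split (two segments, when both pieces are at least
#' `min_seg` bp) or breakpoint-soft-clipped records; read portions inside
#' inserted sequence are clipped away, and reads entirely within an
#' insertion are unmapped. Template length is the outer reference distance
#' between the mates' primary segments.
#'
#' @param origins Origin tibble from [simulate_paired_reads()].
#' @param maps List of the two haplotype maps (`map1`, `map2` from
#'   [build_haplotypes()] or [haplotype_maps()]).
#' @param cfg [sim_config()].
#' @param sample Sample name.
#' @param chrom Reference sequence name.
#' @param min_seg Minimum mapped piece for a split segment (default 20 bp).
#' @param mapq Mapping quality stamped on the records (default 60).
#' @return An alignment-record tibble (see [alignment-records]).
#' @export
truth_alignments <- function(origins, maps, cfg, sample = "S01",
                             chrom = "ref", min_seg = 20L, mapq = 60L) {
  l <- cfg$read_len
  res <- vector("list", 2L)
  for (h in 1:2) {
    o <- origins %>% filter(.data$hap == h)
    if (nrow(o) == 0) next
    m1 <- lift_reads(o$frag_start, o$frag_start + l, maps[[h]], min_seg)
    m2 <- lift_reads(o$frag_start + o$frag_len - l,
                     o$frag_start + o$frag_len, maps[[h]], min_seg)
    res[[h]] <- assemble_pair_records(o$qname, m1, m2, sample, chrom, mapq)
  }
  bind_rows(res)
}

assemble_pair_records <- function(qname, s1, s2, sample, chrom, mapq) {
  n <- base::length(qname)
  # per-read primary span of each mate (one row per mapped read)
  prim <- function(s) {
    p <- s[s$primary, , drop = FALSE]
    ps <- pe <- rep(NA_integer_, n)
    ps[p$read] <- p$start; pe[p$read] <- p$end
    list(start = ps, end = pe)
  }
  p1 <- prim(s1); p2 <- prim(s2)
  mapped1 <- !is.na(p1$start); mapped2 <- !is.na(p2$start)
  both <- mapped1 & mapped2
  os <- pmin(p1$start, p2$start); oe <- pmax(p1$end, p2$end)
  tl <- oe - os
  left1 <- p1$start <= p2$start
  tlen1 <- ifelse(both, ifelse(left1, tl, -tl), 0L)
  tlen2 <- ifelse(both, ifelse(left1, -tl, tl), 0L)
  mk <- function(s, mate, tlen, mm, strand, mstrand_when_both) {
    if (nrow(s) == 0) return(NULL)
    tibble(sample = sample, qname = qname[s$read], mate = mate,
           chrom = chrom, start = as.integer(s$start),
           end = as.integer(s$end), clip_left = as.integer(s$clip_left),
           clip_right = as.integer(s$clip_right), mapq = as.integer(mapq),
           strand = strand, primary = s$primary,
           mate_mapped = mm[s$read],
           mate_strand = ifelse(mm[s$read], mstrand_when_both,
                                NA_character_),
           tlen = as.integer(tlen[s$read]))
  }
  out <- bind_rows(mk(s1, 1L, tlen1, mapped2, "+", "-"),
                   mk(s2, 2L, tlen2, mapped1, "-", "+"))
  if (nrow(out) == 0) empty_alignments() else out
}

#' Coordinate maps of an individual's haplotypes
#'
#' The coordinate-only counterpart of [build_haplotypes()]: builds the two
#' haplotype liftover maps without materializing sequences. Sufficient for
#' truth-placement simulation, where base content never matters.
#'
#' @param ref_length Reference length.
#' @param sites Site tibble.
#' @param truth_one One sample's truth rows.
#' @return List of two maps (`map1`, `map2`), each with a `hap_length`
#'   attribute.
#' @export
haplotype_maps <- function(ref_length, sites, truth_one) {
  check_no_overlap(sites)
  list(map1 = haplotype_map(ref_length, applied_for(sites, truth_one, 1L)),
       map2 = haplotype_map(ref_length, applied_for(sites, truth_one, 2L)))
}

#' Simulate a whole cohort with truth placements
#'
#' The simulator's main driver: assigns truth genotypes, builds each
#' individual's haplotype coordinate maps, samples fragments at the
#' configured coverage, and lifts them back to the reference as
#' truth-placement alignment records. All randomness derives from
#' `cfg$seed`; identical configurations reproduce identical cohorts.
#'
#' @param sites Site tibble.
#' @param cfg [sim_config()].
#' @param ref_length Reference length (default: past the last site plus a
#'   2 kb margin).
#' @param allele_freq Optional per-site allele frequencies (see
#'   [assign_truth_genotypes()]).
#' @param chrom Reference sequence name.
#' @return A list with `truth` (truth tibble), `alignments` (combined
#'   alignment-record tibble), `sites`, `cfg` and `ref_length`.
#' @export
simulate_cohort <- function(sites, cfg, ref_length = NULL,
                            allele_freq = NULL, chrom = "ref") {
  ref_length <- as.integer(ref_length %||% (max(sites$p2) + 2000L))
  truth <- assign_truth_genotypes(sites, cfg, allele_freq = allele_freq)
  smps <- sample_names(cfg$n_individuals)
  aln <- vector("list", base::length(smps))
  for (i in seq_along(smps)) {
    t1 <- truth %>% filter(.data$sample == smps[i])
    maps <- haplotype_maps(ref_length, sites, t1)
    hl <- c(attr(maps$map1, "hap_length"), attr(maps$map2, "hap_length"))
    org <- simulate_paired_reads(hl, ref_length, cfg,
                                 seed = cfg$seed + 1000L + i,
                                 sample = smps[i])
    aln[[i]] <- truth_alignments(org, maps, cfg, sample = smps[i],
                                 chrom = chrom)
  }
  list(truth = truth, alignments = bind_rows(aln), sites = sites,
       cfg = cfg, ref_length = ref_length)
}

#' Simulate trio truth genotypes
#'
#' Parents are drawn from the configured genotype frequencies; the child
#' inherits one allele from each parent (a heterozygous parent transmits
#' the indel allele with probability 1/2). By construction the resulting
#' triples never violate Mendelian inheritance.
#'
#' @param sites Site tibble.
#' @param cfg [sim_config()] (`n_individuals` is ignored; a trio is 3).
#' @return A tibble: `site_id`, `father`, `mother`, `child`.
#' @export
simulate_trio_truth <- function(sites, cfg) {
  m <- nrow(sites)
  withr::with_seed(cfg$seed, {
    f <- sample(0:2, m, replace = TRUE, prob = cfg$genotype_freqs)
    mo <- sample(0:2, m, replace = TRUE, prob = cfg$genotype_freqs)
    child <- rbinom(m, 1L, f / 2) + rbinom(m, 1L, mo / 2)
  })
  tibble(site_id = sites$site_id, father = as.integer(f),
         mother = as.integer(mo), child = as.integer(child))
}

# --- sequence materialization and file output -----------------------------

#' Materialize read sequences with substitution errors
#'
#' Extracts mate sequences from the haplotype strings (mate 2
#' reverse-complemented) and applies i.i.d. per-base substitutions at the
#' configured error rate, seed-stable.
#'
#' @param origins Origin tibble.
#' @param haps List with `h1`, `h2` haplotype sequences
#'   ([build_haplotypes()]).
#' @param cfg [sim_config()].
#' @param seed Seed for the error process.
#' @return `origins` with `seq1` and `seq2` columns added.
#' @export
read_sequences <- function(origins, haps, cfg, seed = 1L) {
  l <- cfg$read_len
  hseq <- c(haps$h1, haps$h2)[origins$hap]
  s1 <- substr(hseq, origins$frag_start + 1L, origins$frag_start + l)
  e <- origins$frag_start + origins$frag_len
  s2 <- revcomp(substr(hseq, e - l + 1L, e))
  withr::with_seed(seed, {
    s1 <- add_substitutions(s1, cfg$error_rate)
    s2 <- add_substitutions(s2, cfg$error_rate)
  })
  origins %>% mutate(seq1 = s1, seq2 = s2)
}

revcomp <- function(x) {
  comp <- chartr("ACGTacgt", "TGCAtgca", x)
  vapply(strsplit(comp, ""), function(ch) paste(rev(ch), collapse = ""),
         character(1))
}

add_substitutions <- function(reads, rate) {
  if (rate <= 0 || base::length(reads) == 0) return(reads)
  l <- nchar(reads[1])
  n_err <- rbinom(1L, base::length(reads) * l, rate)
  if (n_err == 0) return(reads)
  ri <- sample.int(base::length(reads), n_err, replace = TRUE)
  pos <- sample.int(l, n_err, replace = TRUE)
  shift <- sample.int(3L, n_err, replace = TRUE)
  bases <- c("A", "C", "G", "T")
  for (k in seq_len(n_err)) {
    old <- substr(reads[ri[k]], pos[k], pos[k])
    idx <- match(old, bases)
    if (is.na(idx)) next
    substr(reads[ri[k]], pos[k], pos[k]) <- bases[(idx - 1L + shift[k]) %% 4L + 1L]
  }
  reads
}

#' Write simulated reads as paired FASTQ
#'
#' @param origins_with_seq Output of [read_sequences()].
#' @param prefix Output path prefix; writes `<prefix>_1.fastq` and
#'   `<prefix>_2.fastq` with `/1`, `/2` read-name suffixes and uniform
#'   quality `I`.
#' @return The two paths, invisibly.
#' @export
write_sim_fastq <- function(origins_with_seq, prefix) {
  p1 <- paste0(prefix, "_1.fastq"); p2 <- paste0(prefix, "_2.fastq")
  q <- strrep("I", nchar(origins_with_seq$seq1[1]))
  writeLines(rbind(paste0("@", origins_with_seq$qname, "/1"),
                   origins_with_seq$seq1, "+", q), p1)
  writeLines(rbind(paste0("@", origins_with_seq$qname, "/2"),
                   origins_with_seq$seq2, "+", q), p2)
  invisible(c(p1, p2))
}

#' Write a reference as FASTA
#'
#' @param reference [random_reference()] list (or `name` + `seq`).
#' @param path Output path.
#' @param width Line width.
#' @return `path`, invisibly.
#' @export
write_reference_fasta <- function(reference, path, width = 70L) {
  seq <- reference$seq
  starts <- seq(1L, nchar(seq), by = width)
  writeLines(c(paste0(">", reference$name),
               substring(seq, starts, pmin(starts + width - 1L, nchar(seq)))),
             path)
  invisible(path)
}

#' Write truth genotypes as VCF (plus TSV mirror)
#'
#' One record per site with per-sample `GT` (0 -> 0/0, 1 -> 0/1,
#' 2 -> 1/1), `SVTYPE`, `END` and `SVLEN`; a `.tsv` mirror with the long
#' truth table is written next to it.
#'
#' @param truth Truth tibble.
#' @param sites Site tibble.
#' @param path Output `.vcf` path.
#' @return `path`, invisibly.
#' @export
write_truth_vcf <- function(truth, sites, path) {
  smps <- unique(truth$sample)
  gt_map <- c(`0` = "0/0", `1` = "0/1", `2` = "1/1")
  wide <- truth %>%
    mutate(gt = gt_map[as.character(.data$genotype)]) %>%
    select("sample", "site_id", "gt") %>%
    tidyr::pivot_wider(names_from = "sample", values_from = "gt")
  wide <- wide[match(sites$site_id, wide$site_id), , drop = FALSE]
  hdr <- c("##fileformat=VCFv4.2",
           "##INFO=<ID=SVTYPE,Number=1,Type=String,Description=\"SV type\">",
           "##INFO=<ID=END,Number=1,Type=Integer,Description=\"End position\">",
           "##INFO=<ID=SVLEN,Number=1,Type=Integer,Description=\"SV length\">",
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", smps), collapse = "\t"))
  svlen <- ifelse(sites$kind == "DEL", -sites$length, sites$length)
  info <- paste0("SVTYPE=", sites$kind, ";END=",
                 ifelse(sites$kind == "INS", sites$p1 + 1L, sites$p2),
                 ";SVLEN=", svlen)
  alt <- ifelse(sites$kind == "DEL", "<DEL>", "<INS>")
  body <- paste(sites$chrom, sites$p1 + 1L, sites$site_id, "N", alt, ".",
                "PASS", info, "GT",
                apply(as.matrix(wide[, smps, drop = FALSE]), 1, paste,
                      collapse = "\t"),
                sep = "\t")
  writeLines(c(hdr, body), path)
  readr::write_tsv(truth, sub("\\.vcf$", ".tsv", path))
  invisible(path)
}
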