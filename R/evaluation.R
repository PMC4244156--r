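#' Length bins used for stratified reporting
#'
#' Deletion-length strata for accuracy tables: 50–200, 200–400, 400–500,
#' 500–1500 and >1500 bp.
#'
#' @param length Numeric vector of indel lengths.
#' @return Factor of bin labels.
#' @export
length_strata <- function(length) {
  cut(length, breaks = c(0, 200, 400, 500, 1500, Inf),
      labels = c("50-200", "200-400", "400-500", "500-1500", ">1500"),
      right = FALSE)
}

#' Genotype accuracy, stratified
#'
#' Scores calls against truth per stratum. `strata = "length"` bins sites
#' by indel length ([length_strata()]); `strata = "frequency"` bins by the
#' site's indel frequency in the truth (number of individuals carrying at
#' least one indel allele — a property of the population, so it is always
#' computed from truth, not from calls); `strata = "none"` gives the
#' overall row only. Calls with missing genotypes are excluded from the
#' accuracy denominator and tallied in `n_missing`.
#'
#' @param calls Tibble with `sample`, `site_id`, `genotype`.
#' @param truth Truth tibble with `sample`, `site_id`, `genotype`.
#' @param sites Site tibble (needed for `strata = "length"`).
#' @param strata `"length"`, `"frequency"`, or `"none"`.
#' @param freq_breaks Right-closed upper bounds of the frequency bins;
#'   default 5, 15, 30 and the cohort size (bins 0–5, 6–15, 16–30, 31–n).
#' @return A tibble with one row per stratum plus an `overall` row:
#'   `stratum`, `n_sites`, `n_genotypes`, `n_missing`, `accuracy`.
#' @export
stratified_accuracy <- function(calls, truth, sites = NULL,
                                strata = c("length", "frequency", "none"),
                                freq_breaks = NULL) {
  strata <- match.arg(strata)
  orphans <- anti_join(calls, truth, by = c("sample", "site_id"))
  if (nrow(orphans) > 0)
    abort(paste0("calls with no matching truth for ", nrow(orphans),
                 " (sample, site) pairs, e.g. ", orphans$sample[1], "/",
                 orphans$site_id[1]))
  joined <- truth %>%
    select("sample", "site_id", truth_g = "genotype") %>%
    left_join(select(calls, "sample", "site_id", call_g = "genotype"),
              by = c("sample", "site_id"))
  joined <- switch(strata,
    none = mutate(joined, stratum = "overall"),
    length = {
      if (is.null(sites)) abort("length strata need the site table")
      joined %>%
        left_join(select(sites, "site_id", "length"), by = "site_id") %>%
        mutate(stratum = as.character(length_strata(.data$length)))
    },
    frequency = {
      freq <- truth %>%
        group_by(.data$site_id) %>%
        summarise(freq = sum(.data$genotype >= 1L), .groups = "drop")
      n_ind <- dplyr::n_distinct(truth$sample)
      brk <- freq_breaks %||% c(5, 15, 30, n_ind)
      lab <- paste0(c(0, head(brk, -1) + 1), "-", brk)
      joined %>%
        left_join(freq, by = "site_id") %>%
        mutate(stratum = as.character(
          cut(.data$freq, breaks = c(-1, brk), labels = lab)))
    })
  score <- function(d, label) {
    tibble(stratum = label,
           n_sites = dplyr::n_distinct(d$site_id),
           n_genotypes = sum(!is.na(d$call_g)),
           n_missing = sum(is.na(d$call_g)),
           accuracy = if (any(!is.na(d$call_g)))
             mean(d$call_g[!is.na(d$call_g)] == d$truth_g[!is.na(d$call_g)])
           else NA_real_)
  }
  per <- joined %>%
    dplyr::group_split(.data$stratum) %>%
    map_dfr(~ score(.x, .x$stratum[1]))
  if (strata != "none") per <- bind_rows(per, score(joined, "overall"))
  per
}

# the eight parent-unordered trio genotype triples impossible under
# biallelic Mendelian inheritance, written (parent, parent, child)
mendelian_impossible_triples <- function() {
  matrix(c(0, 0, 1,
           0, 0, 2,
           0, 1, 2,
           0, 2, 0,
           0, 2, 2,
           1, 2, 0,
           2, 2, 0,
           2, 2, 1), ncol = 3, byrow = TRUE,
         dimnames = list(NULL, c("parent1", "parent2", "child")))
}

#' Mendelian trio metrics
#'
#' Flags each (father, mother, child) genotype triple that is impossible
#' under biallelic inheritance — the eight parent-unordered cases
#' (0,0,1), (0,0,2), (0,1,2), (0,2,0), (0,2,2), (1,2,0), (2,2,0),
#' (2,2,1) — and counts all-zero triples (0,0,0), which at sites known to
#' carry the indel in the trio indicate a genotyping error. Triples with
#' any missing genotype are excluded from both counts and tallied
#' separately.
#'
#' @param trios Tibble with `father`, `mother`, `child` genotypes (0/1/2
#'   or `NA`), one row per site; other columns (e.g. `site_id`) pass
#'   through.
#' @return A list with `per_site` (input plus `discordant`, `all_zero`)
#'   and counts `n_discordant`, `n_all_zero`, `n_missing`, `n_total`.
#' @export
trio_discordance <- function(trios) {
  g <- trios[, c("father", "mother", "child")]
  ok <- stats::complete.cases(g)
  if (!all(unlist(g[ok, ]) %in% 0:2))
    abort("genotypes must be 0, 1, 2 or NA")
  bad <- mendelian_impossible_triples()
  key <- function(p1, p2, ch) paste(pmin(p1, p2), pmax(p1, p2), ch)
  bad_keys <- key(bad[, 1], bad[, 2], bad[, 3])
  disc <- rep(NA, nrow(g))
  disc[ok] <- key(g$father[ok], g$mother[ok], g$child[ok]) %in% bad_keys
  az <- rep(NA, nrow(g))
  az[ok] <- g$father[ok] == 0L & g$mother[ok] == 0L & g$child[ok] == 0L
  list(per_site = mutate(trios, discordant = disc, all_zero = az),
       n_discordant = sum(disc, na.rm = TRUE),
       n_all_zero = sum(az, na.rm = TRUE),
       n_missing = sum(!ok),
       n_total = sum(ok))
}

#' Randomly downsample read templates
#'
#' Emulates lower sequencing coverage by keeping each template (read pair,
#' both mates atomically) independently with probability `fraction`,
#' seed-deterministically.
#'
#' @param alignments Alignment-record tibble.
#' @param fraction Keep probability in `[0, 1]`.
#' @param seed Integer seed.
#' @return The downsampled alignment tibble.
#' @export
downsample_reads <- function(alignments, fraction, seed = 1L) {
  if (fraction < 0 || fraction > 1)
    abort("fraction must be in [0, 1]")
  check_alignments(alignments)
  keys <- unique(alignments[, c("sample", "qname")])
  kept <- withr::with_seed(seed,
    keys[runif(nrow(keys)) <= fraction, , drop = FALSE])
  inner_join(alignments, kept, by = c("sample", "qname"))
}

#' Count genotypes changed by downsampling
#'
#' Compares calls on reduced-coverage data against full-coverage calls:
#' a genotype counts as changed when it differs or is absent in the
#' reduced calls. The denominator is the full-call universe.
#'
#' @param full_calls,reduced_calls Call tibbles (`sample`, `site_id`,
#'   `genotype`).
#' @return A list with `n_changed`, `n_total` and `fraction`.
#' @export
changed_genotypes <- function(full_calls, reduced_calls) {
  cmp <- full_calls %>%
    select("sample", "site_id", full_g = "genotype") %>%
    left_join(select(reduced_calls, "sample", "site_id",
                     red_g = "genotype"),
              by = c("sample", "site_id"))
  changed <- is.na(cmp$red_g) | cmp$red_g != cmp$full_g
  list(n_changed = sum(changed), n_total = nrow(cmp),
       fraction = mean(changed))
}

#' Read genotype calls from a truth/call TSV or VCF
#'
#' Accepts the TSV mirror written by [write_truth_vcf()] (columns
#' `sample`, `site_id`, `genotype`) or a VCF with per-sample `GT` fields
#' (0/0, 0/1, 1/1, or `./.` for missing).
#'
#' @param path File path.
#' @return A call tibble: `sample`, `site_id`, `genotype`.
#' @export
read_genotypes <- function(path) {
  if (!grepl("\\.vcf(\\.gz)?$", path))
    return(readr::read_tsv(path, show_col_types = FALSE) %>%
             select("sample", "site_id", "genotype"))
  if (!requireNamespace("vcfR", quietly = TRUE))
    abort("reading VCF genotypes requires the vcfR package")
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  ids <- vcfR::getFIX(v)[, "ID"]
  as_tibble(gt) %>%
    mutate(site_id = ids) %>%
    tidyr::pivot_longer(-"site_id", names_to = "sample",
                        values_to = "gt") %>%
    mutate(genotype = dplyr::case_when(
      .data$gt %in% c("0/0", "0|0") ~ 0L,
      .data$gt %in% c("0/1", "1/0", "0|1", "1|0") ~ 1L,
      .data$gt %in% c("1/1", "1|1") ~ 2L,
      TRUE ~ NA_integer_)) %>%
    select("sample", "site_id", "genotype")
}
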