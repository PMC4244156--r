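#' Evidence-collection configuration
#'
#' Tunable thresholds of the read-evidence rules. `n_sigma` sets the width
#' of the concordance/discordance insert-size windows (`mu +/- n_sigma *
#' sigma`, the conventional choice of the discordant-pair literature);
#' `clip_slack` is the breakpoint tolerance for clipped/split reads (reads
#' clipped within `clip_slack` bp of a breakpoint count as clipped at the
#' breakpoint); `mapq_min` defines a well-mapped read; `window_pad`
#' overrides the relevant-read window extension `D` (default
#' `mu + n_sigma * sigma`, one maximal insert).
#'
#' @param n_sigma Window multiplier on the insert-size SD (default 3).
#' @param clip_slack Clip-vs-breakpoint tolerance in bp (default 15).
#' @param mapq_min Minimum mapping quality of a well-mapped read
#'   (default 20).
#' @param window_pad Optional fixed relevant-read window extension in bp;
#'   `NULL` means `mu + n_sigma * sigma`.
#' @return An `evidence_config` list.
#' @examples
#' evidence_config()
#' evidence_config(clip_slack = 10)
#' @export
evidence_config <- function(n_sigma = 3, clip_slack = 15, mapq_min = 20,
                            window_pad = NULL) {
  stopifnot(n_sigma >= 0, clip_slack >= 0, mapq_min >= 0,
            is.null(window_pad) || window_pad >= 0)
  structure(list(n_sigma = n_sigma, clip_slack = clip_slack,
                 mapq_min = mapq_min, window_pad = window_pad),
            class = "evidence_config")
}

window_pad_of <- function(lib, cfg) {
  cfg$window_pad %||% (lib$mu + cfg$n_sigma * lib$sigma)
}

#' Relevant-read window around an indel site
#'
#' Reads can carry evidence for an indel only if they start within one
#' maximal insert of a breakpoint, so the fetch window is the site extended
#' by `D = mu + n_sigma * sigma` (or the configured `window_pad`) on both
#' sides, clipped at the contig start.
#'
#' @param site One row of a site tibble (or a list with `chrom`, `p1`,
#'   `p2`).
#' @param lib [library_stats()].
#' @param cfg [evidence_config()].
#' @return A list with `chrom`, `start`, `end` (0-based half-open).
#' @examples
#' s <- indel_sites("chr1", 10000, 10400, "DEL")
#' relevant_region(s[1, ], library_stats(500, 50, 100), evidence_config())
#' @export
relevant_region <- function(site, lib, cfg = evidence_config()) {
  d <- window_pad_of(lib, cfg)
  list(chrom = site$chrom,
       start = max(0L, as.integer(floor(site$p1 - d))),
       end = as.integer(ceiling(site$p2 + d)))
}

pair_class_levels <- c("DISCORDANT_SUPPORT", "CONCORDANT",
                       "SINGLE_END_MAPPED", "INVALID", "UNINFORMATIVE")
span_class_levels <- c("SPLIT", "PARTIAL", "FULL", "NONE")

#' Classify read pairs against an indel site
#'
#' Applies the insert-size evidence rules to pair summaries. A both-mapped
#' forward–reverse pair whose outer interval strictly contains a breakpoint
#' is *encompassing*; it supports the indel allele
#' (`DISCORDANT_SUPPORT`) when its insert size matches the indel-adjusted
#' expectation `mu + L` (deletion) or `mu - L` (insertion) within
#' `n_sigma * sigma`, supports a wild-type allele (`CONCORDANT`) when it
#' matches the plain library insert `mu` within the same window, and is
#' discarded as likely mismapped (`INVALID`) when the insert exceeds both
#' windows' upper bounds. A pair with exactly one mapped mate is
#' `SINGLE_END_MAPPED` — informative only at insertion sites, where the
#' unmapped mate may originate inside the inserted sequence. Everything
#' else is `UNINFORMATIVE`.
#'
#' @param pairs Tibble of pair summaries with columns `n_mapped` (1 or 2),
#'   `insert` (outer distance, bp), `outer_start`, `outer_end` (0-based
#'   half-open template span) and `innie` (forward–reverse orientation);
#'   `insert`/`outer_*`/`innie` may be `NA` when `n_mapped < 2`.
#' @param site One site-tibble row.
#' @param lib [library_stats()].
#' @param cfg [evidence_config()].
#' @return Character vector of pair classes, one per row of `pairs`.
#' @export
classify_pair <- function(pairs, site, lib, cfg = evidence_config()) {
  need <- c("n_mapped", "insert", "outer_start", "outer_end", "innie")
  miss <- setdiff(need, names(pairs))
  if (base::length(miss) > 0)
    abort(paste0("pair summary is missing column(s): ",
                 paste(miss, collapse = ", ")))
  w <- cfg$n_sigma * lib$sigma
  l_adj <- if (site$kind == "DEL") site$length else -site$length
  out <- rep("UNINFORMATIVE", nrow(pairs))

  single <- pairs$n_mapped == 1L
  out[single] <- if (site$kind == "INS") "SINGLE_END_MAPPED" else "UNINFORMATIVE"

  both <- !single & pairs$n_mapped == 2L & !is.na(pairs$insert) & pairs$innie
  enc <- both &
    ((pairs$outer_start < site$p1 & pairs$outer_end > site$p1) |
       (pairs$outer_start < site$p2 & pairs$outer_end > site$p2))
  disc <- enc & abs(pairs$insert - lib$mu - l_adj) <= w
  conc <- enc & !disc & abs(pairs$insert - lib$mu) <= w
  inval <- enc & !disc & !conc &
    pairs$insert > max(lib$mu, lib$mu + l_adj) + w
  out[disc] <- "DISCORDANT_SUPPORT"
  out[conc] <- "CONCORDANT"
  out[inval] <- "INVALID"
  out
}

#' Classify spanning reads against an indel site
#'
#' Applies the clip/split evidence rules to one read (possibly split into
#' several mapped segments). For deletions, a read mapped as two segments
#' whose inner edges fall within `clip_slack` of the two breakpoints is a
#' `SPLIT` read. A soft-clipped read whose clip boundary falls within
#' `clip_slack` of either breakpoint is `PARTIAL`. A read mapped
#' end-to-end (clips no longer than `clip_slack`) whose aligned span has at
#' least one aligned base on each side of a breakpoint is `FULL` — evidence
#' for a wild-type allele. Anything else is `NONE`. Split reads are not
#' used at insertion sites (a read cannot map as two reference segments
#' around inserted sequence).
#'
#' @param segments Tibble of mapped segments of *one* read (columns
#'   `start`, `end`, `clip_left`, `clip_right`), sorted or not.
#' @param site One site-tibble row.
#' @param cfg [evidence_config()].
#' @return One of `"SPLIT"`, `"PARTIAL"`, `"FULL"`, `"NONE"`.
#' @export
classify_spanning_read <- function(segments, site, cfg = evidence_config()) {
  c_ <- cfg$clip_slack
  segments <- segments[order(segments$start), , drop = FALSE]
  n <- nrow(segments)
  if (n == 0) return("NONE")
  if (site$kind == "DEL" && n >= 2) {
    left <- segments[1, ]; right <- segments[n, ]
    if (abs(left$end - site$p1) <= c_ && abs(right$start - site$p2) <= c_)
      return("SPLIT")
  }
  bks <- unique(c(site$p1, site$p2))
  for (i in seq_len(n)) {
    s <- segments[i, ]
    if ((s$clip_left > 0 && any(abs(s$start - bks) <= c_)) ||
        (s$clip_right > 0 && any(abs(s$end - bks) <= c_)))
      return("PARTIAL")
  }
  for (i in seq_len(n)) {
    s <- segments[i, ]
    if (s$clip_left <= c_ && s$clip_right <= c_ &&
        any(s$start < bks & s$end > bks))
      return("FULL")
  }
  "NONE"
}

#' Tally read evidence at indel sites
#'
#' The workhorse of feature extraction: for every `(sample, site)` pair it
#' fetches the records whose leftmost mapped base lies in
#' [relevant_region()], drops templates whose fetched records are all below
#' `mapq_min` (pairs with both mates low-quality or unmapped carry no
#' usable signal), classifies each surviving template once with
#' [classify_pair()] and each read once with [classify_spanning_read()]
#' (multi-aligned reads are deduplicated by template name and mate), and
#' returns the summed category counts.
#'
#' @param alignments Alignment-record tibble (see [alignment-records]),
#'   one or more samples.
#' @param sites Site tibble from [indel_sites()].
#' @param lib [library_stats()].
#' @param cfg [evidence_config()].
#' @return A tibble with one row per `(sample, site_id)` and columns
#'   `n_discordant`, `n_concordant`, `n_single_end_mapped`, `n_split`,
#'   `n_partial`, `n_full` (zero rows are included for sites with no
#'   relevant reads).
#' @export
collect_evidence <- function(alignments, sites, lib, cfg = evidence_config()) {
  check_alignments(alignments)
  samples <- unique(alignments$sample)
  grid <- tidyr::expand_grid(sample = samples, site_id = sites$site_id)
  zero <- grid %>%
    mutate(n_discordant = 0L, n_concordant = 0L, n_single_end_mapped = 0L,
           n_split = 0L, n_partial = 0L, n_full = 0L)
  hits <- site_read_assignments(alignments, sites, lib, cfg)
  if (nrow(hits) == 0) return(zero)

  # template-level mapq filter: keep a template at a site if any of its
  # fetched records is well-mapped
  hits <- hits %>%
    group_by(.data$sample, .data$site_id, .data$qname) %>%
    filter(max(.data$mapq) >= cfg$mapq_min) %>%
    ungroup()
  if (nrow(hits) == 0) return(zero)

  pair_counts <- count_pair_classes(hits, sites, lib, cfg)
  span_counts <- count_span_classes(hits, sites, cfg)

  out <- zero %>%
    select("sample", "site_id") %>%
    left_join(pair_counts, by = c("sample", "site_id")) %>%
    left_join(span_counts, by = c("sample", "site_id"))
  count_cols <- c("n_discordant", "n_concordant", "n_single_end_mapped",
                  "n_split", "n_partial", "n_full")
  for (cc in setdiff(count_cols, names(out))) out[[cc]] <- 0L
  out %>%
    mutate(across(all_of(count_cols), ~ tidyr::replace_na(.x, 0L))) %>%
    select("sample", "site_id", all_of(count_cols))
}

# assign fetched records to sites: record start within the relevant region
site_read_assignments <- function(alignments, sites, lib, cfg) {
  d <- window_pad_of(lib, cfg)
  out <- vector("list", base::length(unique(sites$chrom)))
  k <- 0L
  for (ch in unique(sites$chrom)) {
    s_ch <- sites %>% filter(.data$chrom == ch)
    a_ch <- alignments %>% filter(.data$chrom == ch)
    if (nrow(a_ch) == 0) next
    reg <- IRanges::IRanges(pmax(0L, as.integer(floor(s_ch$p1 - d))) + 1L,
                            as.integer(ceiling(s_ch$p2 + d)))
    pts <- IRanges::IRanges(a_ch$start + 1L, a_ch$start + 1L)
    ov <- IRanges::findOverlaps(pts, reg)
    if (base::length(ov) == 0) next
    k <- k + 1L
    out[[k]] <- a_ch[S4Vectors::queryHits(ov), ] %>%
      mutate(site_id = s_ch$site_id[S4Vectors::subjectHits(ov)])
  }
  if (k == 0L) return(mutate(empty_alignments(), site_id = character()))
  bind_rows(out[seq_len(k)])
}

# one pair classification per (sample, site, template); vectorized —
# classify_pair() is the reference rule set and tests assert agreement
count_pair_classes <- function(hits, sites, lib, cfg) {
  # representative record per template: prefer primary, then the mate
  # carrying a positive template length (the forward mate of an fr pair)
  reps <- hits %>%
    mutate(has_tlen = !is.na(.data$tlen) & .data$tlen != 0L) %>%
    arrange(.data$sample, .data$site_id, .data$qname,
            dplyr::desc(.data$primary), dplyr::desc(.data$has_tlen),
            dplyr::desc(.data$tlen)) %>%
    distinct(.data$sample, .data$site_id, .data$qname, .keep_all = TRUE) %>%
    mutate(
      n_mapped = ifelse(.data$mate_mapped, 2L, 1L),
      insert = ifelse(.data$has_tlen, abs(as.numeric(.data$tlen)), NA_real_),
      outer_start = dplyr::case_when(
        !.data$has_tlen ~ NA_real_,
        .data$tlen > 0L ~ as.numeric(.data$start),
        TRUE ~ as.numeric(.data$end + .data$tlen)),
      outer_end = dplyr::case_when(
        !.data$has_tlen ~ NA_real_,
        .data$tlen > 0L ~ as.numeric(.data$start + .data$tlen),
        TRUE ~ as.numeric(.data$end)),
      innie = dplyr::case_when(
        !.data$has_tlen ~ FALSE,
        .data$tlen > 0L ~ .data$strand == "+" &
          !is.na(.data$mate_strand) & .data$mate_strand == "-",
        TRUE ~ .data$strand == "-" &
          !is.na(.data$mate_strand) & .data$mate_strand == "+"))
  out <- reps %>%
    dplyr::group_split(.data$site_id) %>%
    map_dfr(function(g) {
      s <- sites[match(g$site_id[1], sites$site_id), ]
      g$class <- classify_pair(g, site = s, lib = lib, cfg = cfg)
      g
    })
  out %>%
    count(.data$sample, .data$site_id, .data$class) %>%
    filter(.data$class %in% c("DISCORDANT_SUPPORT", "CONCORDANT",
                              "SINGLE_END_MAPPED")) %>%
    mutate(class = dplyr::recode(.data$class,
                                 DISCORDANT_SUPPORT = "n_discordant",
                                 CONCORDANT = "n_concordant",
                                 SINGLE_END_MAPPED = "n_single_end_mapped")) %>%
    tidyr::pivot_wider(names_from = "class", values_from = "n",
                       values_fill = 0L)
}

# one span classification per (sample, site, template, mate); vectorized —
# classify_spanning_read() is the reference rule set
count_span_classes <- function(hits, sites, cfg) {
  c_ <- cfg$clip_slack
  ann <- hits %>%
    inner_join(select(sites, "site_id", "kind", "p1", "p2"), by = "site_id") %>%
    mutate(
      near1s = abs(.data$start - .data$p1) <= c_,
      near2s = abs(.data$start - .data$p2) <= c_,
      near1e = abs(.data$end - .data$p1) <= c_,
      near2e = abs(.data$end - .data$p2) <= c_,
      partial = (.data$clip_left > 0 & (.data$near1s | .data$near2s)) |
        (.data$clip_right > 0 & (.data$near1e | .data$near2e)),
      full = .data$clip_left <= c_ & .data$clip_right <= c_ &
        ((.data$start < .data$p1 & .data$end > .data$p1) |
           (.data$start < .data$p2 & .data$end > .data$p2)))
  per_read <- ann %>%
    group_by(.data$sample, .data$site_id, .data$qname, .data$mate) %>%
    summarise(kind = .data$kind[1], n_seg = n(),
              any_partial = any(.data$partial), any_full = any(.data$full),
              left_end = .data$end[which.min(.data$start)],
              right_start = max(.data$start),
              p1 = .data$p1[1], p2 = .data$p2[1], .groups = "drop") %>%
    mutate(
      split = .data$kind == "DEL" & .data$n_seg >= 2L &
        abs(.data$left_end - .data$p1) <= c_ &
        abs(.data$right_start - .data$p2) <= c_,
      class = dplyr::case_when(.data$split ~ "SPLIT",
                               .data$any_partial ~ "PARTIAL",
                               .data$any_full ~ "FULL",
                               TRUE ~ "NONE"))
  per_read %>%
    count(.data$sample, .data$site_id, .data$class) %>%
    filter(.data$class %in% c("SPLIT", "PARTIAL", "FULL")) %>%
    mutate(class = dplyr::recode(.data$class, SPLIT = "n_split",
                                 PARTIAL = "n_partial", FULL = "n_full")) %>%
    tidyr::pivot_wider(names_from = "class", values_from = "n",
                       values_fill = 0L)
}
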