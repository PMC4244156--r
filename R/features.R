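#' Mean read depth of a region
#'
#' The read-depth signature: the average of per-base mapped-read coverage
#' over a region, `sum(d_i) / L_r`.
#'
#' @param depth Numeric vector of per-base depths over the region.
#' @return The mean depth.
#' @examples
#' mean_region_depth(c(0, 1, 2, 3))
#' @export
mean_region_depth <- function(depth) {
  if (base::length(depth) == 0) abort("mean_region_depth(): empty region")
  if (any(depth < 0)) abort("mean_region_depth(): negative depth")
  mean(depth)
}

#' Per-sample coverage profiles
#'
#' Builds a per-base coverage run-length encoding per `(sample, chrom)`
#' from the aligned spans of the records (clipped bases do not contribute).
#' Used by [local_coverage()] and [extract_features()].
#'
#' @param alignments Alignment-record tibble.
#' @return A nested list `cov[[sample]][[chrom]]` of [IRanges::coverage()]
#'   Rle objects, with attribute `mean_cov` (named per sample): aligned
#'   bases divided by the spanned reference extent — the sample-wide
#'   fallback coverage.
#' @export
coverage_profiles <- function(alignments) {
  check_alignments(alignments)
  out <- list()
  mean_cov <- c()
  for (smp in unique(alignments$sample)) {
    a <- alignments %>% filter(.data$sample == smp)
    out[[smp]] <- list()
    tot_bases <- 0; tot_span <- 0
    for (ch in unique(a$chrom)) {
      b <- a %>% filter(.data$chrom == ch)
      ir <- IRanges::IRanges(b$start + 1L, b$end)
      out[[smp]][[ch]] <- IRanges::coverage(ir)
      tot_bases <- tot_bases + sum(as.numeric(b$end - b$start))
      tot_span <- tot_span + (max(b$end) - min(b$start))
    }
    mean_cov[smp] <- if (tot_span > 0) tot_bases / tot_span else 0
  }
  attr(out, "mean_cov") <- mean_cov
  out
}

# mean depth of [start, end) (0-based half-open) on one coverage Rle,
# clipped at the contig edges; NA when the clipped region is empty
rle_region_mean <- function(cov, start, end) {
  if (is.null(cov)) return(NA_real_)
  lo <- max(0L, as.integer(floor(start))); hi <- as.integer(ceiling(end))
  if (hi <= lo) return(NA_real_)
  # positions beyond the run-length vector have depth 0
  hi_in <- min(hi, base::length(cov))
  s <- if (hi_in > lo) sum(as.numeric(S4Vectors::window(cov, lo + 1L, hi_in))) else 0
  s / (hi - lo)
}

#' Local coverage at an indel site
#'
#' The normalizing coverage for a site's features: the mean of the mean
#' depths of the two flanking windows `[p1 - w, p1)` and `[p2, p2 + w)`,
#' with `w = mu + n_sigma * sigma`. For insertions both flanks abut the
#' single breakpoint. Flanks are clipped at contig edges; if one flank is
#' empty the other's mean is returned, and `NA` if both are empty (the
#' caller then falls back to the sample-wide mean coverage).
#'
#' @param site One site-tibble row.
#' @param cov One sample's coverage list (`coverage_profiles()[[sample]]`).
#' @param lib [library_stats()].
#' @param cfg [evidence_config()].
#' @return Local coverage (numeric scalar, possibly `NA`).
#' @export
local_coverage <- function(site, cov, lib, cfg = evidence_config()) {
  w <- window_pad_of(lib, cfg)
  cv <- cov[[site$chrom]]
  if (is.null(cv)) return(NA_real_)
  left <- rle_region_mean(cv, site$p1 - w, site$p1)
  right <- rle_region_mean(cv, site$p2, site$p2 + w)
  if (is.na(left) && is.na(right)) return(NA_real_)
  mean(c(left, right), na.rm = TRUE)
}

del_feature_names <- c("discordant", "concordant", "split", "full", "depth")
ins_feature_names <- c("discordant", "concordant", "single_end_mapped",
                       "partial", "full")
feature_cols <- paste0("f", 1:5)

#' Assemble a raw feature vector from evidence counts
#'
#' Fixes the feature order the classifier consumes. Deletions use
#' (discordant, concordant, split, full, region depth); insertions use
#' (discordant, concordant, single-end-mapped, partial, full) — read depth
#' is not informative for insertions (nothing is missing from the
#' reference), so the `depth` argument is ignored for `kind = "INS"`.
#'
#' @param counts One row of [collect_evidence()] output (or a list with
#'   the `n_*` fields).
#' @param depth Mean read depth of the deleted interval `[p1, p2)`.
#' @param kind `"DEL"` or `"INS"`.
#' @return Named numeric vector of length 5.
#' @examples
#' cnt <- list(n_discordant = 4, n_concordant = 2, n_single_end_mapped = 0,
#'             n_split = 3, n_partial = 0, n_full = 1)
#' build_feature_vector(cnt, depth = 6.2, kind = "DEL")
#' @export
build_feature_vector <- function(counts, depth = NA_real_, kind) {
  if (!kind %in% c("DEL", "INS"))
    abort(paste0("unknown indel kind: ", kind))
  if (kind == "DEL") {
    v <- c(counts$n_discordant, counts$n_concordant, counts$n_split,
           counts$n_full, depth)
    names(v) <- del_feature_names
  } else {
    v <- c(counts$n_discordant, counts$n_concordant,
           counts$n_single_end_mapped, counts$n_partial, counts$n_full)
    names(v) <- ins_feature_names
  }
  as.numeric(v) |> setNames(names(v))
}

#' Normalize a feature vector by local coverage
#'
#' Raw evidence counts scale with sequencing depth; dividing by the site's
#' local coverage makes vectors comparable across samples and sites. When
#' the local coverage is degenerate (`lambda < eps`, e.g. a site in a
#' coverage hole), the sample-wide mean coverage is used instead.
#'
#' @param v Numeric feature vector.
#' @param lambda Local coverage from [local_coverage()] (may be `NA`).
#' @param fallback_cov Sample-wide mean coverage used when `lambda < eps`.
#' @param eps Degeneracy threshold (default 0.5).
#' @return The normalized vector with attribute `lambda` = the divisor
#'   actually used.
#' @examples
#' normalize_vector(c(4, 2, 6, 1, 3), lambda = 2)
#' @export
normalize_vector <- function(v, lambda, fallback_cov = NULL, eps = 0.5) {
  lam <- if (!is.na(lambda) && lambda >= eps) lambda else {
    if (is.null(fallback_cov) || is.na(fallback_cov) || fallback_cov <= 0)
      abort("local coverage is degenerate and no usable fallback coverage given")
    fallback_cov
  }
  out <- v / lam
  attr(out, "lambda") <- lam
  out
}

#' Extract normalized feature vectors for a cohort
#'
#' End-to-end feature extraction: evidence tallies ([collect_evidence()]),
#' per-site region depth and local coverage ([coverage_profiles()],
#' [local_coverage()]), raw vector assembly ([build_feature_vector()]) and
#' local-coverage normalization ([normalize_vector()]), for every
#' `(sample, site)` pair.
#'
#' @param alignments Alignment-record tibble, one or more samples.
#' @param sites Site tibble.
#' @param lib [library_stats()].
#' @param cfg [evidence_config()].
#' @param fallback_cov Optional named (per sample) fallback coverage;
#'   default: each sample's mean coverage from [coverage_profiles()].
#' @return A feature tibble with columns `sample`, `site_id`, `kind`,
#'   `f1`..`f5` (normalized, order per [build_feature_vector()]) and
#'   `lambda` (the divisor used).
#' @export
extract_features <- function(alignments, sites, lib, cfg = evidence_config(),
                             fallback_cov = NULL) {
  counts <- collect_evidence(alignments, sites, lib, cfg)
  cov <- coverage_profiles(alignments)
  if (is.null(fallback_cov)) fallback_cov <- attr(cov, "mean_cov")
  grid <- tidyr::expand_grid(sample = names(cov), site_id = sites$site_id)
  lam_tbl <- purrr::pmap_dfr(grid, function(sample, site_id) {
    s <- sites[match(site_id, sites$site_id), ]
    lam <- local_coverage(s, cov[[sample]], lib, cfg)
    dep <- NA_real_
    if (s$kind == "DEL") {
      dep <- rle_region_mean(cov[[sample]][[s$chrom]], s$p1, s$p2)
      if (is.na(dep)) dep <- 0
    }
    tibble(sample = sample, site_id = site_id,
           lambda_raw = lam, region_depth = dep)
  })
  counts %>%
    left_join(lam_tbl, by = c("sample", "site_id")) %>%
    left_join(select(sites, "site_id", "kind"), by = "site_id") %>%
    purrr::pmap_dfr(function(sample, site_id, n_discordant, n_concordant,
                             n_single_end_mapped, n_split, n_partial, n_full,
                             lambda_raw, region_depth, kind) {
      cnt <- list(n_discordant = n_discordant, n_concordant = n_concordant,
                  n_single_end_mapped = n_single_end_mapped,
                  n_split = n_split, n_partial = n_partial, n_full = n_full)
      v <- build_feature_vector(cnt, depth = region_depth, kind = kind)
      nv <- normalize_vector(v, lambda_raw,
                             fallback_cov = unname(fallback_cov[sample]))
      tibble(sample = sample, site_id = site_id, kind = kind,
             f1 = nv[[1]], f2 = nv[[2]], f3 = nv[[3]], f4 = nv[[4]],
             f5 = nv[[5]], lambda = attr(nv, "lambda"))
    })
}

#' Read and write feature tables
#'
#' Feature matrices are exchanged as TSV with a mandatory header:
#' columns `sample`, `site_id`, `kind`, optional `label`, the five ordered
#' features `f1`..`f5`, and `lambda`.
#'
#' @param features Feature tibble from [extract_features()] (optionally
#'   with a `label` column of truth genotypes).
#' @param path File path.
#' @return `write_features()`: `path`, invisibly; `read_features()`: the
#'   feature tibble.
#' @export
write_features <- function(features, path) {
  need <- c("sample", "site_id", "kind", feature_cols, "lambda")
  miss <- setdiff(need, names(features))
  if (base::length(miss) > 0)
    abort(paste0("feature table is missing column(s): ",
                 paste(miss, collapse = ", ")))
  ord <- c("sample", "site_id", "kind",
           intersect("label", names(features)), feature_cols, "lambda")
  readr::write_tsv(features[, ord], path)
  invisible(path)
}

#' @rdname write_features
#' @export
read_features <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE)
  need <- c("sample", "site_id", "kind", feature_cols, "lambda")
  miss <- setdiff(need, names(df))
  if (base::length(miss) > 0)
    abort(paste0("feature TSV is missing column(s): ",
                 paste(miss, collapse = ", ")))
  df
}
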