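#' Alignment record tibbles
#'
#' indelgt represents alignments as a plain tibble with one row per mapped
#' alignment segment, so that evidence extraction is the same whether the
#' records come from a BAM file ([read_alignments()]) or from the
#' simulator's truth placements ([truth_alignments()]). Columns:
#'
#' * `sample` — individual identifier;
#' * `qname` — template (read-pair) name;
#' * `mate` — 1 or 2 within the template;
#' * `chrom`, `start`, `end` — aligned reference span, 0-based half-open;
#' * `clip_left`, `clip_right` — soft/hard-clipped bases at each end;
#' * `mapq` — mapping quality;
#' * `strand` — `"+"` or `"-"`;
#' * `primary` — `FALSE` for supplementary/secondary segments of a
#'   split-mapped read;
#' * `mate_mapped` — whether the other mate is mapped anywhere;
#' * `mate_strand` — the other mate's strand (`NA` when unmapped);
#' * `tlen` — signed template length (outer distance) as reported by the
#'   aligner; positive on the leftmost mate of a pair.
#'
#' Unmapped reads carry no row; a one-end-mapped pair is visible through
#' `mate_mapped = FALSE` on the mapped mate's row.
#'
#' @name alignment-records
NULL

alignment_cols <- c("sample", "qname", "mate", "chrom", "start", "end",
                    "clip_left", "clip_right", "mapq", "strand", "primary",
                    "mate_mapped", "mate_strand", "tlen")

check_alignments <- function(aln) {
  miss <- setdiff(alignment_cols, names(aln))
  if (base::length(miss) > 0)
    abort(paste0("alignment tibble is missing column(s): ",
                 paste(miss, collapse = ", ")))
  invisible(aln)
}

#' Read alignment records from an indexed BAM file
#'
#' Fetches all records whose leftmost mapped base lies in `region` (or the
#' whole file when `region` is `NULL`) and flattens them into the package's
#' alignment-record tibble (see [alignment-records]). Soft and hard clips
#' are read off the CIGAR; supplementary/secondary records are kept with
#' `primary = FALSE` so split-mapped reads retain both segments.
#'
#' @param path BAM file path; an index (`.bai`) must exist for region
#'   queries.
#' @param region Optional list/tibble with `chrom`, `start`, `end`
#'   (0-based half-open), e.g. the result of [relevant_region()].
#' @param sample Sample label to attach; defaults to the BAM basename.
#' @return An alignment-record tibble.
#' @export
read_alignments <- function(path, region = NULL, sample = NULL) {
  for (pkg in c("Rsamtools", "GenomicAlignments"))
    if (!requireNamespace(pkg, quietly = TRUE))
      abort(paste0("read_alignments() requires the ", pkg, " package"))
  sample <- sample %||% sub("\\.bam$", "", basename(path))
  what <- c("qname", "flag", "mapq", "isize")
  if (!is.null(region)) {
    if (!file.exists(paste0(path, ".bai")) &&
        !file.exists(sub("\\.bam$", ".bai", path)))
      abort(paste0("BAM index not found for ", path,
                   "; region queries need an indexed BAM"))
    hdr <- Rsamtools::scanBamHeader(path)[[1]]$targets
    if (!(region$chrom %in% names(hdr)))
      abort(paste0("contig ", region$chrom, " absent from BAM header"))
    which <- GenomicRanges::GRanges(region$chrom,
                                    IRanges::IRanges(region$start + 1L, region$end))
    param <- Rsamtools::ScanBamParam(what = what, which = which)
  } else {
    param <- Rsamtools::ScanBamParam(what = what)
  }
  ga <- GenomicAlignments::readGAlignments(path, param = param)
  if (base::length(ga) == 0) return(empty_alignments())
  md <- S4Vectors::mcols(ga)
  flag <- md$flag
  cig <- GenomicAlignments::cigar(ga)
  clip_l <- cigar_clip(cig, "^[0-9]+[SH]")
  clip_r <- cigar_clip(cig, "[0-9]+[SH]$")
  tibble(
    sample = sample,
    qname = md$qname,
    mate = ifelse(bitwAnd(flag, 128L) > 0L, 2L, 1L),
    chrom = as.character(GenomicAlignments::seqnames(ga)),
    start = GenomicAlignments::start(ga) - 1L,
    end = GenomicAlignments::end(ga),
    clip_left = clip_l,
    clip_right = clip_r,
    mapq = as.integer(md$mapq),
    strand = as.character(GenomicAlignments::strand(ga)),
    primary = bitwAnd(flag, 2048L) == 0L & bitwAnd(flag, 256L) == 0L,
    mate_mapped = bitwAnd(flag, 8L) == 0L,
    mate_strand = ifelse(bitwAnd(flag, 8L) > 0L, NA_character_,
                         ifelse(bitwAnd(flag, 32L) > 0L, "-", "+")),
    tlen = as.integer(md$isize)
  )
}

empty_alignments <- function() {
  tibble(sample = character(), qname = character(), mate = integer(),
         chrom = character(), start = integer(), end = integer(),
         clip_left = integer(), clip_right = integer(), mapq = integer(),
         strand = character(), primary = logical(), mate_mapped = logical(),
         mate_strand = character(), tlen = integer())
}

#' Library insert-size statistics
#'
#' `library_stats()` records the paired-end library parameters the evidence
#' rules depend on; `estimate_library_stats()` derives them from alignment
#' records when the user does not supply them.
#'
#' Estimation uses the first `max_pairs` proper forward–reverse pairs
#' (positive template length on the forward mate of a both-mapped primary
#' pair), trims outliers by the robust rule
#' `|tlen - median| <= 5 * mad(tlen)`, and reports the mean and sample
#' standard deviation of the surviving template lengths; the read length is
#' the modal full read length (aligned span plus clips).
#'
#' @param mu Mean insert size (outer distance), bp.
#' @param sigma Insert-size standard deviation, bp.
#' @param read_len Read length, bp.
#' @return A `library_stats` list with fields `mu`, `sigma`, `read_len`.
#' @examples
#' library_stats(mu = 500, sigma = 50, read_len = 100)
#' @export
library_stats <- function(mu, sigma, read_len) {
  stopifnot(mu > 0, sigma >= 0, read_len > 0)
  structure(list(mu = as.numeric(mu), sigma = as.numeric(sigma),
                 read_len = as.integer(read_len)),
            class = "library_stats")
}

#' @export
print.library_stats <- function(x, ...) {
  cat(sprintf("<library_stats> insert %.1f +/- %.1f bp, read length %d bp\n",
              x$mu, x$sigma, x$read_len))
  invisible(x)
}

#' @rdname library_stats
#' @param alignments Alignment-record tibble (see [alignment-records]).
#' @param max_pairs Use at most this many proper pairs.
#' @param min_pairs Fail below this many proper pairs (the caller should
#'   then supply `mu`/`sigma` explicitly via [library_stats()]).
#' @export
estimate_library_stats <- function(alignments, max_pairs = 10000L,
                                   min_pairs = 100L) {
  check_alignments(alignments)
  proper <- alignments %>%
    filter(.data$primary, .data$mate_mapped, .data$strand == "+",
           !is.na(.data$tlen), .data$tlen > 0)
  if (nrow(proper) < min_pairs)
    abort(paste0("only ", nrow(proper), " proper pairs found (need >= ",
                 min_pairs, "); supply mu and sigma explicitly with ",
                 "library_stats()"))
  ins <- head(proper$tlen, max_pairs)
  dev <- abs(ins - median(ins))
  keep <- dev <= 5 * mad_or_zero(ins)
  ins <- ins[keep]
  rl <- with(head(proper, max_pairs),
             end - start + clip_left + clip_right)
  rl_mode <- as.integer(names(sort(table(rl), decreasing = TRUE))[1])
  library_stats(mu = mean(ins),
                sigma = if (base::length(ins) > 1) sd(ins) else 0,
                read_len = rl_mode)
}

mad_or_zero <- function(x) stats::mad(x)

cigar_clip <- function(cig, pattern) {
  hit <- regexpr(pattern, cig)
  out <- integer(base::length(cig))
  found <- hit > 0
  out[found] <- as.integer(sub("[SH]", "", regmatches(cig, hit)))
  out
}
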