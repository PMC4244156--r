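#' Construct a table of indel sites
#'
#' A site table is the unit list the genotyper works through: one row per
#' known insertion or deletion, with breakpoints in the package's internal
#' 0-based half-open convention. For a deletion, `p1` is the first deleted
#' base and `p2` one past the last deleted base, so `length == p2 - p1`.
#' For an insertion both breakpoints coincide (`p1 == p2`) at the base
#' where the new sequence is inserted, and `length` is the inserted length.
#'
#' @param chrom Character vector of sequence names.
#' @param p1,p2 Integer breakpoints, 0-based half-open (see Description).
#' @param kind `"DEL"` or `"INS"` per site.
#' @param length Indel length in bp. Optional for deletions (derived as
#'   `p2 - p1`), required for insertions.
#' @param id Optional unique site labels; autogenerated as
#'   `"<kind>_<chrom>_<p1>"` when missing.
#' @return A tibble with columns `site_id`, `chrom`, `p1`, `p2`, `kind`,
#'   `length`, sorted by `(chrom, p1)`.
#' @examples
#' indel_sites("chr1", p1 = c(1000L, 5000L), p2 = c(1400L, 5000L),
#'             kind = c("DEL", "INS"), length = c(NA, 300L))
#' @export
indel_sites <- function(chrom, p1, p2, kind, length = NULL, id = NULL) {
  n <- base::length(p1)
  p1 <- as.integer(p1); p2 <- as.integer(p2)
  kind <- toupper(as.character(kind))
  if (is.null(length)) length <- rep(NA_integer_, n)
  length <- as.integer(length)
  if (!all(kind %in% c("DEL", "INS")))
    abort(paste0("unknown indel kind: ",
                 paste(unique(setdiff(kind, c("DEL", "INS"))), collapse = ", ")))
  length[kind == "DEL" & is.na(length)] <-
    (p2 - p1)[kind == "DEL" & is.na(length)]
  bad <- p1 > p2 |
    (kind == "DEL" & (p2 - p1 <= 0L | length != p2 - p1)) |
    (kind == "INS" & (p1 != p2 | is.na(length) | length <= 0L))
  if (any(bad))
    abort(paste0("invalid site(s) at row(s): ",
                 paste(which(bad), collapse = ", "),
                 " (DEL needs p2 > p1 and length == p2 - p1; ",
                 "INS needs p1 == p2 and length > 0)"))
  if (is.null(id)) id <- paste0(kind, "_", chrom, "_", p1)
  if (anyDuplicated(id))
    abort("site ids are not unique")
  tibble(site_id = as.character(id), chrom = as.character(chrom),
         p1 = p1, p2 = p2, kind = kind, length = length) %>%
    arrange(.data$chrom, .data$p1)
}

#' Read indel sites from VCF or TSV
#'
#' VCF records are interpreted with the standard structural-variant fields:
#' a `SVTYPE=DEL` record spans `(POS, END]` 1-based, giving internal
#' breakpoints `p1 = POS - 1`, `p2 = END` and `length = END - POS`
#' (`SVLEN` is used when `END` is absent); a `SVTYPE=INS` record becomes
#' `p1 = p2 = POS - 1` with `length = |SVLEN|`. Records missing the
#' required fields are skipped and counted. The TSV format has a header
#' with columns `chrom`, `p1`, `p2`, `kind` (optionally `id`), with
#' breakpoints in the same 1-based inclusive convention as VCF
#' (`p1` = POS, `p2` = END; `p1 == p2` for insertions).
#'
#' @param path File path.
#' @param format `"auto"` (by extension), `"vcf"`, or `"tsv"`.
#' @return A site tibble as from [indel_sites()].
#' @export
read_sites <- function(path, format = c("auto", "vcf", "tsv")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.vcf(\\.gz)?$", path, ignore.case = TRUE)) "vcf" else "tsv"
  if (format == "vcf") read_sites_vcf(path) else read_sites_tsv(path)
}

read_sites_tsv <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE)
  need <- c("chrom", "p1", "p2", "kind")
  if (!all(need %in% names(df)))
    abort(paste0("site TSV must have columns ", paste(need, collapse = ", ")))
  len <- if ("length" %in% names(df)) as.integer(df$length) else NULL
  kind <- toupper(df$kind)
  p1 <- as.integer(df$p1) - 1L
  p2 <- ifelse(kind == "INS", p1, as.integer(df$p2))
  if (is.null(len)) {
    len <- rep(NA_integer_, nrow(df))
    if (any(kind == "INS"))
      abort("site TSV with INS rows needs a length column")
  }
  indel_sites(df$chrom, p1, p2, kind, length = len,
              id = if ("id" %in% names(df)) df$id else NULL)
}

read_sites_vcf <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE))
    abort("reading VCF sites requires the vcfR package")
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  info <- fix$INFO %||% vcfR::getINFO(v)
  grab <- function(key) {
    m <- regmatches(info, regexpr(paste0("(^|;)", key, "=[^;]+"), info))
    out <- rep(NA_character_, base::length(info))
    hit <- regexpr(paste0("(^|;)", key, "=[^;]+"), info) > 0
    out[hit] <- sub(paste0("^;?", key, "="), "", m)
    out
  }
  svtype <- grab("SVTYPE")
  end <- suppressWarnings(as.integer(grab("END")))
  svlen <- suppressWarnings(as.integer(grab("SVLEN")))
  pos <- as.integer(fix$POS)
  kind <- toupper(svtype)
  ok_del <- kind == "DEL" & (!is.na(end) | !is.na(svlen))
  ok_ins <- kind == "INS" & !is.na(svlen)
  keep <- !is.na(kind) & (ok_del | ok_ins)
  n_skip <- sum(!keep)
  if (n_skip > 0)
    inform(paste0(n_skip, " VCF record(s) skipped (missing SVTYPE/END/SVLEN ",
                  "or unsupported type)"))
  if (!any(keep)) abort(paste0("no usable indel sites in ", path))
  pos <- pos[keep]; kind <- kind[keep]
  end <- end[keep]; svlen <- svlen[keep]
  id <- fix$ID[keep]
  id[is.na(id) | id == "."] <- NA_character_
  # deleted bases span (POS-1, END] half-open, so length = END - POS + 1;
  # when only SVLEN is present, END = POS + |SVLEN| - 1
  end[kind == "DEL" & is.na(end)] <-
    (pos + abs(svlen) - 1L)[kind == "DEL" & is.na(end)]
  p1 <- pos - 1L
  p2 <- ifelse(kind == "INS", p1, end)
  len <- ifelse(kind == "INS", abs(svlen), p2 - p1)
  if (all(is.na(id))) id <- NULL else {
    auto <- paste0(kind, "_", fix$CHROM[keep], "_", p1)
    id[is.na(id)] <- auto[is.na(id)]
  }
  indel_sites(fix$CHROM[keep], p1, p2, kind, length = len, id = id)
}

#' Write a site table as TSV
#'
#' Inverse of the TSV branch of [read_sites()]: breakpoints are emitted
#' 1-based inclusive so that `read_sites(write_sites(x))` restores the
#' internal representation.
#'
#' @param sites Site tibble from [indel_sites()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sites <- function(sites, path) {
  out <- tibble(chrom = sites$chrom,
                p1 = sites$p1 + 1L,
                p2 = ifelse(sites$kind == "INS", sites$p1 + 1L, sites$p2),
                kind = sites$kind, length = sites$length, id = sites$site_id)
  readr::write_tsv(out, path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
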