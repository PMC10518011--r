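# Internal helpers: CIGAR parsing, small sequence utilities, SAM writing.

#' Parse a CIGAR string into operation/length pairs
#'
#' @param cigar a single CIGAR string, e.g. `"10M2D5M"`; `"*"` yields zero rows.
#' @return a tibble with columns `op` (character) and `len` (integer), in order.
#' @keywords internal
#' @noRd
parse_cigar <- function(cigar) {
  stopifnot(length(cigar) == 1L)
  if (is.na(cigar) || cigar == "*" || cigar == "") {
    return(tibble(op = character(), len = integer()))
  }
  m <- gregexpr("(\\d+)([MIDNSHP=X])", cigar, perl = TRUE)[[1]]
  toks <- regmatches(cigar, list(m))[[1]]
  if (sum(nchar(toks)) != nchar(cigar)) {
    abort(paste0("malformed CIGAR string: '", cigar, "'"))
  }
  tibble(
    op  = substr(toks, nchar(toks), nchar(toks)),
    len = as.integer(substr(toks, 1L, nchar(toks) - 1L))
  )
}

# reference-space width consumed by a CIGAR (M/D/N/=/X)
cigar_ref_width <- function(cigar) {
  vapply(cigar, function(cg) {
    ops <- parse_cigar(cg)
    sum(ops$len[ops$op %in% c("M", "D", "N", "=", "X")])
  }, integer(1), USE.NAMES = FALSE)
}

# query-space width consumed by a CIGAR (M/I/S/=/X); must equal nchar(seq)
cigar_query_width <- function(cigar) {
  vapply(cigar, function(cg) {
    ops <- parse_cigar(cg)
    sum(ops$len[ops$op %in% c("M", "I", "S", "=", "X")])
  }, integer(1), USE.NAMES = FALSE)
}

# vector of random DNA strings, fixed width
random_dna <- function(n, width) {
  if (n == 0L) return(character())
  mat <- matrix(sample(c("A", "C", "G", "T"), n * width, replace = TRUE),
                nrow = n)
  apply(mat, 1L, paste0, collapse = "")
}

# distinct random barcodes (rejection sampling; width chosen so collisions rare)
random_barcodes <- function(n, width) {
  out <- unique(random_dna(n, width))
  while (length(out) < n) {
    out <- unique(c(out, random_dna(n - length(out), width)))
  }
  out[seq_len(n)]
}

assert_dna <- function(x, what = "sequence") {
  bad <- grepl("[^ACGT]", x)
  if (any(bad)) {
    abort(paste0(what, " contains non-ACGT characters: ",
                 paste(utils::head(x[bad], 3L), collapse = ", ")))
  }
  invisible(x)
}

#' Write alignment records as SAM text and convert to a sorted, indexed BAM
#'
#' Records are written as SAM (the plain-text alignment format) and converted
#' with [Rsamtools::asBam()], so the output is readable by any standard tool.
#'
#' @param records tibble with columns `qname`, `flag`, `rname`, `pos`
#'   (0-based leftmost), `mapq`, `cigar`, `seq`, and optionally `tags`
#'   (character; pre-formatted tab-separated SAM tag fields, may be `NA`).
#' @param contigs named integer vector of contig lengths for the header.
#' @param bam_path output path (final `.bam`; a `.bai` index is written too).
#' @param sort_by_coord sort by coordinate before writing (records are written
#'   in the given order otherwise, and coordinate sorting is still applied by
#'   `asBam`).
#' @return `bam_path`, invisibly.
#' @keywords internal
#' @noRd
write_bam_records <- function(records, contigs, bam_path, sort_by_coord = TRUE) {
  stopifnot(is.data.frame(records))
  sam_path <- tempfile(fileext = ".sam")
  on.exit(unlink(sam_path), add = TRUE)
  hdr <- c(
    "@HD\tVN:1.6\tSO:unsorted",
    paste0("@SQ\tSN:", names(contigs), "\tLN:", unname(contigs))
  )
  if (nrow(records) > 0) {
    if (sort_by_coord) {
      records <- dplyr::arrange(records, .data$rname, .data$pos)
    }
    tags <- if ("tags" %in% names(records)) records$tags else rep(NA_character_, nrow(records))
    lines <- paste(
      records$qname, records$flag, records$rname, records$pos + 1L,
      records$mapq, records$cigar, "*", 0L, 0L, records$seq,
      strrep("I", nchar(records$seq)),
      sep = "\t"
    )
    has_tags <- !is.na(tags) & nzchar(tags)
    lines[has_tags] <- paste(lines[has_tags], tags[has_tags], sep = "\t")
    writeLines(c(hdr, lines), sam_path)
  } else {
    writeLines(hdr, sam_path)
  }
  dest <- sub("\\.bam$", "", bam_path)
  out <- Rsamtools::asBam(sam_path, destination = dest,
                          overwrite = TRUE, indexDestination = TRUE)
  invisible(out)
}

# SAM flag helpers
flag_is_secondary     <- function(flag) bitwAnd(flag, 256L) > 0L
flag_is_supplementary <- function(flag) bitwAnd(flag, 2048L) > 0L
flag_is_unmapped      <- function(flag) bitwAnd(flag, 4L) > 0L
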