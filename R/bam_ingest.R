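# Streaming and filtering of barcode/UMI-tagged alignments from the targeted
# guide-RNA library BAM.
#
# Tag dialects: 10x/Cell Ranger writes corrected barcodes as CB/UB and gene
# annotations as GN; Dropseq-tools writes XC/XM and gn. Barcode/UMI sequence
# correction itself is delegated to the upstream aligner (it already corrects
# within 1 Hamming distance); here we only filter against the cell whitelist
# and optionally translate barcodes through a lookup table, as needed when the
# expression and feature-barcoding libraries use paired barcode lists.

dialect_tags <- function(dialect = c("cellranger", "dropseq")) {
  dialect <- match.arg(dialect)
  if (dialect == "cellranger") {
    c(cb = "CB", umi = "UB", gene = "GN")
  } else {
    c(cb = "XC", umi = "XM", gene = "gn")
  }
}

#' Read a cell-barcode whitelist
#'
#' One barcode per line; a trailing `-1`-style GEM-well suffix is tolerated
#' and stripped.
#'
#' @param path text file path.
#' @return character vector of barcodes.
#' @export
read_barcode_whitelist <- function(path) {
  bc <- readLines(path, warn = FALSE)
  bc <- bc[nzchar(bc)]
  sub("-\\d+$", "", bc)
}

#' Read a barcode translation lookup table
#'
#' Two-column TSV (no header): observed barcode, translated barcode.
#'
#' @param path TSV path.
#' @return named character vector mapping observed -> translated.
#' @export
read_barcode_lookup <- function(path) {
  tb <- readr::read_tsv(path, col_names = c("from", "to"),
                        col_types = "cc", progress = FALSE)
  setNames(sub("-\\d+$", "", tb$to), sub("-\\d+$", "", tb$from))
}

#' Load and filter tagged guide-library alignments
#'
#' Streams a coordinate-sorted BAM of the targeted guide library and keeps
#' only usable reads: primary (not secondary, not supplementary), mapped to
#' one of the artificial guide contigs, carrying both a cell barcode and a UMI
#' tag, with the (optionally lookup-translated) barcode present in the
#' whitelist. Every dropped read is counted by reason.
#'
#' @param bam path to the BAM (or a tibble of already-extracted reads, in
#'   which case only the filtering is applied — useful for simulated screens).
#' @param whitelist character vector of valid cell barcodes
#'   (see [read_barcode_whitelist()]).
#' @param reference a `custom_reference`, or a character vector of guide
#'   contig names. Reads mapped elsewhere (e.g. host genome) are dropped.
#' @param lookup optional named character vector translating observed barcodes
#'   to whitelist barcodes (see [read_barcode_lookup()]).
#' @param dialect `"cellranger"` (CB/UB/GN tags) or `"dropseq"` (XC/XM/gn).
#' @return tibble of tagged reads: `cell_barcode`, `umi`, `guide_annotation`
#'   (NA when the tag is absent), `contig`, `pos` (0-based leftmost), `cigar`,
#'   `seq`, with attribute `drop_counts` (named integer vector) satisfying
#'   `reads_in == nrow(out) + sum(drop_counts)`.
#' @export
read_guide_alignments <- function(bam, whitelist, reference,
                                  lookup = NULL,
                                  dialect = c("cellranger", "dropseq")) {
  dialect <- match.arg(dialect)
  tags <- dialect_tags(dialect)
  contigs <- if (inherits(reference, "custom_reference")) {
    names(reference$contigs)
  } else {
    as.character(reference)
  }
  if (is.character(bam)) {
    reads <- scan_tagged_bam(bam, tags, dialect)
  } else {
    reads <- as_tibble(bam)
    if (!"flag" %in% names(reads)) reads$flag <- 0L
  }
  filter_tagged_reads(reads, whitelist = whitelist, contigs = contigs,
                      lookup = lookup)
}

# raw scan of a tagged BAM into a tibble (no filtering beyond what BAM gives)
scan_tagged_bam <- function(bam, tags, dialect) {
  if (!file.exists(bam)) abort(paste0("cannot read BAM: ", bam))
  param <- Rsamtools::ScanBamParam(
    what = c("qname", "flag", "rname", "pos", "cigar", "seq"),
    tag = unname(tags)
  )
  res <- tryCatch(Rsamtools::scanBam(bam, param = param)[[1]],
                  error = function(e) abort(paste0("unreadable BAM: ", conditionMessage(e))))
  n <- length(res$qname)
  get_tag <- function(nm) {
    v <- res$tag[[nm]]
    if (is.null(v)) rep(NA_character_, n) else as.character(v)
  }
  reads <- tibble(
    qname = res$qname,
    flag = as.integer(res$flag),
    contig = as.character(res$rname),
    pos = as.integer(res$pos) - 1L,
    cigar = as.character(res$cigar),
    seq = as.character(res$seq),
    cell_barcode = get_tag(tags[["cb"]]),
    umi = get_tag(tags[["umi"]]),
    guide_annotation = get_tag(tags[["gene"]])
  )
  probe <- utils::head(reads, 10000L)
  if (nrow(probe) > 0 &&
      all(is.na(probe$cell_barcode)) && all(is.na(probe$umi))) {
    other <- if (dialect == "cellranger") "dropseq" else "cellranger"
    abort(paste0("no ", dialect, " barcode/UMI tags found in the first ",
                 nrow(probe), " reads; try dialect = \"", other, "\""))
  }
  reads
}

# the filtering core; order of checks defines the drop-reason precedence
filter_tagged_reads <- function(reads, whitelist, contigs, lookup = NULL) {
  whitelist <- sub("-\\d+$", "", whitelist)
  n_in <- nrow(reads)
  drops <- c(secondary = 0L, supplementary = 0L, unmapped = 0L,
             off_target_contig = 0L, missing_tags = 0L,
             barcode_not_in_whitelist = 0L)
  if (n_in > 0) {
    sec <- flag_is_secondary(reads$flag)
    drops[["secondary"]] <- sum(sec); reads <- reads[!sec, ]
    supp <- flag_is_supplementary(reads$flag)
    drops[["supplementary"]] <- sum(supp); reads <- reads[!supp, ]
    unm <- flag_is_unmapped(reads$flag) | is.na(reads$contig) | is.na(reads$pos)
    drops[["unmapped"]] <- sum(unm); reads <- reads[!unm, ]
    off <- !(reads$contig %in% contigs)
    drops[["off_target_contig"]] <- sum(off); reads <- reads[!off, ]
    no_tag <- is.na(reads$cell_barcode) | is.na(reads$umi) |
      !nzchar(reads$cell_barcode) | !nzchar(reads$umi)
    drops[["missing_tags"]] <- sum(no_tag); reads <- reads[!no_tag, ]
    if (nrow(reads) > 0) {
      cb <- sub("-\\d+$", "", reads$cell_barcode)
      if (!is.null(lookup) && length(lookup) > 0) {
        translatable <- !(cb %in% whitelist) & (cb %in% names(lookup))
        cb[translatable] <- unname(lookup[cb[translatable]])
      }
      reads$cell_barcode <- cb
      miss <- !(cb %in% whitelist)
      drops[["barcode_not_in_whitelist"]] <- sum(miss)
      reads <- reads[!miss, ]
    }
  }
  out <- as_tibble(reads)
  stopifnot(n_in == nrow(out) + sum(drops))
  attr(out, "drop_counts") <- drops
  out
}

#' Per-reason drop counts of a filtered read table
#' @param reads a tibble returned by [read_guide_alignments()].
#' @return named integer vector of dropped-read counts.
#' @export
drop_counts <- function(reads) {
  dc <- attr(reads, "drop_counts")
  if (is.null(dc)) {
    dc <- c(secondary = 0L, supplementary = 0L, unmapped = 0L,
            off_target_contig = 0L, missing_tags = 0L,
            barcode_not_in_whitelist = 0L)
  }
  dc
}

#' Group tagged reads into molecules
#'
#' Reads sharing a (cell barcode, UMI) pair are assumed to derive from the
#' same cDNA molecule. This is an exact partition: the summed group sizes
#' equal the number of input reads.
#'
#' @param reads tibble from [read_guide_alignments()].
#' @return tibble with one row per molecule group: `cell_barcode`, `umi`,
#'   `n_reads`, and a `reads` list-column of per-group read tibbles.
#' @export
group_molecules <- function(reads) {
  if (nrow(reads) == 0) {
    return(tibble(cell_barcode = character(), umi = character(),
                  n_reads = integer(), reads = list()))
  }
  reads %>%
    tidyr::nest(reads = -c("cell_barcode", "umi")) %>%
    mutate(n_reads = vapply(.data$reads, nrow, integer(1))) %>%
    select("cell_barcode", "umi", "n_reads", "reads") %>%
    arrange(.data$cell_barcode, .data$umi)
}
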