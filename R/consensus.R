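# UMI consensus calling.
#
# Reads sharing a (cell barcode, UMI) pair derive from one cDNA molecule, so
# disagreements among them are library-prep or sequencing errors. Each group
# is collapsed to one consensus sequence: first the guide annotation is
# settled by majority vote, then the plurality full-read sequence among the
# annotation-concordant reads becomes the consensus. Requiring >1 supporting
# read downstream removes single-read sequencing errors from the guide pool.

#' Resolve the guide annotation of one molecule group by majority vote
#'
#' Reads carry a gene/guide annotation tag from the aligner; reads lacking the
#' tag vote with the artificial contig they mapped to (the contig is the
#' guide). The annotation with the highest read count wins; on a tie no guide
#' can be confidently called and `NA` is returned (the group is excluded from
#' consensus calling).
#'
#' @param group tibble of reads of one (cell barcode, UMI) group, with columns
#'   `guide_annotation` and `contig`.
#' @return the winning guide id, or `NA_character_` on a tie.
#' @export
resolve_guide_annotation <- function(group) {
  stopifnot(nrow(group) > 0)
  votes <- table(dplyr::coalesce(group$guide_annotation, group$contig))
  top <- names(votes)[votes == max(votes)]
  if (length(top) > 1L) NA_character_ else top
}

#' Call per-molecule consensus sequences
#'
#' Collapses every (cell barcode, UMI) group of reads to a single consensus
#' molecule. Within each group the guide annotation is resolved by majority
#' vote (ties discard the group); among the reads supporting the winning
#' annotation, the most frequent full-read sequence is the consensus. Exact
#' string equality is used — reads of unequal length vote as distinct
#' sequences. Sequence-count ties are broken by a seeded uniform draw, so runs
#' with the same seed are reproducible regardless of input row order.
#'
#' @param reads tibble from [read_guide_alignments()].
#' @param seed integer seed for tie-breaking (pipeline default 17).
#' @return tibble of consensus molecules: `cell_barcode`, `umi`, `guide_id`,
#'   `sequence`, `contig`, `pos`, `cigar` (of the representative read),
#'   `n_reads` (annotation-concordant reads in the group), `n_support`
#'   (reads matching the consensus sequence), `n_excluded` (reads whose
#'   annotation lost the vote). Attribute `consensus_counts` logs the number
#'   of annotation-tie groups discarded and reads excluded by the vote.
#' @export
call_consensus <- function(reads, seed = 17) {
  empty <- tibble(cell_barcode = character(), umi = character(),
                  guide_id = character(), sequence = character(),
                  contig = character(), pos = integer(), cigar = character(),
                  n_reads = integer(), n_support = integer(),
                  n_excluded = integer())
  if (nrow(reads) == 0) {
    attr(empty, "consensus_counts") <- c(annotation_tie_groups = 0L,
                                         annotation_excluded_reads = 0L)
    return(empty)
  }
  reads <- reads %>%
    mutate(.guide = coalesce(.data$guide_annotation, .data$contig),
           .row = row_number())

  votes <- reads %>% count(.data$cell_barcode, .data$umi, .data$.guide)
  vote_result <- votes %>%
    group_by(.data$cell_barcode, .data$umi) %>%
    summarise(
      guide_id = .data$.guide[which.max(.data$n)],
      tie = sum(.data$n == max(.data$n)) > 1L,
      n_group = sum(.data$n),
      .groups = "drop"
    )
  tied <- vote_result %>% filter(.data$tie)
  winners <- vote_result %>% filter(!.data$tie)
  n_tie_groups <- nrow(tied)
  n_tie_reads <- sum(tied$n_group)

  part <- reads %>%
    inner_join(winners %>% select("cell_barcode", "umi", "guide_id"),
               by = c("cell_barcode", "umi")) %>%
    filter(.data$.guide == .data$guide_id)
  excluded <- winners %>%
    left_join(part %>% count(.data$cell_barcode, .data$umi, name = ".n_part"),
              by = c("cell_barcode", "umi")) %>%
    mutate(n_excluded = .data$n_group - coalesce(.data$.n_part, 0L))

  # plurality sequence; deterministic tie-break: rows are first arranged by
  # group and sequence, then each row gets a draw from one seeded RNG stream
  scount <- part %>%
    count(.data$cell_barcode, .data$umi, .data$guide_id, .data$seq) %>%
    arrange(.data$cell_barcode, .data$umi, .data$seq)
  scount$.tb <- withr_seed_runif(nrow(scount), seed)
  cons <- scount %>%
    group_by(.data$cell_barcode, .data$umi) %>%
    arrange(desc(.data$n), desc(.data$.tb), .by_group = TRUE) %>%
    slice(1L) %>%
    ungroup() %>%
    rename(sequence = "seq", n_support = "n")

  rep_read <- part %>%
    inner_join(cons %>% select("cell_barcode", "umi", sequence = "sequence"),
               by = c("cell_barcode", "umi")) %>%
    filter(.data$seq == .data$sequence) %>%
    group_by(.data$cell_barcode, .data$umi) %>%
    arrange(.data$.row, .by_group = TRUE) %>%
    slice(1L) %>%
    ungroup() %>%
    select("cell_barcode", "umi", "contig", "pos", "cigar")

  n_part <- part %>% count(.data$cell_barcode, .data$umi, name = "n_reads")

  out <- cons %>%
    select("cell_barcode", "umi", "guide_id", "sequence", "n_support") %>%
    inner_join(rep_read, by = c("cell_barcode", "umi")) %>%
    inner_join(n_part, by = c("cell_barcode", "umi")) %>%
    inner_join(excluded %>% select("cell_barcode", "umi", "n_excluded"),
               by = c("cell_barcode", "umi")) %>%
    select("cell_barcode", "umi", "guide_id", "sequence", "contig", "pos",
           "cigar", "n_reads", "n_support", "n_excluded") %>%
    arrange(.data$cell_barcode, .data$umi)
  attr(out, "consensus_counts") <- c(annotation_tie_groups = n_tie_groups,
                                     annotation_tie_reads = n_tie_reads,
                                     annotation_excluded_reads = sum(out$n_excluded))
  out
}

# n uniform draws under a local seed, without disturbing the caller's RNG
withr_seed_runif <- function(n, seed) {
  if (n == 0L) return(numeric())
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  }, add = TRUE)
  set.seed(seed)
  runif(n)
}

#' Filter consensus molecules by read support
#'
#' Molecules supported by a single read cannot be distinguished from
#' sequencing errors; the default keeps molecules seen in at least 2 reads.
#'
#' @param molecules tibble from [call_consensus()].
#' @param min_reads minimum group size to keep (default 2, i.e. ">1 read").
#' @param count_all_reads if `TRUE`, the filter counts all reads of the group
#'   including those whose annotation lost the majority vote; default counts
#'   only annotation-concordant reads.
#' @return filtered tibble; attribute `n_dropped_low_support` logs the count.
#' @export
filter_consensus <- function(molecules, min_reads = 2L, count_all_reads = FALSE) {
  stopifnot(min_reads >= 1L)
  n <- if (count_all_reads) molecules$n_reads + molecules$n_excluded else molecules$n_reads
  keep <- n >= min_reads
  out <- molecules[keep, ]
  attr(out, "consensus_counts") <- attr(molecules, "consensus_counts")
  attr(out, "n_dropped_low_support") <- sum(!keep)
  out
}

#' Write consensus molecules as a table and a consensus BAM
#'
#' The table (`consensus.sequence.gRNA.txt`, TSV) carries one row per
#' consensus molecule; the BAM carries the representative alignment of each
#' molecule with cell barcode / UMI / guide tags preserved, coordinate-sorted
#' and indexed so it is compatible with standard tooling.
#'
#' @param molecules tibble from [call_consensus()] / [filter_consensus()].
#' @param dir output directory.
#' @param reference a `custom_reference` (for BAM header contig lengths).
#' @param dialect tag dialect for the BAM, `"cellranger"` or `"dropseq"`.
#' @return named paths (`table`, `bam`), invisibly.
#' @export
write_consensus <- function(molecules, dir, reference,
                            dialect = c("cellranger", "dropseq")) {
  dialect <- match.arg(dialect)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  table_path <- file.path(dir, "consensus.sequence.gRNA.txt")
  readr::write_tsv(
    molecules[c("cell_barcode", "umi", "guide_id", "sequence",
                "n_reads", "n_support")],
    table_path
  )
  tags <- dialect_tags(dialect)
  bam_path <- file.path(dir, "consensus.bam")
  recs <- tibble(
    qname = paste0("consensus:", molecules$cell_barcode, ":", molecules$umi),
    flag = 0L,
    rname = molecules$contig,
    pos = molecules$pos,
    mapq = 255L,
    cigar = molecules$cigar,
    seq = molecules$sequence,
    tags = paste0(tags[["cb"]], ":Z:", molecules$cell_barcode, "\t",
                  tags[["umi"]], ":Z:", molecules$umi, "\t",
                  tags[["gene"]], ":Z:", molecules$guide_id)
  )
  contigs <- vapply(reference$contigs, nchar, integer(1))
  write_bam_records(recs, contigs, bam_path)
  invisible(c(table = table_path, bam = bam_path))
}

#' Read a consensus table written by [write_consensus()]
#' @param path path to `consensus.sequence.gRNA.txt`.
#' @return tibble with the table's columns.
#' @export
read_consensus <- function(path) {
  readr::read_tsv(path, col_types = "ccccii", progress = FALSE)
}
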