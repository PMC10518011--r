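# Cas9 editing detection in the gene-expression library.
#
# Cas9 cuts ~3 nt upstream of the PAM; non-homologous end joining leaves
# indels around that position. Transcriptome reads overlapping a short window
# centered on the predicted cutsite are grouped per (cell barcode, UMI); reads
# of one molecule rarely share a start, so the per-molecule consensus is the
# union of per-position calls. A molecule whose union contains a deletion
# covering the cutsite is classified as a Cas9 editing effect; other indels
# and mismatches are reported but never labelled Cas9-induced.

#' Predict cutsites and detection windows from PAM coordinates
#'
#' The cut is placed `cut_offset` nucleotides upstream of the PAM (default 3;
#' the biology is 3-4 nt, so the offset is configurable by +/-1). The window
#' is symmetric around the cutsite with odd width (default 51 bp).
#'
#' @param targets tibble with columns `guide_id`, `gene`, `chrom`, `pam_pos`
#'   (0-based position of the PAM's first base), `strand` (`"+"`/`"-"`).
#'   Rows with missing PAM information are skipped with a warning.
#' @param window_width odd window width in bp (default 51).
#' @param cut_offset nucleotides upstream of the PAM (default 3).
#' @return tibble `guide_id`, `gene`, `chrom`, `cutsite` (0-based),
#'   `window_start`, `window_end` (half-open).
#' @export
compute_cutsites <- function(targets, window_width = 51L, cut_offset = 3L) {
  if (window_width %% 2L == 0L) {
    abort("window_width must be odd (symmetric window around the cutsite)")
  }
  half <- (window_width - 1L) %/% 2L
  missing <- is.na(targets$pam_pos) | is.na(targets$strand) |
    is.na(targets$chrom)
  if (any(missing)) {
    warn(paste0("skipping ", sum(missing),
                " guide(s) without PAM coordinates: ",
                paste(utils::head(targets$guide_id[missing], 5),
                      collapse = ", ")))
    targets <- targets[!missing, ]
  }
  targets %>%
    mutate(
      cutsite = ifelse(.data$strand == "+",
                       .data$pam_pos - cut_offset,
                       .data$pam_pos + cut_offset),
      cutsite = as.integer(.data$cutsite),
      window_start = .data$cutsite - half,
      window_end = .data$cutsite + half + 1L
    ) %>%
    select("guide_id", "gene", "chrom", "cutsite", "window_start",
           "window_end") %>%
    as_tibble()
}

# exon table (0-based half-open) per gene from a GTF
gtf_exons <- function(gtf) {
  gr <- rtracklayer::import(gtf, format = "gtf")
  ex <- gr[gr$type == "exon"]
  gene <- S4Vectors::mcols(ex)$gene_name
  if (is.null(gene)) gene <- S4Vectors::mcols(ex)$gene_id
  tibble(
    gene = as.character(gene),
    chrom = as.character(GenomicRanges::seqnames(ex)),
    start = as.integer(GenomicRanges::start(ex)) - 1L,
    end = as.integer(GenomicRanges::end(ex))
  )
}

#' Fetch expression-library reads overlapping cutsite windows
#'
#' Reads are kept iff they overlap the window, are primary and mapped, carry
#' both barcode tags, and their aligned span overlaps an exon of the window's
#' gene (a simple unambiguous-overlap gene assignment). Reads overlapping the
#' window but assigned to a different gene are dropped.
#'
#' @param bam expression BAM path, or a tibble of reads (with `flag`,
#'   `contig`, `pos`, `cigar`, `seq`, `cell_barcode`, `umi`) for simulated
#'   data.
#' @param windows tibble from [compute_cutsites()].
#' @param gtf gene-annotation GTF path, or a pre-built exon tibble
#'   (`gene`, `chrom`, `start`, `end`, 0-based half-open).
#' @param dialect tag dialect when reading a BAM.
#' @return tibble of window reads with a `guide_id`/`gene` column appended;
#'   one row per (read, window) incidence.
#' @export
window_reads <- function(bam, windows, gtf,
                         dialect = c("cellranger", "dropseq")) {
  dialect <- match.arg(dialect)
  exons <- if (is.character(gtf)) gtf_exons(gtf) else as_tibble(gtf)
  if (is.character(bam)) {
    tags <- dialect_tags(dialect)
    reads <- scan_tagged_bam(bam, tags, dialect)
  } else {
    reads <- as_tibble(bam)
    if (!"flag" %in% names(reads)) reads$flag <- 0L
  }
  keep <- !flag_is_secondary(reads$flag) &
    !flag_is_supplementary(reads$flag) &
    !flag_is_unmapped(reads$flag) &
    !is.na(reads$cell_barcode) & !is.na(reads$umi) &
    !is.na(reads$contig)
  reads <- reads[keep, ]
  if (nrow(reads) == 0) {
    return(dplyr::bind_cols(reads,
                            tibble(guide_id = character(0), gene = character(0),
                                   ref_end = integer(0))[0, ]))
  }
  reads$ref_end <- reads$pos + cigar_ref_width(reads$cigar)
  out <- purrr::pmap_dfr(windows, function(guide_id, gene, chrom, cutsite,
                                           window_start, window_end, ...) {
    in_win <- reads$contig == chrom &
      reads$pos < window_end & reads$ref_end > window_start
    w <- reads[in_win, , drop = FALSE]
    if (nrow(w) == 0) return(NULL)
    gex <- exons[exons$gene == gene & exons$chrom == chrom, ]
    if (nrow(gex) > 0) {
      on_gene <- vapply(seq_len(nrow(w)), function(i) {
        any(w$pos[i] < gex$end & w$ref_end[i] > gex$start)
      }, logical(1))
      w <- w[on_gene, , drop = FALSE]
    } else {
      w <- w[0, , drop = FALSE]
    }
    if (nrow(w) == 0) return(NULL)
    w$guide_id <- guide_id
    w$gene <- gene
    w$cutsite <- cutsite
    w$window_start <- window_start
    w$window_end <- window_end
    w
  })
  if (is.null(out) || nrow(out) == 0) {
    reads0 <- reads[0, , drop = FALSE]
    reads0$guide_id <- character(0)
    reads0$gene <- character(0)
    reads0$cutsite <- integer(0)
    reads0$window_start <- integer(0)
    reads0$window_end <- integer(0)
    return(as_tibble(reads0))
  }
  as_tibble(out)
}

# per-position union call over a window for one read.
# returns tibble(position, state, base) restricted to [window_start, window_end);
# states: "match_or_base" carries the observed base, "deletion" a deleted
# position, plus zero-width "insertion" anchors recorded separately.
read_window_calls <- function(pos, cigar, seq, window_start, window_end) {
  ops <- parse_cigar(cigar)
  ri <- pos
  qi <- 0L
  calls <- list()
  ins <- list()
  for (k in seq_len(nrow(ops))) {
    op <- ops$op[k]
    len <- ops$len[k]
    if (op %in% c("M", "=", "X")) {
      p <- seq.int(ri, length.out = len)
      b <- strsplit(substr(seq, qi + 1L, qi + len), "", fixed = TRUE)[[1]]
      sel <- p >= window_start & p < window_end
      if (any(sel)) {
        calls[[length(calls) + 1L]] <- tibble(position = p[sel],
                                              state = "base", base = b[sel])
      }
      ri <- ri + len; qi <- qi + len
    } else if (op == "D") {
      p <- seq.int(ri, length.out = len)
      sel <- p >= window_start & p < window_end
      if (any(sel)) {
        calls[[length(calls) + 1L]] <- tibble(position = p[sel],
                                              state = "deletion",
                                              base = NA_character_)
      }
      ri <- ri + len
    } else if (op == "N") {
      # spliced alignment: positions are uncovered, never deletions
      ri <- ri + len
    } else if (op == "I") {
      if (ri >= window_start && ri < window_end) {
        ins[[length(ins) + 1L]] <- tibble(position = ri, state = "insertion",
                                          base = substr(seq, qi + 1L, qi + len))
      }
      qi <- qi + len
    } else if (op == "S") {
      qi <- qi + len
    }
  }
  list(calls = dplyr::bind_rows(calls), insertions = dplyr::bind_rows(ins))
}

#' Union consensus of one molecule's reads over a cutsite window
#'
#' Reads of the same (cell barcode, UMI) molecule need not share an alignment
#' start, so their per-position calls are united: every window position
#' covered by at least one read gets a state (an observed base or a deletion),
#' positions covered by no read are uncovered. Conflicting states at a
#' position are resolved by majority; ties resolve to the reference-style
#' call (a base, i.e. no deletion).
#'
#' @param reads tibble of one molecule's window reads (columns `pos`,
#'   `cigar`, `seq`).
#' @param window_start,window_end half-open window bounds.
#' @return list with `positions` (tibble `position`, `state`, `base`) and
#'   `insertions` (tibble `position`, `base`, `n_reads`).
#' @export
union_consensus <- function(reads, window_start, window_end) {
  stopifnot(nrow(reads) > 0)
  per_read <- purrr::pmap(
    reads[c("pos", "cigar", "seq")],
    function(pos, cigar, seq) {
      read_window_calls(pos, cigar, seq, window_start, window_end)
    }
  )
  calls <- dplyr::bind_rows(lapply(per_read, `[[`, "calls"))
  ins <- dplyr::bind_rows(lapply(per_read, `[[`, "insertions"))
  if (nrow(calls) == 0) {
    positions <- tibble(position = integer(), state = character(),
                        base = character())
  } else {
    positions <- calls %>%
      count(.data$position, .data$state, .data$base) %>%
      group_by(.data$position) %>%
      # majority; ties resolve toward a base call over a deletion
      arrange(desc(.data$n), .data$state, .by_group = TRUE) %>%
      slice(1L) %>%
      ungroup() %>%
      select("position", "state", "base")
  }
  if (nrow(ins) > 0) {
    ins <- ins %>% count(.data$position, .data$base, name = "n_reads")
  } else {
    ins <- tibble(position = integer(), base = character(),
                  n_reads = integer())
  }
  list(positions = positions, insertions = ins)
}

# contiguous deletion runs in a union -> tibble(start, end) half-open
deletion_runs <- function(positions) {
  del <- sort(positions$position[positions$state == "deletion"])
  if (length(del) == 0) return(tibble(start = integer(), end = integer()))
  brk <- c(0L, which(diff(del) > 1L), length(del))
  purrr::map_dfr(seq_len(length(brk) - 1L), function(i) {
    run <- del[(brk[i] + 1L):brk[i + 1L]]
    tibble(start = run[1], end = run[length(run)] + 1L)
  })
}

#' Classify one molecule's union consensus over a cutsite window
#'
#' `cutsite_deletion` iff some deletion interval contains the cutsite
#' position; otherwise `other_indel` if any deletion or insertion is present,
#' `mismatch_only` if the union deviates from the reference sequence only by
#' substitutions, else `unedited`. Spliced alignment gaps (N) are never
#' deletions. All events are reported regardless of class.
#'
#' @param union result of [union_consensus()].
#' @param cutsite 0-based cutsite position.
#' @param ref_seq reference sequence of the window (for mismatch detection);
#'   `NULL` skips mismatch classification (mismatches then undetectable).
#' @param window_start window start matching `ref_seq`.
#' @return list `klass` and `events` (tibble `kind`, `position`, `ref`,
#'   `alt` in genomic coordinates).
#' @export
call_editing <- function(union, cutsite, ref_seq = NULL, window_start = NULL) {
  runs <- deletion_runs(union$positions)
  events <- list()
  if (nrow(runs) > 0) {
    for (i in seq_len(nrow(runs))) {
      ref <- if (!is.null(ref_seq)) {
        substr(ref_seq, runs$start[i] - window_start + 1L,
               runs$end[i] - window_start)
      } else ""
      events[[length(events) + 1L]] <- tibble(
        kind = "deletion", position = runs$start[i], ref = ref, alt = "")
    }
  }
  if (nrow(union$insertions) > 0) {
    for (i in seq_len(nrow(union$insertions))) {
      events[[length(events) + 1L]] <- tibble(
        kind = "insertion", position = union$insertions$position[i],
        ref = "", alt = union$insertions$base[i])
    }
  }
  if (!is.null(ref_seq)) {
    bases <- union$positions[union$positions$state == "base", ]
    if (nrow(bases) > 0) {
      refb <- substr(rep(ref_seq, nrow(bases)),
                     bases$position - window_start + 1L,
                     bases$position - window_start + 1L)
      mm <- which(refb != bases$base & nzchar(refb))
      for (i in mm) {
        events[[length(events) + 1L]] <- tibble(
          kind = "substitution", position = bases$position[i],
          ref = refb[i], alt = bases$base[i])
      }
    }
  }
  events <- if (length(events)) {
    dplyr::bind_rows(events) %>% arrange(.data$position)
  } else {
    tibble(kind = character(), position = integer(), ref = character(),
           alt = character())
  }
  cut_del <- nrow(runs) > 0 &&
    any(runs$start <= cutsite & runs$end > cutsite)
  klass <- if (cut_del) {
    "cutsite_deletion"
  } else if (any(events$kind %in% c("deletion", "insertion"))) {
    "other_indel"
  } else if (any(events$kind == "substitution")) {
    "mismatch_only"
  } else {
    "unedited"
  }
  list(klass = klass, events = events)
}

#' Detect Cas9 editing effects around cutsites
#'
#' End-to-end editing detection: fetch window reads, group them per (cell
#' barcode, UMI) molecule, build each molecule's union consensus, and
#' classify it against the cutsite.
#'
#' @param bam expression BAM path or read tibble (see [window_reads()]).
#' @param windows tibble from [compute_cutsites()].
#' @param gtf GTF path or exon tibble.
#' @param ref_seqs optional named character vector of window reference
#'   sequences (names = `guide_id`) enabling mismatch calls.
#' @param dialect tag dialect.
#' @return tibble with one row per (cell, UMI, window): `cell_barcode`,
#'   `umi`, `gene`, `guide_id`, `klass`, `n_reads`, `mutation_string`, and an
#'   `events` list-column.
#' @export
detect_editing <- function(bam, windows, gtf, ref_seqs = NULL,
                           dialect = c("cellranger", "dropseq")) {
  dialect <- match.arg(dialect)
  wr <- window_reads(bam, windows, gtf, dialect = dialect)
  if (nrow(wr) == 0) {
    return(tibble(cell_barcode = character(), umi = character(),
                  gene = character(), guide_id = character(),
                  klass = character(), n_reads = integer(),
                  mutation_string = character(), events = list()))
  }
  wr %>%
    group_by(.data$guide_id, .data$gene, .data$cutsite, .data$window_start,
             .data$window_end, .data$cell_barcode, .data$umi) %>%
    summarise(.reads = list(dplyr::pick("pos", "cigar", "seq")),
              .groups = "drop") %>%
    mutate(.call = purrr::pmap(
      list(.data$.reads, .data$window_start, .data$window_end, .data$cutsite,
           .data$guide_id),
      function(reads, ws, we, cut, gid) {
        u <- union_consensus(reads, ws, we)
        rs <- if (!is.null(ref_seqs) && gid %in% names(ref_seqs)) {
          ref_seqs[[gid]]
        } else NULL
        call_editing(u, cut, ref_seq = rs, window_start = ws)
      })) %>%
    mutate(
      klass = vapply(.data$.call, `[[`, character(1), "klass"),
      events = lapply(.data$.call, `[[`, "events"),
      n_reads = vapply(.data$.reads, nrow, integer(1)),
      mutation_string = vapply(.data$events, mutation_string, character(1))
    ) %>%
    select("cell_barcode", "umi", "gene", "guide_id", "klass", "n_reads",
           "mutation_string", "events") %>%
    arrange(.data$gene, .data$cell_barcode, .data$umi)
}

#' Write editing calls as TSV
#' @param calls tibble from [detect_editing()].
#' @param path output path (conventionally `editing.effect.txt`).
#' @return `path`, invisibly.
#' @export
write_editing_calls <- function(calls, path) {
  readr::write_tsv(
    calls %>% select("cell_barcode", "umi", "gene", "guide_id", "klass",
                     "n_reads", "mutation_string"),
    path
  )
  invisible(path)
}
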