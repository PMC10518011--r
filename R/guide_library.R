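# Guide library loading and custom-reference construction.
#
# A screen's guide library is designed as a set of spacers cloned into a fixed
# expression cassette. Aligning the targeted guide-RNA sequencing library
# against one artificial contig per guide (cassette context + spacer) lets a
# standard aligner produce per-guide alignments whose CIGARs expose mutations.

#' Read a guide library design table
#'
#' Loads the designed guide library from a delimited file and validates it.
#' Column names are configurable so tables from different design tools can be
#' read directly.
#'
#' @param path path to a TSV/CSV file (delimiter sniffed from the extension:
#'   `.csv` is comma, anything else tab).
#' @param guide_id,spacer,target_gene,targeting column names in the file.
#'   `target_gene` and `targeting` may be absent: genes default to `""` and
#'   all guides to targeting unless the id or gene marks them otherwise.
#' @return a tibble with columns `guide_id`, `spacer`, `target_gene`,
#'   `targeting`, one row per designed guide, input order preserved.
#' @details Duplicate `guide_id`s or duplicate spacer sequences are hard
#'   errors: two guides sharing a spacer would make downstream annotation of
#'   observed molecules ambiguous. Spacers must be non-empty and ACGT-only.
#' @export
read_guide_library <- function(path, guide_id = "guide_id", spacer = "spacer",
                               target_gene = "target_gene",
                               targeting = "targeting") {
  delim <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  raw <- readr::read_delim(path, delim = delim, col_types = readr::cols(.default = "c"),
                           progress = FALSE)
  if (nrow(raw) == 0) abort("no guides: guide library table is empty")
  for (col in c(guide_id, spacer)) {
    if (!col %in% names(raw)) {
      abort(paste0("guide library is missing required column '", col, "'"))
    }
  }
  out <- tibble(
    guide_id    = raw[[guide_id]],
    spacer      = toupper(raw[[spacer]]),
    target_gene = if (target_gene %in% names(raw)) {
      dplyr::coalesce(raw[[target_gene]], "")
    } else "",
    targeting   = if (targeting %in% names(raw)) {
      tolower(raw[[targeting]]) %in% c("true", "t", "1", "yes", "y")
    } else TRUE
  )
  validate_guide_library(out)
}

#' Validate a guide library tibble
#'
#' @param guides tibble with `guide_id`, `spacer`, `target_gene`, `targeting`.
#' @return the validated tibble (invisibly the same object).
#' @export
validate_guide_library <- function(guides) {
  stopifnot(is.data.frame(guides))
  guides <- as_tibble(guides)
  if (!all(c("guide_id", "spacer") %in% names(guides))) {
    abort("guide library needs 'guide_id' and 'spacer' columns")
  }
  if (nrow(guides) == 0) abort("no guides: guide library table is empty")
  if (!"target_gene" %in% names(guides)) guides$target_gene <- ""
  if (!"targeting" %in% names(guides)) guides$targeting <- TRUE
  if (any(is.na(guides$guide_id) | !nzchar(guides$guide_id))) {
    abort("guide_id must be non-empty")
  }
  if (any(is.na(guides$spacer) | !nzchar(guides$spacer))) {
    abort("spacer must be non-empty")
  }
  assert_dna(guides$spacer, "spacer")
  dup_id <- guides$guide_id[duplicated(guides$guide_id)]
  if (length(dup_id) > 0) {
    abort(paste0("duplicate guide_id: ", paste(unique(dup_id), collapse = ", ")))
  }
  dup_sp <- unique(guides$spacer[duplicated(guides$spacer)])
  if (length(dup_sp) > 0) {
    offenders <- guides$guide_id[guides$spacer %in% dup_sp]
    abort(paste0("duplicate spacer sequence shared by guides: ",
                 paste(offenders, collapse = ", "),
                 " (annotation would be ambiguous)"))
  }
  guides[c("guide_id", "spacer", "target_gene", "targeting")]
}

#' Define a guide expression cassette template
#'
#' The cassette is the fixed sequence context each spacer is cloned into:
#' promoter / template-switch context upstream, the spacer slot, and the
#' scaffold (plus capture sequence) downstream. Supply it either as a single
#' string containing exactly one `[spacer]` placeholder, or as a named
#' character vector of region sequences in 5'-to-3' order where exactly one
#' element, named `spacer`, is the empty-string placeholder, e.g.
#' `c(upstream = "AAA", spacer = "", scaffold = "CCC")`.
#'
#' @param template character scalar with `[spacer]`, or named character vector.
#' @return a `cassette_template` object: tibble of regions (`label`, `seq`;
#'   `seq` is `NA` for the spacer slot).
#' @export
cassette_template <- function(template) {
  if (is.character(template) && length(template) == 1L && is.null(names(template))) {
    n_ph <- lengths(regmatches(template, gregexpr("\\[spacer\\]", template, fixed = FALSE)))
    if (n_ph != 1L) {
      abort("cassette template must contain exactly one [spacer] placeholder")
    }
    parts <- strsplit(template, "[spacer]", fixed = TRUE)[[1]]
    up <- parts[1]
    down <- if (length(parts) > 1) parts[2] else ""
    regions <- tibble(
      label = c("upstream", "spacer", "scaffold"),
      seq   = c(toupper(up), NA_character_, toupper(down))
    )
    regions <- regions[!(!is.na(regions$seq) & !nzchar(regions$seq)), ]
  } else {
    if (is.null(names(template)) || any(!nzchar(names(template)))) {
      abort("named-vector cassette template needs a label for every region")
    }
    if (sum(names(template) == "spacer") != 1L) {
      abort("cassette template must contain exactly one 'spacer' region")
    }
    regions <- tibble(label = names(template), seq = toupper(unname(template)))
    regions$seq[regions$label == "spacer"] <- NA_character_
    regions <- regions[regions$label == "spacer" | nzchar(regions$seq), ]
  }
  fixed <- regions$seq[!is.na(regions$seq)]
  if (length(fixed)) assert_dna(fixed, "cassette template")
  if (anyDuplicated(regions$label)) abort("cassette region labels must be unique")
  structure(list(regions = regions), class = "cassette_template")
}

#' @export
print.cassette_template <- function(x, ...) {
  widths <- ifelse(is.na(x$regions$seq), "<spacer slot>",
                   paste0(nchar(x$regions$seq), " bp"))
  cat("<cassette_template> ", nrow(x$regions), " regions: ",
      paste0(x$regions$label, " (", widths, ")", collapse = " | "), "\n", sep = "")
  invisible(x)
}

# trim total context (non-spacer bases) down to context_length, removing bases
# farthest from the spacer: upstream 5' end first, then downstream 3' end
trim_template_context <- function(regions, context_length) {
  i_sp <- which(regions$label == "spacer")
  up <- regions[seq_len(i_sp - 1L), , drop = FALSE]
  down <- regions[seq(i_sp + 1L, length.out = nrow(regions) - i_sp), , drop = FALSE]
  total <- sum(nchar(up$seq)) + sum(nchar(down$seq))
  excess <- total - context_length
  if (excess <= 0) return(regions)
  # trim upstream from its 5' end
  for (i in seq_len(nrow(up))) {
    if (excess <= 0) break
    take <- min(excess, nchar(up$seq[i]))
    up$seq[i] <- substr(up$seq[i], take + 1L, nchar(up$seq[i]))
    excess <- excess - take
  }
  # then downstream from its 3' end, last region first
  for (i in rev(seq_len(nrow(down)))) {
    if (excess <= 0) break
    take <- min(excess, nchar(down$seq[i]))
    down$seq[i] <- substr(down$seq[i], 1L, nchar(down$seq[i]) - take)
    excess <- excess - take
  }
  out <- dplyr::bind_rows(up, regions[i_sp, ], down)
  out[is.na(out$seq) | nzchar(out$seq), ]
}

#' Build a custom reference with one artificial contig per guide
#'
#' Each designed guide becomes one contig: the cassette context with the
#' guide's spacer substituted into the spacer slot. Region coordinates
#' (0-based, half-open) are recorded per contig so mutations found later can
#' be attributed to upstream / spacer / scaffold positions.
#'
#' @param guides validated guide library tibble (see [read_guide_library()]).
#' @param template a [cassette_template()], or something coercible to one.
#' @param context_length optional cap on the total number of context bases
#'   (upstream + downstream, excluding the spacer) retained per contig. Bases
#'   farthest from the spacer are trimmed first (upstream 5' end, then
#'   downstream 3' end). Default keeps the whole template.
#' @return a `custom_reference` object: `contigs` (named character vector of
#'   contig sequences, names = guide ids) and `regions` (tibble `guide_id`,
#'   `label`, `start`, `end` in 0-based half-open contig coordinates).
#' @export
build_custom_reference <- function(guides, template, context_length = NULL) {
  guides <- validate_guide_library(guides)
  if (!inherits(template, "cassette_template")) template <- cassette_template(template)
  regions <- template$regions
  if (!is.null(context_length)) {
    ctx <- sum(nchar(regions$seq[!is.na(regions$seq)]))
    if (context_length > ctx) {
      abort("context_length exceeds the template's context length")
    }
    regions <- trim_template_context(regions, context_length)
  }
  contig_of <- function(spacer) {
    seqs <- regions$seq
    seqs[is.na(seqs)] <- spacer
    paste0(seqs, collapse = "")
  }
  contigs <- vapply(guides$spacer, contig_of, character(1), USE.NAMES = FALSE)
  names(contigs) <- guides$guide_id
  region_tbl <- purrr::map2_dfr(guides$guide_id, guides$spacer, function(id, sp) {
    lens <- nchar(regions$seq)
    lens[is.na(lens) | is.na(regions$seq)] <- nchar(sp)
    ends <- cumsum(lens)
    tibble(guide_id = id, label = regions$label,
           start = c(0L, ends[-length(ends)]), end = as.integer(ends))
  })
  out <- structure(
    list(contigs = contigs, regions = region_tbl, guides = guides),
    class = "custom_reference"
  )
  validate_custom_reference(out)
}

validate_custom_reference <- function(ref) {
  stopifnot(inherits(ref, "custom_reference"))
  reg <- ref$regions
  for (id in names(ref$contigs)) {
    r <- reg[reg$guide_id == id, ]
    if (nrow(r) == 0) abort(paste0("contig ", id, " has no region annotation"))
    if (any(r$start >= r$end)) abort("empty cassette region")
    if (sum(r$label == "spacer") != 1L) {
      abort(paste0("contig ", id, " must have exactly one spacer region"))
    }
    # contiguous, sorted, covering the contig
    if (r$start[1] != 0L || r$end[nrow(r)] != nchar(ref$contigs[[id]]) ||
        (nrow(r) > 1 && any(r$start[-1] != r$end[-nrow(r)]))) {
      abort(paste0("regions of contig ", id, " are not a contiguous sorted cover"))
    }
  }
  if (!is.null(ref$guides)) {
    sp <- reg[reg$label == "spacer", ]
    got <- substr(ref$contigs[sp$guide_id], sp$start + 1L, sp$end)
    want <- ref$guides$spacer[match(sp$guide_id, ref$guides$guide_id)]
    if (any(got != want)) abort("contig spacer region does not equal designed spacer")
  }
  ref
}

#' @export
print.custom_reference <- function(x, ...) {
  cat("<custom_reference> ", length(x$contigs), " guide contigs, ",
      "contig lengths ", paste(range(nchar(x$contigs)), collapse = "-"),
      " bp\n", sep = "")
  invisible(x)
}

#' Spacer region of each contig
#' @param ref a `custom_reference`.
#' @return tibble `guide_id`, `start`, `end` (0-based half-open) of the spacer.
#' @export
spacer_regions <- function(ref) {
  r <- ref$regions
  as_tibble(r[r$label == "spacer", c("guide_id", "start", "end")])
}

#' Write the custom reference as FASTA + GTF
#'
#' Emits one FASTA record per guide contig and a GTF carrying, per contig, a
#' gene/transcript/exon trio spanning the whole contig (so an aligner emits
#' per-guide gene annotations) plus one `cassette_region` feature line per
#' annotated cassette region. The `dialect` switch controls attribute naming:
#' `"cellranger"` emits `gene_id`/`gene_name`/`transcript_id`/`transcript_name`,
#' `"dropseq"` emits `gene_id`/`gene_name` only. Coordinates are 1-based
#' closed in the GTF (standard dialect); internal coordinates stay 0-based
#' half-open.
#'
#' @param ref a `custom_reference`.
#' @param dir output directory (created if missing).
#' @param dialect `"cellranger"` or `"dropseq"`.
#' @param basename file stem, default `"guide_reference"`.
#' @return named character vector with paths `fasta` and `gtf`, invisibly.
#' @export
write_custom_reference <- function(ref, dir, dialect = c("cellranger", "dropseq"),
                                   basename = "guide_reference") {
  dialect <- match.arg(dialect)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fasta <- file.path(dir, paste0(basename, ".fa"))
  gtf <- file.path(dir, paste0(basename, ".gtf"))
  seqs <- Biostrings::DNAStringSet(ref$contigs)
  Biostrings::writeXStringSet(seqs, fasta)

  attr_str <- function(id) {
    if (dialect == "cellranger") {
      paste0('gene_id "', id, '"; gene_name "', id, '"; transcript_id "', id,
             '"; transcript_name "', id, '";')
    } else {
      paste0('gene_id "', id, '"; gene_name "', id, '";')
    }
  }
  lines <- character(0)
  for (id in names(ref$contigs)) {
    len <- nchar(ref$contigs[[id]])
    at <- attr_str(id)
    for (feat in c("gene", "transcript", "exon")) {
      lines <- c(lines, paste(id, "guidecall", feat, 1L, len, ".", "+", ".",
                              at, sep = "\t"))
    }
    r <- ref$regions[ref$regions$guide_id == id, ]
    lines <- c(lines, paste(id, "guidecall", "cassette_region",
                            r$start + 1L, r$end, ".", "+", ".",
                            paste0(at, ' region_label "', r$label, '";'),
                            sep = "\t"))
  }
  writeLines(lines, gtf)
  invisible(c(fasta = fasta, gtf = gtf))
}

#' Read a custom reference back from FASTA + GTF
#'
#' Inverse of [write_custom_reference()]: reconstructs the contig sequences and
#' cassette region annotation (the design table itself is not stored in the
#' reference files; spacer sequences are recovered from the spacer regions).
#'
#' @param fasta,gtf paths written by [write_custom_reference()].
#' @return a `custom_reference`.
#' @export
read_custom_reference <- function(fasta, gtf) {
  seqs <- Biostrings::readDNAStringSet(fasta)
  contigs <- setNames(as.character(seqs), sub("\\s.*$", "", names(seqs)))
  gr <- rtracklayer::import(gtf, format = "gtf")
  reg <- gr[gr$type == "cassette_region"]
  region_tbl <- tibble(
    guide_id = as.character(GenomicRanges::seqnames(reg)),
    label    = S4Vectors::mcols(reg)$region_label,
    start    = as.integer(GenomicRanges::start(reg)) - 1L,
    end      = as.integer(GenomicRanges::end(reg))
  ) %>% arrange(match(.data$guide_id, names(contigs)), .data$start)
  sp <- region_tbl[region_tbl$label == "spacer", ]
  guides <- tibble(
    guide_id = sp$guide_id,
    spacer = substr(contigs[sp$guide_id], sp$start + 1L, sp$end),
    target_gene = "", targeting = TRUE
  ) %>% arrange(match(.data$guide_id, names(contigs)))
  validate_custom_reference(structure(
    list(contigs = contigs, regions = region_tbl, guides = guides),
    class = "custom_reference"
  ))
}
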