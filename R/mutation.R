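# Mutation identification in consensus guide sequences.
#
# Each consensus molecule carries the aligner's CIGAR against its designed
# cassette contig. Walking the CIGAR itemizes every deviation: mismatched
# bases inside M runs (substitutions), insertions (I), deletions (D), skipped
# regions (N) and soft clips (S). A molecule whose aligned span matches the
# cassette perfectly — no mismatch, no indel, no clip — is an intact guide;
# anything else is a mutant. This is deliberately stricter than feature
# barcoding's 1-Hamming tolerance: a single-substitution guide is mutant.

MUTATION_KINDS <- c(substitution = "X", insertion = "I", deletion = "D",
                    skip = "N", softclip = "S")

# itemize deviations of one aligned sequence from its reference contig.
# pos is the 0-based leftmost aligned reference position.
cigar_events <- function(refseq, pos, cigar, seq) {
  ops <- parse_cigar(cigar)
  qw <- sum(ops$len[ops$op %in% c("M", "I", "S", "=", "X")])
  if (qw != nchar(seq)) {
    abort(paste0("CIGAR '", cigar, "' implies query length ", qw,
                 " but sequence has ", nchar(seq), " bases"))
  }
  events <- list()
  ri <- pos
  qi <- 0L
  for (k in seq_len(nrow(ops))) {
    op <- ops$op[k]
    len <- ops$len[k]
    if (op %in% c("M", "=", "X")) {
      rb <- strsplit(substr(refseq, ri + 1L, ri + len), "", fixed = TRUE)[[1]]
      qb <- strsplit(substr(seq, qi + 1L, qi + len), "", fixed = TRUE)[[1]]
      mm <- which(rb != qb)
      for (i in mm) {
        events[[length(events) + 1L]] <- list(
          kind = "substitution", position = ri + i - 1L,
          ref = rb[i], alt = qb[i])
      }
      ri <- ri + len; qi <- qi + len
    } else if (op == "I") {
      events[[length(events) + 1L]] <- list(
        kind = "insertion", position = ri,
        ref = "", alt = substr(seq, qi + 1L, qi + len))
      qi <- qi + len
    } else if (op == "D") {
      events[[length(events) + 1L]] <- list(
        kind = "deletion", position = ri,
        ref = substr(refseq, ri + 1L, ri + len), alt = "")
      ri <- ri + len
    } else if (op == "N") {
      events[[length(events) + 1L]] <- list(
        kind = "skip", position = ri,
        ref = substr(refseq, ri + 1L, ri + len), alt = "")
      ri <- ri + len
    } else if (op == "S") {
      events[[length(events) + 1L]] <- list(
        kind = "softclip", position = ri,
        ref = "", alt = substr(seq, qi + 1L, qi + len))
      qi <- qi + len
    } # H and P consume neither tracked space
  }
  if (length(events) == 0) {
    return(tibble(kind = character(), position = integer(),
                  ref = character(), alt = character()))
  }
  tibble(
    kind = vapply(events, `[[`, character(1), "kind"),
    position = vapply(events, `[[`, integer(1), "position"),
    ref = vapply(events, `[[`, character(1), "ref"),
    alt = vapply(events, `[[`, character(1), "alt")
  ) %>% arrange(.data$position, .data$kind)
}

# label events with the cassette region containing them; deletions/skips by
# their leftmost deleted base, insertions by the following reference base
attach_regions <- function(events, regions_one_guide, contig_len) {
  if (nrow(events) == 0) {
    events$region <- character(0)
    return(events)
  }
  r <- regions_one_guide %>% arrange(.data$start)
  lookup_pos <- pmin(pmax(events$position, 0L), contig_len - 1L)
  idx <- findInterval(lookup_pos, r$start)
  events$region <- r$label[pmax(idx, 1L)]
  events
}

# serialize an event list: "<pos><kind-letter>:<ref>><alt>" joined with ";"
# e.g. "47D:T>-" for a deletion, "12X:C>T" for a substitution
mutation_string <- function(events) {
  if (nrow(events) == 0) return("")
  dash <- function(x) ifelse(nzchar(x), x, "-")
  paste0(events$position, MUTATION_KINDS[events$kind], ":",
         dash(events$ref), ">", dash(events$alt), collapse = ";")
}

#' Annotate mutations in consensus molecules
#'
#' Compares each consensus molecule to its designed cassette contig through
#' the alignment CIGAR and itemizes all deviations as mutation events mapped
#' onto the cassette region annotation. A molecule with zero events (perfect
#' match over the aligned span) is intact.
#'
#' @param molecules tibble from [call_consensus()]/[filter_consensus()].
#' @param reference the `custom_reference` the reads were aligned to.
#' @return the molecules tibble with added columns `mutation_string` (`""`
#'   for intact), `is_intact`, `n_events`, and an `events` list-column of
#'   per-event tibbles (`kind`, `position`, `ref`, `alt`, `region`). Molecules
#'   whose CIGAR is inconsistent with their sequence length are excluded and
#'   reported in the `annotation_errors` attribute.
#' @export
annotate_mutations <- function(molecules, reference) {
  stopifnot(inherits(reference, "custom_reference"))
  if (nrow(molecules) == 0) {
    out <- molecules
    out$mutation_string <- character(0)
    out$is_intact <- logical(0)
    out$n_events <- integer(0)
    out$events <- list()
    attr(out, "annotation_errors") <- tibble(cell_barcode = character(),
                                             umi = character(),
                                             message = character())
    return(out)
  }
  missing <- setdiff(unique(molecules$guide_id), names(reference$contigs))
  if (length(missing) > 0) {
    abort(paste0("guide ids absent from reference: ",
                 paste(utils::head(missing, 5), collapse = ", ")))
  }
  # annotate each distinct alignment once, then join back to molecules
  keys <- molecules %>%
    distinct(.data$guide_id, .data$pos, .data$cigar, .data$sequence)
  ann <- purrr::pmap(keys, function(guide_id, pos, cigar, sequence) {
    refseq <- reference$contigs[[guide_id]]
    ev <- tryCatch(cigar_events(refseq, pos, cigar, sequence),
                   error = function(e) conditionMessage(e))
    if (is.character(ev)) return(list(error = ev))
    ev <- attach_regions(ev,
                         reference$regions[reference$regions$guide_id == guide_id, ],
                         nchar(refseq))
    list(events = ev, string = mutation_string(ev))
  })
  keys$.error <- vapply(ann, function(a) a$error %||% NA_character_, character(1))
  keys$events <- lapply(ann, function(a) a$events)
  keys$mutation_string <- vapply(ann, function(a) a$string %||% NA_character_,
                                 character(1))
  joined <- molecules %>%
    left_join(keys, by = c("guide_id", "pos", "cigar", "sequence"))
  bad <- !is.na(joined$.error)
  errors <- tibble(cell_barcode = joined$cell_barcode[bad],
                   umi = joined$umi[bad],
                   message = joined$.error[bad])
  out <- joined[!bad, ] %>%
    mutate(
      n_events = vapply(.data$events, nrow, integer(1)),
      is_intact = .data$n_events == 0L
    ) %>%
    select(-".error")
  attr(out, "annotation_errors") <- errors
  attr(out, "consensus_counts") <- attr(molecules, "consensus_counts")
  out
}

#' Collate annotated molecules into a guide-variant catalog
#'
#' Molecules with the same guide and identical event list collapse into one
#' variant. The intact form keeps the bare guide id as its variant name;
#' mutant forms get stable numeric suffixes (`guide.1`, `guide.2`, ...)
#' ordered by descending UMI support, then first occurrence.
#'
#' @param annotated tibble from [annotate_mutations()].
#' @return tibble with one row per observed variant: `variant_name`,
#'   `guide_id`, `mutation_string`, `is_intact`, `n_cells`, `n_umis`, and an
#'   `events` list-column.
#' @export
collate_variants <- function(annotated) {
  if (nrow(annotated) == 0) {
    return(tibble(variant_name = character(), guide_id = character(),
                  mutation_string = character(), is_intact = logical(),
                  n_cells = integer(), n_umis = integer(), events = list()))
  }
  grouped <- annotated %>%
    mutate(.occ = row_number()) %>%
    group_by(.data$guide_id, .data$mutation_string) %>%
    summarise(
      is_intact = .data$mutation_string[1] == "",
      n_cells = n_distinct(.data$cell_barcode),
      n_umis = n(),
      first_occurrence = min(.data$.occ),
      events = list(.data$events[[1]]),
      .groups = "drop"
    )
  grouped %>%
    group_by(.data$guide_id) %>%
    arrange(desc(.data$is_intact), desc(.data$n_umis),
            .data$first_occurrence, .by_group = TRUE) %>%
    mutate(variant_name = dplyr::if_else(
      .data$is_intact, .data$guide_id,
      paste0(.data$guide_id, ".", cumsum(!.data$is_intact))
    )) %>%
    ungroup() %>%
    select("variant_name", "guide_id", "mutation_string", "is_intact",
           "n_cells", "n_umis", "events") %>%
    arrange(.data$guide_id, .data$variant_name)
}

#' Attach variant names back onto annotated molecules
#'
#' @param annotated tibble from [annotate_mutations()].
#' @param variants tibble from [collate_variants()].
#' @return `annotated` with a `variant_name` column.
#' @export
name_molecule_variants <- function(annotated, variants) {
  annotated %>%
    left_join(variants %>% select("guide_id", "mutation_string", "variant_name"),
              by = c("guide_id", "mutation_string"))
}

#' Classify the likely source of each mutant variant per cell
#'
#' Applies per-(variant, cell) rules over the co-occurrence of intact and
#' mutant UMIs of the same guide: a variant recurring in more than one cell
#' was already amplified in the virus pool; a single-cell variant supported by
#' all of the cell's UMIs for that guide arose during transduction (or is a
#' rare pool sub-clone); co-expression of intact and mutant forms with more
#' than one UMI each points at a mutation introduced during lentiviral
#' integration/cassette duplication; a single mutant UMI alongside intact
#' UMIs is a cDNA-preparation artifact. Single-read sequencing errors never
#' reach this stage — they are removed at consensus filtering.
#'
#' @param annotated tibble from [annotate_mutations()] with `variant_name`
#'   (see [name_molecule_variants()]).
#' @param variants tibble from [collate_variants()].
#' @return tibble with one row per (mutant variant, cell): `variant_name`,
#'   `guide_id`, `cell_barcode`, `scenario`, and the evidence counts
#'   `n_variant_cells`, `n_mutant_umis` (of this variant in this cell),
#'   `n_guide_mutant_umis` (any mutant variant of the guide in this cell),
#'   `n_intact_umis`.
#' @export
classify_sources <- function(annotated, variants) {
  if (!"variant_name" %in% names(annotated)) {
    annotated <- name_molecule_variants(annotated, variants)
  }
  per_cell_guide <- annotated %>%
    group_by(.data$cell_barcode, .data$guide_id) %>%
    summarise(n_intact_umis = sum(.data$is_intact),
              n_guide_mutant_umis = sum(!.data$is_intact),
              .groups = "drop")
  mut <- annotated %>% filter(!.data$is_intact)
  if (nrow(mut) == 0) {
    return(tibble(variant_name = character(), guide_id = character(),
                  cell_barcode = character(), scenario = character(),
                  n_variant_cells = integer(), n_mutant_umis = integer(),
                  n_guide_mutant_umis = integer(), n_intact_umis = integer()))
  }
  vc <- mut %>%
    count(.data$variant_name, .data$guide_id, .data$cell_barcode,
          name = "n_mutant_umis")
  n_cells_per_variant <- vc %>% count(.data$variant_name, name = "n_variant_cells")
  vc %>%
    left_join(n_cells_per_variant, by = "variant_name") %>%
    left_join(per_cell_guide, by = c("cell_barcode", "guide_id")) %>%
    mutate(scenario = dplyr::case_when(
      .data$n_variant_cells > 1L ~ "virus_pool",
      .data$n_intact_umis == 0L & .data$n_guide_mutant_umis >= 1L ~
        "transduction_or_subclone",
      .data$n_mutant_umis > 1L & .data$n_intact_umis > 1L ~
        "integration_duplication",
      .data$n_mutant_umis == 1L & .data$n_intact_umis >= 1L ~ "cdna_prep",
      TRUE ~ "ambiguous"
    )) %>%
    select("variant_name", "guide_id", "cell_barcode", "scenario",
           "n_variant_cells", "n_mutant_umis", "n_guide_mutant_umis",
           "n_intact_umis") %>%
    arrange(.data$variant_name, .data$cell_barcode)
}

#' Per-position mutation spectrum over the cassette
#'
#' Histogram of mutation events along cassette coordinates, with events
#' weighted by the number of cells (default) or UMIs carrying the variant.
#' For template-switch (TSO) libraries the three positions immediately before
#' the spacer (-2, -1, 0 relative to the spacer start) are artifacts of
#' template switching and can be masked.
#'
#' @param variants tibble from [collate_variants()].
#' @param reference the `custom_reference`.
#' @param mask_tso zero out positions spacer_start-2 .. spacer_start.
#' @param weight `"cells"` or `"umis"`.
#' @return tibble `position`, `region`, `count` covering every cassette
#'   position (union over guides; zero where no event).
#' @export
mutation_spectrum <- function(variants, reference, mask_tso = FALSE,
                              weight = c("cells", "umis")) {
  weight <- match.arg(weight)
  max_len <- max(nchar(reference$contigs))
  # region labels per position from the first contig reaching that position
  region_at <- rep(NA_character_, max_len)
  for (id in names(reference$contigs)) {
    r <- reference$regions[reference$regions$guide_id == id, ]
    for (k in seq_len(nrow(r))) {
      span <- seq(r$start[k] + 1L, r$end[k])
      fill <- is.na(region_at[span])
      region_at[span[fill]] <- r$label[k]
    }
  }
  spectrum <- tibble(position = seq_len(max_len) - 1L, region = region_at,
                     count = 0)
  mut <- variants %>% filter(!.data$is_intact)
  if (nrow(mut) > 0) {
    ev <- mut %>%
      mutate(w = if (weight == "cells") .data$n_cells else .data$n_umis) %>%
      select("guide_id", "events", "w") %>%
      tidyr::unnest("events")
    if (mask_tso) {
      sp <- spacer_regions(reference)
      ev <- ev %>%
        left_join(sp, by = "guide_id") %>%
        filter(!(.data$position >= .data$start - 2L &
                   .data$position <= .data$start)) %>%
        select(-"start", -"end")
    }
    if (nrow(ev) > 0) {
      agg <- ev %>%
        mutate(position = pmin(pmax(.data$position, 0L), max_len - 1L)) %>%
        group_by(.data$position) %>%
        summarise(count = sum(.data$w), .groups = "drop")
      spectrum$count[agg$position + 1L] <- agg$count
    }
  }
  spectrum
}

#' Per-cell mutation frequency per kilobase of profiled guide sequence
#'
#' For each cell: the number of distinct mutated cassette positions observed
#' across its consensus molecules, divided by the total profiled guide length
#' (summed cassette lengths of the distinct guides observed in that cell),
#' scaled to 1000 nucleotides. This normalizes mutation burden across
#' libraries with different gRNA read lengths.
#'
#' @param annotated tibble from [annotate_mutations()].
#' @param reference the `custom_reference`.
#' @return tibble `cell_barcode`, `n_mutated_positions`, `profiled_nt`,
#'   `rate_per_kb`.
#' @export
mutation_rate_per_cell <- function(annotated, reference) {
  contig_len <- tibble(guide_id = names(reference$contigs),
                       len = nchar(unname(reference$contigs)))
  profiled <- annotated %>%
    distinct(.data$cell_barcode, .data$guide_id) %>%
    left_join(contig_len, by = "guide_id") %>%
    group_by(.data$cell_barcode) %>%
    summarise(profiled_nt = sum(.data$len), .groups = "drop")
  mutated <- annotated %>%
    filter(!.data$is_intact) %>%
    select("cell_barcode", "guide_id", "events") %>%
    tidyr::unnest("events") %>%
    distinct(.data$cell_barcode, .data$guide_id, .data$position) %>%
    count(.data$cell_barcode, name = "n_mutated_positions")
  profiled %>%
    left_join(mutated, by = "cell_barcode") %>%
    mutate(n_mutated_positions = coalesce(.data$n_mutated_positions, 0L),
           rate_per_kb = .data$n_mutated_positions / .data$profiled_nt * 1000) %>%
    select("cell_barcode", "n_mutated_positions", "profiled_nt", "rate_per_kb")
}

#' Write the variant catalog table
#'
#' @param variants tibble from [collate_variants()]; if `sources` (from
#'   [classify_sources()]) is supplied, a per-variant scenario summary column
#'   is included.
#' @param path output TSV path (conventionally `gRNA.mutation.txt`).
#' @param sources optional tibble from [classify_sources()].
#' @return `path`, invisibly.
#' @export
write_variant_table <- function(variants, path, sources = NULL) {
  out <- variants %>%
    mutate(region_summary = vapply(.data$events, function(ev) {
      if (nrow(ev) == 0) "" else paste(sort(unique(ev$region)), collapse = ",")
    }, character(1))) %>%
    select("variant_name", "guide_id", "mutation_string", "region_summary",
           "n_cells", "n_umis")
  if (!is.null(sources) && nrow(sources) > 0) {
    src <- sources %>%
      count(.data$variant_name, .data$scenario) %>%
      group_by(.data$variant_name) %>%
      summarise(source_calls = paste0(.data$scenario, ":", .data$n,
                                      collapse = ";"), .groups = "drop")
    out <- out %>% left_join(src, by = "variant_name") %>%
      mutate(source_calls = coalesce(.data$source_calls, ""))
  }
  readr::write_tsv(out, path)
  invisible(path)
}
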