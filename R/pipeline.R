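# End-to-end orchestration: filter -> consensus -> annotate -> assign
# (-> editing, separately), with every filter's drop count logged and a
# derived summary report.

#' Run the guide-calling pipeline
#'
#' Executes the full chain on a guide-library BAM (or an in-memory read
#' table): alignment filtering, UMI consensus calling, read-support
#' filtering, mutation annotation, variant collation, source classification,
#' count-matrix construction and cell assignment. All stage outputs are
#' returned; when `out_dir` is given they are also written in their standard
#' file formats.
#'
#' @param bam BAM path or tagged-read tibble.
#' @param whitelist barcode vector or whitelist file path.
#' @param reference a `custom_reference`, or c(fasta=, gtf=) paths.
#' @param lookup optional barcode lookup (named vector or TSV path).
#' @param dialect `"cellranger"` or `"dropseq"`.
#' @param min_reads consensus read-support filter (default 2).
#' @param mode assignment mode, `"gmm"` or `"fixed"`.
#' @param threshold fixed-mode threshold / GMM fallback (default 3).
#' @param min_cells minimum nonzero cells for a GMM fit (default 10).
#' @param seed pipeline seed for all randomized steps (default 17).
#' @param mask_tso mask template-switch positions in the mutation spectrum.
#' @param out_dir optional output directory.
#' @return a `guidecall_run` list: `reads_drop_counts`, `consensus`
#'   (filtered molecules), `annotated`, `variants`, `sources`, `counts`,
#'   `assignment`, `spectrum`, `saturation`, `report` (one-row tibble).
#' @export
run_pipeline <- function(bam, whitelist, reference, lookup = NULL,
                         dialect = c("cellranger", "dropseq"),
                         min_reads = 2L, mode = c("gmm", "fixed"),
                         threshold = 3L, min_cells = 10L, seed = 17,
                         mask_tso = FALSE, out_dir = NULL) {
  dialect <- match.arg(dialect)
  mode <- match.arg(mode)
  if (is.character(whitelist) && length(whitelist) == 1 &&
      file.exists(whitelist)) {
    whitelist <- read_barcode_whitelist(whitelist)
  }
  if (length(whitelist) == 0) {
    abort("stage filter: the cell-barcode whitelist is empty")
  }
  if (is.character(reference)) {
    reference <- read_custom_reference(reference[["fasta"]],
                                       reference[["gtf"]])
  }
  if (is.character(lookup) && length(lookup) == 1 && file.exists(lookup)) {
    lookup <- read_barcode_lookup(lookup)
  }

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(paste0("stage ", name, ": ", conditionMessage(e)))
    })
  }
  reads <- stage("filter", read_guide_alignments(bam, whitelist, reference,
                                                 lookup = lookup,
                                                 dialect = dialect))
  drops <- drop_counts(reads)
  raw_molecules <- stage("consensus", call_consensus(reads, seed = seed))
  saturation <- sequencing_saturation(nrow(reads), nrow(raw_molecules))
  molecules <- stage("consensus", filter_consensus(raw_molecules,
                                                   min_reads = min_reads))
  n_low_support <- attr(molecules, "n_dropped_low_support")
  annotated <- stage("annotate", annotate_mutations(molecules, reference))
  variants <- stage("annotate", collate_variants(annotated))
  annotated <- name_molecule_variants(annotated, variants)
  sources <- stage("annotate", classify_sources(annotated, variants))
  spectrum <- stage("annotate", mutation_spectrum(variants, reference,
                                                  mask_tso = mask_tso))
  counts <- stage("assign", build_count_matrix(annotated))
  assignment <- stage("assign", assign_guides(counts, mode = mode,
                                              threshold = threshold,
                                              seed = seed,
                                              min_cells = min_cells))
  cc <- attr(raw_molecules, "consensus_counts")
  g <- glance(assignment)
  report <- dplyr::bind_cols(
    g,
    tibble(
      n_variants_total = nrow(variants),
      n_variants_intact = sum(variants$is_intact),
      n_variants_mutant = sum(!variants$is_intact),
      n_molecules = nrow(molecules),
      pct_molecules_mutant = if (nrow(annotated)) {
        100 * mean(!annotated$is_intact)
      } else 0,
      saturation = saturation,
      reads_kept = nrow(reads),
      drop_secondary = drops[["secondary"]],
      drop_supplementary = drops[["supplementary"]],
      drop_unmapped = drops[["unmapped"]],
      drop_off_target = drops[["off_target_contig"]],
      drop_missing_tags = drops[["missing_tags"]],
      drop_whitelist = drops[["barcode_not_in_whitelist"]],
      drop_annotation_tie_groups = cc[["annotation_tie_groups"]],
      drop_low_support_molecules = n_low_support
    )
  )
  run <- structure(
    list(reads_drop_counts = drops, consensus = molecules,
         annotated = annotated, variants = variants, sources = sources,
         counts = counts, assignment = assignment, spectrum = spectrum,
         saturation = saturation, report = report,
         params = list(dialect = dialect, min_reads = min_reads, mode = mode,
                       threshold = threshold, min_cells = min_cells,
                       seed = seed)),
    class = "guidecall_run"
  )
  if (!is.null(out_dir)) {
    write_pipeline_outputs(run, out_dir, reference, dialect)
  }
  run
}

#' @export
print.guidecall_run <- function(x, ...) {
  r <- x$report
  cat("<guidecall_run> ", r$n_cells, " cells, ", r$n_molecules,
      " consensus molecules, ", r$n_variants_intact, " intact + ",
      r$n_variants_mutant, " mutant variants\n",
      "  cells: none ", r$n_none, " | single_intact ", r$n_single_intact,
      " | single_mutant ", r$n_single_mutant, " | multiplet ",
      r$n_multiplet, "\n",
      "  % cells with a mutant guide: ",
      sprintf("%.1f", r$pct_cells_with_mutant),
      " | saturation: ", sprintf("%.3f", r$saturation), "\n", sep = "")
  invisible(x)
}

write_pipeline_outputs <- function(run, out_dir, reference, dialect) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_consensus(run$consensus, out_dir, reference, dialect = dialect)
  write_variant_table(run$variants, file.path(out_dir, "gRNA.mutation.txt"),
                      sources = run$sources)
  readr::write_tsv(run$spectrum, file.path(out_dir, "mutation.spectrum.txt"))
  write_count_matrix(run$counts, out_dir)
  write_assignments(run$assignment, file.path(out_dir, "assignments.txt"))
  readr::write_tsv(run$report, file.path(out_dir, "report.txt"))
  invisible(out_dir)
}
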