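ann_one <- function(ref, seq, pos = 0L, cigar = paste0(nchar(seq), "M"),
                    guide = "guide1") {
  m <- tibble::tibble(cell_barcode = "CB", umi = "U", guide_id = guide,
                      sequence = seq, contig = guide, pos = pos,
                      cigar = cigar, n_reads = 2L, n_support = 2L,
                      n_excluded = 0L)
  annotate_mutations(m, ref)
}

test_that("a perfect aligned span yields an intact molecule with zero events", {
  ref <- tiny_reference(1)
  contig <- ref$contigs[["guide1"]]
  out <- ann_one(ref, substr(contig, 1, 20))
  expect_true(out$is_intact)
  expect_equal(out$n_events, 0L)
  expect_equal(out$mutation_string, "")
})

test_that("hand-built alignments produce the expected itemized events with regions", {
  ref <- tiny_reference(1)  # upstream AAACCC (0-5), spacer (6-25), scaffold
  contig <- ref$contigs[["guide1"]]

  # substitution at spacer offset 5 (cassette position 11)
  s <- substr(contig, 1, 20)
  mut <- s
  substr(mut, 12, 12) <- setdiff(c("A", "C", "G", "T"),
                                 substr(s, 12, 12))[1]
  out <- ann_one(ref, mut)
  ev <- out$events[[1]]
  expect_equal(nrow(ev), 1)
  expect_equal(ev$kind, "substitution")
  expect_equal(ev$position, 11L)
  expect_equal(ev$region, "spacer")
  expect_false(out$is_intact)

  # single-base deletion in the scaffold (cassette position 27)
  del <- paste0(substr(contig, 1, 27), substr(contig, 29, 34))
  out2 <- ann_one(ref, del, cigar = "27M1D6M")
  ev2 <- out2$events[[1]]
  expect_equal(ev2$kind, "deletion")
  expect_equal(ev2$position, 27L)
  expect_equal(ev2$region, "scaffold")
  expect_equal(ev2$ref, substr(contig, 28, 28))

  # insertion anchored to the following reference base, upstream region
  ins <- paste0(substr(contig, 1, 3), "TT", substr(contig, 4, 10))
  out3 <- ann_one(ref, ins, cigar = "3M2I7M")
  ev3 <- out3$events[[1]]
  expect_equal(ev3$kind, "insertion")
  expect_equal(ev3$position, 3L)
  expect_equal(ev3$alt, "TT")
  expect_equal(ev3$region, "upstream")

  # soft clip marks the molecule as deviant without aligning its bases
  sc <- paste0("TTT", substr(contig, 1, 10))
  out4 <- ann_one(ref, sc, cigar = "3S10M")
  expect_false(out4$is_intact)
  expect_true("softclip" %in% out4$events[[1]]$kind)

  # CIGAR inconsistent with the sequence length excludes the molecule
  out5 <- ann_one(ref, "ACGT", cigar = "10M")
  expect_equal(nrow(out5), 0)
  expect_equal(nrow(attr(out5, "annotation_errors")), 1)
})

test_that("intactness is strictly stricter than 1-Hamming tolerance", {
  ref <- tiny_reference(1)
  contig <- ref$contigs[["guide1"]]
  s <- substr(contig, 1, 25)
  one_sub <- s
  substr(one_sub, 10, 10) <- setdiff(c("A", "C", "G", "T"),
                                     substr(s, 10, 10))[1]
  out <- ann_one(ref, one_sub)
  expect_false(out$is_intact)  # 1 mismatch => mutant, never intact
  expect_equal(out$n_events, 1L)
  # oracle: intact <=> Hamming distance 0 and equal length over the span
  expect_true(ann_one(ref, s)$is_intact)
})

test_that("event lists reconstruct the consensus sequence (reconstruction identity)", {
  sim <- simulate_screen(sim_config(n_cells = 40, n_guides = 8,
                                    mean_umis_per_cell = 6,
                                    mean_reads_per_umi = 5, error_rate = 0,
                                    n_edit_genes = 0, seed = 13))
  reads <- read_guide_alignments(sim$reads, sim$whitelist, sim$reference)
  m <- filter_consensus(call_consensus(reads, seed = 13), 2)
  ann <- annotate_mutations(m, sim$reference)
  for (i in seq_len(nrow(ann))) {
    ev <- ann$events[[i]]
    if (any(ev$kind %in% c("skip", "softclip"))) next
    span <- nchar(ann$sequence[i]) -
      sum(nchar(ev$alt[ev$kind == "insertion"])) +
      sum(nchar(ev$ref[ev$kind == "deletion"]))
    rebuilt <- apply_events_oracle(sim$reference$contigs[[ann$guide_id[i]]],
                                   ev, ann$pos[i], span)
    expect_equal(rebuilt, ann$sequence[i])
  }
})

test_that("variant collation collapses identical event lists and names variants stably", {
  ref <- tiny_reference(1)
  contig <- ref$contigs[["guide1"]]
  s <- substr(contig, 1, 20)
  v1 <- s; substr(v1, 5, 5) <- setdiff(c("A","C","G","T"), substr(s,5,5))[1]
  v2 <- s; substr(v2, 9, 9) <- setdiff(c("A","C","G","T"), substr(s,9,9))[1]
  mols <- dplyr::bind_rows(
    tibble::tibble(cell_barcode = c("C1", "C2", "C1"), umi = c("U1","U2","U3"),
                   guide_id = "guide1", sequence = c(v1, v1, v2),
                   contig = "guide1", pos = 0L, cigar = "20M",
                   n_reads = 2L, n_support = 2L, n_excluded = 0L)
  )
  ann <- annotate_mutations(mols, ref)
  vars <- collate_variants(ann)
  expect_equal(nrow(vars), 2)            # no intact entry observed
  expect_false(any(vars$is_intact))
  # suffixes ordered by descending UMI support
  expect_equal(vars$variant_name[vars$n_umis == 2], "guide1.1")
  expect_equal(vars$variant_name[vars$n_umis == 1], "guide1.2")
  v1row <- vars[vars$variant_name == "guide1.1", ]
  expect_equal(v1row$n_cells, 2L)
  # sum of variant UMIs equals surviving molecules per guide
  expect_equal(sum(vars$n_umis), nrow(mols))
})

test_that("planted variant catalogs are recovered exactly on noiseless fixtures", {
  sim <- simulate_screen(sim_config(n_cells = 80, n_guides = 10,
                                    mean_umis_per_cell = 10,
                                    mean_reads_per_umi = 5, error_rate = 0,
                                    n_edit_genes = 0, seed = 23))
  run <- run_pipeline(sim$reads, sim$whitelist, sim$reference, seed = 23)
  got <- sort(paste0(run$variants$guide_id[!run$variants$is_intact], "|",
                     run$variants$mutation_string[!run$variants$is_intact]))
  truth_observed <- sim$truth$molecules |>
    dplyr::filter(n_reads >= 2, mutation_string != "") |>
    dplyr::distinct(guide_id, mutation_string)
  want <- sort(paste0(truth_observed$guide_id, "|",
                      truth_observed$mutation_string))
  expect_equal(got, want)
})

test_that("source classification reproduces the scenario rules", {
  # three worked constellations plus the multi-cell rule
  ref <- tiny_reference(1)
  contig <- ref$contigs[["guide1"]]
  s <- substr(contig, 1, 20)
  mk_mol <- function(cb, umi, seq) {
    tibble::tibble(cell_barcode = cb, umi = umi, guide_id = "guide1",
                   sequence = seq, contig = "guide1", pos = 0L, cigar = "20M",
                   n_reads = 3L, n_support = 3L, n_excluded = 0L)
  }
  mut <- s; substr(mut, 7, 7) <- setdiff(c("A","C","G","T"), substr(s,7,7))[1]
  mut2 <- s; substr(mut2, 12, 12) <- setdiff(c("A","C","G","T"),
                                             substr(s,12,12))[1]
  mut3 <- s; substr(mut3, 15, 15) <- setdiff(c("A","C","G","T"),
                                             substr(s,15,15))[1]
  mols <- dplyr::bind_rows(
    # mut in 5 cells -> virus_pool
    lapply(1:5, function(i) mk_mol(paste0("VP", i), paste0("U", i), mut)),
    # one cell, 1 mutant UMI + many intact UMIs -> cdna_prep
    list(mk_mol("CD1", "UM", mut2)),
    lapply(1:8, function(i) mk_mol("CD1", paste0("UI", i), s)),
    # one cell, 3 mutant + 4 intact UMIs -> integration_duplication
    lapply(1:3, function(i) mk_mol("ID1", paste0("VM", i), mut3)),
    lapply(1:4, function(i) mk_mol("ID1", paste0("VI", i), s))
  )
  ann <- annotate_mutations(mols, ref)
  vars <- collate_variants(ann)
  ann <- name_molecule_variants(ann, vars)
  src <- classify_sources(ann, vars)
  vp <- src[src$cell_barcode %in% paste0("VP", 1:5), ]
  expect_true(all(vp$scenario == "virus_pool"))
  cd <- src[src$cell_barcode == "CD1", ]
  expect_equal(cd$scenario, "cdna_prep")
  id <- src[src$cell_barcode == "ID1", ]
  expect_equal(id$scenario, "integration_duplication")

  # single-cell all-UMI mutant -> transduction_or_subclone
  mols2 <- dplyr::bind_rows(lapply(1:4, function(i)
    mk_mol("TD1", paste0("T", i), mut)))
  ann2 <- annotate_mutations(mols2, ref)
  vars2 <- collate_variants(ann2)
  src2 <- classify_sources(name_molecule_variants(ann2, vars2), vars2)
  expect_equal(src2$scenario, "transduction_or_subclone")
})

test_that("source classifier agrees with planted scenarios on simulated screens", {
  sim <- simulate_screen(sim_config(n_cells = 150, n_guides = 12,
                                    mean_umis_per_cell = 15,
                                    mean_reads_per_umi = 6, error_rate = 0,
                                    ambient_guides_per_cell = 0,
                                    n_edit_genes = 0, seed = 29))
  run <- run_pipeline(sim$reads, sim$whitelist, sim$reference, seed = 29)
  truth <- sim$truth$molecules |>
    dplyr::filter(mutation_string != "", n_reads >= 2) |>
    dplyr::distinct(cell_barcode, guide_id, mutation_string, scenario)
  src <- run$sources |>
    dplyr::left_join(run$variants[c("variant_name", "mutation_string")],
                     by = "variant_name") |>
    dplyr::inner_join(truth, by = c("cell_barcode", "guide_id",
                                    "mutation_string"),
                      suffix = c("_called", "_true"))
  # virus-pool variants seen in > 1 cell are always called virus_pool
  vp <- src[src$scenario_true == "virus_pool" & src$n_variant_cells > 1, ]
  expect_true(all(vp$scenario_called == "virus_pool"))
  # cdna-prep single-UMI mutants alongside intact are called cdna_prep
  cd <- src[src$scenario_true == "cdna_prep", ]
  expect_true(all(cd$scenario_called %in% c("cdna_prep")))
  # integration/duplication cells with > 1 UMI of each form
  id <- src[src$scenario_true == "integration_duplication", ]
  expect_true(all(id$scenario_called == "integration_duplication"))
})

test_that("mutation spectra locate planted events and TSO masking removes pre-spacer positions", {
  ref <- tiny_reference(1)
  contig <- ref$contigs[["guide1"]]
  sp <- spacer_regions(ref)  # spacer starts at 6
  s <- substr(contig, 1, 25)
  at_start <- s
  substr(at_start, sp$start + 1, sp$start + 1) <-
    setdiff(c("A","C","G","T"), substr(s, sp$start + 1, sp$start + 1))[1]
  in_spacer <- s
  substr(in_spacer, 15, 15) <- setdiff(c("A","C","G","T"),
                                       substr(s, 15, 15))[1]
  mols <- tibble::tibble(
    cell_barcode = c("C1", "C2"), umi = c("U1", "U2"), guide_id = "guide1",
    sequence = c(at_start, in_spacer), contig = "guide1", pos = 0L,
    cigar = "25M", n_reads = 2L, n_support = 2L, n_excluded = 0L
  )
  ann <- annotate_mutations(mols, ref)
  vars <- collate_variants(ann)
  spec <- mutation_spectrum(vars, ref)
  expect_equal(sum(spec$count), 2)
  expect_equal(spec$count[spec$position == sp$start], 1)
  expect_equal(spec$count[spec$position == 14], 1)
  # masking removes positions -2..0 relative to the spacer start
  masked <- mutation_spectrum(vars, ref, mask_tso = TRUE)
  expect_equal(masked$count[masked$position == sp$start], 0)
  expect_equal(masked$count[masked$position == 14], 1)
  # no variants -> all-zero spectrum
  zero <- mutation_spectrum(vars[0, ], ref)
  expect_true(all(zero$count == 0))
})

test_that("per-cell mutation rate normalizes by profiled guide length", {
  ref <- tiny_reference(2)
  contig <- ref$contigs[["guide1"]]
  s <- substr(contig, 1, 20)
  mut <- s; substr(mut, 8, 8) <- setdiff(c("A","C","G","T"),
                                         substr(s, 8, 8))[1]
  mols <- tibble::tibble(
    cell_barcode = c("C1", "C1"), umi = c("U1", "U2"), guide_id = "guide1",
    sequence = c(mut, s), contig = "guide1", pos = 0L, cigar = "20M",
    n_reads = 2L, n_support = 2L, n_excluded = 0L
  )
  ann <- annotate_mutations(mols, ref)
  rate <- mutation_rate_per_cell(ann, ref)
  L <- nchar(contig)
  expect_equal(rate$n_mutated_positions, 1L)
  expect_equal(rate$rate_per_kb, 1 / L * 1000)
})
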