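test_that("configs validate their fractions", {
  expect_error(sim_config(fraction_doublet = 1.2), "fractions")
  expect_error(sim_config(fraction_untransformed = 0.7,
                          fraction_doublet = 0.5), "exceed")
})

test_that("simulation is bit-reproducible for a fixed config and seed", {
  cfg <- sim_config(n_cells = 25, n_guides = 5, mean_umis_per_cell = 5,
                    mean_reads_per_umi = 3, seed = 19)
  s1 <- simulate_screen(cfg)
  s2 <- simulate_screen(cfg)
  expect_identical(s1$reads, s2$reads)
  expect_identical(s1$truth$molecules, s2$truth$molecules)
  expect_identical(s1$reference$contigs, s2$reference$contigs)
  # and the serialized BAMs are byte-identical
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  p1 <- write_screen_bam(s1, d1); p2 <- write_screen_bam(s2, d2)
  expect_identical(unname(tools::md5sum(p1[["grna_bam"]])),
                   unname(tools::md5sum(p2[["grna_bam"]])))
  # a different seed changes the reads
  s3 <- simulate_screen(sim_config(n_cells = 25, n_guides = 5,
                                   mean_umis_per_cell = 5,
                                   mean_reads_per_umi = 3, seed = 20))
  expect_false(identical(s1$reads, s3$reads))
})

test_that("truth tables are consistent with the emitted reads", {
  sim <- simulate_screen(sim_config(n_cells = 30, n_guides = 6,
                                    mean_umis_per_cell = 5,
                                    mean_reads_per_umi = 3, n_edit_genes = 0,
                                    seed = 19))
  per_mol <- dplyr::count(sim$reads, cell_barcode, umi, name = "n")
  truth_obs <- dplyr::filter(sim$truth$molecules, n_reads > 0)
  j <- dplyr::full_join(per_mol, truth_obs, by = c("cell_barcode", "umi"))
  expect_false(any(is.na(j$n)) || any(is.na(j$n_reads)))
  expect_equal(j$n, j$n_reads)
})

test_that("scenario constructions satisfy their defining constraints", {
  sim <- simulate_screen(sim_config(n_cells = 120, n_guides = 10,
                                    mean_umis_per_cell = 10,
                                    mean_reads_per_umi = 4,
                                    frac_cdna_cells = 1, n_edit_genes = 0,
                                    seed = 37))
  tm <- sim$truth$molecules
  # every cdna-prep mutant: exactly 1 UMI, in exactly 1 cell, alongside intact
  cd <- dplyr::filter(tm, scenario == "cdna_prep")
  expect_gt(nrow(cd), 0)
  per_var <- dplyr::count(cd, guide_id, mutation_string, name = "n_umis")
  expect_true(all(per_var$n_umis == 1))
  for (i in seq_len(nrow(cd))) {
    sib <- tm[tm$cell_barcode == cd$cell_barcode[i] &
                tm$guide_id == cd$guide_id[i] & !tm$ambient, ]
    expect_gte(sum(sib$mutation_string == ""), 1)
  }
  # virus-pool variants recur across cells (given enough cells)
  vp <- dplyr::filter(tm, scenario == "virus_pool")
  vp_cells <- dplyr::summarise(dplyr::group_by(vp, guide_id, mutation_string),
                               n_cells = dplyr::n_distinct(cell_barcode))
  expect_gt(mean(vp_cells$n_cells > 1), 0.5)
  # integration-duplication cells carry > 1 UMI of both forms
  sim2 <- simulate_screen(sim_config(n_cells = 100, n_guides = 8,
                                     mean_umis_per_cell = 12,
                                     mean_reads_per_umi = 4,
                                     frac_integration_cells = 0.2,
                                     frac_guides_with_pool_mutant = 0,
                                     n_edit_genes = 0, seed = 38))
  tm2 <- sim2$truth$molecules
  dup <- dplyr::filter(tm2, scenario == "integration_duplication")
  expect_gt(nrow(dup), 0)
  for (cb in unique(dup$cell_barcode)) {
    cell <- tm2[tm2$cell_barcode == cb & !tm2$ambient, ]
    expect_gt(sum(cell$mutation_string != ""), 1)
    expect_gt(sum(cell$mutation_string == ""), 1)
  }
})

test_that("downsampling thins binomially, reproducibly, and reduces molecules", {
  sim <- simulate_screen(sim_config(n_cells = 50, n_guides = 6,
                                    mean_umis_per_cell = 8,
                                    mean_reads_per_umi = 4, n_edit_genes = 0,
                                    seed = 43))
  # fraction 1 is the identity
  expect_identical(downsample_reads(sim$reads, 1, seed = 1), sim$reads)
  # kept count within the binomial 99% CI
  n <- nrow(sim$reads)
  ds <- downsample_reads(sim$reads, 0.5, seed = 43)
  ci <- stats::qbinom(c(0.005, 0.995), n, 0.5)
  expect_gte(nrow(ds), ci[1]); expect_lte(nrow(ds), ci[2])
  # reproducible
  expect_identical(ds, downsample_reads(sim$reads, 0.5, seed = 43))
  expect_error(downsample_reads(sim$reads, 0), "fraction")
  # fewer surviving consensus molecules than the full run
  full <- run_pipeline(sim$reads, sim$whitelist, sim$reference, seed = 43)
  down <- run_pipeline(ds, sim$whitelist, sim$reference, seed = 43)
  expect_lt(nrow(down$consensus), nrow(full$consensus))
})

test_that("sequencing saturation follows 1 - unique/reads", {
  expect_equal(sequencing_saturation(100, 100), 0)
  expect_equal(sequencing_saturation(1000, 11), 0.989)
  expect_equal(sequencing_saturation(0, 0), 0)
  # monotone non-decreasing in reads at fixed molecules
  sats <- vapply(100:200, sequencing_saturation,
                 numeric(1), n_unique_molecules = 50)
  expect_true(all(diff(sats) >= 0))
  expect_error(sequencing_saturation(5, 10))
})

test_that("concordance scores exact set matches with an error breakdown", {
  truth <- tibble::tibble(
    cell_barcode = paste0("C", 1:10),
    true_variants = c(rep(list("gA|"), 9), list(c("gA|", "gB|")))
  )
  variants <- tibble::tibble(variant_name = c("gA", "gB"),
                             guide_id = c("gA", "gB"),
                             mutation_string = "")
  counts <- tibble::tibble(
    cell_barcode = c(paste0("C", 1:9), "C10", "C10"),
    variant_name = c(rep("gA", 9), "gA", "gB"),
    guide_id = c(rep("gA", 9), "gA", "gB"),
    count = 10L
  )
  res <- assign_guides(counts, mode = "fixed", threshold = 3)
  cc <- assignment_concordance(truth, res, variants)
  expect_equal(cc$concordance, 1)
  # one of ten cells mislabeled -> 0.9 with the right error mode
  counts2 <- counts[-1, ]  # C1 loses its guide
  res2 <- assign_guides(counts2, mode = "fixed", threshold = 3)
  res2$cells <- dplyr::bind_rows(
    res2$cells,
    tibble::tibble(cell_barcode = "C1", label = "none",
                   variants = list(character(0)), n_assigned = 0L,
                   total_umis = 0L))
  cc2 <- assignment_concordance(truth, res2, variants)
  expect_equal(cc2$concordance, 0.9)
  expect_equal(unname(cc2$breakdown["missed_guide"]), 1L)
})

test_that("noiseless screens at depth are recovered with full concordance", {
  sim <- simulate_screen(sim_config(n_cells = 60, n_guides = 8,
                                    mean_umis_per_cell = 40,
                                    mean_reads_per_umi = 6, error_rate = 0,
                                    ambient_guides_per_cell = 0,
                                    frac_cdna_cells = 0, n_edit_genes = 0,
                                    seed = 53))
  # without ambient there is no background component to separate, so the
  # mixture mode is inapplicable; a fixed threshold recovers the truth
  run <- run_pipeline(sim$reads, sim$whitelist, sim$reference, seed = 53,
                      mode = "fixed", threshold = 3)
  cc <- assignment_concordance(sim$truth$cells, run$assignment, run$variants)
  expect_equal(cc$concordance, 1)
})
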