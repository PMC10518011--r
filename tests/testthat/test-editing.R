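test_that("cutsites sit 3 nt upstream of the PAM with symmetric odd windows", {
  targets <- tibble::tibble(guide_id = "g1", gene = "GENE1", chrom = "chr1",
                            pam_pos = 1000L, strand = "+")
  w <- compute_cutsites(targets)
  expect_equal(w$cutsite, 997L)
  expect_equal(c(w$window_start, w$window_end), c(972L, 1023L))
  # minus strand mirrors the offset
  wm <- compute_cutsites(dplyr::mutate(targets, strand = "-"))
  expect_equal(wm$cutsite, 1003L)
  # even widths are rejected; missing PAM info skips with a warning
  expect_error(compute_cutsites(targets, window_width = 50), "odd")
  expect_warning(
    out <- compute_cutsites(dplyr::bind_rows(
      targets, tibble::tibble(guide_id = "g2", gene = "G2", chrom = "chr1",
                              pam_pos = NA_integer_, strand = "+"))),
    "skipping"
  )
  expect_equal(out$guide_id, "g1")
})

editing_fixture <- function() {
  set.seed(77)
  contig <- paste0(sample(c("A", "C", "G", "T"), 2000, replace = TRUE),
                   collapse = "")
  windows <- compute_cutsites(tibble::tibble(
    guide_id = "g1", gene = "GENE1", chrom = "chr1", pam_pos = 1000L,
    strand = "+"))
  exons <- tibble::tibble(gene = "GENE1", chrom = "chr1",
                          start = 800L, end = 1200L)
  ref_seq <- substr(contig, windows$window_start + 1, windows$window_end)
  list(contig = contig, windows = windows, exons = exons,
       ref_seqs = c(g1 = ref_seq))
}

fx_read <- function(fx, cb, umi, pos, cigar, seq) {
  tibble::tibble(qname = paste0(cb, umi, pos), flag = 0L, contig = "chr1",
                 pos = pos, cigar = cigar, seq = seq,
                 cell_barcode = cb, umi = umi, guide_annotation = "GENE1")
}

sub_ref <- function(fx, from, to) substr(fx$contig, from + 1, to)

test_that("window fetch keeps only exon-overlapping reads inside the window", {
  fx <- editing_fixture()
  reads <- dplyr::bind_rows(
    fx_read(fx, "C1", "U1", 980L, "40M", sub_ref(fx, 980, 1020)),
    # fully outside the window
    fx_read(fx, "C1", "U2", 1500L, "40M", sub_ref(fx, 1500, 1540)),
    # overlapping the window but not the gene's exon (different chrom gene)
    tibble::tibble(qname = "x", flag = 0L, contig = "chr2", pos = 980L,
                   cigar = "40M", seq = sub_ref(fx, 980, 1020),
                   cell_barcode = "C1", umi = "U3",
                   guide_annotation = "OTHER")
  )
  wr <- window_reads(reads, fx$windows, fx$exons)
  expect_equal(nrow(wr), 1)
  expect_equal(wr$umi, "U1")
})

test_that("union consensus merges tiling reads and contains deletions seen by one read", {
  fx <- editing_fixture()
  ws <- fx$windows$window_start
  we <- fx$windows$window_end
  cut <- fx$windows$cutsite
  # two reads tiling left/right halves cover the whole window
  left <- fx_read(fx, "C1", "U1", ws - 5L, "31M", sub_ref(fx, ws - 5, ws + 26))
  right <- fx_read(fx, "C1", "U1", ws + 20L, "31M",
                   sub_ref(fx, ws + 20, ws + 51))
  u <- union_consensus(dplyr::bind_rows(left, right), ws, we)
  expect_equal(sort(u$positions$position), seq(ws, we - 1))
  expect_true(all(u$positions$state == "base"))

  # planted 6-bp deletion covered by only one of two reads
  del_start <- cut - 2L
  del_seq <- paste0(sub_ref(fx, ws - 5, del_start),
                    sub_ref(fx, del_start + 6, del_start + 6 + 14))
  del_read <- fx_read(fx, "C2", "U2", ws - 5L,
                      paste0(del_start - (ws - 5), "M6D15M"), del_seq)
  plain <- fx_read(fx, "C2", "U2", ws + 30L, "15M",
                   sub_ref(fx, ws + 30, ws + 45))
  u2 <- union_consensus(dplyr::bind_rows(del_read, plain), ws, we)
  del_pos <- u2$positions$position[u2$positions$state == "deletion"]
  expect_equal(sort(del_pos), seq(del_start, del_start + 5))
  # single read: union equals that read's calls
  u3 <- union_consensus(left, ws, we)
  expect_equal(nrow(u3$positions), 31 - 5)
})

test_that("editing classification follows the cutsite rule", {
  fx <- editing_fixture()
  ws <- fx$windows$window_start
  we <- fx$windows$window_end
  cut <- fx$windows$cutsite

  call_for <- function(reads) {
    u <- union_consensus(reads, ws, we)
    call_editing(u, cut, ref_seq = fx$ref_seqs[["g1"]], window_start = ws)
  }
  # deletion [cutsite-2, cutsite+3) -> cutsite_deletion
  d5 <- fx_read(fx, "C1", "U1", ws,
                paste0(cut - 2 - ws, "M5D20M"),
                paste0(sub_ref(fx, ws, cut - 2), sub_ref(fx, cut + 3, cut + 23)))
  expect_equal(call_for(d5)$klass, "cutsite_deletion")

  # insertion 10 bp away, no cutsite deletion -> other_indel (reported)
  ins <- fx_read(fx, "C2", "U2", ws, paste0(cut - 10 - ws, "M3I20M"),
                 paste0(sub_ref(fx, ws, cut - 10), "AAA",
                        sub_ref(fx, cut - 10, cut + 10)))
  ci <- call_for(ins)
  expect_equal(ci$klass, "other_indel")
  expect_true("insertion" %in% ci$events$kind)

  # deletion away from the cutsite -> other_indel, never Cas9-induced
  doff <- fx_read(fx, "C3", "U3", ws, "5M3D20M",
                  paste0(sub_ref(fx, ws, ws + 5), sub_ref(fx, ws + 8, ws + 28)))
  expect_equal(call_for(doff)$klass, "other_indel")

  # perfect match -> unedited; mismatch only -> mismatch_only
  ok <- fx_read(fx, "C4", "U4", ws, "40M", sub_ref(fx, ws, ws + 40))
  expect_equal(call_for(ok)$klass, "unedited")
  mm_seq <- sub_ref(fx, ws, ws + 40)
  substr(mm_seq, 5, 5) <- setdiff(c("A", "C", "G", "T"),
                                  substr(mm_seq, 5, 5))[1]
  mm <- fx_read(fx, "C5", "U5", ws, "40M", mm_seq)
  expect_equal(call_for(mm)$klass, "mismatch_only")

  # spliced alignment gaps (N) are never cutsite deletions
  spl <- fx_read(fx, "C6", "U6", ws, paste0(cut - 2 - ws, "M5N20M"),
                 paste0(sub_ref(fx, ws, cut - 2),
                        sub_ref(fx, cut + 3, cut + 23)))
  expect_equal(call_for(spl)$klass, "unedited")
})

test_that("reads outside a window never influence its calls", {
  fx <- editing_fixture()
  ws <- fx$windows$window_start
  we <- fx$windows$window_end
  inside <- fx_read(fx, "C1", "U1", ws, "40M", sub_ref(fx, ws, ws + 40))
  # same molecule also has a read far outside the window carrying a deletion
  outside <- fx_read(fx, "C1", "U1", 1500L, "5M6D20M",
                     paste0(sub_ref(fx, 1500, 1505),
                            sub_ref(fx, 1511, 1531)))
  wr <- window_reads(dplyr::bind_rows(inside, outside), fx$windows, fx$exons)
  expect_equal(nrow(wr), 1)
  calls <- detect_editing(dplyr::bind_rows(inside, outside), fx$windows,
                          fx$exons, ref_seqs = fx$ref_seqs)
  expect_equal(calls$klass, "unedited")
})

test_that("edited carrier cells show more cutsite deletions than controls on fixtures", {
  sim <- simulate_screen(sim_config(n_cells = 80, n_guides = 8,
                                    mean_umis_per_cell = 8,
                                    mean_reads_per_umi = 4,
                                    n_edit_genes = 2, seed = 47))
  ed <- sim$editing
  calls <- detect_editing(ed$reads, ed$windows, ed$exons,
                          ref_seqs = ed$ref_seqs)
  j <- dplyr::inner_join(calls, ed$truth,
                         by = c("cell_barcode", "umi", "gene", "guide_id"))
  # per-molecule classification equals the planted truth
  expect_true(all(j$klass[j$edited] == "cutsite_deletion"))
  expect_true(all(j$klass[!j$edited] == "unedited"))
  frac <- function(keep) mean(j$klass[keep] == "cutsite_deletion")
  expect_gt(frac(j$carrier), frac(!j$carrier))
})
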