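# Ground-truthed synthetic screens.
#
# The generator emulates the data structure a droplet CRISPR screen produces
# after alignment: barcode/UMI-tagged reads over artificial guide contigs,
# with guide mutations arising through the five recognized routes — variants
# amplified in the virus pool (shared across cells), variants private to one
# cell from transduction or a rare pool sub-clone (all UMIs mutant), variants
# from integration-associated cassette duplication (intact and mutant
# co-expressed, >1 UMI each), single-UMI cDNA-preparation mutants alongside
# intact molecules, and per-read sequencing errors within a UMI. Reads are
# emitted pre-aligned (CIGARs computed from the planted events), since the
# pipeline consumes aligner output. Every random quantity flows from one seed,
# so a config reproduces its screen bit-for-bit.

# default cassette context: U6-end / cloning-arm upstream, canonical tracr
# scaffold downstream (both public constant sequences of gRNA cassettes)
DEFAULT_UPSTREAM <- "TCTTGTGGAAAGGACGAAACACC"
DEFAULT_SCAFFOLD <- paste0("GTTTTAGAGCTAGAAATAGCAAGTTAAAATAAGGCTAGTCCGTTATCA",
                           "ACTTGAAAAAGTGGCACCGAGTCGGTGC")

#' Simulation configuration for a synthetic screen
#'
#' Defaults parameterize a desk-scale screen with the mutation economy of a
#' real CROP-seq experiment: ~28% of guide molecules mutant, dominated by
#' virus-pool variants recurring across cells, with rarer transduction
#' (~0.4% of cells), integration/duplication (~1.4%) and single-UMI cDNA
#' (~18%) events, ambient contamination at ~1 UMI, and bimodal per-guide UMI
#' counts.
#'
#' @param n_cells number of cells (default 500).
#' @param n_guides number of guides in the library (default 120).
#' @param spacer_len spacer length including the leading G (default 20).
#' @param fraction_untransformed cells carrying no guide (default 0.05).
#' @param fraction_doublet transformed cells carrying two guides
#'   (default 0.1).
#' @param mean_umis_per_cell mean in-cell UMIs per guide per cell
#'   (log-normal; default 53).
#' @param umi_sdlog log-normal sdlog of in-cell UMI counts (default 0.5).
#' @param ambient_guides_per_cell Poisson mean of contaminating guide species
#'   per cell (default 3).
#' @param ambient_umi_mean mean ambient UMI count per contaminating species;
#'   counts are zero-truncated geometric with this mean (default 1.5).
#' @param mean_reads_per_umi Poisson mean read depth per molecule; molecules
#'   drawing 0 reads are unobserved (default 10).
#' @param error_rate per-base sequencing error probability (default 0.001).
#' @param frac_guides_with_pool_mutant guides with a virus-pool mutant
#'   variant (default 0.6).
#' @param pool_mutant_freq fraction of integrations of such guides carrying
#'   the pool variant (default 0.45).
#' @param frac_transduction_cells,frac_integration_cells,frac_cdna_cells
#'   cell fractions for the private-mutation scenarios
#'   (defaults 0.004, 0.014, 0.18).
#' @param read_len read length in bp (default 91).
#' @param barcode_len,umi_len tag lengths (default 16, 12).
#' @param dialect tag dialect of emitted reads.
#' @param n_edit_genes target genes given a synthetic editing locus
#'   (default 2; 0 disables the editing arm).
#' @param edit_efficiency fraction of transcript molecules of an edited
#'   cell carrying a cutsite-spanning deletion (default 0.7).
#' @param seed integer RNG seed (default 17).
#' @return a `sim_config` list.
#' @export
sim_config <- function(n_cells = 500L, n_guides = 120L, spacer_len = 20L,
                       fraction_untransformed = 0.05, fraction_doublet = 0.1,
                       mean_umis_per_cell = 53, umi_sdlog = 0.5,
                       ambient_guides_per_cell = 3, ambient_umi_mean = 1.5,
                       mean_reads_per_umi = 10, error_rate = 0.001,
                       frac_guides_with_pool_mutant = 0.6,
                       pool_mutant_freq = 0.45,
                       frac_transduction_cells = 0.004,
                       frac_integration_cells = 0.014,
                       frac_cdna_cells = 0.18,
                       read_len = 91L, barcode_len = 16L, umi_len = 12L,
                       dialect = c("cellranger", "dropseq"),
                       n_edit_genes = 2L, edit_efficiency = 0.7,
                       seed = 17L) {
  dialect <- match.arg(dialect)
  cfg <- as.list(environment())
  fr <- c(fraction_untransformed, fraction_doublet, pool_mutant_freq,
          frac_guides_with_pool_mutant, frac_transduction_cells,
          frac_integration_cells, frac_cdna_cells, error_rate,
          edit_efficiency)
  if (any(fr < 0 | fr > 1)) abort("fractions must lie in [0, 1]")
  if (fraction_untransformed + fraction_doublet > 1) {
    abort("untransformed + doublet fractions exceed 1")
  }
  structure(cfg, class = "sim_config")
}

# one random mutation event within [lo, hi) of the cassette, never clashing
# with positions already used for the same guide
random_event <- function(refseq, lo, hi, used_positions) {
  repeat {
    pos <- sample(seq.int(lo, hi - 1L), 1L)
    if (pos %in% used_positions) next
    kind <- sample(c("substitution", "deletion", "insertion"), 1L,
                   prob = c(0.7, 0.25, 0.05))
    refbase <- substr(refseq, pos + 1L, pos + 1L)
    if (kind == "substitution") {
      alt <- sample(setdiff(c("A", "C", "G", "T"), refbase), 1L)
      ev <- tibble(kind = kind, position = pos, ref = refbase, alt = alt)
    } else if (kind == "deletion") {
      len <- sample(1:3, 1L)
      if (pos + len >= hi) next
      ev <- tibble(kind = kind, position = pos,
                   ref = substr(refseq, pos + 1L, pos + len), alt = "")
    } else {
      ev <- tibble(kind = kind, position = pos, ref = "",
                   alt = paste0(sample(c("A", "C", "G", "T"),
                                       sample(1:2, 1L), replace = TRUE),
                                collapse = ""))
    }
    return(ev)
  }
}

# apply events (cassette coords) to the reference and derive the aligned read:
# sequence of at most read_len query bases starting at reference read_start,
# with its CIGAR. Events must lie inside (read_start, read_start+read_len).
mutant_read <- function(refseq, events, read_start = 0L, read_len = 91L) {
  events <- events[order(events$position), , drop = FALSE]
  seq_parts <- character(0)
  cig_ops <- character(0)
  cig_lens <- integer(0)
  push <- function(op, len) {
    n <- length(cig_ops)
    if (n > 0 && cig_ops[n] == op) {
      cig_lens[n] <<- cig_lens[n] + len
    } else {
      cig_ops <<- c(cig_ops, op)
      cig_lens <<- c(cig_lens, len)
    }
  }
  ri <- read_start
  qlen <- 0L
  ref_end <- nchar(refseq)
  emit_match <- function(upto) {
    # copy reference bases [ri, upto) while query budget remains
    avail <- read_len - qlen
    take <- min(upto - ri, avail)
    if (take > 0L) {
      seq_parts <<- c(seq_parts, substr(refseq, ri + 1L, ri + take))
      push("M", take)
      qlen <<- qlen + take
      ri <<- ri + take
    }
  }
  for (k in seq_len(nrow(events))) {
    if (qlen >= read_len) break
    ev <- events[k, ]
    if (ev$position < ri) next  # upstream of the read
    emit_match(ev$position)
    if (qlen >= read_len) break
    if (ev$kind == "substitution") {
      seq_parts <- c(seq_parts, ev$alt)
      push("M", 1L)
      qlen <- qlen + 1L
      ri <- ri + 1L
    } else if (ev$kind == "deletion") {
      push("D", nchar(ev$ref))
      ri <- ri + nchar(ev$ref)
    } else if (ev$kind == "insertion") {
      take <- min(nchar(ev$alt), read_len - qlen)
      seq_parts <- c(seq_parts, substr(ev$alt, 1L, take))
      push("I", take)
      qlen <- qlen + take
    }
  }
  emit_match(ref_end)
  list(seq = paste0(seq_parts, collapse = ""),
       cigar = paste0(cig_lens, cig_ops, collapse = ""),
       pos = read_start)
}

# inject per-base substitution errors into a read sequence (CIGAR untouched:
# an aligner reports such errors as mismatches inside M runs)
inject_errors <- function(seqs, error_rate) {
  if (error_rate <= 0) return(seqs)
  n_err <- rbinom(length(seqs), nchar(seqs), error_rate)
  hit <- which(n_err > 0)
  for (i in hit) {
    ch <- strsplit(seqs[i], "", fixed = TRUE)[[1]]
    at <- sample(length(ch), n_err[i])
    for (j in at) ch[j] <- sample(setdiff(c("A", "C", "G", "T"), ch[j]), 1L)
    seqs[i] <- paste0(ch, collapse = "")
  }
  seqs
}

#' Simulate a ground-truthed synthetic screen
#'
#' Generates a guide library and custom reference, plants mutant variants
#' according to the scenario mix, draws per-cell molecules and per-molecule
#' reads, injects sequencing errors, and returns pre-aligned tagged reads
#' together with exact truth tables. Use [write_screen_bam()] to serialize
#' the reads as a BAM.
#'
#' @param config a [sim_config()].
#' @return a `sim_screen` list: `config`, `guides`, `reference`, `whitelist`,
#'   `reads` (tibble with the columns [read_guide_alignments()] emits),
#'   `truth` (list of `cells`, `molecules`, `variants`), and `editing`
#'   (`NULL` unless `n_edit_genes > 0`; see [simulate_editing_arm()]).
#' @export
simulate_screen <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  cfg <- config

  # --- guide library: 4 guides per target gene plus non-targeting controls
  n_nt <- max(0L, round(cfg$n_guides / 6))
  n_targeting <- cfg$n_guides - n_nt
  genes <- paste0("GENE", seq_len(ceiling(n_targeting / 4)))
  guide_gene <- rep(genes, each = 4L)[seq_len(n_targeting)]
  guides <- tibble(
    guide_id = c(paste0(guide_gene, "_g", rep(1:4, length.out = n_targeting)),
                 if (n_nt > 0) paste0("NT_g", seq_len(n_nt))),
    spacer = paste0("G", random_barcodes(cfg$n_guides, cfg$spacer_len - 1L)),
    target_gene = c(guide_gene, rep("", n_nt)),
    targeting = c(rep(TRUE, n_targeting), rep(FALSE, n_nt))
  )
  template <- cassette_template(c(upstream = DEFAULT_UPSTREAM, spacer = "",
                                  scaffold = DEFAULT_SCAFFOLD))
  reference <- build_custom_reference(guides, template)

  # planting bounds: events fully covered by reads and away from alignment ends
  ev_lo <- 2L
  ev_hi <- function(guide) min(nchar(reference$contigs[[guide]]),
                               cfg$read_len) - 4L

  # --- virus-pool variants
  pool_guides <- sample(guides$guide_id,
                        round(cfg$frac_guides_with_pool_mutant * cfg$n_guides))
  variant_events <- list()  # key: guide|signature -> events tibble
  pool_variant_of <- setNames(rep(NA_character_, cfg$n_guides), guides$guide_id)
  for (g in pool_guides) {
    ev <- random_event(reference$contigs[[g]], ev_lo, ev_hi(g), integer(0))
    key <- paste0(g, "|", mutation_string(ev))
    variant_events[[key]] <- ev
    pool_variant_of[[g]] <- key
  }

  # --- cells and integrations
  barcodes <- random_barcodes(cfg$n_cells, cfg$barcode_len)
  n_untr <- round(cfg$fraction_untransformed * cfg$n_cells)
  n_doub <- round(cfg$fraction_doublet * cfg$n_cells)
  status <- sample(c(rep("untransformed", n_untr), rep("doublet", n_doub),
                     rep("singlet", cfg$n_cells - n_untr - n_doub)))
  integrations <- purrr::map_dfr(seq_len(cfg$n_cells), function(i) {
    k <- switch(status[i], untransformed = 0L, singlet = 1L, doublet = 2L)
    if (k == 0L) return(NULL)
    tibble(cell_barcode = barcodes[i],
           guide_id = sample(guides$guide_id, k))
  })
  # pool-mutant draws at integration level
  integrations$variant_key <- NA_character_
  for (i in seq_len(nrow(integrations))) {
    g <- integrations$guide_id[i]
    if (!is.na(pool_variant_of[[g]]) &&
        runif(1) < cfg$pool_mutant_freq) {
      integrations$variant_key[i] <- pool_variant_of[[g]]
    }
  }
  integrations$scenario <- ifelse(is.na(integrations$variant_key),
                                  "intact", "virus_pool")

  # --- private-mutation scenarios on intact singlet integrations
  intact_singlets <- integrations %>%
    filter(.data$scenario == "intact") %>%
    count(.data$cell_barcode) %>%
    filter(.data$n == 1L) %>%
    pull(.data$cell_barcode)
  intact_singlets <- intersect(intact_singlets,
                               barcodes[status == "singlet"])
  n_trans <- round(cfg$frac_transduction_cells * cfg$n_cells)
  n_integ <- round(cfg$frac_integration_cells * cfg$n_cells)
  n_cdna <- round(cfg$frac_cdna_cells * cfg$n_cells)
  picks <- sample(intact_singlets,
                  min(length(intact_singlets), n_trans + n_integ + n_cdna))
  trans_cells <- picks[seq_len(min(n_trans, length(picks)))]
  integ_cells <- picks[seq_len(min(n_integ, max(0, length(picks) - n_trans))) +
                         min(n_trans, length(picks))]
  cdna_cells <- setdiff(picks, c(trans_cells, integ_cells))

  private_event <- function(g) {
    used <- unlist(lapply(variant_events[grepl(paste0("^", g, "\\|"),
                                               names(variant_events))],
                          function(e) e$position))
    ev <- random_event(reference$contigs[[g]], ev_lo, ev_hi(g), used)
    key <- paste0(g, "|", mutation_string(ev))
    variant_events[[key]] <<- ev
    key
  }
  for (cb in trans_cells) {
    i <- which(integrations$cell_barcode == cb)
    integrations$variant_key[i] <- private_event(integrations$guide_id[i])
    integrations$scenario[i] <- "transduction_or_subclone"
  }
  dup_rows <- list()
  for (cb in integ_cells) {
    i <- which(integrations$cell_barcode == cb)
    g <- integrations$guide_id[i]
    dup_rows[[length(dup_rows) + 1L]] <- tibble(
      cell_barcode = cb, guide_id = g,
      variant_key = private_event(g),
      scenario = "integration_duplication")
  }
  if (length(dup_rows)) integrations <- bind_rows(integrations, dup_rows)

  # --- molecules per expression unit
  umi_count <- function(n, scen) {
    k <- pmax(1L, as.integer(round(rlnorm(
      n, log(cfg$mean_umis_per_cell) - cfg$umi_sdlog^2 / 2, cfg$umi_sdlog))))
    # duplicated mutant cassettes express less; still >1 UMI by construction
    ifelse(scen == "integration_duplication", pmax(2L, k %/% 2L), k)
  }
  integrations$n_umis <- umi_count(nrow(integrations), integrations$scenario)

  molecules <- integrations %>%
    mutate(.unit = row_number()) %>%
    tidyr::uncount(.data$n_umis, .id = ".mol") %>%
    mutate(ambient = FALSE)

  # cDNA-prep single-UMI mutants: one molecule of the cell's intact guide
  # switches to a private variant (needs >=2 UMIs so intact remains)
  for (cb in cdna_cells) {
    idx <- which(molecules$cell_barcode == cb & !molecules$ambient &
                   molecules$scenario == "intact")
    if (length(idx) >= 2L) {
      j <- idx[1]
      molecules$variant_key[j] <- private_event(molecules$guide_id[j])
      molecules$scenario[j] <- "cdna_prep"
    }
  }

  # --- ambient molecules (intact forms, low counts, any cell)
  n_amb_species <- rpois(cfg$n_cells, cfg$ambient_guides_per_cell)
  amb <- purrr::map_dfr(seq_len(cfg$n_cells), function(i) {
    k <- n_amb_species[i]
    if (k == 0L) return(NULL)
    tibble(cell_barcode = barcodes[i],
           guide_id = sample(guides$guide_id, min(k, cfg$n_guides)))
  })
  if (nrow(amb) > 0) {
    # zero-truncated geometric: low mean with the heavy-ish tail ambient
    # profiles show in real screens (support 1, 2, 3, ...)
    amb$n_umis <- 1L + stats::rgeom(nrow(amb),
                                    prob = 1 / max(cfg$ambient_umi_mean, 1))
    amb <- amb %>%
      mutate(variant_key = NA_character_, scenario = "ambient",
             .unit = NA_integer_) %>%
      tidyr::uncount(.data$n_umis, .id = ".mol") %>%
      mutate(ambient = TRUE)
    molecules <- bind_rows(molecules, amb)
  }

  # UMIs unique within each cell
  molecules <- molecules %>%
    group_by(.data$cell_barcode) %>%
    mutate(umi = random_barcodes(n(), cfg$umi_len)) %>%
    ungroup()

  # --- true molecule sequences and alignments
  align_of <- function(key, guide) {
    ev <- if (is.na(key)) {
      tibble(kind = character(), position = integer(), ref = character(),
             alt = character())
    } else variant_events[[key]]
    mutant_read(reference$contigs[[guide]], ev, 0L, cfg$read_len)
  }
  align_keys <- molecules %>%
    distinct(.data$guide_id, .data$variant_key)
  aligns <- purrr::pmap(align_keys, function(guide_id, variant_key) {
    align_of(variant_key, guide_id)
  })
  align_keys$true_seq <- vapply(aligns, `[[`, character(1), "seq")
  align_keys$cigar <- vapply(aligns, `[[`, character(1), "cigar")
  align_keys$pos <- vapply(aligns, `[[`, integer(1), "pos")
  molecules <- molecules %>%
    left_join(align_keys, by = c("guide_id", "variant_key"))

  # --- reads
  molecules$n_reads <- rpois(nrow(molecules), cfg$mean_reads_per_umi)
  observed <- molecules %>% filter(.data$n_reads > 0)
  reads <- observed %>%
    select("cell_barcode", "umi", "guide_id", "true_seq", "cigar", "pos",
           "n_reads") %>%
    tidyr::uncount(.data$n_reads, .id = ".read") %>%
    mutate(
      seq = inject_errors(.data$true_seq, cfg$error_rate),
      qname = paste0("r", row_number(), ":", .data$cell_barcode, ":",
                     .data$umi),
      flag = 0L,
      contig = .data$guide_id,
      guide_annotation = .data$guide_id
    ) %>%
    select("qname", "flag", "contig", "pos", "cigar", "seq", "cell_barcode",
           "umi", "guide_annotation")
  # shuffle so downstream order assumptions are never accidental
  reads <- reads[sample(nrow(reads)), ]

  # --- truth tables
  variant_catalog <- tibble(
    key = names(variant_events),
    guide_id = sub("\\|.*$", "", names(variant_events)),
    mutation_string = sub("^[^|]*\\|", "", names(variant_events)),
    events = unname(variant_events)
  )
  truth_molecules <- molecules %>%
    mutate(mutation_string = ifelse(is.na(.data$variant_key), "",
                                    sub("^[^|]*\\|", "", .data$variant_key))) %>%
    select("cell_barcode", "umi", "guide_id", "mutation_string", "scenario",
           "ambient", "true_seq", "n_reads")
  truth_cells <- tibble(cell_barcode = barcodes, status = status) %>%
    left_join(
      integrations %>%
        mutate(mutation_string = ifelse(is.na(.data$variant_key), "",
                                        sub("^[^|]*\\|", "",
                                            .data$variant_key))) %>%
        group_by(.data$cell_barcode) %>%
        summarise(
          true_variants = list(sort(paste0(.data$guide_id, "|",
                                           .data$mutation_string))),
          n_units = n(),
          n_intact_units = sum(.data$mutation_string == ""),
          .groups = "drop"
        ),
      by = "cell_barcode"
    ) %>%
    mutate(
      true_variants = purrr::map(.data$true_variants,
                                 function(v) v %||% character(0)),
      n_units = coalesce(.data$n_units, 0L),
      n_intact_units = coalesce(.data$n_intact_units, 0L),
      label = dplyr::case_when(
        .data$n_units == 0L ~ "none",
        .data$n_units > 1L ~ "multiplet",
        .data$n_intact_units == 1L ~ "single_intact",
        TRUE ~ "single_mutant"
      )
    )

  out <- list(
    config = cfg,
    guides = guides,
    reference = reference,
    whitelist = barcodes,
    reads = as_tibble(reads),
    truth = list(cells = truth_cells, molecules = truth_molecules,
                 variants = variant_catalog)
  )
  out$editing <- if (cfg$n_edit_genes > 0) simulate_editing_arm(out) else NULL
  class(out) <- "sim_screen"
  out
}

#' @export
print.sim_screen <- function(x, ...) {
  cat("<sim_screen> ", x$config$n_cells, " cells, ", x$config$n_guides,
      " guides, ", nrow(x$reads), " reads, ",
      nrow(x$truth$molecules), " molecules\n", sep = "")
  invisible(x)
}

#' Simulate the transcriptome editing arm of a screen
#'
#' For a few target genes, builds a synthetic genomic locus (one contig per
#' gene, exon spanning the cutsite window region), then emits expression
#' reads for cells carrying a targeting guide for that gene (edited: a
#' fraction of molecules carry a deletion spanning the cutsite) and an equal
#' number of non-carrier control cells (unedited). Reads of one molecule tile
#' the window from different starts, exercising the union consensus.
#'
#' @param sim a `sim_screen` (called internally by [simulate_screen()]).
#' @return list: `reads`, `windows` (from [compute_cutsites()]), `exons`,
#'   `ref_seqs` (window reference sequences named by guide), `truth`
#'   (per-molecule tibble with `edited`).
#' @keywords internal
#' @export
simulate_editing_arm <- function(sim) {
  cfg <- sim$config
  genes <- unique(sim$guides$target_gene[sim$guides$targeting])
  genes <- utils::head(genes, cfg$n_edit_genes)
  if (length(genes) == 0) return(NULL)
  targets <- purrr::map_dfr(genes, function(g) {
    gid <- sim$guides$guide_id[sim$guides$target_gene == g][1]
    tibble(guide_id = gid, gene = g, chrom = paste0("chr_", g),
           pam_pos = 1000L, strand = "+")
  })
  windows <- compute_cutsites(targets, window_width = 51L)
  contig_len <- 2000L
  contigs <- setNames(random_dna(length(genes), contig_len), targets$chrom)
  exons <- tibble(gene = targets$gene, chrom = targets$chrom,
                  start = 800L, end = 1200L)
  ref_seqs <- setNames(
    substr(contigs[targets$chrom], windows$window_start + 1L,
           windows$window_end),
    windows$guide_id
  )

  cells_for <- function(gid) {
    carriers <- sim$truth$molecules %>%
      filter(!.data$ambient, .data$guide_id == gid) %>%
      pull(.data$cell_barcode) %>% unique()
    ctrl_pool <- setdiff(sim$whitelist, carriers)
    controls <- utils::head(ctrl_pool, length(carriers))
    bind_rows(tibble(cell_barcode = carriers, carrier = TRUE),
              tibble(cell_barcode = controls, carrier = FALSE))
  }
  read_len <- 40L
  mol_rows <- purrr::map_dfr(seq_len(nrow(windows)), function(w) {
    win <- windows[w, ]
    cc <- cells_for(win$guide_id)
    if (nrow(cc) == 0) return(NULL)
    cc %>%
      mutate(n_mols = 1L + rpois(n(), 1)) %>%
      tidyr::uncount(.data$n_mols) %>%
      mutate(
        gene = win$gene, guide_id = win$guide_id, chrom = win$chrom,
        cutsite = win$cutsite,
        edited = .data$carrier & runif(n()) < cfg$edit_efficiency
      )
  })
  if (nrow(mol_rows) == 0) return(NULL)
  mol_rows <- mol_rows %>%
    group_by(.data$cell_barcode) %>%
    mutate(umi = random_barcodes(n(), cfg$umi_len)) %>%
    ungroup()

  make_reads <- function(i) {
    m <- mol_rows[i, ]
    del_len <- if (m$edited) sample(3:8, 1L) else 0L
    del_start <- if (m$edited) m$cutsite - sample(0:(del_len - 1L), 1L) else NA
    ev <- if (m$edited) {
      tibble(kind = "deletion", position = del_start,
             ref = substr(contigs[[m$chrom]], del_start + 1L,
                          del_start + del_len),
             alt = "")
    } else {
      tibble(kind = character(), position = integer(), ref = character(),
             alt = character())
    }
    # two reads tiling the window: one from the left, one from the right
    starts <- c(m$cutsite - 30L, m$cutsite - 10L)
    purrr::map_dfr(starts, function(s) {
      r <- mutant_read(contigs[[m$chrom]], ev, s, read_len)
      tibble(qname = paste0("e", i, ":", s), flag = 0L, contig = m$chrom,
             pos = r$pos, cigar = r$cigar, seq = r$seq,
             cell_barcode = m$cell_barcode, umi = m$umi,
             guide_annotation = m$gene)
    })
  }
  reads <- purrr::map_dfr(seq_len(nrow(mol_rows)), make_reads)
  list(reads = as_tibble(reads), windows = windows, exons = exons,
       contigs = contigs, ref_seqs = ref_seqs,
       truth = mol_rows %>% select("cell_barcode", "umi", "gene", "guide_id",
                                   "carrier", "edited"))
}

#' Serialize simulated screen reads as a coordinate-sorted BAM
#'
#' @param sim a `sim_screen`.
#' @param dir output directory; writes `grna.bam` (+ index), the reference
#'   FASTA/GTF, a `barcodes.txt` whitelist, and (when the editing arm is
#'   present) `expression.bam` with its locus FASTA.
#' @param dialect tag dialect for the emitted tags.
#' @return named vector of paths, invisibly.
#' @export
write_screen_bam <- function(sim, dir, dialect = sim$config$dialect) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tags <- dialect_tags(dialect)
  fmt_tags <- function(reads) {
    paste0(tags[["cb"]], ":Z:", reads$cell_barcode, "\t",
           tags[["umi"]], ":Z:", reads$umi, "\t",
           tags[["gene"]], ":Z:", reads$guide_annotation)
  }
  recs <- sim$reads %>%
    mutate(mapq = 255L, tags = fmt_tags(sim$reads)) %>%
    rename(rname = "contig")
  contigs <- vapply(sim$reference$contigs, nchar, integer(1))
  grna_bam <- file.path(dir, "grna.bam")
  write_bam_records(recs, contigs, grna_bam)
  ref_paths <- write_custom_reference(sim$reference, dir, dialect = dialect)
  wl <- file.path(dir, "barcodes.txt")
  writeLines(sim$whitelist, wl)
  paths <- c(grna_bam = grna_bam, whitelist = wl, ref_paths)
  if (!is.null(sim$editing)) {
    erecs <- sim$editing$reads %>%
      mutate(mapq = 255L, tags = fmt_tags(sim$editing$reads)) %>%
      rename(rname = "contig")
    ebam <- file.path(dir, "expression.bam")
    write_bam_records(erecs, vapply(sim$editing$contigs, nchar, integer(1)),
                      ebam)
    paths <- c(paths, expression_bam = ebam)
  }
  invisible(paths)
}

#' Downsample reads by independent Bernoulli thinning
#'
#' @param reads read tibble (or a BAM path; then a downsampled BAM is written
#'   next to it and its path returned).
#' @param fraction keep probability in (0, 1].
#' @param seed RNG seed; same seed and input give the same subsample.
#' @return subsampled tibble (or BAM path).
#' @export
downsample_reads <- function(reads, fraction, seed = 17) {
  stopifnot(fraction > 0, fraction <= 1)
  if (is.character(reads)) {
    return(downsample_bam(reads, fraction, seed))
  }
  if (fraction == 1) return(reads)
  keep <- withr_seeded(seed, runif(nrow(reads)) < fraction)
  reads[keep, ]
}

downsample_bam <- function(bam, fraction, seed = 17) {
  tags <- dialect_tags("cellranger")
  reads <- scan_tagged_bam(bam, tags, "cellranger")
  kept <- downsample_reads(reads, fraction, seed)
  hdr <- Rsamtools::scanBamHeader(bam)[[1]]$targets
  out <- sub("\\.bam$", paste0(".ds", fraction, ".bam"), bam)
  kept <- kept %>%
    mutate(mapq = 255L,
           tags = paste0("CB:Z:", .data$cell_barcode, "\tUB:Z:", .data$umi,
                         ifelse(is.na(.data$guide_annotation), "",
                                paste0("\tGN:Z:", .data$guide_annotation)))) %>%
    rename(rname = "contig")
  write_bam_records(kept, hdr, out)
  out
}

#' Sequencing saturation
#'
#' `1 - unique molecules / reads`: the fraction of tag-valid reads that are
#' duplicates of an already-observed molecule. 0 when there are no reads.
#'
#' @param n_reads number of reads with valid cell barcode + UMI.
#' @param n_unique_molecules number of distinct (cell barcode, UMI) molecules.
#' @return saturation fraction in [0, 1].
#' @export
sequencing_saturation <- function(n_reads, n_unique_molecules) {
  stopifnot(n_reads >= n_unique_molecules, n_unique_molecules >= 0)
  if (n_reads == 0) return(0)
  1 - n_unique_molecules / n_reads
}

#' Concordance between a truth table and an assignment
#'
#' A cell is concordant iff its assigned variant set matches the truth
#' exactly (variants compared as guide + mutation signature). Errors are
#' broken down into cells missing a true guide, cells with an extra
#' (ambient) guide, and cells with both.
#'
#' @param truth_cells `truth$cells` tibble of a `sim_screen`.
#' @param assignment a `guide_assignment`.
#' @param variants variant catalog from [collate_variants()] (to translate
#'   assigned variant names into guide + signature keys).
#' @return list: `concordance` (fraction of cells with the exact truth set),
#'   `per_cell` tibble (`cell_barcode`, `outcome`), `breakdown` (named
#'   counts: `correct`, `missed_guide`, `extra_guide`, `mixed`).
#' @export
assignment_concordance <- function(truth_cells, assignment, variants) {
  key_of <- setNames(paste0(variants$guide_id, "|", variants$mutation_string),
                     variants$variant_name)
  res <- assignment$cells %>%
    mutate(assigned_keys = purrr::map(.data$variants, function(v) {
      sort(unname(key_of[v]))
    })) %>%
    select("cell_barcode", "assigned_keys")
  joined <- truth_cells %>%
    select("cell_barcode", "true_variants") %>%
    left_join(res, by = "cell_barcode") %>%
    mutate(assigned_keys = purrr::map(.data$assigned_keys,
                                      function(v) v %||% character(0)))
  outcome <- purrr::map2_chr(joined$true_variants, joined$assigned_keys,
                             function(tr, as) {
    miss <- length(setdiff(tr, as)) > 0
    extra <- length(setdiff(as, tr)) > 0
    if (!miss && !extra) "correct"
    else if (miss && !extra) "missed_guide"
    else if (!miss && extra) "extra_guide"
    else "mixed"
  })
  per_cell <- tibble(cell_barcode = joined$cell_barcode, outcome = outcome)
  breakdown <- table(factor(outcome, levels = c("correct", "missed_guide",
                                                "extra_guide", "mixed")))
  list(concordance = mean(outcome == "correct"),
       per_cell = per_cell,
       breakdown = setNames(as.integer(breakdown), names(breakdown)))
}
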