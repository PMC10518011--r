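# guidecall

Mutation-aware guide RNA detection, annotation and cell assignment for
single-cell CRISPR screens.

## The problem

Pooled single-cell CRISPR screens (CROP-seq, Perturb-seq and relatives) link
each cell's transcriptome to the guide RNA (gRNA) it expresses. Standard
feature-barcoding pipelines match observed spacer sequences against the
designed library, tolerating one mismatch, and call everything else
background. In practice a large fraction of guide molecules carry real
mutations — introduced during oligo synthesis, cloning, virus production,
lentiviral integration, or cDNA preparation — and those molecules are then
either silently mis-assigned or lost, inflating the apparent number of
untransformed cells, hiding multiplets, and diluting perturbation phenotypes.

`guidecall` recovers and annotates these molecules. For every
(cell barcode, UMI) pair in a targeted gRNA sequencing library it:

1. **calls a consensus sequence** — the guide annotation is settled by a
   majority vote over the group's reads, then the plurality full-read
   sequence wins; with a minimum read support of 2 (default), single-read
   sequencing errors cannot create phantom mutations;
2. **itemizes mutations** by walking the alignment CIGAR against the designed
   cassette (one artificial reference contig per guide): substitutions inside
   M runs, insertions (I), deletions (D), skips (N) and soft-clips (S), each
   mapped onto the cassette's region annotation (upstream/promoter, spacer,
   scaffold). A molecule is *intact* only on a perfect match — strictly
   stricter than the 1-Hamming tolerance of feature barcoding;
3. **names variants** (`guide.1`, `guide.2`, ... by descending UMI support)
   and classifies each variant's likely source from its cell-level
   co-occurrence with the intact form (virus pool, transduction/sub-clone,
   integration duplication, cDNA preparation);
4. **assigns guides to cells** from the cells × variants UMI count matrix,
   with either a fixed UMI cutoff or a per-guide dynamic threshold from a
   two-component Gaussian mixture on log10 counts (intact + mutant counts
   pooled per guide; the threshold is the minimum count of the in-cell
   component), labelling cells `none` / `single_intact` / `single_mutant` /
   `multiplet`;
5. separately, **detects Cas9 editing** in the matched expression library:
   molecules over a 51-bp window centered 3 nt upstream of the PAM are
   collapsed by a per-position union consensus, and a deletion spanning the
   cutsite is called a Cas9-induced editing effect (other indels and
   mismatches are reported but never labelled Cas9-induced).

A first-class synthetic-screen generator (`simulate_screen()`) emits
pre-aligned, fully ground-truthed BAMs covering the five mutation scenarios,
plus downsampling and concordance utilities for depth–accuracy analyses.

## Worked example

```r
library(guidecall)

sim <- simulate_screen(sim_config(n_cells = 60, n_guides = 12,
                                  mean_umis_per_cell = 20,
                                  mean_reads_per_umi = 5, seed = 3))
run <- run_pipeline(sim$reads, sim$whitelist, sim$reference, seed = 3)
run
#> <guidecall_run> 60 cells, 1385 consensus molecules, 12 intact + 29 mutant variants
#>   cells: none 3 | single_intact 36 | single_mutant 12 | multiplet 9
#>   % cells with a mutant guide: 28.3 | saturation: 0.802
```

Reading the output: of 60 simulated cells, 3 show no confidently assigned
guide, 36 express a single intact guide, 12 a single mutant guide (cells a
mismatch-tolerant pipeline would mislabel or drop), and 9 carry two or more
guides (multiplets). 28.3% of cells carry a mutant guide and the library's
sequencing saturation (1 − molecules/reads) is 0.802. Per-stage tables are in
`run$consensus`, `run$variants`, `run$sources`, `run$counts`, and
`tidy(run$assignment)` / `glance(run$assignment)`; `autoplot(run$assignment)`
shows per-guide UMI histograms with their thresholds, and
`plot_mutation_spectrum(run$spectrum)` the mutation positions along the
cassette.

The same pipeline runs from files (BAM + whitelist + reference FASTA/GTF):

```r
paths <- write_screen_bam(sim, "fixtures/")
run <- run_pipeline(paths[["grna_bam"]], paths[["whitelist"]],
                    c(fasta = paths[["fasta"]], gtf = paths[["gtf"]]),
                    out_dir = "out/")
```

which writes `consensus.sequence.gRNA.txt`, `consensus.bam`,
`gRNA.mutation.txt`, the MatrixMarket count matrix with
`barcodes.tsv`/`features.tsv`, `assignments.txt` and a summary `report.txt`.
A thin command-line wrapper with `build-ref`, `run-all`, `simulate` and
`edits` subcommands lives at `inst/cli/guidecall.R`.

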