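# Assignment of guides to cells.
#
# Ambient guide molecules captured in droplets produce low background UMI
# counts for many (cell, guide) pairs; truly expressed guides produce high
# counts. Assignment therefore thresholds the UMI count, either with a fixed
# cutoff or with a per-guide dynamic cutoff from a two-component Gaussian
# mixture on log10 counts (in-cell vs ambient component). Intact and mutant
# forms of the same guide are pooled when fitting — they share the ambient /
# in-cell structure — and the resulting threshold applies to each variant
# column separately.

#' Build the cells x guide-variants UMI count matrix
#'
#' One column per variant (intact and mutant forms are separate columns);
#' counts are the number of distinct UMIs per (cell, variant).
#'
#' @param annotated tibble from [annotate_mutations()] carrying
#'   `variant_name` (see [name_molecule_variants()]).
#' @return a long tibble `cell_barcode`, `variant_name`, `guide_id`, `count`
#'   with only nonzero entries; `sum(count)` equals the number of molecules.
#' @export
build_count_matrix <- function(annotated) {
  if (nrow(annotated) == 0) {
    return(tibble(cell_barcode = character(), variant_name = character(),
                  guide_id = character(), count = integer()))
  }
  stopifnot("variant_name" %in% names(annotated))
  annotated %>%
    distinct(.data$cell_barcode, .data$umi, .data$variant_name, .data$guide_id) %>%
    count(.data$cell_barcode, .data$variant_name, .data$guide_id,
          name = "count") %>%
    arrange(.data$variant_name, .data$cell_barcode)
}

#' Convert the long count table to a sparse matrix
#' @param counts tibble from [build_count_matrix()].
#' @return a `dgCMatrix` with cells as rows and variant names as columns.
#' @export
as_count_matrix <- function(counts) {
  cells <- sort(unique(counts$cell_barcode))
  vars <- sort(unique(counts$variant_name))
  Matrix::sparseMatrix(
    i = match(counts$cell_barcode, cells),
    j = match(counts$variant_name, vars),
    x = counts$count,
    dims = c(length(cells), length(vars)),
    dimnames = list(cells, vars)
  )
}

#' Write the count matrix in MatrixMarket triplet form
#'
#' Emits `matrix.mtx` with `barcodes.tsv` / `features.tsv` sidecars, the
#' standard sparse layout of single-cell count matrices.
#'
#' @param counts tibble from [build_count_matrix()].
#' @param dir output directory.
#' @return named vector of paths, invisibly.
#' @export
write_count_matrix <- function(counts, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  m <- as_count_matrix(counts)
  mtx <- file.path(dir, "matrix.mtx")
  Matrix::writeMM(methods::as(Matrix::t(m), "CsparseMatrix"), mtx)
  writeLines(rownames(m), file.path(dir, "barcodes.tsv"))
  writeLines(colnames(m), file.path(dir, "features.tsv"))
  invisible(c(matrix = mtx,
              barcodes = file.path(dir, "barcodes.tsv"),
              features = file.path(dir, "features.tsv")))
}

#' Dynamic UMI threshold for one guide from a two-component Gaussian mixture
#'
#' Fits a two-component Gaussian mixture to log10 of the nonzero per-cell UMI
#' counts pooled over the guide's intact and mutant forms. The component with
#' the higher mean is the in-cell distribution; the threshold is the minimum
#' raw UMI count among observations assigned to it (posterior >= 0.5). With
#' fewer than `min_cells` nonzero observations, or on a degenerate fit, the
#' fixed `fallback` threshold is used instead.
#'
#' @param counts integer vector of per-cell pooled UMI counts for one guide
#'   (zeros allowed; they are excluded from the fit).
#' @param seed integer seed (the fit itself is deterministic; the seed guards
#'   any internal randomness).
#' @param min_cells minimum number of nonzero observations for a fit
#'   (default 10).
#' @param fallback fixed threshold used when no fit is possible (default 3).
#' @param scale `"log10"` (default) fits on log10 counts, `"linear"` on raw
#'   counts.
#' @return a list: `threshold` (integer; GMM mode assigns at count >=
#'   threshold), `method` (`"gmm"` or `"fallback"`), and for GMM fits the
#'   component `means` (on the fitting scale).
#' @export
gmm_threshold <- function(counts, seed = 17, min_cells = 10L, fallback = 3L,
                          scale = c("log10", "linear")) {
  scale <- match.arg(scale)
  x_raw <- counts[counts > 0]
  fallback_result <- list(threshold = as.integer(fallback),
                          method = "fallback", means = NULL)
  if (length(x_raw) < min_cells) return(fallback_result)
  x <- if (scale == "log10") log10(x_raw) else as.numeric(x_raw)
  if (length(unique(x)) < 2L) return(fallback_result)
  fit <- tryCatch({
    withr_seeded(seed, {
      # Mclust() resolves helper calls in the caller's frame, so evaluate in
      # an environment parented to the mclust namespace (works unattached)
      ev <- list2env(list(.gc_x = x), parent = asNamespace("mclust"))
      suppressWarnings(eval(
        quote(Mclust(.gc_x, G = 2, modelNames = c("E", "V"), verbose = FALSE)),
        envir = ev
      ))
    })
  }, error = function(e) NULL)
  if (is.null(fit) || is.null(fit$parameters)) return(fallback_result)
  means <- fit$parameters$mean
  if (length(means) < 2L || !all(is.finite(means)) ||
      abs(diff(range(means))) < 1e-8) {
    return(fallback_result)
  }
  in_cell <- which.max(means)
  post <- fit$z[, in_cell]
  members <- x_raw[post >= 0.5]
  if (length(members) == 0) return(fallback_result)
  list(threshold = as.integer(min(members)), method = "gmm",
       means = unname(means))
}

# evaluate expr under a local seed, restoring the caller's RNG state
withr_seeded <- function(seed, expr) {
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
  force(expr)
}

#' Assign guides to cells by thresholded UMI counts
#'
#' In fixed mode a variant is assigned to a cell iff its UMI count is
#' strictly greater than the threshold. In GMM mode each guide gets a dynamic
#' per-guide threshold (see [gmm_threshold()], fitted on intact + mutant
#' counts pooled) and a variant is assigned iff its count is at least that
#' threshold (the threshold is itself the minimum in-cell count). Cells are
#' labelled `none`, `single_intact`, `single_mutant`, or `multiplet`.
#'
#' @param counts tibble from [build_count_matrix()].
#' @param mode `"gmm"` or `"fixed"`.
#' @param threshold fixed-mode UMI threshold (default 3; "more UMIs than the
#'   threshold" are required) and GMM fallback.
#' @param seed integer seed forwarded to the mixture fits.
#' @param min_cells minimum nonzero cells for a GMM fit (default 10).
#' @param scale fitting scale for the mixture, `"log10"` or `"linear"`.
#' @return a `guide_assignment` object: list with `cells` (tibble
#'   `cell_barcode`, `label`, `variants` (list-col), `n_assigned`,
#'   `total_umis`), `thresholds` (tibble `guide_id`, `threshold`, `method`),
#'   `assignments` (long tibble of assigned (cell, variant) pairs), `mode`.
#' @export
assign_guides <- function(counts, mode = c("gmm", "fixed"), threshold = 3L,
                          seed = 17, min_cells = 10L,
                          scale = c("log10", "linear")) {
  mode <- match.arg(mode)
  scale <- match.arg(scale)
  all_cells <- sort(unique(counts$cell_barcode))
  intact_names <- counts %>%
    distinct(.data$variant_name, .data$guide_id) %>%
    mutate(is_intact = .data$variant_name == .data$guide_id)

  if (mode == "fixed") {
    thresholds <- counts %>% distinct(.data$guide_id) %>%
      mutate(threshold = as.integer(threshold), method = "fixed")
    assigned <- counts %>% filter(.data$count > as.integer(threshold))
  } else {
    pooled <- counts %>%
      group_by(.data$cell_barcode, .data$guide_id) %>%
      summarise(count = sum(.data$count), .groups = "drop")
    thresholds <- pooled %>%
      group_by(.data$guide_id) %>%
      summarise(fit = list(gmm_threshold(.data$count, seed = seed,
                                         min_cells = min_cells,
                                         fallback = threshold,
                                         scale = scale)),
                .groups = "drop") %>%
      mutate(threshold = vapply(.data$fit, `[[`, integer(1), "threshold"),
             method = vapply(.data$fit, `[[`, character(1), "method")) %>%
      select("guide_id", "threshold", "method")
    assigned <- counts %>%
      left_join(thresholds, by = "guide_id") %>%
      filter(ifelse(.data$method == "gmm",
                    .data$count >= .data$threshold,
                    .data$count > .data$threshold)) %>%
      select(-"threshold", -"method")
  }
  assigned <- assigned %>%
    left_join(intact_names %>% select("variant_name", "is_intact"),
              by = "variant_name")

  per_cell <- assigned %>%
    group_by(.data$cell_barcode) %>%
    summarise(variants = list(sort(.data$variant_name)),
              n_assigned = n(),
              n_intact = sum(.data$is_intact),
              total_umis = sum(.data$count),
              .groups = "drop")
  cells <- tibble(cell_barcode = all_cells) %>%
    left_join(per_cell, by = "cell_barcode") %>%
    mutate(
      n_assigned = coalesce(.data$n_assigned, 0L),
      n_intact = coalesce(.data$n_intact, 0L),
      total_umis = coalesce(.data$total_umis, 0L),
      variants = purrr::map(.data$variants, function(v) v %||% character(0)),
      label = dplyr::case_when(
        .data$n_assigned == 0L ~ "none",
        .data$n_assigned > 1L ~ "multiplet",
        .data$n_intact == 1L ~ "single_intact",
        TRUE ~ "single_mutant"
      )
    ) %>%
    select("cell_barcode", "label", "variants", "n_assigned", "total_umis")

  structure(
    list(cells = cells, thresholds = thresholds,
         assignments = assigned %>% select("cell_barcode", "variant_name",
                                           "guide_id", "count", "is_intact"),
         mode = mode,
         comparison = c(fixed = "count > threshold (strict)",
                        gmm = "count >= in-cell minimum")[[mode]]),
    class = "guide_assignment"
  )
}

#' @export
print.guide_assignment <- function(x, ...) {
  tab <- table(factor(x$cells$label,
                      levels = c("none", "single_intact", "single_mutant",
                                 "multiplet")))
  cat("<guide_assignment> ", nrow(x$cells), " cells (mode: ", x$mode, ")\n",
      sep = "")
  cat(paste0("  ", names(tab), ": ", as.integer(tab), collapse = "\n"), "\n")
  invisible(x)
}

#' Tidy a guide assignment: one row per cell
#'
#' @param x a `guide_assignment`.
#' @param ... unused.
#' @return tibble `cell_barcode`, `label`, `variants` (collapsed `;` string),
#'   `n_assigned`, `total_umis`.
#' @export
tidy.guide_assignment <- function(x, ...) {
  x$cells %>%
    mutate(variants = vapply(.data$variants, paste, character(1),
                             collapse = ";"))
}

#' One-row summary of a guide assignment
#'
#' @param x a `guide_assignment`.
#' @param ... unused.
#' @return tibble with cell totals per label, the fraction of cells carrying
#'   a mutant variant, and the number of guides thresholded by GMM vs
#'   fallback.
#' @export
glance.guide_assignment <- function(x, ...) {
  labs <- table(factor(x$cells$label,
                       levels = c("none", "single_intact", "single_mutant",
                                  "multiplet")))
  mutant_cells <- unique(x$assignments$cell_barcode[!x$assignments$is_intact])
  has_mutant <- x$cells$cell_barcode %in% mutant_cells
  tibble(
    n_cells = nrow(x$cells),
    n_none = as.integer(labs[["none"]]),
    n_single_intact = as.integer(labs[["single_intact"]]),
    n_single_mutant = as.integer(labs[["single_mutant"]]),
    n_multiplet = as.integer(labs[["multiplet"]]),
    pct_cells_with_mutant = 100 * mean(has_mutant),
    n_thresholds_gmm = sum(x$thresholds$method == "gmm"),
    n_thresholds_fallback = sum(x$thresholds$method != "gmm")
  )
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Write per-cell assignments as TSV
#' @param x a `guide_assignment`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_assignments <- function(x, path) {
  readr::write_tsv(tidy(x), path)
  invisible(path)
}
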