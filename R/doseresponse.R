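#' The cAMP dose grid
#'
#' The dose series used for the CRP dose-response experiments:
#' 0, 0.01, 0.03, 0.1, 0.3, 1, 3 and 10 mM cAMP, with 0 mM serving as the
#' reference condition.
#'
#' @return Numeric vector of doses in mM, ascending.
#' @export
camp_dose_grid <- function() c(0, 0.01, 0.03, 0.1, 0.3, 1, 3, 10)

#' Read a log2 expression matrix over a dose series
#'
#' Reads a CSV or TSV file whose first column holds gene identifiers and
#' whose remaining column headers encode dose and replicate as
#' `<dose>mM_r<rep>` (e.g. `0.3mM_r1`).  Values are normalised log2
#' expression.  Validation rejects unparseable headers, doses outside the
#' declared grid, files without a zero-dose column, duplicate gene rows
#' and missing values (they are never imputed).
#'
#' @param path Path to the matrix file; delimiter inferred from the
#'   extension (`.csv` vs anything else = tab).
#' @param dose_grid Declared dose grid in mM; defaults to
#'   [camp_dose_grid()].
#' @return A tibble in long form with columns `gene`, `dose`, `replicate`,
#'   `log2_expr`, carrying the dose grid in attribute `dose_grid`.
#' @export
read_expression_matrix <- function(path, dose_grid = camp_dose_grid()) {
  if (!file.exists(path)) {
    abort(paste0("expression file not found: ", path), class = "crpffl_input_error")
  }
  delim <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  raw <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                           progress = FALSE)
  if (ncol(raw) < 2L) {
    abort("expression matrix needs a gene column plus sample columns",
          class = "crpffl_validation_error")
  }
  names(raw)[1] <- "gene"
  validate_expression(tidyr::pivot_longer(raw, -"gene", names_to = "sample",
                                          values_to = "log2_expr"),
                      dose_grid)
}

# parse sample tokens, enforce matrix invariants, return long tibble
validate_expression <- function(long, dose_grid) {
  m <- stringr::str_match(long$sample, "^([0-9]*\\.?[0-9]+)\\s*mM_r([0-9]+)$")
  bad <- which(is.na(m[, 1]))
  if (length(bad) > 0L) {
    abort(paste0("unparseable sample header: '", long$sample[bad[1]],
                 "' (expected <dose>mM_r<rep>)"), class = "crpffl_validation_error")
  }
  long$dose <- as.numeric(m[, 2])
  long$replicate <- as.integer(m[, 3])
  off <- setdiff(unique(long$dose), dose_grid)
  if (length(off) > 0L) {
    abort(paste0("dose not on the declared grid: ", paste(off, collapse = ", "), " mM"),
          class = "crpffl_validation_error")
  }
  if (!any(long$dose == 0)) {
    abort("no zero-dose (control) column present", class = "crpffl_validation_error")
  }
  dup <- long |>
    dplyr::count(.data$gene, .data$sample) |>
    dplyr::filter(.data$n > 1L)
  if (nrow(dup) > 0L) {
    abort(paste0("duplicate gene row: ", dup$gene[1]), class = "crpffl_validation_error")
  }
  miss <- which(!is.finite(long$log2_expr))
  if (length(miss) > 0L) {
    abort(paste0("missing or non-finite expression value for gene '",
                 long$gene[miss[1]], "', sample '", long$sample[miss[1]], "'"),
          class = "crpffl_validation_error")
  }
  out <- long |>
    dplyr::select("gene", "dose", "replicate", "log2_expr")
  attr(out, "dose_grid") <- sort(dose_grid)
  out
}

#' Dose-response log2 fold-change profiles
#'
#' For every gene and every positive dose, averages replicate log2
#' expression at that dose and subtracts the average zero-dose (control)
#' expression, yielding the log2 fold-change versus the no-cAMP control.
#' Averaging happens on the log2 scale before the ratio is taken.
#'
#' @param expr Long expression tibble from [read_expression_matrix()] (or
#'   any tibble with `gene`, `dose`, `replicate`, `log2_expr`).
#' @return A tibble with columns `gene`, `dose` (positive doses,
#'   ascending within gene) and `log2fc`; gene order follows first
#'   appearance in `expr`.
#' @export
compute_profiles <- function(expr) {
  expr <- tibble::as_tibble(expr)
  req <- c("gene", "dose", "log2_expr")
  if (!all(req %in% names(expr))) {
    abort("expression data must have columns gene, dose, log2_expr",
          class = "crpffl_input_error")
  }
  if (!any(expr$dose == 0)) {
    abort("no zero-dose (control) samples present", class = "crpffl_validation_error")
  }
  gene_order <- unique(expr$gene)
  means <- expr |>
    dplyr::group_by(.data$gene, .data$dose) |>
    dplyr::summarise(m = mean(.data$log2_expr), .groups = "drop")
  ctrl <- means |>
    dplyr::filter(.data$dose == 0) |>
    dplyr::select("gene", ctrl = "m")
  means |>
    dplyr::filter(.data$dose > 0) |>
    dplyr::inner_join(ctrl, by = "gene") |>
    dplyr::transmute(gene = .data$gene, dose = .data$dose,
                     log2fc = .data$m - .data$ctrl) |>
    dplyr::mutate(gene = factor(.data$gene, levels = gene_order)) |>
    dplyr::arrange(.data$gene, .data$dose) |>
    dplyr::mutate(gene = as.character(.data$gene))
}

#' Filter unresponsive genes by maximum absolute fold change
#'
#' A gene is responsive when its absolute log2 fold change versus the
#' zero-cAMP control reaches `threshold` at any dose (`mode = "any"`,
#' the default: a gene is dropped only when every dose stays below the
#' threshold).  `mode = "all"` is the stricter reading requiring every
#' dose to reach the threshold.  The boundary is inclusive: an absolute
#' fold change of exactly `threshold` is kept.
#'
#' @param profiles Profile tibble from [compute_profiles()].
#' @param threshold Positive log2 fold-change threshold, default 0.5.
#' @param mode `"any"` (default) or `"all"`.
#' @return A tibble with one row per gene in input order: `gene`,
#'   `max_abs_log2fc`, `kept` (logical).
#' @export
filter_responsive <- function(profiles, threshold = 0.5, mode = c("any", "all")) {
  mode <- match.arg(mode)
  stopifnot(threshold > 0)
  profiles <- tibble::as_tibble(profiles)
  gene_order <- unique(profiles$gene)
  rep_tbl <- profiles |>
    dplyr::group_by(.data$gene) |>
    dplyr::summarise(
      max_abs_log2fc = max(abs(.data$log2fc)),
      min_abs_log2fc = min(abs(.data$log2fc)),
      .groups = "drop"
    ) |>
    dplyr::mutate(kept = if (mode == "any") .data$max_abs_log2fc >= threshold
                  else .data$min_abs_log2fc >= threshold) |>
    dplyr::select("gene", "max_abs_log2fc", "kept")
  rep_tbl[match(gene_order, rep_tbl$gene), ]
}

#' Spread profiles into a gene-by-dose matrix
#'
#' @param profiles Profile tibble from [compute_profiles()].
#' @return A numeric matrix, rows named by gene, columns by dose (mM),
#'   ascending.
#' @export
profiles_matrix <- function(profiles) {
  wide <- profiles |>
    tidyr::pivot_wider(id_cols = "gene", names_from = "dose",
                       values_from = "log2fc", names_sort = TRUE)
  m <- as.matrix(wide[, -1, drop = FALSE])
  rownames(m) <- wide$gene
  m
}
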