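#' Read gene-to-term annotations and term parents
#'
#' `read_annotations()` reads a GAF-like tab-separated file with columns
#' `gene`, `term` and optionally `namespace`; lines starting with `!` or
#' `#` are skipped.  `read_term_parents()` reads a two-column
#' child-parent table for the ontology's `is_a` relation.
#'
#' @param path Path to a tab-separated file.
#' @return A tibble: `gene`, `term`(, `namespace`) for annotations;
#'   `term`, `parent` for parents.
#' @export
read_annotations <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("annotation file not found: ", path), class = "crpffl_input_error")
  }
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*[!#]", lines) & nzchar(trimws(lines))]
  if (length(lines) == 0L) {
    return(tibble::tibble(gene = character(), term = character()))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  out <- tibble::tibble(
    gene = trimws(vapply(fields, `[`, "", 1L)),
    term = trimws(vapply(fields, `[`, "", 2L))
  )
  if (any(lengths(fields) >= 3L)) {
    out$namespace <- trimws(vapply(fields, function(f) {
      if (length(f) >= 3L) f[3] else ""
    }, ""))
  }
  out
}

#' @rdname read_annotations
#' @export
read_term_parents <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("term-parent file not found: ", path), class = "crpffl_input_error")
  }
  tbl <- readr::read_tsv(path, col_names = c("term", "parent"),
                         comment = "#", show_col_types = FALSE, progress = FALSE)
  tibble::as_tibble(tbl)
}

#' Propagate annotations up the term hierarchy
#'
#' True-path propagation: each gene annotated to a term is also counted
#' as annotated to every ancestor of that term under the (acyclic)
#' parent relation.  Idempotent; with a `NULL` parent table it is the
#' identity.
#'
#' @param annotations Tibble with `gene` and `term` columns.
#' @param parents Tibble with `term` and `parent` columns, or `NULL`.
#' @return The annotation tibble closed under the ancestor relation
#'   (distinct gene-term pairs; extra columns such as `namespace` are
#'   filled from the originating leaf annotation).
#' @export
propagate_annotations <- function(annotations, parents = NULL) {
  annotations <- tibble::as_tibble(annotations)
  if (is.null(parents) || nrow(parents) == 0L) {
    return(dplyr::distinct(annotations, .data$gene, .data$term, .keep_all = TRUE))
  }
  anc <- term_ancestors(parents)
  extra <- annotations |>
    dplyr::inner_join(anc, by = "term", relationship = "many-to-many") |>
    dplyr::mutate(term = .data$ancestor) |>
    dplyr::select(-"ancestor")
  dplyr::bind_rows(annotations, extra) |>
    dplyr::distinct(.data$gene, .data$term, .keep_all = TRUE) |>
    dplyr::arrange(.data$gene, .data$term)
}

# transitive closure of the child->parent relation; errors on cycles
term_ancestors <- function(parents) {
  up <- split(parents$parent, parents$term)
  memo <- new.env(parent = emptyenv())
  visit <- function(term, path) {
    if (term %in% path) {
      abort(paste0("cycle in term hierarchy involving '", term, "'"),
            class = "crpffl_input_error")
    }
    if (!is.null(memo[[term]])) return(memo[[term]])
    ps <- up[[term]]
    if (is.null(ps)) {
      memo[[term]] <- character()
      return(character())
    }
    res <- unique(c(ps, unlist(lapply(ps, visit, path = c(path, term)))))
    memo[[term]] <- res
    res
  }
  terms <- unique(parents$term)
  anc_list <- lapply(terms, visit, path = character())
  tibble::tibble(term = rep(terms, lengths(anc_list)),
                 ancestor = unlist(anc_list))
}

#' Upper-tail hypergeometric probability
#'
#' Probability of observing at least `k` annotated genes in a sample of
#' `n` genes drawn without replacement from a universe of `N` genes of
#' which `K` carry the annotation - the classic over-representation
#' p-value.  Vectorised; numerically stable for large universes.
#'
#' @param k Observed annotated genes in the study set.
#' @param n Study-set size.
#' @param K Annotated genes in the universe.
#' @param N Universe size.
#' @return `P(X >= k)` for `X ~ Hypergeometric(N, K, n)`.
#' @export
#' @examples
#' hypergeometric_p(5, 5, 5, 20)   # 1 / choose(20, 5)
#' hypergeometric_p(0, 10, 5, 50)  # 1: at least zero hits is certain
hypergeometric_p <- function(k, n, K, N) {
  args <- vctrs_recycle(k, n, K, N)
  k <- args[[1]]; n <- args[[2]]; K <- args[[3]]; N <- args[[4]]
  ok <- k >= 0 & n >= 0 & K >= 0 & N >= 1 & k <= pmin(n, K) & n <= N & K <= N
  if (!all(ok)) {
    abort("invalid hypergeometric margins: need 0 <= k <= min(n, K), n <= N, K <= N",
          class = "crpffl_domain_error")
  }
  phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Term over-representation for a gene group
#'
#' Tests every term annotating at least one group member for
#' over-representation against the universe with the upper-tail
#' hypergeometric probability.  Genes absent from the annotation table
#' still count toward the study-set and universe sizes - they simply hit
#' no term.  When the annotation table carries a `namespace` column, only
#' the requested namespace (biological process by default) is consulted.
#' No multiple-testing correction is applied by default, matching a raw
#' p <= 0.01 significance rule; Bonferroni or Benjamini-Hochberg
#' adjustment can be switched on.
#'
#' @param genes Character vector, the study set (must lie in `universe`).
#' @param universe Character vector, the background gene set.
#' @param annotations Tibble with `gene`, `term` and optionally
#'   `namespace`, ideally pre-closed with [propagate_annotations()].
#' @param max_p Significance ceiling on the (adjusted) p-value, default 0.01.
#' @param namespace Namespace to keep when a `namespace` column exists;
#'   default `"biological_process"`.  `NULL` keeps everything.
#' @param adjust One of `"none"` (default), `"bonferroni"`, `"BH"`.
#' @param term_names Optional tibble `term`, `name` to carry labels.
#' @return A tibble sorted by ascending p then term id: `term`, `k`, `n`,
#'   `K`, `N`, `p_value`, `significant`, `genes` (list-column of hit
#'   genes), plus `name` if `term_names` was given.
#' @export
enrich_group <- function(genes, universe, annotations, max_p = 0.01,
                         namespace = "biological_process",
                         adjust = c("none", "bonferroni", "BH"),
                         term_names = NULL) {
  adjust <- match.arg(adjust)
  genes <- unique(genes)
  universe <- unique(universe)
  stray <- setdiff(genes, universe)
  if (length(stray) > 0L) {
    abort(paste0("study genes not in universe: ", paste(stray, collapse = ", ")),
          class = "crpffl_input_error")
  }
  ann <- tibble::as_tibble(annotations)
  if (!is.null(namespace) && "namespace" %in% names(ann)) {
    ann <- ann |> dplyr::filter(.data$namespace == !!namespace)
  }
  ann <- ann |>
    dplyr::filter(.data$gene %in% universe) |>
    dplyr::distinct(.data$gene, .data$term)
  if (length(genes) == 0L || nrow(ann) == 0L) {
    return(tibble::tibble(term = character(), k = integer(), n = integer(),
                          K = integer(), N = integer(), p_value = double(),
                          significant = logical(), genes = list()))
  }
  n <- length(genes)
  N <- length(universe)
  pop <- ann |> dplyr::count(.data$term, name = "K")
  study <- ann |>
    dplyr::filter(.data$gene %in% genes) |>
    dplyr::group_by(.data$term) |>
    dplyr::summarise(k = dplyr::n(), genes = list(sort(.data$gene)),
                     .groups = "drop")
  res <- study |>
    dplyr::inner_join(pop, by = "term") |>
    dplyr::mutate(n = n, N = N,
                  p_value = hypergeometric_p(.data$k, n, .data$K, N))
  res$p_adj <- switch(adjust,
                      none = res$p_value,
                      bonferroni = pmin(1, res$p_value * nrow(res)),
                      BH = stats::p.adjust(res$p_value, method = "BH"))
  res <- res |>
    dplyr::mutate(significant = .data$p_adj <= max_p) |>
    dplyr::arrange(.data$p_value, .data$term) |>
    dplyr::select("term", "k", "n", "K", "N", "p_value", "significant", "genes")
  if (!is.null(term_names)) {
    res <- dplyr::left_join(res, term_names, by = "term") |>
      dplyr::relocate("name", .after = "term")
  }
  res
}
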