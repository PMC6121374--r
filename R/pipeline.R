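#' Read the packaged CRP feed-forward-loop census table
#'
#' Loads the published census of 202 CRP-anchored feed-forward loops as a
#' tibble with one row per loop instance (type, target gene), duplicates
#' preserved: a gene listed twice under one type is regulated there by
#' two distinct intermediate TFs.
#'
#' @param path Path to a census TSV (columns `type`, `gene`); defaults to
#'   the packaged table.
#' @return A tibble with columns `type` and `gene`.
#' @export
read_crp_census <- function(path = system.file("extdata", "crp_ffl_census.tsv",
                                                  package = "crpffl")) {
  if (!file.exists(path)) {
    abort(paste0("census fixture not found: ", path), class = "crpffl_input_error")
  }
  tbl <- readr::read_tsv(path, col_types = "cc", progress = FALSE)
  bad <- setdiff(unique(tbl$type), ffl_types()$type)
  if (length(bad) > 0L) {
    abort(paste0("census fixture has unknown type(s): ", paste(bad, collapse = ", ")),
          class = "crpffl_packaging_error")
  }
  tbl
}

#' Summary statistics for a census instance table
#'
#' Computes, from a (type, gene) instance table, the totals the census
#' implies: instance count, distinct-gene union, per-type instance and
#' distinct-gene counts, and the single-Y / multi-Y partition.  A loop
#' instance is single-Y when its target gene appears exactly once across
#' all types jointly (one intermediate TF regulates it); genes appearing
#' in several instances - in one type or across types - are multi-Y.
#'
#' @param census Tibble with `type` and `gene` columns, e.g. from
#'   [read_crp_census()], or an `ffl_census` (its targets are used).
#' @return A list: `total_ffls`, `distinct_genes`, `single_y_instances`,
#'   `multi_y_instances`, `single_y_genes`, `multi_y_genes`, `per_type`
#'   (tibble `type`, `n_ffl`, `n_gene`, `genes` list-column).
#' @export
fixture_stats <- function(census) {
  inst <- if (inherits(census, "ffl_census")) {
    tibble::tibble(type = census$instances$type, gene = census$instances$z)
  } else {
    tibble::as_tibble(census)
  }
  stopifnot(all(c("type", "gene") %in% names(inst)))
  if (nrow(inst) == 0L) {
    return(list(total_ffls = 0L, distinct_genes = 0L,
                single_y_instances = 0L, multi_y_instances = 0L,
                single_y_genes = 0L, multi_y_genes = 0L,
                per_type = tibble::tibble(type = character(), n_ffl = integer(),
                                          n_gene = integer(), genes = list())))
  }
  mult <- table(inst$gene)
  single <- names(mult)[mult == 1L]
  per_type <- inst |>
    dplyr::mutate(type = factor(.data$type, levels = ffl_types()$type)) |>
    dplyr::group_by(.data$type) |>
    dplyr::summarise(n_ffl = dplyr::n(), n_gene = dplyr::n_distinct(.data$gene),
                     genes = list(sort(.data$gene)), .groups = "drop") |>
    dplyr::mutate(type = as.character(.data$type))
  list(
    total_ffls = nrow(inst),
    distinct_genes = dplyr::n_distinct(inst$gene),
    single_y_instances = sum(inst$gene %in% single),
    multi_y_instances = sum(!inst$gene %in% single),
    single_y_genes = length(single),
    multi_y_genes = dplyr::n_distinct(inst$gene) - length(single),
    per_type = per_type
  )
}

#' Share of master-regulated genes engaged in feed-forward loops
#'
#' The headline regulon statistic: the percentage of all genes regulated
#' by the master TF whose regulation also runs through at least one
#' feed-forward loop, rounded to the nearest integer (147 FFL genes over
#' 432 CRP-regulated genes gives 34).
#'
#' @param n_ffl_genes Distinct responsive FFL target genes.
#' @param n_regulated_genes Total genes regulated by the master TF.
#' @return Percentage, rounded to the nearest integer.
#' @export
ffl_gene_share <- function(n_ffl_genes, n_regulated_genes) {
  stopifnot(n_regulated_genes > 0, n_ffl_genes >= 0)
  round(100 * n_ffl_genes / n_regulated_genes)
}

#' Run the full feed-forward-loop dose-response pipeline
#'
#' Executes the whole analysis: read and sign the interaction table,
#' enumerate and classify master-TF feed-forward loops, compute
#' dose-response fold-change profiles, filter unresponsive genes,
#' restrict the census to responsive targets, split it into single-Y and
#' multi-Y loops, cluster each split's target-gene profiles, label group
#' shapes, merge the two group sets into functional groups and run term
#' over-representation per functional group.  Inputs may be file paths
#' or in-memory tibbles.  All outputs are written as TSV plus a JSON run
#' summary; reruns with identical inputs are byte-identical.
#'
#' @param interactions Interaction table path or tibble
#'   (see [read_interactions()]).
#' @param expression Expression matrix path or long tibble
#'   (see [read_expression_matrix()]).
#' @param annotations Optional annotation table path or tibble
#'   (see [read_annotations()]); enrichment is skipped when `NULL`.
#' @param out_dir Output directory, created if needed; `NULL` writes
#'   nothing.
#' @param master Master TF identifier, default `"crp"`.
#' @param tf_set Optional intermediate-TF identifiers; defaults to every
#'   regulator in the interaction table.
#' @param threshold,filter_mode Fold-change filter settings
#'   (see [filter_responsive()]); defaults 0.5 and `"any"`.
#' @param k_sffl,k_mffl Flat group counts for the single-Y and multi-Y
#'   clusterings, defaults 5 and 6 (capped at the split's gene count).
#' @param max_p Enrichment significance ceiling, default 0.01.
#' @param min_corr Functional-group merge threshold, default 0.8.
#' @param min_evidence Evidence filter for the network, default `"any"`.
#' @return A list (invisibly if `out_dir` given): `network`, `census`
#'   (full), `kept_census` (responsive targets only), `filter_report`,
#'   `groups` (gene, group_id, shape, fg_id), `sg`, `mg` (labelled group
#'   tables), `functional_groups`, `enrichment`, `summary` (named list of
#'   counts and the configuration echo).
#' @export
run_pipeline <- function(interactions, expression, annotations = NULL,
                         out_dir = NULL, master = "crp", tf_set = NULL,
                         threshold = 0.5, filter_mode = "any",
                         k_sffl = 5, k_mffl = 6, max_p = 0.01,
                         min_corr = 0.8, min_evidence = "any") {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(paste0("[", name, "] ", conditionMessage(e)),
            class = "crpffl_pipeline_error")
    })
  }

  ints <- stage("regnet", {
    if (is.character(interactions)) read_interactions(interactions)
    else tibble::as_tibble(interactions)
  })
  if (is.null(tf_set)) tf_set <- unique(ints$regulator)
  net <- stage("regnet", build_network(ints, tf_set = tf_set,
                                       min_evidence = min_evidence))
  census <- stage("motif", enumerate_ffls(net, master = master, tf_set = tf_set))

  expr <- stage("doseresponse", {
    if (is.character(expression)) read_expression_matrix(expression)
    else tibble::as_tibble(expression)
  })
  profiles <- stage("doseresponse", compute_profiles(expr))
  profiles <- profiles |> dplyr::mutate(gene = tolower(.data$gene))
  report <- stage("doseresponse",
                  filter_responsive(profiles, threshold = threshold,
                                    mode = filter_mode))
  kept_genes <- report$gene[report$kept]

  kept_inst <- census$instances |>
    dplyr::filter(.data$z %in% kept_genes) |>
    dplyr::group_by(.data$z) |>
    dplyr::mutate(n_y = dplyr::n_distinct(.data$y)) |>
    dplyr::ungroup() |>
    dplyr::mutate(arity_class = ifelse(.data$n_y >= 2L, "multi", "single"))
  kept_census <- structure(list(instances = kept_inst, master = census$master),
                           class = "ffl_census")

  cluster_split <- function(genes, k, prefix) {
    prof <- profiles |> dplyr::filter(.data$gene %in% genes)
    if (length(genes) == 0L) {
      return(list(groups = tibble::tibble(group_id = character(),
                                          n_genes = integer(), genes = list(),
                                          mean_profile = list(),
                                          shape = character(),
                                          cohesion = double()),
                  assignment = tibble::tibble(gene = character(),
                                              group = integer())))
    }
    k_use <- min(k, length(genes))
    cl <- hierarchical_groups(prof, k = k_use)
    list(groups = profile_groups(prof, cl, prefix = prefix),
         assignment = cl$assignment)
  }
  s_genes <- sort(unique(kept_inst$z[kept_inst$arity_class == "single"]))
  m_genes <- sort(unique(kept_inst$z[kept_inst$arity_class == "multi"]))
  sg <- stage("clustering", cluster_split(s_genes, k_sffl, "SG"))
  mg <- stage("clustering", cluster_split(m_genes, k_mffl, "MG"))
  fg <- stage("clustering",
              merge_functional_groups(sg$groups, mg$groups, min_corr = min_corr))

  group_tbl <- dplyr::bind_rows(
    sg$assignment |> dplyr::mutate(group_id = paste0("SG", .data$group)),
    mg$assignment |> dplyr::mutate(group_id = paste0("MG", .data$group))
  ) |>
    dplyr::select("gene", "group_id") |>
    dplyr::left_join(dplyr::bind_rows(sg$groups, mg$groups) |>
                       dplyr::select("group_id", "shape"),
                     by = "group_id") |>
    dplyr::left_join(fg |> dplyr::select("group_id", "fg_id"), by = "group_id") |>
    dplyr::arrange(.data$group_id, .data$gene)

  enr <- NULL
  if (!is.null(annotations)) {
    ann <- stage("enrichment", {
      if (is.character(annotations)) read_annotations(annotations)
      else tibble::as_tibble(annotations)
    })
    universe <- unique(profiles$gene)
    enr <- stage("enrichment", {
      purrr::map_dfr(sort(unique(fg$fg_id)), function(id) {
        fg_genes <- sort(unique(unlist(fg$genes[fg$fg_id == id])))
        enrich_group(fg_genes, universe = universe, annotations = ann,
                     max_p = max_p) |>
          dplyr::mutate(fg_id = id, .before = 1) |>
          dplyr::mutate(genes = purrr::map_chr(.data$genes, paste, collapse = ","))
      })
    })
  }

  summary <- list(
    n_interactions = nrow(ints),
    n_edges = nrow(net$edges),
    n_excluded_pairs = nrow(net$excluded),
    n_ffls = nrow(census$instances),
    n_ffl_genes = dplyr::n_distinct(census$instances$z),
    n_ffl_tfs = dplyr::n_distinct(census$instances$y),
    n_profiled_genes = nrow(report),
    n_kept_genes = length(kept_genes),
    n_kept_ffls = nrow(kept_inst),
    n_kept_ffl_genes = dplyr::n_distinct(kept_inst$z),
    n_sffl = sum(kept_inst$arity_class == "single"),
    n_mffl = sum(kept_inst$arity_class == "multi"),
    n_sg = nrow(sg$groups), n_mg = nrow(mg$groups),
    n_fg = dplyr::n_distinct(fg$fg_id),
    n_significant_terms = if (is.null(enr)) NA_integer_ else sum(enr$significant),
    config = list(master = master, threshold = threshold,
                  filter_mode = filter_mode, k_sffl = k_sffl, k_mffl = k_mffl,
                  max_p = max_p, min_corr = min_corr,
                  min_evidence = min_evidence)
  )

  result <- list(network = net, census = census, kept_census = kept_census,
                 filter_report = report, groups = group_tbl,
                 sg = sg$groups, mg = mg$groups, functional_groups = fg,
                 enrichment = enr, summary = summary)

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    readr::write_tsv(kept_inst, file.path(out_dir, "census.tsv"))
    readr::write_tsv(report, file.path(out_dir, "filter_report.tsv"))
    readr::write_tsv(group_tbl, file.path(out_dir, "groups.tsv"))
    if (!is.null(enr)) {
      readr::write_tsv(enr, file.path(out_dir, "enrichment.tsv"))
    }
    jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    return(invisible(result))
  }
  result
}
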