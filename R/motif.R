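#' The eight feed-forward-loop types
#'
#' Sign table for the eight FFL types in the Mangan-Alon taxonomy.  A
#' loop is coherent when the sign of the direct X->Z edge equals the
#' product of the X->Y and Y->Z signs.
#'
#' @return A tibble with columns `type`, `sign_xy`, `sign_yz`, `sign_xz`
#'   and `coherent`, one row per type in canonical order
#'   Coh1..Coh4, InCoh1..InCoh4.
#' @export
#' @examples
#' ffl_types()
ffl_types <- function() {
  tibble::tibble(
    type = c("Coh1", "Coh2", "Coh3", "Coh4",
             "InCoh1", "InCoh2", "InCoh3", "InCoh4"),
    sign_xy = c(1L, -1L, 1L, -1L, 1L, -1L, 1L, -1L),
    sign_yz = c(1L, 1L, -1L, -1L, -1L, -1L, 1L, 1L),
    sign_xz = c(1L, -1L, -1L, 1L, 1L, -1L, -1L, 1L)
  ) |>
    dplyr::mutate(coherent = .data$sign_xz == .data$sign_xy * .data$sign_yz)
}

#' Classify feed-forward loops by their three edge signs
#'
#' Maps each (X->Y, Y->Z, X->Z) sign triple to one of the eight FFL type
#' labels.  Vectorised over all three arguments.
#'
#' @param sign_xy,sign_yz,sign_xz Edge signs, each `+1` or `-1`.
#' @return Character vector of type labels (`"Coh1"`..`"InCoh4"`).
#' @export
#' @examples
#' classify_ffl(1, 1, 1)    # Coh1
#' classify_ffl(-1, 1, -1)  # Coh2: CRP represses gadX and gadA, GadX activates gadA
#' classify_ffl(1, -1, 1)   # InCoh1: direct + against indirect -
classify_ffl <- function(sign_xy, sign_yz, sign_xz) {
  args <- vctrs_recycle(sign_xy, sign_yz, sign_xz)
  if (!all(unlist(args) %in% c(-1, 1))) {
    abort("all edge signs must be +1 or -1", class = "crpffl_domain_error")
  }
  key <- paste(args[[1]], args[[2]], args[[3]])
  tab <- ffl_types()
  lut <- setNames(tab$type, paste(tab$sign_xy, tab$sign_yz, tab$sign_xz))
  unname(lut[key])
}

# recycle scalar args against the longest, base-R style
vctrs_recycle <- function(...) {
  args <- list(...)
  n <- max(lengths(args))
  lapply(args, function(a) {
    if (length(a) == n) a else rep(a, length.out = n)
  })
}

#' Enumerate feed-forward loops through a master transcription factor
#'
#' Finds every ordered triple (master, Y, Z) with Y a transcription
#' factor distinct from the master, Z distinct from both, and all three
#' resolved signed edges master->Y, Y->Z and master->Z present in the
#' network.  Each triangle is classified into one of the eight FFL types,
#' and every target gene is tagged with its Y-arity: the number of
#' distinct master-regulated TFs that regulate it, across all types
#' jointly.  Targets with arity 1 form the single-Y (sFFL) partition and
#' arity >= 2 the multi-Y (mFFL) partition.
#'
#' @param net A `signed_regnet` from [build_network()].
#' @param master Master TF identifier (case-insensitive), X in every loop.
#' @param tf_set Optional character vector of admissible Y identifiers;
#'   defaults to the TF-flagged nodes of `net`.
#'
#' @return An object of class `ffl_census`: a list with `instances`
#'   (tibble `x`, `y`, `z`, `sign_xy`, `sign_yz`, `sign_xz`, `type`,
#'   `n_y`, `arity_class`), sorted by type, target, then Y, and `master`.
#' @export
enumerate_ffls <- function(net, master, tf_set = NULL) {
  stopifnot(inherits(net, "signed_regnet"))
  master_id <- tolower(trimws(master))
  if (!master_id %in% net$nodes$id) {
    abort(paste0("master regulator not in network: ", master),
          class = "crpffl_input_error")
  }
  tf_ids <- if (is.null(tf_set)) {
    net$nodes$id[net$nodes$is_tf]
  } else {
    unique(tolower(trimws(tf_set)))
  }
  e <- net$edges
  xy <- e |>
    dplyr::filter(.data$regulator == master_id,
                  .data$target %in% tf_ids,
                  .data$target != master_id) |>
    dplyr::select(y = "target", sign_xy = "sign")
  yz <- e |>
    dplyr::filter(.data$regulator %in% xy$y) |>
    dplyr::select(y = "regulator", z = "target", sign_yz = "sign") |>
    dplyr::filter(.data$z != .data$y, .data$z != master_id)
  xz <- e |>
    dplyr::filter(.data$regulator == master_id) |>
    dplyr::select(z = "target", sign_xz = "sign")

  inst <- xy |>
    dplyr::inner_join(yz, by = "y") |>
    dplyr::inner_join(xz, by = "z") |>
    dplyr::mutate(x = master_id,
                  type = classify_ffl(.data$sign_xy, .data$sign_yz, .data$sign_xz)) |>
    dplyr::select("x", "y", "z", "sign_xy", "sign_yz", "sign_xz", "type")

  inst <- inst |>
    dplyr::group_by(.data$z) |>
    dplyr::mutate(n_y = dplyr::n_distinct(.data$y)) |>
    dplyr::ungroup() |>
    dplyr::mutate(arity_class = ifelse(.data$n_y >= 2L, "multi", "single"),
                  type = factor(.data$type, levels = ffl_types()$type)) |>
    dplyr::arrange(.data$type, .data$z, .data$y) |>
    dplyr::mutate(type = as.character(.data$type))

  structure(list(instances = inst, master = master_id), class = "ffl_census")
}

#' @export
print.ffl_census <- function(x, ...) {
  cat("<ffl_census> master=", x$master, ": ", nrow(x$instances),
      " FFLs over ", dplyr::n_distinct(x$instances$z), " target genes and ",
      dplyr::n_distinct(x$instances$y), " intermediate TFs\n", sep = "")
  print(census_summary(x), ...)
  invisible(x)
}

#' @describeIn enumerate_ffls Tidy accessor: the per-instance tibble.
#' @param x An `ffl_census`.
#' @param ... Unused.
#' @export
tidy.ffl_census <- function(x, ...) x$instances

#' @describeIn enumerate_ffls One-row overview: total loops, distinct
#'   genes and TFs, single-Y and multi-Y instance counts.
#' @export
glance.ffl_census <- function(x, ...) {
  inst <- x$instances
  tibble::tibble(
    n_ffl = nrow(inst),
    n_gene = dplyr::n_distinct(inst$z),
    n_tf = dplyr::n_distinct(inst$y),
    n_sffl = sum(inst$arity_class == "single"),
    n_mffl = sum(inst$arity_class == "multi")
  )
}

#' Per-type census summary
#'
#' Tabulates, for each FFL type present, the number of loop instances,
#' distinct intermediate TFs, distinct target genes, and the sorted
#' per-instance gene list (duplicates kept, one entry per loop), mirroring
#' the layout of published regulon census tables.
#'
#' @param census An `ffl_census`, or a tibble of instances with at least
#'   `type` and `z` columns (and optionally `y`).
#' @return A tibble with columns `type`, `n_ffl`, `n_tf`, `n_gene`,
#'   `genes` (list-column of per-instance target names).
#' @export
census_summary <- function(census) {
  inst <- if (inherits(census, "ffl_census")) census$instances else tibble::as_tibble(census)
  if (nrow(inst) == 0L) {
    return(tibble::tibble(type = character(), n_ffl = integer(),
                          n_tf = integer(), n_gene = integer(), genes = list()))
  }
  has_y <- "y" %in% names(inst)
  inst |>
    dplyr::mutate(type = factor(.data$type, levels = ffl_types()$type)) |>
    dplyr::group_by(.data$type) |>
    dplyr::summarise(
      n_ffl = dplyr::n(),
      n_tf = if (has_y) dplyr::n_distinct(.data$y) else NA_integer_,
      n_gene = dplyr::n_distinct(.data$z),
      genes = list(sort(.data$z)),
      .groups = "drop"
    ) |>
    dplyr::mutate(type = as.character(.data$type))
}

#' Multi-output FFL groups
#'
#' Groups census instances by their (X, Y) transcription-factor pair and
#' reports the pairs that jointly regulate two or more target genes - the
#' multi-output generalisation of the FFL motif.
#'
#' @param census An `ffl_census`.
#' @return A tibble with columns `x`, `y`, `n_targets` and `targets`
#'   (list-column of sorted target identifiers), pairs with >= 2 targets
#'   only, sorted by `x` then `y`.
#' @export
multi_output_groups <- function(census) {
  inst <- if (inherits(census, "ffl_census")) census$instances else tibble::as_tibble(census)
  inst |>
    dplyr::group_by(.data$x, .data$y) |>
    dplyr::summarise(n_targets = dplyr::n_distinct(.data$z),
                     targets = list(sort(unique(.data$z))), .groups = "drop") |>
    dplyr::filter(.data$n_targets >= 2L) |>
    dplyr::arrange(.data$x, .data$y)
}
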