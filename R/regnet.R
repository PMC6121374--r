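#' Read a regulator-target interaction table
#'
#' Parses a RegulonDB/EcoCyc-style flat file of transcription-factor to
#' gene regulatory interactions.  The file is tab-separated with at least
#' three columns (regulator, target, effect) and an optional fourth
#' evidence column; lines starting with `#` are skipped.  A header row is
#' detected automatically when the first non-comment line's third field is
#' not a recognisable effect token.
#'
#' Effect strings are mapped case-insensitively: `+`, `+1`, `activation`,
#' `activator` to `"activation"`; `-`, `-1`, the Unicode minus,
#' `repression`, `repressor` to `"repression"`; `+-`, `-+`, the plus-minus
#' sign and `dual` to `"dual"`.  Anything else becomes `"unknown"` with a
#' warning.  Evidence strings other than `strong`/`weak` become
#' `"unspecified"`.
#'
#' Identifiers are trimmed; the display form keeps its source casing while
#' all downstream matching is case-insensitive (E. coli gene symbols are
#' printed case-sensitively but databases mix cases).
#'
#' @param path Path to a tab-separated interaction file.
#' @param header `"auto"` (default), `TRUE` or `FALSE`.
#' @param comment Comment prefix, default `"#"`.
#'
#' @return A tibble with columns `regulator`, `target`, `effect`,
#'   `evidence`, one row per data row of the file.  An empty file yields a
#'   zero-row tibble.
#' @export
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' writeLines(c("# demo", "crp\tmalE\tactivation\tstrong",
#'              "crp\tcyaA\t-"), tf)
#' read_interactions(tf)
read_interactions <- function(path, header = "auto", comment = "#") {
  if (!file.exists(path)) {
    abort(paste0("interaction file not found: ", path), class = "crpffl_input_error")
  }
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!startsWith(trimws(lines), comment)]
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) {
    return(tibble::tibble(regulator = character(), target = character(),
                          effect = character(), evidence = character()))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(fields) < 3L)
  if (length(short) > 0L) {
    abort(paste0("interaction row with fewer than 3 fields at line ", short[1],
                 ": '", lines[short[1]], "'"), class = "crpffl_parse_error")
  }
  if (identical(header, "auto")) {
    header <- is.na(match_effect(fields[[1]][3]))
  }
  if (isTRUE(header)) {
    fields <- fields[-1]
    if (length(fields) == 0L) {
      return(tibble::tibble(regulator = character(), target = character(),
                            effect = character(), evidence = character()))
    }
  }
  reg <- trimws(vapply(fields, `[`, "", 1L))
  tgt <- trimws(vapply(fields, `[`, "", 2L))
  eff_raw <- trimws(vapply(fields, `[`, "", 3L))
  evd_raw <- trimws(vapply(fields, function(f) if (length(f) >= 4L) f[4] else "", ""))
  if (any(!nzchar(reg)) || any(!nzchar(tgt))) {
    bad <- which(!nzchar(reg) | !nzchar(tgt))[1]
    abort(paste0("empty regulator or target identifier at data row ", bad),
          class = "crpffl_parse_error")
  }
  eff <- match_effect(eff_raw)
  if (anyNA(eff)) {
    unrec <- unique(eff_raw[is.na(eff)])
    warn(paste0("unrecognised effect value(s) treated as 'unknown': ",
                paste(unrec, collapse = ", ")))
    eff[is.na(eff)] <- "unknown"
  }
  evd <- tolower(evd_raw)
  evd[!evd %in% c("strong", "weak")] <- "unspecified"
  tibble::tibble(regulator = reg, target = tgt, effect = eff, evidence = evd)
}

# case-insensitive effect token mapping; NA for unrecognised tokens
match_effect <- function(x) {
  key <- tolower(trimws(x))
  out <- rep(NA_character_, length(key))
  out[key %in% c("activation", "activator", "+", "+1", "1")] <- "activation"
  out[key %in% c("repression", "repressor", "-", "−", "-1")] <- "repression"
  out[key %in% c("dual", "+-", "-+", "±")] <- "dual"
  out[key %in% c("unknown", "?")] <- "unknown"
  out
}

#' Build a signed regulatory network from interaction records
#'
#' Resolves interaction records into a directed network with one signed
#' edge per (regulator, target) pair: activation becomes +1, repression
#' -1.  Pairs whose only records are dual or unknown, pairs with
#' conflicting activation/repression records (treated as dual), and pairs
#' failing the evidence filter are placed on an excluded-pair ledger
#' instead of the edge map.  Duplicate records with the same sign collapse
#' to one edge.  A record of unknown effect alongside a signed record for
#' the same pair adds no information and the signed record wins.
#'
#' @param interactions Tibble as returned by [read_interactions()].
#' @param tf_set Character vector of transcription-factor identifiers
#'   (case-insensitive).
#' @param min_evidence `"any"` (default; the source databases accept both
#'   strong and weak evidence) or `"strong"`.
#'
#' @return An object of class `signed_regnet`: a list with tibbles
#'   `nodes` (`id` lower-case key, `name` display form, `is_tf`),
#'   `edges` (`regulator`, `target`, `sign`) and `excluded`
#'   (`regulator`, `target`, `reason`).  Identifiers in `edges` and
#'   `excluded` are lower-case keys; display forms live in `nodes`.
#' @export
build_network <- function(interactions, tf_set, min_evidence = c("any", "strong")) {
  min_evidence <- match.arg(min_evidence)
  stopifnot(length(tf_set) > 0L)
  ints <- tibble::as_tibble(interactions)
  req <- c("regulator", "target", "effect")
  if (!all(req %in% names(ints))) {
    abort("interactions must have columns regulator, target, effect",
          class = "crpffl_input_error")
  }
  if (!"evidence" %in% names(ints)) ints$evidence <- "unspecified"
  bad_eff <- setdiff(unique(ints$effect),
                     c("activation", "repression", "dual", "unknown"))
  if (length(bad_eff) > 0L) {
    abort(paste0("invalid effect value(s): ", paste(bad_eff, collapse = ", ")),
          class = "crpffl_input_error")
  }

  ints <- ints |>
    dplyr::mutate(reg_id = tolower(trimws(.data$regulator)),
                  tgt_id = tolower(trimws(.data$target)))

  # display name per id: first occurrence wins
  name_tbl <- tibble::tibble(
    id = c(ints$reg_id, ints$tgt_id),
    name = c(trimws(ints$regulator), trimws(ints$target))
  ) |> dplyr::distinct(.data$id, .keep_all = TRUE)

  tf_ids <- unique(tolower(trimws(tf_set)))
  nodes <- name_tbl |>
    dplyr::mutate(is_tf = .data$id %in% tf_ids) |>
    dplyr::arrange(.data$id)

  resolve_pair <- function(effects, evidences) {
    ok <- if (min_evidence == "strong") evidences == "strong" else rep(TRUE, length(effects))
    if (!any(ok)) return("evidence")
    eff <- unique(effects[ok])
    if ("dual" %in% eff) return("dual")
    if (all(c("activation", "repression") %in% eff)) return("conflict")
    if ("activation" %in% eff) return("+1")
    if ("repression" %in% eff) return("-1")
    "unknown"
  }

  pairs <- ints |>
    dplyr::group_by(.data$reg_id, .data$tgt_id) |>
    dplyr::summarise(res = resolve_pair(.data$effect, .data$evidence),
                     .groups = "drop") |>
    dplyr::arrange(.data$reg_id, .data$tgt_id)

  edges <- pairs |>
    dplyr::filter(.data$res %in% c("+1", "-1")) |>
    dplyr::transmute(regulator = .data$reg_id, target = .data$tgt_id,
                     sign = ifelse(.data$res == "+1", 1L, -1L))
  excluded <- pairs |>
    dplyr::filter(!.data$res %in% c("+1", "-1")) |>
    dplyr::transmute(regulator = .data$reg_id, target = .data$tgt_id,
                     reason = .data$res)
  if (any(excluded$reason == "conflict")) {
    warn(paste0(sum(excluded$reason == "conflict"),
                " regulator-target pair(s) with conflicting signs excluded as dual"))
  }

  structure(list(nodes = nodes, edges = edges, excluded = excluded),
            class = "signed_regnet")
}

#' @export
print.signed_regnet <- function(x, ...) {
  cat("<signed_regnet> ", nrow(x$nodes), " nodes (",
      sum(x$nodes$is_tf), " TFs), ", nrow(x$edges), " signed edges, ",
      nrow(x$excluded), " excluded pairs\n", sep = "")
  invisible(x)
}

#' Export a signed network's resolved and excluded edges
#'
#' Writes the resolved edge list (columns `regulator`, `target`, `sign`
#' with values `+1`/`-1`) and, optionally, the excluded-pair ledger to
#' tab-separated files.  Re-reading the edge file with
#' [read_interactions()] and rebuilding reproduces the same network.
#'
#' @param net A `signed_regnet`.
#' @param edges_path Output path for resolved edges.
#' @param excluded_path Optional output path for the excluded-pair ledger.
#' @return `net`, invisibly.
#' @export
write_network <- function(net, edges_path, excluded_path = NULL) {
  stopifnot(inherits(net, "signed_regnet"))
  edges <- net$edges |>
    dplyr::mutate(sign = ifelse(.data$sign > 0, "+1", "-1"))
  readr::write_tsv(edges, edges_path)
  if (!is.null(excluded_path)) readr::write_tsv(net$excluded, excluded_path)
  invisible(net)
}
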