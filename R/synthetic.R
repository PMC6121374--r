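#' Generate a signed regulatory network with planted feed-forward loops
#'
#' Builds a synthetic master-TF regulon whose FFL census is known by
#' construction.  For every requested type, a fresh intermediate TF (and,
#' usually, a fresh target gene) is created and the three signed edges of
#' that type's pattern are added.  With probability `multi_y_fraction` a
#' planted loop reuses an existing target whose master-edge sign is
#' compatible, so that target becomes a multi-Y gene.  Decoy edges add
#' realistic clutter; in the default constrained mode each decoy is
#' checked structurally against the current edge set and resampled until
#' it cannot complete an unplanned triangle through the master, so the
#' planted ledger is the exact ground truth.  With
#' `constrain = FALSE` decoys are unconstrained random edges (useful for
#' stress-testing enumeration against a brute-force oracle).
#'
#' @param n_per_type Named integer vector of planted loop counts, names
#'   from [ffl_types()] (missing types = 0).
#' @param master Master TF identifier, default `"crp"`.
#' @param n_decoys Number of decoy edges, default 0.
#' @param multi_y_fraction Probability that a planted loop reuses an
#'   existing compatible target, default 0.
#' @param constrain Keep decoys triangle-free (default `TRUE`).
#' @param seed Integer seed; the generator is a pure function of its
#'   arguments and the seed.
#' @return A list: `network` (a `signed_regnet`), `interactions` (the
#'   edge table the network was built from), `planted` (tibble `x`, `y`,
#'   `z`, `type` of every planted instance) and `tf_set`.
#' @export
generate_network <- function(n_per_type, master = "crp", n_decoys = 0,
                             multi_y_fraction = 0, constrain = TRUE,
                             seed = 1L) {
  stopifnot(all(n_per_type >= 0), multi_y_fraction >= 0, multi_y_fraction <= 1)
  tab <- ffl_types()
  if (is.null(names(n_per_type))) {
    stopifnot(length(n_per_type) == 8L)
    names(n_per_type) <- tab$type   # canonical Coh1..InCoh4 order
  }
  counts <- setNames(rep(0L, 8L), tab$type)
  counts[names(n_per_type)] <- as.integer(n_per_type)
  unknown <- setdiff(names(n_per_type), tab$type)
  if (length(unknown) > 0L) {
    abort(paste0("unknown FFL type(s): ", paste(unknown, collapse = ", ")),
          class = "crpffl_input_error")
  }

  with_seed_local(seed, {
    edges <- list()   # each: c(regulator, target, sign)
    ekey <- character()
    add_edge <- function(u, v, s) {
      edges[[length(edges) + 1L]] <<- list(u = u, v = v, s = s)
      ekey <<- c(ekey, paste(u, v))
    }
    has_edge <- function(u, v) paste(u, v) %in% ekey

    planted <- list()
    z_sign <- c()        # sign of master->z per planted target
    y_ctr <- 0L; z_ctr <- 0L
    for (ti in seq_len(nrow(tab))) {
      tp <- tab$type[ti]
      for (i in seq_len(counts[[tp]])) {
        y_ctr <- y_ctr + 1L
        y <- sprintf("ty%04d", y_ctr)
        reusable <- names(z_sign)[z_sign == tab$sign_xz[ti]]
        if (length(reusable) > 0L && runif(1) < multi_y_fraction) {
          z <- if (length(reusable) == 1L) reusable else sample(reusable, 1L)
        } else {
          z_ctr <- z_ctr + 1L
          z <- sprintf("gz%04d", z_ctr)
          z_sign[z] <- tab$sign_xz[ti]
          add_edge(master, z, tab$sign_xz[ti])
        }
        add_edge(master, y, tab$sign_xy[ti])
        add_edge(y, z, tab$sign_yz[ti])
        planted[[length(planted) + 1L]] <-
          tibble::tibble(x = master, y = y, z = z, type = tp)
      }
    }
    planted <- if (length(planted) > 0L) dplyr::bind_rows(planted) else
      tibble::tibble(x = character(), y = character(), z = character(),
                     type = character())

    ys <- unique(planted$y)
    # structural check: could edge (u, v) complete a triangle through master?
    edge_df <- function() {
      tibble::tibble(regulator = vapply(edges, `[[`, "", "u"),
                     target = vapply(edges, `[[`, "", "v"),
                     sign = vapply(edges, `[[`, 0, "s"))
    }
    unsafe <- function(u, v) {
      if (u == v) return(TRUE)
      ed <- edge_df()
      m_targets <- ed$target[ed$regulator == master]
      # as y->z edge: u is master-regulated and master also hits v
      if (u %in% m_targets && v %in% m_targets) return(TRUE)
      # as x->z edge: some master-regulated TF already hits v
      if (u == master) {
        regs_of_v <- ed$regulator[ed$target == v]
        if (any(regs_of_v %in% intersect(m_targets, ys))) return(TRUE)
        # as x->y edge: v could act as a Y whose targets master already hits
        tgts_of_v <- ed$target[ed$regulator == v]
        if (any(tgts_of_v %in% m_targets)) return(TRUE)
      }
      has_edge(u, v)
    }

    dt_ctr <- 0L; dg_ctr <- 0L
    for (i in seq_len(n_decoys)) {
      placed <- FALSE
      for (try in seq_len(100L)) {
        if (!constrain) {
          # unconstrained mode: any random ordered pair over current nodes
          nodes <- unique(c(master, ys, names(z_sign),
                            if (dg_ctr > 0L) sprintf("dg%04d", seq_len(dg_ctr)),
                            if (dt_ctr > 0L) sprintf("dt%04d", seq_len(dt_ctr))))
          u <- sample(nodes, 1L); v <- sample(nodes, 1L)
          if (u == v || has_edge(u, v)) next
          add_edge(u, v, sample(c(-1L, 1L), 1L))
          placed <- TRUE
          break
        }
        kind <- sample(3L, 1L)
        if (kind == 1L) {            # master -> fresh orphan gene
          dg_ctr <- dg_ctr + 1L
          u <- master; v <- sprintf("dg%04d", dg_ctr)
        } else if (kind == 2L) {     # fresh non-regulon TF -> existing target
          pool <- unique(c(names(z_sign),
                           if (dg_ctr > 0L) sprintf("dg%04d", seq_len(dg_ctr))))
          if (length(pool) == 0L) next
          dt_ctr <- dt_ctr + 1L
          u <- sprintf("dt%04d", dt_ctr)
          v <- if (length(pool) == 1L) pool else sample(pool, 1L)
        } else {                     # planted Y -> gene outside the regulon
          if (length(ys) == 0L) next
          u <- if (length(ys) == 1L) ys else sample(ys, 1L)
          dg_ctr <- dg_ctr + 1L
          v <- sprintf("yg%04d", dg_ctr)
        }
        if (unsafe(u, v)) next
        add_edge(u, v, sample(c(-1L, 1L), 1L))
        placed <- TRUE
        break
      }
      if (!placed) {
        abort("could not place a triangle-free decoy edge after 100 attempts",
              class = "crpffl_generation_error")
      }
    }

    interactions <- edge_df() |>
      dplyr::transmute(regulator = .data$regulator, target = .data$target,
                       effect = ifelse(.data$sign > 0, "activation", "repression"),
                       evidence = "strong")
    tf_set <- unique(c(master, ys, interactions$regulator))
    net <- build_network(interactions, tf_set = tf_set)
    planted <- planted |>
      dplyr::mutate(type = factor(.data$type, levels = ffl_types()$type)) |>
      dplyr::arrange(.data$type, .data$z, .data$y) |>
      dplyr::mutate(type = as.character(.data$type))
    list(network = net, interactions = interactions, planted = planted,
         tf_set = tf_set)
  })
}

#' Canonical dose-response base shapes
#'
#' Deterministic log2 fold-change curves for the five canonical shapes,
#' anchored to the cAMP dose landmarks of the CRP system (activation from
#' trace doses saturating near 1 mM; switch-like activation above 0.3 mM;
#' log-linear repression; a bell peaking near 0.1-0.3 mM; its mirror).
#'
#' @param shape One of `"saturating_up"`, `"sigmoid_threshold"`,
#'   `"monotone_down"`, `"bell"`, `"inverse_bell"`.
#' @param dose Positive dose(s) in mM.
#' @param amplitude Curve amplitude in log2 units.
#' @return Numeric vector of log2 fold changes.
#' @export
shape_curve <- function(shape, dose, amplitude = 2) {
  switch(shape,
    saturating_up = amplitude * (1 - exp(-dose / 0.05)),
    sigmoid_threshold = amplitude / (1 + (0.3 / dose)^2),
    monotone_down = pmax(-amplitude, pmin(0, -amplitude * log10(dose / 0.01) / 3)),
    bell = amplitude * exp(-(log10(dose / 0.2))^2 / 0.5),
    inverse_bell = -amplitude * exp(-(log10(dose / 0.2))^2 / 0.5),
    abort(paste0("unknown shape: ", shape), class = "crpffl_input_error")
  )
}

#' Generate a dose-response expression matrix with known true shapes
#'
#' Simulates a replicated log2 expression matrix over a dose grid.  Each
#' gene is assigned one of the five canonical shapes; its absolute
#' expression is `baseline + shape_curve(shape, dose, amplitude)` plus
#' i.i.d. Gaussian noise per replicate on the log2 scale, with zero-dose
#' control columns at `baseline` plus noise.  At `noise_sd = 0`,
#' [compute_profiles()] recovers the base curves exactly.
#'
#' @param shape_counts Named integer vector of genes per shape; defaults
#'   to 8 genes for each of the five shapes.
#' @param genes Optional gene identifiers (length = sum of counts).
#' @param dose_grid Dose grid starting at 0, default [camp_dose_grid()].
#' @param amplitude Curve amplitude in log2 units, default 2.
#' @param noise_sd Gaussian noise standard deviation, default 0.1.
#' @param replicates Replicates per dose, default 2.
#' @param baseline Absolute log2 expression baseline, default 8.
#' @param seed Integer seed.
#' @return A list: `expr` (long tibble `gene`, `dose`, `replicate`,
#'   `log2_expr`) and `truth` (tibble `gene`, `shape`).
#' @export
generate_expression <- function(shape_counts = c(saturating_up = 8,
                                                 sigmoid_threshold = 8,
                                                 monotone_down = 8,
                                                 bell = 8,
                                                 inverse_bell = 8),
                                genes = NULL, dose_grid = camp_dose_grid(),
                                amplitude = 2, noise_sd = 0.1,
                                replicates = 2, baseline = 8, seed = 1L) {
  stopifnot(dose_grid[1] == 0, !is.unsorted(dose_grid, strictly = TRUE),
            noise_sd >= 0, replicates >= 1)
  n <- sum(shape_counts)
  if (is.null(genes)) genes <- sprintf("g%04d", seq_len(n))
  stopifnot(length(genes) == n, !anyDuplicated(genes))
  truth <- tibble::tibble(gene = genes,
                          shape = rep(names(shape_counts), shape_counts))
  grid <- tidyr::expand_grid(truth, dose = dose_grid,
                             replicate = seq_len(replicates))
  with_seed_local(seed, {
    base <- ifelse(grid$dose == 0, 0,
                   unlist(purrr::map2(grid$shape, grid$dose,
                                      function(s, d) shape_curve(s, d, amplitude))))
    expr <- grid |>
      dplyr::mutate(log2_expr = baseline + base +
                      rnorm(dplyr::n(), sd = noise_sd)) |>
      dplyr::select("gene", "dose", "replicate", "log2_expr")
    attr(expr, "dose_grid") <- dose_grid
    list(expr = expr, truth = truth)
  })
}

#' Write a generated expression set as a wide matrix file
#'
#' Lays out a long expression tibble as genes-by-samples with
#' `<dose>mM_r<rep>` headers, the format [read_expression_matrix()]
#' consumes.
#'
#' @param expr Long tibble from [generate_expression()].
#' @param path Output path (`.csv` for comma, else tab).
#' @return `path`, invisibly.
#' @export
write_expression_matrix <- function(expr, path) {
  wide <- expr |>
    dplyr::mutate(sample = paste0(.data$dose, "mM_r", .data$replicate)) |>
    tidyr::pivot_wider(id_cols = "gene", names_from = "sample",
                       values_from = "log2_expr")
  if (grepl("\\.csv$", path, ignore.case = TRUE)) {
    readr::write_csv(wide, path)
  } else {
    readr::write_tsv(wide, path)
  }
  invisible(path)
}

#' Generate annotations with terms planted into gene groups
#'
#' Simulates a gene-to-term annotation table: a set of background terms
#' each annotating every universe gene independently at
#' `background_rate`, plus one designated term per gene group annotating
#' group members at `min(1, enrich_factor * background_rate)` and
#' non-members at the background rate.  With `enrich_factor = 1` (or an
#' empty group table) no term is planted above background.
#'
#' @param groups Tibble with `gene` and `group` columns (may be zero-row).
#' @param universe Character vector of all genes.
#' @param n_background_terms Number of background-only terms, default 20.
#' @param enrich_factor Enrichment multiplier (>= 1), default 5.
#' @param background_rate Per-gene annotation probability, in (0, 1),
#'   default 0.1.
#' @param seed Integer seed.
#' @return A list: `annotations` (tibble `gene`, `term`, `namespace`) and
#'   `planted` (tibble `group`, `term` naming each designated term).
#' @export
generate_annotations <- function(groups, universe, n_background_terms = 20,
                                 enrich_factor = 5, background_rate = 0.1,
                                 seed = 1L) {
  stopifnot(enrich_factor >= 1, background_rate > 0, background_rate < 1)
  groups <- tibble::as_tibble(groups)
  universe <- unique(universe)
  with_seed_local(seed, {
    draw <- function(term, rate_of) {
      hit <- runif(length(universe)) < rate_of
      tibble::tibble(gene = universe[hit], term = term)
    }
    bg <- purrr::map_dfr(sprintf("GO:BG%04d", seq_len(n_background_terms)),
                         function(tm) draw(tm, rep(background_rate, length(universe))))
    grp_ids <- if (nrow(groups) > 0L) sort(unique(groups$group)) else character()
    planted <- tibble::tibble(group = grp_ids,
                              term = sprintf("GO:ENR%04d", seq_along(grp_ids)))
    enr <- purrr::map2_dfr(planted$group, planted$term, function(g, tm) {
      members <- groups$gene[groups$group == g]
      rate <- ifelse(universe %in% members,
                     min(1, enrich_factor * background_rate), background_rate)
      hit <- runif(length(universe)) < rate
      tibble::tibble(gene = universe[hit], term = tm)
    })
    ann <- dplyr::bind_rows(bg, enr) |>
      dplyr::mutate(namespace = "biological_process") |>
      dplyr::arrange(.data$term, .data$gene)
    list(annotations = ann, planted = planted)
  })
}

# evaluate code under a temporary RNG state so generators are pure in (args, seed)
with_seed_local <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}
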