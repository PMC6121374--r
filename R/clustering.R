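#' Pearson correlation distance between profile vectors
#'
#' Distance `1 - r` with `r` the Pearson correlation, so identical shapes
#' are at distance 0, uncorrelated shapes at 1 and perfectly
#' anti-correlated shapes at 2.  A zero-variance (flat) profile carries no
#' shape information; its distance to any other profile is defined as 1
#' (and 0 to itself), with a warning.
#'
#' @param p,q Numeric vectors of equal length >= 3, or `q = NULL` with
#'   `p` a gene-by-dose matrix, in which case the full pairwise distance
#'   object over rows is returned.
#' @return A single distance in `[0, 2]`, or a [stats::dist] object.
#' @export
correlation_distance <- function(p, q = NULL) {
  if (is.null(q)) {
    m <- as.matrix(p)
    v <- apply(m, 1L, stats::sd)
    flat <- v == 0 | !is.finite(v)
    if (any(flat)) {
      warn(paste0(sum(flat), " zero-variance profile(s); distances to them set to 1"))
    }
    cm <- suppressWarnings(stats::cor(t(m)))
    cm[flat, ] <- 0
    cm[, flat] <- 0
    diag(cm) <- 1
    return(as.dist(1 - cm))
  }
  if (length(p) != length(q)) {
    abort("profile vectors must have equal length", class = "crpffl_domain_error")
  }
  if (length(p) < 3L) {
    abort("profile vectors must have length >= 3", class = "crpffl_domain_error")
  }
  if (stats::sd(p) == 0 || stats::sd(q) == 0) {
    warn("zero-variance profile; correlation distance defined as 1")
    return(1)
  }
  1 - stats::cor(p, q)
}

#' Hierarchical profile grouping by correlation
#'
#' Agglomerative clustering of dose-response profiles with average
#' linkage on the Pearson correlation distance, cut to exactly `k` flat
#' groups.  Profiles are ordered lexicographically by gene name before
#' clustering so the result is invariant to input permutation, and group
#' indices are relabelled 1..k by descending member count (ties broken by
#' the smallest gene name in the group) so labels are stable.
#'
#' @param profiles Profile tibble from [compute_profiles()], or a
#'   gene-by-dose matrix.
#' @param k Number of flat groups, `1 <= k <=` number of profiles.
#' @return An object of class `profile_clustering`: list with
#'   `assignment` (tibble `gene`, `group`), `tree` (the [stats::hclust]
#'   object) and `k`.
#' @export
hierarchical_groups <- function(profiles, k) {
  m <- if (is.matrix(profiles)) profiles else profiles_matrix(profiles)
  m <- m[order(rownames(m)), , drop = FALSE]
  n <- nrow(m)
  if (k < 1L || k > n) {
    abort(paste0("k must be between 1 and the number of profiles (", n, ")"),
          class = "crpffl_domain_error")
  }
  d <- correlation_distance(m)
  tree <- hclust(d, method = "average")
  raw <- cutree(tree, k = k)
  sizes <- tibble::tibble(raw = raw, gene = rownames(m)) |>
    dplyr::group_by(.data$raw) |>
    dplyr::summarise(n = dplyr::n(), first_gene = min(.data$gene), .groups = "drop") |>
    dplyr::arrange(dplyr::desc(.data$n), .data$first_gene) |>
    dplyr::mutate(group = dplyr::row_number())
  relabel <- setNames(sizes$group, sizes$raw)
  structure(
    list(assignment = tibble::tibble(gene = rownames(m),
                                     group = unname(relabel[as.character(raw)])),
         tree = tree, k = k),
    class = "profile_clustering"
  )
}

#' @export
print.profile_clustering <- function(x, ...) {
  cat("<profile_clustering> ", nrow(x$assignment), " profiles in ",
      x$k, " groups (average linkage, 1 - Pearson r)\n", sep = "")
  print(table(x$assignment$group))
  invisible(x)
}

#' @describeIn hierarchical_groups Tidy accessor: the gene-to-group
#'   assignment tibble.
#' @param x A `profile_clustering`.
#' @param ... Unused.
#' @export
tidy.profile_clustering <- function(x, ...) x$assignment

#' @describeIn hierarchical_groups One-row overview: profile count, k,
#'   and largest/smallest group size.
#' @export
glance.profile_clustering <- function(x, ...) {
  sz <- table(x$assignment$group)
  tibble::tibble(n_profiles = nrow(x$assignment), k = x$k,
                 largest_group = as.integer(max(sz)),
                 smallest_group = as.integer(min(sz)))
}

#' Label the canonical shape of a mean dose-response profile
#'
#' Rule-based labelling of the five canonical cAMP dose-response shapes,
#' evaluated in order:
#'
#' 1. `bell` - a unique interior maximum with both profile ends at least
#'    `span` log2 units below the peak (expression peaking at
#'    intermediate doses, around 0.1-0.3 mM in the CRP system);
#' 2. `inverse_bell` - the mirror image, an interior minimum;
#' 3. `monotone_down` - non-increasing within `mono_tol`, total drop at
#'    least `span` (repression growing with dose, roughly log-linear);
#' 4. `sigmoid_threshold` - non-decreasing within `mono_tol` with at
#'    least `late_frac` of the total rise occurring at doses >=
#'    `late_dose` mM (switch-like activation above a cAMP threshold);
#' 5. `saturating_up` - non-decreasing with at least `early_frac` of the
#'    rise already reached by `early_dose` mM (activation from trace
#'    cAMP, plateauing by ~1 mM);
#'
#' and `unclassified` when no rule fires.  Rules 3-5 operate on relative
#' rise/drop and are invariant to adding a constant; the `span` rules are
#' anchored to the absolute 0.5 log2 landmark by default.
#'
#' @param profile Numeric vector of mean log2 fold changes over the
#'   positive dose grid (length >= 5).
#' @param doses Positive dose grid (mM), same length, ascending.
#' @param span Minimum peak prominence / total drop, log2 units (0.5).
#' @param mono_tol Monotonicity tolerance, log2 units (0.1).
#' @param late_frac Fraction of rise beyond `late_dose` for a sigmoid (0.7).
#' @param early_frac Fraction of rise by `early_dose` for saturation (0.5).
#' @param late_dose,early_dose Dose anchors in mM (0.3 and 0.1).
#' @return One of `"bell"`, `"inverse_bell"`, `"monotone_down"`,
#'   `"sigmoid_threshold"`, `"saturating_up"`, `"unclassified"`.
#' @export
label_shape <- function(profile, doses, span = 0.5, mono_tol = 0.1,
                        late_frac = 0.7, early_frac = 0.5,
                        late_dose = 0.3, early_dose = 0.1) {
  n <- length(profile)
  stopifnot(n == length(doses), n >= 5L, !is.unsorted(doses, strictly = TRUE))
  interior_extremum <- function(v) {
    at <- which(v == max(v))
    all(at > 1L & at < n) &&
      v[1] <= max(v) - span && v[n] <= max(v) - span
  }
  if (interior_extremum(profile)) return("bell")
  if (interior_extremum(-profile)) return("inverse_bell")
  dif <- diff(profile)
  if (all(dif <= mono_tol) && (profile[1] - profile[n]) >= span) {
    return("monotone_down")
  }
  if (all(dif >= -mono_tol)) {
    rise <- profile[n] - profile[1]
    if (rise > 0) {
      pre_late <- which(doses < late_dose)
      if (length(pre_late) > 0L &&
          (profile[n] - profile[max(pre_late)]) / rise >= late_frac) {
        return("sigmoid_threshold")
      }
      at_early <- which(doses <= early_dose)
      if (length(at_early) > 0L &&
          (profile[max(at_early)] - profile[1]) / rise >= early_frac) {
        return("saturating_up")
      }
    }
  }
  "unclassified"
}

#' Summarise clustered profiles into labelled groups
#'
#' Combines a clustering with the underlying profiles into one row per
#' group carrying the member genes, the per-dose mean profile, its shape
#' label and a cohesion statistic (mean pairwise Pearson correlation
#' among member profiles; `NA` for singleton groups).
#'
#' @param profiles Profile tibble from [compute_profiles()].
#' @param clustering A `profile_clustering` from [hierarchical_groups()],
#'   or a tibble with `gene` and `group` columns.
#' @param prefix Group-id prefix, e.g. `"SG"` for single-Y and `"MG"` for
#'   multi-Y groups.
#' @param shape_args Optional named list of threshold overrides passed to
#'   [label_shape()].
#' @return A tibble with columns `group_id`, `n_genes`, `genes`
#'   (list-column), `mean_profile` (list-column over the positive dose
#'   grid), `shape`, `cohesion`, plus attribute `doses`.
#' @export
profile_groups <- function(profiles, clustering, prefix = "G",
                           shape_args = list()) {
  assignment <- if (inherits(clustering, "profile_clustering")) {
    clustering$assignment
  } else {
    tibble::as_tibble(clustering)
  }
  m <- profiles_matrix(profiles)
  doses <- as.numeric(colnames(m))
  grp <- assignment |>
    dplyr::group_by(.data$group) |>
    dplyr::summarise(
      n_genes = dplyr::n(),
      genes = list(sort(.data$gene)),
      .groups = "drop"
    ) |>
    dplyr::arrange(.data$group)
  grp$mean_profile <- purrr::map(grp$genes, function(g) {
    colMeans(m[g, , drop = FALSE])
  })
  grp$shape <- purrr::map_chr(grp$mean_profile, function(mp) {
    do.call(label_shape, c(list(profile = as.numeric(mp), doses = doses), shape_args))
  })
  grp$cohesion <- purrr::map_dbl(grp$genes, function(g) {
    if (length(g) < 2L) return(NA_real_)
    cm <- suppressWarnings(stats::cor(t(m[g, , drop = FALSE])))
    mean(cm[upper.tri(cm)])
  })
  out <- grp |>
    dplyr::transmute(group_id = paste0(prefix, .data$group),
                     n_genes = .data$n_genes, genes = .data$genes,
                     mean_profile = .data$mean_profile,
                     shape = .data$shape, cohesion = .data$cohesion)
  attr(out, "doses") <- doses
  out
}

#' Merge single-Y and multi-Y profile groups into functional groups
#'
#' Every single-Y (SG) group seeds one functional group, in SG order.
#' Each multi-Y (MG) group is attached to the SG group whose mean profile
#' it correlates with best, provided that Pearson correlation reaches
#' `min_corr`; MG groups left unattached are compared, in order, against
#' the aggregate mean profile of every functional group formed so far and
#' join the best one above the same threshold, or else seed a new
#' functional group of their own.
#'
#' @param sg,mg Group tibbles from [profile_groups()] (either may be
#'   empty / zero-row).
#' @param min_corr Minimum Pearson correlation between mean profiles for
#'   a merge, default 0.8.
#' @return A tibble with columns `fg_id`, `group_id`, `n_genes`, `genes`,
#'   `shape` - one row per member profile group, functional groups
#'   numbered FG1.. in seed order.
#' @export
merge_functional_groups <- function(sg, mg, min_corr = 0.8) {
  fgs <- list()   # each: list(members = tibble rows, profiles = list of mean profiles)
  add_member <- function(fgs, i, row) {
    fgs[[i]]$members <- dplyr::bind_rows(fgs[[i]]$members, row)
    fgs[[i]]$profiles <- c(fgs[[i]]$profiles, row$mean_profile)
    fgs
  }
  for (i in seq_len(nrow(sg))) {
    fgs[[length(fgs) + 1L]] <- list(members = sg[i, ], profiles = sg$mean_profile[i])
  }
  unattached <- integer()
  for (j in seq_len(nrow(mg))) {
    if (nrow(sg) > 0L) {
      r <- vapply(sg$mean_profile, function(p) stats::cor(p, mg$mean_profile[[j]]), 0)
      best <- which.max(r)
      if (r[best] >= min_corr) {
        fgs <- add_member(fgs, best, mg[j, ])
        next
      }
    }
    unattached <- c(unattached, j)
  }
  for (j in unattached) {
    r <- vapply(fgs, function(fg) {
      agg <- colMeans(do.call(rbind, fg$profiles))
      stats::cor(agg, mg$mean_profile[[j]])
    }, 0)
    if (length(r) > 0L && max(r) >= min_corr) {
      fgs <- add_member(fgs, which.max(r), mg[j, ])
    } else {
      fgs[[length(fgs) + 1L]] <- list(members = mg[j, ], profiles = mg$mean_profile[j])
    }
  }
  purrr::imap_dfr(fgs, function(fg, i) {
    fg$members |>
      dplyr::transmute(fg_id = paste0("FG", i), group_id = .data$group_id,
                       n_genes = .data$n_genes, genes = .data$genes,
                       shape = .data$shape)
  })
}
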