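test_that("correlation distance behaves as 1 - Pearson r", {
  p <- c(0.1, 0.5, 1.0, 1.2, 1.3, 1.3, 1.3)
  expect_equal(correlation_distance(p, p), 0)
  expect_equal(correlation_distance(p, -p), 2)
  expect_equal(correlation_distance(1:7, 2 * (1:7)), 0)  # scale invariance
  expect_warning(d <- correlation_distance(p, rep(1, 7)), "zero-variance")
  expect_equal(d, 1)
  expect_error(correlation_distance(p, p[1:5]), class = "crpffl_domain_error")
  expect_error(correlation_distance(c(1, 2), c(2, 1)), class = "crpffl_domain_error")
})

test_that("two planted shape classes separate exactly at k = 2", {
  doses <- camp_dose_grid()[-1]
  up <- shape_curve("saturating_up", doses)
  down <- shape_curve("monotone_down", doses)
  prof <- tibble::tibble(
    gene = rep(c("u1", "u2", "d1", "d2"), each = 7),
    dose = rep(doses, 4),
    log2fc = c(up, up + 0.05, down, down - 0.05)
  )
  cl <- hierarchical_groups(prof, k = 2)
  got <- setNames(cl$assignment$group, cl$assignment$gene)
  expect_equal(got[["u1"]], got[["u2"]])
  expect_equal(got[["d1"]], got[["d2"]])
  expect_false(got[["u1"]] == got[["d1"]])

  # brute-force oracle: of all 7 bipartitions of 4 profiles, the returned
  # one minimises total within-group correlation distance
  m <- profiles_matrix(prof)
  dd <- as.matrix(correlation_distance(m))
  within <- function(split) {
    sum(dd[split, split][upper.tri(dd[split, split])]) +
      sum(dd[!split, !split][upper.tri(dd[!split, !split])])
  }
  splits <- lapply(1:7, function(i) as.logical(bitwAnd(i, 2^(0:3)) > 0))
  scores <- vapply(splits, within, 0)
  best <- splits[[which.min(scores)]]
  canon <- function(parts) unname(sort(vapply(parts, function(g)
    paste(sort(g), collapse = "+"), "")))
  expect_equal(canon(split(rownames(m), best)),
               canon(split(cl$assignment$gene, cl$assignment$group)))
})

test_that("k equal to the profile count yields singletons; bad k errors", {
  ge <- generate_expression(shape_counts = c(bell = 3, monotone_down = 3),
                            noise_sd = 0.05, seed = 4)
  prof <- compute_profiles(ge$expr)
  cl <- hierarchical_groups(prof, k = 6)
  expect_equal(sort(table(cl$assignment$group)), sort(table(1:6)),
               ignore_attr = TRUE)
  expect_error(hierarchical_groups(prof, k = 7), class = "crpffl_domain_error")
})

test_that("grouping is invariant to input permutation and labels by size", {
  ge <- generate_expression(shape_counts = c(saturating_up = 6, bell = 3,
                                             inverse_bell = 2),
                            noise_sd = 0.05, seed = 8)
  prof <- compute_profiles(ge$expr)
  cl1 <- hierarchical_groups(prof, k = 3)
  set.seed(1)
  perm <- prof[sample(nrow(prof)), ]
  cl2 <- hierarchical_groups(perm, k = 3)
  expect_identical(cl1$assignment, cl2$assignment)
  sizes <- as.integer(table(cl1$assignment$group))
  expect_true(all(diff(sizes) <= 0))  # group 1 is the largest
})

test_that("planted five-shape profiles are recovered with high agreement", {
  aris <- vapply(1:5, function(seed) {
    ge <- generate_expression(amplitude = 2, noise_sd = 0.1, seed = seed)
    prof <- compute_profiles(ge$expr)
    cl <- hierarchical_groups(prof, k = 5)
    lab <- dplyr::inner_join(cl$assignment, ge$truth, by = "gene")
    mclust::adjustedRandIndex(lab$group, lab$shape)
  }, 0)
  expect_true(mean(aris) >= 0.9)
})

test_that("canonical shape rules fire on their archetypes and not the edges", {
  doses <- camp_dose_grid()[-1]
  expect_equal(label_shape(c(0.1, 0.4, 1.2, 1.6, 1.8, 1.8, 1.8), doses),
               "saturating_up")
  expect_equal(label_shape(c(0.0, 0.3, 1.5, 2.0, 0.6, 0.1, 0.0), doses), "bell")
  expect_equal(label_shape(rep(0, 7), doses), "unclassified")
  for (s in c("saturating_up", "sigmoid_threshold", "monotone_down",
              "bell", "inverse_bell")) {
    expect_equal(label_shape(shape_curve(s, doses), doses), s)
    # relative rules are invariant to an additive offset
    expect_equal(label_shape(shape_curve(s, doses) + 3, doses), s)
  }
})

test_that("group summaries carry mean profiles, shapes and cohesion", {
  ge <- generate_expression(noise_sd = 0.05, seed = 10)
  prof <- compute_profiles(ge$expr)
  cl <- hierarchical_groups(prof, k = 5)
  pg <- profile_groups(prof, cl, prefix = "SG")
  expect_equal(sum(pg$n_genes), 40L)
  expect_setequal(pg$shape, unique(ge$truth$shape))
  expect_true(all(pg$cohesion > 0.95))
  expect_equal(lengths(pg$mean_profile), rep(7L, 5L), ignore_attr = TRUE)
})

test_that("functional-group merging pairs groups by shape and isolates outliers", {
  doses <- camp_dose_grid()[-1]
  shapes <- c("saturating_up", "sigmoid_threshold", "monotone_down",
              "bell", "inverse_bell")
  mk <- function(prefix, jitter) {
    tibble::tibble(
      group_id = paste0(prefix, seq_along(shapes)),
      n_genes = 2L,
      genes = lapply(seq_along(shapes), function(i) paste0(prefix, i, "_g")),
      mean_profile = lapply(shapes, function(s) shape_curve(s, doses) + jitter),
      shape = shapes
    )
  }
  sg <- mk("SG", 0)
  mg <- mk("MG", 0.01)
  fg <- merge_functional_groups(sg, mg)
  expect_equal(dplyr::n_distinct(fg$fg_id), 5L)
  by_fg <- split(fg$shape, fg$fg_id)
  expect_true(all(vapply(by_fg, function(s) length(unique(s)) == 1L, TRUE)))

  # an anticorrelated MG group cannot attach anywhere and seeds its own FG
  lone_mg <- mk("MG", 0)[4, ]  # bell
  only_up_sg <- mk("SG", 0)[1, ]  # saturating
  fg2 <- merge_functional_groups(only_up_sg, lone_mg)
  expect_equal(dplyr::n_distinct(fg2$fg_id), 2L)
  # a single SG group with no MG groups forms exactly one FG
  fg3 <- merge_functional_groups(only_up_sg, mk("MG", 0)[0, ])
  expect_equal(fg3$fg_id, "FG1")
})
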