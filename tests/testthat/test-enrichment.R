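test_that("annotations propagate to every ancestor and the closure is idempotent", {
  ann <- tibble::tibble(gene = "g1", term = "a")
  parents <- tibble::tibble(term = c("a", "b"), parent = c("b", "c"))
  closed <- propagate_annotations(ann, parents)
  expect_setequal(closed$term, c("a", "b", "c"))  # two-level chain
  expect_identical(propagate_annotations(closed, parents), closed)
  # no parent table: identity (up to de-duplication)
  expect_identical(propagate_annotations(ann, NULL), ann)
  # cycles are rejected, naming a member
  loop <- tibble::tibble(term = c("a", "b"), parent = c("b", "a"))
  expect_error(propagate_annotations(ann, loop), "cycle",
               class = "crpffl_input_error")
})

test_that("upper-tail hypergeometric probabilities match exact combinatorics", {
  expect_equal(hypergeometric_p(0, 10, 5, 50), 1)
  expect_equal(hypergeometric_p(5, 5, 5, 20), 1 / choose(20, 5))
  expect_equal(hypergeometric_p(2, 2, 5, 10), choose(5, 2) / choose(10, 2))
  expect_error(hypergeometric_p(6, 5, 5, 20), class = "crpffl_domain_error")
  expect_error(hypergeometric_p(1, 5, 21, 20), class = "crpffl_domain_error")
})

test_that("the hypergeometric mass sums to one and the tail is monotone in k", {
  for (margins in list(c(n = 5, K = 7, N = 12), c(n = 10, K = 3, N = 30))) {
    n <- margins[["n"]]; K <- margins[["K"]]; N <- margins[["N"]]
    ks <- max(0, n + K - N):min(n, K)
    mass <- vapply(ks, function(k) {
      choose(K, k) * choose(N - K, n - k) / choose(N, n)
    }, 0)
    expect_equal(sum(mass), 1)
    tail <- vapply(ks, hypergeometric_p, 0, n = n, K = K, N = N)
    expect_true(all(diff(tail) < 0))
  }
})

test_that("the tail probability equals the one-sided exact test on the same margins", {
  set.seed(99)
  for (i in 1:50) {
    N <- sample(5:60, 1)
    K <- sample(0:N, 1)
    n <- sample(0:N, 1)
    ks <- max(0, n + K - N):min(n, K)
    k <- ks[sample.int(length(ks), 1)]
    p_fisher <- stats::fisher.test(
      matrix(c(k, K - k, n - k, N - K - (n - k)), nrow = 2),
      alternative = "greater")$p.value
    expect_equal(hypergeometric_p(k, n, K, N), p_fisher, tolerance = 1e-12)
  }
})

test_that("group enrichment ranks a fully-planted term first at its exact p", {
  universe <- sprintf("g%02d", 1:20)
  carriers <- universe[1:10]
  ann <- dplyr::bind_rows(
    tibble::tibble(gene = carriers, term = "T_hit"),
    tibble::tibble(gene = universe[c(1:5, 11:13)], term = "T_bg")
  )
  res <- enrich_group(carriers, universe, ann)
  expect_equal(res$term[1], "T_hit")
  expect_equal(res$p_value[1], 1 / choose(20, 10))
  expect_true(res$significant[1])
  expect_lt(res$p_value[1], res$p_value[2])
  # n and N count unannotated genes too
  expect_equal(res$n[1], 10L)
  expect_equal(res$N[1], 20L)
  # empty study set and stray genes
  expect_equal(nrow(enrich_group(character(), universe, ann)), 0L)
  expect_error(enrich_group("nope", universe, ann), "nope",
               class = "crpffl_input_error")
})

test_that("namespace filtering and p adjustment switches behave", {
  universe <- sprintf("g%02d", 1:10)
  ann <- tibble::tibble(gene = rep(universe[1:4], 2),
                        term = rep(c("bp", "mf"), each = 4),
                        namespace = rep(c("biological_process",
                                          "molecular_function"), each = 4))
  res <- enrich_group(universe[1:4], universe, ann)
  expect_equal(res$term, "bp")
  res_all <- enrich_group(universe[1:4], universe, ann, namespace = NULL)
  expect_setequal(res_all$term, c("bp", "mf"))
  bon <- enrich_group(universe[1:4], universe, ann, namespace = NULL,
                      adjust = "bonferroni", max_p = 0.01)
  expect_equal(bon$significant, bon$p_value * 2 <= 0.01)
})

test_that("a term planted at five-fold background is detected reliably", {
  universe <- sprintf("g%03d", 1:500)
  groups <- tibble::tibble(gene = universe[1:20], group = "G1")
  hits <- vapply(1:10, function(seed) {
    ga <- generate_annotations(groups, universe, enrich_factor = 5,
                               background_rate = 0.1, seed = seed)
    res <- enrich_group(groups$gene, universe, ga$annotations)
    tm <- ga$planted$term[ga$planted$group == "G1"]
    isTRUE(res$significant[res$term == tm])
  }, TRUE)
  expect_gte(mean(hits), 0.9)
})
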