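test_that("the eight sign triples map to their canonical type labels", {
  expect_equal(classify_ffl(1, 1, 1), "Coh1")
  expect_equal(classify_ffl(-1, 1, -1), "Coh2")   # CRP represses gadX and gadA
  expect_equal(classify_ffl(1, -1, 1), "InCoh1")  # direct + against indirect -
  # full table: label's coherence always equals the sign-product predicate
  grid <- expand.grid(sxy = c(-1, 1), syz = c(-1, 1), sxz = c(-1, 1))
  types <- classify_ffl(grid$sxy, grid$syz, grid$sxz)
  expect_setequal(types, ffl_types()$type)
  expect_equal(startsWith(types, "Coh"), grid$sxz == grid$sxy * grid$syz)
  expect_error(classify_ffl(0, 1, 1), class = "crpffl_domain_error")
})

test_that("a minimal all-activation triangle yields one single-Y Coh1", {
  ints <- tibble::tibble(regulator = c("A", "B", "A"),
                         target = c("B", "C", "C"),
                         effect = "activation")
  net <- build_network(ints, tf_set = c("A", "B"))
  cen <- enumerate_ffls(net, master = "A", tf_set = "B")
  expect_equal(nrow(cen$instances), 1L)
  expect_equal(cen$instances$type, "Coh1")
  expect_equal(cen$instances$arity_class, "single")
  expect_error(enumerate_ffls(net, master = "Q"), class = "crpffl_input_error")
})

test_that("a target co-regulated by two TFs forms two multi-Y loops", {
  # the gadA situation: CRP represses gadX and gadA, GadX activates gadA
  # (Coh2), CRP represses fis which represses gadA (InCoh2)
  ints <- tibble::tibble(
    regulator = c("crp", "gadX", "crp", "crp", "fis"),
    target    = c("gadX", "gadA", "gadA", "fis", "gadA"),
    effect    = c("repression", "activation", "repression", "repression",
                  "repression")
  )
  net <- build_network(ints, tf_set = c("crp", "gadX", "fis"))
  cen <- enumerate_ffls(net, master = "crp")
  expect_equal(nrow(cen$instances), 2L)
  expect_setequal(cen$instances$type, c("Coh2", "InCoh2"))
  expect_true(all(cen$instances$arity_class == "multi"))
  expect_true(all(cen$instances$z == "gada"))
})

test_that("enumeration matches brute-force triple enumeration on random networks", {
  for (seed in 1:10) {
    rn <- random_signed_network(n_nodes = 10 + 3 * seed,
                                n_edges = 30 + 10 * seed, seed = seed)
    got <- enumerate_ffls(rn$net, rn$master, rn$tf_set)$instances
    want <- brute_force_ffls(rn$net, rn$master, rn$tf_set)
    expect_equal(nrow(got), nrow(want))
    cols <- c("x", "y", "z", "sign_xy", "sign_yz", "sign_xz", "type")
    expect_equal(as.data.frame(got[cols]),
                 as.data.frame(want[cols]), ignore_attr = TRUE)
  }
})

test_that("arity partitions the census and reacts to edge removal", {
  gn <- generate_network(c(Coh1 = 6, InCoh2 = 4), n_decoys = 10,
                         multi_y_fraction = 0.6, seed = 2)
  cen <- enumerate_ffls(gn$network, "crp", gn$tf_set)
  inst <- cen$instances
  expect_equal(sum(inst$arity_class == "single") +
                 sum(inst$arity_class == "multi"), nrow(inst))
  two_tf <- inst$z[inst$n_y == 2][1]
  expect_false(is.na(two_tf))  # seed chosen so a two-TF target exists
  drop_y <- inst$y[inst$z == two_tf][1]
  pruned <- gn$interactions[!(gn$interactions$regulator == drop_y &
                                gn$interactions$target == two_tf), ]
  cen2 <- enumerate_ffls(build_network(pruned, tf_set = gn$tf_set),
                         "crp", gn$tf_set)
  left <- cen2$instances[cen2$instances$z == two_tf, ]
  expect_equal(nrow(left), 1L)
  expect_equal(left$arity_class, "single")
})

test_that("multi-output grouping reports exactly the (x, y) pairs with >= 2 targets", {
  inst <- tibble::tibble(x = "A", y = c("B", "B", "C"),
                         z = c("c1", "c2", "c3"), type = "Coh1")
  mo <- multi_output_groups(inst)
  expect_equal(nrow(mo), 1L)
  expect_equal(mo$targets[[1]], c("c1", "c2"))
  expect_equal(nrow(multi_output_groups(inst[1, ])), 0L)
  # tally oracle on a generated census
  gn <- generate_network(c(Coh1 = 8, Coh4 = 5), multi_y_fraction = 0.5, seed = 9)
  cen <- enumerate_ffls(gn$network, "crp", gn$tf_set)
  mo2 <- multi_output_groups(cen)
  tally <- table(paste(cen$instances$x, cen$instances$y))
  expect_true(all(mo2$n_targets == tally[paste(mo2$x, mo2$y)]))
  not_multi <- setdiff(names(tally), paste(mo2$x, mo2$y))
  expect_true(all(tally[not_multi] < 2))
})

test_that("census summaries tally instances and distinct genes per type", {
  fx <- read_crp_census()
  summ <- census_summary(dplyr::rename(fx, z = gene))
  expect_equal(summ$n_ffl[summ$type == "Coh3"], 2L)
  expect_equal(summ$n_gene[summ$type == "Coh3"], 2L)
  expect_equal(summ$n_ffl[summ$type == "Coh2"], 15L)
  expect_equal(summ$n_gene[summ$type == "Coh2"], 10L)
  expect_equal(sum(summ$n_ffl), 202L)
  empty <- census_summary(tibble::tibble(type = character(), z = character()))
  expect_equal(nrow(empty), 0L)
})

test_that("tidy and glance expose the instance table and overall counts", {
  gn <- generate_network(c(Coh1 = 3, InCoh1 = 2), seed = 5)
  cen <- enumerate_ffls(gn$network, "crp", gn$tf_set)
  expect_identical(tidy(cen), cen$instances)
  g <- glance(cen)
  expect_equal(g$n_ffl, 5L)
  expect_equal(g$n_sffl + g$n_mffl, 5L)
})
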