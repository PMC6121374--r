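# Independent oracles and small fixture builders used across the suite.

# Exhaustive triple enumeration over (y, z): the brute-force reference for
# enumerate_ffls().  Deliberately written against its own inline sign
# table and plain loops so it shares no code with the implementation.
brute_force_ffls <- function(net, master, tf_set) {
  sign_lut <- list(
    "1 1 1" = "Coh1",   "-1 1 -1" = "Coh2", "1 -1 -1" = "Coh3",
    "-1 -1 1" = "Coh4", "1 -1 1" = "InCoh1", "-1 -1 -1" = "InCoh2",
    "1 1 -1" = "InCoh3", "-1 1 1" = "InCoh4"
  )
  ed <- net$edges
  lookup <- function(u, v) {
    i <- which(ed$regulator == u & ed$target == v)
    if (length(i) == 1L) ed$sign[i] else NA_integer_
  }
  master <- tolower(master)
  tfs <- setdiff(tolower(tf_set), master)
  nodes <- net$nodes$id
  rows <- list()
  for (y in tfs) {
    sxy <- lookup(master, y)
    if (is.na(sxy)) next
    for (z in nodes) {
      if (z == y || z == master) next
      syz <- lookup(y, z)
      if (is.na(syz)) next
      sxz <- lookup(master, z)
      if (is.na(sxz)) next
      rows[[length(rows) + 1L]] <- data.frame(
        x = master, y = y, z = z, sign_xy = sxy, sign_yz = syz, sign_xz = sxz,
        type = sign_lut[[paste(sxy, syz, sxz)]]
      )
    }
  }
  if (length(rows) == 0L) {
    return(data.frame(x = character(), y = character(), z = character(),
                      sign_xy = integer(), sign_yz = integer(),
                      sign_xz = integer(), type = character()))
  }
  out <- do.call(rbind, rows)
  out[order(out$type, out$z, out$y), , drop = FALSE]
}

# random signed interaction table + matching network, for oracle stress tests
random_signed_network <- function(n_nodes, n_edges, seed, master = "x0") {
  set.seed(seed)
  nodes <- c(master, sprintf("n%02d", seq_len(n_nodes - 1L)))
  tf_set <- c(master, sample(nodes[-1], max(2L, floor(n_nodes / 3))))
  pairs <- expand.grid(regulator = nodes, target = nodes,
                       stringsAsFactors = FALSE)
  pairs <- pairs[pairs$regulator != pairs$target, ]
  pairs <- pairs[pairs$regulator %in% tf_set, ]
  take <- pairs[sample(nrow(pairs), min(n_edges, nrow(pairs))), ]
  ints <- tibble::tibble(
    regulator = take$regulator, target = take$target,
    effect = sample(c("activation", "repression"), nrow(take), replace = TRUE)
  )
  list(net = build_network(ints, tf_set = tf_set), master = master,
       tf_set = tf_set)
}

# write a tiny interaction TSV and return its path
write_interactions_file <- function(lines, dir = withr::local_tempdir(.local_envir = parent.frame())) {
  path <- file.path(dir, "interactions.tsv")
  writeLines(lines, path)
  path
}

# small wide expression file on the cAMP grid: values[[gene]] is a named
# list dose -> replicate vector
write_expression_file <- function(values, dir = withr::local_tempdir(.local_envir = parent.frame()),
                                  doses = camp_dose_grid(), reps = 2) {
  header <- c("gene", unlist(lapply(doses, function(d) paste0(d, "mM_r", seq_len(reps)))))
  rows <- vapply(names(values), function(g) {
    paste(c(g, unlist(values[[g]])), collapse = "\t")
  }, "")
  path <- file.path(dir, "expr.tsv")
  writeLines(c(paste(header, collapse = "\t"), rows), path)
  path
}
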