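test_that("local alignment scores match hand-derived values", {
  expect_equal(align_pair_score("AA", "AA"), 8)   # two A:A matches at +4
  expect_equal(align_pair_score("A", "C"), 0)     # local floor at zero
  # self-alignment equals the sum of diagonal substitution values
  m <- linker_submat()
  for (s in c("MKTAY", "GGSSTT", "WLDNQ")) {
    ch <- strsplit(s, "")[[1]]
    expect_equal(align_pair_score(s, s), sum(diag(m[ch, ch])))
  }
})

test_that("alignment engine agrees with the exhaustive Gotoh oracle", {
  m <- linker_submat()
  alpha <- c("A", "G", "S", "W")
  # all unordered pairs of sequences up to length 3 over a 4-letter alphabet
  seqs <- unlist(lapply(1:3, function(L) {
    apply(do.call(expand.grid, rep(list(alpha), L)), 1, paste, collapse = "")
  }))
  combos <- utils::combn(length(seqs), 2)
  # sampling the pair grid keeps the suite fast; seeded for reproducibility
  set.seed(404)
  pick <- sample(ncol(combos), 600)
  for (k in pick) {
    a <- seqs[combos[1, k]]; b <- seqs[combos[2, k]]
    expect_equal(align_pair_score(a, b), oracle_local_score(a, b, m),
                 info = paste(a, b))
  }
  # longer sequences (4-6) where affine gaps actually matter
  for (i in 1:150) {
    a <- paste(sample(alpha, sample(4:6, 1), replace = TRUE), collapse = "")
    b <- paste(sample(alpha, sample(4:6, 1), replace = TRUE), collapse = "")
    expect_equal(align_pair_score(a, b), oracle_local_score(a, b, m),
                 info = paste(a, b))
  }
})

test_that("alignment score is symmetric", {
  set.seed(7)
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  for (i in 1:50) {
    a <- paste(sample(aa, 12, replace = TRUE), collapse = "")
    b <- paste(sample(aa, 15, replace = TRUE), collapse = "")
    expect_equal(align_pair_score(a, b), align_pair_score(b, a))
  }
})

test_that("E-value follows the Karlin-Altschul closed form", {
  # bit score 30 over a 100x100 search space
  raw <- (30 * log(2) + log(0.041)) / 0.267
  ev <- evalue(raw, 100, 100)
  expect_equal(ev$bit_score, 30, tolerance = 1e-12)
  expect_equal(ev$e_value, 1e4 * 2^-30, tolerance = 1e-12)
  # raw score 0 floors at E >= m*n*K
  ev0 <- evalue(0, 50, 80)
  expect_gte(ev0$e_value, 50 * 80 * 0.041 - 1e-9)
  # doubling both lengths quadruples E at fixed bit score
  expect_equal(evalue(raw, 200, 200)$e_value, 4 * ev$e_value)
  expect_error(evalue(-1, 10, 10), ">= 0")
})

test_that("identical linkers form an edge and a group; threshold 0 kills all edges", {
  lk <- seq_set(id = c("a", "b"),
                seq = rep(strrep("GSTANDKE", 5), 2))
  net <- build_network_and_group(lk, min_group_size = 2)
  expect_true(all(net$edges$edge))
  expect_equal(net$groups$group, c(1L, 1L))

  net0 <- build_network_and_group(lk, threshold = 0, min_group_size = 2)
  expect_true(all(is.na(net0$groups$group)))
  expect_error(build_network_and_group(lk[1, ]), "at least two")
})

test_that("synthetic templates are recovered as separate groups", {
  fam <- gen_linker_families(n_per_group = 10, groups = c(1, 3, 6), seed = 31)
  ext <- extract_linkers(fam$records)
  net <- build_network_and_group(ext$linkers, min_group_size = 2)
  g <- net$groups
  truth <- fam$truth$group[match(g$id, fam$truth$id)]
  expect_equal(length(unique(na.omit(g$group))), 3L)
  # each recovered group maps to exactly one template and vice versa
  tab <- table(truth, g$group)
  expect_true(all(rowSums(tab > 0) == 1))
  expect_true(all(colSums(tab > 0) == 1))
})

test_that("component grouping equals union-find on random graphs", {
  set.seed(1234)
  for (rep in 1:40) {
    n <- sample(5:40, 1)
    ids <- sprintf("n%02d", seq_len(n))
    n_edges <- sample(0:(2 * n), 1)
    ei <- sample(ids, n_edges, replace = TRUE)
    ej <- sample(ids, n_edges, replace = TRUE)
    keep <- ei != ej
    ei <- ei[keep]; ej <- ej[keep]
    got <- group_components(ids, data.frame(id_i = ei, id_j = ej),
                            min_group_size = 1L)
    want <- oracle_components(ids, ei, ej)
    # same partition up to relabelling
    expect_equal(unname(table(got$component)[as.character(got$component)]),
                 unname(table(want)[as.character(want)]))
    same_got <- outer(got$component, got$component, "==")
    same_want <- outer(want, want, "==")
    expect_true(all(same_got == same_want))
  }
})

test_that("raising the threshold only coarsens the grouping", {
  fam <- gen_linker_families(n_per_group = 6, sub_rate = 0.05, seed = 77)
  ext <- extract_linkers(fam$records)
  net <- build_network_and_group(ext$linkers, min_group_size = 1)
  sweep <- threshold_sweep(net, c(1e-40, 1e-25, 1e-10, 1e-3, 1),
                           min_group_size = 1)
  for (k in seq_len(length(sweep) - 1)) {
    fine <- sweep[[k]]$component
    coarse <- sweep[[k + 1]]$component
    # nodes together at the finer threshold stay together at the coarser one
    together_fine <- outer(fine, fine, "==")
    together_coarse <- outer(coarse, coarse, "==")
    expect_true(all(together_coarse[together_fine]))
  }
})
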