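test_that("edits validate against wild-type numbering and apply atomically", {
  wt <- cdh_reference()$record
  ss <- apply_variant(wt, list(edit_substitute(218, "I", "C"),
                               edit_substitute(459, "N", "C")), "LNK_S=S")
  expect_equal(ss$length, nchar(wt$seq))
  expect_equal(substr(ss$sequence, 218, 218), "C")
  expect_equal(substr(ss$sequence, 459, 459), "C")

  ins <- apply_variant(wt, list(edit_insert(216, "ATAT")), "LNK+4")
  expect_equal(ins$length, nchar(wt$seq) + 4L)
  expect_equal(substr(ins$sequence, 217, 220), "ATAT")
  # downstream coordinates shift by +4
  expect_equal(ins$coord_map[218], 222L)
  expect_equal(substr(ins$sequence, 222, 222), "I")

  del <- apply_variant(wt, list(edit_delete(215)), "LNK-1")
  expect_equal(del$coord_map[216], 215L)
  expect_true(is.na(del$coord_map[215]))

  expect_error(apply_variant(wt, list(edit_substitute(218, "M", "C"))),
               "expects wild-type M")
  expect_error(apply_variant(wt, list(edit_delete(215, 216),
                                      edit_substitute(216, "T", "A"))),
               "overlapping")
})

test_that("theoretical mass uses average residue masses plus one water", {
  expect_equal(theoretical_mw("G"), 75.07, tolerance = 1e-3)
  expect_equal(theoretical_mw("GG"), 132.12, tolerance = 1e-3)
  expect_error(theoretical_mw(""), "empty")
  expect_error(theoretical_mw("GXG"), "non-canonical")
})

test_that("the built-in catalog reproduces all seven variants and round-trips", {
  wt <- cdh_reference()$record
  results <- apply_variant_catalog(wt)
  expect_setequal(names(results),
                  c("LNK-1", "LNK-2", "LNK-4", "LNK+4", "LNK+8",
                    "LNK_S=S", "LNK_S=S+4"))
  n <- nchar(wt$seq)
  expect_equal(results[["LNK-1"]]$length, n - 1L)
  expect_equal(results[["LNK-2"]]$length, n - 2L)
  expect_equal(results[["LNK-4"]]$length, n - 4L)
  expect_equal(results[["LNK+4"]]$length, n + 4L)
  expect_equal(results[["LNK+8"]]$length, n + 8L)
  expect_equal(results[["LNK_S=S"]]$length, n)
  expect_equal(results[["LNK_S=S+4"]]$length, n + 4L)

  for (res in results) {
    # reversing the edits reconstructs the wild type exactly
    expect_equal(invert_variant(res)$sequence, wt$seq, info = res$name)
    # mass delta equals the signed residue-mass sum of the edits
    delta <- 0
    for (op in res$ops) {
      delta <- delta + switch(op$type,
        insert = theoretical_mw(op$residues) - 18.0153,
        delete = -(theoretical_mw(substr(wt$seq, op$start, op$end)) - 18.0153),
        substitute = theoretical_mw(op$to) - theoretical_mw(op$from))
    }
    expect_equal(res$theoretical_mass - theoretical_mw(wt$seq), delta,
                 tolerance = 1e-9, info = res$name)
  }
})

test_that("disulfide screening ranks cross-region Calpha pairs by distance", {
  m <- toy_model(rbind(c(0, 0, 0), c(0, 0, 5.5)), resno = c(1L, 10L))
  hit <- design_disulfide_pairs(m, c(1, 1), c(10, 10), cutoff = 7)
  expect_equal(nrow(hit), 1L)
  expect_equal(hit$distance, 5.5)
  expect_equal(c(hit$res_a, hit$res_b), c(1L, 10L))
  expect_equal(nrow(design_disulfide_pairs(m, c(1, 1), c(10, 10), cutoff = 5)),
               0L)
  expect_error(design_disulfide_pairs(m, c(2, 3), c(10, 10)), "no Calpha")

  # planted contact in the synthetic closed-state structure: 218 to 459
  s <- gen_cdh_structure(seed = 5)
  dd <- design_disulfide_pairs(s, c(208, 231), c(455, 465))
  expect_true(any(dd$res_a == 218 & dd$res_b == 459))
  expect_true(all(diff(dd$distance) >= 0))
})
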