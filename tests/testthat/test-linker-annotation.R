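test_that("end-motif search returns the first [YF]DY start in the window", {
  expect_equal(find_end_motif("ACYDYAC", 1, 7), c(3L, 5L))
  expect_equal(find_end_motif("ACFDYAC", 1, 7), c(3L, 5L))   # Phe variant
  expect_null(find_end_motif("ACDDYAC", 1, 7))
  # first occurrence wins; window can exclude it
  expect_equal(find_end_motif("YDYAAYDY", 1, 8), c(1L, 3L))
  expect_equal(find_end_motif("YDYAAYDY", 2, 8), c(6L, 8L))
  expect_error(find_end_motif("YDY", 2, 9), "invalid search window")
})

test_that("anchor maps through the reference alignment, with indel shifts", {
  ref <- cdh_reference()
  # identity: anchor unchanged
  hit <- locate_anchor_by_reference(ref$record$seq, ref)
  expect_equal(hit$anchor, ref$annotation$cyt_anchor)
  # deleting one residue upstream shifts the anchor by -1
  del <- paste0(substr(ref$record$seq, 1, 49),
                substr(ref$record$seq, 51, nchar(ref$record$seq)))
  expect_equal(locate_anchor_by_reference(del, ref)$anchor,
               ref$annotation$cyt_anchor - 1L)
  # inserting five residues upstream shifts it by +5
  ins <- paste0(substr(ref$record$seq, 1, 50), "GGGGG",
                substr(ref$record$seq, 51, nchar(ref$record$seq)))
  expect_equal(locate_anchor_by_reference(ins, ref)$anchor,
               ref$annotation$cyt_anchor + 5L)
  # no Tyr anywhere: anchor not found
  expect_true(is.na(locate_anchor_by_reference(
    strrep("A", 300), ref)$anchor))
})

test_that("annotation recovers planted segment architecture exactly", {
  fam <- gen_linker_families(n_per_group = 4, seed = 11)
  for (i in seq_len(nrow(fam$records))) {
    ann <- annotate_linker(fam$records[i, ])
    tr <- fam$truth[i, ]
    expect_equal(ann$status, "ok")
    expect_equal(ann$cyt_anchor, tr$anchor)
    expect_equal(ann$linker_span, c(tr$linker_start, tr$linker_end))
    expect_equal(ann$n_attached_span, c(tr$n_attached_start, tr$n_attached_end))
    expect_equal(ann$mobile_span, c(tr$mobile_start, tr$mobile_end))
    expect_equal(ann$c_attached_span, c(tr$c_attached_start, tr$c_attached_end))
    expect_equal(ann$dh_attachment$type, tr$dh_type)
  }
})

test_that("segment spans always partition the linker span", {
  fam <- gen_linker_families(n_per_group = 8, sub_rate = 0.05,
                             indel_rate = 0.05, seed = 23)
  anns <- extract_linkers(fam$records)$annotations
  for (ann in anns) {
    if (ann$status != "ok") next
    expect_equal(ann$n_attached_span[1], ann$linker_span[1])
    expect_equal(ann$c_attached_span[2], ann$linker_span[2])
    expect_equal(ann$mobile_span[1], ann$n_attached_span[2] + 1L)
    expect_equal(ann$c_attached_span[1], ann$mobile_span[2] + 1L)
    expect_true(ann$n_attached_span[2] < ann$mobile_span[1])
    expect_true(ann$mobile_span[2] < ann$c_attached_span[1])
  }
})

test_that("annotation failures are encoded in status, not thrown", {
  ref <- cdh_reference()
  # removing the end motif (Y229 and Y231 -> A) leaves no [YF]DY in window
  ch <- strsplit(ref$record$seq, "")[[1]]
  ch[c(229, 231)] <- "A"
  ann <- annotate_linker(paste(ch, collapse = ""))
  expect_equal(ann$status, "failed")
  expect_match(ann$reason, "end motif not found")
})

test_that("linker extraction deduplicates exact repeats and keeps failures", {
  fam <- gen_linker_families(n_per_group = 3, seed = 2)
  recs <- fam$records
  dup <- recs[1, ]; dup$id <- "dup_of_first"
  recs <- rbind(recs, dup)
  ext <- extract_linkers(recs)
  expect_true("dup_of_first" %in% ext$duplicates ||
                sum(ext$linkers$id == "dup_of_first") == 0)
  expect_lte(nrow(ext$linkers), nrow(recs))
  expect_equal(nrow(ext$failed), 0L)
  # empty input yields empty output
  ext0 <- extract_linkers(seq_set())
  expect_equal(nrow(ext0$linkers), 0L)
})
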