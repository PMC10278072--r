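test_that("generators are deterministic given the seed", {
  a <- gen_linker_families(n_per_group = 3, sub_rate = 0.05,
                           indel_rate = 0.05, seed = 99)
  b <- gen_linker_families(n_per_group = 3, sub_rate = 0.05,
                           indel_rate = 0.05, seed = 99)
  expect_identical(a, b)
  c <- gen_linker_families(n_per_group = 3, sub_rate = 0.05, seed = 100)
  expect_false(identical(a$records$seq, c$records$seq))

  p1 <- gen_pull_series(noise_sd = 0.3, seed = 4)
  p2 <- gen_pull_series(noise_sd = 0.3, seed = 4)
  expect_identical(p1, p2)

  t1 <- gen_exponential_trace(k = 3, noise_sd = 0.001, seed = 6)
  t2 <- gen_exponential_trace(k = 3, noise_sd = 0.001, seed = 6)
  expect_identical(t1, t2)
})

test_that("generated families annotate cleanly and round-trip through FASTA", {
  fam <- gen_linker_families(n_per_group = 2, seed = 13)
  expect_equal(nrow(fam$records), 12L)
  expect_equal(nrow(fam$truth), 12L)
  p <- withr::local_tempfile(fileext = ".fasta")
  tp <- withr::local_tempfile(fileext = ".tsv")
  fam2 <- gen_linker_families(n_per_group = 2, seed = 13, fasta_path = p,
                              truth_path = tp)
  expect_equal(read_fasta(p)$seq, fam$records$seq)
  expect_equal(read.table(tp, header = TRUE, sep = "\t")$anchor,
               fam$truth$anchor)
  expect_error(gen_linker_families(sub_rate = 0.5), "0.2")
})

test_that("motif protection holds at high substitution rates but not in hostile mode", {
  fam <- gen_linker_families(n_per_group = 10, sub_rate = 0.2, seed = 21)
  ch_at <- function(seq, pos) substr(seq, pos, pos)
  for (i in seq_len(nrow(fam$records))) {
    s <- fam$records$seq[i]; tr <- fam$truth[i, ]
    expect_equal(ch_at(s, tr$anchor), "Y")
    expect_match(substr(s, tr$c_attached_end - 2, tr$c_attached_end),
                 "^[YF]DY$")
    if (!is.na(tr$cyt_cys)) expect_equal(ch_at(s, tr$cyt_cys), "C")
  }
  hostile <- gen_linker_families(n_per_group = 10, sub_rate = 0.2,
                                 seed = 21, hostile = TRUE)
  broken <- vapply(seq_len(nrow(hostile$records)), function(i) {
    tr <- hostile$truth[i, ]
    ch_at(hostile$records$seq[i], tr$anchor) != "Y"
  }, TRUE)
  expect_true(any(broken))
})

test_that("pull-series truth records the analytic crossing", {
  gen <- gen_pull_series(d0 = 40, cog_rate = 0.05, distortion_start = 5,
                         distortion_rate = 0.01, n_frames = 1500, seed = 1)
  # 5 + 0.01 t >= 11 first at t = 600, i.e. frame 601
  expect_equal(gen$truth$true_crossing_time, 600)
  expect_equal(gen$truth$true_crossing_frame, 601L)
  never <- gen_pull_series(distortion_rate = 0, n_frames = 300, seed = 2)
  expect_true(is.na(never$truth$true_crossing_frame))
  expect_error(gen_pull_series(n_frames = 100), "201")
})

test_that("noisy crossing detection stays within half a smoothing window", {
  hits <- vapply(1:50, function(s) {
    gen <- gen_pull_series(noise_sd = 0.3, n_frames = 1500, seed = s)
    pa <- analyze_pull(gen$frames)
    abs(pa$crossing_frame - gen$truth$true_crossing_frame)
  }, 1.0)
  expect_gte(mean(hits <= 50), 0.95)
})

test_that("synthetic structure plants the documented geometry", {
  s <- gen_cdh_structure(seed = 8)
  expect_equal(nrow(s), 810L)
  expect_equal(sort(unique(s$residue_number)), 1:810)
  d <- domain_cog_distance(s, domain_selection(c(1, 194)),
                           domain_selection(c(232, 810)))
  expect_equal(d, 35.6, tolerance = 1e-9)
  expect_equal(residue_pair_distance(s, 218, 459), 5.5, tolerance = 1e-9)
  # residue names follow the synthetic reference sequence
  expect_equal(s$residue_name[s$residue_number == 195], "TYR")
  expect_equal(s$residue_name[s$residue_number == 211], "CYS")
})
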