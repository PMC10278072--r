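# Seeded synthetic-data generators.
#
# Every generator emits the ground truth next to the data, so each analysis
# stage can be benchmarked without external downloads. Sequence families
# emulate the architecture the annotation assumes: a pseudo-CYT flank, the
# anchor Tyr with its short helix, an optional CYT-attachment Cys, a
# Gly/Ser/Thr-rich mobile segment, a Pro-Val-Pro or Cys DH attachment, the
# [YF]DY end motif, and a pseudo-DH flank. Six group templates mirror the
# documented group architectures: groups 1-3 attach C-terminally via
# Pro-Val-Pro, groups 4-6 via a Cys; the N-terminal Cys is present in
# groups 1-4, in about half of group 5, and absent in group 6.

# Residues allowed as substitution noise: motif-forming letters (C, Y, F,
# P, V) are excluded so noise exercises the window/segmentation logic
# rather than destroying or forging anchor motifs. Hostile mode lifts all
# protection.
NOISE_ALPHABET <- c("A", "D", "E", "G", "H", "I", "K", "L", "M",
                    "N", "Q", "R", "S", "T", "W")

#' Group templates for the synthetic linker families
#'
#' @return list of six templates with fields `helix`, `has_ncys`
#'   (`TRUE`/`FALSE`/`"partial"`), `mobile_unit`, `mobile_range`,
#'   `dh_type` (`"pvp"`/`"cys"`), `spacer`, `end_motif`.
#' @export
group_templates <- function() {
  # Each group couples the shared GST-rich mobile character with a
  # group-specific pair of seasoning residues, so that groups are
  # homologous within and effectively unrelated across -- the condition
  # the similarity-network benchmarks assume.
  list(
    list(helix = "LADSGAKDG", has_ncys = TRUE,  mobile_unit = "GSDAGD",
         mobile_range = c(15L, 20L), dh_type = "pvp", spacer = "DASG",
         end_motif = "YDY"),
    list(helix = "IQENHETNG", has_ncys = TRUE,  mobile_unit = "TGETNE",
         mobile_range = c(16L, 22L), dh_type = "pvp", spacer = "NETG",
         end_motif = "YDY"),
    list(helix = "MSKQTQKSG", has_ncys = TRUE,  mobile_unit = "STKQSK",
         mobile_range = c(18L, 24L), dh_type = "pvp", spacer = "QKSA",
         end_motif = "FDY"),
    list(helix = "LHGIDHGIG", has_ncys = TRUE,  mobile_unit = "GTHIGH",
         mobile_range = c(20L, 26L), dh_type = "cys", spacer = "HITG",
         end_motif = "YDY"),
    list(helix = "IRMSQRMGG", has_ncys = "partial", mobile_unit = "SGRMQR",
         mobile_range = c(22L, 28L), dh_type = "cys", spacer = "RMSA",
         end_motif = "FDY"),
    list(helix = "MWNLTAWNG", has_ncys = FALSE, mobile_unit = "TSWNAL",
         mobile_range = c(24L, 30L), dh_type = "cys", spacer = "WNTA",
         end_motif = "YDY")
  )
}

#' Generate synthetic CDH-like sequence families with ground truth
#'
#' Renders `n_per_group` sequences from each group template, flanked by
#' noisy copies of the bundled reference's CYT tail and DH head so that
#' reference alignment can propagate the anchor. Substitution noise is
#' applied per position outside the protected motif positions (anchor Tyr,
#' Cys attachments, Pro-Val-Pro, end motif); single-residue indels are
#' applied inside the mobile segment only. All randomness is governed by
#' `seed`; the same seed reproduces the output exactly.
#'
#' @param n_per_group sequences per group.
#' @param sub_rate per-position substitution probability in `[0, 0.2]`.
#' @param indel_rate per-mobile-position indel probability in `[0, 0.2]`.
#' @param seed integer seed.
#' @param groups which of the six templates to draw from.
#' @param flank_n_len,flank_c_len lengths of the pseudo-CYT / pseudo-DH
#'   flanks (anchor lands at `flank_n_len + 1`).
#' @param hostile if `TRUE`, motif positions are not protected from
#'   substitution (for negative tests).
#' @param fasta_path,truth_path optional output files (FASTA / TSV).
#' @return list with `records` (sequence set), `truth` (data frame of
#'   planted coordinates per sequence) and `params`.
#' @export
gen_linker_families <- function(n_per_group = 10L, sub_rate = 0,
                                indel_rate = 0, seed = 1L, groups = 1:6,
                                flank_n_len = 99L, flank_c_len = 80L,
                                hostile = FALSE,
                                fasta_path = NULL, truth_path = NULL) {
  if (sub_rate < 0 || sub_rate > 0.2 || indel_rate < 0 || indel_rate > 0.2) {
    stop("sub_rate and indel_rate must lie in [0, 0.2]", call. = FALSE)
  }
  set.seed(seed)
  templates <- group_templates()
  ref <- cdh_reference()
  ref_seq <- ref$record$seq
  ref_anchor <- ref$annotation$cyt_anchor
  ref_linker_end <- ref$annotation$linker_span[2L]
  flank_n_tpl <- seq_chars(substr(ref_seq, ref_anchor - flank_n_len,
                                  ref_anchor - 1L))
  flank_c_tpl <- seq_chars(substr(ref_seq, ref_linker_end + 1L,
                                  ref_linker_end + flank_c_len))

  mutate <- function(ch, protected) {
    if (sub_rate <= 0) return(ch)
    hit <- stats::runif(length(ch)) < sub_rate
    if (!hostile) hit <- hit & !protected
    n_hit <- sum(hit)
    if (n_hit > 0L) ch[hit] <- sample(NOISE_ALPHABET, n_hit, replace = TRUE)
    ch
  }

  recs <- list(); truths <- list(); k <- 0L
  for (g in groups) {
    tpl <- templates[[g]]
    for (i in seq_len(n_per_group)) {
      k <- k + 1L
      has_cys <- if (identical(tpl$has_ncys, "partial")) {
        stats::runif(1) < 0.5
      } else isTRUE(tpl$has_ncys)
      L <- sample(seq(tpl$mobile_range[1L], tpl$mobile_range[2L]), 1L)
      mobile <- rep_len(seq_chars(tpl$mobile_unit), L)
      if (indel_rate > 0) {
        u <- stats::runif(length(mobile))
        keep <- u >= indel_rate / 2
        ins <- u > 1 - indel_rate / 2
        out <- character(0)
        for (j in seq_along(mobile)) {
          if (keep[j]) out <- c(out, mobile[j])
          if (ins[j]) out <- c(out, sample(NOISE_ALPHABET, 1L))
        }
        if (length(out) < 8L) out <- mobile   # guard absurdly short mobiles
        mobile <- out
      }
      dh_motif <- if (tpl$dh_type == "pvp") c("P", "V", "P") else "C"

      parts <- list(flank_n_tpl, "Y", seq_chars(tpl$helix),
                    if (has_cys) "C" else character(0),
                    mobile, dh_motif, seq_chars(tpl$spacer),
                    seq_chars(tpl$end_motif), flank_c_tpl)
      ch <- unlist(parts)
      lens <- vapply(parts, length, 1L)
      off <- cumsum(c(0L, lens))
      anchor <- off[2L] + 1L
      cys_pos <- if (has_cys) off[4L] + 1L else NA_integer_
      mobile_start <- off[5L] + 1L
      dh_pos <- off[6L] + 1L
      end_start <- off[8L] + 1L

      protected <- rep(FALSE, length(ch))
      protected[anchor] <- TRUE
      if (has_cys) protected[cys_pos] <- TRUE
      protected[dh_pos:(dh_pos + length(dh_motif) - 1L)] <- TRUE
      protected[end_start:(end_start + 2L)] <- TRUE
      ch <- mutate(ch, protected)

      n_end <- if (has_cys) cys_pos else anchor + 6L
      id <- sprintf("g%d_s%03d", g, i)
      recs[[k]] <- data.frame(id = id, desc = sprintf("synthetic group %d", g),
                              seq = paste(ch, collapse = ""),
                              stringsAsFactors = FALSE)
      truths[[k]] <- data.frame(
        id = id, group = g,
        anchor = anchor, cyt_cys = cys_pos,
        n_attached_start = anchor, n_attached_end = n_end,
        mobile_start = n_end + 1L, mobile_end = dh_pos - 1L,
        c_attached_start = dh_pos, c_attached_end = end_start + 2L,
        linker_start = anchor, linker_end = end_start + 2L,
        dh_type = tpl$dh_type, dh_pos = dh_pos,
        end_motif = tpl$end_motif, stringsAsFactors = FALSE)
    }
  }
  records <- do.call(rbind, recs)
  truth <- do.call(rbind, truths)
  if (!is.null(fasta_path)) write_fasta(records, fasta_path)
  if (!is.null(truth_path)) {
    write.table(truth, truth_path, sep = "\t", quote = FALSE,
                row.names = FALSE)
  }
  list(records = records, truth = truth,
       params = list(n_per_group = n_per_group, sub_rate = sub_rate,
                     indel_rate = indel_rate, seed = seed, groups = groups,
                     hostile = hostile))
}

#' Generate a synthetic steered-pull distance series with ground truth
#'
#' COG distance ramps linearly from `d0`; the distortion channel is flat at
#' `distortion_start` until `onset`, then rises linearly. The analytic
#' cutoff crossing (on the noise-free signal) is stored as truth.
#'
#' @param d0 initial COG distance (Angstrom).
#' @param cog_rate COG ramp rate (Angstrom/frame).
#' @param distortion_start,distortion_rate,onset distortion channel
#'   parameters.
#' @param pair_d0,pair_rate tracked residue-pair distance ramp.
#' @param n_frames number of frames (>= 201 to exceed the default
#'   smoothing window).
#' @param noise_sd Gaussian noise on every channel (Angstrom).
#' @param seed integer seed.
#' @param cutoff distortion cutoff used for the analytic truth.
#' @param path optional TSV output for the frame table.
#' @return list with `frames` (frame table, time 0-based), `truth`
#'   (analytic crossing frame/time and the parameters).
#' @export
gen_pull_series <- function(d0 = 40, cog_rate = 0.05, distortion_start = 5,
                            distortion_rate = 0.01, onset = 0,
                            pair_d0 = 10, pair_rate = 0.005,
                            n_frames = 1500L, noise_sd = 0, seed = 1L,
                            cutoff = 11.0, path = NULL) {
  if (n_frames < 201L) stop("n_frames must be >= 201", call. = FALSE)
  set.seed(seed)
  t <- seq(0L, n_frames - 1L)
  distortion_true <- distortion_start +
    distortion_rate * pmax(t - onset, 0)
  cog_true <- d0 + cog_rate * t
  pair_true <- pair_d0 + pair_rate * t
  noise <- function() if (noise_sd > 0) stats::rnorm(n_frames, 0, noise_sd)
    else 0
  frames <- frame_table(t, data.frame(
    cog_distance = cog_true + noise(),
    distortion = distortion_true + noise(),
    pair_distance = pair_true + noise()))
  crossed <- which(distortion_true >= cutoff)
  true_frame <- if (length(crossed) > 0L) crossed[1L] else NA_integer_
  truth <- list(
    true_crossing_frame = true_frame,
    true_crossing_time = if (is.na(true_frame)) NA_real_ else t[true_frame],
    true_max_cog = if (is.na(true_frame)) cog_true[n_frames] else
      max(cog_true[seq_len(true_frame - 1L)]),
    cutoff = cutoff, d0 = d0, cog_rate = cog_rate,
    distortion_start = distortion_start, distortion_rate = distortion_rate,
    onset = onset, noise_sd = noise_sd, seed = seed)
  if (!is.null(path)) write_frame_table(frames, path)
  list(frames = frames, truth = truth)
}

#' Generate a synthetic single-exponential absorbance trace
#'
#' `A(t) = offset + amplitude * exp(-k t)` plus seeded Gaussian noise.
#'
#' @param k true rate constant (1/s).
#' @param amplitude,offset trace parameters (AU); a negative amplitude
#'   gives a rising (reduction-type) trace.
#' @param noise_sd Gaussian noise (AU).
#' @param n_points number of samples.
#' @param t_max trace duration (s); default covers five half-lives plus.
#' @param seed integer seed.
#' @param path optional TSV output.
#' @return list with `trace` (data frame `time`, `absorbance`) and `truth`.
#' @export
gen_exponential_trace <- function(k, amplitude = 0.1, offset = 0.02,
                                  noise_sd = 0, n_points = 200L,
                                  t_max = 5 / k, seed = 1L, path = NULL) {
  if (k <= 0) stop("k must be positive", call. = FALSE)
  set.seed(seed)
  time <- seq(0, t_max, length.out = n_points)
  a <- offset + amplitude * exp(-k * time)
  if (noise_sd > 0) a <- a + stats::rnorm(n_points, 0, noise_sd)
  trace <- data.frame(time = time, absorbance = a)
  if (!is.null(path)) {
    write.table(trace, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  list(trace = trace,
       truth = list(k = k, amplitude = amplitude, offset = offset,
                    noise_sd = noise_sd, seed = seed))
}

#' Generate a synthetic closed-state CDH-like Calpha structure
#'
#' A toy two-domain Calpha model numbered like the bundled synthetic
#' reference (1-810): a compact CYT blob (residues 1-194), a compact DH
#' blob (232-810) whose center of geometry sits `cog_separation` Angstrom
#' from the CYT COG -- the documented closed-state interdomain COG
#' distance of 35.6 Angstrom is the default condition -- and a linker path
#' (195-231) running between the domains. The Calpha of linker residue
#' 218 is placed `pair_distance` Angstrom from the nearest DH atom, and
#' DH residue numbering is arranged so that atom is residue 459, mimicking
#' the documented I218/N459 contact geometry.
#'
#' @param cog_separation CYT-DH center-of-geometry distance (Angstrom).
#' @param pair_distance planted Calpha distance between residues 218 and
#'   459.
#' @param jitter_sd positional jitter on the lattice points (Angstrom).
#' @param seed integer seed.
#' @return a structure model data frame (as from [read_pdb_minimal()]).
#' @export
gen_cdh_structure <- function(cog_separation = 35.6, pair_distance = 5.5,
                              jitter_sd = 0.3, seed = 1L) {
  set.seed(seed)
  blob <- function(n, center) {
    side <- ceiling(n^(1 / 3))
    g <- expand.grid(x = seq_len(side), y = seq_len(side), z = seq_len(side))
    g <- g[order(rowSums((g - (side + 1) / 2)^2)), , drop = FALSE]
    p <- as.matrix(g[seq_len(n), ]) * 3.8
    if (jitter_sd > 0) p <- p + matrix(stats::rnorm(3 * n, 0, jitter_sd),
                                       ncol = 3)
    # translate so the COG is exactly at the requested center
    sweep(p, 2L, colMeans(p) - center, "-")
  }
  cyt <- blob(194L, c(0, 0, 0))
  dh <- blob(579L, c(cog_separation, 0, 0))

  # linker path above the domain gap, high enough that only the planted
  # contact comes within disulfide range of the DH blob
  top_z <- max(c(max(cyt[, 3]), max(dh[, 3])))
  s <- c(4, 0, top_z + 8); e <- c(cog_separation - 6, 0, top_z + 8)
  f <- seq(0, 1, length.out = 37L)
  linker <- cbind(s[1] + f * (e[1] - s[1]), s[2] + f * (e[2] - s[2]),
                  s[3] + f * (e[3] - s[3]))

  # plant the 218/459 contact: put Calpha-218 pair_distance above the
  # topmost DH atom, and relabel the DH blob so that atom is residue 459
  p_top <- which.max(dh[, 3])
  linker[218L - 194L, ] <- dh[p_top, ] + c(0, 0, pair_distance)
  dh_res <- 232:810
  i459 <- which(dh_res == 459L)
  dh[c(p_top, i459), ] <- dh[c(i459, p_top), ]

  coords <- rbind(cyt, linker, dh)
  resno <- c(1:194, 195:231, dh_res)
  ref_ch <- seq_chars(synthetic_cdh_sequence())
  aa3 <- c(A = "ALA", C = "CYS", D = "ASP", E = "GLU", F = "PHE", G = "GLY",
           H = "HIS", I = "ILE", K = "LYS", L = "LEU", M = "MET", N = "ASN",
           P = "PRO", Q = "GLN", R = "ARG", S = "SER", T = "THR", V = "VAL",
           W = "TRP", Y = "TYR")
  model <- data.frame(
    atom_name = "CA",
    residue_name = unname(aa3[ref_ch[resno]]),
    chain_id = "A",
    residue_number = resno,
    x = coords[, 1], y = coords[, 2], z = coords[, 3],
    stringsAsFactors = FALSE)
  model <- model[order(model$residue_number), , drop = FALSE]
  rownames(model) <- NULL
  attr(model, "model_index") <- 1L
  model
}

#' Write a Calpha structure model as a minimal PDB file
#'
#' @param model a structure model data frame.
#' @param path output path.
#' @param model_index model number for the MODEL record (omitted if `NA`).
#' @return invisibly, `path`.
#' @export
write_pdb_minimal <- function(model, path, model_index = NA_integer_) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.na(model_index)) writeLines(sprintf("MODEL %8d", model_index), con)
  for (i in seq_len(nrow(model))) {
    writeLines(sprintf(
      "ATOM  %5d %-4s%1s%3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f",
      i, paste0(" ", model$atom_name[i]), " ", model$residue_name[i],
      model$chain_id[i], model$residue_number[i], " ",
      model$x[i], model$y[i], model$z[i], 1, 0), con)
  }
  if (!is.na(model_index)) writeLines("ENDMDL", con)
  writeLines("END", con)
  invisible(path)
}
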