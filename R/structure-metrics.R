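# Structural observables for pull-trajectory post-processing.

#' Domain selection
#'
#' @param span inclusive residue-number span `c(lo, hi)`.
#' @param atoms `"CA"` (default; robust to hydrogens and glycans) or
#'   `"all"`.
#' @return a `domain_selection` list.
#' @export
domain_selection <- function(span, atoms = c("CA", "all")) {
  atoms <- match.arg(atoms)
  stopifnot(length(span) == 2L, span[1L] <= span[2L])
  structure(list(span = as.integer(span), atoms = atoms),
            class = "domain_selection")
}

#' @noRd
select_atoms <- function(model, sel) {
  rows <- model$residue_number >= sel$span[1L] &
    model$residue_number <= sel$span[2L]
  if (sel$atoms == "CA") rows <- rows & model$atom_name == "CA"
  m <- model[rows, , drop = FALSE]
  if (nrow(m) == 0L) {
    stop("empty selection for residues ", sel$span[1L], "..", sel$span[2L],
         call. = FALSE)
  }
  m
}

#' Center-of-geometry distance between two domain selections
#'
#' The COG is the unweighted mean of the selected atom coordinates.
#'
#' @param model a structure model.
#' @param sel_a,sel_b [domain_selection()] objects.
#' @return distance in Angstrom.
#' @export
domain_cog_distance <- function(model, sel_a, sel_b) {
  a <- select_atoms(model, sel_a)
  b <- select_atoms(model, sel_b)
  cog_a <- c(mean(a$x), mean(a$y), mean(a$z))
  cog_b <- c(mean(b$x), mean(b$y), mean(b$z))
  sqrt(sum((cog_a - cog_b)^2))
}

#' Distance between named atoms of two residues
#'
#' @param model a structure model.
#' @param res_a,res_b residue numbers.
#' @param atom_name atom name (default `"CA"`).
#' @return distance in Angstrom.
#' @export
residue_pair_distance <- function(model, res_a, res_b, atom_name = "CA") {
  get1 <- function(res) {
    m <- model[model$residue_number == res & model$atom_name == atom_name, ]
    if (nrow(m) == 0L) {
      stop("residue ", res, " has no ", atom_name, " atom", call. = FALSE)
    }
    c(m$x[1L], m$y[1L], m$z[1L])
  }
  sqrt(sum((get1(res_a) - get1(res_b))^2))
}

#' Savitzky-Golay smoothing
#'
#' Local least-squares polynomial smoothing; the order-2 default preserves
#' quadratic trends exactly, including at the edges, where the polynomial
#' fitted to the first/last window is evaluated directly (the transient
#' handling of the reference scipy/MATLAB implementations). The output has
#' the input's length. If the series is shorter than the window, the
#' window shrinks to the largest valid odd value and the result is flagged
#' via the `window_used` attribute and a warning.
#'
#' @param series numeric vector.
#' @param window odd filter window length (default 101).
#' @param polyorder polynomial order, `< window` (default 2).
#' @return smoothed numeric vector with attribute `window_used`.
#' @export
smooth_series <- function(series, window = 101L, polyorder = 2L) {
  if (window %% 2L == 0L) stop("window must be odd", call. = FALSE)
  if (polyorder >= window) stop("polyorder must be < window", call. = FALSE)
  n <- length(series)
  used <- window
  if (n < window) {
    used <- if (n %% 2L == 1L) n else n - 1L
    if (used <= polyorder) {
      stop("series too short to smooth (length ", n, ")", call. = FALSE)
    }
    warning("series shorter than window; using window ", used, call. = FALSE)
  }
  out <- as.numeric(signal::sgolayfilt(series, p = polyorder, n = used))
  attr(out, "window_used") <- used
  out
}

#' Derive per-frame distance channels from a structure trajectory
#'
#' @param models list of structure models (one per frame).
#' @param sel_cyt,sel_dh [domain_selection()] objects for the two domains.
#' @param distortion_res residue whose Calpha-to-CYT-COG distance monitors
#'   domain distortion.
#' @param tracked_pair optional `c(res_a, res_b)` Calpha pair to track.
#' @return a frame table with channels `cog_distance`, `distortion` and
#'   optionally `pair_distance`.
#' @export
frames_to_table <- function(models, sel_cyt, sel_dh, distortion_res,
                            tracked_pair = NULL) {
  stopifnot(length(models) >= 1L)
  rows <- lapply(models, function(m) {
    cyt <- select_atoms(m, sel_cyt)
    cog_cyt <- c(mean(cyt$x), mean(cyt$y), mean(cyt$z))
    ca <- m[m$residue_number == distortion_res & m$atom_name == "CA", ]
    if (nrow(ca) == 0L) {
      stop("distortion residue ", distortion_res, " has no CA atom",
           call. = FALSE)
    }
    out <- c(
      cog_distance = domain_cog_distance(m, sel_cyt, sel_dh),
      distortion = sqrt(sum((cog_cyt - c(ca$x[1L], ca$y[1L], ca$z[1L]))^2)))
    if (!is.null(tracked_pair)) {
      out <- c(out, pair_distance = residue_pair_distance(
        m, tracked_pair[1L], tracked_pair[2L]))
    }
    out
  })
  tab <- as.data.frame(do.call(rbind, rows))
  frame_table(seq_len(nrow(tab)), tab)
}

#' Analyze a steered-pull trajectory
#'
#' Smooths the distance channels, finds the first frame at which the
#' (smoothed) CYT distortion reaches the cutoff, and reports the maximum
#' interdomain COG distance and the tracked-pair distance range over the
#' frames strictly before that crossing (all frames if the cutoff is never
#' reached). This mirrors the convention of cutting pull simulations once
#' the pulled domain deforms beyond a tolerated limit, so that the maximum
#' extension reflects linker stretching rather than domain unfolding.
#'
#' @param frames a frame table with channels `cog_distance`, `distortion`
#'   and optionally `pair_distance`, or a list of structure models (then
#'   `sel_cyt`, `sel_dh` and `distortion_res` are required and the table is
#'   built with [frames_to_table()]).
#' @param cutoff distortion cutoff in Angstrom (default 11).
#' @param window,polyorder smoothing parameters for [smooth_series()].
#' @param sel_cyt,sel_dh,distortion_res,tracked_pair see
#'   [frames_to_table()]; used only for structure-model input.
#' @return a `pull_analysis` list: `smoothed` (frame table), `cutoff`,
#'   `crossing_frame` (index, `NA` if never crossed), `crossing_time`,
#'   `max_cog_distance`, `pair_distance_range` (`NA` if no pair channel).
#' @export
analyze_pull <- function(frames, cutoff = 11.0, window = 101L,
                         polyorder = 2L, sel_cyt = NULL, sel_dh = NULL,
                         distortion_res = NULL, tracked_pair = NULL) {
  if (is.list(frames) && !is.data.frame(frames)) {
    stopifnot(!is.null(sel_cyt), !is.null(sel_dh), !is.null(distortion_res))
    frames <- frames_to_table(frames, sel_cyt, sel_dh, distortion_res,
                              tracked_pair)
  }
  need <- c("cog_distance", "distortion")
  missing <- setdiff(need, names(frames))
  if (length(missing) > 0L) {
    stop("missing required channel(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  sm <- frames
  for (ch in setdiff(names(frames), "time")) {
    sm[[ch]] <- as.numeric(smooth_series(frames[[ch]], window, polyorder))
  }
  crossing <- which(sm$distortion >= cutoff)
  crossing_frame <- if (length(crossing) > 0L) crossing[1L] else NA_integer_
  pre <- if (is.na(crossing_frame)) seq_len(nrow(sm)) else
    seq_len(crossing_frame - 1L)
  max_cog <- if (length(pre) > 0L) max(sm$cog_distance[pre]) else NA_real_
  pair_range <- NA_real_
  if ("pair_distance" %in% names(sm) && length(pre) > 0L) {
    pair_range <- diff(range(sm$pair_distance[pre]))
  }
  structure(list(
    smoothed = sm, cutoff = cutoff,
    crossing_frame = crossing_frame,
    crossing_time = if (is.na(crossing_frame)) NA_real_ else
      sm$time[crossing_frame],
    max_cog_distance = max_cog,
    pair_distance_range = pair_range
  ), class = "pull_analysis")
}

#' @export
print.pull_analysis <- function(x, ...) {
  cat("<pull_analysis>", nrow(x$smoothed), "frames, cutoff",
      x$cutoff, "A\n")
  cat("  crossing frame:",
      ifelse(is.na(x$crossing_frame), "none", x$crossing_frame),
      " max COG distance:", round(x$max_cog_distance, 2), "A\n")
  if (!is.na(x$pair_distance_range)) {
    cat("  tracked pair range:", round(x$pair_distance_range, 2), "A\n")
  }
  invisible(x)
}
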