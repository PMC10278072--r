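# Function-based linker annotation.
#
# The linker of a CDH-like sequence is defined from function, not from
# secondary-structure prediction: it starts at the conserved Tyr that
# initiates the last CYT helix (the anchor) and ends with the conserved
# Tyr/Phe-Asp-Tyr motif that is firmly attached to the DH domain. Within
# that span three segments are distinguished: the N-attached segment
# (anchor helix up to the conserved CYT-attachment Cys), the mobile segment
# (Gly/Ser/Thr-rich, the part that actually stretches), and the C-attached
# segment (from the Pro-Val-Pro or Cys DH-attachment to the end motif).

#' Annotation tuning parameters
#'
#' @param end_window offsets (from the anchor) of the end-motif search
#'   window; the default `c(15, 80)` brackets the observed linker length
#'   range (very few linkers are shorter than 30 or longer than 60
#'   residues, measured anchor to motif end).
#' @param cys_depth how far past the anchor to search for the
#'   CYT-attachment Cys (default 20, covering Cys at anchor+16 in the
#'   reference numbering).
#' @param n_attached_fallback N-attached segment length used when no Cys is
#'   found (the anchor helix spans the anchor plus four or five residues; 6
#'   is the upper bound).
#' @param anchor_rescue maximum shift (residues) allowed when the
#'   alignment-mapped anchor column is not a Tyr.
#' @return named list of parameters.
#' @export
annotation_params <- function(end_window = c(15L, 80L), cys_depth = 20L,
                              n_attached_fallback = 6L, anchor_rescue = 3L) {
  stopifnot(length(end_window) == 2L, end_window[1L] < end_window[2L],
            cys_depth >= 0L, n_attached_fallback >= 1L, anchor_rescue >= 0L)
  list(end_window = as.integer(end_window), cys_depth = as.integer(cys_depth),
       n_attached_fallback = as.integer(n_attached_fallback),
       anchor_rescue = as.integer(anchor_rescue))
}

#' Find the linker end motif ([YF]DY) in a search window
#'
#' Scans left to right and returns the first occurrence whose start lies in
#' `[search_start, search_end]`.
#'
#' @param residues residue string (or one-row sequence set).
#' @param search_start,search_end 1-based window bounds for the motif start.
#' @return integer span `c(start, end)` (inclusive) or `NULL` if absent.
#' @export
find_end_motif <- function(residues, search_start = 1L,
                           search_end = nchar(residues)) {
  if (is.data.frame(residues)) residues <- residues$seq[[1L]]
  n <- nchar(residues)
  if (search_start < 1L || search_end > n || search_start > search_end) {
    stop("invalid search window [", search_start, ", ", search_end,
         "] for sequence of length ", n, call. = FALSE)
  }
  m <- gregexpr("(?=[YF]DY)", residues, perl = TRUE)[[1L]]
  starts <- as.integer(m)
  starts <- starts[starts >= search_start & starts <= search_end &
                     starts + 2L <= n]
  if (length(starts) == 0L) return(NULL)
  c(starts[1L], starts[1L] + 2L)
}

#' Map the reference anchor Tyr onto a query sequence
#'
#' Glocal pairwise alignment (BLOSUM62, affine gaps; same engine as the
#' similarity network) of `record` against the reference; the alignment
#' column holding the reference anchor is mapped to the record. If the
#' mapped residue is not Tyr, the nearest Tyr within `anchor_rescue`
#' positions is taken; beyond that the anchor is reported missing.
#'
#' @param record residue string or one-row sequence set.
#' @param reference a [reference_annotation()].
#' @param params [annotation_params()].
#' @param align an [align_params()] list.
#' @return list with `anchor` (integer index or `NA`) and `score`.
#' @export
locate_anchor_by_reference <- function(record, reference = cdh_reference(),
                                       params = annotation_params(),
                                       align = align_params()) {
  if (is.data.frame(record)) record <- record$seq[[1L]]
  stopifnot(nzchar(record), inherits(reference, "reference_annotation"))
  al <- glocal_align(record, reference$record$seq, align)
  ref_anchor <- reference$annotation$cyt_anchor
  mapped <- al$map_ref(ref_anchor)
  if (is.na(mapped)) {
    # anchor column is gapped: approximate from the nearest mapped neighbour
    for (off in seq_len(params$anchor_rescue)) {
      for (s in c(-off, off)) {
        p <- al$map_ref(ref_anchor + s)
        if (!is.na(p)) { mapped <- p - s; break }
      }
      if (!is.na(mapped)) break
    }
  }
  anchor <- NA_integer_
  if (!is.na(mapped)) {
    ch <- seq_chars(record)
    offs <- seq(-params$anchor_rescue, params$anchor_rescue)
    cand <- mapped + offs[order(abs(offs), offs)]   # nearest first, ties left
    cand <- cand[cand >= 1L & cand <= length(ch)]
    hit <- cand[ch[cand] == "Y"]
    if (length(hit) > 0L) anchor <- as.integer(hit[1L])
  }
  list(anchor = anchor, score = al$score)
}

#' Annotate the interdomain linker of one sequence
#'
#' Runs the full function-based definition: (1) anchor Tyr located by
#' reference alignment (best-scoring reference wins); (2) end motif
#' ([YF]DY) searched in the window `anchor + end_window`; (3) CYT-attachment
#' Cys = last Cys within `cys_depth` of the anchor; (4) DH attachment =
#' first Pro-Val-Pro motif or first Cys between the CYT Cys and the end
#' motif; (5) segmentation into N-attached, mobile and C-attached spans.
#' Failures are encoded in `status`/`reason`, never thrown.
#'
#' @param record one-row sequence set (or residue string; then `seq_id` is
#'   `"query"`).
#' @param references list of [reference_annotation()] objects (or a single
#'   one).
#' @param params [annotation_params()].
#' @param align an [align_params()] list.
#' @return a `linker_annotation` list: `seq_id`, `status` (`"ok"` or
#'   `"failed"`), `reason`, `cyt_anchor`, `end_motif_span`, `linker_span`,
#'   `n_attached_span`, `mobile_span`, `c_attached_span`, `cyt_cys`,
#'   `dh_attachment` (list `type` in `pvp`/`cys`/`none` and `pos`),
#'   `ref_id`, `align_score`.
#' @export
annotate_linker <- function(record, references = cdh_reference(),
                            params = annotation_params(),
                            align = align_params()) {
  if (inherits(references, "reference_annotation")) references <- list(references)
  stopifnot(length(references) >= 1L)
  if (is.character(record)) record <- seq_set(id = "query", seq = record)
  record <- as_seq_set(record)
  stopifnot(nrow(record) == 1L)
  residues <- check_residues(record$seq[[1L]], record$id[[1L]])
  n <- nchar(residues)

  fail <- function(reason, extra = list()) {
    ann <- c(list(seq_id = record$id[[1L]], status = "failed",
                  reason = reason, cyt_anchor = NA_integer_,
                  end_motif_span = c(NA_integer_, NA_integer_),
                  linker_span = c(NA_integer_, NA_integer_),
                  n_attached_span = c(NA_integer_, NA_integer_),
                  mobile_span = c(NA_integer_, NA_integer_),
                  c_attached_span = c(NA_integer_, NA_integer_),
                  cyt_cys = NA_integer_,
                  dh_attachment = list(type = "none", pos = NA_integer_)),
             extra)
    class(ann) <- "linker_annotation"
    ann
  }

  hits <- lapply(references, function(r)
    locate_anchor_by_reference(residues, r, params, align))
  best <- which.max(vapply(hits, `[[`, 0, "score"))
  anchor <- hits[[best]]$anchor
  ref_id <- references[[best]]$record$id[[1L]]
  score <- hits[[best]]$score
  if (is.na(anchor)) {
    return(fail("anchor not found",
                list(ref_id = ref_id, align_score = score)))
  }

  win_lo <- anchor + params$end_window[1L]
  win_hi <- min(anchor + params$end_window[2L], n - 2L)
  motif <- if (win_lo <= win_hi && win_lo >= 1L) {
    find_end_motif(residues, win_lo, win_hi)
  } else NULL
  if (is.null(motif)) {
    return(fail("end motif not found",
                list(ref_id = ref_id, align_score = score,
                     cyt_anchor = anchor)))
  }
  end_start <- motif[1L]; end_end <- motif[2L]

  ch <- seq_chars(residues)
  cys_hi <- min(anchor + params$cys_depth, end_start - 1L)
  cys_cand <- which(ch == "C")
  cys_cand <- cys_cand[cys_cand >= anchor & cys_cand <= cys_hi]
  cyt_cys <- if (length(cys_cand) > 0L) max(cys_cand) else NA_integer_

  dh_lo <- if (!is.na(cyt_cys)) cyt_cys + 1L else anchor + 7L
  dh_hi <- end_start - 1L
  dh <- list(type = "none", pos = NA_integer_)
  if (dh_lo <= dh_hi) {
    window <- substr(residues, dh_lo, dh_hi)
    pvp <- regexpr("PVP", window, fixed = TRUE)
    pvp_pos <- if (pvp > 0L && dh_lo + as.integer(pvp) + 1L < end_start) {
      dh_lo + as.integer(pvp) - 1L
    } else NA_integer_
    c_here <- which(seq_chars(window) == "C")
    c_pos <- if (length(c_here) > 0L) dh_lo + c_here[1L] - 1L else NA_integer_
    cands <- c(pvp = pvp_pos, cys = c_pos)
    cands <- cands[!is.na(cands)]
    if (length(cands) > 0L) {
      k <- which.min(cands)
      dh <- list(type = names(cands)[k], pos = unname(cands[k]))
    }
  }

  n_end <- if (!is.na(cyt_cys)) cyt_cys else {
    min(anchor + params$n_attached_fallback, end_start - 2L)
  }
  c_start <- if (dh$type != "none") dh$pos else end_start
  if (!(n_end >= anchor && n_end + 1L < c_start && c_start <= end_start)) {
    return(fail("degenerate segmentation",
                list(ref_id = ref_id, align_score = score,
                     cyt_anchor = anchor)))
  }

  ann <- list(
    seq_id = record$id[[1L]], status = "ok", reason = NA_character_,
    cyt_anchor = as.integer(anchor),
    end_motif_span = c(end_start, end_end),
    linker_span = c(as.integer(anchor), end_end),
    n_attached_span = c(as.integer(anchor), as.integer(n_end)),
    mobile_span = c(as.integer(n_end) + 1L, as.integer(c_start) - 1L),
    c_attached_span = c(as.integer(c_start), end_end),
    cyt_cys = as.integer(cyt_cys),
    dh_attachment = dh,
    ref_id = ref_id, align_score = score
  )
  class(ann) <- "linker_annotation"
  ann
}

#' @export
print.linker_annotation <- function(x, ...) {
  cat("<linker_annotation>", x$seq_id, "status:", x$status, "\n")
  if (x$status == "ok") {
    cat(sprintf("  anchor Y%d, end motif %d-%d, linker %d-%d\n",
                x$cyt_anchor, x$end_motif_span[1], x$end_motif_span[2],
                x$linker_span[1], x$linker_span[2]))
    cat(sprintf("  segments: N-attached %d-%d | mobile %d-%d | C-attached %d-%d\n",
                x$n_attached_span[1], x$n_attached_span[2],
                x$mobile_span[1], x$mobile_span[2],
                x$c_attached_span[1], x$c_attached_span[2]))
    cat(sprintf("  CYT Cys: %s, DH attachment: %s at %s\n",
                ifelse(is.na(x$cyt_cys), "none", x$cyt_cys),
                x$dh_attachment$type,
                ifelse(is.na(x$dh_attachment$pos), "-", x$dh_attachment$pos)))
  } else {
    cat("  reason:", x$reason, "\n")
  }
  invisible(x)
}

#' Annotate a set of records and extract deduplicated linkers
#'
#' Annotates every record, keeps the successful ones, cuts out the linker
#' subsequence (anchor through end motif) and collapses exact duplicate
#' linker sequences to their first occurrence (repeated sequences carry no
#' extra information for diversity analysis).
#'
#' @param records sequence-set data frame.
#' @param references list of [reference_annotation()] objects.
#' @param params [annotation_params()].
#' @param align an [align_params()] list.
#' @return list with `linkers` (sequence set of unique linker
#'   subsequences), `annotations` (list of all annotations, by input
#'   order), `failed` (data frame `id`, `reason`), `duplicates` (ids
#'   collapsed into an earlier representative).
#' @export
extract_linkers <- function(records, references = cdh_reference(),
                            params = annotation_params(),
                            align = align_params()) {
  records <- as_seq_set(records)
  anns <- lapply(seq_len(nrow(records)), function(i)
    annotate_linker(records[i, ], references, params, align))
  ok <- vapply(anns, function(a) a$status == "ok", TRUE)
  failed <- data.frame(
    id = records$id[!ok],
    reason = vapply(anns[!ok], `[[`, "", "reason"),
    stringsAsFactors = FALSE)
  sub <- records[ok, , drop = FALSE]
  oks <- anns[ok]
  linker_seq <- vapply(seq_along(oks), function(i)
    substr(sub$seq[[i]], oks[[i]]$linker_span[1L], oks[[i]]$linker_span[2L]),
    character(1))
  dup <- duplicated(linker_seq)
  linkers <- seq_set(id = sub$id[!dup],
                     desc = sub$desc[!dup],
                     seq = linker_seq[!dup])
  list(linkers = linkers, annotations = anns, failed = failed,
       duplicates = sub$id[dup])
}

#' Flatten annotations into a table
#'
#' @param annotations list of `linker_annotation` objects.
#' @return data frame, one row per annotation.
#' @export
annotation_table <- function(annotations) {
  do.call(rbind, lapply(annotations, function(a) {
    data.frame(
      seq_id = a$seq_id, status = a$status, reason = a$reason,
      cyt_anchor = a$cyt_anchor,
      linker_start = a$linker_span[1L], linker_end = a$linker_span[2L],
      n_attached_start = a$n_attached_span[1L],
      n_attached_end = a$n_attached_span[2L],
      mobile_start = a$mobile_span[1L], mobile_end = a$mobile_span[2L],
      c_attached_start = a$c_attached_span[1L],
      c_attached_end = a$c_attached_span[2L],
      cyt_cys = a$cyt_cys,
      dh_attachment = a$dh_attachment$type,
      dh_attachment_pos = a$dh_attachment$pos,
      stringsAsFactors = FALSE)
  }))
}
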