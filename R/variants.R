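# Rational linker-variant design in wild-type numbering.
#
# Edits are specified against wild-type coordinates and validated against
# the wild-type residues before any are applied (all positions are
# interpreted pre-edit), then applied atomically. The result carries a
# coordinate map from wild-type to variant numbering so downstream
# structure metrics can translate residue selections.

# Average (not monoisotopic) residue masses in Da, ProtParam convention.
AA_AVG_MASS <- c(
  A = 71.0788,  R = 156.1875, N = 114.1038, D = 115.0886, C = 103.1388,
  E = 129.1155, Q = 128.1307, G = 57.0519,  H = 137.1411, I = 113.1594,
  L = 113.1594, K = 128.1741, M = 131.1926, F = 147.1766, P = 97.1167,
  S = 87.0782,  T = 101.1051, W = 186.2132, Y = 163.1760, V = 99.1326)
WATER_AVG_MASS <- 18.0153

#' Edit operations for variant design
#'
#' Constructors for the three edit types, all in wild-type numbering:
#' deletion of an inclusive span, insertion immediately after a position
#' (0 = N-terminus), and substitution with the expected wild-type residue
#' stated explicitly so mismatches are caught.
#'
#' @param start,end inclusive deletion span.
#' @param after_pos insertion site; new residues go immediately after it.
#' @param residues residue string to insert.
#' @param pos substitution position.
#' @param from,to wild-type and replacement residues (single letters).
#' @return an `edit_op` list.
#' @export
edit_delete <- function(start, end = start) {
  stopifnot(start >= 1, end >= start)
  structure(list(type = "delete", start = as.integer(start),
                 end = as.integer(end)), class = "edit_op")
}

#' @rdname edit_delete
#' @export
edit_insert <- function(after_pos, residues) {
  stopifnot(after_pos >= 0, nzchar(residues))
  residues <- check_residues(residues, "insertion")
  structure(list(type = "insert", after_pos = as.integer(after_pos),
                 residues = residues), class = "edit_op")
}

#' @rdname edit_delete
#' @export
edit_substitute <- function(pos, from, to) {
  stopifnot(pos >= 1, nchar(from) == 1L, nchar(to) == 1L)
  structure(list(type = "substitute", pos = as.integer(pos),
                 from = toupper(from), to = toupper(to)), class = "edit_op")
}

#' Apply a set of edits to a wild-type sequence
#'
#' Validates every edit against the wild-type sequence (positions in
#' pre-edit numbering, substitution `from` residues must match, edits must
#' not overlap), then applies them atomically.
#'
#' @param wild_type one-row sequence set or residue string.
#' @param ops list of [edit_delete()]/[edit_insert()]/[edit_substitute()]
#'   operations.
#' @param name variant name.
#' @return a `variant_result` list: `name`, `sequence`, `length`,
#'   `theoretical_mass` (Da, average isotopic), `coord_map` (integer
#'   vector, wild-type position to variant position, `NA` when deleted),
#'   `ops`, `wild_type`.
#' @export
apply_variant <- function(wild_type, ops, name = "variant") {
  if (is.data.frame(wild_type)) wild_type <- wild_type$seq[[1L]]
  wt <- check_residues(wild_type, "wild type")
  n <- nchar(wt)
  ch <- seq_chars(wt)
  deleted <- rep(FALSE, n)
  substituted <- rep(FALSE, n)
  insertions <- vector("list", n + 1L)   # slot i+1 holds inserts after pos i

  for (op in ops) {
    stopifnot(inherits(op, "edit_op"))
    switch(op$type,
      delete = {
        if (op$end > n) stop("deletion span ", op$start, "..", op$end,
                             " outside sequence", call. = FALSE)
        span <- op$start:op$end
        if (any(deleted[span]) || any(substituted[span])) {
          stop("overlapping edits in span ", op$start, "..", op$end,
               call. = FALSE)
        }
        deleted[span] <- TRUE
      },
      insert = {
        if (op$after_pos > n) stop("insertion site ", op$after_pos,
                                   " outside sequence", call. = FALSE)
        slot <- op$after_pos + 1L
        if (!is.null(insertions[[slot]])) {
          stop("two insertions at position ", op$after_pos, call. = FALSE)
        }
        insertions[[slot]] <- op$residues
      },
      substitute = {
        if (op$pos > n) stop("substitution position ", op$pos,
                             " outside sequence", call. = FALSE)
        if (ch[op$pos] != op$from) {
          stop(sprintf(
            "substitution at %d expects wild-type %s but sequence has %s",
            op$pos, op$from, ch[op$pos]), call. = FALSE)
        }
        if (deleted[op$pos] || substituted[op$pos]) {
          stop("overlapping edits at position ", op$pos, call. = FALSE)
        }
        substituted[op$pos] <- TRUE
      },
      stop("unknown edit type: ", op$type, call. = FALSE))
  }
  for (op in ops) {
    if (op$type == "insert" && op$after_pos >= 1L && deleted[op$after_pos]) {
      stop("insertion site ", op$after_pos, " was deleted", call. = FALSE)
    }
    if (op$type == "substitute") ch[op$pos] <- op$to
  }

  out <- character(0)
  coord_map <- rep(NA_integer_, n)
  if (!is.null(insertions[[1L]])) out <- seq_chars(insertions[[1L]])
  for (i in seq_len(n)) {
    if (!deleted[i]) {
      out <- c(out, ch[i])
      coord_map[i] <- length(out)
    }
    if (!is.null(insertions[[i + 1L]])) {
      out <- c(out, seq_chars(insertions[[i + 1L]]))
    }
  }
  sequence <- paste(out, collapse = "")
  structure(list(
    name = name, sequence = sequence, length = nchar(sequence),
    theoretical_mass = theoretical_mw(sequence),
    coord_map = coord_map, ops = ops, wild_type = wt
  ), class = "variant_result")
}

#' Reverse the edits of a variant
#'
#' Builds the inverse edit set (in variant numbering) and applies it to the
#' variant sequence; the result reconstructs the wild type exactly.
#'
#' @param result a `variant_result` from [apply_variant()].
#' @return a `variant_result` whose `sequence` equals the wild type.
#' @export
invert_variant <- function(result) {
  stopifnot(inherits(result, "variant_result"))
  cm <- result$coord_map
  wt <- result$wild_type
  rev_ops <- lapply(result$ops, function(op) {
    switch(op$type,
      delete = {
        before <- which(!is.na(cm[seq_len(op$start - 1L)]))
        after <- if (length(before) > 0L) cm[max(before)] else 0L
        edit_insert(after, substr(wt, op$start, op$end))
      },
      insert = {
        vstart <- if (op$after_pos == 0L) 1L else cm[op$after_pos] + 1L
        edit_delete(vstart, vstart + nchar(op$residues) - 1L)
      },
      substitute = edit_substitute(cm[op$pos], op$to, op$from))
  })
  apply_variant(result$sequence, rev_ops,
                name = paste0(result$name, "_reverted"))
}

#' Theoretical average molecular mass of a protein sequence
#'
#' Sum of standard average residue masses plus one water (18.0153 Da),
#' the ProtParam convention.
#'
#' @param sequence residue string, canonical residues only.
#' @return mass in Da.
#' @export
theoretical_mw <- function(sequence) {
  if (is.data.frame(sequence)) sequence <- sequence$seq[[1L]]
  if (!nzchar(sequence)) stop("empty sequence", call. = FALSE)
  ch <- seq_chars(toupper(sequence))
  bad <- which(!ch %in% names(AA_AVG_MASS))
  if (length(bad) > 0L) {
    stop("cannot compute mass: non-canonical residue '", ch[bad[1L]],
         "' at position ", bad[1L], call. = FALSE)
  }
  sum(AA_AVG_MASS[ch]) + WATER_AVG_MASS
}

#' Built-in catalog of NcCDHIIA linker variants
#'
#' The seven linker variants: LNK-1, LNK-2 and LNK-4 shorten the mobile
#' linker by deleting one, two or four residues (LNK-1 deletes Thr215; the
#' larger deletions are contiguous mobile-linker deletions anchored at 215,
#' an assumption since only the single-residue deletion site is
#' documented). LNK+4 and LNK+8 insert two or four Ala-Thr repeats at the
#' Thr216/Thr217 junction. LNK_S=S introduces I218C and N459C to tether the
#' C-attached linker to the DH domain by a disulfide; LNK_S=S+4 combines
#' the disulfide with the four-residue insertion.
#'
#' @return named list of edit-op lists.
#' @export
variant_catalog <- function() {
  list(
    "LNK-1" = list(edit_delete(215L)),
    "LNK-2" = list(edit_delete(215L, 216L)),
    "LNK-4" = list(edit_delete(215L, 218L)),
    "LNK+4" = list(edit_insert(216L, "ATAT")),
    "LNK+8" = list(edit_insert(216L, "ATATATAT")),
    "LNK_S=S" = list(edit_substitute(218L, "I", "C"),
                     edit_substitute(459L, "N", "C")),
    "LNK_S=S+4" = list(edit_insert(216L, "ATAT"),
                       edit_substitute(218L, "I", "C"),
                       edit_substitute(459L, "N", "C"))
  )
}

#' Apply the built-in variant catalog to a wild-type sequence
#'
#' @param wild_type one-row sequence set or residue string; defaults to the
#'   bundled synthetic NcCDHIIA-like reference.
#' @return named list of `variant_result` objects.
#' @export
apply_variant_catalog <- function(wild_type = cdh_reference()$record) {
  catalog <- variant_catalog()
  out <- lapply(names(catalog), function(nm)
    apply_variant(wild_type, catalog[[nm]], name = nm))
  names(out) <- names(catalog)
  out
}

#' Screen residue pairs for disulfide engineering
#'
#' Lists all cross-region residue pairs whose Calpha-Calpha distance is at
#' or below the cutoff, sorted by distance. Calpha distances (rather than
#' Cbeta or Sgamma) keep the screen robust to missing side-chain atoms; the
#' 7 A default is a permissive geometric window for an engineered
#' disulfide.
#'
#' @param model a structure model (data frame from [read_pdb_minimal()]).
#' @param region_a,region_b inclusive residue-number spans `c(lo, hi)`.
#' @param cutoff maximum Calpha-Calpha distance in Angstrom.
#' @return data frame `res_a`, `res_b`, `distance`, ascending by distance.
#' @export
design_disulfide_pairs <- function(model, region_a, region_b, cutoff = 7.0) {
  ca <- model[model$atom_name == "CA", , drop = FALSE]
  a <- ca[ca$residue_number >= region_a[1L] & ca$residue_number <= region_a[2L], ]
  b <- ca[ca$residue_number >= region_b[1L] & ca$residue_number <= region_b[2L], ]
  if (nrow(a) == 0L) stop("region_a contains no Calpha atoms", call. = FALSE)
  if (nrow(b) == 0L) stop("region_b contains no Calpha atoms", call. = FALSE)
  d <- sqrt(outer(a$x, b$x, "-")^2 + outer(a$y, b$y, "-")^2 +
              outer(a$z, b$z, "-")^2)
  hit <- which(d <= cutoff, arr.ind = TRUE)
  out <- data.frame(res_a = a$residue_number[hit[, 1L]],
                    res_b = b$residue_number[hit[, 2L]],
                    distance = d[hit])
  out[order(out$distance), , drop = FALSE]
}
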