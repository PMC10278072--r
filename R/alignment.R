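# Pairwise alignment engine used across the package.
#
# Scoring follows the common sequence-search convention: BLOSUM62 with
# affine gaps costing open + k * extend for a gap of k residues (open = 11,
# extend = 1). Local (Smith-Waterman-style) alignment scores drive the
# similarity network; global/glocal alignment propagates reference
# coordinates during annotation. X is scored 0 against everything.

.aln_env <- new.env(parent = emptyenv())

#' Substitution matrix used by the alignment engine
#'
#' BLOSUM62 with the `X` row and column zeroed, so unknown residues neither
#' reward nor penalise an alignment.
#'
#' @return an integer substitution matrix.
#' @export
linker_submat <- function() {
  if (is.null(.aln_env$submat)) {
    e <- new.env()
    data("BLOSUM62", package = "Biostrings", envir = e)
    m <- e$BLOSUM62
    m["X", ] <- 0L
    m[, "X"] <- 0L
    .aln_env$submat <- m
  }
  .aln_env$submat
}

#' Alignment parameter set
#'
#' @param gap_open gap opening penalty (positive).
#' @param gap_extend gap extension penalty (positive); a gap of length k
#'   costs `gap_open + k * gap_extend`.
#' @return a named list of alignment parameters.
#' @export
align_params <- function(gap_open = 11, gap_extend = 1) {
  stopifnot(gap_open >= 0, gap_extend >= 0)
  list(gap_open = gap_open, gap_extend = gap_extend)
}

#' Optimal local alignment score of two sequences
#'
#' Smith-Waterman-style optimal local score under BLOSUM62 with affine
#' gaps. The score floors at zero (the empty alignment).
#'
#' @param seq_a,seq_b residue strings (canonical residues plus X).
#' @param params an [align_params()] list.
#' @return numeric scalar raw score.
#' @export
align_pair_score <- function(seq_a, seq_b, params = align_params()) {
  seq_a <- check_residues(seq_a, "seq_a")
  seq_b <- check_residues(seq_b, "seq_b")
  as.numeric(Biostrings::pairwiseAlignment(
    seq_a, seq_b, type = "local",
    substitutionMatrix = linker_submat(),
    gapOpening = params$gap_open, gapExtension = params$gap_extend,
    scoreOnly = TRUE))
}

#' All-vs-all local alignment scores
#'
#' @param seqs character vector of residue strings (named or not).
#' @param params an [align_params()] list.
#' @return data frame `i`, `j` (indices, i < j), `raw_score`.
#' @noRd
all_pair_scores <- function(seqs, params = align_params()) {
  n <- length(seqs)
  out <- vector("list", n)
  submat <- linker_submat()
  for (j in seq_len(n)) {
    if (j == 1L) next
    sc <- as.numeric(Biostrings::pairwiseAlignment(
      seqs[seq_len(j - 1L)], seqs[[j]], type = "local",
      substitutionMatrix = submat,
      gapOpening = params$gap_open, gapExtension = params$gap_extend,
      scoreOnly = TRUE))
    out[[j]] <- data.frame(i = seq_len(j - 1L), j = j, raw_score = sc)
  }
  do.call(rbind, out[-1L])
}

#' Bit score and E-value from a raw alignment score
#'
#' Karlin-Altschul statistics with the standard gapped-BLOSUM62 constants
#' lambda = 0.267 and K = 0.041: `bit = (lambda * raw - ln K) / ln 2` and
#' `E = m * n * 2^-bit` with search space `m * n` the product of the two
#' sequence lengths (pairwise scoring; no database-size correction).
#'
#' @param raw_score raw local alignment score (>= 0).
#' @param len_a,len_b sequence lengths.
#' @param lambda,K Karlin-Altschul constants.
#' @return named list with `bit_score` and `e_value` (vectorised).
#' @export
evalue <- function(raw_score, len_a, len_b, lambda = 0.267, K = 0.041) {
  if (any(raw_score < 0)) stop("raw_score must be >= 0", call. = FALSE)
  bit <- (lambda * raw_score - log(K)) / log(2)
  list(bit_score = bit, e_value = len_a * len_b * 2^(-bit))
}

#' Glocal alignment of a record against a reference, with coordinate map
#'
#' Aligns `record` globally within a locally-chosen window of `reference`
#' ("global-local"), under the same scoring as [align_pair_score()] but
#' without the local zero floor. Used to carry reference coordinates (e.g.
#' the anchor Tyr position) onto a query sequence.
#'
#' @return list with `score` and `map_ref`, a function taking a reference
#'   position and returning the aligned record position (NA if the position
#'   falls in a gap or outside the aligned window).
#' @noRd
glocal_align <- function(record, reference, params = align_params()) {
  pa <- Biostrings::pairwiseAlignment(
    record, reference, type = "global-local",
    substitutionMatrix = linker_submat(),
    gapOpening = params$gap_open, gapExtension = params$gap_extend)
  pat <- seq_chars(as.character(Biostrings::alignedPattern(pa)))
  sub <- seq_chars(as.character(Biostrings::alignedSubject(pa)))
  p_pos <- cumsum(pat != "-")                    # record position per column
  s_pos <- cumsum(sub != "-") +
    Biostrings::start(Biostrings::subject(pa)) - 1L
  map_ref <- function(ref_pos) {
    col <- which(s_pos == ref_pos & sub != "-")
    if (length(col) == 0L) return(NA_integer_)
    col <- col[1L]
    if (pat[col] == "-") return(NA_integer_)
    p_pos[col]
  }
  list(score = as.numeric(Biostrings::score(pa)), map_ref = map_ref)
}

#' Star alignment of a sequence set onto its longest member
#'
#' Progressive pairwise global alignment of every sequence to the set's
#' longest member; residues are projected onto the center sequence's
#' columns (insertions relative to the center are dropped). The result is a
#' gapped, equal-length set suitable for [frequency_matrix_with_ic()]. This
#' is a star-topology approximation to a full multiple alignment.
#'
#' @param seqs character vector of residue strings.
#' @param params an [align_params()] list.
#' @return character vector of aligned strings, all of the center's length.
#' @export
star_align <- function(seqs, params = align_params()) {
  stopifnot(length(seqs) >= 1L)
  center_i <- which.max(nchar(seqs))
  center <- seqs[[center_i]]
  L <- nchar(center)
  submat <- linker_submat()
  out <- vapply(seq_along(seqs), function(i) {
    if (i == center_i) return(center)
    pa <- Biostrings::pairwiseAlignment(
      seqs[[i]], center, type = "global",
      substitutionMatrix = submat,
      gapOpening = params$gap_open, gapExtension = params$gap_extend)
    pat <- seq_chars(as.character(Biostrings::alignedPattern(pa)))
    sub <- seq_chars(as.character(Biostrings::alignedSubject(pa)))
    keep <- sub != "-"                  # drop insertions relative to center
    paste(pat[keep], collapse = "")
  }, character(1))
  stopifnot(all(nchar(out) == L))
  names(out) <- names(seqs)
  out
}
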