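# Composition statistics and logo matrices for linker sets.

#' Amino-acid composition classes
#'
#' The three-way partition of the 20 canonical residues used for linker
#' composition profiles: hydrophilic (Ser, Thr, Glu, Asp, Asn, Gln, His,
#' Lys, Arg), hydrophobic (Ala, Val, Leu, Ile, Tyr, Phe, Trp, Met) and
#' residues with a potential structural function (Gly, Pro, Cys).
#'
#' @return named list of three character vectors partitioning the 20
#'   canonical residues.
#' @export
composition_classes <- function() {
  list(
    hydrophilic = c("S", "T", "E", "D", "N", "Q", "H", "K", "R"),
    hydrophobic = c("A", "V", "L", "I", "Y", "F", "W", "M"),
    structural  = c("G", "P", "C")
  )
}

#' Class composition profile of a sequence
#'
#' Counts residues per composition class. `X` residues are excluded from
#' the denominator and tallied separately.
#'
#' @param residues residue string over the 21-letter alphabet.
#' @return list with `counts` (named integer), `fractions` (named numeric,
#'   summing to 1 over counted residues; `NA` and `undefined = TRUE` when
#'   nothing countable), `n_counted`, `n_excluded`.
#' @export
profile_composition <- function(residues) {
  residues <- check_residues(residues)
  ch <- seq_chars(residues)
  cls <- composition_classes()
  n_x <- sum(ch == "X")
  counts <- vapply(cls, function(set) sum(ch %in% set), 0L)
  n <- sum(counts)
  if (n == 0L) {
    return(list(counts = counts,
                fractions = setNames(rep(NA_real_, 3L), names(cls)),
                n_counted = 0L, n_excluded = n_x, undefined = TRUE))
  }
  list(counts = counts, fractions = counts / n,
       n_counted = n, n_excluded = n_x, undefined = FALSE)
}

#' Linker length histogram
#'
#' Half-open bins `[lo, hi)`; lengths below the first or at/above the last
#' edge are reported as underflow/overflow.
#'
#' @param linkers character vector of linker sequences, or a numeric vector
#'   of lengths, or a sequence set.
#' @param bin_edges strictly increasing numeric edges; defaults to
#'   `seq(20, 80, 10)`.
#' @return list with `counts` (named by bin), `underflow`, `overflow`,
#'   `edges`.
#' @export
length_histogram <- function(linkers, bin_edges = seq(20, 80, by = 10)) {
  if (any(diff(bin_edges) <= 0)) {
    stop("bin_edges must be strictly increasing", call. = FALSE)
  }
  if (is.data.frame(linkers)) linkers <- linkers$seq
  lens <- if (is.character(linkers)) nchar(linkers) else as.numeric(linkers)
  k <- length(bin_edges) - 1L
  lab <- sprintf("[%g,%g)", bin_edges[-length(bin_edges)], bin_edges[-1L])
  counts <- setNames(integer(k), lab)
  for (i in seq_len(k)) {
    counts[i] <- sum(lens >= bin_edges[i] & lens < bin_edges[i + 1L])
  }
  list(counts = counts,
       underflow = sum(lens < bin_edges[1L]),
       overflow = sum(lens >= bin_edges[length(bin_edges)]),
       edges = bin_edges)
}

#' Per-column frequency matrix with information content (logo matrix)
#'
#' For an aligned, equal-length set of sequences (gap character `-`),
#' computes per-column residue frequencies over non-gap residues, the
#' column information content `IC_j = log2(20) - H_j` with
#' `H_j = -sum f * log2 f` (taking `0 * log 0 = 0`), and stacked-letter
#' logo heights `f * IC`. Columns covered by fewer than half the sequences
#' are flagged; all-gap columns get `IC = 0`.
#'
#' @param aligned character vector of equal-length aligned sequences.
#' @param small_sample_correction subtract the standard small-sample
#'   entropy correction `(20 - 1) / (2 ln(2) n_j)` from each column's IC
#'   (floored at 0). Off by default; the correction only matters for small
#'   sequence sets.
#' @return list with `counts` (20 x L), `frequencies` (20 x L), `ic`
#'   (length L), `heights` (20 x L), `coverage` (non-gap count per column),
#'   `low_coverage` (logical per column), `n`, `L`.
#' @export
frequency_matrix_with_ic <- function(aligned, small_sample_correction = FALSE) {
  stopifnot(length(aligned) >= 1L)
  L <- nchar(aligned[[1L]])
  if (any(nchar(aligned) != L)) {
    stop("aligned sequences must all have equal length", call. = FALSE)
  }
  mat <- do.call(rbind, strsplit(toupper(aligned), "", fixed = TRUE))
  counts <- matrix(0L, nrow = 20L, ncol = L,
                   dimnames = list(AA_CANONICAL, NULL))
  for (j in seq_len(L)) {
    tab <- table(factor(mat[, j], levels = AA_CANONICAL))
    counts[, j] <- as.integer(tab)
  }
  coverage <- colSums(counts)
  freq <- sweep(counts, 2L, pmax(coverage, 1L), "/")
  h <- apply(freq, 2L, function(f) {
    f <- f[f > 0]
    if (length(f) == 0L) return(log2(20))   # all-gap column -> IC 0
    -sum(f * log2(f))
  })
  ic <- log2(20) - h
  if (small_sample_correction) {
    corr <- ifelse(coverage > 0, 19 / (2 * log(2) * coverage), 0)
    ic <- pmax(ic - corr, 0)
  }
  ic[coverage == 0L] <- 0
  list(counts = counts, frequencies = freq, ic = ic,
       heights = sweep(freq, 2L, ic, "*"),
       coverage = coverage,
       low_coverage = coverage < length(aligned) / 2,
       n = length(aligned), L = L)
}
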