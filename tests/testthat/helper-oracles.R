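# Independent oracles used by the test suite. These deliberately do not
# share code with the package: the alignment oracle is a plain-R Gotoh
# dynamic program, the component oracle a hand-rolled union-find, and the
# smoothing oracle a windowed least-squares fit.

# Optimal local alignment score, affine gaps costing open + k * extend.
oracle_local_score <- function(a, b, submat, gap_open = 11, gap_ext = 1) {
  a <- strsplit(a, "")[[1]]; b <- strsplit(b, "")[[1]]
  n <- length(a); m <- length(b)
  NEG <- -1e9
  M <- matrix(0, n + 1, m + 1)       # alignment ends in a match/mismatch
  X <- matrix(NEG, n + 1, m + 1)     # ends in a gap in b (a consumed)
  Y <- matrix(NEG, n + 1, m + 1)     # ends in a gap in a (b consumed)
  best <- 0
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      s <- submat[a[i], b[j]]
      M[i + 1, j + 1] <- max(0, M[i, j], X[i, j], Y[i, j]) + s
      X[i + 1, j + 1] <- max(M[i, j + 1] - gap_open - gap_ext,
                             X[i, j + 1] - gap_ext)
      Y[i + 1, j + 1] <- max(M[i + 1, j] - gap_open - gap_ext,
                             Y[i + 1, j] - gap_ext)
      best <- max(best, M[i + 1, j + 1])
    }
  }
  best
}

# Connected components by union-find over an edge list.
oracle_components <- function(ids, edge_i, edge_j) {
  parent <- seq_along(ids)
  find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
  for (k in seq_along(edge_i)) {
    ri <- find(match(edge_i[k], ids)); rj <- find(match(edge_j[k], ids))
    if (ri != rj) parent[ri] <- rj
  }
  roots <- vapply(seq_along(ids), find, 1L)
  match(roots, unique(roots))
}

# Savitzky-Golay value at one interior point by direct least squares.
oracle_sg_point <- function(series, center, window, polyorder) {
  k <- (window - 1) %/% 2
  idx <- (center - k):(center + k)
  fit <- lm(series[idx] ~ poly(seq_along(idx), polyorder, raw = TRUE))
  unname(predict(fit)[k + 1])
}

# Shared small fixture: a toy Calpha model laid out on a line.
toy_model <- function(coords, resno = seq_len(nrow(coords)),
                      atom = "CA") {
  m <- data.frame(atom_name = atom, residue_name = "ALA", chain_id = "A",
                  residue_number = resno,
                  x = coords[, 1], y = coords[, 2], z = coords[, 3],
                  stringsAsFactors = FALSE)
  attr(m, "model_index") <- 1L
  m
}
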