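#' Read protein sequences from a FASTA file
#'
#' Wraps [Biostrings::readAAStringSet()] and normalises the result into the
#' package's sequence-set data frame: one row per record with columns `id`
#' (first whitespace-delimited token of the header), `desc` (remainder of the
#' header, possibly empty) and `seq` (uppercase residues). Residues are
#' restricted to the 20 canonical amino acids plus `X`; anything else is a
#' format error naming the record and position.
#'
#' @param path path to a FASTA file.
#' @return a data frame with columns `id`, `desc`, `seq`. An empty file
#'   yields a zero-row data frame.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (file.size(path) == 0L) return(seq_set())
  # Biostrings drops characters outside its AA alphabet with a warning;
  # surface that as a format error naming the record and position instead
  ss <- withCallingHandlers(
    Biostrings::readAAStringSet(path, format = "fasta"),
    warning = function(w) {
      if (grepl("invalid one-letter sequence codes", conditionMessage(w))) {
        fasta_report_invalid(path)
      }
      warning(w)
    })
  headers <- names(ss)
  id <- sub("\\s.*$", "", headers)
  desc <- ifelse(grepl("\\s", headers), sub("^\\S+\\s+", "", headers), "")
  seqs <- toupper(as.character(ss))
  for (i in seq_along(seqs)) {
    ch <- seq_chars(seqs[[i]])
    bad <- which(!ch %in% AA_ALPHABET)
    if (length(bad) > 0L) {
      stop(sprintf("record '%s': invalid residue '%s' at position %d",
                   id[[i]], ch[bad[1L]], bad[1L]), call. = FALSE)
    }
    if (!nzchar(id[[i]])) stop("empty record id in ", path, call. = FALSE)
    if (!nzchar(seqs[[i]])) {
      stop(sprintf("record '%s': empty sequence", id[[i]]), call. = FALSE)
    }
  }
  seq_set(id = id, desc = desc, seq = unname(seqs))
}

#' Write a sequence set to FASTA
#'
#' @param records a sequence-set data frame (`id`, `desc`, `seq`).
#' @param path output path.
#' @param width line width for wrapping residues.
#' @return invisibly, `path`.
#' @export
write_fasta <- function(records, path, width = 60L) {
  records <- as_seq_set(records)
  ss <- Biostrings::AAStringSet(records$seq)
  names(ss) <- ifelse(nzchar(records$desc),
                      paste(records$id, records$desc),
                      records$id)
  Biostrings::writeXStringSet(ss, filepath = path, width = width)
  invisible(path)
}

#' Locate the first invalid residue in a FASTA file and raise a format error
#' @noRd
fasta_report_invalid <- function(path) {
  lines <- readLines(path, warn = FALSE)
  headers <- grepl("^>", lines)
  id <- NA_character_
  pos <- 0L
  for (ln in lines) {
    if (startsWith(ln, ">")) {
      id <- sub("\\s.*$", "", substring(ln, 2L))
      pos <- 0L
      next
    }
    ch <- seq_chars(toupper(gsub("\\s", "", ln)))
    bad <- which(!ch %in% AA_ALPHABET)
    if (length(bad) > 0L) {
      stop(sprintf("record '%s': invalid residue '%s' at position %d",
                   id, ch[bad[1L]], pos + bad[1L]), call. = FALSE)
    }
    pos <- pos + length(ch)
  }
  stop("invalid sequence characters in ", path, call. = FALSE)
}

#' Construct / validate a sequence-set data frame
#'
#' @param id,desc,seq character vectors of equal length.
#' @return data frame with columns `id`, `desc`, `seq`.
#' @export
seq_set <- function(id = character(), desc = character(length(id)),
                    seq = character()) {
  stopifnot(length(id) == length(seq))
  if (length(desc) != length(id)) desc <- rep_len(desc, length(id))
  data.frame(id = as.character(id), desc = as.character(desc),
             seq = as.character(seq), stringsAsFactors = FALSE)
}

#' @noRd
as_seq_set <- function(x) {
  if (is.character(x)) {
    ids <- names(x)
    if (is.null(ids)) ids <- paste0("seq", seq_along(x))
    return(seq_set(id = ids, seq = unname(x)))
  }
  stopifnot(is.data.frame(x), all(c("id", "seq") %in% names(x)))
  if (is.null(x$desc)) x$desc <- rep("", nrow(x))
  x[, c("id", "desc", "seq")]
}

#' Read a minimal PDB structure (single- or multi-model)
#'
#' Parses fixed-column `ATOM` coordinate records via [bio3d::read.pdb()],
#' honouring `MODEL`/`ENDMDL` blocks. `HETATM` records are ignored by
#' default. For atoms with alternate locations only the first altLoc is
#' kept; insertion codes are rejected with an error, as the structures this
#' package targets do not use them.
#'
#' @param path path to a PDB file.
#' @param keep_hetatm if `TRUE`, also keep HETATM records.
#' @return a list of structure models. Each model is a data frame with
#'   columns `atom_name`, `residue_name`, `chain_id`, `residue_number`,
#'   `x`, `y`, `z` and an attribute `model_index`.
#' @export
read_pdb_minimal <- function(path, keep_hetatm = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  rec <- substr(lines, 1, 6)
  is_atom <- rec == "ATOM  " | (keep_hetatm & rec == "HETATM")
  if (!any(rec == "ATOM  ") && !(keep_hetatm && any(rec == "HETATM"))) {
    stop("no atoms: file contains no ATOM coordinate records", call. = FALSE)
  }
  # pre-validate coordinate fields so errors carry a line number
  for (ln in which(is_atom)) {
    for (cols in list(c(31, 38), c(39, 46), c(47, 54))) {
      field <- substr(lines[ln], cols[1], cols[2])
      if (is.na(suppressWarnings(as.numeric(field)))) {
        stop(sprintf("malformed coordinate field at line %d: '%s'",
                     ln, field), call. = FALSE)
      }
    }
    icode <- substr(lines[ln], 27, 27)
    if (icode != " ") {
      stop(sprintf("insertion code '%s' at line %d not supported",
                   icode, ln), call. = FALSE)
    }
  }
  pdb <- bio3d::read.pdb(path, multi = TRUE, hex = FALSE, verbose = FALSE,
                         rm.alt = TRUE)
  at <- pdb$atom
  if (!keep_hetatm) {
    keep <- at$type == "ATOM"
  } else {
    keep <- rep(TRUE, nrow(at))
  }
  at <- at[keep, , drop = FALSE]
  if (nrow(at) == 0L) stop("no atoms after filtering", call. = FALSE)
  xyz <- pdb$xyz
  n_models <- nrow(xyz)
  idx <- bio3d::atom2xyz(which(keep))
  lapply(seq_len(n_models), function(m) {
    coords <- matrix(xyz[m, idx], ncol = 3, byrow = TRUE)
    if (any(!is.finite(coords))) {
      stop("non-finite coordinates in model ", m, call. = FALSE)
    }
    model <- data.frame(
      atom_name = at$elety,
      residue_name = at$resid,
      chain_id = at$chain,
      residue_number = at$resno,
      x = coords[, 1], y = coords[, 2], z = coords[, 3],
      stringsAsFactors = FALSE
    )
    if (any(model$residue_number <= 0)) {
      stop("non-positive residue number in model ", m, call. = FALSE)
    }
    attr(model, "model_index") <- m
    model
  })
}

#' Read a frame or trace table (time plus named channels)
#'
#' Whitespace/tab-separated numeric table whose first column is time (or a
#' frame index). An optional single header line supplies channel names;
#' without a header, channels are auto-named `c1..cN`.
#'
#' @param path path to the table.
#' @return a data frame with a strictly increasing `time` column followed by
#'   channel columns.
#' @export
read_frame_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  first <- readLines(path, n = 1L, warn = FALSE)
  tokens <- strsplit(trimws(first), "\\s+")[[1L]]
  has_header <- any(is.na(suppressWarnings(as.numeric(tokens))))
  tab <- tryCatch(
    read.table(path, header = has_header, colClasses = "numeric"),
    error = function(e) stop("ragged or non-numeric rows in ", path, ": ",
                             conditionMessage(e), call. = FALSE)
  )
  if (ncol(tab) < 2L) stop("frame table needs a time column plus at least one channel",
                           call. = FALSE)
  if (!has_header) {
    names(tab) <- c("time", paste0("c", seq_len(ncol(tab) - 1L)))
  } else {
    names(tab)[1L] <- "time"
  }
  frame_table(tab$time, tab[, -1L, drop = FALSE])
}

#' Construct / validate a frame table
#'
#' @param time strictly increasing numeric vector.
#' @param channels data frame (or named list) of numeric channels, each the
#'   same length as `time`.
#' @return data frame `time` + channels.
#' @export
frame_table <- function(time, channels) {
  channels <- as.data.frame(channels)
  if (any(!is.finite(time)) || any(diff(time) <= 0)) {
    stop("non-monotone or non-finite time column", call. = FALSE)
  }
  if (any(vapply(channels, length, 1L) != length(time))) {
    stop("channel length differs from time length", call. = FALSE)
  }
  if (any(!vapply(channels, function(ch) all(is.finite(ch)), TRUE))) {
    stop("non-finite channel values", call. = FALSE)
  }
  cbind(data.frame(time = time), channels)
}

#' Write a frame table as TSV
#' @param tab a frame table.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_frame_table <- function(tab, path) {
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
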