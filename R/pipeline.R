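# End-to-end linker sequence analysis pipeline:
# annotate -> dedupe -> composition/length statistics -> similarity
# network grouping -> per-group logo matrices -> summary.

#' Pipeline configuration
#'
#' @param input_fasta path to the input FASTA (or `NULL` when `records`
#'   are supplied directly).
#' @param out_dir output directory (created if missing).
#' @param records optional sequence set, used instead of `input_fasta`.
#' @param references list of [reference_annotation()] objects; defaults to
#'   the bundled synthetic reference.
#' @param threshold similarity-network E-value threshold.
#' @param min_group_size smallest labelled group.
#' @param annotation [annotation_params()].
#' @param align [align_params()].
#' @param bin_edges length-histogram bin edges.
#' @param seed integer seed (the analysis itself is deterministic; the
#'   seed is recorded and set for reproducibility of any downstream use).
#' @param verbose emit progress messages to stderr.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(input_fasta = NULL, out_dir = tempfile("linkerscape_"),
                            records = NULL,
                            references = list(cdh_reference()),
                            threshold = 1e-10, min_group_size = 10L,
                            annotation = annotation_params(),
                            align = align_params(),
                            bin_edges = seq(20, 80, by = 10),
                            seed = 1L, verbose = TRUE) {
  stopifnot(threshold >= 0, min_group_size >= 1L)
  structure(list(input_fasta = input_fasta, out_dir = out_dir,
                 records = records, references = references,
                 threshold = threshold,
                 min_group_size = as.integer(min_group_size),
                 annotation = annotation, align = align,
                 bin_edges = bin_edges, seed = as.integer(seed),
                 verbose = isTRUE(verbose)),
            class = "pipeline_config")
}

#' Run the full linker analysis pipeline
#'
#' Reads sequences, annotates and extracts deduplicated linkers, computes
#' composition and length statistics, builds the similarity network with
#' group labels, and writes per-group logo matrices plus a summary. Output
#' is deterministic for a fixed config and seed.
#'
#' @param config a [pipeline_config()].
#' @return invisibly, a list with `summary`, `annotations`, `linkers`,
#'   `network`, `logos` and the output file paths.
#' @export
run_analysis <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  say <- function(...) if (config$verbose) message("[linkerscape] ", ...)
  set.seed(config$seed)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  tsv <- function(x, name) {
    p <- file.path(config$out_dir, name)
    write.table(x, p, sep = "\t", quote = FALSE, row.names = FALSE)
    p
  }

  records <- if (!is.null(config$records)) as_seq_set(config$records)
    else read_fasta(config$input_fasta)
  if (nrow(records) == 0L) stop("no sequences in input", call. = FALSE)
  say("annotate: ", nrow(records), " sequences")

  ext <- extract_linkers(records, config$references, config$annotation,
                         config$align)
  ann_tab <- annotation_table(ext$annotations)
  paths <- c(annotations = tsv(ann_tab, "annotations.tsv"))
  write_fasta(ext$linkers, file.path(config$out_dir, "linkers.fasta"))
  paths["linkers"] <- file.path(config$out_dir, "linkers.fasta")
  n_ok <- sum(ann_tab$status == "ok")
  say("annotated ", n_ok, "/", nrow(records), ", ",
      nrow(ext$linkers), " unique linkers")
  if (nrow(ext$linkers) == 0L) stop("annotation produced no linkers",
                                    call. = FALSE)

  say("composition and length statistics")
  comp_rows <- lapply(seq_len(nrow(ext$linkers)), function(i) {
    p <- profile_composition(ext$linkers$seq[[i]])
    data.frame(id = ext$linkers$id[[i]], length = nchar(ext$linkers$seq[[i]]),
               t(p$fractions), n_counted = p$n_counted,
               n_excluded = p$n_excluded)
  })
  overall <- profile_composition(paste(ext$linkers$seq, collapse = ""))
  comp <- rbind(do.call(rbind, comp_rows),
                data.frame(id = "ALL", length = sum(nchar(ext$linkers$seq)),
                           t(overall$fractions),
                           n_counted = overall$n_counted,
                           n_excluded = overall$n_excluded))
  paths["composition"] <- tsv(comp, "composition.tsv")
  hist <- length_histogram(ext$linkers, config$bin_edges)
  paths["histogram"] <- tsv(
    data.frame(bin = names(hist$counts), count = as.integer(hist$counts)),
    "length_histogram.tsv")

  if (nrow(ext$linkers) < 2L) {
    stop("network stage needs at least two unique linkers", call. = FALSE)
  }
  say("similarity network over ", nrow(ext$linkers), " linkers")
  net <- build_network_and_group(ext$linkers, config$threshold,
                                 config$min_group_size, config$align)
  paths["edges"] <- tsv(net$edges, "edges.tsv")
  paths["groups"] <- tsv(net$groups, "groups.tsv")
  n_groups <- length(unique(stats::na.omit(net$groups$group)))
  say(n_groups, " groups at E <= ", config$threshold)

  logos <- list()
  for (gr in sort(unique(stats::na.omit(net$groups$group)))) {
    members <- net$groups$id[!is.na(net$groups$group) &
                               net$groups$group == gr]
    seqs <- ext$linkers$seq[match(members, ext$linkers$id)]
    aligned <- star_align(setNames(seqs, members), config$align)
    fm <- frequency_matrix_with_ic(aligned)
    long <- do.call(rbind, lapply(seq_len(fm$L), function(j) {
      nz <- fm$frequencies[, j] > 0
      data.frame(position = j, residue = rownames(fm$frequencies)[nz],
                 frequency = fm$frequencies[nz, j],
                 ic = fm$ic[j], height = fm$heights[nz, j])
    }))
    logos[[as.character(gr)]] <- fm
    paths[paste0("logo_group", gr)] <-
      tsv(long, sprintf("logo_group%d.tsv", gr))
  }

  summary <- data.frame(
    n_in = nrow(records), n_annotated = n_ok,
    n_failed = nrow(records) - n_ok,
    n_unique_linkers = nrow(ext$linkers),
    n_grouped = sum(!is.na(net$groups$group)),
    n_groups = n_groups)
  paths["summary"] <- tsv(summary, "summary.tsv")
  say("done: ", config$out_dir)
  invisible(list(summary = summary, annotations = ext$annotations,
                 linkers = ext$linkers, network = net, logos = logos,
                 failed = ext$failed, paths = paths))
}
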