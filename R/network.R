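# Sequence similarity network (SSN) over linker sequences.
#
# All-vs-all local alignment scores are converted to E-values; pairs at or
# below the E-value threshold become edges and the connected components of
# the resulting graph define the linker groups, labelled 1..k by
# descending size. Components smaller than `min_group_size` stay
# unassigned, mirroring common SSN practice where singletons and tiny
# clusters are left out of the named groups.

#' Build a similarity network and assign group labels
#'
#' @param linkers sequence set (data frame with `id`, `seq`) or named
#'   character vector; at least two sequences.
#' @param threshold E-value edge threshold (default `1e-10`, the grouping
#'   threshold reported for Class II CDH linkers).
#' @param min_group_size smallest component that receives a group label
#'   (default 10).
#' @param params an [align_params()] list.
#' @return list with `edges` (data frame `id_i`, `id_j`, `raw_score`,
#'   `bit_score`, `e_value`, `edge` logical), `groups` (data frame `id`,
#'   `component`, `group` with `NA` for unassigned), `threshold`,
#'   `min_group_size`.
#' @export
build_network_and_group <- function(linkers, threshold = 1e-10,
                                    min_group_size = 10L,
                                    params = align_params()) {
  linkers <- as_seq_set(linkers)
  if (nrow(linkers) < 2L) {
    stop("need at least two linker sequences to build a network",
         call. = FALSE)
  }
  if (anyDuplicated(linkers$id)) {
    stop("duplicate linker ids", call. = FALSE)
  }
  pairs <- all_pair_scores(linkers$seq, params)
  ev <- evalue(pairs$raw_score,
               nchar(linkers$seq)[pairs$i], nchar(linkers$seq)[pairs$j])
  edges <- data.frame(
    id_i = linkers$id[pairs$i], id_j = linkers$id[pairs$j],
    raw_score = pairs$raw_score,
    bit_score = ev$bit_score, e_value = ev$e_value,
    edge = ev$e_value <= threshold,
    stringsAsFactors = FALSE)
  groups <- group_components(linkers$id, edges[edges$edge, c("id_i", "id_j")],
                             min_group_size)
  list(edges = edges, groups = groups, threshold = threshold,
       min_group_size = as.integer(min_group_size))
}

#' Connected-component group assignment
#'
#' @param ids node identifiers.
#' @param edge_list data frame with columns `id_i`, `id_j`.
#' @param min_group_size smallest labelled component.
#' @return data frame `id`, `component` (integer component index),
#'   `group` (1..k by descending component size, ties broken by smallest
#'   member id; `NA` for components below `min_group_size`).
#' @export
group_components <- function(ids, edge_list, min_group_size = 10L) {
  g <- igraph::make_empty_graph(n = length(ids), directed = FALSE)
  g <- igraph::set_vertex_attr(g, "name", value = ids)
  if (nrow(edge_list) > 0L) {
    g <- igraph::add_edges(g, rbind(match(edge_list$id_i, ids),
                                    match(edge_list$id_j, ids)))
  }
  comp <- igraph::components(g)
  member <- comp$membership
  sizes <- comp$csize
  first_id <- vapply(seq_along(sizes), function(k)
    min(ids[member == k]), character(1))
  ord <- order(-sizes, first_id)
  rank <- match(seq_along(sizes), ord)
  group <- ifelse(sizes[member] >= min_group_size, rank[member], NA_integer_)
  # renumber labelled groups densely 1..k while keeping the size order
  lab <- sort(unique(group[!is.na(group)]))
  group <- match(group, lab)
  data.frame(id = ids, component = as.integer(member),
             group = as.integer(group), stringsAsFactors = FALSE)
}

#' Group assignment across a grid of thresholds
#'
#' Re-thresholds a computed edge table over a grid of E-value thresholds
#' without re-running the alignments. Raising the threshold can only merge
#' components, never split them (monotone coarsening).
#'
#' @param network result of [build_network_and_group()].
#' @param thresholds numeric vector of E-value thresholds.
#' @param min_group_size smallest labelled component.
#' @return named list of group data frames, one per threshold.
#' @export
threshold_sweep <- function(network, thresholds, min_group_size = 10L) {
  ids <- network$groups$id
  out <- lapply(thresholds, function(th) {
    keep <- network$edges$e_value <= th
    group_components(ids, network$edges[keep, c("id_i", "id_j")],
                     min_group_size)
  })
  names(out) <- as.character(thresholds)
  out
}
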