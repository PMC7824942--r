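# Sample-organised TCR sharing network: one hub node per sample, one leaf
# node per clonal clonotype attached to its sample hub, and leaf-leaf
# similarity edges for pairs scoring above the threshold. Backed by igraph.

#' Build the TCR sharing network
#'
#' Creates a two-level graph: a hub node for every sample contributing at
#' least one clonal clonotype, a leaf node for every clonotype (attached to
#' its hub by an `attachment` edge), and a `similarity` edge between every
#' pair of leaves with L-sim strictly above `tau`. Leaves without any
#' similarity edge are retained; they still sprout from their hub.
#'
#' @param clonotypes A `tcr_clonotypes` table with per-sample clonotypes
#'   (every row needs a non-missing `sample_id`).
#' @param x The `lsim_matrix` computed over exactly these clonotypes.
#' @param tau Similarity threshold in (0, 1); strict inequality.
#' @param metadata Optional sample metadata supplying `diagnosis_group` for
#'   hubs of samples absent from `clonotypes` annotation.
#' @return An object of class `tcr_network` wrapping an igraph graph with
#'   vertex attributes `kind` (hub/leaf), `sample_id`, `group`, `cdr3a`,
#'   `cdr3b`, `size` and edge attributes `kind` (attachment/similarity) and
#'   `lsim`.
#' @export
build_network <- function(clonotypes, x, tau = 0.8, metadata = NULL) {
  stopifnot(is.data.frame(clonotypes), inherits(x, "lsim_matrix"),
            tau > 0, tau < 1)
  if (!identical(as.character(clonotypes$clonotype_id), as.character(x$ids))) {
    stop("similarity matrix does not cover these clonotypes (id mismatch)",
         call. = FALSE)
  }
  if (anyNA(clonotypes$sample_id)) {
    stop("network construction needs per-sample clonotypes (use within_sample scope)",
         call. = FALSE)
  }
  grp <- clonotypes$diagnosis_group
  if (is.null(grp)) grp <- rep("unknown", nrow(clonotypes))
  if (!is.null(metadata)) {
    m <- match(clonotypes$sample_id, metadata$sample_id)
    grp <- ifelse(is.na(grp) & !is.na(m), metadata$diagnosis_group[m], grp)
  }
  grp[is.na(grp)] <- "unknown"
  samples <- sort(unique(clonotypes$sample_id))
  hub_name <- function(s) paste0("sample:", s)
  hub_group <- grp[match(samples, clonotypes$sample_id)]

  vertices <- data.frame(
    name = c(hub_name(samples), clonotypes$clonotype_id),
    kind = c(rep("hub", length(samples)), rep("leaf", nrow(clonotypes))),
    sample_id = c(samples, clonotypes$sample_id),
    group = c(hub_group, grp),
    cdr3a = c(rep(NA_character_, length(samples)), as.character(clonotypes$cdr3a)),
    cdr3b = c(rep(NA_character_, length(samples)), clonotypes$cdr3b),
    size = c(rep(NA_integer_, length(samples)), clonotypes$size),
    stringsAsFactors = FALSE
  )
  attach_edges <- data.frame(
    from = clonotypes$clonotype_id,
    to = hub_name(clonotypes$sample_id),
    kind = "attachment", lsim = NA_real_, stringsAsFactors = FALSE
  )
  hit <- which(x$scores > tau)
  sim_edges <- if (length(hit)) {
    ij <- condensed_ij(x$n)[hit, , drop = FALSE]
    data.frame(from = x$ids[ij[, 1L]], to = x$ids[ij[, 2L]],
               kind = "similarity", lsim = x$scores[hit],
               stringsAsFactors = FALSE)
  } else {
    attach_edges[0L, ]
  }
  g <- igraph::graph_from_data_frame(
    rbind(attach_edges, sim_edges), directed = FALSE, vertices = vertices)
  structure(list(graph = g, tau = tau), class = "tcr_network")
}

#' @export
print.tcr_network <- function(x, ...) {
  g <- x$graph
  kind <- igraph::V(g)$kind
  ekind <- igraph::E(g)$kind
  cat(sprintf(
    "<tcr_network> tau=%g: %d sample hubs, %d clonal TCR leaves, %d similarity edges\n",
    x$tau, sum(kind == "hub"), sum(kind == "leaf"),
    sum(ekind == "similarity")))
  invisible(x)
}

network_similarity_edges <- function(net) {
  g <- net$graph
  es <- igraph::E(g)[igraph::E(g)$kind == "similarity"]
  if (!length(es)) {
    return(data.frame(from = character(), to = character(), lsim = numeric(),
                      sample_from = character(), sample_to = character(),
                      group_from = character(), group_to = character(),
                      stringsAsFactors = FALSE))
  }
  ends <- igraph::ends(g, es)
  vi <- match(ends[, 1L], igraph::V(g)$name)
  vj <- match(ends[, 2L], igraph::V(g)$name)
  data.frame(
    from = ends[, 1L], to = ends[, 2L], lsim = es$lsim,
    sample_from = igraph::V(g)$sample_id[vi],
    sample_to = igraph::V(g)$sample_id[vj],
    group_from = igraph::V(g)$group[vi],
    group_to = igraph::V(g)$group[vj],
    stringsAsFactors = FALSE
  )
}

#' Diagnosis-group sharing counts
#'
#' Counts similarity edges between (and within) diagnosis groups. Each
#' similarity edge increments the cell for its unordered group pair;
#' within-group edges land on the diagonal. Edges between two clonotypes of
#' the same sample are excluded by default, so counts describe sharing
#' between unique samples.
#'
#' @param net A `tcr_network`.
#' @param include_within_sample Also count edges joining two clonotypes of
#'   the same sample (default `FALSE`).
#' @return A symmetric integer matrix over the sorted group labels.
#' @export
group_sharing_counts <- function(net, include_within_sample = FALSE) {
  stopifnot(inherits(net, "tcr_network"))
  groups <- sort(unique(igraph::V(net$graph)$group))
  m <- matrix(0L, length(groups), length(groups),
              dimnames = list(groups, groups))
  ed <- network_similarity_edges(net)
  if (!include_within_sample && nrow(ed)) {
    ed <- ed[ed$sample_from != ed$sample_to, , drop = FALSE]
  }
  for (r in seq_len(nrow(ed))) {
    gi <- ed$group_from[r]; gj <- ed$group_to[r]
    m[gi, gj] <- m[gi, gj] + 1L
    if (gi != gj) m[gj, gi] <- m[gj, gi] + 1L
  }
  m
}

#' Export a TCR network
#'
#' Writes the network as GraphML (a single file) or as a pair of node/edge
#' CSVs (`<path>_nodes.csv`, `<path>_edges.csv`). Both formats round-trip
#' through [import_network()].
#'
#' @param net A `tcr_network`.
#' @param path Output path (GraphML file, or basename for the CSV pair).
#' @param format `"graphml"` or `"edge_csv"`.
#' @return Character vector of files written, invisibly.
#' @export
export_network <- function(net, path, format = c("graphml", "edge_csv")) {
  format <- match.arg(format)
  stopifnot(inherits(net, "tcr_network"))
  g <- net$graph
  if (format == "graphml") {
    igraph::write_graph(g, path, format = "graphml")
    return(invisible(path))
  }
  nodes <- data.frame(
    name = igraph::V(g)$name, kind = igraph::V(g)$kind,
    sample_id = igraph::V(g)$sample_id, group = igraph::V(g)$group,
    cdr3a = igraph::V(g)$cdr3a, cdr3b = igraph::V(g)$cdr3b,
    size = igraph::V(g)$size, stringsAsFactors = FALSE
  )
  ends <- igraph::ends(g, igraph::E(g))
  edges <- data.frame(
    from = ends[, 1L], to = ends[, 2L],
    kind = igraph::E(g)$kind, lsim = igraph::E(g)$lsim,
    stringsAsFactors = FALSE
  )
  files <- c(paste0(path, "_nodes.csv"), paste0(path, "_edges.csv"))
  data.table::fwrite(nodes, files[1L], na = "NA")
  data.table::fwrite(edges, files[2L], na = "NA")
  invisible(files)
}

#' Re-import an exported TCR network
#'
#' @param path Path given to [export_network()].
#' @param format `"graphml"` or `"edge_csv"`.
#' @param tau Threshold recorded on the re-imported object (GraphML does
#'   not carry it).
#' @return A `tcr_network`.
#' @export
import_network <- function(path, format = c("graphml", "edge_csv"),
                           tau = NA_real_) {
  format <- match.arg(format)
  if (format == "graphml") {
    g <- igraph::read_graph(path, format = "graphml")
  } else {
    nodes <- data.table::fread(paste0(path, "_nodes.csv"), data.table = FALSE,
                               na.strings = "NA")
    edges <- data.table::fread(paste0(path, "_edges.csv"), data.table = FALSE,
                               na.strings = "NA")
    g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                       vertices = nodes)
  }
  structure(list(graph = g, tau = tau), class = "tcr_network")
}

#' Plot a TCR sharing network
#'
#' Best-effort force-directed rendering: hubs drawn large and labelled with
#' the sample id, leaves small and coloured by diagnosis group, similarity
#' edges solid and attachment edges grey. Layout is cosmetic; analysis
#' should use the graph structure, not the picture.
#'
#' @param x A `tcr_network`.
#' @param ... Passed on to [igraph::plot.igraph()].
#' @export
plot.tcr_network <- function(x, ...) {
  g <- x$graph
  kind <- igraph::V(g)$kind
  groups <- factor(igraph::V(g)$group)
  palette <- grDevices::hcl.colors(max(2L, nlevels(groups)), "Dark 3")
  igraph::plot.igraph(
    g,
    layout = igraph::layout_with_fr(g),
    vertex.size = ifelse(kind == "hub", 9, 3),
    vertex.label = ifelse(kind == "hub", igraph::V(g)$sample_id, NA),
    vertex.label.cex = 0.7,
    vertex.color = palette[as.integer(groups)],
    edge.color = ifelse(igraph::E(g)$kind == "attachment", "grey80", "grey20"),
    edge.width = ifelse(igraph::E(g)$kind == "attachment", 0.5, 1.5),
    ...
  )
  invisible(x)
}
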