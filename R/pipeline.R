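# End-to-end workflow: convert -> assemble -> unambiguity filter ->
# clonotypes -> clonal filter -> pairwise L-sim -> clusters -> network ->
# motifs, with all intermediate tables and a run manifest written to an
# output directory. Per-stage record counts go to the log so the filter
# chain is auditable.

#' Run the full TCR similarity workflow
#'
#' @param inputs Either a contig data.frame (e.g. from
#'   [generate_repertoire()]`$contigs`), or a named character vector of
#'   file paths, one per sample (names are the sample ids).
#' @param metadata Sample metadata data.frame (`sample_id`,
#'   `diagnosis_group`) or path to such a CSV. `NULL` assigns "unknown".
#' @param out_dir Output directory; created if needed.
#' @param format Input file format when `inputs` are paths: `"10x"` or
#'   `"airr"`.
#' @param mode `"paired"` or `"beta_only"` chain handling.
#' @param scope Clonotype scope, `"within_sample"` (default) or `"global"`.
#' @param pairing_mode Chain pairing for L-sim; default `"concat_ab"`
#'   (`"beta_only"` is forced when `mode = "beta_only"`).
#' @param tau Similarity threshold (strict `>`).
#' @param min_clone_size Clonal-expansion cutoff (default 2).
#' @param trim,min_length Motif enumeration parameters.
#' @param motif_length Optional length for a ranked motif report.
#' @param db Optional path to a McPAS-format specificity database; the top
#'   motif of `motif_length` is searched against it.
#' @param seed Optional integer seed recorded in the manifest (the pipeline
#'   itself is deterministic).
#' @return Invisibly, a list with every intermediate object
#'   (`repertoire`, `cells`, `clonotypes`, `clonal`, `matrix`, `clusters`,
#'   `network`, `group_counts`, `motifs`, `manifest`).
#' @export
run_pipeline <- function(inputs, metadata = NULL, out_dir,
                         format = c("10x", "airr"),
                         mode = c("paired", "beta_only"),
                         scope = c("within_sample", "global"),
                         pairing_mode = NULL,
                         tau = 0.8, min_clone_size = 2L,
                         trim = 2L, min_length = 3L,
                         motif_length = NULL, db = NULL, seed = NULL) {
  format <- match.arg(format)
  mode <- match.arg(mode)
  scope <- match.arg(scope)
  if (is.null(pairing_mode)) {
    pairing_mode <- if (mode == "beta_only") "beta_only" else "concat_ab"
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  t0 <- Sys.time()

  input_paths <- NULL
  if (is.data.frame(inputs)) {
    contigs <- inputs
    if (!"usable" %in% names(contigs)) contigs <- normalise_contigs(contigs)
  } else {
    stopifnot(is.character(inputs), !is.null(names(inputs)))
    input_paths <- inputs
    reader <- if (format == "10x") read_cellranger_contigs else read_airr
    contigs <- do.call(rbind, lapply(names(inputs), function(sid)
      reader(inputs[[sid]], sid)))
  }
  if (is.character(metadata)) {
    metadata <- data.table::fread(metadata, data.table = FALSE,
                                  colClasses = "character")
  }
  rep <- tcr_repertoire(contigs, metadata,
                        provenance = list(paths = input_paths,
                                          format = format))
  message(sprintf("stage convert: %d contigs from %d sample(s)",
                  nrow(rep$contigs), nrow(rep$metadata)))

  cells <- assemble_cells(rep$contigs)
  message(sprintf("stage assemble: %d cells", nrow(cells)))
  cells_ok <- filter_unambiguous(cells, mode)
  clonotypes <- call_clonotypes(cells_ok, mode, scope, rep$metadata)
  message(sprintf("stage clonotypes: %d clonotypes from %d cells",
                  nrow(clonotypes), nrow(cells_ok)))
  clonal <- filter_clonal(clonotypes, min_clone_size)
  write_table <- function(df, name) {
    data.table::fwrite(df, file.path(out_dir, name), na = "NA")
  }
  write_table(as.data.frame(clonotypes), "clonotypes.csv")
  write_table(as.data.frame(clonal), "clonal_clonotypes.csv")

  if (nrow(clonal) < 2L) {
    stop("stage similarity: fewer than two clonal clonotypes", call. = FALSE)
  }
  smat <- pairwise_lsim(clonal, pairing_mode)
  write_table(lsim_pairs(smat), "similarity_long.csv")
  dist <- lsim_distribution(smat)
  write_table(data.frame(bin_lower = dist$breaks[-length(dist$breaks)],
                         bin_upper = dist$breaks[-1L],
                         count = dist$counts),
              "similarity_histogram.csv")
  message(sprintf("stage similarity: %d pairs, mean L-sim %.3f",
                  dist$n_pairs, dist$mean))

  clusters <- threshold_clusters(smat, tau, clonal)
  write_table(clusters, "clusters.csv")
  message(sprintf("stage clusters: %d cluster(s) at tau=%g",
                  length(unique(clusters$cluster_id)), tau))

  net <- build_network(clonal, smat, tau, rep$metadata)
  export_network(net, file.path(out_dir, "network.graphml"), "graphml")
  export_network(net, file.path(out_dir, "network"), "edge_csv")
  gc_mat <- group_sharing_counts(net)
  write_table(data.frame(group = rownames(gc_mat), gc_mat,
                         check.names = FALSE),
              "group_sharing.csv")
  message(sprintf("stage network: %d similarity edge(s)",
                  sum(igraph::E(net$graph)$kind == "similarity")))

  motifs <- enumerate_motifs(clonal, trim = trim, min_length = min_length)
  write_table(motifs, "motifs.csv")
  report <- NULL
  hits <- NULL
  if (!is.null(motif_length)) {
    report <- motif_report(motifs, motif_length)
    write_table(report, sprintf("motif_report_len%d.csv", motif_length))
    if (!is.null(db) && nrow(report)) {
      dbt <- read_specificity_db(db)
      hits <- search_motif(report$motif[1L], dbt)
      if (nrow(hits$by_pathology)) {
        write_table(hits$by_pathology, "top_motif_pathology.csv")
      }
    }
  }
  message(sprintf("stage motifs: %d distinct motif(s)", nrow(motifs)))

  manifest <- list(
    tool = "tcrsimnet",
    version = as.character(utils::packageVersion("tcrsimnet")),
    parameters = list(format = format, mode = mode, scope = scope,
                      pairing_mode = pairing_mode, tau = tau,
                      min_clone_size = min_clone_size, trim = trim,
                      min_length = min_length,
                      motif_length = motif_length),
    inputs = if (!is.null(input_paths)) {
      list(paths = unname(input_paths),
           md5 = unname(tools::md5sum(input_paths)))
    } else {
      list(in_memory_contigs = nrow(contigs))
    },
    seed = seed,
    started = format(t0, "%Y-%m-%dT%H:%M:%S%z"),
    finished = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, null = "null", pretty = TRUE)

  invisible(list(repertoire = rep, cells = cells, cells_unambiguous = cells_ok,
                 clonotypes = clonotypes, clonal = clonal, matrix = smat,
                 distribution = dist, clusters = clusters, network = net,
                 group_counts = gc_mat, motifs = motifs,
                 motif_report = report, motif_hits = hits,
                 manifest = manifest))
}
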