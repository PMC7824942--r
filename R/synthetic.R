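# Synthetic multi-sample repertoire generator with known ground truth:
# planted expanded clones, planted similarity clusters (seed pair mutated
# within a known edit radius) and planted CDR3beta motifs, on top of a
# background of unrelated CDR3s. Background sequences are rejection-sampled
# so their L-sim to every planted seed stays below (tau - margin), which
# makes cluster recovery separable by construction.

random_cdr3 <- function(n_len) {
  # C...F termini with a random interior, mimicking conserved junction ends
  paste0("C",
         paste(sample(AA_ALPHABET, n_len - 2L, replace = TRUE), collapse = ""),
         "F")
}

AA_CODON <- c(
  A = "GCT", C = "TGT", D = "GAT", E = "GAA", F = "TTT", G = "GGT",
  H = "CAT", I = "ATT", K = "AAA", L = "CTG", M = "ATG", N = "AAT",
  P = "CCT", Q = "CAA", R = "CGT", S = "AGT", T = "ACT", V = "GTT",
  W = "TGG", Y = "TAT"
)

aa_to_nt <- function(aa) {
  vapply(strsplit(aa, ""), function(ch)
    paste(AA_CODON[ch], collapse = ""), "")
}

#' Default planted similarity clusters
#'
#' Three clusters of 4, 5 and 6 variants, each variant one interior
#' substitution away from the cluster's seed pair (so every within-cluster
#' pair differs by at most two edits over the ~26-residue concatenated
#' alpha-beta string, L-sim >= 0.92), assigned to AD and MCI samples with
#' clone size 2. Seed beta chains are 12 residues long, keeping trimmed
#' beta below 9 residues so cluster members cannot shadow a planted
#' length-9 motif.
#'
#' @param n_variants Cluster sizes.
#' @param groups Diagnosis groups whose samples host the cluster members.
#' @return List of cluster specifications for [sim_config()].
#' @export
planted_cluster_spec <- function(n_variants = c(4L, 5L, 6L),
                                 groups = c("AD", "MCI")) {
  lapply(n_variants, function(k)
    list(n_variants = k, radius = 1L, clone_size = 2L, groups = groups,
         alpha_len = 14L, beta_len = 12L))
}

#' Default planted motif
#'
#' One 9-residue motif carried in the trimmed interior of the CDR3beta of
#' five otherwise-unrelated clonal clonotypes in AD/MCI samples.
#'
#' @param motif Motif string.
#' @param carriers Number of distinct carrier clonotypes.
#' @param groups Host diagnosis groups.
#' @return List of motif specifications for [sim_config()].
#' @export
planted_motif_spec <- function(motif = "GTNQVWEAF", carriers = 5L,
                               groups = c("AD", "MCI")) {
  list(list(motif = toupper(motif), carriers = carriers, clone_size = 2L,
            groups = groups))
}

#' Simulation configuration
#'
#' Describes a synthetic cohort. Defaults emulate the study design the
#' package targets: a four-group cohort (8 HC, 4 AD, 5 MCI, 7 PD samples)
#' of ~1300 sequenced cells per sample, background CDR3s of uniform length
#' 10-18 starting with C and ending with F, geometric clone sizes, a small
#' rate of ambiguous (two-beta) and non-productive contigs, and the planted
#' structure of [planted_cluster_spec()] / [planted_motif_spec()].
#'
#' @param groups Named integer vector: samples per diagnosis group.
#' @param cells_per_sample Sequenced cells per sample.
#' @param cdr3_len_range Inclusive background CDR3 length range.
#' @param clone_geom_prob Geometric parameter for extra clone members;
#'   clone size = floor + rgeom(p).
#' @param clone_size_floor Minimum background clone size (default 1; set 2
#'   to make every background clone clonal).
#' @param planted_clusters,planted_motifs Planted structure; see
#'   [planted_cluster_spec()] and [planted_motif_spec()]. Either may be an
#'   empty `list()`.
#' @param ambiguous_rate Probability a background cell gains a second
#'   productive beta contig (removed by the unambiguity filter).
#' @param nonproductive_rate Probability a background cell gains an extra
#'   non-productive contig (removed at assembly).
#' @param tau Design similarity threshold the planted structure targets.
#' @param margin Rejection margin: background-to-seed L-sim is kept below
#'   `tau - margin`.
#' @param seed Integer random seed recorded in provenance.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(groups = c(HC = 8L, AD = 4L, MCI = 5L, PD = 7L),
                       cells_per_sample = 1300L,
                       cdr3_len_range = c(10L, 18L),
                       clone_geom_prob = 0.45,
                       clone_size_floor = 1L,
                       planted_clusters = planted_cluster_spec(),
                       planted_motifs = planted_motif_spec(),
                       ambiguous_rate = 0.05,
                       nonproductive_rate = 0.05,
                       tau = 0.8,
                       margin = 0.1,
                       seed = 1L) {
  stopifnot(length(groups) >= 1L, all(groups >= 1L),
            !is.null(names(groups)),
            cells_per_sample >= 1L,
            length(cdr3_len_range) == 2L,
            cdr3_len_range[1L] >= 6L,
            cdr3_len_range[1L] <= cdr3_len_range[2L],
            clone_geom_prob > 0, clone_geom_prob <= 1,
            clone_size_floor >= 1L,
            ambiguous_rate >= 0, ambiguous_rate <= 1,
            nonproductive_rate >= 0, nonproductive_rate <= 1,
            tau > 0, tau < 1, margin > 0, margin < tau)
  for (pc in planted_clusters) {
    len <- pc$alpha_len + pc$beta_len
    if (1 - 2 * pc$radius / len <= tau) {
      stop("infeasible cluster: radius too large for tau at this length",
           call. = FALSE)
    }
  }
  for (pm in planted_motifs) {
    # interior insert needs C + >=1 residue each side + F within max length
    if (nchar(pm$motif) + 6L > cdr3_len_range[2L] + 4L) {
      stop("infeasible motif: longer than the available CDR3 interior",
           call. = FALSE)
    }
  }
  structure(
    list(groups = groups, cells_per_sample = as.integer(cells_per_sample),
         cdr3_len_range = as.integer(cdr3_len_range),
         clone_geom_prob = clone_geom_prob,
         clone_size_floor = as.integer(clone_size_floor),
         planted_clusters = planted_clusters,
         planted_motifs = planted_motifs,
         ambiguous_rate = ambiguous_rate,
         nonproductive_rate = nonproductive_rate,
         tau = tau, margin = margin, seed = as.integer(seed)),
    class = "sim_config"
  )
}

substitute_at <- function(s, pos) {
  old <- substr(s, pos, pos)
  repl <- sample(setdiff(AA_ALPHABET, old), 1L)
  substr(s, pos, pos) <- repl
  s
}

# One variant = `radius` interior substitutions of the seed pair,
# alternating between the two chains so both carry signal.
mutate_pair <- function(seed_a, seed_b, radius) {
  a <- seed_a; b <- seed_b
  for (r in seq_len(radius)) {
    if (stats::runif(1) < 0.5) {
      a <- substitute_at(a, sample(3:(nchar(a) - 2L), 1L))
    } else {
      b <- substitute_at(b, sample(3:(nchar(b) - 2L), 1L))
    }
  }
  c(a, b)
}

max_lsim_to <- function(strings, refs) {
  if (!length(refs)) return(rep(0, length(strings)))
  apply(cpp_lsim_cross(strings, refs), 1L, max)
}

#' Generate a synthetic repertoire with ground truth
#'
#' Emits a 10x-dialect contig table for a whole cohort plus sample
#' metadata and the planted ground truth. Deterministic for a fixed
#' `config$seed`. See [sim_config()] for the knobs and
#' [write_sim_repertoire()] to materialise per-sample files.
#'
#' @param config A `sim_config`.
#' @return An object of class `sim_repertoire`: `contigs` (one table for
#'   the whole cohort, 10x column dialect plus `sample_id`), `metadata`,
#'   `truth` (per-cell origins, planted cluster members, planted motif
#'   carriers) and the `config`.
#' @export
generate_repertoire <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  tau <- config$tau
  margin <- config$margin
  reject_cap <- tau - margin

  metadata <- do.call(rbind, lapply(names(config$groups), function(g) {
    data.frame(sample_id = sprintf("%s%02d", g, seq_len(config$groups[[g]])),
               diagnosis_group = g, stringsAsFactors = FALSE)
  }))

  # --- planted cluster seeds, mutually separated ------------------------
  n_cl <- length(config$planted_clusters)
  seed_sep <- max(0, reject_cap - 0.1)
  repeat {
    seeds <- lapply(config$planted_clusters, function(pc)
      c(random_cdr3(pc$alpha_len), random_cdr3(pc$beta_len)))
    concat <- vapply(seeds, function(s) paste0(s[1L], s[2L]), "")
    if (n_cl < 2L) break
    pair_ok <- TRUE
    for (i in seq_len(n_cl - 1L)) {
      if (any(cpp_lsim_cross(concat[i], concat[-seq_len(i)]) >= seed_sep)) {
        pair_ok <- FALSE
        break
      }
    }
    if (pair_ok) break
  }
  seed_concat <- if (n_cl) vapply(seeds, function(s) paste0(s[1L], s[2L]), "")
                 else character()

  sample_pool <- function(groups) {
    s <- metadata$sample_id[metadata$diagnosis_group %in% groups]
    if (!length(s)) stop("no samples in groups: ",
                         paste(groups, collapse = ","), call. = FALSE)
    sort(s)
  }

  planted <- list()  # rows: sample_id, cdr3a, cdr3b, size, origin
  truth_clusters <- list()
  for (k in seq_len(n_cl)) {
    pc <- config$planted_clusters[[k]]
    pool <- sample_pool(pc$groups)
    variants <- character(0)
    rows <- vector("list", pc$n_variants)
    for (v in seq_len(pc$n_variants)) {
      repeat {
        ab <- mutate_pair(seeds[[k]][1L], seeds[[k]][2L], pc$radius)
        key <- paste0(ab[1L], ab[2L])
        if (!key %in% variants) break
      }
      variants <- c(variants, paste0(ab[1L], ab[2L]))
      sid <- pool[((v - 1L) %% length(pool)) + 1L]
      rows[[v]] <- data.frame(
        sample_id = sid, cdr3a = ab[1L], cdr3b = ab[2L],
        size = pc$clone_size, origin = sprintf("cluster%d", k),
        stringsAsFactors = FALSE)
    }
    truth_clusters[[k]] <- do.call(rbind, rows)
  }
  planted <- truth_clusters

  # --- planted motif carriers ------------------------------------------
  truth_motifs <- list()
  all_motifs <- vapply(config$planted_motifs, function(pm) pm$motif, "")
  for (m in seq_along(config$planted_motifs)) {
    pm <- config$planted_motifs[[m]]
    pool <- sample_pool(pm$groups)
    seen <- character(0)
    rows <- vector("list", pm$carriers)
    for (v in seq_len(pm$carriers)) {
      repeat {
        n1 <- sample(2:4, 1L)  # >=2 residues inside each trimmed end
        n2 <- sample(2:4, 1L)
        b <- paste0("C", paste(sample(AA_ALPHABET, n1, TRUE), collapse = ""),
                    pm$motif,
                    paste(sample(AA_ALPHABET, n2, TRUE), collapse = ""), "F")
        a <- random_cdr3(sample(config$cdr3_len_range[1L]:config$cdr3_len_range[2L], 1L))
        key <- paste0(a, b)
        if (key %in% seen) next
        if (any(max_lsim_to(key, seed_concat) >= reject_cap)) next
        break
      }
      seen <- c(seen, key)
      sid <- pool[((v - 1L) %% length(pool)) + 1L]
      rows[[v]] <- data.frame(
        sample_id = sid, cdr3a = a, cdr3b = b, size = pm$clone_size,
        origin = sprintf("motif%d", m), stringsAsFactors = FALSE)
    }
    truth_motifs[[m]] <- do.call(rbind, rows)
  }
  planted <- c(planted, truth_motifs)
  planted_df <- if (length(planted)) do.call(rbind, planted) else
    data.frame(sample_id = character(), cdr3a = character(),
               cdr3b = character(), size = integer(), origin = character(),
               stringsAsFactors = FALSE)

  # --- per-sample assembly ---------------------------------------------
  lens <- config$cdr3_len_range
  trim_guard <- function(cdr3b) {
    # background must not accidentally carry a planted motif
    if (!length(all_motifs)) return(TRUE)
    trimmed <- substr(cdr3b, 3L, nchar(cdr3b) - 2L)
    !any(vapply(all_motifs, function(m) grepl(m, trimmed, fixed = TRUE),
                TRUE))
  }
  sample_clones <- function(sid) {
    p <- planted_df[planted_df$sample_id == sid, , drop = FALSE]
    used <- sum(p$size)
    if (used > config$cells_per_sample) {
      stop(sprintf("planted cells exceed cells_per_sample in '%s'", sid),
           call. = FALSE)
    }
    keys <- paste(p$cdr3a, p$cdr3b)
    bg <- list()
    while (used < config$cells_per_sample) {
      size <- config$clone_size_floor + rgeom(1L, config$clone_geom_prob)
      size <- min(size, config$cells_per_sample - used)
      repeat {
        a <- random_cdr3(sample(lens[1L]:lens[2L], 1L))
        b <- random_cdr3(sample(lens[1L]:lens[2L], 1L))
        key <- paste(a, b)
        if (key %in% keys) next
        if (!trim_guard(b)) next
        if (any(max_lsim_to(paste0(a, b), seed_concat) >= reject_cap)) next
        break
      }
      keys <- c(keys, key)
      bg[[length(bg) + 1L]] <- data.frame(
        sample_id = sid, cdr3a = a, cdr3b = b, size = size,
        origin = "background", stringsAsFactors = FALSE)
      used <- used + size
    }
    rbind(p, do.call(rbind, bg))
  }

  clone_tables <- lapply(metadata$sample_id, sample_clones)
  clones <- do.call(rbind, clone_tables)

  # --- cells and contigs -----------------------------------------------
  n_cells <- sum(clones$size)
  cell_clone <- rep(seq_len(nrow(clones)), clones$size)
  cell_sample <- clones$sample_id[cell_clone]
  barcode_one <- function() paste0(
    paste(sample(c("A", "C", "G", "T"), 16L, TRUE), collapse = ""), "-1")
  barcodes <- character(n_cells)
  for (i in seq_len(n_cells)) barcodes[i] <- barcode_one()
  # regenerate any barcode colliding within its sample
  repeat {
    dup <- duplicated(paste(cell_sample, barcodes))
    if (!any(dup)) break
    barcodes[dup] <- vapply(which(dup), function(i) barcode_one(), "")
  }

  cells <- data.frame(
    sample_id = cell_sample, barcode = barcodes,
    cdr3a = clones$cdr3a[cell_clone], cdr3b = clones$cdr3b[cell_clone],
    origin = clones$origin[cell_clone], stringsAsFactors = FALSE
  )
  is_bg <- cells$origin == "background"
  extra_beta <- is_bg & stats::runif(n_cells) < config$ambiguous_rate
  extra_nonprod <- is_bg & stats::runif(n_cells) < config$nonproductive_rate
  cells$ambiguous <- extra_beta

  gene <- function(prefix, n) sprintf("%s%d", prefix, sample(1:30, n, TRUE))
  base_contig <- function(chain, cdr3) {
    data.frame(
      barcode = cells$barcode, sample_id = cells$sample_id,
      chain = chain, cdr3 = cdr3, cdr3_nt = aa_to_nt(cdr3),
      v_gene = gene(paste0("TR", substr(chain, 3L, 3L), "V"), n_cells),
      j_gene = gene(paste0("TR", substr(chain, 3L, 3L), "J"), n_cells),
      productive = "True", high_confidence = "True",
      stringsAsFactors = FALSE
    )
  }
  contigs <- rbind(base_contig("TRA", cells$cdr3a),
                   base_contig("TRB", cells$cdr3b))
  if (any(extra_beta)) {
    idx <- which(extra_beta)
    amb_cdr3 <- vapply(sample(lens[1L]:lens[2L], length(idx), TRUE),
                       random_cdr3, "")
    contigs <- rbind(contigs, data.frame(
      barcode = cells$barcode[idx], sample_id = cells$sample_id[idx],
      chain = "TRB", cdr3 = amb_cdr3, cdr3_nt = aa_to_nt(amb_cdr3),
      v_gene = gene("TRBV", length(idx)), j_gene = gene("TRBJ", length(idx)),
      productive = "True", high_confidence = "True",
      stringsAsFactors = FALSE))
  }
  if (any(extra_nonprod)) {
    idx <- which(extra_nonprod)
    np_cdr3 <- vapply(sample(lens[1L]:lens[2L], length(idx), TRUE),
                      random_cdr3, "")
    contigs <- rbind(contigs, data.frame(
      barcode = cells$barcode[idx], sample_id = cells$sample_id[idx],
      chain = "TRA", cdr3 = np_cdr3, cdr3_nt = aa_to_nt(np_cdr3),
      v_gene = gene("TRAV", length(idx)), j_gene = gene("TRAJ", length(idx)),
      productive = "False", high_confidence = "True",
      stringsAsFactors = FALSE))
  }
  contigs <- contigs[order(contigs$sample_id, contigs$barcode,
                           contigs$chain, contigs$cdr3), , drop = FALSE]
  rownames(contigs) <- NULL

  truth <- list(
    cells = cells,
    clusters = if (n_cl) do.call(rbind, truth_clusters) else NULL,
    cluster_sizes = vapply(config$planted_clusters,
                           function(pc) pc$n_variants, 1L),
    motifs = if (length(truth_motifs)) do.call(rbind, truth_motifs) else NULL,
    motif_specs = config$planted_motifs,
    seed = config$seed
  )
  structure(
    list(contigs = contigs, metadata = metadata, truth = truth,
         config = config),
    class = "sim_repertoire"
  )
}

#' @export
print.sim_repertoire <- function(x, ...) {
  cat(sprintf(
    "<sim_repertoire> %d samples, %d cells, %d contigs (seed %d)\n",
    nrow(x$metadata), nrow(x$truth$cells), nrow(x$contigs), x$truth$seed))
  invisible(x)
}

#' Write a synthetic repertoire to disk
#'
#' Materialises one contig file per sample (10x CSV dialect or AIRR TSV)
#' plus `metadata.csv` under `out_dir`.
#'
#' @param sim A `sim_repertoire`.
#' @param out_dir Output directory (created if needed).
#' @param format `"10x"` or `"airr"`.
#' @return Named character vector of the files written, invisibly.
#' @export
write_sim_repertoire <- function(sim, out_dir, format = c("10x", "airr")) {
  format <- match.arg(format)
  stopifnot(inherits(sim, "sim_repertoire"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  files <- c(metadata = file.path(out_dir, "metadata.csv"))
  data.table::fwrite(sim$metadata, files[["metadata"]])
  for (sid in sim$metadata$sample_id) {
    rows <- sim$contigs[sim$contigs$sample_id == sid, , drop = FALSE]
    if (format == "10x") {
      path <- file.path(out_dir, paste0(sid, "_contig_annotations.csv"))
      out <- rows[, c("barcode", "chain", "v_gene", "j_gene", "cdr3",
                      "cdr3_nt", "productive", "high_confidence")]
      data.table::fwrite(out, path)
    } else {
      path <- file.path(out_dir, paste0(sid, "_airr.tsv"))
      out <- data.frame(
        cell_id = rows$barcode, repertoire_id = rows$sample_id,
        locus = rows$chain, junction_aa = rows$cdr3,
        junction = rows$cdr3_nt, v_call = rows$v_gene, j_call = rows$j_gene,
        productive = ifelse(parse_flag(rows$productive), "T", "F"),
        high_confidence = ifelse(parse_flag(rows$high_confidence), "T", "F"),
        stringsAsFactors = FALSE)
      data.table::fwrite(out, path, sep = "\t", quote = FALSE)
    }
    files[[sid]] <- path
  }
  invisible(files)
}

#' Score recovery of planted structure
#'
#' Compares pipeline output against the generator's ground truth. For each
#' planted cluster the best-matching detected cluster is found; recall is
#' the fraction of planted members it contains and contamination the number
#' of its members that were not planted in that cluster. For each planted
#' motif the rank and frequency at its length are reported.
#'
#' @param truth A `sim_repertoire` or its `$truth` element.
#' @param clonotypes The `tcr_clonotypes` table called from the generated
#'   data (within-sample scope).
#' @param clusters Membership table from [threshold_clusters()].
#' @param motifs Optional motif table from [enumerate_motifs()].
#' @return A list of class `recovery_report` with data.frames `clusters`
#'   (`cluster, n_planted, n_recovered, recall, contamination`) and
#'   `motifs` (`motif, designed_frequency, observed_frequency, rank`).
#' @export
score_recovery <- function(truth, clonotypes, clusters, motifs = NULL) {
  if (inherits(truth, "sim_repertoire")) truth <- truth$truth
  key <- function(df) paste(df$sample_id, df$cdr3a, df$cdr3b, sep = "\r")
  ct_key <- key(clonotypes)

  cl_report <- NULL
  if (!is.null(truth$clusters)) {
    tc <- truth$clusters
    tc$clonotype_id <- clonotypes$clonotype_id[match(key(tc), ct_key)]
    if (anyNA(tc$clonotype_id)) {
      stop("planted cluster member missing from clonotype table (id mismatch)",
           call. = FALSE)
    }
    detected_of <- clusters$cluster_id[match(tc$clonotype_id,
                                             clusters$clonotype_id)]
    cl_report <- do.call(rbind, lapply(
      sort(unique(tc$origin)), function(orig) {
        members <- tc$clonotype_id[tc$origin == orig]
        det <- detected_of[tc$origin == orig]
        det <- det[!is.na(det)]
        if (!length(det)) {
          return(data.frame(cluster = orig, n_planted = length(members),
                            n_recovered = 0L, recall = 0,
                            contamination = 0L, stringsAsFactors = FALSE))
        }
        best <- names(sort(table(det), decreasing = TRUE))[1L]
        in_best <- clusters$clonotype_id[clusters$cluster_id == best]
        data.frame(
          cluster = orig, n_planted = length(members),
          n_recovered = sum(members %in% in_best),
          recall = sum(members %in% in_best) / length(members),
          contamination = sum(!in_best %in% members),
          stringsAsFactors = FALSE)
      }))
  }

  mt_report <- NULL
  if (!is.null(motifs) && length(truth$motif_specs)) {
    mt_report <- do.call(rbind, lapply(truth$motif_specs, function(pm) {
      rep_tab <- motif_report(motifs, nchar(pm$motif))
      pos <- match(pm$motif, rep_tab$motif)
      data.frame(
        motif = pm$motif, designed_frequency = pm$carriers,
        observed_frequency = if (is.na(pos)) 0L else rep_tab$frequency[pos],
        rank = if (is.na(pos)) NA_integer_ else pos,
        stringsAsFactors = FALSE)
    }))
  }
  structure(list(clusters = cl_report, motifs = mt_report),
            class = "recovery_report")
}

#' @export
print.recovery_report <- function(x, ...) {
  if (!is.null(x$clusters)) {
    cat("planted clusters:\n")
    print(x$clusters, row.names = FALSE)
  }
  if (!is.null(x$motifs)) {
    cat("planted motifs:\n")
    print(x$motifs, row.names = FALSE)
  }
  invisible(x)
}
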