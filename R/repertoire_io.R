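# Reading, validating and writing per-cell TCR contig tables.
#
# Contigs are represented as a plain data.frame with one row per contig and
# the normalised columns: barcode, sample_id, chain, cdr3_aa, cdr3_nt,
# v_gene, j_gene, productive, high_confidence, usable. Parsing is lossless:
# every input row yields a row here; unusable CDR3s are flagged, never
# dropped, so the effect of each downstream filter can be audited.

CONTIG_COLUMNS <- c(
  "barcode", "sample_id", "chain", "cdr3_aa", "cdr3_nt",
  "v_gene", "j_gene", "productive", "high_confidence", "usable"
)

# Column-name synonyms, matched case-insensitively after stripping
# non-alphanumeric characters (so "CDR3.beta.aa" == "cdr3betaaa").
normalise_colname <- function(x) gsub("[^a-z0-9]", "", tolower(x))

match_column <- function(cols, synonyms) {
  norm <- normalise_colname(cols)
  for (s in synonyms) {
    hit <- which(norm == normalise_colname(s))
    if (length(hit)) return(cols[hit[1L]])
  }
  NA_character_
}

parse_flag <- function(x) {
  if (is.logical(x)) return(x)
  x <- tolower(trimws(as.character(x)))
  out <- rep(NA, length(x))
  out[x %in% c("true", "t", "yes", "y", "1")] <- TRUE
  out[x %in% c("false", "f", "no", "n", "0", "none", "")] <- FALSE
  out
}

classify_chain <- function(x) {
  x <- toupper(trimws(as.character(x)))
  out <- rep("other", length(x))
  out[x == "TRA"] <- "TRA"
  out[x == "TRB"] <- "TRB"
  out
}

cdr3_usable <- function(x) {
  !is.na(x) & grepl(AA_REGEX, x)
}

empty_contigs <- function() {
  data.frame(
    barcode = character(), sample_id = character(), chain = character(),
    cdr3_aa = character(), cdr3_nt = character(), v_gene = character(),
    j_gene = character(), productive = logical(),
    high_confidence = logical(), usable = logical(),
    stringsAsFactors = FALSE
  )
}

finalise_contigs <- function(df) {
  df$chain <- classify_chain(df$chain)
  df$cdr3_aa <- toupper(trimws(as.character(df$cdr3_aa)))
  df$cdr3_aa[is.na(df$cdr3_aa)] <- ""
  df$usable <- cdr3_usable(df$cdr3_aa)
  df$productive <- parse_flag(df$productive)
  df$productive[is.na(df$productive)] <- FALSE
  df$high_confidence <- parse_flag(df$high_confidence)
  df$high_confidence[is.na(df$high_confidence)] <- TRUE
  rownames(df) <- NULL
  df[, CONTIG_COLUMNS]
}

read_contig_table <- function(path, sample_id, sep, required, synonyms,
                              format_name) {
  if (!file.exists(path)) stop(sprintf("file '%s' not found", path), call. = FALSE)
  if (file.size(path) == 0L) {
    warning(sprintf("'%s' is empty", path), call. = FALSE)
    return(empty_contigs())
  }
  dt <- data.table::fread(path, sep = sep, header = TRUE,
                          colClasses = "character", data.table = FALSE,
                          na.strings = c("NA", ""))
  for (col in required) {
    if (is.na(match_column(names(dt), synonyms[[col]]))) {
      stop(sprintf("%s file '%s' is missing required column '%s'",
                   format_name, path, col), call. = FALSE)
    }
  }
  if (nrow(dt) == 0L) {
    warning(sprintf("'%s' contains no contig rows", path), call. = FALSE)
    return(empty_contigs())
  }
  pick <- function(col, default = NA_character_) {
    m <- match_column(names(dt), synonyms[[col]])
    if (is.na(m)) rep(default, nrow(dt)) else dt[[m]]
  }
  df <- data.frame(
    barcode = pick("barcode"),
    sample_id = if (is.null(sample_id)) pick("sample_id", NA_character_)
                else rep(sample_id, nrow(dt)),
    chain = pick("chain"),
    cdr3_aa = pick("cdr3_aa"),
    cdr3_nt = pick("cdr3_nt"),
    v_gene = pick("v_gene"),
    j_gene = pick("j_gene"),
    productive = pick("productive"),
    high_confidence = pick("high_confidence", "TRUE"),
    stringsAsFactors = FALSE
  )
  if (anyNA(df$sample_id)) {
    stop("sample_id must be supplied when the file carries no sample column",
         call. = FALSE)
  }
  finalise_contigs(df)
}

#' Read 10x Cell Ranger VDJ contig annotations
#'
#' Parses a `filtered_contig_annotations.csv`-dialect table into the
#' normalised contig representation used throughout the package. Every row
#' is kept: contigs from non-TCR loci are retained with `chain = "other"`,
#' and contigs whose CDR3 amino-acid string is empty, `"None"`, or contains
#' characters outside the 20 standard residues are flagged `usable = FALSE`
#' rather than dropped, so later filter steps are auditable.
#'
#' @param path Path to a comma-separated contig annotation file with at
#'   least barcode, chain, cdr3 and productive columns (case-insensitive;
#'   common synonyms such as `locus` or `junction_aa` are accepted).
#' @param sample_id Sample identifier attached to every contig. Barcodes
#'   are only unique within a sample, so this is required.
#' @return A data.frame with one row per contig and columns
#'   `barcode, sample_id, chain, cdr3_aa, cdr3_nt, v_gene, j_gene,
#'   productive, high_confidence, usable`.
#' @seealso [read_airr()], [assemble_cells()]
#' @export
read_cellranger_contigs <- function(path, sample_id) {
  stopifnot(is.character(sample_id), length(sample_id) == 1L)
  read_contig_table(
    path, sample_id, sep = ",",
    required = c("barcode", "chain", "cdr3_aa", "productive"),
    synonyms = list(
      barcode = c("barcode", "cell_id"),
      sample_id = c("sample_id", "sample"),
      chain = c("chain", "locus"),
      cdr3_aa = c("cdr3", "cdr3_aa", "junction_aa"),
      cdr3_nt = c("cdr3_nt", "junction"),
      v_gene = c("v_gene", "v_call"),
      j_gene = c("j_gene", "j_call"),
      productive = "productive",
      high_confidence = c("high_confidence", "is_cell_and_high_confidence")
    ),
    format_name = "10x contig annotation"
  )
}

#' Read an AIRR Rearrangement table
#'
#' Reads a tab-separated AIRR Rearrangement file into the same normalised
#' contig representation as [read_cellranger_contigs()]; `junction_aa` maps
#' to `cdr3_aa` and `locus` to `chain`.
#'
#' @param path Path to an AIRR Rearrangement TSV with at least
#'   `junction_aa`, `locus` and `productive` columns.
#' @param sample_id Sample identifier. May be `NULL` when the file carries
#'   a `repertoire_id` column (as written by [write_airr()]).
#' @return A contig data.frame; see [read_cellranger_contigs()].
#' @export
read_airr <- function(path, sample_id = NULL) {
  read_contig_table(
    path, sample_id, sep = "\t",
    required = c("barcode", "chain", "cdr3_aa", "productive"),
    synonyms = list(
      barcode = c("cell_id", "barcode"),
      sample_id = c("repertoire_id", "sample_id", "sample"),
      chain = c("locus", "chain"),
      cdr3_aa = c("junction_aa", "cdr3_aa", "cdr3"),
      cdr3_nt = c("junction", "cdr3_nt"),
      v_gene = c("v_call", "v_gene"),
      j_gene = c("j_call", "j_gene"),
      productive = "productive",
      high_confidence = "high_confidence"
    ),
    format_name = "AIRR Rearrangement"
  )
}

#' Normalise an in-memory contig data.frame
#'
#' Brings a raw contig table (e.g. the `contigs` element of a
#' [generate_repertoire()] result, or a data.frame assembled by hand with a
#' `cdr3` column) into the validated representation produced by the file
#' readers: synonym columns renamed, optional columns filled, chains
#' classified, booleans parsed, and the `usable` flag computed.
#'
#' @param contigs Data.frame with at least `barcode`, `sample_id`, `chain`
#'   and `cdr3` (or `cdr3_aa`) columns.
#' @return A contig data.frame; see [read_cellranger_contigs()].
#' @export
normalise_contigs <- function(contigs) {
  stopifnot(is.data.frame(contigs))
  if (!"cdr3_aa" %in% names(contigs) && "cdr3" %in% names(contigs)) {
    names(contigs)[names(contigs) == "cdr3"] <- "cdr3_aa"
  }
  required <- c("barcode", "sample_id", "chain", "cdr3_aa")
  miss <- setdiff(required, names(contigs))
  if (length(miss)) {
    stop("contig table is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (!"cdr3_nt" %in% names(contigs)) contigs$cdr3_nt <- NA_character_
  if (!"v_gene" %in% names(contigs)) contigs$v_gene <- NA_character_
  if (!"j_gene" %in% names(contigs)) contigs$j_gene <- NA_character_
  if (!"productive" %in% names(contigs)) contigs$productive <- TRUE
  if (!"high_confidence" %in% names(contigs)) contigs$high_confidence <- TRUE
  finalise_contigs(contigs)
}

#' Group contigs into per-cell TCR records
#'
#' Partitions contigs by `(sample_id, barcode)` into cells. Only
#' productive, usable TRA/TRB contigs populate a cell's alpha/beta chain
#' sets; everything else is counted but not carried forward, so a cell with
#' two productive beta contigs is visibly ambiguous downstream.
#'
#' @param contigs Contig data.frame from [read_cellranger_contigs()] or
#'   [read_airr()].
#' @param require_high_confidence Drop contigs not flagged high-confidence
#'   before populating chain sets (default `TRUE`).
#' @return A data.frame with one row per cell: `sample_id`, `barcode`,
#'   list-columns `alpha` and `beta` holding the usable CDR3 amino-acid
#'   strings of each chain, and the counts `n_alpha`, `n_beta`.
#' @export
assemble_cells <- function(contigs, require_high_confidence = TRUE) {
  stopifnot(is.data.frame(contigs))
  if (nrow(contigs) == 0L) {
    return(data.frame(
      sample_id = character(), barcode = character(),
      alpha = I(list()), beta = I(list()),
      n_alpha = integer(), n_beta = integer(), stringsAsFactors = FALSE
    ))
  }
  keep <- contigs$usable & contigs$productive & contigs$chain %in% c("TRA", "TRB")
  if (require_high_confidence) keep <- keep & contigs$high_confidence
  key <- paste(contigs$sample_id, contigs$barcode, sep = "\r")
  cells_key <- sort(unique(key))
  idx <- split(which(keep), factor(key[keep], levels = cells_key))
  parts <- strsplit(cells_key, "\r", fixed = TRUE)
  alpha <- lapply(idx, function(i) contigs$cdr3_aa[i][contigs$chain[i] == "TRA"])
  beta <- lapply(idx, function(i) contigs$cdr3_aa[i][contigs$chain[i] == "TRB"])
  out <- data.frame(
    sample_id = vapply(parts, `[`, "", 1L),
    barcode = vapply(parts, `[`, "", 2L),
    stringsAsFactors = FALSE
  )
  out$alpha <- unname(alpha)
  out$beta <- unname(beta)
  out$n_alpha <- lengths(out$alpha)
  out$n_beta <- lengths(out$beta)
  rownames(out) <- NULL
  out
}

#' Construct a validated repertoire
#'
#' Bundles a contig table with sample metadata. Every `sample_id` in the
#' contigs must appear in the metadata; missing samples are assigned the
#' diagnosis group `"unknown"` with a warning so no cell is silently lost.
#'
#' @param contigs Contig data.frame (possibly concatenated across samples).
#' @param metadata Data.frame with columns `sample_id` and
#'   `diagnosis_group`; extra columns are preserved. `NULL` builds a
#'   metadata table of all-"unknown" groups.
#' @param provenance Optional list recording source paths / parser dialect.
#' @return An object of class `tcr_repertoire`.
#' @export
tcr_repertoire <- function(contigs, metadata = NULL, provenance = list()) {
  stopifnot(is.data.frame(contigs))
  samples <- unique(contigs$sample_id)
  if (is.null(metadata)) {
    metadata <- data.frame(sample_id = samples,
                           diagnosis_group = "unknown",
                           stringsAsFactors = FALSE)
  }
  stopifnot(all(c("sample_id", "diagnosis_group") %in% names(metadata)))
  if (anyDuplicated(metadata$sample_id)) {
    stop("metadata sample_id values must be unique", call. = FALSE)
  }
  missing <- setdiff(samples, metadata$sample_id)
  if (length(missing)) {
    warning(sprintf(
      "%d sample(s) absent from metadata assigned diagnosis group 'unknown': %s",
      length(missing), paste(missing, collapse = ", ")), call. = FALSE)
    metadata <- rbind(
      metadata[, c("sample_id", "diagnosis_group"), drop = FALSE],
      data.frame(sample_id = missing, diagnosis_group = "unknown",
                 stringsAsFactors = FALSE)
    )
  }
  structure(
    list(contigs = contigs, metadata = metadata, provenance = provenance),
    class = "tcr_repertoire"
  )
}

#' @export
print.tcr_repertoire <- function(x, ...) {
  cat(sprintf(
    "<tcr_repertoire> %d contigs, %d cells, %d samples (%s)\n",
    nrow(x$contigs),
    length(unique(paste(x$contigs$sample_id, x$contigs$barcode))),
    nrow(x$metadata),
    paste(sort(unique(x$metadata$diagnosis_group)), collapse = "/")
  ))
  invisible(x)
}

#' Write contigs as an AIRR Rearrangement TSV
#'
#' Writes the usable TRA/TRB contigs of a repertoire (or raw contig table)
#' in AIRR Rearrangement layout. `other`-chain and unusable rows are
#' omitted and their count reported, so
#' `read_airr(write_airr(x))` reproduces exactly the usable contigs of `x`.
#'
#' @param x A `tcr_repertoire` or contig data.frame.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_airr <- function(x, path) {
  contigs <- if (inherits(x, "tcr_repertoire")) x$contigs else x
  stopifnot(is.data.frame(contigs))
  keep <- contigs$chain %in% c("TRA", "TRB") & contigs$usable
  n_omit <- sum(!keep)
  if (n_omit > 0L) {
    message(sprintf("write_airr: omitting %d non-TCR or unusable contig(s)",
                    n_omit))
  }
  out <- data.frame(
    cell_id = contigs$barcode[keep],
    repertoire_id = contigs$sample_id[keep],
    locus = contigs$chain[keep],
    junction_aa = contigs$cdr3_aa[keep],
    junction = contigs$cdr3_nt[keep],
    v_call = contigs$v_gene[keep],
    j_call = contigs$j_gene[keep],
    productive = ifelse(contigs$productive[keep], "T", "F"),
    high_confidence = ifelse(contigs$high_confidence[keep], "T", "F"),
    stringsAsFactors = FALSE
  )
  data.table::fwrite(out, path, sep = "\t", quote = FALSE, na = "")
  invisible(path)
}
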