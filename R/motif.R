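# Sliding-window CDR3beta motif enumeration with conserved-end trimming,
# and lookup of motifs in a McPAS-TCR-format specificity database.

#' Enumerate CDR3beta motifs by sliding window
#'
#' For each clonotype the first `trim` and last `trim` residues of the
#' CDR3beta are removed (the termini are germline-conserved and carry no
#' specificity signal), then every contiguous substring of length
#' `min_length` up to the full trimmed length is generated. A motif's
#' frequency is the number of distinct clonotypes whose trimmed CDR3beta
#' contains it, counted once per clonotype regardless of multiplicity, so
#' clone sizes do not inflate "shared" motifs.
#'
#' @param clonotypes A `tcr_clonotypes` table (typically the clonal subset
#'   from [filter_clonal()]).
#' @param trim Residues removed from each end (default 2).
#' @param min_length Shortest motif reported (default 3; set 1 to emit
#'   every size).
#' @param max_length Longest motif reported (default unlimited).
#' @return Data.frame `(motif, length, frequency, clonotype_ids, samples,
#'   groups)` with `clonotype_ids` (and supports) `;`-collapsed. Clonotypes
#'   whose trimmed CDR3beta is shorter than `min_length` contribute
#'   nothing; their count is reported via [message()].
#' @export
enumerate_motifs <- function(clonotypes, trim = 2L, min_length = 3L,
                             max_length = Inf) {
  stopifnot(is.data.frame(clonotypes), trim >= 0L, min_length >= 1L,
            max_length >= min_length)
  cdr3b <- clonotypes$cdr3b
  L <- nchar(cdr3b)
  trimmed <- substr(cdr3b, trim + 1L, L - trim)
  Lt <- pmax(0L, L - 2L * trim)
  skip <- Lt < min_length
  if (any(skip)) {
    message(sprintf(
      "enumerate_motifs: %d clonotype(s) with trimmed CDR3b shorter than %d skipped",
      sum(skip), min_length))
  }
  use <- which(!skip)
  if (!length(use)) {
    return(data.frame(motif = character(), length = integer(),
                      frequency = integer(), clonotype_ids = character(),
                      samples = character(), groups = character(),
                      stringsAsFactors = FALSE))
  }
  windows <- function(s, lt) {
    lens <- min_length:min(lt, max_length)
    unique(unlist(lapply(lens, function(w)
      substring(s, 1:(lt - w + 1L), w:lt)), use.names = FALSE))
  }
  per <- lapply(use, function(k) windows(trimmed[k], Lt[k]))
  dt <- data.table::data.table(
    motif = unlist(per, use.names = FALSE),
    clonotype_id = rep(clonotypes$clonotype_id[use], lengths(per)),
    sample = rep(as.character(clonotypes$sample_id[use]), lengths(per)),
    group = rep(as.character(clonotypes$diagnosis_group[use]), lengths(per))
  )
  agg <- dt[, list(
    length = nchar(motif[1L]),
    frequency = length(unique(clonotype_id)),
    clonotype_ids = paste(sort(unique(clonotype_id)), collapse = ";"),
    samples = paste(sort(unique(sample)), collapse = ";"),
    groups = paste(sort(unique(group)), collapse = ";")
  ), by = "motif"]
  data.table::setorder(agg, -frequency, motif)
  as.data.frame(agg)
}

#' Rank motifs of one length
#'
#' @param motifs Output of [enumerate_motifs()].
#' @param length Motif length to report.
#' @param top_n Keep the top `top_n` rows (default all).
#' @return Motifs of the requested length sorted by frequency descending,
#'   ties broken lexicographically.
#' @export
motif_report <- function(motifs, length, top_n = Inf) {
  stopifnot(is.data.frame(motifs))
  out <- motifs[motifs$length == length, , drop = FALSE]
  out <- out[order(-out$frequency, out$motif), , drop = FALSE]
  if (is.finite(top_n)) out <- head(out, top_n)
  rownames(out) <- NULL
  out
}

#' Read a McPAS-TCR-format specificity database
#'
#' Loads a CSV with, at minimum, a CDR3beta column (`CDR3.beta.aa` in
#' McPAS-TCR; common synonyms are matched case-insensitively). Annotation
#' columns (`Pathology`, `Antigen.protein`, `Epitope.peptide`,
#' `T.Cell.Type`, ...) are preserved verbatim. Rows whose CDR3beta is
#' missing or contains non-standard residues are dropped with a count.
#'
#' @param path CSV file path.
#' @param cdr3b_column Optional explicit name of the CDR3beta column.
#' @return Data.frame with a normalised uppercase `cdr3b` column first,
#'   then all source columns.
#' @export
read_specificity_db <- function(path, cdr3b_column = NULL) {
  db <- data.table::fread(path, header = TRUE, colClasses = "character",
                          data.table = FALSE, na.strings = c("NA", ""))
  col <- cdr3b_column %||%
    match_column(names(db), c("CDR3.beta.aa", "cdr3b", "cdr3_beta",
                              "cdr3_b_aa", "junction_aa_beta", "cdr3beta"))
  if (is.na(col) || !col %in% names(db)) {
    stop(sprintf("no recognizable CDR3beta column in '%s'", path),
         call. = FALSE)
  }
  cdr3b <- toupper(trimws(db[[col]]))
  ok <- cdr3_usable(cdr3b)
  if (any(!ok)) {
    message(sprintf(
      "read_specificity_db: dropped %d entr(ies) with missing/invalid CDR3beta",
      sum(!ok)))
  }
  out <- cbind(data.frame(cdr3b = cdr3b[ok], stringsAsFactors = FALSE),
               db[ok, , drop = FALSE])
  rownames(out) <- NULL
  out
}

#' Search a motif against a specificity database
#'
#' Finds database entries whose full (untrimmed) CDR3beta contains the
#' motif as a contiguous substring, and tabulates hits by pathology and by
#' T cell type.
#'
#' @param motif Non-empty amino-acid string (case-insensitive).
#' @param db Database from [read_specificity_db()].
#' @return A list of class `motif_hits`: `motif`, `n_hits`, the matching
#'   `entries`, and descending count tables `by_pathology` and
#'   `by_t_cell_type` (empty when the column is absent).
#' @export
search_motif <- function(motif, db) {
  stopifnot(is.character(motif), length(motif) == 1L, nzchar(motif))
  motif <- toupper(motif)
  hits <- db[grepl(motif, db$cdr3b, fixed = TRUE), , drop = FALSE]
  count_by <- function(col_syn) {
    col <- match_column(names(hits), col_syn)
    if (is.na(col) || nrow(hits) == 0L) {
      return(data.frame(value = character(), n = integer(),
                        stringsAsFactors = FALSE))
    }
    tab <- table(hits[[col]], useNA = "no")
    out <- data.frame(value = names(tab), n = as.integer(tab),
                      stringsAsFactors = FALSE)
    out[order(-out$n, out$value), , drop = FALSE]
  }
  structure(
    list(motif = motif, n_hits = nrow(hits), entries = hits,
         by_pathology = count_by(c("Pathology", "disease")),
         by_t_cell_type = count_by(c("T.Cell.Type", "t_cell_type"))),
    class = "motif_hits"
  )
}

#' @export
print.motif_hits <- function(x, ...) {
  cat(sprintf("<motif_hits> motif %s: %d database entr(ies)\n",
              x$motif, x$n_hits))
  if (nrow(x$by_pathology)) {
    cat("pathology:\n")
    print(x$by_pathology, row.names = FALSE)
  }
  invisible(x)
}
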