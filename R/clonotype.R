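# Clonotype calling: identical amino-acid CDR3 keys, the unambiguity
# filter, the clonal-expansion (size >= 2) filter, and clone-size binning.

#' Keep cells with unambiguous TCR chains
#'
#' A cell is unambiguous in `paired` mode when it carries exactly one
#' usable productive alpha chain and exactly one beta chain; `beta_only`
#' mode (used e.g. for external beta-chain-only validation sets) requires
#' exactly one beta chain and ignores alpha. Cells with zero or multiple
#' chains of a required locus are removed.
#'
#' The returned data.frame gains convenience columns `cdr3a` / `cdr3b`
#' (single strings; `cdr3a` is `NA` in beta-only mode when no unique alpha
#' exists) and an `"audit"` attribute with the in/out counts, which are
#' also reported via [message()].
#'
#' @param cells Cell table from [assemble_cells()].
#' @param mode `"paired"` or `"beta_only"`.
#' @return Filtered cell data.frame with an `audit` attribute.
#' @export
filter_unambiguous <- function(cells, mode = c("paired", "beta_only")) {
  mode <- match.arg(mode)
  stopifnot(is.data.frame(cells))
  keep <- if (mode == "paired") {
    cells$n_alpha == 1L & cells$n_beta == 1L
  } else {
    cells$n_beta == 1L
  }
  out <- cells[keep, , drop = FALSE]
  out$cdr3a <- vapply(out$alpha, function(a)
    if (length(a) == 1L) a else NA_character_, "")
  out$cdr3b <- vapply(out$beta, function(b) b[1L], "")
  rownames(out) <- NULL
  audit <- list(
    mode = mode, n_in = nrow(cells), n_out = nrow(out),
    n_removed = nrow(cells) - nrow(out)
  )
  attr(out, "audit") <- audit
  message(sprintf(
    "filter_unambiguous(%s): %d cells in, %d retained, %d removed as ambiguous/incomplete",
    mode, audit$n_in, audit$n_out, audit$n_removed))
  out
}

#' Call clonotypes from unambiguous cells
#'
#' Groups cells by identical CDR3 amino-acid key: `(cdr3a, cdr3b)` in
#' paired mode, `cdr3b` alone in beta-only mode. With the default
#' `within_sample` scope the key additionally includes `sample_id`, so a
#' clone is one subject's expansion; `global` scope pools identical
#' sequences across samples. Identifiers are assigned after sorting by key,
#' making the result invariant to input row order.
#'
#' @param cells Output of [filter_unambiguous()].
#' @param mode `"paired"` or `"beta_only"`; must match the filtering mode.
#' @param scope `"within_sample"` (default) or `"global"`.
#' @param metadata Optional sample metadata (`sample_id`,
#'   `diagnosis_group`) used to annotate each clonotype's groups.
#' @return A data.frame of class `tcr_clonotypes` with columns
#'   `clonotype_id, cdr3a, cdr3b, size, sample_id, diagnosis_group,
#'   n_samples, samples, groups`. In global scope spanning several samples
#'   `sample_id`/`diagnosis_group` are `NA` and the multi-valued `samples`
#'   / `groups` columns carry the support.
#' @export
call_clonotypes <- function(cells, mode = c("paired", "beta_only"),
                            scope = c("within_sample", "global"),
                            metadata = NULL) {
  mode <- match.arg(mode)
  scope <- match.arg(scope)
  stopifnot(is.data.frame(cells))
  if (!all(c("cdr3a", "cdr3b") %in% names(cells))) {
    stop("cells must come from filter_unambiguous()", call. = FALSE)
  }
  if (nrow(cells) == 0L) {
    out <- data.frame(
      clonotype_id = character(), cdr3a = character(), cdr3b = character(),
      size = integer(), sample_id = character(),
      diagnosis_group = character(), n_samples = integer(),
      samples = character(), groups = character(), stringsAsFactors = FALSE
    )
    class(out) <- c("tcr_clonotypes", "data.frame")
    return(out)
  }
  if (mode == "paired" && anyNA(cells$cdr3a)) {
    stop("paired mode requires a unique alpha chain for every cell",
         call. = FALSE)
  }
  group_of <- function(sid) {
    if (is.null(metadata)) return(rep("unknown", length(sid)))
    g <- metadata$diagnosis_group[match(sid, metadata$sample_id)]
    g[is.na(g)] <- "unknown"
    g
  }
  key_a <- if (mode == "paired") cells$cdr3a else ""
  key <- if (scope == "within_sample") {
    paste(cells$sample_id, key_a, cells$cdr3b, sep = "\r")
  } else {
    paste(key_a, cells$cdr3b, sep = "\r")
  }
  levels_sorted <- sort(unique(key))
  idx <- split(seq_len(nrow(cells)), factor(key, levels = levels_sorted))
  n <- length(idx)
  one <- function(i) {
    sid <- unique(cells$sample_id[i])
    grp <- unique(group_of(sid))
    data.frame(
      cdr3a = if (mode == "paired") cells$cdr3a[i[1L]] else NA_character_,
      cdr3b = cells$cdr3b[i[1L]],
      size = length(i),
      sample_id = if (length(sid) == 1L) sid else NA_character_,
      diagnosis_group = if (length(grp) == 1L) grp else NA_character_,
      n_samples = length(sid),
      samples = collapse_sorted(sid),
      groups = collapse_sorted(grp),
      stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, lapply(idx, one))
  out <- cbind(
    data.frame(clonotype_id = sprintf("CT%05d", seq_len(n)),
               stringsAsFactors = FALSE),
    out
  )
  rownames(out) <- NULL
  attr(out, "member_cells") <- lapply(idx, function(i)
    cells[i, c("sample_id", "barcode")])
  attr(out, "mode") <- mode
  attr(out, "scope") <- scope
  class(out) <- c("tcr_clonotypes", "data.frame")
  out
}

#' Keep clonally expanded clonotypes
#'
#' Clonal expansion means at least `min_size` member cells (default 2:
#' a TCR shared with at least one other cell). Singletons are excluded from
#' downstream similarity analysis.
#'
#' @param clonotypes A `tcr_clonotypes` table.
#' @param min_size Minimum clone size retained (default 2).
#' @return The clonal subset, with an `audit` attribute.
#' @export
filter_clonal <- function(clonotypes, min_size = 2L) {
  stopifnot(is.data.frame(clonotypes), min_size >= 1L)
  keep <- clonotypes$size >= min_size
  out <- clonotypes[keep, , drop = FALSE]
  rownames(out) <- NULL
  if (nrow(out) == 0L) {
    warning("no clonally expanded clonotypes (all clones below min_size)",
            call. = FALSE)
  }
  attr(out, "audit") <- list(n_in = nrow(clonotypes), n_out = nrow(out),
                             min_size = min_size)
  message(sprintf(
    "filter_clonal(min_size=%d): %d clonotypes in, %d clonal retained",
    min_size, nrow(clonotypes), nrow(out)))
  out
}

#' Define clone-size bins
#'
#' @param labels Bin labels.
#' @param lower,upper Integer bounds, inclusive; `Inf` for an unbounded top
#'   bin. Bins must be disjoint and cover all sizes from 1 upwards.
#' @return A data.frame of bins. The default corresponds to singleton /
#'   small (2-5) / large (>5) clones.
#' @export
clone_size_bins <- function(labels = c("1", "2-5", ">5"),
                            lower = c(1, 2, 6),
                            upper = c(1, 5, Inf)) {
  stopifnot(length(labels) == length(lower), length(lower) == length(upper))
  o <- order(lower)
  bins <- data.frame(label = labels[o], lower = lower[o], upper = upper[o],
                     stringsAsFactors = FALSE)
  if (any(bins$lower > bins$upper)) {
    stop("each bin needs lower <= upper", call. = FALSE)
  }
  if (bins$lower[1L] != 1) stop("bins must start at clone size 1", call. = FALSE)
  if (nrow(bins) > 1L) {
    gaps <- bins$lower[-1L] - bins$upper[-nrow(bins)]
    if (any(gaps != 1)) {
      stop("bins must be disjoint and cover [1, Inf) without gaps",
           call. = FALSE)
    }
  }
  if (!is.infinite(bins$upper[nrow(bins)])) {
    stop("the last bin must be unbounded above", call. = FALSE)
  }
  bins
}

#' Assign clonotypes to clone-size bins
#'
#' @param clonotypes A `tcr_clonotypes` table.
#' @param bins Bin definition from [clone_size_bins()].
#' @return Data.frame `(clonotype_id, size, bin)`; each clonotype falls in
#'   exactly one bin.
#' @export
bin_clone_sizes <- function(clonotypes, bins = clone_size_bins()) {
  stopifnot(is.data.frame(clonotypes))
  hit <- vapply(clonotypes$size, function(s) {
    which(s >= bins$lower & s <= bins$upper)[1L]
  }, 1L)
  data.frame(
    clonotype_id = clonotypes$clonotype_id,
    size = clonotypes$size,
    bin = bins$label[hit],
    stringsAsFactors = FALSE
  )
}
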