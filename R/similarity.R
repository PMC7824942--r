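# Length-normalised Levenshtein similarity (L-sim) over clonotypes and
# threshold-based similarity clustering.
#
# L-sim(a, b) = 1 - d(a, b) / max(|a|, |b|), where d is the unit-cost edit
# distance. Scores are computed from exact integer distances and lengths,
# so threshold comparisons (e.g. "> 0.8") are reproducible without
# floating-point tolerances.

#' Levenshtein edit distance
#'
#' Unit-cost substitution/insertion/deletion distance between character
#' strings, vectorised over pairs (arguments are recycled to a common
#' length).
#'
#' @param a,b Character vectors.
#' @return Integer vector of edit distances.
#' @examples
#' levenshtein_distance("kitten", "sitting")  # 3
#' @export
levenshtein_distance <- function(a, b) {
  a <- as.character(a)
  b <- as.character(b)
  n <- max(length(a), length(b))
  if (length(a) != n) a <- rep_len(a, n)
  if (length(b) != n) b <- rep_len(b, n)
  cpp_lev_dist(a, b)
}

#' Levenshtein similarity (L-sim)
#'
#' `1 - d(a, b) / max(nchar(a), nchar(b))`, in `[0, 1]` with 1 for
#' identical strings. Undefined (an error) when both strings of a pair are
#' empty.
#'
#' @param a,b Character vectors (recycled to a common length).
#' @return Numeric vector of similarities in `[0, 1]`.
#' @examples
#' lsim("CASSLGQAYEQYF", "CASSLGQAYEQYF")  # 1
#' lsim("CASSF", "CASTF")                  # 0.8
#' @export
lsim <- function(a, b) {
  a <- as.character(a)
  b <- as.character(b)
  n <- max(length(a), length(b))
  if (length(a) != n) a <- rep_len(a, n)
  if (length(b) != n) b <- rep_len(b, n)
  m <- pmax(nchar(a), nchar(b))
  if (any(m == 0, na.rm = TRUE)) {
    stop("lsim is undefined when both strings are empty", call. = FALSE)
  }
  1 - cpp_lev_dist(a, b) / m
}

mode_strings <- function(clonotypes, pairing_mode) {
  if (pairing_mode != "beta_only") {
    if (anyNA(clonotypes$cdr3a) || any(clonotypes$cdr3a == "")) {
      stop(sprintf("pairing mode '%s' requires both chains on every clonotype",
                   pairing_mode), call. = FALSE)
    }
  }
  switch(pairing_mode,
    concat_ab = paste0(clonotypes$cdr3a, clonotypes$cdr3b),
    beta_only = clonotypes$cdr3b
  )
}

#' All pairwise L-sim scores over a clonotype list
#'
#' Computes L-sim for every unordered pair of clonotypes. The alpha and
#' beta chain can be combined in three ways: `concat_ab` (default) scores
#' the no-separator concatenation `cdr3a + cdr3b` as a single string;
#' `per_chain_mean` averages the alpha-alpha and beta-beta scores;
#' `beta_only` scores beta chains alone.
#'
#' @param clonotypes A `tcr_clonotypes` table (>= 2 rows). In `concat_ab` /
#'   `per_chain_mean` modes every clonotype must carry both chains.
#' @param pairing_mode One of `"concat_ab"`, `"per_chain_mean"`,
#'   `"beta_only"`.
#' @return An object of class `lsim_matrix`: the ordered clonotype ids, the
#'   condensed upper triangle of scores (ordering of [stats::dist]), and
#'   the pairing mode. Use [as.matrix()] for the full symmetric matrix or
#'   [lsim_pairs()] for a long-format table.
#' @export
pairwise_lsim <- function(clonotypes,
                          pairing_mode = c("concat_ab", "per_chain_mean",
                                           "beta_only")) {
  pairing_mode <- match.arg(pairing_mode)
  stopifnot(is.data.frame(clonotypes))
  n <- nrow(clonotypes)
  if (n < 2L) stop("need at least two clonotypes", call. = FALSE)
  if (anyDuplicated(clonotypes$clonotype_id)) {
    stop("clonotype ids must be unique", call. = FALSE)
  }
  scores <- if (pairing_mode == "per_chain_mean") {
    if (anyNA(clonotypes$cdr3a) || any(clonotypes$cdr3a == "")) {
      stop("pairing mode 'per_chain_mean' requires both chains on every clonotype",
           call. = FALSE)
    }
    (cpp_lsim_condensed(clonotypes$cdr3a) +
       cpp_lsim_condensed(clonotypes$cdr3b)) / 2
  } else {
    cpp_lsim_condensed(mode_strings(clonotypes, pairing_mode))
  }
  structure(
    list(ids = clonotypes$clonotype_id, scores = scores, n = n,
         pairing_mode = pairing_mode),
    class = "lsim_matrix"
  )
}

# Condensed index of pair (i, j), i < j, 1-based, dist() ordering.
condensed_index <- function(n, i, j) {
  swap <- i > j
  if (any(swap)) {
    tmp <- i[swap]; i[swap] <- j[swap]; j[swap] <- tmp
  }
  n * (i - 1) - i * (i - 1) / 2 + (j - i)
}

# Inverse: row indices i of each condensed position (1..n(n-1)/2).
condensed_ij <- function(n) {
  i <- rep.int(seq_len(n - 1L), (n - 1L):1L)
  j <- sequence((n - 1L):1L) + i
  cbind(i = i, j = j)
}

#' @export
print.lsim_matrix <- function(x, ...) {
  cat(sprintf("<lsim_matrix> %d clonotypes, %d pairs, mode=%s\n",
              x$n, length(x$scores), x$pairing_mode))
  invisible(x)
}

#' @export
as.matrix.lsim_matrix <- function(x, ...) {
  m <- diag(1, x$n)
  ij <- condensed_ij(x$n)
  m[ij] <- x$scores
  m[ij[, c(2, 1), drop = FALSE]] <- x$scores
  dimnames(m) <- list(x$ids, x$ids)
  m
}

#' Long-format table of pairwise scores
#'
#' @param x An `lsim_matrix`.
#' @return Data.frame `(id_i, id_j, lsim)`, one row per unordered pair.
#' @export
lsim_pairs <- function(x) {
  stopifnot(inherits(x, "lsim_matrix"))
  ij <- condensed_ij(x$n)
  data.frame(id_i = x$ids[ij[, 1L]], id_j = x$ids[ij[, 2L]],
             lsim = x$scores, stringsAsFactors = FALSE)
}

#' Summarise the off-diagonal L-sim distribution
#'
#' Histogram and summary statistics of all pairwise scores (self-pairs are
#' never stored, so the summary describes distinct-clonotype similarity).
#'
#' @param x An `lsim_matrix`.
#' @param binwidth Histogram bin width on `[0, 1]` (default 0.05).
#' @return A list of class `lsim_distribution`: `breaks`, `counts`, `mids`,
#'   `n_pairs`, `mean`, `sd`, `quantiles`, and `frac_above_0.8`, the
#'   fraction of pairs exceeding 0.8.
#' @export
lsim_distribution <- function(x, binwidth = 0.05) {
  stopifnot(inherits(x, "lsim_matrix"), binwidth > 0, binwidth <= 1)
  s <- x$scores
  if (!length(s)) stop("empty similarity matrix", call. = FALSE)
  breaks <- seq(0, 1, by = binwidth)
  if (breaks[length(breaks)] < 1) breaks <- c(breaks, 1)
  nbin <- length(breaks) - 1L
  # bins [b_k, b_{k+1}) with the last bin closed at 1
  bin <- findInterval(s, breaks, rightmost.closed = TRUE)
  counts <- tabulate(bin, nbins = nbin)
  mids <- (breaks[-1L] + breaks[-length(breaks)]) / 2
  structure(
    list(breaks = breaks, counts = counts, mids = mids,
         n_pairs = length(s), mean = mean(s), sd = sd(s),
         quantiles = quantile(s, c(0, 0.25, 0.5, 0.75, 0.95, 1)),
         frac_above_0.8 = mean(s > 0.8)),
    class = "lsim_distribution"
  )
}

#' @export
print.lsim_distribution <- function(x, ...) {
  cat(sprintf(
    "<lsim_distribution> %d pairs, mean=%.3f, sd=%.3f, frac > 0.8 = %.4f\n",
    x$n_pairs, x$mean, x$sd, x$frac_above_0.8))
  invisible(x)
}

#' Similarity clusters above a threshold
#'
#' Builds the graph whose vertices are clonotypes and whose edges join
#' pairs with L-sim strictly greater than `tau`, and returns its connected
#' components with at least two members. Clusters are numbered by
#' decreasing size, ties broken by the lexicographically smallest member
#' id.
#'
#' @param x An `lsim_matrix`.
#' @param tau Similarity threshold in (0, 1); edges require `score > tau`.
#' @param clonotypes Optional `tcr_clonotypes` table used to annotate
#'   members with sample and diagnosis group.
#' @return Data.frame `(cluster_id, clonotype_id[, sample_id,
#'   diagnosis_group])`, one row per cluster member, with a `summary`
#'   attribute `(cluster_id, n_members, min_lsim, max_lsim)` giving the
#'   within-cluster score range.
#' @export
threshold_clusters <- function(x, tau = 0.8, clonotypes = NULL) {
  stopifnot(inherits(x, "lsim_matrix"), tau > 0, tau < 1)
  hit <- which(x$scores > tau)
  if (!length(hit)) {
    out <- data.frame(cluster_id = character(), clonotype_id = character(),
                      stringsAsFactors = FALSE)
    attr(out, "summary") <- data.frame(
      cluster_id = character(), n_members = integer(),
      min_lsim = numeric(), max_lsim = numeric(), stringsAsFactors = FALSE)
    attr(out, "tau") <- tau
    return(out)
  }
  ij <- condensed_ij(x$n)[hit, , drop = FALSE]
  g <- igraph::graph_from_edgelist(
    cbind(ij[, 1L], ij[, 2L]), directed = FALSE)
  g <- igraph::add_vertices(g, max(0L, x$n - igraph::vcount(g)))
  comp <- igraph::components(g)
  sizes <- comp$csize
  keep <- which(sizes >= 2L)
  # order: size desc, then smallest member id
  min_member <- vapply(keep, function(k)
    min(x$ids[comp$membership == k]), "")
  o <- order(-sizes[keep], min_member)
  keep <- keep[o]
  rows <- lapply(seq_along(keep), function(r) {
    members <- which(comp$membership == keep[r])
    members <- members[order(x$ids[members])]
    data.frame(cluster_id = sprintf("C%d", r),
               clonotype_id = x$ids[members],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (!is.null(clonotypes)) {
    m <- match(out$clonotype_id, clonotypes$clonotype_id)
    out$sample_id <- clonotypes$sample_id[m]
    out$diagnosis_group <- clonotypes$diagnosis_group[m]
  }
  summ <- do.call(rbind, lapply(seq_along(keep), function(r) {
    members <- which(comp$membership == keep[r])
    pair_idx <- utils::combn(sort(members), 2L)
    sc <- x$scores[condensed_index(x$n, pair_idx[1L, ], pair_idx[2L, ])]
    data.frame(cluster_id = sprintf("C%d", r),
               n_members = length(members),
               min_lsim = min(sc), max_lsim = max(sc),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  attr(out, "summary") <- summ
  attr(out, "tau") <- tau
  out
}
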