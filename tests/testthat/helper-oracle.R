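# Independent oracles and fixture builders shared across the suite.

AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

# Naive full-DP-table Levenshtein distance, kept deliberately independent
# of the package's optimized implementation.
oracle_lev <- function(a, b) {
  ca <- strsplit(a, "")[[1]]
  cb <- strsplit(b, "")[[1]]
  n <- length(ca)
  m <- length(cb)
  D <- matrix(0L, n + 1L, m + 1L)
  D[, 1L] <- 0:n
  D[1L, ] <- 0:m
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      D[i + 1L, j + 1L] <- min(
        D[i, j] + (ca[i] != cb[j]),
        D[i, j + 1L] + 1L,
        D[i + 1L, j] + 1L
      )
    }
  }
  D[n + 1L, m + 1L]
}

oracle_lsim <- function(a, b) 1 - oracle_lev(a, b) / max(nchar(a), nchar(b))

random_aa_string <- function(len, alphabet = AA20) {
  if (len == 0L) return("")
  paste(sample(alphabet, len, replace = TRUE), collapse = "")
}

random_cdr3_string <- function(len) {
  paste0("C", random_aa_string(len - 2L), "F")
}

# Brute-force connected components over an explicit edge list: repeatedly
# merge groups sharing a vertex.
oracle_components <- function(n, edges) {
  comp <- seq_len(n)
  repeat {
    changed <- FALSE
    for (r in seq_len(nrow(edges))) {
      i <- edges[r, 1L]; j <- edges[r, 2L]
      if (comp[i] != comp[j]) {
        comp[comp == comp[j]] <- comp[i]
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  match(comp, unique(comp))
}

# Build a contig data.frame row-by-row for hand-constructed fixtures.
contig_row <- function(barcode, sample_id, chain, cdr3,
                       productive = TRUE, high_confidence = TRUE) {
  data.frame(barcode = barcode, sample_id = sample_id, chain = chain,
             cdr3_aa = cdr3, cdr3_nt = NA_character_,
             v_gene = NA_character_, j_gene = NA_character_,
             productive = productive, high_confidence = high_confidence,
             usable = grepl("^[ACDEFGHIKLMNPQRSTVWY]+$", cdr3),
             stringsAsFactors = FALSE)
}

# Clonotype table shortcut for similarity/motif tests.
make_clonotypes <- function(cdr3a, cdr3b, sample_id = "S1",
                            group = "unknown", size = 2L) {
  n <- length(cdr3b)
  out <- data.frame(
    clonotype_id = sprintf("CT%05d", seq_len(n)),
    cdr3a = if (is.null(cdr3a)) NA_character_ else cdr3a,
    cdr3b = cdr3b,
    size = rep_len(size, n),
    sample_id = rep_len(sample_id, n),
    diagnosis_group = rep_len(group, n),
    n_samples = 1L,
    samples = rep_len(sample_id, n),
    groups = rep_len(group, n),
    stringsAsFactors = FALSE
  )
  class(out) <- c("tcr_clonotypes", "data.frame")
  out
}

# Scaled-down cohort used where the full ~1300-cells-per-sample default
# would be needlessly slow; planted structure is the package default.
small_sim_config <- function(seed, ...) {
  sim_config(groups = c(HC = 2L, AD = 2L, MCI = 2L, PD = 2L),
             cells_per_sample = 120L, seed = seed, ...)
}

extdata <- function(name) system.file("extdata", name, package = "tcrsimnet")
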