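# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: naive window scans, enumeration, and a
# long-horizon projected-gradient solver.

# Naive k-mer counter: slice every window, skip windows with non-ACGT
# characters, tally into a named accumulator.
naive_count_kmers <- function(sequence, k) {
  counts <- integer(4^k)
  seq_chars <- strsplit(toupper(sequence), "", fixed = TRUE)[[1]]
  n <- length(seq_chars)
  total <- 0L
  skipped <- 0L
  if (n >= k) {
    base_val <- c(A = 0L, C = 1L, G = 2L, T = 3L)
    for (i in seq_len(n - k + 1L)) {
      window <- seq_chars[i:(i + k - 1L)]
      vals <- base_val[window]
      if (anyNA(vals)) {
        skipped <- skipped + 1L
      } else {
        idx <- sum(vals * 4^((k - 1):0)) + 1L
        counts[idx] <- counts[idx] + 1L
        total <- total + 1L
      }
    }
  }
  list(counts = counts, total = total, n_skipped = skipped)
}

random_dna <- function(len, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, len, replace = TRUE), collapse = "")
}

# Projected-gradient NNLS oracle on the explicit augmented system
# M = rbind(1, lam * A), b = c(1, lam * s). Fixed step 1/L with L the
# largest eigenvalue of M'M; long horizon with an early stop on stalled
# objective. Returns the achieved objective ||M x - b||^2.
pg_nnls_objective <- function(M, b, iters = 200000L) {
  MtM <- crossprod(M)
  Mtb <- as.numeric(crossprod(M, b))
  L <- max(eigen(MtM, symmetric = TRUE, only.values = TRUE)$values)
  x <- numeric(ncol(M))
  obj <- function(x) sum((as.numeric(M %*% x) - b)^2)
  last <- obj(x)
  for (i in seq_len(iters)) {
    x <- pmax(0, x - (as.numeric(MtM %*% x) - Mtb) / L)
    if (i %% 2000L == 0L) {
      cur <- obj(x)
      if (last - cur < 1e-15 * max(1, cur)) break
      last <- cur
    }
  }
  obj(x)
}

# Explicit augmented system for a training matrix at one lambda.
augmented_system <- function(A, s, lam) {
  list(M = rbind(1, lam * A), b = c(1, lam * s))
}

# Random column-stochastic matrix (n_rows x n_cols).
random_stochastic <- function(n_rows, n_cols) {
  A <- matrix(runif(n_rows * n_cols), n_rows, n_cols)
  sweep(A, 2, colSums(A), "/")
}

# Wrap a bare column-stochastic matrix as a training_matrix (k inferred
# from the row count, which must be a power of 4).
as_training_matrix <- function(A, ids = sprintf("s%d", seq_len(ncol(A)))) {
  k <- as.integer(round(log(nrow(A), 4)))
  stopifnot(4^k == nrow(A))
  colnames(A) <- ids
  structure(list(A = A, seq_ids = ids, k = k, orientation = "as-given",
                 n_skipped = integer(ncol(A)), built = "test"),
            class = "training_matrix")
}

# A tiny taxonomy data.frame for n sequences given per-rank name vectors.
tiny_taxonomy <- function(seq_id, genus, species = paste0(genus, "_sp"),
                          phylum = "phylum_A", family = "family_A") {
  load_taxonomy(data.frame(
    seq_id = seq_id, superkingdom = "Bacteria", phylum = phylum,
    class = paste0(phylum, "_c"), order = paste0(phylum, "_o"),
    family = family, genus = genus, species = species,
    stringsAsFactors = FALSE))
}

# Random probability vector with named entries.
random_profile <- function(n, rank = "genus", prefix = "t") {
  v <- runif(n)
  tax_profile(setNames(v / sum(v), paste0(prefix, seq_len(n))), rank)
}
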