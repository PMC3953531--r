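# Training matrix construction and persistence, and the taxonomy table.
#
# The training matrix A has 4^k rows (k-mers in lexicographic order) and one
# column per database sequence; column j is the k-mer frequency vector of
# sequence g_j, so every column sums to 1. Chromosome and plasmid of one
# organism are separate columns that share a taxonomy entry and are merged
# only when aggregating profiles to a rank.

TAXONOMY_RANKS <- c("superkingdom", "phylum", "class", "order",
                    "family", "genus", "species")

DB_FORMAT <- "kmermix_training_matrix"
DB_FORMAT_VERSION <- 1L

#' Build the k-mer training matrix from a genome database
#'
#' Converts a database of genome (and plasmid) sequences into the
#' column-stochastic matrix \eqn{A}: entry \eqn{A_{ij}} is the frequency of
#' the i-th k-mer (lexicographic order) in the j-th sequence. Column order
#' follows input order; each input sequence becomes its own column.
#'
#' @param db A named `DNAStringSet` or named character vector of sequences;
#'   names are the sequence IDs and must be unique.
#' @param scheme A [kmer_scheme()].
#' @param orientation `"as-given"` (default) counts each sequence on the
#'   strand as stored; `"with-reverse-complement"` pools each sequence's
#'   counts with its reverse complement's, giving strand-symmetric columns.
#'   Symmetrized columns are required for samples whose reads come from
#'   both strands (the usual WGS situation): count the sample with the
#'   matching orientation (the orientation is recorded in the matrix and
#'   its on-disk container so classification can match automatically).
#' @return An object of class `training_matrix`: `A` (dense `4^k x N`
#'   matrix, columns named by sequence ID), `seq_ids`, `k`, `orientation`,
#'   `n_skipped` (ambiguous windows skipped per sequence) and `built`
#'   (timestamp).
#' @examples
#' tm <- build_training_matrix(c(s1 = "ACGTACGT", s2 = "AAAACCCC"),
#'                             kmer_scheme(1))
#' colSums(tm$A)
#' @export
build_training_matrix <- function(db, scheme,
                                  orientation = c("as-given",
                                                  "with-reverse-complement")) {
  stopifnot(inherits(scheme, "kmer_scheme"))
  orientation <- match.arg(orientation)
  db <- as_dna_set(db)
  ids <- names(db)
  if (is.null(ids) || any(!nzchar(ids))) {
    stop("every database sequence must have a non-empty ID (names attribute)")
  }
  if (anyDuplicated(ids)) {
    stop("duplicate sequence IDs: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  # rows = sequences, cols = 4^k k-mers; transposed below
  counts <- Biostrings::oligonucleotideFrequency(db, width = scheme$k)
  if (orientation == "with-reverse-complement") {
    counts <- counts + Biostrings::oligonucleotideFrequency(
      Biostrings::reverseComplement(db), width = scheme$k)
  }
  totals <- rowSums(counts)
  if (any(totals == 0)) {
    stop("sequence(s) with zero valid k-mer windows at k = ", scheme$k, ": ",
         paste(ids[totals == 0], collapse = ", "))
  }
  A <- t(counts / totals)
  dimnames(A) <- list(NULL, ids)
  possible <- pmax(0L, Biostrings::width(db) - scheme$k + 1L)
  if (orientation == "with-reverse-complement") possible <- 2L * possible
  structure(list(A = A,
                 seq_ids = ids,
                 k = scheme$k,
                 orientation = orientation,
                 n_skipped = as.integer(possible - totals),
                 built = format(Sys.time(), tz = "UTC")),
            class = "training_matrix")
}

#' @export
print.training_matrix <- function(x, ...) {
  cat(sprintf("<training_matrix> k = %d: %d k-mers x %d sequences\n",
              x$k, nrow(x$A), length(x$seq_ids)))
  invisible(x)
}

validate_training_matrix <- function(tm, tol = 1e-9) {
  if (!is.matrix(tm$A) || !is.numeric(tm$A)) stop("A must be a numeric matrix")
  if (nrow(tm$A) != 4^tm$k) {
    stop("container integrity error: A has ", nrow(tm$A),
         " rows but k = ", tm$k, " implies ", 4^tm$k)
  }
  if (ncol(tm$A) != length(tm$seq_ids)) {
    stop("container integrity error: ", ncol(tm$A), " columns but ",
         length(tm$seq_ids), " sequence IDs")
  }
  if (anyDuplicated(tm$seq_ids)) stop("container integrity error: duplicate IDs")
  cs <- colSums(tm$A)
  if (any(tm$A < 0) || any(abs(cs - 1) > tol)) {
    stop("container integrity error: columns are not probability vectors")
  }
  invisible(tm)
}

#' Persist and restore a training matrix
#'
#' The on-disk container is a single serialized archive holding the matrix,
#' the sequence IDs, `k` and a format-version field; `load_training_matrix()`
#' validates the container and reproduces the matrix bit-for-bit.
#'
#' @param tm A `training_matrix`.
#' @param path File path for the container (conventionally `.rds`).
#' @return `save_training_matrix()` returns `path` invisibly;
#'   `load_training_matrix()` returns the validated `training_matrix`.
#' @export
save_training_matrix <- function(tm, path) {
  stopifnot(inherits(tm, "training_matrix"))
  saveRDS(list(format = DB_FORMAT, format_version = DB_FORMAT_VERSION,
               k = tm$k, seq_ids = tm$seq_ids, A = tm$A,
               orientation = tm$orientation,
               n_skipped = tm$n_skipped, built = tm$built,
               package_version = as.character(packageVersion("kmermix"))),
          path)
  invisible(path)
}

#' @rdname save_training_matrix
#' @export
load_training_matrix <- function(path) {
  if (!file.exists(path)) stop("training database not found: ", path)
  obj <- tryCatch(suppressWarnings(readRDS(path)),
                  error = function(e) stop("cannot read training database '",
                                           path, "': ", conditionMessage(e)))
  if (!is.list(obj) || !identical(obj$format, DB_FORMAT)) {
    stop("'", path, "' is not a kmermix training database")
  }
  if (!identical(obj$format_version, DB_FORMAT_VERSION)) {
    stop("unsupported training database version: ", obj$format_version)
  }
  tm <- structure(list(A = obj$A, seq_ids = obj$seq_ids, k = obj$k,
                       orientation = obj$orientation,
                       n_skipped = obj$n_skipped, built = obj$built),
                  class = "training_matrix")
  validate_training_matrix(tm)
}

#' Load and validate a taxonomy table
#'
#' Reads a UTF-8 tab-separated file with a header row naming a `seq_id`
#' column plus the seven ranks superkingdom..species, mapping each database
#' sequence to its ranked lineage. Empty rank cells become explicit
#' `unclassified_<parent>` tokens. Lineages must form a consistent tree:
#' the same name at a rank must sit under the same names at all ranks above
#' it; violations are rejected with the offending taxa listed.
#'
#' @param path Path to the TSV file, or a `data.frame` already in memory
#'   with the same columns.
#' @return A `data.frame` of class `taxonomy_table` with columns `seq_id`
#'   and the seven ranks.
#' @export
load_taxonomy <- function(path) {
  tab <- if (is.data.frame(path)) {
    as.data.frame(path, stringsAsFactors = FALSE)
  } else {
    read.delim(path, header = TRUE, sep = "\t", quote = "",
               colClasses = "character", check.names = FALSE,
               fileEncoding = "UTF-8")
  }
  missing_cols <- setdiff(c("seq_id", TAXONOMY_RANKS), names(tab))
  if (length(missing_cols) > 0L) {
    stop("taxonomy schema error: missing column(s) ",
         paste(missing_cols, collapse = ", "))
  }
  tab <- tab[, c("seq_id", TAXONOMY_RANKS)]
  tab[] <- lapply(tab, as.character)
  if (anyDuplicated(tab$seq_id)) {
    stop("taxonomy error: duplicate seq_id(s): ",
         paste(unique(tab$seq_id[duplicated(tab$seq_id)]), collapse = ", "))
  }
  # fill empty cells top-down with unclassified_<parent>
  parent <- rep("root", nrow(tab))
  for (rank in TAXONOMY_RANKS) {
    blank <- is.na(tab[[rank]]) | !nzchar(trimws(tab[[rank]]))
    tab[[rank]][blank] <- paste0("unclassified_", parent[blank])
    parent <- tab[[rank]]
  }
  # consistency: a name at rank r determines the lineage above it
  for (r in seq_along(TAXONOMY_RANKS)[-1]) {
    rank <- TAXONOMY_RANKS[r]
    above <- do.call(paste, c(tab[TAXONOMY_RANKS[seq_len(r - 1)]], sep = "\r"))
    paths_per_name <- tapply(above, tab[[rank]],
                             function(v) length(unique(v)))
    bad <- names(paths_per_name)[paths_per_name > 1L]
    if (length(bad) > 0L) {
      stop("taxonomy consistency error at rank ", rank,
           ": name(s) with multiple parent lineages: ",
           paste(bad, collapse = ", "))
    }
  }
  class(tab) <- c("taxonomy_table", "data.frame")
  tab
}

#' Write a taxonomy table as TSV
#' @param tax A `taxonomy_table` (or compatible data frame).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_taxonomy <- function(tax, path) {
  write.table(as.data.frame(tax), path, sep = "\t", quote = FALSE,
              row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}
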