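# k-mer indexing and counting. The index is the lexicographic rank of a
# k-mer over the alphabet A < C < G < T, i.e. its base-4 value with
# A=0, C=1, G=2, T=3 -- the row order of the training matrix.

KMER_ALPHABET <- c("A", "C", "G", "T")

#' Create a k-mer indexing scheme
#'
#' Fixes the word length `k` and the lexicographic bijection between k-mers
#' over \{A,C,G,T\} and the integers `0 .. 4^k - 1`. All counting, training
#' and classification functions take a scheme so that the row dimension
#' `4^k` is fixed consistently across a workflow. The default `k = 7`
#' (16384 rows) trades off resolution against memory and solve time;
#' larger `k` grows the matrix fourfold per unit.
#'
#' @param k Integer word length, between 1 and 12.
#' @return An object of class `kmer_scheme` with fields `k` and `n_kmers`.
#' @examples
#' sc <- kmer_scheme(2)
#' kmer_to_index(c("AA", "TT"), sc)
#' @export
kmer_scheme <- function(k = 7L) {
  k <- as.integer(k)
  if (length(k) != 1L || is.na(k) || k < 1L || k > 12L) {
    stop("k must be a single integer in [1, 12] (4^k rows must fit in memory)")
  }
  structure(list(k = k, n_kmers = 4L^k), class = "kmer_scheme")
}

#' @export
print.kmer_scheme <- function(x, ...) {
  cat(sprintf("<kmer_scheme> k = %d (%d k-mers, A < C < G < T)\n",
              x$k, x$n_kmers))
  invisible(x)
}

#' Map k-mers to lexicographic indices and back
#'
#' `kmer_to_index()` returns the 0-based rank of each k-mer among all `4^k`
#' words in lexicographic order (so `"AA..A"` is 0 and `"TT..T"` is
#' `4^k - 1`); `index_to_kmer()` is its inverse.
#'
#' @param kmer Character vector of k-mers over A,C,G,T (case-insensitive).
#' @param index Integer vector of indices in `0 .. 4^k - 1`.
#' @param scheme A [kmer_scheme()].
#' @return An integer vector of indices, or a character vector of k-mers.
#' @examples
#' sc <- kmer_scheme(4)
#' kmer_to_index("ACGT", sc)  # 27
#' index_to_kmer(27, sc)
#' @export
kmer_to_index <- function(kmer, scheme) {
  stopifnot(inherits(scheme, "kmer_scheme"))
  kmer <- toupper(kmer)
  if (any(nchar(kmer) != scheme$k)) {
    stop("all k-mers must have length k = ", scheme$k)
  }
  mat <- matrix(match(unlist(strsplit(kmer, "", fixed = TRUE)), KMER_ALPHABET) - 1L,
                nrow = scheme$k)
  if (anyNA(mat)) stop("k-mers may only contain A, C, G, T")
  as.integer(colSums(mat * 4^((scheme$k - 1):0)))
}

#' @rdname kmer_to_index
#' @export
index_to_kmer <- function(index, scheme) {
  stopifnot(inherits(scheme, "kmer_scheme"))
  index <- as.integer(index)
  if (anyNA(index) || any(index < 0L) || any(index >= scheme$n_kmers)) {
    stop("index out of range 0 .. 4^k - 1")
  }
  vapply(index, function(i) {
    digits <- integer(scheme$k)
    for (pos in scheme$k:1) {
      digits[pos] <- i %% 4L
      i <- i %/% 4L
    }
    paste(KMER_ALPHABET[digits + 1L], collapse = "")
  }, character(1))
}

## Coerce character / DNAString input to a DNAStringSet.
as_dna_set <- function(x) {
  if (methods::is(x, "DNAStringSet")) return(x)
  if (methods::is(x, "DNAString")) return(Biostrings::DNAStringSet(x))
  out <- Biostrings::DNAStringSet(toupper(x))
  names(out) <- names(x)  # as.character()/toupper() can drop names
  out
}

#' Count k-mers in a nucleotide sequence
#'
#' Counts every overlapping length-`k` window made up exclusively of
#' A, C, G, T, on the strand as given. Windows containing any other IUPAC
#' code (N, ambiguity codes, gaps) are skipped, not randomly resolved, and
#' tallied in `n_skipped`; lowercase (masked) bases are counted normally.
#' A sequence shorter than `k` yields all-zero counts.
#'
#' @param sequence A single nucleotide string or `DNAString`.
#' @param scheme A [kmer_scheme()].
#' @return A list of class `kmer_counts`: `counts` (integer vector of
#'   length `4^k`, lexicographic order), `total` (number of counted
#'   windows) and `n_skipped` (windows skipped for ambiguity).
#' @examples
#' count_kmers("ACNGT", kmer_scheme(2))
#' @export
count_kmers <- function(sequence, scheme) {
  stopifnot(inherits(scheme, "kmer_scheme"))
  dna <- as_dna_set(sequence)
  if (length(dna) != 1L) stop("count_kmers() expects a single sequence")
  counts <- Biostrings::oligonucleotideFrequency(dna[[1]], width = scheme$k)
  total <- sum(counts)
  possible <- max(0L, length(dna[[1]]) - scheme$k + 1L)
  structure(list(counts = as.integer(counts), total = as.integer(total),
                 n_skipped = as.integer(possible - total), k = scheme$k),
            class = "kmer_counts")
}

## Pooled k-mer counts over a read set, optionally adding the
## reverse-complement windows. Returns the raw numeric count vector.
pooled_counts <- function(reads, scheme,
                          orientation = c("as-given", "with-reverse-complement")) {
  orientation <- match.arg(orientation)
  counts <- Biostrings::oligonucleotideFrequency(reads, width = scheme$k,
                                                 simplify.as = "collapsed")
  if (orientation == "with-reverse-complement") {
    counts <- counts + Biostrings::oligonucleotideFrequency(
      Biostrings::reverseComplement(reads), width = scheme$k,
      simplify.as = "collapsed")
  }
  as.numeric(counts)
}

#' Pool a read set into a sample k-mer frequency vector
#'
#' Counts the k-mers of every read, pools the counts over the whole sample,
#' and normalizes by the pooled total, producing the probability vector
#' \eqn{s} of length `4^k` that the mixture model is fit against. Reads are
#' counted on the strand as sequenced by default; set
#' `orientation = "with-reverse-complement"` to also pool each read's
#' reverse-complement windows (no alignment-based orientation is
#' attempted). Reads shorter than `k` contribute no windows and are tallied
#' in `n_short_reads`.
#'
#' @param reads A `DNAStringSet`, character vector of read sequences, or a
#'   path passed through [read_sequences()] first by the caller.
#' @param scheme A [kmer_scheme()].
#' @param orientation `"as-given"` (default) or `"with-reverse-complement"`.
#' @return An object of class `sample_vector`: `freqs` (probability vector
#'   of length `4^k`), `k`, `n_reads`, `n_skipped_windows`, `n_short_reads`.
#' @examples
#' sv <- sample_vector(c("ACGT", "ACGA"), kmer_scheme(1))
#' sum(sv$freqs)
#' @export
sample_vector <- function(reads, scheme,
                          orientation = c("as-given", "with-reverse-complement")) {
  stopifnot(inherits(scheme, "kmer_scheme"))
  orientation <- match.arg(orientation)
  reads <- as_dna_set(reads)
  if (length(reads) == 0L) stop("empty sample: no reads supplied")
  counts <- pooled_counts(reads, scheme, orientation)
  total <- sum(counts)
  if (total == 0) {
    stop("empty sample: no read contributed a valid k-mer window at k = ",
         scheme$k)
  }
  widths <- Biostrings::width(reads)
  possible <- sum(pmax(0L, widths - scheme$k + 1L))
  if (orientation == "with-reverse-complement") possible <- 2L * possible
  structure(list(freqs = counts / total,
                 k = scheme$k,
                 n_reads = length(reads),
                 n_skipped_windows = as.integer(possible - total),
                 n_short_reads = sum(widths < scheme$k)),
            class = "sample_vector")
}

#' @export
print.sample_vector <- function(x, ...) {
  cat(sprintf(
    "<sample_vector> k = %d, %d reads, %d skipped windows, %d reads < k\n",
    x$k, x$n_reads, x$n_skipped_windows, x$n_short_reads))
  invisible(x)
}

#' Read sequences from FASTA or FASTQ
#'
#' Thin wrapper around [Biostrings::readDNAStringSet()] that sniffs the
#' format from the file extension (`.fq`/`.fastq`, optionally `.gz`) and
#' is gzip-transparent. Quality strings are ignored throughout the package.
#'
#' @param path Path to a FASTA or FASTQ file, optionally gzipped.
#' @param format `"auto"` (default), `"fasta"` or `"fastq"`.
#' @return A `DNAStringSet`.
#' @export
read_sequences <- function(path, format = c("auto", "fasta", "fastq")) {
  format <- match.arg(format)
  if (format == "auto") {
    base <- sub("\\.(gz|bz2|xz)$", "", path, ignore.case = TRUE)
    format <- if (grepl("\\.(fq|fastq)$", base, ignore.case = TRUE))
      "fastq" else "fasta"
  }
  Biostrings::readDNAStringSet(path, format = format)
}
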