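# Rank-level taxonomic profiles and reconstruction metrics.
#
# A profile is a probability vector over taxon names at one rank. The
# reconstruction metric is the L1 distance sum(|p - q|) between the actual
# and predicted profiles -- the "total error", bounded in [0, 2] with 0 for
# perfect reconstruction and 2 for disjoint supports.

#' Aggregate a concentration vector to a taxonomic rank
#'
#' Sums the sequence-level concentrations over all database sequences
#' sharing the same taxon name at the requested rank (so the chromosome and
#' plasmid columns of one organism are merged here) and renormalizes to
#' guard against drift.
#'
#' @param x A `concentration` from [reconstruct()], or a named nonnegative
#'   numeric vector over sequence IDs (e.g. a simulation ground truth).
#' @param tax A `taxonomy_table` from [load_taxonomy()].
#' @param rank One of superkingdom, phylum, class, order, family, genus,
#'   species.
#' @return An object of class `tax_profile`: `rank`, `abundances` (named
#'   numeric, descending), `n_contributing` (sequences per taxon) and
#'   `provenance` (seq IDs per taxon).
#' @examples
#' tax <- load_taxonomy(data.frame(seq_id = c("s1", "s2"),
#'   superkingdom = "B", phylum = "P", class = "C", order = "O",
#'   family = "F", genus = c("G1", "G2"), species = c("sp1", "sp2")))
#' aggregate_to_rank(c(s1 = 0.4, s2 = 0.6), tax, "genus")$abundances
#' @export
aggregate_to_rank <- function(x, tax, rank) {
  rank <- match.arg(rank, TAXONOMY_RANKS)
  stopifnot(inherits(tax, "taxonomy_table"))
  if (inherits(x, "concentration")) x <- x$x
  if (is.null(names(x))) stop("x must be named by sequence ID")
  if (any(x < 0)) stop("concentrations must be nonnegative")
  total <- sum(x)
  if (total <= 0) stop("cannot aggregate an all-zero concentration vector")
  hit <- match(names(x), tax$seq_id)
  if (anyNA(hit)) {
    stop("seq_id(s) missing from the taxonomy: ",
         paste(names(x)[is.na(hit)], collapse = ", "))
  }
  taxa <- tax[[rank]][hit]
  ab <- tapply(x / total, taxa, sum)
  ab <- sort(ab / sum(ab), decreasing = TRUE)
  structure(list(rank = rank,
                 abundances = c(ab),
                 n_contributing = vapply(names(ab), function(t)
                   sum(taxa == t & x > 0), integer(1)),
                 provenance = split(names(x)[x > 0], taxa[x > 0])),
            class = "tax_profile")
}

#' Construct a profile directly from named abundances
#'
#' Convenience constructor for a `tax_profile` at a given rank from a named
#' vector of nonnegative values (renormalized to sum to 1).
#'
#' @param abundances Named nonnegative numeric vector.
#' @param rank Taxonomic rank label.
#' @return A `tax_profile`.
#' @export
tax_profile <- function(abundances, rank) {
  rank <- match.arg(rank, TAXONOMY_RANKS)
  if (is.null(names(abundances)) || any(!nzchar(names(abundances)))) {
    stop("abundances must be named by taxon")
  }
  if (any(abundances < 0) || sum(abundances) <= 0) {
    stop("abundances must be nonnegative and not all zero")
  }
  ab <- tapply(abundances, names(abundances), sum)  # merge duplicate names
  ab <- sort(ab / sum(ab), decreasing = TRUE)
  structure(list(rank = rank, abundances = c(ab),
                 n_contributing = setNames(rep(NA_integer_, length(ab)),
                                           names(ab)),
                 provenance = NULL),
            class = "tax_profile")
}

#' @export
print.tax_profile <- function(x, n = 10L, ...) {
  cat(sprintf("<tax_profile> rank = %s, %d taxa\n", x$rank,
              length(x$abundances)))
  print(utils::head(round(x$abundances, 4), n))
  invisible(x)
}

#' L1 distance ("total error") between two profiles
#'
#' Computes `sum(|p(t) - q(t)|)` over the union of taxon names, reading
#' missing taxa as 0. The value lies in \[0, 2\]: 0 for identical profiles
#' (perfect reconstruction) and 2 for disjoint supports.
#'
#' @param p,q `tax_profile` objects at the same rank.
#' @return A single number in \[0, 2\].
#' @export
l1_error <- function(p, q) {
  stopifnot(inherits(p, "tax_profile"), inherits(q, "tax_profile"))
  if (!identical(p$rank, q$rank)) {
    stop("rank mismatch: ", p$rank, " vs ", q$rank)
  }
  taxa <- union(names(p$abundances), names(q$abundances))
  pv <- ifelse(taxa %in% names(p$abundances), p$abundances[taxa], 0)
  qv <- ifelse(taxa %in% names(q$abundances), q$abundances[taxa], 0)
  sum(abs(pv - qv))
}

#' L1 error restricted to the top-k taxa of the reference profile
#'
#' Restricts both profiles to the `k_top` most abundant taxa of `p` (ties
#' broken by taxon name), renormalizes both restrictions to probability
#' vectors, and returns their L1 distance. This measures how well the
#' predominant community structure is recovered, ignoring the rare tail.
#' If `q` carries no mass on the selected taxa the maximal error 2 is
#' returned.
#'
#' @param p Reference (actual) `tax_profile`; defines the top-k set.
#' @param q Predicted `tax_profile`, same rank.
#' @param k_top Number of top taxa of `p` to keep (>= 1).
#' @return A single number in \[0, 2\].
#' @export
topk_restricted_error <- function(p, q, k_top) {
  stopifnot(inherits(p, "tax_profile"), inherits(q, "tax_profile"))
  if (!identical(p$rank, q$rank)) {
    stop("rank mismatch: ", p$rank, " vs ", q$rank)
  }
  if (!is.numeric(k_top) || length(k_top) != 1L || k_top < 1) {
    stop("k_top must be a single integer >= 1")
  }
  pa <- p$abundances[p$abundances > 0]
  if (length(pa) == 0L) stop("reference profile has no support")
  ord <- order(-pa, names(pa))
  keep <- names(pa)[ord][seq_len(min(k_top, length(pa)))]
  pr <- pa[keep] / sum(pa[keep])
  qv <- ifelse(keep %in% names(q$abundances), q$abundances[keep], 0)
  if (sum(qv) <= 0) return(2)
  qr <- qv / sum(qv)
  sum(abs(pr - qr))
}

#' Read and write rank-level profiles as TSV
#'
#' The on-disk profile format is a 4-column TSV: `rank`, `taxon`,
#' `abundance`, `n_contributing_sequences`, sorted by abundance descending.
#'
#' @param profile A `tax_profile`.
#' @param path File path.
#' @return `write_profile()` returns `path` invisibly; `read_profile()`
#'   returns a `tax_profile`.
#' @export
write_profile <- function(profile, path) {
  stopifnot(inherits(profile, "tax_profile"))
  df <- data.frame(rank = profile$rank,
                   taxon = names(profile$abundances),
                   abundance = unname(profile$abundances),
                   n_contributing_sequences =
                     unname(profile$n_contributing[names(profile$abundances)]),
                   stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_profile
#' @export
read_profile <- function(path) {
  df <- read.delim(path, header = TRUE, sep = "\t", quote = "",
                   stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  needed <- c("rank", "taxon", "abundance")
  if (!all(needed %in% names(df))) {
    stop("profile file must have columns rank, taxon, abundance")
  }
  rank <- unique(df$rank)
  if (length(rank) != 1L) stop("profile file mixes ranks: ",
                               paste(rank, collapse = ", "))
  out <- tax_profile(setNames(df$abundance, df$taxon), rank)
  if ("n_contributing_sequences" %in% names(df)) {
    out$n_contributing <- setNames(as.integer(df$n_contributing_sequences),
                                   df$taxon)[names(out$abundances)]
  }
  out
}
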