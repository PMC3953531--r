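# Grinder-style WGS read simulation and fixture databases.
#
# "Abundance" throughout means the fraction of reads drawn from a source
# sequence -- the same scale the profiler estimates -- not cell counts
# weighted by genome length. Rank-abundance models follow the simulator
# conventions common in the field: uniform, linear (n, n-1, ..., 1),
# power law rank^-a, exponential exp(-r * rank); the ranks are assigned to
# the chosen sources by a random permutation.

#' Simulation configuration
#'
#' Bundles the knobs of one simulated WGS dataset. The defaults mirror a
#' typical held-out evaluation sample: read lengths normally distributed
#' with mean 150 bp and standard deviation 5 bp, a power-law abundance
#' model and a diversity of 10 source sequences; `n_reads` defaults to
#' 10^4 for desk-scale runs (the original protocol used 10^6).
#'
#' @param n_reads Number of reads to draw (>= 1).
#' @param diversity Number of distinct source sequences contributing reads.
#' @param abundance_model One of `"uniform"`, `"linear"`, `"powerlaw"`,
#'   `"exponential"`.
#' @param abundance_param Exponent of the power law (default 1) or rate of
#'   the exponential (default 0.7); ignored for uniform/linear.
#' @param read_length One of `fixed_length(L)` / `normal_length(mean, sd)`,
#'   i.e. a list `list(model = "fixed", length = L)` or
#'   `list(model = "normal", mean = m, sd = s)`.
#' @param error_model A list: `list(type = "none")`,
#'   `list(type = "substitution", rate = r)` or
#'   `list(type = "homopolymer", sd_scale = s)` (see
#'   [apply_homopolymer_errors()]).
#' @param seed Optional integer seed; if supplied, the whole simulation is
#'   reproducible from it.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_reads = 1e4, diversity = 10,
                       abundance_model = c("powerlaw", "uniform", "linear",
                                           "exponential"),
                       abundance_param = NULL,
                       read_length = normal_length(150, 5),
                       error_model = list(type = "none"),
                       seed = NULL) {
  abundance_model <- match.arg(abundance_model)
  n_reads <- as.integer(n_reads)
  diversity <- as.integer(diversity)
  if (is.na(n_reads) || n_reads < 1L) stop("n_reads must be >= 1")
  if (is.na(diversity) || diversity < 1L) stop("diversity must be >= 1")
  if (is.null(abundance_param)) {
    abundance_param <- switch(abundance_model, powerlaw = 1,
                              exponential = 0.7, NA_real_)
  }
  if (!is.list(read_length) ||
      !read_length$model %in% c("fixed", "normal")) {
    stop("read_length must be fixed_length() or normal_length()")
  }
  if (!is.list(error_model) ||
      !error_model$type %in% c("none", "substitution", "homopolymer")) {
    stop("error_model type must be none, substitution or homopolymer")
  }
  if (identical(error_model$type, "substitution")) {
    r <- error_model$rate
    if (!is.numeric(r) || r < 0 || r > 1) {
      stop("substitution rate must be in [0, 1]")
    }
  }
  structure(list(n_reads = n_reads, diversity = diversity,
                 abundance_model = abundance_model,
                 abundance_param = abundance_param,
                 read_length = read_length, error_model = error_model,
                 seed = if (is.null(seed)) NULL else as.integer(seed)),
            class = "sim_config")
}

#' @rdname sim_config
#' @param L,mean,sd Read-length parameters (bp).
#' @export
fixed_length <- function(L) list(model = "fixed", length = as.integer(L))

#' @rdname sim_config
#' @export
normal_length <- function(mean, sd) list(model = "normal", mean = mean, sd = sd)

#' Draw relative abundances from a rank-abundance model
#'
#' Computes the model weights for ranks `1..n` -- uniform `1/n`; linear
#' `(n, n-1, ..., 1)`; power law `rank^-a`; exponential `exp(-r * rank)` --
#' normalizes them, and (by default) assigns the ranks to the `n` sources
#' in a random permutation.
#'
#' @param model One of `"uniform"`, `"linear"`, `"powerlaw"`,
#'   `"exponential"`.
#' @param n Number of sources.
#' @param param Power-law exponent `a` (default 1) or exponential rate `r`
#'   (default 0.7).
#' @param permute If `TRUE` (default), randomly permute the ranked weights
#'   across sources; `FALSE` returns the weights in rank order.
#' @param seed Optional integer seed for the permutation.
#' @return A probability vector of length `n`.
#' @examples
#' draw_abundances("powerlaw", 3, permute = FALSE)  # (1, 1/2, 1/3) / (11/6)
#' @export
draw_abundances <- function(model = c("uniform", "linear", "powerlaw",
                                      "exponential"),
                            n, param = NULL, permute = TRUE, seed = NULL) {
  model <- match.arg(model)
  n <- as.integer(n)
  if (is.na(n) || n < 1L) stop("n must be >= 1")
  if (is.null(param)) {
    param <- switch(model, powerlaw = 1, exponential = 0.7, NA_real_)
  }
  if (model %in% c("powerlaw", "exponential") &&
      (!is.numeric(param) || !is.finite(param) || param < 0)) {
    stop("abundance model parameter must be a nonnegative number")
  }
  ranks <- seq_len(n)
  w <- switch(model,
              uniform = rep(1, n),
              linear = rev(ranks),
              powerlaw = ranks^(-param),
              exponential = exp(-param * ranks))
  w <- w / sum(w)
  if (permute && n > 1L) {
    if (!is.null(seed)) set.seed(seed)
    w <- w[sample.int(n)]
  }
  w
}

#' Rewrite homopolymer run lengths with normally distributed noise
#'
#' Models homopolymer miscalls: each maximal run of identical bases of true
#' length `n` is rewritten with length `max(0, round(N(n, sd_scale *
#' sqrt(n))))`, so longer runs are noisier and the expected length is
#' (nearly) unbiased. `sd_scale = 0` leaves reads unchanged.
#'
#' @param reads Character vector of read sequences.
#' @param sd_scale Standard-deviation scale per sqrt(run length);
#'   default 0.15.
#' @return Character vector of mutated reads (possibly different lengths).
#' @export
apply_homopolymer_errors <- function(reads, sd_scale = 0.15) {
  if (!is.numeric(sd_scale) || sd_scale < 0) {
    stop("sd_scale must be nonnegative")
  }
  if (sd_scale == 0) return(reads)
  vapply(reads, function(r) {
    runs <- rle(strsplit(r, "", fixed = TRUE)[[1]])
    new_len <- pmax(0L, as.integer(round(
      rnorm(length(runs$lengths), runs$lengths,
            sd_scale * sqrt(runs$lengths)))))
    paste(rep.int(runs$values, new_len), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

## Substitution errors: per read, Binomial(L, rate) positions are replaced
## by a uniformly chosen *different* base.
apply_substitution_errors <- function(reads, rate) {
  if (rate == 0) return(reads)
  lens <- nchar(reads)
  n_mut <- stats::rbinom(length(reads), lens, rate)
  for (i in which(n_mut > 0L)) {
    pos <- sample.int(lens[i], n_mut[i])
    chars <- strsplit(reads[i], "", fixed = TRUE)[[1]]
    for (p in pos) {
      chars[p] <- sample(setdiff(KMER_ALPHABET, chars[p]), 1L)
    }
    reads[i] <- paste(chars, collapse = "")
  }
  reads
}

#' Simulate a WGS read set from a genome database
#'
#' Draws each read's source from a rank-abundance model over `diversity`
#' chosen sequences, its start position uniformly, its strand uniformly
#' (reverse-complement emitted for minus-strand reads), its length from the
#' configured model (truncated to `[min_length, source length]`), and then
#' applies the configured sequencing-error model. Fully reproducible from
#' `config$seed`.
#'
#' @param db Named `DNAStringSet` or named character vector of source
#'   sequences.
#' @param config A [sim_config()].
#' @param truth Optional pre-drawn ground truth (a list with `seq_ids` and
#'   `abundances`), e.g. to hold the community fixed across replicates;
#'   by default sources and abundances are drawn from `config`.
#' @param min_length Shortest emitted read (default 1; set to `k` to
#'   guarantee every read contributes windows).
#' @param strand `"both"` (default; uniform over plus/minus) or
#'   `"forward"` to emit every read on the source strand.
#' @return A list of class `sim_reads`: `reads` (named character vector),
#'   `truth` (class `ground_truth`: `seq_ids`, `abundances`, `read_source`
#'   per-read labels, `read_counts`), and `config`.
#' @export
simulate_reads <- function(db, config, truth = NULL, min_length = 1L,
                           strand = c("both", "forward")) {
  stopifnot(inherits(config, "sim_config"))
  strand <- match.arg(strand)
  seqs <- as.character(as_dna_set(db))
  ids <- names(seqs)
  if (is.null(ids)) stop("db sequences must be named")
  if (!is.null(config$seed)) set.seed(config$seed)
  if (is.null(truth)) {
    if (config$diversity > length(seqs)) {
      stop("diversity ", config$diversity, " exceeds database size ",
           length(seqs))
    }
    chosen <- sample(ids, config$diversity)
    ab <- draw_abundances(config$abundance_model, config$diversity,
                          config$abundance_param)
  } else {
    chosen <- truth$seq_ids
    ab <- truth$abundances
    if (length(chosen) != length(ab) || abs(sum(ab) - 1) > 1e-9) {
      stop("truth must pair seq_ids with abundances summing to 1")
    }
  }
  src_len <- nchar(seqs[chosen])
  # per-read source and length
  src <- sample.int(length(chosen), config$n_reads, replace = TRUE, prob = ab)
  rl <- config$read_length
  len <- if (rl$model == "fixed") {
    rep.int(rl$length, config$n_reads)
  } else {
    as.integer(round(rnorm(config$n_reads, rl$mean, rl$sd)))
  }
  len <- pmax(len, as.integer(min_length))
  too_short <- src_len[src] < len
  if (any(too_short)) {
    if (rl$model == "fixed") {
      stop("source(s) shorter than the read length: ",
           paste(unique(chosen[src[too_short]]), collapse = ", "))
    }
    len[too_short] <- src_len[src][too_short]  # truncate normal-tail draws
  }
  start <- as.integer(floor(runif(config$n_reads) *
                              (src_len[src] - len + 1))) + 1L
  reads <- substring(seqs[chosen][src], start, start + len - 1L)
  minus <- if (strand == "both") runif(config$n_reads) < 0.5
           else rep(FALSE, config$n_reads)
  if (any(minus)) {
    reads[minus] <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAStringSet(reads[minus])))
  }
  em <- config$error_model
  reads <- switch(em$type,
                  none = reads,
                  substitution = apply_substitution_errors(reads, em$rate),
                  homopolymer = apply_homopolymer_errors(
                    reads, if (is.null(em$sd_scale)) 0.15 else em$sd_scale))
  names(reads) <- sprintf("read_%0*d", nchar(config$n_reads), seq_along(reads))
  truth_out <- structure(
    list(seq_ids = chosen,
         abundances = setNames(ab, chosen),
         read_source = chosen[src],
         read_start = start,
         read_strand = ifelse(minus, "-", "+"),
         read_counts = setNames(tabulate(src, length(chosen)), chosen)),
    class = "ground_truth")
  structure(list(reads = reads, truth = truth_out, config = config),
            class = "sim_reads")
}

#' Write simulated reads to FASTA or FASTQ
#'
#' FASTA is the default since qualities are never used downstream; FASTQ
#' (constant quality "I") is available for interface testing.
#'
#' @param sim A `sim_reads` object or named character vector of reads.
#' @param path Output path.
#' @param format `"fasta"` or `"fastq"`.
#' @return `path`, invisibly.
#' @export
write_reads <- function(sim, path, format = c("fasta", "fastq")) {
  format <- match.arg(format)
  reads <- if (inherits(sim, "sim_reads")) sim$reads else sim
  dna <- Biostrings::DNAStringSet(reads)
  if (format == "fasta") {
    Biostrings::writeXStringSet(dna, path)
  } else {
    qual <- Biostrings::BStringSet(vapply(Biostrings::width(dna), function(w)
      strrep("I", w), character(1)))
    Biostrings::writeXStringSet(dna, path, format = "fastq", qualities = qual)
  }
  invisible(path)
}

#' Generate a random genome database with a consistent synthetic taxonomy
#'
#' Produces i.i.d.-uniform ACGT genomes plus a nested random taxonomy over
#' the seven ranks: each rank has a configurable number of distinct taxa,
#' every taxon is attached to a single parent at the rank above (so lineage
#' consistency holds by construction), and each genome is assigned a leaf
#' species. Optional plasmid companions share their genome's lineage.
#' Deterministic given `seed`.
#'
#' @param n_genomes Number of genomes (>= 1).
#' @param genome_length Length of each genome in bp.
#' @param taxonomy_shape Named or positional integer vector of length 7:
#'   the number of distinct taxa at each rank (non-decreasing recommended);
#'   default `c(1, 2, 3, 4, 6, 8, n_genomes)`.
#' @param seed Integer seed.
#' @param n_plasmids Number of genomes that also get a plasmid companion
#'   sequence (length `plasmid_length`), sharing the genome's lineage.
#' @param plasmid_length Plasmid length in bp (default `genome_length %/% 10`).
#' @return A list of class `fixture_db`: `sequences` (named character),
#'   `taxonomy` (a `taxonomy_table`).
#' @export
make_fixture_database <- function(n_genomes, genome_length,
                                  taxonomy_shape = NULL, seed = NULL,
                                  n_plasmids = 0L,
                                  plasmid_length = max(genome_length %/% 10, 20L)) {
  n_genomes <- as.integer(n_genomes)
  if (is.na(n_genomes) || n_genomes < 1L) stop("n_genomes must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  if (is.null(taxonomy_shape)) {
    taxonomy_shape <- pmin(c(1L, 2L, 3L, 4L, 6L, 8L, n_genomes), n_genomes)
  }
  if (length(taxonomy_shape) != 7L || any(taxonomy_shape < 1L)) {
    stop("taxonomy_shape must give a positive taxon count for each of the 7 ranks")
  }
  random_genome <- function(len) {
    paste(sample(KMER_ALPHABET, len, replace = TRUE), collapse = "")
  }
  genome_ids <- sprintf("genome_%03d", seq_len(n_genomes))
  sequences <- setNames(
    vapply(seq_len(n_genomes), function(i) random_genome(genome_length),
           character(1)),
    genome_ids)
  # nested taxonomy: each taxon at rank r gets one parent at rank r - 1
  n_taxa <- as.integer(taxonomy_shape)
  taxon_names <- lapply(seq_along(TAXONOMY_RANKS), function(r)
    sprintf("%s_%02d", TAXONOMY_RANKS[r], seq_len(n_taxa[r])))
  parent_of <- vector("list", 7L)  # taxon index -> parent taxon index
  parent_of[[1]] <- rep(NA_integer_, n_taxa[1])
  for (r in 2:7) {
    # cover every parent before sampling extras, so no rank collapses
    p <- c(seq_len(min(n_taxa[r - 1], n_taxa[r])),
           if (n_taxa[r] > n_taxa[r - 1])
             sample.int(n_taxa[r - 1], n_taxa[r] - n_taxa[r - 1],
                        replace = TRUE))
    parent_of[[r]] <- p[sample.int(n_taxa[r])]
  }
  # map each genome to a species (cover all species first), then walk up
  sp <- c(seq_len(min(n_taxa[7], n_genomes)),
          if (n_genomes > n_taxa[7])
            sample.int(n_taxa[7], n_genomes - n_taxa[7], replace = TRUE))
  sp <- sp[sample.int(n_genomes)]
  lineage <- matrix(NA_integer_, nrow = n_genomes, ncol = 7L)
  lineage[, 7] <- sp
  for (r in 6:1) lineage[, r] <- parent_of[[r + 1]][lineage[, r + 1]]
  tax <- data.frame(seq_id = genome_ids, stringsAsFactors = FALSE)
  for (r in seq_along(TAXONOMY_RANKS)) {
    tax[[TAXONOMY_RANKS[r]]] <- taxon_names[[r]][lineage[, r]]
  }
  if (n_plasmids > 0L) {
    n_plasmids <- min(as.integer(n_plasmids), n_genomes)
    host <- sample.int(n_genomes, n_plasmids)
    pl_ids <- sprintf("%s_plasmid", genome_ids[host])
    sequences <- c(sequences, setNames(
      vapply(seq_len(n_plasmids), function(i) random_genome(plasmid_length),
             character(1)),
      pl_ids))
    pl_tax <- tax[host, , drop = FALSE]
    pl_tax$seq_id <- pl_ids
    tax <- rbind(tax, pl_tax)
  }
  structure(list(sequences = sequences, taxonomy = load_taxonomy(tax)),
            class = "fixture_db")
}

#' Write a fixture database to FASTA + taxonomy TSV
#' @param db A `fixture_db` from [make_fixture_database()].
#' @param fasta_path,taxonomy_path Output paths.
#' @return A list with the two paths, invisibly.
#' @export
write_fixture_database <- function(db, fasta_path, taxonomy_path) {
  stopifnot(inherits(db, "fixture_db"))
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(db$sequences),
                              fasta_path)
  write_taxonomy(db$taxonomy, taxonomy_path)
  invisible(list(fasta = fasta_path, taxonomy = taxonomy_path))
}
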