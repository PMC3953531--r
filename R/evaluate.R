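# End-to-end experiment harness: simulate -> classify -> score, a hold-out
# cross-validation protocol to gauge performance under database novelty,
# and a parameter sweep summarizing error against simulation parameters.

## Deterministic child seeds derived from a base seed (kept < 2^31).
derive_seed <- function(seed, i) {
  as.integer((as.numeric(seed) * 48271 + 1000003 * as.numeric(i)) %%
               2147483647) + 1L
}

#' Simulate, classify and score one dataset
#'
#' Runs the full loop on a fixture (or real) database: simulates a read set
#' per `config`, reconstructs the concentration vector against the training
#' matrix, aggregates both the ground truth and the prediction to each
#' requested rank, and scores the L1 error.
#'
#' @param db Named sequences (`DNAStringSet` or character), or a
#'   `fixture_db`.
#' @param tax A `taxonomy_table` (taken from `db` if it is a `fixture_db`).
#' @param config A [sim_config()].
#' @param ranks Character vector of ranks to score (default genus).
#' @param schedule A [lambda_schedule()] or fixed lambda for
#'   [reconstruct()].
#' @param tm Optional prebuilt `training_matrix` for `db` (avoids
#'   recounting across replicates); its stored orientation is used for the
#'   sample.
#' @param scheme A [kmer_scheme()] used when `tm` is not supplied.
#' @param orientation Strand handling for both the training matrix and the
#'   sample; defaults to `"with-reverse-complement"` because simulated (and
#'   real) reads come from both strands.
#' @return A list of class `experiment_result`: `errors` (named by rank),
#'   `sequence_l1` (L1 at the sequence level), `lambda_used`,
#'   `support_size`, `runtime_s`, `config`, plus the `truth` and
#'   `estimate`.
#' @export
run_experiment <- function(db, tax = NULL, config = sim_config(),
                           ranks = "genus", schedule = lambda_schedule(),
                           tm = NULL, scheme = kmer_scheme(7),
                           orientation = "with-reverse-complement") {
  if (inherits(db, "fixture_db")) {
    if (is.null(tax)) tax <- db$taxonomy
    db <- db$sequences
  }
  stopifnot(inherits(tax, "taxonomy_table"))
  ranks <- vapply(ranks, match.arg, character(1), choices = TAXONOMY_RANKS)
  t0 <- proc.time()[["elapsed"]]
  if (is.null(tm)) tm <- build_training_matrix(db, scheme, orientation)
  sim <- simulate_reads(db, config, min_length = tm$k)
  sv <- sample_vector(sim$reads, kmer_scheme(tm$k),
                      orientation = tm$orientation)
  est <- reconstruct(tm, sv, schedule)
  truth_x <- setNames(numeric(length(tm$seq_ids)), tm$seq_ids)
  truth_x[sim$truth$seq_ids] <- sim$truth$abundances
  errors <- vapply(ranks, function(r) {
    l1_error(aggregate_to_rank(truth_x, tax, r),
             aggregate_to_rank(est, tax, r))
  }, numeric(1))
  seq_l1 <- sum(abs(truth_x - est$x[names(truth_x)]))
  structure(list(errors = errors, sequence_l1 = seq_l1,
                 lambda_used = est$lambda_used,
                 support_size = length(est$support),
                 runtime_s = proc.time()[["elapsed"]] - t0,
                 config = config, truth = sim$truth, estimate = est),
            class = "experiment_result")
}

#' Hold-out cross-validation under database novelty
#'
#' Gauges performance when the sample contains organisms absent from the
#' training database. The sequence set is partitioned into `folds` disjoint
#' sets; for each fold the held-out sequences alone source a simulated
#' sample, the remaining sequences form a reduced training matrix, and the
#' reconstruction is scored at each requested rank. Errors are averaged
#' over folds, then over `iterations` repeats with fresh seeds. Because
#' fine ranks accumulate more novel taxa than coarse ranks, error is
#' expected to grow toward the species level.
#'
#' @param db Named sequences or a `fixture_db`.
#' @param tax A `taxonomy_table` (taken from `db` if a `fixture_db`).
#' @param folds Number of folds (>= 2; default 10).
#' @param config A [sim_config()]; `diversity` is capped at the fold size.
#'   Its `seed` field is ignored in favour of `seed`.
#' @param iterations Number of independent repeats (default 1).
#' @param ranks Ranks to score (default phylum and genus).
#' @param seed Integer seed; folds and samples derive from it.
#' @param scheme A [kmer_scheme()].
#' @param schedule A [lambda_schedule()] or fixed lambda.
#' @param stratify_by Optional rank name: assign folds so that taxa at this
#'   rank are spread across folds (off by default; fold assignment is
#'   plain seeded-random by sequence).
#' @param orientation Strand handling for training and sample counting
#'   (default `"with-reverse-complement"`).
#' @return A list of class `crossval_report`: `per_fold` (data frame of
#'   iteration, fold, rank, l1_error), `summary` (per-rank mean and
#'   variance over all fold x iteration cells), `folds`, `iterations`.
#' @export
crossval <- function(db, tax = NULL, folds = 10L, config = sim_config(),
                     iterations = 1L, ranks = c("phylum", "genus"),
                     seed = 1L, scheme = kmer_scheme(7),
                     schedule = lambda_schedule(), stratify_by = NULL,
                     orientation = "with-reverse-complement") {
  if (inherits(db, "fixture_db")) {
    if (is.null(tax)) tax <- db$taxonomy
    db <- db$sequences
  }
  stopifnot(inherits(tax, "taxonomy_table"), inherits(config, "sim_config"))
  folds <- as.integer(folds)
  iterations <- as.integer(iterations)
  if (folds < 2L) stop("folds must be >= 2")
  if (iterations < 1L) stop("iterations must be >= 1")
  db <- as.character(as_dna_set(db))
  n <- length(db)
  if (n < folds) stop("database has fewer sequences than folds")
  ranks <- vapply(ranks, match.arg, character(1), choices = TAXONOMY_RANKS)

  # count all sequences once; fold matrices are column subsets
  tm_full <- build_training_matrix(db, scheme, orientation)
  rows <- vector("list", iterations * folds * length(ranks))
  ri <- 0L
  for (it in seq_len(iterations)) {
    set.seed(derive_seed(seed, it))
    assign_ids <- if (is.null(stratify_by)) {
      sample(rep_len(seq_len(folds), n))
    } else {
      stratified_folds(tax, names(db), stratify_by, folds)
    }
    for (f in seq_len(folds)) {
      held <- which(assign_ids == f)
      if (length(held) == 0L) stop("fold ", f, " is empty")
      train <- setdiff(seq_len(n), held)
      tm_f <- tm_full
      tm_f$A <- tm_full$A[, train, drop = FALSE]
      tm_f$seq_ids <- tm_full$seq_ids[train]
      cfg <- config
      cfg$diversity <- min(config$diversity, length(held))
      cfg$seed <- derive_seed(seed, it * 1000L + f)
      sim <- simulate_reads(db[held], cfg, min_length = scheme$k)
      sv <- sample_vector(sim$reads, scheme, orientation = tm_full$orientation)
      est <- reconstruct(tm_f, sv, schedule)
      truth_prof <- lapply(ranks, function(r)
        aggregate_to_rank(sim$truth$abundances, tax, r))
      est_prof <- lapply(ranks, function(r) aggregate_to_rank(est, tax, r))
      for (k in seq_along(ranks)) {
        ri <- ri + 1L
        rows[[ri]] <- data.frame(iteration = it, fold = f, rank = ranks[k],
                                 l1_error = l1_error(truth_prof[[k]],
                                                     est_prof[[k]]))
      }
    }
  }
  per_fold <- do.call(rbind, rows)
  summary <- do.call(rbind, lapply(ranks, function(r) {
    e <- per_fold$l1_error[per_fold$rank == r]
    data.frame(rank = r, mean_l1_error = mean(e),
               var_l1_error = if (length(e) > 1L) var(e) else NA_real_)
  }))
  structure(list(per_fold = per_fold, summary = summary, folds = folds,
                 iterations = iterations, config = config, seed = seed),
            class = "crossval_report")
}

## Spread the taxa observed at `rank` across folds.
stratified_folds <- function(tax, seq_ids, rank, folds) {
  rank <- match.arg(rank, TAXONOMY_RANKS)
  taxa <- tax[[rank]][match(seq_ids, tax$seq_id)]
  assign_ids <- integer(length(seq_ids))
  nxt <- 0L
  for (t in sample(unique(taxa))) {
    members <- sample(which(taxa == t))
    assign_ids[members] <- (nxt + seq_along(members) - 1L) %% folds + 1L
    nxt <- nxt + length(members)
  }
  assign_ids
}

#' @export
print.crossval_report <- function(x, ...) {
  cat(sprintf("<crossval_report> %d-fold x %d iteration(s)\n",
              x$folds, x$iterations))
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' Parameter sweep over simulation conditions
#'
#' Runs [run_experiment()] over the Cartesian grid of the supplied
#' simulation-parameter levels, with `replicates` seeded repeats per cell,
#' and summarizes the mean error per level of each swept parameter.
#'
#' @param db Named sequences or a `fixture_db`.
#' @param tax A `taxonomy_table` (taken from `db` if a `fixture_db`).
#' @param n_reads,read_length,abundance_model,diversity Vectors of levels
#'   to sweep (`read_length` is a list of length models, e.g.
#'   `list(fixed_length(100), normal_length(150, 5))`).
#' @param replicates Seeded replicates per grid cell (>= 1).
#' @param ranks Ranks to score.
#' @param seed Base seed.
#' @param scheme,schedule Passed to [run_experiment()].
#' @param error_model Error model applied in every cell.
#' @param orientation Strand handling for training and sample counting.
#' @return A list of class `sweep_result`: `results` (one row per run:
#'   parameters, replicate, per-rank errors) and `summary` (mean error per
#'   parameter level per rank).
#' @export
sweep_experiments <- function(db, tax = NULL,
                              n_reads = 1e4, read_length = list(normal_length(150, 5)),
                              abundance_model = "powerlaw", diversity = 10,
                              replicates = 5L, ranks = "genus", seed = 1L,
                              scheme = kmer_scheme(7),
                              schedule = lambda_schedule(),
                              error_model = list(type = "none"),
                              orientation = "with-reverse-complement") {
  if (inherits(db, "fixture_db")) {
    if (is.null(tax)) tax <- db$taxonomy
    db <- db$sequences
  }
  replicates <- as.integer(replicates)
  if (is.na(replicates) || replicates < 1L) {
    stop("replicates must be an integer >= 1")
  }
  if (!is.list(read_length) || is.null(read_length[[1]]$model)) {
    read_length <- list(read_length)
  }
  grid <- expand.grid(n_reads = n_reads,
                      read_length = seq_along(read_length),
                      abundance_model = abundance_model,
                      diversity = diversity,
                      replicate = seq_len(replicates),
                      stringsAsFactors = FALSE)
  tm <- build_training_matrix(db, scheme, orientation)
  rows <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    g <- grid[i, ]
    rl <- read_length[[g$read_length]]
    cfg <- sim_config(n_reads = g$n_reads, diversity = g$diversity,
                      abundance_model = g$abundance_model,
                      read_length = rl, error_model = error_model,
                      seed = derive_seed(seed, i))
    res <- run_experiment(db, tax, cfg, ranks = ranks, schedule = schedule,
                          tm = tm)
    rows[[i]] <- cbind(
      data.frame(n_reads = g$n_reads,
                 read_length = if (rl$model == "fixed")
                   sprintf("fixed_%d", rl$length)
                 else sprintf("normal_%g_%g", rl$mean, rl$sd),
                 abundance_model = g$abundance_model,
                 diversity = g$diversity, replicate = g$replicate,
                 stringsAsFactors = FALSE),
      as.data.frame(as.list(setNames(res$errors,
                                     paste0("l1_", names(res$errors))))))
  }
  results <- do.call(rbind, rows)
  err_cols <- grep("^l1_", names(results), value = TRUE)
  summary <- do.call(rbind, lapply(
    c("n_reads", "read_length", "abundance_model", "diversity"),
    function(p) {
      do.call(rbind, lapply(split(results, results[[p]]), function(chunk) {
        cbind(data.frame(parameter = p, level = as.character(chunk[[p]][1]),
                         n_runs = nrow(chunk), stringsAsFactors = FALSE),
              as.data.frame(as.list(colMeans(chunk[, err_cols, drop = FALSE]))))
      }))
    }))
  rownames(summary) <- NULL
  structure(list(results = results, summary = summary, seed = seed),
            class = "sweep_result")
}
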