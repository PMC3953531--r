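# Read simulation: abundance models, error models, fixture databases.

test_that("draw_abundances evaluates the stated parametric forms", {
  expect_equal(draw_abundances("uniform", 4), rep(0.25, 4))
  expect_equal(draw_abundances("linear", 3, permute = FALSE), c(3, 2, 1) / 6)
  expect_equal(draw_abundances("powerlaw", 3, param = 1, permute = FALSE),
               c(1, 1 / 2, 1 / 3) / (11 / 6))
  r <- 0.7
  expect_equal(draw_abundances("exponential", 3, param = r, permute = FALSE),
               exp(-r * 1:3) / sum(exp(-r * 1:3)))
  expect_error(draw_abundances("powerlaw", 3, param = -1), "parameter")
  expect_error(draw_abundances("uniform", 0), "n must be")

  # permutation is seeded and mass-preserving
  a1 <- draw_abundances("powerlaw", 5, seed = 3)
  a2 <- draw_abundances("powerlaw", 5, seed = 3)
  expect_identical(a1, a2)
  expect_equal(sort(a1, decreasing = TRUE),
               draw_abundances("powerlaw", 5, permute = FALSE))
})

test_that("forward-strand error-free reads are exact source substrings", {
  set.seed(17)
  src <- c(g1 = random_dna(2000))
  cfg <- sim_config(n_reads = 100, diversity = 1,
                    read_length = fixed_length(50),
                    error_model = list(type = "none"), seed = 9)
  sim <- simulate_reads(src, cfg, strand = "forward")
  expect_length(sim$reads, 100)
  expect_true(all(nchar(sim$reads) == 50))
  expect_true(all(vapply(sim$reads, grepl, logical(1), x = src[[1]],
                         fixed = TRUE)))
  expect_true(all(sim$truth$read_source == "g1"))
})

test_that("minus-strand reads are reverse complements of source windows", {
  set.seed(18)
  src <- c(g1 = random_dna(1000))
  cfg <- sim_config(n_reads = 200, diversity = 1,
                    read_length = fixed_length(30), seed = 4)
  sim <- simulate_reads(src, cfg)
  minus <- sim$truth$read_strand == "-"
  expect_gt(sum(minus), 50)  # both strands show up
  back <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAStringSet(sim$reads[minus])))
  expect_true(all(vapply(back, grepl, logical(1), x = src[[1]],
                         fixed = TRUE)))
})

test_that("per-source read fractions follow the abundance vector", {
  set.seed(21)
  src <- setNames(replicate(2, random_dna(3000)), c("a", "b"))
  truth <- list(seq_ids = c("a", "b"), abundances = c(0.9, 0.1))
  cfg <- sim_config(n_reads = 10000, diversity = 2,
                    read_length = fixed_length(40), seed = 31)
  sim <- simulate_reads(src, cfg, truth = truth)
  frac_a <- sim$truth$read_counts[["a"]] / 10000
  sigma <- sqrt(0.9 * 0.1 / 10000)
  expect_lt(abs(frac_a - 0.9), 3 * sigma)
})

test_that("substitution errors hit at the configured rate", {
  set.seed(42)
  read <- random_dna(100)
  reads <- rep(read, 1000)
  mutated <- kmermix:::apply_substitution_errors(reads, 0.1)
  mismatches <- mapply(function(a, b) {
    sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
  }, reads, mutated)
  expect_true(mean(mismatches) >= 9 && mean(mismatches) <= 11)
  expect_identical(kmermix:::apply_substitution_errors(reads[1:5], 0),
                   reads[1:5])
})

test_that("homopolymer errors are unbiased and rare on short runs", {
  expect_identical(apply_homopolymer_errors(c("AAACCG", "T"), 0),
                   c("AAACCG", "T"))
  set.seed(11)
  out <- apply_homopolymer_errors(rep("AAAAAA", 10000), 0.15)
  expect_true(all(grepl("^A*$", out)))
  mean_len <- mean(nchar(out))
  expect_gt(mean_len, 5.8)
  expect_lt(mean_len, 6.2)

  # single-base runs: P(round(N(1, 0.15)) != 1) ~ 8.6e-4
  out1 <- apply_homopolymer_errors(rep("A", 10000), 0.15)
  expect_lt(mean(out1 != "A"), 0.01)
})

test_that("simulation is reproducible from the seed", {
  src <- setNames(replicate(3, random_dna(1000)), c("a", "b", "c"))
  cfg <- sim_config(n_reads = 500, diversity = 2, seed = 77,
                    read_length = normal_length(60, 5),
                    error_model = list(type = "homopolymer", sd_scale = 0.15))
  s1 <- simulate_reads(src, cfg)
  s2 <- simulate_reads(src, cfg)
  expect_identical(s1$reads, s2$reads)
  expect_identical(s1$truth$abundances, s2$truth$abundances)
})

test_that("validation catches impossible configurations", {
  src <- c(a = "ACGTACGTACGT")
  expect_error(
    simulate_reads(src, sim_config(n_reads = 10, diversity = 1,
                                   read_length = fixed_length(100), seed = 1)),
    "shorter than")
  expect_error(
    simulate_reads(src, sim_config(n_reads = 10, diversity = 5, seed = 1)),
    "diversity")
  expect_error(sim_config(n_reads = 0), "n_reads")
  expect_error(sim_config(error_model = list(type = "substitution", rate = 2)),
               "rate")
})

test_that("10x error-free coverage reproduces the source's training column", {
  # window-sampling noise scales as 1/sqrt(total windows), so the 0.05
  # bound needs a genome of realistic bacterial size (1 Mb here; a 100 kb
  # toy genome bottoms out near 0.07 at 10x regardless of implementation)
  set.seed(202)
  src <- c(g = random_dna(1000000))
  sc <- kmer_scheme(7)
  tm <- build_training_matrix(src, sc, "with-reverse-complement")
  cfg <- sim_config(n_reads = round(10 * 1000000 / 150), diversity = 1,
                    read_length = fixed_length(150), seed = 5)
  sim <- simulate_reads(src, cfg)
  sv <- sample_vector(sim$reads, sc, orientation = "with-reverse-complement")
  expect_lt(sum(abs(sv$freqs - tm$A[, 1])), 0.05)
})

test_that("empirical read fractions converge to the drawn abundances", {
  set.seed(303)
  src <- setNames(replicate(5, random_dna(2000)), paste0("g", 1:5))
  cfg <- sim_config(n_reads = 1e5, diversity = 5, abundance_model = "powerlaw",
                    read_length = fixed_length(50), seed = 12)
  sim <- simulate_reads(src, cfg)
  emp <- sim$truth$read_counts / sum(sim$truth$read_counts)
  expect_lt(sum(abs(emp - sim$truth$abundances)), 0.05)
})

test_that("fixture databases are deterministic and taxonomically consistent", {
  db1 <- make_fixture_database(6, 500, seed = 99, n_plasmids = 2)
  db2 <- make_fixture_database(6, 500, seed = 99, n_plasmids = 2)
  expect_identical(db1$sequences, db2$sequences)
  expect_identical(as.data.frame(db1$taxonomy), as.data.frame(db2$taxonomy))

  expect_length(db1$sequences, 8)  # 6 genomes + 2 plasmids
  expect_true(all(nchar(db1$sequences[1:6]) == 500))
  # load_taxonomy re-validates lineage consistency
  expect_s3_class(load_taxonomy(as.data.frame(db1$taxonomy)),
                  "taxonomy_table")
  # plasmids share their host lineage
  pl <- grep("_plasmid$", db1$taxonomy$seq_id, value = TRUE)
  host <- sub("_plasmid$", "", pl[1])
  lineage_of <- function(id) {
    row <- db1$taxonomy[db1$taxonomy$seq_id == id, -1]
    unlist(row, use.names = TRUE)
  }
  expect_identical(lineage_of(pl[1]), lineage_of(host))

  # forcing 2 genera under 1 phylum passes the consistency check
  db3 <- make_fixture_database(4, 300, taxonomy_shape = c(1, 1, 1, 1, 1, 2, 4),
                               seed = 1)
  expect_identical(length(unique(db3$taxonomy$genus)), 2L)
  expect_identical(length(unique(db3$taxonomy$phylum)), 1L)
})

test_that("writing and re-reading a fixture database round-trips", {
  tmp <- withr::local_tempdir()
  db <- make_fixture_database(3, 400, seed = 8)
  paths <- write_fixture_database(db, file.path(tmp, "db.fasta"),
                                  file.path(tmp, "tax.tsv"))
  seqs <- read_sequences(paths$fasta)
  expect_identical(as.character(seqs), db$sequences)
  tax <- load_taxonomy(paths$taxonomy)
  expect_identical(as.data.frame(tax), as.data.frame(db$taxonomy))
})
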