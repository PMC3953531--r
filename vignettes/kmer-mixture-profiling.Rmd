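---
title: "Whole-metagenome profiling as sparse nonnegative k-mer deconvolution"
author: "kmermix authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Whole-metagenome profiling as sparse nonnegative k-mer deconvolution}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kmermix)
```

## The model

A whole-genome shotgun (WGS) metagenome is a mixture of reads drawn from
the genomes of the organisms in the sample. Instead of classifying reads
one by one, `kmermix` summarizes the entire read set by a single
statistic — the pooled k-mer frequency vector $s \in \Delta^{4^k - 1}$ —
and models it as a convex mixture of reference k-mer profiles:

$$ A x \approx s, \qquad x \ge 0, \ \textstyle\sum_j x_j = 1, $$

where column $j$ of $A$ is the k-mer frequency vector of database
sequence $g_j$ and $x_j$ is the relative concentration of that sequence
in the sample. The model assumes (i) the sample is dominated by organisms
whose relatives are in the database, (ii) reads sample genome positions
roughly uniformly, and (iii) sequencing errors perturb $s$ mildly. None
of these hold exactly — assumption (i) in particular fails for novel
taxa, which is what the cross-validation harness quantifies.

Because any real community contains few of the database's organisms, $x$
is sparse. Nonnegative basis pursuit denoising — minimize $\|x\|_1$
subject to $\|A x - s\|_2 \le \eta$, $x \ge 0$ — is the natural sparse
recovery formulation, and for nonnegative $x$ the L1 norm is the plain
coordinate sum $\mathbf{1}^\top x$. We therefore solve the augmented
nonnegative least-squares problem

$$ x^\star(\lambda) \;=\; \arg\min_{x \ge 0}
   \left\| \begin{bmatrix} \mathbf{1}^\top \\ \lambda A \end{bmatrix} x
         - \begin{bmatrix} 1 \\ \lambda s \end{bmatrix} \right\|_2 . $$

The ones row pulls the total mass toward 1 while the data block, weighted
by $\lambda$, fits the observed k-mers. At small $\lambda$ the mass
constraint dominates and the solution collapses onto few columns
(sparsity promotion); at large $\lambda$ the problem tends to plain NNLS
on $(A, s)$. The normalized solution $x^\star / \mathbf{1}^\top x^\star$
is reported.

## Solver

The solver is a textbook Lawson–Hanson active-set NNLS, run on the normal
equations of the augmented system:

$$ M^\top M = J + \lambda^2 A^\top A, \qquad
   M^\top b = \mathbf{1} + \lambda^2 A^\top s , $$

with $J$ the all-ones matrix. Only $A^\top A$ ($N \times N$) and
$A^\top s$ enter, so a sweep over $\lambda$ re-uses one set of
crossproducts and the per-solve cost is independent of both the read
count and (after the crossproduct) nearly independent of $4^k$. The
solver is deterministic (starts at $x = 0$, no random initialization),
caps outer iterations at $10N$, and falls back to a QR solve if a
passive-set system is near-singular. Dual feasibility is tested at
$10^{-12} \cdot \max(\mathrm{diag}(M^\top M))$.

## The adaptive regularization parameter

$\lambda$ is chosen per dataset by a residual-plateau rule on a geometric
grid ($10^0, 10^1, \dots, 10^8$ by default): solve at every grid value,
record the residual $r(\lambda) = \|A \hat x(\lambda) - s\|_1$ of the
normalized solution, and return the **smallest** grid value with

$$ r(\lambda) \;\le\; (1 + \tau)\, r_{\min} + 10^{-8},
   \qquad \tau = 0.01 . $$

Ties toward small $\lambda$ deliberately favor the most
sparsity-promoting solution on the plateau. The additive floor of
$10^{-8}$ exists for exactly representable samples: there $r_{\min}$ is
numerical noise (order $10^{-12}$), a purely multiplicative band around
it would be meaninglessly narrow, and the floor makes the rule return the
smallest grid value, which is the sparsest solution consistent with the
data.

One numerical subtlety is worth recording. The quantity that provably
cannot increase with $\lambda$ is the **L2 residual of the raw
(unnormalized) solution** — the standard argument compares the two terms
of the objective at two $\lambda$ values. The L1 residual of the
*normalized* solution, which the plateau rule uses because it matches the
reporting metric, is only plateau-flat: it can wiggle by a few $10^{-4}$
(and often *rises* slightly with $\lambda$, since an L2-optimal fit is
not L1-optimal). Both residuals are recorded in the selection
diagnostics; monotonicity checks in the test suite are asserted on the
raw L2 residual, and the $\tau = 0.01$ plateau band is two orders of
magnitude wider than the wiggle, so selection is unaffected.

After normalization, entries at or below $10^{-4}$ are reported as absent
(`support`): Lawson–Hanson solutions carry numerical dust at that scale,
and $10^{-4}$ is far below any abundance the method can resolve at
desk-scale read counts. The threshold affects reporting only, never the
solve; normalization happens before thresholding.

## Strand handling

Reference genomes are stored on one strand, but shotgun reads come from
both. A read from the reverse strand contributes the reverse-complement
k-mer profile of the genomic window it covers, so a sample counted
as-sequenced is a mixture of column profiles *and their reverse
complements* — which lies outside the cone of single-strand columns and
breaks recovery (sequence-level L1 error around 0.7 on clean three-source
mixtures in our measurements). Without alignment there is no per-read
orientation oracle, so "orienting the reads" is operationalized by
**strand-symmetrized counting**: each training column pools a sequence's
k-mer counts with its reverse complement's, and the sample is counted the
same way. Symmetrization is idempotent, so reads from any strand mix then
reproduce exactly the symmetrized source profile (up to edge and
sampling noise), restoring the mixture identity. The primitive counting
functions default to as-given counting and expose
`orientation = "with-reverse-complement"`; the pipeline layer (evaluation
harness, `train`/`classify` subcommands) defaults to symmetrized
counting, and the trained database records its orientation so
classification counts the sample consistently without user intervention.
This is distinct from a canonical-k-mer (min of strand pair) scheme,
which is deliberately not implemented.

## Choice of k

`k = 7` (16,384 rows) is the default: error decreases roughly linearly
in k while memory and solve cost grow fourfold per unit, and at k = 7 a
dense double matrix for a few thousand reference sequences fits in
hundreds of megabytes. The package supports $1 \le k \le 12$; the
training database embeds k and classification refuses a mismatched k
rather than silently recounting.

## What the simulator emulates — and what it does not

The simulator provides the statistical structure needed to exercise the
profiler without external data:

* **Abundances.** Rank-abundance models with ranks assigned to the chosen
  sources by a seeded permutation: uniform ($1/n$), linear
  ($n, n-1, \dots, 1$), power law ($\mathrm{rank}^{-a}$, default $a = 1$)
  and exponential ($e^{-r\,\mathrm{rank}}$, default $r = 0.7$).
  "Abundance" means *fraction of reads*, the same scale the profiler
  estimates, so L1 evaluation is self-consistent; no genome-length
  weighting is applied.
* **Reads.** Source drawn per read from the abundance vector, start
  position uniform, strand uniform (or forced forward), length fixed or
  normal (the evaluation default is 150 ± 5 bp, a typical short-read
  configuration; lengths are truncated to the valid range).
* **Errors.** Uniform substitutions at a configurable rate, or a
  homopolymer model: each maximal run of identical bases of length $n$ is
  rewritten with length $\max(0, \mathrm{round}(\mathcal{N}(n,
  \sigma\sqrt{n})))$, $\sigma = 0.15$ by default. The $\sqrt{n}$ scaling
  makes long runs proportionally noisier, the signature of
  pyrosequencing-style homopolymer miscalls; the rounding scheme is
  empirically unbiased.

Fixture genomes are i.i.d.-uniform ACGT with a nested random taxonomy
(every taxon has exactly one parent, so lineage consistency holds by
construction). Real genomes are *easier* than this in one way — related
genomes share k-mer structure, so a held-out organism's relatives absorb
its mass — and *harder* in another: real genome profiles are correlated,
making $A^\top A$ worse-conditioned than for random fixtures. A green
test on fixtures therefore establishes the mechanics (counting, algebra,
bookkeeping, trends) but not field accuracy on real communities; no
chimeras, amplicon biases, copy-number variation or quality-model realism
are simulated.

## Evaluation harness

`run_experiment()` wires simulate → classify → score; profiles are scored
with the L1 total error $\sum_t |p(t) - q(t)| \in [0, 2]$ at any rank,
plus a top-k restricted variant (both profiles restricted to the
reference's k most abundant taxa, ties broken by name, then
renormalized — if the prediction carries no mass on those taxa the
maximal error 2 is returned). `crossval()` partitions the sequences into
seeded-random folds (a taxon-stratified option exists but is off by
default), trains on all but one fold, sources the simulated sample
exclusively from the held-out fold, and scores at the requested ranks —
the held-out organisms are novel to the classifier, so error grows toward
fine ranks, and the fold means quantify that. Fold means are averaged
with equal weight per fold even when the database size does not divide
evenly (fold sizes then differ by one; the induced weighting bias is
negligible at the tested sizes). `sweep_experiments()` runs the Cartesian
grid over read count, read length, abundance model and diversity with
seeded replicates per cell.

The cross-validation default sample configuration is power-law
abundances, diversity 10, 150 ± 5 bp reads and the homopolymer error
model; read count defaults to $10^4$ rather than $10^6$ to keep
desk-scale runs in seconds — at $10^4$ reads the k-mer sampling noise is
already well below the novelty-induced error the protocol measures.

## Numerical choices and degenerate inputs

* Windows containing any non-ACGT character are skipped deterministically
  and tallied, never randomly resolved; lowercase (masked) bases count.
* Reads shorter than k contribute no windows and are tallied, not fatal;
  a sample with zero valid windows is an explicit error.
* A database sequence with zero valid windows (e.g. all-N) fails the
  build with the sequence named; duplicate IDs are rejected.
* Column sums are validated to within $10^{-9}$ on build and on load;
  the on-disk container carries a format-version field and is rejected
  on any dimension/ID inconsistency.
* Derived seeds for folds, iterations and sweep cells come from a fixed
  affine map of the base seed, kept below $2^{31}$.
* Profile aggregation renormalizes after summing to guard float drift;
  empty-support profiles are errors, not NaNs.

## Known limitations

* Accuracy claims transfer to real data only insofar as the database
  covers the community; organisms absent at the reported rank are
  redistributed over present taxa (quantified by `crossval()`, not
  fixed by the method).
* The solver returns one point estimate; no uncertainty quantification.
* No paired-end awareness, quality trimming, or canonical-k-mer scheme.
* The dense $4^k \times N$ matrix is the memory bottleneck: practical
  limits are roughly $k \le 10$ with a few thousand reference sequences.

## A compact end-to-end run

```{r example, eval = FALSE}
db <- make_fixture_database(20, 20000, seed = 42)
scheme <- kmer_scheme(7)
tm <- build_training_matrix(db$sequences, scheme, "with-reverse-complement")
cfg <- sim_config(n_reads = 5000, diversity = 4,
                  abundance_model = "powerlaw",
                  read_length = normal_length(150, 5), seed = 7)
sim <- simulate_reads(db$sequences, cfg)
sv <- sample_vector(sim$reads, scheme, orientation = "with-reverse-complement")
est <- reconstruct(tm, sv)
l1_error(aggregate_to_rank(sim$truth$abundances, db$taxonomy, "genus"),
         aggregate_to_rank(est, db$taxonomy, "genus"))
```

On this configuration the measured genus-level total error is below 0.01
(see the README for the printed run); the package's test suite asserts
the corresponding properties at fixed seeds.
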