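# Sparsity-promoting reconstruction of the concentration vector.
#
# The sample vector s is modelled as A x with x a sparse probability
# vector. Nonnegative basis pursuit denoising
#     min ||x||_1  s.t.  ||A x - s||_2 <= eta,  x >= 0
# reduces, for nonnegative x (where ||x||_1 = sum(x)), to the augmented
# nonnegative least-squares problem
#     x* = argmin_{x >= 0} || [ 1^T ; lam * A ] x - [ 1 ; lam * s ] ||_2 ,
# i.e. ordinary NNLS on A with a top row of ones pulling sum(x) toward 1
# while lam weights the data fit. Small lam collapses mass onto few
# columns (sparsity); large lam reproduces s faithfully. lam is chosen
# adaptively per dataset by a residual-plateau rule on a geometric grid.
#
# Only crossproducts enter the solver:
#   MtM = J + lam^2 * AtA,  Mtb = 1 + lam^2 * A^T s   (J = all-ones N x N),
# so a lambda sweep reuses one AtA -- the solve cost is independent of the
# number of reads and nearly independent of 4^k.

#' Candidate grid for the adaptive regularization parameter
#'
#' A geometric grid of candidate `lambda` values together with the plateau
#' tolerance `tau` used by [select_lambda()]: the smallest grid value whose
#' L1 residual is within a factor `(1 + tau)` of the best residual over the
#' whole grid is selected (ties resolved toward small `lambda`, the most
#' sparsity-promoting choice).
#'
#' @param lambdas Strictly increasing vector of positive candidate values;
#'   default `10^(0:8)`.
#' @param tau Plateau tolerance (default 0.01).
#' @return An object of class `lambda_schedule`.
#' @export
lambda_schedule <- function(lambdas = 10^(0:8), tau = 0.01) {
  lambdas <- as.numeric(lambdas)
  if (length(lambdas) < 1L || any(!is.finite(lambdas)) || any(lambdas <= 0) ||
      is.unsorted(lambdas, strictly = TRUE)) {
    stop("lambdas must be a strictly increasing vector of positive values")
  }
  if (!is.numeric(tau) || length(tau) != 1L || tau < 0) {
    stop("tau must be a single nonnegative number")
  }
  structure(list(lambdas = lambdas, tau = tau), class = "lambda_schedule")
}

#' Lawson-Hanson nonnegative least squares on normal equations
#'
#' Active-set (Lawson-Hanson) solver for
#' `argmin_{x >= 0} ||M x - b||_2` given the crossproducts `MtM = M'M` and
#' `Mtb = M'b`. Deterministic: starts from `x = 0` and has no random
#' initialization. Used internally on the augmented system; exported
#' because it is generally useful and exercised directly by the tests.
#'
#' @param MtM Symmetric positive semi-definite `N x N` matrix.
#' @param Mtb Numeric vector of length `N`.
#' @param max_iter Iteration cap; default `10 * N` outer iterations.
#' @param tol Dual-feasibility tolerance, scaled by `max(diag(MtM))`.
#' @return List with `x` (the solution), `iterations`, and `passive`
#'   (logical support indicator).
#' @export
nnls_normal <- function(MtM, Mtb, max_iter = 10L * length(Mtb),
                        tol = 1e-12) {
  n <- length(Mtb)
  stopifnot(is.matrix(MtM), nrow(MtM) == n, ncol(MtM) == n)
  x <- numeric(n)
  passive <- logical(n)
  scale <- max(diag(MtM), 1)
  wtol <- tol * scale
  iter <- 0L
  w <- Mtb  # gradient of -0.5||Mx-b||^2 at x = 0
  repeat {
    candidates <- which(!passive & w > wtol)
    if (length(candidates) == 0L) break
    if (iter >= max_iter) {
      stop("nnls_normal did not converge within ", max_iter,
           " iterations (support size ", sum(passive), " of ", n, ")")
    }
    iter <- iter + 1L
    j <- candidates[which.max(w[candidates])]
    passive[j] <- TRUE
    repeat {
      P <- which(passive)
      z <- numeric(n)
      z[P] <- tryCatch(
        solve(MtM[P, P, drop = FALSE], Mtb[P]),
        error = function(e) qr.solve(MtM[P, P, drop = FALSE], Mtb[P],
                                     tol = 1e-12))
      if (all(z[P] > 0)) {
        x <- z
        break
      }
      neg <- P[z[P] <= 0]
      alpha <- min(x[neg] / (x[neg] - z[neg]))
      x <- x + alpha * (z - x)
      passive[P[x[P] <= tol]] <- FALSE
      x[!passive] <- 0
    }
    w <- Mtb - as.numeric(MtM %*% x)
  }
  list(x = x, iterations = iter, passive = passive)
}

## Internal fast path: solve at one lambda from precomputed crossproducts.
## AtA = A'A, Ats = A's; returns raw (unnormalized) x and iteration count.
solve_lambda_xprod <- function(AtA, Ats, lam) {
  n <- length(Ats)
  MtM <- matrix(1, n, n) + lam^2 * AtA
  Mtb <- 1 + lam^2 * Ats
  nnls_normal(MtM, Mtb)
}

as_sample_freqs <- function(s, tm) {
  if (inherits(s, "sample_vector")) {
    if (s$k != tm$k) {
      stop("k mismatch: sample counted at k = ", s$k,
           " but training matrix built at k = ", tm$k)
    }
    s$freqs
  } else {
    s <- as.numeric(s)
    if (length(s) != nrow(tm$A)) {
      stop("sample vector has length ", length(s), " but the training ",
           "matrix has ", nrow(tm$A), " rows")
    }
    s
  }
}

make_concentration <- function(x_raw, tm, s_freqs, lam, iterations,
                               support_threshold = 1e-4) {
  total <- sum(x_raw)
  if (total <= 0) stop("solver returned an all-zero concentration vector")
  x <- x_raw / total
  names(x) <- tm$seq_ids
  structure(list(x = x,
                 x_raw = x_raw,
                 support = which(x > support_threshold),
                 residual_l1 = sum(abs(as.numeric(tm$A %*% x) - s_freqs)),
                 lambda_used = lam,
                 iterations = iterations,
                 support_threshold = support_threshold),
            class = "concentration")
}

#' @export
print.concentration <- function(x, ...) {
  cat(sprintf(
    "<concentration> N = %d, support = %d (> %g), lambda = %g, L1 residual = %.4g\n",
    length(x$x), length(x$support), x$support_threshold, x$lambda_used,
    x$residual_l1))
  invisible(x)
}

#' Solve the regularized nonnegative least-squares problem at fixed lambda
#'
#' Solves `argmin_{x >= 0} || [1^T; lam A] x - [1; lam s] ||_2` by
#' Lawson-Hanson NNLS and normalizes the solution to a probability vector
#' (the raw solution is retained in `x_raw`). The ones-row anchors the
#' total mass near 1, so small `lam` promotes sparsity and large `lam`
#' prioritizes the k-mer data fit.
#'
#' @param tm A `training_matrix`.
#' @param s A `sample_vector` (same `k` as `tm`) or bare numeric frequency
#'   vector of length `4^k`.
#' @param lam Positive regularization weight on the data-fit block.
#' @param support_threshold Entries of the normalized solution at or below
#'   this value are treated as absent when reporting support
#'   (default `1e-4`; suppresses NNLS numerical dust).
#' @return An object of class `concentration`: `x` (normalized, named by
#'   sequence ID), `x_raw`, `support`, `residual_l1` (L1 norm of
#'   `A x - s`), `lambda_used`, `iterations`.
#' @export
solve_fixed_lambda <- function(tm, s, lam, support_threshold = 1e-4) {
  stopifnot(inherits(tm, "training_matrix"))
  if (!is.numeric(lam) || length(lam) != 1L || !is.finite(lam) || lam <= 0) {
    stop("lam must be a single positive number")
  }
  s_freqs <- as_sample_freqs(s, tm)
  AtA <- crossprod(tm$A)
  Ats <- as.numeric(crossprod(tm$A, s_freqs))
  fit <- solve_lambda_xprod(AtA, Ats, lam)
  make_concentration(fit$x, tm, s_freqs, lam, fit$iterations,
                     support_threshold)
}

## Shared grid sweep. Returns list(diagnostics, fits) where fits holds the
## raw solver output per grid point.
lambda_sweep <- function(tm, s_freqs, schedule) {
  AtA <- crossprod(tm$A)
  Ats <- as.numeric(crossprod(tm$A, s_freqs))
  lambdas <- schedule$lambdas
  residuals <- numeric(length(lambdas))
  residuals_l2 <- numeric(length(lambdas))
  support <- integer(length(lambdas))
  fits <- vector("list", length(lambdas))
  for (i in seq_along(lambdas)) {
    fit <- solve_lambda_xprod(AtA, Ats, lambdas[i])
    x <- fit$x / sum(fit$x)
    residuals[i] <- sum(abs(as.numeric(tm$A %*% x) - s_freqs))
    # the raw L2 data-fit residual is the quantity that is provably
    # non-increasing in lambda; the normalized L1 residual used for
    # selection can wiggle by ~1e-4 (plateau tolerance absorbs this)
    residuals_l2[i] <- sqrt(sum((as.numeric(tm$A %*% fit$x) - s_freqs)^2))
    support[i] <- sum(x > 1e-4)
    fits[[i]] <- fit
  }
  list(diagnostics = data.frame(lambda = lambdas, residual = residuals,
                                residual_l2_raw = residuals_l2,
                                support_size = support),
       fits = fits)
}

#' Adaptive choice of the regularization parameter
#'
#' Solves the augmented problem along the increasing `lambda` grid,
#' records the L1 residual `r(lambda) = ||A x(lambda) - s||_1` of each
#' normalized solution, and returns the smallest grid value whose residual
#' is within `(1 + tau)` of the minimum residual over the whole grid (plus
#' an absolute floor of 1e-8 so that exactly representable samples, where
#' every residual is numerically zero, select the smallest -- most
#' sparsity-promoting -- grid value).
#'
#' @inheritParams solve_fixed_lambda
#' @param schedule A [lambda_schedule()].
#' @return A list with `lambda` (the selected value) and `diagnostics`
#'   (data frame of `lambda`, `residual`, `support_size` per grid point).
#' @export
select_lambda <- function(tm, s, schedule = lambda_schedule()) {
  stopifnot(inherits(tm, "training_matrix"), inherits(schedule, "lambda_schedule"))
  s_freqs <- as_sample_freqs(s, tm)
  sweep <- lambda_sweep(tm, s_freqs, schedule)
  diag <- sweep$diagnostics
  rmin <- min(diag$residual)
  ok <- diag$residual <= (1 + schedule$tau) * rmin + 1e-8
  list(lambda = diag$lambda[which(ok)[1]], diagnostics = diag)
}

#' Reconstruct the concentration vector with adaptive regularization
#'
#' The full reconstruction step: selects `lambda` by the residual-plateau
#' rule ([select_lambda()]) and solves the augmented nonnegative
#' least-squares problem at the selected value, returning the normalized
#' concentration vector over database sequences.
#'
#' @inheritParams solve_fixed_lambda
#' @param schedule A [lambda_schedule()], or a single positive number to
#'   skip selection and solve at that fixed `lambda`.
#' @return A `concentration` (see [solve_fixed_lambda()]) with the grid
#'   diagnostics attached as attribute `"diagnostics"`.
#' @examples
#' tm <- build_training_matrix(c(a = "AAAAAAAA", c = "CCCCCCCC"),
#'                             kmer_scheme(1))
#' sv <- sample_vector(c("AAAA", "AAAA", "CCCC"), kmer_scheme(1))
#' reconstruct(tm, sv)$x
#' @export
reconstruct <- function(tm, s, schedule = lambda_schedule(),
                        support_threshold = 1e-4) {
  stopifnot(inherits(tm, "training_matrix"))
  if (is.numeric(schedule) && length(schedule) == 1L) {
    return(solve_fixed_lambda(tm, s, schedule, support_threshold))
  }
  stopifnot(inherits(schedule, "lambda_schedule"))
  s_freqs <- as_sample_freqs(s, tm)
  sweep <- lambda_sweep(tm, s_freqs, schedule)
  diag <- sweep$diagnostics
  rmin <- min(diag$residual)
  pick <- which(diag$residual <= (1 + schedule$tau) * rmin + 1e-8)[1]
  fit <- sweep$fits[[pick]]
  out <- make_concentration(fit$x, tm, s_freqs, diag$lambda[pick],
                            fit$iterations, support_threshold)
  attr(out, "diagnostics") <- diag
  out
}
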