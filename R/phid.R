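# Gaussian MMI-PhiID decomposition of a two-region lagged system.

DEFAULT_RIDGE <- 1e-8
CONDITION_GUARD <- 1e12

# log-determinant of a symmetric submatrix; errors if not positive definite.
.logdet <- function(S) {
  d <- determinant(S, logarithm = TRUE)
  if (d$sign <= 0) stop("covariance submatrix is not positive definite", call. = FALSE)
  as.numeric(d$modulus)
}

# Gaussian mutual information (bits) between column sets a and b of S.
.gauss_mi <- function(S, a, b) {
  ab <- c(a, b)
  0.5 * (.logdet(S[a, a, drop = FALSE]) + .logdet(S[b, b, drop = FALSE]) -
           .logdet(S[ab, ab, drop = FALSE])) / log(2)
}

#' Estimate the lagged Gaussian model of a region pair
#'
#' Z-scores the two series, aligns their past (`t - tau`) and present (`t`)
#' segments, and returns the 4x4 sample covariance of the stacked vector
#' (x1 past, x2 past, x1 now, x2 now). A small ridge is added to the
#' diagonal so the matrix stays positive definite even for degenerate input
#' (e.g. one series an exact copy of the other).
#'
#' @param x1,x2 Numeric vectors of equal length `T` (BOLD samples).
#' @param tau Positive integer lag in samples; `T - tau` must be at least 20.
#' @param ridge Diagonal jitter added to the covariance.
#' @return An object of class `lagged_gaussian_model`: list with elements
#'   `cov` (4x4 covariance), `tau` and `n_obs` (number of aligned pairs).
#' @examples
#' set.seed(1)
#' m <- estimate_lagged_covariance(rnorm(200), rnorm(200), tau = 1)
#' round(m$cov, 2)
#' @export
estimate_lagged_covariance <- function(x1, x2, tau = 1L, ridge = DEFAULT_RIDGE) {
  if (length(x1) != length(x2)) {
    stop("`x1` and `x2` must have the same length (got ",
         length(x1), " and ", length(x2), ")", call. = FALSE)
  }
  if (!all(is.finite(x1)) || !all(is.finite(x2))) {
    stop("series contain non-finite values", call. = FALSE)
  }
  tau <- as.integer(tau)
  if (tau < 1L) stop("`tau` must be a positive integer lag", call. = FALSE)
  n <- length(x1) - tau
  if (n < 20L) {
    stop("series too short: need at least tau + 20 samples, got ",
         length(x1), " with tau = ", tau, call. = FALSE)
  }
  s1 <- sd(x1); s2 <- sd(x2)
  if (s1 == 0 || s2 == 0) {
    stop("constant series (zero variance) cannot be decomposed", call. = FALSE)
  }
  z1 <- (x1 - mean(x1)) / s1
  z2 <- (x2 - mean(x2)) / s2
  past <- cbind(z1[seq_len(n)], z2[seq_len(n)])
  now <- cbind(z1[seq_len(n) + tau], z2[seq_len(n) + tau])
  S <- cov(cbind(past, now))
  diag(S) <- diag(S) + ridge
  dimnames(S) <- list(NULL, NULL)
  structure(list(cov = S, tau = tau, n_obs = n),
            class = "lagged_gaussian_model")
}

#' Build a `lagged_gaussian_model` from a covariance matrix
#'
#' Wraps an externally supplied (e.g. analytic) 4x4 covariance of the stacked
#' (x1 past, x2 past, x1 now, x2 now) vector for use with
#' [phiid_decompose()].
#'
#' @param cov 4x4 symmetric positive-definite matrix.
#' @param tau Lag the covariance refers to (bookkeeping only).
#' @return A `lagged_gaussian_model`.
#' @export
lagged_gaussian_model <- function(cov, tau = 1L) {
  cov <- as.matrix(cov)
  if (!identical(dim(cov), c(4L, 4L))) stop("`cov` must be 4x4", call. = FALSE)
  if (max(abs(cov - t(cov))) > 1e-8) stop("`cov` must be symmetric", call. = FALSE)
  if (any(diag(cov) <= 0)) stop("`cov` must have positive diagonal", call. = FALSE)
  structure(list(cov = cov, tau = as.integer(tau), n_obs = NA_integer_),
            class = "lagged_gaussian_model")
}

#' Gaussian mutual information between variable subsets of a lagged model
#'
#' Closed-form Gaussian mutual information, in bits:
#' `I(A; B) = 0.5 * log2(det(S_A) * det(S_B) / det(S_AB))`.
#'
#' @param model A `lagged_gaussian_model`.
#' @param set_a,set_b Disjoint, non-empty subsets of `1:4` indexing the
#'   stacked vector (x1 past, x2 past, x1 now, x2 now).
#' @return Mutual information in bits (non-negative up to numerical
#'   tolerance, symmetric in its arguments).
#' @examples
#' S <- diag(4); S[1, 3] <- S[3, 1] <- 0.5
#' gaussian_mi(lagged_gaussian_model(S), 1, 3)  # -0.5 * log2(1 - 0.25)
#' @export
gaussian_mi <- function(model, set_a, set_b) {
  stopifnot(inherits(model, "lagged_gaussian_model"))
  set_a <- as.integer(set_a); set_b <- as.integer(set_b)
  if (length(set_a) == 0L || length(set_b) == 0L) {
    stop("variable sets must be non-empty", call. = FALSE)
  }
  if (!all(c(set_a, set_b) %in% 1:4)) {
    stop("variable sets must index the stacked vector 1:4", call. = FALSE)
  }
  if (length(intersect(set_a, set_b)) > 0L) {
    stop("`set_a` and `set_b` must be disjoint", call. = FALSE)
  }
  ab <- c(set_a, set_b)
  kap <- kappa(model$cov[ab, ab, drop = FALSE], exact = TRUE)
  if (!is.finite(kap) || kap > CONDITION_GUARD) {
    stop("covariance submatrix is numerically singular (condition number ",
         format(kap, digits = 3), " exceeds 1e12)", call. = FALSE)
  }
  .gauss_mi(model$cov, set_a, set_b)
}

#' Minimum-mutual-information redundancy
#'
#' The MMI redundancy function: the minimum of the candidate mutual
#' informations. Used both for the single-sided redundancies of the lattice
#' (minimum over source or target components) and for the predefined double
#' redundancy (minimum over all pairwise lagged mutual informations).
#'
#' @param mis Non-empty numeric vector of mutual informations (bits).
#' @return The minimum, in bits.
#' @export
mmi_redundancy <- function(mis) {
  if (length(mis) == 0L) stop("`mis` must be non-empty", call. = FALSE)
  if (!is.numeric(mis) || any(!is.finite(mis))) {
    stop("`mis` must be finite numeric values", call. = FALSE)
  }
  min(mis)
}

# Cumulative informed values for all 16 lattice atoms of a 4x4 covariance.
.phiid_icap <- function(S) {
  lat <- phiid_lattice()
  pair_mi <- c(m11 = .gauss_mi(S, 1L, 3L), m12 = .gauss_mi(S, 1L, 4L),
               m21 = .gauss_mi(S, 2L, 3L), m22 = .gauss_mi(S, 2L, 4L))
  vapply(seq_len(nrow(lat)), function(k) {
    s <- lat$source[k]; t <- lat$target[k]
    switch(lat$eval[k],
      mi = .gauss_mi(S, SRC_COLS[[s]], TGT_COLS[[t]]),
      red_forward = mmi_redundancy(c(.gauss_mi(S, 1L, TGT_COLS[[t]]),
                                     .gauss_mi(S, 2L, TGT_COLS[[t]]))),
      red_backward = mmi_redundancy(c(.gauss_mi(S, SRC_COLS[[s]], 3L),
                                      .gauss_mi(S, SRC_COLS[[s]], 4L))),
      double_red = mmi_redundancy(pair_mi))
  }, numeric(1))
}

#' Integrated information decomposition of a lagged Gaussian model
#'
#' Computes the 16 cumulative informed values of the PhiID lattice under the
#' MMI redundancy function (9 plain Gaussian mutual informations, 3 forward
#' and 3 backward single-sided redundancies, and the predefined double
#' redundancy), then recovers the atoms by Moebius inversion over the product
#' order: atoms are visited in topological order and the strictly-lower atoms
#' already solved are subtracted from each cumulative value.
#'
#' The atoms sum to the time-delayed mutual information between the joint
#' past and the joint present (conservation holds to solver precision).
#' Individual atoms may be slightly negative under MMI; no clipping is done
#' here — flooring is a connectivity-level policy.
#'
#' @param model A `lagged_gaussian_model`.
#' @return An object of class `phiid_atoms`: list with `atoms` (data frame
#'   `source`, `target`, `i_cap`, `i_partial` in bits), `tdmi` and `tau`.
#' @examples
#' S <- diag(4); S[1, 3] <- S[3, 1] <- 0.8; S[2, 4] <- S[4, 2] <- 0.8
#' phiid_decompose(lagged_gaussian_model(S))
#' @export
phiid_decompose <- function(model) {
  stopifnot(inherits(model, "lagged_gaussian_model"))
  lat <- phiid_lattice()
  icap <- .phiid_icap(model$cov)
  leq16 <- lattice_leq()
  ipart <- numeric(nrow(lat))
  for (k in lattice_topo_order()) {
    below <- leq16[, k]
    below[k] <- FALSE
    ipart[k] <- icap[k] - sum(ipart[below])
  }
  atoms <- cbind(lat[, c("source", "target")],
                 data.frame(i_cap = icap, i_partial = ipart))
  structure(list(atoms = atoms,
                 tdmi = icap[lat$source == "syn" & lat$target == "syn"],
                 tau = model$tau),
            class = "phiid_atoms")
}

#' @export
print.phiid_atoms <- function(x, digits = 4, ...) {
  cat("PhiID atoms (MMI, bits); tau =", x$tau, "\n")
  m <- matrix(x$atoms$i_partial, 4L, 4L, byrow = TRUE,
              dimnames = list(source = PID_LABELS, target = PID_LABELS))
  print(round(m, digits))
  cat("TDMI:", format(x$tdmi, digits = digits + 2),
      " sum of atoms:", format(sum(x$atoms$i_partial), digits = digits + 2), "\n")
  invisible(x)
}

# Extract one atom by pattern pair.
phiid_atom <- function(x, source, target) {
  stopifnot(inherits(x, "phiid_atoms"))
  x$atoms$i_partial[x$atoms$source == source & x$atoms$target == target]
}

#' Persistent synergy of a region pair
#'
#' Convenience composition: estimate the lagged Gaussian model of the two
#' series, decompose it, and return the syn -> syn atom (the information the
#' joint past carries about the joint present exclusively synergistically).
#' Symmetric under swapping `x1` and `x2`.
#'
#' @inheritParams estimate_lagged_covariance
#' @return The syn -> syn atom in bits (may be slightly negative).
#' @examples
#' set.seed(1)
#' synergy(rnorm(500), rnorm(500), tau = 1)
#' @export
synergy <- function(x1, x2, tau = 1L) {
  phiid_atom(phiid_decompose(estimate_lagged_covariance(x1, x2, tau)),
             "syn", "syn")
}
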