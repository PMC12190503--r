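# Independent brute-force oracles. These share no code with the package
# internals: mutual information via eigenvalues, the atom order via explicit
# down-set tables, atoms via a dense zeta-matrix solve, distances via
# Floyd-Warshall, and the node metrics via literal double/triple loops.

# --- PhiID oracle -----------------------------------------------------------

oracle_pid_downsets <- list(
  red = "red",
  un1 = c("red", "un1"),
  un2 = c("red", "un2"),
  syn = c("red", "un1", "un2", "syn"))

oracle_atom_order <- local({
  labs <- c("red", "un1", "un2", "syn")
  out <- list()
  for (s in labs) for (t in labs) out[[length(out) + 1L]] <- c(s, t)
  out
})

oracle_mi <- function(S, a, b) {
  ld <- function(idx) sum(log(eigen(S[idx, idx, drop = FALSE],
                                    symmetric = TRUE,
                                    only.values = TRUE)$values))
  0.5 * (ld(a) + ld(b) - ld(c(a, b))) / log(2)
}

# Cumulative lattice values per the MMI definitions, written from scratch.
oracle_icap <- function(S) {
  src <- list(un1 = 1, un2 = 2, syn = c(1, 2))
  tgt <- list(un1 = 3, un2 = 4, syn = c(3, 4))
  vapply(oracle_atom_order, function(node) {
    s <- node[1]; t <- node[2]
    if (s == "red" && t == "red") {
      min(oracle_mi(S, 1, 3), oracle_mi(S, 1, 4),
          oracle_mi(S, 2, 3), oracle_mi(S, 2, 4))
    } else if (s == "red") {
      min(oracle_mi(S, 1, tgt[[t]]), oracle_mi(S, 2, tgt[[t]]))
    } else if (t == "red") {
      min(oracle_mi(S, src[[s]], 3), oracle_mi(S, src[[s]], 4))
    } else {
      oracle_mi(S, src[[s]], tgt[[t]])
    }
  }, numeric(1))
}

# Atoms by solving the full inclusion-exclusion system zeta %*% atoms = icap.
oracle_phiid <- function(S) {
  icap <- oracle_icap(S)
  n <- length(oracle_atom_order)
  zeta <- matrix(0, n, n)
  for (x in seq_len(n)) {
    for (y in seq_len(n)) {
      a <- oracle_atom_order[[y]]; b <- oracle_atom_order[[x]]
      if (a[1] %in% oracle_pid_downsets[[b[1]]] &&
          a[2] %in% oracle_pid_downsets[[b[2]]]) {
        zeta[x, y] <- 1
      }
    }
  }
  list(icap = icap, ipart = drop(solve(zeta, icap)))
}

oracle_atom_index <- function(source, target) {
  which(vapply(oracle_atom_order, function(n) {
    n[1] == source && n[2] == target
  }, logical(1)))
}

rand_pd4 <- function() {
  A <- matrix(rnorm(16), 4)
  crossprod(A) + 0.5 * diag(4)
}

# --- graph oracles ----------------------------------------------------------

oracle_distances <- function(W) {
  n <- nrow(W)
  D <- ifelse(W > 0, 1 / W, Inf)
  diag(D) <- 0
  for (k in seq_len(n)) {
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (D[i, k] + D[k, j] < D[i, j]) D[i, j] <- D[i, k] + D[k, j]
      }
    }
  }
  D
}

oracle_cpl <- function(W) {
  D <- oracle_distances(W)
  off <- D[row(D) != col(D)]
  mean(off[is.finite(off)])
}

oracle_clustering <- function(W) {
  n <- nrow(W)
  cw <- numeric(n)
  for (i in seq_len(n)) {
    nb <- which(W[i, ] > 0)
    k <- length(nb)
    if (k < 2) next
    s <- 0
    for (j in nb) for (l in nb) {
      if (j != l) s <- s + (W[i, j] * W[j, l] * W[l, i])^(1 / 3)
    }
    cw[i] <- s / (k * (k - 1))
  }
  cw
}

oracle_commcap <- function(W, coords) {
  n <- nrow(W)
  out <- numeric(n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (j != i && W[i, j] > 0) {
        out[i] <- out[i] + W[i, j] / sqrt(sum((coords[i, ] - coords[j, ])^2))
      }
    }
  }
  out
}

# --- fixtures ---------------------------------------------------------------

# Random sparsified graph with coordinates, for oracle-equivalence tests.
rand_graph <- function(n = 15, seed = 1, fraction = 0.3) {
  set.seed(seed)
  W <- matrix(0, n, n)
  W[upper.tri(W)] <- runif(n * (n - 1) / 2)
  W <- W + t(W)
  coords <- matrix(runif(3 * n, -50, 50), n, 3)
  sparsify_top_fraction(W, fraction = fraction, coords = coords)
}

# A miniature multi-stage study for IO/pipeline tests.
tiny_study <- function(seed = 5, n_regions = 6, n_timepoints = 60,
                       stages = c(CN = 3, AD = 4), affected = NULL) {
  model <- var_model(diag(0.4, n_regions) +
                       0.1 * (abs(row(diag(n_regions)) -
                                    col(diag(n_regions))) == 1))
  design <- study_design(stages, affected = affected,
                         n_timepoints = n_timepoints, seed = seed)
  generate_study(design, model)
}
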