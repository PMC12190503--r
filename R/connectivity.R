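# Per-subject region x region connectivity matrices (mutual information or
# persistent synergy).

#' Connectivity matrix container
#'
#' @param weights Square symmetric numeric matrix (bits) with zero diagonal;
#'   dimnames give the region names.
#' @param method `"mi"` or `"syn"`.
#' @param tau Lag used (relevant for `"syn"`).
#' @param n_floored Number of negative synergy estimates floored to zero.
#' @return An object of class `connectivity_matrix`.
#' @export
connectivity_matrix <- function(weights, method = c("mi", "syn"), tau = 1L,
                                n_floored = 0L) {
  method <- match.arg(method)
  weights <- as.matrix(weights)
  if (nrow(weights) != ncol(weights)) stop("`weights` must be square", call. = FALSE)
  if (is.null(rownames(weights))) {
    rownames(weights) <- colnames(weights) <-
      sprintf("ROI_%03d", seq_len(nrow(weights)))
  }
  if (any(!is.finite(weights))) stop("`weights` must be finite", call. = FALSE)
  if (max(abs(weights - t(weights))) > 1e-12) {
    stop("`weights` must be symmetric", call. = FALSE)
  }
  if (any(diag(weights) != 0)) stop("diagonal must be zero", call. = FALSE)
  if (method == "mi" && any(weights < 0)) {
    stop("mutual-information weights must be non-negative", call. = FALSE)
  }
  structure(list(weights = weights, method = method, tau = as.integer(tau),
                 region_names = rownames(weights),
                 n_floored = as.integer(n_floored)),
            class = "connectivity_matrix")
}

#' @export
print.connectivity_matrix <- function(x, ...) {
  cat("Connectivity matrix (", x$method, "): ", length(x$region_names),
      " regions", if (x$method == "syn") paste0(", tau = ", x$tau), "\n",
      sep = "")
  if (x$n_floored > 0) {
    cat(x$n_floored, "negative synergy estimates floored to 0\n")
  }
  invisible(x)
}

# Z-score columns; errors name the offending constant region.
zscore_regions <- function(ts) {
  ts <- as.matrix(ts)
  if (is.null(colnames(ts))) {
    colnames(ts) <- sprintf("ROI_%03d", seq_len(ncol(ts)))
  }
  if (any(!is.finite(ts))) stop("time series contain non-finite values", call. = FALSE)
  sds <- apply(ts, 2, sd)
  if (any(sds == 0)) {
    stop("constant region(s): ", paste(colnames(ts)[sds == 0], collapse = ", "),
         call. = FALSE)
  }
  scale(ts)
}

# Raw (unfloored) pairwise syn->syn matrix from a joint past/present
# covariance; `engine = "r"` is the slow reference path over the same
# covariance entries, used to validate the compiled kernel.
syn_pairs_from_cov <- function(Sbig, n, ridge = DEFAULT_RIDGE,
                               engine = c("cpp", "r")) {
  engine <- match.arg(engine)
  lat <- phiid_lattice()
  syn_row <- lattice_mobius()[lat$source == "syn" & lat$target == "syn", ]
  if (engine == "cpp") {
    return(phid_syn_pairs_cpp(Sbig, n, ridge, syn_row))
  }
  out <- matrix(0, n, n)
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1L, n)) {
      idx <- c(i, j, n + i, n + j)
      S <- Sbig[idx, idx]
      diag(S) <- diag(S) + ridge
      out[i, j] <- out[j, i] <- sum(syn_row * .phiid_icap(S))
    }
  }
  out
}

#' Build a subject's connectivity matrix
#'
#' For every unordered region pair, computes either the static Gaussian
#' mutual information of the two z-scored series (zero lag, `method = "mi"`)
#' or the persistent-synergy atom of the lagged pair decomposition
#' (`method = "syn"`). Synergy estimates below zero are floored to 0 (the
#' downstream graph metrics require non-negative weights); the count of
#' floored entries is retained in the result.
#'
#' @param ts Time x region numeric matrix (column names are region names).
#' @param method `"mi"` or `"syn"`.
#' @param tau Lag in samples for the synergy decomposition.
#' @param engine Internal: `"cpp"` (compiled pairwise kernel) or `"r"`
#'   (reference loop); both produce identical values.
#' @return A `connectivity_matrix`.
#' @examples
#' set.seed(1)
#' ts <- matrix(rnorm(300), 100, 3, dimnames = list(NULL, c("a", "b", "c")))
#' build_matrix(ts, method = "mi")
#' @export
build_matrix <- function(ts, method = c("mi", "syn"), tau = 1L,
                         engine = c("cpp", "r")) {
  method <- match.arg(method)
  engine <- match.arg(engine)
  z <- zscore_regions(ts)
  n <- ncol(z)
  if (n < 2L) stop("need at least 2 regions", call. = FALSE)
  if (method == "mi") {
    S <- cov(z)
    diag(S) <- diag(S) + DEFAULT_RIDGE
    d <- diag(S)
    rho2 <- (S^2) / outer(d, d)
    rho2 <- pmin(rho2, 1 - 1e-15)
    W <- -0.5 * log2(1 - rho2)
    diag(W) <- 0
    W <- (W + t(W)) / 2
    dimnames(W) <- list(colnames(z), colnames(z))
    return(connectivity_matrix(W, method = "mi", tau = tau))
  }
  tau <- as.integer(tau)
  nT <- nrow(z) - tau
  if (nT < 20L) {
    stop("series too short for tau = ", tau, ": need at least tau + 20 samples",
         call. = FALSE)
  }
  past <- z[seq_len(nT), , drop = FALSE]
  now <- z[seq_len(nT) + tau, , drop = FALSE]
  Sbig <- cov(cbind(past, now))
  W <- syn_pairs_from_cov(Sbig, n, engine = engine)
  n_floored <- sum(W[upper.tri(W)] < 0)
  W[W < 0] <- 0
  diag(W) <- 0
  dimnames(W) <- list(colnames(z), colnames(z))
  connectivity_matrix(W, method = "syn", tau = tau, n_floored = n_floored)
}

#' Population synergy matrix of a VAR(1) model
#'
#' Analytic counterpart of `build_matrix(..., method = "syn")`: the
#' syn -> syn atom of every region pair computed from the model's stationary
#' covariance instead of from simulated data. Used to designate ground-truth
#' hub nodes and as an estimation-noise-free reference in tests.
#'
#' @param model A stationary `var_model`.
#' @param tau Positive integer lag.
#' @return A `connectivity_matrix` with `method = "syn"`.
#' @export
analytic_synergy_matrix <- function(model, tau = 1L) {
  stopifnot(inherits(model, "var_model"))
  assert_stationary(model)
  p <- model$n_regions
  S <- stationary_covariance(model)
  Ak <- diag(p)
  for (k in seq_len(as.integer(tau))) Ak <- model$coupling %*% Ak
  G <- Ak %*% S
  d <- sqrt(diag(S))
  Sn <- S / outer(d, d)
  Gn <- G / outer(d, d)
  Sbig <- rbind(cbind(Sn, t(Gn)), cbind(Gn, Sn))
  W <- syn_pairs_from_cov(Sbig, p, ridge = 0)
  n_floored <- sum(W[upper.tri(W)] < 0)
  W[W < 0] <- 0
  diag(W) <- 0
  dimnames(W) <- list(sprintf("ROI_%03d", seq_len(p)),
                      sprintf("ROI_%03d", seq_len(p)))
  connectivity_matrix(W, method = "syn", tau = tau, n_floored = n_floored)
}
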