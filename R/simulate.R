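# Surrogate BOLD generator: stationary VAR(1) region dynamics with
# stage-specific attenuation of inter-regional coupling at designated nodes.

STAGE_LEVELS <- c("CN", "EMCI", "LMCI", "AD")
NETWORK_LABELS <- c("VIS", "SMN", "DAN", "VAN", "LN", "FN", "DMN", "OTH")

#' First-order vector-autoregressive model
#'
#' @param coupling Square matrix of autoregressive coefficients; entry (i, j)
#'   is the influence of region j at time t-1 on region i at time t. Its
#'   spectral radius must be below 1 (stationarity).
#' @param noise_sd Innovation standard deviation, recycled to one value per
#'   region; must be positive.
#' @return An object of class `var_model` with elements `coupling`,
#'   `noise_sd`, `n_regions` and `spectral_radius`.
#' @examples
#' m <- var_model(matrix(c(0.5, 0.2, 0.2, 0.5), 2, 2))
#' m$spectral_radius
#' @export
var_model <- function(coupling, noise_sd = 1) {
  coupling <- as.matrix(coupling)
  if (nrow(coupling) != ncol(coupling) || !is.numeric(coupling) ||
      any(!is.finite(coupling))) {
    stop("`coupling` must be a finite square numeric matrix", call. = FALSE)
  }
  p <- nrow(coupling)
  noise_sd <- rep_len(as.numeric(noise_sd), p)
  if (any(!is.finite(noise_sd)) || any(noise_sd <= 0)) {
    stop("`noise_sd` must be positive for every region", call. = FALSE)
  }
  rad <- max(Mod(eigen(coupling, only.values = TRUE)$values))
  structure(list(coupling = coupling, noise_sd = noise_sd,
                 n_regions = p, spectral_radius = rad),
            class = "var_model")
}

#' @export
print.var_model <- function(x, ...) {
  cat("VAR(1) model:", x$n_regions, "regions, spectral radius",
      format(x$spectral_radius, digits = 4), "\n")
  invisible(x)
}

assert_stationary <- function(model) {
  if (model$spectral_radius >= 1) {
    stop("VAR coupling is non-stationary: spectral radius ",
         format(model$spectral_radius, digits = 4), " >= 1", call. = FALSE)
  }
}

#' Stationary covariance of a VAR(1) model
#'
#' Solves the discrete Lyapunov equation `S = A S A' + Q` (with
#' `Q = diag(noise_sd^2)`) by doubling, so no Kronecker system is formed and
#' large region counts stay cheap.
#'
#' @param model A stationary `var_model`.
#' @param iterations Number of doubling steps (each squares the effective
#'   horizon; the default is far past double-precision convergence).
#' @return The stationary covariance matrix of the process.
#' @export
stationary_covariance <- function(model, iterations = 60L) {
  stopifnot(inherits(model, "var_model"))
  assert_stationary(model)
  S <- diag(model$noise_sd^2, model$n_regions)
  Ak <- model$coupling
  for (k in seq_len(iterations)) {
    S <- S + Ak %*% S %*% t(Ak)
    Ak <- Ak %*% Ak
    if (max(abs(Ak)) < 1e-300) break
  }
  (S + t(S)) / 2
}

#' Analytic lagged Gaussian model of a region pair under a VAR(1) process
#'
#' Assembles the population 4x4 covariance of
#' (x_i at t-tau, x_j at t-tau, x_i at t, x_j at t) from the stationary
#' covariance `S` and the lagged cross-covariance `A^tau S`, standardized to
#' unit variances (mutual information is scale invariant). Useful as an
#' estimation-noise-free reference for the decomposition.
#'
#' @param model A stationary `var_model`.
#' @param i,j Distinct region indices.
#' @param tau Positive integer lag.
#' @return A `lagged_gaussian_model`.
#' @export
lagged_pair_model <- function(model, i, j, tau = 1L) {
  stopifnot(inherits(model, "var_model"))
  assert_stationary(model)
  i <- as.integer(i); j <- as.integer(j); tau <- as.integer(tau)
  if (i == j || any(c(i, j) < 1L) || any(c(i, j) > model$n_regions)) {
    stop("`i` and `j` must be distinct region indices", call. = FALSE)
  }
  S <- stationary_covariance(model)
  G <- S
  Ak <- diag(model$n_regions)
  for (k in seq_len(tau)) Ak <- model$coupling %*% Ak
  G <- Ak %*% S                        # cov(x_t, x_{t-tau})
  idx <- c(i, j)
  S4 <- rbind(cbind(S[idx, idx], t(G[idx, idx])),
              cbind(G[idx, idx], S[idx, idx]))
  d <- sqrt(diag(S4))
  lagged_gaussian_model(S4 / outer(d, d), tau = tau)
}

#' Simulate one subject's regional time series from a VAR(1) model
#'
#' Runs the recursion `x_t = A x_{t-1} + e_t` with independent Gaussian
#' innovations, discards a burn-in prefix, and returns the remaining samples.
#' Identical seeds and models give bit-identical output.
#'
#' @param model A stationary `var_model`.
#' @param n_timepoints Number of retained samples (at least 50).
#' @param seed Integer seed for this subject's innovations.
#' @param burn_in Discarded prefix length.
#' @return A numeric matrix with `n_timepoints` rows (time) and one column
#'   per region.
#' @examples
#' m <- var_model(diag(0.5, 3))
#' x <- generate_var_subject(m, n_timepoints = 100, seed = 1)
#' dim(x)
#' @export
generate_var_subject <- function(model, n_timepoints = 140L, seed,
                                 burn_in = 200L) {
  stopifnot(inherits(model, "var_model"))
  assert_stationary(model)
  n_timepoints <- as.integer(n_timepoints)
  if (n_timepoints < 50L) {
    stop("`n_timepoints` must be at least 50 (got ", n_timepoints, ")",
         call. = FALSE)
  }
  p <- model$n_regions
  total <- burn_in + n_timepoints
  eps <- with_local_seed(seed, matrix(rnorm(p * total), p, total)) *
    model$noise_sd
  A <- model$coupling
  x <- numeric(p)
  out <- matrix(0, n_timepoints, p)
  for (t in seq_len(total)) {
    x <- drop(A %*% x) + eps[, t]
    if (t > burn_in) out[t - burn_in, ] <- x
  }
  out
}

#' Multi-stage study design for the surrogate generator
#'
#' @param stages Named integer vector of subjects per stage, in progression
#'   order (e.g. `c(CN = 34, EMCI = 60, LMCI = 59, AD = 50)`).
#' @param affected Data frame with columns `stage`, `node`, `factor`
#'   describing coupling attenuation: from stage `stage` onward, the
#'   off-diagonal coupling row and column of region `node` are multiplied by
#'   `factor` (in (0, 1]; attenuations at successive stages are cumulative).
#'   May have zero rows (null study).
#' @param n_timepoints Samples per subject.
#' @param seed Study-level seed; every subject seed derives from it.
#' @return An object of class `study_design`.
#' @export
study_design <- function(stages, affected = NULL, n_timepoints = 140L,
                         seed = 1L) {
  if (is.null(names(stages)) || any(!nzchar(names(stages)))) {
    stop("`stages` must be a named vector of subject counts", call. = FALSE)
  }
  stages <- setNames(as.integer(stages), names(stages))
  if (any(stages <= 0L)) stop("stage subject counts must be positive", call. = FALSE)
  if (is.null(affected)) {
    affected <- data.frame(stage = character(), node = integer(),
                           factor = numeric())
  }
  if (!all(c("stage", "node", "factor") %in% names(affected))) {
    stop("`affected` needs columns stage, node, factor", call. = FALSE)
  }
  if (nrow(affected) > 0) {
    if (any(!affected$stage %in% names(stages))) {
      stop("`affected` refers to unknown stages: ",
           paste(setdiff(affected$stage, names(stages)), collapse = ", "),
           call. = FALSE)
    }
    if (any(affected$stage == names(stages)[1])) {
      stop("attenuation cannot start at the first (reference) stage", call. = FALSE)
    }
    if (any(affected$factor <= 0) || any(affected$factor > 1)) {
      stop("attenuation factors must lie in (0, 1]", call. = FALSE)
    }
  }
  structure(list(stages = stages, affected = affected,
                 n_timepoints = as.integer(n_timepoints),
                 seed = as.integer(seed)),
            class = "study_design")
}

#' Region metadata table
#'
#' Generates a node-metadata table: unique region names, a resting-state
#' network label per region (contiguous blocks over the eight canonical
#' labels), and 3-D centroid coordinates drawn uniformly inside a
#' brain-sized bounding box (mm).
#'
#' @param n_regions Number of regions.
#' @param seed Seed for the coordinates.
#' @return Data frame with columns `region`, `network`, `x_mm`, `y_mm`,
#'   `z_mm`.
#' @export
node_metadata <- function(n_regions, seed = 1L) {
  region <- sprintf("ROI_%03d", seq_len(n_regions))
  network <- rep(NETWORK_LABELS, each = ceiling(n_regions / 8))[seq_len(n_regions)]
  coords <- with_local_seed(seed, {
    repeat {
      xyz <- cbind(runif(n_regions, -70, 70),
                   runif(n_regions, -105, 70),
                   runif(n_regions, -45, 80))
      if (!anyDuplicated(round(xyz, 6))) break
    }
    xyz
  })
  data.frame(region = region, network = network,
             x_mm = coords[, 1], y_mm = coords[, 2], z_mm = coords[, 3])
}

# Stage-specific coupling matrices under cumulative attenuation.
stage_coupling <- function(design, base_model) {
  p <- base_model$n_regions
  cum <- rep(1, p)
  out <- list()
  for (s in names(design$stages)) {
    rows <- design$affected[design$affected$stage == s, , drop = FALSE]
    if (nrow(rows) > 0) {
      if (any(rows$node < 1L) || any(rows$node > p)) {
        stop("affected node index outside 1..", p, call. = FALSE)
      }
      for (r in seq_len(nrow(rows))) {
        cum[rows$node[r]] <- cum[rows$node[r]] * rows$factor[r]
      }
    }
    A <- base_model$coupling
    for (v in which(cum < 1)) {
      A[v, -v] <- A[v, -v] * cum[v]
      A[-v, v] <- A[-v, v] * cum[v]
    }
    out[[s]] <- var_model(A, base_model$noise_sd)
  }
  out
}

#' Generate a complete multi-stage surrogate study
#'
#' Each stage's subjects are simulated from the base model with the
#' cumulative attenuation of all transitions up to that stage applied to the
#' affected nodes' inter-regional coupling (rescaling toward zero can only
#' shrink the spectral radius, so stationarity is preserved). Subject seeds
#' derive deterministically from `design$seed`.
#'
#' @param design A `study_design`.
#' @param base_model A stationary `var_model` whose dimension the design's
#'   affected nodes must respect.
#' @param metadata Optional `node_metadata()`-style data frame; generated
#'   from the design seed when omitted.
#' @return An object of class `synth_study`: list with `series` (named list
#'   of time x region matrices), `manifest` (subject_id, stage), `metadata`,
#'   `ground_truth` (affected nodes per stage transition), `stage_models`
#'   and `design`.
#' @examples
#' m <- var_model(diag(0.4, 2))
#' d <- study_design(c(CN = 3, AD = 4), n_timepoints = 60, seed = 7)
#' st <- generate_study(d, m)
#' nrow(st$manifest)
#' @export
generate_study <- function(design, base_model, metadata = NULL) {
  stopifnot(inherits(design, "study_design"), inherits(base_model, "var_model"))
  assert_stationary(base_model)
  models <- stage_coupling(design, base_model)
  if (is.null(metadata)) {
    metadata <- node_metadata(base_model$n_regions,
                              seed = derive_seed(design$seed, 0L))
  }
  if (nrow(metadata) != base_model$n_regions) {
    stop("metadata has ", nrow(metadata), " regions but the model has ",
         base_model$n_regions, call. = FALSE)
  }
  series <- list()
  manifest <- data.frame(subject_id = character(), stage = character())
  k <- 0L
  for (s in names(design$stages)) {
    for (i in seq_len(design$stages[[s]])) {
      k <- k + 1L
      id <- sprintf("sub-%03d", k)
      x <- generate_var_subject(models[[s]], design$n_timepoints,
                                seed = derive_seed(design$seed, k))
      colnames(x) <- metadata$region
      series[[id]] <- x
      manifest <- rbind(manifest, data.frame(subject_id = id, stage = s))
    }
  }
  stage_names <- names(design$stages)
  ground_truth <- lapply(seq_along(stage_names)[-1], function(si) {
    rows <- design$affected[design$affected$stage == stage_names[si], ,
                            drop = FALSE]
    list(transition = paste(stage_names[si - 1L], stage_names[si], sep = "-"),
         nodes = as.integer(rows$node),
         regions = metadata$region[rows$node],
         factor = as.numeric(rows$factor))
  })
  structure(list(series = series, manifest = manifest, metadata = metadata,
                 ground_truth = ground_truth, stage_models = models,
                 design = design),
            class = "synth_study")
}

#' @export
print.synth_study <- function(x, ...) {
  cat("Synthetic study:", length(x$series), "subjects,",
      nrow(x$metadata), "regions,", x$design$n_timepoints, "time points\n")
  print(table(x$manifest$stage)[names(x$design$stages)])
  invisible(x)
}
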