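# Canned generator profiles: a base connectome-like VAR(1) model and the
# study designs used throughout the package's examples and tests.

#' Default base VAR(1) model
#'
#' A connectome-like stationary coupling structure: heterogeneous
#' self-coupling (0.25-0.45, shuffled across regions), a ring lattice
#' (neighbors within distance 2, weights ~ U(0.12, 0.18)) plus `n/2`
#' long-range symmetric couplings (~ U(0.10, 0.15)), with the off-diagonal
#' block rescaled so the spectral radius is exactly `radius`. Innovations
#' have unit standard deviation.
#'
#' @param n_regions Number of regions.
#' @param seed Seed for edge placement and weights (part of the model
#'   definition, not of the subject-level noise).
#' @param radius Target spectral radius (< 1).
#' @return A `var_model`.
#' @export
default_base_model <- function(n_regions = 90L, seed = 101L, radius = 0.90) {
  p <- as.integer(n_regions)
  if (p < 4L) stop("`n_regions` must be at least 4", call. = FALSE)
  if (radius <= 0 || radius >= 1) stop("`radius` must lie in (0, 1)", call. = FALSE)
  A <- with_local_seed(seed, {
    selfc <- seq(0.25, 0.45, length.out = p)[sample(p)]
    A <- diag(selfc)
    for (i in seq_len(p)) {
      for (d in 1:2) {
        j <- ((i - 1L + d) %% p) + 1L
        w <- runif(1, 0.12, 0.18)
        A[i, j] <- A[j, i] <- w
      }
    }
    for (e in seq_len(p %/% 2L)) {
      ij <- sample(p, 2L)
      w <- runif(1, 0.10, 0.15)
      A[ij[1], ij[2]] <- A[ij[2], ij[1]] <- w
    }
    attr(A, "selfc") <- selfc
    A
  })
  selfc <- attr(A, "selfc")
  attr(A, "selfc") <- NULL
  rad <- function(s) {
    B <- A * s
    diag(B) <- selfc
    max(Mod(eigen(B, only.values = TRUE)$values)) - radius
  }
  s <- stats::uniroot(rad, c(0.01, 1.5), tol = 1e-10)$root
  B <- A * s
  diag(B) <- selfc
  var_model(B, noise_sd = 1)
}

#' Synergy hubs of a VAR(1) model
#'
#' Regions with the highest degree in the sparsified analytic population
#' synergy network of the model. The default study profiles designate their
#' ground-truth affected nodes among these hubs: a node with no edges in the
#' top-fraction sparse graph is invisible to the sparsified graph metrics,
#' so attenuating it would be untestable by construction (and degeneration
#' in practice is hub-preferential).
#'
#' @param model A stationary `var_model`.
#' @param k Number of hubs to return.
#' @param fraction Sparsification fraction.
#' @param tau Lag for the synergy decomposition.
#' @return Integer vector of `k` region indices, strongest hub first.
#' @export
synergy_hubs <- function(model, k = 5L, fraction = 0.10, tau = 1L) {
  cm <- analytic_synergy_matrix(model, tau = tau)
  g <- sparsify_top_fraction(cm, fraction = fraction)
  deg <- rowSums(g$weights > 0)
  utils::head(order(-deg, seq_along(deg)), k)
}

#' Canned study profiles
#'
#' Bundles a base model and a study design:
#' \describe{
#'   \item{`clinical`}{90 regions, stage sizes CN 34 / EMCI 60 / LMCI 59 /
#'     AD 50, 140 time points per subject; six hub nodes progressively
#'     attenuated (three from EMCI at 0.7, two from LMCI at 0.6, one from
#'     AD at 0.5).}
#'   \item{`small`}{20 regions, 10 subjects per stage, 120 time points; two
#'     hubs attenuated at 0.5 from EMCI. Meant for fast tests and examples.}
#'   \item{`recovery`}{90 regions, two stages (CN 30 / AD 30), 300 time
#'     points; five hubs attenuated at 0.4 — the parameter-recovery study.}
#'   \item{`null-small`}{the `small` layout with no attenuation anywhere.}
#' }
#'
#' @param profile Profile name.
#' @param seed Study-level seed (drives subject noise, metadata coordinates
#'   and nothing else; the base model is fixed per profile).
#' @return List with elements `design` (a `study_design`) and `model`
#'   (a `var_model`).
#' @export
study_profile <- function(profile = c("small", "clinical", "recovery",
                                      "null-small"),
                          seed = 1L) {
  profile <- match.arg(profile)
  if (profile %in% c("small", "null-small")) {
    model <- default_base_model(20L)
    hubs <- synergy_hubs(model, k = 2L)
    affected <- if (profile == "small") {
      data.frame(stage = "EMCI", node = hubs, factor = 0.5)
    } else NULL
    design <- study_design(c(CN = 10L, EMCI = 10L, LMCI = 10L, AD = 10L),
                           affected = affected, n_timepoints = 120L,
                           seed = seed)
  } else if (profile == "clinical") {
    model <- default_base_model(90L)
    hubs <- synergy_hubs(model, k = 6L)
    affected <- data.frame(
      stage = c("EMCI", "EMCI", "EMCI", "LMCI", "LMCI", "AD"),
      node = hubs,
      factor = c(0.7, 0.7, 0.7, 0.6, 0.6, 0.5))
    design <- study_design(c(CN = 34L, EMCI = 60L, LMCI = 59L, AD = 50L),
                           affected = affected, n_timepoints = 140L,
                           seed = seed)
  } else {
    model <- default_base_model(90L)
    hubs <- synergy_hubs(model, k = 5L)
    affected <- data.frame(stage = "AD", node = hubs, factor = 0.4)
    design <- study_design(c(CN = 30L, AD = 30L), affected = affected,
                           n_timepoints = 300L, seed = seed)
  }
  list(design = design, model = model)
}
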