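# Single-subject network reconstruction against the control-group average.

#' Control-group average reference matrix
#'
#' Elementwise mean of the control subjects' connectivity matrices.
#'
#' @param control_matrices List of at least two `connectivity_matrix`
#'   objects with identical region sets and method.
#' @return An object of class `reference_matrix`: list with `cn_avg`,
#'   `n_controls`, `method`, `region_names`.
#' @export
compute_reference <- function(control_matrices) {
  if (length(control_matrices) < 2L) {
    stop("need at least 2 control matrices", call. = FALSE)
  }
  ok <- vapply(control_matrices, inherits, logical(1), "connectivity_matrix")
  if (!all(ok)) stop("all elements must be connectivity matrices", call. = FALSE)
  first <- control_matrices[[1]]
  for (cm in control_matrices[-1]) {
    if (!identical(cm$region_names, first$region_names)) {
      stop("control matrices have mismatched region labels", call. = FALSE)
    }
    if (!identical(cm$method, first$method)) {
      stop("control matrices mix methods (", first$method, " vs ",
           cm$method, ")", call. = FALSE)
    }
  }
  avg <- Reduce(`+`, lapply(control_matrices, `[[`, "weights")) /
    length(control_matrices)
  structure(list(cn_avg = avg, n_controls = length(control_matrices),
                 method = first$method, region_names = first$region_names),
            class = "reference_matrix")
}

#' Reconstruct a subject's network against the control reference
#'
#' Elementwise, with `R` the subject matrix and `C` the control average:
#' `F = (R - C) / ((R^2 + C^2) / 2)`, the bounded group-difference weight
#' `W = 1 - (exp(2F) - 1) / (exp(2F) + 1) = 1 - tanh(F)` in (0, 2), and the
#' reconstructed matrix `X = W * C`. Cells where both `R` and `C` are zero
#' take `F = 0` (continuity by symmetry), hence `X = 0`; reconstruction can
#' never create an edge absent from the reference, and reconstructing the
#' reference itself returns it unchanged.
#'
#' @param subject A `connectivity_matrix`.
#' @param ref A `reference_matrix` with the same regions and method.
#' @return A `connectivity_matrix` of reconstructed weights.
#' @examples
#' # R = 0 against C = 1 gives W = 1 - tanh(-2) = 1.96403
#' @export
reconstruct <- function(subject, ref) {
  stopifnot(inherits(subject, "connectivity_matrix"),
            inherits(ref, "reference_matrix"))
  if (!identical(subject$region_names, ref$region_names)) {
    stop("subject and reference have mismatched region labels", call. = FALSE)
  }
  if (!identical(subject$method, ref$method)) {
    stop("subject method ", subject$method, " does not match reference method ",
         ref$method, call. = FALSE)
  }
  R <- subject$weights
  C <- ref$cn_avg
  den <- (R^2 + C^2) / 2
  F <- ifelse(den > 0, (R - C) / den, 0)
  W <- 1 - tanh(F)
  X <- W * C
  diag(X) <- 0
  X <- (X + t(X)) / 2
  out <- connectivity_matrix(X, method = subject$method, tau = subject$tau)
  out$reconstructed <- TRUE
  out
}

#' Reconstruct a cohort of subject matrices
#'
#' Applies [reconstruct()] to every subject using the average of the control
#' subjects as reference. By default the reference includes all controls
#' (each control subject is then compared against a reference containing
#' itself); `loo = TRUE` excludes each control from its own reference as a
#' robustness option.
#'
#' @param matrices Named list of `connectivity_matrix` objects.
#' @param is_control Logical vector along `matrices` flagging the control
#'   subjects.
#' @param loo Leave each control subject out of its own reference?
#' @return Named list of reconstructed `connectivity_matrix` objects.
#' @export
reconstruct_cohort <- function(matrices, is_control, loo = FALSE) {
  stopifnot(length(is_control) == length(matrices))
  controls <- matrices[is_control]
  ref <- compute_reference(controls)
  out <- vector("list", length(matrices))
  names(out) <- names(matrices)
  for (k in seq_along(matrices)) {
    r <- ref
    if (loo && is_control[k]) {
      others <- controls[setdiff(names(controls), names(matrices)[k])]
      r <- compute_reference(others)
    }
    out[[k]] <- reconstruct(matrices[[k]], r)
  }
  out
}
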