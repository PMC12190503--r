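# Stage-pair statistics: t tests with FDR, Cohen's d, coefficient of
# variation, change scores and the node-selection rule.

#' Two-sample t test
#'
#' Student's pooled-variance two-sample t by default (two-sided p from the t
#' distribution with `n1 + n2 - 2` degrees of freedom); `var_equal = FALSE`
#' gives the Welch variant with Satterthwaite degrees of freedom.
#'
#' @param a,b Numeric samples with at least two observations each.
#' @param var_equal Pooled (TRUE, default) or Welch (FALSE) variance.
#' @return List with `t`, `p` and `df`.
#' @examples
#' two_sample_t(c(1, 2, 3), c(2, 3, 4))  # t = -1.2247
#' @export
two_sample_t <- function(a, b, var_equal = TRUE) {
  n1 <- length(a); n2 <- length(b)
  if (n1 < 2L || n2 < 2L) {
    stop("each sample needs at least 2 observations", call. = FALSE)
  }
  v1 <- var(a); v2 <- var(b)
  if (v1 == 0 && v2 == 0) {
    stop("zero variance in both samples", call. = FALSE)
  }
  delta <- mean(a) - mean(b)
  if (var_equal) {
    sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- n1 + n2 - 2
  } else {
    se <- sqrt(v1 / n1 + v2 / n2)
    df <- (v1 / n1 + v2 / n2)^2 /
      ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  }
  t <- delta / se
  list(t = t, p = 2 * pt(-abs(t), df), df = df)
}

#' Cohen's d from a t statistic
#'
#' `d = t * sqrt(1/n1 + 1/n2)` — the effect size implied by a
#' pooled-variance two-sample t statistic and the two group sizes.
#'
#' @param t t statistic.
#' @param n1,n2 Group sizes (at least 2).
#' @return Cohen's d (unrounded; summaries conventionally print 2 decimals).
#' @examples
#' round(cohens_d(2.2802, 34, 60), 2)  # 0.49
#' @export
cohens_d <- function(t, n1, n2) {
  if (any(c(n1, n2) < 2L)) stop("group sizes must be at least 2", call. = FALSE)
  t * sqrt(1 / n1 + 1 / n2)
}

#' Coefficient of variation
#'
#' Sample standard deviation (n - 1 denominator) divided by the mean; scale
#' invariant for positive rescalings.
#'
#' @param x Numeric sample, length at least 2, nonzero mean.
#' @return SD / mean.
#' @export
coefficient_of_variation <- function(x) {
  if (length(x) < 2L) stop("need at least 2 observations", call. = FALSE)
  m <- mean(x)
  if (m == 0) stop("zero mean: coefficient of variation undefined", call. = FALSE)
  sd(x) / m
}

#' Benjamini-Hochberg adjusted p values
#'
#' Step-up false-discovery-rate adjustment (monotone, capped at 1).
#'
#' @param pvals Numeric vector of p values in \[0, 1\].
#' @return Adjusted values, same order as the input.
#' @export
fdr_adjust <- function(pvals) {
  if (any(!is.finite(pvals)) || any(pvals < 0) || any(pvals > 1)) {
    stop("p values must lie in [0, 1]", call. = FALSE)
  }
  p.adjust(pvals, method = "BH")
}

#' Per-node change score
#'
#' Each node's stage-to-stage mean decline relative to the network-average
#' decline: `CS(k) = (a_k - b_k) / mean(a - b)` with `a` the earlier stage's
#' per-node means and `b` the later stage's. Nodes declining more than
#' average score above 1 and the scores sum exactly to the number of nodes.
#' `as_printed = TRUE` flips the denominator's sign (the literal published
#' form, whose scores sum to minus the number of nodes); see the methods
#' vignette for why the sign-corrected form is the default.
#'
#' @param means_a,means_b Per-node means of the earlier (`a`) and later
#'   (`b`) stage.
#' @param as_printed Use the literal (sign-inconsistent) denominator.
#' @return Numeric vector of change scores.
#' @examples
#' change_score(c(3, 1, 1), c(1, 1, 1))  # c(3, 0, 0)
#' @export
change_score <- function(means_a, means_b, as_printed = FALSE) {
  if (length(means_a) != length(means_b) || length(means_a) < 1L) {
    stop("`means_a` and `means_b` must be equal-length, non-empty", call. = FALSE)
  }
  decline <- means_a - means_b
  md <- mean(decline)
  if (md == 0) stop("zero mean decline: change score undefined", call. = FALSE)
  if (as_printed) decline / (-md) else decline / md
}

#' Compare two disease stages node by node
#'
#' For one node metric: a two-sample t test per node across subjects,
#' Benjamini-Hochberg adjustment across all nodes, the change score from the
#' stage means, and the selection flag `q < alpha & CS > cs_threshold`.
#' Nodes whose metric is constant and equal in both groups (e.g. isolated in
#' every subject's sparse graph) take `t = 0, p = 1` rather than aborting
#' the comparison.
#'
#' @param metrics Long data frame with columns `subject_id`, `stage`,
#'   `region` and the metric columns (as produced by stacking
#'   [node_metrics()] tables).
#' @param metric Name of the metric column to compare.
#' @param stage_a,stage_b Stage labels; `stage_a` is the earlier stage.
#' @param alpha FDR threshold.
#' @param cs_threshold Change-score threshold.
#' @param var_equal Pooled (default) or Welch t.
#' @param cs_as_printed Passed to [change_score()].
#' @return A data frame of class `stage_comparison` with one row per node
#'   (columns `region`, `t`, `p`, `q`, `cs`, `selected`), ranked by change
#'   score, descending. The stage pair, metric and thresholds are attached
#'   as attributes.
#' @export
compare_stages <- function(metrics, metric, stage_a, stage_b,
                           alpha = 0.05, cs_threshold = 6,
                           var_equal = TRUE, cs_as_printed = FALSE) {
  req <- c("subject_id", "stage", "region", metric)
  if (!all(req %in% names(metrics))) {
    stop("`metrics` needs columns ", paste(req, collapse = ", "), call. = FALSE)
  }
  for (s in c(stage_a, stage_b)) {
    if (sum(metrics$stage == s) == 0L) stop("stage ", s, " absent", call. = FALSE)
  }
  regions <- unique(metrics$region)
  a_df <- metrics[metrics$stage == stage_a, ]
  b_df <- metrics[metrics$stage == stage_b, ]
  if (length(unique(a_df$subject_id)) < 2L ||
      length(unique(b_df$subject_id)) < 2L) {
    stop("each stage needs at least 2 subjects", call. = FALSE)
  }
  res <- t(vapply(regions, function(r) {
    a <- a_df[[metric]][a_df$region == r]
    b <- b_df[[metric]][b_df$region == r]
    if (var(a) == 0 && var(b) == 0) {
      if (mean(a) == mean(b)) c(mean(a), mean(b), 0, 1)
      else c(mean(a), mean(b), sign(mean(a) - mean(b)) * Inf, 0)
    } else {
      tt <- two_sample_t(a, b, var_equal = var_equal)
      c(mean(a), mean(b), tt$t, tt$p)
    }
  }, numeric(4)))
  q <- fdr_adjust(res[, 4])
  cs <- change_score(res[, 1], res[, 2], as_printed = cs_as_printed)
  out <- data.frame(region = regions, t = res[, 3], p = res[, 4], q = q,
                    cs = cs, selected = q < alpha & cs > cs_threshold)
  out <- out[order(-out$cs), ]
  rownames(out) <- NULL
  structure(out, class = c("stage_comparison", "data.frame"),
            metric = metric, stage_a = stage_a, stage_b = stage_b,
            alpha = alpha, cs_threshold = cs_threshold)
}

# Per-subject global weighted clustering for a list of connectivity matrices.
global_clustering_by_subject <- function(matrices, fraction) {
  vapply(matrices, function(cm) {
    g <- sparsify_top_fraction(cm, fraction = fraction)
    weighted_clustering(g)$global
  }, numeric(1))
}

#' Reconstruction validation table
#'
#' Reproduces the before/after-reconstruction comparison protocol on a study
#' bundle: per method (mi, syn) and condition (raw subject matrices vs
#' matrices reconstructed against the first-stage reference), subjects'
#' global weighted clustering coefficients (top-fraction sparsified) are
#' compared between adjacent stages with a two-sample t test and Cohen's d.
#'
#' @param bundle A `synth_study`.
#' @param tau Lag for the synergy decomposition.
#' @param fraction Sparsification fraction.
#' @param methods Connectivity methods to include.
#' @param var_equal Pooled (default) or Welch t.
#' @return Data frame with columns `method`, `condition`, `stage_a`,
#'   `stage_b`, `t`, `abs_t`, `p`, `d` — one row per method x condition x
#'   adjacent stage pair.
#' @export
reconstruction_validation <- function(bundle, tau = 1L, fraction = 0.10,
                                      methods = c("mi", "syn"),
                                      var_equal = TRUE) {
  stopifnot(inherits(bundle, "synth_study"))
  stages <- unique(bundle$manifest$stage)
  if (length(stages) < 2L) stop("need at least 2 stages", call. = FALSE)
  is_control <- bundle$manifest$stage == stages[1]
  rows <- list()
  for (method in methods) {
    mats <- lapply(bundle$series, build_matrix, method = method, tau = tau)
    recon <- reconstruct_cohort(mats, is_control)
    for (condition in c("before", "after")) {
      cc <- global_clustering_by_subject(
        if (condition == "before") mats else recon, fraction)
      for (si in seq_len(length(stages) - 1L)) {
        a <- cc[bundle$manifest$stage == stages[si]]
        b <- cc[bundle$manifest$stage == stages[si + 1L]]
        tt <- two_sample_t(a, b, var_equal = var_equal)
        rows[[length(rows) + 1L]] <- data.frame(
          method = method, condition = condition,
          stage_a = stages[si], stage_b = stages[si + 1L],
          t = tt$t, abs_t = abs(tt$t), p = tt$p,
          d = cohens_d(tt$t, length(a), length(b)))
      }
    }
  }
  do.call(rbind, rows)
}
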