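# Plain-text serialization: study bundles and connectivity matrices.
# Numeric cells are written with 17 significant digits so every round trip
# is exact to the last bit.

fmt_num <- function(x) sprintf("%.17g", x)

write_tsv <- function(df, path) {
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], fmt_num)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

read_tsv <- function(path) {
  read.delim(path, sep = "\t", check.names = FALSE,
             stringsAsFactors = FALSE)
}

#' Write a study bundle to a directory
#'
#' Layout: `manifest.tsv` (subject_id, stage), `metadata.tsv` (region,
#' network, x_mm, y_mm, z_mm), `ground_truth.json` (affected nodes per stage
#' transition) and `series/<subject_id>.tsv` (header row of region names,
#' one row per time point).
#'
#' @param bundle A `synth_study`.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_study <- function(bundle, dir) {
  stopifnot(inherits(bundle, "synth_study"))
  dir.create(file.path(dir, "series"), recursive = TRUE, showWarnings = FALSE)
  write_tsv(bundle$manifest, file.path(dir, "manifest.tsv"))
  write_tsv(bundle$metadata, file.path(dir, "metadata.tsv"))
  jsonlite::write_json(
    list(stages = as.list(bundle$design$stages),
         n_timepoints = bundle$design$n_timepoints,
         seed = bundle$design$seed,
         transitions = bundle$ground_truth),
    file.path(dir, "ground_truth.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE)
  for (id in names(bundle$series)) {
    write_tsv(as.data.frame(bundle$series[[id]]),
              file.path(dir, "series", paste0(id, ".tsv")))
  }
  invisible(dir)
}

#' Read a study bundle from a directory
#'
#' Validates the manifest against the series files and the metadata against
#' the series headers; malformed input is rejected with the offending file
#' (and, for NaN cells, line) named.
#'
#' @param dir Directory written by [write_study()] (or following the same
#'   layout).
#' @return A `synth_study`-like list with `series`, `manifest`, `metadata`
#'   and (when present) `ground_truth`; `stage_models` is `NULL` for a
#'   bundle read from disk.
#' @export
read_study <- function(dir) {
  manifest_path <- file.path(dir, "manifest.tsv")
  metadata_path <- file.path(dir, "metadata.tsv")
  for (f in c(manifest_path, metadata_path)) {
    if (!file.exists(f)) stop("missing file: ", f, call. = FALSE)
  }
  manifest <- read_tsv(manifest_path)
  if (!all(c("subject_id", "stage") %in% names(manifest))) {
    stop(manifest_path, ": needs columns subject_id, stage", call. = FALSE)
  }
  if (anyDuplicated(manifest$subject_id)) {
    stop(manifest_path, ": duplicated subject_id ",
         manifest$subject_id[duplicated(manifest$subject_id)][1], call. = FALSE)
  }
  metadata <- read_tsv(metadata_path)
  req <- c("region", "network", "x_mm", "y_mm", "z_mm")
  if (!all(req %in% names(metadata))) {
    stop(metadata_path, ": needs columns ", paste(req, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(metadata$region)) {
    stop(metadata_path, ": duplicated region name ",
         metadata$region[duplicated(metadata$region)][1], call. = FALSE)
  }
  series <- list()
  for (id in manifest$subject_id) {
    f <- file.path(dir, "series", paste0(id, ".tsv"))
    if (!file.exists(f)) {
      stop("manifest references subject ", id, " but ", f, " is missing",
           call. = FALSE)
    }
    x <- as.matrix(read_tsv(f))
    if (!setequal(colnames(x), metadata$region)) {
      missing <- setdiff(metadata$region, colnames(x))
      extra <- setdiff(colnames(x), metadata$region)
      stop(f, ": region columns disagree with metadata",
           if (length(missing)) paste0(" (missing: ",
                                       paste(missing, collapse = ", "), ")"),
           if (length(extra)) paste0(" (unknown: ",
                                     paste(extra, collapse = ", "), ")"),
           call. = FALSE)
    }
    x <- x[, metadata$region, drop = FALSE]
    if (!is.numeric(x) || any(!is.finite(x))) {
      bad <- which(!is.finite(x), arr.ind = TRUE)
      stop(f, ": non-finite value at line ", bad[1, 1] + 1L,
           " (region ", colnames(x)[bad[1, 2]], ")", call. = FALSE)
    }
    series[[id]] <- x
  }
  gt_path <- file.path(dir, "ground_truth.json")
  ground_truth <- if (file.exists(gt_path)) {
    gt <- jsonlite::read_json(gt_path, simplifyVector = FALSE)$transitions
    lapply(gt, function(tr) {
      list(transition = tr$transition,
           nodes = as.integer(unlist(tr$nodes)),
           regions = as.character(unlist(tr$regions)),
           factor = as.numeric(unlist(tr$factor)))
    })
  } else NULL
  structure(list(series = series, manifest = manifest, metadata = metadata,
                 ground_truth = ground_truth, stage_models = NULL,
                 design = NULL),
            class = "synth_study")
}

#' Write / read a connectivity matrix
#'
#' Square TSV with a region-name header row and a leading region column.
#' `read_matrix()` validates squareness and symmetry (tolerance 1e-12) and,
#' when `metadata` is supplied, that the header regions match it.
#'
#' @param cm A `connectivity_matrix`.
#' @param path File path.
#' @return `write_matrix()`: `path` invisibly; `read_matrix()`: a
#'   `connectivity_matrix`.
#' @export
write_matrix <- function(cm, path) {
  stopifnot(inherits(cm, "connectivity_matrix"))
  df <- data.frame(region = cm$region_names,
                   as.data.frame(cm$weights, check.names = FALSE),
                   check.names = FALSE)
  write_tsv(df, path)
  invisible(path)
}

#' @rdname write_matrix
#' @param method,tau Method and lag to record on the matrix read back.
#' @param metadata Optional node metadata to validate region names against.
#' @export
read_matrix <- function(path, method = c("mi", "syn"), tau = 1L,
                        metadata = NULL) {
  method <- match.arg(method)
  df <- read_tsv(path)
  if (names(df)[1] != "region") {
    stop(path, ": first column must be `region`", call. = FALSE)
  }
  W <- as.matrix(df[, -1, drop = FALSE])
  rownames(W) <- df$region
  if (nrow(W) != ncol(W) || !identical(rownames(W), colnames(W))) {
    stop(path, ": matrix is not square with matching region labels",
         call. = FALSE)
  }
  if (max(abs(W - t(W))) > 1e-12) {
    stop(path, ": matrix is asymmetric beyond 1e-12", call. = FALSE)
  }
  if (!is.null(metadata)) {
    unknown <- setdiff(rownames(W), metadata$region)
    if (length(unknown) > 0) {
      stop(path, ": unknown region(s) vs metadata: ",
           paste(unknown, collapse = ", "), call. = FALSE)
    }
  }
  connectivity_matrix(W, method = method, tau = tau)
}
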