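# Configured, logged pipeline: simulate -> connectivity -> reconstruct ->
# metrics -> compare, with plain-text config files and a run manifest.

PIPELINE_DEFAULTS <- list(
  study_dir = "",          # empty: simulate `profile` instead of reading
  out_dir = "phidnet-run",
  profile = "small",
  method = "both",         # mi, syn or both
  tau = 1L,
  fraction = 0.10,
  alpha = 0.05,
  cs_threshold = 6,
  loo = FALSE,
  seed = 1L
)

#' Pipeline configuration
#'
#' @param ... Overrides of the defaults: `study_dir` (read an existing study
#'   instead of simulating), `out_dir`, `profile` (see [study_profile()]),
#'   `method` (`"mi"`, `"syn"` or `"both"`), `tau`, `fraction`, `alpha`,
#'   `cs_threshold`, `loo`, `seed`.
#' @return An object of class `pipeline_config` (a named list).
#' @export
pipeline_config <- function(...) {
  over <- list(...)
  unknown <- setdiff(names(over), names(PIPELINE_DEFAULTS))
  if (length(unknown) > 0) {
    stop("unknown config field(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  cfg <- modifyList(PIPELINE_DEFAULTS, over)
  if (!cfg$method %in% c("mi", "syn", "both")) {
    stop("`method` must be mi, syn or both", call. = FALSE)
  }
  if (cfg$fraction <= 0 || cfg$fraction > 1) {
    stop("`fraction` must lie in (0, 1]", call. = FALSE)
  }
  if (cfg$alpha <= 0 || cfg$alpha >= 1) stop("`alpha` must lie in (0, 1)", call. = FALSE)
  if (cfg$tau < 1) stop("`tau` must be a positive integer", call. = FALSE)
  cfg$tau <- as.integer(cfg$tau)
  cfg$seed <- as.integer(cfg$seed)
  cfg$loo <- isTRUE(cfg$loo) || identical(cfg$loo, "TRUE")
  structure(cfg, class = "pipeline_config")
}

#' Write / read a pipeline configuration file
#'
#' Plain `key: value` text; the round trip is lossless.
#'
#' @param cfg A `pipeline_config`.
#' @param path File path.
#' @export
write_pipeline_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "pipeline_config"))
  writeLines(sprintf("%s: %s", names(cfg),
                     vapply(cfg, function(v) {
                       if (is.numeric(v)) fmt_num(v) else as.character(v)
                     }, character(1))),
             path)
  invisible(path)
}

#' @rdname write_pipeline_config
#' @export
read_pipeline_config <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  m <- regmatches(lines, regexec("^([^:]+):[[:space:]]*(.*)$", lines))
  bad <- vapply(m, length, integer(1)) != 3L
  if (any(bad)) {
    stop(path, ": malformed line ", which(bad)[1], ": ", lines[bad][1],
         call. = FALSE)
  }
  keys <- vapply(m, `[`, character(1), 2)
  vals <- vapply(m, `[`, character(1), 3)
  cfg <- as.list(PIPELINE_DEFAULTS)
  for (k in seq_along(keys)) {
    key <- trimws(keys[k])
    if (!key %in% names(cfg)) {
      stop(path, ": unknown config key `", key, "`", call. = FALSE)
    }
    proto <- PIPELINE_DEFAULTS[[key]]
    cfg[[key]] <- if (is.numeric(proto)) as.numeric(vals[k])
      else if (is.logical(proto)) as.logical(vals[k])
      else vals[k]
  }
  do.call(pipeline_config, cfg)
}

#' Validate a study directory
#'
#' Checks manifest/series/metadata consistency, series length against the
#' lag, and NaN or constant region columns. Returns every violation rather
#' than stopping at the first.
#'
#' @param dir Study directory.
#' @param tau Lag the series must support.
#' @return Data frame with columns `file` and `issue`; zero rows when clean.
#' @export
validate_inputs <- function(dir, tau = 1L) {
  issues <- data.frame(file = character(), issue = character())
  note <- function(file, issue) {
    issues <<- rbind(issues, data.frame(file = file, issue = issue))
  }
  manifest_path <- file.path(dir, "manifest.tsv")
  metadata_path <- file.path(dir, "metadata.tsv")
  if (!file.exists(manifest_path)) {
    note(manifest_path, "missing manifest")
    return(issues)
  }
  if (!file.exists(metadata_path)) {
    note(metadata_path, "missing metadata")
    return(issues)
  }
  manifest <- read_tsv(manifest_path)
  metadata <- read_tsv(metadata_path)
  if (!all(c("subject_id", "stage") %in% names(manifest))) {
    note(manifest_path, "needs columns subject_id, stage")
    return(issues)
  }
  req <- c("region", "network", "x_mm", "y_mm", "z_mm")
  miss <- setdiff(req, names(metadata))
  if (length(miss) > 0) {
    note(metadata_path, paste("missing column(s):", paste(miss, collapse = ", ")))
  }
  if (anyDuplicated(metadata$region)) {
    note(metadata_path,
         paste("duplicated region name:",
               metadata$region[duplicated(metadata$region)][1]))
  }
  if (all(c("x_mm", "y_mm", "z_mm") %in% names(metadata)) &&
      any(!is.finite(as.matrix(metadata[, c("x_mm", "y_mm", "z_mm")])))) {
    note(metadata_path, "non-finite coordinates")
  }
  for (k in seq_len(nrow(manifest))) {
    id <- manifest$subject_id[k]
    f <- file.path(dir, "series", paste0(id, ".tsv"))
    if (!file.exists(f)) {
      note(f, paste("subject", id, "listed in manifest but file missing"))
      next
    }
    x <- suppressWarnings(as.matrix(read_tsv(f)))
    if (!setequal(colnames(x), metadata$region)) {
      note(f, "region columns disagree with metadata")
      next
    }
    if (any(!is.finite(x))) {
      bad <- which(!is.finite(x), arr.ind = TRUE)[1, ]
      note(f, paste0("non-finite value at line ", bad[1] + 1L, ", region ",
                     colnames(x)[bad[2]]))
      next
    }
    if (nrow(x) < tau + 20L) {
      note(f, paste0("only ", nrow(x), " time points; need at least tau + 20"))
    }
    sds <- apply(x, 2, sd)
    if (any(sds == 0)) {
      note(f, paste("constant region(s):",
                    paste(colnames(x)[sds == 0], collapse = ", ")))
    }
  }
  issues
}

# Polynomial rolling hash (mod 2^32) of the canonical config text, for the
# run manifest.
config_hash <- function(cfg) {
  txt <- paste(sprintf("%s=%s", names(cfg), vapply(cfg, as.character,
                                                   character(1))),
               collapse = ";")
  h <- 5381
  for (b in utf8ToInt(txt)) h <- (h * 33 + b) %% 4294967296
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

#' Run the full analysis pipeline
#'
#' Orchestrates simulate (or read) -> connectivity -> reconstruct ->
#' sparsify/metrics -> stage comparisons -> reconstruction-validation table,
#' writing every stage's artifacts under `out_dir` together with a run
#' manifest (config, config hash, per-stage row counts, floored-synergy
#' counts). Rerunning with an identical config reproduces identical numbers.
#'
#' @param config A `pipeline_config`.
#' @param quiet Suppress per-stage progress messages.
#' @return Invisibly, a list with the study bundle, matrices, metric table,
#'   comparisons, validation table and manifest.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  say <- function(...) if (!quiet) message("[phidnet] ", ...)
  t0 <- Sys.time()
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)

  if (nzchar(config$study_dir)) {
    say("reading study from ", config$study_dir)
    issues <- validate_inputs(config$study_dir, tau = config$tau)
    if (nrow(issues) > 0) {
      stop("stage `input validation` failed:\n",
           paste(" -", issues$file, ":", issues$issue, collapse = "\n"),
           call. = FALSE)
    }
    bundle <- read_study(config$study_dir)
  } else {
    say("simulating profile `", config$profile, "` (seed ", config$seed, ")")
    prof <- study_profile(config$profile, seed = config$seed)
    bundle <- generate_study(prof$design, prof$model)
    write_study(bundle, file.path(out, "study"))
  }
  stages <- unique(bundle$manifest$stage)
  methods <- if (config$method == "both") c("mi", "syn") else config$method
  coords <- as.matrix(bundle$metadata[, c("x_mm", "y_mm", "z_mm")])

  matrices <- list()
  reconstructed <- list()
  metric_tabs <- list()
  comparisons <- list()
  skipped <- list()
  n_floored_total <- 0L
  for (method in methods) {
    say("connectivity (", method, ") for ", length(bundle$series), " subjects")
    mdir <- file.path(out, "connectivity", method)
    dir.create(mdir, recursive = TRUE, showWarnings = FALSE)
    mats <- lapply(bundle$series, build_matrix, method = method,
                   tau = config$tau)
    for (id in names(mats)) {
      write_matrix(mats[[id]], file.path(mdir, paste0(id, ".tsv")))
    }
    n_floored_total <- n_floored_total +
      sum(vapply(mats, `[[`, integer(1), "n_floored"))

    say("reconstruction against ", stages[1], " reference")
    rdir <- file.path(out, "reconstructed", method)
    dir.create(rdir, recursive = TRUE, showWarnings = FALSE)
    recon <- reconstruct_cohort(mats, bundle$manifest$stage == stages[1],
                                loo = config$loo)
    for (id in names(recon)) {
      write_matrix(recon[[id]], file.path(rdir, paste0(id, ".tsv")))
    }

    say("graph metrics (fraction ", config$fraction, ")")
    summaries <- list()
    tabs <- lapply(names(recon), function(id) {
      g <- sparsify_top_fraction(recon[[id]], fraction = config$fraction,
                                 coords = coords)
      L <- char_path_length(g)
      net <- suppressWarnings(network_summary(g, bundle$metadata))
      summaries[[id]] <<- list(
        subject_id = id,
        char_path_length = as.numeric(L),
        n_unreachable_pairs = attr(L, "n_unreachable"),
        global_clustering = weighted_clustering(g)$global,
        networks = net)
      cbind(subject_id = id,
            stage = bundle$manifest$stage[bundle$manifest$subject_id == id],
            node_metrics(g))
    })
    tab <- do.call(rbind, tabs)
    metric_tabs[[method]] <- tab
    dir.create(file.path(out, "metrics"), showWarnings = FALSE)
    write_tsv(tab, file.path(out, "metrics",
                             paste0(method, "_node_metrics.tsv")))
    jsonlite::write_json(summaries,
                         file.path(out, "metrics",
                                   paste0(method, "_graph_summary.json")),
                         auto_unbox = TRUE, digits = NA, dataframe = "rows",
                         pretty = TRUE)

    dir.create(file.path(out, "comparisons"), showWarnings = FALSE)
    for (metric in c("comm_capacity", "degree_centrality")) {
      for (si in seq_len(length(stages) - 1L)) {
        key <- paste(method, metric, stages[si], stages[si + 1L], sep = "_")
        # Proportional thresholding fixes the total degree of every
        # subject's graph, so the network-average change of degree
        # centrality can be exactly zero; such degenerate change scores
        # make the comparison undefined and it is skipped with a note.
        cmp <- tryCatch(
          compare_stages(tab, metric, stages[si], stages[si + 1L],
                         alpha = config$alpha,
                         cs_threshold = config$cs_threshold),
          error = function(e) {
            say("comparison ", key, " skipped: ", conditionMessage(e))
            skipped[[key]] <<- conditionMessage(e)
            NULL
          })
        if (is.null(cmp)) next
        comparisons[[key]] <- cmp
        write_tsv(as.data.frame(cmp),
                  file.path(out, "comparisons", paste0(key, ".tsv")))
      }
    }
    matrices[[method]] <- mats
    reconstructed[[method]] <- recon
  }

  say("reconstruction validation table")
  validation <- reconstruction_validation(bundle, tau = config$tau,
                                          fraction = config$fraction,
                                          methods = methods)
  write_tsv(validation, file.path(out, "validation.tsv"))

  manifest <- list(
    config = unclass(config),
    config_hash = config_hash(config),
    n_subjects = length(bundle$series),
    n_regions = nrow(bundle$metadata),
    stages = as.list(table(bundle$manifest$stage)[stages]),
    n_floored_synergy = n_floored_total,
    n_comparisons = length(comparisons),
    skipped_comparisons = skipped,
    elapsed_s = as.numeric(difftime(Sys.time(), t0, units = "secs")))
  jsonlite::write_json(manifest, file.path(out, "run_manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  say("done in ", sprintf("%.1f", manifest$elapsed_s), " s")
  invisible(list(bundle = bundle, matrices = matrices,
                 reconstructed = reconstructed, metrics = metric_tabs,
                 comparisons = comparisons, validation = validation,
                 manifest = manifest))
}
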