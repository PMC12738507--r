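#' Read an embeddings JSON file
#'
#' Embedding files map image IDs to fixed-length numeric vectors
#' (`{"ISIC_0000001": [0.12, ...], ...}`). IDs must be unique and all vectors
#' the same length.
#'
#' @param path Path to the JSON file.
#' @return Numeric matrix, one row per ID (rownames = IDs).
#' @export
read_embeddings <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyVector = TRUE, simplifyMatrix = FALSE)
  if (!is.list(obj) || is.null(names(obj))) stop("embeddings JSON must map ID -> vector")
  if (anyDuplicated(names(obj)))
    stop("duplicate IDs in embeddings file: ",
         paste(unique(names(obj)[duplicated(names(obj))]), collapse = ", "))
  lens <- lengths(obj)
  if (length(unique(lens)) > 1) {
    off <- names(obj)[lens != stats::median(lens)]
    stop("ragged embedding vectors for IDs: ", paste(off, collapse = ", "))
  }
  x <- do.call(rbind, lapply(obj, as.numeric))
  rownames(x) <- names(obj)
  x
}

#' Write an embeddings JSON file
#'
#' @param x Numeric matrix with ID rownames (e.g. `cohort$x`).
#' @param path Output path.
#' @export
write_embeddings <- function(x, path) {
  stopifnot(!is.null(rownames(x)))
  obj <- stats::setNames(lapply(seq_len(nrow(x)), function(i) unname(x[i, ])),
                         rownames(x))
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = FALSE)
  invisible(path)
}

#' Read ground-truth labels and demographic metadata CSVs
#'
#' The ground-truth CSV is either the one-hot dialect (ID column followed by
#' one 0/1 column per class, exactly one 1 per row) or a long dialect
#' (`id,label`); the dialect is auto-detected from the header. Rows labelled
#' `UNK` are dropped with a message. The metadata CSV (optional) carries
#' `id`/`image`, `age_approx`, `sex`, `anatom_site` (or
#' `anatom_site_general`), and optionally `cohort`; IDs without metadata get
#' `"unknown"` levels, and a missing metadata file yields all-unknown
#' demographics so cohorts without patient metadata still audit.
#'
#' @param gt_path Ground-truth CSV path.
#' @param meta_path Optional metadata CSV path.
#' @return data.frame with columns id, label, sex, age_approx, age_band,
#'   anatom_site, cohort.
#' @export
read_labels_metadata <- function(gt_path, meta_path = NULL) {
  gt <- utils::read.csv(gt_path, check.names = FALSE, stringsAsFactors = FALSE)
  if (anyDuplicated(gt[[1]]))
    stop("duplicate IDs in ground truth: ",
         paste(unique(gt[[1]][duplicated(gt[[1]])]), collapse = ", "))
  if (ncol(gt) == 2 && !all(unlist(gt[[2]]) %in% c(0, 1))) {
    out <- data.frame(id = as.character(gt[[1]]), label = as.character(gt[[2]]),
                      stringsAsFactors = FALSE)
  } else {
    onehot <- as.matrix(gt[, -1, drop = FALSE])
    if (!all(onehot %in% c(0, 1))) stop("one-hot ground truth must contain only 0/1")
    rs <- rowSums(onehot)
    if (any(rs != 1))
      stop("rows without exactly one 1: ",
           paste(gt[[1]][rs != 1], collapse = ", "))
    out <- data.frame(id = as.character(gt[[1]]),
                      label = colnames(onehot)[max.col(onehot)],
                      stringsAsFactors = FALSE)
  }
  n_unk <- sum(out$label == "UNK")
  if (n_unk > 0) {
    message(sprintf("dropping %d UNK-labelled records", n_unk))
    out <- out[out$label != "UNK", , drop = FALSE]
  }
  meta <- NULL
  if (!is.null(meta_path) && file.exists(meta_path)) {
    meta <- utils::read.csv(meta_path, stringsAsFactors = FALSE)
    idcol <- intersect(c("id", "image"), names(meta))[1]
    if (is.na(idcol)) stop("metadata CSV needs an 'id' or 'image' column")
    names(meta)[names(meta) == idcol] <- "id"
    if ("anatom_site_general" %in% names(meta))
      names(meta)[names(meta) == "anatom_site_general"] <- "anatom_site"
    if (anyDuplicated(meta$id))
      stop("duplicate IDs in metadata: ",
           paste(unique(meta$id[duplicated(meta$id)]), collapse = ", "))
    ord <- out$id
    out <- merge(out, meta, by = "id", all.x = TRUE, sort = FALSE)
    out <- out[match(ord, out$id), , drop = FALSE]
    rownames(out) <- NULL
  }
  for (col in c("sex", "anatom_site", "cohort")) {
    if (!col %in% names(out)) out[[col]] <- "unknown"
    out[[col]][is.na(out[[col]]) | out[[col]] == ""] <- "unknown"
  }
  if (!"age_approx" %in% names(out)) out$age_approx <- NA_real_
  out$age_band <- age_to_band(out$age_approx)
  out[c("id", "label", "sex", "age_approx", "age_band", "anatom_site", "cohort")]
}

#' Write a synthetic cohort in the pipeline's on-disk formats
#'
#' Emits `embeddings.json` (ID -> vector), `groundtruth.csv` (ID + one-hot
#' class columns) and `metadata.csv` (id, age_approx, sex, anatom_site,
#' cohort) under `dir` — the same formats [read_embeddings()] and
#' [read_labels_metadata()] consume.
#'
#' @param cohort A `cohort`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_embeddings(cohort$x, file.path(dir, "embeddings.json"))
  onehot <- stats::model.matrix(~ 0 + cohort$labels)
  colnames(onehot) <- levels(cohort$labels)
  gt <- data.frame(image = rownames(cohort$x), onehot, check.names = FALSE)
  utils::write.csv(gt, file.path(dir, "groundtruth.csv"), row.names = FALSE)
  meta <- cohort$demographics[c("id", "age_approx", "sex", "anatom_site", "cohort")]
  names(meta)[1] <- "image"
  utils::write.csv(meta, file.path(dir, "metadata.csv"), row.names = FALSE)
  invisible(dir)
}

#' Read a cohort back from its on-disk files
#'
#' @param dir Directory with `embeddings.json`, `groundtruth.csv`,
#'   `metadata.csv` (metadata optional).
#' @return A `cohort`.
#' @export
read_cohort <- function(dir) {
  x <- read_embeddings(file.path(dir, "embeddings.json"))
  meta_path <- file.path(dir, "metadata.csv")
  lab <- read_labels_metadata(file.path(dir, "groundtruth.csv"),
                              if (file.exists(meta_path)) meta_path else NULL)
  keep <- intersect(rownames(x), lab$id)
  x <- x[keep, , drop = FALSE]
  lab <- lab[match(keep, lab$id), , drop = FALSE]
  structure(list(x = x,
                 labels = factor(lab$label, levels = sort(unique(lab$label))),
                 demographics = lab[c("id", "sex", "age_approx", "age_band",
                                      "anatom_site", "cohort")],
                 spec = NULL),
            class = "cohort")
}

#' Write prediction sets as JSON lines
#'
#' One JSON object per line: `{"id":..., "entries": [[label, confidence],
#' ...], "truth":...}`, entries ordered by descending confidence.
#'
#' @param sets A `prediction_sets`.
#' @param path Output path (conventionally `sets.jsonl`).
#' @export
write_sets_jsonl <- function(sets, path) {
  lines <- vapply(sets, function(s) {
    entries <- lapply(seq_along(s$labels), function(i)
      list(s$labels[i], s$confidence[i]))
    jsonlite::toJSON(list(id = s$id, entries = entries, truth = s$truth),
                     auto_unbox = TRUE, digits = NA, null = "null", na = "null")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read prediction sets from JSON lines
#'
#' @param path Path written by [write_sets_jsonl()].
#' @return A `prediction_sets`.
#' @export
read_sets_jsonl <- function(path) {
  sets <- lapply(readLines(path), function(line) {
    o <- jsonlite::fromJSON(line, simplifyVector = FALSE)
    labs <- vapply(o$entries, function(e) as.character(e[[1]]), character(1))
    conf <- vapply(o$entries, function(e) as.numeric(e[[2]]), numeric(1))
    structure(list(id = o$id,
                   labels = labs, confidence = conf,
                   truth = if (is.null(o$truth)) NA_character_ else o$truth,
                   size = length(labs)),
              class = "prediction_set")
  })
  structure(sets, class = "prediction_sets")
}

#' Write the audit report to disk
#'
#' Emits `report.json` plus plot-ready CSVs: `setsize_by_group.csv`,
#' `a2_by_group.csv`, `gt_confidence.csv`, `top2_guarantee.csv` and
#' `region_ranking.csv`.
#'
#' @param report An [audit_report()].
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_audit_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(unclass(report), file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  sz <- do.call(rbind, lapply(names(report$setsize_hist), function(a)
    data.frame(attribute = a, report$setsize_hist[[a]])))
  utils::write.csv(sz, file.path(dir, "setsize_by_group.csv"), row.names = FALSE)
  a2 <- do.call(rbind, lapply(names(report$a2_by_group), function(a)
    data.frame(attribute = a, report$a2_by_group[[a]])))
  utils::write.csv(a2, file.path(dir, "a2_by_group.csv"), row.names = FALSE)
  utils::write.csv(report$gt_confidences, file.path(dir, "gt_confidence.csv"),
                   row.names = FALSE)
  utils::write.csv(report$top2_guarantees, file.path(dir, "top2_guarantee.csv"),
                   row.names = FALSE)
  if (!is.null(report$region_table))
    utils::write.csv(report$region_table, file.path(dir, "region_ranking.csv"),
                     row.names = FALSE)
  invisible(dir)
}

default_run_config <- function() {
  list(seed = 1L, alpha = 0.2,
       cohort = list(class_counts = isic2019_counts(total = 2000)),
       mlp = list(epochs = 10),
       sampler = list(),
       attributes = c("sex", "age_band", "anatom_site", "cohort"))
}

#' Load and validate a run configuration
#'
#' A run config is a named list (or YAML file) with fields `seed`, `alpha`,
#' either `cohort` (arguments to [cohort_spec()], synthetic mode) or `paths`
#' (`embeddings`, `groundtruth`, `metadata`; real-data mode), `mlp`
#' (arguments to [mlp_config()]), `sampler` (arguments to [sampler_config()],
#' or `NULL` to disable dynamic sampling) and `attributes` to audit.
#'
#' @param config Named list or path to a YAML file.
#' @return Validated config list.
#' @export
run_config <- function(config = list()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- utils::modifyList(default_run_config(), config)
  if (!is.numeric(cfg$alpha) || cfg$alpha <= 0 || cfg$alpha >= 1)
    bad_field("alpha", "must lie in (0, 1)")
  # YAML maps arrive as lists; cohort_spec wants named numeric counts
  if (!is.null(cfg$cohort$class_counts) && is.list(cfg$cohort$class_counts))
    cfg$cohort$class_counts <- unlist(cfg$cohort$class_counts)
  if (!is.null(config$paths)) {
    cfg$cohort <- NULL
    for (p in c("embeddings", "groundtruth"))
      if (!file.exists(cfg$paths[[p]] %||% ""))
        bad_field("paths", sprintf("missing %s file", p))
  }
  cfg
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stage_artifact <- function(out_dir, name, stage) {
  p <- file.path(out_dir, name)
  if (!file.exists(p))
    stop(sprintf("stage '%s' failed: required artifact '%s' not found (run the earlier stages first)",
                 stage, name), call. = FALSE)
  p
}

#' Run the full pipeline: simulate, split, train, calibrate, predict, audit
#'
#' Orchestrates the end-to-end workflow and leaves every stage's artifact
#' under `out_dir`, so later stages can resume from disk: `data/` (cohort
#' files), `splits.json`, `model.rds` + `train_log.csv`, `calibration.json`,
#' `sets.jsonl`, and `audit/` (report.json + CSVs). All randomness derives
#' from the single master seed in the config, so a rerun with the same config
#' reproduces `report.json` exactly.
#'
#' @param config A [run_config()] (list or YAML path).
#' @param out_dir Run directory.
#' @param stages Which stages to run, in pipeline order.
#' @return The `audit_report` (invisibly) when the audit stage runs, else
#'   `NULL`.
#' @export
run_pipeline <- function(config, out_dir,
                         stages = c("simulate", "split", "train", "calibrate",
                                    "predict-sets", "audit")) {
  cfg <- run_config(if (is.character(config)) config else config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  data_dir <- file.path(out_dir, "data")

  if ("simulate" %in% stages) {
    if (is.null(cfg$cohort)) {
      dir.create(data_dir, recursive = TRUE, showWarnings = FALSE)
      file.copy(cfg$paths$embeddings, file.path(data_dir, "embeddings.json"),
                overwrite = TRUE)
      file.copy(cfg$paths$groundtruth, file.path(data_dir, "groundtruth.csv"),
                overwrite = TRUE)
      if (!is.null(cfg$paths$metadata))
        file.copy(cfg$paths$metadata, file.path(data_dir, "metadata.csv"),
                  overwrite = TRUE)
    } else {
      spec <- do.call(cohort_spec,
                      utils::modifyList(cfg$cohort,
                                        list(seed = derive_seed(cfg$seed, "simulate"))))
      write_cohort(generate_cohort(spec), data_dir)
    }
  }

  if ("split" %in% stages) {
    stage_artifact(out_dir, "data/embeddings.json", "split")
    cohort <- read_cohort(data_dir)
    split <- split_cohort(cohort, seed = derive_seed(cfg$seed, "split"))
    jsonlite::write_json(unclass(split), file.path(out_dir, "splits.json"))
  }

  if ("train" %in% stages) {
    stage_artifact(out_dir, "splits.json", "train")
    cohort <- read_cohort(data_dir)
    split <- jsonlite::fromJSON(file.path(out_dir, "splits.json"))
    sampler <- if (is.null(cfg$sampler)) NULL else do.call(sampler_config, cfg$sampler)
    mcfg <- do.call(mlp_config,
                    utils::modifyList(cfg$mlp %||% list(),
                                      list(input_dim = ncol(cohort$x),
                                           sampler = sampler,
                                           seed = derive_seed(cfg$seed, "train"))))
    model <- train_head(subset_cohort(cohort, split$train),
                        subset_cohort(cohort, split$validation), mcfg)
    saveRDS(model, file.path(out_dir, "model.rds"))
    utils::write.csv(model$log, file.path(out_dir, "train_log.csv"),
                     row.names = FALSE)
  }

  if ("calibrate" %in% stages) {
    stage_artifact(out_dir, "model.rds", "calibrate")
    cohort <- read_cohort(data_dir)
    split <- jsonlite::fromJSON(stage_artifact(out_dir, "splits.json", "calibrate"))
    model <- readRDS(file.path(out_dir, "model.rds"))
    cal_cohort <- subset_cohort(cohort, split$calibration)
    calib <- calibrate(nonconformity_scores(predict_proba(model, cal_cohort),
                                            cal_cohort$labels),
                       cfg$alpha)
    jsonlite::write_json(unclass(calib), file.path(out_dir, "calibration.json"),
                         auto_unbox = TRUE, digits = NA)
  }

  if ("predict-sets" %in% stages) {
    stage_artifact(out_dir, "calibration.json", "predict-sets")
    cohort <- read_cohort(data_dir)
    split <- jsonlite::fromJSON(stage_artifact(out_dir, "splits.json", "predict-sets"))
    model <- readRDS(stage_artifact(out_dir, "model.rds", "predict-sets"))
    cj <- jsonlite::fromJSON(file.path(out_dir, "calibration.json"))
    calib <- structure(list(alpha = cj$alpha, n = cj$n, scores = cj$scores,
                            q_hat = cj$q_hat),
                       class = "calibration_result")
    test_cohort <- subset_cohort(cohort, split$test)
    sets <- build_sets(predict_proba(model, test_cohort), calib,
                       truth = test_cohort$labels)
    write_sets_jsonl(sets, file.path(out_dir, "sets.jsonl"))
  }

  report <- NULL
  if ("audit" %in% stages) {
    sets <- read_sets_jsonl(stage_artifact(out_dir, "sets.jsonl", "audit"))
    cohort <- read_cohort(data_dir)
    report <- audit_report(sets, cohort$demographics, attributes = cfg$attributes)
    write_audit_report(report, file.path(out_dir, "audit"))
  }
  invisible(report)
}
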