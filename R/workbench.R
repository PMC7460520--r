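#' Experiment configuration
#'
#' Bundles the per-stage settings of a full experiment run: phantom cohort,
#' split, preprocessing/augmentation, model, training, staging and the
#' global seed from which every per-stage seed is derived. The
#' configuration survives a YAML round-trip unchanged.
#'
#' @param cohort A [cohort_spec()].
#' @param modality Image channel used for training/prediction.
#' @param train_fraction,val_count,evaluation Split settings (see
#'   [split_cohort()]).
#' @param augment_plan Augmentation ops applied to training cases.
#' @param model A [model_spec()].
#' @param training A [train_config()].
#' @param n_rays,fit_order Staging settings.
#' @param seed Global seed; stage seeds are derived from it.
#' @return An `experiment_config` list.
#' @export
experiment_config <- function(cohort = cohort_spec(),
                              modality = "T1c",
                              train_fraction = 1 / 3,
                              val_count = 6,
                              evaluation = "pooled",
                              augment_plan = c("flips", "intensity"),
                              model = model_spec("tiny"),
                              training = train_config(),
                              n_rays = 720,
                              fit_order = 3,
                              seed = 1L) {
  structure(
    list(
      cohort = cohort, modality = modality,
      train_fraction = train_fraction, val_count = val_count,
      evaluation = evaluation, augment_plan = augment_plan,
      model = model, training = training,
      n_rays = n_rays, fit_order = fit_order, seed = as.integer(seed)
    ),
    class = "experiment_config"
  )
}

#' Write / read an experiment configuration as YAML
#'
#' @param cfg An [experiment_config()].
#' @param path YAML file path.
#' @return `read_experiment_config` returns the configuration;
#'   `write_experiment_config` returns `path` invisibly.
#' @export
write_experiment_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "experiment_config"))
  lst <- rapply(unclass(cfg), identity, how = "replace")
  lst$cohort <- unclass(lst$cohort)
  lst$cohort$fraction_law <- NULL # functions are not serialized; default law
  lst$model <- unclass(lst$model)
  lst$training <- unclass(lst$training)
  yaml::write_yaml(lst, path, precision = 15)
  invisible(path)
}

#' @rdname write_experiment_config
#' @export
read_experiment_config <- function(path) {
  lst <- yaml::read_yaml(path)
  experiment_config(
    cohort = do.call(cohort_spec, lst$cohort),
    modality = lst$modality,
    train_fraction = lst$train_fraction,
    val_count = lst$val_count,
    evaluation = lst$evaluation,
    augment_plan = lst$augment_plan,
    model = do.call(model_spec, lst$model[c("encoder_family", "structures")]),
    training = do.call(train_config, lst$training),
    n_rays = lst$n_rays,
    fit_order = lst$fit_order,
    seed = lst$seed
  )
}

#' Run a full experiment
#'
#' Executes the whole pipeline: generate the phantom cohort, split it,
#' standardize and augment (training cases only), train the segmentation
#' model with best-validation-loss checkpointing, predict masks on the
#' evaluation group, estimate invasion fractions, stage each case, and
#' assemble the concordance report. Deterministic under a fixed seed in
#' single-threaded mode. When `out_dir` is given, the truth/split/staging
#' tables, the training history and the report are written there and
#' listed in the returned manifest.
#'
#' @param cfg An [experiment_config()].
#' @param out_dir Optional output directory.
#' @return An `experiment_result`: `staging` (per-case tibble joining
#'   estimates with truth), `summary` (diagnostic summary), `report`
#'   (cohort concordance report), `training`, `split`, `manifest`.
#' @export
run_experiment <- function(cfg, out_dir = NULL) {
  stopifnot(inherits(cfg, "experiment_config"))

  cohort <- generate_cohort(cfg$cohort)
  truth <- cohort_truth(cohort)
  split <- split_cohort(
    truth, train_fraction = cfg$train_fraction, val_count = cfg$val_count,
    seed = child_seed(cfg$seed, "split"), evaluation = cfg$evaluation
  )

  ids <- truth$case_id
  train_cases <- cohort[split$split == "train"]
  val_cases <- cohort[split$split == "validation"]
  eval_cases <- cohort[split$in_evaluation]

  # augmentation is applied to the training pool only
  train_samples <- list()
  for (cs in train_cases) {
    img <- standardize(cs$images[[cfg$modality]])
    aug <- augment(img, cs$lesion_mask, plan = cfg$augment_plan,
                   seed = child_seed(cfg$seed, "augment") + match(cs$case_id, ids))
    # re-derive both masks under each geometric transform
    for (k in seq_len(nrow(aug))) {
      tr_name <- aug$transform[k]
      um <- transform_like(cs$uterus_mask, tr_name, aug$params[[k]])
      lm <- transform_like(cs$lesion_mask, tr_name, aug$params[[k]])
      s <- prepare_sample(aug$image[[k]], um, lm)
      s$case_id <- cs$case_id
      s$provenance <- aug$provenance[k]
      train_samples[[length(train_samples) + 1L]] <- s
    }
  }
  val_samples <- prepare_cases(val_cases, cfg$modality)
  for (i in seq_along(val_samples)) val_samples[[i]]$provenance <- "original"

  model <- build_model(cfg$model, seed = cfg$seed)
  training <- train_model(model, train_samples, val_samples, cfg$training)

  preds <- list()
  for (cs in eval_cases) {
    img <- standardize(cs$images[[cfg$modality]])
    preds[[cs$case_id]] <- predict_masks(training$model, img, cs$case_id)
  }

  staging <- stage_cohort(eval_cases, masks = preds,
                          n_rays = cfg$n_rays, fit_order = cfg$fit_order)
  staging <- dplyr::left_join(staging, truth, by = "case_id")
  report <- cohort_report(staging, evaluation = attr(split, "evaluation"))

  ok <- !is.na(staging$stage)
  summary <- diagnostic_summary(staging$stage[ok], staging$true_stage[ok])

  manifest <- NULL
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    files <- c(
      truth = file.path(out_dir, "truth.csv"),
      split = file.path(out_dir, "split.csv"),
      staging = file.path(out_dir, "staging.csv"),
      history = file.path(out_dir, "history.csv"),
      report = file.path(out_dir, "report.json")
    )
    readr::write_csv(truth, files["truth"])
    readr::write_csv(split, files["split"])
    readr::write_csv(staging, files["staging"])
    readr::write_csv(training$history, files["history"])
    jsonlite::write_json(report, files["report"], auto_unbox = TRUE,
                         digits = NA, pretty = TRUE, force = TRUE)
    manifest <- tibble::tibble(
      stage = names(files), path = unname(files),
      exists = file.exists(files)
    )
    attr(manifest, "config_hash") <- rlang::hash(cfg)
    attr(manifest, "timestamp") <- format(Sys.time(), tz = "UTC")
  }

  structure(
    list(
      staging = staging, summary = summary, report = report,
      training = training, split = split, manifest = manifest, config = cfg
    ),
    class = "experiment_result"
  )
}

# Replay a named geometric transform on another congruent mask.
transform_like <- function(mask, transform, params) {
  switch(sub("_[0-9]+$", "", transform),
    identity = mask,
    intensity = mask,
    hflip = mask[, rev(seq_len(ncol(mask))), drop = FALSE],
    vflip = mask[rev(seq_len(nrow(mask))), , drop = FALSE],
    affine = apply_affine(mask, params, kind = "mask"),
    abort_myo(sprintf("unknown transform '%s'", transform))
  )
}

#' Concordance report for a staged cohort
#'
#' Mirrors the structure of the published concordance analysis on any
#' staged cohort: stage-vs-pathology confusion counts, accuracy and
#' over-/under-diagnosis rates, the leiomyoma-effect chi-square, and
#' five-number summaries of the invasion fraction by concordance group.
#'
#' @param staging Tibble from [stage_cohort()] joined with the truth table
#'   (columns `stage`, `true_stage`, `fraction`, `leiomyoma_present`).
#' @param evaluation Label describing the evaluation pool.
#' @return A `cohort_report` list.
#' @export
cohort_report <- function(staging, evaluation = "pooled") {
  ok <- !is.na(staging$stage)
  st <- staging[ok, ]
  ds <- diagnostic_summary(st$stage, st$true_stage)
  confusion <- table(
    predicted = factor(st$stage, c("IA", "IB")),
    pathology = factor(st$true_stage, c("IA", "IB"))
  )
  leio_chi2 <- NULL
  if ("leiomyoma_present" %in% names(st) &&
      length(unique(st$leiomyoma_present)) == 2) {
    correct <- st$stage == st$true_stage
    tab <- rbind(
      c(sum(correct & st$leiomyoma_present), sum(!correct & st$leiomyoma_present)),
      c(sum(correct & !st$leiomyoma_present), sum(!correct & !st$leiomyoma_present))
    )
    leio_chi2 <- if (all(rowSums(tab) > 0) && all(colSums(tab) > 0)) {
      tidy(pearson_chi2(tab))
    }
  }
  grp <- dplyr::case_when(
    st$stage == st$true_stage & st$true_stage == "IA" ~ "compatible_IA",
    st$stage == st$true_stage & st$true_stage == "IB" ~ "compatible_IB",
    TRUE ~ "discrepancy"
  )
  fns <- dplyr::bind_cols(
    tibble::tibble(group = sort(unique(grp))),
    dplyr::bind_rows(lapply(sort(unique(grp)), function(g) {
      five_number_summary(st$fraction[grp == g])
    }))
  )
  structure(
    list(
      evaluation_pool = evaluation,
      n_evaluated = nrow(st),
      n_failed = sum(!ok),
      confusion = confusion,
      summary = ds,
      leiomyoma_effect = leio_chi2,
      fraction_five_number = fns
    ),
    class = "cohort_report"
  )
}

#' @export
print.cohort_report <- function(x, ...) {
  cat(sprintf(
    "<cohort_report> %d cases evaluated (pool: %s%s)\n",
    x$n_evaluated, x$evaluation_pool,
    if (x$n_failed) sprintf(", %d failed", x$n_failed) else ""
  ))
  if (x$evaluation_pool == "pooled") {
    cat("  note: evaluation pool includes the validation cases\n")
  }
  print(x$confusion)
  with(x$summary, cat(sprintf(
    "  accuracy %.1f%% (%d/%d), over-diagnosis rate %.1f%%, under %.1f%%\n",
    100 * accuracy, n_compatible, n, 100 * over_diagnosis_rate,
    100 * under_diagnosis_rate
  )))
  invisible(x)
}

#' @export
print.experiment_result <- function(x, ...) {
  cat("<experiment_result>\n")
  print(x$report)
  invisible(x)
}

# ---- case I/O ------------------------------------------------------------

#' Write / read a phantom case to and from disk
#'
#' Images are written losslessly as NIfTI (`.nii.gz`), masks as 8-bit PNG
#' (values 0/1; 0/255-coded masks are normalized on read), the truth row
#' and junction samples as CSV. The round-trip is exact for masks and
#' truth.
#'
#' @param case A `phantom_case`.
#' @param dir Directory for this case's files (created if needed).
#' @return `write_case` returns the directory invisibly; `read_case`
#'   returns a `phantom_case`.
#' @export
write_case <- function(case, dir) {
  stopifnot(inherits(case, "phantom_case"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (mod in names(case$images)) {
    RNifti::writeNifti(case$images[[mod]],
                       file.path(dir, paste0(mod, ".nii.gz")))
  }
  png::writePNG(case$uterus_mask, file.path(dir, "uterus_mask.png"))
  png::writePNG(case$lesion_mask, file.path(dir, "lesion_mask.png"))
  readr::write_csv(case$truth, file.path(dir, "truth.csv"))
  readr::write_csv(case$junction_truth, file.path(dir, "junction_truth.csv"))
  writeLines(
    yaml::as.yaml(list(
      case_id = case$case_id,
      origin = as.numeric(case$origin),
      lesion_center_angle = case$lesion_center_angle
    )),
    file.path(dir, "meta.yaml")
  )
  invisible(dir)
}

#' @rdname write_case
#' @export
read_case <- function(dir) {
  meta <- yaml::read_yaml(file.path(dir, "meta.yaml"))
  nii <- list.files(dir, pattern = "\\.nii(\\.gz)?$", full.names = TRUE)
  images <- lapply(nii, function(f) {
    img <- RNifti::readNifti(f)
    matrix(as.numeric(img), dim(img)[1], dim(img)[2])
  })
  names(images) <- sub("\\.nii(\\.gz)?$", "", basename(nii))
  read_mask <- function(f) {
    m <- png::readPNG(f)
    if (length(dim(m)) == 3) m <- m[, , 1]
    normalize_mask(m)
  }
  uterus <- read_mask(file.path(dir, "uterus_mask.png"))
  lesion <- read_mask(file.path(dir, "lesion_mask.png"))
  for (img in images) {
    assert_same_shape(img, uterus, "image", "uterus mask")
  }
  structure(
    list(
      case_id = meta$case_id,
      images = images,
      uterus_mask = uterus,
      lesion_mask = lesion,
      junction_truth = readr::read_csv(
        file.path(dir, "junction_truth.csv"), show_col_types = FALSE
      ),
      origin = c(row = meta$origin[1], col = meta$origin[2]),
      lesion_center_angle = meta$lesion_center_angle,
      truth = readr::read_csv(file.path(dir, "truth.csv"),
                              show_col_types = FALSE),
      params = NULL
    ),
    class = "phantom_case"
  )
}

#' Normalize a mask encoding to 0/1
#'
#' Accepts 0/1, 0/255 (or any two-level encoding with the high level
#' mapping to 1) and unit-scaled PNG reads.
#'
#' @param m Numeric matrix.
#' @return Binary 0/1 matrix.
#' @export
normalize_mask <- function(m) {
  u <- sort(unique(as.vector(m)))
  if (length(u) > 2) {
    abort_myo(sprintf("mask has %d distinct values; expected 2", length(u)))
  }
  (m >= max(u) & max(u) > 0) * 1
}
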