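#' Pipeline configuration
#'
#' One nested configuration for the whole workflow: phantom cohort sizes
#' (or manifests of existing data), normalization range, chest band,
#' augmentation plan, detector backend, mining threshold and
#' cross-validation parameters. Round-trips losslessly through YAML.
#'
#' @param seed base seed of every random stage.
#' @param out_dir artifact directory.
#' @param pretrain,target either `list(n_positive =, n_negative =)` for
#'   phantom generation or `list(manifest = "path.csv")` for existing data.
#' @param normalize `list(t1 =, t2 =)`, default (7, 14).
#' @param chest_band two fractions of body height, default `c(0.10, 0.45)`.
#' @param augment augmentation plan fields (low, high, n_levels,
#'   include_flips).
#' @param backend [backend_config()] overrides.
#' @param mining [mining_config()] overrides.
#' @param cv `list(n_shuffles =, k =, decision_conf =, iou =,
#'   confidence_floor =)`.
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1L, out_dir = "scintihot-run",
                            pretrain = list(n_positive = 12, n_negative = 12),
                            target = list(n_positive = 10, n_negative = 10),
                            normalize = list(t1 = 7, t2 = 14),
                            chest_band = c(0.10, 0.45),
                            augment = list(low = 25, high = 48,
                                           n_levels = 6, include_flips = TRUE),
                            backend = list(),
                            mining = list(harvest_confidence = 0.1),
                            cv = list(n_shuffles = 2, k = 5,
                                      decision_conf = 0.5, iou = 0.3,
                                      confidence_floor = 0.1)) {
  cfg <- structure(list(seed = as.integer(seed), out_dir = out_dir,
                        pretrain = pretrain, target = target,
                        normalize = normalize, chest_band = chest_band,
                        augment = augment, backend = backend,
                        mining = mining, cv = cv),
                   class = "pipeline_config")
  validate_pipeline_config(cfg)
}

validate_pipeline_config <- function(cfg) {
  nz <- cfg$normalize
  if (!(nz$t1 > 0 && nz$t1 < nz$t2 && nz$t2 <= 255))
    stopf("config validation error: need 0 < t1 < t2 <= 255 (got %s, %s)", nz$t1, nz$t2)
  if (!(cfg$augment$low < cfg$augment$high))
    stopf("config validation error: augmentation range low < high required")
  if (!(length(cfg$chest_band) == 2 && cfg$chest_band[1] < cfg$chest_band[2]))
    stopf("config validation error: chest_band must be two increasing fractions")
  if (!(cfg$cv$k >= 2)) stopf("config validation error: cv k >= 2 required")
  hc <- cfg$mining$harvest_confidence %||% 0.1
  if (hc < 0 || hc > 1) stopf("config validation error: harvest_confidence in [0,1]")
  cfg
}

#' Read a pipeline configuration from YAML
#'
#' Missing keys fall back to the [pipeline_config()] defaults; the file's
#' keys override them.
#'
#' @param path YAML file.
#' @return validated `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stopf("config file not found: %s", path)
  raw <- yaml::read_yaml(path)
  defaults <- pipeline_config()
  merged <- utils::modifyList(unclass(defaults), raw)
  cfg <- structure(merged, class = "pipeline_config")
  validate_pipeline_config(cfg)
}

resolve_cohort <- function(spec, seed, dir, cfg) {
  if (!is.null(spec$manifest)) {
    load_fused_cohort(spec$manifest, t1 = cfg$normalize$t1,
                      t2 = cfg$normalize$t2, band = cfg$chest_band)
  } else {
    simulate_fused_cohort(spec$n_positive, spec$n_negative, seed = seed,
                          t1 = cfg$normalize$t1, t2 = cfg$normalize$t2,
                          band = cfg$chest_band)
  }
}

#' Run the full training and evaluation pipeline
#'
#' End-to-end order of operations: pre-train a one-class detector on the
#' pre-train cohort's positives, mine negatives from its normals, retrain
#' to the two-class pre-trained model, then fine-tune and evaluate on the
#' target cohort with shuffled stratified cross-validation. All artifacts
#' (mined-negative store with provenance, per-shuffle report as CSV and
#' JSON, config digest) are written under `config$out_dir`. Re-running
#' with the same configuration reproduces the report exactly.
#'
#' @param config a [pipeline_config()].
#' @return invisibly, a list with the `report` (a `cv_report`), the
#'   trained `pretrained` model and artifact `paths`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  validate_pipeline_config(config)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)

  bk <- do.call(backend_config, c(config$backend, list(seed = config$seed)))
  mc <- mining_config(harvest_confidence = config$mining$harvest_confidence %||% 0.1,
                      seed = config$seed)
  plan <- augment_plan(low = config$augment$low, high = config$augment$high,
                       n_levels = config$augment$n_levels,
                       include_flips = isTRUE(config$augment$include_flips))

  pre <- resolve_cohort(config$pretrain, seed = config$seed + 1000L,
                        dir = config$out_dir, cfg = config)
  pos <- pre$images[pre$manifest$patient_positive]
  neg <- pre$images[!pre$manifest$patient_positive]

  premodel <- pretrain_positive_only(pos, bk)
  mined <- harvest_negatives(premodel, neg, mc)

  mined_dir <- file.path(config$out_dir, "mined")
  dir.create(mined_dir, showWarnings = FALSE)
  for (im in mined$images) {
    d <- fused_dims(im)
    write_labels(im$boxes, file.path(mined_dir, paste0(im$source_id, ".txt")),
                 width = d[2], height = d[1])
  }
  jsonlite::write_json(
    list(model_digest = mined$model_digest,
         harvest_confidence = mined$config$harvest_confidence,
         n_mined = nrow(mined$boxes),
         config_digest = text_digest(unclass(config))),
    file.path(mined_dir, "provenance.json"), auto_unbox = TRUE, digits = NA)

  pretrained <- retrain_two_class(pos, mined, bk)

  tgt <- resolve_cohort(config$target, seed = config$seed + 2000L,
                        dir = config$out_dir, cfg = config)
  report <- run_shuffles(tgt, pretrained,
                         n_shuffles = config$cv$n_shuffles, k = config$cv$k,
                         base_seed = config$seed, config = bk, plan = plan,
                         iou_threshold = config$cv$iou %||% 0.3,
                         decision_conf = config$cv$decision_conf %||% 0.5,
                         confidence_floor = config$cv$confidence_floor %||% 0.1)

  report_csv <- file.path(config$out_dir, "cv_report.csv")
  write.csv(report$rows, report_csv, row.names = FALSE)
  report_json <- file.path(config$out_dir, "cv_report.json")
  jsonlite::write_json(
    list(rows = report$rows,
         aggregate = lapply(report$aggregate, function(a)
           list(mean = a$mean, sd = a$sd, rendered = a$rendered)),
         n_mined = nrow(mined$boxes),
         config_digest = text_digest(unclass(config))),
    report_json, auto_unbox = TRUE, digits = NA)

  invisible(list(report = report, pretrained = pretrained, mined = mined,
                 paths = list(report_csv = report_csv,
                              report_json = report_json,
                              mined_dir = mined_dir)))
}
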