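#' Pipeline configuration
#'
#' One nested list holding every tunable of the end-to-end run. Every
#' stochastic stage carries an explicit seed derived from \code{seed}, so a
#' run is fully reproducible from its config.
#'
#' @param m patch side.
#' @param stride patch stride.
#' @param roi_min_frac ROI gating fraction for patches.
#' @param k,r benign / malignant reference counts.
#' @param max_iter clustering iteration cap.
#' @param hidden relation-head hidden widths.
#' @param learning_rate,momentum,weight_decay,batch_size,epochs,pairs_per_epoch
#'   encoder training settings (see \code{\link{train_config}}).
#' @param train_fraction fraction of each class used for training when the
#'   manifest has no split column.
#' @param seed master seed.
#' @return a \code{lrsc_config} nested list.
#' @export
lrsc_config <- function(m = 16L, stride = 8L, roi_min_frac = 0.5,
                        k = 25L, r = 25L, max_iter = 300L,
                        hidden = c(64L, 64L), learning_rate = 0.001,
                        momentum = 0.9, weight_decay = 1e-6,
                        batch_size = 64L, epochs = 30L,
                        pairs_per_epoch = 1024L, train_fraction = 0.8,
                        seed = 1L) {
  structure(list(
    patch = list(m = as.integer(m), stride = as.integer(stride),
                 roi_min_frac = roi_min_frac),
    references = list(k = as.integer(k), r = as.integer(r),
                      max_iter = as.integer(max_iter)),
    encoder = list(hidden = as.integer(hidden), learning_rate = learning_rate,
                   momentum = momentum, weight_decay = weight_decay,
                   batch_size = as.integer(batch_size),
                   epochs = as.integer(epochs),
                   pairs_per_epoch = as.integer(pairs_per_epoch)),
    split = list(train_fraction = train_fraction),
    seed = as.integer(seed)
  ), class = "lrsc_config")
}

#' Read a pipeline config from a YAML file
#'
#' Keys mirror the arguments of \code{\link{lrsc_config}} (flat or nested
#' under patch/references/encoder/split); missing keys keep their defaults.
#'
#' @param path YAML file.
#' @return an \code{lrsc_config}.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop_lrsc("config file not found: '%s'", path)
  y <- yaml::read_yaml(path)
  flat <- c(y[!vapply(y, is.list, logical(1))],
            unlist(y[vapply(y, is.list, logical(1))], recursive = FALSE,
                   use.names = TRUE))
  names(flat) <- sub("^(patch|references|encoder|split)\\.", "", names(flat))
  known <- names(formals(lrsc_config))
  do.call(lrsc_config, flat[intersect(names(flat), known)])
}

# stratified train/test split; honors an existing manifest split column
resolve_split <- function(manifest, train_fraction, seed) {
  if ("split" %in% names(manifest) &&
      all(manifest$split %in% c("train", "test"))) {
    return(manifest$split)
  }
  split <- rep("test", nrow(manifest))
  for (class in unique(manifest$label)) {
    rows <- which(manifest$label == class)
    n_train <- round(train_fraction * length(rows))
    take <- with_seed(derive_seed(seed, 777, match(class, LRSC_CLASSES)),
                      sample(rows, n_train))
    split[take] <- "train"
  }
  split
}

#' Run the full pipeline: split, cluster, train, encode, classify, evaluate
#'
#' Executes the whole method on a manifest and writes every artifact needed
#' to reproduce the evaluation without retraining: the evaluation report
#' (JSON), per-image predictions (CSV), the learned references, the trained
#' encoder, and a run log recording the full configuration and seeds.
#' Identical config + manifest always produce byte-identical reports.
#'
#' @param config an \code{\link{lrsc_config}} (or path to a YAML config).
#' @param manifest manifest CSV path or data.frame.
#' @param out_dir output directory; created if needed. \code{NULL} skips
#'   writing and just returns the report.
#' @param quiet suppress progress messages (messages go to stderr).
#' @return the evaluation report: list with \code{counts}, \code{metrics},
#'   \code{auc}, \code{n_images}, \code{n_train}, \code{config_digest}, and
#'   the per-image prediction table as \code{per_image}.
#' @export
run_pipeline <- function(config = lrsc_config(), manifest, out_dir = NULL,
                         quiet = FALSE) {
  if (is.character(config)) config <- read_config(config)
  stopifnot(inherits(config, "lrsc_config"))
  if (is.character(manifest)) manifest <- read_manifest(manifest)
  say <- function(fmt, ...) if (!quiet) message(sprintf(paste0("[lrsc] ", fmt), ...))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop_lrsc("stage '%s' failed: %s", name, conditionMessage(e))
    })
  }
  split <- stage("split", resolve_split(manifest, config$split$train_fraction,
                                        config$seed))
  train_man <- manifest[split == "train", , drop = FALSE]
  test_man <- manifest[split == "test", , drop = FALSE]
  if (length(unique(train_man$label)) < 2) {
    stop_lrsc("stage 'split' failed: training split must contain both classes (found: %s)",
              paste(unique(train_man$label), collapse = ", "))
  }
  say("training on %d images, testing on %d", nrow(train_man), nrow(test_man))
  fit <- stage("fit", lrsc(
    train_man,
    k = config$references$k, r = config$references$r,
    m = config$patch$m, stride = config$patch$stride,
    roi_min_frac = config$patch$roi_min_frac,
    max_iter = config$references$max_iter,
    config = train_config(
      learning_rate = config$encoder$learning_rate,
      momentum = config$encoder$momentum,
      weight_decay = config$encoder$weight_decay,
      batch_size = config$encoder$batch_size,
      epochs = config$encoder$epochs,
      pairs_per_epoch = config$encoder$pairs_per_epoch,
      hidden = config$encoder$hidden,
      seed = derive_seed(config$seed, 2)
    ),
    seed = config$seed
  ))
  say("references learned (%d iterations), encoder trained (%d epochs)",
      fit$references$meta$iterations, nrow(fit$encoder$history))
  pred <- stage("predict", predict(fit, test_man))
  report <- stage("evaluate", build_report(pred, config, nrow(train_man)))
  if (!is.null(out_dir)) {
    stage("write", write_run_artifacts(out_dir, fit, pred, report, config))
    say("artifacts written to %s", out_dir)
  }
  report
}

build_report <- function(pred, config, n_train) {
  ev <- evaluate_predictions(pred$truth, pred$label, pred$score)
  ev$n_train <- n_train
  ev$config_digest <- config_digest(config)
  ev$per_image <- pred
  ev
}

# small deterministic checksum of the serialized config (polynomial hash of
# the canonical JSON text; avoids an external digest dependency)
config_digest <- function(config) {
  txt <- jsonlite::toJSON(unclass(config), auto_unbox = TRUE, digits = NA)
  h <- 0
  for (b in utf8ToInt(as.character(txt))) h <- (h * 131 + b) %% 2147483647
  sprintf("%08x", h)
}

write_run_artifacts <- function(out_dir, fit, pred, report, config) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  save_references(fit$references, file.path(out_dir, "references"))
  save_encoder(fit$encoder, file.path(out_dir, "encoder.json"))
  utils::write.csv(pred, file.path(out_dir, "per_image.csv"),
                   row.names = FALSE)
  rep_json <- report[c("metrics", "auc", "n_images", "n_train",
                       "config_digest")]
  rep_json$counts <- unclass(report$counts)
  rep_json$metrics <- as.list(report$metrics)
  jsonlite::write_json(rep_json, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  jsonlite::write_json(list(config = unclass(config),
                            n_train_patches = fit$n_train_patches,
                            clustering = fit$references$meta,
                            epochs_run = nrow(fit$encoder$history)),
                       file.path(out_dir, "run_log.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}

#' Re-evaluate a finished run from its serialized artifacts
#'
#' Loads the references and encoder written by \code{\link{run_pipeline}}
#' and re-runs encoding + self-matching on the manifest's test split,
#' without any retraining. The evaluation output equals the original run's.
#'
#' @param run_dir directory written by \code{\link{run_pipeline}}.
#' @param manifest manifest path or data.frame.
#' @param config the \code{\link{lrsc_config}} of the run (for the patch
#'   settings and split seed).
#' @return an evaluation report as in \code{\link{run_pipeline}}.
#' @export
reevaluate_run <- function(run_dir, manifest, config = lrsc_config()) {
  if (is.character(config)) config <- read_config(config)
  if (is.character(manifest)) manifest <- read_manifest(manifest)
  refs <- load_references(file.path(run_dir, "references"))
  enc <- load_encoder(file.path(run_dir, "encoder.json"))
  split <- resolve_split(manifest, config$split$train_fraction, config$seed)
  test_man <- manifest[split == "test", , drop = FALSE]
  images <- load_manifest_images(test_man)
  codes <- lapply(images, image_semantic_code, refs = refs, encoder = enc,
                  stride = config$patch$stride,
                  roi_min_frac = config$patch$roi_min_frac)
  pred <- codes_to_table(codes)
  pred$truth <- vapply(images, `[[`, character(1), "label")
  build_report(pred, config, sum(split == "train"))
}
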