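# Run configuration: a single structured file (YAML) with one section per
# component, schema-validated before any work, plus dot-path overrides.

run_config_schema <- function() {
  list(
    top = c("seed", "output_dir", "data", "checkpoint",
            "phantom", "preprocess", "backbone", "rl", "train", "eval"),
    phantom = names(formals(phantom_config)),
    preprocess = c(setdiff(names(formals(augment_config)), "seed"),
                   "balance", "augment_enabled"),
    backbone = names(formals(backbone_config)),
    rl = c(names(formals(ppo_config)), "enabled"),
    train = names(formals(train_config)),
    eval = c("n_val_per_class", "threshold", "level", "ci_method")
  )
}

#' Validate a run configuration
#'
#' Checks the section structure and rejects unknown keys with a
#' field-level message; fills defaults for missing sections.
#'
#' @param config named list (typically parsed from YAML).
#' @return the validated configuration, with defaults filled in.
#' @export
validate_run_config <- function(config) {
  schema <- run_config_schema()
  unknown <- setdiff(names(config), schema$top)
  if (length(unknown)) {
    stop("unknown configuration field(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  for (sec in c("phantom", "preprocess", "backbone", "rl", "train", "eval")) {
    if (is.null(config[[sec]])) config[[sec]] <- list()
    bad <- setdiff(names(config[[sec]]), schema[[sec]])
    if (length(bad)) {
      stop("unknown configuration field(s) in section '", sec, "': ",
           paste(paste0(sec, ".", bad), collapse = ", "), call. = FALSE)
    }
  }
  config$seed <- as.integer(config$seed %||% 1L)
  config$output_dir <- config$output_dir %||% "drlroi_out"
  config$eval$n_val_per_class <- config$eval$n_val_per_class %||% 2L
  config$eval$threshold <- config$eval$threshold %||% 0.5
  config$eval$level <- config$eval$level %||% 0.95
  config$eval$ci_method <- config$eval$ci_method %||% "delong"
  config
}

#' Read a run configuration from YAML
#'
#' @param path YAML file.
#' @return validated configuration list.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  validate_run_config(yaml::read_yaml(path))
}

# Apply dot-path overrides such as "train.epochs=1".
apply_overrides <- function(config, overrides) {
  for (ov in overrides) {
    kv <- regmatches(ov, regexpr("=", ov), invert = TRUE)[[1]]
    if (length(kv) != 2L) {
      stop("override must have the form key.path=value: ", ov, call. = FALSE)
    }
    path <- strsplit(kv[1], ".", fixed = TRUE)[[1]]
    val <- utils::type.convert(kv[2], as.is = TRUE)
    # create missing intermediate sections so overrides can introduce keys
    if (length(path) > 1L) {
      for (d in seq_len(length(path) - 1L)) {
        if (is.null(config[[path[seq_len(d)]]])) {
          config[[path[seq_len(d)]]] <- list()
        }
      }
    }
    config[[path]] <- val
  }
  config
}

build_configs <- function(config) {
  list(
    phantom = do.call(phantom_config,
                      utils::modifyList(list(seed = config$seed),
                                        config$phantom)),
    backbone = do.call(backbone_config, config$backbone),
    rl = do.call(ppo_config,
                 config$rl[setdiff(names(config$rl), "enabled")]),
    train = do.call(train_config,
                    utils::modifyList(list(seed = config$seed),
                                      config$train)),
    augment = {
      pp <- config$preprocess
      if (isFALSE(pp$augment_enabled)) NULL else {
        do.call(augment_config,
                pp[setdiff(names(pp), c("balance", "augment_enabled"))])
      }
    },
    rl_enabled = !isFALSE(config$rl$enabled),
    balance = !isFALSE(config$preprocess$balance)
  )
}

write_run_artifacts <- function(config, out, produced) {
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  resolved <- file.path(out, "resolved_config.yaml")
  yaml::write_yaml(config, resolved)
  manifest <- file.path(out, "run_manifest.json")
  jsonlite::write_json(
    list(config_hash = config_hash(config),
         artifacts = as.list(produced)),
    manifest, auto_unbox = TRUE, pretty = TRUE)
  c(produced, resolved_config = resolved, run_manifest = manifest)
}

#' Execute a reproducible run
#'
#' Binds phantom generation, training, evaluation and explanation into one
#' entry point.  Every run writes a resolved copy of its configuration and
#' a machine-readable manifest of produced files (stamped with the config
#' hash) into the output directory; identical configuration and seed give
#' identical metrics on the deterministic paths.
#'
#' @param command one of `"generate"`, `"train"`, `"evaluate"`,
#'   `"explain"`.
#' @param config a validated configuration list, or a path to a YAML file.
#' @param overrides character vector of dot-path overrides, e.g.
#'   `"train.epochs=1"`.
#' @param data path to a cohort manifest CSV (defaults to the one produced
#'   by `generate` in the output directory).
#' @param checkpoint path to a model checkpoint (defaults to the one
#'   produced by `train`).
#' @param out output directory (defaults to `output_dir` in the config).
#' @param verbose print progress.
#' @return named character vector of produced artifact paths, invisibly.
#' @export
drlroi_run <- function(command = c("generate", "train", "evaluate", "explain"),
                       config = list(), overrides = character(),
                       data = NULL, checkpoint = NULL, out = NULL,
                       verbose = FALSE) {
  command <- match.arg(command)
  if (is.character(config)) config <- read_run_config(config)
  config <- validate_run_config(apply_overrides(config, overrides))
  out <- out %||% config$output_dir
  cc <- build_configs(config)
  data <- data %||% config$data %||% file.path(out, "cohort", "manifest.csv")
  checkpoint <- checkpoint %||% config$checkpoint %||%
    file.path(out, "checkpoint.rds")

  produced <- character()
  if (command == "generate") {
    cohort <- phantom_cohort(cc$phantom)
    man <- write_cohort(cohort, file.path(out, "cohort"))
    produced <- c(cohort_manifest = man)
  } else if (command == "train") {
    cohort <- preprocess_cohort(read_cohort(data),
                                window = cc$backbone$input_size)
    sp <- split_cohort(cohort, config$eval$n_val_per_class,
                       seed = config$seed)
    fit <- drlroi_fit(sp$train, backbone = cc$backbone, rl = cc$rl,
                      train = cc$train, augment = cc$augment,
                      rl_enabled = cc$rl_enabled, balance = cc$balance,
                      verbose = verbose)
    dir.create(out, recursive = TRUE, showWarnings = FALSE)
    drlroi_checkpoint(fit, checkpoint)
    hist_path <- file.path(out, "history.csv")
    utils::write.csv(fit$history, hist_path, row.names = FALSE)
    produced <- c(checkpoint = checkpoint, history = hist_path)
  } else if (command == "evaluate") {
    fit <- drlroi_restore(checkpoint)
    cohort <- preprocess_cohort(read_cohort(data),
                                window = fit$backbone_config$input_size)
    sp <- split_cohort(cohort, config$eval$n_val_per_class,
                       seed = config$seed)
    rep <- eval_report(fit, sp$val, threshold = config$eval$threshold,
                       level = config$eval$level,
                       ci_method = config$eval$ci_method)
    dir.create(out, recursive = TRUE, showWarnings = FALSE)
    rep_path <- file.path(out, "eval_report.json")
    jsonlite::write_json(
      list(patient = rep$patient[c("accuracy", "sensitivity", "specificity",
                                   "auc")],
           patient_auc_ci = as.list(rep$patient$auc_ci),
           slice_auc = rep$slice$auc,
           config_hash = config_hash(config)),
      rep_path, auto_unbox = TRUE, pretty = TRUE, digits = NA)
    roc_path <- file.path(out, "roc_points.csv")
    utils::write.csv(rep$patient$roc, roc_path, row.names = FALSE)
    produced <- c(eval_report = rep_path, roc_points = roc_path)
  } else if (command == "explain") {
    fit <- drlroi_restore(checkpoint)
    cohort <- preprocess_cohort(read_cohort(data),
                                window = fit$backbone_config$input_size)
    cam_dir <- file.path(out, "cam")
    dir.create(cam_dir, recursive = TRUE, showWarnings = FALSE)
    n_show <- min(8L, length(cohort$samples))
    paths <- vapply(seq_len(n_show), function(i) {
      s <- cohort$samples[[i]]
      cam <- drlroi_cam(fit, s)
      overlay <- clip01(0.6 * s$image + 0.4 * cam$cam)
      p <- file.path(cam_dir, paste0(s$slice_id, "_cam.png"))
      png::writePNG(overlay, p)
      p
    }, "")
    produced <- c(cam_dir = cam_dir)
  }
  invisible(write_run_artifacts(config, out, produced))
}
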