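# Archives, manifests and the command-line entry point.
#
# A dataset archive is one directory with an RDS array archive per split
# (keys: depth, pressure, posture, subject_id, calibration_kpa, mass_kg) and
# a JSON manifest recording the seed, generation parameters and split map,
# sufficient to regenerate the directory.

.archive_keys <- c("depth", "pressure", "posture", "subject_id",
                   "calibration_kpa", "mass_kg")

# stable hash of a configuration list (recorded in every output artifact)
config_hash <- function(x) {
  s <- jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA, force = TRUE)
  h <- 0
  for (ch in utf8ToInt(as.character(s))) h <- (h * 131 + ch) %% 2147483647
  sprintf("%08x", as.integer(h))
}

#' Write a synthetic dataset to an archive directory
#'
#' @param dataset a `synthetic_dataset`
#' @param path directory to create/populate
#' @return `path`, invisibly
#' @export
write_archive <- function(dataset, path) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  for (sp in c("train", "val", "test")) {
    ss <- split_samples(dataset, sp)
    payload <- list(
      depth = lapply(ss, `[[`, "depth"),
      pressure = lapply(ss, `[[`, "pressure"),
      posture = vapply(ss, `[[`, character(1), "posture"),
      subject_id = vapply(ss, `[[`, character(1), "subject_id"),
      calibration_kpa = vapply(ss, `[[`, numeric(1), "calibration_kpa"),
      mass_kg = vapply(ss, `[[`, numeric(1), "mass_kg"))
    saveRDS(payload, file.path(path, paste0(sp, ".rds")))
  }
  manifest <- list(seed = dataset$seed, params = dataset$params,
                   split = as.list(dataset$split),
                   config_hash = config_hash(dataset$params),
                   package_version = as.character(utils::packageVersion("attnfnet")))
  jsonlite::write_json(manifest, file.path(path, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a dataset archive written by [write_archive()]
#'
#' Validates the schema (required keys, pressure-grid orientation) and
#' reconstructs a `synthetic_dataset`.
#'
#' @param path archive directory
#' @return a `synthetic_dataset`
#' @export
read_archive <- function(path) {
  mf <- file.path(path, "manifest.json")
  if (!file.exists(mf)) {
    afn_stop(sprintf("no manifest.json under '%s'", path), "afn_schema_error")
  }
  manifest <- jsonlite::read_json(mf, simplifyVector = TRUE)
  samples <- list()
  split <- character()
  for (sp in c("train", "val", "test")) {
    f <- file.path(path, paste0(sp, ".rds"))
    if (!file.exists(f)) afn_stop(sprintf("missing %s.rds", sp), "afn_schema_error")
    payload <- tryCatch(readRDS(f), error = function(e) {
      afn_stop(sprintf("unreadable archive file %s.rds: %s", sp,
                       conditionMessage(e)), "afn_schema_error")
    })
    miss <- setdiff(.archive_keys, names(payload))
    if (length(miss) > 0) {
      afn_stop(sprintf("archive %s.rds missing key(s): %s", sp,
                       paste(miss, collapse = ", ")), "afn_schema_error")
    }
    for (i in seq_along(payload$depth)) {
      pr <- payload$pressure[[i]]
      if (nrow(pr) == 64 && ncol(pr) == 27) {
        afn_stop(paste0("pressure grid in ", sp, ".rds sample ", i,
                        " is 64x27: transposed relative to the package ",
                        "convention (27 rows = bed width, 64 columns = bed ",
                        "length, column 1 at the head end)"),
                 "afn_orientation_error")
      }
      if (!all(dim(pr) == c(27, 64))) {
        afn_stop(sprintf("pressure grid in %s.rds sample %d has shape %dx%d, expected 27x64",
                         sp, i, nrow(pr), ncol(pr)), "afn_schema_error")
      }
      samples[[length(samples) + 1L]] <- structure(list(
        depth = payload$depth[[i]], pressure = pr,
        posture = payload$posture[i], subject_id = payload$subject_id[i],
        calibration_kpa = payload$calibration_kpa[i],
        mass_kg = payload$mass_kg[i]), class = "paired_sample")
      split[payload$subject_id[i]] <- sp
    }
  }
  structure(list(samples = samples, split = split,
                 params = manifest$params, seed = manifest$seed),
            class = "synthetic_dataset")
}

#' Save / load a model checkpoint
#'
#' A checkpoint is a parameter archive (RDS) plus a JSON spec sidecar (all
#' architecture fields, seed and config hash) so any checkpoint is
#' reconstructable.
#'
#' @param model generator or discriminator object
#' @param path file path without extension
#' @return `path`, invisibly
#' @export
save_checkpoint <- function(model, path) {
  dir.create(dirname(path), showWarnings = FALSE, recursive = TRUE)
  saveRDS(model$params, paste0(path, ".rds"))
  spec <- unclass(model$spec)
  jsonlite::write_json(list(class = class(model)[1], spec = spec,
                            seed = model$seed,
                            config_hash = config_hash(spec)),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  params <- readRDS(paste0(path, ".rds"))
  spec <- meta$spec
  cls <- meta$class
  spec_class <- switch(cls,
    attnfnet_generator = "generator_spec",
    patchgan_discriminator = "discriminator_spec",
    unet_generator = "unet_spec",
    afn_stop("unknown checkpoint class", "afn_schema_error"))
  class(spec) <- spec_class
  structure(list(spec = spec, params = params, seed = meta$seed), class = cls)
}

.log_line <- function(stage, msg) {
  cat(sprintf("[%s] %s  %s\n", format(Sys.time(), "%H:%M:%S"), stage, msg))
}

#' Command-line entry point
#'
#' Subcommands: `simulate`, `train`, `evaluate`, `predict`, `report`. Each
#' reads dotted `--key value` flags (and optionally `--config file.yaml`
#' whose sections the flags override) and writes its outputs under `--out`
#' together with a manifest carrying the configuration hash. See the package
#' README for examples; `inst/cli/attnfnet.R` is a thin Rscript wrapper.
#'
#' @param argv character vector of arguments (e.g. `commandArgs(TRUE)`)
#' @return exit status, invisibly (0 on success)
#' @export
attnfnet_cli <- function(argv) {
  if (length(argv) == 0) {
    cat("usage: attnfnet <simulate|train|evaluate|predict|report> [--flag value ...]\n")
    return(invisible(1L))
  }
  cmd <- argv[1]
  flags <- list()
  i <- 2L
  while (i <= length(argv)) {
    if (!startsWith(argv[i], "--")) {
      message("unknown positional argument: ", argv[i])
      return(invisible(2L))
    }
    key <- sub("^--", "", argv[i])
    flags[[key]] <- if (i + 1L <= length(argv)) argv[i + 1L] else ""
    i <- i + 2L
  }
  if (!is.null(flags$config)) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      message("--config requires the 'yaml' package")
      return(invisible(2L))
    }
    cfgf <- yaml::read_yaml(flags$config)
    for (k in names(cfgf)) if (is.null(flags[[k]])) flags[[k]] <- cfgf[[k]]
  }
  num <- function(k, d) if (is.null(flags[[k]])) d else as.numeric(flags[[k]])
  chr <- function(k, d) if (is.null(flags[[k]])) d else as.character(flags[[k]])
  out <- chr("out", "attnfnet_out")
  seed <- as.integer(num("seed", 1))
  res <- tryCatch({
    switch(cmd,
      simulate = {
        ds <- generate_dataset(n_subjects = as.integer(num("n-subjects", 8)),
                               poses_per_subject = as.integer(num("poses", 6)),
                               seed = seed)
        write_archive(ds, out)
        .log_line("simulate", sprintf("wrote %d samples to %s",
                                      length(ds$samples), out))
        0L
      },
      train = {
        preset <- tiny_preset(seed = seed, variant = chr("variant", "attnfnet"))
        ds <- if (!is.null(flags$data)) read_archive(flags$data)
              else do.call(generate_dataset, preset$data_args)
        preset$train_cfg$epochs <- as.integer(num("epochs",
                                                  preset$train_cfg$epochs))
        fitres <- fit_cgan(ds, preset$train_cfg, preset$loss_cfg,
                           preset$gen_spec, preset$disc_spec,
                           preset$pp_config, verbose = TRUE)
        dir.create(out, showWarnings = FALSE, recursive = TRUE)
        utils::write.csv(fitres$history, file.path(out, "history.csv"),
                         row.names = FALSE)
        save_checkpoint(fitres$G, file.path(out, "generator_final"))
        save_checkpoint(fitres$G_best, file.path(out, "generator_best"))
        save_checkpoint(fitres$D, file.path(out, "discriminator"))
        jsonlite::write_json(
          list(seed = seed, variant = preset$train_cfg$variant,
               config_hash = config_hash(unclass(preset$train_cfg)),
               epochs = preset$train_cfg$epochs),
          file.path(out, "manifest.json"), auto_unbox = TRUE, pretty = TRUE)
        .log_line("train", sprintf("final val MSE %.6f",
                                   utils::tail(fitres$history$val_mse, 1)))
        0L
      },
      evaluate = {
        preset <- tiny_preset(seed = seed)
        ds <- if (!is.null(flags$data)) read_archive(flags$data)
              else do.call(generate_dataset, preset$data_args)
        G <- load_checkpoint(chr("checkpoint", stop("--checkpoint required")))
        prepared <- prepare_training_data(ds, preset$pp_config)
        rep <- evaluate_model(G, prepared)
        dir.create(out, showWarnings = FALSE, recursive = TRUE)
        utils::write.csv(rep$per_sample, file.path(out, "per_sample.csv"),
                         row.names = FALSE)
        jsonlite::write_json(rep$aggregates, file.path(out, "aggregates.json"),
                             auto_unbox = TRUE, digits = NA, pretty = TRUE)
        print(rep)
        0L
      },
      {
        message("unknown subcommand: ", cmd)
        2L
      })
  }, attnfnet_error = function(e) {
    message("error: ", conditionMessage(e))
    1L
  })
  invisible(res)
}
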