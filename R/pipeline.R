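# Pipeline orchestration: generate -> morphometry -> simulate -> train ->
# predict -> evaluate, driven by one YAML/list config with a master seed.

#' Default pipeline configuration
#'
#' Desk-scale defaults: small grids (48^3 native, 2x partial-volume
#' coarsening for simulation) and a few hundred VOIs, so a full run finishes
#' in minutes on one CPU.  Full-scale settings (123^3 VOIs, tens of
#' thousands of samples) are reachable by editing the returned list or the
#' YAML equivalent.
#'
#' @param out_dir output directory for all artifacts.
#' @param seed master seed; every stochastic stage derives its seed from it.
#' @return Nested configuration list.
#' @export
default_config <- function(out_dir = "vsdmri_run", seed = 1L) {
  list(
    seed = as.integer(seed),
    out_dir = out_dir,
    stages = list(generate = TRUE, train = TRUE, evaluate = TRUE),
    generate = list(n_voi = 300L, grid_shape = c(48L, 48L, 48L),
                    voxel_size = 1.8, downsample = 2L,
                    cbv_range = c(0.015, 0.38), branch_prob = 0.2,
                    radius_min = 1.8, radius_max = 20,
                    radius_meanlog = log(5), radius_sdlog = 0.5,
                    n_tubes_max = 400L),
    simulate = list(B0 = 3, delta_chi = 1e-6, chi_convention = "si_ppm",
                    D = 1e-3, dt_max = 5e-4, refocus_time = 0.060),
    train = list(max_epochs = 60L, patience = 20L, batch_size = 256L,
                 lr = 1e-4),
    evaluate = list(snr_db = c(15, 30, 45, 60))
  )
}

#' Read a pipeline configuration from YAML
#'
#' Fields missing from the file fall back to [default_config()] values.
#'
#' @param path YAML file.
#' @return Configuration list.
#' @export
read_config <- function(path) {
  user <- yaml::read_yaml(path)
  merge_cfg <- function(base, over) {
    for (nm in names(over)) {
      base[[nm]] <- if (is.list(base[[nm]]) && is.list(over[[nm]]))
        merge_cfg(base[[nm]], over[[nm]]) else over[[nm]]
    }
    base
  }
  merge_cfg(default_config(), user)
}

cfg_sim <- function(config) {
  s <- config$simulate
  sim_config(B0 = s$B0, delta_chi = s$delta_chi,
             chi_convention = s$chi_convention, D = s$D, dt_max = s$dt_max,
             refocus_time = s$refocus_time)
}

cfg_sampler <- function(config) {
  g <- config$generate
  radius_sampler(meanlog = g$radius_meanlog, sdlog = g$radius_sdlog,
                 min = g$radius_min, max = g$radius_max)
}

#' Run the full pipeline
#'
#' Executes the enabled stages in order -- dataset generation + simulation,
#' two-stage training, evaluation against the dictionary baseline and under
#' noise -- and writes a manifest listing every output file with its MD5
#' checksum and the configuration hash.  A failed stage aborts with the
#' stage name; partial outputs are retained.
#'
#' @param config list from [default_config()] or [read_config()].
#' @return The manifest (invisibly written as `manifest.json`).
#' @export
run_pipeline <- function(config = default_config()) {
  out <- config$out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE))
  }
  ds_dir <- file.path(out, "dataset")
  model_path <- file.path(out, "models.rds")

  if (isTRUE(config$stages$generate)) {
    dsim <- stage("generate", {
      g <- config$generate
      simulate_dataset(g$n_voi,
                       grid = voxel_grid(g$grid_shape, g$voxel_size),
                       downsample = g$downsample, cbv_range = g$cbv_range,
                       sampler = cfg_sampler(config), cfg = cfg_sim(config),
                       seed = config$seed, n_tubes_max = g$n_tubes_max,
                       branch_prob = g$branch_prob)
    })
    files <- c(files, write_dataset_csv(dsim, ds_dir))
  } else {
    if (!file.exists(file.path(ds_dir, "signals.csv")))
      stop("pipeline stage 'train' missing input: ",
           file.path(ds_dir, "signals.csv"),
           " (generate stage disabled and no dataset present)")
    dsim <- read_dataset_csv(ds_dir)
  }

  ds <- filter_and_split(dsim$signals, dsim$cbv, dsim$vsd,
                         seed = config$seed)
  if (isTRUE(config$stages$train)) {
    models <- stage("train", {
      t <- config$train
      spec <- model_spec(lr = t$lr, batch_size = t$batch_size,
                         max_epochs = t$max_epochs, patience = t$patience)
      train_two_stage(ds, spec, seed = config$seed)
    })
    save_model_pair(models, model_path)
    files <- c(files, model_path, paste0(model_path, ".json"))
    hist <- do.call(rbind, lapply(names(models$training_history), function(nm)
      cbind(stage = nm, models$training_history[[nm]])))
    hist_path <- file.path(out, "training_log.csv")
    write.csv(hist, hist_path, row.names = FALSE)
    files <- c(files, hist_path)
  } else if (isTRUE(config$stages$evaluate)) {
    if (!file.exists(model_path))
      stop("pipeline stage 'evaluate' missing input: ", model_path,
           " (train stage disabled and no checkpoint present)")
    models <- load_model_pair(model_path)
  }

  metrics_path <- file.path(out, "metrics.json")
  if (isTRUE(config$stages$evaluate)) {
    metrics <- stage("evaluate", {
      te <- ds_part(ds, "test")
      tr <- ds_part(ds, "train")
      pred <- predict(models, te$X)
      dl <- metrics_report(te$cbv, pred$cbv, te$vsd, pred$vsd)
      dict <- signal_dictionary(tr$X, tr$cbv, tr$vsd)
      dm <- dictionary_match(te$X, dict)
      base <- metrics_report(te$cbv, dm$cbv, te$vsd, dm$vsd)
      noise <- lapply(config$evaluate$snr_db, function(snr) {
        noisy <- add_noise(te$X, snr, seed = config$seed + round(snr))
        p <- predict(models, noisy)
        m <- metrics_report(te$cbv, p$cbv, te$vsd, p$vsd)
        list(snr_db = snr, pearson_r = m$pearson_r,
             mre_percent = m$mre_percent, bc_mean = m$bc_mean)
      })
      list(dl = dl[c("pearson_r", "mre_percent", "bc_mean", "bc_sd")],
           dictionary = base[c("pearson_r", "mre_percent", "bc_mean",
                               "bc_sd")],
           noise = noise)
    })
    jsonlite::write_json(metrics, metrics_path, auto_unbox = TRUE,
                         digits = NA)
    files <- c(files, metrics_path)
  }

  manifest <- list(
    config = config,
    config_hash = digest_obj(config),
    files = lapply(unname(files), function(f)
      list(path = f, md5 = unname(tools::md5sum(f)))))
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}
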