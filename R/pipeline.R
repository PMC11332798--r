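#' Default configuration for an end-to-end run
#'
#' One global seed fans out into named substreams (generation, splitting,
#' weight init, epoch shuffling, explanation sampling), so a single integer
#' reproduces the whole run.
#'
#' @param n_per_class synthetic images per class.
#' @param image_size smear canvas side in pixels.
#' @param target_size crop side fed to the network.
#' @param epochs,batch_size,learning_rate training regime.
#' @param train,val,test split fractions.
#' @param n_explain test images explained per class.
#' @param seed global seed.
#' @return a nested configuration list of class `wbc_run_config`.
#' @export
run_config <- function(n_per_class = 20, image_size = 120, target_size = 48,
                       epochs = 2, batch_size = 64, learning_rate = 1e-3,
                       train = 0.7, val = 0.15, test = 0.15,
                       n_explain = 1, seed = 1) {
  structure(list(n_per_class = n_per_class, image_size = image_size,
                 target_size = target_size, epochs = epochs,
                 batch_size = batch_size, learning_rate = learning_rate,
                 train = train, val = val, test = test,
                 n_explain = n_explain, seed = seed),
            class = "wbc_run_config")
}

#' Read a run configuration from a YAML file
#'
#' Unknown keys are rejected; missing keys take the [run_config()] defaults.
#'
#' @param path YAML file.
#' @return a `wbc_run_config`.
#' @export
load_run_config <- function(path) {
  vals <- yaml::read_yaml(path)
  defaults <- run_config()
  bad <- setdiff(names(vals), names(defaults))
  if (length(bad) > 0)
    stop_wbc("wbc_config_error", "unknown config keys: %s",
             paste(bad, collapse = ", "))
  cfg <- utils::modifyList(unclass(defaults), vals)
  class(cfg) <- "wbc_run_config"
  cfg
}

run_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    stop_wbc("wbc_stage_error", "stage '%s' failed: %s", stage,
             conditionMessage(e))
  })
}

#' Run the full pipeline: generate, preprocess, split, train, evaluate,
#' explain
#'
#' Executes the four-stage flow (data, pre-processing, model, explanation)
#' under one output directory with a machine-readable provenance file
#' (config, seed, package version). The evaluation report is free of
#' timestamps, so the same config and seed reproduce it bit for bit.
#'
#' @param config a [run_config()].
#' @param out_dir output directory for the run.
#' @return invisibly, a list with the run directory, the fitted `wbc_net`,
#'   and the `wbc_eval_report`.
#' @export
run_end_to_end <- function(config = run_config(), out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- config$seed
  spec <- smear_spec(image_size = config$image_size)
  pcfg <- pipeline_config(target_size = config$target_size)

  manifest <- run_stage("generate",
    generate_dataset(config$n_per_class, spec, file.path(out_dir, "data"),
                     seed = derive_seed(seed, "generate")))

  log_path <- file.path(out_dir, "preprocess.log")
  proc_dir <- file.path(out_dir, "processed")
  manifest$processed <- NA_character_
  run_stage("preprocess", {
    lines <- character(0)
    for (i in seq_len(nrow(manifest))) {
      img <- read_image(manifest$path[i])
      sg <- run_pipeline(img, pcfg, id = manifest$path[i])
      dst <- file.path(proc_dir, basename(dirname(manifest$path[i])),
                       basename(manifest$path[i]))
      write_image(sg$cell_image, dst)
      manifest$processed[i] <- dst
      lines <- c(lines, sprintf("%s\t%s", manifest$path[i], sg$status))
    }
    writeLines(lines, log_path)
  })

  splits <- run_stage("split",
    stratified_split(manifest, split_plan(config$train, config$val, config$test,
                                          seed = derive_seed(seed, "split"))))

  load_set <- function(m) {
    x <- array(0, c(config$target_size, config$target_size, 3, nrow(m)))
    for (i in seq_len(nrow(m))) x[, , , i] <- read_image(m$processed[i]) / 255
    list(x = x, y = m$label)
  }

  fit <- run_stage("train", {
    tr <- load_set(splits$train); va <- load_set(splits$val)
    net <- build_network(scaled_network_spec(config$target_size),
                         seed = derive_seed(seed, "init"))
    train_network(net, tr$x, tr$y, va$x, va$y,
                  training_params(learning_rate = config$learning_rate,
                                  batch_size = config$batch_size,
                                  epochs = config$epochs,
                                  seed = derive_seed(seed, "train")))
  })
  saveRDS(fit, file.path(out_dir, "model.rds"))
  jsonlite::write_json(fit$network$spec, file.path(out_dir, "architecture.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  write.csv(fit$history, file.path(out_dir, "history.csv"), row.names = FALSE)

  report <- run_stage("evaluate", {
    te <- load_set(splits$test)
    ev <- evaluate_network(fit, te$x, te$y)
    write.csv(ev$confusion, file.path(out_dir, "confusion.csv"))
    write.csv(ev$metrics$per_class, file.path(out_dir, "per_class.csv"),
              row.names = FALSE)
    jsonlite::write_json(
      list(accuracy = ev$metrics$accuracy,
           macro_precision = ev$metrics$macro_precision,
           macro_recall = ev$metrics$macro_recall,
           macro_f1 = ev$metrics$macro_f1,
           macro_auc = ev$roc$macro_auc,
           confusion = ev$confusion,
           per_class = ev$metrics$per_class),
      file.path(out_dir, "report.json"), auto_unbox = TRUE, digits = NA)
    ev
  })

  run_stage("explain", {
    ex_dir <- file.path(out_dir, "explanations")
    dir.create(ex_dir, showWarnings = FALSE)
    pf <- function(batch) predict(fit, batch, type = "prob")
    for (lab in 0:3) {
      rows <- which(splits$test$label == lab)
      rows <- utils::head(rows, config$n_explain)
      for (i in rows) {
        img <- read_image(splits$test$processed[i]) / 255
        stem <- sprintf("%s_%s", wbc_classes()[lab + 1],
                        sub("\\.png$", "", basename(splits$test$processed[i])))
        gc1 <- grad_cam(fit, img, lab)
        gc2 <- grad_cam_pp(fit, img, lab)
        lm <- lime_explain(pf, img, lab, superpixel_plan(n_segments = 16),
                           n_samples = 64, seed = derive_seed(seed, "explain", i))
        ks <- kernel_shap(pf, img, lab, superpixel_plan(n_segments = 8),
                          seed = derive_seed(seed, "explain", i))
        for (att in list(gc1, gc2, lm, ks))
          write_image(render_overlay(img, att) * 255,
                      file.path(ex_dir, sprintf("%s_%s.png", stem, att$method)))
        jsonlite::write_json(
          list(image = splits$test$processed[i], label = lab,
               lime_weights = lm$weights, shap_values = ks$weights),
          file.path(ex_dir, sprintf("%s_weights.json", stem)),
          auto_unbox = TRUE, digits = NA)
      }
    }
  })

  jsonlite::write_json(
    list(package = "wbcnet",
         version = as.character(utils::packageVersion("wbcnet")),
         config = unclass(config), seed = seed),
    file.path(out_dir, "provenance.json"), auto_unbox = TRUE, digits = NA)
  invisible(list(dir = out_dir, fit = fit, report = report))
}
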