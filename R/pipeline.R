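#' Pipeline configuration
#'
#' A single nested list drives the end-to-end pipeline; every stochastic
#' stage has an explicit seed. Unknown keys are rejected so typos fail
#' early. The defaults reproduce the full-scale study conditions; the
#' `scale` arguments are what a desk-scale run would shrink (grid sizes,
#' augmentation step, epochs).
#'
#' @param ... Named overrides of the default fields (nested lists are
#'   merged).
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(...) {
  defaults <- list(
    workdir = NULL, # NULL = no artifact caching
    seed = 1L,
    noise = list(absorption_sd = 0.002, eem_sd = 2),
    simulate = list(ife = TRUE, scatter = TRUE),
    preprocess = list(upsample_side = 2217L, augment_step = 0.01,
                      test_n = 1000L, scatter_k = 3),
    gabor = list(lams = c(3, 6, 9, 12, 15),
                 thetas = c(0, pi / 12, pi / 8, pi / 6, pi / 4, pi / 3, 3 * pi / 8),
                 psi = 0, sigma = 2 * pi, gamma = 0.5, feature_side = 554L),
    dimred = list(method = "Isomap", n_components = 20L, n_neighbors = 10L,
                  n_keep = 32L),
    net = list(hidden = 175L, dropout = 0.5),
    train = list(lr0 = 1e-3, decay = 0.96, cycles = 3L, epochs_per_cycle = 50L,
                 batch_size = 32L, val_fraction = 0.1)
  )
  overrides <- list(...)
  unknown <- setdiff(names(overrides), names(defaults))
  if (length(unknown) > 0) {
    abort(paste0("unknown config keys: ", paste(unknown, collapse = ", ")))
  }
  for (nm in names(overrides)) {
    if (is.list(defaults[[nm]]) && is.list(overrides[[nm]])) {
      bad <- setdiff(names(overrides[[nm]]), names(defaults[[nm]]))
      if (length(bad) > 0) {
        abort(paste0("unknown config keys in ", nm, ": ",
                     paste(bad, collapse = ", ")))
      }
      defaults[[nm]] <- modifyList(defaults[[nm]], overrides[[nm]])
    } else {
      defaults[[nm]] <- overrides[[nm]]
    }
  }
  structure(defaults, class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file whose top-level keys match [pipeline_config()].
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  fields <- yaml::read_yaml(path)
  do.call(pipeline_config, as.list(fields))
}

# order-independent hash of a config (recursively sorts keys, then md5)
config_hash <- function(config) {
  canonical <- function(x) {
    if (is.list(x)) {
      if (!is.null(names(x))) x <- x[order(names(x))]
      lapply(x, canonical)
    } else x
  }
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(canonical(unclass(config)), tmp, auto_unbox = TRUE,
                       digits = NA)
  unname(tools::md5sum(tmp))
}

stage_log <- function(stage, msg) {
  message(sprintf("[%s] %s", stage, msg))
}

cache_path <- function(config, stage) {
  if (is.null(config$workdir)) return(NULL)
  dir.create(config$workdir, showWarnings = FALSE, recursive = TRUE)
  file.path(config$workdir, paste0(stage, "-", config_hash(config), ".rds"))
}

run_stage <- function(config, stage, fun) {
  cp <- cache_path(config, stage)
  if (!is.null(cp) && file.exists(cp)) {
    stage_log(stage, "reusing cached artifact")
    return(list(value = readRDS(cp), seconds = 0, cached = TRUE))
  }
  t0 <- proc.time()[["elapsed"]]
  value <- tryCatch(fun(), error = function(e) {
    abort(sprintf("stage '%s' failed: %s", stage, conditionMessage(e)))
  })
  secs <- proc.time()[["elapsed"]] - t0
  stage_log(stage, sprintf("done in %.1f s", secs))
  if (!is.null(cp)) {
    tmp <- paste0(cp, ".tmp"); saveRDS(value, tmp); file.rename(tmp, cp)
  }
  list(value = value, seconds = secs, cached = FALSE)
}

#' Run the end-to-end COD retrieval pipeline
#'
#' Executes the fixed stage order: simulate the design dataset, preprocess
#' the EEMs (scatter removal from a blank, cubic-spline upsampling) and the
#' absorption dataset (label-grid augmentation, test split), extract Gabor
#' features, reduce them to fluorescence feature blocks, pair the blocks
#' with the augmented spectra, train the fusion network, and evaluate on
#' the held-out test set. With a `workdir`, deterministic stage artifacts
#' are cached keyed by the config hash, so a rerun resumes.
#'
#' @param config A [pipeline_config()].
#' @param design Optional design tibble; defaults to the packaged design.
#' @return An object of class `run_record`: list with `config`,
#'   `config_hash`, `stages` (tibble of timings), `metrics`
#'   (`retrieval_metrics` on the test split), `fit` (the `fusion_fit`) and
#'   `package_version`.
#' @export
run_pipeline <- function(config = pipeline_config(), design = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  stages <- list()
  tick <- function(stage, res) {
    stages[[stage]] <<- tibble::tibble(stage = stage, seconds = res$seconds,
                                       cached = res$cached)
    res$value
  }
  sim <- tick("simulate", run_stage(config, "simulate", function() {
    design <- design %||% mixture_design()
    generate_design_dataset(design,
                            noise = noise_spec(config$noise$absorption_sd,
                                               config$seed),
                            eem_noise = noise_spec(config$noise$eem_sd,
                                                   config$seed),
                            ife = config$simulate$ife,
                            scatter = config$simulate$scatter)
  }))
  pre <- tick("preprocess", run_stage(config, "preprocess", function() {
    blank <- simulate_blank(scatter = config$simulate$scatter,
                            noise = noise_spec(config$noise$eem_sd, config$seed))
    bands <- detect_scatter_bands(blank, k = config$preprocess$scatter_k)
    eems <- lapply(sim$eems, function(e) {
      upsample_eem(remove_scatter(e, bands),
                   out_side = config$preprocess$upsample_side)
    })
    aug <- augment_absorption(sim$spectra, step = config$preprocess$augment_step)
    split <- split_test(aug, n = config$preprocess$test_n, seed = config$seed)
    list(eems = eems, bands = bands, split = split)
  }))
  feats <- tick("features", run_stage(config, "features", function() {
    bank <- gabor_bank(config$gabor$lams, config$gabor$thetas,
                       config$gabor$psi, config$gabor$sigma, config$gabor$gamma)
    lapply(pre$eems, function(e) {
      flatten_features(apply_bank(e, bank,
                                  feature_side = config$gabor$feature_side))
    })
  }))
  blocks <- tick("reduce", run_stage(config, "reduce", function() {
    n_kernels <- ncol(feats[[1]])
    n_keep <- min(config$dimred$n_keep, n_kernels)
    n_el <- config$dimred$n_components * n_keep
    block_rows <- if (n_el %% 128L == 0L) n_el %/% 128L else 1L
    lapply(feats, function(f) {
      select_and_reshape(reduce_features(f, config$dimred$method,
                                         config$dimred$n_components,
                                         seed = config$seed,
                                         n_neighbors = config$dimred$n_neighbors),
                         n_keep = n_keep, block_rows = block_rows)
    })
  }))
  paired <- tick("pair", run_stage(config, "pair", function() {
    split <- pre$split
    labels <- sim$manifest$cod_label
    list(train = pair_fluorescence(split$train$cod_label, labels, blocks),
         test = pair_fluorescence(split$test$cod_label, labels, blocks))
  }))
  fit <- tick("train", run_stage(config, "train", function() {
    net <- build_fusion_net(input_len = ncol(pre$split$train$absorbance),
                            fluor_dim = dim(blocks[[1]]$matrix),
                            hidden = config$net$hidden,
                            dropout = config$net$dropout, seed = config$seed)
    cfg <- train_config(lr0 = config$train$lr0, decay = config$train$decay,
                        cycles = config$train$cycles,
                        epochs_per_cycle = config$train$epochs_per_cycle,
                        batch_size = config$train$batch_size,
                        val_fraction = config$train$val_fraction,
                        seed = config$seed)
    train_fusion(net, pre$split$train$absorbance, paired$train,
                 pre$split$train$cod_label, cfg)
  }))
  metrics <- tick("evaluate", run_stage(config, "evaluate", function() {
    pred <- predict(fit, pre$split$test$absorbance, paired$test)
    evaluate_retrieval(pred, pre$split$test$cod_label)
  }))
  structure(list(config = config, config_hash = config_hash(config),
                 stages = dplyr::bind_rows(stages), metrics = metrics,
                 fit = fit,
                 package_version = as.character(utils::packageVersion("codfusion"))),
            class = "run_record")
}

#' @export
print.run_record <- function(x, ...) {
  cat(sprintf("<run_record> config %s, %d stages\n", x$config_hash,
              nrow(x$stages)))
  print(x$stages)
  print(x$metrics)
  invisible(x)
}
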