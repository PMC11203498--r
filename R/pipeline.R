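# End-to-end orchestration: synthetic data -> vocabulary -> pre-training ->
# fine-tuning -> generation -> evaluation -> QSAR, driven by one nested
# config. Each stage writes its artifacts (plus an md5 manifest and a
# resolved-config copy) under the output directory; rerunning a stage with
# the same config and seed reproduces identical artifacts.

#' Default pipeline configuration
#'
#' Desk-scale settings: a 5,000-molecule synthetic corpus, a reduced model
#' (64-dimensional embeddings, 4 heads, 3 blocks), short pre-training, the
#' alternating fine-tuning schedule, 1,000 generated molecules per run at
#' temperature 1.5. Any field can be overridden through the YAML config
#' read by [run_pipeline()].
#'
#' @param seed Global seed; per-stage seeds derive from it.
#' @return Nested configuration list.
#' @export
default_pipeline_config <- function(seed = 1L) {
  list(
    seed = as.integer(seed),
    out_dir = "adaptmol_run",
    synth = list(corpus_n = 5000L, length_min = 6L, length_max = 24L,
                 bias = 6, noise_sd = 0.3),
    model = list(d_model = 64L, h = 4L, n_blocks = 3L, adapter_dim = 16L,
                 dropout = 0.1, max_len = 72L),
    pretrain = list(epochs = 5L, lr0 = 1e-4, decay = 0.95, batch_size = 256L),
    finetune = list(adapter_phase_len = 15L, main_phase_len = 10L,
                    max_epochs = 200L, patience = 5L, peak_lr = 1e-3,
                    warmup_epochs = 20L, cycle_len = 100L, n_cycles = 2L,
                    batch_size = 256L),
    generate = list(n = 1000L, temperature = 1.5, max_len = 72L),
    qsar = list(nrounds = 300L)
  )
}

.mg_merge_config <- function(base, override) {
  for (k in names(override)) {
    if (is.list(base[[k]]) && is.list(override[[k]])) {
      base[[k]] <- .mg_merge_config(base[[k]], override[[k]])
    } else {
      if (!k %in% names(base)) stop("unknown config key: ", k)
      base[[k]] <- override[[k]]
    }
  }
  base
}

#' Read a pipeline configuration file
#'
#' YAML (or JSON) overriding [default_pipeline_config()]; unknown keys are
#' rejected.
#'
#' @param path Config file path, or `NULL` for pure defaults.
#' @param seed Fallback seed when the file sets none.
#' @return Nested configuration list.
#' @export
read_pipeline_config <- function(path = NULL, seed = 1L) {
  cfg <- default_pipeline_config(seed)
  if (!is.null(path)) {
    cfg <- .mg_merge_config(cfg, yaml::read_yaml(path))
  }
  cfg
}

.mg_artifact <- function(cfg, name) file.path(cfg$out_dir, name)

.mg_require_artifact <- function(cfg, name, producer) {
  p <- .mg_artifact(cfg, name)
  if (!file.exists(p)) {
    stop("missing artifact '", name, "': run stage '", producer, "' first",
         call. = FALSE)
  }
  p
}

.mg_log <- function(cfg, stage, ...) {
  line <- jsonlite::toJSON(c(list(stage = stage), list(...)),
                           auto_unbox = TRUE)
  cat(line, "\n", sep = "", file = .mg_artifact(cfg, "log.jsonl"),
      append = TRUE)
}

#' Run the generation workflow
#'
#' Executes the requested stages in order. Stage artifacts (CSV datasets,
#' JSON vocabulary, model checkpoints, the evaluation report) are written
#' under `cfg$out_dir` together with a resolved-config copy and an md5
#' manifest. A missing upstream artifact is an error naming the stage to
#' run first.
#'
#' @param cfg Configuration list from [read_pipeline_config()].
#' @param stages Character subset of `"synth-data"`, `"build-vocab"`,
#'   `"pretrain"`, `"finetune"`, `"generate"`, `"evaluate"`, `"qsar"`.
#' @return (Invisibly) the evaluation report list, when computed.
#' @export
run_pipeline <- function(cfg = default_pipeline_config(),
                         stages = c("synth-data", "build-vocab", "pretrain",
                                    "finetune", "generate", "evaluate",
                                    "qsar")) {
  known <- c("synth-data", "build-vocab", "pretrain", "finetune", "generate",
             "evaluate", "qsar")
  stopifnot(all(stages %in% known))
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(cfg, .mg_artifact(cfg, "resolved_config.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  report <- NULL

  if ("synth-data" %in% stages) {
    corpus <- generate_corpus(cfg$synth$corpus_n,
                              c(cfg$synth$length_min, cfg$synth$length_max),
                              seed = cfg$seed + 100L)
    utils::write.csv(corpus, .mg_artifact(cfg, "corpus.csv"),
                     row.names = FALSE)
    targets <- generate_target_sets(target_profiles(cfg$synth$bias),
                                    c(cfg$synth$length_min, cfg$synth$length_max),
                                    noise_sd = cfg$synth$noise_sd,
                                    seed = cfg$seed + 200L)
    utils::write.csv(targets, .mg_artifact(cfg, "targets.csv"),
                     row.names = FALSE)
    .mg_log(cfg, "synth-data", corpus_n = nrow(corpus),
            targets_n = nrow(targets))
  }

  if ("build-vocab" %in% stages) {
    corpus <- utils::read.csv(.mg_require_artifact(cfg, "corpus.csv",
                                                   "synth-data"))
    vocab <- build_vocabulary(corpus$selfies)
    write_vocabulary(vocab, .mg_artifact(cfg, "vocab.json"))
    .mg_log(cfg, "build-vocab", vocab_size = vocab$n)
  }

  if ("pretrain" %in% stages) {
    corpus <- utils::read.csv(.mg_require_artifact(cfg, "corpus.csv",
                                                   "synth-data"))
    vocab <- read_vocabulary(.mg_require_artifact(cfg, "vocab.json",
                                                  "build-vocab"))
    mc <- model_config(vocab$n, d_model = cfg$model$d_model, h = cfg$model$h,
                       n_blocks = cfg$model$n_blocks,
                       adapter_dim = cfg$model$adapter_dim,
                       dropout = cfg$model$dropout,
                       max_len = cfg$model$max_len)
    model <- init_model(mc, vocab, seed = cfg$seed)
    fit <- pretrain(model, corpus,
                    pretrain_config(cfg$pretrain$epochs, cfg$pretrain$lr0,
                                    cfg$pretrain$decay,
                                    cfg$pretrain$batch_size),
                    seed = cfg$seed + 300L)
    save_checkpoint(fit$model, .mg_artifact(cfg, "pretrained.rds"))
    utils::write.csv(fit$history, .mg_artifact(cfg, "pretrain_history.csv"),
                     row.names = FALSE)
    .mg_log(cfg, "pretrain",
            final_loss = fit$history$train_loss[nrow(fit$history)])
  }

  if ("finetune" %in% stages) {
    targets <- utils::read.csv(.mg_require_artifact(cfg, "targets.csv",
                                                    "synth-data"))
    model <- load_checkpoint(.mg_require_artifact(cfg, "pretrained.rds",
                                                  "pretrain"))
    ft <- finetune(model, targets,
                   finetune_config(cfg$finetune$adapter_phase_len,
                                   cfg$finetune$main_phase_len,
                                   cfg$finetune$max_epochs,
                                   cfg$finetune$patience,
                                   cfg$finetune$peak_lr,
                                   cfg$finetune$warmup_epochs,
                                   cfg$finetune$cycle_len,
                                   cfg$finetune$n_cycles,
                                   cfg$finetune$batch_size),
                   seed = cfg$seed + 400L)
    save_checkpoint(ft$model, .mg_artifact(cfg, "finetuned.rds"))
    utils::write.csv(ft$history, .mg_artifact(cfg, "finetune_history.csv"),
                     row.names = FALSE)
    .mg_log(cfg, "finetune", epochs = max(ft$history$epoch),
            best_val = min(ft$history$val_loss, na.rm = TRUE))
  }

  if ("generate" %in% stages) {
    has_ft <- file.exists(.mg_artifact(cfg, "finetuned.rds"))
    model <- load_checkpoint(
      if (has_ft) .mg_artifact(cfg, "finetuned.rds")
      else .mg_require_artifact(cfg, "pretrained.rds", "pretrain")
    )
    ids <- if (has_ft) 0:model$config$n_targets else 0L
    for (tid in ids) {
      gen <- generate(model, cfg$generate$n, target_id = tid,
                      temperature = cfg$generate$temperature,
                      max_len = cfg$generate$max_len,
                      seed = cfg$seed + 500L + tid)
      utils::write.csv(gen,
                       .mg_artifact(cfg, sprintf("generated_t%d.csv", tid)),
                       row.names = FALSE)
    }
    .mg_log(cfg, "generate", n = cfg$generate$n, targets = length(ids))
  }

  if ("evaluate" %in% stages) {
    corpus <- utils::read.csv(.mg_require_artifact(cfg, "corpus.csv",
                                                   "synth-data"))
    gen_path <- .mg_require_artifact(cfg, "generated_t0.csv", "generate")
    gen <- utils::read.csv(gen_path)
    gen$smiles[is.na(gen$smiles)] <- ""
    ks <- c(1000L, 10000L)
    report <- evaluate_generation(gen, corpus,
                                  reference = corpus[corpus$split == "valid", ],
                                  unique_k = ks[ks <= nrow(gen)],
                                  seed = cfg$seed)
    jsonlite::write_json(
      list(valid = report$valid, unique_at = as.list(report$unique_at),
           novel = report$novel, wasserstein = as.list(report$wasserstein),
           good_ranges = report$good_ranges),
      .mg_artifact(cfg, "report.json"), auto_unbox = TRUE, pretty = TRUE,
      digits = NA
    )
    .mg_log(cfg, "evaluate", valid = report$valid, novel = report$novel)
  }

  if ("qsar" %in% stages) {
    targets <- utils::read.csv(.mg_require_artifact(cfg, "targets.csv",
                                                    "synth-data"))
    for (tid in sort(unique(targets$target))) {
      dat <- targets[targets$target == tid, ]
      qm <- train_qsar(dat, tid, seed = cfg$seed,
                       nrounds = cfg$qsar$nrounds)
      saveRDS(qm, .mg_artifact(cfg, sprintf("qsar_t%d.rds", tid)))
      gen_file <- .mg_artifact(cfg, sprintf("generated_t%d.csv", tid))
      if (file.exists(gen_file)) {
        gen <- utils::read.csv(gen_file)
        gen <- gen[!is.na(gen$smiles) & gen$smiles != "", ]
        ranked <- predict_and_rank(qm, gen$smiles)
        utils::write.csv(ranked,
                         .mg_artifact(cfg, sprintf("scored_t%d.csv", tid)),
                         row.names = FALSE)
      }
    }
    .mg_log(cfg, "qsar", targets = length(unique(targets$target)))
  }

  # md5 manifest of all artifacts (provenance)
  files <- setdiff(list.files(cfg$out_dir), "manifest.json")
  sums <- tools::md5sum(file.path(cfg$out_dir, files))
  jsonlite::write_json(
    list(seed = cfg$seed, artifacts = as.list(stats::setNames(unname(sums),
                                                              files))),
    .mg_artifact(cfg, "manifest.json"), auto_unbox = TRUE, pretty = TRUE
  )
  invisible(report)
}
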