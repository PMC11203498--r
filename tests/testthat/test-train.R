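# Schedules, freeze masks, early stopping, and the two training loops.

test_that("pre-training learning rate decays multiplicatively from 1e-4", {
  cfg <- pretrain_config()
  expect_equal(pretrain_lr(1, cfg), 1e-4)
  expect_equal(pretrain_lr(2, cfg), 9.5e-5)
  lrs <- pretrain_lr(1:100, cfg)
  expect_true(all(diff(lrs) < 0))
  expect_error(pretrain_lr(0, cfg))
})

test_that("cosine fine-tuning schedule hits its anchors and repeats", {
  cfg <- finetune_config()
  expect_equal(finetune_lr(0, cfg), 0)
  expect_equal(finetune_lr(20, cfg), 1e-3)
  expect_equal(finetune_lr(120, cfg), finetune_lr(20, cfg))
  expect_equal(finetune_lr(60, cfg), 1e-3 * (1 + cos(pi * 40 / 80)) / 2)
  expect_equal(finetune_lr(0:99, cfg), finetune_lr(100:199, cfg))
  expect_error(finetune_lr(200, cfg), "out of range")
  expect_error(finetune_config(cycle_len = 50, n_cycles = 2,
                               max_epochs = 200))
})

test_that("phases alternate 15 adapter / 10 main with period 25", {
  cfg <- finetune_config()
  expect_identical(phase_for_epoch(c(0, 14), cfg), rep("adapter", 2))
  expect_identical(phase_for_epoch(c(15, 24), cfg), rep("main", 2))
  expect_identical(phase_for_epoch(25, cfg), "adapter")
  expect_identical(phase_for_epoch(0:199, cfg),
                   phase_for_epoch(0:199 %% 25, cfg))
})

test_that("freeze masks select the documented groups per phase", {
  m <- insert_adapters(fx_model(), seed = 1)
  groups <- parameter_groups(m)
  fa <- apply_freeze_mask(groups, "adapter")
  expect_true(all(fa[c("embeddings", "target_table", "output_linear",
                       "block2_adapter", "block3_adapter")]))
  expect_false(any(fa[grepl("_(self|cond)_attn$|_ffn$", names(fa))]))
  fm <- apply_freeze_mask(groups, "main")
  expect_false(any(fm[grepl("_adapter$", names(fm))]))
  expect_true(all(fm[!grepl("_adapter$", names(fm))]))
  expect_error(apply_freeze_mask(groups, "warmup"), "unknown phase")
})

test_that("early stopping follows the more-than-patience rule", {
  expect_false(early_stop(c(3, 2, 2, 2, 2, 2, 2), patience = 5))
  expect_true(early_stop(c(3, 2, 2, 2, 2, 2, 2, 2), patience = 5))
  expect_false(early_stop(seq(200, 1), patience = 5)) # strictly decreasing
  expect_false(early_stop(c(5, 4, 6, 6, 6, 3, 6, 6), patience = 5))
  expect_true(early_stop(c(5, 4, 6, 6, 6, 3, 6, 6, 6, 6, 6, 6), patience = 5))
})

test_that("frozen groups are bit-identical across an optimizer epoch", {
  m <- insert_adapters(fx_model(), seed = 4)
  targets <- generate_target_sets(
    dplyr::mutate(target_profiles(bias = 4), n_molecules = 40L),
    length_range = c(4, 10), seed = 6
  )
  enc <- encode_dataset(targets, m$vocab, m$config$max_len)
  pad <- m$vocab$specials[["PAD"]]
  groups <- parameter_groups(m)
  for (phase in c("adapter", "main")) {
    flags <- adaptmol:::.mg_tensor_flags(groups,
                                         apply_freeze_mask(groups, phase),
                                         m$weights)
    state <- adaptmol:::.mg_adam_new()
    set.seed(1)
    res <- adaptmol:::.mg_train_epoch(m$weights, m$config, m$adapter_blocks,
                                      enc$tokens, enc$target, 32L, 1e-3,
                                      flags, state, 0, pad)
    for (nm in names(m$weights)) {
      if (flags[[nm]]) next
      expect_identical(res$w[[nm]], m$weights[[nm]])
    }
    # always-trained layers move in both phases
    expect_false(identical(res$w[["tok_emb"]], m$weights[["tok_emb"]]))
    expect_false(identical(res$w[["out.W"]], m$weights[["out.W"]]))
    if (phase == "adapter") {
      expect_false(identical(res$w[["b2.adapter.Wd"]],
                             m$weights[["b2.adapter.Wd"]]))
    }
    # the unconditional embedding row stays pinned to zero
    expect_identical(res$w[["tgt_emb"]][1, ], rep(0, m$config$d_model))
  }
})

test_that("short pre-training reduces the loss and is seed-reproducible", {
  corp <- generate_corpus(200, c(4, 12), seed = 23)
  v <- build_vocabulary(corp$selfies)
  cfg <- model_config(v$n, d_model = 16, h = 2, n_blocks = 2, adapter_dim = 4,
                      dropout = 0, max_len = 16)
  pc <- pretrain_config(epochs = 2, batch_size = 64)
  fit1 <- pretrain(init_model(cfg, v, seed = 5), corp, pc, seed = 6)
  expect_lt(fit1$history$train_loss[2], fit1$history$train_loss[1])
  fit2 <- pretrain(init_model(cfg, v, seed = 5), corp, pc, seed = 6)
  expect_identical(fit1$model$weights, fit2$model$weights)
})

test_that("a single repeated molecule is memorized toward zero loss", {
  corp <- tibble::tibble(selfies = rep("[C][N][O][C]", 60), target = 0L,
                         split = "train")
  v <- build_vocabulary(c(corp$selfies[1], paste(selfies_alphabet(),
                                                 collapse = "")))
  cfg <- model_config(v$n, d_model = 16, h = 2, n_blocks = 2, adapter_dim = 4,
                      dropout = 0, max_len = 10)
  fit <- pretrain(init_model(cfg, v, seed = 5), corp,
                  pretrain_config(epochs = 60, lr0 = 0.01, decay = 0.99,
                                  batch_size = 20), seed = 6)
  expect_lt(dplyr::last(fit$history$train_loss), 0.15)
})

test_that("fine-tuning starts from the pre-trained validation loss", {
  corp <- generate_corpus(150, c(4, 10), seed = 31)
  v <- build_vocabulary(corp$selfies)
  cfg <- model_config(v$n, d_model = 16, h = 2, n_blocks = 3, adapter_dim = 4,
                      dropout = 0, max_len = 14)
  pre <- pretrain(init_model(cfg, v, seed = 7), corp,
                  pretrain_config(epochs = 1, batch_size = 64), seed = 8)
  targets <- generate_target_sets(
    dplyr::mutate(target_profiles(bias = 4), n_molecules = c(60L, 60L, 60L)),
    length_range = c(4, 10), seed = 9
  )
  enc <- encode_dataset(targets, v, 14)
  va <- enc$split == "valid"
  ref_loss <- adaptmol:::.mg_dataset_loss(pre$model$weights, cfg, integer(),
                                          enc$tokens[va, , drop = FALSE],
                                          enc$target[va],
                                          v$specials[["PAD"]])
  ft <- finetune(pre, targets,
                 finetune_config(max_epochs = 2, cycle_len = 2, n_cycles = 1,
                                 warmup_epochs = 1, batch_size = 64),
                 seed = 10)
  expect_equal(ft$history$val_loss[1], ref_loss, tolerance = 1e-10)
  expect_error(finetune(pre, dplyr::select(targets, -target)),
               "target")
})
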