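# Decoder model: causality, adapter identities, parameter census, and the
# batched training path against the reference forward.

test_that("config validates architecture invariants", {
  cfg <- model_config(32, d_model = 512, h = 8)
  expect_identical(cfg$d_k, 64L)
  expect_identical(cfg$d_v, 64L)
  expect_error(model_config(32, d_model = 30, h = 4))
  expect_error(model_config(32, d_model = 16, h = 2, adapter_dim = 16))
})

test_that("position-t logits ignore later tokens (causality)", {
  m <- fx_model()
  v <- fx_vocab()
  set.seed(31)
  toks <- c(v$specials[["SOS"]], sample(4:v$n, 8, TRUE), v$specials[["EOS"]])
  base <- model_forward(m, toks, target_id = 0)
  for (t in c(3, 6, 9)) {
    mutated <- toks
    mutated[(t + 1):length(toks)] <- sample(4:v$n, length(toks) - t, TRUE)
    alt <- model_forward(m, mutated, target_id = 0)
    expect_equal(alt[1:t, ], base[1:t, ], tolerance = 1e-12)
    expect_false(isTRUE(all.equal(alt[t + 1, ], base[t + 1, ])))
  }
})

test_that("model_forward validates inputs and output shape", {
  m <- fx_model()
  toks <- tokenize(fx_corpus()$selfies[1], fx_vocab())[[1]]
  lg <- model_forward(m, toks, 1L)
  expect_identical(dim(lg), c(length(toks), fx_vocab()$n))
  expect_error(model_forward(m, c(1L, 999L), 0L), "out of range")
})

test_that("zero-init adapters and zero target leave the block unchanged", {
  m <- fx_model()
  m2 <- insert_adapters(m, blocks = 2:3, seed = 5)
  bp <- adaptmol:::.mg_block_params(m2$weights, 2)
  set.seed(32)
  x <- matrix(rnorm(6 * 16), 6, 16)
  zero_t <- rep(0, 16)
  full <- decoder_block_forward(x, zero_t, bp, h = 2, use_adapter = TRUE)
  stripped <- decoder_block_forward(x, zero_t, bp, h = 2, use_adapter = FALSE,
                                    include_conditional = FALSE)
  expect_equal(full, stripped, tolerance = 1e-12)
  # nonzero target embedding must change the output
  cond <- decoder_block_forward(x, rnorm(16), bp, h = 2, use_adapter = TRUE)
  expect_false(isTRUE(all.equal(cond, full)))
})

test_that("inserting zero-init adapters changes no logit", {
  m <- fx_model()
  toks <- tokenize(fx_corpus()$selfies[2], fx_vocab())[[1]]
  before <- model_forward(m, toks, 0L)
  after <- model_forward(insert_adapters(m, seed = 9), toks, 0L)
  expect_lt(max(abs(after - before)), 1e-6)
  expect_identical(insert_adapters(m, seed = 9)$adapter_blocks, c(2L, 3L))
})

test_that("parameter groups partition every tensor exactly once", {
  m <- insert_adapters(fx_model(), seed = 1)
  groups <- parameter_groups(m)
  all_names <- unlist(groups, use.names = FALSE)
  expect_setequal(all_names, names(m$weights))
  expect_identical(anyDuplicated(all_names), 0L)
  total <- sum(vapply(m$weights, length, integer(1)))
  by_group <- sum(vapply(groups, function(g) {
    sum(vapply(m$weights[g], length, integer(1)))
  }, numeric(1)))
  expect_equal(by_group, total)
  # adapter group census: down + up projection, no biases
  cfg <- m$config
  expect_identical(
    sum(vapply(m$weights[groups$block2_adapter], length, integer(1))),
    2L * cfg$d_model * cfg$adapter_dim
  )
  # orphan tensors are rejected
  m$weights[["stray"]] <- matrix(0, 2, 2)
  expect_error(parameter_groups(m), "orphan")
})

test_that("group census matches hand-computed arithmetic for a config", {
  cfg <- model_config(20, d_model = 16, h = 2, n_blocks = 3, adapter_dim = 4,
                      max_len = 10)
  m <- insert_adapters(init_model(cfg, fx_vocab_sized(20), seed = 1), seed = 1)
  groups <- parameter_groups(m)
  sizes <- vapply(groups, function(g) {
    sum(vapply(m$weights[g], length, integer(1)))
  }, numeric(1))
  d <- 16; f <- 64; V <- 20
  expect_identical(unname(sizes[["embeddings"]]), V * d + 10 * d)
  expect_identical(unname(sizes[["target_table"]]), 4 * d)
  expect_identical(unname(sizes[["output_linear"]]), d * V + V)
  expect_identical(unname(sizes[["block1_self_attn"]]), 4 * d * d + 2 * d)
  expect_identical(unname(sizes[["block1_cond_attn"]]), 4 * d * d + 2 * d)
  expect_identical(unname(sizes[["block1_ffn"]]), d * f + f + f * d + d + 2 * d)
  expect_identical(unname(sizes[["block2_adapter"]]), 2 * d * 4)
})

test_that("batched training forward equals the reference model forward", {
  m <- insert_adapters(fx_model(), seed = 2)
  m$weights[["b3.adapter.Wu"]][] <- rnorm(length(m$weights[["b3.adapter.Wu"]]),
                                          0, 0.05)
  m$weights[["tgt_emb"]][2:4, ] <- rnorm(48, 0, 0.1)
  enc <- encode_dataset(fx_corpus()[1:6, ], fx_vocab(), 20)
  tgt <- c(0L, 1L, 2L, 3L, 1L, 0L)
  fwd <- adaptmol:::.mg_forward_batch(m$weights, m$config, m$adapter_blocks,
                                      enc$tokens, tgt, dropout = 0)
  pad <- fx_vocab()$specials[["PAD"]]
  T_ <- ncol(enc$tokens)
  for (b in seq_len(6)) {
    len <- sum(enc$tokens[b, ] != pad)
    ref <- model_forward(m, enc$tokens[b, seq_len(len)], tgt[b])
    rows <- ((b - 1) * T_ + 1):((b - 1) * T_ + len)
    expect_equal(fwd$logits[rows, ], ref, tolerance = 1e-10)
  }
})

test_that("analytic gradients match finite differences", {
  set.seed(42)
  corp <- fx_corpus()[1:10, ]
  v <- fx_vocab()
  cfg <- model_config(v$n, d_model = 8, h = 2, n_blocks = 2, adapter_dim = 3,
                      max_len = 16, dropout = 0)
  m <- insert_adapters(init_model(cfg, v, seed = 2), blocks = 2, seed = 3)
  m$weights[["b2.adapter.Wu"]][] <- rnorm(24, 0, 0.05)
  m$weights[["tgt_emb"]][2:4, ] <- rnorm(24, 0, 0.1)
  enc <- encode_dataset(corp, v, 16)
  tok <- enc$tokens
  tgt <- rep(c(0L, 1L, 2L, 3L, 2L), 2)
  pad <- v$specials[["PAD"]]
  y <- cbind(tok[, -1], pad)
  lossfun <- function(w) {
    fwd <- adaptmol:::.mg_forward_batch(w, cfg, m$adapter_blocks, tok, tgt,
                                        0, keep_cache = FALSE)
    adaptmol:::.mg_ce_loss(fwd$logits, y, pad)$loss
  }
  fwd <- adaptmol:::.mg_forward_batch(m$weights, cfg, m$adapter_blocks, tok,
                                      tgt, 0)
  ce <- adaptmol:::.mg_ce_loss(fwd$logits, y, pad)
  gr <- adaptmol:::.mg_backward_batch(m$weights, cfg, m$adapter_blocks, fwd,
                                      ce$dlogits)
  eps <- 1e-6
  for (nm in names(gr)) {
    g <- gr[[nm]]
    for (ii in sample(length(g), min(2, length(g)))) {
      if (nm == "tgt_emb" && (ii - 1) %% 4 == 0) next # pinned row
      w2 <- m$weights; w2[[nm]][ii] <- w2[[nm]][ii] + eps
      w3 <- m$weights; w3[[nm]][ii] <- w3[[nm]][ii] - eps
      fd <- (lossfun(w2) - lossfun(w3)) / (2 * eps)
      expect_lt(abs(fd - g[ii]) / max(1e-4, abs(fd), abs(g[ii])), 1e-4)
    }
  }
})

test_that("checkpoints reload bit-exact with a vocabulary hash sidecar", {
  m <- fx_model()
  path <- withr::local_tempfile(fileext = ".rds")
  save_checkpoint(m, path)
  m2 <- load_checkpoint(path)
  expect_identical(m2$weights, m$weights)
  side <- jsonlite::read_json(paste0(path, ".json"))
  expect_identical(side$vocab_hash, unname(adaptmol:::vocab_hash(m$vocab)))
})
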