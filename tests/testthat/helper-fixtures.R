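# Shared fixtures, built in code and memoized for the session.

.fx <- new.env()

fx_corpus <- function() {
  if (is.null(.fx$corpus)) .fx$corpus <- generate_corpus(120, c(4, 12), seed = 7)
  .fx$corpus
}

fx_vocab <- function() {
  if (is.null(.fx$vocab)) .fx$vocab <- build_vocabulary(fx_corpus()$selfies)
  .fx$vocab
}

# tiny 3-block model bound to the fixture vocabulary, dropout off
fx_model <- function() {
  if (is.null(.fx$model)) {
    cfg <- model_config(fx_vocab()$n, d_model = 16L, h = 2L, n_blocks = 3L,
                        adapter_dim = 4L, dropout = 0, max_len = 20L)
    .fx$model <- init_model(cfg, fx_vocab(), seed = 3)
  }
  .fx$model
}

# vocabulary with an exact total size (chemical tokens + 3 specials)
fx_vocab_sized <- function(n_total) {
  build_vocabulary(paste0(selfies_alphabet()[seq_len(n_total - 3L)],
                          collapse = ""))
}

# one fine-tuning recovery run: pretrain briefly on a synthetic corpus, then
# fine-tune on the default target sets and check that each target's
# generated token histogram is TV-closest to its own training histogram.
run_conditioning_recovery <- function(seed, n_generate = 250L) {
  corpus <- generate_corpus(1000, c(6, 24), seed = seed)
  vocab <- build_vocabulary(corpus$selfies)
  cfg <- model_config(vocab$n, d_model = 32L, h = 4L, n_blocks = 3L,
                      adapter_dim = 8L, dropout = 0.1, max_len = 28L)
  fit <- pretrain(init_model(cfg, vocab, seed = seed), corpus,
                  pretrain_config(epochs = 3L, batch_size = 128L),
                  seed = seed + 1L)
  targets <- generate_target_sets(seed = seed + 2L)
  ft <- finetune(fit, targets, finetune_config(batch_size = 128L),
                 seed = seed + 3L)
  alphabet <- selfies_alphabet()
  train_hist <- lapply(1:3, function(t) {
    token_histogram(targets$selfies[targets$target == t &
                                      targets$split == "train"], alphabet)
  })
  vapply(1:3, function(t) {
    gen <- generate(ft, n_generate, target_id = t, temperature = 1.5,
                    seed = seed + 10L + t)
    gh <- token_histogram(gen$selfies[nchar(gen$selfies) > 0], alphabet)
    tvs <- vapply(train_hist, function(hh) total_variation(gh, hh), numeric(1))
    which.min(tvs) == t
  }, logical(1))
}

# independent single-head attention oracle: explicit loops, no matrix algebra
brute_force_attention <- function(Q, K, V, mask = NULL) {
  T_ <- nrow(Q); M <- nrow(K); dk <- ncol(Q)
  out <- matrix(0, T_, ncol(V))
  for (t in seq_len(T_)) {
    s <- numeric(M)
    for (m in seq_len(M)) {
      s[m] <- sum(Q[t, ] * K[m, ]) / sqrt(dk)
      if (!is.null(mask) && mask[t, m]) s[m] <- -Inf
    }
    w <- exp(s - max(s)); w <- w / sum(w)
    for (m in seq_len(M)) out[t, ] <- out[t, ] + w[m] * V[m, ]
  }
  out
}

# independent multi-head oracle built on the single-head oracle
brute_force_mha <- function(Q, K, V, params, h, mask = NULL) {
  dk <- ncol(params$Wq) / h
  heads <- list()
  for (i in seq_len(h)) {
    cl <- ((i - 1) * dk + 1):(i * dk)
    heads[[i]] <- brute_force_attention(Q %*% params$Wq[, cl, drop = FALSE],
                                        K %*% params$Wk[, cl, drop = FALSE],
                                        V %*% params$Wv[, cl, drop = FALSE],
                                        mask)
  }
  do.call(cbind, heads) %*% params$Wo
}

random_mha_params <- function(d, seed) {
  set.seed(seed)
  list(Wq = matrix(rnorm(d * d), d, d), Wk = matrix(rnorm(d * d), d, d),
       Wv = matrix(rnorm(d * d), d, d), Wo = matrix(rnorm(d * d), d, d))
}
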