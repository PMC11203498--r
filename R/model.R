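# Model container: a flat named list of weight tensors plus a config.
# Flat naming ("b2.self.Wq", "out.W", ...) keeps the optimizer, the freeze
# masks and the parameter-group census simple and exhaustive.

#' Model configuration
#'
#' Architecture hyperparameters of the conditional decoder. Defaults follow
#' the full-scale configuration (512-dimensional embeddings, 8 heads, 3
#' blocks); tests and desk-scale runs pass smaller values.
#'
#' @param vocab_size Vocabulary size (including SOS/EOS/PAD).
#' @param d_model Embedding dimension; must be divisible by `h`.
#' @param h Number of attention heads. Per-head dims are
#'   `d_k = d_v = d_model / h`.
#' @param n_blocks Number of decoder blocks.
#' @param ffn_dim Inner feed-forward width (default `4 * d_model`).
#' @param adapter_dim Bottleneck width of adapter modules; must be smaller
#'   than `d_model`.
#' @param dropout Dropout rate used by the training engine.
#' @param max_len Maximum token sequence length including specials.
#' @param n_targets Number of protein targets (ids `1..n_targets`; id 0 is
#'   the unconditional mode).
#' @return A list of class `mg_config`.
#' @export
model_config <- function(vocab_size, d_model = 512L, h = 8L, n_blocks = 3L,
                         ffn_dim = 4L * d_model, adapter_dim = 64L,
                         dropout = 0.1, max_len = 72L, n_targets = 3L) {
  stopifnot(d_model %% h == 0L, n_blocks >= 1L, adapter_dim < d_model,
            vocab_size > 3L, max_len >= 3L, dropout >= 0, dropout < 1)
  structure(list(
    vocab_size = as.integer(vocab_size), d_model = as.integer(d_model),
    h = as.integer(h), d_k = as.integer(d_model %/% h),
    d_v = as.integer(d_model %/% h), n_blocks = as.integer(n_blocks),
    ffn_dim = as.integer(ffn_dim), adapter_dim = as.integer(adapter_dim),
    dropout = dropout, max_len = as.integer(max_len),
    n_targets = as.integer(n_targets)
  ), class = "mg_config")
}

.mg_rand_mat <- function(nr, nc, sd = 0.02) matrix(stats::rnorm(nr * nc, 0, sd), nr, nc)

#' Initialize a conditional decoder model
#'
#' Weights are drawn N(0, 0.02^2); layer-norm gains start at 1, all biases at
#' 0. The target embedding table starts at zero everywhere; row 1 (target id
#' 0, the unconditional mode) is pinned to zero and never updated. Adapters
#' are not present at initialization — they are inserted by
#' [insert_adapters()] at fine-tuning time.
#'
#' @param config An `mg_config`.
#' @param vocab The `mg_vocab` the model is bound to (stored for generation
#'   and checkpoint hashing).
#' @param seed Integer RNG seed.
#' @return An object of class `mg_model`.
#' @export
init_model <- function(config, vocab, seed = 1L) {
  stopifnot(inherits(config, "mg_config"), inherits(vocab, "mg_vocab"),
            config$vocab_size == vocab$n)
  with_seed(seed, {
    d <- config$d_model
    w <- list(
      tok_emb = .mg_rand_mat(config$vocab_size, d),
      pos_emb = .mg_rand_mat(config$max_len, d),
      tgt_emb = matrix(0, config$n_targets + 1L, d)
    )
    for (j in seq_len(config$n_blocks)) {
      p <- function(nm) paste0("b", j, ".", nm)
      w[[p("self.Wq")]] <- .mg_rand_mat(d, d)
      w[[p("self.Wk")]] <- .mg_rand_mat(d, d)
      w[[p("self.Wv")]] <- .mg_rand_mat(d, d)
      w[[p("self.Wo")]] <- .mg_rand_mat(d, d)
      w[[p("ln1.g")]] <- rep(1, d); w[[p("ln1.b")]] <- rep(0, d)
      w[[p("cond.Wq")]] <- .mg_rand_mat(d, d)
      w[[p("cond.Wk")]] <- .mg_rand_mat(d, d)
      w[[p("cond.Wv")]] <- .mg_rand_mat(d, d)
      w[[p("cond.Wo")]] <- .mg_rand_mat(d, d)
      w[[p("ln2.g")]] <- rep(1, d); w[[p("ln2.b")]] <- rep(0, d)
      w[[p("ffn.W1")]] <- .mg_rand_mat(d, config$ffn_dim)
      w[[p("ffn.b1")]] <- rep(0, config$ffn_dim)
      w[[p("ffn.W2")]] <- .mg_rand_mat(config$ffn_dim, d)
      w[[p("ffn.b2")]] <- rep(0, d)
      w[[p("ln3.g")]] <- rep(1, d); w[[p("ln3.b")]] <- rep(0, d)
    }
    w[["out.W"]] <- .mg_rand_mat(d, config$vocab_size)
    w[["out.b"]] <- rep(0, config$vocab_size)
    structure(list(config = config, vocab = vocab, weights = w,
                   adapter_blocks = integer()),
              class = "mg_model")
  })
}

#' @export
print.mg_model <- function(x, ...) {
  np <- sum(vapply(x$weights, length, integer(1)))
  cat("<mg_model> d_model=", x$config$d_model, " h=", x$config$h,
      " blocks=", x$config$n_blocks, " vocab=", x$config$vocab_size,
      " params=", np,
      if (length(x$adapter_blocks))
        paste0(" adapters@{", paste(x$adapter_blocks, collapse = ","), "}")
      else "",
      "\n", sep = "")
  invisible(x)
}

#' Insert bottleneck adapters into decoder blocks
#'
#' Adds a down/up-projection adapter to the given blocks. The up-projection
#' is zero-initialized and the down-projection is small random, so the model
#' function is unchanged at insertion — fine-tuning starts exactly from the
#' pre-trained function.
#'
#' @param model An `mg_model`.
#' @param blocks Integer block indices (default: every block except the
#'   first, matching the fine-tuning architecture of one pre-trained block
#'   without an adapter followed by adapter-equipped blocks).
#' @param seed RNG seed for the down-projections.
#' @return The model with adapter parameters added.
#' @export
insert_adapters <- function(model, blocks = NULL, seed = 1L) {
  stopifnot(inherits(model, "mg_model"))
  cfg <- model$config
  if (is.null(blocks)) blocks <- setdiff(seq_len(cfg$n_blocks), 1L)
  stopifnot(all(blocks %in% seq_len(cfg$n_blocks)))
  with_seed(seed, {
    for (j in blocks) {
      model$weights[[paste0("b", j, ".adapter.Wd")]] <-
        .mg_rand_mat(cfg$d_model, cfg$adapter_dim)
      model$weights[[paste0("b", j, ".adapter.Wu")]] <-
        matrix(0, cfg$adapter_dim, cfg$d_model)
    }
  })
  model$adapter_blocks <- sort(unique(c(model$adapter_blocks, as.integer(blocks))))
  model
}

# assemble the nested per-block parameter view used by the reference path
.mg_block_params <- function(weights, j) {
  g <- function(nm) weights[[paste0("b", j, ".", nm)]]
  out <- list(
    self = list(Wq = g("self.Wq"), Wk = g("self.Wk"),
                Wv = g("self.Wv"), Wo = g("self.Wo")),
    ln1 = list(g = g("ln1.g"), b = g("ln1.b")),
    cond = list(Wq = g("cond.Wq"), Wk = g("cond.Wk"),
                Wv = g("cond.Wv"), Wo = g("cond.Wo")),
    ln2 = list(g = g("ln2.g"), b = g("ln2.b")),
    ffn = list(W1 = g("ffn.W1"), b1 = g("ffn.b1"),
               W2 = g("ffn.W2"), b2 = g("ffn.b2")),
    ln3 = list(g = g("ln3.g"), b = g("ln3.b"))
  )
  if (!is.null(g("adapter.Wd"))) {
    out$adapter <- list(Wd = g("adapter.Wd"), Wu = g("adapter.Wu"))
  }
  out
}

#' Model forward pass for one token sequence
#'
#' Produces next-token logits at every position. Position-`t` logits depend
#' only on tokens at positions `<= t` (causal masking) and on the target
#' embedding; target id 0 selects the pinned all-zeros embedding
#' (unconditional mode). This is the deterministic reference path (dropout
#' off); the training engine's batched pass is tested against it.
#'
#' @param model An `mg_model`.
#' @param tokens Integer vector of vocabulary indices, starting with SOS.
#' @param target_id Integer in `0..n_targets`.
#' @return `length(tokens) x vocab_size` logit matrix.
#' @export
model_forward <- function(model, tokens, target_id = 0L) {
  stopifnot(inherits(model, "mg_model"))
  cfg <- model$config
  tokens <- as.integer(tokens)
  if (any(tokens < 1L | tokens > cfg$vocab_size)) {
    stop("token index out of range (vocab size ", cfg$vocab_size, ")")
  }
  stopifnot(target_id %in% 0:cfg$n_targets, length(tokens) <= cfg$max_len)
  w <- model$weights
  T_ <- length(tokens)
  x <- w$tok_emb[tokens, , drop = FALSE] + w$pos_emb[seq_len(T_), , drop = FALSE]
  temb <- w$tgt_emb[target_id + 1L, ]
  for (j in seq_len(cfg$n_blocks)) {
    bp <- .mg_block_params(w, j)
    x <- decoder_block_forward(x, temb, bp, cfg$h,
                               use_adapter = j %in% model$adapter_blocks)
  }
  x %*% w$out.W + matrix(w$out.b, T_, cfg$vocab_size, byrow = TRUE)
}

#' Partition model weights into named parameter groups
#'
#' Every tensor belongs to exactly one group: `embeddings` (token +
#' positional), `target_table`, `output_linear`, and per-block `self_attn`
#' (with its layer norm), `cond_attn` (with its layer norm), `ffn` (with its
#' layer norm) and `adapter` groups. The partition is checked exhaustively;
#' an unassigned tensor is an error.
#'
#' @param model An `mg_model`.
#' @return Named list mapping group name to character vector of tensor names.
#' @export
parameter_groups <- function(model) {
  stopifnot(inherits(model, "mg_model"))
  nms <- names(model$weights)
  groups <- list(
    embeddings = intersect(c("tok_emb", "pos_emb"), nms),
    target_table = intersect("tgt_emb", nms),
    output_linear = intersect(c("out.W", "out.b"), nms)
  )
  for (j in seq_len(model$config$n_blocks)) {
    pre <- paste0("b", j, ".")
    bn <- nms[startsWith(nms, pre)]
    sub <- substring(bn, nchar(pre) + 1L)
    groups[[paste0("block", j, "_self_attn")]] <-
      bn[startsWith(sub, "self.") | startsWith(sub, "ln1.")]
    groups[[paste0("block", j, "_cond_attn")]] <-
      bn[startsWith(sub, "cond.") | startsWith(sub, "ln2.")]
    groups[[paste0("block", j, "_ffn")]] <-
      bn[startsWith(sub, "ffn.") | startsWith(sub, "ln3.")]
    ad <- bn[startsWith(sub, "adapter.")]
    if (length(ad)) groups[[paste0("block", j, "_adapter")]] <- ad
  }
  groups <- groups[vapply(groups, length, integer(1)) > 0L]
  assigned <- unlist(groups, use.names = FALSE)
  if (anyDuplicated(assigned)) {
    stop("tensor assigned to more than one group: ",
         paste(assigned[duplicated(assigned)], collapse = ", "))
  }
  orphan <- setdiff(nms, assigned)
  if (length(orphan)) {
    stop("orphan tensor(s) not covered by any parameter group: ",
         paste(orphan, collapse = ", "))
  }
  groups
}

#' Save / load a model checkpoint
#'
#' The weight archive is an RDS file; a JSON sidecar (same path + `.json`)
#' records the configuration and the vocabulary hash, which [generate()]
#' checks against the vocabulary it is asked to use.
#'
#' @param model An `mg_model`.
#' @param path Checkpoint file path.
#' @export
save_checkpoint <- function(model, path) {
  stopifnot(inherits(model, "mg_model"))
  saveRDS(model, path)
  jsonlite::write_json(
    list(config = unclass(model$config),
         adapter_blocks = model$adapter_blocks,
         vocab_hash = vocab_hash(model$vocab)),
    paste0(path, ".json"), auto_unbox = TRUE, pretty = TRUE
  )
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  model <- readRDS(path)
  stopifnot(inherits(model, "mg_model"))
  model
}

# run `code` under a temporary RNG state seeded with `seed`
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  }
  on.exit({
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  code
}
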