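# Training engine: batched forward/backward passes with hand-derived
# gradients, Adam, the pre-training decay schedule and the alternating
# adapter/main fine-tuning schedule with a twice-repeated cosine LR.

#' Pre-training configuration
#'
#' @param epochs Number of epochs.
#' @param lr0 Initial learning rate.
#' @param decay Multiplicative per-epoch decay factor.
#' @param batch_size Minibatch size.
#' @return List of class `mg_pretrain_config`.
#' @export
pretrain_config <- function(epochs = 100L, lr0 = 1e-4, decay = 0.95,
                            batch_size = 512L) {
  stopifnot(epochs >= 1L, lr0 > 0, decay > 0, decay < 1, batch_size >= 1L)
  structure(list(epochs = as.integer(epochs), lr0 = lr0, decay = decay,
                 batch_size = as.integer(batch_size)),
            class = "mg_pretrain_config")
}

#' Fine-tuning configuration
#'
#' The alternation trains adapters (plus embeddings, target table and output
#' layer) for `adapter_phase_len` epochs, then everything except the
#' adapters for `main_phase_len` epochs, and repeats. The learning rate is a
#' half-cosine ramp from 0 to `peak_lr` over `warmup_epochs`, a half-cosine
#' decay back to 0 by `cycle_len`, repeated `n_cycles` times
#' (`cycle_len * n_cycles` must equal `max_epochs`).
#'
#' @param adapter_phase_len,main_phase_len Phase lengths in epochs.
#' @param max_epochs Epoch budget.
#' @param patience Early-stopping patience (validation epochs without a new
#'   best before stopping).
#' @param peak_lr,warmup_epochs,cycle_len,n_cycles Cosine schedule shape.
#' @param batch_size Minibatch size.
#' @return List of class `mg_finetune_config`.
#' @export
finetune_config <- function(adapter_phase_len = 15L, main_phase_len = 10L,
                            max_epochs = 200L, patience = 5L,
                            peak_lr = 1e-3, warmup_epochs = 20L,
                            cycle_len = 100L, n_cycles = 2L,
                            batch_size = 512L) {
  stopifnot(adapter_phase_len >= 1L, main_phase_len >= 1L,
            cycle_len * n_cycles == max_epochs, warmup_epochs < cycle_len,
            patience >= 1L, batch_size >= 1L)
  structure(list(adapter_phase_len = as.integer(adapter_phase_len),
                 main_phase_len = as.integer(main_phase_len),
                 max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience),
                 peak_lr = peak_lr, warmup_epochs = as.integer(warmup_epochs),
                 cycle_len = as.integer(cycle_len),
                 n_cycles = as.integer(n_cycles),
                 batch_size = as.integer(batch_size)),
            class = "mg_finetune_config")
}

#' Pre-training learning rate
#'
#' Exponential decay: `lr0 * decay^(epoch - 1)` for 1-based epochs, so epoch
#' 1 runs at `lr0` and the rate is strictly decreasing.
#'
#' @param epoch 1-based epoch index (vectorized).
#' @param cfg An `mg_pretrain_config`.
#' @return Learning rate(s).
#' @export
pretrain_lr <- function(epoch, cfg = pretrain_config()) {
  if (any(epoch < 1L)) stop("epoch must be >= 1")
  cfg$lr0 * cfg$decay^(epoch - 1)
}

#' Fine-tuning cosine learning rate
#'
#' Half-cosine ramp 0 -> `peak_lr` over the first `warmup_epochs` epochs of
#' each cycle, then half-cosine decay back to 0 by `cycle_len`; the cycle
#' repeats, so `finetune_lr(e + cycle_len) == finetune_lr(e)`.
#'
#' @param epoch 0-based epoch index (vectorized), in
#'   `[0, cycle_len * n_cycles)`.
#' @param cfg An `mg_finetune_config`.
#' @return Learning rate(s).
#' @export
finetune_lr <- function(epoch, cfg = finetune_config()) {
  if (any(epoch < 0L) || any(epoch >= cfg$cycle_len * cfg$n_cycles)) {
    stop("epoch out of range [0, ", cfg$cycle_len * cfg$n_cycles, ")")
  }
  e <- epoch %% cfg$cycle_len
  ifelse(e <= cfg$warmup_epochs,
         cfg$peak_lr * (1 - cos(pi * e / cfg$warmup_epochs)) / 2,
         cfg$peak_lr *
           (1 + cos(pi * (e - cfg$warmup_epochs) /
                      (cfg$cycle_len - cfg$warmup_epochs))) / 2)
}

#' Fine-tuning phase for an epoch
#'
#' Epochs alternate: the first `adapter_phase_len` epochs of each period are
#' the adapter phase, the next `main_phase_len` the main phase (period
#' `adapter_phase_len + main_phase_len`, i.e. 15 + 10 = 25 by default).
#'
#' @param epoch 0-based epoch index (vectorized).
#' @param cfg An `mg_finetune_config`.
#' @return `"adapter"` or `"main"`.
#' @export
phase_for_epoch <- function(epoch, cfg = finetune_config()) {
  if (any(epoch < 0L)) stop("epoch must be >= 0")
  period <- cfg$adapter_phase_len + cfg$main_phase_len
  ifelse(epoch %% period < cfg$adapter_phase_len, "adapter", "main")
}

#' Per-group trainability flags for a fine-tuning phase
#'
#' Adapter phase: only the adapter modules, the token/positional embeddings,
#' the target embedding table and the output linear layer train. Main phase:
#' everything except the adapters trains. The embedding and output layers
#' therefore train in every epoch.
#'
#' @param groups Parameter groups from [parameter_groups()].
#' @param phase `"adapter"` or `"main"`.
#' @return Named logical vector over groups.
#' @export
apply_freeze_mask <- function(groups, phase) {
  nms <- names(groups)
  always <- nms %in% c("embeddings", "target_table", "output_linear")
  is_adapter <- grepl("_adapter$", nms)
  flags <- switch(phase,
    adapter = always | is_adapter,
    main = !is_adapter,
    stop("unknown phase: ", phase)
  )
  names(flags) <- nms
  flags
}

.mg_tensor_flags <- function(groups, group_flags, weights) {
  flags <- logical(length(weights))
  names(flags) <- names(weights)
  for (g in names(groups)) flags[groups[[g]]] <- group_flags[[g]]
  flags
}

#' Early-stopping decision
#'
#' Stop when the running best (minimum) validation loss has not improved for
#' more than `patience` consecutive epochs.
#'
#' @param history Numeric vector of validation losses, oldest first.
#' @param patience Number of non-improving epochs tolerated.
#' @return `TRUE` if training should stop now.
#' @export
early_stop <- function(history, patience = 5L) {
  stopifnot(length(history) >= 1L)
  best <- which.min(history)
  (length(history) - best) > patience
}

# --- dataset encoding --------------------------------------------------------

#' Encode a molecule table for training
#'
#' Tokenizes the `selfies` column with specials, drops molecules longer than
#' `max_len` tokens (with a message giving the count), and pads to a
#' rectangular integer matrix.
#'
#' @param data Tibble with columns `selfies` and optionally `target`
#'   (defaults to 0) and `split`.
#' @param vocab An `mg_vocab`.
#' @param max_len Maximum sequence length including SOS/EOS.
#' @return List with `tokens` (matrix, PAD-filled), `target` (integer
#'   vector) and `split` (character vector).
#' @export
encode_dataset <- function(data, vocab, max_len = 72L) {
  stopifnot(is.data.frame(data), "selfies" %in% names(data))
  seqs <- tokenize(data$selfies, vocab, add_specials = TRUE)
  lens <- lengths(seqs)
  keep <- lens <= max_len
  if (any(!keep)) {
    message(sum(!keep), " molecule(s) longer than max_len = ", max_len,
            " dropped")
  }
  seqs <- seqs[keep]
  pad <- vocab$specials[["PAD"]]
  T_ <- max(lengths(seqs))
  tok <- matrix(pad, length(seqs), T_)
  for (i in seq_along(seqs)) tok[i, seq_along(seqs[[i]])] <- seqs[[i]]
  list(
    tokens = tok,
    target = if ("target" %in% names(data)) as.integer(data$target[keep])
             else integer(length(seqs)),
    split = if ("split" %in% names(data)) data$split[keep]
            else rep("train", length(seqs))
  )
}

# --- batched forward / backward ---------------------------------------------

.mg_ln_fwd <- function(x, g, b, eps = 1e-5) {
  mu <- rowMeans(x)
  xc <- x - mu
  inv <- 1 / sqrt(rowMeans(xc * xc) + eps)
  xhat <- xc * inv
  list(y = sweep(xhat, 2L, g, "*") +
         matrix(b, nrow(x), length(b), byrow = TRUE),
       xhat = xhat, inv = inv)
}

.mg_ln_bwd <- function(dy, cache, g) {
  xhat <- cache$xhat
  dxhat <- sweep(dy, 2L, g, "*")
  m1 <- rowMeans(dxhat)
  m2 <- rowMeans(dxhat * xhat)
  dx <- (dxhat - m1 - xhat * m2) * cache$inv
  list(dx = dx, dg = colSums(dy * xhat), db = colSums(dy))
}

.mg_dropout_mask <- function(nr, nc, p) {
  if (p <= 0) return(NULL)
  matrix((stats::runif(nr * nc) >= p) / (1 - p), nr, nc)
}

.mg_apply_mask <- function(x, m) if (is.null(m)) x else x * m

# batched forward pass; tok: B x T integer matrix (right-padded),
# tgt: length-B integer target ids (0-based). Row r of the flat state is
# sequence b = (r - 1) %/% T + 1, position t = (r - 1) %% T + 1.
.mg_forward_batch <- function(w, cfg, adapter_blocks, tok, tgt,
                              dropout = 0, keep_cache = TRUE) {
  B <- nrow(tok); T_ <- ncol(tok)
  h <- cfg$h; dk <- cfg$d_k; d <- cfg$d_model
  tokvec <- as.vector(t(tok))
  posvec <- rep(seq_len(T_), B)
  x <- w$tok_emb[tokvec, , drop = FALSE] + w$pos_emb[posvec, , drop = FALSE]
  rows_of <- lapply(seq_len(B), function(b) ((b - 1L) * T_ + 1L):(b * T_))
  scale <- 1 / sqrt(dk)
  cache <- list(tokvec = tokvec, posvec = posvec, B = B, T_ = T_, tgt = tgt,
                blocks = vector("list", cfg$n_blocks))
  for (j in seq_len(cfg$n_blocks)) {
    p <- function(nm) w[[paste0("b", j, ".", nm)]]
    bc <- list(x_in = x)
    Qf <- x %*% p("self.Wq"); Kf <- x %*% p("self.Wk"); Vf <- x %*% p("self.Wv")
    att <- .mg_attn_fwd_cpp(Qf, Kf, Vf, B, T_, h)
    Hf <- att$Hf
    sa <- Hf %*% p("self.Wo")
    D1 <- .mg_dropout_mask(B * T_, d, dropout)
    l1 <- .mg_ln_fwd(x + .mg_apply_mask(sa, D1), p("ln1.g"), p("ln1.b"))
    x1 <- l1$y
    # conditional MHA with a single-slot memory: softmax weight is 1, so the
    # sub-layer output is a per-target constant row (zero for target 0)
    cv_table <- (w$tgt_emb %*% p("cond.Wv")) %*% p("cond.Wo")
    cv <- cv_table[rep(tgt, each = T_) + 1L, , drop = FALSE]
    D2 <- .mg_dropout_mask(B * T_, d, dropout)
    l2 <- .mg_ln_fwd(x1 + .mg_apply_mask(cv, D2), p("ln2.g"), p("ln2.b"))
    x2 <- l2$y
    U <- x2 %*% p("ffn.W1") +
      matrix(p("ffn.b1"), B * T_, cfg$ffn_dim, byrow = TRUE)
    Am <- pmax(U, 0)
    Ff <- Am %*% p("ffn.W2") + matrix(p("ffn.b2"), B * T_, d, byrow = TRUE)
    if (j %in% adapter_blocks) {
      Qm <- pmax(Ff %*% p("adapter.Wd"), 0)
      F2 <- Ff + Qm %*% p("adapter.Wu")
    } else {
      Qm <- NULL; F2 <- Ff
    }
    D3 <- .mg_dropout_mask(B * T_, d, dropout)
    l3 <- .mg_ln_fwd(x2 + .mg_apply_mask(F2, D3), p("ln3.g"), p("ln3.b"))
    if (keep_cache) {
      bc$Qf <- Qf; bc$Kf <- Kf; bc$Vf <- Vf; bc$Abuf <- att$A; bc$Hf <- Hf
      bc$D1 <- D1; bc$l1 <- l1; bc$x1 <- x1; bc$D2 <- D2; bc$l2 <- l2
      bc$x2 <- x2; bc$Am <- Am; bc$Ff <- Ff; bc$Qm <- Qm; bc$F2 <- F2
      bc$D3 <- D3; bc$l3 <- l3
      cache$blocks[[j]] <- bc
    }
    x <- l3$y
  }
  logits <- x %*% w$out.W + matrix(w$out.b, B * T_, cfg$vocab_size, byrow = TRUE)
  list(logits = logits, x_final = x, cache = if (keep_cache) cache)
}

# cross-entropy over next tokens; y: B x T matrix of target indices with PAD
# where masked. Returns loss and dlogits (already divided by n kept rows).
.mg_ce_loss <- function(logits, y, pad) {
  yvec <- as.vector(t(y))
  keep <- which(yvec != pad)
  Z <- logits[keep, , drop = FALSE]
  m <- apply(Z, 1L, max)
  lse <- m + log(rowSums(exp(Z - m)))
  idx <- cbind(seq_along(keep), yvec[keep])
  loss <- mean(lse - Z[idx])
  P <- exp(Z - lse)
  P[idx] <- P[idx] - 1
  dlogits <- matrix(0, nrow(logits), ncol(logits))
  dlogits[keep, ] <- P / length(keep)
  list(loss = loss, dlogits = dlogits)
}

.mg_backward_batch <- function(w, cfg, adapter_blocks, fwd, dlogits) {
  cache <- fwd$cache
  B <- cache$B; T_ <- cache$T_; h <- cfg$h; dk <- cfg$d_k; d <- cfg$d_model
  tgt <- cache$tgt
  rows_of <- lapply(seq_len(B), function(b) ((b - 1L) * T_ + 1L):(b * T_))
  scale <- 1 / sqrt(dk)
  g <- list()
  g[["out.W"]] <- crossprod(fwd$x_final, dlogits)
  g[["out.b"]] <- colSums(dlogits)
  dx <- dlogits %*% t(w$out.W)
  g[["tgt_emb"]] <- matrix(0, cfg$n_targets + 1L, d)
  for (j in rev(seq_len(cfg$n_blocks))) {
    p <- function(nm) w[[paste0("b", j, ".", nm)]]
    nm <- function(s) paste0("b", j, ".", s)
    bc <- cache$blocks[[j]]
    # x3 = LN3(x2 + D3 * F2)
    lb <- .mg_ln_bwd(dx, bc$l3, p("ln3.g"))
    g[[nm("ln3.g")]] <- lb$dg; g[[nm("ln3.b")]] <- lb$db
    dr3 <- lb$dx
    dF2 <- .mg_apply_mask(dr3, bc$D3)
    dx2 <- dr3
    if (j %in% adapter_blocks) {
      g[[nm("adapter.Wu")]] <- crossprod(bc$Qm, dF2)
      dQm <- dF2 %*% t(p("adapter.Wu"))
      dUad <- dQm * (bc$Qm > 0)
      g[[nm("adapter.Wd")]] <- crossprod(bc$Ff, dUad)
      dF <- dF2 + dUad %*% t(p("adapter.Wd"))
    } else {
      dF <- dF2
    }
    g[[nm("ffn.W2")]] <- crossprod(bc$Am, dF)
    g[[nm("ffn.b2")]] <- colSums(dF)
    dAm <- dF %*% t(p("ffn.W2"))
    dU <- dAm * (bc$Am > 0)
    g[[nm("ffn.W1")]] <- crossprod(bc$x2, dU)
    g[[nm("ffn.b1")]] <- colSums(dU)
    dx2 <- dx2 + dU %*% t(p("ffn.W1"))
    # x2 = LN2(x1 + D2 * cv)
    lb <- .mg_ln_bwd(dx2, bc$l2, p("ln2.g"))
    g[[nm("ln2.g")]] <- lb$dg; g[[nm("ln2.b")]] <- lb$db
    dr2 <- lb$dx
    dcv <- .mg_apply_mask(dr2, bc$D2)
    dx1 <- dr2
    # conditional sub-layer: out = tgt_emb[t] Wv Wo per row; Q/K get no
    # gradient (single-slot softmax is constant 1)
    g[[nm("cond.Wv")]] <- matrix(0, d, d)
    g[[nm("cond.Wo")]] <- matrix(0, d, d)
    for (t in setdiff(unique(tgt), 0L)) {
      brows <- which(tgt == t)
      rws <- unlist(rows_of[brows], use.names = FALSE)
      s_t <- colSums(dcv[rws, , drop = FALSE])
      emb <- w$tgt_emb[t + 1L, ]
      v_t <- emb %*% p("cond.Wv")
      g[[nm("cond.Wo")]] <- g[[nm("cond.Wo")]] + crossprod(v_t, t(s_t))
      dv <- s_t %*% t(p("cond.Wo"))
      g[[nm("cond.Wv")]] <- g[[nm("cond.Wv")]] + outer(emb, as.vector(dv))
      g[["tgt_emb"]][t + 1L, ] <- g[["tgt_emb"]][t + 1L, ] +
        as.vector(dv %*% t(p("cond.Wv")))
    }
    g[[nm("cond.Wq")]] <- matrix(0, d, d)
    g[[nm("cond.Wk")]] <- matrix(0, d, d)
    # x1 = LN1(x + D1 * sa)
    lb <- .mg_ln_bwd(dx1, bc$l1, p("ln1.g"))
    g[[nm("ln1.g")]] <- lb$dg; g[[nm("ln1.b")]] <- lb$db
    dr1 <- lb$dx
    dsa <- .mg_apply_mask(dr1, bc$D1)
    dx <- dr1
    g[[nm("self.Wo")]] <- crossprod(bc$Hf, dsa)
    dHf <- dsa %*% t(p("self.Wo"))
    ab <- .mg_attn_bwd_cpp(bc$Qf, bc$Kf, bc$Vf, bc$Abuf, dHf, B, T_, h)
    dQf <- ab$dQf; dKf <- ab$dKf; dVf <- ab$dVf
    g[[nm("self.Wq")]] <- crossprod(bc$x_in, dQf)
    g[[nm("self.Wk")]] <- crossprod(bc$x_in, dKf)
    g[[nm("self.Wv")]] <- crossprod(bc$x_in, dVf)
    dx <- dx + dQf %*% t(p("self.Wq")) + dKf %*% t(p("self.Wk")) +
      dVf %*% t(p("self.Wv"))
  }
  dTok <- matrix(0, cfg$vocab_size, d)
  rs <- rowsum(dx, group = cache$tokvec)
  dTok[as.integer(rownames(rs)), ] <- rs
  g[["tok_emb"]] <- dTok
  dPos <- matrix(0, cfg$max_len, d)
  rs <- rowsum(dx, group = cache$posvec)
  dPos[as.integer(rownames(rs)), ] <- rs
  g[["pos_emb"]] <- dPos
  g[["tgt_emb"]][1L, ] <- 0 # pinned unconditional row
  g
}

# --- Adam -------------------------------------------------------------------

.mg_adam_new <- function() {
  env <- new.env(parent = emptyenv())
  env$m <- list(); env$v <- list(); env$t <- 0L
  env
}

.mg_adam_step <- function(w, grads, state, lr, trainable,
                          beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nmv in names(grads)) {
    if (!isTRUE(trainable[[nmv]])) next
    gr <- grads[[nmv]]
    m <- state$m[[nmv]]; v <- state$v[[nmv]]
    if (is.null(m)) { m <- gr * 0; v <- gr * 0 }
    m <- beta1 * m + (1 - beta1) * gr
    v <- beta2 * v + (1 - beta2) * gr * gr
    state$m[[nmv]] <- m; state$v[[nmv]] <- v
    w[[nmv]] <- w[[nmv]] - lr * (m / bc1) / (sqrt(v / bc2) + eps)
  }
  w$tgt_emb[1L, ] <- 0
  w
}

# one epoch of minibatch training; returns list(w, loss)
.mg_train_epoch <- function(w, cfg, adapter_blocks, tok, tgt, batch_size, lr,
                            trainable, state, dropout, pad) {
  nr <- nrow(tok)
  ord <- sample.int(nr)
  losses <- numeric(0)
  for (start in seq(1L, nr, by = batch_size)) {
    idx <- ord[start:min(start + batch_size - 1L, nr)]
    bt <- tok[idx, , drop = FALSE]
    # strip all-PAD trailing columns for this batch
    keep_cols <- which(colSums(bt != pad) > 0L)
    bt <- bt[, seq_len(max(keep_cols)), drop = FALSE]
    y <- cbind(bt[, -1L, drop = FALSE], pad)
    fwd <- .mg_forward_batch(w, cfg, adapter_blocks, bt, tgt[idx], dropout)
    ce <- .mg_ce_loss(fwd$logits, y, pad)
    if (!is.finite(ce$loss)) {
      stop("non-finite training loss (", ce$loss, "); aborting")
    }
    grads <- .mg_backward_batch(w, cfg, adapter_blocks, fwd, ce$dlogits)
    w <- .mg_adam_step(w, grads, state, lr, trainable)
    losses <- c(losses, ce$loss)
  }
  list(w = w, loss = mean(losses))
}

# mean next-token loss of a dataset (no dropout, no update)
.mg_dataset_loss <- function(w, cfg, adapter_blocks, tok, tgt, pad,
                             batch_size = 512L) {
  tot <- 0; n <- 0
  for (start in seq(1L, nrow(tok), by = batch_size)) {
    idx <- start:min(start + batch_size - 1L, nrow(tok))
    bt <- tok[idx, , drop = FALSE]
    y <- cbind(bt[, -1L, drop = FALSE], pad)
    fwd <- .mg_forward_batch(w, cfg, adapter_blocks, bt, tgt[idx],
                             dropout = 0, keep_cache = FALSE)
    yvec <- as.vector(t(y))
    keep <- which(yvec != pad)
    Z <- fwd$logits[keep, , drop = FALSE]
    m <- apply(Z, 1L, max)
    lse <- m + log(rowSums(exp(Z - m)))
    tot <- tot + sum(lse - Z[cbind(seq_along(keep), yvec[keep])])
    n <- n + length(keep)
  }
  tot / n
}

# --- top-level training loops -----------------------------------------------

#' Pre-train the unconditional model
#'
#' Next-token cross-entropy with teacher forcing over the corpus, all records
#' forced to target id 0 (the pinned zero embedding). The learning rate
#' follows [pretrain_lr()]; all parameters train.
#'
#' @param model An `mg_model` (freshly initialized).
#' @param corpus Tibble with a `selfies` column (and optional `split`; only
#'   the `"train"` rows are used when present).
#' @param cfg An `mg_pretrain_config`.
#' @param seed RNG seed (shuffling, dropout).
#' @return An `mg_fit`: the trained model plus a per-epoch history tibble.
#' @export
pretrain <- function(model, corpus, cfg = pretrain_config(), seed = 1L) {
  stopifnot(inherits(model, "mg_model"), inherits(cfg, "mg_pretrain_config"))
  enc <- encode_dataset(corpus, model$vocab, model$config$max_len)
  use <- enc$split == "train"
  tok <- enc$tokens[use, , drop = FALSE]
  tgt <- integer(nrow(tok)) # unconditional
  pad <- model$vocab$specials[["PAD"]]
  groups <- parameter_groups(model)
  trainable <- .mg_tensor_flags(groups, stats::setNames(rep(TRUE, length(groups)),
                                                        names(groups)),
                                model$weights)
  state <- .mg_adam_new()
  hist <- vector("list", cfg$epochs)
  with_seed(seed, {
    w <- model$weights
    for (ep in seq_len(cfg$epochs)) {
      lr <- pretrain_lr(ep, cfg)
      res <- .mg_train_epoch(w, model$config, model$adapter_blocks, tok, tgt,
                             cfg$batch_size, lr, trainable, state,
                             model$config$dropout, pad)
      w <- res$w
      hist[[ep]] <- tibble::tibble(stage = "pretrain", epoch = ep, lr = lr,
                                   phase = "all", train_loss = res$loss,
                                   val_loss = NA_real_)
    }
    model$weights <- w
  })
  structure(list(model = model, history = dplyr::bind_rows(hist),
                 kind = "pretrain"),
            class = "mg_fit")
}

#' Fine-tune on target-labelled molecules with the alternating schedule
#'
#' Inserts zero-initialized adapters into every block except the first (if
#' not already present), then runs the alternating freeze schedule: adapter
#' phases train adapters + embeddings + target table + output layer, main
#' phases train everything except adapters. The learning rate follows
#' [finetune_lr()]; validation loss on the pooled `"valid"` split drives
#' early stopping ([early_stop()]) and best-checkpoint selection. Because
#' the adapters start as exact identities, the validation loss recorded at
#' epoch 0 (before any update) equals the pre-trained model's.
#'
#' @param fit An `mg_fit` from [pretrain()] or an `mg_model`.
#' @param target_sets Tibble with `selfies`, `target` (1..n_targets) and
#'   `split` columns.
#' @param cfg An `mg_finetune_config`.
#' @param seed RNG seed.
#' @return An `mg_fit` holding the best-validation model and the history.
#' @export
finetune <- function(fit, target_sets, cfg = finetune_config(), seed = 1L) {
  model <- if (inherits(fit, "mg_fit")) fit$model else fit
  stopifnot(inherits(model, "mg_model"), inherits(cfg, "mg_finetune_config"))
  if (!"target" %in% names(target_sets) || anyNA(target_sets$target)) {
    stop("target_sets must carry a complete `target` column")
  }
  stopifnot(all(target_sets$target %in% seq_len(model$config$n_targets)))
  if (length(model$adapter_blocks) == 0L) {
    model <- insert_adapters(model, seed = seed)
  }
  enc <- encode_dataset(target_sets, model$vocab, model$config$max_len)
  tr <- enc$split == "train"; va <- enc$split == "valid"
  if (!any(va)) stop("target_sets must contain a 'valid' split")
  pad <- model$vocab$specials[["PAD"]]
  groups <- parameter_groups(model)
  state <- .mg_adam_new()
  hist <- list()
  with_seed(seed, {
    w <- model$weights
    val0 <- .mg_dataset_loss(w, model$config, model$adapter_blocks,
                             enc$tokens[va, , drop = FALSE], enc$target[va],
                             pad)
    hist[[1]] <- tibble::tibble(stage = "finetune", epoch = 0L, lr = 0,
                                phase = "init", train_loss = NA_real_,
                                val_loss = val0)
    val_hist <- val0
    best_val <- val0
    best_w <- w
    for (ep in seq_len(cfg$max_epochs) - 1L) {
      phase <- phase_for_epoch(ep, cfg)
      flags <- .mg_tensor_flags(groups, apply_freeze_mask(groups, phase), w)
      lr <- finetune_lr(ep, cfg)
      res <- .mg_train_epoch(w, model$config, model$adapter_blocks,
                             enc$tokens[tr, , drop = FALSE], enc$target[tr],
                             cfg$batch_size, lr, flags, state,
                             model$config$dropout, pad)
      w <- res$w
      val <- .mg_dataset_loss(w, model$config, model$adapter_blocks,
                              enc$tokens[va, , drop = FALSE], enc$target[va],
                              pad)
      hist[[length(hist) + 1L]] <- tibble::tibble(
        stage = "finetune", epoch = ep + 1L, lr = lr, phase = phase,
        train_loss = res$loss, val_loss = val
      )
      val_hist <- c(val_hist, val)
      if (val < best_val) { best_val <- val; best_w <- w }
      if (early_stop(val_hist, cfg$patience)) break
    }
    model$weights <- best_w
  })
  structure(list(model = model, history = dplyr::bind_rows(hist),
                 kind = "finetune"),
            class = "mg_fit")
}

#' @export
print.mg_fit <- function(x, ...) {
  cat("<mg_fit> ", x$kind, ", ", max(x$history$epoch), " epochs",
      if (any(!is.na(x$history$val_loss)))
        paste0(", best val loss ",
               signif(min(x$history$val_loss, na.rm = TRUE), 4)),
      "\n", sep = "")
  invisible(x)
}
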