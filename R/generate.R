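# Autoregressive sampling: temperature-scaled categorical sampling over
# next-token logits, with an incremental key/value cache so a batch of
# sequences is decoded in O(T^2) attention work total.

#' Sample one token from temperature-scaled logits
#'
#' Draws from `softmax(logits / temperature)`. As `temperature -> 0+` the
#' draw concentrates on the argmax; large temperatures flatten the
#' distribution for more diverse generation.
#'
#' @param logits Finite numeric vector of unnormalized log-probabilities.
#' @param temperature Positive scalar.
#' @return 1-based index of the sampled entry.
#' @export
sample_next_token <- function(logits, temperature = 1.5) {
  if (!all(is.finite(logits))) stop("logits must be finite")
  stopifnot(temperature > 0)
  z <- (logits - max(logits)) / temperature
  p <- exp(z) / sum(exp(z))
  sample.int(length(p), 1L, prob = p)
}

# vectorized row-wise categorical draw from softmax(logits / temperature);
# optionally restricted to the top_k largest logits per row
.mg_sample_rows <- function(logits, temperature, top_k = NULL) {
  if (!is.null(top_k) && top_k < ncol(logits)) {
    thr <- apply(logits, 1L, function(r) sort(r, decreasing = TRUE)[top_k])
    logits[logits < thr] <- -Inf
  }
  z <- (logits - apply(logits, 1L, max)) / temperature
  P <- exp(z)
  P <- P / rowSums(P)
  cum <- t(apply(P, 1L, cumsum))
  u <- stats::runif(nrow(P))
  as.integer(rowSums(cum < u) + 1L)
}

# incremental decoding of one chunk of sequences; returns B x L token matrix
# (column 1 is SOS). `force_tokens`, when given, replaces sampling and is
# used by the equivalence test against model_forward().
.mg_decode_chunk <- function(model, B, target_id, temperature, max_len,
                             top_k = NULL, force_tokens = NULL,
                             return_logits = FALSE) {
  cfg <- model$config
  w <- model$weights
  vocab <- model$vocab
  sos <- vocab$specials[["SOS"]]; eos <- vocab$specials[["EOS"]]
  pad <- vocab$specials[["PAD"]]
  d <- cfg$d_model; h <- cfg$h; dk <- cfg$d_k
  scale <- 1 / sqrt(dk)
  nb <- cfg$n_blocks
  Kc <- lapply(seq_len(nb), function(j) array(0, c(B, max_len, d)))
  Vc <- lapply(seq_len(nb), function(j) array(0, c(B, max_len, d)))
  tokens <- matrix(pad, B, max_len)
  tokens[, 1L] <- sos
  alive <- rep(TRUE, B)
  cv_rows <- lapply(seq_len(nb), function(j) {
    cvt <- (w$tgt_emb %*% w[[paste0("b", j, ".cond.Wv")]]) %*%
      w[[paste0("b", j, ".cond.Wo")]]
    matrix(cvt[target_id + 1L, ], B, d, byrow = TRUE)
  })
  logit_log <- if (return_logits) vector("list", max_len - 1L)
  ln <- function(x, g, b) {
    mu <- rowMeans(x); xc <- x - mu
    inv <- 1 / sqrt(rowMeans(xc * xc) + 1e-5)
    sweep(xc * inv, 2L, g, "*") + matrix(b, nrow(x), length(b), byrow = TRUE)
  }
  for (t in seq_len(max_len - 1L)) {
    x <- w$tok_emb[tokens[, t], , drop = FALSE] +
      matrix(w$pos_emb[t, ], B, d, byrow = TRUE)
    for (j in seq_len(nb)) {
      p <- function(s) w[[paste0("b", j, ".", s)]]
      q <- x %*% p("self.Wq")
      Kc[[j]][, t, ] <- x %*% p("self.Wk")
      Vc[[j]][, t, ] <- x %*% p("self.Wv")
      ctx <- matrix(0, B, d)
      for (i in seq_len(h)) {
        cl <- ((i - 1L) * dk + 1L):(i * dk)
        qh <- q[, cl, drop = FALSE]
        S <- matrix(0, B, t)
        for (m in seq_len(t)) {
          S[, m] <- rowSums(qh * matrix(Kc[[j]][, m, cl], B, dk)) * scale
        }
        A <- exp(S - apply(S, 1L, max))
        A <- A / rowSums(A)
        acc <- matrix(0, B, dk)
        for (m in seq_len(t)) {
          acc <- acc + A[, m] * matrix(Vc[[j]][, m, cl], B, dk)
        }
        ctx[, cl] <- acc
      }
      sa <- ctx %*% p("self.Wo")
      x1 <- ln(x + sa, p("ln1.g"), p("ln1.b"))
      x2 <- ln(x1 + cv_rows[[j]], p("ln2.g"), p("ln2.b"))
      ff <- pmax(x2 %*% p("ffn.W1") +
                   matrix(p("ffn.b1"), B, cfg$ffn_dim, byrow = TRUE), 0) %*%
        p("ffn.W2") + matrix(p("ffn.b2"), B, d, byrow = TRUE)
      if (j %in% model$adapter_blocks) {
        ff <- ff + pmax(ff %*% p("adapter.Wd"), 0) %*% p("adapter.Wu")
      }
      x <- ln(x2 + ff, p("ln3.g"), p("ln3.b"))
    }
    logits <- x %*% w$out.W + matrix(w$out.b, B, cfg$vocab_size, byrow = TRUE)
    if (return_logits) logit_log[[t]] <- logits
    if (is.null(force_tokens)) {
      logits[, c(sos, pad)] <- -Inf # only chemical tokens and EOS are emitted
      nxt <- .mg_sample_rows(logits, temperature, top_k)
    } else {
      nxt <- force_tokens[, t + 1L]
    }
    nxt[!alive] <- pad
    tokens[, t + 1L] <- nxt
    alive <- alive & nxt != eos
    if (!any(alive) && is.null(force_tokens)) break
  }
  if (return_logits) list(tokens = tokens, logits = logit_log) else tokens
}

#' Generate molecules by autoregressive temperature sampling
#'
#' Each sequence starts from SOS, appends temperature-sampled tokens, and
#' terminates at EOS or `max_len`; the token sequence (specials removed,
#' truncated at EOS) is decoded through the SELFIES codec, so every output
#' is a valid molecule regardless of how well the model is trained — the
#' guarantee is representational, not learned.
#'
#' Sequences are generated in fixed-size internal chunks, each with its own
#' derived seed, so results do not depend on how the request is batched.
#'
#' @param model An `mg_model` or `mg_fit`.
#' @param n Number of molecules to sample.
#' @param target_id Conditioning target id (0 = unconditional).
#' @param temperature Sampling temperature (default 1.5).
#' @param max_len Maximum sequence length including SOS/EOS.
#' @param seed RNG seed.
#' @param top_k Optional top-k restriction of the categorical draw (e.g. 30);
#'   `NULL` (default) samples the full vocabulary.
#' @param vocab Optional vocabulary to check against the model's (hash
#'   comparison); a mismatch is an error.
#' @return Tibble with columns `selfies`, `smiles`, `target`.
#' @export
generate <- function(model, n, target_id = 0L, temperature = 1.5,
                     max_len = NULL, seed = 1L, top_k = NULL, vocab = NULL) {
  if (inherits(model, "mg_fit")) model <- model$model
  stopifnot(inherits(model, "mg_model"), n >= 1L, temperature > 0,
            target_id %in% 0:model$config$n_targets)
  if (!is.null(vocab) &&
      !identical(vocab_hash(vocab), vocab_hash(model$vocab))) {
    stop("vocabulary hash mismatch between checkpoint and supplied vocabulary")
  }
  if (is.null(max_len)) max_len <- model$config$max_len
  stopifnot(max_len >= 2L, max_len <= model$config$max_len)
  chunk <- 1000L
  starts <- seq(1L, n, by = chunk)
  toks <- vector("list", length(starts))
  for (ci in seq_along(starts)) {
    B <- min(chunk, n - starts[ci] + 1L)
    toks[[ci]] <- with_seed(seed + ci - 1L, {
      .mg_decode_chunk(model, B, target_id, temperature, max_len, top_k)
    })
  }
  vocabulary <- model$vocab
  eos <- vocabulary$specials[["EOS"]]
  selfies <- unlist(lapply(toks, function(tm) {
    apply(tm, 1L, function(row) {
      stop_at <- match(eos, row)
      if (!is.na(stop_at)) row <- row[seq_len(stop_at)]
      detokenize(row, vocabulary)
    })
  }))
  tibble::tibble(selfies = selfies,
                 smiles = selfies_to_smiles(selfies),
                 target = as.integer(target_id))
}
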