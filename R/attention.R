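# Attention primitives. These are the reference (per-sequence) definitions;
# the training engine has a batched implementation that is tested against
# these for equality.

#' Scaled dot-product attention for one head
#'
#' Computes `softmax(Q K' / sqrt(d_k)) V`. Masked positions receive `-Inf`
#' score before the softmax, so each output row is a convex combination of
#' the unmasked value rows.
#'
#' @param Q Query matrix, `T x d_k`.
#' @param K Key matrix, `M x d_k`.
#' @param V Value matrix, `M x d_v`.
#' @param mask Optional `T x M` logical matrix; `TRUE` blocks a position.
#'   A fully-masked query row is an error (the softmax is undefined).
#' @return `T x d_v` matrix.
#' @export
scaled_dot_attention <- function(Q, K, V, mask = NULL) {
  Q <- as.matrix(Q); K <- as.matrix(K); V <- as.matrix(V)
  stopifnot(ncol(Q) == ncol(K), nrow(K) == nrow(V))
  S <- Q %*% t(K) / sqrt(ncol(Q))
  if (!is.null(mask)) {
    stopifnot(is.logical(mask), all(dim(mask) == c(nrow(Q), nrow(K))))
    if (any(rowSums(!mask) == 0L)) {
      stop("fully-masked attention row: softmax undefined")
    }
    S[mask] <- -Inf
  }
  A <- .mg_softmax_rows(S)
  A %*% V
}

.mg_softmax_rows <- function(S) {
  m <- apply(S, 1L, max)
  E <- exp(S - m)
  E / rowSums(E)
}

#' Multi-head attention
#'
#' Projects queries/keys/values with per-head slices of the (bias-free)
#' parameter matrices, applies [scaled_dot_attention()] per head, and maps
#' the concatenated heads through the output projection. With the target
#' embedding as a single-slot key/value memory this is the conditioning
#' sub-layer: the all-zeros embedding then contributes exactly zero.
#'
#' @param Q `T x d_model` query input.
#' @param K,V `M x d_model` key/value inputs.
#' @param params List with projection matrices `Wq`, `Wk`, `Wv` (each
#'   `d_model x (h * d_k)`, heads as column blocks) and `Wo`
#'   (`(h * d_v) x d_model`). No bias terms.
#' @param h Number of attention heads.
#' @param mask Optional `T x M` logical mask (`TRUE` = blocked).
#' @return `T x d_model` matrix.
#' @export
multi_head_attention <- function(Q, K, V, params, h, mask = NULL) {
  Q <- as.matrix(Q); K <- as.matrix(K); V <- as.matrix(V)
  stopifnot(ncol(params$Wq) %% h == 0L)
  dk <- ncol(params$Wq) %/% h
  dv <- ncol(params$Wv) %/% h
  Qp <- Q %*% params$Wq
  Kp <- K %*% params$Wk
  Vp <- V %*% params$Wv
  heads <- lapply(seq_len(h), function(i) {
    qc <- ((i - 1L) * dk + 1L):(i * dk)
    vc <- ((i - 1L) * dv + 1L):(i * dv)
    scaled_dot_attention(Qp[, qc, drop = FALSE], Kp[, qc, drop = FALSE],
                         Vp[, vc, drop = FALSE], mask)
  })
  do.call(cbind, heads) %*% params$Wo
}

#' Residual bottleneck adapter
#'
#' `x + relu(x W_down) W_up`, applied row-wise. A zero-initialized
#' up-projection makes the adapter an exact identity, so inserting fresh
#' adapters into a trained model changes no output.
#'
#' @param x `T x d_model` input.
#' @param params List with `Wd` (`d_model x adapter_dim`) and `Wu`
#'   (`adapter_dim x d_model`). No bias terms.
#' @return `T x d_model` matrix.
#' @export
adapter_forward <- function(x, params) {
  x <- as.matrix(x)
  x + pmax(x %*% params$Wd, 0) %*% params$Wu
}

.mg_layernorm <- function(x, g, b, eps = 1e-5) {
  mu <- rowMeans(x)
  xc <- x - mu
  inv <- 1 / sqrt(rowMeans(xc^2) + eps)
  sweep(xc * inv, 2L, g, "*") + matrix(b, nrow(x), length(b), byrow = TRUE)
}

.mg_causal_mask <- function(T_, M = T_) {
  outer(seq_len(T_), seq_len(M), function(t, m) m > t)
}

#' Decoder block forward pass (reference path)
#'
#' One block: masked self-attention, target-conditioned cross-attention with
#' the target embedding as the single-slot key/value memory, then the
#' feed-forward sub-layer (optionally wrapped by a bottleneck adapter).
#' Each sub-layer is residual with post-layer normalization. Dropout is a
#' training-time concern of the training engine; this reference path is
#' deterministic.
#'
#' @param x `T x d_model` input states.
#' @param target_emb Length-`d_model` target embedding vector (all zeros for
#'   the unconditional mode).
#' @param block List of block parameters (`self`, `ln1`, `cond`, `ln2`,
#'   `ffn`, `ln3`, optionally `adapter`), as stored in an `mg_model`.
#' @param h Number of attention heads.
#' @param use_adapter Apply the block's adapter after the feed-forward
#'   sub-layer (requires `block$adapter`).
#' @param include_conditional If `FALSE`, the conditional attention output is
#'   omitted (its residual normalization is kept): the stripped comparator
#'   used by equivalence tests.
#' @param causal Apply the autoregressive mask in self-attention.
#' @return `T x d_model` matrix.
#' @export
decoder_block_forward <- function(x, target_emb, block, h,
                                  use_adapter = FALSE,
                                  include_conditional = TRUE,
                                  causal = TRUE) {
  x <- as.matrix(x)
  T_ <- nrow(x)
  mask <- if (causal) .mg_causal_mask(T_) else NULL
  sa <- multi_head_attention(x, x, x, block$self, h, mask)
  x1 <- .mg_layernorm(x + sa, block$ln1$g, block$ln1$b)
  cv <- if (include_conditional) {
    multi_head_attention(x1, matrix(target_emb, 1L), matrix(target_emb, 1L),
                         block$cond, h)
  } else {
    0
  }
  x2 <- .mg_layernorm(x1 + cv, block$ln2$g, block$ln2$b)
  ff <- pmax(x2 %*% block$ffn$W1 +
               matrix(block$ffn$b1, T_, length(block$ffn$b1), byrow = TRUE), 0) %*%
    block$ffn$W2 +
    matrix(block$ffn$b2, T_, length(block$ffn$b2), byrow = TRUE)
  if (use_adapter) {
    if (is.null(block$adapter)) stop("block has no adapter parameters")
    ff <- adapter_forward(ff, block$adapter)
  }
  .mg_layernorm(x2 + ff, block$ln3$g, block$ln3$b)
}
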