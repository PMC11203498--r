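# Attention primitives against independent brute-force oracles.

test_that("single-slot attention returns the value row", {
  expect_equal(scaled_dot_attention(matrix(1), matrix(1), matrix(1)),
               matrix(1))
})

test_that("attention outputs are convex combinations of value rows", {
  set.seed(4)
  v <- c(2, -1, 0.5)
  V <- matrix(v, 4, 3, byrow = TRUE)
  out <- scaled_dot_attention(matrix(rnorm(6), 3, 2),
                              matrix(rnorm(8), 4, 2), V)
  expect_equal(out, matrix(v, 3, 3, byrow = TRUE))
})

test_that("scaled dot attention matches the brute-force oracle", {
  set.seed(21)
  for (rep in 1:20) {
    T_ <- sample(1:4, 1); M <- sample(1:4, 1)
    dk <- sample(1:4, 1); dv <- sample(1:4, 1)
    Q <- matrix(sample(-3:3, T_ * dk, TRUE), T_, dk)
    K <- matrix(sample(-3:3, M * dk, TRUE), M, dk)
    V <- matrix(sample(-3:3, M * dv, TRUE), M, dv)
    mask <- if (rep %% 2 == 0 && M > 1) {
      mm <- matrix(FALSE, T_, M); mm[, M] <- TRUE; mm
    }
    expect_equal(scaled_dot_attention(Q, K, V, mask),
                 brute_force_attention(Q, K, V, mask), tolerance = 1e-6)
  }
})

test_that("softmax rows sum to one over unmasked positions", {
  set.seed(5)
  S <- matrix(rnorm(20), 4, 5)
  A <- adaptmol:::.mg_softmax_rows(S)
  expect_equal(rowSums(A), rep(1, 4))
  expect_error(scaled_dot_attention(matrix(1), matrix(1), matrix(1),
                                    mask = matrix(TRUE)),
               "fully-masked")
})

test_that("multi-head attention reduces to single-head with identity maps", {
  set.seed(6)
  d <- 3
  Q <- matrix(rnorm(12), 4, d); K <- matrix(rnorm(6), 2, d)
  V <- matrix(rnorm(6), 2, d)
  id <- diag(d)
  params <- list(Wq = id, Wk = id, Wv = id, Wo = id)
  expect_equal(multi_head_attention(Q, K, V, params, h = 1),
               scaled_dot_attention(Q, K, V))
})

test_that("zero key/value memory yields exactly zero output", {
  set.seed(7)
  d <- 8
  params <- random_mha_params(d, 7)
  zero_mem <- matrix(0, 1, d)
  out <- multi_head_attention(matrix(rnorm(4 * d), 4, d), zero_mem, zero_mem,
                              params, h = 2)
  expect_identical(out, matrix(0, 4, d))
})

test_that("multi-head attention matches the per-head brute-force oracle", {
  set.seed(8)
  for (h in c(1, 2, 4)) {
    d <- 8
    params <- random_mha_params(d, 100 + h)
    Q <- matrix(rnorm(3 * d), 3, d)
    K <- matrix(rnorm(4 * d), 4, d)
    V <- matrix(rnorm(4 * d), 4, d)
    expect_equal(multi_head_attention(Q, K, V, params, h),
                 brute_force_mha(Q, K, V, params, h), tolerance = 1e-6)
  }
})

test_that("adapter with zero up-projection is the identity", {
  set.seed(9)
  x <- matrix(rnorm(12), 3, 4)
  params <- list(Wd = matrix(rnorm(8), 4, 2), Wu = matrix(0, 2, 4))
  expect_identical(adapter_forward(x, params), x)
})

test_that("adapter residual equals input plus bottleneck path", {
  set.seed(10)
  x <- matrix(rnorm(12), 3, 4)
  params <- list(Wd = matrix(rnorm(8), 4, 2), Wu = matrix(rnorm(8), 2, 4))
  up_path <- pmax(x %*% params$Wd, 0) %*% params$Wu
  expect_equal(adapter_forward(x, params) - x, up_path)
})

test_that("adapter matches a hand computation on a 1x2 case", {
  # x = (1, 2), Wd = (1, -1)', Wu = (3, 4): relu(1*1 + 2*(-1)) = 0 -> x
  x <- matrix(c(1, 2), 1, 2)
  p <- list(Wd = matrix(c(1, -1), 2, 1), Wu = matrix(c(3, 4), 1, 2))
  expect_equal(adapter_forward(x, p), x)
  # x = (2, 1): relu(2 - 1) = 1 -> x + (3, 4)
  x2 <- matrix(c(2, 1), 1, 2)
  expect_equal(adapter_forward(x2, p), matrix(c(5, 5), 1, 2))
})

test_that("batched C++ attention agrees with the reference primitives", {
  set.seed(12)
  B <- 3L; T_ <- 5L; d <- 8L; h <- 2L
  Qf <- matrix(rnorm(B * T_ * d), B * T_, d)
  Kf <- matrix(rnorm(B * T_ * d), B * T_, d)
  Vf <- matrix(rnorm(B * T_ * d), B * T_, d)
  att <- adaptmol:::.mg_attn_fwd_cpp(Qf, Kf, Vf, B, T_, h)
  mask <- adaptmol:::.mg_causal_mask(T_)
  for (b in seq_len(B)) {
    rows <- ((b - 1) * T_ + 1):(b * T_)
    for (i in seq_len(h)) {
      cl <- ((i - 1) * (d / h) + 1):(i * (d / h))
      ref <- scaled_dot_attention(Qf[rows, cl], Kf[rows, cl], Vf[rows, cl],
                                  mask)
      expect_equal(att$Hf[rows, cl], ref, tolerance = 1e-12)
    }
  }
})
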