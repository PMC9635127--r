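# Literal brute-force oracles, written as plain elementwise loops so they
# stay independent of the package's vectorized/compiled implementations.

oracle_layer_norm <- function(x, gamma, beta, eps) {
  C <- length(x)
  mu <- sum(x) / C
  v <- sum((x - mu)^2) / C
  out <- numeric(C)
  for (j in seq_len(C))
    out[j] <- (x[j] - mu) / sqrt(v + eps) * gamma[j] + beta[j]
  out
}

# 1-D conv (stride 1, zero same-padding) -> per-position layer norm -> ReLU
# -> non-overlapping average pooling, all with explicit loops.
oracle_conv_block <- function(x, W, b, gamma, beta, eps, pool) {
  L <- nrow(x); Cin <- ncol(x); Cout <- dim(W)[1]; K <- dim(W)[3]
  pl <- (K - 1) %/% 2
  y <- matrix(0, L, Cout)
  for (t in seq_len(L)) {
    for (o in seq_len(Cout)) {
      acc <- b[o]
      for (k in seq_len(K)) {
        src <- t + (k - 1) - pl
        if (src >= 1 && src <= L)
          for (c in seq_len(Cin)) acc <- acc + W[o, c, k] * x[src, c]
      }
      y[t, o] <- acc
    }
  }
  for (t in seq_len(L)) y[t, ] <- oracle_layer_norm(y[t, ], gamma, beta, eps)
  y[y < 0] <- 0
  Lout <- L %/% pool
  p <- matrix(0, Lout, Cout)
  for (j in seq_len(Lout))
    for (o in seq_len(Cout))
      p[j, o] <- mean(y[((j - 1) * pool + 1):(j * pool), o])
  p
}

oracle_softmax_row <- function(s) {
  e <- exp(s - max(s))
  e / sum(e)
}

oracle_sdpa <- function(Q, K, V) {
  l <- nrow(Q); dk <- ncol(Q)
  out <- matrix(0, l, ncol(V))
  for (i in seq_len(l)) {
    s <- numeric(l)
    for (j in seq_len(l)) s[j] <- sum(Q[i, ] * K[j, ]) / sqrt(dk)
    a <- oracle_softmax_row(s)
    for (c in seq_len(ncol(V))) out[i, c] <- sum(a * V[, c])
  }
  out
}

oracle_mha <- function(Z, Wq, Wk, Wv, Wo, h) {
  d <- ncol(Z); dh <- d %/% h
  H <- matrix(0, nrow(Z), d)
  for (i in seq_len(h)) {
    cols <- ((i - 1) * dh + 1):(i * dh)
    H[, cols] <- oracle_sdpa(Z %*% Wq[, cols], Z %*% Wk[, cols],
                             Z %*% Wv[, cols])
  }
  H %*% Wo
}

oracle_encoder <- function(Z, w, h, eps) {
  mh <- oracle_mha(Z, w$tx_Wq, w$tx_Wk, w$tx_Wv, w$tx_Wo, h)
  mid <- Z + mh
  for (t in seq_len(nrow(mid)))
    mid[t, ] <- oracle_layer_norm(mid[t, ], w$tx_ln1_g, w$tx_ln1_b, eps)
  f1 <- mid %*% w$tx_ffn_W1 + matrix(w$tx_ffn_b1, nrow(mid), length(w$tx_ffn_b1),
                                     byrow = TRUE)
  f1[f1 < 0] <- 0
  f <- f1 %*% w$tx_ffn_W2 + matrix(w$tx_ffn_b2, nrow(mid), ncol(Z),
                                   byrow = TRUE)
  out <- mid + f
  for (t in seq_len(nrow(out)))
    out[t, ] <- oracle_layer_norm(out[t, ], w$tx_ln2_g, w$tx_ln2_b, eps)
  out
}

# random transformer weight list for d, dff
random_tx_weights <- function(d, dff) {
  list(tx_Wq = matrix(rnorm(d * d, sd = 0.4), d, d),
       tx_Wk = matrix(rnorm(d * d, sd = 0.4), d, d),
       tx_Wv = matrix(rnorm(d * d, sd = 0.4), d, d),
       tx_Wo = matrix(rnorm(d * d, sd = 0.4), d, d),
       tx_ln1_g = runif(d, 0.5, 1.5), tx_ln1_b = rnorm(d, sd = 0.2),
       tx_ffn_W1 = matrix(rnorm(d * dff, sd = 0.4), d, dff),
       tx_ffn_b1 = rnorm(dff, sd = 0.2),
       tx_ffn_W2 = matrix(rnorm(dff * d, sd = 0.4), dff, d),
       tx_ffn_b2 = rnorm(d, sd = 0.2),
       tx_ln2_g = runif(d, 0.5, 1.5), tx_ln2_b = rnorm(d, sd = 0.2))
}

# small random labeled profile set for fast training tests
random_profile_set <- function(n_pos, n_neg, min_len = 18, max_len = 60,
                               gain = 6, name = "toy") {
  cfg <- GeneratorConfig(nPos = n_pos, nNeg = n_neg, minLen = min_len,
                         maxLen = max_len, motifGain = gain)
  profiles <- c(
    lapply(seq_len(n_pos), function(i)
      sampleProfile(cfg, 1L, id = sprintf("p%03d", i))),
    lapply(seq_len(n_neg), function(i)
      sampleProfile(cfg, 0L, id = sprintf("n%03d", i))))
  PSSMSet(profiles, name = name)
}

random_profile <- function(id = "r1", n = 10, label = NA_integer_) {
  res <- paste(sample(pssmResidueOrder(), n, replace = TRUE), collapse = "")
  PSSMProfile(id, res, matrix(sample(-16:13, n * 20, replace = TRUE), n, 20),
              label = label)
}

# hand-rolled Adam reference used by accumulation-equivalence tests
oracle_adam <- function(w, g, m, v, t, lr, b1 = 0.9, b2 = 0.999, eps = 1e-8) {
  t <- t + 1
  m <- b1 * m + (1 - b1) * g
  v <- b2 * v + (1 - b2) * g^2
  w <- w - lr * (m / (1 - b1^t)) / (sqrt(v / (1 - b2^t)) + eps)
  list(w = w, m = m, v = v, t = t)
}
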