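# Minimal BERT-style encoder in base R.
#
# The probing framework needs a trainable masked-language model that runs on
# one CPU in seconds-to-minutes. This file implements a small pre-LayerNorm
# transformer encoder (token + learned position embeddings, multi-head
# self-attention, ReLU feed-forward, residual connections) with hand-written
# reverse-mode gradients and an Adam optimizer. Gradients are verified
# against finite differences in the test suite.
#
# Batches are dense: a B x S id matrix plus per-sample valid lengths; padded
# key positions are masked out of the attention softmax and excluded from
# losses and pooling. Hidden states are stored as a (B*S) x d matrix with
# sample-major rows (row (b-1)*S + s is position s of sample b).

LN_EPS <- 1e-5

init_matrix <- function(nr, nc, sd = 0.02) {
  matrix(rnorm(nr * nc, sd = sd), nr, nc)
}

# Flat named parameter list; layer parameters are prefixed "L<i>.".
init_transformer_params <- function(V, d, n_layers, n_heads, ff_dim, maxlen,
                                    seed = NULL) {
  stopifnot(d %% n_heads == 0)
  with_seed(seed, {
    p <- list(
      tok_emb = init_matrix(V, d),
      pos_emb = init_matrix(maxlen, d),
      lnf_g = rep(1, d), lnf_b = rep(0, d),
      mlm_W = init_matrix(d, V), mlm_b = rep(0, V)
    )
    for (l in seq_len(n_layers)) {
      pre <- function(nm) paste0("L", l, ".", nm)
      p[[pre("ln1_g")]] <- rep(1, d); p[[pre("ln1_b")]] <- rep(0, d)
      p[[pre("Wq")]] <- init_matrix(d, d); p[[pre("bq")]] <- rep(0, d)
      p[[pre("Wk")]] <- init_matrix(d, d); p[[pre("bk")]] <- rep(0, d)
      p[[pre("Wv")]] <- init_matrix(d, d); p[[pre("bv")]] <- rep(0, d)
      p[[pre("Wo")]] <- init_matrix(d, d); p[[pre("bo")]] <- rep(0, d)
      p[[pre("ln2_g")]] <- rep(1, d); p[[pre("ln2_b")]] <- rep(0, d)
      p[[pre("W1")]] <- init_matrix(d, ff_dim); p[[pre("b1")]] <- rep(0, ff_dim)
      p[[pre("W2")]] <- init_matrix(ff_dim, d); p[[pre("b2")]] <- rep(0, d)
    }
    p
  })
}

add_bias <- function(M, b) sweep(M, 2, b, "+")

layernorm_fwd <- function(X, g, b) {
  mu <- rowMeans(X)
  xc <- X - mu
  invstd <- 1 / sqrt(rowMeans(xc * xc) + LN_EPS)
  xhat <- xc * invstd
  Y <- sweep(sweep(xhat, 2, g, "*"), 2, b, "+")
  list(Y = Y, xhat = xhat, invstd = invstd)
}

layernorm_bwd <- function(dY, cache, g) {
  xhat <- cache$xhat
  dxhat <- sweep(dY, 2, g, "*")
  m1 <- rowMeans(dxhat)
  m2 <- rowMeans(dxhat * xhat)
  dX <- cache$invstd * (dxhat - m1 - xhat * m2)
  list(dX = dX, dg = colSums(dY * xhat), db = colSums(dY))
}

softmax_rows <- function(X) {
  m <- apply(X, 1, max)
  E <- exp(X - m)
  E / rowSums(E)
}

# Forward pass. Returns final hidden states and (optionally) every cache
# needed for the backward pass.
transformer_forward <- function(params, ids, lens, n_layers, n_heads,
                                keep_cache = TRUE) {
  B <- nrow(ids); S <- ncol(ids)
  d <- ncol(params$tok_emb)
  dh <- d %/% n_heads
  scale <- 1 / sqrt(dh)
  tokvec <- as.vector(t(ids))
  posvec <- rep.int(seq_len(S), B)
  H <- params$tok_emb[tokvec, , drop = FALSE] +
    params$pos_emb[posvec, , drop = FALSE]
  caches <- list(tokvec = tokvec, posvec = posvec, B = B, S = S,
                 lens = lens, layers = vector("list", n_layers))
  for (l in seq_len(n_layers)) {
    pre <- function(nm) params[[paste0("L", l, ".", nm)]]
    ln1 <- layernorm_fwd(H, pre("ln1_g"), pre("ln1_b"))
    Xn <- ln1$Y
    Q <- add_bias(Xn %*% pre("Wq"), pre("bq"))
    K <- add_bias(Xn %*% pre("Wk"), pre("bk"))
    Vm <- add_bias(Xn %*% pre("Wv"), pre("bv"))
    O <- matrix(0, B * S, d)
    A_list <- if (keep_cache) vector("list", B * n_heads)
    for (b in seq_len(B)) {
      rows <- ((b - 1L) * S + 1L):(b * S)
      Lb <- lens[b]
      for (h in seq_len(n_heads)) {
        cols <- ((h - 1L) * dh + 1L):(h * dh)
        sc <- (Q[rows, cols, drop = FALSE] %*%
                 t(K[rows, cols, drop = FALSE])) * scale
        if (Lb < S) sc[, (Lb + 1L):S] <- -1e30
        A <- softmax_rows(sc)
        O[rows, cols] <- A %*% Vm[rows, cols, drop = FALSE]
        if (keep_cache) A_list[[(b - 1L) * n_heads + h]] <- A
      }
    }
    Att <- add_bias(O %*% pre("Wo"), pre("bo"))
    H2 <- H + Att
    ln2 <- layernorm_fwd(H2, pre("ln2_g"), pre("ln2_b"))
    Xn2 <- ln2$Y
    F1pre <- add_bias(Xn2 %*% pre("W1"), pre("b1"))
    F1 <- pmax(F1pre, 0)
    F2 <- add_bias(F1 %*% pre("W2"), pre("b2"))
    Hout <- H2 + F2
    if (keep_cache) {
      caches$layers[[l]] <- list(ln1 = ln1, Xn = Xn, Q = Q, K = K, V = Vm,
                                 O = O, A_list = A_list, ln2 = ln2, Xn2 = Xn2,
                                 F1pre = F1pre, F1 = F1)
    }
    H <- Hout
  }
  lnf <- layernorm_fwd(H, params$lnf_g, params$lnf_b)
  if (keep_cache) caches$lnf <- lnf
  list(H = lnf$Y, caches = caches)
}

# Backward pass: dH is the gradient at the final (post-LayerNorm) hidden
# states. Returns a flat named gradient list matching `params`.
transformer_backward <- function(params, caches, dH, n_layers, n_heads) {
  B <- caches$B; S <- caches$S; lens <- caches$lens
  d <- ncol(params$tok_emb)
  dh <- d %/% n_heads
  scale <- 1 / sqrt(dh)
  g <- list()
  lnf <- layernorm_bwd(dH, caches$lnf, params$lnf_g)
  g$lnf_g <- lnf$dg; g$lnf_b <- lnf$db
  dHcur <- lnf$dX
  for (l in rev(seq_len(n_layers))) {
    pre <- function(nm) params[[paste0("L", l, ".", nm)]]
    nm_ <- function(nm) paste0("L", l, ".", nm)
    cc <- caches$layers[[l]]
    # FFN block: Hout = H2 + F2
    dF2 <- dHcur
    g[[nm_("W2")]] <- t(cc$F1) %*% dF2
    g[[nm_("b2")]] <- colSums(dF2)
    dF1 <- dF2 %*% t(pre("W2"))
    dF1pre <- dF1 * (cc$F1pre > 0)
    g[[nm_("W1")]] <- t(cc$Xn2) %*% dF1pre
    g[[nm_("b1")]] <- colSums(dF1pre)
    dXn2 <- dF1pre %*% t(pre("W1"))
    ln2 <- layernorm_bwd(dXn2, cc$ln2, pre("ln2_g"))
    g[[nm_("ln2_g")]] <- ln2$dg; g[[nm_("ln2_b")]] <- ln2$db
    dH2 <- dHcur + ln2$dX
    # attention block: H2 = H + Att
    dAtt <- dH2
    g[[nm_("Wo")]] <- t(cc$O) %*% dAtt
    g[[nm_("bo")]] <- colSums(dAtt)
    dO <- dAtt %*% t(pre("Wo"))
    dQ <- matrix(0, B * S, d); dK <- matrix(0, B * S, d)
    dV <- matrix(0, B * S, d)
    for (b in seq_len(B)) {
      rows <- ((b - 1L) * S + 1L):(b * S)
      for (h in seq_len(n_heads)) {
        cols <- ((h - 1L) * dh + 1L):(h * dh)
        A <- cc$A_list[[(b - 1L) * n_heads + h]]
        dObh <- dO[rows, cols, drop = FALSE]
        Vbh <- cc$V[rows, cols, drop = FALSE]
        dA <- dObh %*% t(Vbh)
        dV[rows, cols] <- t(A) %*% dObh
        dS <- A * (dA - rowSums(dA * A))
        dQ[rows, cols] <- (dS %*% cc$K[rows, cols, drop = FALSE]) * scale
        dK[rows, cols] <- (t(dS) %*% cc$Q[rows, cols, drop = FALSE]) * scale
      }
    }
    g[[nm_("Wq")]] <- t(cc$Xn) %*% dQ; g[[nm_("bq")]] <- colSums(dQ)
    g[[nm_("Wk")]] <- t(cc$Xn) %*% dK; g[[nm_("bk")]] <- colSums(dK)
    g[[nm_("Wv")]] <- t(cc$Xn) %*% dV; g[[nm_("bv")]] <- colSums(dV)
    dXn <- dQ %*% t(pre("Wq")) + dK %*% t(pre("Wk")) + dV %*% t(pre("Wv"))
    ln1 <- layernorm_bwd(dXn, cc$ln1, pre("ln1_g"))
    g[[nm_("ln1_g")]] <- ln1$dg; g[[nm_("ln1_b")]] <- ln1$db
    dHcur <- dH2 + ln1$dX
  }
  V <- nrow(params$tok_emb)
  dtok <- matrix(0, V, d)
  agg <- rowsum(dHcur, group = caches$tokvec)
  dtok[as.integer(rownames(agg)), ] <- agg
  dpos <- matrix(0, nrow(params$pos_emb), d)
  aggp <- rowsum(dHcur, group = caches$posvec)
  dpos[as.integer(rownames(aggp)), ] <- aggp
  g$tok_emb <- dtok
  g$pos_emb <- dpos
  g
}

# Cross-entropy over the MLM head at the given flat row indices.
# Returns loss, dH (gradient at final hidden states), and head gradients.
mlm_loss_grad <- function(params, H, mask_rows, targets) {
  n <- length(mask_rows)
  Hm <- H[mask_rows, , drop = FALSE]
  logits <- add_bias(Hm %*% params$mlm_W, params$mlm_b)
  P <- softmax_rows(logits)
  loss <- -mean(log(pmax(P[cbind(seq_len(n), targets)], 1e-12)))
  dlogits <- P
  dlogits[cbind(seq_len(n), targets)] <-
    dlogits[cbind(seq_len(n), targets)] - 1
  dlogits <- dlogits / n
  dH <- matrix(0, nrow(H), ncol(H))
  dH[mask_rows, ] <- dlogits %*% t(params$mlm_W)
  list(loss = loss,
       dH = dH,
       g_mlm_W = t(Hm) %*% dlogits,
       g_mlm_b = colSums(dlogits))
}

# Probabilities of the MLM head at the given rows (no gradient).
mlm_probs <- function(params, H, mask_rows) {
  softmax_rows(add_bias(H[mask_rows, , drop = FALSE] %*% params$mlm_W,
                        params$mlm_b))
}

# Mean-pool final hidden states over valid positions -> B x d matrix.
pool_mean <- function(H, B, S, lens) {
  grp <- rep.int(seq_len(B), rep.int(S, B))
  valid <- as.vector(vapply(seq_len(B), function(b) {
    c(rep(1, lens[b]), rep(0, S - lens[b]))
  }, numeric(S)))
  pooled <- rowsum(H * valid, group = grp)
  pooled / lens
}

pool_mean_bwd <- function(dpooled, B, S, lens) {
  dH <- matrix(0, B * S, ncol(dpooled))
  for (b in seq_len(B)) {
    rows <- ((b - 1L) * S + 1L):((b - 1L) * S + lens[b])
    dH[rows, ] <- matrix(dpooled[b, ] / lens[b], length(rows),
                         ncol(dpooled), byrow = TRUE)
  }
  dH
}

# --- Adam ----------------------------------------------------------------

adam_init <- function(params) {
  zero_like <- function(x) if (is.matrix(x)) matrix(0, nrow(x), ncol(x)) else rep(0, length(x))
  list(m = lapply(params, zero_like), v = lapply(params, zero_like), t = 0L)
}

adam_step <- function(params, grads, state, lr, beta1, beta2, eps) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(grads)) {
    gv <- grads[[nm]]
    if (is.null(gv)) next
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * gv
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * gv * gv
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(params = params, state = state)
}

# Pad a list of id vectors into a dense B x S matrix (PAD id fills).
pad_id_matrix <- function(id_list, pad_id) {
  lens <- lengths(id_list)
  S <- max(lens)
  ids <- matrix(pad_id, length(id_list), S)
  for (i in seq_along(id_list)) ids[i, seq_len(lens[i])] <- id_list[[i]]
  list(ids = ids, lens = lens)
}
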