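# Internal neural-network primitives.
#
# Feature tensors are 4D arrays (C, T, V, N): channels, frames, joints,
# batch. Every op returns list(out, cache) and has a matching *_bwd taking
# (dout, cache) and returning the input gradient plus parameter gradients.
# Heavy contractions are expressed as BLAS matrix products; the per-frame
# attention products are vectorized over all frames of the whole batch.

dims4 <- function(x) {
  d <- dim(x)
  if (length(d) != 4) stop("expected a (C, T, V, N) array")
  d
}

# ---- 1x1 convolution over channels -----------------------------------------

conv1x1_fwd <- function(x, W, b = NULL) {
  d <- dims4(x)
  xm <- matrix(x, d[1], prod(d[2:4]))
  ym <- W %*% xm
  if (!is.null(b)) ym <- ym + b
  list(out = array(ym, c(nrow(W), d[2], d[3], d[4])),
       cache = list(xm = xm, W = W, d = d, has_b = !is.null(b)))
}

conv1x1_bwd <- function(dout, cache) {
  dm <- matrix(dout, dim(dout)[1], prod(dim(dout)[2:4]))
  list(dx = array(crossprod(cache$W, dm),
                  cache$d),
       dW = tcrossprod(dm, cache$xm),
       db = if (cache$has_b) rowSums(dm) else NULL)
}

# ---- graph aggregation with per-subset masks --------------------------------
# Subset matrices are indexed (root, neighbor); aggregation for root i sums
# masked neighbor features along row i, i.e. out = f %*% t(A_k * M_k).

graph_aggregate_fwd <- function(f, subsets, M) {
  # f: (K*C_out, T, V, N); M: (V, V, K)
  K <- length(subsets)
  d <- dims4(f)
  C_out <- d[1] %/% K
  V <- d[3]
  cache_fk <- vector("list", K)
  outm <- matrix(0, C_out * d[2] * d[4], V)
  for (k in seq_len(K)) {
    chunk <- seq_len(C_out) + (k - 1L) * C_out
    fk <- matrix(aperm(f[chunk, , , , drop = FALSE], c(1, 2, 4, 3)),
                 C_out * d[2] * d[4], V)             # rows (c, t, n)
    S <- subsets[[k]] * M[, , k]                     # (root, neighbor)
    outm <- outm + fk %*% t(S)
    cache_fk[[k]] <- fk
  }
  out <- aperm(array(outm, c(C_out, d[2], d[4], V)), c(1, 2, 4, 3))
  list(out = out,
       cache = list(subsets = subsets, M = M, fk = cache_fk,
                    d = d, C_out = C_out))
}

graph_aggregate_bwd <- function(dout, cache) {
  d <- cache$d
  K <- length(cache$subsets)
  C_out <- cache$C_out
  dm <- matrix(aperm(dout, c(1, 2, 4, 3)), C_out * d[2] * d[4], d[3])
  dM <- array(0, dim(cache$M))
  dfp <- array(0, c(d[1], d[2], d[4], d[3]))
  for (k in seq_len(K)) {
    S <- cache$subsets[[k]] * cache$M[, , k]
    dfk <- dm %*% S                                  # out = fk %*% t(S)
    dS <- crossprod(dm, cache$fk[[k]])               # dS[i,j] = sum_m dm[m,i] fk[m,j]
    dM[, , k] <- dS * cache$subsets[[k]]
    chunk <- seq_len(C_out) + (k - 1L) * C_out
    dfp[chunk, , , ] <- array(dfk, c(C_out, d[2], d[4], d[3]))
  }
  list(dx = aperm(dfp, c(1, 2, 4, 3)), dM = dM)
}

# ---- multi-head scaled dot-product attention over joints --------------------
# Frames are independent: logits e_ij = (a_i Wq)(a_j Wk)' / sqrt(d_k) within
# each frame, softmax over j, weighted sum of values, heads concatenated and
# projected by Wo. Parameters are shared across frames and samples.

attention_fwd <- function(x, p) {
  d <- dims4(x)
  C_in <- d[1]; Tn <- d[2]; V <- d[3]; N <- d[4]
  Fr <- Tn * N                                        # frames in batch
  H <- dim(p$Wq)[3]
  dk <- dim(p$Wq)[2]; dv <- dim(p$Wv)[2]
  Xall <- matrix(aperm(x, c(3, 2, 4, 1)), V * Fr, C_in)  # rows (v, t, n)
  Sall <- matrix(0, V * Fr, H * dv)
  heads <- vector("list", H)
  for (h in seq_len(H)) {
    Q <- Xall %*% p$Wq[, , h]
    Km <- Xall %*% p$Wk[, , h]
    Vm <- Xall %*% p$Wv[, , h]
    qa <- array(Q, c(V, Fr, dk)); ka <- array(Km, c(V, Fr, dk))
    E <- qk_logits(qa, ka) / sqrt(dk)                 # rows (j, i), cols f
    alpha <- softmax_columns(matrix(E, V, V * Fr))    # cols (i, f)
    va <- array(Vm, c(V, Fr, dv))
    Sall[, (h - 1L) * dv + seq_len(dv)] <-
      attn_weighted_values(alpha, va)                 # rows (i, f)
    heads[[h]] <- list(Q = Q, K = Km, V = Vm, alpha = alpha)
  }
  OutM <- Sall %*% p$Wo
  out <- aperm(array(OutM, c(V, Tn, N, ncol(p$Wo))), c(4, 2, 1, 3))
  list(out = out,
       cache = list(Xall = Xall, Sall = Sall, heads = heads, p = p, d = d))
}

attention_bwd <- function(dout, cache) {
  p <- cache$p
  d <- cache$d
  C_in <- d[1]; Tn <- d[2]; V <- d[3]; N <- d[4]
  Fr <- Tn * N
  H <- dim(p$Wq)[3]; dk <- dim(p$Wq)[2]; dv <- dim(p$Wv)[2]
  dOutM <- matrix(aperm(dout, c(3, 2, 4, 1)), V * Fr, dim(dout)[1])
  dWo <- crossprod(cache$Sall, dOutM)
  dSall <- tcrossprod(dOutM, p$Wo)
  dXall <- matrix(0, V * Fr, C_in)
  dWq <- array(0, dim(p$Wq)); dWk <- array(0, dim(p$Wk))
  dWv <- array(0, dim(p$Wv))
  for (h in seq_len(H)) {
    hd <- cache$heads[[h]]
    dSh <- dSall[, (h - 1L) * dv + seq_len(dv), drop = FALSE]
    va <- array(hd$V, c(V, Fr, dv))
    vb <- attn_values_bwd(hd$alpha, va, dSh)          # dAlpha, dV
    dE <- softmax_columns_bwd(hd$alpha, vb$dAlpha) / sqrt(dk)
    qa <- array(hd$Q, c(V, Fr, dk)); ka <- array(hd$K, c(V, Fr, dk))
    qk <- qk_bwd(dE, qa, ka)                          # dQ rows (i,f); dK rows (j,f)
    dXall <- dXall + tcrossprod(qk$dQ, p$Wq[, , h]) +
      tcrossprod(qk$dK, p$Wk[, , h]) + tcrossprod(vb$dV, p$Wv[, , h])
    dWq[, , h] <- crossprod(cache$Xall, qk$dQ)
    dWk[, , h] <- crossprod(cache$Xall, qk$dK)
    dWv[, , h] <- crossprod(cache$Xall, vb$dV)
  }
  dx <- aperm(array(dXall, c(V, Tn, N, C_in)), c(4, 2, 1, 3))
  list(dx = dx, dWq = dWq, dWk = dWk, dWv = dWv, dWo = dWo)
}

# ---- residual projection (f_in W_R when channel counts differ) --------------

residual_fwd <- function(x, Wr = NULL) {
  if (is.null(Wr)) return(list(out = x, cache = list(identity = TRUE)))
  d <- dims4(x)
  xm <- matrix(x, d[1], prod(d[2:4]))
  list(out = array(crossprod(Wr, xm), c(ncol(Wr), d[2], d[3], d[4])),
       cache = list(identity = FALSE, xm = xm, Wr = Wr, d = d))
}

residual_bwd <- function(dout, cache) {
  if (cache$identity) return(list(dx = dout, dWr = NULL))
  dm <- matrix(dout, dim(dout)[1], prod(dim(dout)[2:4]))
  list(dx = array(cache$Wr %*% dm, cache$d),
       dWr = tcrossprod(cache$xm, dm))
}

# ---- gated combination of the two branches ----------------------------------

gate_fwd <- function(fg, fa, r) {
  list(out = (fg + r * fa) / 2, cache = list(fa = fa, r = r))
}

gate_bwd <- function(dout, cache) {
  list(dfg = dout / 2, dfa = cache$r * dout / 2,
       dr = sum(dout * cache$fa) / 2)
}

# ---- batch normalization ----------------------------------------------------
# Generic over a (features x m) matrix view; the caller reshapes.

bn_mat_fwd <- function(xm, g, b, rm, rv, training, momentum = 0.9,
                       eps = 1e-5) {
  if (training) {
    mu <- rowMeans(xm)
    xc <- xm - mu
    va <- rowMeans(xc * xc)
    rm <- momentum * rm + (1 - momentum) * mu
    m <- ncol(xm)
    rv <- momentum * rv + (1 - momentum) * va * m / max(1, m - 1)
  } else {
    mu <- rm; va <- rv
    xc <- xm - mu
  }
  ivar <- 1 / sqrt(va + eps)
  xhat <- xc * ivar
  list(out = g * xhat + b,
       cache = list(xhat = xhat, ivar = ivar, g = g, training = training),
       rm = rm, rv = rv)
}

bn_mat_bwd <- function(dout, cache) {
  dg <- rowSums(dout * cache$xhat)
  db <- rowSums(dout)
  if (cache$training) {
    m <- ncol(dout)
    dx <- (cache$g * cache$ivar) *
      (dout - db / m - cache$xhat * (dg / m))
  } else {
    dx <- (cache$g * cache$ivar) * dout
  }
  list(dx = dx, dg = dg, db = db)
}

# per-channel BN on a (C,T,V,N) tensor
bn_fwd <- function(x, p, s, training) {
  d <- dims4(x)
  r <- bn_mat_fwd(matrix(x, d[1], prod(d[2:4])), p$g, p$b, s$rm, s$rv,
                  training)
  list(out = array(r$out, d), cache = c(r$cache, list(d = d)),
       state = list(rm = r$rm, rv = r$rv))
}

bn_bwd <- function(dout, cache) {
  r <- bn_mat_bwd(matrix(dout, cache$d[1], prod(cache$d[2:4])), cache)
  list(dx = array(r$dx, cache$d), dg = r$dg, db = r$db)
}

# ---- activations / dropout --------------------------------------------------

relu_fwd <- function(x) list(out = pmax(x, 0), cache = x > 0)
relu_bwd <- function(dout, cache) dout * cache

dropout_fwd <- function(x, rate, training) {
  if (!training || rate <= 0) {
    return(list(out = x, cache = NULL))
  }
  mask <- array(stats::rbinom(length(x), 1, 1 - rate) / (1 - rate), dim(x))
  list(out = x * mask, cache = mask)
}

dropout_bwd <- function(dout, cache) {
  if (is.null(cache)) dout else dout * cache
}

# ---- temporal convolution ---------------------------------------------------
# 1-D convolution along T per joint: kernel (Kt, 1), symmetric zero padding
# (Kt-1)/2, stride s, so T' = ceiling(T / s).

tconv_fwd <- function(x, W, b, stride) {
  d <- dims4(x)
  out <- tconv_forward(x, as.integer(d), W, b, as.integer(stride))
  list(out = out,
       cache = list(x = x, d = d, W = W, stride = as.integer(stride)))
}

tconv_bwd <- function(dout, cache) {
  tconv_backward(cache$x, as.integer(cache$d), cache$W, cache$stride,
                 dout)
}

# ---- global average pooling + linear output ---------------------------------

pool_fwd <- function(x) {
  d <- dims4(x)
  xm <- matrix(aperm(x, c(1, 4, 2, 3)), d[1] * d[4], d[2] * d[3])
  list(out = matrix(rowMeans(xm), d[1], d[4]), cache = d)
}

pool_bwd <- function(dout, cache) {
  d <- cache
  per <- dout / (d[2] * d[3])                         # (C, N)
  dx <- array(0, c(d[1], d[4], d[2], d[3]))
  dx[] <- as.vector(per)                              # recycled over (T, V)
  aperm(dx, c(1, 3, 4, 2))
}

linear_fwd <- function(x, W, b) {
  list(out = W %*% x + b, cache = list(x = x, W = W))
}

linear_bwd <- function(dout, cache) {
  list(dx = crossprod(cache$W, dout),
       dW = tcrossprod(dout, cache$x),
       db = rowSums(dout))
}

softmax_cols <- function(z) {
  z <- sweep(z, 2, apply(z, 2, max))
  ez <- exp(z)
  sweep(ez, 2, colSums(ez), "/")
}

# cross-entropy of column logits against 1-based labels; returns mean loss
# and gradient w.r.t. logits
softmax_ce <- function(logits, labels) {
  n <- ncol(logits)
  probs <- softmax_cols(logits)
  idx <- cbind(labels, seq_len(n))
  loss <- -mean(log(pmax(probs[idx], 1e-12)))
  dlogits <- probs
  dlogits[idx] <- dlogits[idx] - 1
  list(loss = loss, dlogits = dlogits / n, probs = probs)
}
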