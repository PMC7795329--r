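# Independent loop-based reference implementations of the spatial layer
# math, shared by the unit tests and the acceptance suite. These stay
# deliberately naive (explicit loops, no shared code with the package
# internals).

# dense triple-loop evaluation of the partitioned graph convolution:
# out[c', t, i] = sum_k sum_j f_k[c', t, j] * (A_k * M_k)[i, j]
# with f = W f_in (+ b) split into K channel chunks
oracle_graph_conv <- function(f_in, adj, params) {
  d <- dim(f_in)
  K <- length(adj$subsets)
  C_out <- nrow(params$W) / K
  V <- d[3]
  out <- array(0, c(C_out, d[2], V))
  for (t in seq_len(d[2])) {
    for (j in seq_len(V)) {
      fv <- params$W %*% f_in[, t, j]
      if (!is.null(params$b)) fv <- fv + params$b
      for (k in seq_len(K)) {
        S <- adj$subsets[[k]] * params$M[, , k]
        fk <- fv[(k - 1) * C_out + seq_len(C_out)]
        for (i in seq_len(V)) {
          out[, t, i] <- out[, t, i] + fk * S[i, j]
        }
      }
    }
  }
  out
}

# explicit-loop evaluation of multi-head scaled dot-product attention:
# per frame, e_ij = (a_i Wq)(a_j Wk)' / sqrt(d_k), softmax over j,
# s_i = sum_j alpha_ij (a_j Wv), heads concatenated, projected by Wo
oracle_attention <- function(f_in, p) {
  d <- dim(f_in)
  V <- d[3]; H <- dim(p$Wq)[3]
  dk <- dim(p$Wq)[2]; dv <- dim(p$Wv)[2]
  C_out <- ncol(p$Wo)
  out <- array(0, c(C_out, d[2], V))
  for (t in seq_len(d[2])) {
    A <- matrix(0, V, d[1])
    for (v in seq_len(V)) A[v, ] <- f_in[, t, v]
    S_heads <- NULL
    for (h in seq_len(H)) {
      Q <- A %*% p$Wq[, , h]; K <- A %*% p$Wk[, , h]
      Vv <- A %*% p$Wv[, , h]
      S <- matrix(0, V, dv)
      for (i in seq_len(V)) {
        e <- numeric(V)
        for (j in seq_len(V)) e[j] <- sum(Q[i, ] * K[j, ]) / sqrt(dk)
        alpha <- exp(e - max(e)); alpha <- alpha / sum(alpha)
        for (j in seq_len(V)) S[i, ] <- S[i, ] + alpha[j] * Vv[j, ]
      }
      S_heads <- cbind(S_heads, S)
    }
    out[, t, ] <- t(S_heads %*% p$Wo)
  }
  out
}

make_sgc_params <- function(C_in, C_out, V, K = 3, seed = 11,
                            ones_mask = FALSE) {
  set.seed(seed)
  list(W = matrix(rnorm(K * C_out * C_in), K * C_out, C_in),
       b = rnorm(K * C_out),
       M = if (ones_mask) array(1, c(V, V, K)) else
         array(rnorm(V * V * K), c(V, V, K)))
}
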