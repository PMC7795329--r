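# User-facing single-sample versions of the layer operations. These wrap
# the batched engine with N = 1 and are the surface exercised by the
# loop-based oracle tests.

as_batch1 <- function(f) {
  if (length(dim(f)) != 3) stop("expected a (C, T, V) array")
  array(f, c(dim(f), 1))
}

drop_batch <- function(x) array(x, dim(x)[1:3])

#' Spatial graph convolution with partitioned adjacency
#'
#' Implements the graph-convolution branch of the S-SGC layer: a 1x1
#' convolution maps the input to K channel chunks `f_k`, and the output is
#' `sum_k f_k (A_k * M_k)` where `A_k` are the partitioned adjacency
#' subsets (indexed root x neighbor, so each root aggregates along its
#' row), `M_k` are trainable element-wise masks, and `*` is the
#' element-wise product.
#'
#' @param f_in Input features, `C_in x T x V` array.
#' @param adj A [spatial_partition()] result with K subsets.
#' @param params List with `W` (`(K*C_out) x C_in` matrix of the 1x1
#'   convolution), optional `b` (length `K*C_out` bias), and `M`
#'   (`V x V x K` array of masks).
#' @return A `C_out x T x V` array.
#' @export
spatial_graph_conv <- function(f_in, adj, params) {
  K <- length(adj$subsets)
  V <- adj$num_joints
  d <- dim(f_in)
  if (length(d) != 3) stop("f_in must be a C x T x V array")
  if (d[3] != V) {
    stop(sprintf("joint dimension mismatch: f_in has V=%d, adjacency V=%d",
                 d[3], V))
  }
  if (ncol(params$W) != d[1]) {
    stop(sprintf("channel dimension mismatch: W expects C_in=%d, got %d",
                 ncol(params$W), d[1]))
  }
  if (nrow(params$W) %% K != 0) {
    stop("nrow(W) must be K * C_out")
  }
  x <- as_batch1(f_in)
  c1 <- conv1x1_fwd(x, params$W, params$b)
  ga <- graph_aggregate_fwd(c1$out, adj$subsets, params$M)
  drop_batch(ga$out)
}

#' Multi-head scaled dot-product self-attention over joints
#'
#' For every frame independently, attention logits between joints i and j
#' are `(a_i W_Q)(a_j W_K)' / sqrt(d_k)`, normalized by a softmax over j;
#' each joint's output is the attention-weighted sum of value projections,
#' heads are concatenated and projected by `W_O`. Parameters are shared
#' across frames.
#'
#' @param f_in Input features, `C_in x T x V` array.
#' @param params List with arrays `Wq`, `Wk` (`C_in x d_k x H`), `Wv`
#'   (`C_in x d_v x H`) and matrix `Wo` (`(H*d_v) x C_out`).
#' @return A `C_out x T x V` array.
#' @export
multi_head_spatial_attention <- function(f_in, params) {
  at <- attention_fwd(as_batch1(f_in), params)
  drop_batch(at$out)
}

#' Attention coefficients for a single frame
#'
#' Diagnostic helper returning the per-head softmax attention matrices for
#' one frame of input (rows = key joint j, columns = query joint i; each
#' column sums to 1).
#'
#' @param frame `C_in x V` matrix of joint features for one frame.
#' @param params As in [multi_head_spatial_attention()].
#' @return A `V x V x H` array of attention coefficients.
#' @export
attention_coefficients <- function(frame, params) {
  C <- nrow(frame); V <- ncol(frame)
  at <- attention_fwd(array(frame, c(C, 1, V, 1)), params)
  H <- dim(params$Wq)[3]
  out <- array(0, c(V, V, H))
  for (h in seq_len(H)) out[, , h] <- at$cache$heads[[h]]$alpha
  out
}

#' Residual connection of the attention branch
#'
#' Adds the layer input to the attention output; when the channel counts
#' differ the input is first projected by `W_R`.
#'
#' @param f_o Attention output, `C_out x T x V`.
#' @param f_in Layer input, `C_in x T x V`.
#' @param Wr `C_in x C_out` projection matrix, required iff
#'   `C_in != C_out`.
#' @return A `C_out x T x V` array.
#' @export
attention_residual <- function(f_o, f_in, Wr = NULL) {
  if (dim(f_o)[1] != dim(f_in)[1] && is.null(Wr)) {
    stop("Wr is required when input and output channel counts differ")
  }
  if (dim(f_o)[1] == dim(f_in)[1] && is.null(Wr)) {
    return(f_o + f_in)
  }
  rs <- residual_fwd(as_batch1(f_in), Wr)
  f_o + drop_batch(rs$out)
}

#' Gated combination of the graph-convolution and attention branches
#'
#' `f_out = (f_g + r * f_a) / 2`. The trainable scalar r (initialized at
#' 1) weights the attention branch; with gating disabled r is frozen at 1,
#' which reduces to the plain average of the two branches.
#'
#' @param f_g Graph-convolution branch output.
#' @param f_a Attention branch output, same shape.
#' @param r Gate coefficient.
#' @return Array of the same shape.
#' @export
gated_combine <- function(f_g, f_a, r = 1) {
  if (!identical(dim(f_g), dim(f_a))) {
    stop("f_g and f_a must have identical shapes")
  }
  (f_g + r * f_a) / 2
}

#' Temporal convolution along the frame axis
#'
#' A 1-D convolution with receptive field `(K_t, 1)`: each joint's channel
#' vector is convolved over time with symmetric zero padding
#' `(K_t - 1)/2`, so the output length is `ceiling(T / stride)`.
#'
#' @param f Input, `C_in x T x V` array.
#' @param W Kernel, `C_out x C_in x K_t` array (K_t odd).
#' @param b Bias, length `C_out` (default zeros).
#' @param stride Temporal stride (1 or 2).
#' @return A `C_out x ceiling(T/stride) x V` array.
#' @export
temporal_conv <- function(f, W, b = NULL, stride = 1) {
  if (dim(W)[3] %% 2 != 1) stop("temporal kernel K_t must be odd")
  if (is.null(b)) b <- numeric(dim(W)[1])
  tc <- tconv_fwd(as_batch1(f), W, b, stride)
  drop_batch(tc$out)
}

#' Forward pass of one basic block
#'
#' S-SGC (graph convolution + attention + residual + gate) followed by
#' batch normalization, ReLU, temporal convolution, batch normalization,
#' dropout, a block-level residual connection (projected and strided when
#' the shape changes), and a final ReLU. Evaluation mode: running
#' normalization statistics are used and dropout is inactive, so the
#' output is deterministic.
#'
#' @param f_in Input, `C_in x T x V` array.
#' @param adj A [spatial_partition()] result.
#' @param params Block parameter list as created inside [sstgcn()]
#'   (fields `sgc`, `att`, `r`, `bn1`, `tconv`, `bn2`, optional `res`).
#' @param state Block normalization state (running means/variances); when
#'   `NULL`, fresh zero-mean unit-variance statistics are used.
#' @param stride Temporal stride of the block.
#' @param config A [model_config()] (supplies dropout rate and gating
#'   flag).
#' @return A `C_out x ceiling(T/stride) x V` array.
#' @export
basic_block_forward <- function(f_in, adj, params, state = NULL, stride = 1,
                                config = model_config()) {
  c_out <- length(params$bn1$g)
  if (is.null(state)) {
    state <- init_block_state(c_out, has_res = !is.null(params$res))
  }
  bf <- block_fwd(as_batch1(f_in), params, state, adj, stride, config,
                  training = FALSE)
  drop_batch(bf$out)
}
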