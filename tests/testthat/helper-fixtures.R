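# Shared fixtures: tiny graphs and sequences built in code.

chain3_graph <- function() {
  # c (center) - a - b
  skeleton_graph(3, rbind(c(1, 2), c(2, 3)), center_joint = 1,
                 joint_names = c("c", "a", "b"))
}

random_sequence <- function(Tn = 6, V = 10, seed = 1, label = 1,
                            frame_rate = 30) {
  set.seed(seed)
  skeleton_sequence(array(rnorm(Tn * V * 3), c(Tn, V, 3)), label = label,
                    sample_id = paste0("rand", seed),
                    frame_rate = frame_rate)
}

tiny_model_config <- function(...) {
  args <- list(num_classes = 3, num_joints = 3, in_channels = 3,
               channels = c(4, 6), strides = c(1, 2), temporal_kernel = 3,
               heads = 2, dropout = 0, t_fix = 5)
  override <- list(...)
  args[names(override)] <- override
  do.call(model_config, args)
}

tiny_model <- function(seed = 7, ...) {
  sstgcn(tiny_model_config(...), chain3_graph(), seed = seed)
}

# small attention parameter set for oracle tests
small_attention_params <- function(C_in = 2, dk = 2, dv = 2, H = 1,
                                   C_out = 2, seed = 3) {
  set.seed(seed)
  list(Wq = array(rnorm(C_in * dk * H), c(C_in, dk, H)),
       Wk = array(rnorm(C_in * dk * H), c(C_in, dk, H)),
       Wv = array(rnorm(C_in * dv * H), c(C_in, dv, H)),
       Wo = matrix(rnorm(H * dv * C_out), H * dv, C_out))
}
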