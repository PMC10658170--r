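# shared fixtures: built in code, deterministic under fixed seeds

random_grid <- function(size = 8L, occupancy = 0.2, seed = 1L) {
  set.seed(seed)
  arr <- array(as.integer(runif(size^3) < occupancy), dim = rep(size, 3L))
  voxel_grid(arr)
}

random_tensor <- function(n = 50L, extent = 16L, channels = 1L, seed = 1L,
                          tensor_stride = 1L) {
  set.seed(seed)
  cc <- matrix(as.integer(floor(runif(3L * n, 0, extent))), ncol = 3L)
  cc <- (cc %/% tensor_stride) * tensor_stride
  cc <- unique(cc)
  sparse_tensor(cc, matrix(rnorm(nrow(cc) * channels), ncol = channels),
                tensor_stride = tensor_stride)
}

random_params <- function(cin, cout, Ks, seed = 1L, norm = FALSE) {
  set.seed(seed)
  p <- layer_params(array(rnorm(cin * cout * Ks^3, sd = 0.3),
                          dim = c(cin, cout, Ks^3)),
                    rnorm(cout, sd = 0.2),
                    if (norm) norm_params(cout) else NULL)
  if (norm) {
    p$norm$gamma <- runif(cout, 0.5, 1.5)
    p$norm$beta <- rnorm(cout, sd = 0.3)
  }
  p
}

tiny_completion_sample <- function(size = 16L, seed = 3L) {
  g <- make_shell(shell_spec(size = size, seed = seed))
  dd <- suppressMessages(apply_defect(g, defect_spec("sphere", 0.3,
                                                     seed = seed + 2L)))
  list(defective = dd$defective, complete = g, implant = dd$implant)
}
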