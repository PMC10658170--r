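#' Network configuration
#'
#' Parameterizes the sparse encoder-decoder by a 7-element channel list.
#' The encoder applies one kernel-size-3 convolution from 1 channel to
#' `ch[1]`, then six blocks of a stride-2 kernel-size-2 convolution and
#' a kernel-size-3 convolution walking the channel list, reaching tensor
#' stride 64 at the bottleneck.  The decoder mirrors it with six
#' upsample-by-2 generative transposed convolutions (the first with
#' kernel size 4, the rest kernel size 2), each followed by a
#' kernel-size-3 convolution and a 1-channel scoring convolution that
#' drives a pruning layer; a final 1x1x1 projection to one channel and a
#' sigmoid close the network.  Every convolution except the final
#' projection and the scoring heads carries per-channel affine
#' normalization.
#'
#' @param ch positive integer channel list of length 7.  Two reference
#'   settings are `c(8, 8, 16, 16, 32, 32, 64)` (0.435M parameters) and
#'   `c(22, 32, 32, 128, 156, 256, 388)` (18.14M parameters).
#' @param task `"completion"` or `"superres"` (the same architecture
#'   serves both).
#' @param tau pruning threshold (default 0).
#' @param additive_skips experimental parameter-neutral additive skip
#'   connections between mirrored encoder/decoder stages (default off).
#' @param normalization include normalization layers (default `TRUE`;
#'   required to reproduce the reference parameter counts).
#' @return An object of class `NetworkConfig`.
#' @export
network_config <- function(ch, task = c("completion", "superres"), tau = 0,
                           additive_skips = FALSE, normalization = TRUE) {
  ch <- as.integer(ch)
  if (length(ch) != 7L || any(is.na(ch)) || any(ch < 1L)) {
    stop("ch must be a 7-element positive integer channel list")
  }
  structure(list(ch = ch, task = match.arg(task), tau = tau,
                 additive_skips = isTRUE(additive_skips),
                 normalization = isTRUE(normalization)),
            class = "NetworkConfig")
}

.layer_spec <- function(role, cin, cout, ks, stride = 1L, norm = FALSE,
                        act = NA_character_, stage = NA_integer_) {
  stopifnot(ks >= 1L, stride %in% c(1L, 2L), cin >= 1L, cout >= 1L)
  structure(list(role = role, cin = as.integer(cin), cout = as.integer(cout),
                 ks = as.integer(ks), stride = as.integer(stride),
                 norm = norm, act = act, stage = stage),
            class = "LayerSpec")
}

#' Layer specifications of a configuration
#'
#' @param cfg a [network_config()].
#' @return List of `LayerSpec` records in execution order.  Roles are
#'   `conv`, `strided-conv`, `generative-transposed-conv`,
#'   `scoring-conv` (followed by pruning) and `final-projection`.
#' @export
network_specs <- function(cfg) {
  stopifnot(inherits(cfg, "NetworkConfig"))
  ch <- cfg$ch
  nrm <- cfg$normalization
  specs <- list(.layer_spec("conv", 1L, ch[1], 3L, 1L, nrm, "relu"))
  for (i in 1:6) {
    specs <- c(specs, list(
      .layer_spec("strided-conv", ch[i], ch[i + 1], 2L, 2L, nrm, "relu"),
      .layer_spec("conv", ch[i + 1], ch[i + 1], 3L, 1L, nrm, "relu")
    ))
  }
  for (j in 1:6) {
    i <- 8L - j  # walks ch[7] -> ch[1] (1-based)
    ks_gen <- if (j == 1L) 4L else 2L
    specs <- c(specs, list(
      .layer_spec("generative-transposed-conv", ch[i], ch[i - 1], ks_gen,
                  2L, nrm, "relu", stage = j),
      .layer_spec("conv", ch[i - 1], ch[i - 1], 3L, 1L, nrm, "relu",
                  stage = j),
      .layer_spec("scoring-conv", ch[i - 1], 1L, 1L, 1L, FALSE,
                  NA_character_, stage = j)
    ))
  }
  c(specs, list(.layer_spec("final-projection", ch[1], 1L, 1L, 1L, FALSE,
                            "sigmoid")))
}

.init_layer <- function(spec, normalization) {
  k <- spec$ks^3
  fan_in <- k * spec$cin
  limit <- 1 / sqrt(fan_in)
  W <- array(runif(spec$cin * spec$cout * k, -limit, limit),
             dim = c(spec$cin, spec$cout, k))
  # small positive bias keeps ReLU channels alive on single-point
  # supports (where batch standardization cannot apply); it is inert in
  # batch-normalized layers with two or more points
  b <- rep(0.1, spec$cout)
  if (spec$role == "scoring-conv") b <- rep(0.5, spec$cout)
  if (spec$role == "final-projection") b <- rep(0, spec$cout)
  norm <- if (isTRUE(spec$norm)) norm_params(spec$cout) else NULL
  layer_params(W, b, norm)
}

#' Build the encoder-decoder network
#'
#' Instantiates [network_specs()] with seeded, fan-in-scaled uniform
#' weight initialization, zero biases (scoring convolutions get bias
#' +0.5 so an untrained network does not prune everything) and unit
#' scale / zero shift normalization.
#'
#' @param cfg a [network_config()].
#' @param seed integer RNG seed; two builds with the same seed produce
#'   identical parameters.
#' @return An object of class `SparseNetwork`: `list(cfg, specs, params)`
#'   with one [layer_params()] per spec.
#' @export
build_network <- function(cfg, seed = 1L) {
  specs <- network_specs(cfg)
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(as.integer(seed))
  params <- lapply(specs, .init_layer, normalization = cfg$normalization)
  structure(list(cfg = cfg, specs = specs, params = params, seed = seed),
            class = "SparseNetwork")
}

#' @export
print.SparseNetwork <- function(x, ...) {
  cat(sprintf("SparseNetwork (%s): %d layers, %s parameters, ch = [%s]\n",
              x$cfg$task, length(x$specs),
              format(enumerate_parameters(x), big.mark = ","),
              paste(x$cfg$ch, collapse = ", ")))
  invisible(x)
}

#' Analytic parameter count
#'
#' Sums `Ks^3 * Cin * Cout + Cout` over all convolutions (including the
#' scoring heads and final projection) plus `2 * Cout` per normalization
#' layer.  The count equals the exact enumeration of the built network's
#' parameter arrays ([enumerate_parameters()]).
#'
#' @param cfg a [network_config()] or a bare channel list.
#' @return Integer (double) parameter count.
#' @export
count_parameters <- function(cfg) {
  if (!inherits(cfg, "NetworkConfig")) cfg <- network_config(cfg)
  specs <- network_specs(cfg)
  sum(vapply(specs, function(s) {
    n <- s$ks^3 * s$cin * s$cout + s$cout
    if (isTRUE(s$norm)) n <- n + 2 * s$cout
    as.numeric(n)
  }, numeric(1)))
}

#' Enumerate the parameters of a built network
#'
#' @param net a [build_network()] result.
#' @return Total number of trainable scalars (weights, biases, and
#'   normalization scale/shift).
#' @export
enumerate_parameters <- function(net) {
  stopifnot(inherits(net, "SparseNetwork"))
  sum(vapply(net$params, function(p) {
    n <- length(p$W) + length(p$b)
    if (!is.null(p$norm)) n <- n + length(p$norm$gamma) + length(p$norm$beta)
    as.numeric(n)
  }, numeric(1)))
}

.printed_size <- function(n, ks, s, p) (n + 2 * p - ks) / s
.conventional_size <- function(n, ks, s, p) floor((n + 2 * p - ks) / s) + 1

#' Analytic activation-size model
#'
#' For the dense execution path, per-layer spatial sizes follow the
#' linear size recursion `N_i = (N_{i-1} + 2p - Ks) / s` as well as the
#' conventional `floor((N + 2p - Ks)/s) + 1` (the two differ by one; see
#' the methods vignette), with `p = (Ks-1)/2` for odd kernels and 0
#' otherwise, and `N * s` for upsampling layers.  For the sparse path,
#' voxel counts are propagated through stride/generation rules: copies
#' for stride-1 layers, an `N` upper bound for strided layers, and an
#' `N * Ks^3` upper bound for generative layers.
#'
#' @param cfg a [network_config()].
#' @param input_spatial_size integer length-1 or length-3 grid size.
#' @param input_voxel_count occupied-voxel count of the input.
#' @return A data frame with one row per layer (`role`, `ks`, `stride`,
#'   `cin`, `cout`, `dense_size_printed`, `dense_size_conventional`,
#'   `dense_values`, `sparse_voxels_bound`).
#' @export
activation_sizes <- function(cfg, input_spatial_size, input_voxel_count) {
  if (!inherits(cfg, "NetworkConfig")) cfg <- network_config(cfg)
  specs <- network_specs(cfg)
  sz_p <- rep_len(as.numeric(input_spatial_size), 3L)
  sz_c <- sz_p
  nvox <- as.numeric(input_voxel_count)
  rows <- lapply(specs, function(s) {
    p <- if (s$ks %% 2L == 1L) (s$ks - 1L) / 2L else 0L
    if (s$role == "generative-transposed-conv") {
      sz_p <<- sz_p * s$stride
      sz_c <<- sz_c * s$stride
      nvox <<- nvox * s$ks^3
    } else {
      sz_p <<- .printed_size(sz_p, s$ks, s$stride, p)
      sz_c <<- .conventional_size(sz_c, s$ks, s$stride, p)
      # stride-1 layers keep the support; strided layers can only shrink it
    }
    data.frame(role = s$role, ks = s$ks, stride = s$stride,
               cin = s$cin, cout = s$cout,
               dense_size_printed = paste(round(sz_p, 2), collapse = "x"),
               dense_size_conventional = paste(sz_c, collapse = "x"),
               dense_values = prod(pmax(sz_c, 0)) * s$cout,
               sparse_voxels_bound = nvox,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Analytic FLOP estimate
#'
#' Per layer, `N_i * Ks^3 * Cin * Cout`, where `N_i` is the number of
#' computed sites of layer `i` — so the total is linear in the input
#' voxel count when per-layer counts scale with it.
#'
#' @param cfg a [network_config()].
#' @param voxel_counts per-layer site counts; a scalar is recycled to
#'   all layers (the fixed-occupancy linear model).
#' @return A data frame of per-layer FLOPs with a `total` attribute.
#' @export
flops_estimate <- function(cfg, voxel_counts) {
  if (!inherits(cfg, "NetworkConfig")) cfg <- network_config(cfg)
  specs <- network_specs(cfg)
  nv <- rep_len(as.numeric(voxel_counts), length(specs))
  fl <- vapply(seq_along(specs), function(i) {
    s <- specs[[i]]
    nv[i] * s$ks^3 * s$cin * s$cout
  }, numeric(1))
  df <- data.frame(layer = seq_along(specs),
                   role = vapply(specs, `[[`, character(1), "role"),
                   voxels = nv, flops = fl, stringsAsFactors = FALSE)
  attr(df, "total") <- sum(fl)
  df
}

#' Save / load a network checkpoint
#'
#' A checkpoint is a single-file archive of the named parameter arrays,
#' the configuration, the seed and a format version.
#'
#' @param ckpt a checkpoint list (as returned by [train_completion()]) or
#'   a `SparseNetwork`.
#' @param path file path.
#' @return `save_checkpoint` the path invisibly; `load_checkpoint` the
#'   checkpoint.
#' @export
save_checkpoint <- function(ckpt, path) {
  if (inherits(ckpt, "SparseNetwork")) {
    ckpt <- list(net = ckpt, cfg = ckpt$cfg, seed = ckpt$seed,
                 history = NULL, version = "sparsevox-ckpt-1")
  }
  ckpt$version <- ckpt$version %||% "sparsevox-ckpt-1"
  saveRDS(ckpt, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  ckpt <- readRDS(path)
  if (is.null(ckpt$version) || !grepl("^sparsevox-ckpt-", ckpt$version)) {
    stop("not a sparsevox checkpoint (version mismatch): ", path)
  }
  ckpt
}
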