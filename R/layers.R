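#' Layer parameter container
#'
#' Weights of one (possibly normalized) convolution: `W` is a
#' `Cin x Cout x Ks^3` array with one slice per kernel offset (in
#' [kernel_offsets()] order), `b` the per-output-channel bias, and
#' `norm` optional per-channel affine normalization state.
#'
#' @param W numeric `Cin x Cout x K` array.
#' @param b numeric length-`Cout` bias.
#' @param norm `NULL` or a list with `gamma`, `beta`, `running_mean`,
#'   `running_var`, `momentum`, `eps`.
#' @return An object of class `LayerParams`.
#' @export
layer_params <- function(W, b = NULL, norm = NULL) {
  W <- as.array(W)
  if (length(dim(W)) == 2L) dim(W) <- c(dim(W), 1L)
  stopifnot(length(dim(W)) == 3L, all(is.finite(W)))
  if (is.null(b)) b <- numeric(dim(W)[2])
  stopifnot(length(b) == dim(W)[2], all(is.finite(b)))
  structure(list(W = W, b = as.numeric(b), norm = norm),
            class = "LayerParams")
}

#' Normalization state constructor
#'
#' @param channels number of channels.
#' @param momentum running-moment update rate.
#' @param eps variance floor.
#' @return A list usable as the `norm` field of [layer_params()].
#' @export
norm_params <- function(channels, momentum = 0.1, eps = 1e-5) {
  list(gamma = rep(1, channels), beta = rep(0, channels),
       running_mean = rep(0, channels), running_var = rep(1, channels),
       momentum = momentum, eps = eps)
}

#' Pruning configuration
#'
#' Points whose score falls below the threshold `tau` are pruned
#' (default `tau = 0`).  In training mode the ground-truth occupancy at
#' the current tensor stride additionally forces its points to be kept
#' (teacher forcing), so supervision targets are never starved; at
#' inference only the threshold rule applies.
#'
#' @param tau finite score threshold.
#' @param training logical; ground-truth-guided mode.
#' @return An object of class `PruneConfig`.
#' @export
prune_config <- function(tau = 0, training = FALSE) {
  stopifnot(is.finite(tau))
  structure(list(tau = tau, training = isTRUE(training)),
            class = "PruneConfig")
}

.as_weight_cube <- function(params, Ks) {
  W <- params$W
  K <- as.integer(Ks)^3
  if (dim(W)[3] != K) {
    stop("weight array has ", dim(W)[3], " offset slices, expected Ks^3 = ", K)
  }
  W
}

# forward with cache (internal; used by the training tape)
.conv_fwd <- function(st, params, Ks, stride = 1L, out_coords = NULL,
                      transposed = FALSE, upstride = 1L) {
  W <- .as_weight_cube(params, Ks)
  cin <- dim(W)[1]
  if (ncol(st$feats) != cin) {
    stop("input has ", ncol(st$feats), " channels, weights expect ", cin)
  }
  if (transposed) {
    if (st$tensor_stride %% upstride != 0L) {
      stop("tensor stride ", st$tensor_stride, " not divisible by upstride ",
           upstride)
    }
    ts_out <- st$tensor_stride %/% upstride
    if (is.null(out_coords)) {
      off <- kernel_offsets(Ks)
      if (ncol(st$coords) == 4L) off <- cbind(0L, off)
      out_coords <- cpp_expand_coords(st$coords, off, as.integer(ts_out))
    }
    km <- build_kernel_map(st, out_coords, Ks, out_stride = ts_out,
                           transposed = TRUE)
  } else {
    ts_out <- st$tensor_stride * as.integer(stride)
    if (is.null(out_coords)) {
      out_coords <- if (stride == 1L) st$coords else
        stride_coords(st$coords, st$tensor_stride, stride)$coords
    }
    km <- build_kernel_map(st, out_coords, Ks, in_stride = st$tensor_stride)
  }
  n_out <- nrow(out_coords)
  fout <- cpp_conv_forward(st$feats, W, params$b, unclass(km), n_out)
  out <- sparse_tensor(out_coords, fout, tensor_stride = ts_out, check = FALSE)
  list(out = out, cache = list(km = km, fin = st$feats))
}

.conv_bwd <- function(params, cache, dfout) {
  cpp_conv_backward(dfout, cache$fin, params$W, unclass(cache$km))
}

#' Sparse convolution
#'
#' Computes, for each output coordinate, `bias + sum_k W_k f(D' + k*ts)`
#' over the kernel offsets present in the input — the sparse analogue of
#' a zero-padded dense convolution evaluated only at occupied sites.
#' With `stride > 1` the output coordinates are the strided coarsening
#' of the input support ([stride_coords()]); rows with no contributing
#' input still receive the bias.
#'
#' @param st input [sparse_tensor()].
#' @param params a [layer_params()] with `Cin` matching `st`.
#' @param Ks kernel size.
#' @param stride 1 or 2.
#' @param out_coords optional explicit output coordinate matrix.
#' @return A [sparse_tensor()] with `Cout` channels.
#' @export
sparse_conv <- function(st, params, Ks, stride = 1L, out_coords = NULL) {
  stopifnot(inherits(st, "SparseTensor"))
  .conv_fwd(st, params, Ks, stride = stride, out_coords = out_coords)$out
}

#' Generative transposed convolution
#'
#' The output coordinate set is the kernel-span expansion
#' `{c + ts_out * k : c in input, k in kernel_offsets(Ks)}` of the input
#' support (deduplicated), so the layer can create points absent from
#' its input; features are accumulated over all input points within the
#' kernel neighborhood of each output point.  `upstride` divides the
#' tensor stride, moving the output onto a finer lattice.
#'
#' @inheritParams sparse_conv
#' @param upstride integer upsampling factor; must divide the input
#'   tensor stride.
#' @return A [sparse_tensor()] at tensor stride
#'   `st$tensor_stride / upstride`.
#' @export
generative_transposed_conv <- function(st, params, Ks, upstride = 1L) {
  stopifnot(inherits(st, "SparseTensor"))
  .conv_fwd(st, params, Ks, transposed = TRUE,
            upstride = as.integer(upstride))$out
}

# batch normalization over tensor rows (internal, with cache).  A
# single-row batch has no usable batch statistics (standardizing it
# would erase the features entirely — fatal at a one-point bottleneck),
# so training falls back to the running moments in that degenerate case.
.norm_fwd <- function(feats, norm, training) {
  n <- nrow(feats)
  if (n == 0L) {
    return(list(out = feats, cache = list(empty = TRUE), norm = norm))
  }
  if (training && n < 2L) training <- FALSE
  if (training) {
    mu <- colMeans(feats)
    xc <- sweep(feats, 2, mu)
    v <- colMeans(xc^2)
    norm$running_mean <- (1 - norm$momentum) * norm$running_mean +
      norm$momentum * mu
    norm$running_var <- (1 - norm$momentum) * norm$running_var +
      norm$momentum * v
  } else {
    mu <- norm$running_mean
    v <- norm$running_var
    xc <- sweep(feats, 2, mu)
  }
  invstd <- 1 / sqrt(v + norm$eps)
  xhat <- sweep(xc, 2, invstd, `*`)
  out <- sweep(sweep(xhat, 2, norm$gamma, `*`), 2, norm$beta, `+`)
  list(out = out,
       cache = list(xhat = xhat, invstd = invstd, training = training),
       norm = norm)
}

.norm_bwd <- function(norm, cache, dout) {
  if (isTRUE(cache$empty)) {
    z <- rep(0, length(norm$gamma))
    return(list(dx = dout, dgamma = z, dbeta = z))
  }
  dgamma <- colSums(dout * cache$xhat)
  dbeta <- colSums(dout)
  if (!cache$training) {
    dx <- sweep(dout, 2, norm$gamma * cache$invstd, `*`)
    return(list(dx = dx, dgamma = dgamma, dbeta = dbeta))
  }
  n <- nrow(dout)
  t1 <- sweep(dout, 2, dbeta / n)
  t2 <- sweep(cache$xhat, 2, dgamma / n, `*`)
  dx <- sweep(t1 - t2, 2, norm$gamma * cache$invstd, `*`)
  list(dx = dx, dgamma = dgamma, dbeta = dbeta)
}

#' Per-channel normalization of a sparse tensor
#'
#' Standardizes each feature channel over the rows of the batch and
#' applies an affine scale/shift.  Training mode uses batch moments and
#' updates the running moments (returned via the `"norm"` attribute);
#' inference uses the stored running moments.  A variance floor `eps`
#' keeps single-row and constant-channel batches well defined.
#'
#' @param st input [sparse_tensor()].
#' @param params a [layer_params()] whose `norm` field is set, or a bare
#'   norm list from [norm_params()].
#' @param training logical.
#' @return A [sparse_tensor()]; the (possibly updated) norm state is
#'   attached as attribute `"norm"`.
#' @export
normalize <- function(st, params, training = FALSE) {
  stopifnot(inherits(st, "SparseTensor"))
  norm <- if (inherits(params, "LayerParams")) params$norm else params
  if (is.null(norm)) stop("no normalization parameters supplied")
  r <- .norm_fwd(st$feats, norm, training)
  out <- sparse_tensor(st$coords, r$out, st$tensor_stride, check = FALSE)
  attr(out, "norm") <- r$norm
  out
}

#' Elementwise nonlinearity
#'
#' @param st input [sparse_tensor()].
#' @param kind `"relu"` or `"sigmoid"`; coordinates are unchanged.
#' @return A [sparse_tensor()].
#' @export
activation <- function(st, kind = c("relu", "sigmoid")) {
  stopifnot(inherits(st, "SparseTensor"))
  kind <- match.arg(kind)
  f <- if (kind == "relu") function(x) pmax(x, 0) else .sigmoid
  sparse_tensor(st$coords, f(st$feats), st$tensor_stride, check = FALSE)
}

.sigmoid <- function(x) 1 / (1 + exp(-x))

#' Prune points of a sparse tensor by score
#'
#' Keeps the rows whose score is at least `cfg$tau`.  In training mode
#' rows whose coordinate occurs in the ground-truth occupancy at this
#' tensor stride are kept regardless of score, so the supervision never
#' loses its positive targets; at inference only the threshold applies.
#' Pruning never introduces coordinates, and an all-pruned result is a
#' legal empty tensor that downstream layers propagate.
#'
#' @param st input [sparse_tensor()].
#' @param scores numeric vector of one score per row.
#' @param cfg a [prune_config()].
#' @param gt_occupancy integer coordinate matrix of ground-truth
#'   occupancy at `st$tensor_stride`; required in training mode.
#' @return The kept-row [sparse_tensor()]; the kept row indices are
#'   attached as attribute `"kept"`.
#' @export
prune <- function(st, scores, cfg = prune_config(), gt_occupancy = NULL) {
  stopifnot(inherits(st, "SparseTensor"))
  scores <- as.numeric(scores)
  if (length(scores) != nrow(st$coords)) {
    stop("scores (", length(scores), ") must align with tensor rows (",
         nrow(st$coords), ")")
  }
  keep <- scores >= cfg$tau
  if (cfg$training) {
    if (is.null(gt_occupancy)) {
      stop("training-mode pruning requires gt_occupancy")
    }
    if (nrow(st$coords) > 0L && nrow(gt_occupancy) > 0L) {
      hit <- lookup_rows(build_manager(gt_occupancy), st$coords)
      keep <- keep | !is.na(hit)
    }
  }
  idx <- which(keep)
  out <- sparse_tensor(st$coords[idx, , drop = FALSE],
                       st$feats[idx, , drop = FALSE],
                       st$tensor_stride, check = FALSE)
  attr(out, "kept") <- idx
  out
}

#' Dense strided 3-D convolution (reference oracle)
#'
#' A plain zero-padded ("same" for odd `Ks`) strided dense convolution
#' over a multichannel voxel array, sharing the kernel-offset
#' enumeration of the sparse engine.  It serves as the independent
#' oracle for [sparse_conv()] and as the layer primitive of the toy
#' dense baseline.
#'
#' @param x numeric 3-D array (one channel) or 4-D `X x Y x Z x Cin`
#'   array.
#' @param params a [layer_params()].
#' @param Ks kernel size.
#' @param stride 1 or 2.
#' @return A 4-D `ceiling(X/stride) x ... x Cout` array.
#' @export
dense_conv_reference <- function(x, params, Ks, stride = 1L) {
  if (length(dim(x)) == 3L) dim(x) <- c(dim(x), 1L)
  stopifnot(length(dim(x)) == 4L)
  W <- .as_weight_cube(params, Ks)
  cin <- dim(W)[1]; cout <- dim(W)[2]
  stopifnot(dim(x)[4] == cin)
  d <- dim(x)[1:3]
  s <- as.integer(stride)
  vd <- as.integer(ceiling(d / s))
  out <- array(rep(params$b, each = prod(vd)), dim = c(vd, cout))
  off <- kernel_offsets(Ks)
  for (k in seq_len(nrow(off))) {
    rngs <- lapply(1:3, function(ax) {
      dk <- off[k, ax]
      v_lo <- max(0L, as.integer(ceiling(-dk / s)))
      v_hi <- min(vd[ax] - 1L, as.integer(floor((d[ax] - 1L - dk) / s)))
      if (v_lo > v_hi) return(NULL)
      v <- v_lo:v_hi
      list(v = v + 1L, i = s * v + dk + 1L)
    })
    if (any(vapply(rngs, is.null, logical(1)))) next
    xs <- x[rngs[[1]]$i, rngs[[2]]$i, rngs[[3]]$i, , drop = FALSE]
    n <- prod(dim(xs)[1:3])
    g <- matrix(xs, n, cin) %*% W[, , k]
    out[rngs[[1]]$v, rngs[[2]]$v, rngs[[3]]$v, ] <-
      out[rngs[[1]]$v, rngs[[2]]$v, rngs[[3]]$v, , drop = FALSE] +
      array(g, dim = c(dim(xs)[1:3], cout))
  }
  out
}
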