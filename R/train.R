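#' Binary cross-entropy loss over sparse logits
#'
#' Mean over points of `-(y' log sigma(z) + (1 - y') log(1 - sigma(z)))`
#' computed in the numerically stable softplus form, so extreme logits
#' never produce non-finite values.
#'
#' @param pred_logits numeric vector of per-coordinate logits.
#' @param target 0/1 occupancy per coordinate.
#' @return Scalar loss (0 with a warning when both are empty).
#' @export
bce_loss <- function(pred_logits, target) {
  x <- as.numeric(pred_logits)
  y <- as.numeric(target)
  if (length(x) == 0L) {
    warning("BCE over an empty coordinate union: defined as 0")
    return(0)
  }
  stopifnot(length(x) == length(y))
  mean(pmax(x, 0) - x * y + log1p(exp(-abs(x))))
}

.bce_grad <- function(logits, target) {
  (.sigmoid(logits) - target) / length(logits)
}

#' Two-class squared-denominator Dice loss
#'
#' `-2 * sum_i (sum y_i o y'_i) / (sum y_i o y_i + sum y'_i o y'_i)` over
#' background (`i = 0`) and target (`i = 1`), with minimum -2 at a
#' perfect binary match.  Used by the dense reference baseline; the
#' sparse network trains with [bce_loss()].
#'
#' @param pred numeric array of foreground probabilities on a dense grid.
#' @param target binary array of the same shape.
#' @return Scalar loss in `[-2, 0]`.
#' @export
dice_loss <- function(pred, target) {
  stopifnot(length(pred) == length(target))
  p <- as.numeric(pred)
  y <- as.numeric(target)
  total <- 0
  for (cls in 0:1) {
    pc <- if (cls == 1L) p else 1 - p
    yc <- if (cls == 1L) y else 1 - y
    num <- sum(pc * yc)
    den <- sum(pc * pc) + sum(yc * yc)
    if (den > 0) total <- total + num / den
  }
  -2 * total
}

#' Training configuration
#'
#' @param task `"completion"` or `"superres"`.
#' @param ch 7-element channel list (see [network_config()]).
#' @param epochs number of passes over the training set.
#' @param lr Adam learning rate.
#' @param optimizer only `"adam"` (beta 0.9/0.999) is provided.
#' @param tau pruning threshold used in training and inference.
#' @param seed integer seed controlling initialization and shuffling;
#'   recorded in every checkpoint.
#' @param loss_weights list with `final` and `stage` weights for the
#'   final BCE and the per-stage pruning BCEs.
#' @param batch_size samples per optimizer step (default 1).
#' @param union_input at prediction time, unite the output with the
#'   input coordinates (the completion target contains the input by
#'   definition; default off, the network is trained toward it).
#' @param checkpoint_every epochs between history snapshots (0 = end
#'   only).
#' @return An object of class `TrainConfig`.
#' @export
train_config <- function(task = c("completion", "superres"),
                         ch = c(4L, 4L, 8L, 8L, 16L, 16L, 32L),
                         epochs = 10L, lr = 1e-3, optimizer = "adam",
                         tau = 0, seed = 1L,
                         loss_weights = list(final = 1, stage = 1),
                         batch_size = 1L, union_input = FALSE,
                         checkpoint_every = 0L) {
  stopifnot(epochs >= 1L, lr >= 0, optimizer == "adam")
  structure(list(task = match.arg(task), ch = as.integer(ch),
                 epochs = as.integer(epochs), lr = lr, optimizer = optimizer,
                 tau = tau, seed = as.integer(seed),
                 loss_weights = loss_weights,
                 batch_size = as.integer(batch_size),
                 union_input = isTRUE(union_input),
                 checkpoint_every = as.integer(checkpoint_every)),
            class = "TrainConfig")
}

# ground-truth occupancy coordinates at each required tensor stride,
# by occupancy-preserving block-max coarsening of the target grid
.gt_coords_by_stride <- function(grid, strides) {
  out <- list()
  for (s in sort(unique(as.integer(strides)))) {
    cc <- if (s == 1L) {
      dense_to_sparse(grid)$coords
    } else {
      suppressMessages(dense_to_sparse(downsample(grid, s))$coords * s)
    }
    out[[as.character(s)]] <- cc
  }
  out
}

# full forward pass; records a tape for backpropagation and returns the
# per-stage scoring logits/targets plus the final logits.  `bounds`
# clips generatively created coordinates to the voxel domain
# [0, bounds): points outside the grid are definitionally empty (zero
# padding), and dropping them early prevents the unbounded
# over-generation failure mode of untrained generative decoders.
.net_forward <- function(net, st, training = FALSE, gt_coords = NULL,
                         tau = net$cfg$tau, bounds = NULL) {
  if (training && is.null(gt_coords)) {
    stop("training-mode forward requires ground-truth occupancy")
  }
  tape <- vector("list", 3L * length(net$specs))
  ti <- 0L
  push <- function(op) {
    ti <<- ti + 1L
    tape[[ti]] <<- op
  }
  x <- st
  stages <- list()
  final <- NULL
  for (i in seq_along(net$specs)) {
    s <- net$specs[[i]]
    if (s$role %in% c("conv", "strided-conv", "generative-transposed-conv")) {
      transposed <- s$role == "generative-transposed-conv"
      r <- .conv_fwd(x, net$params[[i]], s$ks,
                     stride = if (transposed) 1L else s$stride,
                     transposed = transposed,
                     upstride = if (transposed) s$stride else 1L)
      push(list(type = "conv", i = i, cache = r$cache))
      x <- r$out
      if (transposed && !is.null(bounds)) {
        cc <- x$coords
        inb <- cc[, 1] >= 0L & cc[, 1] < bounds[1] &
          cc[, 2] >= 0L & cc[, 2] < bounds[2] &
          cc[, 3] >= 0L & cc[, 3] < bounds[3]
        if (!all(inb)) {
          idx <- which(inb)
          push(list(type = "prune", kept = idx, n_before = nrow(cc),
                    channels = ncol(x$feats)))
          x <- sparse_tensor(cc[idx, , drop = FALSE],
                             x$feats[idx, , drop = FALSE],
                             x$tensor_stride, check = FALSE)
        }
      }
      if (!is.null(net$params[[i]]$norm)) {
        rn <- .norm_fwd(x$feats, net$params[[i]]$norm, training)
        net$params[[i]]$norm <- rn$norm
        x$feats <- rn$out
        push(list(type = "norm", i = i, cache = rn$cache))
      }
      if (identical(s$act, "relu")) {
        mask <- x$feats > 0
        x$feats <- x$feats * mask
        push(list(type = "relu", mask = mask))
      }
    } else if (s$role == "scoring-conv") {
      r <- .conv_fwd(x, net$params[[i]], 1L)
      z <- r$out$feats[, 1]
      push(list(type = "scoring", i = i, cache = r$cache, stage = s$stage))
      y <- NULL
      if (!is.null(gt_coords)) {
        gtc <- gt_coords[[as.character(x$tensor_stride)]]
        y <- if (is.null(gtc) || nrow(x$coords) == 0L) {
          rep(0, nrow(x$coords))
        } else {
          as.numeric(!is.na(lookup_rows(build_manager(gtc), x$coords)))
        }
      }
      keep <- z >= tau
      if (training) keep <- keep | (y >= 1)
      idx <- which(keep)
      push(list(type = "prune", kept = idx, n_before = nrow(x$coords),
                channels = ncol(x$feats)))
      stages[[s$stage]] <- list(logits = z, target = y,
                                stride = x$tensor_stride,
                                n_before = nrow(x$coords),
                                n_kept = length(idx),
                                n_score_kept = sum(z >= tau))
      x <- sparse_tensor(x$coords[idx, , drop = FALSE],
                         x$feats[idx, , drop = FALSE],
                         x$tensor_stride, check = FALSE)
    } else { # final-projection
      r <- .conv_fwd(x, net$params[[i]], 1L)
      push(list(type = "final", i = i, cache = r$cache))
      yf <- NULL
      if (!is.null(gt_coords)) {
        gtc <- gt_coords[[as.character(x$tensor_stride)]]
        yf <- if (is.null(gtc) || nrow(x$coords) == 0L) {
          rep(0, nrow(x$coords))
        } else {
          as.numeric(!is.na(lookup_rows(build_manager(gtc), x$coords)))
        }
      }
      final <- list(coords = x$coords, logits = r$out$feats[, 1],
                    target = yf, tensor_stride = x$tensor_stride)
    }
  }
  list(net = net, final = final, stages = stages,
       tape = tape[seq_len(ti)])
}

.zero_like_grads <- function(params) {
  lapply(params, function(p) {
    g <- list(W = array(0, dim(p$W)), b = numeric(length(p$b)))
    if (!is.null(p$norm)) {
      g$gamma <- numeric(length(p$norm$gamma))
      g$beta <- numeric(length(p$norm$beta))
    }
    g
  })
}

.net_backward <- function(net, fwd, d_final, d_stage) {
  grads <- .zero_like_grads(net$params)
  g <- NULL
  for (op in rev(fwd$tape)) {
    if (op$type == "final") {
      r <- .conv_bwd(net$params[[op$i]], op$cache, matrix(d_final, ncol = 1))
      grads[[op$i]]$W <- grads[[op$i]]$W + r$dW
      grads[[op$i]]$b <- grads[[op$i]]$b + r$db
      g <- r$dfin
    } else if (op$type == "prune") {
      gp <- matrix(0, op$n_before, op$channels)
      if (length(op$kept) > 0L && !is.null(g) && nrow(g) > 0L) {
        gp[op$kept, ] <- g
      }
      g <- gp
    } else if (op$type == "scoring") {
      dz <- d_stage[[op$stage]]
      r <- .conv_bwd(net$params[[op$i]], op$cache, matrix(dz, ncol = 1))
      grads[[op$i]]$W <- grads[[op$i]]$W + r$dW
      grads[[op$i]]$b <- grads[[op$i]]$b + r$db
      g <- g + r$dfin
    } else if (op$type == "relu") {
      g <- g * op$mask
    } else if (op$type == "norm") {
      r <- .norm_bwd(net$params[[op$i]]$norm, op$cache, g)
      grads[[op$i]]$gamma <- grads[[op$i]]$gamma + r$dgamma
      grads[[op$i]]$beta <- grads[[op$i]]$beta + r$dbeta
      g <- r$dx
    } else if (op$type == "conv") {
      r <- .conv_bwd(net$params[[op$i]], op$cache, g)
      grads[[op$i]]$W <- grads[[op$i]]$W + r$dW
      grads[[op$i]]$b <- grads[[op$i]]$b + r$db
      g <- r$dfin
    }
  }
  grads
}

#' Total task loss with gradients
#'
#' Runs one training-mode forward pass (ground-truth-guided pruning),
#' assembles the loss `w_final * BCE(final) + w_stage * sum_j
#' BCE(stage_j)` — the final BCE over the coordinates surviving the
#' decoder, the per-stage BCEs supervising each pruning score against
#' the block-max coarsened target occupancy — and backpropagates it
#' through the tape.
#'
#' @param net a [build_network()] network.
#' @param input_grid defective (or up-scaled coarse) [voxel_grid()].
#' @param target_grid complete (or high-resolution) [voxel_grid()].
#' @param weights list with `final` and `stage` loss weights.
#' @param tau pruning threshold.
#' @param with_grads compute gradients (set `FALSE` for evaluation).
#' @return List with `loss`, the per-part `loss_final` / `loss_stages`,
#'   `grads` (aligned with `net$params`), the updated `net` (running
#'   normalization moments), and the forward record `fwd`.
#' @export
network_loss <- function(net, input_grid, target_grid,
                         weights = list(final = 1, stage = 1), tau = 0,
                         with_grads = TRUE) {
  st <- dense_to_sparse(input_grid)
  gt <- .gt_coords_by_stride(target_grid, c(1L, 2L^(1:6)))
  .loss_step(net, st, gt, dim(input_grid$data), weights, tau, with_grads)
}

# core training step on precomputed tensors (shared by network_loss and
# the training loops, which cache inputs and ground-truth pyramids)
.loss_step <- function(net, st, gt, bounds, weights, tau, with_grads = TRUE) {
  fwd <- .net_forward(net, st, training = TRUE, gt_coords = gt, tau = tau,
                      bounds = bounds)
  l_final <- bce_loss(fwd$final$logits, fwd$final$target)
  l_stages <- vapply(fwd$stages, function(sg) bce_loss(sg$logits, sg$target),
                     numeric(1))
  loss <- weights$final * l_final + weights$stage * sum(l_stages)
  grads <- NULL
  if (with_grads) {
    d_final <- weights$final * .bce_grad(fwd$final$logits, fwd$final$target)
    d_stage <- lapply(fwd$stages, function(sg) {
      weights$stage * .bce_grad(sg$logits, sg$target)
    })
    grads <- .net_backward(fwd$net, fwd, d_final, d_stage)
  }
  list(loss = loss, loss_final = l_final, loss_stages = l_stages,
       grads = grads, net = fwd$net, fwd = fwd)
}

.adam_init <- function(params) {
  lapply(params, function(p) {
    s <- list(mW = array(0, dim(p$W)), vW = array(0, dim(p$W)),
              mb = numeric(length(p$b)), vb = numeric(length(p$b)))
    if (!is.null(p$norm)) {
      s$mg <- numeric(length(p$norm$gamma)); s$vg <- s$mg
      s$mB <- numeric(length(p$norm$beta)); s$vB <- s$mB
    }
    s
  })
}

.adam_step <- function(params, grads, state, t, lr,
                       beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  corr1 <- 1 - beta1^t
  corr2 <- 1 - beta2^t
  upd <- function(x, g, m, v) {
    m <- beta1 * m + (1 - beta1) * g
    v <- beta2 * v + (1 - beta2) * g^2
    x <- x - lr * (m / corr1) / (sqrt(v / corr2) + eps)
    list(x = x, m = m, v = v)
  }
  for (i in seq_along(params)) {
    gi <- grads[[i]]
    u <- upd(params[[i]]$W, gi$W, state[[i]]$mW, state[[i]]$vW)
    params[[i]]$W <- u$x; state[[i]]$mW <- u$m; state[[i]]$vW <- u$v
    u <- upd(params[[i]]$b, gi$b, state[[i]]$mb, state[[i]]$vb)
    params[[i]]$b <- u$x; state[[i]]$mb <- u$m; state[[i]]$vb <- u$v
    if (!is.null(params[[i]]$norm)) {
      u <- upd(params[[i]]$norm$gamma, gi$gamma, state[[i]]$mg, state[[i]]$vg)
      params[[i]]$norm$gamma <- u$x; state[[i]]$mg <- u$m; state[[i]]$vg <- u$v
      u <- upd(params[[i]]$norm$beta, gi$beta, state[[i]]$mB, state[[i]]$vB)
      params[[i]]$norm$beta <- u$x; state[[i]]$mB <- u$m; state[[i]]$vB <- u$v
    }
  }
  list(params = params, state = state)
}

.train_loop <- function(dataset, cfg, task) {
  stopifnot(length(dataset) >= 1L)
  netcfg <- network_config(cfg$ch, task = task, tau = cfg$tau)
  net <- build_network(netcfg, seed = cfg$seed)
  input_field <- if (task == "completion") "defective" else "input"
  target_field <- if (task == "completion") "complete" else "target"
  inputs <- lapply(dataset, `[[`, input_field)
  targets <- lapply(dataset, `[[`, target_field)
  if (task == "superres") {
    ok <- mapply(function(a, b) identical(dim(a$data), dim(b$data)),
                 inputs, targets)
    if (!all(ok)) {
      stop("super-resolution input and target must live on the same ",
           "lattice; up-scale the coarse grid first")
    }
  }
  state <- .adam_init(net$params)
  sts <- lapply(inputs, dense_to_sparse)
  gts <- lapply(targets, .gt_coords_by_stride, strides = c(1L, 2L^(1:6)))
  bounds_l <- lapply(inputs, function(g) dim(g$data))
  set.seed(cfg$seed)
  history <- list()
  t_step <- 0L
  empty_epochs <- 0L
  for (epoch in seq_len(cfg$epochs)) {
    ord <- sample(length(dataset))
    losses <- numeric(0)
    any_score_kept <- FALSE
    for (si in ord) {
      r <- .loss_step(net, sts[[si]], gts[[si]], bounds_l[[si]],
                      cfg$loss_weights, cfg$tau)
      net <- r$net
      if (cfg$lr > 0) {
        t_step <- t_step + 1L
        a <- .adam_step(net$params, r$grads, state, t_step, cfg$lr)
        net$params <- a$params
        state <- a$state
      }
      losses <- c(losses, r$loss)
      last <- r$fwd$stages[[length(r$fwd$stages)]]
      if (!is.null(last) && last$n_score_kept > 0L) any_score_kept <- TRUE
    }
    empty_epochs <- if (any_score_kept) 0L else empty_epochs + 1L
    if (empty_epochs >= 5L) {
      stop("over-pruning: no point passed the score threshold in any ",
           "sample for ", empty_epochs, " consecutive epochs (last: ",
           epoch, "); consider a larger scoring bias or lower tau")
    }
    history[[epoch]] <- data.frame(epoch = epoch, loss = mean(losses))
  }
  list(net = net, cfg = cfg, seed = cfg$seed,
       history = do.call(rbind, history), version = "sparsevox-ckpt-1")
}

#' Train the sparse completion network
#'
#' Per step: a training-mode forward pass (ground-truth-guided pruning
#' at every decoder stage), the combined final + per-stage BCE loss, and
#' an Adam update.  Fully reproducible given the configuration seed.
#'
#' @param dataset list of completion samples, each a list with
#'   `defective`, `complete` (and typically `implant`) [voxel_grid()]s —
#'   as produced by [make_dataset()].
#' @param cfg a [train_config()].
#' @return A checkpoint: `list(net, cfg, seed, history, version)`;
#'   `history` holds one row of mean training loss per epoch.
#' @export
train_completion <- function(dataset, cfg = train_config("completion")) {
  .train_loop(dataset, cfg, "completion")
}

#' Train the sparse super-resolution network
#'
#' The same machinery as [train_completion()] with the up-scaled coarse
#' grid as input and the high-resolution grid as target: the network
#' both prunes misplaced input points and generates missing detail
#' points.  Input and target must be on the same lattice.
#'
#' @param dataset list of super-resolution samples, each a list with
#'   `input` (up-scaled coarse [voxel_grid()]) and `target`
#'   (high-resolution [voxel_grid()]).
#' @param cfg a [train_config()].
#' @return A checkpoint (see [train_completion()]).
#' @export
train_superres <- function(dataset, cfg = train_config("superres")) {
  .train_loop(dataset, cfg, "superres")
}

#' Predict with a trained network
#'
#' Inference forward pass: pruning uses only the score threshold `tau`
#' (no ground truth), and the predicted occupancy is the set of
#' coordinates surviving the final pruning stage whose sigmoid output
#' exceeds 0.5, densified onto the input lattice.  Coordinates generated
#' outside the grid bounds are dropped.
#'
#' @param checkpoint a checkpoint from [train_completion()] /
#'   [train_superres()] (or a bare `SparseNetwork`).
#' @param grid input [voxel_grid()].
#' @param task unused placeholder kept for interface symmetry; the task
#'   is recorded in the checkpoint configuration.
#' @param union_input unite the prediction with the input occupancy
#'   (defaults to the training configuration's setting).
#' @return A predicted [voxel_grid()] of the input shape.
#' @export
predict_grid <- function(checkpoint, grid, task = NULL, union_input = NULL) {
  net <- if (inherits(checkpoint, "SparseNetwork")) checkpoint else checkpoint$net
  if (!inherits(net, "SparseNetwork")) {
    stop("checkpoint does not contain a SparseNetwork (version mismatch?)")
  }
  tau <- net$cfg$tau
  if (is.null(union_input)) {
    union_input <- isTRUE(checkpoint$cfg$union_input)
  }
  st <- dense_to_sparse(grid)
  if (nrow(st$coords) == 0L) {
    return(voxel_grid(array(0L, dim(grid$data)), grid$spacing, grid$origin))
  }
  fwd <- .net_forward(net, st, training = FALSE, tau = tau,
                      bounds = dim(grid$data))
  cc <- fwd$final$coords
  keep <- .sigmoid(fwd$final$logits) > 0.5
  cc <- cc[keep, , drop = FALSE]
  shape <- dim(grid$data)
  inb <- cc[, 1] >= 0L & cc[, 1] < shape[1] &
    cc[, 2] >= 0L & cc[, 2] < shape[2] &
    cc[, 3] >= 0L & cc[, 3] < shape[3]
  cc <- cc[inb, , drop = FALSE]
  arr <- array(0L, dim = shape)
  if (nrow(cc) > 0L) arr[cc + 1L] <- 1L
  if (union_input) arr <- pmax(arr, grid$data)
  voxel_grid(arr, grid$spacing, grid$origin)
}
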