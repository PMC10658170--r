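test_that("identity kernels reproduce their input", {
  st <- random_tensor(n = 40, extent = 10, channels = 3, seed = 2)
  p <- layer_params(array(diag(3), dim = c(3, 3, 1)), rep(0, 3))
  out <- sparse_conv(st, p, Ks = 1)
  expect_equal(out$coords, st$coords)
  expect_equal(out$feats, st$feats, tolerance = 1e-12)
})

test_that("an isolated point only sees the center offset", {
  st <- sparse_tensor(matrix(c(5L, 5L, 5L), 1), matrix(1))
  p <- layer_params(array(1, dim = c(1, 1, 27)), 0)
  out <- sparse_conv(st, p, Ks = 3)
  expect_equal(out$feats[1, 1], 1)
})

test_that("sparse convolution agrees with the dense reference oracle", {
  for (case in 1:12) {
    set.seed(100 + case)
    Ks <- sample(c(1L, 2L, 3L, 4L), 1)
    stride <- sample(c(1L, 2L), 1)
    cin <- sample(1:3, 1); cout <- sample(1:3, 1)
    g <- array(0, dim = c(12, 12, 12, cin))
    occ <- array(runif(12^3) < 0.2, dim = c(12, 12, 12))
    for (ch in seq_len(cin)) g[, , , ch][occ] <- rnorm(sum(occ))
    p <- random_params(cin, cout, Ks, seed = case)
    dense <- dense_conv_reference(g, p, Ks, stride)
    cc <- which(occ, arr.ind = TRUE) - 1L
    storage.mode(cc) <- "integer"
    feats <- matrix(0, nrow(cc), cin)
    for (ch in seq_len(cin)) feats[, ch] <- g[, , , ch][occ]
    st <- sparse_tensor(cc, feats)
    out <- sparse_conv(st, p, Ks, stride)
    for (r in seq_len(nrow(out$coords))) {
      v <- out$coords[r, ] / stride
      expect_equal(out$feats[r, ], dense[v[1] + 1, v[2] + 1, v[3] + 1, ],
                   tolerance = 1e-6)
    }
  }
})

test_that("the dense reference has the expected impulse response", {
  g <- array(0, c(7, 7, 7)); g[4, 4, 4] <- 1
  p <- random_params(1, 1, 3, seed = 5)
  out <- dense_conv_reference(g, p, 3, 1)
  off <- kernel_offsets(3)
  # cross-correlation convention: the response is the reflected kernel
  for (k in seq_len(27)) {
    expect_equal(out[4 - off[k, 1], 4 - off[k, 2], 4 - off[k, 3], 1],
                 p$W[1, 1, k] + p$b, tolerance = 1e-12,
                 label = paste("offset", k))
  }
  # all-zero input gives the bias everywhere
  z <- dense_conv_reference(array(0, c(5, 5, 5)), p, 3, 1)
  expect_true(all(abs(z - p$b) < 1e-12))
})

test_that("generative transposed convolutions expand the kernel span", {
  st <- sparse_tensor(matrix(c(0L, 0L, 0L), 1), matrix(1))
  p <- random_params(1, 1, 3, seed = 1)
  out <- generative_transposed_conv(st, p, Ks = 3, upstride = 1)
  expect_equal(nrow(out$coords), 27L)
  expect_equal(range(out$coords), c(-1L, 1L))
  # identity 1x1x1 creates no new points
  pid <- layer_params(array(1, c(1, 1, 1)), 0)
  out1 <- generative_transposed_conv(st, pid, Ks = 1, upstride = 1)
  expect_equal(out1$coords, st$coords)
  expect_equal(out1$feats, st$feats)
  # two points sharing a face of their spans: 27 + 27 - 9
  st2 <- sparse_tensor(rbind(c(0L, 0L, 0L), c(2L, 0L, 0L)))
  out2 <- generative_transposed_conv(st2, p, Ks = 3, upstride = 1)
  expect_equal(nrow(out2$coords), 45L)
})

test_that("generative outputs satisfy the kernel-span neighbor constraint", {
  st <- random_tensor(n = 60, extent = 16, seed = 9, tensor_stride = 2L)
  for (Ks in c(2L, 3L)) {
    p <- random_params(1, 2, Ks, seed = Ks)
    out <- generative_transposed_conv(st, p, Ks, upstride = 2)
    expect_equal(out$tensor_stride, 1L)
    off <- kernel_offsets(Ks)
    # brute force: every output coordinate equals input + offset exactly,
    # and every such candidate appears exactly once
    want <- unique(do.call(rbind, lapply(seq_len(nrow(st$coords)), function(i) {
      sweep(off, 2, st$coords[i, ], `+`)
    })))
    key <- function(m) paste(m[, 1], m[, 2], m[, 3])
    expect_setequal(key(out$coords), key(want))
    # features match direct summation over contributing inputs
    for (r in sample(nrow(out$coords), 10)) {
      oc <- out$coords[r, ]
      acc <- p$b
      for (i in seq_len(nrow(st$coords))) {
        d <- oc - st$coords[i, ]
        k <- which(off[, 1] == d[1] & off[, 2] == d[2] & off[, 3] == d[3])
        if (length(k) == 1) acc <- acc + st$feats[i, ] %*% p$W[, , k]
      }
      expect_equal(out$feats[r, ], as.numeric(acc), tolerance = 1e-10)
    }
  }
})

test_that("permuting input rows permutes nothing observable", {
  st <- random_tensor(n = 80, extent = 12, channels = 2, seed = 12)
  set.seed(99)
  perm <- sample(nrow(st$coords))
  stp <- sparse_tensor(st$coords[perm, , drop = FALSE],
                       st$feats[perm, , drop = FALSE])
  p <- random_params(2, 3, 3, seed = 7)
  a <- sparse_conv(st, p, 3)
  b <- sparse_conv(stp, p, 3)
  key <- function(m) paste(m[, 1], m[, 2], m[, 3])
  ka <- key(a$coords); kb <- key(b$coords)
  expect_setequal(ka, kb)
  expect_equal(a$feats[order(ka), ], b$feats[order(kb), ], tolerance = 1e-12)
})

test_that("sparse convolution is linear in its features at zero bias", {
  st <- random_tensor(n = 50, extent = 10, channels = 2, seed = 3)
  p <- random_params(2, 2, 3, seed = 4)
  p$b <- rep(0, 2)
  f2 <- matrix(rnorm(length(st$feats)), nrow(st$feats))
  st2 <- sparse_tensor(st$coords, f2)
  stc <- sparse_tensor(st$coords, 2 * st$feats - 3 * f2)
  lhs <- sparse_conv(stc, p, 3)$feats
  rhs <- 2 * sparse_conv(st, p, 3)$feats - 3 * sparse_conv(st2, p, 3)$feats
  expect_equal(lhs, rhs, tolerance = 1e-10)
})

test_that("pruning keeps scores >= tau and never invents coordinates", {
  st <- sparse_tensor(rbind(c(0L, 0L, 0L), c(1L, 0L, 0L)),
                      matrix(c(1, 2), ncol = 1))
  out <- prune(st, c(0.5, -0.5), prune_config(tau = 0))
  expect_equal(out$coords, st$coords[1, , drop = FALSE])
  # all pruned is a legal empty tensor
  empty <- prune(st, c(-1, -2), prune_config(tau = 0))
  expect_equal(nrow(empty$coords), 0L)
  expect_equal(ncol(empty$feats), 1L)
  # training mode: ground truth rescues its rows
  st10 <- random_tensor(n = 10, extent = 4, seed = 20)
  gt <- st10$coords[c(2, 5, 7), , drop = FALSE]
  kept <- prune(st10, rep(-1, nrow(st10$coords)),
                prune_config(tau = 0, training = TRUE), gt_occupancy = gt)
  expect_equal(nrow(kept$coords), 3L)
  expect_setequal(paste(kept$coords[, 1], kept$coords[, 2], kept$coords[, 3]),
                  paste(gt[, 1], gt[, 2], gt[, 3]))
  expect_error(prune(st10, rep(1, 10), prune_config(training = TRUE)),
               "gt_occupancy")
  expect_error(prune(st, c(1, 2, 3)), "align")
})

test_that("normalization standardizes, floors variance, updates moments", {
  set.seed(6)
  f <- matrix(as.vector(scale(matrix(rnorm(300), 100, 3))), 100, 3) *
    sqrt(100 / 99)  # population sd 1, mean 0
  st <- sparse_tensor(unique(matrix(as.integer(floor(runif(600, 0, 20))),
                                    ncol = 3))[1:100, ], f)
  out <- normalize(st, norm_params(3), training = TRUE)
  expect_equal(out$feats, st$feats, tolerance = 1e-4)
  # constant column collapses to the shift value
  stc <- sparse_tensor(st$coords, matrix(5, 100, 3))
  np <- norm_params(3); np$beta <- c(1, 2, 3)
  outc <- normalize(stc, np, training = TRUE)
  expect_equal(unname(colMeans(outc$feats)), c(1, 2, 3), tolerance = 1e-10)
  # single row stays finite
  st1 <- sparse_tensor(matrix(c(0L, 0L, 0L), 1), matrix(c(4, -2, 0), 1))
  out1 <- normalize(st1, norm_params(3), training = TRUE)
  expect_true(all(is.finite(out1$feats)))
  # inference uses running moments
  np2 <- norm_params(1)
  np2$running_mean <- 10; np2$running_var <- 4
  sti <- sparse_tensor(matrix(c(0L, 0L, 0L), 1), matrix(12))
  outi <- normalize(sti, np2, training = FALSE)
  expect_equal(outi$feats[1, 1], (12 - 10) / sqrt(4 + 1e-5), tolerance = 1e-6)
})

test_that("activations are elementwise and preserve order", {
  st <- random_tensor(n = 30, extent = 8, seed = 15)
  expect_equal(activation(st, "sigmoid")$feats[st$feats == 0], numeric(0))
  s0 <- sparse_tensor(matrix(c(0L, 0L, 0L), 1), matrix(0))
  expect_equal(activation(s0, "sigmoid")$feats[1, 1], 0.5)
  sm <- sparse_tensor(matrix(c(0L, 0L, 0L), 1), matrix(-3))
  expect_equal(activation(sm, "relu")$feats[1, 1], 0)
  sg <- activation(st, "sigmoid")
  expect_equal(order(st$feats), order(sg$feats))  # monotone
  expect_equal(sg$coords, st$coords)
})

test_that("empty tensors propagate through every layer type", {
  e <- sparse_tensor(matrix(integer(0), 0, 3), matrix(numeric(0), 0, 2))
  p <- random_params(2, 3, 3, seed = 30, norm = TRUE)
  out <- sparse_conv(e, p, 3)
  expect_equal(nrow(out$coords), 0L)
  expect_equal(ncol(out$feats), 3L)
  gen <- generative_transposed_conv(e, p, 3, upstride = 1)
  expect_equal(nrow(gen$coords), 0L)
  nrm <- normalize(sparse_conv(e, p, 3), p$norm, training = TRUE)
  expect_equal(nrow(nrm$feats), 0L)
  act <- activation(e, "relu")
  expect_equal(nrow(act$feats), 0L)
  pr <- prune(e, numeric(0))
  expect_equal(nrow(pr$coords), 0L)
})
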