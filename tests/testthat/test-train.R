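test_that("BCE loss matches its closed forms and an elementwise oracle", {
  expect_equal(bce_loss(0, 1), log(2), tolerance = 1e-12)  # -log(0.5)
  expect_lt(bce_loss(30, 1), 1e-12)                        # limit to 0
  expect_lt(bce_loss(-30, 0), 1e-12)
  expect_true(is.finite(bce_loss(1000, 0)))                # no overflow
  set.seed(5)
  z <- rnorm(100, sd = 3); y <- rbinom(100, 1, 0.4)
  oracle <- -mean(y * log(plogis(z)) + (1 - y) * log(1 - plogis(z)))
  expect_equal(bce_loss(z, y), oracle, tolerance = 1e-8)
  expect_warning(v <- bce_loss(numeric(0), numeric(0)), "empty")
  expect_equal(v, 0)
})

test_that("Dice loss reproduces the two-class squared-denominator form", {
  y <- array(as.integer(runif(4^3) < 0.3), c(4, 4, 4))
  expect_equal(dice_loss(y, y), -2)
  # total mismatch (both classes nonempty) zeroes both numerators
  expect_equal(dice_loss(1 - y, y), 0)
  set.seed(6)
  p <- array(runif(4^3), c(4, 4, 4))
  oracle <- -2 * (sum(p * y) / (sum(p^2) + sum(y^2)) +
                    sum((1 - p) * (1 - y)) / (sum((1 - p)^2) + sum((1 - y)^2)))
  expect_equal(dice_loss(p, y), oracle, tolerance = 1e-8)
})

test_that("a zero learning rate leaves parameters untouched", {
  smp <- tiny_completion_sample(16, seed = 3)
  cfg <- train_config("completion", ch = rep(2L, 7), epochs = 1, lr = 0,
                      seed = 2)
  ck <- suppressMessages(train_completion(list(smp), cfg))
  ref <- build_network(network_config(rep(2L, 7), tau = 0), seed = 2)
  for (i in seq_along(ref$params)) {
    expect_identical(ck$net$params[[i]]$W, ref$params[[i]]$W)
    expect_identical(ck$net$params[[i]]$b, ref$params[[i]]$b)
  }
})

test_that("training is bit-reproducible from the seed", {
  smp <- tiny_completion_sample(16, seed = 3)
  cfg <- train_config("completion", ch = rep(2L, 7), epochs = 2, lr = 1e-3,
                      seed = 5)
  a <- suppressMessages(train_completion(list(smp), cfg))
  b <- suppressMessages(train_completion(list(smp), cfg))
  expect_identical(serialize(a$net$params, NULL),
                   serialize(b$net$params, NULL))
  expect_identical(a$history, b$history)
})

test_that("teacher forcing keeps every reachable ground-truth coordinate", {
  smp <- tiny_completion_sample(16, seed = 3)
  net <- build_network(network_config(c(2, 2, 4, 4, 4, 4, 8)), seed = 1)
  st <- dense_to_sparse(smp$defective)
  gt <- sparsevox:::.gt_coords_by_stride(smp$complete, c(1L, 2L^(1:6)))
  fwd <- sparsevox:::.net_forward(net, st, training = TRUE, gt_coords = gt,
                                  tau = 0, bounds = rep(16L, 3))
  # the final coordinate set contains all stride-1 ground-truth points
  hits <- lookup_rows(build_manager(fwd$final$coords), gt[["1"]])
  expect_false(anyNA(hits))
  expect_equal(sum(fwd$final$target), nrow(gt[["1"]]))
})

test_that("an untrained network predicts a non-empty grid (scoring bias)", {
  smp <- tiny_completion_sample(16, seed = 4)
  net <- build_network(network_config(c(2, 2, 4, 4, 4, 4, 8)), seed = 9)
  p <- predict_grid(net, smp$defective)
  expect_gt(nnz(p), 0)
  # an empty input grid predicts an empty output grid
  e <- voxel_grid(array(0L, c(16, 16, 16)))
  expect_equal(nnz(predict_grid(net, e)), 0)
})

test_that("overfitting one sample restores its own skull", {
  smp <- tiny_completion_sample(16, seed = 3)
  cfg <- train_config("completion", ch = c(4L, 4L, 8L, 8L, 16L, 16L, 32L),
                      epochs = 300, lr = 3e-3, seed = 1)
  ck <- suppressMessages(train_completion(list(smp), cfg))
  loss <- ck$history$loss
  # epoch-averaged loss decreases over training
  thirds <- split(loss, cut(seq_along(loss), 3))
  expect_true(all(diff(vapply(thirds, mean, numeric(1))) < 0))
  p <- predict_grid(ck, smp$defective)
  expect_gt(dsc(p, smp$complete), 0.95)
})

test_that("super-resolution requires a shared lattice and learns detail", {
  ds <- suppressMessages(make_dataset(2, resolutions = c(16, 32),
                                      task = "superres", seed = 21))
  bad <- list(list(input = ds$samples[[1]]$coarse,
                   target = ds$samples[[1]]$target))
  cfg <- train_config("superres", ch = rep(2L, 7), epochs = 1, seed = 1)
  expect_error(train_superres(bad, cfg), "lattice")
  # identity case: coarse equals the target (factor-1 pair) is learnable
  # to near-perfect DSC
  g <- make_shell(shell_spec(size = 16, seed = 31))
  cfg2 <- train_config("superres", ch = c(4L, 4L, 8L, 8L, 16L, 16L, 32L),
                       epochs = 350, lr = 3e-3, seed = 2)
  ck <- suppressMessages(train_superres(list(list(input = g, target = g)),
                                        cfg2))
  p <- predict_grid(ck, g)
  expect_gt(dsc(p, g), 0.95)
})

test_that("gradients of the completion loss pass a finite-difference check", {
  smp <- tiny_completion_sample(12, seed = 8)
  net <- build_network(network_config(rep(4L, 7)), seed = 3)
  # randomize every parameter so no ReLU or pruning score sits exactly at
  # its switching point (the zero-initialized shifts do at build time)
  set.seed(11)
  for (i in seq_along(net$params)) {
    net$params[[i]]$W <- net$params[[i]]$W +
      array(rnorm(length(net$params[[i]]$W), sd = 0.05),
            dim = dim(net$params[[i]]$W))
    net$params[[i]]$b <- net$params[[i]]$b +
      rnorm(length(net$params[[i]]$b), sd = 0.05)
    if (!is.null(net$params[[i]]$norm)) {
      net$params[[i]]$norm$gamma <- net$params[[i]]$norm$gamma +
        rnorm(length(net$params[[i]]$norm$gamma), sd = 0.05)
      net$params[[i]]$norm$beta <- rnorm(length(net$params[[i]]$norm$beta),
                                         sd = 0.05)
    }
  }
  r <- network_loss(net, smp$defective, smp$complete)
  h <- 1e-5
  set.seed(12)
  checked <- 0L
  while (checked < 20L) {
    i <- sample(length(net$params), 1)
    field <- sample(c("W", "b"), 1)
    j <- sample(length(net$params[[i]][[field]]), 1)
    ana <- r$grads[[i]][[field]][j]
    if (abs(ana) < 1e-6) next  # measure-zero dead path, no signal to compare
    n1 <- net; n1$params[[i]][[field]][j] <- n1$params[[i]][[field]][j] + h
    n2 <- net; n2$params[[i]][[field]][j] <- n2$params[[i]][[field]][j] - h
    fd <- (network_loss(n1, smp$defective, smp$complete, with_grads = FALSE)$loss -
             network_loss(n2, smp$defective, smp$complete, with_grads = FALSE)$loss) /
      (2 * h)
    expect_lt(abs(ana - fd) / max(abs(ana), abs(fd)), 1e-3)
    checked <- checked + 1L
  }
})
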