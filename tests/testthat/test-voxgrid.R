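test_that("grids round-trip through every on-disk format", {
  g <- random_grid(8, 0.3, seed = 42)
  for (ext in c("nrrd", "nii.gz", "rds")) {
    path <- file.path(tempdir(), paste0("rt.", ext))
    write_grid(g, path)
    back <- read_grid(path)
    expect_identical(back$data, g$data, label = ext)
  }
  # empty grid reads back empty
  e <- voxel_grid(array(0L, c(4, 4, 4)))
  path <- file.path(tempdir(), "empty.nrrd")
  write_grid(e, path)
  expect_equal(nnz(read_grid(path)), 0)
})

test_that("reading binarizes nonzero values but keeps the support", {
  arr <- array(0L, c(5, 5, 5))
  arr[c(2, 30, 77)] <- c(255L, 7L, 1L)
  path <- file.path(tempdir(), "vals.nrrd")
  sparsevox:::write_nrrd(arr, path)
  expect_message(g <- read_grid(path), "binarizing")
  expect_setequal(unique(as.vector(g$data)), c(0L, 1L))
  expect_identical(which(g$data != 0L), which(arr != 0L))
})

test_that("a large thin slab with one voxel survives a round trip", {
  arr <- array(0L, c(512, 512, 4))
  arr[101, 202, 3] <- 1L
  path <- file.path(tempdir(), "slab.nrrd")
  write_grid(voxel_grid(arr), path)
  back <- read_grid(path)
  expect_equal(nnz(back), 1)
  expect_equal(unname(which(back$data != 0L, arr.ind = TRUE)[1, ]),
               c(101, 202, 3))
})

test_that("NRRD spacing and origin metadata survive", {
  g <- voxel_grid(random_grid(6, 0.2, 7)$data, spacing = c(0.5, 0.7, 2),
                  origin = c(-1, 3, 0.5))
  path <- file.path(tempdir(), "meta.nrrd")
  write_grid(g, path)
  back <- read_grid(path)
  expect_equal(back$spacing, c(0.5, 0.7, 2))
  expect_equal(back$origin, c(-1, 3, 0.5))
})

test_that("dense_to_sparse enumerates occupied voxels with unit features", {
  arr <- array(0L, c(4, 4, 4))
  arr[1, 1, 1] <- 1L     # voxel (0,0,0)
  arr[3, 2, 4] <- 1L     # voxel (2,1,3)
  st <- dense_to_sparse(voxel_grid(arr))
  expect_equal(st$coords, rbind(c(0L, 0L, 0L), c(2L, 1L, 3L)))
  expect_equal(st$feats, matrix(1, 2, 1))
  expect_equal(st$tensor_stride, 1L)
  # empty grid
  st0 <- dense_to_sparse(voxel_grid(array(0L, c(3, 3, 3))))
  expect_equal(nrow(st0$coords), 0L)
  # row count equals an independent nonzero count
  g <- random_grid(16, 0.1, seed = 5)
  expect_equal(nrow(dense_to_sparse(g)$coords), sum(g$data != 0L))
})

test_that("sparse_to_dense inverts dense_to_sparse and thresholds features", {
  g <- random_grid(8, 0.25, seed = 9)
  expect_identical(sparse_to_dense(dense_to_sparse(g), dim(g))$data, g$data)
  st <- sparse_tensor(rbind(c(1L, 1L, 1L), c(2L, 2L, 2L)),
                      matrix(c(0.4, -0.2), ncol = 1))
  d <- sparse_to_dense(st, c(4, 4, 4))
  expect_equal(nnz(d), 1)
  expect_equal(d$data[2, 2, 2], 1L)
  # out-of-bounds coordinates are named in the error
  bad <- sparse_tensor(matrix(c(5L, 0L, 0L), 1), matrix(1))
  expect_error(sparse_to_dense(bad, c(4, 4, 4)), "row 1")
  # densified support equals the unique coordinate count
  set.seed(31)
  cc <- unique(matrix(as.integer(floor(runif(3000, 0, 32))), ncol = 3))
  stu <- sparse_tensor(cc, matrix(1, nrow(cc), 1))
  expect_equal(nnz(sparse_to_dense(stu, c(32, 32, 32))), nrow(cc))
})

test_that("block-max downsampling preserves occupancy", {
  arr <- array(0L, c(4, 4, 4)); arr[2, 3, 1] <- 1L
  d <- downsample(voxel_grid(arr), 2)
  expect_equal(dim(d$data), c(2L, 2L, 2L))
  expect_equal(nnz(d), 1)
  expect_equal(d$data[1, 2, 1], 1L)
  expect_true(all(downsample(voxel_grid(array(1L, c(8, 8, 8))), 2)$data == 1L))
  # brute-force block scan oracle
  g <- random_grid(16, 0.15, seed = 13)
  d2 <- downsample(g, 2)
  for (i in 0:7) for (j in 0:7) for (k in 0:7) {
    blk <- g$data[2 * i + 1:2, 2 * j + 1:2, 2 * k + 1:2]
    expect_equal(d2$data[i + 1, j + 1, k + 1], max(blk))
  }
  # idempotence on constant grids; monotone nonzero counts
  expect_equal(nnz(downsample(voxel_grid(array(0L, c(8, 8, 8))), 2)), 0)
  expect_lte(nnz(d2), nnz(g))
  expect_error(downsample(g, 0), "positive")
})

test_that("non-divisible axes are zero-padded before downsampling", {
  arr <- array(1L, c(6, 6, 6))
  expect_message(d <- downsample(voxel_grid(arr), 4), "padding")
  expect_equal(dim(d$data), c(2L, 2L, 2L))
})

test_that("trilinear upscale behaves on constants and point sources", {
  expect_true(all(upscale(voxel_grid(array(1L, c(4, 4, 4))), 2)$data == 1L))
  expect_equal(nnz(upscale(voxel_grid(array(0L, c(4, 4, 4))), 2)), 0)
  arr <- array(0L, c(8, 8, 8)); arr[4, 4, 4] <- 1L
  u <- upscale(voxel_grid(arr), 2)
  expect_equal(dim(u$data), c(16L, 16L, 16L))
  supp <- which(u$data != 0L, arr.ind = TRUE)
  expect_gt(nrow(supp), 0)
  # support is one connected neighborhood around the scaled center (6,6,6)
  expect_true(any(apply(supp - 1L, 1, function(v) all(v == c(6, 6, 6)))))
  expect_true(all(apply(abs(sweep(supp - 1L, 2, c(6, 6, 6))), 1, max) <= 1))
  cc <- supp - 1L
  storage.mode(cc) <- "integer"
  expect_equal(max(sparsevox:::cpp_connected_components(cc)), 1L)
  expect_error(upscale(voxel_grid(arr), 0), "positive")
})

test_that("downsample of upscale never loses the original support", {
  g <- random_grid(8, 0.2, seed = 21)
  rt <- downsample(upscale(g, 2), 2)
  expect_true(all(rt$data[g$data == 1L] == 1L))
})

test_that("occupancy statistics summarize per grid and per label", {
  g0 <- voxel_grid(array(0L, c(4, 4, 4)))
  g1 <- voxel_grid(array(1L, c(4, 4, 4)))
  st <- occupancy_stats(list(g0, g1), labels = c("a", "b"))
  expect_equal(st$fraction, c(0, 1))
  expect_equal(st$total, c(64, 64))
  agg <- attr(st, "by_label")
  expect_equal(agg$mean_fraction[agg$label == "b"], 1)
})

test_that("shell occupancy thins as resolution grows (surface scaling)", {
  fr30 <- fr60 <- numeric(3)
  for (i in 1:3) {
    g30 <- make_shell(shell_spec(size = 30, seed = i))
    g60 <- make_shell(shell_spec(size = 60, seed = i))
    fr30[i] <- nnz(g30) / 30^3
    fr60[i] <- nnz(g60) / 60^3
    expect_lt(nnz(g60), 8 * nnz(g30))   # grows slower than the volume
  }
  expect_true(all(fr60 < fr30))
})
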