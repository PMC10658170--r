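test_that("fnv1a64 matches the reference values", {
  expect_equal(fnv1a64(raw(0)), "cbf29ce484222325")   # offset basis
  expect_equal(fnv1a64("a"), "af63dc4c8601ec8c")
  expect_equal(fnv1a64(charToRaw("foobar")), "85944171f73967e8")
})

test_that("coordinate hashing separates nearby coordinates", {
  set.seed(4)
  seen <- character(0)
  for (i in 1:200) {
    c0 <- as.integer(floor(runif(3, 0, 64)))
    h0 <- fnv1a64(c0)
    ax <- sample(3, 1)
    c1 <- c0; c1[ax] <- c1[ax] + 1L
    expect_false(h0 == fnv1a64(c1))
    seen <- c(seen, h0)
  }
  expect_equal(anyDuplicated(unique(seen)), 0)
})

test_that("the coordinate manager deduplicates in insertion order", {
  m <- build_manager(rbind(c(0L, 0L, 0L), c(0L, 0L, 0L)))
  expect_equal(nrow(m$coords), 1L)
  m2 <- build_manager(rbind(c(1L, 2L, 3L), c(3L, 2L, 1L)))
  expect_equal(nrow(m2$coords), 2L)
  expect_equal(lookup_rows(m2, rbind(c(1L, 2L, 3L), c(3L, 2L, 1L))), c(1L, 2L))
  expect_true(is.na(lookup_rows(m2, matrix(c(9L, 9L, 9L), 1))))
  expect_error(build_manager(matrix(c(0.5, 1, 2), 1)), "integer")
  # row count equals independent distinct-coordinate count
  set.seed(8)
  cc <- matrix(as.integer(floor(runif(3e4, 0, 64))), ncol = 3)
  m3 <- build_manager(cc)
  expect_equal(nrow(m3$coords), nrow(unique(cc)))
  # determinism: identical streams give identical row assignment
  m4 <- build_manager(cc)
  expect_identical(m3$coords, m4$coords)
})

test_that("stride_coords coarsens onto the strided lattice", {
  r <- stride_coords(rbind(c(0L, 0L, 0L), c(1L, 1L, 1L)), 1L, 2L)
  expect_equal(r$coords, matrix(0L, 1, 3))
  expect_equal(r$tensor_stride, 2L)
  r2 <- stride_coords(rbind(c(0L, 0L, 0L), c(2L, 0L, 0L)), 1L, 2L)
  expect_equal(nrow(r2$coords), 2L)
  # brute-force oracle on random coordinates
  set.seed(10)
  cc <- unique(matrix(as.integer(floor(runif(1500, 0, 32))), ncol = 3))
  r3 <- stride_coords(cc, 1L, 2L)
  oracle <- unique((cc %/% 2L) * 2L)
  expect_equal(nrow(r3$coords), nrow(oracle))
  expect_true(all(!is.na(lookup_rows(build_manager(oracle), r3$coords))))
  expect_error(stride_coords(cc, 1L, 0L), "stride")
})

test_that("kernel offsets follow the odd/even conventions", {
  expect_equal(kernel_offsets(1), matrix(0L, 1, 3))
  o3 <- kernel_offsets(3)
  expect_equal(nrow(o3), 27L)
  expect_equal(range(o3), c(-1L, 1L))
  o2 <- kernel_offsets(2)
  expect_equal(nrow(o2), 8L)
  expect_equal(sort(unique(as.vector(o2))), c(0L, 1L))
  o4 <- kernel_offsets(4)
  expect_equal(nrow(o4), 64L)
  expect_equal(sort(unique(as.vector(o4))), c(-1L, 0L, 1L, 2L))
})

test_that("kernel maps match a brute-force neighbor scan", {
  st1 <- sparse_tensor(matrix(c(3L, 4L, 5L), 1))
  km1 <- build_kernel_map(st1, st1$coords, Ks = 1)
  expect_equal(km1[[1]]$`in`, 1L)
  expect_equal(km1[[1]]$out, 1L)
  km3 <- build_kernel_map(st1, st1$coords, Ks = 3)
  pairs <- sum(vapply(km3, function(p) length(p$`in`), numeric(1)))
  expect_equal(pairs, 1L)  # only the zero offset matches
  # O(N^2) scan: pair (i, o) exists for some offset iff |in - out|_inf <= 1
  st <- random_tensor(n = 200, extent = 12, seed = 6)
  km <- build_kernel_map(st, st$coords, Ks = 3)
  got <- unique(do.call(rbind, lapply(km, function(p) cbind(p$`in`, p$out))))
  want <- which(outer(seq_len(nrow(st$coords)), seq_len(nrow(st$coords)),
                      Vectorize(function(i, o) {
                        all(abs(st$coords[i, ] - st$coords[o, ]) <= 1L)
                      })), arr.ind = TRUE)
  expect_equal(nrow(got), nrow(want))
  key <- function(m) paste(m[, 1], m[, 2])
  expect_setequal(key(got), key(want))
  # every offset pairs an output with at most one input
  for (p in km) expect_equal(anyDuplicated(p$out), 0)
})

test_that("sparse tensors validate their invariants", {
  expect_error(sparse_tensor(rbind(c(0L, 0L, 0L), c(0L, 0L, 0L))), "unique")
  expect_error(sparse_tensor(matrix(c(1L, 1L, 1L), 1), tensor_stride = 2L),
               "stride")
  expect_error(sparse_tensor(matrix(c(1L, 1L, 1L), 1), matrix(1, 2, 1)),
               "match")
  st <- sparse_tensor(matrix(c(2L, 4L, 6L), 1), tensor_stride = 2L)
  expect_equal(n_points(st), 1L)
})

test_that("tensor storage grows linearly in the point count", {
  sizes <- vapply(c(100L, 200L, 400L), function(n) {
    st <- random_tensor(n = n, extent = 64L, channels = 2L, seed = n)
    as.numeric(object.size(st$coords) + object.size(st$feats)) /
      nrow(st$coords)
  }, numeric(1))
  expect_lt(max(sizes) / min(sizes), 1.2)  # constant bytes per point
})

test_that("batched tensors carry a leading batch index", {
  a <- sparse_tensor(matrix(c(0L, 0L, 0L), 1))
  b <- sparse_tensor(matrix(c(1L, 1L, 1L), 1))
  bt <- batch_tensors(list(a, b))
  expect_equal(ncol(bt$coords), 4L)
  expect_equal(bt$coords[, 1], c(0L, 1L))
})

test_that("tensor text dumps list one point per line", {
  st <- sparse_tensor(rbind(c(0L, 1L, 2L), c(3L, 4L, 5L)),
                      matrix(c(1.5, -2), ncol = 1))
  lines <- dump_tensor(st)
  expect_length(lines, 2L)
  expect_match(lines[1], "^0 1 2 1\\.5$")
})
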