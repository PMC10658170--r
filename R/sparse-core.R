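#' Sparse tensors
#'
#' A `SparseTensor` stores a shape (or intermediate network features) as
#' an N x 3 integer coordinate matrix (optionally N x 4 with a leading
#' batch index) plus an N x C feature matrix.  Coordinates always live
#' on the original input lattice: after k stride-2 downsamplings the
#' tensor stride is 2^k and every coordinate is a multiple of it.
#' Coordinate rows are unique; uniqueness and row order are established
#' by the FNV-1a coordinate manager (first-occurrence order).
#'
#' @param coords integer N x 3 (or N x 4 with leading batch column)
#'   coordinate matrix.
#' @param feats numeric N x C feature matrix (a vector is treated as one
#'   channel).  For task inputs C = 1 and all features are 1.
#' @param tensor_stride positive integer lattice spacing (uniform across
#'   axes).
#' @param check validate invariants (uniqueness, stride multiples).
#' @return An object of class `SparseTensor`.
#' @examples
#' st <- sparse_tensor(rbind(c(0L, 0L, 0L), c(2L, 1L, 3L)))
#' st$coords
#' @export
sparse_tensor <- function(coords, feats = NULL, tensor_stride = 1L,
                          check = TRUE) {
  coords <- as.matrix(coords)
  if (nrow(coords) > 0L && any(coords != round(coords))) {
    stop("coordinates must be integer-valued")
  }
  storage.mode(coords) <- "integer"
  if (!ncol(coords) %in% c(3L, 4L)) {
    stop("coordinates must have 3 columns (or 4 with a batch index)")
  }
  if (is.null(feats)) feats <- matrix(1, nrow(coords), 1)
  if (is.vector(feats)) feats <- matrix(feats, ncol = 1)
  feats <- as.matrix(feats)
  storage.mode(feats) <- "double"
  if (nrow(feats) != nrow(coords)) {
    stop("feature rows (", nrow(feats), ") must match coordinate rows (",
         nrow(coords), ")")
  }
  tensor_stride <- as.integer(tensor_stride)
  stopifnot(length(tensor_stride) == 1L, tensor_stride >= 1L)
  if (check && nrow(coords) > 0L) {
    sp_cols <- (ncol(coords) - 2L):ncol(coords)
    if (tensor_stride > 1L &&
        any(coords[, sp_cols] %% tensor_stride != 0L)) {
      stop("coordinates must be integer multiples of the tensor stride")
    }
    dd <- cpp_dedup_coords(coords)
    if (length(dd$unique_rows) != nrow(coords)) {
      stop("coordinate rows must be unique")
    }
  }
  dimnames(coords) <- NULL
  dimnames(feats) <- NULL
  structure(list(coords = coords, feats = feats,
                 tensor_stride = tensor_stride),
            class = "SparseTensor")
}

#' @export
print.SparseTensor <- function(x, ...) {
  cat(sprintf("SparseTensor: %d points, %d channel(s), tensor stride %d\n",
              nrow(x$coords), ncol(x$feats), x$tensor_stride))
  invisible(x)
}

#' Number of points in a sparse tensor
#' @param st a [sparse_tensor()].
#' @return Integer row count.
#' @export
n_points <- function(st) nrow(st$coords)

#' Dump a sparse tensor as a text table
#'
#' Debug helper: one line per point, `x y z f1 ... fC`.
#'
#' @param st a [sparse_tensor()].
#' @param path optional file path; when `NULL` the lines are returned.
#' @return Character vector of lines (invisibly when written to file).
#' @export
dump_tensor <- function(st, path = NULL) {
  stopifnot(inherits(st, "SparseTensor"))
  lines <- apply(cbind(st$coords, signif(st$feats, 8)), 1, paste,
                 collapse = " ")
  if (is.null(lines)) lines <- character(0)
  if (!is.null(path)) {
    writeLines(lines, path)
    return(invisible(lines))
  }
  lines
}

#' FNV-1a 64-bit hash
#'
#' The byte-stream hash used to key the coordinate hash table: starting
#' from the offset basis, each byte is XORed in and the state multiplied
#' by the FNV prime modulo 2^64.  Returned as a 16-character lowercase
#' hex string because R has no native unsigned 64-bit integer.
#'
#' @param x a raw vector, a character scalar (hashed as its bytes), or
#'   an integer vector (serialized as little-endian 4-byte words, the
#'   coordinate-key serialization).
#' @return 16-character hex string.
#' @examples
#' fnv1a64(raw(0))      # offset basis
#' fnv1a64("a")
#' @export
fnv1a64 <- function(x) {
  if (is.character(x)) {
    stopifnot(length(x) == 1L)
    x <- charToRaw(x)
  } else if (is.numeric(x)) {
    x <- writeBin(as.integer(x), raw(), size = 4L, endian = "little")
  }
  stopifnot(is.raw(x))
  cpp_fnv1a64(x)
}

#' Build a coordinate manager
#'
#' Indexes integer coordinate rows in a hash table keyed by the FNV-1a
#' 64-bit hash of their little-endian 4-byte serialization, with exact-
#' coordinate chaining.  Duplicates collapse to the first occurrence and
#' row order is the insertion order of the deduplicated stream, making
#' row assignment deterministic across runs and platforms.
#'
#' @param coords integer coordinate matrix (3 or 4 columns).
#' @return An object of class `CoordinateManager` with the deduplicated
#'   `coords` and the original row count `n_input`.
#' @export
build_manager <- function(coords) {
  coords <- as.matrix(coords)
  if (nrow(coords) > 0L && any(coords != round(coords))) {
    stop("coordinates must be integer-valued")
  }
  storage.mode(coords) <- "integer"
  dd <- cpp_dedup_coords(coords)
  uc <- coords[dd$unique_rows, , drop = FALSE]
  dimnames(uc) <- NULL
  structure(list(coords = uc, n_input = nrow(coords), rank = dd$rank),
            class = "CoordinateManager")
}

#' @export
print.CoordinateManager <- function(x, ...) {
  cat(sprintf("CoordinateManager: %d unique rows (from %d inserted)\n",
              nrow(x$coords), x$n_input))
  invisible(x)
}

#' Look up coordinate rows in a manager
#'
#' @param manager a [build_manager()] result (or a `SparseTensor`).
#' @param coords integer query coordinate matrix.
#' @return Integer vector of 1-based row indices, `NA` where absent.
#' @export
lookup_rows <- function(manager, coords) {
  table <- if (inherits(manager, "SparseTensor")) manager$coords else manager$coords
  coords <- as.matrix(coords)
  storage.mode(coords) <- "integer"
  cpp_lookup_coords(table, coords)
}

#' Coarsen coordinates by a stride
#'
#' Output coordinates are the unique values of
#' `floor(c / (tensor_stride * s)) * (tensor_stride * s)` in
#' first-occurrence order; they stay on the original input lattice with
#' tensor stride multiplied by `s`.
#'
#' @param coords integer coordinate matrix.
#' @param tensor_stride current tensor stride.
#' @param stride stride factor `s >= 1`.
#' @return List with `coords` and the new `tensor_stride`.
#' @export
stride_coords <- function(coords, tensor_stride = 1L, stride = 2L) {
  stride <- as.integer(stride)
  if (is.na(stride) || stride < 1L) stop("stride must be >= 1")
  coords <- as.matrix(coords)
  storage.mode(coords) <- "integer"
  step <- as.integer(tensor_stride) * stride
  nb <- ncol(coords)
  out <- coords
  sp_cols <- (nb - 2L):nb   # leading batch column, when present, is untouched
  out[, sp_cols] <- (out[, sp_cols] %/% step) * step
  dd <- cpp_dedup_coords(out)
  list(coords = out[dd$unique_rows, , drop = FALSE],
       tensor_stride = step)
}

#' Kernel offset vectors
#'
#' For odd `Ks` the symmetric cube `{-(Ks-1)/2, ..., (Ks-1)/2}^3`; for
#' even `Ks` the convention `{-Ks/2+1, ..., Ks/2}^3` (footprint biased
#' one step positive), so `Ks = 2` spans `{0,1}^3`.  This single
#' function fixes the even-kernel convention for the whole engine.
#'
#' @param Ks kernel size per axis (>= 1).
#' @param dimension spatial dimension (3).
#' @return Integer `Ks^dimension` x `dimension` offset matrix.
#' @export
kernel_offsets <- function(Ks, dimension = 3L) {
  Ks <- as.integer(Ks)
  stopifnot(Ks >= 1L)
  r <- if (Ks %% 2L == 1L) {
    seq.int(-(Ks - 1L) %/% 2L, (Ks - 1L) %/% 2L)
  } else {
    seq.int(-Ks %/% 2L + 1L, Ks %/% 2L)
  }
  off <- as.matrix(do.call(expand.grid, rep(list(r), dimension)))
  dimnames(off) <- NULL
  storage.mode(off) <- "integer"
  off
}

#' Build the kernel map between two coordinate sets
#'
#' For each kernel offset `k` and each output coordinate `D'`, the map
#' pairs the row of the input coordinate `D = D' + k * in_stride` with
#' the row of `D'`, when `D` exists in the input — the neighbor
#' constraint of the sparse convolution.  For a generative transposed
#' convolution the roles reverse: `D' = D + k * out_stride`
#' (`transposed = TRUE`).
#'
#' @param in_st a [sparse_tensor()] (or bare coordinate matrix) holding
#'   the input coordinates.
#' @param out_coords integer matrix of output coordinates.
#' @param Ks kernel size.
#' @param in_stride input tensor stride (taken from `in_st` when it is a
#'   `SparseTensor`).
#' @param out_stride output tensor stride (only used when
#'   `transposed = TRUE`).
#' @param transposed build the map of a generative transposed
#'   convolution.
#' @return Object of class `KernelMap`: a list with one `list(in=, out=)`
#'   pair of 1-based row-index vectors per kernel offset, plus an
#'   `offsets` attribute.
#' @export
build_kernel_map <- function(in_st, out_coords, Ks, in_stride = NULL,
                             out_stride = NULL, transposed = FALSE) {
  in_coords <- if (inherits(in_st, "SparseTensor")) in_st$coords else as.matrix(in_st)
  storage.mode(in_coords) <- "integer"
  out_coords <- as.matrix(out_coords)
  storage.mode(out_coords) <- "integer"
  if (is.null(in_stride)) {
    in_stride <- if (inherits(in_st, "SparseTensor")) in_st$tensor_stride else 1L
  }
  d <- ncol(in_coords)
  off <- kernel_offsets(Ks, dimension = 3L)
  if (d == 4L) off <- cbind(0L, off)  # batch column never shifts
  km <- if (transposed) {
    if (is.null(out_stride)) stop("out_stride required for transposed maps")
    raw <- cpp_kernel_map(out_coords, in_coords, off, as.integer(out_stride))
    lapply(raw, function(p) list(`in` = p$base, out = p$table))
  } else {
    raw <- cpp_kernel_map(in_coords, out_coords, off, as.integer(in_stride))
    lapply(raw, function(p) list(`in` = p$table, out = p$base))
  }
  structure(km, offsets = off, Ks = as.integer(Ks), class = "KernelMap")
}

#' @export
print.KernelMap <- function(x, ...) {
  np <- sum(vapply(x, function(p) length(p$`in`), numeric(1)))
  cat(sprintf("KernelMap: %d offsets, %d pairs\n", length(x), np))
  invisible(x)
}

#' Concatenate sparse tensors into a batch
#'
#' Adds a leading batch-index column (0-based) and row-binds the
#' tensors.  Default pipelines use batch size 1; batching is provided
#' for completeness of the data model.
#'
#' @param tensors list of [sparse_tensor()]s with equal channel counts
#'   and tensor strides.
#' @return A batched `SparseTensor` with 4-column coordinates.
#' @export
batch_tensors <- function(tensors) {
  stopifnot(length(tensors) >= 1L)
  ts <- tensors[[1]]$tensor_stride
  cc <- lapply(seq_along(tensors), function(i) {
    st <- tensors[[i]]
    stopifnot(st$tensor_stride == ts, ncol(st$coords) == 3L)
    cbind(i - 1L, st$coords)
  })
  ff <- lapply(tensors, function(st) st$feats)
  sparse_tensor(do.call(rbind, cc), do.call(rbind, ff), tensor_stride = ts)
}
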