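#' Binary voxel occupancy grids
#'
#' A `VoxelGrid` is a dense 3-D binary occupancy array together with the
#' physical voxel spacing (mm) and the physical coordinate of voxel
#' (0,0,0).  It is the I/O-facing representation of a shape; the sparse
#' engine operates on its [sparse_tensor()] counterpart, which stores
#' only the occupied voxels.
#'
#' @param data 3-D array; any nonzero value marks an occupied voxel.
#' @param spacing numeric length-3 vector of strictly positive per-axis
#'   voxel sizes in mm.
#' @param origin numeric length-3 physical coordinate of voxel (0,0,0).
#' @return An object of class `VoxelGrid` with elements `data` (0/1
#'   array), `spacing` and `origin`.
#' @examples
#' g <- voxel_grid(array(0L, c(4, 4, 4)))
#' nnz(g)
#' @export
voxel_grid <- function(data, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  if (is.null(dim(data)) || length(dim(data)) != 3L) {
    stop("VoxelGrid data must be a 3-D array")
  }
  if (any(dim(data) < 1L)) stop("VoxelGrid dimensions must be positive")
  spacing <- rep_len(as.numeric(spacing), 3L)
  if (any(!is.finite(spacing)) || any(spacing <= 0)) {
    stop("spacing components must be strictly positive")
  }
  d <- dim(data)
  storage.mode(data) <- "integer"
  if (!all(data %in% c(0L, 1L))) {
    n_other <- sum(!(data %in% c(0L, 1L)))
    message("binarizing ", n_other, " values outside {0,1}")
    data <- as.integer(data != 0L)
  }
  data <- array(as.integer(data), dim = d)  # strip foreign classes/attributes
  structure(list(data = data, spacing = spacing,
                 origin = rep_len(as.numeric(origin), 3L)),
            class = "VoxelGrid")
}

#' @export
print.VoxelGrid <- function(x, ...) {
  cat(sprintf("VoxelGrid %s, %d/%d occupied (%.2f%%), spacing %s mm\n",
              paste(dim(x$data), collapse = "x"), nnz(x),
              length(x$data), 100 * nnz(x) / length(x$data),
              paste(format(x$spacing), collapse = "x")))
  invisible(x)
}

#' @export
dim.VoxelGrid <- function(x) dim(x$data)

#' Number of occupied voxels
#' @param grid a [voxel_grid()].
#' @return Integer count of nonzero voxels.
#' @export
nnz <- function(grid) {
  stopifnot(inherits(grid, "VoxelGrid"))
  sum(grid$data != 0L)
}

.grid_format <- function(path, format = NULL) {
  if (!is.null(format)) return(match.arg(format, c("nrrd", "nifti", "rds")))
  lp <- tolower(path)
  if (grepl("\\.nrrd$", lp)) return("nrrd")
  if (grepl("\\.nii(\\.gz)?$", lp)) return("nifti")
  if (grepl("\\.rds$", lp)) return("rds")
  stop("cannot infer grid format from path: ", path)
}

#' Read a binary voxel grid from disk
#'
#' Reads NRRD (the canonical on-disk format here), NIfTI-1, or the
#' package's internal RDS container.  Any nonzero stored value is mapped
#' to 1; binarization is reported with a message.  For NIfTI, spacing is
#' taken from the pixdim fields; orientation handling beyond spacing is
#' out of scope.
#'
#' @param path file path.
#' @param format one of `"nrrd"`, `"nifti"`, `"rds"`; inferred from the
#'   file extension when `NULL`.
#' @return A [voxel_grid()].
#' @export
read_grid <- function(path, format = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  format <- .grid_format(path, format)
  if (format == "nrrd") {
    raw <- read_nrrd(path)
    voxel_grid(raw$data, spacing = raw$spacing, origin = raw$origin)
  } else if (format == "nifti") {
    img <- RNifti::readNifti(path)
    arr <- as.array(img)
    if (length(dim(arr)) != 3L) stop("expected a 3-D NIfTI volume, got ",
                                     length(dim(arr)), "-D")
    sp <- attr(img, "pixdim")
    if (is.null(sp)) sp <- RNifti::pixdim(img)
    voxel_grid(arr, spacing = sp[seq_len(3)])
  } else {
    obj <- readRDS(path)
    if (inherits(obj, "VoxelGrid")) return(voxel_grid(obj$data, obj$spacing, obj$origin))
    voxel_grid(obj$data, spacing = obj$spacing %||% c(1, 1, 1),
               origin = obj$origin %||% c(0, 0, 0))
  }
}

#' Write a binary voxel grid to disk
#'
#' @inheritParams read_grid
#' @param grid a [voxel_grid()].
#' @return The path, invisibly.
#' @export
write_grid <- function(grid, path, format = NULL) {
  stopifnot(inherits(grid, "VoxelGrid"))
  format <- .grid_format(path, format)
  dir <- dirname(path)
  if (!dir.exists(dir)) stop("directory does not exist: ", dir)
  if (format == "nrrd") {
    write_nrrd(grid$data, path, spacing = grid$spacing, origin = grid$origin)
  } else if (format == "nifti") {
    img <- RNifti::asNifti(grid$data)
    RNifti::pixdim(img) <- grid$spacing
    RNifti::writeNifti(img, path)
  } else {
    saveRDS(list(data = grid$data, spacing = grid$spacing,
                 origin = grid$origin), path)
  }
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Convert a dense grid to a sparse tensor
#'
#' Lists the 0-based voxel indices of all occupied voxels in
#' lexicographic (x, y, z) order with an all-ones one-channel feature
#' vector, the standard input formatting for the sparse network.
#'
#' @param grid a [voxel_grid()].
#' @return A [sparse_tensor()] with tensor stride 1.
#' @export
dense_to_sparse <- function(grid) {
  stopifnot(inherits(grid, "VoxelGrid"))
  idx <- which(grid$data != 0L, arr.ind = TRUE)
  if (nrow(idx) == 0L) {
    return(sparse_tensor(matrix(integer(0), 0, 3), matrix(numeric(0), 0, 1)))
  }
  coords <- idx - 1L
  ord <- order(coords[, 1], coords[, 2], coords[, 3])
  coords <- coords[ord, , drop = FALSE]
  dimnames(coords) <- NULL
  sparse_tensor(coords, matrix(1, nrow(coords), 1), tensor_stride = 1L)
}

#' Densify a sparse tensor onto a voxel lattice
#'
#' A voxel is set to 1 iff a coordinate row exists there whose (first
#' channel) feature value exceeds `threshold`.
#'
#' @param st a [sparse_tensor()].
#' @param shape integer length-3 grid dimensions.
#' @param threshold feature threshold (default 0).
#' @param spacing,origin metadata for the resulting grid.
#' @return A [voxel_grid()].
#' @export
sparse_to_dense <- function(st, shape, threshold = 0,
                            spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  stopifnot(inherits(st, "SparseTensor"))
  shape <- as.integer(shape)
  arr <- array(0L, dim = shape)
  if (nrow(st$coords) > 0L) {
    bad <- which(st$coords[, 1] < 0L | st$coords[, 1] >= shape[1] |
                 st$coords[, 2] < 0L | st$coords[, 2] >= shape[2] |
                 st$coords[, 3] < 0L | st$coords[, 3] >= shape[3])
    if (length(bad) > 0L) {
      stop("coordinate out of bounds at row ", bad[1], ": (",
           paste(st$coords[bad[1], ], collapse = ","), ") outside [0,",
           paste(shape, collapse = ")x[0,"), ")")
    }
    keep <- st$feats[, 1] > threshold
    if (any(keep)) {
      cc <- st$coords[keep, , drop = FALSE]
      arr[cc + 1L] <- 1L
    }
  }
  voxel_grid(arr, spacing = spacing, origin = origin)
}

.pad_to_multiple <- function(data, factor) {
  d <- dim(data)
  target <- as.integer(ceiling(d / factor) * factor)
  if (all(target == d)) return(data)
  message("padding grid from ", paste(d, collapse = "x"), " to ",
          paste(target, collapse = "x"), " (high end, zeros)")
  out <- array(0L, dim = target)
  out[seq_len(d[1]), seq_len(d[2]), seq_len(d[3])] <- data
  out
}

.block_reduce <- function(data, factor, op = c("max", "mean")) {
  # fold each axis in turn: reshape so the axis splits into
  # (factor, axis/factor) and reduce over the first part
  op <- match.arg(op)
  data <- data + 0.0
  for (ax in 1:3) {
    d <- dim(data)
    perm <- c(ax, setdiff(1:3, ax))
    a <- aperm(data, perm)
    da <- dim(a)
    dim(a) <- c(factor, da[1] / factor, da[2], da[3])
    out <- a[1, , , , drop = TRUE]
    dim(out) <- c(da[1] / factor, da[2], da[3])
    if (factor > 1L) {
      for (i in 2:factor) {
        sl <- a[i, , , , drop = TRUE]
        dim(sl) <- dim(out)
        out <- if (op == "max") pmax(out, sl) else out + sl
      }
    }
    if (op == "mean") out <- out / factor
    data <- aperm(out, order(perm))
  }
  data
}

#' Downsample a binary grid
#'
#' With `method = "max"` (the default) each output voxel is the maximum
#' over its `factor`^3 input block, so occupancy is never lost: thin
#' shell structures 1-2 voxels thick survive coarsening.  This is the
#' path for completion ground truth and multi-resolution pyramids.  With
#' `method = "trilinear"` the block mean is thresholded at 0.5 (ties to
#' 1), which roughly preserves occupied volume; this is the path that
#' produces the coarse super-resolution input, whose up-scaled version
#' should match the target's voxel count.  Axes not divisible by
#' `factor` are zero-padded at the high end first (reported with a
#' message).
#'
#' @param grid a [voxel_grid()].
#' @param factor positive integer downsampling factor.
#' @param method `"max"` (occupancy-preserving) or `"trilinear"`
#'   (volume-preserving block mean + 0.5 threshold).
#' @return A [voxel_grid()] of size `ceiling(dim/factor)` with spacing
#'   multiplied by `factor`.
#' @export
downsample <- function(grid, factor, method = c("max", "trilinear")) {
  stopifnot(inherits(grid, "VoxelGrid"))
  method <- match.arg(method)
  factor <- as.integer(factor)
  if (is.na(factor) || factor < 1L) stop("factor must be a positive integer")
  if (factor == 1L) return(grid)
  data <- .pad_to_multiple(grid$data, factor)
  out <- if (method == "max") {
    .block_reduce(data, factor, "max")
  } else {
    v <- .block_reduce(data, factor, "mean")
    v >= 0.5 - 1e-9
  }
  voxel_grid(array(as.integer(out), dim = dim(out)),
             spacing = grid$spacing * factor, origin = grid$origin)
}

.interp_axis <- function(arr, ax, factor) {
  n_in <- dim(arr)[ax]
  n_out <- n_in * factor
  # corner-aligned mapping: output index i sits at input position i/f,
  # so input voxel v maps exactly onto output voxel f*v (consistent with
  # the block conventions of downsample())
  pos <- (seq_len(n_out) - 1) / factor
  i0 <- pmax(0L, pmin(n_in - 1L, as.integer(floor(pos))))
  i1 <- pmin(n_in - 1L, i0 + 1L)
  w <- pos - i0
  w[pos < 0] <- 0
  w[pos > n_in - 1] <- 0
  perm <- c(ax, setdiff(1:3, ax))
  a <- aperm(arr, perm)
  da <- dim(a)
  m <- matrix(a, nrow = da[1])
  out <- m[i0 + 1L, , drop = FALSE] * (1 - w) + m[i1 + 1L, , drop = FALSE] * w
  dim(out) <- c(n_out, da[2], da[3])
  aperm(out, order(perm))
}

#' Upscale a grid by trilinear interpolation
#'
#' Interpolates the 0/1 occupancy field trilinearly and re-binarizes at
#' 0.5 (ties map to 1).  This is the "blurry and coarse" up-scaled
#' input of the super-resolution task, deliberately distinct from the
#' occupancy-preserving [downsample()].
#'
#' @inheritParams downsample
#' @param factor positive integer upscaling factor.
#' @return A [voxel_grid()] of size `dim * factor`.
#' @export
upscale <- function(grid, factor) {
  stopifnot(inherits(grid, "VoxelGrid"))
  factor <- as.integer(factor)
  if (is.na(factor) || factor < 1L) stop("factor must be a positive integer")
  if (factor == 1L) return(grid)
  field <- grid$data + 0.0
  for (ax in 1:3) field <- .interp_axis(field, ax, factor)
  out <- array(as.integer(field >= 0.5 - 1e-9), dim = dim(field))
  voxel_grid(out, spacing = grid$spacing / factor, origin = grid$origin)
}

#' Occupancy statistics of a batch of grids
#'
#' @param grids a list of [voxel_grid()]s.
#' @param labels optional character labels (e.g. a resolution tag) of
#'   the same length as `grids`.
#' @return A data frame with one row per grid (`label`, `total`,
#'   `nonzero`, `fraction`) carrying a `"by_label"` attribute with
#'   mean/min/max of `nonzero` and `fraction` per label group.
#' @export
occupancy_stats <- function(grids, labels = NULL) {
  if (inherits(grids, "VoxelGrid")) grids <- list(grids)
  if (is.null(labels)) {
    labels <- vapply(grids, function(g) paste(dim(g$data), collapse = "x"),
                     character(1))
  }
  stopifnot(length(labels) == length(grids))
  df <- data.frame(
    label = as.character(labels),
    total = vapply(grids, function(g) length(g$data), numeric(1)),
    nonzero = vapply(grids, function(g) as.numeric(nnz(g)), numeric(1)),
    stringsAsFactors = FALSE
  )
  df$fraction <- ifelse(df$total > 0, df$nonzero / df$total, 0)
  agg <- do.call(rbind, lapply(split(df, df$label), function(s) {
    data.frame(label = s$label[1], n = nrow(s),
               mean_nonzero = mean(s$nonzero),
               min_nonzero = min(s$nonzero), max_nonzero = max(s$nonzero),
               mean_fraction = mean(s$fraction),
               min_fraction = min(s$fraction), max_fraction = max(s$fraction),
               stringsAsFactors = FALSE)
  }))
  rownames(agg) <- NULL
  attr(df, "by_label") <- agg
  df
}
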