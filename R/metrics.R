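#' Dice similarity coefficient
#'
#' `2|P intersect G| / (|P| + |G|)` between two binary masks; symmetric
#' in its arguments.  Two empty masks compare as 1 by convention
#' (reported with a message).
#'
#' @param pred,gt [voxel_grid()]s (or bare binary arrays) of equal shape.
#' @return DSC in `[0, 1]`.
#' @export
dsc <- function(pred, gt) {
  p <- if (inherits(pred, "VoxelGrid")) pred$data else pred
  g <- if (inherits(gt, "VoxelGrid")) gt$data else gt
  stopifnot(identical(dim(p), dim(g)))
  np <- sum(p != 0)
  ng <- sum(g != 0)
  if (np + ng == 0) {
    message("both masks empty: DSC = 1 by convention")
    return(1)
  }
  2 * sum(p != 0 & g != 0) / (np + ng)
}

#' Reconstruction error
#'
#' The percentage of misclassified voxels: `100 * |P xor G| / total`.
#'
#' @inheritParams dsc
#' @return List with `re_percent` and `misclassified` count.
#' @export
reconstruction_error <- function(pred, gt) {
  p <- if (inherits(pred, "VoxelGrid")) pred$data else pred
  g <- if (inherits(gt, "VoxelGrid")) gt$data else gt
  stopifnot(identical(dim(p), dim(g)))
  mis <- sum((p != 0) != (g != 0))
  list(re_percent = 100 * mis / length(p), misclassified = mis)
}

#' Misclassified-voxel count implied by a reconstruction error
#'
#' Back-computes the voxel count from a printed RE percentage,
#' truncating the product to an integer (the rounding convention used
#' when reporting counts from percentages).
#'
#' @param re_percent reconstruction error in percent.
#' @param shape grid dimensions.
#' @return Integer voxel count `floor(re/100 * prod(shape))`.
#' @export
misclassified_from_re <- function(re_percent, shape) {
  floor(re_percent / 100 * prod(as.numeric(shape)))
}

#' Extract the implant from a completed skull
#'
#' Set difference `completed \ defective`; with `cleanup = TRUE` only
#' the largest 26-connected component is kept, removing isolated specks
#' (the default for reports; unit comparisons use `cleanup = FALSE`).
#'
#' @param completed,defective [voxel_grid()]s of equal shape.
#' @param cleanup keep only the largest connected component.
#' @return The implant [voxel_grid()].
#' @export
extract_implant <- function(completed, defective, cleanup = FALSE) {
  stopifnot(inherits(completed, "VoxelGrid"), inherits(defective, "VoxelGrid"),
            identical(dim(completed$data), dim(defective$data)))
  imp <- completed$data * (1L - defective$data)
  if (cleanup && sum(imp) > 0L) {
    cc <- which(imp != 0L, arr.ind = TRUE) - 1L
    storage.mode(cc) <- "integer"
    lab <- cpp_connected_components(cc)
    main <- as.integer(names(which.max(table(lab))))
    keep <- cc[lab == main, , drop = FALSE]
    imp <- array(0L, dim(imp))
    imp[keep + 1L] <- 1L
  }
  voxel_grid(imp, completed$spacing, completed$origin)
}

# boundary voxels: occupied with an unoccupied (or out-of-grid)
# 6-neighbor
.boundary_coords <- function(data) {
  if (sum(data) == 0L) return(matrix(integer(0), 0, 3))
  d <- dim(data)
  interior <- array(TRUE, d)
  shift_and <- function(acc, ax, by) {
    idx_to <- as.list(rep(TRUE, 3))
    idx_from <- as.list(rep(TRUE, 3))
    n <- d[ax]
    if (by == 1L) {
      idx_to[[ax]] <- 1:(n - 1); idx_from[[ax]] <- 2:n
    } else {
      idx_to[[ax]] <- 2:n; idx_from[[ax]] <- 1:(n - 1)
    }
    nb <- array(0L, d)  # outside the grid counts as empty
    nb[idx_to[[1]], idx_to[[2]], idx_to[[3]]] <-
      data[idx_from[[1]], idx_from[[2]], idx_from[[3]]]
    acc & (nb != 0L)
  }
  for (ax in 1:3) for (by in c(1L, -1L)) {
    interior <- shift_and(interior, ax, by)
  }
  border <- data != 0L & !interior
  cc <- which(border, arr.ind = TRUE) - 1L
  storage.mode(cc) <- "integer"
  cc
}

#' 95th percentile Hausdorff distance
#'
#' The 95th percentile of the pooled directed surface distances (both
#' directions) between the boundary voxels of the two masks, scaled by
#' the voxel spacing.  Identical masks give 0; an empty mask gives `Inf`
#' with a warning.
#'
#' @inheritParams dsc
#' @param spacing per-axis physical voxel size (defaults to the grids').
#' @return HD95 in mm (voxel units at unit spacing).
#' @export
hd95 <- function(pred, gt, spacing = NULL) {
  pg <- if (inherits(pred, "VoxelGrid")) pred else voxel_grid(pred)
  gg <- if (inherits(gt, "VoxelGrid")) gt else voxel_grid(gt)
  if (is.null(spacing)) spacing <- pg$spacing
  bp <- .boundary_coords(pg$data)
  bg <- .boundary_coords(gg$data)
  if (nrow(bp) == 0L || nrow(bg) == 0L) {
    warning("empty mask in HD95: returning Inf")
    return(Inf)
  }
  d1 <- cpp_min_dists(bp, bg, spacing)
  d2 <- cpp_min_dists(bg, bp, spacing)
  as.numeric(quantile(c(d1, d2), 0.95, type = 7, names = FALSE))
}

.chebyshev_dilate <- function(mask, radius) {
  d <- dim(mask)
  out <- mask
  offs <- expand.grid(dx = -radius:radius, dy = -radius:radius,
                      dz = -radius:radius)
  for (r in seq_len(nrow(offs))) {
    o <- as.integer(offs[r, ])
    if (all(o == 0L)) next
    src <- lapply(1:3, function(ax) {
      lo <- max(1L, 1L - o[ax]); hi <- min(d[ax], d[ax] - o[ax])
      if (lo > hi) return(NULL)
      lo:hi
    })
    if (any(vapply(src, is.null, logical(1)))) next
    dst <- lapply(1:3, function(ax) src[[ax]] + o[ax])
    out[dst[[1]], dst[[2]], dst[[3]]] <-
      out[dst[[1]], dst[[2]], dst[[3]]] | mask[src[[1]], src[[2]], src[[3]]]
  }
  out
}

#' Border Dice coefficient
#'
#' DSC restricted to the band of voxels within a Chebyshev radius of the
#' ground-truth implant's boundary surface (built by morphological
#' dilation of the implant border), emphasizing rim fit — the clinically
#' critical contact region of an implant.  The band definition is this
#' package's approximation and is reported with its radius.
#'
#' @param pred,gt predicted and ground-truth implant [voxel_grid()]s.
#' @param defective accepted for interface symmetry with full-skull
#'   evaluation; the band is built from the ground-truth implant border.
#' @param band_radius Chebyshev dilation radius in voxels (default 2).
#' @return Border DSC in `[0, 1]` with the radius attached as attribute
#'   `"band_radius"`.
#' @export
border_dsc <- function(pred, gt, defective = NULL, band_radius = 2L) {
  p <- if (inherits(pred, "VoxelGrid")) pred$data else pred
  g <- if (inherits(gt, "VoxelGrid")) gt$data else gt
  stopifnot(identical(dim(p), dim(g)))
  bc <- .boundary_coords(array(as.integer(g != 0), dim(g)))
  if (nrow(bc) == 0L) {
    message("empty ground-truth implant: border DSC = 0")
    return(structure(0, band_radius = band_radius))
  }
  border <- array(FALSE, dim(g))
  border[bc + 1L] <- TRUE
  band <- .chebyshev_dilate(border, as.integer(band_radius))
  val <- dsc(array(as.integer(p != 0 & band), dim(p)),
             array(as.integer(g != 0 & band), dim(g)))
  structure(val, band_radius = band_radius)
}

#' Full metric report for a prediction
#'
#' @param pred,gt predicted and ground-truth [voxel_grid()]s (complete
#'   skulls).
#' @param defective optional defective input grid: when given, implants
#'   are extracted by subtracting it from both masks and implant DSC,
#'   border DSC and HD95 are reported alongside the skull metrics.
#' @param band_radius border-DSC band radius.
#' @param cleanup largest-component cleanup of the extracted implants.
#' @return An object of class `MetricReport` (a list of named numbers).
#' @export
metric_report <- function(pred, gt, defective = NULL, band_radius = 2L,
                          cleanup = TRUE) {
  re <- reconstruction_error(pred, gt)
  out <- list(dsc = dsc(pred, gt), re_percent = re$re_percent,
              misclassified = re$misclassified,
              total = length(if (inherits(gt, "VoxelGrid")) gt$data else gt))
  if (!is.null(defective)) {
    imp_gt <- extract_implant(gt, defective, cleanup = FALSE)
    imp_pred <- extract_implant(pred, defective, cleanup = cleanup)
    out$implant_dsc <- dsc(imp_pred, imp_gt)
    out$bdsc <- as.numeric(border_dsc(imp_pred, imp_gt, defective, band_radius))
    out$band_radius <- band_radius
    out$hd95 <- if (nnz(imp_pred) > 0L && nnz(imp_gt) > 0L) {
      hd95(imp_pred, imp_gt)
    } else {
      Inf
    }
  }
  structure(out, class = "MetricReport")
}

#' @export
print.MetricReport <- function(x, ...) {
  cat(sprintf("DSC %.4f | RE %.4f%% (%d/%d voxels)\n",
              x$dsc, x$re_percent, x$misclassified, x$total))
  if (!is.null(x$implant_dsc)) {
    cat(sprintf("implant DSC %.4f | bDSC %.4f (band %d) | HD95 %.4g\n",
                x$implant_dsc, x$bdsc, x$band_radius, x$hd95))
  }
  invisible(x)
}

#' Scope of quantitative reproduction
#'
#' Returns the package's statement of which published skull
#' reconstruction results its synthetic desk-scale benchmark does and
#' does not reproduce.
#'
#' @return Character vector of statements.
#' @export
reproducibility_notes <- function() {
  c(
    paste("Reproduced analytically: the reference parameter counts",
          "(0.435M for ch1 = [8,8,16,16,32,32,64]; 18.14M for",
          "ch2 = [22,32,32,128,156,256,388]; ratio > 40) and the",
          "misclassified-voxel count implied by RE = 0.1144% on a",
          "512x512x256 grid (76772 voxels)."),
    paste("Reproduced as properties on synthetic shells: sparse/dense",
          "convolution equivalence, generative coordinate arithmetic,",
          "gradient correctness, and the orderings 'trained completion",
          "beats the defective input' and 'learned super-resolution",
          "beats trilinear interpolation'."),
    paste("NOT reproduced at desk scale: the published DSC/RE tables on",
          "the real MRI and CT skull datasets (e.g. DSC 0.9903 at full",
          "CT resolution), implant comparisons against challenge",
          "submissions, GPU memory measurements and wall-clock timings.",
          "Those require the external datasets and GPU-scale training",
          "and are out of scope of this package's benchmark.")
  )
}
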