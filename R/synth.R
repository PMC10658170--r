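#' Synthetic skull-shell specification
#'
#' Describes one synthetic "skull": the region between two concentric
#' perturbed ellipsoid surfaces — a thin closed shell occupying a few
#' percent of the grid, like binarized cranial bone.  A sinusoidal
#' radial perturbation adds sub-voxel geometric detail that is lost at
#' coarse resolution and recoverable at fine resolution (the premise of
#' the super-resolution task); random rotation varies head pose.
#'
#' @param size grid side length in voxels.
#' @param semi_axes outer ellipsoid semi-axes as fractions of half the
#'   grid size.
#' @param thickness shell thickness in voxels at this resolution.
#' @param detail_amp amplitude of the sinusoidal radial perturbation
#'   (fraction of the radius).
#' @param detail_freq angular frequency of the perturbation.
#' @param angles length-3 rotation angles (radians) about x, y, z.
#' @param seed integer seed recorded with the spec.
#' @return An object of class `ShellSpec`.
#' @export
shell_spec <- function(size = 64L, semi_axes = c(0.72, 0.82, 0.78),
                       thickness = 2, detail_amp = 0.04, detail_freq = 6,
                       angles = c(0, 0, 0), seed = 1L) {
  size <- as.integer(size)
  stopifnot(size >= 8L, length(semi_axes) == 3L, all(semi_axes > 0),
            all(semi_axes <= 0.95), thickness >= 1)
  structure(list(size = size, semi_axes = as.numeric(semi_axes),
                 thickness = thickness, detail_amp = detail_amp,
                 detail_freq = detail_freq, angles = as.numeric(angles),
                 seed = as.integer(seed)),
            class = "ShellSpec")
}

.rotation_matrix <- function(a) {
  cx <- cos(a[1]); sx <- sin(a[1])
  cy <- cos(a[2]); sy <- sin(a[2])
  cz <- cos(a[3]); sz <- sin(a[3])
  Rx <- matrix(c(1, 0, 0, 0, cx, sx, 0, -sx, cx), 3, 3)
  Ry <- matrix(c(cy, 0, -sy, 0, 1, 0, sy, 0, cy), 3, 3)
  Rz <- matrix(c(cz, sz, 0, -sz, cz, 0, 0, 0, 1), 3, 3)
  Rz %*% Ry %*% Rx
}

#' Generate a synthetic skull shell
#'
#' Voxels between the inner and outer perturbed ellipsoid surfaces are
#' set to 1.  The shell is closed and, for default specifications,
#' 26-connected with occupancy in the single-digit percent range,
#' matching the sparsity regime of binarized skull data.
#'
#' @param spec a [shell_spec()].
#' @return A [voxel_grid()].
#' @export
make_shell <- function(spec) {
  stopifnot(inherits(spec, "ShellSpec"))
  n <- spec$size
  half <- n / 2
  ctr <- (n - 1) / 2
  ax <- seq_len(n) - 1 - ctr
  X <- array(rep(ax, times = n * n), dim = c(n, n, n))
  Y <- aperm(X, c(2, 1, 3))
  Z <- aperm(X, c(3, 2, 1))
  R <- .rotation_matrix(spec$angles)
  P <- cbind(as.vector(X), as.vector(Y), as.vector(Z)) %*% t(R)
  a <- spec$semi_axes * half
  # normalized ellipsoid radius: 1 on the unperturbed outer surface
  f <- sqrt((P[, 1] / a[1])^2 + (P[, 2] / a[2])^2 + (P[, 3] / a[3])^2)
  u <- P / half
  pert <- spec$detail_amp *
    sin(spec$detail_freq * u[, 1]) *
    sin(spec$detail_freq * u[, 2]) *
    sin(spec$detail_freq * u[, 3])
  phi <- f * (1 + pert)
  # radial gradient of f is about 1/mean(a), so this delta makes the
  # shell `thickness` voxels thick along the radius
  delta <- spec$thickness / mean(a)
  occ <- phi <= 1 & phi >= 1 - delta
  voxel_grid(array(as.integer(occ), dim = c(n, n, n)))
}

#' Synthetic craniotomy defect specification
#'
#' @param shape `"sphere"` or `"box"`.
#' @param size defect radius (half-width for boxes) as a fraction of the
#'   outer shell radius (half the grid extent); values above 1 allow
#'   degenerate defects covering the whole grid.
#' @param seed integer seed; the defect center is drawn from the upper
#'   (cranial) third of the shell's occupied voxels.
#' @return An object of class `DefectSpec`.
#' @export
defect_spec <- function(shape = c("sphere", "box"), size = 0.25, seed = 1L) {
  stopifnot(size > 0, size <= 2)
  structure(list(shape = match.arg(shape), size = size,
                 seed = as.integer(seed)),
            class = "DefectSpec")
}

#' Cut a synthetic cranial defect from a shell
#'
#' Simulates a craniotomy: a spherical or box region centered in the
#' upper third of the shell is removed.  The defective grid and the
#' removed bone (the implant) partition the input exactly:
#' `defective + implant = grid`, disjoint, implant nonempty.
#'
#' @param grid a [voxel_grid()] (the complete shell).
#' @param spec a [defect_spec()].
#' @param max_tries resample attempts for a center whose region misses
#'   the shell.
#' @return List with `defective` and `implant` [voxel_grid()]s; the
#'   sampled center and radius are attached as attribute `"defect"`.
#' @export
apply_defect <- function(grid, spec, max_tries = 10L) {
  stopifnot(inherits(grid, "VoxelGrid"), inherits(spec, "DefectSpec"))
  occ <- which(grid$data != 0L, arr.ind = TRUE)
  if (nrow(occ) == 0L) stop("cannot cut a defect from an empty grid")
  n <- dim(grid$data)
  zs <- occ[, 3]
  z_lo <- min(zs) + 2 / 3 * (max(zs) - min(zs))
  top <- occ[zs >= z_lo, , drop = FALSE]
  if (nrow(top) == 0L) top <- occ
  radius <- spec$size * max(dim(grid$data)) / 2
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(spec$seed)
  for (try in seq_len(max_tries)) {
    ctr <- top[sample(nrow(top), 1L), ]
    ax <- lapply(1:3, function(a) seq_len(n[a]) - ctr[a])
    if (spec$shape == "sphere") {
      D2 <- outer(outer(ax[[1]]^2, ax[[2]]^2, `+`), ax[[3]]^2, `+`)
      region <- D2 <= radius^2
    } else {
      inside <- lapply(ax, function(v) abs(v) <= radius)
      region <- outer(outer(inside[[1]], inside[[2]], `&`), inside[[3]], `&`)
    }
    implant <- grid$data * region
    if (sum(implant) > 0L) {
      defective <- grid$data - implant
      res <- list(
        defective = voxel_grid(defective, grid$spacing, grid$origin),
        implant = voxel_grid(implant, grid$spacing, grid$origin)
      )
      attr(res, "defect") <- list(center = as.integer(ctr) - 1L,
                                  radius = radius, shape = spec$shape,
                                  tries = try)
      return(res)
    }
  }
  stop("defect region missed the shell in ", max_tries, " attempts")
}

# block-mean coarsening calibrated so that trilinear up-scaling of the
# result reproduces the fine grid's occupied-voxel count on average:
# means above 5/8 are kept, the 5/8 boundary class is kept on a
# checkerboard (deterministic, volume-unbiased)
.volume_preserving_coarse <- function(grid, factor) {
  v <- .block_reduce(.pad_to_multiple(grid$data, factor), factor, "mean")
  keep <- v > 0.625 + 1e-9
  tie <- abs(v - 0.625) <= 1e-9
  if (any(tie)) {
    d <- dim(v)
    idx <- which(tie, arr.ind = TRUE)
    even <- (idx[, 1] + idx[, 2] + idx[, 3]) %% 2L == 0L
    keep[which(tie)[even]] <- TRUE
  }
  voxel_grid(array(as.integer(keep), dim = dim(v)),
             spacing = grid$spacing * factor, origin = grid$origin)
}

.derive_seed <- function(seed, i, salt = 0L) {
  # counter-based substream; stays far below 2^31
  as.integer((as.numeric(seed) * 7919 + i * 104729 + salt * 31) %% 2147483629)
}

.random_shell_spec <- function(size, seed) {
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(seed)
  shell_spec(
    size = size,
    semi_axes = runif(3, 0.60, 0.85),
    thickness = runif(1, 1.6, 2.4),
    detail_amp = runif(1, 0.02, 0.06),
    detail_freq = sample(4:8, 1),
    angles = runif(3, -0.25, 0.25),
    seed = seed
  )
}

#' Generate a synthetic multi-resolution dataset
#'
#' Produces `n` randomized shells at the largest requested resolution
#' plus block-max downsampled versions at the remaining resolutions.
#' For the completion task each sample carries a defective/implant pair
#' cut at every resolution; for super-resolution each sample carries the
#' coarse grid, its trilinearly up-scaled version, and the
#' high-resolution target.  All randomness flows from `seed` through a
#' counter-based substream per sample, so a repeated call reproduces the
#' dataset (and its manifest) exactly.
#'
#' @param n number of samples.
#' @param resolutions increasing vector of grid sizes; each must divide
#'   the next (e.g. `c(16, 32)`).
#' @param task `"completion"` or `"superres"`.
#' @param seed master seed.
#' @param defect_shape,defect_size forwarded to [defect_spec()].
#' @param split_fraction fraction of samples assigned to the training
#'   split (the remainder is the test split).
#' @param out_dir optional directory: samples are written as NRRD files
#'   with a `manifest.json` describing specs, seeds and splits.
#' @return List with `samples` (per-sample lists of grids), `manifest`
#'   (a list mirroring `manifest.json`), and `split` assignments.
#' @export
make_dataset <- function(n, resolutions = c(32L), task = c("completion", "superres"),
                         seed = 1L, defect_shape = "sphere",
                         defect_size = 0.25, split_fraction = 0.75,
                         out_dir = NULL) {
  task <- match.arg(task)
  resolutions <- sort(as.integer(resolutions))
  rmax <- max(resolutions)
  stopifnot(all(rmax %% resolutions == 0L))
  if (task == "superres" && length(resolutions) < 2L) {
    stop("super-resolution needs at least two resolutions")
  }
  n_train <- ceiling(split_fraction * n)
  split <- rep(c("train", "test"), c(n_train, n - n_train))
  samples <- vector("list", n)
  manifest_samples <- vector("list", n)
  if (!is.null(out_dir) && !dir.exists(out_dir)) {
    dir.create(out_dir, recursive = TRUE)
  }
  for (i in seq_len(n)) {
    sseed <- .derive_seed(seed, i)
    sp <- .random_shell_spec(rmax, sseed)
    complete <- make_shell(sp)
    grids <- list()
    grids[[as.character(rmax)]] <- complete
    for (r in rev(resolutions[resolutions < rmax])) {
      grids[[as.character(r)]] <- downsample(complete, rmax %/% r)
    }
    smp <- list(id = i, split = split[i], grids = grids, spec = sp)
    if (task == "completion") {
      for (r in resolutions) {
        dsp <- defect_spec(defect_shape, defect_size,
                           seed = .derive_seed(seed, i, salt = r))
        dd <- apply_defect(grids[[as.character(r)]], dsp)
        smp[[paste0("defective_", r)]] <- dd$defective
        smp[[paste0("implant_", r)]] <- dd$implant
      }
      # convenience aliases at the maximum resolution
      smp$complete <- grids[[as.character(rmax)]]
      smp$defective <- smp[[paste0("defective_", rmax)]]
      smp$implant <- smp[[paste0("implant_", rmax)]]
    } else {
      # the coarse input is made by volume-preserving block-mean
      # coarsening (not the occupancy-preserving block max used for
      # ground-truth pyramids), so its up-scaled version matches the
      # target's voxel count -- the rearrangement premise of the task.
      # Block means are multiples of 1/f^3; the boundary class is
      # dithered on a checkerboard so neither rounding direction biases
      # the occupied volume.
      r_lo <- resolutions[1]
      coarse <- .volume_preserving_coarse(complete, rmax %/% r_lo)
      smp$coarse <- coarse
      smp$input <- upscale(coarse, rmax %/% r_lo)
      smp$target <- grids[[as.character(rmax)]]
    }
    samples[[i]] <- smp
    manifest_samples[[i]] <- list(
      id = i, split = split[i], seed = sseed,
      shell = unclass(sp)[c("size", "semi_axes", "thickness", "detail_amp",
                            "detail_freq", "angles")],
      nonzero = lapply(grids, nnz)
    )
    if (task == "completion") {
      manifest_samples[[i]]$conservation <- lapply(resolutions, function(r) {
        list(resolution = r,
             defective = nnz(smp[[paste0("defective_", r)]]),
             implant = nnz(smp[[paste0("implant_", r)]]),
             complete = nnz(grids[[as.character(r)]]))
      })
    }
    if (!is.null(out_dir)) {
      base <- file.path(out_dir, sprintf("sample%03d", i))
      for (r in names(grids)) {
        write_grid(grids[[r]], paste0(base, "_complete_", r, ".nrrd"))
      }
      if (task == "completion") {
        for (r in resolutions) {
          write_grid(smp[[paste0("defective_", r)]],
                     paste0(base, "_defective_", r, ".nrrd"))
          write_grid(smp[[paste0("implant_", r)]],
                     paste0(base, "_implant_", r, ".nrrd"))
        }
      } else {
        write_grid(smp$input, paste0(base, "_upscaled.nrrd"))
      }
    }
  }
  manifest <- list(n = n, task = task, resolutions = resolutions,
                   seed = as.integer(seed), defect_shape = defect_shape,
                   defect_size = defect_size,
                   split_fraction = split_fraction,
                   samples = manifest_samples)
  if (!is.null(out_dir)) {
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }
  list(samples = samples, manifest = manifest, split = split)
}

#' Split a dataset into train and test sample lists
#'
#' @param ds a [make_dataset()] result.
#' @return List with `train` and `test` sample lists.
#' @export
dataset_splits <- function(ds) {
  list(train = ds$samples[ds$split == "train"],
       test = ds$samples[ds$split == "test"])
}
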