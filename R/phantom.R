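#' Configuration for the synthetic MRI phantom
#'
#' The phantom emulates anisotropic paediatric brain acquisitions: an
#' ellipsoidal white-matter compartment inside GM and CSF rims, with thin
#' tubular structures planted inside the white matter that are hyperintense
#' on T2 and hypointense on T1, the way perivascular spaces appear. The
#' default grids reproduce the study geometry (T1 0.8 x 0.8 x 4.4 mm, T2
#' 0.4 x 0.4 x 4.4 mm).
#'
#' @param grid_dims integer length-3, voxels per axis of the T1 grid.
#' @param spacing_t1,spacing_t2 mm per axis.
#' @param n_tubes number of tubes to plant (>= 0).
#' @param tube_radius_mm length-2 range of tube radii, mm.
#' @param tube_length_mm length-2 range of tube lengths, mm.
#' @param orientation_model `"isotropic"` (uniform directions),
#'   `"axis_mix"` (tube axes drawn from the three grid axes), or `"z_axis"`
#'   (all tubes through-plane, perpendicular to the axial slices).
#' @param snap_to_slices logical; snap tube endpoints to slice-slab
#'   boundaries so each intersected slab is fully traversed and the
#'   half-volume ground truth is unambiguous at slab edges.
#' @param tissue_intensities per-modality named levels for `wm`, `gm`,
#'   `csf`, `pvs`, `bg`. PVS must be brighter than WM on T2 and darker on T1.
#' @param bias_amplitude fractional peak deviation of a smooth multiplicative
#'   field, in [0, 1).
#' @param noise_sigma noise scale as a fraction of the WM level (>= 0).
#' @param noise_model `"gaussian"` or `"rician"`.
#' @param misalignment a [rigid_transform()] applied to the T2 acquisition
#'   (what registration must recover).
#' @param supersample sub-voxel sampling factor per axis for partial-volume
#'   rendering.
#' @param min_separation_mm minimum surface-to-surface distance between tubes.
#' @param seed integer RNG seed.
#' @return An object of class `phantom_config`.
#' @export
phantom_config <- function(grid_dims = c(128, 128, 24),
                           spacing_t1 = c(0.8, 0.8, 4.4),
                           spacing_t2 = c(0.4, 0.4, 4.4),
                           n_tubes = 10,
                           tube_radius_mm = c(0.3, 1.2),
                           tube_length_mm = c(8, 30),
                           orientation_model = c("isotropic", "axis_mix", "z_axis"),
                           snap_to_slices = FALSE,
                           tissue_intensities = list(
                             t1 = c(wm = 1000, gm = 800, csf = 400, pvs = 700, bg = 0),
                             t2 = c(wm = 1000, gm = 1100, csf = 1500, pvs = 1300, bg = 0)),
                           bias_amplitude = 0,
                           noise_sigma = 0,
                           noise_model = c("gaussian", "rician"),
                           misalignment = rigid_transform(),
                           supersample = 2L,
                           min_separation_mm = 2.5,
                           seed = 1L) {
  orientation_model <- match.arg(orientation_model)
  noise_model <- match.arg(noise_model)
  stopifnot(length(grid_dims) == 3L, all(grid_dims >= 4))
  if (any(spacing_t1 <= 0) || any(spacing_t2 <= 0))
    stop("spacings must be strictly positive", call. = FALSE)
  if (n_tubes < 0) stop("`n_tubes` must be >= 0", call. = FALSE)
  if (any(tube_radius_mm <= 0)) stop("tube radii must be positive", call. = FALSE)
  if (noise_sigma < 0) stop("`noise_sigma` must be >= 0", call. = FALSE)
  if (bias_amplitude < 0 || bias_amplitude >= 1)
    stop("`bias_amplitude` must be in [0, 1)", call. = FALSE)
  for (m in c("t1", "t2"))
    stopifnot(all(c("wm", "gm", "csf", "pvs", "bg") %in%
                    names(tissue_intensities[[m]])))
  if (tissue_intensities$t2["pvs"] <= tissue_intensities$t2["wm"])
    stop("PVS must be T2-hyperintense relative to WM", call. = FALSE)
  if (tissue_intensities$t1["pvs"] >= tissue_intensities$t1["wm"])
    stop("PVS must be T1-hypointense relative to WM", call. = FALSE)
  structure(list(grid_dims = as.integer(grid_dims),
                 spacing_t1 = spacing_t1, spacing_t2 = spacing_t2,
                 n_tubes = as.integer(n_tubes),
                 tube_radius_mm = tube_radius_mm,
                 tube_length_mm = tube_length_mm,
                 orientation_model = orientation_model,
                 snap_to_slices = snap_to_slices,
                 tissue_intensities = tissue_intensities,
                 bias_amplitude = bias_amplitude,
                 noise_sigma = noise_sigma, noise_model = noise_model,
                 misalignment = misalignment,
                 supersample = as.integer(supersample),
                 min_separation_mm = min_separation_mm,
                 seed = as.integer(seed)),
            class = "phantom_config")
}

# Ellipsoid semi-axes of the brain compartments, derived from the T1
# field of view. Normalized radius rho = |x / a_brain|; WM is rho <= 0.70,
# GM rim 0.70-0.92, CSF rim 0.92-1.
phantom_geometry <- function(config) {
  fov <- config$grid_dims * config$spacing_t1
  a_brain <- 0.44 * fov
  list(a_brain = a_brain, wm_rho = 0.70, gm_rho = 0.92)
}

ellipsoid_rho <- function(pts, a) {
  sqrt((pts[, 1] / a[1])^2 + (pts[, 2] / a[2])^2 + (pts[, 3] / a[3])^2)
}

# Minimum distance between two 3D segments (standard clamped closest-point
# computation), used to keep planted tubes apart.
segment_distance <- function(p0, p1, q0, q1) {
  u <- p1 - p0; v <- q1 - q0; w <- p0 - q0
  a <- sum(u * u); b <- sum(u * v); c <- sum(v * v)
  d <- sum(u * w); e <- sum(v * w)
  D <- a * c - b * b
  sc <- sD <- tc <- tD <- D
  # relative parallelism test: D is a difference of O(a*c) products, so an
  # absolute cutoff misclassifies near-parallel segments
  if (D < 1e-9 * max(a * c, 1e-12)) { sN <- 0; sD <- 1; tN <- e; tD <- c }
  else {
    sN <- b * e - c * d; tN <- a * e - b * d
    if (sN < 0) { sN <- 0; tN <- e; tD <- c }
    else if (sN > sD) { sN <- sD; tN <- e + b; tD <- c }
  }
  if (tN < 0) {
    tN <- 0
    if (-d < 0) sN <- 0 else if (-d > a) sN <- sD else { sN <- -d; sD <- a }
  } else if (tN > tD) {
    tN <- tD
    if ((-d + b) < 0) sN <- 0 else if ((-d + b) > a) sN <- sD
    else { sN <- -d + b; sD <- a }
  }
  sc <- if (abs(sN) < 1e-12 || sD <= 0) 0 else sN / sD
  tc <- if (abs(tN) < 1e-12 || tD <= 0) 0 else tN / tD
  dP <- w + sc * u - tc * v
  sqrt(sum(dP * dP))
}

sample_direction <- function(model) {
  switch(model,
    isotropic = {
      z <- stats::runif(1, -1, 1)
      phi <- stats::runif(1, 0, 2 * pi)
      r <- sqrt(1 - z^2)
      c(r * cos(phi), r * sin(phi), z)
    },
    axis_mix = {
      ax <- sample.int(3, 1)
      d <- c(0, 0, 0); d[ax] <- 1
      d
    },
    z_axis = c(0, 0, 1))
}

place_tubes <- function(config, geom) {
  if (config$n_tubes == 0L)
    return(data.frame(x0 = numeric(0), y0 = numeric(0), z0 = numeric(0),
                      x1 = numeric(0), y1 = numeric(0), z1 = numeric(0),
                      radius = numeric(0)))
  a_wm <- geom$wm_rho * geom$a_brain
  if (max(config$tube_radius_mm) > 0.25 * min(a_wm))
    stop("tube radius too large for the white-matter compartment thickness",
         call. = FALSE)
  dz <- config$spacing_t1[3]
  z_lo <- -config$grid_dims[3] * dz / 2
  tubes <- list()
  attempts <- 0L
  max_attempts <- 400L * config$n_tubes
  while (length(tubes) < config$n_tubes && attempts < max_attempts) {
    attempts <- attempts + 1L
    radius <- stats::runif(1, config$tube_radius_mm[1], config$tube_radius_mm[2])
    len <- stats::runif(1, config$tube_length_mm[1], config$tube_length_mm[2])
    dir <- sample_direction(config$orientation_model)
    # centre well inside the WM compartment
    repeat {
      ctr <- stats::runif(3, -1, 1) * 0.55 * a_wm
      if (ellipsoid_rho(matrix(ctr, 1), a_wm) <= 0.8) break
    }
    p0 <- ctr - dir * len / 2
    p1 <- ctr + dir * len / 2
    if (config$snap_to_slices && abs(dir[3]) > 0.99) {
      # snap endpoints to slab boundaries (z planes at z_lo + k * dz) and
      # the centre to the in-plane voxel lattice, so the half-volume ground
      # truth is unambiguous at slab edges and voxel corners
      p0[3] <- z_lo + round((p0[3] - z_lo) / dz) * dz
      p1[3] <- z_lo + round((p1[3] - z_lo) / dz) * dz
      if (abs(p1[3] - p0[3]) < dz) p1[3] <- p0[3] + dz * sign(dir[3])
      for (ax in 1:2) {
        sp <- config$spacing_t1[ax]
        half <- (config$grid_dims[ax] - 1) / 2
        snapped <- (round(p0[ax] / sp + half) - half) * sp
        p0[ax] <- snapped; p1[ax] <- snapped
      }
    }
    # keep the whole tube (and its partial-volume shell) inside the WM
    # compartment even after one-voxel 3D erosion: per-axis margin of two
    # voxels plus the tube radius
    a_eff <- a_wm - (radius + 1 + 2 * config$spacing_t1)
    if (any(a_eff <= 0))
      stop("tube radius too large for the white-matter compartment thickness",
           call. = FALSE)
    if (max(ellipsoid_rho(rbind(p0, p1), a_eff)) > 1) next
    ok <- TRUE
    for (tb in tubes) {
      d <- segment_distance(p0, p1, tb$p0, tb$p1)
      if (d < radius + tb$radius + config$min_separation_mm) { ok <- FALSE; break }
    }
    if (ok) tubes[[length(tubes) + 1L]] <- list(p0 = p0, p1 = p1, radius = radius)
  }
  if (length(tubes) < config$n_tubes)
    stop(sprintf(
      "could only place %d of %d tubes without overlap after %d attempts",
      length(tubes), config$n_tubes, attempts), call. = FALSE)
  do.call(rbind, lapply(tubes, function(tb)
    data.frame(x0 = tb$p0[1], y0 = tb$p0[2], z0 = tb$p0[3],
               x1 = tb$p1[1], y1 = tb$p1[2], z1 = tb$p1[3],
               radius = tb$radius)))
}

# Sub-voxel offsets (in voxel units) for partial-volume supersampling.
supersample_offsets <- function(s) {
  g <- (seq_len(s) - 0.5) / s - 0.5
  as.matrix(expand.grid(dx = g, dy = g, dz = g))
}

# Render one modality on a grid. `world_pts` are anatomical coordinates of
# the voxel centres; tissue levels come from ellipsoid classification and
# tubes are painted with analytic-distance partial-volume fractions.
render_modality <- function(world_pts, dims, affine, geom, tubes, levels,
                            supersample) {
  n <- nrow(world_pts)
  offs <- supersample_offsets(supersample)
  lin <- affine[1:3, 1:3]
  acc <- numeric(n)
  frac <- numeric(n)
  for (q in seq_len(nrow(offs))) {
    pts <- world_pts + matrix(rep(lin %*% as.numeric(offs[q, ]), each = n),
                              n, 3)
    rho <- ellipsoid_rho(pts, geom$a_brain)
    base <- ifelse(rho <= geom$wm_rho, levels["wm"],
            ifelse(rho <= geom$gm_rho, levels["gm"],
            ifelse(rho <= 1, levels["csf"], levels["bg"])))
    in_tube <- rep(FALSE, n)
    if (nrow(tubes) > 0) {
      for (t in seq_len(nrow(tubes))) {
        d <- dist_to_segment_cpp(pts, as.numeric(tubes[t, 1:3]),
                                 as.numeric(tubes[t, 4:6]))
        in_tube <- in_tube | (d <= tubes$radius[t])
      }
    }
    acc <- acc + ifelse(in_tube, levels["pvs"], base)
    frac <- frac + in_tube
  }
  m <- nrow(offs)
  list(voxels = array(acc / m, dims), pvs_fraction = array(frac / m, dims))
}

smooth_bias_field <- function(dims, amplitude) {
  # random quadratic polynomial in scaled coordinates, peak-normalized
  u <- lapply(dims, function(d) seq(-1, 1, length.out = d))
  cf <- stats::rnorm(9)
  x <- u[[1]][slice.index(array(0, dims), 1)]
  y <- u[[2]][slice.index(array(0, dims), 2)]
  z <- u[[3]][slice.index(array(0, dims), 3)]
  q <- cf[1] * x + cf[2] * y + cf[3] * z + cf[4] * x * y + cf[5] * x * z +
    cf[6] * y * z + cf[7] * x^2 + cf[8] * y^2 + cf[9] * z^2
  1 + amplitude * q / max(abs(q))
}

add_noise <- function(voxels, sigma, model) {
  if (sigma <= 0) return(voxels)
  d <- dim(voxels)
  if (model == "gaussian") {
    voxels + array(stats::rnorm(length(voxels), 0, sigma), d)
  } else {
    n1 <- array(stats::rnorm(length(voxels), 0, sigma), d)
    n2 <- array(stats::rnorm(length(voxels), 0, sigma), d)
    sqrt((voxels + n1)^2 + n2^2)
  }
}

#' Generate a synthetic T1/T2 phantom with ground truth
#'
#' Plants non-overlapping straight cylinders inside an ellipsoidal
#' white-matter compartment, renders both modalities with sub-voxel
#' partial-volume fractions, applies a smooth multiplicative bias field and
#' noise after structure painting, and acquires the T2 volume through the
#' configured rigid misalignment. The ground-truth PVS mask on the T1 grid
#' marks voxels at least half filled by a tube.
#'
#' @param config a [phantom_config()].
#' @return An object of class `pvs_phantom`: list with elements `t1`, `t2`
#'   (`pvs_volume`), `wm_mask_true`, `pvs_mask_true` (`pvs_mask` on the T1
#'   grid), `per_slice_true_counts`, `transform_true`, `tubes`, `config`.
#' @export
generate_phantom <- function(config) {
  stopifnot(inherits(config, "phantom_config"))
  geom <- phantom_geometry(config)
  with_seed(config$seed, {
    tubes <- place_tubes(config, geom)

    d1 <- config$grid_dims
    aff1 <- diag(c(config$spacing_t1, 1))
    aff1[1:3, 4] <- -config$spacing_t1 * (d1 - 1) / 2
    fov <- d1 * config$spacing_t1
    d2 <- as.integer(round(fov / config$spacing_t2))
    aff2 <- diag(c(config$spacing_t2, 1))
    aff2[1:3, 4] <- -config$spacing_t2 * (d2 - 1) / 2

    proto1 <- image_volume(array(0, d1), config$spacing_t1, aff1)
    ctr1 <- voxel_centers(proto1)
    r1 <- render_modality(ctr1, d1, aff1, geom, tubes,
                          config$tissue_intensities$t1, config$supersample)

    proto2 <- image_volume(array(0, d2), config$spacing_t2, aff2)
    ctr2 <- apply_transform(config$misalignment, voxel_centers(proto2))
    r2 <- render_modality(ctr2, d2, aff2, geom, tubes,
                          config$tissue_intensities$t2, config$supersample)

    t1v <- r1$voxels
    t2v <- r2$voxels
    if (config$bias_amplitude > 0) {
      t1v <- t1v * smooth_bias_field(d1, config$bias_amplitude)
      t2v <- t2v * smooth_bias_field(d2, config$bias_amplitude)
    }
    t1v <- add_noise(t1v, config$noise_sigma * config$tissue_intensities$t1["wm"],
                     config$noise_model)
    t2v <- add_noise(t2v, config$noise_sigma * config$tissue_intensities$t2["wm"],
                     config$noise_model)

    t1 <- image_volume(t1v, config$spacing_t1, aff1, modality = "T1")
    t2 <- image_volume(t2v, config$spacing_t2, aff2, modality = "T2")

    rho1 <- ellipsoid_rho(ctr1, geom$a_brain)
    wm_true <- binary_mask(array(rho1 <= geom$wm_rho, d1), t1)
    pvs_true <- binary_mask(r1$pvs_fraction >= 0.5 & wm_true$voxels, t1)

    counts <- label_clusters_per_slice(pvs_true, slice_axis = 3L)$counts

    structure(list(t1 = t1, t2 = t2, wm_mask_true = wm_true,
                   pvs_mask_true = pvs_true,
                   per_slice_true_counts = counts,
                   transform_true = config$misalignment,
                   tubes = tubes, config = config),
              class = "pvs_phantom")
  })
}

#' @export
print.pvs_phantom <- function(x, ...) {
  cat(sprintf("<pvs_phantom> %d tubes, T1 %s, T2 %s, max true slice count %d\n",
              nrow(x$tubes), paste(dim(x$t1$voxels), collapse = "x"),
              paste(dim(x$t2$voxels), collapse = "x"),
              max(x$per_slice_true_counts)))
  invisible(x)
}

#' Write a phantom case to disk
#'
#' Writes `t1.nii.gz`, `t2.nii.gz`, `wm_mask.nii.gz`, `pvs_mask.nii.gz` and a
#' `truth.json` sidecar holding the per-slice true counts, the misalignment
#' transform and the seed.
#'
#' @param case a `pvs_phantom`.
#' @param dir output directory (created if absent).
#' @return `dir` invisibly.
#' @export
write_phantom <- function(case, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_volume(case$t1, file.path(dir, "t1.nii.gz"))
  write_volume(case$t2, file.path(dir, "t2.nii.gz"))
  write_volume(case$wm_mask_true, file.path(dir, "wm_mask.nii.gz"))
  write_volume(case$pvs_mask_true, file.path(dir, "pvs_mask.nii.gz"))
  sidecar <- list(per_slice_true_counts = case$per_slice_true_counts,
                  transform_true = case$transform_true[c("rotation",
                                                         "translation",
                                                         "center")],
                  seed = case$config$seed,
                  tubes = case$tubes)
  jsonlite::write_json(sidecar, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
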