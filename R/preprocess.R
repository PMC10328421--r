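# ---- resampling -----------------------------------------------------------

#' Resample a volume onto the grid of another through a rigid transform
#'
#' The transform maps moving-image world coordinates to fixed-image world
#' coordinates (the registration convention). Intensities are interpolated
#' trilinearly; masks should use `nearest = TRUE` to stay binary. Voxels
#' falling outside the moving grid get `fill`.
#'
#' @param moving a `pvs_volume` (or `pvs_mask`).
#' @param fixed a `pvs_volume` supplying the target grid.
#' @param transform a [rigid_transform()] (identity by default).
#' @param nearest logical; nearest-neighbour instead of trilinear.
#' @param fill value for out-of-field voxels.
#' @return a `pvs_volume` on the fixed grid.
#' @export
resample_to_grid <- function(moving, fixed, transform = rigid_transform(),
                             nearest = FALSE, fill = 0) {
  map <- solve(moving$affine) %*% transform_inverse_matrix(transform) %*%
    fixed$affine
  src <- moving$voxels
  if (is.logical(src)) src <- array(as.numeric(src), dim(src))
  out <- resample_trilinear_cpp(src, as.integer(dim(fixed$voxels)), map)
  if (nearest) out <- array(as.numeric(out >= 0.5), dim(out))
  out[is.na(out)] <- fill
  image_volume(out, fixed$spacing, fixed$affine, modality = moving$modality)
}

normalized_mutual_information <- function(a, b, bins = 32L) {
  ok <- is.finite(a) & is.finite(b)
  a <- a[ok]; b <- b[ok]
  if (length(a) < 10) return(0)
  cut_bins <- function(x) {
    r <- range(x)
    if (r[2] - r[1] <= 0) return(rep(1L, length(x)))
    pmin(pmax(1L, as.integer((x - r[1]) / (r[2] - r[1]) * bins) + 1L), bins)
  }
  ia <- cut_bins(a); ib <- cut_bins(b)
  joint <- tabulate((ia - 1L) * bins + ib, nbins = bins * bins)
  p <- joint / sum(joint)
  h <- function(p) { p <- p[p > 0]; -sum(p * log(p)) }
  pj <- matrix(p, bins, bins)
  ha <- h(colSums(pj)); hb <- h(rowSums(pj)); hab <- h(p)
  if (hab <= 0) return(0)
  (ha + hb) / hab
}

#' Registration settings
#' @param bins joint-histogram bins for the mutual-information metric.
#' @param levels in-plane subsampling strides of the multi-resolution
#'   schedule (coarse to fine).
#' @param maxit Nelder-Mead iteration cap per level.
#' @param init optional initial [rigid_transform()].
#' @return a list of settings.
#' @export
register_settings <- function(bins = 32L, levels = c(4L, 2L, 1L),
                              maxit = c(1000L, 800L, 800L), init = NULL) {
  list(bins = bins, levels = levels,
       maxit = rep_len(maxit, length(levels)), init = init)
}

#' Rigid T2-to-T1 registration by normalized mutual information
#'
#' Estimates the 6-DOF transform aligning `moving` to `fixed` by maximizing
#' normalized mutual information over a coarse-to-fine in-plane subsampling
#' schedule (Nelder-Mead), rotations parameterized about the fixed-volume
#' world centre. A user-supplied `transform` bypasses optimization entirely.
#'
#' @param moving,fixed `pvs_volume`s with overlapping fields of view.
#' @param settings a [register_settings()] list.
#' @param transform optional known [rigid_transform()]; if given, no
#'   optimization is run.
#' @return list with `transform` (a `pvs_rigid`), `resampled` (moving on the
#'   fixed grid), `metric` (final NMI), `converged`.
#' @export
rigid_register <- function(moving, fixed, settings = register_settings(),
                           transform = NULL) {
  if (stats::sd(moving$voxels) == 0 || stats::sd(fixed$voxels) == 0)
    stop("degenerate (constant) image cannot be registered", call. = FALSE)
  center <- as.numeric(fixed$affine %*% c((dim(fixed$voxels) - 1) / 2, 1))[1:3]
  raw_resample <- function(tf) {
    map <- solve(moving$affine) %*% transform_inverse_matrix(tf) %*%
      fixed$affine
    resample_trilinear_cpp(moving$voxels, as.integer(dim(fixed$voxels)), map)
  }
  if (!is.null(transform)) {
    raw <- raw_resample(transform)
    metric <- normalized_mutual_information(fixed$voxels, raw, settings$bins)
    raw[is.na(raw)] <- 0
    return(list(transform = transform,
                resampled = image_volume(raw, fixed$spacing, fixed$affine,
                                         modality = moving$modality),
                metric = metric, converged = TRUE))
  }
  par0 <- c(0, 0, 0, 0, 0, 0)
  if (!is.null(settings$init))
    par0 <- c(settings$init$rotation, settings$init$translation)

  # strict best-seen record: the metric can plateau (histogram binning on
  # piecewise-constant content), and on a tie the earliest parameter wins,
  # so an exact starting alignment is never drifted away from
  best <- list(value = Inf, par = par0)
  objective <- function(par, sub_fixed) {
    tf <- rigid_transform(par[1:3], par[4:6], center)
    map <- solve(moving$affine) %*% transform_inverse_matrix(tf) %*%
      sub_fixed$affine
    mv <- resample_trilinear_cpp(moving$voxels,
                                 as.integer(dim(sub_fixed$voxels)), map)
    val <- -normalized_mutual_information(sub_fixed$voxels, mv, settings$bins)
    if (val < best$value) best <<- list(value = val, par = par)
    val
  }

  par <- par0
  converged <- TRUE
  # only the finest level's convergence status matters: coarse levels are
  # warm starts and may legitimately exhaust their iteration caps
  for (li in seq_along(settings$levels)) {
    s <- settings$levels[li]
    best <- list(value = Inf, par = par)  # per-level record (metric scales differ)
    d <- dim(fixed$voxels)
    # in-plane block-mean pooling: the averaging smooths the metric, which
    # removes the grid-aligned interpolation scallops that trap the
    # optimizer at coarse levels (plain stride subsampling does not)
    ds <- pmax(c(d[1] %/% s, d[2] %/% s), 1L)
    a <- fixed$voxels[seq_len(ds[1] * s), seq_len(ds[2] * s), , drop = FALSE]
    dim(a) <- c(s, ds[1], s * ds[2] * d[3])
    a <- colMeans(a)
    dim(a) <- c(ds[1], s, ds[2] * d[3])
    a <- colMeans(aperm(a, c(2, 1, 3)))
    dim(a) <- c(ds[1], ds[2], d[3])
    affs <- fixed$affine %*%
      rbind(cbind(diag(c(s, s, 1)), c((s - 1) / 2, (s - 1) / 2, 0)),
            c(0, 0, 0, 1))
    sub <- image_volume(a, fixed$spacing * c(s, s, 1), affs)
    opt <- stats::optim(par, objective, sub_fixed = sub,
                        method = "Nelder-Mead",
                        control = list(maxit = settings$maxit[li],
                                       parscale = c(rep(0.05, 3), rep(8, 3)),
                                       reltol = 1e-6))
    par <- opt$par
    if (li == length(settings$levels)) {
      # small-step refinement: the wide exploration simplex above escapes
      # interpolation scallops but limits final precision; restart locally
      opt <- stats::optim(par, objective, sub_fixed = sub,
                          method = "Nelder-Mead",
                          control = list(maxit = settings$maxit[li],
                                         parscale = c(rep(0.005, 3),
                                                      rep(0.5, 3)),
                                         reltol = 1e-8))
      par <- opt$par
      converged <- opt$convergence == 0
    }
    if (best$value <= opt$value) par <- best$par
    if (li == length(settings$levels)) {
      # tie-break toward the starting parameters: on a metric plateau the
      # initial alignment is preferred over optimizer drift
      if (objective(par0, sub) <= objective(par, sub)) par <- par0
    }
  }
  tf <- rigid_transform(par[1:3], par[4:6], center)
  if (!converged) {
    cond <- structure(class = c("wmpvs_registration_error", "error",
                                "condition"),
                      list(message = "registration did not converge within the iteration budget",
                           call = sys.call(-1), transform = tf))
    stop(cond)
  }
  raw <- raw_resample(tf)
  metric <- normalized_mutual_information(fixed$voxels, raw, settings$bins)
  raw[is.na(raw)] <- 0
  list(transform = tf,
       resampled = image_volume(raw, fixed$spacing, fixed$affine,
                                modality = moving$modality),
       metric = metric, converged = TRUE)
}

# ---- adaptive denoising ---------------------------------------------------

# In-plane 8-neighbour mean via array shifts; returns list(sum, count) so
# border voxels use only their in-image neighbours.
inplane_neighbor_mean <- function(arr) {
  d <- dim(arr)
  s <- array(0, d)
  cnt <- array(0L, d)
  one <- array(1, d)
  for (dx in -1:1) for (dy in -1:1) {
    if (dx == 0 && dy == 0) next
    xs <- seq_len(d[1]) + dx
    ys <- seq_len(d[2]) + dy
    okx <- xs >= 1 & xs <= d[1]
    oky <- ys >= 1 & ys <= d[2]
    s[okx, oky, ] <- s[okx, oky, ] + arr[xs[okx], ys[oky], , drop = FALSE]
    cnt[okx, oky, ] <- cnt[okx, oky, ] + 1L
  }
  list(mean = s / pmax(cnt, 1L), count = cnt)
}

#' Estimate the noise level of a volume
#'
#' Robust estimate from high-pass residuals: each voxel minus the mean of
#' its in-plane 8-neighbour ring, scaled by the median absolute deviation
#' and the variance inflation of the residual operator.
#'
#' @param vol a `pvs_volume`.
#' @return scalar noise sd estimate.
#' @export
estimate_noise_sigma <- function(vol) {
  r <- vol$voxels - inplane_neighbor_mean(vol$voxels)$mean
  stats::mad(r) / sqrt(1 + 1 / 8)
}

#' Adaptive non-local-means denoising
#'
#' Per-slice non-local-means filtering with the smoothing strength tied to a
#' noise level estimated from the volume itself, so structural detail (thin
#' tubes) is preserved while unstructured high-frequency noise is removed.
#' A volume with (near) zero estimated noise is returned unchanged.
#'
#' @param vol a `pvs_volume` with finite intensities.
#' @param patch_radius patch half-width (pixels).
#' @param search_radius search-window half-width (pixels).
#' @param h_factor filtering strength as a multiple of the estimated noise sd.
#' @param guard_beta centre-difference guard activation, in units of the
#'   noise variance (the guard only engages when two centre pixels differ
#'   by more than `sqrt(guard_beta)` sd, protecting single-voxel detail).
#' @param guard_h_factor guard decay scale as a multiple of the noise sd.
#' @return the filtered `pvs_volume`.
#' @export
denoise_adaptive <- function(vol, patch_radius = 1L, search_radius = 5L,
                             h_factor = 0.8, guard_beta = 9,
                             guard_h_factor = 1.3) {
  if (!all(is.finite(vol$voxels)))
    stop("non-finite voxels cannot be denoised", call. = FALSE)
  sigma <- estimate_noise_sigma(vol)
  scale <- diff(range(vol$voxels))
  if (sigma <= 1e-8 * max(scale, 1)) return(vol)
  # adjacent-slab local contrast: gates the centre-difference guard so it
  # protects through-plane tubular structure but not isolated noise spikes
  D <- abs(vol$voxels - inplane_neighbor_mean(vol$voxels)$mean)
  nz <- dim(D)[3]
  zsupport <- array(0, dim(D))
  if (nz > 1) {
    zsupport[, , seq_len(nz - 1)] <- D[, , 2:nz]
    zsupport[, , 2:nz] <- pmax(zsupport[, , 2:nz, drop = FALSE],
                               D[, , seq_len(nz - 1), drop = FALSE])
  }
  out <- nlm2d_cpp(vol$voxels, as.integer(patch_radius),
                   as.integer(search_radius), h_factor * sigma, sigma,
                   guard_beta, guard_h_factor * sigma,
                   zsupport, 2.5 * sigma)
  image_volume(out, vol$spacing, vol$affine, modality = vol$modality)
}

# ---- white-matter intensity uniformization --------------------------------

poly_design <- function(idx, dims, order) {
  u <- sweep(idx, 2, (dims - 1) / 2, "-")
  u <- sweep(u, 2, pmax((dims - 1) / 2, 1), "/")
  cols <- list(rep(1, nrow(u)))
  for (total in 1:order)
    for (i in 0:total) for (j in 0:(total - i)) {
      k <- total - i - j
      cols[[length(cols) + 1L]] <- u[, 1]^i * u[, 2]^j * u[, 3]^k
    }
  do.call(cbind, cols)
}

#' Uniformize white-matter intensity
#'
#' Fits a smooth multiplicative bias field (low-order 3D polynomial) to the
#' white-matter voxel intensities, robust to the hyperintense PVS minority
#' via iterative residual trimming, divides it out and rescales so the WM
#' median equals `target_level` exactly. The fixed median anchor is what
#' makes the downstream detection threshold a reproducible quantity.
#'
#' @param vol a `pvs_volume`.
#' @param wm a `pvs_mask` congruent with `vol`.
#' @param target_level WM median after rescaling (default 1000).
#' @param order polynomial order of the bias model.
#' @param trim_iters robust refit iterations.
#' @param trim_k residual cut in MAD units.
#' @return the corrected `pvs_volume`.
#' @export
uniformize_wm <- function(vol, wm, target_level = 1000, order = 2L,
                          trim_iters = 3L, trim_k = 2.5) {
  check_congruent(vol, wm)
  widx <- which(wm$voxels)
  d <- dim(vol$voxels)
  n_terms <- choose(order + 3, 3)
  if (length(widx) < 4 * n_terms)
    stop("white-matter mask too small for the bias model's degrees of freedom",
         call. = FALSE)
  sub <- arrayInd(widx, d)
  X <- poly_design(sub, d, order)
  y <- vol$voxels[widx]
  keep <- rep(TRUE, length(y))
  beta <- NULL
  for (it in seq_len(trim_iters)) {
    beta <- stats::lm.fit(X[keep, , drop = FALSE], y[keep])$coefficients
    beta[is.na(beta)] <- 0
    res <- y - as.numeric(X %*% beta)
    s <- stats::mad(res[keep])
    if (s <= 1e-8 * max(abs(y))) break  # residuals at numerical zero
    nxt <- abs(res) <= trim_k * s
    if (sum(nxt) < 4 * n_terms) break
    keep <- nxt
  }
  fit_wm <- as.numeric(X %*% beta)
  mean_fit <- mean(fit_wm)
  if (mean_fit <= 0) stop("bias fit degenerate (non-positive level)", call. = FALSE)
  all_idx <- arrayInd(seq_along(vol$voxels), d)
  field <- as.numeric(poly_design(all_idx, d, order) %*% beta) / mean_fit
  field <- pmin(pmax(field, 0.2), 5)
  corrected <- vol$voxels / array(field, d)
  scale <- target_level / stats::median(corrected[widx])
  image_volume(corrected * scale, vol$spacing, vol$affine,
               modality = vol$modality)
}

# ---- mask erosion ---------------------------------------------------------

shift_logical <- function(arr, dx, dy, dz) {
  d <- dim(arr)
  out <- array(FALSE, d)
  xs <- seq_len(d[1]) + dx; ys <- seq_len(d[2]) + dy; zs <- seq_len(d[3]) + dz
  okx <- xs >= 1 & xs <= d[1]; oky <- ys >= 1 & ys <= d[2]
  okz <- zs >= 1 & zs <= d[3]
  out[okx, oky, okz] <- arr[xs[okx], ys[oky], zs[okz], drop = FALSE]
  out
}

#' Morphological erosion of a binary mask
#'
#' Face-connected erosion applied `iterations` times. The default `"3d6"`
#' mode uses the 6-neighbour 3D structuring element; `"2d4"` restricts
#' erosion to in-plane 4-neighbours per axial slice, which is less
#' aggressive when slices are much thicker than the in-plane resolution.
#' Out-of-image neighbours count as background, so border voxels erode.
#'
#' @param mask a `pvs_mask`.
#' @param iterations number of erosion passes (default 1 voxel).
#' @param mode `"3d6"` or `"2d4"`.
#' @return the eroded `pvs_mask`.
#' @export
erode_mask <- function(mask, iterations = 1L, mode = c("3d6", "2d4")) {
  mode <- match.arg(mode)
  offsets <- if (mode == "3d6")
    list(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
         c(0, 0, 1), c(0, 0, -1))
  else
    list(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0))
  v <- mask$voxels
  for (i in seq_len(iterations)) {
    keep <- v
    for (off in offsets)
      keep <- keep & shift_logical(v, off[1], off[2], off[3])
    v <- keep
  }
  out <- mask
  out$voxels <- v
  out
}

# ---- T1/T2 ratio map ------------------------------------------------------

#' Enhanced PVS contrast map (T1/T2 ratio)
#'
#' Voxel-wise T1/T2 ratio combining both modalities: PVS are T1-dark and
#' T2-bright, so they show a depressed ratio against white matter. Provided
#' as a visualization/QC product; detection itself runs on the uniformized
#' T2.
#'
#' @param t1,t2 `pvs_volume`s on the same grid (post-registration).
#' @param mask optional `pvs_mask` restricting the validity check; defaults
#'   to the whole grid.
#' @return a derived `pvs_volume` of ratios (0 where T2 is non-positive
#'   outside the mask).
#' @export
compute_epc <- function(t1, t2, mask = NULL) {
  check_congruent(t1, t2)
  roi <- if (is.null(mask)) array(TRUE, dim(t1$voxels)) else {
    check_congruent(t1, mask)
    mask$voxels
  }
  bad <- sum(t2$voxels[roi] <= 0)
  if (bad > 0)
    stop(sprintf("%d voxels with zero/negative T2 inside the mask", bad),
         call. = FALSE)
  ratio <- array(0, dim(t1$voxels))
  ok <- t2$voxels > 0
  ratio[ok] <- t1$voxels[ok] / t2$voxels[ok]
  image_volume(ratio, t1$spacing, t1$affine, modality = "derived")
}

# ---- fallback white-matter segmentation -----------------------------------

#' Intensity-clustering white-matter segmentation (phantom-grade)
#'
#' A simple stand-in used when no externally produced white-matter mask is
#' supplied: brain extraction by intensity thresholding plus largest
#' 6-connected component, then 3-class 1D k-means on brain voxel
#' intensities (quantile-initialized, deterministic); the brightest-in-T1
#' class is returned as white matter. Suitable for phantoms and QC only,
#' not for clinical-grade segmentation.
#'
#' @param t1 a T1 `pvs_volume` with at least 3 separable intensity classes.
#' @param k number of intensity classes.
#' @return a `pvs_mask` of white matter.
#' @export
segment_wm_fallback <- function(t1, k = 3L) {
  rng <- range(t1$voxels)
  if (rng[2] - rng[1] <= 0)
    stop("constant image: fewer than 3 separable intensity classes",
         call. = FALSE)
  v <- denoise_adaptive(t1)$voxels
  thr <- rng[1] + 0.15 * (rng[2] - rng[1])
  brain <- array(v > thr, dim(v))
  lab <- label3d6_cpp(brain)
  if (max(lab) == 0)
    stop("no brain component found above threshold", call. = FALSE)
  biggest <- which.max(tabulate(lab[lab > 0]))
  brain <- array(lab == biggest, dim(v))
  x <- v[brain]
  centers <- unique(as.numeric(stats::quantile(x, c(0.15, 0.5, 0.9))))
  if (length(centers) < k)
    stop("fewer than 3 separable intensity classes in the brain mask",
         call. = FALSE)
  km <- stats::kmeans(x, centers = matrix(centers, ncol = 1),
                      iter.max = 50)
  wm_class <- which.max(km$centers)
  out <- array(FALSE, dim(v))
  out[brain] <- km$cluster == wm_class
  # in-plane majority vote regularizes the class boundary
  nb <- inplane_neighbor_mean(array(as.numeric(out), dim(out)))
  votes <- nb$mean * nb$count + as.numeric(out)
  out <- array(votes / (nb$count + 1) >= 0.5, dim(out))
  binary_mask(out, t1)
}
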