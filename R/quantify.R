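# ---- local intensity-difference map ---------------------------------------

#' Neighbourhood specification for the local-contrast map
#'
#' @param type `"inplane"` (default; neighbours within the same axial slice,
#'   appropriate when slices are much thicker than the in-plane voxel) or
#'   `"3d"` (full 26-neighbour style cube).
#' @param radius Chebyshev radius of the ring/cube (default 1: the 8- or
#'   26-neighbour shell plus interior, excluding the centre).
#' @param include_outside_mask logical; whether neighbours outside the WM
#'   mask (but inside the image) contribute to the local mean. They are
#'   included by default: PVS contrast is measured against whatever tissue
#'   actually surrounds the voxel.
#' @return a list of class `pvs_neighborhood`.
#' @export
neighborhood_spec <- function(type = c("inplane", "3d"), radius = 1L,
                              include_outside_mask = TRUE) {
  type <- match.arg(type)
  radius <- as.integer(radius)
  if (radius < 1L) stop("neighbourhood radius must be >= 1", call. = FALSE)
  structure(list(type = type, radius = radius,
                 include_outside_mask = include_outside_mask),
            class = "pvs_neighborhood")
}

neighborhood_offsets <- function(spec) {
  r <- spec$radius
  zs <- if (spec$type == "inplane") 0L else seq(-r, r)
  offs <- expand.grid(dx = seq(-r, r), dy = seq(-r, r), dz = zs)
  offs[!(offs$dx == 0 & offs$dy == 0 & offs$dz == 0), , drop = FALSE]
}

shift_numeric <- function(arr, dx, dy, dz, fill = 0) {
  d <- dim(arr)
  out <- array(fill, d)
  xs <- seq_len(d[1]) + dx; ys <- seq_len(d[2]) + dy; zs <- seq_len(d[3]) + dz
  okx <- xs >= 1 & xs <= d[1]; oky <- ys >= 1 & ys <= d[2]
  okz <- zs >= 1 & zs <= d[3]
  out[okx, oky, okz] <- arr[xs[okx], ys[oky], zs[okz], drop = FALSE]
  out
}

#' Local intensity-difference map inside the eroded white matter
#'
#' For each voxel inside the eroded WM mask, the value is the voxel's
#' intensity minus the mean intensity of its surrounding voxels (default:
#' the in-plane 3x3 ring of 8 neighbours). Neighbours outside the image are
#' excluded from the mean; neighbours outside the WM mask are included
#' unless the spec says otherwise. Values are exactly zero outside the mask.
#'
#' @param t2 the registered, uniformized T2 `pvs_volume`.
#' @param eroded_wm a `pvs_mask` congruent with `t2`.
#' @param spec a [neighborhood_spec()].
#' @return An object of class `pvs_diffmap`: list with `values` (array),
#'   `mask`, `neighborhood`.
#' @export
neighborhood_difference_map <- function(t2, eroded_wm,
                                        spec = neighborhood_spec()) {
  check_congruent(t2, eroded_wm)
  if (!any(eroded_wm$voxels))
    stop("empty white-matter mask", call. = FALSE)
  if (!all(is.finite(t2$voxels[eroded_wm$voxels])))
    stop("non-finite intensity inside the mask", call. = FALSE)
  offs <- neighborhood_offsets(spec)
  arr <- t2$voxels
  d <- dim(arr)
  valid_src <- if (spec$include_outside_mask) array(1, d)
               else array(as.numeric(eroded_wm$voxels), d)
  s <- array(0, d)
  cnt <- array(0, d)
  for (q in seq_len(nrow(offs))) {
    s <- s + shift_numeric(arr * valid_src, offs$dx[q], offs$dy[q], offs$dz[q])
    cnt <- cnt + shift_numeric(valid_src, offs$dx[q], offs$dy[q], offs$dz[q])
  }
  vals <- array(0, d)
  inm <- eroded_wm$voxels & cnt > 0
  vals[inm] <- arr[inm] - s[inm] / cnt[inm]
  structure(list(values = vals, mask = eroded_wm, neighborhood = spec,
                 spacing = t2$spacing, affine = t2$affine),
            class = "pvs_diffmap")
}

#' @export
print.pvs_diffmap <- function(x, ...) {
  cat(sprintf("<pvs_diffmap> %s neighbourhood (radius %d), %d in-mask voxels\n",
              x$neighborhood$type, x$neighborhood$radius, sum(x$mask$voxels)))
  invisible(x)
}

#' Threshold the difference map into a PVS voxel mask
#'
#' A voxel is a WM-PVS voxel iff its local intensity difference is strictly
#' higher than the threshold (default 60, on the uniformized scale where the
#' WM median is 1000). A value exactly at the threshold is not PVS.
#'
#' @param diff a `pvs_diffmap`.
#' @param threshold finite scalar (default 60).
#' @return a `pvs_mask` of PVS voxels, confined to the eroded WM mask.
#' @export
detect_pvs_voxels <- function(diff, threshold = 60) {
  stopifnot(inherits(diff, "pvs_diffmap"))
  if (!is.finite(threshold)) stop("threshold must be finite", call. = FALSE)
  binary_mask(diff$values > threshold & diff$mask$voxels, diff$mask)
}

# ---- per-slice clustering --------------------------------------------------

infer_slice_axis <- function(spacing) {
  mx <- max(spacing)
  hit <- which(abs(spacing - mx) < 1e-9)
  if (length(hit) != 1L)
    stop("ambiguous slice axis (no dominant spacing); pass `slice_axis`",
         call. = FALSE)
  hit
}

#' Label PVS voxel clusters independently per axial slice
#'
#' 8-connectivity within each slice (voxels in one cluster iff their edges
#' or corners touch); voxels at the same in-plane position on adjacent
#' slices always belong to different clusters. The slice axis is identified
#' as the axis with the dominant spacing (the thick-slice axis) unless
#' overridden.
#'
#' @param pvs a `pvs_mask` of detected PVS voxels.
#' @param slice_axis optional integer axis override (1-3).
#' @return An object of class `pvs_clusters`: list with `labels` (integer
#'   array, 0 = background, labels unique across slices), `counts`
#'   (clusters per slice), `slice_axis`, `spacing`.
#' @export
label_clusters_per_slice <- function(pvs, slice_axis = NULL) {
  stopifnot(inherits(pvs, "pvs_mask"))
  if (is.null(slice_axis)) slice_axis <- infer_slice_axis(pvs$spacing)
  slice_axis <- as.integer(slice_axis)
  stopifnot(slice_axis %in% 1:3)
  perm <- c(setdiff(1:3, slice_axis), slice_axis)
  m <- aperm(pvs$voxels, perm)
  lab <- label_slices8_cpp(m)
  nz <- dim(m)[3]
  counts <- integer(nz)
  for (k in seq_len(nz))
    counts[k] <- length(unique(lab[, , k][lab[, , k] > 0]))
  inv <- order(perm)
  structure(list(labels = aperm(lab, inv), counts = counts,
                 slice_axis = slice_axis, spacing = pvs$spacing),
            class = "pvs_clusters")
}

#' @export
print.pvs_clusters <- function(x, ...) {
  cat(sprintf("<pvs_clusters> %d slices, max per-slice count %d\n",
              length(x$counts), if (length(x$counts)) max(x$counts) else 0L))
  invisible(x)
}

# ---- grading ----------------------------------------------------------------

#' The 5-point WM-PVS grade scale
#'
#' Grade bins over the maximum per-slice cluster count: 0 -> grade 0,
#' 1-10 -> 1, 11-20 -> 2, 21-40 -> 3, above 40 -> 4.
#'
#' @return data.frame of bins (`grade`, `min_count`, `max_count`).
#' @export
grade_scale <- function() {
  data.frame(grade = 0:4,
             min_count = c(0, 1, 11, 21, 41),
             max_count = c(0, 10, 20, 40, Inf))
}

#' Grade from the maximum per-slice cluster count
#'
#' @param per_slice_counts non-negative integer vector (one entry per axial
#'   slice), or a single maximum count.
#' @return integer grade 0-4.
#' @export
grade_from_max_count <- function(per_slice_counts) {
  if (length(per_slice_counts) == 0)
    stop("empty per-slice count list", call. = FALSE)
  if (any(per_slice_counts < 0) || any(per_slice_counts != round(per_slice_counts)))
    stop("counts must be non-negative integers", call. = FALSE)
  m <- max(per_slice_counts)
  if (m == 0) 0L
  else if (m <= 10) 1L
  else if (m <= 20) 2L
  else if (m <= 40) 3L
  else 4L
}

# ---- enlargement criterion --------------------------------------------------

# Minor side (in voxel units) of the minimum-area rectangle enclosing a set
# of in-plane pixel centres, by rotating calipers over convex-hull edge
# directions; one full voxel is added to each side so a single pixel has
# extent 1, an n-pixel row extent n.
min_box_minor_side <- function(xy) {
  if (nrow(xy) == 1) return(1)
  xy <- unique(xy)
  if (nrow(xy) == 1) return(1)
  hull <- tryCatch(grDevices::chull(xy), error = function(e) NULL)
  dirs <- if (!is.null(hull) && length(hull) >= 2) {
    h <- xy[hull, , drop = FALSE]
    e <- rbind(h[-1, , drop = FALSE], h[1, , drop = FALSE]) - h
    e[sqrt(rowSums(e^2)) > 0, , drop = FALSE]
  } else {
    # collinear points: use the segment direction
    d <- xy[which.max(rowSums(sweep(xy, 2, xy[1, ])^2)), ] - xy[1, ]
    matrix(d, 1)
  }
  best <- Inf
  minor <- Inf
  for (q in seq_len(nrow(dirs))) {
    u <- dirs[q, ] / sqrt(sum(dirs[q, ]^2))
    v <- c(-u[2], u[1])
    pu <- xy %*% u
    pv <- xy %*% v
    side_u <- diff(range(pu)) + 1
    side_v <- diff(range(pv)) + 1
    area <- side_u * side_v
    if (area < best) {
      best <- area
      minor <- min(side_u, side_v)
    }
  }
  minor
}

#' Per-cluster perpendicular diameters
#'
#' For every in-plane cluster, the extent along the minor axis of its
#' minimum-area bounding rectangle, in mm (the diameter perpendicular to
#' the cluster's main axis).
#'
#' @param clusters a `pvs_clusters`.
#' @return numeric vector, one diameter per cluster (mm).
#' @export
cluster_minor_diameters <- function(clusters) {
  stopifnot(inherits(clusters, "pvs_clusters"))
  inplane <- setdiff(1:3, clusters$slice_axis)
  sp <- clusters$spacing[inplane]
  if (abs(sp[1] - sp[2]) > 1e-9)
    warning("anisotropic in-plane spacing; using the mean for diameters")
  spmm <- mean(sp)
  lab <- clusters$labels
  ids <- sort(unique(lab[lab > 0]))
  vapply(ids, function(id) {
    idx <- which(lab == id, arr.ind = TRUE)
    xy <- idx[, inplane, drop = FALSE]
    min_box_minor_side(xy) * spmm
  }, numeric(1))
}

#' PVS enlargement criterion
#'
#' PVS are called enlarged when at least `min_count` clusters anywhere in
#' the volume have a perpendicular diameter above `min_diameter_mm`
#' (defaults: 3 clusters above 3 mm).
#'
#' @param clusters a `pvs_clusters`.
#' @param min_diameter_mm diameter cut in mm (strict `>`).
#' @param min_count minimum number of qualifying clusters.
#' @return logical flag.
#' @export
enlargement_flag <- function(clusters, min_diameter_mm = 3, min_count = 3L) {
  d <- cluster_minor_diameters(clusters)
  sum(d > min_diameter_mm) >= min_count
}

# ---- subject summary --------------------------------------------------------

#' Assemble the per-subject PVS quantification
#'
#' Both the raw PVS voxel count and the WM-normalized ratio are reported
#' (volumes are voxel counts throughout: slices are thicker than the PVS,
#' so mm^3 volumetry is not meaningful).
#'
#' @param pvs a `pvs_mask` of detected PVS voxels.
#' @param eroded_wm the congruent eroded WM `pvs_mask`.
#' @param threshold the detection threshold used (recorded in the result).
#' @param slice_axis optional slice-axis override passed to clustering.
#' @return An object of class `pvs_result`: `pvs_voxel_count`,
#'   `wm_voxel_count`, `normalized_volume`, `per_slice_cluster_counts`,
#'   `max_slice_count`, `grade`, `enlargement` flag, `threshold_used`.
#' @export
summarize_pvs <- function(pvs, eroded_wm, threshold = 60, slice_axis = NULL) {
  check_congruent(pvs, eroded_wm)
  wm_n <- sum(eroded_wm$voxels)
  if (wm_n == 0) stop("empty white-matter mask", call. = FALSE)
  cl <- label_clusters_per_slice(pvs, slice_axis = slice_axis)
  pvs_n <- sum(pvs$voxels)
  counts <- cl$counts
  structure(list(pvs_voxel_count = pvs_n,
                 wm_voxel_count = wm_n,
                 normalized_volume = pvs_n / wm_n,
                 per_slice_cluster_counts = counts,
                 max_slice_count = if (length(counts)) max(counts) else 0L,
                 grade = grade_from_max_count(if (length(counts)) counts else 0L),
                 enlargement = enlargement_flag(cl),
                 threshold_used = threshold,
                 clusters = cl),
            class = "pvs_result")
}

#' @export
print.pvs_result <- function(x, ...) {
  cat(sprintf(paste0("<pvs_result> %d PVS voxels / %d WM voxels ",
                     "(normalized %.5f)\n  max slice count %d, grade %d, ",
                     "enlargement %s\n"),
              x$pvs_voxel_count, x$wm_voxel_count, x$normalized_volume,
              x$max_slice_count, x$grade, x$enlargement))
  invisible(x)
}
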