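#' @useDynLib wmpvs, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

#' Construct a 3D image volume
#'
#' A lightweight container for a 3D intensity grid with physical geometry:
#' voxel spacing in mm, a 4x4 voxel-to-world affine (0-based voxel indices),
#' and a modality tag.
#'
#' @param voxels 3D numeric array of finite intensities.
#' @param spacing numeric length-3, mm per axis; strictly positive.
#' @param affine optional 4x4 voxel-to-world matrix; defaults to a diagonal
#'   affine built from `spacing` with the origin at the grid centre.
#' @param modality one of `"T1"`, `"T2"`, `"derived"`.
#' @return An object of class `pvs_volume`.
#' @export
image_volume <- function(voxels, spacing, affine = NULL,
                         modality = c("derived", "T1", "T2")) {
  modality <- match.arg(modality)
  if (!is.array(voxels) || length(dim(voxels)) != 3L)
    stop("`voxels` must be a 3D array", call. = FALSE)
  if (length(voxels) == 0L) stop("empty voxel grid", call. = FALSE)
  if (!all(is.finite(voxels))) stop("non-finite voxel intensities", call. = FALSE)
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(spacing <= 0))
    stop("`spacing` must be 3 strictly positive mm values", call. = FALSE)
  if (is.null(affine)) {
    affine <- diag(c(spacing, 1))
    # centre the grid on the world origin
    affine[1:3, 4] <- -spacing * (dim(voxels) - 1) / 2
  }
  stopifnot(is.matrix(affine), all(dim(affine) == c(4L, 4L)))
  structure(list(voxels = voxels, spacing = spacing, affine = affine,
                 modality = modality),
            class = "pvs_volume")
}

#' @export
print.pvs_volume <- function(x, ...) {
  cat(sprintf("<pvs_volume %s> %s voxels, spacing %s mm\n", x$modality,
              paste(dim(x$voxels), collapse = "x"),
              paste(format(x$spacing), collapse = " x ")))
  invisible(x)
}

#' Construct a binary mask congruent with a parent volume
#'
#' @param voxels logical 3D array (numeric input is coerced with `!= 0`).
#' @param reference a `pvs_volume` (or another `pvs_mask`) supplying geometry.
#' @return An object of class `pvs_mask`.
#' @export
binary_mask <- function(voxels, reference) {
  if (!is.array(voxels) || length(dim(voxels)) != 3L)
    stop("`voxels` must be a 3D array", call. = FALSE)
  v <- array(as.logical(voxels != 0), dim(voxels))
  if (!all(dim(v) == dim(reference$voxels)))
    stop("mask dimensions do not match reference geometry", call. = FALSE)
  structure(list(voxels = v, spacing = reference$spacing,
                 affine = reference$affine),
            class = "pvs_mask")
}

#' @export
print.pvs_mask <- function(x, ...) {
  cat(sprintf("<pvs_mask> %s voxels, %d foreground\n",
              paste(dim(x$voxels), collapse = "x"), sum(x$voxels)))
  invisible(x)
}

#' Check geometric congruence of two grids
#'
#' Dimensions, spacing and pose must agree; operations never silently
#' resample.
#'
#' @param a,b `pvs_volume` or `pvs_mask` objects.
#' @param tol numeric tolerance on spacing/affine entries.
#' @return `TRUE` invisibly, or an error.
#' @export
check_congruent <- function(a, b, tol = 1e-6) {
  if (!all(dim(a$voxels) == dim(b$voxels)))
    stop("grids are not congruent: dimensions differ", call. = FALSE)
  if (max(abs(a$spacing - b$spacing)) > tol)
    stop("grids are not congruent: spacing differs", call. = FALSE)
  if (max(abs(a$affine - b$affine)) > tol)
    stop("grids are not congruent: pose differs", call. = FALSE)
  invisible(TRUE)
}

#' Rigid (6-DOF) spatial transform
#'
#' Rotation angles are applied as Rz %*% Ry %*% Rx about `center` (world mm),
#' followed by translation.
#'
#' @param rotation numeric length-3, radians about x, y, z.
#' @param translation numeric length-3, mm.
#' @param center numeric length-3, world-space rotation centre in mm.
#' @return An object of class `pvs_rigid`.
#' @export
rigid_transform <- function(rotation = c(0, 0, 0), translation = c(0, 0, 0),
                            center = c(0, 0, 0)) {
  stopifnot(length(rotation) == 3L, length(translation) == 3L,
            length(center) == 3L,
            all(is.finite(c(rotation, translation, center))))
  structure(list(rotation = as.numeric(rotation),
                 translation = as.numeric(translation),
                 center = as.numeric(center)),
            class = "pvs_rigid")
}

#' @export
print.pvs_rigid <- function(x, ...) {
  cat(sprintf("<pvs_rigid> rot (rad): %s; trans (mm): %s\n",
              paste(signif(x$rotation, 4), collapse = ", "),
              paste(signif(x$translation, 4), collapse = ", ")))
  invisible(x)
}

rotation_matrix3 <- function(rotation) {
  cx <- cos(rotation[1]); sx <- sin(rotation[1])
  cy <- cos(rotation[2]); sy <- sin(rotation[2])
  cz <- cos(rotation[3]); sz <- sin(rotation[3])
  Rx <- matrix(c(1, 0, 0, 0, cx, sx, 0, -sx, cx), 3, 3)
  Ry <- matrix(c(cy, 0, -sy, 0, 1, 0, sy, 0, cy), 3, 3)
  Rz <- matrix(c(cz, sz, 0, -sz, cz, 0, 0, 0, 1), 3, 3)
  Rz %*% Ry %*% Rx
}

#' 4x4 homogeneous matrix of a rigid transform
#' @param x a `pvs_rigid`.
#' @return 4x4 matrix mapping world mm to world mm.
#' @export
transform_matrix <- function(x) {
  R <- rotation_matrix3(x$rotation)
  M <- diag(4)
  M[1:3, 1:3] <- R
  M[1:3, 4] <- x$center - R %*% x$center + x$translation
  M
}

#' Invert a rigid transform
#' @param x a `pvs_rigid`.
#' @return the inverse as a 4x4 matrix.
#' @export
transform_inverse_matrix <- function(x) solve(transform_matrix(x))

#' Apply a rigid transform to world-space points
#' @param x a `pvs_rigid`.
#' @param pts n x 3 matrix of mm coordinates.
#' @return n x 3 matrix of transformed coordinates.
#' @export
apply_transform <- function(x, pts) {
  pts <- rbind(t(pts), 1)
  t((transform_matrix(x) %*% pts)[1:3, , drop = FALSE])
}

#' World coordinates of every voxel centre
#' @param vol a `pvs_volume` or `pvs_mask`.
#' @return n x 3 matrix (column-major voxel order) of mm coordinates.
#' @export
voxel_centers <- function(vol) {
  d <- dim(vol$voxels)
  idx <- cbind(rep(seq_len(d[1]) - 1, times = d[2] * d[3]),
               rep(rep(seq_len(d[2]) - 1, each = d[1]), times = d[3]),
               rep(seq_len(d[3]) - 1, each = d[1] * d[2]))
  t(vol$affine[1:3, 1:3] %*% t(idx) + vol$affine[1:3, 4])
}

# Evaluate a block of code with a locally fixed RNG state, restoring the
# caller's stream afterwards.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Half-up decimal rounding
#'
#' Display rounding used for all printed percentages (R's `round()` is
#' round-half-even, which prints 56.25 as 56.2; reports here round half up).
#'
#' @param x numeric.
#' @param digits decimal places.
#' @return rounded numeric.
#' @export
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  floor(x * p + 0.5) / p
}

#' Read a NIfTI volume
#' @param path file path (`.nii` or `.nii.gz`).
#' @param modality modality tag to attach.
#' @return a `pvs_volume`.
#' @export
read_volume <- function(path, modality = "derived") {
  img <- RNifti::readNifti(path)
  aff <- unclass(RNifti::xform(img))
  attr(aff, "imagedim") <- NULL
  attr(aff, "code") <- NULL
  spacing <- sqrt(colSums(aff[1:3, 1:3]^2))
  arr <- as.array(img)
  image_volume(array(as.numeric(arr), dim(arr)), spacing = spacing,
               affine = aff, modality = modality)
}

#' Write a NIfTI volume
#' @param vol a `pvs_volume` or `pvs_mask`.
#' @param path output path.
#' @return `path` invisibly.
#' @export
write_volume <- function(vol, path) {
  arr <- vol$voxels
  if (is.logical(arr)) arr <- array(as.integer(arr), dim(arr))
  img <- RNifti::asNifti(arr)
  RNifti::sform(img) <- structure(vol$affine, code = 2L)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a NIfTI mask
#' @param path file path.
#' @param reference optional `pvs_volume` whose geometry the mask must match.
#' @return a `pvs_mask`.
#' @export
read_mask <- function(path, reference = NULL) {
  vol <- read_volume(path)
  if (is.null(reference)) reference <- vol
  else check_congruent(vol, reference)
  binary_mask(vol$voxels != 0, reference)
}
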