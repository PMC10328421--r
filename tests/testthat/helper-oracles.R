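# Independent brute-force oracles used to validate the package's
# implementations. These deliberately use different algorithms (nested
# loops, queue-based flood fill, direct enumeration) from the code they
# check.

# Per-voxel nested-loop local difference map: value = I(v) - mean of
# neighbours within the spec, neighbours outside the image excluded,
# neighbours outside the mask included unless include_outside_mask = FALSE.
oracle_diff_map <- function(arr, mask, radius = 1L, inplane = TRUE,
                            include_outside_mask = TRUE) {
  d <- dim(arr)
  out <- array(0, d)
  zr <- if (inplane) 0L else seq(-radius, radius)
  for (k in seq_len(d[3])) for (j in seq_len(d[2])) for (i in seq_len(d[1])) {
    if (!mask[i, j, k]) next
    vals <- c()
    for (dz in zr) for (dy in seq(-radius, radius)) for (dx in seq(-radius, radius)) {
      if (dx == 0 && dy == 0 && dz == 0) next
      ii <- i + dx; jj <- j + dy; kk <- k + dz
      if (ii < 1 || ii > d[1] || jj < 1 || jj > d[2] || kk < 1 || kk > d[3]) next
      if (!include_outside_mask && !mask[ii, jj, kk]) next
      vals <- c(vals, arr[ii, jj, kk])
    }
    if (length(vals)) out[i, j, k] <- arr[i, j, k] - mean(vals)
  }
  out
}

# Queue-based 8-connected flood fill per slice; returns per-slice cluster
# counts and a label array (labels unique per volume).
oracle_label_slices <- function(mask) {
  d <- dim(mask)
  lab <- array(0L, d)
  nxt <- 0L
  counts <- integer(d[3])
  for (k in seq_len(d[3])) {
    for (j0 in seq_len(d[2])) for (i0 in seq_len(d[1])) {
      if (!mask[i0, j0, k] || lab[i0, j0, k] != 0L) next
      nxt <- nxt + 1L
      counts[k] <- counts[k] + 1L
      queue <- list(c(i0, j0))
      lab[i0, j0, k] <- nxt
      while (length(queue)) {
        p <- queue[[1]]; queue <- queue[-1]
        for (dy in -1:1) for (dx in -1:1) {
          if (dx == 0 && dy == 0) next
          ii <- p[1] + dx; jj <- p[2] + dy
          if (ii < 1 || ii > d[1] || jj < 1 || jj > d[2]) next
          if (mask[ii, jj, k] && lab[ii, jj, k] == 0L) {
            lab[ii, jj, k] <- nxt
            queue[[length(queue) + 1L]] <- c(ii, jj)
          }
        }
      }
    }
  }
  list(labels = lab, counts = counts)
}

# Brute-force binary erosion with an explicit offset list; out-of-image
# neighbours count as background.
oracle_erode <- function(mask, offsets) {
  d <- dim(mask)
  out <- array(FALSE, d)
  for (k in seq_len(d[3])) for (j in seq_len(d[2])) for (i in seq_len(d[1])) {
    if (!mask[i, j, k]) next
    keep <- TRUE
    for (off in offsets) {
      ii <- i + off[1]; jj <- j + off[2]; kk <- k + off[3]
      if (ii < 1 || ii > d[1] || jj < 1 || jj > d[2] || kk < 1 || kk > d[3] ||
          !mask[ii, jj, kk]) { keep <- FALSE; break }
    }
    out[i, j, k] <- keep
  }
  out
}

offsets_6 <- list(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
                  c(0, 0, 1), c(0, 0, -1))
offsets_4 <- offsets_6[1:4]

# Fisher exact p for a 2x2 table by direct hypergeometric enumeration over
# all tables with the observed margins (two-sided: sum of probabilities
# <= that of the observed table).
oracle_fisher_2x2 <- function(a, b, c, d) {
  r1 <- a + b; r2 <- c + d; c1 <- a + c
  lo <- max(0L, c1 - r2); hi <- min(r1, c1)
  logp <- function(x) {
    lchoose(r1, x) + lchoose(r2, c1 - x) - lchoose(r1 + r2, c1)
  }
  probs <- vapply(lo:hi, function(x) exp(logp(x)), numeric(1))
  p_obs <- exp(logp(a))
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Spearman rho by the direct sum-of-squared-rank-differences formula
# (valid without ties).
oracle_spearman_rho <- function(x, y) {
  n <- length(x)
  d <- rank(x) - rank(y)
  1 - 6 * sum(d^2) / (n * (n^2 - 1))
}

# Count of slice slabs a z-aligned segment [z0, z1] overlaps by at least
# half a slab (the analytic counterpart of the half-volume ground truth
# for through-plane tubes).
oracle_slab_overlap_counts <- function(z0, z1, z_lo, dz, nz) {
  counts <- integer(nz)
  for (k in seq_len(nz)) {
    a <- z_lo + (k - 1) * dz
    b <- a + dz
    ov <- min(max(z0, z1), b) - max(min(z0, z1), a)
    if (ov >= dz / 2 - 1e-9) counts[k] <- 1L
  }
  counts
}
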