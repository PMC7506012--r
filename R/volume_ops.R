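# Vectorised low-level array operations shared by the registration,
# segmentation and scoring code. Everything here works on plain 3-D arrays;
# ct_volume wrappers live next to their callers.

## Trilinear interpolation of `arr` at continuous 1-based voxel coordinates
## `idx` (n x 3). Coordinates outside the grid return `outside`.
interp_trilinear <- function(arr, idx, outside = NA_real_) {
  d <- dim(arr)
  x <- idx[, 1]; y <- idx[, 2]; z <- idx[, 3]
  inside <- x >= 1 & x <= d[1] & y >= 1 & y <= d[2] & z >= 1 & z <= d[3] &
    is.finite(x) & is.finite(y) & is.finite(z)
  out <- rep(outside, length(x))
  if (!any(inside)) return(out)
  x <- x[inside]; y <- y[inside]; z <- z[inside]
  x0 <- pmin(floor(x), d[1] - 1); x0 <- pmax(x0, 1)
  y0 <- pmin(floor(y), d[2] - 1); y0 <- pmax(y0, 1)
  z0 <- pmin(floor(z), d[3] - 1); z0 <- pmax(z0, 1)
  fx <- x - x0; fy <- y - y0; fz <- z - z0
  n12 <- d[1] * d[2]
  base <- x0 + (y0 - 1) * d[1] + (z0 - 1) * n12
  v000 <- arr[base]
  v100 <- arr[base + 1]
  v010 <- arr[base + d[1]]
  v110 <- arr[base + d[1] + 1]
  v001 <- arr[base + n12]
  v101 <- arr[base + n12 + 1]
  v011 <- arr[base + n12 + d[1]]
  v111 <- arr[base + n12 + d[1] + 1]
  c00 <- v000 * (1 - fx) + v100 * fx
  c10 <- v010 * (1 - fx) + v110 * fx
  c01 <- v001 * (1 - fx) + v101 * fx
  c11 <- v011 * (1 - fx) + v111 * fx
  c0 <- c00 * (1 - fy) + c10 * fy
  c1 <- c01 * (1 - fy) + c11 * fy
  out[inside] <- c0 * (1 - fz) + c1 * fz
  out
}

## Integer shift of a 3-D array with constant fill.
shift_array <- function(arr, by, fill = 0) {
  d <- dim(arr)
  out <- array(fill, d)
  src <- dst <- vector("list", 3)
  for (a in 1:3) {
    b <- by[a]
    if (abs(b) >= d[a]) return(out)
    if (b >= 0) {
      dst[[a]] <- (1 + b):d[a]; src[[a]] <- 1:(d[a] - b)
    } else {
      dst[[a]] <- 1:(d[a] + b); src[[a]] <- (1 - b):d[a]
    }
  }
  out[dst[[1]], dst[[2]], dst[[3]]] <- arr[src[[1]], src[[2]], src[[3]]]
  out
}

neighbour_offsets6 <- function() {
  list(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0), c(0, 0, 1), c(0, 0, -1))
}

dilate6 <- function(mask) {
  out <- mask
  for (off in neighbour_offsets6())
    out <- out | shift_array(mask, off, FALSE)
  out
}

erode6 <- function(mask) {
  out <- mask
  for (off in neighbour_offsets6())
    out <- out & shift_array(mask, off, FALSE)
  out
}

## Morphological erosion of a binary mask by a Euclidean ball of radius_mm,
## honouring anisotropic spacing. Exact for the offsets enumerated.
erode_ball <- function(mask, radius_mm, spacing) {
  if (radius_mm <= 0) return(mask)
  r <- ceiling(radius_mm / spacing)
  offs <- expand.grid(i = -r[1]:r[1], j = -r[2]:r[2], k = -r[3]:r[3])
  dd <- sqrt((offs$i * spacing[1])^2 + (offs$j * spacing[2])^2 +
               (offs$k * spacing[3])^2)
  offs <- offs[dd <= radius_mm & dd > 0, , drop = FALSE]
  out <- mask
  for (n in seq_len(nrow(offs))) {
    out <- out & shift_array(mask, as.numeric(offs[n, ]), FALSE)
    if (!any(out)) break
  }
  out
}

## Connected-component labelling by iterated minimum-label propagation.
## connectivity: 6 (3-D faces) or 4 (in-plane only; slices stay separate,
## as needed for per-slice calcium lesions).
label_components <- function(mask, connectivity = 6) {
  d <- dim(mask)
  lab <- array(0, d)
  lab[mask] <- which(mask)
  offs <- neighbour_offsets6()
  if (connectivity == 4) offs <- offs[1:4]
  repeat {
    prev <- lab
    for (off in offs) {
      sh <- shift_array(lab, off, 0)
      take <- mask & sh > 0 & sh < lab
      lab[take] <- sh[take]
    }
    if (identical(lab, prev)) break
  }
  ids <- sort(unique(lab[lab > 0]))
  relab <- array(0L, d)
  relab[lab > 0] <- match(lab[lab > 0], ids)
  relab
}

## City-block (6-connected) breadth-first distance, in steps, from
## `from_mask` to every voxel of `within_mask`. Voxels of `within_mask`
## never reached get NA.
bfs_distance <- function(from_mask, within_mask, max_steps = 512L) {
  dist <- array(NA_real_, dim(from_mask))
  reached <- from_mask
  step <- 0L
  while (any(within_mask & !reached) && step < max_steps) {
    step <- step + 1L
    frontier <- dilate6(reached) & !reached
    if (!any(frontier)) break
    hit <- frontier & within_mask
    dist[hit] <- step
    reached <- reached | frontier
  }
  dist
}

## Separable Gaussian smoothing with edge replication. sigma_vox may be a
## scalar or length-3 vector (in voxels); sigma 0 skips an axis.
smooth_gaussian <- function(arr, sigma_vox) {
  sigma_vox <- rep_len(sigma_vox, 3)
  for (axis in 1:3) {
    s <- sigma_vox[axis]
    if (s <= 0) next
    r <- max(1L, ceiling(3 * s))
    k <- exp(-((-r:r)^2) / (2 * s^2))
    k <- k / sum(k)
    arr <- conv_axis(arr, k, axis)
  }
  arr
}

conv_axis <- function(arr, kernel, axis) {
  d <- dim(arr)
  r <- (length(kernel) - 1L) / 2L
  perm <- c(axis, setdiff(1:3, axis))
  a <- aperm(arr, perm)
  dp <- dim(a)
  m <- matrix(a, dp[1], dp[2] * dp[3])
  m <- rbind(m[rep(1L, r), , drop = FALSE], m,
             m[rep(nrow(m), r), , drop = FALSE])
  f <- stats::filter(m, kernel, sides = 2)
  f <- f[(r + 1L):(r + dp[1]), , drop = FALSE]
  a <- array(as.numeric(f), dp)
  aperm(a, order(perm))
}

## Block-mean downsampling by integer factor (anti-aliased decimation for
## the multi-resolution registration pyramid). Trailing voxels that do not
## fill a block are dropped.
downsample_block <- function(arr, factor) {
  if (factor == 1) return(arr)
  d <- dim(arr)
  nd <- d %/% factor
  arr <- arr[1:(nd[1] * factor), 1:(nd[2] * factor), 1:(nd[3] * factor)]
  dim(arr) <- c(factor, nd[1], factor, nd[2], factor, nd[3])
  m <- colMeans(arr, dims = 1)                      # (n1, f, n2, f, n3)
  m <- colMeans(aperm(m, c(2, 1, 3, 4, 5)), dims = 1)  # (n1, n2, f, n3)
  m <- colMeans(aperm(m, c(3, 1, 2, 4)), dims = 1)     # (n1, n2, n3)
  m
}

## Monotone intensity normalisation of `moving` onto `fixed` by matching
## empirical quantiles (histogram matching). Used before mean-squared
## difference metrics when the two phases differ by regional enhancement.
match_quantiles <- function(moving, fixed, n_points = 256L) {
  p <- seq(0, 1, length.out = n_points)
  qm <- stats::quantile(moving, p, na.rm = TRUE, names = FALSE)
  qf <- stats::quantile(fixed, p, na.rm = TRUE, names = FALSE)
  keep <- !duplicated(qm)
  if (sum(keep) < 2) return(moving - mean(moving, na.rm = TRUE) +
                              mean(fixed, na.rm = TRUE))
  stats::approx(qm[keep], qf[keep], xout = moving, rule = 2)$y
}

## Run `expr` under a temporary RNG state seeded with `seed`, restoring the
## caller's state afterwards. All phantom generators go through this so
## identical seeds give bit-identical output without disturbing the session.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
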