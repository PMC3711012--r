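## Internal vectorized grid primitives shared across modules. Coordinates are
## 1-based R index space; anything read outside the grid is background 0.

.gridCoords <- function(d) {
  list(x = rep(seq_len(d[1]), times = d[2] * d[3]),
       y = rep(rep(seq_len(d[2]), each = d[1]), times = d[3]),
       z = rep(seq_len(d[3]), each = d[1] * d[2]))
}

## Trilinear interpolation of 3D array `a` at coordinates (cx, cy, cz);
## out-of-bounds corners contribute 0.
.trilinear <- function(a, cx, cy, cz) {
  d <- dim(a)
  x0 <- floor(cx); y0 <- floor(cy); z0 <- floor(cz)
  fx <- cx - x0; fy <- cy - y0; fz <- cz - z0
  out <- numeric(length(cx))
  nxy <- d[1] * d[2]
  for (dx in 0:1) {
    wx <- if (dx == 1) fx else 1 - fx
    xi <- x0 + dx
    okx <- xi >= 1 & xi <= d[1]
    for (dy in 0:1) {
      wy <- if (dy == 1) fy else 1 - fy
      yi <- y0 + dy
      okxy <- okx & yi >= 1 & yi <= d[2]
      for (dz in 0:1) {
        zi <- z0 + dz
        w <- wx * wy * (if (dz == 1) fz else 1 - fz)
        ok <- okxy & zi >= 1 & zi <= d[3] & w != 0
        if (any(ok)) {
          idx <- (zi[ok] - 1) * nxy + (yi[ok] - 1) * d[1] + xi[ok]
          out[ok] <- out[ok] + w[ok] * a[idx]
        }
      }
    }
  }
  out
}

## Central difference along `axis`, one-sided at the two boundary slabs.
.centralDiff <- function(a, axis) {
  d <- dim(a)
  n <- d[axis]
  g <- array(0, d)
  ix <- function(lo, hi, ax) {
    idx <- list(quote(expr = ), quote(expr = ), quote(expr = ))
    idx[[ax]] <- lo:hi
    idx
  }
  sub <- function(lo, hi) do.call(`[`, c(list(a), ix(lo, hi, axis), drop = FALSE))
  asg <- function(lo, hi, val) {
    idx <- ix(lo, hi, axis)
    do.call(`[<-`, c(list(g), idx, list(val)))
  }
  g <- asg(2, n - 1, (sub(3, n) - sub(1, n - 2)) / 2)
  g <- asg(1, 1, sub(2, 2) - sub(1, 1))
  g <- asg(n, n, sub(n, n) - sub(n - 1, n - 1))
  g
}

## Shift array content by `by` voxels along `axis`, filling with zeros
## (consistent with the clamped-zero boundary condition of the solvers).
.shiftZero <- function(a, axis, by) {
  if (by == 0) return(a)
  d <- dim(a)
  n <- d[axis]
  out <- array(0, d)
  if (abs(by) >= n) return(out)
  idx <- function(lo, hi, ax) {
    ii <- list(quote(expr = ), quote(expr = ), quote(expr = ))
    ii[[ax]] <- lo:hi
    ii
  }
  if (by > 0) {
    src <- do.call(`[`, c(list(a), idx(1 + by, n, axis), drop = FALSE))
    out <- do.call(`[<-`, c(list(out), idx(1, n - by, axis), list(src)))
  } else {
    src <- do.call(`[`, c(list(a), idx(1, n + by, axis), drop = FALSE))
    out <- do.call(`[<-`, c(list(out), idx(1 - by, n, axis), list(src)))
  }
  out
}

.gaussKernel1d <- function(sigma) {
  r <- max(1L, as.integer(ceiling(4 * sigma)))
  x <- (-r):r
  k <- exp(-x^2 / (2 * sigma^2))
  k / sum(k)
}

## Zero-padded separable filtering along one axis via a band matrix product.
.filterAxis <- function(a, kern, axis) {
  d <- dim(a)
  n <- d[axis]
  r <- (length(kern) - 1L) %/% 2L
  M <- matrix(0, n, n)
  for (o in -r:r) {
    i <- seq_len(n)
    j <- i + o
    ok <- j >= 1 & j <= n
    M[cbind(i[ok], j[ok])] <- kern[o + r + 1L]
  }
  if (axis == 1L) {
    array(M %*% matrix(a, n, d[2] * d[3]), d)
  } else if (axis == 2L) {
    p <- aperm(a, c(2, 1, 3))
    out <- array(M %*% matrix(p, n, d[1] * d[3]), c(n, d[1], d[3]))
    aperm(out, c(2, 1, 3))
  } else {
    p <- aperm(a, c(3, 1, 2))
    out <- array(M %*% matrix(p, n, d[1] * d[2]), c(n, d[1], d[2]))
    aperm(out, c(2, 3, 1))
  }
}

## Separable Gaussian smoothing with per-axis sigma in voxels, zero-padded.
.gaussSmooth <- function(a, sigmaVox) {
  sigmaVox <- rep_len(sigmaVox, 3L)
  for (ax in 1:3) {
    if (sigmaVox[ax] > 0) a <- .filterAxis(a, .gaussKernel1d(sigmaVox[ax]), ax)
  }
  a
}

## Evaluate the RNG-dependent expression under a local seed, restoring the
## caller's RNG state afterwards.
.withSeed <- function(seed, expr) {
  hadSeed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (hadSeed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (hadSeed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(abs(seed) %% .Machine$integer.max))
  expr
}

.sameShape <- function(a, b) identical(dim(a)[1:3], dim(b)[1:3])

.stopShape <- function(a, b, what = "inputs") {
  if (!.sameShape(a, b))
    stop(sprintf("dimension mismatch: %s have shapes %s and %s", what,
                 paste(dim(a)[1:3], collapse = "x"),
                 paste(dim(b)[1:3], collapse = "x")), call. = FALSE)
  invisible(TRUE)
}

.vecNorm <- function(u) sqrt(u[, , , 1]^2 + u[, , , 2]^2 + u[, , , 3]^2)

.ssd <- function(a, b) sum((a - b)^2)
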