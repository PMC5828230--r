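# Independent brute-force oracles used to validate the compiled kernels.
# These deliberately follow the literal textbook definitions (fixed-point
# iteration, exhaustive priority flooding) rather than the package's
# algorithms.

# Wrap a vector as an nx x 1 x 1 array (1D profiles as degenerate volumes).
arr1d <- function(v) array(as.double(v), c(length(v), 1L, 1L))

# unit 6-connected dilation by explicit shifting, -Inf padding
naive_dilate6 <- function(a) {
  dm <- dim(a)
  out <- a
  shift <- function(a, axis, by) {
    idx <- seq_len(dm[axis]) - by
    pad <- idx < 1L | idx > dm[axis]
    idx[pad] <- 1L
    s <- switch(axis,
                a[idx, , , drop = FALSE],
                a[, idx, , drop = FALSE],
                a[, , idx, drop = FALSE])
    if (any(pad)) {
      if (axis == 1L) s[pad, , ] <- -Inf
      else if (axis == 2L) s[, pad, ] <- -Inf
      else s[, , pad] <- -Inf
    }
    s
  }
  for (axis in 1:3)
    for (by in c(-1L, 1L))
      out <- pmax(out, shift(a, axis, by))
  out
}

# literal fixed-point iteration of geodesic dilation under the mask
naive_reconstruct <- function(marker, mask) {
  cur <- marker
  repeat {
    nxt <- pmin(naive_dilate6(cur), mask)
    if (identical(nxt, cur)) return(cur)
    cur <- nxt
  }
}

# Exhaustive marker-controlled priority flood with dams. Mirrors the rule
# set: frontier seeded in linear-index order, pops ordered by (altitude,
# insertion order), neighbours examined/pushed in ascending linear-offset
# order (-z, -y, -x, +x, +y, +z); a popped voxel seeing two catchments (or
# only dams) becomes a dam.
naive_watershed <- function(grad, obj, bg) {
  dm <- dim(grad)
  n <- prod(dm)
  nx <- dm[1]; ny <- dm[2]; nz <- dm[3]
  lab <- integer(n)
  lab[as.vector(obj)] <- 1L
  lab[as.vector(bg)] <- 2L
  g <- as.vector(grad)
  neighbours <- function(i0) {           # i0 is 0-based
    x <- i0 %% nx; r <- i0 %/% nx; y <- r %% ny; z <- r %/% ny
    res <- integer(0)
    if (z > 0)      res <- c(res, i0 - nx * ny)
    if (y > 0)      res <- c(res, i0 - nx)
    if (x > 0)      res <- c(res, i0 - 1L)
    if (x < nx - 1) res <- c(res, i0 + 1L)
    if (y < ny - 1) res <- c(res, i0 + nx)
    if (z < nz - 1) res <- c(res, i0 + nx * ny)
    res
  }
  qp <- numeric(0); qo <- numeric(0); qi <- integer(0)
  cnt <- 0
  push <- function(i0) {
    qp <<- c(qp, g[i0 + 1L]); qo <<- c(qo, cnt); qi <<- c(qi, i0)
    cnt <<- cnt + 1
  }
  for (i0 in 0:(n - 1)) {
    if (lab[i0 + 1L] != 0L) next
    nb <- neighbours(i0)
    if (any(lab[nb + 1L] > 0L)) push(i0)
  }
  while (length(qi) > 0) {
    j <- order(qp, qo)[1]
    p0 <- qi[j]
    qp <- qp[-j]; qo <- qo[-j]; qi <- qi[-j]
    if (lab[p0 + 1L] != 0L) next
    nb <- neighbours(p0)
    ls <- unique(lab[nb + 1L])
    ls <- ls[ls > 0L]
    lab[p0 + 1L] <- if (length(ls) == 1L) ls else -1L
    for (q0 in nb) if (lab[q0 + 1L] == 0L) push(q0)
  }
  lab[lab == -1L] <- 0L
  array(lab, dm)
}

# random binary mask with occupancy p
rand_mask <- function(dm, p) array(runif(prod(dm)) < p, dm)

# two random disjoint nonempty markers on a grid
rand_marker_pair <- function(dm) {
  n <- prod(dm)
  repeat {
    obj <- rand_mask(dm, 0.08)
    bg <- rand_mask(dm, 0.15) & !obj
    if (any(obj) && any(bg)) return(list(object = obj, background = bg))
  }
}

# compact phantom used by the faster end-to-end tests
small_phantom_spec <- function(...) {
  phantom_spec(shape = c(96L, 96L, 64L), spacing = c(4, 4, 3.5), ...)
}
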