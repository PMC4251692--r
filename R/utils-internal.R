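## Internal numerical helpers shared across modules.

.clip01 <- function(x) pmin(pmax(x, 0), 1)

## Evaluate expr under a fixed RNG seed, restoring the caller's RNG state.
.withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed %% .Machine$integer.max))
  eval.parent(substitute(expr))
}

## Half-up decimal rounding (the convention of most printed clinical
## tables); base round() is half-to-even. A tiny epsilon shields values
## that are exact halves in decimal but sit just below in binary.
.roundHalfUp <- function(x, digits = 0) {
  s <- 10^digits
  sign(x) * floor(abs(x) * s + 0.5 + 1e-9) / s
}

## 'reflect' boundary index (mirror about the edge pixel, period 2n - 2):
## positions ..., 3, 2, [1, ..., n], n-1, n-2, ...
.reflectIdx <- function(i, n) {
  if (n == 1) return(rep(1L, length(i)))
  j <- (i - 1L) %% (2L * (n - 1L))
  ifelse(j < n, j + 1L, 2L * n - 1L - j)
}

.padReflect <- function(m, k) {
  if (k <= 0) return(m)
  m[.reflectIdx(seq.int(1L - k, nrow(m) + k), nrow(m)),
    .reflectIdx(seq.int(1L - k, ncol(m) + k), ncol(m)), drop = FALSE]
}

## Truncated, renormalized 1-D Gaussian taps at integer offsets.
.gaussTaps <- function(sigmaPx, radius = max(1L, ceiling(4 * sigmaPx))) {
  x <- seq.int(-radius, radius)
  g <- exp(-x^2 / (2 * sigmaPx^2))
  g / sum(g)
}

.gaussKernel <- function(sigmaPx) {
  if (sigmaPx <= 0) return(matrix(1, 1, 1))
  g <- .gaussTaps(sigmaPx)
  outer(g, g)
}

## 2-D convolution with reflect padding: pad by the kernel radius so the
## result is independent of filter2's own boundary rule, then crop.
.convolveReflect <- function(m, kernel) {
  kr <- (nrow(kernel) - 1L) %/% 2L
  kc <- (ncol(kernel) - 1L) %/% 2L
  k <- max(kr, kc)
  if (k == 0) return(m * kernel[1, 1])
  p <- EBImage::filter2(.padReflect(m, k), kernel, boundary = 0)
  p[(k + 1):(k + nrow(m)), (k + 1):(k + ncol(m)), drop = FALSE]
}

.gaussBlurReflect <- function(m, sigmaPx) {
  if (sigmaPx <= 0) return(m)
  .convolveReflect(m, .gaussKernel(sigmaPx))
}

## Minimum distance (mm) from every pixel centre to a polyline, computed
## per segment inside an inflated bounding box; Inf beyond maxDist.
.distFieldToPolyline <- function(nr, nc, pitch, pts, maxDist) {
  D <- matrix(Inf, nr, nc)
  xs <- (seq_len(nc) - 0.5) * pitch
  ys <- (seq_len(nr) - 0.5) * pitch
  for (i in seq_len(nrow(pts) - 1L)) {
    p <- pts[i, ]; q <- pts[i + 1L, ]
    ci <- which(xs >= min(p[1], q[1]) - maxDist & xs <= max(p[1], q[1]) + maxDist)
    ri <- which(ys >= min(p[2], q[2]) - maxDist & ys <= max(p[2], q[2]) + maxDist)
    if (!length(ci) || !length(ri)) next
    X <- matrix(xs[ci], length(ri), length(ci), byrow = TRUE)
    Y <- matrix(ys[ri], length(ri), length(ci))
    vx <- q[1] - p[1]; vy <- q[2] - p[2]
    t <- .clip01(((X - p[1]) * vx + (Y - p[2]) * vy) / (vx^2 + vy^2))
    d <- sqrt((X - (p[1] + t * vx))^2 + (Y - (p[2] + t * vy))^2)
    D[ri, ci] <- pmin(D[ri, ci], d)
  }
  D
}

## 8-connected component labelling (EBImage::bwlabel is 4-connected).
.label8 <- function(mask) {
  lab <- matrix(0L, nrow(mask), ncol(mask))
  idx <- which(mask)
  if (!length(idx)) return(lab)
  nr <- nrow(mask); nc <- ncol(mask)
  vid <- matrix(0L, nr, nc)
  vid[idx] <- seq_along(idx)
  rc <- arrayInd(idx, dim(mask))
  from <- integer(0); to <- integer(0)
  for (off in list(c(0L, 1L), c(1L, 1L), c(1L, 0L), c(1L, -1L))) {
    r2 <- rc[, 1] + off[1]; c2 <- rc[, 2] + off[2]
    ok <- r2 >= 1L & r2 <= nr & c2 >= 1L & c2 <= nc
    nb <- integer(length(idx))
    nb[ok] <- vid[cbind(r2[ok], c2[ok])]
    has <- nb > 0L
    from <- c(from, which(has)); to <- c(to, nb[has])
  }
  g <- igraph::make_graph(rbind(from, to), n = length(idx), directed = FALSE)
  lab[idx] <- as.integer(igraph::components(g)$membership)
  lab
}

.fail <- function(...) stop(sprintf(...), call. = FALSE)
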