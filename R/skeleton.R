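## Morphological skeletonization (Zhang-Suen thinning) and centerline
## tracing. No installed package provides 2-D binary thinning, so it is
## implemented here, vectorized over whole-image shifts.

## Shift a matrix by (dr, dc), filling with 0.
.shift0 <- function(m, dr, dc) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(0L, nr, nc)
  rs <- seq_len(nr) - dr; cs <- seq_len(nc) - dc
  okr <- rs >= 1 & rs <= nr; okc <- cs >= 1 & cs <= nc
  out[okr, okc] <- m[rs[okr], cs[okc]]
  out
}

#' Skeletonize a binary mask
#'
#' Zhang-Suen iterative thinning: alternately deletes border pixels in two
#' sub-iterations until the mask stops changing, leaving an 8-connected,
#' one-pixel-wide skeleton that preserves the topology of each component.
#'
#' @param mask logical matrix.
#' @return Logical matrix of the same size, TRUE on skeleton pixels (a
#'   subset of the input mask).
#' @examples
#' m <- matrix(FALSE, 16, 32); m[6:10, 4:28] <- TRUE
#' sum(skeletonize(m)) < sum(m)
#' @export
skeletonize <- function(mask) {
  stopifnot(is.logical(mask))
  p <- matrix(as.integer(mask), nrow(mask), ncol(mask))
  repeat {
    changed <- FALSE
    for (phase in 1:2) {
      # neighbours P2..P9 clockwise from north
      p2 <- .shift0(p, -1, 0);  p3 <- .shift0(p, -1, 1)
      p4 <- .shift0(p, 0, 1);   p5 <- .shift0(p, 1, 1)
      p6 <- .shift0(p, 1, 0);   p7 <- .shift0(p, 1, -1)
      p8 <- .shift0(p, 0, -1);  p9 <- .shift0(p, -1, -1)
      B <- p2 + p3 + p4 + p5 + p6 + p7 + p8 + p9
      A <- (p2 == 0 & p3 == 1) + (p3 == 0 & p4 == 1) + (p4 == 0 & p5 == 1) +
           (p5 == 0 & p6 == 1) + (p6 == 0 & p7 == 1) + (p7 == 0 & p8 == 1) +
           (p8 == 0 & p9 == 1) + (p9 == 0 & p2 == 1)
      if (phase == 1) {
        cond <- p == 1 & B >= 2 & B <= 6 & A == 1 &
          p2 * p4 * p6 == 0 & p4 * p6 * p8 == 0
      } else {
        cond <- p == 1 & B >= 2 & B <= 6 & A == 1 &
          p2 * p4 * p8 == 0 & p2 * p6 * p8 == 0
      }
      if (any(cond)) {
        p[cond] <- 0L
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  p == 1L
}

## Order the skeleton pixels of one component into a polyline: start from
## an endpoint (a pixel with a single 8-neighbour) and greedily walk to
## the nearest unvisited skeleton pixel; side branches are appended where
## the walk picks them up. Adequate for arc-length accounting, which uses
## pixel counts, not the ordering.
.tracePolyline <- function(px) {
  n <- nrow(px)
  if (n <= 2) return(px)
  nbrCount <- vapply(seq_len(n), function(i) {
    sum(abs(px[, 1] - px[i, 1]) <= 1 & abs(px[, 2] - px[i, 2]) <= 1) - 1L
  }, integer(1))
  start <- if (any(nbrCount == 1L)) which(nbrCount == 1L)[1] else 1L
  visited <- logical(n)
  order <- integer(n)
  cur <- start
  for (k in seq_len(n)) {
    order[k] <- cur
    visited[cur] <- TRUE
    if (k == n) break
    rest <- which(!visited)
    d <- pmax(abs(px[rest, 1] - px[cur, 1]), abs(px[rest, 2] - px[cur, 2]))
    cur <- rest[which.min(d)]
  }
  px[order, , drop = FALSE]
}

## Skeleton centerlines per 8-connected component of a mask.
.maskCenterlines <- function(mask) {
  lab <- .label8(mask)
  nComp <- max(lab)
  if (nComp == 0) return(list())
  skel <- skeletonize(mask)
  out <- vector("list", nComp)
  for (i in seq_len(nComp)) {
    px <- which(skel & lab == i)
    if (!length(px)) {
      # thinning can erase a tiny blob entirely; keep a single anchor pixel
      px <- which(lab == i)[1]
    }
    out[[i]] <- .tracePolyline(arrayInd(px, dim(mask)))
  }
  out[order(vapply(out, nrow, integer(1)), decreasing = TRUE)]
}
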