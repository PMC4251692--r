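## Synthetic NIR forearm phantom: vein geometry, illumination, rendering.

#' Generate a random subcutaneous vein network
#'
#' Draws `nVeins` vein segments as smooth random polylines (a random walk
#' with bounded curvature) that stay inside the phantom's field of view.
#' Depths are uniform on `depthRange` and radii uniform on `radiusRange`.
#' Fully deterministic given `rngSeed`.
#'
#' @param spec a [PhantomSpec-class]; provides the field of view.
#' @param nVeins number of veins (>= 0).
#' @param rngSeed integer seed; defaults to the spec's seed.
#' @param depthRange (min, max) vein depth in mm, default c(0.5, 4).
#' @param radiusRange (min, max) vein radius in mm, default c(0.8, 2).
#' @return A list of [VeinSegment-class] of length `nVeins`.
#' @examples
#' spec <- PhantomSpec(imageSize = c(128, 192))
#' vs <- generateVeinNetwork(spec, 3, rngSeed = 7)
#' length(vs)
#' @export
generateVeinNetwork <- function(spec, nVeins, rngSeed = spec@rngSeed,
                                depthRange = c(0.5, 4),
                                radiusRange = c(0.8, 2)) {
  stopifnot(is(spec, "PhantomSpec"))
  if (length(nVeins) != 1 || !is.finite(nVeins) || nVeins < 0)
    .fail("nVeins must be a single non-negative number")
  nVeins <- as.integer(nVeins)
  if (nVeins == 0L) return(list())
  fov <- fieldOfView(spec)
  W <- fov[["width"]]; H <- fov[["height"]]
  .withSeed(rngSeed, {
    lapply(seq_len(nVeins), function(i) {
      radius <- runif(1, radiusRange[1], radiusRange[2])
      depth <- runif(1, depthRange[1], depthRange[2])
      margin <- radius + 0.5
      step <- 1.5
      nSteps <- max(3L, ceiling(0.9 * max(W, H) / step))
      pt <- c(runif(1, margin, W - margin), runif(1, margin, H - margin))
      heading <- runif(1, 0, 2 * pi)
      pts <- matrix(NA_real_, nSteps + 1L, 2L)
      pts[1L, ] <- pt
      n <- 1L
      for (s in seq_len(nSteps)) {
        heading <- heading + runif(1, -0.3, 0.3)
        cand <- pt + step * c(cos(heading), sin(heading))
        tries <- 0L
        while ((cand[1] < margin || cand[1] > W - margin ||
                cand[2] < margin || cand[2] > H - margin) && tries < 16L) {
          # steer back toward the field centre when the walk hits the edge
          toCentre <- atan2(H / 2 - pt[2], W / 2 - pt[1])
          heading <- toCentre + runif(1, -0.5, 0.5)
          cand <- pt + step * c(cos(heading), sin(heading))
          tries <- tries + 1L
        }
        if (tries == 16L) break
        pt <- cand
        n <- n + 1L
        pts[n, ] <- pt
      }
      VeinSegment(pts[seq_len(n), , drop = FALSE], radius = radius,
                  depth = depth)
    })
  })
}

#' Radial LED illumination field
#'
#' Superposes a Gaussian radial falloff from each LED, saturating at 1:
#' `L(x, y) = min(1, sum_i exp(-r_i^2 / (2 sigma_L^2)))`, with `r_i` the
#' distance in mm from the pixel centre to LED i. With the default wide
#' falloff (30 mm) and four-LED rectangular layout the combined field
#' saturates over the whole default field of view — the layout is designed
#' to illuminate the camera's view uniformly; narrow the falloff or drop
#' LEDs to expose the radial structure.
#'
#' @param spec a [PhantomSpec-class].
#' @return An [NIRImage-class] with the illumination in \[0, 1\].
#' @examples
#' L <- illuminationField(PhantomSpec(imageSize = c(64, 96)))
#' range(pixels(L))
#' @export
illuminationField <- function(spec) {
  stopifnot(is(spec, "PhantomSpec"))
  if (spec@ledFalloff <= 0) .fail("ledFalloff must be > 0")
  nr <- spec@imageSize[1]; nc <- spec@imageSize[2]
  xs <- (seq_len(nc) - 0.5) * spec@pixelPitch
  ys <- (seq_len(nr) - 0.5) * spec@pixelPitch
  L <- matrix(0, nr, nc)
  for (i in seq_len(nrow(spec@ledPositions))) {
    dx2 <- outer(rep(1, nr), (xs - spec@ledPositions[i, 1])^2)
    dy2 <- outer((ys - spec@ledPositions[i, 2])^2, rep(1, nc))
    L <- L + exp(-(dx2 + dy2) / (2 * spec@ledFalloff^2))
  }
  NIRImage(pmin(L, 1), pixelPitch = spec@pixelPitch)
}

## Absorption footprint of one vein: binary capsule footprint (for truth)
## plus its depth-attenuated, scatter-blurred contribution.
.veinFootprint <- function(spec, vein) {
  nr <- spec@imageSize[1]; nc <- spec@imageSize[2]
  dEff <- vein@depth + spec@adiposeThickness
  sigmaMm <- spec@blurBase + spec@blurSlope * dEff
  reach <- vein@radius + 4 * sigmaMm + spec@pixelPitch
  D <- .distFieldToPolyline(nr, nc, spec@pixelPitch, vein@centerline, reach)
  foot <- D <= vein@radius
  amp <- spec@maxAbsorption * exp(-dEff / spec@depthDecay)
  a <- .gaussBlurReflect(foot * amp, sigmaMm / spec@pixelPitch)
  list(foot = foot, absorption = a)
}

## Hair occlusion: thin (1 px) anti-aliased random arcs, each multiplying
## the underlying intensity by 0.2 at full coverage; arcs are added until
## the covered pixel fraction reaches spec@hairDensity.
.hairField <- function(spec) {
  nr <- spec@imageSize[1]; nc <- spec@imageSize[2]
  cover <- matrix(0, nr, nc)
  if (spec@hairDensity <= 0) return(cover)
  W <- nc * spec@pixelPitch; H <- nr * spec@pixelPitch
  halfw <- 0.5 * spec@pixelPitch            # 1-pixel-wide stroke
  guard <- 0L
  while (mean(cover > 0) < spec@hairDensity && guard < 4000L) {
    guard <- guard + 1L
    # quadratic arc through three jittered points
    p0 <- c(runif(1, 0, W), runif(1, 0, H))
    ang <- runif(1, 0, 2 * pi)
    len <- runif(1, 5, 15)
    p2 <- p0 + len * c(cos(ang), sin(ang))
    mid <- (p0 + p2) / 2 + runif(2, -2, 2)
    t <- seq(0, 1, length.out = 24)
    arc <- cbind((1 - t)^2 * p0[1] + 2 * t * (1 - t) * mid[1] + t^2 * p2[1],
                 (1 - t)^2 * p0[2] + 2 * t * (1 - t) * mid[2] + t^2 * p2[2])
    D <- .distFieldToPolyline(nr, nc, spec@pixelPitch, arc,
                              halfw + spec@pixelPitch)
    w <- .clip01(1 - (D - halfw) / spec@pixelPitch)   # anti-aliased edge
    cover <- pmax(cover, w)
  }
  cover
}

#' Render an NIR reflectance phantom
#'
#' Renders the image `I = clip01(I0 * L * R_bg * (1 - A) + noise)`, where
#' `L` is the LED illumination field and `A` the combined vein absorption:
#' each vein contributes its projected capsule footprint (width twice the
#' radius) scaled by `maxAbsorption * exp(-(depth + adipose) / depthDecay)`
#' and blurred with a Gaussian of sigma `blurBase + blurSlope * (depth +
#' adipose)` (scatter widening); contributions sum, saturating at 1.
#' Zero-mean Gaussian sensor noise (sd `noiseSigma`) and optional dark hair
#' strokes are applied last; both are driven by the spec's `rngSeed`, so
#' identical spec and veins render bit-identically.
#'
#' @param spec a [PhantomSpec-class].
#' @param veins list of [VeinSegment-class]; every centerline point must
#'   lie inside the field of view.
#' @return A [PhantomOutput-class]: rendered image, ground-truth footprint
#'   mask, per-pixel depth map (mm; `Inf` off-vein) and the input veins.
#' @examples
#' spec <- PhantomSpec(imageSize = c(96, 128), noiseSigma = 0)
#' v <- VeinSegment(cbind(c(2, 10), c(5, 5)), radius = 1, depth = 2)
#' out <- renderPhantom(spec, list(v))
#' mean(truthMask(out))
#' @export
renderPhantom <- function(spec, veins) {
  stopifnot(is(spec, "PhantomSpec"))
  validObject(spec)
  fov <- fieldOfView(spec)
  for (v in veins) {
    stopifnot(is(v, "VeinSegment"))
    if (any(v@centerline[, 1] < 0) || any(v@centerline[, 1] > fov[["width"]]) ||
        any(v@centerline[, 2] < 0) || any(v@centerline[, 2] > fov[["height"]]))
      .fail("vein centerline extends outside the field of view")
  }
  nr <- spec@imageSize[1]; nc <- spec@imageSize[2]
  L <- pixels(illuminationField(spec))
  A <- matrix(0, nr, nc)
  truth <- matrix(FALSE, nr, nc)
  depth <- matrix(Inf, nr, nc)
  for (v in veins) {
    fp <- .veinFootprint(spec, v)
    A <- A + fp$absorption
    truth <- truth | fp$foot
    depth[fp$foot] <- pmin(depth[fp$foot], v@depth)
  }
  A <- pmin(A, 1)
  img <- spec@baseIntensity * L * spec@backgroundReflectance * (1 - A)
  .withSeed(spec@rngSeed, {
    if (spec@noiseSigma > 0)
      img <- img + matrix(rnorm(nr * nc, 0, spec@noiseSigma), nr, nc)
    if (spec@hairDensity > 0) {
      hair <- .hairField(spec)
      img <- img * (1 - 0.8 * hair)
    }
  })
  new("PhantomOutput",
      image = NIRImage(.clip01(img), pixelPitch = spec@pixelPitch),
      truthMask = truth, depthMap = depth, veins = veins)
}

#' Ground-truth centerline pixels of a vein list
#'
#' Rasterizes vein centerlines to pixel coordinates (nearest pixel centre
#' per densely sampled arc point), for recall computations against a
#' detected mask.
#'
#' @param spec a [PhantomSpec-class] (fixes the pixel grid).
#' @param veins list of [VeinSegment-class].
#' @return Integer m x 2 matrix of unique (row, col) centerline pixels.
#' @export
truthCenterlinePixels <- function(spec, veins) {
  px <- matrix(integer(0), 0, 2)
  for (v in veins) {
    cl <- v@centerline
    for (i in seq_len(nrow(cl) - 1L)) {
      p <- cl[i, ]; q <- cl[i + 1L, ]
      n <- max(2L, ceiling(sqrt(sum((q - p)^2)) / (spec@pixelPitch / 2)))
      t <- seq(0, 1, length.out = n)
      x <- p[1] + t * (q[1] - p[1]); y <- p[2] + t * (q[2] - p[2])
      r <- pmax(1L, pmin(spec@imageSize[1], as.integer(ceiling(y / spec@pixelPitch))))
      c <- pmax(1L, pmin(spec@imageSize[2], as.integer(ceiling(x / spec@pixelPitch))))
      px <- rbind(px, cbind(r, c))
    }
  }
  unique(px)
}
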