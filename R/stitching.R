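# Overlap of tile B placed at integer shift (dy, dx) relative to tile A.
# Returns NULL when the overlap is empty.
.overlapWindows <- function(dimA, dimB, shift) {
  ra <- c(max(1L, 1L + shift[1]), min(dimA[1], dimB[1] + shift[1]))
  ca <- c(max(1L, 1L + shift[2]), min(dimA[2], dimB[2] + shift[2]))
  if (ra[1] > ra[2] || ca[1] > ca[2]) return(NULL)
  list(aRows = ra[1]:ra[2], aCols = ca[1]:ca[2],
       bRows = (ra[1]:ra[2]) - shift[1], bCols = (ca[1]:ca[2]) - shift[2])
}

#' Refine a tile offset by normalized cross-correlation
#'
#' Searches integer shifts within `searchRadiusPx` of the nominal stage
#' shift and returns the one maximizing the Pearson correlation of the two
#' tiles over their overlap. Stage positions of a tiled acquisition are
#' nearly correct, so a small bounded search suffices and avoids spurious
#' distant matches. Ties are broken towards the nominal shift. If every
#' candidate overlap is flat (zero variance), the nominal shift is returned
#' with score 0 and a warning.
#'
#' @param tileA,tileB numeric matrices (or [ShgImage-class] FOVs).
#' @param nominalShift integer (dy, dx): origin of B minus origin of A, in
#'   pixels.
#' @param searchRadiusPx half-width of the square search window (default 20).
#' @return list with `shift` (integer (dy, dx)) and `score` (correlation at
#'   that shift).
#' @export
refineOffset <- function(tileA, tileB, nominalShift, searchRadiusPx = 20L) {
  if (is(tileA, "ShgImage")) tileA <- intensities(tileA)
  if (is(tileB, "ShgImage")) tileB <- intensities(tileB)
  stopifnot(is.matrix(tileA), is.matrix(tileB))
  nominalShift <- as.integer(round(nominalShift))
  ov <- .overlapWindows(dim(tileA), dim(tileB), nominalShift)
  if (is.null(ov) || length(ov$aRows) < 32L || length(ov$aCols) < 32L)
    stop("overlap at the nominal shift is smaller than 32 px in some ",
         "dimension")
  r <- as.integer(searchRadiusPx)
  cand <- expand.grid(dy = nominalShift[1] + (-r:r),
                      dx = nominalShift[2] + (-r:r))
  # prefer candidates near the nominal shift on ties
  dist <- abs(cand$dy - nominalShift[1]) + abs(cand$dx - nominalShift[2])
  cand <- cand[order(dist, cand$dy, cand$dx), ]
  best <- NULL
  bestScore <- -Inf
  for (i in seq_len(nrow(cand))) {
    sh <- c(cand$dy[i], cand$dx[i])
    w <- .overlapWindows(dim(tileA), dim(tileB), sh)
    if (is.null(w) || length(w$aRows) < 2L || length(w$aCols) < 2L) next
    a <- as.vector(tileA[w$aRows, w$aCols])
    b <- as.vector(tileB[w$bRows, w$bCols])
    if (stats::sd(a) == 0 || stats::sd(b) == 0) next
    sc <- stats::cor(a, b)
    if (sc > bestScore + 1e-12) {
      bestScore <- sc
      best <- sh
    }
  }
  if (is.null(best)) {
    warning("flat overlap: no informative correlation; keeping the nominal ",
            "shift")
    return(list(shift = nominalShift, score = 0))
  }
  list(shift = as.integer(best), score = bestScore)
}

#' Stitch a tile layout into a mosaic
#'
#' Places the first tile at its nominal origin, then registers each further
#' tile against the already-placed tile with which it nominally overlaps the
#' most, using [refineOffset()]. The canvas is the union of the refined tile
#' footprints (re-anchored to start at the origin); voxels covered by several
#' tiles take the maximum across contributors, which is idempotent where the
#' tiles agree and avoids seam dimming for sparse bright-on-dark signal;
#' voxels covered once are copied exactly.
#'
#' @param layout a [TileLayout-class].
#' @param searchRadiusPx search half-width passed to [refineOffset()].
#' @param refine set `FALSE` to stitch at the nominal origins only.
#' @return an [ShgImage-class] mosaic.
#' @export
stitchTiles <- function(layout, searchRadiusPx = 20L, refine = TRUE) {
  stopifnot(is(layout, "TileLayout"))
  validObject(layout)
  tiles <- layout@tiles
  if (length(tiles) == 0L)
    stop("empty layout")
  ps <- vapply(tiles, function(tl) {
    if (!is.null(tl$pixelSizeUm)) tl$pixelSizeUm else layout@pixelSizeUm
  }, numeric(1))
  if (any(abs(ps - ps[1]) > 1e-9))
    stop("inconsistent pixel sizes across tiles")
  n <- length(tiles)
  placed <- matrix(NA_real_, n, 2)
  placed[1, ] <- tiles[[1]]$origin
  nomOrigin <- t(vapply(tiles, function(tl) tl$origin, numeric(2)))
  dims <- t(vapply(tiles, function(tl) dim(tl$image), integer(2)))
  if (n > 1L) for (i in 2:n) {
    if (!refine) {
      placed[i, ] <- nomOrigin[i, ]
      next
    }
    # pick the placed tile with the largest nominal overlap area
    areas <- vapply(seq_len(i - 1L), function(j) {
      sh <- round(nomOrigin[i, ] - nomOrigin[j, ])
      w <- .overlapWindows(dims[j, ], dims[i, ], sh)
      if (is.null(w)) 0 else length(w$aRows) * length(w$aCols)
    }, numeric(1))
    j <- which.max(areas)
    sh <- round(nomOrigin[i, ] - nomOrigin[j, ])
    w <- .overlapWindows(dims[j, ], dims[i, ], sh)
    if (areas[j] == 0 || is.null(w) || length(w$aRows) < 32L ||
        length(w$aCols) < 32L) {
      warning(sprintf(
        "tile %d has no usable overlap with a placed tile; using its ",
        i), "nominal origin")
      placed[i, ] <- nomOrigin[i, ]
      next
    }
    ref <- refineOffset(tiles[[j]]$image, tiles[[i]]$image, sh,
                        searchRadiusPx)
    placed[i, ] <- placed[j, ] + ref$shift
  }
  placed <- sweep(placed, 2, apply(placed, 2, min))
  canvas <- matrix(0, max(placed[, 1] + dims[, 1]),
                   max(placed[, 2] + dims[, 2]))
  for (i in seq_len(n)) {
    rr <- (placed[i, 1] + 1):(placed[i, 1] + dims[i, 1])
    cc <- (placed[i, 2] + 1):(placed[i, 2] + dims[i, 2])
    canvas[rr, cc] <- pmax(canvas[rr, cc], tiles[[i]]$image)
  }
  ShgImage(canvas, pixelSizeUm = ps[1])
}

#' Split an image into overlapping quadrant tiles
#'
#' Utility (mainly for simulation and tests): cuts a 2D image into a
#' `ny x nx` grid of tiles whose neighbours share `overlapPx` pixels, and
#' returns a [TileLayout-class] with the exact origins. Jitter the origins to
#' emulate imperfect stage coordinates.
#'
#' @param image an [ShgImage-class] or numeric matrix.
#' @param ny,nx tile grid size.
#' @param overlapPx overlap between adjacent tiles in pixels.
#' @param jitterPx maximum absolute uniform integer jitter added to each
#'   nominal origin except the first (default 0 = exact).
#' @param seed RNG seed used when `jitterPx > 0`.
#' @return a [TileLayout-class].
#' @export
quadrantLayout <- function(image, ny = 2L, nx = 2L, overlapPx = 64L,
                           jitterPx = 0L, seed = 1L) {
  px <- if (is(image, "ShgImage")) pixelSize(image) else 0.53
  m <- if (is(image, "ShgImage")) intensities(image) else image
  stopifnot(is.matrix(m))
  cuts <- function(total, k, ov) {
    size <- ceiling((total + (k - 1L) * ov) / k)
    starts <- round(seq(0L, total - size, length.out = k))
    cbind(start = starts, size = size)
  }
  ry <- cuts(nrow(m), ny, overlapPx)
  rx <- cuts(ncol(m), nx, overlapPx)
  tiles <- list()
  for (iy in seq_len(ny)) for (ix in seq_len(nx)) {
    o <- c(ry[iy, "start"], rx[ix, "start"])
    img <- m[(o[1] + 1):(o[1] + ry[iy, "size"]),
             (o[2] + 1):(o[2] + rx[ix, "size"])]
    tiles[[length(tiles) + 1L]] <- list(image = img, origin = o)
  }
  if (jitterPx > 0L) {
    tiles <- withr::with_seed(as.integer(seed), {
      for (i in 2:length(tiles)) {
        tiles[[i]]$origin <- tiles[[i]]$origin +
          sample(-jitterPx:jitterPx, 2L, replace = TRUE)
      }
      tiles
    })
  }
  TileLayout(tiles, pixelSizeUm = px, overlapUm = overlapPx * px)
}
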