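# Connected-component labeling. EBImage::bwlabel is 4-connected; for
# 8-connectivity, labels that touch diagonally are merged by union-find.
.labelConnected <- function(mask, connectivity = 8L) {
  lab <- EBImage::bwlabel(mask * 1L)
  nlab <- max(lab)
  if (connectivity == 4L || nlab <= 1L) return(lab)
  nr <- nrow(lab); nc <- ncol(lab)
  pairs <- NULL
  for (off in list(c(1L, 1L), c(1L, -1L))) {
    dy <- off[1]; dx <- off[2]
    ra <- seq_len(nr - 1L); ca <- if (dx > 0) seq_len(nc - 1L) else 2:nc
    a <- lab[ra, ca, drop = FALSE]
    b <- lab[ra + dy, ca + dx, drop = FALSE]
    sel <- a > 0 & b > 0 & a != b
    if (any(sel)) pairs <- rbind(pairs, cbind(a[sel], b[sel]))
  }
  parent <- seq_len(nlab)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  if (!is.null(pairs)) {
    for (r in seq_len(nrow(pairs))) {
      ra <- find(pairs[r, 1]); rb <- find(pairs[r, 2])
      if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
    }
  }
  root <- vapply(seq_len(nlab), find, integer(1))
  remap <- c(0L, match(root, sort(unique(root))))
  out <- remap[lab + 1L]
  dim(out) <- dim(lab)
  out
}

# Zhang-Suen morphological thinning of a binary matrix (0/1), vectorized over
# the whole grid. Returns a 1-px-wide skeleton.
.thinMask <- function(mask) {
  nr0 <- nrow(mask); nc0 <- ncol(mask)
  M <- matrix(0L, nr0 + 2L, nc0 + 2L)
  M[2:(nr0 + 1L), 2:(nc0 + 1L)] <- mask * 1L
  nr <- nrow(M); nc <- ncol(M)
  sh <- function(dy, dx) M[(2L + dy):(nr - 1L + dy), (2L + dx):(nc - 1L + dx)]
  repeat {
    changed <- FALSE
    for (step in 1:2) {
      P2 <- sh(-1L, 0L); P3 <- sh(-1L, 1L); P4 <- sh(0L, 1L)
      P5 <- sh(1L, 1L); P6 <- sh(1L, 0L); P7 <- sh(1L, -1L)
      P8 <- sh(0L, -1L); P9 <- sh(-1L, -1L)
      C <- M[2:(nr - 1L), 2:(nc - 1L)]
      B <- P2 + P3 + P4 + P5 + P6 + P7 + P8 + P9
      ring <- list(P2, P3, P4, P5, P6, P7, P8, P9, P2)
      A <- 0L
      for (i in 1:8) A <- A + (ring[[i]] == 0L) * (ring[[i + 1L]] == 1L)
      cond <- (C == 1L) & (B >= 2L) & (B <= 6L) & (A == 1L)
      cond <- cond & if (step == 1L) {
        (P2 * P4 * P6 == 0L) & (P4 * P6 * P8 == 0L)
      } else {
        (P2 * P4 * P8 == 0L) & (P2 * P6 * P8 == 0L)
      }
      if (any(cond)) {
        changed <- TRUE
        C[cond] <- 0L
        M[2:(nr - 1L), 2:(nc - 1L)] <- C
      }
    }
    if (!changed) break
  }
  M[2:(nr - 1L), 2:(nc - 1L)]
}

# Longest weighted geodesic through a set of skeleton pixels (8-neighbour
# graph, orthogonal steps 1, diagonal sqrt(2)), by double Dijkstra sweep.
# Returns the path length in pixel steps and the indices of its endpoints.
.skeletonDiameter <- function(rows, cols) {
  n <- length(rows)
  if (n == 1L) return(list(steps = 0, ends = c(1L, 1L)))
  span <- max(rows) - min(rows) + 2L
  key <- (cols - min(cols)) * span + (rows - min(rows))
  offs <- cbind(dy = c(-1L, -1L, -1L, 0L, 0L, 1L, 1L, 1L),
                dx = c(-1L, 0L, 1L, -1L, 1L, -1L, 0L, 1L))
  from <- integer(0); to <- integer(0); wt <- numeric(0)
  for (i in seq_len(nrow(offs))) {
    nk <- (cols + offs[i, 2] - min(cols)) * span + (rows + offs[i, 1] -
          min(rows))
    j <- match(nk, key)
    hit <- !is.na(j)
    if (any(hit)) {
      from <- c(from, which(hit)); to <- c(to, j[hit])
      wt <- c(wt, rep(if (all(offs[i, ] != 0L)) sqrt(2) else 1, sum(hit)))
    }
  }
  g <- igraph::graph_from_data_frame(
    data.frame(from = from, to = to, weight = wt),
    directed = FALSE, vertices = data.frame(name = seq_len(n)))
  d1 <- igraph::distances(g, v = 1)[1, ]
  d1[!is.finite(d1)] <- -1            # skeleton fragments: stay on component
  e1 <- which.max(d1)
  d2 <- igraph::distances(g, v = e1)[1, ]
  d2[!is.finite(d2)] <- -1
  e2 <- which.max(d2)
  list(steps = max(d2[e2], 0), ends = c(as.integer(e1), as.integer(e2)))
}

#' Label and measure fiber components
#'
#' Finds connected components of a binary fiber mask and measures each one:
#' voxel count, skeleton length, mean ridge width, and length/width aspect
#' ratio. The skeleton is obtained by Zhang-Suen thinning; length is the
#' longest geodesic through the skeleton (orthogonal steps 1 px, diagonal
#' sqrt(2) px, plus one pixel for the endpoints and a distance-transform
#' correction for the end retraction that thinning introduces). Width is
#' estimated as `2 * mean(EDT) - 1` pixels sampled on the skeleton, where EDT
#' is the Euclidean distance to background.
#'
#' Only 2D masks are measured; project stacks first (see [maxProject()]).
#'
#' @param mask a [FiberMask-class] (2D).
#' @param config a [ShapeFilterConfig-class]; only `connectivity` is used
#'   here.
#' @return a data.frame with one row per component and columns `component`,
#'   `area_px`, `skeleton_length_um`, `mean_width_um`, `aspect`. The label
#'   matrix and pixel size are attached as attributes `labels` and
#'   `pixelSizeUm` for use by [shapeFilter()].
#' @export
labelFiberComponents <- function(mask, config = ShapeFilterConfig()) {
  stopifnot(is(mask, "FiberMask"))
  validObject(config)
  if (length(dim(mask)) != 2L)
    stop("component morphometry is 2D; project the mask first ",
         "(see maxProject)")
  px <- pixelSize(mask)
  m <- maskArray(mask)
  empty <- data.frame(component = integer(0), area_px = integer(0),
                      skeleton_length_um = numeric(0),
                      mean_width_um = numeric(0), aspect = numeric(0))
  if (!any(m)) {
    attr(empty, "labels") <- matrix(0L, nrow(m), ncol(m))
    attr(empty, "pixelSizeUm") <- px
    return(empty)
  }
  lab <- .labelConnected(m, config@connectivity)
  dt <- EBImage::distmap(m * 1L)
  skel <- .thinMask(m) == 1L
  # thinning can in principle erase a tiny component; fall back to its
  # innermost pixel
  ids <- sort(unique(lab[lab > 0]))
  skLab <- lab * (skel * 1L)
  out <- lapply(ids, function(id) {
    inComp <- lab == id
    area <- sum(inComp)
    skIdx <- which(skLab == id)
    if (length(skIdx) == 0L)
      skIdx <- which(inComp & dt == max(dt[inComp]))[1]
    rows <- ((skIdx - 1L) %% nrow(m)) + 1L
    cols <- ((skIdx - 1L) %/% nrow(m)) + 1L
    diam <- .skeletonDiameter(rows, cols)
    dtSk <- dt[skIdx]
    endCorr <- sum(pmax(dtSk[diam$ends] - 1, 0))
    lengthPx <- diam$steps + 1 + endCorr
    widthPx <- max(2 * mean(dtSk) - 1, 1)
    data.frame(component = id, area_px = area,
               skeleton_length_um = lengthPx * px,
               mean_width_um = widthPx * px,
               aspect = lengthPx / widthPx)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  attr(out, "labels") <- lab
  attr(out, "pixelSizeUm") <- px
  out
}

#' Fibrillar shape filter
#'
#' Retains a component iff `skeleton_length_um >= minLengthUm` and
#' `mean_width_um <= maxWidthUm` and `aspect >= minAspect`, and returns the
#' union mask of the survivors. This removes blobs and stray speckle whose
#' geometry is not fiber-like while keeping long thin curvilinear structures.
#'
#' @param components output of [labelFiberComponents()].
#' @param config a [ShapeFilterConfig-class].
#' @return a [FiberMask-class]; always a subset of the input mask.
#' @export
shapeFilter <- function(components, config = ShapeFilterConfig()) {
  validObject(config)
  lab <- attr(components, "labels")
  px <- attr(components, "pixelSizeUm")
  if (is.null(lab) || is.null(px))
    stop("'components' must come from labelFiberComponents()")
  keep <- components$component[
    components$skeleton_length_um >= config@minLengthUm &
    components$mean_width_um <= config@maxWidthUm &
    components$aspect >= config@minAspect]
  out <- matrix(lab %in% keep, nrow(lab), ncol(lab))
  FiberMask(out, pixelSizeUm = px)
}

#' Segment, filter and quantify in one step
#'
#' Convenience wrapper: [segmentFibers()] then [labelFiberComponents()] and
#' [shapeFilter()].
#'
#' @param image an [ShgImage-class].
#' @param fcm an [FcmConfig-class].
#' @param shape a [ShapeFilterConfig-class].
#' @return a list with `mask` (filtered [FiberMask-class]), `rawMask`
#'   (pre-filter), `components` (measurement table) and
#'   `percentFiberVolume`.
#' @export
extractFibers <- function(image, fcm = FcmConfig(),
                          shape = ShapeFilterConfig()) {
  raw <- segmentFibers(image, fcm)
  comp <- labelFiberComponents(raw, shape)
  filt <- shapeFilter(comp, shape)
  list(mask = filt, rawMask = raw, components = comp,
       percentFiberVolume = percentFiberVolume(filt))
}

#' Percent fiber volume of a field of view
#'
#' `100 * (fiber voxels) / (total voxels)`, the primary imaging readout. The
#' denominator is the full grid of the field of view.
#'
#' @param mask a [FiberMask-class] or logical array.
#' @return a single number in \[0, 100\].
#' @examples
#' percentFiberVolume(FiberMask(matrix(c(TRUE, FALSE, FALSE, FALSE), 2, 2)))
#' @export
percentFiberVolume <- function(mask) {
  m <- if (is(mask, "FiberMask")) maskArray(mask) else mask
  if (length(m) == 0L)
    stop("zero-size mask")
  100 * mean(m)
}

#' Aggregate FOV volumes per patient
#'
#' Arithmetic mean and standard error of the percent fiber volume across the
#' fields of view of each patient. Group labels must be consistent within a
#' patient; a single-FOV patient gets `se = 0` and is flagged by
#' `se_defined = FALSE`.
#'
#' @param fovs data.frame with columns `patient_id`, `group`,
#'   `percent_fiber_volume` (and optionally `fov_id`).
#' @return data.frame with columns `patient_id`, `group`, `mean_volume`,
#'   `se`, `n_fov`, `se_defined`.
#' @export
patientAggregate <- function(fovs) {
  need <- c("patient_id", "group", "percent_fiber_volume")
  if (!all(need %in% names(fovs)))
    stop("'fovs' must have columns ", paste(need, collapse = ", "))
  if (nrow(fovs) == 0L)
    stop("no FOV records")
  sp <- split(fovs, fovs$patient_id)
  out <- lapply(sp, function(df) {
    g <- unique(as.character(df$group))
    if (length(g) != 1L)
      stop("conflicting group labels for patient ", df$patient_id[1], ": ",
           paste(g, collapse = ", "))
    v <- df$percent_fiber_volume
    n <- length(v)
    data.frame(patient_id = df$patient_id[1], group = g,
               mean_volume = mean(v),
               se = if (n > 1L) stats::sd(v) / sqrt(n) else 0,
               n_fov = n, se_defined = n > 1L)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
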