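# Hexagonal detector grids: discretization of a habitat patch into
# flat-topped regular hexagons used both as the SCR state space (activity
# centres live on cell centroids) and as polygon detectors (detections are
# mapped to the centroid of the cell they fall in).

#' Build a hexagonal detector grid over a patch boundary
#'
#' Tessellates the plane with flat-topped regular hexagons of the requested
#' area and keeps the cells whose centroid falls inside the boundary
#' polygon. The centroid-to-centroid spacing of a regular hexagonal lattice
#' with cell area \eqn{A} is \eqn{\sqrt{2A/\sqrt{3}}} (3.398 m for 10 m2
#' cells). Cells are indexed column-major (west to east, south to north
#' within a column), which fixes the deterministic tie-break used when a
#' detection lies exactly between two centroids.
#'
#' @param boundary two-column matrix of vertices of a simple polygon, in
#'   projected metric coordinates (metres). Closure optional.
#' @param cell_area target hexagon area in m2 (default 10).
#' @param strata_id label for the stratum (patch) this grid discretizes.
#' @param sigma_guess optional prior guess of the half-normal movement
#'   scale (m); a warning is emitted if the lattice spacing is not below
#'   1.5 times this value, the usual detector-spacing guideline.
#' @return an object of class `detector_grid`: a list with centroids
#'   (`x`, `y`), `cell_area`, `spacing`, circumradius `hex_R`, per-cell
#'   `effort`/`effort_std` (zeros until [rasterize_effort()] is called),
#'   `altitude`/`altitude_std` (NA until [attach_covariates()]), logical
#'   `habitat`, and the boundary polygon.
#' @export
build_hex_grid <- function(boundary, cell_area = 10, strata_id = "patch",
                           sigma_guess = NULL) {
  boundary <- as.matrix(boundary)
  if (ncol(boundary) != 2 || nrow(boundary) < 3)
    stop("`boundary` must be a polygon given as an n x 2 vertex matrix")
  if (!is.numeric(cell_area) || length(cell_area) != 1 || cell_area <= 0)
    stop("`cell_area` must be a positive scalar (m2)")
  if (polygon_area(boundary) <= 0)
    stop("degenerate boundary polygon (zero area)")

  R <- sqrt(2 * cell_area / (3 * sqrt(3)))   # circumradius
  spacing <- sqrt(3) * R                     # centre-to-centre distance
  if (!is.null(sigma_guess) && spacing >= 1.5 * sigma_guess)
    warning(sprintf(paste0(
      "detector spacing %.3f m is not below 1.5 * sigma_guess = %.3f m; ",
      "the movement scale may be under-resolved"), spacing, 1.5 * sigma_guess))

  xr <- range(boundary[, 1]); yr <- range(boundary[, 2])
  # lattice: columns at 1.5 R pitch in x, rows at `spacing` in y, odd
  # columns shifted up by half a spacing
  qs <- seq(-2, ceiling((xr[2] - xr[1]) / (1.5 * R)) + 2)
  rs <- seq(-2, ceiling((yr[2] - yr[1]) / spacing) + 2)
  cx0 <- xr[1]; cy0 <- yr[1]
  grid_q <- rep(qs, each = length(rs))
  grid_r <- rep(rs, times = length(qs))
  x <- cx0 + 1.5 * R * grid_q
  y <- cy0 + spacing * grid_r + (grid_q %% 2) * spacing / 2
  keep <- point_in_polygon(x, y, boundary)
  if (!any(keep)) {
    # boundary smaller than one cell: keep the single cell nearest the
    # polygon's vertex centroid
    ctr <- colMeans(boundary[!duplicated(boundary), , drop = FALSE])
    keep <- seq_along(x) == which.min((x - ctr[1])^2 + (y - ctr[2])^2)
  }
  x <- x[keep]; y <- y[keep]
  ord <- order(x, y)   # column-major, deterministic cell ids
  x <- x[ord]; y <- y[ord]
  J <- length(x)

  structure(list(
    strata_id = strata_id,
    cell_id = seq_len(J),
    x = x, y = y,
    cell_area = cell_area,
    spacing = spacing,
    hex_R = R,
    effort = rep(0, J),
    effort_std = rep(0, J),
    altitude = rep(NA_real_, J),
    altitude_std = rep(0, J),
    habitat = rep(TRUE, J),
    boundary = boundary
  ), class = "detector_grid")
}

#' @export
print.detector_grid <- function(x, ...) {
  cat(sprintf(
    "<detector_grid '%s': %d hexagonal cells of %.3g m2 (spacing %.3f m), %.3f ha habitat>\n",
    x$strata_id, length(x$x), x$cell_area, x$spacing,
    sum(x$habitat) * x$cell_area / 1e4))
  invisible(x)
}

#' Grid area of the habitat mask in hectares
#' @param grid a `detector_grid`.
#' @export
grid_area_ha <- function(grid) sum(grid$habitat) * grid$cell_area / 1e4

#' Rasterize survey transects into per-cell sampling effort
#'
#' Effort for a cell is the total transect length (m) intersecting its
#' hexagon. The standardized copy is the z-score computed over cells with
#' positive effort; unsurveyed cells keep raw and standardized effort 0 and
#' are treated as unable to detect (the detection model has no intercept
#' and defines the encounter rate as exactly zero there).
#'
#' @param transects a two-column coordinate matrix (one polyline) or a list
#'   of such matrices, in the grid's coordinate system.
#' @param grid a `detector_grid`.
#' @return the grid with `effort` and `effort_std` filled in.
#' @export
rasterize_effort <- function(transects, grid) {
  stopifnot(inherits(grid, "detector_grid"))
  if (is.matrix(transects) || is.data.frame(transects))
    transects <- list(as.matrix(transects))
  J <- length(grid$x)
  effort <- rep(0, J)
  R <- grid$hex_R
  # half-plane representation of the reference hexagon (outward normals)
  ang <- pi / 3 * (0:5) + pi / 6   # edge-normal directions, flat-topped
  nx <- cos(ang); ny <- sin(ang)
  apo <- sqrt(3) / 2 * R           # apothem: distance centre -> edge
  for (line in transects) {
    line <- as.matrix(line)
    if (nrow(line) < 2) next
    for (s in seq_len(nrow(line) - 1)) {
      x1 <- line[s, 1]; y1 <- line[s, 2]
      x2 <- line[s + 1, 1]; y2 <- line[s + 1, 2]
      # candidate cells: centroid within segment bounding box + R
      cand <- which(grid$x >= min(x1, x2) - R & grid$x <= max(x1, x2) + R &
                    grid$y >= min(y1, y2) - R & grid$y <= max(y1, y2) + R)
      for (j in cand) {
        len <- clip_segment_convex(
          x1, y1, x2, y2, nx, ny,
          grid$x[j] + apo * nx, grid$y[j] + apo * ny)
        if (len > 0) effort[j] <- effort[j] + len
      }
    }
  }
  grid$effort <- effort
  grid$effort_std <- rep(0, J)
  pos <- effort > 0
  if (any(pos)) grid$effort_std[pos] <- zscore(effort[pos])
  grid
}

#' Attach an altitude covariate to a detector grid
#'
#' Per-cell altitude is the mean of the raster values whose cell centres
#' fall inside the hexagon; the standardized copy is a z-score over habitat
#' cells (the density model uses the standardized value and its square).
#'
#' @param grid a `detector_grid`.
#' @param raster an `esri_grid` object (see [read_esri_ascii()]) or any
#'   list with fields `x`, `y` (cell-centre coordinate vectors) and
#'   `values` (matrix indexed `[y, x]`, rows south to north).
#' @return the grid with `altitude` and `altitude_std` filled in.
#' @export
attach_covariates <- function(grid, raster) {
  stopifnot(inherits(grid, "detector_grid"))
  rx <- rep(raster$x, each = length(raster$y))
  ry <- rep(raster$y, times = length(raster$x))
  rv <- as.vector(raster$values)   # column-major: [y, x] stacked by x
  ok <- is.finite(rv)
  rx <- rx[ok]; ry <- ry[ok]; rv <- rv[ok]
  R <- grid$hex_R
  apo <- sqrt(3) / 2 * R
  ang <- pi / 3 * (0:5) + pi / 6
  nx <- cos(ang); ny <- sin(ang)
  alt <- rep(NA_real_, length(grid$x))
  for (j in seq_along(grid$x)) {
    near <- which(abs(rx - grid$x[j]) <= R & abs(ry - grid$y[j]) <= R)
    if (!length(near)) next
    dx <- rx[near] - grid$x[j]; dy <- ry[near] - grid$y[j]
    inside <- rep(TRUE, length(near))
    for (e in 1:6) inside <- inside & (dx * nx[e] + dy * ny[e] <= apo + 1e-9)
    if (any(inside)) alt[j] <- mean(rv[near[inside]])
  }
  if (anyNA(alt[grid$habitat]))
    stop(sprintf("invalid-data: altitude raster does not cover %d habitat cell(s), e.g. cell %d",
                 sum(is.na(alt[grid$habitat])),
                 grid$cell_id[grid$habitat][which(is.na(alt[grid$habitat]))[1]]))
  grid$altitude <- alt
  grid$altitude_std <- rep(0, length(alt))
  grid$altitude_std[grid$habitat] <- zscore(alt[grid$habitat])
  grid
}

#' Map identified and unidentified samples onto the detector grid
#'
#' Each sample increments the count of the habitat cell whose centroid is
#' nearest its coordinates (ties broken by lowest cell index, the
#' column-major id). Identified samples build the detection array
#' `y[individual, cell, occasion]`; samples that failed genotyping build
#' the unidentified count matrix `c[cell, occasion]`.
#'
#' @param catalog an `individual_catalog` (see [match_individuals()]) whose
#'   detections carry coordinates and visit numbers, or NULL if
#'   `identified` is supplied directly.
#' @param failed_samples data frame of genotyping failures with columns
#'   `x`, `y`, `visit`.
#' @param grid a `detector_grid`.
#' @param n_occasions number of occasions K; visits must be in `1..K`.
#' @param identified optional data frame (`individual`, `x`, `y`, `visit`)
#'   used instead of `catalog`.
#' @return an object of class `scr_dataset` with fields `y` (n x J x K
#'   array), `c` (J x K matrix), `sexes` (per observed individual,
#'   "F"/"M"/"U"), `individual_ids`, `n_occasions` and the grid.
#' @export
assign_detections <- function(catalog = NULL, failed_samples = NULL, grid,
                              n_occasions, identified = NULL) {
  stopifnot(inherits(grid, "detector_grid"))
  if (is.null(identified)) {
    if (is.null(catalog)) stop("supply either `catalog` or `identified`")
    identified <- catalog$detections
    sexes <- catalog$individuals$sex[match(sort(unique(identified$individual)),
                                           catalog$individuals$individual_id)]
  } else {
    sexes <- attr(identified, "sexes")
  }
  ids <- sort(unique(identified$individual))
  if (is.null(sexes)) sexes <- rep("U", length(ids))
  n <- length(ids)
  J <- length(grid$x)
  K <- as.integer(n_occasions)
  stopifnot(K >= 1)

  locate <- function(px, py, what) {
    if (!length(px)) return(integer(0))
    cell <- integer(length(px))
    for (s in seq_along(px)) {
      d2 <- (grid$x - px[s])^2 + (grid$y - py[s])^2
      j <- which.min(d2)   # first minimum = lowest cell index on ties
      if (sqrt(d2[j]) > grid$spacing)
        stop(sprintf("invalid-data: %s sample %d at (%.2f, %.2f) lies outside every grid cell",
                     what, s, px[s], py[s]))
      cell[s] <- j
    }
    cell
  }

  y <- array(0L, dim = c(n, J, K))
  if (nrow(identified)) {
    if (any(identified$visit < 1 | identified$visit > K))
      stop("invalid-data: visit outside 1..n_occasions")
    cells <- locate(identified$x, identified$y, "identified")
    ii <- match(identified$individual, ids)
    for (s in seq_len(nrow(identified)))
      y[ii[s], cells[s], identified$visit[s]] <- y[ii[s], cells[s], identified$visit[s]] + 1L
  }
  cmat <- matrix(0L, J, K)
  if (!is.null(failed_samples) && nrow(failed_samples)) {
    if (any(failed_samples$visit < 1 | failed_samples$visit > K))
      stop("invalid-data: visit outside 1..n_occasions")
    cells <- locate(failed_samples$x, failed_samples$y, "unidentified")
    for (s in seq_len(nrow(failed_samples)))
      cmat[cells[s], failed_samples$visit[s]] <- cmat[cells[s], failed_samples$visit[s]] + 1L
  }
  structure(list(
    strata_id = grid$strata_id,
    y = y, c = cmat,
    sexes = sexes,
    individual_ids = ids,
    n_occasions = K,
    grid = grid
  ), class = "scr_dataset")
}

#' @export
print.scr_dataset <- function(x, ...) {
  cat(sprintf(
    "<scr_dataset '%s': %d observed individuals, %d identified detections, %d unidentified, %d cells x %d occasions>\n",
    x$strata_id, dim(x$y)[1], sum(x$y), sum(x$c), dim(x$y)[2], x$n_occasions))
  invisible(x)
}

#' Convenience rectangular patch boundary
#' @param width,height rectangle dimensions in metres.
#' @param origin lower-left corner (length-2 numeric).
#' @export
rect_boundary <- function(width, height, origin = c(0, 0)) {
  if (width <= 0 || height <= 0) stop("invalid-argument: non-positive extent")
  cbind(origin[1] + c(0, width, width, 0),
        origin[2] + c(0, 0, height, height))
}

#' Serpentine survey transects covering a rectangle
#'
#' Emulates zigzag field searches: parallel north-south passes `spacing`
#' metres apart joined at alternate ends, as a single polyline.
#' @param width,height rectangle dimensions (m).
#' @param spacing distance between passes (m).
#' @param origin lower-left corner.
#' @export
serpentine_transects <- function(width, height, spacing = 15, origin = c(0, 0)) {
  xs <- seq(spacing / 2, width - spacing / 4, by = spacing)
  pts <- matrix(0, 0, 2)
  for (i in seq_along(xs)) {
    ys <- if (i %% 2 == 1) c(0, height) else c(height, 0)
    pts <- rbind(pts, cbind(xs[i], ys))
  }
  pts[, 1] <- pts[, 1] + origin[1]
  pts[, 2] <- pts[, 2] + origin[2]
  pts
}
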