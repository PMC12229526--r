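#' @keywords internal
"_PACKAGE"

#' @useDynLib gnisscr, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats dnorm dpois dbinom dunif quantile rbinom rpois runif
#'   rnorm sd var setNames complete.cases
#' @importFrom utils head read.csv write.csv
NULL

# Set the RNG locally when a seed is supplied; restores the caller's RNG
# state on exit so simulation helpers do not disturb the global stream.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

# Ray-casting point-in-polygon test. `poly` is an n x 2 vertex matrix of a
# simple polygon (closure optional). Points exactly on an edge may fall on
# either side; callers relying on boundary points use tolerance-based
# assignment instead.
point_in_polygon <- function(px, py, poly) {
  poly <- as.matrix(poly)
  n <- nrow(poly)
  if (all(poly[1, ] == poly[n, ])) {
    poly <- poly[-n, , drop = FALSE]
    n <- n - 1L
  }
  inside <- logical(length(px))
  j <- n
  for (i in seq_len(n)) {
    xi <- poly[i, 1]; yi <- poly[i, 2]
    xj <- poly[j, 1]; yj <- poly[j, 2]
    crosses <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}

polygon_area <- function(poly) {
  poly <- as.matrix(poly)
  n <- nrow(poly)
  if (all(poly[1, ] == poly[n, ])) poly <- poly[-n, , drop = FALSE]
  x <- poly[, 1]; y <- poly[, 2]
  abs(sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y)) / 2
}

# Clip the segment (p1, p2) to a convex polygon given as half-planes
# (outward normals `nx`, `ny` through vertex points `vx`, `vy`); returns the
# length of the clipped piece. Liang-Barsky style parametric clipping.
clip_segment_convex <- function(x1, y1, x2, y2, nx, ny, vx, vy) {
  dx <- x2 - x1; dy <- y2 - y1
  t0 <- 0; t1 <- 1
  for (e in seq_along(nx)) {
    # signed distance of endpoints to edge e (positive = outside)
    denom <- nx[e] * dx + ny[e] * dy
    dist1 <- nx[e] * (x1 - vx[e]) + ny[e] * (y1 - vy[e])
    if (abs(denom) < 1e-300) {
      if (dist1 > 0) return(0)
    } else {
      t <- -dist1 / denom
      if (denom > 0) t1 <- min(t1, t) else t0 <- max(t0, t)
      if (t0 > t1) return(0)
    }
  }
  (t1 - t0) * sqrt(dx^2 + dy^2)
}

# Vertices of a flat-topped regular hexagon centred at (cx, cy) with
# circumradius R, listed counter-clockwise starting at angle 0.
hex_vertices <- function(cx, cy, R) {
  ang <- pi / 3 * (0:5)
  cbind(cx + R * cos(ang), cy + R * sin(ang))
}

# z-score that tolerates zero variance (returns zeros).
zscore <- function(x) {
  s <- sd(x)
  if (!is.finite(s) || s == 0) return(rep(0, length(x)))
  (x - mean(x)) / s
}

# FNV-1a hash of a character scalar, for stamping outputs with a config
# fingerprint without a digest dependency.
fnv1a_hash <- function(x) {
  bytes <- utf8ToInt(paste(deparse(x), collapse = "\n"))
  h <- 2166136261
  for (b in bytes) {
    lo <- h %% 256
    h <- h - lo + bitwXor(as.integer(lo), as.integer(b))
    h <- (h * 16777619) %% 4294967296
  }
  paste0(format(as.hexmode(h %/% 65536), width = 4),
         format(as.hexmode(h %% 65536), width = 4))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
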