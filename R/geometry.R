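#' Junction-belt geometry
#'
#' A `junction_geometry` describes the belt-like meshwork of cell-cell
#' contacts in a monolayer field of view: a list of polylines (belts) in
#' nanometre coordinates, with the origin at the top-left corner of the
#' field (x growing along columns, y along rows).
#'
#' @param belts list of two-column matrices (`x_nm`, `y_nm`), each with at
#'   least two vertices.
#' @param field_size_nm numeric length-2, field width and height in nm.
#' @param n_cells number of cells that generated the tessellation.
#' @return An object of class `junction_geometry`.
#' @export
junction_geometry <- function(belts, field_size_nm, n_cells = NA_integer_) {
  stopifnot(length(field_size_nm) == 2, all(field_size_nm > 0))
  if (length(belts) == 0L)
    stop("geometry must contain at least one belt polyline")
  for (b in belts) {
    if (!is.matrix(b) || ncol(b) != 2 || nrow(b) < 2)
      stop("each belt must be a 2-column matrix with >= 2 vertices")
    if (any(b[, 1] < -1e-6) || any(b[, 2] < -1e-6) ||
        any(b[, 1] > field_size_nm[1] + 1e-6) ||
        any(b[, 2] > field_size_nm[2] + 1e-6))
      stop("belt vertices must lie inside the field")
  }
  geom <- structure(
    list(belts = belts, field_size_nm = as.numeric(field_size_nm),
         n_cells = as.integer(n_cells)),
    class = "junction_geometry")
  if (belt_length(geom) <= 0) stop("total belt length must be positive")
  geom
}

#' Total belt length of a junction geometry
#'
#' @param geometry a [junction_geometry()].
#' @param unit `"nm"` or `"um"`.
#' @return Total arc length of all belt polylines.
#' @export
belt_length <- function(geometry, unit = c("nm", "um")) {
  unit <- match.arg(unit)
  len <- sum(vapply(geometry$belts, function(b) {
    d <- diff(b)
    sum(sqrt(rowSums(d^2)))
  }, numeric(1)))
  if (unit == "um") len / 1000 else len
}

#' @export
print.junction_geometry <- function(x, ...) {
  cat(sprintf("junction_geometry: %d cells, %d belt segments, %.1f um total length, field %.1f x %.1f um\n",
              x$n_cells, length(x$belts), belt_length(x, "um"),
              x$field_size_nm[1] / 1000, x$field_size_nm[2] / 1000))
  invisible(x)
}

# Sutherland-Hodgman clip of a convex polygon against half-plane a.x <= b
clip_halfplane <- function(poly, a, b) {
  n <- nrow(poly)
  if (n == 0L) return(poly)
  out <- matrix(numeric(0), ncol = 2)
  d <- poly %*% a - b
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    di <- d[i]; dj <- d[j]
    if (di <= 1e-9) out <- rbind(out, poly[i, ])
    if ((di < -1e-9 && dj > 1e-9) || (di > 1e-9 && dj < -1e-9)) {
      t <- di / (di - dj)
      out <- rbind(out, poly[i, ] + t * (poly[j, ] - poly[i, ]))
    }
  }
  out
}

# Voronoi cell of seeds[i, ] within the field rectangle, by clipping the
# rectangle against the perpendicular bisector of i and every other seed.
voronoi_cell <- function(seeds, i, field) {
  poly <- rbind(c(0, 0), c(field[1], 0), c(field[1], field[2]), c(0, field[2]))
  pi_ <- seeds[i, ]
  for (j in seq_len(nrow(seeds))) {
    if (j == i) next
    pj <- seeds[j, ]
    a <- pj - pi_                       # half-plane a.x <= b keeps side of i
    b <- sum(pj^2 - pi_^2) / 2
    poly <- clip_halfplane(poly, a, b)
    if (nrow(poly) < 3L) break
  }
  poly
}

#' Generate a junction-belt network from a random cell tessellation
#'
#' Emulates the cell-cell contact geometry of a confluent monolayer: `n_cells`
#' seed points are dropped uniformly in the field and the belts are the shared
#' edges of their bounded Voronoi tessellation, mimicking the anastomosing
#' junctional meshwork seen in ZO-1 / claudin-5 stainings.
#'
#' @param n_cells integer >= 2, number of cells.
#' @param field_size_nm numeric length-2, field width/height in nm.
#' @param seed integer RNG seed; identical seeds give identical geometries.
#' @return A [junction_geometry()] whose belts are the tessellation edges
#'   (each a 2-vertex polyline), excluding the outer field border.
#' @examples
#' g <- generate_junction_network(9, c(20000, 20000), seed = 1)
#' belt_length(g, "um")
#' @export
generate_junction_network <- function(n_cells, field_size_nm, seed = 1L) {
  if (n_cells < 2) stop("cannot form junctions: need at least 2 cells")
  stopifnot(length(field_size_nm) == 2, all(field_size_nm > 0))
  set.seed(seed)
  field <- as.numeric(field_size_nm)
  seeds <- cbind(runif(n_cells, 0, field[1]), runif(n_cells, 0, field[2]))

  cells <- lapply(seq_len(n_cells), function(i) voronoi_cell(seeds, i, field))
  belts <- list()
  tol <- 1e-6 * max(field)
  for (i in seq_len(n_cells - 1L)) {
    poly <- cells[[i]]
    if (nrow(poly) < 2L) next
    for (j in (i + 1L):n_cells) {
      # vertices of cell i equidistant from seeds i and j lie on the shared edge
      di <- sqrt(rowSums((poly - matrix(seeds[i, ], nrow(poly), 2, byrow = TRUE))^2))
      dj <- sqrt(rowSums((poly - matrix(seeds[j, ], nrow(poly), 2, byrow = TRUE))^2))
      on_edge <- abs(di - dj) < tol
      if (sum(on_edge) >= 2L) {
        v <- poly[on_edge, , drop = FALSE]
        # take the two extreme points along the edge direction
        dir <- v[which.max(rowSums((v - matrix(v[1, ], nrow(v), 2, byrow = TRUE))^2)), ] - v[1, ]
        if (sum(dir^2) < tol^2) next
        proj <- v %*% dir
        seg <- v[c(which.min(proj), which.max(proj)), , drop = FALSE]
        if (sqrt(sum((seg[1, ] - seg[2, ])^2)) > tol)
          belts[[length(belts) + 1L]] <- seg
      }
    }
  }
  if (length(belts) == 0L)
    stop("degenerate tessellation produced no shared edges")
  geom <- junction_geometry(lapply(belts, function(b) {
    b[, 1] <- pmin(pmax(b[, 1], 0), field[1])
    b[, 2] <- pmin(pmax(b[, 2], 0), field[2])
    b
  }), field, n_cells)
  geom$seeds <- seeds
  geom
}

# distance from points (n x 2) to a segment p1-p2
dist_to_segment <- function(pts, p1, p2) {
  v <- p2 - p1
  l2 <- sum(v^2)
  if (l2 == 0) return(sqrt(rowSums((pts - matrix(p1, nrow(pts), 2, byrow = TRUE))^2)))
  w <- sweep(pts, 2, p1)
  t <- pmin(pmax((w %*% v) / l2, 0), 1)
  proj <- cbind(p1[1] + t * v[1], p1[2] + t * v[2])
  sqrt(rowSums((pts - proj)^2))
}

#' Rasterize junction belts to a binary ROI mask
#'
#' Pixels whose centre lies within `halfwidth_nm` of any belt polyline are set
#' true. Used both to paint widefield junction signal and to build the ROI
#' masks that condition SMLM analyses on the membrane region.
#'
#' @param geometry a [junction_geometry()].
#' @param pixel_nm pixel pitch of the mask grid in nm.
#' @param halfwidth_nm half-width of the painted belt ribbon in nm; `0` keeps
#'   only pixels whose centre is within half a pixel of the skeleton.
#' @return An [roi_mask()] covering the geometry's field.
#' @export
rasterize_belts <- function(geometry, pixel_nm, halfwidth_nm = 0) {
  field <- geometry$field_size_nm
  nc <- max(1L, ceiling(field[1] / pixel_nm))
  nr <- max(1L, ceiling(field[2] / pixel_nm))
  mask <- matrix(FALSE, nr, nc)
  reach <- max(halfwidth_nm, pixel_nm / 2)
  xc <- (seq_len(nc) - 0.5) * pixel_nm
  yc <- (seq_len(nr) - 0.5) * pixel_nm
  for (b in geometry$belts) {
    for (s in seq_len(nrow(b) - 1L)) {
      p1 <- b[s, ]; p2 <- b[s + 1L, ]
      cmin <- max(1L, floor((min(p1[1], p2[1]) - reach) / pixel_nm))
      cmax <- min(nc, ceiling((max(p1[1], p2[1]) + reach) / pixel_nm) + 1L)
      rmin <- max(1L, floor((min(p1[2], p2[2]) - reach) / pixel_nm))
      rmax <- min(nr, ceiling((max(p1[2], p2[2]) + reach) / pixel_nm) + 1L)
      if (cmin > cmax || rmin > rmax) next
      cols <- cmin:cmax; rows <- rmin:rmax
      grid <- cbind(rep(xc[cols], each = length(rows)),
                    rep(yc[rows], times = length(cols)))
      d <- dist_to_segment(grid, p1, p2)
      hit <- matrix(d <= reach, nrow = length(rows))
      mask[rows, cols] <- mask[rows, cols] | hit
    }
  }
  roi_mask(mask, pixel_nm)
}
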