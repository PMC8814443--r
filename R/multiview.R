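#' Geometry of the nine canonical view planes
#'
#' Every plane passes through the cube centre `(31.5, 31.5, 31.5)` (0-based
#' voxel coordinates of a 64^3 grid). Views 1-3 are the axis-aligned
#' central planes (axial, sagittal, coronal). Views 4-9 are the six
#' "edge-diagonal" symmetry planes of the cube: each contains one
#' coordinate axis and bisects the other two at 45 degrees; their unit
#' normals are the lexicographically ordered set
#' `(0,1,-1), (0,1,1), (1,-1,0), (1,0,-1), (1,0,1), (1,1,0)` scaled by
#' `1/sqrt(2)`.
#'
#' @param index View index in 1..9 (1 axial, 2 sagittal, 3 coronal,
#'   4-9 diagonals).
#' @return List with `name`, `point` (a point on the plane: the cube
#'   centre), `normal`, and in-plane unit vectors `u`, `v`
#'   (`v = normal x u`).
#' @export
view_plane_geometry <- function(index) {
  if (length(index) != 1L || is.na(index) || index < 1 || index > 9 ||
      index != round(index))
    stop("contract error: view index must be a single integer in 1..9", call. = FALSE)
  centre <- c(31.5, 31.5, 31.5)
  diag_normals <- list(c(0, 1, -1), c(0, 1, 1), c(1, -1, 0),
                       c(1, 0, -1), c(1, 0, 1), c(1, 1, 0))
  if (index <= 3) {
    def <- switch(index,
      list(name = "axial",    normal = c(0, 0, 1), u = c(1, 0, 0)),
      list(name = "sagittal", normal = c(1, 0, 0), u = c(0, 1, 0)),
      list(name = "coronal",  normal = c(0, 1, 0), u = c(1, 0, 0)))
  } else {
    nrm <- diag_normals[[index - 3L]] / sqrt(2)
    axis <- which(abs(nrm) < 1e-12)  # the coordinate axis contained in the plane
    u <- c(0, 0, 0); u[axis] <- 1
    def <- list(name = paste0("diag", paste(diag_normals[[index - 3L]] + 1,
                                            collapse = "")),
                normal = nrm, u = u)
  }
  v <- cross3(def$normal, def$u)
  v <- v / sqrt(sum(v^2))
  list(name = def$name, point = centre, normal = def$normal, u = def$u, v = v)
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

VIEW_ORDER_TAG <- paste(vapply(1:9, function(i) view_plane_geometry(i)$name,
                               character(1)), collapse = "|")

# Trilinear sampling of `grid` (3-D array, 0-based coords) at arbitrary
# points. Coordinates are clamped to [0, d-1] (edge extension), so a
# constant volume samples to the constant everywhere, including the few
# diagonal-grid points that fall just outside the cube.
sample_points_trilinear <- function(grid, pts) {
  d <- dim(grid)
  x <- pmin(pmax(pts[, 1], 0), d[1] - 1)
  y <- pmin(pmax(pts[, 2], 0), d[2] - 1)
  z <- pmin(pmax(pts[, 3], 0), d[3] - 1)
  x0 <- pmax(pmin(floor(x), d[1] - 2), 0)
  y0 <- pmax(pmin(floor(y), d[2] - 2), 0)
  z0 <- pmax(pmin(floor(z), d[3] - 2), 0)
  fx <- x - x0; fy <- y - y0; fz <- z - z0
  at <- function(i, j, k)
    grid[cbind(x0 + i + 1, y0 + j + 1, z0 + k + 1)]
  (at(0,0,0) * (1-fx) + at(1,0,0) * fx) * (1-fy) * (1-fz) +
    (at(0,1,0) * (1-fx) + at(1,1,0) * fx) * fy     * (1-fz) +
    (at(0,0,1) * (1-fx) + at(1,0,1) * fx) * (1-fy) * fz +
    (at(0,1,1) * (1-fx) + at(1,1,1) * fx) * fy     * fz
}

# Sample a plane on an nu x nv grid of unit-spaced points centred on
# `point`, spanned by unit vectors u and v.
sample_plane <- function(grid, point, u, v, nu, nv) {
  ou <- seq_len(nu) - 1 - (nu - 1) / 2
  ov <- seq_len(nv) - 1 - (nv - 1) / 2
  pu <- outer(ou, rep(1, nv))
  pv <- outer(rep(1, nu), ov)
  pts <- cbind(as.vector(point[1] + pu * u[1] + pv * v[1]),
               as.vector(point[2] + pu * u[2] + pv * v[2]),
               as.vector(point[3] + pu * u[3] + pv * v[3]))
  matrix(sample_points_trilinear(grid, pts), nu, nv)
}

#' Bilinear resize of a 2-D image
#'
#' Pixel-centre aligned, clamped at the borders (no overshoot).
#'
#' @param img Numeric matrix.
#' @param out_dim Length-2 target shape.
#' @return Resized matrix.
#' @export
resize_bilinear <- function(img, out_dim) {
  d <- dim(img)
  cs <- lapply(1:2, function(a) resample_coords(d[a], out_dim[a]))
  lo <- lapply(1:2, function(a) pmax(pmin(floor(cs[[a]]), d[a] - 2), 0))
  fr <- lapply(1:2, function(a) pmin(pmax(cs[[a]] - lo[[a]], 0), 1))
  l1 <- lo[[1]] + 1; l2 <- lo[[2]] + 1
  h1 <- pmin(l1 + 1, d[1]); h2 <- pmin(l2 + 1, d[2])
  fx <- matrix(fr[[1]], out_dim[1], out_dim[2])
  fy <- matrix(fr[[2]], out_dim[1], out_dim[2], byrow = TRUE)
  img[l1, l2] * (1 - fx) * (1 - fy) + img[h1, l2] * fx * (1 - fy) +
    img[l1, h2] * (1 - fx) * fy + img[h1, h2] * fx * fy
}

DIAG_NATIVE_NV <- 91L  # ceil(64 * sqrt(2)): native extent across the diagonal

#' Extract the nine canonical 2.5-D views from a cube
#'
#' Views 1-3 are the central axial/sagittal/coronal planes, interpolated at
#' the exact cube centre (coordinate 31.5 between the two middle slices).
#' Views 4-9 are the six diagonal planes (see [view_plane_geometry()]),
#' sampled on a native 64 x 91 unit-spaced grid (91 = ceil(64 * sqrt(2)))
#' and resized to 64 x 64 bilinearly; the few sample points falling just
#' outside the cube take the nearest boundary value (edge clamping), so a
#' constant cube yields exactly constant views.
#' The output order is fixed and recorded in `order_tag`; the
#' downstream feature concatenation depends on it.
#'
#' @param cube A [cube64()].
#' @return Object of class `view_stack`: list with `views` (list of nine
#'   64x64 matrices) and `order_tag`.
#' @export
extract_nine_views <- function(cube) {
  if (!inherits(cube, "cube64"))
    stop("contract error: extract_nine_views needs a cube64", call. = FALSE)
  views <- lapply(1:9, function(i) {
    g <- view_plane_geometry(i)
    if (i <= 3) {
      sample_plane(cube$grid, g$point, g$u, g$v, 64L, 64L)
    } else {
      native <- sample_plane(cube$grid, g$point, g$u, g$v, 64L, DIAG_NATIVE_NV)
      resize_bilinear(native, c(64L, 64L))
    }
  })
  structure(list(views = views, order_tag = VIEW_ORDER_TAG), class = "view_stack")
}

#' @export
print.view_stack <- function(x, ...) {
  cat("<view_stack> 9 views 64x64:", x$order_tag, "\n")
  invisible(x)
}
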