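#' Define a regular voxel grid
#'
#' The grid is voxel-centered: voxel `(i, j, k)` (0-based) has its center at
#' `origin + (index + 0.5) * spacing`. Coordinates and spacings are in mm;
#' linear voxel indices run x-fastest (R array order).
#'
#' @param dims integer triple, voxels per axis (all >= 1).
#' @param spacing length triple, mm (all > 0). A scalar is recycled.
#' @param origin position triple, mm, of the grid's lower corner.
#' @return An object of class `voxel_grid`.
#' @examples
#' g <- voxel_grid(c(10, 10, 5), 2)
#' n_voxels(g)
#' @export
voxel_grid <- function(dims, spacing, origin = c(0, 0, 0)) {
  if (length(dims) != 3L || anyNA(dims)) stopf("'dims' must be an integer triple")
  dims <- as.integer(dims)
  if (any(dims < 1L)) stopf("all grid dims must be >= 1")
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  spacing <- chk_num(spacing, "spacing", len = 3, lower = 0, strict = TRUE)
  origin <- chk_num(origin, "origin", len = 3)
  structure(list(dims = dims, spacing = spacing, origin = origin),
            class = "voxel_grid")
}

#' @rdname voxel_grid
#' @param grid a `voxel_grid`.
#' @export
n_voxels <- function(grid) prod(grid$dims)

#' @rdname voxel_grid
#' @export
voxel_volume_cc <- function(grid) prod(grid$spacing) / 1000

# voxel-center coordinates along one axis
axis_centers <- function(grid, axis) {
  grid$origin[axis] + (seq_len(grid$dims[axis]) - 0.5) * grid$spacing[axis]
}

grid_extent <- function(grid) grid$dims * grid$spacing

#' @export
print.voxel_grid <- function(x, ...) {
  cat(sprintf("voxel_grid: %d x %d x %d voxels, spacing %s mm, %d voxels (%.2f cc each)\n",
              x$dims[1], x$dims[2], x$dims[3],
              paste(format(x$spacing), collapse = " x "),
              n_voxels(x), voxel_volume_cc(x)))
  invisible(x)
}

#' Define a region-of-interest mask
#'
#' @param name ROI label.
#' @param role one of `"target"`, `"oar"`, `"external"`.
#' @param mask logical vector, one entry per grid voxel (x-fastest order).
#' @param grid the `voxel_grid` the mask refers to.
#' @return An object of class `roi_mask`.
#' @export
roi_mask <- function(name, role = c("target", "oar", "external"), mask, grid) {
  role <- match.arg(role)
  mask <- chk_flag_mask(mask, n_voxels(grid), name)
  if (role == "target" && !any(mask))
    stopf("target ROI '%s' has zero volume", name)
  structure(list(name = name, role = role, mask = mask),
            class = "roi_mask")
}

#' @export
print.roi_mask <- function(x, ...) {
  cat(sprintf("roi_mask '%s' (%s): %d voxels\n", x$name, x$role, sum(x$mask)))
  invisible(x)
}

# combine per-axis membership vectors into a linear mask (x fastest)
outer_mask <- function(mx, my, mz) {
  as.vector(outer(outer(mx, my, "&"), mz, "&"))
}

box_mask <- function(grid, center, size, tol = 1e-9) {
  half <- size / 2
  m <- lapply(1:3, function(a)
    abs(axis_centers(grid, a) - center[a]) <= half[a] + tol)
  outer_mask(m[[1]], m[[2]], m[[3]])
}

sphere_mask <- function(grid, center, radius, tol = 1e-9) {
  d2 <- lapply(1:3, function(a) (axis_centers(grid, a) - center[a])^2)
  as.vector(outer(outer(d2[[1]], d2[[2]], "+"), d2[[3]], "+")) <=
    (radius + tol)^2
}

roi_extent <- function(shape, center, size = NULL, radius = NULL) {
  if (shape == "box") list(lo = center - size / 2, hi = center + size / 2)
  else list(lo = center - radius, hi = center + radius)
}

build_shape_mask <- function(grid, spec, what) {
  shape <- spec$shape %||% "box"
  center <- spec$center %||% (grid$origin + grid_extent(grid) / 2)
  center <- chk_num(center, paste0(what, " center"), len = 3)
  if (shape == "box") {
    if (length(spec$size) == 1L) spec$size <- rep(spec$size, 3L)
    size <- chk_num(spec$size, paste0(what, " size"), len = 3, lower = 0,
                    strict = TRUE)
    list(mask = box_mask(grid, center, size),
         ext = roi_extent("box", center, size = size))
  } else if (shape == "sphere") {
    radius <- chk_num(spec$radius, paste0(what, " radius"), len = 1, lower = 0,
                      strict = TRUE)
    list(mask = sphere_mask(grid, center, radius),
         ext = roi_extent("sphere", center, radius = radius))
  } else stopf("unknown ROI shape '%s'", shape)
}

#' Generate a synthetic voxel phantom with target and OAR masks
#'
#' Builds a uniform water phantom on a regular grid with a clinical target
#' volume (CTV; box or sphere), one or more organ-at-risk (OAR) masks and an
#' "external" ROI covering the whole phantom. OAR masks are trimmed so that
#' CTV and OARs are disjoint by construction. Deterministic: identical specs
#' produce identical phantoms.
#'
#' @param spec a list with elements `dims`, `spacing`, optional `origin`,
#'   `ctv` (list with `shape` = "box"/"sphere", optional `center`, and `size`
#'   or `radius`) and `oars` (list of lists with `name` plus the same shape
#'   fields). The CTV must lie fully inside the grid.
#' @return list with elements `grid` (a [voxel_grid]) and `rois` (named list
#'   of [roi_mask]: the CTV, each OAR, and `external`).
#' @examples
#' ph <- generate_phantom(list(dims = c(50, 50, 30), spacing = 2,
#'                             ctv = list(shape = "box", size = 20)))
#' sum(ph$rois$CTV$mask)  # 1000
#' @export
generate_phantom <- function(spec) {
  grid <- voxel_grid(spec$dims, spec$spacing, spec$origin %||% c(0, 0, 0))
  if (is.null(spec$ctv)) stopf("phantom spec must define a 'ctv'")

  ctv <- build_shape_mask(grid, spec$ctv, "ctv")
  lo <- grid$origin; hi <- grid$origin + grid_extent(grid)
  if (any(ctv$ext$lo < lo - 1e-9) || any(ctv$ext$hi > hi + 1e-9))
    stopf("CTV extends outside the phantom grid")
  if (!any(ctv$mask)) stopf("CTV has zero volume on this grid")

  ctv_name <- spec$ctv$name %||% "CTV"
  rois <- list()
  rois[[ctv_name]] <- roi_mask(ctv_name, "target", ctv$mask, grid)

  for (o in spec$oars %||% list()) {
    nm <- o$name %||% stopf("every OAR needs a 'name'")
    om <- build_shape_mask(grid, o, nm)$mask & !ctv$mask
    if (!any(om)) stopf("OAR '%s' has zero volume (after removing CTV overlap)", nm)
    rois[[nm]] <- roi_mask(nm, "oar", om, grid)
  }
  rois$external <- roi_mask("external", "external", rep(TRUE, n_voxels(grid)), grid)
  list(grid = grid, rois = rois)
}
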