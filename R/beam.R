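#' Parameters of the analytic carbon pencil-beam depth curves
#'
#' Parametric stand-in for Monte Carlo depth-dose and dose-averaged-LET
#' curves of a scanned carbon pencil beam in water. The depth-dose is a
#' Bragg-peak Gaussian of width `peak_sigma` on top of a slowly rising
#' entrance plateau, normalized so the peak value is exactly 1 (per unit
#' fluence weight) and the entrance value is `entrance_ratio`; beyond the
#' peak a fragmentation tail of relative amplitude `tail_fraction` decays
#' exponentially over `tail_length`. The dose-averaged LET rises from
#' `let_entrance` at the surface to `let_peak` at the Bragg peak as
#' `(z/R)^let_shape_q` and relaxes linearly back to `let_entrance` over the
#' tail. Defaults are fixture values with a carbon-like shape.
#'
#' @param entrance_ratio entrance-to-peak dose ratio, in (0, 1/1.15).
#' @param peak_sigma Bragg-peak Gaussian width, mm.
#' @param tail_fraction fragmentation-tail dose fraction just beyond the peak,
#'   in `[0, entrance_ratio)`.
#' @param tail_length tail decay length, mm.
#' @param let_entrance,let_peak dose-averaged LET at surface / peak, keV/um
#'   (`let_peak > let_entrance > 0`).
#' @param let_shape_q dimensionless exponent of the LET rise (> 0).
#' @return object of class `depth_curve_params`.
#' @export
depth_curve_params <- function(entrance_ratio = 0.35, peak_sigma = 3,
                               tail_fraction = 0.05, tail_length = 20,
                               let_entrance = 13, let_peak = 80,
                               let_shape_q = 3) {
  chk_num(entrance_ratio, "entrance_ratio", 1, lower = 0, strict = TRUE)
  if (entrance_ratio >= 1 / 1.15)
    stopf("entrance_ratio must be < 1/1.15 for the plateau normalization")
  chk_num(peak_sigma, "peak_sigma", 1, lower = 0, strict = TRUE)
  chk_num(tail_fraction, "tail_fraction", 1, lower = 0)
  if (tail_fraction >= entrance_ratio)
    stopf("tail_fraction must be < entrance_ratio")
  chk_num(tail_length, "tail_length", 1, lower = 0, strict = TRUE)
  chk_num(let_entrance, "let_entrance", 1, lower = 0, strict = TRUE)
  chk_num(let_peak, "let_peak", 1, lower = let_entrance, strict = TRUE)
  chk_num(let_shape_q, "let_shape_q", 1, lower = 0, strict = TRUE)
  structure(list(entrance_ratio = entrance_ratio, peak_sigma = peak_sigma,
                 tail_fraction = tail_fraction, tail_length = tail_length,
                 let_entrance = let_entrance, let_peak = let_peak,
                 let_shape_q = let_shape_q),
            class = "depth_curve_params")
}

#' Analytic depth-dose of a carbon pencil beam
#'
#' Dose per unit fluence weight on the central axis at water-equivalent depth
#' `z` for a beamlet with Bragg-peak depth `R`. The global maximum is at
#' `z = R` with value 1; for `R` much larger than `peak_sigma` the entrance
#' value is `entrance_ratio`.
#'
#' @param z depth(s), mm, >= 0 (vectorized).
#' @param R Bragg-peak depth (range), mm, > 0.
#' @param params a [depth_curve_params] object.
#' @return numeric vector of doses (Gy per unit weight).
#' @export
depth_dose <- function(z, R, params) {
  chk_num(z, "z", lower = 0)
  chk_num(R, "R", 1, lower = 0, strict = TRUE)
  stopifnot(inherits(params, "depth_curve_params"))
  er <- params$entrance_ratio; sp <- params$peak_sigma
  tf <- params$tail_fraction; tl <- params$tail_length
  bg <- 1 - 1.15 * er          # Gaussian amplitude so that peak value is 1
  zp <- max(R - 2 * sp, 1e-9)  # plateau rises 15% from z = 0 to z = R - 2*sigma
  d <- numeric(length(z))
  pre <- z <= R
  if (any(pre)) {
    s <- pmin(z[pre], zp) / zp
    d[pre] <- bg * exp(-(z[pre] - R)^2 / (2 * sp^2)) + er * (1 + 0.15 * s)
  }
  if (any(!pre)) {
    dz <- z[!pre] - R
    d[!pre] <- (1 - tf) * exp(-dz^2 / (2 * sp^2)) + tf * exp(-dz / tl)
  }
  d
}

#' Analytic dose-averaged LET of a carbon pencil beam
#'
#' Monotone nondecreasing on `[0, R]` from `let_entrance` to `let_peak`,
#' then linear decay back to `let_entrance` over `tail_length`.
#'
#' @inheritParams depth_dose
#' @return numeric vector of LET values (keV/um).
#' @export
dose_averaged_let <- function(z, R, params) {
  chk_num(z, "z", lower = 0)
  chk_num(R, "R", 1, lower = 0, strict = TRUE)
  stopifnot(inherits(params, "depth_curve_params"))
  le <- params$let_entrance; lp <- params$let_peak
  q <- params$let_shape_q; tl <- params$tail_length
  out <- numeric(length(z))
  pre <- z <= R
  out[pre] <- le + (lp - le) * (z[pre] / R)^q
  tail <- !pre & z <= R + tl
  out[tail] <- lp - (lp - le) * (z[tail] - R) / tl
  out[z > R + tl] <- le
  out
}

#' Define a scanned beam
#'
#' Beams are restricted to axis-aligned directions; e.g. `"+x"` enters through
#' the grid face at minimum x, `"-x"` through the face at maximum x.
#'
#' @param direction one of `"+x"`, `"-x"`, `"+y"`, `"-y"`, `"+z"`, `"-z"`, or
#'   an axis-aligned unit vector such as `c(0, -1, 0)`.
#' @param spot_spacing lateral lattice pitch, mm.
#' @param layer_spacing range step between energy layers, mm (water-equivalent).
#' @param sigma_lateral Gaussian lateral spread at depth 0, mm. The spread
#'   grows with depth as `sigma_lateral * (1 + 0.5 * z / R)`.
#' @return object of class `beam_spec`.
#' @export
beam_spec <- function(direction, spot_spacing, layer_spacing, sigma_lateral) {
  if (is.character(direction)) {
    m <- regmatches(direction, regexec("^([+-])([xyz])$", direction))[[1]]
    if (length(m) != 3L) stopf("beam direction '%s' is not axis-aligned", direction)
    axis <- match(m[3], c("x", "y", "z"))
    sign <- if (m[2] == "+") 1L else -1L
  } else {
    v <- chk_num(direction, "direction", len = 3)
    nz <- which(abs(v) > 1e-12)
    if (length(nz) != 1L || abs(abs(v[nz]) - 1) > 1e-9)
      stopf("beam direction must be an axis-aligned unit vector")
    axis <- nz; sign <- if (v[nz] > 0) 1L else -1L
  }
  chk_num(spot_spacing, "spot_spacing", 1, lower = 0, strict = TRUE)
  chk_num(layer_spacing, "layer_spacing", 1, lower = 0, strict = TRUE)
  chk_num(sigma_lateral, "sigma_lateral", 1, lower = 0, strict = TRUE)
  structure(list(axis = axis, sign = sign, spot_spacing = spot_spacing,
                 layer_spacing = layer_spacing, sigma_lateral = sigma_lateral),
            class = "beam_spec")
}

# depth of coordinates `coord` (along beam axis) from the beam's entry face
beam_depth <- function(coord, beam, grid) {
  if (beam$sign > 0) coord - grid$origin[beam$axis]
  else grid$origin[beam$axis] + grid_extent(grid)[beam$axis] - coord
}

#' Build the spot (beamlet) list for a beam covering a target
#'
#' Places a rectangular lateral lattice of pitch `spot_spacing` centered on
#' the target's projected footprint, keeping spots whose central axis passes
#' within `margin` (plus half a voxel) of the CTV, and energy layers covering
#' the CTV depth extent expanded by `margin` at `layer_spacing` steps.
#'
#' @param beam a [beam_spec] (must be axis-aligned).
#' @param ctv a target [roi_mask] or logical mask vector; must be non-empty.
#' @param grid the [voxel_grid].
#' @param margin lateral and range margin, mm (>= 0).
#' @param beam_index integer tag stored with each beamlet.
#' @return a data.frame of class `spot_list`, one row per beamlet with columns
#'   `beam_index`, `u`, `v` (lateral position, mm), `range` (Bragg-peak depth,
#'   mm), plus the beam geometry (`axis`, `sign`, `u_axis`, `v_axis`,
#'   `sigma0`).
#' @export
build_spot_list <- function(beam, ctv, grid, margin = 0, beam_index = 1L) {
  stopifnot(inherits(beam, "beam_spec"))
  mask <- if (inherits(ctv, "roi_mask")) ctv$mask else ctv
  mask <- chk_flag_mask(mask, n_voxels(grid), "ctv")
  if (!any(mask)) stopf("CTV mask is empty")
  chk_num(margin, "margin", 1, lower = 0)

  idx <- arrayInd(which(mask), grid$dims)
  ax <- beam$axis
  lat <- setdiff(1:3, ax)
  ua <- lat[1]; va <- lat[2]
  cu <- axis_centers(grid, ua)[idx[, ua]]
  cv <- axis_centers(grid, va)[idx[, va]]
  cz <- beam_depth(axis_centers(grid, ax)[idx[, ax]], beam, grid)

  # energy layers span the geometric depth extent (voxel faces) plus margin
  half <- grid$spacing[ax] / 2
  proximal <- min(cz) - half
  distal <- max(cz) + half
  nl <- ceiling(round((distal - proximal + 2 * margin) / beam$layer_spacing, 9)) + 1
  ranges <- proximal - margin + (seq_len(nl) - 1) * beam$layer_spacing
  ranges <- ranges[ranges > 1e-9]
  if (!length(ranges)) stopf("no energy layer lies inside the phantom")

  # lateral lattice centered on the footprint midpoint (mirror-symmetric)
  lattice_1d <- function(cc, pitch) {
    mid <- (min(cc) + max(cc)) / 2
    k <- ceiling(round((max(cc) + margin - mid) / pitch, 9))
    mid + (-k:k) * pitch
  }
  us <- lattice_1d(cu, beam$spot_spacing)
  vs <- lattice_1d(cv, beam$spot_spacing)

  # keep lattice points within margin (per-axis, plus half voxel) of any
  # projected CTV voxel center
  fp <- unique(cbind(cu, cv))
  tu <- margin + grid$spacing[ua] / 2 + 1e-9
  tv <- margin + grid$spacing[va] / 2 + 1e-9
  near_u <- abs(outer(us, fp[, 1], "-")) <= tu
  near_v <- abs(outer(vs, fp[, 2], "-")) <= tv
  keep <- (near_u %*% t(near_v)) > 0   # [u, v]: any footprint point near both

  uv <- which(keep, arr.ind = TRUE)
  uv <- uv[order(uv[, 1], uv[, 2]), , drop = FALSE]
  spots <- expand.grid(k = seq_along(ranges), p = seq_len(nrow(uv)))
  out <- data.frame(
    beam_index = as.integer(beam_index),
    u = us[uv[spots$p, 1]],
    v = vs[uv[spots$p, 2]],
    range = ranges[spots$k],
    axis = ax, sign = beam$sign, u_axis = ua, v_axis = va,
    sigma0 = beam$sigma_lateral
  )
  class(out) <- c("spot_list", "data.frame")
  out
}

# lateral cutoff radius: 3*sigma or the 1e-4 relative-dose radius,
# whichever is larger (the latter, sqrt(2*log(1e4)) ~ 4.29 sigma, wins)
LATERAL_CUT_SIGMA <- sqrt(2 * log(1e4))
KERNEL_REL_FLOOR <- 1e-7

#' Sparse per-voxel dose kernel of one beamlet
#'
#' Pencil-beam kernel: central-axis depth-dose times a normalized 2-D lateral
#' Gaussian whose spread grows with depth, integrated per voxel cross-section
#' (midpoint rule). Entries beyond the lateral cutoff radius (the larger of
#' 3 sigma and the 1e-4 relative-dose radius) or below a small relative floor
#' are dropped; all retained entries are positive.
#'
#' @param b one beamlet: a single-row `spot_list` (or list with fields `u`,
#'   `v`, `range`, `axis`, `sign`, `u_axis`, `v_axis`, `sigma0`).
#' @param grid the [voxel_grid].
#' @param params a [depth_curve_params].
#' @return list with `idx` (linear voxel indices, sorted), `dose` (Gy per unit
#'   weight) and `let` (keV/um at each entry's depth).
#' @export
beamlet_dose_kernel <- function(b, grid, params) {
  if (is.data.frame(b)) b <- as.list(b[1, ])
  R <- b$range
  ax <- b$axis
  extent <- grid_extent(grid)[ax]
  if (R > extent + 1e-9) stopf("beamlet range %.1f mm beyond grid extent %.1f mm", R, extent)
  if (R <= 0) stopf("beamlet range must be > 0")

  z <- beam_depth(axis_centers(grid, ax), b, grid)   # one depth per slice
  ord <- order(z)                                    # entry-face first
  dose_z <- depth_dose(pmax(z, 0), R, params)
  let_z <- dose_averaged_let(pmax(z, 0), R, params)
  sig_z <- b$sigma0 * (1 + 0.5 * z / R)
  rcut <- LATERAL_CUT_SIGMA * sig_z

  du <- axis_centers(grid, b$u_axis) - b$u
  dv <- axis_centers(grid, b$v_axis) - b$v
  area <- grid$spacing[b$u_axis] * grid$spacing[b$v_axis]
  nd <- grid$dims

  ii <- vector("list", length(z)); vv <- ii; ll <- ii
  for (k in ord) {
    if (dose_z[k] <= 0) next
    iu <- which(abs(du) <= rcut[k]); if (!length(iu)) next
    iv <- which(abs(dv) <= rcut[k]); if (!length(iv)) next
    s2 <- 2 * sig_z[k]^2
    gu <- exp(-du[iu]^2 / s2)
    gv <- exp(-dv[iv]^2 / s2)
    val <- (dose_z[k] * area / (pi * s2)) * outer(gu, gv)
    sel <- outer(du[iu]^2, dv[iv]^2, "+") <= rcut[k]^2
    if (!any(sel)) next
    Iu <- rep(iu, times = length(iv))[sel]
    Iv <- rep(iv, each = length(iu))[sel]
    pos <- matrix(0L, nrow = length(Iu), ncol = 3)
    pos[, ax] <- k; pos[, b$u_axis] <- Iu; pos[, b$v_axis] <- Iv
    lin <- pos[, 1] + nd[1] * (pos[, 2] - 1L) + nd[1] * nd[2] * (pos[, 3] - 1L)
    ii[[k]] <- lin
    vv[[k]] <- val[sel]
    ll[[k]] <- rep(let_z[k], length(lin))
  }
  idx <- unlist(ii, use.names = FALSE)
  if (is.null(idx) || !length(idx))
    return(list(idx = integer(0), dose = numeric(0), let = numeric(0)))
  dose <- unlist(vv, use.names = FALSE)
  let <- unlist(ll, use.names = FALSE)
  keep <- dose >= KERNEL_REL_FLOOR * max(dose)
  o <- order(idx[keep])
  list(idx = idx[keep][o], dose = dose[keep][o], let = let[keep][o])
}
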