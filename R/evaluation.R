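# dose vector extraction: accept rbe_dose or numeric
roi_doses <- function(dose, mask = NULL) {
  v <- if (inherits(dose, "rbe_dose")) dose$values else dose
  if (!is.null(mask)) {
    if (inherits(mask, "roi_mask")) mask <- mask$mask
    v <- v[mask]
  }
  v
}

#' Dose received by at least x% of an ROI (D_x%)
#'
#' Discrete (non-interpolated) convention: sort descending and return the
#' `ceil(x/100 * n)`-th hottest voxel's dose, i.e. the largest dose such that
#' at least x% of the ROI receives at least that dose.
#'
#' @param doses dose values of the ROI voxels (non-empty), or an [rbe_dose]
#'   combined with `mask`.
#' @param x volume percentage in (0, 100].
#' @param mask optional [roi_mask] or logical vector selecting the ROI.
#' @return dose, Gy(RBE).
#' @export
dose_at_volume <- function(doses, x, mask = NULL) {
  v <- roi_doses(doses, mask)
  if (!length(v)) stopf("empty ROI")
  chk_num(x, "x", 1, lower = 0, upper = 100, strict = TRUE)
  s <- sort(v, decreasing = TRUE)
  s[max(1L, ceiling(x / 100 * length(s) - 1e-9))]
}

#' Dose exceeded by the hottest v cc of an ROI (e.g. D_2cc)
#'
#' Returns the `ceil(v / voxel_volume)`-th hottest voxel's dose; partial-voxel
#' interpolation is not applied.
#'
#' @inheritParams dose_at_volume
#' @param voxel_volume voxel volume in cc.
#' @param v absolute volume in cc, `0 < v <=` ROI volume.
#' @return dose, Gy(RBE).
#' @export
dose_at_absolute_volume <- function(doses, voxel_volume, v, mask = NULL) {
  w <- roi_doses(doses, mask)
  if (!length(w)) stopf("empty ROI")
  chk_num(voxel_volume, "voxel_volume", 1, lower = 0, strict = TRUE)
  chk_num(v, "v", 1, lower = 0, strict = TRUE)
  k <- max(1L, ceiling(v / voxel_volume - 1e-9))
  if (k > length(w))
    stopf("ROI volume %.2f cc is smaller than requested %.2f cc",
          length(w) * voxel_volume, v)
  sort(w, decreasing = TRUE)[k]
}

#' Percentage of an ROI receiving at least a dose level (V_D)
#'
#' @inheritParams dose_at_volume
#' @param level dose level, Gy(RBE).
#' @return volume percentage in `[0, 100]`.
#' @export
volume_at_dose <- function(doses, level, mask = NULL) {
  v <- roi_doses(doses, mask)
  if (!length(v)) stopf("empty ROI")
  chk_num(level, "level", 1, lower = 0)
  100 * mean(v >= level)
}

#' Homogeneity index of a dose distribution on an ROI
#'
#' `HI [%] = 100 * (D_2% - D_98%) / D_50%`; lower is more homogeneous, with
#' about 17% as the usual clinical acceptability bound. Invariant under
#' positive scaling of the doses.
#'
#' @inheritParams dose_at_volume
#' @return HI in percent.
#' @export
homogeneity_index <- function(doses, mask = NULL) {
  v <- roi_doses(doses, mask)
  if (!length(v)) stopf("empty ROI")
  d50 <- dose_at_volume(v, 50)
  if (d50 <= 0) stopf("median ROI dose is zero; HI undefined")
  100 * (dose_at_volume(v, 2) - dose_at_volume(v, 98)) / d50
}

#' Cumulative dose-volume histogram of an ROI
#'
#' @inheritParams dose_at_volume
#' @param bin_width dose bin width, Gy(RBE).
#' @param roi,model labels stored with the curve.
#' @return object of class `dvh_curve` with `dose` (bin edges) and `volume`
#'   (% of ROI receiving at least that dose; monotone nonincreasing, 100% at
#'   dose 0, 0% above the maximum).
#' @export
dvh_curve <- function(doses, bin_width = 0.5, mask = NULL,
                      roi = "", model = "") {
  v <- roi_doses(doses, mask)
  if (!length(v)) stopf("empty ROI")
  chk_num(bin_width, "bin_width", 1, lower = 0, strict = TRUE)
  edges <- seq(0, max(v) + bin_width, by = bin_width)
  vol <- vapply(edges, function(e) 100 * mean(v >= e), numeric(1))
  structure(list(dose = edges, volume = vol, roi = roi, model = model),
            class = "dvh_curve")
}

#' @export
plot.dvh_curve <- function(x, add = FALSE, col = 1, lty = 1, ...) {
  if (!add) {
    graphics::plot(x$dose, x$volume, type = "s", col = col, lty = lty,
                   xlab = "Dose [Gy(RBE)]", ylab = "Volume [%]",
                   ylim = c(0, 100), ...)
  } else {
    graphics::lines(x$dose, x$volume, type = "s", col = col, lty = lty, ...)
  }
  invisible(x)
}

#' Median-dose scaling factor between two models (F_scal)
#'
#' Ratio of the CTV median doses `D_50%` of the same plan expressed in two
#' RBE models; the theoretical LEM-I/NIRS-MKM value is about 1.153.
#'
#' @param dose_a,dose_b per-voxel doses ([rbe_dose] or numeric) for the two
#'   models on the same grid.
#' @param mask ROI ([roi_mask] or logical) over which medians are taken.
#' @return dimensionless ratio `D_50%(a) / D_50%(b)`.
#' @export
f_scal <- function(dose_a, dose_b, mask = NULL) {
  num <- dose_at_volume(roi_doses(dose_a, mask), 50)
  den <- dose_at_volume(roi_doses(dose_b, mask), 50)
  if (den == 0) stopf("median dose of the denominator model is zero")
  num / den
}

#' Voxelwise difference or ratio map between two dose distributions
#'
#' @param grid_a,grid_b [rbe_dose] objects (or numeric vectors of equal
#'   length) on the same geometry.
#' @param mode `"difference"` (`a - b`) or `"ratio"` (`a / b` where
#'   `b > floor`, `NA` elsewhere).
#' @param floor dose floor below which the ratio is flagged undefined
#'   (default 1% of the maximum of `b`).
#' @return numeric per-voxel map (`NA` marks undefined ratio voxels).
#' @export
dose_comparison_map <- function(grid_a, grid_b,
                                mode = c("difference", "ratio"),
                                floor = NULL) {
  mode <- match.arg(mode)
  if (inherits(grid_a, "rbe_dose") && inherits(grid_b, "rbe_dose") &&
      !identical(grid_a$grid, grid_b$grid))
    stopf("dose grids have mismatched geometry")
  a <- roi_doses(grid_a); b <- roi_doses(grid_b)
  if (length(a) != length(b)) stopf("dose grids have mismatched geometry")
  if (mode == "difference") return(a - b)
  floor <- floor %||% (0.01 * max(b))
  out <- rep(NA_real_, length(a))
  ok <- b > floor
  out[ok] <- a[ok] / b[ok]
  out
}

#' Define a clinical goal
#'
#' @param roi,model labels the goal refers to.
#' @param metric one of `"V"` (% volume at `level`), `"D_pct"` (dose at
#'   `volume` % of the ROI), `"D_cc"` (dose at `volume` cc), `"HI"`,
#'   `"mean"`.
#' @param limit the threshold the achieved value is compared against.
#' @param cmp comparator, `">="` or `"<="`; comparisons are inclusive
#'   (equality passes).
#' @param level dose level for `"V"`, Gy(RBE).
#' @param volume volume parameter for `"D_pct"` (%) or `"D_cc"` (cc).
#' @return object of class `clinical_goal`.
#' @export
clinical_goal <- function(roi, model, metric = c("V", "D_pct", "D_cc", "HI", "mean"),
                          limit, cmp = c(">=", "<="), level = NULL,
                          volume = NULL) {
  metric <- match.arg(metric)
  cmp <- match.arg(cmp)
  chk_num(limit, "limit", 1, lower = 0)
  if (metric == "V") chk_num(level, "level", 1, lower = 0)
  if (metric %in% c("D_pct", "D_cc")) chk_num(volume, "volume", 1, lower = 0, strict = TRUE)
  structure(list(roi = roi, model = model, metric = metric, limit = limit,
                 cmp = cmp, level = level, volume = volume),
            class = "clinical_goal")
}

goal_label <- function(g) {
  switch(g$metric,
         V = sprintf("V_%.4g [%%] %s %.4g", g$level, g$cmp, g$limit),
         D_pct = sprintf("D_%.4g%% %s %.4g", g$volume, g$cmp, g$limit),
         D_cc = sprintf("D_%.4gcc %s %.4g", g$volume, g$cmp, g$limit),
         HI = sprintf("HI [%%] %s %.4g", g$cmp, g$limit),
         mean = sprintf("mean %s %.4g", g$cmp, g$limit))
}

eval_goal_metric <- function(g, doses, voxel_volume) {
  switch(g$metric,
         V = volume_at_dose(doses, g$level),
         D_pct = dose_at_volume(doses, g$volume),
         D_cc = dose_at_absolute_volume(doses, voxel_volume, g$volume),
         HI = homogeneity_index(doses),
         mean = mean(doses))
}

#' Check clinical goals against per-model dose distributions
#'
#' Evaluates each goal on the corresponding (roi, model) dose values and
#' compares inclusively against its threshold (achieving exactly the
#' threshold passes). An empty goal list yields a vacuous overall pass.
#'
#' @param doses named list (by model label) of [rbe_dose] objects (or numeric
#'   per-voxel vectors).
#' @param rois named list of [roi_mask] objects.
#' @param goals list of [clinical_goal] objects.
#' @param grid optional [voxel_grid] (needed for `"D_cc"` goals when `doses`
#'   are plain vectors).
#' @return data.frame of class `goal_table`, one row per goal with the
#'   achieved value, threshold and pass flag; attribute `verdict` is the
#'   all-pass overall plan verdict.
#' @export
check_goals <- function(doses, rois, goals, grid = NULL) {
  if (!length(goals)) {
    out <- data.frame(roi = character(0), model = character(0),
                      goal = character(0), achieved = numeric(0),
                      threshold = numeric(0), cmp = character(0),
                      pass = logical(0))
    attr(out, "verdict") <- TRUE
    class(out) <- c("goal_table", "data.frame")
    return(out)
  }
  grid <- grid %||% (if (inherits(doses[[1]], "rbe_dose")) doses[[1]]$grid)
  vv <- if (!is.null(grid)) voxel_volume_cc(grid) else NA_real_
  rows <- lapply(goals, function(g) {
    if (!g$model %in% names(doses))
      stopf("no dose distribution for model '%s' in the report", g$model)
    if (!g$roi %in% names(rois)) stopf("unknown ROI '%s' in goal", g$roi)
    v <- roi_doses(doses[[g$model]], rois[[g$roi]])
    ach <- eval_goal_metric(g, v, vv)
    pass <- if (g$cmp == ">=") ach >= g$limit else ach <= g$limit
    data.frame(roi = g$roi, model = g$model, goal = goal_label(g),
               achieved = ach, threshold = g$limit, cmp = g$cmp, pass = pass)
  })
  out <- do.call(rbind, rows)
  attr(out, "verdict") <- all(out$pass)
  class(out) <- c("goal_table", "data.frame")
  out
}

#' @export
print.goal_table <- function(x, ...) {
  df <- as.data.frame(x)
  if (nrow(df)) df$mark <- ifelse(df$pass, "ok", "X")
  print.data.frame(df, row.names = FALSE, digits = 4)
  cat(sprintf("overall verdict: %s\n",
              if (isTRUE(attr(x, "verdict"))) "all goals met" else "goals violated"))
  invisible(x)
}

#' Standard DVH metric report for a set of ROIs and models
#'
#' Computes `D_50%`, `D_98%`, `D_2%`, `D_2cc` (where the ROI holds at least
#' 2 cc), arithmetic mean dose and homogeneity index for every (roi, model)
#' combination.
#'
#' @inheritParams check_goals
#' @return data.frame with one row per (roi, model).
#' @export
metric_report <- function(doses, rois, grid = NULL) {
  grid <- grid %||% (if (inherits(doses[[1]], "rbe_dose")) doses[[1]]$grid)
  vv <- if (!is.null(grid)) voxel_volume_cc(grid) else NA_real_
  rows <- list()
  for (rn in names(rois)) for (mn in names(doses)) {
    v <- roi_doses(doses[[mn]], rois[[rn]])
    d50 <- dose_at_volume(v, 50)
    rows[[length(rows) + 1L]] <- data.frame(
      roi = rn, model = mn,
      D50 = d50, D98 = dose_at_volume(v, 98), D2 = dose_at_volume(v, 2),
      D2cc = if (!is.na(vv) && length(v) * vv >= 2)
        dose_at_absolute_volume(v, vv, 2) else NA_real_,
      mean = mean(v),
      HI = if (d50 > 0) homogeneity_index(v) else NA_real_)
  }
  do.call(rbind, rows)
}
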