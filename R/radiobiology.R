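#' Photon reference linear-quadratic parameters
#'
#' @param alpha_x photon alpha, 1/Gy (> 0).
#' @param beta_x photon beta, 1/Gy^2 (>= 0).
#' @return object of class `photon_lq`.
#' @export
photon_lq <- function(alpha_x, beta_x) {
  chk_num(alpha_x, "alpha_x", 1, lower = 0, strict = TRUE)
  chk_num(beta_x, "beta_x", 1, lower = 0)
  structure(list(alpha_x = alpha_x, beta_x = beta_x), class = "photon_lq")
}

#' Define an RBE model from alpha/beta-vs-LET tables
#'
#' A named radiobiological model: photon LQ reference, monotone LET grid with
#' per-LET ion `alpha` and `beta` values, and a clinical scaling factor
#' applied after RBE-weighted dose (1 for models reporting plain
#' photon-equivalent dose; != 1 for NIRS-style clinical dose).
#'
#' @param name model label, e.g. `"LEMlike"`.
#' @param photon a [photon_lq].
#' @param let strictly increasing LET grid, keV/um.
#' @param alpha,beta ion LQ coefficients on the `let` grid (>= 0).
#' @param clinical_scale dimensionless factor (> 0).
#' @return object of class `rbe_model`.
#' @export
rbe_model <- function(name, photon, let, alpha, beta, clinical_scale = 1) {
  stopifnot(is.character(name), length(name) == 1L, inherits(photon, "photon_lq"))
  let <- chk_num(let, "let", lower = 0)
  if (length(let) < 1L) stopf("model '%s': empty LET table", name)
  if (is.unsorted(let, strictly = TRUE))
    stopf("model '%s': LET grid must be strictly increasing", name)
  alpha <- chk_num(alpha, "alpha", len = length(let), lower = 0)
  beta <- chk_num(beta, "beta", len = length(let), lower = 0)
  chk_num(clinical_scale, "clinical_scale", 1, lower = 0, strict = TRUE)
  structure(list(name = name, photon = photon, let = let, alpha = alpha,
                 beta = beta, clinical_scale = clinical_scale),
            class = "rbe_model")
}

#' @export
print.rbe_model <- function(x, ...) {
  cat(sprintf(
    "rbe_model '%s': %d LET nodes [%g, %g] keV/um, alpha_x = %g, beta_x = %g, clinical scale = %g\n",
    x$name, length(x$let), min(x$let), max(x$let),
    x$photon$alpha_x, x$photon$beta_x, x$clinical_scale))
  invisible(x)
}

#' Look up model alpha/beta at given LET values
#'
#' Linear interpolation on the model's LET grid, clamped to the end values
#' outside the grid.
#'
#' @param model an [rbe_model].
#' @param let LET value(s), keV/um, >= 0 (vectorized).
#' @return list with numeric vectors `alpha` (1/Gy) and `beta` (1/Gy^2).
#' @export
model_alpha_beta <- function(model, let) {
  stopifnot(inherits(model, "rbe_model"))
  let <- chk_num(let, "let", lower = 0)
  if (length(model$let) == 1L) {
    return(list(alpha = rep(model$alpha, length(let)),
                beta = rep(model$beta, length(let))))
  }
  list(alpha = stats::approx(model$let, model$alpha, xout = let, rule = 2)$y,
       beta = stats::approx(model$let, model$beta, xout = let, rule = 2)$y)
}

#' Mixed-field linear-quadratic state of a plan
#'
#' Accumulates the mixed radiation field produced by all beamlets under the
#' dose-weighted-alpha / dose-weighted-sqrt(beta) mixing rule: per voxel i,
#' `D_i = sum_j w_j d_ij`, `A_i = sum_j w_j alpha_ij d_ij`,
#' `B_i = sum_j w_j sqrt(beta_ij) d_ij`, and biological effect
#' `E_i = A_i + B_i^2` (the per-fraction -ln survival). The mixed-field
#' coefficients follow as `alpha_mix = A/D` and `sqrt(beta)_mix = B/D`.
#'
#' @param weights nonnegative beamlet fluence weights (per fraction).
#' @param infl an [influence_set].
#' @param model model label registered in `infl`.
#' @return object of class `mixed_field` with per-voxel vectors `D`, `A`,
#'   `B`, `E` and the model label.
#' @export
mixed_field_effect <- function(weights, infl, model) {
  stopifnot(inherits(infl, "influence_set"))
  weights <- chk_num(weights, "weights", len = ncol(infl$d))
  if (any(weights < 0)) stopf("beamlet weights must be nonnegative")
  if (!model %in% names(infl$a))
    stopf("model '%s' is not registered in the influence set", model)
  D <- as.numeric(infl$d %*% weights)
  A <- as.numeric(infl$a[[model]] %*% weights)
  B <- as.numeric(infl$b[[model]] %*% weights)
  structure(list(D = D, A = A, B = B, E = A + B^2, model = model),
            class = "mixed_field")
}

#' RBE-weighted (photon-equivalent) dose from biological effect
#'
#' Inverts the photon LQ curve: `D_RBE` solves
#' `alpha_x * D + beta_x * D^2 = E`, i.e.
#' `D_RBE = (sqrt(alpha_x^2 + 4 beta_x E) - alpha_x) / (2 beta_x)`
#' (`E / alpha_x` when `beta_x = 0`). Strictly increasing in `E`.
#'
#' @param effect nonnegative per-voxel biological effect, or a
#'   [mixed_field_effect] result (its `E` is used).
#' @param photon a [photon_lq]; `alpha_x` must be > 0.
#' @return numeric vector of RBE-weighted doses, Gy(RBE).
#' @export
rbe_weighted_dose <- function(effect, photon) {
  if (inherits(effect, "mixed_field")) effect <- effect$E
  effect <- chk_num(effect, "effect", lower = 0)
  if (!inherits(photon, "photon_lq")) stopf("'photon' must be a photon_lq object")
  ax <- photon$alpha_x; bx <- photon$beta_x
  if (ax <= 0) stopf("alpha_x must be > 0")
  if (bx == 0) effect / ax
  else (sqrt(ax^2 + 4 * bx * effect) - ax) / (2 * bx)
}

#' Container for an RBE-weighted dose distribution
#'
#' @param values nonnegative per-voxel doses, Gy(RBE).
#' @param grid the [voxel_grid].
#' @param model model label the dose is expressed in.
#' @param fractions fraction count the values correspond to.
#' @param per_fraction logical; `TRUE` if `values` are per fraction.
#' @param unit unit tag, e.g. `"Gy(RBE)[LEMlike]"`.
#' @return object of class `rbe_dose`.
#' @export
rbe_dose <- function(values, grid, model, fractions = 1L,
                     per_fraction = FALSE, unit = NULL) {
  values <- chk_num(values, "values", len = n_voxels(grid), lower = 0)
  structure(list(values = values, grid = grid, model = model,
                 fractions = as.integer(fractions),
                 per_fraction = isTRUE(per_fraction),
                 unit = unit %||% sprintf("Gy(RBE)[%s]", model)),
            class = "rbe_dose")
}

#' @export
print.rbe_dose <- function(x, ...) {
  cat(sprintf("rbe_dose [%s], %s, %d fraction(s): max %.2f, mean %.2f %s\n",
              x$model, if (x$per_fraction) "per fraction" else "total",
              x$fractions, max(x$values), mean(x$values), x$unit))
  invisible(x)
}

#' Apply a model's clinical scaling factor to an RBE-weighted dose
#'
#' Multiplies every voxel by `model$clinical_scale` and retags the unit
#' (NIRS-style clinical dose when the scale differs from 1).
#'
#' @param d an [rbe_dose].
#' @param model an [rbe_model] with `clinical_scale > 0`.
#' @return an [rbe_dose] on the clinical scale.
#' @export
clinical_dose <- function(d, model) {
  stopifnot(inherits(d, "rbe_dose"), inherits(model, "rbe_model"))
  unit <- if (model$clinical_scale == 1) d$unit
          else sprintf("Gy(RBE)[%s,clinical]", model$name)
  rbe_dose(d$values * model$clinical_scale, d$grid, d$model,
           fractions = d$fractions, per_fraction = d$per_fraction, unit = unit)
}

#' Convert a prescription dose between RBE-model unit systems
#'
#' Multiplies a prescription by a model-to-model scaling factor and rounds to
#' the prescription reporting precision (2 decimals by default); e.g. a
#' 3.60 Gy(RBE) per-fraction prescription with factor 1.153 converts to
#' 4.15 Gy(RBE).
#'
#' @param dose prescription dose, Gy(RBE), >= 0.
#' @param factor dimensionless conversion factor, > 0.
#' @param digits reporting precision (decimals).
#' @return converted (rounded) prescription dose.
#' @export
prescription_convert <- function(dose, factor, digits = 2) {
  dose <- chk_num(dose, "dose", lower = 0)
  chk_num(factor, "factor", 1)
  if (factor <= 0) stopf("conversion factor must be > 0")
  round(dose * factor, digits)
}

#' Recalculate a plan's dose distribution under a given RBE model
#'
#' Computes the per-fraction mixed-field effect from the (per-fraction)
#' beamlet weights, inverts it to photon-equivalent dose, and scales by the
#' fraction count and the model's clinical factor. Deterministic.
#'
#' @param weights nonnegative per-fraction beamlet weights.
#' @param infl an [influence_set] with the model registered.
#' @param model an [rbe_model].
#' @param fractions number of fractions (>= 1).
#' @return an [rbe_dose] with the total RBE-weighted dose.
#' @export
recalc_plan <- function(weights, infl, model, fractions = 1L) {
  stopifnot(inherits(model, "rbe_model"))
  fractions <- as.integer(chk_num(fractions, "fractions", 1, lower = 1))
  mf <- mixed_field_effect(weights, infl, model$name)
  d_fx <- rbe_weighted_dose(mf, model$photon)
  unit <- if (model$clinical_scale == 1) NULL
          else sprintf("Gy(RBE)[%s,clinical]", model$name)
  rbe_dose(d_fx * fractions * model$clinical_scale, infl$grid, model$name,
           fractions = fractions, per_fraction = FALSE, unit = unit)
}
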