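#' Fit a treatment plan: optimize beamlet fluence weights
#'
#' The central fitting function of the package. Solves the fluence
#' optimization problem with the projected-gradient solver and recalculates
#' the resulting plan under every RBE model registered in the influence set
#' (the cross-model audit: a plan optimized in one model is always
#' reported in all of them).
#'
#' @param problem a [plan_problem] (typically from [make_scenario()]).
#' @param settings a [solver_settings].
#' @return object of class `ion_plan` with components `weights`, `report`
#'   (a `solve_report`), `doses` (named list of [rbe_dose], one per model),
#'   `problem` and `fractions`. Supported methods: `print`, `summary`,
#'   `coef` (the weights), `predict` (dose under a chosen model), `plot`
#'   (DVH curves), `residuals` (target dose minus prescription).
#' @export
plan_optimize <- function(problem, settings = solver_settings()) {
  stopifnot(inherits(problem, "plan_problem"))
  sol <- solve_fluence(problem, settings)
  doses <- lapply(problem$infl$models, function(m)
    recalc_plan(sol$weights, problem$infl, m, problem$fractions))
  names(doses) <- names(problem$infl$models)
  structure(list(weights = sol$weights, report = sol$report, doses = doses,
                 problem = problem, fractions = problem$fractions),
            class = "ion_plan")
}

#' @export
print.ion_plan <- function(x, ...) {
  cat(sprintf("ion_plan: %d beamlets, %d fractions, models: %s\n",
              length(x$weights), x$fractions,
              paste(names(x$doses), collapse = ", ")))
  print(x$report)
  invisible(x)
}

#' @export
coef.ion_plan <- function(object, ...) object$weights

#' @param model model label; default the first registered model.
#' @rdname plan_optimize
#' @export
predict.ion_plan <- function(object, model = names(object$doses)[1], ...) {
  if (!model %in% names(object$doses))
    stopf("model '%s' not recalculated for this plan", model)
  object$doses[[model]]
}

#' @export
summary.ion_plan <- function(object, ...) {
  rois <- object$problem$rois
  rois <- rois[vapply(rois, `[[`, "", "role") != "external"]
  out <- list(report = object$report,
              metrics = metric_report(object$doses, rois),
              n_beamlets = length(object$weights))
  class(out) <- "summary.ion_plan"
  out
}

#' @export
print.summary.ion_plan <- function(x, ...) {
  print(x$report)
  cat("\nDVH metrics [total Gy(RBE), HI in %]:\n")
  print(x$metrics, row.names = FALSE, digits = 4)
  invisible(x)
}

#' @export
residuals.ion_plan <- function(object, ...) {
  roles <- vapply(object$problem$rois, `[[`, "", "role")
  res <- list()
  for (t in object$problem$terms) {
    if (roles[[t$roi]] != "target" || t$kind != "uniform") next
    v <- object$doses[[t$model]]$values[object$problem$rois[[t$roi]]$mask]
    res[[paste(t$roi, t$model, sep = ".")]] <- v - t$dose_level
  }
  res
}

#' @export
plot.ion_plan <- function(x, rois = NULL, bin_width = 0.5, ...) {
  masks <- x$problem$rois
  masks <- masks[vapply(masks, `[[`, "", "role") != "external"]
  if (!is.null(rois)) masks <- masks[rois]
  models <- names(x$doses)
  first <- TRUE
  cols <- seq_along(masks)
  for (ri in seq_along(masks)) for (mi in seq_along(models)) {
    dv <- dvh_curve(x$doses[[models[mi]]], bin_width = bin_width,
                    mask = masks[[ri]], roi = names(masks)[ri],
                    model = models[mi])
    plot(dv, add = !first, col = cols[ri], lty = mi, ...)
    first <- FALSE
  }
  graphics::legend("topright",
                   legend = c(names(masks), models),
                   col = c(cols, rep(1, length(models))),
                   lty = c(rep(1, length(masks)), seq_along(models)),
                   bty = "n")
  invisible(x)
}
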