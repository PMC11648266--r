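#' Packaged demonstration planning configurations
#'
#' Three phantom/plan families are packaged:
#' \describe{
#'   \item{`two_beam`}{the standard demonstration case: a pelvic-like box CTV
#'     with an abutting OAR, two opposite horizontal beams, 16 fractions,
#'     per-fraction prescriptions 4.15 Gy(RBE) in the LEM-like model and
#'     3.60 Gy(RBE) in the NIRS-like model (totals 66.4 / 57.6), coverage
#'     goals `V >= 95%` at 95% of each prescription (63.08 / 54.72) and
#'     homogeneity goals HI <= 17%.}
#'   \item{`three_beam`}{a head-and-neck-like spherical CTV treated with
#'     three orthogonal beams, 20 fractions, equal 60 Gy(RBE) prescriptions
#'     in the LEM-like and MKM-like models (shared photon endpoint), coverage
#'     goal `V_57 >= 95%` in both.}
#'   \item{`mini`}{a small fast variant of `two_beam` for examples and tests.}
#' }
#'
#' @param case one of `"two_beam"`, `"three_beam"`, `"mini"`.
#' @param scenario `"A"` (single-model), `"B"` (mixed-RBE) or `"C"`
#'   (multi-RBE).
#' @return a config list accepted by [run_scenario()].
#' @export
standard_config <- function(case = c("two_beam", "three_beam", "mini"),
                            scenario = c("A", "B", "C")) {
  case <- match.arg(case)
  scenario <- match.arg(scenario)

  if (case == "three_beam") {
    models <- c("LEMlike", "MKMlike")
    p_tot <- c(LEMlike = 60, MKMlike = 60)
    fractions <- 20L
    phantom <- list(
      dims = c(40, 40, 40), spacing = 2.5,
      ctv = list(shape = "sphere", radius = 16),
      oars = list(list(name = "OAR", shape = "box",
                       center = c(50, 73, 50), size = c(28, 14, 28))))
    beams <- list(list(direction = "+x"), list(direction = "+y"),
                  list(direction = "+z"))
    oar_limit <- 42
    cover <- 0.95 * p_tot
  } else {
    models <- c("LEMlike", "NIRSlike")
    p_tot <- c(LEMlike = 66.4, NIRSlike = 57.6)
    fractions <- 16L
    cover <- c(LEMlike = 63.08, NIRSlike = 54.72)
    if (case == "two_beam") {
      phantom <- list(
        dims = c(48, 48, 28), spacing = 2.5,
        ctv = list(shape = "box", size = c(40, 40, 30)),
        oars = list(list(name = "OAR", shape = "box",
                         center = c(60, 87.5, 35), size = c(40, 15, 30))))
      oar_limit <- 50
    } else {  # mini
      phantom <- list(
        dims = c(20, 20, 12), spacing = 3,
        ctv = list(shape = "box", size = c(18, 18, 18)),
        oars = list(list(name = "OAR", shape = "box",
                         center = c(30, 42, 18), size = c(18, 9, 18))))
      oar_limit <- 50
    }
    beams <- list(list(direction = "+x"), list(direction = "-x"))
  }
  beam_defaults <- list(spot_spacing = 6, layer_spacing = 5, sigma_lateral = 4)
  beams <- lapply(beams, function(b) utils::modifyList(beam_defaults, b))

  m1 <- models[1]; m2 <- models[2]
  sc <- switch(scenario,
    A = list(target_models = m1, oar_model = m1),
    B = list(target_models = m2, oar_model = m1),
    C = list(target_models = c(m1, m2), oar_model = m1))

  goals <- list()
  for (m in models) {
    goals[[length(goals) + 1L]] <- list(roi = "CTV", model = m, metric = "V",
                                        level = unname(cover[m]), limit = 95,
                                        cmp = ">=")
    goals[[length(goals) + 1L]] <- list(roi = "CTV", model = m, metric = "HI",
                                        limit = 17, cmp = "<=")
  }
  goals[[length(goals) + 1L]] <- list(roi = "OAR", model = m1,
                                      metric = "D_pct", volume = 2,
                                      limit = oar_limit * 1.2, cmp = "<=")

  list(
    name = sprintf("%s.%s", case, scenario),
    case = case,
    phantom = phantom,
    beams = beams,
    curve = list(),          # depth_curve_params() defaults
    margin = 4,
    models = "default",
    scenario = list(scenario = scenario, target_models = sc$target_models,
                    oar_model = sc$oar_model,
                    prescriptions = as.list(p_tot), fractions = fractions),
    oar_constraints = list(list(roi = "OAR", kind = "max_dose",
                                limit = oar_limit)),
    priorities = list(target = 1, oar = if (case == "three_beam") 0.6 else 0.3),
    goals = goals,
    solver = list(max_iter = if (case == "mini") 300L else 200L,
                  grad_tol = 1e-5)
  )
}

resolve_models <- function(spec) {
  if (is.character(spec) && identical(spec, "default")) return(default_rbe_models())
  if (is.list(spec) && all(vapply(spec, inherits, TRUE, "rbe_model"))) return(spec)
  stopf("config 'models' must be \"default\" or a named list of rbe_model objects")
}

build_goals <- function(goal_specs) {
  lapply(goal_specs, function(g)
    clinical_goal(g$roi, g$model, g$metric, g$limit, g$cmp,
                  level = g$level, volume = g$volume))
}

run_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e)
    stopf("[stage %s] %s", stage, conditionMessage(e)))
}

#' Run one planning scenario end to end
#'
#' Pipeline: build phantom, place spots, assemble the multi-model influence
#' set, construct the scenario's optimization problem, solve it, recalculate
#' the plan under every registered model, and evaluate DVH metrics and
#' clinical goals. With `outdir` set, all artifacts are written to disk
#' (weights CSV, per-model NIfTI dose volumes, DVH and metric CSV tables,
#' goal table, solve report and config snapshot JSON, log, and an md5-stamped
#' manifest). Fully deterministic: identical configs reproduce identical
#' metric tables.
#'
#' @param config a config list (see [standard_config()]) or the path of a
#'   YAML file holding one.
#' @param outdir optional output directory for artifacts.
#' @param quiet suppress progress messages.
#' @return object of class `scenario_run`: list with `plan` (the [ion_plan]),
#'   `doses`, `metrics`, `goal_table`, `verdict`, `phantom`, `config` and
#'   `artifacts` (paths, when written).
#' @export
run_scenario <- function(config, outdir = NULL, quiet = TRUE) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  say <- function(...) if (!quiet) message(sprintf(...))

  say("stage phantom: building grid and ROIs")
  ph <- run_stage("phantom", generate_phantom(config$phantom))
  curve <- run_stage("phantom", do.call(depth_curve_params, config$curve %||% list()))
  models <- run_stage("models", resolve_models(config$models %||% "default"))

  say("stage spots: placing beamlets")
  target <- ph$rois[[which(vapply(ph$rois, `[[`, "", "role") == "target")[1]]]
  spots <- run_stage("spots", {
    sl <- lapply(seq_along(config$beams), function(i) {
      b <- do.call(beam_spec, config$beams[[i]])
      build_spot_list(b, target, ph$grid, margin = config$margin %||% 0,
                      beam_index = i)
    })
    do.call(rbind, sl)
  })
  say("stage influence: %d beamlets over %d voxels", nrow(spots), n_voxels(ph$grid))
  infl <- run_stage("influence",
                    assemble_influence(ph$grid, spots, curve, models))

  say("stage problem: scenario %s", config$scenario$scenario)
  sc <- run_stage("problem", scenario_config(
    config$scenario$scenario, config$scenario$target_models,
    config$scenario$oar_model,
    unlist(config$scenario$prescriptions),
    goals = build_goals(config$goals %||% list()),
    fractions = config$scenario$fractions %||% 1L))
  pr <- config$priorities %||% list(target = 1, oar = 1)
  problem <- run_stage("problem", make_scenario(
    sc, infl, ph$rois, config$oar_constraints %||% list(),
    target_priority = pr$target %||% 1, oar_priority = pr$oar %||% 1,
    coverage_priority = pr$coverage %||% (2 * (pr$target %||% 1))))

  say("stage solve: optimizing %d weights", ncol(infl$d))
  sset <- do.call(solver_settings, config$solver %||% list())
  plan <- run_stage("solve", plan_optimize(problem, sset))

  say("stage evaluate")
  eval_rois <- ph$rois[vapply(ph$rois, `[[`, "", "role") != "external"]
  metrics <- run_stage("evaluate", metric_report(plan$doses, eval_rois))
  gt <- run_stage("evaluate", check_goals(plan$doses, ph$rois, sc$goals))

  out <- structure(list(plan = plan, doses = plan$doses, metrics = metrics,
                        goal_table = gt, verdict = attr(gt, "verdict"),
                        phantom = ph, spots = spots, config = config,
                        scenario = sc, artifacts = NULL),
                   class = "scenario_run")
  if (!is.null(outdir)) out$artifacts <- run_stage("write",
    write_artifacts(out, outdir))
  out
}

#' @export
print.scenario_run <- function(x, ...) {
  cat(sprintf("scenario_run '%s' (scenario %s)\n",
              x$config$name %||% "unnamed", x$scenario$scenario))
  print(x$goal_table)
  invisible(x)
}

write_artifacts <- function(run, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  put <- function(p) { paths[[length(paths) + 1L]] <<- p; p }

  wcsv <- put(file.path(outdir, "weights.csv"))
  utils::write.csv(cbind(run$spots[, c("beam_index", "u", "v", "range")],
                         weight = run$plan$weights),
                   wcsv, row.names = FALSE)
  dims <- run$phantom$grid$dims
  for (mn in names(run$doses)) {
    f <- put(file.path(outdir, sprintf("dose_%s.nii.gz", mn)))
    img <- array(run$doses[[mn]]$values, dim = dims)
    RNifti::writeNifti(RNifti::asNifti(img, pixdim = run$phantom$grid$spacing), f)
  }
  eval_rois <- run$phantom$rois[
    vapply(run$phantom$rois, `[[`, "", "role") != "external"]
  for (rn in names(eval_rois)) for (mn in names(run$doses)) {
    dv <- dvh_curve(run$doses[[mn]], mask = eval_rois[[rn]], roi = rn, model = mn)
    f <- put(file.path(outdir, sprintf("dvh_%s_%s.csv", rn, mn)))
    utils::write.csv(data.frame(dose = dv$dose, volume_pct = dv$volume),
                     f, row.names = FALSE)
  }
  mcsv <- put(file.path(outdir, "metrics.csv"))
  utils::write.csv(run$metrics, mcsv, row.names = FALSE)
  gcsv <- put(file.path(outdir, "goals.csv"))
  utils::write.csv(as.data.frame(run$goal_table), gcsv, row.names = FALSE)
  rjson <- put(file.path(outdir, "solve_report.json"))
  jsonlite::write_json(unclass(run$plan$report), rjson, auto_unbox = TRUE,
                       digits = NA, na = "null")
  cjson <- put(file.path(outdir, "config.json"))
  jsonlite::write_json(run$config, cjson, auto_unbox = TRUE, digits = NA,
                       force = TRUE)
  log <- put(file.path(outdir, "log.txt"))
  writeLines(c(sprintf("config: %s", run$config$name %||% "unnamed"),
               sprintf("iterations: %d", run$plan$report$iterations),
               sprintf("objective: %.6g -> %.6g",
                       run$plan$report$initial_objective,
                       run$plan$report$final_objective),
               sprintf("verdict: %s",
                       if (run$verdict) "all goals met" else "goals violated"),
               "objective trace:",
               sprintf("  %.6g", run$plan$report$objective_trace)), log)

  config_hash <- unname(tools::md5sum(cjson))
  manifest <- list(config_hash = config_hash,
                   files = lapply(stats::setNames(nm = basename(unlist(paths))),
                                  function(b) unname(tools::md5sum(file.path(outdir, b)))))
  mjson <- file.path(outdir, "manifest.json")
  jsonlite::write_json(manifest, mjson, auto_unbox = TRUE)
  c(unlist(paths), mjson)
}

#' Compare planning scenarios on a shared phantom
#'
#' Runs (or accepts already-run) scenario configurations that differ only in
#' the scenario letter, and tabulates the per-(scenario, roi, model) DVH
#' metrics together with the per-scenario CTV median-dose scaling factor
#' between the first two registered models.
#'
#' @param configs list of config lists (or `scenario_run` results).
#' @param quiet passed to [run_scenario()].
#' @return data.frame with one row per (scenario, roi, model); attribute
#'   `summary` holds per-scenario max target HI and F_scal.
#' @export
compare_scenarios <- function(configs, quiet = TRUE) {
  runs <- lapply(configs, function(cf)
    if (inherits(cf, "scenario_run")) cf else run_scenario(cf, quiet = quiet))
  phantoms <- lapply(runs, function(r) r$config$phantom)
  if (length(unique(vapply(phantoms, function(p) paste(deparse(p), collapse = ""), ""))) != 1L)
    stopf("scenario configs use mismatched phantom specs")
  letters_seen <- vapply(runs, function(r) r$scenario$scenario, "")
  missing <- setdiff(c("A", "B", "C"), letters_seen)
  if (length(missing))
    warning(sprintf("scenario(s) %s missing; returning a partial table",
                    paste(missing, collapse = ", ")), call. = FALSE)

  tabs <- lapply(runs, function(r)
    cbind(scenario = r$scenario$scenario, r$metrics))
  out <- do.call(rbind, tabs)

  target_name <- function(r) {
    roles <- vapply(r$phantom$rois, `[[`, "", "role")
    names(r$phantom$rois)[roles == "target"][1]
  }
  summ <- do.call(rbind, lapply(runs, function(r) {
    tn <- target_name(r)
    mods <- names(r$doses)[1:2]
    hi <- vapply(mods, function(m)
      homogeneity_index(r$doses[[m]], r$phantom$rois[[tn]]), numeric(1))
    data.frame(scenario = r$scenario$scenario,
               max_target_HI = max(hi),
               F_scal = f_scal(r$doses[[mods[1]]], r$doses[[mods[2]]],
                               r$phantom$rois[[tn]]))
  }))
  attr(out, "summary") <- summ
  out
}
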