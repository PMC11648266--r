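#' Define one cost-function term
#'
#' Quadratic inverse-planning penalties on the total RBE-weighted dose of one
#' ROI expressed in one model: `uniform` penalizes `(D - level)^2`, `max_dose`
#' penalizes `max(0, D - level)^2`, `min_dose` penalizes `max(0, level - D)^2`,
#' and `dvh_max` applies the `max_dose` penalty only to voxels exceeding
#' `level` beyond the allowed `volume_param` percent of the ROI (the allowed
#' hottest voxels are exempt; ties broken by voxel index).
#'
#' @param roi ROI label.
#' @param model model label the dose is evaluated in.
#' @param kind one of `"uniform"`, `"max_dose"`, `"min_dose"`, `"dvh_max"`.
#' @param dose_level dose level, total Gy(RBE) (>= 0).
#' @param volume_param allowed volume, % of the ROI (`dvh_max` only).
#' @param priority nonnegative term weight.
#' @return object of class `cost_term`.
#' @export
cost_term <- function(roi, model,
                      kind = c("uniform", "max_dose", "min_dose", "dvh_max"),
                      dose_level, volume_param = NULL, priority = 1) {
  kind <- match.arg(kind)
  chk_num(dose_level, "dose_level", 1, lower = 0)
  chk_num(priority, "priority", 1, lower = 0)
  if (kind == "dvh_max") {
    if (is.null(volume_param)) stopf("dvh_max terms require 'volume_param'")
    chk_num(volume_param, "volume_param", 1, lower = 0, upper = 100)
  }
  structure(list(roi = roi, model = model, kind = kind,
                 dose_level = dose_level, volume_param = volume_param,
                 priority = priority),
            class = "cost_term")
}

#' Build an optimization problem from influence data and cost terms
#'
#' Precomputes, per referenced model, the influence rows restricted to the
#' union of the term ROIs (the optimizer never needs doses elsewhere).
#'
#' @param infl an [influence_set].
#' @param rois named list of [roi_mask] objects.
#' @param terms list of [cost_term] objects (>= 1 term must reference a
#'   target-role ROI).
#' @param fractions number of fractions; weights are per fraction and cost
#'   levels are totals.
#' @return object of class `plan_problem`.
#' @export
plan_problem <- function(infl, rois, terms, fractions = 1L) {
  stopifnot(inherits(infl, "influence_set"))
  fractions <- as.integer(chk_num(fractions, "fractions", 1, lower = 1))
  if (!length(terms)) stopf("at least one cost term is required")
  for (t in terms) {
    if (!inherits(t, "cost_term")) stopf("terms must be cost_term objects")
    if (!t$roi %in% names(rois)) stopf("unknown ROI '%s' in cost term", t$roi)
    if (!t$model %in% names(infl$a)) stopf("unknown model '%s' in cost term", t$model)
  }
  roles <- vapply(rois, `[[`, "", "role")
  has_target <- any(vapply(terms, function(t) roles[[t$roi]] == "target", TRUE))
  if (!has_target) stopf("no cost term references a target ROI")

  models_used <- unique(vapply(terms, `[[`, "", "model"))
  blocks <- list()
  for (mn in models_used) {
    tm <- terms[vapply(terms, function(t) t$model == mn, TRUE)]
    uidx <- sort(unique(unlist(lapply(tm, function(t) which(rois[[t$roi]]$mask)))))
    m <- infl$models[[mn]]
    blocks[[mn]] <- list(
      uidx = uidx,
      a = infl$a[[mn]][uidx, , drop = FALSE],
      b = infl$b[[mn]][uidx, , drop = FALSE],
      alpha_x = m$photon$alpha_x, beta_x = m$photon$beta_x,
      scale = m$clinical_scale)
  }
  terms <- lapply(terms, function(t) {
    t$loc <- match(which(rois[[t$roi]]$mask), blocks[[t$model]]$uidx)
    t$n <- length(t$loc)
    t
  })
  structure(list(infl = infl, rois = rois, terms = terms,
                 fractions = fractions, blocks = blocks,
                 models_used = models_used, n_beamlets = ncol(infl$d)),
            class = "plan_problem")
}

# penalty value and derivative on the total-dose scale for one term
term_penalty <- function(t, D) {
  L <- t$dose_level
  switch(t$kind,
    uniform = {
      r <- D - L
      list(p = r^2, dp = 2 * r)
    },
    max_dose = {
      e <- pmax(D - L, 0)
      list(p = e^2, dp = 2 * e)
    },
    min_dose = {
      e <- pmax(L - D, 0)
      list(p = e^2, dp = -2 * e)
    },
    dvh_max = {
      p <- numeric(length(D)); dp <- p
      over <- which(D > L)
      k_allow <- floor(t$volume_param / 100 * length(D))
      if (length(over) > k_allow) {
        ord <- over[order(-D[over], over)]       # hottest first, ties by index
        pen <- ord[(k_allow + 1):length(ord)]    # allowed hottest are exempt
        p[pen] <- (D[pen] - L)^2
        dp[pen] <- 2 * (D[pen] - L)
      }
      list(p = p, dp = dp)
    })
}

#' Objective and analytic gradient of a fluence-optimization problem
#'
#' `F(w) = sum_t priority_t / |ROI_t| * sum_{i in ROI_t} penalty_t(D_i^m)`
#' with `D^m` the total RBE-weighted dose of model m. The gradient is exact,
#' via the chain rule through the photon-LQ inversion:
#' `dD_i/dw_j = s * (a_ij + 2 B_i b_ij) / sqrt(alpha_x^2 + 4 beta_x E_i)`
#' where `s` is the fraction count times the model's clinical scale.
#'
#' @param w nonnegative per-fraction beamlet weights.
#' @param problem a [plan_problem].
#' @return list with `F` (scalar objective), `grad` (per-beamlet gradient)
#'   and `term_values` (per-term contributions to `F`).
#' @export
objective_and_gradient <- function(w, problem) {
  stopifnot(inherits(problem, "plan_problem"))
  w <- chk_num(w, "w", len = problem$n_beamlets)
  if (any(w < 0)) stopf("weights must be nonnegative")
  Fv <- 0
  grad <- numeric(problem$n_beamlets)
  term_values <- numeric(length(problem$terms))
  for (mn in problem$models_used) {
    bl <- problem$blocks[[mn]]
    A <- as.numeric(bl$a %*% w)
    B <- as.numeric(bl$b %*% w)
    E <- A + B^2
    root <- if (bl$beta_x > 0) sqrt(bl$alpha_x^2 + 4 * bl$beta_x * E)
            else rep(bl$alpha_x, length(E))
    s <- problem$fractions * bl$scale
    D <- s * (if (bl$beta_x > 0) (root - bl$alpha_x) / (2 * bl$beta_x)
              else E / bl$alpha_x)
    r <- numeric(length(bl$uidx))
    for (ti in seq_along(problem$terms)) {
      t <- problem$terms[[ti]]
      if (t$model != mn) next
      pen <- term_penalty(t, D[t$loc])
      wgt <- t$priority / t$n
      term_values[ti] <- wgt * sum(pen$p)
      Fv <- Fv + term_values[ti]
      r[t$loc] <- r[t$loc] + wgt * pen$dp
    }
    g <- r * s / root
    grad <- grad + as.numeric(Matrix::crossprod(bl$a, g)) +
                   as.numeric(Matrix::crossprod(bl$b, 2 * B * g))
  }
  if (!is.finite(Fv))
    stopf("non-finite objective (F = %g); check weights and dose levels", Fv)
  list(F = Fv, grad = grad, term_values = term_values)
}

#' Solver settings for the projected-gradient fluence optimizer
#'
#' @param max_iter maximum accepted iterations.
#' @param grad_tol relative convergence tolerance on the projected-gradient
#'   infinity norm (relative to its initial value).
#' @param armijo sufficient-decrease constant of the backtracking line search.
#' @param max_backtrack maximum step halvings per iteration.
#' @param w0 optional starting weights (default: uniform, scaled so the mean
#'   target physical dose times a nominal RBE of 2 matches the first target
#'   prescription).
#' @param seed integer recorded in the solve report (the solver itself is
#'   deterministic).
#' @return list of class `solver_settings`.
#' @export
solver_settings <- function(max_iter = 500L, grad_tol = 1e-6, armijo = 1e-4,
                            max_backtrack = 40L, w0 = NULL, seed = NA_integer_) {
  structure(list(max_iter = as.integer(max_iter), grad_tol = grad_tol,
                 armijo = armijo, max_backtrack = as.integer(max_backtrack),
                 w0 = w0, seed = seed),
            class = "solver_settings")
}

default_start <- function(problem) {
  roles <- vapply(problem$rois, `[[`, "", "role")
  tt <- NULL
  for (t in problem$terms)
    if (roles[[t$roi]] == "target" && t$kind %in% c("uniform", "min_dose")) {
      tt <- t; break
    }
  if (is.null(tt)) tt <- problem$terms[[1]]
  bl <- problem$blocks[[tt$model]]
  idx <- which(problem$rois[[tt$roi]]$mask)
  mean_d <- mean(as.numeric(problem$infl$d[idx, , drop = FALSE] %*%
                              rep(1, problem$n_beamlets)))
  # nominal RBE of 2: physical target dose per fraction ~ prescription/(2*nfx)
  target_phys <- tt$dose_level / (2 * problem$fractions * bl$scale)
  rep(max(target_phys / max(mean_d, 1e-12), 1e-9), problem$n_beamlets)
}

#' Solve the fluence-optimization problem
#'
#' Projected-gradient descent with Barzilai-Borwein step length and Armijo
#' backtracking onto the nonnegative orthant. The objective is monotone
#' nonincreasing over accepted iterations; the run is deterministic given
#' the settings (fixed initialization, no randomness).
#'
#' @param problem a [plan_problem].
#' @param settings a [solver_settings].
#' @return list with `weights` (nonnegative, per fraction) and `report`
#'   (class `solve_report`: iterations, initial/final objective, objective
#'   trace, per-term final values, convergence flag, projected-gradient
#'   norm, seed).
#' @export
solve_fluence <- function(problem, settings = solver_settings()) {
  stopifnot(inherits(problem, "plan_problem"))
  w <- settings$w0 %||% default_start(problem)
  w <- pmax(chk_num(w, "w0", len = problem$n_beamlets), 0)

  fg <- objective_and_gradient(w, problem)
  f0 <- fg$F
  proj_grad <- function(w, g) ifelse(w <= 0 & g > 0, 0, g)
  pg <- proj_grad(w, fg$grad)
  pg0 <- max(abs(pg))
  trace <- f0
  step <- if (pg0 > 0) 0.1 * max(max(w), 1e-9) / pg0 else 1
  converged <- pg0 == 0
  it <- 0L

  while (!converged && it < settings$max_iter) {
    accepted <- FALSE
    t_try <- step
    for (bt in seq_len(settings$max_backtrack)) {
      wn <- pmax(w - t_try * fg$grad, 0)
      dec <- sum(fg$grad * (w - wn))  # >= 0 on the projected arc
      if (dec <= 0) break
      fgn <- objective_and_gradient(wn, problem)
      if (fgn$F <= fg$F - settings$armijo * dec) { accepted <- TRUE; break }
      t_try <- t_try / 2
    }
    if (!accepted) break  # no further descent possible at machine precision
    s_vec <- wn - w
    y_vec <- fgn$grad - fg$grad
    sy <- sum(s_vec * y_vec)
    step <- if (is.finite(sy) && sy > 0) sum(s_vec^2) / sy else t_try * 2
    w <- wn; fg <- fgn
    it <- it + 1L
    trace <- c(trace, fg$F)
    pg <- proj_grad(w, fg$grad)
    converged <- max(abs(pg)) <= settings$grad_tol * pg0
  }

  report <- structure(list(
    iterations = it,
    initial_objective = f0,
    final_objective = fg$F,
    objective_trace = trace,
    term_values = fg$term_values,
    converged = converged,
    grad_norm = max(abs(pg)),
    seed = settings$seed), class = "solve_report")
  list(weights = w, report = report)
}

#' @export
print.solve_report <- function(x, ...) {
  cat(sprintf(
    "solve_report: %d iterations, objective %.4g -> %.4g, proj-grad inf-norm %.3g, %s\n",
    x$iterations, x$initial_objective, x$final_objective, x$grad_norm,
    if (x$converged) "converged" else "stopped at iteration limit"))
  invisible(x)
}

#' Describe a scenario's per-ROI model assignment
#'
#' Scenario A optimizes every ROI in a single model; scenario B (mixed-RBE)
#' optimizes targets in a second model while keeping OAR constraints in the
#' first; scenario C (multi-RBE) duplicates the target objectives in both
#' models (equal priority by default) with OAR constraints in the first.
#'
#' @param scenario `"A"`, `"B"` or `"C"`.
#' @param target_models model label(s) for target objectives (1 for A/B,
#'   2 for C).
#' @param oar_model model label for OAR constraints.
#' @param prescriptions named numeric, total prescription Gy(RBE) per model.
#' @param goals optional list of [clinical_goal] objects evaluated after
#'   optimization.
#' @param fractions fraction count.
#' @return object of class `scenario_config`.
#' @export
scenario_config <- function(scenario = c("A", "B", "C"), target_models,
                            oar_model, prescriptions, goals = list(),
                            fractions = 1L) {
  scenario <- match.arg(scenario)
  if (scenario == "A" &&
      !(length(target_models) == 1L && target_models == oar_model))
    stopf("scenario A uses one model for both targets and OARs")
  if (scenario == "B" &&
      !(length(target_models) == 1L && target_models != oar_model))
    stopf("scenario B uses one target model different from the OAR model")
  if (scenario == "C" && length(target_models) != 2L)
    stopf("scenario C requires two target models")
  for (m in target_models)
    if (!m %in% names(prescriptions))
      stopf("no prescription given for target model '%s'", m)
  structure(list(scenario = scenario, target_models = target_models,
                 oar_model = oar_model,
                 prescriptions = prescriptions, goals = goals,
                 fractions = as.integer(fractions)),
            class = "scenario_config")
}

#' Build the optimization problem for a planning scenario
#'
#' Converts a [scenario_config] plus OAR constraints into [cost_term]s:
#' each target ROI receives a `uniform` term at the model's prescription for
#' every target model (scenario C duplicates them at equal priority), and
#' every OAR constraint becomes a `max_dose` or `dvh_max` term in the OAR
#' model.
#'
#' @param config a [scenario_config].
#' @param infl an [influence_set] with all referenced models registered.
#' @param rois named list of [roi_mask] objects (targets found by role).
#' @param oar_constraints list of lists with `roi`, `limit` (total Gy(RBE)),
#'   optional `kind` (`"max_dose"` default, or `"dvh_max"`) and `volume`
#'   (% for `dvh_max`).
#' @param target_priority,oar_priority term priorities.
#' @param coverage_priority priority of an additional `min_dose` term at the
#'   prescription level for each target term (0 disables); emphasizes target
#'   coverage over the symmetric uniform penalty, as clinical objective sets
#'   do.
#' @return a [plan_problem].
#' @export
make_scenario <- function(config, infl, rois, oar_constraints = list(),
                          target_priority = 1, oar_priority = 1,
                          coverage_priority = 2 * target_priority) {
  stopifnot(inherits(config, "scenario_config"))
  roles <- vapply(rois, `[[`, "", "role")
  targets <- names(rois)[roles == "target"]
  if (!length(targets)) stopf("no target ROI present")
  terms <- list()
  for (tm in config$target_models) for (tr in targets) {
    terms[[length(terms) + 1L]] <-
      cost_term(tr, tm, "uniform", config$prescriptions[[tm]],
                priority = target_priority)
    if (coverage_priority > 0)
      terms[[length(terms) + 1L]] <-
        cost_term(tr, tm, "min_dose", config$prescriptions[[tm]],
                  priority = coverage_priority)
  }
  for (oc in oar_constraints) {
    kind <- oc$kind %||% "max_dose"
    terms[[length(terms) + 1L]] <-
      cost_term(oc$roi, config$oar_model, kind, oc$limit,
                volume_param = oc$volume, priority = oar_priority)
  }
  plan_problem(infl, rois, terms, fractions = config$fractions)
}
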