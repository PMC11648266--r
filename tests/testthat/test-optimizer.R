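test_that("objective matches the hand-differentiated single-voxel case", {
  # F(w) = (0.5 w - 2)^2; at w = 2: F = 1, grad = 2(0.5w-2)*0.5 = -1
  prob <- one_voxel_problem(d = 0.5, prescription = 2)
  og <- objective_and_gradient(2, prob)
  expect_equal(og$F, 1)
  expect_equal(og$grad, -1)
  # at the minimum the uniform term vanishes with zero gradient
  og4 <- objective_and_gradient(4, prob)
  expect_equal(og4$F, 0)
  expect_equal(og4$grad, 0)
  expect_error(objective_and_gradient(-1, prob), "nonnegative")
})

test_that("analytic gradients match central finite differences", {
  for (seed in 1:4) {
    prob <- random_problem(seed = seed)
    set.seed(seed + 100)
    w <- runif(prob$n_beamlets, 0.2, 1.5)
    og <- objective_and_gradient(w, prob)
    h <- 1e-6
    fd <- vapply(seq_along(w), function(j) {
      wp <- w; wp[j] <- w[j] + h
      wm <- w; wm[j] <- w[j] - h
      (objective_and_gradient(wp, prob)$F -
         objective_and_gradient(wm, prob)$F) / (2 * h)
    }, numeric(1))
    denom <- pmax(abs(fd), 1e-8)
    expect_lt(max(abs(og$grad - fd) / denom), 1e-5)
  }
})

test_that("solver recovers the closed-form single-voxel optimum", {
  prob <- one_voxel_problem(d = 0.5, prescription = 2)
  sol <- solve_fluence(prob)
  expect_equal(sol$weights, 4, tolerance = 1e-6)  # w* = P / d
  expect_true(sol$report$converged)
  expect_lte(sol$report$final_objective, sol$report$initial_objective)
})

test_that("solver matches the NNLS active-set oracle on a 3-beamlet problem", {
  set.seed(5)
  nv <- 5; nb <- 3
  d <- matrix(runif(nv * nb, 0.1, 1), nv, nb)
  infl <- dense_influence(d)
  g <- infl$grid
  rois <- list(T = roi_mask("T", "target", rep(TRUE, nv), g))
  P <- 2
  prob <- plan_problem(infl, rois, list(cost_term("T", "photon_id",
                                                  "uniform", P)))
  sol <- solve_fluence(prob, solver_settings(max_iter = 2000, grad_tol = 1e-10))
  # oracle: photon-identity uniform objective is nonnegative least squares;
  # enumerate active sets, solving the unconstrained LS on each support
  best <- Inf
  for (S in list(1, 2, 3, c(1, 2), c(1, 3), c(2, 3), 1:3)) {
    ds <- d[, S, drop = FALSE]
    ws <- tryCatch(solve(crossprod(ds), crossprod(ds, rep(P, nv))),
                   error = function(e) NULL)
    if (is.null(ws) || any(ws < -1e-12)) next
    w_full <- numeric(nb); w_full[S] <- pmax(ws, 0)
    best <- min(best, mean((d %*% w_full - P)^2))
  }
  expect_lt(abs(sol$report$final_objective - best), 1e-6)
  expect_true(all(sol$weights >= 0))
})

test_that("solver cross-checks against L-BFGS-B on a mixed multi-model problem", {
  prob <- random_problem(seed = 9)
  sol <- solve_fluence(prob, solver_settings(max_iter = 3000, grad_tol = 1e-9))
  ref <- optim(rep(0.5, prob$n_beamlets),
               fn = function(w) objective_and_gradient(w, prob)$F,
               gr = function(w) objective_and_gradient(w, prob)$grad,
               method = "L-BFGS-B", lower = 0,
               control = list(maxit = 2000, factr = 1e2))
  expect_lt(sol$report$final_objective, ref$value + 1e-6)
})

test_that("objective trace is monotone nonincreasing and weights stay feasible", {
  prob <- random_problem(seed = 2)
  sol <- solve_fluence(prob, solver_settings(max_iter = 150))
  expect_true(all(diff(sol$report$objective_trace) <= 1e-12))
  expect_true(all(sol$weights >= 0))
  expect_true(all(is.finite(sol$weights)))
})

test_that("mirror-symmetric two-beam problems give mirror-symmetric weights", {
  ph <- generate_phantom(list(dims = c(24, 12, 12), spacing = 3,
                              ctv = list(shape = "box", size = 18)))
  p <- depth_curve_params()
  sp1 <- build_spot_list(beam_spec("+x", 6, 6, 4), ph$rois$CTV, ph$grid, 3, 1L)
  sp2 <- build_spot_list(beam_spec("-x", 6, 6, 4), ph$rois$CTV, ph$grid, 3, 2L)
  sp <- rbind(sp1, sp2)
  infl <- assemble_influence(ph$grid, sp, p, list(id = identity_model("id")))
  rois <- list(CTV = roi_mask("CTV", "target", ph$rois$CTV$mask, ph$grid))
  prob <- plan_problem(infl, rois,
                       list(cost_term("CTV", "id", "uniform", 2)))
  sol <- solve_fluence(prob, solver_settings(max_iter = 400))
  w1 <- sol$weights[sp$beam_index == 1]
  w2 <- sol$weights[sp$beam_index == 2]
  # same (u, v, range) ordering on both beams by construction
  expect_equal(w1, w2, tolerance = 1e-4)
})

test_that("scenario construction assigns cost terms to the right models", {
  mods <- default_rbe_models()
  g <- voxel_grid(c(4, 1, 1), 5)
  infl <- influence_set(matrix(runif(8, 0.5, 1), 4, 2), 40, mods, g)
  rois <- list(CTV = roi_mask("CTV", "target", c(TRUE, TRUE, FALSE, FALSE), g),
               OAR = roi_mask("OAR", "oar", c(FALSE, FALSE, TRUE, TRUE), g))
  oc <- list(list(roi = "OAR", limit = 40),
             list(roi = "OAR", kind = "dvh_max", limit = 30, volume = 20))
  presc <- c(LEMlike = 66.4, NIRSlike = 57.6)

  cfgA <- scenario_config("A", "LEMlike", "LEMlike", presc)
  pA <- make_scenario(cfgA, infl, rois, oc)
  expect_true(all(vapply(pA$terms, `[[`, "", "model") == "LEMlike"))

  cfgB <- scenario_config("B", "NIRSlike", "LEMlike", presc)
  pB <- make_scenario(cfgB, infl, rois, oc)
  ctv_models <- vapply(Filter(function(t) t$roi == "CTV", pB$terms),
                       `[[`, "", "model")
  expect_true(all(ctv_models == "NIRSlike"))   # no CTV term in the OAR model
  oar_models <- vapply(Filter(function(t) t$roi == "OAR", pB$terms),
                       `[[`, "", "model")
  expect_true(all(oar_models == "LEMlike"))

  cfgC <- scenario_config("C", c("LEMlike", "NIRSlike"), "LEMlike", presc)
  pC <- make_scenario(cfgC, infl, rois, oc, coverage_priority = 0)
  ctvC <- Filter(function(t) t$roi == "CTV" && t$kind == "uniform", pC$terms)
  expect_equal(sort(vapply(ctvC, `[[`, "", "model")),
               c("LEMlike", "NIRSlike"))
  expect_equal(vapply(ctvC, `[[`, 1, "priority"), c(1, 1))
  expect_equal(vapply(ctvC, `[[`, 1, "dose_level"), c(66.4, 57.6))

  expect_error(scenario_config("C", "LEMlike", "LEMlike", presc), "two")
  expect_error(scenario_config("A", "LEMlike", "NIRSlike", presc), "scenario A")
  expect_error(make_scenario(cfgA, infl,
                             list(OAR = rois$OAR), oc), "target")
})
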