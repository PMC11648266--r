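test_that("alpha/beta lookup interpolates linearly and clamps at the ends", {
  m <- rbe_model("m", photon_lq(0.1, 0.05),
                 let = c(10, 20, 40), alpha = c(0.2, 0.4, 0.5),
                 beta = c(0.05, 0.04, 0.03))
  expect_equal(model_alpha_beta(m, 20)$alpha, 0.4)    # node identity
  expect_equal(model_alpha_beta(m, 15)$alpha, 0.3)    # midpoint
  expect_equal(model_alpha_beta(m, 5)$alpha, 0.2)     # clamp below
  expect_equal(model_alpha_beta(m, 100)$beta, 0.03)   # clamp above
  expect_error(rbe_model("bad", photon_lq(0.1, 0.05), numeric(0),
                         numeric(0), numeric(0)), "empty")
  expect_error(rbe_model("bad", photon_lq(0.1, 0.05), c(10, 10),
                         c(0.1, 0.1), c(0.05, 0.05)), "increasing")
})

test_that("mixed-field accumulation matches the hand-worked two-beamlet case", {
  # one voxel, two beamlets: d = (1, 1), alpha = (0.2, 0.4), sqrt(beta) =
  # (0.2, 0.3), w = (1, 1) -> D = 2, A = 0.6, B = 0.5, E = 0.85
  g <- voxel_grid(c(1, 1, 1), 10)
  m <- rbe_model("m", photon_lq(0.1, 0.05), let = c(10, 20),
                 alpha = c(0.2, 0.4), beta = c(0.04, 0.09))
  infl <- influence_set(matrix(c(1, 1), 1, 2), matrix(c(10, 20), 1, 2),
                        list(m = m), g)
  mf <- mixed_field_effect(c(1, 1), infl, "m")
  expect_equal(mf$D, 2)
  expect_equal(mf$A, 0.6)
  expect_equal(mf$B, 0.5)
  expect_equal(mf$E, 0.85)
  expect_equal(mf$A / mf$D, 0.3)   # alpha_mix
  expect_equal(mf$B / mf$D, 0.25)  # sqrt(beta)_mix
  # all-zero weights give the empty field
  mf0 <- mixed_field_effect(c(0, 0), infl, "m")
  expect_equal(mf0$E, 0)
  # single nonzero beamlet: alpha_mix equals that beamlet's alpha
  mf1 <- mixed_field_effect(c(3, 0), infl, "m")
  expect_equal(mf1$A / mf1$D, 0.2)
  expect_error(mixed_field_effect(c(-1, 1), infl, "m"), "nonnegative")
  expect_error(mixed_field_effect(c(1, 1), infl, "nope"), "not registered")
})

test_that("mixed-field effect equals brute-force per-beamlet LQ accumulation", {
  set.seed(7)
  nv <- 40; nb <- 10
  d <- matrix(runif(nv * nb), nv, nb); d[d < 0.5] <- 0
  let <- matrix(runif(nv * nb, 5, 120), nv, nb)
  m <- default_rbe_models()$MKMlike
  g <- voxel_grid(c(nv, 1, 1), 1)
  infl <- influence_set(d, let, list(MKMlike = m), g)
  w <- runif(nb, 0, 2)
  mf <- mixed_field_effect(w, infl, "MKMlike")
  # oracle: explicit summation over beamlets
  Ao <- Bo <- Do <- numeric(nv)
  for (j in 1:nb) for (i in 1:nv) if (d[i, j] > 0) {
    ab <- model_alpha_beta(m, let[i, j])
    Do[i] <- Do[i] + w[j] * d[i, j]
    Ao[i] <- Ao[i] + w[j] * ab$alpha * d[i, j]
    Bo[i] <- Bo[i] + w[j] * sqrt(ab$beta) * d[i, j]
  }
  expect_equal(mf$D, Do, tolerance = 1e-12)
  expect_equal(mf$A, Ao, tolerance = 1e-12)
  expect_equal(mf$E, Ao + Bo^2, tolerance = 1e-12)
  # single-field consistency: one beamlet reproduces direct LQ evaluation
  w1 <- c(2, rep(0, nb - 1))
  mf1 <- mixed_field_effect(w1, infl, "MKMlike")
  i <- which(d[, 1] > 0)[1]
  ab <- model_alpha_beta(m, let[i, 1])
  dd <- 2 * d[i, 1]
  expect_equal(mf1$E[i], ab$alpha * dd + ab$beta * dd^2, tolerance = 1e-12)
})

test_that("RBE-weighted dose inverts the photon LQ curve", {
  ph <- photon_lq(0.1, 0.05)
  expect_equal(rbe_weighted_dose(0, ph), 0)
  # against a bisection oracle on alpha_x D + beta_x D^2 = E
  E <- 0.6
  oracle <- uniroot(function(D) 0.1 * D + 0.05 * D^2 - E, c(0, 100),
                    tol = 1e-12)$root
  expect_equal(rbe_weighted_dose(E, ph), oracle, tolerance = 1e-9)
  expect_equal(rbe_weighted_dose(E, ph), 2.60555, tolerance = 1e-5)
  # beta_x = 0 branch
  expect_equal(rbe_weighted_dose(0.5, photon_lq(0.1, 0)), 5)
  pp <- photon_lq(0.1, 0.05); pp$alpha_x <- -1
  expect_error(rbe_weighted_dose(0.5, pp), "alpha_x")
  # monotone increasing in E
  Es <- seq(0, 3, by = 0.1)
  expect_true(all(diff(rbe_weighted_dose(Es, ph)) > 0))
})

test_that("photon-identity biology round-trips physical dose", {
  set.seed(3)
  d <- matrix(runif(30), 10, 3)
  infl <- dense_influence(d, let = 50)
  w <- runif(3, 0.5, 2)
  mf <- mixed_field_effect(w, infl, "photon_id")
  drbe <- rbe_weighted_dose(mf, photon_lq(0.1, 0.05))
  expect_equal(drbe, as.numeric(d %*% w), tolerance = 1e-10)
})

test_that("prescription conversion reproduces the clinical arithmetic", {
  expect_identical(prescription_convert(3.60, 1.153), 4.15)
  expect_identical(prescription_convert(3.60, 1), 3.6)
  expect_equal(4.15 * 16, 66.4)
  expect_error(prescription_convert(3.6, 0), "factor")
  expect_error(prescription_convert(-1, 1.1), "dose")
})

test_that("clinical scaling is linear and commutes with fraction summation", {
  g <- voxel_grid(c(2, 1, 1), 10)
  m <- rbe_model("jp", photon_lq(0.1, 0.05), c(0, 100), c(0.1, 0.3),
                 c(0.05, 0.05), clinical_scale = 1.2)
  d_fx <- rbe_dose(c(3, 1), g, "jp", fractions = 1L, per_fraction = TRUE)
  scaled <- clinical_dose(d_fx, m)
  expect_equal(scaled$values, c(3.6, 1.2))
  expect_equal(clinical_dose(rbe_dose(16 * d_fx$values, g, "jp"), m)$values,
               16 * scaled$values)
  m1 <- rbe_model("id", photon_lq(0.1, 0.05), c(0, 100), c(0.1, 0.1),
                  c(0.05, 0.05))
  expect_equal(clinical_dose(d_fx, m1)$values, d_fx$values)
})

test_that("plan recalculation scales per-fraction effect linearly in fractions", {
  infl <- dense_influence(matrix(2), let = 10)
  d <- recalc_plan(1, infl, identity_model(), fractions = 10)
  expect_equal(d$values, 20)   # photon identity: 2 Gy/fraction x 10
  expect_equal(recalc_plan(0, infl, identity_model(), 10)$values, 0)
})

test_that("entrance-region dose ordering follows the alpha-table ordering", {
  # at entrance LET the LEM-like alpha exceeds the MKM-like alpha, so the
  # same mixed field converts to a higher LEM-like photon-equivalent dose
  mods <- default_rbe_models()
  g <- voxel_grid(c(1, 1, 1), 10)
  infl <- influence_set(matrix(1), matrix(15), mods, g)
  d_lem <- recalc_plan(2, infl, mods$LEMlike)
  d_mkm <- recalc_plan(2, infl, mods$MKMlike)
  expect_gt(d_lem$values, d_mkm$values)
})
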