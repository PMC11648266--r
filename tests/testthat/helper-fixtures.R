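# shared fixtures, all built in code

# an RBE model whose tables equal the photon reference at every LET:
# mixed-field biology then reproduces the physical dose exactly
identity_model <- function(name = "photon_id", alpha_x = 0.1, beta_x = 0.05) {
  rbe_model(name, photon_lq(alpha_x, beta_x),
            let = c(0, 200), alpha = c(alpha_x, alpha_x),
            beta = c(beta_x, beta_x))
}

tiny_grid <- function(dims = c(4, 4, 4), spacing = 2) voxel_grid(dims, spacing)

# influence set over a dense dose matrix on a one-row-per-voxel grid
dense_influence <- function(d, let = 10, models = list(identity_model())) {
  g <- voxel_grid(c(nrow(d), 1, 1), 1)
  influence_set(d, let, models, g)
}

# a single-voxel, single-beamlet problem with photon-identity biology
one_voxel_problem <- function(d = 0.5, prescription = 2, fractions = 1L) {
  g <- voxel_grid(c(1, 1, 1), 10)
  infl <- influence_set(matrix(d), 10, list(id = identity_model("id")), g)
  rois <- list(T = roi_mask("T", "target", TRUE, g))
  plan_problem(infl, rois,
               list(cost_term("T", "id", "uniform", prescription)),
               fractions = fractions)
}

# seeded random sparse problem for gradient checks: nv voxels, nb beamlets,
# two models with LET-dependent tables
random_problem <- function(nv = 12, nb = 5, seed = 1) {
  set.seed(seed)
  g <- voxel_grid(c(nv, 1, 1), 1)
  d <- matrix(stats::runif(nv * nb), nv, nb)
  d[d < 0.4] <- 0
  let <- matrix(stats::runif(nv * nb, 10, 90), nv, nb)
  models <- default_rbe_models()[c("LEMlike", "MKMlike")]
  infl <- influence_set(d, let, models, g)
  tmask <- rep(FALSE, nv); tmask[1:ceiling(nv / 2)] <- TRUE
  omask <- !tmask
  rois <- list(T = roi_mask("T", "target", tmask, g),
               O = roi_mask("O", "oar", omask, g))
  terms <- list(cost_term("T", "LEMlike", "uniform", 3),
                cost_term("T", "MKMlike", "min_dose", 2.5, priority = 2),
                cost_term("O", "LEMlike", "max_dose", 1, priority = 0.5),
                cost_term("O", "MKMlike", "dvh_max", 0.8, volume_param = 30,
                          priority = 0.7))
  plan_problem(infl, rois, terms, fractions = 2L)
}

# micro end-to-end config for fast pipeline tests
micro_config <- function(scenario = "A") {
  cfg <- standard_config("mini", scenario)
  cfg$phantom <- list(dims = c(14, 14, 8), spacing = 3,
                      ctv = list(shape = "box", size = c(15, 15, 15)),
                      oars = list(list(name = "OAR", shape = "box",
                                       center = c(21, 31.5, 12),
                                       size = c(15, 6, 15))))
  cfg$beams <- lapply(cfg$beams, function(b) { b$spot_spacing <- 7; b })
  cfg$solver <- list(max_iter = 60L, grad_tol = 1e-4)
  cfg$name <- sprintf("micro.%s", scenario)
  cfg
}

# independent sort-and-count DVH oracles (brute force over candidate levels)
oracle_dose_at_volume <- function(v, x) {
  cand <- sort(unique(v), decreasing = TRUE)
  ok <- vapply(cand, function(D) 100 * mean(v >= D) >= x - 1e-12, TRUE)
  max(cand[ok])
}
oracle_volume_at_dose <- function(v, level) 100 * sum(v >= level) / length(v)
oracle_dose_at_cc <- function(v, voxel_cc, cc) {
  cand <- sort(unique(v), decreasing = TRUE)
  ok <- vapply(cand, function(D) sum(v >= D) * voxel_cc >= cc - 1e-12, TRUE)
  max(cand[ok])
}
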