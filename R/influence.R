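#' Construct an influence set from explicit dose and LET matrices
#'
#' Low-level constructor linking beamlet weights to voxel biology: from a
#' physical dose-influence matrix `d` (voxel x beamlet, Gy per unit weight)
#' and matching per-entry LET values, precomputes for every registered model
#' the alpha-influence `a_ij = alpha_m(LET_ij) * d_ij` and sqrt(beta)-influence
#' `b_ij = sqrt(beta_m(LET_ij)) * d_ij` blocks on the shared sparsity pattern
#' of `d`. Mostly useful for tests and custom pipelines;
#' [assemble_influence()] builds the same structure from beamlet kernels.
#'
#' @param d dense or `Matrix` sparse voxel-by-beamlet dose matrix (>= 0).
#' @param let matrix of the same shape with the dose-averaged LET seen by
#'   each (voxel, beamlet) pair, or a single value.
#' @param models named list of [rbe_model] objects.
#' @param grid the [voxel_grid] (rows of `d` must match its voxel count).
#' @param beamlets optional `spot_list` carried along for bookkeeping.
#' @return object of class `influence_set` with fields `d`, `a` (per model),
#'   `b` (per model), `grid`, `beamlets`, `models`.
#' @export
influence_set <- function(d, let, models, grid, beamlets = NULL) {
  d <- methods::as(methods::as(Matrix::Matrix(d, sparse = TRUE), "generalMatrix"),
                   "CsparseMatrix")
  if (nrow(d) != n_voxels(grid))
    stopf("dose matrix has %d rows but the grid has %d voxels", nrow(d), n_voxels(grid))
  if (any(d@x < 0)) stopf("dose-influence entries must be nonnegative")
  if (length(let) == 1L) {
    let_x <- rep(as.numeric(let), length(d@x))
  } else {
    if (!all(dim(let) == dim(d))) stopf("'let' must match the shape of 'd'")
    # pull LET at the sparse entries of d
    ijd <- Matrix::summary(d)
    let_x <- as.matrix(let)[cbind(ijd$i, ijd$j)]
  }
  build_influence(d, let_x, models, grid, beamlets)
}

# shared finalizer: attach per-model a/b blocks on d's sparsity pattern
build_influence <- function(d, let_x, models, grid, beamlets) {
  if (!length(models)) stopf("at least one RBE model is required")
  if (is.null(names(models)))
    names(models) <- vapply(models, `[[`, "", "name")
  a <- list(); b <- list()
  for (m in models) {
    if (!inherits(m, "rbe_model")) stopf("model table missing or invalid")
    ab <- model_alpha_beta(m, let_x)
    am <- d; am@x <- ab$alpha * d@x
    bm <- d; bm@x <- sqrt(ab$beta) * d@x
    a[[m$name]] <- am; b[[m$name]] <- bm
  }
  structure(list(d = d, a = a, b = b, grid = grid, beamlets = beamlets,
                 models = models),
            class = "influence_set")
}

#' @export
print.influence_set <- function(x, ...) {
  cat(sprintf("influence_set: %d voxels x %d beamlets, %d nonzeros, models: %s\n",
              nrow(x$d), ncol(x$d), length(x$d@x),
              paste(names(x$a), collapse = ", ")))
  invisible(x)
}

#' Assemble the sparse multi-model dose-influence data
#'
#' For every beamlet, computes the pencil-beam kernel
#' ([beamlet_dose_kernel()]) and the dose-averaged LET at each covered
#' voxel's depth along that beam, then precomputes the per-model
#' alpha/sqrt(beta) influence blocks. Each beamlet carries its own LET at a
#' voxel; mixing across beamlets happens through the summation of the a/b
#' blocks. Deterministic.
#'
#' @param grid the [voxel_grid].
#' @param beamlets a `spot_list` (from [build_spot_list()], possibly row-bound
#'   over several beams); >= 1 row.
#' @param params a [depth_curve_params].
#' @param models named list of [rbe_model] objects (>= 1).
#' @return an `influence_set`; see [influence_set()].
#' @export
assemble_influence <- function(grid, beamlets, params, models) {
  if (!is.data.frame(beamlets) || nrow(beamlets) < 1L)
    stopf("at least one beamlet is required")
  nb <- nrow(beamlets)
  nv <- n_voxels(grid)
  ii <- vector("list", nb); xx <- ii; ll <- ii
  bl <- as.list(beamlets)
  for (j in seq_len(nb)) {
    k <- beamlet_dose_kernel(lapply(bl, `[[`, j), grid, params)
    ii[[j]] <- k$idx; xx[[j]] <- k$dose; ll[[j]] <- k$let
  }
  nper <- lengths(ii)
  d <- Matrix::sparseMatrix(i = as.integer(unlist(ii, use.names = FALSE)),
                            p = as.integer(c(0, cumsum(nper))),
                            x = as.numeric(unlist(xx, use.names = FALSE)),
                            dims = c(nv, nb))
  build_influence(d, unlist(ll, use.names = FALSE), models, grid, beamlets)
}

#' Physical dose delivered by a set of beamlet weights
#'
#' Linear accumulation `D = d %*% w`.
#'
#' @param weights nonnegative beamlet weights.
#' @param infl an [influence_set].
#' @return numeric per-voxel physical dose, Gy.
#' @export
physical_dose <- function(weights, infl) {
  stopifnot(inherits(infl, "influence_set"))
  if (length(weights) != ncol(infl$d))
    stopf("weight vector has length %d but there are %d beamlets",
          length(weights), ncol(infl$d))
  weights <- chk_num(weights, "weights", lower = 0)
  as.numeric(infl$d %*% weights)
}
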