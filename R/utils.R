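# internal helpers shared across modules

stopf <- function(...) stop(sprintf(...), call. = FALSE)

`%||%` <- function(a, b) if (is.null(a)) b else a

# numeric scalar/vector validation; `strict` excludes the lower bound
chk_num <- function(x, name, len = NULL, lower = -Inf, upper = Inf,
                    strict = FALSE) {
  if (!is.numeric(x) || anyNA(x)) stopf("'%s' must be numeric without NAs", name)
  if (!is.null(len) && length(x) != len)
    stopf("'%s' must have length %d", name, len)
  if (any(!is.finite(x))) stopf("'%s' must be finite", name)
  if (strict) {
    if (any(x <= lower)) stopf("'%s' must be > %g", name, lower)
  } else if (any(x < lower)) stopf("'%s' must be >= %g", name, lower)
  if (any(x > upper)) stopf("'%s' must be <= %g", name, upper)
  as.numeric(x)
}

chk_flag_mask <- function(mask, n, name = "mask") {
  if (!is.logical(mask) || anyNA(mask)) stopf("'%s' must be logical without NAs", name)
  if (length(mask) != n)
    stopf("'%s' has length %d but the grid has %d voxels", name, length(mask), n)
  mask
}
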