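# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

iso8601 <- function(t) format(t, "%Y-%m-%dT%H:%M:%S", tz = "UTC", usetz = FALSE)

check_scalar <- function(x, name, lower = -Inf, upper = Inf,
                         strict_lower = FALSE, strict_upper = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("`%s` must be a single finite number", name), call. = FALSE)
  lo_bad <- if (strict_lower) x <= lower else x < lower
  hi_bad <- if (strict_upper) x >= upper else x > upper
  if (lo_bad || hi_bad)
    stop(sprintf("`%s` = %g is outside the allowed range %s%g, %g%s", name, x,
                 if (strict_lower) "(" else "[", lower, upper,
                 if (strict_upper) ")" else "]"), call. = FALSE)
  invisible(x)
}

check_raster <- function(x, name) {
  if (!is.matrix(x) || !is.numeric(x))
    stop(sprintf("`%s` must be a numeric matrix", name), call. = FALSE)
  invisible(x)
}

check_binary_mask <- function(mask, name = "mask") {
  check_raster(mask, name)
  if (anyNA(mask) || !all(mask == 0L | mask == 1L))
    stop(sprintf("`%s` must be strictly binary (values 0/1)", name),
         call. = FALSE)
  storage.mode(mask) <- "integer"
  mask
}

# Deterministic sub-seeds (all < 2^31) derived from one user seed, so that
# composite simulations can seed each stage independently.
derive_seeds <- function(seed, n) {
  if (is.null(seed)) return(rep(list(NULL), n))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  as.list(sample.int(.Machine$integer.max - 1L, n))
}
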