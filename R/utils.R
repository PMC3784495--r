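# shared small helpers (internal)

`%||%` <- function(a, b) if (is.null(a)) b else a

# wrap an angle in radians to (-pi, pi]
wrap_pi <- function(phi) {
  w <- (phi + pi) %% (2 * pi) - pi
  w[w <= -pi] <- pi  # map the -pi boundary to +pi (half-open convention)
  w
}

# wrap an angle in degrees to (-180, 180]
wrap_deg <- function(theta) {
  w <- (theta + 180) %% 360 - 180
  w[w <= -180] <- 180
  w
}

stopifnot_finite <- function(x, what = "values") {
  if (!all(is.finite(x)))
    stop("non-finite ", what, " are not allowed", call. = FALSE)
  invisible(TRUE)
}

# write a data.frame as a plain TSV (no quoting, no row names)
write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

vec_norm <- function(v) sqrt(sum(v^2))

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# seeded evaluation that does not clobber the caller's RNG stream
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(eval.parent(substitute(expr)))
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  eval.parent(substitute(expr))
}
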