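# Small numeric helpers shared across the package.

`%||%` <- function(a, b) if (is.null(a)) b else a

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

norm3 <- function(v) sqrt(sum(v * v))

unit3 <- function(v) {
  n <- norm3(v)
  if (n < 1e-15) stop("cannot normalise a zero vector", call. = FALSE)
  v / n
}

# Rodrigues rotation of vector v about unit axis k by angle (degrees).
rotate_about <- function(v, k, angle_deg) {
  th <- angle_deg * pi / 180
  k <- unit3(k)
  v * cos(th) + cross3(k, v) * sin(th) + k * sum(k * v) * (1 - cos(th))
}

# Evaluate `code` under a temporary RNG state seeded with `seed`; the caller's
# RNG stream is untouched. A NULL seed uses (and advances) the global stream.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

stop_classed <- function(class, message, ...) {
  cond <- structure(
    class = c(class, "stereoloc_error", "error", "condition"),
    list(message = message, call = sys.call(-1), ...)
  )
  stop(cond)
}
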