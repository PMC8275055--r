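# Independent oracles used to freeze expected values: each one solves the
# forward problem by a different route than the package internals.

# Point on a plane from its basis expansion.
oracle_plane_point <- function(plane, u, v) {
  plane$origin + u * plane$e_u + v * plane$e_v
}

# Bar/plane intersection by solving the 3x3 linear system
#   origin + u e_u + v e_v = p0 + t (p1 - p0)
# (a different formulation than the normal-projection used in the package).
oracle_intersect <- function(bar, plane) {
  p0 <- c(bar$x0, bar$y0, bar$z0)
  p1 <- c(bar$x1, bar$y1, bar$z1)
  A <- cbind(plane$e_u, plane$e_v, -(p1 - p0))
  if (abs(det(A)) < 1e-12) return(NULL)
  s <- solve(A, p0 - plane$origin)
  if (s[3] < 0 || s[3] >= 1) return(NULL)
  list(point = p0 + s[3] * (p1 - p0), u = s[1], v = s[2])
}

# Brute-force weighted normal equations for the affine fit.
oracle_fit <- function(corr, weighted = TRUE) {
  A <- cbind(corr$u, corr$v, 1)
  B <- cbind(corr$x, corr$y, corr$z)
  W <- diag(if (weighted) corr$w^2 else rep(1, nrow(corr)))
  solve(t(A) %*% W %*% A) %*% (t(A) %*% W %*% B)
}

# All true fiducials of a frame in a plane, by the oracle intersection.
oracle_fiducials <- function(frame, plane) {
  out <- list()
  for (i in seq_len(nrow(frame$bars))) {
    hit <- oracle_intersect(frame$bars[i, ], plane)
    if (is.null(hit)) next
    out[[length(out) + 1]] <- data.frame(
      panel = frame$bars$panel[i], bar = frame$bars$bar[i],
      u = hit$u, v = hit$v, stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

# Strip labels so a fiducial table exercises the unlabeled bootstrap path.
strip_labels <- function(fids) {
  fids$bar <- NA_character_
  fids$panel <- NA_character_
  fids$role <- NA_character_
  fids$members <- NA_character_
  fids
}

expect_point_equal <- function(p, q, tol = 1e-9) {
  expect_lt(max(abs(as.numeric(p) - as.numeric(q))), tol)
}
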