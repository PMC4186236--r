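# Small planar-geometry helpers shared by the somatic level.

#' Wrap an angle to [-pi, pi)
#' @param theta angle(s) in radians.
#' @return wrapped angle(s).
#' @export
wrap_angle <- function(theta) {
  out <- (theta + pi) %% (2 * pi) - pi
  # %% can return 2*pi - eps for inputs just below -pi, mapping to +pi exactly
  out[out >= pi] <- -pi
  out
}

# Parametric intersection of motion p -> p + d*t (t in [0,1]) with segment
# (a, b). Returns t at contact or Inf.
ray_segment_t <- function(p, d, a, b) {
  e <- b - a
  denom <- d[1] * e[2] - d[2] * e[1]
  if (abs(denom) < 1e-14) return(Inf)
  ap <- a - p
  t <- (ap[1] * e[2] - ap[2] * e[1]) / denom
  u <- (ap[1] * d[2] - ap[2] * d[1]) / denom
  if (t >= 0 && t <= 1 && u >= -1e-12 && u <= 1 + 1e-12) t else Inf
}

# Move from `from` toward `to`. Interior walls stop motion at the wall
# face (no pass-through, no sliding). The outer boundary acts as a guard
# rail: the target is clamped coordinate-wise, so motion slides along the
# boundary instead of freezing in corners. A tiny inset keeps the agent
# strictly off interior walls so later moves do not start degenerate.
clip_move <- function(arena, from, to) {
  to <- pmin(pmax(to, c(0, 0)), c(arena$width, arena$height))
  d <- to - from
  if (all(d == 0)) return(from)
  tmax <- 1
  for (w in arena$walls) {
    tw <- ray_segment_t(from, d, c(w[1], w[2]), c(w[3], w[4]))
    if (tw < tmax) tmax <- tw
  }
  if (tmax < 1) tmax <- max(0, tmax - 1e-9 / max(sqrt(sum(d^2)), 1e-12))
  pos <- from + tmax * d
  pmin(pmax(pos, c(0, 0)), c(arena$width, arena$height))
}

# Euclidean norm of a 2-vector.
vnorm <- function(v) sqrt(sum(v * v))
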