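# Geometric fixtures built in code.

equilateral_triangle <- function(side = 2) {
  rbind(c(0, 0, 0), c(side, 0, 0), c(side / 2, side * sqrt(3) / 2, 0))
}

# Two far-separated equilateral triangles (locality of the alpha complex).
two_triangles <- function(side = 2, gap = 100) {
  t1 <- equilateral_triangle(side)
  rbind(t1, sweep(t1, 2, c(gap, 0, 0), "+"))
}

# Irregular convex planar pentagon with a single 1-cycle.
pentagon_points <- function() {
  ang <- c(0.1, 1.4, 2.7, 4.0, 5.2)
  r <- c(1.9, 2.2, 1.8, 2.1, 2.0)
  cbind(r * cos(ang), r * sin(ang), 0)
}

# Six points reproducing the two-vs-three-triangle volume comparison: a
# generic convex quadrilateral hole (optimal filling: two triangles across a
# diagonal) with two outer points offering a three-triangle detour filling.
six_point_volume_fixture <- function() {
  rbind(c(0.0, 0.0, 0), c(2.6, 0.0, 0), c(2.4, 1.9, 0), c(0.2, 1.7, 0),
        c(1.2, 3.1, 0), c(3.6, 1.0, 0))
}

regular_tetrahedron <- function(edge = 2) {
  rbind(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1), c(-1, -1, 1)) *
    edge / (2 * sqrt(2))
}

random_rigid_motion <- function(P, seed) {
  set.seed(seed)
  ax <- rnorm(3); ax <- ax / sqrt(sum(ax^2))
  ang <- runif(1, 0, 2 * pi)
  K <- matrix(c(0, -ax[3], ax[2], ax[3], 0, -ax[1], -ax[2], ax[1], 0), 3, 3,
              byrow = TRUE)
  Rm <- diag(3) * cos(ang) + sin(ang) * K + (1 - cos(ang)) * tcrossprod(ax)
  sweep(P %*% t(Rm), 2, rnorm(3, sd = 10), "+")
}
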