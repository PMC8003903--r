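# Independent oracles used across the suite. These deliberately re-derive
# quantities with different algorithms than the package (plain-R geometry,
# enumeration, permutation, profiled 1-D optimisation) so that agreement is
# informative.

# --- point-to-triangle distance, plain R ------------------------------
# Projects onto the triangle plane and tests the foot by barycentric
# coordinates; otherwise takes the minimum over the three edge segments.
# Different decomposition than the compiled Ericson region walk.

.seg_dist2 <- function(p, a, b) {
  ab <- b - a
  t <- sum((p - a) * ab) / sum(ab * ab)
  t <- min(1, max(0, t))
  q <- a + t * ab
  sum((p - q)^2)
}

.tri_dist_oracle <- function(p, a, b, c) {
  n <- c((b - a)[2] * (c - a)[3] - (b - a)[3] * (c - a)[2],
         (b - a)[3] * (c - a)[1] - (b - a)[1] * (c - a)[3],
         (b - a)[1] * (c - a)[2] - (b - a)[2] * (c - a)[1])
  n2 <- sum(n * n)
  dist2 <- Inf
  if (n2 > 0) {
    dplane <- sum((p - a) * n) / sqrt(n2)
    foot <- p - dplane * n / sqrt(n2)
    # barycentric coordinates of the foot
    v0 <- c - a; v1 <- b - a; v2 <- foot - a
    d00 <- sum(v0 * v0); d01 <- sum(v0 * v1); d11 <- sum(v1 * v1)
    d20 <- sum(v2 * v0); d21 <- sum(v2 * v1)
    den <- d00 * d11 - d01 * d01
    u <- (d11 * d20 - d01 * d21) / den
    v <- (d00 * d21 - d01 * d20) / den
    if (u >= 0 && v >= 0 && u + v <= 1) dist2 <- dplane^2
  }
  min(dist2, .seg_dist2(p, a, b), .seg_dist2(p, b, c), .seg_dist2(p, a, c))
}

# brute-force double loop over all vertex-triangle pairs
mesh_dist_oracle <- function(points, mesh) {
  v <- mesh$vertices; f <- mesh$faces
  apply(points, 1, function(p) {
    sqrt(min(vapply(seq_len(nrow(f)), function(t) {
      .tri_dist_oracle(p, v[f[t, 1], ], v[f[t, 2], ], v[f[t, 3], ])
    }, 0)))
  })
}

# --- nonlinear monoexponential fit oracle -----------------------------
# Profiled 1-D least squares: for fixed T2 the optimal S0 is closed-form,
# so the nonlinear fit reduces to optimize() over T2.
nls_t2_oracle <- function(signal, te, lower = 1, upper = 500) {
  sse <- function(t2) {
    e <- exp(-te / t2)
    s0 <- sum(signal * e) / sum(e * e)
    sum((signal - s0 * e)^2)
  }
  stats::optimize(sse, c(lower, upper))$minimum
}

# --- Wilcoxon signed-rank enumeration oracle --------------------------
# Exact two-sided p by full enumeration of all 2^n sign assignments.
wilcoxon_enum_oracle <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  w_plus <- sum(r[d > 0])
  w_minus <- sum(r) - w_plus
  t_obs <- min(w_plus, w_minus)
  count <- 0L
  for (mask in 0:(2^n - 1)) {
    signs <- bitwAnd(mask, 2^(seq_len(n) - 1)) > 0
    wp <- sum(r[signs])
    wm <- sum(r) - wp
    if (min(wp, wm) <= t_obs) count <- count + 1L
  }
  min(1, count / 2^n)  # two tails counted via min(W+, W-)
}

# --- Friedman permutation oracle --------------------------------------
# Monte-Carlo permutation p: chi-squared statistic recomputed from scratch
# under random within-row reorderings.
friedman_perm_oracle <- function(m, n_perm = 20000, seed = 99) {
  chi <- function(mm) {
    r <- t(apply(mm, 1, rank))
    n <- nrow(mm); k <- ncol(mm)
    rj <- colSums(r)
    a1 <- sum(r^2); c1 <- n * k * (k + 1)^2 / 4
    den <- a1 - c1
    if (den <= 0) return(0)
    (k - 1) * sum((rj - n * (k + 1) / 2)^2) / den
  }
  obs <- chi(m)
  set.seed(seed)
  hits <- 0L
  for (i in seq_len(n_perm)) {
    mp <- t(apply(m, 1, sample))
    if (chi(mp) >= obs - 1e-12) hits <- hits + 1L
  }
  (hits + 1) / (n_perm + 1)
}

# --- repeated-measures ANOVA sums-of-squares oracle -------------------
# From-scratch cell-by-cell decomposition (explicit loops, no matrix
# shortcuts).
rm_anova_oracle <- function(m) {
  n <- nrow(m); k <- ncol(m)
  gm <- mean(m)
  ss_time <- 0; ss_subj <- 0; ss_err <- 0
  for (j in 1:k) ss_time <- ss_time + n * (mean(m[, j]) - gm)^2
  for (i in 1:n) ss_subj <- ss_subj + k * (mean(m[i, ]) - gm)^2
  for (i in 1:n) {
    for (j in 1:k) {
      ss_err <- ss_err + (m[i, j] - mean(m[i, ]) - mean(m[, j]) + gm)^2
    }
  }
  f <- (ss_time / (k - 1)) / (ss_err / ((n - 1) * (k - 1)))
  list(F = f, p = stats::pf(f, k - 1, (n - 1) * (k - 1), lower.tail = FALSE))
}

# --- small meshes built in code ---------------------------------------

# rectangular planar patch in the z = z0 plane, nx x ny vertices
planar_patch <- function(nx, ny, dx = 1, z0 = 0, flip = FALSE) {
  v <- as.matrix(expand.grid(x = (0:(nx - 1)) * dx, y = (0:(ny - 1)) * dx))
  v <- cbind(v, z0)
  id <- function(i, j) (j - 1) * nx + i
  f <- list()
  for (j in 1:(ny - 1)) {
    for (i in 1:(nx - 1)) {
      f[[length(f) + 1]] <- c(id(i, j), id(i + 1, j), id(i + 1, j + 1))
      f[[length(f) + 1]] <- c(id(i, j), id(i + 1, j + 1), id(i, j + 1))
    }
  }
  f <- do.call(rbind, f)
  if (flip) f <- f[, c(1, 3, 2)]
  surface_mesh(v, f)
}

# closed UV sphere (reuses the generator's deterministic mesher)
sphere_mesh <- function(center, radius, res) {
  s <- qmricart:::.uv_sphere(center, radius, res)
  surface_mesh(s$vertices, s$faces)
}

random_rotation <- function(seed) {
  set.seed(seed)
  q <- rnorm(4); q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)
  ), 3, 3, byrow = TRUE)
}

# small phantom spec used across tests (desk-scale geometry)
tiny_spec <- function(seed = 1, ...) {
  args <- list(condyle_radius_medial = 8, condyle_radius_lateral = 7.5,
               condyle_separation = 26, mesh_resolution = 3,
               spacing = c(1.3, 1.3, 2.6), margin = 3, seed = seed)
  override <- list(...)
  args[names(override)] <- override
  do.call(phantom_spec, args)
}
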