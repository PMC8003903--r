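test_that("surface_mesh validates vertices and faces", {
  v <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0))
  expect_s3_class(surface_mesh(v, matrix(c(1L, 2L, 3L), 1)), "surface_mesh")
  expect_error(surface_mesh(rbind(v, c(NA, 0, 0)), matrix(c(1L, 2L, 3L), 1)),
               "non-finite")
  expect_error(surface_mesh(v, matrix(c(1L, 2L, 4L), 1)), "out of range")
  # zero-area face (repeated vertex)
  expect_error(surface_mesh(v, matrix(c(1L, 2L, 2L), 1)), "degenerate")
})

test_that("thickness on concentric spheres recovers the shell width", {
  bone <- sphere_mesh(c(0, 0, 0), 10, 1)
  cart <- sphere_mesh(c(0, 0, 0), 12, 1)
  tm <- compute_thickness(bone, cart)
  expect_true(all(tm$covered))
  # chordal error: outer sphere sags below the true sphere by <= r(1-cos)
  edge <- 1
  expect_lt(max(abs(tm$thickness - 2)), 2 * edge)
  expect_lt(max(abs(tm$thickness - 2)), 0.1)
})

test_that("thickness on parallel planar patches equals the offset", {
  bone <- planar_patch(9, 9, dx = 1, z0 = 0)
  cart <- planar_patch(9, 9, dx = 1, z0 = 1.5, flip = TRUE)
  tm <- compute_thickness(bone, cart, normal_check = FALSE)
  # interior vertices see the opposing plane directly above
  expect_equal(unname(tm$thickness), rep(1.5, 81), tolerance = 1e-12)
})

test_that("spatial index equals brute force and the plain-R oracle", {
  set.seed(42)
  sp <- qmricart:::.uv_sphere(c(0, 0, 0), 10, 2.5)
  v <- sp$vertices + matrix(rnorm(length(sp$vertices), 0, 0.15),
                            ncol = 3)  # perturbed, ~200 vertices
  mesh <- surface_mesh(v, sp$faces)
  pts <- matrix(runif(60 * 3, -14, 14), ncol = 3)
  di <- mesh_distance(pts, mesh, method = "index")$dist
  db <- mesh_distance(pts, mesh, method = "brute")$dist
  expect_identical(di, db)
  expect_lt(max(abs(di - mesh_dist_oracle(pts, mesh))), 1e-9)
})

test_that("thickness is invariant under joint rigid motion", {
  spec <- tiny_spec()
  mod <- make_condyle_models(spec)
  tm0 <- compute_thickness(mod$bone, mod$cartilage)
  r <- random_rotation(7)
  tr <- rigid_transform(r, c(5, -3, 11))
  bone2 <- surface_mesh(apply_transform(tr, mod$bone$vertices),
                        mod$bone$faces)
  cart2 <- surface_mesh(apply_transform(tr, mod$cartilage$vertices),
                        mod$cartilage$faces)
  tm1 <- compute_thickness(bone2, cart2)
  expect_lt(max(abs(tm0$thickness - tm1$thickness)), 1e-9)
  expect_identical(tm0$covered, tm1$covered)
})

test_that("inflating the cartilage outward raises thickness by at most delta", {
  spec <- tiny_spec()
  mod <- make_condyle_models(spec)
  tm0 <- compute_thickness(mod$bone, mod$cartilage)
  delta <- 0.4
  # push every cartilage vertex outward along its (radial) normal
  geom <- qmricart:::.condyle_geom(spec)
  v <- mod$cartilage$vertices
  side_m <- v[, 1] > 0
  dirs <- v
  dirs[side_m, ] <- sweep(v[side_m, , drop = FALSE], 2, geom$M$center, "-")
  dirs[!side_m, ] <- sweep(v[!side_m, , drop = FALSE], 2, geom$L$center, "-")
  dirs <- dirs / sqrt(rowSums(dirs^2))
  cart2 <- surface_mesh(v + delta * dirs, mod$cartilage$faces)
  tm1 <- compute_thickness(mod$bone, cart2)
  diff <- tm1$thickness[tm0$covered] - tm0$thickness[tm0$covered]
  expect_true(all(diff >= -1e-9))
  expect_true(all(diff <= delta + spec$mesh_resolution))
})

test_that("per-VOI thickness means aggregate covered vertices only", {
  spec <- tiny_spec(thickness_amp = 0)
  mod <- make_condyle_models(spec)
  part <- partition_vois(mod$bone, anatomical_frame())
  tm <- compute_thickness(mod$bone, mod$cartilage)
  agg <- mean_thickness_per_voi(tm, part)
  # constant-thickness phantom: every VOI mean equals the constant
  got <- agg$mean_mm[agg$n_vertices > 0]
  expect_true(all(abs(got - spec$thickness_base) < 0.1))
  # hand-built case: Ma vertices {1, 3} -> mean 2; empty VOI -> NA not 0
  fake_map <- structure(list(
    thickness = c(1, 3, 5), covered = c(TRUE, TRUE, FALSE),
    nearest_face = c(1L, 1L, 1L), n_vertices = 3L), class = "thickness_map")
  fake_part <- structure(list(
    vertex_voi = factor(c("Ma", "Ma", "Lc"),
                        levels = qmricart:::.VOI_LEVELS),
    vertex_subvoi = factor(rep(NA_character_, 3),
                           levels = qmricart:::.SUBVOI_LEVELS)),
    class = "voi_partition")
  agg2 <- mean_thickness_per_voi(fake_map, fake_part)
  expect_equal(agg2$mean_mm[agg2$voi == "Ma"], 2)
  expect_true(is.na(agg2$mean_mm[agg2$voi == "Lc"]))  # covered count is 0
  expect_equal(agg2$n_vertices[agg2$voi == "Lc"], 0L)
})

test_that("dense-sampling oracle matches per-VOI means on a gradient field", {
  spec <- tiny_spec(thickness_amp = 0.3, mesh_resolution = 1)
  mod <- make_condyle_models(spec)
  part <- partition_vois(mod$bone, anatomical_frame())
  tm <- compute_thickness(mod$bone, mod$cartilage)
  agg <- mean_thickness_per_voi(tm, part)
  # oracle: average the analytic field over a dense deterministic sample of
  # directions falling in each VOI (vertex-uniform quadrature)
  fine <- qmricart:::.uv_sphere(c(0, 0, 0), 1, 0.02 * pi)
  for (lab in c("Ma", "Lc", "Mp")) {
    side <- substr(lab, 1, 1)
    g <- qmricart:::.condyle_geom(spec)[[side]]
    pts <- sweep(fine$dirs * g$radius, 2, g$center, "+")
    truth <- qmricart:::.labels_for_dirs(spec, side, fine$dirs,
                                         abs(pts[, 1]), g$radius)
    fld <- qmricart:::.thickness_field(spec, fine$dirs)
    oracle <- mean(fld[truth$voi == lab])
    got <- agg$mean_mm[agg$voi == lab]
    expect_lt(abs(got - oracle) / oracle, 0.01)
  }
})
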