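test_that("world/voxel maps follow the zero-based voxel-center convention", {
  g <- image_geometry(origin = c(10, -5, 2), spacing = c(0.5, 1, 3),
                      dims = c(8, 8, 4))
  idx <- rbind(c(0, 0, 0), c(1, 2, 3), c(7, 7, 3))
  w <- voxel_to_world(g, idx)
  expect_equal(w[1, ], c(10, -5, 2))
  expect_equal(w[2, ], c(10.5, -3, 11))
  expect_equal(world_to_voxel(g, w), idx, tolerance = 1e-12)
  expect_error(image_geometry(c(0, 0, 0), c(1, 1, 1),
                              matrix(c(1, 0, 0, 1, 0, 0, 0, 0, 1), 3),
                              c(4, 4, 4)),
               "orthonormal")
})

test_that("header registration is identity and exposes world-to-voxel", {
  src <- image_geometry(c(0, 0, 0), c(0.365, 0.456, 0.7), dims = c(16, 16, 8))
  tgt <- image_geometry(c(0, 0, 0), c(0.313, 0.446, 3), dims = c(16, 16, 4))
  reg <- header_transform(src, tgt)
  expect_equal(reg$transform$rotation, diag(3))
  expect_equal(reg$transform$translation, c(0, 0, 0))
  # target origin shifted +5 mm on x: world (0,0,0) lands at voxel -5/dx
  tgt2 <- image_geometry(c(5, 0, 0), c(0.313, 0.446, 3), dims = c(16, 16, 4))
  reg2 <- header_transform(src, tgt2)
  vox <- reg2$world_to_voxel(rbind(c(0, 0, 0)))
  # independent affine built directly from the header fields
  aff <- diag(c(0.313, 0.446, 3))
  expect_equal(as.numeric(vox), as.numeric(solve(aff) %*% c(-5, 0, 0)),
               tolerance = 1e-12)
  expect_equal(vox[1, 1], -5 / 0.313, tolerance = 1e-12)
})

test_that("rigid transforms compose, invert and validate", {
  r <- random_rotation(2)
  tr <- rigid_transform(r, c(1, 2, 3))
  rt <- compose_transforms(invert_transform(tr), tr)
  expect_lt(max(abs(rt$rotation - diag(3))), 1e-9)
  expect_lt(max(abs(rt$translation)), 1e-9)
  pts <- matrix(rnorm(30), ncol = 3)
  back <- apply_transform(invert_transform(tr), apply_transform(tr, pts))
  expect_lt(max(abs(back - pts)), 1e-9)
  expect_error(rigid_transform(matrix(1, 3, 3)), "orthonormal")
  refl <- diag(c(-1, 1, 1))
  expect_error(rigid_transform(refl), "determinant")
  # correction transforms compose after the header mapping
  src <- image_geometry(c(0, 0, 0), c(1, 1, 1), dims = c(4, 4, 4))
  reg <- header_transform(src, src, correction = tr)
  expect_equal(reg$transform$rotation, tr$rotation)
})

test_that("VOI partition is a partition and is left-right balanced", {
  spec <- tiny_spec(condyle_radius_lateral = 8)  # symmetric phantom
  mod <- make_condyle_models(spec)
  part <- partition_vois(mod$bone, anatomical_frame())
  voi <- part$vertex_voi
  expect_false(anyNA(voi))  # every vertex gets exactly one VOI
  counts <- table(substr(as.character(voi), 1, 1))
  expect_lt(abs(counts[["M"]] - counts[["L"]]) / counts[["L"]], 0.02)
  # anterior sub-VOIs exactly tile the anterior VOIs
  sub <- as.character(part$vertex_subvoi)
  ant <- as.character(voi) %in% c("Ma", "La")
  expect_true(all(!is.na(sub[ant])))
  expect_true(all(is.na(sub[!ant])))
  expect_identical(substr(sub[ant], 1, 2), substr(as.character(voi)[ant], 1, 2))
  expect_error(partition_vois(mod$bone,
                              anatomical_frame(ap = c(1, 0, 0),
                                               ml = c(2, 0, 0))),
               "collinear")
})

test_that("partition is stable under joint rigid rotation", {
  spec <- tiny_spec()
  mod <- make_condyle_models(spec)
  part0 <- partition_vois(mod$bone, anatomical_frame())
  r <- random_rotation(9)
  bone2 <- surface_mesh(mod$bone$vertices %*% t(r), mod$bone$faces)
  fr2 <- anatomical_frame(ap = r %*% c(0, 1, 0), ml = r %*% c(1, 0, 0),
                          pd = r %*% c(0, 0, 1), notch_point = c(0, 0, 0))
  part1 <- partition_vois(bone2, fr2)
  expect_identical(as.character(part0$vertex_voi),
                   as.character(part1$vertex_voi))
  expect_identical(as.character(part0$vertex_subvoi),
                   as.character(part1$vertex_subvoi))
})

test_that("split_layers uses the declared 0.5 boundary", {
  expect_identical(split_layers(c(0.3, 0.5, 0.49999, 1, 0)),
                   c("deep", "superficial", "deep", "superficial", "deep"))
  expect_error(split_layers(c(0.2, 1.2)), "0, 1")
  set.seed(8)
  n <- 4000
  lay <- split_layers(runif(n))
  ci <- qbinom(c(0.005, 0.995), n, 0.5)
  expect_true(sum(lay == "deep") >= ci[1] && sum(lay == "deep") <= ci[2])
})

test_that("voxel depth is 0 on bone, 0.5 midway in a slab", {
  bone <- planar_patch(9, 9, dx = 1, z0 = 0)
  cart <- planar_patch(9, 9, dx = 1, z0 = 2, flip = TRUE)
  part <- structure(list(
    vertex_voi = factor(rep("Ma", 81), levels = qmricart:::.VOI_LEVELS),
    vertex_subvoi = factor(rep(NA_character_, 81),
                           levels = qmricart:::.SUBVOI_LEVELS)),
    class = "voi_partition")
  pts <- rbind(c(4, 4, 0), c(4, 4, 1), c(4, 4, 0.5), c(3.5, 3.5, 1.5))
  asg <- assign_voxels(pts, NULL, bone, cart, part)
  expect_equal(asg$depth, c(0, 0.5, 0.25, 0.75), tolerance = 1e-12)
  expect_identical(asg$layer, c("deep", "superficial", "deep", "superficial"))
  expect_true(all(asg$voi == "Ma"))
})

test_that("assign_voxels respects a supplied model-to-image transform", {
  spec <- tiny_spec(noise_sigma = 0)
  r <- render_multiecho(spec)
  mod <- make_condyle_models(spec)
  part <- partition_vois(mod$bone, anatomical_frame())
  a0 <- assign_voxels(r$truth$mask, r$volume$geometry, mod$bone,
                      mod$cartilage, part)
  # move the models by a rigid transform and declare it: same assignment
  tr <- rigid_transform(random_rotation(4), c(3, -2, 1))
  inv <- invert_transform(tr)
  bone2 <- surface_mesh(apply_transform(inv, mod$bone$vertices),
                        mod$bone$faces)
  cart2 <- surface_mesh(apply_transform(inv, mod$cartilage$vertices),
                        mod$cartilage$faces)
  a1 <- assign_voxels(r$truth$mask, r$volume$geometry, bone2, cart2, part,
                      transform = tr)
  expect_identical(a0$voi, a1$voi)
  expect_equal(a0$depth, a1$depth, tolerance = 1e-9)
})

test_that("voxel VOI labels match the generator truth at default resolution", {
  spec <- phantom_spec(noise_sigma = 0)  # package defaults = the stated geometry
  r <- render_multiecho(spec)
  mod <- make_condyle_models(spec)
  part <- partition_vois(mod$bone, anatomical_frame())
  asg <- assign_voxels(r$truth$mask, r$volume$geometry, mod$bone,
                       mod$cartilage, part)
  truth_voi <- r$truth$voi[asg$voxel]
  expect_gte(mean(asg$voi == truth_voi), 0.98)
  # relative depth agrees with the analytic shell depth
  expect_lt(mean(abs(asg$depth - r$truth$depth[asg$voxel])), 0.05)
})
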