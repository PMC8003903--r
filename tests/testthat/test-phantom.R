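test_that("phantom_spec enforces its invariants", {
  expect_error(phantom_spec(condyle_radius_medial = -1), "positive")
  expect_error(phantom_spec(thickness_amp = 1.2), "positive")
  expect_error(phantom_spec(noise_sigma = -1), ">= 0")
  expect_error(phantom_spec(condyle_separation = 10), "overlap")
  expect_error(phantom_spec(echo_times = c(10, 10, 20)), "ascending")
})

test_that("constant thickness field gives constant truth and closed meshes", {
  spec <- tiny_spec(thickness_base = 2.0, thickness_amp = 0)
  mod <- make_condyle_models(spec)
  expect_true(all(mod$truth_thickness == 2.0))
  # each closed component: every edge shared by exactly two faces
  edges <- rbind(mod$bone$faces[, c(1, 2)], mod$bone$faces[, c(2, 3)],
                 mod$bone$faces[, c(3, 1)])
  key <- paste(pmin(edges[, 1], edges[, 2]), pmax(edges[, 1], edges[, 2]))
  expect_true(all(table(key) == 2))
  # outward winding: face normals point away from the condyle centers
  fn <- face_normals(mod$bone)
  ctr <- mod$bone$vertices[mod$bone$faces[, 1], ]
  geom <- qmricart:::.condyle_geom(spec)
  cen <- t(vapply(ctr[, 1] > 0, function(m)
    if (m) geom$M$center else geom$L$center, numeric(3)))
  expect_true(all(rowSums(fn * (ctr - cen)) > 0))
})

test_that("same seed reproduces meshes and volumes bit for bit", {
  spec <- tiny_spec(seed = 42)
  m1 <- make_condyle_models(spec)
  m2 <- make_condyle_models(spec)
  expect_identical(m1$bone, m2$bone)
  expect_identical(m1$cartilage, m2$cartilage)
  r1 <- render_multiecho(spec)
  r2 <- render_multiecho(spec)
  expect_identical(r1$volume$data, r2$volume$data)
  # and serialized forms are byte-identical
  f1 <- tempfile(fileext = ".ply"); f2 <- tempfile(fileext = ".ply")
  write_mesh(m1$bone, f1); write_mesh(m2$bone, f2)
  expect_identical(readLines(f1), readLines(f2))
  unlink(c(f1, f2))
})

test_that("computed thickness matches generator truth within mesh tolerance", {
  spec <- tiny_spec()
  mod <- make_condyle_models(spec)
  tm <- compute_thickness(mod$bone, mod$cartilage)
  expect_true(all(tm$covered))
  expect_lt(max(abs(tm$thickness - mod$truth_thickness)),
            2 * spec$mesh_resolution)
})

test_that("noiseless rendering follows the closed-form signal model", {
  spec <- tiny_spec(noise_sigma = 0, t2_deep = 40, t2_surf = 40, s0 = 1000)
  r <- render_multiecho(spec)
  e40 <- which(spec$echo_times == 40)
  sig <- r$volume$data[, , , e40]
  expect_equal(unname(sig[r$truth$mask]),
               rep(1000 * exp(-1), sum(r$truth$mask)), tolerance = 1e-12)
  expect_true(all(sig[!r$truth$mask] == 0))
})

test_that("background magnitudes follow a Rayleigh law", {
  spec <- tiny_spec(noise_sigma = 12)
  r <- render_multiecho(spec)
  bg <- r$volume$data[, , , 1][!r$truth$mask]
  set.seed(1)
  bg <- sample(bg, 3000)
  ks <- suppressWarnings(stats::ks.test(bg, function(q)
    1 - exp(-q^2 / (2 * 12^2))))
  expect_gt(ks$p.value, 0.01)
})

test_that("progression multipliers do exact bookkeeping in the truth table", {
  spec <- tiny_spec()
  pm <- progression_model(
    t2_mult = list(KL2 = c(Ma = 1.10, Mc = 1.10, Mp = 1.10), KL3 = NULL),
    th_mult = list(KL2 = NULL, KL3 = c(Mc = 0.85)))
  coh <- simulate_cohort(3, spec, pm, render = FALSE, keep_cells = FALSE)
  tr <- coh$truth
  for (k in 1:3) {
    base <- tr[tr$knee == k & tr$timepoint == "KL1", ]
    kl2 <- tr[tr$knee == k & tr$timepoint == "KL2", ]
    kl3 <- tr[tr$knee == k & tr$timepoint == "KL3", ]
    g <- function(df, fam, m) df$value[df$family == fam & df$measure == m]
    # +10% exactly in medial VOIs (and their sub-VOIs) at KL2
    for (m in c("Ma", "Mc", "Mp", "Mac", "Mae", "Mai")) {
      expect_equal(g(kl2, "t2", m), 1.10 * g(base, "t2", m))
    }
    expect_equal(g(kl2, "t2", "La"), g(base, "t2", "La"))  # untouched
    expect_equal(g(kl3, "thickness", "Mc"), 0.85 * g(base, "thickness", "Mc"))
    expect_equal(g(kl3, "t2", "Mc"), g(base, "t2", "Mc"))  # KL3 t2 identity here
  }
})

test_that("identity progression with zero variability freezes the knee", {
  spec <- tiny_spec(noise_sigma = 0)
  pm <- null_progression_model(t2_bkv = 0, th_bkv = 0, size_bkv = 0,
                               scan_t2 = 0, scan_th = 0)
  cells <- lapply(1:3, function(tp)
    simulate_knee_timepoint(spec, pm, knee = 1, timepoint = tp, seed = 9))
  expect_identical(cells[[1]]$models$bone, cells[[2]]$models$bone)
  expect_identical(cells[[1]]$models$cartilage, cells[[3]]$models$cartilage)
  expect_identical(cells[[1]]$render$volume$data, cells[[2]]$render$volume$data)
  expect_identical(cells[[2]]$render$volume$data, cells[[3]]$render$volume$data)
})

test_that("cohort cells are reproducible independently of generation order", {
  spec <- tiny_spec()
  pm <- progression_model()
  coh <- simulate_cohort(3, spec, pm, seed = 77, render = TRUE)
  solo <- simulate_knee_timepoint(spec, pm, knee = 2, timepoint = 3, seed = 77)
  expect_identical(coh$cells[[2]][[3]]$render$volume$data,
                   solo$render$volume$data)
  expect_identical(coh$cells[[2]][[3]]$models$cartilage, solo$models$cartilage)
})

test_that("thickness multipliers reach the cartilage mesh, not the bone", {
  spec <- tiny_spec(thickness_amp = 0, thickness_base = 2.0)
  m0 <- make_condyle_models(spec)
  m1 <- make_condyle_models(spec, th_mult = c(Mc = 0.5))
  expect_identical(m0$bone, m1$bone)
  mc <- m1$vertex_voi == "Mc"
  expect_true(all(m1$truth_thickness[mc] == 1.0))
  expect_true(all(m1$truth_thickness[!mc] == 2.0))
})
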