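#' Synthetic bi-condylar knee phantom specification
#'
#' The phantom models the two femoral condyles as smooth spherical lobes
#' separated across an intercondylar notch plane (x = 0; +x is medial, +y
#' anterior, +z proximal). The subchondral bone surface of each condyle is a
#' sphere; the cartilage surface is the bone surface offset outward along
#' vertex normals by a smooth, strictly positive thickness field. Ground
#' truth T2 varies with relative depth (lower near bone, higher near the
#' articular surface). Real anatomy is not reproduced, only its topology.
#'
#' Default acquisition geometry follows a clinical MSME T2 protocol:
#' echo times 10-70 ms in 10 ms steps and anisotropic voxels of
#' 0.313 x 0.446 x 3 mm.
#'
#' @param condyle_radius_medial,condyle_radius_lateral bone radii (mm).
#' @param condyle_separation center-to-center distance (mm); must exceed the
#'   two cartilage-inclusive radii.
#' @param thickness_base baseline cartilage thickness (mm).
#' @param thickness_amp relative smooth anterior-posterior modulation of the
#'   thickness field (|amp| < 1 keeps the field positive).
#' @param t2_deep,t2_surf ground-truth T2 (ms) at the bone and articular
#'   surfaces; T2 is linear in relative depth between them.
#' @param s0 noiseless signal at TE = 0 (arbitrary units).
#' @param noise_sigma Rician noise scale (signal units, >= 0).
#' @param mesh_resolution target triangle edge length (mm).
#' @param spacing MSME voxel spacing (mm).
#' @param margin background margin (mm) around the condyles in the rendered
#'   grid.
#' @param echo_times MSME echo times (ms), strictly ascending.
#' @param ap_fractions,ml_fractions VOI boundary fractions used for the
#'   ground-truth labels (same convention as [partition_vois()]).
#' @param seed integer; fixes all randomness derived from this spec.
#' @return An object of class `phantom_spec`.
#' @export
#' @examples
#' spec <- phantom_spec(mesh_resolution = 4)
phantom_spec <- function(condyle_radius_medial = 16,
                         condyle_radius_lateral = 15,
                         condyle_separation = 44,
                         thickness_base = 2.2,
                         thickness_amp = 0.15,
                         t2_deep = 35, t2_surf = 55,
                         s0 = 1000, noise_sigma = 15,
                         mesh_resolution = 1.5,
                         spacing = c(0.313, 0.446, 3),
                         margin = 4,
                         echo_times = seq(10, 70, 10),
                         ap_fractions = c(1, 2) / 3,
                         ml_fractions = c(1, 2) / 3,
                         seed = 1L) {
  .assert(condyle_radius_medial > 0 && condyle_radius_lateral > 0,
          "condyle radii must be positive")
  .assert(thickness_base > 0, "thickness_base must be positive")
  .assert(abs(thickness_amp) < 1,
          "thickness_amp must have magnitude < 1 (thickness field must stay positive)")
  .assert(t2_deep > 0 && t2_surf > 0, "T2 field must be positive")
  .assert(s0 > 0, "s0 must be positive")
  .assert(noise_sigma >= 0, "noise_sigma must be >= 0")
  .assert(mesh_resolution > 0, "mesh_resolution must be positive")
  .assert(length(spacing) == 3 && all(spacing > 0), "spacing must be 3 positive values")
  .assert(all(diff(echo_times) > 0) && length(echo_times) >= 3,
          "echo_times must be >= 3 strictly ascending values")
  tmax <- thickness_base * (1 + abs(thickness_amp)) * 1.5  # headroom for progression
  .assert(condyle_separation >
            condyle_radius_medial + condyle_radius_lateral + 2 * tmax,
          "condyles overlap: increase condyle_separation")
  structure(list(
    condyle_radius_medial = condyle_radius_medial,
    condyle_radius_lateral = condyle_radius_lateral,
    condyle_separation = condyle_separation,
    thickness_base = thickness_base, thickness_amp = thickness_amp,
    t2_deep = t2_deep, t2_surf = t2_surf,
    s0 = s0, noise_sigma = noise_sigma,
    mesh_resolution = mesh_resolution, spacing = as.numeric(spacing),
    margin = margin, echo_times = as.numeric(echo_times),
    ap_fractions = ap_fractions, ml_fractions = ml_fractions,
    seed = as.integer(seed)
  ), class = "phantom_spec")
}

# condyle centers and radii; medial on +x
.condyle_geom <- function(spec) {
  list(
    M = list(center = c(+spec$condyle_separation / 2, 0, 0),
             radius = spec$condyle_radius_medial),
    L = list(center = c(-spec$condyle_separation / 2, 0, 0),
             radius = spec$condyle_radius_lateral)
  )
}

# thickness field (mm) as a function of unit direction on a condyle
.thickness_field <- function(spec, dirs) {
  spec$thickness_base * (1 + spec$thickness_amp * dirs[, 2])
}

# per-point VOI / sub-VOI truth labels for points on or around one condyle
.labels_for_dirs <- function(spec, side, dirs, xabs, radius) {
  s <- abs(atan2(dirs[, 3], dirs[, 2])) / pi  # arc fraction from anterior
  reg <- c("a", "c", "p")[1L + (s >= spec$ap_fractions[1]) +
                            (s >= spec$ap_fractions[2])]
  voi <- paste0(side, reg)
  cx <- spec$condyle_separation / 2
  q <- (cx - radius) + spec$ml_fractions * (2 * radius)
  band <- c("i", "c", "e")[1L + (xabs >= q[1]) + (xabs >= q[2])]
  sub <- rep(NA_character_, length(s))
  ant <- reg == "a"
  sub[ant] <- paste0(side, "a", band[ant])
  list(voi = voi, subvoi = sub)
}

# expand a named multiplier vector to all 12 labels: sub-VOIs inherit their
# parent VOI's value unless named explicitly
.expand_mult <- function(mult) {
  labs <- c(.VOI_LEVELS, .SUBVOI_LEVELS)
  out <- setNames(rep(1, length(labs)), labs)
  if (is.null(mult) || !length(mult)) return(out)
  voi_names <- intersect(names(mult), .VOI_LEVELS)
  for (vn in voi_names) {
    out[vn] <- mult[[vn]]
    kids <- .SUBVOI_LEVELS[startsWith(.SUBVOI_LEVELS, vn)]
    out[kids] <- mult[[vn]]
  }
  sub_names <- intersect(names(mult), .SUBVOI_LEVELS)
  out[sub_names] <- mult[sub_names]
  out
}

# multiplier per point: sub-VOI entry when the point has one, else VOI entry
.mult_lookup <- function(voi, subvoi, mult) {
  if (is.null(mult) || !length(mult)) return(rep(1, length(voi)))
  m <- .expand_mult(mult)
  unname(m[ifelse(is.na(subvoi), voi, subvoi)])
}

# UV sphere with poles on the x axis (the medial-lateral axis), outward winding
.uv_sphere <- function(center, radius, res) {
  nt <- max(6L, ceiling(pi * radius / res))
  np <- max(8L, ceiling(2 * pi * radius / res))
  theta <- seq(0, pi, length.out = nt + 1L)[-c(1L, nt + 1L)]
  phi <- seq(0, 2 * pi, length.out = np + 1L)[-(np + 1L)]
  ring <- function(th) {
    cbind(cos(th), sin(th) * cos(phi), sin(th) * sin(phi))
  }
  dirs <- rbind(c(1, 0, 0), do.call(rbind, lapply(theta, ring)), c(-1, 0, 0))
  nv <- nrow(dirs)
  faces <- list()
  # +x pole fan (vertex 1); ring 1 starts at vertex 2
  r1 <- 1L + seq_len(np)
  faces[[1]] <- cbind(1L, r1, c(r1[-1], r1[1]))
  for (i in seq_len(length(theta) - 1L)) {
    a <- 1L + (i - 1L) * np + seq_len(np)
    b <- a + np
    a2 <- c(a[-1], a[1]); b2 <- c(b[-1], b[1])
    faces[[length(faces) + 1L]] <- rbind(cbind(a, b, b2), cbind(a, b2, a2))
  }
  rl <- 1L + (length(theta) - 1L) * np + seq_len(np)
  faces[[length(faces) + 1L]] <- cbind(nv, c(rl[-1], rl[1]), rl)
  f <- do.call(rbind, faces)
  v <- sweep(dirs * radius, 2, center, "+")
  list(vertices = v, faces = f, dirs = dirs)
}

#' Generate bone and cartilage condyle models with ground truth
#'
#' Builds the two-lobe bone mesh, offsets it outward along vertex normals by
#' the (optionally modulated) thickness field to obtain the cartilage mesh,
#' and returns the per-vertex ground-truth thickness and VOI labels.
#'
#' @param spec a [phantom_spec()].
#' @param th_mult optional named numeric vector of per-(sub-)VOI thickness
#'   multipliers (e.g. `c(Mc = 0.85)`); entries named by sub-VOI override
#'   the parent VOI within that sub-region.
#' @param t2_mult optional named per-(sub-)VOI T2 multipliers, recorded for
#'   downstream rendering.
#' @return list with `bone` and `cartilage` ([surface_mesh()]),
#'   `truth_thickness` (mm per bone vertex), `vertex_voi`, `vertex_subvoi`
#'   (ground-truth labels), `t2_mult`, `th_mult` and `spec`.
#' @export
#' @examples
#' mod <- make_condyle_models(phantom_spec(mesh_resolution = 4))
#' range(mod$truth_thickness)
make_condyle_models <- function(spec, th_mult = NULL, t2_mult = NULL) {
  .assert(inherits(spec, "phantom_spec"), "spec must be a phantom_spec")
  if (!is.null(th_mult)) .assert(all(th_mult > 0), "thickness multipliers must be > 0")
  geom <- .condyle_geom(spec)
  vb <- list(); fb <- list(); thick <- list()
  voi <- list(); sub <- list()
  off <- 0L
  for (side in c("M", "L")) {
    g <- geom[[side]]
    sp <- .uv_sphere(g$center, g$radius, spec$mesh_resolution)
    lab <- .labels_for_dirs(spec, side, sp$dirs, abs(sp$vertices[, 1]),
                            g$radius)
    t0 <- .thickness_field(spec, sp$dirs) *
      .mult_lookup(lab$voi, lab$subvoi, th_mult)
    .assert(all(t0 > 0), "thickness field must be strictly positive")
    vb[[side]] <- sp$vertices
    fb[[side]] <- sp$faces + off
    thick[[side]] <- t0
    voi[[side]] <- lab$voi
    sub[[side]] <- lab$subvoi
    off <- off + nrow(sp$vertices)
  }
  bone_v <- do.call(rbind, vb)
  faces <- do.call(rbind, fb)
  thickness <- unlist(thick, use.names = FALSE)
  # cartilage = bone offset outward along (radial) vertex normals
  dirs <- rbind(
    sweep(vb$M, 2, geom$M$center, "-") / geom$M$radius,
    sweep(vb$L, 2, geom$L$center, "-") / geom$L$radius
  )
  cart_v <- bone_v + dirs * thickness
  list(bone = surface_mesh(bone_v, faces),
       cartilage = surface_mesh(cart_v, faces),
       truth_thickness = thickness,
       vertex_voi = factor(unlist(voi, use.names = FALSE), levels = .VOI_LEVELS),
       vertex_subvoi = factor(unlist(sub, use.names = FALSE),
                              levels = .SUBVOI_LEVELS),
       t2_mult = t2_mult, th_mult = th_mult, spec = spec)
}

#' Analytic phantom ground truth at arbitrary world points
#'
#' For each point: whether it lies inside the cartilage shell, its condyle,
#' VOI and sub-VOI, relative depth (0 at bone, 1 at articular surface) and
#' ground-truth T2 (ms) under the given multipliers.
#'
#' @param spec a [phantom_spec()].
#' @param points n x 3 world coordinates (mm).
#' @param t2_mult,th_mult optional named per-(sub-)VOI multipliers.
#' @return data.frame with columns `inside`, `voi`, `subvoi`, `depth`, `t2`,
#'   `thickness`.
#' @export
phantom_truth_at <- function(spec, points, t2_mult = NULL, th_mult = NULL) {
  points <- matrix(as.numeric(points), ncol = 3)
  n <- nrow(points)
  geom <- .condyle_geom(spec)
  # nearest condyle center decides attribution
  dm <- .rownorm(sweep(points, 2, geom$M$center, "-"))
  dl <- .rownorm(sweep(points, 2, geom$L$center, "-"))
  side <- c("L", "M")[1L + (dm <= dl)]
  v_inside <- logical(n); v_voi <- rep(NA_character_, n)
  v_sub <- rep(NA_character_, n); v_depth <- rep(NA_real_, n)
  v_t2 <- rep(NA_real_, n); v_th <- rep(NA_real_, n)
  for (sd in c("M", "L")) {
    sel <- side == sd
    if (!any(sel)) next
    g <- geom[[sd]]
    rel <- sweep(points[sel, , drop = FALSE], 2, g$center, "-")
    r <- .rownorm(rel)
    rsafe <- r; rsafe[rsafe == 0] <- 1
    dirs <- rel / rsafe
    lab <- .labels_for_dirs(spec, sd, dirs, abs(points[sel, 1]), g$radius)
    teff <- .thickness_field(spec, dirs) *
      .mult_lookup(lab$voi, lab$subvoi, th_mult)
    inside <- r >= g$radius & r <= g$radius + teff
    depth <- pmin(1, pmax(0, (r - g$radius) / teff))
    t2 <- (spec$t2_deep + (spec$t2_surf - spec$t2_deep) * depth) *
      .mult_lookup(lab$voi, lab$subvoi, t2_mult)
    v_inside[sel] <- inside
    v_voi[sel] <- lab$voi
    v_sub[sel] <- lab$subvoi
    v_depth[sel] <- depth
    v_t2[sel] <- t2
    v_th[sel] <- teff
  }
  v_voi[!v_inside] <- NA_character_
  v_sub[!v_inside] <- NA_character_
  v_depth[!v_inside] <- NA_real_
  v_t2[!v_inside] <- NA_real_
  data.frame(inside = v_inside, voi = v_voi, subvoi = v_sub,
             depth = v_depth, t2 = v_t2, thickness = v_th,
             stringsAsFactors = FALSE)
}

#' Render a multi-echo MSME volume of the phantom
#'
#' Voxel signal at echo time TE inside cartilage is the Rician-corrupted
#' monoexponential `S0 * exp(-TE / T2(x))`; background voxels carry pure
#' Rician noise (Rayleigh magnitudes). Rician corruption is implemented as
#' the magnitude of the noiseless signal plus complex Gaussian noise of
#' scale `noise_sigma` per channel.
#'
#' @param spec a [phantom_spec()].
#' @param t2_mult,th_mult optional named per-(sub-)VOI multipliers.
#' @param seed RNG seed for the noise (default `spec$seed`).
#' @return list with `volume` (a [multi_echo_volume()]) and `truth` (list of
#'   arrays: logical `mask`, `t2`, `depth`, character `voi`, `subvoi`).
#' @export
render_multiecho <- function(spec, t2_mult = NULL, th_mult = NULL,
                             seed = spec$seed) {
  .assert(inherits(spec, "phantom_spec"), "spec must be a phantom_spec")
  geom <- .condyle_geom(spec)
  tmax <- spec$thickness_base * (1 + abs(spec$thickness_amp)) * 1.5
  xr <- c(geom$L$center[1] - geom$L$radius, geom$M$center[1] + geom$M$radius) +
    c(-1, 1) * (tmax + spec$margin)
  rmax <- max(geom$M$radius, geom$L$radius) + tmax + spec$margin
  lo <- c(xr[1], -rmax, -rmax)
  hi <- c(xr[2], rmax, rmax)
  dims <- pmax(2L, ceiling((hi - lo) / spec$spacing))
  gg <- image_geometry(origin = lo + spec$spacing / 2, spacing = spec$spacing,
                       dims = dims)
  pts <- .grid_world_coords(gg)
  truth <- phantom_truth_at(spec, pts, t2_mult = t2_mult, th_mult = th_mult)
  mask <- array(truth$inside, dims)
  t2vec <- truth$t2
  t2vec[!truth$inside] <- NA_real_
  t2a <- array(t2vec, dims)
  ne <- length(spec$echo_times)
  data <- array(0, c(dims, ne))
  nvox <- prod(dims)
  set.seed(seed)
  for (e in seq_len(ne)) {
    s <- numeric(nvox)
    s[truth$inside] <- spec$s0 * exp(-spec$echo_times[e] / truth$t2[truth$inside])
    if (spec$noise_sigma > 0) {
      s <- sqrt((s + rnorm(nvox, 0, spec$noise_sigma))^2 +
                  rnorm(nvox, 0, spec$noise_sigma)^2)
    }
    data[, , , e] <- s
  }
  list(volume = multi_echo_volume(spec$echo_times, data, gg),
       truth = list(mask = mask, t2 = t2a,
                    depth = array(truth$depth, dims),
                    voi = array(truth$voi, dims),
                    subvoi = array(truth$subvoi, dims)))
}

#' Longitudinal progression model for the simulated cohort
#'
#' Per-(sub-)VOI multiplicative offsets applied to the ground-truth T2 and
#' thickness fields at each severity timepoint (KL1, KL2, KL3), plus the
#' between-knee and scan-to-scan variability scales. KL1 multipliers are the
#' identity by construction.
#'
#' The defaults encode a fast-progressing medial-OA pattern: medial T2
#' rises by 10% from KL2 onward, anterior-lateral T2 drops by 7% from KL2
#' onward, and medial-central thickness loses 15% at KL3 — early
#' compositional change followed by later-stage thinning.
#'
#' @param t2_mult,th_mult lists with elements `KL2`, `KL3`: named numeric
#'   multiplier vectors (see [make_condyle_models()]); missing entries mean
#'   no change.
#' @param months months since KL1 of the three severity timepoints.
#' @param t2_bkv,th_bkv,size_bkv between-knee lognormal variability scales
#'   (sd of log) of the T2 field, thickness field and condyle size.
#' @param scan_t2,scan_th scan-to-scan lognormal variability (sd of log)
#'   applied per knee, timepoint and (sub-)VOI, emulating repositioning and
#'   segmentation error.
#' @return An object of class `progression_model`.
#' @export
progression_model <- function(
    t2_mult = list(
      KL2 = c(Ma = 1.10, Mc = 1.10, Mp = 1.10, La = 0.93),
      KL3 = c(Ma = 1.10, Mc = 1.10, Mp = 1.10, La = 0.93)
    ),
    th_mult = list(
      KL2 = NULL,
      KL3 = c(Mc = 0.85)
    ),
    months = c(0, 18, 36),
    t2_bkv = 0.06, th_bkv = 0.06, size_bkv = 0.04,
    scan_t2 = 0.02, scan_th = 0.03) {
  chk <- function(l) {
    for (m in l) if (!is.null(m)) .assert(all(m > 0), "multipliers must be > 0")
  }
  chk(t2_mult); chk(th_mult)
  .assert(length(months) == 3 && all(diff(months) > 0),
          "months must be 3 increasing values")
  .assert(all(c(t2_bkv, th_bkv, size_bkv, scan_t2, scan_th) >= 0),
          "variability scales must be >= 0")
  structure(list(
    t2_mult = list(KL1 = NULL, KL2 = t2_mult$KL2, KL3 = t2_mult$KL3),
    th_mult = list(KL1 = NULL, KL2 = th_mult$KL2, KL3 = th_mult$KL3),
    months = as.numeric(months),
    t2_bkv = t2_bkv, th_bkv = th_bkv, size_bkv = size_bkv,
    scan_t2 = scan_t2, scan_th = scan_th
  ), class = "progression_model")
}

#' Identity progression model (no longitudinal change)
#'
#' @param ... overrides passed to [progression_model()].
#' @return a [progression_model()] with identity multipliers.
#' @export
null_progression_model <- function(...) {
  progression_model(t2_mult = list(KL2 = NULL, KL3 = NULL),
                    th_mult = list(KL2 = NULL, KL3 = NULL), ...)
}

# knee-level random perturbation of the spec (deterministic substream)
.perturb_spec <- function(spec, model, seed, knee) {
  set.seed(.substream_seed(seed, knee, 0L))
  sz <- exp(rnorm(1, 0, model$size_bkv))
  th <- exp(rnorm(1, 0, model$th_bkv))
  t2 <- exp(rnorm(1, 0, model$t2_bkv))
  sp <- spec
  sp$condyle_radius_medial <- spec$condyle_radius_medial * sz
  sp$condyle_radius_lateral <- spec$condyle_radius_lateral * sz
  sp$thickness_base <- spec$thickness_base * th
  sp$t2_deep <- spec$t2_deep * t2
  sp$t2_surf <- spec$t2_surf * t2
  sp
}

# scan-noise multipliers for one (knee, timepoint): one lognormal factor per
# (sub-)VOI label, drawn from the substream
.scan_factors <- function(model, seed, knee, timepoint) {
  labs <- c(.VOI_LEVELS, .SUBVOI_LEVELS)
  set.seed(.substream_seed(seed, knee, timepoint))
  list(
    t2 = setNames(exp(rnorm(length(labs), 0, model$scan_t2)), labs),
    th = setNames(exp(rnorm(length(labs), 0, model$scan_th)), labs),
    noise_seed = .substream_seed(seed, knee, timepoint + 100L)
  )
}

# combine progression and scan multipliers over the full label vocabulary
# (sub-VOIs inherit the parent progression effect before scan noise applies)
.combine_mult <- function(base, extra) {
  if (is.null(base) && is.null(extra)) return(NULL)
  .expand_mult(base) * .expand_mult(extra)
}

#' Generate one knee-timepoint cell of a simulated cohort
#'
#' @param spec cohort-level [phantom_spec()].
#' @param model a [progression_model()].
#' @param knee knee index (1-based).
#' @param timepoint severity timepoint index (1 = KL1, 2 = KL2, 3 = KL3).
#' @param seed cohort-level seed.
#' @param render render the multi-echo volume (default `TRUE`).
#' @return list with the perturbed `spec`, `models`
#'   (from [make_condyle_models()], scan noise included in the thickness
#'   field), `render` (when requested), the applied `t2_mult`/`th_mult`
#'   (progression only) and `scan` factors.
#' @export
simulate_knee_timepoint <- function(spec, model, knee, timepoint, seed,
                                    render = TRUE) {
  kl <- c("KL1", "KL2", "KL3")[timepoint]
  sp <- .perturb_spec(spec, model, seed, knee)
  scan <- .scan_factors(model, seed, knee, timepoint)
  t2m <- model$t2_mult[[kl]]
  thm <- model$th_mult[[kl]]
  t2_eff <- .combine_mult(t2m, scan$t2)
  th_eff <- .combine_mult(thm, scan$th)
  models <- make_condyle_models(sp, th_mult = th_eff, t2_mult = t2_eff)
  rend <- NULL
  if (render) {
    rend <- render_multiecho(sp, t2_mult = t2_eff, th_mult = th_eff,
                             seed = scan$noise_seed)
  }
  list(spec = sp, models = models, render = rend,
       timepoint = kl, knee = knee,
       t2_mult = t2m, th_mult = thm, scan = scan)
}

#' Simulate a longitudinal phantom cohort with ground truth
#'
#' Each knee carries its own random perturbation of the cohort spec
#' (condyle size, cartilage thickness, T2 level); each severity timepoint
#' applies the progression multipliers plus scan-to-scan noise. A single
#' cohort seed expands into per-knee, per-timepoint substreams, so the
#' cohort is reproducible and insensitive to generation order.
#'
#' The ground-truth table records, for every knee, timepoint and (sub-)VOI,
#' the noise-free true median T2 and mean thickness: the knee's baseline
#' value times the progression multiplier (scan noise excluded by
#' definition of "truth").
#'
#' @param n_knees number of knees (>= 2).
#' @param spec a [phantom_spec()].
#' @param model a [progression_model()].
#' @param seed cohort seed (default `spec$seed`).
#' @param render render multi-echo volumes for each cell (default `TRUE`;
#'   set `FALSE` for statistics-only simulations).
#' @param keep_cells keep the per-cell data in the result (default `TRUE`;
#'   `FALSE` returns only the truth table).
#' @return An object of class `phantom_cohort`: list with `truth` (the
#'   ground-truth data.frame: knee, timepoint, months, family, measure,
#'   value) and, when kept, `cells[[knee]][[timepoint]]`.
#' @export
simulate_cohort <- function(n_knees, spec, model, seed = spec$seed,
                            render = TRUE, keep_cells = TRUE) {
  .assert(n_knees >= 2, "n_knees must be >= 2")
  .assert(inherits(model, "progression_model"), "model must be a progression_model")
  cells <- if (keep_cells) vector("list", n_knees) else NULL
  truth <- list()
  for (k in seq_len(n_knees)) {
    sp <- .perturb_spec(spec, model, seed, k)
    base <- .knee_baseline_truth(sp)
    if (keep_cells) cells[[k]] <- vector("list", 3L)
    for (tp in 1:3) {
      kl <- c("KL1", "KL2", "KL3")[tp]
      t2m <- .mult_lookup(base$voi, base$subvoi, model$t2_mult[[kl]])
      thm <- .mult_lookup(base$voi, base$subvoi, model$th_mult[[kl]])
      truth[[length(truth) + 1L]] <- data.frame(
        knee = k, timepoint = kl, months = model$months[tp],
        family = rep(c("t2", "thickness"), each = length(base$measure)),
        measure = rep(base$measure, 2),
        value = c(base$t2 * t2m, base$thickness * thm),
        stringsAsFactors = FALSE
      )
      if (keep_cells) {
        cells[[k]][[tp]] <- simulate_knee_timepoint(spec, model, k, tp, seed,
                                                    render = render)
      }
    }
  }
  structure(list(truth = do.call(rbind, truth), cells = cells,
                 n_knees = n_knees, spec = spec, model = model, seed = seed),
            class = "phantom_cohort")
}

# baseline (KL1, noise-free) per-(sub-)VOI truth for one knee's spec:
# median T2 over the shell (T2 linear in depth, depth ~ uniform => value at
# depth 0.5) and area-ish mean thickness from the generated mesh truth
.knee_baseline_truth <- function(sp) {
  mod <- make_condyle_models(sp)
  labs <- c(.VOI_LEVELS, .SUBVOI_LEVELS)
  t2_mid <- sp$t2_deep + 0.5 * (sp$t2_surf - sp$t2_deep)
  th <- numeric(length(labs))
  voi_chr <- as.character(mod$vertex_voi)
  sub_chr <- as.character(mod$vertex_subvoi)
  for (i in seq_along(labs)) {
    sel <- if (labs[i] %in% .VOI_LEVELS) voi_chr == labs[i]
           else !is.na(sub_chr) & sub_chr == labs[i]
    th[i] <- mean(mod$truth_thickness[sel])
  }
  is_sub <- labs %in% .SUBVOI_LEVELS
  list(measure = labs,
       voi = ifelse(is_sub, substr(labs, 1, 2), labs),
       subvoi = ifelse(is_sub, labs, NA_character_),
       t2 = rep(t2_mid, length(labs)), thickness = th)
}

#' @export
print.phantom_cohort <- function(x, ...) {
  cat(sprintf("<phantom_cohort> %d knees x 3 timepoints (seed %d)\n",
              x$n_knees, x$seed))
  invisible(x)
}
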