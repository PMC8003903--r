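#' Image geometry (origin, spacing, direction cosines, dims)
#'
#' World/voxel convention: voxel indices are zero-based with the voxel
#' center at the index coordinate, so
#' `world = origin + direction %*% diag(spacing) %*% index`.
#'
#' @param origin length-3 world position (mm) of voxel (0,0,0).
#' @param spacing length-3 voxel spacing (mm), all > 0.
#' @param direction 3 x 3 orthonormal direction-cosine matrix (columns are
#'   the world directions of the image axes).
#' @param dims length-3 integer grid size.
#' @return An object of class `image_geometry`.
#' @export
image_geometry <- function(origin, spacing, direction = diag(3), dims) {
  origin <- as.numeric(origin); spacing <- as.numeric(spacing)
  direction <- as.matrix(direction)
  .assert(length(origin) == 3 && length(spacing) == 3 && length(dims) == 3,
          "origin, spacing and dims must have length 3")
  .assert(all(spacing > 0), "spacing must be positive")
  .assert(all(dim(direction) == c(3, 3)), "direction must be 3 x 3")
  .assert(max(abs(crossprod(direction) - diag(3))) < 1e-9,
          "direction matrix is not orthonormal")
  structure(list(origin = origin, spacing = spacing, direction = direction,
                 dims = as.integer(dims)),
            class = "image_geometry")
}

#' @rdname image_geometry
#' @param geometry an `image_geometry`.
#' @param index n x 3 matrix of zero-based voxel indices (may be fractional).
#' @return `voxel_to_world()`: n x 3 world coordinates (mm);
#'   `world_to_voxel()`: n x 3 zero-based (fractional) voxel coordinates.
#' @export
voxel_to_world <- function(geometry, index) {
  index <- matrix(as.numeric(index), ncol = 3)
  sweep(index %*% t(geometry$direction %*% diag(geometry$spacing)), 2,
        geometry$origin, "+")
}

#' @rdname image_geometry
#' @param world n x 3 matrix of world coordinates (mm).
#' @export
world_to_voxel <- function(geometry, world) {
  world <- matrix(as.numeric(world), ncol = 3)
  a <- geometry$direction %*% diag(geometry$spacing)
  sweep(world, 2, geometry$origin, "-") %*% t(solve(a))
}

# world coordinates of every voxel center, fastest-varying first axis
.grid_world_coords <- function(geometry) {
  d <- geometry$dims
  idx <- cbind(
    rep.int(seq_len(d[1]) - 1L, d[2] * d[3]),
    rep.int(rep(seq_len(d[2]) - 1L, each = d[1]), d[3]),
    rep(seq_len(d[3]) - 1L, each = d[1] * d[2])
  )
  voxel_to_world(geometry, idx)
}

#' Rigid transform (rotation + translation)
#'
#' @param rotation 3 x 3 orthonormal matrix with determinant +1.
#' @param translation length-3 vector (mm).
#' @return An object of class `rigid_transform`.
#' @export
rigid_transform <- function(rotation = diag(3), translation = c(0, 0, 0)) {
  rotation <- as.matrix(rotation)
  translation <- as.numeric(translation)
  .assert(all(dim(rotation) == c(3, 3)), "rotation must be 3 x 3")
  .assert(max(abs(crossprod(rotation) - diag(3))) < 1e-9,
          "rotation is not orthonormal")
  .assert(abs(det(rotation) - 1) < 1e-9, "rotation determinant must be +1")
  .assert(length(translation) == 3 && all(is.finite(translation)),
          "translation must be a finite length-3 vector")
  structure(list(rotation = rotation, translation = translation),
            class = "rigid_transform")
}

#' @rdname rigid_transform
#' @param transform,a,b `rigid_transform` objects.
#' @param points n x 3 matrix.
#' @export
apply_transform <- function(transform, points) {
  points <- matrix(as.numeric(points), ncol = 3)
  sweep(points %*% t(transform$rotation), 2, transform$translation, "+")
}

#' @rdname rigid_transform
#' @export
compose_transforms <- function(a, b) {
  # (a o b)(x) = a(b(x))
  rigid_transform(a$rotation %*% b$rotation,
                  as.numeric(a$rotation %*% b$translation) + a$translation)
}

#' @rdname rigid_transform
#' @export
invert_transform <- function(transform) {
  rt <- t(transform$rotation)
  rigid_transform(rt, -as.numeric(rt %*% transform$translation))
}

#' Header-based registration between two image geometries
#'
#' Initial registration of models segmented on one sequence (e.g. DESS) to
#' another (e.g. MSME) using only the geometry recorded in the image
#' headers. Both headers express positions in the same patient frame, so the
#' patient-frame mapping is the identity; a manual refinement, when
#' available, is supplied as a `correction` rigid transform and composed on
#' top. The result also exposes the target's world-to-voxel map.
#'
#' @param source_geometry,target_geometry [image_geometry()] objects.
#' @param correction optional [rigid_transform()] refinement (applied after
#'   the header mapping).
#' @return An object of class `header_registration`: list with `transform`
#'   (patient-frame [rigid_transform()]), `target_geometry`, and
#'   `world_to_voxel(points)` convenience closure.
#' @export
header_transform <- function(source_geometry, target_geometry,
                             correction = NULL) {
  .assert(inherits(source_geometry, "image_geometry") &&
            inherits(target_geometry, "image_geometry"),
          "geometries must be image_geometry objects")
  tr <- rigid_transform()
  if (!is.null(correction)) {
    .assert(inherits(correction, "rigid_transform"),
            "correction must be a rigid_transform")
    tr <- compose_transforms(correction, tr)
  }
  structure(list(transform = tr, target_geometry = target_geometry,
                 world_to_voxel = function(points)
                   world_to_voxel(target_geometry, points)),
            class = "header_registration")
}

#' Anatomical frame of the distal femur
#'
#' Supplies the axes and intercondylar notch plane needed to partition
#' condylar cartilage. Axes need not be exactly orthogonal but must not be
#' collinear; `ml` points from the notch toward the medial side.
#'
#' @param ap,ml,pd unit-ish direction vectors: anterior-posterior (pointing
#'   anterior), medial-lateral (pointing medial), proximal-distal.
#' @param notch_point a point (mm) on the intercondylar (sagittal) plane.
#' @return An object of class `anatomical_frame`.
#' @export
anatomical_frame <- function(ap = c(0, 1, 0), ml = c(1, 0, 0),
                             pd = c(0, 0, 1), notch_point = c(0, 0, 0)) {
  ap <- as.numeric(ap); ml <- as.numeric(ml); pd <- as.numeric(pd)
  m <- cbind(ap, ml, pd)
  .assert(all(is.finite(m)) && all(sqrt(colSums(m^2)) > 0),
          "frame axes must be finite and non-zero")
  m <- sweep(m, 2, sqrt(colSums(m^2)), "/")
  .assert(abs(det(m)) > 1e-6, "frame axes are collinear (degenerate frame)")
  structure(list(ap = m[, 1], ml = m[, 2], pd = m[, 3],
                 notch_point = as.numeric(notch_point)),
            class = "anatomical_frame")
}

#' Partition condylar bone vertices into VOIs and anterior sub-VOIs
#'
#' Medial/lateral assignment is by side of the intercondylar plane.
#' Within each condyle, vertices are ordered along the anterior-posterior
#' condylar arc (angle from the anterior axis within the sagittal plane,
#' measured about the condyle centroid) and split at fractional boundaries
#' (defaults: thirds) into anterior/central/posterior. Anterior vertices are
#' further split into external/central/internal sub-VOIs at fractional
#' boundaries of the condyle's medial-lateral extent; "external" is farther
#' from the intercondylar notch, "internal" nearer.
#'
#' @param bone a [surface_mesh()] of the subchondral bone.
#' @param frame an [anatomical_frame()].
#' @param ap_fractions two increasing numbers in (0,1): anterior/central and
#'   central/posterior arc boundaries (default `c(1/3, 2/3)`).
#' @param ml_fractions two increasing numbers in (0,1): sub-VOI boundaries
#'   along the medial-lateral extent (default `c(1/3, 2/3)`).
#' @return An object of class `voi_partition`: `vertex_voi` (factor over
#'   Ma..Lp), `vertex_subvoi` (factor over Mae..Lai; `NA` outside anterior
#'   VOIs), plus per-condyle metadata.
#' @export
partition_vois <- function(bone, frame, ap_fractions = c(1, 2) / 3,
                           ml_fractions = c(1, 2) / 3) {
  .assert(inherits(bone, "surface_mesh"), "bone must be a surface_mesh")
  .assert(inherits(frame, "anatomical_frame"), "frame must be an anatomical_frame")
  .assert(length(ap_fractions) == 2 && all(diff(ap_fractions) > 0) &&
            all(ap_fractions > 0 & ap_fractions < 1),
          "ap_fractions must be two increasing values in (0,1)")
  .assert(length(ml_fractions) == 2 && all(diff(ml_fractions) > 0) &&
            all(ml_fractions > 0 & ml_fractions < 1),
          "ml_fractions must be two increasing values in (0,1)")
  v <- bone$vertices
  rel <- sweep(v, 2, frame$notch_point, "-")
  mlc <- as.vector(rel %*% frame$ml)  # signed distance from notch plane
  # snap tolerance: rotating mesh and frame together perturbs dot products
  # at rounding level; snapping keeps degenerate (on-axis) vertices stable
  snap <- 1e-9 * max(1, max(abs(v)))
  mlc[abs(mlc) < snap] <- 0
  medial <- mlc >= 0

  n <- nrow(v)
  voi <- character(n)
  sub <- rep(NA_character_, n)
  meta <- list()
  for (side in c("M", "L")) {
    sel <- if (side == "M") medial else !medial
    if (!any(sel)) next
    centroid <- colMeans(v[sel, , drop = FALSE])
    relc <- sweep(v[sel, , drop = FALSE], 2, centroid, "-")
    u <- as.vector(relc %*% frame$ap)
    w <- as.vector(relc %*% frame$pd)
    u[abs(u) < snap] <- 0
    w[abs(w) < snap] <- 0
    s <- abs(atan2(w, u)) / pi  # 0 = anterior pole, 1 = posterior pole
    reg <- ifelse(s < ap_fractions[1], "a",
                  ifelse(s < ap_fractions[2], "c", "p"))
    voi[sel] <- paste0(side, reg)
    # anterior sub-VOIs along the condyle's medial-lateral extent
    dml <- abs(mlc[sel])
    rng <- range(dml)
    q <- rng[1] + ml_fractions * diff(rng)
    band <- ifelse(dml < q[1], "i", ifelse(dml < q[2], "c", "e"))
    ant <- reg == "a"
    sub[sel][ant] <- paste0(side, "a", band[ant])
    meta[[side]] <- list(centroid = centroid, ml_extent = rng,
                         n_vertices = sum(sel))
  }
  structure(list(
    vertex_voi = factor(voi, levels = .VOI_LEVELS),
    vertex_subvoi = factor(sub, levels = .SUBVOI_LEVELS),
    condyles = meta, frame = frame,
    ap_fractions = ap_fractions, ml_fractions = ml_fractions
  ), class = "voi_partition")
}

#' @export
print.voi_partition <- function(x, ...) {
  cat("<voi_partition>\n")
  print(table(x$vertex_voi))
  invisible(x)
}

#' Assign masked voxels to VOIs and relative cartilage depth
#'
#' Each masked voxel center (transformed into the model frame) takes the VOI
#' label of its nearest bone vertex (ties broken by lowest vertex index).
#' Relative depth is `d_bone / (d_bone + d_cart)` with `d_bone`, `d_cart`
#' the minimum distances to the bone and cartilage surfaces: 0 at the bone,
#' 1 at the articular surface. Voxels where depth is undefined
#' (`d_bone + d_cart == 0`) are dropped and counted.
#'
#' @param mask logical array over the T2 grid (or an n x 3 matrix of world
#'   points in the T2 frame).
#' @param geometry the T2 [image_geometry()] (ignored when `mask` is a
#'   point matrix).
#' @param bone,cartilage [surface_mesh()] objects in the model frame.
#' @param partition a [partition_vois()] result on `bone`.
#' @param transform [rigid_transform()] mapping the model frame into the T2
#'   patient frame (identity by default); voxel centers are pulled back
#'   through its inverse.
#' @return data.frame with columns `voxel` (linear index into the mask, or
#'   row of the point matrix), `voi`, `subvoi`, `depth`, `layer`; attribute
#'   `n_dropped` counts voxels with undefined depth.
#' @export
assign_voxels <- function(mask, geometry = NULL, bone, cartilage, partition,
                          transform = rigid_transform()) {
  .assert(inherits(partition, "voi_partition"), "partition must be a voi_partition")
  if (is.array(mask) && is.logical(mask)) {
    .assert(inherits(geometry, "image_geometry"),
            "geometry is required for an array mask")
    .assert(all(dim(mask) == geometry$dims), "mask dims do not match geometry")
    idx <- which(mask)
    if (!length(idx)) {
      warning("empty mask: no voxels assigned")
      out <- data.frame(voxel = integer(), voi = character(),
                        subvoi = character(), depth = numeric(),
                        layer = character())
      attr(out, "n_dropped") <- 0L
      return(out)
    }
    all_world <- .grid_world_coords(geometry)
    pts_world <- all_world[idx, , drop = FALSE]
  } else {
    pts_world <- matrix(as.numeric(mask), ncol = 3)
    idx <- seq_len(nrow(pts_world))
  }
  # pull voxel centers back into the model frame
  pts <- apply_transform(invert_transform(transform), pts_world)

  nv <- cpp_nearest_vertex(pts, bone$vertices) + 1L
  db <- mesh_distance(pts, bone)$dist
  dc <- mesh_distance(pts, cartilage)$dist
  denom <- db + dc
  keep <- denom > 0
  depth <- db[keep] / denom[keep]
  out <- data.frame(
    voxel = idx[keep],
    voi = as.character(partition$vertex_voi[nv[keep]]),
    subvoi = as.character(partition$vertex_subvoi[nv[keep]]),
    depth = depth,
    layer = split_layers(depth),
    stringsAsFactors = FALSE
  )
  attr(out, "n_dropped") <- sum(!keep)
  out
}

#' Split relative depths into deep and superficial layers
#'
#' The cartilage slab is halved at 50% relative thickness: `deep` when
#' depth < 0.5 (adjacent to bone), `superficial` when depth >= 0.5.
#'
#' @param depths numeric vector of relative depths in \[0, 1\].
#' @return character vector of `"deep"` / `"superficial"`.
#' @export
#' @examples
#' split_layers(c(0.3, 0.5))  # deep, superficial
split_layers <- function(depths) {
  .assert(all(is.finite(depths)) && all(depths >= 0 & depths <= 1),
          "depths must lie in [0, 1]")
  ifelse(depths < 0.5, "deep", "superficial")
}
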