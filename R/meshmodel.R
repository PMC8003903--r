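#' Triangle surface mesh in patient millimetre coordinates
#'
#' Constructs a validated triangle mesh. Vertices are given in the patient
#' (world) frame in millimetres; faces index into the vertex matrix.
#'
#' @param vertices numeric n x 3 matrix of vertex coordinates (mm).
#' @param faces integer m x 3 matrix of 1-based vertex indices.
#' @return An object of class `surface_mesh` with elements `vertices` and
#'   `faces`.
#' @details Validation rejects non-finite coordinates, out-of-range face
#'   indices and degenerate (zero-area) faces.
#' @export
#' @examples
#' v <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0))
#' surface_mesh(v, matrix(c(1L, 2L, 3L), 1))
surface_mesh <- function(vertices, faces) {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  .assert(.is_num_mat3(vertices), "vertices must be an n x 3 numeric matrix")
  .assert(all(is.finite(vertices)), "mesh vertices contain non-finite coordinates")
  faces <- as.matrix(faces)
  storage.mode(faces) <- "integer"
  .assert(is.matrix(faces) && ncol(faces) == 3L,
          "faces must be an m x 3 integer matrix")
  .assert(nrow(faces) >= 1L, "mesh has no faces")
  .assert(all(faces >= 1L) && all(faces <= nrow(vertices)),
          "face indices out of range")
  a <- vertices[faces[, 1], , drop = FALSE]
  b <- vertices[faces[, 2], , drop = FALSE]
  c_ <- vertices[faces[, 3], , drop = FALSE]
  n <- .cross_rows(b - a, c_ - a)
  .assert(all(.rownorm(n) > 0),
          "mesh contains degenerate (zero-area) faces")
  structure(list(vertices = vertices, faces = faces), class = "surface_mesh")
}

#' @export
print.surface_mesh <- function(x, ...) {
  cat(sprintf("<surface_mesh> %d vertices, %d faces\n",
              nrow(x$vertices), nrow(x$faces)))
  invisible(x)
}

# row-wise cross product
.cross_rows <- function(u, v) {
  cbind(u[, 2] * v[, 3] - u[, 3] * v[, 2],
        u[, 3] * v[, 1] - u[, 1] * v[, 3],
        u[, 1] * v[, 2] - u[, 2] * v[, 1])
}

#' Face normals of a mesh
#'
#' Unit outward normals under the mesh's winding convention
#' (counter-clockwise seen from outside).
#'
#' @param mesh a [surface_mesh()].
#' @return m x 3 matrix of unit normals.
#' @export
face_normals <- function(mesh) {
  v <- mesh$vertices
  f <- mesh$faces
  n <- .cross_rows(v[f[, 2], , drop = FALSE] - v[f[, 1], , drop = FALSE],
                   v[f[, 3], , drop = FALSE] - v[f[, 1], , drop = FALSE])
  n / .rownorm(n)
}

#' Minimum distance from points to a triangulated surface
#'
#' Exact point-to-triangle minimum Euclidean distance over all faces of
#' `mesh`, for each row of `points`. The default spatial-index path returns
#' values identical to the brute-force double loop.
#'
#' @param points n x 3 matrix of query points (mm).
#' @param mesh a [surface_mesh()].
#' @param method `"index"` (uniform-grid accelerated, default) or `"brute"`.
#' @return A list with `dist` (mm), `face` (1-based nearest face index) and
#'   `closest` (n x 3 matrix of closest surface points).
#' @export
mesh_distance <- function(points, mesh, method = c("index", "brute")) {
  method <- match.arg(method)
  points <- as.matrix(points)
  storage.mode(points) <- "double"
  .assert(.is_num_mat3(points), "points must be an n x 3 numeric matrix")
  .assert(all(is.finite(points)), "query points contain non-finite coordinates")
  res <- cpp_mesh_dist(points, mesh$vertices, mesh$faces - 1L,
                       method == "index")
  list(dist = res$dist, face = res$face + 1L, closest = res$closest)
}

#' Cartilage thickness map from bone and cartilage surface meshes
#'
#' Computes cartilage thickness at each vertex of the subchondral bone mesh
#' as the minimum Euclidean distance to the cartilage surface (continuous
#' point-to-triangle distance, not point-to-vertex).
#'
#' A bone vertex counts as *covered* when its minimum distance does not
#' exceed `coverage_cap` and (optionally) the nearest cartilage face's
#' outward normal points away from the bone vertex; uncovered vertices are
#' flagged and excluded from aggregation. The clinical analogue of an
#' uncovered vertex is denuded or non-articular bone.
#'
#' @param bone,cartilage [surface_mesh()] objects in a common frame.
#' @param coverage_cap maximum distance (mm) for a vertex to count as
#'   covered; default 8 mm.
#' @param normal_check require the nearest cartilage normal to face away
#'   from bone (default `TRUE`; set `FALSE` for meshes without a consistent
#'   outward winding).
#' @param method distance query method, see [mesh_distance()].
#' @return An object of class `thickness_map`: list with `thickness` (mm,
#'   per bone vertex), `covered` (logical), `nearest_face` (into cartilage
#'   faces) and `n_vertices`.
#' @export
#' @examples
#' ph <- phantom_spec(mesh_resolution = 4)
#' mod <- make_condyle_models(ph)
#' tm <- compute_thickness(mod$bone, mod$cartilage)
#' summary(tm$thickness[tm$covered])
compute_thickness <- function(bone, cartilage, coverage_cap = 8,
                              normal_check = TRUE,
                              method = c("index", "brute")) {
  .assert(inherits(bone, "surface_mesh") && inherits(cartilage, "surface_mesh"),
          "bone and cartilage must be surface_mesh objects")
  .assert(nrow(cartilage$faces) > 0, "cartilage mesh is empty")
  q <- mesh_distance(bone$vertices, cartilage, method = method)
  covered <- q$dist <= coverage_cap
  if (normal_check) {
    fn <- face_normals(cartilage)[q$face, , drop = FALSE]
    away <- rowSums(fn * (q$closest - bone$vertices))
    # tolerance absorbs rounding when the vertex lies on the surface
    covered <- covered & (away >= -1e-9)
  }
  structure(list(thickness = q$dist, covered = covered,
                 nearest_face = q$face, n_vertices = nrow(bone$vertices)),
            class = "thickness_map")
}

#' @export
print.thickness_map <- function(x, ...) {
  cat(sprintf("<thickness_map> %d vertices, %d covered; mean %.3f mm\n",
              x$n_vertices, sum(x$covered),
              mean(x$thickness[x$covered])))
  invisible(x)
}

#' Mean cartilage thickness per VOI and sub-VOI
#'
#' Arithmetic mean of covered-vertex thickness within each VOI label of a
#' partition, plus the anterior sub-VOIs. A label with zero covered vertices
#' yields `NA` (missing), never zero.
#'
#' @param map a [compute_thickness()] result.
#' @param partition a [partition_vois()] result on the same bone mesh.
#' @return data.frame with columns `voi`, `mean_mm`, `n_vertices`.
#' @export
mean_thickness_per_voi <- function(map, partition) {
  .assert(inherits(map, "thickness_map"), "map must be a thickness_map")
  .assert(inherits(partition, "voi_partition"),
          "partition must be a voi_partition")
  .assert(length(partition$vertex_voi) == map$n_vertices,
          "partition and thickness map refer to different meshes")
  labs <- c(.VOI_LEVELS, .SUBVOI_LEVELS)
  out <- data.frame(voi = labs, mean_mm = NA_real_, n_vertices = 0L,
                    stringsAsFactors = FALSE)
  lab_vec <- as.character(partition$vertex_voi)
  sub_vec <- as.character(partition$vertex_subvoi)
  for (i in seq_along(labs)) {
    lab <- labs[i]
    sel <- if (lab %in% .VOI_LEVELS) {
      !is.na(lab_vec) & lab_vec == lab
    } else {
      !is.na(sub_vec) & sub_vec == lab
    }
    sel <- sel & map$covered
    out$n_vertices[i] <- sum(sel)
    if (any(sel)) out$mean_mm[i] <- mean(map$thickness[sel])
  }
  out
}
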