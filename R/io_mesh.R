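# ASCII PLY and OBJ mesh I/O. Coordinates are printed with %.17g so that a
# write/read round trip reproduces doubles bitwise (serialized forms are
# deterministic for identical meshes).

#' Write a surface mesh to PLY or OBJ
#'
#' Format is chosen from the file extension (`.ply` ASCII or `.obj`).
#'
#' @param mesh a [surface_mesh()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_mesh <- function(mesh, path) {
  .assert(inherits(mesh, "surface_mesh"), "mesh must be a surface_mesh")
  ext <- tolower(tools::file_ext(path))
  v <- mesh$vertices; f <- mesh$faces
  if (ext == "ply") {
    header <- c(
      "ply", "format ascii 1.0", "comment qmricart",
      sprintf("element vertex %d", nrow(v)),
      "property double x", "property double y", "property double z",
      sprintf("element face %d", nrow(f)),
      "property list uchar int vertex_indices",
      "end_header"
    )
    vl <- sprintf("%.17g %.17g %.17g", v[, 1], v[, 2], v[, 3])
    fl <- sprintf("3 %d %d %d", f[, 1] - 1L, f[, 2] - 1L, f[, 3] - 1L)
    writeLines(c(header, vl, fl), path)
  } else if (ext == "obj") {
    vl <- sprintf("v %.17g %.17g %.17g", v[, 1], v[, 2], v[, 3])
    fl <- sprintf("f %d %d %d", f[, 1], f[, 2], f[, 3])
    writeLines(c("# qmricart", vl, fl), path)
  } else {
    stop("unsupported mesh format: ", ext, call. = FALSE)
  }
  invisible(path)
}

#' Read a surface mesh from PLY or OBJ
#'
#' ASCII PLY (triangular faces; vertex properties x, y, z by name) and
#' Wavefront OBJ (`v`/`f` records, polygon faces fan-triangulated) are
#' supported.
#'
#' @param path input path.
#' @return a [surface_mesh()].
#' @export
read_mesh <- function(path) {
  .assert(file.exists(path), paste("file not found:", path))
  ext <- tolower(tools::file_ext(path))
  if (ext == "ply") .read_ply(path) else if (ext == "obj") .read_obj(path)
  else stop("unsupported mesh format: ", ext, call. = FALSE)
}

.read_ply <- function(path) {
  lines <- readLines(path)
  .assert(length(lines) > 0 && trimws(lines[1]) == "ply",
          "malformed PLY: missing 'ply' magic line")
  endh <- which(trimws(lines) == "end_header")[1]
  .assert(!is.na(endh), "malformed PLY: missing end_header")
  header <- lines[seq_len(endh)]
  .assert(any(grepl("^format ascii", trimws(header))),
          "only ASCII PLY is supported")
  # parse element declarations and their property names in order
  elems <- list()
  cur <- NULL
  for (ln in header) {
    tok <- strsplit(trimws(ln), "\\s+")[[1]]
    if (length(tok) >= 3 && tok[1] == "element") {
      cur <- tok[2]
      elems[[cur]] <- list(count = as.integer(tok[3]), props = character())
    } else if (length(tok) >= 2 && tok[1] == "property" && !is.null(cur)) {
      elems[[cur]]$props <- c(elems[[cur]]$props, tok[length(tok)])
    }
  }
  .assert(all(c("vertex", "face") %in% names(elems)),
          "malformed PLY: vertex or face element missing")
  nv <- elems$vertex$count; nf <- elems$face$count
  body <- lines[(endh + 1):length(lines)]
  .assert(length(body) >= nv + nf, "malformed PLY: truncated body")
  vprops <- elems$vertex$props
  xyz <- match(c("x", "y", "z"), vprops)
  .assert(!anyNA(xyz), "malformed PLY: vertex element lacks x/y/z properties")
  vmat <- matrix(as.numeric(unlist(strsplit(trimws(body[seq_len(nv)]), "\\s+"))),
                 nrow = nv, byrow = TRUE)
  v <- vmat[, xyz, drop = FALSE]
  ftoks <- strsplit(trimws(body[nv + seq_len(nf)]), "\\s+")
  f <- t(vapply(ftoks, function(tk) {
    cnt <- as.integer(tk[1])
    .assert(cnt == 3L, "malformed PLY: only triangular faces are supported")
    as.integer(tk[2:4]) + 1L
  }, integer(3)))
  surface_mesh(v, f)
}

.read_obj <- function(path) {
  lines <- readLines(path)
  vl <- lines[startsWith(lines, "v ")]
  fl <- lines[startsWith(lines, "f ")]
  .assert(length(vl) > 0 && length(fl) > 0, "malformed OBJ: no v/f records")
  v <- matrix(as.numeric(unlist(lapply(strsplit(trimws(vl), "\\s+"),
                                       function(tk) tk[2:4]))),
              ncol = 3, byrow = TRUE)
  faces <- list()
  for (ln in fl) {
    tk <- strsplit(trimws(ln), "\\s+")[[1]][-1]
    idx <- as.integer(vapply(strsplit(tk, "/"), `[[`, "", 1))
    .assert(length(idx) >= 3 && !anyNA(idx), "malformed OBJ: bad face record")
    for (j in seq_len(length(idx) - 2L)) {   # fan triangulation
      faces[[length(faces) + 1L]] <- c(idx[1], idx[j + 1], idx[j + 2])
    }
  }
  surface_mesh(v, do.call(rbind, faces))
}

#' Write / read a data table as RFC-4180 CSV
#'
#' `read_table()` rejects files with missing cells by default, naming the
#' offending row and column.
#'
#' @param table a data.frame.
#' @param path CSV path.
#' @return `write_table()`: `path` invisibly; `read_table()`: a data.frame.
#' @export
write_table <- function(table, path) {
  write.csv(table, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_table
#' @param allow_missing permit empty/NA cells (default `FALSE`).
#' @export
read_table <- function(path, allow_missing = FALSE) {
  .assert(file.exists(path), paste("file not found:", path))
  df <- read.csv(path, stringsAsFactors = FALSE)
  if (!allow_missing) {
    for (j in seq_along(df)) {
      bad <- which(is.na(df[[j]]) | (is.character(df[[j]]) & df[[j]] == ""))
      if (length(bad)) {
        stop(sprintf("missing value at row %d, column '%s' of %s",
                     bad[1], names(df)[j], path), call. = FALSE)
      }
    }
  }
  df
}
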