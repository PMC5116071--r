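#' Construct a triangle mesh
#'
#' @param vertices V x 3 numeric matrix of coordinates (mm).
#' @param faces F x 3 integer matrix of 1-based vertex indices, consistently
#'   wound (counter-clockwise seen from outside for closed meshes).
#' @return Object of class `triangle_mesh` with a `closed` flag (every edge
#'   shared by exactly two faces).
#' @export
triangle_mesh <- function(vertices, faces) {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  faces <- as.matrix(faces)
  storage.mode(faces) <- "integer"
  if (ncol(vertices) != 3L) stop("vertices must be V x 3")
  if (ncol(faces) != 3L) stop("faces must be F x 3")
  if (min(faces) < 1L || max(faces) > nrow(vertices))
    stop("face indices out of range")
  structure(list(vertices = vertices, faces = faces,
                 closed = .mesh_is_closed(faces)),
            class = "triangle_mesh")
}

#' @export
print.triangle_mesh <- function(x, ...) {
  cat("triangle_mesh:", nrow(x$vertices), "vertices,", nrow(x$faces),
      "faces,", if (x$closed) "closed" else "open", "\n")
  invisible(x)
}

# every undirected edge must appear exactly twice (once per direction for
# consistent winding)
.mesh_is_closed <- function(faces) {
  e <- rbind(faces[, c(1, 2)], faces[, c(2, 3)], faces[, c(3, 1)])
  key <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  all(table(key) == 2L)
}

#' Enclosed volume of a closed mesh
#'
#' Signed volume by the divergence theorem (sum of signed tetrahedra to the
#' origin); positive for outward-wound closed meshes.
#'
#' @param mesh a [triangle_mesh()].
#' @return Volume in mm^3.
#' @export
mesh_volume <- function(mesh) {
  v <- mesh$vertices
  f <- mesh$faces
  a <- v[f[, 1], , drop = FALSE]
  b <- v[f[, 2], , drop = FALSE]
  c_ <- v[f[, 3], , drop = FALSE]
  cr <- cbind(b[, 2] * c_[, 3] - b[, 3] * c_[, 2],
              b[, 3] * c_[, 1] - b[, 1] * c_[, 3],
              b[, 1] * c_[, 2] - b[, 2] * c_[, 1])
  sum(a * cr) / 6
}

#' Surface area of a mesh
#' @param mesh a [triangle_mesh()].
#' @return Total triangle area.
#' @export
mesh_area <- function(mesh) {
  v <- mesh$vertices
  f <- mesh$faces
  e1 <- v[f[, 2], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  e2 <- v[f[, 3], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  cr <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
              e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
              e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  sum(sqrt(rowSums(cr^2))) / 2
}

#' Geometric (Taubin) smoothing of a mesh
#'
#' Iterative local averaging of vertex positions with alternating positive
#' and negative relaxation factors (lambda / mu passes), which smooths the
#' surface while limiting the volume shrinkage of plain Laplacian
#' smoothing. One iteration is one lambda pass followed by one mu pass.
#' Topology (faces) is unchanged; `iterations = 0` is the identity.
#'
#' @param mesh a [triangle_mesh()].
#' @param iterations number of smoothing iterations (default 3).
#' @param lambda,mu relaxation factors (defaults 0.33 and -0.34).
#' @return The smoothed `triangle_mesh`.
#' @export
smooth_mesh <- function(mesh, iterations = 3L, lambda = 0.33, mu = -0.34) {
  stopifnot(inherits(mesh, "triangle_mesh"))
  if (iterations < 0) stop("iterations must be nonnegative")
  if (iterations == 0L) return(mesh)
  f <- mesh$faces
  nv <- nrow(mesh$vertices)
  i <- c(f[, 1], f[, 2], f[, 2], f[, 3], f[, 3], f[, 1])
  j <- c(f[, 2], f[, 1], f[, 3], f[, 2], f[, 1], f[, 3])
  A <- Matrix::sparseMatrix(i = i, j = j, x = 1, dims = c(nv, nv))
  A@x[] <- 1  # collapse duplicate edges
  A <- Matrix::Diagonal(x = 1 / Matrix::rowSums(A)) %*% A
  V <- mesh$vertices
  for (it in seq_len(iterations)) {
    V <- V + lambda * (as.matrix(A %*% V) - V)
    V <- V + mu * (as.matrix(A %*% V) - V)
  }
  triangle_mesh(V, f)
}

#' Extract a boundary surface mesh from a labelled volume
#'
#' Builds the closed triangulated isosurface of a binary label at the 0.5
#' level: boundary faces between voxels carrying the label and background
#' are emitted as outward-wound triangle pairs on the voxel-corner grid and
#' scaled to physical units. The result is watertight by construction;
#' downstream geometric smoothing (see [smooth_mesh()]) removes the voxel
#' staircase before spectra are computed.
#'
#' @param labels 3D integer array (or a NIfTI image read by
#'   [read_label_volume()]).
#' @param label_id the label value to extract.
#' @param voxel_size scalar or length-3 voxel edge length in mm (default 1).
#' @return A closed [triangle_mesh()].
#' @export
extract_surface <- function(labels, label_id, voxel_size = 1) {
  labels <- as.array(labels)
  if (length(dim(labels)) != 3L) stop("labels must be a 3D volume")
  voxel_size <- rep_len(as.numeric(voxel_size), 3L)
  mask <- labels == label_id
  if (!any(mask)) stop("label ", label_id, " is absent from the volume")
  d <- dim(mask)
  # pad so every boundary face has a background neighbour
  M <- array(FALSE, d + 2L)
  M[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)] <- mask
  dm <- dim(M)
  idx <- which(M)
  ai <- arrayInd(idx, dm)
  # corner-grid key for vertex dedup: corners live on (0..nx) x ... lattice
  nxc <- dm[1] + 1L
  nyc <- dm[2] + 1L
  corner_key <- function(x, y, z) (z * nyc + y) * nxc + x
  quads_i <- list(); quads_j <- list(); quads_k <- list(); quads_l <- list()
  shifts <- list(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
                 c(0, 0, 1), c(0, 0, -1))
  # for each face direction: the 4 corner offsets, ordered so the normal
  # (right-hand rule) points along the shift direction
  corner_tab <- list(
    `+x` = rbind(c(1, 0, 0), c(1, 1, 0), c(1, 1, 1), c(1, 0, 1)),
    `-x` = rbind(c(0, 0, 0), c(0, 0, 1), c(0, 1, 1), c(0, 1, 0)),
    `+y` = rbind(c(0, 1, 0), c(0, 1, 1), c(1, 1, 1), c(1, 1, 0)),
    `-y` = rbind(c(0, 0, 0), c(1, 0, 0), c(1, 0, 1), c(0, 0, 1)),
    `+z` = rbind(c(0, 0, 1), c(1, 0, 1), c(1, 1, 1), c(0, 1, 1)),
    `-z` = rbind(c(0, 0, 0), c(0, 1, 0), c(1, 1, 0), c(1, 0, 0)))
  keys <- list()
  for (s in seq_along(shifts)) {
    sh <- shifts[[s]]
    nb <- cbind(ai[, 1] + sh[1], ai[, 2] + sh[2], ai[, 3] + sh[3])
    exposed <- !M[nb]
    if (!any(exposed)) { keys[[s]] <- NULL; next }
    base <- ai[exposed, , drop = FALSE] - 1L  # voxel lower corner (0-based)
    co <- corner_tab[[s]]
    k4 <- sapply(1:4, function(q)
      corner_key(base[, 1] + co[q, 1], base[, 2] + co[q, 2],
                 base[, 3] + co[q, 3]))
    if (is.null(dim(k4))) k4 <- matrix(k4, nrow = 1)
    keys[[s]] <- k4
  }
  quads <- do.call(rbind, keys)
  ukeys <- sort(unique(as.vector(quads)))
  vid <- match(quads, ukeys)
  dim(vid) <- dim(quads)
  # decode corner keys back to lattice coordinates (0-based, minus padding)
  z <- ukeys %/% (nyc * nxc)
  rem <- ukeys %% (nyc * nxc)
  y <- rem %/% nxc
  x <- rem %% nxc
  verts <- cbind((x - 1) * voxel_size[1], (y - 1) * voxel_size[2],
                 (z - 1) * voxel_size[3])
  faces <- rbind(vid[, c(1, 2, 3)], vid[, c(1, 3, 4)])
  mesh <- triangle_mesh(verts, faces)
  if (!mesh$closed) warning("extracted surface is not watertight")
  mesh
}

#' Read a NIfTI label volume
#'
#' Thin wrapper over RNifti returning the integer array and voxel size.
#'
#' @param path NIfTI-1 file.
#' @return List with `data` (3D array) and `voxel_size` (length 3, mm).
#' @export
read_label_volume <- function(path) {
  img <- RNifti::readNifti(path)
  vs <- RNifti::pixdim(img)[1:3]
  list(data = as.array(img), voxel_size = vs)
}

#' Read and write meshes in ascii OFF / PLY formats
#'
#' @param path file path; format chosen by extension for `read_mesh()`.
#' @return `read_mesh()` returns a [triangle_mesh()].
#' @export
read_mesh <- function(path) {
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         off = .read_off(path),
         ply = .read_ply(path),
         stop("unsupported mesh format: ", ext))
}

#' @rdname read_mesh
#' @param mesh a [triangle_mesh()].
#' @export
write_mesh <- function(mesh, path) {
  stopifnot(inherits(mesh, "triangle_mesh"))
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         off = .write_off(mesh, path),
         ply = .write_ply(mesh, path),
         stop("unsupported mesh format: ", ext))
  invisible(path)
}

.read_off <- function(path) {
  lines <- readLines(path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (toupper(lines[1]) != "OFF") stop(path, " is not an OFF file")
  counts <- scan(text = lines[2], quiet = TRUE)
  nv <- counts[1]; nf <- counts[2]
  verts <- matrix(scan(text = lines[3:(2 + nv)], quiet = TRUE),
                  ncol = 3, byrow = TRUE)
  fl <- lapply(lines[(3 + nv):(2 + nv + nf)], function(l)
    scan(text = l, quiet = TRUE))
  if (any(vapply(fl, `[`, numeric(1), 1) != 3))
    stop("only triangular OFF faces are supported")
  faces <- t(vapply(fl, function(r) r[2:4], numeric(3))) + 1L
  triangle_mesh(verts, faces)
}

.write_off <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("OFF", con)
  writeLines(sprintf("%d %d 0", nrow(mesh$vertices), nrow(mesh$faces)), con)
  writeLines(apply(mesh$vertices, 1, paste, collapse = " "), con)
  writeLines(paste(3, mesh$faces[, 1] - 1L, mesh$faces[, 2] - 1L,
                   mesh$faces[, 3] - 1L), con)
}

.read_ply <- function(path) {
  lines <- readLines(path)
  if (trimws(lines[1]) != "ply") stop(path, " is not a PLY file")
  hdr_end <- which(trimws(lines) == "end_header")[1]
  hdr <- lines[1:hdr_end]
  if (!any(grepl("format ascii", hdr))) stop("only ascii PLY is supported")
  nv <- as.integer(sub(".*element vertex (\\d+).*", "\\1",
                       grep("element vertex", hdr, value = TRUE)[1]))
  nf <- as.integer(sub(".*element face (\\d+).*", "\\1",
                       grep("element face", hdr, value = TRUE)[1]))
  body <- lines[(hdr_end + 1):length(lines)]
  verts <- matrix(scan(text = body[1:nv], quiet = TRUE),
                  nrow = nv, byrow = TRUE)[, 1:3, drop = FALSE]
  fl <- lapply(body[(nv + 1):(nv + nf)], function(l)
    scan(text = l, quiet = TRUE))
  faces <- t(vapply(fl, function(r) r[2:4], numeric(3))) + 1L
  triangle_mesh(verts, faces)
}

.write_ply <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("ply", "format ascii 1.0",
               sprintf("element vertex %d", nrow(mesh$vertices)),
               "property float x", "property float y", "property float z",
               sprintf("element face %d", nrow(mesh$faces)),
               "property list uchar int vertex_indices",
               "end_header"), con)
  writeLines(apply(mesh$vertices, 1, paste, collapse = " "), con)
  writeLines(paste(3, mesh$faces[, 1] - 1L, mesh$faces[, 2] - 1L,
                   mesh$faces[, 3] - 1L), con)
}
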