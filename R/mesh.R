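#' Construct a SurfaceMesh
#'
#' Computes the watertight flag (every edge shared by exactly two
#' triangles) and the number of connected components.
#'
#' @param vertices n x 3 numeric matrix of world coordinates, mm.
#' @param triangles m x 3 integer matrix of 1-based vertex indices with
#'   outward-facing winding.
#' @return A [SurfaceMesh-class].
#' @export
SurfaceMesh <- function(vertices, triangles) {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  triangles <- as.matrix(triangles)
  storage.mode(triangles) <- "integer"
  wt <- FALSE; nc <- 0L
  if (nrow(triangles)) {
    e1 <- rbind(triangles[, c(1, 2), drop = FALSE],
                triangles[, c(2, 3), drop = FALSE],
                triangles[, c(3, 1), drop = FALSE])
    key <- pmin(e1[, 1], e1[, 2]) * (nrow(vertices) + 1) +
      pmax(e1[, 1], e1[, 2])
    wt <- all(table(key) == 2L)
    vcomp <- .meshComponents(triangles, nrow(vertices))
    nc <- length(unique(vcomp[triangles[, 1]]))
  }
  new("SurfaceMesh", vertices = vertices, triangles = triangles,
      watertight = wt, ncomp = nc)
}

#' @describeIn SurfaceMesh total surface area, mm^2
#' @param x a SurfaceMesh.
#' @export
setMethod("meshArea", "SurfaceMesh", function(x) {
  if (!nrow(x@triangles)) return(0)
  a <- x@vertices[x@triangles[, 1], , drop = FALSE]
  b <- x@vertices[x@triangles[, 2], , drop = FALSE]
  cc <- x@vertices[x@triangles[, 3], , drop = FALSE]
  cr <- vecCross(b - a, cc - a)
  sum(sqrt(rowSums(cr^2))) / 2
})

#' @describeIn SurfaceMesh enclosed volume by the divergence theorem, mm^3
#'   (positive for outward-oriented watertight meshes)
#' @export
setMethod("meshVolume", "SurfaceMesh", function(x) {
  if (!nrow(x@triangles)) return(0)
  a <- x@vertices[x@triangles[, 1], , drop = FALSE]
  b <- x@vertices[x@triangles[, 2], , drop = FALSE]
  cc <- x@vertices[x@triangles[, 3], , drop = FALSE]
  sum(rowSums(a * vecCross(b, cc))) / 6
})

vecCross <- function(u, v) {
  cbind(u[, 2] * v[, 3] - u[, 3] * v[, 2],
        u[, 3] * v[, 1] - u[, 1] * v[, 3],
        u[, 1] * v[, 2] - u[, 2] * v[, 1])
}

## per-triangle component ids
triangleComponents <- function(mesh) {
  vcomp <- .meshComponents(mesh@triangles, nrow(mesh@vertices))
  vcomp[mesh@triangles[, 1]]
}

## subset a mesh to the given triangles, dropping unreferenced vertices
subsetMesh <- function(mesh, keepTri) {
  tris <- mesh@triangles[keepTri, , drop = FALSE]
  used <- sort(unique(as.vector(tris)))
  remap <- integer(nrow(mesh@vertices))
  remap[used] <- seq_along(used)
  SurfaceMesh(mesh@vertices[used, , drop = FALSE],
              matrix(remap[tris], ncol = 3))
}

## largest connected component by enclosed volume (area as tie-break)
largestComponent <- function(mesh) {
  if (mesh@ncomp <= 1L) return(mesh)
  tc <- triangleComponents(mesh)
  comps <- unique(tc)
  vols <- vapply(comps, function(cid)
    abs(meshVolume(subsetMesh(mesh, tc == cid))), numeric(1))
  subsetMesh(mesh, tc == comps[which.max(vols)])
}

#' Export a surface mesh
#'
#' Formats by extension: `.stl` (binary, little-endian), `.ply` (ASCII),
#' `.obj` (Wavefront ASCII).  Output is byte-stable for fixed input.
#'
#' @param mesh a [SurfaceMesh-class].
#' @param path output path.
#' @return Invisibly, a report list with `path`, `triangles` and
#'   `watertight` (non-watertight meshes are written with a recorded flag,
#'   not rejected).
#' @export
exportSurface <- function(mesh, path) {
  v <- mesh@vertices; tr <- mesh@triangles
  if (grepl("\\.stl$", path, ignore.case = TRUE)) {
    con <- file(path, "wb")
    on.exit(close(con))
    writeBin(charToRaw(formatC("poroseg binary STL", width = -80)), con)
    writeBin(as.integer(nrow(tr)), con, size = 4L, endian = "little")
    a <- v[tr[, 1], , drop = FALSE]; b <- v[tr[, 2], , drop = FALSE]
    cc <- v[tr[, 3], , drop = FALSE]
    n <- vecCross(b - a, cc - a)
    len <- sqrt(rowSums(n^2)); len[len == 0] <- 1
    n <- n / len
    block <- t(cbind(n, a, b, cc))  # 12 floats per triangle
    for (i in seq_len(nrow(tr))) {
      writeBin(as.numeric(block[, i]), con, size = 4L, endian = "little")
      writeBin(raw(2), con)
    }
  } else if (grepl("\\.ply$", path, ignore.case = TRUE)) {
    hdr <- c("ply", "format ascii 1.0",
             paste("element vertex", nrow(v)),
             "property double x", "property double y", "property double z",
             paste("element face", nrow(tr)),
             "property list uchar int vertex_indices", "end_header")
    vl <- apply(format(v, digits = 17, trim = TRUE, scientific = FALSE),
                1, paste, collapse = " ")
    fl <- paste(3, tr[, 1] - 1L, tr[, 2] - 1L, tr[, 3] - 1L)
    writeLines(c(hdr, vl, fl), path)
  } else if (grepl("\\.obj$", path, ignore.case = TRUE)) {
    vl <- paste("v", apply(format(v, digits = 17, trim = TRUE,
                                  scientific = FALSE), 1, paste,
                           collapse = " "))
    fl <- paste("f", tr[, 1], tr[, 2], tr[, 3])
    writeLines(c(vl, fl), path)
  } else stop("unsupported mesh format for '", path,
              "' (use .stl, .ply or .obj)", call. = FALSE)
  invisible(list(path = path, triangles = nrow(tr),
                 watertight = mesh@watertight))
}

#' Read a surface mesh (STL binary, PLY ASCII or OBJ)
#'
#' STL stores a triangle soup; identical vertex coordinates are merged on
#' read so that connectivity is restored.
#'
#' @param path mesh file path.
#' @return A [SurfaceMesh-class].
#' @export
readSurface <- function(path) {
  if (grepl("\\.stl$", path, ignore.case = TRUE)) {
    con <- file(path, "rb")
    on.exit(close(con))
    readBin(con, "raw", 80L)
    nt <- readBin(con, "integer", 1L, size = 4L, endian = "little")
    blocks <- readBin(con, "raw", nt * 50L)  # 12 floats + 2 bytes each
    dataIdx <- rep((seq_len(nt) - 1L) * 50L, each = 48L) + seq_len(48L)
    vals <- readBin(blocks[dataIdx], "double", nt * 12L, size = 4L,
                    endian = "little")
    vals <- matrix(vals, ncol = 12L, byrow = TRUE)  # n, a, b, c
    verts <- matrix(0, nt * 3L, 3L)
    verts[seq(1, 3 * nt, 3), ] <- vals[, 4:6, drop = FALSE]
    verts[seq(2, 3 * nt, 3), ] <- vals[, 7:9, drop = FALSE]
    verts[seq(3, 3 * nt, 3), ] <- vals[, 10:12, drop = FALSE]
    key <- apply(verts, 1, paste, collapse = "|")
    uid <- match(key, unique(key))
    uverts <- verts[!duplicated(key), , drop = FALSE]
    tris <- matrix(uid, ncol = 3, byrow = TRUE)
    SurfaceMesh(uverts, tris)
  } else if (grepl("\\.ply$", path, ignore.case = TRUE)) {
    lines <- readLines(path)
    endH <- which(lines == "end_header")[1]
    nv <- as.integer(sub("element vertex ", "",
                         grep("^element vertex", lines, value = TRUE)[1]))
    nf <- as.integer(sub("element face ", "",
                         grep("^element face", lines, value = TRUE)[1]))
    v <- do.call(rbind, lapply(strsplit(lines[endH + seq_len(nv)], " "),
                               as.numeric))
    f <- do.call(rbind, lapply(strsplit(lines[endH + nv + seq_len(nf)], " "),
                               as.integer))
    SurfaceMesh(v[, 1:3, drop = FALSE], f[, 2:4, drop = FALSE] + 1L)
  } else if (grepl("\\.obj$", path, ignore.case = TRUE)) {
    lines <- readLines(path)
    vlines <- grep("^v ", lines, value = TRUE)
    flines <- grep("^f ", lines, value = TRUE)
    v <- do.call(rbind, lapply(strsplit(vlines, "\\s+"),
                               function(x) as.numeric(x[2:4])))
    f <- do.call(rbind, lapply(strsplit(flines, "\\s+"),
                               function(x) as.integer(sub("/.*", "", x[2:4]))))
    SurfaceMesh(v, f)
  } else stop("unsupported mesh format for '", path, "'", call. = FALSE)
}
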