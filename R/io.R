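# File formats: NIfTI label/tensor volumes (RNifti), MRtrix TCK tract
# files, JSON-lines polylines, binary-little-endian PLY and ASCII STL
# meshes, and marker CSV tables. World coordinates are always mm; the
# NIfTI affine (0-based voxel index to world) is the single source of the
# voxel-to-world mapping.

.tensorDescrip <- "DT lower-tri: Dxx Dxy Dyy Dxz Dyz Dzz (mm^2/s)"

.asNiftiWithAffine <- function(arr, affine, descrip = "") {
  vox <- sqrt(colSums(affine[1:3, 1:3]^2))
  img <- RNifti::asNifti(arr, reference = list(
    pixdim = c(-1, vox, rep(1, 4)), descrip = descrip))
  RNifti::`sform<-`(img, structure(affine, code = 2L))
}

#' Write a label map as NIfTI
#'
#' @param labels 3D integer array.
#' @param affine 4x4 voxel(0-based)-to-world map.
#' @param path output file (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
writeLabelNifti <- function(labels, affine, path) {
  RNifti::writeNifti(.asNiftiWithAffine(labels, affine, "label map"), path)
  invisible(path)
}

#' Read a label map from NIfTI
#' @param path NIfTI file.
#' @return List with `labels` (3D array) and `affine`.
#' @export
readLabelNifti <- function(path) {
  img <- RNifti::readNifti(path)
  aff <- structure(RNifti::xform(img), imagedim = NULL, code = NULL)
  list(labels = array(as.integer(round(img)), dim(img)),
       affine = matrix(as.numeric(aff), 4L, 4L))
}

#' Write a tensor volume as a 6-component NIfTI
#'
#' The fourth dimension carries the unique tensor components in
#' lower-triangular order `Dxx, Dxy, Dyy, Dxz, Dyz, Dzz`, recorded in the
#' header description field.
#'
#' @param vol a [TensorVolume-class].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeTensorNifti <- function(vol, path) {
  RNifti::writeNifti(.asNiftiWithAffine(vol@tensors, vol@affine,
                                        .tensorDescrip), path)
  invisible(path)
}

#' Read a tensor volume from a 6-component NIfTI
#' @param path NIfTI file with a trailing dimension of 6.
#' @return A [TensorVolume-class].
#' @export
readTensorNifti <- function(path) {
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) != 4L || d[4L] != 6L)
    stop("expected a 4D NIfTI with 6 tensor components")
  aff <- RNifti::xform(img)
  tensorVolume(array(as.numeric(img), d),
               matrix(as.numeric(aff), 4L, 4L))
}

# --- TCK -------------------------------------------------------------------

#' Write a tract bundle as an MRtrix TCK file
#'
#' World-mm Float32LE triplets with NaN tract separators and an Inf
#' terminator, as read by MRtrix and DSI Studio.
#'
#' @param bundle a [TractBundle-class].
#' @param path output `.tck` file.
#' @return `path`, invisibly.
#' @export
writeTck <- function(bundle, path) {
  mkHeader <- function(offset)
    sprintf("mrtrix tracks\ndatatype: Float32LE\ncount: %d\nfile: . %d\nEND\n",
            nTracts(bundle), offset)
  off <- nchar(mkHeader(0))
  while (nchar(mkHeader(off)) != off) off <- nchar(mkHeader(off))
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar(mkHeader(off), con, eos = NULL)
  for (t in bundle@tracts) {
    writeBin(as.numeric(t(t)), con, size = 4L, endian = "little")
    writeBin(rep(NaN, 3), con, size = 4L, endian = "little")
  }
  writeBin(rep(Inf, 3), con, size = 4L, endian = "little")
  invisible(path)
}

#' Read an MRtrix TCK file
#' @param path `.tck` file (Float32LE).
#' @return A [TractBundle-class].
#' @export
readTck <- function(path) {
  raw <- readBin(path, "raw", file.size(path))
  hdrEnd <- grepRaw("END\n", raw)[1L]
  if (is.na(hdrEnd)) stop("not a TCK file (no END marker)")
  hdr <- strsplit(rawToChar(raw[seq_len(hdrEnd + 3L)]), "\n")[[1L]]
  if (hdr[1L] != "mrtrix tracks") stop("not a TCK file")
  kv <- hdr[grepl(":", hdr, fixed = TRUE)]
  keys <- sub(":.*", "", kv)
  vals <- trimws(sub("^[^:]*:", "", kv))
  if (tolower(vals[keys == "datatype"]) != "float32le")
    stop("only Float32LE TCK files are supported")
  off <- as.integer(strsplit(vals[keys == "file"], " ")[[1L]][2L])
  dat <- readBin(raw[(off + 1L):length(raw)], "numeric",
                 n = (length(raw) - off) / 4L, size = 4L,
                 endian = "little")
  pts <- matrix(dat, ncol = 3L, byrow = TRUE)
  tracts <- list(); cur <- 1L
  for (i in seq_len(nrow(pts))) {
    if (all(is.infinite(pts[i, ]))) break
    if (all(is.nan(pts[i, ]))) {
      if (i > cur)
        tracts[[length(tracts) + 1L]] <- pts[cur:(i - 1L), , drop = FALSE]
      cur <- i + 1L
    }
  }
  tractBundle(tracts)
}

#' Write a tract bundle as JSON lines
#'
#' Plain-text fallback for the binary TCK format: one JSON array of
#' `[x, y, z]` points per line, one line per tract.
#'
#' @param bundle a [TractBundle-class].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeTractsJsonl <- function(bundle, path) {
  lines <- vapply(bundle@tracts, function(t)
    as.character(jsonlite::toJSON(unname(split(t, row(t))),
                                  digits = NA)), character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a JSON-lines tract file
#' @param path file written by [writeTractsJsonl()].
#' @return A [TractBundle-class].
#' @export
readTractsJsonl <- function(path) {
  lines <- readLines(path)
  tracts <- lapply(lines, function(l) {
    m <- jsonlite::fromJSON(l)
    if (is.list(m)) m <- do.call(rbind, m)
    matrix(as.numeric(m), ncol = 3L)
  })
  tractBundle(tracts)
}

# --- meshes ----------------------------------------------------------------

#' Write a mesh as binary little-endian PLY
#' @param mesh a [SurfaceMesh-class].
#' @param path output `.ply` file.
#' @return `path`, invisibly.
#' @export
writePly <- function(mesh, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    "ply\nformat binary_little_endian 1.0\n",
    "element vertex ", nrow(mesh@vertices), "\n",
    "property float x\nproperty float y\nproperty float z\n",
    "element face ", nrow(mesh@triangles), "\n",
    "property list uchar int vertex_indices\nend_header\n")
  writeChar(hdr, con, eos = NULL)
  writeBin(as.numeric(t(mesh@vertices)), con, size = 4L, endian = "little")
  tri0 <- t(mesh@triangles) - 1L
  for (i in seq_len(ncol(tri0))) {
    writeBin(as.raw(3L), con)
    writeBin(as.integer(tri0[, i]), con, size = 4L, endian = "little")
  }
  invisible(path)
}

#' Read a binary little-endian PLY mesh
#' @param path `.ply` file in the layout written by [writePly()].
#' @return A [SurfaceMesh-class].
#' @export
readPly <- function(path) {
  raw <- readBin(path, "raw", file.size(path))
  hdrEnd <- grepRaw("end_header\n", raw)[1L]
  if (is.na(hdrEnd)) stop("not a PLY file")
  hdr <- strsplit(rawToChar(raw[seq_len(hdrEnd + 10L)]), "\n")[[1L]]
  if (hdr[1L] != "ply") stop("not a PLY file")
  if (!any(grepl("binary_little_endian", hdr)))
    stop("only binary little-endian PLY is supported")
  nv <- as.integer(sub("element vertex ", "",
                       hdr[grepl("^element vertex", hdr)]))
  nf <- as.integer(sub("element face ", "",
                       hdr[grepl("^element face", hdr)]))
  off <- hdrEnd + 10L
  verts <- readBin(raw[(off + 1L):length(raw)], "numeric", n = 3L * nv,
                   size = 4L, endian = "little")
  off <- off + 12L * nv
  tri <- matrix(0L, nf, 3L)
  for (i in seq_len(nf)) {
    cnt <- as.integer(raw[off + 1L])
    if (cnt != 3L) stop("only triangle faces are supported")
    tri[i, ] <- readBin(raw[(off + 2L):(off + 13L)], "integer", n = 3L,
                        size = 4L, endian = "little") + 1L
    off <- off + 13L
  }
  surfaceMesh(matrix(verts, ncol = 3L, byrow = TRUE), tri)
}

#' Write a mesh as ASCII STL
#' @param mesh a [SurfaceMesh-class].
#' @param path output `.stl` file.
#' @param name solid name recorded in the file.
#' @return `path`, invisibly.
#' @export
writeStl <- function(mesh, path, name = "muscle") {
  V <- mesh@vertices; Tm <- mesh@triangles; N <- mesh@normals
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste("solid", name), con)
  for (i in seq_len(nrow(Tm))) {
    writeLines(c(
      sprintf("  facet normal %.9g %.9g %.9g", N[i, 1L], N[i, 2L], N[i, 3L]),
      "    outer loop",
      sprintf("      vertex %.9g %.9g %.9g",
              V[Tm[i, ], 1L], V[Tm[i, ], 2L], V[Tm[i, ], 3L]),
      "    endloop", "  endfacet"), con)
  }
  writeLines(paste("endsolid", name), con)
  invisible(path)
}

#' Read an ASCII STL mesh
#'
#' Vertices are welded by exact coordinate match before the mesh is
#' rebuilt.
#'
#' @param path ASCII `.stl` file.
#' @return A [SurfaceMesh-class].
#' @export
readStl <- function(path) {
  lines <- readLines(path)
  vl <- grep("^\\s*vertex ", lines, value = TRUE)
  nums <- do.call(rbind, lapply(strsplit(trimws(vl), "\\s+"), function(p)
    as.numeric(p[2:4])))
  if (nrow(nums) %% 3L != 0L) stop("malformed STL: vertex count not a multiple of 3")
  key <- paste(nums[, 1L], nums[, 2L], nums[, 3L])
  uid <- match(key, key[!duplicated(key)])
  surfaceMesh(nums[!duplicated(key), , drop = FALSE],
              matrix(uid, ncol = 3L, byrow = TRUE))
}

# --- markers ---------------------------------------------------------------

#' Write a marker scene as CSV
#'
#' Columns `label, frame, x_mm, y_mm, z_mm`; the ground-truth transform
#' (if any) is not serialized.
#'
#' @param scene a [MarkerScene-class].
#' @param path output `.csv` file.
#' @return `path`, invisibly.
#' @export
writeMarkersCsv <- function(scene, path) {
  write.csv(scene@markers, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a marker scene from CSV
#' @param path CSV with columns `label, frame, x_mm, y_mm, z_mm`.
#' @return A [MarkerScene-class] (no ground-truth transform).
#' @export
readMarkersCsv <- function(path) {
  new("MarkerScene", markers = read.csv(path, stringsAsFactors = FALSE),
      trueTransform = NULL)
}

# --- results ---------------------------------------------------------------

#' Write a DTI measurement (or architecture result) as JSON
#'
#' @param x a `dtiMeasurement` list from [measureDti()] or an
#'   [ArchitectureResult-class].
#' @param path output `.json` file.
#' @return `path`, invisibly.
#' @export
writeResultJson <- function(x, path) {
  payload <- if (is(x, "ArchitectureResult")) {
    as.list(asArchitectureRow(x))
  } else {
    list(result = as.list(asArchitectureRow(x$result)),
         perBundle = x$perBundle, exclusions = x$exclusions)
  }
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(path)
}
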