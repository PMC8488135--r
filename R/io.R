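## Mesh, landmark and image-volume interchange.
## Meshes: PLY (ascii / binary little-endian) and legacy-VTK polydata
## (ascii). surface_tag and phase are carried by the file naming
## convention <subject>_<phase>_<endo|epi>.<ext> or given explicitly.
## Landmarks: strict JSON schema. Volumes: NIfTI-1 (via RNifti) and
## MetaImage (.mha, local uncompressed data).

guess_mesh_meta <- function(path) {
  base <- tolower(basename(path))
  tag <- if (grepl("epi", base)) "epi" else "endo"
  phase <- if (grepl("(^|[._-])es([._-]|$)", base)) "ES" else "ED"
  list(surface_tag = tag, phase = phase)
}

#' Read or write an LV surface mesh (PLY or legacy VTK polydata)
#'
#' Formats are chosen by file extension: `.ply` (ascii or binary
#' little-endian, selected on write by `binary`) or `.vtk` (ascii legacy
#' polydata). Vertices round-trip in double precision. `surface_tag` and
#' `phase` default to the `<subject>_<phase>_<endo|epi>` naming convention
#' of the file.
#'
#' @param path file path ending in `.ply` or `.vtk`.
#' @param surface_tag,phase mesh metadata; defaults inferred from the file
#'   name.
#' @return A [surface_model()].
#' @export
read_mesh <- function(path, surface_tag = NULL, phase = NULL) {
  meta <- guess_mesh_meta(path)
  surface_tag <- surface_tag %||% meta$surface_tag
  phase <- phase %||% meta$phase
  ext <- tolower(tools::file_ext(path))
  md <- switch(ext,
               ply = read_ply(path),
               vtk = read_vtk_polydata(path),
               stop("unsupported mesh format: .", ext))
  surface_model(md$vertices, md$triangles, surface_tag = surface_tag,
                phase = phase)
}

#' @rdname read_mesh
#' @param mesh a [surface_model()].
#' @param binary write binary little-endian PLY (ignored for VTK).
#' @export
write_mesh <- function(mesh, path, binary = FALSE) {
  stopifnot(inherits(mesh, "surface_model"))
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         ply = write_ply(mesh, path, binary = binary),
         vtk = write_vtk_polydata(mesh, path),
         stop("unsupported mesh format: .", ext))
  invisible(path)
}

read_ply <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  header <- character(0)
  repeat {
    line <- readLines(con, n = 1L)
    if (length(header) == 0L && (length(line) == 0L || line != "ply"))
      stop("parse error in ", path, ": not a PLY file (line 1)")
    if (length(line) == 0L) stop("parse error in ", path, ": truncated header")
    header <- c(header, line)
    if (line == "end_header") break
    if (length(header) > 200L) stop("parse error in ", path, ": header too long")
  }
  fmt <- grep("^format ", header, value = TRUE)
  binary <- grepl("binary_little_endian", fmt)
  if (!binary && !grepl("ascii", fmt))
    stop("parse error in ", path, ": unsupported PLY format '", fmt, "'")
  nv <- as.integer(sub("element vertex ", "", grep("^element vertex", header, value = TRUE)))
  nf_line <- grep("^element face", header, value = TRUE)
  nf <- if (length(nf_line)) as.integer(sub("element face ", "", nf_line)) else 0L
  vprop <- grep("^property (float|double)", header, value = TRUE)
  dbl <- grepl("double", vprop[1L])
  if (binary) {
    sz <- if (dbl) 8L else 4L
    verts <- matrix(readBin(con, "double", n = 3L * nv, size = sz,
                            endian = "little"), nv, 3L, byrow = TRUE)
    tris <- matrix(integer(0), 0L, 3L)
    if (nf > 0L) {
      tris <- matrix(0L, nf, 3L)
      for (i in seq_len(nf)) {
        cnt <- readBin(con, "integer", n = 1L, size = 1L, signed = FALSE)
        if (cnt != 3L) stop("parse error in ", path, ": non-triangular face ", i)
        tris[i, ] <- readBin(con, "integer", n = 3L, size = 4L, endian = "little")
      }
    }
  } else {
    txt <- readLines(con)
    vdat <- scan(text = txt[seq_len(nv)], quiet = TRUE)
    verts <- matrix(vdat, nv, byrow = TRUE)[, 1:3, drop = FALSE]
    tris <- matrix(integer(0), 0L, 3L)
    if (nf > 0L) {
      fdat <- scan(text = txt[nv + seq_len(nf)], quiet = TRUE)
      fm <- matrix(fdat, nf, byrow = TRUE)
      if (any(fm[, 1L] != 3)) stop("parse error in ", path, ": non-triangular face")
      tris <- matrix(as.integer(fm[, 2:4]), nf, 3L)
    }
  }
  list(vertices = verts, triangles = tris + 1L)
}

write_ply <- function(mesh, path, binary = FALSE) {
  nv <- nrow(mesh$vertices); nf <- nrow(mesh$triangles)
  header <- c("ply",
              if (binary) "format binary_little_endian 1.0" else "format ascii 1.0",
              paste("element vertex", nv),
              "property double x", "property double y", "property double z",
              paste("element face", nf),
              "property list uchar int vertex_indices",
              "end_header")
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(header, con)
  if (binary) {
    writeBin(as.double(t(mesh$vertices)), con, size = 8L, endian = "little")
    for (i in seq_len(nf)) {
      writeBin(as.raw(3L), con)
      writeBin(as.integer(mesh$triangles[i, ] - 1L), con, size = 4L,
               endian = "little")
    }
  } else {
    writeLines(apply(mesh$vertices, 1L, function(v)
      paste(sprintf("%.17g", v), collapse = " ")), con)
    if (nf > 0L)
      writeLines(paste(3L, mesh$triangles[, 1L] - 1L, mesh$triangles[, 2L] - 1L,
                       mesh$triangles[, 3L] - 1L), con)
  }
}

read_vtk_polydata <- function(path) {
  txt <- readLines(path)
  if (!grepl("^# vtk DataFile", txt[1L]))
    stop("parse error in ", path, ": not a legacy VTK file (line 1)")
  if (!any(toupper(txt) == "ASCII"))
    stop("parse error in ", path, ": only ASCII legacy VTK is supported")
  ip <- grep("^POINTS ", txt)
  if (length(ip) != 1L) stop("parse error in ", path, ": POINTS section missing")
  nv <- as.integer(strsplit(txt[ip], "\\s+")[[1L]][2L])
  after <- txt[(ip + 1L):length(txt)]
  ipoly <- grep("^POLYGONS ", after)
  pts_txt <- if (length(ipoly)) after[seq_len(ipoly[1L] - 1L)] else after
  vdat <- scan(text = pts_txt, quiet = TRUE)
  if (length(vdat) < 3L * nv)
    stop("parse error in ", path, ": expected ", 3L * nv, " point coordinates")
  verts <- matrix(vdat[seq_len(3L * nv)], nv, 3L, byrow = TRUE)
  tris <- matrix(integer(0), 0L, 3L)
  if (length(ipoly)) {
    nf <- as.integer(strsplit(after[ipoly[1L]], "\\s+")[[1L]][2L])
    fdat <- scan(text = after[(ipoly[1L] + 1L):length(after)],
                 n = 4L * nf, quiet = TRUE)
    fm <- matrix(fdat, nf, 4L, byrow = TRUE)
    if (any(fm[, 1L] != 3)) stop("parse error in ", path, ": non-triangular polygon")
    tris <- matrix(as.integer(fm[, 2:4]), nf, 3L) + 1L
  }
  list(vertices = verts, triangles = tris)
}

write_vtk_polydata <- function(mesh, path) {
  nv <- nrow(mesh$vertices); nf <- nrow(mesh$triangles)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0",
               "LV surface model", "ASCII", "DATASET POLYDATA",
               paste("POINTS", nv, "double")), con)
  writeLines(apply(mesh$vertices, 1L, function(v)
    paste(sprintf("%.17g", v), collapse = " ")), con)
  if (nf > 0L) {
    writeLines(paste("POLYGONS", nf, 4L * nf), con)
    writeLines(paste(3L, mesh$triangles[, 1L] - 1L, mesh$triangles[, 2L] - 1L,
                     mesh$triangles[, 3L] - 1L), con)
  }
}

#' Read or write a landmark set (JSON)
#'
#' Schema: `apical_centroid` and `basal_centroid` as `[x, y, z]` arrays
#' (mm), `rv_insertions` as a list of `{xyz: [x, y, z], label: "inferior" |
#' "anterior" | null}`, and `convention` (`"cmr"` or `"echo"`). Validation
#' is strict (a missing required field is an error naming the field);
#' unknown top-level keys are preserved on rewrite.
#'
#' @param path JSON file path.
#' @return A [landmark_set()].
#' @export
read_landmarks <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = FALSE)
  for (fld in c("apical_centroid", "basal_centroid", "rv_insertions", "convention"))
    if (is.null(j[[fld]]))
      stop("schema error in ", path, ": missing required field '", fld, "'")
  ins <- do.call(rbind, lapply(j$rv_insertions, function(e) {
    if (is.null(e$xyz) || length(e$xyz) != 3L)
      stop("schema error in ", path, ": rv_insertions entries need field 'xyz'")
    data.frame(x = e$xyz[[1L]], y = e$xyz[[2L]], z = e$xyz[[3L]],
               label = if (is.null(e$label)) "unlabeled" else e$label)
  }))
  lm <- landmark_set(unlist(j$apical_centroid), unlist(j$basal_centroid),
                     ins, convention = j$convention)
  extra <- j[setdiff(names(j), c("apical_centroid", "basal_centroid",
                                 "rv_insertions", "convention"))]
  if (length(extra)) attr(lm, "extra") <- extra
  lm
}

#' @rdname read_landmarks
#' @param landmarks a [landmark_set()].
#' @export
write_landmarks <- function(landmarks, path) {
  stopifnot(inherits(landmarks, "landmark_set"))
  ins <- lapply(seq_len(nrow(landmarks$rv_insertions)), function(i) {
    row <- landmarks$rv_insertions[i, ]
    list(xyz = c(row$x, row$y, row$z),
         label = if (row$label == "unlabeled") NULL else row$label)
  })
  obj <- c(list(apical_centroid = landmarks$apical_centroid,
                basal_centroid = landmarks$basal_centroid,
                rv_insertions = ins,
                convention = landmarks$convention),
           attr(landmarks, "extra"))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read or write a 3D image volume (NIfTI-1 or MetaImage)
#'
#' `.nii` / `.nii.gz` files go through RNifti with the spacing, origin and
#' direction encoded in the sform affine; `.mha` files use the MetaImage
#' header with local uncompressed data. Direction matrices must be
#' orthonormal.
#'
#' @param path file ending in `.nii`, `.nii.gz` or `.mha`.
#' @return An [image_volume()].
#' @export
read_volume <- function(path) {
  if (grepl("\\.nii(\\.gz)?$", path, ignore.case = TRUE)) {
    img <- RNifti::readNifti(path)
    aff <- RNifti::xform(img)
    direction <- aff[1:3, 1:3]
    spacing <- sqrt(colSums(direction^2))
    direction <- sweep(direction, 2L, spacing, "/")
    image_volume(array(as.double(img), dim(img)[1:3]), spacing = spacing,
                 origin = aff[1:3, 4L], direction = direction)
  } else if (grepl("\\.mha$", path, ignore.case = TRUE)) {
    read_mha(path)
  } else stop("unsupported volume format: ", basename(path))
}

#' @rdname read_volume
#' @param vol an [image_volume()].
#' @export
write_volume <- function(vol, path) {
  stopifnot(inherits(vol, "image_volume"))
  if (grepl("\\.nii(\\.gz)?$", path, ignore.case = TRUE)) {
    aff <- rbind(cbind(vol$direction %*% diag(vol$spacing), vol$origin),
                 c(0, 0, 0, 1))
    img <- RNifti::asNifti(vol$data)
    img <- RNifti::`sform<-`(img, structure(aff, code = 2L))
    RNifti::writeNifti(img, path)
  } else if (grepl("\\.mha$", path, ignore.case = TRUE)) {
    write_mha(vol, path)
  } else stop("unsupported volume format: ", basename(path))
  invisible(path)
}

read_mha <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- list()
  repeat {
    line <- readLines(con, n = 1L)
    if (length(line) == 0L) stop("parse error in ", path, ": truncated header")
    kv <- strsplit(line, "\\s*=\\s*")[[1L]]
    hdr[[kv[1L]]] <- kv[2L]
    if (kv[1L] == "ElementDataFile") break
  }
  if (!identical(hdr$ElementDataFile, "LOCAL"))
    stop("only LOCAL MetaImage data is supported")
  if (isTRUE(hdr$BinaryDataByteOrderMSB == "True"))
    stop("big-endian MetaImage data is not supported")
  d <- as.integer(strsplit(hdr$DimSize, "\\s+")[[1L]])
  spacing <- as.double(strsplit(hdr$ElementSpacing, "\\s+")[[1L]])
  origin <- as.double(strsplit(hdr$Offset %||% "0 0 0", "\\s+")[[1L]])
  direction <- matrix(as.double(strsplit(
    hdr$TransformMatrix %||% "1 0 0 0 1 0 0 0 1", "\\s+")[[1L]]), 3L, 3L,
    byrow = TRUE)
  size <- switch(hdr$ElementType,
                 MET_DOUBLE = 8L, MET_FLOAT = 4L,
                 stop("unsupported MetaImage element type ", hdr$ElementType))
  n <- prod(d)
  vals <- readBin(con, "double", n = n, size = size, endian = "little")
  image_volume(array(vals, d), spacing = spacing, origin = origin,
               direction = direction)
}

write_mha <- function(vol, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  d <- dim(vol$data)
  writeLines(c("ObjectType = Image",
               "NDims = 3",
               "BinaryData = True",
               "BinaryDataByteOrderMSB = False",
               paste("TransformMatrix =",
                     paste(sprintf("%.17g", t(vol$direction)), collapse = " ")),
               paste("Offset =", paste(sprintf("%.17g", vol$origin), collapse = " ")),
               paste("ElementSpacing =",
                     paste(sprintf("%.17g", vol$spacing), collapse = " ")),
               paste("DimSize =", paste(d, collapse = " ")),
               "ElementType = MET_DOUBLE",
               "ElementDataFile = LOCAL"), con)
  writeBin(as.double(vol$data), con, size = 8L, endian = "little")
}
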