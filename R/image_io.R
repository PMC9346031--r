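#' Read a 3D scalar volume from NIfTI, NRRD or MetaImage
#'
#' Geometry (spacing, origin, direction) is converted to the package's
#' internal convention: physical LPS coordinates in millimetres, 0-based
#' voxel indices, voxel-centre convention. NIfTI stores RAS world
#' coordinates; its affine is flipped to LPS on load.
#'
#' @param path file path ending in .nii, .nii.gz, .nrrd, .mha or .mhd.
#' @return a \linkS4class{ScalarVolume}.
#' @export
readVolume <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  ext <- volume_format(path)
  switch(ext,
         nifti = read_nifti_volume(path),
         nrrd = read_nrrd_volume(path),
         mha = read_meta_volume(path),
         mhd = read_meta_volume(path),
         stop("unsupported volume format: ", path))
}

#' Write a ScalarVolume to NIfTI, NRRD or MetaImage
#'
#' @param vol a \linkS4class{ScalarVolume}.
#' @param path output path (.nii, .nii.gz, .nrrd, .mha or .mhd).
#' @param datatype "auto" (uint8 for integer-valued volumes in [0, 255],
#'   double otherwise), "uint8", "int16", "float" or "double".
#' @return invisibly, \code{path}.
#' @export
writeVolume <- function(vol, path, datatype = "auto") {
  stopifnot(is(vol, "ScalarVolume"))
  datatype <- match.arg(datatype, c("auto", "uint8", "int16", "float", "double"))
  if (datatype == "auto") {
    v <- vol@values
    datatype <- if (all(v == round(v)) && min(v) >= 0 && max(v) <= 255)
      "uint8" else "double"
  }
  ext <- volume_format(path)
  switch(ext,
         nifti = write_nifti_volume(vol, path, datatype),
         nrrd = write_nrrd_volume(vol, path, datatype),
         mha = write_meta_volume(vol, path, datatype, local = TRUE),
         mhd = write_meta_volume(vol, path, datatype, local = FALSE),
         stop("unsupported volume format: ", path))
  invisible(path)
}

volume_format <- function(path) {
  low <- tolower(path)
  if (grepl("\\.nii(\\.gz)?$", low)) return("nifti")
  if (grepl("\\.nrrd$", low)) return("nrrd")
  if (grepl("\\.mha$", low)) return("mha")
  if (grepl("\\.mhd$", low)) return("mhd")
  stop("unsupported volume extension: ", path,
       " (expected .nii/.nii.gz/.nrrd/.mha/.mhd)")
}

# ---- NIfTI (via RNifti; NIfTI world frame is RAS) -------------------------

ras_to_lps <- diag(c(-1, -1, 1))

read_nifti_volume <- function(path) {
  img <- RNifti::readNifti(path)
  values <- as.array(img)
  attributes(values) <- list(dim = dim(values))
  if (length(dim(values)) == 2L) dim(values) <- c(dim(values), 1L)
  if (length(dim(values)) != 3L)
    stop("geometry error: expected a 3D volume, got ",
         length(dim(values)), "D: ", path)
  aff <- RNifti::xform(img)  # voxel (0-based) -> RAS mm
  A <- ras_to_lps %*% aff[1:3, , drop = FALSE]
  M <- A[, 1:3, drop = FALSE]
  spacing <- sqrt(colSums(M^2))
  if (any(spacing <= 0) || any(!is.finite(spacing)))
    stop("geometry error: missing or invalid spacing in ", path)
  direction <- sweep(M, 2, spacing, "/")
  if (max(abs(crossprod(direction) - diag(3))) > 1e-4)
    stop("geometry error: sheared affine (non-orthogonal axes) in ", path)
  direction <- nearest_orthonormal(direction)
  scalarVolume(values, spacing = spacing, origin = A[, 4], direction = direction)
}

write_nifti_volume <- function(vol, path, datatype) {
  dt <- switch(datatype, uint8 = "uint8", int16 = "int16",
               float = "float", double = "double")
  img <- RNifti::asNifti(vol@values)
  RNifti::pixdim(img) <- vol@spacing
  A <- ras_to_lps %*% cbind(vol@direction %*% diag(vol@spacing), vol@origin)
  aff <- structure(rbind(A, c(0, 0, 0, 1)), code = 2L)
  img <- RNifti::`sform<-`(img, aff)
  img <- RNifti::`qform<-`(img, aff)
  RNifti::writeNifti(img, path, datatype = dt)
}

# project onto the nearest orthonormal matrix (polar factor)
nearest_orthonormal <- function(M) {
  s <- svd(M)
  s$u %*% t(s$v)
}

# ---- NRRD (detached header + raw/gzip payload in one file) ----------------

nrrd_types <- c(uint8 = "uchar", int16 = "short", float = "float",
                double = "double")

read_nrrd_volume <- function(path) {
  bytes <- readBin(path, "raw", n = file.size(path))
  split <- find_blank_line(bytes)
  header <- strsplit(rawToChar(bytes[seq_len(split$header_end)]), "\n")[[1]]
  if (!grepl("^NRRD", header[1])) stop("format error: not a NRRD file: ", path)
  fields <- parse_nrrd_fields(header[-1])
  need <- function(key) {
    if (is.null(fields[[key]]))
      stop("geometry error: NRRD field '", key, "' missing in ", path)
    fields[[key]]
  }
  if (as.integer(need("dimension")) != 3L)
    stop("format error: only 3D NRRD supported: ", path)
  sizes <- as.integer(strsplit(need("sizes"), "\\s+")[[1]])
  type <- gsub("\\s", "", need("type"))
  rtype <- switch(type,
                  uchar = , uint8 = , "unsignedchar" = list(what = "integer", size = 1, signed = FALSE),
                  short = , int16 = list(what = "integer", size = 2, signed = TRUE),
                  float = list(what = "double", size = 4, signed = TRUE),
                  double = list(what = "double", size = 8, signed = TRUE),
                  stop("format error: unsupported NRRD type '", type, "'"))
  encoding <- tolower(gsub("\\s", "", need("encoding")))
  payload <- bytes[(split$data_start):length(bytes)]
  if (encoding %in% c("gzip", "gz")) payload <- memDecompress(payload, type = "gzip")
  else if (encoding != "raw")
    stop("format error: unsupported NRRD encoding '", encoding, "'")
  n <- prod(sizes)
  values <- readBin(payload, what = rtype$what, n = n, size = rtype$size,
                    signed = rtype$signed, endian = "little")
  if (length(values) != n) stop("format error: truncated NRRD payload in ", path)
  dirs <- fields[["space directions"]]
  spacing <- c(1, 1, 1); direction <- diag(3); origin <- c(0, 0, 0)
  if (!is.null(dirs)) {
    M <- parse_nrrd_vectors(dirs)
    spacing <- sqrt(colSums(M^2))
    direction <- nearest_orthonormal(sweep(M, 2, spacing, "/"))
  } else if (!is.null(fields[["spacings"]])) {
    spacing <- as.numeric(strsplit(fields[["spacings"]], "\\s+")[[1]])
  } else stop("geometry error: NRRD has neither 'space directions' nor 'spacings': ", path)
  if (!is.null(fields[["space origin"]]))
    origin <- parse_nrrd_vectors(fields[["space origin"]])[, 1]
  space <- fields[["space"]]
  if (!is.null(space) && grepl("right-anterior-superior", space)) {
    direction <- ras_to_lps %*% direction
    origin <- as.numeric(ras_to_lps %*% origin)
  }
  scalarVolume(array(as.double(values), sizes), spacing = spacing,
               origin = origin, direction = direction)
}

write_nrrd_volume <- function(vol, path, datatype) {
  M <- vol@direction %*% diag(vol@spacing)
  vecfmt <- function(v) sprintf("(%.17g,%.17g,%.17g)", v[1], v[2], v[3])
  header <- c(
    "NRRD0004",
    "# Complete NRRD file format specification at:",
    "# http://teem.sourceforge.net/nrrd/format.html",
    paste0("type: ", nrrd_types[[datatype]]),
    "dimension: 3",
    "space: left-posterior-superior",
    paste("sizes:", paste(dim(vol@values), collapse = " ")),
    paste("space directions:", vecfmt(M[, 1]), vecfmt(M[, 2]), vecfmt(M[, 3])),
    "kinds: domain domain domain",
    "endian: little",
    "encoding: raw",
    paste("space origin:", vecfmt(vol@origin)),
    "")
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(header, con, sep = "\n")
  write_binary_values(vol@values, con, datatype)
}

parse_nrrd_fields <- function(lines) {
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  out <- list()
  for (ln in lines) {
    m <- regmatches(ln, regexec("^([^:]+):=?\\s*(.*)$", ln))[[1]]
    if (length(m) == 3) out[[tolower(trimws(m[2]))]] <- trimws(m[3])
  }
  out
}

# parse "(a,b,c) (d,e,f) ..." into a 3 x K matrix (columns are the vectors)
parse_nrrd_vectors <- function(txt) {
  vecs <- regmatches(txt, gregexpr("\\(([^)]*)\\)", txt))[[1]]
  cols <- lapply(vecs, function(v)
    as.numeric(strsplit(gsub("[()]", "", v), ",")[[1]]))
  do.call(cbind, cols)
}

find_blank_line <- function(bytes) {
  nl <- which(bytes == as.raw(10L))
  for (t in seq_along(nl)[-1]) {
    gap <- nl[t] - nl[t - 1]
    if (gap == 1L || (gap == 2L && bytes[nl[t] - 1] == as.raw(13L)))
      return(list(header_end = nl[t - 1], data_start = nl[t] + 1))
  }
  stop("format error: no header/data separator found")
}

write_binary_values <- function(values, con, datatype) {
  v <- as.vector(values)
  switch(datatype,
         uint8 = writeBin(as.integer(v), con, size = 1, endian = "little"),
         int16 = writeBin(as.integer(v), con, size = 2, endian = "little"),
         float = writeBin(as.double(v), con, size = 4, endian = "little"),
         double = writeBin(as.double(v), con, size = 8, endian = "little"))
}

# ---- MetaImage (.mha local payload, .mhd + .raw) --------------------------

meta_types <- c(uint8 = "MET_UCHAR", int16 = "MET_SHORT",
                float = "MET_FLOAT", double = "MET_DOUBLE")

read_meta_volume <- function(path) {
  local <- grepl("\\.mha$", tolower(path))
  if (local) {
    bytes <- readBin(path, "raw", n = file.size(path))
    txt_end <- find_meta_header_end(bytes)
    header <- strsplit(rawToChar(bytes[seq_len(txt_end$header_end)]), "\n")[[1]]
    payload <- bytes[txt_end$data_start:length(bytes)]
  } else {
    header <- readLines(path, warn = FALSE)
    payload <- NULL
  }
  kv <- list()
  for (ln in header) {
    m <- regmatches(ln, regexec("^\\s*([A-Za-z]+)\\s*=\\s*(.*)$", ln))[[1]]
    if (length(m) == 3) kv[[m[2]]] <- trimws(m[3])
  }
  if (is.null(kv$DimSize)) stop("geometry error: DimSize missing in ", path)
  sizes <- as.integer(strsplit(kv$DimSize, "\\s+")[[1]])
  if (length(sizes) != 3L) stop("format error: only 3D MetaImage supported")
  if (is.null(kv$ElementSpacing))
    stop("geometry error: ElementSpacing missing in ", path)
  spacing <- as.numeric(strsplit(kv$ElementSpacing, "\\s+")[[1]])
  origin <- if (!is.null(kv$Offset))
    as.numeric(strsplit(kv$Offset, "\\s+")[[1]]) else c(0, 0, 0)
  direction <- diag(3)
  if (!is.null(kv$TransformMatrix)) {
    tm <- as.numeric(strsplit(kv$TransformMatrix, "\\s+")[[1]])
    # rows of the MetaImage matrix are the axis direction cosines
    direction <- nearest_orthonormal(t(matrix(tm, 3, 3, byrow = TRUE)))
  }
  if (!is.null(kv$CompressedData) && toupper(kv$CompressedData) == "TRUE")
    stop("format error: compressed MetaImage not supported")
  rtype <- switch(kv$ElementType,
                  MET_UCHAR = list(what = "integer", size = 1, signed = FALSE),
                  MET_SHORT = list(what = "integer", size = 2, signed = TRUE),
                  MET_FLOAT = list(what = "double", size = 4, signed = TRUE),
                  MET_DOUBLE = list(what = "double", size = 8, signed = TRUE),
                  stop("format error: unsupported ElementType ", kv$ElementType))
  if (!local) {
    datafile <- file.path(dirname(path), kv$ElementDataFile)
    payload <- readBin(datafile, "raw", n = file.size(datafile))
  }
  n <- prod(sizes)
  values <- readBin(payload, what = rtype$what, n = n, size = rtype$size,
                    signed = rtype$signed, endian = "little")
  if (length(values) != n)
    stop("format error: truncated MetaImage payload in ", path)
  scalarVolume(array(as.double(values), sizes), spacing = spacing,
               origin = origin, direction = direction)
}

find_meta_header_end <- function(bytes) {
  marker <- charToRaw("ElementDataFile")
  hits <- which(bytes == marker[1])
  for (h in hits) {
    if (h + length(marker) - 1 <= length(bytes) &&
        identical(bytes[h:(h + length(marker) - 1)], marker)) {
      nl <- h
      while (nl <= length(bytes) && bytes[nl] != as.raw(10L)) nl <- nl + 1L
      return(list(header_end = nl - 1L, data_start = nl + 1L))
    }
  }
  stop("format error: ElementDataFile not found in MetaImage header")
}

write_meta_volume <- function(vol, path, datatype, local) {
  Dt <- t(vol@direction)  # rows = axis direction cosines
  header <- c(
    "ObjectType = Image",
    "NDims = 3",
    "BinaryData = True",
    "BinaryDataByteOrderMSB = False",
    "CompressedData = False",
    paste("TransformMatrix =", paste(sprintf("%.17g", as.vector(t(Dt))), collapse = " ")),
    paste("Offset =", paste(sprintf("%.17g", vol@origin), collapse = " ")),
    "CenterOfRotation = 0 0 0",
    "AnatomicalOrientation = LPS",
    paste("ElementSpacing =", paste(sprintf("%.17g", vol@spacing), collapse = " ")),
    paste("DimSize =", paste(dim(vol@values), collapse = " ")),
    paste("ElementType =", meta_types[[datatype]]))
  if (local) {
    con <- file(path, "wb")
    on.exit(close(con))
    writeLines(c(header, "ElementDataFile = LOCAL"), con, sep = "\n")
    write_binary_values(vol@values, con, datatype)
  } else {
    rawname <- sub("\\.mhd$", ".raw", basename(path), ignore.case = TRUE)
    writeLines(c(header, paste("ElementDataFile =", rawname)), path)
    con <- file(file.path(dirname(path), rawname), "wb")
    on.exit(close(con))
    write_binary_values(vol@values, con, datatype)
  }
}

# ---- Fiducials ------------------------------------------------------------

#' Read fiducial landmarks from a Slicer .fcsv markups file or a JSON list
#'
#' Slicer \code{.fcsv} files store coordinates in RAS unless the header says
#' otherwise; they are converted to the internal LPS frame by negating the
#' first two components. The JSON format is the package's own:
#' \code{{"points": [[x,y,z], ...], "labels": [...]}} already in LPS mm.
#'
#' @param path a \code{.fcsv} or \code{.json} file with at least 2 points.
#' @return a \linkS4class{FiducialSet}; order of appearance is preserved,
#'   the first point being the duct head and the last the tail.
#' @export
readFiducials <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (grepl("\\.json$", tolower(path))) {
    doc <- jsonlite::fromJSON(path, simplifyMatrix = TRUE)
    pts <- matrix(as.numeric(doc$points), ncol = 3)
    labels <- if (!is.null(doc$labels)) as.character(doc$labels) else NULL
    if (nrow(pts) < 2) stop("precondition error: need at least 2 fiducials")
    return(fiducialSet(pts, labels))
  }
  lines <- readLines(path, warn = FALSE)
  comment <- grepl("^\\s*#", lines)
  lps_file <- any(grepl("CoordinateSystem\\s*=\\s*(LPS|1)\\s*$", lines[comment]))
  rows <- lines[!comment & nzchar(trimws(lines))]
  pts <- matrix(NA_real_, length(rows), 3)
  labels <- character(length(rows))
  for (t in seq_along(rows)) {
    f <- strsplit(rows[t], ",")[[1]]
    if (length(f) < 4) stop("parse error in fiducial file at line: ", rows[t])
    xyz <- suppressWarnings(as.numeric(f[2:4]))
    if (any(is.na(xyz)))
      stop("parse error in fiducial file at line: ", rows[t])
    pts[t, ] <- xyz
    labels[t] <- if (length(f) >= 12 && nzchar(trimws(f[12]))) trimws(f[12])
                 else paste0("F-", t)
  }
  if (nrow(pts) < 2) stop("precondition error: need at least 2 fiducials")
  if (!lps_file) pts[, 1:2] <- -pts[, 1:2]  # RAS -> LPS
  fiducialSet(pts, labels)
}

#' Write fiducials to .fcsv (RAS on disk) or JSON (LPS)
#'
#' @param fids a \linkS4class{FiducialSet}.
#' @param path output path ending in .fcsv or .json.
#' @return invisibly, \code{path}.
#' @export
writeFiducials <- function(fids, path) {
  stopifnot(is(fids, "FiducialSet"))
  pts <- fids@points
  if (grepl("\\.json$", tolower(path))) {
    jsonlite::write_json(
      list(points = unname(pts), labels = fids@labels),
      path, digits = NA, auto_unbox = FALSE)
    return(invisible(path))
  }
  ras <- pts
  ras[, 1:2] <- -ras[, 1:2]
  rows <- vapply(seq_len(nrow(ras)), function(t)
    sprintf("vtkMRMLMarkupsFiducialNode_%d,%.10g,%.10g,%.10g,0,0,0,1,1,1,0,%s,,",
            t - 1L, ras[t, 1], ras[t, 2], ras[t, 3], fids@labels[t]),
    character(1))
  writeLines(c(
    "# Markups fiducial file version = 4.11",
    "# CoordinateSystem = 0",
    "# columns = id,x,y,z,ow,ox,oy,oz,vis,sel,lock,label,desc,associatedNodeID",
    rows), path)
  invisible(path)
}

#' Serialize a CenterlineCurve to/from JSON
#'
#' Vertices are stored in mm (LPS) together with the cumulative arc length,
#' accumulated path cost and section-joint indices.
#'
#' @param curve a \linkS4class{CenterlineCurve}.
#' @param path JSON file path.
#' @return \code{writeCenterline}: invisibly \code{path};
#'   \code{readCenterline}: a \linkS4class{CenterlineCurve}.
#' @export
writeCenterline <- function(curve, path) {
  stopifnot(is(curve, "CenterlineCurve"))
  jsonlite::write_json(list(
    vertices = unname(curve@vertices),
    arclength = curve@arclength,
    cost = curve@cost,
    section_breaks = curve@sectionBreaks), path, digits = NA, auto_unbox = FALSE,
    na = "null")
  invisible(path)
}

#' @rdname writeCenterline
#' @export
readCenterline <- function(path) {
  doc <- jsonlite::fromJSON(path)
  cost <- if (is.null(doc$cost) || length(doc$cost) == 0 || is.na(doc$cost[1]))
    NA_real_ else as.numeric(doc$cost[1])
  new("CenterlineCurve",
      vertices = matrix(as.numeric(doc$vertices), ncol = 3),
      arclength = as.numeric(doc$arclength),
      cost = cost,
      sectionBreaks = as.integer(doc$section_breaks))
}
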