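## Readers/writers for every format the pipeline touches: NIfTI volumes,
## CSV landmark tables, JSON rigid transforms, TIFF/PNG sections. Parsing of
## the container formats is delegated to RNifti / jsonlite / tiff / png; this
## layer enforces the package's domain invariants and rejects malformed
## inputs with explicit messages rather than coercing.

#' Read and write volumes as NIfTI
#'
#' Volumes are stored as NIfTI-1 with the world geometry in the sform
#' (code 2) and voxel sizes in pixdim; data are written as float64 so a
#' write/read round trip preserves the array bit-exactly and the geometry to
#' within 1e-6.
#'
#' @param path Path to a \code{.nii} or \code{.nii.gz} file.
#' @param spaceName Coordinate-space tag attached to the returned volume.
#' @param volume A \linkS4class{Volume}.
#' @return \code{readVolume}: a \linkS4class{Volume}. \code{writeVolume}:
#'   the path, invisibly.
#' @export
readVolume <- function(path, spaceName = "unnamed") {
  if (!file.exists(path)) stop("file not found: ", path)
  img <- RNifti::readNifti(path)
  arr <- as.array(img)
  arr <- array(as.numeric(arr), dim(arr))  # strip niftiImage attributes
  if (length(dim(arr)) == 4L && dim(arr)[4L] == 1L)
    arr <- array(arr, dim(arr)[1:3])
  if (length(dim(arr)) != 3L)
    stop("expected 3D volume, got ", length(dim(arr)), "D payload: ", path)
  aff <- RNifti::xform(img, useQuaternionFirst = FALSE)
  A <- unclass(aff)[1:3, 1:3]
  sp <- sqrt(colSums(A^2))
  if (any(sp <= 0)) stop("non-positive voxel spacing in ", path)
  dir <- sweep(A, 2L, sp, "/")
  if (!.is_orthonormal(dir))
    stop("non-orthonormal direction matrix in ", path)
  Volume(arr, spacing = sp, origin = unclass(aff)[1:3, 4], direction = dir,
         spaceName = spaceName)
}

#' @rdname readVolume
#' @export
writeVolume <- function(volume, path) {
  stopifnot(is(volume, "Volume"))
  aff <- diag(4)
  aff[1:3, 1:3] <- volume@direction %*% diag(volume@spacing)
  aff[1:3, 4] <- volume@origin
  img <- RNifti::asNifti(volume@data)
  RNifti::pixdim(img) <- volume@spacing
  RNifti::sform(img) <- structure(aff, code = 2L)
  RNifti::writeNifti(img, path, datatype = "double")
  invisible(path)
}

#' Read and write landmark tables as CSV
#'
#' The file holds one comment line \code{# space_name: <tag>} followed by a
#' CSV table with header \code{label,x,y[,z]}; coordinates are millimetres.
#'
#' @param path CSV path.
#' @param landmarks A \linkS4class{LandmarkSet}.
#' @return \code{readLandmarks}: a \linkS4class{LandmarkSet} with labels in
#'   file order. \code{writeLandmarks}: the path, invisibly.
#' @export
readLandmarks <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  first <- readLines(path, n = 1L)
  space <- "unnamed"
  if (startsWith(first, "#")) {
    m <- regmatches(first, regexec("space_name:\\s*(\\S+)", first))[[1]]
    if (length(m) == 2L) space <- m[2]
  }
  tab <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  cols <- intersect(c("x", "y", "z"), names(tab))
  if (!"label" %in% names(tab) || length(cols) < 2L)
    stop("landmark CSV needs columns label,x,y[,z]: ", path)
  if (anyDuplicated(tab$label))
    stop("duplicate landmark labels in ", path, ": ",
         paste(unique(tab$label[duplicated(tab$label)]), collapse = ", "))
  co <- as.matrix(tab[, cols, drop = FALSE])
  if (any(!is.finite(co)))
    stop("missing or non-numeric coordinates (mixed dimensionality?) in ", path)
  LandmarkSet(co, labels = tab$label, spaceName = space)
}

#' @rdname readLandmarks
#' @export
writeLandmarks <- function(landmarks, path) {
  stopifnot(is(landmarks, "LandmarkSet"))
  co <- landmarks@coords
  df <- data.frame(label = rownames(co), co, check.names = FALSE)
  colnames(df) <- c("label", c("x", "y", "z")[seq_len(ncol(co))])
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# space_name: ", landmarks@spaceName), con)
  utils::write.csv(df, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read and write rigid transforms as JSON
#'
#' The JSON dialect is \code{{"matrix": [[...4x4 row-major...]],
#' "fixed_space": str, "moving_space": str}}: a homogeneous matrix whose
#' upper-left block must be a proper rotation (determinant +1).
#'
#' @param path JSON path.
#' @param transform A \linkS4class{RigidTransform}.
#' @param fixedSpace,movingSpace Space tags recorded alongside the matrix.
#' @return \code{readRigidJSON}: a \linkS4class{RigidTransform} with
#'   attributes \code{fixedSpace} and \code{movingSpace}.
#'   \code{writeRigidJSON}: the path, invisibly.
#' @export
readRigidJSON <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  obj <- jsonlite::fromJSON(path)
  m <- obj$matrix
  if (is.null(m) || !is.matrix(m) || !all(dim(m) == c(4L, 4L)))
    stop("rigid JSON must hold a 4x4 'matrix': ", path)
  R <- m[1:3, 1:3]
  if (!.is_orthonormal(R)) stop("rotation block is not orthonormal: ", path)
  if (det(R) <= 0) stop("improper rotation (determinant <= 0): ", path)
  out <- RigidTransform(rotation = R, translation = m[1:3, 4])
  attr(out, "fixedSpace") <- if (!is.null(obj$fixed_space)) obj$fixed_space else NA_character_
  attr(out, "movingSpace") <- if (!is.null(obj$moving_space)) obj$moving_space else NA_character_
  out
}

#' @rdname readRigidJSON
#' @export
writeRigidJSON <- function(transform, path, fixedSpace = "in_vivo",
                           movingSpace = "ex_vivo_1") {
  stopifnot(is(transform, "RigidTransform"))
  m <- diag(4)
  m[1:3, 1:3] <- transform@rotation
  m[1:3, 4] <- transform@translation
  jsonlite::write_json(
    list(matrix = m, fixed_space = fixedSpace, moving_space = movingSpace),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read and write digitized section images
#'
#' TIFF and PNG are supported; RGB images keep 3 channels, grayscale 1.
#' Pixel values are in [0, 1] as returned by the underlying readers.
#'
#' @param path TIFF or PNG path.
#' @param pixelSize mm per pixel (> 0).
#' @param sectionIndex Zero-based section position along the cutting axis.
#' @param kind Section kind; see \linkS4class{SectionImage}.
#' @param section A \linkS4class{SectionImage}.
#' @return \code{readSection}: a \linkS4class{SectionImage}.
#'   \code{writeSection}: the path, invisibly.
#' @export
readSection <- function(path, pixelSize, sectionIndex = 0L,
                        kind = "macroscopic") {
  if (!file.exists(path)) stop("file not found: ", path)
  if (pixelSize <= 0) stop("pixelSize must be positive (mm per pixel)")
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    png = png::readPNG(path),
    tif = , tiff = tiff::readTIFF(path),
    stop("unsupported section format '", ext, "' (use TIFF or PNG)"))
  if (length(dim(img)) == 3L && dim(img)[3L] == 4L)
    img <- img[, , 1:3]  # drop alpha
  if (length(dim(img)) == 3L && dim(img)[3L] == 2L)
    img <- img[, , 1L]   # gray+alpha -> gray
  SectionImage(img, pixelSize = pixelSize, sectionIndex = sectionIndex,
               kind = kind)
}

#' @rdname readSection
#' @export
writeSection <- function(section, path) {
  stopifnot(is(section, "SectionImage"))
  img <- section@data
  if (length(dim(img)) == 3L && dim(img)[3L] == 1L)
    img <- img[, , 1L]
  img <- pmin(pmax(img, 0), 1)
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    png = png::writePNG(img, path),
    tif = , tiff = tiff::writeTIFF(img, path, bits.per.sample = 16L),
    stop("unsupported section format '", ext, "' (use TIFF or PNG)"))
  invisible(path)
}

#' Read and write a parametric map stack as per-channel NIfTI files
#'
#' Channels are stored as \code{<prefix><name>.nii.gz} plus
#' \code{<prefix>roi.nii.gz} in one directory. On read, alternate channel
#' names (e.g. \code{iAUC} for \code{vp}, \code{D*} for \code{Dstar}) are
#' accepted and canonicalized.
#'
#' @param dir Directory holding the files.
#' @param prefix File-name prefix (default \code{"map_"}).
#' @param stack A \linkS4class{ParametricMapStack}.
#' @return \code{readMapStack}: a \linkS4class{ParametricMapStack};
#'   \code{writeMapStack}: the directory, invisibly.
#' @export
readMapStack <- function(dir, prefix = "map_") {
  files <- list.files(dir, pattern = paste0("^", prefix, ".*\\.nii(\\.gz)?$"),
                      full.names = TRUE)
  nm <- sub("\\.nii(\\.gz)?$", "", sub(paste0("^", prefix), "", basename(files)))
  nm <- .canonicalChannel(nm)
  roiFile <- files[nm == "roi"]
  if (length(roiFile) != 1L) stop("expected exactly one ", prefix, "roi file in ", dir)
  chFiles <- files[nm != "roi"]
  chNames <- nm[nm != "roi"]
  channels <- stats::setNames(
    lapply(chFiles, readVolume, spaceName = "in_vivo"), chNames)
  ParametricMapStack(channels, roi = readVolume(roiFile, spaceName = "in_vivo"))
}

#' @rdname readMapStack
#' @export
writeMapStack <- function(stack, dir, prefix = "map_") {
  stopifnot(is(stack, "ParametricMapStack"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (nm in names(stack@channels))
    writeVolume(stack@channels[[nm]],
                file.path(dir, paste0(prefix, nm, ".nii.gz")))
  writeVolume(stack@roi, file.path(dir, paste0(prefix, "roi.nii.gz")))
  invisible(dir)
}
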