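# Reading and writing volumes, label masks and displacement fields.
# NIfTI is the primary format (via RNifti); uncompressed MetaImage (.mha)
# is accepted as a secondary dialect. Readers never resample: the stored
# grid is returned exactly, after reorientation of the axes to the
# canonical RAS order.

is_mha <- function(path) grepl("\\.mha$", path, ignore.case = TRUE)

read_nifti_canonical <- function(path) {
  img <- RNifti::readNifti(path)
  src <- tryCatch(RNifti::orientation(img), error = function(e) NA_character_)
  if (!identical(src, "RAS")) RNifti::orientation(img) <- "RAS"
  aff <- RNifti::xform(img)
  spacing <- RNifti::pixdim(img)[seq_len(min(3L, length(dim(img))))]
  rot <- aff[1:3, 1:3]
  offdiag <- rot - diag(diag(rot))
  if (max(abs(offdiag)) > 1e-3 * max(abs(diag(rot))))
    stop("read: oblique voxel axes are not supported (off-diagonal xform terms)",
         call. = FALSE)
  data <- as.array(img)
  attributes(data) <- list(dim = dim(data))
  # NIfTI headers hold pixdim/srow as float32; normalise to write precision
  list(data = data, spacing = signif(as.numeric(spacing), 7),
       origin = signif(as.numeric(aff[1:3, 4]), 7), source_orientation = src)
}

write_nifti_canonical <- function(data, spacing, origin, path) {
  img <- RNifti::asNifti(data)
  RNifti::pixdim(img) <- c(spacing, rep(1, length(dim(data)) - 3L))
  aff <- diag(4)
  diag(aff)[1:3] <- spacing
  aff[1:3, 4] <- origin
  RNifti::sform(img) <- structure(aff, code = 2L)
  RNifti::qform(img) <- structure(aff, code = 2L)
  RNifti::writeNifti(img, path)
  invisible(path)
}

mha_types <- c(MET_UCHAR = "integer", MET_CHAR = "integer", MET_SHORT = "integer",
               MET_USHORT = "integer", MET_INT = "integer", MET_UINT = "integer",
               MET_FLOAT = "double", MET_DOUBLE = "double")
mha_sizes <- c(MET_UCHAR = 1, MET_CHAR = 1, MET_SHORT = 2, MET_USHORT = 2,
               MET_INT = 4, MET_UINT = 4, MET_FLOAT = 4, MET_DOUBLE = 8)

read_mha <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- list()
  repeat {
    line <- readLines(con, n = 1L)
    if (length(line) == 0L) stop("read: truncated MetaImage header in ", path,
                                 call. = FALSE)
    kv <- strsplit(line, "=", fixed = TRUE)[[1]]
    key <- trimws(kv[1]); val <- trimws(paste(kv[-1], collapse = "="))
    hdr[[key]] <- val
    if (key == "ElementDataFile") break
  }
  if (!identical(hdr[["ElementDataFile"]], "LOCAL"))
    stop("read: only LOCAL-data MetaImage files are supported", call. = FALSE)
  if (identical(tolower(hdr[["CompressedData"]] %||% "false"), "true"))
    stop("read: compressed MetaImage data is not supported", call. = FALSE)
  d <- as.integer(strsplit(hdr[["DimSize"]], "\\s+")[[1]])
  type <- hdr[["ElementType"]]
  if (!type %in% names(mha_types))
    stop("read: unsupported MetaImage element type ", type, call. = FALSE)
  nchan <- as.integer(hdr[["ElementNumberOfChannels"]] %||% "1")
  spacing <- as.numeric(strsplit(hdr[["ElementSpacing"]] %||%
                                   paste(rep(1, length(d)), collapse = " "),
                                 "\\s+")[[1]])
  origin <- as.numeric(strsplit(hdr[["Offset"]] %||%
                                  paste(rep(0, length(d)), collapse = " "),
                                "\\s+")[[1]])
  n <- prod(d) * nchan
  signed <- !type %in% c("MET_UCHAR", "MET_USHORT", "MET_UINT")
  raw_vals <- readBin(con, what = mha_types[[type]], n = n,
                      size = mha_sizes[[type]], signed = signed,
                      endian = "little")
  if (length(raw_vals) != n)
    stop("read: MetaImage pixel data shorter than DimSize implies", call. = FALSE)
  data <- if (nchan > 1L) {
    # channels interleaved fastest -> move them last
    aperm(array(as.double(raw_vals), c(nchan, d)), c(seq_along(d) + 1L, 1L))
  } else array(as.double(raw_vals), d)
  list(data = data, spacing = spacing, origin = origin,
       source_orientation = NA_character_)
}

write_mha <- function(data, spacing, origin, path, channels_last = FALSE) {
  d <- dim(data)
  nchan <- 1L
  if (channels_last) {
    nchan <- d[length(d)]
    data <- aperm(data, c(length(d), seq_len(length(d) - 1L)))
    d <- d[-length(d)]
  }
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- c("ObjectType = Image",
           paste0("NDims = ", length(d)),
           "BinaryData = True",
           "BinaryDataByteOrderMSB = False",
           "CompressedData = False",
           paste0("DimSize = ", paste(d, collapse = " ")),
           paste0("ElementSpacing = ", paste(spacing[seq_along(d)], collapse = " ")),
           paste0("Offset = ", paste(origin[seq_along(d)], collapse = " ")),
           if (nchan > 1L) paste0("ElementNumberOfChannels = ", nchan),
           "ElementType = MET_DOUBLE",
           "ElementDataFile = LOCAL")
  writeLines(hdr, con)
  writeBin(as.double(data), con, size = 8, endian = "little")
  invisible(path)
}

#' Read a scalar 3D volume
#'
#' Reads a NIfTI (`.nii`/`.nii.gz`) or uncompressed MetaImage (`.mha`) scalar
#' volume, reorients the axes to the canonical RAS order and returns a
#' [knee_volume]. Intensities are returned unchanged; no resampling happens.
#'
#' @param path file path.
#' @return A [knee_volume]; the attribute `"source_orientation"` records the
#'   axis code of the file before reorientation (NIfTI only).
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) stop("read_volume: file not found: ", path, call. = FALSE)
  r <- if (is_mha(path)) read_mha(path) else read_nifti_canonical(path)
  nd <- length(dim(r$data))
  if (nd != 3L)
    stop("read_volume: expected a scalar 3D volume, got ", nd,
         " dimensions in ", path, call. = FALSE)
  v <- knee_volume(r$data, r$spacing[1:3], r$origin[1:3])
  attr(v, "source_orientation") <- r$source_orientation
  v
}

#' Write a scalar 3D volume
#' @param volume a [knee_volume].
#' @param path output path (`.nii`, `.nii.gz` or `.mha`).
#' @export
write_volume <- function(volume, path) {
  stopifnot(inherits(volume, "knee_volume"))
  if (is_mha(path)) write_mha(volume$data, volume$spacing, volume$origin, path)
  else write_nifti_canonical(volume$data, volume$spacing, volume$origin, path)
  invisible(path)
}

#' Read structure masks onto the grid of a companion volume
#'
#' Accepts either one file per structure or a single integer label image with
#' a `labels` mapping. Files must live on exactly the companion grid; a
#' mismatch is an error, never a silent resample.
#'
#' @param paths named character vector of file paths (names from the canonical
#'   structure set), or a single path when `labels` is given.
#' @param companion the [knee_volume] whose grid the masks must share.
#' @param labels optional named integer vector mapping structure names to
#'   label values inside a single label image.
#' @return A [structure_set].
#' @export
read_structures <- function(paths, companion, labels = NULL) {
  stopifnot(inherits(companion, "knee_volume"))
  masks <- list()
  if (!is.null(labels)) {
    stopifnot(length(paths) == 1L)
    vol <- read_volume(paths)
    check_companion_grid(vol, companion, paths)
    for (nm in names(labels)) masks[[nm]] <- vol$data == labels[[nm]]
  } else {
    if (is.null(names(paths)) || any(names(paths) == ""))
      stop("read_structures: `paths` must be named by structure", call. = FALSE)
    for (nm in names(paths)) {
      vol <- read_volume(paths[[nm]])
      check_companion_grid(vol, companion, paths[[nm]])
      masks[[nm]] <- vol$data != 0
    }
  }
  structure_set(masks, companion$spacing, companion$origin)
}

check_companion_grid <- function(vol, companion, path) {
  if (!same_grid(vol, companion))
    stop("read_structures: grid of ", path, " (",
         paste(dim(vol$data), collapse = "x"), ", spacing ",
         paste(signif(vol$spacing, 6), collapse = "/"),
         ") does not match the companion volume (",
         paste(dim(companion$data), collapse = "x"), ", spacing ",
         paste(signif(companion$spacing, 6), collapse = "/"), ")", call. = FALSE)
}

#' Write structure masks
#'
#' Writes each mask of a [structure_set] as `<name>.nii.gz` (0/1 valued)
#' under `dir`.
#'
#' @param structures a [structure_set].
#' @param dir output directory (created if needed).
#' @return Named vector of the written paths, invisibly.
#' @export
write_structures <- function(structures, dir) {
  stopifnot(inherits(structures, "structure_set"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  out <- character(0)
  for (nm in names(structures$masks)) {
    p <- file.path(dir, paste0(nm, ".nii.gz"))
    write_nifti_canonical(array(as.integer(structures$masks[[nm]]),
                                dim(structures$masks[[nm]])),
                          structures$spacing, structures$origin, p)
    out[nm] <- p
  }
  invisible(out)
}

#' Write a displacement field
#'
#' Stores the field as a 4D image with the vector dimension last
#' (components in mm along the canonical axes).
#'
#' @param field a [deformation_field].
#' @param path output path (`.nii`, `.nii.gz` or `.mha`).
#' @export
write_field <- function(field, path) {
  stopifnot(inherits(field, "deformation_field"))
  if (is_mha(path))
    write_mha(field$vectors, field$spacing, field$origin, path, channels_last = TRUE)
  else write_nifti_canonical(field$vectors, field$spacing, field$origin, path)
  invisible(path)
}

#' Read a displacement field
#'
#' @param path file path of a 4D image with 3 components in the last dimension.
#' @param reference optional [knee_volume]; if given, the field grid must
#'   match it exactly.
#' @return A [deformation_field].
#' @export
read_field <- function(path, reference = NULL) {
  if (!file.exists(path)) stop("read_field: file not found: ", path, call. = FALSE)
  r <- if (is_mha(path)) read_mha(path) else {
    img <- RNifti::readNifti(path)
    data <- as.array(img)
    attributes(data) <- list(dim = dim(data))
    list(data = data,
         spacing = signif(as.numeric(RNifti::pixdim(img))[1:3], 7),
         origin = signif(as.numeric(RNifti::xform(img)[1:3, 4]), 7))
  }
  d <- dim(r$data)
  if (length(d) == 5L && d[4] == 1L) { # NIfTI vector convention (dim5)
    r$data <- array(r$data, d[c(1:3, 5)])
    d <- dim(r$data)
  }
  if (length(d) != 4L || d[4] != 3L)
    stop("read_field: expected a 3-component 4D field, got dimensions ",
         paste(d, collapse = "x"), call. = FALSE)
  f <- deformation_field(r$data, r$spacing[1:3], r$origin[1:3])
  if (!is.null(reference) && !same_grid(f, reference))
    stop_grid_mismatch(f, reference, "field and reference volume")
  f
}
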