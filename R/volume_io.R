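#' Construct a voxel volume
#'
#' A `voxel_volume` is a 3D scalar grid (intensity values or integer labels)
#' together with the physical voxel spacing along each grid axis, in mm.
#' Grid axes are ordered (x, y, z); by convention z is the default slicing
#' axis and readers permute file-native orderings into this layout.
#'
#' @param values 3D array of scalars or integer labels.
#' @param spacing Numeric length-3, mm per voxel along each grid axis;
#'   all strictly positive.
#' @param axis_names Character length-3 labelling the grid axes.
#' @return An object of class `voxel_volume` with elements `values`,
#'   `spacing` and `axis_names`.
#' @export
voxel_volume <- function(values, spacing = c(1, 1, 1),
                         axis_names = c("x", "y", "z")) {
  values <- as.array(values)
  if (length(dim(values)) != 3L)
    stop("`values` must be a 3D array, got ", length(dim(values)),
         " dimension(s)", call. = FALSE)
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("`spacing` must be three strictly positive finite numbers (mm)",
         call. = FALSE)
  if (length(axis_names) != 3L)
    stop("`axis_names` must have length 3", call. = FALSE)
  structure(list(values = values, spacing = spacing,
                 axis_names = as.character(axis_names)),
            class = "voxel_volume")
}

#' @export
print.voxel_volume <- function(x, ...) {
  d <- dim(x$values)
  cat("<voxel_volume> ", paste(d, collapse = " x "),
      " voxels; spacing (mm): ", paste(signif(x$spacing, 6), collapse = ", "),
      "; axes: ", paste(x$axis_names, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Construct a binary segment mask
#'
#' @param voxels 3D array; nonzero entries are foreground.
#' @param spacing Numeric length-3 voxel spacing in mm.
#' @param label_value Integer label this mask was extracted from.
#' @return An object of class `segment_mask`.
#' @export
segment_mask <- function(voxels, spacing = c(1, 1, 1), label_value = 1L) {
  voxels <- as.array(voxels)
  if (length(dim(voxels)) != 3L)
    stop("`voxels` must be a 3D array", call. = FALSE)
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("`spacing` must be three strictly positive finite numbers (mm)",
         call. = FALSE)
  storage.mode(voxels) <- "integer"
  voxels[voxels != 0L] <- 1L
  structure(list(voxels = voxels, spacing = spacing,
                 label_value = as.integer(label_value)),
            class = "segment_mask")
}

#' @export
print.segment_mask <- function(x, ...) {
  d <- dim(x$voxels)
  cat("<segment_mask> ", paste(d, collapse = " x "),
      " voxels; ", sum(x$voxels), " foreground; spacing (mm): ",
      paste(signif(x$spacing, 6), collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Extract a binary mask for one label
#'
#' @param volume A [voxel_volume()] whose values are integer labels.
#' @param label Integer label to extract.
#' @return A [segment_mask()] with the voxels equal to `label`; spacing is
#'   copied from the volume.
#' @export
extract_mask <- function(volume, label = 1L) {
  stopifnot(inherits(volume, "voxel_volume"))
  present <- sort(unique(as.vector(volume$values)))
  if (!(label %in% present))
    stop("label ", label, " not present in volume; labels present: ",
         paste(present, collapse = ", "), call. = FALSE)
  segment_mask((volume$values == label) * 1L, volume$spacing,
               label_value = label)
}

# ---------------------------------------------------------------------------
# NRRD reader/writer (minimal NRRD0004 dialect: attached or detached header,
# raw / ascii / gzip encodings, 3D scalar data). Written in-package because
# no installed R package reads NRRD.

.nrrd_types <- data.frame(
  nrrd = c("signed char", "int8", "int8_t",
           "uchar", "unsigned char", "uint8", "uint8_t",
           "short", "short int", "signed short", "int16", "int16_t",
           "ushort", "unsigned short", "uint16", "uint16_t",
           "int", "signed int", "int32", "int32_t",
           "uint", "unsigned int", "uint32", "uint32_t",
           "float", "double"),
  what = c(rep("integer", 24), "double", "double"),
  size = c(1, 1, 1, 1, 1, 1, 1, 2, 2, 2, 2, 2, 2, 2, 2, 2,
           4, 4, 4, 4, 4, 4, 4, 4, 4, 8),
  signed = c(rep(TRUE, 7), rep(TRUE, 5), rep(FALSE, 4), rep(TRUE, 4),
             rep(FALSE, 4), TRUE, TRUE),
  stringsAsFactors = FALSE
)
# unsigned char/uint8 are read signed=FALSE; fix the signed column
.nrrd_types$signed[.nrrd_types$nrrd %in%
  c("uchar", "unsigned char", "uint8", "uint8_t")] <- FALSE

read_nrrd <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con), add = TRUE)
  magic <- readLines(con, n = 1L, warn = FALSE)
  if (!grepl("^NRRD000", magic))
    stop("not an NRRD file: ", path, call. = FALSE)
  fields <- list()
  repeat {
    line <- readLines(con, n = 1L, warn = FALSE)
    if (length(line) == 0L || line == "") break
    if (grepl("^#", line)) next
    kv <- regmatches(line, regexec("^([^:]+):=?\\s*(.*)$", line))[[1]]
    if (length(kv) == 3L) fields[[tolower(trimws(kv[2]))]] <- trimws(kv[3])
  }
  need <- function(k) {
    if (is.null(fields[[k]])) stop("NRRD header missing '", k, "': ", path,
                                   call. = FALSE)
    fields[[k]]
  }
  ndim <- as.integer(need("dimension"))
  if (ndim != 3L)
    stop("expected 3D NRRD data, got dimension ", ndim, ": ", path,
         call. = FALSE)
  sizes <- as.integer(strsplit(need("sizes"), "\\s+")[[1]])
  type <- tolower(need("type"))
  ti <- match(type, .nrrd_types$nrrd)
  if (is.na(ti)) stop("unsupported NRRD type: ", type, call. = FALSE)
  encoding <- tolower(if (is.null(fields$encoding)) "raw" else fields$encoding)
  endian <- if (is.null(fields$endian)) "little" else fields$endian

  spacing <- NULL
  if (!is.null(fields$spacings)) {
    spacing <- as.numeric(strsplit(trimws(fields$spacings), "\\s+")[[1]])
  } else if (!is.null(fields[["space directions"]])) {
    vecs <- regmatches(fields[["space directions"]],
                       gregexpr("\\(([^)]*)\\)", fields[["space directions"]]))[[1]]
    mat <- vapply(vecs, function(v) {
      as.numeric(strsplit(gsub("[()]", "", v), ",")[[1]])
    }, numeric(3))
    # reject oblique direction matrices; allow axis-aligned (perm/flip) only
    if (any(colSums(abs(mat) > 1e-9) > 1L))
      stop("NRRD space directions are oblique (non axis-aligned); ",
           "resample the volume to an axis-aligned grid first: ", path,
           call. = FALSE)
    spacing <- sqrt(colSums(mat^2))
  }
  if (is.null(spacing)) {
    warning("NRRD file has no spacing metadata; assuming 1 mm isotropic: ",
            path)
    spacing <- c(1, 1, 1)
  }

  data_con <- con
  if (!is.null(fields[["data file"]]) || !is.null(fields$datafile)) {
    dfile <- if (!is.null(fields[["data file"]])) fields[["data file"]] else
      fields$datafile
    dpath <- file.path(dirname(path), dfile)
    if (!file.exists(dpath))
      stop("NRRD detached data file not found: ", dpath, call. = FALSE)
    data_con <- file(dpath, "rb")
    on.exit(close(data_con), add = TRUE)
  }

  n <- prod(sizes)
  if (encoding %in% c("raw")) {
    vals <- readBin(data_con, what = .nrrd_types$what[ti], n = n,
                    size = .nrrd_types$size[ti],
                    signed = .nrrd_types$signed[ti], endian = endian)
  } else if (encoding %in% c("gzip", "gz")) {
    blob <- readBin(data_con, "raw", n = file.size(path))
    vals <- readBin(memDecompress(blob, type = "gzip"),
                    what = .nrrd_types$what[ti], n = n,
                    size = .nrrd_types$size[ti],
                    signed = .nrrd_types$signed[ti], endian = endian)
  } else if (encoding %in% c("ascii", "txt", "text")) {
    txt <- readLines(data_con, warn = FALSE)
    vals <- as.numeric(unlist(strsplit(paste(txt, collapse = " "), "\\s+")))
    vals <- vals[!is.na(vals)]
    if (.nrrd_types$what[ti] == "integer") vals <- as.integer(vals)
  } else stop("unsupported NRRD encoding: ", encoding, call. = FALSE)
  if (length(vals) < n)
    stop("NRRD data truncated: expected ", n, " values, got ", length(vals),
         call. = FALSE)
  voxel_volume(array(vals[seq_len(n)], dim = sizes), spacing = spacing)
}

write_nrrd <- function(volume, path) {
  v <- volume$values
  integral <- is.integer(v) ||
    (is.numeric(v) && all(v == round(v)) && max(abs(range(v))) < 2^31)
  type <- if (integral) "int" else "double"
  header <- c(
    "NRRD0004",
    "# written by the xsection R package",
    paste0("type: ", type),
    "dimension: 3",
    paste0("sizes: ", paste(dim(v), collapse = " ")),
    paste0("spacings: ", paste(format(volume$spacing, digits = 17),
                               collapse = " ")),
    "endian: little",
    "encoding: raw",
    ""
  )
  con <- file(path, "wb")
  on.exit(close(con), add = TRUE)
  writeLines(header, con, sep = "\n")
  if (integral) {
    writeBin(as.integer(v), con, size = 4, endian = "little")
  } else {
    writeBin(as.double(v), con, size = 8, endian = "little")
  }
  invisible(path)
}

# ---------------------------------------------------------------------------

.nifti_unit_to_mm <- function(units) {
  switch(units, m = 1000, mm = 1, um = 1e-3, 1)
}

read_nifti_volume <- function(path) {
  img <- RNifti::readNifti(path)
  arr <- as.array(img)
  if (length(dim(arr)) == 4L && dim(arr)[4] == 1L)
    arr <- array(arr, dim = dim(arr)[1:3])
  if (length(dim(arr)) != 3L)
    stop("expected 3D NIfTI data, got ", length(dim(arr)), "D: ", path,
         call. = FALSE)
  xf <- structure(RNifti::xform(img), imagedim = NULL, code = NULL)
  rot <- xf[1:3, 1:3]
  if (any(colSums(abs(rot) > 1e-6 * max(abs(rot))) > 1L))
    stop("NIfTI orientation matrix is oblique (non axis-aligned); ",
         "resample the volume to an axis-aligned grid first: ", path,
         call. = FALSE)
  spacing <- RNifti::pixdim(img)[1:3]
  units <- tryCatch(RNifti::pixunits(img)[1], error = function(e) "Unknown")
  spacing <- spacing * .nifti_unit_to_mm(units)
  if (all(arr == round(arr))) storage.mode(arr) <- "integer"
  voxel_volume(arr, spacing = spacing)
}

write_nifti_volume <- function(volume, path) {
  img <- RNifti::asNifti(volume$values)
  RNifti::pixdim(img) <- volume$spacing
  RNifti::writeNifti(img, path)
  invisible(path)
}

read_tiff_stack <- function(paths) {
  planes <- lapply(paths, function(p) {
    pl <- tiff::readTIFF(p, as.is = TRUE)
    if (length(dim(pl)) == 3L) pl <- pl[, , 1]  # first channel of RGB(A)
    pl
  })
  d <- dim(planes[[1]])
  if (!all(vapply(planes, function(p) identical(dim(p), d), logical(1))))
    stop("TIFF planes have inconsistent dimensions", call. = FALSE)
  arr <- array(unlist(planes), dim = c(d, length(planes)))
  if (all(arr == round(arr))) storage.mode(arr) <- "integer"
  warning("TIFF stacks carry no spacing metadata; assuming 1 mm isotropic")
  voxel_volume(arr, spacing = c(1, 1, 1))
}

#' Read a 3D volume with physical spacing
#'
#' Reads NRRD (`.nrrd`/`.nhdr`, attached or detached header), NIfTI-1
#' (`.nii`, `.nii.gz`) or an ordered stack of single-plane TIFF files.
#' Spacing is normalized to millimetres (the NIfTI units field is honored).
#' Oblique orientation matrices (beyond axis permutations and flips) are
#' rejected: slice-wise metrics on an oblique native grid would be silently
#' wrong, so such volumes must be resampled first.
#'
#' @param path Path to an NRRD/NIfTI file, a directory of TIFF planes, or a
#'   character vector of TIFF paths in slice order.
#' @param format_hint Optional: one of `"nrrd"`, `"nifti"`, `"tiff"`;
#'   inferred from the file extension when omitted.
#' @return A [voxel_volume()]. TIFF stacks with no spacing metadata get
#'   spacing (1, 1, 1) mm with a warning.
#' @export
read_volume <- function(path, format_hint = NULL) {
  if (length(path) > 1L) {
    if (!all(file.exists(path)))
      stop("missing TIFF plane(s): ",
           paste(path[!file.exists(path)], collapse = ", "), call. = FALSE)
    return(read_tiff_stack(path))
  }
  if (!file.exists(path))
    stop("cannot read volume, no such file: ", path, call. = FALSE)
  if (dir.exists(path)) {
    tifs <- list.files(path, pattern = "\\.tiff?$", ignore.case = TRUE,
                       full.names = TRUE)
    if (length(tifs) == 0L)
      stop("directory contains no TIFF planes: ", path, call. = FALSE)
    nums <- suppressWarnings(as.numeric(gsub("\\D", "", basename(tifs))))
    if (anyNA(nums) || anyDuplicated(nums))
      stop("ambiguous TIFF plane ordering in ", path,
           "; pass an explicit ordered vector of file paths", call. = FALSE)
    return(read_tiff_stack(tifs[order(nums)]))
  }
  fmt <- format_hint
  if (is.null(fmt)) {
    fmt <- if (grepl("\\.(nrrd|nhdr)$", path, ignore.case = TRUE)) "nrrd"
    else if (grepl("\\.nii(\\.gz)?$", path, ignore.case = TRUE)) "nifti"
    else if (grepl("\\.tiff?$", path, ignore.case = TRUE)) "tiff"
    else stop("cannot infer format of ", path,
              "; pass format_hint = 'nrrd', 'nifti' or 'tiff'", call. = FALSE)
  }
  switch(fmt,
         nrrd = read_nrrd(path),
         nifti = read_nifti_volume(path),
         tiff = read_tiff_stack(path),
         stop("unknown format_hint: ", fmt, call. = FALSE))
}

#' Write a 3D volume
#'
#' @param volume A [voxel_volume()] or [segment_mask()].
#' @param path Destination path.
#' @param format `"nrrd"` or `"nifti"`; inferred from the extension when
#'   omitted.
#' @return The path, invisibly. The file round-trips through
#'   [read_volume()] with identical grid and spacing (bit-exact for
#'   integer-valued grids).
#' @export
write_volume <- function(volume, path, format = NULL) {
  if (inherits(volume, "segment_mask"))
    volume <- voxel_volume(volume$voxels, volume$spacing)
  stopifnot(inherits(volume, "voxel_volume"))
  if (is.null(format)) {
    format <- if (grepl("\\.(nrrd|nhdr)$", path, ignore.case = TRUE)) "nrrd"
    else if (grepl("\\.nii(\\.gz)?$", path, ignore.case = TRUE)) "nifti"
    else stop("cannot infer format of ", path,
              "; pass format = 'nrrd' or 'nifti'", call. = FALSE)
  }
  if (!dir.exists(dirname(path)))
    stop("unwritable destination, no such directory: ", dirname(path),
         call. = FALSE)
  switch(format,
         nrrd = write_nrrd(volume, path),
         nifti = write_nifti_volume(volume, path),
         stop("unknown format: ", format, call. = FALSE))
  invisible(path)
}
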