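# Image IO: minimal NIfTI-1 and NRRD readers/writers plus the NoduleImage /
# PlanarSection containers. In-memory arrays use the (slice, row, column)
# axis convention: the FIRST array axis is the axial (z) direction. On disk
# both NIfTI and NRRD store the fastest-varying axis first, which we take to
# be the in-plane column axis, so arrays are permuted (3,2,1) on read/write
# and the spacing vector is reversed accordingly.

#' Construct a nodule image
#'
#' Bundles a CT intensity volume (Hounsfield units), a co-registered binary
#' segmentation mask and the per-axis voxel spacing. Axis order is
#' (slice, row, column); the first axis is axial.
#'
#' @param intensities 3D numeric array of CT intensities (HU).
#' @param mask 3D array of the same shape; any nonzero value is foreground.
#' @param spacing numeric length-3 voxel spacing in mm, (slice, row, column).
#' @return An object of class `nodule_image`.
#' @export
nodule_image <- function(intensities, mask, spacing = c(1, 1, 1)) {
  if (length(dim(intensities)) != 3L)
    stage_error("image_io", "intensities must be a 3D array")
  if (!identical(dim(intensities), dim(mask)))
    stage_error("image_io", "mask shape does not match intensity shape")
  m <- array(as.integer(mask != 0), dim = dim(mask))
  if (sum(m) < 1L)
    stage_error("image_io", "degenerate input: mask has no foreground element")
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stage_error("image_io", "spacing must be 3 positive values (mm)")
  structure(
    list(intensities = intensities, mask = m, spacing = as.numeric(spacing),
         axis_order = c("slice", "row", "column")),
    class = "nodule_image")
}

#' @export
print.nodule_image <- function(x, ...) {
  d <- dim(x$mask)
  cat(sprintf("<nodule_image> grid %dx%dx%d (slice,row,col), %d foreground voxels, spacing %s mm\n",
              d[1], d[2], d[3], sum(x$mask),
              paste(signif(x$spacing, 3), collapse = "x")))
  invisible(x)
}

#' Read a CT volume and its segmentation mask
#'
#' Supports NIfTI-1 (`.nii`, `.nii.gz`) and NRRD (`.nrrd`). The mask is
#' binarized by a nonzero test; with `strict = TRUE` a mask carrying more
#' than one distinct nonzero value is rejected.
#'
#' @param image_path,mask_path paths to the image and mask files.
#' @param strict reject multi-label masks.
#' @param spacing_tol relative tolerance for image/mask spacing agreement.
#' @return A [nodule_image()].
#' @export
read_nodule <- function(image_path, mask_path, strict = FALSE, spacing_tol = 1e-3) {
  with_stage("image_io", {
    img <- read_image_any(image_path)
    msk <- read_image_any(mask_path)
    if (!identical(dim(img$data), dim(msk$data)))
      stage_error("image_io", sprintf(
        "alignment error: image grid %s but mask grid %s",
        paste(dim(img$data), collapse = "x"), paste(dim(msk$data), collapse = "x")))
    rel <- abs(img$spacing - msk$spacing) / pmax(img$spacing, 1e-12)
    if (any(rel > spacing_tol))
      stage_error("image_io", "alignment error: image and mask spacing differ")
    vals <- unique(msk$data[msk$data != 0])
    if (strict && length(vals) > 1L)
      stage_error("image_io", sprintf(
        "mask carries %d distinct nonzero labels (strict mode)", length(vals)))
    nodule_image(img$data, msk$data != 0, img$spacing)
  })
}

#' Write a nodule image and mask
#'
#' Format is chosen from the file extension (`.nii`/`.nii.gz` or `.nrrd`).
#'
#' @param img a [nodule_image()].
#' @param image_path,mask_path output paths.
#' @export
write_nodule <- function(img, image_path, mask_path) {
  stopifnot(inherits(img, "nodule_image"))
  write_image_any(img$intensities, img$spacing, image_path)
  write_image_any(img$mask, img$spacing, mask_path)
  invisible(c(image_path, mask_path))
}

#' Extract the largest axial cross-section
#'
#' Returns the axial slice (first-array-axis index) whose in-mask pixel count
#' is maximal; ties are broken by the lowest slice index. Pixel count (not
#' physical area) defines "largest", keeping the 2D score unitless.
#'
#' @param img a [nodule_image()].
#' @return An object of class `planar_section` with fields `intensities`
#'   (matrix), `mask` (binary matrix), `slice_index`, `spacing` (row, column).
#' @export
largest_axial_section <- function(img) {
  stopifnot(inherits(img, "nodule_image"))
  counts <- apply(img$mask, 1L, sum)
  idx <- which.max(counts)  # which.max takes the first maximum: low-index tie-break
  structure(
    list(intensities = img$intensities[idx, , , drop = TRUE],
         mask = img$mask[idx, , , drop = TRUE],
         slice_index = as.integer(idx),
         spacing = img$spacing[2:3]),
    class = "planar_section")
}

#' @export
print.planar_section <- function(x, ...) {
  cat(sprintf("<planar_section> slice %d, %dx%d, %d foreground pixels\n",
              x$slice_index, nrow(x$mask), ncol(x$mask), sum(x$mask)))
  invisible(x)
}

## ---- generic dispatch by extension -----------------------------------------

read_image_any <- function(path) {
  if (!file.exists(path)) stage_error("image_io", paste("file not found:", path))
  lp <- tolower(path)
  if (grepl("\\.nii(\\.gz)?$", lp)) read_nifti(path)
  else if (grepl("\\.nrrd$", lp)) read_nrrd(path)
  else stage_error("image_io", paste("unsupported image format:", path))
}

write_image_any <- function(arr, spacing, path) {
  lp <- tolower(path)
  if (grepl("\\.nii(\\.gz)?$", lp)) write_nifti(arr, spacing, path)
  else if (grepl("\\.nrrd$", lp)) write_nrrd(arr, spacing, path)
  else stage_error("image_io", paste("unsupported image format:", path))
}

# memory (slice,row,col) -> disk (col,row,slice)
to_disk_order <- function(arr) aperm(arr, c(3, 2, 1))
from_disk_order <- function(arr) aperm(arr, c(3, 2, 1))

## ---- NIfTI-1 ----------------------------------------------------------------

nifti_dtypes <- list(`2` = list(what = "integer", size = 1, signed = FALSE),
                     `4` = list(what = "integer", size = 2, signed = TRUE),
                     `8` = list(what = "integer", size = 4, signed = TRUE),
                     `16` = list(what = "double", size = 4, signed = TRUE),
                     `64` = list(what = "double", size = 8, signed = TRUE),
                     `256` = list(what = "integer", size = 1, signed = TRUE),
                     `512` = list(what = "integer", size = 2, signed = FALSE))

read_nifti <- function(path) {
  con <- if (grepl("\\.gz$", tolower(path))) gzfile(path, "rb") else file(path, "rb")
  on.exit(close(con))
  hdr <- readBin(con, "raw", n = 348L)
  if (length(hdr) < 348L) stage_error("image_io", "truncated NIfTI header")
  endian <- "little"
  sz <- readBin(hdr[1:4], "integer", size = 4, endian = endian)
  if (sz != 348L) {
    endian <- "big"
    sz <- readBin(hdr[1:4], "integer", size = 4, endian = endian)
    if (sz != 348L) stage_error("image_io", "not a NIfTI-1 file (bad sizeof_hdr)")
  }
  rd <- function(off, what, size, n = 1L, signed = TRUE)
    readBin(hdr[(off + 1):(off + n * size)], what, n = n, size = size,
            endian = endian, signed = signed)
  dims <- rd(40, "integer", 2, n = 8)
  nd <- dims[1]
  if (nd < 2 || nd > 3) stage_error("image_io", "only 2D/3D NIfTI volumes supported")
  shape <- dims[2:(1 + nd)]
  datatype <- rd(70, "integer", 2)
  dt <- nifti_dtypes[[as.character(datatype)]]
  if (is.null(dt)) stage_error("image_io", paste("unsupported NIfTI datatype", datatype))
  pixdim <- rd(76, "double", 4, n = 8)
  vox_offset <- rd(108, "double", 4)
  scl_slope <- rd(112, "double", 4)
  scl_inter <- rd(116, "double", 4)
  magic <- rawToChar(hdr[345:347])
  if (!magic %in% c("n+1", "ni1")) stage_error("image_io", "bad NIfTI magic")
  skip <- max(0L, as.integer(round(vox_offset)) - 348L)
  if (skip > 0) readBin(con, "raw", n = skip)
  n_el <- prod(shape)
  data <- readBin(con, dt$what, n = n_el, size = dt$size, endian = endian,
                  signed = dt$signed)
  if (length(data) < n_el) stage_error("image_io", "truncated NIfTI data section")
  data <- as.double(data)
  if (is.finite(scl_slope) && scl_slope != 0 && !(scl_slope == 1 && scl_inter == 0))
    data <- data * scl_slope + scl_inter
  if (nd == 2) shape <- c(shape, 1L)
  arr <- array(data, dim = shape)
  sp_disk <- pixdim[2:4]
  sp_disk[sp_disk <= 0 | !is.finite(sp_disk)] <- 1
  list(data = from_disk_order(arr), spacing = rev(sp_disk))
}

write_nifti <- function(arr, spacing, path) {
  if (length(dim(arr)) != 3L) stage_error("image_io", "write_nifti expects a 3D array")
  disk <- to_disk_order(arr)
  sp_disk <- rev(spacing)
  con <- if (grepl("\\.gz$", tolower(path))) gzfile(path, "wb") else file(path, "wb")
  on.exit(close(con))
  wint <- function(x, size) writeBin(as.integer(x), con, size = size, endian = "little")
  wflt <- function(x) writeBin(as.double(x), con, size = 4, endian = "little")
  wraw <- function(n) writeBin(raw(n), con)
  wint(348L, 4)                      # sizeof_hdr
  wraw(34); writeBin(charToRaw("r"), con)  # data_type/db_name/extents/session_error, regular
  wraw(1)                            # dim_info
  wint(c(3L, dim(disk), 1L, 1L, 1L, 1L), 2)  # dim[8]
  wflt(c(0, 0, 0)); wint(0L, 2)      # intent_p1-3, intent_code
  wint(64L, 2); wint(64L, 2)         # datatype float64, bitpix
  wint(0L, 2)                        # slice_start
  wflt(c(1, sp_disk, 1, 1, 1, 1))    # pixdim[8], qfac = 1
  wflt(352); wflt(1); wflt(0)        # vox_offset, scl_slope, scl_inter
  wint(0L, 2); wraw(1)               # slice_end, slice_code
  writeBin(as.raw(2L), con)          # xyzt_units: mm
  wflt(c(0, 0, 0, 0))                # cal_max, cal_min, slice_duration, toffset
  wint(c(0L, 0L), 4)                 # glmax, glmin
  wraw(80); wraw(24)                 # descrip, aux_file
  wint(0L, 2); wint(1L, 2)           # qform_code, sform_code
  wflt(c(0, 0, 0, 0, 0, 0))          # quatern b,c,d + qoffset x,y,z
  wflt(c(sp_disk[1], 0, 0, 0))       # srow_x
  wflt(c(0, sp_disk[2], 0, 0))       # srow_y
  wflt(c(0, 0, sp_disk[3], 0))       # srow_z
  wraw(16)                           # intent_name
  writeBin(c(charToRaw("n+1"), raw(1)), con)  # magic
  wraw(4)                            # extension flag
  writeBin(as.double(disk), con, size = 8, endian = "little")
  invisible(path)
}

## ---- NRRD -------------------------------------------------------------------

nrrd_types <- list(
  uchar = list(what = "integer", size = 1, signed = FALSE),
  `unsigned char` = list(what = "integer", size = 1, signed = FALSE),
  uint8 = list(what = "integer", size = 1, signed = FALSE),
  short = list(what = "integer", size = 2, signed = TRUE),
  int16 = list(what = "integer", size = 2, signed = TRUE),
  ushort = list(what = "integer", size = 2, signed = FALSE),
  uint16 = list(what = "integer", size = 2, signed = FALSE),
  int = list(what = "integer", size = 4, signed = TRUE),
  int32 = list(what = "integer", size = 4, signed = TRUE),
  float = list(what = "double", size = 4, signed = TRUE),
  double = list(what = "double", size = 8, signed = TRUE))

read_nrrd <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readLines(con, n = 1L)
  if (!grepl("^NRRD000", magic)) stage_error("image_io", "not an NRRD file")
  fields <- list()
  repeat {
    line <- readLines(con, n = 1L)
    if (length(line) == 0L) stage_error("image_io", "NRRD header not terminated")
    if (line == "") break
    if (grepl("^#", line)) next
    kv <- regmatches(line, regexec("^([^:]+):=?\\s*(.*)$", line))[[1]]
    if (length(kv) == 3L) fields[[tolower(trimws(kv[2]))]] <- trimws(kv[3])
  }
  type <- fields[["type"]] %||% stage_error("image_io", "NRRD missing type")
  ti <- nrrd_types[[type]]
  if (is.null(ti)) stage_error("image_io", paste("unsupported NRRD type", type))
  ndim <- as.integer(fields[["dimension"]] %||% "0")
  if (!ndim %in% c(2L, 3L)) stage_error("image_io", "only 2D/3D NRRD supported")
  sizes <- as.integer(strsplit(fields[["sizes"]], "\\s+")[[1]])
  enc <- tolower(fields[["encoding"]] %||% "raw")
  endian <- tolower(fields[["endian"]] %||% "little")
  spacing <- rep(1, ndim)
  if (!is.null(fields[["spacings"]]))
    spacing <- as.numeric(strsplit(fields[["spacings"]], "\\s+")[[1]])
  if (!is.null(fields[["space directions"]])) {
    rows <- strsplit(fields[["space directions"]], "\\)\\s*")[[1]]
    sp <- vapply(rows, function(r) {
      v <- as.numeric(strsplit(gsub("[()]", "", r), ",")[[1]])
      sqrt(sum(v^2))
    }, numeric(1))
    sp <- sp[is.finite(sp) & sp > 0]
    if (length(sp) == ndim) spacing <- sp
  }
  n_el <- prod(sizes)
  data <- switch(enc,
    raw = readBin(con, ti$what, n = n_el, size = ti$size, endian = endian,
                  signed = ti$signed),
    gzip = {
      comp <- readBin(con, "raw", n = file.size(path))
      readBin(memDecompress(comp, type = "gzip"), ti$what, n = n_el,
              size = ti$size, endian = endian, signed = ti$signed)
    },
    ascii = ,
    text = ,
    txt = scan(con, what = double(), n = n_el, quiet = TRUE),
    stage_error("image_io", paste("unsupported NRRD encoding", enc)))
  if (length(data) < n_el) stage_error("image_io", "truncated NRRD data")
  if (ndim == 2L) sizes <- c(sizes, 1L)
  if (length(spacing) == 2L) spacing <- c(spacing, 1)
  arr <- array(as.double(data), dim = sizes)
  list(data = from_disk_order(arr), spacing = rev(spacing))
}

write_nrrd <- function(arr, spacing, path) {
  if (length(dim(arr)) != 3L) stage_error("image_io", "write_nrrd expects a 3D array")
  disk <- to_disk_order(arr)
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- c("NRRD0004",
           "# generated by ithscore",
           "type: double",
           "dimension: 3",
           paste("sizes:", paste(dim(disk), collapse = " ")),
           paste("spacings:", paste(rev(spacing), collapse = " ")),
           "endian: little",
           "encoding: raw",
           "")
  writeLines(hdr, con, sep = "\n")
  writeBin(as.double(disk), con, size = 8, endian = "little")
  invisible(path)
}
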