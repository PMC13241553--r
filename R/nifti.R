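# Minimal NIfTI-1 reader/writer (single-file .nii / .nii.gz, little-endian
# with byte-swap fallback on read). Only what volumetric segmentation I/O
# needs: 3D images, the common datatypes, pixdim spacing, sform affine.

.nifti_datatypes <- list(
  `2`   = list(what = "integer", size = 1L, signed = FALSE, name = "uint8"),
  `4`   = list(what = "integer", size = 2L, signed = TRUE,  name = "int16"),
  `8`   = list(what = "integer", size = 4L, signed = TRUE,  name = "int32"),
  `16`  = list(what = "double",  size = 4L, signed = TRUE,  name = "float32"),
  `64`  = list(what = "double",  size = 8L, signed = TRUE,  name = "float64"),
  `512` = list(what = "integer", size = 2L, signed = FALSE, name = "uint16")
)

.nifti_open <- function(path, mode) {
  if (grepl("\\.gz$", path)) gzfile(path, mode) else file(path, mode)
}

#' Read a 3D NIfTI-1 volume
#'
#' @param path path to a `.nii` or `.nii.gz` file
#' @return an [avp_volume()] with data, spacing (mm) and affine populated
#' @details The affine is taken from the sform when `sform_code > 0`,
#'   otherwise a diagonal affine from `pixdim` is used. Scaling
#'   (`scl_slope`/`scl_inter`) is applied when present. Images whose
#'   dimensionality is not 3 (ignoring trailing singleton axes) are
#'   rejected.
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  con <- .nifti_open(path, "rb")
  on.exit(close(con), add = TRUE)
  hdr <- readBin(con, "raw", n = 348L)
  if (length(hdr) < 348L) stop("not a NIfTI-1 file (truncated header): ", path)
  endian <- "little"
  szh <- readBin(hdr[1:4], "integer", size = 4L, endian = endian)
  if (szh != 348L) {
    endian <- "big"
    szh <- readBin(hdr[1:4], "integer", size = 4L, endian = endian)
    if (szh != 348L) stop("not a NIfTI-1 file (bad sizeof_hdr): ", path)
  }
  magic <- rawToChar(hdr[345:347])
  if (!magic %in% c("n+1", "ni1"))
    stop("not a NIfTI-1 file (bad magic '", magic, "'): ", path)
  rd <- function(off, what, n, size)
    readBin(hdr[(off + 1L):(off + n * size)], what, n = n, size = size,
            endian = endian)
  dims <- rd(40L, "integer", 8L, 2L)
  ndim <- dims[1]
  shape <- dims[2:(1 + max(ndim, 1L))]
  extra <- shape[-(1:3)]
  if (ndim < 3L || (length(extra) && any(extra > 1L)))
    stop("expected a 3D image, got ", ndim, "D with dim (",
         paste(shape, collapse = ", "), "): ", path)
  shape <- shape[1:3]
  datatype <- rd(70L, "integer", 1L, 2L)
  dt <- .nifti_datatypes[[as.character(datatype)]]
  if (is.null(dt)) stop("unsupported NIfTI datatype code ", datatype)
  pixdim <- rd(76L, "double", 8L, 4L)
  vox_offset <- rd(108L, "double", 1L, 4L)
  scl_slope <- rd(112L, "double", 1L, 4L)
  scl_inter <- rd(116L, "double", 1L, 4L)
  sform_code <- rd(254L, "integer", 1L, 2L)
  srow <- rbind(rd(280L, "double", 4L, 4L),
                rd(296L, "double", 4L, 4L),
                rd(312L, "double", 4L, 4L))
  # pixdim/srow are float32 on disk; round to 7 significant digits so
  # that millimetre spacings written from doubles round-trip exactly
  spacing <- signif(abs(pixdim[2:4]), 7)
  srow <- signif(srow, 7)
  if (sform_code > 0L) {
    affine <- rbind(srow, c(0, 0, 0, 1))
  } else {
    affine <- diag(4); diag(affine)[1:3] <- spacing
  }
  # skip to the data (header may carry extensions)
  skip <- as.integer(round(vox_offset)) - 348L
  if (skip > 0L) readBin(con, "raw", n = skip)
  n <- prod(shape)
  vals <- readBin(con, dt$what, n = n, size = dt$size, signed = dt$signed,
                  endian = endian)
  if (length(vals) < n) stop("NIfTI data truncated: ", path)
  if (is.finite(scl_slope) && scl_slope != 0 &&
      !(scl_slope == 1 && scl_inter == 0))
    vals <- vals * scl_slope + scl_inter
  data <- array(vals, dim = shape)
  if (any(!is.finite(data))) stop("volume contains non-finite values: ", path)
  sid <- sub("\\.nii(\\.gz)?$", "", basename(path))
  avp_volume(data, spacing = spacing, affine = affine, subject_id = sid)
}

#' Read a label map from NIfTI, attaching the standard scheme
#'
#' @param path path to a `.nii`/`.nii.gz` integer image
#' @param scheme label scheme; defaults to [avp_label_scheme()]
#' @return an [avp_labelmap()]
#' @export
read_labelmap <- function(path, scheme = avp_label_scheme()) {
  v <- read_volume(path)
  data <- v$data
  if (max(abs(data - round(data))) > 0)
    stop("label map contains non-integer values: ", path)
  avp_labelmap(array(as.integer(round(data)), dim(data)),
               spacing = v$spacing, affine = v$affine, scheme = scheme,
               subject_id = v$subject_id)
}

.nifti_header_raw <- function(shape, spacing, affine, datatype, bitpix) {
  con <- rawConnection(raw(0), "wb")
  on.exit(close(con), add = TRUE)
  wint <- function(x, size) writeBin(as.integer(x), con, size = size,
                                     endian = "little")
  wflt <- function(x) writeBin(as.numeric(x), con, size = 4L,
                               endian = "little")
  wraw <- function(n) writeBin(raw(n), con)
  wint(348L, 4L)                       # sizeof_hdr
  wraw(36L)                            # data_type, db_name, extents, ...
  wint(c(3L, shape, 1L, 1L, 1L, 1L), 2L)  # dim[8]
  wflt(c(0, 0, 0)); wint(0L, 2L)       # intent
  wint(datatype, 2L); wint(bitpix, 2L) # datatype, bitpix
  wint(0L, 2L)                         # slice_start
  wflt(c(1, spacing, 1, 1, 1, 1))      # pixdim[8] (qfac = 1)
  wflt(352)                            # vox_offset
  wflt(1); wflt(0)                     # scl_slope, scl_inter
  wint(0L, 2L); wraw(1L)               # slice_end, slice_code
  writeBin(as.raw(10L), con)           # xyzt_units: mm (2) | sec (8)
  wflt(c(0, 0, 0, 0))                  # cal_max/min, slice_duration, toffset
  wint(c(0L, 0L), 4L)                  # glmax, glmin
  wraw(80L); wraw(24L)                 # descrip, aux_file
  wint(0L, 2L); wint(1L, 2L)           # qform_code = 0, sform_code = 1
  wflt(c(0, 0, 0)); wflt(c(0, 0, 0))   # quatern, qoffset
  wflt(affine[1, ]); wflt(affine[2, ]); wflt(affine[3, ])
  wraw(16L)                            # intent_name
  writeBin(c(charToRaw("n+1"), as.raw(0L)), con)  # magic
  wraw(4L)                             # extension flag
  rawConnectionValue(con)
}

#' Write a volume or label map as NIfTI-1
#'
#' Volumes are stored as float64 (exact round-trip), label maps as uint8;
#' the object's
#' affine is stored in the sform. A label map additionally gets a JSON
#' sidecar (`<path minus .nii[.gz]>.json`) documenting the label scheme.
#'
#' @param v an `avp_volume` or `avp_labelmap`
#' @param path output path ending in `.nii` or `.nii.gz`
#' @param sidecar write the scheme sidecar for label maps (default TRUE)
#' @return `path`, invisibly
#' @export
write_volume <- function(v, path, sidecar = TRUE) {
  stopifnot(inherits(v, "avp_volume") || inherits(v, "avp_labelmap"))
  is_lab <- inherits(v, "avp_labelmap")
  hdr <- .nifti_header_raw(dim(v$data), v$spacing, v$affine,
                           datatype = if (is_lab) 2L else 64L,
                           bitpix = if (is_lab) 8L else 64L)
  con <- .nifti_open(path, "wb")
  on.exit(close(con), add = TRUE)
  writeBin(hdr, con)
  if (is_lab) {
    writeBin(as.integer(v$data), con, size = 1L, endian = "little")
  } else {
    writeBin(as.numeric(v$data), con, size = 8L, endian = "little")
  }
  if (is_lab && sidecar) {
    side <- sub("\\.nii(\\.gz)?$", ".json", path)
    jsonlite::write_json(
      list(labels = as.list(v$scheme$names),
           side = as.list(v$scheme$side)),
      side, auto_unbox = TRUE, pretty = TRUE)
  }
  invisible(path)
}
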