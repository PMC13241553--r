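#' 3D image volume
#'
#' A scalar 3D grid with voxel spacing in mm and a 4x4 voxel-to-world
#' affine. The internal convention is RAS-like: with a positive-diagonal
#' affine, increasing first-axis index moves toward the anatomical right.
#'
#' @param data numeric 3D array
#' @param spacing numeric length-3, voxel spacing in mm (all > 0)
#' @param affine 4x4 voxel-to-world matrix; default `diag(spacing)` with
#'   zero origin
#' @param subject_id optional subject identifier
#' @return an object of class `avp_volume`
#' @export
avp_volume <- function(data, spacing = c(0.6, 0.6, 0.6), affine = NULL,
                       subject_id = "") {
  if (length(dim(data)) != 3L)
    stop("volume data must be 3D, got ", length(dim(data)), "D")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("spacing must be three positive finite values")
  if (any(!is.finite(data)))
    stop("volume contains non-finite values")
  if (is.null(affine)) {
    affine <- diag(4)
    diag(affine)[1:3] <- spacing
  }
  structure(list(data = data, spacing = spacing, affine = affine,
                 subject_id = subject_id),
            class = "avp_volume")
}

#' Multiclass label map
#'
#' An integer 3D grid aligned to a [avp_volume()]; values are ids of an
#' [avp_label_scheme()].
#'
#' @param data integer 3D array of label ids
#' @param spacing,affine,subject_id as in [avp_volume()]
#' @param scheme an `avp_scheme`; defaults to [avp_label_scheme()]
#' @return an object of class `avp_labelmap`
#' @export
avp_labelmap <- function(data, spacing = c(0.6, 0.6, 0.6), affine = NULL,
                         scheme = avp_label_scheme(), subject_id = "") {
  if (length(dim(data)) != 3L)
    stop("label data must be 3D, got ", length(dim(data)), "D")
  storage.mode(data) <- "integer"
  bad <- setdiff(unique(as.vector(data)), scheme$ids)
  if (length(bad))
    stop("label map contains ids outside the scheme: ",
         paste(bad, collapse = ", "))
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(spacing <= 0))
    stop("spacing must be three positive values")
  if (is.null(affine)) {
    affine <- diag(4)
    diag(affine)[1:3] <- spacing
  }
  structure(list(data = data, spacing = spacing, affine = affine,
                 scheme = scheme, subject_id = subject_id),
            class = "avp_labelmap")
}

#' @export
print.avp_volume <- function(x, ...) {
  cat(sprintf("aVP volume [%s] %s, spacing %s mm, range [%.3g, %.3g]\n",
              x$subject_id, paste(dim(x$data), collapse = "x"),
              paste(format(x$spacing), collapse = "x"),
              min(x$data), max(x$data)))
  invisible(x)
}

#' @export
print.avp_labelmap <- function(x, ...) {
  fg <- sum(x$data != 0L)
  cat(sprintf("aVP label map [%s] %s, %d foreground voxels, labels {%s}\n",
              x$subject_id, paste(dim(x$data), collapse = "x"), fg,
              paste(sort(unique(as.vector(x$data))), collapse = ",")))
  invisible(x)
}

#' Crop or pad a volume to a standard matrix
#'
#' Center crop and/or symmetric zero-pad each axis independently to reach
#' `target_shape` (e.g. the standardized acquisition matrix 256 x 256 x 64).
#' When an axis difference is odd the extra voxel is cropped from / padded
#' onto the high-index side. Spacing and affine voxel scaling are
#' unchanged.
#'
#' @param v an `avp_volume` or `avp_labelmap`
#' @param target_shape integer length-3 of positive target dimensions
#' @return object of the same class with `dim(data) == target_shape`
#' @export
standardize <- function(v, target_shape = c(256L, 256L, 64L)) {
  stopifnot(inherits(v, "avp_volume") || inherits(v, "avp_labelmap"))
  target_shape <- as.integer(target_shape)
  if (length(target_shape) != 3L || any(target_shape <= 0L))
    stop("target_shape must be three positive integers")
  d <- dim(v$data)
  fill <- if (inherits(v, "avp_labelmap")) 0L else 0
  out <- array(fill, dim = target_shape)
  # source and destination index ranges per axis
  idx <- lapply(1:3, function(a) {
    n <- d[a]; t <- target_shape[a]
    if (n >= t) {
      lo <- (n - t) %/% 2L
      list(src = (lo + 1L):(lo + t), dst = 1:t)
    } else {
      lo <- (t - n) %/% 2L
      list(src = 1:n, dst = (lo + 1L):(lo + n))
    }
  })
  out[idx[[1]]$dst, idx[[2]]$dst, idx[[3]]$dst] <-
    v$data[idx[[1]]$src, idx[[2]]$src, idx[[3]]$src]
  v$data <- out
  v
}

#' Z-score intensity normalization over nonzero voxels
#'
#' Subtracts the mean and divides by the SD of the nonzero voxels, then
#' clips to \[-5, 5\]. If the nonzero voxels have zero SD only the mean is
#' subtracted (degenerate constant volume).
#'
#' @param v an `avp_volume` with at least one nonzero voxel
#' @return normalized `avp_volume`
#' @export
normalize_intensity <- function(v) {
  stopifnot(inherits(v, "avp_volume"))
  nz <- v$data != 0
  if (!any(nz)) stop("cannot normalize an all-zero volume")
  m <- mean(v$data[nz])
  s <- stats::sd(v$data[nz])
  x <- v$data - m
  if (is.finite(s) && s > 0) x <- x / s
  v$data <- pmin(pmax(x, -5), 5)
  v
}

#' Merge two readers' label maps into a union ground truth
#'
#' The reference standard keeps any voxel delineated by either reader:
#' the output foreground is exactly the set union of the two readers'
#' foregrounds. A voxel labelled by one reader only takes that reader's
#' label; agreement keeps the shared label; a multiclass conflict (both
#' readers labelled the voxel, differently) is resolved in favour of
#' reader 1 and counted.
#'
#' @param r1,r2 `avp_labelmap`s of the two readers, same shape and scheme
#' @return a list with `gt` (the merged `avp_labelmap`) and `conflicts`,
#'   a list with the total conflicting-voxel count and a 9x9 table of
#'   (reader1 label, reader2 label) disagreements
#' @export
merge_union_gt <- function(r1, r2) {
  stopifnot(inherits(r1, "avp_labelmap"), inherits(r2, "avp_labelmap"))
  if (!identical(dim(r1$data), dim(r2$data)))
    stop("reader label maps differ in shape")
  if (!identical(r1$scheme$names, r2$scheme$names))
    stop("reader label maps use different schemes")
  a <- r1$data; b <- r2$data
  out <- a
  only2 <- a == 0L & b != 0L
  out[only2] <- b[only2]
  conflict <- a != 0L & b != 0L & a != b
  nlab <- length(r1$scheme$ids) - 1L
  tab <- matrix(0L, nlab, nlab,
                dimnames = list(r1 = r1$scheme$names[-1],
                                r2 = r2$scheme$names[-1]))
  if (any(conflict)) {
    pairs <- table(factor(a[conflict], levels = 1:nlab),
                   factor(b[conflict], levels = 1:nlab))
    tab[] <- as.integer(pairs)
  }
  gt <- r1
  gt$data <- out
  list(gt = gt, conflicts = list(n = sum(conflict), table = tab))
}
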