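# Spatial similarity metrics between binary masks, in mm where relevant.
#
# Surface voxels are mask voxels with at least one 6-neighbour outside
# the mask (the image border counts as outside). Surface distances are
# measured between surface voxel centers, scaled by the voxel spacing,
# using an exact Euclidean distance transform of each surface; this is
# algebraically identical to the all-pairs nearest-neighbour distances.

.as_mask <- function(x) {
  if (is.array(x) && is.logical(x)) return(x)
  if (inherits(x, "avp_labelmap")) return(x$data != 0L)
  stop("expected a logical 3D array")
}

.check_pair <- function(a, b) {
  if (!identical(dim(a), dim(b)))
    stop("mask shapes differ: ", paste(dim(a), collapse = "x"), " vs ",
         paste(dim(b), collapse = "x"))
}

#' Dice similarity coefficient
#'
#' `DSC(A, B) = 2|A n B| / (|A| + |B|)`. Convention: both masks empty
#' gives 1 (perfect agreement on absence); exactly one empty gives 0.
#'
#' @param a,b logical 3D arrays (test and reference mask)
#' @return value in \[0, 1\]
#' @export
dsc <- function(a, b) {
  a <- .as_mask(a); b <- .as_mask(b); .check_pair(a, b)
  sa <- sum(a); sb <- sum(b)
  if (sa + sb == 0) return(1)
  2 * sum(a & b) / (sa + sb)
}

#' Jaccard index
#' @inheritParams dsc
#' @return `|A n B| / |A u B|`; 1 when both masks are empty
#' @export
jaccard <- function(a, b) {
  a <- .as_mask(a); b <- .as_mask(b); .check_pair(a, b)
  u <- sum(a | b)
  if (u == 0) return(1)
  sum(a & b) / u
}

#' Precision of a test mask against a reference
#' @inheritParams dsc
#' @return `|A n B| / |A|`; 0 when the test mask is empty
#' @export
precision <- function(a, b) {
  a <- .as_mask(a); b <- .as_mask(b); .check_pair(a, b)
  if (sum(a) == 0) return(0)
  sum(a & b) / sum(a)
}

#' Recall (sensitivity) of a test mask against a reference
#' @inheritParams dsc
#' @return `|A n B| / |B|`; 0 when the reference mask is empty
#' @export
recall <- function(a, b) {
  a <- .as_mask(a); b <- .as_mask(b); .check_pair(a, b)
  if (sum(b) == 0) return(0)
  sum(a & b) / sum(b)
}

#' Volumetric similarity
#' @inheritParams dsc
#' @return `1 - ||A| - |B|| / (|A| + |B|)`; 1 when both masks are empty
#' @export
volumetric_similarity <- function(a, b) {
  a <- .as_mask(a); b <- .as_mask(b); .check_pair(a, b)
  sa <- sum(a); sb <- sum(b)
  if (sa + sb == 0) return(1)
  1 - abs(sa - sb) / (sa + sb)
}

# directed surface distances (mm): for every surface voxel of `from`,
# distance to the nearest surface voxel of `to`
.surface_distances <- function(from, to, spacing) {
  d <- dim(from)
  sf <- cpp_surface(as.vector(from), d)
  st <- cpp_surface(as.vector(to), d)
  edt <- sqrt(cpp_edt_sq(st, d, spacing))
  edt[sf]
}

#' Hausdorff distance between two masks
#'
#' `H(A, B) = max(sup_a inf_b d(a, b), sup_b inf_a d(b, a))` over surface
#' voxel centers, in mm. The robustified `percentile = 95` variant
#' (HD95) takes the maximum of the two directed 95th percentiles
#' (`stats::quantile`, default type).
#'
#' @inheritParams dsc
#' @param spacing voxel spacing in mm
#' @param percentile 100 for the classical Hausdorff distance, 95 for HD95
#' @return distance in mm
#' @export
hausdorff <- function(a, b, spacing = c(1, 1, 1), percentile = 100) {
  a <- .as_mask(a); b <- .as_mask(b); .check_pair(a, b)
  if (sum(a) == 0) stop("hausdorff: test mask (A) is empty")
  if (sum(b) == 0) stop("hausdorff: reference mask (B) is empty")
  dab <- .surface_distances(a, b, spacing)
  dba <- .surface_distances(b, a, spacing)
  if (percentile >= 100) return(max(max(dab), max(dba)))
  max(stats::quantile(dab, percentile / 100, names = FALSE),
      stats::quantile(dba, percentile / 100, names = FALSE))
}

#' Average symmetric surface distance
#'
#' Mean of the nearest-surface distances pooled over both directions, mm.
#'
#' @inheritParams hausdorff
#' @return distance in mm
#' @export
assd <- function(a, b, spacing = c(1, 1, 1)) {
  a <- .as_mask(a); b <- .as_mask(b); .check_pair(a, b)
  if (sum(a) == 0) stop("assd: test mask (A) is empty")
  if (sum(b) == 0) stop("assd: reference mask (B) is empty")
  dab <- .surface_distances(a, b, spacing)
  dba <- .surface_distances(b, a, spacing)
  mean(c(dab, dba))
}

#' All eight similarity metrics for one mask pair
#'
#' @inheritParams hausdorff
#' @return named list: dsc, jaccard, precision, recall, vs, hd, hd95,
#'   assd. Distance metrics are `NA` (with attribute `reason`) when
#'   either mask is empty.
#' @export
all_metrics <- function(a, b, spacing = c(1, 1, 1)) {
  a <- .as_mask(a); b <- .as_mask(b); .check_pair(a, b)
  out <- list(dsc = dsc(a, b), jaccard = jaccard(a, b),
              precision = precision(a, b), recall = recall(a, b),
              vs = volumetric_similarity(a, b))
  if (sum(a) == 0 || sum(b) == 0) {
    out$hd <- NA_real_; out$hd95 <- NA_real_; out$assd <- NA_real_
    attr(out, "reason") <- sprintf(
      "distance metrics undefined: %s mask empty",
      if (sum(a) == 0 && sum(b) == 0) "both"
      else if (sum(a) == 0) "test" else "reference")
  } else {
    out$hd <- hausdorff(a, b, spacing, 100)
    out$hd95 <- hausdorff(a, b, spacing, 95)
    out$assd <- assd(a, b, spacing)
  }
  out
}

#' Per-group metric rows for one subject
#'
#' Computes the eight metrics for each reporting group (whole pathway,
#' per nerve, chiasm, tracts, nerve subdivisions) by binarizing with
#' [aggregate_labels()].
#'
#' @param pred,gt `avp_labelmap`s with the same shape and scheme
#' @param groups character vector of group names (default
#'   [report_groups()])
#' @return data.frame with columns subject_id, group, metric, value,
#'   note (empty-mask reason where applicable)
#' @export
evaluate_subject <- function(pred, gt, groups = report_groups()) {
  stopifnot(inherits(pred, "avp_labelmap"), inherits(gt, "avp_labelmap"))
  if (!identical(dim(pred$data), dim(gt$data)))
    stop("prediction and ground truth differ in shape")
  if (!identical(pred$scheme$names, gt$scheme$names))
    stop("prediction and ground truth use different schemes")
  rows <- lapply(groups, function(g) {
    m <- all_metrics(aggregate_labels(pred, g), aggregate_labels(gt, g),
                     spacing = gt$spacing)
    data.frame(subject_id = gt$subject_id, group = g,
               metric = names(unlist(m)), value = unname(unlist(m)),
               note = attr(m, "reason") %||% "",
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
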