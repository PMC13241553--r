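# Anatomically-aware corrections applied after ensemble voting:
# cluster removal, side-aware label enforcement, gap interpolation, and
# continuity correction along the nerve-chiasm-tract chains.

#' Post-processing configuration
#'
#' @param connectivity neighbourhood for connected components (6/18/26)
#' @param closing_len length (voxels) of the line structuring element
#'   used for directional morphological closing
#' @param bridge_max_mm maximum centerline gap (mm) bridged by the
#'   continuity correction; longer gaps are reported, not bridged
#' @param midline optional explicit midline x index; default derives the
#'   midline sagittal plane from the chiasm centroid
#' @return object of class `avp_post_config`
#' @export
postprocess_config <- function(connectivity = 26L, closing_len = 5L,
                               bridge_max_mm = 3, midline = NULL) {
  if (!connectivity %in% c(6L, 18L, 26L))
    stop("connectivity must be 6, 18 or 26")
  stopifnot(closing_len >= 0, bridge_max_mm >= 0)
  structure(list(connectivity = as.integer(connectivity),
                 closing_len = as.integer(closing_len),
                 bridge_max_mm = bridge_max_mm, midline = midline),
            class = "avp_post_config")
}

.centroid <- function(mask) {
  idx <- which(mask, arr.ind = TRUE)
  colMeans(idx)
}

#' Keep only the largest connected component of each label
#'
#' Ties in size are broken toward the component whose centroid is
#' closest to the image center. Removed voxels become background.
#'
#' @param l an `avp_labelmap`
#' @param cfg a [postprocess_config()]
#' @return cleaned `avp_labelmap` with attribute `"diagnostics"`
#' @export
remove_clusters <- function(l, cfg = postprocess_config()) {
  stopifnot(inherits(l, "avp_labelmap"))
  lab <- l$data
  d <- dim(lab)
  center <- (d + 1) / 2
  removed <- list()
  for (id in setdiff(sort(unique(as.vector(lab))), 0L)) {
    mask <- lab == id
    comp <- array(cpp_label_components(as.vector(mask), d,
                                       cfg$connectivity), d)
    ncomp <- max(comp)
    if (ncomp <= 1L) next
    sizes <- tabulate(comp[comp > 0L], nbins = ncomp)
    biggest <- which(sizes == max(sizes))
    if (length(biggest) > 1L) {
      dist2 <- vapply(biggest, function(ci)
        sum((.centroid(comp == ci) - center)^2), numeric(1))
      biggest <- biggest[which.min(dist2)]
    } else biggest <- biggest[1]
    drop <- mask & comp != biggest
    lab[drop] <- 0L
    removed[[l$scheme$names[[as.character(id)]]]] <-
      list(components = ncomp - 1L, voxels = sum(drop))
  }
  out <- l
  out$data <- lab
  attr(out, "diagnostics") <- list(removed = removed)
  out
}

.contralateral <- function(scheme) {
  nm <- scheme$names
  map <- stats::setNames(nm, nm)
  for (n in nm) {
    if (grepl("^ONR", n)) map[[n]] <- sub("^ONR", "ONL", n)
    else if (grepl("^ONL", n)) map[[n]] <- sub("^ONL", "ONR", n)
    else if (n == "OTR") map[[n]] <- "OTL"
    else if (n == "OTL") map[[n]] <- "OTR"
  }
  map
}

#' Relabel connected components lying on the wrong side
#'
#' The midline sagittal plane passes through the chiasm centroid (or an
#' explicit `cfg$midline` index). Laterality is read from the affine's
#' first axis: with a positive first diagonal, larger first-axis index
#' is the anatomical right. A sided label's component whose centroid
#' lies strictly on the wrong side is relabelled to the contralateral
#' label; components exactly on the midline are untouched.
#'
#' @inheritParams remove_clusters
#' @return corrected `avp_labelmap` with attribute `"diagnostics"`
#' @export
enforce_sides <- function(l, cfg = postprocess_config()) {
  stopifnot(inherits(l, "avp_labelmap"))
  lab <- l$data
  d <- dim(lab)
  scheme <- l$scheme
  right_dir <- sign(l$affine[1, 1])
  if (right_dir == 0) right_dir <- 1
  if (!is.null(cfg$midline)) {
    xm <- cfg$midline
  } else {
    onc <- lab == label_id(scheme, "ONC")
    if (!any(onc))
      stop("cannot enforce sides: chiasm absent and no midline configured")
    xm <- .centroid(onc)[1]
  }
  contra <- .contralateral(scheme)
  flips <- list()
  for (id in setdiff(sort(unique(as.vector(lab))), 0L)) {
    nm <- scheme$names[[as.character(id)]]
    side <- scheme$side[[nm]]
    if (!side %in% c("left", "right")) next
    mask <- lab == id
    comp <- array(cpp_label_components(as.vector(mask), d,
                                       cfg$connectivity), d)
    for (ci in seq_len(max(comp))) {
      cx <- .centroid(comp == ci)[1]
      pos <- right_dir * (cx - xm)   # > 0: on the right of the midline
      wrong <- (side == "right" && pos < 0) || (side == "left" && pos > 0)
      if (wrong) {
        lab[comp == ci] <- label_id(scheme, contra[[nm]])
        flips[[length(flips) + 1L]] <-
          list(from = nm, to = contra[[nm]], voxels = sum(comp == ci))
      }
    }
  }
  out <- l
  out$data <- lab
  attr(out, "diagnostics") <- list(side_flips = flips)
  out
}

.line_se_offsets <- function(mask, len) {
  if (len < 2L) return(matrix(0L, 1, 3))
  idx <- which(mask, arr.ind = TRUE)
  if (nrow(idx) < 2L) {
    axis <- c(1, 0, 0)
  } else {
    cv <- stats::cov(idx)
    axis <- eigen(cv, symmetric = TRUE)$vectors[, 1]
  }
  t <- seq(-(len - 1) / 2, (len - 1) / 2, by = 0.5)
  off <- unique(round(t %o% axis))
  storage.mode(off) <- "integer"
  off
}

#' Fill small gaps by directional morphological closing
#'
#' Per label, a morphological closing with a line structuring element
#' oriented along the label's principal axis fills gaps up to roughly
#' the closing length. Only currently-background voxels are filled;
#' other labels are never overwritten.
#'
#' @inheritParams remove_clusters
#' @return filled `avp_labelmap` with attribute `"diagnostics"`
#' @export
interpolate_gaps <- function(l, cfg = postprocess_config()) {
  stopifnot(inherits(l, "avp_labelmap"))
  lab <- l$data
  d <- dim(lab)
  filled <- list()
  if (cfg$closing_len >= 2L) {
    for (id in setdiff(sort(unique(as.vector(lab))), 0L)) {
      mask <- lab == id
      # a single-component label has no gap to interpolate; skipping it
      # also keeps directional closing from thickening curved tubes
      if (max(cpp_label_components(as.vector(mask), d,
                                   cfg$connectivity)) <= 1L) next
      off <- .line_se_offsets(mask, cfg$closing_len)
      dil <- cpp_dilate(as.vector(mask), d, off)
      # erosion(X) = !dilate(!X, -SE)
      ero <- !cpp_dilate(!dil, d, -off)
      new <- array(ero, d) & !mask & lab == 0L
      if (any(new)) {
        lab[new] <- id
        filled[[l$scheme$names[[as.character(id)]]]] <- sum(new)
      }
    }
  }
  out <- l
  out$data <- lab
  attr(out, "diagnostics") <- list(filled = filled)
  out
}

.adjacent26 <- function(a, b, d) {
  off <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  storage.mode(off) <- "integer"
  any(array(cpp_dilate(as.vector(a), d, off), d) & b)
}

#' Bridge disconnected adjacent segments of each side's chain
#'
#' For each adjacent pair in the iOrb -> iCan -> iCran -> chiasm ->
#' tract chain whose components are not 26-adjacent, a 1-voxel-thick
#' straight bridge is drawn between their nearest surface voxels,
#' through background only, labelled by the nearer segment up to the
#' midpoint. Gaps longer than `cfg$bridge_max_mm` are reported in the
#' diagnostics and left unbridged.
#'
#' @inheritParams remove_clusters
#' @return connected `avp_labelmap` with attribute `"diagnostics"`
#' @export
enforce_continuity <- function(l, cfg = postprocess_config()) {
  stopifnot(inherits(l, "avp_labelmap"))
  lab <- l$data
  d <- dim(lab)
  sp <- l$spacing
  scheme <- l$scheme
  bridges <- list()
  pairs <- unique(do.call(rbind, lapply(scheme$chains, function(ch)
    cbind(ch[-length(ch)], ch[-1]))))
  for (i in seq_len(nrow(pairs))) {
    na <- pairs[i, 1]; nb <- pairs[i, 2]
    ia <- label_id(scheme, na); ib <- label_id(scheme, nb)
    a <- lab == ia; b <- lab == ib
    if (!any(a) || !any(b)) next
    if (.adjacent26(a, b, d)) next
    db <- sqrt(cpp_edt_sq(as.vector(b), d, sp))
    ai <- which(a)
    va_lin <- ai[which.min(db[ai])]
    va <- arrayInd(va_lin, d)[1, ]
    gap <- min(db[ai])
    bi <- which(b, arr.ind = TRUE)
    dv <- sweep(bi, 2, va) %*% diag(sp)
    vb <- bi[which.min(rowSums(dv^2)), ]
    rec <- list(from = na, to = nb, gap_mm = gap)
    if (gap > cfg$bridge_max_mm) {
      rec$bridged <- FALSE
      bridges[[length(bridges) + 1L]] <- rec
      next
    }
    nstep <- max(2L, ceiling(2 * gap / min(sp)) + 1L)
    ts <- seq(0, 1, length.out = nstep)
    for (t in ts) {
      v <- round(va + t * (vb - va))
      if (any(v < 1) || any(v > d)) next
      if (lab[v[1], v[2], v[3]] == 0L)
        lab[v[1], v[2], v[3]] <- if (t <= 0.5) ia else ib
    }
    rec$bridged <- TRUE
    bridges[[length(bridges) + 1L]] <- rec
  }
  out <- l
  out$data <- lab
  attr(out, "diagnostics") <- list(bridges = bridges)
  out
}

#' Full anatomical post-processing
#'
#' Composition of the four operators in the order gap interpolation ->
#' cluster removal -> side enforcement -> continuity correction. Gaps
#' are closed first so that a thin structure transected by a small gap
#' is reunified rather than having one half discarded as a "cluster";
#' speckle noise survives the closing stage (it is far from any
#' structure) and is then removed before the geometric reasoning. On
#' anatomically valid input the composition is a no-op, and the
#' composition is idempotent.
#'
#' @inheritParams remove_clusters
#' @param max_sweeps upper bound on fixpoint sweeps of the four-stage
#'   composition; a sweep that changes nothing terminates the loop, so
#'   the operator is idempotent by construction
#' @return corrected `avp_labelmap`; attribute `"diagnostics"` collects
#'   the per-stage reports of every sweep
#' @export
postprocess <- function(l, cfg = postprocess_config(), max_sweeps = 4L) {
  cur <- l
  diags <- list()
  for (sweep in seq_len(max_sweeps)) {
    s1 <- interpolate_gaps(cur, cfg)
    s2 <- remove_clusters(s1, cfg)
    s3 <- enforce_sides(s2, cfg)
    s4 <- enforce_continuity(s3, cfg)
    diags[[sweep]] <- c(attr(s1, "diagnostics"), attr(s2, "diagnostics"),
                        attr(s3, "diagnostics"), attr(s4, "diagnostics"))
    changed <- !identical(s4$data, cur$data)
    cur <- s4
    if (!changed) break
  }
  attr(cur, "diagnostics") <- diags
  cur
}
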