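#' The nine-label anatomical scheme of the anterior visual pathway
#'
#' Fixed integer coding for the ten classes (background plus nine
#' structures): each optic nerve is subdivided into intraorbital (iOrb),
#' intracanalicular (iCan) and intracranial (iCran) segments, plus the
#' optic chiasm (ONC) and the left and right optic tracts (OTL, OTR).
#' Integer ids are contiguous 0..9 with background = 0 so that label maps
#' can be exchanged as unsigned 8-bit NIfTI volumes.
#'
#' @return An object of class `avp_scheme`: a list with `ids` (0..9),
#'   `names` (id -> label name), `side` (label name -> "left"/"right"/
#'   "midline"), and `chains`, the anatomical segment order
#'   iOrb -> iCan -> iCran -> chiasm -> tract for each side.
#' @export
avp_label_scheme <- function() {
  nm <- c("background",
          "ONR_iOrb", "ONR_iCan", "ONR_iCran",
          "ONL_iOrb", "ONL_iCan", "ONL_iCran",
          "ONC", "OTR", "OTL")
  side <- c(background = "none",
            ONR_iOrb = "right", ONR_iCan = "right", ONR_iCran = "right",
            ONL_iOrb = "left", ONL_iCan = "left", ONL_iCran = "left",
            ONC = "midline", OTR = "right", OTL = "left")
  scheme <- list(
    ids = 0:9,
    names = stats::setNames(nm, as.character(0:9)),
    side = side,
    chains = list(
      right = c("ONR_iOrb", "ONR_iCan", "ONR_iCran", "ONC", "OTR"),
      left  = c("ONL_iOrb", "ONL_iCan", "ONL_iCran", "ONC", "OTL")
    )
  )
  class(scheme) <- "avp_scheme"
  scheme
}

#' @export
print.avp_scheme <- function(x, ...) {
  cat("aVP label scheme:", length(x$ids), "classes\n")
  for (i in x$ids) {
    nm <- x$names[[as.character(i)]]
    cat(sprintf("  %d  %-10s %s\n", i, nm, x$side[[nm]]))
  }
  invisible(x)
}

#' Integer id of a label name
#' @param scheme an `avp_scheme`
#' @param name label name, e.g. `"ONR_iCan"`
#' @return integer id
#' @export
label_id <- function(scheme, name) {
  hit <- match(name, scheme$names)
  if (anyNA(hit)) stop("unknown label name: ", paste(name[is.na(hit)], collapse = ", "))
  as.integer(names(scheme$names)[hit])
}

#' Named structure groups used in reporting
#'
#' Groups mirror the reporting granularity: the whole pathway, each optic
#' nerve (union of its three segments), the chiasm, each tract, and the
#' three bilateral nerve subdivisions. Any single label name is also a
#' valid group.
#'
#' @param scheme an `avp_scheme`
#' @param group group name
#' @return integer vector of member label ids
#' @export
group_labels <- function(scheme, group) {
  lid <- function(...) label_id(scheme, c(...))
  switch(group,
    whole_aVP = 1:9,
    ONR = lid("ONR_iOrb", "ONR_iCan", "ONR_iCran"),
    ONL = lid("ONL_iOrb", "ONL_iCan", "ONL_iCran"),
    ONC = lid("ONC"),
    OTR = lid("OTR"),
    OTL = lid("OTL"),
    iOrb = lid("ONR_iOrb", "ONL_iOrb"),
    iCan = lid("ONR_iCan", "ONL_iCan"),
    iCran = lid("ONR_iCran", "ONL_iCran"),
    {
      if (group %in% scheme$names) label_id(scheme, group)
      else stop("unknown structure group: ", group)
    })
}

#' Standard report groups
#' @return character vector of group names in reporting order
#' @export
report_groups <- function() {
  c("whole_aVP", "ONL", "ONR", "ONC", "OTL", "OTR", "iOrb", "iCan", "iCran")
}

#' Binary mask of a structure group
#'
#' @param l an `avp_labelmap`
#' @param group a group name accepted by [group_labels()]
#' @return logical 3D array, the union of the member labels
#' @export
aggregate_labels <- function(l, group) {
  stopifnot(inherits(l, "avp_labelmap"))
  ids <- group_labels(l$scheme, group)
  array(l$data %in% ids, dim = dim(l$data))
}
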