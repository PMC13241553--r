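# Synthetic CISS-like phantom of the anterior visual pathway.
#
# Geometry: each optic nerve is a tube swept along a cubic Bezier curve
# from an anterolateral orbital point to the chiasm; the chiasm is an
# ellipsoid; the tracts are tubes diverging posteriorly. Nerve arc length
# is split into iOrb/iCan/iCran segments by fixed fractions. Contrast
# follows the nerve--CSF interface that drives the segmentation task:
# dark nerve core inside a bright fluid sheath, orbital fat anteriorly,
# dark bone around the optic canal, plus Gaussian noise and an optional
# multiplicative signal drop in the canal (field-inhomogeneity mimic).

#' Run an expression with a temporary RNG seed
#' @param seed integer seed
#' @param expr expression
#' @return value of `expr`
#' @keywords internal
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  }, add = TRUE)
  set.seed(seed)
  expr
}

#' Parametric description of an aVP phantom
#'
#' Defaults state the emulated acquisition: 0.6-mm isotropic voxels and a
#' desk-scale 64 x 64 x 32 grid. Nerve caliber defaults to a 1.5-mm tube
#' radius (a plausible adult optic-nerve scale; the true population
#' distribution is not modelled). Arc-length fractions of the nerve
#' subdivisions default to 0.5/0.2/0.3 (iOrb/iCan/iCran).
#'
#' @param shape integer grid dimensions (voxels)
#' @param spacing voxel spacing in mm
#' @param nerve_radius_mm tube radius of the optic nerves (mm)
#' @param nerve_radius_sd between-subject SD of the radius (mm), used by
#'   [make_cohort()]
#' @param arc_fractions length-3 fractions of nerve arc length assigned
#'   to iOrb, iCan, iCran; must sum to 1
#' @param chiasm_halfwidth_mm ellipsoid semi-axis along x (mm)
#' @param tract_length_mm approximate tract arc length (mm)
#' @param sheath_mm thickness of the bright CSF sheath (mm)
#' @param intensities named levels for nerve, fluid, fat, bone, background
#' @param noise_sd additive Gaussian noise SD (image units)
#' @param canal_shading list with `drop` (fractional signal loss at the
#'   canal center, 0 disables) and `extent_mm` (Gaussian radius)
#' @param lateral_jitter_mm random lateral offset of the orbit entry
#'   points (used by [make_cohort()] variation)
#' @param seed integer seed making generation deterministic
#' @return an object of class `avp_phantom_spec`
#' @export
phantom_spec <- function(shape = c(64L, 64L, 32L),
                         spacing = c(0.6, 0.6, 0.6),
                         nerve_radius_mm = 1.5,
                         nerve_radius_sd = 0.2,
                         arc_fractions = c(0.5, 0.2, 0.3),
                         chiasm_halfwidth_mm = 4.5,
                         tract_length_mm = 12,
                         sheath_mm = 1.0,
                         intensities = c(nerve = 0.35, fluid = 0.85,
                                         fat = 0.9, bone = 0.05,
                                         background = 0.4),
                         noise_sd = 0.04,
                         canal_shading = list(drop = 0.35, extent_mm = 3),
                         lateral_jitter_mm = 0,
                         seed = 1L) {
  stopifnot(length(shape) == 3L, all(shape > 0),
            length(spacing) == 3L, all(spacing > 0),
            nerve_radius_mm > 0, length(arc_fractions) == 3L)
  if (abs(sum(arc_fractions) - 1) > 1e-8)
    stop("arc_fractions must sum to 1")
  fov <- shape * spacing
  if (2 * chiasm_halfwidth_mm > 0.6 * fov[1] ||
      nerve_radius_mm * 4 > fov[3])
    stop("phantom geometry exceeds the grid")
  structure(list(shape = as.integer(shape), spacing = as.numeric(spacing),
                 nerve_radius_mm = nerve_radius_mm,
                 nerve_radius_sd = nerve_radius_sd,
                 arc_fractions = arc_fractions,
                 chiasm_halfwidth_mm = chiasm_halfwidth_mm,
                 tract_length_mm = tract_length_mm,
                 sheath_mm = sheath_mm,
                 intensities = intensities,
                 noise_sd = noise_sd,
                 canal_shading = canal_shading,
                 lateral_jitter_mm = lateral_jitter_mm,
                 seed = as.integer(seed)),
            class = "avp_phantom_spec")
}

# Cubic Bezier sampled at ~step mm arc length; returns matrix of points
# (rows) and cumulative arc length attribute.
.bezier_points <- function(p0, p1, p2, p3, step = 0.3) {
  t <- seq(0, 1, length.out = 200L)
  b <- sapply(1:3, function(a)
    (1 - t)^3 * p0[a] + 3 * (1 - t)^2 * t * p1[a] +
      3 * (1 - t) * t^2 * p2[a] + t^3 * p3[a])
  seglen <- sqrt(rowSums(diff(b)^2))
  arc <- c(0, cumsum(seglen))
  total <- arc[length(arc)]
  want <- seq(0, total, by = step)
  out <- sapply(1:3, function(a) stats::approx(arc, b[, a], xout = want)$y)
  attr(out, "arc") <- want
  out
}

# geometry of one phantom in world mm; returns the centerline samples of
# each structure with their label ids
.phantom_geometry <- function(spec, lat_off = c(0, 0)) {
  fov <- spec$shape * spec$spacing
  xm <- (spec$shape[1] - 1) * spec$spacing[1] / 2
  zm <- (spec$shape[3] - 1) * spec$spacing[3] / 2
  yc <- 0.55 * fov[2]
  cw <- spec$chiasm_halfwidth_mm
  structures <- list()
  for (s in c("right", "left")) {
    sgn <- if (s == "right") 1 else -1
    off <- if (s == "right") lat_off[1] else lat_off[2]
    # nerve: orbit -> chiasm
    p0 <- c(xm + sgn * (0.30 * fov[1] + off), 0.12 * fov[2], zm - 0.08 * fov[3])
    p3 <- c(xm + sgn * 0.55 * cw, yc - 0.45 * cw, zm)
    p1 <- p0 + c(-sgn * 0.04 * fov[1], 0.20 * fov[2], 0.05 * fov[3])
    p2 <- p3 + c(sgn * 0.05 * fov[1], -0.18 * fov[2], 0)
    nerve <- .bezier_points(p0, p1, p2, p3)
    arc <- attr(nerve, "arc")
    frac <- arc / max(arc)
    cf <- cumsum(spec$arc_fractions)
    seg <- ifelse(frac <= cf[1], "iOrb", ifelse(frac <= cf[2], "iCan", "iCran"))
    pre <- if (s == "right") "ONR_" else "ONL_"
    structures[[paste0("nerve_", s)]] <-
      list(pts = nerve, label = paste0(pre, seg), kind = "tube",
           radius = spec$nerve_radius_mm)
    # tract: chiasm -> posterolateral
    q0 <- c(xm + sgn * 0.50 * cw, yc + 0.40 * cw, zm)
    q3 <- q0 + c(sgn * 0.55, 0.80, 0.25) / sqrt(0.55^2 + 0.80^2 + 0.25^2) *
      spec$tract_length_mm
    q1 <- q0 + c(sgn * 0.5, 2.0, 0.2)
    q2 <- q3 + c(-sgn * 0.5, -2.0, 0)
    tract <- .bezier_points(q0, q1, q2, q3)
    structures[[paste0("tract_", s)]] <-
      list(pts = tract, label = if (s == "right") "OTR" else "OTL",
           kind = "tube", radius = spec$nerve_radius_mm * 0.95)
  }
  structures$chiasm <- list(center = c(xm, yc, zm),
                            axes = c(cw, 0.55 * cw, 0.45 * cw),
                            label = "ONC", kind = "ellipsoid")
  structures
}

#' Generate a synthetic aVP phantom
#'
#' @param spec an [phantom_spec()]
#' @return list with `volume` (an [avp_volume()]) and `gt`
#'   (an [avp_labelmap()]); deterministic given `spec$seed`
#' @export
generate_phantom <- function(spec = phantom_spec()) {
  stopifnot(inherits(spec, "avp_phantom_spec"))
  with_seed(spec$seed, .generate_phantom_impl(spec))
}

.generate_phantom_impl <- function(spec) {
  scheme <- avp_label_scheme()
  sh <- spec$shape; sp <- spec$spacing
  lat_off <- if (spec$lateral_jitter_mm > 0)
    stats::rnorm(2, 0, spec$lateral_jitter_mm) else c(0, 0)
  geo <- .phantom_geometry(spec, lat_off)
  xs <- (seq_len(sh[1]) - 1) * sp[1]
  ys <- (seq_len(sh[2]) - 1) * sp[2]
  zs <- (seq_len(sh[3]) - 1) * sp[3]
  margin <- array(-Inf, sh)      # signed membership margin (mm)
  lab <- array(0L, sh)
  dcan <- array(Inf, sh)         # distance to iCan centerline (shading)
  reach <- spec$nerve_radius_mm + spec$sheath_mm + 2.5
  paint_tube <- function(pts, labels, radius) {
    n <- nrow(pts)
    for (i in seq_len(n)) {
      p <- pts[i, ]
      xr <- which(abs(xs - p[1]) <= reach)
      yr <- which(abs(ys - p[2]) <= reach)
      zr <- which(abs(zs - p[3]) <= reach)
      if (!length(xr) || !length(yr) || !length(zr)) next
      d2 <- outer(outer((xs[xr] - p[1])^2, (ys[yr] - p[2])^2, "+"),
                  (zs[zr] - p[3])^2, "+")
      d <- sqrt(d2)
      m <- radius - d
      cur <- margin[xr, yr, zr]
      sel <- m > cur
      if (any(sel)) {
        cur[sel] <- m[sel]
        margin[xr, yr, zr] <<- cur
        lb <- lab[xr, yr, zr]
        lb[sel] <- label_id(scheme, labels[i])
        lab[xr, yr, zr] <<- lb
      }
      if (grepl("iCan$", labels[i])) {
        dc <- dcan[xr, yr, zr]
        upd <- d < dc
        dc[upd] <- d[upd]
        dcan[xr, yr, zr] <<- dc
      }
    }
  }
  for (g in geo) {
    if (g$kind == "tube") {
      paint_tube(g$pts, if (length(g$label) == 1)
        rep(g$label, nrow(g$pts)) else g$label, g$radius)
    }
  }
  # chiasm ellipsoid: margin = (1 - normalized radial coord) * smallest axis
  ch <- geo$chiasm
  q <- sqrt(outer(outer(((xs - ch$center[1]) / ch$axes[1])^2,
                        ((ys - ch$center[2]) / ch$axes[2])^2, "+"),
                  ((zs - ch$center[3]) / ch$axes[3])^2, "+"))
  mch <- (1 - q) * min(ch$axes)
  sel <- mch > margin
  margin[sel] <- mch[sel]
  lab[sel] <- label_id(scheme, "ONC")
  # image synthesis
  iv <- spec$intensities
  img <- array(iv[["background"]], sh)
  yfat <- 0.22 * sh[2] * sp[2]
  fat_region <- outer(outer(rep(TRUE, sh[1]), ys < yfat, "&"),
                      rep(TRUE, sh[3]), "&")
  img[fat_region] <- iv[["fat"]]
  bone <- dcan > spec$nerve_radius_mm + spec$sheath_mm &
    dcan <= spec$nerve_radius_mm + spec$sheath_mm + 1.8
  img[bone] <- iv[["bone"]]
  sheath <- margin <= 0 & margin > -spec$sheath_mm
  img[sheath] <- iv[["fluid"]]
  inside <- margin > 0
  img[inside] <- iv[["nerve"]]
  if (spec$canal_shading$drop > 0) {
    shade <- 1 - spec$canal_shading$drop *
      exp(-(dcan / spec$canal_shading$extent_mm)^2)
    img <- img * shade
  }
  img <- img + stats::rnorm(length(img), 0, spec$noise_sd)
  img <- pmin(pmax(img, 0), 1.5)
  lab[margin <= 0] <- 0L
  sid <- sprintf("phantom-seed%03d", spec$seed)
  list(volume = avp_volume(array(img, sh), spacing = sp, subject_id = sid),
       gt = avp_labelmap(lab, spacing = sp, scheme = scheme,
                         subject_id = sid))
}

#' Reader-perturbation parameters
#'
#' Emulates inter-reader variability: stochastic one-voxel edits along
#' structure boundaries and systematic shifts of the segment-transition
#' planes, including the posterior tract truncation that drives most
#' reader disagreement.
#'
#' @param boundary_prob probability that a boundary voxel is edited
#' @param band boundary band half-width in voxels (editing passes)
#' @param transition_jitter_mm SD of the shift applied to each
#'   iOrb/iCan/iCran/ONC transition (mm)
#' @param truncation_jitter_mm SD of posterior tract truncation (mm)
#' @param seed integer seed
#' @return object of class `avp_reader_perturbation`
#' @export
reader_perturbation <- function(boundary_prob = 0.35, band = 1L,
                                transition_jitter_mm = 0.8,
                                truncation_jitter_mm = 1.2,
                                seed = 1L) {
  stopifnot(boundary_prob >= 0, boundary_prob <= 1, band >= 0)
  structure(list(boundary_prob = boundary_prob, band = as.integer(band),
                 transition_jitter_mm = transition_jitter_mm,
                 truncation_jitter_mm = truncation_jitter_mm,
                 seed = as.integer(seed)),
            class = "avp_reader_perturbation")
}

#' Simulate one reader's delineation from the ground truth
#'
#' @param gt an [avp_labelmap()]
#' @param p an [reader_perturbation()]
#' @return perturbed `avp_labelmap`; differs from `gt` only near label
#'   boundaries and segment transitions; deterministic given `p$seed`
#' @export
perturb_reader <- function(gt, p = reader_perturbation()) {
  stopifnot(inherits(gt, "avp_labelmap"),
            inherits(p, "avp_reader_perturbation"))
  with_seed(p$seed, .perturb_reader_impl(gt, p))
}

.perturb_reader_impl <- function(gt, p) {
  lab <- gt$data
  sh <- dim(lab)
  sp <- gt$spacing
  scheme <- gt$scheme
  # 1) segment-transition jitter along each side's chain
  if (p$transition_jitter_mm > 0) {
    for (side in names(scheme$chains)) {
      chain <- scheme$chains[[side]]
      for (i in seq_len(length(chain) - 1L)) {
        a <- label_id(scheme, chain[i]); b <- label_id(scheme, chain[i + 1])
        s <- stats::rnorm(1, 0, p$transition_jitter_mm)
        if (abs(s) < 1e-9) next
        from <- if (s > 0) a else b
        to <- if (s > 0) b else a
        tomask <- lab == to
        if (!any(tomask) || !any(lab == from)) next
        d <- sqrt(cpp_edt_sq(as.vector(tomask), sh, sp))
        sel <- lab == from & array(d, sh) <= abs(s)
        lab[sel] <- to
      }
    }
  }
  # 2) posterior tract truncation
  if (p$truncation_jitter_mm > 0) {
    ys <- (seq_len(sh[2]) - 1) * sp[2]
    yarr <- array(rep(ys, each = sh[1]), sh)
    for (tr in c("OTR", "OTL")) {
      id <- label_id(scheme, tr)
      m <- lab == id
      if (!any(m)) next
      s <- abs(stats::rnorm(1, 0, p$truncation_jitter_mm))
      if (s < 1e-9) next
      ymax <- max(yarr[m])
      lab[m & yarr > ymax - s] <- 0L
    }
  }
  # 3) stochastic one-voxel boundary edits, `band` passes
  if (p$boundary_prob > 0 && p$band > 0) {
    shift <- function(a, dx, dy, dz) {
      out <- array(0L, dim(a))
      src <- list(x = seq_len(sh[1]) - dx, y = seq_len(sh[2]) - dy,
                  z = seq_len(sh[3]) - dz)
      okx <- src$x >= 1 & src$x <= sh[1]
      oky <- src$y >= 1 & src$y <= sh[2]
      okz <- src$z >= 1 & src$z <= sh[3]
      out[okx, oky, okz] <- a[src$x[okx], src$y[oky], src$z[okz]]
      out
    }
    offs <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0),
                  c(0, -1, 0), c(0, 0, 1), c(0, 0, -1))
    # per-offset probability such that a voxel on a single-direction
    # boundary is edited with ~boundary_prob per pass
    p_off <- 1 - (1 - p$boundary_prob)^(1 / 6)
    for (pass in seq_len(p$band)) {
      for (o in sample.int(6)) {
        neigh <- shift(lab, offs[o, 1], offs[o, 2], offs[o, 3])
        boundary <- neigh != lab
        edit <- boundary &
          array(stats::runif(length(lab)) < p_off, sh)
        lab[edit] <- neigh[edit]
      }
    }
  }
  out <- gt
  out$data <- lab
  out
}

#' Simulate a cohort of phantom subjects with two readers each
#'
#' @param n number of subjects (>= 1)
#' @param template a [phantom_spec()] used as the base geometry
#' @param variation list of between-subject variation ranges:
#'   `radius_sd` (mm, overrides template), `lateral_jitter_mm`,
#'   `chiasm_frac` (relative half-width jitter)
#' @param perturbation a [reader_perturbation()] template for the two
#'   simulated readers
#' @param seed cohort seed; all subject seeds derive from it
#' @return list with `subjects` (each: `subject_id`, `volume`, `gt`,
#'   `r1`, `r2`, `spec`) and `manifest` (data.frame of per-subject
#'   geometry parameters and seeds)
#' @export
make_cohort <- function(n, template = phantom_spec(),
                        variation = list(radius_sd = NULL,
                                         lateral_jitter_mm = 0.5,
                                         chiasm_frac = 0.08),
                        perturbation = reader_perturbation(),
                        seed = 1L) {
  stopifnot(n >= 1)
  radius_sd <- if (is.null(variation$radius_sd)) template$nerve_radius_sd
               else variation$radius_sd
  pars <- with_seed(seed, {
    data.frame(
      subject_id = sprintf("sub-%03d", seq_len(n)),
      seed = sample.int(.Machine$integer.max %/% 4L, n),
      nerve_radius_mm = pmax(0.8, stats::rnorm(n, template$nerve_radius_mm,
                                               radius_sd)),
      chiasm_halfwidth_mm = template$chiasm_halfwidth_mm *
        (1 + stats::rnorm(n, 0, variation$chiasm_frac %||% 0)),
      lateral_jitter_mm = variation$lateral_jitter_mm %||% 0
    )
  })
  subjects <- lapply(seq_len(n), function(i) {
    spec <- template
    spec$seed <- pars$seed[i]
    spec$nerve_radius_mm <- pars$nerve_radius_mm[i]
    spec$chiasm_halfwidth_mm <- pars$chiasm_halfwidth_mm[i]
    spec$lateral_jitter_mm <- pars$lateral_jitter_mm[i]
    ph <- generate_phantom(spec)
    ph$volume$subject_id <- pars$subject_id[i]
    ph$gt$subject_id <- pars$subject_id[i]
    p1 <- perturbation; p1$seed <- spec$seed + 1L
    p2 <- perturbation; p2$seed <- spec$seed + 2L
    list(subject_id = pars$subject_id[i], volume = ph$volume, gt = ph$gt,
         r1 = perturb_reader(ph$gt, p1), r2 = perturb_reader(ph$gt, p2),
         spec = spec)
  })
  names(subjects) <- pars$subject_id
  list(subjects = subjects, manifest = pars)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
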