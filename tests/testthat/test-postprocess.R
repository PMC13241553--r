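# The four anatomical correction operators and their composition.

test_that("remove_clusters keeps exactly the largest component per label", {
  gt <- generate_phantom(tiny_spec(seed = 31))$gt
  # single-component input is untouched
  expect_identical(remove_clusters(gt)$data, gt$data)
  # inject speckles: a 2-voxel cluster of label 1 far from the nerve
  noisy <- gt
  noisy$data[1:2, 1, 1] <- 1L
  noisy$data[1, 3, 1] <- 7L
  out <- remove_clusters(noisy)
  expect_identical(out$data[1:2, 1, 1], c(0L, 0L))
  expect_identical(out$data[1, 3, 1], 0L)
  expect_identical(out$data == 0L, gt$data == 0L | FALSE)
  di <- attr(out, "diagnostics")$removed
  expect_identical(di$ONR_iOrb$voxels, 2L)
})

test_that("surviving component sizes match a flood-fill oracle", {
  set.seed(32)
  for (rep in 1:3) {
    l <- random_labelmap(c(16L, 16L, 16L), k = 3, p = 0.25)
    out <- remove_clusters(l)
    for (id in 1:3) {
      comp <- brute_components(l$data == id, 26L)
      if (max(comp) == 0) next
      expect_identical(sum(out$data == id),
                       max(tabulate(comp[comp > 0L])))
    }
  }
})

test_that("enforce_sides relabels wrong-side components, midline ties stay", {
  gt <- generate_phantom(tiny_spec(seed = 33))$gt
  expect_identical(enforce_sides(gt)$data, gt$data)  # valid anatomy: no-op
  # swap both tract labels: each now sits on the wrong side
  swapped <- gt
  swapped$data[gt$data == 8L] <- 9L
  swapped$data[gt$data == 9L] <- 8L
  fixed <- enforce_sides(swapped)
  expect_identical(fixed$data, gt$data)
  flips <- attr(fixed, "diagnostics")$side_flips
  expect_length(flips, 2)
  # a component centred exactly on the midline is untouched
  d <- c(9L, 9L, 5L)
  lab <- array(0L, d)
  lab[4:6, 4, 2] <- 7L                  # chiasm centroid at x = 5
  lab[4:6, 6, 2] <- 9L                  # OTL centred exactly at x = 5
  l <- avp_labelmap(lab)
  expect_identical(enforce_sides(l)$data, lab)
  # without a chiasm and with no explicit midline, refuse
  noc <- avp_labelmap(array(c(rep(0L, 100), 9L, rep(0L, 24)), c(5, 5, 5)))
  expect_error(enforce_sides(noc), "midline")
  expect_silent(enforce_sides(noc, postprocess_config(midline = 3)))
})

test_that("interpolate_gaps closes small gaps without touching others", {
  # straight tube along x with a one-voxel transverse gap
  d <- c(16L, 8L, 8L)
  lab <- array(0L, d)
  lab[2:14, 4:5, 4:5] <- 1L
  lab[8, 4:5, 4:5] <- 0L
  l <- avp_labelmap(lab)
  ncomp <- function(m) max(avpseg:::cpp_label_components(as.vector(m), dim(m), 26L))
  expect_identical(ncomp(l$data == 1L), 2L)
  out <- interpolate_gaps(l, postprocess_config(closing_len = 5))
  expect_identical(ncomp(out$data == 1L), 1L)
  expect_true(all(out$data[lab == 1L] == 1L))
  # gap-free input unchanged
  full <- avp_labelmap(array(0L, d)); full$data[2:14, 4:5, 4:5] <- 1L
  expect_identical(interpolate_gaps(full,
                                    postprocess_config(closing_len = 5))$data,
                   full$data)
  # another label in the gap is never overwritten
  l2 <- l; l2$data[8, 4, 4] <- 7L
  out2 <- interpolate_gaps(l2, postprocess_config(closing_len = 5))
  expect_identical(out2$data[8, 4, 4], 7L)
})

test_that("filled voxels equal brute-force directional closing on background", {
  d <- c(16L, 8L, 8L)
  lab <- array(0L, d)
  lab[2:14, 4, 4] <- 2L
  lab[c(6, 10), 4, 4] <- 0L
  l <- avp_labelmap(lab)
  cfg <- postprocess_config(closing_len = 5)
  out <- interpolate_gaps(l, cfg)
  # oracle: dilation then erosion with the same line element, by hand
  off <- avpseg:::.line_se_offsets(lab == 2L, 5L)
  shift_or <- function(m, offs) {
    acc <- array(FALSE, dim(m))
    for (r in seq_len(nrow(offs))) {
      src <- which(m, arr.ind = TRUE)
      dst <- sweep(src, 2, -offs[r, ])
      keep <- dst[, 1] >= 1 & dst[, 1] <= d[1] & dst[, 2] >= 1 &
        dst[, 2] <= d[2] & dst[, 3] >= 1 & dst[, 3] <= d[3]
      acc[dst[keep, , drop = FALSE]] <- TRUE
    }
    acc
  }
  dil <- shift_or(lab == 2L, off)
  ero <- !shift_or(!dil, -off)
  fill <- ero & lab == 0L
  expected <- lab
  expected[fill] <- 2L
  expect_identical(out$data, expected)
})

test_that("enforce_continuity bridges short chain gaps and reports long ones", {
  gt <- generate_phantom(tiny_spec(seed = 34))$gt
  expect_identical(enforce_continuity(gt)$data, gt$data)  # connected: no-op
  # cut a 2-voxel gap between intracranial nerve and chiasm
  cut <- gt
  d <- dim(cut$data)
  onc <- cut$data == 7L
  dist <- sqrt(avpseg:::cpp_edt_sq(as.vector(onc), d, cut$spacing))
  near <- cut$data == 3L & array(dist, d) <= 2 * 0.6
  expect_gt(sum(near), 0)
  cut$data[near] <- 0L
  off26 <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  storage.mode(off26) <- "integer"
  adjacent <- function(lab, a, b)
    any(array(avpseg:::cpp_dilate(as.vector(lab == a), d, off26), d) & lab == b)
  expect_false(adjacent(cut$data, 3L, 7L))
  out <- enforce_continuity(cut, postprocess_config(bridge_max_mm = 3))
  expect_true(adjacent(out$data, 3L, 7L))
  br <- attr(out, "diagnostics")$bridges
  expect_true(any(vapply(br, function(b)
    b$from == "ONR_iCran" && b$bridged, logical(1))))
  # a gap longer than the budget is reported, not bridged
  out2 <- enforce_continuity(cut, postprocess_config(bridge_max_mm = 0.5))
  expect_identical(out2$data, cut$data)
  br2 <- attr(out2, "diagnostics")$bridges
  expect_true(any(vapply(br2, function(b) !b$bridged, logical(1))))
})

test_that("postprocess fixes an adversarial fixture and is a GT fixpoint", {
  gt <- generate_phantom(tiny_spec(seed = 35))$gt
  d <- dim(gt$data)
  expect_identical(postprocess(gt)$data, gt$data)   # fixpoint on anatomy
  bad <- gt
  bad$data[1:2, 1:2, 1] <- 3L                        # speckle cluster
  otl <- bad$data == 9L; otr <- bad$data == 8L
  bad$data[otl] <- 8L; bad$data[otr] <- 9L           # swapped tract sides
  mid <- which(bad$data == 2L, arr.ind = TRUE)       # cut canal segment
  cutx <- stats::median(mid[, 2])
  bad$data[bad$data == 2L &
             array(rep(seq_len(d[2]), each = d[1]), d) == cutx] <- 0L
  out <- postprocess(bad)
  # one component per label, no wrong-side components, chains connected
  sc <- avp_label_scheme()
  off26 <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  storage.mode(off26) <- "integer"
  xm <- mean(which(out$data == 7L, arr.ind = TRUE)[, 1])
  for (id in 1:9) {
    m <- out$data == id
    if (!any(m)) next
    expect_lte(max(avpseg:::cpp_label_components(as.vector(m), d, 26L)), 1L)
    nm <- sc$names[[as.character(id)]]
    cx <- mean(which(m, arr.ind = TRUE)[, 1])
    if (sc$side[[nm]] == "right") expect_gte(cx, xm)
    if (sc$side[[nm]] == "left") expect_lte(cx, xm)
  }
  adjacent <- function(lab, a, b)
    any(array(avpseg:::cpp_dilate(as.vector(lab == a), d, off26), d) & lab == b)
  for (side in names(sc$chains)) {
    ch <- label_id(sc, sc$chains[[side]])
    for (i in seq_len(length(ch) - 1))
      expect_true(adjacent(out$data, ch[i], ch[i + 1]))
  }
})

test_that("postprocess is idempotent on perturbed random inputs", {
  set.seed(36)
  gt <- generate_phantom(tiny_spec(seed = 37))$gt
  for (rep in 1:20) {
    x <- perturb_reader(gt, reader_perturbation(seed = rep * 7L))
    # sprinkle speckle noise
    idx <- sample(length(x$data), 5)
    x$data[idx] <- sample(0:9, 5, replace = TRUE)
    once <- postprocess(x)
    twice <- postprocess(once)
    expect_identical(twice$data, once$data)
    # scheme validity always holds
    expect_true(all(once$data %in% 0:9))
  }
})

test_that("foreground growth is bounded and stages are non-invasive", {
  gt <- generate_phantom(tiny_spec(seed = 38))$gt
  x <- perturb_reader(gt, reader_perturbation(seed = 40))
  cfg <- postprocess_config()
  out <- postprocess(x, cfg)
  # growth budget: fills bounded by the structuring element / bridges
  grown <- sum(out$data != 0L & x$data == 0L)
  fg <- sum(x$data != 0L)
  expect_lt(grown, 0.5 * fg)
  # non-invasiveness: the largest component of an untouched healthy label
  # is never relabelled by cleanup of other labels
  keep <- remove_clusters(x, cfg)
  main7 <- keep$data == 7L
  expect_true(all(out$data[main7] == 7L))
})
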