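# Network architectures and loss functions.

test_that("principal network satisfies the shape and normalization contract", {
  cfg <- network_config(base_width = 4, depth = 3, num_classes = 10,
                        res2_scale = 4)
  net <- build_principal(cfg, seed = 1)
  x <- array(stats::rnorm(32 * 32 * 16), c(32, 32, 16, 1))
  fw <- net_forward(net, x)
  expect_identical(dim(fw$main), c(32L, 32L, 16L, 10L))
  expect_identical(dim(fw$aux), c(16L, 16L, 8L, 10L))   # 1/2 resolution
  p <- softmax_classes(fw$main)
  expect_lt(max(abs(rowSums(matrix(p, ncol = 10)) - 1)), 1e-6)
  # inference is deterministic: identical weights and input, identical out
  fw2 <- net_forward(net, x)
  expect_identical(fw$main, fw2$main)
  # indivisible spatial shape is rejected
  expect_error(net_forward(net, array(0, c(30, 32, 16, 1))), "divisible")
})

test_that("refinement network is lightweight and robust to zeroed input", {
  net <- build_refinement(num_classes = 10, seed = 2)
  principal <- build_principal(network_config(), seed = 1)
  expect_lt(count_params(net), count_params(principal))
  x <- array(stats::rnorm(16 * 16 * 8 * 11), c(16, 16, 8, 11))
  fw <- net_forward(net, x)
  expect_identical(dim(fw$main), c(16L, 16L, 8L, 10L))
  expect_null(fw$aux)
  # zeroed segmentation channels still yield a valid normalized output
  x0 <- x; x0[, , , 2:11] <- 0
  p <- softmax_classes(net_forward(net, x0)$main)
  expect_true(all(is.finite(p)))
  expect_lt(max(abs(rowSums(matrix(p, ncol = 10)) - 1)), 1e-6)
  expect_error(build_refinement(network_config(in_channels = 5)),
               "refinement input")
})

test_that("dice_loss matches its definition and closed-form oracle", {
  # perfect prediction: loss below the smoothing scale
  d <- c(4L, 4L, 4L); K <- 10L
  target <- array(0L, d); target[1:8] <- 1L
  onehot <- array(0, c(d, K))
  for (c in 0:(K - 1)) onehot[, , , c + 1] <- as.numeric(target == c)
  expect_lt(dice_loss(onehot, target), 1e-4)
  # uniform prediction vs a single-class foreground: brute-force scalar sum
  unif <- array(1 / K, c(d, K))
  eps <- 1e-5
  expected_dice <- vapply(1:(K - 1), function(c) {
    tc <- as.numeric(target == c)
    (2 * sum(tc / K) + eps) / (sum(rep(1 / K, 64)) + sum(tc) + eps)
  }, numeric(1))
  expect_equal(dice_loss(unif, target), 1 - mean(expected_dice),
               tolerance = 1e-12)
  # consistent permutation of foreground labels leaves the loss unchanged
  perm <- c(0L, sample(1:9))
  t2 <- array(perm[target + 1L], d)
  o2 <- onehot * 0
  for (c in 0:9) o2[, , , perm[c + 1L] + 1L] <- onehot[, , , c + 1L]
  noisy <- 0.6 * onehot + 0.4 / K
  n2 <- 0.6 * o2 + 0.4 / K
  expect_equal(dice_loss(noisy, target), dice_loss(n2, t2),
               tolerance = 1e-12)
  # non-normalized probabilities are rejected
  expect_error(dice_loss(onehot * 1.2, target), "not normalized")
})

test_that("dice_loss gradient matches finite differences", {
  set.seed(4)
  d <- c(4L, 4L, 2L); K <- 4L
  target <- array(sample(0:(K - 1), prod(d), TRUE), d)
  logits <- array(stats::rnorm(prod(d) * K), c(d, K))
  p <- softmax_classes(logits)
  w <- array(stats::runif(prod(d), 1, 3), d)
  g <- dice_loss(p, target, weights = w, grad = TRUE)$grad
  for (j in sample(length(p), 8)) {
    h <- 1e-7
    pp <- p; pp[j] <- pp[j] + h
    pm <- p; pm[j] <- pm[j] - h
    num <- (dice_loss(pp, target, weights = w) -
              dice_loss(pm, target, weights = w)) / (2 * h)
    expect_equal(g[j], num, tolerance = 1e-4)
  }
})

test_that("translating prediction and target together leaves dice_loss fixed", {
  set.seed(5)
  d <- c(12L, 12L, 8L); K <- 3L
  # pattern living on a 6x6x4 interior block
  blk_t <- array(sample(0:(K - 1), 6 * 6 * 4, TRUE), c(6L, 6L, 4L))
  blk_p <- softmax_classes(array(stats::rnorm(6 * 6 * 4 * K),
                                 c(6L, 6L, 4L, K)))
  embed <- function(off) {
    p <- array(1 / K, c(d, K))
    t <- array(0L, d)
    xi <- off[1] + 1:6; yi <- off[2] + 1:6; zi <- off[3] + 1:4
    p[xi, yi, zi, ] <- blk_p
    t[xi, yi, zi] <- blk_t
    # interior crop around the embedded block
    list(p = p[xi, yi, zi, , drop = FALSE], t = t[xi, yi, zi])
  }
  a <- embed(c(1L, 2L, 1L))
  b <- embed(c(4L, 3L, 2L))
  expect_lt(abs(dice_loss(a$p, a$t) - dice_loss(b$p, b$t)), 1e-6)
})

test_that("boundary_weight_map follows the exponential-decay definition", {
  # uniform map: no boundaries, all weights exactly 1
  expect_true(all(boundary_weight_map(array(3L, c(5, 5, 5))) == 1))
  # two-block map on 8^3: compare with all-pairs brute-force distances
  lab <- array(0L, c(8L, 8L, 8L)); lab[1:4, , ] <- 1L
  w_max <- 5; tau <- 2
  w <- boundary_weight_map(lab, w_max = w_max, tau = tau)
  boundary <- array(FALSE, dim(lab))
  for (i in seq_along(lab)) {
    v <- arrayInd(i, dim(lab))
    for (o in list(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
                   c(0, 0, 1), c(0, 0, -1))) {
      u <- v + o
      if (all(u >= 1) && all(u <= dim(lab)) &&
          lab[u[1], u[2], u[3]] != lab[i]) boundary[i] <- TRUE
    }
  }
  bidx <- which(boundary, arr.ind = TRUE)
  for (i in sample(length(lab), 40)) {
    v <- arrayInd(i, dim(lab))
    dmin <- sqrt(min(rowSums(sweep(bidx, 2, v)^2)))
    expect_equal(w[i], 1 + (w_max - 1) * exp(-dmin / tau),
                 tolerance = 1e-12)
  }
  expect_true(all(w[boundary] == w_max))   # d = 0 on the boundary
})

test_that("boundary weighting reduces to plain dice and penalizes edges", {
  set.seed(6)
  d <- c(8L, 8L, 8L); K <- 3L
  target <- array(0L, d); target[3:6, 3:6, 3:6] <- 1L
  logits <- array(stats::rnorm(prod(d) * K), c(d, K))
  p <- softmax_classes(logits)
  w1 <- array(1, d)
  expect_equal(boundary_weighted_dice_loss(p, target, w1),
               dice_loss(p, target), tolerance = 1e-9)
  # an error voxel on the boundary hurts more than the same error inside
  onehot <- array(0, c(d, K))
  for (c in 0:(K - 1)) onehot[, , , c + 1] <- as.numeric(target == c)
  soft <- 0.98 * onehot + 0.02 / K
  w <- boundary_weight_map(target, w_max = 5, tau = 2)
  flip <- function(px, v) {
    # move the target-class mass (class 1) onto class 2 at one voxel
    px[v[1], v[2], v[3], ] <- px[v[1], v[2], v[3], c(1, 3, 2)]
    px
  }
  l_edge <- boundary_weighted_dice_loss(flip(soft, c(3, 3, 3)), target, w)
  l_core <- boundary_weighted_dice_loss(flip(soft, c(5, 5, 5)), target, w)
  expect_gt(l_edge, l_core)
  # perfect prediction stays near zero regardless of weights
  expect_lt(boundary_weighted_dice_loss(onehot, target, w), 1e-3)
})

test_that("deep supervision combines main and auxiliary terms", {
  set.seed(7)
  d <- c(8L, 8L, 8L); K <- 3L
  target <- array(sample(0:(K - 1), prod(d), TRUE), d)
  main <- softmax_classes(array(stats::rnorm(prod(d) * K), c(d, K)))
  aux <- softmax_classes(array(stats::rnorm(prod(d) * K / 8),
                               c(d %/% 2L, K)))
  # lambda = 0 recovers the main loss exactly
  expect_identical(deep_supervision_loss(main, aux, target, lambda_aux = 0),
                   dice_loss(main, target))
  # scalar recomputation oracle
  taux <- target[seq(1, 8, 2), seq(1, 8, 2), seq(1, 8, 2)]
  expect_equal(deep_supervision_loss(main, aux, target, lambda_aux = 0.4),
               dice_loss(main, target) + 0.4 * dice_loss(aux, taux),
               tolerance = 1e-12)
  # perfect main and aux stay below (1 + lambda) * eps scale
  oh <- array(0, c(d, K)); oha <- array(0, c(d %/% 2L, K))
  for (c in 0:(K - 1)) {
    oh[, , , c + 1] <- as.numeric(target == c)
    oha[, , , c + 1] <- as.numeric(taux == c)
  }
  expect_lt(deep_supervision_loss(oh, oha, target, lambda_aux = 0.4), 1e-3)
})

test_that("a training step decreases the loss (gradient-flow smoke)", {
  ph <- generate_phantom(phantom_spec(shape = c(16L, 16L, 8L),
                                      chiasm_halfwidth_mm = 2,
                                      tract_length_mm = 4,
                                      nerve_radius_mm = 1.0, seed = 12))
  cfg <- network_config(base_width = 4, depth = 2, res2_scale = 2)
  net <- build_principal(cfg, seed = 3)
  x <- array(normalize_intensity(ph$volume)$data, c(16, 16, 8, 1))
  lg <- avpseg:::.train_one_net(net, list(s = x), list(s = ph$gt$data),
                                epochs = 4, lr = 1e-2)
  expect_lt(lg$loss[4], lg$loss[1])
})

test_that("helpful segmentation input trains to lower loss than zeros", {
  ph <- generate_phantom(phantom_spec(shape = c(16L, 16L, 8L),
                                      chiasm_halfwidth_mm = 2,
                                      tract_length_mm = 4,
                                      nerve_radius_mm = 1.0, seed = 13))
  x <- array(normalize_intensity(ph$volume)$data, c(16, 16, 8, 1))
  onehot <- array(0, c(16, 16, 8, 10))
  for (c in 0:9) onehot[, , , c + 1] <- as.numeric(ph$gt$data == c)
  run_ref <- function(seg) {
    net <- build_refinement(num_classes = 10, seed = 4)
    inp <- avpseg:::.concat_c(x, seg)
    lg <- avpseg:::.train_one_net(net, list(s = inp), list(s = ph$gt$data),
                                  epochs = 3, lr = 1e-2, lambda_aux = 0)
    tail(lg$loss, 1)
  }
  expect_lt(run_ref(onehot), run_ref(onehot * 0))
})

test_that("checkpoints round-trip through save_net/load_net", {
  cfg <- network_config(base_width = 4, depth = 2, res2_scale = 2)
  net <- build_principal(cfg, seed = 8)
  x <- array(stats::rnorm(16 * 16 * 8), c(16, 16, 8, 1))
  y1 <- net_forward(net, x)$main
  tmp <- withr::local_tempdir()
  save_net(net, file.path(tmp, "net.rds"))
  net2 <- load_net(file.path(tmp, "net.rds"))
  expect_equal(net_forward(net2, x)$main, y1, tolerance = 1e-12)
  expect_true(file.exists(file.path(tmp, "net_config.json")))
})
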