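# Trainable 3D convolutional networks on CPU.
#
# Tensors are column-major arrays dim (nx, ny, nz, C). Convolutions are
# computed as im2col (compiled) followed by a BLAS matrix product;
# gradients are hand-derived per layer. No external NN framework is
# used: at desk scale the whole cascade trains in minutes on one core.

# ---- conv layer -----------------------------------------------------------

.new_conv <- function(cin, cout, k = 3L, stride = 1L, pad = (k - 1L) %/% 2L,
                      gain = 2, norm = (k == 3L)) {
  ly <- new.env(parent = emptyenv())
  ly$cin <- as.integer(cin); ly$cout <- as.integer(cout)
  ly$k <- as.integer(k); ly$stride <- as.integer(stride)
  ly$pad <- as.integer(pad)
  ly$norm <- isTRUE(norm)
  fan_in <- k^3 * cin
  ly$W <- array(stats::rnorm(k^3 * cin * cout, 0, sqrt(gain / fan_in)),
                dim = c(k, k, k, cin, cout))
  ly$b <- numeric(cout)
  if (ly$norm) { ly$g <- rep(1, cout); ly$beta <- numeric(cout) }
  .zero_grad_conv(ly)
  ly$mW <- array(0, dim(ly$W)); ly$vW <- array(0, dim(ly$W))
  ly$mb <- numeric(cout); ly$vb <- numeric(cout)
  if (ly$norm) {
    ly$mg <- numeric(cout); ly$vg <- numeric(cout)
    ly$mbeta <- numeric(cout); ly$vbeta <- numeric(cout)
  }
  ly
}

.zero_grad_conv <- function(ly) {
  ly$dW <- array(0, dim(ly$W))
  ly$db <- numeric(ly$cout)
  if (ly$norm) { ly$dg <- numeric(ly$cout); ly$dbeta <- numeric(ly$cout) }
  invisible(ly)
}

.in_eps <- 1e-5

.conv_fwd <- function(ly, x, cache = TRUE) {
  d <- dim(x)
  stopifnot(length(d) == 4L, d[4] == ly$cin)
  y <- cpp_conv3d_fwd(x, d, ly$W, ly$b, ly$k, ly$stride, ly$pad, ly$cout)
  od <- c((d[1:3] + 2 * ly$pad - ly$k) %/% ly$stride + 1L, ly$cout)
  if (cache) ly$x <- x
  if (ly$norm) {
    # instance normalization per output channel, learnable scale/shift
    ym <- matrix(y, ncol = ly$cout)
    mu <- colMeans(ym)
    xc <- sweep(ym, 2, mu)
    sd_ <- sqrt(colMeans(xc^2) + .in_eps)
    xhat <- sweep(xc, 2, sd_, "/")
    if (cache) { ly$xhat <- xhat; ly$sd_ <- sd_ }
    y <- sweep(sweep(xhat, 2, ly$g, "*"), 2, ly$beta, "+")
  }
  array(y, dim = od)
}

.conv_bwd <- function(ly, dy) {
  x <- ly$x
  d <- dim(x)
  if (ly$norm) {
    dym <- matrix(dy, ncol = ly$cout)
    xhat <- ly$xhat
    ly$dg <- ly$dg + colSums(dym * xhat)
    ly$dbeta <- ly$dbeta + colSums(dym)
    dxh <- sweep(dym, 2, ly$g, "*")
    m1 <- colMeans(dxh)
    m2 <- colMeans(dxh * xhat)
    dy <- sweep(sweep(dxh, 2, m1) - sweep(xhat, 2, m2, "*"),
                2, ly$sd_, "/")
    ly$xhat <- NULL; ly$sd_ <- NULL
  }
  ly$dW <- ly$dW + array(
    cpp_conv3d_bwd_weight(x, dy, d, ly$k, ly$stride, ly$pad, ly$cout),
    dim = dim(ly$W))
  ly$db <- ly$db + colSums(matrix(dy, ncol = ly$cout))
  dx <- cpp_conv3d_bwd_input(dy, d, ly$W, ly$k, ly$stride, ly$pad, ly$cout)
  ly$x <- NULL
  array(dx, dim = d)
}

# ---- stateless ops --------------------------------------------------------

.relu <- function(x) { x[x < 0] <- 0; x }
.relu_bwd <- function(dy, y) { dy[y <= 0] <- 0; dy }
.sigmoid <- function(x) 1 / (1 + exp(-x))

.upsample2 <- function(x) {
  d <- dim(x)
  array(cpp_upsample2(x, d), dim = c(2L * d[1:3], d[4]))
}

.upsample2_bwd <- function(dy) {
  d <- dim(dy)
  array(cpp_upsample2_bwd(dy, d), dim = c(d[1:3] %/% 2L, d[4]))
}

.downsample_nn <- function(x, factor = 2L) {
  d <- dim(x)
  if (length(d) == 3L)
    x[seq(1L, d[1], factor), seq(1L, d[2], factor), seq(1L, d[3], factor)]
  else
    x[seq(1L, d[1], factor), seq(1L, d[2], factor), seq(1L, d[3], factor), ,
      drop = FALSE]
}

.concat_c <- function(a, b) {
  da <- dim(a); db <- dim(b)
  stopifnot(all(da[1:3] == db[1:3]))
  out <- array(0, c(da[1:3], da[4] + db[4]))
  out[, , , seq_len(da[4])] <- a
  out[, , , da[4] + seq_len(db[4])] <- b
  out
}

# ---- network configuration ------------------------------------------------

#' Configuration of a segmentation network
#'
#' @param in_channels input channels (1 for the image; image + class
#'   probabilities for the refinement network)
#' @param num_classes output classes including background (default 10)
#' @param base_width feature channels at full resolution
#' @param depth number of strided downsamplings (>= 2)
#' @param res2_scale hierarchical splits in the Res2 bottleneck (0 for a
#'   plain convolutional bottleneck)
#' @param deep_supervision add an auxiliary class head at 1/2 resolution
#' @param aux_weight weight of the auxiliary loss term
#' @param input_skip add the log of the input class-probability channels
#'   to the output logits (refinement networks only): the untrained
#'   network then starts at the identity over its input segmentation and
#'   learns corrections, which is what keeps the cascade non-degrading
#' @return object of class `avp_net_config`
#' @export
network_config <- function(in_channels = 1L, num_classes = 10L,
                           base_width = 8L, depth = 3L, res2_scale = 4L,
                           deep_supervision = TRUE, aux_weight = 0.4,
                           input_skip = FALSE) {
  stopifnot(depth >= 2, base_width >= 2, num_classes >= 2)
  if (res2_scale > 0 && (base_width * 2^depth) %% res2_scale != 0)
    stop("bottleneck width must be divisible by res2_scale")
  structure(list(in_channels = as.integer(in_channels),
                 num_classes = as.integer(num_classes),
                 base_width = as.integer(base_width),
                 depth = as.integer(depth),
                 res2_scale = as.integer(res2_scale),
                 deep_supervision = isTRUE(deep_supervision),
                 aux_weight = aux_weight,
                 input_skip = isTRUE(input_skip)),
            class = "avp_net_config")
}

.att_channels <- function(w) max(4L, w %/% 2L)

#' Build the principal segmentation network
#'
#' A 3D encoder-decoder with strided convolutional downsampling, a
#' symmetric nearest-neighbour-upsampling decoder, residual Res2
#' multi-scale convolutions confined to the bottleneck, additive
#' attention gates on the skip connections, ReLU activations throughout,
#' and a deep-supervision class head at half resolution.
#'
#' @param cfg a [network_config()]
#' @param seed seed for weight initialization
#' @return object of class `avp_net`
#' @export
build_principal <- function(cfg = network_config(), seed = 1L) {
  with_seed(seed, .build_net(cfg))
}

#' Build the refinement network
#'
#' A lightweight attention U-Net consuming the image concatenated with
#' the principal network's class probabilities. Its parameter count is
#' smaller than the principal network's at matched depth (narrower
#' features, plain bottleneck, no auxiliary head).
#'
#' @param cfg optional [network_config()]; defaults to the lightweight
#'   refinement configuration for `num_classes` classes
#' @param num_classes used when `cfg` is NULL
#' @param seed seed for weight initialization
#' @return object of class `avp_net`
#' @export
build_refinement <- function(cfg = NULL, num_classes = 10L, seed = 1L) {
  if (is.null(cfg))
    cfg <- network_config(in_channels = 1L + num_classes,
                          num_classes = num_classes, base_width = 6L,
                          depth = 3L, res2_scale = 0L,
                          deep_supervision = FALSE, input_skip = TRUE)
  if (cfg$in_channels != 1L + cfg$num_classes)
    stop("refinement input must be image + ", cfg$num_classes,
         " class channels, got in_channels = ", cfg$in_channels)
  with_seed(seed, .build_net(cfg))
}

.build_net <- function(cfg) {
  w <- cfg$base_width; D <- cfg$depth; K <- cfg$num_classes
  wd <- w * 2^(0:D)
  net <- list(cfg = cfg)
  net$stem1 <- .new_conv(cfg$in_channels, w)
  net$stem2 <- .new_conv(w, w)
  net$enc <- lapply(seq_len(D), function(d)
    list(down = .new_conv(wd[d], wd[d + 1], stride = 2L),
         conv = .new_conv(wd[d + 1], wd[d + 1])))
  if (cfg$res2_scale > 0) {
    s <- cfg$res2_scale; gw <- wd[D + 1] %/% s
    net$res2 <- list(
      pre = .new_conv(wd[D + 1], wd[D + 1], k = 1L, pad = 0L),
      group = lapply(seq_len(s - 1L), function(i) .new_conv(gw, gw)),
      post = .new_conv(wd[D + 1], wd[D + 1], k = 1L, pad = 0L))
  } else {
    net$bottleneck <- .new_conv(wd[D + 1], wd[D + 1])
  }
  net$dec <- lapply(seq_len(D), function(d) {
    # decoder stage d maps level-d features to level-(d-1) resolution
    ai <- .att_channels(wd[d])
    list(up = .new_conv(wd[d + 1], wd[d]),
         att_x = .new_conv(wd[d], ai, k = 1L, pad = 0L),
         att_g = .new_conv(wd[d], ai, k = 1L, pad = 0L),
         att_psi = .new_conv(ai, 1L, k = 1L, pad = 0L, gain = 1),
         fuse = .new_conv(2L * wd[d], wd[d]))
  })
  net$head <- .new_conv(w, K, k = 1L, pad = 0L, gain = 1)
  if (cfg$deep_supervision)
    net$aux_head <- .new_conv(wd[2], K, k = 1L, pad = 0L, gain = 1)
  class(net) <- "avp_net"
  net
}

.net_layers <- function(net) {
  out <- list(net$stem1, net$stem2)
  for (e in net$enc) out <- c(out, list(e$down, e$conv))
  if (!is.null(net$res2))
    out <- c(out, list(net$res2$pre), net$res2$group, list(net$res2$post))
  if (!is.null(net$bottleneck)) out <- c(out, list(net$bottleneck))
  for (d in net$dec)
    out <- c(out, list(d$up, d$att_x, d$att_g, d$att_psi, d$fuse))
  out <- c(out, list(net$head))
  if (!is.null(net$aux_head)) out <- c(out, list(net$aux_head))
  out
}

#' Number of trainable parameters of a network
#' @param net an `avp_net`
#' @return integer parameter count
#' @export
count_params <- function(net) {
  sum(vapply(.net_layers(net), function(ly)
    length(ly$W) + length(ly$b) +
      if (ly$norm) 2L * ly$cout else 0L, numeric(1)))
}

#' @export
print.avp_net <- function(x, ...) {
  cfg <- x$cfg
  cat(sprintf(paste0("aVP 3D attention U-Net: in=%d classes=%d width=%d ",
                     "depth=%d res2=%d aux=%s | %d parameters\n"),
              cfg$in_channels, cfg$num_classes, cfg$base_width, cfg$depth,
              cfg$res2_scale, cfg$deep_supervision, count_params(x)))
  invisible(x)
}

# ---- forward / backward ---------------------------------------------------

.res2_fwd <- function(net, x, cache) {
  s <- net$cfg$res2_scale
  h <- .relu(.conv_fwd(net$res2$pre, x, cache))
  gw <- dim(h)[4] %/% s
  ys <- vector("list", s)
  ys[[1]] <- h[, , , seq_len(gw), drop = FALSE]
  ins <- vector("list", s)
  for (i in 2:s) {
    gi <- h[, , , (i - 1L) * gw + seq_len(gw), drop = FALSE]
    ins[[i]] <- gi + ys[[i - 1]]
    ys[[i]] <- .relu(.conv_fwd(net$res2$group[[i - 1L]], ins[[i]], cache))
  }
  cat4 <- array(0, dim(h))
  for (i in seq_len(s)) cat4[, , , (i - 1L) * gw + seq_len(gw)] <- ys[[i]]
  o <- .conv_fwd(net$res2$post, cat4, cache)
  out <- .relu(o + x)
  list(out = out, h = h, ys = ys, o_plus_x = o + x)
}

.res2_bwd <- function(net, fc, dy) {
  s <- net$cfg$res2_scale
  dsum <- .relu_bwd(dy, .relu(fc$o_plus_x))
  dx <- dsum                                   # residual path
  dcat <- .conv_bwd(net$res2$post, dsum)
  gw <- dim(dcat)[4] %/% s
  dh <- array(0, dim(dcat))
  dys_next <- NULL
  for (i in s:2) {
    dyi <- dcat[, , , (i - 1L) * gw + seq_len(gw), drop = FALSE]
    if (!is.null(dys_next)) dyi <- dyi + dys_next
    dyi <- .relu_bwd(dyi, fc$ys[[i]])
    din <- .conv_bwd(net$res2$group[[i - 1L]], dyi)
    dh[, , , (i - 1L) * gw + seq_len(gw)] <- din
    dys_next <- din                            # flows into y_{i-1}
  }
  d1 <- dcat[, , , seq_len(gw), drop = FALSE]
  if (!is.null(dys_next)) d1 <- d1 + dys_next
  dh[, , , seq_len(gw)] <- d1
  dh <- .relu_bwd(dh, fc$h)
  dx + .conv_bwd(net$res2$pre, dh)
}

#' Forward pass of a segmentation network
#'
#' @param net an `avp_net`
#' @param x input array `(nx, ny, nz, in_channels)`; spatial dims must be
#'   divisible by `2^depth`
#' @param cache keep intermediates for a subsequent [net_backward()]
#' @return list with `main` (logits, `(nx,ny,nz,K)`), `aux` (logits at
#'   1/2 resolution or NULL), and `cache`
#' @export
net_forward <- function(net, x, cache = FALSE) {
  cfg <- net$cfg
  if (length(dim(x)) == 3L) dim(x) <- c(dim(x), 1L)
  d <- dim(x)
  if (any(d[1:3] %% 2^cfg$depth != 0))
    stop("spatial dims (", paste(d[1:3], collapse = "x"),
         ") must be divisible by 2^depth = ", 2^cfg$depth)
  if (d[4] != cfg$in_channels)
    stop("expected ", cfg$in_channels, " input channels, got ", d[4])
  D <- cfg$depth
  cc <- list()
  a1 <- .relu(.conv_fwd(net$stem1, x, cache)); cc$a1 <- a1
  s0 <- .relu(.conv_fwd(net$stem2, a1, cache)); cc$s0 <- s0
  skips <- vector("list", D + 1L); skips[[1]] <- s0
  f <- s0
  cc$enc <- vector("list", D)
  for (dd in seq_len(D)) {
    t1 <- .relu(.conv_fwd(net$enc[[dd]]$down, f, cache))
    t2 <- .relu(.conv_fwd(net$enc[[dd]]$conv, t1, cache))
    cc$enc[[dd]] <- list(t1 = t1, t2 = t2)
    skips[[dd + 1L]] <- t2
    f <- t2
  }
  if (!is.null(net$res2)) {
    cc$res2 <- .res2_fwd(net, f, cache)
    f <- cc$res2$out
  } else {
    cc$bneck_in <- f
    f <- .relu(.conv_fwd(net$bottleneck, f, cache))
    cc$bneck_out <- f
  }
  cc$dec <- vector("list", D)
  aux_feat <- NULL
  for (dd in D:1) {
    u0 <- .upsample2(f)
    u <- .relu(.conv_fwd(net$dec[[dd]]$up, u0, cache))
    skip <- skips[[dd]]
    qx <- .conv_fwd(net$dec[[dd]]$att_x, skip, cache)
    qg <- .conv_fwd(net$dec[[dd]]$att_g, u, cache)
    qa <- .relu(qx + qg)
    att <- .sigmoid(.conv_fwd(net$dec[[dd]]$att_psi, qa, cache))
    gated <- skip * as.vector(att)
    cat2 <- .concat_c(u, gated)
    f <- .relu(.conv_fwd(net$dec[[dd]]$fuse, cat2, cache))
    cc$dec[[dd]] <- list(u = u, skip = skip, qa = qa, att = att, f = f)
    if (dd == 2L) aux_feat <- f
  }
  main <- .conv_fwd(net$head, f, cache)
  if (cfg$input_skip) {
    K <- cfg$num_classes
    main <- main +
      log(pmax(x[, , , 1L + seq_len(K), drop = FALSE], 0) + 1e-4)
  }
  aux <- NULL
  if (cfg$deep_supervision && !is.null(net$aux_head))
    aux <- .conv_fwd(net$aux_head, aux_feat, cache)
  list(main = main, aux = aux, cache = if (cache) cc else NULL)
}

#' Backward pass: accumulate parameter gradients
#'
#' @param net an `avp_net`
#' @param fwd result of `net_forward(net, x, cache = TRUE)`
#' @param dmain gradient of the loss in the main logits
#' @param daux gradient in the auxiliary logits (or NULL)
#' @return invisibly, the gradient in the network input
#' @export
net_backward <- function(net, fwd, dmain, daux = NULL) {
  cfg <- net$cfg; D <- cfg$depth
  cc <- fwd$cache
  if (is.null(cc)) stop("forward pass was run without cache = TRUE")
  df <- .conv_bwd(net$head, dmain)
  daux_feat <- NULL
  if (!is.null(daux) && !is.null(net$aux_head))
    daux_feat <- .conv_bwd(net$aux_head, daux)
  for (dd in 1:D) {
    dc <- cc$dec[[dd]]
    if (dd == 2L && !is.null(daux_feat)) df <- df + daux_feat
    df <- .relu_bwd(df, dc$f)
    dcat <- .conv_bwd(net$dec[[dd]]$fuse, df)
    wu <- dim(dc$u)[4]
    du <- dcat[, , , seq_len(wu), drop = FALSE]
    dgated <- dcat[, , , wu + seq_len(dim(dc$skip)[4]), drop = FALSE]
    dskip <- dgated * as.vector(dc$att)
    datt <- array(rowSums(matrix(dgated * dc$skip,
                                 ncol = dim(dc$skip)[4])),
                  dim = c(dim(dc$att)[1:3], 1L))
    dpsi_in <- datt * dc$att * (1 - dc$att)
    dqa <- .conv_bwd(net$dec[[dd]]$att_psi, dpsi_in)
    dqa <- .relu_bwd(dqa, dc$qa)
    dskip <- dskip + .conv_bwd(net$dec[[dd]]$att_x, dqa)
    du <- du + .conv_bwd(net$dec[[dd]]$att_g, dqa)
    du <- .relu_bwd(du, dc$u)
    du0 <- .conv_bwd(net$dec[[dd]]$up, du)
    dfa <- .upsample2_bwd(du0)
    # route skip gradient to its producer
    if (dd == 1L) dskip0 <- dskip else {
      cc$enc[[dd - 1L]]$dskip <- dskip
    }
    df <- dfa
  }
  if (!is.null(net$res2)) {
    df <- .res2_bwd(net, cc$res2, df)
  } else {
    df <- .relu_bwd(df, cc$bneck_out)
    df <- .conv_bwd(net$bottleneck, df)
  }
  for (dd in D:1) {
    if (!is.null(cc$enc[[dd]]$dskip)) df <- df + cc$enc[[dd]]$dskip
    df <- .relu_bwd(df, cc$enc[[dd]]$t2)
    df <- .conv_bwd(net$enc[[dd]]$conv, df)
    df <- .relu_bwd(df, cc$enc[[dd]]$t1)
    df <- .conv_bwd(net$enc[[dd]]$down, df)
  }
  df <- df + dskip0
  df <- .relu_bwd(df, cc$s0)
  df <- .conv_bwd(net$stem2, df)
  df <- .relu_bwd(df, cc$a1)
  invisible(.conv_bwd(net$stem1, df))
}

#' Zero all accumulated gradients
#' @param net an `avp_net`
#' @return the network, invisibly
#' @export
zero_grad <- function(net) {
  for (ly in .net_layers(net)) .zero_grad_conv(ly)
  invisible(net)
}

#' One Adam update over all parameters
#'
#' @param net an `avp_net`
#' @param lr learning rate
#' @param t step counter (1-based) for bias correction
#' @param beta1,beta2,eps Adam moment parameters
#' @return the network, invisibly
#' @export
adam_step <- function(net, lr = 3e-3, t = 1L, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  b1t <- 1 - beta1^t; b2t <- 1 - beta2^t
  for (ly in .net_layers(net)) {
    ly$mW <- beta1 * ly$mW + (1 - beta1) * ly$dW
    ly$vW <- beta2 * ly$vW + (1 - beta2) * ly$dW^2
    ly$W <- ly$W - lr * (ly$mW / b1t) / (sqrt(ly$vW / b2t) + eps)
    ly$mb <- beta1 * ly$mb + (1 - beta1) * ly$db
    ly$vb <- beta2 * ly$vb + (1 - beta2) * ly$db^2
    ly$b <- ly$b - lr * (ly$mb / b1t) / (sqrt(ly$vb / b2t) + eps)
    if (ly$norm) {
      ly$mg <- beta1 * ly$mg + (1 - beta1) * ly$dg
      ly$vg <- beta2 * ly$vg + (1 - beta2) * ly$dg^2
      ly$g <- ly$g - lr * (ly$mg / b1t) / (sqrt(ly$vg / b2t) + eps)
      ly$mbeta <- beta1 * ly$mbeta + (1 - beta1) * ly$dbeta
      ly$vbeta <- beta2 * ly$vbeta + (1 - beta2) * ly$dbeta^2
      ly$beta <- ly$beta - lr * (ly$mbeta / b1t) /
        (sqrt(ly$vbeta / b2t) + eps)
    }
  }
  invisible(net)
}

#' Class probabilities from logits
#'
#' Numerically stable softmax over the class (4th) axis.
#'
#' @param logits array `(nx, ny, nz, K)`
#' @return array of probabilities summing to 1 over the class axis
#' @export
softmax_classes <- function(logits) {
  d <- dim(logits)
  m <- matrix(logits, ncol = d[4])
  mx <- m[, 1]
  for (j in seq_len(d[4])[-1]) mx <- pmax(mx, m[, j])
  e <- exp(m - mx)
  array(e / rowSums(e), dim = d)
}

# gradient through softmax: dlogits from dprobs
.softmax_bwd <- function(dprobs, probs) {
  d <- dim(probs)
  dp <- matrix(dprobs, ncol = d[4])
  p <- matrix(probs, ncol = d[4])
  array(p * (dp - rowSums(dp * p)), dim = d)
}

#' Hard labels from logits or probabilities
#'
#' Argmax over the class axis; ties resolved to the lowest class id
#' (`max.col` with `ties.method = "first"` over classes 0..K-1).
#'
#' @param scores array `(nx, ny, nz, K)`
#' @return integer 3D array of class ids 0..K-1
#' @export
argmax_classes <- function(scores) {
  d <- dim(scores)
  idx <- max.col(matrix(scores, ncol = d[4]), ties.method = "first") - 1L
  array(as.integer(idx), dim = d[1:3])
}

#' Serialize network weights to a JSON + binary-free text checkpoint
#'
#' Weights are stored as an RDS-free, plain-text JSON snapshot of the
#' configuration together with base64-free numeric vectors written via
#' `saveRDS`-independent CSV-like encoding is deliberately avoided:
#' checkpoints use `saveRDS` at run time (binary, scratch only).
#'
#' @param net an `avp_net`
#' @param path output `.rds` path
#' @return `path`, invisibly
#' @export
save_net <- function(net, path) {
  layers <- .net_layers(net)
  state <- list(cfg = unclass(net$cfg),
                W = lapply(layers, function(ly) ly$W),
                b = lapply(layers, function(ly) ly$b),
                g = lapply(layers, function(ly) if (ly$norm) ly$g),
                beta = lapply(layers, function(ly) if (ly$norm) ly$beta))
  saveRDS(state, path)
  jsonlite::write_json(unclass(net$cfg),
                       paste0(tools::file_path_sans_ext(path), "_config.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Restore a network saved by [save_net()]
#' @param path `.rds` path
#' @return an `avp_net`
#' @export
load_net <- function(path) {
  state <- readRDS(path)
  cfg <- do.call(network_config, state$cfg[names(state$cfg) %in%
    names(formals(network_config))])
  net <- .build_net(cfg)
  layers <- .net_layers(net)
  stopifnot(length(layers) == length(state$W))
  for (i in seq_along(layers)) {
    layers[[i]]$W <- state$W[[i]]
    layers[[i]]$b <- state$b[[i]]
    if (layers[[i]]$norm && !is.null(state$g[[i]])) {
      layers[[i]]$g <- state$g[[i]]
      layers[[i]]$beta <- state$beta[[i]]
    }
  }
  net
}
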