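# Soft Dice losses over the nine foreground classes, optionally
# boundary-weighted, plus the deep-supervision combination.

.check_probs <- function(pred, tol = 1e-3) {
  d <- dim(pred)
  s <- rowSums(matrix(pred, ncol = d[4]))
  if (max(abs(s - 1)) > tol)
    stop("predicted probabilities are not normalized (max |sum - 1| = ",
         format(max(abs(s - 1))), ")")
  invisible(TRUE)
}

#' Soft Dice loss
#'
#' `1 - mean_c soft-Dice_c` over the foreground classes
#' `c = 1..K-1`, where `soft-Dice_c = (2 sum w p_c t_c + eps) /
#' (sum w p_c + sum w t_c + eps)` with optional voxel weights `w`
#' (default 1). A class absent from both target and prediction
#' contributes a Dice of 1 (the smoothing term). The loss is 0 (up to
#' `eps`) iff the prediction equals the one-hot target.
#'
#' @param pred array `(nx, ny, nz, K)` of class probabilities (must sum
#'   to 1 over classes within 1e-3)
#' @param target integer 3D array of class ids 0..K-1
#' @param weights optional voxel weight 3D array (>= 1 everywhere for
#'   boundary weighting); NULL means uniform
#' @param class_weights optional length `K-1` nonnegative weights over
#'   foreground classes (renormalized to mean 1)
#' @param eps smoothing constant
#' @param grad also return the gradient in `pred`
#' @param include_background also average the background class's soft
#'   Dice (training aid against foreground collapse; the reported loss
#'   defaults to foreground classes only)
#' @return the scalar loss, or (with `grad = TRUE`) a list
#'   `(loss, grad)`
#' @export
dice_loss <- function(pred, target, weights = NULL, class_weights = NULL,
                      eps = 1e-5, grad = FALSE,
                      include_background = FALSE) {
  d <- dim(pred)
  stopifnot(length(d) == 4L, identical(dim(target), d[1:3]))
  .check_probs(pred)
  K <- d[4]
  w <- if (is.null(weights)) 1 else {
    stopifnot(identical(dim(weights), d[1:3]))
    as.vector(weights)
  }
  classes <- if (include_background) 0:(K - 1L) else seq_len(K - 1L)
  nc <- length(classes)
  cw <- if (is.null(class_weights)) rep(1, nc) else {
    stopifnot(length(class_weights) == nc, all(class_weights >= 0))
    class_weights / mean(class_weights)
  }
  pm <- matrix(pred, ncol = K)
  tv <- as.vector(target)
  dices <- numeric(nc)
  g <- if (grad) matrix(0, nrow(pm), K) else NULL
  for (i in seq_len(nc)) {
    c <- classes[i]
    tc <- as.numeric(tv == c)
    pc <- pm[, c + 1L]
    num <- 2 * sum(w * pc * tc) + eps
    den <- sum(w * pc) + sum(w * tc) + eps
    dices[i] <- num / den
    if (grad) {
      # d(num/den)/dpc = (2 w tc den - num w) / den^2
      g[, c + 1L] <- -cw[i] / nc *
        (2 * w * tc * den - num * w) / den^2
    }
  }
  loss <- 1 - sum(cw * dices) / nc
  if (!grad) return(loss)
  list(loss = loss, grad = array(g, dim = d),
       dice_per_class = stats::setNames(dices, classes))
}

#' Boundary weight map for a label map
#'
#' `w(v) = 1 + (w_max - 1) * exp(-d(v) / tau)` where `d(v)` is the
#' Euclidean distance in voxels to the nearest boundary voxel; a
#' boundary voxel is one whose 6-neighbourhood (within the grid)
#' contains a different label. A uniform label map has all weights 1.
#'
#' @param l an `avp_labelmap` or integer 3D array
#' @param w_max weight on the boundary (>= 1)
#' @param tau decay length in voxels (> 0)
#' @return numeric 3D array of weights in `[1, w_max]`
#' @export
boundary_weight_map <- function(l, w_max = 5, tau = 2) {
  stopifnot(w_max >= 1, tau > 0)
  lab <- if (inherits(l, "avp_labelmap")) l$data else l
  d <- dim(lab)
  boundary <- array(FALSE, d)
  cmp <- function(dx, dy, dz) {
    i1 <- list(x = seq_len(d[1] - abs(dx)), y = seq_len(d[2] - abs(dy)),
               z = seq_len(d[3] - abs(dz)))
    a <- lab[i1$x + max(dx, 0), i1$y + max(dy, 0), i1$z + max(dz, 0),
             drop = FALSE]
    b <- lab[i1$x + max(-dx, 0), i1$y + max(-dy, 0), i1$z + max(-dz, 0),
             drop = FALSE]
    diffm <- a != b
    boundary[i1$x + max(dx, 0), i1$y + max(dy, 0), i1$z + max(dz, 0)] <<-
      boundary[i1$x + max(dx, 0), i1$y + max(dy, 0),
               i1$z + max(dz, 0), drop = FALSE] | diffm
    boundary[i1$x + max(-dx, 0), i1$y + max(-dy, 0), i1$z + max(-dz, 0)] <<-
      boundary[i1$x + max(-dx, 0), i1$y + max(-dy, 0),
               i1$z + max(-dz, 0), drop = FALSE] | diffm
  }
  cmp(1L, 0L, 0L); cmp(0L, 1L, 0L); cmp(0L, 0L, 1L)
  if (!any(boundary)) return(array(1, d))
  dist <- sqrt(cpp_edt_sq(as.vector(boundary), d, c(1, 1, 1)))
  array(1 + (w_max - 1) * exp(-dist / tau), d)
}

#' Boundary-weighted soft Dice loss
#'
#' [dice_loss()] with voxel weights from a [boundary_weight_map()]:
#' intersection and sums are voxel-weighted, so errors near structure
#' boundaries are penalized more. With `weights = 1` everywhere it
#' reduces exactly to the unweighted loss.
#'
#' @inheritParams dice_loss
#' @param weights voxel weight 3D array (e.g. from
#'   [boundary_weight_map()])
#' @return as [dice_loss()]
#' @export
boundary_weighted_dice_loss <- function(pred, target, weights,
                                        eps = 1e-5, grad = FALSE) {
  stopifnot(!is.null(weights))
  dice_loss(pred, target, weights = weights, eps = eps, grad = grad)
}

#' Deep-supervision loss
#'
#' `L(main, target) + lambda_aux * L(aux, nn-downsampled target)`.
#' With `lambda_aux = 0` (or `aux = NULL`) this is exactly the main
#' loss.
#'
#' @param main_pred probabilities at full resolution
#' @param aux_pred probabilities at 1/2 resolution, or NULL
#' @param target integer 3D array of class ids at full resolution
#' @param lambda_aux auxiliary weight
#' @param weights optional voxel weights at full resolution; the aux
#'   term uses their nearest-neighbour downsampling
#' @param eps smoothing constant
#' @param grad also return gradients
#' @param include_background as in [dice_loss()]
#' @return scalar loss, or list `(loss, grad_main, grad_aux)`
#' @export
deep_supervision_loss <- function(main_pred, aux_pred, target,
                                  lambda_aux = 0.4, weights = NULL,
                                  eps = 1e-5, grad = FALSE,
                                  include_background = FALSE) {
  lm <- dice_loss(main_pred, target, weights = weights, eps = eps,
                  grad = grad, include_background = include_background)
  use_aux <- !is.null(aux_pred) && lambda_aux != 0
  la <- NULL
  if (use_aux) {
    t2 <- .downsample_nn(target)
    w2 <- if (is.null(weights)) NULL else .downsample_nn(weights)
    la <- dice_loss(aux_pred, t2, weights = w2, eps = eps, grad = grad,
                    include_background = include_background)
  }
  if (!grad) {
    return(if (use_aux) lm + lambda_aux * la else lm)
  }
  list(loss = if (use_aux) lm$loss + lambda_aux * la$loss else lm$loss,
       grad_main = lm$grad,
       grad_aux = if (use_aux) lambda_aux * la$grad else NULL)
}
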