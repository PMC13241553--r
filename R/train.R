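# Monte Carlo cross-validation, refinement gating, majority voting, and
# the end-to-end training orchestration of the two-stage cascade.

#' Monte Carlo train/validation splits with full validation coverage
#'
#' Repeats a random 80/20 partition until every subject has appeared in
#' a validation set at least once (or errors after `max_runs` attempts).
#'
#' @param subject_ids character vector (>= 5 subjects)
#' @param ratio training fraction (default 0.8)
#' @param seed integer seed; the split list is deterministic given it
#' @param max_runs hard cap on the number of runs
#' @return list of splits, each a list with `run`, `train`, `validation`,
#'   `seed`; the union of validation sets covers all subjects
#' @export
make_mc_splits <- function(subject_ids, ratio = 0.8, seed = 1L,
                           max_runs = 20L) {
  n <- length(subject_ids)
  if (n < 5) stop("need at least 5 subjects, got ", n)
  stopifnot(ratio > 0, ratio < 1)
  n_train <- max(1L, min(n - 1L, floor(ratio * n)))
  with_seed(seed, {
    splits <- list()
    covered <- character(0)
    for (run in seq_len(max_runs)) {
      tr <- sample(subject_ids, n_train)
      va <- setdiff(subject_ids, tr)
      splits[[run]] <- list(run = run, train = sort(tr),
                            validation = sort(va), seed = seed + run)
      covered <- union(covered, va)
      if (setequal(covered, subject_ids)) return(splits)
    }
    stop("validation coverage not achieved within ", max_runs,
         " runs (", length(setdiff(subject_ids, covered)),
         " subjects never validated)")
  })
}

#' Fixed-count random splits (no coverage requirement)
#'
#' Used for a budgeted number of Monte Carlo folds; same partition
#' mechanics as [make_mc_splits()] but exactly `n_folds` runs.
#'
#' @inheritParams make_mc_splits
#' @param n_folds number of runs
#' @return list of splits as in [make_mc_splits()]
#' @export
make_fixed_splits <- function(subject_ids, n_folds, ratio = 0.8,
                              seed = 1L) {
  n <- length(subject_ids)
  n_train <- max(1L, min(n - 1L, floor(ratio * n)))
  with_seed(seed, lapply(seq_len(n_folds), function(run) {
    tr <- sample(subject_ids, n_train)
    list(run = run, train = sort(tr),
         validation = sort(setdiff(subject_ids, tr)), seed = seed + run)
  }))
}

#' Gate predictions for refinement training
#'
#' Retains exactly the subjects whose mean DSC against the ground truth
#' is at or above the threshold (inclusive): only sufficiently accurate
#' principal predictions guide refinement.
#'
#' @param dsc_by_subject named numeric vector of per-subject mean DSC
#'   (mean over the foreground labels present in that subject's GT)
#' @param threshold retention threshold (default 0.7)
#' @return character vector of retained subject ids (possibly empty,
#'   with a warning)
#' @export
gate_for_refinement <- function(dsc_by_subject, threshold = 0.7) {
  stopifnot(!is.null(names(dsc_by_subject)))
  keep <- names(dsc_by_subject)[dsc_by_subject >= threshold]
  if (length(keep) == 0)
    warning("no subjects passed the DSC >= ", threshold,
            " refinement gate")
  keep
}

#' Mean DSC of a multiclass prediction over GT-present labels
#'
#' @param pred,gt `avp_labelmap`s
#' @return unweighted mean of per-label DSC over the foreground labels
#'   present in `gt`
#' @export
mean_label_dsc <- function(pred, gt) {
  ids <- setdiff(sort(unique(as.vector(gt$data))), 0L)
  if (length(ids) == 0) return(NA_real_)
  mean(vapply(ids, function(id) dsc(pred$data == id, gt$data == id),
              numeric(1)))
}

#' Majority vote over an ensemble of label maps
#'
#' A voxel is assigned class `c` iff strictly more than `threshold` of
#' the models predict `c` there; otherwise it is background. With
#' `threshold = 0.5` at most one class can qualify, so the rule is
#' well-defined; an exact 50/50 split yields background.
#'
#' @param predictions non-empty list of `avp_labelmap`s sharing shape
#'   and scheme
#' @param threshold vote fraction in (0, 1]
#' @return the fused `avp_labelmap`
#' @export
majority_vote <- function(predictions, threshold = 0.5) {
  if (length(predictions) == 0) stop("empty ensemble")
  stopifnot(threshold > 0, threshold <= 1)
  ref <- predictions[[1]]
  d <- dim(ref$data)
  for (p in predictions)
    if (!identical(dim(p$data), d)) stop("ensemble shapes differ")
  n <- length(predictions)
  K <- length(ref$scheme$ids)
  need <- threshold * n
  votes <- matrix(0L, prod(d), length(predictions))
  for (i in seq_along(predictions))
    votes[, i] <- as.vector(predictions[[i]]$data)
  # among classes clearing the threshold keep the most-voted (ties ->
  # lowest id); with threshold >= 0.5 at most one class can clear it
  win <- integer(prod(d))
  winv <- numeric(prod(d))
  for (c in seq_len(K - 1L)) {
    vc <- rowSums(votes == c)
    sel <- vc > need & vc > winv
    win[sel] <- c
    winv[sel] <- vc[sel]
  }
  out <- array(win, d)
  fused <- ref
  fused$data <- out
  fused$subject_id <- ref$subject_id
  fused
}

# ---- training -------------------------------------------------------------

#' Training hyperparameters
#'
#' Optimization settings are implementation choices (not taken from any
#' publication): Adam with a fixed learning rate, full-volume batches of
#' one subject, soft-Dice objectives.
#'
#' @param epochs_principal,epochs_refinement epochs per stage
#' @param lr Adam learning rate
#' @param dsc_gate refinement retention threshold on mean DSC
#' @param vote_threshold majority-vote fraction
#' @param boundary_w_max,boundary_tau boundary weighting of the
#'   refinement loss
#' @param use_refinement ablation switch for the second stage
#' @param seed global training seed
#' @return object of class `avp_train_config`
#' @export
train_config <- function(epochs_principal = 16L, epochs_refinement = 6L,
                         lr = 1e-2, dsc_gate = 0.7, vote_threshold = 0.5,
                         boundary_w_max = 5, boundary_tau = 2,
                         use_refinement = TRUE, seed = 1L) {
  structure(list(epochs_principal = as.integer(epochs_principal),
                 epochs_refinement = as.integer(epochs_refinement),
                 lr = lr, dsc_gate = dsc_gate,
                 vote_threshold = vote_threshold,
                 boundary_w_max = boundary_w_max,
                 boundary_tau = boundary_tau,
                 use_refinement = isTRUE(use_refinement),
                 seed = as.integer(seed)),
            class = "avp_train_config")
}

.train_one_net <- function(net, inputs, targets, epochs, lr,
                           weights = NULL, lambda_aux = 0.4,
                           log_prefix = "net", verbose = FALSE) {
  ids <- names(inputs)
  step <- 0L
  log <- data.frame()
  for (ep in seq_len(epochs)) {
    ep_losses <- numeric(0)
    for (id in ids) {
      fwd <- net_forward(net, inputs[[id]], cache = TRUE)
      probs <- softmax_classes(fwd$main)
      aux_probs <- if (!is.null(fwd$aux)) softmax_classes(fwd$aux)
      w <- if (is.null(weights)) NULL else weights[[id]]
      ls <- deep_supervision_loss(probs, aux_probs, targets[[id]],
                                  lambda_aux = lambda_aux, weights = w,
                                  grad = TRUE, include_background = TRUE)
      if (!is.finite(ls$loss))
        stop("training diverged: non-finite loss at ", log_prefix,
             " epoch ", ep, " subject ", id)
      dmain <- .softmax_bwd(ls$grad_main, probs)
      daux <- if (!is.null(ls$grad_aux)) .softmax_bwd(ls$grad_aux, aux_probs)
      zero_grad(net)
      net_backward(net, fwd, dmain, daux)
      step <- step + 1L
      adam_step(net, lr = lr, t = step)
      ep_losses <- c(ep_losses, ls$loss)
    }
    log <- rbind(log, data.frame(stage = log_prefix, epoch = ep,
                                 loss = mean(ep_losses)))
    if (verbose)
      message(sprintf("[%s] epoch %d/%d loss %.4f", log_prefix, ep,
                      epochs, mean(ep_losses)))
  }
  log
}

#' Predict a multiclass label map with one network
#'
#' @param net an `avp_net`
#' @param volume an `avp_volume` (already standardized/normalized)
#' @param init optional initial-segmentation probability array appended
#'   to the image channel (refinement input)
#' @return list with `labels` (an `avp_labelmap`) and `probs`
#' @export
net_predict <- function(net, volume, init = NULL) {
  x <- array(volume$data, c(dim(volume$data), 1L))
  if (!is.null(init)) x <- .concat_c(x, init)
  fwd <- net_forward(net, x, cache = FALSE)
  probs <- softmax_classes(fwd$main)
  lab <- argmax_classes(probs)
  list(labels = avp_labelmap(lab, spacing = volume$spacing,
                             affine = volume$affine,
                             subject_id = volume$subject_id),
       probs = probs)
}

#' Train the full two-stage cascade with Monte Carlo folds
#'
#' Per fold: train the principal network on the training subjects,
#' predict the validation subjects, gate subjects at mean DSC >=
#' `dsc_gate` and train the refinement network (boundary-weighted Dice)
#' on the retained training-set pairs; refinement targets are the full
#' multiclass ground truth.
#'
#' @param cohort output of [make_cohort()] (or a compatible list)
#' @param net_cfg a [network_config()] for the principal network
#' @param tr_cfg a [train_config()]
#' @param n_folds number of Monte Carlo folds
#' @param verbose print per-epoch losses
#' @return object of class `avp_run`: per-fold `principal`,
#'   `refinement` (may be NULL), `split`, validation predictions
#'   (`val_pred_raw`, `val_pred_refined`), gate decisions, and the
#'   concatenated training `log`
#' @export
run_training <- function(cohort, net_cfg = network_config(),
                         tr_cfg = train_config(), n_folds = 3L,
                         verbose = FALSE) {
  subjects <- cohort$subjects
  ids <- names(subjects)
  inputs <- lapply(subjects, function(s) {
    v <- normalize_intensity(s$volume)
    array(v$data, c(dim(v$data), 1L))
  })
  targets <- lapply(subjects, function(s) s$gt$data)
  splits <- make_fixed_splits(ids, n_folds, ratio = 0.8,
                              seed = tr_cfg$seed)
  folds <- vector("list", n_folds)
  log <- data.frame()
  for (f in seq_len(n_folds)) {
    sp <- splits[[f]]
    principal <- build_principal(net_cfg, seed = tr_cfg$seed + 100L * f)
    lg <- .train_one_net(principal, inputs[sp$train], targets[sp$train],
                         epochs = tr_cfg$epochs_principal, lr = tr_cfg$lr,
                         lambda_aux = net_cfg$aux_weight,
                         log_prefix = sprintf("fold%d/principal", f),
                         verbose = verbose)
    log <- rbind(log, lg)
    # raw principal predictions
    pred_raw <- lapply(ids, function(id) {
      v <- subjects[[id]]$volume
      nv <- normalize_intensity(v)
      net_predict(principal, nv)
    })
    names(pred_raw) <- ids
    # gate on training subjects: refinement learns from retained pairs
    train_dsc <- vapply(sp$train, function(id)
      mean_label_dsc(pred_raw[[id]]$labels, subjects[[id]]$gt), numeric(1))
    names(train_dsc) <- sp$train
    retained <- gate_for_refinement(train_dsc, tr_cfg$dsc_gate)
    refinement <- NULL
    if (tr_cfg$use_refinement && length(retained) > 0) {
      refinement <- build_refinement(num_classes = net_cfg$num_classes,
                                     seed = tr_cfg$seed + 100L * f + 1L)
      rin <- lapply(retained, function(id)
        .concat_c(inputs[[id]], pred_raw[[id]]$probs))
      names(rin) <- retained
      wmaps <- lapply(retained, function(id)
        boundary_weight_map(targets[[id]], tr_cfg$boundary_w_max,
                            tr_cfg$boundary_tau))
      names(wmaps) <- retained
      lg <- .train_one_net(refinement, rin, targets[retained],
                           epochs = tr_cfg$epochs_refinement,
                           lr = tr_cfg$lr, weights = wmaps,
                           lambda_aux = 0,
                           log_prefix = sprintf("fold%d/refinement", f),
                           verbose = verbose)
      log <- rbind(log, lg)
    }
    refine_subject <- function(id) {
      if (is.null(refinement)) return(pred_raw[[id]])
      v <- normalize_intensity(subjects[[id]]$volume)
      net_predict(refinement, v, init = pred_raw[[id]]$probs)
    }
    val_refined <- lapply(sp$validation, refine_subject)
    names(val_refined) <- sp$validation
    folds[[f]] <- list(split = sp, principal = principal,
                       refinement = refinement,
                       gate = list(dsc = train_dsc, retained = retained),
                       val_pred_raw = pred_raw[sp$validation],
                       val_pred_refined = val_refined,
                       pred_raw_all = pred_raw)
  }
  structure(list(folds = folds, log = log, cfg = net_cfg,
                 train_cfg = tr_cfg, subject_ids = ids),
            class = "avp_run")
}

#' End-to-end cascade prediction for one subject
#'
#' Principal network of every fold, per-fold refinement, majority vote
#' across the fold models, then anatomical post-processing.
#'
#' @param run an `avp_run` from [run_training()]
#' @param volume an `avp_volume` (raw intensities; normalized internally)
#' @param post_cfg a [postprocess_config()]
#' @param vote_threshold majority-vote fraction
#' @return list with `labels` (final `avp_labelmap`), `voted` (before
#'   post-processing) and `per_model` label maps
#' @export
predict_cascade <- function(run, volume, post_cfg = postprocess_config(),
                            vote_threshold = NULL) {
  theta <- vote_threshold %||% run$train_cfg$vote_threshold
  nv <- normalize_intensity(volume)
  per_model <- lapply(run$folds, function(fold) {
    raw <- net_predict(fold$principal, nv)
    if (!is.null(fold$refinement))
      net_predict(fold$refinement, nv, init = raw$probs)$labels
    else raw$labels
  })
  voted <- majority_vote(per_model, threshold = theta)
  if (is.null(post_cfg$midline) &&
      !any(voted$data == label_id(voted$scheme, "ONC")))
    post_cfg$midline <- (dim(voted$data)[1] + 1) / 2  # chiasm-free fallback
  final <- postprocess(voted, post_cfg)
  list(labels = final, voted = voted, per_model = per_model)
}
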