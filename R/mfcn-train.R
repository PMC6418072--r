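# Training loop: class-weighted pixel-wise cross-entropy, Adam, one master
# seed fanning out to shuffling (parameter initialisation is seeded in
# build_mfcn).

# Weighted softmax cross-entropy. labels: [H, W, N] integer 0/1.
# Returns loss and the gradient w.r.t. the logits.
weighted_ce <- function(probs, labels, w_bg, w_fg) {
  d <- dim(probs)
  p_bg <- probs[, , 1, , drop = FALSE]; dim(p_bg) <- c(d[1], d[2], d[4])
  p_fg <- probs[, , 2, , drop = FALSE]; dim(p_fg) <- c(d[1], d[2], d[4])
  eps <- 1e-12
  wmap <- w_bg + (w_fg - w_bg) * labels
  p_true <- p_bg + (p_fg - p_bg) * labels
  wsum <- sum(wmap)
  loss <- -sum(wmap * log(p_true + eps)) / wsum
  dlogits <- probs
  dlogits[, , 1, ] <- (p_bg - (1 - labels)) * wmap / wsum
  dlogits[, , 2, ] <- (p_fg - labels) * wmap / wsum
  list(loss = loss, dlogits = dlogits)
}

adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = 0L)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(grads)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(params = params, state = state)
}

#' Train the MFCN on image/label pairs
#'
#' Minimises pixel-wise 2-class cross-entropy with inverse-frequency class
#' weighting — granules occupy only a small part of an EM image, so
#' unweighted loss lets an all-background predictor look good — using Adam.
#' Images must already be histogram-equalized (the same pre-processing is
#' applied at prediction time). Training is bit-reproducible on a fixed
#' machine given the config seed.
#'
#' @param net An [build_mfcn()] network.
#' @param pairs List of training pairs as from [scene_to_training_pair()]:
#'   each a list with `image` ([gray_image] or matrix) and `labels`
#'   (0/1 matrix of the same size).
#' @param cfg A [run_config()]; uses `epochs`, `batch_size`,
#'   `learning_rate` and `seed`.
#' @return An object of class `mfcn_train_state`: the trained `network`,
#'   a `loss_history` tibble (one row per optimisation step), the class
#'   weights and the config.
#' @export
mfcn_train <- function(net, pairs, cfg = run_config()) {
  if (length(pairs) < 1) abort("training set is empty")
  xs <- lapply(pairs, function(p) normalize_input(as_pixels(p$image)))
  ys <- lapply(pairs, function(p) {
    lab <- p$labels
    if (!all(dim(lab) == dim(as_pixels(p$image)))) {
      abort("label raster size does not match its image")
    }
    storage.mode(lab) <- "integer"
    lab
  })
  H <- nrow(xs[[1]]); W <- ncol(xs[[1]])
  f <- max(net$spec$branch_factors)
  if (H %% f != 0 || W %% f != 0) {
    abort("training images must be divisible by the largest branch factor")
  }
  n_fg <- sum(vapply(ys, function(y) sum(y == 1L), numeric(1)))
  n_tot <- sum(vapply(ys, length, numeric(1)))
  n_bg <- n_tot - n_fg
  w_fg <- if (n_fg > 0) n_tot / (2 * n_fg) else 1
  w_bg <- if (n_bg > 0) n_tot / (2 * n_bg) else 1

  n <- length(pairs)
  bs <- min(cfg$batch_size, n)
  opt <- adam_init(net$params)
  history <- list()
  step <- 0L
  with_seed(cfg$seed, {
    for (epoch in seq_len(cfg$epochs)) {
      ord <- sample.int(n)
      for (start in seq(1, n, by = bs)) {
        idx <- ord[start:min(start + bs - 1, n)]
        B <- length(idx)
        x <- array(0, dim = c(H, W, 1, B))
        y <- array(0L, dim = c(H, W, B))
        for (i in seq_len(B)) {
          x[, , 1, i] <- xs[[idx[i]]]
          y[, , i] <- ys[[idx[i]]]
        }
        fwd <- mfcn_forward_full(net, x, mode = "train", keep = TRUE)
        net$stats <- fwd$stats
        ce <- weighted_ce(fwd$probs, y, w_bg, w_fg)
        bwd <- mfcn_backward_full(net, fwd, ce$dlogits, mode = "train")
        upd <- adam_step(net$params, bwd$grads, opt, cfg$learning_rate)
        net$params <- upd$params
        opt <- upd$state
        step <- step + 1L
        history[[step]] <- tibble(step = step, epoch = epoch, loss = ce$loss)
      }
    }
  })
  structure(list(
    network = net,
    loss_history = bind_rows(history),
    class_weights = c(background = w_bg, granule = w_fg),
    cfg = cfg
  ), class = "mfcn_train_state")
}

#' @export
print.mfcn_train_state <- function(x, ...) {
  g <- glance(x)
  cat(sprintf(
    "<mfcn_train_state> %d steps over %d epochs; mean loss epoch 1: %.4f, final epoch: %.4f\n",
    g$steps, g$epochs, g$first_epoch_loss, g$final_epoch_loss))
  invisible(x)
}

#' Tidy the optimisation trace
#'
#' @param x An `mfcn_train_state`.
#' @param ... Unused.
#' @return `tidy()` returns the per-step loss history tibble; `glance()` a
#'   one-row summary with the mean loss of the first and last epoch.
#' @export
tidy.mfcn_train_state <- function(x, ...) x$loss_history

#' @rdname tidy.mfcn_train_state
#' @export
glance.mfcn_train_state <- function(x, ...) {
  h <- x$loss_history
  tibble(
    steps = nrow(h),
    epochs = max(h$epoch),
    first_epoch_loss = mean(h$loss[h$epoch == 1]),
    final_epoch_loss = mean(h$loss[h$epoch == max(h$epoch)]),
    final_loss = h$loss[nrow(h)]
  )
}
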