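# Trainable part of the hybrid network: plain stride-1 "same" (zero-padded)
# convolutions implemented by im2col + matrix multiply. Activations for a
# whole mini-batch are stacked (layout h x w x batch x channel) so each layer
# is a single BLAS call per batch in both directions.

as_hwbc <- function(x) {
  # single image/activation -> batch-of-one in h x w x batch x channel layout
  if (is.matrix(x)) array(x, c(dim(x), 1L, 1L)) else x
}

im2col_b <- function(xp, h, w, nb, f, nc) {
  m <- matrix(0, h * w * nb, f * f * nc)
  col <- 0L
  for (ch in seq_len(nc)) for (cc in seq_len(f)) for (r in seq_len(f)) {
    col <- col + 1L
    m[, col] <- xp[r:(r + h - 1L), cc:(cc + w - 1L), , ch]
  }
  m
}

conv_forward <- function(x, W, b, m_pre = NULL) {
  x <- as_hwbc(x)
  f <- dim(W)[1]; nc <- dim(W)[3]; k <- dim(W)[4]
  stopifnot(dim(W)[2] == f, dim(x)[4] == nc)
  h <- dim(x)[1]; w <- dim(x)[2]; nb <- dim(x)[3]
  p <- (f - 1L) %/% 2L
  m <- if (!is.null(m_pre)) {
    m_pre
  } else if (f == 1L) {
    matrix(x, h * w * nb, nc)          # 1x1: the patch matrix is the input
  } else {
    xp <- array(0, c(h + 2L * p, w + 2L * p, nb, nc))
    xp[p + seq_len(h), p + seq_len(w), , ] <- x
    im2col_b(xp, h, w, nb, f, nc)
  }
  outm <- m %*% matrix(W, f * f * nc, k)
  outm <- sweep(outm, 2L, b, "+")
  list(out = array(outm, c(h, w, nb, k)), m = m,
       dims = c(h, w, f, nc, k, p, nb))
}

conv_backward <- function(cache, W, d_out, need_dx = TRUE) {
  d <- cache$dims
  h <- d[1]; w <- d[2]; f <- d[3]; nc <- d[4]; k <- d[5]; p <- d[6]; nb <- d[7]
  dm_out <- matrix(d_out, h * w * nb, k)
  dW <- array(crossprod(cache$m, dm_out), dim(W))
  db <- colSums(dm_out)
  if (!need_dx) return(list(dW = dW, db = db, dx = NULL))
  if (f == 1L) {
    dm <- dm_out %*% t(matrix(W, nc, k))
    return(list(dW = dW, db = db, dx = array(dm, c(h, w, nb, nc))))
  }
  # adjoint of a stride-1 "same" zero-padded convolution: convolve the
  # output gradient with the 180-degree-rotated kernel, channels swapped
  w_flip <- array(0, c(f, f, k, nc))
  for (ch in seq_len(nc)) for (kk in seq_len(k)) {
    w_flip[, , kk, ch] <- W[f:1, f:1, ch, kk]
  }
  dx <- conv_forward(array(d_out, c(h, w, nb, k)), w_flip, numeric(nc))$out
  list(dW = dW, db = db, dx = dx)
}

#' Construct the hybrid super-resolution network
#'
#' Builds the network: a frozen x4 bicubic template layer followed by a
#' patch-extraction/representation convolution (`f2 x f2`, `n2` filters,
#' ReLU), a 1x1 nonlinear-mapping convolution (`n3` filters, ReLU) and a
#' linear `f3 x f3` reconstruction convolution producing one channel. Only
#' the three convolutions are trainable; the template bank never changes.
#'
#' Two initializations are available. `"gaussian"` draws every weight from
#' `N(0, sd^2)` with zero biases, so the untrained output is essentially
#' zero. `"identity"` (default) additionally places a unit pass-through
#' stencil on one channel path (centre tap of one layer-2 filter, the
#' matching 1x1 tap of layer 3, and the centre tap of the reconstruction
#' filter), so the untrained network already reproduces the template-layer
#' upscale and training starts from bicubic quality instead of from black.
#'
#' @param f2,n2 spatial size / filter count of the patch-extraction layer.
#' @param n3 filter count of the 1x1 nonlinear-mapping layer.
#' @param f3 spatial size of the reconstruction layer.
#' @param init `"identity"` or `"gaussian"`.
#' @param sd standard deviation of the Gaussian weight noise.
#' @param seed integer RNG seed for the initialization.
#' @param bank template bank; built once if not supplied.
#' @return A list of class `hybrid_network` with fields `bank`, `W2`, `b2`,
#'   `W3`, `b3`, `W4`, `b4`, `specs`, `seed`, `loss_history`.
#' @export
hybrid_network <- function(f2 = 9, n2 = 64, n3 = 32, f3 = 5,
                           init = c("identity", "gaussian"), sd = 1e-3,
                           seed = 1L, bank = build_template_bank()) {
  init <- match.arg(init)
  stopifnot(f2 %% 2 == 1, f3 %% 2 == 1, n2 >= 1, n3 >= 1)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  W2 <- array(stats::rnorm(f2 * f2 * 1 * n2, 0, sd), c(f2, f2, 1, n2))
  W3 <- array(stats::rnorm(1 * 1 * n2 * n3, 0, sd), c(1, 1, n2, n3))
  W4 <- array(stats::rnorm(f3 * f3 * n3 * 1, 0, sd), c(f3, f3, n3, 1))
  if (init == "identity") {
    c2 <- (f2 + 1) %/% 2; c4 <- (f3 + 1) %/% 2
    W2[c2, c2, 1, 1] <- W2[c2, c2, 1, 1] + 1
    W3[1, 1, 1, 1] <- W3[1, 1, 1, 1] + 1
    W4[c4, c4, 1, 1] <- W4[c4, c4, 1, 1] + 1
  }
  structure(list(bank = bank,
                 W2 = W2, b2 = numeric(n2),
                 W3 = W3, b3 = numeric(n3),
                 W4 = W4, b4 = numeric(1),
                 specs = list(f2 = f2, n2 = n2, n3 = n3, f3 = f3,
                              init = init, sd = sd),
                 seed = as.integer(seed),
                 loss_history = numeric(0)),
            class = "hybrid_network")
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

#' @export
print.hybrid_network <- function(x, ...) {
  s <- x$specs
  cat(sprintf(paste0("<hybrid_network> template layer (frozen, 16 stencils) + ",
                     "conv %dx%dx%d ReLU + conv 1x1x%d ReLU + conv %dx%dx1; ",
                     "%d epochs trained\n"),
              s$f2, s$f2, s$n2, s$n3, s$f3, s$f3, length(x$loss_history)))
  invisible(x)
}

#' Forward pass of the hybrid network
#'
#' Runs the frozen template upscaling followed by the three trainable
#' convolutions: `F2 = relu(W2 * Y + b2)`, `F3 = relu(W3 * F2 + b3)`,
#' `F4 = W4 * F3 + b4` (linear).
#'
#' @param net a [hybrid_network()].
#' @param lr_image single-channel numeric matrix with intensities in
#'   `[0, 1]`.
#' @param keep_cache keep intermediate activations (needed for backprop).
#' @return A list with `output` (matrix, `4 * dim(lr_image)`), `upscaled`
#'   (the template-layer output `Y`) and, if requested, `cache`.
#' @export
forward_network <- function(net, lr_image, keep_cache = FALSE) {
  stopifnot(inherits(net, "hybrid_network"), is.matrix(lr_image))
  y <- upscale4(lr_image, net$bank, rounding = "none")
  attributes(y) <- list(dim = dim(y))
  fw <- forward_stack(net, array(y, c(dim(y), 1L, 1L)))
  res <- list(output = fw$c4$out[, , 1L, 1L], upscaled = y)
  if (keep_cache) res$cache <- fw
  res
}

# batched forward over a stack of template-layer outputs (h x w x nb x 1);
# m2 optionally supplies the precomputed layer-2 patch matrix (the template
# layer is frozen, so it never changes across epochs)
forward_stack <- function(net, ystack, m2 = NULL) {
  c2 <- conv_forward(ystack, net$W2, net$b2, m_pre = m2)
  a2 <- pmax(c2$out, 0)
  c3 <- conv_forward(a2, net$W3, net$b3)
  a3 <- pmax(c3$out, 0)
  c4 <- conv_forward(a3, net$W4, net$b4)
  list(c2 = c2, c3 = c3, c4 = c4, a2 = a2, a3 = a3)
}

#' Mean squared error loss
#'
#' Mean over all pixels (and, for lists, samples) of the squared difference
#' between prediction and ground truth.
#'
#' @param predicted,ground_truth numeric matrices of identical shape, or
#'   lists of such matrices.
#' @return A nonnegative scalar.
#' @export
mse_loss <- function(predicted, ground_truth) {
  if (is.list(predicted)) {
    stopifnot(is.list(ground_truth), length(predicted) == length(ground_truth))
    return(mean(mapply(mse_loss, predicted, ground_truth)))
  }
  if (!identical(dim(predicted), dim(ground_truth)))
    stop("shape mismatch between predicted and ground-truth images")
  mean((predicted - ground_truth)^2)
}

# stack the template-layer outputs and HR targets of a batch of pairs
stack_batch <- function(net, batch) {
  ys <- lapply(batch, function(p) {
    y <- upscale4(p$lr, net$bank, rounding = "none")
    attributes(y) <- list(dim = dim(y))
    y
  })
  stack_ys(ys, lapply(batch, `[[`, "hr"))
}

stack_ys <- function(ys, hrs) {
  h <- nrow(ys[[1]]); w <- ncol(ys[[1]]); nb <- length(ys)
  list(y = array(unlist(ys), c(h, w, nb, 1L)),
       hr = array(unlist(hrs), c(h, w, nb)))
}

# loss and analytic parameter gradients on a stacked batch; the loss is the
# mean over samples of the per-pixel mean squared error
batch_gradients <- function(net, stk, m2 = NULL) {
  fw <- forward_stack(net, stk$y, m2 = m2)
  diffa <- array(fw$c4$out, dim(stk$hr)) - stk$hr  # output has one channel
  loss <- mean(diffa^2)
  d4 <- array(2 * diffa / length(diffa), c(dim(stk$hr), 1L))
  b4g <- conv_backward(fw$c4, net$W4, d4)
  d3 <- b4g$dx * (fw$c3$out > 0)
  b3g <- conv_backward(fw$c3, net$W3, d3)
  d2 <- b3g$dx * (fw$c2$out > 0)
  b2g <- conv_backward(fw$c2, net$W2, d2, need_dx = FALSE)
  list(grads = list(W2 = b2g$dW, b2 = b2g$db, W3 = b3g$dW, b3 = b3g$db,
                    W4 = b4g$dW, b4 = b4g$db),
       loss = loss)
}

# loss/gradients from a list of (lr, hr) pairs (equal sizes)
network_gradients <- function(net, batch) {
  batch_gradients(net, stack_batch(net, batch))
}

#' Train the hybrid network by SGD with backpropagation
#'
#' Minimizes the mean-squared-error loss over (LR, HR) training pairs by
#' mini-batch stochastic gradient descent. The template layer is frozen;
#' only `W2, b2, W3, b3, W4, b4` are updated. Fully reproducible from
#' `seed`.
#'
#' @param net a [hybrid_network()].
#' @param pairs nonempty list of training pairs, each a list with matrices
#'   `lr` and `hr` in `[0, 1]`, HR side length four times the LR side.
#' @param epochs number of passes over the training set.
#' @param learning_rate SGD step size.
#' @param batch_size mini-batch size.
#' @param momentum classical momentum coefficient (0 disables it).
#' @param seed RNG seed controlling the per-epoch shuffling.
#' @return The trained network; `loss_history` holds the mean training loss
#'   of each epoch (evaluated on the forward passes of that epoch's
#'   batches, before each update), and `initial_loss` the full-set loss
#'   before any update.
#' @export
train_network <- function(net, pairs, epochs = 200, learning_rate = 0.1,
                          batch_size = 10, momentum = 0, seed = 1L) {
  stopifnot(inherits(net, "hybrid_network"), length(pairs) >= 1)
  for (p in pairs) {
    stopifnot(is.matrix(p$lr), is.matrix(p$hr),
              identical(4L * dim(p$lr), dim(p$hr)))
  }
  bank_before <- net$bank
  # the frozen template layer never changes: compute its outputs once
  ys <- lapply(pairs, function(p) {
    y <- upscale4(p$lr, net$bank, rounding = "none")
    attributes(y) <- list(dim = dim(y))
    y
  })
  hrs <- lapply(pairs, `[[`, "hr")
  hh <- nrow(ys[[1]]); ww <- ncol(ys[[1]])
  all_stk <- stack_ys(ys, hrs)
  m2_all <- conv_forward(all_stk$y, net$W2, net$b2)$m
  net$initial_loss <- batch_gradients(net, all_stk, m2 = m2_all)$loss
  vel <- list(W2 = array(0, dim(net$W2)), b2 = numeric(length(net$b2)),
              W3 = array(0, dim(net$W3)), b3 = numeric(length(net$b3)),
              W4 = array(0, dim(net$W4)), b4 = numeric(length(net$b4)))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  n <- length(pairs)
  for (ep in seq_len(epochs)) {
    ord <- sample.int(n)
    ep_loss <- 0; nbatch <- 0L
    for (start in seq(1, n, by = batch_size)) {
      idx <- ord[start:min(start + batch_size - 1, n)]
      rows <- as.vector(outer(seq_len(hh * ww), (idx - 1L) * hh * ww, "+"))
      gr <- batch_gradients(net, stack_ys(ys[idx], hrs[idx]),
                            m2 = m2_all[rows, , drop = FALSE])
      if (!is.finite(gr$loss))
        stop(sprintf("training diverged at epoch %d (non-finite loss); %s",
                     ep, "reduce the learning rate"))
      ep_loss <- ep_loss + gr$loss; nbatch <- nbatch + 1L
      for (nm in names(gr$grads)) {
        vel[[nm]] <- momentum * vel[[nm]] - learning_rate * gr$grads[[nm]]
        net[[nm]] <- net[[nm]] + vel[[nm]]
      }
    }
    net$loss_history <- c(net$loss_history, ep_loss / nbatch)
  }
  stopifnot(identical(bank_before, net$bank))  # frozen-layer invariant
  net
}

#' Finite-difference gradient check
#'
#' Compares the analytic backpropagation gradients against central finite
#' differences of the loss for every trainable parameter tensor, on a small
#' batch. Intended for tiny networks.
#'
#' @param net a [hybrid_network()] (keep it small).
#' @param pairs a short list of training pairs.
#' @param eps finite-difference step.
#' @return Maximum relative error
#'   `|analytic - numeric| / max(|analytic|, |numeric|, 1e-8)` over all
#'   parameters.
#' @export
gradient_check <- function(net, pairs, eps = 1e-5) {
  an <- network_gradients(net, pairs)$grads
  worst <- 0
  for (nm in c("W2", "b2", "W3", "b3", "W4", "b4")) {
    theta <- net[[nm]]
    for (i in seq_along(theta)) {
      np <- net; np[[nm]][i] <- theta[i] + eps
      lp <- network_gradients(np, pairs)$loss
      nm2 <- net; nm2[[nm]][i] <- theta[i] - eps
      lm <- network_gradients(nm2, pairs)$loss
      num <- (lp - lm) / (2 * eps)
      a <- an[[nm]][i]
      rel <- abs(a - num) / max(abs(a), abs(num), 1e-8)
      worst <- max(worst, rel)
    }
  }
  worst
}

#' Super-resolve an image with a (trained) network
#'
#' @param net a [hybrid_network()].
#' @param lr_image numeric matrix in `[0, 1]`.
#' @param clamp clamp the output into `[0, 1]`.
#' @return The reconstructed image, `4 * dim(lr_image)`.
#' @export
super_resolve <- function(net, lr_image, clamp = TRUE) {
  out <- forward_network(net, lr_image)$output
  if (clamp) out <- pmin(pmax(out, 0), 1)
  out
}

#' Save / load a hybrid network as JSON
#'
#' Serializes layer specs, weights, biases, seed and loss history to a
#' single JSON document (numbers written at full precision).
#'
#' @param net a [hybrid_network()].
#' @param path file path.
#' @return `path` (save) or the restored network (load).
#' @export
save_model <- function(net, path) {
  stopifnot(inherits(net, "hybrid_network"))
  obj <- list(
    format = "medsrr-model-1",
    specs = net$specs,
    seed = net$seed,
    loss_history = net$loss_history,
    weights = lapply(c("W2", "b2", "W3", "b3", "W4", "b4"), function(nm) {
      list(name = nm, dim = if (is.array(net[[nm]])) dim(net[[nm]]) else
           length(net[[nm]]), data = as.vector(net[[nm]]))
    }))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  stopifnot(identical(obj$format, "medsrr-model-1"))
  s <- obj$specs
  net <- hybrid_network(f2 = s$f2, n2 = s$n2, n3 = s$n3, f3 = s$f3,
                        init = s$init, sd = s$sd, seed = obj$seed)
  for (i in seq_len(nrow(obj$weights))) {
    nm <- obj$weights$name[i]
    dm <- obj$weights$dim[[i]]
    dat <- obj$weights$data[[i]]
    net[[nm]] <- if (length(dm) > 1) array(dat, dm) else as.numeric(dat)
  }
  net$loss_history <- as.numeric(obj$loss_history)
  net
}
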