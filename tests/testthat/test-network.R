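naive_conv <- function(x, W, b) {
  # independent "same" zero-padded stride-1 convolution, scalar loops
  h <- dim(x)[1]; w <- dim(x)[2]; nc <- dim(x)[3]
  f <- dim(W)[1]; k <- dim(W)[4]; p <- (f - 1) %/% 2
  out <- array(0, c(h, w, k))
  for (kk in 1:k) for (i in 1:h) for (j in 1:w) {
    acc <- b[kk]
    for (ch in 1:nc) for (r in 1:f) for (cc in 1:f) {
      ir <- i + r - 1 - p; jc <- j + cc - 1 - p
      if (ir >= 1 && ir <= h && jc >= 1 && jc <= w)
        acc <- acc + x[ir, jc, ch] * W[r, cc, ch, kk]
    }
    out[i, j, kk] <- acc
  }
  out
}

test_that("the im2col convolution matches a scalar reference", {
  withr::with_seed(11, {
    x <- array(rnorm(7 * 6 * 2), c(7, 6, 1, 2))
    W <- array(rnorm(3 * 3 * 2 * 4), c(3, 3, 2, 4))
    b <- rnorm(4)
    got <- medsrr:::conv_forward(x, W, b)$out
    expect_equal(got[, , 1, ], naive_conv(array(x, c(7, 6, 2)), W, b),
                 tolerance = 1e-12)
    # 1x1 fast path
    W1 <- array(rnorm(2 * 3), c(1, 1, 2, 3))
    got1 <- medsrr:::conv_forward(x, W1, numeric(3))$out
    expect_equal(got1[, , 1, ], naive_conv(array(x, c(7, 6, 2)), W1, numeric(3)),
                 tolerance = 1e-12)
  })
})

test_that("batched convolution equals per-image convolution", {
  withr::with_seed(12, {
    xs <- lapply(1:3, function(i) array(rnorm(5 * 5 * 2), c(5, 5, 1, 2)))
    W <- array(rnorm(3 * 3 * 2 * 2), c(3, 3, 2, 2))
    b <- rnorm(2)
    stack <- array(unlist(lapply(xs, function(x) aperm(x, c(1, 2, 4, 3)))),
                   c(5, 5, 2, 3))
    stack <- aperm(stack, c(1, 2, 4, 3))  # h x w x batch x channel
    got <- medsrr:::conv_forward(stack, W, b)$out
    for (i in 1:3) {
      expect_equal(got[, , i, ], medsrr:::conv_forward(xs[[i]], W, b)$out[, , 1, ],
                   tolerance = 1e-12)
    }
  })
})

test_that("noise-free identity init passes the template output through", {
  net <- hybrid_network(f2 = 5, n2 = 4, n3 = 3, f3 = 3, init = "identity",
                        sd = 0, seed = 1, bank = test_bank)
  lr <- matrix(withr::with_seed(5, runif(64, 0.2, 0.8)), 8, 8)
  fw <- forward_network(net, lr)
  # inputs bounded away from 0 keep the pass-through channel positive, so
  # both ReLUs are active on it and the output equals the upscaled image
  expect_equal(fw$output, fw$upscaled, tolerance = 1e-14, ignore_attr = TRUE)
  expect_identical(dim(fw$output), 4L * dim(lr))
})

test_that("analytic gradients match finite differences", {
  err <- gradient_check(tiny_check_net(), tiny_pairs(2, 16), eps = 1e-5)
  expect_lt(err, 1e-6)
})

test_that("training reduces the loss and is reproducible", {
  pairs <- tiny_pairs(6, 16, seed = 3)
  net0 <- hybrid_network(f2 = 3, n2 = 4, n3 = 3, f3 = 3, init = "identity",
                         seed = 4, bank = test_bank)
  net1 <- train_network(net0, pairs, epochs = 10, learning_rate = 0.1,
                        batch_size = 3, seed = 5)
  expect_length(net1$loss_history, 10)
  expect_lt(tail(net1$loss_history, 1), net1$initial_loss)
  net2 <- train_network(net0, pairs, epochs = 10, learning_rate = 0.1,
                        batch_size = 3, seed = 5)
  expect_identical(net1$W2, net2$W2)
  expect_identical(net1$W4, net2$W4)
  # the template layer is frozen
  expect_identical(net1$bank, net0$bank)
})

test_that("momentum training runs and differs from plain SGD", {
  pairs <- tiny_pairs(4, 16, seed = 8)
  net0 <- hybrid_network(f2 = 3, n2 = 2, n3 = 2, f3 = 3, init = "identity",
                         seed = 4, bank = test_bank)
  plain <- train_network(net0, pairs, epochs = 5, seed = 6)
  mom <- train_network(net0, pairs, epochs = 5, momentum = 0.9, seed = 6)
  expect_false(identical(plain$W2, mom$W2))
  expect_true(all(is.finite(mom$loss_history)))
})

test_that("training aborts with a clear error when it diverges", {
  pairs <- tiny_pairs(4, 16, seed = 9)
  net0 <- hybrid_network(f2 = 3, n2 = 2, n3 = 2, f3 = 3, init = "identity",
                         seed = 4, bank = test_bank)
  expect_error(
    train_network(net0, pairs, epochs = 50, learning_rate = 1e4, seed = 6),
    "diverged")
})

test_that("pair shapes are validated", {
  net <- hybrid_network(f2 = 3, n2 = 2, n3 = 2, f3 = 3, bank = test_bank)
  bad <- list(list(lr = matrix(0, 4, 4), hr = matrix(0, 15, 16)))
  expect_error(train_network(net, bad, epochs = 1))
  expect_error(mse_loss(matrix(0, 2, 2), matrix(0, 3, 3)), "shape")
  expect_equal(mse_loss(list(matrix(1, 2, 2)), list(matrix(0, 2, 2))), 1)
})

test_that("models survive a JSON save/load round trip", {
  net <- train_network(
    hybrid_network(f2 = 3, n2 = 2, n3 = 2, f3 = 3, seed = 4, bank = test_bank),
    tiny_pairs(2, 16), epochs = 2, seed = 1)
  path <- withr::local_tempfile(fileext = ".json")
  save_model(net, path)
  back <- load_model(path)
  expect_equal(back$W2, net$W2)
  expect_equal(back$b3, net$b3)
  expect_equal(back$loss_history, net$loss_history)
  lr <- matrix(withr::with_seed(2, runif(64)), 8, 8)
  expect_equal(super_resolve(back, lr), super_resolve(net, lr),
               ignore_attr = TRUE)
})

test_that("super_resolve clamps into [0, 1]", {
  net <- hybrid_network(f2 = 3, n2 = 2, n3 = 2, f3 = 3, init = "identity",
                        sd = 0, seed = 1, bank = test_bank)
  lr <- matrix(c(0, 1, 1, 0), 4, 4)  # overshooting edges
  out <- super_resolve(net, lr)
  expect_true(all(out >= 0 & out <= 1))
  raw <- super_resolve(net, lr, clamp = FALSE)
  expect_true(min(raw) < 0 || max(raw) > 1)
})
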