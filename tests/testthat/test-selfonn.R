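# Generative-neuron layer: forward contract, oracle equivalence,
# linearity, parameter-count formula.

test_that("hand-evaluated forward examples hold", {
  # q = 1 on all-ones reduces to plain cross-correlation
  sp <- selfonn_layer_spec(1, 1, kernel_size = 3, q = 1)
  co <- taylor_coefficients(sp, init = "zeros")
  co$weights[] <- 1
  expect_equal(as.vector(selfonn_forward(array(1, c(1, 3, 3)), sp, co)), 9)

  # q = 2 on constant 2s: each of the 9 positions contributes 2 + 4
  sp2 <- selfonn_layer_spec(1, 1, kernel_size = 3, q = 2)
  co2 <- taylor_coefficients(sp2, init = "zeros")
  co2$weights[] <- 1
  expect_equal(as.vector(selfonn_forward(array(2, c(1, 3, 3)), sp2, co2)),
               54)

  # 1x1 kernel, x = 3, q = 3, unit coefficients, bias 1: 1 + 3 + 9 + 27
  sp3 <- selfonn_layer_spec(1, 1, kernel_size = 1, q = 3)
  co3 <- taylor_coefficients(sp3, init = "zeros")
  co3$weights[] <- 1
  co3$bias[] <- 1
  expect_equal(as.vector(selfonn_forward(array(3, c(1, 1, 1)), sp3, co3)),
               40)
  expect_equal(
    as.vector(selfonn_forward_bruteforce(array(3, c(1, 1, 1)), sp3, co3)),
    40)

  # zero input kills every power term; all pixels equal the bias
  sp4 <- selfonn_layer_spec(2, 3, kernel_size = 3, q = 4, padding = 1)
  co4 <- taylor_coefficients(sp4, seed = 1)
  co4$bias <- c(-0.3, 0.1, 2)
  out <- selfonn_forward(array(0, c(2, 5, 5)), sp4, co4)
  for (o in 1:3) expect_true(all(out[o, , ] == co4$bias[o]))
})

test_that("vectorised forward agrees with the brute-force oracle", {
  set.seed(1234)
  for (r in 1:60) {
    q <- sample(1:4, 1)
    C <- sample(1:3, 1); O <- sample(1:3, 1)
    k <- sample(c(1L, 3L), 1)
    H <- sample(4:8, 1); W <- sample(4:8, 1)
    sp <- selfonn_layer_spec(C, O, k, q = q, stride = sample(1:2, 1),
                             padding = sample(0:1, 1))
    co <- taylor_coefficients(sp, seed = 1000 + r)
    co$bias <- stats::rnorm(O)
    x <- array(stats::runif(C * H * W, -1, 1), c(C, H, W))
    expect_lt(max(abs(selfonn_forward(x, sp, co) -
                      selfonn_forward_bruteforce(x, sp, co))), 1e-4)
  }
})

test_that("q = 1 equals a test-local plain cross-correlation", {
  # independent naive routine, written here rather than reusing the
  # package's brute-force path
  naive_xcorr <- function(x, w, b, pad) {
    C <- dim(x)[1]; H <- dim(x)[2]; W <- dim(x)[3]
    O <- dim(w)[1]; k <- dim(w)[3]
    out <- array(0, c(O, H + 2 * pad - k + 1, W + 2 * pad - k + 1))
    xp <- array(0, c(C, H + 2 * pad, W + 2 * pad))
    xp[, pad + seq_len(H), pad + seq_len(W)] <- x
    for (o in seq_len(O)) for (i in seq_len(dim(out)[2]))
      for (j in seq_len(dim(out)[3])) {
        acc <- b[o]
        for (c in seq_len(C))
          acc <- acc + sum(w[o, c, , ] *
                           xp[c, i:(i + k - 1), j:(j + k - 1)])
        out[o, i, j] <- acc
      }
    out
  }
  set.seed(77)
  sp <- selfonn_layer_spec(2, 2, 3, q = 1, padding = 1)
  co <- taylor_coefficients(sp, seed = 5)
  co$bias <- stats::rnorm(2)
  x <- array(stats::runif(2 * 6 * 6, -1, 1), c(2, 6, 6))
  w1 <- array(co$weights[1, , , , ], c(2, 2, 3, 3))
  expect_lt(max(abs(selfonn_forward(x, sp, co) -
                    naive_xcorr(x, w1, co$bias, 1))), 1e-5)
})

test_that("output is linear in the coefficients", {
  set.seed(3)
  sp <- selfonn_layer_spec(2, 2, 3, q = 3, padding = 1)
  co <- taylor_coefficients(sp, seed = 9)
  co$bias <- stats::rnorm(2)
  x <- array(stats::runif(2 * 6 * 6, -1, 1), c(2, 6, 6))
  y1 <- selfonn_forward(x, sp, co)
  co2 <- co
  co2$weights <- 2 * co$weights
  co2$bias <- 2 * co$bias
  expect_equal(selfonn_forward(x, sp, co2), 2 * y1, tolerance = 1e-12)
})

test_that("parameter-count formula holds on a grid and validation errors fire", {
  for (ic in c(1L, 2L, 3L)) for (oc in c(1L, 4L)) for (k in c(1L, 3L, 5L))
    for (q in c(1L, 2L, 5L)) {
      sp <- selfonn_layer_spec(ic, oc, k, q = q)
      co <- taylor_coefficients(sp, seed = 1)
      expect_identical(selfonn_param_count(sp),
                       length(co$weights) + length(co$bias))
      expect_equal(selfonn_param_count(sp), q * ic * oc * k^2 + oc)
    }
  expect_error(selfonn_layer_spec(1, 1, 3, q = 0), "q")
  expect_error(selfonn_layer_spec(1, 1, 4), "odd")
  sp <- selfonn_layer_spec(2, 1, 3)
  co <- taylor_coefficients(sp, seed = 1)
  expect_error(selfonn_forward(array(0, c(3, 5, 5)), sp, co), "channels")
  co$weights <- co$weights[, , 1, , , drop = FALSE]
  expect_error(selfonn_forward(array(0, c(2, 5, 5)), sp, co), "shape")
})
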