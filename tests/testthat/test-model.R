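test_that("channel bookkeeping follows the regime", {
  s17 <- model_spec(17, "GAM")
  expect_equal(s17$in_channels, 19L)   # mid image + pre image + 17 labels
  expect_equal(s17$out_channels, 17L)
  expect_equal(model_spec(17, "RM")$in_channels, 1L)
  expect_equal(model_spec(17, "PSM")$in_channels, 1L)
  expect_equal(model_spec(3, "GAM")$in_channels, 5L)
})

test_that("parameter count is a deterministic function of (C, S, width)", {
  n1 <- sum(adaptseg:::unet_layout(1, 3, 8)$n)
  n2 <- sum(adaptseg:::unet_layout(1, 3, 8)$n)
  expect_identical(n1, n2)
  expect_gt(sum(adaptseg:::unet_layout(1, 3, 16)$n), n1)
  expect_gt(sum(adaptseg:::unet_layout(5, 3, 8)$n), n1)
  net <- build_model(model_spec(3, "RM"), c(16, 16, 16), seed = 1)
  expect_equal(net$n_params, n1)
  net2 <- build_model(model_spec(3, "RM"), c(16, 16, 16), seed = 1)
  expect_identical(net$par, net2$par)
})

test_that("forward pass has the contracted shape and probability range", {
  net <- build_model(model_spec(2, "RM", width = 2), c(16, 16, 16), seed = 2)
  input <- array(rnorm(16^3), c(16, 16, 16, 1))
  p <- unet_predict(net, input)
  expect_equal(dim(p), c(16L, 16L, 16L, 2L))
  expect_true(all(p >= 0 & p <= 1))
})

test_that("indivisible grids raise an error naming the required padding", {
  expect_error(build_model(model_spec(2, "RM"), c(48, 48, 50)), "divisible by 16")
  expect_error(build_model(model_spec(2, "RM"), c(48, 48, 50)), "64")
  net <- build_model(model_spec(2, "RM", width = 2), c(16, 16, 16))
  expect_error(unet_predict(net, array(0, c(20, 16, 16, 1))), "divisible")
  expect_error(unet_predict(net, array(0, c(16, 16, 16, 3))), "channels")
})

test_that("output responds to intensity structure and channel order", {
  net <- build_model(model_spec(2, "GAM", width = 2), c(16, 16, 16), seed = 3)
  set.seed(4)
  input <- array(rnorm(16^3 * 4, sd = 0.3) + 0.5, c(16, 16, 16, 4))
  p1 <- unet_predict(net, input)
  # instance normalization makes the network exactly invariant to global
  # intensity rescaling (a calibration-robustness property; intensity
  # shifts are not exactly removed because the zero boundary padding does
  # not shift with them) ...
  p2 <- unet_predict(net, input * 2)
  expect_lt(max(abs(p1 - p2)), 1e-3)
  # ... but not to nonlinear intensity changes
  p2b <- unet_predict(net, pmax(input, 0.4))
  expect_gt(max(abs(p1 - p2b)), 1e-3)
  # permuting label channels changes predictions: order is contractual
  perm <- input[, , , c(1, 2, 4, 3)]
  p3 <- unet_predict(net, perm)
  expect_gt(max(abs(p1 - p3)), 1e-3)
})

test_that("backpropagation matches finite-difference gradients", {
  s <- tiny_net_setup()
  run <- function(p, grad = FALSE)
    adaptseg:::unet_run_cpp(p, s$S, s$w, s$d, s$input, s$target,
                            rep(1L, s$S), c(1.5, 0.5), 1, 1, 2, 1e-6,
                            grad, FALSE)
  g <- run(s$par, grad = TRUE)$grad
  set.seed(11)
  idx <- sample(length(s$par), 12)
  h <- 5e-3
  fd <- vapply(idx, function(i) {
    pp <- s$par; pp[i] <- pp[i] + h
    pm <- s$par; pm[i] <- pm[i] - h
    (run(pp)$loss - run(pm)$loss) / (2 * h)
  }, 1)
  # float32 forward: agreement to a few percent of the gradient scale
  expect_lt(max(abs(g[idx] - fd)), 0.1 * max(abs(fd)) + 1e-5)
})

test_that("absent structures receive identically zero gradients", {
  s <- tiny_net_setup()
  r_all <- adaptseg:::unet_run_cpp(s$par, s$S, s$w, s$d, s$input, s$target,
                                   c(1L, 1L), c(1, 1), 1, 1, 2, 1e-6, TRUE, FALSE)
  r_one <- adaptseg:::unet_run_cpp(s$par, s$S, s$w, s$d, s$input, s$target,
                                   c(1L, 0L), c(1, 1), 1, 1, 2, 1e-6, TRUE, FALSE)
  lay <- adaptseg:::unet_layout(s$C, s$S, s$w)
  fb <- lay[lay$name == "final_b", ]
  gb <- r_one$grad[fb$offset + seq_len(fb$n)]
  expect_identical(gb[2], 0)       # absent channel: zero bias gradient
  expect_gt(abs(gb[1]), 0)
  # and the loss of the absent structure does not contribute
  expect_false(isTRUE(all.equal(r_all$loss, r_one$loss)))
})

test_that("model weights round-trip through the spec sidecar", {
  net <- build_model(model_spec(c("a", "b"), "RM", width = 2), c(16, 16, 16),
                     seed = 5)
  base <- file.path(withr::local_tempdir(), "model")
  write_model(net, base)
  back <- read_model(base)
  expect_equal(back$par, net$par, tolerance = 1e-15)
  expect_equal(back$spec$structures, c("a", "b"))
  expect_equal(back$spec$in_channels, 1L)
})
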