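test_that("all-zero input leaves the network silent at rest", {
  net <- toy_net()
  r <- feed_forward_pass(net, c(0, 0))
  expect_equal(r$spikes_output, c(0L, 0L))
  expect_equal(r$v_output_final, rep(net$params$v_l, 2))
  expect_equal(r$act_hidden, c(0, 0))
})

test_that("drive is monotone: all-ones input beats all-zero input", {
  net <- toy_net()
  r0 <- feed_forward_pass(net, c(0, 0))
  r1 <- feed_forward_pass(net, c(1, 1))
  expect_true(all(r1$v_hidden_final > r0$v_hidden_final |
                    r1$spikes_hidden > r0$spikes_hidden))
  expect_true(all(r1$act_hidden > r0$act_hidden))
  expect_error(feed_forward_pass(net, c(1, 1), window = 0.01),
               "shorter than one time step")
})

test_that("feed-forward potentials match the deSolve oracle within 1%", {
  skip_if_not_installed("deSolve")
  p <- lif_params()
  net <- vpsnn_network(2, 2, 2, schedule = vpsnn_schedule(window = 100),
                       seed = 5)
  # printed-in-test weights, subthreshold regime
  net$w1 <- matrix(c(0.08, 0.03, 0.05, 0.09), 2, 2)
  net$w2 <- matrix(c(0.10, 0.04, 0.06, 0.12), 2, 2)
  input <- c(1, 0.5)
  r <- feed_forward_pass(net, input, fb = 0)
  orc <- oracle_toy_net(net$w1, net$w2, input, p, p$eta, 100)
  expect_equal(r$spikes_hidden, c(0L, 0L))
  span <- p$v_th - p$v_l
  expect_lt(max(abs(r$v_hidden_final - orc$v_hidden)) / span, 0.01)
  expect_lt(max(abs(r$v_output_final - orc$v_output)) / span, 0.01)
})

test_that("the homeostatic correction vanishes identically at full blend", {
  net <- toy_net()
  a <- feed_forward_pass(net, c(1, 0), blend = 1)
  sch <- net$schedule
  sch$eta_i <- 0
  net2 <- net
  net2$schedule <- sch
  b <- feed_forward_pass(net2, c(1, 0), blend = 0.37)
  expect_identical(a$v_output_final, b$v_output_final)
  expect_identical(a$act_hidden, b$act_hidden)
})

test_that("a linearly separable two-pattern task trains to 100%", {
  net <- train_vpsnn(toy_net(seed = 3), toy_samples())
  expect_true(net$converged)
  expect_equal(vpsnn_accuracy(net, toy_samples()), 1)
  # exhaustive evaluation of both patterns
  labs <- vapply(toy_samples(), function(s) {
    decode_output(feed_forward_pass(net, s$input)$act_output, net$labels)
  }, character(1))
  expect_identical(labs, c("a", "b"))
  expect_false(is.null(net$history))
  expect_true(all(c("loss", "imbalance_hidden") %in% names(net$history)))
})

test_that("training is bit-identical under the same seed", {
  n1 <- train_vpsnn(toy_net(seed = 9), toy_samples())
  n2 <- train_vpsnn(toy_net(seed = 9), toy_samples())
  expect_identical(n1$w1, n2$w1)
  expect_identical(n1$w2, n2$w2)
  expect_identical(n1$history, n2$history)
})

test_that("an epoch of all-zero presynaptic input changes no weight", {
  net <- toy_net(seed = 4, epochs = 1)
  zero_samples <- list(list(input = c(0, 0), target = 1L),
                       list(input = c(0, 0), target = 2L))
  sch <- net$schedule
  sch$max_epochs <- 1
  sch$decay <- 0  # isolate the consolidation rule from synaptic decay
  trained <- train_vpsnn(net, zero_samples, schedule = sch)
  expect_identical(trained$w1, net$w1)
  expect_identical(trained$w2, net$w2)
})

test_that("network imbalance does not grow over the homeostatic-dominated epochs", {
  net <- train_vpsnn(toy_net(seed = 6, epochs = 30), toy_samples())
  h <- net$history
  early <- h[h$blend < 0.2, ]
  # allow small fluctuation, no systematic growth while homeostasis dominates
  expect_lt(early$imbalance_hidden[nrow(early)],
            early$imbalance_hidden[1] * 1.05 + 0.01)
})

test_that("sample and target validation reject mismatched shapes", {
  net <- toy_net()
  expect_error(train_vpsnn(net, list(list(input = c(1, 0, 0), target = 1L))),
               "input length")
  expect_error(train_vpsnn(net, list(list(input = c(1, 0), target = 5L))),
               "target outside")
})

test_that("checkpoints round-trip through JSON", {
  net <- train_vpsnn(toy_net(seed = 8), toy_samples())
  path <- tempfile(fileext = ".json")
  write_vpsnn(net, path)
  back <- read_vpsnn(path)
  expect_equal(back$w1, net$w1)
  expect_equal(back$w2, net$w2)
  expect_identical(back$labels, net$labels)
  expect_identical(back$converged, net$converged)
  r1 <- feed_forward_pass(net, c(1, 0))
  r2 <- feed_forward_pass(back, c(1, 0))
  expect_equal(r1$act_output, r2$act_output)
  unlink(path)
})
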