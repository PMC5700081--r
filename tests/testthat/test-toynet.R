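test_that("toy net construction is deterministic and validates layers", {
  a <- build_toy_net(toy_net_spec(seed = 7))
  b <- build_toy_net(toy_net_spec(seed = 7))
  x <- test_image(12, 12, seed = 3)
  expect_identical(toy_net_forward(a, x), toy_net_forward(b, x))
  c <- build_toy_net(toy_net_spec(seed = 8))
  expect_false(identical(a$layers[[1]]$w, c$layers[[1]]$w))
  expect_error(toy_net_spec(layer_defs = list(list(id = "x", type = "fft"))),
               "unknown layer operation")
  expect_error(
    toy_net_spec(layer_defs = list(list(id = "a", type = "relu"),
                                   list(id = "a", type = "relu"))),
    "unique")
})

test_that("zero input through zero-bias convolutions gives zero activations", {
  net <- test_net()
  z <- array(0, dim = c(10, 10, 3))
  acts <- toy_net_forward(net, z)
  for (a in acts) expect_true(all(a == 0))
})

test_that("forward pass matches a direct nested-loop convolution oracle", {
  for (padding in c("circular", "zero")) {
    net <- test_net(seed = 5, padding = padding)
    x <- test_image(16, 16, seed = 9)
    acts <- toy_net_forward(net, x)
    cur <- x
    for (l in net$layers) {
      cur <- if (l$type == "conv") conv_oracle(cur, l$w, l$bias, padding)
             else pmax(cur, 0)
    }
    expect_equal(acts[["relu3"]], cur, tolerance = 1e-12)
  }
})

test_that("input gradient matches central finite differences", {
  net <- test_net(seed = 2)
  x <- test_image(16, 16, seed = 4)
  g <- input_gradient(net, x, "relu3")
  obj <- function(img) {
    a <- toy_net_forward(net, img, "relu3")
    dream_objective(a[["relu3"]])
  }
  eps <- 1e-3
  idx <- seq(1, length(x), by = 7)  # ~110 pixels across all channels
  for (i in idx) {
    xp <- x; xp[i] <- xp[i] + eps
    xm <- x; xm[i] <- xm[i] - eps
    fd <- (obj(xp) - obj(xm)) / (2 * eps)
    expect_lt(abs(fd - g[i]) / max(abs(fd), 1e-8), 1e-3)
  }
})

test_that("gradient scales linearly with the objective", {
  net <- test_net()
  x <- test_image(12, 12, seed = 6)
  g1 <- input_gradient(net, x, "relu2")
  # doubling every activation's contribution doubles the seed gradient;
  # realized by comparing against a net-level rescale of the objective
  a <- toy_net_forward(net, x, "relu2")[["relu2"]]
  expect_equal(dream_objective(2 * a), 4 * dream_objective(a))
  # gradient of the single-channel objective sums to the full one
  gs <- Reduce(`+`, lapply(seq_len(dim(a)[3]), function(ch) {
    input_gradient(net, x, "relu2", channel = ch)
  }))
  expect_equal(gs, g1, tolerance = 1e-10)
})

test_that("zero image has zero gradient (dead rectifiers)", {
  net <- test_net()
  z <- array(0, dim = c(10, 10, 3))
  expect_true(all(input_gradient(net, z, "relu3") == 0))
})

test_that("max-pool layers forward and backpropagate correctly", {
  spec <- toy_net_spec(layer_defs = list(
    list(id = "conv1", type = "conv", kernel = 3L, out_channels = 4L),
    list(id = "relu1", type = "relu"),
    list(id = "pool1", type = "pool"),
    list(id = "conv2", type = "conv", kernel = 3L, out_channels = 4L),
    list(id = "relu2", type = "relu")
  ), seed = 3)
  net <- build_toy_net(spec)
  x <- test_image(16, 16, seed = 8)
  acts <- toy_net_forward(net, x)
  expect_equal(dim(acts[["pool1"]]), c(8, 8, 4))
  expect_equal(acts[["pool1"]][1, 1, 1], max(acts[["relu1"]][1:2, 1:2, 1]))
  g <- input_gradient(net, x, "relu2")
  obj <- function(img) dream_objective(toy_net_forward(net, img, "relu2")[["relu2"]])
  eps <- 1e-3
  for (i in seq(1, length(x), by = 37)) {
    xp <- x; xp[i] <- xp[i] + eps
    xm <- x; xm[i] <- xm[i] - eps
    fd <- (obj(xp) - obj(xm)) / (2 * eps)
    expect_lt(abs(fd - g[i]) / max(abs(fd), 1e-6), 1e-3)
  }
})

test_that("unknown layer id raises a configuration error", {
  net <- test_net()
  x <- test_image(8, 8)
  expect_error(toy_net_forward(net, x, "inception_4d/pool"), "unknown layer id")
})
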