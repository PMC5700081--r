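test_that("dream objective closed forms hold", {
  expect_equal(dream_objective(array(0, c(2, 2, 3))), 0)
  k <- 2 * 3 * 4
  expect_equal(dream_objective(array(1, c(2, 3, 4))), k / 2)
  a <- test_image(4, 4, seed = 1)
  expect_equal(dream_objective(2 * a), 4 * dream_objective(a))
  expect_error(dream_objective(numeric(0)), "empty")
})

test_that("octave sizes follow the round-half-away rule and end at base", {
  expect_equal(octave_sizes(c(64, 64), 1, 1.8), list(c(64L, 64L)))
  expect_equal(octave_sizes(c(100, 100), 3, 1.8),
               list(c(31L, 31L), c(56L, 56L), c(100L, 100L)))
  expect_equal(octave_sizes(c(64, 64), 2, 2),
               list(c(32L, 32L), c(64L, 64L)))
  expect_error(octave_sizes(c(20, 20), 3, 1.8), "8 px")
})

test_that("zero-step ascent and zero-iteration dreams are identities", {
  net <- test_net()
  x <- test_image(24, 24, seed = 5)
  set.seed(1)
  expect_equal(ascent_step(x, net, "relu3", step_size = 0, jitter = 4), x)
  cfg <- dream_config("relu3", octaves = 1L, iterations = 0L, seed = 2)
  expect_identical(dream_image(x, net, cfg), x)
  cfg3 <- dream_config("relu3", octaves = 2L, octave_scale = 2,
                       iterations = 0L, seed = 2)
  expect_equal(dream_image(x, net, cfg3), x, tolerance = 1e-12)
})

test_that("an ascent step increases the objective", {
  net <- test_net()
  x <- test_image(32, 32, seed = 7)
  obj <- function(img) dream_objective(toy_net_forward(net, img, "relu3")[["relu3"]])
  set.seed(3)
  y <- ascent_step(x, net, "relu3", step_size = 1.5, jitter = 0)
  expect_gt(obj(y), obj(x))
  # at a small step the first-order ascent property holds stepwise too
  z <- x
  for (i in 1:5) {
    z2 <- ascent_step(z, net, "relu3", step_size = 0.1, jitter = 0)
    expect_gt(obj(z2), obj(z))
    z <- z2
  }
})

test_that("dreaming is equivariant to cyclic shifts with a periodic net", {
  net <- test_net(padding = "circular")
  x <- test_image(24, 24, seed = 9)
  cfg <- dream_config("relu3", octaves = 1L, iterations = 4L, jitter = 0L,
                      seed = 4)
  a <- dream_image(x, net, cfg)
  b <- dream_image(roll_image(x, 0, 5), net, cfg)
  expect_equal(roll_image(a, 0, 5), b, tolerance = 1e-9)
})

test_that("full dream increases the objective and is seed-deterministic", {
  net <- test_net()
  x <- test_image(48, 48, seed = 12)
  cfg <- fast_config()
  obj <- function(img) dream_objective(toy_net_forward(net, img, "relu3")[["relu3"]])
  out <- dream_image(x, net, cfg)
  expect_gt(obj(out), obj(x))
  expect_identical(out, dream_image(x, net, cfg))
  expect_true(all(out >= 0 & out <= 255))
  # with the periodic toy net, cyclic jitter is exactly undone by
  # shift-equivariance, so the jitter seed only matters for nets with
  # boundary effects: assert seed sensitivity on a zero-padding net
  netz <- test_net(padding = "zero")
  cfg2 <- fast_config(); cfg2$seed <- 99L
  expect_false(identical(dream_image(x, netz, fast_config()),
                         dream_image(x, netz, cfg2)))
})

test_that("shallow and deep layers dream different textures", {
  net <- test_net()
  x <- test_image(32, 32, seed = 13)
  lo <- dream_image(x, net, fast_config(layer_id = dream_preset_layer("lower", net)))
  hi <- dream_image(x, net, fast_config(layer_id = dream_preset_layer("higher", net)))
  expect_gt(mean(abs(lo - hi)), 0)
  expect_identical(dream_preset_layer("lower", net), "relu1")
  expect_identical(dream_preset_layer("middle", net), "relu2")
  expect_identical(dream_preset_layer("higher", net), "relu3")
})

test_that("zoom crops the centre and preserves dimensions", {
  x <- test_image(16, 16, seed = 2)
  expect_identical(apply_zoom(x, 1), x)
  expect_equal(dim(apply_zoom(x, 2)), dim(x))
  # zoom = 2 on 4x4: central 2x2 block upsampled with the bilinear kernel;
  # oracle computed by hand from the half-pixel-centre convention:
  # output pixel centres sample source coords (-0.25, 0.25, 0.75, 1.25)
  # within the crop, i.e. edge-clamped weights (1, .75/.25, .25/.75, 1).
  m <- array(0, c(4, 4, 3))
  m[, , 1] <- matrix(c(0, 1, 0, 1,
                       1, 0, 1, 0,
                       0, 1, 0, 1,
                       1, 0, 1, 0), 4, 4, byrow = TRUE)
  z <- apply_zoom(m, 2)
  crop <- m[2:3, 2:3, 1]  # 0 1 / 1 0
  wts <- rbind(c(1, 0), c(0.75, 0.25), c(0.25, 0.75), c(0, 1))
  oracle <- wts %*% crop %*% t(wts)
  expect_equal(z[, , 1], oracle, tolerance = 1e-12)
  expect_error(apply_zoom(test_image(4, 4), 4), "2 px")
})
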