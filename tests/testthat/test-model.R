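test_that("transfer mode without pretrained weights names the compact fallback", {
  cfg <- fall_cnn_config(mode = "transfer_alexnet")
  expect_error(fall_cnn_init(cfg), "compact")
  expect_error(fall_cnn_init(cfg), "pretrained")
})

test_that("the output layer has exactly two units and softmax normalizes", {
  net <- fall_cnn_init(fall_cnn_config(seed = 8))
  expect_equal(ncol(net$fc2$W), 2L)
  expect_equal(net$classes, c("not_fall", "fall"))

  img <- make_toy_image("burst", seed = 1)
  p <- predict(net, img)
  expect_equal(p$p_fall + p$p_not_fall, 1, tolerance = 1e-9)
  expect_true(p$p_fall >= 0 && p$p_fall <= 1)
  # Inference is deterministic.
  expect_identical(predict(net, img), predict(net, img))
})

test_that("initialization and training are seed-deterministic", {
  cfg <- fall_cnn_config(seed = 21)
  n1 <- fall_cnn_init(cfg)
  n2 <- fall_cnn_init(cfg)
  expect_identical(n1$conv, n2$conv)
  expect_identical(n1$fc1, n2$fc1)

  toy <- make_toy_set(6, seed = 2)
  cfg <- fall_cnn_config(epochs = 2, seed = 21)
  m1 <- fall_cnn(toy$images, toy$labels, cfg)
  m2 <- fall_cnn(toy$images, toy$labels, cfg)
  expect_identical(m1$conv, m2$conv)
  expect_identical(m1$history, m2$history)
})

test_that("backpropagation matches finite-difference gradients", {
  cfg <- fall_cnn_config(stem_size = 16, filters = c(2, 2, 2, 2),
                         dense_units = 4, seed = 3)
  net <- fall_cnn_init(cfg)
  set.seed(42)
  x <- array(runif(16 * 16 * 3) - 0.5, dim = c(16, 16, 3))
  attr(x, "stemmed") <- TRUE
  fw <- fallradar:::cnn_forward(net, x, keep = TRUE)
  gr <- fallradar:::cnn_backward(net, fw$cache, fw$probs - c(0, 1))
  loss_at <- function(n) -log(fallradar:::cnn_forward(n, x)$probs[2])
  base <- loss_at(net)
  eps <- 1e-6
  for (l in c(1, 3)) {
    for (rep in 1:3) {
      i <- sample(nrow(net$conv[[l]]$W), 1)
      j <- sample(ncol(net$conv[[l]]$W), 1)
      n2 <- net
      n2$conv[[l]]$W[i, j] <- n2$conv[[l]]$W[i, j] + eps
      expect_equal((loss_at(n2) - base) / eps, gr$conv[[l]]$W[i, j],
        tolerance = 1e-4
      )
    }
  }
  for (nm in c("fc1", "fc2")) {
    i <- sample(nrow(net[[nm]]$W), 1)
    j <- sample(ncol(net[[nm]]$W), 1)
    n2 <- net
    n2[[nm]]$W[i, j] <- n2[[nm]]$W[i, j] + eps
    expect_equal((loss_at(n2) - base) / eps, gr[[nm]]$W[i, j], tolerance = 1e-4)
  }
})

test_that("a separable toy problem is learned to 100% and generalizes", {
  toy <- make_toy_set(40, seed = 7)
  cfg <- fall_cnn_config(epochs = 10, seed = 7)
  net <- fall_cnn(toy$images, toy$labels, cfg)
  expect_equal(net$history$accuracy[nrow(net$history)], 1)

  held_out <- make_toy_image("burst", seed = 9999)
  expect_equal(predict(net, held_out, type = "class"), "fall")
  held_low <- make_toy_image("low", seed = 8888)
  expect_equal(predict(net, held_low, type = "class"), "not_fall")
})

test_that("permuted labels cannot be learned much above chance", {
  toy <- make_toy_set(30, seed = 11)
  set.seed(13)
  shuffled <- sample(toy$labels)
  cfg <- fall_cnn_config(epochs = 3, seed = 11, patience = 99)
  net <- fall_cnn(toy$images, shuffled, cfg)
  acc <- net$history$accuracy[nrow(net$history)]
  expect_gte(acc, 0.35)
  expect_lte(acc, 0.65)
})

test_that("degenerate training inputs are rejected", {
  toy <- make_toy_set(2, seed = 1)
  expect_error(
    fall_cnn(toy$images, rep("fall", 4)),
    "single-class"
  )
  expect_error(
    fall_cnn(toy$images, c("fall", "cat", "not_fall", "fall")),
    "cat"
  )
  net <- fall_cnn_init(fall_cnn_config())
  bad <- array(0, dim = c(100, 100, 3))
  err <- tryCatch(predict(net, bad), error = conditionMessage)
  expect_match(err, "100, 100, 3")
  expect_match(err, "227, 227, 3")
})
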