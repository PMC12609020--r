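test_that("the network architecture matches the configured geometry", {
  cfg <- cnn_config()
  expect_equal(cfg$filters, c(16L, 32L, 64L))
  model <- build_cnn(cfg, input_resolution = 128)
  # three 2x max-pools: 128 -> 16 spatial map before the dense layer
  expect_equal(model$blocks[[3]]$H / 2, 16)
  expect_equal(model$feat_dim, 64 * 16 * 16)
  expect_gt(model$n_parameters, 0)
  expect_error(build_cnn(cfg, input_resolution = 100), "multiple of 8")
  expect_error(cnn_config(filters = c(32, 16, 8)))
})

test_that("initialisation is seed-deterministic and softmax normalises", {
  cfg <- cnn_config(seed = 5)
  m1 <- build_cnn(cfg, 8)
  m2 <- build_cnn(cfg, 8)
  expect_identical(m1$blocks[[1]]$W, m2$blocks[[1]]$W)
  expect_identical(m1$fc$W, m2$fc$W)
  set.seed(1)
  Xs <- lapply(1:3, function(i) array(runif(8 * 8 * 3), c(8, 8, 3)))
  fwd <- vagdfa:::cnn_forward(m1, Xs, training = FALSE)
  expect_equal(colSums(fwd$probs), rep(1, 3), tolerance = 1e-12)
})

test_that("backpropagation matches finite-difference gradients", {
  cfg <- cnn_config(dropout = 0, seed = 3)
  model <- build_cnn(cfg, input_resolution = 8)
  set.seed(2)
  Xs <- lapply(1:4, function(i) array(runif(8 * 8 * 3), c(8, 8, 3)))
  y <- c(1L, 2L, 1L, 2L)
  fwd <- vagdfa:::cnn_forward(model, Xs, training = TRUE)
  gr <- vagdfa:::cnn_backward(model, fwd, y)
  check_param <- function(get_model, grad, n_checks = 4) {
    p <- get_model(model)
    idx <- sample(length(p), n_checks)
    for (i in idx) {
      eps <- 1e-5
      for (sgn in c(1, -1)) {
        m2 <- model
        p2 <- p; p2[i] <- p[i] + sgn * eps
        m2 <- attr(get_model, "set")(m2, p2)
        f2 <- vagdfa:::cnn_forward(m2, Xs, training = TRUE)
        if (sgn > 0) lp <- vagdfa:::cnn_loss(m2, f2, y)
        else lm_ <- vagdfa:::cnn_loss(m2, f2, y)
      }
      num <- (lp - lm_) / (2e-5)
      expect_equal(grad[i], num, tolerance = 1e-4)
    }
  }
  for (b in 1:3) for (nm in c("W", "gamma", "beta")) {
    getter <- function(m) m$blocks[[b]][[nm]]
    attr(getter, "set") <- local({
      bb <- b; nn <- nm
      function(m, p) { m$blocks[[bb]][[nn]] <- p; m }
    })
    check_param(getter, gr$blocks[[b]][[nm]], n_checks = 3)
  }
  getter <- function(m) m$fc$W
  attr(getter, "set") <- function(m, p) { m$fc$W <- p; m }
  check_param(getter, gr$fc$W, n_checks = 4)
})

test_that("the HC-probability threshold rule is inclusive at the boundary", {
  expect_equal(apply_threshold(0.71), "HC")
  expect_equal(apply_threshold(0.69), "OA")
  expect_equal(apply_threshold(0.70), "HC")
  expect_equal(apply_threshold(c(0.9, 0.1)), c("HC", "OA"))
  expect_error(apply_threshold(1.2), "\\[0, 1\\]")
  # monotone thresholding: raising the cutoff cannot add HC predictions
  set.seed(17)
  p <- runif(100)
  expect_lte(sum(apply_threshold(p, 0.7) == "HC"),
             sum(apply_threshold(p, 0.5) == "HC"))
})

test_that("augmentation warps a copy and leaves the input untouched", {
  set.seed(18)
  img <- array(runif(32 * 32 * 3), c(32, 32, 3))
  orig <- img
  aug <- augment_image(img)
  expect_identical(img, orig)
  expect_equal(dim(aug), dim(img))
  expect_false(identical(aug, img))
  expect_true(all(aug >= 0 & aug <= 1 + 1e-9))
})

test_that("a short training run learns trivially separable images", {
  # bright-left vs bright-right synthetic images; tiny resolution for speed
  set.seed(19)
  make <- function(cls) {
    a <- array(runif(16 * 16 * 3, 0, 0.3), c(16, 16, 3))
    if (cls == "HC") a[, 1:8, ] <- a[, 1:8, ] + 0.6 else a[, 9:16, ] <- a[, 9:16, ] + 0.6
    a
  }
  imgs <- c(lapply(1:10, function(i) make("HC")), lapply(1:10, function(i) make("OA")))
  labs <- rep(c("HC", "OA"), each = 10)
  cfg <- cnn_config(epochs = 8, batch = 8, seed = 7)
  r <- cnn_train_cv(imgs, labs, cfg, augment = FALSE, k = 2)
  expect_gte(r$summary$mean[r$summary$metric == "accuracy"], 0.9)
})
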