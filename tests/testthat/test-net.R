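test_that("parameter count matches an independent closed-form sum", {
  cfg <- net_config()
  m <- build_model(cfg, seed = 1L)
  # independent spreadsheet-style oracle over the printed schedules
  ch <- c(32, 64, 128, 256, 512); a3 <- c(15, 13, 11, 9, 7)
  a5 <- c(1, 5, 1, 1, 5); y <- c(256, 128, 64, 32); m2 <- c(1, 1, 1, 5)
  cin <- c(1, ch[-5])
  total <- 0
  for (j in 1:5) {
    total <- total + 9 * cin[j] * ch[j] + ch[j] + 9 * ch[j]^2 + ch[j]  # basic
    total <- total + 9 * cin[j] * ch[j] + ch[j] + 9 * ch[j]^2 + ch[j]  # E a1,a2
    total <- total + a3[j] * cin[j] * ch[j] + ch[j] +
      a3[j] * ch[j]^2 + ch[j]                                          # E r1,r2
    total <- total + 9 * ch[j]^2 + ch[j] + a5[j]^2 * ch[j]^2 + ch[j]   # E a4,a5
  }
  xc <- 2 * ch[5]
  for (j in 1:4) {
    lev <- 5 - j
    total <- total + 4 * xc^2 + xc                      # 2x2 deconv
    total <- total + 9 * (xc + 2 * ch[lev]) * y[j] + y[j]
    total <- total + m2[j]^2 * y[j]^2 + y[j]
    total <- total + 9 * (y[j] + ch[lev]) * y[j] + y[j]
    xc <- y[j]
  }
  total <- total + y[4] * 1 + 1
  expect_equal(count_parameters(m), total)
  expect_equal(sum(layer_table(cfg)$params), total)
})

test_that("single-layer parameter counts follow k_h*k_w*c_in*c_out + c_out", {
  lt <- layer_table(net_config())
  expect_equal(lt$params[lt$name == "B1.c1"], 3 * 3 * 1 * 32 + 32)  # 320
  expect_equal(lt$params[lt$name == "E1.r1"], 15 * 1 * 1 * 32 + 32) # 512
})

test_that("shape contract holds and taps follow the channel schedules", {
  cfg <- tiny_net_config()
  m <- build_model(cfg, seed = 2L)
  fw <- model_forward(m, matrix(runif(32 * 32), 32, 32))
  expect_equal(dim(fw$prob), c(32L, 32L))
  expect_true(all(fw$prob > 0 & fw$prob < 1))
  for (j in 1:5) {
    side <- 32L / 2L^(j - 1L)
    expect_equal(dim(fw$cache$B[[j]]$t1),
                     c(side, side, cfg$channels[j]))
    expect_equal(dim(fw$cache$B[[j]]$t2),
                     c(side, side, cfg$channels[j]))
    expect_equal(dim(fw$cache$E[[j]]$fused),
                     c(side, side, cfg$channels[j]))
  }
  # block 5 un-pooled: bottleneck is the two 2x2 block-5 outputs
  expect_equal(dim(fw$cache$U[[1]]$x_in),
                   c(2L, 2L, 2L * cfg$channels[5]))
  expect_error(model_forward(m, matrix(0, 24, 24)), "divisible by 16")
})

test_that("zero input with zero biases yields zero taps and probability 1/2", {
  m <- build_model(tiny_net_config(), seed = 3L)
  fw <- model_forward(m, matrix(0, 32, 32))
  expect_true(all(fw$cache$B[[1]]$t1 == 0))
  expect_true(all(fw$cache$E[[3]]$fused == 0))
  expect_true(all(fw$prob == 0.5))
})

test_that("separable row-column delta kernels act as the identity", {
  x <- array(runif(20 * 20), c(20, 20, 1))
  k <- 15L
  w_col <- matrix(0, k, 1); w_col[(k + 1) / 2, 1] <- 1   # 15x1, center tap
  w_row <- matrix(0, k, 1); w_row[(k + 1) / 2, 1] <- 1   # 1x15, center tap
  mid <- estan:::conv2d_fwd(x, w_col, 0, k, 1L, TRUE)
  out <- estan:::conv2d_fwd(mid, w_row, 0, 1L, k, TRUE)
  expect_equal(out, x, tolerance = 1e-12)
})

test_that("row-column branch has the configured receptive footprint", {
  # linear regime: positive input, non-negative kernels, zero bias
  set.seed(8)
  k <- 15L; n <- 41L; ctr <- 21L
  w1 <- matrix(abs(rnorm(k)), k, 1)
  w2 <- matrix(abs(rnorm(k)), k, 1)
  x <- array(runif(n * n), c(n, n, 1))
  path <- function(z) estan:::conv2d_fwd(
    estan:::conv2d_fwd(z, w1, 0, k, 1L, TRUE), w2, 0, 1L, k, TRUE)
  full <- path(x)[ctr, ctr, 1]
  win <- (k - 1L) / 2L
  xz <- x * 0
  rows <- (ctr - win):(ctr + win)
  xz[rows, rows, 1] <- x[rows, rows, 1]
  expect_equal(path(xz)[ctr, ctr, 1], full, tolerance = 1e-12)
  # and a strictly smaller window changes the output
  xs <- x * 0
  rows2 <- (ctr - win + 1L):(ctr + win - 1L)
  xs[rows2, rows2, 1] <- x[rows2, rows2, 1]
  expect_false(isTRUE(all.equal(path(xs)[ctr, ctr, 1], full,
                                tolerance = 1e-12)))
})

test_that("analytic gradients match central finite differences", {
  cfg <- net_config(channels = c(2L, 3L, 4L, 5L, 6L),
                    rowcol_sizes = c(5L, 5L, 3L, 3L, 3L),
                    a5_sizes = c(1L, 3L, 1L, 1L, 3L),
                    decoder_channels = c(6L, 4L, 3L, 2L))
  m <- build_model(cfg, seed = 4L)
  img <- matrix(runif(32 * 32), 32, 32)
  target <- matrix(0, 32, 32); target[10:20, 12:22] <- 1
  fw <- model_forward(m, img)
  g <- model_backward(m, fw$cache, estan:::dice_loss_grad(fw$prob, target))
  lossfn <- function(mm)
    dice_loss(model_forward(mm, img, want_cache = FALSE)$prob, target)
  set.seed(5)
  eps <- 1e-6
  for (nm in c("B1.c1", "E2.r1", "E4.a5", "U1.up", "U3.c2", "head")) {
    wd <- dim(m$params[[nm]]$w)
    for (rep in 1:2) {
      i <- sample(wd[1], 1); j <- sample(wd[2], 1)
      mp <- m; mp$params[[nm]]$w[i, j] <- mp$params[[nm]]$w[i, j] + eps
      mn <- m; mn$params[[nm]]$w[i, j] <- mn$params[[nm]]$w[i, j] - eps
      num <- (lossfn(mp) - lossfn(mn)) / (2 * eps)
      expect_equal(g[[nm]]$w[i, j], num, tolerance = 1e-4)
    }
  }
})

test_that("no branch is dead: every parameter tensor receives gradient", {
  m <- build_model(tiny_net_config(), seed = 6L)
  img <- matrix(runif(32 * 32), 32, 32)
  target <- random_blob(32L, seed = 77L)
  fw <- model_forward(m, img)
  g <- model_backward(m, fw$cache, estan:::dice_loss_grad(fw$prob, target))
  for (nm in names(m$params)) {
    expect_true(any(g[[nm]]$w != 0), info = nm)
    expect_true(any(g[[nm]]$b != 0), info = nm)
  }
})

test_that("quartering the width shrinks the parameter count ~16-fold", {
  full <- sum(layer_table(net_config())$params)
  quarter <- sum(layer_table(quarter_width_config())$params)
  expect_gt(full / quarter, 14)
  expect_lt(full / quarter, 17)
})

test_that("nearest-neighbour upsampling variant preserves the shape contract", {
  cfg <- tiny_net_config()
  cfg$upsample <- "nearest"
  m <- build_model(cfg, seed = 9L)
  fw <- model_forward(m, matrix(runif(32 * 32), 32, 32))
  expect_identical(dim(fw$prob), c(32L, 32L))
  expect_true(all(fw$prob > 0 & fw$prob < 1))
})
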