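# Model assembly and the hand-rolled forward/backward passes.
#
# The architecture is a fixed topology, so rather than a generic autograd
# graph the backward pass is written out explicitly, mirroring the forward
# pass layer by layer.  All heavy kernels live in src/conv_ops.cpp; this
# file only does the plumbing (branching, concatenation, skip routing).

as_cube <- function(x) {
  if (is.matrix(x)) array(x, dim = c(nrow(x), ncol(x), 1L)) else x
}

cat3 <- function(...) {
  parts <- list(...)
  d <- dim(parts[[1L]])
  array(unlist(parts, use.names = FALSE),
        dim = c(d[1L], d[2L], sum(vapply(parts, function(p) dim(p)[3L], 0))))
}

slice3 <- function(x, from, n) {
  x[, , from:(from + n - 1L), drop = FALSE]
}

#' Build an ESTAN model from a configuration
#'
#' Instantiates every convolution of [layer_table()] with He-uniform
#' weights (`limit = sqrt(6 / fan_in)`, the standard choice for ReLU
#' layers) and zero biases.  Initialization is driven by R's RNG, so a
#' fixed `seed` gives a bit-identical model.
#'
#' @param config an [net_config()] object.
#' @param seed integer seed for weight initialization.
#' @return An object of class `estan_model`: the configuration, the layer
#'   table, and a named list of parameter tensors.
#' @examples
#' m <- build_model(net_config(channels = c(2, 2, 4, 4, 8)), seed = 1)
#' count_parameters(m)
#' @export
build_model <- function(config = net_config(), seed = 1L) {
  stopifnot(inherits(config, "estan_net_config"))
  lt <- layer_table(config)
  set.seed(seed)
  params <- vector("list", nrow(lt))
  names(params) <- lt$name
  for (i in seq_len(nrow(lt))) {
    r <- lt[i, ]
    if (r$type == "deconv") {
      fan_in <- r$cin
      w <- matrix(runif(r$cin * 4L * r$cout, -1, 1) * sqrt(6 / fan_in),
                  nrow = r$cin)
    } else {
      fan_in <- r$kh * r$kw * r$cin
      w <- matrix(runif(fan_in * r$cout, -1, 1) * sqrt(6 / fan_in),
                  nrow = fan_in)
    }
    params[[i]] <- list(w = w, b = numeric(r$cout))
  }
  structure(list(config = config, layers = lt, params = params),
            class = "estan_model")
}

#' Count trainable parameters of a built model
#'
#' @param model an `estan_model`.
#' @return Integer scalar: the number of trainable scalars actually stored
#'   (weights plus biases).
#' @export
count_parameters <- function(model) {
  stopifnot(inherits(model, "estan_model"))
  sum(vapply(model$params, function(p) length(p$w) + length(p$b), 0))
}

#' @export
print.estan_model <- function(x, ...) {
  cat(sprintf("ESTAN model: %d conv layers, %s parameters\n",
              nrow(x$layers), format(count_parameters(x), big.mark = ",")))
  print(x$config)
  invisible(x)
}

layer_meta <- function(model, name) {
  model$layers[match(name, model$layers$name), ]
}

conv_f <- function(model, name, x) {
  m <- layer_meta(model, name)
  p <- model$params[[name]]
  conv2d_fwd(x, p$w, p$b, m$kh, m$kw, m$relu)
}

conv_b <- function(model, name, x, y, dy) {
  m <- layer_meta(model, name)
  p <- model$params[[name]]
  conv2d_bwd(x, p$w, y, dy, m$kh, m$kw, m$relu)
}

#' Forward pass of an ESTAN model
#'
#' Runs both encoders in parallel on the input, concatenates the two
#' un-pooled block-5 outputs into the bottleneck, applies the four up
#' blocks with their three-way skip connections, and the 1x1 sigmoid head.
#'
#' @param model an `estan_model`.
#' @param x numeric matrix (H x W, values in any range; typically [0,1])
#'   with both sides divisible by 16 (four pooling stages).
#' @param want_cache keep every intermediate activation for
#'   [model_backward()]; switch off for inference to save memory.
#' @return list with `prob` (H x W matrix strictly inside (0,1)) and,
#'   when requested, `cache`.
#' @export
model_forward <- function(model, x, want_cache = TRUE) {
  stopifnot(inherits(model, "estan_model"))
  x <- as_cube(x)
  H <- dim(x)[1L]; W <- dim(x)[2L]
  if (H %% 16 != 0 || W %% 16 != 0)
    stop(sprintf("input side %dx%d not divisible by 16 (four pooling stages)",
                 H, W))
  if (dim(x)[3L] != model$config$in_channels)
    stop("input channel count does not match configuration")
  B <- vector("list", 5L); E <- vector("list", 5L)
  xb <- x; xe <- x
  for (j in 1:5) {
    t1 <- conv_f(model, sprintf("B%d.c1", j), xb)
    t2 <- conv_f(model, sprintf("B%d.c2", j), t1)
    if (j < 5L) {
      pl <- maxpool2_fwd(t2); outb <- pl$y; idxb <- pl$idx
    } else { outb <- t2; idxb <- NULL }
    B[[j]] <- list(x_in = xb, t1 = t1, t2 = t2, idx = idxb)
    xb <- outb

    b1a <- conv_f(model, sprintf("E%d.a1", j), xe)
    b1b <- conv_f(model, sprintf("E%d.a2", j), b1a)
    r1  <- conv_f(model, sprintf("E%d.r1", j), xe)
    r2  <- conv_f(model, sprintf("E%d.r2", j), r1)
    b2c <- conv_f(model, sprintf("E%d.a4", j), r2)
    s <- b1b + b2c
    fused <- conv_f(model, sprintf("E%d.a5", j), s)
    if (j < 5L) {
      pl <- maxpool2_fwd(fused); oute <- pl$y; idxe <- pl$idx
    } else { oute <- fused; idxe <- NULL }
    E[[j]] <- list(x_in = xe, b1a = b1a, b1b = b1b, r1 = r1, r2 = r2,
                   b2c = b2c, s = s, fused = fused, idx = idxe)
    xe <- oute
  }
  cur <- cat3(xb, xe)       # bottleneck: both block-5 outputs
  U <- vector("list", 4L)
  for (j in 1:4) {
    lev <- 5L - j
    if (model$config$upsample == "deconv") {
      p <- model$params[[sprintf("U%d.up", j)]]
      u <- upconv2_fwd(cur, p$w, p$b)
    } else u <- upnn2_fwd(cur)
    z <- cat3(u, B[[lev]]$t1, E[[lev]]$fused)
    a <- conv_f(model, sprintf("U%d.c1", j), z)
    bb <- conv_f(model, sprintf("U%d.c2", j), a)
    zc <- cat3(bb, B[[lev]]$t2)
    cc <- conv_f(model, sprintf("U%d.c3", j), zc)
    U[[j]] <- list(x_in = cur, u = u, z = z, a = a, bb = bb, zc = zc,
                   cc = cc)
    cur <- cc
  }
  h <- conv_f(model, "head", cur)
  prob <- 1 / (1 + exp(-h))
  out <- list(prob = prob[, , 1L])
  if (want_cache)
    out$cache <- list(B = B, E = E, U = U, head_in = cur, h = h, prob = prob)
  out
}

#' Backward pass: parameter gradients from an output-probability gradient
#'
#' @param model an `estan_model`.
#' @param cache the cache returned by [model_forward()].
#' @param dprob matrix of partial derivatives of the loss with respect to
#'   the per-pixel output probabilities.
#' @return Named list (one entry per layer) of `list(w, b)` gradients.
#' @export
model_backward <- function(model, cache, dprob) {
  ch <- model$config$channels
  grads <- vector("list", length(model$params))
  names(grads) <- names(model$params)
  put <- function(name, g) grads[[name]] <<- list(w = g$dw, b = g$db)

  p <- cache$prob
  dh <- as_cube(dprob) * p * (1 - p)
  g <- conv_b(model, "head", cache$head_in, cache$h, dh)
  put("head", g)
  dcur <- g$dx

  dtap1B <- vector("list", 4L); dtap2B <- vector("list", 4L)
  dtap1E <- vector("list", 4L)
  for (j in 4:1) {
    lev <- 5L - j
    Uc <- cache$U[[j]]
    y <- model$config$decoder_channels[j]
    g <- conv_b(model, sprintf("U%d.c3", j), Uc$zc, Uc$cc, dcur)
    put(sprintf("U%d.c3", j), g)
    dbb <- slice3(g$dx, 1L, y)
    dtap2B[[lev]] <- slice3(g$dx, y + 1L, ch[lev])
    g <- conv_b(model, sprintf("U%d.c2", j), Uc$a, Uc$bb, dbb)
    put(sprintf("U%d.c2", j), g)
    g <- conv_b(model, sprintf("U%d.c1", j), Uc$z, Uc$a, g$dx)
    put(sprintf("U%d.c1", j), g)
    cu <- dim(Uc$u)[3L]
    du <- slice3(g$dx, 1L, cu)
    dtap1B[[lev]] <- slice3(g$dx, cu + 1L, ch[lev])
    dtap1E[[lev]] <- slice3(g$dx, cu + ch[lev] + 1L, ch[lev])
    if (model$config$upsample == "deconv") {
      pm <- model$params[[sprintf("U%d.up", j)]]
      g <- upconv2_bwd(Uc$x_in, pm$w, du)
      put(sprintf("U%d.up", j), g)
      dcur <- g$dx
    } else dcur <- upnn2_bwd(du)
  }
  dB <- slice3(dcur, 1L, ch[5L])
  dE <- slice3(dcur, ch[5L] + 1L, ch[5L])

  for (j in 5:1) {
    Bc <- cache$B[[j]]
    dt2 <- if (j == 5L) dB else maxpool2_bwd(Bc$idx, dB)
    if (j <= 4L) dt2 <- dt2 + dtap2B[[j]]
    g <- conv_b(model, sprintf("B%d.c2", j), Bc$t1, Bc$t2, dt2)
    put(sprintf("B%d.c2", j), g)
    dt1 <- g$dx
    if (j <= 4L) dt1 <- dt1 + dtap1B[[j]]
    g <- conv_b(model, sprintf("B%d.c1", j), Bc$x_in, Bc$t1, dt1)
    put(sprintf("B%d.c1", j), g)
    dB <- g$dx

    Ec <- cache$E[[j]]
    dfused <- if (j == 5L) dE else maxpool2_bwd(Ec$idx, dE)
    if (j <= 4L) dfused <- dfused + dtap1E[[j]]
    g <- conv_b(model, sprintf("E%d.a5", j), Ec$s, Ec$fused, dfused)
    put(sprintf("E%d.a5", j), g)
    ds <- g$dx
    g <- conv_b(model, sprintf("E%d.a2", j), Ec$b1a, Ec$b1b, ds)
    put(sprintf("E%d.a2", j), g)
    g <- conv_b(model, sprintf("E%d.a1", j), Ec$x_in, Ec$b1a, g$dx)
    put(sprintf("E%d.a1", j), g)
    dx1 <- g$dx
    g <- conv_b(model, sprintf("E%d.a4", j), Ec$r2, Ec$b2c, ds)
    put(sprintf("E%d.a4", j), g)
    g <- conv_b(model, sprintf("E%d.r2", j), Ec$r1, Ec$r2, g$dx)
    put(sprintf("E%d.r2", j), g)
    g <- conv_b(model, sprintf("E%d.r1", j), Ec$x_in, Ec$r1, g$dx)
    put(sprintf("E%d.r1", j), g)
    dE <- dx1 + g$dx
  }
  grads
}

#' Predict a tumor-probability map for one image
#'
#' @param model an `estan_model`.
#' @param image numeric matrix in `[0,1]`, sides divisible by 16.
#' @return Matrix of per-pixel tumor probabilities in (0,1).
#' @export
model_predict <- function(model, image) {
  model_forward(model, image, want_cache = FALSE)$prob
}
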