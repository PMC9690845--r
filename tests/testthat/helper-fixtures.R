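# Shared fixtures: tiny network configurations and random binary masks.

tiny_net_config <- function() {
  net_config(channels = c(4L, 4L, 8L, 8L, 8L),
             rowcol_sizes = c(5L, 5L, 3L, 3L, 3L),
             a5_sizes = c(1L, 3L, 1L, 1L, 3L),
             decoder_channels = c(8L, 8L, 4L, 4L))
}

quarter_width_config <- function() {
  net_config(channels = c(8L, 16L, 32L, 64L, 128L),
             decoder_channels = c(64L, 32L, 16L, 8L))
}

# Random connected-ish blob: a filled ellipse plus salt, always nonempty.
random_blob <- function(side = 16L, seed = 1L) {
  set.seed(seed)
  cy <- runif(1, side * 0.25, side * 0.75)
  cx <- runif(1, side * 0.25, side * 0.75)
  a <- runif(1, 1, side * 0.3); b <- runif(1, 1, side * 0.3)
  yy <- matrix(seq_len(side), side, side) - cy
  xx <- matrix(seq_len(side), side, side, byrow = TRUE) - cx
  m <- (yy / a)^2 + (xx / b)^2 <= 1
  extra <- matrix(runif(side * side) < 0.02, side, side)
  out <- matrix(as.numeric(m | extra), side, side)
  if (!any(out > 0)) out[ceiling(side / 2), ceiling(side / 2)] <- 1
  out
}

# Brute-force confusion counts (independent of area_metrics internals).
confusion_oracle <- function(pred, gt) {
  tp <- 0L; fp <- 0L; fn <- 0L; tn <- 0L
  for (i in seq_along(pred)) {
    p <- pred[i] > 0; g <- gt[i] > 0
    if (p && g) tp <- tp + 1L
    else if (p && !g) fp <- fp + 1L
    else if (!p && g) fn <- fn + 1L
    else tn <- tn + 1L
  }
  list(tp = tp, fp = fp, fn = fn, tn = tn)
}

# All-pairs boundary-distance oracle using a direct 4-neighbour scan.
boundary_oracle <- function(mask) {
  m <- mask > 0
  H <- nrow(m); W <- ncol(m)
  out <- NULL
  for (i in seq_len(H)) for (j in seq_len(W)) {
    if (!m[i, j]) next
    nb <- c(if (i > 1) m[i - 1, j] else FALSE,
            if (i < H) m[i + 1, j] else FALSE,
            if (j > 1) m[i, j - 1] else FALSE,
            if (j < W) m[i, j + 1] else FALSE)
    if (!all(nb)) out <- rbind(out, c(i, j))
  }
  out
}

hd_mae_oracle <- function(pred, gt) {
  A <- boundary_oracle(pred); G <- boundary_oracle(gt)
  d_ag <- apply(A, 1, function(p) min(sqrt((G[, 1] - p[1])^2 +
                                             (G[, 2] - p[2])^2)))
  d_ga <- apply(G, 1, function(p) min(sqrt((A[, 1] - p[1])^2 +
                                             (A[, 2] - p[2])^2)))
  list(hd = max(c(d_ag, d_ga)),
       mae = (sum(d_ag) + sum(d_ga)) / (length(d_ag) + length(d_ga)))
}

# Exact Wilcoxon null by explicit sign enumeration (expand.grid route,
# deliberately different from the package's bit-twiddling enumeration).
wilcoxon_enum_oracle <- function(x, y) {
  d <- x - y
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  v <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(FALSE, TRUE)), n)))
  null_v <- apply(signs, 1, function(s) sum(r[s]))
  min(1, 2 * min(mean(null_v >= v), mean(null_v <= v)))
}

# Small phantom training set: generated at base resolution, resized for
# the network.
phantom_training_set <- function(n, side, seed, height = 256L) {
  ph <- generate_dataset(n, phantom_config(height = height, width = height),
                         seed = seed)
  lapply(seq_along(ph), function(i) {
    s <- resize_for_net(ph[[i]], side = side)
    s$id <- sprintf("ph_%04d", i)
    s
  })
}
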