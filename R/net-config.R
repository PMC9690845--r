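#' Network configuration for the ESTAN architecture
#'
#' Collects every kernel-size and channel schedule of the dual-encoder
#' architecture in one declarative object.  The defaults are the published
#' schedules: five encoder blocks with 32, 64, 128, 256 and 512 kernels;
#' square kernels of size 3 throughout the basic encoder; row-column-wise
#' kernel lengths 15, 13, 11, 9 and 7 (one per ESTAN block, shrinking with
#' depth as the feature maps shrink); fusion kernel sizes 1, 5, 1, 1, 5;
#' decoder channel counts 256, 128, 64, 32 with mid-block kernel sizes
#' 1, 1, 1, 5.  Block 5 of both encoders is not pooled, so a 256-px input
#' reaches a 16x16 bottleneck after four pooling stages.
#'
#' @param channels integer(5), kernel counts per encoder block (shared by
#'   both encoders).
#' @param basic_kernel odd integer, square kernel size in the basic encoder.
#' @param rowcol_sizes integer(5), row-column-wise kernel length A3 per
#'   ESTAN block; the default schedule is strictly decreasing.
#' @param a5_sizes integer(5), fusion kernel size A5 per ESTAN block.
#' @param square_sizes integer(3), sizes of the ESTAN square kernels
#'   A1, A2, A4 (not published; small squares by default).
#' @param decoder_channels integer(4), kernel counts Y per up block.
#' @param decoder_m2 integer(4), mid-block kernel size M2 per up block.
#' @param in_channels integer, input image channels (1 for grayscale BUS).
#' @param upsample `"deconv"` (2x2 stride-2 transposed convolution, the
#'   default) or `"nearest"` (parameter-free nearest-neighbour doubling).
#' @return An object of class `estan_net_config`.
#' @seealso [build_model()], [layer_table()], [summarize_net()]
#' @export
net_config <- function(channels = c(32L, 64L, 128L, 256L, 512L),
                       basic_kernel = 3L,
                       rowcol_sizes = c(15L, 13L, 11L, 9L, 7L),
                       a5_sizes = c(1L, 5L, 1L, 1L, 5L),
                       square_sizes = c(3L, 3L, 3L),
                       decoder_channels = c(256L, 128L, 64L, 32L),
                       decoder_m2 = c(1L, 1L, 1L, 5L),
                       in_channels = 1L,
                       upsample = c("deconv", "nearest")) {
  upsample <- match.arg(upsample)
  stopifnot(length(channels) == 5L, all(channels > 0),
            length(rowcol_sizes) == 5L, all(rowcol_sizes >= 1),
            length(a5_sizes) == 5L, all(a5_sizes >= 1),
            length(square_sizes) == 3L, all(square_sizes >= 1),
            length(decoder_channels) == 4L, all(decoder_channels > 0),
            length(decoder_m2) == 4L, all(decoder_m2 >= 1),
            basic_kernel >= 1, basic_kernel %% 2 == 1,
            in_channels >= 1)
  odd <- c(basic_kernel, rowcol_sizes, a5_sizes, square_sizes, decoder_m2)
  if (any(odd %% 2 == 0))
    stop("all kernel sizes must be odd (zero-padded 'same' convolutions)")
  structure(list(
    channels = as.integer(channels),
    basic_kernel = as.integer(basic_kernel),
    rowcol_sizes = as.integer(rowcol_sizes),
    a5_sizes = as.integer(a5_sizes),
    square_sizes = as.integer(square_sizes),
    decoder_channels = as.integer(decoder_channels),
    decoder_m2 = as.integer(decoder_m2),
    in_channels = as.integer(in_channels),
    upsample = upsample
  ), class = "estan_net_config")
}

#' Enumerate every parameterized layer of a configuration
#'
#' Produces the architecture's layer list as a data frame: one row per
#' convolution (or transposed convolution), with kernel extents, channel
#' counts and the exact trainable-parameter count
#' `kh * kw * c_in * c_out + c_out`.  This is the audit surface for the
#' published schedules and the closed-form oracle for [count_parameters()].
#'
#' @param config an [net_config()] object.
#' @return data.frame with columns `name`, `type`, `kh`, `kw`, `cin`,
#'   `cout`, `relu`, `params`.
#' @export
layer_table <- function(config = net_config()) {
  stopifnot(inherits(config, "estan_net_config"))
  ch <- config$channels
  a1 <- config$square_sizes[1]; a2 <- config$square_sizes[2]
  a4 <- config$square_sizes[3]
  rows <- list()
  add <- function(name, type, kh, kw, cin, cout, relu) {
    rows[[length(rows) + 1L]] <<- data.frame(
      name = name, type = type, kh = kh, kw = kw, cin = cin, cout = cout,
      relu = relu, params = kh * kw * cin * cout + cout,
      stringsAsFactors = FALSE)
  }
  s <- config$basic_kernel
  for (j in 1:5) {
    cin <- if (j == 1L) config$in_channels else ch[j - 1L]
    add(sprintf("B%d.c1", j), "conv", s, s, cin, ch[j], TRUE)
    add(sprintf("B%d.c2", j), "conv", s, s, ch[j], ch[j], TRUE)
  }
  for (j in 1:5) {
    cin <- if (j == 1L) config$in_channels else ch[j - 1L]
    a3 <- config$rowcol_sizes[j]; a5 <- config$a5_sizes[j]
    add(sprintf("E%d.a1", j), "conv", a1, a1, cin, ch[j], TRUE)
    add(sprintf("E%d.a2", j), "conv", a2, a2, ch[j], ch[j], TRUE)
    add(sprintf("E%d.r1", j), "conv", a3, 1L, cin, ch[j], TRUE)
    add(sprintf("E%d.r2", j), "conv", 1L, a3, ch[j], ch[j], TRUE)
    add(sprintf("E%d.a4", j), "conv", a4, a4, ch[j], ch[j], TRUE)
    add(sprintf("E%d.a5", j), "conv", a5, a5, ch[j], ch[j], TRUE)
  }
  xch <- 2L * ch[5]            # both bottleneck outputs, concatenated
  for (j in 1:4) {
    lev <- 5L - j
    y <- config$decoder_channels[j]
    if (config$upsample == "deconv")
      add(sprintf("U%d.up", j), "deconv", 2L, 2L, xch, xch, FALSE)
    zc <- xch + 2L * ch[lev]   # upsampled path + the two first-skip taps
    add(sprintf("U%d.c1", j), "conv", 3L, 3L, zc, y, TRUE)
    m2 <- config$decoder_m2[j]
    add(sprintf("U%d.c2", j), "conv", m2, m2, y, y, TRUE)
    add(sprintf("U%d.c3", j), "conv", 3L, 3L, y + ch[lev], y, TRUE)
    xch <- y
  }
  add("head", "conv", 1L, 1L, xch, 1L, FALSE)
  do.call(rbind, rows)
}

#' @export
print.estan_net_config <- function(x, ...) {
  cat("ESTAN network configuration\n")
  cat("  encoder channels: ", paste(x$channels, collapse = ", "), "\n")
  cat("  basic kernel:     ", x$basic_kernel, "\n")
  cat("  row-column sizes: ", paste(x$rowcol_sizes, collapse = ", "), "\n")
  cat("  fusion (A5):      ", paste(x$a5_sizes, collapse = ", "), "\n")
  cat("  square (A1,A2,A4):", paste(x$square_sizes, collapse = ", "), "\n")
  cat("  decoder channels: ", paste(x$decoder_channels, collapse = ", "), "\n")
  cat("  decoder M2:       ", paste(x$decoder_m2, collapse = ", "), "\n")
  cat("  upsampling:       ", x$upsample, "\n")
  invisible(x)
}

#' Print the layer table and parameter count of a configuration
#'
#' @param config an [net_config()] object.
#' @return Invisibly, the layer table.
#' @export
summarize_net <- function(config = net_config()) {
  lt <- layer_table(config)
  print(config)
  print(lt, row.names = FALSE)
  cat(sprintf("total trainable parameters: %s\n",
              format(sum(lt$params), big.mark = ",")))
  invisible(lt)
}
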