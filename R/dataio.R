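# Dataset loading, tumor-size measurement, size-group assignment,
# resizing to the network resolution, and cross-validation fold planning.

#' Longest axis (Feret diameter) of a tumor mask
#'
#' The tumor size criterion: the maximum Euclidean distance between any
#' two foreground pixel centers, measured on the original-resolution
#' mask.  When the mask has several connected components the axis is
#' measured per component (8-connectivity) and the maximum is returned,
#' so disjoint spurious islands do not inflate the measurement.
#' Implemented via the convex hull (the diameter of a point set is
#' attained on its hull), which matches the brute-force all-pairs maximum
#' exactly.
#'
#' @param mask nonempty binary grid.
#' @return Longest-axis length in pixels (0 for a single-pixel mask).
#' @export
tumor_longest_axis <- function(mask) {
  m <- mask > 0
  if (!any(m)) stop("empty mask: longest axis undefined")
  lab <- EBImage::bwlabel(m)
  labs <- setdiff(unique(as.vector(lab)), 0)
  max(vapply(labs, function(l) {
    pts <- which(lab == l, arr.ind = TRUE, useNames = FALSE)
    feret_diameter(pts)
  }, 0))
}

feret_diameter <- function(pts) {
  n <- nrow(pts)
  if (n == 1L) return(0)
  if (n > 3L) {
    h <- grDevices::chull(pts[, 1L], pts[, 2L])
    pts <- pts[h, , drop = FALSE]
  }
  max(stats::dist(pts))
}

#' Assign tumor-size groups from longest-axis lengths
#'
#' Groups tile the positive axis with half-open-above intervals:
#' G1 = (0, 100], G2 = (100, 120], G3 = (120, 160], G4 = (160, Inf).
#' A tumor is "small" iff its longest axis is at most 120 px, i.e. the
#' union of G1 and G2 — the boundary convention under which the two
#' small groups (19 + 30 images on the BUSIS benchmark) add up to that
#' benchmark's published small-tumor count of 49.
#'
#' @param axis_px numeric vector of positive longest-axis lengths.
#' @return data.frame with columns `axis_px`, `label` (factor G1..G4) and
#'   `is_small`.
#' @export
assign_size_group <- function(axis_px) {
  if (any(!is.finite(axis_px) | axis_px <= 0))
    stop("axis_px must be positive and finite")
  label <- cut(axis_px, breaks = c(0, 100, 120, 160, Inf),
               labels = c("G1", "G2", "G3", "G4"), right = TRUE)
  data.frame(axis_px = axis_px, label = label,
             is_small = axis_px <= 120)
}

read_gray_png <- function(path) {
  a <- png::readPNG(path)
  if (length(dim(a)) == 3L) a <- rowMeans(a, dims = 2L)
  a
}

#' Load an image/mask dataset from a manifest CSV
#'
#' The manifest has columns `image_path`, `mask_path` and optionally
#' `id`; paths are resolved relative to the manifest's directory.  PNG
#' images (8- or 16-bit, single channel) are normalized to `[0,1]`;
#' masks are binarized at value > 0.  The longest-axis length is measured
#' on the original-resolution mask.  Samples whose mask is all zeros are
#' kept but flagged (`empty_mask = TRUE`); the evaluation harness
#' excludes them from metric computation.
#'
#' @param manifest path to the manifest CSV.
#' @return List of samples; each is a list with `id`, `image`, `mask`,
#'   `axis_px`, `empty_mask`.
#' @export
load_dataset <- function(manifest) {
  if (!file.exists(manifest)) stop("manifest not found: ", manifest)
  df <- read.csv(manifest, stringsAsFactors = FALSE)
  if (nrow(df) == 0L) stop("empty manifest: ", manifest)
  if (!all(c("image_path", "mask_path") %in% names(df)))
    stop("manifest must have columns image_path, mask_path")
  base <- dirname(normalizePath(manifest))
  resolve <- function(p) ifelse(grepl("^(/|[A-Za-z]:)", p), p,
                                file.path(base, p))
  lapply(seq_len(nrow(df)), function(i) {
    ip <- resolve(df$image_path[i]); mp <- resolve(df$mask_path[i])
    if (!file.exists(ip) || !file.exists(mp))
      stop(sprintf("row %d: unreadable file(s): %s / %s", i, ip, mp))
    img <- read_gray_png(ip)
    msk <- as_binary(read_gray_png(mp))
    if (!identical(dim(img), dim(msk)))
      stop(sprintf("row %d: image/mask shape mismatch (%s vs %s)", i,
                   paste(dim(img), collapse = "x"),
                   paste(dim(msk), collapse = "x")))
    empty <- !any(msk > 0)
    list(id = if ("id" %in% names(df)) as.character(df$id[i])
              else sprintf("sample_%04d", i),
         image = img, mask = msk,
         axis_px = if (empty) NA_real_ else tumor_longest_axis(msk),
         empty_mask = empty)
  })
}

#' Resize a sample to the network input resolution
#'
#' Bilinear interpolation for the image, nearest-neighbour for the mask
#' (so it stays strictly binary).  The original-resolution `axis_px` is
#' retained unchanged: size grouping is always based on the original
#' image, not the working resolution.
#'
#' @param sample a sample as returned by [load_dataset()] (or any list
#'   with `image` and `mask`).
#' @param side target side in pixels (default 256; must be at least 16,
#'   the footprint of the four pooling stages).
#' @return The sample with `image` and `mask` replaced by `side x side`
#'   grids.
#' @export
resize_for_net <- function(sample, side = 256L) {
  if (side < 16L) stop("side must be >= 16 (four pooling stages)")
  img <- sample$image; msk <- sample$mask
  if (!identical(dim(img), c(as.integer(side), as.integer(side)))) {
    img <- unclass(EBImage::resize(img, w = side, h = side,
                                   filter = "bilinear"))
    img <- pmin(pmax(img, 0), 1)
    msk <- unclass(EBImage::resize(msk, w = side, h = side,
                                   filter = "none"))
  }
  sample$image <- matrix(as.numeric(img), side, side)
  sample$mask <- matrix(as.numeric(msk > 0), side, side)
  sample
}

#' Plan balanced cross-validation folds
#'
#' Deterministic seeded shuffle followed by a round-robin assignment, so
#' fold sizes differ by at most one and the folds partition the ids.
#'
#' @param ids character or integer vector of sample ids.
#' @param k number of folds (default 5).
#' @param seed integer seed for the shuffle.
#' @return List with `k`, `seed` and `assignment`, a named integer vector
#'   mapping each id to its fold in `1..k`.
#' @export
make_folds <- function(ids, k = 5L, seed = 1L) {
  n <- length(ids)
  if (n < k) stop(sprintf("need at least k = %d ids, got %d", k, n))
  if (anyDuplicated(ids)) stop("ids must be unique")
  set.seed(seed)
  perm <- sample.int(n)
  assignment <- integer(n)
  assignment[perm] <- rep_len(seq_len(k), n)
  names(assignment) <- as.character(ids)
  list(k = as.integer(k), seed = as.integer(seed), assignment = assignment)
}
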