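# Paired significance testing between segmentation methods: Wilcoxon
# signed-rank with an exact small-sample null, and Holm-Bonferroni
# adjustment across metrics.

#' Wilcoxon signed-rank test for paired per-sample metrics
#'
#' Two-sided test of the paired differences `x - y`.  Zero differences
#' are discarded (the classic reduced-sample convention) and tied
#' absolute differences get midranks.  For `n <= exact_max` remaining
#' pairs the null distribution of the positive-rank sum is obtained by
#' full enumeration of all `2^n` sign assignments of the ranked absolute
#' differences — exact even under ties, unlike the textbook exact test.
#' For larger `n` the normal approximation with tie correction and
#' continuity correction is used.
#'
#' @param x,y equal-length numeric vectors of paired per-sample values.
#' @param exact_max largest `n` for which the exact enumeration null is
#'   used (default 12; `2^12` sign patterns).
#' @return List with `p.value`, `statistic` (positive-rank sum `V`),
#'   `n` (pairs after zero removal) and `method`.
#' @export
wilcoxon_signed_rank <- function(x, y, exact_max = 12L) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  d <- x - y
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L) stop("all paired differences are zero: degenerate comparison")
  if (n < 5L)
    warning("fewer than 5 nonzero differences; the test has little power")
  r <- rank(abs(d))
  v <- sum(r[d > 0])
  if (n <= exact_max) {
    # enumerate the null distribution of V over all 2^n sign patterns
    null_v <- numeric(2^n)
    for (s in 0:(2^n - 1)) {
      signs <- bitwAnd(bitwShiftR(s, 0:(n - 1L)), 1L) == 1L
      null_v[s + 1L] <- sum(r[signs])
    }
    p <- min(1, 2 * min(mean(null_v >= v), mean(null_v <= v)))
    method <- "exact (sign-pattern enumeration)"
  } else {
    mu <- n * (n + 1) / 4
    ties <- table(r)
    sig2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
    z <- (v - mu - 0.5 * sign(v - mu)) / sqrt(sig2)
    p <- 2 * pnorm(-abs(z))
    method <- "normal approximation (tie + continuity correction)"
  }
  list(p.value = p, statistic = v, n = n, method = method)
}

#' Holm-Bonferroni step-down adjustment
#'
#' `adj_(i) = max_{j <= i} min(1, (m - j + 1) * p_(j))` over the
#' ascending order statistics, returned in the original order.  A thin
#' validating wrapper over `stats::p.adjust(method = "holm")`, which
#' implements exactly this recursion.
#'
#' @param pvals numeric vector of p-values in `[0,1]`.
#' @return Adjusted p-values, same order as the input.
#' @export
holm_bonferroni <- function(pvals) {
  if (any(!is.finite(pvals) | pvals < 0 | pvals > 1))
    stop("p-values must lie in [0,1]")
  p.adjust(pvals, method = "holm")
}

#' Compare two methods' per-sample metric tables
#'
#' Runs a paired Wilcoxon signed-rank test per metric on the per-sample
#' values of the two methods (matched by `id`), then applies
#' Holm-Bonferroni across the metrics.
#'
#' @param a,b data.frames of per-sample metrics (as produced by
#'   [evaluate_sample()] rows), sharing an `id` column.
#' @param metrics metric columns to compare.
#' @param alpha significance level for the `significant` flag.
#' @return data.frame: `metric`, `n`, `p_raw`, `p_adjusted`,
#'   `significant`.
#' @export
compare_methods <- function(a, b,
                            metrics = c("tpr", "fpr", "ji", "dsc", "aer",
                                        "hd", "mae"),
                            alpha = 0.05) {
  common <- intersect(a$id, b$id)
  if (length(common) == 0L) stop("no common sample ids")
  a <- a[match(common, a$id), ]
  b <- b[match(common, b$id), ]
  rows <- lapply(metrics, function(m) {
    xa <- a[[m]]; xb <- b[[m]]
    ok <- is.finite(xa) & is.finite(xb)
    res <- tryCatch(wilcoxon_signed_rank(xa[ok], xb[ok]),
                    error = function(e) NULL)
    data.frame(metric = m, n = sum(ok),
               p_raw = if (is.null(res)) NA_real_ else res$p.value,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  ok <- is.finite(out$p_raw)
  out$p_adjusted <- NA_real_
  out$p_adjusted[ok] <- holm_bonferroni(out$p_raw[ok])
  out$significant <- !is.na(out$p_adjusted) & out$p_adjusted < alpha
  out
}
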