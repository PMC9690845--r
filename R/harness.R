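# Training loop, k-fold cross-validation and size-stratified reporting.

#' Training configuration
#'
#' @param epochs number of passes over the training set.
#' @param batch_size mini-batch size (gradients averaged per batch).
#' @param lr Adam learning rate.
#' @param beta1,beta2,adam_eps Adam moment decay rates and stabilizer.
#' @param seed seed controlling shuffling (model init has its own seed in
#'   [build_model()]).
#' @param shuffle reshuffle the sample order each epoch.
#' @param stop_dsc optional early-stopping target: training stops once
#'   the mean training DSC (at threshold 0.5) reaches this value, checked
#'   every `check_every` epochs.
#' @param check_every epoch interval for the early-stopping check.
#' @param verbose print per-epoch loss.
#' @return Object of class `train_config`.
#' @export
train_config <- function(epochs = 100L, batch_size = 8L, lr = 1e-4,
                         beta1 = 0.9, beta2 = 0.999, adam_eps = 1e-8,
                         seed = 1L, shuffle = TRUE, stop_dsc = NULL,
                         check_every = 10L, verbose = FALSE) {
  stopifnot(epochs >= 1, batch_size >= 1, lr >= 0)
  structure(list(epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size), lr = lr,
                 beta1 = beta1, beta2 = beta2, adam_eps = adam_eps,
                 seed = as.integer(seed), shuffle = isTRUE(shuffle),
                 stop_dsc = stop_dsc, check_every = as.integer(check_every),
                 verbose = isTRUE(verbose)),
            class = "train_config")
}

zero_like_params <- function(params)
  lapply(params, function(p) list(w = p$w * 0, b = p$b * 0))

#' Train a model by minimizing the Dice loss with Adam
#'
#' Mini-batch gradient descent on the soft Dice loss, one Adam step per
#' batch, gradients averaged over the batch.  Deterministic for fixed
#' seeds under single-threaded numerics.
#'
#' @param model an `estan_model`.
#' @param samples list of training samples, each with `image` and `mask`
#'   matrices whose sides are divisible by 16.
#' @param cfg a [train_config()].
#' @return List: `model` (trained), `history` (mean loss per epoch),
#'   `epochs_run`, `train_dsc` (mean training DSC at the end).
#' @export
train <- function(model, samples, cfg = train_config()) {
  stopifnot(inherits(model, "estan_model"), length(samples) >= 1)
  n <- length(samples)
  set.seed(cfg$seed)
  mstate <- zero_like_params(model$params)
  vstate <- zero_like_params(model$params)
  t_step <- 0L
  history <- numeric(0)
  epochs_run <- 0L
  for (epoch in seq_len(cfg$epochs)) {
    ord <- if (cfg$shuffle) sample.int(n) else seq_len(n)
    batch_starts <- seq(1L, n, by = cfg$batch_size)
    losses <- numeric(0)
    for (bs in batch_starts) {
      idx <- ord[bs:min(bs + cfg$batch_size - 1L, n)]
      acc <- NULL
      bl <- 0
      for (i in idx) {
        fw <- model_forward(model, samples[[i]]$image, want_cache = TRUE)
        loss <- dice_loss(fw$prob, samples[[i]]$mask)
        if (!is.finite(loss))
          stop(sprintf("non-finite loss at epoch %d, sample %d", epoch, i))
        bl <- bl + loss
        dprob <- dice_loss_grad(fw$prob, samples[[i]]$mask)
        g <- model_backward(model, fw$cache, dprob)
        acc <- if (is.null(acc)) g else
          Map(function(a, b) list(w = a$w + b$w, b = a$b + b$b), acc, g)
      }
      nb <- length(idx)
      losses <- c(losses, bl / nb)
      t_step <- t_step + 1L
      corr1 <- 1 - cfg$beta1^t_step
      corr2 <- 1 - cfg$beta2^t_step
      for (nm in names(model$params)) {
        gw <- acc[[nm]]$w / nb; gb <- acc[[nm]]$b / nb
        mstate[[nm]]$w <- cfg$beta1 * mstate[[nm]]$w + (1 - cfg$beta1) * gw
        mstate[[nm]]$b <- cfg$beta1 * mstate[[nm]]$b + (1 - cfg$beta1) * gb
        vstate[[nm]]$w <- cfg$beta2 * vstate[[nm]]$w + (1 - cfg$beta2) * gw^2
        vstate[[nm]]$b <- cfg$beta2 * vstate[[nm]]$b + (1 - cfg$beta2) * gb^2
        model$params[[nm]]$w <- model$params[[nm]]$w -
          cfg$lr * (mstate[[nm]]$w / corr1) /
          (sqrt(vstate[[nm]]$w / corr2) + cfg$adam_eps)
        model$params[[nm]]$b <- model$params[[nm]]$b -
          cfg$lr * (mstate[[nm]]$b / corr1) /
          (sqrt(vstate[[nm]]$b / corr2) + cfg$adam_eps)
      }
    }
    history <- c(history, mean(losses))
    epochs_run <- epoch
    if (cfg$verbose)
      message(sprintf("epoch %d: dice loss %.4f", epoch, mean(losses)))
    if (!is.null(cfg$stop_dsc) && epoch %% cfg$check_every == 0L) {
      if (training_dsc(model, samples) >= cfg$stop_dsc) break
    }
  }
  list(model = model, history = history, epochs_run = epochs_run,
       train_dsc = training_dsc(model, samples))
}

training_dsc <- function(model, samples, threshold = 0.5) {
  mean(vapply(samples, function(s) {
    pred <- model_predict(model, s$image) > threshold
    area_metrics(pred, s$mask)$dsc
  }, 0))
}

#' Evaluate a model on a list of samples
#'
#' Skips (with a message) samples whose ground-truth mask is empty.
#'
#' @param model an `estan_model`.
#' @param samples list of samples with `image`, `mask` and optionally
#'   `id` and `axis_px` (for size-group labelling).
#' @param threshold binarization threshold.
#' @return data.frame of per-sample metric rows ([evaluate_sample()]).
#' @export
evaluate_model <- function(model, samples, threshold = 0.5) {
  rows <- lapply(seq_along(samples), function(i) {
    s <- samples[[i]]
    id <- if (!is.null(s$id)) s$id else sprintf("sample_%04d", i)
    if (!any(s$mask > 0)) {
      message("skipping ", id, ": empty ground-truth mask")
      return(NULL)
    }
    group <- if (!is.null(s$axis_px) && is.finite(s$axis_px))
      as.character(assign_size_group(s$axis_px)$label) else NA_character_
    prob <- model_predict(model, s$image)
    row <- evaluate_sample(prob, s$mask, threshold = threshold, id = id,
                           group = group)
    row$axis_px <- if (!is.null(s$axis_px)) s$axis_px else NA_real_
    row
  })
  do.call(rbind, Filter(Negate(is.null), rows))
}

#' k-fold cross-validation of the full pipeline
#'
#' For each fold: build a freshly initialized model from a fold-specific
#' seed, train on the other k-1 folds, evaluate on the held-out fold.
#' Every sample is evaluated exactly once across folds.
#'
#' @param samples list of samples (`image`, `mask`, `id`, `axis_px`).
#' @param net_cfg a [net_config()].
#' @param train_cfg a [train_config()].
#' @param k number of folds (default 5).
#' @param seed master seed: drives the fold split and the per-fold model
#'   initialization and shuffling seeds.
#' @return List of per-fold results, each with `fold`, `reports`
#'   (per-sample metric rows) and `means`; plus attribute-free overall
#'   access via [stratified_report()].
#' @export
cross_validate <- function(samples, net_cfg = net_config(),
                           train_cfg = train_config(), k = 5L, seed = 1L) {
  n <- length(samples)
  if (n < k) stop("need at least k samples")
  ids <- vapply(seq_len(n), function(i) {
    if (!is.null(samples[[i]]$id)) samples[[i]]$id
    else sprintf("sample_%04d", i)
  }, "")
  for (i in seq_len(n)) samples[[i]]$id <- ids[i]
  plan <- make_folds(ids, k = k, seed = seed)
  set.seed(seed + 1L)
  fold_seeds <- sample.int(2^30, k)
  lapply(seq_len(k), function(f) {
    test_ids <- names(plan$assignment)[plan$assignment == f]
    tr <- samples[!(ids %in% test_ids)]
    te <- samples[ids %in% test_ids]
    model <- build_model(net_cfg, seed = fold_seeds[f])
    tc <- train_cfg
    tc$seed <- fold_seeds[f]
    fit <- train(model, tr, tc)
    reports <- evaluate_model(fit$model, te)
    if (is.null(reports) || nrow(reports) == 0L)
      stop(sprintf("fold %d has no evaluable samples", f))
    num <- c("tpr", "fpr", "ji", "dsc", "aer", "hd", "mae")
    means <- vapply(num, function(m) mean(reports[[m]], na.rm = TRUE), 0)
    reports$fold <- f
    list(fold = f, reports = reports, means = means,
         history = fit$history)
  })
}

metric_means <- function(df) {
  num <- c("tpr", "fpr", "ji", "dsc", "aer", "hd", "mae")
  out <- as.data.frame(as.list(vapply(num, function(m)
    if (nrow(df) == 0L) NA_real_ else mean(df[[m]], na.rm = TRUE), 0)))
  out$n <- nrow(df)
  out$hd_mae_excluded <- if (nrow(df) == 0L) 0L else sum(!is.finite(df$hd))
  out
}

#' Size-stratified report tables from cross-validation results
#'
#' Combines all per-sample test-set metric rows and emits three tables:
#' `overall` (mean of the seven metrics over every sample), `small`
#' (restricted to longest axis <= 120 px) and `by_group` (JI and FPR per
#' size group G1..G4, with counts).  Boundary-metric means skip flagged
#' empty predictions; the exclusion count is reported alongside.
#'
#' @param results list returned by [cross_validate()] (or a single-fold
#'   list of the same shape).
#' @return List with `overall`, `small`, `by_group` and `per_sample`.
#' @export
stratified_report <- function(results) {
  per_sample <- do.call(rbind, lapply(results, `[[`, "reports"))
  overall <- metric_means(per_sample)
  small <- metric_means(per_sample[!is.na(per_sample$axis_px) &
                                     per_sample$axis_px <= 120, ])
  groups <- c("G1", "G2", "G3", "G4")
  by_group <- do.call(rbind, lapply(groups, function(g) {
    sub <- per_sample[!is.na(per_sample$group) & per_sample$group == g, ]
    data.frame(group = g, n = nrow(sub),
               ji = if (nrow(sub)) mean(sub$ji) else NA_real_,
               fpr = if (nrow(sub)) mean(sub$fpr) else NA_real_,
               stringsAsFactors = FALSE)
  }))
  list(overall = overall, small = small, by_group = by_group,
       per_sample = per_sample)
}
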