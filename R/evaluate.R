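#' @name evaluate
#' @title Segmentation metrics, recognition rates, and parameter sweeps
NULL

#' Per-pixel segmentation metrics
#'
#' @param pred,truth integer label matrices of equal shape
#' @param labels the declared label set (defaults to the union observed)
#' @return a `seg_metrics` list: `pixel_accuracy`, per-class `dice` and
#'   `iou` (Dice = 1 for a class empty in both masks), and the K x K
#'   `confusion` matrix (rows = truth, cols = prediction)
#' @export
seg_metrics <- function(pred, truth, labels = NULL) {
  check(is.matrix(pred) && is.matrix(truth) && all(dim(pred) == dim(truth)),
        "pred and truth must be matrices of equal shape")
  if (is.null(labels)) labels <- sort(unique(c(pred, truth)))
  check(all(pred %in% labels) && all(truth %in% labels),
        "masks contain labels outside the declared label set")
  K <- length(labels)
  ft <- factor(truth, levels = labels)
  fp <- factor(pred, levels = labels)
  confusion <- table(truth = ft, pred = fp)
  acc <- sum(diag(confusion)) / length(pred)
  dice <- iou <- setNames(numeric(K), labels)
  for (i in seq_len(K)) {
    P <- sum(confusion[, i]); T <- sum(confusion[i, ]); I <- confusion[i, i]
    dice[i] <- if (P + T == 0) 1 else 2 * I / (P + T)
    iou[i] <- if (P + T - I == 0) 1 else I / (P + T - I)
  }
  structure(list(pixel_accuracy = acc, dice = dice, iou = iou,
                 confusion = confusion),
            class = "seg_metrics")
}

#' Per-category recognition rates
#'
#' `rate_c = correct_c / total_c`; a category with no cases gets `NA`
#' (never silently zero).  The macro rate averages the defined categories.
#'
#' @param case_preds predicted category per case
#' @param case_truth true category per case
#' @param classes category set (defaults to the union observed)
#' @return list of per-category `rates` and `macro` average
#' @export
recognition_rate <- function(case_preds, case_truth, classes = NULL) {
  check(length(case_preds) == length(case_truth),
        "predictions and truth must have equal length")
  if (is.null(classes)) classes <- sort(unique(c(case_preds, case_truth)))
  rates <- setNames(rep(NA_real_, length(classes)), classes)
  for (cl in classes) {
    idx <- case_truth == cl
    if (any(idx)) rates[cl] <- mean(case_preds[idx] == cl)
  }
  list(rates = rates, macro = mean(rates, na.rm = TRUE))
}

# stratified fold assignment: per class, shuffled indices dealt round-robin
stratified_folds <- function(y, k, seed = NULL) {
  fold <- integer(length(y))
  with_seed(seed, {
    for (cl in unique(y)) {
      idx <- which(y == cl)
      check(length(idx) >= k,
            sprintf("class %s has fewer cases (%d) than folds (%d)",
                    cl, length(idx), k))
      idx <- sample(idx)
      fold[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  fold
}

#' Cross-validate the hidden-layer size
#'
#' Stratified k-fold cross-validation of block-classification accuracy for
#' each candidate hidden-node count; the feature scaler is refitted inside
#' every training fold.
#'
#' @param dataset list with `X` (samples x d feature matrix) and `y`
#'   (integer labels `0..K-1`)
#' @param hidden_counts candidate hidden-layer sizes (default 2..8)
#' @param k_folds number of folds
#' @param ga_cfg,train_cfg optimizer settings, see [default_config()]
#' @param seed master seed
#' @return a `sweep_result` data frame: `n_hidden`, `mean_accuracy`,
#'   `sd_accuracy`, plus attribute `"folds"`
#' @export
hl_sweep <- function(dataset, hidden_counts = 2:8, k_folds = 5L,
                     ga_cfg = list(), train_cfg = list(), seed = 0L) {
  X <- as.matrix(dataset$X); y <- as.integer(dataset$y)
  K <- length(unique(y))
  fold <- stratified_folds(y, k_folds, seed = derive_seed(seed, 1L))
  rows <- lapply(hidden_counts, function(nh) {
    accs <- vapply(seq_len(k_folds), function(f) {
      tr <- fold != f
      scaler <- fit_scaler(X[tr, , drop = FALSE])
      Xtr <- apply_scaler(scaler, X[tr, , drop = FALSE])
      Xva <- apply_scaler(scaler, X[!tr, , drop = FALSE])
      Y <- matrix(0, sum(tr), K)
      Y[cbind(seq_len(sum(tr)), y[tr] + 1L)] <- 1
      cfg <- merge_lists(ga_cfg, list(seed = derive_seed(seed, 100L * nh + f)))
      fit <- optimize_bpnn(Xtr, Y, c(ncol(X), nh, K), cfg, train_cfg)
      mean(predict_labels(fit$model, Xva) == y[!tr])
    }, numeric(1))
    data.frame(n_hidden = nh, mean_accuracy = mean(accs),
               sd_accuracy = stats::sd(accs))
  })
  out <- do.call(rbind, rows)
  attr(out, "folds") <- fold
  class(out) <- c("sweep_result", class(out))
  out
}

#' Sweep block size and overlap step
#'
#' Trains and evaluates the full pipeline at every `(block_size,
#' overlap_step)` combination and reports segmentation metrics together
#' with informational wall-clock time (never asserted: hardware
#' dependent).  Invalid pairs are skipped with a warning.
#'
#' @param train_pairs,test_pairs lists of `labeled_image_pair`
#' @param block_sizes,overlap_steps candidate values in pixels
#' @param cfg pipeline configuration, see [default_config()]
#' @param seed master seed
#' @return a `sweep_result` data frame: `block_size`, `overlap_step`,
#'   `n_blocks` (per image), `pixel_accuracy`, `fg_dice`, `seconds`
#' @export
block_param_sweep <- function(train_pairs, test_pairs, block_sizes = c(32L, 48L),
                              overlap_steps = c(8L, 16L), cfg = default_config(),
                              seed = 0L) {
  min_dim <- min(vapply(c(train_pairs, test_pairs),
                        function(p) min(dim(p$image)), numeric(1)))
  rows <- list()
  for (b in block_sizes) for (s in overlap_steps) {
    if (s > b || b > min_dim) {
      warning(sprintf("skipping invalid block/step pair (%d, %d)", b, s))
      next
    }
    cfg_bs <- cfg
    cfg_bs$blocks$block_size <- as.integer(b)
    cfg_bs$blocks$overlap_step <- as.integer(s)
    t0 <- proc.time()["elapsed"]
    model <- train_segmenter(train_pairs, cfg_bs, seed = derive_seed(seed, b * 100L + s))
    res <- evaluate_segmenter(model, test_pairs)
    secs <- as.numeric(proc.time()["elapsed"] - t0)
    g <- extract_blocks(test_pairs[[1]]$image, b, s)
    rows[[length(rows) + 1]] <- data.frame(
      block_size = b, overlap_step = s, n_blocks = nrow(g$origins),
      pixel_accuracy = res$mean_pixel_accuracy, fg_dice = res$mean_fg_dice,
      seconds = secs)
  }
  out <- do.call(rbind, rows)
  class(out) <- c("sweep_result", class(out))
  out
}
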