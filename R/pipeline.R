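#' @name pipeline
#' @title End-to-end block-classification segmentation pipeline
#' @description
#' Glues the modules together.  Images are cut into overlapping blocks;
#' each block becomes a 6-feature sample.  One GA-initialized network
#' classifies blocks into five classes -- background, lumen, and one
#' lesion class per lesion-bearing archetype (the three lesion
#' appearances are too heterogeneous to pool into a single output, and
#' keeping them separate also yields the case-level category for free).
#' Blocks carry their pixel-majority truth label, which keeps region
#' boundaries unbiased, and the training set is class-rebalanced by
#' resampling because background blocks outnumber lesion blocks roughly
#' 50:1.  The per-block scores are averaged into a per-pixel probability
#' map, collapsed to background / lumen / lesion, and refined by graph
#' cuts with the smoothness weight selected on the training phantoms.
#' The case-level category call is the majority vote over predicted
#' lesion blocks; a case with no predicted lesion block is called
#' "adhesive", the one lesion-free archetype.
NULL

# Block classes: 0 background, 1 lumen, then one class per lesion-bearing
# archetype in this fixed order.
LESION_ARCHETYPES <- c("sist", "colon_cancer", "volvulus")
BLOCK_CLASSES <- c("background", "lumen", paste0("lesion_", LESION_ARCHETYPES))

# Label a truth block.  labeling = "majority": pixel-majority class (ties
# to the lower label) -- unbiased region boundaries.  labeling =
# "priority": lesion wins once it covers >= min_frac of the block, then
# lumen, then the majority -- for worlds whose lesions are small relative
# to the block.
block_label <- function(truth_block, labeling = c("majority", "priority"),
                        min_frac = 0.25) {
  labeling <- match.arg(labeling)
  fr <- tabulate(as.vector(truth_block) + 1L, nbins = 3) / length(truth_block)
  if (labeling == "priority") {
    if (fr[3] >= min_frac) return(2L)
    if (fr[2] >= min_frac) return(1L)
  }
  which.max(fr) - 1L
}

#' Build a labeled block feature dataset from phantom pairs
#'
#' @param pairs list of `labeled_image_pair`
#' @param block_size,overlap_step block geometry, pixels
#' @param lesion_classes if `TRUE`, lesion blocks are labeled by their
#'   phantom's archetype (5-class problem); if `FALSE`, all lesion blocks
#'   share label 2 (3-class problem)
#' @param labeling `"majority"` (unbiased boundaries; the default) or
#'   `"priority"` (lesion/lumen preferred above `min_frac` coverage)
#' @param min_frac priority threshold, see above
#' @param cfg feature settings, see `default_config()$features`
#' @return list: `X` (raw features), `y` (integer block labels), `case`
#'   (source pair index per block), `classes` (label names)
#' @export
make_block_dataset <- function(pairs, block_size = 32L, overlap_step = 16L,
                               lesion_classes = FALSE,
                               labeling = c("majority", "priority"),
                               min_frac = 0.25,
                               cfg = default_config()$features) {
  labeling <- match.arg(labeling)
  Xs <- list(); ys <- list(); cases <- list()
  for (i in seq_along(pairs)) {
    p <- pairs[[i]]
    g <- extract_blocks(p$image, block_size, overlap_step)
    gt <- extract_blocks(p$truth, block_size, overlap_step)
    feats <- grid_features(g, cfg$hist_bins, cfg$glcm_levels)
    lab <- vapply(gt$blocks, block_label, integer(1),
                  labeling = labeling, min_frac = min_frac)
    if (lesion_classes) {
      arch <- match(p$spec$class_label, LESION_ARCHETYPES)
      lab[lab == 2L] <- 1L + arch  # 2,3,4 by archetype
    }
    Xs[[i]] <- feats
    ys[[i]] <- lab
    cases[[i]] <- rep(i, length(lab))
  }
  list(X = do.call(rbind, Xs), y = unlist(ys), case = unlist(cases),
       classes = if (lesion_classes) BLOCK_CLASSES else c("background", "lumen", "lesion"))
}

# class-rebalanced row indices: each class resampled (up or down) to
# `per_class` rows; draws from the current RNG
balance_indices <- function(y, per_class) {
  unlist(lapply(sort(unique(y)), function(cl) {
    i <- which(y == cl)
    if (length(i) >= per_class) sample(i, per_class)
    else c(i, sample(i, per_class - length(i), replace = TRUE))
  }))
}

#' Train the GA-initialized block-classifier segmenter
#'
#' Fits the feature scaler and the 5-class block head on a
#' class-rebalanced sample (`cfg$bpnn$balance_per_class` blocks per
#' class), then selects the graph-cut smoothness weight from
#' `cfg$graphcut$lambda_grid` by foreground Dice on the training pairs
#' (set the grid to a single value to skip the selection).
#'
#' @param train_pairs list of `labeled_image_pair` used for training
#' @param cfg full configuration, see [default_config()]
#' @param seed master seed for resampling, GA, and training
#' @return an `obstruseg_model`: feature scaler, trained network, selected
#'   lambda, configuration, and optimization histories
#' @export
train_segmenter <- function(train_pairs, cfg = default_config(), seed = 0L) {
  ds <- make_block_dataset(train_pairs, cfg$blocks$block_size,
                           cfg$blocks$overlap_step, lesion_classes = TRUE,
                           labeling = "majority", cfg = cfg$features)
  K <- length(BLOCK_CLASSES)
  scaler <- fit_scaler(ds$X)
  X <- apply_scaler(scaler, ds$X)
  idx <- with_seed(derive_seed(seed, 3L),
                   balance_indices(ds$y, cfg$bpnn$balance_per_class))
  Y <- matrix(0, length(idx), K)
  Y[cbind(seq_along(idx), ds$y[idx] + 1L)] <- 1
  fit <- optimize_bpnn(X[idx, , drop = FALSE], Y,
                       c(ncol(X), cfg$bpnn$n_hidden, K),
                       merge_lists(cfg$ga, list(seed = derive_seed(seed, 1L))),
                       cfg$bpnn)
  log_msg("trained block head: MSE %.4g (%s)",
          utils::tail(fit$train_history$mse, 1), fit$train_history$stop_reason,
          seed = seed)
  model <- structure(list(scaler = scaler, model = fit$model, cfg = cfg,
                          lambda = cfg$graphcut$lambda_grid[1],
                          ga_history = fit$ga_history,
                          train_history = fit$train_history,
                          classes = BLOCK_CLASSES),
                     class = "obstruseg_model")
  grid <- cfg$graphcut$lambda_grid
  if (isTRUE(cfg$graphcut$enabled) && length(grid) > 1) {
    dice <- vapply(grid, function(lam) {
      model$lambda <- lam
      mean(vapply(train_pairs, function(p) {
        m <- segment_image(model, p$image)$mask
        a <- m > 0; b <- p$truth > 0
        if (sum(a) + sum(b) == 0) 1 else 2 * sum(a & b) / (sum(a) + sum(b))
      }, numeric(1)))
    }, numeric(1))
    model$lambda <- grid[which.max(dice)]
    log_msg("selected graph-cut lambda = %g (training fg Dice %.3f)",
            model$lambda, max(dice), seed = seed)
  }
  model
}

#' Case-level category from block predictions
#'
#' Majority vote over blocks predicted as a lesion class.  A case is
#' called `"adhesive"` (the lesion-free archetype) when no lesion block
#' is predicted, or -- when the refined mask is supplied -- when the
#' segmented lesion region is smaller than `min_lesion_frac` of the
#' image: the smallest archetype lesion template occupies about 2% of
#' the image, so a region under 0.5% is segmentation noise, not a mass.
#' Vote ties break toward the earlier archetype.
#'
#' @param block_preds integer block labels (`0..4`)
#' @param lesion_area optional refined-mask lesion pixel count
#' @param n_pixels optional image pixel count (required with `lesion_area`)
#' @param min_lesion_frac minimal lesion area fraction for a mass call
#' @return archetype name
#' @export
classify_case <- function(block_preds, lesion_area = NULL, n_pixels = NULL,
                          min_lesion_frac = 0.005) {
  if (!is.null(lesion_area)) {
    check(!is.null(n_pixels), "n_pixels is required alongside lesion_area")
    if (lesion_area < min_lesion_frac * n_pixels) return("adhesive")
  }
  lesion <- block_preds[block_preds >= 2L]
  if (length(lesion) == 0) return("adhesive")
  counts <- tabulate(lesion - 1L, nbins = length(LESION_ARCHETYPES))
  LESION_ARCHETYPES[which.max(counts)]
}

#' Segment one image with a trained model
#'
#' @param model an `obstruseg_model`
#' @param image numeric intensity matrix in `[0,1]`
#' @return list: `mask` (0 background / 1 lumen / 2 lesion), `probs`
#'   (H x W x 3 averaged class probabilities), `block_preds` (5-class
#'   block labels), `case_class`, `grid`
#' @export
segment_image <- function(model, image) {
  check(inherits(model, "obstruseg_model"), "model must come from train_segmenter()")
  cfg <- model$cfg
  g <- extract_blocks(image, cfg$blocks$block_size, cfg$blocks$overlap_step)
  feats <- apply_scaler(model$scaler,
                        grid_features(g, cfg$features$hist_bins,
                                      cfg$features$glcm_levels))
  scores <- forward(model$model, feats)
  block_preds <- max.col(scores, "first") - 1L
  probs5 <- reassemble_probs(g, scores)
  h <- dim(probs5)[1]; w <- dim(probs5)[2]
  probs <- array(0, c(h, w, 3))
  probs[, , 1] <- probs5[, , 1]
  probs[, , 2] <- probs5[, , 2]
  probs[, , 3] <- probs5[, , 3] + probs5[, , 4] + probs5[, , 5]
  tot <- probs[, , 1] + probs[, , 2] + probs[, , 3]
  for (k in 1:3) probs[, , k] <- probs[, , k] / tot
  mask <- if (isTRUE(cfg$graphcut$enabled))
    graphcut_refine(unclass(image), probs, model$lambda, cfg$graphcut$sigma)
  else probs_argmax(probs)
  list(mask = mask, probs = probs, block_preds = block_preds,
       case_class = classify_case(block_preds, lesion_area = sum(mask == 2L),
                                  n_pixels = length(mask)),
       grid = g)
}

#' Evaluate a trained segmenter on labeled pairs
#'
#' @param model an `obstruseg_model`
#' @param pairs list of `labeled_image_pair`
#' @return list: per-case data frame `cases` (pixel accuracy, foreground
#'   Dice, predicted and true category), `mean_pixel_accuracy`,
#'   `mean_fg_dice`, `mean_fg_accuracy`, `recognition` (per-archetype
#'   rates and macro average)
#' @export
evaluate_segmenter <- function(model, pairs) {
  rows <- lapply(seq_along(pairs), function(i) {
    p <- pairs[[i]]
    seg <- segment_image(model, p$image)
    m <- seg_metrics(seg$mask, p$truth, labels = 0:2)
    fg <- seg_metrics(matrix(as.integer(seg$mask > 0), nrow(seg$mask)),
                      matrix(as.integer(p$truth > 0), nrow(p$truth)),
                      labels = 0:1)
    data.frame(case = i, truth_class = p$spec$class_label,
               pred_class = seg$case_class,
               pixel_accuracy = m$pixel_accuracy,
               fg_dice = fg$dice[["1"]],
               fg_accuracy = fg$pixel_accuracy)
  })
  cases <- do.call(rbind, rows)
  rec <- recognition_rate(cases$pred_class, cases$truth_class,
                          classes = PHANTOM_CLASSES)
  list(cases = cases,
       mean_pixel_accuracy = mean(cases$pixel_accuracy),
       mean_fg_dice = mean(cases$fg_dice),
       mean_fg_accuracy = mean(cases$fg_accuracy),
       recognition = rec)
}
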