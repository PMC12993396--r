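# The variant-scoring neural network (VS-NN): grouped stratified splitting,
# training of a feed-forward network with class weighting, scoring in [0,1]
# with a 0.5 decision threshold, evaluation with report-based TP/FN/FP
# definitions, and the TP-vs-FN feature contrast.

#' VS-NN model configuration
#'
#' @param hidden_sizes Hidden-layer widths of the feed-forward network.
#' @param epochs Training epochs (full-batch Adam steps).
#' @param learning_rate Adam step size.
#' @param class_weight Weight of positive rows in the loss; `NULL` (default)
#'   uses the negative:positive row ratio, countering the strong class
#'   imbalance of reanalysis training sets.
#' @param seed Integer seed fixing initialization (training itself is
#'   full-batch and therefore deterministic given the seed).
#' @param threshold Decision threshold on the pathogenicity score; scores
#'   greater than or equal to it are flagged.
#' @param patience Early-stopping patience in epochs, used only when a
#'   validation set is supplied to [train_model()].
#' @return A `vsnn_config` list.
#' @export
vsnn_config <- function(hidden_sizes = c(64, 16), epochs = 200,
                        learning_rate = 0.01, class_weight = NULL,
                        seed = 1L, threshold = 0.5, patience = 25L) {
  stopifnot(threshold > 0, threshold < 1, length(hidden_sizes) >= 1)
  structure(as.list(environment()), class = "vsnn_config")
}

#' Grouped, stratified train/validation split
#'
#' Reserves a fraction of the dataset for validation without letting any
#' proband straddle the split: probands are stratified by their strongest
#' label (P/LP over VUS over negatives-only), shuffled under the seed, and
#' assigned greedily so the validation row fraction tracks the target.
#'
#' @param dataset List with `rows`, `labels`, `groups` (and optionally `X`,
#'   `mask`) as built by [assemble_training_set()] / [encode_dataset()].
#' @param fraction Target validation fraction of rows (default 0.30).
#' @param seed Integer seed.
#' @return List with `train` and `validation` datasets of the same shape.
#' @export
split_dataset <- function(dataset, fraction = 0.30, seed = 1L) {
  groups <- dataset$groups
  labels <- dataset$labels
  probands <- unique(groups)
  if (length(probands) < 4) stop("too few proband groups to split")
  strat <- vapply(probands, function(p) {
    ls <- labels[groups == p]
    if (any(ls %in% c("pathogenic", "likely_pathogenic"))) "plp"
    else if (any(ls == "VUS")) "vus" else "neg"
  }, character(1))
  set.seed(seed)
  val_probands <- character(0)
  for (s in unique(strat)) {
    ps <- sample(probands[strat == s])
    sizes <- vapply(ps, function(p) sum(groups == p), numeric(1))
    target <- fraction * sum(sizes)
    cum <- cumsum(sizes)
    take <- which(cum <= target + max(sizes) / 2)
    if (length(take) == 0 && length(ps) > 1) take <- 1L
    val_probands <- c(val_probands, ps[take])
  }
  in_val <- groups %in% val_probands
  subset_ds <- function(keep) {
    out <- list(rows = dataset$rows[keep, , drop = FALSE],
                labels = dataset$labels[keep],
                groups = dataset$groups[keep])
    if (!is.null(dataset$X)) out$X <- dataset$X[keep, , drop = FALSE]
    if (!is.null(dataset$mask)) out$mask <- dataset$mask[keep, , drop = FALSE]
    out
  }
  list(train = subset_ds(!in_val), validation = subset_ds(in_val))
}

#' Attach the encoded feature matrix to a dataset
#'
#' @param dataset Output of [assemble_training_set()].
#' @param cohort,ontology,ic,schema,term_set Passed to [encode_features()].
#' @return The dataset with `X` and `mask` added.
#' @export
encode_dataset <- function(dataset, cohort, ontology, ic,
                           schema = default_feature_schema(),
                           term_set = "combined") {
  enc <- encode_features(dataset$rows, cohort, ontology, ic, schema,
                         term_set = term_set)
  dataset$X <- enc$X
  dataset$mask <- enc$mask
  dataset$schema <- enc$schema
  dataset
}

relu <- function(x) (x > 0) * x
sigmoid <- function(x) 1 / (1 + exp(-x))

mlp_init <- function(n_in, hidden, seed) {
  set.seed(seed)
  sizes <- c(n_in, hidden, 1L)
  lapply(seq_len(length(sizes) - 1L), function(i) {
    list(W = matrix(stats::rnorm(sizes[i] * sizes[i + 1],
                                 sd = sqrt(2 / sizes[i])),
                    nrow = sizes[i]),
         b = rep(0, sizes[i + 1]))
  })
}

mlp_forward <- function(layers, X) {
  acts <- list(X)
  n <- length(layers)
  for (i in seq_len(n)) {
    Z <- acts[[i]] %*% layers[[i]]$W
    Z <- sweep(Z, 2, layers[[i]]$b, `+`)
    acts[[i + 1]] <- if (i < n) relu(Z) else sigmoid(Z)
  }
  acts
}

weighted_bce <- function(p, y, w) {
  p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
  -sum(w * (y * log(p) + (1 - y) * log(1 - p))) / sum(w)
}

#' Train the variant-scoring network
#'
#' Trains a feed-forward network (rectifier hidden layers, logistic output)
#' on the binary objective positive (P/LP/VUS) versus negative with
#' class-weighted cross-entropy, full-batch Adam and seeded initialization.
#' The model stores the median imputer and standardizer fitted on its
#' training rows only. When a validation dataset is supplied, the epoch
#' with the lowest validation loss is kept (early stopping).
#'
#' @param dataset Encoded dataset (must carry `X` and `labels`).
#' @param config A [vsnn_config()].
#' @param validation Optional encoded validation dataset.
#' @return A `pgr_vsnn` model.
#' @export
train_model <- function(dataset, config = vsnn_config(), validation = NULL) {
  X_raw <- dataset$X
  y <- as.numeric(dataset$labels != "negative")
  if (length(unique(y)) < 2) stop("training labels are single-class")
  medians <- fit_imputer(X_raw)
  X <- apply_imputer(X_raw, medians)
  std <- fit_standardizer(X)
  X <- apply_standardizer(std, X)
  w_pos <- config$class_weight
  if (is.null(w_pos)) w_pos <- sum(y == 0) / max(1, sum(y == 1))
  w <- ifelse(y == 1, w_pos, 1)

  Xv <- NULL; yv <- NULL; wv <- NULL
  if (!is.null(validation)) {
    Xv <- apply_standardizer(std, apply_imputer(validation$X, medians))
    yv <- as.numeric(validation$labels != "negative")
    wv <- ifelse(yv == 1, w_pos, 1)
  }

  layers <- mlp_init(ncol(X), config$hidden_sizes, config$seed)
  m <- lapply(layers, function(l) list(W = l$W * 0, b = l$b * 0))
  v <- m
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  lr <- config$learning_rate
  n <- nrow(X)
  history <- data.frame(epoch = integer(), loss = numeric(),
                        val_loss = numeric())
  best <- list(loss = Inf, layers = layers, epoch = 0L)
  bad_epochs <- 0L

  for (epoch in seq_len(config$epochs)) {
    acts <- mlp_forward(layers, X)
    p <- acts[[length(acts)]][, 1]
    loss <- weighted_bce(p, y, w)
    # backprop
    delta <- matrix(w * (p - y) / sum(w), ncol = 1)
    grads <- vector("list", length(layers))
    for (i in rev(seq_along(layers))) {
      grads[[i]] <- list(W = crossprod(acts[[i]], delta),
                         b = colSums(delta))
      if (i > 1) {
        delta <- (delta %*% t(layers[[i]]$W)) * (acts[[i]] > 0)
      }
    }
    t_adam <- epoch
    for (i in seq_along(layers)) {
      for (slot in c("W", "b")) {
        g <- grads[[i]][[slot]]
        m[[i]][[slot]] <- b1 * m[[i]][[slot]] + (1 - b1) * g
        v[[i]][[slot]] <- b2 * v[[i]][[slot]] + (1 - b2) * g^2
        mh <- m[[i]][[slot]] / (1 - b1^t_adam)
        vh <- v[[i]][[slot]] / (1 - b2^t_adam)
        layers[[i]][[slot]] <- layers[[i]][[slot]] - lr * mh / (sqrt(vh) + eps)
      }
    }
    val_loss <- NA_real_
    if (!is.null(Xv)) {
      pv <- mlp_forward(layers, Xv)
      val_loss <- weighted_bce(pv[[length(pv)]][, 1], yv, wv)
      if (val_loss < best$loss) {
        best <- list(loss = val_loss, layers = layers, epoch = epoch)
        bad_epochs <- 0L
      } else {
        bad_epochs <- bad_epochs + 1L
        if (bad_epochs >= config$patience) {
          history <- rbind(history, data.frame(epoch = epoch, loss = loss,
                                               val_loss = val_loss))
          break
        }
      }
    }
    history <- rbind(history, data.frame(epoch = epoch, loss = loss,
                                         val_loss = val_loss))
  }
  if (!is.null(Xv) && is.finite(best$loss)) layers <- best$layers
  structure(list(layers = layers, imputer = medians, standardizer = std,
                 feature_names = colnames(X_raw), config = config,
                 history = history, schema_version = "1"),
            class = "pgr_vsnn")
}

#' Retrain the final model on the full dataset
#'
#' After evaluation on the held-out fraction, the production model is
#' refit on every labeled row with the same configuration.
#'
#' @param dataset Full encoded dataset.
#' @param config A [vsnn_config()].
#' @return A `pgr_vsnn` model.
#' @export
retrain_full <- function(dataset, config = vsnn_config()) {
  train_model(dataset, config, validation = NULL)
}

#' @export
print.pgr_vsnn <- function(x, ...) {
  cat(sprintf("<pgr_vsnn> %d features -> %s -> 1; %d epochs trained\n",
              length(x$feature_names),
              paste(x$config$hidden_sizes, collapse = "-"),
              max(x$history$epoch)))
  invisible(x)
}

#' Score candidate feature vectors
#'
#' @param model A trained `pgr_vsnn`.
#' @param X Raw (unimputed, unstandardized) feature matrix whose columns
#'   match the model's schema.
#' @return Data frame with `score` in \[0, 1\] and `flagged`
#'   (score at or above the model threshold; the threshold is inclusive).
#' @export
predict_scores <- function(model, X) {
  if (is.null(dim(X))) X <- matrix(X, nrow = 1,
                                   dimnames = list(NULL, model$feature_names))
  if (!identical(colnames(X), model$feature_names)) {
    stop("feature matrix does not match the model schema")
  }
  Xs <- apply_standardizer(model$standardizer, apply_imputer(X, model$imputer))
  acts <- mlp_forward(model$layers, Xs)
  score <- acts[[length(acts)]][, 1]
  data.frame(score = score, flagged = score >= model$config$threshold)
}

#' Rank-statistic AUC
#'
#' Mann-Whitney AUC with midrank tie handling.
#'
#' @param scores Numeric scores.
#' @param positive Logical vector of the same length.
#' @return AUC in \[0, 1\], or `NA` if either class is empty.
#' @export
auc_rank <- function(scores, positive) {
  n1 <- sum(positive); n0 <- sum(!positive)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(scores)
  (sum(r[positive]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Evaluate scores against reported labels
#'
#' True positives are reported variants scoring at or above the threshold;
#' false negatives are reported variants scoring below it; false positives
#' are unreported variants scoring at or above it. Metrics are computed for
#' the pooled positive set and separately with positives restricted to
#' P/LP or to VUS (the false-positive set is shared, as all classes are
#' called from the same score).
#'
#' @param scores Numeric pathogenicity scores.
#' @param labels Character labels (`pathogenic`, `likely_pathogenic`,
#'   `VUS`, `negative`).
#' @param threshold Decision threshold (inclusive), default 0.5.
#' @return Data frame with one row per class (`pooled`, `PLP`, `VUS`):
#'   confusion counts, precision, recall and rank AUC (`NA` when
#'   undefined).
#' @export
evaluate_model <- function(scores, labels, threshold = 0.5) {
  stopifnot(length(scores) == length(labels))
  called <- scores >= threshold
  neg <- labels == "negative"
  fp <- sum(called & neg)
  class_sets <- list(pooled = !neg,
                     PLP = labels %in% c("pathogenic", "likely_pathogenic"),
                     VUS = labels == "VUS")
  rows <- lapply(names(class_sets), function(cl) {
    pos <- class_sets[[cl]]
    tp <- sum(called & pos)
    fn <- sum(!called & pos)
    keep <- pos | neg
    data.frame(class = cl, n_pos = sum(pos), n_neg = sum(neg),
               tp = tp, fn = fn, fp = fp,
               precision = if (tp + fp == 0) NA_real_ else tp / (tp + fp),
               recall = if (tp + fn == 0) NA_real_ else tp / (tp + fn),
               auc = auc_rank(scores[keep], pos[keep]),
               threshold = threshold, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Feature contrast between true-positive and false-negative variants
#'
#' Per feature: a two-sided Wilcoxon rank-sum test between the TP and FN
#' rows, Benjamini-Hochberg adjustment across features, and the direction
#' of the shift (sign of the TP minus FN median difference). Features that
#' are constant across both groups are reported with `p = 1`.
#'
#' @param tp_X,fn_X Feature matrices of the two groups (same columns).
#' @return Data frame sorted by adjusted q: `feature`, `p`, `q`,
#'   `direction`, `median_tp`, `median_fn`. Groups smaller than 3 rows
#'   yield a warning and an empty table.
#' @export
feature_contrast <- function(tp_X, fn_X) {
  if (nrow(tp_X) < 3 || nrow(fn_X) < 3) {
    warning("group of size < 3; feature contrast skipped", call. = FALSE)
    return(data.frame(feature = character(), p = numeric(), q = numeric(),
                      direction = character(), median_tp = numeric(),
                      median_fn = numeric(), stringsAsFactors = FALSE))
  }
  stats_rows <- lapply(colnames(tp_X), function(f) {
    a <- tp_X[, f]; b <- fn_X[, f]
    a <- a[!is.na(a)]; b <- b[!is.na(b)]
    p <- if (length(a) == 0 || length(b) == 0 ||
             (length(unique(c(a, b))) < 2)) 1 else wilcoxon_rank_sum(a, b)$p
    m_tp <- stats::median(a); m_fn <- stats::median(b)
    data.frame(feature = f, p = p,
               direction = if (isTRUE(m_tp > m_fn)) "up"
                           else if (isTRUE(m_tp < m_fn)) "down" else "none",
               median_tp = m_tp, median_fn = m_fn, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, stats_rows)
  out$q <- benjamini_hochberg(out$p)
  out[order(out$q, out$p), c("feature", "p", "q", "direction",
                             "median_tp", "median_fn")]
}
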