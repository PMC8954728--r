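#' Architecture of the dual-branch affinity network
#'
#' Each branch applies three blocks of (3x3 valid convolution with ReLU,
#' then 2x2 max-pooling) to its single-channel signature image and
#' flattens the result; the two flatten vectors are concatenated and fed
#' through dropout, a ReLU dense layer, dropout again and a final linear
#' unit that outputs the predicted affinity.  With the default filter
#' counts (32, 32, 32) per branch the molecule branch (36x36 input)
#' flattens to 2*2*32 = 128 units, the protein branch (97x97) to
#' 10*10*32 = 3200, and the concatenation to 3328.
#'
#' `strict` enforces that computed concatenation width of 3328; any other
#' configuration is rejected with the width it would produce.
#'
#' @param filters Integer vector of three per-block filter counts (shared
#'   by both branches).
#' @param hidden Width of the dense ReLU layer.
#' @param dropout Dropout rate applied before and after the dense layer.
#' @param mol_side,prot_side Input image sides.
#' @param strict Enforce the reference concatenation width of 3328.
#' @return A `sigdta_arch` list including the derived `mol_flat`,
#'   `prot_flat` and `concat` widths.
#' @examples
#' architecture_spec()$concat  # 3328
#' @export
architecture_spec <- function(filters = c(32, 32, 32), hidden = 512,
                              dropout = 0.4, mol_side = 36, prot_side = 97,
                              strict = FALSE) {
  filters <- as.integer(filters)
  stopifnot(length(filters) == 3, all(filters >= 1),
            hidden >= 1, dropout >= 0, dropout < 1)
  flat_side <- function(side) {
    s <- as.integer(side)
    for (i in 1:3) {
      s <- s - 2L          # 3x3 valid convolution
      if (s < 2L) stop(sprintf("input side %d collapses inside the network",
                               side))
      s <- s %/% 2L        # 2x2 max-pool, floor
    }
    s
  }
  mol_flat <- flat_side(mol_side)^2 * filters[3]
  prot_flat <- flat_side(prot_side)^2 * filters[3]
  concat <- mol_flat + prot_flat
  if (strict && concat != 3328L)
    stop(sprintf(
      "strict mode: computed concatenation width %d != reference 3328",
      concat))
  structure(list(filters = filters, hidden = as.integer(hidden),
                 dropout = dropout, mol_side = as.integer(mol_side),
                 prot_side = as.integer(prot_side), mol_flat = mol_flat,
                 prot_flat = prot_flat, concat = concat),
            class = "sigdta_arch")
}

#' Training configuration
#'
#' Adam hyperparameters and schedule for minimizing the mean squared
#' error.  The defaults are the reference protocol: learning rate 0.001,
#' beta1 0.9, beta2 0.999, epsilon 1e-7, batch size 256, 1000 epochs.
#' `patience` enables early stopping on the validation loss (number of
#' epochs without improvement tolerated before halting); `Inf` disables
#' it, which is the reference fixed-epoch protocol.
#'
#' @param lr,beta1,beta2,epsilon Adam parameters.
#' @param batch_size Minibatch size.
#' @param epochs Number of passes over the training split.
#' @param patience Early-stopping patience in epochs, or `Inf`.
#' @param seed Seed for weight initialization, shuffling and dropout.
#' @return A `sigdta_train_config` list.
#' @export
training_config <- function(lr = 0.001, beta1 = 0.9, beta2 = 0.999,
                            epsilon = 1e-7, batch_size = 256, epochs = 1000,
                            patience = Inf, seed = 1) {
  stopifnot(lr > 0, beta1 > 0, beta1 < 1, beta2 > 0, beta2 < 1, epsilon > 0,
            batch_size >= 1, epochs >= 1, patience >= 1)
  structure(list(lr = lr, beta1 = beta1, beta2 = beta2, epsilon = epsilon,
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), patience = patience,
                 seed = as.integer(seed)),
            class = "sigdta_train_config")
}

he_init <- function(nr, nc, fan_in) matrix(rnorm(nr * nc, 0, sqrt(2 / fan_in)), nr, nc)

#' Build a trainable dual-branch model
#'
#' Initializes the weights of the architecture (He-normal for the ReLU
#' convolution and dense layers, scaled-normal for the linear output,
#' zero biases) under the given seed.  Convolution kernels are stored in
#' im2col layout: a (9 * in_channels) x out_channels matrix per layer.
#'
#' @param arch An [architecture_spec()].
#' @param seed Integer seed for the initialization.
#' @return A `sigdta_model`: list with `arch` and the `params` list.
#' @export
build_model <- function(arch = architecture_spec(), seed = 1) {
  stopifnot(inherits(arch, "sigdta_arch"))
  set.seed(seed)
  f <- arch$filters
  params <- list(
    mW1 = he_init(9, f[1], 9), mb1 = numeric(f[1]),
    mW2 = he_init(9 * f[1], f[2], 9 * f[1]), mb2 = numeric(f[2]),
    mW3 = he_init(9 * f[2], f[3], 9 * f[2]), mb3 = numeric(f[3]),
    pW1 = he_init(9, f[1], 9), pb1 = numeric(f[1]),
    pW2 = he_init(9 * f[1], f[2], 9 * f[1]), pb2 = numeric(f[2]),
    pW3 = he_init(9 * f[2], f[3], 9 * f[2]), pb3 = numeric(f[3]),
    Wd = he_init(arch$concat, arch$hidden, arch$concat),
    bd = numeric(arch$hidden),
    Wo = matrix(rnorm(arch$hidden, 0, sqrt(1 / arch$hidden)), ncol = 1),
    bo = 0
  )
  structure(list(arch = arch, params = params, seed = seed),
            class = "sigdta_model")
}

#' @export
print.sigdta_model <- function(x, ...) {
  npar <- sum(vapply(x$params, length, 0L))
  cat(sprintf(
    "<dual-branch CNN: %dx%d + %dx%d inputs, concat %d, %d parameters>\n",
    x$arch$mol_side, x$arch$mol_side, x$arch$prot_side, x$arch$prot_side,
    x$arch$concat, npar))
  invisible(x)
}

gather_batch <- function(images, pairs, idx) {
  list(mol = images$mol[, , pairs$drug[idx], drop = FALSE],
       prot = images$prot[, , pairs$target[idx], drop = FALSE],
       y = pairs$y[idx])
}

#' Predict affinities for drug-target pairs
#'
#' Inference-mode forward pass (dropout inactive).
#'
#' @param object A `sigdta_model`.
#' @param images Image stacks from [encode_table()].
#' @param pairs `data.frame` with `drug` and `target` index columns (as
#'   from [interactions()]).
#' @param batch_size Samples per forward pass.
#' @param ... Unused.
#' @return Numeric vector of predicted affinities.
#' @export
predict.sigdta_model <- function(object, images, pairs, batch_size = 512, ...) {
  n <- nrow(pairs)
  out <- numeric(n)
  for (lo in seq(1L, n, by = batch_size)) {
    idx <- lo:min(lo + batch_size - 1L, n)
    b <- gather_batch(images, pairs, idx)
    out[idx] <- cnn_predict(object$params, b$mol, b$prot)
  }
  out
}

#' Fit a model by minibatch Adam on the mean squared error
#'
#' Shuffles the training pairs each epoch, assembles image minibatches,
#' applies inverted dropout with freshly drawn masks, and updates all
#' weights with Adam.  When a validation set is given, the validation MSE
#' is tracked per epoch and early stopping with `config$patience` returns
#' the weights of the best validation epoch.
#'
#' @param model A `sigdta_model`.
#' @param images Image stacks from [encode_table()].
#' @param pairs Training pairs (`drug`, `target`, `y`).
#' @param validation Optional validation pairs in the same format.
#' @param config A [training_config()].
#' @param verbose Print per-epoch losses.
#' @return The fitted model, with a `history` data.frame (`epoch`, `loss`,
#'   `val_loss`) attached.
#' @export
fit_model <- function(model, images, pairs, validation = NULL,
                      config = training_config(), verbose = FALSE) {
  stopifnot(inherits(model, "sigdta_model"),
            inherits(config, "sigdta_train_config"))
  n <- nrow(pairs)
  if (n == 0) stop("empty training split")
  p <- model$params
  mstate <- lapply(p, function(x) x * 0)
  vstate <- lapply(p, function(x) x * 0)
  tstep <- 0
  keep <- 1 - model$arch$dropout
  concat <- model$arch$concat
  hidden <- model$arch$hidden
  set.seed(config$seed)
  history <- data.frame(epoch = integer(), loss = numeric(),
                        val_loss = numeric())
  best_val <- Inf
  best_params <- NULL
  stall <- 0

  for (epoch in seq_len(config$epochs)) {
    ord <- sample.int(n)
    tot <- 0
    for (lo in seq(1L, n, by = config$batch_size)) {
      idx <- ord[lo:min(lo + config$batch_size - 1L, n)]
      nb <- length(idx)
      b <- gather_batch(images, pairs, idx)
      if (keep < 1) {
        m1 <- matrix((runif(nb * concat) < keep) / keep, nb, concat)
        m2 <- matrix((runif(nb * hidden) < keep) / keep, nb, hidden)
      } else {
        m1 <- matrix(1, nb, concat)
        m2 <- matrix(1, nb, hidden)
      }
      r <- cnn_forward_backward(p, b$mol, b$prot, b$y, m1, m2)
      tstep <- tstep + 1
      bc1 <- 1 - config$beta1^tstep
      bc2 <- 1 - config$beta2^tstep
      for (nm in names(p)) {
        g <- r$grads[[nm]]
        mstate[[nm]] <- config$beta1 * mstate[[nm]] + (1 - config$beta1) * g
        vstate[[nm]] <- config$beta2 * vstate[[nm]] + (1 - config$beta2) * g * g
        p[[nm]] <- p[[nm]] - config$lr * (mstate[[nm]] / bc1) /
          (sqrt(vstate[[nm]] / bc2) + config$epsilon)
      }
      tot <- tot + r$loss * nb
    }
    train_loss <- tot / n
    val_loss <- NA_real_
    if (!is.null(validation)) {
      model$params <- p
      val_pred <- predict(model, images, validation)
      val_loss <- mse(validation$y, val_pred)
      if (val_loss < best_val) {
        best_val <- val_loss
        best_params <- p
        stall <- 0
      } else {
        stall <- stall + 1
      }
    }
    history <- rbind(history, data.frame(epoch = epoch, loss = train_loss,
                                         val_loss = val_loss))
    if (verbose)
      message(sprintf("epoch %d: loss %.5f val %.5f", epoch, train_loss,
                      val_loss))
    if (!is.null(validation) && is.finite(config$patience) &&
        stall >= config$patience) {
      if (verbose) message(sprintf("early stop at epoch %d", epoch))
      break
    }
  }
  model$params <- if (!is.null(validation) && !is.null(best_params) &&
                      is.finite(config$patience)) best_params else p
  model$history <- history
  model
}

#' Train one cross-validation fold and evaluate it on the held-out test set
#'
#' Two-phase protocol.  Phase 1 trains on the four training parts of the
#' plan with the fold's own part as validation, and persists the fitted
#' model to `checkpoint` (standard R serialization).  Phase 2 reloads the
#' persisted model and evaluates it once on the held-out test part with
#' the full metric suite.
#'
#' @param table A `sigdta_table`.
#' @param plan A `sigdta_plan`.
#' @param fold Fold number in 1..5.
#' @param arch An [architecture_spec()].
#' @param config A [training_config()]; the fold index is folded into its
#'   seed so that folds get distinct initializations.
#' @param images Optional pre-encoded [encode_table()] result.
#' @param checkpoint Path for the persisted phase-1 model (a temporary
#'   file by default).
#' @return List with `fold`, `model`, `history`, test `metrics` (one-row
#'   data.frame) and test `predictions`.
#' @export
train_fold <- function(table, plan, fold, arch = architecture_spec(),
                       config = training_config(), images = NULL,
                       checkpoint = tempfile(fileext = ".rds")) {
  stopifnot(inherits(table, "sigdta_table"), inherits(plan, "sigdta_plan"))
  images <- images %||% encode_table(table)
  ints <- interactions(table)
  split <- fold_split(plan, fold)
  if (any(lengths(split) == 0)) stop("empty split in the experiment plan")
  fold_seed <- config$seed + fold - 1L
  fold_config <- config
  fold_config$seed <- fold_seed

  # phase 1: train on four parts, validate on the fold's own part, persist
  model <- build_model(arch, seed = fold_seed)
  model <- fit_model(model, images, ints[split$train, ],
                     validation = ints[split$validation, ],
                     config = fold_config)
  saveRDS(model, checkpoint)

  # phase 2: evaluate the persisted model on the held-out test part
  persisted <- readRDS(checkpoint)
  test_pairs <- ints[split$test, ]
  preds <- predict(persisted, images, test_pairs)
  metrics <- evaluate_predictions(test_pairs$y, preds, dataset = table$kind)
  list(fold = fold, model = persisted, history = model$history,
       metrics = metrics, predictions = preds, checkpoint = checkpoint)
}

#' 5-fold cross-validation with a held-out test set
#'
#' Runs [train_fold()] for each of the five folds and collects the
#' held-out test metrics into a summary table with per-fold rows plus
#' their mean and standard deviation, the usual benchmark report shape.
#'
#' @inheritParams train_fold
#' @return List with `folds` (the five [train_fold()] results) and
#'   `summary` (data.frame of metrics; rows fold1..fold5, mean, sd).
#' @export
cross_validate <- function(table, plan, arch = architecture_spec(),
                           config = training_config(), images = NULL) {
  images <- images %||% encode_table(table)
  results <- lapply(seq_along(plan$folds), function(k)
    train_fold(table, plan, k, arch, config, images))
  metrics <- do.call(rbind, lapply(results, `[[`, "metrics"))
  summary <- rbind(metrics,
                   colMeans(metrics, na.rm = TRUE),
                   vapply(metrics, function(col) sd(col, na.rm = TRUE), 0))
  rownames(summary) <- c(paste0("fold", seq_len(nrow(metrics))), "mean", "sd")
  list(folds = results, summary = summary)
}
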