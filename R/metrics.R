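#' Kd to pKd transform
#'
#' Converts a dissociation constant measured in nanomolar units to its
#' negative molar log, `pKd = -log10(Kd / 1e9)`.  A Kd of 100 nM maps to
#' pKd = 7, the conventional binding threshold for the Davis benchmark.
#'
#' @param kd Numeric vector of Kd values in nM; must be strictly positive.
#' @return Numeric vector of pKd values.
#' @examples
#' pkd_transform(c(1e9, 100, 10000))  # 0 7 5
#' @export
pkd_transform <- function(kd) {
  if (any(!is.finite(kd)) || any(kd <= 0))
    stop("Kd values must be finite and strictly positive")
  -log10(kd / 1e9)
}

check_pairs <- function(obs, pred) {
  if (length(obs) != length(pred))
    stop(sprintf("observed (%d) and predicted (%d) lengths differ",
                 length(obs), length(pred)))
  if (length(obs) == 0) stop("empty affinity pair set")
  if (anyNA(obs) || anyNA(pred)) stop("affinity pairs must not contain NA")
}

#' Mean squared error
#'
#' @param obs,pred Numeric vectors of equal length.
#' @return The average squared difference; 0 iff the vectors are identical.
#' @export
mse <- function(obs, pred) {
  check_pairs(obs, pred)
  mean((pred - obs)^2)
}

#' Concordance index
#'
#' Probability that two randomly chosen pairs are ranked by the predictions
#' in the same order as by the true affinities.  Over every ordered pair
#' `(i, j)` with `obs[i] > obs[j]`, the step function of the prediction
#' difference contributes 1 if `pred[i] > pred[j]`, 0.5 if tied, else 0;
#' the sum is divided by the number N of such comparable pairs.  Pairs tied
#' in the true affinity are not comparable and are excluded from N.  The
#' index is invariant under strictly increasing transforms of the
#' predictions.
#'
#' @param obs,pred Numeric vectors of equal length (at least 2).
#' @return A value in `[0, 1]`.
#' @examples
#' concordance_index(c(1, 2, 3), c(0.1, 0.2, 0.3))  # 1
#' @export
concordance_index <- function(obs, pred) {
  check_pairs(obs, pred)
  n <- length(obs)
  num <- 0
  N <- 0
  step <- max(1L, 4e6 %/% n)
  for (lo in seq(1L, n, by = step)) {
    rows <- lo:min(lo + step - 1L, n)
    comp <- outer(obs[rows], obs, ">")
    dp <- outer(pred[rows], pred, "-")
    h <- (dp > 0) + 0.5 * (dp == 0)
    num <- num + sum(h[comp])
    N <- N + sum(comp)
  }
  if (N == 0)
    stop("all observed affinities are equal: no comparable pairs")
  num / N
}

#' rm2 external-validation metric
#'
#' Combines the squared correlation between observation and prediction with
#' intercept (`r2`) and without intercept (`r02`, using the through-origin
#' slope `k`):
#' `rm2 = r2 * (1 - sqrt(r2 - r02))`.  Values above 0.5 are conventionally
#' read as an acceptable regression model.  When `r02 > r2` the square root
#' argument is clamped at zero (giving `rm2 = r2`) and a warning is issued,
#' since the formula is undefined there.
#'
#' @param obs,pred Numeric vectors of equal length with non-degenerate
#'   variance; `sum(pred^2)` must be positive.
#' @return A `sigdta_rm2` list with `rm2` and the intermediates `r2`, `r02`
#'   and `k`.
#' @examples
#' rm_squared(1:5, 1:5)$rm2  # 1
#' @export
rm_squared <- function(obs, pred) {
  check_pairs(obs, pred)
  if (sd(obs) == 0 || sd(pred) == 0)
    stop("zero variance in observed or predicted values")
  sp2 <- sum(pred^2)
  if (sp2 == 0) stop("predictions are identically zero")
  do <- obs - mean(obs)
  dp <- pred - mean(pred)
  r2 <- sum(dp * do)^2 / (sum(do^2) * sum(dp^2))
  k <- sum(obs * pred) / sp2
  r02 <- 1 - sum((obs - k * pred)^2) / sum(do^2)
  arg <- r2 - r02
  if (arg < 0) {
    warning(sprintf("r2 (%.4f) < r02 (%.4f); clamping sqrt argument at 0",
                    r2, r02))
    arg <- 0
  }
  structure(list(rm2 = r2 * (1 - sqrt(arg)), r2 = r2, r02 = r02, k = k),
            class = "sigdta_rm2")
}

#' @export
print.sigdta_rm2 <- function(x, ...) {
  cat(sprintf("rm2 = %.4f  (r2 = %.4f, r02 = %.4f, k = %.4f)\n",
              x$rm2, x$r2, x$r02, x$k))
  invisible(x)
}

#' Binarize affinities at the benchmark threshold
#'
#' Davis affinities (pKd) are labelled 1 when `>= 7` (Kd of 100 nM or
#' stronger); KIBA scores are labelled 1 when strictly `< 12.1` (lower KIBA
#' score means stronger binding).  Synthetic data follows the Davis rule,
#' matching its pKd-like affinity scale.
#'
#' @param values Numeric vector of affinities.
#' @param dataset `"davis"`, `"kiba"` or `"synthetic"`.
#' @return Integer vector of 0/1 labels, empty for empty input.
#' @examples
#' binarize(c(6.99, 7, 7.01), "davis")  # 0 1 1
#' binarize(12.1, "kiba")               # 0
#' @export
binarize <- function(values, dataset = c("davis", "kiba", "synthetic")) {
  dataset <- match.arg(dataset)
  if (dataset == "kiba") as.integer(values < 12.1) else as.integer(values >= 7)
}

#' Area under the precision-recall curve
#'
#' Step-wise (non-interpolated) summation: scores are swept from high to
#' low, tied scores are grouped into a single threshold, and the area is
#' `sum((R_i - R_{i-1}) * P_i)` over thresholds (average precision).  A
#' constant score yields a single PR point and an area equal to the
#' positive-class prevalence.
#'
#' @param labels 0/1 vector; both classes must be present.
#' @param scores Numeric vector; larger scores mean "more positive".
#' @return A value in `[0, 1]`.
#' @export
auc_pr <- function(labels, scores) {
  check_pairs(labels, scores)
  if (!all(labels %in% c(0, 1))) stop("labels must be 0/1")
  P <- sum(labels == 1)
  if (P == 0 || P == length(labels))
    stop("AUC-PR needs both classes present")
  o <- order(scores, decreasing = TRUE)
  lab <- labels[o]
  sc <- scores[o]
  grp_end <- which(diff(sc) != 0)
  grp_end <- c(grp_end, length(sc))
  tp <- cumsum(lab)[grp_end]
  pp <- grp_end
  prec <- tp / pp
  rec <- tp / P
  sum(diff(c(0, rec)) * prec)
}

#' Classification accuracy
#'
#' @param labels,predicted 0/1 vectors of equal length.
#' @return Fraction of agreeing positions.
#' @export
accuracy <- function(labels, predicted) {
  check_pairs(labels, predicted)
  mean(labels == predicted)
}

#' Evaluate predictions with the full benchmark metric suite
#'
#' Computes MSE, concordance index, rm2, AUC-PR and accuracy for a set of
#' observed/predicted affinities.  AUC-PR and accuracy are computed after
#' [binarize()]-ing the observations into labels; for KIBA the prediction
#' score is negated for the PR sweep since lower KIBA scores mean stronger
#' binding.  Metrics whose preconditions fail on degenerate data (constant
#' observations for CI/rm2, single-class labels for AUC-PR) are reported as
#' `NA` with a warning rather than aborting the whole evaluation.
#'
#' @param obs,pred Numeric vectors of equal length.
#' @param dataset `"davis"`, `"kiba"` or `"synthetic"` (Davis-style rule).
#' @return A one-row `data.frame` with columns `mse`, `ci`, `rm2`, `aucpr`,
#'   `acc`.
#' @export
evaluate_predictions <- function(obs, pred,
                                 dataset = c("davis", "kiba", "synthetic")) {
  dataset <- match.arg(dataset)
  check_pairs(obs, pred)
  relax <- function(expr, what) {
    tryCatch(expr, error = function(e) {
      warning(sprintf("%s not computable: %s", what, conditionMessage(e)),
              call. = FALSE)
      NA_real_
    })
  }
  lab <- binarize(obs, dataset)
  sweep_score <- if (dataset == "kiba") -pred else pred
  data.frame(
    mse = mse(obs, pred),
    ci = relax(concordance_index(obs, pred), "concordance index"),
    rm2 = relax(rm_squared(obs, pred)$rm2, "rm2"),
    aucpr = relax(auc_pr(lab, sweep_score), "AUC-PR"),
    acc = accuracy(lab, binarize(pred, dataset))
  )
}
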