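tiny_arch <- function() {
  architecture_spec(filters = c(3, 3, 3), hidden = 5,
                    mol_side = 22, prot_side = 30)
}

test_that("default architecture reproduces the reference widths", {
  arch <- architecture_spec()
  expect_equal(arch$mol_flat, 128L)    # 36 -> 34 -> 17 -> 15 -> 7 -> 5 -> 2
  expect_equal(arch$prot_flat, 3200L)  # 97 -> 95 -> 47 -> 45 -> 22 -> 20 -> 10
  expect_equal(arch$concat, 3328L)

  # strict mode rejects any deviation, naming the width it computes
  expect_error(architecture_spec(filters = c(16, 16, 16), strict = TRUE),
               "1664")
  expect_silent(architecture_spec(strict = TRUE))
  # concat width propagates into the weight shapes
  m <- build_model(architecture_spec(), seed = 1)
  expect_equal(nrow(m$params$Wd), 3328L)
})

test_that("a built model maps an image pair to one finite affinity", {
  arch <- tiny_arch()
  m <- build_model(arch, seed = 3)
  xm <- array(0, c(22, 22, 1))
  xp <- array(0, c(30, 30, 1))
  out <- predict(m, list(mol = xm, prot = xp),
                 data.frame(drug = 1L, target = 1L))
  expect_length(out, 1)
  expect_true(is.finite(out))

  # mismatched weights vs. input sides are rejected with the computed width
  big <- build_model(architecture_spec(), seed = 1)
  expect_error(predict(big, list(mol = xm, prot = xp),
                       data.frame(drug = 1L, target = 1L)),
               "concat width")
})

test_that("analytic gradients agree with finite differences", {
  set.seed(42)
  arch <- tiny_arch()
  m <- build_model(arch, seed = 11)
  n <- 5
  xm <- array(runif(22 * 22 * n), c(22, 22, n))
  xp <- array(runif(30 * 30 * n), c(30, 30, n))
  y <- rnorm(n)
  m1 <- matrix(rbinom(n * arch$concat, 1, 0.7) / 0.7, n)
  m2 <- matrix(rbinom(n * arch$hidden, 1, 0.7) / 0.7, n)
  r <- sigdta:::cnn_forward_backward(m$params, xm, xp, y, m1, m2)
  lossfn <- function(p) sigdta:::cnn_forward_backward(p, xm, xp, y, m1, m2)$loss

  eps <- 1e-3
  for (nm in c("mW1", "mW3", "pW2", "Wd", "Wo", "bd")) {
    g <- r$grads[[nm]]
    idx <- which(abs(g) > 0.02)           # entries above the float noise floor
    idx <- idx[seq_len(min(4, length(idx)))]
    for (i in idx) {
      p2 <- m$params
      p2[[nm]][i] <- p2[[nm]][i] + eps
      lp <- lossfn(p2)
      p2[[nm]][i] <- m$params[[nm]][i] - eps
      lm_ <- lossfn(p2)
      fd <- (lp - lm_) / (2 * eps)
      expect_equal(g[i], fd, tolerance = 0.02)
    }
  }
})

test_that("training is reproducible under a fixed seed", {
  tb <- tiny_table(seed = 31)
  images <- encode_table(tb)
  ints <- interactions(tb)
  arch <- architecture_spec(filters = c(4, 4, 4), hidden = 16)
  cfg <- training_config(epochs = 2, batch_size = 16, seed = 9)
  f1 <- fit_model(build_model(arch, 9), images, ints, config = cfg)
  f2 <- fit_model(build_model(arch, 9), images, ints, config = cfg)
  expect_identical(f1$history, f2$history)
  expect_equal(f1$params, f2$params, tolerance = 1e-12)
})

test_that("train_fold runs the two-phase protocol and records history", {
  tb <- tiny_table(seed = 17)
  plan <- make_plan(tb, seed = 17)
  cfg <- training_config(epochs = 1, batch_size = 32, seed = 2)
  ckpt <- withr::local_tempfile(fileext = ".rds")
  res <- train_fold(tb, plan, 1, config = cfg, checkpoint = ckpt)
  expect_equal(nrow(res$history), 1)
  expect_true(is.finite(res$history$loss))
  expect_true(is.finite(res$history$val_loss))
  expect_true(file.exists(ckpt))          # phase 1 persisted the model
  persisted <- readRDS(ckpt)
  expect_s3_class(persisted, "sigdta_model")
  expect_length(res$predictions, length(plan$test))
  expect_named(res$metrics, c("mse", "ci", "rm2", "aucpr", "acc"))
})

test_that("the network memorizes a small fixed set (overfit capacity)", {
  # capacity check: dropout off (it is regularization, the opposite of what
  # is measured here) and noiseless targets, i.e. a clean deterministic
  # function of the two input images
  tb <- tiny_table(seed = 23, n_drugs = 16, n_targets = 4, density = 1,
                   noise_sd = 0)
  images <- encode_table(tb)
  ints <- interactions(tb)                 # 64 fixed pairs
  cfg <- training_config(epochs = 200, batch_size = 64, seed = 5)
  m <- fit_model(build_model(architecture_spec(dropout = 0), 5), images,
                 ints, config = cfg)
  final_mse <- mse(ints$y, predict(m, images, ints))
  expect_lt(final_mse, 0.01)
})

test_that("observation noise degrades the trained model's test ranking", {
  cis <- vapply(c(0, 1, 4), function(noise) {
    tb <- generate_synthetic(synthetic_spec(
      n_drugs = 40, n_targets = 12, density = 0.5,
      mol_len = c(20, 40, 80), prot_len = c(215, 260, 320),
      noise_sd = noise, seed = 71))
    plan <- make_plan(tb, seed = 71)
    cfg <- training_config(epochs = 10, batch_size = 64, seed = 71)
    res <- train_fold(tb, plan, 1, config = cfg)
    res$metrics$ci
  }, numeric(1))
  expect_true(all(diff(cis) < 0))
})

test_that("cross_validate summarizes folds and flags degenerate data", {
  tb <- tiny_table(seed = 41, n_drugs = 10, n_targets = 6, density = 1)
  plan <- make_plan(tb, seed = 41)
  arch <- architecture_spec(filters = c(2, 2, 2), hidden = 8)
  cfg <- training_config(epochs = 1, batch_size = 32, seed = 1)
  cv <- cross_validate(tb, plan, arch, cfg)
  expect_equal(rownames(cv$summary),
               c(paste0("fold", 1:5), "mean", "sd"))
  expect_equal(cv$summary["mean", "mse"],
               mean(cv$summary[1:5, "mse"]))

  # constant-affinity data: CI/rm2 surface as NA instead of a silent average
  tb$affinity[] <- 7.5
  res <- suppressWarnings(train_fold(tb, plan, 1, arch, cfg))
  expect_true(is.na(res$metrics$ci))
  expect_true(is.finite(res$metrics$mse))
})
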