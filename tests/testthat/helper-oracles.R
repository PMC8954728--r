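# Independent oracles used to cross-check the package implementations.
# These deliberately take different computational routes (string matching,
# explicit double loops, cor()/lm() fits) from the code they verify.

# All n^k words in row-major lexicographic order by alphabet position:
# expand.grid varies its first factor fastest, so pasting columns k..1
# makes the last character the fastest-varying one.
enumerate_kmers <- function(ab, k) {
  g <- expand.grid(rep(list(unclass(ab)), k), stringsAsFactors = FALSE)
  do.call(paste0, g[seq(k, 1)])
}

# naive substring-scan k-mer counting
count_oracle <- function(s, k, ab) {
  words <- enumerate_kmers(ab, k)
  l <- nchar(s) - k + 1
  wins <- substring(s, 1:l, k:(l + k - 1))
  tabulate(match(wins, words), nbins = length(words))
}

# literal all-pairs concordance index with the three-valued step function
ci_oracle <- function(y, yh) {
  num <- 0
  N <- 0
  n <- length(y)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (y[i] > y[j]) {
        N <- N + 1
        d <- yh[i] - yh[j]
        num <- num + (if (d > 0) 1 else if (d == 0) 0.5 else 0)
      }
    }
  }
  num / N
}

# rm2 via cor() and through-origin lm(), an independent route from the
# plain-sum transcription inside the package
rm2_oracle <- function(obs, pred) {
  r2 <- cor(obs, pred)^2
  fit0 <- lm(obs ~ 0 + pred)
  r02 <- 1 - sum(residuals(fit0)^2) / sum((obs - mean(obs))^2)
  r2 * (1 - sqrt(max(0, r2 - r02)))
}

# step-wise AUC-PR by explicit confusion counts at every distinct threshold
aucpr_oracle <- function(labels, scores) {
  thr <- sort(unique(scores), decreasing = TRUE)
  P <- sum(labels == 1)
  prev_r <- 0
  area <- 0
  for (t in thr) {
    called <- scores >= t
    tp <- sum(called & labels == 1)
    prec <- tp / sum(called)
    rec <- tp / P
    area <- area + (rec - prev_r) * prec
    prev_r <- rec
  }
  area
}

random_string <- function(len, ab) {
  paste(sample(unclass(ab), len, replace = TRUE), collapse = "")
}

# small fast synthetic table shared by several tests
tiny_table <- function(seed = 7, n_drugs = 12, n_targets = 6, density = 1,
                       noise_sd = 0.2) {
  generate_synthetic(synthetic_spec(
    n_drugs = n_drugs, n_targets = n_targets, density = density,
    mol_len = c(20, 40, 80), prot_len = c(215, 260, 320),
    noise_sd = noise_sd, seed = seed))
}
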