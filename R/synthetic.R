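#' Specification of a synthetic drug-target dataset
#'
#' Describes a desk-scale benchmark with a known generative model so that
#' the encoder, the experiment plan, the network and the metrics can be
#' exercised end-to-end without external downloads.  Sequences are uniform
#' random strings over the two fixed alphabets with log-normal lengths
#' (clipped to the given ranges); the default length statistics emulate the
#' public kinase benchmarks (molecule SMILES mean about 64 characters,
#' proteins about 728 residues).  The affinity of drug d and target t is a
#' known function of k-mer content:
#' \deqn{g = a <u, f_mol(d)> + b <v, f_prot(t)> + c <u,f_mol> <v,f_prot>}
#' where f are the max-normalized k-mer profiles and u, v latent Gaussian
#' weight vectors.  g is standardized over the sampled interactions to
#' mean `center` (a pKd-like 7) and unit standard deviation, and Gaussian
#' noise with standard deviation `noise_sd` (in units of the signal SD) is
#' added.  Everything is determined by `seed`.
#'
#' @param n_drugs,n_targets Numbers of molecules and proteins.
#' @param density Fraction of the drug-target grid that is measured, in
#'   (0, 1].
#' @param mol_len,prot_len Length triples `c(min, mean, max)`.
#' @param noise_sd Noise standard deviation relative to the (unit) signal
#'   standard deviation.
#' @param mol_active,prot_active Number of k-mers with nonzero latent
#'   weight in each space.  Binding affinity in this generator is driven by
#'   a limited set of sequence motifs (k-mers), mimicking the
#'   substructure/motif view of molecular recognition rather than a signal
#'   diffused over every possible k-mer.
#' @param a,b,c Weights of the two linear terms and the interaction term.
#' @param center Mean affinity on the pKd-like scale.
#' @param mol_k,prot_k k-mer word lengths of the profile spaces.
#' @param seed Integer seed fixing the whole dataset.
#' @return A `sigdta_synth_spec` list.
#' @export
synthetic_spec <- function(n_drugs = 200, n_targets = 50, density = 0.2,
                           mol_len = c(20, 64, 590),
                           prot_len = c(215, 728, 4128),
                           noise_sd = 0.2, mol_active = 40,
                           prot_active = 60, a = 1, b = 1, c = 0.5,
                           center = 7, mol_k = 2, prot_k = 3, seed = 1) {
  stopifnot(n_drugs >= 1, n_targets >= 1, density > 0, density <= 1,
            noise_sd >= 0, length(mol_len) == 3, length(prot_len) == 3,
            mol_active >= 1, prot_active >= 1)
  if (mol_len[1] < mol_k || prot_len[1] < prot_k)
    stop("minimum sequence lengths must be at least the word length k")
  structure(list(n_drugs = as.integer(n_drugs),
                 n_targets = as.integer(n_targets),
                 density = density, mol_len = mol_len, prot_len = prot_len,
                 noise_sd = noise_sd,
                 mol_active = as.integer(mol_active),
                 prot_active = as.integer(prot_active),
                 a = a, b = b, c = c, center = center,
                 mol_k = as.integer(mol_k), prot_k = as.integer(prot_k),
                 seed = as.integer(seed)),
            class = "sigdta_synth_spec")
}

# log-normal lengths with the requested mean, clipped to [min, max]
sample_lengths <- function(n, len, sdlog = 0.4) {
  meanlog <- log(len[2]) - sdlog^2 / 2
  pmin(pmax(round(rlnorm(n, meanlog, sdlog)), len[1]), len[3])
}

random_sequences <- function(n, lengths, ab) {
  vapply(lengths, function(L)
    paste(sample(unclass(ab), L, replace = TRUE), collapse = ""),
    character(1))
}

profile_matrix <- function(seqs, space) {
  out <- matrix(0, length(seqs), space$nk)
  for (i in seq_along(seqs))
    out[i, ] <- normalize_counts(count_kmers(seqs[[i]], space))
  out
}

#' Generate a synthetic interaction table with known ground truth
#'
#' Draws the dataset described by a [synthetic_spec()].  The generative
#' parameters (latent weights `u` and `v`, term weights, the
#' standardization applied to the noiseless signal, and the realized
#' noiseless affinities) are attached as the `"truth"` attribute so that
#' recovery tests can check them.  The same spec always produces the same
#' table bit for bit.
#'
#' @param spec A [synthetic_spec()].
#' @return A `sigdta_table` of kind `"synthetic"` with a `"truth"`
#'   attribute.
#' @export
generate_synthetic <- function(spec = synthetic_spec()) {
  stopifnot(inherits(spec, "sigdta_synth_spec"))
  set.seed(spec$seed)
  mol_ab <- molecule_alphabet()
  prot_ab <- protein_alphabet()
  mol_sp <- kmer_space(mol_ab, spec$mol_k)
  prot_sp <- kmer_space(prot_ab, spec$prot_k)

  mol_seqs <- random_sequences(spec$n_drugs,
                               sample_lengths(spec$n_drugs, spec$mol_len),
                               mol_ab)
  prot_seqs <- random_sequences(spec$n_targets,
                                sample_lengths(spec$n_targets, spec$prot_len),
                                prot_ab)
  names(mol_seqs) <- sprintf("D%03d", seq_len(spec$n_drugs))
  names(prot_seqs) <- sprintf("T%03d", seq_len(spec$n_targets))

  fm <- profile_matrix(mol_seqs, mol_sp)
  fp <- profile_matrix(prot_seqs, prot_sp)
  # motif-like latent weights: only a limited set of k-mers drives binding
  u <- numeric(mol_sp$nk)
  u[sample.int(mol_sp$nk, min(spec$mol_active, mol_sp$nk))] <-
    rnorm(min(spec$mol_active, mol_sp$nk))
  v <- numeric(prot_sp$nk)
  v[sample.int(prot_sp$nk, min(spec$prot_active, prot_sp$nk))] <-
    rnorm(min(spec$prot_active, prot_sp$nk))
  zm <- as.vector(fm %*% u)
  zp <- as.vector(fp %*% v)

  ncell <- spec$n_drugs * spec$n_targets
  npresent <- max(1L, round(spec$density * ncell))
  present <- if (npresent == ncell) seq_len(ncell)
             else sort(sample.int(ncell, npresent))
  # cell index is drug-major: cell = (drug - 1) * n_targets + target
  drug <- (present - 1L) %/% spec$n_targets + 1L
  target <- (present - 1L) %% spec$n_targets + 1L

  g <- spec$a * zm[drug] + spec$b * zp[target] +
       spec$c * zm[drug] * zp[target]
  sdg <- sd(g)
  if (!is.finite(sdg) || sdg == 0) sdg <- 1
  signal <- spec$center + (g - mean(g)) / sdg
  y <- signal + rnorm(npresent, 0, spec$noise_sd)

  Y <- matrix(NA_real_, spec$n_drugs, spec$n_targets)
  Y[cbind(drug, target)] <- y

  drugs <- mapply(function(s, id) tokenize(s, mol_ab, id = id),
                  mol_seqs, names(mol_seqs), SIMPLIFY = FALSE)
  targets <- mapply(function(s, id) tokenize(s, prot_ab, id = id),
                    prot_seqs, names(prot_seqs), SIMPLIFY = FALSE)
  table <- structure(list(drugs = drugs, targets = targets, affinity = Y,
                          kind = "synthetic", folds = NULL,
                          dropped = c(drugs = 0L, targets = 0L)),
                     class = "sigdta_table")
  attr(table, "truth") <- list(u = u, v = v, a = spec$a, b = spec$b,
                               c = spec$c, center = spec$center,
                               shift = mean(g), scale = 1 / sdg,
                               noise_sd = spec$noise_sd, signal = signal,
                               spec = spec)
  table
}

#' Write an interaction table as a benchmark-layout fixture directory
#'
#' Emits the DeepDTA-style text layout consumed by [load_benchmark()]:
#' `ligands_can.txt` and `proteins.txt` (JSON objects id -> raw sequence),
#' `Y.txt` (tab-delimited affinity matrix, `NA` for missing cells, full
#' double precision) and, when the table carries folds, the two JSON fold
#' index files under `folds/`.  `load_benchmark(write_fixture(x), kind)`
#' reproduces `x` exactly.
#'
#' @param table A `sigdta_table`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_fixture <- function(table, dir) {
  stopifnot(inherits(table, "sigdta_table"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(dir)) stop(sprintf("cannot create directory %s", dir))
  lig <- lapply(table$drugs, `[[`, "raw")
  prot <- lapply(table$targets, `[[`, "raw")
  jsonlite::write_json(lig, file.path(dir, "ligands_can.txt"),
                       auto_unbox = TRUE)
  jsonlite::write_json(prot, file.path(dir, "proteins.txt"),
                       auto_unbox = TRUE)
  ych <- matrix(formatC(table$affinity, format = "g", digits = 17),
                nrow(table$affinity), ncol(table$affinity))
  ych[is.na(table$affinity)] <- "NA"
  write.table(ych, file.path(dir, "Y.txt"), sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  if (!is.null(table$folds)) {
    fd <- file.path(dir, "folds")
    dir.create(fd, showWarnings = FALSE)
    jsonlite::write_json(lapply(table$folds$train, function(v) v - 1L),
                         file.path(fd, "train_fold_setting1.txt"))
    jsonlite::write_json(table$folds$test - 1L,
                         file.path(fd, "test_fold_setting1.txt"))
  }
  invisible(dir)
}
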