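#' Read sequences from plain text or FASTA
#'
#' Plain-text files hold one sequence per line, optionally preceded by an
#' identifier and a tab.  FASTA reading is delegated to Biostrings.
#'
#' @param path File path.
#' @param format `"lines"` or `"fasta"`.
#' @return Named character vector of raw sequences.
#' @export
read_sequences <- function(path, format = c("lines", "fasta")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  if (format == "fasta") {
    if (!requireNamespace("Biostrings", quietly = TRUE))
      stop("reading FASTA requires the Biostrings package")
    ss <- Biostrings::readBStringSet(path)
    out <- as.character(ss)
    names(out) <- sub("\\s.*$", "", names(ss))
    return(out)
  }
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  has_id <- grepl("\t", lines, fixed = TRUE)
  ids <- ifelse(has_id, sub("\t.*$", "", lines), paste0("seq", seq_along(lines)))
  seqs <- ifelse(has_id, sub("^[^\t]*\t", "", lines), lines)
  names(seqs) <- ids
  seqs
}

first_existing <- function(dir, candidates) {
  for (f in candidates) {
    p <- file.path(dir, f)
    if (file.exists(p)) return(p)
  }
  stop(sprintf("none of [%s] found in %s",
               paste(candidates, collapse = ", "), dir))
}

#' Load a drug-target benchmark in the DeepDTA text layout
#'
#' Expects a directory with a ligand map (`ligands_can.txt` or
#' `ligands.json`: JSON object id -> SMILES), a protein map
#' (`proteins.txt` or `proteins.json`: JSON object id -> sequence), and a
#' drugs-by-targets affinity matrix (`Y.txt` or `affinities.txt`:
#' tab-delimited, `NA` for missing cells).  If a `folds/` subdirectory with
#' `train_fold_setting1.txt` (JSON list of five 0-based index arrays) and
#' `test_fold_setting1.txt` (JSON array) is present, the published
#' experiment plan is attached.
#'
#' Davis affinities are raw Kd in nM and are transformed to pKd via
#' [pkd_transform()]; KIBA scores and synthetic affinities are passed
#' through.  Sequences are tokenized with the given out-of-alphabet policy;
#' the total number of dropped characters is kept in the `dropped` field.
#'
#' @param dir Benchmark directory.
#' @param kind `"davis"`, `"kiba"` or `"synthetic"`.
#' @param policy Out-of-alphabet policy for [tokenize()].
#' @return A `sigdta_table`: list with `drugs` and `targets` (lists of
#'   `sigdta_seq` records), `affinity` (drugs x targets matrix, `NA` where
#'   unmeasured), `kind`, `folds` (or `NULL`) and `dropped` counts.
#' @export
load_benchmark <- function(dir, kind = c("davis", "kiba", "synthetic"),
                           policy = c("drop", "error")) {
  kind <- match.arg(kind)
  policy <- match.arg(policy)
  if (!dir.exists(dir)) stop(sprintf("directory not found: %s", dir))
  lig_path <- first_existing(dir, c("ligands_can.txt", "ligands.json"))
  prot_path <- first_existing(dir, c("proteins.txt", "proteins.json"))
  y_path <- first_existing(dir, c("Y.txt", "affinities.txt"))

  ligands <- unlist(jsonlite::fromJSON(lig_path, simplifyVector = TRUE))
  proteins <- unlist(jsonlite::fromJSON(prot_path, simplifyVector = TRUE))
  Y <- as.matrix(read.table(y_path, sep = "\t", header = FALSE,
                            na.strings = "NA"))
  dimnames(Y) <- NULL
  if (nrow(Y) != length(ligands) || ncol(Y) != length(proteins))
    stop(sprintf(
      "%s is %dx%d but there are %d ligands and %d proteins",
      basename(y_path), nrow(Y), ncol(Y), length(ligands), length(proteins)))
  if (kind == "davis") Y[] <- pkd_transform(as.vector(Y))

  mol_ab <- molecule_alphabet()
  prot_ab <- protein_alphabet()
  drugs <- mapply(function(s, id) tokenize(s, mol_ab, policy, id = id),
                  ligands, names(ligands), SIMPLIFY = FALSE)
  targets <- mapply(function(s, id) tokenize(s, prot_ab, policy, id = id),
                    proteins, names(proteins), SIMPLIFY = FALSE)
  dropped <- c(drugs = sum(vapply(drugs, `[[`, 0L, "dropped_count")),
               targets = sum(vapply(targets, `[[`, 0L, "dropped_count")))

  folds <- NULL
  fold_dir <- file.path(dir, "folds")
  if (dir.exists(fold_dir)) {
    tr <- first_existing(fold_dir, "train_fold_setting1.txt")
    te <- first_existing(fold_dir, "test_fold_setting1.txt")
    train <- jsonlite::fromJSON(tr, simplifyVector = TRUE)
    if (!is.list(train)) train <- lapply(seq_len(nrow(train)), function(i) train[i, ])
    folds <- list(train = lapply(train, function(v) as.integer(v) + 1L),
                  test = as.integer(jsonlite::fromJSON(te)) + 1L)
  }

  structure(list(drugs = drugs, targets = targets, affinity = Y,
                 kind = kind, folds = folds, dropped = dropped),
            class = "sigdta_table")
}

#' @export
print.sigdta_table <- function(x, ...) {
  cat(sprintf("<%s interaction table: %d drugs x %d targets, %d interactions>\n",
              x$kind, length(x$drugs), length(x$targets),
              sum(!is.na(x$affinity))))
  if (sum(x$dropped) > 0)
    cat(sprintf("  dropped characters: %d (drugs), %d (targets)\n",
                x$dropped[["drugs"]], x$dropped[["targets"]]))
  invisible(x)
}

#' Enumerate the non-missing interactions of a table
#'
#' Interactions are indexed in drug-major (row-major) order over the
#' affinity matrix, skipping missing cells; this is the index space that
#' experiment plans partition.
#'
#' @param table A `sigdta_table`.
#' @return `data.frame` with columns `drug`, `target`, `y`.
#' @export
interactions <- function(table) {
  stopifnot(inherits(table, "sigdta_table"))
  tA <- t(table$affinity)
  nt <- nrow(tA)
  idx <- which(!is.na(tA))
  data.frame(drug = (idx - 1L) %/% nt + 1L,
             target = (idx - 1L) %% nt + 1L,
             y = tA[idx])
}

#' Build an experiment plan: five CV folds plus a held-out test part
#'
#' Either reproduces a published fold layout verbatim (`folds` = list with
#' `train`, a list of five validation-fold index vectors, and `test`), or
#' randomly partitions the interactions of a table into six near-equal
#' disjoint parts under a seed: five cross-validation folds and one test
#' part never touched during training.  For each fold k, the other four
#' folds form the training split and fold k the validation split.
#'
#' @param table A `sigdta_table`, or an interaction count.
#' @param folds Optional published layout (1-based indices).
#' @param seed Seed for the random partition when `folds` is `NULL`.
#' @return A `sigdta_plan`: list with `folds` (list of 5 integer vectors),
#'   `test` and `n`.
#' @export
make_plan <- function(table, folds = NULL, seed = NULL) {
  n <- if (inherits(table, "sigdta_table")) sum(!is.na(table$affinity))
       else as.integer(table)
  if (is.null(folds) && !is.null(table) && inherits(table, "sigdta_table") &&
      !is.null(table$folds))
    folds <- table$folds
  if (!is.null(folds)) {
    parts <- c(folds$train, list(folds$test))
    if (length(folds$train) != 5L)
      stop("a published layout must have exactly 5 training folds")
    all_idx <- unlist(parts)
    if (anyDuplicated(all_idx))
      stop("fold parts overlap")
    if (!setequal(all_idx, seq_len(n)))
      stop(sprintf("fold parts do not cover the %d interactions exactly", n))
    plan <- list(folds = lapply(folds$train, as.integer),
                 test = as.integer(folds$test), n = n)
  } else {
    if (is.null(seed)) stop("either published folds or a seed is required")
    set.seed(seed)
    perm <- sample.int(n)
    sizes <- rep(n %/% 6L, 6L) + (seq_len(6L) <= n %% 6L)
    ends <- cumsum(sizes)
    starts <- c(1L, head(ends, -1L) + 1L)
    parts <- lapply(seq_len(6L), function(i) sort(perm[starts[i]:ends[i]]))
    plan <- list(folds = parts[1:5], test = parts[[6]], n = n)
  }
  structure(plan, class = "sigdta_plan")
}

#' @export
print.sigdta_plan <- function(x, ...) {
  cat(sprintf("<experiment plan: %d interactions; folds %s; test %d>\n",
              x$n, paste(lengths(x$folds), collapse = "/"), length(x$test)))
  invisible(x)
}

#' Train/validation/test indices for one cross-validation fold
#'
#' @param plan A `sigdta_plan`.
#' @param fold Fold number in 1..5; its part is the validation split and
#'   the remaining four parts the training split.
#' @return List with `train`, `validation`, `test` integer vectors.
#' @export
fold_split <- function(plan, fold) {
  stopifnot(inherits(plan, "sigdta_plan"))
  fold <- as.integer(fold)
  if (fold < 1L || fold > length(plan$folds))
    stop(sprintf("fold must be in 1..%d", length(plan$folds)))
  list(train = sort(unlist(plan$folds[-fold], use.names = FALSE)),
       validation = plan$folds[[fold]],
       test = plan$test)
}

#' Encode every drug and target of a table as image stacks
#'
#' @param table A `sigdta_table`.
#' @param mol_k,prot_k Word lengths for the two branches.
#' @return List with `mol` (m x m x n_drugs) and `prot` arrays plus the two
#'   k-mer spaces.
#' @export
encode_table <- function(table, mol_k = 2, prot_k = 3) {
  stopifnot(inherits(table, "sigdta_table"))
  list(mol = encode_set(table$drugs, molecule_alphabet(), mol_k),
       prot = encode_set(table$targets, protein_alphabet(), prot_k),
       mol_space = kmer_space(molecule_alphabet(), mol_k),
       prot_space = kmer_space(protein_alphabet(), prot_k))
}
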