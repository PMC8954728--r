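#' Tokenize a raw character sequence against an alphabet
#'
#' Splits `raw` into single characters and keeps those that belong to the
#' alphabet.  Characters outside the alphabet are handled according to
#' `policy`: `"drop"` removes them (their number is reported in
#' `dropped_count`), `"error"` aborts at the first foreign character,
#' naming it and its position.  Tokenization is strictly character-level:
#' `"Cl"` tokenizes as `'C','l'` and `"Br"` as `'B','r'`.
#'
#' @param raw A single character string.
#' @param alphabet A [alphabet()] object.
#' @param policy `"drop"` (default) or `"error"`.
#' @param id Optional identifier carried along with the record.
#' @return A `sigdta_seq` record: list with `id`, `raw`, `cleaned` (string
#'   containing only alphabet symbols, order preserved) and `dropped_count`.
#' @examples
#' rec <- tokenize("Nc1ncnc2sccc12", molecule_alphabet())
#' nchar(rec$cleaned)  # 14
#' @export
tokenize <- function(raw, alphabet, policy = c("drop", "error"), id = NULL) {
  policy <- match.arg(policy)
  stopifnot(inherits(alphabet, "sigdta_alphabet"))
  if (length(raw) != 1L || is.na(raw))
    stop("'raw' must be a single character string")
  chars <- strsplit(raw, "", fixed = TRUE)[[1L]]
  hit <- chars %in% unclass(alphabet)
  if (policy == "error" && !all(hit)) {
    p <- which(!hit)[1L]
    stop(sprintf("foreign character '%s' at position %d", chars[p], p))
  }
  cleaned <- paste(chars[hit], collapse = "")
  if (nchar(cleaned) == 0L)
    stop("sequence is empty after cleaning")
  structure(list(id = id, raw = raw, cleaned = cleaned,
                 dropped_count = sum(!hit)),
            class = "sigdta_seq")
}

#' @export
print.sigdta_seq <- function(x, ...) {
  cat(sprintf("<sequence%s: %d characters kept, %d dropped>\n",
              if (is.null(x$id)) "" else paste0(" ", x$id),
              nchar(x$cleaned), x$dropped_count))
  invisible(x)
}

#' k-mer space of an alphabet
#'
#' Describes the enumeration of all n^k k-mers over an alphabet of size n
#' and the geometry of the signature image built from it: the image side is
#' `m = ceiling(sqrt(n^k))` and `e = m^2 - n^k` zeros are appended before
#' reshaping.  For the default spaces, molecules (n = 36, k = 2) give a
#' 36x36 image with no padding and proteins (n = 21, k = 3) a 97x97 image
#' with 148 padding cells.
#'
#' @param alphabet A [alphabet()] object.
#' @param k Word length (positive integer).
#' @return A `sigdta_kmer_space`: list with `alphabet`, `k`, `n`, `nk`, `m`
#'   and `e`.
#' @examples
#' kmer_space(protein_alphabet(), 3)$m  # 97
#' @export
kmer_space <- function(alphabet, k) {
  stopifnot(inherits(alphabet, "sigdta_alphabet"))
  k <- as.integer(k)
  if (is.na(k) || k < 1L) stop("'k' must be a positive integer")
  n <- length(alphabet)
  nk <- n^k
  if (nk > 2^31 - 1) stop("k-mer space too large to enumerate")
  m <- as.integer(ceiling(sqrt(nk)))
  structure(list(alphabet = alphabet, k = k, n = n, nk = as.integer(nk),
                 m = m, e = as.integer(m^2 - nk)),
            class = "sigdta_kmer_space")
}

#' Rank of a k-mer word within its space
#'
#' Returns the 0-based rank of `word` in row-major lexicographic order by
#' alphabet position: the first alphabet symbol repeated k times has rank 0
#' and the last repeated k times has rank `nk - 1`.  The mapping is a
#' bijection between the n^k words and `0:(nk-1)`.
#'
#' @param word Character vector of k-character words.
#' @param space A [kmer_space()].
#' @return Integer vector of 0-based ranks.
#' @examples
#' sp <- kmer_space(molecule_alphabet(), 2)
#' kmer_index("BC", sp)  # 1
#' @export
kmer_index <- function(word, space) {
  stopifnot(inherits(space, "sigdta_kmer_space"))
  if (any(nchar(word) != space$k))
    stop(sprintf("words must have exactly k = %d characters", space$k))
  vapply(strsplit(word, "", fixed = TRUE), function(chars) {
    codes <- match(chars, unclass(space$alphabet)) - 1L
    if (anyNA(codes))
      stop(sprintf("foreign character '%s' in k-mer word",
                   chars[which(is.na(codes))[1L]]))
    as.integer(sum(codes * space$n^((space$k - 1):0)))
  }, integer(1))
}

#' Count the overlapping k-mers of a sequence
#'
#' Slides a window of length k over the cleaned sequence and tallies each
#' word at its [kmer_index()] position.  The `l = c - k + 1` windows are
#' contiguous over the cleaned sequence (foreign characters were removed
#' before windowing), so `sum(counts) == l` always.
#'
#' @param seq A `sigdta_seq` record from [tokenize()], or a plain string of
#'   alphabet characters.
#' @param space A [kmer_space()].
#' @return A `sigdta_kmer_counts`: list with `space`, integer `counts` of
#'   length `nk`, and `l`.
#' @examples
#' sp <- kmer_space(molecule_alphabet(), 2)
#' count_kmers(tokenize("Nc1ncnc2sccc12", molecule_alphabet()), sp)$l  # 13
#' @export
count_kmers <- function(seq, space) {
  stopifnot(inherits(space, "sigdta_kmer_space"))
  cleaned <- if (inherits(seq, "sigdta_seq")) seq$cleaned else seq
  chars <- strsplit(cleaned, "", fixed = TRUE)[[1L]]
  codes <- match(chars, unclass(space$alphabet)) - 1L
  if (anyNA(codes))
    stop(sprintf("foreign character '%s'; tokenize the sequence first",
                 chars[which(is.na(codes))[1L]]))
  cl <- length(codes)
  if (cl < space$k)
    stop(sprintf("sequence length %d is shorter than k = %d", cl, space$k))
  l <- cl - space$k + 1L
  acc <- numeric(l)
  for (j in seq_len(space$k))
    acc <- acc * space$n + codes[j:(j + l - 1L)]
  counts <- tabulate(as.integer(acc) + 1L, nbins = space$nk)
  structure(list(space = space, counts = counts, l = l),
            class = "sigdta_kmer_counts")
}

#' Max-normalize a k-mer count vector
#'
#' Divides every count by the largest count, so the output lies in `[0, 1]`
#' with maximum exactly 1 and zeros preserved.
#'
#' @param counts A `sigdta_kmer_counts` from [count_kmers()], or a bare
#'   non-negative numeric vector.
#' @return Numeric vector of the same length.
#' @export
normalize_counts <- function(counts) {
  x <- if (inherits(counts, "sigdta_kmer_counts")) counts$counts else counts
  if (any(x < 0)) stop("counts must be non-negative")
  mx <- max(x)
  if (mx == 0) stop("cannot normalize an all-zero count vector")
  x / mx
}

#' Reshape a normalized profile into a signature image
#'
#' Appends `e = m^2 - nk` zeros to the normalized counting vector and
#' reshapes it row-major into an m-by-m matrix.  The padding therefore
#' occupies the trailing cells of the last row(s), and the operation is
#' invertible up to that padding.
#'
#' @param normalized Numeric vector of length `space$nk` (from
#'   [normalize_counts()]).
#' @param space A [kmer_space()].
#' @return A `sigdta_image`: an m-by-m numeric matrix with the space stored
#'   in the `"space"` attribute.
#' @export
to_image <- function(normalized, space) {
  stopifnot(inherits(space, "sigdta_kmer_space"))
  if (length(normalized) != space$nk)
    stop(sprintf("expected a vector of length nk = %d, got %d",
                 space$nk, length(normalized)))
  img <- matrix(c(normalized, numeric(space$e)),
                nrow = space$m, ncol = space$m, byrow = TRUE)
  structure(img, space = space, class = c("sigdta_image", "matrix"))
}

#' @export
print.sigdta_image <- function(x, ...) {
  sp <- attr(x, "space")
  cat(sprintf("<%dx%d signature image (%s alphabet, k = %d), %d nonzero pixels>\n",
              sp$m, sp$m, attr(sp$alphabet, "kind"), sp$k, sum(x > 0)))
  invisible(x)
}

#' Encode a sequence as a signature image
#'
#' Composition of [tokenize()], [count_kmers()], [normalize_counts()] and
#' [to_image()]: the full deterministic map from a raw character sequence
#' to its m-by-m signature image.  `encode_molecule()` and
#' `encode_protein()` fix the alphabet and the conventional word lengths
#' (k = 2 for SMILES, k = 3 for proteins).
#'
#' @param raw A single character string.
#' @param alphabet A [alphabet()] object.
#' @param k Word length.
#' @param policy Out-of-alphabet policy, see [tokenize()].
#' @return A `sigdta_image` matrix; the sequence record is attached as the
#'   `"record"` attribute and the window count as `"l"`.
#' @examples
#' img <- encode_molecule("Nc1ncnc2sccc12")
#' dim(img)      # 36 36
#' max(img)      # 1
#' @export
encode <- function(raw, alphabet, k, policy = c("drop", "error")) {
  rec <- tokenize(raw, alphabet, policy)
  sp <- kmer_space(alphabet, k)
  cnt <- count_kmers(rec, sp)
  img <- to_image(normalize_counts(cnt), sp)
  attr(img, "record") <- rec
  attr(img, "l") <- cnt$l
  img
}

#' @rdname encode
#' @export
encode_molecule <- function(raw, k = 2, policy = c("drop", "error")) {
  encode(raw, molecule_alphabet(), k, policy)
}

#' @rdname encode
#' @export
encode_protein <- function(raw, k = 3, policy = c("drop", "error")) {
  encode(raw, protein_alphabet(), k, policy)
}

#' Encode many sequences into an image stack
#'
#' @param raws Character vector (optionally named) of sequences, or a list
#'   of `sigdta_seq` records.
#' @param alphabet,k,policy As in [encode()].
#' @return An m x m x n numeric array; the third dimension follows the
#'   input order and carries its names.
#' @export
encode_set <- function(raws, alphabet, k, policy = c("drop", "error")) {
  sp <- kmer_space(alphabet, k)
  n <- length(raws)
  out <- array(0, dim = c(sp$m, sp$m, n))
  for (i in seq_len(n)) {
    s <- if (is.list(raws)) raws[[i]] else raws[[i]]
    rec <- if (inherits(s, "sigdta_seq")) s else tokenize(s, alphabet, policy)
    out[, , i] <- to_image(normalize_counts(count_kmers(rec, sp)), sp)
  }
  dimnames(out) <- list(NULL, NULL, names(raws))
  out
}
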