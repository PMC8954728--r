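#' Sequence alphabets
#'
#' Fixed, ordered symbol sets over which k-mers are enumerated.  The order
#' of the symbols is part of the encoding: the rank of a k-mer (and hence
#' its pixel position in the signature image) is its row-major lexicographic
#' rank with respect to this order.
#'
#' `molecule_alphabet()` holds the 36 characters used for SMILES strings;
#' two-letter element symbols are read character-wise (`"Cl"` is `'C','l'`,
#' `"Br"` is `'B','r'`), which is why the lowercase `l` and `r` appear.
#' `protein_alphabet()` holds the 20 standard amino-acid letters plus the
#' ambiguity code `X`, 21 symbols in total.
#'
#' @param symbols Character vector of unique single characters, in the order
#'   that defines k-mer ranks.
#' @param kind Label for the alphabet (`"molecule"`, `"protein"`, or any
#'   user-supplied tag).
#' @return An object of class `sigdta_alphabet`: a character vector with a
#'   `kind` attribute.
#' @examples
#' length(molecule_alphabet())  # 36
#' length(protein_alphabet())   # 21
#' @export
alphabet <- function(symbols, kind = "custom") {
  symbols <- as.character(symbols)
  if (any(nchar(symbols) != 1L))
    stop("alphabet symbols must be single characters")
  if (anyDuplicated(symbols))
    stop("alphabet symbols must be unique")
  if (length(symbols) < 2L)
    stop("an alphabet needs at least two symbols")
  structure(symbols, kind = kind, class = "sigdta_alphabet")
}

#' @rdname alphabet
#' @export
molecule_alphabet <- function() {
  alphabet(c("B", "C", "H", "N", "O", "S", "P", "F", "I",
             "b", "c", "l", "n", "o", "s", "p", "r",
             "0", "1", "2", "3", "4", "5", "6", "7", "8", "9",
             "(", ")", "[", "]", "=", ".", "+", "-", "#"),
           kind = "molecule")
}

#' @rdname alphabet
#' @export
protein_alphabet <- function() {
  alphabet(c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L", "M",
             "N", "P", "Q", "R", "S", "T", "V", "W", "X", "Y"),
           kind = "protein")
}

#' @export
print.sigdta_alphabet <- function(x, ...) {
  cat(sprintf("<%s alphabet, %d symbols>\n", attr(x, "kind"), length(x)))
  cat(paste(unclass(x), collapse = " "), "\n")
  invisible(x)
}
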