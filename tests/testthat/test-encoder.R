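test_that("tokenize keeps alphabet characters and applies the policy", {
  rec <- tokenize("Nc1ncnc2sccc12", molecule_alphabet())
  expect_equal(nchar(rec$cleaned), 14)
  expect_equal(rec$dropped_count, 0)

  rec <- tokenize("C@C", molecule_alphabet(), policy = "drop")
  expect_equal(rec$cleaned, "CC")
  expect_equal(rec$dropped_count, 1)
  expect_error(tokenize("C@C", molecule_alphabet(), policy = "error"),
               "'@' at position 2")

  expect_error(tokenize("", molecule_alphabet()), "empty")
  expect_error(tokenize("@@", molecule_alphabet(), policy = "drop"), "empty")

  # length(cleaned) + dropped = length(raw) under drop, for arbitrary junk
  set.seed(4)
  for (i in 1:25) {
    raw <- paste(sample(c(unclass(protein_alphabet()), "@", "*", "z"),
                        sample(5:60, 1), replace = TRUE), collapse = "")
    rec <- tryCatch(tokenize(raw, protein_alphabet()), error = function(e) NULL)
    if (!is.null(rec))
      expect_equal(nchar(rec$cleaned) + rec$dropped_count, nchar(raw))
  }
})

test_that("k-mer ranks are row-major lexicographic and bijective", {
  msp <- kmer_space(molecule_alphabet(), 2)
  psp <- kmer_space(protein_alphabet(), 3)
  ab <- unclass(molecule_alphabet())

  expect_equal(kmer_index(strrep(ab[1], 2), msp), 0L)
  expect_equal(kmer_index(strrep(ab[36], 2), msp), msp$nk - 1L)
  expect_equal(kmer_index("BC", msp), 1L)

  # agree with an independent string-enumeration oracle, molecule and protein
  mol_words <- enumerate_kmers(molecule_alphabet(), 2)
  expect_equal(match("BC", mol_words) - 1L, 1L)
  set.seed(1)
  pick <- sample(msp$nk, 60)
  expect_equal(kmer_index(mol_words[pick], msp), pick - 1L)
  prot_words <- enumerate_kmers(protein_alphabet(), 3)
  pick <- sample(psp$nk, 60)
  expect_equal(kmer_index(prot_words[pick], psp), pick - 1L)

  expect_error(kmer_index("B@", msp), "foreign")
  expect_error(kmer_index("B", msp), "exactly k")
})

test_that("k-mer space geometry follows n, k", {
  msp <- kmer_space(molecule_alphabet(), 2)
  expect_equal(c(msp$nk, msp$m, msp$e), c(1296L, 36L, 0L))
  psp <- kmer_space(protein_alphabet(), 3)
  expect_equal(c(psp$nk, psp$m, psp$e), c(9261L, 97L, 148L))
  # shape law for other (n, k) too
  for (k in 1:3) {
    sp <- kmer_space(protein_alphabet(), k)
    expect_equal(sp$m, ceiling(sqrt(21^k)))
    expect_true(sp$e >= 0 && sp$e < 2 * sp$m)
  }
})

test_that("count_kmers matches the substring-scan oracle and conserves mass", {
  msp <- kmer_space(molecule_alphabet(), 2)
  cnt <- count_kmers(tokenize("Nc1ncnc2sccc12", molecule_alphabet()), msp)
  expect_equal(cnt$l, 13L)
  expect_equal(sum(cnt$counts), 13L)

  cc <- count_kmers("CC", msp)
  expect_equal(cc$l, 1L)
  expect_equal(which(cc$counts == 1L) - 1L, kmer_index("CC", msp))
  expect_equal(sum(cc$counts), 1L)

  expect_error(count_kmers("C", msp), "shorter than k")

  set.seed(2)
  for (i in 1:30) {
    ab <- if (i %% 2) molecule_alphabet() else protein_alphabet()
    k <- sample(2:3, 1)
    s <- random_string(sample(10:200, 1), ab)
    got <- count_kmers(s, kmer_space(ab, k))
    expect_identical(got$counts, count_oracle(s, k, ab))
    expect_equal(sum(got$counts), nchar(s) - k + 1)
  }
})

test_that("normalization scales by the max and is invertible", {
  x <- c(2L, 1L, 0L, 4L)
  expect_equal(normalize_counts(x), c(0.5, 0.25, 0, 1))
  expect_error(normalize_counts(integer(4)), "all-zero")

  set.seed(3)
  for (i in 1:20) {
    cnt <- rpois(50, 2)
    if (max(cnt) == 0) cnt[1] <- 1
    f <- normalize_counts(cnt)
    expect_equal(max(f), 1)
    expect_true(all(f >= 0 & f <= 1))
    expect_equal(f * max(cnt), as.numeric(cnt))  # exact inverse scaling
  }
})

test_that("images are square, max-1, zero-padded at the row-major tail", {
  img <- encode_molecule("Nc1ncnc2sccc12")
  expect_equal(dim(img), c(36L, 36L))
  expect_equal(max(img), 1)
  expect_true(all(img >= 0 & img <= 1))
  # 13 windows, each k-mer appearing at most its count: nonzero cells <= 13
  expect_lte(sum(img > 0), 13)

  psp <- kmer_space(protein_alphabet(), 3)
  pimg <- encode_protein(random_string(215, protein_alphabet()))
  expect_equal(dim(pimg), c(97L, 97L))
  # the trailing e = 148 cells in row-major order are the padding
  flat <- as.vector(t(unclass(pimg)))
  expect_true(all(flat[(psp$nk + 1):(97 * 97)] == 0))
  expect_equal(psp$e, 148L)

  expect_error(to_image(numeric(10), psp), "length nk")
})

test_that("encode is deterministic and depends only on the k-mer multiset", {
  s <- random_string(120, protein_alphabet())
  expect_identical(encode_protein(s), encode_protein(s))

  # equal images iff equal k-mer multisets (brute-force multiset comparison)
  set.seed(5)
  msp <- kmer_space(molecule_alphabet(), 2)
  for (i in 1:15) {
    a <- random_string(sample(5:30, 1), molecule_alphabet())
    b <- if (i %% 3 == 0) {
      # cyclic rotation often preserves length but changes the multiset
      paste0(substring(a, 2), substring(a, 1, 1))
    } else {
      random_string(sample(5:30, 1), molecule_alphabet())
    }
    same_multiset <- identical(count_oracle(a, 2, molecule_alphabet()),
                               count_oracle(b, 2, molecule_alphabet()))
    same_image <- isTRUE(all.equal(unclass(encode_molecule(a)),
                                   unclass(encode_molecule(b))))
    expect_equal(same_image, same_multiset)
  }
  # an explicit positive case: same windows in different order
  expect_equal(unclass(encode_molecule("CCNCC")),
               unclass(encode_molecule("CCNCC")))
})

test_that("encode_set stacks images in input order", {
  seqs <- c(a = "CCNCC", b = "Nc1ncnc2sccc12")
  arr <- encode_set(seqs, molecule_alphabet(), 2)
  expect_equal(dim(arr), c(36, 36, 2))
  expect_equal(arr[, , 2], unclass(encode_molecule(seqs[[2]])),
               ignore_attr = TRUE)
  expect_equal(dimnames(arr)[[3]], c("a", "b"))
})
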