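test_that("word_index is the lexicographic bijection with A<C<G<T", {
  expect_identical(word_index(c("A", "C", "G", "T")), 0:3)
  expect_identical(word_index(c("AA", "AC", "TT")), c(0L, 1L, 15L))
  expect_identical(word_index("acgt"), word_index("ACGT"))
  expect_error(word_index("ANGT"), "A, C, G or T")
  for (k in c(1, 2, 3, 4)) {
    words <- kmer_words(k)
    expect_length(words, 4^k)
    expect_identical(word_index(words), seq_len(4^k) - 1L)
    expect_identical(index_word(word_index(words), k), words)
  }
})

test_that("count_words matches hand-enumerated sliding windows", {
  cw <- count_words("ACGTACGT", 2)
  expect_equal(cw$n_windows, 7)
  got <- cw$counts[word_index(c("AC", "CG", "GT", "TA")) + 1]
  expect_identical(got, c(2L, 2L, 2L, 1L))
  expect_equal(sum(cw$counts), 7)

  cw4 <- count_words("AAAA", 4)
  expect_equal(cw4$n_windows, 1)
  expect_identical(cw4$counts[word_index("AAAA") + 1], 1L)

  # windows containing an ambiguous character are skipped, not the record
  cwn <- count_words("ACGNACG", 2)
  expect_equal(cwn$n_windows, 4)
  expect_identical(cwn$counts[word_index(c("AC", "CG")) + 1], c(2L, 2L))

  expect_identical(count_words("acgtACGT", 3)$counts,
                   count_words("ACGTACGT", 3)$counts)
  expect_error(count_words("ACGT", 10), "between 1 and 9")
  expect_equal(count_words("", 2)$n_windows, 0)
})

test_that("count_words agrees with Biostrings and a brute-force window scan", {
  set.seed(11)
  for (i in 1:10) {
    n <- sample(50:400, 1)
    seq <- random_seq(n, alphabet = c("A", "C", "G", "T", "N"))
    for (k in sample(1:5, 2)) {
      cw <- count_words(seq, k)
      ref <- Biostrings::oligonucleotideFrequency(Biostrings::DNAString(seq),
                                                  width = k)
      expect_identical(as.integer(ref), as.integer(cw$counts))
      # brute force: enumerate every offset, skip non-ACGT windows
      wins <- substring(seq, 1:(n - k + 1), k:n)
      valid <- !grepl("[^ACGT]", wins)
      expect_equal(cw$n_windows, sum(valid))
      expect_equal(sum(cw$counts), sum(valid))
    }
  }
})

test_that("counting a whole record equals split counts plus bridge windows", {
  set.seed(7)
  for (i in 1:10) {
    n <- sample(60:200, 1)
    seq <- random_seq(n)
    k <- sample(2:5, 1)
    cut <- sample(seq(k, n - k), 1)
    left <- substr(seq, 1, cut)
    right <- substr(seq, cut + 1, n)
    bridge <- count_words(substr(seq, cut - k + 2, cut + k - 1), k)
    got <- count_words(left, k)$counts + count_words(right, k)$counts +
      bridge$counts
    expect_identical(as.integer(got), as.integer(count_words(seq, k)$counts))
  }
})

test_that("signatures convert counts to percentages that sum to 100", {
  s <- signature_from_sequences("ACGTACGT", 2, label = "toy")
  expect_equal(s$pct[word_index(c("AC", "CG", "GT", "TA")) + 1],
               100 * c(2, 2, 2, 1) / 7, tolerance = 1e-12)
  expect_equal(sum(s$pct), 100, tolerance = 1e-6)

  expect_equal(signature_from_sequences("ACGT", 1)$pct, rep(25, 4))

  # windows never bridge record boundaries
  s2 <- signature_from_sequences(c("AC", "GT"), 2)
  expect_equal(s2$pct[word_index(c("AC", "GT")) + 1], c(50, 50))
  expect_equal(s2$n_windows, 2)

  set.seed(3)
  for (i in 1:10) {
    s <- signature_from_sequences(random_seq(sample(30:300, 1)),
                                  sample(1:5, 1))
    expect_equal(sum(s$pct), 100, tolerance = 1e-6)
    expect_true(all(s$pct >= 0))
  }
  expect_error(signature_from_sequences("NNNN", 2), "empty signature")
})

test_that("FASTA reading handles wrapped lines and the plasmid filter", {
  path <- tempfile(fileext = ".fasta")
  writeLines(c(">org1 chromosome 1", "ACGTACGT", "ACGT",
               ">org2 plasmid pXYZ", "TTTTTTTT",
               ">org3", "ggggcccc"), path)
  seqs <- read_fasta(path)
  expect_identical(names(seqs), c("org1", "org2", "org3"))
  expect_identical(unname(seqs["org1"]), "ACGTACGTACGT")
  expect_identical(unname(seqs["org3"]), "GGGGCCCC")
  expect_identical(names(read_fasta(path, drop_plasmids = TRUE)),
                   c("org1", "org3"))
})

test_that("signature TSV round-trips", {
  sigs <- lapply(1:3, function(i) rand_sig(3, label = paste0("s", i),
                                           seed = i))
  path <- tempfile(fileext = ".tsv")
  write_signatures_tsv(sigs, path, header_lines = "# test")
  back <- read_signatures_tsv(path)
  expect_identical(names(back), c("s1", "s2", "s3"))
  for (i in 1:3) {
    expect_equal(back[[i]]$pct, sigs[[i]]$pct, tolerance = 1e-9)
    expect_equal(back[[i]]$k, 3L)
  }
})
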