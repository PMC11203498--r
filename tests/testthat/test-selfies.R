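# SELFIES codec: round trips, robustness, vocabulary, tokenization.

test_that("single atoms and simple chains encode and decode", {
  expect_identical(smiles_to_selfies("C"), "[C]")
  sf <- smiles_to_selfies("CCO")
  expect_length(split_selfies(sf), 3L)
  expect_identical(selfies_to_smiles(sf), "CCO")
  expect_identical(selfies_to_smiles("[C][C][O]"), "CCO")
})

test_that("round trip preserves canonical structure for ring systems", {
  mols <- c("C1=CC=CC=C1",            # benzene
            "CC(C)Cc1ccc(cc1)C(C)C(=O)O", # ibuprofen
            "C1CC1", "O=C=O", "N#Cc1ccccc1", "C1CCC2CCCCC2C1",
            "FC(F)(F)c1ccccc1", "S=C=S", "ClCBr")
  back <- selfies_to_smiles(smiles_to_selfies(mols))
  expect_identical(chem_canonicalize(back)$canonical,
                   chem_canonicalize(mols)$canonical)
})

test_that("every random token sequence decodes to a valid molecule", {
  set.seed(11)
  alphabet <- selfies_alphabet()
  random_selfies <- vapply(seq_len(1000), function(i) {
    paste(sample(alphabet, sample(1:40, 1), replace = TRUE), collapse = "")
  }, character(1))
  smiles <- selfies_to_smiles(random_selfies)
  expect_true(all(chem_canonicalize(smiles)$valid))
})

test_that("decoding degenerate and out-of-alphabet input", {
  expect_identical(selfies_to_smiles(""), "")      # empty molecule sentinel
  expect_identical(selfies_to_smiles("[Ring1][C]"), "") # no atom tokens
  expect_error(selfies_to_smiles("[Xx]"), "not in the SELFIES alphabet")
  expect_error(split_selfies("[C]junk[O]"), "malformed")
})

test_that("encoder rejects molecules outside the codec's domain", {
  expect_error(smiles_to_selfies("C[N+](C)(C)C"), "charged")
  expect_error(smiles_to_selfies("not_a_smiles"), "unparsable")
})

test_that("vocabulary is deterministic with fixed special indices", {
  v1 <- build_vocabulary(c("[C][C]", "[C][O]"))
  expect_s3_class(v1, "mg_vocab")
  expect_identical(v1$n, 5L) # two chemical tokens + three specials
  expect_identical(v1$tokens[1:3], c("<SOS>", "<EOS>", "<PAD>"))
  expect_identical(v1$specials, c(SOS = 1L, EOS = 2L, PAD = 3L))
  # order-insensitive and duplication-insensitive
  v2 <- build_vocabulary(c("[C][O]", "[C][C]", "[C][C]"))
  expect_identical(v1, v2)
  v3 <- build_vocabulary(rep("[N]", 1000))
  expect_identical(v3$n, 4L)
  expect_error(build_vocabulary(character()), "empty corpus")
})

test_that("token index maps are inverse bijections", {
  v <- fx_vocab()
  idx <- seq_len(v$n)
  expect_identical(adaptmol:::token_to_index(v, adaptmol:::index_to_token(v, idx)),
                   idx)
})

test_that("tokenize adds specials and detokenize inverts exactly", {
  v <- build_vocabulary(c("[C][O]", "[N]"))
  seq1 <- tokenize("[C][O]", v)[[1]]
  expect_identical(seq1[1], v$specials[["SOS"]])
  expect_identical(seq1[length(seq1)], v$specials[["EOS"]])
  expect_length(seq1, 4L)
  for (s in c("[C][O]", "[N]", "[C][C][N][O]")) {
    expect_identical(detokenize(tokenize(s, v)[[1]], v), s)
  }
  expect_error(tokenize("[Xx]", v), "not in vocabulary")
})

test_that("vocabulary JSON round trip preserves the object and its hash", {
  v <- fx_vocab()
  path <- withr::local_tempfile(fileext = ".json")
  write_vocabulary(v, path)
  v2 <- read_vocabulary(path)
  expect_identical(v$tokens, v2$tokens)
  expect_identical(v$specials, v2$specials)
  expect_identical(adaptmol:::vocab_hash(v), adaptmol:::vocab_hash(v2))
})

test_that("molecule files read from plain text and CSV", {
  txt <- withr::local_tempfile(fileext = ".smi")
  writeLines(c("CCO", "", "c1ccccc1"), txt)
  mols <- read_molecules(txt)
  expect_identical(mols$smiles, c("CCO", "c1ccccc1"))
  expect_identical(mols$target, c(0L, 0L))
  csv <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(data.frame(smiles = c("CCO", "CCN"), target = c(1, 2)),
                   csv, row.names = FALSE)
  mols2 <- read_molecules(csv)
  expect_identical(mols2$target, c(1L, 2L))
  bad <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(data.frame(x = 1), bad, row.names = FALSE)
  expect_error(read_molecules(bad), "smiles")
})
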