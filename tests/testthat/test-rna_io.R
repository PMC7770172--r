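test_that("parse_sequence normalizes case, DNA alphabet and unknowns", {
  expect_equal(parse_sequence("aucg")$bases, "AUCG")
  expect_equal(parse_sequence("ATCG")$bases, "AUCG")
  expect_warning(s <- parse_sequence("AXCG"), "mapped to N")
  expect_equal(s$bases, "ANCG")
  expect_error(parse_sequence("   "), "empty")
  expect_error(rna_sequence("AXCG"), "invalid")
})

test_that("one_hot follows the encoding table, N rows all-zero", {
  expect_equal(one_hot(rna_sequence("A")), rbind(c(1, 0, 0, 0)))
  expect_equal(one_hot(rna_sequence("N")), rbind(c(0, 0, 0, 0)))
  expect_equal(one_hot(rna_sequence("AUCG")), diag(4))
  # row sums: 1 for A/U/C/G, 0 for N, over random sequences
  for (k in 1:20) {
    ch <- with_seed_local(k, sample(c("A", "U", "C", "G", "N"), 15,
                                    replace = TRUE))
    m <- one_hot(rna_sequence(paste(ch, collapse = "")))
    expect_equal(rowSums(m), as.numeric(ch != "N"))
  }
})

test_that("pairing matrix round-trips with the pair set", {
  m <- pairs_to_matrix(rbind(c(0, 4)), n = 5)
  expect_equal(which(m == 1), c(5, 21))  # (5,1) and (1,5) column-major
  expect_equal(pairs_to_matrix(NULL, n = 3), matrix(0, 3, 3))
  expect_error(pairs_to_matrix(rbind(c(0, 4), c(0, 3)), n = 5),
               "at most once")
  expect_equal(matrix_to_pairs(matrix(0, 4, 4)),
               matrix(integer(0), ncol = 2,
                      dimnames = list(NULL, c("i", "j"))))
  st <- rna_structure(rbind(c(1, 6)), 8)
  expect_equal(matrix_to_pairs(pairs_to_matrix(st)), st$pairs)
  bad <- matrix(0, 6, 6); bad[3, 6] <- 1
  expect_error(matrix_to_pairs(bad), "symmetric")
  multi <- pairs_to_matrix(rbind(c(0, 4)), 6) +
    pairs_to_matrix(rbind(c(0, 5)), 6)
  expect_error(matrix_to_pairs(multi), "at most once")
})

test_that("round trips hold on generated structures, pseudoknots included", {
  for (k in 1:25) {
    ex <- random_example(k, pk_prob = 0.5)
    expect_equal(matrix_to_pairs(pairs_to_matrix(ex$struct)),
                 ex$struct$pairs)
    rt <- from_dotbracket(to_dotbracket(ex$struct))
    expect_equal(rt$pairs, ex$struct$pairs)
  }
})

test_that("BPSEQ reading converts 1-based indices and checks mutuality", {
  path <- withr::local_tempfile(fileext = ".bpseq")
  writeLines(c("1 G 5", "2 A 0", "3 A 0", "4 A 0", "5 C 1"), path)
  rec <- read_bpseq(path)
  expect_equal(rec$seq$bases, "GAAAC")
  expect_equal(rec$struct$pairs, rna_structure(rbind(c(0, 4)), 5)$pairs)
  writeLines(c("1 G 5", "2 A 0", "3 A 0", "4 A 0", "5 C 2"), path)
  expect_error(read_bpseq(path), "non-mutual")
  writeLines(c("1 G 0", "3 A 0"), path)
  expect_error(read_bpseq(path), "without gaps")
})

test_that("BPSEQ and CT writers round-trip sequence and pairs exactly", {
  for (k in 1:10) {
    ex <- random_example(k, pk_prob = 0.5)
    pb <- withr::local_tempfile(fileext = ".bpseq")
    write_bpseq(ex$seq, ex$struct, pb)
    back <- read_bpseq(pb)
    expect_equal(back$seq$bases, ex$seq$bases)
    expect_equal(back$struct$pairs, ex$struct$pairs)
    pc <- withr::local_tempfile(fileext = ".ct")
    write_ct(ex$seq, ex$struct, pc)
    back <- read_ct(pc)
    expect_equal(back$seq$bases, ex$seq$bases)
    expect_equal(back$struct$pairs, ex$struct$pairs)
  }
})

test_that("CT header is validated", {
  path <- withr::local_tempfile(fileext = ".ct")
  writeLines(c("3 t", "1 G 0 2 0 1", "2 A 1 3 0 2"), path)
  expect_error(read_ct(path), "declares")
})

test_that("FASTA writes and reads multiple records", {
  seqs <- list(rna_sequence("GGGAAACCC", id = "a"),
               rna_sequence("AUGCAUGC", id = "b"))
  path <- withr::local_tempfile(fileext = ".fasta")
  write_fasta(seqs, path)
  back <- read_fasta(path)
  expect_equal(vapply(back, `[[`, "", "bases"),
               vapply(seqs, `[[`, "", "bases"))
  expect_equal(vapply(back, `[[`, "", "id"), c("a", "b"))
})

test_that("dot-bracket assigns crossing pairs to higher tiers greedily", {
  expect_equal(to_dotbracket(rna_structure(rbind(c(0, 5), c(2, 8)), 9)),
               "(.[..)..]")
  expect_equal(to_dotbracket(rna_structure(rbind(c(0, 9), c(1, 8)), 10)),
               "((......))")
  # parser does not enforce the distance constraint on labels
  expect_equal(from_dotbracket("(.)")$pairs,
               rna_structure(rbind(c(0, 2)), 3)$pairs)
  expect_error(from_dotbracket("(.))"), "unbalanced")
  expect_error(from_dotbracket("((."), "unbalanced")
})

test_that("pseudoknot detection uses the crossing criterion", {
  pk <- detect_pseudoknots(rna_structure(rbind(c(0, 5), c(2, 8)), 9))
  expect_true(pk$pseudoknotted)
  expect_length(pk$crossings, 1)
  expect_false(
    detect_pseudoknots(rna_structure(rbind(c(0, 9), c(1, 8)), 10))$
      pseudoknotted)
  expect_false(detect_pseudoknots(rna_structure(NULL, 5))$pseudoknotted)
})
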