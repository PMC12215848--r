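test_that("dot-bracket parsing matches per-layer stacks and flags nesting", {
  ss <- parse_dotbracket("((...))")
  expect_equal(ss$length, 7L)
  expect_equal(unname(ss$pairs), cbind(c(1L, 2L), c(7L, 6L)), ignore_attr = TRUE)
  expect_true(is_nested(ss))

  pk <- parse_dotbracket("..((..[[..))..]]")
  expect_equal(unname(pk$pairs[order(pk$pairs[, 1]), ]),
               cbind(c(3L, 4L, 7L, 8L), c(12L, 11L, 16L, 15L)),
               ignore_attr = TRUE)
  expect_false(is_nested(pk))
  expect_setequal(pk$layers, c("()", "[]"))

  expect_error(parse_dotbracket("(()"), "unbalanced '\\(' at position 1")
  expect_error(parse_dotbracket("(.?.)"), "illegal character '\\?' at position 3")
  expect_error(parse_dotbracket("(.x.)"), "unbalanced 'x' at position 3")
  expect_error(parse_dotbracket("())"), "unbalanced '\\)' at position 3")
})

test_that("dot-bracket writing assigns crossing layers and round-trips", {
  expect_equal(write_dotbracket(rna_structure(7, cbind(c(1, 2), c(7, 6)))),
               "((...))")
  expect_equal(write_dotbracket(rna_structure(3)), "...")
  crossing <- rna_structure(10, cbind(c(1, 2, 4, 5), c(7, 6, 10, 9)))
  db <- write_dotbracket(crossing)
  reparsed <- parse_dotbracket(db)
  expect_equal(unname(reparsed$pairs), unname(crossing$pairs))
})

test_that("dot-bracket round-trip is the identity on random nested structures", {
  for (ss in random_structures(60, lengths = 20:120, seed = 11)) {
    db <- write_dotbracket(ss)
    back <- parse_dotbracket(db)
    expect_equal(unname(back$pairs), unname(ss$pairs))
    expect_equal(back$length, ss$length)
  }
})

test_that("parsed structures always satisfy the structure invariants", {
  # random strings assembled from balanced fragments across layers
  withr::with_seed(3, {
    frags <- c(".", "(.)", "((..))", "[..]", "{.}", "<...>", "A..a", "(..[..)..]")
    for (rep in 1:1000) {
      txt <- paste(sample(frags, sample(1:6, 1), replace = TRUE), collapse = "")
      ss <- parse_dotbracket(txt)
      expect_equal(ss$length, nchar(txt))
      if (nrow(ss$pairs)) {
        expect_true(all(ss$pairs[, 1] < ss$pairs[, 2]))
        expect_true(all(ss$pairs >= 1 & ss$pairs <= ss$length))
        expect_false(anyDuplicated(c(ss$pairs)) > 0)
      }
    }
  })
})

test_that("BPSEQ read/write round-trips and enforces reciprocality", {
  lines <- c("1 G 7", "2 G 6", "3 A 0", "4 A 0", "5 A 0", "6 C 2", "7 C 1")
  ss <- read_bpseq(lines)
  expect_equal(unname(ss$pairs), cbind(c(1L, 2L), c(7L, 6L)), ignore_attr = TRUE)
  expect_equal(ss$sequence, "GGAAACC")
  expect_equal(write_bpseq(parse_dotbracket("((...))", sequence = "GGAAACC")),
               lines)

  bad <- lines; bad[7] <- "7 C 0"
  expect_error(read_bpseq(bad), "non-reciprocal")
  expect_error(read_bpseq(c(lines[1:6], "6 C 2")), "duplicate index")
  expect_error(read_bpseq(lines[c(1:5, 7)]), "gap")
})

test_that("CT read/write agrees with BPSEQ and validates the header", {
  ss <- parse_dotbracket("((...))", sequence = "GGAAACC")
  expect_equal(unname(read_ct(write_ct(ss))$pairs), unname(ss$pairs))
  ct <- write_ct(ss)
  expect_error(read_ct(ct[1:6]), "7 rows but 5 present")
})

test_that("format conversions preserve the pair set on random fixtures", {
  for (ss in random_structures(100, lengths = 20:100, seed = 21)) {
    via_bpseq <- read_bpseq(write_bpseq(ss))
    via_ct <- read_ct(write_ct(ss))
    expect_equal(unname(via_bpseq$pairs), unname(ss$pairs))
    expect_equal(unname(via_ct$pairs), unname(ss$pairs))
    expect_equal(via_bpseq$sequence, ss$sequence)
    expect_equal(write_dotbracket(via_ct), write_dotbracket(ss))
  }
})

test_that("Stockholm/WUSS reading maps layers and validates columns", {
  sto <- c("# STOCKHOLM 1.0", "#=GF AC RF99999",
           "seq1 ACAGU", "seq2 AC-GU", "#=GC SS_cons <<.>>", "//")
  fam <- read_stockholm(sto)
  expect_equal(fam$accession, "RF99999")
  expect_setequal(paste(fam$consensus_pairs$i, fam$consensus_pairs$j),
                  c("1 5", "2 4"))
  expect_true(all(fam$consensus_pairs$layer == "<>"))

  flat <- read_stockholm(c("s1 AAAAA", "#=GC SS_cons :::::"))
  expect_equal(nrow(flat$consensus_pairs), 0L)

  # mixed bracket and letter layers resolve per-layer with their own stacks
  mixed <- read_stockholm(c("s1 AAAAAAAAA", "#=GC SS_cons <<AA.>>aa"))
  expect_setequal(paste(mixed$consensus_pairs$i, mixed$consensus_pairs$j,
                        mixed$consensus_pairs$layer),
                  c("1 7 <>", "2 6 <>", "3 9 Aa", "4 8 Aa"))
  expect_error(parse_wuss("<A>a<"), "unbalanced")
  expect_error(read_stockholm(c("s1 ACGU")), "SS_cons")
  expect_error(read_stockholm(c("s1 ACGUA", "s2 ACG", "#=GC SS_cons <<.>>")),
               "width")
})

test_that("wrapped multi-block Stockholm files concatenate per row", {
  sto <- c("# STOCKHOLM 1.0",
           "seq1 ACA", "seq2 AC-", "#=GC SS_cons <<.",
           "",
           "seq1 GU", "seq2 GU", "#=GC SS_cons >>", "//")
  fam <- read_stockholm(sto)
  expect_equal(fam$n_columns, 5L)
  expect_equal(fam$rows$seq, c("ACAGU", "AC-GU"))
  expect_setequal(paste(fam$consensus_pairs$i, fam$consensus_pairs$j),
                  c("1 5", "2 4"))
})

test_that("WUSS letter layers are pseudoknot layers and unpaired chars accepted", {
  cp <- parse_wuss("<<AA..>>.aa,:_-~")
  expect_setequal(cp$layer, c("<>", "Aa"))
  expect_equal(sort(cp$i), c(1L, 2L, 3L, 4L))
  expect_equal(cp$j[match(3:4, cp$i)], c(11L, 10L))   # letter layer pairs
})

test_that("dataset CSV round-trips and validates schema", {
  ss <- parse_dotbracket("((..((...))..))", sequence = "GGAAGGAAACCAACC")
  loops <- decompose_loops(ss)
  rec <- extract_records(ss, "rnasolo", "X_1_A", "XXXX", category = "7")
  path <- withr::local_tempfile(fileext = ".csv")
  write_dataset_csv(rec, path)
  back <- read_dataset_csv(path)
  expect_equal(as.data.frame(back), as.data.frame(rec))

  write_dataset_csv(rec[0, ], path)
  expect_equal(nrow(read_dataset_csv(path)), 0L)
  expect_equal(names(readr::read_csv(path, show_col_types = FALSE)),
               rnaloopkit:::dataset_columns)

  bad <- rec; bad$loop_seq <- paste0(bad$loop_seq, "A")
  write_dataset_csv(bad, path)
  expect_error(read_dataset_csv(path), "row 1")
})

test_that("dataset CSV round-trip holds for many generated records", {
  recs <- purrr::map_dfr(random_structures(25, lengths = 40:120, seed = 31),
                         function(ss) extract_records(ss, "rfam", "row", "RFx"))
  expect_gt(nrow(recs), 10)
  path <- withr::local_tempfile(fileext = ".csv")
  write_dataset_csv(recs, path)
  expect_equal(as.data.frame(read_dataset_csv(path)), as.data.frame(recs))
})

test_that("FASTA reading and writing round-trips through Biostrings", {
  path <- withr::local_tempfile(fileext = ".fa")
  x <- tibble::tibble(id = c("a", "b"), sequence = c("ACGU", "GGGAAACCC"))
  write_fasta(x, path)
  expect_equal(as.data.frame(read_fasta(path)), as.data.frame(x))
})
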