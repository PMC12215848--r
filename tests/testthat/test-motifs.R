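test_that("stems are maximal stacked runs in 5'-to-3' order", {
  s1 <- find_stems(parse_dotbracket("((...))"))
  expect_equal(unique(s1$stem), 1L)
  expect_equal(nrow(s1), 2L)

  s2 <- find_stems(parse_dotbracket("(.((...)).)"))
  expect_equal(unname(split(paste(s2$i, s2$j), s2$stem)),
               list("1 11", c("3 9", "4 8")))

  s3 <- find_stems(parse_dotbracket("((..((...))..((...))..))"))
  expect_equal(max(s3$stem), 3L)
  expect_equal(s3$i[s3$stem == 2], c(5L, 6L))
  expect_equal(s3$j[s3$stem == 3], c(20L, 19L))

  expect_error(find_stems(parse_dotbracket("..((..[[..))..]]")), "pseudoknot")
  expect_equal(nrow(find_stems(rna_structure(5))), 0L)
})

test_that("loop decomposition classifies the worked examples", {
  d <- decompose_loops(parse_dotbracket("((..((...))..((...))..))"))
  j <- d[d$loop_class == "junction", ]
  expect_equal(nrow(j), 1L)
  expect_equal(j$order, 3L)
  expect_equal(j$closing_i, 2L)
  expect_equal(j$closing_j, 23L)
  expect_equal(unname(j$children[[1]][, 1]), c(5L, 14L))
  expect_equal(j$strand_lengths[[1]], c(2L, 2L, 2L))
  expect_equal(sum(d$loop_class == "hairpin"), 2L)
  expect_equal(d$strand_lengths[d$loop_class == "exterior"][[1]], c(0L, 0L))

  d2 <- decompose_loops(parse_dotbracket("((..((...))..))"))
  int <- d2[d2$loop_class == "internal", ]
  expect_equal(int$strand_lengths[[1]], c(2L, 2L))

  d3 <- decompose_loops(parse_dotbracket("((.((...))))"))
  bulge <- d3[d3$loop_class == "internal", ]
  expect_equal(bulge$strand_lengths[[1]], c(1L, 0L))

  # empty structure: exterior only
  d4 <- decompose_loops(rna_structure(6))
  expect_equal(d4$loop_class, "exterior")
})

test_that("decomposition agrees with the brute-force oracle on random fixtures", {
  for (ss in random_structures(500, lengths = 20:200, seed = 101)) {
    expect_equal(loop_signature(decompose_loops(ss)),
                 loop_signature(brute_force_decompose(ss)))
  }
})

test_that("positions are conserved across stems, loop strands and exterior", {
  for (ss in random_structures(100, lengths = 20:150, seed = 55)) {
    stems <- find_stems(ss)
    loops <- decompose_loops(ss)
    strand_total <- sum(unlist(loops$strand_lengths))
    expect_equal(2L * nrow(stems) + strand_total, ss$length)
    # loop count bookkeeping: loops of order >= 2 = stems - hairpins - top-level
    n_hairpin <- sum(loops$loop_class == "hairpin")
    n_top <- nrow(loops$children[loops$loop_class == "exterior"][[1]])
    n_multi <- sum(!is.na(loops$order) & loops$order >= 2)
    expect_equal(n_multi, max(stems$stem, 0) - n_hairpin)
    # junction feature vectors sum to the loop's unpaired total
    for (r in which(loops$loop_class == "junction")) {
      feats <- junction_features(loops[r, ], generalize = TRUE)
      expect_equal(length(feats), loops$order[r])
      expect_equal(sum(feats), sum(loops$strand_lengths[[r]]))
    }
  }
})

test_that("junction features echo strand lengths and reject non-junctions", {
  d <- decompose_loops(parse_dotbracket("((..((...))..((...))..))"))
  j <- d[d$loop_class == "junction", ]
  expect_equal(junction_features(j), c(2L, 2L, 2L))
  hp <- d[d$loop_class == "hairpin", ][1, ]
  expect_error(junction_features(hp), "3-way")
  expect_equal(junction_features(hp, generalize = TRUE), 3L)
  ext <- d[d$loop_class == "exterior", ]
  expect_error(junction_features(ext), "exterior")
})

test_that("instance generation reproduces the worked examples", {
  ss <- parse_dotbracket("((..((...))..((...))..))",
                         sequence = "GGAAGGAAACCAAGGAAACCAACC")
  loops <- decompose_loops(ss)
  j <- loops[loops$loop_class == "junction", ]
  inst <- make_instances(ss, j)
  expect_equal(inst$len_loop, 12L)
  expect_equal(inst$len_loop_stems, 18L)
  expect_equal(inst$len_full, 24L)
  # the two excised hairpins were exactly 3 nt, so the capped instance
  # coincides with the full structure
  expect_equal(inst$loop_stems_db, "((..((...))..((...))..))")
  expect_equal(inst$loop_db, "(..(...)..(...)..)")
  expect_equal(nchar(inst$loop_seq), nchar(inst$loop_db))

  ss2 <- parse_dotbracket("((..((...))..))", sequence = "GGAAGGAAACCAACC")
  l2 <- decompose_loops(ss2)
  int <- l2[l2$loop_class == "internal", ]
  inst2 <- make_instances(ss2, int)
  expect_equal(inst2$len_loop_stems, 12L)
  expect_equal(inst2$loop_stems_db, "((..((...))..))")

  hp <- l2[l2$loop_class == "hairpin", ]
  expect_error(make_instances(ss2, hp), "order >= 2")
})

test_that("instances re-parse and respect the length ordering", {
  for (ss in random_structures(60, lengths = 40:150, seed = 77)) {
    loops <- decompose_loops(ss)
    loops <- loops[!is.na(loops$order) & loops$order >= 2, ]
    for (r in seq_len(nrow(loops))) {
      inst <- make_instances(ss, loops[r, ])
      expect_no_error(parse_dotbracket(inst$loop_db))
      expect_no_error(parse_dotbracket(inst$loop_stems_db))
      expect_equal(nchar(inst$loop_seq), nchar(inst$loop_db))
      expect_equal(nchar(inst$loop_stems_seq), nchar(inst$loop_stems_db))
      expect_lte(inst$len_loop, inst$len_loop_stems)
      expect_lte(inst$len_loop_stems, inst$len_full)
      # capped hairpins never shorter than the cap
      hp <- decompose_loops(parse_dotbracket(inst$loop_db))
      hp <- hp[hp$loop_class == "hairpin", ]
      if (nrow(hp)) expect_true(all(unlist(hp$strand_lengths) >= 3))
    }
  }
})

test_that("cap length zero emits the raw fragment without splices", {
  ss <- parse_dotbracket("((..((...))..))", sequence = "GGAAGGAAACCAACC")
  int <- decompose_loops(ss)
  int <- int[int$loop_class == "internal", ]
  inst <- make_instances(ss, int, cap_length = 0L)
  expect_equal(inst$len_loop_stems, nchar(inst$loop_stems_seq))
  expect_equal(inst$loop_stems_db, "((..(())..))")
})

test_that("the random-structure generator is seeded and respects constraints", {
  a <- generate_random_structure(30, seed = 1)
  b <- generate_random_structure(30, seed = 1)
  expect_equal(unname(a$pairs), unname(b$pairs))
  expect_equal(a$sequence, b$sequence)
  c1 <- generate_random_structure(30, seed = 2)
  expect_false(identical(a$sequence, c1$sequence))

  # forcing <= 1 child per face yields no junctions
  withr::with_seed(9, {
    for (rep in 1:20) {
      ss <- generate_random_structure(80, branching_weights = c(0.3, 0.7))
      loops <- decompose_loops(ss)
      expect_equal(sum(loops$loop_class == "junction"), 0L)
    }
  })
})

test_that("generated structures satisfy the structural invariants", {
  for (ss in random_structures(500, lengths = 20:200, seed = 13)) {
    expect_true(is_nested(ss))
    expect_equal(nchar(ss$sequence), ss$length)
    loops <- decompose_loops(ss)
    hp <- loops[loops$loop_class == "hairpin", ]
    if (nrow(hp)) expect_true(all(unlist(hp$strand_lengths) >= 3))
    # paired letters are complementary (canonical or wobble)
    if (nrow(ss$pairs)) {
      chars <- strsplit(ss$sequence, "")[[1]]
      duo <- paste0(chars[ss$pairs[, 1]], chars[ss$pairs[, 2]])
      expect_true(all(duo %in% c("AU", "UA", "GC", "CG", "GU", "UG")))
    }
  }
  expect_error(generate_random_structure(0), ">= 1")
})
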