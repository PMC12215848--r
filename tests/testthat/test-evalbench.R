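test_that("base-pair F1 follows the set-arithmetic definition", {
  t <- rna_structure(7, cbind(c(1, 2), c(7, 6)))
  p <- rna_structure(7, cbind(1, 7))
  f <- bp_f1(t, p)
  expect_equal(f$precision, 1)
  expect_equal(f$recall, 0.5)
  expect_equal(f$f1, 2 / 3)

  expect_equal(bp_f1(t, t)$f1, 1)
  disjoint <- rna_structure(7, cbind(2, 5))
  expect_equal(bp_f1(t, disjoint)$f1, 0)
  expect_equal(bp_f1(rna_structure(5), rna_structure(5))$f1, 1)  # both empty
  expect_equal(bp_f1(t, rna_structure(7))$f1, 0)                 # pred empty
  expect_error(bp_f1(t, rna_structure(6)), "length")
})

test_that("F1 matches a brute-force oracle and swaps precision/recall", {
  withr::with_seed(17, {
    for (rep in 1:100) {
      a <- generate_random_structure(sample(20:80, 1))
      b <- generate_random_structure(a$length)
      f <- bp_f1(a, b)
      # oracle: direct double loop over pair rows
      tp <- 0L
      for (r in seq_len(nrow(a$pairs))) {
        for (s in seq_len(nrow(b$pairs))) {
          if (all(a$pairs[r, ] == b$pairs[s, ])) tp <- tp + 1L
        }
      }
      prec <- if (nrow(b$pairs)) tp / nrow(b$pairs) else 0
      rec <- if (nrow(a$pairs)) tp / nrow(a$pairs) else 0
      expect_equal(f$precision, prec)
      expect_equal(f$recall, rec)
      swapped <- bp_f1(b, a)
      expect_equal(swapped$precision, f$recall)
      expect_equal(swapped$recall, f$precision)
      expect_equal(swapped$f1, f$f1)
    }
  })
})

test_that("tree edit distance is a metric with the expected small cases", {
  expect_equal(tree_edit_distance("((...))", "((...))"), 0)
  expect_equal(tree_edit_distance(".", ".."), 1)     # one leaf insertion
  expect_equal(tree_edit_distance("(...)", "....."), 4)  # pair del + 2 leaves
  expect_error(tree_edit_distance("..((..[[..))..]]", "...."), "nested")

  withr::with_seed(23, {
    ref <- lapply(1:30, function(k) generate_random_structure(sample(15:60, 1)))
    for (rep in 1:200) {
      tri <- sample(ref, 3)
      dab <- tree_edit_distance(tri[[1]], tri[[2]])
      dba <- tree_edit_distance(tri[[2]], tri[[1]])
      dbc <- tree_edit_distance(tri[[2]], tri[[3]])
      dac <- tree_edit_distance(tri[[1]], tri[[3]])
      expect_equal(dab, dba)                 # symmetry
      expect_lte(dac, dab + dbc)             # triangle inequality
      expect_equal(tree_edit_distance(tri[[1]], tri[[1]]), 0)
    }
  })
})

test_that("tree edit distance matches the reference RNAdistance binary", {
  withr::with_seed(31, {
    for (rep in 1:100) {
      a <- write_dotbracket(generate_random_structure(sample(15:80, 1)))
      b <- write_dotbracket(generate_random_structure(sample(15:80, 1)))
      expect_equal(tree_edit_distance(a, b), rnadistance_ref(a, b))
    }
  })
})

test_that("distance normalisation divides by target length", {
  expect_equal(normalize_distance(14, 100), 0.14)
  expect_equal(normalize_distance(0, 57), 0)
  expect_equal(normalize_distance(2 * 14, 100), 2 * normalize_distance(14, 100))
  expect_error(normalize_distance(3, 0), "positive")
})

test_that("failure aggregation substitutes worst-case values per metric", {
  m <- tibble::tibble(tool = rep(c("A", "B"), each = 3),
                      case_id = rep(1:3, 2),
                      value = c(1.2, NA, 0.5, 0.3, 0.4, NA))
  agg <- aggregate_with_failures(m, "rnadistance")
  expect_equal(agg$values$A, c(1.2, Inf, 0.5))
  expect_equal(agg$values$B, c(0.3, 0.4, Inf))
  expect_equal(agg$common, c(TRUE, FALSE, FALSE))
  expect_equal(agg$direction, "lower")

  f <- tibble::tibble(tool = "A", case_id = 1:2, value = c(0.9, NA))
  expect_equal(aggregate_with_failures(f, "f1")$values$A, c(0.9, 0))
  # finite values are never altered and case counts are conserved
  expect_equal(nrow(agg$values), 3L)
  expect_error(aggregate_with_failures(m, "bogus"), "unknown metric")
})

test_that("one-sided signed-rank p-values match exact enumeration", {
  # strict dominance over 5 pairs: p = 1/32
  w <- wilcoxon_matrix(tibble::tibble(A = 1:5, B = 2:6), direction = "lower")
  expect_equal(w$p["A", "B"], 1 / 32)
  expect_equal(w$p["B", "A"], 1)

  # identical vectors: p = 1 by convention
  w2 <- wilcoxon_matrix(tibble::tibble(A = 1:5, B = 1:5), direction = "lower")
  expect_equal(w2$p["A", "B"], 1)

  # exact enumeration oracle over all sign assignments, n <= 10
  enumerate_p <- function(x, y, lower_better) {
    d <- x - y
    d <- d[d != 0]
    n <- length(d)
    r <- rank(abs(d))
    w_obs <- sum(r[d > 0])
    total <- 0
    for (mask in 0:(2^n - 1)) {
      signs <- ifelse(bitwAnd(mask, 2^(seq_len(n) - 1)) > 0, 1, -1)
      w_sim <- sum(r[signs > 0])
      hit <- if (lower_better) w_sim <= w_obs else w_sim >= w_obs
      total <- total + hit
    }
    total / 2^n
  }
  withr::with_seed(41, {
    for (rep in 1:25) {
      n <- sample(4:10, 1)
      x <- sample(1:6, n, replace = TRUE)
      y <- sample(1:6, n, replace = TRUE)
      if (all(x == y)) next
      for (dir in c("lower", "higher")) {
        p <- wilcoxon_matrix(tibble::tibble(A = x, B = y), dir)$p["A", "B"]
        expect_equal(p, enumerate_p(x, y, dir == "lower"))
      }
    }
  })
})

test_that("signed-rank p-values agree with wilcox.test on tie-free data", {
  withr::with_seed(53, {
    for (rep in 1:20) {
      n <- sample(8:20, 1)
      x <- stats::rnorm(n)
      y <- stats::rnorm(n)
      p <- wilcoxon_matrix(tibble::tibble(A = x, B = y), "lower")$p["A", "B"]
      ref <- stats::wilcox.test(x, y, paired = TRUE, alternative = "less",
                                exact = TRUE)$p.value
      expect_equal(p, ref)
    }
  })
})

test_that("failures never beat finite results in the comparison matrix", {
  n <- 12
  vals <- tibble::tibble(good = stats::runif(n), bad = rep(Inf, n))
  w <- wilcoxon_matrix(vals, "lower")
  expect_equal(w$p["bad", "good"], 1)
  expect_equal(w$p["good", "bad"], 1 / 2^n)
  # higher-better metric: failures become 0
  f <- tibble::tibble(good = stats::runif(n, 0.5, 1), bad = rep(0, n))
  wf <- wilcoxon_matrix(f, "higher")
  expect_equal(wf$p["bad", "good"], 1)
  expect_lt(wf$p["good", "bad"], 0.001)
  expect_error(wilcoxon_matrix(list(A = 1:3, B = 1:4)), "length")
})

test_that("target probabilities and candidate selection follow the energy rule", {
  expect_equal(target_probability(-10, -10), 1)
  RT <- 0.61633
  expect_equal(target_probability(-10 + RT * log(2), -10), 0.5)
  expect_error(target_probability(1, 1, RT = 0), "positive")

  cands <- tibble::tibble(sequence = c("s1", "s2", "s3"),
                          psum = c(0.8, 0.8, 0.5),
                          mfe = c(-12, -15, -20))
  expect_equal(select_candidate(cands), "s2")
  expect_equal(select_candidate(cands[3, ]), "s3")
  expect_error(select_candidate(cands[0, ]), "empty")
})

test_that("comparison matrices tidy and summarise cleanly", {
  w <- wilcoxon_matrix(tibble::tibble(A = 1:6, B = 2:7, C = c(3, 1, 4, 1, 5, 9)),
                       "lower")
  td <- tidy(w)
  expect_equal(nrow(td), 6L)
  expect_true(all(td$p_value >= 0 & td$p_value <= 1))
  gl <- glance(w)
  expect_equal(gl$tool, c("A", "B", "C"))
  p <- autoplot(w)
  expect_s3_class(p, "ggplot")
})
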