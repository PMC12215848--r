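# Shared fixture builders for the suite. Everything is generated in code so
# the repository carries no binary data.

# A batch of seeded random nested structures.
random_structures <- function(n, lengths = 20:200, seed = 1L) {
  withr::with_seed(seed, {
    lens <- sample(lengths, n, replace = TRUE)
    lapply(seq_len(n), function(k) {
      generate_random_structure(lens[k], seed = sample.int(1e6, 1))
    })
  })
}

# A random (possibly crossing) pair set over `length` positions with at most
# `max_pairs` pairs, each position used at most once.
random_pair_set <- function(length, max_pairs) {
  n_pairs <- sample.int(min(max_pairs, length %/% 2L), 1)
  pos <- sample.int(length, 2L * n_pairs)
  i <- pmin(pos[seq_len(n_pairs)], pos[n_pairs + seq_len(n_pairs)])
  j <- pmax(pos[seq_len(n_pairs)], pos[n_pairs + seq_len(n_pairs)])
  keep <- i < j
  cbind(i[keep], j[keep])
}

# Exhaustive maximum nested subset size over all 2^P subsets (oracle).
exhaustive_max_nested <- function(pairs) {
  np <- nrow(pairs)
  if (np == 0L) return(0L)
  crossing <- function(sel) {
    p <- pairs[sel, , drop = FALSE]
    if (nrow(p) < 2L) return(FALSE)
    for (a in seq_len(nrow(p) - 1L)) {
      for (b in (a + 1L):nrow(p)) {
        i <- p[a, 1L]; j <- p[a, 2L]; k <- p[b, 1L]; l <- p[b, 2L]
        if ((i < k && k < j && j < l) || (k < i && i < l && l < j)) return(TRUE)
      }
    }
    FALSE
  }
  best <- 0L
  for (mask in 0:(2^np - 1L)) {
    sel <- which(bitwAnd(mask, 2^(seq_len(np) - 1L)) > 0L)
    if (length(sel) > best && !crossing(sel)) best <- length(sel)
  }
  best
}

# Simulated annotator ensemble: a true structure plus per-annotator noise
# (random pair dropout and a few spurious pairs), as pair matrices.
random_annotations <- function(true_ss, n_annotators, dropout = 0.15,
                               spurious = 2L) {
  partner <- pair_partners(true_ss)
  free0 <- which(partner == 0L)
  lapply(seq_len(n_annotators), function(a) {
    p <- true_ss$pairs
    keep <- stats::runif(nrow(p)) > dropout
    p <- p[keep, , drop = FALSE]
    n_sp <- sample.int(spurious + 1L, 1) - 1L
    free <- free0
    for (s in seq_len(n_sp)) {
      if (length(free) < 2L) break
      duo <- sort(sample(free, 2L))
      free <- setdiff(free, duo)
      p <- rbind(p, duo)
    }
    unname(p)
  })
}

# Multiset signature of a decomposition, for oracle comparison.
loop_signature <- function(loops) {
  sig <- vapply(seq_len(nrow(loops)), function(r) {
    paste(loops$loop_class[r],
          paste(sort(loops$strand_lengths[[r]]), collapse = ","))
  }, character(1))
  sort(sig)
}
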