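# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: the diagonality oracle projects onto the line
# with vector algebra instead of the cross-product formula, and the span
# matcher is a quadratic greedy matcher instead of multiset key counting.

# Mean point-to-line distance by explicit projection, explicit cell loop.
brute_force_diagonality <- function(m) {
  a <- c(1, 1)
  b <- c(nrow(m), ncol(m))
  total <- 0; count <- 0
  for (i in seq_len(nrow(m))) {
    for (j in seq_len(ncol(m))) {
      if (m[i, j] != 0) {
        p <- c(i, j)
        if (all(b == a)) {
          dist <- sqrt(sum((p - a)^2))
        } else {
          u <- (b - a) / sqrt(sum((b - a)^2))
          proj <- a + sum((p - a) * u) * u
          dist <- sqrt(sum((p - proj)^2))
        }
        total <- total + dist
        count <- count + 1
      }
    }
  }
  total / count
}

# Greedy one-to-one exact matcher over raw span lists.
brute_force_entity_prf <- function(gold, pred) {
  used <- rep(FALSE, nrow(pred))
  tp <- 0L
  for (g in seq_len(nrow(gold))) {
    for (q in seq_len(nrow(pred))) {
      if (!used[q] &&
          gold$sentence_id[g] == pred$sentence_id[q] &&
          gold$start[g] == pred$start[q] &&
          gold$end[g] == pred$end[q] &&
          gold$label[g] == pred$label[q]) {
        used[q] <- TRUE
        tp <- tp + 1L
        break
      }
    }
  }
  p <- if (nrow(pred)) 100 * tp / nrow(pred) else 0
  r <- if (nrow(gold)) 100 * tp / nrow(gold) else 0
  f <- if (p + r > 0) 2 * p * r / (p + r) else 0
  list(precision = p, recall = r, f1 = f)
}

random_link_matrix <- function(max_dim = 12L) {
  nr <- sample.int(max_dim, 1)
  nc <- sample.int(max_dim, 1)
  m <- matrix(0L, nr, nc)
  k <- sample.int(nr * nc, 1)
  m[sample.int(nr * nc, k)] <- 1L
  m
}
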