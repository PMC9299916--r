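# Independent oracles and small fixture builders used across the suite.

# Brute-force complete-linkage agglomeration: rescans every cluster pair at
# every step and recomputes the furthest-neighbour distance from the
# original matrix. Same tie-break rule as the implementation (smallest
# (left, right) representative-label pair), but none of its incremental
# machinery.
brute_complete_linkage <- function(d) {
  clusters <- as.list(rownames(d))
  steps <- list()
  while (length(clusters) > 1L) {
    bh <- Inf; bi <- NA_integer_; bj <- NA_integer_; bkey <- c("", "")
    for (i in seq_along(clusters)) {
      for (j in seq_along(clusters)) {
        if (i >= j) next
        h <- max(d[clusters[[i]], clusters[[j]]])
        ri <- min(clusters[[i]]); rj <- min(clusters[[j]])
        key <- c(min(ri, rj), max(ri, rj))
        if (h < bh ||
            (h == bh && (key[1L] < bkey[1L] ||
                         (key[1L] == bkey[1L] && key[2L] < bkey[2L])))) {
          bh <- h; bi <- i; bj <- j; bkey <- key
        }
      }
    }
    left <- if (min(clusters[[bi]]) <= min(clusters[[bj]])) bi else bj
    right <- if (left == bi) bj else bi
    steps[[length(steps) + 1L]] <- list(left = clusters[[left]],
                                        right = clusters[[right]],
                                        height = bh)
    clusters[[left]] <- c(clusters[[left]], clusters[[right]])
    clusters[[right]] <- NULL
  }
  steps
}

# Brute-force Jaccard: explicit per-species double loop counting shared,
# a-only and b-only presences.
brute_jaccard_matrix <- function(m) {
  n <- nrow(m)
  out <- diag(1, n)
  dimnames(out) <- list(rownames(m), rownames(m))
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      a <- 0L; b <- 0L; cc <- 0L
      for (s in seq_len(ncol(m))) {
        if (m[i, s] == 1L && m[j, s] == 1L) a <- a + 1L
        else if (m[i, s] == 1L) b <- b + 1L
        else if (m[j, s] == 1L) cc <- cc + 1L
      }
      out[i, j] <- a / (a + b + cc)
    }
  }
  out
}

# random binary incidence matrix with no empty row or column
random_incidence <- function(n_moas, n_species, p = 0.4) {
  repeat {
    m <- matrix(rbinom(n_moas * n_species, 1L, p), n_moas, n_species,
                dimnames = list(sprintf("m%02d", seq_len(n_moas)),
                                sprintf("s%02d", seq_len(n_species))))
    if (all(rowSums(m) > 0L) && all(colSums(m) > 0L)) return(m)
  }
}

# random symmetric distance matrix with zero diagonal
random_distance <- function(n, digits = 2) {
  d <- matrix(0, n, n,
              dimnames = list(sprintf("x%02d", seq_len(n)),
                              sprintf("x%02d", seq_len(n))))
  vals <- round(runif(n * (n - 1) / 2, 0.05, 1), digits)
  d[upper.tri(d)] <- vals
  d[lower.tri(d)] <- t(d)[lower.tri(d)]
  d
}

# sorted member sets of the first k merge steps, for structural comparison
merge_signature <- function(steps) {
  lapply(steps, function(s) {
    pair <- list(sort(s$left), sort(s$right))
    pair[order(vapply(pair, `[`, character(1), 1L))]
  })
}

dend_signature <- function(dend) {
  merge_signature(lapply(seq_along(dend$height), function(i)
    c(dend$members[[i]], height = dend$height[i])))
}

# small canonical record table
toy_records <- function() {
  data.frame(
    species = c("Lolium rigidum", "Lolium rigidum", "Poa annua",
                "Amaranthus palmeri", "Poa annua"),
    growth_form = c("monocot", "monocot", "monocot", "dicot", "monocot"),
    moa_group = c("1", "2", "2", "2", "5"),
    stringsAsFactors = FALSE)
}
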