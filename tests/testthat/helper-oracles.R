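# Independent brute-force oracles used to validate the package's
# implementations. These deliberately share no code with the package.

# full three-state affine-gap global alignment, score only;
# a gap of length k scores gap_open + k * gap_ext
nw_affine_oracle <- function(a, b, match = 1, mismatch = -3,
                             gap_open = -5, gap_ext = -2) {
  x <- strsplit(a, "")[[1]]; y <- strsplit(b, "")[[1]]
  n <- length(x); m <- length(y)
  NEG <- -1e15
  M <- matrix(NEG, n + 1, m + 1)
  IX <- matrix(NEG, n + 1, m + 1)  # gap in b (consumes a)
  IY <- matrix(NEG, n + 1, m + 1)  # gap in a (consumes b)
  M[1, 1] <- 0
  if (n > 0) for (i in 2:(n + 1)) IX[i, 1] <- gap_open + gap_ext * (i - 1)
  if (m > 0) for (j in 2:(m + 1)) IY[1, j] <- gap_open + gap_ext * (j - 1)
  if (n > 0 && m > 0) {
    for (i in 2:(n + 1)) {
      for (j in 2:(m + 1)) {
        s <- if (x[i - 1] == y[j - 1] && x[i - 1] != "N") match else mismatch
        M[i, j] <- max(M[i - 1, j - 1], IX[i - 1, j - 1],
                       IY[i - 1, j - 1]) + s
        IX[i, j] <- max(M[i - 1, j] + gap_open + gap_ext,
                        IY[i - 1, j] + gap_open + gap_ext,
                        IX[i - 1, j] + gap_ext)
        IY[i, j] <- max(M[i, j - 1] + gap_open + gap_ext,
                        IX[i, j - 1] + gap_open + gap_ext,
                        IY[i, j - 1] + gap_ext)
      }
    }
  }
  max(M[n + 1, m + 1], IX[n + 1, m + 1], IY[n + 1, m + 1])
}

# step-up Benjamini-Hochberg, written from the definition
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- p[o] * m / seq_len(m)
  q <- rev(cummin(rev(q)))
  q <- pmin(q, 1)
  out <- numeric(m)
  out[o] <- q
  out
}

# naive agglomerative average linkage; returns the cophenetic matrix
avg_linkage_cophenetic <- function(d) {
  d <- as.matrix(d)
  n <- nrow(d)
  members <- as.list(seq_len(n))
  coph <- matrix(0, n, n)
  active <- seq_len(n)
  dd <- d
  while (length(active) > 1) {
    sub <- dd[active, active, drop = FALSE]
    diag(sub) <- Inf
    k <- which(sub == min(sub), arr.ind = TRUE)[1, ]
    i <- active[k[1]]; j <- active[k[2]]
    h <- sub[k[1], k[2]]
    for (a in members[[i]]) for (b in members[[j]]) {
      coph[a, b] <- h; coph[b, a] <- h
    }
    # average-linkage update, weighted by member counts
    ni <- length(members[[i]]); nj <- length(members[[j]])
    for (l in active) {
      if (l == i || l == j) next
      dd[i, l] <- (ni * dd[i, l] + nj * dd[j, l]) / (ni + nj)
      dd[l, i] <- dd[i, l]
    }
    members[[i]] <- c(members[[i]], members[[j]])
    active <- setdiff(active, j)
  }
  coph
}

random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                       replace = TRUE), collapse = "")
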