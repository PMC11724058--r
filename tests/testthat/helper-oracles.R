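# Independent brute-force oracles. These deliberately avoid the package's
# own code paths (C++ string ops, svd-based fit) so agreement is evidence.

rand_dna <- function(n, len) {
  vapply(seq_len(n), function(i)
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = ""),
    character(1))
}

hamming_chr <- function(a, b) {
  sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
}

# exhaustive barcode assignment: unique minimum within max_mismatch
oracle_assign <- function(query, whitelist, max_mismatch) {
  d <- vapply(whitelist, hamming_chr, numeric(1), a = query)
  if (min(d) > max_mismatch) return(NA_character_)
  hits <- which(d == min(d))
  if (length(hits) > 1) return("ambiguous")
  whitelist[hits]
}

# connected components of the Hamming<=1 graph by BFS over an adjacency
# matrix built with plain R string comparison
oracle_umi_count <- function(umis, max_dist = 1) {
  uu <- unique(umis)
  n <- length(uu)
  if (n == 0) return(0L)
  adj <- outer(seq_len(n), seq_len(n), Vectorize(function(i, j)
    hamming_chr(uu[i], uu[j]) <= max_dist))
  seen <- rep(FALSE, n)
  comps <- 0L
  for (s in seq_len(n)) {
    if (seen[s]) next
    comps <- comps + 1L
    queue <- s
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      if (seen[v]) next
      seen[v] <- TRUE
      queue <- c(queue, which(adj[v, ] & !seen))
    }
  }
  comps
}

# co-inertia eigenvalues via eigendecomposition of the cross-product's
# Gram matrix (no svd), on column-centered tables
oracle_coinertia_eig <- function(X, Y) {
  Xc <- sweep(X, 2, colMeans(X))
  Yc <- sweep(Y, 2, colMeans(Y))
  C <- t(Yc) %*% Xc
  ev <- eigen(t(C) %*% C, symmetric = TRUE, only.values = TRUE)$values
  head(sort(pmax(ev, 0), decreasing = TRUE), min(ncol(X), ncol(Y)))
}

# RV via explicit trace of configuration-matrix products
oracle_rv <- function(X, Y) {
  Xc <- sweep(X, 2, colMeans(X))
  Yc <- sweep(Y, 2, colMeans(Y))
  Wx <- Xc %*% t(Xc)
  Wy <- Yc %*% t(Yc)
  sum(diag(Wx %*% Wy)) / sqrt(sum(diag(Wx %*% Wx)) * sum(diag(Wy %*% Wy)))
}

# exact two-sided rank-sum p-value by full enumeration of group assignments
oracle_wilcox_p <- function(a, b) {
  m <- length(a); n <- length(b)
  pooled <- c(a, b)
  r <- rank(pooled)
  obs <- sum(r[seq_len(m)])
  idx <- utils::combn(m + n, m)
  sums <- apply(idx, 2, function(ix) sum(r[ix]))
  mu <- m * (m + n + 1) / 2
  mean(abs(sums - mu) >= abs(obs - mu) - 1e-9)
}

# small deterministic tagged-read fixture builder
toy_reads <- function(seqs, ids = sprintf("r%03d", seq_along(seqs))) {
  data.frame(read_id = ids, seq = seqs,
             qual = strrep("I", nchar(seqs)))
}
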