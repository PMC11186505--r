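# Small in-code fixtures shared across test files.

# A toy compendium of hand-built signatures.
toy_compendium <- function() {
  list(
    A = drug_signature("A", up = c("G1", "G2"), down = c("G3", "G4")),
    B = drug_signature("B", up = c("G3", "G4"), down = c("G1", "G2")),
    C = drug_signature("C", up = c("G9", "G10"), down = c("G11"))
  )
}

# Independent Welch t-test oracle via stats::t.test, per gene.
welch_oracle <- function(mat, groups, case, control) {
  t(apply(mat, 1, function(row) {
    a <- row[groups == case]; b <- row[groups == control]
    ht <- stats::t.test(a, b)
    c(logfc = mean(a) - mean(b), p = ht$p.value)
  }))
}

# Exhaustive hypergeometric upper-tail oracle by enumerating all
# C(N, n) draws of the DEG positions.
hyper_tail_oracle <- function(k, K, n, N) {
  draws <- utils::combn(N, n)
  in_set <- seq_len(K)  # WLOG the set occupies the first K positions
  hits <- apply(draws, 2, function(d) sum(d %in% in_set))
  mean(hits >= k)
}

# BH step-up oracle: q_i = min_{j >= i} p_(j) * m / j in sorted order.
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- rev(cummin(rev(sort(p) * m / seq_len(m))))
  q <- numeric(m)
  q[o] <- pmin(q_sorted, 1)
  q
}

# Random signed gene set over a universe prefix.
random_query <- function(n_up, n_down, universe) {
  g <- sample(universe, n_up + n_down)
  signed_gene_set(up = g[seq_len(n_up)],
                  down = g[n_up + seq_len(n_down)])
}
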