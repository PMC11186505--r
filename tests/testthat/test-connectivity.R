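test_that("overlap score counts signed concordance over the full query", {
  q <- signed_gene_set(up = c("G1", "G2"), down = c("G3", "G4"))
  sig_same <- drug_signature("s", up = q$up, down = q$down)
  expect_equal(overlap_score(q, sig_same, "mimic"), 1)
  expect_equal(overlap_score(q, sig_same, "reverse"), 0)
  sig_disjoint <- drug_signature("d", up = c("X1"), down = c("X2"))
  expect_equal(overlap_score(q, sig_disjoint, "mimic"), 0)
  # 10-gene query with exactly 3 reverse-concordant genes -> 0.3
  q10 <- signed_gene_set(up = paste0("U", 1:5), down = paste0("D", 1:5))
  sig3 <- drug_signature("r", up = c("D1", "D2"), down = c("U1", "Z9"))
  expect_equal(overlap_score(q10, sig3, "reverse"), 0.3)
  expect_error(overlap_score(signed_gene_set(), sig3, "mimic"), "empty query")
})

test_that("mode/flip duality holds on 10^4 random query/signature pairs", {
  set.seed(101)
  universe <- sprintf("g%03d", 1:60)
  ok <- vapply(seq_len(10000), function(i) {
    q <- random_query(sample(1:5, 1), sample(1:5, 1), universe)
    g <- sample(universe, 12)
    sig <- drug_signature("s", up = g[1:6], down = g[7:12])
    flipped <- drug_signature("s", up = sig$down, down = sig$up)
    identical(overlap_score(q, sig, "mimic"),
              overlap_score(q, flipped, "reverse"))
  }, logical(1))
  expect_true(all(ok))
})

test_that("scores ignore signature genes outside the query", {
  q <- signed_gene_set(up = c("A", "B"), down = c("C"))
  s1 <- drug_signature("s", up = c("A"), down = c("C"))
  s2 <- drug_signature("s", up = c("A", "Z1", "Z2"), down = c("C", "Z3"))
  for (mode in c("mimic", "reverse")) {
    expect_equal(overlap_score(q, s1, mode), overlap_score(q, s2, mode))
  }
})

test_that("cosine score matches hand arithmetic and its trivial poles", {
  q <- signed_gene_set(up = c("A", "B", "C"), down = c("D", "E"))
  enc <- c(A = 1, B = 1, C = 1, D = -1, E = -1)
  expect_equal(cosine_score(q, drug_signature("s", up = names(enc)[1:3],
                                              down = names(enc)[4:5],
                                              vector = enc)), 1)
  expect_equal(cosine_score(q, drug_signature("s", up = names(enc)[4:5],
                                              down = names(enc)[1:3],
                                              vector = -enc)), -1)
  v <- c(A = 2, B = -1, C = 0.5, D = -3, E = 1)
  sig <- drug_signature("s", up = c("A", "C", "E"), down = c("B", "D"),
                        vector = v)
  manual <- sum(c(1, 1, 1, -1, -1) * v) / (sqrt(5) * sqrt(sum(v^2)))
  expect_equal(cosine_score(q, sig), manual, tolerance = 1e-12)
})

test_that("query_compendium returns min(top_k, n) ranked results", {
  comp <- toy_compendium()
  q <- signed_gene_set(up = c("G1", "G2"), down = c("G3", "G4"))
  res <- query_compendium("q1", q, comp, "mimic", top_k = 50)
  expect_equal(nrow(res), 3)
  expect_equal(res$rank, 1:3)
  expect_equal(res$drug_id[1], "A")
  expect_true(all(diff(res$score) <= 0))
  one <- query_compendium("q1", q, comp["B"], "reverse", top_k = 50)
  expect_equal(nrow(one), 1)
  expect_equal(one$rank, 1L)
  expect_error(query_compendium("q1", q, comp, top_k = 0), "top_k")
  expect_error(query_compendium("q1", q, list(), "mimic"), "empty compendium")
})

test_that("ranking is invariant to compendium order (deterministic ties)", {
  set.seed(33)
  universe <- sprintf("g%02d", 1:30)
  q <- random_query(4, 4, universe)
  comp <- lapply(1:20, function(i) {
    g <- sample(universe, 8)
    drug_signature(sprintf("D%02d", i), up = g[1:4], down = g[5:8])
  })
  names(comp) <- vapply(comp, `[[`, character(1), "drug_id")
  r1 <- query_compendium("q", q, comp, "mimic", top_k = 10)
  for (i in 1:5) {
    r2 <- query_compendium("q", q, comp[sample(names(comp))], "mimic",
                           top_k = 10)
    expect_identical(r1, r2)
  }
})

test_that("planted reverser drugs dominate a reverse-mode query", {
  q <- signed_gene_set(up = sprintf("U%02d", 1:15),
                       down = sprintf("D%02d", 1:15))
  uni <- c(q$up, q$down, sprintf("B%04d", 1:2000))
  sim <- simulate_compendium(n_drugs = 200, sig_size = 100, universe = uni,
                             query = q, n_reversers = 5, concordance = 0.8,
                             background_concordance = 0.1, seed = 7)
  res <- query_compendium("q", q, sim$compendium, "reverse", top_k = 200)
  top10 <- res$drug_id[1:10]
  expect_true(all(sim$truth$planted_reverser_drugs %in% top10))
})

test_that("score filtering is strict and preserves pre-filter ranks", {
  res <- data.frame(query_id = "q", drug_id = paste0("d", 1:4),
                    mode = "mimic", score = c(0.5, 0.1, 0.12, 0),
                    rank = 1:4, stringsAsFactors = FALSE)
  kept <- filter_by_score(res, 0.1)
  expect_setequal(kept$drug_id, c("d1", "d3"))   # exactly 0.1 removed
  expect_equal(kept$rank, c(1L, 3L))
  expect_equal(nrow(filter_by_score(res, -1)), 4)
  # brute force: retained iff score > cutoff
  for (cut in c(0, 0.05, 0.2)) {
    expect_setequal(filter_by_score(res, cut)$drug_id,
                    res$drug_id[res$score > cut])
  }
})
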