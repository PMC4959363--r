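# Markov clustering, cluster refinement, scoring, and the exhaustive
# baseline.

test_that("clusters never span exactly block-diagonal components", {
  set.seed(71)
  for (rep in 1:5) {
    S <- matrix(0, 9, 9)
    g1 <- 1:4; g2 <- 5:9
    S[g1, g1] <- runif(16, 1, 5); S[g2, g2] <- runif(25, 1, 5)
    S <- (S + t(S)) / 2; diag(S) <- 0
    cs <- mcl_cluster(S)
    for (cl in cs$clusters)
      expect_true(all(cl %in% g1) || all(cl %in% g2))
  }
})

test_that("two connected nodes form one cluster", {
  S <- matrix(c(0, 2, 2, 0), 2, 2)
  cs <- mcl_cluster(S)
  expect_identical(cs$clusters, list(c(1L, 2L)))
  expect_true(cs$validity[1])
})

test_that("planted two-group structure is recovered and matches a reference MCL", {
  set.seed(81)
  g1 <- 1:6; g2 <- 7:12
  S <- matrix(1, 12, 12)
  S[g1, g1] <- 10; S[g2, g2] <- 10
  diag(S) <- 0
  cs <- mcl_cluster(S)
  expect_length(cs$clusters, 2)
  expect_identical(cs$clusters[[1]], g1)
  expect_identical(cs$clusters[[2]], g2)
  ref <- naive_mcl_partition(S)
  ref <- ref[order(vapply(ref, min, integer(1)))]
  expect_identical(lapply(cs$clusters, as.integer), lapply(ref, as.integer))
})

test_that("non-finite similarities are rejected", {
  S <- matrix(c(0, Inf, Inf, 0), 2, 2)
  expect_error(mcl_cluster(S), "finite")
})

test_that("refinement handles its three cases and invalid singletons", {
  set.seed(91)
  data <- make_seq_set(6, 25)
  mat <- similarity_matrix(data, pms_params(5, 1, 4))
  # case (a): |C| = k
  rs <- refine_cluster(c(2, 4, 5), 3, mat)
  expect_identical(rs$indices, c(2L, 4L, 5L))
  expect_identical(rs$provenance$case, "a")
  # singleton: invalid
  expect_null(refine_cluster(4, 3, mat))
  # case (b): |C| > k, greedy from the best pair
  rs_b <- refine_cluster(1:5, 3, mat)
  expect_identical(rs_b$provenance$case, "b")
  expect_identical(rs_b$indices, naive_refine_b(1:5, 3, mat$sim))
  # case (c): |C| < k, grown over the whole graph
  rs_c <- refine_cluster(c(1, 2), 4, mat)
  expect_identical(rs_c$provenance$case, "c")
  expect_identical(rs_c$indices, naive_refine_c(c(1L, 2L), 4, mat$sim))
  expect_error(refine_cluster(1:3, 1, mat), "k")
  expect_error(refine_cluster(1:3, 6, mat), "k")
})

test_that("case (b) trace matches a hand-evaluated 5-node example", {
  S <- matrix(0, 5, 5)
  S[1, 2] <- 9; S[1, 3] <- 1; S[1, 4] <- 2; S[1, 5] <- 1
  S[2, 3] <- 1; S[2, 4] <- 3; S[2, 5] <- 1
  S[3, 4] <- 1; S[3, 5] <- 8; S[4, 5] <- 1
  S <- S + t(S)
  # initial pair: (1,2) with sim 9; sums to {1,2}: node3 = 2, node4 = 5,
  # node5 = 2 -> add 4
  rs <- refine_cluster(1:5, 3, S)
  expect_identical(rs$indices, c(1L, 2L, 4L))
})

test_that("greedy refinement matches the naive recurrences on random matrices", {
  set.seed(101)
  for (case in 1:100) {
    t <- resample(6:10)
    S <- rand_sim_matrix(t)
    k <- resample(2:(t - 1))
    cl_b <- sort(sample(t, resample((k + 1):t)))
    expect_identical(refine_cluster(cl_b, k, S)$indices,
                     naive_refine_b(cl_b, k, S))
    if (k > 2) {
      cl_c <- sort(sample(t, resample(2:(k - 1))))
      expect_identical(refine_cluster(cl_c, k, S)$indices,
                       naive_refine_c(cl_c, k, S))
    }
  }
})

test_that("score_set sums unordered-pair similarities", {
  set.seed(111)
  S <- rand_sim_matrix(6)
  expect_equal(score_set(c(2, 5), S), S[2, 5])
  expect_equal(score_set(c(1, 3, 4, 6), S),
               S[1, 3] + S[1, 4] + S[1, 6] + S[3, 4] + S[3, 6] + S[4, 6])
  # adding a node never decreases the score
  expect_gte(score_set(c(1, 3, 4, 6), S), score_set(c(1, 3, 4), S))
  expect_error(score_set(5, S), "at least 2")
})

test_that("exhaustive selection matches an independent enumeration", {
  set.seed(121)
  data <- make_seq_set(8, 30)
  mat <- similarity_matrix(data, pms_params(7, 2, 4))
  ex <- exhaustive_select(mat, 3)
  ref <- naive_best_subset(mat, 3)
  expect_identical(ex$indices, as.integer(ref$indices))
  expect_equal(ex$total_count, ref$total)
  # t = k + 1: best of t drop-one subsets
  ex2 <- exhaustive_select(mat, 7)
  totals <- vapply(1:8, function(i) total_candidate_count(setdiff(1:8, i), mat),
                   numeric(1))
  expect_equal(ex2$total_count, min(totals))
  # guarded edge k = t
  expect_identical(exhaustive_select(mat, 8)$indices, 1:8)
})

test_that("select_references returns k distinct indices deterministically", {
  set.seed(131)
  data <- make_seq_set(10, 40)
  mat <- similarity_matrix(data, pms_params(7, 2, 4))
  s1 <- select_references(mat, 4)
  s2 <- select_references(mat, 4)
  expect_length(s1$indices, 4)
  expect_identical(s1$indices, unique(s1$indices))
  expect_identical(s1$indices, s2$indices)
  expect_equal(s1$score, score_set(s1$indices, mat))
  expect_error(select_references(mat, 1), "k")
  expect_warning(sk <- select_references(mat, 10), "k = t")
  expect_identical(sk$indices, 1:10)
})

test_that("sequences sharing an identical implant are rarely selected together", {
  hits <- 0L
  for (seed in 1:50) {
    set.seed(1000 + seed)
    seqs <- vapply(1:7, function(i) rand_string(40, ALPH_DNA), character(1))
    motif <- rand_string(7, ALPH_DNA)
    for (i in 1:2) {
      pos <- sample(40 - 7 + 1, 1)
      substr(seqs[i], pos, pos + 6) <- motif
    }
    data <- sequence_set(seqs, alphabet = "dna")
    mat <- similarity_matrix(data, pms_params(7, 2, 4))
    sel <- select_references(mat, 3)
    if (all(c(1L, 2L) %in% sel$indices)) hits <- hits + 1L
  }
  expect_lt(hits, 10)  # < 20 % of 50 seeds
})
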