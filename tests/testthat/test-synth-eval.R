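# Planted-dataset generator, evaluation ratio, and brute-force oracles.

hamming_str <- function(a, b) {
  sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
}

test_that("implants obey the requested mismatch law", {
  ds0 <- generate_planted_dataset(t = 10, n = 60, l = 8, d = 0, q = 6, seed = 2)
  expect_identical(nrow(ds0$implants), 6L)
  expect_true(all(ds0$implants$instance == ds0$motif))
  expect_true(all(ds0$implants$distance == 0L))

  dse <- generate_planted_dataset(t = 10, n = 60, l = 8, d = 3, q = 10,
                                  seed = 3, mode = "exact_d")
  expect_true(all(dse$implants$distance == 3L))
  expect_true(all(vapply(seq_len(10), function(r)
    hamming_str(dse$implants$instance[r], dse$motif), integer(1)) == 3L))

  dsa <- generate_planted_dataset(t = 10, n = 60, l = 8, d = 3, q = 10, seed = 4)
  expect_true(all(dsa$implants$distance <= 3L))
})

test_that("recorded implants match the sequences that carry them", {
  for (mode in c("at_most_d", "exact_d")) {
    ds <- generate_planted_dataset(t = 12, n = 80, l = 9, d = 2, q = 8,
                                   seed = 5, mode = mode)
    im <- ds$implants
    for (r in seq_len(nrow(im))) {
      window <- substr(ds$data$sequences[im$seq_index[r]],
                       im$start[r], im$start[r] + 8L)
      expect_identical(window, im$instance[r])
      expect_lte(hamming_str(window, ds$motif), 2L)
    }
    # every chosen sequence has at least one window within d of the motif
    for (i in unique(im$seq_index)) {
      s <- ds$data$sequences[i]
      dists <- vapply(seq_len(80 - 9 + 1), function(u)
        hamming_str(substr(s, u, u + 8L), ds$motif), integer(1))
      expect_lte(min(dists), 2L)
    }
  }
})

test_that("generation is reproducible from the seed alone", {
  d1 <- generate_planted_dataset(t = 6, n = 40, l = 7, d = 2, seed = 99)
  d2 <- generate_planted_dataset(t = 6, n = 40, l = 7, d = 2, seed = 99)
  d3 <- generate_planted_dataset(t = 6, n = 40, l = 7, d = 2, seed = 100)
  expect_identical(d1$data$sequences, d2$data$sequences)
  expect_identical(d1$implants, d2$implants)
  expect_false(identical(d1$data$sequences, d3$data$sequences))
  # the generator does not disturb the caller's RNG stream
  set.seed(1); before <- runif(1)
  set.seed(1); invisible(generate_planted_dataset(6, 40, 7, 2, seed = 1))
  expect_identical(runif(1), before)
})

test_that("generator validates its parameters", {
  expect_error(generate_planted_dataset(5, 40, 9, 9, seed = 1), "d < l")
  expect_error(generate_planted_dataset(5, 9, 9, 2, seed = 1), "l < n")
  expect_error(generate_planted_dataset(5, 40, 9, 2, q = 6, seed = 1), "q")
})

# first three sequences nearly identical, rest independent
rand_string_fixture <- function() {
  set.seed(19)
  s1 <- rand_string(50, ALPH_DNA)
  mut <- function(s) {
    p <- sample(50, 1)
    substr(s, p, p) <- sample(setdiff(ALPH_DNA, substr(s, p, p)), 1)
    s
  }
  seqs <- c(s1, mut(s1), mut(s1),
            vapply(1:5, function(i) rand_string(50, ALPH_DNA), character(1)))
  data <- sequence_set(seqs, alphabet = "dna")
  mat <- similarity_matrix(data, pms_params(9, 2, 4))
  list(data = data, mat = mat, good = exhaustive_select(mat, 3)$indices)
}

test_that("evaluate_ratio compares first-k against the selection", {
  ds <- generate_planted_dataset(t = 8, n = 50, l = 9, d = 2, seed = 17)
  params <- pms_params(9, 2, 4)
  mat <- similarity_matrix(ds$data, params)
  # selected = first k: ratio exactly 1
  ev <- evaluate_ratio(ds$data, 1:3, 3, params, matrix = mat)
  expect_identical(ev$ratio, 1)
  expect_identical(ev$n_original, ev$n_improved)
  expect_error(evaluate_ratio(ds$data, 1:3, 4, params, matrix = mat),
               "k members")
  # a deliberately similar first-k block is avoidable: ratio > 1
  base <- rand_string_fixture()
  ev2 <- evaluate_ratio(base$data, base$good, 3, params, matrix = base$mat)
  expect_gt(ev2$ratio, 1)
})

test_that("brute-force neighborhood counts close the loop with the formula", {
  # h = 1: the d-ball volume
  expect_identical(brute_force_common_neighbors("ACGTA", 2),
                   sum(choose(5, 0:2) * 3^(0:2)))
  # h = 2 at every distance for (l = 5, d = 2)
  p <- pms_params(5, 2, 4)
  x <- "AAAAA"
  mates <- c("AAAAA", "CAAAA", "CCAAA", "CCCAA", "CCCCA", "CCCCC")
  for (dist in 0:5) {
    expect_identical(brute_force_common_neighbors(c(x, mates[dist + 1]), 2),
                     common_candidate_count(p, dist))
  }
  # return_set agrees with the count and contains only true neighbors
  res <- brute_force_common_neighbors(c("AAAAA", "CCAAA"), 2,
                                      return_set = TRUE)
  expect_length(res$set, res$count)
  expect_true(all(vapply(res$set, function(y)
    hamming_str(y, "AAAAA") <= 2 && hamming_str(y, "CCAAA") <= 2,
    logical(1))))
  expect_error(brute_force_common_neighbors(rand_string(20, ALPH_PROT), 3,
                                            alphabet = "protein"), "1e7")
})

test_that("joint and pairwise-sum counts move together for l-mer triples", {
  # quick qualitative check (the full sweep runs in the acceptance suite)
  p <- pms_params(7, 2, 4)
  x1 <- "AAAAAAA"
  x2 <- "CCAAAAA"                      # d_H(x1, x2) = 2d - 2 = 2
  n1 <- c(); n2 <- c()
  for (j in 0:3) {
    x3 <- paste0("AA", strrep("G", j), strrep("A", 5 - j))
    n1 <- c(n1, brute_force_common_neighbors(c(x1, x2, x3), 2))
    n2 <- c(n2, common_candidate_count(p, 2) +
              common_candidate_count(p, j) +
              common_candidate_count(p, hamming_str(x2, x3)))
  }
  expect_true(all(diff(n1) <= 0))
  expect_true(all(diff(n2) <= 0))
})
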