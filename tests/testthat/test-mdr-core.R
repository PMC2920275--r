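test_that("cell index is a base-3 encoding with the first locus most significant", {
  expect_identical(mdr_cell_index(c(0)), 0L)
  expect_identical(mdr_cell_index(c(2, 1)), 7L)
  expect_identical(mdr_cell_index(c(1, 1, 1)), 13L)
  expect_error(mdr_cell_index(c(0, 3)), "0, 1 or 2")

  for (k in 1:4) {
    grid <- as.matrix(expand.grid(rep(list(0:2), k)))[, k:1, drop = FALSE]
    idx <- mdr_cell_index(grid)
    expect_identical(sort(idx), 0:(3^k - 1L))          # bijective onto [0, 3^k)
    decoded <- mdr_cell_genotypes(idx, k)
    expect_identical(unname(decoded), unname(grid))    # decode inverts encode
  }
})

test_that("high/low-risk labels follow the case:control ratio threshold conventions", {
  # balanced data: genotype 0 has 3 cases/1 control (ratio > 1 -> high),
  # genotype 1 has 1/3 (low), genotype 2 has 2/2 (equality -> low)
  d <- tibble::tibble(
    L1 = c(rep(0, 4), rep(1, 4), rep(2, 4)),
    Class = c(1, 1, 1, 0, 1, 0, 0, 0, 1, 1, 0, 0)
  )
  m <- mdr_fit(d, "L1")
  expect_equal(m$threshold, 1)
  expect_identical(m$labels, c(TRUE, FALSE, FALSE))

  # cases with zero controls -> high (infinite ratio); empty cell -> low
  d2 <- tibble::tibble(L1 = c(0, 0, 1, 1), Class = c(1, 0, 1, 1))
  m2 <- mdr_fit(d2, "L1")                # threshold 3/1
  expect_identical(m2$labels, c(FALSE, TRUE, FALSE))
})

test_that("an infinite-data XOR draw labels exactly the four penetrant cells high-risk", {
  pm <- penetrance_xor()
  d <- simulate_mdr_data(pm, n_cases = 100000, n_controls = 100000,
                         n_loci = 2, seed = 11)
  m <- mdr_fit(d, c("L1", "L2"))
  cells <- mdr_cell_genotypes(0:8, 2)
  penetrant <- (cells[, 1] + cells[, 2]) %% 2 == 1
  expect_identical(m$labels, penetrant)
})

test_that("balanced accuracy matches the closed form and its bounds", {
  # constructed evaluation: n1 = 10 with n11 = 8, n0 = 10 with n00 = 6
  model <- mdrsplit:::new_mdr_model(
    loci = "L1", labels = c(TRUE, FALSE, FALSE),
    case_counts = c(8, 2, 0), control_counts = c(4, 6, 0), n1 = 10, n0 = 10)
  d <- tibble::tibble(
    L1 = c(rep(0, 12), rep(1, 8)),
    Class = c(rep(1, 8), rep(0, 4), rep(1, 2), rep(0, 6))
  )
  acc <- mdr_accuracy(model, d)
  expect_equal(acc$n11, 8)
  expect_equal(acc$n00, 6)
  expect_equal(acc$balanced_accuracy, 0.70)
  expect_equal(acc$balanced_accuracy + acc$balanced_error, 1)

  # a perfect classifier reaches BA = 1; all-high labels on balanced data
  # give sensitivity 1, specificity 0, BA = 0.5
  dp <- perfect_locus_data()
  mp <- mdr_fit(dp, "L5")
  expect_equal(mdr_accuracy(mp, dp)$balanced_accuracy, 1)
  all_high <- mdrsplit:::new_mdr_model(
    loci = "L1", labels = rep(TRUE, 3),
    case_counts = rep(0, 3), control_counts = rep(0, 3),
    n1 = sum(d$Class), n0 = sum(1 - d$Class))
  expect_equal(mdr_accuracy(all_high, d)$balanced_accuracy, 0.5)
})

test_that("exhaustive search enumerates all combinations and finds perfect predictors", {
  d <- noise_data(n_cases = 30, n_controls = 30, n_loci = 25, seed = 5)
  ranked <- mdr_search(d, k = 2)
  expect_equal(nrow(ranked), choose(25, 2))   # C(25,2) = 300 candidates

  dp <- perfect_locus_data(locus = 5)
  best <- mdr_best(dp, k = 1)
  expect_identical(best$loci, "L5")
  expect_equal(mdr_accuracy(best, dp)$balanced_accuracy, 1)

  expect_error(mdr_search(d, k = 26), "exceeds")
})

test_that("balanced-accuracy ties break to the lexicographically smallest locus tuple", {
  d <- perfect_locus_data(locus = 5, seed = 2)
  d$L3 <- d$L5   # duplicate the perfect predictor at an earlier column
  expect_identical(mdr_best(d, k = 1)$loci, "L3")
})

test_that("exhaustive search agrees with the brute-force oracle on small data", {
  for (seed in 1:5) {
    n_loci <- sample(4:6, 1)
    d <- noise_data(n_cases = 25, n_controls = 30, n_loci = n_loci,
                    seed = 100 + seed)
    for (k in 1:2) {
      got <- mdr_best(d, k = k)
      ba <- mdr_accuracy(got, d)$balanced_accuracy
      want <- oracle_best_model(d, k)
      expect_identical(got$loci, want$loci)
      expect_equal(ba, want$ba)
    }
  }
})

test_that("MDR labelling maximizes fitting balanced accuracy over all labelings", {
  d <- noise_data(n_cases = 20, n_controls = 20, n_loci = 3, seed = 7)
  m <- mdr_fit(d, "L1")
  mdr_ba <- mdr_accuracy(m, d)$balanced_accuracy
  # enumerate all 2^3 high/low labelings at k = 1
  for (bits in 0:7) {
    labels <- as.logical(bitwAnd(bits, c(4L, 2L, 1L)) > 0)
    alt <- mdrsplit:::new_mdr_model("L1", labels, m$case_counts,
                                    m$control_counts, m$n1, m$n0)
    expect_lte(mdr_accuracy(alt, d)$balanced_accuracy, mdr_ba)
  }
})

test_that("swapping case/control labels and inverting cell labels preserves BA", {
  d <- noise_data(n_cases = 40, n_controls = 35, n_loci = 4, seed = 9)
  m <- mdr_fit(d, c("L2", "L4"))
  ba <- mdr_accuracy(m, d)$balanced_accuracy
  d_swap <- d
  d_swap$Class <- 1L - d$Class
  m_inv <- mdrsplit:::new_mdr_model(m$loci, !m$labels, m$control_counts,
                                    m$case_counts, m$n0, m$n1)
  expect_equal(mdr_accuracy(m_inv, d_swap)$balanced_accuracy, ba)
})

test_that("model ranking honours x_top and stays deterministic on noise", {
  d <- noise_data(n_cases = 40, n_controls = 40, n_loci = 25, seed = 13)
  full <- mdr_search(d, k = 2)                      # x >= C(K,k): full list
  expect_equal(nrow(full), choose(25, 2))
  top25 <- mdr_search(d, k = 2, x_top = 25)
  expect_identical(nrow(top25), 25L)                # x = number of loci
  expect_identical(top25$loci, full$loci[1:25])
  expect_true(all(diff(full$ba) <= 0))              # descending BA
  again <- mdr_search(d, k = 2, x_top = 25)
  expect_identical(top25, again)                    # deterministic ranking
  expect_true(all(abs(top25$ba - 0.5) < 0.35))      # noise hovers near 0.5
})

test_that("balanced accuracy stays within [0, 1] with BA + BE = 1 on random data", {
  for (seed in 1:5) {
    d <- noise_data(n_cases = 15 + seed, n_controls = 20, n_loci = 5,
                    seed = 200 + seed)
    acc <- mdr_accuracy(mdr_best(d, k = 2), d)
    expect_gte(acc$balanced_accuracy, 0)
    expect_lte(acc$balanced_accuracy, 1)
    expect_equal(acc$balanced_accuracy + acc$balanced_error, 1)
  }
})
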