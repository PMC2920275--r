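test_that("stratified splits apportion classes by largest remainder", {
  d <- noise_data(n_cases = 500, n_controls = 500, n_loci = 2, seed = 1)
  s <- split_stratified(d, c(1, 1, 1), seed = 2)
  case_sizes <- vapply(s, function(i) sum(d$Class[i] == 1), 0L)
  expect_identical(unname(case_sizes), c(167L, 167L, 166L))

  s221 <- split_stratified(d, c(2, 2, 1), seed = 2)
  expect_identical(unname(vapply(s221, function(i) sum(d$Class[i] == 1), 0L)),
                   c(200L, 200L, 100L))
  expect_identical(unname(vapply(s221, function(i) sum(d$Class[i] == 0), 0L)),
                   c(200L, 200L, 100L))

  s2 <- split_stratified(d, c(1, 1), seed = 2)   # two-way split
  expect_identical(unname(vapply(s2, length, 0L)), c(500L, 500L))
  expect_identical(unname(vapply(s2, function(i) sum(d$Class[i] == 1), 0L)),
                   c(250L, 250L))

  # disjoint and exhaustive
  expect_identical(sort(unlist(s, use.names = FALSE)), seq_len(nrow(d)))
  expect_identical(s, split_stratified(d, c(1, 1, 1), seed = 2))

  tiny <- noise_data(n_cases = 2, n_controls = 20, n_loci = 2, seed = 3)
  expect_error(split_stratified(tiny, c(1, 1, 1), seed = 1), "at least one")
})

test_that("a perfectly predictive pair survives all three stages with validation BA 1", {
  d <- perfect_pair_data(n = 300, n_loci = 6, seed = 6)
  fit <- mdr_3ws(d, k = 1:3, seed = 7)
  expect_identical(fit$final$loci[[1]], c("L1", "L2"))
  expect_equal(fit$final$ba, 1)
  expect_identical(fit$final$k, 2L)    # BA tie with k = 3 resolves to smaller k
})

test_that("stage fit counts follow the 3WS work accounting", {
  d <- noise_data(n_cases = 60, n_controls = 60, n_loci = 25, seed = 8)
  fit <- mdr_3ws(d, k = 1:3, x_top = 25, seed = 9)
  expect_equal(fit$n_fits, choose(25, 1) + choose(25, 2) + choose(25, 3))
  expect_identical(fit$n_carry, 3L * 25L)    # min(x, C(K,k)) per size
  expect_identical(fit$n_valid, 3L)
  # training ranks retain at most x models per size
  expect_true(all(table(fit$training$k) <= 25))
  # x larger than the candidate pool keeps the whole pool
  fit2 <- mdr_3ws(d, k = 1, x_top = 100, seed = 9)
  expect_identical(fit2$n_carry, 25L)
})

test_that("final selection maximizes validation BA with parsimony tie-breaks", {
  # per-size validation accuracies shaped like a candidate-gene 3WS run:
  # the four-locus model carries the highest validation accuracy
  tab <- tibble::tibble(
    k = 1:4,
    loci = list("IL2RB_6844", c("CD132_9823", "IL2RB_6844"),
                c("CD132_9823", "IL15RA_2990", "IL2RB_6844"),
                c("CD132_9823", "IL15RA_2990", "IL15_87710", "IL2RB_6844")),
    ba = c(0.5645, 0.5701, 0.5865, 0.6260)
  )
  final <- select_3ws_final(tab)
  expect_identical(final$k, 4L)
  expect_equal(final$ba, 0.6260)

  tie <- tibble::tibble(k = 2:3, loci = list(c("L1", "L2"), c("L1", "L2", "L3")),
                        ba = c(0.6, 0.6))
  expect_identical(select_3ws_final(tie)$k, 2L)
  expect_error(select_3ws_final(tie[0, ]), "no stage results")
})

test_that("three-way split runs are deterministic and the 2WS variant stops at testing", {
  d <- simulate_mdr_data(penetrance_zz(), 150, 150, 8, seed = 31)
  a <- mdr_3ws(d, k = 1:2, seed = 41)
  b <- mdr_3ws(d, k = 1:2, seed = 41)
  expect_identical(a$final, b$final)
  expect_identical(a$validation, b$validation)

  two <- mdr_3ws(d, k = 1:2, seed = 41, mode = "2ws")
  expect_null(two$validation)
  expect_identical(two$n_valid, 0L)
  expect_identical(length(two$split), 2L)
  # final comes from the testing stage
  expect_true(two$final$ba %in% two$testing$ba)

  off <- mdr_3ws(d, k = 1:2, seed = 41, refit = FALSE)
  expect_identical(off$final, mdr_3ws(d, k = 1:2, seed = 41, refit = FALSE)$final)
})

test_that("3WS selects larger models than CV-5 on matched epistatic replicates", {
  pm <- penetrance_xor()
  common <- list(n_datasets = 50, k = 1:3, n_cases = 200, n_controls = 200,
                 n_loci = 10, seed = 77)
  p3 <- do.call(mdr_power, c(list(pm, method = "3ws"), common))
  p5 <- do.call(mdr_power, c(list(pm, method = "cv", m = 5), common))
  expect_gt(glance(p3)$mean_size, glance(p5)$mean_size)
})
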