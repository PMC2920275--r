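test_that("the XOR and ZZ penetrance tables are exact", {
  xor <- penetrance_xor()
  # 0.1 wherever the total minor-allele count is odd, 0 elsewhere
  expect_equal(xor$table[mdr_cell_index(c(0, 1)) + 1], 0.1)  # AABb
  expect_equal(xor$table[mdr_cell_index(c(0, 0)) + 1], 0.0)  # AABB
  cells <- mdr_cell_genotypes(0:8, 2)
  expect_equal(xor$table, ifelse((cells[, 1] + cells[, 2]) %% 2 == 1, 0.1, 0))

  zz <- penetrance_zz()
  expect_equal(zz$table[mdr_cell_index(c(0, 2)) + 1], 0.1)   # AAbb
  expect_equal(zz$table[mdr_cell_index(c(2, 0)) + 1], 0.1)   # aaBB
  expect_equal(zz$table[mdr_cell_index(c(1, 1)) + 1], 0.05)  # AaBb
  expect_equal(sum(zz$table), 0.25)                          # nothing else
})

test_that("prevalence and heritability match closed forms and the enumeration oracle", {
  xor <- penetrance_xor()
  zz <- penetrance_zz()
  expect_equal(prevalence(xor), 0.05)
  expect_equal(prevalence(zz), 0.025)
  expect_equal(heritability(xor), 0.0025 / (0.05 * 0.95))
  expect_equal(heritability(zz), 0.00125 / (0.025 * 0.975))

  # constant penetrance has no genotypic variance
  flat <- penetrance_model(rep(0.3, 9), 0.5)
  expect_equal(heritability(flat), 0)
  expect_equal(prevalence(penetrance_model(rep(0, 3), 0.5)), 0)
  expect_error(heritability(penetrance_model(rep(0, 3), 0.5)), "degenerate")

  # random tables, d = 1..3, against nested-loop enumeration
  withr::with_seed(99, {
    for (d in 1:3) {
      tab <- runif(3^d, 0, 0.4)
      mafs <- runif(d, 0.1, 0.5)
      m <- penetrance_model(tab, mafs)
      want <- oracle_prevalence_h2(tab, mafs)
      expect_equal(prevalence(m), want$prevalence)
      expect_equal(heritability(m), want$h2)
    }
  })
})

test_that("the single-locus penetrance solver round-trips heritability and effect ratio", {
  dom <- solve_penetrance("dominant", maf = 0.5, h2 = 0.05, or = 2.5)
  expect_equal(dom$table[2], dom$table[3])
  expect_gt(dom$table[2], dom$table[1])
  expect_equal(heritability(dom), 0.05, tolerance = 1e-8)
  expect_equal(dom$table[2] / dom$table[1], 2.5, tolerance = 1e-8)

  rec <- solve_penetrance("recessive", maf = 0.25, h2 = 0.01, or = 1.5)
  expect_equal(rec$table[1], rec$table[2])
  expect_gt(rec$table[3], rec$table[2])
  expect_equal(heritability(rec), 0.01, tolerance = 1e-8)

  add <- solve_penetrance("additive", maf = 0.5, h2 = 0.05, or = 2.5)
  expect_equal(add$table[2] / add$table[1], 2.5, tolerance = 1e-8)
  expect_equal(add$table[3] / add$table[2], 2.5, tolerance = 1e-8)

  expect_error(solve_penetrance("dominant", maf = 0.5, h2 = 0.05, or = 1),
               "exceed 1")
  expect_error(solve_penetrance("recessive", maf = 0.1, h2 = 0.5, or = 1.1),
               "attains")
})

test_that("the simulator fills quotas exactly with valid codes, reproducibly", {
  pm <- penetrance_xor()
  d <- simulate_mdr_data(pm, n_cases = 500, n_controls = 500, n_loci = 25,
                         seed = 42)
  expect_identical(dim(d), c(1000L, 26L))
  expect_identical(sum(d$Class == 1), 500L)
  expect_identical(sum(d$Class == 0), 500L)
  geno <- as.matrix(d[paste0("L", 1:25)])
  expect_true(all(geno %in% 0:2))
  expect_identical(attr(d, "disease_loci"), c("L1", "L2"))

  # byte-identical reproduction under the same seed
  expect_identical(d, simulate_mdr_data(pm, 500, 500, 25, seed = 42))

  # nuisance loci follow HWE at MAF 0.5
  freqs <- table(factor(geno[, 25], levels = 0:2)) / 1000
  expect_equal(as.numeric(freqs), c(0.25, 0.5, 0.25), tolerance = 0.07)

  # cases can only arise in penetrant cells under XOR
  cases <- d[d$Class == 1, ]
  expect_true(all((cases$L1 + cases$L2) %% 2 == 1))

  expect_error(simulate_mdr_data(penetrance_model(rep(0, 9), 0.5), 10, 10, 5),
               "unreachable")
})

test_that("per-cell case:control composition converges to the penetrance odds", {
  pm <- penetrance_xor()
  d <- simulate_mdr_data(pm, n_cases = 100000, n_controls = 100000,
                         n_loci = 2, seed = 314)
  K <- prevalence(pm)
  idx <- mdr_cell_index(as.matrix(d[c("L1", "L2")]))
  for (cell in 0:8) {
    p <- pm$table[cell + 1]
    in_cell <- idx == cell
    n_cell <- sum(in_cell)
    frac_case <- sum(d$Class[in_cell] == 1) / n_cell
    want <- p * (1 - K) / (p * (1 - K) + (1 - p) * K)
    tol <- 3 * sqrt(max(want * (1 - want), 1e-6) / n_cell)
    expect_lt(abs(frac_case - want), max(tol, 1e-12) + 1e-9)
  }
})

test_that("nuisance loci are unassociated with the phenotype", {
  pvals <- vapply(1:10, function(s) {
    d <- simulate_mdr_data(penetrance_xor(), 200, 200, 3, seed = 600 + s)
    suppressWarnings(chisq.test(table(d$L3, d$Class))$p.value)
  }, 0)
  expect_gte(mean(pvals > 0.05), 0.7)
  expect_gt(mean(pvals), 0.2)
})
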