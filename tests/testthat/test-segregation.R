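test_that("expected F2 ratios come from exhaustive genotype enumeration", {
  # single locus, every dominance setting, against the 4-gamete Punnett oracle
  punnett <- function(dominant) {
    gametes <- expand.grid(g1 = c("A", "B"), g2 = c("A", "B"),
                           stringsAsFactors = FALSE)
    expressed <- with(gametes, if (dominant) g1 == "B" | g2 == "B"
                      else g1 == "B" & g2 == "B")
    mean(expressed)
  }
  for (dom in c(TRUE, FALSE)) {
    r <- expected_f2_ratio(segregation_model(1, dominant = dom))
    expect_equal(sum(r), 1)
    expect_equal(unname(r[ifelse(dom, "M", "W")]),
                 ifelse(dom, punnett(TRUE), 1 - punnett(FALSE)))
  }
  expect_equal(unname(expected_f2_ratio(segregation_model(1))), c(0.75, 0.25))

  # recessive epistatic masking of a dominant locus: 9:7
  m97 <- segregation_model(2, phenotypic = c(TRUE, FALSE),
                           epistasis = list(masker = 2, genotype = "A",
                                            masked = 1))
  expect_equal(unname(expected_f2_ratio(m97)), c(9, 7) / 16)

  # two independent dominant loci: 9:3:3:1
  r2 <- expected_f2_ratio(segregation_model(2))
  expect_equal(unname(r2), c(9, 3, 3, 1) / 16)

  expect_error(segregation_model(3), "1- or 2-locus")
  expect_error(segregation_model(1, epistasis = list(masker = 1,
                                                     genotype = "A",
                                                     masked = 1)),
               "2 loci")
})

test_that("goodness of fit reproduces hand-computed chi-square values", {
  g0 <- goodness_of_fit(c(75, 25), c(3, 1) / 4)
  expect_equal(g0$statistic, 0)
  expect_equal(g0$p.value, 1)
  g1 <- goodness_of_fit(c(90, 10), c(3, 1) / 4)
  expect_equal(g1$statistic, 12)  # 225/75 + 225/25
  expect_equal(g1$p.value, pchisq(12, 1, lower.tail = FALSE))
  expect_lt(abs(g1$p.value - 5.3e-4), 5e-5)
  expect_error(goodness_of_fit(c(1, 1), c(0.9, 0.2)), "sum to 1")
  expect_error(goodness_of_fit(integer(0), numeric(0)), "at least one")
})

test_that("exact multinomial and chi-square p-values agree asymptotically", {
  # small-count path: exact test auto-selected when expected counts < 5
  small <- goodness_of_fit(c(10, 0), c(0.75, 0.25))
  expect_equal(small$method, "exact multinomial")
  expect_false(is.na(small$exact_p))
  # exact binomial tail cross-check at k = 2
  expect_equal(goodness_of_fit(c(10, 0), c(0.5, 0.5), exact = TRUE)$exact_p,
               2 * dbinom(0, 10, 0.5))

  # rejection rates of the two paths differ by < 0.01 at moderate n
  set.seed(61)
  counts <- rmultinom(2000, 200, c(0.75, 0.25))
  p_chi <- numeric(2000); p_ex <- numeric(2000)
  for (i in 1:2000) {
    g <- goodness_of_fit(counts[, i], c(0.75, 0.25), exact = TRUE)
    p_chi[i] <- g$p.value; p_ex[i] <- g$exact_p
  }
  expect_lt(abs(mean(p_chi < 0.05) - mean(p_ex < 0.05)), 0.01)
})

test_that("marker-trait contingency detects and localizes association", {
  # perfect dominant co-segregation
  marker <- c(rep("A", 25), rep("H", 50), rep("B", 25))
  trait <- as.integer(marker %in% c("H", "B"))
  res <- marker_trait_contingency(marker, trait)
  expect_equal(res$misclassified, 0)
  expect_lt(res$dominant$p.value, 1e-15)
  expect_equal(dim(res$table), c(3L, 2L))

  # epistatic second locus: recessive marker class is uniformly wild-type,
  # carrier classes are mixed
  gm <- genetic_map(data.frame(chrom = c("chr02", "chr04"),
                               marker = c("mt", "aprr"),
                               bp = c(5e6, 8e6), cM = c(15, 24)))
  tm <- trait_model(loci = data.frame(chrom = c("chr02", "chr04"),
                                      bp = c(5e6, 8e6),
                                      a = c(1, 0), d = c(1, 0)),
                    epistasis = data.frame(masker = 2L, genotype = "A",
                                           masked = 1L),
                    type = "binary")
  f2 <- simulate_cross(c(mt = "A", aprr = "A"), c(mt = "B", aprr = "B"),
                       "F2", 2000, gm, tm, seed = 62)
  res2 <- marker_trait_contingency(f2$geno[, "mt"], f2$phenotype)
  tab <- res2$table
  expect_equal(tab["A", "1"], 0)           # A class never mutant
  expect_gt(tab["H", "1"], 0)
  expect_gt(tab["H", "0"], 0)              # carriers include wild types
  expect_gt(res2$misclassified, 0)

  expect_error(marker_trait_contingency(c(NA, NA), c(1, 0)), "all-missing")
  expect_error(marker_trait_contingency(c("A", "X"), c(1, 0)), "codes")
})

test_that("allelism tests flag exceptions and bound the excluded fraction", {
  ok <- allelism_test(100, 0)
  expect_true(ok$consistent)
  expect_equal(ok$mutant_fraction, 1)
  expect_equal(ok$max_excluded_fraction, 1 - 0.05^(1 / 100))
  expect_lt(abs(ok$max_excluded_fraction - 0.0295), 5e-4)

  bad <- allelism_test(95, 5)
  expect_false(bad$consistent)
  expect_true(allelism_test(95, 5, tolerance = 5)$consistent)
  expect_error(allelism_test(0, 0), "n = 0")
})

test_that("dominance degree classifies mode of inheritance", {
  pa <- c(4.0, 4.1, 3.9); pb <- c(14.0, 14.1, 13.9)
  mid <- mean(c(pa, pb))
  add <- mode_of_inheritance(pa, pb, c(9.0, 9.05, 8.95))
  expect_equal(add$class, "additive")
  expect_lt(abs(add$da_ratio), 0.05)

  dom <- mode_of_inheritance(pa, pb, c(14.0, 13.95, 14.05))
  expect_equal(dom$class, "dominant")
  expect_lt(abs(dom$da_ratio - 1), 0.05)

  over <- mode_of_inheritance(pa, pb, c(17, 17.1, 16.9))
  expect_equal(over$class, "overdominant")

  zero_a <- mode_of_inheritance(c(5, 5), c(5, 5), c(7, 7.1))
  expect_equal(zero_a$class, "overdominant")
  expect_match(zero_a$flag, "zero parental difference")

  # significance gate: a noisy F1 indistinguishable from mid-parent
  set.seed(63)
  gated <- mode_of_inheritance(pa, pb, mid + rnorm(3, 0.5, 3))
  expect_equal(gated$class, "additive")
})

test_that("mid-parent regression reflects additivity", {
  mp <- c(4, 7, 9, 12, 14)
  perfect <- midparent_regression(mp, mp)
  expect_equal(perfect$r, 1)
  expect_warning(deg <- midparent_regression(rep(5, 5), c(1, 2, 3, 4, 5)),
                 "degenerate")
  expect_true(deg$degenerate)
  expect_error(midparent_regression(1:2, 1:2), ">= 3")

  # shuffling F1 values across crosses destroys the correlation
  set.seed(64)
  g <- rnorm(190); f1 <- g + rnorm(190, 0, 0.2)
  rs <- replicate(50, midparent_regression(g, sample(f1))$r)
  expect_lt(abs(mean(rs)), 0.05)
  expect_gt(midparent_regression(g, f1)$r, 0.9)
})

test_that("tail selection is deterministic, disjoint and correctly sized", {
  vals <- setNames(seq_len(200) + 0.0, sprintf("f%03d", 1:200))
  t1 <- select_tails(vals, vals, 0.1)
  expect_equal(t1$k, 20)
  expect_equal(t1$high, sort(names(vals)[181:200]))
  expect_equal(t1$low, sort(names(vals)[1:20]))
  expect_length(intersect(t1$high, t1$low), 0)
  expect_equal(t1$correlation, 1)

  # family-order invariance
  shuf <- sample(names(vals))
  t2 <- select_tails(vals[shuf], vals[shuf], 0.1)
  expect_identical(t1[c("high", "low")], t2[c("high", "low")])

  # uncorrelated generations: expected joint tail size ~ q^2 * n
  set.seed(65)
  sizes <- replicate(200, {
    a <- setNames(rnorm(200), sprintf("f%03d", 1:200))
    b <- setNames(rnorm(200), sprintf("f%03d", 1:200))
    length(select_tails(a, b, 0.1)$high)
  })
  expect_lt(abs(mean(sizes) - 0.1 * 20), 0.5)

  expect_error(select_tails(vals, vals, 0.5), "0, 0.5")
  expect_error(select_tails(unname(vals), unname(vals), 0.1), "named")
})
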