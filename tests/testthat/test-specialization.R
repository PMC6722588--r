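test_that("shannon_H2 matches direct summation", {
  expect_equal(shannon_H2(diag(2)), log(2))
  expect_equal(shannon_H2(matrix(5, 1, 1)), 0)
  # direct-summation oracle for a mixed table
  a <- matrix(c(4, 2, 2, 1), 2, 2)
  p <- a / sum(a)
  expect_equal(shannon_H2(a), -sum(p * log(p)))
  expect_equal(shannon_H2(a), 1.27302, tolerance = 1e-5)
})

test_that("entropy extrema agree with exhaustive enumeration on small margins", {
  # worked 2x2 case: min at [[6,0],[0,3]], max at [[4,2],[2,1]]
  ex <- h2_extrema(c(6, 3), c(6, 3))
  expect_equal(ex$H2min, entropy_of(matrix(c(6, 0, 0, 3), 2, 2)))
  expect_equal(ex$H2max, entropy_of(matrix(c(4, 2, 2, 1), 2, 2)))

  # only permutation tables exist
  ex2 <- h2_extrema(c(1, 1), c(1, 1))
  expect_equal(ex2$H2min, log(2))
  expect_equal(ex2$H2max, log(2))

  margins <- list(
    list(r = c(6, 3), c = c(6, 3)),
    list(r = c(4, 2), c = c(3, 3)),
    list(r = c(5, 4, 3), c = c(7, 5)),
    list(r = c(2, 2, 2), c = c(3, 3)),
    list(r = c(8, 1), c = c(3, 3, 3)),
    list(r = c(1, 1, 2), c = c(2, 2)))
  for (mg in margins) {
    got <- h2_extrema(mg$r, mg$c)
    want <- enum_entropy_range(mg$r, mg$c)
    expect_equal(got$H2min, unname(want["min"]), tolerance = 1e-12)
    expect_equal(got$H2max, unname(want["max"]), tolerance = 1e-12)
  }
})

test_that("extrema bracket the entropy of arbitrary realizable tables", {
  for (s in 1:8) {
    a <- random_web(4, 3, seed = 200 + s)
    ex <- h2_extrema(rowSums(a), colSums(a))
    expect_lte(ex$H2min, shannon_H2(a) + 1e-12)
    expect_gte(ex$H2max, shannon_H2(a) - 1e-12)
  }
})

test_that("H2' standardizes to [0, 1] with the documented anchors", {
  expect_equal(h2prime(matrix(c(6, 0, 0, 3), 2, 2))$H2prime, 1)
  expect_equal(h2prime(matrix(c(4, 2, 2, 1), 2, 2))$H2prime, 0)
  for (s in 1:6) {
    r <- h2prime(random_web(5, 4, seed = 300 + s))$H2prime
    expect_gte(r, 0)
    expect_lte(r, 1)
  }
  # degenerate marginals (single realizable table) give 0
  expect_equal(h2prime(matrix(c(1, 0, 0, 1), 2, 2))$H2prime, 0)
})

test_that("d' measures selectivity against resource availability", {
  # a species using hosts proportionally to availability has d = 0
  a <- rbind(c(4, 2, 2), c(8, 4, 4))
  d <- dprime(a)
  expect_equal(d$d, c(0, 0), tolerance = 1e-12)
  expect_equal(d$dprime, c(0, 0))

  # one-term KL sum: row concentrated on a host holding half the total
  b <- rbind(c(0, 10), c(10, 0))
  db <- dprime(b)
  expect_equal(db$d, c(log(2), log(2)), tolerance = 1e-12)
  expect_equal(db$dprime, c(1, 1)) # maximal given the marginals

  for (s in 1:6) {
    dd <- dprime(random_web(5, 4, seed = 400 + s))
    expect_true(all(dd$dprime >= 0 & dd$dprime <= 1))
    expect_true(all(dd$dmax >= dd$dmin - 1e-12))
  }
  expect_error(dprime(matrix(1, 2, 2), axis = "plants"))
})
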