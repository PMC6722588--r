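test_that("accumulation curves pool to observed richness", {
  # one unit holding three species
  r1 <- records_from_units(list(u1 = c(a = 2, b = 1, c = 4)))
  expect_equal(accumulation_curve(r1), data.frame(k = 1L, mean = 3, sd = 0))

  # disjoint singleton species accumulate linearly
  r2 <- records_from_units(list(u1 = c(a = 1), u2 = c(b = 1), u3 = c(c = 1)))
  ac <- accumulation_curve(r2, n_perm = 50, seed = 1)
  expect_equal(ac$mean, c(1, 2, 3))

  # final point equals pooled richness regardless of permutations
  set.seed(31)
  units <- lapply(1:12, function(u) {
    sp <- sample(letters[1:9], sample(1:4, 1))
    stats::setNames(rpois(length(sp), 2) + 1, sp)
  })
  names(units) <- paste0("u", 1:12)
  r3 <- records_from_units(units)
  pooled <- length(unique(r3$species[r3$count > 0]))
  for (np in c(5, 40)) {
    ac3 <- accumulation_curve(r3, n_perm = np, seed = 2)
    expect_equal(ac3$mean[nrow(ac3)], pooled)
    expect_true(all(diff(ac3$mean) >= -1e-12)) # monotone
  }
})

test_that("jackknife-1 follows its closed form and vegan agrees", {
  # 10 units, S_obs = 5, two species in exactly one unit
  units <- c(
    list(u01 = c(a = 1, b = 2), u02 = c(a = 1, c = 1), u03 = c(b = 1, c = 2)),
    lapply(1:5, function(i) c(a = 1, b = 1)),
    list(u09 = c(d = 3), u10 = c(e = 1, a = 2)))
  names(units)[4:8] <- paste0("u0", 4:8)
  rec <- records_from_units(units)
  j <- jackknife1(rec)
  expect_equal(j$S_obs, 5L)
  expect_equal(j$Q1, 2L)
  expect_equal(j$m_units, 10L)
  expect_equal(j$S_jack1, 5 + 2 * 9 / 10) # 6.8
  expect_equal(j$completeness, 100 * 5 / 6.8)

  # no uniques: estimate equals the observation
  runi <- records_from_units(list(u1 = c(a = 1, b = 1), u2 = c(a = 2, b = 2)))
  juni <- jackknife1(runi)
  expect_equal(juni$S_jack1, juni$S_obs)
  expect_equal(juni$completeness, 100)
  expect_error(jackknife1(records_from_units(list(u1 = c(a = 1)))), "two sampling")

  # independent implementation: vegan::specpool on the unit matrix
  set.seed(77)
  units2 <- lapply(1:15, function(u) {
    sp <- sample(letters[1:10], sample(1:5, 1))
    stats::setNames(rpois(length(sp), 3) + 1, sp)
  })
  names(units2) <- sprintf("u%02d", 1:15)
  rec2 <- records_from_units(units2)
  comm <- tapply(rec2$count, list(rec2$unit_id, rec2$species), sum, default = 0)
  expect_equal(jackknife1(rec2)$S_jack1,
               vegan::specpool(comm)$jack1, tolerance = 1e-9)

  # abundance variant counts single individuals instead of single units
  ra <- records_from_units(list(u1 = c(a = 1, b = 5), u2 = c(b = 4, c = 1)))
  expect_equal(jackknife1(ra, variant = "abundance")$Q1, 2L)
})

test_that("Bray-Curtis partition components are additive and anchored", {
  z <- bray_curtis_partition(c(3, 1, 2), c(3, 1, 2))
  expect_equal(c(z$total, z$balanced, z$gradient), c(0, 0, 0))

  z2 <- bray_curtis_partition(c(5, 0), c(0, 5))
  expect_equal(c(z2$total, z2$balanced, z2$gradient), c(1, 1, 0))

  # nested abundance gradient: x = 2y
  z3 <- bray_curtis_partition(c(2, 2), c(1, 1))
  expect_equal(c(z3$total, z3$balanced, z3$gradient), c(1 / 3, 0, 1 / 3))

  expect_error(bray_curtis_partition(c(0, 0), c(0, 0)), "empty")

  # additivity and symmetry across random pairs
  set.seed(13)
  for (i in 1:200) {
    x <- rpois(8, 3)
    y <- rpois(8, 3)
    if (sum(x) + sum(y) == 0) next
    d <- bray_curtis_partition(x, y)
    expect_equal(d$balanced + d$gradient, d$total, tolerance = 1e-12)
    d2 <- bray_curtis_partition(y, x)
    expect_equal(d$total, d2$total)
    expect_equal(d$balanced, d2$balanced)
    expect_gte(d$balanced, 0)
    expect_gte(d$gradient, -1e-12)
  }
})

test_that("multi-site partition reduces to pairs and matches pair sums", {
  m2 <- rbind(c(4, 1, 0), c(2, 2, 1))
  pair <- bray_curtis_partition(m2[1, ], m2[2, ])
  multi <- multi_site_bray(m2)
  expect_equal(multi$total, pair$total)
  expect_equal(multi$balanced, pair$balanced)

  # identical sites: no dissimilarity
  expect_equal(multi_site_bray(rbind(c(2, 1), c(2, 1), c(2, 1)))$total, 0)

  # three sites against hand-computed pair sums
  m3 <- rbind(s1 = c(5, 0, 2), s2 = c(1, 3, 2), s3 = c(0, 4, 1))
  pr <- list(c(1, 2), c(1, 3), c(2, 3))
  A <- B <- C <- mn <- 0
  for (p in pr) {
    x <- m3[p[1], ]; y <- m3[p[2], ]
    a <- sum(pmin(x, y))
    A <- A + a; B <- B + sum(x) - a; C <- C + sum(y) - a
    mn <- mn + min(sum(x) - a, sum(y) - a)
  }
  got <- multi_site_bray(m3)
  expect_equal(got$total, (B + C) / (2 * A + B + C))
  expect_equal(got$balanced, mn / (A + mn))
  expect_equal(got$gradient, got$total - got$balanced)
  expect_error(multi_site_bray(rbind(c(0, 0), c(1, 1))), "zero total")
})

test_that("a pure abundance gradient has no balanced component", {
  # all species scaled by a common site factor
  base <- c(8, 4, 2, 1, 5)
  mat <- rbind(low = 4 * base, mid = 2 * base, high = base)
  expect_equal(multi_site_bray(mat)$balanced, 0, tolerance = 1e-12)
  expect_gt(multi_site_bray(mat)$gradient, 0)
})
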