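test_that("generation is reproducible and internally consistent", {
  cf <- synthetic_config(n_hosts = 6, n_insects = 12, seed = 5)
  r1 <- generate_community(cf)
  r2 <- generate_community(cf)
  expect_identical(r1, r2)

  # aggregating the records reproduces the generator's internal web
  web <- attr(r1, "web")
  agg <- records_to_web(r1)
  expect_identical(agg$counts[rownames(web$counts), colnames(web$counts)],
                   web$counts)
  expect_error(synthetic_config(kappa = 1.4), "kappa")
  expect_error(synthetic_config(units = matrix(0, 8, 3)), "units")
})

test_that("perfect concentration plants a recoverable block partition", {
  cf <- synthetic_config(n_hosts = 6, n_insects = 9, n_blocks = 3,
                         kappa = 1, tau = 0,
                         units = matrix(5L, 6, 1),
                         meanlog = 3, sdlog = 0, seed = 3)
  rec <- generate_community(cf)
  web <- attr(rec, "web")
  ib <- attr(rec, "insect_blocks")[rownames(web$counts)]
  hb <- attr(rec, "host_blocks")[colnames(web$counts)]
  # off-block cells are empty
  expect_true(all(web$counts[outer(ib, hb, `!=`)] == 0))
  # equal per-species abundance makes the three blocks carry equal weight
  mp <- dirt_lpawb_plus(web, n_restarts = 10, seed = 1)
  expect_equal(mp$Q, 1 - 1 / 3, tolerance = 1e-12)
  expect_equal(mp$n_modules, 3L)
  # recovered modules coincide with the planted blocks up to relabeling
  expect_equal(length(unique(paste(ib, mp$row_labels))), 3L)
})

test_that("turnover rate controls species-pool replacement", {
  cf0 <- synthetic_config(n_hosts = 4, n_insects = 12, tau = 0, seed = 8,
                          units = matrix(6L, 4, 3))
  pools0 <- attr(generate_community(cf0), "pools")
  expect_identical(pools0[[1]], pools0[[2]])
  expect_identical(pools0[[1]], pools0[[3]])

  cf1 <- synthetic_config(n_hosts = 4, n_insects = 12, tau = 1, seed = 8,
                          units = matrix(6L, 4, 3))
  rec1 <- generate_community(cf1)
  pools1 <- attr(rec1, "pools")
  expect_length(intersect(pools1[[1]], pools1[[2]]), 0L)
  # complete replacement: adjacent strata share no species, so pairwise
  # dissimilarity is pure balanced variation
  st <- stratify(rec1, "elevation")
  sp <- sort(unique(rec1$species))
  vec <- function(w) {
    v <- stats::setNames(numeric(length(sp)), sp)
    v[rownames(w$counts)] <- rowSums(w$counts)
    v
  }
  d <- bray_curtis_partition(vec(st[[1]]), vec(st[[2]]))
  expect_equal(d$balanced, 1)
  expect_equal(d$total, 1)
})

test_that("the survey-like configuration matches the sampled design", {
  cf <- survey_config()
  expect_equal(sum(cf$units), 250L)
  expect_equal(unname(colSums(cf$units)), c(123, 94, 33))
  expect_equal(cf$n_insects, 34L)
  expect_equal(cf$n_hosts, 8L)
  web <- attr(generate_community(cf), "web")
  ab <- sort(rowSums(web$counts), decreasing = TRUE)
  # dominance: the four most abundant species hold well over half of all
  # individuals at the default seed
  expect_gte(sum(ab[1:4]) / sum(ab), 0.6)
})
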