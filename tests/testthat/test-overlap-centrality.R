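test_that("Morisita-Horn similarity has its documented anchors", {
  expect_equal(morisita_horn(c(3, 1), c(3, 1)), 1)
  expect_equal(morisita_horn(c(5, 0), c(0, 5)), 0)
  expect_equal(morisita_horn(c(2, 2), c(1, 1)), 1)
  expect_error(morisita_horn(c(0, 0), c(1, 1)), "zero-sum")
  expect_error(morisita_horn(c(1, 2), c(1, 2, 3)), "length")
})

test_that("Morisita-Horn is symmetric and scale-invariant", {
  set.seed(7)
  for (i in 1:20) {
    x <- rpois(6, 3) + c(1, rep(0, 5))
    y <- rpois(6, 3) + c(0, 1, rep(0, 4))
    expect_equal(morisita_horn(x, y), morisita_horn(y, x))
    expect_equal(morisita_horn(x, y), morisita_horn(3 * x, y), tolerance = 1e-12)
    expect_equal(morisita_horn(x, y), morisita_horn(x, 7 * y), tolerance = 1e-12)
    expect_gte(morisita_horn(x, y), 0)
    expect_lte(morisita_horn(x, y), 1 + 1e-12)
  }
})

test_that("mean niche overlap averages all unordered pairs", {
  expect_equal(mean_niche_overlap(diag(2)), 0)
  expect_equal(mean_niche_overlap(matrix(1, 3, 3)), 1)
  # three rows: mean of the three pairwise similarities
  a <- rbind(c(4, 0), c(0, 4), c(2, 2))
  want <- mean(c(morisita_horn(c(4, 0), c(0, 4)),
                 morisita_horn(c(4, 0), c(2, 2)),
                 morisita_horn(c(0, 4), c(2, 2))))
  expect_equal(mean_niche_overlap(a), want)
  expect_error(mean_niche_overlap(matrix(c(1, 2), 1, 2)), "at least two")
})

test_that("HITS scores converge deterministically with max 1 per side", {
  h <- hits_scores(matrix(1, 2, 2))
  expect_equal(unname(h$hub), c(1, 1))
  expect_equal(unname(h$authority), c(1, 1))

  # one insect in two hosts: everything maximal after one iteration
  h2 <- hits_scores(matrix(c(1, 1), 1, 2))
  expect_equal(unname(h2$hub), 1)
  expect_equal(unname(h2$authority), c(1, 1))

  a <- random_web(6, 4, seed = 11)
  h3 <- hits_scores(a, transform = "none")
  h4 <- hits_scores(10 * a, transform = "none") # global rescale of W
  expect_equal(h3$hub, h4$hub, tolerance = 1e-9)
  expect_equal(h3$authority, h4$authority, tolerance = 1e-9)
  expect_equal(max(h3$hub), 1)
  expect_equal(max(h3$authority), 1)
  expect_true(all(h3$hub >= 0 & h3$hub <= 1))
  expect_error(hits_scores(a, tol = -1), "tol")
})

test_that("HITS agrees with the igraph implementation", {
  a <- random_web(5, 4, seed = 42)
  W <- ifelse(a > 0, log10(a) + 1, 0)
  el <- which(W > 0, arr.ind = TRUE)
  g <- igraph::graph_from_edgelist(
    cbind(paste0("I", el[, 1]), paste0("H", el[, 2])), directed = TRUE)
  igraph::E(g)$weight <- W[el]
  hs <- tryCatch(igraph::hits_scores(g),
                 error = function(e) list(hub = igraph::hub_score(g)$vector,
                                          authority = igraph::authority_score(g)$vector))
  ih <- hs$hub[paste0("I", 1:5)]
  ia <- hs$authority[paste0("H", 1:4)]
  mine <- hits_scores(a)
  expect_equal(unname(ih / max(ih)), unname(mine$hub), tolerance = 1e-8)
  expect_equal(unname(ia / max(ia)), unname(mine$authority), tolerance = 1e-8)
})
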