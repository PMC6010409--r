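test_that("Jaccard index handles the canonical cases", {
  expect_equal(jaccard(c("A", "B"), c("A", "B")), 1)
  expect_equal(jaccard(c("A", "B"), c("C", "D")), 0)
  expect_equal(jaccard(c("A", "B", "C"), c("B", "C", "D")), 0.5)
  fx <- make_fixture("toy_jaccard")
  expect_equal(jaccard(fx$syllables[[1]], fx$syllables[[2]]), 0.5)
  expect_error(jaccard(character(0), "A"), "empty")
})

test_that("distance-binned sharing respects the geometry", {
  # all individuals at one point: a single bin holds all pairs
  s <- repertoire_sample(paste0("i", 1:6), rep("p", 6), rep(0, 6),
                         rep(0, 6), as.list(LETTERS[1:6]))
  tab <- sharing_vs_distance(s, c(0, 10))
  expect_equal(sum(tab$n_pairs), 15)      # 6*5/2
  expect_equal(sum(tab$n_pairs[tab$scope == "within"]), 15)

  # two populations far apart: between-population pairs only in the
  # largest bin
  s2 <- repertoire_sample(paste0("i", 1:4), c("p", "p", "q", "q"),
                          c(0, 1, 1000, 1001), rep(0, 4),
                          list("A", "A", "B", "B"))
  tab2 <- sharing_vs_distance(s2, c(0, 10, 2000))
  btw <- tab2[tab2$scope == "between", ]
  expect_equal(btw$n_pairs[1], 0)
  expect_equal(btw$n_pairs[2], 4)
})

test_that("synthetic studies share more within than between populations", {
  study <- make_fixture("mini_study")
  ct <- sharing_contrast(study$sample)
  expect_gt(ct[["within"]], ct[["between"]])
  tab <- sharing_vs_distance(study$sample, c(0, 3000, 3e5))
  w <- tab$mean_jaccard[tab$scope == "within" & tab$n_pairs > 0]
  b <- tab$mean_jaccard[tab$scope == "between" & tab$n_pairs > 0]
  expect_gt(min(w), max(b))
})

test_that("Mantel correlation and stratification match a naive oracle", {
  set.seed(60)
  n <- 25
  xy <- matrix(rnorm(2 * n), n, 2)
  D1 <- as.matrix(dist(xy))
  D2 <- D1 + matrix(runif(n * n, 0, 0.5), n, n)
  D2 <- (D2 + t(D2)) / 2; diag(D2) <- 0
  m <- mantel_test(D1, D2, n_perm = 199, seed = 61)
  o <- oracle_mantel(D1, D2, n_perm = 199)
  expect_equal(m$r, o$r, tolerance = 1e-12)
  expect_equal(mantel_test(D1, D1, n_perm = 99, seed = 62)$r, 1)
  # all-one-group strata equal the unstratified statistic
  m1 <- mantel_test(D1, D2, strata = rep(1, n), n_perm = 199, seed = 63)
  expect_equal(m1$r, m$r)
  expect_error(mantel_test(D1, matrix(0, n, n)), "constant")
})

test_that("stratified permutations stay within strata", {
  # between-strata signal is huge; within strata D2 is pure noise. A
  # stratified test must not find the between-strata association.
  set.seed(64)
  strata <- rep(1:2, each = 10)
  base <- outer(strata, strata, function(a, b) ifelse(a == b, 0, 10))
  noise <- matrix(runif(400, 0, 0.5), 20, 20)
  D1 <- base + (noise + t(noise)) / 2
  noise2 <- matrix(runif(400, 0, 0.5), 20, 20)
  D2 <- base + (noise2 + t(noise2)) / 2
  diag(D1) <- 0; diag(D2) <- 0
  unstrat <- mantel_test(D1, D2, n_perm = 199, seed = 65)
  strat <- mantel_test(D1, D2, strata = strata, n_perm = 199, seed = 66)
  expect_lt(unstrat$p, 0.01)   # cross-strata permutation finds it
  expect_gt(strat$p, 0.2)      # within-strata permutation cannot
})

test_that("Mantel p-values are calibrated under the null", {
  set.seed(67)
  ps <- replicate(25, {
    D1 <- as.matrix(dist(rnorm(12)))
    D2 <- as.matrix(dist(rnorm(12)))
    mantel_test(D1, D2, n_perm = 99)$p
  })
  expect_gt(mean(ps > 0.05), 0.5)  # mostly non-significant
  expect_gt(max(ps), 0.5)
  expect_lt(min(ps), 0.5)
})

test_that("UPGMA reproduces known merge structure and an oracle", {
  D <- matrix(c(0, 1, 10, 1, 0, 10, 10, 10, 0), 3, 3,
              dimnames = list(letters[1:3], letters[1:3]))
  h <- upgma(D)
  expect_equal(sort(h$height), c(1, 10))
  # ultrametric input is reproduced exactly by cophenetic distances
  expect_equal(as.matrix(stats::cophenetic(h))[letters[1:3], letters[1:3]],
               D)
  # random matrices agree with the naive average-linkage oracle
  set.seed(68)
  for (i in 1:3) {
    M <- matrix(runif(400, 0.1, 2), 20, 20)
    M <- (M + t(M)) / 2; diag(M) <- 0
    expect_equal(unname(as.matrix(stats::cophenetic(upgma(M)))),
                 oracle_upgma_cophenetic(M), tolerance = 1e-10)
  }
  expect_error(upgma(matrix(c(0, 1, 2, 0), 2, 2)), "symmetric")
})

test_that("the GSI profile finds planted cluster structure", {
  set.seed(69)
  pd <- planted_dissim(2, 8)
  g <- gsi_profile(pd$D, k_range = 2:10)
  expect_equal(g$k_star, 2)
  expect_gt(max(g$profile$gsi), 0.8)

  pd4 <- planted_dissim(4, 6)
  g4 <- gsi_profile(pd4$D, k_range = 2:12)
  expect_equal(g4$k_star, 4)
  gsi_at <- function(g, k) g$profile$gsi[g$profile$k == k]
  expect_gt(gsi_at(g4, 4), gsi_at(g4, 8))

  # uniform random dissimilarities: weak clustering tendency everywhere
  U <- matrix(runif(3600), 60, 60)
  U <- (U + t(U)) / 2; diag(U) <- 0
  for (m in c("cluster_mean", "item_mean")) {
    gU <- gsi_profile(U, k_range = 2:12, method = m)
    expect_lt(max(gU$profile$gsi), 0.3)
  }
})

test_that("NMI matches its definition and the igraph oracle", {
  a <- rep(1:3, each = 10)
  expect_equal(nmi(a, a), 1)
  expect_equal(nmi(a, rep(1, 30)), 0)
  set.seed(70)
  r1 <- sample(1:4, 400, replace = TRUE)
  r2 <- sample(1:4, 400, replace = TRUE)
  expect_lt(nmi(r1, r2), 0.05)
  skip_if_not_installed("igraph")
  b <- sample(1:3, 30, replace = TRUE)
  expect_equal(nmi(a, b), igraph::compare(a, b, method = "nmi"),
               tolerance = 1e-12)
})

test_that("dissimilarity CSV and Newick exports round-trip", {
  set.seed(71)
  M <- matrix(runif(100), 10, 10)
  M <- (M + t(M)) / 2; diag(M) <- 0
  dimnames(M) <- list(paste0("syl", 1:10), paste0("syl", 1:10))
  path <- tempfile(fileext = ".csv")
  write_dissim(M, path)
  expect_equal(read_dissim(path), M)
  nw <- tempfile(fileext = ".nwk")
  write_dendrogram(upgma(M), nw)
  tree <- ape::read.tree(nw)
  expect_setequal(tree$tip.label, rownames(M))
})
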