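# naive double-sum RV for the oracle: explicit trace formula on small input
rv_bruteforce <- function(X, Y) {
  X <- scale(X, center = TRUE, scale = FALSE)
  Y <- scale(Y, center = TRUE, scale = FALSE)
  Sx <- X %*% t(X)
  Sy <- Y %*% t(Y)
  num <- 0
  dx <- 0
  dy <- 0
  n <- nrow(X)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      num <- num + Sx[i, j] * Sy[i, j]
      dx <- dx + Sx[i, j]^2
      dy <- dy + Sy[i, j]^2
    }
  }
  num / sqrt(dx * dy)
}

test_that("Gower centering has the expected closed-form spectrum", {
  # 2-point matrix: single non-zero eigenvalue d^2/2
  two <- dist_matrix(matrix(c(0, 3, 3, 0), 2, 2,
                            dimnames = list(c("a", "b"), c("a", "b"))))
  ev <- gower_center(two)$eigenvalues
  expect_equal(ev, c(9 / 2, 0), tolerance = 1e-12)
  # Euclidean distances from a point set: all eigenvalues >= -tol
  pts <- withr::with_seed(41, matrix(rnorm(12), 6, 2))
  rownames(pts) <- paste0("p", 1:6)
  de <- dist_matrix(as.matrix(dist(pts)))
  expect_gt(min(gower_center(de)$eigenvalues), -1e-10)
  # zero matrix: all eigenvalues zero
  z <- dist_matrix(matrix(0, 3, 3, dimnames = list(letters[1:3],
                                                   letters[1:3])))
  expect_equal(gower_center(z)$eigenvalues, rep(0, 3))
})

test_that("Lingoes correction makes matrices Euclidean-embeddable", {
  # already Euclidean: unchanged, constant 0
  pts <- withr::with_seed(42, matrix(rnorm(10), 5, 2))
  rownames(pts) <- paste0("p", 1:5)
  de <- dist_matrix(as.matrix(dist(pts)))
  corrected <- lingoes_correction(de)
  expect_equal(attr(corrected, "lingoes_constant"), 0)
  expect_equal(unclass(corrected), unclass(de), ignore_attr = TRUE)
  # constructed non-Euclidean input becomes embeddable
  dn <- random_nonmetric_distances(6, seed = 43)
  ev0 <- gower_center(dn)$eigenvalues
  expect_lt(min(ev0), -1e-8)
  fixed <- lingoes_correction(dn)
  ev1 <- gower_center(fixed)$eigenvalues
  expect_gte(min(ev1), -1e-8 * max(ev1))
  # the map is monotone: off-diagonal ordering preserved
  o0 <- order(unclass(dn)[upper.tri(dn)])
  o1 <- order(unclass(fixed)[upper.tri(fixed)])
  expect_identical(o0, o1)
  # constant agrees with the independent PCoA implementation in ape
  ap <- ape::pcoa(as.dist(unclass(dn)), correction = "lingoes")
  c_ape <- as.numeric(sub(".*eigenvalues: D' = -0.5\\*D\\^2 - ", "",
                          sub(" , except diagonal elements", "", ap$note)))
  expect_equal(attr(fixed, "lingoes_constant"), c_ape, tolerance = 1e-6)
})

test_that("PCoA reconstructs configurations from their distances", {
  pts <- withr::with_seed(44, matrix(rnorm(16), 8, 2))
  rownames(pts) <- paste0("p", 1:8)
  d <- dist_matrix(as.matrix(dist(pts)))
  cs <- pcoa(d)
  rec <- as.matrix(dist(cs$coordinates))
  expect_equal(unname(rec), unname(unclass(d)), tolerance = 1e-10)
  expect_identical(ncol(cs$coordinates), 2L)
  # 2 points embed on a single axis
  cs2 <- pcoa(dist_matrix(matrix(c(0, 1, 1, 0), 2, 2,
                                 dimnames = list(c("a", "b"),
                                                 c("a", "b")))))
  expect_identical(ncol(cs2$coordinates), 1L)
  # duplicated points share coordinates
  pts_dup <- rbind(pts, p9 = pts[1, ])
  ddup <- dist_matrix(as.matrix(dist(pts_dup)))
  csd <- pcoa(ddup)
  expect_equal(csd$coordinates["p9", ], csd$coordinates["p1", ],
               tolerance = 1e-8)
  # non-Euclidean input is refused with guidance
  expect_error(pcoa(random_nonmetric_distances(6, seed = 45)),
               "lingoes_correction")
})

test_that("RV coefficient satisfies its identities and oracle", {
  X <- withr::with_seed(46, matrix(rnorm(10), 5, 2))
  Y <- withr::with_seed(47, matrix(rnorm(10), 5, 2))
  rownames(X) <- rownames(Y) <- paste0("i", 1:5)
  expect_equal(rv_coefficient(X, X), 1, tolerance = 1e-12)
  # naive double-sum oracle
  expect_equal(rv_coefficient(X, Y), rv_bruteforce(X, Y), tolerance = 1e-12)
  # symmetry in arguments
  expect_equal(rv_coefficient(X, Y), rv_coefficient(Y, X))
  expect_true(rv_coefficient(X, Y) >= 0 && rv_coefficient(X, Y) <= 1)
  # invariance under orthogonal rotation and positive scaling
  th <- 0.7
  Q <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  expect_equal(rv_coefficient(X, 5 * (X %*% Q)), 1, tolerance = 1e-12)
  # row order must not matter (alignment by ids)
  expect_equal(rv_coefficient(X, Y[c(3, 1, 2, 5, 4), ]),
               rv_coefficient(X, Y), tolerance = 1e-12)
  # errors
  Ybad <- Y
  rownames(Ybad) <- paste0("j", 1:5)
  expect_error(rv_coefficient(X, Ybad), "mismatched ids")
  expect_error(rv_coefficient(X, matrix(0, 5, 2,
                                        dimnames = list(rownames(X), NULL))),
               "zero-variance")
})

test_that("RV permutation test attains its bounds and is reproducible", {
  X <- withr::with_seed(48, matrix(rnorm(24), 12, 2))
  rownames(X) <- paste0("i", 1:12)
  # y = x exactly: minimum attainable p
  t1 <- rv_test(X, X, n_permutations = 199, seed = 5)
  expect_equal(t1$p_value, 1 / 200)
  # deterministic given seed
  Y <- withr::with_seed(49, X + matrix(rnorm(24, sd = 0.05), 12, 2))
  t2a <- rv_test(X, Y, n_permutations = 299, seed = 7)
  t2b <- rv_test(X, Y, n_permutations = 299, seed = 7)
  expect_identical(t2a$p_value, t2b$p_value)
  # strong dependence: p at or near the minimum
  expect_lte(t2a$p_value, 3 / 300)
  expect_error(rv_test(X, Y, n_permutations = 50), "99")
})

test_that("population aggregation matches direct enumeration", {
  membership <- tibble::tibble(id = c("a1", "a2", "b1"),
                               population = c("A", "A", "B"))
  # DAS population distance = mean of between-population pairs
  m <- matrix(0, 3, 3, dimnames = list(c("a1", "a2", "b1"),
                                       c("a1", "a2", "b1")))
  m["a1", "a2"] <- m["a2", "a1"] <- 0.2
  m["a1", "b1"] <- m["b1", "a1"] <- 0.6
  m["a2", "b1"] <- m["b1", "a2"] <- 0.8
  agg <- population_aggregate(membership, das = dist_matrix(m))
  expect_equal(unclass(agg$das)["A", "B"], mean(c(0.6, 0.8)))
  expect_equal(diag(unclass(agg$das)), c(A = 0, B = 0))
  # mean scores: Euclidean between population means
  scores <- tibble::tibble(id = c("a1", "a2", "b1"),
                           d1 = c(1, 3, 10), d2 = c(0, 0, 4))
  agg2 <- population_aggregate(membership, colour = scores)
  expect_equal(unclass(agg2$colour)["A", "B"],
               sqrt((10 - 2)^2 + 4^2))
  # singleton population keeps its member's coordinates
  loc <- tibble::tibble(id = c("a1", "a2", "b1"),
                        lat = c(10, 12, 40), lon = c(5, 7, 60))
  agg3 <- population_aggregate(membership, localities = loc)
  direct <- unclass(geodesic_distances(
    tibble::tibble(id = c("A", "B"), lat = c(11, 40), lon = c(6, 60))))
  expect_equal(unclass(agg3$geodesic), direct)
  # identical specimens across two populations -> all distances zero
  same_scores <- tibble::tibble(id = c("a1", "a2", "b1"),
                                d1 = 2, d2 = 2)
  agg4 <- population_aggregate(membership, colour = same_scores)
  expect_equal(max(unclass(agg4$colour)), 0)
  expect_error(population_aggregate(membership), "no data layer")
})

test_that("congruence tree dissimilarities behave as 1 - RV^2", {
  base <- withr::with_seed(50, matrix(rnorm(60), 20, 3))
  rownames(base) <- paste0("i", 1:20)
  sets <- list(
    a = coordinate_set(rownames(base), base),
    a_copy = coordinate_set(rownames(base), base %*% diag(3) * 2),
    b = coordinate_set(rownames(base),
                       withr::with_seed(51, matrix(rnorm(60), 20, 3)))
  )
  ct <- congruence_tree(sets)
  expect_equal(unclass(ct$dissimilarity)["a", "a_copy"], 0,
               tolerance = 1e-12)
  expect_true(all(unclass(ct$dissimilarity) >= 0 &
                  unclass(ct$dissimilarity) <= 1))
  expect_s3_class(ct$tree, "phylo")
  expect_error(congruence_tree(sets[1:2]), "3 coordinate sets")
  # mutually independent noise: dissimilarities near 1
  noise <- lapply(1:3, function(k) {
    coordinate_set(rownames(base),
                   withr::with_seed(60 + k, matrix(rnorm(60), 20, 3)))
  })
  names(noise) <- c("x", "y", "z")
  ctn <- congruence_tree(noise)
  expect_true(all(unclass(ctn$dissimilarity)[upper.tri(diag(3))] > 0.8))
})

test_that("distance-profile correlations detect matched structure", {
  pts <- withr::with_seed(52, matrix(rnorm(24), 12, 2))
  rownames(pts) <- paste0("i", 1:12)
  d1 <- dist_matrix(as.matrix(dist(pts)))
  # identical matrices: unit diagonal
  pc <- distance_profile_correlation(d1, d1)
  expect_equal(unname(diag(pc$correlation)), rep(1, 12))
  expect_identical(pc$hclust_rows$method, "complete")
  # copy with two labels swapped: the swapped pair's profiles (which
  # exclude both members of the pair) still match exactly
  sw <- replace(1:12, c(3, 7), c(7, 3))
  m2 <- unclass(d1)[sw, sw]
  rownames(m2) <- colnames(m2) <- rownames(pts)
  pc2 <- distance_profile_correlation(d1, dist_matrix(m2))
  expect_equal(pc2$correlation[3, 7], 1, tolerance = 1e-10)
  expect_equal(pc2$correlation[7, 3], 1, tolerance = 1e-10)
  # independent random structures: mean off-diagonal correlation ~ 0
  pts_b <- withr::with_seed(54, matrix(rnorm(24), 12, 2))
  rownames(pts_b) <- rownames(pts)
  pc3 <- distance_profile_correlation(
    d1, dist_matrix(as.matrix(dist(pts_b))))
  off <- pc3$correlation[row(pc3$correlation) != col(pc3$correlation)]
  expect_lt(abs(mean(off)), 0.25)
  expect_error(distance_profile_correlation(
    d1, dist_matrix(as.matrix(dist(pts_b[1:5, ])))), "same ids")
})
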