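test_that("CA total inertia matches the brute-force chi-square oracle", {
  for (seed in 1:5) {
    X <- withr::with_seed(seed, matrix(rexp(10 * 6), 10, 6))
    rownames(X) <- paste0("r", 1:10)
    colnames(X) <- paste0("c", 1:6)
    space <- correspondence_analysis(
      tibble::tibble(id = rownames(X), !!!as.data.frame(X)))
    expect_equal(space$total_inertia, chisq_bruteforce(X) / sum(X),
                 tolerance = 1e-10)
    expect_equal(sum(space$eigenvalues), space$total_inertia,
                 tolerance = 1e-10)
  }
})

test_that("row principal coordinates reproduce chi-square row distances", {
  X <- withr::with_seed(7, matrix(rexp(8 * 5), 8, 5))
  rownames(X) <- paste0("r", 1:8)
  colnames(X) <- paste0("c", 1:5)
  space <- correspondence_analysis(
    tibble::tibble(id = rownames(X), !!!as.data.frame(X)))
  F <- as.matrix(space$row_coordinates[-1])
  expect_equal(unname(as.matrix(dist(F))), chisq_row_distances(X),
               tolerance = 1e-10)
})

test_that("colour space matches an independent CA implementation", {
  chars <- tiny_characters()
  sp <- random_specimens(chars, 30, seed = 8)
  coded <- encode_specimens(sp, chars)
  space <- correspondence_analysis(coded)
  # corresp warns about non-integer entries; fuzzy values are intentional
  ref <- suppressWarnings(
    MASS::corresp(as.matrix(coded[-1]), nf = space$n_dimensions))
  expect_equal(space$eigenvalues, unname(ref$cor^2), tolerance = 1e-8)
  # coordinates agree up to per-axis sign
  F_own <- as.matrix(space$row_coordinates[-1])
  F_ref <- ref$rscore %*% diag(ref$cor, space$n_dimensions)
  for (j in seq_len(ncol(F_own))) {
    expect_equal(abs(F_own[, j]), unname(abs(F_ref[, j])), tolerance = 1e-8)
  }
})

test_that("CA structural invariants hold on fuzzy-coded matrices", {
  chars <- velutina_characters()
  sp <- random_specimens(chars, 60, seed = 9)
  coded <- encode_specimens(sp, chars)
  space <- correspondence_analysis(coded)
  # rank bound: one dimension per character at most
  expect_lte(space$n_dimensions, min(nrow(chars), nrow(sp) - 1L))
  expect_true(all(diff(space$eigenvalues) <= 1e-12))
  expect_true(all(space$eigenvalues >= 0))
  expect_equal(sum(space$inertia_proportions), 1, tolerance = 1e-10)
  # mass-weighted centroid of rows sits at the origin
  F <- as.matrix(space$row_coordinates[-1])
  expect_equal(unname(colSums(F * space$row_masses)), rep(0, ncol(F)),
               tolerance = 1e-10)
  # scale invariance of the correspondence table
  coded3 <- coded
  coded3[-1] <- coded3[-1] * 3
  space3 <- correspondence_analysis(coded3)
  expect_equal(space3$inertia_proportions, space$inertia_proportions)
  expect_equal(space3$row_coordinates, space$row_coordinates)
  # light and dark vectors of one character are antipodal in column space
  G <- as.matrix(space$column_coordinates[-1])
  rownames(G) <- space$column_coordinates$variable
  for (nm in chars$name[1:5]) {
    expect_equal(
      cor(G[paste0(nm, ".light"), ], G[paste0(nm, ".dark"), ]), -1,
      tolerance = 1e-8)
  }
})

test_that("degenerate and invalid CA inputs are handled per contract", {
  chars <- tiny_characters()
  same <- tibble::tibble(id = c("a", "b", "c"), cap = "dark",
                         stripe = "mixed", band = "m2")
  space <- correspondence_analysis(encode_specimens(same, chars))
  expect_true(space$degenerate)
  expect_identical(space$n_dimensions, 0L)
  expect_equal(space$total_inertia, 0, tolerance = 1e-12)

  bad <- tibble::tibble(id = c("a", "b"), v1 = c(1, 2), v2 = c(-1, 3))
  expect_error(correspondence_analysis(bad), "non-negative")
  zero_col <- tibble::tibble(id = c("a", "b"), v1 = c(1, 2), v2 = c(0, 0))
  expect_error(correspondence_analysis(zero_col), "all-zero col")
})

test_that("MCA is the CA algorithm applied to the indicator matrix", {
  chars <- tiny_characters()
  sp <- random_specimens(chars, 25, seed = 10)
  ind <- build_indicator_matrix(sp, chars)
  mca <- multiple_correspondence_analysis(ind)
  ca_same <- correspondence_analysis(ind)
  expect_equal(mca$eigenvalues, ca_same$eigenvalues, tolerance = 1e-12)
  expect_equal(mca$total_inertia, ca_same$total_inertia)

  one <- colour_characters("c1", "head", list(c("a", "b")))
  mixed <- tibble::tibble(id = paste0("s", 1:6),
                          c1 = rep(c("a", "b"), 3))
  m1 <- multiple_correspondence_analysis(build_indicator_matrix(mixed, one))
  expect_identical(m1$n_dimensions, 1L)

  # identical specimens: zero inertia, flagged degenerate
  const <- tibble::tibble(id = paste0("s", 1:4), c1 = "a")
  m0 <- multiple_correspondence_analysis(build_indicator_matrix(const, one))
  expect_true(m0$degenerate)
  expect_equal(m0$total_inertia, 0)
  non_bin <- tibble::tibble(id = "x", v = 0.5)
  expect_error(multiple_correspondence_analysis(non_bin), "binary")
})

test_that("cross-validation separates disjoint morphs perfectly", {
  chars <- tiny_characters()
  sp <- withr::with_seed(11, {
    dark <- tibble::tibble(id = sprintf("d%02d", 1:15), cap = "dark",
                           stripe = sample(c("black", "mixed"), 15, TRUE),
                           band = sample(c("m2", "m3"), 15, TRUE))
    light <- tibble::tibble(id = sprintf("l%02d", 1:15), cap = "light",
                            stripe = "yellow",
                            band = sample(c("m0", "m1"), 15, TRUE))
    dplyr::bind_rows(dark, light)
  })
  space <- correspondence_analysis(encode_specimens(sp, chars))
  cv <- crossvalidate_morphs(space, rep(c("dark", "light"), each = 15))
  expect_identical(cv$accuracy, 1)
  expect_identical(cv$n_misclassified, 0L)
  conf <- tidyr::pivot_wider(cv$confusion, names_from = "predicted",
                             values_from = "n")
  expect_identical(sum(cv$confusion$n), 30L)
})

test_that("cross-validation is at chance on label-permuted data", {
  chars <- velutina_characters()
  sp <- random_specimens(chars, 90, seed = 12)
  space <- correspondence_analysis(encode_specimens(sp, chars))
  labels <- withr::with_seed(12, sample(rep(c("a", "b", "c"), 30)))
  cv <- crossvalidate_morphs(space, labels)
  # permutation expectation 1/3; generous simulation band
  expect_gt(cv$accuracy, 1 / 3 - 0.2)
  expect_lt(cv$accuracy, 1 / 3 + 0.2)
})

test_that("cross-validation input contracts are enforced", {
  chars <- tiny_characters()
  sp <- random_specimens(chars, 12, seed = 13)
  space <- correspondence_analysis(encode_specimens(sp, chars))
  expect_warning(
    cv <- crossvalidate_morphs(space, c(rep(c("a", "b"), 5), "a", "lone")),
    "lone")
  expect_identical(cv$n_total, 11L)
  expect_error(crossvalidate_morphs(space, rep("a", 12)), "two morphs")
  expect_error(crossvalidate_morphs(space, rep(c("a", "b"), 6),
                                    n_dims = 99), "n_dims")
  expect_error(crossvalidate_morphs(space, c("a", "b")), "length")
})

test_that("character vector correlations behave as correlations", {
  chars <- velutina_characters()
  sp <- latent_factor_specimens(chars, 200, seed = 14)
  space <- correspondence_analysis(encode_specimens(sp, chars))
  cc <- character_vector_correlations(space)
  expect_identical(dim(unclass(cc)), c(23L, 23L))
  expect_equal(unname(diag(unclass(cc))), rep(1, 23))
  expect_equal(unclass(cc), t(unclass(cc)))
  expect_true(all(abs(unclass(cc)) <= 1 + 1e-12))
  # a single latent melanisation factor makes all pairs positive
  expect_identical(integration_summary(cc)$fraction_positive, 1)
  # cosine variant is also a valid similarity with unit diagonal
  cos <- character_vector_correlations(space, method = "cosine")
  expect_equal(unname(diag(unclass(cos))), rep(1, 23))
})

test_that("duplicated characters correlate exactly at one", {
  chars <- colour_characters(
    c("c1", "c2", "c3"), "head",
    list(c("a", "b", "c"), c("a", "b", "c"), c("u", "v"))
  )
  sp <- random_specimens(chars, 40, seed = 15)
  sp$c2 <- sp$c1  # coded identically for every specimen
  space <- correspondence_analysis(encode_specimens(sp, chars))
  cc <- character_vector_correlations(space)
  expect_equal(unclass(cc)["c1", "c2"], 1, tolerance = 1e-8)
})

test_that("integration summary counts the strict upper triangle", {
  m <- matrix(c(1, 0.5, -0.2, 0.5, 1, 0.8, -0.2, 0.8, 1), 3, 3,
              dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  cc <- structure(m, class = c("character_correlations", "matrix"))
  s <- integration_summary(cc)
  expect_identical(s$n_pairs, 3L)
  expect_equal(s$fraction_positive, 2 / 3)
  expect_identical(s$negative_pairs$character1, "a")
  expect_identical(s$negative_pairs$character2, "c")

  all_pos <- structure(matrix(0.4, 2, 2, dimnames = list(c("a", "b"),
                                                         c("a", "b"))),
                       class = c("character_correlations", "matrix"))
  diag(all_pos) <- 1
  expect_identical(integration_summary(all_pos)$fraction_positive, 1)
  one_neg <- all_pos
  one_neg[1, 2] <- one_neg[2, 1] <- -0.4
  expect_identical(integration_summary(one_neg)$fraction_positive, 0)
})

test_that("independent characters show ~50% positive correlations", {
  chars <- velutina_characters()
  sp <- random_specimens(chars, 500, seed = 16)
  space <- correspondence_analysis(encode_specimens(sp, chars))
  fr <- integration_summary(character_vector_correlations(space))$fraction_positive
  expect_gt(fr, 0.35)
  expect_lt(fr, 0.65)
})

test_that("modularity clustering recovers planted character blocks", {
  # planted partition: 0.9 within blocks, 0 between
  blocks <- rep(1:2, each = 4)
  m <- outer(blocks, blocks, function(a, b) ifelse(a == b, 0.9, 0))
  diag(m) <- 1
  dimnames(m) <- list(paste0("ch", 1:8), paste0("ch", 1:8))
  cc <- structure(m, class = c("character_correlations", "matrix"))
  mod <- modularity_clusters(cc, 2)
  expect_identical(length(unique(mod$module[1:4])), 1L)
  expect_identical(length(unique(mod$module[5:8])), 1L)
  expect_false(mod$module[1] == mod$module[5])
  # boundary cuts
  expect_identical(unique(modularity_clusters(cc, 1)$module), 1L)
  expect_identical(sort(modularity_clusters(cc, 8)$module), 1:8)
  expect_error(modularity_clusters(cc, 9), "n_modules")
  expect_error(modularity_clusters(cc, 0), "n_modules")
})
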