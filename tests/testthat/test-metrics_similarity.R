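test_that("r_squared: squared Pearson by default, R2 flag available", {
  obs <- c(1, 2, 3, 4.5)
  expect_equal(r_squared(obs, obs), 1.0)
  expect_equal(r_squared(2 * obs + 1, obs), 1.0)       # affine invariance
  # textbook-formula oracle on a worked case
  o <- c(1, 2, 3); p <- c(1, 2, 2)
  num <- sum((p - mean(p)) * (o - mean(o)))
  want <- (num / sqrt(sum((p - mean(p))^2) * sum((o - mean(o))^2)))^2
  expect_equal(r_squared(p, o), want)
  expect_equal(r_squared(p, o, "determination"),
               1 - sum((o - p)^2) / sum((o - mean(o))^2))
  expect_error(r_squared(c(1, 2, 3), c(2, 2, 2)), "constant")
  expect_error(r_squared(c(1, 2), c(1, 2)), "3 pairs")
})

test_that("fold accuracy thresholds |log10 error| inclusively", {
  x <- c(0.1, -0.2, 0.05)
  expect_equal(fold_accuracy(x, x, 2), 1.0)
  expect_equal(fold_accuracy(log10(2), 0, 2), 1.0)     # boundary included
  # log10(2) ~ 0.3010, log10(3) ~ 0.4771: errors 0.2, 0.45, 1.0
  expect_equal(fold_accuracy(c(0.2, 0.45, 1.0), c(0, 0, 0), 2), 1 / 3)
  expect_equal(fold_accuracy(c(0.2, 0.45, 1.0), c(0, 0, 0), 3), 2 / 3)
  expect_error(fold_accuracy(numeric(), numeric(), 2), "empty")
  # 3-fold fraction dominates 2-fold on any input
  set.seed(2)
  for (i in 1:10) {
    p <- rnorm(20); o <- rnorm(20)
    expect_gte(fold_accuracy(p, o, 3), fold_accuracy(p, o, 2))
  }
})

test_that("evaluation report fields are consistent", {
  set.seed(3)
  o <- rnorm(50); p <- o + rnorm(50, sd = 0.3)
  rep <- evaluation_report(p, o)
  expect_equal(rep$std_error, sqrt(mean((p - o)^2)))
  expect_gte(rep$within_3fold, rep$within_2fold)
  expect_true(rep$r_squared >= 0 && rep$r_squared <= 1)
})

test_that("circular fingerprints are deterministic, order-free, radius-aware", {
  mols <- fixture_mols(4, seed = 111, size_range = c(6L, 10L))
  fp1 <- circular_fingerprint(mols[[1]])
  fp2 <- circular_fingerprint(mols[[1]])
  expect_identical(fp1, fp2)
  expect_gt(length(fp1), 0L)
  # atom order must not matter
  set.seed(7)
  perm <- sample(length(mols[[1]]$elements))
  fp_perm <- circular_fingerprint(permute_molecule(mols[[1]], perm))
  expect_identical(unclass(fp1), unclass(fp_perm))
  # radius 0 identifiers depend only on atom invariants: methane and
  # ethane carbons collide
  fpm <- circular_fingerprint(mol_methane(), radius = 0)
  fpe <- circular_fingerprint(mol_ethane(), radius = 0)
  expect_true(length(intersect(fpm, fpe)) > 0L)
  # deeper radius separates environments: distinct molecules get
  # distinct bit sets
  fpA <- circular_fingerprint(mols[[1]], radius = 2)
  fpB <- circular_fingerprint(mols[[2]], radius = 2)
  expect_false(identical(unclass(fpA), unclass(fpB)))
})

test_that("tanimoto agrees with brute-force set arithmetic", {
  A <- structure(c(1L, 5L, 9L, 20L), class = "fingerprint")
  B <- structure(c(5L, 9L, 77L), class = "fingerprint")
  expect_equal(tanimoto(A, B), 2 / (4 + 3 - 2))
  expect_equal(tanimoto(A, A), 1.0)
  expect_equal(tanimoto(A, structure(c(2L, 3L), class = "fingerprint")), 0.0)
  expect_error(tanimoto(integer(), integer()), "empty")
  set.seed(13)
  for (i in 1:25) {
    a <- sample(50, sample(1:20, 1))
    b <- sample(50, sample(1:20, 1))
    brute <- sum(a %in% b) / length(unique(c(a, b)))
    expect_equal(tanimoto(a, b), brute)
    expect_equal(tanimoto(a, b), tanimoto(b, a))
    expect_gte(tanimoto(a, b), 0); expect_lte(tanimoto(a, b), 1)
  }
})

test_that("confidence score is the max training similarity with neighbors", {
  mols <- fixture_mols(5, seed = 121, size_range = c(6L, 10L))
  train <- mols[1:4]
  # identical query: score 1, that molecule first
  cs <- confidence_score(mols[[2]], train)
  expect_equal(cs$score, 1.0)
  expect_equal(cs$neighbors$id[1], mols[[2]]$id)
  # training set of one: returned regardless of top_n
  cs1 <- confidence_score(mols[[5]], mols[1], top_n = 5)
  expect_equal(nrow(cs1$neighbors), 1L)
  # hand-built fingerprints with known similarities 0.4 / 0.7 / 0.1
  fpq <- structure(1:10, class = "fingerprint")
  fps <- list(structure(c(1:4, 11:16), class = "fingerprint"),   # 4/10? no:
              structure(c(1:7, 11:13), class = "fingerprint"),
              structure(c(1L, 11:19), class = "fingerprint"))
  # sim(q, fps[[1]]) = |{1:4}| / |{1:10,11:16}| = 4/16 = 0.25
  sims <- vapply(fps, tanimoto, numeric(1), fpB = fpq)
  cs2 <- confidence_score(fpq, fps, top_n = 3)
  expect_equal(cs2$score, max(sims))
  expect_equal(cs2$neighbors$index, order(-sims))
  expect_equal(cs2$neighbors$similarity, sort(sims, decreasing = TRUE))
})

test_that("similarity summaries match brute-force pair averages", {
  fps <- list(structure(c(1L, 2L, 3L), class = "fingerprint"),
              structure(c(2L, 3L, 4L), class = "fingerprint"),
              structure(c(9L, 10L), class = "fingerprint"))
  s12 <- tanimoto(fps[[1]], fps[[2]])   # 2/4
  s13 <- tanimoto(fps[[1]], fps[[3]])   # 0
  s23 <- tanimoto(fps[[2]], fps[[3]])   # 0
  within <- similarity_summary(fps)
  expect_equal(within$mean_pairwise, mean(c(s12, s13, s23)))
  expect_equal(within$mean_of_max, mean(c(s12, s12, 0)))
  q <- list(structure(c(1L, 9L), class = "fingerprint"))
  cross <- similarity_summary(q, fps)
  sims <- vapply(fps, tanimoto, numeric(1), fpA = q[[1]])
  expect_equal(cross$mean_pairwise, mean(sims))
  expect_equal(cross$mean_of_max, max(sims))
})

test_that("similarity binning reports per-bin n and R2 with a min-n rule", {
  set.seed(31)
  o <- rnorm(30); p <- o + rnorm(30, sd = 0.2)
  # all compounds in one bin: that bin's R2 equals the global R2
  sims <- rep(0.9, 30)
  tab <- similarity_bin_analysis(p, o, similarities = sims,
                                 breaks = c(0, 0.5, 1))
  expect_equal(tab$n, c(0L, 30L))
  expect_equal(tab$r_squared[2], r_squared(p, o))
  expect_true(is.na(tab$r_squared[1]))
  # a bin with 2 compounds is undefined, not a number
  sims2 <- c(rep(0.2, 2), rep(0.9, 28))
  tab2 <- similarity_bin_analysis(p, o, similarities = sims2,
                                  breaks = c(0, 0.5, 1))
  expect_equal(tab2$n[1], 2L)
  expect_true(is.na(tab2$r_squared[1]))
  # constructed data where the high-similarity bin is less noisy
  set.seed(41)
  o3 <- rnorm(60)
  noise <- c(rnorm(30, sd = 1.5), rnorm(30, sd = 0.1))
  p3 <- o3 + noise
  sims3 <- c(runif(30, 0.05, 0.45), runif(30, 0.55, 0.95))
  tab3 <- similarity_bin_analysis(p3, o3, similarities = sims3,
                                  breaks = c(0, 0.5, 1))
  expect_gt(tab3$r_squared[2], tab3$r_squared[1])
  expect_error(similarity_bin_analysis(p3, o3, similarities = sims3,
                                       breaks = c(0.2, 1)), "cover")
})

test_that("chronological split trains on the oldest compounds", {
  mols <- fixture_mols(100, seed = 131, size_range = c(5L, 7L))
  sp <- chronological_split(mols, 0.8)
  expect_length(sp$train, 80L)
  expect_length(sp$test, 20L)
  expect_lte(max(vapply(sp$train, function(m) as.numeric(m$date),
                        numeric(1))),
             min(vapply(sp$test, function(m) as.numeric(m$date),
                        numeric(1))))
  # partition: union is everything, intersection empty
  ids <- function(v) vapply(v, function(m) m$id, character(1))
  expect_setequal(c(ids(sp$train), ids(sp$test)), ids(mols))
  expect_length(intersect(ids(sp$train), ids(sp$test)), 0L)
  # input order does not matter, dates decide
  sp2 <- chronological_split(rev(mols), 0.8)
  expect_setequal(ids(sp2$train), ids(sp$train))
  # rounding: 5 compounds at 0.8 -> 4 train / 1 test
  sp5 <- chronological_split(mols[1:5], 0.8)
  expect_length(sp5$train, 4L)
  # missing dates error unless the fallback is requested
  undated <- lapply(mols[1:5], function(m) { m$date <- NULL; m })
  expect_error(chronological_split(undated, 0.8), "dates")
  sp3 <- chronological_split(undated, 0.8, allow_order_fallback = TRUE)
  expect_length(sp3$train, 4L)
})
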