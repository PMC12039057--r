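test_that("fbeta implements the displayed formula and its conventions", {
  # the worked candidate example: P = 11/16, R = 11/12, beta = 2
  expect_equal(fbeta(11 / 16, 11 / 12, 2), 0.859375)
  expect_equal(fbeta(11 / 16, 11 / 12, 2), oracle_fbeta(11 / 16, 11 / 12, 2),
               tolerance = 1e-15)
  expect_equal(fbeta(1, 1, 0.5), 1.0)
  expect_equal(fbeta(0, 0, 2), 0.0)
  x <- 0.37
  expect_equal(fbeta(x, x, 1), x) # harmonic-mean identity
  expect_error(fbeta(0.5, 0.5, 0), "beta")
  expect_error(fbeta(0.5, 0.5, -1), "beta")
})

test_that("fbeta agrees with the independent oracle on 1000 random triples", {
  set.seed(123)
  for (i in 1:1000) {
    p <- runif(1); r <- runif(1); b <- runif(1, 0.1, 5)
    expect_equal(fbeta(p, r, b), oracle_fbeta(p, r, b), tolerance = 1e-12)
  }
})

test_that("score_candidates applies occurrence, universal and top-10 rules", {
  # 45 spectra, group of 12; one signal in 16 spectra (11 in-group)
  ids <- sprintf("s%02d", 1:45)
  gids <- ids[1:12]
  m <- matrix(0, 45, 1, dimnames = list(ids, "F:124.0429"))
  m[c(1:11, 13:17), 1] <- 1 # 11 in-group + 5 out-group = 16 occurrences
  bsm <- make_signal_matrix(m, "fragment", 124.0429)
  out <- score_candidates(bsm, list(grp = gids))
  expect_equal(out$grp$precision, 11 / 16)
  expect_equal(out$grp$recall, 11 / 12)
  expect_equal(out$grp$fscore, fbeta(11 / 16, 11 / 12, 2))
  expect_false(out$grp$universal)

  # below the 3-occurrence floor -> not a candidate
  m2 <- matrix(0, 45, 1, dimnames = list(ids, "F:150.0000"))
  m2[1:2, 1] <- 1
  out2 <- score_candidates(make_signal_matrix(m2, "fragment", 150), list(grp = gids))
  expect_equal(nrow(out2$grp), 0L)

  # universal in a 5-member group, present in 40 others: retained anyway
  gids5 <- ids[1:5]
  m3 <- matrix(0, 45, 1, dimnames = list(ids, "F:180.0000"))
  m3[1:45, 1] <- 1
  out3 <- score_candidates(make_signal_matrix(m3, "fragment", 180), list(grp = gids5))
  expect_equal(nrow(out3$grp), 1L)
  expect_true(out3$grp$universal)
  expect_equal(out3$grp$precision, 5 / 45)

  # 12 non-universal candidates with distinct F2 -> exactly 10 survive
  gids13 <- ids[1:13]
  m4 <- matrix(0, 45, 12)
  for (j in 1:12) m4[c(seq_len(j), 14:21), j] <- 1 # tp = j < 13, fp = 8
  dimnames(m4) <- list(ids, sprintf("F:%.4f", 200 + 1:12))
  out4 <- score_candidates(make_signal_matrix(m4, rep("fragment", 12), 200 + 1:12),
                           list(grp = gids13))
  expect_equal(nrow(out4$grp), 10L)
  expect_equal(out4$grp$fscore, sort(out4$grp$fscore, decreasing = TRUE))

  expect_error(score_candidates(bsm, list(grp = c(gids, "nosuch"))), "absent")
})

test_that("min_score drops weak candidates", {
  ids <- sprintf("s%02d", 1:20)
  m <- matrix(0, 20, 2, dimnames = list(ids, c("F:100.0000", "F:200.0000")))
  m[c(1:5, 6:12), 1] <- 1  # strong: tp 5 of group 5, fp 7
  m[c(1, 6:12), 2] <- 1    # weak: tp 1, fp 7
  bsm <- make_signal_matrix(m, c("fragment", "fragment"), c(100, 200))
  out <- score_candidates(bsm, list(grp = ids[1:5]), min_score = 0.5)
  expect_equal(out$grp$mz, 100)
})

test_that("match_query uses AND semantics over fragments and losses", {
  s <- make_spectrum("x", 400.2000, c(144.0808, 250.0), c(1, 1))
  q_both <- data.frame(kind = c("fragment", "loss"), mz = c(144.0808, 150.2))
  expect_true(match_query(q_both, s))
  q_missing <- data.frame(kind = c("fragment", "loss"), mz = c(144.0808, 99.9))
  expect_false(match_query(q_missing, s))
  expect_error(match_query(data.frame(kind = character(0), mz = numeric(0)), s),
               "at least one")
  # a peak above the precursor never yields a loss
  s2 <- make_spectrum("y", 200.0, c(250.0), c(1))
  expect_false(match_query(data.frame(kind = "loss", mz = -50), s2))
})

test_that("a perfect candidate yields the single perfect query", {
  spectra <- c(
    lapply(1:6, function(i) make_spectrum(sprintf("g%d", i), 500,
                                          c(144.0808, 150 + i), c(1, 1),
                                          skeleton = "grp")),
    lapply(1:6, function(i) make_spectrum(sprintf("o%d", i), 500,
                                          c(200 + i), 1)))
  lib <- spectral_library(spectra)
  cand <- data.frame(kind = "fragment", mz = 144.0808, singleton_only = FALSE)
  out <- enumerate_and_score(cand, "grp", lib, min_group = 5)
  expect_length(out, 1L)
  expect_equal(out[[1]]$f05, 1.0)
  expect_equal(out[[1]]$precision, 1.0)
  expect_equal(out[[1]]$recall, 1.0)
  expect_equal(out[[1]]$counts, list(tp = 6, fp = 0, fn = 0, tn = 6))
})

test_that("disjoint perfect halves tie as singletons; their AND is excluded", {
  # group of 6: A covers the first half, B the second; no spectrum has both
  spectra <- c(
    lapply(1:3, function(i) make_spectrum(sprintf("a%d", i), 500, 111.1111, 1,
                                          skeleton = "grp")),
    lapply(1:3, function(i) make_spectrum(sprintf("b%d", i), 500, 222.2222, 1,
                                          skeleton = "grp")),
    lapply(1:4, function(i) make_spectrum(sprintf("o%d", i), 500, 300 + i, 1)))
  lib <- spectral_library(spectra)
  cand <- data.frame(kind = "fragment", mz = c(111.1111, 222.2222),
                     singleton_only = FALSE)
  out <- enumerate_and_score(cand, "grp", lib, min_group = 5)
  expect_length(out, 2L)
  for (q in out) {
    expect_equal(q$f05, (1.25 * 1 * 0.5) / (0.25 * 1 + 0.5), tolerance = 1e-12)
    expect_equal(nrow(q$signals), 1L)
  }
})

test_that("groups below the minimum size are skipped with a notice", {
  spectra <- c(
    lapply(1:3, function(i) make_spectrum(sprintf("g%d", i), 500, 100, 1,
                                          skeleton = "small")),
    lapply(1:3, function(i) make_spectrum(sprintf("o%d", i), 500, 200, 1)))
  lib <- spectral_library(spectra)
  cand <- data.frame(kind = "fragment", mz = 100, singleton_only = FALSE)
  expect_message(out <- enumerate_and_score(cand, "small", lib, min_group = 5),
                 "group size")
  expect_length(out, 0L)
  expect_error(enumerate_and_score(cand, "nosuch", lib), "unknown skeleton")
})

test_that("max_signals caps the enumerated subset size", {
  spectra <- lapply(1:8, function(i) {
    make_spectrum(sprintf("g%d", i), 600, 100 + (1:12) * 10, rep(1, 12),
                  skeleton = "grp")
  })
  lib <- spectral_library(spectra)
  cand <- data.frame(kind = "fragment", mz = 100 + (1:12) * 10,
                     singleton_only = FALSE)
  out <- enumerate_and_score(cand, "grp", lib, max_signals = 3, min_group = 5)
  expect_true(all(vapply(out, function(q) nrow(q$signals), integer(1)) <= 3))
})

test_that("enumerate_and_score matches the brute-force oracle (50 instances)", {
  set.seed(20240901)
  for (rep in 1:50) {
    inst <- random_instance(n_spectra = sample(8:20, 1),
                            n_candidates = sample(3:8, 1))
    out <- enumerate_and_score(inst$candidates, "grp", inst$library,
                               min_group = 5)
    oracle <- oracle_enumerate(inst$candidates, inst$library, inst$group_ids)
    if (oracle$best <= 0) {
      expect_length(out, 0L)
      next
    }
    expect_equal(out[[1]]$f05, oracle$best, tolerance = 1e-12)
    keys <- sort(vapply(out, function(q) {
      paste(sort(sprintf("%s:%.4f",
                         ifelse(q$signals$kind == "fragment", "F", "L"),
                         q$signals$mz)), collapse = "&")
    }, character(1)))
    expect_equal(keys, oracle$keys)
  }
})

test_that("retrieved sets are monotone under query growth", {
  set.seed(99)
  inst <- random_instance(n_spectra = 15, n_candidates = 6)
  lib <- inst$library
  cand <- inst$candidates
  for (rep in 1:20) {
    k <- sample(2:nrow(cand), 1)
    idx <- sample(nrow(cand), k)
    sub <- sample(idx, k - 1)
    r_small <- run_query(cand[sub, c("kind", "mz")], lib)
    r_big <- run_query(cand[idx, c("kind", "mz")], lib)
    expect_true(all(r_big %in% r_small))
    gs <- length(inst$group_ids)
    expect_lte(sum(r_big %in% inst$group_ids) / gs,
               sum(r_small %in% inst$group_ids) / gs)
  }
})

test_that("extract_signatures recovers planted signatures end to end", {
  sim <- simulate_library(simulation_config(seed = 7, n_groups = 3,
                                            members_per_group = 6,
                                            noise_peaks_per_spectrum = 15))
  res <- extract_signatures(sim$library)
  expect_setequal(names(res), names(sim$truth$planted))
  for (skel in names(res)) {
    expect_gt(length(res[[skel]]), 0L)
    planted <- sim$truth$planted[[skel]]
    for (q in res[[skel]]) {
      expect_equal(q$f05, 1.0)
      for (i in seq_len(nrow(q$signals))) {
        same_kind <- planted$mz[planted$kind == q$signals$kind[i]]
        expect_lte(min(abs(same_kind - q$signals$mz[i])), 0.011)
      }
    }
  }
})

test_that("an all-identical library makes every signal universal", {
  spectra <- lapply(1:8, function(i) {
    make_spectrum(sprintf("s%d", i), 400.5, c(120.5, 180.7, 240.9),
                  c(0.3, 1, 0.5), skeleton = if (i <= 5) "grp" else "other")
  })
  lib <- spectral_library(spectra)
  res <- suppressMessages(extract_signatures(lib, min_group = 5))
  cands <- attr(res, "candidates")$grp
  expect_true(all(cands$universal))
  # any query retrieves everything: precision = group/library ratio
  expect_equal(res$grp[[1]]$precision, 5 / 8)
  expect_equal(res$grp[[1]]$recall, 1.0)
})

test_that("a library with no groups yields an empty result", {
  lib <- spectral_library(list(make_spectrum("a", 300, 100),
                               make_spectrum("b", 300, 120)))
  expect_message(res <- extract_signatures(lib), "no skeleton groups")
  expect_length(res, 0L)
})

test_that("extraction is deterministic across runs", {
  sim <- simulate_library(simulation_config(seed = 13, n_groups = 2,
                                            members_per_group = 5,
                                            noise_peaks_per_spectrum = 10))
  r1 <- extract_signatures(sim$library)
  r2 <- extract_signatures(sim$library)
  expect_identical(r1, r2)
})

test_that("query tables serialize to TSV", {
  sim <- simulate_library(simulation_config(seed = 21, n_groups = 2,
                                            members_per_group = 5,
                                            noise_peaks_per_spectrum = 10))
  res <- extract_signatures(sim$library)
  path <- tempfile(fileext = ".tsv")
  write_queries_tsv(res, path)
  df <- read.delim(path)
  expect_true(all(c("skeleton", "signals", "f05") %in% names(df)))
  expect_gt(nrow(df), 0L)
})
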