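tol <- tolerance() # 10 mDa / 25 ppm

test_that("tolerance window takes the max of absolute and ppm components", {
  expect_equal(tol_window(tol, 400), 0.01) # components coincide at 400 Th
  expect_equal(tol_window(tol, 100), 0.01) # absolute dominates below
  expect_equal(tol_window(tol, 800), 0.02) # ppm dominates above
  expect_error(tolerance(absolute = 0), "absolute")
})

test_that("deisotope removes 13C isotopologues only when M is more intense", {
  s <- make_spectrum("a", 500, c(200.0000, 201.0034), c(1.0, 0.3))
  expect_equal(deisotope(s, tol)$peaks$mz, 200.0000)

  s2 <- make_spectrum("b", 500, c(200.0000, 201.0034), c(0.3, 1.0))
  expect_equal(deisotope(s2, tol)$peaks$mz, c(200.0000, 201.0034))

  # the +2 isotopologue is removed too
  s3 <- make_spectrum("c", 500, c(200.0000, 202.0067), c(1.0, 0.1))
  expect_equal(deisotope(s3, tol)$peaks$mz, 200.0000)

  s4 <- make_spectrum("d", 500, 150.1, 2)
  expect_equal(deisotope(s4, tol)$peaks, s4$peaks)
})

test_that("reduce_concurrent keeps the most intense, lower m/z on ties", {
  s <- make_spectrum("a", 500, c(100.0000, 100.0050), c(0.5, 0.9))
  expect_equal(reduce_concurrent(s, tol)$peaks$mz, 100.0050)

  s2 <- make_spectrum("b", 500, c(100.0000, 100.0300), c(0.5, 0.9))
  expect_equal(nrow(reduce_concurrent(s2, tol)$peaks), 2L)

  s3 <- make_spectrum("c", 500, c(100.0000, 100.0050), c(0.5, 0.5))
  expect_equal(reduce_concurrent(s3, tol)$peaks$mz, 100.0000)

  # chained cluster collapses to its single most intense member
  s4 <- make_spectrum("d", 500, c(100.000, 100.008, 100.016), c(1, 3, 2))
  out <- reduce_concurrent(s4, tol)
  expect_equal(out$peaks$mz, 100.008)
  gaps <- diff(out$peaks$mz)
  expect_true(all(gaps > tol_window(tol, out$peaks$mz[-nrow(out$peaks)])))
})

test_that("remove_precursor_region drops the boundary inclusively", {
  s <- make_spectrum("a", 353.1865, c(144.0808, 353.1865), c(1, 1))
  out <- remove_precursor_region(s)
  expect_equal(out$peaks$mz, 144.0808)

  s2 <- make_spectrum("b", 353.1865, c(144.0808, 200.1), c(1, 1))
  expect_equal(remove_precursor_region(s2)$peaks, s2$peaks)

  s3 <- make_spectrum("c", 100, c(100.0, 150.0), c(1, 1))
  out3 <- remove_precursor_region(s3)
  expect_equal(nrow(out3$peaks), 0L)
  expect_true(isTRUE(attr(out3, "empty_after_filtering")))
})

test_that("normalization scales to base peak and rejects zero spectra", {
  s <- make_spectrum("a", 500, c(100, 200), c(200, 50))
  expect_equal(normalize_spectrum(s)$peaks$intensity, c(1.0, 0.25))
  expect_equal(normalize_spectrum(make_spectrum("b", 500, 100, 7))$peaks$intensity, 1.0)
  expect_error(normalize_spectrum(make_spectrum("c", 500, c(1, 2), c(0, 0))),
               "zero")
})

test_that("compute_losses subtracts from the precursor, fragment-wise", {
  s <- make_spectrum("a", 400.2, c(150.0, 250.0, 300.1), c(0.2, 0.4, 1.0))
  l <- compute_losses(s)
  expect_equal(l$mz, c(250.2, 150.2, 100.1))
  expect_equal(l$intensity, s$peaks$intensity) # inherited
  expect_equal(nrow(compute_losses(make_spectrum("b", 400.2, numeric(0),
                                                 numeric(0)))), 0L)
})

test_that("harmonize merges within tolerance and matches the cluster oracle", {
  lib <- spectral_library(list(
    make_spectrum("a", 500, 212.0702, 1),
    make_spectrum("b", 500, 212.0708, 1)))
  m <- harmonize(lib, tol, "fragment")
  expect_equal(ncol(m$matrix), 1L)
  expect_gte(m$signals$mz, 212.0702)
  expect_lte(m$signals$mz, 212.0708)
  expect_length(oracle_cluster(c(212.0702, 212.0708)), 1L)

  lib2 <- spectral_library(list(
    make_spectrum("a", 500, 100.00, 1),
    make_spectrum("b", 500, 100.05, 1)))
  expect_equal(ncol(harmonize(lib2, tol, "fragment")$matrix), 2L)
  expect_length(oracle_cluster(c(100.00, 100.05)), 2L)

  lib3 <- spectral_library(list(
    normalize_spectrum(make_spectrum("a", 500, 300.1234, 42))))
  m3 <- harmonize(lib3, tol, "fragment")
  expect_equal(dim(m3$matrix), c(1L, 1L))
  expect_equal(unname(m3$matrix[1, 1]), 1.0)
})

test_that("harmonize clustering agrees with the brute-force oracle on a pool", {
  set.seed(7)
  vals <- sort(round(runif(60, 100, 120), 4))
  lib <- spectral_library(lapply(seq_along(vals), function(i) {
    make_spectrum(sprintf("s%02d", i), 500, vals[i], 1)
  }))
  m <- harmonize(lib, tol, "fragment")
  expect_equal(ncol(m$matrix), length(oracle_cluster(vals)))
})

test_that("representative m/z stays within tolerance of merged members", {
  sim <- simulate_library(simulation_config(seed = 3, n_groups = 2,
                                            members_per_group = 6))
  pre <- preprocess_library(sim$library)
  m <- harmonize(pre$library, tol, "fragment")
  # every non-zero cell's source spectrum holds a peak near the column m/z
  for (k in seq_len(ncol(m$matrix))) {
    rows <- which(m$matrix[, k] > 0)
    for (r in rows) {
      pk <- pre$library$spectra[[rownames(m$matrix)[r]]]$peaks$mz
      expect_lte(min(abs(pk - m$signals$mz[k])),
                 tol_window(tol, m$signals$mz[k]) + 5e-5)
    }
  }
})

test_that("the conditioning chain is idempotent and counts survive per row", {
  sim <- simulate_library(simulation_config(seed = 11, n_groups = 2,
                                            members_per_group = 5))
  pre1 <- preprocess_library(sim$library)
  pre2 <- preprocess_library(pre1$library)
  expect_equal(lapply(pre2$library$spectra, `[[`, "peaks"),
               lapply(pre1$library$spectra, `[[`, "peaks"))

  m <- harmonize(pre1$library, tol, "fragment")
  surviving <- vapply(pre1$library$spectra, function(s) nrow(s$peaks),
                      integer(1))
  expect_equal(unname(rowSums(m$matrix > 0)), unname(surviving))
})

test_that("harmonized column m/z is deterministic across runs", {
  sim <- simulate_library(simulation_config(seed = 5, n_groups = 2,
                                            members_per_group = 5))
  m1 <- harmonize(preprocess_library(sim$library)$library, tol, "fragment")
  m2 <- harmonize(preprocess_library(sim$library)$library, tol, "fragment")
  expect_identical(m1$signals$mz, m2$signals$mz)
})
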