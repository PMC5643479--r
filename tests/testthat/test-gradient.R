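test_that("percent-of-gradient normalization sums to 100 and scales linearly", {
  pr <- uniform_profile(n = 4)
  norm <- normalize_profile(pr)
  expect_equal(norm$dna_percent, rep(25, 4))
  expect_equal(sum(norm$dna_percent), 100, tolerance = 1e-11)
  expect_equal(sum(norm$copies_percent), 100, tolerance = 1e-11)

  pr3 <- fraction_profile(tibble::tibble(
    fraction_index = 1:3, density_g_ml = c(1.74, 1.72, 1.70),
    dna_ng = c(10, 30, 60), copies_16s = c(1, 1, 2)
  ))
  norm3 <- normalize_profile(pr3)
  expect_equal(norm3$dna_percent, c(10, 30, 60))
  expect_equal(norm3$copies_percent, c(25, 25, 50))

  zero <- fraction_profile(tibble::tibble(
    fraction_index = 1:2, density_g_ml = c(1.72, 1.70),
    dna_ng = c(0, 0), copies_16s = c(1, 1)
  ))
  expect_error(normalize_profile(zero), "All-zero DNA")
})

test_that("profiles validate ordering, index and density invariants", {
  expect_error(fraction_profile(tibble::tibble(
    fraction_index = c(1, 1), density_g_ml = c(1.72, 1.70),
    dna_ng = 1, copies_16s = 1
  )), "Duplicate")
  expect_error(fraction_profile(tibble::tibble(
    fraction_index = 1:2, density_g_ml = c(1.9, 1.7),
    dna_ng = 1, copies_16s = 1
  )), "1.60, 1.80")
  # top-first input is repaired with a warning, preserving the data
  expect_warning(
    pr <- fraction_profile(tibble::tibble(
      fraction_index = 1:3, density_g_ml = c(1.70, 1.72, 1.74),
      dna_ng = c(5, 10, 20), copies_16s = c(1, 2, 4)
    )),
    "top-first"
  )
  expect_equal(pr$density_g_ml, c(1.74, 1.72, 1.70))
  expect_equal(pr$dna_ng, c(20, 10, 5))
  expect_equal(pr$fraction_index, 1:3)
})

test_that("pooling assigns fractions to density windows with dense-side-closed boundaries", {
  pr <- normalize_profile(uniform_profile(n = 12, dmin = 1.66, dmax = 1.78))
  scheme <- pooling_scheme(
    name = c("lower", "medium", "upper"),
    low = c(1.74, 1.70, 1.66), high = c(1.78, 1.74, 1.70),
    dense = c(TRUE, TRUE, FALSE)
  )
  pooled <- pool_fractions(pr, scheme)
  expect_equal(pooled$dna_percent, rep(100 / 3, 3), tolerance = 1e-9)
  expect_equal(pooled$n_fractions, rep(4L, 3))
  expect_equal(sum(pooled$copies_percent), 100, tolerance = 1e-9)

  # single whole-range window
  whole <- pooling_scheme("all", 1.66, 1.78, TRUE)
  expect_equal(pool_fractions(pr, whole)$dna_percent, 100, tolerance = 1e-11)

  # a fraction exactly on a shared boundary goes to the denser window
  pr2 <- normalize_profile(fraction_profile(tibble::tibble(
    fraction_index = 1:2, density_g_ml = c(1.74, 1.70),
    dna_ng = c(1, 1), copies_16s = c(1, 1)
  )))
  pooled2 <- pool_fractions(pr2, scheme)
  expect_equal(pooled2$dna_percent[pooled2$pool == "lower"], 50)   # 1.74 tie -> dense
  expect_equal(pooled2$dna_percent[pooled2$pool == "medium"], 50)  # 1.70 tie -> denser of the two
})

test_that("fractions outside every window are reported as unpooled, percents conserved", {
  pr <- normalize_profile(uniform_profile(n = 12, dmin = 1.66, dmax = 1.78))
  narrow <- pooling_scheme(c("lower", "medium"), c(1.74, 1.72), c(1.78, 1.74),
                           dense = c(TRUE, FALSE))
  expect_message(pooled <- pool_fractions(pr, narrow), "unpooled")
  unpooled <- attr(pooled, "unpooled")
  expect_equal(sum(pooled$dna_percent) + sum(unpooled$dna_percent), 100,
               tolerance = 1e-9)
  expect_equal(sum(pooled$copies_percent) + sum(unpooled$copies_percent), 100,
               tolerance = 1e-9)
  none <- pooling_scheme("x", 1.781, 1.80, TRUE)
  expect_error(pool_fractions(pr, none), "zero fractions")
})

test_that("pooling percents are invariant to re-normalizing a pooled-then-flattened profile", {
  pr <- normalize_profile(uniform_profile(n = 12, dna = rgamma(12, 2) + 0.1))
  scheme <- default_pooling_scheme("cellulose")
  p1 <- pool_fractions(pr, scheme)
  # flatten each pool into one synthetic fraction and re-pool
  flat <- fraction_profile(tibble::tibble(
    fraction_index = seq_len(nrow(p1)),
    density_g_ml = (scheme$low + scheme$high) / 2,
    dna_ng = p1$dna_percent, copies_16s = pmax(p1$copies_percent, 1e-9)
  ))
  p2 <- pool_fractions(normalize_profile(flat), scheme)
  expect_equal(p2$dna_percent, p1$dna_percent, tolerance = 1e-9)
})

test_that("density shift is the DNA-weighted mean density difference", {
  pr <- normalize_profile(uniform_profile(n = 12))
  expect_equal(density_shift(pr, pr), 0)

  # all DNA moved one fraction denser on a uniform 0.004 g/ml spacing
  n <- 6
  dens <- seq(1.76, by = -0.004, length.out = n)
  ctl <- normalize_profile(fraction_profile(tibble::tibble(
    fraction_index = 1:n, density_g_ml = dens,
    dna_ng = c(0, 10, 20, 30, 20, 10), copies_16s = 1
  )))
  lab <- normalize_profile(fraction_profile(tibble::tibble(
    fraction_index = 1:n, density_g_ml = dens,
    dna_ng = c(10, 20, 30, 20, 10, 0), copies_16s = 1
  )))
  expect_equal(density_shift(lab, ctl), 0.004, tolerance = 1e-12)

  # control uniform, labeled all in densest fraction
  ctl_u <- normalize_profile(fraction_profile(tibble::tibble(
    fraction_index = 1:n, density_g_ml = dens, dna_ng = 1, copies_16s = 1
  )))
  lab_d <- normalize_profile(fraction_profile(tibble::tibble(
    fraction_index = 1:n, density_g_ml = dens,
    dna_ng = c(1, rep(0, n - 1)), copies_16s = 1
  )))
  expect_equal(density_shift(lab_d, ctl_u), dens[1] - mean(dens),
               tolerance = 1e-12)
})

test_that("simulated labeling yields a positive density shift", {
  for (iso in c("13C", "15N")) {
    taxa <- default_community(n_taxa = 10, n_labeled = 3, atom_excess = 0.7,
                              seed = 4)
    d <- simulate_sip_dataset(sim_config(taxa = taxa, isotope = iso,
                                         reads_per_pool = 1000, seed = 4))
    shift <- density_shift(normalize_profile(d$labeled_profile),
                           normalize_profile(d$control_profile))
    expect_gt(shift, 0)
  }
})

test_that("gradient geometry: collection volumes determine fraction counts", {
  expect_identical(n_collected_fractions(4.8, 400), 12L)
  expect_identical(n_collected_fractions(4.8, 200), 24L)
  expect_error(n_collected_fractions(0, 400), "positive")
})
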