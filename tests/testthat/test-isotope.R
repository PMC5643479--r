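test_that("delta notation matches its defining formula and inverts exactly", {
  expect_equal(delta_from_ratio(0.003676, 0.003676), 0)
  expect_equal(delta_from_ratio(1.02 * 0.003676, 0.003676), 20,
               tolerance = 1e-12)
  set.seed(2)
  r <- runif(50, 0.001, 0.01)
  s <- runif(50, 0.001, 0.01)
  expect_equal(ratio_from_delta(delta_from_ratio(r, s), s), r,
               tolerance = 1e-12)
  # strictly increasing in the sample ratio
  expect_true(all(diff(delta_from_ratio(sort(r), 0.003676)) > 0))
  expect_error(delta_from_ratio(-1, 0.003676), "positive")
})

test_that("two-point normalization is affine and maps anchors exactly to certified values", {
  anchors <- iaea_anchors(measured = c(0.20, 19.90))
  expect_equal(two_point_normalize(0.20, anchors), 0.43, tolerance = 1e-12)
  expect_equal(two_point_normalize(19.90, anchors), 20.40, tolerance = 1e-12)
  # hand-solved two-point line: measured (0, 20) -> certified (0.43, 20.40)
  expect_equal(two_point_normalize(10, iaea_anchors(measured = c(0, 20))),
               10.415, tolerance = 1e-12)
  # anchors already on the certified scale: identity map
  ident <- iaea_anchors()
  expect_equal(two_point_normalize(c(-5, 0, 7.3), ident), c(-5, 0, 7.3))
  # affinity: three collinear probes stay collinear
  cal <- two_point_normalize(c(1, 2, 3), anchors)
  expect_equal(cal[2] - cal[1], cal[3] - cal[2], tolerance = 1e-12)
  bad <- iaea_anchors(measured = c(5, 5))
  expect_error(two_point_normalize(1, bad), "coincide")
})

test_that("a working-standard chain composes two affine calibrations", {
  # sample measured against lab standard; lab standard anchored to IAEA
  lab_anchors <- tibble::tibble(name = c("wk1", "wk2"),
                                certified_delta = c(-1.44, 10),
                                measured_delta = c(-1.0, 10.6))
  iaea <- iaea_anchors(measured = c(0.30, 20.10))
  chained <- two_point_normalize(two_point_normalize(5, lab_anchors), iaea)
  # equivalent single affine map computed by hand
  m1 <- (10 - (-1.44)) / (10.6 - (-1.0))
  b1 <- -1.44 - m1 * (-1.0)
  m2 <- (20.40 - 0.43) / (20.10 - 0.30)
  b2 <- 0.43 - m2 * 0.30
  expect_equal(chained, m2 * (m1 * 5 + b1) + b2, tolerance = 1e-12)
})

test_that("technical replicates average per biological replicate", {
  data <- tibble::tibble(
    sample_id = "s", tissue = "gut", life_stage = "larva",
    treatment = "15N", bio_rep = rep(1:2, each = 3), tech_rep = rep(1:3, 2),
    delta_per_mil = c(5, 5, 5, 4, 5, 6)
  )
  agg <- aggregate_technical(data)
  expect_equal(nrow(agg), 2)
  expect_equal(agg$delta_per_mil, c(5, 5))
  expect_equal(agg$n_technical, c(3L, 3L))
  # grand mean of per-replicate means equals pooled mean for equal tech counts
  expect_equal(mean(agg$delta_per_mil), mean(data$delta_per_mil))
  expect_error(aggregate_technical(data[, -3]), "Missing IRMS columns")
})

test_that("Mann-Whitney exact p enumerates rank assignments, including full separation", {
  # fully separated n = 3 vs 3: U = 9, one-sided 1/20, two-sided 2/20
  res_g <- mann_whitney_u(c(10, 11, 12), c(1, 2, 3), "greater")
  res_t <- mann_whitney_u(c(10, 11, 12), c(1, 2, 3), "two.sided")
  expect_equal(res_g$U, 9)
  expect_equal(res_g$p, 0.05, tolerance = 1e-12)
  expect_equal(res_t$p, 0.10, tolerance = 1e-12)
  # identical tied groups: no separation, two-sided p = 1
  expect_equal(mann_whitney_u(c(1, 2, 3), c(1, 2, 3), "two.sided")$p, 1)
  # cross-check against the reference implementation on tie-free data
  set.seed(6)
  for (i in 1:40) {
    n1 <- sample(2:6, 1)
    n2 <- sample(2:6, 1)
    x <- runif(n1)
    y <- runif(n2)
    for (alt in c("two.sided", "greater", "less")) {
      ours <- mann_whitney_u(x, y, alt)
      ref <- suppressWarnings(stats::wilcox.test(x, y, alternative = alt,
                                                 exact = TRUE))
      expect_equal(ours$U, unname(ref$statistic))
      expect_equal(ours$p, ref$p.value, tolerance = 1e-12)
    }
  }
  expect_error(mann_whitney_u(numeric(0), 1:3), "non-empty")
})

test_that("normal approximation agrees with exact enumeration at n = 8 per group", {
  set.seed(17)
  diffs <- replicate(100, {
    x <- rnorm(8)
    y <- rnorm(8, 0.5)
    exact <- mann_whitney_u(x, y, "two.sided", exact_limit = 8)$p
    approx <- mann_whitney_u(x, y, "two.sided", exact_limit = 0)$p
    abs(exact - approx)
  })
  expect_lt(max(diffs), 0.02)
})

test_that("U and p are invariant to adding a constant to all deltas", {
  set.seed(8)
  x <- rnorm(5)
  y <- rnorm(6)
  a <- mann_whitney_u(x, y, "two.sided")
  b <- mann_whitney_u(x + 13.7, y + 13.7, "two.sided")
  expect_equal(a$U, b$U)
  expect_equal(a$p, b$p)
})

test_that("treatment comparison reports mean, SEM and both sidedness p-values", {
  data <- tibble::tibble(
    tissue = rep(c("gut", "fat_body"), each = 6),
    life_stage = "larva",
    treatment = rep(rep(c("15N", "14N"), each = 3), 2),
    bio_rep = rep(1:3, 4),
    delta_per_mil = c(2, 4, 6, 0.1, 0.2, 0.3,   # gut: separated
                      1.0, 1.1, 1.2, 1.05, 1.15, 1.25)  # fat body: interleaved
  )
  res <- compare_treatments(data)
  gut <- res[res$tissue == "gut", ]
  expect_equal(gut$mean_15N, 4)
  expect_equal(gut$sem_15N, 2 / sqrt(3), tolerance = 1e-12)  # sd of (2,4,6) = 2
  expect_equal(gut$p_one_sided, 0.05, tolerance = 1e-12)
  expect_equal(gut$p_two_sided, 0.10, tolerance = 1e-12)
  expect_true(gut$significant)
  fat <- res[res$tissue == "fat_body", ]
  expect_false(fat$significant)
  # two-sided calls can never reach 0.05 with n = 3 per group
  res2 <- compare_treatments(data, sidedness = "two.sided")
  expect_false(any(res2$significant[res2$tissue == "gut"]))
  expect_error(
    compare_treatments(data[data$bio_rep == 1, ]),
    "at least 2"
  )
})
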