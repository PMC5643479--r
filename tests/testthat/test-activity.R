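test_that("relative abundance normalizes each library to 100 percent", {
  tab <- tibble::tibble(taxon = c("a", "b", "c", "d"), s1 = c(1, 2, 3, 4))
  expect_equal(relative_abundance(tab)$s1, c(10, 20, 30, 40))
  one <- tibble::tibble(taxon = "a", s1 = 7)
  expect_equal(relative_abundance(one)$s1, 100)
  zero <- tibble::tibble(taxon = c("a", "b"), s1 = c(0, 0))
  expect_error(relative_abundance(zero), "zero total")
})

test_that("activity equals the difference of percent relative abundances", {
  lab <- tibble::tibble(taxon = c("a", "b"), pool = c(30, 70))
  ctl <- tibble::tibble(taxon = c("a", "b"), pool = c(10, 90))
  act <- compute_activity(lab, ctl, dense_pools = "pool")
  expect_equal(act$A[act$taxon == "a"], 20)
  expect_equal(act$A[act$taxon == "b"], -20)
  # identical tables: all A zero, Fisher p = 1
  act0 <- compute_activity(lab, lab, dense_pools = "pool")
  expect_equal(act0$A, c(0, 0))
  expect_equal(act0$p, c(1, 1))
})

test_that("activity sums to zero per dense pool and is antisymmetric under treatment swap", {
  for (seed in 1:5) {
    pair <- random_pair(seed)
    fwd <- compute_activity(pair$labeled, pair$control)
    bwd <- compute_activity(pair$control, pair$labeled)
    sums <- tapply(fwd$A, fwd$pool, sum)
    expect_true(all(abs(sums) < 1e-9))
    merged <- dplyr::inner_join(
      tidy(fwd), tidy(bwd), by = c("taxon", "pool"), suffix = c("_f", "_b")
    )
    expect_equal(merged$A_f, -merged$A_b, tolerance = 1e-12)
    expect_equal(merged$p_f, merged$p_b, tolerance = 1e-12)
  }
})

test_that("taxa absent from one table are zero-filled; absent from both are dropped", {
  lab <- tibble::tibble(taxon = c("a", "b", "ghost"), pool = c(30, 70, 0))
  ctl <- tibble::tibble(taxon = c("a", "c", "ghost"), pool = c(50, 50, 0))
  act <- compute_activity(lab, ctl, dense_pools = "pool")
  expect_setequal(act$taxon, c("a", "b", "c"))
  expect_equal(act$tNS_control[act$taxon == "b"], 0)
  expect_equal(act$tNS_labeled[act$taxon == "c"], 0)
  expect_error(compute_activity(lab, ctl, dense_pools = "nope"), "missing")
})

test_that("Fisher exact p matches closed forms and the reference implementation", {
  expect_equal(fisher_enrichment_p(5, 100, 5, 100), 1)
  expect_equal(fisher_enrichment_p(10, 10, 0, 10), 2 / choose(20, 10),
               tolerance = 1e-12)
  set.seed(42)
  for (i in 1:200) {
    n1 <- sample(1:40, 1)
    n2 <- sample(1:40, 1)
    t1 <- sample(0:n1, 1)
    t2 <- sample(0:n2, 1)
    ours <- fisher_enrichment_p(t1, n1, t2, n2)
    ref <- stats::fisher.test(matrix(c(t1, n1 - t1, t2, n2 - t2), 2,
                                     byrow = TRUE))$p.value
    expect_equal(ours, ref, tolerance = 1e-12)
  }
  expect_error(fisher_enrichment_p(-1, 10, 0, 10), "non-negative")
  expect_error(fisher_enrichment_p(11, 10, 0, 10), "exceed")
})

test_that("BH adjustment matches a naive step-up oracle and permutes with its input", {
  expect_equal(bh_fdr(0.03), 0.03)
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  naive_bh <- function(p) {
    m <- length(p)
    o <- order(p)
    q <- p[o] * m / seq_len(m)
    q <- rev(cummin(rev(q)))
    pmin(q, 1)[order(o)]
  }
  set.seed(9)
  for (i in 1:20) {
    p <- runif(sample(1:50, 1))
    expect_equal(bh_fdr(p), naive_bh(p), tolerance = 1e-12)
    perm <- sample(seq_along(p))
    expect_equal(bh_fdr(p[perm]), bh_fdr(p)[perm], tolerance = 1e-12)
  }
  p <- runif(30)
  expect_true(all(bh_fdr(p) >= p))
  expect_error(bh_fdr(numeric(0)), "Empty")
})

test_that("rank collapsing sums counts, preserves totals and is idempotent", {
  tab <- tiny_count_table()
  fam <- collapse_rank(tab, "family")
  expect_setequal(fam$taxon, c("Lachnospiraceae", "Enterobacteriaceae",
                               "unclassified Clostridiales"))
  for (s in c("medium", "lower")) {
    expect_equal(sum(fam[[s]]), sum(tab[[s]]))
  }
  expect_equal(fam$medium[fam$taxon == "Lachnospiraceae"],
               tab$medium[tab$taxon == "tA"])
  # idempotence
  fam2 <- collapse_rank(fam, "family")
  expect_equal(fam2[order(fam2$taxon), c("taxon", "medium", "lower")],
               fam[order(fam$taxon), c("taxon", "medium", "lower")])
  # two genera of one family sum
  two <- tibble::tibble(
    taxon = c("g1", "g2"),
    s = c(10, 20),
    lineage = rep("k__Bacteria; p__P; c__C; o__O; f__F; g__X", 2)
  )
  two$lineage[2] <- "k__Bacteria; p__P; c__C; o__O; f__F; g__Y"
  expect_equal(collapse_rank(two, "family")$s, 30)
  expect_error(collapse_rank(two, "strain"), "Unknown rank")
})

test_that("significance tiers follow the heatmap legend convention", {
  lab <- tibble::tibble(taxon = letters[1:4], pool = c(4000, 100, 60, 40))
  ctl <- tibble::tibble(taxon = letters[1:4], pool = c(2000, 1100, 550, 550))
  act <- compute_activity(lab, ctl, dense_pools = "pool")
  expect_true(all(act$tier[act$q < 0.01] == "p<0.01"))
  expect_true(all(act$symbol[act$q < 0.01] == "**"))
  expect_true(all(act$symbol[act$q >= 0.1] == ""))
  # q is never below p under step-up adjustment
  expect_true(all(act$q >= act$p))
})

test_that("heatmap matrices mirror the activity records", {
  pair <- random_pair(3, n_taxa = 5)
  act <- compute_activity(pair$labeled, pair$control)
  hm <- activity_heatmap_matrix(act)
  expect_equal(dim(hm$values), c(5, 2))
  for (i in seq_len(nrow(act))) {
    expect_equal(hm$values[act$taxon[i], act$pool[i]], act$A[i])
    expect_equal(hm$annotations[act$taxon[i], act$pool[i]], act$symbol[i])
  }
  dup <- dplyr::bind_rows(act, act[1, ])
  expect_error(activity_heatmap_matrix(dup), "Duplicate")
})

test_that("activity ranking sorts by max A with lexicographic tie-break", {
  records <- tibble::tibble(
    taxon = c("b", "a", "c"), pool = "lower",
    A = c(5, 5, 1), p = 0.01, q = c(0.02, 0.03, 0.5)
  )
  ranked <- rank_activity(records)
  expect_equal(ranked$taxon, c("a", "b", "c"))
  expect_equal(ranked$max_A, c(5, 5, 1))
})

test_that("halving sequencing depth preserves expected activity but widens p-values", {
  taxa <- default_community(n_taxa = 12, n_labeled = 2, atom_excess = 0.6,
                            seed = 21)
  target <- taxa$name[taxa$atom_excess_labeled > 0][1]
  mean_abs_a <- function(reads, seeds) {
    vals <- purrr::map_dbl(seeds, function(s) {
      d <- simulate_sip_dataset(sim_config(taxa = taxa, reads_per_pool = reads,
                                           seed = s))
      act <- compute_activity(d$labeled_counts, d$control_counts,
                              dense_pools = "medium")
      act$A[act$taxon == target]
    })
    mean(vals)
  }
  full <- mean_abs_a(20000, 1:15)
  half <- mean_abs_a(10000, 1:15)
  expect_equal(full, half, tolerance = 0.25)
})
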