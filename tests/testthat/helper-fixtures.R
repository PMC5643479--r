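# Small in-code fixtures shared across test files.

tiny_count_table <- function(pools = c("medium", "lower")) {
  counts <- list(
    tA = c(30, 10), tB = c(50, 60), tC = c(20, 30)
  )
  df <- tibble::tibble(
    taxon = names(counts),
    lineage = c(
      "k__Bacteria; p__Firmicutes; c__Clostridia; o__Clostridiales; f__Lachnospiraceae; g__Blautia",
      "k__Bacteria; p__Proteobacteria; c__Gammaproteobacteria; o__Enterobacteriales; f__Enterobacteriaceae; g__Serratia",
      "k__Bacteria; p__Firmicutes; c__Clostridia; o__Clostridiales; f__"
    )
  )
  for (i in seq_along(pools)) {
    df[[pools[i]]] <- unname(vapply(counts, `[`, numeric(1), i))
  }
  df[c("taxon", pools, "lineage")]
}

uniform_profile <- function(n = 12, dna = rep(10, n), copies = dna * 1e5,
                            dmin = 1.66, dmax = 1.78) {
  w <- (dmax - dmin) / n
  dens <- dmax - w * (seq_len(n) - 1) - w / 2
  fraction_profile(tibble::tibble(
    fraction_index = seq_len(n), density_g_ml = dens,
    dna_ng = dna, copies_16s = copies
  ))
}

# paired random count tables over the same pools (used by zero-sum and
# antisymmetry properties)
random_pair <- function(seed, n_taxa = 12, pools = c("medium", "lower"),
                        depth = 2000) {
  set.seed(seed)
  mk <- function() {
    df <- tibble::tibble(taxon = sprintf("t%02d", seq_len(n_taxa)))
    for (p in pools) {
      df[[p]] <- as.integer(rmultinom(1, depth, rgamma(n_taxa, 1)))
    }
    df
  }
  list(labeled = mk(), control = mk())
}
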