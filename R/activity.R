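# Per-taxon activity in dense pooled fractions: relative-abundance
# enrichment of the labeled gradient over the control gradient, with Fisher
# exact significance and Benjamini-Hochberg FDR control.

#' Relative abundances as percent of total sequences
#'
#' Normalizes each sample column of a count table to percentages of the
#' column total, correcting for library-size differences.
#'
#' @param table Count table: `taxon` column, one numeric column per sample,
#'   optional `lineage` column.
#' @return The table with sample columns replaced by percentages; each
#'   column sums to 100.
#' @export
relative_abundance <- function(table) {
  assert_count_table(table)
  for (s in sample_cols(table)) {
    tot <- sum(table[[s]])
    if (tot <= 0) abort(sprintf("Sample `%s` has zero total count.", s))
    table[[s]] <- 100 * table[[s]] / tot
  }
  table
}

#' Collapse a count table to a taxonomic rank
#'
#' Sums counts over all taxa sharing a value at `rank`. Taxa unresolved at
#' that rank are grouped as `"unclassified <parent>"`, where the parent is
#' the nearest resolved higher rank (e.g. "unclassified Clostridiales").
#' Column totals are preserved.
#'
#' @param table Count table with a `lineage` column.
#' @param rank One of `"phylum"`, `"class"`, `"order"`, `"family"`,
#'   `"genus"`.
#' @return Collapsed count table whose `taxon` column holds rank values
#'   and whose `lineage` is truncated at `rank`.
#' @export
collapse_rank <- function(table, rank = "family") {
  if (!rank %in% TAXONOMIC_RANKS[-1L]) {
    abort(sprintf("Unknown rank `%s`; use one of %s.", rank,
                  paste(TAXONOMIC_RANKS[-1L], collapse = ", ")))
  }
  assert_count_table(table)
  if (!"lineage" %in% names(table)) abort("`table` needs a `lineage` column to collapse.")
  ranks <- parse_lineage(table$lineage)
  ridx <- match(rank, TAXONOMIC_RANKS)
  label <- ranks[[rank]]
  for (i in which(is.na(label))) {
    parents <- unlist(ranks[i, seq_len(ridx - 1L)])
    resolved <- parents[!is.na(parents) & !startsWith(parents, "unclassified ")]
    parent <- if (length(resolved)) resolved[length(resolved)] else "Root"
    label[i] <- paste0("unclassified ", parent)
  }
  # truncated lineage for each collapsed group: ranks above `rank` that are
  # constant within the group are kept, the rest blanked
  ranks[[rank]] <- label
  upper <- TAXONOMIC_RANKS[seq_len(ridx)]
  sc <- sample_cols(table)
  grouped <- dplyr::bind_cols(tibble(.group = label), table[sc], ranks[upper]) |>
    group_by(.data$.group) |>
    summarise(
      across(all_of(sc), sum),
      dplyr::across(all_of(upper), ~ if (dplyr::n_distinct(.x) == 1L) .x[1L] else NA_character_),
      .groups = "drop"
    )
  grouped[[rank]] <- grouped$.group
  out <- grouped |>
    mutate(taxon = .data$.group, lineage = make_lineage(grouped[upper], upto = rank)) |>
    select(all_of(c("taxon", sc, "lineage"))) |>
    arrange(.data$taxon)
  out
}

#' Two-sided Fisher exact p-value for taxon enrichment
#'
#' Tests the 2x2 table `[[tNS_lab, NS_lab - tNS_lab], [tNS_ctl, NS_ctl -
#' tNS_ctl]]` contrasting a taxon's sequence counts against the remainder
#' of the library in the labeled and control pooled fractions. The
#' two-sided p-value sums all hypergeometric table probabilities not
#' exceeding the observed table's probability (with a relative tie
#' tolerance of 1e-7 against floating-point rank flips).
#'
#' @param t_lab,n_lab Taxon count and library total in the labeled pool.
#' @param t_ctl,n_ctl Taxon count and library total in the control pool.
#' @return The two-sided p-value (vectorized over the four arguments).
#' @export
fisher_enrichment_p <- function(t_lab, n_lab, t_ctl, n_ctl) {
  args <- vctrs_recycle(t_lab, n_lab, t_ctl, n_ctl)
  purrr::pmap_dbl(args, fisher_p_one)
}

vctrs_recycle <- function(t_lab, n_lab, t_ctl, n_ctl) {
  n <- max(length(t_lab), length(n_lab), length(t_ctl), length(n_ctl))
  list(t_lab = rep_len(t_lab, n), n_lab = rep_len(n_lab, n),
       t_ctl = rep_len(t_ctl, n), n_ctl = rep_len(n_ctl, n))
}

fisher_p_one <- function(t_lab, n_lab, t_ctl, n_ctl) {
  if (any(c(t_lab, n_lab, t_ctl, n_ctl) < 0)) abort("Counts must be non-negative.")
  if (t_lab > n_lab || t_ctl > n_ctl) abort("Taxon counts cannot exceed library totals.")
  k_total <- t_lab + t_ctl
  support <- max(0, k_total - n_ctl):min(k_total, n_lab)
  d <- dhyper(support, n_lab, n_ctl, k_total)
  d_obs <- dhyper(t_lab, n_lab, n_ctl, k_total)
  min(1, sum(d[d <= d_obs * (1 + 1e-7)]))
}

#' Benjamini-Hochberg false discovery rate adjustment
#'
#' Step-up adjusted p-values (q-values): monotone in p-value rank, `q >= p`
#' and `q <= 1`.
#'
#' @param p Vector of p-values in \[0, 1\].
#' @return Adjusted q-values in the original order.
#' @export
bh_fdr <- function(p) {
  if (length(p) == 0L) abort("Empty p-value vector.")
  if (any(p < 0 | p > 1, na.rm = TRUE)) abort("p-values must lie in [0, 1].")
  p.adjust(p, method = "BH")
}

tier_labels <- c("p<0.01", "p<0.05", "p<0.1", "ns")

assign_tier <- function(x, thresholds = c(0.01, 0.05, 0.1)) {
  factor(
    case_when(
      x < thresholds[1] ~ "p<0.01",
      x < thresholds[2] ~ "p<0.05",
      x < thresholds[3] ~ "p<0.1",
      TRUE ~ "ns"
    ),
    levels = tier_labels
  )
}

tier_symbol <- function(tier) {
  unname(c(`p<0.01` = "**", `p<0.05` = "*", `p<0.1` = "+",
           ns = "")[as.character(tier)])
}

#' Per-taxon activity in dense pooled fractions
#'
#' For each taxon and each dense pooled fraction, activity is the taxon's
#' percent relative abundance in the labeled gradient's pool minus its
#' percent relative abundance in the same pool of the control gradient:
#' `A = 100 * tNS_lab / NS_lab - 100 * tNS_ctl / NS_ctl`. Positive values
#' indicate enrichment through heavy-isotope incorporation; negative
#' values indicate underrepresentation. Each comparison receives a
#' two-sided Fisher exact p-value and a Benjamini-Hochberg q-value
#' (adjusted across taxa, within each dense pool by default), plus a
#' significance tier (`p<0.01` / `p<0.05` / `p<0.1` / `ns`).
#'
#' @param labeled,control Count tables sharing the dense pool columns.
#'   Taxa present in only one table are zero-filled in the other; taxa
#'   absent from both are dropped.
#' @param dense_pools Names of the dense pooled-fraction columns; defaults
#'   to all shared sample columns.
#' @param rank Optional taxonomic rank at which to collapse both tables
#'   before computing activity (e.g. `"family"` or `"genus"`).
#' @param fdr_scope `"pool"` (adjust within each dense pool, default) or
#'   `"global"` (one adjustment across all records).
#' @param tier_on `"q"` (default) assigns tiers on adjusted values,
#'   `"p"` on raw p-values.
#' @param tier_thresholds Tier cut points, default `c(0.01, 0.05, 0.1)`.
#' @return A tibble with class `sip_activity`: one row per (taxon, dense
#'   pool) with counts, `A`, `p`, `q`, `tier` and `symbol`.
#' @export
compute_activity <- function(labeled, control, dense_pools = NULL, rank = NULL,
                             fdr_scope = c("pool", "global"),
                             tier_on = c("q", "p"),
                             tier_thresholds = c(0.01, 0.05, 0.1)) {
  fdr_scope <- match.arg(fdr_scope)
  tier_on <- match.arg(tier_on)
  assert_count_table(labeled, "labeled")
  assert_count_table(control, "control")
  if (!is.null(rank)) {
    labeled <- collapse_rank(labeled, rank)
    control <- collapse_rank(control, rank)
  }
  if (is.null(dense_pools)) {
    dense_pools <- intersect(sample_cols(labeled), sample_cols(control))
  }
  miss_l <- setdiff(dense_pools, sample_cols(labeled))
  miss_c <- setdiff(dense_pools, sample_cols(control))
  if (length(miss_l) || length(miss_c)) {
    abort(sprintf("Dense pool(s) missing from tables: %s",
                  paste(union(miss_l, miss_c), collapse = ", ")))
  }
  taxa <- union(labeled$taxon, control$taxon)
  lineage <- NULL
  if ("lineage" %in% names(labeled) || "lineage" %in% names(control)) {
    pick <- function(tab) {
      if (!"lineage" %in% names(tab)) return(rep(NA_character_, length(taxa)))
      unname(setNames(tab$lineage, tab$taxon)[taxa])
    }
    lineage <- dplyr::coalesce(pick(labeled), pick(control))
  }
  get_counts <- function(tab, pool) {
    x <- unname(setNames(tab[[pool]], tab$taxon)[taxa])
    ifelse(is.na(x), 0, x)
  }
  records <- purrr::map_dfr(dense_pools, function(pool) {
    tl <- get_counts(labeled, pool)
    tc <- get_counts(control, pool)
    nl <- sum(tl)
    nc <- sum(tc)
    if (nl <= 0 || nc <= 0) {
      abort(sprintf("Pool `%s` has a zero library total.", pool))
    }
    tibble(
      taxon = taxa, pool = pool,
      tNS_labeled = tl, NS_labeled = nl,
      tNS_control = tc, NS_control = nc,
      A = 100 * tl / nl - 100 * tc / nc,
      p = fisher_enrichment_p(tl, nl, tc, nc)
    )
  })
  # drop taxa absent from both tables in every dense pool
  present <- records |>
    group_by(.data$taxon) |>
    summarise(any_count = sum(.data$tNS_labeled + .data$tNS_control) > 0,
              .groups = "drop")
  records <- filter(records,
                    .data$taxon %in% present$taxon[present$any_count])
  if (nrow(records) == 0L) abort("No taxa with counts in the dense pools.")
  records <- if (fdr_scope == "pool") {
    records |> group_by(.data$pool) |> mutate(q = bh_fdr(.data$p)) |> ungroup()
  } else {
    mutate(records, q = bh_fdr(.data$p))
  }
  records$tier <- assign_tier(if (tier_on == "q") records$q else records$p,
                              tier_thresholds)
  records$symbol <- tier_symbol(records$tier)
  if (!is.null(lineage)) {
    records$lineage <- lineage[match(records$taxon, taxa)]
  }
  class(records) <- c("sip_activity", class(records))
  records
}

#' Activity heatmap matrices
#'
#' Reshapes activity records into a taxa-by-pool matrix of activity values
#' and a parallel matrix of significance annotations (`**` for the
#' strongest tier, `*`, `+`, empty for not significant), the layout used
#' for SIP activity heatmaps.
#'
#' @param records A `sip_activity` tibble (see [compute_activity()]).
#' @return A list with `values` (numeric matrix) and `annotations`
#'   (character matrix), rows = taxa, columns = dense pools.
#' @export
activity_heatmap_matrix <- function(records) {
  if (nrow(records) == 0L) abort("No activity records.")
  if (anyDuplicated(records[c("taxon", "pool")])) {
    abort("Duplicate (taxon, pool) records.")
  }
  taxa <- unique(records$taxon)
  pools <- unique(records$pool)
  values <- matrix(0, length(taxa), length(pools), dimnames = list(taxa, pools))
  ann <- matrix("", length(taxa), length(pools), dimnames = list(taxa, pools))
  values[cbind(records$taxon, records$pool)] <- records$A
  ann[cbind(records$taxon, records$pool)] <- records$symbol
  list(values = values, annotations = ann)
}

#' Rank taxa by highest activity
#'
#' Orders taxa by their maximum activity over the dense pools (descending),
#' breaking ties lexicographically by taxon name — the layout of
#' "most active genera" summary tables.
#'
#' @param records A `sip_activity` tibble.
#' @param n Number of top taxa to keep (default all).
#' @return A tibble with one row per taxon: `taxon`, `max_A`, `best_pool`,
#'   `best_q`, plus per-pool activity columns.
#' @export
rank_activity <- function(records, n = Inf) {
  summary <- records |>
    group_by(.data$taxon) |>
    summarise(
      max_A = max(.data$A),
      best_pool = .data$pool[which.max(.data$A)],
      best_q = .data$q[which.max(.data$A)],
      .groups = "drop"
    ) |>
    arrange(desc(.data$max_A), .data$taxon)
  wide <- tidyr::pivot_wider(records, id_cols = "taxon", names_from = "pool",
                             values_from = "A")
  out <- left_join(summary, wide, by = "taxon")
  head(out, n)
}

#' @method tidy sip_activity
#' @export
tidy.sip_activity <- function(x, ...) {
  as_tibble(unclass_activity(x))
}

#' @method glance sip_activity
#' @export
glance.sip_activity <- function(x, ...) {
  tibble(
    n_taxa = dplyr::n_distinct(x$taxon),
    n_pools = dplyr::n_distinct(x$pool),
    n_enriched = sum(x$A > 0),
    n_significant_q05 = sum(x$q < 0.05),
    max_A = max(x$A)
  )
}

unclass_activity <- function(x) {
  class(x) <- setdiff(class(x), "sip_activity")
  x
}
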