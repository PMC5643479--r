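# PICRUSt-style arithmetic on user-supplied reference tables: 16S
# copy-number normalization, KO-profile prediction, labeled-family
# filtering, KO enrichment in dense labeled pools.

#' Normalize a count table by 16S copy number
#'
#' Divides each taxon's counts by its genomic 16S rRNA gene copy number,
#' converting read counts into organism-abundance units.
#'
#' @param table Count table.
#' @param copy_numbers Tibble with columns `taxon` and `copy_number`
#'   (or a named numeric vector).
#' @param default_copy_number Copy number used for taxa missing from the
#'   reference; with the default `NULL` a missing taxon is an error.
#' @return The table with sample columns divided by copy number.
#' @export
copy_number_normalize <- function(table, copy_numbers,
                                  default_copy_number = NULL) {
  assert_count_table(table)
  if (is.data.frame(copy_numbers)) {
    cn <- setNames(copy_numbers$copy_number, copy_numbers$taxon)
  } else {
    cn <- copy_numbers
  }
  if (any(cn < 1)) abort("16S copy numbers must be >= 1.")
  x <- cn[table$taxon]
  if (anyNA(x)) {
    if (is.null(default_copy_number)) {
      abort(sprintf("No copy number for taxa: %s",
                    paste(head(table$taxon[is.na(x)], 3L), collapse = ", ")))
    }
    x[is.na(x)] <- default_copy_number
  }
  for (s in sample_cols(table)) table[[s]] <- table[[s]] / unname(x)
  table
}

#' Keep only isotopically labeled taxa
#'
#' Restricts a count table to the rows whose value at `rank` is among the
#' labeled taxa (the step that makes the predicted metagenome reflect only
#' labeled families). Removed rows are attached as the `removed` attribute.
#'
#' @param table Count table with a `lineage` column (or whose `taxon`
#'   values are themselves rank labels when `rank = NULL`).
#' @param labeled_taxa Character vector of labeled rank values.
#' @param rank Rank at which `labeled_taxa` is expressed (default
#'   `"family"`); `NULL` matches against `taxon` directly.
#' @return The filtered table, with attribute `removed` holding the
#'   discarded rows.
#' @export
filter_to_labeled_taxa <- function(table, labeled_taxa, rank = "family") {
  assert_count_table(table)
  if (length(labeled_taxa) == 0L) abort("`labeled_taxa` is empty.")
  key <- if (is.null(rank)) {
    table$taxon
  } else {
    if (!"lineage" %in% names(table)) abort("`table` needs a `lineage` column.")
    parse_lineage(table$lineage)[[rank]]
  }
  keep <- !is.na(key) & key %in% labeled_taxa
  if (!any(keep)) abort("Filtering removed every row; check `labeled_taxa`.")
  out <- table[keep, ]
  attr(out, "removed") <- table[!keep, ]
  out
}

#' Predict a KO profile from taxon abundances and reference gene counts
#'
#' The predicted abundance of a KEGG Ortholog in a sample is the
#' cross-product of taxon abundances with the reference gene counts:
#' `KO(k, s) = sum_t abundance(t, s) * gene_count(t, k)`. Taxa without a
#' reference row contribute zero gene copies.
#'
#' @param table Abundance table (usually copy-number normalized counts).
#' @param ko_ref Reference tibble: `taxon` column plus one numeric column
#'   per KO identifier (`K#####`).
#' @return A tibble with `ko` column and one column per sample.
#' @export
predict_ko_profile <- function(table, ko_ref) {
  assert_count_table(table)
  if (!"taxon" %in% names(ko_ref)) abort("`ko_ref` needs a `taxon` column.")
  kos <- setdiff(names(ko_ref), "taxon")
  if (length(kos) == 0L) abort("`ko_ref` has no KO columns.")
  gene <- as.matrix(as.data.frame(ko_ref[kos]))
  rownames(gene) <- ko_ref$taxon
  if (any(gene < 0)) abort("Gene counts must be non-negative.")
  common <- intersect(table$taxon, ko_ref$taxon)
  if (length(common) == 0L) abort("No overlap between table taxa and `ko_ref` taxa.")
  sc <- sample_cols(table)
  ab <- as.matrix(as.data.frame(table[sc]))
  rownames(ab) <- table$taxon
  prof <- t(gene[common, , drop = FALSE]) %*% ab[common, , drop = FALSE]
  dplyr::bind_cols(tibble(ko = kos), as_tibble(as.data.frame(prof)))
}

#' KO enrichment in dense labeled pooled fractions
#'
#' Applies the activity formula to predicted KO abundances: a KO's
#' enrichment in a dense pool is its percent share of the labeled
#' profile's column total minus its share of the control profile's, after
#' optionally restricting both profiles to a curated KO subset (which then
#' defines the denominator).
#'
#' @param labeled_profile,control_profile KO profiles from
#'   [predict_ko_profile()] sharing pool columns.
#' @param dense_pools Pool columns to compare; default all shared columns.
#' @param ko_subset Optional character vector of KO ids to restrict to
#'   (e.g. a curated lignocellulose or nitrogen list); `NULL` uses all KOs.
#' @return Tibble with one row per (ko, pool): shares and `enrichment`
#'   (percentage points, labeled minus control; sums to 0 per pool).
#' @export
ko_enrichment <- function(labeled_profile, control_profile, dense_pools = NULL,
                          ko_subset = NULL) {
  for (nm in c("labeled_profile", "control_profile")) {
    prof <- get(nm)
    if (!"ko" %in% names(prof)) abort(sprintf("`%s` needs a `ko` column.", nm))
  }
  if (!is.null(ko_subset)) {
    labeled_profile <- filter(labeled_profile, .data$ko %in% ko_subset)
    control_profile <- filter(control_profile, .data$ko %in% ko_subset)
    if (nrow(labeled_profile) == 0L) abort("`ko_subset` matches no KO in the profiles.")
  }
  if (!setequal(labeled_profile$ko, control_profile$ko)) {
    abort("Labeled and control profiles must share the same KO set.")
  }
  control_profile <- control_profile[match(labeled_profile$ko, control_profile$ko), ]
  if (is.null(dense_pools)) {
    dense_pools <- intersect(setdiff(names(labeled_profile), "ko"),
                             setdiff(names(control_profile), "ko"))
  }
  purrr::map_dfr(dense_pools, function(pool) {
    if (!pool %in% names(labeled_profile) || !pool %in% names(control_profile)) {
      abort(sprintf("Pool `%s` missing from a profile.", pool))
    }
    tot_l <- sum(labeled_profile[[pool]])
    tot_c <- sum(control_profile[[pool]])
    if (tot_l <= 0 || tot_c <= 0) abort(sprintf("Pool `%s` has a zero column total.", pool))
    share_l <- 100 * labeled_profile[[pool]] / tot_l
    share_c <- 100 * control_profile[[pool]] / tot_c
    tibble(ko = labeled_profile$ko, pool = pool,
           share_labeled = share_l, share_control = share_c,
           enrichment = share_l - share_c)
  })
}
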