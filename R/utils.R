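# Shared internals: lineage handling, count-table column bookkeeping,
# deterministic seed derivation.

TAXONOMIC_RANKS <- c("kingdom", "phylum", "class", "order", "family", "genus")
RANK_PREFIXES <- c(
  kingdom = "k__", phylum = "p__", class = "c__",
  order = "o__", family = "f__", genus = "g__"
)

#' Parse QIIME-style lineage strings into rank columns
#'
#' Splits semicolon-separated lineages ("k__Bacteria; p__Firmicutes; ...")
#' into one column per rank (kingdom through genus). Missing or empty rank
#' labels become `NA`.
#'
#' @param lineage Character vector of lineage strings.
#' @return A tibble with columns `kingdom`, `phylum`, `class`, `order`,
#'   `family`, `genus` (character, `NA` where unresolved).
#' @examples
#' parse_lineage("k__Bacteria; p__Firmicutes; c__Clostridia")
#' @export
parse_lineage <- function(lineage) {
  stopifnot(is.character(lineage))
  parts <- stringr::str_split(lineage, ";")
  rows <- purrr::map(parts, function(p) {
    p <- stringr::str_trim(p)
    p <- p[p != ""]
    out <- setNames(rep(NA_character_, length(TAXONOMIC_RANKS)), TAXONOMIC_RANKS)
    for (tok in p) {
      hit <- which(startsWith(tok, RANK_PREFIXES))
      if (length(hit) == 1L) {
        val <- substring(tok, 4L)
        if (nzchar(val)) out[[names(RANK_PREFIXES)[hit]]] <- val
      }
    }
    out
  })
  as_tibble(do.call(rbind, rows))
}

#' Build a lineage string from rank values
#'
#' Inverse of [parse_lineage()] up to whitespace: emits
#' `k__...; p__...; ...` truncated at `upto` (default genus). `NA` ranks are
#' written as bare prefixes, the QIIME convention for unresolved ranks.
#'
#' @param ranks A data frame with columns named after taxonomic ranks.
#' @param upto Deepest rank to include.
#' @return Character vector of lineage strings.
#' @export
make_lineage <- function(ranks, upto = "genus") {
  upto <- match.arg(upto, TAXONOMIC_RANKS)
  keep <- TAXONOMIC_RANKS[seq_len(match(upto, TAXONOMIC_RANKS))]
  apply(as.data.frame(ranks)[keep], 1L, function(r) {
    paste0(RANK_PREFIXES[keep], ifelse(is.na(r), "", r), collapse = "; ")
  })
}

# Sample (count-bearing) columns of a count table: everything that is not
# the taxon id or the lineage/taxonomy column.
sample_cols <- function(table) {
  setdiff(names(table), c("taxon", "lineage", "taxonomy"))
}

assert_count_table <- function(table, arg = "table") {
  if (!is.data.frame(table)) abort(sprintf("`%s` must be a data frame.", arg))
  if (!"taxon" %in% names(table)) {
    abort(sprintf("`%s` must have a `taxon` column.", arg))
  }
  if (anyDuplicated(table$taxon)) {
    dup <- unique(table$taxon[duplicated(table$taxon)])
    abort(sprintf("Duplicate taxon ids in `%s`: %s", arg,
                  paste(head(dup, 3L), collapse = ", ")))
  }
  sc <- sample_cols(table)
  if (length(sc) == 0L) abort(sprintf("`%s` has no sample columns.", arg))
  for (s in sc) {
    x <- table[[s]]
    if (!is.numeric(x)) abort(sprintf("Sample column `%s` is not numeric.", s))
    if (any(x < 0, na.rm = TRUE)) {
      abort(sprintf("Negative counts in sample column `%s`.", s))
    }
  }
  invisible(table)
}

# Deterministic stream splitting: every stochastic stage of a simulation
# derives its own seed from the root seed through one multiplicative
# congruential step (MINSTD multiplier, modulus 2^31 - 1), offset by a
# stage id. Distinct stages therefore never share a stream, and the whole
# dataset is a pure function of the root seed.
derive_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.numeric(stage))
  x <- ((abs(seed) %% 2147483646) * 48271) %% 2147483647
  as.integer((x + stage) %% 2147483647)
}

# percent formatting used by the TSV writers (6 decimal places)
format_percent <- function(x) sprintf("%.6f", x)
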