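# Readers and writers for the pipeline's table formats: fraction-table
# CSV, count-table TSV (QIIME-style trailing taxonomy column) with BIOM
# JSON acceptance, IRMS CSV, and YAML/JSON run configuration.

write_with_header <- function(df, path, delim, comments = character()) {
  lines <- character()
  if (length(comments)) lines <- paste0("# ", comments)
  body <- readr::format_delim(df, delim = delim, eol = "\n")
  writeLines(c(lines, sub("\n$", "", body)), path, sep = "\n")
  invisible(path)
}

#' Write / read a count table as TSV
#'
#' The TSV layout is a `taxon` id column, one integer column per sample
#' (pooled fraction), and a trailing `taxonomy` column holding the
#' QIIME-style semicolon-separated lineage. Lines starting with `#` are
#' provenance comments. A write-then-read round trip reproduces counts
#' and lineages exactly.
#'
#' @param table Count table.
#' @param path File path.
#' @param comments Optional character vector of comment-header lines.
#' @return `write_count_table()` returns `path` invisibly;
#'   `read_count_table()` returns a validated count table tibble.
#' @export
write_count_table <- function(table, path, comments = character()) {
  assert_count_table(table)
  out <- table
  if ("lineage" %in% names(out)) out <- rename(out, taxonomy = "lineage")
  write_with_header(out, path, "\t", comments)
}

#' @rdname write_count_table
#' @export
read_count_table <- function(path) {
  if (grepl("\\.biom$", path, ignore.case = TRUE)) {
    return(read_count_table_biom(path))
  }
  df <- readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                        progress = FALSE)
  if ("taxonomy" %in% names(df)) df <- rename(df, lineage = "taxonomy")
  if (!"taxon" %in% names(df)) names(df)[1L] <- "taxon"
  df$taxon <- as.character(df$taxon)
  for (s in sample_cols(df)) {
    bad <- which(df[[s]] < 0)
    if (length(bad)) {
      abort(sprintf("Negative count in `%s`, row %d of %s.", s, bad[1L], path))
    }
    if (any(df[[s]] != round(df[[s]]))) {
      abort(sprintf("Non-integer count in column `%s` of %s.", s, path))
    }
    df[[s]] <- as.integer(df[[s]])
  }
  if ("lineage" %in% names(df)) {
    parsed <- parse_lineage(df$lineage)
    if (all(is.na(parsed$kingdom)) && all(is.na(parsed$family))) {
      abort(sprintf("Lineage column of %s has no parseable rank labels.", path))
    }
  }
  assert_count_table(df)
  df
}

# BIOM v1 (JSON) dialect; delegates parsing to the biomformat package.
read_count_table_biom <- function(path) {
  if (!requireNamespace("biomformat", quietly = TRUE)) {
    abort("Reading .biom files requires the `biomformat` package.")
  }
  b <- biomformat::read_biom(path)
  m <- as.matrix(biomformat::biom_data(b))
  df <- dplyr::bind_cols(tibble(taxon = rownames(m)),
                         as_tibble(as.data.frame(m)))
  md <- tryCatch(biomformat::observation_metadata(b), error = function(e) NULL)
  if (!is.null(md)) {
    lin <- if (is.data.frame(md)) {
      apply(md, 1L, function(r) paste(r[!is.na(r) & nzchar(r)], collapse = "; "))
    } else {
      vapply(md, function(r) paste(unlist(r), collapse = "; "), character(1))
    }
    df$lineage <- unname(lin)
  }
  for (s in sample_cols(df)) df[[s]] <- as.integer(df[[s]])
  assert_count_table(df)
  df
}

#' Write / read a gradient fraction table as CSV
#'
#' Columns: `fraction_index`, `density_g_ml`, `dna_ng`, `copies_16s`.
#' On read, the bottom-first ordering invariant is validated; a file in
#' top-first order is re-indexed with a warning, and densities outside
#' the physical range 1.60-1.80 g/ml are rejected.
#'
#' @param profile A fraction profile tibble.
#' @param path File path.
#' @param comments Optional comment-header lines.
#' @inheritParams fraction_profile
#' @return `read_fraction_table()` returns a [fraction_profile()] tibble.
#' @export
write_fraction_table <- function(profile, path, comments = character()) {
  cols <- c("fraction_index", "density_g_ml", "dna_ng", "copies_16s")
  write_with_header(as_tibble(profile)[cols], path, ",", comments)
}

#' @rdname write_fraction_table
#' @export
read_fraction_table <- function(path, substrate = NULL, treatment = NULL,
                                life_stage = NULL) {
  df <- readr::read_csv(path, comment = "#", show_col_types = FALSE,
                        progress = FALSE)
  fraction_profile(df, substrate = substrate, treatment = treatment,
                   life_stage = life_stage)
}

#' Read / write IRMS measurement tables as CSV
#'
#' Columns: `sample_id`, `tissue`, `life_stage`, `treatment`, `bio_rep`,
#' `tech_rep`, `delta_per_mil`.
#'
#' @param data IRMS measurement tibble.
#' @param path File path.
#' @return A tibble of measurements.
#' @export
read_irms_table <- function(path) {
  df <- readr::read_csv(path, comment = "#", show_col_types = FALSE,
                        progress = FALSE)
  need <- c("sample_id", "tissue", "life_stage", "treatment", "bio_rep",
            "tech_rep", "delta_per_mil")
  missing <- setdiff(need, names(df))
  if (length(missing)) {
    abort(paste0("IRMS table is missing columns: ", paste(missing, collapse = ", ")))
  }
  df
}

#' @rdname read_irms_table
#' @export
write_irms_table <- function(data, path) {
  write_with_header(data, path, ",")
  invisible(path)
}

#' Read and validate a pipeline run configuration
#'
#' Accepts YAML or JSON. Top-level fields: `substrate`, `life_stage`,
#' `rank`, `fdr_level`, `dense_pools` (optional), `pooling` (list of
#' windows with `name`, `low`, `high`, `dense`), `simulate` (logical),
#' `simulator` (a [sim_config()] block), `inputs` (paths used when
#' `simulate` is false), `ko` (optional: `copy_numbers`, `ko_ref`,
#' `ko_subset`, `labeled_taxa`), `anchors` (optional measured anchor
#' readings), `seed`, `out_dir`.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` configuration file.
#' @return A validated configuration list.
#' @export
read_sip_config <- function(path) {
  if (!file.exists(path)) abort(sprintf("Config file not found: %s", path))
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  validate_sip_config(cfg)
}

validate_sip_config <- function(cfg) {
  if (!is.list(cfg)) abort("Config must be a mapping/object.")
  cfg$substrate <- cfg$substrate %||% "cellulose"
  if (!cfg$substrate %in% c("cellulose", "urea")) {
    abort("Config field `substrate` must be \"cellulose\" or \"urea\".")
  }
  cfg$rank <- cfg$rank %||% NULL
  cfg$fdr_level <- cfg$fdr_level %||% 0.05
  if (cfg$fdr_level <= 0 || cfg$fdr_level >= 1) {
    abort("Config field `fdr_level` must lie in (0, 1).")
  }
  cfg$seed <- as.integer(cfg$seed %||% 1L)
  cfg$simulate <- isTRUE(cfg$simulate)
  if (!cfg$simulate) {
    if (is.null(cfg$inputs)) {
      abort("Config needs an `inputs` block (or `simulate: true`).")
    }
    for (f in c("labeled_counts", "control_counts")) {
      if (is.null(cfg$inputs[[f]])) {
        abort(sprintf("Config field `inputs.%s` is required.", f))
      }
      if (!file.exists(cfg$inputs[[f]])) {
        abort(sprintf("Config file `inputs.%s` does not exist: %s", f, cfg$inputs[[f]]))
      }
    }
  }
  if (!is.null(cfg$pooling)) {
    pw <- cfg$pooling
    if (is.data.frame(pw)) pw <- as.list(pw)
    need <- c("name", "low", "high", "dense")
    if (!all(need %in% names(pw))) {
      abort("Config field `pooling` needs `name`, `low`, `high`, `dense`.")
    }
    cfg$pooling <- pooling_scheme(pw$name, as.numeric(pw$low),
                                  as.numeric(pw$high), pw$dense)
  }
  cfg
}
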