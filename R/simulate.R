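# Synthetic DNA-SIP experiment generator: paired labeled/control gradients
# with known ground truth about which taxa incorporated the heavy isotope.

# 16S copies carried per ng of DNA per genomic 16S copy, assuming a ~5 Mb
# genome (1 ng of 5 Mb dsDNA is ~1.85e5 genome equivalents). Only the scale
# of qPCR copy numbers depends on this; all downstream statistics use
# percent-of-gradient shares, which are scale-free.
COPIES_PER_NG_GENOME <- 1.85e5

with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

FAMILY_POOL <- c(
  "Lachnospiraceae", "Enterococcaceae", "Enterobacteriaceae",
  "Ruminococcaceae", "Desulfovibrionaceae", "Bacteroidaceae",
  "Porphyromonadaceae", "Burkholderiaceae", "Christensenellaceae",
  "Acetobacteraceae", "Moraxellaceae", "Propionibacteriaceae",
  "Xanthomonadaceae", "Staphylococcaceae", "Alcaligenaceae",
  "Pseudomonadaceae", "Rhodobacteraceae", "Clostridiaceae",
  "Streptococcaceae", "Veillonellaceae"
)

#' Specify one taxon of a synthetic community
#'
#' @param name Taxon identifier.
#' @param lineage QIIME-style lineage string; defaults to a minimal
#'   bacterial lineage carrying `name` as the genus.
#' @param base_abundance Relative abundance fraction in \[0, 1\]; the whole
#'   community must sum to 1.
#' @param gc_content GC fraction in (0, 1).
#' @param copy_number_16s Genomic 16S rRNA gene copies, >= 1.
#' @param atom_excess_labeled Heavy-isotope atom fraction excess attained
#'   under the labeled treatment (0 = taxon does not assimilate the
#'   substrate).
#' @param label_fraction Fraction of the taxon's population that is labeled
#'   (1 = whole band shifts; < 1 yields a two-component band).
#' @return One-row tibble.
#' @export
taxon_spec <- function(name, lineage = NULL, base_abundance, gc_content,
                       copy_number_16s = 1, atom_excess_labeled = 0,
                       label_fraction = 1) {
  if (is.null(lineage)) {
    lineage <- sprintf("k__Bacteria; p__; c__; o__; f__; g__%s", name)
  }
  tibble(
    name = as.character(name), lineage = lineage,
    base_abundance = base_abundance, gc_content = gc_content,
    copy_number_16s = copy_number_16s,
    atom_excess_labeled = atom_excess_labeled,
    label_fraction = label_fraction
  )
}

assert_taxa <- function(taxa) {
  need <- c("name", "lineage", "base_abundance", "gc_content",
            "copy_number_16s", "atom_excess_labeled")
  missing <- setdiff(need, names(taxa))
  if (length(missing)) {
    abort(paste0("Taxa table is missing columns: ", paste(missing, collapse = ", ")))
  }
  if (!"label_fraction" %in% names(taxa)) taxa$label_fraction <- 1
  if (abs(sum(taxa$base_abundance) - 1) > 1e-9) {
    abort("`base_abundance` must sum to 1 over all taxa.")
  }
  if (any(taxa$gc_content <= 0 | taxa$gc_content >= 1)) {
    abort("`gc_content` must lie in (0, 1).")
  }
  if (any(taxa$atom_excess_labeled < 0 | taxa$atom_excess_labeled > 1)) {
    abort("`atom_excess_labeled` must lie in [0, 1].")
  }
  if (any(taxa$copy_number_16s < 1)) abort("`copy_number_16s` must be >= 1.")
  if (anyDuplicated(taxa$name)) abort("Taxon names must be unique.")
  taxa
}

#' Generate a random synthetic community
#'
#' Builds `n_taxa` taxa with lognormally distributed relative abundances
#' (a standard rank-abundance shape for gut communities), GC content
#' uniform on (0.35, 0.65), 16S copy numbers uniform on 1-7, families
#' cycled from a pool of gut-associated bacterial families and a unique
#' genus per taxon. `n_labeled` randomly chosen taxa assimilate the
#' substrate at `atom_excess`.
#'
#' @param n_taxa,n_labeled Community size and number of truly labeled taxa.
#' @param atom_excess Atom fraction excess of the labeled taxa.
#' @param seed Integer seed making the community reproducible.
#' @return Tibble of [taxon_spec()] rows.
#' @export
default_community <- function(n_taxa = 30, n_labeled = 3, atom_excess = 0.5,
                              seed = 1) {
  stopifnot(n_taxa >= 1, n_labeled >= 0, n_labeled <= n_taxa)
  with_seed(derive_seed(seed, 101), {
    ab <- rlnorm(n_taxa, meanlog = 0, sdlog = 1)
    ab <- ab / sum(ab)
    gc <- runif(n_taxa, 0.35, 0.65)
    cn <- round(runif(n_taxa, 1, 7), 1)
    fam <- rep_len(FAMILY_POOL, n_taxa)
    genus <- sprintf("Genus%02d", seq_len(n_taxa))
    labeled <- sample.int(n_taxa, n_labeled)
    excess <- rep(0, n_taxa)
    excess[labeled] <- atom_excess
    tibble(
      name = sprintf("taxon%02d", seq_len(n_taxa)),
      lineage = sprintf(
        "k__Bacteria; p__Firmicutes; c__Clostridia; o__Clostridiales; f__%s; g__%s",
        fam, genus),
      base_abundance = ab, gc_content = gc, copy_number_16s = cn,
      atom_excess_labeled = excess, label_fraction = 1
    )
  })
}

#' Configuration of a synthetic SIP experiment
#'
#' Defaults emulate the post-sequencing data of an in vivo SIP study:
#' a 4.8 ml CsCl gradient collected bottom-first into 12 fractions
#' (\eqn{^{13}}C cellulose) or 24 fractions (\eqn{^{15}}N urea), ~750 ng
#' of DNA recovered per gradient, Gaussian bands of spread 0.006 g/ml,
#' 50,000 amplicon reads per pooled fraction and 10% lognormal qPCR noise.
#'
#' @param taxa Community table (see [taxon_spec()], [default_community()]).
#' @param isotope `"13C"` or `"15N"`.
#' @param n_fractions Number of collected fractions (12 or 24 by default,
#'   depending on isotope).
#' @param density_min,density_max Collected density range, g/ml.
#' @param band_sigma Within-taxon buoyant-density spread, g/ml.
#' @param reads_per_pool Amplicon reads sequenced per pooled fraction.
#' @param total_dna_ng DNA recovered per gradient, ng.
#' @param qpcr_cv Lognormal coefficient of variation of qPCR copy counts.
#' @param pooling A [pooling_scheme()]; defaults to the substrate's scheme.
#' @param seed Root integer seed; all stochastic stages derive their own
#'   stream from it.
#' @return A list with class `sip_config`.
#' @export
sim_config <- function(taxa = default_community(seed = seed),
                       isotope = c("13C", "15N"),
                       n_fractions = NULL,
                       density_min = 1.66, density_max = 1.78,
                       band_sigma = 0.006,
                       reads_per_pool = 50000,
                       total_dna_ng = 750,
                       qpcr_cv = 0.1,
                       pooling = NULL,
                       seed = 1) {
  isotope <- match.arg(isotope)
  substrate <- if (isotope == "13C") "cellulose" else "urea"
  if (is.null(n_fractions)) n_fractions <- if (isotope == "13C") 12L else 24L
  if (density_min >= density_max) abort("`density_min` must be < `density_max`.")
  if (is.null(pooling)) {
    pooling <- default_pooling_scheme(substrate, density_min, density_max)
  }
  taxa <- assert_taxa(as_tibble(taxa))
  if (n_fractions < 2) abort("`n_fractions` must be >= 2.")
  if (band_sigma <= 0) abort("`band_sigma` must be > 0.")
  if (reads_per_pool <= 0) abort("`reads_per_pool` must be positive.")
  if (qpcr_cv < 0) abort("`qpcr_cv` must be non-negative.")
  structure(
    list(taxa = taxa, isotope = isotope, substrate = substrate,
         n_fractions = as.integer(n_fractions),
         density_min = density_min, density_max = density_max,
         band_sigma = band_sigma, reads_per_pool = as.integer(reads_per_pool),
         total_dna_ng = total_dna_ng, qpcr_cv = qpcr_cv,
         pooling = pooling, seed = as.integer(seed)),
    class = "sip_config"
  )
}

# Fraction collection windows, densest-first, equal width over the
# collected range.
fraction_windows <- function(config) {
  w <- (config$density_max - config$density_min) / config$n_fractions
  high <- config$density_max - w * (seq_len(config$n_fractions) - 1)
  tibble(fraction_index = seq_len(config$n_fractions),
         low = high - w, high = high, midpoint = high - w / 2)
}

# Expected per-fraction DNA mass for every taxon (taxa x fractions matrix).
# Under the labeled treatment a taxon's band is a mixture of a shifted
# component (weight label_fraction) and an unshifted one.
taxon_mass_matrix <- function(config, treatment) {
  wins <- fraction_windows(config)
  taxa <- config$taxa
  t(vapply(seq_len(nrow(taxa)), function(i) {
    bd0 <- mean_buoyant_density(taxa$gc_content[i], "none")
    props0 <- band_fraction_masses(bd0, config$band_sigma, wins)
    if (treatment == "labeled" && taxa$atom_excess_labeled[i] > 0) {
      bd1 <- mean_buoyant_density(taxa$gc_content[i], config$isotope,
                                  taxa$atom_excess_labeled[i])
      props1 <- band_fraction_masses(bd1, config$band_sigma, wins)
      lf <- taxa$label_fraction[i]
      props <- lf * props1 + (1 - lf) * props0
    } else {
      props <- props0
    }
    config$total_dna_ng * taxa$base_abundance[i] * props
  }, numeric(config$n_fractions)))
}

simulate_profile <- function(config, treatment, noise_seed) {
  wins <- fraction_windows(config)
  mass <- taxon_mass_matrix(config, treatment)
  dna <- colSums(mass)
  copies <- colSums(mass * config$taxa$copy_number_16s) * COPIES_PER_NG_GENOME
  if (config$qpcr_cv > 0) {
    sdlog <- sqrt(log(1 + config$qpcr_cv^2))
    noise <- with_seed(noise_seed,
                       rlnorm(length(copies), meanlog = -sdlog^2 / 2, sdlog = sdlog))
    copies <- copies * noise
  }
  fraction_profile(
    tibble(fraction_index = wins$fraction_index, density_g_ml = wins$midpoint,
           dna_ng = dna, copies_16s = copies),
    substrate = config$substrate,
    treatment = treatment
  )
}

simulate_counts <- function(config, treatment, count_seed) {
  wins <- fraction_windows(config)
  mass <- taxon_mass_matrix(config, treatment)
  pool_idx <- assign_window(wins$midpoint, config$pooling)
  pools <- config$pooling$name
  counts <- with_seed(count_seed, {
    cols <- lapply(seq_along(pools), function(w) {
      members <- which(!is.na(pool_idx) & pool_idx == w)
      weight <- if (length(members)) {
        rowSums(mass[, members, drop = FALSE]) * config$taxa$copy_number_16s
      } else {
        rep(0, nrow(mass))
      }
      if (sum(weight) <= 0) return(rep(0L, nrow(mass)))
      as.integer(rmultinom(1, config$reads_per_pool, weight))
    })
    matrix(unlist(cols), nrow = nrow(mass))
  })
  out <- as_tibble(as.data.frame(counts), .name_repair = "minimal")
  names(out) <- pools
  dplyr::bind_cols(tibble(taxon = config$taxa$name), out,
                   tibble(lineage = config$taxa$lineage))
}

#' Simulate a paired labeled/control SIP dataset
#'
#' Generates the two gradient fraction profiles (DNA mass and noisy 16S
#' copy numbers per fraction) and the two pooled-fraction amplicon count
#' tables of one SIP experiment, together with the ground truth of which
#' taxa are labeled. Per-fraction DNA masses are deterministic Gaussian
#' band integrals; qPCR copy numbers carry lognormal noise; read counts
#' are multinomial draws of `reads_per_pool` reads from each pool's
#' 16S-copy-weighted DNA shares. Identical configuration (including the
#' seed) yields an identical dataset.
#'
#' @param config A [sim_config()].
#' @return A list with class `sip_dataset`: `labeled_profile`,
#'   `control_profile`, `labeled_counts`, `control_counts`, `truth`
#'   (tibble of taxon, labeled flag, atom excess) and `config`.
#' @export
simulate_sip_dataset <- function(config) {
  if (!inherits(config, "sip_config")) abort("`config` must come from sim_config().")
  if (!any(config$pooling$dense)) abort("Pooling scheme has no dense window.")
  structure(
    list(
      labeled_profile = simulate_profile(config, "labeled", derive_seed(config$seed, 1)),
      control_profile = simulate_profile(config, "control", derive_seed(config$seed, 2)),
      labeled_counts = simulate_counts(config, "labeled", derive_seed(config$seed, 3)),
      control_counts = simulate_counts(config, "control", derive_seed(config$seed, 4)),
      truth = tibble(
        taxon = config$taxa$name,
        labeled = config$taxa$atom_excess_labeled > 0,
        atom_excess = config$taxa$atom_excess_labeled
      ),
      config = config
    ),
    class = "sip_dataset"
  )
}

#' Score detection of labeled taxa against simulation ground truth
#'
#' A taxon counts as flagged when at least one of its activity records in
#' a dense pooled fraction is enriched (`A > 0`) at adjusted significance
#' `q < alpha`.
#'
#' @param records Activity records from [compute_activity()].
#' @param truth Truth tibble of a [simulate_sip_dataset()] result.
#' @param alpha FDR level for flagging, default 0.05.
#' @return One-row tibble: `sensitivity`, `specificity`,
#'   `false_discovery_proportion`, `n_flagged`, `n_labeled`, `n_taxa`.
#' @export
evaluate_detection <- function(records, truth, alpha = 0.05) {
  if (is.null(truth) || nrow(truth) == 0L) abort("`truth` is empty.")
  flagged_taxa <- records |>
    group_by(.data$taxon) |>
    summarise(flagged = any(.data$q < alpha & .data$A > 0), .groups = "drop")
  scored <- left_join(truth, flagged_taxa, by = "taxon") |>
    mutate(flagged = dplyr::coalesce(.data$flagged, FALSE))
  tp <- sum(scored$flagged & scored$labeled)
  fp <- sum(scored$flagged & !scored$labeled)
  tn <- sum(!scored$flagged & !scored$labeled)
  n_lab <- sum(scored$labeled)
  tibble(
    sensitivity = if (n_lab > 0) tp / n_lab else NA_real_,
    specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_,
    false_discovery_proportion = if (tp + fp > 0) fp / (tp + fp) else 0,
    n_flagged = tp + fp, n_labeled = n_lab, n_taxa = nrow(scored)
  )
}
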