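# CsCl gradient profiles: percent-of-gradient normalization, density-window
# pooling, density shift between labeled and control gradients.

#' Define a pooling scheme of named density windows
#'
#' Pooled fractions are named density windows (e.g. upper / medium / lower)
#' into which collected gradient fractions are grouped. Windows are
#' half-open `[low, high)` with the closed edge on the dense side: a
#' fraction whose density equals a window's `high` bound belongs to the
#' adjacent denser window. Windows flagged `dense` are the ones entering
#' the activity test.
#'
#' @param name Window names, densest-first.
#' @param low,high Density bounds, g/ml.
#' @param dense Logical, which windows are dense (tested) pools.
#' @return A tibble with class `sip_pooling`, ordered densest-first.
#' @export
pooling_scheme <- function(name, low, high, dense) {
  scheme <- tibble(name = as.character(name), low = low, high = high,
                   dense = as.logical(dense))
  if (anyDuplicated(scheme$name)) abort("Window names must be unique.")
  scheme <- arrange(scheme, desc(.data$high))
  if (any(scheme$high <= scheme$low)) abort("Each window needs `high` > `low`.")
  if (nrow(scheme) > 1L) {
    overlap <- scheme$low[-nrow(scheme)] < scheme$high[-1L] - 1e-12
    if (any(overlap)) abort("Pooling windows must be pairwise disjoint.")
  }
  if (!any(scheme$dense)) abort("At least one window must be flagged `dense`.")
  class(scheme) <- c("sip_pooling", class(scheme))
  scheme
}

#' Default pooling schemes for cellulose and urea gradients
#'
#' Cellulose gradients use three pooled fractions (upper / medium / lower;
#' dense = medium + lower, giving two activity values per taxon); urea
#' gradients use four (upper / upper_medium / lower_medium / lower; dense =
#' the three densest, giving three activity values). The density bounds are
#' configuration values, not physical constants. The defaults place the
#' dense windows above the buoyant densities of unlabeled bands of typical
#' GC content (0.35-0.65 maps to about 1.694-1.724 g/ml), mirroring how
#' pooled density ranges are selected in practice: where the labeled
#' gradient shows visibly more DNA than the control. Dense windows that
#' instead overlap the unlabeled community band would gain spurious
#' enrichment of unlabeled taxa whenever a labeled band shifts out of
#' them (a compositional artifact of relative abundances).
#'
#' @param substrate `"cellulose"` or `"urea"`.
#' @param density_min,density_max Bounds of the collected gradient, g/ml.
#' @return A [pooling_scheme()] tibble.
#' @export
default_pooling_scheme <- function(substrate = c("cellulose", "urea"),
                                   density_min = 1.66, density_max = 1.78) {
  substrate <- match.arg(substrate)
  if (substrate == "cellulose") {
    pooling_scheme(
      name = c("lower", "medium", "upper"),
      low = c(1.745, 1.724, density_min),
      high = c(density_max, 1.745, 1.724),
      dense = c(TRUE, TRUE, FALSE)
    )
  } else {
    pooling_scheme(
      name = c("lower", "lower_medium", "upper_medium", "upper"),
      low = c(1.748, 1.736, 1.724, density_min),
      high = c(density_max, 1.748, 1.736, 1.724),
      dense = c(TRUE, TRUE, TRUE, FALSE)
    )
  }
}

#' Number of fractions collected from a gradient
#'
#' Drop-wise bottom-first collection of a gradient of `gradient_volume_ml`
#' milliliters into fractions of `fraction_volume_ul` microliters: e.g. a
#' 4.8 ml gradient yields 12 fractions of 400 ul or 24 fractions of 200 ul.
#'
#' @param gradient_volume_ml Gradient volume, ml.
#' @param fraction_volume_ul Collected volume per fraction, ul.
#' @return Integer number of (complete) fractions.
#' @export
n_collected_fractions <- function(gradient_volume_ml, fraction_volume_ul) {
  if (gradient_volume_ml <= 0 || fraction_volume_ul <= 0) {
    abort("Volumes must be positive.")
  }
  as.integer(floor(gradient_volume_ml * 1000 / fraction_volume_ul + 1e-9))
}

#' Construct a gradient fraction profile
#'
#' Validates a table of per-fraction measurements for one gradient.
#' Fractions are collected drop-wise from the bottom of the tube, so index
#' 1 is the densest fraction and density is non-increasing with index. A
#' table supplied in top-first order (density increasing with index) is
#' detected and re-indexed with a warning.
#'
#' @param fractions Data frame with columns `fraction_index`,
#'   `density_g_ml`, `dna_ng`, `copies_16s`.
#' @param substrate,treatment,life_stage Optional experiment annotations
#'   stored as attributes (`"cellulose"`/`"urea"`, `"labeled"`/`"control"`,
#'   `"larva"`/`"adult"`).
#' @return A tibble ordered bottom-first with attribute `sip_meta`.
#' @export
fraction_profile <- function(fractions, substrate = NULL, treatment = NULL,
                             life_stage = NULL) {
  need <- c("fraction_index", "density_g_ml", "dna_ng", "copies_16s")
  missing <- setdiff(need, names(fractions))
  if (length(missing)) {
    abort(paste0("Missing fraction columns: ", paste(missing, collapse = ", ")))
  }
  fr <- as_tibble(fractions)[need]
  if (nrow(fr) < 2L) abort("A gradient profile needs at least 2 fractions.")
  if (anyDuplicated(fr$fraction_index)) abort("Duplicate fraction indices.")
  fr <- arrange(fr, .data$fraction_index)
  if (!all(fr$fraction_index == seq_len(nrow(fr)))) {
    abort("Fraction indices must be consecutive starting at 1.")
  }
  bad <- which(fr$density_g_ml < 1.60 | fr$density_g_ml > 1.80)
  if (length(bad)) {
    abort(sprintf("Density outside [1.60, 1.80] g/ml at fraction index %s.",
                  paste(fr$fraction_index[bad], collapse = ", ")))
  }
  if (any(fr$dna_ng < 0) || any(fr$copies_16s < 0)) {
    abort("`dna_ng` and `copies_16s` must be non-negative.")
  }
  d <- fr$density_g_ml
  if (is.unsorted(rev(d))) {
    # not non-increasing with index: either a top-first file or disordered
    if (!is.unsorted(d)) {
      warn("Fractions appear to be in top-first order; re-indexing bottom-first.")
      fr <- fr[rev(seq_len(nrow(fr))), ]
      fr$fraction_index <- seq_len(nrow(fr))
    } else {
      abort("Densities must be non-increasing with fraction index (bottom-first collection).")
    }
  }
  meta <- list(substrate = substrate, treatment = treatment, life_stage = life_stage)
  attr(fr, "sip_meta") <- meta
  fr
}

#' Percent-of-gradient normalization of a fraction profile
#'
#' Expresses each fraction's DNA mass and 16S copy number as a percentage
#' of the gradient's total, the normalization that makes labeled and
#' control gradients comparable despite different DNA recovery.
#'
#' @param profile A [fraction_profile()] tibble.
#' @return The profile with `dna_percent` and `copies_percent` columns;
#'   each series sums to 100.
#' @export
normalize_profile <- function(profile) {
  tot_dna <- sum(profile$dna_ng)
  tot_cop <- sum(profile$copies_16s)
  if (tot_dna <= 0) abort("All-zero DNA across the gradient; cannot normalize.")
  if (tot_cop <= 0) abort("All-zero 16S copies across the gradient; cannot normalize.")
  out <- mutate(profile,
    dna_percent = 100 * .data$dna_ng / tot_dna,
    copies_percent = 100 * .data$copies_16s / tot_cop
  )
  attr(out, "sip_meta") <- attr(profile, "sip_meta")
  out
}

# Window assignment: half-open [low, high), ties at a shared boundary go to
# the denser window (whose closed low edge equals the boundary); the densest
# window additionally includes its own high edge.
assign_window <- function(density, scheme) {
  vapply(density, function(d) {
    hit <- which(d >= scheme$low & d < scheme$high)
    if (length(hit) == 0L && isTRUE(abs(d - scheme$high[1L]) < 1e-12)) hit <- 1L
    if (length(hit) == 0L) NA_integer_ else min(hit)
  }, integer(1))
}

#' Group gradient fractions into pooled fractions
#'
#' @param profile A normalized profile (see [normalize_profile()]).
#' @param scheme A [pooling_scheme()].
#' @return A tibble with one row per window: `pool`, `dense`,
#'   `member_indices` (list column), `n_fractions`, `dna_percent`,
#'   `copies_percent`. Fractions falling outside every window are attached
#'   as the `unpooled` attribute (a tibble) and reported via a message.
#' @export
pool_fractions <- function(profile, scheme) {
  if (!all(c("dna_percent", "copies_percent") %in% names(profile))) {
    profile <- normalize_profile(profile)
  }
  idx <- assign_window(profile$density_g_ml, scheme)
  if (all(is.na(idx))) abort("Pooling scheme captures zero fractions.")
  pooled <- purrr::map_dfr(seq_len(nrow(scheme)), function(w) {
    members <- which(!is.na(idx) & idx == w)
    tibble(
      pool = scheme$name[w],
      dense = scheme$dense[w],
      member_indices = list(profile$fraction_index[members]),
      n_fractions = length(members),
      dna_percent = sum(profile$dna_percent[members]),
      copies_percent = sum(profile$copies_percent[members])
    )
  })
  unpooled <- profile[is.na(idx), ]
  if (nrow(unpooled) > 0L) {
    inform(sprintf("%d fraction(s) fall outside all pooling windows (%.2f%% of DNA); kept as `unpooled` attribute.",
                   nrow(unpooled), sum(unpooled$dna_percent)))
  }
  attr(pooled, "unpooled") <- unpooled
  attr(pooled, "sip_meta") <- attr(profile, "sip_meta")
  pooled
}

#' DNA-weighted mean density shift between labeled and control gradients
#'
#' The buoyant-density shift is the DNA-percent-weighted mean density of
#' the labeled gradient minus that of the control gradient; a positive
#' value means labeled DNA bands denser on average, the signature of
#' heavy-isotope incorporation.
#'
#' @param labeled,control Normalized profiles.
#' @return Density difference in g/ml.
#' @export
density_shift <- function(labeled, control) {
  ml <- attr(labeled, "sip_meta")
  mc <- attr(control, "sip_meta")
  if (!is.null(ml$substrate) && !is.null(mc$substrate) &&
      !identical(ml$substrate, mc$substrate)) {
    abort("Labeled and control profiles come from different substrates.")
  }
  for (p in list(labeled, control)) {
    if (!"dna_percent" %in% names(p)) abort("Profiles must be normalized first.")
  }
  wmean <- function(p) sum(p$density_g_ml * p$dna_percent) / sum(p$dna_percent)
  wmean(labeled) - wmean(control)
}
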