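# Trait-structured synthetic communities, illustrative stream-type
# configurations, and cross-tabulation fixtures. Everything downstream of
# the readers can be exercised from these generators alone.

#' Generate a trait-structured synthetic taxon pool
#'
#' Builds a taxon pool spanning the trait strata the assessment metrics
#' respond to: saprobic-sensitive riffle taxa (low saprobic values, positive
#' fauna-index scores, Ephemeroptera/Plecoptera/Trichoptera group flags,
#' epirhithral preference), saprobic-tolerant taxa (high saprobic values,
#' negative scores), mud-dwelling (pelal) and littoral taxa carrying
#' fractional preference shares — characteristically occurring at low
#' abundance — and trait-less taxa that only contribute to totals.
#'
#' @param n_sensitive,n_tolerant,n_pelal,n_littoral,n_neutral stratum pool
#'   sizes.
#' @param seed RNG seed.
#' @return a [trait_table] with an extra `stratum` column.
#' @export
generate_trait_table <- function(n_sensitive = 25, n_tolerant = 20,
                                 n_pelal = 12, n_littoral = 12,
                                 n_neutral = 11, seed = 1) {
  set.seed(seed)
  mk <- function(prefix, n) sprintf("%s_%03d", prefix, seq_len(n))
  ept_groups <- c("Ephemeroptera", "Plecoptera", "Trichoptera")

  sens <- if (n_sensitive > 0) data.frame(
    taxon_name = mk("Sens", n_sensitive),
    stratum = "sensitive",
    saprobic_value = round(stats::runif(n_sensitive, 1.0, 2.2), 1),
    saprobic_weight = sample(c(4, 8, 16), n_sensitive, replace = TRUE),
    fauna_index_score = round(stats::runif(n_sensitive, 0.5, 2), 1),
    group_flags = sample(ept_groups, n_sensitive, replace = TRUE),
    pref_epirhithral = round(stats::runif(n_sensitive, 0.4, 0.8), 1),
    pref_pelal = 0, pref_littoral = 0,
    stringsAsFactors = FALSE) else NULL

  tol <- if (n_tolerant > 0) data.frame(
    taxon_name = mk("Tol", n_tolerant),
    stratum = "tolerant",
    saprobic_value = round(stats::runif(n_tolerant, 2.6, 4.0), 1),
    saprobic_weight = sample(c(2, 4, 8), n_tolerant, replace = TRUE),
    fauna_index_score = round(stats::runif(n_tolerant, -2, -0.5), 1),
    group_flags = "",
    pref_epirhithral = 0, pref_pelal = 0, pref_littoral = 0,
    stringsAsFactors = FALSE) else NULL

  pel <- if (n_pelal > 0) data.frame(
    taxon_name = mk("Pel", n_pelal),
    stratum = "pelal",
    saprobic_value = round(stats::runif(n_pelal, 2.2, 3.5), 1),
    saprobic_weight = 2,
    fauna_index_score = round(stats::runif(n_pelal, -1.5, 0), 1),
    group_flags = "",
    pref_epirhithral = 0,
    pref_pelal = round(stats::runif(n_pelal, 0.5, 0.9), 1),
    pref_littoral = 0,
    stringsAsFactors = FALSE) else NULL

  lit <- if (n_littoral > 0) data.frame(
    taxon_name = mk("Lit", n_littoral),
    stratum = "littoral",
    saprobic_value = round(stats::runif(n_littoral, 2.0, 3.2), 1),
    saprobic_weight = 2,
    fauna_index_score = round(stats::runif(n_littoral, -1.5, 0), 1),
    group_flags = "",
    pref_epirhithral = 0, pref_pelal = 0,
    pref_littoral = round(stats::runif(n_littoral, 0.5, 0.9), 1),
    stringsAsFactors = FALSE) else NULL

  neu <- if (n_neutral > 0) data.frame(
    taxon_name = mk("Neu", n_neutral),
    stratum = "neutral",
    saprobic_value = NA_real_, saprobic_weight = NA_real_,
    fauna_index_score = NA_real_, group_flags = "",
    pref_epirhithral = 0, pref_pelal = 0, pref_littoral = 0,
    stringsAsFactors = FALSE) else NULL

  trait_table(do.call(rbind, Filter(Negate(is.null),
                                    list(sens, tol, pel, lit, neu))))
}

#' Generate a synthetic cohort of community samples
#'
#' Each sample receives a degradation level g in \[0, 1\] that tilts both
#' occurrence probabilities and expected counts: increasing g favours
#' saprobic-tolerant, negative-indicator and mud-dwelling/littoral taxa and
#' suppresses the sensitive stratum. Counts follow a geometric rank-abundance
#' series over the occurring taxa (so most taxa are rare), with the
#' pelal/littoral strata forced to characteristically low abundance, and are
#' allocated by a multinomial draw of the fixed sample size — 350 or 700
#' sorted individuals, mirroring standard field protocols — so every
#' retained count is at least 1.
#'
#' @param traits a trait table from [generate_trait_table()] (needs the
#'   `stratum` column).
#' @param n_samples number of samples.
#' @param stream_type_id stream type assigned to the cohort.
#' @param seed RNG seed.
#' @param degradation optional vector of degradation levels in \[0, 1\]
#'   (default: uniform draws).
#' @param sample_sizes candidate totals of sorted individuals.
#' @param geom_p geometric rank-abundance parameter in (0, 1).
#' @return named list of [community_sample] objects; the degradation levels
#'   are attached as attribute `"degradation"` (data frame `sample_id`, `g`).
#' @export
generate_cohort <- function(traits, n_samples = 200,
                            stream_type_id = "SYN_GRAVEL", seed = 1,
                            degradation = NULL,
                            sample_sizes = c(350, 700), geom_p = 0.25) {
  stopifnot("stratum" %in% names(traits))
  set.seed(seed)
  n_tax <- nrow(traits)
  stratum <- traits$stratum
  g_lev <- if (is.null(degradation)) stats::runif(n_samples)
           else rep_len(degradation, n_samples)
  stopifnot(all(g_lev >= 0 & g_lev <= 1))

  # characteristic commonness ranks, fixed for the cohort
  rank <- sample(n_tax)
  base_w <- (1 - geom_p)^(rank - 1)
  base_w[stratum %in% c("pelal", "littoral")] <-
    0.05 * max(base_w) * stats::runif(sum(stratum %in% c("pelal", "littoral")),
                                      0.2, 1)

  occ_prob <- function(g) {
    p <- rep(0.5, n_tax)
    p[stratum == "sensitive"] <- 0.85 - 0.55 * g
    p[stratum == "tolerant"] <- 0.30 + 0.55 * g
    p[stratum %in% c("pelal", "littoral")] <- 0.35 + 0.45 * g
    p
  }
  tilt <- function(g) {
    t <- rep(0, n_tax)
    t[stratum == "sensitive"] <- -1.2 * g
    t[stratum == "tolerant"] <- 1.2 * g
    t[stratum %in% c("pelal", "littoral")] <- 0.8 * g
    exp(t)
  }

  has_sap <- !is.na(traits$saprobic_value)
  ids <- sprintf("S%04d", seq_len(n_samples))
  samples <- vector("list", n_samples)
  for (j in seq_len(n_samples)) {
    g <- g_lev[j]
    repeat {
      occ <- stats::rbinom(n_tax, 1, occ_prob(g)) == 1
      if (sum(occ) >= 8 && sum(occ & has_sap) >= 5) break
    }
    w <- base_w[occ] * tilt(g)[occ]
    n_ind <- sample(sample_sizes, 1)
    counts <- as.vector(stats::rmultinom(1, n_ind, w / sum(w)))
    keep <- counts > 0
    samples[[j]] <- community_sample(
      ids[j], stream_type_id,
      data.frame(taxon_name = traits$taxon_name[occ][keep],
                 abundance = counts[keep], stringsAsFactors = FALSE))
  }
  names(samples) <- ids
  attr(samples, "degradation") <- data.frame(sample_id = ids, g = g_lev,
                                             stringsAsFactors = FALSE)
  samples
}

#' Illustrative stream-type configurations
#'
#' Four templates spanning the metric-family patterns found across national
#' stream typologies: `"gravel_lowland"` — five GDM metrics of which two
#' (pelal and littoral individual shares) use raw abundance;
#' `"lake_outlet"` — three metrics with one raw-abundance metric (littoral
#' share) at 25% weight; `"highland"` — four metrics with one raw-abundance
#' metric (epirhithral share) at 12.5%; `"large_river"` — a single
#' class-based Potamon-type-index metric. Anchors and class boundaries are
#' illustrative, not regulatory values.
#'
#' @param template template name.
#' @param stream_type_id identifier (defaults to the template name in upper
#'   case prefixed `"SYN_"`).
#' @return a [stream_type_config].
#' @export
synthetic_stream_type_config <- function(template = c("gravel_lowland",
                                                      "lake_outlet",
                                                      "highland",
                                                      "large_river"),
                                         stream_type_id = NULL) {
  template <- match.arg(template)
  if (is.null(stream_type_id)) {
    stream_type_id <- paste0("SYN_", toupper(template))
  }
  opm <- metric_spec("saprobic_index", kernel = "saprobic",
                     family = "class_based", anchors = c(4, 1))
  fi <- metric_spec("fauna_index", kernel = "class_weighted_indicator",
                    family = "class_based", anchors = c(-1.5, 1.5),
                    score_column = "fauna_index_score", fauna_index = TRUE)
  ept_cls <- metric_spec("ept_pct", kernel = "proportion",
                         family = "class_based", anchors = c(10, 80),
                         selector = list(groups = c("Ephemeroptera",
                                                    "Plecoptera",
                                                    "Trichoptera")),
                         basis_mode = "class_units")
  tri_rich <- metric_spec("trichoptera_richness", kernel = "richness",
                          family = "presence_based", anchors = c(0, 8),
                          selector = list(groups = "Trichoptera"))
  pel <- metric_spec("pelal_pct", kernel = "proportion",
                     family = "raw_abundance_based", anchors = c(40, 0),
                     selector = list(preference = "pelal"))
  lit <- metric_spec("littoral_pct", kernel = "proportion",
                     family = "raw_abundance_based", anchors = c(40, 0),
                     selector = list(preference = "littoral"))
  epi <- metric_spec("epirhithral_pct", kernel = "proportion",
                     family = "raw_abundance_based", anchors = c(0, 60),
                     selector = list(preference = "epirhithral"))
  pti <- metric_spec("potamon_type_index",
                     kernel = "class_weighted_indicator",
                     family = "class_based", anchors = c(-1.5, 1.5),
                     score_column = "fauna_index_score")
  gdm <- switch(template,
    gravel_lowland = list(fi, ept_cls, tri_rich, pel, lit),
    lake_outlet = list(fi, ept_cls, lit),
    highland = list(fi, ept_cls, tri_rich, epi),
    large_river = list(pti))
  stream_type_config(stream_type_id, opm_metric = opm,
                     si_class_boundaries = c(1.8, 2.3, 2.7, 3.2),
                     gdm_metrics = gdm)
}

#' Expand a 5x5 cross-tabulation into paired class labels
#'
#' Produces the multiset of (abundance-class, presence/absence-class) pairs
#' whose cross-tabulation equals the input matrix exactly, in deterministic
#' row-major order. Inverse of [tabulate_deviations()].
#'
#' @param m 5x5 matrix of non-negative integer counts.
#' @return data frame with integer columns `ab_class`, `pa_class`.
#' @export
expand_crosstab <- function(m) {
  m <- as.matrix(m)
  stopifnot(nrow(m) == 5, ncol(m) == 5)
  if (any(is.na(m)) || any(m < 0) || any(m != round(m))) {
    stop("cells must be non-negative integers")
  }
  ab <- integer(0); pa <- integer(0)
  for (i in 1:5) for (j in 1:5) {
    k <- m[i, j]
    if (k > 0) {
      ab <- c(ab, rep.int(i, k))
      pa <- c(pa, rep.int(j, k))
    }
  }
  data.frame(ab_class = ab, pa_class = pa)
}

#' Published reference cross-tabulations
#'
#' The 5x5 cross-tabulations of abundance-based (rows) versus
#' presence/absence-based (columns) classifications reported by a nationwide
#' comparison of German stream assessments (13,312 monitoring samples):
#' final ecological status class (`esc`), organic pollution module (`opm`)
#' and general degradation module (`gdm`, 13,295 samples with valid module
#' results). Shipped as validation fixtures for the tabulation and
#' congruence machinery.
#'
#' @return named list of three 5x5 integer matrices.
#' @export
reference_crosstabs <- function() {
  esc <- matrix(c(
    247,  103,    1,    0,    0,
     91, 2922,  627,    7,    0,
      1,  420, 2564,  523,   11,
      0,    5,  532, 2187,  348,
      0,    0,    9,  443, 2271), nrow = 5, byrow = TRUE)
  opm <- matrix(c(
    821,  147,    0,    0,    0,
    165, 8758,  307,    0,    0,
      0,  428, 2597,    5,    0,
      0,    0,   49,   31,    1,
      0,    0,    0,    2,    1), nrow = 5, byrow = TRUE)
  gdm <- matrix(c(
    698,  263,    3,    0,    0,
    162, 2295,  616,    6,    0,
      2,  426, 2521,  517,    7,
      0,    5,  534, 2175,  344,
      0,    0,    9,  445, 2267), nrow = 5, byrow = TRUE)
  lapply(list(esc = esc, opm = opm, gdm = gdm), function(m) {
    storage.mode(m) <- "integer"
    dimnames(m) <- list(abundance = 1:5, presence_absence = 1:5)
    m
  })
}

#' Write the reference cross-tabulations as CSV fixtures
#'
#' @param dir output directory (created if needed).
#' @return invisibly, the written file paths.
#' @export
write_reference_crosstabs <- function(dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  tabs <- reference_crosstabs()
  paths <- vapply(names(tabs), function(nm) {
    p <- file.path(dir, paste0("crosstab_", nm, ".csv"))
    utils::write.csv(as.data.frame(tabs[[nm]]), p, row.names = FALSE)
    p
  }, character(1))
  invisible(paths)
}
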