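# Shared in-code fixtures: a small hand-checkable trait table and samples.

tiny_traits <- function() {
  trait_table(data.frame(
    taxon_name = c("Baetis", "Perla", "Hydropsyche", "Asellus",
                   "Chironomus", "Pisidium", "Radix"),
    saprobic_value = c(2.0, 1.2, 1.8, 2.7, 3.4, 2.4, 2.2),
    saprobic_weight = c(4, 16, 8, 4, 8, 2, 2),
    fauna_index_score = c(1.0, 2.0, 1.5, -1.0, -2.0, -0.5, NA),
    group_flags = c("Ephemeroptera", "Plecoptera", "Trichoptera", "",
                    "", "", ""),
    pref_pelal = c(0, 0, 0, 0.2, 0.8, 0.6, 0),
    pref_littoral = c(0, 0, 0, 0.3, 0, 0.2, 0.9),
    stringsAsFactors = FALSE))
}

tiny_sample <- function(counts = c(Baetis = 30, Perla = 5, Hydropsyche = 12,
                                   Asellus = 40, Chironomus = 150,
                                   Pisidium = 3, Radix = 2),
                        sample_id = "T1", stream_type_id = "SYN_GRAVEL") {
  community_sample(sample_id, stream_type_id,
                   data.frame(taxon_name = names(counts),
                              abundance = unname(counts),
                              stringsAsFactors = FALSE))
}

# Independent brute-force oracle for the saprobic index: explicit per-term
# accumulation, no shared code with the implementation.
oracle_saprobic <- function(counts, s, g, bounds = c(2, 10, 30, 100, 300, 1000)) {
  num <- 0; den <- 0
  for (i in seq_along(counts)) {
    if (is.na(s[i]) || is.na(g[i])) next
    a <- 1
    for (b in bounds) if (counts[i] > b) a <- a + 1
    num <- num + s[i] * a * g[i]
    den <- den + a * g[i]
  }
  num / den
}

oracle_indicator <- function(counts, v, bounds = c(2, 10, 30, 100, 300, 1000)) {
  num <- 0; den <- 0
  for (i in seq_along(counts)) {
    if (is.na(v[i])) next
    a <- 1
    for (b in bounds) if (counts[i] > b) a <- a + 1
    num <- num + v[i] * a
    den <- den + a
  }
  num / den
}

# Brute-force pairwise tabulation oracle.
oracle_crosstab <- function(ab, pa) {
  m <- matrix(0L, 5, 5)
  for (i in seq_along(ab)) m[ab[i], pa[i]] <- m[ab[i], pa[i]] + 1L
  m
}

random_crosstab <- function() {
  matrix(rpois(25, 8), 5, 5)
}
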