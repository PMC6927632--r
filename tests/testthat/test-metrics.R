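test_that("presence/absence transform is definitional, idempotent, degenerate-safe", {
  s <- tiny_sample(c(A = 17, B = 1, C = 230))
  p <- to_presence_absence(s)
  expect_equal(p$records$abundance, c(1, 1, 1))
  expect_equal(p$basis, "presence_absence")
  expect_identical(to_presence_absence(p), p)
  expect_setequal(p$records$taxon_key, s$records$taxon_key)

  empty <- community_sample("E", "T",
                            data.frame(taxon_name = character(0),
                                       abundance = numeric(0)))
  expect_equal(nrow(to_presence_absence(empty)$records), 0)
})

test_that("abundance classes follow the default boundaries", {
  expect_equal(abundance_class(c(1, 2, 3, 10, 11, 30, 31, 100, 101, 300,
                                 301, 1000, 1001, 1e6)),
               c(1, 1, 2, 2, 3, 3, 4, 4, 5, 5, 6, 6, 7, 7))
  expect_error(abundance_class(0), ">= 1")
  # non-decreasing in count under an arbitrary scheme
  sch <- abundance_class_scheme(c(5, 50))
  cls <- abundance_class(1:200, sch)
  expect_true(all(diff(cls) >= 0))
  expect_error(abundance_class_scheme(c(10, 10)), "increasing")
})

test_that("saprobic index matches hand-computed cases and the brute-force oracle", {
  tr <- tiny_traits()
  # single indicator taxon: SI equals its saprobic value
  one <- trait_table(data.frame(taxon_name = "A", saprobic_value = 2,
                                saprobic_weight = 4))
  s1 <- community_sample("s", "t", data.frame(taxon_name = "A", abundance = 9))
  expect_equal(saprobic_index(s1, one, min_indicator_taxa = 1)$raw_value, 2.0)

  # two taxa, symmetric weights and classes: midpoint
  two <- trait_table(data.frame(taxon_name = c("A", "B"),
                                saprobic_value = c(1, 3),
                                saprobic_weight = c(4, 4)))
  s2 <- community_sample("s", "t", data.frame(taxon_name = c("A", "B"),
                                              abundance = c(5, 5)))
  expect_equal(saprobic_index(s2, two, min_indicator_taxa = 2)$raw_value, 2.0)

  # mixed community vs independent oracle
  s <- tiny_sample()
  si <- saprobic_index(s, tr)
  idx <- match(s$records$taxon_key, tr$taxon_key)
  expect_equal(si$raw_value,
               oracle_saprobic(s$records$abundance, tr$saprobic_value[idx],
                               tr$saprobic_weight[idx]),
               tolerance = 1e-12)
  expect_true(si$raw_value >= min(tr$saprobic_value) &&
              si$raw_value <= max(tr$saprobic_value))
})

test_that("saprobic index on random fixtures agrees with the oracle to 1e-12", {
  set.seed(42)
  for (rep in 1:25) {
    n <- sample(5:25, 1)
    sv <- ifelse(runif(n) < 0.8, round(runif(n, 1, 4), 1), NA)
    tr <- trait_table(data.frame(
      taxon_name = sprintf("T%02d", 1:n),
      saprobic_value = sv,
      saprobic_weight = ifelse(is.na(sv), NA,
                               sample(c(1, 2, 4, 8, 16), n, replace = TRUE))))
    counts <- sample(1:2000, n, replace = TRUE)
    s <- community_sample("r", "t", data.frame(taxon_name = tr$taxon_name,
                                               abundance = counts))
    res <- saprobic_index(s, tr, min_indicator_taxa = 1)
    idx <- match(s$records$taxon_key, tr$taxon_key)
    exp <- oracle_saprobic(s$records$abundance, tr$saprobic_value[idx],
                           tr$saprobic_weight[idx])
    if (is.nan(exp)) {
      expect_false(res$assessable)
    } else {
      expect_equal(res$raw_value, exp, tolerance = 1e-12)
    }
  }
})

test_that("saprobic index flags insufficient indicator taxa instead of erroring", {
  tr <- tiny_traits()
  s <- tiny_sample(c(Baetis = 10, Perla = 3))
  r <- saprobic_index(s, tr)   # default minimum is 5 indicator taxa
  expect_false(r$assessable)
  expect_true(is.na(r$raw_value))
  expect_equal(r$n_contributing_taxa, 2L)
})

test_that("class-weighted indicator index evaluates its defining ratio", {
  # one taxon: index equals its score
  tr1 <- trait_table(data.frame(taxon_name = "A", fauna_index_score = 2))
  s1 <- community_sample("s", "t", data.frame(taxon_name = "A", abundance = 50))
  expect_equal(class_weighted_indicator_index(s1, tr1,
                                              "fauna_index_score")$raw_value, 2)

  # v = +2 at class 3, v = -2 at class 1: (2*3 - 2*1) / 4 = 1
  tr2 <- trait_table(data.frame(taxon_name = c("A", "B"),
                                fauna_index_score = c(2, -2)))
  s2 <- community_sample("s", "t", data.frame(taxon_name = c("A", "B"),
                                              abundance = c(11, 1)))
  expect_equal(class_weighted_indicator_index(s2, tr2,
                                              "fauna_index_score")$raw_value,
               1.0)

  # presence/absence: unweighted mean of the scores
  tr <- tiny_traits()
  s <- to_presence_absence(tiny_sample())
  r <- class_weighted_indicator_index(s, tr, "fauna_index_score")
  expect_equal(r$raw_value,
               mean(tr$fauna_index_score, na.rm = TRUE))

  # no scored taxa: flagged, not an error
  none <- trait_table(data.frame(taxon_name = "Z", saprobic_value = 2,
                                 saprobic_weight = 2))
  r0 <- class_weighted_indicator_index(tiny_sample(c(Z = 5)), none,
                                       "fauna_index_score")
  expect_false(r0$assessable)
})

test_that("proportion metric handles group and fractional preference selectors", {
  tr <- tiny_traits()
  # all taxa selected -> 100%
  s_all <- tiny_sample(c(Baetis = 10, Perla = 20))
  expect_equal(proportion_metric(s_all, tr,
                                 list(groups = c("Ephemeroptera",
                                                 "Plecoptera")))$raw_value,
               100)
  # 30 of 100 individuals
  s <- tiny_sample(c(Baetis = 30, Chironomus = 70))
  expect_equal(proportion_metric(s, tr,
                                 list(groups = c("Ephemeroptera", "Plecoptera",
                                                 "Trichoptera")))$raw_value,
               30)
  # fractional pelal shares vs hand-computed weighted sum
  s5 <- tiny_sample(c(Asellus = 10, Chironomus = 20, Pisidium = 5,
                      Radix = 5, Baetis = 60))
  expected <- 100 * (0.2 * 10 + 0.8 * 20 + 0.6 * 5) / 100
  expect_equal(proportion_metric(s5, tr,
                                 list(preference = "pelal"))$raw_value,
               expected, tolerance = 1e-12)
  # empty sample flagged
  empty <- community_sample("E", "T", data.frame(taxon_name = character(0),
                                                 abundance = numeric(0)))
  expect_false(proportion_metric(empty, tr, list(preference = "pelal"))$assessable)
})

test_that("proportion metrics over a partitioning selector family sum to <= 100", {
  tr <- generate_trait_table(seed = 3)
  coh <- generate_cohort(tr, n_samples = 30, seed = 3)
  for (s in coh[1:10]) {
    tot <- sum(vapply(c("pelal", "littoral", "epirhithral"), function(cat) {
      proportion_metric(s, tr, list(preference = cat))$raw_value
    }, numeric(1)))
    expect_lte(tot, 100 + 1e-9)
  }
})

test_that("richness metric counts distinct selected taxa and ignores abundance", {
  tr <- tiny_traits()
  s <- tiny_sample()
  r <- richness_metric(s, tr, list(groups = "Trichoptera"))
  expect_equal(r$raw_value, 1)
  all3 <- richness_metric(s, tr, list(groups = c("Ephemeroptera",
                                                 "Plecoptera",
                                                 "Trichoptera")))
  expect_equal(all3$raw_value, 3)
  expect_equal(richness_metric(to_presence_absence(s), tr,
                               list(groups = c("Ephemeroptera", "Plecoptera",
                                               "Trichoptera")))$raw_value,
               all3$raw_value)
  empty <- community_sample("E", "T", data.frame(taxon_name = character(0),
                                                 abundance = numeric(0)))
  expect_equal(richness_metric(empty, tr, list(groups = "Trichoptera"))$raw_value,
               0)
})

test_that("presence-based metrics are exactly invariant under the transform", {
  tr <- generate_trait_table(seed = 11)
  coh <- generate_cohort(tr, n_samples = 40, seed = 11)
  spec <- metric_spec("tri", kernel = "richness", family = "presence_based",
                      anchors = c(0, 8), selector = list(groups = "Trichoptera"))
  ab <- vapply(coh, function(s) compute_metric(s, tr, spec)$raw_value,
               numeric(1))
  pa <- vapply(coh, function(s) {
    compute_metric(to_presence_absence(s), tr, spec)$raw_value
  }, numeric(1))
  expect_identical(ab, pa)
})

test_that("class-based metrics under presence/absence reduce to unweighted means", {
  tr <- generate_trait_table(seed = 5)
  coh <- generate_cohort(tr, n_samples = 10, seed = 5)
  for (s in coh[1:5]) {
    p <- to_presence_absence(s)
    r <- class_weighted_indicator_index(p, tr, "fauna_index_score")
    idx <- match(p$records$taxon_key, tr$taxon_key)
    v <- tr$fauna_index_score[idx]
    expect_equal(r$raw_value, mean(v[!is.na(v)]), tolerance = 1e-12)
  }
})

test_that("increasing the count of a max-saprobity taxon never lowers the index", {
  tr <- tiny_traits()                      # Chironomus has the max s (3.4)
  base <- c(Baetis = 30, Perla = 5, Hydropsyche = 12, Asellus = 40,
            Chironomus = 10, Pisidium = 3, Radix = 2)
  vals <- vapply(c(10, 50, 200, 900, 5000), function(k) {
    base["Chironomus"] <- k
    saprobic_index(tiny_sample(base), tr)$raw_value
  }, numeric(1))
  expect_true(all(diff(vals) >= 0))
})
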