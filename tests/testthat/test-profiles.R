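test_that("reading profiles drops zero-abundance rows with a message", {
  d <- withr::local_tempdir()
  fx <- write_profile_fixture(
    d,
    data.frame(dataset = c("S1", "S1", "M1"),
               lineage = acido_lineage(c("A", "B", "A")),
               relative_abundance_pct = c(10, 0, 1)),
    data.frame(dataset = c("S1", "M1"), habitat = c("soil", "marine")))
  expect_message(x <- read_profiles(fx$profiles, fx$habitats),
                 "1 zero-abundance")
  expect_equal(nrow(x$records), 2L)
})

test_that("unknown habitat labels and unmapped datasets are load errors", {
  d <- withr::local_tempdir()
  fx <- write_profile_fixture(
    d,
    data.frame(dataset = "S1", lineage = acido_lineage("A"),
               relative_abundance_pct = 5),
    data.frame(dataset = "S1", habitat = "sediment"))
  expect_error(read_profiles(fx$profiles, fx$habitats), "sediment")

  fx <- write_profile_fixture(
    d,
    data.frame(dataset = c("S1", "S9"), lineage = acido_lineage(c("A", "A")),
               relative_abundance_pct = c(5, 5)),
    data.frame(dataset = "S1", habitat = "soil"))
  expect_error(read_profiles(fx$profiles, fx$habitats), "S9")
})

test_that("duplicate (dataset, lineage) pairs are rejected", {
  expect_error(
    habitat_profiles(
      data.frame(dataset = c("S1", "S1"),
                 lineage = acido_lineage(c("A", "A")),
                 abundance = c(1, 2)),
      c(S1 = "soil")),
    "duplicate")
})

test_that("write/read round-trip reproduces the collection", {
  x <- mini_profiles()
  d <- withr::local_tempdir()
  pf <- file.path(d, "p.tsv"); hf <- file.path(d, "h.tsv")
  write_profiles(x, pf, hf)
  y <- read_profiles(pf, hf)
  o1 <- order(x$records$dataset, x$records$lineage)
  o2 <- order(y$records$dataset, y$records$lineage)
  expect_equal(x$records[o1, ], y$records[o2, ], ignore_attr = TRUE)
  expect_identical(x$habitat_of[sort(names(x$habitat_of))],
                   y$habitat_of[sort(names(y$habitat_of))])
})

test_that("aggregation sums sub-lineages within a dataset", {
  x <- habitat_profiles(
    data.frame(dataset = "S1",
               lineage = c(acido_lineage("A", "Ord1", "Fam1"),
                           acido_lineage("A", "Ord1", "Fam2")),
               abundance = c(1.5, 2.5)),
    c(S1 = "soil"))
  agg <- aggregate_to_rank(x, "order")
  expect_equal(nrow(agg$records), 1L)
  expect_equal(agg$records$abundance, 4.0)
  expect_identical(agg$records$lineage, acido_lineage("A", "Ord1"))
})

test_that("aggregation at the native rank is the identity", {
  x <- mini_profiles()  # class-level records
  agg <- aggregate_to_rank(x, "class")
  o1 <- order(x$records$dataset, x$records$lineage)
  o2 <- order(agg$records$dataset, agg$records$lineage)
  expect_equal(x$records[o1, c("dataset", "lineage", "abundance")],
               agg$records[o2, c("dataset", "lineage", "abundance")],
               ignore_attr = TRUE)
})

test_that("aggregation conserves per-dataset totals and uniqueness", {
  small <- stats::setNames(rep(10L, 7), HABITAT_LEVELS)
  x <- simulate_profiles(profile_sim_config(n_datasets = small, seed = 21))
  before <- tapply(x$records$abundance, x$records$dataset, sum)
  for (rk in c("class", "phylum", "domain")) {
    agg <- aggregate_to_rank(x, rk)
    after <- tapply(agg$records$abundance, agg$records$dataset, sum)
    expect_equal(after[names(before)], before, tolerance = 1e-12)
    expect_equal(anyDuplicated(agg$records[, c("dataset", "lineage")]), 0L)
  }
})

test_that("the 70-dataset synthetic fixture covers all habitats", {
  small <- stats::setNames(rep(10L, 7), HABITAT_LEVELS)
  x <- simulate_profiles(profile_sim_config(n_datasets = small, seed = 21))
  expect_length(x$habitat_of, 70L)
  expect_setequal(unique(unname(x$habitat_of)), HABITAT_LEVELS)
  expect_lte(nrow(x$records), 70L * 5L)
  expect_true(all(unique(x$records$lineage) %in%
                    vapply(phylohab:::default_taxa(), `[[`, "", "lineage")))
})
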