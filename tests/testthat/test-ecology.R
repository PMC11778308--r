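test_that("per-habitat metrics count detections against habitat totals", {
  m <- compute_metrics(mini_profiles(), "class")
  ph <- m$per_habitat
  expect_true(all(ph$n_detected <= ph$n_datasets))
  a <- ph[ph$taxon == acido_lineage("A"), ]
  expect_equal(a$ubiquity_pct[a$habitat == "soil"], 100)
  expect_equal(a$ubiquity_pct[a$habitat == "marine"], 100)
  # habitat with zero datasets: undefined, not zero
  expect_true(is.na(a$ubiquity_pct[a$habitat == "engineered"]))
  # taxon B: soil only
  b <- m$summary[m$summary$taxon == acido_lineage("B"), ]
  expect_equal(b$soil_ubiquity_pct, 50)
  expect_equal(b$nonsoil_ubiquity_pct, 0)
  expect_true(is.infinite(b$preference_ratio))
  expect_true(b$ratio_denom_zero)
})

test_that("non-soil aggregates pool datasets and exclude host-associated", {
  # taxon A: detected in soil 2/2, marine 1/1, freshwater 0/1, host 1/1.
  # pooled non-soil (marine + freshwater, host excluded) = 1/2 = 50, NOT the
  # per-habitat percentage average (100 + 0)/2 computed over habitats.
  m <- compute_metrics(mini_profiles(), "class")
  a <- m$summary[m$summary$taxon == acido_lineage("A"), ]
  expect_equal(a$nonsoil_n_datasets, 2L)
  expect_equal(a$nonsoil_n_detected, 1L)
  expect_equal(a$nonsoil_ubiquity_pct, 50)
  expect_equal(a$preference_ratio, 2)
  # host-associated abundance (0.5) must not enter the non-soil mean
  expect_equal(a$nonsoil_mean_abundance_pct, 1)
  # but host detections do count toward the rarity total
  expect_equal(a$n_studies_total, 4L)
})

test_that("mean abundance is detection-conditional by default, with the
          over-all-datasets alternative available", {
  m1 <- compute_metrics(mini_profiles(), "class")
  a1 <- m1$summary[m1$summary$taxon == acido_lineage("A"), ]
  expect_equal(a1$soil_mean_abundance_pct, 15)     # (10 + 20) / 2 detected
  m2 <- compute_metrics(mini_profiles(), "class",
                        abundance_over_detected = FALSE)
  a2 <- m2$summary[m2$summary$taxon == acido_lineage("A"), ]
  expect_equal(a2$soil_mean_abundance_pct, 15)     # detected in all soil here
  b2 <- m2$summary[m2$summary$taxon == acido_lineage("B"), ]
  expect_equal(b2$soil_mean_abundance_pct, 2.5)    # 5 over 2 soil datasets
})

test_that("preference cutoffs are strict inequalities", {
  s <- data.frame(taxon = c("t75", "tover"),
                  soil_ubiquity_pct = c(75, 75.01),
                  nonsoil_ubiquity_pct = c(10, 10),
                  preference_ratio = c(4, 4.01),
                  ratio_denom_zero = FALSE,
                  soil_mean_abundance_pct = c(2, 2),
                  nonsoil_mean_abundance_pct = c(2, 1),
                  abundance_ratio = c(1, 2),
                  n_studies_total = 1000L)
  calls <- classify_preference(s)
  expect_equal(calls$ubiquity_call, c("not-ubiquitous", "ubiquitous"))
  expect_equal(calls$preference_call,
               c("not-soil-preferring", "soil-preferring"))
  expect_equal(calls$abundance_call, c("not-soil-enriched", "soil-enriched"))
  # a taxon sitting exactly on every cutoff fails all three calls
  expect_equal(calls$summary, c("NSPL", "SPL"))
})

test_that("rare taxa override the summary and NSPL needs all calls negative", {
  s <- data.frame(taxon = c("rare", "nspl"),
                  soil_ubiquity_pct = c(90, 10),
                  nonsoil_ubiquity_pct = c(5, 40),
                  preference_ratio = c(18, 0.25),
                  ratio_denom_zero = FALSE,
                  soil_mean_abundance_pct = c(5, 0.2),
                  nonsoil_mean_abundance_pct = c(0.5, 2),
                  abundance_ratio = c(10, 0.1),
                  n_studies_total = c(249L, 251L))
  calls <- classify_preference(s, rare_cutoff = 250)
  expect_equal(calls$summary, c("rare", "NSPL"))
  # without the rare cutoff the first taxon is a clean SPL
  expect_equal(classify_preference(s, rare_cutoff = 0)$summary[1], "SPL")
})

test_that("classification is monotone in soil detections", {
  n_soil <- 100L
  calls <- sapply(0:100, function(k) {
    s <- data.frame(taxon = "t",
                    soil_ubiquity_pct = 100 * k / n_soil,
                    nonsoil_ubiquity_pct = 18,
                    preference_ratio = (100 * k / n_soil) / 18,
                    ratio_denom_zero = FALSE,
                    soil_mean_abundance_pct = 3,
                    nonsoil_mean_abundance_pct = 1,
                    abundance_ratio = 3,
                    n_studies_total = 10000L)
    classify_preference(s)$summary
  })
  # once SPL is reached it is never left as detections increase
  first_spl <- match("SPL", calls)
  expect_false(is.na(first_spl))
  expect_true(all(calls[first_spl:length(calls)] == "SPL"))
})

test_that("breadth calls require all seven habitats for a generalist", {
  # planted: 3 generalists (detection everywhere), 2 soil-only specialists
  small <- stats::setNames(rep(40L, 7), HABITAT_LEVELS)
  gen <- lapply(paste0("Gen", 1:3), function(cl)
    taxon_spec(acido_lineage(cl), 0.9, 1))
  spc <- lapply(paste0("Spc", 1:2), function(cl)
    taxon_spec(acido_lineage(cl), c(soil = 0.9), c(soil = 1)))
  x <- simulate_profiles(profile_sim_config(n_datasets = small,
                                            taxa = c(gen, spc), seed = 8))
  b <- classify_breadth(x, "class", min_studies = 10)
  expect_equal(sum(b$call == "generalist"), 3L)
  expect_equal(sum(b$call == "specialist"), 2L)
  expect_true(all(b$n_habitats_detected[grepl("Spc", b$taxon)] == 1L))
})

test_that("the rare-study cutoff flags instead of reclassifying", {
  small <- stats::setNames(c(300L, rep(0L, 6)), HABITAT_LEVELS)
  x <- simulate_profiles(profile_sim_config(
    n_datasets = small,
    taxa = list(taxon_spec(acido_lineage("OnlySoil"), c(soil = 1),
                           c(soil = 1))),
    seed = 2))
  out <- classify_breadth(x, "class", min_studies = 301)
  expect_equal(out$call, "rare-excluded")
  expect_equal(out$call_unfiltered, "specialist")
  out2 <- classify_breadth(x, "class", min_studies = 300)
  expect_equal(out2$call, "specialist")
})

test_that("genome-based breadth uses the two-or-more-habitat rule", {
  rec <- small_genome_records()
  rec$class <- rep(c("Multi", "Single"), length.out = nrow(rec))
  rec$habitat[rec$class == "Single"] <- "freshwater"
  tab <- genome_table(rec)
  b <- classify_breadth_from_genomes(tab, min_genomes = 5)
  expect_equal(b$call[b$taxon == "Multi"], "generalist")
  expect_equal(b$call[b$taxon == "Single"], "specialist")

  # four freshwater genomes: excluded under the cutoff, specialist without
  rec4 <- rec[rec$class == "Single", ][1:4, ]
  b4 <- classify_breadth_from_genomes(genome_table(rec4), min_genomes = 5)
  expect_equal(b4$call, "rare-excluded")
  expect_equal(b4$call_unfiltered, "specialist")
})

test_that("a class with genomes from five habitats is a generalist", {
  # shaped like the genome survey row with 231 genomes over five habitats
  n <- c(soil = 44, engineered = 35, freshwater = 59,
         `host-associated` = 47, marine = 46)
  rec <- small_genome_records(n_rep = 1)[rep(1, sum(n)), ]
  rec$accession <- sprintf("V%03d", seq_len(sum(n)))
  rec$class <- "Vicinamibacteria"
  rec$habitat <- rep(names(n), n)
  b <- classify_breadth_from_genomes(genome_table(rec))
  expect_equal(b$n_habitats, 5L)
  expect_equal(b$call, "generalist")
})

test_that("empirical ubiquity converges to the planted detection probability", {
  for (p in c(0.2, 0.7)) {
    n <- 4000L
    x <- simulate_profiles(profile_sim_config(
      n_datasets = stats::setNames(c(n, rep(0L, 6)), HABITAT_LEVELS),
      taxa = list(taxon_spec(acido_lineage("T"), c(soil = p), c(soil = 1))),
      seed = 31))
    m <- compute_metrics(x, "class")
    # three binomial standard errors
    tol <- 3 * 100 * sqrt(p * (1 - p) / n)
    expect_lt(abs(m$summary$soil_ubiquity_pct - 100 * p), tol)
  }
})

test_that("half-up rounding follows the reporting convention", {
  expect_equal(round_half_up(0.125, 2), 0.13)
  expect_equal(round_half_up(-0.125, 2), -0.13)
  expect_equal(round_half_up(95.746, 1), 95.7)
  expect_equal(round_half_up(2.5), 3)
})
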