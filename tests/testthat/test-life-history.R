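test_that("investment indices follow the two formulas exactly", {
  p <- compute_indices(data.frame(
    accession = c("G1", "G2"), tf_count = c(100, 50),
    total_genes = c(4000, 2000),
    secreted_cazymes = c(10, 20), secreted_proteases = c(5, 10),
    secreted_lipases = c(5, 10), bgc_count = c(10, 20),
    transporter_count = c(60, 120)))
  expect_equal(p$regulatory_index, c(0.025, 0.025))
  expect_equal(p$acquisition_index, c(0.5, 0.5))
  # scale-free: doubling every count leaves both indices unchanged
  expect_equal(p$regulatory_index[1], p$regulatory_index[2])
  expect_equal(p$acquisition_index[1], p$acquisition_index[2])
})

test_that("zero denominators flag the profile instead of zeroing it", {
  p <- compute_indices(data.frame(
    accession = "G1", tf_count = 10, total_genes = 0,
    secreted_cazymes = 1, secreted_proteases = 1, secreted_lipases = 1,
    bgc_count = 1, transporter_count = 0))
  expect_true(p$undefined_regulatory)
  expect_true(p$undefined_acquisition)
  expect_true(is.na(p$regulatory_index))
  expect_true(is.na(p$acquisition_index))
  expect_error(compute_indices(data.frame(
    accession = "G1", tf_count = -1, total_genes = 10,
    secreted_cazymes = 0, secreted_proteases = 0, secreted_lipases = 0,
    bgc_count = 0, transporter_count = 1)), "negative")
})

test_that("training recovers tight planted clusters", {
  tight <- list(ruderal = list(mean = c(0.070, 0.30), sd = c(1e-5, 1e-4)),
                competitor = list(mean = c(0.040, 1.20), sd = c(1e-5, 1e-4)),
                scarcity = list(mean = c(0.018, 0.15), sd = c(1e-5, 1e-4)))
  tr <- simulate_training_profiles(seed = 7, clusters = tight)
  model <- train_strategy_model(tr, seed = 1)
  # with negligible dispersion, centroids sit on the planted means
  z <- function(v) (v - model$scaling$center) / model$scaling$sd
  for (s in names(tight)) {
    got <- model$centroids[match(s, model$labels), ]
    expect_lt(max(abs(got - z(tight[[s]]$mean))), 0.01)
  }
})

test_that("the model is invariant to training row order", {
  tr <- simulate_training_profiles(seed = 7)
  m1 <- train_strategy_model(tr, seed = 1)
  set.seed(99)
  m2 <- train_strategy_model(tr[sample(nrow(tr)), ], seed = 1)
  expect_identical(m1$centroids, m2$centroids)
  expect_identical(m1$labels, m2$labels)
})

test_that("inadequate training sets are rejected", {
  tr <- simulate_training_profiles(seed = 7)
  expect_error(train_strategy_model(tr[tr$label != "scarcity", ], seed = 1),
               "3 points spanning")
  # two spatial clusters share a majority label: no clean labelling exists
  bad <- tr
  bad$label[bad$label == "scarcity"] <- "competitor"
  bad$label[which(bad$label == "ruderal")[1:2]] <- "scarcity"
  expect_error(train_strategy_model(bad, seed = 1), "cleaner training set")
})

test_that("assignment is nearest-centroid with deterministic tie-breaks", {
  tr <- simulate_training_profiles(seed = 7)
  model <- train_strategy_model(tr, seed = 1)
  # a profile placed exactly at a centroid gets that centroid's label
  raw <- sweep(sweep(model$centroids, 2, model$scaling$sd, "*"), 2,
               model$scaling$center, "+")
  at_centroids <- data.frame(accession = model$labels,
                             regulatory_index = raw[, 1],
                             acquisition_index = raw[, 2])
  asn <- assign_strategy(model, at_centroids)
  expect_equal(asn$strategy, model$labels)
  expect_equal(asn$distance, rep(0, 3), tolerance = 1e-9)

  # equidistant point: fixed label order (competitor first) and a flag
  sym <- structure(list(
    centroids = matrix(c(-1, 1, 5, 0, 0, 5), 3, 2,
                       dimnames = list(NULL, c("regulatory_index",
                                               "acquisition_index"))),
    labels = c("competitor", "ruderal", "scarcity"),
    scaling = list(center = c(regulatory_index = 0, acquisition_index = 0),
                   sd = c(regulatory_index = 1, acquisition_index = 1),
                   standardized = FALSE),
    seed = 1, n_training = 3), class = "strategy_model")
  tiep <- assign_strategy(sym, data.frame(regulatory_index = 0,
                                          acquisition_index = 0))
  expect_equal(tiep$strategy, "competitor")
  expect_true(tiep$tie)

  # undefined profiles are explicitly unassignable
  und <- assign_strategy(model, data.frame(regulatory_index = NA_real_,
                                           acquisition_index = 1,
                                           undefined_regulatory = TRUE,
                                           undefined_acquisition = FALSE))
  expect_true(und$unassignable)
  expect_true(is.na(und$strategy))
})

test_that("a planted cohort is recovered with the planted mixture", {
  tr <- simulate_training_profiles(seed = 7)
  model <- train_strategy_model(tr, seed = 1)
  mix <- c(competitor = 0.5, ruderal = 0.3, scarcity = 0.2)
  coh <- simulate_investment_cohort(n = 500, mixture = mix, seed = 4)
  asn <- assign_strategy(model, coh$profiles)
  expect_gte(mean(asn$strategy == coh$labels), 0.95)
  got <- table(asn$strategy) / nrow(coh$profiles)
  for (s in names(mix)) {   # within 3 binomial standard errors
    tol <- 3 * sqrt(mix[[s]] * (1 - mix[[s]]) / 500)
    expect_lt(abs(got[[s]] - mix[[s]]), tol + 0.02)
  }
  # idempotent and order-invariant
  asn2 <- assign_strategy(model, coh$profiles[rev(seq_len(500)), ])
  expect_equal(rev(asn2$strategy), asn$strategy)
})

test_that("strategy models survive JSON round-trips", {
  tr <- simulate_training_profiles(seed = 7)
  model <- train_strategy_model(tr, seed = 1)
  path <- withr::local_tempfile(fileext = ".json")
  write_strategy_model(model, path)
  model2 <- read_strategy_model(path)
  expect_equal(model2$centroids, model$centroids, ignore_attr = TRUE,
               tolerance = 1e-12)
  coh <- simulate_investment_cohort(n = 50, seed = 9)
  expect_equal(assign_strategy(model2, coh$profiles)$strategy,
               assign_strategy(model, coh$profiles)$strategy)
})
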