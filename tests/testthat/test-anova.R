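test_that("balanced two-by-two design matches the closed-form class SS", {
  set.seed(14)
  n_per <- 25
  cls <- rep(c("a", "b"), each = 2 * n_per)
  hab <- rep(rep(c("soil", "marine"), each = n_per), 2)
  y <- rnorm(length(cls), sd = 1) + ifelse(cls == "a", 0, 3)
  fit <- fit_type3_anova(y, cls, hab, tukey = FALSE)
  t <- fit$terms
  # on balanced data, the type III class SS is the classical between-class SS
  closed <- sum(tapply(y, cls, length) * (tapply(y, cls, mean) - mean(y))^2)
  expect_equal(t$ss[t$term == "class"], closed, tolerance = 1e-10)
  # habitat and interaction carry no planted signal
  expect_gt(t$p_value[t$term == "habitat"], 1e-4)
  expect_gt(t$p_value[t$term == "interaction"], 1e-4)
  # and type III coincides with sequential SS on balanced data
  seq_ss <- anova(lm(y ~ factor(cls) * factor(hab)))[["Sum Sq"]]
  expect_equal(t$ss, c(seq_ss[1:3], seq_ss[4]), tolerance = 1e-10,
               ignore_attr = TRUE)
})

test_that("type III SS equals brute-force full-vs-reduced residual SS", {
  skip_if_not_installed("MASS")
  set.seed(7)
  for (i in 1:25) {
    d <- random_design(sample(2:4, 1), sample(2:4, 1))
    y <- rnorm(nrow(d)) + as.integer(factor(d$cls)) * runif(1, 0, 2)
    fit <- fit_type3_anova(y, d$cls, d$hab, tukey = FALSE)
    oracle <- brute_force_type3(y, d$cls, d$hab)
    got <- fit$terms$ss[match(names(oracle), fit$terms$term)]
    expect_equal(got, unname(oracle), tolerance = 1e-8)
  }
})

test_that("type III terms agree with the car reference implementation", {
  skip_if_not_installed("car")
  set.seed(99)
  n <- 80
  cls <- factor(sample(letters[1:3], n, TRUE))
  hab <- factor(sample(LETTERS[1:4], n, TRUE))
  y <- rnorm(n) + as.integer(cls) * 0.5
  fit <- fit_type3_anova(y, cls, hab, tukey = FALSE)
  ref <- car::Anova(lm(y ~ cls * hab,
                       contrasts = list(cls = "contr.sum",
                                        hab = "contr.sum")), type = 3)
  expect_equal(fit$terms$ss, ref[["Sum Sq"]][2:5], tolerance = 1e-10)
  expect_equal(fit$terms$p_value[1:3], ref[["Pr(>F)"]][2:4],
               tolerance = 1e-10)
})

test_that("percentage contributions are a nonnegative partition of 100", {
  set.seed(3)
  d <- random_design(3, 3)
  y <- rnorm(nrow(d))
  fit <- fit_type3_anova(y, d$cls, d$hab, tukey = FALSE)
  expect_true(all(fit$terms$ss >= 0))
  expect_equal(sum(fit$terms$pct_contribution), 100, tolerance = 1e-6)
  fit2 <- fit_type3_anova(y, d$cls, d$hab, tukey = FALSE,
                          pct_denominator = "explained")
  keep <- fit2$terms$term != "residual"
  expect_equal(sum(fit2$terms$pct_contribution[keep]), 100, tolerance = 1e-6)
})

test_that("degenerate designs fail loudly", {
  expect_error(fit_type3_anova(rnorm(10), rep("a", 10),
                               rep(c("x", "y"), 5)),
               "fewer than 2 levels")
  # one observation per cell with interaction: saturated
  d <- expand.grid(cls = c("a", "b"), hab = c("x", "y"))
  expect_error(fit_type3_anova(rnorm(4), d$cls, d$hab), "saturated")
})

test_that("empty cells drop unestimable interaction columns, not the fit", {
  set.seed(4)
  d <- random_design(3, 3)
  d <- d[!(d$cls == "c1" & d$hab == "h1"), ]   # knock out one cell
  y <- rnorm(nrow(d))
  fit <- fit_type3_anova(y, d$cls, d$hab, tukey = FALSE)
  expect_gt(length(fit$dropped_columns), 0)
  expect_equal(fit$terms$df[fit$terms$term == "interaction"], 3L)
})

test_that("a constant feature yields ns tiers through the batch, which
          completes", {
  rec <- small_genome_records()
  rec$gc_pct <- 50
  tab <- genome_table(rec)
  batch <- batch_partition(tab)
  s <- batch$summary
  expect_equal(s$class_tier[s$name == "gc_pct"], "ns")
  expect_equal(s$specificity[s$name == "gc_pct"], "neither")
  expect_true(all(CONTINUOUS_FEATURES %in% s$name))
})

test_that("batch partition flags planted lineage-only and habitat-only
          structure", {
  cc <- default_class_design()
  fm <- phylohab:::default_feature_models()
  for (f in names(fm)) {              # lineage-only world, uniform effect
    fm[[f]]$habitat_share <- 0
    fm[[f]]$class_share <- 20
  }
  cfg <- genome_sim_config(cell_counts = cc, feature_models = fm,
                           trait_models = list(
                             hab_only = trait_model(-1.5,
                                                    habitat_logits = c(soil = 3)),
                             null_1 = trait_model(0)),
                           seed = 5)
  sim <- simulate_genomes(cfg)
  batch <- batch_partition(sim$table)
  s <- batch$summary
  cont <- s[s$name %in% CONTINUOUS_FEATURES, ]
  expect_true(all(cont$class_tier == "strong"))
  expect_false(any(cont$specificity == "habitat-specific"))
  expect_equal(s$specificity[s$name == "hab_only"], "habitat-specific")
  expect_equal(s$specificity[s$name == "null_1"], "neither")
})
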