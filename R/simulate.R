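#' Synthetic data with planted, recoverable structure
#'
#' Every input the pipeline consumes can be generated offline with known
#' ground truth: taxonomic profile collections with planted per-habitat
#' detection probabilities and abundances, genome feature tables with
#' planted class/habitat variance shares, binary traits with planted logit
#' effects, and life-history training/cohort sets drawn from planted
#' clusters. All generators are pure functions of (config, seed).
#'
#' @name synthetic-data
NULL

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv())
          else if (exists(".Random.seed", globalenv()))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  force(code)
}

#' Default number of datasets per habitat
#'
#' The per-habitat dataset counts of the metagenome corpus the ecology
#' metrics are designed for: soil 10250, engineered 16320, freshwater
#' 11408, host-associated 165152, marine 13880, non-marine saline and
#' alkaline 1306, terrestrial non-soil 5039 (freshwater derived from the
#' pooled non-host non-soil total of 47953).
#'
#' @return named integer vector over [HABITAT_LEVELS].
#' @export
default_dataset_counts <- function() {
  stats::setNames(c(10250L, 16320L, 11408L, 165152L, 13880L, 1306L, 5039L),
                  HABITAT_LEVELS)
}

#' Describe a simulated taxon
#'
#' @param lineage prefixed lineage string.
#' @param detection_prob per-habitat detection probability; a single number
#'   recycles across habitats, a named vector overrides per habitat.
#' @param abundance_mean per-habitat mean relative abundance (percent) given
#'   detection; single number or named vector.
#' @param abundance_dispersion log-normal sdlog of the detected abundances.
#' @return named list (a taxon spec for [profile_sim_config()]).
#' @export
taxon_spec <- function(lineage, detection_prob, abundance_mean,
                       abundance_dispersion = 1) {
  expand <- function(v) {
    if (length(v) == 1L && is.null(names(v))) {
      return(stats::setNames(rep(as.numeric(v), length(HABITAT_LEVELS)),
                             HABITAT_LEVELS))
    }
    out <- stats::setNames(rep(0, length(HABITAT_LEVELS)), HABITAT_LEVELS)
    bad <- setdiff(names(v), HABITAT_LEVELS)
    if (length(bad)) stop("unknown habitat(s): ", paste(bad, collapse = ", "),
                          call. = FALSE)
    out[names(v)] <- as.numeric(v)
    out
  }
  p <- expand(detection_prob)
  if (any(p < 0 | p > 1)) stop("detection probabilities must be in [0, 1]",
                               call. = FALSE)
  m <- expand(abundance_mean)
  if (any(m[p > 0] <= 0)) {
    stop("abundance mean must be positive wherever detection is possible",
         call. = FALSE)
  }
  stopifnot(abundance_dispersion > 0)
  list(lineage = lineage, detection_prob = p, abundance_mean = m,
       abundance_dispersion = abundance_dispersion)
}

default_taxa <- function() {
  acido <- function(cls) paste0("d__Bacteria; p__Acidobacteriota; c__", cls)
  list(
    taxon_spec(acido("SoilCladeA"),
               c(soil = 0.90, engineered = 0.10, freshwater = 0.12,
                 `host-associated` = 0.02, marine = 0.05,
                 `non-marine saline and alkaline` = 0.05,
                 `terrestrial non-soil` = 0.15),
               c(soil = 10, engineered = 1, freshwater = 1,
                 `host-associated` = 0.2, marine = 0.5,
                 `non-marine saline and alkaline` = 0.5,
                 `terrestrial non-soil` = 1)),
    taxon_spec(acido("SoilCladeB"),
               c(soil = 0.80, engineered = 0.15, freshwater = 0.15,
                 `host-associated` = 0.02, marine = 0.08,
                 `non-marine saline and alkaline` = 0.08,
                 `terrestrial non-soil` = 0.20),
               c(soil = 4, engineered = 0.8, freshwater = 0.8,
                 `host-associated` = 0.2, marine = 0.4,
                 `non-marine saline and alkaline` = 0.4,
                 `terrestrial non-soil` = 0.8)),
    taxon_spec(acido("SedimentClade"),
               c(soil = 0.12, engineered = 0.45, freshwater = 0.55,
                 `host-associated` = 0.03, marine = 0.50,
                 `non-marine saline and alkaline` = 0.40,
                 `terrestrial non-soil` = 0.25),
               c(soil = 0.5, engineered = 3, freshwater = 3,
                 `host-associated` = 0.2, marine = 3,
                 `non-marine saline and alkaline` = 2,
                 `terrestrial non-soil` = 1)),
    taxon_spec(acido("CosmopolitanClade"), 0.30, 1),
    taxon_spec(acido("RareClade"), 0.001, 0.1))
}

#' Configuration for the profile simulator
#'
#' @param n_datasets named integer vector: datasets per habitat (defaults to
#'   [default_dataset_counts()]).
#' @param taxa list of [taxon_spec()] entries (defaults plant two
#'   soil-preferring clades, a sediment-preferring clade, a moderate
#'   generalist and a rare clade).
#' @param seed integer seed.
#' @return validated config of class `profile_sim_config`.
#' @export
profile_sim_config <- function(n_datasets = default_dataset_counts(),
                               taxa = default_taxa(), seed = 1) {
  bad <- setdiff(names(n_datasets), HABITAT_LEVELS)
  if (length(bad)) stop("unknown habitat(s): ", paste(bad, collapse = ", "),
                        call. = FALSE)
  full <- stats::setNames(rep(0L, length(HABITAT_LEVELS)), HABITAT_LEVELS)
  full[names(n_datasets)] <- as.integer(n_datasets)
  if (any(full < 0)) stop("dataset counts must be nonnegative", call. = FALSE)
  structure(list(n_datasets = full, taxa = taxa, seed = as.integer(seed)),
            class = "profile_sim_config")
}

#' Simulate a taxonomic profile collection
#'
#' For every dataset and taxon, detection is Bernoulli with the planted
#' per-habitat probability; detected relative abundances are log-normal
#' with the planted mean and dispersion, truncated above at 100 percent.
#' Byte-identical output for identical (config, seed).
#'
#' @param config a [profile_sim_config()].
#' @return A [habitat_profiles] object.
#' @export
simulate_profiles <- function(config) {
  stopifnot(inherits(config, "profile_sim_config"))
  with_seed(config$seed, {
    hab_short <- c("SOIL", "ENG", "FW", "HOST", "MAR", "SAL", "TNS")
    ids <- character(0); habs <- character(0)
    for (i in seq_along(HABITAT_LEVELS)) {
      n <- config$n_datasets[[HABITAT_LEVELS[i]]]
      if (n > 0) {
        ids <- c(ids, sprintf("%s%06d", hab_short[i], seq_len(n)))
        habs <- c(habs, rep(HABITAT_LEVELS[i], n))
      }
    }
    habitat_of <- stats::setNames(habs, ids)
    recs <- vector("list", length(config$taxa))
    for (t in seq_along(config$taxa)) {
      tx <- config$taxa[[t]]
      p <- tx$detection_prob[habs]
      det <- stats::rbinom(length(ids), 1L, p) == 1L
      if (!any(det)) next
      m <- tx$abundance_mean[habs][det]
      sdl <- tx$abundance_dispersion
      ab <- stats::rlnorm(sum(det), meanlog = log(m) - sdl^2 / 2, sdlog = sdl)
      recs[[t]] <- data.frame(dataset = ids[det], lineage = tx$lineage,
                              abundance = pmin(ab, 100),
                              stringsAsFactors = FALSE)
    }
    records <- do.call(rbind, recs)
    if (is.null(records)) {
      records <- data.frame(dataset = character(0), lineage = character(0),
                            abundance = numeric(0))
    }
    habitat_profiles(records, habitat_of)
  })
}

#' Default six-class genome survey design
#'
#' The unbalanced class-by-habitat genome counts used as the generator's
#' default design (1930 genomes across six classes and seven habitats,
#' including empty cells such as the nearly empty non-marine saline
#' column), so downstream empty-cell handling is exercised by default.
#'
#' @return integer matrix, classes x [HABITAT_LEVELS].
#' @export
default_class_design <- function() {
  m <- rbind(
    Blastocatellia      = c(64, 103, 35, 8, 1, 0, 4),
    Terriglobia         = c(537, 179, 197, 50, 16, 0, 27),
    Thermoanaerobaculia = c(25, 49, 22, 37, 17, 0, 3),
    Vicinamibacteria    = c(44, 35, 59, 47, 46, 0, 0),
    Aminicenantia       = c(7, 27, 49, 0, 35, 1, 0),
    Holophagae          = c(16, 30, 151, 4, 5, 0, 0))
  colnames(m) <- HABITAT_LEVELS
  storage.mode(m) <- "integer"
  m
}

# Planted effect vectors scaled so that their genome-weighted variances
# equal the requested percentage shares of a total variance of 100.
#
# In an unbalanced design the two factors are confounded: an arbitrary class
# pattern induces between-habitat differences through the uneven cell
# counts, so part of its variance would be planted as a habitat signal. To
# plant *identifiable* structure, each factor's pattern is chosen as the
# generalized eigenvector minimizing the share of its variance explained by
# the other factor (between-other-factor variance over total weighted
# variance), then scaled to the requested share.
planted_effects <- function(cell_counts, class_share, habitat_share) {
  n_c <- rowSums(cell_counts); n_h <- colSums(cell_counts)
  N <- sum(cell_counts)
  least_confounded <- function(counts, share) {
    # pattern over rows of `counts`, minimally explainable by its columns
    out <- stats::setNames(rep(0, nrow(counts)), rownames(counts))
    if (share <= 0) return(out)
    counts <- counts[, colSums(counts) > 0, drop = FALSE]  # unused habitats
    live <- rowSums(counts) > 0
    cnt <- counts[live, , drop = FALSE]
    w_r <- rowSums(cnt); w_c <- colSums(cnt)
    k <- length(w_r)
    if (k < 2L) stop("need at least two non-empty rows to plant an effect",
                     call. = FALSE)
    W <- diag(w_r, k) - outer(w_r, w_r) / N       # total weighted variance
    M <- t(cnt) / w_c                             # column-mean operator
    B <- t(M) %*% (diag(w_c, length(w_c)) - outer(w_c, w_c) / N) %*% M
    C <- stats::contr.helmert(k)                  # basis of centered space
    Wc <- t(C) %*% W %*% C; Bc <- t(C) %*% B %*% C
    ev <- eigen(solve(Wc, Bc))
    u <- Re(ev$vectors[, which.min(Re(ev$values))])
    a <- as.numeric(C %*% u)
    a <- a - sum(w_r * a) / N
    out[live] <- a * sqrt(share / (sum(w_r * a^2) / N))
    out
  }
  a <- stats::setNames(least_confounded(cell_counts, class_share),
                       rownames(cell_counts))
  b <- stats::setNames(least_confounded(t(cell_counts), habitat_share),
                       colnames(cell_counts))
  cov_ab <- sum(cell_counts * outer(a, b)) / N
  list(class_effects = a, habitat_effects = b, cov = cov_ab)
}

#' Describe a planted continuous feature
#'
#' The feature is generated as
#' `mean + (sd / 10) * (class effect + habitat effect + noise)` where the
#' effects live on a total-variance-100 scale: the class effect pattern is
#' scaled so its genome-weighted variance equals `class_share` (a
#' percentage), likewise `habitat_share`, and the noise variance is the
#' remainder.
#'
#' @param mean,sd location and overall scale of the feature.
#' @param class_share,habitat_share planted percentage variance shares.
#' @param kind `"real"`, `"count"` (rounded, floored at 0) or `"pct"`
#'   (clamped to [0, 100]); `"ph"` clamps to [0, 14].
#' @return a feature model (named list).
#' @export
feature_model <- function(mean, sd, class_share = 30, habitat_share = 2,
                          kind = c("real", "count", "pct", "ph")) {
  kind <- match.arg(kind)
  stopifnot(sd > 0, class_share >= 0, habitat_share >= 0,
            class_share + habitat_share < 100)
  list(mean = mean, sd = sd, class_share = class_share,
       habitat_share = habitat_share, kind = kind)
}

default_feature_models <- function() {
  list(
    genome_size = feature_model(4.5e6, 1.4e6, 35, 1.5, "count"),
    gc_pct = feature_model(58, 7, 40, 1, "pct"),
    coding_density = feature_model(88, 2.5, 25, 1, "pct"),
    mean_gene_length = feature_model(950, 70, 15, 1, "count"),
    protein_count = feature_model(4000, 1100, 30, 1.5, "count"),
    crispr_count = feature_model(3, 2, 10, 1, "count"),
    viral_contig_count = feature_model(5, 3, 12, 1, "count"),
    cazyme_count = feature_model(120, 45, 30, 2, "count"),
    peptidase_count = feature_model(90, 30, 15, 1.5, "count"),
    bgc_count = feature_model(6, 3, 8, 2, "count"),
    pred_ogt = feature_model(25, 6, 26, 2, "real"),
    pred_ph = feature_model(6.5, 1.2, 21, 2, "ph"))
}

#' Describe a planted binary trait (or binary feature)
#'
#' Presence is Bernoulli with `plogis(intercept + class term + habitat
#' term)`; `class_logits`/`habitat_logits` are named vectors of logit
#' offsets (unnamed levels get 0).
#'
#' @param intercept baseline logit.
#' @param class_logits,habitat_logits named numeric vectors.
#' @return a trait model (named list).
#' @export
trait_model <- function(intercept = 0, class_logits = numeric(0),
                        habitat_logits = numeric(0)) {
  list(intercept = intercept, class_logits = class_logits,
       habitat_logits = habitat_logits)
}

default_trait_models <- function() {
  spl <- names(default_spl_groups())[default_spl_groups() == "SPL"]
  spl_hi <- stats::setNames(rep(4.4, length(spl)), spl)   # 0.9 vs 0.1
  list(
    lineage_trait_1 = trait_model(-2.2, class_logits = spl_hi),
    lineage_trait_2 = trait_model(2.2, class_logits = -spl_hi),
    habitat_trait = trait_model(-1.5,
                                habitat_logits = c(soil = 3)),
    null_trait_1 = trait_model(0),
    null_trait_2 = trait_model(-1))
}

#' Default planted cluster parameters for the life-history strategies
#'
#' Cluster means/sds in (regulatory index, acquisition index) space:
#' ruderals invest in regulatory flexibility, competitors in secreted
#' resource acquisition, scarcity strategists in neither (streamlined).
#'
#' @return named list of per-strategy `list(mean = c(reg, acq), sd = c(reg,
#'   acq))`.
#' @export
default_strategy_clusters <- function() {
  list(ruderal = list(mean = c(0.070, 0.30), sd = c(0.008, 0.08)),
       competitor = list(mean = c(0.040, 1.20), sd = c(0.006, 0.15)),
       scarcity = list(mean = c(0.018, 0.15), sd = c(0.004, 0.05)))
}

#' Configuration for the genome-table simulator
#'
#' @param cell_counts class-by-habitat genome counts (defaults to the
#'   unbalanced [default_class_design()]).
#' @param feature_models named list of [feature_model()]s for the twelve
#'   continuous features.
#' @param aerobe_model [trait_model()] for the aerobic/anaerobic feature.
#' @param trait_models named list of [trait_model()]s for the binary
#'   metabolic traits (`NULL` for none).
#' @param strategy_mixture proportions over (competitor, ruderal, scarcity)
#'   summing to 1, or a per-class matrix with those columns.
#' @param strategy_clusters planted cluster parameters
#'   ([default_strategy_clusters()]).
#' @param seed integer seed.
#' @return validated config of class `genome_sim_config`.
#' @export
genome_sim_config <- function(cell_counts = default_class_design(),
                              feature_models = default_feature_models(),
                              aerobe_model = trait_model(
                                0.3, class_logits = c(Terriglobia = 1.5,
                                                      Blastocatellia = 1.5,
                                                      Aminicenantia = -2,
                                                      Holophagae = -1.5)),
                              trait_models = default_trait_models(),
                              strategy_mixture = c(competitor = 0.4,
                                                   ruderal = 0.35,
                                                   scarcity = 0.25),
                              strategy_clusters = default_strategy_clusters(),
                              seed = 1) {
  stopifnot(is.matrix(cell_counts), all(cell_counts >= 0))
  if (is.null(colnames(cell_counts)) ||
      !all(colnames(cell_counts) %in% HABITAT_LEVELS)) {
    stop("cell_counts columns must be habitat levels", call. = FALSE)
  }
  miss <- setdiff(CONTINUOUS_FEATURES, names(feature_models))
  if (length(miss)) stop("feature_models missing: ",
                         paste(miss, collapse = ", "), call. = FALSE)
  if (is.matrix(strategy_mixture)) {
    stopifnot(all(rownames(cell_counts) %in% rownames(strategy_mixture)),
              all(abs(rowSums(strategy_mixture) - 1) < 1e-8))
  } else {
    stopifnot(abs(sum(strategy_mixture) - 1) < 1e-8)
  }
  structure(list(cell_counts = cell_counts, feature_models = feature_models,
                 aerobe_model = aerobe_model, trait_models = trait_models,
                 strategy_mixture = strategy_mixture,
                 strategy_clusters = strategy_clusters,
                 seed = as.integer(seed)),
            class = "genome_sim_config")
}

logit_terms <- function(model, cls, hab) {
  eta <- rep(model$intercept, length(cls))
  if (length(model$class_logits)) {
    hit <- match(cls, names(model$class_logits))
    eta <- eta + ifelse(is.na(hit), 0, model$class_logits[hit])
  }
  if (length(model$habitat_logits)) {
    hit <- match(hab, names(model$habitat_logits))
    eta <- eta + ifelse(is.na(hit), 0, model$habitat_logits[hit])
  }
  eta
}

#' Simulate a genome table with planted ground truth
#'
#' Continuous features follow grand mean + class effect + habitat effect +
#' Gaussian noise with effect sizes set by the planted percentage variance
#' shares (see [feature_model()]); binary features and traits are Bernoulli
#' with planted logit terms; life-history strategies are drawn from the
#' mixture, with matching investment indices drawn from the planted
#' clusters. The returned `truth` record contains, per feature, the planted
#' and realized (genome-weighted, including the class-habitat covariance of
#' the unbalanced design) variance shares, plus all planted effect vectors
#' and per-genome strategy labels, sufficient to compute the expected value
#' of every downstream statistic without re-running the generator.
#'
#' @param config a [genome_sim_config()].
#' @return list with `table` (a [genome_table] with a `life_history` column
#'   and trait matrix), `indices` (per-genome investment indices) and
#'   `truth`.
#' @export
simulate_genomes <- function(config) {
  stopifnot(inherits(config, "genome_sim_config"))
  with_seed(config$seed, {
    cc <- config$cell_counts
    cls <- rep(rep(rownames(cc), times = ncol(cc)), times = as.vector(cc))
    hab <- rep(rep(colnames(cc), each = nrow(cc)), times = as.vector(cc))
    N <- length(cls)
    acc <- sprintf("SYN_%05d", seq_len(N))
    rec <- data.frame(accession = acc, class = cls, habitat = hab,
                      stringsAsFactors = FALSE)

    truth <- list(cell_counts = cc, features = list())
    for (f in CONTINUOUS_FEATURES) {
      fm <- config$feature_models[[f]]
      eff <- planted_effects(cc, fm$class_share, fm$habitat_share)
      noise_var <- 100 - fm$class_share - fm$habitat_share
      zstd <- eff$class_effects[cls] + eff$habitat_effects[hab] +
        stats::rnorm(N, 0, sqrt(noise_var))
      y <- fm$mean + fm$sd / 10 * zstd
      y <- switch(fm$kind,
                  count = pmax(0, round(y)),
                  pct = pmin(100, pmax(0, y)),
                  ph = pmin(14, pmax(0, y)),
                  y)
      rec[[f]] <- y
      tot <- fm$class_share + fm$habitat_share + 2 * eff$cov + noise_var
      truth$features[[f]] <- list(
        class_share_planted = fm$class_share,
        habitat_share_planted = fm$habitat_share,
        class_effects = eff$class_effects,
        habitat_effects = eff$habitat_effects,
        cov_class_habitat = eff$cov,
        noise_var = noise_var,
        class_share_realized = 100 * fm$class_share / tot,
        habitat_share_realized = 100 * fm$habitat_share / tot)
    }

    eta <- logit_terms(config$aerobe_model, cls, hab)
    rec$pred_aerobe <- ifelse(stats::rbinom(N, 1L, stats::plogis(eta)) == 1L,
                              "aerobic", "anaerobic")
    truth$aerobe_model <- config$aerobe_model

    mix <- config$strategy_mixture
    strategies <- if (is.matrix(mix)) {
      vapply(cls, function(cl) sample(colnames(mix), 1L, prob = mix[cl, ]),
             character(1))
    } else {
      sample(names(mix), N, replace = TRUE, prob = mix)
    }
    rec$life_history <- strategies
    clp <- config$strategy_clusters
    reg <- numeric(N); acq <- numeric(N)
    for (s in names(clp)) {
      i <- strategies == s
      reg[i] <- pmax(1e-5, stats::rnorm(sum(i), clp[[s]]$mean[1],
                                        clp[[s]]$sd[1]))
      acq[i] <- pmax(1e-4, stats::rnorm(sum(i), clp[[s]]$mean[2],
                                        clp[[s]]$sd[2]))
    }
    indices <- data.frame(accession = acc, regulatory_index = reg,
                          acquisition_index = acq,
                          stringsAsFactors = FALSE)
    truth$strategies <- stats::setNames(strategies, acc)
    truth$strategy_clusters <- clp

    traits <- NULL
    if (length(config$trait_models)) {
      traits <- matrix(0, N, length(config$trait_models),
                       dimnames = list(acc, names(config$trait_models)))
      for (tr in names(config$trait_models)) {
        eta <- logit_terms(config$trait_models[[tr]], cls, hab)
        traits[, tr] <- stats::rbinom(N, 1L, stats::plogis(eta))
      }
      truth$trait_models <- config$trait_models
    }

    list(table = genome_table(rec, traits), indices = indices, truth = truth)
  })
}

#' Simulate a labelled life-history training set
#'
#' A synthetic stand-in for the isotope-labelled training genomes: by
#' default 9 genomes per strategy (27 total) drawn from the planted
#' clusters.
#'
#' @param n_per_strategy genomes per strategy.
#' @param seed integer seed.
#' @param clusters planted cluster parameters.
#' @return data.frame with `accession`, `regulatory_index`,
#'   `acquisition_index`, `label`.
#' @export
simulate_training_profiles <- function(n_per_strategy = 9, seed = 7,
                                       clusters = default_strategy_clusters()) {
  with_seed(seed, {
    rows <- lapply(names(clusters), function(s) {
      cl <- clusters[[s]]
      data.frame(
        accession = sprintf("TRAIN_%s_%02d", toupper(substr(s, 1, 3)),
                            seq_len(n_per_strategy)),
        regulatory_index = pmax(1e-5, stats::rnorm(n_per_strategy,
                                                   cl$mean[1], cl$sd[1])),
        acquisition_index = pmax(1e-4, stats::rnorm(n_per_strategy,
                                                    cl$mean[2], cl$sd[2])),
        label = s, stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  })
}

#' Simulate an unlabelled cohort of investment profiles
#'
#' @param n cohort size.
#' @param mixture proportions over strategies (named, sums to 1).
#' @param seed integer seed.
#' @param clusters planted cluster parameters.
#' @return list with `profiles` (data.frame of indices) and `labels` (true
#'   strategies).
#' @export
simulate_investment_cohort <- function(n = 300,
                                       mixture = c(competitor = 1 / 3,
                                                   ruderal = 1 / 3,
                                                   scarcity = 1 / 3),
                                       seed = 1,
                                       clusters = default_strategy_clusters()) {
  stopifnot(abs(sum(mixture) - 1) < 1e-8)
  with_seed(seed, {
    labels <- sample(names(mixture), n, replace = TRUE, prob = mixture)
    reg <- numeric(n); acq <- numeric(n)
    for (s in names(clusters)) {
      i <- labels == s
      reg[i] <- pmax(1e-5, stats::rnorm(sum(i), clusters[[s]]$mean[1],
                                        clusters[[s]]$sd[1]))
      acq[i] <- pmax(1e-4, stats::rnorm(sum(i), clusters[[s]]$mean[2],
                                        clusters[[s]]$sd[2]))
    }
    list(profiles = data.frame(accession = sprintf("COH_%05d", seq_len(n)),
                               regulatory_index = reg,
                               acquisition_index = acq,
                               stringsAsFactors = FALSE),
         labels = labels)
  })
}
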