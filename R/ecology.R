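#' Round half away from zero
#'
#' Reported percentages use commercial (half-up) rounding, not the IEEE
#' round-half-even of [round()].
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return numeric vector.
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * trunc(abs(x) * p + 0.5) / p
}

#' Ubiquity: percentage of datasets in which a taxon is detected
#'
#' @param n_detected number of datasets with a non-zero abundance.
#' @param n_datasets total number of datasets in the habitat (or pool).
#' @return percentage in [0, 100]; `NA` when `n_datasets` is zero (a habitat
#'   with no datasets has undefined, not zero, ubiquity).
#' @examples
#' ubiquity_pct(9814, 10250) # 95.74634
#' @export
ubiquity_pct <- function(n_detected, n_datasets) {
  stopifnot(all(n_detected <= n_datasets | n_datasets == 0))
  ifelse(n_datasets > 0, 100 * n_detected / n_datasets, NA_real_)
}

#' Per-taxon, per-habitat occupancy and abundance metrics
#'
#' For every taxon at `rank`, computes per habitat: the number of datasets,
#' the number of datasets where the taxon is detected, ubiquity (percentage
#' of datasets with a detection) and mean relative abundance over the
#' datasets where the taxon is detected. Soil versus non-soil comparative
#' fields pool datasets over the five non-host, non-soil habitats
#' ([NONSOIL_COMPARE_LEVELS]); they are ratios of pooled counts, never
#' averages of per-habitat percentages.
#'
#' @param x a [habitat_profiles] object.
#' @param rank taxonomic rank at which taxa are compared.
#' @param abundance_over_detected if `TRUE` (default) mean abundance is
#'   conditional on detection; if `FALSE` it is averaged over all datasets
#'   of the habitat (absences counting as zero).
#' @return An object of class `ecology_metrics`: a list with
#'   `per_habitat` (long data.frame: taxon, habitat, n_datasets, n_detected,
#'   ubiquity_pct, mean_abundance_pct) and `summary` (one row per taxon with
#'   the pooled soil/non-soil fields, `preference_ratio`, `abundance_ratio`,
#'   `n_studies_total` and a `ratio_denom_zero` flag).
#' @export
compute_metrics <- function(x, rank, abundance_over_detected = TRUE) {
  stopifnot(inherits(x, "habitat_profiles"))
  if (nrow(x$records) == 0L) stop("empty profile collection", call. = FALSE)
  agg <- aggregate_to_rank(x, rank)
  rec <- agg$records
  rec$habitat <- unname(agg$habitat_of[rec$dataset])
  taxa <- sort(unique(rec$lineage))
  n_by_hab <- table(factor(agg$habitat_of, levels = HABITAT_LEVELS))

  per_habitat <- expand.grid(taxon = taxa, habitat = HABITAT_LEVELS,
                             KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  key <- paste(per_habitat$taxon, per_habitat$habitat, sep = "\r")
  rkey <- paste(rec$lineage, rec$habitat, sep = "\r")
  det <- table(rkey)
  absum <- rowsum(rec$abundance, rkey)
  per_habitat$n_datasets <- as.integer(n_by_hab[per_habitat$habitat])
  per_habitat$n_detected <- as.integer(det[key])
  per_habitat$n_detected[is.na(per_habitat$n_detected)] <- 0L
  sum_ab <- as.numeric(absum[match(key, rownames(absum))])
  sum_ab[is.na(sum_ab)] <- 0
  per_habitat$ubiquity_pct <- ubiquity_pct(per_habitat$n_detected,
                                           per_habitat$n_datasets)
  denom <- if (abundance_over_detected) per_habitat$n_detected else per_habitat$n_datasets
  per_habitat$mean_abundance_pct <- ifelse(denom > 0, sum_ab / denom, NA_real_)

  pool <- function(taxon, habs) {
    ph <- per_habitat[per_habitat$taxon == taxon &
                        per_habitat$habitat %in% habs, , drop = FALSE]
    n_data <- sum(ph$n_datasets)
    n_det <- sum(ph$n_detected)
    s_ab <- sum(ifelse(ph$n_detected > 0,
                       ph$mean_abundance_pct *
                         (if (abundance_over_detected) ph$n_detected else ph$n_datasets),
                       0))
    d <- if (abundance_over_detected) n_det else n_data
    c(n_data = n_data, n_det = n_det,
      mean_ab = if (d > 0) s_ab / d else NA_real_)
  }
  summ <- do.call(rbind, lapply(taxa, function(tx) {
    soil <- pool(tx, "soil")
    ns <- pool(tx, NONSOIL_COMPARE_LEVELS)
    soil_ub <- ubiquity_pct(soil[["n_det"]], soil[["n_data"]])
    ns_ub <- ubiquity_pct(ns[["n_det"]], ns[["n_data"]])
    denom_zero <- isTRUE(!is.na(ns_ub) && ns_ub == 0)
    pref <- if (is.na(soil_ub) || is.na(ns_ub)) {
      NA_real_
    } else if (ns_ub > 0) {
      soil_ub / ns_ub
    } else if (soil_ub > 0) {
      Inf
    } else {
      NA_real_  # 0/0: undefined
    }
    ab_ratio <- if (is.na(soil[["mean_ab"]]) || is.na(ns[["mean_ab"]])) {
      if (!is.na(soil[["mean_ab"]]) && is.na(ns[["mean_ab"]])) Inf else NA_real_
    } else if (ns[["mean_ab"]] > 0) {
      soil[["mean_ab"]] / ns[["mean_ab"]]
    } else {
      Inf
    }
    data.frame(taxon = tx,
               soil_n_datasets = soil[["n_data"]],
               soil_n_detected = soil[["n_det"]],
               soil_ubiquity_pct = soil_ub,
               nonsoil_n_datasets = ns[["n_data"]],
               nonsoil_n_detected = ns[["n_det"]],
               nonsoil_ubiquity_pct = ns_ub,
               preference_ratio = pref,
               ratio_denom_zero = denom_zero,
               soil_mean_abundance_pct = soil[["mean_ab"]],
               nonsoil_mean_abundance_pct = ns[["mean_ab"]],
               abundance_ratio = ab_ratio,
               n_studies_total = sum(per_habitat$n_detected[per_habitat$taxon == tx]),
               stringsAsFactors = FALSE)
  }))
  rownames(summ) <- NULL
  structure(list(per_habitat = per_habitat, summary = summ, rank = rank,
                 abundance_over_detected = abundance_over_detected),
            class = "ecology_metrics")
}

#' @export
print.ecology_metrics <- function(x, ...) {
  cat("<ecology_metrics> at rank '", x$rank, "': ", nrow(x$summary),
      " taxa\n", sep = "")
  s <- x$summary
  s$soil_ubiquity_pct <- round_half_up(s$soil_ubiquity_pct, 2)
  s$nonsoil_ubiquity_pct <- round_half_up(s$nonsoil_ubiquity_pct, 2)
  print(utils::head(s[, c("taxon", "soil_ubiquity_pct", "nonsoil_ubiquity_pct",
                          "preference_ratio", "abundance_ratio",
                          "n_studies_total")], 12L), row.names = FALSE)
  invisible(x)
}

#' Soil-preference classification from occupancy metrics
#'
#' Applies the three strict cutoffs: soil-ubiquitous if soil ubiquity
#' exceeds `cutoffs$ubiquity` (percent), soil-preferring if the
#' soil/non-soil ubiquity ratio exceeds `cutoffs$ratio`, soil-enriched if
#' the soil/non-soil mean-abundance ratio exceeds `cutoffs$abundance_ratio`.
#' A taxon is an SPL (soil-preferring lineage) when all three calls are
#' positive, an NSPL when all three are negative, otherwise intermediate;
#' taxa detected in fewer than `rare_cutoff` studies overall are called
#' rare. The separate `abundant_in_soil` column records whether soil mean
#' abundance exceeds `cutoffs$abundance` percent; it does not enter the
#' summary call.
#'
#' @param metrics an [ecology_metrics] object (or its `summary` data.frame).
#' @param cutoffs list with elements `ubiquity`, `ratio`, `abundance`,
#'   `abundance_ratio`; all comparisons are strict (`>`).
#' @param rare_cutoff minimum total number of studies with a detection.
#' @return data.frame with one row per taxon: component calls, summary call,
#'   and flags.
#' @export
classify_preference <- function(metrics,
                                cutoffs = list(ubiquity = 75, ratio = 4,
                                               abundance = 1,
                                               abundance_ratio = 1),
                                rare_cutoff = 250) {
  s <- if (inherits(metrics, "ecology_metrics")) metrics$summary else metrics
  ub_pos <- !is.na(s$soil_ubiquity_pct) & s$soil_ubiquity_pct > cutoffs$ubiquity
  pref_pos <- !is.na(s$preference_ratio) & s$preference_ratio > cutoffs$ratio
  ab_pos <- !is.na(s$abundance_ratio) & s$abundance_ratio > cutoffs$abundance_ratio
  summary_call <- ifelse(ub_pos & pref_pos & ab_pos, "SPL",
                         ifelse(!ub_pos & !pref_pos & !ab_pos, "NSPL",
                                "intermediate"))
  rare <- s$n_studies_total < rare_cutoff
  summary_call[rare] <- "rare"
  data.frame(taxon = s$taxon,
             ubiquity_call = ifelse(ub_pos, "ubiquitous", "not-ubiquitous"),
             preference_call = ifelse(pref_pos, "soil-preferring",
                                      "not-soil-preferring"),
             abundance_call = ifelse(ab_pos, "soil-enriched",
                                     "not-soil-enriched"),
             abundant_in_soil = !is.na(s$soil_mean_abundance_pct) &
               s$soil_mean_abundance_pct > cutoffs$abundance,
             denominator_zero = s$ratio_denom_zero,
             n_studies_total = s$n_studies_total,
             summary = summary_call,
             stringsAsFactors = FALSE)
}

#' Habitat generalist versus specialist calls from profiles
#'
#' A taxon is a habitat generalist when it is detected in all seven habitat
#' categories (host-associated included), a specialist otherwise. Because
#' rarely encountered taxa are easily misclassified as specialists, taxa
#' detected in fewer than `min_studies` datasets are additionally flagged
#' `rare-excluded`; both the filtered and unfiltered calls are reported.
#'
#' @param x a [habitat_profiles] object.
#' @param rank taxonomic rank.
#' @param min_studies rare-taxon exclusion cutoff (total detections).
#' @return data.frame: taxon, n_habitats_detected, n_studies_total,
#'   `call` (with the rare exclusion applied) and `call_unfiltered`.
#' @export
classify_breadth <- function(x, rank, min_studies = 250) {
  m <- compute_metrics(x, rank)
  ph <- m$per_habitat
  n_hab <- tapply(ph$n_detected > 0, ph$taxon, sum)
  n_tot <- tapply(ph$n_detected, ph$taxon, sum)
  taxa <- names(n_hab)
  unfiltered <- ifelse(n_hab == length(HABITAT_LEVELS), "generalist",
                       "specialist")
  call <- ifelse(n_tot < min_studies, "rare-excluded", unfiltered)
  data.frame(taxon = taxa,
             n_habitats_detected = as.integer(n_hab),
             n_studies_total = as.integer(n_tot),
             call = unname(call),
             call_unfiltered = unname(unfiltered),
             stringsAsFactors = FALSE)
}

#' Habitat generalist versus specialist calls from genome origins
#'
#' The genome-based criterion: a taxon is a generalist when its genome
#' representatives originate from two or more habitat categories. Taxa
#' represented by fewer than `min_genomes` genomes are flagged
#' `rare-excluded` (both filtered and unfiltered calls reported).
#'
#' @param genomes a [genome_table] object.
#' @param rank grouping rank; genome records carry class-level taxonomy, so
#'   only `"class"` is supported unless records include a `lineage` column.
#' @param min_genomes minimum number of genomes per taxon.
#' @return data.frame: taxon, n_genomes, n_habitats, `call`,
#'   `call_unfiltered`.
#' @export
classify_breadth_from_genomes <- function(genomes, rank = "class",
                                          min_genomes = 5) {
  stopifnot(inherits(genomes, "genome_table"))
  rec <- genomes$records
  grp <- if ("lineage" %in% names(rec)) {
    truncate_lineage(rec$lineage, rank)$lineage
  } else {
    if (rank != "class") {
      stop("genome records carry class-level taxonomy only; rank must be ",
           "'class' unless a 'lineage' column is present", call. = FALSE)
    }
    rec$class
  }
  n_gen <- tapply(rep(1L, nrow(rec)), grp, sum)
  n_hab <- tapply(rec$habitat, grp, function(h) length(unique(h)))
  unfiltered <- ifelse(n_hab >= 2, "generalist", "specialist")
  call <- ifelse(n_gen < min_genomes, "rare-excluded", unfiltered)
  data.frame(taxon = names(n_gen),
             n_genomes = as.integer(n_gen),
             n_habitats = as.integer(n_hab),
             call = unname(call),
             call_unfiltered = unname(unfiltered),
             stringsAsFactors = FALSE)
}
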