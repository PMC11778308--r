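#' Default cutoffs for the full analysis
#'
#' Every threshold of the workflow in one overridable list: soil ubiquity
#' (percent), soil/non-soil ubiquity ratio, soil abundance (percent),
#' soil/non-soil abundance ratio, rare-taxon study cutoff, minimum genomes
#' and habitats per class, and the strong/weak significance cutoffs.
#'
#' @return named list.
#' @export
default_cutoffs <- function() {
  list(ubiquity = 75, ratio = 4, abundance = 1, abundance_ratio = 1,
       rare_cutoff = 250, min_genomes_per_class = 100,
       min_habitats_per_class = 5, min_genomes_per_taxon = 5,
       p_strong = 1e-5, p_weak = 0.05)
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
}

config_digest <- function(obj) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(obj, tmp, auto_unbox = TRUE, digits = NA, force = TRUE)
  unname(tools::md5sum(tmp))
}

#' Run the full phylogeny-versus-habitat workflow
#'
#' Wires the modules end to end: ecology metrics and soil-preference calls
#' per rank, habitat breadth calls from profiles and from genome origins
#' (with and without the rare exclusions), the 14-feature type III ANOVA
#' partition, the binary-trait logistic partition with the
#' lineage-/habitat-specific tallies, and life-history strategy
#' assignments. Each stage writes a TSV; a JSON summary and a run manifest
#' complete the bundle. Failing or skipped stages are recorded in the
#' manifest and later independent stages still run.
#'
#' @param profiles a [habitat_profiles] object, or `NULL` to skip the
#'   ecology stages.
#' @param genomes a [genome_table] object, or `NULL` to skip the genomic
#'   stages (its `traits` slot may be `NULL`, skipping the trait stage).
#' @param training labelled training data.frame for
#'   [train_strategy_model()], or `NULL` to skip strategy assignment.
#' @param indices per-genome investment indices (data.frame with
#'   `accession`, `regulatory_index`, `acquisition_index`) for strategy
#'   assignment.
#' @param out_dir output directory (created if needed).
#' @param ranks taxonomic ranks for the ecology stages.
#' @param cutoffs list as [default_cutoffs()]; partial overrides allowed.
#' @param seed integer seed (used by the strategy-model training restarts).
#' @return (invisibly) a list with the stage results and the manifest.
#' @export
run_full_analysis <- function(profiles = NULL, genomes = NULL,
                              training = NULL, indices = NULL,
                              out_dir, ranks = c("class", "order", "family"),
                              cutoffs = list(), seed = 1) {
  co <- utils::modifyList(default_cutoffs(), cutoffs)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stages <- list()
  results <- list()
  run_stage <- function(name, expr) {
    res <- tryCatch(expr, error = function(e) e)
    if (inherits(res, "error")) {
      message("stage '", name, "' failed: ", conditionMessage(res))
      stages[[name]] <<- list(status = "failed",
                              error = conditionMessage(res))
      NULL
    } else {
      stages[[name]] <<- list(status = "ok")
      res
    }
  }
  skip_stage <- function(name, why) {
    stages[[name]] <<- list(status = "skipped", reason = why)
  }

  if (!is.null(profiles)) {
    for (rk in ranks) {
      met <- run_stage(paste0("ecology_", rk), {
        m <- compute_metrics(profiles, rk)
        write_tsv(m$per_habitat, file.path(out_dir,
                                           paste0("ecology_per_habitat_", rk, ".tsv")))
        write_tsv(m$summary, file.path(out_dir,
                                       paste0("ecology_metrics_", rk, ".tsv")))
        m
      })
      if (!is.null(met)) {
        results[[paste0("metrics_", rk)]] <- met
        pref <- run_stage(paste0("preference_", rk), {
          p <- classify_preference(met,
                                   cutoffs = co[c("ubiquity", "ratio",
                                                  "abundance",
                                                  "abundance_ratio")],
                                   rare_cutoff = co$rare_cutoff)
          write_tsv(p, file.path(out_dir,
                                 paste0("preference_calls_", rk, ".tsv")))
          p
        })
        results[[paste0("preference_", rk)]] <- pref
        br <- run_stage(paste0("breadth_", rk), {
          b <- classify_breadth(profiles, rk, min_studies = co$rare_cutoff)
          write_tsv(b, file.path(out_dir,
                                 paste0("breadth_calls_", rk, ".tsv")))
          b
        })
        results[[paste0("breadth_", rk)]] <- br
      }
    }
  } else {
    skip_stage("ecology", "no profiles supplied")
  }

  if (!is.null(genomes)) {
    filt <- run_stage("genome_filter", {
      f <- filter_for_comparison(genomes, co$min_genomes_per_class,
                                 co$min_habitats_per_class)
      write_tsv(attr(f, "audit"), file.path(out_dir, "genome_filter_audit.tsv"))
      f
    })
    gb <- run_stage("breadth_genomes", {
      b <- classify_breadth_from_genomes(genomes,
                                         min_genomes = co$min_genomes_per_taxon)
      write_tsv(b, file.path(out_dir, "breadth_calls_genomes.tsv"))
      b
    })
    results$breadth_genomes <- gb
    if (!is.null(filt)) {
      results$genomes_filtered <- filt
      part <- run_stage("partition", {
        p <- batch_partition(filt)
        write_tsv(p$summary, file.path(out_dir, "partition_summary.tsv"))
        anova_rows <- do.call(rbind, lapply(p$anova, function(a) {
          cbind(feature = a$feature, a$terms)
        }))
        if (!is.null(anova_rows)) {
          write_tsv(anova_rows, file.path(out_dir, "partition_anova_terms.tsv"))
        }
        p
      })
      results$partition <- part
      if (is.null(genomes$traits)) skip_stage("traits", "no trait matrix supplied")
    }
  } else {
    skip_stage("genomes", "no genome table supplied")
  }

  if (!is.null(training) && !is.null(indices)) {
    lh <- run_stage("life_history", {
      model <- train_strategy_model(training, seed = seed)
      asn <- assign_strategy(model, indices)
      write_tsv(asn, file.path(out_dir, "strategy_assignments.tsv"))
      write_strategy_model(model, file.path(out_dir, "strategy_model.json"))
      list(model = model, assignments = asn)
    })
    results$life_history <- lh
  } else {
    skip_stage("life_history", "no training set and/or indices supplied")
  }

  summary <- list(
    taxa_per_rank = if (!is.null(profiles))
      lapply(stats::setNames(ranks, ranks), function(rk) {
        m <- results[[paste0("metrics_", rk)]]
        if (is.null(m)) NA_integer_ else nrow(m$summary)
      }),
    preference_tally = lapply(stats::setNames(ranks, ranks), function(rk) {
      p <- results[[paste0("preference_", rk)]]
      if (is.null(p)) NULL else as.list(table(p$summary))
    }),
    breadth_tally = lapply(stats::setNames(ranks, ranks), function(rk) {
      b <- results[[paste0("breadth_", rk)]]
      if (is.null(b)) NULL else as.list(table(b$call))
    }),
    specificity_tally = if (!is.null(results$partition))
      as.list(results$partition$tally),
    strategy_tally = if (!is.null(results$life_history))
      as.list(table(results$life_history$assignments$strategy)))
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  manifest <- list(
    tool = "phylohab",
    version = as.character(utils::packageVersion("phylohab")),
    command = "run_full_analysis",
    config_digest = config_digest(co),
    seeds = list(strategy_training = seed),
    cutoffs = co,
    stages = stages,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(results = results, stages = stages, manifest = manifest))
}
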