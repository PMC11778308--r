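#' Continuous genome features compared across lineages and habitats
#'
#' Twelve continuous features: five general genomic features (genome size,
#' GC content, coding density, mean gene length, protein-coding gene count),
#' two phage infection/immunity features (CRISPR count, viral contig count),
#' three secretory-arsenal features (CAZyme, peptidase and biosynthetic gene
#' cluster counts) and two predicted physiological optima (optimal growth
#' temperature and pH). Together with the predicted oxygen preference and
#' the predicted life-history strategy they make the 14 analysis features.
#'
#' @export
CONTINUOUS_FEATURES <- c("genome_size", "gc_pct", "coding_density",
                         "mean_gene_length", "protein_count", "crispr_count",
                         "viral_contig_count", "cazyme_count",
                         "peptidase_count", "bgc_count", "pred_ogt",
                         "pred_ph")

CATEGORICAL_FEATURES <- c("pred_aerobe", "life_history")

COUNT_FEATURES <- c("genome_size", "mean_gene_length", "protein_count",
                    "crispr_count", "viral_contig_count", "cazyme_count",
                    "peptidase_count", "bgc_count")

#' Construct a genome table
#'
#' One record per genome (accession, GTDB class, habitat of origin and the
#' 14 analysis features), with an optional binary metabolic-trait matrix
#' alongside (METABOLIC-style presence/absence converted to 1/0).
#'
#' @param records data.frame with columns `accession`, `class`, `habitat`,
#'   the twelve [CONTINUOUS_FEATURES], `pred_aerobe`
#'   (`"aerobic"`/`"anaerobic"`) and optionally `life_history`
#'   (`"ruderal"`/`"competitor"`/`"scarcity"` or `NA`). Missing feature
#'   values are permitted (excluded pairwise downstream).
#' @param traits optional numeric matrix (genomes x traits, values strictly
#'   0/1, rownames = accessions) or a long data.frame with columns
#'   `accession`, `trait`, `value`.
#' @return An object of class `genome_table`.
#' @export
genome_table <- function(records, traits = NULL) {
  stopifnot(is.data.frame(records))
  need <- c("accession", "class", "habitat", CONTINUOUS_FEATURES, "pred_aerobe")
  miss <- setdiff(need, names(records))
  if (length(miss)) {
    stop("genome records missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  records$accession <- as.character(records$accession)
  if (anyDuplicated(records$accession)) {
    stop("duplicate genome accession(s): ",
         paste(unique(records$accession[duplicated(records$accession)]),
               collapse = ", "), call. = FALSE)
  }
  bad_hab <- setdiff(unique(records$habitat), HABITAT_LEVELS)
  if (length(bad_hab)) {
    stop("unknown habitat label(s) in genome table: ",
         paste(bad_hab, collapse = ", "), call. = FALSE)
  }
  for (f in CONTINUOUS_FEATURES) records[[f]] <- as.numeric(records[[f]])
  chk <- function(f, lo, hi) {
    v <- records[[f]]
    if (any(v < lo | v > hi, na.rm = TRUE)) {
      stop("feature '", f, "' outside [", lo, ", ", hi, "]", call. = FALSE)
    }
  }
  chk("gc_pct", 0, 100); chk("coding_density", 0, 100); chk("pred_ph", 0, 14)
  for (f in COUNT_FEATURES) {
    if (any(records[[f]] < 0, na.rm = TRUE)) {
      stop("count feature '", f, "' has negative values", call. = FALSE)
    }
  }
  bad_aer <- setdiff(unique(stats::na.omit(records$pred_aerobe)),
                     c("aerobic", "anaerobic"))
  if (length(bad_aer)) {
    stop("pred_aerobe must be 'aerobic' or 'anaerobic', got: ",
         paste(bad_aer, collapse = ", "), call. = FALSE)
  }
  if (!"life_history" %in% names(records)) records$life_history <- NA_character_
  bad_lh <- setdiff(unique(stats::na.omit(records$life_history)),
                    c("ruderal", "competitor", "scarcity"))
  if (length(bad_lh)) {
    stop("life_history must be ruderal/competitor/scarcity, got: ",
         paste(bad_lh, collapse = ", "), call. = FALSE)
  }
  n_miss <- sum(is.na(records[, CONTINUOUS_FEATURES]))
  if (n_miss > 0) {
    message(n_miss, " missing feature value(s) retained; they are excluded ",
            "per-feature from downstream statistics")
  }

  if (!is.null(traits)) {
    if (is.data.frame(traits)) {
      need_t <- c("accession", "trait", "value")
      if (!all(need_t %in% names(traits))) {
        stop("long-format traits need columns accession, trait, value",
             call. = FALSE)
      }
      bad <- !traits$value %in% c(0, 1)
      if (any(bad)) {
        i <- which(bad)[1L]
        stop("non-binary trait value ", traits$value[i], " at (",
             traits$accession[i], ", ", traits$trait[i], ")", call. = FALSE)
      }
      accs <- sort(unique(traits$accession))
      trts <- sort(unique(traits$trait))
      m <- matrix(0, length(accs), length(trts), dimnames = list(accs, trts))
      m[cbind(match(traits$accession, accs), match(traits$trait, trts))] <-
        traits$value
      traits <- m
    }
    stopifnot(is.matrix(traits))
    if (!all(traits %in% c(0, 1))) {
      bad <- which(!traits %in% c(0, 1))[1L]
      stop("non-binary trait value in matrix cell ",
           rownames(traits)[(bad - 1) %% nrow(traits) + 1], " / ",
           colnames(traits)[(bad - 1) %/% nrow(traits) + 1], call. = FALSE)
    }
    orphan <- setdiff(rownames(traits), records$accession)
    if (length(orphan)) {
      stop("trait matrix has accession(s) absent from genome records: ",
           paste(utils::head(orphan, 5L), collapse = ", "), call. = FALSE)
    }
  }
  rownames(records) <- NULL
  structure(list(records = records, traits = traits), class = "genome_table")
}

#' @export
print.genome_table <- function(x, ...) {
  cat("<genome_table> ", nrow(x$records), " genomes, ",
      length(unique(x$records$class)), " classes",
      if (!is.null(x$traits)) paste0(", ", ncol(x$traits), " binary traits"),
      "\n", sep = "")
  print(summarize_by_class_habitat(x))
  invisible(x)
}

#' Load the genome feature table and trait matrix from TSV files
#'
#' @param features_file tab-separated genome feature table (one row per
#'   genome; see [genome_table()] for required columns).
#' @param traits_file optional long-format tab-separated trait table with
#'   columns `accession`, `trait`, `value` (0/1).
#' @return A [genome_table] object.
#' @export
load_genome_table <- function(features_file, traits_file = NULL) {
  rec <- utils::read.delim(features_file, stringsAsFactors = FALSE,
                           check.names = FALSE, fileEncoding = "UTF-8")
  traits <- NULL
  if (!is.null(traits_file)) {
    traits <- utils::read.delim(traits_file, stringsAsFactors = FALSE,
                                check.names = FALSE, fileEncoding = "UTF-8")
  }
  genome_table(rec, traits)
}

#' Write a genome table to TSV files
#' @param x a [genome_table] object.
#' @param features_file,traits_file output paths (`traits_file` ignored when
#'   the table has no traits).
#' @return `x`, invisibly.
#' @export
write_genome_table <- function(x, features_file, traits_file = NULL) {
  stopifnot(inherits(x, "genome_table"))
  utils::write.table(x$records, features_file, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  if (!is.null(traits_file) && !is.null(x$traits)) {
    long <- data.frame(accession = rep(rownames(x$traits), ncol(x$traits)),
                       trait = rep(colnames(x$traits), each = nrow(x$traits)),
                       value = as.vector(x$traits))
    utils::write.table(long, traits_file, sep = "\t", quote = FALSE,
                       row.names = FALSE, fileEncoding = "UTF-8")
  }
  invisible(x)
}

#' Per-(class, habitat) genome counts
#'
#' @param x a [genome_table] object.
#' @return An integer matrix (classes x the seven habitats); row sums equal
#'   class totals.
#' @export
summarize_by_class_habitat <- function(x) {
  stopifnot(inherits(x, "genome_table"))
  if (nrow(x$records) == 0L) {
    return(matrix(integer(0), 0, length(HABITAT_LEVELS),
                  dimnames = list(NULL, HABITAT_LEVELS)))
  }
  tab <- table(x$records$class,
               factor(x$records$habitat, levels = HABITAT_LEVELS))
  m <- matrix(as.integer(tab), nrow(tab), ncol(tab), dimnames = dimnames(tab))
  m
}

#' Restrict a genome table to classes suitable for comparison
#'
#' Keeps only genomes belonging to classes with at least
#' `min_genomes_per_class` genomes AND genomes recovered from at least
#' `min_habitats_per_class` of the seven habitats. A per-class audit (kept
#' or dropped, with the reason) is attached as attribute `"audit"`.
#'
#' @param x a [genome_table] object.
#' @param min_genomes_per_class minimum class size.
#' @param min_habitats_per_class minimum number of distinct origin habitats.
#' @return A filtered [genome_table]; errors if nothing survives.
#' @export
filter_for_comparison <- function(x, min_genomes_per_class = 100,
                                  min_habitats_per_class = 5) {
  stopifnot(inherits(x, "genome_table"))
  cnt <- summarize_by_class_habitat(x)
  n_gen <- rowSums(cnt)
  n_hab <- rowSums(cnt > 0)
  keep <- n_gen >= min_genomes_per_class & n_hab >= min_habitats_per_class
  reason <- ifelse(keep, "",
                   trimws(paste(
                     ifelse(n_gen < min_genomes_per_class,
                            sprintf("<%d genomes", min_genomes_per_class), ""),
                     ifelse(n_hab < min_habitats_per_class,
                            sprintf("<%d habitats", min_habitats_per_class), ""))))
  audit <- data.frame(class = rownames(cnt), n_genomes = as.integer(n_gen),
                      n_habitats = as.integer(n_hab), kept = unname(keep),
                      reason = unname(reason), stringsAsFactors = FALSE)
  if (!any(keep)) {
    stop("no class satisfies the comparison filter (",
         min_genomes_per_class, " genomes, ", min_habitats_per_class,
         " habitats)", call. = FALSE)
  }
  sel <- x$records$class %in% rownames(cnt)[keep]
  traits <- x$traits
  if (!is.null(traits)) {
    traits <- traits[rownames(traits) %in% x$records$accession[sel], ,
                     drop = FALSE]
  }
  out <- genome_table(x$records[sel, , drop = FALSE], traits)
  attr(out, "audit") <- audit
  out
}

#' Default SPL/NSPL grouping of classes
#'
#' The soil-preferring (SPL) versus non-soil-preferring (NSPL) grouping used
#' when pooling classes: Terriglobia, Vicinamibacteria, Blastocatellia and
#' Thermoanaerobaculia are SPLs; Holophagae and Aminicenantia are NSPLs.
#' Supply your own named vector to regroup.
#'
#' @return named character vector mapping class name to `"SPL"`/`"NSPL"`.
#' @export
default_spl_groups <- function() {
  c(Terriglobia = "SPL", Vicinamibacteria = "SPL", Blastocatellia = "SPL",
    Thermoanaerobaculia = "SPL", Holophagae = "NSPL", Aminicenantia = "NSPL")
}
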