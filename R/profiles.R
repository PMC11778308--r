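#' The seven habitat categories
#'
#' Every dataset (metagenome accession) carries exactly one of these labels;
#' anything else is rejected at load time.
#'
#' @export
HABITAT_LEVELS <- c("soil", "engineered", "freshwater", "host-associated",
                    "marine", "non-marine saline and alkaline",
                    "terrestrial non-soil")

#' Non-soil habitats used in soil versus non-soil comparisons
#'
#' Host-associated datasets are excluded from all comparative soil/non-soil
#' fields (preference and abundance ratios) because of their extreme
#' overrepresentation in public archives; they still count in the
#' seven-habitat breadth analysis.
#'
#' @export
NONSOIL_COMPARE_LEVELS <- setdiff(HABITAT_LEVELS, c("soil", "host-associated"))

#' Construct a profile collection
#'
#' A profile collection holds one record per (dataset, taxon) pair with a
#' strictly positive relative abundance percentage, plus a dataset-to-habitat
#' map. Absence of a taxon from a dataset is encoded by absence of the row:
#' detection is any non-zero relative abundance.
#'
#' @param records data.frame with columns `dataset`, `lineage`,
#'   `abundance` (relative abundance, percent, in (0, 100]).
#' @param habitat_of named character vector mapping every dataset accession
#'   (including datasets with no detections) to a habitat label from
#'   [HABITAT_LEVELS].
#' @return An object of class `habitat_profiles`.
#' @seealso [read_profiles()], [simulate_profiles()]
#' @export
habitat_profiles <- function(records, habitat_of) {
  stopifnot(is.data.frame(records))
  need <- c("dataset", "lineage", "abundance")
  miss <- setdiff(need, names(records))
  if (length(miss)) {
    stop("records is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  records <- records[, c(need, intersect("unresolved", names(records)))]
  records$dataset <- as.character(records$dataset)
  records$lineage <- as.character(records$lineage)
  records$abundance <- as.numeric(records$abundance)

  bad_hab <- setdiff(unique(habitat_of), HABITAT_LEVELS)
  if (length(bad_hab)) {
    stop("unknown habitat label(s): ", paste(bad_hab, collapse = ", "),
         "; allowed labels are: ", paste(HABITAT_LEVELS, collapse = ", "),
         call. = FALSE)
  }
  if (is.null(names(habitat_of)) || anyNA(names(habitat_of))) {
    stop("habitat_of must be a named vector (names = dataset accessions)",
         call. = FALSE)
  }
  orphans <- setdiff(unique(records$dataset), names(habitat_of))
  if (length(orphans)) {
    stop("dataset(s) present in profiles but missing a habitat label: ",
         paste(utils::head(orphans, 10L), collapse = ", "),
         if (length(orphans) > 10L) " ..." else "", call. = FALSE)
  }
  if (anyDuplicated(records[, c("dataset", "lineage")])) {
    dup <- records[duplicated(records[, c("dataset", "lineage")]), , drop = FALSE]
    stop("duplicate (dataset, lineage) pair(s), e.g. ",
         dup$dataset[1L], " / ", dup$lineage[1L], call. = FALSE)
  }
  if (any(!is.finite(records$abundance)) ||
      any(records$abundance <= 0 | records$abundance > 100)) {
    stop("abundances must be finite percentages in (0, 100]", call. = FALSE)
  }
  # validate that every stored lineage parses
  invisible(parse_lineage(unique(records$lineage)))

  rownames(records) <- NULL
  structure(list(records = records, habitat_of = habitat_of),
            class = "habitat_profiles")
}

#' @export
print.habitat_profiles <- function(x, ...) {
  hab <- table(factor(x$habitat_of, levels = HABITAT_LEVELS))
  cat("<habitat_profiles>\n")
  cat("  ", nrow(x$records), " detection records, ",
      length(unique(x$records$lineage)), " taxa, ",
      length(x$habitat_of), " datasets\n", sep = "")
  cat("  datasets per habitat:\n")
  for (h in names(hab)) cat(sprintf("    %-32s %d\n", h, hab[[h]]))
  invisible(x)
}

#' Read taxonomic profiles and habitat metadata from TSV files
#'
#' The profile table is SingleM/Sandpiper shaped: one row per
#' (dataset, lineage) with a relative abundance percentage. Zero-abundance
#' rows are dropped (absence is encoded by absence) with a message stating
#' how many were removed.
#'
#' @param profile_file path to a UTF-8 tab-separated file with a header row.
#' @param habitat_file path to a UTF-8 tab-separated file with a header row.
#' @param profile_cols named list giving the column names in `profile_file`
#'   for `dataset`, `lineage` and `abundance`.
#' @param habitat_cols named list giving the column names in `habitat_file`
#'   for `dataset` and `habitat`.
#' @return A [habitat_profiles] object.
#' @export
read_profiles <- function(profile_file, habitat_file,
                          profile_cols = list(dataset = "dataset",
                                              lineage = "lineage",
                                              abundance = "relative_abundance_pct"),
                          habitat_cols = list(dataset = "dataset",
                                              habitat = "habitat")) {
  prof <- utils::read.delim(profile_file, stringsAsFactors = FALSE,
                            check.names = FALSE, fileEncoding = "UTF-8")
  hab <- utils::read.delim(habitat_file, stringsAsFactors = FALSE,
                           check.names = FALSE, fileEncoding = "UTF-8")
  for (nm in c("dataset", "lineage", "abundance")) {
    if (!profile_cols[[nm]] %in% names(prof)) {
      stop("profile table lacks column '", profile_cols[[nm]], "'",
           call. = FALSE)
    }
  }
  for (nm in c("dataset", "habitat")) {
    if (!habitat_cols[[nm]] %in% names(hab)) {
      stop("habitat table lacks column '", habitat_cols[[nm]], "'",
           call. = FALSE)
    }
  }
  records <- data.frame(dataset = as.character(prof[[profile_cols$dataset]]),
                        lineage = as.character(prof[[profile_cols$lineage]]),
                        abundance = as.numeric(prof[[profile_cols$abundance]]),
                        stringsAsFactors = FALSE)
  n_zero <- sum(records$abundance == 0)
  if (n_zero > 0) {
    message("dropping ", n_zero, " zero-abundance row(s) (absence is encoded ",
            "by absence of the row)")
    records <- records[records$abundance != 0, , drop = FALSE]
  }
  habitat_of <- stats::setNames(as.character(hab[[habitat_cols$habitat]]),
                                as.character(hab[[habitat_cols$dataset]]))
  if (anyDuplicated(names(habitat_of))) {
    stop("duplicate dataset accession(s) in habitat table", call. = FALSE)
  }
  habitat_profiles(records, habitat_of)
}

#' Write a profile collection back to TSV files
#'
#' Emits the same dialect [read_profiles()] consumes, so a read/write
#' round-trip reproduces the input rows (up to row order).
#'
#' @param x a [habitat_profiles] object.
#' @param profile_file,habitat_file output paths.
#' @return `x`, invisibly.
#' @export
write_profiles <- function(x, profile_file, habitat_file) {
  stopifnot(inherits(x, "habitat_profiles"))
  prof <- data.frame(dataset = x$records$dataset,
                     lineage = x$records$lineage,
                     relative_abundance_pct = x$records$abundance)
  utils::write.table(prof, profile_file, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  hab <- data.frame(dataset = names(x$habitat_of), habitat = unname(x$habitat_of))
  utils::write.table(hab, habitat_file, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(x)
}

#' Aggregate a profile collection to a coarser taxonomic rank
#'
#' Within each dataset, abundances of lineages sharing the same prefix up to
#' `rank` are summed (sub-lineage abundances are assumed additive). Lineages
#' not resolved at `rank` are retained under their deepest resolved prefix
#' and flagged `unresolved`, so per-dataset total abundance is conserved.
#'
#' @param x a [habitat_profiles] object.
#' @param rank target rank, one of `r toString(GTDB_RANKS)`.
#' @return A [habitat_profiles] object whose records carry an extra logical
#'   column `unresolved`.
#' @export
aggregate_to_rank <- function(x, rank) {
  stopifnot(inherits(x, "habitat_profiles"))
  tr <- truncate_lineage(x$records$lineage, rank)
  key <- paste(x$records$dataset, tr$lineage, sep = "\r")
  ab <- rowsum(x$records$abundance, group = key, reorder = FALSE)
  first <- !duplicated(key)
  agg <- data.frame(dataset = x$records$dataset[first],
                    lineage = tr$lineage[first],
                    abundance = as.numeric(ab[match(unique(key), rownames(ab))]),
                    unresolved = as.logical(
                      tapply(tr$unresolved, key, all)[unique(key)]),
                    stringsAsFactors = FALSE)
  habitat_profiles(agg, x$habitat_of)
}
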