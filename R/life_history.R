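#' Genomic investment indices
#'
#' Two scale-free indices summarize a genome's life-history investment:
#' regulatory flexibility (transcription factors per gene) and resource
#' acquisition (secreted CAZymes + secreted proteases + secreted
#' lipases/hydrolases + biosynthetic gene clusters, per membrane
#' transporter). A zero denominator leaves the index undefined and flags
#' the profile; it is never silently set to 0.
#'
#' @param counts data.frame with columns `accession`, `tf_count`,
#'   `total_genes`, `secreted_cazymes`, `secreted_proteases`,
#'   `secreted_lipases`, `bgc_count`, `transporter_count` (all counts
#'   nonnegative).
#' @return data.frame of class `investment_profile`: the input counts plus
#'   `regulatory_index`, `acquisition_index` and the logical flags
#'   `undefined_regulatory`, `undefined_acquisition`.
#' @examples
#' compute_indices(data.frame(accession = "G1", tf_count = 100,
#'   total_genes = 4000, secreted_cazymes = 10, secreted_proteases = 5,
#'   secreted_lipases = 5, bgc_count = 10, transporter_count = 60))
#' @export
compute_indices <- function(counts) {
  stopifnot(is.data.frame(counts))
  need <- c("accession", "tf_count", "total_genes", "secreted_cazymes",
            "secreted_proteases", "secreted_lipases", "bgc_count",
            "transporter_count")
  miss <- setdiff(need, names(counts))
  if (length(miss)) {
    stop("counts missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  num <- setdiff(need, "accession")
  for (f in num) {
    v <- as.numeric(counts[[f]])
    if (any(v < 0, na.rm = TRUE)) {
      stop("negative value in '", f, "'", call. = FALSE)
    }
    counts[[f]] <- v
  }
  out <- counts
  out$undefined_regulatory <- is.na(out$total_genes) | out$total_genes == 0
  out$undefined_acquisition <- is.na(out$transporter_count) |
    out$transporter_count == 0
  out$regulatory_index <- ifelse(out$undefined_regulatory, NA_real_,
                                 out$tf_count / out$total_genes)
  secreted <- out$secreted_cazymes + out$secreted_proteases +
    out$secreted_lipases + out$bgc_count
  out$acquisition_index <- ifelse(out$undefined_acquisition, NA_real_,
                                  secreted / out$transporter_count)
  class(out) <- c("investment_profile", "data.frame")
  out
}

STRATEGY_LEVELS <- c("competitor", "ruderal", "scarcity")  # tie-break order

#' Train the life-history strategy model
#'
#' k-means clustering (k = 3, seeded multiple restarts) of a labelled
#' training set in the (regulatory index, acquisition index) plane. Each
#' axis is standardized (z-score fitted on the training data) before
#' clustering because the two indices differ by orders of magnitude; set
#' `standardize = FALSE` to cluster raw values. Each centroid is labelled
#' by the majority label of its members, ties broken by the label of the
#' nearest training point; the three centroids must end up with three
#' distinct labels. Training rows are canonically sorted before clustering
#' so the model is invariant to input row order.
#'
#' @param training data.frame with columns `regulatory_index`,
#'   `acquisition_index` and `label` (values among competitor, ruderal,
#'   scarcity); at least 3 rows spanning at least 3 labels. Typically the
#'   27 isotope-labelled training genomes.
#' @param seed integer seed for the k-means restarts.
#' @param standardize z-score both axes on the training data first.
#' @return An object of class `strategy_model` with `centroids` (3 x 2,
#'   standardized space), `labels`, `scaling` (per-axis center/sd), `seed`.
#' @export
train_strategy_model <- function(training, seed = 1, standardize = TRUE) {
  stopifnot(is.data.frame(training))
  need <- c("regulatory_index", "acquisition_index", "label")
  miss <- setdiff(need, names(training))
  if (length(miss)) {
    stop("training missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  bad <- setdiff(unique(training$label), STRATEGY_LEVELS)
  if (length(bad)) {
    stop("unknown strategy label(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(training) < 3L || length(unique(training$label)) < 3L) {
    stop("training set must contain at least 3 points spanning the 3 ",
         "strategy labels", call. = FALSE)
  }
  # canonical order: model is a pure function of the row *set*
  training <- training[order(training$regulatory_index,
                             training$acquisition_index, training$label), ]
  xy <- as.matrix(training[, c("regulatory_index", "acquisition_index")])
  if (anyNA(xy)) stop("training indices contain NA", call. = FALSE)
  if (standardize) {
    center <- colMeans(xy)
    scale_ <- apply(xy, 2L, stats::sd)
    if (any(scale_ == 0)) stop("degenerate training axis (zero variance)",
                               call. = FALSE)
  } else {
    center <- c(regulatory_index = 0, acquisition_index = 0)
    scale_ <- c(regulatory_index = 1, acquisition_index = 1)
  }
  z <- sweep(sweep(xy, 2L, center), 2L, scale_, "/")

  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(seed)
  km <- stats::kmeans(z, centers = 3L, nstart = 25L, iter.max = 100L)

  labels <- character(3L)
  for (cl in 1:3) {
    members <- training$label[km$cluster == cl]
    tab <- sort(table(members), decreasing = TRUE)
    top <- names(tab)[tab == max(tab)]
    if (length(top) == 1L) {
      labels[cl] <- top
    } else {
      # tie: label of the training point nearest this centroid
      d2 <- rowSums(sweep(z, 2L, km$centers[cl, ])^2)
      labels[cl] <- training$label[which.min(d2)]
    }
  }
  if (anyDuplicated(labels)) {
    stop("clusters do not separate the three strategy labels (no majority ",
         "labelling possible); provide a cleaner training set", call. = FALSE)
  }
  ord <- match(STRATEGY_LEVELS, labels)
  structure(list(centroids = km$centers[ord, , drop = FALSE],
                 labels = STRATEGY_LEVELS,
                 scaling = list(center = center, sd = scale_,
                                standardized = standardize),
                 seed = seed, tot_withinss = km$tot.withinss,
                 n_training = nrow(training)),
            class = "strategy_model")
}

#' @export
print.strategy_model <- function(x, ...) {
  cat("<strategy_model> trained on", x$n_training, "labelled genomes\n")
  cent <- x$centroids
  rownames(cent) <- x$labels
  cat("centroids (standardized space):\n")
  print(round(cent, 3))
  invisible(x)
}

#' Assign life-history strategies by nearest centroid
#'
#' Each genome is assigned the label of the nearest trained centroid
#' (Euclidean distance in the model's standardized space). Genomes are
#' never re-clustered jointly with the training data, so assignments do not
#' change as the cohort grows. Exact distance ties are broken by the fixed
#' label order competitor, ruderal, scarcity and flagged. Profiles with an
#' undefined index are explicitly unassignable (`NA` strategy).
#'
#' @param model a [strategy_model].
#' @param profiles an [compute_indices()] result, or any data.frame with
#'   `regulatory_index` and `acquisition_index` columns.
#' @return data.frame: `accession` (if present), `strategy`, `distance`
#'   (to the winning centroid), `tie` and `unassignable` flags.
#' @export
assign_strategy <- function(model, profiles) {
  stopifnot(inherits(model, "strategy_model"))
  stopifnot(all(c("regulatory_index", "acquisition_index") %in%
                  names(profiles)))
  xy <- as.matrix(profiles[, c("regulatory_index", "acquisition_index")])
  undef <- rowSums(is.na(xy)) > 0
  if ("undefined_regulatory" %in% names(profiles)) {
    undef <- undef | profiles$undefined_regulatory |
      profiles$undefined_acquisition
  }
  z <- sweep(sweep(xy, 2L, model$scaling$center), 2L, model$scaling$sd, "/")
  d2 <- matrix(NA_real_, nrow(z), 3L, dimnames = list(NULL, model$labels))
  for (j in 1:3) d2[, j] <- rowSums(sweep(z, 2L, model$centroids[j, ])^2)
  strategy <- rep(NA_character_, nrow(z))
  tie <- rep(FALSE, nrow(z))
  dist <- rep(NA_real_, nrow(z))
  for (i in which(!undef)) {
    dmin <- min(d2[i, ])
    winners <- which(d2[i, ] <= dmin + 1e-12)
    strategy[i] <- model$labels[winners[1L]]  # labels in tie-break order
    tie[i] <- length(winners) > 1L
    dist[i] <- sqrt(dmin)
  }
  out <- data.frame(strategy = strategy, distance = dist, tie = tie,
                    unassignable = undef, stringsAsFactors = FALSE)
  if ("accession" %in% names(profiles)) {
    out <- cbind(accession = profiles$accession, out)
  }
  out
}

#' @rdname assign_strategy
#' @param object a [strategy_model].
#' @param newdata profiles to assign.
#' @param ... ignored.
#' @export
predict.strategy_model <- function(object, newdata, ...) {
  assign_strategy(object, newdata)
}

#' Serialize / restore a strategy model as JSON
#'
#' @param model a [strategy_model].
#' @param path output (input) file path.
#' @return `write_strategy_model`: `path`, invisibly;
#'   `read_strategy_model`: a [strategy_model].
#' @export
write_strategy_model <- function(model, path) {
  stopifnot(inherits(model, "strategy_model"))
  obj <- list(centroids = unclass(model$centroids),
              labels = model$labels,
              scaling = model$scaling, seed = model$seed,
              n_training = model$n_training)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE,
                       matrix = "rowmajor")
  invisible(path)
}

#' @rdname write_strategy_model
#' @export
read_strategy_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  cent <- matrix(as.numeric(obj$centroids), 3L, 2L, byrow = FALSE)
  if (is.matrix(obj$centroids)) cent <- obj$centroids
  colnames(cent) <- c("regulatory_index", "acquisition_index")
  structure(list(centroids = cent, labels = obj$labels,
                 scaling = list(center = stats::setNames(
                   as.numeric(obj$scaling$center),
                   c("regulatory_index", "acquisition_index")),
                   sd = stats::setNames(
                     as.numeric(obj$scaling$sd),
                     c("regulatory_index", "acquisition_index")),
                   standardized = isTRUE(obj$scaling$standardized)),
                 seed = obj$seed, n_training = obj$n_training),
            class = "strategy_model")
}
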