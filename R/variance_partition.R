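#' Significance tiers for F-test / likelihood-ratio p-values
#'
#' `strong` below 1e-5, `weak` in [1e-5, 0.05), `ns` otherwise. The fixed
#' cutoffs are applied as-is (no multiplicity correction); an informational
#' Benjamini-Hochberg column is available in [batch_partition()].
#'
#' @param p numeric vector of p-values.
#' @param strong,weak tier cutoffs.
#' @return character vector of tiers (`NA` p maps to `"ns"`).
#' @export
p_tier <- function(p, strong = 1e-5, weak = 0.05) {
  ifelse(is.na(p), "ns",
         ifelse(p < strong, "strong", ifelse(p < weak, "weak", "ns")))
}

# Build the sum-to-zero two-factor design, fit it, and record which columns
# of each term are estimable (non-aliased) under the observed cell pattern.
build_design <- function(cls, hab, include_interaction = TRUE) {
  cls <- droplevels(as.factor(cls))
  hab <- droplevels(as.factor(hab))
  if (nlevels(cls) < 2L) stop("factor 'class' has fewer than 2 levels",
                              call. = FALSE)
  if (nlevels(hab) < 2L) stop("factor 'habitat' has fewer than 2 levels",
                              call. = FALSE)
  df <- data.frame(cls = cls, hab = hab)
  form <- if (include_interaction) ~ cls * hab else ~ cls + hab
  X <- stats::model.matrix(form, df,
                           contrasts.arg = list(cls = "contr.sum",
                                                hab = "contr.sum"))
  term_of <- attr(X, "assign")  # 0 = intercept, 1 = cls, 2 = hab, 3 = cls:hab
  qrX <- qr(X)
  est <- sort(qrX$pivot[seq_len(qrX$rank)])
  list(X = X, term_of = term_of, estimable = est,
       dropped = setdiff(seq_len(ncol(X)), est),
       cls = cls, hab = hab)
}

#' Two-factor type III ANOVA with percentage contributions
#'
#' Fits `y ~ class * habitat` under sum-to-zero contrasts and computes, for
#' each term, the type III sum of squares: the increase in residual SS when
#' that term's (estimable) columns are removed from the full model. Columns
#' made unestimable by empty class-by-habitat cells are dropped from the
#' full model and reported, rather than failing. Percentage contribution of
#' a term is its SS as a share of the total SS (all terms plus residual by
#' default).
#'
#' @param y numeric response (one genome feature); `NA`s are dropped
#'   pairwise with their labels.
#' @param class_labels,habitat_labels factors (or coercibles) of equal
#'   length to `y`.
#' @param include_interaction include the class:habitat interaction.
#' @param pct_denominator `"total"` (all term SS + residual SS, default) or
#'   `"explained"` (term SS only); recorded in the result.
#' @param feature optional feature name carried into the result.
#' @param tukey also run [tukey_hsd()] one-way on each factor whose term is
#'   at least weak-tier significant.
#' @return An object of class `type3_anova`: list with `terms` (term, ss,
#'   df, f_stat, p_value, pct_contribution, tier), `n_used`,
#'   `dropped_columns` (unestimable interaction columns), `tukey` (list of
#'   pairwise tables per factor) and metadata.
#' @export
fit_type3_anova <- function(y, class_labels, habitat_labels,
                            include_interaction = TRUE,
                            pct_denominator = c("total", "explained"),
                            feature = NULL, tukey = TRUE) {
  pct_denominator <- match.arg(pct_denominator)
  y <- as.numeric(y)
  ok <- !is.na(y)
  y <- y[ok]
  d <- build_design(as.factor(class_labels)[ok], as.factor(habitat_labels)[ok],
                    include_interaction)
  n <- length(y)
  Xe <- d$X[, d$estimable, drop = FALSE]
  rank_full <- ncol(Xe)
  df_res <- n - rank_full
  if (df_res < 1L) {
    stop("saturated model: zero residual degrees of freedom", call. = FALSE)
  }
  rss_full <- sum(stats::lm.fit(Xe, y)$residuals^2)

  term_names <- c("class", "habitat", if (include_interaction) "interaction")
  term_ids <- seq_along(term_names)
  rows <- lapply(term_ids, function(t) {
    cols_t <- d$estimable[d$term_of[d$estimable] == t]
    df_t <- length(cols_t)
    if (df_t == 0L) {
      return(data.frame(term = term_names[t], ss = 0, df = 0L,
                        f_stat = NA_real_, p_value = NA_real_))
    }
    Xr <- d$X[, setdiff(d$estimable, cols_t), drop = FALSE]
    ss <- max(0, sum(stats::lm.fit(Xr, y)$residuals^2) - rss_full)
    f <- (ss / df_t) / (rss_full / df_res)
    data.frame(term = term_names[t], ss = ss, df = df_t, f_stat = f,
               p_value = stats::pf(f, df_t, df_res, lower.tail = FALSE))
  })
  terms <- do.call(rbind, rows)
  terms <- rbind(terms,
                 data.frame(term = "residual", ss = rss_full, df = df_res,
                            f_stat = NA_real_, p_value = NA_real_))
  denom <- if (pct_denominator == "total") sum(terms$ss) else
    sum(terms$ss[terms$term != "residual"])
  terms$pct_contribution <- if (denom > 0) 100 * terms$ss / denom else NA_real_
  terms$tier <- p_tier(terms$p_value)
  terms$tier[terms$term == "residual"] <- NA_character_

  tukey_tabs <- list()
  if (tukey) {
    for (fac in c("class", "habitat")) {
      ti <- terms[terms$term == fac, ]
      if (!is.na(ti$p_value) && ti$p_value < 0.05) {
        g <- if (fac == "class") d$cls else d$hab
        tukey_tabs[[fac]] <- tukey_hsd(y, g)
      }
    }
  }
  structure(list(feature = feature, terms = terms, n_used = n,
                 rank = rank_full, dropped_columns = colnames(d$X)[d$dropped],
                 include_interaction = include_interaction,
                 pct_denominator = pct_denominator, tukey = tukey_tabs),
            class = "type3_anova")
}

#' @export
print.type3_anova <- function(x, digits = 4, ...) {
  cat("Type III ANOVA",
      if (!is.null(x$feature)) paste0(" for '", x$feature, "'"),
      " (n = ", x$n_used, ")\n", sep = "")
  t <- x$terms
  t$ss <- signif(t$ss, digits); t$f_stat <- signif(t$f_stat, digits)
  t$p_value <- signif(t$p_value, 3)
  t$pct_contribution <- round_half_up(t$pct_contribution, 2)
  print(t, row.names = FALSE)
  if (length(x$dropped_columns)) {
    cat("dropped (unestimable) columns:",
        length(x$dropped_columns), "\n")
  }
  invisible(x)
}

#' @export
summary.type3_anova <- function(object, ...) {
  print(object, ...)
  if (length(object$tukey)) {
    for (fac in names(object$tukey)) {
      cat("\nTukey HSD pairs for", fac, "(adjusted p < 0.05):\n")
      tt <- object$tukey[[fac]]
      print(tt[tt$adjusted_p < 0.05, , drop = FALSE], row.names = FALSE)
    }
  }
  invisible(object)
}

#' Tukey-Kramer honest significant difference comparisons
#'
#' All pairwise comparisons of group means with studentized-range adjusted
#' p-values, using the pooled within-group variance; the Kramer form
#' accommodates unequal group sizes. With two groups the adjusted p equals
#' the pooled two-sided t-test p.
#'
#' @param y numeric response.
#' @param group_labels group factor.
#' @param conf_level confidence level for the adjusted intervals.
#' @return data.frame of class `tukey_hsd`: `group_a`, `group_b`,
#'   `mean_diff` (b minus a), `lwr`, `upr`, `adjusted_p`.
#' @export
tukey_hsd <- function(y, group_labels, conf_level = 0.95) {
  y <- as.numeric(y)
  g <- droplevels(as.factor(group_labels))
  ok <- !is.na(y)
  y <- y[ok]; g <- droplevels(g[ok])
  k <- nlevels(g)
  if (k < 2L) stop("need at least two groups", call. = FALSE)
  n_i <- tabulate(g)
  m_i <- tapply(y, g, mean)
  df_res <- length(y) - k
  if (df_res < 1L) stop("no residual degrees of freedom", call. = FALSE)
  mse <- sum((y - m_i[as.integer(g)])^2) / df_res
  pairs <- utils::combn(levels(g), 2L)
  out <- apply(pairs, 2L, function(pr) {
    a <- pr[1L]; b <- pr[2L]
    se <- sqrt(mse / 2 * (1 / n_i[match(a, levels(g))] +
                            1 / n_i[match(b, levels(g))]))
    diff <- m_i[[b]] - m_i[[a]]
    if (se == 0) {
      p <- if (diff == 0) 1 else 0
      qcrit <- 0
    } else {
      q <- abs(diff) / se
      p <- stats::ptukey(q, k, df_res, lower.tail = FALSE)
      qcrit <- stats::qtukey(conf_level, k, df_res)
    }
    data.frame(group_a = a, group_b = b, mean_diff = diff,
               lwr = diff - qcrit * se, upr = diff + qcrit * se,
               adjusted_p = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  class(out) <- c("tukey_hsd", "data.frame")
  out
}

mcfadden_r2 <- function(fit, ll_null) {
  as.numeric(1 - stats::logLik(fit) / ll_null)
}

#' Partition a binary trait between phylogeny and habitat
#'
#' Fits the logistic regression `trait ~ class * habitat` (main effects only
#' if `include_interaction = FALSE`) by maximum likelihood and attributes
#' the trait to each variable via McFadden pseudo-R-squared drops: the
#' contribution of a variable is the full-model pseudo-R-squared minus that
#' of the model with the variable (main effect and its interaction columns)
#' removed. Term p-values come from likelihood-ratio tests. Complete or
#' quasi-complete separation is detected heuristically (runaway
#' coefficients / non-convergence) and flags the result unreliable instead
#' of returning a silent number.
#'
#' The full model is main-effects by default: with sparse class-by-habitat
#' cells an interaction term overfits (quasi-separation in near-empty
#' cells), inflating every pseudo-R-squared drop; set
#' `include_interaction = TRUE` to add it where that is not a concern.
#'
#' @param trait 0/1 vector (both values must occur).
#' @param class_labels,habitat_labels factors of matching length.
#' @param include_interaction include the interaction in the full model.
#' @param trait_name optional name carried into the result.
#' @return An object of class `logistic_partition`: pseudo-R2 of the full
#'   model, per-variable contributions (pseudo-R2 drops), likelihood-ratio
#'   p-values and tiers per term, per-class prevalence directions, and an
#'   `unreliable` flag.
#' @export
fit_logistic_partition <- function(trait, class_labels, habitat_labels,
                                   include_interaction = FALSE,
                                   trait_name = NULL) {
  trait <- as.numeric(trait)
  if (!all(trait %in% c(0, 1))) stop("trait must be 0/1", call. = FALSE)
  if (length(unique(trait)) < 2L) {
    stop("trait is constant; both 0 and 1 must occur", call. = FALSE)
  }
  df <- data.frame(trait = trait,
                   cls = droplevels(as.factor(class_labels)),
                   hab = droplevels(as.factor(habitat_labels)))
  form_full <- if (include_interaction) trait ~ cls * hab else trait ~ cls + hab
  fit <- function(f) {
    suppressWarnings(stats::glm(f, family = stats::binomial(), data = df))
  }
  full <- fit(form_full)
  null <- fit(trait ~ 1)
  no_cls <- fit(trait ~ hab)
  no_hab <- fit(trait ~ cls)
  ll_null <- stats::logLik(null)

  r2_full <- mcfadden_r2(full, ll_null)
  contribution <- c(class = r2_full - mcfadden_r2(no_cls, ll_null),
                    habitat = r2_full - mcfadden_r2(no_hab, ll_null))
  lrt <- function(reduced) {
    stat <- as.numeric(2 * (stats::logLik(full) - stats::logLik(reduced)))
    dfd <- full$rank - reduced$rank
    if (dfd < 1L) return(NA_real_)
    stats::pchisq(max(stat, 0), dfd, lower.tail = FALSE)
  }
  term_p <- c(class = lrt(no_cls), habitat = lrt(no_hab))
  if (include_interaction) {
    main <- fit(trait ~ cls + hab)
    stat <- as.numeric(2 * (stats::logLik(full) - stats::logLik(main)))
    dfd <- full$rank - main$rank
    term_p <- c(term_p,
                interaction = if (dfd >= 1L)
                  stats::pchisq(max(stat, 0), dfd, lower.tail = FALSE)
                else NA_real_)
  }

  coefs <- stats::coef(full)
  unreliable <- !full$converged || any(abs(coefs) > 15, na.rm = TRUE)
  prev <- tapply(df$trait, df$cls, mean)
  direction <- ifelse(prev > mean(df$trait), "higher", "lower")

  structure(list(trait = trait_name, pseudo_r2_full = r2_full,
                 contribution = contribution, term_p = term_p,
                 tier = p_tier(term_p), direction = direction,
                 prevalence = prev, n = nrow(df),
                 include_interaction = include_interaction,
                 unreliable = unreliable),
            class = "logistic_partition")
}

#' @export
print.logistic_partition <- function(x, ...) {
  cat("Logistic partition",
      if (!is.null(x$trait)) paste0(" for trait '", x$trait, "'"),
      " (n = ", x$n, ")\n", sep = "")
  cat("  McFadden pseudo-R2 (full):", signif(x$pseudo_r2_full, 4), "\n")
  cat("  contribution (pseudo-R2 drop): class =",
      signif(x$contribution[["class"]], 4), ", habitat =",
      signif(x$contribution[["habitat"]], 4), "\n")
  cat("  LRT p:", paste(names(x$term_p), signif(x$term_p, 3),
                        sep = " = ", collapse = ", "), "\n")
  if (x$unreliable) cat("  WARNING: separation suspected; unreliable\n")
  invisible(x)
}

#' Partition every feature and trait of a genome table
#'
#' Runs [fit_type3_anova()] on the twelve continuous features, on predicted
#' oxygen preference encoded aerobic = 1 / anaerobic = 0, and on the
#' three-level life-history strategy as one-vs-rest indicators (reporting
#' the indicator with the largest class SS); and [fit_logistic_partition()]
#' on every binary metabolic trait. Per-feature failures are recorded, not
#' propagated. Each analysis is then labelled lineage-specific,
#' habitat-specific, both or neither according to which terms reach the
#' strong tier (p < 1e-5).
#'
#' @param x a (filtered) [genome_table] object.
#' @param include_interaction_anova include the interaction in the type III
#'   fits (the default; empty-cell columns are dropped and reported).
#' @param include_interaction_logistic include the interaction in the
#'   logistic fits (off by default; see [fit_logistic_partition()]).
#' @param pct_denominator passed to [fit_type3_anova()].
#' @return An object of class `partition_batch`: `$anova` (named list of
#'   [fit_type3_anova] results), `$logistic` (named list), `$summary` (one
#'   row per analysis: kind, class/habitat p, tiers, pct or pseudo-R2
#'   contributions, BH-adjusted p, specificity label, error message if the
#'   fit failed) and `$tally` (counts of the four specificity labels).
#' @export
batch_partition <- function(x, include_interaction_anova = TRUE,
                            include_interaction_logistic = FALSE,
                            pct_denominator = "total") {
  stopifnot(inherits(x, "genome_table"))
  rec <- x$records
  anova_res <- list(); logistic_res <- list(); rows <- list()

  add_row <- function(name, kind, cls_p, hab_p, cls_contrib, hab_contrib,
                      error = NA_character_) {
    cls_t <- p_tier(cls_p); hab_t <- p_tier(hab_p)
    label <- if (!is.na(error)) {
      NA_character_
    } else if (cls_t == "strong" && hab_t == "strong") {
      "both"
    } else if (cls_t == "strong") {
      "lineage-specific"
    } else if (hab_t == "strong") {
      "habitat-specific"
    } else {
      "neither"
    }
    rows[[length(rows) + 1L]] <<- data.frame(
      name = name, kind = kind, class_p = cls_p, habitat_p = hab_p,
      class_tier = cls_t, habitat_tier = hab_t,
      class_contribution = cls_contrib, habitat_contribution = hab_contrib,
      specificity = label, error = error, stringsAsFactors = FALSE)
  }

  run_anova <- function(name, y) {
    res <- tryCatch(fit_type3_anova(y, rec$class, rec$habitat,
                                    include_interaction = include_interaction_anova,
                                    pct_denominator = pct_denominator,
                                    feature = name, tukey = FALSE),
                    error = function(e) e)
    if (inherits(res, "error")) {
      add_row(name, "anova", NA_real_, NA_real_, NA_real_, NA_real_,
              error = conditionMessage(res))
      return(invisible(NULL))
    }
    anova_res[[name]] <<- res
    t <- res$terms
    add_row(name, "anova",
            t$p_value[t$term == "class"], t$p_value[t$term == "habitat"],
            t$pct_contribution[t$term == "class"],
            t$pct_contribution[t$term == "habitat"])
  }

  for (f in CONTINUOUS_FEATURES) run_anova(f, rec[[f]])
  run_anova("pred_aerobe", as.numeric(rec$pred_aerobe == "aerobic"))

  if (any(!is.na(rec$life_history))) {
    lh_levels <- c("ruderal", "competitor", "scarcity")
    fits <- lapply(lh_levels, function(lv) {
      tryCatch(fit_type3_anova(as.numeric(rec$life_history == lv),
                               rec$class, rec$habitat,
                               include_interaction = include_interaction_anova,
                               pct_denominator = pct_denominator,
                               feature = paste0("life_history:", lv),
                               tukey = FALSE),
               error = function(e) NULL)
    })
    ok <- !vapply(fits, is.null, logical(1))
    if (any(ok)) {
      cls_ss <- vapply(fits, function(f) {
        if (is.null(f)) -Inf else f$terms$ss[f$terms$term == "class"]
      }, numeric(1))
      best <- fits[[which.max(cls_ss)]]
      anova_res[[best$feature]] <- best
      t <- best$terms
      add_row(best$feature, "anova",
              t$p_value[t$term == "class"], t$p_value[t$term == "habitat"],
              t$pct_contribution[t$term == "class"],
              t$pct_contribution[t$term == "habitat"])
    } else {
      add_row("life_history", "anova", NA_real_, NA_real_, NA_real_,
              NA_real_, error = "no life-history indicator was estimable")
    }
  }

  if (!is.null(x$traits)) {
    idx <- match(rownames(x$traits), rec$accession)
    for (tr in colnames(x$traits)) {
      res <- tryCatch(
        fit_logistic_partition(x$traits[, tr], rec$class[idx],
                               rec$habitat[idx],
                               include_interaction = include_interaction_logistic,
                               trait_name = tr),
        error = function(e) e)
      if (inherits(res, "error")) {
        add_row(tr, "logistic", NA_real_, NA_real_, NA_real_, NA_real_,
                error = conditionMessage(res))
      } else {
        logistic_res[[tr]] <- res
        add_row(tr, "logistic", res$term_p[["class"]],
                res$term_p[["habitat"]], res$contribution[["class"]],
                res$contribution[["habitat"]])
      }
    }
  }

  summary <- do.call(rbind, rows)
  rownames(summary) <- NULL
  # informational only: the primary tiers use the fixed cutoffs
  summary$class_p_bh <- stats::p.adjust(summary$class_p, method = "BH")
  summary$habitat_p_bh <- stats::p.adjust(summary$habitat_p, method = "BH")
  tally <- table(factor(summary$specificity,
                        levels = c("lineage-specific", "habitat-specific",
                                   "both", "neither")))
  structure(list(anova = anova_res, logistic = logistic_res,
                 summary = summary, tally = tally),
            class = "partition_batch")
}

#' @export
print.partition_batch <- function(x, ...) {
  cat("<partition_batch> ", length(x$anova), " ANOVA analyses, ",
      length(x$logistic), " logistic analyses\n", sep = "")
  cat("specificity tally:\n")
  print(x$tally)
  invisible(x)
}
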