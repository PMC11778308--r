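# Small in-code fixtures shared across test files.

acido_lineage <- function(cls, ord = NULL, fam = NULL) {
  s <- paste0("d__Bacteria; p__Acidobacteriota; c__", cls)
  if (!is.null(ord)) s <- paste0(s, "; o__", ord)
  if (!is.null(fam)) s <- paste0(s, "; f__", fam)
  s
}

# A tiny hand-built collection: 2 soil, 1 marine, 1 freshwater, 1
# host-associated dataset; 2 class-level taxa.
mini_profiles <- function() {
  habitat_of <- c(S1 = "soil", S2 = "soil", M1 = "marine", F1 = "freshwater",
                  H1 = "host-associated")
  records <- data.frame(
    dataset = c("S1", "S2", "M1", "H1", "S1"),
    lineage = c(acido_lineage("A"), acido_lineage("A"), acido_lineage("A"),
                acido_lineage("A"), acido_lineage("B")),
    abundance = c(10, 20, 1, 0.5, 5),
    stringsAsFactors = FALSE)
  habitat_profiles(records, habitat_of)
}

write_profile_fixture <- function(dir, profiles_df, habitats_df) {
  pf <- file.path(dir, "profiles.tsv")
  hf <- file.path(dir, "habitats.tsv")
  utils::write.table(profiles_df, pf, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(habitats_df, hf, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  list(profiles = pf, habitats = hf)
}

# A small balanced genome-record table: 6 classes x 2 habitats x n_rep.
small_genome_records <- function(n_rep = 5, seed = 11) {
  set.seed(seed)
  classes <- c("ClsA", "ClsB", "ClsC", "ClsD", "ClsE", "ClsF")
  habs <- c("soil", "marine")
  grid <- expand.grid(class = classes, habitat = habs,
                      rep = seq_len(n_rep), stringsAsFactors = FALSE)
  n <- nrow(grid)
  data.frame(accession = sprintf("G%03d", seq_len(n)),
             class = grid$class, habitat = grid$habitat,
             genome_size = round(rnorm(n, 4e6, 5e5)),
             gc_pct = rnorm(n, 60, 4),
             coding_density = rnorm(n, 88, 2),
             mean_gene_length = round(rnorm(n, 950, 50)),
             protein_count = round(rnorm(n, 4000, 400)),
             crispr_count = rpois(n, 2),
             viral_contig_count = rpois(n, 4),
             cazyme_count = rpois(n, 100),
             peptidase_count = rpois(n, 80),
             bgc_count = rpois(n, 5),
             pred_ogt = rnorm(n, 25, 4),
             pred_ph = rnorm(n, 6.5, 0.8),
             pred_aerobe = sample(c("aerobic", "anaerobic"), n, TRUE),
             life_history = sample(c("ruderal", "competitor", "scarcity"),
                                   n, TRUE),
             stringsAsFactors = FALSE)
}

# Independent brute-force type III oracle: residual SS via Moore-Penrose
# projection (MASS::ginv), full model vs model with ALL of a term's columns
# removed. Shares no code with fit_type3_anova.
brute_force_type3 <- function(y, cls, hab, include_interaction = TRUE) {
  df <- data.frame(cls = factor(cls), hab = factor(hab))
  form <- if (include_interaction) ~ cls * hab else ~ cls + hab
  X <- model.matrix(form, df, contrasts.arg = list(cls = "contr.sum",
                                                   hab = "contr.sum"))
  rss <- function(M) {
    H <- M %*% MASS::ginv(crossprod(M)) %*% t(M)
    as.numeric(crossprod(y - H %*% y))
  }
  rss_full <- rss(X)
  asg <- attr(X, "assign")
  terms <- c(class = 1, habitat = 2,
             if (include_interaction) c(interaction = 3))
  sapply(terms, function(t) rss(X[, asg != t, drop = FALSE]) - rss_full)
}

# random unbalanced two-factor design with every cell occupied
random_design <- function(n_cls, n_hab, max_extra = 4) {
  cells <- expand.grid(cls = paste0("c", seq_len(n_cls)),
                       hab = paste0("h", seq_len(n_hab)),
                       stringsAsFactors = FALSE)
  reps <- 1L + sample.int(max_extra, nrow(cells), replace = TRUE)
  data.frame(cls = rep(cells$cls, reps), hab = rep(cells$hab, reps),
             stringsAsFactors = FALSE)
}
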