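# Orchestration of the full transplant analysis: group summaries, ODAC,
# plasticity, the home-vs-away / local-vs-foreign ANOVA framework, the
# cost-of-plasticity regressions, and significance-filtered correlation
# networks with Mantel comparisons.

#' Analysis configuration
#'
#' @param odac_mode ODAC normalization mode used for the trait-attached index
#'   (`"within_habitat"` primary; the global mode is always also reported by
#'   [run_full_analysis()] as a robustness check).
#' @param alpha Significance threshold for filtered edges and stars.
#' @param cutoffs Increasing pair of |r| cut-offs separating weak/thin/thick
#'   network edges.
#' @param exclude_traits Traits dropped from correlation analyses; Chl_a and
#'   Chl_b are excluded by default (redundant with Chl_tot and the a/b ratio),
#'   as is raw MDA (already inside ODAC).
#' @param n_perm,seed Mantel permutation count and seed.
#' @return An `analysis_config` list.
#' @export
analysis_config <- function(odac_mode = c("within_habitat", "global"),
                            alpha = 0.05, cutoffs = c(0.60, 0.80),
                            exclude_traits = c("Chl_a", "Chl_b", "MDA"),
                            n_perm = 999, seed = 20260325) {
  odac_mode <- match.arg(odac_mode)
  stopifnot(alpha > 0, alpha < 1, length(cutoffs) == 2,
            cutoffs[1] < cutoffs[2], cutoffs[1] > 0, cutoffs[2] <= 1)
  structure(list(odac_mode = odac_mode, alpha = alpha, cutoffs = cutoffs,
                 exclude_traits = exclude_traits,
                 n_perm = n_perm, seed = as.integer(seed)),
            class = "analysis_config")
}

.analysis_traits <- function(table) {
  tc <- trait_columns(table)
  # keep canonical ordering, ODAC (if attached) last
  ord <- c(intersect(trait_names(), tc), setdiff(tc, trait_names()))
  ord
}

#' "Home vs. away" one-way ANOVAs
#'
#' For each population separately, a one-way ANOVA of every trait across the
#' two habitats (df = 1, N - 2): does the population express different trait
#' values in its home and away environments?
#'
#' @param table A `trait_table` (attach ODAC first with [add_odac()] to
#'   include the composite).
#' @param traits Traits to test.
#' @param alpha Significance threshold for the star codes.
#' @return Data frame: population, trait, df, ms, f, p, signif.
#' @export
home_vs_away <- function(table, traits = .analysis_traits(table),
                         alpha = 0.05) {
  rows <- list()
  for (pop in .populations) {
    sub <- table[table$population == pop, ]
    for (tr in traits) {
      at <- one_way_anova(sub[[tr]], sub$habitat)
      rows[[length(rows) + 1]] <- data.frame(
        population = pop, trait = tr, df = at$df[1], ms = at$ms[1],
        f = at$f[1], p = at$p[1], stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out$signif <- significance_stars(out$p)
  out
}

#' "Local vs. foreign" one-way ANOVAs
#'
#' For each habitat separately, a one-way ANOVA of every trait between the
#' local and the foreign population (df = 1, N - 2): do the two populations
#' differ under identical conditions?
#'
#' @inheritParams home_vs_away
#' @return Data frame: habitat, trait, df, ms, f, p, signif.
#' @export
local_vs_foreign <- function(table, traits = .analysis_traits(table),
                             alpha = 0.05) {
  rows <- list()
  for (hab in .habitats) {
    sub <- table[table$habitat == hab, ]
    for (tr in traits) {
      at <- one_way_anova(sub[[tr]], sub$population)
      rows[[length(rows) + 1]] <- data.frame(
        habitat = hab, trait = tr, df = at$df[1], ms = at$ms[1],
        f = at$f[1], p = at$p[1], stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out$signif <- significance_stars(out$p)
  out
}

#' Two-way habitat x population ANOVA per trait
#'
#' Balanced two-way decomposition for every trait; a significant interaction
#' is flagged as evidence of population-specific plastic responses.
#'
#' @inheritParams home_vs_away
#' @return Data frame: trait, term, df, ss, ms, f, p, signif, plus a
#'   `interaction_significant` attribute listing flagged traits.
#' @export
population_habitat_anova <- function(table, traits = .analysis_traits(table),
                                     alpha = 0.05) {
  rows <- list()
  for (tr in traits) {
    if (anyNA(table[[tr]])) {
      # flagged composite values (e.g. an undefined ODAC) cannot enter the
      # balanced decomposition; report the trait as untestable, not a crash
      warning("trait '", tr, "' has flagged/missing values: two-way ANOVA ",
              "skipped", call. = FALSE)
      at <- .anova_table(c("habitat", "population", "habitat:population",
                           "error"), rep(NA_real_, 4), rep(NA_real_, 4))
    } else {
      at <- two_way_anova_balanced(table[[tr]], table$habitat,
                                   table$population)
    }
    at$trait <- tr
    rows[[length(rows) + 1]] <- at
  }
  out <- do.call(rbind, rows)
  out <- out[, c("trait", "term", "df", "ss", "ms", "f", "p")]
  out$signif <- significance_stars(out$p)
  flagged <- unique(out$trait[out$term == "habitat:population" &
                                !is.na(out$p) & out$p < alpha])
  attr(out, "interaction_significant") <- flagged
  rownames(out) <- NULL
  out
}

#' Population comparison of plasticity indices
#'
#' Per trait: population mean PI_V and CV%, plus the two-sided Wilcoxon
#' rank-sum p-value for the Dune-Woods difference with star codes.
#'
#' @param ptable A [plasticity_table()].
#' @return Data frame: trait, pi_dune, cv_dune, pi_woods, cv_woods, w, p,
#'   signif.
#' @export
plasticity_comparison <- function(ptable) {
  traits <- setdiff(names(ptable), c("genotype_id", "population"))
  summ <- summarize_plasticity(ptable)
  rows <- list()
  for (tr in traits) {
    d <- ptable[[tr]][ptable$population == "Dune"]
    w <- ptable[[tr]][ptable$population == "Woods"]
    d <- d[!is.na(d)]; w <- w[!is.na(w)]
    test <- wilcoxon_rank_sum(d, w)
    sd_ <- summ[summ$trait == tr & summ$population == "Dune", ]
    sw_ <- summ[summ$trait == tr & summ$population == "Woods", ]
    rows[[length(rows) + 1]] <- data.frame(
      trait = tr, pi_dune = sd_$mean_pi, cv_dune = sd_$cv_pct,
      pi_woods = sw_$mean_pi, cv_woods = sw_$cv_pct,
      w = test$statistic, p = test$p_value, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  out$signif <- significance_stars(out$p)
  out
}

#' Cost-of-plasticity standardized regressions
#'
#' Within each population, regresses mean specific leaf area (mSLA, the
#' per-genotype mean of SLA across the two habitats, used as a performance
#' proxy) on each trait's per-genotype mean and its plasticity index, on
#' standardized variables. A significant negative plasticity coefficient is
#' labeled a plasticity cost. The SLA row is marked self-referential (its
#' genotype mean is mSLA itself) and its mean-trait predictor is dropped.
#'
#' @param table A `trait_table` with SLA present.
#' @param ptable Matching [plasticity_table()].
#' @return Data frame: population, trait, predictor, estimate, se, t, p,
#'   signif, r_squared, self_referential, cost_flag.
#' @export
cost_of_plasticity <- function(table, ptable) {
  stopifnot("SLA" %in% names(table))
  traits <- setdiff(names(ptable), c("genotype_id", "population"))
  rows <- list()
  for (pop in .populations) {
    pt <- ptable[ptable$population == pop, ]
    sub <- table[table$population == pop, ]
    gmean <- function(tr) {
      vapply(pt$genotype_id, function(g) mean(sub[[tr]][sub$genotype_id == g]),
             numeric(1))
    }
    msla <- gmean("SLA")
    for (tr in traits) {
      self_ref <- tr == "SLA"
      pi <- pt[[tr]]
      ok <- !is.na(pi)
      preds <- if (self_ref) data.frame(PI = pi[ok])
               else data.frame(trait_mean = gmean(tr)[ok], PI = pi[ok])
      fit <- standardized_ols(msla[ok], preds)
      cf <- fit$coefficients
      cf$predictor[cf$predictor == "PI"] <- paste0("PI_", tr)
      cf$predictor[cf$predictor == "trait_mean"] <- paste0("mean_", tr)
      rows[[length(rows) + 1]] <- data.frame(
        population = pop, trait = tr, predictor = cf$predictor,
        estimate = cf$estimate, se = cf$se, t = cf$t, p = cf$p,
        r_squared = fit$r_squared, self_referential = self_ref,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out$signif <- significance_stars(out$p)
  out$cost_flag <- grepl("^PI_", out$predictor) & out$estimate < 0 &
    !is.na(out$p) & out$p < 0.05
  rownames(out) <- NULL
  out
}

#' Significance-filtered correlation networks and Mantel comparisons
#'
#' Per population x habitat: the Pearson correlation matrix on the included
#' traits, the edge list of significant correlations (p < alpha) classed by
#' |r| (`thick` above the upper cut-off, `thin` between the cut-offs, `weak`
#' below — retained for auditability though displays typically omit it), and
#' the positive/negative edge counts. Mantel tests compare the four matrix
#' pairs of the transplant design (between populations within each habitat;
#' between habitats within each population) and the two populations'
#' Spearman matrices of plasticity indices.
#'
#' @param table A `trait_table` (with ODAC attached for the full trait set).
#' @param cfg An [analysis_config()].
#' @param ptable Optional [plasticity_table()] for the plasticity-integration
#'   Mantel comparison.
#' @return A `network_report` list: `matrices`, `edges`, `counts`, `mantel`.
#' @export
correlation_networks <- function(table, cfg = analysis_config(),
                                 ptable = NULL) {
  traits <- setdiff(.analysis_traits(table), cfg$exclude_traits)
  if (length(traits) < 3) stop("need >= 3 included traits", call. = FALSE)
  groups <- expand.grid(population = .populations, habitat = .habitats,
                        stringsAsFactors = FALSE)
  matrices <- list()
  edges <- list()
  counts <- list()
  for (i in seq_len(nrow(groups))) {
    pop <- groups$population[i]; hab <- groups$habitat[i]
    sub <- table[table$population == pop & table$habitat == hab, traits]
    if (nrow(sub) < 3) stop("need n >= 3 per group", call. = FALSE)
    cm <- corr_matrix(sub, "pearson")
    key <- paste(pop, hab, sep = "_")
    matrices[[key]] <- cm
    el <- .edge_list(cm, cfg)
    el$population <- rep(pop, nrow(el))
    el$habitat <- rep(hab, nrow(el))
    edges[[key]] <- el
    counts[[key]] <- data.frame(
      population = pop, habitat = hab,
      n_significant = nrow(el),
      n_positive = sum(el$r > 0), n_negative = sum(el$r < 0),
      stringsAsFactors = FALSE)
  }
  pairs <- list(
    c("Dune_open", "Woods_open"), c("Dune_shaded", "Woods_shaded"),
    c("Dune_open", "Dune_shaded"), c("Woods_open", "Woods_shaded"))
  mantel <- list()
  for (k in seq_along(pairs)) {
    pr <- pairs[[k]]
    mt <- mantel_test(matrices[[pr[1]]]$r, matrices[[pr[2]]]$r,
                      n_perm = cfg$n_perm, seed = cfg$seed + k)
    mantel[[length(mantel) + 1]] <- data.frame(
      comparison = paste(pr, collapse = " vs "), matrix = "trait_pearson",
      r = mt$r_observed, p = mt$p_value, n_perm = mt$n_perm,
      stringsAsFactors = FALSE)
  }
  if (!is.null(ptable)) {
    ptraits <- setdiff(names(ptable),
                       c("genotype_id", "population", cfg$exclude_traits))
    sm <- lapply(.populations, function(pop) {
      corr_matrix(ptable[ptable$population == pop, ptraits], "spearman")
    })
    mt <- mantel_test(sm[[1]]$r, sm[[2]]$r, n_perm = cfg$n_perm,
                      seed = cfg$seed + 99)
    mantel[[length(mantel) + 1]] <- data.frame(
      comparison = "Dune vs Woods", matrix = "plasticity_spearman",
      r = mt$r_observed, p = mt$p_value, n_perm = mt$n_perm,
      stringsAsFactors = FALSE)
  }
  structure(list(matrices = matrices, edges = do.call(rbind, edges),
                 counts = do.call(rbind, counts),
                 mantel = do.call(rbind, mantel)),
            class = "network_report")
}

.edge_list <- function(cm, cfg) {
  labs <- cm$labels
  rows <- list()
  for (i in seq_len(length(labs) - 1)) {
    for (j in (i + 1):length(labs)) {
      p <- cm$p[i, j]
      if (!is.na(p) && p < cfg$alpha) {
        r <- cm$r[i, j]
        cls <- if (abs(r) > cfg$cutoffs[2]) "thick"
               else if (abs(r) > cfg$cutoffs[1]) "thin" else "weak"
        rows[[length(rows) + 1]] <- data.frame(
          trait_1 = labs[i], trait_2 = labs[j], r = r, p = p,
          weight_class = cls, stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(rows)) {
    return(data.frame(trait_1 = character(0), trait_2 = character(0),
                      r = numeric(0), p = numeric(0),
                      weight_class = character(0)))
  }
  do.call(rbind, rows)
}

#' Long-format reaction-norm export
#'
#' Plot-ready genotype x trait x habitat long table for external
#' reaction-norm figures.
#'
#' @param table A `trait_table`.
#' @return Data frame: genotype_id, population, habitat, trait, value.
#' @export
reaction_norms_long <- function(table) {
  traits <- .analysis_traits(table)
  out <- do.call(rbind, lapply(traits, function(tr) {
    data.frame(genotype_id = table$genotype_id,
               population = table$population, habitat = table$habitat,
               trait = tr, value = table[[tr]], stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Run the full transplant analysis
#'
#' Executes, in order: paired-design validation, group summaries, ODAC under
#' both normalization modes, plasticity indices and their population
#' comparison, the two-way habitat x population ANOVA, the home-vs-away and
#' local-vs-foreign one-way ANOVA batteries, cost-of-plasticity regressions,
#' and correlation networks with Mantel comparisons. Optionally writes a CSV
#' report bundle plus a JSON summary and a plain-text run log. Any stage
#' failure aborts with a stage-named error and removes partial outputs.
#'
#' @param table A `trait_table` (e.g. from [simulate_experiment()] or
#'   [load_trait_table()]).
#' @param cfg An [analysis_config()].
#' @param out_dir Optional output directory for the report bundle.
#' @return A `report_bundle` list with every stage's result, invisibly when
#'   `out_dir` is given.
#' @export
run_full_analysis <- function(table, cfg = analysis_config(), out_dir = NULL) {
  written <- character(0)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      unlink(written)
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
    })
  }
  res <- list(config = cfg)
  res$design <- stage("design", validate_paired_design(table))
  res$group_summary <- stage("summaries", summarize_groups(table))
  res$odac_within <- stage("odac", odac_table(table, "within_habitat"))
  res$odac_global <- stage("odac", odac_table(table, "global"))
  tab_odac <- stage("odac", add_odac(table, cfg$odac_mode))
  res$plasticity <- stage("plasticity", plasticity_table(tab_odac))
  res$plasticity_comparison <- stage("plasticity",
                                     plasticity_comparison(res$plasticity))
  res$two_way_anova <- stage("two_way_anova",
                             population_habitat_anova(tab_odac,
                                                      alpha = cfg$alpha))
  res$home_vs_away <- stage("home_vs_away",
                            home_vs_away(tab_odac, alpha = cfg$alpha))
  res$local_vs_foreign <- stage("local_vs_foreign",
                                local_vs_foreign(tab_odac, alpha = cfg$alpha))
  res$cost_of_plasticity <- stage("cost_of_plasticity",
                                  cost_of_plasticity(tab_odac, res$plasticity))
  res$networks <- stage("networks",
                        correlation_networks(tab_odac, cfg, res$plasticity))
  res$reaction_norms <- stage("export", reaction_norms_long(tab_odac))
  class(res) <- "report_bundle"

  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    wr <- function(df, name) {
      path <- file.path(out_dir, name)
      utils::write.csv(as.data.frame(df), path, row.names = FALSE)
      written <<- c(written, path)
    }
    stage("write", {
      wr(res$group_summary, "group_summary.csv")
      wr(res$odac_within, "odac_within_habitat.csv")
      wr(res$odac_global, "odac_global.csv")
      wr(res$plasticity, "plasticity_indices.csv")
      wr(res$plasticity_comparison, "plasticity_comparison.csv")
      wr(res$two_way_anova, "anova_two_way.csv")
      wr(res$home_vs_away, "anova_home_vs_away.csv")
      wr(res$local_vs_foreign, "anova_local_vs_foreign.csv")
      wr(res$cost_of_plasticity, "cost_of_plasticity.csv")
      wr(res$networks$edges, "network_edges.csv")
      wr(res$networks$counts, "network_counts.csv")
      wr(res$networks$mantel, "mantel_tests.csv")
      wr(res$reaction_norms, "reaction_norms_long.csv")
      json_path <- file.path(out_dir, "report_bundle.json")
      jsonlite::write_json(
        list(config = unclass(cfg),
             mantel = res$networks$mantel,
             network_counts = res$networks$counts,
             plasticity_comparison = res$plasticity_comparison),
        json_path, auto_unbox = TRUE, digits = NA)
      written <<- c(written, json_path)
      log_path <- file.path(out_dir, "run_log.txt")
      writeLines(c(
        "transplantTraits run log",
        paste0("package_version: ",
               as.character(utils::packageVersion("transplantTraits"))),
        paste0("seed: ", cfg$seed),
        paste0("odac_mode: ", cfg$odac_mode),
        paste0("alpha: ", cfg$alpha),
        paste0("n_perm: ", cfg$n_perm),
        paste0("records: ", nrow(table)),
        paste0("balanced: ", res$design$balanced)), log_path)
      written <<- c(written, log_path)
    })
    return(invisible(res))
  }
  res
}

#' @export
print.report_bundle <- function(x, ...) {
  cat("Transplant analysis report bundle\n")
  cat("  balanced design:", x$design$balanced, "\n")
  cat("  stages:", paste(setdiff(names(x), "config"), collapse = ", "), "\n")
  invisible(x)
}
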