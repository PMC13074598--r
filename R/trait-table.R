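#' @keywords internal
"_PACKAGE"

# Canonical trait vocabulary ------------------------------------------------

#' Canonical leaf trait names
#'
#' The thirteen measured traits handled by the package, in canonical order:
#' structural (SLA, LDMC), physiological (SLWC, pigments, Chl a/b ratio) and
#' biochemical (antioxidant enzymes, non-enzymatic antioxidants, MDA).
#' MDA (malondialdehyde, the lipid-peroxidation marker) is carried as supplied;
#' the package never derives it from raw readings.
#'
#' @return Character vector of trait column names.
#' @export
trait_names <- function() {
  c("SLA", "LDMC", "SLWC", "Chl_a", "Chl_b", "Chl_tot", "Chl_ab_ratio",
    "Cars", "POD", "GR", "ANTH", "PHEN", "MDA")
}

#' Measurement units for the canonical traits
#'
#' @return Named character vector mapping trait name to its unit string.
#'   Units are carried as metadata only; no dimensional analysis is enforced
#'   (the trait set mixes per-area and per-fresh-weight bases).
#' @export
trait_units <- function() {
  c(SLA = "cm2 g-1", LDMC = "g g-1", SLWC = "g cm-2",
    Chl_a = "ug cm-2", Chl_b = "ug cm-2", Chl_tot = "ug cm-2",
    Chl_ab_ratio = "", Cars = "ug cm-2",
    POD = "umol min-1 mg-1 protein", GR = "umol NADPH min-1 mg-1 protein",
    ANTH = "ug c3g eq g-1 FW", PHEN = "mg GAE g-1 FW",
    MDA = "as supplied")
}

.populations <- c("Dune", "Woods")
.habitats <- c("open", "shaded")

# Construction and validation ------------------------------------------------

#' Build a validated trait table
#'
#' A trait table is a data frame with one row per genotype x habitat holding
#' identifier columns (`genotype_id`, `population`, `habitat`) and any subset
#' of the canonical trait columns (see [trait_names()]); unknown numeric
#' columns are preserved as auxiliary traits.
#'
#' Validation enforces: populations in Dune/Woods, habitats in open/shaded,
#' strictly positive trait values, at most one record per genotype x habitat,
#' and internal chlorophyll consistency — `Chl_tot` must equal `Chl_a + Chl_b`
#' and `Chl_ab_ratio` must equal `Chl_a / Chl_b` (relative tolerance 1e-6) when
#' supplied; both are recomputed from `Chl_a`/`Chl_b` when absent.
#'
#' @param df Data frame of records.
#' @param allow_missing Logical; if `FALSE` (default, matching a complete
#'   design with no missing samples) any `NA` in a trait column is an error.
#' @return The validated data frame with class `trait_table`.
#' @export
trait_table <- function(df, allow_missing = FALSE) {
  stopifnot(is.data.frame(df))
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  required <- c("genotype_id", "population", "habitat")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols)) {
    stop("trait table is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  df$genotype_id <- as.character(df$genotype_id)
  df$population <- as.character(df$population)
  df$habitat <- as.character(df$habitat)
  bad_pop <- setdiff(unique(df$population), .populations)
  if (length(bad_pop)) {
    stop("unknown population level(s): ", paste(bad_pop, collapse = ", "),
         "; expected ", paste(.populations, collapse = "/"), call. = FALSE)
  }
  bad_hab <- setdiff(unique(df$habitat), .habitats)
  if (length(bad_hab)) {
    stop("unknown habitat level(s): ", paste(bad_hab, collapse = ", "),
         "; expected ", paste(.habitats, collapse = "/"), call. = FALSE)
  }

  dup <- duplicated(df[, c("genotype_id", "habitat")])
  if (any(dup)) {
    stop("duplicate (genotype_id, habitat) record(s): ",
         paste(unique(paste(df$genotype_id[dup], df$habitat[dup], sep = "/")),
               collapse = ", "), call. = FALSE)
  }

  tcols <- trait_columns(df)
  for (tc in tcols) {
    v <- df[[tc]]
    if (!is.numeric(v)) {
      stop("trait column '", tc, "' is not numeric", call. = FALSE)
    }
    if (!allow_missing && anyNA(v)) {
      stop("trait column '", tc, "' has missing values at row(s) ",
           paste(which(is.na(v)), collapse = ", "),
           " (use allow_missing = TRUE for incomplete tables)", call. = FALSE)
    }
    bad <- which(!is.na(v) & v <= 0)
    if (length(bad)) {
      stop("non-positive value in trait '", tc, "' at row(s) ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
  }

  df <- .reconcile_chlorophyll(df)
  class(df) <- unique(c("trait_table", class(df)))
  df
}

# Chl_tot / Chl_ab_ratio: recompute when absent, cross-check when supplied.
.reconcile_chlorophyll <- function(df, rel_tol = 1e-6) {
  has <- function(nm) nm %in% names(df)
  if (has("Chl_a") && has("Chl_b")) {
    tot <- df$Chl_a + df$Chl_b
    if (!has("Chl_tot")) {
      df$Chl_tot <- tot
    } else {
      off <- which(abs(df$Chl_tot - tot) > rel_tol * pmax(abs(tot), 1e-300))
      off <- off[!is.na(off)]
      if (length(off)) {
        stop("Chl_tot != Chl_a + Chl_b at row(s) ",
             paste(off, collapse = ", "), call. = FALSE)
      }
    }
    ratio <- df$Chl_a / df$Chl_b
    if (!has("Chl_ab_ratio")) {
      df$Chl_ab_ratio <- ratio
    } else {
      off <- which(abs(df$Chl_ab_ratio - ratio) >
                     rel_tol * pmax(abs(ratio), 1e-300))
      off <- off[!is.na(off)]
      if (length(off)) {
        stop("Chl_ab_ratio != Chl_a / Chl_b at row(s) ",
             paste(off, collapse = ", "), call. = FALSE)
      }
    }
  }
  df
}

#' Trait columns present in a table
#'
#' @param df Data frame (usually a `trait_table`).
#' @param canonical_only If `TRUE`, restrict to [trait_names()]; otherwise
#'   auxiliary numeric columns (anything numeric beyond the id columns) are
#'   included too.
#' @return Character vector of column names.
#' @export
trait_columns <- function(df, canonical_only = FALSE) {
  ids <- c("genotype_id", "population", "habitat")
  if (canonical_only) return(intersect(trait_names(), names(df)))
  cand <- setdiff(names(df), ids)
  cand[vapply(df[cand], is.numeric, logical(1))]
}

#' @export
print.trait_table <- function(x, ...) {
  cat("Trait table: ", nrow(x), " records, ",
      length(unique(x$genotype_id)), " genotypes, traits: ",
      paste(trait_columns(x), collapse = ", "), "\n", sep = "")
  print(utils::head(as.data.frame(x), 6))
  if (nrow(x) > 6) cat("... (", nrow(x) - 6, " more rows)\n", sep = "")
  invisible(x)
}

# I/O -------------------------------------------------------------------------

.detect_delim <- function(path) {
  first <- readLines(path, n = 1L, warn = FALSE)
  counts <- c("," = lengths(regmatches(first, gregexpr(",", first, fixed = TRUE))),
              "\t" = lengths(regmatches(first, gregexpr("\t", first, fixed = TRUE))),
              ";" = lengths(regmatches(first, gregexpr(";", first, fixed = TRUE))))
  if (all(counts == 0)) return(",")
  names(counts)[which.max(counts)]
}

#' Read a trait table from delimited text
#'
#' The delimiter is auto-detected among comma, tab and semicolon. Decimal
#' values must use the dot separator. Foreign headers can be adapted with
#' `col_map`, a named character vector or list mapping canonical names to the
#' names used in the file (e.g. `c(genotype_id = "clone")`).
#'
#' @param path Path to a CSV/TSV file with a header row.
#' @param col_map Optional column-name map (canonical = foreign).
#' @param allow_missing Passed to [trait_table()].
#' @return A validated `trait_table`.
#' @export
load_trait_table <- function(path, col_map = NULL, allow_missing = FALSE) {
  delim <- .detect_delim(path)
  df <- utils::read.table(path, header = TRUE, sep = delim, dec = ".",
                          stringsAsFactors = FALSE, check.names = FALSE)
  if (!is.null(col_map)) {
    col_map <- unlist(col_map)
    for (canon in names(col_map)) {
      foreign <- col_map[[canon]]
      if (!foreign %in% names(df)) {
        stop("column map names '", foreign, "' which is absent from ", path,
             call. = FALSE)
      }
      names(df)[names(df) == foreign] <- canon
    }
  }
  trait_table(df, allow_missing = allow_missing)
}

#' Write a trait table as CSV
#'
#' Values are written at full double precision (17 significant digits) so a
#' write/load round trip reproduces the table exactly.
#'
#' @param x A `trait_table`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_trait_table <- function(x, path) {
  out <- as.data.frame(x)
  num <- vapply(out, is.numeric, logical(1))
  out[num] <- lapply(out[num], function(v) formatC(v, digits = 17, format = "g"))
  utils::write.table(out, path, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}

# Design validation -----------------------------------------------------------

#' Check the paired reciprocal-transplant design
#'
#' The reference design has every genotype represented by one ramet in each of
#' the two habitats (its home habitat and the away habitat), with equal
#' genotype counts in the two populations.
#'
#' @param table A `trait_table`.
#' @return A `design_report` list with elements `n_genotypes` (named count per
#'   population), `paired` (named logical per genotype), `missing_cells`
#'   (data frame of genotype x habitat cells with no record) and `balanced`.
#' @export
validate_paired_design <- function(table) {
  stopifnot(nrow(table) > 0)
  key <- unique(table[, c("genotype_id", "population")])
  if (anyDuplicated(key$genotype_id)) {
    stop("genotype(s) assigned to more than one population: ",
         paste(key$genotype_id[duplicated(key$genotype_id)], collapse = ", "),
         call. = FALSE)
  }
  paired <- vapply(key$genotype_id, function(g) {
    all(.habitats %in% table$habitat[table$genotype_id == g])
  }, logical(1))
  names(paired) <- key$genotype_id
  missing_cells <- do.call(rbind, lapply(key$genotype_id[!paired], function(g) {
    hab <- setdiff(.habitats, table$habitat[table$genotype_id == g])
    data.frame(genotype_id = g, habitat = hab, stringsAsFactors = FALSE)
  }))
  if (is.null(missing_cells)) {
    missing_cells <- data.frame(genotype_id = character(0),
                                habitat = character(0))
  }
  n_genotypes <- table(factor(key$population, levels = .populations))
  n_genotypes <- stats::setNames(as.integer(n_genotypes), .populations)
  balanced <- all(paired) && length(unique(n_genotypes)) == 1 &&
    all(n_genotypes > 0)
  structure(list(n_genotypes = n_genotypes, paired = paired,
                 missing_cells = missing_cells, balanced = balanced),
            class = "design_report")
}

#' @export
print.design_report <- function(x, ...) {
  cat("Paired design report\n")
  cat("  genotypes:", paste(names(x$n_genotypes), x$n_genotypes,
                            sep = "=", collapse = ", "), "\n")
  cat("  balanced:", x$balanced, "\n")
  if (nrow(x$missing_cells)) {
    cat("  missing cells:\n")
    print(x$missing_cells)
  }
  invisible(x)
}

# Group summaries -------------------------------------------------------------

#' Group descriptive statistics (mean, SE, CV%)
#'
#' Per (population, habitat, trait): mean, standard error `sd/sqrt(n)` and
#' coefficient of variation `100 * sd / mean`, with the sample standard
#' deviation (n - 1 denominator). Groups of size one are flagged (`degenerate`)
#' and get `NA` SE/CV rather than a silent zero.
#'
#' @param table A `trait_table`.
#' @param traits Trait columns to summarize; defaults to all present.
#' @return Data frame with columns population, habitat, trait, n, mean, se,
#'   cv_pct, degenerate; class `group_summary`.
#' @export
summarize_groups <- function(table, traits = trait_columns(table)) {
  groups <- expand.grid(population = .populations, habitat = .habitats,
                        stringsAsFactors = FALSE)
  rows <- list()
  for (i in seq_len(nrow(groups))) {
    sel <- table$population == groups$population[i] &
      table$habitat == groups$habitat[i]
    if (!any(sel)) next
    for (tr in traits) {
      v <- table[[tr]][sel]
      v <- v[!is.na(v)]
      n <- length(v)
      if (n == 0) next
      m <- mean(v)
      if (n >= 2) {
        s <- stats::sd(v)
        se <- s / sqrt(n)
        cv <- 100 * s / m
        degenerate <- FALSE
      } else {
        se <- NA_real_; cv <- NA_real_; degenerate <- TRUE
      }
      rows[[length(rows) + 1]] <- data.frame(
        population = groups$population[i], habitat = groups$habitat[i],
        trait = tr, n = n, mean = m, se = se, cv_pct = cv,
        degenerate = degenerate, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  if (any(out$degenerate)) {
    warning("group(s) of size 1: SE and CV% undefined", call. = FALSE)
  }
  class(out) <- c("group_summary", class(out))
  out
}

#' Write a group summary in a population x habitat block layout
#'
#' @param x A `group_summary`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_group_summary <- function(x, path) {
  df <- as.data.frame(x)
  df$group <- paste(df$population, df$habitat, sep = "_")
  wide <- stats::reshape(df[, c("trait", "group", "mean", "se", "cv_pct")],
                         idvar = "trait", timevar = "group",
                         direction = "wide")
  utils::write.csv(wide, path, row.names = FALSE)
  invisible(path)
}
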