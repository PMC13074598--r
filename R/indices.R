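# The two bespoke indices: the ODAC oxidative-balance composite (min-max
# normalized components) and the Valladares PI_V phenotypic-plasticity index.

#' Min-max normalization, optionally within groups
#'
#' `x' = (x - min) / (max - min)` computed per group (each group's minimum
#' maps to 0 and maximum to 1). With `groups = NULL` the scaling is global
#' across all values.
#'
#' @param values Numeric vector.
#' @param groups Optional group labels (same length as `values`), e.g. the
#'   habitat of each sample for within-habitat scaling.
#' @param constant How to handle a constant group (max == min, the formula is
#'   0/0): `"midpoint"` (default) sets all its values to 0.5 with a warning,
#'   preserving the equal-contribution intent; `"error"` aborts.
#' @return Normalized vector in `[0, 1]`.
#' @export
minmax_normalize <- function(values, groups = NULL,
                             constant = c("midpoint", "error")) {
  constant <- match.arg(constant)
  if (is.null(groups)) groups <- rep(1L, length(values))
  stopifnot(length(groups) == length(values))
  out <- rep(NA_real_, length(values))
  for (g in unique(groups)) {
    sel <- which(groups == g)
    if (length(sel) < 2) {
      stop("min-max normalization needs >= 2 values per group", call. = FALSE)
    }
    v <- values[sel]
    rng <- range(v)
    if (rng[1] == rng[2]) {
      if (constant == "error") {
        stop("constant group in min-max normalization (max == min)",
             call. = FALSE)
      }
      warning("constant group in min-max normalization: values set to 0.5",
              call. = FALSE)
      out[sel] <- 0.5
    } else {
      out[sel] <- (v - rng[1]) / (rng[2] - rng[1])
    }
  }
  out
}

#' ODAC from normalized components
#'
#' `ODAC = MDA' / (POD' + GR' + PHEN' + ANTH')` on min-max normalized
#' components: the ratio of lipid-peroxidation damage to the summed enzymatic
#' and non-enzymatic antioxidant investment, all treated as equally
#' contributing after normalization. Higher values indicate greater oxidative
#' damage relative to antioxidant investment.
#'
#' @param mda,pod,gr,phen,anth Normalized components in `[0, 1]`.
#' @return ODAC values; a zero antioxidant denominator gives `NA` with a
#'   warning (flagged, not silently dropped).
#' @export
compute_odac <- function(mda, pod, gr, phen, anth) {
  comp <- cbind(mda, pod, gr, phen, anth)
  if (any(comp < 0 | comp > 1, na.rm = TRUE)) {
    stop("compute_odac expects normalized components in [0, 1]", call. = FALSE)
  }
  denom <- pod + gr + phen + anth
  out <- ifelse(denom == 0, NA_real_, mda / denom)
  if (any(denom == 0, na.rm = TRUE)) {
    warning("zero antioxidant denominator: ODAC undefined for ",
            sum(denom == 0, na.rm = TRUE), " sample(s)", call. = FALSE)
  }
  out
}

#' ODAC table for a trait table
#'
#' Normalizes MDA, POD, GR, PHEN and ANTH by min-max scaling — within each
#' light environment (`"within_habitat"`, the primary mode; both populations
#' pooled per habitat) or across all samples (`"global"`, the robustness
#' variant) — then computes ODAC per genotype x habitat record. Under
#' within-habitat scaling ODAC is interpreted primarily for within-habitat
#' population comparisons; cross-habitat magnitudes are reported but carry a
#' `cross_habitat_caveat` attribute.
#'
#' @param table A `trait_table` with MDA, POD, GR, PHEN, ANTH present.
#' @param mode Normalization mode.
#' @param constant Passed to [minmax_normalize()].
#' @return Data frame (class `odac_table`) with the id columns, the
#'   normalized components (`*_n`), `ODAC` and the `mode`.
#' @export
odac_table <- function(table, mode = c("within_habitat", "global"),
                       constant = c("midpoint", "error")) {
  mode <- match.arg(mode)
  comps <- c("MDA", "POD", "GR", "PHEN", "ANTH")
  missing_c <- setdiff(comps, names(table))
  if (length(missing_c)) {
    stop("odac_table needs component(s): ", paste(missing_c, collapse = ", "),
         call. = FALSE)
  }
  groups <- if (mode == "within_habitat") table$habitat else NULL
  norm <- lapply(comps, function(cc) {
    minmax_normalize(table[[cc]], groups = groups, constant = constant)
  })
  names(norm) <- paste0(comps, "_n")
  out <- cbind(table[, c("genotype_id", "population", "habitat")],
               as.data.frame(norm))
  out$ODAC <- compute_odac(out$MDA_n, out$POD_n, out$GR_n, out$PHEN_n,
                           out$ANTH_n)
  out$mode <- mode
  attr(out, "cross_habitat_caveat") <- mode == "within_habitat"
  class(out) <- c("odac_table", class(out))
  out
}

#' Attach ODAC as a trait column
#'
#' Convenience for downstream analyses that treat the composite index as a
#' fourteenth trait (plasticity, ANOVA, correlation networks).
#'
#' @param table A `trait_table`.
#' @param mode Passed to [odac_table()].
#' @return The table with an `ODAC` column (plain data frame columns appended;
#'   ODAC is not range-restricted to positive values by the trait validator
#'   because normalized minima are exactly 0).
#' @export
add_odac <- function(table, mode = c("within_habitat", "global")) {
  ot <- odac_table(table, mode = mode)
  stopifnot(identical(ot$genotype_id, table$genotype_id),
            identical(ot$habitat, table$habitat))
  table$ODAC <- ot$ODAC
  table
}

#' Phenotypic plasticity index PI_V
#'
#' `PI_V = |X1 - X2| / (X1 + X2)` for a genotype's trait values in the two
#' environments (X1 open, X2 shaded by reporting convention; the formula is
#' symmetric). Ranges from 0 (no plasticity) to 1 (maximum plasticity) for
#' strictly positive trait values.
#'
#' @param x_open,x_shaded Trait values (>= 0, not both zero) of the same
#'   genotype in the two habitats. Zeros arise legitimately for normalized
#'   composites such as ODAC, where PI_V reaches its maximum of 1.
#' @return PI_V in `[0, 1]`.
#' @export
plasticity_index <- function(x_open, x_shaded) {
  if (any(x_open < 0) || any(x_shaded < 0)) {
    stop("plasticity_index requires non-negative trait values", call. = FALSE)
  }
  if (any(x_open + x_shaded == 0)) {
    stop("plasticity_index undefined when both habitat values are zero",
         call. = FALSE)
  }
  abs(x_open - x_shaded) / abs(x_open + x_shaded)
}

#' Per-genotype plasticity table
#'
#' Computes PI_V for every genotype and trait from its paired open/shaded
#' records. Genotypes lacking one habitat are excluded with a warning naming
#' them.
#'
#' @param table A `trait_table` (ODAC may be attached via [add_odac()]).
#' @param traits Trait columns to use; defaults to all numeric trait columns.
#' @return Data frame (class `plasticity_table`): genotype_id, population and
#'   one PI_V column per trait.
#' @export
plasticity_table <- function(table, traits = trait_columns(table)) {
  rep_design <- validate_paired_design(table)
  unpaired <- names(rep_design$paired)[!rep_design$paired]
  if (length(unpaired)) {
    warning("excluding unpaired genotype(s): ",
            paste(unpaired, collapse = ", "), call. = FALSE)
  }
  keep <- setdiff(names(rep_design$paired), unpaired)
  open <- table[table$habitat == "open" & table$genotype_id %in% keep, ]
  shaded <- table[table$habitat == "shaded" & table$genotype_id %in% keep, ]
  shaded <- shaded[match(open$genotype_id, shaded$genotype_id), ]
  out <- open[, c("genotype_id", "population")]
  for (tr in traits) {
    x1 <- open[[tr]]; x2 <- shaded[[tr]]
    zero <- x1 + x2 == 0          # e.g. ODAC at the normalized minimum twice
    if (any(zero)) {
      warning("PI_V undefined (both habitat values zero) for trait '", tr,
              "', genotype(s) ", paste(open$genotype_id[zero], collapse = ", "),
              call. = FALSE)
      x1[zero] <- NA_real_
    }
    pi <- rep(NA_real_, length(x1))
    ok <- !is.na(x1)
    pi[ok] <- plasticity_index(x1[ok], x2[ok])
    out[[tr]] <- pi
  }
  rownames(out) <- NULL
  class(out) <- c("plasticity_table", "data.frame")
  out
}

#' Population-level plasticity summary
#'
#' Mean PI_V and its CV% per population and trait.
#'
#' @param ptable A [plasticity_table()].
#' @return Data frame with columns trait, population, n, mean_pi, cv_pct.
#' @export
summarize_plasticity <- function(ptable) {
  traits <- setdiff(names(ptable), c("genotype_id", "population"))
  rows <- list()
  for (tr in traits) {
    for (pop in unique(ptable$population)) {
      v <- ptable[[tr]][ptable$population == pop]
      v <- v[!is.na(v)]
      rows[[length(rows) + 1]] <- data.frame(
        trait = tr, population = pop, n = length(v), mean_pi = mean(v),
        cv_pct = if (length(v) >= 2 && mean(v) > 0)
          100 * stats::sd(v) / mean(v) else NA_real_,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
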