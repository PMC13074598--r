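# Invertible raw-assay synthesis: given a trait table, produce leaf geometry
# and absorbance readings that the forward derivations map back onto the
# traits (exactly in zero-noise mode). The inversions use the same formulas
# as the forward module, algebraically solved for the readings.
#
# SLA, LDMC and SLWC are mutually constrained for a single leaf
# (SLWC = (1/LDMC - 1)/SLA), but the trait table treats them as separate
# traits. Two leaf records are therefore emitted per sample: a structural
# leaf inverted from SLA + LDMC and a hydration leaf inverted from
# LDMC + SLWC, mirroring leaf-to-leaf variation in real sampling.

#' Synthesize raw assay readings from a trait table
#'
#' @param table A `trait_table` containing the traits to invert.
#' @param cfg An [assay_config()]; extraction volumes, extinction
#'   coefficients and pigment equations used for the inversion.
#' @param seed Integer seed for the measurement-noise draws (unused when
#'   `noise_cv = 0`).
#' @param noise_cv Relative measurement noise (CV) applied multiplicatively
#'   to every synthesized reading; 0 (default) gives the exact inversion.
#' @param protein Nominal soluble-protein concentration of the enzyme
#'   extracts (mg mL-1).
#' @param linearity_max Absorbance linearity bound; synthesized readings above
#'   it are flagged (`flagged` column) as outside the invertible range.
#' @return A `raw_assays` list of data frames: `structural`, `hydration`,
#'   `pigments`, `enzymes`, `phenolics`, `anthocyanins`, `mda`, plus the
#'   synthetic calibration points `protein_standards` and `gallic_standards`.
#' @export
synthesize_raw_assays <- function(table, cfg = assay_config(), seed = 1,
                                  noise_cv = 0, protein = 2,
                                  linearity_max = 4) {
  stopifnot(inherits(table, "trait_table"), noise_cv >= 0, protein > 0)
  ids <- table[, c("genotype_id", "population", "habitat")]
  out <- list()

  noisy <- function(x) x  # replaced below when noise is requested
  if (noise_cv > 0) {
    set.seed(as.integer(seed))
    noisy <- function(x) x * exp(stats::rnorm(length(x), 0, noise_cv))
  }

  has <- function(nm) nm %in% names(table)

  if (has("SLA") && has("LDMC")) {
    lfm <- rep(1, nrow(table))                       # 1 g fresh mass reference
    ldm <- table$LDMC * lfm
    la <- table$SLA * ldm
    out$structural <- cbind(ids, data.frame(
      LA = noisy(la), LFM = lfm, LDM = noisy(ldm)))
  }
  if (has("SLWC") && has("LDMC")) {
    lfm <- rep(1, nrow(table))
    ldm <- table$LDMC * lfm
    la <- (lfm - ldm) / table$SLWC
    out$hydration <- cbind(ids, data.frame(
      LA = noisy(la), LFM = lfm, LDM = noisy(ldm)))
  }

  if (has("Chl_a") && has("Chl_b") && has("Cars")) {
    scale <- cfg$pigment_leaf_area / cfg$pigment_volume  # per-area -> ug mL-1
    ca <- table$Chl_a * scale
    cb <- table$Chl_b * scale
    cc <- table$Cars * scale
    pc <- cfg$pigment_coef
    m <- matrix(c(pc$a[1], pc$a[2], pc$b[1], pc$b[2]), 2, byrow = TRUE)
    ab <- t(solve(m, rbind(ca, cb)))                 # columns A665, A649
    a480 <- (pc$cars[4] * cc - pc$cars[2] * ca - pc$cars[3] * cb) / pc$cars[1]
    flagged <- ab[, 1] < 0 | ab[, 2] < 0 | a480 < 0 |
      pmax(ab[, 1], ab[, 2], a480) > linearity_max
    out$pigments <- cbind(ids, data.frame(
      A665 = noisy(ab[, 1]), A649 = noisy(ab[, 2]), A480 = noisy(a480),
      volume = cfg$pigment_volume, leaf_area = cfg$pigment_leaf_area,
      flagged = flagged))
  }

  bsa_conc <- c(0.25, 0.5, 1, 1.5, 2)
  bsa_curve <- list(slope = 0.5, intercept = 0.05)
  out$protein_standards <- data.frame(
    concentration = bsa_conc,
    absorbance = bsa_curve$slope * bsa_conc + bsa_curve$intercept)
  if (has("POD") || has("GR")) {
    a595 <- bsa_curve$slope * protein + bsa_curve$intercept
    enz <- cbind(ids, data.frame(A595 = noisy(rep(a595, nrow(table)))))
    if (has("POD")) {
      enz$dA430_per_min <- noisy(table$POD * protein *
        (cfg$v_extract / cfg$v_rxn) * cfg$eps_pod * cfg$path_length)
    }
    if (has("GR")) {
      enz$dA340_per_min <- noisy(table$GR * protein *
        (cfg$v_extract / cfg$v_rxn) * cfg$eps_gr * cfg$path_length)
    }
    out$enzymes <- enz
  }

  gal_conc <- c(0.05, 0.1, 0.2, 0.3, 0.4, 0.5)
  gal_curve <- list(slope = 2, intercept = 0.02)
  out$gallic_standards <- data.frame(
    concentration = gal_conc,
    absorbance = gal_curve$slope * gal_conc + gal_curve$intercept)
  if (has("PHEN")) {
    conc <- table$PHEN / cfg$phen_volume_per_g       # mg GAE mL-1
    a724 <- gal_curve$slope * conc + gal_curve$intercept
    out$phenolics <- cbind(ids, data.frame(
      A724 = noisy(a724), flagged = a724 > linearity_max))
  }

  if (has("ANTH")) {
    per_acorr <- cfg$mw_anth * 1000 / (cfg$eps_anth * cfg$path_length) *
      cfg$anth_volume_per_g                          # ug g-1 FW per unit A_corr
    a_corr <- table$ANTH / per_acorr
    a653 <- rep(0.1, nrow(table))                    # nominal carbohydrate signal
    a530 <- a_corr + cfg$anth_correction * a653
    out$anthocyanins <- cbind(ids, data.frame(
      A530 = noisy(a530), A653 = noisy(a653), flagged = a530 > linearity_max))
  }

  if (has("MDA")) {
    out$mda <- cbind(ids, data.frame(MDA = table$MDA))
  }

  structure(out, class = "raw_assays")
}

#' Derive a trait table from raw assay readings
#'
#' Forward counterpart of [synthesize_raw_assays()]: applies the structural
#' formulas, pigment equations, standard-curve inversions and enzyme kinetics
#' to a `raw_assays` bundle (or an equally shaped list of data frames read
#' from per-assay CSVs) and merges the results into a validated trait table.
#'
#' @param raw A `raw_assays`-shaped list; records are linked by
#'   genotype_id + habitat.
#' @param cfg The [assay_config()] used for the measurements.
#' @return A `trait_table` with all derivable traits (MDA is passed through
#'   when present).
#' @export
derive_trait_table <- function(raw, cfg = assay_config()) {
  key <- NULL
  add <- function(base, df) {
    if (is.null(base)) return(df)
    merge(base, df, by = c("genotype_id", "population", "habitat"),
          sort = FALSE)
  }
  idcols <- c("genotype_id", "population", "habitat")

  if (!is.null(raw$structural)) {
    s <- raw$structural
    st <- derive_structural(s$LA, s$LFM, s$LDM)
    key <- add(key, cbind(s[idcols], st[, c("SLA", "LDMC")]))
  }
  if (!is.null(raw$hydration)) {
    h <- raw$hydration
    hy <- derive_structural(h$LA, h$LFM, h$LDM)
    key <- add(key, cbind(h[idcols], data.frame(SLWC = hy$SLWC)))
  }
  if (!is.null(raw$pigments)) {
    p <- raw$pigments
    pg <- quantify_pigments(p$A665, p$A649, p$A480, cfg,
                            volume = p$volume[1], leaf_ref = p$leaf_area[1])
    key <- add(key, cbind(p[idcols], pg))
  }
  if (!is.null(raw$enzymes)) {
    e <- raw$enzymes
    curve <- fit_standard_curve(raw$protein_standards$concentration,
                                raw$protein_standards$absorbance)
    prot <- vapply(e$A595, function(a) protein_bradford(a, curve), numeric(1))
    enz <- e[idcols]
    if (!is.null(e$dA430_per_min)) {
      enz$POD <- enzyme_specific_activity(e$dA430_per_min, prot, "POD", cfg)
    }
    if (!is.null(e$dA340_per_min)) {
      enz$GR <- enzyme_specific_activity(e$dA340_per_min, prot, "GR", cfg)
    }
    key <- add(key, enz)
  }
  if (!is.null(raw$phenolics)) {
    f <- raw$phenolics
    curve <- fit_standard_curve(raw$gallic_standards$concentration,
                                raw$gallic_standards$absorbance)
    phen <- vapply(f$A724, function(a) {
      total_phenolics(a, curve, volume_per_g = cfg$phen_volume_per_g)
    }, numeric(1))
    key <- add(key, cbind(f[idcols], data.frame(PHEN = phen)))
  }
  if (!is.null(raw$anthocyanins)) {
    a <- raw$anthocyanins
    anth <- total_anthocyanins(a$A530, a$A653, cfg,
                               volume_per_g = cfg$anth_volume_per_g)
    key <- add(key, cbind(a[idcols], data.frame(ANTH = anth)))
  }
  if (!is.null(raw$mda)) {
    key <- add(key, raw$mda)
  }
  if (is.null(key)) stop("no derivable assay families in 'raw'", call. = FALSE)
  trait_table(key)
}
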