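# Conversion of raw leaf measurements and spectrophotometric readings into
# the measured traits: leaf geometry ratios, pigment equations, Beer-Lambert
# enzyme kinetics, and standard-curve colorimetry.

#' Spectrophotometric assay configuration
#'
#' Extinction coefficients, geometry and volumes shared by the forward
#' derivations and their synthetic inversions. Defaults follow the wet-lab
#' protocol the package models: pyrogallol POD kinetics at 430 nm
#' (eps 2.4 mM-1 cm-1), NADPH-linked GR kinetics at 340 nm (eps 6.2),
#' cyanidin-3-glucoside anthocyanin quantification at 530 nm
#' (eps 26900 L mol-1 cm-1, MW 445, carbohydrate correction A530 - 0.24 A653),
#' and Wellburn-style DMSO pigment equations (coefficients configurable; the
#' per-mL concentrations are `chl_a = 12.47 A665 - 3.62 A649`,
#' `chl_b = 25.06 A649 - 6.50 A665`,
#' `cars = (1000 A480 - 1.29 chl_a - 53.78 chl_b) / 220`).
#'
#' @param path_length Optical path (cm); cuvette convention 1 cm (the quoted
#'   extinction coefficients are per cm).
#' @param eps_pod,eps_gr Extinction coefficients (mM-1 cm-1).
#' @param eps_anth Anthocyanin extinction coefficient (L mol-1 cm-1).
#' @param mw_anth Molar mass of cyanidin-3-glucoside (g mol-1).
#' @param anth_correction Carbohydrate-interference coefficient on A653.
#' @param v_rxn,v_extract Enzyme reaction volume and extract aliquot (mL).
#' @param enzyme_extract_ratio Extract volume per g FW for the enzyme extract
#'   (mL g-1). Required for FW-based bookkeeping of enzyme assays; the modeled
#'   protocol does not fix it, so there is no default.
#' @param pigment_coef 2x2-plus-carotenoid coefficient list with elements
#'   `a` (on A665, A649 for Chl a), `b` (on A665, A649 for Chl b) and
#'   `cars` (c(scale480, on_chl_a, on_chl_b, divisor)).
#' @param pigment_volume Pigment extract volume per sample (mL).
#' @param pigment_leaf_area Leaf area extracted per sample (cm2).
#' @param phen_volume_per_g Pooled phenolics extract volume per g FW (mL g-1);
#'   the two-step 1:15 + 1:7 methanol extraction pools to 22.
#' @param anth_volume_per_g Anthocyanin extract volume per g FW (mL g-1).
#' @return An `assay_config` list.
#' @export
assay_config <- function(path_length = 1,
                         eps_pod = 2.4, eps_gr = 6.2,
                         eps_anth = 26900, mw_anth = 445,
                         anth_correction = 0.24,
                         v_rxn = 1, v_extract = 0.05,
                         enzyme_extract_ratio = NA_real_,
                         pigment_coef = list(a = c(12.47, -3.62),
                                             b = c(-6.50, 25.06),
                                             cars = c(1000, -1.29, -53.78, 220)),
                         pigment_volume = 3, pigment_leaf_area = 5,
                         phen_volume_per_g = 22, anth_volume_per_g = 30) {
  cfg <- list(path_length = path_length, eps_pod = eps_pod, eps_gr = eps_gr,
              eps_anth = eps_anth, mw_anth = mw_anth,
              anth_correction = anth_correction,
              v_rxn = v_rxn, v_extract = v_extract,
              enzyme_extract_ratio = enzyme_extract_ratio,
              pigment_coef = pigment_coef,
              pigment_volume = pigment_volume,
              pigment_leaf_area = pigment_leaf_area,
              phen_volume_per_g = phen_volume_per_g,
              anth_volume_per_g = anth_volume_per_g)
  pos <- c("path_length", "eps_pod", "eps_gr", "eps_anth", "mw_anth",
           "v_rxn", "v_extract", "pigment_volume", "pigment_leaf_area",
           "phen_volume_per_g", "anth_volume_per_g")
  for (nm in pos) {
    if (!is.na(cfg[[nm]]) && cfg[[nm]] <= 0) {
      stop("assay_config: '", nm, "' must be > 0", call. = FALSE)
    }
  }
  structure(cfg, class = "assay_config")
}

# Structural traits -----------------------------------------------------------

#' Structural leaf traits from leaf geometry and mass
#'
#' `SLA = LA / LDM` (cm2 g-1), `LDMC = LDM / LFM` (g g-1),
#' `SLWC = (LFM - LDM) / LA` (g cm-2).
#'
#' @param la Leaf area (cm2).
#' @param lfm Leaf fresh mass (g).
#' @param ldm Leaf dry mass (g).
#' @return Data frame with columns SLA, LDMC, SLWC.
#' @export
derive_structural <- function(la, lfm, ldm) {
  if (any(la <= 0)) stop("leaf area must be > 0", call. = FALSE)
  if (any(ldm <= 0)) stop("leaf dry mass must be > 0", call. = FALSE)
  if (any(ldm > lfm)) stop("dry mass exceeds fresh mass", call. = FALSE)
  data.frame(SLA = la / ldm, LDMC = ldm / lfm, SLWC = (lfm - ldm) / la)
}

# Pigments --------------------------------------------------------------------

#' Photosynthetic pigment quantification from absorbance readings
#'
#' Applies the configured linear pigment equations to A665/A649/A480 to get
#' per-mL concentrations, scales by the extract volume and divides by the leaf
#' reference to express pigments per cm2 leaf area (default) or per g FW.
#'
#' @param a665,a649,a480 Absorbance readings (dimensionless, >= 0).
#' @param cfg An [assay_config()].
#' @param volume Extract volume (mL); defaults to `cfg$pigment_volume`.
#' @param leaf_ref Leaf area (cm2) or fresh mass (g) of the extracted tissue;
#'   defaults to `cfg$pigment_leaf_area`.
#' @return Data frame with Chl_a, Chl_b, Chl_tot, Chl_ab_ratio, Cars in
#'   ug per unit leaf reference; `Chl_ab_ratio` is `NA` (flagged by warning)
#'   where `Chl_b` is 0, and negative computed concentrations are flagged by
#'   warning (out-of-model readings) but returned as computed.
#' @export
quantify_pigments <- function(a665, a649, a480, cfg = assay_config(),
                              volume = cfg$pigment_volume,
                              leaf_ref = cfg$pigment_leaf_area) {
  stopifnot(all(a665 >= 0), all(a649 >= 0), all(a480 >= 0), leaf_ref > 0)
  pc <- cfg$pigment_coef
  chl_a <- pc$a[1] * a665 + pc$a[2] * a649          # ug mL-1
  chl_b <- pc$b[1] * a665 + pc$b[2] * a649
  cars <- (pc$cars[1] * a480 + pc$cars[2] * chl_a + pc$cars[3] * chl_b) /
    pc$cars[4]
  if (any(chl_a < 0 | chl_b < 0 | cars < 0)) {
    warning("negative computed pigment concentration (out-of-model reading)",
            call. = FALSE)
  }
  scale <- volume / leaf_ref
  ratio <- ifelse(chl_b == 0, NA_real_, chl_a / chl_b)
  if (anyNA(ratio)) {
    warning("Chl_b is zero: Chl a/b ratio undefined", call. = FALSE)
  }
  data.frame(Chl_a = chl_a * scale, Chl_b = chl_b * scale,
             Chl_tot = (chl_a + chl_b) * scale, Chl_ab_ratio = ratio,
             Cars = cars * scale)
}

# Standard curves -------------------------------------------------------------

#' Fit a colorimetric standard curve by ordinary least squares
#'
#' `absorbance = slope * concentration + intercept`, fitted on >= 3
#' calibration points with >= 2 distinct concentrations.
#'
#' @param concentration,absorbance Calibration points.
#' @return A `standard_curve` list with slope, intercept, r_squared and the
#'   calibration points.
#' @export
fit_standard_curve <- function(concentration, absorbance) {
  stopifnot(length(concentration) == length(absorbance))
  if (length(concentration) < 3) {
    stop("standard curve needs at least 3 calibration points", call. = FALSE)
  }
  if (length(unique(concentration)) < 2) {
    stop("standard curve needs at least 2 distinct concentrations",
         call. = FALSE)
  }
  sxx <- sum((concentration - mean(concentration))^2)
  sxy <- sum((concentration - mean(concentration)) *
               (absorbance - mean(absorbance)))
  slope <- sxy / sxx
  intercept <- mean(absorbance) - slope * mean(concentration)
  fitted <- slope * concentration + intercept
  sst <- sum((absorbance - mean(absorbance))^2)
  r2 <- if (sst == 0) 1 else 1 - sum((absorbance - fitted)^2) / sst
  structure(list(slope = slope, intercept = intercept, r_squared = r2,
                 points = data.frame(concentration = concentration,
                                     absorbance = absorbance)),
            class = "standard_curve")
}

#' @export
print.standard_curve <- function(x, ...) {
  cat(sprintf("Standard curve: A = %.6g * conc + %.6g (R^2 = %.4f, %d points)\n",
              x$slope, x$intercept, x$r_squared, nrow(x$points)))
  invisible(x)
}

#' Inverse prediction from a standard curve
#'
#' @param curve A [fit_standard_curve()] result.
#' @param absorbance Absorbance reading(s); vectors are interpreted as
#'   technical replicates and averaged before inversion.
#' @return Predicted concentration (same unit as the calibration points).
#' @export
predict_concentration <- function(curve, absorbance) {
  stopifnot(inherits(curve, "standard_curve"))
  if (curve$slope == 0) stop("standard curve slope is zero", call. = FALSE)
  (mean(absorbance) - curve$intercept) / curve$slope
}

#' Soluble protein by the Bradford method
#'
#' Inverse prediction of protein concentration from a BSA calibration curve;
#' triplicate readings are averaged before inversion.
#'
#' @param a595 Absorbance reading(s) at 595 nm.
#' @param curve BSA `standard_curve`.
#' @return Protein concentration (mg mL-1). Negative predictions are flagged
#'   by warning.
#' @export
protein_bradford <- function(a595, curve) {
  conc <- predict_concentration(curve, a595)
  if (any(conc < 0)) {
    warning("negative predicted protein concentration", call. = FALSE)
  }
  conc
}

# Enzyme kinetics -------------------------------------------------------------

#' Specific enzyme activity from kinetic absorbance change
#'
#' Beer-Lambert conversion of an absorbance rate into a reaction rate:
#' `rate (mM min-1) = dA / (eps * path)`; scaled by reaction over extract
#' volume to umol min-1 per mL extract; divided by the soluble-protein
#' concentration of the extract to give the specific activity
#' (umol min-1 mg-1 protein). `dA_per_min` is the magnitude of the absorbance
#' change (increase at 430 nm for POD, decrease at 340 nm for GR).
#'
#' @param dA_per_min Absorbance change per minute (>= 0).
#' @param protein Soluble protein of the extract (mg mL-1, > 0).
#' @param which `"POD"` or `"GR"` (selects the extinction coefficient).
#' @param cfg An [assay_config()].
#' @return Specific activity (umol min-1 mg-1 protein).
#' @export
enzyme_specific_activity <- function(dA_per_min, protein,
                                     which = c("POD", "GR"),
                                     cfg = assay_config()) {
  which <- match.arg(which)
  if (any(dA_per_min < 0)) {
    stop("dA_per_min is a magnitude and must be >= 0", call. = FALSE)
  }
  if (any(protein <= 0)) stop("protein concentration must be > 0", call. = FALSE)
  eps <- if (which == "POD") cfg$eps_pod else cfg$eps_gr
  if (is.null(eps) || is.null(cfg$path_length)) {
    stop("extinction coefficient / path length not configured", call. = FALSE)
  }
  rate_mM <- dA_per_min / (eps * cfg$path_length)        # mM min-1 in reaction
  per_ml_extract <- rate_mM * cfg$v_rxn / cfg$v_extract  # umol min-1 mL-1
  per_ml_extract / protein
}

# Non-enzymatic antioxidants --------------------------------------------------

#' Total phenolics (Folin-Ciocalteu, gallic-acid equivalents)
#'
#' Inverse prediction of the gallic-acid-equivalent concentration from the
#' 724 nm absorbance, scaled by the pooled extract volume per g fresh weight.
#'
#' @param a724 Absorbance at 724 nm (replicates averaged).
#' @param curve Gallic-acid `standard_curve` (mg mL-1 vs absorbance).
#' @param volume_per_g Total extract volume per g FW (mL g-1).
#' @param dilution Assay dilution factor applied to the extract.
#' @return PHEN (mg GAE g-1 FW).
#' @export
total_phenolics <- function(a724, curve, volume_per_g = 22, dilution = 1) {
  stopifnot(volume_per_g > 0, dilution > 0)
  conc <- predict_concentration(curve, a724) * dilution
  if (any(conc < 0)) warning("negative predicted phenolic concentration",
                             call. = FALSE)
  conc * volume_per_g
}

#' Total anthocyanins (cyanidin-3-glucoside equivalents)
#'
#' Corrected absorbance `A_corr = A530 - 0.24 * A653`; molar concentration by
#' Beer-Lambert `A_corr / (eps * path)`; mass concentration
#' `molar * MW * 1e6` (ug mL-1); scaled by the extract volume per g FW.
#' A negative corrected absorbance (plausible at very low pigment with a noisy
#' A653) is clamped to 0 with a warning.
#'
#' @param a530,a653 Absorbance readings (>= 0).
#' @param cfg An [assay_config()].
#' @param volume_per_g Extract volume per g FW (mL g-1).
#' @return ANTH (ug cyanidin-3-glucoside eq. g-1 FW).
#' @export
total_anthocyanins <- function(a530, a653, cfg = assay_config(),
                               volume_per_g = cfg$anth_volume_per_g) {
  stopifnot(all(a530 >= 0), all(a653 >= 0), volume_per_g > 0)
  a_corr <- a530 - cfg$anth_correction * a653
  if (any(a_corr < 0)) {
    warning("negative corrected anthocyanin absorbance clamped to 0",
            call. = FALSE)
    a_corr <- pmax(a_corr, 0)
  }
  molar <- a_corr / (cfg$eps_anth * cfg$path_length)   # mol L-1
  ug_ml <- molar * cfg$mw_anth * 1000                  # g L-1 = mg mL-1 -> ug mL-1
  ug_ml * volume_per_g
}
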