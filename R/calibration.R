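#' Fit a linear fluorescence standard curve
#'
#' Ordinary least squares of intensity against concentration (or surface
#' density). Two-point curves fit exactly (r^2 = 1 by construction) and are
#' flagged `low_n`.
#'
#' @param points data frame whose first column is the abscissa (concentration
#'   or density) and second column the intensity, or a two-column matrix.
#' @param through_origin force a zero intercept.
#' @return A list of class `standard_curve`: `slope`, `intercept`, `r2`,
#'   `n_points`, `x_max`, `low_n`.
#' @export
fit_standard <- function(points, through_origin = FALSE) {
  points <- as.data.frame(points)
  x <- points[[1]]; y <- points[[2]]
  if (length(unique(x)) < 2) stop("at least 2 distinct x values are required")
  fit <- if (through_origin) stats::lm(y ~ x - 1) else stats::lm(y ~ x)
  co <- stats::coef(fit)
  r2 <- suppressWarnings(summary(fit)$r.squared)
  structure(list(slope = unname(co[["x"]]),
                 intercept = if (through_origin) 0 else unname(co[["(Intercept)"]]),
                 r2 = r2, n_points = length(x), x_max = max(x),
                 low_n = length(x) < 3),
            class = "standard_curve")
}

#' Brightness correction factor F
#'
#' `F = I_labeled_protein / I_labeled_SUV`: the ratio of the solution standard
#' curve slopes of the labeled protein and of the fluorescent reference lipid,
#' capturing the relative per-molecule brightness of (and instrument
#' sensitivity for) the two fluorophores. Dividing protein fluorescence by F
#' expresses it on the lipid-standard intensity scale.
#'
#' @param protein_curve,dye_curve `standard_curve` objects with positive
#'   slopes.
#' @return The dimensionless correction factor.
#' @export
correction_factor <- function(protein_curve, dye_curve) {
  if (protein_curve$slope <= 0 || dye_curve$slope <= 0)
    stop("standard curve slopes must be positive")
  protein_curve$slope / dye_curve$slope
}

#' Convert a lipid mole fraction to surface density
#'
#' `density = fraction x leaflets x (1e8 A^2/um^2 / headgroup_area)`: with the
#' default 69 A^2 headgroup and both leaflets of the bilayer counted, 0.4 mol%
#' fluorescent lipid corresponds to about 1.16e4 molecules/um^2 and 0.05 mol%
#' to about 1.45e3 molecules/um^2.
#'
#' @param fraction mole fraction of the fluorescent lipid, in `[0, 1]`.
#' @param headgroup_area lipid headgroup area in A^2.
#' @param leaflets number of leaflets contributing fluorescence (2 for a
#'   supported bilayer imaged in epifluorescence or TIRF).
#' @return Surface density in molecules/um^2.
#' @examples
#' molpercent_to_density(0.004)   # 0.4 mol%
#' @export
molpercent_to_density <- function(fraction, headgroup_area = 69, leaflets = 2) {
  if (any(fraction < 0 | fraction > 1)) stop("fraction must be in [0, 1]")
  if (headgroup_area <= 0) stop("headgroup_area must be positive")
  fraction * leaflets * 1e8 / headgroup_area
}

#' Assemble a density calibration
#'
#' Bundles the correction factor F, the bilayer standard curve (intensity vs
#' molecules/um^2) and the labeled fraction of the protein into a calibration
#' object for [intensity_to_density()]. Labeling fractions above 60% are
#' outside the verified linear range of fluorophore response and trigger a
#' warning; quantitative work used 15% or less.
#'
#' @param F correction factor from [correction_factor()].
#' @param bilayer_curve `standard_curve` of bilayer intensity vs density.
#' @param labeled_fraction fraction of protein molecules carrying the
#'   fluorophore, in `(0, 1]`.
#' @param headgroup_area lipid headgroup area (A^2), carried for provenance.
#' @return A list of class `density_calibration`.
#' @export
density_calibration <- function(F, bilayer_curve, labeled_fraction = 1,
                                headgroup_area = 69) {
  if (F <= 0) stop("F must be positive")
  if (!inherits(bilayer_curve, "standard_curve"))
    stop("bilayer_curve must be a standard_curve")
  if (labeled_fraction <= 0 || labeled_fraction > 1)
    stop("labeled_fraction must be in (0, 1]")
  if (labeled_fraction > 0.6)
    warning("labeled_fraction above 0.6 exceeds the verified linear range")
  structure(list(F = F, bilayer_curve = bilayer_curve,
                 labeled_fraction = labeled_fraction,
                 headgroup_area = headgroup_area),
            class = "density_calibration")
}

#' Convert fluorescence intensity to absolute surface density
#'
#' Divides the measured intensity by the correction factor F, inverts the
#' bilayer standard curve to obtain the density of labeled molecules, and
#' divides by the labeled fraction to report total (labeled plus unlabeled)
#' molecules per um^2. Intensities more than 1.5x the largest bilayer standard
#' are refused (extrapolation beyond the verified linear range); negative
#' densities after inversion signal background mis-subtraction and raise an
#' error.
#'
#' @param I measured intensity (counts), background-corrected.
#' @param cal a [density_calibration()].
#' @return Surface density in molecules/um^2.
#' @export
intensity_to_density <- function(I, cal) {
  bc <- cal$bilayer_curve
  i_scaled <- I / cal$F
  i_max <- bc$slope * bc$x_max + bc$intercept
  if (any(i_scaled > 1.5 * i_max))
    stop("intensity beyond 1.5x the largest standard: refusing to extrapolate")
  d <- (i_scaled - bc$intercept) / bc$slope
  if (any(d < 0))
    stop("negative density after curve inversion: check background subtraction")
  d / cal$labeled_fraction
}

#' Predict intensity from surface density
#'
#' Inverse of [intensity_to_density()], used for round-trip validation:
#' `I = (density x labeled_fraction x slope + intercept) x F`.
#'
#' @param density total surface density (molecules/um^2).
#' @param cal a [density_calibration()].
#' @return Predicted intensity (counts).
#' @export
density_to_intensity <- function(density, cal) {
  bc <- cal$bilayer_curve
  (density * cal$labeled_fraction * bc$slope + bc$intercept) * cal$F
}

#' Build a density calibration from a calibration dataset
#'
#' Fits the three standards of a [gen_calibration()] dataset (or any list with
#' `dye`, `protein`, `bilayer` data frames) and assembles the
#' [density_calibration()].
#'
#' @param dataset a `calibration_dataset`.
#' @param labeled_fraction see [density_calibration()].
#' @return A `density_calibration`; the fitted standard curves are attached as
#'   attribute `curves`.
#' @export
build_calibration <- function(dataset, labeled_fraction = 1) {
  dye <- fit_standard(dataset$dye)
  protein <- fit_standard(dataset$protein)
  bilayer <- fit_standard(dataset$bilayer)
  cal <- density_calibration(correction_factor(protein, dye), bilayer,
                             labeled_fraction = labeled_fraction)
  attr(cal, "curves") <- list(dye = dye, protein = protein, bilayer = bilayer)
  cal
}
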