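#' Tissue specification for the synthetic phantom
#'
#' A tissue is described by its relative proton density (signal at TE = 0)
#' and transverse relaxation time T2. These two numbers fully determine the
#' noise-free spin-echo signal \eqn{S(TE) = \rho \exp(-TE/T_2)} at long TR.
#'
#' @param label Integer label code (> 0; 0 is reserved for background).
#' @param name Tissue name.
#' @param proton_density Relative signal at TE = 0 (unitless, >= 0).
#' @param t2 Transverse relaxation time in ms (> 0).
#' @param volume_fraction_hint Optional expected volume fraction in `[0, 1]`.
#' @return An object of class `tissue_spec`.
#' @examples
#' tissue_spec(2, "posterior_muscle", 1, 24.83)
#' @export
tissue_spec <- function(label, name, proton_density, t2,
                        volume_fraction_hint = NA_real_) {
  stopifnot(length(label) == 1L, label == as.integer(label), label >= 0)
  if (!is.numeric(t2) || length(t2) != 1L || !is.finite(t2) || t2 <= 0)
    stop("t2 must be a single positive number (ms)")
  if (!is.numeric(proton_density) || proton_density < 0)
    stop("proton_density must be >= 0")
  if (!is.na(volume_fraction_hint) &&
      (volume_fraction_hint < 0 || volume_fraction_hint > 1))
    stop("volume_fraction_hint must lie in [0, 1]")
  structure(
    list(label = as.integer(label), name = as.character(name),
         proton_density = proton_density, t2 = t2,
         volume_fraction_hint = volume_fraction_hint),
    class = "tissue_spec")
}

#' Default hindlimb tissue set
#'
#' Anterior and posterior compartment muscle, a hyperintense lesion tissue,
#' and cortical bone. Muscle T2 defaults to the healthy wild-type value;
#' lesion T2 is set well above the 27 ms hyperintensity cutoff so that
#' lesion pixels are separable on the T2 map.
#'
#' @param muscle_t2 Muscle T2 in ms applied to both compartments.
#' @param lesion_t2 Lesion T2 in ms (inflammation/edema-like, > 27 ms).
#' @param bone_pd,bone_t2 Proton density and T2 of bone.
#' @return List of [tissue_spec()] objects covering labels 1--4.
#' @export
default_tissues <- function(muscle_t2 = 24.83, lesion_t2 = 40,
                            bone_pd = 0.1, bone_t2 = 8) {
  list(
    tissue_spec(1L, "anterior_muscle", 1, muscle_t2),
    tissue_spec(2L, "posterior_muscle", 1, muscle_t2),
    tissue_spec(3L, "lesion", 1, lesion_t2),
    tissue_spec(4L, "bone", bone_pd, bone_t2)
  )
}

#' Acquisition specification
#'
#' Holds pulse-sequence timing and geometry. Voxel size is derived as
#' FOV / matrix per in-plane axis.
#'
#' @param te Echo time(s) in ms, strictly increasing.
#' @param tr Repetition time in ms.
#' @param tm Mixing time in ms (STEAM spectroscopy only).
#' @param flip_angle Flip angle in degrees.
#' @param fov Field of view in mm per axis.
#' @param matrix_size Acquisition matrix in voxels per axis.
#' @param slice_thickness Slice thickness in mm (2D multislice only).
#' @param n_averages Number of signal averages.
#' @return An object of class `acquisition_spec`.
#' @export
acquisition_spec <- function(te, tr, tm = NA_real_, flip_angle = 90,
                             fov = NULL, matrix_size = NULL,
                             slice_thickness = NA_real_, n_averages = 1L) {
  te <- as.numeric(te)
  if (any(te <= 0) || is.unsorted(te, strictly = TRUE))
    stop("te must be strictly increasing and positive (ms)")
  if (!is.null(fov) && any(fov <= 0)) stop("fov must be strictly positive")
  if (!is.null(matrix_size) && any(matrix_size <= 0))
    stop("matrix_size must be strictly positive")
  structure(
    list(te = te, tr = tr, tm = tm, flip_angle = flip_angle,
         fov = fov, matrix_size = matrix_size,
         slice_thickness = slice_thickness, n_averages = n_averages),
    class = "acquisition_spec")
}

#' Dual-echo spin-echo protocol (TE 14/40 ms, TR 2000 ms)
#'
#' The T2-weighted multislice single-spin-echo imaging protocol: TR 2000 ms,
#' TE 14 and 40 ms, 1 mm slices, 128 x 256 acquisition matrix, two averages.
#' @param fov In-plane field of view in mm (study range 10--20 mm).
#' @return An `acquisition_spec`.
#' @export
acq_dual_echo <- function(fov = c(15, 15)) {
  acquisition_spec(te = c(14, 40), tr = 2000, fov = fov,
                   matrix_size = c(128L, 256L), slice_thickness = 1,
                   n_averages = 2L)
}

#' STEAM single-voxel relaxometry protocol (29 echo times)
#'
#' Stimulated-echo acquisition mode protocol for localized water
#' relaxometry: TR 9000 ms, TM 20 ms, 4 phase-cycled averages and 29
#' non-linearly spaced echo times from 5 to 200 ms.
#' @return An `acquisition_spec` whose `te` field is [steam_te_list()].
#' @export
acq_steam <- function() {
  acquisition_spec(te = steam_te_list(), tr = 9000, tm = 20, n_averages = 4L)
}

#' The 29 STEAM echo times (ms)
#' @return Numeric vector of 29 echo times in ms.
#' @export
steam_te_list <- function() {
  c(5, 6, 7, 8, 9, 10, 15, 20, 25, 30, 35, 40, 45, 50, 55, 60, 65, 70,
    80, 90, 100, 110, 120, 130, 140, 150, 160, 170, 200)
}

#' 3D gradient-echo (T1-weighted) volumetric protocol
#'
#' Geometry used for compartment volumetry: 15 x 15 x 15 mm^3 FOV on a
#' 256 x 192 x 96 matrix, TR/TE 50/7 ms, flip angle 40 degrees.
#' @return An `acquisition_spec`.
#' @export
acq_gre3d <- function() {
  acquisition_spec(te = 7, tr = 50, flip_angle = 40,
                   fov = c(15, 15, 15), matrix_size = c(256L, 192L, 96L),
                   n_averages = 2L)
}

# default hindlimb cross-section: two elliptical muscle compartments and a
# small circular bone, specified in mm within the in-plane FOV. Shapes are
# schematic; only the label bookkeeping and voxel arithmetic matter.
default_compartments <- function(fov = c(15, 15)) {
  cx <- fov[1] / 2
  list(
    list(label = 1L, name = "anterior", center = c(cx, 0.31 * fov[2]),
         semi_axes = c(0.18, 0.12) * fov[1]),
    list(label = 2L, name = "posterior", center = c(cx, 0.69 * fov[2]),
         semi_axes = c(0.21, 0.16) * fov[1]),
    list(label = 4L, name = "bone", center = c(cx, 0.485 * fov[2]),
         semi_axes = c(0.035, 0.035) * fov[1])
  )
}

#' Phantom specification for the synthetic hindlimb
#'
#' Describes a stack of axial slices containing elliptical anterior and
#' posterior muscle compartments plus bone, the tissue properties to paint
#' into them, the fraction of muscle voxels replaced by hyperintense lesion
#' tissue, and the Rician noise level anchored to the muscle-ROI SNR at
#' TE = 14 ms (33:1 in the emulated protocol).
#'
#' @param grid Voxel grid dimensions (x, y, slices). Defaults to the
#'   dual-echo acquisition matrix of 128 x 256 with 10 slices of 1 mm.
#' @param fov In-plane field of view in mm.
#' @param slice_thickness Slice thickness in mm.
#' @param compartments List of elliptical regions (label, name, center mm,
#'   semi_axes mm); see `default_compartments`.
#' @param tissues List of [tissue_spec()] covering every non-background label.
#' @param lesion_fraction Fraction of muscle voxels replaced by lesion
#'   tissue, in `[0, 1]`.
#' @param snr_te14 Muscle-ROI signal-to-noise ratio at TE = 14 ms. `Inf`
#'   (or 0) means noise-free.
#' @param lesion_cluster_radius In-plane clustering radius in mm for lesion
#'   placement; 0 (default) scatters lesion voxels independently.
#' @param seed Integer seed making phantom generation reproducible.
#' @return An object of class `phantom_spec`.
#' @examples
#' spec <- phantom_spec(grid = c(32, 32, 6), lesion_fraction = 0.2)
#' @export
phantom_spec <- function(grid = c(128L, 256L, 10L), fov = c(15, 15),
                         slice_thickness = 1,
                         compartments = default_compartments(fov),
                         tissues = default_tissues(),
                         lesion_fraction = 0, snr_te14 = 33,
                         lesion_cluster_radius = 0, seed = 1L) {
  grid <- as.integer(grid)
  stopifnot(length(grid) == 3L, all(grid >= 1L), length(fov) == 2L,
            all(fov > 0), slice_thickness > 0)
  if (lesion_fraction < 0 || lesion_fraction > 1)
    stop("lesion_fraction must lie in [0, 1]")
  labs <- vapply(tissues, function(t) t$label, integer(1))
  if (anyDuplicated(labs)) stop("tissue labels must be unique")
  structure(
    list(grid = grid, fov = fov, slice_thickness = slice_thickness,
         voxel_size = c(fov / grid[1:2], slice_thickness),
         compartments = compartments, tissues = tissues,
         lesion_fraction = lesion_fraction, snr_te14 = snr_te14,
         lesion_cluster_radius = lesion_cluster_radius,
         seed = as.integer(seed)),
    class = "phantom_spec")
}

#' Cohort group specification
#'
#' Per-group distributional parameters from which the generator draws
#' per-animal scalars (body weight, muscle T2, lesion burden, Mac-1 field
#' counts, qPCR Ct values). All draws are normal, truncated at 0.
#'
#' @param group Group name (e.g. "WT", "DyW", "DyW-Los").
#' @param n Number of animals (>= 1).
#' @param weight_mean,weight_sd Body weight distribution in g.
#' @param muscle_t2_mean,muscle_t2_sd Lesion-free muscle T2 distribution
#'   in ms (the "muscle-only" value after hyperintense-pixel exclusion).
#' @param lesion_fraction_mean Mean fraction of muscle voxels that are
#'   hyperintense lesion.
#' @param mac1_mean,mac1_sd Mac-1-positive cells per 40x field.
#' @param ct_params Named list of per-gene `c(mean, sd)` qPCR Ct parameters.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(group, n, weight_mean, weight_sd,
                        muscle_t2_mean, muscle_t2_sd,
                        lesion_fraction_mean = 0,
                        mac1_mean = 0, mac1_sd = 0,
                        ct_params = list()) {
  stopifnot(n >= 1, weight_sd >= 0, muscle_t2_sd >= 0, mac1_sd >= 0,
            lesion_fraction_mean >= 0, lesion_fraction_mean <= 1)
  if (length(ct_params) && any(vapply(ct_params, function(p) p[2], 1) < 0))
    stop("Ct standard deviations must be >= 0")
  structure(
    list(group = as.character(group), n = as.integer(n),
         weight_mean = weight_mean, weight_sd = weight_sd,
         muscle_t2_mean = muscle_t2_mean, muscle_t2_sd = muscle_t2_sd,
         lesion_fraction_mean = lesion_fraction_mean,
         mac1_mean = mac1_mean, mac1_sd = mac1_sd,
         ct_params = ct_params),
    class = "cohort_spec")
}

#' Lesion fraction implied by whole-compartment and lesion-free means
#'
#' On a per-pixel T2 map a compartment containing a fraction f of lesion
#' pixels has mean T2 `(1 - f) * muscle + f * lesion`, so
#' `f = (whole - muscle) / (lesion - muscle)`.
#'
#' @param whole_t2 Whole-compartment mean T2 (ms).
#' @param muscle_t2 Lesion-free muscle T2 (ms).
#' @param lesion_t2 Lesion T2 (ms).
#' @return Lesion fraction in `[0, 1]`.
#' @export
derive_lesion_fraction <- function(whole_t2, muscle_t2, lesion_t2 = 40) {
  f <- (whole_t2 - muscle_t2) / (lesion_t2 - muscle_t2)
  if (f < -1e-9 || f > 1 + 1e-9)
    stop("inconsistent T2 triple: implied lesion fraction outside [0, 1]")
  min(max(f, 0), 1)
}

#' Default study cohorts (wild-type, dystrophic, Losartan-treated)
#'
#' The three groups of the emulated 7-week DyW study with their reported
#' sample sizes, body weights, muscle T2 distributions and Mac-1 counts:
#' WT (n = 6, 18.05 +/- 2.91 g, T2 24.83 +/- 0.66 ms, Mac-1 3.915),
#' DyW (n = 8, 10.11 +/- 3.39 g, lesion-free muscle T2 21.20 +/- 0.68 ms,
#' Mac-1 19.33) and DyW-Los (n = 4, 10.35 +/- 1.85 g, 23.91 +/- 0.84 ms,
#' Mac-1 8.585). Dystrophic lesion fractions are derived from the gap
#' between whole-compartment and lesion-free means via
#' [derive_lesion_fraction()]. Mac-1 field-count SDs and Ct parameters are
#' not reported group statistics; defaults are realistic choices documented
#' in the methods vignette.
#'
#' @param lesion_t2 Lesion T2 (ms) used to derive lesion fractions.
#' @return Named list of three [cohort_spec()] objects.
#' @export
study_cohorts <- function(lesion_t2 = 40) {
  ct_wt <- list(col1a = c(26.0, 0.4), r18s = c(9.5, 0.3))
  ct_dyw <- list(col1a = c(23.0, 0.4), r18s = c(9.5, 0.3))
  ct_los <- list(col1a = c(25.8, 0.4), r18s = c(9.5, 0.3))
  list(
    WT = cohort_spec("WT", 6, 18.05, 2.91, 24.83, 0.66,
                     lesion_fraction_mean = 0,
                     mac1_mean = 3.915, mac1_sd = 1.2, ct_params = ct_wt),
    DyW = cohort_spec("DyW", 8, 10.11, 3.39, 21.20, 0.68,
                      lesion_fraction_mean =
                        derive_lesion_fraction(27.10, 21.20, lesion_t2),
                      mac1_mean = 19.33, mac1_sd = 4.0, ct_params = ct_dyw),
    `DyW-Los` = cohort_spec("DyW-Los", 4, 10.35, 1.85, 23.91, 0.84,
                            lesion_fraction_mean =
                              derive_lesion_fraction(23.92, 23.91, lesion_t2),
                            mac1_mean = 8.585, mac1_sd = 2.5,
                            ct_params = ct_los)
  )
}
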