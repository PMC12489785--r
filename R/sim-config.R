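#' Configuration for the synthetic iEEG study generator
#'
#' Bundles every tunable of the synthetic-data module: electrode geometry,
#' boundary-mask shape, planted network densities and overlap, single pulse
#' electrical stimulation (SPES) parameters, and the multi-patient cohort
#' parameters for the multilevel-model stage. Defaults reproduce the study
#' conditions the pipeline is designed for: 10 mm pitch subdural grids (ECoG)
#' or 3.5/5 mm pitch depth shafts (sEEG), 2048 Hz recordings with ten
#' monophasic pulses per stimulus pair at 0.2 Hz, structural/effective
#' densities 0.20/0.23 with overlap chosen so the planted Jaccard index is
#' close to 0.25, and a 13-patient cohort with standardized fixed effects
#' 0.13 (effective degree) and -0.13 (node proximity) and intraclass
#' correlation 0.37.
#'
#' @param modality `"ECoG"` (subdural grid) or `"sEEG"` (depth shafts).
#' @param grid_dim Integer c(rows, cols) for ECoG grids.
#' @param grid_pitch_mm Inter-contact distance on the grid, mm.
#' @param n_shafts,contacts_per_shaft sEEG shaft geometry.
#' @param shaft_pitch_mm Within-shaft inter-contact distance, mm (3.5 or 5).
#' @param voxel_size_mm Isotropic voxel edge of the boundary mask, mm.
#' @param d_sc,d_ec Target densities of the planted structural and effective
#'   networks, in \[0, 1\].
#' @param overlap Target overlap fraction: the planted shared-edge count is
#'   `round(overlap * min(edge counts))`.
#' @param fs Sampling frequency, Hz (>= 512).
#' @param n_pulses Pulses per stimulus pair (10).
#' @param inter_pulse_s Inter-pulse interval, s (5, i.e. 0.2 Hz).
#' @param amplitude_uv Peak amplitude of the planted evoked deflection, uV.
#' @param latency_ms Latency of the deflection peak after the stimulus, ms.
#' @param noise_sd_uv Gaussian noise SD per sample, uV. Zero gives a
#'   noiseless recording for exact round-trip checks.
#' @param soz_fraction Fraction of contacts flagged as seizure onset zone.
#' @param n_patients,nodes_per_patient Cohort dimensions for
#'   [simulate_cohort()].
#' @param beta_ecd,beta_np Fixed effects (standardized scale) of effective
#'   degree and node proximity on structural degree.
#' @param intercept_sd,residual_sd Between-patient intercept SD and residual
#'   SD; the generative intraclass correlation is
#'   `intercept_sd^2 / (intercept_sd^2 + residual_sd^2)`.
#' @param n_soz_undetermined Number of cohort patients whose SOZ labels are
#'   missing (not determined), as happens when seizure onset is diffuse.
#' @param seed Integer seed; all generator randomness flows from it.
#' @return A list of class `sim_config`.
#' @examples
#' cfg <- sim_config("ECoG", grid_dim = c(4, 4), fs = 512)
#' cfg$n_contacts
#' @export
sim_config <- function(modality = c("sEEG", "ECoG"),
                       grid_dim = c(4, 8),
                       grid_pitch_mm = 10,
                       n_shafts = 8,
                       contacts_per_shaft = 8,
                       shaft_pitch_mm = 3.5,
                       voxel_size_mm = 1,
                       d_sc = 0.20,
                       d_ec = 0.23,
                       overlap = 0.43,
                       fs = 2048,
                       n_pulses = 10,
                       inter_pulse_s = 5,
                       amplitude_uv = 200,
                       latency_ms = 30,
                       noise_sd_uv = 10,
                       soz_fraction = 0.18,
                       n_patients = 13,
                       nodes_per_patient = 66,
                       beta_ecd = 0.13,
                       beta_np = -0.13,
                       intercept_sd = sqrt(0.37),
                       residual_sd = sqrt(0.63),
                       n_soz_undetermined = 2,
                       seed = 1L) {
  modality <- match.arg(modality)
  if (modality == "ECoG") {
    stopifnot(length(grid_dim) == 2, all(grid_dim >= 1))
    n_contacts <- prod(grid_dim)
  } else {
    stopifnot(n_shafts >= 1, contacts_per_shaft >= 1)
    if (!shaft_pitch_mm %in% c(3.5, 5) ) {
      # other pitches are allowed but unusual; keep going
    }
    n_contacts <- n_shafts * contacts_per_shaft
  }
  # a single contact is a legal degenerate geometry; network stages require >= 2
  if (n_contacts < 1) stop("Geometry must yield at least 1 contact.", call. = FALSE)
  for (d in c(d_sc = d_sc, d_ec = d_ec, overlap = overlap)) {
    if (!is.finite(d) || d < 0 || d > 1) {
      stop("Densities and overlap must lie in [0, 1].", call. = FALSE)
    }
  }
  if (fs <= 0) stop("`fs` must be positive.", call. = FALSE)
  stopifnot(noise_sd_uv >= 0, amplitude_uv >= 0, n_pulses >= 1,
            inter_pulse_s > 0, latency_ms > 0, voxel_size_mm > 0,
            soz_fraction >= 0, soz_fraction <= 1,
            n_patients >= 1, nodes_per_patient >= 2,
            intercept_sd >= 0, residual_sd >= 0)
  structure(list(
    modality = modality,
    grid_dim = as.integer(grid_dim),
    grid_pitch_mm = grid_pitch_mm,
    n_shafts = as.integer(n_shafts),
    contacts_per_shaft = as.integer(contacts_per_shaft),
    shaft_pitch_mm = shaft_pitch_mm,
    n_contacts = as.integer(n_contacts),
    voxel_size_mm = voxel_size_mm,
    d_sc = d_sc, d_ec = d_ec, overlap = overlap,
    fs = fs, n_pulses = as.integer(n_pulses), inter_pulse_s = inter_pulse_s,
    amplitude_uv = amplitude_uv, latency_ms = latency_ms,
    noise_sd_uv = noise_sd_uv,
    soz_fraction = soz_fraction,
    n_patients = as.integer(n_patients),
    nodes_per_patient = as.integer(nodes_per_patient),
    beta_ecd = beta_ecd, beta_np = beta_np,
    intercept_sd = intercept_sd, residual_sd = residual_sd,
    n_soz_undetermined = as.integer(n_soz_undetermined),
    seed = as.integer(seed)
  ), class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  geom <- if (x$modality == "ECoG") {
    sprintf("%dx%d grid, %.1f mm pitch", x$grid_dim[1], x$grid_dim[2], x$grid_pitch_mm)
  } else {
    sprintf("%d shafts x %d contacts, %.1f mm pitch",
            x$n_shafts, x$contacts_per_shaft, x$shaft_pitch_mm)
  }
  cat(sprintf("<sim_config> %s (%s; %d contacts), fs %g Hz, d_SC %.2f, d_EC %.2f, overlap %.2f, seed %d\n",
              x$modality, geom, x$n_contacts, x$fs, x$d_sc, x$d_ec, x$overlap, x$seed))
  invisible(x)
}
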