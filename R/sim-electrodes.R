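#' Simulate electrode contact coordinates
#'
#' Generates labelled contact coordinates in scanner millimetre space for
#' either a coplanar subdural grid (ECoG, 10 mm pitch by default) or a set of
#' parallel depth shafts (sEEG, 3.5 or 5 mm within-shaft pitch). Coordinates
#' are purely geometric and therefore deterministic; the seizure onset zone
#' (SOZ) flags cover a contiguous block of contacts whose position is drawn
#' from the configuration seed.
#'
#' @param config A [sim_config()].
#' @return A tibble with one row per contact: `label`, `x`, `y`, `z` (mm),
#'   `modality`, `group` (grid row or shaft), `included`, `soz`.
#' @examples
#' simulate_electrodes(sim_config("ECoG", grid_dim = c(4, 4)))
#' @export
simulate_electrodes <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  origin <- c(30, 30, 30)  # keep all contacts well inside the mask volume
  if (config$modality == "ECoG") {
    rows <- config$grid_dim[1]; cols <- config$grid_dim[2]
    grid <- expand.grid(col = seq_len(cols), row = seq_len(rows))
    el <- tibble::tibble(
      label = sprintf("G%02d", seq_len(nrow(grid))),
      x = origin[1] + (grid$col - 1) * config$grid_pitch_mm,
      y = origin[2] + (grid$row - 1) * config$grid_pitch_mm,
      z = origin[3],
      modality = "ECoG",
      group = sprintf("row%d", grid$row)
    )
  } else {
    sh <- expand.grid(contact = seq_len(config$contacts_per_shaft),
                      shaft = seq_len(config$n_shafts))
    el <- tibble::tibble(
      label = sprintf("S%dC%02d", sh$shaft, sh$contact),
      x = origin[1] + (sh$contact - 1) * config$shaft_pitch_mm,
      y = origin[2] + (sh$shaft - 1) * 15,
      z = origin[3] + (sh$shaft - 1) * 2,
      modality = "sEEG",
      group = sprintf("shaft%d", sh$shaft)
    )
  }
  stopifnot(!anyDuplicated(el$label))
  n <- nrow(el)
  n_soz <- round(config$soz_fraction * n)
  soz <- rep(FALSE, n)
  if (n_soz > 0) {
    start <- withr::with_seed(config$seed, sample.int(n - n_soz + 1, 1))
    soz[seq(start, length.out = n_soz)] <- TRUE
  }
  el$included <- TRUE
  el$soz <- soz
  el
}

#' Adjacent stimulation pairs for a simulated electrode set
#'
#' SPES stimulates pairs of adjacent contacts. The generator uses disjoint
#' consecutive pairs within each shaft (sEEG) or grid row (ECoG): contacts
#' 1-2, 3-4, ... of each group. Disjoint pairs make the planted effective
#' network exactly recoverable under the bi-directional network construction
#' rule (edges are drawn from both contacts of a pair to every responding
#' channel).
#'
#' @param electrodes Electrode tibble from [simulate_electrodes()].
#' @return A tibble with columns `pair_id`, `anode`, `cathode`, `site`
#'   (label of the form `"A-B"`).
#' @export
stim_pairs <- function(electrodes) {
  grp <- split(electrodes$label, electrodes$group)
  # split() reorders groups alphabetically; restore first-appearance order
  grp <- grp[unique(electrodes$group)]
  pairs <- purrr::map(grp, function(labels) {
    k <- length(labels) %/% 2
    if (k == 0) return(NULL)
    tibble::tibble(anode = labels[2 * seq_len(k) - 1],
                   cathode = labels[2 * seq_len(k)])
  })
  out <- dplyr::bind_rows(pairs)
  if (nrow(out) == 0) stop("Geometry yields no adjacent stimulation pairs.", call. = FALSE)
  out$pair_id <- seq_len(nrow(out))
  out$site <- paste(out$anode, out$cathode, sep = "-")
  out[, c("pair_id", "anode", "cathode", "site")]
}
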