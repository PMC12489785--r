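#' Simulate a multi-patient node table with planted fixed effects
#'
#' Generates the long node table the multilevel-model stage consumes, with
#' known ground truth: for every node,
#' `sc_degree = beta_ecd * ec_degree + beta_np * proximity + u_patient + e`,
#' where `u_patient ~ N(0, intercept_sd^2)` and `e ~ N(0, residual_sd^2)`.
#' The continuous predictors (effective degree, node proximity) are drawn as
#' standard normal deviates, i.e. already on the standardized scale of the
#' planted coefficients. VEA and SOZ columns are generated with zero true
#' effect (null predictors); `n_soz_undetermined` patients get missing SOZ
#' labels, as happens when seizure onset is diffuse. The generative
#' intraclass correlation is `intercept_sd^2 / (intercept_sd^2 +
#' residual_sd^2)`; the ICC of an intercept-only fit is slightly smaller
#' because the planted fixed effects fold into the within-patient variance.
#'
#' @param config A [sim_config()] (cohort parameters and seed).
#' @return A tibble with `n_patients * nodes_per_patient` rows: `patient`,
#'   `label`, `sc_degree`, `ec_degree`, `proximity_mm`, `vea_mm3`, `soz`.
#' @examples
#' tab <- simulate_cohort(sim_config(n_patients = 4, nodes_per_patient = 30))
#' dplyr::count(tab, patient)
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (config$n_patients < 2) {
    stop("Cohort simulation requires at least 2 patients.", call. = FALSE)
  }
  n_pat <- config$n_patients
  n_node <- config$nodes_per_patient
  withr::with_seed(config$seed + 3L, {
    u <- stats::rnorm(n_pat, sd = config$intercept_sd)
    no_soz <- if (config$n_soz_undetermined > 0) {
      sample.int(n_pat, min(config$n_soz_undetermined, n_pat))
    } else integer(0)
    purrr::map_dfr(seq_len(n_pat), function(p) {
      ecd <- stats::rnorm(n_node)
      np <- stats::rnorm(n_node)
      e <- stats::rnorm(n_node, sd = config$residual_sd)
      soz <- stats::runif(n_node) < config$soz_fraction
      if (p %in% no_soz) soz <- rep(NA, n_node)
      tibble::tibble(
        patient = sprintf("pt%02d", p),
        label = sprintf("n%03d", seq_len(n_node)),
        sc_degree = config$beta_ecd * ecd + config$beta_np * np + u[p] + e,
        ec_degree = ecd,
        proximity_mm = np,
        vea_mm3 = stats::runif(n_node, 16, 64),
        soz = soz
      )
    })
  })
}
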