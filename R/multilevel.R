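#' Linear multilevel (random-intercept) models for node metrics
#'
#' Fits `outcome ~ predictors + (1 | patient)` by REML on the long node
#' table, pooling nodes across patients while a per-patient random intercept
#' absorbs between-patient differences in network size and overall
#' connectivity. By default the outcome and all continuous predictors are
#' z-scored over the pooled rows, so coefficients are standardized; binary
#' predictors (SOZ) stay on their 0/1 scale. Wald t statistics use residual
#' degrees of freedom `rows - fixed effects - patients` by default
#' (Satterthwaite via \pkg{lmerTest} is available), with matching 95%
#' confidence intervals. Variance components give the intraclass correlation
#' `sigma2_inter / (sigma2_inter + sigma2_intra)`; marginal and conditional
#' R^2 follow the Nakagawa variance decomposition.
#'
#' `fit_intercept_only()` fits the null model used to quantify the
#' dependency in the data through the ICC before any predictor enters.
#'
#' @param node_table Long node table ([node_metrics()] rows or
#'   [simulate_cohort()]); must contain `patient`, the outcome and the
#'   predictors. Rows with missing values in the used columns are dropped
#'   with a message.
#' @param outcome Outcome column (default `"sc_degree"`, the structural
#'   connectivity degree).
#' @param predictors Character vector of predictor columns.
#' @param standardize Z-score the outcome and continuous predictors over all
#'   pooled rows (default TRUE).
#' @param df_method `"residual"` (default) or `"satterthwaite"`.
#' @param conf_level Confidence level for the fixed-effect intervals.
#' @return An object of class `ml_fit`.
#' @export
fit_multilevel <- function(node_table, outcome = "sc_degree",
                           predictors = c("ec_degree", "proximity_mm"),
                           standardize = TRUE,
                           df_method = c("residual", "satterthwaite"),
                           conf_level = 0.95) {
  df_method <- match.arg(df_method)
  stopifnot("patient" %in% names(node_table),
            outcome %in% names(node_table),
            all(predictors %in% names(node_table)))
  used <- unique(c("patient", outcome, predictors))
  dat <- node_table[, used, drop = FALSE]
  n0 <- nrow(dat)
  dat <- dat[stats::complete.cases(dat), , drop = FALSE]
  if (nrow(dat) < n0) {
    message(sprintf("Dropped %d row(s) with missing values.", n0 - nrow(dat)))
  }
  if (length(unique(dat$patient)) < 2) {
    stop("Multilevel fit requires at least 2 patients.", call. = FALSE)
  }
  dat$patient <- factor(dat$patient)
  # binary/logical predictors keep their scale; continuous ones are z-scored
  zscore <- function(v) if (stats::sd(v) > 0) (v - mean(v)) / stats::sd(v) else v * 0
  is_binary <- function(v) is.logical(v) || all(v %in% c(0, 1))
  for (col in c(outcome, predictors)) {
    v <- dat[[col]]
    if (is.logical(v)) v <- as.numeric(v)
    if (standardize && !(col %in% predictors && is_binary(dat[[col]]))) v <- zscore(v)
    dat[[col]] <- v
  }
  rhs <- if (length(predictors) == 0) "1" else paste(predictors, collapse = " + ")
  fml <- stats::as.formula(sprintf("%s ~ %s + (1 | patient)", outcome, rhs))
  model <- lme4::lmer(fml, data = dat, REML = TRUE)
  singular <- lme4::isSingular(model)
  if (singular) message("Random-intercept fit is singular (between-patient variance ~ 0).")

  n <- nrow(dat)
  n_pat <- nlevels(dat$patient)
  beta <- lme4::fixef(model)
  se <- sqrt(diag(as.matrix(stats::vcov(model))))
  tval <- beta / se
  if (df_method == "satterthwaite") {
    if (!requireNamespace("lmerTest", quietly = TRUE)) {
      stop("Satterthwaite df requires the lmerTest package.", call. = FALSE)
    }
    mt <- lmerTest::as_lmerModLmerTest(model)
    smt <- stats::coef(summary(mt))
    dfree <- smt[, "df"]
  } else {
    dfree <- rep(n - length(beta) - n_pat, length(beta))
  }
  alpha <- 1 - conf_level
  crit <- stats::qt(1 - alpha / 2, dfree)
  fixed <- tibble::tibble(
    term = names(beta),
    estimate = unname(beta),
    std_error = unname(se),
    statistic = unname(tval),
    df = unname(dfree),
    p_value = unname(2 * stats::pt(abs(tval), dfree, lower.tail = FALSE)),
    conf_low = unname(beta - crit * se),
    conf_high = unname(beta + crit * se)
  )

  vc <- as.data.frame(lme4::VarCorr(model))
  sigma2_inter <- vc$vcov[vc$grp == "patient"]
  sigma2_intra <- vc$vcov[vc$grp == "Residual"]
  icc <- sigma2_inter / (sigma2_inter + sigma2_intra)
  # Nakagawa variance decomposition
  fe_pred <- as.vector(stats::model.matrix(model) %*% beta)
  var_f <- stats::var(fe_pred)
  denom <- var_f + sigma2_inter + sigma2_intra
  structure(list(
    model = model,
    outcome = outcome,
    predictors = predictors,
    fixed = fixed,
    sigma2_inter = sigma2_inter,
    sigma2_intra = sigma2_intra,
    icc = icc,
    r2_marginal = var_f / denom,
    r2_conditional = (var_f + sigma2_inter) / denom,
    n_obs = n,
    n_patients = n_pat,
    standardize = standardize,
    df_method = df_method,
    singular = singular,
    retained = predictors,
    path = NULL,
    all_eliminated = FALSE
  ), class = "ml_fit")
}

#' @rdname fit_multilevel
#' @export
fit_intercept_only <- function(node_table, outcome = "sc_degree",
                               standardize = TRUE,
                               df_method = c("residual", "satterthwaite")) {
  fit_multilevel(node_table, outcome = outcome, predictors = character(0),
                 standardize = standardize, df_method = match.arg(df_method))
}

#' Backward elimination of multilevel-model predictors
#'
#' Starting from the full predictor set, iteratively refits the
#' random-intercept model after dropping the least significant predictor
#' (largest p-value above `alpha`) until every retained predictor is
#' significant. Models that include the SOZ predictor are fit on the subset
#' of patients with determined SOZ labels (rows with missing SOZ drop); once
#' SOZ is eliminated, subsequent fits use all patients. If every predictor
#' is eliminated, the intercept-only model is returned with
#' `all_eliminated = TRUE`.
#'
#' @inheritParams fit_multilevel
#' @param alpha Retention threshold on the fixed-effect p-value (0.05).
#' @return An `ml_fit` for the final model, with the elimination `path`
#'   (step, predictors, dropped term, its p-value) recorded.
#' @export
backward_eliminate <- function(node_table, outcome = "sc_degree",
                               predictors = c("ec_degree", "proximity_mm",
                                              "vea_mm3", "soz"),
                               alpha = 0.05, standardize = TRUE,
                               df_method = c("residual", "satterthwaite")) {
  df_method <- match.arg(df_method)
  current <- predictors
  path <- list()
  step <- 0L
  repeat {
    step <- step + 1L
    fit <- suppressMessages(
      fit_multilevel(node_table, outcome, current,
                     standardize = standardize, df_method = df_method)
    )
    pv <- fit$fixed[fit$fixed$term %in% current, , drop = FALSE]
    worst <- pv[which.max(pv$p_value), , drop = FALSE]
    if (nrow(worst) == 0 || worst$p_value <= alpha) {
      path[[step]] <- tibble::tibble(step = step, predictors = paste(current, collapse = "+"),
                                     dropped = NA_character_, p_dropped = NA_real_)
      break
    }
    path[[step]] <- tibble::tibble(step = step, predictors = paste(current, collapse = "+"),
                                   dropped = worst$term, p_dropped = worst$p_value)
    current <- setdiff(current, worst$term)
    if (length(current) == 0) {
      fit <- suppressMessages(fit_intercept_only(node_table, outcome,
                                                 standardize = standardize,
                                                 df_method = df_method))
      fit$all_eliminated <- TRUE
      break
    }
  }
  fit$path <- dplyr::bind_rows(path)
  fit$retained <- if (fit$all_eliminated) character(0) else current
  fit
}

#' @export
print.ml_fit <- function(x, ...) {
  cat(sprintf("<ml_fit> %s ~ %s + (1 | patient); %d rows, %d patients\n",
              x$outcome,
              if (length(x$predictors) == 0) "1" else paste(x$predictors, collapse = " + "),
              x$n_obs, x$n_patients))
  cat(sprintf("  ICC %.3f; marginal R2 %.3f, conditional R2 %.3f\n",
              x$icc, x$r2_marginal, x$r2_conditional))
  print(as.data.frame(x$fixed), digits = 3, row.names = FALSE)
  invisible(x)
}

#' @rdname fit_multilevel
#' @param x,object An `ml_fit` object.
#' @param ... Unused.
#' @export
tidy.ml_fit <- function(x, ...) x$fixed

#' @rdname fit_multilevel
#' @export
glance.ml_fit <- function(x, ...) {
  tibble::tibble(
    n_obs = x$n_obs, n_patients = x$n_patients,
    sigma2_inter = x$sigma2_inter, sigma2_intra = x$sigma2_intra,
    icc = x$icc, r2_marginal = x$r2_marginal, r2_conditional = x$r2_conditional,
    singular = x$singular,
    retained = paste(x$retained, collapse = "+")
  )
}

#' @rdname fit_multilevel
#' @export
autoplot.ml_fit <- function(object, ...) {
  df <- object$fixed[object$fixed$term != "(Intercept)", , drop = FALSE]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$estimate, y = .data$term)) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::geom_pointrange(ggplot2::aes(xmin = .data$conf_low,
                                          xmax = .data$conf_high)) +
    ggplot2::labs(x = "standardized coefficient (95% CI)", y = NULL) +
    ggplot2::theme_minimal()
}
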