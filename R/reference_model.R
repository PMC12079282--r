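#' The published QSPR reference model for quinoline hydrogenation rates
#'
#' The final four-descriptor multiple linear regression selected by the
#' genetic algorithm, with its printed coefficients and standard errors:
#'
#' log10(r0) = -5.72 + 7.90 D1 + 1.72 D2 - 0.443 D3 + 0.161 D4
#'
#' D1 `I50_F_AB_nCi_2_M12_SS1_T_LGP[5]_s_MID` (softness up to the 5th bond),
#' D2 `GM_B_AB_nCi_2_M15_SS3_T_LGL[1-2]_e-s_MID` (electronegativity x
#' softness at 1-2 Angstrom), D3 `S_B_AB_nCi_2_M3_SS4_T_LGL[2-3]_m-h_MID`
#' (mass x hardness at 2-3 Angstrom), D4 `VC_Q_AB_nCi_2_M15_NS4_T_KA_m_MID`
#' (mass dispersion, no cutoff).
#'
#' @param response_sign +1 (default) models log10(r0); -1 models
#'   -log10(r0). The sign convention is configurable because larger r0
#'   means a faster reaction while some plots are drawn on the reciprocal
#'   logarithm.
#' @return object of class `"reference_model"` with `intercept`,
#'   `coefficients`, `se`, `descriptor_names`, `response_sign`, `version`.
#' @export
reference_model <- function(response_sign = 1) {
  if (!response_sign %in% c(-1, 1)) stop("response_sign must be +1 or -1")
  structure(
    list(
      intercept = -5.72,
      coefficients = c(D1 = 7.90, D2 = 1.72, D3 = -0.443, D4 = 0.161),
      se = c(intercept = 0.35, D1 = 0.97, D2 = 0.30, D3 = 0.071, D4 = 0.061),
      descriptor_names = c(
        D1 = "I50_F_AB_nCi_2_M12_SS1_T_LGP[5]_s_MID",
        D2 = "GM_B_AB_nCi_2_M15_SS3_T_LGL[1-2]_e-s_MID",
        D3 = "S_B_AB_nCi_2_M3_SS4_T_LGL[2-3]_m-h_MID",
        D4 = "VC_Q_AB_nCi_2_M15_NS4_T_KA_m_MID"
      ),
      response_sign = response_sign,
      version = "1.0"
    ),
    class = "reference_model"
  )
}

#' @export
print.reference_model <- function(x, ...) {
  cat("<reference_model> v", x$version, "\n", sep = "")
  cat(sprintf("  log10(r0) = %.2f %+.2f D1 %+.2f D2 %+.3f D3 %+.3f D4\n",
              x$intercept, x$coefficients[1], x$coefficients[2],
              x$coefficients[3], x$coefficients[4]))
  invisible(x)
}

#' Predict the initial hydrogenation rate from descriptor values
#'
#' @param model a [reference_model()].
#' @param D numeric vector or 4-column matrix of descriptor values
#'   (D1..D4).
#' @return data frame with `log_response` and `r0` (M s^-1,
#'   `10^(response_sign * log_response)`).
#' @export
predict_r0 <- function(model = reference_model(), D) {
  stopifnot(inherits(model, "reference_model"))
  if (is.null(dim(D))) D <- matrix(D, nrow = 1L)
  D <- as.matrix(D)
  if (ncol(D) != 4L) stop("need 4 descriptor values per candidate")
  if (any(!is.finite(D))) stop("descriptor values must be finite")
  lr <- model$intercept + as.numeric(D %*% model$coefficients)
  data.frame(log_response = lr, r0 = 10^(model$response_sign * lr))
}

#' Score screening candidates: prediction plus applicability domain
#'
#' Combines the reference-model prediction with a leverage check against a
#' training design and an LOF novelty score against a training projection.
#' Out-of-domain candidates are reported with `in_domain = FALSE`, not
#' suppressed.
#'
#' @param D matrix of candidate descriptor values (columns D1..D4).
#' @param fit an `mlr_fit` on the training descriptors (for leverage).
#' @param Z_train reference points for LOF (e.g. an NCA projection).
#' @param Z_query candidate points in the same space.
#' @param model a [reference_model()].
#' @param lof_threshold in-domain LOF bound (default 1.5).
#' @param k_neighbors LOF neighborhood size.
#' @param ids candidate identifiers.
#' @return data frame: id, log_response, r0, leverage, lof_score,
#'   in_domain.
#' @export
screen_candidates <- function(D, fit, Z_train, Z_query,
                              model = reference_model(),
                              lof_threshold = 1.5,
                              k_neighbors = min(10L, nrow(Z_train) - 1L),
                              ids = NULL) {
  D <- as.matrix(D)
  pred <- predict_r0(model, D)
  wr <- williams_report(fit, X_query = D)
  lof <- lof_scores(Z_train, Z_query, k_neighbors = k_neighbors)
  if (is.null(ids)) ids <- paste0("cand", seq_len(nrow(D)))
  data.frame(
    id = ids,
    log_response = pred$log_response,
    r0 = pred$r0,
    leverage = wr$query$leverage,
    lof_score = lof,
    in_domain = !wr$query$influential & lof < lof_threshold
  )
}
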