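# Classical least-squares (CLS) full-spectrum unmixing.

#' Classical least-squares fit of a spectrum onto references
#'
#' Minimizes `|| y - sum_i c_i ref_i - nuisance ||^2` over the reference
#' coefficients and optional nuisance terms (constant offset, linear
#' slope in wavenumber). The unconstrained problem is solved exactly by
#' QR; with `nonneg = TRUE` (default - concentrations cannot be
#' negative) the reference coefficients are constrained to be >= 0 by an
#' exact active-set solve (nuisance terms stay unconstrained). With
#' references named `lut`/`zea`, raw and cross-section-corrected
#' zeaxanthin fractions are derived from the coefficients as in
#' [fractions_from_areas()].
#'
#' @param spectrum A `raman_spectrum`.
#' @param references Named list of `raman_spectrum` sharing the
#'   spectrum's wavenumber axis (>= 2, linearly independent), e.g. from
#'   [basis_references()].
#' @param nonneg Constrain reference coefficients to be non-negative.
#' @param nuisance Character vector from `c("offset", "slope")`;
#'   default `"offset"`.
#' @param cross_sections Optional named vector `c(lut =, zea =)` for the
#'   corrected fraction.
#' @return A `cls_result`: `coefficients` (named, per reference),
#'   `nuisance`, `residual_norm`, `raw_fraction_zea`,
#'   `corrected_fraction_zea`, `fitted`, `residuals`.
#' @export
cls_fit <- function(spectrum, references, nonneg = TRUE,
                    nuisance = "offset", cross_sections = NULL) {
  if (length(references) < 2) stop_domain("at least two references required")
  y <- spectrum$intensity
  R <- sapply(references, function(ref) {
    if (length(ref$wavenumber) != length(spectrum$wavenumber) ||
        any(ref$wavenumber != spectrum$wavenumber)) {
      stop_data("reference wavenumber axis does not match the spectrum")
    }
    ref$intensity
  })
  R <- as.matrix(R)
  nuisance <- intersect(nuisance %||% character(0), c("offset", "slope"))
  N <- NULL
  if ("offset" %in% nuisance) N <- cbind(N, offset = rep(1, length(y)))
  if ("slope" %in% nuisance) {
    N <- cbind(N, slope = (spectrum$wavenumber - mean(spectrum$wavenumber)) /
                 stats::sd(spectrum$wavenumber))
  }
  X <- cbind(R, N)
  qrx <- qr(X)
  if (qrx$rank < ncol(X)) {
    stop_numeric("reference set (plus nuisance) is rank deficient",
                 diagnostics = list(rank = qrx$rank, ncol = ncol(X)))
  }
  coef_all <- qr.coef(qrx, y)
  k <- ncol(R)
  if (nonneg && any(coef_all[seq_len(k)] < 0)) {
    # exact active-set: try every subset of references clamped to zero,
    # keep the feasible solution with smallest SSE (k is small)
    best <- NULL
    for (m in 0:(2^k - 1)) {
      active <- which(bitwAnd(m, 2^(seq_len(k) - 1)) == 0)
      Xs <- cbind(R[, active, drop = FALSE], N)
      if (ncol(Xs) == 0) {
        cf <- numeric(0); res <- y
      } else {
        fit <- stats::lm.fit(Xs, y)
        cf <- fit$coefficients; res <- fit$residuals
        if (any(is.na(cf))) next
      }
      full <- numeric(k)
      full[active] <- if (length(active)) cf[seq_along(active)] else numeric(0)
      if (any(full < -1e-12)) next
      sse <- sum(res^2)
      if (is.null(best) || sse < best$sse) {
        best <- list(coef = pmax(full, 0), sse = sse,
                     nuis = if (!is.null(N)) utils::tail(cf, ncol(N)) else numeric(0),
                     residuals = res)
      }
    }
    coefs <- best$coef
    nuis <- best$nuis
    residuals <- best$residuals
  } else {
    coefs <- coef_all[seq_len(k)]
    nuis <- if (!is.null(N)) utils::tail(coef_all, ncol(N)) else numeric(0)
    residuals <- y - X %*% coef_all
  }
  names(coefs) <- names(references)
  raw <- corr <- NA_real_
  if (all(c("lut", "zea") %in% names(coefs)) && sum(coefs[c("lut", "zea")]) > 0) {
    fr <- fractions_from_areas(coefs[["lut"]], coefs[["zea"]],
                               s_lut = cross_sections[["lut"]] %||% 1,
                               s_zea = cross_sections[["zea"]] %||% 1)
    raw <- fr$raw_fraction_zea
    corr <- fr$corrected_fraction_zea
  }
  fitted <- as.numeric(y - residuals)
  structure(list(coefficients = coefs, nuisance = nuis,
                 residual_norm = sqrt(sum(residuals^2)),
                 raw_fraction_zea = raw, corrected_fraction_zea = corr,
                 fitted = fitted, residuals = as.numeric(residuals),
                 nonneg = nonneg),
            class = "cls_result")
}

#' @export
print.cls_result <- function(x, ...) {
  cat("<cls_result> coefficients:",
      paste(sprintf("%s = %.4g", names(x$coefficients), x$coefficients),
            collapse = ", "),
      sprintf("\n  residual norm %.3g, raw f_zea = %.3f\n",
              x$residual_norm, x$raw_fraction_zea))
  invisible(x)
}
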