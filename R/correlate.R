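#' Correlation between retained initial H-bonds and solvent exposure
#'
#' Computes the Spearman rank correlation between per-monomer time-averaged
#' initial-dimer H-bond counts and per-monomer time-averaged SASA, and fits
#' a decreasing sigmoid `y = a / (1 + exp((x - x0)/w)) + b` by nonlinear
#' least squares: monomers retaining their four H-bonds sit on the buried
#' plateau, fully ruptured ones on the exposed plateau.
#'
#' @param hb_mean Per-monomer mean initial H-bond count (x variable).
#' @param sasa_mean Per-monomer mean SASA in nm^2 (y variable), same order.
#' @return List with `spearman` (rho), `p_value`, `fit` (named parameter
#'   vector a, x0, w, b, or NULL if the fit failed), `fitted` (fitted y),
#'   `residuals`. With constant input the correlation is reported as NA
#'   with a note.
#' @export
correlate_hb_sasa <- function(hb_mean, sasa_mean) {
  stopifnot(length(hb_mean) == length(sasa_mean))
  if (length(hb_mean) < 4L) stop("need at least 4 monomers")
  if (stats::sd(hb_mean) == 0 || stats::sd(sasa_mean) == 0) {
    return(list(spearman = NA_real_, p_value = NA_real_, fit = NULL,
                fitted = NULL, residuals = NULL,
                note = "constant input: correlation undefined"))
  }
  ct <- suppressWarnings(
    stats::cor.test(hb_mean, sasa_mean, method = "spearman", exact = FALSE))
  fit <- tryCatch({
    x <- hb_mean; y <- sasa_mean
    start <- list(a = max(y) - min(y), x0 = stats::median(x),
                  w = max(stats::sd(x) / 2, 1e-3), b = min(y))
    m <- minpack.lm::nlsLM(y ~ a / (1 + exp((x - x0) / w)) + b,
                           start = start,
                           control = minpack.lm::nls.lm.control(maxiter = 200))
    stats::coef(m)
  }, error = function(e) NULL)
  fitted <- if (!is.null(fit)) {
    fit[["a"]] / (1 + exp((hb_mean - fit[["x0"]]) / fit[["w"]])) + fit[["b"]]
  } else NULL
  list(spearman = unname(ct$estimate), p_value = ct$p.value, fit = fit,
       fitted = fitted,
       residuals = if (is.null(fitted)) NULL else sasa_mean - fitted)
}
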