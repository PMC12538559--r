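#' Unbiased transition time from a biased run
#'
#' Infrequent well-tempered metadynamics rescaling: the real (unbiased)
#' time of a transition observed at biased time `t_transition` is the
#' running integral of the bias acceleration factor,
#' `t = sum_i dt_i * exp(beta * V(t_i))`, accumulated over the trace rows
#' up to the transition (left-rule discretization of
#' t = t_b * <exp(beta V)>). With V >= 0 the unbiased time is never smaller
#' than the biased one.
#'
#' @param trace A [bias_trace()] covering `[0, t_transition]`.
#' @param t_transition Biased transition time (ps); defaults to the
#'   trace's recorded `transition_time` attribute if present.
#' @return Unbiased transition time in ps.
#' @export
unbiased_time <- function(trace, t_transition = NULL) {
  if (is.null(t_transition)) t_transition <- attr(trace, "transition_time")
  if (is.null(t_transition)) stop("t_transition not given and not recorded on trace")
  tt <- trace$time; V <- trace$bias
  if (t_transition > tt[length(tt)] * (1 + 1e-9) + 1e-9) {
    stop("t_transition ", t_transition, " beyond trace end ", tt[length(tt)])
  }
  if (t_transition < tt[1]) stop("t_transition before trace start")
  keep <- tt < t_transition
  t_grid <- c(tt[keep], t_transition)
  V_grid <- V[keep]
  if (!length(V_grid)) return(0)
  sum(diff(t_grid) * exp(trace$beta * V_grid))
}

#' Ensemble of unbiased transition times
#'
#' @param times Unbiased transition times (ps), > 0.
#' @param censored Logical flags marking runs that ended without a
#'   transition (their `times` entry is the trace end); censored runs are
#'   excluded from fitting but counted in reports.
#' @return Object of class `transition_ensemble`.
#' @export
transition_ensemble <- function(times, censored = rep(FALSE, length(times))) {
  stopifnot(length(times) == length(censored), all(times > 0))
  if (!any(!censored)) stop("need at least one uncensored transition time")
  structure(list(times = as.numeric(times), censored = censored),
            class = "transition_ensemble")
}

#' Fit a Poisson-process CDF to transition times
#'
#' The characteristic timescale tau is obtained by nonlinear least squares
#' of the Poisson-like cumulative probability `P(t) = 1 - exp(-t / tau)`
#' against the empirical CDF at the sorted uncensored times (plotting
#' positions k/(n+1)). The exponential MLE (the sample mean) is reported
#' alongside as a diagnostic, together with a Kolmogorov-Smirnov test of
#' the sample against Exp(tau-hat) -- reported, never used to drop runs.
#'
#' @param ensemble A [transition_ensemble()] or a numeric vector of times.
#' @return Object of class `cdf_fit`: `tau` (ps), `tau_se`, `tau_mle`,
#'   `ecdf` (data frame t, p), `ks` (statistic and p-value), `n`,
#'   `n_censored`, `degenerate` flag.
#' @export
fit_poisson_cdf <- function(ensemble) {
  if (!inherits(ensemble, "transition_ensemble")) {
    ensemble <- transition_ensemble(ensemble)
  }
  t_unc <- sort(ensemble$times[!ensemble$censored])
  n <- length(t_unc)
  if (n < 5L) warning("fewer than 5 uncensored times: point estimate only")
  p <- seq_len(n) / (n + 1)
  degenerate <- n == 1L || stats::sd(t_unc) == 0
  if (degenerate) {
    tau <- t_unc[1]
    tau_se <- NA_real_
  } else {
    dat <- data.frame(t = t_unc, p = p)
    fit <- minpack.lm::nlsLM(p ~ 1 - exp(-t / tau), data = dat,
                             start = list(tau = mean(t_unc)),
                             lower = c(tau = .Machine$double.xmin),
                             control = minpack.lm::nls.lm.control(maxiter = 500))
    tau <- unname(stats::coef(fit)[["tau"]])
    tau_se <- tryCatch(unname(summary(fit)$coefficients["tau", "Std. Error"]),
                       error = function(e) NA_real_)
  }
  ks <- if (n >= 2L && !degenerate) {
    kt <- suppressWarnings(stats::ks.test(t_unc, "pexp", rate = 1 / tau))
    list(statistic = unname(kt$statistic), p_value = kt$p.value)
  } else list(statistic = NA_real_, p_value = NA_real_)
  structure(list(tau = tau, tau_se = tau_se, tau_mle = mean(t_unc),
                 ecdf = data.frame(t = t_unc, p = p), ks = ks, n = n,
                 n_censored = sum(ensemble$censored), degenerate = degenerate),
            class = "cdf_fit")
}

#' @export
print.cdf_fit <- function(x, ...) {
  cat("cdf_fit: tau =", signif(x$tau, 5), "ps (MLE", signif(x$tau_mle, 5),
      "), n =", x$n, "uncensored")
  if (x$n_censored) cat(" +", x$n_censored, "censored")
  if (x$degenerate) cat(" [degenerate]")
  cat("\n")
  invisible(x)
}

#' Ratio of two characteristic timescales
#'
#' Returns tau_b / tau_a and its log10, with uncertainty propagated from
#' the fit standard errors (first-order; on the log10 scale the variances
#' of the two relative errors add).
#'
#' @param fit_a,fit_b [fit_poisson_cdf()] results (fit_a the faster
#'   process, conventionally).
#' @return List with `ratio`, `log10_ratio`, `log10_se`.
#' @export
compare_timescales <- function(fit_a, fit_b) {
  if (fit_a$degenerate || fit_b$degenerate) {
    stop("degenerate fit input: ratio undefined")
  }
  ratio <- fit_b$tau / fit_a$tau
  rel_a <- if (is.finite(fit_a$tau_se)) fit_a$tau_se / fit_a$tau else NA_real_
  rel_b <- if (is.finite(fit_b$tau_se)) fit_b$tau_se / fit_b$tau else NA_real_
  log10_se <- sqrt(rel_a^2 + rel_b^2) / log(10)
  list(ratio = ratio, log10_ratio = log10(ratio), log10_se = log10_se)
}
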