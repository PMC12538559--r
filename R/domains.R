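#' Gaussian kernel density estimate
#'
#' Thin wrapper around [stats::density()] with a Scott-rule default
#' bandwidth, returning a curve that integrates to 1. Zero-variance samples
#' produce a delta-like curve with a warning.
#'
#' @param samples Numeric sample, length >= 2.
#' @param bw Bandwidth: `"scott"`, `"silverman"` or a number.
#' @param n Grid size.
#' @param from,to Optional grid range.
#' @return Data frame with columns `x` and `density`.
#' @export
kde_density <- function(samples, bw = "scott", n = 512L,
                        from = NULL, to = NULL) {
  samples <- samples[is.finite(samples)]
  if (length(samples) < 2L) stop("need at least 2 samples")
  if (is.character(bw)) {
    bw <- switch(match.arg(bw, c("scott", "silverman")),
                 scott = stats::bw.nrd, silverman = stats::bw.nrd0)
    bwv <- tryCatch(bw(samples), error = function(e) NA_real_)
  } else bwv <- bw
  if (!is.finite(bwv) || bwv <= 0) {
    warning("zero-variance sample: returning delta-like density")
    bwv <- max(1e-9, abs(mean(samples)) * 1e-9 + 1e-12)
  }
  args <- list(x = samples, bw = bwv, n = n)
  if (!is.null(from)) args$from <- from
  if (!is.null(to)) args$to <- to
  d <- do.call(stats::density, args)
  data.frame(x = d$x, density = d$y)
}

# 1-D Gaussian mixture by EM with restarts and a variance floor.
gmm_em_1d <- function(x, k, n_init = 10L, max_iter = 500L, tol = 1e-10,
                      var_floor = NULL) {
  n <- length(x)
  if (is.null(var_floor)) var_floor <- 1e-6 * stats::var(x) + 1e-12
  if (stats::sd(x) == 0) {
    warning("all values identical: degenerate mixture with floored variances")
    return(list(mu = rep(x[1], k), s2 = rep(var_floor, k),
                w = rep(1 / k, k), ll = NA_real_))
  }
  best <- NULL
  km <- tryCatch(suppressWarnings(stats::kmeans(x, k, nstart = 5)),
                 error = function(e) NULL)
  init_of <- function(j) {
    if (j == 1L && !is.null(km)) {
      o <- order(km$centers)
      mu <- as.vector(km$centers)[o]
      s2 <- vapply(o, function(c) stats::var(x[km$cluster == c]), numeric(1))
      s2[!is.finite(s2)] <- 0
      w <- tabulate(km$cluster, k)[o] / n
      return(list(mu = mu, s2 = pmax(s2, var_floor), w = pmax(w, 1e-6)))
    }
    if (j == 2L) {
      # point-mass-aware start: a tied minimum (e.g. isolated centers whose
      # descriptor never changes) gets its own tight component
      at_min <- x <= min(x) + 1e-12
      if (mean(at_min) > 0.005 && sum(!at_min) >= 10L * (k - 1L)) {
        xr <- x[!at_min]
        mu <- c(min(x), stats::quantile(xr, probs = (seq_len(k - 1) - 0.5) / (k - 1),
                                        names = FALSE))
        s2 <- c(var_floor, rep(stats::var(xr) / k + var_floor, k - 1))
        return(list(mu = mu, s2 = s2, w = pmax(c(mean(at_min),
                    rep(mean(!at_min) / (k - 1), k - 1)), 1e-6)))
      }
    }
    mu <- if (j <= 3L) {
      stats::quantile(x, probs = (seq_len(k) - 0.5) / k, names = FALSE)
    } else sort(sample(x, k))
    list(mu = mu, s2 = rep(stats::var(x) / k + var_floor, k), w = rep(1 / k, k))
  }
  for (j in seq_len(n_init)) {
    ini <- init_of(j)
    mu <- ini$mu; s2 <- ini$s2; w <- ini$w
    ll_old <- -Inf
    degenerate <- FALSE
    for (it in seq_len(max_iter)) {
      lg <- vapply(seq_len(k), function(c)
        log(w[c]) + stats::dnorm(x, mu[c], sqrt(s2[c]), log = TRUE),
        numeric(n))
      m <- apply(lg, 1, max)
      lse <- m + log(rowSums(exp(lg - m)))
      ll <- sum(lse)
      g <- exp(lg - lse)                       # n x k responsibilities
      nk <- colSums(g)
      if (anyNA(nk) || any(nk < 1e-8)) { degenerate <- TRUE; break }
      w <- nk / n
      mu <- colSums(g * x) / nk
      s2 <- colSums(g * (x - rep(mu, each = n))^2) / nk
      if (any(s2 < var_floor)) s2 <- pmax(s2, var_floor)
      if (is.finite(ll_old) && abs(ll - ll_old) < tol * (1 + abs(ll))) break
      ll_old <- ll
    }
    if (degenerate) next
    if (is.null(best) || ll > best$ll) {
      best <- list(mu = mu, s2 = s2, w = w, ll = ll)
    }
  }
  if (is.null(best)) {
    warning("EM degenerate for all restarts; refitting with a larger variance floor")
    return(gmm_em_1d(x, k, n_init = n_init, max_iter = max_iter, tol = tol,
                     var_floor = max(var_floor * 1e3, 1e-8)))
  }
  best
}

#' Fit the three-domain Gaussian mixture over tauSOAP values
#'
#' Expectation-maximization over the pooled 1-D tauSOAP values with
#' `n_init` restarts; components are sorted by mean and labelled by the
#' monomer-state convention: the lowest-mean component is domain III
#' (travelling monomers, whose empty surroundings appear static), the
#' middle one domain I (stacked bound monomers, moderate neighbourhood
#' rearrangement), and the highest domain II (stacked unbound monomers,
#' the most dynamic neighbourhoods).
#'
#' @param tau A `tausoap_series` (from [tau_soap_series()]) or a numeric
#'   vector of pooled values.
#' @param k Number of components (default 3; the I/II/III label map is
#'   defined for k = 3).
#' @param n_init EM restarts.
#' @param seed Integer seed making the restarts deterministic.
#' @return Object of class `domain_model`: `means`, `vars`, `weights`
#'   (sorted by mean), `labels` (component -> domain), `loglik`.
#' @export
fit_domains <- function(tau, k = 3L, n_init = 10L, seed = 1L) {
  x <- if (inherits(tau, "tausoap_series")) as.vector(tau$tau) else as.numeric(tau)
  x <- x[is.finite(x)]
  if (length(x) < 10L * k) stop("need at least 10*k pooled values")
  fit <- with_seed(seed, gmm_em_1d(x, k, n_init = n_init))
  o <- order(fit$mu)
  labels <- if (k == 3L) c("III", "I", "II") else paste0("C", seq_len(k))
  structure(list(means = fit$mu[o], vars = fit$s2[o], weights = fit$w[o],
                 labels = labels, loglik = fit$ll, k = k),
            class = "domain_model")
}

#' @export
print.domain_model <- function(x, ...) {
  cat("domain_model (k =", x$k, "):\n")
  for (c in seq_len(x$k)) {
    cat(sprintf("  %-3s mean %.4f sd %.4f weight %.3f\n",
                x$labels[c], x$means[c], sqrt(x$vars[c]), x$weights[c]))
  }
  invisible(x)
}

#' Assign per-center per-frame domain labels
#'
#' Maximum-posterior component per tauSOAP value, mapped to the domain
#' labels, followed by a dwell filter: runs shorter than `dwell_min` frames
#' are merged into the preceding run's state (the following run's state at
#' a series start), suppressing transient flickers.
#'
#' @param tau A `tausoap_series` or a centers x frames matrix of values.
#' @param model A [fit_domains()] model.
#' @param dwell_min Minimum dwell length in frames (1 = no filtering).
#' @return Character matrix centers x frames of domain labels.
#' @export
assign_domains <- function(tau, model, dwell_min = 5L) {
  m <- if (inherits(tau, "tausoap_series")) tau$tau else as.matrix(tau)
  x <- as.vector(m)
  lg <- vapply(seq_len(model$k), function(c)
    log(model$weights[c]) + stats::dnorm(x, model$means[c],
                                         sqrt(model$vars[c]), log = TRUE),
    numeric(length(x)))
  comp <- max.col(lg, ties.method = "first")
  lab <- matrix(model$labels[comp], nrow = nrow(m), dimnames = dimnames(m))
  if (dwell_min > 1L) {
    for (i in seq_len(nrow(lab))) lab[i, ] <- dwell_filter(lab[i, ], dwell_min)
  }
  lab
}

# Merge runs shorter than dwell_min into the flanking (preceding) state.
dwell_filter <- function(labels, dwell_min) {
  repeat {
    r <- rle(labels)
    if (length(r$lengths) <= 1L) return(labels)
    short <- which(r$lengths < dwell_min)
    if (!length(short)) return(labels)
    s <- short[1]
    r$values[s] <- if (s > 1L) r$values[s - 1L] else r$values[s + 1L]
    labels <- inverse.rle(r)
  }
}

#' Detect defect, self-healing and exchange events
#'
#' Scans the filtered domain labels of each center for transitions and
#' classifies them: I to II or I to III is a defect (dimer rupture creating
#' a stacked-unbound or travelling monomer), II to I or III to I is
#' self-healing (a restored dimer), and II to III or III to II is an
#' exchange of defect configuration.
#'
#' @param labels Character matrix centers x frames from [assign_domains()].
#' @param class Optional named tip/backbone vector (from [label_tips()])
#'   used for the per-class summary.
#' @return Object of class `event_log`: `events` data frame (center, frame,
#'   from, to, type) and `summary` (counts by type, and by type x class
#'   when `class` is given).
#' @export
detect_events <- function(labels, class = NULL) {
  evs <- list()
  for (i in seq_len(nrow(labels))) {
    l <- labels[i, ]
    ch <- which(l[-1] != l[-length(l)])
    if (!length(ch)) next
    from <- l[ch]; to <- l[ch + 1L]
    type <- ifelse(from == "I" & to %in% c("II", "III"), "defect",
            ifelse(from %in% c("II", "III") & to == "I", "self-heal",
                   "exchange"))
    evs[[length(evs) + 1L]] <- data.frame(
      center = rownames(labels)[i], frame = ch + 1L, from = from, to = to,
      type = type, stringsAsFactors = FALSE)
  }
  events <- if (length(evs)) do.call(rbind, evs) else
    data.frame(center = character(0), frame = integer(0), from = character(0),
               to = character(0), type = character(0))
  summary <- table(factor(events$type, levels = c("defect", "self-heal", "exchange")))
  by_class <- NULL
  if (!is.null(class) && nrow(events)) {
    by_class <- table(factor(events$type, levels = c("defect", "self-heal", "exchange")),
                      factor(class[events$center], levels = c("tip", "backbone")))
  } else if (!is.null(class)) {
    by_class <- table(factor(character(0), levels = c("defect", "self-heal", "exchange")),
                      factor(character(0), levels = c("tip", "backbone")))
  }
  structure(list(events = events, summary = summary, by_class = by_class),
            class = "event_log")
}

#' @export
print.event_log <- function(x, ...) {
  cat("event_log:", nrow(x$events), "events (")
  cat(paste(names(x$summary), as.integer(x$summary), collapse = ", "), ")\n")
  invisible(x)
}
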