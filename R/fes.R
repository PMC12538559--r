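#' Reweight a free-energy surface from biased CV samples
#'
#' Each biased sample carries a statistical weight `exp(beta (V - c_t))`;
#' when no c(t) column is available the weights use the bias directly
#' (time-independent / final-bias approximation -- any constant offset
#' cancels in the min-shift). The free energy per grid cell is
#' `F(s) = -kT log(sum of weights)`, shifted so the sampled minimum is 0;
#' unsampled cells are NA (flagged, not zero).
#'
#' @param samples Data frame with one or two CV columns (named in `cv`),
#'   a bias column `bias` (kJ/mol) and optionally `ct`.
#' @param kT Thermal energy in kJ/mol (e.g. `kB * 298`).
#' @param cv Character vector (length 1 or 2) naming the CV columns.
#' @param breaks List (per CV) of bin break vectors, or a number of bins.
#' @return Object of class `fes_grid`: `F` (vector or matrix, kJ/mol),
#'   `mids` (bin centers per CV), `counts`, `kT`, `ct_mode`.
#' @export
reweight_fes <- function(samples, kT, cv, breaks = 50L) {
  stopifnot(length(cv) %in% 1:2, all(cv %in% names(samples)),
            "bias" %in% names(samples))
  beta <- 1 / kT
  has_ct <- "ct" %in% names(samples)
  w <- exp(beta * (samples$bias - if (has_ct) samples$ct else 0))
  mk_breaks <- function(x, b) if (length(b) > 1L) b else
    seq(min(x), max(x) + 1e-12, length.out = b + 1L)
  if (!is.list(breaks)) breaks <- rep(list(breaks), length(cv))
  br <- lapply(seq_along(cv), function(i) mk_breaks(samples[[cv[i]]], breaks[[i]]))
  idx <- lapply(seq_along(cv), function(i) {
    ii <- findInterval(samples[[cv[i]]], br[[i]], rightmost.closed = TRUE)
    ii[ii < 1L | ii > length(br[[i]]) - 1L] <- NA_integer_
    ii
  })
  ok <- !Reduce(`|`, lapply(idx, is.na))
  mids <- lapply(br, function(b) (b[-1] + b[-length(b)]) / 2)
  if (length(cv) == 1L) {
    nb <- length(mids[[1]])
    wsum <- rep(0, nb); cnt <- integer(nb)
    t1 <- tapply(w[ok], idx[[1]][ok], sum)
    wsum[as.integer(names(t1))] <- t1
    t2 <- table(idx[[1]][ok])
    cnt[as.integer(names(t2))] <- as.integer(t2)
    F <- ifelse(wsum > 0, -kT * log(wsum), NA_real_)
  } else {
    nb1 <- length(mids[[1]]); nb2 <- length(mids[[2]])
    key <- (idx[[2]] - 1L) * nb1 + idx[[1]]
    wsum <- rep(0, nb1 * nb2); cnt <- integer(nb1 * nb2)
    t1 <- tapply(w[ok], key[ok], sum)
    wsum[as.integer(names(t1))] <- t1
    t2 <- table(key[ok])
    cnt[as.integer(names(t2))] <- as.integer(t2)
    F <- matrix(ifelse(wsum > 0, -kT * log(wsum), NA_real_), nb1, nb2)
    cnt <- matrix(cnt, nb1, nb2)
  }
  F <- F - min(F, na.rm = TRUE)
  structure(list(F = F, mids = setNames(mids, cv), counts = cnt, kT = kT,
                 ct_mode = if (has_ct) "explicit" else "final-bias"),
            class = "fes_grid")
}

#' @export
print.fes_grid <- function(x, ...) {
  cat("fes_grid over", paste(names(x$mids), collapse = " x "),
      "; sampled cells:", sum(!is.na(x$F)), "/", length(x$F),
      "; c(t) mode:", x$ct_mode, "\n")
  invisible(x)
}
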