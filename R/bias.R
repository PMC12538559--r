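#' Bias trace: collective variables and metadynamics bias versus time
#'
#' Holds rows of (time, CV values, bias energy, optional time-dependent
#' offset c(t)) from a well-tempered metadynamics run, plus the temperature
#' and the derived inverse thermal energy beta = 1/(kB T).
#'
#' @param time Times in ps, strictly increasing.
#' @param bias Bias potential V in kJ/mol, finite.
#' @param cvs Data frame (or NULL) of CV columns aligned with `time`.
#' @param c_t Optional c(t) offset column (kJ/mol).
#' @param temperature Temperature in K.
#' @return An object of class `bias_trace` with elements `time`, `bias`,
#'   `cvs`, `c_t`, `temperature`, `beta`.
#' @export
bias_trace <- function(time, bias, cvs = NULL, c_t = NULL, temperature = 298) {
  stopifnot(length(time) == length(bias))
  if (any(!is.finite(bias))) stop("bias values must be finite")
  if (is.unsorted(time, strictly = TRUE)) {
    warning("bias trace times not sorted; sorting rows by time")
    o <- order(time)
    time <- time[o]; bias <- bias[o]
    if (!is.null(cvs)) cvs <- cvs[o, , drop = FALSE]
    if (!is.null(c_t)) c_t <- c_t[o]
    if (anyDuplicated(time)) stop("duplicate times in bias trace")
  }
  structure(list(time = as.numeric(time), bias = as.numeric(bias),
                 cvs = cvs, c_t = c_t, temperature = temperature,
                 beta = beta_from_temperature(temperature)),
            class = "bias_trace")
}

#' @export
print.bias_trace <- function(x, ...) {
  cat("bias_trace:", length(x$time), "rows, t in [",
      min(x$time), ",", max(x$time), "] ps, T =", x$temperature,
      "K (beta =", signif(x$beta, 6), "mol/kJ)\n")
  invisible(x)
}

#' Read a COLVAR-style bias table
#'
#' Accepts whitespace-delimited tables with either a PLUMED `#! FIELDS ...`
#' header or a plain header row naming the columns.
#'
#' @param file Path to the table.
#' @param temperature Temperature in K used to derive beta.
#' @param column_map List naming the relevant columns: `time`, `bias`, and
#'   optionally `cvs` (character vector) and `ct`.
#' @return A [bias_trace()] with rows sorted by time.
#' @export
read_bias_trace <- function(file, temperature = 298,
                            column_map = list(time = "time", bias = "bias")) {
  lines <- readLines(file)
  header <- NULL
  first <- lines[1]
  if (startsWith(first, "#! FIELDS")) {
    header <- strsplit(trimws(sub("^#! FIELDS", "", first)), "\\s+")[[1]]
    body <- lines[!startsWith(lines, "#")]
  } else {
    header <- strsplit(trimws(first), "\\s+")[[1]]
    body <- lines[-1]
    body <- body[!startsWith(body, "#")]
  }
  body <- body[nzchar(trimws(body))]
  if (!length(body)) stop("empty bias table")
  toks <- strsplit(trimws(body), "\\s+")
  ncol_expect <- length(header)
  vals <- suppressWarnings(lapply(toks, as.numeric))
  badlen <- which(lengths(vals) != ncol_expect)
  if (length(badlen)) stop("malformed row at line ", badlen[1], " of data block")
  badnum <- which(vapply(vals, anyNA, logical(1)))
  if (length(badnum)) stop("non-numeric value at data line ", badnum[1])
  tab <- do.call(rbind, vals)
  colnames(tab) <- header
  need <- c(column_map$time, column_map$bias)
  missing_col <- setdiff(need, header)
  if (length(missing_col)) stop("missing column '", missing_col[1], "' in bias table")
  cv_cols <- column_map$cvs
  if (is.null(cv_cols)) cv_cols <- setdiff(header, c(column_map$time, column_map$bias, column_map$ct))
  cvs <- if (length(cv_cols)) as.data.frame(tab[, cv_cols, drop = FALSE]) else NULL
  ct <- if (!is.null(column_map$ct) && column_map$ct %in% header) tab[, column_map$ct] else NULL
  bias_trace(tab[, column_map$time], tab[, column_map$bias],
             cvs = cvs, c_t = ct, temperature = temperature)
}

#' Write a bias trace as a COLVAR-style table
#'
#' @param trace A [bias_trace()].
#' @param file Output path.
#' @return `file`, invisibly.
#' @export
write_bias_trace <- function(trace, file) {
  cols <- list(time = trace$time)
  if (!is.null(trace$cvs)) for (nm in names(trace$cvs)) cols[[nm]] <- trace$cvs[[nm]]
  cols$bias <- trace$bias
  if (!is.null(trace$c_t)) cols$ct <- trace$c_t
  con <- file(file, "wt")
  on.exit(close(con))
  writeLines(paste("#! FIELDS", paste(names(cols), collapse = " ")), con)
  df <- as.data.frame(cols)
  utils::write.table(format(df, digits = 15, scientific = TRUE, trim = TRUE),
                     con, row.names = FALSE, col.names = FALSE, quote = FALSE)
  invisible(file)
}
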