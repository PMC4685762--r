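#' Read a joint rating table from CSV
#'
#' The on-disk format is a plain CSV of 9 x 9 (generally square) nonnegative
#' cells with a `r1..r9` header row, preceded by a `#`-prefixed key-value
#' block declaring at least `order` and `kind`; tables of kind
#' `relative_frequency` additionally declare `scale` (`percent` or
#' `proportion`) and `n`.  Nothing is guessed: missing metadata is an
#' error.  Percent tables are divided by 100 and renormalised, with a
#' warning if their sum was off by more than 0.02.
#'
#' @param path Path to the file.
#' @return A [joint_table()].
#' @examples
#' read_joint_table(system.file("extdata", "selffirst_observed.csv",
#'                              package = "ratingwalk"))
#' @export
read_joint_table <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  hdr <- grep("^#", lines)
  meta <- list()
  for (ln in lines[hdr]) {
    kv <- sub("^#\\s*", "", ln)
    key <- trimws(sub(":.*$", "", kv))
    val <- trimws(sub("^[^:]*:", "", kv))
    meta[[key]] <- val
  }
  for (key in c("order", "kind"))
    if (is.null(meta[[key]]))
      stop("missing required metadata '", key, "' in ", path)
  body <- lines[setdiff(seq_along(lines), hdr)]
  body <- body[nzchar(trimws(body))]
  df <- utils::read.csv(text = paste(body, collapse = "\n"),
                        header = TRUE, check.names = FALSE)
  m <- as.matrix(df)
  if (!is.numeric(m) || nrow(m) != ncol(m))
    stop(sprintf("malformed table in %s: expected a square numeric matrix, got %d rows x %d columns",
                 path, nrow(m), ncol(m)))
  kind <- meta$kind
  n <- if (!is.null(meta$n)) as.numeric(meta$n) else NULL
  if (kind == "relative_frequency") {
    if (is.null(meta$scale))
      stop("relative-frequency tables must declare 'scale' (percent or proportion) in ", path)
    if (is.null(n)) stop("relative-frequency tables must declare 'n' in ", path)
    if (meta$scale == "percent") m <- m / 100
    if (abs(sum(m) - 1) > 0.02)
      warning(sprintf("table in %s sums to %.4f; renormalising", path, sum(m)))
    m <- m / sum(m)
  }
  joint_table(m, order = meta$order, kind = kind, n = n)
}

#' Write a joint rating table to CSV
#'
#' Inverse of [read_joint_table()]; proportion-scale tables round-trip
#' losslessly at 12 significant digits.
#'
#' @param x A [joint_table()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_joint_table <- function(x, path) {
  stopifnot(inherits(x, "joint_table"))
  m <- unclass_joint(x)
  meta <- c(sprintf("# order: %s", table_order(x)),
            sprintf("# kind: %s", table_kind(x)))
  if (table_kind(x) == "relative_frequency")
    meta <- c(meta, "# scale: proportion", sprintf("# n: %g", table_n(x)))
  rows <- apply(m, 1, function(r) paste(sprintf("%.12g", r), collapse = ","))
  writeLines(c(meta, paste(colnames(m), collapse = ","), rows), path)
  invisible(path)
}

#' Observed joint rating tables of the packaged study
#'
#' The two order-conditioned 9 x 9 joint distributions of
#' public-service-announcement effectiveness ratings bundled with the
#' package: 131 participants each rated 12 announcements for perceived
#' effectiveness "to you" (self) and "to your friends" (other) on 9-point
#' scales, with the question order randomised per trial (775 self-first and
#' 797 other-first trials).  Cells are published integer percentages, read
#' back as renormalised proportions with the order sample sizes attached.
#'
#' @return Named list of two relative-frequency [joint_table()]s,
#'   `self_first` and `other_first`.
#' @examples
#' obs <- psa_tables()
#' table_means(obs$self_first)
#' @export
psa_tables <- function() {
  list(
    self_first = read_joint_table(system.file("extdata", "selffirst_observed.csv",
                                              package = "ratingwalk")),
    other_first = read_joint_table(system.file("extdata", "otherfirst_observed.csv",
                                               package = "ratingwalk"))
  )
}

#' Reference parameter estimates for the packaged study
#'
#' Published point estimates of the five model parameters for each
#' model-objective combination, together with the fit statistic reported
#' alongside them.  They serve as inputs for forward predictions and for
#' likelihood evaluations, and as plausibility anchors for refits.
#'
#' @return A data frame with columns `objective`, `model`, `alpha_s`,
#'   `beta_s`, `alpha_o`, `beta_o`, `lambda`, `statistic`, `value`.
#' @examples
#' subset(psa_estimates(), objective == "sse" & model == "quantum")
#' @export
psa_estimates <- function() {
  utils::read.csv(system.file("extdata", "reference_estimates.csv",
                              package = "ratingwalk"))
}

#' Reference quantum-model predictions for the packaged study
#'
#' The published model-predicted joint distributions (quantum walk at its
#' SSE estimates, mixture applied), rounded to integer percentages -- the
#' values the package's own forward predictions are checked against.
#'
#' @return Named list of two 9 x 9 integer matrices (percent scale),
#'   `self_first` and `other_first`.
#' @export
psa_reference_predictions <- function() {
  rd <- function(f) {
    m <- as.matrix(utils::read.csv(system.file("extdata", f,
                                               package = "ratingwalk"),
                                   check.names = FALSE))
    dimnames(m) <- list(first = paste0("r", 1:9), second = paste0("r", 1:9))
    m
  }
  list(self_first = rd("selffirst_quantum_predicted.csv"),
       other_first = rd("otherfirst_quantum_predicted.csv"))
}
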