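#' Joint rating tables
#'
#' A `joint_table` holds the joint distribution of a pair of ratings for one
#' question order.  Rows always index the *first* question asked, columns
#' the second.  The table may contain probabilities (model predictions),
#' relative frequencies, or raw counts.
#'
#' @param cells Square numeric matrix of nonnegative cells (9 x 9 for the
#'   standard design).
#' @param order `"self_first"` or `"other_first"`; which question was asked
#'   first.
#' @param kind `"probability"`, `"relative_frequency"` or `"count"`.
#' @param n Sample size (number of trials).  Required for counts and
#'   relative frequencies; ignored for probability tables.
#'
#' @return An object of class `"joint_table"`: the cell matrix with
#'   attributes `order`, `kind` and `n`.
#' @examples
#' m <- matrix(1 / 81, 9, 9)
#' joint_table(m, "self_first", "probability")
#' @export
joint_table <- function(cells, order = c("self_first", "other_first"),
                        kind = c("probability", "relative_frequency", "count"),
                        n = NULL) {
  order <- match.arg(order)
  kind <- match.arg(kind)
  cells <- as.matrix(cells)
  if (nrow(cells) != ncol(cells))
    stop("'cells' must be a square matrix")
  if (any(!is.finite(cells)) || any(cells < 0))
    stop("'cells' must be finite and nonnegative")
  if (kind == "probability") {
    if (abs(sum(cells) - 1) > 1e-10)
      stop(sprintf("probability table must sum to 1 (got %.12f)", sum(cells)))
    n <- NULL
  } else if (kind == "count") {
    n <- sum(cells)
  } else {
    if (is.null(n)) stop("relative-frequency tables require a sample size 'n'")
    n <- as.numeric(n)
  }
  dimnames(cells) <- list(first = paste0("r", seq_len(nrow(cells))),
                          second = paste0("r", seq_len(ncol(cells))))
  structure(cells, order = order, kind = kind, n = n, class = "joint_table")
}

#' @export
print.joint_table <- function(x, digits = 3, ...) {
  cat(sprintf("Joint rating table (%s, %s%s)\n", attr(x, "order"),
              attr(x, "kind"),
              if (!is.null(attr(x, "n"))) sprintf(", n = %g", attr(x, "n")) else ""))
  print(round(unclass_joint(x), digits), ...)
  invisible(x)
}

# strip class/attrs, keep the bare matrix
unclass_joint <- function(x) {
  m <- unclass(x)
  attr(m, "order") <- NULL; attr(m, "kind") <- NULL; attr(m, "n") <- NULL
  m
}

#' @export
as.matrix.joint_table <- function(x, ...) unclass_joint(x)

table_order <- function(x) attr(x, "order")
table_kind <- function(x) attr(x, "kind")
table_n <- function(x) attr(x, "n")

# observed table (count or relative frequency) as proportions
as_proportions <- function(x) {
  m <- unclass_joint(x)
  m / sum(m)
}

# observed table as (possibly non-integral) counts
as_counts <- function(x) {
  m <- unclass_joint(x)
  switch(table_kind(x),
         count = m,
         relative_frequency = m / sum(m) * table_n(x),
         stop("a probability table carries no sample size; supply counts or ",
              "relative frequencies with 'n'"))
}

#' Non-judgemental mixture
#'
#' On a fraction `1 - lambda` of trials the judge skips the evaluation
#' process altogether and simply answers with the scale midpoint for both
#' questions.  The mixed distribution multiplies every model cell by
#' `lambda` and adds mass `1 - lambda` to the (neutral, neutral) cell --
#' cell (5, 5) on the 9-point scale.  `lambda = 1` leaves the table
#' unchanged; `lambda = 0` is a point mass at the midpoint.
#'
#' @param table A probability-kind [joint_table()].
#' @param lambda Mixture weight in `[0, 1]`: probability that a trial
#'   engages the walk process.
#' @return A probability-kind `joint_table`.
#' @examples
#' u <- joint_table(matrix(1 / 81, 9, 9), "self_first", "probability")
#' apply_mixture(u, 0.5)[5, 5] # 0.5 + 0.5/81
#' @export
apply_mixture <- function(table, lambda) {
  stopifnot(inherits(table, "joint_table"))
  if (table_kind(table) != "probability")
    stop("the mixture applies to probability tables")
  if (!is.finite(lambda) || lambda < 0 || lambda > 1)
    stop("'lambda' must lie in [0, 1]")
  m <- unclass_joint(table)
  mid <- (nrow(m) + 1L) %/% 2L
  m <- lambda * m
  m[mid, mid] <- m[mid, mid] + (1 - lambda)
  joint_table(m, table_order(table), "probability")
}

#' Marginal mean ratings of a joint table
#'
#' @param table A [joint_table()] of probabilities or relative frequencies
#'   (counts are normalised first).
#' @return Named numeric vector `c(first = , second = )`: the mean rating of
#'   the first and of the second question asked.
#' @examples
#' u <- joint_table(matrix(1 / 81, 9, 9), "self_first", "probability")
#' table_means(u) # both 5
#' @export
table_means <- function(table) {
  stopifnot(inherits(table, "joint_table"))
  p <- as_proportions(table)
  r <- seq_len(nrow(p))
  c(first = sum(r * rowSums(p)), second = sum(r * colSums(p)))
}

#' Self--other mean differences by question order
#'
#' Summarises the order effect on the mean level of the two judgements.
#' Within each order the difference is taken as (self mean - other mean);
#' self is the row (first) variable of a self-first table and the column
#' (second) variable of an other-first table.  The interaction is the
#' self-first difference minus the other-first difference: positive values
#' mean the self-over-other elevation is larger when self is judged first.
#'
#' @param t_self_first,t_other_first [joint_table()]s for the two orders.
#' @return Named vector `c(diff_self_first, diff_other_first, interaction)`.
#' @export
order_effect_summary <- function(t_self_first, t_other_first) {
  stopifnot(inherits(t_self_first, "joint_table"),
            inherits(t_other_first, "joint_table"))
  if (table_order(t_self_first) != "self_first" ||
      table_order(t_other_first) != "other_first")
    stop("tables must be supplied as (self_first, other_first)")
  m1 <- table_means(t_self_first)
  m2 <- table_means(t_other_first)
  d1 <- unname(m1["first"] - m1["second"])
  d2 <- unname(m2["second"] - m2["first"])
  c(diff_self_first = d1, diff_other_first = d2, interaction = d1 - d2)
}
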