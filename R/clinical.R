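#' Positivity percentage of a count pair
#'
#' 100 * positive / total, rounded half-up to one decimal (so 272/487 =
#' 55.85...% prints as 55.9), as positivity percentages are conventionally
#' reported for immunohistochemistry tissue-microarray scoring.
#'
#' @param positive,total non-negative counts, \code{positive <= total},
#'   \code{total > 0}.
#' @return list with \code{percent} (1-decimal, half-up) and
#'   \code{fraction} (raw proportion).
#' @examples
#' positivityRate(272, 487)$percent  # 55.9
#' @export
positivityRate <- function(positive, total) {
  if (total <= 0) stop("total must be positive")
  if (positive < 0 || positive > total)
    stop("need 0 <= positive <= total")
  frac <- positive / total
  list(percent = floor(1000 * frac + 0.5) / 10, fraction = frac)
}

#' Association test for a labeled 2x2 count table
#'
#' Chi-square (with or without Yates continuity correction) or Fisher's
#' exact test on a 2x2 contingency table, plus the sample cross-product
#' odds ratio ad/bc (NA when any cell is zero; no Haldane correction).
#' The default is the Yates-corrected chi-square.
#'
#' @param table 2x2 numeric matrix of non-negative integer counts
#'   (row/column names kept in the output).
#' @param method \code{"chisq-yates"} (default), \code{"chisq"} or
#'   \code{"fisher"}.
#' @return list with \code{method}, \code{statistic} (NA for Fisher),
#'   \code{p}, \code{oddsRatio}, \code{table}.
#' @export
association2x2 <- function(table,
                           method = c("chisq-yates", "chisq", "fisher")) {
  method <- match.arg(method)
  m <- as.matrix(table)
  if (!all(dim(m) == c(2L, 2L))) stop("need a 2x2 table")
  if (any(m < 0) || any(m != round(m)))
    stop("counts must be non-negative integers")
  if (method != "fisher" && (any(rowSums(m) == 0) || any(colSums(m) == 0)))
    stop("chi-square requires positive row and column marginals; ",
         "use method = \"fisher\"")
  orv <- if (any(m == 0)) NA_real_ else (m[1, 1] * m[2, 2]) /
    (m[1, 2] * m[2, 1])
  res <- switch(method,
    "chisq-yates" = {
      t <- suppressWarnings(chisq.test(m, correct = TRUE))
      list(statistic = unname(t$statistic), p = t$p.value)
    },
    "chisq" = {
      t <- suppressWarnings(chisq.test(m, correct = FALSE))
      list(statistic = unname(t$statistic), p = t$p.value)
    },
    "fisher" = {
      t <- fisher.test(m)
      list(statistic = NA_real_, p = t$p.value)
    })
  list(method = method, statistic = res$statistic, p = res$p,
       oddsRatio = orv, table = m)
}

#' Clinical contingency report
#'
#' Bundles the positivity rates of each row of a labeled 2x2 table with
#' the association test, as a JSON-ready list. Row convention: rows are
#' the conditioning variable (e.g. marker A positive/negative), columns
#' the outcome (e.g. marker B positive/negative), with the first column
#' taken as "positive".
#'
#' @inheritParams association2x2
#' @return list with per-row positivity (\code{percent}, \code{positive},
#'   \code{total}) and the [association2x2()] result.
#' @export
clinicalReport <- function(table,
                           method = c("chisq-yates", "chisq", "fisher")) {
  m <- as.matrix(table)
  assoc <- association2x2(m, method)
  rows <- lapply(seq_len(nrow(m)), function(i) {
    pr <- positivityRate(m[i, 1], sum(m[i, ]))
    list(label = rownames(m)[i], positive = unname(m[i, 1]),
         total = unname(sum(m[i, ])), percent = pr$percent)
  })
  list(positivity = rows,
       association = assoc[c("method", "statistic", "p", "oddsRatio")])
}
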