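#' One-sample t-statistic for tissue enrichment
#'
#' Tests whether a gene's abundance in a target tissue exceeds its abundance
#' in a panel of comparison tissues. The statistic is
#' \deqn{t = (\bar{x} - \mu) / (s / \sqrt{n})}
#' where \eqn{\bar{x}} is the target-tissue value, \eqn{\mu} and \eqn{s} the
#' mean and sample standard deviation (denominator n-1) of the `n`
#' comparison-tissue values. The p-value is the upper tail of Student's t
#' with n-1 degrees of freedom: enrichment (not depletion) is the alternative
#' of interest, so the test is one-sided and pairs naturally with the 0.025
#' selection level (the one-sided twin of a two-sided 0.05).
#'
#' When every comparison value is zero the gene is expressed exclusively in
#' the target tissue: `s = 0`, the statistic is undefined, and the gene is
#' flagged `exclusive` with `p = NA`. If `s = 0` with nonzero comparisons the
#' input is degenerate (all comparison values identical); `p` is again `NA`
#' and `degenerate` is set.
#'
#' @param x_bar Target-tissue abundance (RPKM or intensity).
#' @param comparisons Numeric vector (length >= 2) of comparison-tissue
#'   values.
#' @return List with `x_bar`, `mu`, `s`, `n`, `t`, `p`, `exclusive`,
#'   `degenerate`.
#' @examples
#' enrichment_t_test(100, c(10, 20, 30))
#' @export
enrichment_t_test <- function(x_bar, comparisons) {
  if (length(comparisons) < 2L)
    stop("need at least 2 comparison values")
  if (any(comparisons < 0) || x_bar < 0)
    stop("abundance values must be >= 0")
  n <- length(comparisons)
  mu <- mean(comparisons)
  s <- stats::sd(comparisons)
  exclusive <- all(comparisons == 0)
  degenerate <- !exclusive && s == 0
  if (s == 0) {
    t_stat <- NA_real_; p <- NA_real_
  } else {
    t_stat <- (x_bar - mu) / (s / sqrt(n))
    p <- stats::pt(t_stat, df = n - 1, lower.tail = FALSE)
  }
  list(x_bar = x_bar, mu = mu, s = s, n = n, t = t_stat, p = p,
       exclusive = exclusive, degenerate = degenerate)
}

#' Select tissue-enriched genes from an expression matrix
#'
#' A gene is enriched in the target tissue when all of:
#' \itemize{
#'   \item its one-sided enrichment p-value is below `alpha`, or it is
#'     expressed exclusively in the target (all comparison values zero,
#'     p unavailable) and `include_exclusive` is `TRUE`;
#'   \item its target-tissue abundance strictly exceeds `rpkm_min`;
#'   \item its target-tissue abundance strictly exceeds its mean abundance
#'     over all compared tissues (target included).
#' }
#' No multiple-testing correction is applied at this stage.
#'
#' @param mat Numeric matrix, rows = gene clusters, columns = tissues.
#' @param target Target tissue (column name).
#' @param alpha Significance level on the one-sided p (default 0.025).
#' @param rpkm_min Strict abundance floor in the target tissue (default 10).
#' @param include_exclusive Admit target-exclusive genes whose p is
#'   unavailable (default `TRUE`).
#' @return Data frame (`cluster_id`, `rpkm`, `t`, `p`, `exclusive`) ordered
#'   by descending target abundance, with attributes `tissue`, `alpha`,
#'   `rpkm_min`.
#' @export
select_enriched <- function(mat, target, alpha = 0.025, rpkm_min = 10,
                            include_exclusive = TRUE) {
  if (!target %in% colnames(mat))
    stop("target tissue '", target, "' is not a matrix column")
  comp_cols <- setdiff(colnames(mat), target)
  if (length(comp_cols) < 2L)
    stop("need at least 2 comparison tissues")
  x <- mat[, target]
  comp <- mat[, comp_cols, drop = FALSE]
  n <- ncol(comp)
  mu <- rowMeans(comp)
  s <- sqrt(pmax(0, (rowSums(comp^2) - n * mu^2) / (n - 1)))
  t_stat <- ifelse(s > 0, (x - mu) / (s / sqrt(n)), NA_real_)
  p <- stats::pt(t_stat, df = n - 1, lower.tail = FALSE)
  exclusive <- rowSums(comp != 0) == 0L
  sig <- !is.na(p) & p < alpha
  if (include_exclusive) sig <- sig | exclusive
  keep <- sig & x > rpkm_min & x > rowMeans(mat)
  out <- data.frame(cluster_id = rownames(mat)[keep],
                    rpkm = x[keep],
                    t = t_stat[keep],
                    p = p[keep],
                    exclusive = exclusive[keep],
                    row.names = NULL)
  out <- out[order(-out$rpkm, out$cluster_id), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "tissue") <- target
  attr(out, "alpha") <- alpha
  attr(out, "rpkm_min") <- rpkm_min
  out
}
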