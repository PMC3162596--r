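#' Construct a ranked gene list
#'
#' @param ids Character vector of unique gene ids.
#' @param scores Finite numeric scores, same length as `ids`.
#' @return Data frame (`id`, `score`) sorted by descending score, ties broken
#'   by id; class `ranked_list`.
#' @export
ranked_list <- function(ids, scores) {
  ids <- as.character(ids)
  if (anyDuplicated(ids)) stop("ranked list ids must be unique")
  if (length(ids) != length(scores)) stop("ids and scores differ in length")
  if (any(!is.finite(scores))) stop("scores must be finite")
  o <- order(-scores, ids)
  structure(data.frame(id = ids[o], score = scores[o], row.names = NULL),
            class = c("ranked_list", "data.frame"))
}

#' Rank an enriched-gene table by -log10 p
#'
#' Scores each gene as `-log10(p)` of its enrichment test. Genes expressed
#' exclusively in the target tissue carry no p-value; they are the strongest
#' possible evidence of enrichment and receive the maximum finite score plus
#' 1, placing them at the head of the list.
#'
#' @param enriched Data frame with columns `cluster_id`, `p`, `exclusive`
#'   (as returned by [select_enriched()]).
#' @return A [ranked_list()].
#' @export
rank_by_neglog_p <- function(enriched) {
  if (nrow(enriched) == 0L) stop("empty enrichment table")
  score <- -log10(enriched$p)
  finite <- is.finite(score)
  top <- if (any(finite)) max(score[finite]) + 1 else 1
  score[enriched$exclusive | !finite] <- top
  ranked_list(enriched$cluster_id, score)
}

#' Rank genes by tissue specificity
#'
#' Scores each gene by the log2 ratio of its target-tissue abundance to its
#' mean abundance in the remaining tissues, with a pseudocount guarding
#' against zeros:
#' `log2((x_target + eps) / (mean(x_others) + eps))`.
#'
#' @param mat Numeric matrix, rows = genes, columns = tissues.
#' @param target Target tissue (column name).
#' @param pseudocount The pseudocount `eps` (default 1, on the abundance
#'   scale).
#' @return A [ranked_list()].
#' @export
rank_by_specificity <- function(mat, target, pseudocount = 1) {
  if (!target %in% colnames(mat))
    stop("target tissue '", target, "' is not a matrix column")
  if (ncol(mat) < 2L) stop("need at least 2 tissues")
  if (any(mat < 0)) stop("abundance values must be >= 0")
  others <- mat[, setdiff(colnames(mat), target), drop = FALSE]
  score <- log2((mat[, target] + pseudocount) /
                  (rowMeans(others) + pseudocount))
  ranked_list(rownames(mat), score)
}

#' Running-sum enrichment score
#'
#' Walks down the ranked list keeping a running sum: at a gene-set member
#' ("hit") the sum increases by the gene's weighted score
#' `|score|^weight_exponent` divided by the total weighted score over all
#' hits; at a non-member ("miss") it decreases by `1/(L - H)` (L list length,
#' H hits). The enrichment score (ES) is the running-sum value of maximal
#' absolute deviation from zero; when the positive and negative extrema tie
#' in magnitude the negative one is taken. The leading edge is the set of hit
#' genes at or before the extremum for positive ES, and at or after it for
#' negative ES.
#'
#' @param ranked A [ranked_list()].
#' @param gene_set Character vector of member ids (must intersect the list).
#' @param weight_exponent Weighting exponent on |score| (default 1; 0 gives
#'   the classic unweighted Kolmogorov-Smirnov statistic).
#' @return List with `es`, `running_sum` (one value per list position) and
#'   `leading_edge`.
#' @export
enrichment_score <- function(ranked, gene_set, weight_exponent = 1) {
  ids <- ranked$id
  L <- length(ids)
  hit <- ids %in% gene_set
  H <- sum(hit)
  if (H == 0L)
    stop("gene set has no member in the ranked list")
  w <- abs(ranked$score)^weight_exponent
  nr <- sum(w[hit])
  inc <- if (nr > 0) w / nr else rep(1 / H, L)
  miss_step <- if (L > H) 1 / (L - H) else 0
  steps <- ifelse(hit, inc, -miss_step)
  rs <- cumsum(steps)
  mx <- max(rs, 0)
  mn <- min(rs, 0)
  # positive and negative extrema tying in magnitude (to within 1e-12)
  # resolve to the negative one
  es <- if (abs(mx) > abs(mn) + 1e-12) mx else mn
  if (es > 0) {
    pos <- which(rs == mx)[1]
    le <- ids[hit & seq_len(L) <= pos]
  } else if (es < 0) {
    pos <- which(rs == mn)[1]
    le <- ids[hit & seq_len(L) >= pos]
  } else {
    le <- character(0)
  }
  list(es = es, running_sum = rs, leading_edge = le)
}

# ES from hit positions only: O(H) once weights are precomputed. Used inside
# the permutation loop where the full running sum is not needed.
.es_from_hits <- function(w_all, hit_idx, L) {
  h <- sort.int(hit_idx)
  H <- length(h)
  wh <- w_all[h]
  nr <- sum(wh)
  inc <- if (nr > 0) wh / nr else rep(1 / H, H)
  m <- if (L > H) 1 / (L - H) else 0
  after <- cumsum(inc) - (h - seq_len(H)) * m
  before <- after - inc
  mx <- max(after, 0)
  mn <- min(before, 0)
  if (abs(mx) > abs(mn) + 1e-12) mx else mn
}

#' Preranked gene-set enrichment analysis
#'
#' Scores each gene set against a ranked list with the running-sum statistic
#' and calibrates it by gene-label permutation: set membership is reassigned
#' uniformly at random among the ranked genes, preserving set size. The
#' nominal p-value is the add-one-smoothed fraction of same-sign null scores
#' at least as extreme as the observed one; NES is the observed ES divided by
#' the mean magnitude of same-sign null scores; the FDR q-value compares each
#' NES against the pooled same-sign null NES distribution across all sets, in
#' the usual ratio-of-tail-fractions form, clipped to `[0, 1]`.
#'
#' @param ranked A [ranked_list()].
#' @param gene_sets Named list of character vectors.
#' @param n_perm Number of permutations (default 1000).
#' @param seed Integer seed; the caller's RNG state is restored on exit.
#' @param weight_exponent Passed to the running-sum statistic (default 1).
#' @param min_size,max_size Sets whose intersection with the ranked list
#'   falls outside `[min_size, max_size]` are dropped (defaults 5 and Inf).
#' @return List with `results` (data frame: `set`, `size`, `es`, `nes`, `p`,
#'   `fdr_q`) and `leading_edges` (named list).
#' @export
gsea_preranked <- function(ranked, gene_sets, n_perm = 1000, seed = 1,
                           weight_exponent = 1, min_size = 5,
                           max_size = Inf) {
  if (n_perm < 1) stop("n_perm must be >= 1")
  if (is.null(names(gene_sets)) || any(names(gene_sets) == ""))
    stop("gene_sets must be a named list")
  ids <- ranked$id
  L <- length(ids)
  w_all <- abs(ranked$score)^weight_exponent
  sizes <- vapply(gene_sets, function(s) sum(ids %in% s), integer(1))
  keep <- sizes >= min_size & sizes <= max_size
  if (!any(keep))
    stop("no gene set has an intersection within [min_size, max_size]")
  gene_sets <- gene_sets[keep]
  sizes <- sizes[keep]

  if (exists(".Random.seed", envir = .GlobalEnv)) {
    old_seed <- get(".Random.seed", envir = .GlobalEnv)
    on.exit(assign(".Random.seed", old_seed, envir = .GlobalEnv))
  }
  set.seed(seed)

  n_sets <- length(gene_sets)
  es <- numeric(n_sets); nes <- numeric(n_sets); p <- numeric(n_sets)
  les <- vector("list", n_sets)
  null_nes <- vector("list", n_sets)
  for (i in seq_len(n_sets)) {
    obs <- enrichment_score(ranked, gene_sets[[i]], weight_exponent)
    es[i] <- obs$es
    les[[i]] <- obs$leading_edge
    H <- sizes[i]
    null_es <- vapply(seq_len(n_perm), function(b)
      .es_from_hits(w_all, sample.int(L, H), L), numeric(1))
    same <- if (es[i] >= 0) null_es[null_es >= 0] else null_es[null_es < 0]
    p[i] <- (sum(abs(same) >= abs(es[i])) + 1) / (length(same) + 1)
    denom <- mean(abs(same))
    nes[i] <- if (length(same) > 0 && denom > 0) es[i] / denom else NA_real_
    pos_mean <- mean(null_es[null_es >= 0])
    neg_mean <- mean(abs(null_es[null_es < 0]))
    nn <- ifelse(null_es >= 0,
                 null_es / pos_mean,
                 null_es / neg_mean)
    null_nes[[i]] <- nn[is.finite(nn)]
  }
  pool <- unlist(null_nes)
  fdr_q <- vapply(seq_len(n_sets), function(i) {
    if (is.na(nes[i])) return(NA_real_)
    if (nes[i] >= 0) {
      tail_null <- pool[pool >= 0]
      num <- if (length(tail_null)) mean(tail_null >= nes[i]) else 1
      obs_pos <- nes[nes >= 0 & !is.na(nes)]
      den <- mean(obs_pos >= nes[i])
    } else {
      tail_null <- pool[pool < 0]
      num <- if (length(tail_null)) mean(tail_null <= nes[i]) else 1
      obs_neg <- nes[nes < 0 & !is.na(nes)]
      den <- mean(obs_neg <= nes[i])
    }
    if (den == 0) return(1)
    min(1, max(0, num / den))
  }, numeric(1))

  results <- data.frame(set = names(gene_sets), size = sizes,
                        es = es, nes = nes, p = p, fdr_q = fdr_q,
                        row.names = NULL)
  list(results = results,
       leading_edges = stats::setNames(les, names(gene_sets)))
}

#' Cross-species tissue relatedness matrix
#'
#' For each target-species tissue, genes are ranked by tissue specificity
#' ([rank_by_specificity()]) and every query-tissue enriched gene set
#' (already projected into the target id space) is scored by preranked GSEA.
#' The result is a query-tissue by target-tissue grid of NES, nominal p and
#' FDR q. A query set with too small an intersection with a target ranking
#' leaves that cell `NA` (not assessable) and the run continues.
#'
#' @param query_sets Named list: query tissue -> character vector of
#'   projected gene ids.
#' @param target_matrix Numeric matrix, rows = target-species gene ids,
#'   columns = target tissues.
#' @param n_perm Permutations per cell ranking (default 1000).
#' @param seed Integer seed; column `j` uses `seed + j - 1`.
#' @param pseudocount Passed to [rank_by_specificity()].
#' @param min_size Minimum query-set intersection (default 5).
#' @param weight_exponent Passed to the running-sum statistic.
#' @return Object of class `nes_matrix`: list of matrices `nes`, `p`, `fdr`
#'   (queries x targets).
#' @export
cross_species_matrix <- function(query_sets, target_matrix, n_perm = 1000,
                                 seed = 1, pseudocount = 1, min_size = 5,
                                 weight_exponent = 1) {
  queries <- names(query_sets)
  targets <- colnames(target_matrix)
  if (is.null(queries)) stop("query_sets must be a named list")
  shell <- matrix(NA_real_, length(queries), length(targets),
                  dimnames = list(queries, targets))
  out <- list(nes = shell, p = shell, fdr = shell)
  for (j in seq_along(targets)) {
    ranked <- rank_by_specificity(target_matrix, targets[j], pseudocount)
    assessable <- vapply(query_sets, function(s)
      sum(ranked$id %in% s) >= min_size, logical(1))
    if (!any(assessable)) next
    res <- gsea_preranked(ranked, query_sets[assessable], n_perm = n_perm,
                          seed = seed + j - 1,
                          weight_exponent = weight_exponent,
                          min_size = min_size)$results
    out$nes[res$set, j] <- res$nes
    out$p[res$set, j] <- res$p
    out$fdr[res$set, j] <- res$fdr_q
  }
  structure(out, class = "nes_matrix")
}

#' Significance annotation used in relatedness matrices
#'
#' @param p Numeric vector of nominal p-values.
#' @return `"**"` for p < 0.001, `"*"` for p < 0.05, `""` otherwise.
#' @export
significance_stars <- function(p) {
  ifelse(is.na(p), "", ifelse(p < 0.001, "**", ifelse(p < 0.05, "*", "")))
}

#' @export
print.nes_matrix <- function(x, digits = 2, ...) {
  cat("Tissue relatedness (NES; *: p<0.05, **: p<0.001; FDR q in brackets)\n")
  stars <- matrix(significance_stars(x$p), nrow = nrow(x$p))
  cells <- matrix(sprintf("%s%s [%s]", format(round(x$nes, digits)),
                          format(stars, width = 2),
                          format(round(x$fdr, digits + 1))),
                  nrow = nrow(x$nes),
                  dimnames = dimnames(x$nes))
  print(cells, quote = FALSE)
  invisible(x)
}
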