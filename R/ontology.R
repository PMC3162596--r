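#' GO slim classification counts
#'
#' Tallies, per namespace, how many genes of a list fall in each category. A
#' gene annotated to several categories contributes one count to each; a gene
#' with no annotation in a namespace is tallied under `"unknown function"` in
#' that namespace.
#'
#' @param genes Character vector of gene ids.
#' @param annotations Data frame with columns `term`, `namespace`, `gene`.
#' @return Data frame `namespace`, `term`, `n_genes`.
#' @export
classify_slim <- function(genes, annotations) {
  genes <- unique(as.character(genes))
  ann <- annotations[annotations$gene %in% genes, , drop = FALSE]
  namespaces <- unique(as.character(annotations$namespace))
  out <- list()
  for (ns in namespaces) {
    a <- ann[ann$namespace == ns, , drop = FALSE]
    a <- a[!duplicated(a[c("term", "gene")]), , drop = FALSE]
    tab <- table(a$term)
    unknown <- sum(!genes %in% a$gene)
    out[[ns]] <- data.frame(
      namespace = ns,
      term = c(names(tab), "unknown function"),
      n_genes = c(as.integer(tab), unknown),
      row.names = NULL)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Over-representation tail probability for one contingency table
#'
#' With a gene list of size `n` drawn from a background of size `N` of which
#' `K` belong to a term, the probability of observing `k` or more term
#' members in the list is the hypergeometric upper tail \eqn{P(X \ge k)}.
#' The EASE variant substitutes `k - 1` (floored at 0) for `k`.
#'
#' @param k Observed term members in the list.
#' @param n List size.
#' @param K Term members in the background.
#' @param N Background size.
#' @param method `"hypergeometric"` or `"ease"`.
#' @return Upper-tail probability (vectorized over `k`, `n`, `K`, `N`).
#' @export
hypergeom_overrep_p <- function(k, n, K, N,
                                method = c("hypergeometric", "ease")) {
  method <- match.arg(method)
  k_eff <- if (method == "ease") pmax(k - 1, 0) else k
  stats::phyper(k_eff - 1, K, N - K, n, lower.tail = FALSE)
}

#' Term over-representation statistics
#'
#' For each annotation term, tests whether the gene list contains more term
#' members than expected from the background. With list size `n`, background
#' size `N`, `K` background members of the term and `k` list members, the
#' hypergeometric p-value is the upper tail \eqn{P(X \ge k)} for
#' \eqn{X \sim Hypergeom(N, K, n)}. The EASE variant (DAVID's "modified
#' Fisher exact") removes one gene from the overlap — \eqn{P(X \ge k-1)},
#' floored at zero — which penalizes terms supported by a single gene.
#' Benjamini-Hochberg q-values are computed over all tested terms; terms with
#' no background members are skipped.
#'
#' @param list_ids Character vector: the gene list (must be a subset of the
#'   background).
#' @param background_ids Character vector: the background universe.
#' @param annotations Data frame with columns `term`, `namespace`, `gene`.
#' @param method `"hypergeometric"` or `"ease"`.
#' @return Data frame `term`, `namespace`, `k`, `n`, `K`, `N`, `fold`, `p`,
#'   `q`, ordered by `p`.
#' @export
term_enrichment <- function(list_ids, background_ids, annotations,
                            method = c("hypergeometric", "ease")) {
  method <- match.arg(method)
  list_ids <- unique(as.character(list_ids))
  background_ids <- unique(as.character(background_ids))
  if (!all(list_ids %in% background_ids))
    stop("gene list is not a subset of the background")
  if (length(background_ids) == 0L) stop("background is empty")
  ann <- annotations[annotations$gene %in% background_ids, , drop = FALSE]
  ann <- ann[!duplicated(ann[c("term", "gene")]), , drop = FALSE]
  terms <- unique(ann$term)
  N <- length(background_ids)
  n <- length(list_ids)
  rows <- lapply(terms, function(tm) {
    members <- ann$gene[ann$term == tm]
    K <- length(members)
    if (K == 0L) return(NULL)
    k <- sum(list_ids %in% members)
    p <- hypergeom_overrep_p(k, n, K, N, method)
    data.frame(term = tm,
               namespace = ann$namespace[match(tm, ann$term)],
               k = k, n = n, K = K, N = N,
               fold = (k / n) / (K / N),
               p = p, row.names = NULL)
  })
  res <- do.call(rbind, rows)
  if (is.null(res)) stop("no term has background members")
  res$q <- stats::p.adjust(res$p, method = "BH")
  res <- res[order(res$p, res$term), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Transcriptional energy distribution over functional categories
#'
#' Contrasts how genes are spread over categories (gene-count share) with how
#' the summed transcript abundance is spread (energy share): a category can
#' be gene-diverse yet transcriptionally quiet, or vice versa. Genes
#' annotated to several categories contribute fully to each; genes without
#' annotation are pooled in an `"unclassified"` bucket. Shares are fractions
#' of total contributions (categories plus the unclassified bucket) and sum
#' to 1.
#'
#' @param expr Named numeric vector of non-negative abundances (RPKM), names
#'   are gene ids.
#' @param annotations Data frame with columns `term`, `namespace`, `gene`.
#' @param namespace Optional: restrict to one namespace.
#' @return Data frame `category`, `n_genes`, `gene_count_share`,
#'   `rpkm_share`; the last row is the unclassified bucket.
#' @export
energy_distribution <- function(expr, annotations, namespace = NULL) {
  if (any(expr < 0)) stop("expression values must be >= 0")
  if (sum(expr) == 0) stop("all-zero expression: no energy to distribute")
  ann <- annotations
  if (!is.null(namespace))
    ann <- ann[ann$namespace == namespace, , drop = FALSE]
  ann <- ann[ann$gene %in% names(expr), , drop = FALSE]
  ann <- ann[!duplicated(ann[c("term", "gene")]), , drop = FALSE]
  terms <- sort(unique(ann$term))
  counts <- vapply(terms, function(tm) sum(ann$term == tm), integer(1))
  energy <- vapply(terms, function(tm)
    sum(expr[ann$gene[ann$term == tm]]), numeric(1))
  uncl <- setdiff(names(expr), ann$gene)
  counts <- c(counts, length(uncl))
  energy <- c(energy, sum(expr[uncl]))
  data.frame(category = c(terms, "unclassified"),
             n_genes = as.integer(counts),
             gene_count_share = counts / sum(counts),
             rpkm_share = energy / sum(energy),
             row.names = NULL)
}
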