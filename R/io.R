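#' Read a tab-separated table
#'
#' All pipeline tables are UTF-8, tab-separated with a single header line and
#' `NA` as the missing-value token.
#'
#' @param path File path.
#' @return Data frame.
#' @export
read_tsv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  utils::read.delim(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE, check.names = FALSE,
                    na.strings = "NA")
}

#' Write a tab-separated table
#'
#' @param df Data frame.
#' @param path File path.
#' @return Invisibly, `path`.
#' @export
write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE, na = "NA",
                     fileEncoding = "UTF-8", eol = "\n")
  invisible(path)
}

#' Read a transcript count table
#'
#' @param path TSV with columns `transcript_id`, `length_bp`, `read_count`
#'   (and optionally `cluster_id`).
#' @return Data frame.
#' @export
read_counts_table <- function(path) {
  df <- read_tsv(path)
  req <- c("transcript_id", "length_bp", "read_count")
  miss <- setdiff(req, names(df))
  if (length(miss))
    stop("counts table ", path, " missing column(s): ",
         paste(miss, collapse = ", "))
  df
}

#' Read/write an expression matrix
#'
#' Stored as a TSV whose first column (`cluster_id`) holds row ids and whose
#' remaining columns are tissues.
#'
#' @param path File path.
#' @return Numeric matrix with cluster row names.
#' @export
read_expression_matrix <- function(path) {
  df <- read_tsv(path)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "double"
  m
}

#' @rdname read_expression_matrix
#' @param mat Numeric matrix, rows = clusters, columns = tissues.
#' @export
write_expression_matrix <- function(mat, path) {
  df <- data.frame(cluster_id = rownames(mat), mat, check.names = FALSE,
                   row.names = NULL)
  write_tsv(df, path)
}

#' Parse gene sets in GMT format
#'
#' One set per line: name, description, then one or more member ids, all
#' tab-separated. Duplicate members within a line are collapsed with a
#' warning.
#'
#' @param path GMT file path.
#' @return Named list of character vectors.
#' @export
parse_gene_sets_gmt <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  sets <- list()
  for (i in seq_along(lines)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 3L)
      stop("GMT parse error at line ", i, ": fewer than 3 fields")
    members <- f[-(1:2)]
    if (anyDuplicated(members)) {
      warning("GMT line ", i, " ('", f[1], "'): duplicate members collapsed")
      members <- unique(members)
    }
    sets[[f[1]]] <- members
  }
  sets
}

#' Write gene sets in GMT format
#'
#' @param sets Named list of character vectors.
#' @param path Output path.
#' @param descriptions Optional character vector of per-set descriptions.
#' @return Invisibly, `path`.
#' @export
write_gene_sets_gmt <- function(sets, path, descriptions = NULL) {
  if (is.null(descriptions)) descriptions <- rep("na", length(sets))
  lines <- vapply(seq_along(sets), function(i)
    paste(c(names(sets)[i], descriptions[i], sets[[i]]), collapse = "\t"),
    character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Parse a two-column mapping table into a typed object
#'
#' @param path TSV path with a header line.
#' @param kind `"homology"` (columns `source`, `target`, optional `rank`),
#'   `"probe"` (columns `probe`, `cluster`) or `"annotation"` (columns
#'   `term`, `namespace`, `gene`).
#' @return A [homology_map()], a probe-map data frame, or an annotation data
#'   frame. Malformed rows (empty required fields) are rejected with a
#'   message reporting the count.
#' @export
parse_mapping_table <- function(path, kind = c("homology", "probe",
                                               "annotation")) {
  kind <- match.arg(kind)
  df <- read_tsv(path)
  req <- switch(kind,
                homology = c("source", "target"),
                probe = c("probe", "cluster"),
                annotation = c("term", "namespace", "gene"))
  miss <- setdiff(req, names(df))
  if (length(miss))
    stop(kind, " table ", path, " missing column(s): ",
         paste(miss, collapse = ", "))
  bad <- Reduce(`|`, lapply(df[req], function(x) is.na(x) | x == ""))
  if (any(bad)) {
    message(sum(bad), " malformed ", kind, " row(s) rejected")
    df <- df[!bad, , drop = FALSE]
  }
  if (kind == "homology") return(homology_map(df))
  rownames(df) <- NULL
  df[order(df[[req[1]]], df[[req[2]]]), , drop = FALSE]
}
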