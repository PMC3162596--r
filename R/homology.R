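#' Construct a homology map
#'
#' A homology map relates each source-species gene cluster to an ordered list
#' of target-species clusters. When the table carries no explicit `rank`
#' column, targets of a source are ranked lexicographically so that "first
#' homolog" is deterministic; an explicit rank column takes precedence.
#'
#' @param df Data frame with columns `source`, `target` and optionally
#'   `rank`.
#' @param species Target species tag (e.g. `"human"`, `"mouse"`).
#' @return A `homology_map`: the table sorted by (source, rank) with a
#'   `species` attribute.
#' @export
homology_map <- function(df, species = "human") {
  req <- c("source", "target")
  miss <- setdiff(req, names(df))
  if (length(miss)) stop("homology table missing column(s): ",
                         paste(miss, collapse = ", "))
  df$source <- as.character(df$source)
  df$target <- as.character(df$target)
  bad <- is.na(df$source) | is.na(df$target) |
    df$source == "" | df$target == ""
  if (any(bad)) {
    message(sum(bad), " malformed homology row(s) dropped")
    df <- df[!bad, , drop = FALSE]
  }
  if (!"rank" %in% names(df)) {
    df <- df[order(df$source, df$target), , drop = FALSE]
    df$rank <- stats::ave(seq_len(nrow(df)), df$source, FUN = seq_along)
  } else {
    df <- df[order(df$source, df$rank), , drop = FALSE]
  }
  rownames(df) <- NULL
  structure(df[, c("source", "target", "rank")],
            species = species, class = c("homology_map", "data.frame"))
}

#' First-listed homolog for each source cluster
#'
#' @param map A [homology_map()].
#' @return Named character vector: source id -> first-ranked target id.
#' @export
first_targets <- function(map) {
  stopifnot(inherits(map, "homology_map"))
  first <- map[!duplicated(map$source), , drop = FALSE]
  stats::setNames(first$target, first$source)
}

#' Collapse transcript quantifications to gene clusters
#'
#' Several transcript entries can map to one Unigene-style cluster; the
#' highest RPKM among them represents the cluster's expression level.
#' Transcripts without a cluster assignment are dropped (a message reports
#' how many).
#'
#' @param quants Data frame with `cluster_id` and `rpkm` columns.
#' @return Data frame with one row per cluster: `cluster_id`, `rpkm` (the
#'   maximum over member transcripts), sorted by cluster id.
#' @export
collapse_to_clusters <- function(quants) {
  if (!all(c("cluster_id", "rpkm") %in% names(quants)))
    stop("quants must carry cluster_id and rpkm columns")
  unassigned <- is.na(quants$cluster_id) | quants$cluster_id == ""
  if (any(unassigned)) {
    message(sum(unassigned), " transcript(s) without cluster assignment dropped")
    quants <- quants[!unassigned, , drop = FALSE]
  }
  if (nrow(quants) == 0L)
    return(data.frame(cluster_id = character(0), rpkm = numeric(0)))
  agg <- tapply(quants$rpkm, quants$cluster_id, max)
  data.frame(cluster_id = names(agg), rpkm = as.numeric(agg),
             row.names = NULL)
}

#' Project gene ids or an expression matrix across species
#'
#' Each source cluster with at least one homolog is replaced by its
#' first-listed target; sources without homologs are dropped. For id
#' vectors, duplicate targets are deduplicated keeping the first occurrence.
#' For matrices, when several sources project onto one target, the
#' representative row value is the per-column maximum (consistent with the
#' max-representative convention used when collapsing transcripts and
#' probes).
#'
#' @param x Character vector of source cluster ids, or a numeric matrix with
#'   source cluster ids as row names.
#' @param map A [homology_map()].
#' @return Projected id vector or matrix keyed by target ids.
#' @export
project_to_species <- function(x, map) {
  stopifnot(inherits(map, "homology_map"))
  ft <- first_targets(map)
  if (length(ft) == 0L) {
    warning("empty homology map: projection yields an empty result")
    if (is.matrix(x)) return(x[0, , drop = FALSE])
    return(character(0))
  }
  if (is.matrix(x)) {
    hit <- rownames(x) %in% names(ft)
    sub <- x[hit, , drop = FALSE]
    tgt <- unname(ft[rownames(sub)])
    out_ids <- unique(tgt)
    out <- matrix(-Inf, length(out_ids), ncol(x),
                  dimnames = list(out_ids, colnames(x)))
    for (i in seq_len(nrow(sub))) {
      t <- tgt[i]
      out[t, ] <- pmax(out[t, ], sub[i, ])
    }
    return(out)
  }
  x <- as.character(x)
  tgt <- unname(ft[x[x %in% names(ft)]])
  unique(tgt)
}

#' Collapse a probe-level signal matrix to gene clusters
#'
#' Microarray platforms carry several probes per gene cluster; the maximum
#' signal intensity over a cluster's probes represents its expression in
#' each tissue. Probes not present in the map are dropped (a message reports
#' how many).
#'
#' @param probe_matrix Numeric matrix, rows = probe ids, columns = tissues.
#' @param probe_map Data frame with columns `probe`, `cluster`.
#' @return Numeric matrix keyed by cluster ids.
#' @export
collapse_probe_signals <- function(probe_matrix, probe_map) {
  if (!all(c("probe", "cluster") %in% names(probe_map)))
    stop("probe map must carry probe and cluster columns")
  pm <- stats::setNames(as.character(probe_map$cluster),
                        as.character(probe_map$probe))
  mapped <- rownames(probe_matrix) %in% names(pm)
  if (any(!mapped))
    message(sum(!mapped), " unmapped probe(s) dropped")
  sub <- probe_matrix[mapped, , drop = FALSE]
  cl <- unname(pm[rownames(sub)])
  out_ids <- sort(unique(cl))
  out <- matrix(-Inf, length(out_ids), ncol(probe_matrix),
                dimnames = list(out_ids, colnames(probe_matrix)))
  for (i in seq_len(nrow(sub))) {
    out[cl[i], ] <- pmax(out[cl[i], ], sub[i, ])
  }
  out
}
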