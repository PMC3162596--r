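#' Configuration for the synthetic multi-tissue expression generator
#'
#' Defaults emulate the study design the pipeline is built for: four pooled
#' zebrafish tissues (swimbladder, brain, heart, head kidney), one deeply
#' sequenced library per tissue, a log-normal baseline abundance spanning
#' several orders of magnitude, and disjoint modules of tissue-enriched genes
#' planted at a known fold change.
#'
#' @param seed Integer seed; all downstream generators derive their streams
#'   from it.
#' @param n_genes Number of gene clusters.
#' @param tissue_labels Character vector of at least 2 tissue names.
#' @param n_enriched_per_tissue Planted enriched genes per tissue (disjoint
#'   across tissues).
#' @param log2_fold Planted log2 fold change in the gene's own tissue
#'   (default 3, i.e. 8-fold).
#' @param baseline_log_mean,baseline_log_sd Parameters of the log-normal
#'   baseline abundance (natural-log scale). The defaults (3, 1.5) give a
#'   median near 20 RPKM and a dynamic range of several orders of magnitude.
#' @param noise_cv Coefficient of variation of multiplicative (log-normal,
#'   mean 1) per-cell abundance noise. With one pooled library per tissue no
#'   biological-replicate variance is estimable from the emulated design;
#'   this is a free parameter (default 0.25).
#' @param total_reads_per_tissue Library size per tissue (default 1e7).
#' @param length_range_bp Integer (min, max) transcript length range.
#' @param homolog_coverage Fraction of source genes with at least one
#'   homolog.
#' @param multi_homolog_fraction Fraction of mapped genes with two homologs.
#' @param n_terms Number of annotation terms.
#' @param term_overlap Members a planted term shares with its tissue's
#'   enriched set.
#' @param unannotated_fraction Fraction of genes with no annotation (default
#'   0.4).
#' @return Validated list of class `synthetic_config`.
#' @export
synthetic_config <- function(seed = 1,
                             n_genes = 5000,
                             tissue_labels = c("swimbladder", "brain",
                                               "heart", "kidney"),
                             n_enriched_per_tissue = 200,
                             log2_fold = 3,
                             baseline_log_mean = 3,
                             baseline_log_sd = 1.5,
                             noise_cv = 0.25,
                             total_reads_per_tissue = 1e7,
                             length_range_bp = c(500L, 3000L),
                             homolog_coverage = 0.8,
                             multi_homolog_fraction = 0.2,
                             n_terms = 50,
                             term_overlap = 20,
                             unannotated_fraction = 0.4) {
  cfg <- list(seed = as.integer(seed), n_genes = as.integer(n_genes),
              tissue_labels = as.character(tissue_labels),
              n_enriched_per_tissue = as.integer(n_enriched_per_tissue),
              log2_fold = log2_fold,
              baseline_log_mean = baseline_log_mean,
              baseline_log_sd = baseline_log_sd,
              noise_cv = noise_cv,
              total_reads_per_tissue = as.double(total_reads_per_tissue),
              length_range_bp = as.integer(length_range_bp),
              homolog_coverage = homolog_coverage,
              multi_homolog_fraction = multi_homolog_fraction,
              n_terms = as.integer(n_terms),
              term_overlap = as.integer(term_overlap),
              unannotated_fraction = unannotated_fraction)
  if (length(cfg$tissue_labels) < 2L)
    stop("invalid config: tissue_labels needs at least 2 tissues")
  if (cfg$n_enriched_per_tissue * length(cfg$tissue_labels) > cfg$n_genes)
    stop("invalid config: n_enriched_per_tissue x tissues exceeds n_genes")
  if (cfg$log2_fold < 0) stop("invalid config: log2_fold must be >= 0")
  if (cfg$noise_cv < 0) stop("invalid config: noise_cv must be >= 0")
  if (length(cfg$length_range_bp) != 2L || cfg$length_range_bp[1] < 1L ||
      cfg$length_range_bp[2] < cfg$length_range_bp[1])
    stop("invalid config: length_range_bp must be (min >= 1, max >= min)")
  if (cfg$total_reads_per_tissue < 0)
    stop("invalid config: total_reads_per_tissue must be >= 0")
  for (f in c("homolog_coverage", "multi_homolog_fraction",
              "unannotated_fraction")) {
    if (cfg[[f]] < 0 || cfg[[f]] > 1)
      stop("invalid config: ", f, " must lie in [0, 1]")
  }
  structure(cfg, class = "synthetic_config")
}

# Deterministic per-stage seeds derived from the single config seed, kept
# below 2^31.
.stage_seed <- function(cfg, stage) {
  offset <- c(profiles = 0L, counts = 1L, homology = 2L,
              annotations = 3L, target = 4L)[[stage]]
  (cfg$seed %% 2147480000L) + offset
}

.with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = .GlobalEnv)) {
    old <- get(".Random.seed", envir = .GlobalEnv)
    on.exit(assign(".Random.seed", old, envir = .GlobalEnv))
  }
  set.seed(seed)
  expr
}

#' Generate true multi-tissue abundance profiles with planted modules
#'
#' Baseline abundance per gene is log-normal(`baseline_log_mean`,
#' `baseline_log_sd`). Each tissue receives a disjoint set of
#' `n_enriched_per_tissue` planted genes whose abundance is multiplied by
#' `2^log2_fold` in that tissue only. Multiplicative log-normal noise with
#' mean 1 and coefficient of variation `noise_cv` is applied per cell.
#'
#' @param config A [synthetic_config()].
#' @return List: `matrix` (genes x tissues, true RPKM) and `truth` (list with
#'   `enriched_sets`, a named list of planted gene ids per tissue).
#' @export
generate_tissue_profiles <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  .with_seed(.stage_seed(config, "profiles"), {
    n <- config$n_genes
    tissues <- config$tissue_labels
    ids <- sprintf("g%05d", seq_len(n))
    baseline <- stats::rlnorm(n, config$baseline_log_mean,
                              config$baseline_log_sd)
    mat <- matrix(baseline, n, length(tissues),
                  dimnames = list(ids, tissues))
    k <- config$n_enriched_per_tissue
    planted <- if (k > 0) sample.int(n, k * length(tissues)) else integer(0)
    enriched_sets <- stats::setNames(vector("list", length(tissues)),
                                     tissues)
    for (t in seq_along(tissues)) {
      idx <- planted[seq_len(k) + (t - 1L) * k]
      enriched_sets[[t]] <- ids[sort(idx)]
      mat[idx, t] <- mat[idx, t] * 2^config$log2_fold
    }
    if (config$noise_cv > 0) {
      sdl <- sqrt(log(1 + config$noise_cv^2))
      noise <- stats::rlnorm(length(mat), -sdl^2 / 2, sdl)
      mat <- mat * matrix(noise, nrow(mat), ncol(mat))
    }
    list(matrix = mat, truth = list(enriched_sets = enriched_sets))
  })
}

#' Sample per-tissue read-count tables from true abundances
#'
#' Inverts the RPKM formula: a transcript of length `L` bp at abundance `r`
#' RPKM in a library of `N` reads is expected to receive `r * L * N / 1e9`
#' reads; realized counts are Poisson with that mean. Transcript lengths are
#' drawn uniformly within `length_range_bp` (one length per gene, shared
#' across tissues).
#'
#' @param truth_matrix Numeric matrix of true RPKM (genes x tissues), values
#'   must be non-negative.
#' @param config A [synthetic_config()].
#' @return Named list (one element per tissue) of data frames with columns
#'   `transcript_id`, `cluster_id`, `length_bp`, `read_count`.
#' @export
sample_read_counts <- function(truth_matrix, config) {
  stopifnot(inherits(config, "synthetic_config"))
  if (any(truth_matrix < 0)) stop("abundance values must be >= 0")
  .with_seed(.stage_seed(config, "counts"), {
    n <- nrow(truth_matrix)
    lr <- config$length_range_bp
    len <- sample.int(lr[2] - lr[1] + 1L, n, replace = TRUE) + lr[1] - 1L
    lapply(stats::setNames(colnames(truth_matrix),
                           colnames(truth_matrix)), function(tis) {
      lambda <- truth_matrix[, tis] * len *
        config$total_reads_per_tissue / 1e9
      data.frame(transcript_id = rownames(truth_matrix),
                 cluster_id = rownames(truth_matrix),
                 length_bp = len,
                 read_count = stats::rpois(n, lambda),
                 row.names = NULL)
    })
  })
}

#' Generate a partially many-to-many homology map
#'
#' A fraction `homolog_coverage` of source genes receives at least one target
#' id; among those, a fraction `multi_homolog_fraction` receives a second
#' target (rank 2). Target ids are derived deterministically from source ids.
#'
#' @param config A [synthetic_config()].
#' @return A [homology_map()] with columns `source`, `target`, `rank`.
#' @export
generate_homology_map <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  .with_seed(.stage_seed(config, "homology"), {
    ids <- sprintf("g%05d", seq_len(config$n_genes))
    mapped <- stats::runif(config$n_genes) < config$homolog_coverage
    src <- ids[mapped]
    multi <- stats::runif(length(src)) < config$multi_homolog_fraction
    second <- src[multi]
    df <- data.frame(
      source = c(src, second),
      target = c(if (length(src)) paste0("HS_", src) else character(0),
                 if (length(second)) paste0("HS_", second, "_b")
                 else character(0)),
      rank = c(rep(1L, length(src)), rep(2L, length(second))),
      row.names = NULL)
    homology_map(df, species = "human")
  })
}

#' Generate annotation terms overlapping the planted modules
#'
#' Creates `n_terms` terms spread over the three GO namespaces. The first
#' terms are "planted": one per tissue, each containing exactly
#' `term_overlap` members of that tissue's enriched set plus background
#' genes. A fraction `unannotated_fraction` of genes belongs to no term.
#'
#' @param config A [synthetic_config()].
#' @param truth Truth list from [generate_tissue_profiles()].
#' @return List: `annotations` (data frame `term`, `namespace`, `gene`) and
#'   `term_plants` (named character: planted term -> tissue).
#' @export
generate_annotations <- function(config, truth) {
  stopifnot(inherits(config, "synthetic_config"))
  .with_seed(.stage_seed(config, "annotations"), {
    ids <- sprintf("g%05d", seq_len(config$n_genes))
    tissues <- config$tissue_labels
    namespaces <- c("Biological Process", "Molecular Function",
                    "Cellular Component")
    n_terms <- config$n_terms
    if (n_terms < 1) stop("invalid config: n_terms must be >= 1")
    sizes <- vapply(truth$enriched_sets, length, integer(1))
    ov <- config$term_overlap
    plant_tissues <- tissues[seq_len(min(length(tissues), n_terms))]
    if (ov > 0 && any(sizes[plant_tissues] < ov))
      stop("term_overlap exceeds the size of an enriched set")

    # unannotated pool, excluding genes a planted term must contain
    planted_members <- unlist(lapply(plant_tissues, function(tis)
      truth$enriched_sets[[tis]][seq_len(ov)]), use.names = FALSE)
    n_unann <- round(config$unannotated_fraction * config$n_genes)
    eligible <- setdiff(ids, planted_members)
    if (n_unann > length(eligible))
      stop("unannotated_fraction leaves too few genes to annotate")
    unannotated <- sample(eligible, n_unann)
    annotatable <- setdiff(ids, unannotated)

    rows <- list()
    term_plants <- character(0)
    for (i in seq_len(n_terms)) {
      term <- sprintf("T%03d", i)
      ns <- namespaces[(i - 1L) %% length(namespaces) + 1L]
      if (i <= length(plant_tissues) && ov > 0) {
        tis <- plant_tissues[i]
        core <- truth$enriched_sets[[tis]][seq_len(ov)]
        pool <- setdiff(annotatable, unlist(truth$enriched_sets))
        extra <- sample(pool, min(length(pool), ov))
        members <- c(core, extra)
        term_plants[term] <- tis
      } else {
        members <- sample(annotatable,
                          min(length(annotatable),
                              max(5L, stats::rpois(1, 20))))
      }
      rows[[i]] <- if (length(members)) {
        data.frame(term = term, namespace = ns, gene = members,
                   row.names = NULL)
      } else {
        data.frame(term = character(0), namespace = character(0),
                   gene = character(0))
      }
    }
    ann <- do.call(rbind, rows)
    # genes in no term so far (other than the deliberately unannotated ones)
    # receive one membership each so the unannotated fraction is as
    # configured
    orphan <- setdiff(annotatable, ann$gene)
    if (length(orphan)) {
      plain <- setdiff(sprintf("T%03d", seq_len(n_terms)),
                       names(term_plants))
      if (!length(plain)) plain <- sprintf("T%03d", n_terms)
      add <- data.frame(term = sample(plain, length(orphan), replace = TRUE),
                        namespace = NA_character_, gene = orphan,
                        row.names = NULL)
      add$namespace <- namespaces[(match(add$term,
                                         sprintf("T%03d", seq_len(n_terms)))
                                   - 1L) %% length(namespaces) + 1L]
      ann <- rbind(ann, add)
    }
    ann <- ann[!duplicated(ann[c("term", "gene")]), , drop = FALSE]
    ann <- ann[order(ann$term, ann$gene), , drop = FALSE]
    rownames(ann) <- NULL
    list(annotations = ann, term_plants = term_plants)
  })
}

#' Synthetic expression matrix for a second ("target") species
#'
#' Projects the true source abundance matrix through the homology map (first
#' homolog, max on collisions) and applies fresh multiplicative noise, giving
#' a matched-structure matrix keyed by target-species ids — a stand-in for an
#' independently measured tissue panel in the other species.
#'
#' @param profiles Output of [generate_tissue_profiles()].
#' @param map A [homology_map()].
#' @param config A [synthetic_config()].
#' @return Numeric matrix keyed by target ids.
#' @export
generate_target_matrix <- function(profiles, map, config) {
  stopifnot(inherits(config, "synthetic_config"))
  proj <- project_to_species(profiles$matrix, map)
  .with_seed(.stage_seed(config, "target"), {
    if (config$noise_cv > 0) {
      sdl <- sqrt(log(1 + config$noise_cv^2))
      proj <- proj * matrix(stats::rlnorm(length(proj), -sdl^2 / 2, sdl),
                            nrow(proj), ncol(proj))
    }
    proj
  })
}

#' Write a complete synthetic fixture bundle to disk
#'
#' Generates profiles, per-tissue count tables, the homology map, the
#' annotation table and a target-species matrix, and writes them as
#' tab-separated files plus a JSON truth record. Identical configurations
#' produce byte-identical bundles.
#'
#' @param config A [synthetic_config()].
#' @param dir Output directory (created if absent).
#' @return Invisibly, a named list of file paths plus the in-memory objects.
#' @export
write_fixture_bundle <- function(config, dir) {
  stopifnot(inherits(config, "synthetic_config"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  profiles <- generate_tissue_profiles(config)
  counts <- sample_read_counts(profiles$matrix, config)
  map <- generate_homology_map(config)
  ann <- generate_annotations(config, profiles$truth)
  target <- generate_target_matrix(profiles, map, config)

  paths <- list(expression = file.path(dir, "expression.tsv"),
                homologs = file.path(dir, "homologs.tsv"),
                annotations = file.path(dir, "annotations.tsv"),
                target_expression = file.path(dir, "target_expression.tsv"),
                truth = file.path(dir, "truth.json"))
  write_expression_matrix(profiles$matrix, paths$expression)
  write_tsv(as.data.frame(map), paths$homologs)
  write_tsv(ann$annotations, paths$annotations)
  write_expression_matrix(target, paths$target_expression)
  for (tis in names(counts)) {
    p <- file.path(dir, paste0("counts_", tis, ".tsv"))
    write_tsv(counts[[tis]], p)
    paths[[paste0("counts_", tis)]] <- p
  }
  truth <- list(enriched_sets = profiles$truth$enriched_sets,
                term_plants = as.list(ann$term_plants),
                homolog_map_truth = split(map$target, map$source))
  jsonlite::write_json(truth, paths$truth, auto_unbox = FALSE, pretty = TRUE)
  invisible(c(paths, list(config = config, profiles = profiles,
                          counts = counts, map = map,
                          annotations = ann$annotations,
                          term_plants = ann$term_plants,
                          target_matrix = target)))
}
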