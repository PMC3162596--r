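test_that("config invariants are enforced with the offending field named", {
  expect_error(synthetic_config(tissue_labels = "one"), "tissue_labels")
  expect_error(synthetic_config(n_genes = 10, n_enriched_per_tissue = 5),
               "n_enriched_per_tissue")
  expect_error(synthetic_config(log2_fold = -1), "log2_fold")
  expect_error(synthetic_config(noise_cv = -0.1), "noise_cv")
  expect_error(synthetic_config(length_range_bp = c(0, 10)),
               "length_range_bp")
  expect_error(synthetic_config(homolog_coverage = 1.2), "homolog_coverage")
})

test_that("profiles are seeded, planted disjointly and truth-contained", {
  cfg <- small_config(seed = 7)
  a <- generate_tissue_profiles(cfg)
  b <- generate_tissue_profiles(cfg)
  expect_identical(a, b)
  sets <- a$truth$enriched_sets
  expect_equal(length(unique(unlist(sets))), length(unlist(sets)))
  expect_true(all(unlist(sets) %in% rownames(a$matrix)))
  # zero planted genes: truth sets empty
  none <- generate_tissue_profiles(small_config(n_enriched_per_tissue = 0))
  expect_true(all(lengths(none$truth$enriched_sets) == 0))
})

test_that("a zero fold change is a no-op on the marginal distribution", {
  cfg0 <- small_config(seed = 2, log2_fold = 0, noise_cv = 0)
  prof <- generate_tissue_profiles(cfg0)
  planted <- prof$truth$enriched_sets$swimbladder
  expect_gt(length(planted), 0)
  # with fold 1 and no noise every tissue column equals the baseline
  expect_true(all(prof$matrix[, 1] == prof$matrix[, 2]))
})

test_that("planted genes carry the configured fold change on average", {
  cfg <- synthetic_config(seed = 7, n_genes = 2000,
                          n_enriched_per_tissue = 120, log2_fold = 3)
  prof <- generate_tissue_profiles(cfg)
  planted <- prof$truth$enriched_sets$swimbladder
  expect_gte(length(planted), 100)
  ratios <- prof$matrix[planted, "swimbladder"] /
    rowMeans(prof$matrix[planted, c("brain", "heart", "kidney")])
  expect_lt(abs(mean(ratios) - 8) / 8, 0.20)
})

test_that("read counts are Poisson around rpkm * L * N / 1e9 and seeded", {
  cfg <- small_config(seed = 4)
  prof <- generate_tissue_profiles(cfg)
  a <- sample_read_counts(prof$matrix, cfg)
  b <- sample_read_counts(prof$matrix, cfg)
  expect_identical(a, b)
  # zero depth: all counts zero
  cfg0 <- small_config(total_reads_per_tissue = 0)
  z <- sample_read_counts(generate_tissue_profiles(cfg0)$matrix, cfg0)
  expect_true(all(z[[1]]$read_count == 0))
  expect_error(sample_read_counts(matrix(-1, 1, 2), cfg), ">= 0")
})

test_that("count sampling hits the Poisson mean rpkm*L*N/1e9", {
  # rpkm 100, L 1000, N 1e6 -> mean 100; check 1000 draws within 3 SE
  cfg <- synthetic_config(seed = 8, n_genes = 1000,
                          n_enriched_per_tissue = 0, noise_cv = 0,
                          tissue_labels = c("a", "b"),
                          total_reads_per_tissue = 1e6,
                          length_range_bp = c(1000L, 1000L))
  truth <- matrix(100, 1000, 2,
                  dimnames = list(sprintf("g%05d", 1:1000), c("a", "b")))
  counts <- sample_read_counts(truth, cfg)
  m <- mean(counts$a$read_count)
  expect_lt(abs(m - 100), 3 * sqrt(100 / 1000))
  # conservation: the per-tissue total matches sum(rpkm * L) * N / 1e9
  expect_lt(abs(sum(counts$a$read_count) - 1000 * 100),
            4 * sqrt(1000 * 100))
})

test_that("homology map respects coverage and multiplicity settings", {
  # zero coverage: empty map
  z <- generate_homology_map(small_config(homolog_coverage = 0))
  expect_equal(nrow(z), 0L)
  # full coverage, no multi-homolog rows: a bijection
  bij <- generate_homology_map(small_config(homolog_coverage = 1,
                                            multi_homolog_fraction = 0))
  expect_equal(nrow(bij), 400L)
  expect_equal(anyDuplicated(bij$source), 0L)
  expect_equal(anyDuplicated(bij$target), 0L)
  # coverage 0.8 on 1000 genes within binomial 99% bounds
  cfg <- synthetic_config(seed = 3, n_genes = 1000,
                          n_enriched_per_tissue = 0, homolog_coverage = 0.8)
  map <- generate_homology_map(cfg)
  frac <- length(unique(map$source)) / 1000
  bound <- qnorm(0.995) * sqrt(0.8 * 0.2 / 1000)
  expect_lt(abs(frac - 0.8), bound)
  expect_identical(map, generate_homology_map(cfg))
})

test_that("annotations honour planted overlap and the unannotated fraction", {
  cfg <- small_config(seed = 9)
  prof <- generate_tissue_profiles(cfg)
  ann <- generate_annotations(cfg, prof$truth)
  for (term in names(ann$term_plants)) {
    tis <- ann$term_plants[[term]]
    members <- ann$annotations$gene[ann$annotations$term == term]
    expect_equal(length(intersect(members, prof$truth$enriched_sets[[tis]])),
                 cfg$term_overlap)
  }
  # overlap larger than the enriched set is a configuration error
  bad <- small_config(term_overlap = 30, n_enriched_per_tissue = 5)
  expect_error(generate_annotations(bad, generate_tissue_profiles(bad)$truth),
               "term_overlap")
  # fully unannotated config yields empty terms (no planted overlap)
  cfg1 <- small_config(unannotated_fraction = 1, term_overlap = 0)
  ann1 <- generate_annotations(cfg1, generate_tissue_profiles(cfg1)$truth)
  expect_equal(nrow(ann1$annotations), 0L)
})

test_that("the observed unannotated fraction tracks the configured one", {
  cfg <- synthetic_config(seed = 5, n_genes = 10000,
                          n_enriched_per_tissue = 100,
                          unannotated_fraction = 0.4)
  prof <- generate_tissue_profiles(cfg)
  ann <- generate_annotations(cfg, prof$truth)
  ids <- rownames(prof$matrix)
  observed <- mean(!ids %in% ann$annotations$gene)
  expect_lt(abs(observed - 0.4), 0.02)
})

test_that("a fixture bundle is byte-identical across reruns", {
  cfg <- small_config(seed = 12)
  d1 <- file.path(tempdir(), "bundle1")
  d2 <- file.path(tempdir(), "bundle2")
  write_fixture_bundle(cfg, d1)
  write_fixture_bundle(cfg, d2)
  files <- list.files(d1)
  expect_true(length(files) >= 5)
  for (f in files) {
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))),
                     label = f)
  }
  unlink(c(d1, d2), recursive = TRUE)
})
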