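test_that("ranking by -log10 p puts exclusive genes first and breaks ties by id", {
  e <- data.frame(cluster_id = c("b", "a", "c", "x"),
                  p = c(0.01, 0.001, 0.05, NA),
                  exclusive = c(FALSE, FALSE, FALSE, TRUE))
  r <- rank_by_neglog_p(e)
  expect_equal(r$id, c("x", "a", "b", "c"))
  expect_equal(r$score[2:4], c(3, 2, -log10(0.05)), tolerance = 1e-12)
  expect_equal(r$score[1], 4)  # max finite score + 1
  # equal p: adjacent, ordered by id
  e2 <- data.frame(cluster_id = c("zz", "aa"), p = c(0.01, 0.01),
                   exclusive = FALSE)
  expect_equal(rank_by_neglog_p(e2)$id, c("aa", "zz"))
  expect_error(rank_by_neglog_p(e2[0, ]), "empty")
})

test_that("specificity ranking is a log ratio to the mean of other tissues", {
  mat <- rbind(g1 = c(80, 12, 8), g2 = c(10, 10, 10))
  colnames(mat) <- c("lung", "brain", "heart")
  r <- rank_by_specificity(mat, "lung", pseudocount = 1)
  expect_equal(r$score[r$id == "g1"], log2(81 / 11), tolerance = 1e-12)
  expect_equal(log2(81 / 11), 2.880, tolerance = 1e-3)
  # identical columns: all scores zero
  same <- matrix(5, 3, 3, dimnames = list(paste0("g", 1:3),
                                          c("a", "b", "c")))
  expect_true(all(rank_by_specificity(same, "a")$score == 0))
  # global rescaling preserves the ordering
  r2 <- rank_by_specificity(mat * 37, "lung")
  expect_equal(r2$id, r$id)
})

test_that("the running sum reproduces the step-by-step example", {
  r <- ranked_list(paste0("g", 1:5), c(5, 4, 3, 2, 1))
  es <- enrichment_score(r, c("g1", "g3"))
  expect_equal(es$running_sum,
               c(0.625, 0.625 - 1/3, 0.625 - 1/3 + 3/8, 2/3 - 1/3, 0),
               tolerance = 1e-12)
  expect_equal(es$es, 2/3, tolerance = 1e-12)
  expect_setequal(es$leading_edge, c("g1", "g3"))
  # full set: no misses, the sum peaks at exactly 1
  expect_equal(enrichment_score(r, paste0("g", 1:5))$es, 1)
  # a single top gene with positive scores reaches 1 at the first step
  expect_equal(enrichment_score(r, "g1")$es, 1)
  expect_error(enrichment_score(r, "absent"), "no member")
})

test_that("ES equals the exhaustive oracle on small lists and sets", {
  set.seed(31)
  for (L in 3:8) {
    ids <- paste0("g", 1:L)
    scores <- sort(rnorm(L, 0, 3), decreasing = TRUE)
    r <- ranked_list(ids, scores)
    for (size in 1:min(3, L)) {
      for (rep in 1:5) {
        set <- sample(ids, size)
        mine <- enrichment_score(r, set)
        orac <- oracle_running_sum(r$id, r$score, set)
        expect_equal(mine$es, orac$es, tolerance = 1e-12)
        expect_equal(mine$running_sum, orac$running_sum, tolerance = 1e-12)
        expect_setequal(mine$leading_edge, orac$leading_edge)
        expect_lte(abs(mine$es), 1)
      }
    }
  }
})

test_that("reversing score signs and list order negates the ES", {
  set.seed(57)
  for (rep in 1:10) {
    ids <- paste0("g", 1:12)
    scores <- rnorm(12, 0, 2)
    set <- sample(ids, 4)
    a <- enrichment_score(ranked_list(ids, scores), set)
    b <- enrichment_score(ranked_list(ids, -scores), set)
    expect_equal(a$es, -b$es, tolerance = 1e-12)
  }
})

test_that("ES agrees with an independent reference implementation", {
  skip_if_not_installed("fgsea")
  set.seed(101)
  for (rep in 1:20) {
    L <- sample(20:60, 1)
    ids <- paste0("g", 1:L)
    r <- ranked_list(ids, rnorm(L, 0, 2))
    set <- sample(ids, sample(4:10, 1))
    mine <- enrichment_score(r, set)$es
    ref <- fgsea::calcGseaStat(stats::setNames(r$score, r$id),
                               selectedStats = which(r$id %in% set),
                               gseaParam = 1)
    expect_equal(mine, ref, tolerance = 1e-10)
  }
})

test_that("preranked GSEA is seeded, sign-consistent and bounded", {
  set.seed(71)
  ids <- paste0("g", 1:300)
  scores <- sort(rnorm(300, 0, 2), decreasing = TRUE)
  r <- ranked_list(ids, scores)
  sets <- list(top = ids[1:15],                 # concentrated at the head
               bottom = ids[286:300],           # concentrated at the tail
               spread = ids[seq(10, 290, by = 20)])
  a <- gsea_preranked(r, sets, n_perm = 300, seed = 5)
  b <- gsea_preranked(r, sets, n_perm = 300, seed = 5)
  expect_identical(a$results, b$results)
  res <- a$results
  expect_true(all(sign(res$nes) == sign(res$es)))
  expect_true(all(res$fdr_q >= 0 & res$fdr_q <= 1))
  expect_gt(res$es[res$set == "top"], 0)
  expect_lt(res$es[res$set == "bottom"], 0)
  expect_lt(res$p[res$set == "top"], 0.05)
  # sets below the intersection floor are dropped
  expect_error(gsea_preranked(r, list(tiny = ids[1:2]), n_perm = 10),
               "min_size")
})

test_that("nominal p approximates the exhaustive placement null on tiny lists", {
  # list of 10, set of 2: all C(10,2)=45 placements enumerable
  ids <- paste0("g", 1:10)
  scores <- c(9, 7, 6, 5, 4, 3.5, 3, 2, 1.5, 1)
  r <- ranked_list(ids, scores)
  set <- c("g1", "g2")
  obs <- enrichment_score(r, set)$es
  combs <- combn(10, 2)
  null_es <- apply(combs, 2, function(ix)
    oracle_running_sum(r$id, r$score, ids[ix])$es)
  same <- null_es[sign(null_es) == sign(obs) | null_es == 0]
  exact_p <- mean(abs(same) >= abs(obs))
  res <- gsea_preranked(r, list(s = set), n_perm = 2000, seed = 9,
                        min_size = 2)$results
  # binomial Monte-Carlo tolerance at 2000 permutations
  expect_lt(abs(res$p - exact_p), 3 * sqrt(exact_p * (1 - exact_p) / 2000)
            + 2 / 2000)
})

test_that("cross-species matrix finds planted matches and flags empty cells", {
  cfg <- small_config(seed = 11, n_genes = 600,
                      n_enriched_per_tissue = 30,
                      tissue_labels = c("swimbladder", "brain", "heart"))
  prof <- generate_tissue_profiles(cfg)
  map <- generate_homology_map(cfg)
  target <- generate_target_matrix(prof, map, cfg)
  queries <- lapply(prof$truth$enriched_sets, project_to_species, map = map)
  nm <- cross_species_matrix(queries, target, n_perm = 200, seed = 13)
  expect_s3_class(nm, "nes_matrix")
  for (tis in rownames(nm$nes)) {
    expect_equal(names(which.max(nm$nes[tis, ])), tis)
    expect_lt(nm$p[tis, tis], 0.05)
  }
  expect_true(all(nm$fdr >= 0 & nm$fdr <= 1, na.rm = TRUE))
  # a query disjoint from the target ids is not assessable
  queries$alien <- paste0("ZZ", 1:30)
  nm2 <- cross_species_matrix(queries, target, n_perm = 50, seed = 13)
  expect_true(all(is.na(nm2$nes["alien", ])))
  expect_output(print(nm2), "NES")
})

test_that("identical target columns give equal cells up to permutation noise", {
  set.seed(3)
  ids <- sprintf("h%03d", 1:200)
  col <- rlnorm(200, 2, 1)
  tm <- cbind(t1 = col, t2 = col, t3 = col)
  rownames(tm) <- ids
  queries <- list(q = ids[1:20])
  nm <- cross_species_matrix(queries, tm, n_perm = 200, seed = 4)
  # all scores are 0 in every ranking, so ES is identical across columns
  expect_equal(nm$nes["q", "t1"], nm$nes["q", "t2"], tolerance = 0.3)
  expect_equal(nm$nes["q", "t1"], nm$nes["q", "t3"], tolerance = 0.3)
})
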