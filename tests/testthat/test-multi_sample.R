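test_that("clonal_space_homeostasis bins mass by clone frequency", {
  r <- rep_from_counts(c(50, 30, 15, 5))
  h <- clonal_space_homeostasis(r)
  expect_equal(unname(h$mass_per_bin["hyperexpanded"]), 0.95)
  expect_equal(unname(h$mass_per_bin["expanded"]), 0.05)
  expect_equal(sum(h$mass_per_bin), 1, tolerance = 1e-9)
  expect_equal(sum(h$reads_per_bin), r$total_reads)

  single <- rep_from_counts(1000)
  hs <- clonal_space_homeostasis(single)
  expect_equal(unname(hs$mass_per_bin["hyperexpanded"]), 1)

  expect_error(clonal_space_homeostasis(r, bin_edges = c(0.5, 0.4, 1)),
               "ascending")
  expect_error(clonal_space_homeostasis(r, bin_edges = c(0.5, 0.9)),
               "final edge 1")
})

test_that("homeostasis masses equal a brute-force per-clone scan", {
  edges <- default_homeostasis_edges()
  for (seed in 1:20) {
    r <- sim_rep(seed, n_clones = 300L, depth = 20000L)
    h <- clonal_space_homeostasis(r)
    expect_equal(unname(h$mass_per_bin),
                 oracle_homeostasis_mass(r$clonotypes$freq, unname(edges)),
                 tolerance = 1e-10)
    expect_equal(sum(h$mass_per_bin), 1, tolerance = 1e-9)
  }
})

test_that("compare_homeostasis runs Pearson chi-square on read counts", {
  # two-bin profiles engineered to the 2x2 table [[10,20],[20,10]]
  edges <- c(low = 0.15, high = 1)
  a <- clonal_space_homeostasis(
    rep_from_counts(c(20, base::rep(1, 10))), bin_edges = edges)
  b <- clonal_space_homeostasis(
    rep_from_counts(c(10, base::rep(1, 20))), bin_edges = edges)
  expect_equal(unname(a$reads_per_bin), c(10, 20))
  expect_equal(unname(b$reads_per_bin), c(20, 10))
  res <- compare_homeostasis(a, b)
  expect_equal(res$chi2, 20 / 3, tolerance = 1e-4) # = 6.6667
  expect_equal(res$df, 1L)

  # identical profiles: chi2 = 0, p = 1
  same <- compare_homeostasis(a, a)
  expect_equal(same$chi2, 0)
  expect_equal(same$p, 1)

  expect_error(compare_homeostasis(a, clonal_space_homeostasis(
    rep_from_counts(c(20, base::rep(1, 10))))), "different bin edges")
})

test_that("compare_homeostasis p matches the reference chi-square", {
  for (seed in 1:10) {
    a <- clonal_space_homeostasis(sim_rep(seed, 200L, 10000L))
    b <- clonal_space_homeostasis(sim_rep(seed + 100L, 200L, 10000L))
    res <- compare_homeostasis(a, b)
    ref <- suppressWarnings(stats::chisq.test(res$table, correct = FALSE))
    expect_equal(res$chi2, unname(ref$statistic), tolerance = 1e-10)
    expect_equal(res$df, unname(ref$parameter))
    expect_equal(res$p, ref$p.value, tolerance = 1e-10)
  }
})

test_that("clonotype_tracking selects and fills the frequency matrix", {
  # clone X at freq (0.10, 0.01) is the global maximum over filler clones
  filler_a <- paste0(strrep("GGG", 2), c("AAA", "AAC", "AAG", "AAT", "ACA",
                                         "ACC", "ACG", "ACT", "AGA"))
  filler_b <- paste0(strrep("TTT", 2), c("AAA", "AAC", "AAG", "AAT", "ACA",
                                         "ACC", "ACG", "ACT", "AGA", "AGC",
                                         "AGG"))
  a <- build_repertoire(recs(c("AAACCC", filler_a), c(10, base::rep(10, 9))),
                        "nt+vj", "t1")
  b <- build_repertoire(recs(c("AAACCC", filler_b), c(1, base::rep(9, 11))),
                        "nt+vj", "t2")
  tr <- clonotype_tracking(list(a, b), n = 1)
  expect_equal(dim(tr), c(1L, 2L))
  expect_equal(rownames(tr), "AAACCC|TRBV1|TRBJ1-1")
  expect_equal(as.numeric(tr), c(0.10, 0.01))

  # a clone absent from one sample gets an explicit 0, not NA
  tr_all <- clonotype_tracking(list(a, b), n = 25)
  expect_equal(unname(tr_all[paste0(filler_a[1], "|TRBV1|TRBJ1-1"), "t2"]), 0)
  expect_true(all(tr_all >= 0 & tr_all <= 1))

  anchored <- clonotype_tracking(list(a, b), select = "top_n_from_sample",
                                 n = 1, anchor = "t2")
  expect_equal(unname(anchored[1, "t2"]), 0.09)
  expect_error(clonotype_tracking(list(a, b), select = "top_n_from_sample",
                                  n = 1, anchor = "nope"), "anchor")
  expect_error(clonotype_tracking(list(a)), "at least 2")
})

test_that("tracking recovers a programmed expansion/contraction pattern", {
  base <- simulation_params(n_clones = 100L, depth = 20000L,
                            abundance = "uniform", seed = 33L)
  ids <- as.character(1:3)
  script <- longitudinal_script(base, list(
    list(label = "t1", fold = setNames(base::rep(1, 3), ids)),
    list(label = "t2", fold = setNames(base::rep(30, 3), ids)),
    list(label = "t3", fold = setNames(base::rep(3, 3), ids)),
    list(label = "t4", fold = setNames(base::rep(0.5, 3), ids)),
    list(label = "t5", fold = setNames(base::rep(3, 3), ids))))
  reps <- simulate_longitudinal(script)
  tr <- clonotype_tracking(unname(reps), n = 3)
  # every tracked trajectory peaks at the programmed expansion timepoint
  expect_true(all(apply(tr, 1L, which.max) == 2L))
  # and the t4 contraction sits below t3 and t5
  expect_true(all(tr[, "t4"] < tr[, "t3"]))
  expect_true(all(tr[, "t4"] < tr[, "t5"]))
})

test_that("similarity indices: closed cases and bounds", {
  a <- rep_from_counts(c(5, 3, 2), sample_id = "A")
  a2 <- rep_from_counts(c(5, 3, 2), sample_id = "A2")
  for (ix in c("jaccard", "overlap_coefficient", "morisita_horn",
               "bhattacharyya")) {
    m <- similarity_matrix(list(a, a2), ix)
    expect_equal(unname(m$values["A", "A2"]), 1, tolerance = 1e-9)
    d <- similarity_matrix(list(sim_rep(1, 30, 500), sim_rep(2, 30, 500)), ix)
    expect_equal(unname(d$values[1, 2]), 0)
  }

  # {a,b,c} vs {b,c,d}: jaccard 2/4
  x <- build_repertoire(recs(c("AAAAAA", "CCCCCC", "GGGGGG"), c(1, 1, 1)),
                        "nt+vj", "X")
  y <- build_repertoire(recs(c("CCCCCC", "GGGGGG", "TTTTTT"), c(1, 1, 1)),
                        "nt+vj", "Y")
  expect_equal(unname(similarity_matrix(list(x, y), "jaccard")$values[1, 2]),
               0.5)
  expect_error(similarity_matrix(list(x, y), "sorensen"), "options")
})

test_that("similarity matrices match the oracle, symmetric, unit diagonal", {
  for (seed in 1:10) {
    reps <- list(sim_rep(seed, 50, 1000), sim_rep(seed + 50, 50, 1000),
                 downsample(sim_rep(seed, 50, 1000), 500, seed = 1))
    reps[[3]]$sample_id <- "ds"
    fmap <- lapply(reps, function(r) {
      setNames(r$clonotypes$freq, clonotype_key(r$clonotypes, "nt+vj"))
    })
    jac <- similarity_matrix(reps, "jaccard")
    ovc <- similarity_matrix(reps, "overlap_coefficient")
    for (ix in c("jaccard", "overlap_coefficient", "morisita_horn",
                 "bhattacharyya")) {
      m <- similarity_matrix(reps, ix)$values
      expect_equal(m, t(m))
      expect_equal(unname(diag(m)), base::rep(1, 3), tolerance = 1e-9)
      expect_true(all(m >= 0 & m <= 1 + 1e-12))
      for (i in 1:2) for (j in (i + 1):3) {
        expect_equal(m[i, j], oracle_similarity(ix, fmap[[i]], fmap[[j]]),
                     tolerance = 1e-10)
      }
    }
    expect_true(all(jac$values <= ovc$values + 1e-12))
  }
})

test_that("cluster_samples agrees with the naive agglomeration oracle", {
  a <- rep_from_counts(c(5, 3, 2), sample_id = "A")
  b <- rep_from_counts(c(4, 3, 2, 1), sample_id = "B")
  m2 <- similarity_matrix(list(a, b), "jaccard")
  hc2 <- cluster_samples(m2)
  expect_equal(hc2$height, 1 - m2$values["A", "B"])
  expect_match(as_newick(hc2), "^\\(")

  # three samples: the closest pair merges first
  reps3 <- list(sim_rep(1, 40, 800), downsample(sim_rep(1, 40, 800), 700, 2),
                sim_rep(9, 40, 800))
  reps3[[1]]$sample_id <- "A"; reps3[[2]]$sample_id <- "B"
  reps3[[3]]$sample_id <- "C"
  m3 <- similarity_matrix(reps3, "morisita_horn")
  hc3 <- cluster_samples(m3)
  expect_equal(sort(hc3$labels[-hc3$merge[1, ]]), c("A", "B"))

  # six samples vs brute-force agglomeration at every linkage
  reps6 <- lapply(1:6, function(s) {
    r <- sim_rep(s, 40, 800)
    if (s %% 2 == 0) {
      donor <- sim_rep(s - 1, 40, 800)
      r <- build_repertoire(
        rbind(r$clonotypes[record_cols <- c("cdr3_nt", "cdr3_aa", "v_gene",
                                            "j_gene", "count")],
              donor$clonotypes[record_cols]), "nt+vj", paste0("s", s))
    }
    r$sample_id <- paste0("s", s)
    r
  })
  m6 <- similarity_matrix(reps6, "morisita_horn")
  for (linkage in c("average", "complete", "single")) {
    hc <- cluster_samples(m6, linkage)
    oracle <- oracle_agglomerate(1 - m6$values, linkage)
    expect_equal(hc$height,
                 vapply(oracle, function(m) m$height, numeric(1)),
                 tolerance = 1e-10)
  }

  bad <- m6
  bad$values[1, 2] <- NaN
  expect_error(cluster_samples(bad), "non-finite")
})

test_that("diversity indices: closed forms and formula cases", {
  uniform4 <- rep_from_counts(base::rep(25, 4))
  expect_equal(diversity(uniform4, "shannon")$value, log(4),
               tolerance = 1e-12)
  expect_equal(diversity(uniform4, "inverse_simpson")$value, 4,
               tolerance = 1e-12)
  expect_equal(diversity(uniform4, "clonality")$value, 0, tolerance = 1e-12)
  expect_equal(diversity(uniform4, "gini_simpson")$value, 0.75,
               tolerance = 1e-12)

  single <- rep_from_counts(100)
  expect_equal(diversity(single, "shannon")$value, 0)
  expect_equal(diversity(single, "clonality")$value, 1)
  expect_equal(diversity(single, "normalized_shannon")$value, 0)

  # direct summation: -0.7 ln 0.7 - 0.2 ln 0.2 - 0.1 ln 0.1 = 0.801819
  mix <- rep_from_counts(c(70, 20, 10))
  expect_equal(diversity(mix, "shannon")$value, 0.801819, tolerance = 1e-6)
  expect_equal(diversity(mix, "shannon", base = 2)$value,
               0.801819 / log(2), tolerance = 1e-6)

  # chao1 with S = 10, f1 = 3, f2 = 2 -> 10 + 9/4 = 12.25
  chao_counts <- c(1, 1, 1, 2, 2, 3, 4, 5, 6, 7)
  expect_equal(diversity(rep_from_counts(chao_counts), "chao1")$value, 12.25)
  # f2 = 0 falls back to the bias-corrected form
  nof2 <- c(1, 1, 1, 3, 4)
  expect_equal(diversity(rep_from_counts(nof2), "chao1")$value,
               5 + 3 * 2 / 2)

  expect_equal(diversity(mix, "d50")$value, 1)
  expect_error(diversity(mix, "renyi"), "options")
})

test_that("diversity matches oracle and vegan on simulated repertoires", {
  for (seed in 1:20) {
    r <- sim_rep(seed, n_clones = 200L, depth = 8000L)
    counts <- r$clonotypes$count
    for (ix in c("shannon", "normalized_shannon", "inverse_simpson",
                 "gini_simpson", "clonality", "chao1", "d50")) {
      expect_equal(diversity(r, ix)$value, oracle_diversity(ix, counts),
                   tolerance = 1e-10)
    }
    expect_equal(diversity(r, "shannon")$value,
                 unname(vegan::diversity(counts, "shannon")),
                 tolerance = 1e-10)
    expect_equal(diversity(r, "inverse_simpson")$value,
                 unname(vegan::diversity(counts, "invsimpson")),
                 tolerance = 1e-10)
    # bounds: 0 <= H <= ln S, 1 <= 1/D <= S
    s <- length(counts)
    H <- diversity(r, "shannon")$value
    expect_true(H >= 0 && H <= log(s) + 1e-12)
    isim <- diversity(r, "inverse_simpson")$value
    expect_true(isim >= 1 && isim <= s + 1e-9)
  }
})

test_that("rarefied_diversity is reproducible and depth-consistent", {
  r <- sim_rep(21, n_clones = 100L, depth = 4000L)
  full <- rarefied_diversity(r, "shannon", depth = r$total_reads,
                             n_resamples = 5, seed = 9)
  expect_equal(full$rarefaction$mean, diversity(r, "shannon")$value)
  expect_equal(full$rarefaction$sd, 0)

  a <- rarefied_diversity(r, "shannon", depth = 2000, n_resamples = 10,
                          seed = 4)
  b <- rarefied_diversity(r, "shannon", depth = 2000, n_resamples = 10,
                          seed = 4)
  expect_identical(a, b)
  expect_error(rarefied_diversity(r, "shannon", depth = 5000,
                                  n_resamples = 2, seed = 1),
               "no upsampling")
})

test_that("rarefied shannon sits in the Monte-Carlo band of the oracle", {
  r <- build_repertoire(recs(
    as.vector(outer(c("AAA", "CCC", "GGG", "TTT", "ACG"),
                    c("AAA", "CCC", "GGG", "TTT"), paste0)),
    base::rep(50, 20)), "nt+vj", "uni")
  depth <- r$total_reads / 2
  got <- rarefied_diversity(r, "shannon", depth, n_resamples = 200,
                            seed = 5)
  oracle <- withr::with_seed(99, oracle_rarefied_shannon(
    r$clonotypes$count, depth, 200))
  expect_true(got$rarefaction$mean <= log(n_clonotypes(r)))
  band <- 4 * sd(oracle) / sqrt(length(oracle))
  expect_lt(abs(got$rarefaction$mean - mean(oracle)),
            band + 4 * got$rarefaction$sd / sqrt(200))
})

test_that("compare_groups: exact and approximate Mann-Whitney paths", {
  exact <- compare_groups(list(a = c(1, 2, 3), b = c(4, 5, 6)))
  expect_equal(exact$p, 0.1)
  expect_equal(exact$statistic, 0)
  expect_equal(exact$method_label, "mann_whitney_exact")

  same <- compare_groups(list(a = c(1, 2, 3), b = c(1, 2, 3)))
  expect_equal(same$p, 1)
  expect_equal(same$method_label, "mann_whitney_normal_approx")

  expect_error(compare_groups(list(a = 1, b = 2, c = 3)), "pairwise")
  expect_error(compare_groups(list(a = numeric(), b = 1)), "at least one")

  # agreement with the stats reference on tie-free data
  withr::with_seed(8, {
    for (i in 1:10) {
      x <- rnorm(6); y <- rnorm(7)
      ours <- compare_groups(list(x = x, y = y))
      ref <- stats::wilcox.test(x, y, exact = TRUE)
      expect_equal(ours$p, ref$p.value, tolerance = 1e-12)
    }
  })
})

test_that("compare_groups detects a 2-sd lognormal shift with power > 80%", {
  n_reps <- 300L
  rejections <- withr::with_seed(17, {
    sum(replicate(n_reps, {
      x <- exp(rnorm(8, 0, 0.5))
      y <- exp(rnorm(8, 1, 0.5)) # 2 sd shift on the log scale
      compare_groups(list(x = x, y = y))$p < 0.05
    }))
  })
  expect_gt(rejections / n_reps, 0.8)
})
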