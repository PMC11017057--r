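test_that("gene-window SNP mapping uses inclusive 20 kb boundaries", {
  genes <- data.frame(name = "g1", chrom = 1L, start = 100000L,
                      end = 120000L)
  map <- data.frame(id = c("in_edge", "out_edge", "inside", "right_edge",
                           "right_out"),
                    chrom = 1L,
                    pos = c(100000L - 20000L, 100000L - 20001L, 110000L,
                            120000L + 20000L, 120000L + 20001L),
                    allele1 = "A", allele2 = "G", maf = 0.2)
  got <- map_snps_to_pathway(map, genes, window = 20000)
  expect_setequal(got, c("in_edge", "inside", "right_edge"))
})

test_that("overlapping genes contribute each SNP once (union semantics)", {
  genes <- data.frame(name = c("g1", "g2", "g3"), chrom = 1L,
                      start = c(1000L, 1500L, 90000L),
                      end = c(2000L, 2500L, 95000L))
  map <- data.frame(id = c("shared", "only3", "nowhere"), chrom = 1L,
                    pos = c(1800L, 91000L, 50000L),
                    allele1 = "A", allele2 = "G", maf = 0.2)
  got <- map_snps_to_pathway(map, genes, window = 100)
  expect_identical(got, c("shared", "only3"))
})

test_that("chromosome mismatch yields an empty set with a warning", {
  genes <- data.frame(name = "g1", chrom = 2L, start = 1000L, end = 2000L)
  map <- data.frame(id = "s1", chrom = 1L, pos = 1500L,
                    allele1 = "A", allele2 = "G", maf = 0.2)
  expect_warning(got <- map_snps_to_pathway(map, genes), "chromosome")
  expect_length(got, 0)
})

test_that("allele alignment attaches log-OR weights in the right orientation", {
  g <- toy_genotypes(matrix(c(0, 1, 2), 3, 3), allele1 = c("A", "A", "A"),
                     allele2 = c("G", "G", "T"))
  # SNP1: effect allele = counted allele -> direct weight ln 2
  # SNP2: effect allele = other allele -> flip
  # SNP3: A/T ambiguous -> dropped
  ss <- toy_sumstats(g$snp_map, odds_ratio = c(2, 2, 2),
                     effect_allele = c("A", "G", "A"),
                     other_allele = c("G", "A", "T"))
  expect_message(al <- align_alleles(g$snp_map, ss), "1 strand-ambiguous")
  expect_identical(al$id, c("snp001", "snp002"))
  expect_equal(al$weight, c(log(2), log(2)), tolerance = 1e-12)
  expect_identical(al$flip, c(FALSE, TRUE))
  expect_identical(attr(al, "n_ambiguous"), 1L)
  # flipped SNP: an individual with dosage 0 contributes 2 * ln 2
  prs <- compute_prs(g, al[al$id == "snp002", ], "snp002")
  expect_equal(unname(prs$score[1]), 2 * log(2), tolerance = 1e-12)
})

test_that("strand-complemented matches are reconciled; irreconcilable dropped", {
  g <- toy_genotypes(matrix(1, 2, 3), allele1 = c("A", "A", "A"),
                     allele2 = c("G", "G", "G"))
  ss <- toy_sumstats(g$snp_map, odds_ratio = c(1.5, 1.5, 1.5),
                     effect_allele = c("T", "C", "A"),
                     other_allele = c("C", "T", "C"))
  # SNP1: complement of A/G is T/C -> direct after strand flip
  # SNP2: complement reversed -> flip after strand flip
  # SNP3: A/C vs map A/G -> irreconcilable
  expect_message(al <- align_alleles(g$snp_map, ss), "1 irreconcilable")
  expect_identical(al$flip, c(FALSE, TRUE))
  expect_identical(attr(al, "n_irreconcilable"), 1L)
})

test_that("threshold selection filters at p <= t and nests", {
  map <- data.frame(id = paste0("s", 1:4), chrom = 1L, pos = 1:4 * 1000L,
                    allele1 = "A", allele2 = "G", maf = 0.2)
  ss <- toy_sumstats(map, odds_ratio = rep(1.1, 4),
                     p_value = c(1e-9, 2e-5, 0.01, 0.2))
  expect_length(select_by_threshold(ss, 1e-4), 2)
  expect_length(select_by_threshold(ss, 1), 4)
  s1 <- select_by_threshold(ss, 5e-8)
  s2 <- select_by_threshold(ss, 1e-4)
  s3 <- select_by_threshold(ss, 0.05)
  expect_true(all(s1 %in% s2) && all(s2 %in% s3))
})

test_that("compute_prs matches hand-computed sums", {
  # 3 SNPs, ORs {1.5, 0.8, 1.2}, dosages {2, 1, 0}
  g <- toy_genotypes(matrix(c(2, 1, 0), 1, 3))
  ss <- toy_sumstats(g$snp_map, odds_ratio = c(1.5, 0.8, 1.2))
  al <- align_alleles(g$snp_map, ss)
  prs <- compute_prs(g, al, al$id)
  expect_equal(unname(prs$score), 2 * log(1.5) + log(0.8),
               tolerance = 1e-12)
  expect_identical(prs$n_snps, 3L)
  # all dosages zero with positive weights -> score 0
  g0 <- toy_genotypes(matrix(0, 2, 3))
  al0 <- align_alleles(g0$snp_map, toy_sumstats(g0$snp_map, rep(2, 3)))
  expect_equal(unname(compute_prs(g0, al0, al0$id)$score), c(0, 0))
  # single SNP, OR 2, dosage 2 -> 2 ln 2
  g1 <- toy_genotypes(matrix(2, 1, 1))
  al1 <- align_alleles(g1$snp_map, toy_sumstats(g1$snp_map, 2))
  expect_equal(unname(compute_prs(g1, al1, al1$id)$score), 2 * log(2),
               tolerance = 1e-12)
})

test_that("missing dosages are imputed at twice the sample frequency", {
  d <- matrix(c(0, 1, 2, NA), 4, 1)
  g <- toy_genotypes(d)
  al <- align_alleles(g$snp_map, toy_sumstats(g$snp_map, 2))
  prs <- compute_prs(g, al, al$id)
  expect_equal(unname(prs$score[4]), log(2) * 1, tolerance = 1e-12)
})

test_that("scores equal the brute-force double loop on random instances", {
  set.seed(42)
  for (rep in 1:5) {
    n <- 50; m <- 200
    d <- matrix(rbinom(n * m, 2, 0.3), n, m)
    g <- toy_genotypes(d)
    or <- exp(rnorm(m, 0, 0.1))
    flip_truth <- runif(m) < 0.4
    ss <- toy_sumstats(
      g$snp_map, or,
      p_value = runif(m),
      effect_allele = ifelse(flip_truth, g$snp_map$allele2,
                             g$snp_map$allele1),
      other_allele = ifelse(flip_truth, g$snp_map$allele1,
                            g$snp_map$allele2))
    al <- align_alleles(g$snp_map, ss)
    use <- sample(al$id, 120)
    fast <- compute_prs(g, al, use)
    slow <- oracle_prs(g$dosages, al$weight, al$flip, al$id, use)
    expect_equal(unname(fast$score), slow, tolerance = 1e-10)
  }
})

test_that("threshold nestedness and allele-recoding invariance hold broadly", {
  set.seed(7)
  for (rep in 1:40) {
    n <- 12; m <- 25
    d <- matrix(rbinom(n * m, 2, runif(1, 0.1, 0.5)), n, m)
    g <- toy_genotypes(d)
    ss <- toy_sumstats(g$snp_map, exp(rnorm(m, 0, 0.2)), p_value = runif(m))
    al <- align_alleles(g$snp_map, ss)
    t1 <- runif(1, 0, 0.5); t2 <- runif(1, t1, 1)
    set1 <- select_by_threshold(al, t1)
    set2 <- select_by_threshold(al, t2)
    expect_true(all(set1 %in% set2))
    # the two scores differ exactly by the SNPs in the set difference
    s1 <- compute_prs(g, al, set1)$score
    s2 <- compute_prs(g, al, set2)$score
    extra <- setdiff(set2, set1)
    diff_direct <- if (length(extra)) compute_prs(g, al, extra)$score
                   else setNames(rep(0, n), g$sample_ids)
    if (length(set1)) {
      expect_equal(s2 - s1, diff_direct, tolerance = 1e-10)
    }
    # recode one SNP (swap alleles, reflect dosage): all scores unchanged
    j <- sample(m, 1)
    g2 <- g
    g2$dosages[, j] <- 2 - g2$dosages[, j]
    tmp <- g2$snp_map$allele1[j]
    g2$snp_map$allele1[j] <- g2$snp_map$allele2[j]
    g2$snp_map$allele2[j] <- tmp
    al2 <- align_alleles(g2$snp_map, ss)
    expect_equal(compute_prs(g2, al2, set2)$score, s2, tolerance = 1e-10)
  }
})

test_that("weights are linear: doubling all weights doubles all scores", {
  g <- toy_genotypes(matrix(rbinom(40, 2, 0.3), 8, 5))
  ss <- toy_sumstats(g$snp_map, exp(rnorm(5, 0, 0.2)))
  al <- align_alleles(g$snp_map, ss)
  al2 <- al
  al2$weight <- 2 * al$weight
  expect_equal(compute_prs(g, al2, al$id)$score,
               2 * compute_prs(g, al, al$id)$score, tolerance = 1e-12)
})

test_that("score_pathways profiles every pathway at a nested grid", {
  study <- small_study(seed = 3)
  prs <- score_pathways(study$genotypes, study$sumstats, study$annotation,
                        thresholds = c(1e-4, 0.05, 1))
  expect_setequal(unique(prs$pathway), names(study$annotation$pathways))
  # n_snps non-increasing as the threshold tightens
  for (pw in unique(prs$pathway)) {
    ns <- sapply(c(1e-4, 0.05, 1), function(th)
      prs$n_snps[prs$pathway == pw & prs$threshold == th][1])
    expect_true(all(diff(ns) >= 0))
  }
  gw <- prs[prs$pathway == "genome_wide" & prs$threshold == 1, ]
  expect_identical(gw$n_snps[1], nrow(study$sumstats))
  # averaging mode rescales sums by n_snps
  prs_avg <- score_pathways(study$genotypes, study$sumstats,
                            study$annotation, thresholds = 1,
                            pathways = "genome_wide", average = TRUE)
  expect_equal(prs_avg$score * prs_avg$n_snps, gw$score, tolerance = 1e-10)
})

test_that("empty pathway/threshold cells are flagged, not fabricated", {
  study <- small_study(seed = 9)
  prs <- score_pathways(study$genotypes, study$sumstats, study$annotation,
                        thresholds = 1e-300, pathways = "mir137_gene")
  expect_true(all(prs$n_snps == 0L))
  expect_true(all(is.na(prs$score)))
})
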