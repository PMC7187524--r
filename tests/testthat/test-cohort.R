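# Prioritization statistics: Wilcoxon case-control test, bootstrap
# outlier z-scores, ranking, and the analysis filters.

test_that("one-sided Wilcoxon matches exact enumeration on small inputs", {
  expect_equal(wilcoxon_one_sided(c(10, 11), c(1, 2, 3)), 0.1)
  expect_equal(wilcoxon_one_sided(c(1, 2, 3), c(10, 11)), 1)
  expect_gte(wilcoxon_one_sided(c(5, 5, 5), c(5, 5, 5)), 0.5)
  expect_error(wilcoxon_one_sided(numeric(0), 1), "non-empty")
})

test_that("Wilcoxon p equals the brute-force permutation oracle", {
  # oracle: enumerate all C(n+m, n) assignments of the pooled values
  # to the case group and compute P(U_perm >= U_obs)
  oracle <- function(x, y) {
    pooled <- c(x, y)
    n <- length(x)
    u_of <- function(idx) {
      r <- rank(pooled)
      sum(r[idx]) - n * (n + 1) / 2
    }
    u_obs <- u_of(seq_len(n))
    combs <- utils::combn(length(pooled), n)
    mean(apply(combs, 2, u_of) >= u_obs)
  }
  set.seed(701)
  for (rep in 1:40) {
    n <- sample(1:9, 1)
    m <- sample(seq_len(10 - n), 1)
    vals <- sample(1000, n + m)  # tie-free
    x <- vals[seq_len(n)]; y <- vals[-seq_len(n)]
    expect_equal(wilcoxon_one_sided(x, y), oracle(x, y),
                 tolerance = 1e-12)
  }
})

test_that("Wilcoxon p is shift-invariant and scale leaves rankings fixed", {
  set.seed(702)
  x <- rexp(8); y <- rexp(12)
  expect_equal(wilcoxon_one_sided(x, y),
               wilcoxon_one_sided(x + 17.3, y + 17.3))
  counts <- matrix(rexp(60), 3, 20,
                   dimnames = list(NULL, sprintf("s%02d", 1:20)))
  st <- setNames(rep(c("case", "control"), c(5, 15)), colnames(counts))
  r1 <- case_control_analysis(make_cohort_table(counts, st), "locus")
  r2 <- case_control_analysis(make_cohort_table(counts * 3.7, st),
                              "locus")
  expect_equal(r1$target_id, r2$target_id)
  expect_equal(r1$statistic_value, r2$statistic_value)
})

test_that("bootstrap outlier z-scores flag the single spiked case", {
  counts <- setNames(c(10, rep(0, 20)),
                     c("case1", sprintf("ctrl%02d", 1:20)))
  z <- outlier_zscores(counts, "case1", outlier_params(seed = 1))
  expect_equal(names(z), "case1")
  expect_gt(z[["case1"]], 0)

  # identical counts: no case exceeds the quantile mean
  flat <- setNames(rep(4, 21), names(counts))
  expect_length(outlier_zscores(flat, "case1",
                                outlier_params(seed = 1)), 0)

  # a case below the quantile mean is omitted
  low <- setNames(c(1, rep(5, 20)), names(counts))
  expect_length(outlier_zscores(low, "case1",
                                outlier_params(seed = 1)), 0)

  expect_error(outlier_zscores(c(a = 1, b = 2), "a",
                               outlier_params()), "at least 3")
})

test_that("bootstrap is reproducible under a seed and stable across seeds", {
  set.seed(703)
  counts <- setNames(c(rexp(20), 9), c(sprintf("c%02d", 1:20), "case1"))
  p1 <- outlier_params(seed = 42)
  expect_identical(outlier_zscores(counts, "case1", p1),
                   outlier_zscores(counts, "case1", p1))
  z_by_seed <- vapply(1:20, function(s)
    outlier_zscores(counts, "case1", outlier_params(seed = s))[[1]],
    numeric(1))
  # different seeds perturb the bootstrap only slightly at B = 1000
  expect_lt(stats::sd(z_by_seed) / mean(z_by_seed), 0.1)
})

test_that("degenerate bootstrap spread yields an infinite z that sorts first", {
  # all controls identical, case above: sd of the bootstrap quantile
  # collapses
  counts <- setNames(c(rep(2, 30), 50), c(sprintf("c%02d", 1:30), "k"))
  z <- outlier_zscores(counts, "k", outlier_params(seed = 5,
                                                   controls_only = TRUE),
                       control_ids = sprintf("c%02d", 1:30))
  expect_true(is.infinite(z[["k"]]))
})

test_that("ranking orders by statistic with deterministic tie-breaks", {
  res <- data.frame(
    target_id = c("t1", "t2", "t3"),
    statistic_name = "z_score",
    statistic_value = c(5, 2, 9.9),
    case_total = c(1, 1, 1), stringsAsFactors = FALSE)
  r <- rank_targets(res, "z_score")
  expect_equal(r$target_id, c("t3", "t1", "t2"))
  expect_equal(r$rank, 1:3)

  # equal statistic: larger case total wins, then lexicographic id
  res2 <- data.frame(
    target_id = c("b", "a", "c"),
    statistic_name = "z_score",
    statistic_value = c(3, 3, 3),
    case_total = c(2, 2, 7), stringsAsFactors = FALSE)
  r2 <- rank_targets(res2, "z_score")
  expect_equal(r2$target_id, c("c", "a", "b"))

  # NA statistics sort last
  res3 <- data.frame(target_id = c("x", "y"),
                     statistic_name = "z_score",
                     statistic_value = c(NA, 1),
                     case_total = c(9, 1), stringsAsFactors = FALSE)
  expect_equal(rank_targets(res3, "z_score")$target_id, c("y", "x"))
})

test_that("filters compose: motif length, BED flank, count minima", {
  counts <- matrix(c(6, 1, 4, 1, 9, 1), 3, 2, byrow = TRUE,
                   dimnames = list(NULL, c("a", "b")))
  tab <- make_cohort_table(counts, c(a = "case", b = "control"))
  tab$anchored$targets$motif <- c("AAG", "AACCCT", "AC")
  tab$anchored$targets$contig <- c("chr1", "chr1", "chr2")
  tab$anchored$targets$start <- c(10000L, 2000L, 50L)
  tab$anchored$targets$end <- c(10100L, 2100L, 150L)
  tab$anchored$targets$target_id <- sprintf(
    "%s@%s:%d-%d", tab$anchored$targets$motif,
    tab$anchored$targets$contig, tab$anchored$targets$start,
    tab$anchored$targets$end)
  rownames(tab$anchored$raw) <- rownames(tab$anchored$norm) <-
    tab$anchored$targets$target_id

  # 6-bp telomeric motif retained by the 2-6 range, AAG too, all pass
  f1 <- filter_cohort(tab, motif_len_range = c(2, 6))
  expect_equal(nrow(f1$anchored$targets), 3L)
  f2 <- filter_cohort(tab, motif_len_range = c(2, 3))
  expect_equal(sort(f2$anchored$targets$motif), c("AAG", "AC"))

  # BED: interval 4000-5000 + 5-kb flank reaches exactly 10000
  # (half-open boundary contact is kept)
  bed <- tempfile(fileext = ".bed")
  writeLines("chr1\t4000\t5000", bed)
  f3 <- filter_cohort(tab, bed = bed, flank_bp = 5000L)
  expect_true("AAG@chr1:10000-10100" %in% f3$anchored$targets$target_id)
  expect_false("AC@chr2:50-150" %in% f3$anchored$targets$target_id)

  # raw-count minimum: max anchored 4 < 5 drops the second region
  f4 <- filter_cohort(tab, min_anchored = 5L)
  expect_equal(sort(f4$anchored$targets$motif), c("AAG", "AC"))

  # filters compose
  f5 <- filter_cohort(tab, motif_len_range = c(2, 3), bed = bed,
                      flank_bp = 5000L, min_anchored = 5L)
  expect_equal(f5$anchored$targets$motif, "AAG")
})

test_that("malformed BED input fails loudly", {
  bed <- tempfile(fileext = ".bed")
  writeLines("chr1\tnot_a_number\t5000", bed)
  counts <- matrix(1:2, 1, 2, dimnames = list(NULL, c("a", "b")))
  tab <- make_cohort_table(counts, c(a = "case", b = "control"))
  expect_error(filter_cohort(tab, bed = bed), "BED")
})

test_that("case-control analysis ranks a constructed signal first", {
  set.seed(704)
  n_reg <- 30
  ids <- c(sprintf("case%02d", 1:10), sprintf("ctrl%02d", 1:20))
  st <- setNames(rep(c("case", "control"), c(10, 20)), ids)
  counts <- matrix(rexp(n_reg * 30), n_reg, 30,
                   dimnames = list(NULL, ids))
  counts[7, 1:10] <- counts[7, 1:10] + 25  # shared case expansion
  tab <- make_cohort_table(counts, st)
  res <- case_control_analysis(tab, "locus")
  expect_equal(res$rank[res$target_id == tab$anchored$targets$target_id[7]],
               1L)
  expect_equal(res$adjusted_p,
               pmin(res$statistic_value * n_reg, 1))

  # shuffling the statuses destroys the signal in most shuffles
  hits <- 0
  for (i in 1:10) {
    sh <- setNames(sample(st), ids)
    r <- case_control_analysis(make_cohort_table(counts, sh), "locus")
    if (r$target_id[1] == tab$anchored$targets$target_id[7])
      hits <- hits + 1
  }
  expect_lte(hits, 1)
})

test_that("a motif absent from every case yields p = 1", {
  ids <- c("case1", "case2", "ctrl1", "ctrl2", "ctrl3")
  st <- setNames(c("case", "case", rep("control", 3)), ids)
  counts <- matrix(c(0, 1, 3, 4, 5), 1, 5,
                   dimnames = list(NULL, ids))
  res <- case_control_analysis(make_cohort_table(counts, st), "locus")
  expect_equal(res$statistic_value, 1)
  # with ties among the zero counts the approximation stays near 1
  tied <- matrix(c(0, 0, 3, 4, 5), 1, 5, dimnames = list(NULL, ids))
  res2 <- case_control_analysis(make_cohort_table(tied, st), "locus")
  expect_gt(res2$statistic_value, 0.9)
})

test_that("analyses validate the cohort's statuses", {
  counts <- matrix(1:4, 2, 2, dimnames = list(NULL, c("a", "b")))
  tab <- make_cohort_table(counts, c(a = "case", b = "case"))
  expect_error(case_control_analysis(tab, "locus"), "both case and control")
  # outlier run with no cases gives an empty result
  tab2 <- make_cohort_table(counts, c(a = "control", b = "control"))
  expect_equal(nrow(outlier_analysis(tab2, "locus")), 0L)
})

test_that("the motif method works on paired-IRR counts", {
  ids <- sprintf("s%02d", 1:12)
  st <- setNames(rep(c("case", "control"), c(4, 8)), ids)
  tab <- make_cohort_table(matrix(0, 1, 12,
                                  dimnames = list(NULL, ids)), st)
  tab$paired$motifs <- c("AAG", "AGC")
  m <- matrix(rexp(24, 2), 2, 12, dimnames = list(c("AAG", "AGC"), ids))
  m["AGC", 1:4] <- m["AGC", 1:4] + 30
  tab$paired$raw <- tab$paired$norm <- m
  res <- case_control_analysis(tab, "motif")
  expect_equal(res$target_id[1], "AGC")
  res_o <- outlier_analysis(tab, "motif", outlier_params(seed = 2))
  expect_s3_class(res_o, "irr_results")
})
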