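test_that("alpha diversity matches hand-derived and closed-form values", {
  counts <- rbind(a = c(5, 1, 1, 2, 0), b = c(10, 10, 10, 10, 10))
  colnames(counts) <- paste0("t", 1:5)
  tab <- abundance_table(counts, "bacteria")
  div <- alpha_diversity(tab)
  # {5,1,1,2}: S=4, F1=2, F2=1 -> chao1 = 4 + 2*1/(2*(1+1)) = 4.5
  expect_equal(div$chao1[1], 4.5)
  expect_equal(div$coverage[1], 1 - 2 / 9)
  # uniform community of S taxa: simpson = 1 - 1/S; F1 = 0 collapses
  # coverage to 1 and chao1 to S_obs
  expect_equal(div$simpson[2], 1 - 1 / 5)
  expect_equal(div$coverage[2], 1)
  expect_equal(div$chao1[2], 5)
  expect_equal(alpha_diversity(tab, simpson = "dominance")$simpson[2], 1 / 5)
  expect_equal(alpha_diversity(tab, simpson = "inverse")$simpson[2], 5)
  empty <- counts; empty[1, ] <- 0
  expect_error(alpha_diversity(abundance_table(empty, "bacteria")), "empty")
})

test_that("chao1 >= observed richness, equality iff F1 <= 1", {
  set.seed(1)
  for (i in 1:50) {
    x <- stats::rpois(30, 2)
    if (sum(x) == 0) next
    s <- sum(x > 0)
    c1 <- oracle_chao1(x)
    div <- alpha_diversity(abundance_table(
      matrix(c(x, x), 2, byrow = TRUE,
             dimnames = list(c("s1", "s2"), paste0("t", seq_along(x)))),
      "bacteria"))
    expect_equal(div$chao1[1], c1)
    expect_gte(div$chao1[1], s)
    if (sum(x == 1) <= 1) expect_equal(div$chao1[1], s)
  }
})

test_that("bray-curtis matches the brute-force oracle and its bounds", {
  counts <- rbind(s1 = c(4, 6, 0), s2 = c(4, 6, 0), s3 = c(0, 0, 5),
                  s4 = c(1, 2, 3))
  colnames(counts) <- paste0("t", 1:3)
  d <- as.matrix(bray_curtis(abundance_table(counts, "bacteria")))
  expect_equal(d["s1", "s2"], 0)            # identical composition
  expect_equal(d["s1", "s3"], 1)            # disjoint
  expect_equal(d["s1", "s4"], oracle_bray(counts[1, ], counts[4, ]))
  set.seed(2)
  tab <- random_table(8, 15)
  dm <- as.matrix(bray_curtis(tab))
  for (i in 1:7) for (j in (i + 1):8)
    expect_equal(dm[i, j], oracle_bray(tab$counts[i, ], tab$counts[j, ]),
                 tolerance = 1e-12)
  expect_true(all(dm >= 0 & dm <= 1))
  bad <- counts; bad[2, ] <- 0
  expect_error(bray_curtis(abundance_table(bad, "bacteria")), "zero total")
})

test_that("PCoA reproduces Euclidean configurations and the centering oracle", {
  set.seed(3)
  pts <- matrix(stats::rnorm(12), 6, 2)
  d <- stats::dist(pts)
  ord <- ordinate(d, k = 2)
  expect_equal(as.matrix(stats::dist(ord$points)), as.matrix(d),
               tolerance = 1e-9, ignore_attr = TRUE)
  expect_lte(sum(ord$explained), 1 + 1e-12)
  # 4-sample non-Euclidean fixture vs the double-centering oracle
  tab <- random_table(4, 10)
  db <- bray_curtis(tab)
  ord2 <- ordinate(db, k = 2)
  orc <- oracle_pcoa(db, k = 2)
  expect_equal(ord2$eig, orc$values, tolerance = 1e-9)
  expect_equal(abs(ord2$points), abs(orc$points), tolerance = 1e-9,
               ignore_attr = TRUE)  # axes defined up to sign
  expect_true(all(diff(ord2$explained) <= 1e-12))
  expect_error(ordinate(matrix(c(0, 1, 2, 0), 2)), "symmetric")
})

test_that("ANOSIM: extremes, exact enumeration oracle, invariances", {
  # perfectly separated groups: all between > all within -> R = 1
  x <- c(0, 0.1, 0.2, 10, 10.1, 10.2)
  d <- stats::dist(x)
  g <- rep(c("a", "b"), each = 3)
  res <- anosim(d, g, exact = TRUE)
  expect_equal(res$statistic, 1)
  orc <- oracle_anosim_exact(as.matrix(d), g)
  expect_equal(res$statistic, orc$statistic)
  expect_equal(res$p_value, orc$p_value)
  # complementary assignments produce the same partition, so the smallest
  # attainable p with equal group sizes is 2 / choose(6, 3)
  expect_equal(res$p_value, 2 / choose(6, 3))
  # random fixture: exact p agrees with enumeration oracle, R label-invariant
  set.seed(4)
  for (i in 1:5) {
    dm <- as.matrix(stats::dist(stats::rnorm(6)))
    res <- anosim(dm, g, exact = TRUE)
    orc <- oracle_anosim_exact(dm, g)
    expect_equal(res$statistic, orc$statistic, tolerance = 1e-12)
    expect_equal(res$p_value, orc$p_value, tolerance = 1e-12)
    relab <- anosim(dm, ifelse(g == "a", "x", "y"), exact = TRUE)
    expect_equal(relab$statistic, res$statistic, tolerance = 1e-12)
  }
  expect_error(anosim(d, c("a", "a", "a", "a", "a", "b")), "at least two")
  expect_error(anosim(d, rep("a", 6)), "two groups")
})

test_that("distance, ANOSIM and Mantel agree with vegan's implementations", {
  set.seed(14)
  tab <- random_table(8, 20)
  d <- bray_curtis(tab)
  ref <- vegan::vegdist(tab$counts / rowSums(tab$counts), method = "bray")
  expect_equal(as.matrix(d), as.matrix(ref), tolerance = 1e-12,
               ignore_attr = TRUE)
  g <- rep(c("a", "b"), each = 4)
  expect_equal(anosim(d, g, n_perm = 49)$statistic,
               unname(vegan::anosim(d, g, permutations = 9)$statistic),
               tolerance = 1e-12)
  d2 <- stats::dist(stats::rnorm(8))
  expect_equal(mantel_test(d, d2, n_perm = 49)$statistic,
               unname(vegan::mantel(d, d2, method = "spearman",
                                    permutations = 9)$statistic),
               tolerance = 1e-12)
})

test_that("sampled ANOSIM p lies in (0,1] and is seed-stable", {
  set.seed(5)
  dm <- as.matrix(stats::dist(stats::rnorm(10)))
  g <- rep(c("a", "b"), each = 5)
  r1 <- anosim(dm, g, n_perm = 99, seed = 11)
  r2 <- anosim(dm, g, n_perm = 99, seed = 11)
  expect_identical(r1, r2)
  expect_gt(r1$p_value, 0)
  expect_lte(r1$p_value, 1)
})

test_that("Mann-Whitney group test: exact enumeration and approximation", {
  # complete separation 4 vs 4 -> two-sided exact p = 2/70
  v <- c(1, 2, 3, 4, 10, 11, 12, 13)
  g <- rep(c("a", "b"), each = 4)
  res <- group_compare(v, g)
  expect_equal(res$p_value, 2 / 70)
  expect_match(res$method, "exact")
  set.seed(6)
  for (i in 1:10) {
    v <- stats::rnorm(11)
    g <- rep(c("a", "b"), c(5, 6))
    expect_equal(group_compare(v, g)$p_value, oracle_mwu_exact(v, g),
                 tolerance = 1e-12)
  }
  # large groups take the tie-corrected normal path, close to wilcox.test
  set.seed(7)
  v <- c(stats::rnorm(12), stats::rnorm(12, 1))
  g <- rep(c("a", "b"), each = 12)
  res <- group_compare(v, g)
  expect_match(res$method, "normal")
  ref <- stats::wilcox.test(v[g == "a"], v[g == "b"], exact = FALSE,
                            correct = FALSE)
  expect_equal(res$p_value, ref$p.value, tolerance = 1e-10)
  expect_error(group_compare(v, rep("a", 24)), "two groups")
})
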