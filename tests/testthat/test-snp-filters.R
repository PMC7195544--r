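test_that("missingness filters use the documented boundary directions", {
  # sample missing at 95/100 sites removed; exactly 90% retained (strict >)
  g <- matrix(0L, 3, 100)
  g[1, 1:95] <- NA_integer_
  g[2, 1:90] <- NA_integer_
  m <- gm(g)
  out <- filter_sample_missing(m, 0.90)
  expect_equal(attr(out, "removed_samples"), "S01")
  expect_equal(out$samples, c("S02", "S03"))
  expect_error(filter_sample_missing(gm(matrix(NA_integer_, 2, 4)), 0.5),
               "no samples")

  # site missing in exactly half the samples kept; 6/10 removed
  g2 <- matrix(rep(c(0L, 1L), 5), 10, 3)
  g2[1:5, 2] <- NA_integer_
  g2[1:6, 3] <- NA_integer_
  m2 <- gm(g2)
  out2 <- filter_site_missing(m2, 0.5)
  expect_equal(out2$sites$id, c("s001", "s002"))
  # threshold 0: only complete sites survive
  expect_equal(filter_site_missing(m2, 0)$sites$id, "s001")
  # no missing data: identity
  full <- rand_gm(10, 50, missing_rate = 0, seed = 6)
  expect_equal(filter_site_missing(full, 0.5)$sites, full$sites)
})

test_that("MAF filter folds allele frequency and keeps the 0.02 boundary", {
  # 9 x hom-ref + 1 het in 10 samples: maf 1/20 = 0.05 -> kept
  m <- gm(matrix(c(rep(0L, 9), 1L), 10, 1))
  expect_equal(nrow(filter_maf(m, 0.02)$sites), 1L)
  # 24 x hom-ref + 1 het in 25 samples: maf 1/50 = 0.02 -> kept (>=)
  m2 <- gm(matrix(c(rep(0L, 24), 1L), 25, 1))
  expect_equal(nrow(filter_maf(m2, 0.02)$sites), 1L)
  # just under the boundary is removed
  m3 <- gm(matrix(c(rep(0L, 25), 1L), 26, 1))
  expect_equal(nrow(filter_maf(m3, 0.02)$sites), 0L)
  # monomorphic removed whenever min_maf > 0, kept at 0
  m4 <- gm(matrix(0L, 10, 1))
  expect_equal(nrow(filter_maf(m4, 0.02)$sites), 0L)
  expect_equal(nrow(filter_maf(m4, 0)$sites), 1L)
  # folding: an all-alt site is monomorphic too
  m5 <- gm(matrix(2L, 10, 1))
  expect_equal(nrow(filter_maf(m5, 0.02)$sites), 0L)
  # a site with zero calls is removed and counted separately
  g6 <- cbind(c(0L, 1L), c(NA_integer_, NA_integer_))
  m6 <- gm(g6)
  out6 <- filter_maf(m6, 0)
  expect_equal(attr(out6, "removed_no_calls"), "s002")
})

test_that("heterozygosity filter boundaries and excess-het removal", {
  # 1 het among 100 samples: H = 0.01 -> kept at min_het 0.01
  m <- gm(matrix(c(1L, rep(0L, 98), 2L), 100, 1))
  expect_equal(nrow(filter_het(m, 0.01)$sites), 1L)
  # 0 hets removed when min_het > 0
  m2 <- gm(matrix(c(rep(0L, 50), rep(2L, 50)), 100, 1))
  expect_equal(nrow(filter_het(m2, 0.01)$sites), 0L)
  # 80% hets removed under max_het = 0.6
  m3 <- gm(matrix(c(rep(1L, 8), 0L, 2L), 10, 1))
  expect_equal(nrow(filter_het(m3, 0.01, max_het = 0.6)$sites), 0L)
  expect_equal(nrow(filter_het(m3, 0.01)$sites), 1L)
})

test_that("depth masking uses strict inequalities around the threshold", {
  # mean depth exactly 7; a depth-5 call goes missing, a depth-7 call stays
  g <- matrix(c(0L, 1L, 2L, 1L), 2, 2)
  d <- matrix(c(5L, 7L, 9L, 7L), 2, 2)
  m <- gm(g, depth = d)
  out <- filter_depth(m, "floor_mean")
  expect_equal(attr(out, "depth_threshold"), 7)
  expect_true(is.na(out$geno[1, 1]))
  expect_equal(unname(out$geno[2, 1]), 1L)
  expect_equal(attr(out, "masked_calls"), 1L)

  # ceiling 7: the depth-9 call goes missing
  out2 <- filter_depth(m, "ceiling_value", 7)
  expect_true(is.na(out2$geno[1, 2]))
  expect_equal(sum(is.na(out2$geno)), 1L)

  # sites left with zero calls are dropped
  g3 <- matrix(c(0L, 1L), 1, 2)
  m3 <- gm(g3, depth = matrix(c(2L, 30L), 1, 2))
  out3 <- filter_depth(m3, "floor_value", 10)
  expect_equal(out3$sites$id, "s002")
  expect_equal(attr(out3, "removed_sites"), "s001")
})

test_that("invariant-site removal keeps polymorphism including all-het sites", {
  g <- cbind(rep(0L, 4), c(0L, 0L, 2L, 2L), rep(1L, 4), rep(2L, 4),
             c(NA, 0L, 0L, NA))
  m <- gm(g)
  out <- drop_invariant(m)
  expect_equal(out$sites$id, c("s002", "s003"))
})

test_that("linkage pruning is greedy with strict distance and documented tie-breaks", {
  mk <- function(pos) gm(matrix(0:2, 3, length(pos)), pos = pos)
  # 127 apart: second removed; 128 apart: both kept
  r1 <- prune_linked(mk(c(1000L, 1127L)), 128)
  expect_equal(r1$matrix$sites$pos, 1000L)
  expect_equal(r1$report$blocked_by, "s001")
  expect_equal(r1$report$distance, 127L)
  r2 <- prune_linked(mk(c(1000L, 1128L)), 128)
  expect_equal(nrow(r2$report), 0L)
  # greedy scan: {0, 100, 200} -> keep 0, drop 100, keep 200
  r3 <- prune_linked(mk(c(0L, 100L, 200L)), 128)
  expect_equal(r3$matrix$sites$pos, c(0L, 200L))
  # position tie: the site with fewer missing calls wins
  g <- cbind(c(0L, NA, 2L), c(0L, 1L, 2L))
  m4 <- gm(g, pos = c(500L, 500L))
  r4 <- prune_linked(m4, 128)
  expect_equal(r4$matrix$sites$id, "s002")
  # de novo (unpositioned) sites pass through with a warning
  m5 <- mk(c(10L, 20L))
  m5$sites$source <- "denovo"
  expect_warning(r5 <- prune_linked(m5, 128), "unpositioned")
  expect_equal(nrow(r5$matrix$sites), 2L)
})

test_that("each filter equals its brute-force recount on random matrices", {
  set.seed(17)
  for (k in 1:10) {
    m <- rand_gm(20, 100, missing_rate = runif(1, 0, 0.4))
    t_miss <- runif(1, 0.1, 0.6)
    expect_equal(filter_site_missing(m, t_miss)$sites$id,
                 oracle_keep_site_missing(m, t_miss))
    t_maf <- runif(1, 0, 0.2)
    expect_equal(filter_maf(m, t_maf)$sites$id, oracle_keep_maf(m, t_maf))
    t_het <- runif(1, 0, 0.3)
    expect_equal(filter_het(m, t_het)$sites$id, oracle_keep_het(m, t_het))
    o_d <- oracle_depth(m, "floor_mean")
    got_d <- filter_depth(m, "floor_mean")
    expect_equal(got_d$sites$id, o_d$keep)
    expect_equal(attr(got_d, "masked_calls"), o_d$masked)
    expect_equal(sort(prune_linked(m, 128)$matrix$sites$id),
                 oracle_prune(m, 128))
    expect_equal(drop_invariant(m)$sites$id, oracle_keep_invariant(m))
  }
})

test_that("filters are idempotent and counts non-increasing along any chain", {
  set.seed(23)
  m <- rand_gm(25, 150, missing_rate = 0.3)
  same_sites <- function(a, b) expect_equal(a$sites$id, b$sites$id)
  f1 <- filter_site_missing(m, 0.4); same_sites(filter_site_missing(f1, 0.4), f1)
  f2 <- filter_maf(m, 0.05); same_sites(filter_maf(f2, 0.05), f2)
  f3 <- filter_het(m, 0.05); same_sites(filter_het(f3, 0.05), f3)
  f4 <- filter_depth(m, "floor_value", 5)
  f4b <- filter_depth(f4, "floor_value", 5)
  same_sites(f4b, f4)
  expect_equal(attr(f4b, "masked_calls"), 0L)
  f5 <- drop_invariant(m); same_sites(drop_invariant(f5), f5)
  f6 <- prune_linked(m, 128)$matrix; same_sites(prune_linked(f6, 128)$matrix, f6)
  f7 <- filter_sample_missing(m, 0.5)
  expect_equal(filter_sample_missing(f7, 0.5)$samples, f7$samples)

  res <- apply_filters(m, filter_config(depth_mode = "floor_value",
                                        depth_value = 4))
  expect_true(all(diff(res$report$sites_before) <= 0))
  expect_true(all(res$report$sites_removed >= 0))
})

test_that("MAF and het filters are invariant under sample order and allele labels", {
  set.seed(29)
  m <- rand_gm(20, 80, missing_rate = 0.2)
  perm <- sample(length(m$samples))
  mp <- m[perm, ]
  expect_equal(filter_maf(mp, 0.05)$sites$id, filter_maf(m, 0.05)$sites$id)
  expect_equal(filter_het(mp, 0.05)$sites$id, filter_het(m, 0.05)$sites$id)
  flip <- sample(c(TRUE, FALSE), 80, replace = TRUE)
  mf <- relabel_alleles(m, flip)
  expect_equal(filter_maf(mf, 0.05)$sites$id, filter_maf(m, 0.05)$sites$id)
  expect_equal(filter_het(mf, 0.05)$sites$id, filter_het(m, 0.05)$sites$id)
})

test_that("apply_filters honors order, logs a consistent report, and has an identity setting", {
  set.seed(37)
  m <- rand_gm(20, 120, missing_rate = 0.15)
  ident <- filter_config(max_site_missing = 1, max_sample_missing = 1,
                         min_maf = 0, min_het = 0, depth_mode = "none",
                         min_link_dist = 0, drop_invariant = FALSE)
  res <- apply_filters(m, ident)
  expect_equal(res$matrix$sites$id, m$sites$id)
  expect_true(all(res$report$sites_removed == 0L))

  cfg <- filter_config()   # the composite reference setting
  res2 <- apply_filters(m, cfg)
  # report is internally consistent: before - removed chains through
  rep <- res2$report
  expect_equal(rep$sites_before[-1], (rep$sites_before - rep$sites_removed)[-nrow(rep)])
  # equals the same rules applied by hand in the same order
  h <- filter_sample_missing(m, 0.9)
  h <- filter_depth(h, "floor_mean")
  h <- filter_site_missing(h, 0.5)
  h <- filter_maf(h, 0.02)
  h <- filter_het(h, 0.01)
  h <- drop_invariant(h)
  h <- prune_linked(h, 128)$matrix
  expect_equal(res2$matrix$sites$id, h$sites$id)
  expect_identical(unname(res2$matrix$geno), unname(h$geno))

  # a permuted order is applied as stated and logged in that order
  ord <- c("maf", "het", "sample_missing", "depth", "site_missing",
           "invariant", "linkage")
  res3 <- apply_filters(m, cfg, order = ord)
  expect_equal(res3$report$rule, ord)
  h2 <- filter_maf(m, 0.02)
  h2 <- filter_het(h2, 0.01)
  h2 <- filter_sample_missing(h2, 0.9)
  h2 <- filter_depth(h2, "floor_mean")
  h2 <- filter_site_missing(h2, 0.5)
  h2 <- drop_invariant(h2)
  h2 <- prune_linked(h2, 128)$matrix
  expect_equal(res3$matrix$sites$id, h2$sites$id)
  expect_error(apply_filters(m, cfg, order = c("maf", "bogus")), "unknown")
})
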