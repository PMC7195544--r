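test_that("allele-sharing distances match a per-pair recount", {
  # identical rows -> 0; opposite homozygotes everywhere -> 1
  m <- gm(rbind(c(0L, 1L, 2L), c(0L, 1L, 2L), c(2L, NA, 0L)))
  d <- pdistance_matrix(m)
  expect_equal(unname(d["S01", "S02"]), 0)
  expect_equal(unname(d["S01", "S03"]), 1)   # |0-2|/2 and |2-0|/2 over 2 sites
  expect_true(isSymmetric(d))
  expect_equal(unname(diag(d)), rep(0, 3))

  set.seed(59)
  m2 <- rand_gm(5, 100, missing_rate = 0.2)
  d2 <- pdistance_matrix(m2)
  for (i in 1:4) for (j in (i + 1):5) {
    gi <- m2$geno[i, ]; gj <- m2$geno[j, ]
    ok <- !is.na(gi) & !is.na(gj)
    expect_equal(unname(d2[i, j]), mean(abs(gi[ok] - gj[ok]) / 2))
  }

  # a pair sharing no called sites is an error naming the pair
  g3 <- rbind(c(0L, NA), c(NA, 1L), c(0L, 1L))
  expect_error(pdistance_matrix(gm(g3)), "S01/S02")
  expect_error(pdistance_matrix(gm(rbind(0L, 1L))), "3 samples")
})

test_that("neighbor joining recovers additive trees exactly", {
  # hand-built additive matrix from ((a:1,b:2):1,(c:3,d:4))
  D <- matrix(c(0, 3, 5, 6,
                3, 0, 6, 7,
                5, 6, 0, 7,
                6, 7, 7, 0), 4, 4,
              dimnames = list(letters[1:4], letters[1:4]))
  tr <- nj_tree(D)
  expect_equal(attr(tr, "clamp_deficit"), 0)
  expect_equal(unname(ape::cophenetic.phylo(tr)[letters[1:4], letters[1:4]]),
               unname(D), tolerance = 1e-12)
  expect_equal(tree_splits(tr), "c,d")
  expect_equal(sort(tr$edge.length), c(1, 1, 2, 3, 4))

  # 3 taxa: unique star with closed-form lengths
  D3 <- matrix(c(0, 2, 3, 2, 0, 5, 3, 5, 0), 3, 3,
               dimnames = list(c("x", "y", "z"), c("x", "y", "z")))
  tr3 <- nj_tree(D3)
  expect_equal(tr3$Nnode, 1L)
  lens <- setNames(tr3$edge.length, tr3$tip.label[tr3$edge[, 2]])
  expect_equal(lens[c("x", "y", "z")], c(x = 0, y = 2, z = 3))

  # random additive instances: path metric and topology both recovered
  for (k in 1:10) {
    inst <- additive_instance(sample(6:12, 1), seed = 100 + k)
    tr_k <- nj_tree(inst$D)
    lbl <- rownames(inst$D)
    expect_lt(max(abs(ape::cophenetic.phylo(tr_k)[lbl, lbl] - inst$D)), 1e-9)
    expect_equal(rf_distance(tr_k, inst$tree)$rf, 0L)
    # independent implementations agree on the topology
    expect_equal(phangorn::RF.dist(tr_k, ape::nj(inst$D)), 0)
  }

  Dbad <- D; Dbad[1, 2] <- NA
  expect_error(nj_tree(Dbad), "NA")
  expect_error(nj_tree(matrix(0, 2, 2)), "3 taxa")
})

test_that("Robinson-Foulds distance equals explicit bipartition enumeration", {
  t1 <- ape::read.tree(text = "((a,b),(c,d));")
  expect_equal(rf_distance(t1, t1)$rf, 0L)
  t2 <- ape::read.tree(text = "((a,c),(b,d));")
  r <- rf_distance(t1, t2)
  expect_equal(r$rf, 2L)               # each tree has one private split
  expect_equal(r$normalized_rf, 1)

  # 8-leaf caterpillar vs balanced: splits enumerated by hand
  cat8 <- ape::read.tree(text = "(((((((a,b),c),d),e),f),g),h);")
  bal8 <- ape::read.tree(text = "(((a,b),(c,d)),((e,f),(g,h)));")
  splits_cat <- list(c("a","b"), c("a","b","c"), c("a","b","c","d"),
                     c("a","b","c","d","e"), c("a","b","c","d","e","f"))
  splits_bal <- list(c("a","b"), c("c","d"), c("e","f"), c("g","h"),
                     c("a","b","c","d"))
  canon <- function(s) {
    all <- letters[1:8]
    vapply(s, function(x) {
      if ("a" %in% x) x <- setdiff(all, x)
      paste(sort(x), collapse = ",")
    }, character(1), USE.NAMES = FALSE)
  }
  shared <- intersect(canon(splits_cat), canon(splits_bal))
  want_rf <- (5 - length(shared)) * 2L
  got <- rf_distance(cat8, bal8)
  expect_equal(got$rf, want_rf)
  expect_setequal(tree_splits(cat8), canon(splits_cat))
  expect_setequal(tree_splits(bal8), canon(splits_bal))
  expect_equal(got$rf, as.integer(phangorn::RF.dist(cat8, bal8)))

  expect_error(rf_distance(t1, ape::read.tree(text = "((a,b),(c,e));")),
               "leaf sets")
})

test_that("rf_distance behaves as a metric on small random trees", {
  set.seed(61)
  trees <- replicate(6, ape::rtree(7, tip.label = letters[1:7]),
                     simplify = FALSE)
  for (i in 1:5) for (j in (i + 1):6) {
    a <- rf_distance(trees[[i]], trees[[j]])$rf
    b <- rf_distance(trees[[j]], trees[[i]])$rf
    expect_equal(a, b)                                   # symmetry
    expect_equal(a, as.integer(phangorn::RF.dist(trees[[i]], trees[[j]])))
    for (k in seq_along(trees)) {                        # triangle inequality
      expect_lte(a, rf_distance(trees[[i]], trees[[k]])$rf +
                   rf_distance(trees[[k]], trees[[j]])$rf)
    }
  }
  expect_equal(rf_distance(trees[[1]], trees[[1]])$rf, 0L)
})

test_that("bootstrap supports are deterministic under a seed and bounded", {
  # two clearly separated groups: 50 fixed differences cannot be broken
  g <- rbind(matrix(0L, 4, 50), matrix(2L, 4, 50))
  m <- gm(g)
  bt <- bootstrap_trees(m, replicates = 50, seed = 5)
  key <- tree_splits(bt$main_tree)
  group_split <- paste(sort(m$samples[5:8]), collapse = ",")
  expect_true(group_split %in% names(bt$supports))
  expect_equal(unname(bt$supports[group_split]), 100)
  expect_true(all(bt$supports >= 0 & bt$supports <= 100))

  set.seed(67)
  m2 <- rand_gm(8, 60, missing_rate = 0.1)
  b1 <- bootstrap_trees(m2, replicates = 30, seed = 9)
  b2 <- bootstrap_trees(m2, replicates = 30, seed = 9)
  expect_identical(b1$supports, b2$supports)
  b3 <- bootstrap_trees(m2, replicates = 1, seed = 9)
  expect_true(all(b3$supports %in% c(0, 100)))
})

test_that("concordance_suite reports zero RF for a matrix against itself", {
  set.seed(71)
  m <- rand_gm(10, 120, missing_rate = 0.1)
  suite <- concordance_suite(list(a = m, b = m), replicates = 20, seed = 3)
  expect_equal(suite$summary$rf, 0L)
  expect_equal(length(suite$reports[["a|b"]]$unique_to_a), 0L)
  m_small <- m[1:2, ]
  expect_error(concordance_suite(list(a = m, b = m_small)), "at least 3")
})
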