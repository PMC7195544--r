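test_that("demultiplexing assigns by longest barcode prefix and counts discards", {
  set.seed(1)
  key <- barcode_key(c("s1", "s2", "s3"), c("ACGT", "TTAGC", "ACGA"))
  tag64 <- random_tag_seqs(1, 64)
  tag_n <- paste0(substr(tag64, 1, 63), "N")
  reads <- data.frame(
    read_id = sprintf("r%d", 1:5),
    sequence = c(
      paste0("ACGT", tag64),                    # full tag after barcode
      paste0("ACGT", substr(tag64, 1, 63)),     # one base short
      paste0("GGGG", tag64),                    # no barcode
      paste0("TTAGC", tag64),                   # 5-mer barcode
      paste0("ACGA", tag_n)                     # N inside the window
    ),
    quality = "x", stringsAsFactors = FALSE
  )
  res <- demultiplex_and_trim(reads, key, tag_length = 64)
  expect_equal(res$tags$s1, tag64)
  expect_equal(res$tags$s2, tag64)
  expect_length(res$tags$s3, 0L)
  expect_equal(res$discards,
               c(no_barcode = 1L, too_short = 1L, ambiguous_base = 1L))
  expect_error(demultiplex_and_trim(reads, key[0, ]), "empty")
})

test_that("collapse_tags counts per sample and conserves reads", {
  res <- collapse_tags(list(s1 = c("AAAA", "AAAA", "AAAA", "AAAT", "AAAT"),
                            s2 = "AAAA"))
  expect_equal(res$sequences, c("AAAA", "AAAT"))
  expect_equal(res$counts["AAAA", ], c(s1 = 3L, s2 = 1L))
  expect_equal(res$counts["AAAT", ], c(s1 = 2L, s2 = 0L))
  expect_equal(sum(res$totals), 6L)

  empty <- collapse_tags(list(s1 = character(0)))
  expect_length(empty$sequences, 0L)

  # 10,000 reads over 50 distinct sequences: brute-force recount
  set.seed(5)
  pool <- random_tag_seqs(50, 20)
  draws <- split(sample(pool, 10000, replace = TRUE),
                 sample(c("a", "b", "c"), 10000, replace = TRUE))
  res2 <- collapse_tags(draws)
  expect_length(res2$sequences, 50L)
  expect_equal(sum(res2$totals), 10000L)
  for (s in c("a", "b", "c")) {   # independent recount per sample
    expect_equal(unname(res2$counts[, s]),
                 as.integer(table(factor(draws[[s]], levels = res2$sequences))))
  }
})

test_that("pair_tags finds exactly the Hamming-distance-1 pairs", {
  ts <- as_tag_set(c("ACGT", "ACGA", "AGGA"))
  pr <- pair_tags(ts)
  expect_equal(nrow(pr), 2L)  # ACGA-ACGT (pos 4) and ACGA-AGGA (pos 2)
  p1 <- pr[pr$tag_a == "ACGA" & pr$tag_b == "ACGT", ]
  expect_equal(p1$snp_offset, 4L)
  expect_equal(c(p1$allele_a, p1$allele_b), c("A", "T"))
  # distance-2 pair is absent
  expect_false(any(pr$tag_a == "ACGT" & pr$tag_b == "AGGA"))

  # planted partners against the all-pairs oracle
  set.seed(9)
  base <- random_tag_seqs(400, 64)
  planted <- vapply(base[1:20], function(s) {
    p <- sample.int(64, 1)
    substr(s, p, p) <- sample(setdiff(BASES4, substr(s, p, p)), 1)
    s
  }, character(1), USE.NAMES = FALSE)
  ts2 <- as_tag_set(c(base, planted))
  got <- pair_tags(ts2)
  want <- oracle_pairs_bf(ts2$sequences)
  got_keys <- paste(got$a_idx, got$b_idx)
  want_keys <- paste(want$a_idx, want$b_idx)
  expect_setequal(got_keys, want_keys)
  expect_gte(nrow(got), 20L)
})

test_that("pairing is invariant to input order (canonical internal ordering)", {
  set.seed(21)
  seqs <- random_tag_seqs(100, 32)
  seqs[51:60] <- vapply(seqs[1:10], function(s) {
    substr(s, 7, 7) <- setdiff(BASES4, substr(s, 7, 7))[1]; s
  }, character(1), USE.NAMES = FALSE)
  p1 <- pair_tags(as_tag_set(seqs))
  p2 <- pair_tags(as_tag_set(rev(seqs)))
  expect_identical(p1$tag_a, p2$tag_a)
  expect_identical(p1$tag_b, p2$tag_b)
  expect_identical(p1$snp_offset, p2$snp_offset)
})

test_that("network error filter drops skewed-count pairs and complex networks", {
  mk_pairs <- function(seqs, counts) {
    ts <- as_tag_set(rep(seqs, counts))
    pair_tags(ts)
  }
  # (100, 1): 1/101 < 0.03 -> dropped; (60, 40) kept
  pr <- mk_pairs(c("AAAA", "AAAT", "GGGG", "GGGC"), c(100, 1, 60, 40))
  out <- network_error_filter(pr, etr = 0.03)
  expect_equal(nrow(out), 1L)
  expect_equal(sort(c(out$tag_a, out$tag_b)), c("GGGC", "GGGG"))
  rep <- attr(out, "network_filter_report")
  expect_equal(unname(rep["dropped_error_ratio"]), 1L)

  # A pairs with both B and C -> all of A's pairs dropped unless allowed
  pr2 <- mk_pairs(c("AAAA", "AAAT", "AAAC"), c(50, 50, 50))
  out2 <- network_error_filter(pr2, etr = 0.03)
  expect_equal(nrow(out2), 0L)
  expect_equal(unname(attr(out2, "network_filter_report")["dropped_complex"]),
               nrow(pr2))
  out3 <- network_error_filter(pr2, etr = 0.03, allow_complex = TRUE)
  expect_equal(nrow(out3), nrow(pr2))
})

test_that("map_tags keeps unique best placements and discards multimappers", {
  set.seed(13)
  ref <- paste(sample(BASES4, 3000, replace = TRUE), collapse = "")
  win <- function(at) substr(ref, at, at + 63)
  # plant a duplicated segment so its tag multimaps
  dup <- win(101)
  ref <- paste0(substr(ref, 1, 2000), dup, substr(ref, 2065, 3000))
  tag_unique <- win(501)
  tag_mut <- tag_unique
  substr(tag_mut, 10, 10) <- setdiff(BASES4, substr(tag_mut, 10, 10))[1]
  tag_alien <- random_tag_seqs(1, 64)
  ts <- as_tag_set(c(tag_unique, tag_mut, dup, tag_alien))
  pl <- map_tags(ts, c(chrA = ref))
  st <- attr(pl, "stats")
  expect_equal(sum(st), 1)
  expect_equal(unname(st["multimapped_frac"]), 0.25)
  expect_equal(unname(st["unaligned_frac"]), 0.25)
  got_u <- pl[pl$tag == tag_unique, ]
  expect_equal(got_u$start, 501L)
  expect_equal(got_u$n_mismatch, 0L)
  got_m <- pl[pl$tag == tag_mut, ]
  expect_equal(got_m$n_mismatch, 1L)
  expect_equal(got_m$mismatches[[1]]$offset, 10L)
  expect_false(dup %in% pl$tag)

  # reverse-complement placement
  rc <- paste(rev(strsplit(chartr("ACGT", "TGCA", win(801)), "")[[1]]),
              collapse = "")
  pl2 <- map_tags(as_tag_set(rc), c(chrA = ref))
  expect_equal(pl2$strand, "-")
  expect_equal(pl2$start, 801L)
})

test_that("placements_to_sites emits biallelic sites and counts triallelic positions", {
  set.seed(14)
  ref <- paste(sample(BASES4, 400, replace = TRUE), collapse = "")
  w <- substr(ref, 51, 114)
  mk_var <- function(at, base) { s <- w; substr(s, at, at) <- base; s }
  othersA <- setdiff(BASES4, substr(w, 20, 20))
  othersB <- setdiff(BASES4, substr(w, 40, 40))
  ts <- as_tag_set(c(w, mk_var(20, othersA[1]),
                     mk_var(40, othersB[1]), mk_var(40, othersB[2])))
  pl <- map_tags(ts, c(c1 = ref))
  sites <- placements_to_sites(pl)
  expect_equal(attr(sites, "triallelic_count"), 1L)  # position 90: 3 alleles
  expect_equal(nrow(sites), 1L)
  expect_equal(sites$pos, 70L)                       # 51 + 20 - 1
  expect_equal(sites$ref, substr(w, 20, 20))
  expect_equal(sites$alt, othersA[1])
  obs <- sites$obs[[1]]
  expect_equal(nrow(obs), 4L)                        # all four tags cover it
})
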