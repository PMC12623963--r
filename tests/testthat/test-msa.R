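test_that("column depth counts non-gap rows, including the query", {
  msa <- toy_msa(c("q"), c("ACDE"))
  expect_equal(column_depth(msa), rep(1L, 4))

  msa <- toy_msa(c("q", "r"), c("AAAA", "A--A"))
  expect_equal(column_depth(msa), c(2L, 1L, 1L, 2L))
  expect_equal(depth_window(msa, 2, 3), 1)
  expect_error(depth_window(msa, 0, 2), "outside")
})

test_that("empirical depth of a sampled MSA matches the binomial expectation", {
  # column coverage p over n rows: depth ~ 1 + Binomial(n, p)
  n <- 1000L
  p <- 0.35
  msa <- make_msa(40, n, coverage_profile = p, rng_seed = 99)
  d <- column_depth(msa) - 1L  # remove the always-present query
  expect_true(all(abs(d - n * p) <= 3 * sqrt(n * p * (1 - p))))
})

test_that("template filter applies the e-value, length and coverage cutoffs", {
  hits <- toy_hits(list(start = 1, end = 100, evalue = 2.0),      # e-value
                   list(start = 1, end = 40),                     # 40 exactly
                   list(start = 1, end = 41),                     # 41: kept
                   list(start = 1, end = 100, coverage = 0.5),    # 0.5 exactly
                   list(start = 1, end = 100))                    # kept
  kept <- filter_hits(hits)
  expect_equal(nrow(kept), 2L)
  expect_equal(kept$target_end, c(41, 100))
  expect_equal(filter_hits(kept), kept)  # idempotent
  expect_equal(nrow(filter_hits(hits[0, ])), 0L)
})

test_that("domain segmentation follows the gap rules", {
  # no hits: everything is one domain
  seg <- segment_domains(toy_hits()[0, ], 200)
  expect_equal(seg$domains, matrix(c(1L, 200L), 1))

  # 40-residue gap splits at the midpoint
  seg <- segment_domains(toy_hits(list(start = 1, end = 120),
                                  list(start = 161, end = 320)), 320)
  expect_equal(seg$domains, rbind(c(1L, 140L), c(141L, 320L)))

  # 59-residue gap (> 40) becomes its own domain
  seg <- segment_domains(toy_hits(list(start = 1, end = 100),
                                  list(start = 160, end = 320)), 320)
  expect_equal(seg$domains, rbind(c(1L, 100L), c(101L, 159L), c(160L, 320L)))

  expect_error(segment_domains(toy_hits()[0, ], 0), "target_length")
})

test_that("segmentation always partitions the target on randomized hit tables", {
  set.seed(7)
  for (trial in 1:50) {
    L <- sample(80:400, 1)
    nh <- sample(0:6, 1)
    hits <- if (nh > 0) {
      s <- sort(sample.int(L, nh))
      e <- pmin(L, s + sample(10:120, nh, replace = TRUE))
      data.frame(template_id = paste0("t", seq_len(nh)), target_start = s,
                 target_end = e, evalue = 1e-4, template_length = e - s + 1,
                 coverage = 0.9)
    } else toy_hits()[0, ]
    seg <- segment_domains(hits, L)
    covered <- unlist(apply(seg$domains, 1, function(d) d[1]:d[2],
                            simplify = FALSE))
    expect_equal(as.integer(covered), seq_len(L))
  }
})

test_that("disorder refinement moves boundaries to the run midpoint", {
  hits <- toy_hits(list(start = 1, end = 100), list(start = 160, end = 320))
  dis <- rep(FALSE, 320)
  dis[95:110] <- TRUE  # run of 16 containing the 1-100|101 boundary
  seg <- segment_domains(hits, 320, disorder = dis)
  expect_equal(seg$domains[1, 2], 102L)  # midpoint of 95..110
  expect_equal(seg$domains[2, 1], 103L)

  # short runs (< 5) leave boundaries alone
  dis2 <- rep(FALSE, 320)
  dis2[99:101] <- TRUE
  seg2 <- segment_domains(hits, 320, disorder = dis2)
  expect_equal(seg2$domains[1, ], c(1L, 100L))
})

test_that("identifier pairing matches the set-intersection oracle", {
  d1 <- toy_msa(c("q1", "U1", "U2", "U3"), c("AAAA", "AC-A", "AAAA", "CCCC"))
  d2 <- toy_msa(c("q2", "U1", "U4"), c("GGG", "G-G", "GGG"))
  pr <- pair_domain_alignments(list(d1, d2))
  expect_equal(pr$paired$id, "U1")
  expect_equal(pr$paired$domain1, "AC-A")
  expect_equal(pr$paired$domain2, "G-G")
  expect_length(pr$unpaired[[1]], 2L)
  expect_length(pr$unpaired[[2]], 1L)

  set.seed(11)
  universe <- sprintf("U%03d", 1:60)
  for (trial in 1:50) {
    ids1 <- sample(universe, sample(5:30, 1))
    ids2 <- sample(universe, sample(5:30, 1))
    m1 <- toy_msa(c("q1", ids1), c("AAAA", rep("ACAA", length(ids1))))
    m2 <- toy_msa(c("q2", ids2), c("GG", rep("GG", length(ids2))))
    pr <- pair_domain_alignments(list(m1, m2))
    expect_equal(nrow(pr$paired), length(intersect(ids1, ids2)))
    expect_length(pr$unpaired[[1]], length(setdiff(ids1, ids2)))
    expect_length(pr$unpaired[[2]], length(setdiff(ids2, ids1)))
  }
})

test_that("gap padding reconstructs full-length rows", {
  expect_equal(pad_unpaired("WXYZ", c(3, 6), 8), "--WXYZ--")
  expect_equal(pad_unpaired("WXYZ", c(1, 4), 4), "WXYZ")
  expect_error(pad_unpaired("WXY", c(3, 6), 8), "length")

  # gap arithmetic: padding adds exactly the outside-interval positions
  row <- "AC--DE"
  padded <- pad_unpaired(row, c(5, 10), 20)
  expect_equal(nchar(padded), 20L)
  expect_equal(lengths(regmatches(padded, gregexpr("-", padded))),
               20 - 6 + 2)
})

test_that("domain-based MSA combines full, paired and padded rows", {
  seg <- domain_segmentation(8, rbind(c(1, 4), c(5, 8)))
  full <- toy_msa(c("q", paste0("F", 1:10)),
                  c("ACDEFGHI", replicate(10, "ACDEFGH-")))
  d1 <- toy_msa(c("q1", "P1", "P2", "P3", "X1", "X2"),
                c("ACDE", "AC-E", "ACDE", "AADE", "CCDE", "GCDE"))
  d2 <- toy_msa(c("q2", "P1", "P2", "P3", "Y1"),
                c("FGHI", "FG-I", "FGHI", "FFHI", "GGHI"))
  out <- build_domain_msa(full, list(d1, d2), seg)
  # 1 query + 10 full + 3 paired + 2 + 1 unpaired
  expect_length(out, 17L)
  expect_true(all(nchar(out$seqs) == 8L))
  expect_equal(out$seqs[out$ids == "P1"], "AC-EFG-I")
  expect_equal(out$seqs[out$ids == "Y1"], "----GGHI")

  # no domain MSAs: query + full rows only
  out2 <- build_domain_msa(full, list(), seg)
  expect_length(out2, 11L)

  # duplicate (id, sequence) rows are dropped
  fulldup <- toy_msa(c("q", "F1", "F1"), c("ACDEFGHI", "ACDEFGH-", "ACDEFGH-"))
  expect_length(build_domain_msa(fulldup, list(), seg), 2L)

  expect_error(build_domain_msa(full, list(d1), seg), "one domain MSA per")
})

test_that("profile augmentation substitutes dominant column residues", {
  # 9 of 10 rows carry L where the query has V: synthetic row 1 takes L
  msa <- toy_msa(c("q", paste0("r", 1:9)),
                 c("VAAA", replicate(9, "LAAA")))
  aug <- augment_with_profile(msa, n_sequences = 2)
  expect_length(aug, 12L)
  syn1 <- aug$seqs[aug$ids == "profile_syn_1"]
  expect_equal(substr(syn1, 1, 1), "L")
  # no second-most-frequent residue above threshold: row 2 keeps the query
  syn2 <- aug$seqs[aug$ids == "profile_syn_2"]
  expect_equal(substr(syn2, 1, 1), "V")

  # query-only MSA has no signal: synthetic rows equal the query
  qonly <- toy_msa("q", "VWAC")
  aug2 <- augment_with_profile(qonly)
  expect_equal(aug2$seqs[2:3], c("VWAC", "VWAC"))

  expect_error(augment_with_profile(msa, n_sequences = 0), "n_sequences")
})
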