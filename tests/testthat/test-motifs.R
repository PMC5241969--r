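# PWM scanning, motif-pair taxonomy, interaction enrichment, network nulls

test_that("scanner scores match the worked examples", {
  # PWM equal to background: all scores 0, nothing at threshold 6
  flat <- pwm("flat", matrix(0.25, nrow = 4, ncol = 5))
  hits <- scan_motifs("ACGTACGTACGT", flat, scan_config(threshold = 6))
  expect_equal(nrow(hits), 0)
  hits0 <- scan_motifs("ACGTACGT", flat,
                       scan_config(threshold = 0, pseudocount = 0))
  expect_true(all(abs(hits0$score) < 1e-12))
  # consensus 4-mer at p = 0.97: exact match scores 4*ln(0.97/0.25)
  mat <- matrix(0.01, nrow = 4, ncol = 4)
  mat[cbind(c(1, 2, 3, 4), 1:4)] <- 0.97
  cons <- pwm("cons", mat)
  sc <- 4 * log(0.97 / 0.25)
  h5 <- scan_motifs("TTACGTTT", cons, scan_config(threshold = 5,
                                                  pseudocount = 0))
  expect_equal(nrow(h5[h5$strand == "+", ]), 1)
  expect_equal(h5$score[h5$strand == "+"], sc, tolerance = 1e-9)
  expect_equal(h5$start[h5$strand == "+"], 2L)  # 0-based
  h6 <- scan_motifs("TTACGTTT", cons, scan_config(threshold = 6,
                                                  pseudocount = 0))
  expect_equal(nrow(h6), 0)
  # zero probability without pseudocount errors
  zero <- pwm("z", matrix(c(1, 0, 0, 0), nrow = 4, ncol = 2))
  expect_error(scan_motifs("AAAA", zero, scan_config(pseudocount = 0)),
               "zero-probability")
  # windows containing N are skipped
  hN <- scan_motifs("TTANGTTT", cons, scan_config(threshold = -100,
                                                  pseudocount = 0.01))
  expect_false(any(hN$start <= 3 & hN$end > 3))
})

test_that("scanner agrees with exhaustive k-mer enumeration", {
  set.seed(61)
  for (w in c(3, 5, 8)) {
    counts <- matrix(rpois(4 * w, 5) + 1, nrow = 4)
    p <- pwm(sprintf("M%d", w), counts)
    cfg <- scan_config(threshold = 2, pseudocount = 0.01)
    seq <- paste(sample(c("A", "C", "G", "T"), 500, replace = TRUE),
                 collapse = "")
    hits <- scan_motifs(seq, p, cfg)
    # oracle: enumerate every window on both strands with naive scoring
    mat <- sweep(p$matrix + 0.01, 2, colSums(p$matrix + 0.01), "/")
    expected <- list()
    for (s in 1:(nchar(seq) - w + 1)) {
      win <- substr(seq, s, s + w - 1)
      fs <- oracle_score(win, mat, p$background)
      rs <- oracle_score(oracle_revcomp(win), mat, p$background)
      if (!is.na(fs) && fs >= cfg$threshold) {
        expected[[length(expected) + 1]] <- c(s - 1, "+", fs)
      }
      if (!is.na(rs) && rs >= cfg$threshold) {
        expected[[length(expected) + 1]] <- c(s - 1, "-", rs)
      }
    }
    exp_df <- do.call(rbind, expected)
    expect_equal(nrow(hits), NROW(exp_df))
    if (NROW(exp_df) > 0) {
      o1 <- order(hits$start, hits$strand)
      o2 <- order(as.integer(exp_df[, 1]), exp_df[, 2])
      expect_equal(hits$start[o1], as.integer(exp_df[o2, 1]))
      expect_equal(hits$strand[o1], exp_df[o2, 2])
      expect_equal(hits$score[o1], as.numeric(exp_df[o2, 3]),
                   tolerance = 1e-9)
    }
  }
})

test_that("scores on the reverse complement swap strands", {
  set.seed(62)
  counts <- matrix(rpois(4 * 6, 4) + 1, nrow = 4)
  p <- pwm("M", counts)
  cfg <- scan_config(threshold = 1)
  seq <- paste(sample(c("A", "C", "G", "T"), 300, replace = TRUE),
               collapse = "")
  rc <- oracle_revcomp(seq)
  h1 <- scan_motifs(seq, p, cfg)
  h2 <- scan_motifs(rc, p, cfg)
  # hit at [s, e) on + of seq <-> hit at [L-e, L-s) on - of revcomp
  L <- nchar(seq)
  k1 <- sort(paste(h1$start, h1$end, h1$strand, round(h1$score, 9)))
  k2 <- sort(paste(L - h2$end, L - h2$start,
                   ifelse(h2$strand == "+", "-", "+"), round(h2$score, 9)))
  expect_equal(k1, k2)
})

test_that("classify_motif_pair applies the precedence order", {
  tfnet <- tf_network(c("X", "Y", "Z"), data.frame(tf1 = "X", tf2 = "Y"))
  hit <- function(tf, start, chrom = "chr1", strand = "+") {
    data.frame(tf = tf, chrom = chrom, start = start, end = start + 8L,
               strand = strand, score = 10, stringsAsFactors = FALSE)
  }
  expect_equal(classify_motif_pair(hit("X", 100L), hit("X", 100L), tfnet),
               "same_motif_same_position")
  expect_equal(classify_motif_pair(hit("X", 100L), hit("X", 900L), tfnet),
               "same_motif_different_position")
  expect_equal(classify_motif_pair(hit("X", 100L), hit("Y", 900L), tfnet),
               "different_motifs_tfs_interact")
  expect_equal(classify_motif_pair(hit("X", 100L), hit("Z", 900L), tfnet),
               "different_motifs_tfs_do_not_interact")
  # same-position beats everything even when other hits are present
  a <- rbind(hit("X", 100L), hit("Y", 300L))
  b <- rbind(hit("X", 100L), hit("Z", 700L))
  expect_equal(classify_motif_pair(a, b, tfnet), "same_motif_same_position")
  # excluded unless both mutations are in at least one motif
  expect_true(is.na(classify_motif_pair(hit("X", 1L)[0, ], hit("X", 1L),
                                        tfnet)))
  # symmetry
  expect_equal(classify_motif_pair(a, b, tfnet),
               classify_motif_pair(b, a, tfnet))
})

test_that("motif-pair enrichment handles baselines and self-pair policy", {
  tfnet <- tf_network(c("A", "B"), data.frame(tf1 = "A", tf2 = "B"))
  region_pairs <- data.frame(region_a = "r1", region_b = "r2")
  hits <- data.frame(region = c("r1", "r2", "r2", "r2"),
                     tf = c("A", "B", "B", "A"))
  # cross pairs: (A,B), (A,B), (A,A) -> 2/3 interacting
  res <- motif_pair_interaction_enrichment(region_pairs, hits, tfnet,
                                           include_self_pairs = TRUE)
  expect_equal(res$observed$fraction, 2 / 3)
  expect_equal(res$baseline1, 1 / 3)   # {AA, AB, BB}
  expect_equal(res$enrichment1, 2.0)
  res2 <- motif_pair_interaction_enrichment(region_pairs, hits, tfnet,
                                            include_self_pairs = FALSE)
  expect_equal(res2$baseline1, 1)      # {AB} only
  # complete TF network saturates baseline 1
  full <- tf_network(c("A", "B"), data.frame(tf1 = c("A", "A", "B"),
                                             tf2 = c("A", "B", "B")))
  res3 <- motif_pair_interaction_enrichment(region_pairs, hits, full,
                                            include_self_pairs = TRUE)
  expect_equal(res3$baseline1, 1)
  expect_equal(res3$enrichment1, res3$observed$fraction)
  expect_error(motif_pair_interaction_enrichment(
    region_pairs, hits, tf_network(c("A", "B"))), "no edges")
})

test_that("scrambled networks preserve every node degree", {
  d <- simulate_motif_dataset(sim_config(seed = 9, n_regions = 30L))
  ref <- degree_multiset(d$region_pairs)
  changed <- 0
  for (s in 1:25) {
    sc <- scramble_edges(d$region_pairs, seed = s)
    expect_equal(degree_multiset(sc), ref)
    if (!identical(sc, d$region_pairs)) changed <- changed + 1
  }
  expect_gt(changed, 20)  # the null actually randomises
  # seeded scrambles are reproducible and leave the caller's RNG alone
  set.seed(99); before <- runif(1)
  set.seed(99)
  s1 <- scramble_edges(d$region_pairs, seed = 42)
  expect_equal(runif(1), before)
  expect_identical(s1, scramble_edges(d$region_pairs, seed = 42))
})

test_that("planted interacting-TF co-occurrence is detected", {
  d <- simulate_motif_dataset(sim_config(seed = 13))
  res <- motif_pair_interaction_enrichment(d$region_pairs, d$hits_by_region,
                                           d$tfnet, n_scrambles = 30,
                                           seed = 5)
  expect_gt(res$enrichment1, 1.5)
  expect_lt(res$p1, 0.05)
  expect_gt(res$enrichment2, 1)
  expect_lt(res$p2, 0.1)
})

test_that("motif-category concordance uses the non-interacting reference", {
  tfnet <- tf_network(c("X", "Y", "Z"), data.frame(tf1 = "X", tf2 = "Y"))
  muts <- mutations(
    id = sprintf("v%d", 1:6), chrom = "chr1",
    pos = c(1000L, 1002L, 9000L, 20000L, 30000L, 40000L),
    mclass = "non_coding",
    diseases = list("d1", "d1", "d1", "d1", "d2", "d3"))
  hit <- function(tf, start) data.frame(tf = tf, chrom = "chr1",
                                        start = start, end = start + 8L,
                                        strand = "+", score = 10,
                                        stringsAsFactors = FALSE)
  hits <- rbind(hit("X", 996L),     # covers v1 and v2: one shared instance
                hit("X", 8996L),    # v3
                hit("Y", 19996L),   # v4
                hit("Z", 29996L),   # v5
                hit("Z", 39996L))   # v6
  empty_net <- chromatin_net(
    anchors = data.frame(anchor_id = character(0), chrom = character(0),
                         start = integer(0), end = integer(0)),
    edges = data.frame(anchor_id = character(0), chrom = character(0),
                       start = integer(0), end = integer(0)))
  pairs <- classify_pairs(muts, empty_net)
  out <- concordance_by_motif_category(pairs, hits, tfnet, scope = "all")
  get <- function(cat, col) out[out$category == cat, col]
  expect_equal(get("same_motif_same_position", "n"), 1L)         # (v1,v2)
  expect_equal(get("same_motif_same_position", "fraction"), 1.0)
  expect_equal(get("same_motif_different_position", "n"), 3L)    # v1/2-v3, v5-v6
  expect_equal(get("same_motif_different_position", "fraction"), 2 / 3)
  expect_equal(get("different_motifs_tfs_interact", "n"), 3L)    # X-Y pairs
  expect_equal(get("different_motifs_tfs_interact", "fraction"), 1.0)
  expect_equal(get("different_motifs_tfs_do_not_interact", "fraction"), 0)
  expect_lt(get("different_motifs_tfs_interact", "p"), 0.05)
})
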