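# PWM log-likelihood motif scanning, the motif-localised mutation-pair
# taxonomy, and the interacting-TF motif-pair enrichment with its two nulls.

MOTIF_PAIR_CATEGORIES <- c("same_motif_same_position",
                           "same_motif_different_position",
                           "different_motifs_tfs_interact",
                           "different_motifs_tfs_do_not_interact")

#' Scanner configuration
#'
#' @param threshold log-likelihood score cutoff for reporting hits. The
#'   motif-localisation analyses use the grid 6, 7, 8, 9 (default 6); the
#'   interacting-TF motif-pair analysis uses 8, 9, 10.
#' @param window search-region width (bp) centred at each variant.
#' @param pseudocount added to every PWM cell before column renormalisation;
#'   0 disables it (then zero-probability cells are an error).
#' @param log_base base of the log-likelihood (default natural log).
#' @return a `scan_config` list.
#' @export
scan_config <- function(threshold = 6, window = 4000, pseudocount = 0.01,
                        log_base = exp(1)) {
  stopifnot(window %% 2 == 0, pseudocount >= 0, log_base > 1)
  structure(list(threshold = threshold, window = window,
                 pseudocount = pseudocount, log_base = log_base),
            class = "scan_config")
}

# log-likelihood-ratio matrix (4 x w) after pseudocount; rows A,C,G,T
pwm_llr <- function(p, cfg) {
  mat <- p$matrix
  if (cfg$pseudocount > 0) {
    mat <- sweep(mat + cfg$pseudocount, 2, colSums(mat + cfg$pseudocount), "/")
  } else if (any(mat == 0)) {
    stop("PWM ", p$tf, " has zero-probability cells and pseudocount is 0")
  }
  log(mat / p$background, base = cfg$log_base)
}

# reverse-complement of an LLR matrix: complement rows, reverse columns
llr_revcomp <- function(lr) lr[c(4, 3, 2, 1), rev(seq_len(ncol(lr))), drop = FALSE]

encode_seq <- function(seq) {
  if (methods::is(seq, "DNAString") || methods::is(seq, "DNAStringSet")) {
    seq <- as.character(seq)
  }
  code <- match(strsplit(toupper(seq), "")[[1]], c("A", "C", "G", "T"))
  code  # N and anything else -> NA
}

# windowed sums of lr over the encoded sequence; NA where the window has an N
window_scores <- function(code, lr) {
  w <- ncol(lr); n <- length(code) - w + 1L
  if (n < 1L) return(numeric(0))
  sc <- numeric(n)
  for (k in seq_len(w)) {
    v <- lr[, k][code[k:(k + n - 1L)]]
    sc <- sc + v  # NA propagates through windows containing N
  }
  sc
}

#' Scan a sequence for PWM hits
#'
#' Scores every window of PWM width on both strands with the summed
#' log-likelihood ratio of motif versus background base probabilities;
#' windows containing N are skipped. Hits are windows scoring at or above
#' the threshold, reported with strand and 0-based half-open coordinates.
#'
#' @param seq nucleotide string (character or `DNAString`) over A, C, G, T,
#'   N.
#' @param p a [pwm()].
#' @param cfg a [scan_config()].
#' @param chrom sequence name recorded in the hits.
#' @param offset 0-based genomic start of `seq` (so hits carry genomic
#'   coordinates when scanning an extracted window).
#' @return data.frame: `tf`, `chrom`, `start`, `end`, `strand`, `score`.
#' @export
scan_motifs <- function(seq, p, cfg = scan_config(), chrom = "seq",
                        offset = 0L) {
  code <- encode_seq(seq)
  lr <- pwm_llr(p, cfg)
  w <- ncol(lr)
  fwd <- window_scores(code, lr)
  rev <- window_scores(code, llr_revcomp(lr))
  collect <- function(sc, strand) {
    keep <- which(!is.na(sc) & sc >= cfg$threshold)
    if (length(keep) == 0) {
      return(data.frame(tf = character(0), chrom = character(0),
                        start = integer(0), end = integer(0),
                        strand = character(0), score = numeric(0)))
    }
    data.frame(tf = p$tf, chrom = chrom,
               start = as.integer(offset + keep - 1L),
               end = as.integer(offset + keep - 1L + w),
               strand = strand, score = sc[keep],
               stringsAsFactors = FALSE)
  }
  out <- rbind(collect(fwd, "+"), collect(rev, "-"))
  rownames(out) <- NULL
  out
}

#' Scan a genome (set of named sequences) with a set of PWMs
#'
#' @param seqs named `DNAStringSet` or named character vector.
#' @param pwms list of [pwm()] objects.
#' @param cfg a [scan_config()].
#' @return combined hit data.frame (see [scan_motifs()]).
#' @export
scan_genome <- function(seqs, pwms, cfg = scan_config()) {
  seqs <- setNames(as.character(seqs), names(seqs))
  if (is.null(names(seqs))) stop("sequences must be named")
  out <- list()
  for (nm in names(seqs)) {
    for (p in pwms) {
      out[[length(out) + 1L]] <- scan_motifs(seqs[[nm]], p, cfg, chrom = nm)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Motif hits covering each mutation
#'
#' @param muts a [mutations()] table.
#' @param hits a hit data.frame from [scan_motifs()] / [read_motif_hits()].
#' @return list (one element per mutation row) of hit data.frames whose
#'   interval contains the mutation's position.
#' @export
mutation_hits <- function(muts, hits) {
  lapply(seq_len(nrow(muts)), function(k) {
    p0 <- muts$pos[k] - 1L  # 0-based
    sel <- hits$chrom == muts$chrom[k] & hits$start <= p0 & p0 < hits$end
    hits[sel, , drop = FALSE]
  })
}

#' Classify a mutation pair by its motif context
#'
#' Both mutations must lie in at least one TF binding motif, otherwise the
#' pair is excluded (`NA`). Across all combinations of hits the best
#' category wins, with precedence: same motif instance at the same position
#' (identical tf/chrom/start/end/strand) > binding sites of the same TF at
#' different positions > motifs of two TFs that interact > motifs of two
#' TFs that do not interact.
#'
#' @param hits_a,hits_b hit data.frames for the two mutations (see
#'   [mutation_hits()]).
#' @param tfnet a [tf_network()].
#' @return one of `MOTIF_PAIR_CATEGORIES`, or `NA`.
#' @export
classify_motif_pair <- function(hits_a, hits_b, tfnet) {
  if (nrow(hits_a) == 0 || nrow(hits_b) == 0) return(NA_character_)
  key <- function(h) paste(h$tf, h$chrom, h$start, h$end, h$strand, sep = "\r")
  if (length(intersect(key(hits_a), key(hits_b))) > 0) {
    return("same_motif_same_position")
  }
  ta <- unique(hits_a$tf); tb <- unique(hits_b$tf)
  if (length(intersect(ta, tb)) > 0) {
    return("same_motif_different_position")
  }
  combos <- expand.grid(a = ta, b = tb, stringsAsFactors = FALSE)
  if (any(tfs_interact(tfnet, combos$a, combos$b))) {
    return("different_motifs_tfs_interact")
  }
  "different_motifs_tfs_do_not_interact"
}

#' Disease concordance per motif-pair category
#'
#' Restricts chromatin-classified pairs to a scope, assigns each pair its
#' motif category (pairs where either mutation lacks a motif hit are
#' dropped), and reports per category the same-disease fraction, SEM and an
#' upper-tail cumulative binomial p value against the
#' `different_motifs_tfs_do_not_interact` reference.
#'
#' @param pairs output of [classify_pairs()].
#' @param hits motif hit data.frame (typically scanned at threshold 6).
#' @param tfnet a [tf_network()].
#' @param scope `"all"`, `"same_chromosome"`, `"same_anchor"` or
#'   `"interacting"`.
#' @return data.frame: `category`, `n`, `k_same`, `fraction`, `sem`, `p`.
#' @export
concordance_by_motif_category <- function(pairs, hits, tfnet,
                                          scope = c("all", "same_chromosome",
                                                    "same_anchor",
                                                    "interacting")) {
  scope <- match.arg(scope)
  muts <- attr(pairs, "muts")
  if (is.null(muts)) stop("pairs must come from classify_pairs()")
  sel <- switch(scope,
    all = rep(TRUE, nrow(pairs)),
    same_chromosome = muts$chrom[pairs$i] == muts$chrom[pairs$j],
    same_anchor = !is.na(pairs$category) & pairs$category == "same_anchor",
    interacting = !is.na(pairs$category) & pairs$category == "interacting")
  pairs <- pairs[sel, , drop = FALSE]
  mhits <- mutation_hits(muts, hits)
  mcat <- vapply(seq_len(nrow(pairs)), function(k)
    classify_motif_pair(mhits[[pairs$i[k]]], mhits[[pairs$j[k]]], tfnet), "")
  keep <- !is.na(mcat)
  pairs <- pairs[keep, , drop = FALSE]; mcat <- mcat[keep]
  ref <- mcat == "different_motifs_tfs_do_not_interact"
  if (!any(ref)) stop("reference motif category is empty")
  p0 <- mean(pairs$same_disease[ref])
  out <- do.call(rbind, lapply(MOTIF_PAIR_CATEGORIES, function(cat) {
    s <- mcat == cat
    n <- sum(s); k <- sum(pairs$same_disease[s])
    f <- if (n > 0) k / n else NA_real_
    data.frame(category = cat, n = n, k_same = k, fraction = f,
               sem = if (n > 0) prop_sem(f, n) else NA_real_,
               p = if (n > 0 && !identical(cat, "different_motifs_tfs_do_not_interact"))
                 binom_upper_p(k, n, p0) else NA_real_,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Degree-preserving scramble of an edge list
#'
#' Randomised double-edge swaps: repeatedly pick two edges (a, b), (c, d)
#' and propose (a, d), (c, b), rejecting swaps that would create a self-loop
#' or duplicate edge. Every node's degree is preserved exactly.
#'
#' @param edges two-column data.frame (an undirected edge list; for the
#'   chromatin network, anchor/target region identifiers).
#' @param nswap number of attempted swaps (default 10 x the edge count).
#' @param seed optional integer seed; when supplied the caller's RNG state
#'   is untouched.
#' @return a scrambled edge data.frame with the same columns.
#' @export
scramble_edges <- function(edges, nswap = 10 * nrow(edges), seed = NULL) {
  run <- function() {
    a <- as.character(edges[[1]]); b <- as.character(edges[[2]])
    m <- length(a)
    if (m < 2) return(edges)
    ekey <- function(x, y) paste(pmin(x, y), pmax(x, y), sep = "\r")
    keys <- new.env(hash = TRUE, parent = emptyenv())
    for (k in ekey(a, b)) assign(k, TRUE, envir = keys)
    for (t in seq_len(nswap)) {
      e <- sample.int(m, 2)
      i <- e[1]; j <- e[2]
      na1 <- a[i]; nb1 <- b[j]   # proposal: (a_i, b_j), (a_j, b_i)
      na2 <- a[j]; nb2 <- b[i]
      if (na1 == nb1 || na2 == nb2) next
      k1 <- ekey(na1, nb1); k2 <- ekey(na2, nb2)
      if (exists(k1, envir = keys) || exists(k2, envir = keys) || k1 == k2) next
      rm(list = c(ekey(a[i], b[i]), ekey(a[j], b[j])), envir = keys)
      b[i] <- nb1; b[j] <- nb2
      assign(ekey(a[i], b[i]), TRUE, envir = keys)
      assign(ekey(a[j], b[j]), TRUE, envir = keys)
    }
    out <- edges
    out[[1]] <- a; out[[2]] <- b
    out
  }
  if (is.null(seed)) run() else with_seed(seed, run())
}

# fraction of cross-region motif-instance pairs whose TFs interact, over a
# set of interacting region pairs; hits_by_region: data.frame(region, tf)
observed_interacting_fraction <- function(region_pairs, hits_by_region, tfnet) {
  by_region <- split(hits_by_region$tf, hits_by_region$region)
  n <- 0; k <- 0
  for (r in seq_len(nrow(region_pairs))) {
    ta <- by_region[[as.character(region_pairs[r, 1])]]
    tb <- by_region[[as.character(region_pairs[r, 2])]]
    if (is.null(ta) || is.null(tb)) next
    grid <- expand.grid(a = ta, b = tb, stringsAsFactors = FALSE)
    n <- n + nrow(grid)
    k <- k + sum(tfs_interact(tfnet, grid$a, grid$b))
  }
  list(n = n, k = k, fraction = if (n > 0) k / n else NA_real_)
}

#' Enrichment of interacting-TF motif pairs across interacting regions
#'
#' The observed quantity is the fraction of cross-region motif pairs (over
#' all interacting region pairs) whose TFs interact. Two nulls:
#'
#' * baseline 1 -- the fraction of interacting TF pairs among all possible
#'   TF pairs restricted to TFs involved in at least one TF-TF interaction
#'   (self-pairs included or not via `include_self_pairs`); the p value is a
#'   Z-test on the log enrichment with a count-based SE.
#' * baseline 2 -- the mean observed fraction over `n_scrambles`
#'   degree-preserving scrambles of the region-region interaction network;
#'   the p value is the empirical rank of the observed fraction among the
#'   scrambles.
#'
#' @param region_pairs two-column data.frame of interacting region IDs.
#' @param hits_by_region data.frame `region`, `tf`: one row per motif
#'   instance found in each region's search window.
#' @param tfnet a [tf_network()].
#' @param include_self_pairs count homodimer (self) TF pairs in baseline 1's
#'   denominator (and self-edges in its numerator).
#' @param n_scrambles scrambles for baseline 2 (0 disables it).
#' @param seed seed for the scrambles.
#' @return list with `observed` (n, k, fraction), `baseline1`,
#'   `enrichment1`, `p1`, and when requested `baseline2`, `enrichment2`,
#'   `p2`, `scramble_fractions`.
#' @export
motif_pair_interaction_enrichment <- function(region_pairs, hits_by_region,
                                              tfnet,
                                              include_self_pairs = TRUE,
                                              n_scrambles = 0, seed = 1L) {
  if (nrow(tfnet$edges) == 0) stop("TF network has no edges")
  obs <- observed_interacting_fraction(region_pairs, hits_by_region, tfnet)
  if (obs$n == 0) stop("no eligible cross-region motif pairs")
  deg_nodes <- unique(c(tfnet$edges$tf1, tfnet$edges$tf2))
  t_n <- length(deg_nodes)
  self <- tfnet$edges$tf1 == tfnet$edges$tf2
  if (include_self_pairs) {
    k_base <- nrow(tfnet$edges)
    n_base <- t_n * (t_n + 1) / 2
  } else {
    k_base <- sum(!self)
    n_base <- t_n * (t_n - 1) / 2
  }
  if (n_base == 0 || k_base == 0) stop("no eligible TF pairs for baseline 1")
  baseline1 <- k_base / n_base
  enrichment1 <- obs$fraction / baseline1
  p1 <- NA_real_
  if (obs$k > 0 && obs$k < obs$n && k_base < n_base) {
    se <- sqrt(1 / obs$k - 1 / obs$n + 1 / k_base - 1 / n_base)
    p1 <- 2 * pnorm(-abs(log(enrichment1) / se))
  }
  out <- list(observed = obs, baseline1 = baseline1,
              enrichment1 = enrichment1, p1 = p1)
  if (n_scrambles > 0) {
    fracs <- with_seed(seed, vapply(seq_len(n_scrambles), function(s) {
      sp <- scramble_edges(region_pairs)
      observed_interacting_fraction(sp, hits_by_region, tfnet)$fraction
    }, numeric(1)))
    fracs <- fracs[!is.na(fracs)]
    if (length(fracs) == 0) stop("all scrambles produced no motif pairs")
    out$baseline2 <- mean(fracs)
    out$enrichment2 <- obs$fraction / out$baseline2
    out$p2 <- (1 + sum(fracs >= obs$fraction)) / (length(fracs) + 1)
    out$scramble_fractions <- fracs
  }
  out
}
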