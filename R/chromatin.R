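# Classification of non-coding mutation pairs against the chromatin
# interaction network, disease-concordance statistics, and Hi-C contact
# comparison.

PAIR_CATEGORIES <- c("same_anchor", "interacting",
                     "non_interacting_same_chrom", "different_chromosomes")

#' Distance filter for mutation pairs
#'
#' Interacting and non-interacting same-chromosome pairs are kept only when
#' `min_bp < |pos_a - pos_b| < max_bp` (both strict). The maximum is fixed at
#' 2 Mb; the minimum is a configurable knob (0, 2 kb or 5 kb in the core
#' analyses, 20 kb / 50 kb in the stricter ones).
#'
#' @param min_bp minimum pair distance in bp (default 0).
#' @param max_bp maximum pair distance in bp (default 2e6).
#' @return a `distance_filter` list.
#' @export
distance_filter <- function(min_bp = 0, max_bp = 2e6) {
  stopifnot(min_bp >= 0, max_bp > min_bp)
  structure(list(min_bp = min_bp, max_bp = max_bp), class = "distance_filter")
}

# anchor ids containing each 1-based position (list per mutation)
anchors_containing <- function(net, chrom, pos) {
  n <- length(pos)
  if (nrow(net$anchors) == 0) return(rep(list(character(0)), n))
  q <- GenomicRanges::GRanges(normalize_chrom(chrom),
                              IRanges::IRanges(start = pos, end = pos))
  a <- GenomicRanges::GRanges(net$anchors$chrom,
                              IRanges::IRanges(start = net$anchors$start + 1L,
                                               end = net$anchors$end))
  hits <- GenomicRanges::findOverlaps(q, a)
  out <- rep(list(character(0)), n)
  qh <- S4Vectors::queryHits(hits); sh <- S4Vectors::subjectHits(hits)
  for (k in seq_along(qh)) {
    out[[qh[k]]] <- c(out[[qh[k]]], net$anchors$anchor_id[sh[k]])
  }
  out
}

# anchor ids whose *target* intervals contain each position
targets_containing <- function(net, chrom, pos) {
  n <- length(pos)
  if (nrow(net$edges) == 0) return(rep(list(character(0)), n))
  q <- GenomicRanges::GRanges(normalize_chrom(chrom),
                              IRanges::IRanges(start = pos, end = pos))
  t <- GenomicRanges::GRanges(net$edges$chrom,
                              IRanges::IRanges(start = net$edges$start + 1L,
                                               end = net$edges$end))
  hits <- GenomicRanges::findOverlaps(q, t)
  out <- rep(list(character(0)), n)
  qh <- S4Vectors::queryHits(hits); sh <- S4Vectors::subjectHits(hits)
  for (k in seq_along(qh)) {
    out[[qh[k]]] <- c(out[[qh[k]]], net$edges$anchor_id[sh[k]])
  }
  out
}

#' Classify all non-coding mutation pairs against a chromatin network
#'
#' Each unordered pair falls into exactly one category:
#' `different_chromosomes`; `same_anchor` when some anchor contains both
#' mutations (tested first, no distance filter); `interacting` when one
#' mutation is in an anchor and the other inside a target interval linked to
#' that anchor (direction-symmetric); otherwise
#' `non_interacting_same_chrom`. Interacting and non-interacting pairs are
#' excluded (category `NA`) unless they pass the [distance_filter()].
#'
#' @param muts a [mutations()] table (non-coding rows are used).
#' @param net a [chromatin_net()].
#' @param filter a [distance_filter()].
#' @return data.frame with columns `i`, `j` (row indices into the non-coding
#'   subset, returned as attribute `muts`), `id_a`, `id_b`, `distance`
#'   (NA across chromosomes), `category` (NA = excluded), `same_disease`.
#' @export
classify_pairs <- function(muts, net, filter = distance_filter()) {
  nc <- muts[muts$mclass == "non_coding", , drop = FALSE]
  rownames(nc) <- NULL
  idx <- pair_index(nrow(nc))
  anch <- anchors_containing(net, nc$chrom, nc$pos)
  targ <- targets_containing(net, nc$chrom, nc$pos)
  n_pairs <- nrow(idx)
  i <- idx[, 1]; j <- idx[, 2]
  same_chrom <- nc$chrom[i] == nc$chrom[j]
  dist <- ifelse(same_chrom, abs(nc$pos[i] - nc$pos[j]), NA_real_)
  # default: cross-chromosome or (distance-filtered) non-interacting
  category <- ifelse(!same_chrom, "different_chromosomes",
                     "non_interacting_same_chrom")
  # only mutations sitting in anchors / targets can upgrade a pair, so
  # restrict the set-intersection work to those candidate pairs
  has_anch <- lengths(anch) > 0
  has_targ <- lengths(targ) > 0
  cand <- which(same_chrom &
                  ((has_anch[i] & (has_anch[j] | has_targ[j])) |
                   (has_targ[i] & has_anch[j])))
  for (k in cand) {
    a <- i[k]; b <- j[k]
    if (length(intersect(anch[[a]], anch[[b]])) > 0) {
      category[k] <- "same_anchor"   # precedence over interacting
    } else if (length(intersect(anch[[a]], targ[[b]])) > 0 ||
               length(intersect(anch[[b]], targ[[a]])) > 0) {
      category[k] <- "interacting"
    }
  }
  filtered <- category %in% c("interacting", "non_interacting_same_chrom") &
    !(dist > filter$min_bp & dist < filter$max_bp)
  category[filtered] <- NA_character_   # excluded by the distance filter
  out <- data.frame(i = idx[, 1], j = idx[, 2],
                    id_a = nc$id[idx[, 1]], id_b = nc$id[idx[, 2]],
                    distance = dist, category = category,
                    stringsAsFactors = FALSE)
  out$same_disease <- pair_same_disease(nc, idx)
  attr(out, "muts") <- nc
  out
}

#' Classify one mutation pair
#'
#' Scalar convenience wrapper around [classify_pairs()].
#'
#' @param a,b single-row [mutations()] tables (non-coding).
#' @param net a [chromatin_net()].
#' @param filter a [distance_filter()].
#' @return the category string, or `NA` when the pair is excluded by the
#'   distance filter.
#' @export
classify_pair <- function(a, b, net, filter = distance_filter()) {
  both <- rbind(a, b)
  both$id <- c("..a", "..b")
  classify_pairs(validate_mutations(both), net, filter)$category[1]
}

#' Disease concordance per chromatin pair category
#'
#' For each category, the fraction of mutation pairs whose disease-ID sets
#' intersect, its SEM, and an upper-tail cumulative binomial p value against
#' the reference category (`non_interacting_same_chrom`) whose observed
#' fraction serves as null probability. Pairs involving a mutation with no
#' disease ID should be absent upstream.
#'
#' @param pairs output of [classify_pairs()].
#' @param reference the null category (default
#'   `"non_interacting_same_chrom"`).
#' @return data.frame: `category`, `n`, `k_same`, `fraction`, `sem`, `p`.
#' @export
concordance_by_category <- function(pairs,
                                    reference = "non_interacting_same_chrom") {
  keep <- !is.na(pairs$category)
  pairs <- pairs[keep, , drop = FALSE]
  ref <- pairs$category == reference
  if (!any(ref)) stop("reference category '", reference, "' is empty")
  p0 <- mean(pairs$same_disease[ref])
  out <- do.call(rbind, lapply(PAIR_CATEGORIES, function(cat) {
    sel <- pairs$category == cat
    n <- sum(sel); k <- sum(pairs$same_disease[sel])
    f <- if (n > 0) k / n else NA_real_
    p <- if (n > 0 && cat != reference) binom_upper_p(k, n, p0) else NA_real_
    data.frame(category = cat, n = n, k_same = k, fraction = f,
               sem = if (n > 0) prop_sem(f, n) else NA_real_, p = p,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' SQRTVC-normalised contact count between two positions
#'
#' raw(i, j) / (v\[i\] * v\[j\]) with i, j the bins of the two 1-based
#' positions; an absent entry is 0.
#'
#' @param cm a [contact_matrix()].
#' @param pos_a,pos_b 1-based positions on `cm$chrom`.
#' @return the normalised contact count.
#' @export
normalized_contact <- function(cm, pos_a, pos_b) {
  i <- bin_index(pos_a, cm$resolution) + 1L
  j <- bin_index(pos_b, cm$resolution) + 1L
  nb <- length(cm$normvec)
  if (i < 1L || i > nb || j < 1L || j > nb) {
    stop("position outside the normalisation vector (bins ", i - 1L, ", ",
         j - 1L, " of ", nb, ")")
  }
  vi <- cm$normvec[i]; vj <- cm$normvec[j]
  if (vi <= 0 || vj <= 0) stop("non-positive normalisation value at bin ",
                               if (vi <= 0) i - 1L else j - 1L)
  cm$mat[i, j] / (vi * vj)
}

#' Compare contact frequency between same-disease and different-disease pairs
#'
#' Computes the SQRTVC-normalised contact for every same-chromosome mutation
#' pair and contrasts pairs associated with the same disease against pairs
#' associated with different diseases using the Mann-Whitney U test
#' (tie-corrected normal approximation; exact permutation when the combined
#' sample size is at most 12).
#'
#' @param pairs output of [classify_pairs()] restricted to `cm`'s chromosome
#'   (cross-chromosome rows are dropped).
#' @param cm a [contact_matrix()].
#' @return list: `test` (see [mann_whitney()]), and the per-group contact
#'   vectors `contacts_same`, `contacts_diff`.
#' @export
contact_comparison <- function(pairs, cm) {
  muts <- attr(pairs, "muts")
  if (is.null(muts)) stop("pairs must come from classify_pairs()")
  sel <- muts$chrom[pairs$i] == cm$chrom & muts$chrom[pairs$j] == cm$chrom
  pairs <- pairs[sel, , drop = FALSE]
  if (nrow(pairs) == 0) stop("no same-chromosome pairs on ", cm$chrom)
  vals <- vapply(seq_len(nrow(pairs)), function(k)
    normalized_contact(cm, muts$pos[pairs$i[k]], muts$pos[pairs$j[k]]),
    numeric(1))
  xs <- vals[pairs$same_disease]
  ys <- vals[!pairs$same_disease]
  if (length(xs) == 0 || length(ys) == 0) {
    stop("one of the disease-concordance groups is empty")
  }
  list(test = mann_whitney(xs, ys), contacts_same = xs, contacts_diff = ys)
}
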