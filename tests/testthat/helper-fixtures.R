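# Small in-code fixture builders shared across test files.

make_muts <- function(n = 3, chrom = "chr1", pos = NULL, mclass = "non_coding",
                      protein = NA_character_, residue = NA_integer_,
                      diseases = NULL) {
  if (is.null(pos)) pos <- seq_len(n) * 100L
  mutations(id = sprintf("m%d", seq_len(n)), chrom = chrom, pos = pos,
            mclass = mclass, protein = protein, residue = residue,
            diseases = diseases)
}

# one-anchor toy chromatin network: anchor [a0, a1) linked to target [t0, t1)
toy_net <- function(chrom = "chr1", a = c(0L, 1000L), t = c(29000L, 31000L)) {
  chromatin_net(
    anchors = data.frame(anchor_id = "A1", chrom = chrom,
                         start = a[1], end = a[2]),
    edges = data.frame(anchor_id = "A1", chrom = chrom,
                       start = t[1], end = t[2]))
}

# pairs table in the shape produced by classify_pairs(), for tests that
# exercise the concordance summaries directly
toy_pairs <- function(category, same_disease) {
  data.frame(i = seq_along(category), j = seq_along(category) + 1L,
             id_a = "x", id_b = "y", distance = 1000,
             category = category, same_disease = same_disease,
             stringsAsFactors = FALSE)
}

# exact upper-tail binomial by direct summation (independent of pbinom)
oracle_binom_upper <- function(k, n, p0) {
  if (k == 0) return(1)
  sum(vapply(k:n, function(i) choose(n, i) * p0^i * (1 - p0)^(n - i), 1))
}

# naive PWM window score, written independently of the scanner
oracle_score <- function(window, mat, background) {
  bases <- strsplit(window, "")[[1]]
  idx <- match(bases, c("A", "C", "G", "T"))
  if (anyNA(idx)) return(NA_real_)
  sum(log(mat[cbind(idx, seq_along(idx))] / background[idx]))
}

oracle_revcomp <- function(x) {
  chartr("ACGT", "TGCA", paste(rev(strsplit(x, "")[[1]]), collapse = ""))
}

degree_multiset <- function(edges) {
  sort(as.vector(table(c(as.character(edges[[1]]),
                         as.character(edges[[2]])))))
}
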