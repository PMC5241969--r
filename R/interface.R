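# Interface assignment of coding missense mutations and the odds-ratio
# enrichment of mutations on protein-binding / DNA-binding / double
# interfaces, plus the TF-pair disease-concordance analysis.

#' Interface class of a coding missense mutation
#'
#' Returns the unique class of the mutated residue after the double-merge
#' rule: `double`, `protein_binding`, `dna_binding` or `none`.
#'
#' @param m single-row [mutations()] table (or a list with `protein` and
#'   `residue`).
#' @param imap the [interface_map()] of the same protein.
#' @return one of [INTERFACE_CLASSES].
#' @export
classify_mutation_interface <- function(m, imap) {
  if (!identical(as.character(m$protein), imap$protein)) {
    stop("mutation protein '", m$protein, "' does not match interface map '",
         imap$protein, "'")
  }
  res <- as.integer(m$residue)
  if (is.na(res) || res < 1L || res > imap$length) {
    stop("residue ", res, " out of range 1..", imap$length,
         " for ", imap$protein)
  }
  imap$residue_class[res]
}

# does this protein carry both a protein-protein and a protein-DNA
# interface? "double" residues bind both, so they satisfy either side.
has_both_interface_kinds <- function(imap) {
  cls <- imap$residue_class
  any(cls %in% c("protein_binding", "double")) &&
    any(cls %in% c("dna_binding", "double"))
}

#' Count mutations and residues per interface class
#'
#' Tallies, over a set of proteins, how many residues and how many coding
#' missense mutations fall in each interface class. With `restrict = TRUE`,
#' proteins lacking either a protein-binding or a DNA-binding interface are
#' excluded before counting (to minimise misclassification from incomplete
#' annotations); their residues and mutations do not contribute.
#'
#' @param muts a [mutations()] table; only `coding_missense` rows whose
#'   protein has an interface map are counted (others are dropped with a
#'   message).
#' @param imaps named list of [interface_map()] objects.
#' @param restrict drop proteins without both interface kinds.
#' @return an `interface_counts` object: matrices `n_mut`, `n_res` indexed by
#'   class, plus totals.
#' @export
build_interface_counts <- function(muts, imaps, restrict = FALSE) {
  if (nrow(muts) == 0 || length(imaps) == 0) {
    stop("build_interface_counts: empty input")
  }
  if (restrict) {
    imaps <- Filter(has_both_interface_kinds, imaps)
    if (length(imaps) == 0) stop("no protein passes the restrict filter")
  }
  n_res <- setNames(numeric(length(INTERFACE_CLASSES)), INTERFACE_CLASSES)
  for (m in imaps) {
    tab <- table(factor(m$residue_class, levels = INTERFACE_CLASSES))
    n_res <- n_res + as.numeric(tab)
  }
  cm <- muts[muts$mclass == "coding_missense", , drop = FALSE]
  known <- cm$protein %in% names(imaps)
  if (any(!known)) {
    message(sum(!known), " coding mutation(s) on proteins without an ",
            "interface map (or excluded by restrict); dropped")
  }
  cm <- cm[known, , drop = FALSE]
  cls <- vapply(seq_len(nrow(cm)), function(k)
    classify_mutation_interface(cm[k, ], imaps[[cm$protein[k]]]), "")
  n_mut <- as.numeric(table(factor(cls, levels = INTERFACE_CLASSES)))
  names(n_mut) <- INTERFACE_CLASSES
  structure(list(n_mut = n_mut, n_res = n_res,
                 n_mut_total = sum(n_mut), n_res_total = sum(n_res)),
            class = "interface_counts")
}

#' @export
print.interface_counts <- function(x, ...) {
  df <- data.frame(class = INTERFACE_CLASSES,
                   n_mut = x$n_mut, n_res = x$n_res, row.names = NULL)
  print(df)
  invisible(x)
}

#' Odds-ratio enrichment of mutations in one interface class
#'
#' Compares the fraction of mutations in the class (p1) against the fraction
#' of residues in the class (p2):
#' OR = (p1/(1-p1)) / (p2/(1-p2)), with
#' SE(ln OR) = sqrt(1/n_mut_region + 1/n_mut_other + 1/n_res_region +
#' 1/n_res_other), Z = ln(OR)/SE and a two-sided normal p value. Errors on
#' any zero cell rather than applying a continuity correction.
#'
#' @param counts an [build_interface_counts()] result.
#' @param class the focal interface class.
#' @return an [enrichment_result()].
#' @export
interface_odds_ratio <- function(counts, class) {
  class <- match.arg(class, INTERFACE_CLASSES)
  odds_ratio_test(counts$n_mut[[class]], counts$n_mut_total,
                  counts$n_res[[class]], counts$n_res_total)
}

#' Disease concordance of mutation pairs across TF pairs
#'
#' Enumerates unordered pairs of coding missense mutations lying on two
#' distinct TFs (within-TF pairs are excluded) and splits them by whether the
#' two TFs interact in the TF-TF network. Reports per category the fraction
#' of pairs whose disease-ID sets intersect, the SEM, and for the interacting
#' category an upper-tail cumulative binomial p value with the
#' non-interacting fraction as null probability.
#'
#' @param muts a [mutations()] table; rows without disease IDs are dropped.
#' @param tfnet a [tf_network()].
#' @return data.frame with one row per category (`across_interacting`,
#'   `across_non_interacting`): `n`, `k_same`, `fraction`, `sem`, `p`,
#'   `flagged`.
#' @export
same_disease_fraction_tf_pairs <- function(muts, tfnet) {
  cm <- muts[muts$mclass == "coding_missense" &
               vapply(muts$diseases, length, 1L) > 0 &
               !is.na(muts$protein), , drop = FALSE]
  idx <- pair_index(nrow(cm))
  if (nrow(idx) > 0) {
    cross <- cm$protein[idx[, 1]] != cm$protein[idx[, 2]]
    idx <- idx[cross, , drop = FALSE]
  }
  inter <- if (nrow(idx)) tfs_interact(tfnet, cm$protein[idx[, 1]],
                                       cm$protein[idx[, 2]]) else logical(0)
  shared <- pair_same_disease(cm, idx)
  summarise <- function(sel) {
    n <- sum(sel); k <- sum(shared[sel])
    if (n == 0) {
      data.frame(n = 0L, k_same = 0L, fraction = NA_real_, sem = NA_real_,
                 p = NA_real_, flagged = TRUE)
    } else {
      f <- k / n
      data.frame(n = n, k_same = k, fraction = f, sem = prop_sem(f, n),
                 p = NA_real_, flagged = FALSE)
    }
  }
  out <- rbind(summarise(inter), summarise(!inter))
  out <- cbind(category = c("across_interacting", "across_non_interacting"),
               out)
  if (!out$flagged[1] && !out$flagged[2]) {
    out$p[1] <- binom_upper_p(out$k_same[1], out$n[1], out$fraction[2])
  }
  out
}
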