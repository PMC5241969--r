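#' Mutation classes understood by the package
#' @keywords internal
MUTATION_CLASSES <- c("coding_missense", "non_coding")

#' Interface classes for transcription-factor residues
#'
#' Residues mediating both protein and DNA binding form the separate
#' \code{"double"} category; after the double-merge rule the four classes are
#' mutually exclusive.
#' @export
INTERFACE_CLASSES <- c("double", "protein_binding", "dna_binding", "none")

#' Normalise chromosome names to the "chr" prefix
#'
#' @param x character vector of chromosome names (e.g. \code{"11"},
#'   \code{"chr11"}).
#' @return character vector with a \code{"chr"} prefix on every element.
#' @export
normalize_chrom <- function(x) {
  x <- as.character(x)
  ifelse(grepl("^chr", x), x, paste0("chr", x))
}

#' Construct a mutation table
#'
#' The central variant container: one row per mutation. Positions are 1-based
#' genomic coordinates; \code{diseases} is a list column of character vectors
#' of disease IDs (possibly empty -- such mutations are excluded from
#' concordance analyses).
#'
#' @param id unique mutation identifiers.
#' @param chrom chromosome names (normalised to "chr" prefix).
#' @param pos 1-based genomic positions.
#' @param mclass \code{"coding_missense"} or \code{"non_coding"}.
#' @param ref,alt optional nucleotide strings.
#' @param protein optional protein/TF identifier (required for
#'   \code{coding_missense}).
#' @param residue optional 1-based amino-acid index (required for
#'   \code{coding_missense}).
#' @param diseases list of character vectors of disease IDs.
#' @return a \code{data.frame} of class \code{"mutations"}.
#' @export
mutations <- function(id, chrom, pos, mclass,
                      ref = NA_character_, alt = NA_character_,
                      protein = NA_character_, residue = NA_integer_,
                      diseases = NULL) {
  n <- length(id)
  if (is.null(diseases)) diseases <- rep(list(character(0)), n)
  df <- data.frame(
    id = as.character(id),
    chrom = normalize_chrom(chrom),
    pos = as.integer(pos),
    ref = rep_len(as.character(ref), n),
    alt = rep_len(as.character(alt), n),
    mclass = rep_len(as.character(mclass), n),
    protein = rep_len(as.character(protein), n),
    residue = rep_len(as.integer(residue), n),
    stringsAsFactors = FALSE
  )
  df$diseases <- diseases
  validate_mutations(df)
}

#' Validate a data.frame as a mutation table
#'
#' Checks the invariants (unique IDs, 1-based positions, known classes,
#' protein/residue present for coding missense rows, list-typed diseases)
#' and stamps the `mutations` class. Useful after `rbind`-ing tables.
#'
#' @param df a data.frame with the [mutations()] columns.
#' @return the validated [mutations()] table.
#' @export
validate_mutations <- function(df) {
  stopifnot(is.data.frame(df))
  if (anyDuplicated(df$id)) {
    stop("duplicate mutation IDs: ",
         paste(unique(df$id[duplicated(df$id)]), collapse = ", "))
  }
  if (any(is.na(df$pos)) || any(df$pos < 1L)) {
    stop("mutation positions must be 1-based integers >= 1")
  }
  bad <- !df$mclass %in% MUTATION_CLASSES
  if (any(bad)) {
    stop("unknown mutation class: ", paste(unique(df$mclass[bad]), collapse = ", "))
  }
  cm <- df$mclass == "coding_missense"
  if (any(cm & (is.na(df$protein) | is.na(df$residue)))) {
    stop("coding_missense mutations require protein and residue")
  }
  if (any(!is.na(df$residue) & df$residue < 1L)) {
    stop("residue indices are 1-based (>= 1)")
  }
  if (!is.list(df$diseases)) stop("'diseases' must be a list column")
  class(df) <- c("mutations", "data.frame")
  df
}

#' Build an interface map for one protein
#'
#' Residue intervals (1-based, inclusive) labelled \code{protein_binding},
#' \code{dna_binding} or \code{double}. At construction the double-merge rule
#' is applied: any residue annotated both protein-binding and DNA-binding is
#' reassigned to class \code{double}, so each residue resolves to exactly one
#' class.
#'
#' @param protein protein identifier.
#' @param length residue count of the protein.
#' @param intervals data.frame with columns \code{start}, \code{end},
#'   \code{class} (1-based inclusive residue intervals).
#' @return an \code{interface_map} object with a per-residue class vector.
#' @export
interface_map <- function(protein, length, intervals) {
  length <- as.integer(length)
  stopifnot(length >= 1L)
  if (nrow(intervals) > 0) {
    if (any(intervals$start < 1L) || any(intervals$end > length) ||
        any(intervals$start > intervals$end)) {
      stop("interface intervals must satisfy 1 <= start <= end <= length (",
           protein, ")")
    }
    bad <- !intervals$class %in% c("protein_binding", "dna_binding", "double")
    if (any(bad)) stop("unknown interface class: ",
                       paste(unique(intervals$class[bad]), collapse = ", "))
  }
  pb <- db <- dbl <- logical(length)
  for (k in seq_len(nrow(intervals))) {
    idx <- intervals$start[k]:intervals$end[k]
    switch(intervals$class[k],
           protein_binding = {pb[idx] <- TRUE},
           dna_binding     = {db[idx] <- TRUE},
           double          = {dbl[idx] <- TRUE})
  }
  cls <- rep("none", length)
  cls[pb] <- "protein_binding"
  cls[db] <- "dna_binding"
  cls[(pb & db) | dbl] <- "double"   # double-merge rule
  structure(
    list(protein = as.character(protein), length = length,
         intervals = intervals, residue_class = cls),
    class = "interface_map"
  )
}

#' @export
print.interface_map <- function(x, ...) {
  tab <- table(factor(x$residue_class, levels = INTERFACE_CLASSES))
  cat("interface_map:", x$protein, "(", x$length, "residues )\n")
  print(tab)
  invisible(x)
}

#' Construct a chromatin interaction network
#'
#' Anchors are genomic intervals (0-based half-open) with IDs; edges link an
#' anchor to an intra-chromosomal target interval. Every edge must share a
#' chromosome with its anchor.
#'
#' @param anchors data.frame: \code{anchor_id}, \code{chrom}, \code{start},
#'   \code{end}.
#' @param edges data.frame: \code{anchor_id}, \code{chrom}, \code{start},
#'   \code{end} (the target interval).
#' @return a \code{chromatin_net} object.
#' @export
chromatin_net <- function(anchors, edges) {
  anchors$chrom <- normalize_chrom(anchors$chrom)
  edges$chrom <- normalize_chrom(edges$chrom)
  stopifnot(all(anchors$start >= 0), all(anchors$start < anchors$end))
  if (anyDuplicated(anchors$anchor_id)) stop("duplicate anchor IDs")
  if (nrow(edges) > 0) {
    stopifnot(all(edges$start >= 0), all(edges$start < edges$end))
    m <- match(edges$anchor_id, anchors$anchor_id)
    if (anyNA(m)) stop("edge references unknown anchor: ",
                       paste(unique(edges$anchor_id[is.na(m)]), collapse = ", "))
    if (any(edges$chrom != anchors$chrom[m])) {
      stop("all chromatin interactions must be intra-chromosomal")
    }
  }
  structure(list(anchors = anchors, edges = edges), class = "chromatin_net")
}

#' Construct a sparse intra-chromosomal contact matrix
#'
#' Raw binned Hi-C counts for one chromosome plus the per-bin normalisation
#' vector (SQRTVC-style): the normalised contact between bins i and j is
#' raw(i, j) / (v\[i\] * v\[j\]). Bins are \code{floor(pos0 / resolution)} of
#' 0-based positions, so the first \code{resolution} bp map to bin 0.
#'
#' @param chrom chromosome name.
#' @param resolution bin size in bp; one of 5000, 10000, 25000, 50000.
#' @param entries data.frame \code{bin_i}, \code{bin_j}, \code{count} (raw
#'   counts; bins 0-based; order of i and j irrelevant).
#' @param normvec per-bin positive normalisation values; its length sets the
#'   number of bins.
#' @return a \code{contact_matrix} object backed by a symmetric sparse matrix.
#' @export
contact_matrix <- function(chrom, resolution, entries, normvec) {
  resolution <- as.integer(resolution)
  if (!resolution %in% c(5000L, 10000L, 25000L, 50000L)) {
    stop("resolution must be one of 5000, 10000, 25000, 50000 bp")
  }
  nb <- length(normvec)
  if (nrow(entries) > 0) {
    stopifnot(all(entries$bin_i >= 0), all(entries$bin_j >= 0))
    if (any(entries$bin_i >= nb) || any(entries$bin_j >= nb)) {
      stop("contact entry bin outside the normalisation vector")
    }
  }
  i <- pmin(entries$bin_i, entries$bin_j) + 1L
  j <- pmax(entries$bin_i, entries$bin_j) + 1L
  mat <- Matrix::sparseMatrix(i = i, j = j, x = as.numeric(entries$count),
                              dims = c(nb, nb), symmetric = TRUE)
  structure(list(chrom = normalize_chrom(chrom), resolution = resolution,
                 mat = mat, normvec = as.numeric(normvec)),
            class = "contact_matrix")
}

#' Bin index of a 1-based genomic position
#' @param pos 1-based position(s).
#' @param resolution bin size in bp.
#' @return 0-based bin indices (the first \code{resolution} bp map to bin 0).
#' @export
bin_index <- function(pos, resolution) as.integer((pos - 1L) %/% resolution)

#' Construct a TF-TF interaction network
#'
#' Unordered TF pairs; self-edges are allowed (homodimers). Edges are
#' canonicalised (lexicographic order) and de-duplicated.
#'
#' @param nodes TF identifiers.
#' @param edges data.frame with columns \code{tf1}, \code{tf2}.
#' @return a \code{tf_network} object.
#' @export
tf_network <- function(nodes, edges = NULL) {
  nodes <- unique(as.character(nodes))
  if (is.null(edges) || nrow(edges) == 0) {
    edges <- data.frame(tf1 = character(0), tf2 = character(0))
  } else {
    a <- as.character(edges$tf1); b <- as.character(edges$tf2)
    if (!all(c(a, b) %in% nodes)) {
      stop("edge endpoints must be network nodes")
    }
    edges <- unique(data.frame(tf1 = pmin(a, b), tf2 = pmax(a, b),
                               stringsAsFactors = FALSE))
  }
  structure(list(nodes = nodes, edges = edges), class = "tf_network")
}

#' Test whether two TFs interact in a TF network
#' @param net a [tf_network()].
#' @param a,b TF identifiers (vectorised).
#' @return logical vector.
#' @export
tfs_interact <- function(net, a, b) {
  key <- paste(pmin(a, b), pmax(a, b), sep = "\r")
  ekey <- paste(net$edges$tf1, net$edges$tf2, sep = "\r")
  key %in% ekey
}

#' Construct a position weight matrix
#'
#' @param tf TF identifier the motif belongs to.
#' @param matrix 4 x width numeric matrix of per-position base probabilities;
#'   rows in A, C, G, T order (rownames enforced). Each column must sum to 1
#'   within 1e-9. Count matrices are accepted and normalised per column.
#' @param background length-4 background probabilities (A, C, G, T); defaults
#'   to uniform.
#' @return a \code{pwm} object.
#' @export
pwm <- function(tf, matrix, background = rep(0.25, 4)) {
  matrix <- as.matrix(matrix)
  if (nrow(matrix) != 4) stop("PWM must have 4 rows (A, C, G, T)")
  cs <- colSums(matrix)
  if (any(cs <= 0)) stop("PWM column with non-positive sum")
  if (any(abs(cs - 1) > 1e-9)) matrix <- sweep(matrix, 2, cs, "/")  # counts
  rownames(matrix) <- c("A", "C", "G", "T")
  background <- as.numeric(background)
  if (length(background) != 4 || abs(sum(background) - 1) > 1e-9) {
    stop("background must be 4 probabilities summing to 1")
  }
  structure(list(tf = as.character(tf), matrix = matrix,
                 background = background),
            class = "pwm")
}

#' Width (bp) of a PWM
#' @param x a [pwm()].
#' @export
pwm_width <- function(x) ncol(x$matrix)

#' Construct an enrichment result
#'
#' Point estimate (odds ratio or fold enrichment) with the standard error of
#' its natural log, the Z score \code{ln(estimate)/se_log} and a two-sided
#' normal p value.
#'
#' @param estimate odds ratio or fold enrichment.
#' @param se_log standard error of \code{ln(estimate)}.
#' @param flagged TRUE when the estimate is degenerate (e.g. zero numerator)
#'   and z/p are undefined.
#' @return an \code{enrichment_result} (list with \code{estimate},
#'   \code{se_log}, \code{z}, \code{p}, \code{flagged}).
#' @export
enrichment_result <- function(estimate, se_log, flagged = FALSE) {
  if (!flagged && !is.na(se_log) && se_log == 0 && estimate == 1) {
    # degenerate identity case (region = whole space): no enrichment signal
    z <- 0; p <- 1
  } else if (flagged || is.na(se_log) || se_log <= 0) {
    z <- NA_real_; p <- NA_real_
  } else {
    z <- log(estimate) / se_log
    p <- 2 * pnorm(-abs(z))
    p <- min(max(p, .Machine$double.xmin), 1)
  }
  structure(list(estimate = estimate, se_log = se_log, z = z, p = p,
                 flagged = flagged),
            class = "enrichment_result")
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat(sprintf("estimate = %.4g  se(ln) = %.4g  Z = %.3f  p = %.3g%s\n",
              x$estimate, x$se_log,
              ifelse(is.na(x$z), NA, x$z), ifelse(is.na(x$p), NA, x$p),
              if (x$flagged) "  [flagged]" else ""))
  invisible(x)
}
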