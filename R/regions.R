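# Chromatin-state segment enrichment (TSS / enhancer) and motif-territory
# enrichment of non-coding variants.

# Raw segmentation label -> derived class, per annotation scheme. These maps
# are fixed: Tss/TssF count as TSS under both chromhmm and segway; the
# enhancer vocabulary differs; the combined scheme uses TSS and E.
SEGMENT_LABEL_MAPS <- list(
  chromhmm = list(TSS = c("Tss", "TssF"),
                  enhancer = c("Enh", "EnhF")),
  segway   = list(TSS = c("Tss", "TssF"),
                  enhancer = c("Enh", "Enh1", "Enh2", "EnhF", "EnhF1",
                               "EnhF2", "EnhF3", "EnhP", "EnhPr")),
  combined = list(TSS = "TSS",
                  enhancer = "E")
)

#' Chromatin-state segmentation track
#'
#' Segments are 0-based half-open genomic intervals carrying the raw
#' segmentation label; the derived class (`TSS`, `enhancer`, `other`) is
#' computed from the scheme's fixed label map.
#'
#' @param scheme `"chromhmm"`, `"segway"` or `"combined"`.
#' @param segments data.frame: `chrom`, `start`, `end`, `label`.
#' @return a `segmentation_track` object.
#' @export
segmentation_track <- function(scheme, segments) {
  scheme <- match.arg(scheme, names(SEGMENT_LABEL_MAPS))
  stopifnot(all(c("chrom", "start", "end", "label") %in% names(segments)))
  segments$chrom <- normalize_chrom(segments$chrom)
  stopifnot(all(segments$start >= 0), all(segments$start < segments$end))
  map <- SEGMENT_LABEL_MAPS[[scheme]]
  segments$class <- ifelse(segments$label %in% map$TSS, "TSS",
                    ifelse(segments$label %in% map$enhancer, "enhancer",
                           "other"))
  structure(list(scheme = scheme, segments = segments),
            class = "segmentation_track")
}

# intervals df(chrom,start,end) -> GRanges (0-based half-open -> 1-based
# closed internally to GenomicRanges)
intervals_to_gr <- function(df) {
  GenomicRanges::GRanges(df$chrom,
                         IRanges::IRanges(start = df$start + 1L, end = df$end))
}

gr_to_intervals <- function(gr) {
  data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr) - 1L,
             end = GenomicRanges::end(gr),
             stringsAsFactors = FALSE)
}

#' Merge one segment class across cell-line tracks
#'
#' Takes the union of all intervals of the requested class over several
#' tracks of the same scheme and merges them into disjoint intervals, so the
#' total region length is well defined.
#'
#' @param tracks list of [segmentation_track()] objects (same scheme).
#' @param cls `"TSS"` or `"enhancer"`.
#' @return data.frame `chrom`, `start`, `end` of disjoint merged intervals,
#'   with attribute `total_length` (bp).
#' @export
merge_cell_lines <- function(tracks, cls) {
  schemes <- unique(vapply(tracks, function(t) t$scheme, ""))
  if (length(schemes) != 1) {
    stop("all tracks must share one scheme; found: ",
         paste(schemes, collapse = ", "))
  }
  segs <- do.call(rbind, lapply(tracks, function(t)
    t$segments[t$segments$class == cls, c("chrom", "start", "end")]))
  if (is.null(segs) || nrow(segs) == 0) {
    out <- data.frame(chrom = character(0), start = integer(0),
                      end = integer(0))
    attr(out, "total_length") <- 0
    return(out)
  }
  merged <- GenomicRanges::reduce(intervals_to_gr(segs))
  out <- gr_to_intervals(merged)
  out <- out[order(out$chrom, out$start), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "total_length") <- sum(out$end - out$start)
  out
}

#' Total length (bp) of an interval set
#' @param region_set data.frame `chrom`, `start`, `end` (assumed disjoint if
#'   produced by [merge_cell_lines()]; otherwise the union is measured).
#' @export
region_length <- function(region_set) {
  if (nrow(region_set) == 0) return(0)
  tl <- attr(region_set, "total_length")
  if (!is.null(tl)) return(tl)
  sum(IRanges::width(GenomicRanges::reduce(intervals_to_gr(region_set))))
}

# which 1-based positions fall inside the interval set (half-open 0-based)?
positions_in_regions <- function(chrom, pos, region_set) {
  if (nrow(region_set) == 0 || length(pos) == 0) {
    return(logical(length(pos)))
  }
  q <- GenomicRanges::GRanges(normalize_chrom(chrom),
                              IRanges::IRanges(start = pos, end = pos))
  IRanges::overlapsAny(q, intervals_to_gr(region_set))
}

#' Enrichment of mutations in a merged segment class
#'
#' Enrichment = (n_mut_region * l_total) / (n_mut_total * l_region), with
#' SE(ln E) = sqrt(1/n_mut_region - 1/n_mut_total + 1/l_region - 1/l_total),
#' Z = ln(E)/SE and a two-sided normal p value. With no mutations in the
#' region the estimate is 0 and the result is flagged (SE undefined).
#'
#' @param muts a [mutations()] table (non-coding rows are used; pass a
#'   pre-filtered table to override).
#' @param region_set merged intervals from [merge_cell_lines()].
#' @param l_total total genome length under consideration (bp) -- the sum of
#'   the supplied chromosome lengths, not a hard-coded genome constant.
#' @return an [enrichment_result()] with `n_region`/`n_total` attached.
#' @export
segment_enrichment <- function(muts, region_set, l_total) {
  use <- muts[muts$mclass == "non_coding", , drop = FALSE]
  if (nrow(use) == 0) use <- muts
  l_region <- region_length(region_set)
  stopifnot(l_region > 0, l_total >= l_region)
  inside <- positions_in_regions(use$chrom, use$pos, region_set)
  res <- log_enrichment_test(sum(inside), nrow(use), l_region, l_total)
  res$n_region <- sum(inside); res$n_total <- nrow(use)
  res
}

#' Enrichment of variants in TF binding-motif territory
#'
#' Search regions of `window` bp are centred at each variant; motif hits are
#' clipped to the union of search regions and overlapping footprints are
#' merged before length measurement (double counting would inflate the motif
#' length). The estimate is
#' (n_var_motif * l_search) / (n_var_total * l_motifs): the fraction of
#' variants lying in at least one motif, relative to the fraction of search
#' territory covered by motifs -- the orientation that equals 1 under
#' uniform random placement. SE and Z are computed as for
#' [segment_enrichment()].
#'
#' @param variants a [mutations()] table of non-coding variants.
#' @param hits motif-hit data.frame (`chrom`, `start`, `end`, 0-based
#'   half-open).
#' @param window search-region width in bp (even; default 4000).
#' @return an [enrichment_result()] with the underlying counts and lengths
#'   attached (`n_var_motif`, `n_var_total`, `l_motifs`, `l_search`).
#' @export
motif_territory_enrichment <- function(variants, hits, window = 4000) {
  stopifnot(window %% 2 == 0, nrow(variants) > 0)
  half <- window %/% 2
  search <- data.frame(chrom = variants$chrom,
                       start = pmax(0L, variants$pos - 1L - half),
                       end = variants$pos - 1L + half)
  search_gr <- GenomicRanges::reduce(intervals_to_gr(search))
  l_search <- sum(IRanges::width(search_gr))
  if (nrow(hits) == 0) {
    res <- enrichment_result(0, NA_real_, flagged = TRUE)
    res$n_var_motif <- 0L; res$n_var_total <- nrow(variants)
    res$l_motifs <- 0; res$l_search <- l_search
    return(res)
  }
  hit_gr <- GenomicRanges::reduce(intervals_to_gr(
    hits[, c("chrom", "start", "end")]))
  foot <- GenomicRanges::intersect(hit_gr, search_gr)
  l_motifs <- sum(IRanges::width(foot))
  in_motif <- positions_in_regions(variants$chrom, variants$pos,
                                   gr_to_intervals(hit_gr))
  k <- sum(in_motif)
  if (l_motifs == 0) {
    res <- enrichment_result(0, NA_real_, flagged = TRUE)
  } else {
    res <- log_enrichment_test(k, nrow(variants), l_motifs, l_search)
  }
  res$n_var_motif <- k; res$n_var_total <- nrow(variants)
  res$l_motifs <- l_motifs; res$l_search <- l_search
  res
}
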