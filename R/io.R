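# Readers and writers for every on-disk format. All coordinate conversion
# (1-based mutations, 0-based half-open intervals, bin starts in bp) happens
# here and nowhere else.

MUTATION_COLS <- c("id", "chrom", "pos", "ref", "alt", "mclass",
                   "protein", "residue", "diseases")

na_dot <- function(x) ifelse(is.na(x), ".", as.character(x))
dot_na <- function(x) ifelse(x == "." | x == "", NA_character_, x)

split_diseases <- function(x) {
  lapply(strsplit(ifelse(is.na(x) | x == "." , "", x), "[;,]"),
         function(d) unique(d[nzchar(d)]))
}

#' Read mutations from TSV or minimal VCF
#'
#' The TSV dialect has a required header with columns
#' `id, chrom, pos, ref, alt, mclass, protein, residue, diseases`
#' (diseases semicolon-separated; missing values "."). The minimal VCF
#' dialect uses the usual `CHROM POS ID REF ALT` columns and the INFO keys
#' `MCLASS`, `PROT`, `RES`, `DIS`. Positions are 1-based in both dialects and
#' are kept 1-based.
#'
#' @param path input file.
#' @param dialect `"tsv"` or `"vcf_minimal"`.
#' @param valid_chroms optional character vector; rows on other chromosomes
#'   are skipped with a warning that reports the count.
#' @return a [mutations()] table.
#' @export
read_mutations <- function(path, dialect = c("tsv", "vcf_minimal"),
                           valid_chroms = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  if (dialect == "tsv") {
    df <- parse_mutations_tsv(lines, path)
  } else {
    df <- parse_mutations_vcf(lines, path)
  }
  if (!is.null(valid_chroms)) {
    valid_chroms <- normalize_chrom(valid_chroms)
    bad <- !df$chrom %in% valid_chroms
    if (any(bad)) {
      warning(sum(bad), " mutation(s) on unknown chromosomes skipped")
      df <- df[!bad, , drop = FALSE]
      rownames(df) <- NULL
    }
  }
  validate_mutations(df)
}

parse_mutations_tsv <- function(lines, path) {
  if (length(lines) == 0) stop(path, ": empty file")
  header <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
  if (!identical(header, MUTATION_COLS)) {
    stop(path, ": header must be: ", paste(MUTATION_COLS, collapse = ", "))
  }
  body <- lines[-1]
  body <- body[nzchar(body)]
  rows <- strsplit(body, "\t", fixed = TRUE)
  n <- length(rows)
  out <- vector("list", n)
  for (k in seq_len(n)) {
    f <- rows[[k]]
    lineno <- k + 1L
    if (length(f) != length(MUTATION_COLS)) {
      stop(path, " line ", lineno, ": expected ", length(MUTATION_COLS),
           " fields, found ", length(f))
    }
    pos <- suppressWarnings(as.integer(f[3]))
    if (is.na(pos) || pos < 1L) {
      stop(path, " line ", lineno, ": invalid position '", f[3], "'")
    }
    res <- dot_na(f[8])
    if (!is.na(res)) {
      res <- suppressWarnings(as.integer(res))
      if (is.na(res)) stop(path, " line ", lineno, ": invalid residue '", f[8], "'")
    } else res <- NA_integer_
    out[[k]] <- data.frame(
      id = f[1], chrom = normalize_chrom(f[2]), pos = pos,
      ref = dot_na(f[4]), alt = dot_na(f[5]), mclass = f[6],
      protein = dot_na(f[7]), residue = as.integer(res),
      stringsAsFactors = FALSE)
    out[[k]]$diseases <- split_diseases(f[9])
  }
  df <- do.call(rbind, out)
  if (is.null(df)) df <- empty_mutations()
  df
}

parse_mutations_vcf <- function(lines, path) {
  body <- lines[!grepl("^#", lines) & nzchar(lines)]
  n <- length(body)
  out <- vector("list", n)
  lineno_of <- match(body, lines)
  for (k in seq_len(n)) {
    f <- strsplit(body[k], "\t", fixed = TRUE)[[1]]
    if (length(f) < 5) {
      stop(path, " line ", lineno_of[k], ": expected >= 5 VCF fields")
    }
    pos <- suppressWarnings(as.integer(f[2]))
    if (is.na(pos) || pos < 1L) {
      stop(path, " line ", lineno_of[k], ": invalid POS '", f[2], "'")
    }
    info <- if (length(f) >= 8) f[8] else ""
    kv <- strsplit(strsplit(info, ";", fixed = TRUE)[[1]], "=", fixed = TRUE)
    keys <- vapply(kv, `[`, "", 1)
    vals <- vapply(kv, function(x) if (length(x) > 1) x[2] else "", "")
    getv <- function(key, default = NA_character_) {
      i <- match(key, keys); if (is.na(i) || !nzchar(vals[i])) default else vals[i]
    }
    res <- getv("RES")
    out[[k]] <- data.frame(
      id = f[3], chrom = normalize_chrom(f[1]), pos = pos,
      ref = dot_na(f[4]), alt = dot_na(f[5]),
      mclass = getv("MCLASS", "non_coding"),
      protein = getv("PROT"),
      residue = if (is.na(res)) NA_integer_ else as.integer(res),
      stringsAsFactors = FALSE)
    out[[k]]$diseases <- split_diseases(getv("DIS"))
  }
  df <- do.call(rbind, out)
  if (is.null(df)) df <- empty_mutations()
  df
}

empty_mutations <- function() {
  df <- data.frame(id = character(0), chrom = character(0),
                   pos = integer(0), ref = character(0), alt = character(0),
                   mclass = character(0), protein = character(0),
                   residue = integer(0), stringsAsFactors = FALSE)
  df$diseases <- list()
  df
}

#' Write mutations to the TSV dialect read by [read_mutations()]
#' @param muts a [mutations()] table.
#' @param path output file.
#' @export
write_mutations <- function(muts, path) {
  df <- data.frame(
    id = muts$id, chrom = muts$chrom, pos = muts$pos,
    ref = na_dot(muts$ref), alt = na_dot(muts$alt), mclass = muts$mclass,
    protein = na_dot(muts$protein), residue = na_dot(muts$residue),
    diseases = vapply(muts$diseases,
                      function(d) if (length(d)) paste(d, collapse = ";") else ".",
                      ""),
    stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read interface maps from TSV
#'
#' Columns: `protein, length, start, end, class` (1-based inclusive residue
#' intervals). A protein with no intervals can be declared with a single row
#' whose start/end are ".".
#'
#' @param path input TSV with header.
#' @return named list of [interface_map()] objects.
#' @export
read_interface_maps <- function(path) {
  df <- read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
                   colClasses = "character")
  stopifnot(all(c("protein", "length", "start", "end", "class") %in% names(df)))
  out <- lapply(split(df, df$protein), function(g) {
    keep <- g$start != "."
    intervals <- data.frame(start = as.integer(g$start[keep]),
                            end = as.integer(g$end[keep]),
                            class = g$class[keep], stringsAsFactors = FALSE)
    interface_map(g$protein[1], as.integer(g$length[1]), intervals)
  })
  out[order(names(out))]
}

#' Write interface maps to TSV
#' @param imaps named list of [interface_map()] objects.
#' @param path output file.
#' @export
write_interface_maps <- function(imaps, path) {
  rows <- lapply(imaps, function(m) {
    if (nrow(m$intervals) == 0) {
      data.frame(protein = m$protein, length = m$length,
                 start = ".", end = ".", class = ".", stringsAsFactors = FALSE)
    } else {
      data.frame(protein = m$protein, length = m$length,
                 start = as.character(m$intervals$start),
                 end = as.character(m$intervals$end),
                 class = m$intervals$class, stringsAsFactors = FALSE)
    }
  })
  write.table(do.call(rbind, rows), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Read a chromatin interaction network
#'
#' Anchors come as 4-column BED (chrom, start, end, name; 0-based half-open,
#' no header); edges as a TSV with header `anchor_id, chrom, start, end`
#' giving the target interval of each interaction.
#'
#' @param anchors_path BED file of anchors.
#' @param edges_path TSV of anchor-target interactions.
#' @return a [chromatin_net()].
#' @export
read_chromatin_net <- function(anchors_path, edges_path) {
  a <- read.table(anchors_path, sep = "\t", header = FALSE,
                  stringsAsFactors = FALSE,
                  col.names = c("chrom", "start", "end", "anchor_id"))
  e <- read.table(edges_path, sep = "\t", header = TRUE,
                  stringsAsFactors = FALSE)
  chromatin_net(a[, c("anchor_id", "chrom", "start", "end")],
                e[, c("anchor_id", "chrom", "start", "end")])
}

#' Write a chromatin interaction network
#' @param net a [chromatin_net()].
#' @param anchors_path,edges_path output paths (BED, TSV).
#' @export
write_chromatin_net <- function(net, anchors_path, edges_path) {
  write.table(net$anchors[, c("chrom", "start", "end", "anchor_id")],
              anchors_path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  write.table(net$edges[, c("anchor_id", "chrom", "start", "end")],
              edges_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(anchors_path)
}

#' Read a sparse contact matrix (triple format) plus normalisation vector
#'
#' The triple file has three whitespace-separated columns
#' `bin_i_start_bp  bin_j_start_bp  raw_count` (no header) and the vector
#' file one normalisation value per line, one line per bin, as in published
#' high-resolution Hi-C dumps.
#'
#' @param triples_path triple-format raw counts.
#' @param normvec_path one-column normalisation vector.
#' @param chrom chromosome the matrix belongs to.
#' @param resolution bin size in bp.
#' @return a [contact_matrix()].
#' @export
read_contact_matrix <- function(triples_path, normvec_path, chrom, resolution) {
  tr <- read.table(triples_path, header = FALSE,
                   col.names = c("i_bp", "j_bp", "count"))
  v <- scan(normvec_path, what = numeric(), quiet = TRUE)
  entries <- data.frame(bin_i = as.integer(tr$i_bp %/% resolution),
                        bin_j = as.integer(tr$j_bp %/% resolution),
                        count = tr$count)
  contact_matrix(chrom, resolution, entries, v)
}

#' Write a contact matrix in triple format plus normalisation vector
#' @param cm a [contact_matrix()].
#' @param triples_path,normvec_path output paths.
#' @export
write_contact_matrix <- function(cm, triples_path, normvec_path) {
  tri <- Matrix::summary(Matrix::triu(as(cm$mat, "generalMatrix")))
  df <- data.frame(i_bp = (tri$i - 1L) * cm$resolution,
                   j_bp = (tri$j - 1L) * cm$resolution,
                   count = tri$x)
  write.table(df, triples_path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  writeLines(format(cm$normvec, trim = TRUE, scientific = FALSE),
             normvec_path)
  invisible(triples_path)
}

#' Read a TF-TF network from a two-column TSV (no header)
#' @param path edge list file; nodes are the union of endpoints.
#' @return a [tf_network()].
#' @export
read_tf_network <- function(path) {
  e <- read.table(path, sep = "\t", header = FALSE, stringsAsFactors = FALSE,
                  col.names = c("tf1", "tf2"))
  tf_network(unique(c(e$tf1, e$tf2)), e)
}

#' Write a TF-TF network as a two-column TSV
#' @param net a [tf_network()].
#' @param path output file.
#' @export
write_tf_network <- function(net, path) {
  write.table(net$edges, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read PWMs from simple PFM text
#'
#' Each motif is a `>name` line followed by four whitespace-separated rows of
#' counts or probabilities in A, C, G, T order (an optional leading base
#' letter per row is tolerated).
#'
#' @param path PFM file; may hold several motifs.
#' @return named list of [pwm()] objects.
#' @export
read_pfm <- function(path) {
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines)]
  starts <- grep("^>", lines)
  if (length(starts) == 0) stop(path, ": no '>' motif headers found")
  ends <- c(starts[-1] - 1L, length(lines))
  out <- list()
  for (k in seq_along(starts)) {
    name <- sub("^>\\s*", "", lines[starts[k]])
    rows <- lines[(starts[k] + 1L):ends[k]]
    if (length(rows) != 4) stop(path, ": motif ", name, " needs 4 rows")
    rows <- sub("^[ACGTacgt][:|]?\\s+", "", rows)
    mat <- do.call(rbind, lapply(rows, function(r)
      as.numeric(strsplit(r, "\\s+")[[1]])))
    out[[name]] <- pwm(name, mat)
  }
  out
}

#' Write PWMs in simple PFM text
#' @param pwms named list of [pwm()] objects.
#' @param path output file.
#' @export
write_pfm <- function(pwms, path) {
  con <- file(path, "w"); on.exit(close(con))
  for (p in pwms) {
    writeLines(paste0(">", p$tf), con)
    for (r in 1:4) {
      writeLines(paste(format(p$matrix[r, ], digits = 8), collapse = " "), con)
    }
  }
  invisible(path)
}

#' Read PWMs from MEME minimal format
#'
#' Supports the minimal motif format: a `MOTIF <name>` line followed by a
#' `letter-probability matrix:` header and `w` rows of four probabilities
#' (A C G T). Background letter frequencies are honoured when present.
#'
#' @param path MEME minimal file.
#' @return named list of [pwm()] objects.
#' @export
read_meme <- function(path) {
  lines <- trimws(readLines(path))
  bg <- rep(0.25, 4)
  bg_at <- grep("^Background letter frequencies", lines)
  if (length(bg_at)) {
    f <- strsplit(lines[bg_at[1] + 1L], "\\s+")[[1]]
    bg <- as.numeric(f[c(2, 4, 6, 8)])
  }
  motif_at <- grep("^MOTIF\\b", lines)
  if (length(motif_at) == 0) stop(path, ": no MOTIF records")
  out <- list()
  for (m in motif_at) {
    name <- strsplit(lines[m], "\\s+")[[1]][2]
    hdr <- m + grep("^letter-probability matrix", lines[(m + 1):length(lines)])[1]
    w <- as.integer(sub(".*\\bw=\\s*(\\d+).*", "\\1", lines[hdr]))
    rows <- lines[(hdr + 1L):(hdr + w)]
    mat <- t(do.call(rbind, lapply(rows, function(r)
      as.numeric(strsplit(r, "\\s+")[[1]]))))
    out[[name]] <- pwm(name, mat, bg)
  }
  out
}

#' Write PWMs in MEME minimal format
#' @param pwms named list of [pwm()] objects.
#' @param path output file.
#' @param background length-4 background written to the header block.
#' @export
write_meme <- function(pwms, path, background = rep(0.25, 4)) {
  con <- file(path, "w"); on.exit(close(con))
  writeLines(c("MEME version 4", "", "ALPHABET= ACGT", "",
               "strands: + -", "",
               "Background letter frequencies",
               sprintf("A %.6f C %.6f G %.6f T %.6f",
                       background[1], background[2],
                       background[3], background[4]), ""), con)
  for (p in pwms) {
    writeLines(sprintf("MOTIF %s", p$tf), con)
    writeLines(sprintf("letter-probability matrix: alength= 4 w= %d",
                       pwm_width(p)), con)
    for (k in seq_len(pwm_width(p))) {
      writeLines(paste(sprintf("%.6f", p$matrix[, k]), collapse = " "), con)
    }
    writeLines("", con)
  }
  invisible(path)
}

#' Read genome sequences from FASTA
#' @param path FASTA file.
#' @return a [Biostrings::DNAStringSet].
#' @export
read_genome <- function(path) Biostrings::readDNAStringSet(path)

#' Write genome sequences to FASTA
#' @param seqs a named [Biostrings::DNAStringSet] or named character vector.
#' @param path output file.
#' @export
write_genome <- function(seqs, path) {
  if (!methods::is(seqs, "DNAStringSet")) {
    seqs <- Biostrings::DNAStringSet(seqs)
  }
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}

#' Read a chromatin-state segmentation track from BED
#'
#' 4-column BED (chrom, start, end, label), the raw segmentation label in the
#' name column.
#'
#' @param path BED file.
#' @param scheme `"chromhmm"`, `"segway"` or `"combined"`; fixes the label
#'   map used downstream.
#' @return a [segmentation_track()].
#' @export
read_segments <- function(path, scheme) {
  df <- read.table(path, sep = "\t", header = FALSE, stringsAsFactors = FALSE,
                   col.names = c("chrom", "start", "end", "label"))
  segmentation_track(scheme, df)
}

#' Read a disease-name mapping table
#' @param path two-column TSV `name, id` with header.
#' @return named character vector keyed by normalised (lower-case) name.
#' @export
read_disease_table <- function(path) {
  df <- read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
  setNames(df$id, tolower(trimws(df$name)))
}

#' Read motif hits from TSV
#' @param path TSV with header `tf, chrom, start, end, strand, score`.
#' @return a motif-hit data.frame (0-based half-open intervals).
#' @export
read_motif_hits <- function(path) {
  read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
}

#' Write motif hits to TSV
#' @param hits motif-hit data.frame.
#' @param path output file.
#' @export
write_motif_hits <- function(hits, path) {
  write.table(hits, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
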