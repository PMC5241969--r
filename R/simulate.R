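# Seeded synthetic generators. Every generator is a pure function of the
# configuration (seed included): the caller's RNG stream is never touched.
# Defaults encode the "stated world" the analyses are calibrated against:
# ~3000 coding mutations, a planted interface log-odds of ln 2.5, same-
# disease probabilities of 0.8 / 0.4 / 0.05 for same-anchor / interacting /
# background pairs, and 5-kb contact bins.

#' Simulation configuration
#'
#' @param seed integer seed; the generators restore the caller's RNG state.
#' @param n_proteins,protein_length_range proteins to simulate and their
#'   residue-count range.
#' @param interface_fraction named fractions of residues per interface class
#'   (`double`, `protein_binding`, `dna_binding`); must sum to <= 1.
#' @param n_mut_coding coding missense mutations to place.
#' @param planted_log_or named per-class log odds multipliers for mutation
#'   placement; the class-vs-rest log-OR is recovered exactly when a single
#'   class is non-null.
#' @param n_chroms,chrom_length chromosomes and their length (bp).
#' @param n_anchors,anchor_width,edges_per_anchor chromatin-network shape
#'   (anchors per chromosome; all intervals non-overlapping).
#' @param n_pairs_same_anchor,n_pairs_interacting planted mutation-pair
#'   units per category; each unit occupies its own anchor so the pair
#'   categories stay uncontaminated.
#' @param n_mut_noncoding background non-coding mutations (outside anchors
#'   and targets).
#' @param theta_same_anchor,theta_int,theta_bg same-disease probabilities
#'   per pair category. The background level is realised through the
#'   disease-pool size, so `n_diseases` defaults to `round(1/theta_bg)`.
#' @param n_diseases disease-ID pool size (overrides the theta_bg default).
#' @param motif_set_size,motif_width,n_regions,region_length motif-world
#'   shape: number of TF motifs, their width, and the regions scanned.
#' @param interacting_cooccurrence co-plants of interacting-TF motif pairs
#'   per interacting region pair (the planted excess).
#' @param contact_mu,contact_dispersion,contact_decay,contact_boost
#'   negative-binomial contact model: mean at distance d bins is
#'   `contact_mu / max(1, d)^contact_decay`, overdispersed with NB size
#'   `contact_dispersion`; bin pairs of planted same-disease mutation pairs
#'   get their mean multiplied by `contact_boost`.
#' @param resolution contact-matrix bin size (bp).
#' @param contacts generate the contact matrix (disable to speed up
#'   replicated concordance runs).
#' @return a validated `sim_config` list.
#' @export
sim_config <- function(seed = 1L,
                       n_proteins = 100L,
                       protein_length_range = c(200L, 600L),
                       interface_fraction = c(double = 0.05,
                                              protein_binding = 0.10,
                                              dna_binding = 0.10),
                       n_mut_coding = 3000L,
                       planted_log_or = c(double = 0,
                                          protein_binding = log(2.5),
                                          dna_binding = 0),
                       n_chroms = 2L,
                       chrom_length = 4e6,
                       n_anchors = 80L,
                       anchor_width = 2000L,
                       edges_per_anchor = 2L,
                       n_pairs_same_anchor = 60L,
                       n_pairs_interacting = 60L,
                       n_mut_noncoding = 150L,
                       theta_same_anchor = 0.8,
                       theta_int = 0.4,
                       theta_bg = 0.05,
                       n_diseases = NULL,
                       motif_set_size = 8L,
                       motif_width = 8L,
                       n_regions = 40L,
                       region_length = 1000L,
                       interacting_cooccurrence = 3,
                       contact_mu = 20,
                       contact_dispersion = 2,
                       contact_decay = 1,
                       contact_boost = 3,
                       resolution = 5000L,
                       contacts = TRUE) {
  fr <- interface_fraction
  stopifnot(all(fr >= 0))
  if (sum(fr) > 1) stop("interface fractions must sum to <= 1")
  probs <- c(theta_same_anchor, theta_int, theta_bg)
  stopifnot(all(probs >= 0), all(probs <= 1), theta_bg > 0)
  if (is.null(n_diseases)) n_diseases <- max(2L, round(1 / theta_bg))
  cfg <- list(seed = as.integer(seed), n_proteins = n_proteins,
              protein_length_range = protein_length_range,
              interface_fraction = fr, n_mut_coding = n_mut_coding,
              planted_log_or = planted_log_or, n_chroms = n_chroms,
              chrom_length = chrom_length, n_anchors = n_anchors,
              anchor_width = anchor_width,
              edges_per_anchor = edges_per_anchor,
              n_pairs_same_anchor = n_pairs_same_anchor,
              n_pairs_interacting = n_pairs_interacting,
              n_mut_noncoding = n_mut_noncoding,
              theta_same_anchor = theta_same_anchor,
              theta_int = theta_int, theta_bg = theta_bg,
              n_diseases = as.integer(n_diseases),
              motif_set_size = motif_set_size, motif_width = motif_width,
              n_regions = n_regions, region_length = region_length,
              interacting_cooccurrence = interacting_cooccurrence,
              contact_mu = contact_mu,
              contact_dispersion = contact_dispersion,
              contact_decay = contact_decay, contact_boost = contact_boost,
              resolution = as.integer(resolution), contacts = contacts)
  structure(cfg, class = "sim_config")
}

# partition 1..len into class blocks hitting the target fractions, separated
# by randomly sized "none" gaps
interface_blocks <- function(len, fractions) {
  want <- round(fractions * len)
  classes <- names(want)[want > 0]
  if (sum(want) > len) stop("interface fractions infeasible for length ", len)
  if (length(classes) == 0) {
    return(data.frame(start = integer(0), end = integer(0),
                      class = character(0)))
  }
  n_gap <- length(classes) + 1L
  gaps <- as.integer(rmultinom(1, len - sum(want), rep(1, n_gap)))
  order_cls <- sample(classes)
  start <- 1L
  out <- vector("list", length(order_cls))
  for (k in seq_along(order_cls)) {
    start <- start + gaps[k]
    w <- want[[order_cls[k]]]
    out[[k]] <- data.frame(start = start, end = start + w - 1L,
                           class = order_cls[k], stringsAsFactors = FALSE)
    start <- start + w
  }
  do.call(rbind, out)
}

#' Simulate interface maps and coding mutations with a planted log-OR
#'
#' Residues are assigned to interface classes at the configured fractions;
#' mutations are placed by sampling residues with odds multiplied by
#' `exp(planted_log_or[class])`, so with a single non-null class the
#' class-versus-rest odds ratio equals the planted value exactly. Each
#' mutation carries one disease ID drawn uniformly from the pool.
#'
#' @param cfg a [sim_config()].
#' @return list: `imaps` (named list of [interface_map()]), `muts`
#'   (a [mutations()] table).
#' @export
simulate_interface_dataset <- function(cfg) {
  with_seed(cfg$seed, {
    lens <- sample(cfg$protein_length_range[1]:cfg$protein_length_range[2],
                   cfg$n_proteins, replace = TRUE)
    prots <- sprintf("TF%03d", seq_len(cfg$n_proteins))
    imaps <- lapply(seq_len(cfg$n_proteins), function(k)
      interface_map(prots[k], lens[k],
                    interface_blocks(lens[k], cfg$interface_fraction)))
    names(imaps) <- prots
    pool_prot <- rep(prots, lens)
    pool_res <- unlist(lapply(lens, seq_len))
    pool_cls <- unlist(lapply(imaps, function(m) m$residue_class))
    theta <- setNames(numeric(length(INTERFACE_CLASSES)), INTERFACE_CLASSES)
    theta[names(cfg$planted_log_or)] <- cfg$planted_log_or
    w <- exp(theta[pool_cls])
    pick <- sample.int(length(pool_res), cfg$n_mut_coding, replace = TRUE,
                       prob = w)
    muts <- mutations(
      id = sprintf("CM%05d", seq_len(cfg$n_mut_coding)),
      chrom = "chr1", pos = seq_len(cfg$n_mut_coding),  # placeholder coords
      mclass = "coding_missense",
      protein = pool_prot[pick], residue = pool_res[pick],
      diseases = as.list(sprintf("D%03d", sample.int(cfg$n_diseases,
                                                     cfg$n_mut_coding,
                                                     replace = TRUE))))
    list(imaps = imaps, muts = muts)
  })
}

# draw a disease-ID pair honouring a same-disease probability theta
draw_disease_pair <- function(theta, n_diseases) {
  if (runif(1) < theta) {
    d <- sprintf("D%03d", sample.int(n_diseases, 1))
    c(d, d)
  } else {
    sprintf("D%03d", sample.int(n_diseases, 2, replace = FALSE))
  }
}

#' Simulate a chromatin world: network, non-coding mutations, contacts
#'
#' Anchors are non-overlapping intervals on each chromosome; every anchor
#' links to `edges_per_anchor` disjoint target intervals within 1.5 Mb.
#' Mutation pairs are planted per category -- both members inside one
#' anchor, or one in an anchor and one in a linked target -- with
#' same-disease probabilities `theta_same_anchor` and `theta_int`; each
#' planted unit occupies its own anchor, so the pair categories recovered by
#' [classify_pairs()] contain exactly the planted pairs plus background
#' cross-pairs. Background mutations fall in free intervals and share
#' diseases at the pool rate 1/n_diseases (= `theta_bg` by default).
#' Contacts on chr1 follow a distance-decaying negative binomial, with the
#' bin pairs of planted same-disease pairs boosted; the normalisation
#' vector is the square root of the row sums, so SQRTVC normalisation is
#' exercised non-trivially.
#'
#' @param cfg a [sim_config()].
#' @return list: `net` ([chromatin_net()]), `muts` ([mutations()]),
#'   `cm` ([contact_matrix()] for chr1, or NULL), `units` (planted pair
#'   metadata: kind and the two mutation row indices).
#' @export
simulate_chromatin_dataset <- function(cfg) {
  n_units <- cfg$n_pairs_same_anchor + cfg$n_pairs_interacting
  if (n_units > cfg$n_anchors * cfg$n_chroms) {
    stop("not enough anchors for the requested planted pairs: need ",
         n_units, ", have ", cfg$n_anchors * cfg$n_chroms)
  }
  with_seed(cfg$seed, {
    w <- cfg$anchor_width
    chroms <- sprintf("chr%d", seq_len(cfg$n_chroms))
    slot_starts <- seq(0, cfg$chrom_length - w, by = 3L * w)
    n_targets <- cfg$n_anchors * cfg$edges_per_anchor
    n_bg_slots <- ceiling(cfg$n_mut_noncoding / cfg$n_chroms) + 5L
    if (length(slot_starts) < cfg$n_anchors + n_targets + n_bg_slots) {
      stop("anchors cannot fit: chromosome too short for the requested ",
           "anchor/target count")
    }
    anchors <- list(); edges <- list(); free <- list()
    for (ci in seq_along(chroms)) {
      s <- sample(slot_starts)
      a_start <- s[seq_len(cfg$n_anchors)]
      t_start <- s[cfg$n_anchors + seq_len(n_targets)]
      rest <- s[-seq_len(cfg$n_anchors + n_targets)]
      ids <- sprintf("%s_A%03d", chroms[ci], seq_len(cfg$n_anchors))
      anchors[[ci]] <- data.frame(anchor_id = ids, chrom = chroms[ci],
                                  start = a_start, end = a_start + w,
                                  stringsAsFactors = FALSE)
      # nearest unused target slots within 1.5 Mb of each anchor
      tpool <- t_start
      ed <- vector("list", cfg$n_anchors)
      for (k in seq_len(cfg$n_anchors)) {
        near <- order(abs(tpool - a_start[k]))
        take <- head(near[abs(tpool[near] - a_start[k]) <= 1.5e6],
                     cfg$edges_per_anchor)
        # no free slot within 1.5 Mb: fall back to the nearest one
        if (length(take) == 0) take <- near[1]
        ed[[k]] <- data.frame(anchor_id = ids[k], chrom = chroms[ci],
                              start = tpool[take], end = tpool[take] + w,
                              stringsAsFactors = FALSE)
        tpool <- tpool[-take]
      }
      edges[[ci]] <- do.call(rbind, ed)
      free[[ci]] <- data.frame(chrom = chroms[ci], start = rest,
                               stringsAsFactors = FALSE)
    }
    anchors <- do.call(rbind, anchors)
    edges <- do.call(rbind, edges)
    free <- do.call(rbind, free)
    rownames(anchors) <- rownames(edges) <- NULL
    net <- chromatin_net(anchors, edges)

    pos_in <- function(start) as.integer(start + sample.int(w, 1))
    rows <- list(); units <- list()
    add <- function(chrom, pos, dis) {
      rows[[length(rows) + 1L]] <<- list(chrom = chrom, pos = pos, dis = dis)
      length(rows)
    }
    unit_anchor <- sample(nrow(anchors), n_units)   # one anchor per unit
    # same-anchor units
    for (k in head(unit_anchor, cfg$n_pairs_same_anchor)) {
      d <- draw_disease_pair(cfg$theta_same_anchor, cfg$n_diseases)
      i <- add(anchors$chrom[k], pos_in(anchors$start[k]), d[1])
      j <- add(anchors$chrom[k], pos_in(anchors$start[k]), d[2])
      units[[length(units) + 1L]] <- list(kind = "same_anchor", i = i, j = j)
    }
    # interacting units: one mutation in the anchor, one in a linked target
    for (k in utils::tail(unit_anchor, cfg$n_pairs_interacting)) {
      own <- which(edges$anchor_id == anchors$anchor_id[k])
      if (length(own) == 0) next
      e <- own[sample.int(length(own), 1)]
      d <- draw_disease_pair(cfg$theta_int, cfg$n_diseases)
      i <- add(anchors$chrom[k], pos_in(anchors$start[k]), d[1])
      j <- add(edges$chrom[e], pos_in(edges$start[e]), d[2])
      units[[length(units) + 1L]] <- list(kind = "interacting", i = i, j = j)
    }
    # background mutations in free slots
    bg <- free[sample(nrow(free), cfg$n_mut_noncoding), , drop = FALSE]
    for (k in seq_len(nrow(bg))) {
      add(bg$chrom[k], pos_in(bg$start[k]),
          sprintf("D%03d", sample.int(cfg$n_diseases, 1)))
    }
    muts <- mutations(
      id = sprintf("NC%05d", seq_along(rows)),
      chrom = vapply(rows, `[[`, "", "chrom"),
      pos = vapply(rows, function(r) r$pos, 1L),
      mclass = "non_coding",
      diseases = lapply(rows, `[[`, "dis"))

    cm <- if (isTRUE(cfg$contacts)) simulate_contacts(cfg, muts, units)
          else NULL
    list(net = net, muts = muts, cm = cm, units = units)
  })
}

# distance-decaying negative-binomial contacts on chr1, boosted on the bin
# pairs of planted same-disease pairs
simulate_contacts <- function(cfg, muts, units) {
  res <- cfg$resolution
  nb <- as.integer(ceiling(cfg$chrom_length / res))
  band <- min(nb - 1L, as.integer(2e6 %/% res))
  ij <- do.call(rbind, lapply(0:band, function(d)
    cbind(i = 0:(nb - 1L - d), j = d:(nb - 1L))))
  d <- pmax(1L, ij[, 2] - ij[, 1])
  mu <- cfg$contact_mu / d^cfg$contact_decay
  boosted <- vapply(units, function(u) {
    muts$chrom[u$i] == "chr1" &&
      same_disease(muts$diseases[[u$i]], muts$diseases[[u$j]])
  }, logical(1))
  if (any(boosted)) {
    bi <- vapply(units[boosted], function(u) bin_index(muts$pos[u$i], res), 1L)
    bj <- vapply(units[boosted], function(u) bin_index(muts$pos[u$j], res), 1L)
    pkey <- pmin(bi, bj) * nb + pmax(bi, bj)
    hit <- match(unique(pkey), ij[, 1] * nb + ij[, 2])
    hit <- hit[!is.na(hit)]
    mu[hit] <- mu[hit] * cfg$contact_boost
  }
  counts <- rnbinom(length(mu), size = cfg$contact_dispersion, mu = mu)
  keep <- counts > 0
  entries <- data.frame(bin_i = ij[keep, 1], bin_j = ij[keep, 2],
                        count = counts[keep])
  mat <- Matrix::sparseMatrix(i = entries$bin_i + 1L, j = entries$bin_j + 1L,
                              x = entries$count, dims = c(nb, nb),
                              symmetric = TRUE)
  normvec <- sqrt(pmax(Matrix::rowSums(mat), 1))
  contact_matrix("chr1", res, entries, normvec)
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

consensus_pwm <- function(tf, consensus, p_major = 0.97) {
  bases <- c("A", "C", "G", "T")
  idx <- match(strsplit(consensus, "")[[1]], bases)
  mat <- matrix((1 - p_major) / 3, nrow = 4, ncol = length(idx))
  mat[cbind(idx, seq_along(idx))] <- p_major
  pwm(tf, mat)
}

revcomp_chr <- function(x) {
  chartr("ACGT", "TGCA", paste(rev(strsplit(x, "")[[1]]), collapse = ""))
}

#' Simulate sequences, PWMs and a TF network with planted motif sites
#'
#' Builds consensus-heavy PWMs (one per TF; major-base probability 0.97),
#' uniform-background region sequences, and embeds consensus sites at known
#' coordinates: one background plant of a random TF in every region, plus an
#' excess of interacting-TF motif pairs across the interacting region pairs
#' (`interacting_cooccurrence` co-plants per pair). The scanner is expected
#' to recover essentially all planted sites at threshold 6.
#'
#' @param cfg a [sim_config()].
#' @return list: `seqs` (named character, one per region), `pwms`,
#'   `tfnet`, `region_pairs` (interacting region IDs), `planted`
#'   (data.frame region/tf/start/strand), `hits_by_region`.
#' @export
simulate_motif_dataset <- function(cfg) {
  with_seed(cfg$seed, {
    wlen <- cfg$motif_width
    if (wlen > cfg$region_length) stop("motif longer than region sequence")
    tfs <- sprintf("TF%02d", seq_len(cfg$motif_set_size))
    cons <- vapply(tfs, function(t) random_dna(wlen), "")
    pwms <- lapply(seq_along(tfs), function(k) consensus_pwm(tfs[k], cons[k]))
    names(pwms) <- tfs
    all_pairs <- pair_index(length(tfs))
    pick <- runif(nrow(all_pairs)) < 0.3
    if (!any(pick)) pick[sample(length(pick), 1)] <- TRUE
    tfnet <- tf_network(tfs, data.frame(tf1 = tfs[all_pairs[pick, 1]],
                                        tf2 = tfs[all_pairs[pick, 2]],
                                        stringsAsFactors = FALSE))
    regions <- sprintf("R%03d", seq_len(cfg$n_regions))
    seqs <- setNames(vapply(regions, function(r)
      random_dna(cfg$region_length), ""), regions)
    region_pairs <- data.frame(
      region_a = regions[seq(1, cfg$n_regions - 1, by = 2)],
      region_b = regions[seq(2, cfg$n_regions, by = 2)],
      stringsAsFactors = FALSE)
    planted <- list()
    occupied <- setNames(rep(list(integer(0)), length(regions)), regions)
    embed <- function(region, tf) {
      # rejection-sample a slot that does not clobber an earlier plant, so
      # every recorded planted site is actually present in the sequence
      slot <- NA_integer_
      for (try in 1:100) {
        cand <- sample.int(cfg$region_length - wlen + 1L, 1)
        if (!any(abs(occupied[[region]] - cand) < wlen)) {
          slot <- cand
          break
        }
      }
      if (is.na(slot)) return(invisible(NULL))  # region saturated; skip
      occupied[[region]] <<- c(occupied[[region]], slot)
      strand <- sample(c("+", "-"), 1)
      site <- if (strand == "+") cons[[tf]] else revcomp_chr(cons[[tf]])
      s <- seqs[[region]]
      substr(s, slot, slot + wlen - 1L) <- site
      seqs[[region]] <<- s
      planted[[length(planted) + 1L]] <<- data.frame(
        region = region, tf = tf, start = slot - 1L, strand = strand,
        stringsAsFactors = FALSE)
    }
    for (r in regions) embed(r, sample(tfs, 1))  # one background site each
    n_co <- round(cfg$interacting_cooccurrence)
    if (nrow(tfnet$edges) > 0 && n_co > 0) {
      for (k in seq_len(nrow(region_pairs))) {
        for (rep_k in seq_len(n_co)) {
          e <- tfnet$edges[sample.int(nrow(tfnet$edges), 1), ]
          embed(region_pairs$region_a[k], e$tf1)
          embed(region_pairs$region_b[k], e$tf2)
        }
      }
    }
    planted <- do.call(rbind, planted)
    list(seqs = seqs, pwms = pwms, tfnet = tfnet,
         region_pairs = region_pairs, planted = planted,
         hits_by_region = planted[, c("region", "tf")])
  })
}
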