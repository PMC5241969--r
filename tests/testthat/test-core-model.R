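# core model: readers/writers, coordinate conventions, disease mapping,
# template scoring

test_that("mutation TSV round-trips and validates", {
  m <- mutations(id = c("a", "b", "c"), chrom = c("1", "chr2", "chrX"),
                 pos = c(100L, 200L, 300L),
                 mclass = c("coding_missense", "non_coding", "non_coding"),
                 ref = c("C", NA, "G"), alt = c("T", NA, "A"),
                 protein = c("TP53", NA, NA), residue = c(244L, NA, NA),
                 diseases = list(c("MESH:D001943", "MESH:D009369"),
                                 character(0), "OMIM:256450"))
  expect_equal(m$chrom, c("chr1", "chr2", "chrX"))  # chr prefix normalised
  path <- withr::local_tempfile(fileext = ".tsv")
  write_mutations(m, path)
  back <- read_mutations(path)
  expect_equal(as.data.frame(back), as.data.frame(m))
})

test_that("malformed mutation rows error with the line number", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(paste(c("id", "chrom", "pos", "ref", "alt", "mclass",
                       "protein", "residue", "diseases"), collapse = "\t"),
               "m1\tchr1\t0\t.\t.\tnon_coding\t.\t.\t."), path)
  expect_error(read_mutations(path), "line 2")
  writeLines(c(paste(c("id", "chrom", "pos", "ref", "alt", "mclass",
                       "protein", "residue", "diseases"), collapse = "\t"),
               "m1\tchr1\t10\t.\t.\tnon_coding\t.\t.\t.",
               "m1\tchr1\t20\t.\t.\tnon_coding\t.\t.\t."), path)
  expect_error(read_mutations(path), "duplicate")
  expect_error(mutations(id = "x", chrom = "chr1", pos = 5,
                         mclass = "coding_missense"),
               "require protein and residue")
})

test_that("minimal VCF parsing keeps 1-based positions", {
  path <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c("##fileformat=VCFv4.2",
               "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO",
               "chr11\t17498513\tv1\tC\tG\t.\t.\tMCLASS=non_coding;DIS=MESH:D044903",
               "11\t17409692\tv2\tC\tT\t.\t.\tDIS=MESH:D044903"), path)
  v <- read_mutations(path, dialect = "vcf_minimal")
  expect_equal(v$chrom, c("chr11", "chr11"))
  expect_equal(v$pos, c(17498513L, 17409692L))
  expect_equal(v$mclass, c("non_coding", "non_coding"))  # MCLASS default
  expect_equal(v$diseases[[1]], "MESH:D044903")
})

test_that("unknown chromosomes are skipped with a warning", {
  path <- withr::local_tempfile(fileext = ".tsv")
  m <- make_muts(4, chrom = c("chr1", "chr1", "chrUn_gl000220", "chr2"))
  write_mutations(m, path)
  expect_warning(kept <- read_mutations(path, valid_chroms = c("chr1", "chr2")),
                 "1 mutation")
  expect_equal(nrow(kept), 3L)
})

test_that("map_disease_names drops unmapped names with drop semantics", {
  tab <- c("breast cancer" = "MESH:D001943", "lung cancer" = "MESH:D008175",
           "diabetes" = "MESH:D003920")
  expect_equal(map_disease_names("breast cancer", tab), "MESH:D001943")
  expect_equal(suppressMessages(map_disease_names("unknownitis", tab)),
               character(0))
  mixed <- c("breast cancer", "nopeopathy", "Diabetes", "lung cancer",
             "fooosis")
  expect_length(suppressMessages(map_disease_names(mixed, tab)), 3L)
})

test_that("match score and admissibility follow the 40% rule", {
  expect_equal(match_score(1, 1, 1, 1), 2)
  expect_true(template_admissible(1, 1, 1, 1))
  expect_equal(match_score(0.5, 0.8, 0.6, 0.9), 0.94)
  expect_false(template_admissible(0.39, 0.9, 0.9, 0.9))
  expect_error(match_score(1.2, 0.5, 0.5, 0.5), "\\[0, 1\\]")
  # monotone non-decreasing in each argument
  set.seed(11)
  for (r in 1:50) {
    x <- runif(4)
    k <- sample(4, 1)
    y <- x; y[k] <- min(1, x[k] + runif(1, 0, 1 - x[k]))
    expect_gte(do.call(match_score, as.list(y)),
               do.call(match_score, as.list(x)))
  }
})

test_that("bin indexing maps the first resolution bp to bin 0", {
  expect_equal(bin_index(1L, 5000L), 0L)
  expect_equal(bin_index(5000L, 5000L), 0L)
  expect_equal(bin_index(5001L, 5000L), 1L)
  set.seed(4)
  res <- sample(c(5000L, 10000L, 25000L, 50000L), 20, replace = TRUE)
  pos <- sample.int(1e6, 20)
  expect_true(all(bin_index(pos, res) == (pos - 1) %/% res))
})

test_that("interface map applies the double-merge rule at load", {
  im <- interface_map("TFX", 20, data.frame(
    start = c(3L, 8L, 15L), end = c(10L, 12L, 16L),
    class = c("protein_binding", "dna_binding", "double")))
  expect_equal(im$residue_class[5], "protein_binding")
  expect_equal(im$residue_class[9], "double")     # pb and db overlap
  expect_equal(im$residue_class[11], "dna_binding")
  expect_equal(im$residue_class[15], "double")    # explicit double
  expect_equal(im$residue_class[1], "none")
  expect_error(interface_map("TFX", 10, data.frame(
    start = 5L, end = 12L, class = "protein_binding")), "1 <= start")
})

test_that("all remaining formats round-trip losslessly", {
  dir <- withr::local_tempdir()
  # interface maps
  imaps <- list(
    A = interface_map("A", 50, data.frame(start = c(5L, 30L),
                                          end = c(10L, 35L),
                                          class = c("protein_binding",
                                                    "dna_binding"))),
    B = interface_map("B", 20, data.frame(start = integer(0),
                                          end = integer(0),
                                          class = character(0))))
  p <- file.path(dir, "imaps.tsv")
  write_interface_maps(imaps, p)
  back <- read_interface_maps(p)
  expect_equal(lapply(back, `[[`, "residue_class"),
               lapply(imaps, `[[`, "residue_class"))
  # chromatin net
  net <- toy_net()
  write_chromatin_net(net, file.path(dir, "a.bed"), file.path(dir, "e.tsv"))
  net2 <- read_chromatin_net(file.path(dir, "a.bed"), file.path(dir, "e.tsv"))
  expect_equal(net2$anchors, net$anchors)
  expect_equal(net2$edges, net$edges)
  # contact matrix
  cm <- contact_matrix("chr1", 5000L,
                       data.frame(bin_i = c(0L, 3L), bin_j = c(2L, 1L),
                                  count = c(12, 5)),
                       normvec = c(2, 3, 1, 4))
  write_contact_matrix(cm, file.path(dir, "c.triples"),
                       file.path(dir, "c.vec"))
  cm2 <- read_contact_matrix(file.path(dir, "c.triples"),
                             file.path(dir, "c.vec"), "chr1", 5000L)
  expect_equal(as.matrix(cm2$mat), as.matrix(cm$mat))
  expect_equal(cm2$normvec, cm$normvec)
  # TF network
  tn <- tf_network(c("A", "B", "C"),
                   data.frame(tf1 = c("B", "C"), tf2 = c("A", "C")))
  write_tf_network(tn, file.path(dir, "tf.tsv"))
  tn2 <- read_tf_network(file.path(dir, "tf.tsv"))
  expect_equal(tn2$edges, tn$edges)
  # PWMs: PFM and MEME minimal
  pwms <- list(M1 = pwm("M1", matrix(c(10, 0, 0, 0,
                                       0, 10, 0, 0,
                                       2, 2, 4, 2), nrow = 4)),
               M2 = pwm("M2", matrix(0.25, nrow = 4, ncol = 5)))
  write_pfm(pwms, file.path(dir, "m.pfm"))
  expect_equal(lapply(read_pfm(file.path(dir, "m.pfm")), `[[`, "matrix"),
               lapply(pwms, `[[`, "matrix"))
  write_meme(pwms, file.path(dir, "m.meme"))
  back <- read_meme(file.path(dir, "m.meme"))
  expect_equal(lapply(back, `[[`, "matrix"),
               lapply(pwms, `[[`, "matrix"), tolerance = 1e-5)
  # FASTA
  write_genome(c(s1 = "ACGTACGT", s2 = "GGGCCC"), file.path(dir, "g.fa"))
  g <- read_genome(file.path(dir, "g.fa"))
  expect_equal(as.character(g), c(s1 = "ACGTACGT", s2 = "GGGCCC"))
})

test_that("constructors reject invalid containers", {
  expect_error(chromatin_net(
    anchors = data.frame(anchor_id = "A1", chrom = "chr1",
                         start = 0L, end = 100L),
    edges = data.frame(anchor_id = "A1", chrom = "chr2",
                       start = 0L, end = 50L)),
    "intra-chromosomal")
  expect_error(contact_matrix("chr1", 1234L,
                              data.frame(bin_i = 0L, bin_j = 0L, count = 1),
                              normvec = 1), "resolution")
  expect_error(pwm("x", matrix(1, nrow = 3, ncol = 2)), "4 rows")
  expect_error(tf_network("A", data.frame(tf1 = "A", tf2 = "Z")),
               "network nodes")
})
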