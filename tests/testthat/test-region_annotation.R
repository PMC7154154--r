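test_that("region classification matches the hand-built fixture", {
  gm <- fixture_gene_models()
  v <- fixture_variants()
  rc <- classify_variant_region(v, gm)
  expect_equal(rc$category,
               c("UTR5",            # 5050 in GA UTR5
                 "exonic",          # 5200 in GA first exon past the UTR
                 "intronic",        # 6000 in GA intron
                 "UTR3",            # 8950 in GA UTR3
                 "upstream",        # 4500, 500 bp upstream of GA TSS
                 "downstream",      # 9500, past GA TES
                 "ncRNA_intronic",  # 21000 intron of noncoding GB
                 "intergenic",      # 12000 far from both
                 "exonic"))         # 23900 exon of GB
  expect_equal(rc$gene_id[1:4], rep("GA", 4))
  expect_true(is.na(rc$gene_id[8]))
})

test_that("every variant receives exactly one category (partition)", {
  b <- default_bundle()
  rc <- classify_variant_region(b$variants, b$gene_models)
  expect_equal(nrow(rc), nrow(b$variants))
  expect_true(all(rc$category %in% c("exonic", "UTR5", "UTR3", "intronic",
                                     "ncRNA_intronic", "upstream",
                                     "downstream", "intergenic")))
})

test_that("region classifier agrees with the per-position oracle on random models", {
  set.seed(404)
  for (rep in 1:4) {
    gm <- generate_gene_models(5e4, n_genes = 4)
    pos <- sample.int(5e4 - 400, 25) + 200
    v <- make_variants("chrS", pos, "A", "G")
    v$ref <- "A"; v$alt <- "G"   # alleles irrelevant to classification
    rc <- suppressWarnings(classify_variant_region(v, gm))
    for (i in seq_along(pos)) {
      o <- oracle_classify_pos(pos[i], "chrS", gm)
      expect_equal(rc$category[i], o$category,
                   info = paste("pos", pos[i], "rep", rep))
    }
  }
})

test_that("fold enrichment reproduces hand arithmetic and its invariances", {
  fe <- fold_enrichment(c(introns = 30, exons = 10),
                        c(introns = 5000, exons = 1000),
                        total_variants = 40, total_length = 10000)
  expect_equal(fe$ratio, c(1.5, 2.5))

  # identity: one category covering everything
  expect_equal(fold_enrichment(c(all = 7), c(all = 1234))$ratio, 1)
  # zero-variant category
  expect_equal(fold_enrichment(c(a = 10, b = 0), c(a = 100, b = 300))$ratio[2], 0)
  # scale invariance in lengths
  f1 <- fold_enrichment(c(a = 3, b = 9), c(a = 100, b = 500))
  f2 <- fold_enrichment(c(a = 3, b = 9), c(a = 1700, b = 8500))
  expect_equal(f1$ratio, f2$ratio)
})

test_that("substitution spectrum counts and strand-collapse", {
  v <- make_variants("chr1", c(10, 20, 30, 40),
                     c("A", "C", "C", "AT"), c("G", "T", "T", "A"))
  expect_message(sp <- substitution_spectrum(v), "indel")
  expect_equal(unname(sp["C>T"]), 2)
  expect_equal(unname(sp["A>G"]), 1)
  expect_equal(sum(sp), 3)
  expect_equal(names(which.max(sp)), "C>T")

  empty <- substitution_spectrum(make_variants(character(0), integer(0),
                                               character(0), character(0)))
  expect_equal(sum(empty), 0)
  expect_length(empty, 12)

  # collapsed view merges complementary pairs
  v2 <- make_variants("chr1", c(1, 2), c("G", "C"), c("A", "T"))
  sp6 <- substitution_spectrum(v2, collapse = TRUE)
  expect_equal(unname(sp6["C>T"]), 2)
  expect_length(sp6, 6)
})

test_that("planted spectrum is recovered within the binomial 95% CI", {
  set.seed(71)
  genome <- generate_genome(3e5, gc = 0.41)
  gm <- generate_gene_models(3e5, n_genes = 20)
  gv <- generate_variants(genome, gm, n = 5000, indel_fraction = 0,
                          region_weights = c(intronic = 0.4, intergenic = 0.6),
                          spectrum = default_spectrum())
  sp <- substitution_spectrum(gv$variants)
  n <- sum(sp)
  for (cl in names(default_spectrum())) {
    p <- default_spectrum()[[cl]]
    half <- 1.96 * sqrt(p * (1 - p) / n)
    expect_lt(abs(sp[[cl]] / n - p), half + 0.01, label = cl)
  }
})

test_that("nearest-TSS assignment: basic geometry, tie rule, oracle equivalence", {
  tx <- data.frame(transcript_id = c("a.t1", "b.t1"),
                   gene_id = c("a", "b"), chrom = "chrF", strand = "+",
                   start = c(1000L, 5000L), end = c(1500L, 5500L),
                   biotype = "coding", stringsAsFactors = FALSE)
  ex <- data.frame(transcript_id = c("a.t1", "b.t1"),
                   start = c(1000L, 5000L), end = c(1500L, 5500L),
                   stringsAsFactors = FALSE)
  gm <- make_gene_models(tx, ex)
  v <- make_variants("chrF", c(2999, 3000), c("A", "A"), c("G", "G"))
  asg <- assign_nearest_tss(v, gm)
  expect_equal(asg$gene_id, c("a", "a"))   # 2999 closer to 1000; 3000 tie -> "a"
  expect_equal(asg$distance[1], 1999)

  b <- default_bundle()
  set.seed(99)
  idx <- sample(nrow(b$variants), 200)
  asg2 <- assign_nearest_tss(b$variants[idx, ], b$gene_models)
  for (k in seq_along(idx)) {
    o <- oracle_nearest_tss(b$variants$pos[idx[k]], b$variants$chrom[idx[k]],
                            b$gene_models)
    expect_equal(asg2$gene_id[k], o$gene_id)
    expect_equal(asg2$distance[k], o$distance)
  }
})

test_that("TSS distance profile: boundaries and brute-force histogram", {
  gm <- fixture_gene_models()
  # variant exactly at GA's TSS (5000)
  v0 <- make_variants("chrF", 5000, "A", "G")
  pr <- tss_distance_profile(v0, gm)
  expect_equal(sum(pr$count), 1)
  expect_equal(pr$count[pr$bin_start == 0], 1)

  # farther than the window from every TSS -> empty
  v1 <- make_variants("chrF", 12600, "A", "G")
  expect_equal(sum(tss_distance_profile(v1, gm)$count), 0)

  # random cohort vs direct per-variant histogram
  set.seed(11)
  pos <- sample(3000:11000, 150)
  v <- make_variants("chrF", pos, "A", "G")
  pr2 <- tss_distance_profile(v, gm, half_window = 2500, bin = 50)
  asg <- assign_nearest_tss(v, gm)
  d <- asg$distance[abs(asg$distance) <= 2500]
  manual <- sapply(seq_len(nrow(pr2)), function(i)
    if (pr2$bin_end[i] == 2500)
      sum(d >= pr2$bin_start[i] & d <= pr2$bin_end[i])
    else sum(d >= pr2$bin_start[i] & d < pr2$bin_end[i]))
  expect_equal(pr2$count, as.integer(manual))
  expect_equal(sum(pr2$count), length(d))
})
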