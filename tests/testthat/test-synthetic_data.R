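test_that("genome generation: determinism, GC target, degenerate gc", {
  g1 <- generate_genome(20000, gc = 0.41, seed = 9)
  g2 <- generate_genome(20000, gc = 0.41, seed = 9)
  expect_identical(g1, g2)
  g3 <- generate_genome(20000, gc = 0.41, seed = 10)
  expect_false(identical(g1, g3))

  g0 <- generate_genome(5000, gc = 0, seed = 1)
  expect_false(grepl("[GC]", g0[[1]]))

  # base frequencies within binomial CI at 500 kb
  g <- generate_genome(5e5, gc = 0.41, seed = 2)
  gc_obs <- mean(strsplit(g[[1]], "")[[1]] %in% c("G", "C"))
  expect_lt(abs(gc_obs - 0.41), 1.96 * sqrt(0.41 * 0.59 / 5e5) + 1e-3)
})

test_that("gene models: bounds, disjoint exons, GTF round-trip", {
  gm <- generate_gene_models(2e5, n_genes = 15, seed = 4)
  expect_equal(nrow(gm$transcripts), 15)
  expect_true(all(gm$transcripts$start >= 1 & gm$transcripts$end <= 2e5))
  for (tid in gm$transcripts$transcript_id) {
    ex <- gm$exons[gm$exons$transcript_id == tid, ]
    ex <- ex[order(ex$start), ]
    expect_gte(nrow(ex), 2)
    if (nrow(ex) > 1) expect_true(all(ex$start[-1] > ex$end[-nrow(ex)]))
  }
  expect_setequal(unique(gm$transcripts$biotype), c("coding", "noncoding"))
  f <- withr::local_tempfile(fileext = ".gtf")
  write_gtf(gm, f)
  gm2 <- read_gene_models(f)
  o <- order(gm2$transcripts$transcript_id)
  expect_equal(gm2$transcripts$tss[o],
               gm$transcripts$tss[order(gm$transcripts$transcript_id)])
})

test_that("variants land in their planted categories with matching ref alleles", {
  set.seed(21)
  genome <- generate_genome(2e5, seed = 21)
  gm <- generate_gene_models(2e5, n_genes = 15)
  gv <- generate_variants(genome, gm, n = 300)
  v <- gv$variants
  # ref alleles always match the genome
  for (i in sample(nrow(v), 50))
    expect_equal(substr(genome[[1]], v$pos[i], v$pos[i] + nchar(v$ref[i]) - 1),
                 v$ref[i])
  # planted category equals the classifier's call
  rc <- classify_variant_region(v, gm)
  expect_equal(rc$category, gv$truth$planted_category)

  # weights all on intergenic -> every variant intergenic
  gvi <- generate_variants(genome, gm, n = 50,
                           region_weights = c(intergenic = 1))
  rci <- classify_variant_region(gvi$variants, gm)
  expect_true(all(rci$category == "intergenic"))
})

test_that("peak generation realizes the switch plan exactly", {
  set.seed(33)
  genome <- generate_genome(2e5, seed = 33)
  gm <- generate_gene_models(2e5, n_genes = 15)
  v <- generate_variants(genome, gm, n = 250)$variants
  plan <- default_switch_plan()
  sw <- assign_switch_classes(v, plan)
  pk <- generate_peaks(v, sw, 2e5)
  st <- epi_state_table(v, pk, conditions = c("stem", "induced"))
  got <- merge(st, sw, by = c("variant_id", "mark"))
  expect_equal(got$switch, got$class)   # plan-vs-call identity, all marks
  # planned I->I variants sit outside peaks in both conditions
  ii <- sw$variant_id[sw$mark == "H3K4me3" & sw$class == "I->I"]
  ii_states <- st[st$mark == "H3K4me3" & st$variant_id %in% ii, ]
  expect_true(all(ii_states$switch == "I->I"))
})

test_that("expression generator: null calibration, planted ratio, determinism", {
  ge0 <- generate_expression(sprintf("g%04d", 1:1000), de_fraction = 0,
                             reps = 3, seed = 61)
  de0 <- differential_expression(ge0$expr, "stem", "induced")
  # under the null the raw-p distribution is calibrated: fraction below
  # 0.05 close to 0.05 (binomial tolerance), and no gene passes the
  # joint FC + FDR gate
  fp <- mean(de0$pvalue < 0.05, na.rm = TRUE)
  expect_lt(abs(fp - 0.05), 0.025)
  expect_equal(sum(de0$direction != "ns"), 0)

  # planted up gene: observed TPM ratio close to 4x by construction
  ge1 <- generate_expression(c("up1", sprintf("n%03d", 1:99)),
                             de_genes = c(up1 = 2), reps = 3, seed = 62)
  m <- tapply(ge1$expr$tpm[ge1$expr$gene_id == "up1"],
              ge1$expr$condition[ge1$expr$gene_id == "up1"], mean)
  expect_gt(m[["induced"]] / m[["stem"]], 2.5)
  de1 <- differential_expression(ge1$expr, "stem", "induced")
  expect_equal(de1$direction[de1$gene_id == "up1"], "up")
  # the strict preset's FC >= 4 gate needs an effect above 4-fold on
  # the pseudocounted scale (an exactly 4-fold effect lands just below)
  ge1s <- generate_expression(c("up1", sprintf("n%03d", 1:99)),
                              de_genes = c(up1 = 2.5), reps = 3,
                              sigma_log2 = 0.05, de_baseline_min = 5,
                              seed = 64)
  de1s <- differential_expression(ge1s$expr, "stem", "induced",
                                  preset = "strict")
  expect_equal(de1s$direction[de1s$gene_id == "up1"], "up")

  ge2 <- generate_expression(sprintf("g%04d", 1:50), seed = 63)
  ge3 <- generate_expression(sprintf("g%04d", 1:50), seed = 63)
  expect_identical(ge2$expr, ge3$expr)
})

test_that("TF expression plan straddles the gate as planned", {
  b <- default_bundle()
  plan <- b$truth$tf_plan
  tf1 <- expressed_tfs(b$expr, "stem", b$tf_map)
  tf2 <- expressed_tfs(b$expr, "induced", b$tf_map)
  want1 <- b$tf_map$tf_name[match(plan$gene_id[plan$expressed_1],
                                  b$tf_map$gene_id)]
  want2 <- b$tf_map$tf_name[match(plan$gene_id[plan$expressed_2],
                                  b$tf_map$gene_id)]
  expect_setequal(tf1, want1)
  expect_setequal(tf2, want2)
})

test_that("regulatory plants guarantee score separation at the cutoff", {
  set.seed(91)
  genome <- c(chrW = random_dna(2000))
  v <- make_variants("chrW", 1000, substr(genome, 1000, 1000),
                     setdiff(c("A", "C", "G", "T"),
                             substr(genome, 1000, 1000))[1])
  pwm <- pfm_to_pwm(toy_pfms()$TF04)
  gain <- plant_regulatory_variant(genome, pwm, v, "gain")
  wg <- extract_allele_windows(gain$genome, v, 6)
  dg <- allele_delta(pwm, wg)
  expect_gte(dg$score_alt, 10)
  expect_lt(dg$score_ref, 10)
  expect_gt(dg$diff, 0)

  loss <- plant_regulatory_variant(genome, pwm, v, "loss")
  wl <- extract_allele_windows(loss$genome, v, 6)
  dl <- allele_delta(pwm, wl)
  expect_gte(dl$score_ref, 10)
  expect_lt(dl$score_alt, 10)
  expect_lt(dl$diff, 0)

  # a motif too wide for the rescoring window is rejected
  expect_error(plant_regulatory_variant(genome, pfm_to_pwm(toy_pfms()$TF10),
                                        v, "gain"), "window|separate")
})

test_that("bundles parse through every reader and regenerate identically", {
  b <- default_bundle()
  dir <- default_bundle_dir()
  expect_identical(read_fasta(file.path(dir, "genome.fa")), b$genome)
  v2 <- read_variants(file.path(dir, "variants.vcf"))
  expect_equal(v2[, c("chrom", "pos", "ref", "alt", "vclass")],
               b$variants[, c("chrom", "pos", "ref", "alt", "vclass")])
  expect_equal(nrow(read_expression(file.path(dir, "expression.tsv"))),
               nrow(b$expr))
  expect_length(read_jaspar(file.path(dir, "motifs.jaspar")), 10)
  gm2 <- read_gene_models(file.path(dir, "genes.gtf"))
  expect_equal(nrow(gm2$transcripts), nrow(b$gene_models$transcripts))

  # same seed regenerates the same bundle; different seed differs
  b2 <- generate_bundle(sim_config(), seed = 202)
  expect_identical(b2$genome, b$genome)
  expect_identical(b2$variants, b$variants)
  expect_identical(b2$truth$causal, b$truth$causal)
  b3 <- generate_bundle(sim_config(n_variants = 400, genome_length = 3e5,
                                   n_genes = 30, count_plant_n = 0),
                        seed = 303)
  expect_false(identical(b3$variants$variant_id, b$variants$variant_id))
})
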