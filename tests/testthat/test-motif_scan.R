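test_that("PFM to PWM: uniform column, hand arithmetic, count-doubling", {
  pfm <- list(tf_name = "X",
              counts = matrix(c(1, 1, 1, 1, 10, 0, 0, 0), nrow = 4,
                              dimnames = list(c("A", "C", "G", "T"), NULL)))
  pwm <- pfm_to_pwm(pfm)
  expect_equal(unname(pwm$weights[, 1]), rep(0, 4))
  expect_equal(unname(pwm$weights["A", 2]), log((10.5 / 12) / 0.25),
               tolerance = 1e-9)
  expect_equal(unname(pwm$weights["A", 2]), 1.2528, tolerance = 1e-4)
  expect_equal(unname(pwm$weights["C", 2]), -1.7918, tolerance = 1e-4)

  # doubling all counts of a zero-free matrix barely moves the weights
  # (pseudocount dilution only) and preserves each column's argmax;
  # zero-count cells move more because the pseudocount dominates them
  pfm3 <- list(tf_name = "Y",
               counts = matrix(c(10, 1, 2, 3, 1, 12, 2, 1), nrow = 4,
                               dimnames = list(c("A", "C", "G", "T"), NULL)))
  pwm3 <- pfm_to_pwm(pfm3)
  pfm4 <- pfm3; pfm4$counts <- pfm3$counts * 2
  pwm4 <- pfm_to_pwm(pfm4)
  expect_true(all(abs(pwm4$weights - pwm3$weights) < 0.2))
  expect_equal(apply(pwm4$weights, 2, which.max),
               apply(pwm3$weights, 2, which.max))

  expect_error(pfm_to_pwm(pfm, background = c(0.5, 0.5, 0, 0)), "positive")
  expect_error(pfm_to_pwm(pfm, background = c(0.3, 0.3, 0.3, 0.2)), "sum")
})

test_that("best-hit scanning: consensus, strand symmetry, tie rule", {
  pwm <- pfm_to_pwm(toy_pfms()$TF03)           # consensus GATCGATC
  cons <- consensus_sequence(pwm)
  expect_equal(cons, "GATCGATC")
  hit <- scan_best_hit(pwm, cons)
  expect_equal(hit$offset, 0L)
  expect_equal(hit$strand, "+")
  expect_equal(hit$score, sum(apply(pwm$weights, 2, max)), tolerance = 1e-12)

  # scanning the reverse complement gives the same best score; a
  # non-palindromic consensus lands on the minus strand there
  pwm4 <- pfm_to_pwm(toy_pfms()$TF04)
  seqs <- paste0("TT", consensus_sequence(pwm4), "ACGTAG")
  h1 <- scan_best_hit(pwm4, seqs)
  h2 <- scan_best_hit(pwm4, reverse_complement(seqs))
  expect_equal(h1$score, h2$score, tolerance = 1e-12)
  expect_equal(h1$strand, "+")
  expect_equal(h2$strand, "-")

  # palindromic motif: + preferred on a strand tie at the same offset
  pal <- list(tf_name = "PAL",
              counts = matrix(0, 4, 4, dimnames = list(c("A", "C", "G", "T"),
                                                       NULL)))
  pal$counts[cbind(match(c("A", "C", "G", "T"), c("A", "C", "G", "T")),
                   1:4)] <- 9
  ppwm <- pfm_to_pwm(pal)                      # consensus ACGT, palindrome
  hp <- scan_best_hit(ppwm, "ACGT")
  expect_equal(hp$strand, "+")
  expect_equal(hp$offset, 0L)

  # too-short sequence
  expect_null(scan_best_hit(pwm, "ACGT"))
})

test_that("best-hit scanning equals exhaustive enumeration on random cases", {
  set.seed(202)
  for (rep in 1:100) {
    w <- sample(4:9, 1)
    pwm <- random_pwm(w)
    s <- random_dna(sample(w:40, 1))
    got <- scan_best_hit(pwm, s)
    want <- oracle_best_hit(pwm, s)
    expect_equal(got$score, want$score, tolerance = 1e-12)
    expect_equal(got$offset, want$offset)
  }
})

test_that("consensus attains the global maximum over all words (width <= 8)", {
  set.seed(17)
  for (w in c(3, 5, 8)) {
    pwm <- random_pwm(w)
    cons_score <- scan_best_hit(pwm, consensus_sequence(pwm))$score
    # exhaustive enumeration over all 4^w words
    words <- do.call(expand.grid, rep(list(c("A", "C", "G", "T")), w))
    scores <- apply(as.matrix(words), 1, function(b)
      sum(pwm$weights[cbind(match(b, c("A", "C", "G", "T")), seq_len(w))]))
    expect_equal(cons_score, max(scores), tolerance = 1e-12)
  }
})

test_that("allele windows: SNV, deletion, mismatch error, truncation", {
  genome <- c(chrW = paste(rep("ACGT", 50), collapse = ""))   # 200 bp
  # SNV at pos 101 (genome base A)
  v <- make_variants("chrW", 101, "A", "G")
  win <- extract_allele_windows(genome, v, half_width = 6)
  expect_equal(nchar(win$ref_window), 12)
  expect_equal(nchar(win$alt_window), 12)
  expect_equal(substr(win$ref_window, win$anchor, win$anchor), "A")
  expect_equal(substr(win$alt_window, win$anchor, win$anchor), "G")
  same <- substr(win$ref_window, 1, 6) == substr(win$alt_window, 1, 6)
  expect_true(same)

  # deletion: alt window 2 bp shorter, or re-padded to width on request
  vd <- make_variants("chrW", 101, "ACG", "A")
  wd <- extract_allele_windows(genome, vd, half_width = 6)
  expect_equal(nchar(wd$ref_window) - nchar(wd$alt_window), 2)
  wdp <- extract_allele_windows(genome, vd, half_width = 6, pad = TRUE)
  expect_equal(nchar(wdp$alt_window), 12)
  expect_true(wdp$padded)

  # reference mismatch is an error
  vm <- make_variants("chrW", 101, "C", "G")
  expect_error(extract_allele_windows(genome, vm, 6), "mismatch")

  # contig edge truncation is flagged
  ve <- make_variants("chrW", 3, "G", "A")
  we <- extract_allele_windows(genome, ve, 6)
  expect_true(we$truncated)
})

test_that("allele deltas: exact difference, antisymmetry, planted gain", {
  pwm <- pfm_to_pwm(toy_pfms()$TF03)
  genome <- c(chrW = random_dna(400))
  set.seed(3)
  genome <- c(chrW = random_dna(400))
  v <- make_variants("chrW", 201, substr(genome, 201, 201),
                     setdiff(c("A", "C", "G", "T"),
                             substr(genome, 201, 201))[1])
  win <- extract_allele_windows(genome, v, 20)
  d <- allele_delta(pwm, win)
  expect_equal(d$diff, d$score_alt - d$score_ref, tolerance = 1e-12)

  # swapping the windows flips the sign
  win_sw <- win
  win_sw$ref_window <- win$alt_window
  win_sw$alt_window <- win$ref_window
  d_sw <- allele_delta(pwm, win_sw)
  expect_equal(d_sw$diff, -d$diff, tolerance = 1e-12)

  # degenerate: identical windows give diff 0
  win_id <- win; win_id$alt_window <- win_id$ref_window
  expect_equal(allele_delta(pwm, win_id)$diff, 0)

  # planted gain: alt completes the consensus, ref breaks it
  pl <- plant_regulatory_variant(genome, pwm, v, "gain")
  wing <- extract_allele_windows(pl$genome, v, 6)
  dg <- allele_delta(pwm, wing)
  expect_gt(dg$diff, 0)
  expect_equal(dg$score_alt, pl$max_score, tolerance = 1e-9)
  expect_lt(dg$score_ref, 10)
  expect_gte(dg$score_alt, 10)
})

test_that("expression gating of TFs is inclusive at the cutoff", {
  tf_map <- data.frame(tf_name = c("T1", "T2", "T3"),
                       gene_id = c("g1", "g2", "g3"),
                       stringsAsFactors = FALSE)
  expr <- data.frame(
    gene_id = rep(c("g1", "g2", "g3"), each = 2),
    condition = "stem", replicate = rep(c("1", "2"), 3),
    tpm = c(3.0, 3.0, 2.99, 2.99, 100, 0), stringsAsFactors = FALSE)
  got <- expressed_tfs(expr, "stem", tf_map)
  expect_setequal(got, c("T1", "T3"))   # mean 3.0 in; 2.99 out; mean 50 in
})

test_that("strong-hit counting and differential TFs behave as filters", {
  set.seed(41)
  genome <- c(chrW = random_dna(5000))
  pos <- seq(300, 4500, by = 300)
  v <- make_variants("chrW", pos, substring(genome, pos, pos),
                     vapply(substring(genome, pos, pos), function(b)
                       setdiff(c("A", "C", "G", "T"), b)[1], ""))
  pwms <- lapply(toy_pfms()[c("TF03", "TF04")], pfm_to_pwm)

  # plant a consensus site into 7 alt windows for TF03
  for (i in 1:7) {
    pl <- plant_regulatory_variant(genome, pwms$TF03,
                                   v[i, , drop = FALSE], "gain")
    genome <- pl$genome
  }
  cr <- strong_hit_counts(v, genome, pwms, "ref", half_width = 75)
  ca <- strong_hit_counts(v, genome, pwms, "alt", half_width = 75)
  expect_equal(unname(ca["TF03"] - cr["TF03"]), 7L)

  d <- differential_tfs(cr, ca, expressed_set = c("TF03", "TF04"),
                        min_count_diff = 5)
  expect_equal(d$tf_name, "TF03")
  expect_equal(d$diff, 7L)
  # below the count-difference floor -> dropped
  expect_equal(nrow(differential_tfs(cr, ca, c("TF03", "TF04"),
                                     min_count_diff = 10)), 0)
  # expression gate beats the count filter
  expect_equal(nrow(differential_tfs(cr, ca, character(0), 5)), 0)
  # identical maps -> empty
  expect_equal(nrow(differential_tfs(cr, cr, c("TF03", "TF04"), 1)), 0)
})

test_that("top-k ranking equals a full sort of the gated counts", {
  counts <- c(TFa = 5L, TFb = 9L, TFc = 9L, TFd = 1L, TFe = 3L)
  expressed <- c("TFa", "TFb", "TFc", "TFe")
  top <- top_k_tfs(counts, expressed, k = 20)
  expect_equal(top$tf_name, c("TFb", "TFc", "TFa", "TFe"))  # ties by name
  expect_equal(nrow(top_k_tfs(counts, expressed, k = 0)), 0)
  expect_equal(top_k_tfs(counts, expressed, k = 2)$tf_name, c("TFb", "TFc"))
})
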