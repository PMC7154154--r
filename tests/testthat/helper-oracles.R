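# Independent reference implementations used as oracles. These are
# deliberately naive (loops, if-chains) and share no code with the
# package's vectorized/interval-tree paths.

ORACLE_CATS <- c("exonic", "UTR5", "UTR3", "intronic", "ncRNA_intronic",
                 "upstream", "downstream", "intergenic")

# per-position region label by explicit per-transcript if-chain
oracle_classify_pos <- function(pos, chrom, gm, flank = 1000L) {
  best_rank <- 8L
  best_gene <- NA_character_
  tx <- gm$transcripts
  for (i in seq_len(nrow(tx))) {
    t1 <- tx[i, ]
    if (t1$chrom != chrom) next
    in_tab <- function(tab) {
      d <- tab[tab$transcript_id == t1$transcript_id, , drop = FALSE]
      nrow(d) > 0 && any(pos >= d$start & pos <= d$end)
    }
    lab <- NULL
    if (in_tab(gm$utr5)) lab <- "UTR5"
    else if (in_tab(gm$utr3)) lab <- "UTR3"
    else if (in_tab(gm$exons)) lab <- "exonic"
    else if (pos >= t1$start && pos <= t1$end)
      lab <- if (t1$biotype == "noncoding") "ncRNA_intronic" else "intronic"
    else if (t1$strand == "+" && pos >= t1$tss - flank && pos < t1$tss)
      lab <- "upstream"
    else if (t1$strand == "-" && pos > t1$tss && pos <= t1$tss + flank)
      lab <- "upstream"
    else if (t1$strand == "+" && pos > t1$tes && pos <= t1$tes + flank)
      lab <- "downstream"
    else if (t1$strand == "-" && pos >= t1$tes - flank && pos < t1$tes)
      lab <- "downstream"
    if (is.null(lab)) next
    r <- match(lab, ORACLE_CATS)
    if (r < best_rank ||
        (r == best_rank && !is.na(best_gene) && t1$gene_id < best_gene)) {
      best_rank <- r
      best_gene <- t1$gene_id
    }
  }
  list(category = ORACLE_CATS[best_rank],
       gene_id = if (best_rank == 8L) NA_character_ else best_gene)
}

# exhaustive offset x strand PWM scan with explicit per-base loops
oracle_best_hit <- function(pwm, sequence) {
  w <- ncol(pwm$weights)
  n <- nchar(sequence)
  if (n < w) return(NULL)
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  score_word <- function(word) {
    s <- 0
    for (j in seq_len(w)) {
      b <- substr(word, j, j)
      if (!b %in% rownames(pwm$weights)) return(-Inf)
      s <- s + pwm$weights[b, j]
    }
    unname(s)
  }
  best <- NULL
  for (off in 0:(n - w)) {
    word <- substr(sequence, off + 1, off + w)
    rc <- paste(rev(unname(comp[strsplit(word, "")[[1]]])), collapse = "")
    for (strand in c("+", "-")) {
      sc <- score_word(if (strand == "+") word else rc)
      if (is.finite(sc) && (is.null(best) || sc > best$score))
        best <- list(offset = off, strand = strand, score = sc)
    }
  }
  best
}

# linear scan over every transcript TSS
oracle_nearest_tss <- function(pos, chrom, gm) {
  tx <- gm$transcripts[gm$transcripts$chrom == chrom, , drop = FALSE]
  if (!nrow(tx)) return(NULL)
  best <- NULL
  for (i in seq_len(nrow(tx))) {
    d <- abs(pos - tx$tss[i])
    if (is.null(best) || d < best$d ||
        (d == best$d && tx$gene_id[i] < best$gene_id) ||
        (d == best$d && tx$gene_id[i] == best$gene_id &&
         tx$transcript_id[i] < best$transcript_id)) {
      sgn <- if (tx$strand[i] == "+") pos - tx$tss[i] else tx$tss[i] - pos
      best <- list(d = d, gene_id = tx$gene_id[i],
                   transcript_id = tx$transcript_id[i], distance = sgn)
    }
  }
  best
}

# textbook step-up FDR adjustment
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p, decreasing = TRUE)
  ro <- order(o)
  pmin(1, cummin(p[o] * m / (m:1)))[ro]
}

# closed-form paired t
oracle_paired_t <- function(x1, x2) {
  d <- x2 - x1
  n <- length(d)
  t <- mean(d) / (stats::sd(d) / sqrt(n))
  list(statistic = t, p.value = 2 * stats::pt(-abs(t), n - 1))
}

# naive point-in-interval state check (boundary convention start <= pos < end)
oracle_state <- function(pos, peaks) {
  hit <- FALSE
  for (i in seq_len(nrow(peaks)))
    if (peaks$start[i] <= pos && pos < peaks$end[i]) hit <- TRUE
  hit
}
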