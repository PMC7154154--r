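#' Default planted substitution spectrum
#'
#' Probabilities over the 12 ordered single-base substitutions,
#' dominated by the deamination-driven C>T / G>A pair and with G>C
#' rarest, the shape typically seen in paired-genome SNV calls.
#'
#' @return named numeric vector of 12 probabilities summing to 1.
#' @export
default_spectrum <- function() {
  c("C>T" = 0.22, "G>A" = 0.20, "A>G" = 0.09, "T>C" = 0.09,
    "C>A" = 0.06, "G>T" = 0.06, "A>C" = 0.05, "T>G" = 0.05,
    "A>T" = 0.05, "T>A" = 0.05, "C>G" = 0.07, "G>C" = 0.01)
}

#' Default planted region-category weights
#'
#' Intron-heavy, echoing the observation that variant calls concentrate
#' in introns.
#'
#' @return named numeric vector over the region categories, summing
#'   to 1.
#' @export
default_region_weights <- function() {
  c(exonic = 0.05, UTR5 = 0.02, UTR3 = 0.03, intronic = 0.40,
    ncRNA_intronic = 0.06, upstream = 0.08, downstream = 0.06,
    intergenic = 0.30)
}

#' Default switch-class plan
#'
#' Counts of variants to plant per epigenetic switch class and mark:
#' 46 promoter-stable (H3K4me3 A->A) and 20 enhancer-stable (H3K27ac
#' A->A) variants in disjoint sets, the surrounding activation/
#' deactivation classes, a small inhibited-in-both background on the
#' repressive signals, and no repressive switches. All remaining
#' variants sit outside peaks in both conditions.
#'
#' @return named list of named count vectors, one per mark.
#' @export
default_switch_plan <- function() {
  list(H3K4me3 = c("I->A" = 30, "A->I" = 30, "A->A" = 46),
       H3K27ac = c("I->A" = 18, "A->I" = 12, "A->A" = 20),
       H3K27me3 = c("In->In" = 10),
       DNAme = c("In->In" = 10))
}

#' Generate an i.i.d. random genome
#'
#' @param length contig length in bp (>= 10 kb by default scale; any
#'   positive length is accepted).
#' @param gc GC content in [0, 1].
#' @param seed RNG seed; NULL to continue the current stream.
#' @param contig contig name.
#' @return named character vector of length 1.
#' @export
generate_genome <- function(length = 5e5, gc = 0.41, seed = NULL,
                            contig = "chrS") {
  with_seed_maybe(seed)
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  seqs <- paste(sample(names(p), length, replace = TRUE, prob = p),
                collapse = "")
  setNames(seqs, contig)
}

#' Generate non-overlapping multi-exon gene models
#'
#' Genes are laid out in equal slots along the contig with intergenic
#' margins on both sides, 2-5 exons each, both strands, roughly 20
#' percent noncoding biotype. Coding transcripts carry 30-bp UTR5/UTR3
#' intervals at the ends of their terminal exons (strand-aware).
#'
#' @param genome_length contig length in bp.
#' @param n_genes number of genes (one transcript each).
#' @param noncoding_fraction fraction of noncoding-biotype genes.
#' @param seed RNG seed; NULL to continue the current stream.
#' @param contig contig name.
#' @return a \code{gene_models} object.
#' @export
generate_gene_models <- function(genome_length, n_genes = 50,
                                 noncoding_fraction = 0.2, seed = NULL,
                                 contig = "chrS") {
  with_seed_maybe(seed)
  slot <- floor(genome_length / n_genes)
  margin <- 1500L
  if (slot < 2 * margin + 1200L)
    stop("genome too short for ", n_genes, " genes")
  tx_rows <- list(); exon_rows <- list(); u5_rows <- list(); u3_rows <- list()
  noncoding <- sample(c(rep(TRUE, round(n_genes * noncoding_fraction)),
                        rep(FALSE, n_genes - round(n_genes * noncoding_fraction))))
  for (i in seq_len(n_genes)) {
    s0 <- (i - 1L) * slot
    span_max <- slot - 2L * margin
    span <- sample(seq(1200L, span_max), 1L)
    gstart <- s0 + margin + sample.int(span_max - span + 1L, 1L)
    gend <- gstart + span - 1L
    strand <- sample(c("+", "-"), 1L)
    n_ex <- sample(2:5, 1L)
    ex_len <- sample(80:250, n_ex, replace = TRUE)
    gaps <- span - sum(ex_len)
    while (gaps < n_ex - 1L) {            # shrink exons until introns fit
      ex_len <- pmax(80L, ex_len - 50L)
      gaps <- span - sum(ex_len)
    }
    cuts <- sort(sample.int(gaps - 1L, n_ex - 1L))
    intron_len <- diff(c(0L, cuts, gaps))[seq_len(n_ex - 1L)]
    starts <- gstart + cumsum(c(0L, ex_len[-n_ex] + intron_len))
    ends <- starts + ex_len - 1L
    ends[n_ex] <- gend
    gid <- sprintf("G%03d", i)
    tid <- paste0(gid, ".t1")
    bt <- if (noncoding[i]) "noncoding" else "coding"
    tx_rows[[i]] <- data.frame(
      transcript_id = tid, gene_id = gid, gene_name = gid, chrom = contig,
      strand = strand, start = gstart, end = gend,
      tss = if (strand == "+") gstart else gend,
      tes = if (strand == "+") gend else gstart,
      biotype = bt, stringsAsFactors = FALSE)
    exon_rows[[i]] <- data.frame(transcript_id = tid, start = starts,
                                 end = ends, stringsAsFactors = FALSE)
    if (bt == "coding") {
      # 30-bp UTRs at the transcript's 5' and 3' terminal exon ends
      if (strand == "+") {
        u5 <- c(starts[1], starts[1] + 29L)
        u3 <- c(ends[n_ex] - 29L, ends[n_ex])
      } else {
        u5 <- c(ends[n_ex] - 29L, ends[n_ex])
        u3 <- c(starts[1], starts[1] + 29L)
      }
      u5_rows[[i]] <- data.frame(transcript_id = tid, start = u5[1],
                                 end = u5[2], stringsAsFactors = FALSE)
      u3_rows[[i]] <- data.frame(transcript_id = tid, start = u3[1],
                                 end = u3[2], stringsAsFactors = FALSE)
    }
  }
  empty <- data.frame(transcript_id = character(0), start = integer(0),
                      end = integer(0), stringsAsFactors = FALSE)
  out <- list(transcripts = do.call(rbind, tx_rows),
              exons = do.call(rbind, exon_rows),
              utr5 = if (length(u5_rows)) do.call(rbind, u5_rows) else empty,
              utr3 = if (length(u3_rows)) do.call(rbind, u3_rows) else empty)
  class(out) <- "gene_models"
  validate_gene_models(out)
}

# Paint every base of the contig with its region category (precedence
# applied high-to-low), used to place variants inside target categories.
paint_region_map <- function(gene_models, genome_length, flank = 1000L) {
  ann <- annotation_intervals(gene_models, flank = flank)
  paint <- rep(8L, genome_length)                     # intergenic
  for (r in 7L:1L) {                                   # low precedence first
    a <- ann[ann$rank == r, , drop = FALSE]
    for (j in seq_len(nrow(a))) {
      lo <- max(1L, a$start[j]); hi <- min(genome_length, a$end[j])
      if (lo <= hi) paint[lo:hi] <- r
    }
  }
  paint
}

#' Generate variants with planted region categories and substitution
#' spectrum
#'
#' Variant anchor positions are sampled inside bases of the target
#' category (painted with the same precedence rules the classifier
#' applies); SNV substitution classes are drawn from the spectrum and
#' placed on matching reference bases, so the planted spectrum is the
#' sampling distribution itself. Indels (anchored, VCF-style, lengths
#' 1-5) make up \code{indel_fraction} of the calls. Anchors are kept at
#' least 8 bp apart and clear of the contig edges.
#'
#' @param genome named character vector (single contig).
#' @param gene_models gene_models object.
#' @param n number of variants.
#' @param region_weights named category weights (default
#'   [default_region_weights()]).
#' @param spectrum named 12-class substitution probabilities (default
#'   [default_spectrum()]).
#' @param indel_fraction fraction of calls that are indels (default
#'   0.55, the indel-heavy ratio seen in paired-genome calls).
#' @param flank flank used when painting categories.
#' @param seed RNG seed; NULL to continue the current stream.
#' @return list with \code{variants} (variants data frame) and
#'   \code{truth} (variant_id, planted_category, planted_substitution —
#'   NA for indels).
#' @export
generate_variants <- function(genome, gene_models, n = 1000,
                              region_weights = default_region_weights(),
                              spectrum = default_spectrum(),
                              indel_fraction = 0.55, flank = 1000L,
                              seed = NULL) {
  with_seed_maybe(seed)
  stopifnot(length(genome) == 1L)
  contig <- names(genome)
  L <- nchar(genome[[1]])
  base_at <- strsplit(genome[[1]], "")[[1]]
  paint <- paint_region_map(gene_models, L, flank = flank)
  edge <- 200L
  usable <- rep(TRUE, L)
  usable[seq_len(edge)] <- FALSE
  usable[(L - edge):L] <- FALSE
  pools <- lapply(seq_along(REGION_CATEGORIES), function(r) {
    idx <- which(paint == r & usable)
    split(idx, base_at[idx])
  })
  names(pools) <- REGION_CATEGORIES
  stopifnot(all(names(region_weights) %in% REGION_CATEGORIES))
  sizes <- vapply(pools, function(p) length(unlist(p, use.names = FALSE)), 0L)
  empty <- names(region_weights)[sizes[names(region_weights)] == 0L]
  if (length(empty)) {
    warning("no genomic bases available for categorie(s) ",
            paste(empty, collapse = ","), "; weights renormalized")
    region_weights <- region_weights[setdiff(names(region_weights), empty)]
    region_weights <- region_weights / sum(region_weights)
  }
  taken <- logical(L)
  block <- function(pos) {
    lo <- max(1L, pos - 7L); hi <- min(L, pos + 7L)
    taken[lo:hi] <<- TRUE
  }
  cats <- sample(names(region_weights), n, replace = TRUE,
                 prob = region_weights)
  is_indel <- stats::runif(n) < indel_fraction
  pos <- integer(n); ref <- character(n); alt <- character(n)
  sub_class <- rep(NA_character_, n)
  draw_pos <- function(cat, want_base = NULL) {
    cand <- if (is.null(want_base)) unlist(pools[[cat]], use.names = FALSE)
            else pools[[cat]][[want_base]]
    cand <- cand[!taken[cand]]
    if (!length(cand)) return(NA_integer_)
    cand[sample.int(length(cand), 1L)]
  }
  for (i in seq_len(n)) {
    if (!is_indel[i]) {
      tries <- 0L
      repeat {
        tries <- tries + 1L
        cl <- sample(names(spectrum), 1L, prob = spectrum)
        p <- draw_pos(cats[i], substr(cl, 1L, 1L))
        if (!is.na(p)) break
        if (tries > 50L) {
          # base pool exhausted: take any base, condition the class on it
          p <- draw_pos(cats[i])
          if (is.na(p)) stop("category pool exhausted: ", cats[i])
          sub <- spectrum[substr(names(spectrum), 1L, 1L) == base_at[p]]
          cl <- sample(names(sub), 1L, prob = sub)
          break
        }
      }
      pos[i] <- p; ref[i] <- substr(cl, 1L, 1L); alt[i] <- substr(cl, 3L, 3L)
      sub_class[i] <- cl
    } else {
      p <- draw_pos(cats[i])
      if (is.na(p)) stop("category pool exhausted: ", cats[i])
      pos[i] <- p
      anchor <- base_at[p]
      len <- sample.int(5L, 1L)
      if (stats::runif(1) < 0.5) {                    # deletion
        ref[i] <- paste(base_at[p:(p + len)], collapse = "")
        alt[i] <- anchor
      } else {                                        # insertion
        ref[i] <- anchor
        alt[i] <- paste(c(anchor, sample(DNA_BASES, len, replace = TRUE)),
                        collapse = "")
      }
    }
    block(pos[i])
  }
  ord <- order(pos)
  variants <- make_variants(contig, pos[ord], ref[ord], alt[ord])
  truth <- data.frame(variant_id = variants$variant_id,
                      planted_category = cats[ord],
                      planted_substitution = sub_class[ord],
                      stringsAsFactors = FALSE)
  list(variants = variants, truth = truth)
}

#' Assign each variant a switch class per mark following a plan
#'
#' Variants carrying any planned (non-default) class form disjoint sets
#' across all plan entries; every other variant gets the mark's
#' quiescent default (I->I for activating marks, T->T for repressive
#' signals). \code{special_sets} optionally pins chosen variant ids to
#' chosen (mark, class) entries before the random assignment.
#'
#' @param variants variants data frame.
#' @param plan named list of named class-count vectors per mark (see
#'   [default_switch_plan()]).
#' @param special_sets optional list of lists with fields mark, class,
#'   ids.
#' @param seed RNG seed; NULL to continue the current stream.
#' @return long data frame with variant_id, mark, class.
#' @export
assign_switch_classes <- function(variants, plan = default_switch_plan(),
                                  special_sets = NULL, seed = NULL) {
  with_seed_maybe(seed)
  ids <- variants$variant_id
  default_class <- function(mark)
    if (mark %in% ACTIVATING_MARKS) "I->I" else "T->T"
  out <- lapply(names(plan), function(mk)
    setNames(rep(default_class(mk), length(ids)), ids))
  names(out) <- names(plan)
  used <- character(0)
  if (!is.null(special_sets)) {
    for (s in special_sets) {
      stopifnot(all(s$ids %in% ids), !any(s$ids %in% used))
      out[[s$mark]][s$ids] <- s$class
      used <- c(used, s$ids)
    }
  }
  for (mk in names(plan)) {
    for (cl in names(plan[[mk]])) {
      already <- if (!is.null(special_sets))
        sum(vapply(special_sets, function(s)
          if (s$mark == mk && s$class == cl) length(s$ids) else 0L, 0L))
      else 0L
      need <- plan[[mk]][[cl]] - already
      if (need < 0L) stop("special sets exceed plan for ", mk, " ", cl)
      if (need == 0L) next
      free <- setdiff(ids, used)
      if (length(free) < need) stop("not enough variants for the switch plan")
      pick <- sample(free, need)
      out[[mk]][pick] <- cl
      used <- c(used, pick)
    }
  }
  long <- do.call(rbind, lapply(names(out), function(mk)
    data.frame(variant_id = ids, mark = mk, class = unname(out[[mk]][ids]),
               stringsAsFactors = FALSE)))
  long
}

#' Generate peak calls realizing a planned switch class per variant
#'
#' For every variant and mark, peaks are built so that [mark_state()]
#' and [classify_switch()] recover the planned class exactly: a peak
#' covering the variant's position is emitted in each condition where
#' the plan says "covered" (A or In), with extents trimmed so no peak
#' ever covers a neighbouring variant. Background peaks clear of all
#' variants are added for realism.
#'
#' @param variants variants data frame.
#' @param switch_classes long data frame (variant_id, mark, class) from
#'   the plan assignment.
#' @param genome_length contig length.
#' @param conditions length-2 condition labels.
#' @param n_background background peaks per mark/condition.
#' @param seed RNG seed; NULL to continue the current stream.
#' @return peaks data frame covering all marks and both conditions.
#' @export
generate_peaks <- function(variants, switch_classes, genome_length,
                           conditions = c("stem", "induced"),
                           n_background = 40L, seed = NULL) {
  with_seed_maybe(seed)
  stopifnot(length(conditions) == 2L)
  v <- variants[order(variants$pos), , drop = FALSE]
  gap_prev <- c(Inf, diff(v$pos))
  gap_next <- c(diff(v$pos), Inf)
  lw <- pmax(0L, pmin(50, gap_prev - 1))
  rw <- pmax(0L, pmin(50, gap_next - 1))
  contig <- v$chrom[1]
  out <- list()
  covered_state <- function(mark) if (mark %in% ACTIVATING_MARKS) "A" else "In"
  for (mk in unique(switch_classes$mark)) {
    sc <- switch_classes[switch_classes$mark == mk, , drop = FALSE]
    cls <- setNames(sc$class, sc$variant_id)[v$variant_id]
    s1 <- sub("->.*$", "", cls); s2 <- sub("^.*->", "", cls)
    for (k in 1:2) {
      state <- if (k == 1L) s1 else s2
      hit <- state == covered_state(mk)
      planted <- if (any(hit))
        make_peaks(contig, v$pos[hit] - lw[hit], v$pos[hit] + rw[hit] + 1L,
                   mk, conditions[k], score = 5)
      else NULL
      bg <- list()
      tries <- 0L
      while (length(bg) < n_background && tries < n_background * 50L) {
        tries <- tries + 1L
        w <- sample(200:800, 1L)
        s <- sample.int(genome_length - w, 1L)
        if (!any(v$pos >= s & v$pos < s + w))
          bg[[length(bg) + 1L]] <- c(s, s + w)
      }
      bgp <- if (length(bg)) {
        m <- do.call(rbind, bg)
        make_peaks(contig, m[, 1], m[, 2], mk, conditions[k], score = 2)
      } else NULL
      out[[paste(mk, k)]] <- rbind(planted, bgp)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Generate a replicated lognormal TPM expression table with planted
#' differential genes
#'
#' Per-gene baseline log2 TPM ~ Normal(3, 2) truncated at 0; each
#' sample adds Normal(0, sigma_log2) noise in log2 space. Planted
#' differential genes shift the condition-2 baseline by +/- effect_log2.
#' TF genes can be pinned above or below the expression gate per
#' condition through \code{tf_plan}.
#'
#' @param gene_ids character vector of gene ids.
#' @param de_genes optional named numeric vector: names are gene ids,
#'   values the signed log2 effect; overrides de_fraction for those
#'   genes.
#' @param de_fraction fraction of remaining genes to perturb by
#'   +/- effect_log2 (random sign).
#' @param effect_log2 planted |log2 fold change| (default 2, i.e.
#'   4-fold).
#' @param reps replicates per condition (default 2).
#' @param sigma_log2 per-sample noise SD in log2 space (default 0.3).
#' @param conditions length-2 condition labels.
#' @param tf_plan optional data frame (gene_id, expressed_1,
#'   expressed_2 logical): expressed genes get baseline log2 TPM 4,
#'   silent ones -1, per condition.
#' @param de_baseline_min floor on the baseline log2 TPM of genes with
#'   a planted effect (default 2): differential genes are planted in
#'   the expressed pool, where a fold change is not swallowed by the
#'   log pseudocount.
#' @param seed RNG seed; NULL to continue the current stream.
#' @return list with \code{expr} (long table) and \code{truth}
#'   (gene_id, planted_effect_log2; 0 for unperturbed genes).
#' @export
generate_expression <- function(gene_ids, de_genes = NULL, de_fraction = 0.2,
                                effect_log2 = 2, reps = 2, sigma_log2 = 0.3,
                                conditions = c("stem", "induced"),
                                tf_plan = NULL, de_baseline_min = 2,
                                seed = NULL) {
  with_seed_maybe(seed)
  gene_ids <- unique(gene_ids)
  n <- length(gene_ids)
  base <- pmax(0, stats::rnorm(n, mean = 3, sd = 2))
  names(base) <- gene_ids
  effect <- setNames(numeric(n), gene_ids)
  if (!is.null(de_genes)) {
    stopifnot(all(names(de_genes) %in% gene_ids))
    effect[names(de_genes)] <- de_genes
  }
  pool <- setdiff(gene_ids, c(names(de_genes),
                              if (!is.null(tf_plan)) tf_plan$gene_id))
  n_extra <- max(0L, round(de_fraction * n) - length(de_genes))
  if (n_extra > 0L && length(pool)) {
    pick <- sample(pool, min(n_extra, length(pool)))
    effect[pick] <- sample(c(-1, 1), length(pick), replace = TRUE) * effect_log2
  }
  base[effect != 0] <- pmax(base[effect != 0], de_baseline_min)
  b1 <- base; b2 <- base + effect
  if (!is.null(tf_plan)) {
    stopifnot(all(c("gene_id", "expressed_1", "expressed_2") %in% names(tf_plan)))
    b1[tf_plan$gene_id] <- ifelse(tf_plan$expressed_1, 4, -1)
    b2[tf_plan$gene_id] <- ifelse(tf_plan$expressed_2, 4, -1)
  }
  rows <- list()
  for (k in 1:2) {
    b <- if (k == 1L) b1 else b2
    for (r in seq_len(reps)) {
      val <- 2^(b + stats::rnorm(n, 0, sigma_log2))
      rows[[paste(k, r)]] <- data.frame(
        gene_id = gene_ids, condition = conditions[k],
        replicate = as.character(r), tpm = val, stringsAsFactors = FALSE)
    }
  }
  list(expr = do.call(rbind, rows),
       truth = data.frame(gene_id = gene_ids,
                          planted_effect_log2 = unname(effect),
                          stringsAsFactors = FALSE))
}

#' Built-in toy motif library
#'
#' Ten sharp position frequency matrices of widths 6-15 (consensus
#' count 18, off-consensus 0), each consensus containing all four
#' bases. With the default PWM settings (pseudocount 0.5, flat
#' background) the per-column consensus weight is ln(3.7) ~ 1.31, so
#' motifs of width >= 8 can exceed the strong-hit score cutoff of 10.
#'
#' @return named list of PFMs.
#' @export
toy_pfms <- function() {
  consensi <- c(TF01 = "ACGTAC", TF02 = "TGCATGC", TF03 = "GATCGATC",
                TF04 = "CTAGCTAGC", TF05 = "AACGTTACGT",
                TF06 = "GGATCCATCGA", TF07 = "TTGACGTCATGC",
                TF08 = "ACGTACGTACGTA", TF09 = "CGATCGATCGATCG",
                TF10 = "TGCATGCATGCATGC")
  pfms <- lapply(names(consensi), function(nm) {
    bases <- strsplit(consensi[[nm]], "")[[1]]
    counts <- matrix(0, 4, length(bases), dimnames = list(DNA_BASES, NULL))
    counts[cbind(match(bases, DNA_BASES), seq_along(bases))] <- 18
    list(tf_name = nm, counts = counts)
  })
  setNames(pfms, names(consensi))
}

#' Plant a regulatory variant: write a motif site whose match the
#' alternate allele completes (gain) or destroys (loss)
#'
#' The motif consensus is written into the genome around an existing
#' SNV so that the variant position falls on a consensus column whose
#' base equals the alternate allele (gain; the reference allele is then
#' re-imposed at the position, breaking the site in the reference
#' genome) or the reference allele (loss). The construction is verified
#' algebraically: the completed site scores the PWM maximum, the
#' one-mismatch allele scores below \code{score_cutoff}; an error is
#' raised if the chosen PWM cannot guarantee both, so planted gains are
#' separable at the cutoff by construction.
#'
#' @param genome named character vector (single contig).
#' @param pwm a PWM (its consensus is written).
#' @param variant one-row variants data frame, SNV.
#' @param mode "gain" or "loss".
#' @param score_cutoff the strong-hit threshold to guarantee
#'   separability against (default 10).
#' @param window_half_width the rescoring half-width the site must fit
#'   inside (default 6, i.e. a 12-bp window).
#' @return list with \code{genome} (edited), tf_name, motif_start
#'   (1-based), max_score and broken_score.
#' @export
plant_regulatory_variant <- function(genome, pwm, variant,
                                     mode = c("gain", "loss"),
                                     score_cutoff = 10,
                                     window_half_width = 6L) {
  mode <- match.arg(mode)
  stopifnot(nrow(variant) == 1L, variant$vclass == "SNV")
  cons <- consensus_sequence(pwm)
  w <- nchar(cons)
  target <- if (mode == "gain") variant$alt else variant$ref
  cols <- which(strsplit(cons, "")[[1]] == target)
  # the whole motif must fit inside the rescoring window around pos
  cols <- cols[cols <= window_half_width + 1L & cols >= w - window_half_width + 1L]
  if (!length(cols))
    stop("no consensus column matches allele ", target,
         " within the rescoring window for ", pwm$tf_name)
  cc <- cols[which.min(abs(cols - (w + 1) / 2))]
  col_w <- pwm$weights[, cc]
  max_score <- sum(apply(pwm$weights, 2, max))
  broken <- max_score - max(col_w) +
    col_w[[if (mode == "gain") variant$ref else variant$alt]]
  if (max_score < score_cutoff || broken >= score_cutoff)
    stop(pwm$tf_name, " cannot separate alleles at cutoff ", score_cutoff,
         " (max ", round(max_score, 2), ", broken ", round(broken, 2), ")")
  seqs <- genome[[1]]
  mstart <- variant$pos - cc + 1L
  if (mstart < 1L || mstart + w - 1L > nchar(seqs))
    stop("motif would run off the contig")
  substr(seqs, mstart, mstart + w - 1L) <- cons
  keep <- if (mode == "gain") variant$ref else variant$ref  # genome carries ref
  substr(seqs, variant$pos, variant$pos) <- keep
  genome[[1]] <- seqs
  list(genome = genome, tf_name = pwm$tf_name, motif_start = mstart,
       max_score = max_score, broken_score = unname(broken))
}

#' Bundle generation configuration
#'
#' Defaults define the study conditions the generator emulates: a
#' 500-kb contig, 50 genes, 1000 variants (55 percent indels, intron-
#' enriched, C>T-dominated spectrum), the Table-2-style switch plan
#' with 46 + 20 disjoint stable variants, 6 causal variants (5
#' promoter-stable, 1 enhancer-stable) at distinct 4-fold up-regulated
#' genes with planted TF-binding gains, 3 replicates of lognormal TPM
#' expression at sigma 0.3, and a 12-site strong-hit count plant for
#' one TF so the differential-TF stage has signal.
#'
#' @param ... overrides for any field.
#' @return named list.
#' @export
sim_config <- function(...) {
  cfg <- list(genome_length = 5e5, gc = 0.41, n_genes = 50,
              noncoding_fraction = 0.2, n_variants = 1000,
              indel_fraction = 0.55,
              region_weights = default_region_weights(),
              spectrum = default_spectrum(),
              switch_plan = default_switch_plan(),
              n_causal_promoter = 5L, n_causal_enhancer = 1L,
              causal_effect_log2 = 2, de_fraction = 0.2, effect_log2 = 2,
              reps = 3L, sigma_log2 = 0.3,
              conditions = c("stem", "induced"),
              n_background_peaks = 40L, count_plant_n = 12L,
              count_plant_tf = "TF04", clearance = 200L, flank = 1000L,
              score_cutoff = 10, rescore_half_width = 6L)
  mods <- list(...)
  cfg[names(mods)] <- mods
  cfg
}

#' Generate a complete synthetic bundle with a planted truth manifest
#'
#' One call produces everything [run_pipeline()] consumes — genome
#' FASTA, gene-model GTF, variant VCF, per-mark/condition peak BEDs,
#' expression TSV, JASPAR motif file, TF/gene map — together with a
#' truth manifest sufficient to score recovery of every planted signal:
#' region categories, substitution classes, switch classes, the stable
#' set, differential genes, and the causal variants (epigenetically
#' stable, at a differentially up-regulated gene, with a planted
#' TF-binding gain). Causal variants are chosen so their genes are not
#' assigned to any other stable variant and no other stable variant's
#' gene is differentially expressed, making the planted causal set the
#' unique ground truth of the candidate stage.
#'
#' @param config bundle configuration from [sim_config()].
#' @param seed RNG seed; the single source for all randomness.
#' @param out_dir if non-NULL, write all files there.
#' @return list with genome, gene_models, variants, peaks, expr,
#'   tf_map, pfms, config, and \code{truth} (regions, switches,
#'   stable_ids, de, causal, count_plant, tf_plan).
#' @export
generate_bundle <- function(config = sim_config(), seed = 1, out_dir = NULL) {
  with_seed_maybe(seed)
  cfg <- config
  genome <- generate_genome(cfg$genome_length, cfg$gc)
  gm <- generate_gene_models(cfg$genome_length, cfg$n_genes,
                             cfg$noncoding_fraction)
  gv <- generate_variants(genome, gm, cfg$n_variants, cfg$region_weights,
                          cfg$spectrum, cfg$indel_fraction, cfg$flank)
  variants <- gv$variants
  assignments <- assign_nearest_tss(variants, gm)
  gene_of <- setNames(assignments$gene_id, assignments$variant_id)

  # causal variants: SNVs with clearance on both sides, pairwise
  # distinct genes not shared with any other variant's assignment
  ord <- order(variants$pos)
  gap_prev <- c(Inf, diff(variants$pos[ord]))
  gap_next <- c(diff(variants$pos[ord]), Inf)
  clear <- logical(nrow(variants))
  clear[ord] <- gap_prev >= cfg$clearance & gap_next >= cfg$clearance
  n_causal <- cfg$n_causal_promoter + cfg$n_causal_enhancer
  pool <- variants$variant_id[variants$vclass == "SNV" & clear]
  pool <- pool[!is.na(gene_of[pool])]
  pool <- sample(pool)
  pool <- pool[!duplicated(gene_of[pool])]      # pairwise distinct genes
  if (length(pool) < n_causal)
    stop("not enough clear SNVs for the causal plant")
  causal_ids <- pool[seq_len(n_causal)]
  causal_prom <- causal_ids[seq_len(cfg$n_causal_promoter)]
  causal_enh <- setdiff(causal_ids, causal_prom)
  causal_gene_set <- unname(gene_of[causal_ids])

  # the remaining stable variants must not share a nearest gene with a
  # causal variant, so stable-and-differential identifies exactly the
  # causal set
  plan <- cfg$switch_plan
  eligible <- setdiff(variants$variant_id[!gene_of %in% causal_gene_set],
                      causal_ids)
  n_prom <- plan$H3K4me3[["A->A"]] - cfg$n_causal_promoter
  n_enh <- plan$H3K27ac[["A->A"]] - cfg$n_causal_enhancer
  stopifnot(n_prom >= 0, n_enh >= 0, length(eligible) >= n_prom + n_enh)
  extra_stable <- sample(eligible, n_prom + n_enh)
  special <- list(
    list(mark = "H3K4me3", class = "A->A",
         ids = c(causal_prom, extra_stable[seq_len(n_prom)])),
    list(mark = "H3K27ac", class = "A->A",
         ids = c(causal_enh, extra_stable[n_prom + seq_len(n_enh)])))
  switches <- assign_switch_classes(variants, plan, special)
  stable_plan <- unique(switches$variant_id[
    (switches$mark == "H3K4me3" | switches$mark == "H3K27ac") &
      switches$class == "A->A"])
  peaks <- generate_peaks(variants, switches, cfg$genome_length,
                          cfg$conditions, cfg$n_background_peaks)

  # expression: causal genes up 4-fold; extra planted genes only among
  # genes not assigned to any stable variant (so stable & DE <=> causal)
  pfms <- toy_pfms()
  tf_map <- data.frame(tf_name = names(pfms),
                       gene_id = paste0(names(pfms), "_gene"),
                       stringsAsFactors = FALSE)
  tf_plan <- data.frame(gene_id = tf_map$gene_id,
                        expressed_1 = !tf_map$tf_name %in% c("TF06", "TF07"),
                        expressed_2 = tf_map$tf_name != "TF06",
                        stringsAsFactors = FALSE)
  causal_genes <- unname(gene_of[causal_ids])
  stable_genes <- unique(gene_of[stable_plan])
  all_genes <- c(unique(gm$transcripts$gene_id), tf_map$gene_id)
  de_named <- setNames(rep(cfg$causal_effect_log2, n_causal), causal_genes)
  free_genes <- setdiff(unique(gm$transcripts$gene_id), stable_genes)
  n_extra <- max(0L, round(cfg$de_fraction * length(all_genes)) - n_causal)
  extra <- if (n_extra > 0L && length(free_genes))
    sample(free_genes, min(n_extra, length(free_genes))) else character(0)
  de_named <- c(de_named, setNames(
    sample(c(-1, 1), length(extra), replace = TRUE) * cfg$effect_log2, extra))
  ge <- generate_expression(all_genes, de_genes = de_named, de_fraction = 0,
                            effect_log2 = cfg$effect_log2, reps = cfg$reps,
                            sigma_log2 = cfg$sigma_log2,
                            conditions = cfg$conditions, tf_plan = tf_plan)

  # TF-binding gain plants at the causal variants; PWMs must separate
  # alleles at the cutoff and be expressed in the induced condition
  pwms <- lapply(pfms, pfm_to_pwm)
  plantable <- c("TF03", "TF04", "TF05")
  causal_tf <- character(n_causal)
  for (i in seq_len(n_causal)) {
    v <- variants[variants$variant_id == causal_ids[i], , drop = FALSE]
    planted <- NULL
    for (tf in sample(plantable)) {
      planted <- tryCatch(
        plant_regulatory_variant(genome, pwms[[tf]], v, "gain",
                                 cfg$score_cutoff, cfg$rescore_half_width),
        error = function(e) NULL)
      if (!is.null(planted)) break
    }
    if (is.null(planted)) stop("could not plant a gain at ", causal_ids[i])
    genome <- planted$genome
    causal_tf[i] <- planted$tf_name
  }

  # count plant: the same TF gains a strong alt-allele site at
  # count_plant_n additional non-causal clear SNVs
  count_ids <- character(0)
  if (cfg$count_plant_n > 0L) {
    cp_pool <- setdiff(variants$variant_id[variants$vclass == "SNV" & clear],
                       causal_ids)
    count_ids <- sample(cp_pool, min(cfg$count_plant_n, length(cp_pool)))
    for (id in count_ids) {
      v <- variants[variants$variant_id == id, , drop = FALSE]
      planted <- plant_regulatory_variant(genome, pwms[[cfg$count_plant_tf]],
                                          v, "gain", cfg$score_cutoff,
                                          cfg$rescore_half_width)
      genome <- planted$genome
    }
  }

  # sanity: every variant's ref allele must still match the genome
  for (i in seq_len(nrow(variants))) {
    obs <- substr(genome[[1]], variants$pos[i],
                  variants$pos[i] + nchar(variants$ref[i]) - 1L)
    if (obs != variants$ref[i])
      stop("internal error: plant disturbed variant ", variants$variant_id[i])
  }

  truth <- list(
    regions = gv$truth,
    switches = switches,
    stable_ids = stable_plan,
    de = ge$truth,
    causal = data.frame(variant_id = causal_ids,
                        gene_id = causal_genes,
                        tf_name = causal_tf,
                        mark = c(rep("H3K4me3", cfg$n_causal_promoter),
                                 rep("H3K27ac", cfg$n_causal_enhancer)),
                        stringsAsFactors = FALSE),
    count_plant = list(tf_name = cfg$count_plant_tf, variant_ids = count_ids),
    tf_plan = tf_plan)

  bundle <- list(genome = genome, gene_models = gm, variants = variants,
                 peaks = peaks, expr = ge$expr, tf_map = tf_map, pfms = pfms,
                 config = cfg, truth = truth)
  if (!is.null(out_dir)) write_bundle(bundle, out_dir, seed = seed)
  bundle
}

#' Write a generated bundle to disk in the pipeline's input layout
#'
#' @param bundle output of [generate_bundle()].
#' @param out_dir target directory (created if needed).
#' @param seed recorded in the truth manifest.
#' @return the directory, invisibly.
#' @export
write_bundle <- function(bundle, out_dir, seed = NA) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(out_dir, f)
  write_fasta(bundle$genome, p("genome.fa"))
  write_gtf(bundle$gene_models, p("genes.gtf"))
  write_vcf(bundle$variants, p("variants.vcf"),
            contigs = setNames(nchar(bundle$genome), names(bundle$genome)))
  pk <- bundle$peaks
  for (mk in unique(pk$mark)) for (cd in unique(pk$condition)) {
    sel <- pk[pk$mark == mk & pk$condition == cd, , drop = FALSE]
    write_peaks(sel, p(sprintf("peaks_%s_%s.bed", mk, cd)))
  }
  write_expression(bundle$expr, p("expression.tsv"))
  write_jaspar(bundle$pfms, p("motifs.jaspar"))
  utils::write.table(bundle$tf_map, p("tf_map.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  tr <- bundle$truth
  utils::write.table(tr$regions, p("truth_regions.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(tr$switches, p("truth_switches.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(tr$causal, p("truth_causal.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  jsonlite::write_json(
    list(seed = seed, stable_ids = tr$stable_ids,
         causal = tr$causal, de = tr$de,
         count_plant = tr$count_plant),
    p("truth.json"), auto_unbox = TRUE, pretty = TRUE)
  invisible(out_dir)
}
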