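DNA_BASES <- c("A", "C", "G", "T")

encode_dna <- function(sequence) {
  match(strsplit(toupper(sequence), "")[[1]], DNA_BASES)
}

#' Convert a position frequency matrix to a log-odds PWM
#'
#' Column counts are turned into probabilities with an additive
#' pseudocount, p = (count + pseudocount) / (colsum + 4 * pseudocount),
#' and weights are natural-log odds against the background,
#' w = ln(p / bg). The default background is flat (0.25 each); a
#' genome-derived background may be supplied instead.
#'
#' @param pfm a PFM (list with tf_name and 4 x w counts matrix).
#' @param pseudocount positive additive pseudocount (default 0.5).
#' @param background length-4 probability vector over A,C,G,T summing
#'   to 1; NULL for flat.
#' @return a PWM: list with tf_name, 4 x w weights matrix (rownames
#'   A,C,G,T), background, pseudocount.
#' @export
pfm_to_pwm <- function(pfm, pseudocount = 0.5, background = NULL) {
  stopifnot(pseudocount > 0)
  bg <- background %||% rep(0.25, 4)
  if (length(bg) != 4L || any(bg <= 0))
    stop("background must be 4 positive probabilities")
  if (abs(sum(bg) - 1) > 1e-9) stop("background must sum to 1")
  counts <- pfm$counts
  p <- sweep(counts + pseudocount, 2, colSums(counts) + 4 * pseudocount, "/")
  w <- log(p / bg)
  rownames(w) <- DNA_BASES
  list(tf_name = pfm$tf_name, weights = w,
       background = bg, pseudocount = pseudocount)
}

#' Consensus sequence of a PWM
#'
#' The per-column argmax base (ties to the earlier base in A,C,G,T
#' order); by construction it attains the PWM's maximum possible score.
#'
#' @param pwm a PWM.
#' @return character consensus string of the motif width.
#' @export
consensus_sequence <- function(pwm) {
  paste(DNA_BASES[apply(pwm$weights, 2, which.max)], collapse = "")
}

# Score every offset of an encoded sequence against a weights matrix.
# Windows containing N (NA codes) score -Inf.
scan_scores <- function(enc, weights) {
  w <- ncol(weights)
  n_off <- length(enc) - w + 1L
  if (n_off < 1L) return(numeric(0))
  idx <- outer(seq_len(n_off) - 1L, seq_len(w), "+")   # n_off x w positions
  val <- matrix(weights[cbind(as.vector(enc[idx]), rep(seq_len(w), each = n_off))],
                nrow = n_off)
  sc <- rowSums(val)
  sc[is.na(sc)] <- -Inf
  sc
}

#' Best motif hit of a PWM in a sequence
#'
#' Scores every offset on both strands (the minus strand scores the
#' reverse complement of the window) and returns the maximum. Ties are
#' broken toward the smallest offset, then the + strand.
#'
#' @param pwm a PWM.
#' @param sequence character DNA string.
#' @return list with tf_name, offset (0-based within the sequence),
#'   strand ("+"/"-"), score; or NULL when the sequence is shorter than
#'   the motif.
#' @export
scan_best_hit <- function(pwm, sequence) {
  w <- ncol(pwm$weights)
  if (nchar(sequence) < w) return(NULL)
  enc <- encode_dna(sequence)
  fwd <- scan_scores(enc, pwm$weights)
  # minus strand: complement rows (A<->T, C<->G) and reverse columns,
  # so rc_weights scored on the forward bases equals scoring the
  # reverse complement of each window with the original PWM
  rc_w <- pwm$weights[c(4L, 3L, 2L, 1L), rev(seq_len(w)), drop = FALSE]
  rev_ <- scan_scores(enc, rc_w)
  best <- max(fwd, rev_)
  if (!is.finite(best)) return(NULL)
  off <- which(pmax(fwd, rev_) == best)[1L]
  strand <- if (fwd[off] >= rev_[off]) "+" else "-"
  list(tf_name = pwm$tf_name, offset = off - 1L, strand = strand, score = best)
}

#' Extract reference- and alternate-allele windows around a variant
#'
#' The reference window covers the 1-based genomic interval
#' [pos - half_width, pos + half_width - 1] (length 2 * half_width),
#' truncated at contig edges with a flag. The genome must carry the
#' variant's reference allele at pos (a mismatch is an error). The
#' alternate window is the reference window with ref spliced to alt, so
#' its length differs for indels; with \code{pad = TRUE} it is re-padded
#' from the genome on the right to the nominal width so scans stay
#' comparable near motif-width boundaries.
#'
#' @param genome named character vector of contig sequences.
#' @param variant one-row variants data frame.
#' @param half_width half window width in bp (150-bp windows at the
#'   default cohort setting of 75; 12-bp at the rescore setting of 6).
#' @param pad re-pad indel alt windows to the nominal width.
#' @return list with variant_id, ref_window, alt_window, offset of the
#'   allele anchor within the window (1-based), truncated and padded
#'   flags.
#' @export
extract_allele_windows <- function(genome, variant, half_width = 75L, pad = FALSE) {
  stopifnot(nrow(variant) == 1L)
  chrom <- variant$chrom
  if (!chrom %in% names(genome)) stop("contig not in genome: ", chrom)
  seqs <- genome[[chrom]]
  L <- nchar(seqs)
  pos <- variant$pos
  ref <- variant$ref; alt <- variant$alt
  if (pos + nchar(ref) - 1L > L) stop("variant runs off the contig end")
  obs <- substr(seqs, pos, pos + nchar(ref) - 1L)
  if (obs != ref)
    stop("reference mismatch at ", chrom, ":", pos, " (genome ", obs,
         ", variant ref ", ref, ")")
  a <- max(1L, pos - half_width)
  b <- min(L, pos + half_width - 1L)
  truncated <- (a != pos - half_width) || (b != pos + half_width - 1L)
  ref_window <- substr(seqs, a, b)
  anchor <- pos - a + 1L
  alt_window <- paste0(substr(ref_window, 1L, anchor - 1L), alt,
                       substr(ref_window, anchor + nchar(ref), nchar(ref_window)))
  padded <- FALSE
  deficit <- nchar(ref_window) - nchar(alt_window)
  if (pad && deficit > 0L && b < L) {
    extra <- substr(seqs, b + 1L, min(L, b + deficit))
    alt_window <- paste0(alt_window, extra)
    padded <- TRUE
  }
  list(variant_id = variant$variant_id, ref_window = ref_window,
       alt_window = alt_window, anchor = anchor,
       truncated = truncated, padded = padded)
}

#' Allele-specific best-hit score difference for one PWM
#'
#' Scores both allele windows with [scan_best_hit()]; the reported
#' difference is score_alt - score_ref, so positive values mean the
#' alternate allele (the induced genome) gains predicted binding
#' affinity.
#'
#' @param pwm a PWM.
#' @param windows output of [extract_allele_windows()].
#' @return data frame row with tf_name, score_ref, score_alt, diff,
#'   offsets and strands of the best hit per allele (NA when no hit).
#' @export
allele_delta <- function(pwm, windows) {
  hr <- scan_best_hit(pwm, windows$ref_window)
  ha <- scan_best_hit(pwm, windows$alt_window)
  data.frame(
    variant_id = windows$variant_id, tf_name = pwm$tf_name,
    score_ref = if (is.null(hr)) NA_real_ else hr$score,
    score_alt = if (is.null(ha)) NA_real_ else ha$score,
    diff = if (is.null(hr) || is.null(ha)) NA_real_ else ha$score - hr$score,
    offset_ref = if (is.null(hr)) NA_integer_ else hr$offset,
    strand_ref = if (is.null(hr)) NA_character_ else hr$strand,
    offset_alt = if (is.null(ha)) NA_integer_ else ha$offset,
    strand_alt = if (is.null(ha)) NA_character_ else ha$strand,
    stringsAsFactors = FALSE)
}

#' Transcription factors expressed above a TPM cutoff
#'
#' A motif is only biologically meaningful when the TF's gene is
#' expressed in the cell; the gate is mean TPM over replicates >=
#' \code{tpm_cutoff} (inclusive) in the given condition.
#'
#' @param expr long expression data frame.
#' @param condition condition to evaluate.
#' @param tf_map data frame mapping tf_name to gene_id (exact ids, no
#'   fuzzy matching).
#' @param tpm_cutoff inclusive mean-TPM threshold (default 3).
#' @return character vector of TF names passing the gate.
#' @export
expressed_tfs <- function(expr, condition, tf_map, tpm_cutoff = 3) {
  stopifnot(all(c("tf_name", "gene_id") %in% names(tf_map)))
  d <- expr[expr$condition == condition & expr$gene_id %in% tf_map$gene_id, ,
            drop = FALSE]
  mu <- tapply(d$tpm, d$gene_id, mean)
  ok_genes <- names(mu)[mu >= tpm_cutoff]
  sort(unique(tf_map$tf_name[tf_map$gene_id %in% ok_genes]))
}

#' Per-TF counts of variant windows with a strong motif hit
#'
#' For each PWM, counts the variant windows (built with the chosen
#' allele: the reference allele stands for the stem genome, the
#' alternate for the induced genome) whose best hit reaches
#' \code{score_cutoff}.
#'
#' @param variants variants data frame.
#' @param genome named character vector of contig sequences.
#' @param pwms list of PWMs.
#' @param allele "ref" or "alt".
#' @param half_width window half-width in bp (default 75).
#' @param score_cutoff minimum best-hit score (default 10).
#' @return named integer vector of counts per TF.
#' @export
strong_hit_counts <- function(variants, genome, pwms, allele = c("ref", "alt"),
                              half_width = 75L, score_cutoff = 10) {
  allele <- match.arg(allele)
  wins <- lapply(seq_len(nrow(variants)), function(i)
    extract_allele_windows(genome, variants[i, , drop = FALSE], half_width))
  seqs <- vapply(wins, function(w)
    if (allele == "ref") w$ref_window else w$alt_window, "")
  counts <- vapply(pwms, function(pwm) {
    sum(vapply(seqs, function(s) {
      h <- scan_best_hit(pwm, s)
      !is.null(h) && h$score >= score_cutoff
    }, logical(1)))
  }, integer(1))
  setNames(as.integer(counts),
           vapply(pwms, `[[`, "", "tf_name"))
}

#' TFs whose strong-hit counts differ between the two genomes
#'
#' Applies the combined filter: TF expressed (caller supplies the gated
#' set), and |count_ref - count_alt| >= \code{min_count_diff}. The
#' signed difference is count_alt - count_ref.
#'
#' @param counts_ref,counts_alt named count vectors over the same TF
#'   universe (from [strong_hit_counts()]).
#' @param expressed_set character vector of expressed TF names.
#' @param min_count_diff minimum absolute count difference (default 10).
#' @return data frame tf_name, count_ref, count_alt, diff, sorted by
#'   |diff| descending (ties by name).
#' @export
differential_tfs <- function(counts_ref, counts_alt, expressed_set,
                             min_count_diff = 10) {
  tfs <- names(counts_ref)
  stopifnot(setequal(tfs, names(counts_alt)))
  d <- data.frame(tf_name = tfs,
                  count_ref = as.integer(counts_ref[tfs]),
                  count_alt = as.integer(counts_alt[tfs]),
                  stringsAsFactors = FALSE)
  d$diff <- d$count_alt - d$count_ref
  d <- d[d$tf_name %in% expressed_set & abs(d$diff) >= min_count_diff, , drop = FALSE]
  d <- d[order(-abs(d$diff), d$tf_name), , drop = FALSE]
  rownames(d) <- NULL
  d
}

#' Top-k expressed TFs by strong-hit count
#'
#' @param counts named count vector (from [strong_hit_counts()]).
#' @param expressed_set character vector of expressed TF names.
#' @param k number of TFs to return (default 20).
#' @return data frame tf_name, count, ranked by count descending, ties
#'   by name; fewer than k rows when fewer TFs qualify.
#' @export
top_k_tfs <- function(counts, expressed_set, k = 20L) {
  d <- data.frame(tf_name = names(counts), count = as.integer(counts),
                  stringsAsFactors = FALSE)
  d <- d[d$tf_name %in% expressed_set, , drop = FALSE]
  d <- d[order(-d$count, d$tf_name), , drop = FALSE]
  d <- utils::head(d, k)
  rownames(d) <- NULL
  d
}
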