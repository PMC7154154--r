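#' Benjamini-Hochberg adjusted p-values
#'
#' Standard step-up false-discovery-rate adjustment (monotone, capped at
#' 1), delegated to \code{stats::p.adjust}.
#'
#' @param pvalues numeric vector in [0, 1]; NAs are propagated.
#' @return adjusted p-values.
#' @export
bh_adjust <- function(pvalues) {
  if (any(pvalues < 0 | pvalues > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(pvalues, method = "BH")
}

#' Per-gene differential expression between two conditions
#'
#' Two-sample t-test on log2(TPM + 1) per gene, with Benjamini-Hochberg
#' adjustment across all tested genes. The default pools the two group
#' variances (Student's t): with the 2-3 replicates typical of these
#' designs, per-gene variance estimates are too unstable for Welch's
#' df correction, which costs a large fraction of power — variance
#' pooling is the simple analogue of the moderated tests the field
#' uses at such replicate counts. Set \code{var_equal = FALSE} for
#' Welch's test. The fold change is 2^(mean log2(TPM+1) difference),
#' i.e. a ratio of geometric means of the pseudocounted TPM. Two
#' presets reflect the two threshold sets commonly used together:
#' \code{default} calls a gene at FC > fc_threshold (or <
#' 1/fc_threshold) and FDR < fdr_threshold; \code{strict} at raw
#' p <= 1e-5 and FC >= 4 (or <= 1/4). Genes with zero TPM in every
#' sample are reported as ns and excluded from testing; with a single
#' replicate per condition no p-values exist and calling is
#' fold-change-only (announced in a message).
#'
#' @param expr long expression data frame (gene_id, condition,
#'   replicate, tpm).
#' @param cond1 reference condition (e.g. the stem state).
#' @param cond2 comparison condition; fold changes are cond2 over cond1.
#' @param preset "default" or "strict".
#' @param fc_threshold fold-change threshold for the default preset.
#' @param fdr_threshold FDR threshold for the default preset.
#' @param var_equal pool group variances (default TRUE).
#' @return data frame with gene_id, mean_tpm_1, mean_tpm_2, log2fc,
#'   pvalue, fdr, direction in {up, down, ns}.
#' @export
differential_expression <- function(expr, cond1, cond2,
                                    preset = c("default", "strict"),
                                    fc_threshold = 2, fdr_threshold = 0.05,
                                    var_equal = TRUE) {
  preset <- match.arg(preset)
  e <- expr[expr$condition %in% c(cond1, cond2), , drop = FALSE]
  if (!all(c(cond1, cond2) %in% e$condition))
    stop("both conditions must be present in the expression table")
  genes <- sort(unique(e$gene_id))
  wide <- function(cond) {
    d <- e[e$condition == cond, , drop = FALSE]
    reps <- sort(unique(d$replicate))
    m <- matrix(NA_real_, length(genes), length(reps),
                dimnames = list(genes, reps))
    m[cbind(match(d$gene_id, genes), match(d$replicate, reps))] <- d$tpm
    m
  }
  m1 <- wide(cond1); m2 <- wide(cond2)
  l1 <- log2(m1 + 1); l2 <- log2(m2 + 1)
  n1 <- rowSums(!is.na(l1)); n2 <- rowSums(!is.na(l2))
  mu1 <- rowMeans(l1, na.rm = TRUE); mu2 <- rowMeans(l2, na.rm = TRUE)
  log2fc <- mu2 - mu1
  all_zero <- rowSums(m1, na.rm = TRUE) == 0 & rowSums(m2, na.rm = TRUE) == 0
  single_rep <- max(n1, na.rm = TRUE) < 2 || max(n2, na.rm = TRUE) < 2
  pvalue <- rep(NA_real_, length(genes))
  if (single_rep) {
    message("single replicate per condition: p-values unavailable, ",
            "differential calls are fold-change-only")
  } else {
    v1 <- apply(l1, 1, stats::var, na.rm = TRUE)
    v2 <- apply(l2, 1, stats::var, na.rm = TRUE)
    if (var_equal) {
      sp <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
      se2 <- sp * (1 / n1 + 1 / n2)
      df <- n1 + n2 - 2
    } else {
      se2 <- v1 / n1 + v2 / n2
      df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
    }
    tstat <- log2fc / sqrt(se2)
    ok <- is.finite(tstat) & is.finite(df) & df > 0 & !all_zero
    pvalue[ok] <- 2 * stats::pt(-abs(tstat[ok]), df[ok])
  }
  fdr <- rep(NA_real_, length(genes))
  tested <- !is.na(pvalue)
  fdr[tested] <- bh_adjust(pvalue[tested])
  fc <- 2^log2fc
  direction <- rep("ns", length(genes))
  if (preset == "default") {
    sig <- if (single_rep) rep(TRUE, length(genes)) else
      !is.na(fdr) & fdr < fdr_threshold
    hit <- sig & (fc > fc_threshold | fc < 1 / fc_threshold)
  } else {
    hit <- !is.na(pvalue) & pvalue <= 1e-5 & (fc >= 4 | fc <= 1 / 4)
  }
  hit <- hit & !all_zero
  direction[hit & log2fc > 0] <- "up"
  direction[hit & log2fc < 0] <- "down"
  data.frame(gene_id = genes,
             mean_tpm_1 = rowMeans(m1, na.rm = TRUE),
             mean_tpm_2 = rowMeans(m2, na.rm = TRUE),
             log2fc = log2fc, pvalue = pvalue, fdr = fdr,
             direction = direction, stringsAsFactors = FALSE,
             row.names = NULL)
}

#' Overlap of two gene sets with printed-style percentages
#'
#' @param set_a,set_b character vectors of gene ids (deduplicated).
#' @param denominator the set size used as the percentage denominator;
#'   defaults to |set_a|.
#' @return list with n_a, n_b, n_overlap, denominator, and pct_overlap
#'   (= 100 * n_overlap / denominator, rounded half-up to 2 decimals).
#' @export
target_set_overlap <- function(set_a, set_b, denominator = NULL) {
  a <- unique(set_a); b <- unique(set_b)
  ov <- length(intersect(a, b))
  den <- denominator %||% length(a)
  stopifnot(den > 0)
  list(n_a = length(a), n_b = length(b), n_overlap = ov,
       denominator = den,
       pct_overlap = round_half_up(100 * ov / den, 2))
}

#' Paired shift test over a target-gene set
#'
#' For each target gene, the per-condition expression summary is the
#' mean of log2(TPM + 1) over replicates; the test is a paired t-test of
#' cond2 against cond1 across genes, i.e. of the per-gene differences.
#'
#' @param target_genes character vector of gene ids; genes absent from
#'   the table are dropped (reported in a message).
#' @param expr long expression data frame.
#' @param cond1,cond2 condition labels; the shift is cond2 - cond1.
#' @return list with statistic, p.value, mean_shift, n_genes.
#' @export
paired_target_shift_test <- function(target_genes, expr, cond1, cond2) {
  target_genes <- unique(target_genes)
  mean_log <- function(cond) {
    d <- expr[expr$condition == cond & expr$gene_id %in% target_genes, , drop = FALSE]
    tapply(log2(d$tpm + 1), d$gene_id, mean)
  }
  a <- mean_log(cond1); b <- mean_log(cond2)
  common <- intersect(names(a), names(b))
  missing <- setdiff(target_genes, common)
  if (length(missing))
    message(length(missing), " target gene(s) absent from the expression table")
  if (length(common) < 2L) stop("need >= 2 target genes with expression in both conditions")
  d <- b[common] - a[common]
  if (stats::sd(d) == 0) {
    # degenerate: identical shift (incl. all-zero) across genes
    res <- list(statistic = if (all(d == 0)) 0 else sign(mean(d)) * Inf,
                p.value = if (all(d == 0)) 1 else 0)
  } else {
    tt <- stats::t.test(b[common], a[common], paired = TRUE)
    res <- list(statistic = unname(tt$statistic), p.value = tt$p.value)
  }
  c(res, list(mean_shift = mean(d), n_genes = length(common)))
}
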