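#' @import methods
NULL

REGION_CATEGORIES <- c("exonic", "UTR5", "UTR3", "intronic", "ncRNA_intronic",
                       "upstream", "downstream", "intergenic")

# Build labeled, precedence-ranked annotation intervals (1-based inclusive)
# for one set of gene models. Per transcript: UTR5/UTR3 first (they are
# subsets of exons), exon-minus-UTR as exonic, the rest of the span as
# intronic (ncRNA_intronic for noncoding biotypes), plus strand-aware
# 'flank'-bp upstream-of-TSS and downstream-of-TES windows.
annotation_intervals <- function(gene_models, flank = 1000L) {
  tx <- gene_models$transcripts
  pieces <- vector("list", nrow(tx))
  iv_of <- function(tab, id) {
    d <- tab[tab$transcript_id == id, , drop = FALSE]
    IRanges::IRanges(start = d$start, end = d$end)
  }
  for (i in seq_len(nrow(tx))) {
    t1 <- tx[i, ]
    ex <- iv_of(gene_models$exons, t1$transcript_id)
    u5 <- iv_of(gene_models$utr5, t1$transcript_id)
    u3 <- iv_of(gene_models$utr3, t1$transcript_id)
    span <- IRanges::IRanges(t1$start, t1$end)
    coding_ex <- IRanges::setdiff(ex, IRanges::union(u5, u3))
    introns <- IRanges::setdiff(span, ex)
    intron_cat <- if (t1$biotype == "noncoding") "ncRNA_intronic" else "intronic"
    if (t1$strand == "+") {
      up <- IRanges::IRanges(max(1L, t1$tss - flank), max(1L, t1$tss - 1L))
      dn <- IRanges::IRanges(t1$tes + 1L, t1$tes + flank)
      if (t1$tss == 1L) up <- IRanges::IRanges()
    } else {
      up <- IRanges::IRanges(t1$tss + 1L, t1$tss + flank)
      dn <- IRanges::IRanges(max(1L, t1$tes - flank), max(1L, t1$tes - 1L))
      if (t1$tes == 1L) dn <- IRanges::IRanges()
    }
    lab <- function(iv, category) {
      if (!length(iv)) return(NULL)
      data.frame(chrom = t1$chrom, start = IRanges::start(iv),
                 end = IRanges::end(iv), category = category,
                 gene_id = t1$gene_id, stringsAsFactors = FALSE)
    }
    pieces[[i]] <- rbind(lab(coding_ex, "exonic"), lab(u5, "UTR5"),
                         lab(u3, "UTR3"), lab(introns, intron_cat),
                         lab(up, "upstream"), lab(dn, "downstream"))
  }
  out <- do.call(rbind, pieces)
  out$rank <- match(out$category, REGION_CATEGORIES)
  out
}

#' Classify variants into genomic region categories
#'
#' Each variant (anchored at its first reference base, also for indels)
#' receives exactly one category with the fixed precedence
#' exonic > UTR5 > UTR3 > intronic > ncRNA_intronic > upstream >
#' downstream > intergenic. "upstream"/"downstream" mean within
#' \code{flank} bp of a TSS/TES in gene orientation; intronic positions
#' of noncoding-biotype transcripts are labeled ncRNA_intronic. Ties at
#' equal precedence across genes resolve to the lexicographically
#' smallest gene_id.
#'
#' @param variants variants data frame.
#' @param gene_models gene_models object.
#' @param flank up/downstream window size in bp (default 1000).
#' @return data frame with variant_id, category, gene_id (NA for
#'   intergenic).
#' @export
classify_variant_region <- function(variants, gene_models, flank = 1000L) {
  ann <- annotation_intervals(gene_models, flank = flank)
  n <- nrow(variants)
  category <- rep("intergenic", n)
  gene <- rep(NA_character_, n)
  known <- unique(ann$chrom)
  unknown <- setdiff(unique(variants$chrom), known)
  if (length(unknown))
    warning("no gene models on chromosome(s) ", paste(unknown, collapse = ","),
            "; variants there are intergenic")
  for (ch in intersect(unique(variants$chrom), known)) {
    vi <- which(variants$chrom == ch)
    a <- ann[ann$chrom == ch, , drop = FALSE]
    hits <- IRanges::findOverlaps(
      IRanges::IRanges(variants$pos[vi], width = 1L),
      IRanges::IRanges(a$start, a$end))
    if (!length(hits)) next
    hdf <- data.frame(q = S4Vectors::queryHits(hits),
                      rank = a$rank[S4Vectors::subjectHits(hits)],
                      gene = a$gene_id[S4Vectors::subjectHits(hits)])
    hdf <- hdf[order(hdf$q, hdf$rank, hdf$gene), , drop = FALSE]
    hdf <- hdf[!duplicated(hdf$q), , drop = FALSE]
    category[vi[hdf$q]] <- REGION_CATEGORIES[hdf$rank]
    gene[vi[hdf$q]] <- hdf$gene
  }
  data.frame(variant_id = variants$variant_id, category = category,
             gene_id = gene, stringsAsFactors = FALSE)
}

#' Genomic length of each region category
#'
#' Applies the same precedence as [classify_variant_region()] to compute
#' how many bases of the genome fall into each category; the intergenic
#' length is the remainder of the supplied total.
#'
#' @param gene_models gene_models object.
#' @param genome_lengths named vector of contig lengths.
#' @param flank up/downstream window size in bp.
#' @return named numeric vector of base counts per category.
#' @export
region_category_lengths <- function(gene_models, genome_lengths, flank = 1000L) {
  ann <- annotation_intervals(gene_models, flank = flank)
  out <- setNames(numeric(length(REGION_CATEGORIES)), REGION_CATEGORIES)
  for (ch in names(genome_lengths)) {
    a <- ann[ann$chrom == ch, , drop = FALSE]
    claimed <- IRanges::IRanges()
    for (k in seq_along(REGION_CATEGORIES)[-length(REGION_CATEGORIES)]) {
      cat_k <- REGION_CATEGORIES[k]
      iv <- IRanges::reduce(IRanges::IRanges(a$start[a$category == cat_k],
                                             a$end[a$category == cat_k]))
      iv <- IRanges::restrict(iv, start = 1L, end = as.integer(genome_lengths[[ch]]))
      iv <- IRanges::setdiff(iv, claimed)
      out[cat_k] <- out[cat_k] + sum(IRanges::width(iv))
      claimed <- IRanges::union(claimed, iv)
    }
    out["intergenic"] <- out["intergenic"] +
      genome_lengths[[ch]] - sum(IRanges::width(claimed))
  }
  out
}

#' Per-category fold enrichment of variant counts
#'
#' ratio_c = (n_c / N) / (L_c / L): the share of variants falling in a
#' category divided by the share of the genome the category occupies.
#' Categories with zero variants return 0.
#'
#' @param category_counts named vector of variant counts per category.
#' @param category_lengths named vector of genomic bp per category.
#' @param total_variants N; defaults to sum(category_counts).
#' @param total_length L; defaults to sum(category_lengths).
#' @return data frame with category, n, L, ratio.
#' @export
fold_enrichment <- function(category_counts, category_lengths,
                            total_variants = sum(category_counts),
                            total_length = sum(category_lengths)) {
  stopifnot(total_variants > 0, total_length > 0)
  cats <- names(category_counts)
  if (is.null(cats)) stop("category_counts must be named")
  L <- category_lengths[cats]
  if (any(is.na(L)) || any(L <= 0))
    stop("every category needs a positive genomic length")
  ratio <- ifelse(category_counts == 0, 0,
                  (category_counts / total_variants) / (L / total_length))
  data.frame(category = cats, n = as.numeric(category_counts), L = as.numeric(L),
             ratio = as.numeric(ratio), stringsAsFactors = FALSE, row.names = NULL)
}

#' Single-base substitution spectrum
#'
#' Counts SNVs by ordered substitution (ref>alt, 12 classes) or by the
#' strand-collapsed 6-class view in which complementary pairs are merged
#' (C>T with G>A, etc., keyed by the pyrimidine ref). Indels are ignored
#' with a message.
#'
#' @param variants variants data frame.
#' @param collapse if TRUE return the 6-class pyrimidine-keyed spectrum.
#' @return named integer vector of counts (all classes present, zeros
#'   kept).
#' @export
substitution_spectrum <- function(variants, collapse = FALSE) {
  snv <- variants[variants$vclass == "SNV", , drop = FALSE]
  n_dropped <- nrow(variants) - nrow(snv)
  if (n_dropped > 0) message(n_dropped, " indel(s) ignored in substitution spectrum")
  bases <- c("A", "C", "G", "T")
  classes12 <- unlist(lapply(bases, function(r)
    paste0(r, ">", setdiff(bases, r))))
  counts <- setNames(integer(12), classes12)
  if (nrow(snv)) {
    tab <- table(paste0(snv$ref, ">", snv$alt))
    counts[names(tab)] <- as.integer(tab)
  }
  if (!collapse) return(counts)
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  key6 <- vapply(classes12, function(cl) {
    r <- substr(cl, 1, 1); a <- substr(cl, 3, 3)
    if (r %in% c("C", "T")) cl else paste0(comp[r], ">", comp[a])
  }, "")
  out <- tapply(counts, key6, sum)
  out[sort(unique(key6))]
}

#' Assign variants to their nearest transcription start site
#'
#' Distance is signed in gene orientation: positive downstream of the
#' TSS (into the gene body), negative upstream. Ties in |distance| are
#' broken by the lexicographically smaller gene_id, then transcript_id.
#'
#' @param variants variants data frame.
#' @param gene_models gene_models object.
#' @return data frame with variant_id, gene_id, transcript_id, distance;
#'   variants on chromosomes without any gene get NA with a warning.
#' @export
assign_nearest_tss <- function(variants, gene_models) {
  tx <- gene_models$transcripts
  tx <- tx[order(tx$gene_id, tx$transcript_id), , drop = FALSE]
  n <- nrow(variants)
  gene <- rep(NA_character_, n); txid <- rep(NA_character_, n)
  dist <- rep(NA_real_, n)
  for (ch in unique(variants$chrom)) {
    vi <- which(variants$chrom == ch)
    tc <- tx[tx$chrom == ch, , drop = FALSE]
    if (!nrow(tc)) next
    for (i in vi) {
      p <- variants$pos[i]
      d_abs <- abs(p - tc$tss)
      j <- which(d_abs == min(d_abs))[1]   # tc pre-sorted by gene_id: tie rule
      gene[i] <- tc$gene_id[j]; txid[i] <- tc$transcript_id[j]
      dist[i] <- if (tc$strand[j] == "+") p - tc$tss[j] else tc$tss[j] - p
    }
  }
  if (anyNA(gene))
    warning(sum(is.na(gene)), " variant(s) on chromosomes without gene models")
  data.frame(variant_id = variants$variant_id, gene_id = gene,
             transcript_id = txid, distance = dist, stringsAsFactors = FALSE)
}

#' Binned variant counts around the nearest TSS
#'
#' Bins signed, orientation-aware distances to the nearest TSS into
#' \code{bin}-bp bins over [-half_window, half_window]; bins are
#' left-closed, right-open (the last bin closed). Variants farther than
#' half_window from every TSS are excluded, so the bins sum to the
#' number of variants inside the window.
#'
#' @param variants variants data frame.
#' @param gene_models gene_models object.
#' @param half_window window half-width in bp (default 2500).
#' @param bin bin width in bp (default 50).
#' @return data frame with bin_start, bin_end (distance coordinates) and
#'   count.
#' @export
tss_distance_profile <- function(variants, gene_models,
                                 half_window = 2500L, bin = 50L) {
  asg <- assign_nearest_tss(variants, gene_models)
  d <- asg$distance[!is.na(asg$distance)]
  d <- d[abs(d) <= half_window]
  breaks <- seq(-half_window, half_window, by = bin)
  counts <- if (length(d)) {
    as.integer(table(cut(d, breaks = breaks, right = FALSE, include.lowest = TRUE)))
  } else integer(length(breaks) - 1L)
  data.frame(bin_start = breaks[-length(breaks)], bin_end = breaks[-1],
             count = counts)
}
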