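#' Pipeline configuration with every threshold at its standard default
#'
#' @param flank up/downstream annotation window (bp).
#' @param scan_half_width half-width of the cohort motif-scan window
#'   (75, i.e. 150-bp windows).
#' @param rescore_half_width half-width of the candidate rescoring
#'   window (6, i.e. 12-bp windows).
#' @param score_cutoff motif-score threshold for a "strong" hit.
#' @param tpm_cutoff TF expression gate (mean TPM, inclusive).
#' @param min_count_diff minimum |strong-hit count difference| for a
#'   differential TF.
#' @param fc_threshold,fdr_threshold default differential-expression
#'   thresholds.
#' @param de_preset DE preset used for candidate selection ("default"
#'   or "strict").
#' @param conditions length-2 vector naming condition 1 (stem state)
#'   and condition 2 (induced state).
#' @param pseudocount,pwm_background PWM construction parameters.
#' @return named list of settings.
#' @export
varepi_config <- function(flank = 1000L, scan_half_width = 75L,
                          rescore_half_width = 6L, score_cutoff = 10,
                          tpm_cutoff = 3, min_count_diff = 10,
                          fc_threshold = 2, fdr_threshold = 0.05,
                          de_preset = "default",
                          conditions = c("stem", "induced"),
                          pseudocount = 0.5, pwm_background = NULL) {
  list(flank = flank, scan_half_width = scan_half_width,
       rescore_half_width = rescore_half_width, score_cutoff = score_cutoff,
       tpm_cutoff = tpm_cutoff, min_count_diff = min_count_diff,
       fc_threshold = fc_threshold, fdr_threshold = fdr_threshold,
       de_preset = de_preset, conditions = conditions,
       pseudocount = pseudocount, pwm_background = pwm_background)
}

#' Select candidate variants: epigenetically stable and at a
#' differentially expressed gene
#'
#' The integration step: a variant is a candidate when its local
#' promoter or enhancer state is active in both conditions (so the
#' expression change cannot be blamed on epigenetic alteration) and its
#' nearest-TSS gene is differentially expressed. The qualifying mark is
#' recorded as the "modification type" of the candidate.
#'
#' @param stable output of [select_epigenetically_stable()].
#' @param assignments output of [assign_nearest_tss()].
#' @param de_results output of [differential_expression()].
#' @param regions optional output of [classify_variant_region()];
#'   attaches the region category when given.
#' @return data frame with one row per candidate: variant_id, gene_id,
#'   distance, qualifying_mark, category (if regions given), log2fc,
#'   pvalue, fdr, direction.
#' @export
select_candidates <- function(stable, assignments, de_results, regions = NULL) {
  m <- merge(stable, assignments, by = "variant_id")
  m <- merge(m, de_results[, c("gene_id", "log2fc", "pvalue", "fdr", "direction")],
             by = "gene_id")
  m <- m[m$direction != "ns", , drop = FALSE]
  if (!is.null(regions))
    m <- merge(m, regions[, c("variant_id", "category")], by = "variant_id")
  m <- m[order(m$variant_id), , drop = FALSE]
  rownames(m) <- NULL
  m
}

#' Allele-aware TF binding gains at candidate variants
#'
#' For every expressed TF, rescans a short window (default 12 bp) around
#' each candidate with both alleles and keeps the TFs whose
#' alternate-allele best hit reaches \code{score_cutoff} — the gate is
#' on the alternate (induced-genome) score only, since the question is
#' which TFs can bind the induced allele. Results are sorted by score
#' difference (alt - ref) descending within each candidate.
#'
#' @param candidates output of [select_candidates()].
#' @param variants variants data frame (coordinates for the window
#'   extraction).
#' @param genome named character vector of contig sequences.
#' @param pwms list of PWMs.
#' @param expr long expression data frame (for the TF expression
#'   columns of the report).
#' @param tf_map tf_name/gene_id map.
#' @param config pipeline configuration ([varepi_config()]); uses
#'   rescore_half_width, score_cutoff, tpm_cutoff, conditions.
#' @param gate_condition condition whose expression gates the TF set;
#'   defaults to the induced condition (conditions[2]).
#' @return data frame with variant_id, tf_name, expr_cond1, expr_cond2
#'   (mean TPM of the TF gene), score_ref, score_alt, diff.
#' @export
annotate_tf_gains <- function(candidates, variants, genome, pwms, expr, tf_map,
                              config = varepi_config(),
                              gate_condition = NULL) {
  gate_condition <- gate_condition %||% config$conditions[2]
  tf_set <- expressed_tfs(expr, gate_condition, tf_map, config$tpm_cutoff)
  pwms_use <- Filter(function(p) p$tf_name %in% tf_set, pwms)
  mean_tpm <- function(cond, gene) {
    d <- expr[expr$condition == cond & expr$gene_id == gene, , drop = FALSE]
    if (!nrow(d)) NA_real_ else mean(d$tpm)
  }
  out <- list()
  for (i in seq_len(nrow(candidates))) {
    vid <- candidates$variant_id[i]
    v <- variants[variants$variant_id == vid, , drop = FALSE]
    wins <- extract_allele_windows(genome, v, config$rescore_half_width,
                                   pad = TRUE)
    rows <- do.call(rbind, lapply(pwms_use, allele_delta, windows = wins))
    if (is.null(rows)) next
    rows <- rows[!is.na(rows$score_alt) & rows$score_alt >= config$score_cutoff, ,
                 drop = FALSE]
    if (!nrow(rows)) next
    gene <- tf_map$gene_id[match(rows$tf_name, tf_map$tf_name)]
    rows$expr_cond1 <- vapply(gene, mean_tpm, 0, cond = config$conditions[1])
    rows$expr_cond2 <- vapply(gene, mean_tpm, 0, cond = config$conditions[2])
    rows <- rows[order(-rows$diff, rows$tf_name), , drop = FALSE]
    out[[vid]] <- rows[, c("variant_id", "tf_name", "expr_cond1", "expr_cond2",
                           "score_ref", "score_alt", "diff")]
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(variant_id = character(0), tf_name = character(0),
               expr_cond1 = numeric(0), expr_cond2 = numeric(0),
               score_ref = numeric(0), score_alt = numeric(0),
               diff = numeric(0), stringsAsFactors = FALSE)
  rownames(res) <- NULL
  res
}

#' Write the candidate report
#'
#' Emits two tab-separated files with a commented header line carrying
#' the package version and configuration hash: \code{candidates.tsv}
#' (variant, region, gene, modification type, DE statistics) and
#' \code{tf_gains.tsv} (per-TF allele scores, sorted by diff within a
#' candidate), plus \code{manifest.json} recording version, hash and
#' seed. Identical inputs produce byte-identical files.
#'
#' @param candidates output of [select_candidates()].
#' @param tf_gains output of [annotate_tf_gains()].
#' @param dir output directory (created if needed).
#' @param config pipeline configuration (hashed into the header).
#' @param seed seed recorded in the manifest (NA when none used).
#' @return the directory, invisibly.
#' @export
write_report <- function(candidates, tf_gains, dir, config = varepi_config(),
                         seed = NA) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ver <- as.character(utils::packageVersion("varepi"))
  hash <- config_hash(config)
  stamp <- sprintf("# varepi %s config=%s", ver, hash)
  emit <- function(df, path) {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(stamp, con)
    utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  emit(candidates, file.path(dir, "candidates.tsv"))
  emit(tf_gains, file.path(dir, "tf_gains.tsv"))
  jsonlite::write_json(
    list(tool = "varepi", version = ver, config_hash = hash, seed = seed,
         n_candidates = nrow(candidates)),
    file.path(dir, "manifest.json"), auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}

#' Read a report TSV back (skipping the comment stamp)
#'
#' @param path a TSV written by [write_report()].
#' @return data frame.
#' @export
read_report_tsv <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, comment.char = "#",
                    stringsAsFactors = FALSE)
}

#' Run the full pipeline on a data bundle
#'
#' Orchestrates every stage over a directory laid out like the output
#' of [generate_bundle()]: genome.fa, genes.gtf, variants.vcf,
#' peaks_<mark>_<condition>.bed, expression.tsv, motifs.jaspar,
#' tf_map.tsv. Stages: region classification and fold enrichment,
#' nearest-TSS assignment, epigenetic state calls and stable-variant
#' selection, differential expression, cohort motif scanning
#' (differential and top TFs), candidate selection and allele-aware TF
#' gain rescoring.
#'
#' @param bundle_dir input directory.
#' @param config pipeline configuration ([varepi_config()]).
#' @param out_dir if non-NULL, [write_report()] target.
#' @param seed recorded in the report manifest; the pipeline itself is
#'   deterministic.
#' @return list with variants, gene_models, regions, enrichment,
#'   assignments, states, stable, de, expressed_tfs (per condition),
#'   hit_counts_ref/alt, differential_tfs, top_tfs, candidates,
#'   tf_gains.
#' @export
run_pipeline <- function(bundle_dir, config = varepi_config(), out_dir = NULL,
                         seed = NA) {
  p <- function(f) file.path(bundle_dir, f)
  genome <- read_fasta(p("genome.fa"))
  gm <- read_gene_models(p("genes.gtf"))
  variants <- read_variants(p("variants.vcf"))
  expr <- read_expression(p("expression.tsv"))
  pfms <- read_jaspar(p("motifs.jaspar"))
  tf_map <- utils::read.table(p("tf_map.tsv"), sep = "\t", header = TRUE,
                              stringsAsFactors = FALSE)
  conds <- config$conditions
  peak_files <- list.files(bundle_dir, pattern = "^peaks_.*\\.bed$")
  peaks <- do.call(rbind, lapply(peak_files, function(f) {
    parts <- strsplit(sub("^peaks_(.*)\\.bed$", "\\1", f), "_")[[1]]
    read_peaks(p(f), mark = parts[1],
               condition = paste(parts[-1], collapse = "_"))
  }))

  regions <- classify_variant_region(variants, gm, flank = config$flank)
  glen <- setNames(nchar(genome), names(genome))
  lens <- region_category_lengths(gm, glen, flank = config$flank)
  counts <- table(factor(regions$category, levels = REGION_CATEGORIES))
  enrichment <- fold_enrichment(setNames(as.numeric(counts), names(counts)), lens)
  assignments <- assign_nearest_tss(variants, gm)
  states <- epi_state_table(variants, peaks, conditions = conds)
  stable <- select_epigenetically_stable(states)
  de <- differential_expression(expr, conds[1], conds[2],
                                preset = config$de_preset,
                                fc_threshold = config$fc_threshold,
                                fdr_threshold = config$fdr_threshold)
  pwms <- lapply(pfms, pfm_to_pwm, pseudocount = config$pseudocount,
                 background = config$pwm_background)
  tf1 <- expressed_tfs(expr, conds[1], tf_map, config$tpm_cutoff)
  tf2 <- expressed_tfs(expr, conds[2], tf_map, config$tpm_cutoff)
  hc_ref <- strong_hit_counts(variants, genome, pwms, "ref",
                              config$scan_half_width, config$score_cutoff)
  hc_alt <- strong_hit_counts(variants, genome, pwms, "alt",
                              config$scan_half_width, config$score_cutoff)
  dtf <- differential_tfs(hc_ref, hc_alt, union(tf1, tf2),
                          config$min_count_diff)
  top1 <- top_k_tfs(hc_ref, tf1)
  top2 <- top_k_tfs(hc_alt, tf2)
  candidates <- select_candidates(stable, assignments, de, regions)
  gains <- annotate_tf_gains(candidates, variants, genome, pwms, expr, tf_map,
                             config)
  if (!is.null(out_dir))
    write_report(candidates, gains, out_dir, config, seed)
  list(variants = variants, gene_models = gm, regions = regions,
       enrichment = enrichment, assignments = assignments, states = states,
       stable = stable, de = de,
       expressed_tfs = list(cond1 = tf1, cond2 = tf2),
       hit_counts_ref = hc_ref, hit_counts_alt = hc_alt,
       differential_tfs = dtf, top_tfs = list(cond1 = top1, cond2 = top2),
       candidates = candidates, tf_gains = gains)
}
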