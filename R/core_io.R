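#' Construct a validated variants table
#'
#' The canonical in-memory representation of called variants is a plain
#' data frame with one row per biallelic call. Indels follow the VCF
#' anchor-base convention: \code{ref} and \code{alt} share their first
#' base and \code{pos} is the 1-based position of that anchor.
#'
#' @param chrom chromosome names.
#' @param pos 1-based positions (anchor base for indels).
#' @param ref reference allele strings over A/C/G/T.
#' @param alt alternate allele strings over A/C/G/T.
#' @param pair_id identifier of the cell-line pair the call belongs to.
#' @return data frame with columns chrom, pos, ref, alt, vclass
#'   (SNV/INS/DEL), pair_id and a variant_id key.
#' @export
make_variants <- function(chrom, pos, ref, alt, pair_id = "pair1") {
  chrom <- as.character(chrom)
  ref <- toupper(as.character(ref))
  alt <- toupper(as.character(alt))
  pos <- as.integer(pos)
  if (any(pos < 1L)) stop("variant positions must be >= 1")
  if (any(ref == alt)) stop("ref and alt alleles must differ")
  bad <- grepl("[^ACGT]", ref) | grepl("[^ACGT]", alt)
  if (any(bad)) stop("alleles must be over {A,C,G,T}: ", ref[bad][1], ">", alt[bad][1])
  nr <- nchar(ref); na <- nchar(alt)
  vclass <- ifelse(nr == 1L & na == 1L, "SNV", ifelse(na > nr, "INS", "DEL"))
  indel <- vclass != "SNV"
  if (any(indel & substr(ref, 1, 1) != substr(alt, 1, 1)))
    stop("indels must share the anchor (first) base between ref and alt")
  out <- data.frame(
    chrom = chrom, pos = pos, ref = ref, alt = alt,
    vclass = vclass, pair_id = rep_len(as.character(pair_id), length(pos)),
    stringsAsFactors = FALSE
  )
  out$variant_id <- variant_id(out)
  out
}

#' Read a FASTA file into a named character vector
#'
#' @param path FASTA file.
#' @return named character vector of uppercased sequences; names are
#'   taken up to the first whitespace of each header.
#' @export
read_fasta <- function(path) {
  stopifnot(file.exists(path))
  if (file.size(path) == 0L) {
    warning("empty FASTA file: ", path)
    return(setNames(character(0), character(0)))
  }
  ss <- Biostrings::readBStringSet(path)   # validate the alphabet ourselves
  seqs <- toupper(as.character(ss))
  names(seqs) <- sub("\\s.*$", "", names(ss))
  bad <- grepl("[^ACGTN]", seqs)
  if (any(bad))
    stop("non-ACGTN characters in FASTA record: ", names(seqs)[bad][1])
  seqs
}

#' Write sequences to FASTA
#'
#' @param seqs named character vector of sequences.
#' @param path output file.
#' @param width line wrap width.
#' @return the path, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  ss <- Biostrings::DNAStringSet(seqs)
  names(ss) <- names(seqs)
  Biostrings::writeXStringSet(ss, path, width = width)
  invisible(path)
}

#' Read biallelic variant calls from a VCF
#'
#' Only CHROM/POS/REF/ALT/FILTER are consumed. Records whose FILTER is
#' neither PASS nor "." are dropped (the count is reported in a message),
#' mirroring the convention of retaining only PASS somatic calls.
#' Multiallelic records are rejected: paired-genome somatic callers emit
#' biallelic records, and silently splitting alleles hides errors.
#'
#' @param path VCF file (uncompressed or bgzipped).
#' @param pair_id pair label attached to every record.
#' @return variants data frame (see [make_variants()]).
#' @export
read_variants <- function(path, pair_id = "pair1") {
  stopifnot(file.exists(path))
  v <- suppressWarnings(vcfR::read.vcfR(path, verbose = FALSE))
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  fix <- as.data.frame(fix, stringsAsFactors = FALSE)
  if (nrow(fix) == 0L)
    return(make_variants(character(0), integer(0), character(0), character(0)))
  if (any(grepl(",", fix$ALT)))
    stop("multiallelic ALT records are not supported; split or drop them first")
  filt <- fix$FILTER
  keep <- is.na(filt) | filt %in% c("PASS", ".")
  if (any(!keep))
    message(sum(!keep), " non-PASS records dropped from ", basename(path))
  fix <- fix[keep, , drop = FALSE]
  make_variants(fix$CHROM, as.integer(fix$POS), fix$REF, fix$ALT, pair_id)
}

#' Write variants to a minimal VCF
#'
#' @param variants variants data frame.
#' @param path output file.
#' @param contigs optional named vector of contig lengths for the header.
#' @return the path, invisibly.
#' @export
write_vcf <- function(variants, path, contigs = NULL) {
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##source=varepi",
    if (!is.null(contigs))
      sprintf("##contig=<ID=%s,length=%d>", names(contigs), as.integer(contigs)),
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"
  )
  body <- sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\t.",
                  variants$chrom, variants$pos, variants$ref, variants$alt)
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read peak intervals from a BED3 or narrowPeak file
#'
#' Intervals are kept in their native 0-based half-open convention; the
#' overlap predicates in the state-calling module consume them directly.
#' When the file has the 10-column narrowPeak layout, column 7
#' (signalValue) is used as the peak score, otherwise score is 0.
#'
#' @param path BED-like file, >= 3 tab-separated columns.
#' @param mark mark label attached to every peak (e.g. "H3K4me3").
#' @param condition condition label (e.g. "stem", "induced").
#' @return data frame with chrom, start, end, mark, condition, score.
#' @export
read_peaks <- function(path, mark, condition) {
  stopifnot(file.exists(path))
  tab <- utils::read.table(path, sep = "\t", header = FALSE,
                           stringsAsFactors = FALSE, comment.char = "#")
  if (ncol(tab) < 3L) stop("peak file needs >= 3 columns: ", path)
  start <- as.integer(tab[[2]]); end <- as.integer(tab[[3]])
  if (any(start >= end))
    stop("inverted or empty interval (start >= end) in ", path)
  score <- if (ncol(tab) >= 7L) as.numeric(tab[[7]]) else 0
  make_peaks(as.character(tab[[1]]), start, end, mark, condition, score)
}

#' Construct a validated peaks table
#'
#' @param chrom,start,end interval coordinates, 0-based half-open.
#' @param mark,condition labels.
#' @param score non-negative peak score.
#' @return peaks data frame.
#' @export
make_peaks <- function(chrom, start, end, mark, condition, score = 0) {
  start <- as.integer(start); end <- as.integer(end)
  if (any(start >= end)) stop("peak intervals must satisfy start < end")
  if (any(score < 0)) stop("peak scores must be non-negative")
  n <- length(start)
  data.frame(chrom = as.character(chrom), start = start, end = end,
             mark = rep_len(as.character(mark), n),
             condition = rep_len(as.character(condition), n),
             score = rep_len(as.numeric(score), n),
             stringsAsFactors = FALSE)
}

#' Write peaks as a narrowPeak-style file
#'
#' Emits the 10-column ENCODE narrowPeak layout with the score in column
#' 7 so that [read_peaks()] round-trips it.
#'
#' @param peaks peaks data frame.
#' @param path output file.
#' @return the path, invisibly.
#' @export
write_peaks <- function(peaks, path) {
  n <- nrow(peaks)
  lines <- sprintf("%s\t%d\t%d\tpeak%d\t0\t.\t%g\t-1\t-1\t-1",
                   peaks$chrom, peaks$start, peaks$end, seq_len(max(n, 0)),
                   peaks$score)
  writeLines(lines, path)
  invisible(path)
}

#' Read transcript models from a GTF file
#'
#' One model per transcript. The TSS is the 5' end in gene orientation
#' (leftmost coordinate on "+", rightmost on "-"), the TES the 3' end.
#' UTR features are recognised under the Ensembl-style types
#' \code{five_prime_utr} / \code{three_prime_utr}. Transcripts without
#' any exon feature are skipped with a warning.
#'
#' @param path GTF file.
#' @return a \code{gene_models} object: a list of data frames
#'   \code{transcripts} (transcript_id, gene_id, gene_name, chrom,
#'   strand, start, end, tss, tes, biotype), \code{exons}, \code{utr5},
#'   \code{utr3} (transcript_id, start, end), class "gene_models".
#' @export
read_gene_models <- function(path) {
  stopifnot(file.exists(path))
  gr <- rtracklayer::import(path, format = "gtf")
  df <- as.data.frame(gr, stringsAsFactors = FALSE)
  df$seqnames <- as.character(df$seqnames)
  df$strand <- as.character(df$strand)
  ex <- df[df$type == "exon", , drop = FALSE]
  if (nrow(ex) == 0L) stop("no exon features in GTF: ", path)
  tx_ids <- unique(ex$transcript_id)
  tx_rows <- df[df$type == "transcript" & df$transcript_id %in% tx_ids, , drop = FALSE]
  no_exon <- setdiff(unique(df$transcript_id[df$type == "transcript"]), tx_ids)
  no_exon <- no_exon[!is.na(no_exon)]
  if (length(no_exon))
    warning(length(no_exon), " transcript(s) without exons skipped")
  if (nrow(tx_rows) == 0L) {
    # no explicit transcript features: derive spans from the exons
    sp <- split(ex, ex$transcript_id)
    tx_rows <- do.call(rbind, lapply(sp, function(d) {
      d1 <- d[1, , drop = FALSE]
      d1$start <- min(d$start); d1$end <- max(d$end)
      d1
    }))
  }
  biotype_col <- intersect(c("transcript_biotype", "gene_biotype", "transcript_type",
                             "gene_type"), names(df))
  bt <- if (length(biotype_col)) tx_rows[[biotype_col[1]]] else rep(NA, nrow(tx_rows))
  bt <- ifelse(is.na(bt) | bt %in% c("protein_coding", "coding"), "coding", "noncoding")
  gname <- if ("gene_name" %in% names(tx_rows)) tx_rows$gene_name else tx_rows$gene_id
  gname[is.na(gname)] <- tx_rows$gene_id[is.na(gname)]
  transcripts <- data.frame(
    transcript_id = tx_rows$transcript_id,
    gene_id = tx_rows$gene_id,
    gene_name = gname,
    chrom = tx_rows$seqnames,
    strand = tx_rows$strand,
    start = tx_rows$start, end = tx_rows$end,
    tss = ifelse(tx_rows$strand == "-", tx_rows$end, tx_rows$start),
    tes = ifelse(tx_rows$strand == "-", tx_rows$start, tx_rows$end),
    biotype = bt,
    stringsAsFactors = FALSE
  )
  rownames(transcripts) <- NULL
  iv <- function(type_names) {
    d <- df[df$type %in% type_names, c("transcript_id", "start", "end"), drop = FALSE]
    rownames(d) <- NULL
    d[order(d$transcript_id, d$start), , drop = FALSE]
  }
  out <- list(transcripts = transcripts,
              exons = iv("exon"),
              utr5 = iv(c("five_prime_utr", "5UTR")),
              utr3 = iv(c("three_prime_utr", "3UTR")))
  class(out) <- "gene_models"
  validate_gene_models(out)
}

#' Construct a gene_models object from its component tables
#'
#' @param transcripts data frame with transcript_id, gene_id, chrom,
#'   strand, start, end, biotype (gene_name, tss, tes filled in when
#'   absent).
#' @param exons data frame with transcript_id, start, end.
#' @param utr5,utr3 optional UTR interval tables (same columns as
#'   exons).
#' @return a validated \code{gene_models} object.
#' @export
make_gene_models <- function(transcripts, exons, utr5 = NULL, utr3 = NULL) {
  if (is.null(transcripts$gene_name)) transcripts$gene_name <- transcripts$gene_id
  if (is.null(transcripts$tss))
    transcripts$tss <- ifelse(transcripts$strand == "-", transcripts$end,
                              transcripts$start)
  if (is.null(transcripts$tes))
    transcripts$tes <- ifelse(transcripts$strand == "-", transcripts$start,
                              transcripts$end)
  empty <- data.frame(transcript_id = character(0), start = integer(0),
                      end = integer(0), stringsAsFactors = FALSE)
  out <- list(transcripts = transcripts,
              exons = exons[order(exons$transcript_id, exons$start), , drop = FALSE],
              utr5 = utr5 %||% empty, utr3 = utr3 %||% empty)
  class(out) <- "gene_models"
  validate_gene_models(out)
}

validate_gene_models <- function(gm) {
  sp <- split(gm$exons, gm$exons$transcript_id)
  for (d in sp) {
    if (nrow(d) > 1L && any(d$start[-1] <= d$end[-nrow(d)]))
      stop("overlapping or unsorted exons in transcript ", d$transcript_id[1])
  }
  gm
}

#' @export
print.gene_models <- function(x, ...) {
  cat("gene_models:", nrow(x$transcripts), "transcripts,",
      length(unique(x$transcripts$gene_id)), "genes,",
      nrow(x$exons), "exons\n")
  invisible(x)
}

#' Write gene models to GTF
#'
#' @param gene_models a \code{gene_models} object.
#' @param path output file.
#' @param source source field for column 2.
#' @return the path, invisibly.
#' @export
write_gtf <- function(gene_models, path, source = "varepi") {
  tx <- gene_models$transcripts
  feat <- function(type, chrom, start, end, strand, gene_id, tx_id, biotype) {
    sprintf(
      '%s\t%s\t%s\t%d\t%d\t.\t%s\t.\tgene_id "%s"; transcript_id "%s"; gene_name "%s"; transcript_biotype "%s";',
      chrom, source, type, as.integer(start), as.integer(end), strand,
      gene_id, tx_id, gene_id, biotype)
  }
  lines <- character(0)
  for (i in seq_len(nrow(tx))) {
    t1 <- tx[i, ]
    lines <- c(lines,
               feat("transcript", t1$chrom, t1$start, t1$end, t1$strand,
                    t1$gene_id, t1$transcript_id, t1$biotype))
    for (tab_name in c("exons", "utr5", "utr3")) {
      type <- c(exons = "exon", utr5 = "five_prime_utr",
                utr3 = "three_prime_utr")[[tab_name]]
      d <- gene_models[[tab_name]]
      d <- d[d$transcript_id == t1$transcript_id, , drop = FALSE]
      if (nrow(d))
        lines <- c(lines, feat(type, t1$chrom, d$start, d$end, t1$strand,
                               t1$gene_id, t1$transcript_id, t1$biotype))
    }
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read a TPM expression table
#'
#' Expected layout: a header line \code{gene_id<TAB>cond:rep...}, one row
#' per gene, TPM values in the body. Returned long so that downstream
#' code never has to parse column names again.
#'
#' @param path tab-separated file.
#' @return data frame with gene_id, condition, replicate, tpm.
#' @export
read_expression <- function(path) {
  stopifnot(file.exists(path))
  tab <- utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                           stringsAsFactors = FALSE, comment.char = "#")
  if (names(tab)[1] != "gene_id") stop("first column must be gene_id")
  samples <- names(tab)[-1]
  parts <- strsplit(samples, ":", fixed = TRUE)
  if (any(lengths(parts) != 2L))
    stop("sample columns must be named condition:replicate")
  long <- data.frame(
    gene_id = rep(tab$gene_id, times = length(samples)),
    condition = rep(vapply(parts, `[`, "", 1L), each = nrow(tab)),
    replicate = rep(vapply(parts, `[`, "", 2L), each = nrow(tab)),
    tpm = as.numeric(unlist(tab[-1], use.names = FALSE)),
    stringsAsFactors = FALSE
  )
  if (any(is.na(long$tpm)) || any(long$tpm < 0)) stop("TPM values must be >= 0")
  key <- paste(long$gene_id, long$condition, long$replicate)
  if (anyDuplicated(key)) stop("duplicate (gene, condition, replicate) records")
  long
}

#' Write a long expression table in the wide TSV layout
#'
#' @param expr long expression data frame.
#' @param path output file.
#' @return the path, invisibly.
#' @export
write_expression <- function(expr, path) {
  sample <- paste(expr$condition, expr$replicate, sep = ":")
  wide <- stats::reshape(
    data.frame(gene_id = expr$gene_id, sample = sample, tpm = expr$tpm,
               stringsAsFactors = FALSE),
    idvar = "gene_id", timevar = "sample", direction = "wide")
  names(wide) <- sub("^tpm\\.", "", names(wide))
  utils::write.table(wide, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a motif library in JASPAR PFM text format
#'
#' Format: a header line \code{>ID NAME}, then four rows like
#' \code{A  [ 3 10 0 ]}. Rows may appear in any base order; counts are
#' returned with rows in canonical A,C,G,T order.
#'
#' @param path JASPAR-format text file.
#' @return named list of PFMs, each a list with \code{tf_name} and a
#'   4 x w \code{counts} matrix (rownames A,C,G,T).
#' @export
read_jaspar <- function(path) {
  stopifnot(file.exists(path))
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  hdr_i <- grep("^>", lines)
  if (!length(hdr_i)) stop("no motif headers ('>') found in ", path)
  bounds <- c(hdr_i, length(lines) + 1L)
  pfms <- list()
  for (k in seq_along(hdr_i)) {
    block <- lines[(bounds[k] + 1L):(bounds[k + 1L] - 1L)]
    hdr <- sub("^>\\s*", "", lines[hdr_i[k]])
    toks <- strsplit(hdr, "\\s+")[[1]]
    name <- if (length(toks) >= 2L) toks[2] else toks[1]
    rows <- list()
    for (b in block) {
      base <- toupper(sub("^\\s*([ACGTacgt]).*$", "\\1", b))
      body <- sub("^\\s*[ACGTacgt]", "", b)
      nums <- regmatches(body, gregexpr("[0-9.eE+-]+", body))[[1]]
      rows[[base]] <- as.numeric(nums)
    }
    missing <- setdiff(c("A", "C", "G", "T"), names(rows))
    if (length(missing))
      stop("motif ", name, " missing base row(s): ", paste(missing, collapse = ","))
    if (length(unique(lengths(rows[c("A", "C", "G", "T")]))) != 1L)
      stop("motif ", name, " has rows of unequal width")
    counts <- do.call(rbind, rows[c("A", "C", "G", "T")])
    rownames(counts) <- c("A", "C", "G", "T")
    if (any(counts < 0)) stop("negative counts in motif ", name)
    if (any(colSums(counts) <= 0)) stop("zero column sum in motif ", name)
    pfms[[name]] <- list(tf_name = name, counts = counts)
  }
  pfms
}

#' Write PFMs in JASPAR text format
#'
#' @param pfms list of PFMs as returned by [read_jaspar()].
#' @param path output file.
#' @return the path, invisibly.
#' @export
write_jaspar <- function(pfms, path) {
  lines <- unlist(lapply(pfms, function(p) {
    c(paste0(">", p$tf_name, " ", p$tf_name),
      vapply(c("A", "C", "G", "T"), function(b) {
        paste0(b, "  [ ", paste(format(p$counts[b, ], trim = TRUE), collapse = " "), " ]")
      }, ""))
  }))
  writeLines(lines, path)
  invisible(path)
}
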