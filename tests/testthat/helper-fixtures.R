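# Deterministic hand-built fixtures plus a cached default bundle so the
# expensive end-to-end objects are generated once per test run.

# two genes on "chrF": plus-strand coding with UTRs, minus-strand
# noncoding; layout chosen so every region category is reachable
fixture_gene_models <- function() {
  tx <- data.frame(
    transcript_id = c("GA.t1", "GB.t1"),
    gene_id = c("GA", "GB"),
    chrom = "chrF",
    strand = c("+", "-"),
    start = c(5000L, 20000L),
    end = c(9000L, 24000L),
    biotype = c("coding", "noncoding"),
    stringsAsFactors = FALSE)
  exons <- data.frame(
    transcript_id = c("GA.t1", "GA.t1", "GA.t1", "GB.t1", "GB.t1"),
    start = c(5000L, 6500L, 8500L, 20000L, 23000L),
    end = c(5400L, 6900L, 9000L, 20500L, 24000L),
    stringsAsFactors = FALSE)
  utr5 <- data.frame(transcript_id = "GA.t1", start = 5000L, end = 5099L,
                     stringsAsFactors = FALSE)
  utr3 <- data.frame(transcript_id = "GA.t1", start = 8900L, end = 9000L,
                     stringsAsFactors = FALSE)
  make_gene_models(tx, exons, utr5, utr3)
}

fixture_variants <- function() {
  make_variants(
    chrom = "chrF",
    pos = c(5050, 5200, 6000, 8950, 4500, 9500, 21000, 12000, 23900),
    ref = c("A", "C", "G", "T", "A", "C", "G", "T", "A"),
    alt = c("G", "T", "A", "C", "G", "T", "A", "C", "G"))
}

.bundle_cache <- new.env(parent = emptyenv())

# default-scale bundle under a fixed seed, built once
default_bundle <- function() {
  if (is.null(.bundle_cache$b)) {
    .bundle_cache$dir <- file.path(tempdir(), "varepi-bundle")
    .bundle_cache$b <- generate_bundle(sim_config(), seed = 202,
                                       out_dir = .bundle_cache$dir)
  }
  .bundle_cache$b
}

default_bundle_dir <- function() {
  default_bundle()
  .bundle_cache$dir
}

default_pipeline <- function() {
  if (is.null(.bundle_cache$res))
    .bundle_cache$res <- suppressWarnings(suppressMessages(
      run_pipeline(default_bundle_dir())))
  .bundle_cache$res
}

random_pwm <- function(width, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  counts <- matrix(stats::rpois(4 * width, 5) + 0.1, nrow = 4,
                   dimnames = list(c("A", "C", "G", "T"), NULL))
  pfm_to_pwm(list(tf_name = "RND", counts = counts))
}

random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                                collapse = "")
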