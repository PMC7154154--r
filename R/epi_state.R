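ACTIVATING_MARKS <- c("H3K4me3", "H3K27ac")
REPRESSIVE_MARKS <- c("H3K27me3", "DNAme")

state_vocab <- function(mark) {
  if (mark %in% ACTIVATING_MARKS) c("A", "I")
  else if (mark %in% REPRESSIVE_MARKS) c("In", "T")
  else stop("unknown mark: ", mark)
}

#' Epigenetic state of each variant site for one mark and condition
#'
#' A site is in the "covered" state when its position lies inside any
#' peak interval of the given mark/condition, using the half-open
#' convention \code{start <= pos < end}. Activating marks (H3K4me3,
#' H3K27ac) yield A (active) / I (inactive); repressive signals
#' (H3K27me3, DNAme) yield In (inhibited) / T (permissive).
#'
#' @param variants variants data frame.
#' @param peaks peaks data frame (may contain many marks/conditions).
#' @param mark mark to evaluate.
#' @param condition condition to evaluate.
#' @return character vector of states, one per variant.
#' @export
mark_state <- function(variants, peaks, mark, condition) {
  vocab <- state_vocab(mark)
  pk <- peaks[peaks$mark == mark & peaks$condition == condition, , drop = FALSE]
  n <- nrow(variants)
  covered <- logical(n)
  for (ch in unique(variants$chrom)) {
    vi <- which(variants$chrom == ch)
    p <- pk[pk$chrom == ch, , drop = FALSE]
    if (!nrow(p)) next
    covered[vi] <- IRanges::countOverlaps(
      IRanges::IRanges(variants$pos[vi], width = 1L),
      IRanges::IRanges(p$start, p$end - 1L)) > 0L
  }
  ifelse(covered, vocab[1], vocab[2])
}

#' Render a pair of states as a switch label
#'
#' @param state1 states in condition 1.
#' @param state2 states in condition 2 (same vocabulary).
#' @return character vector like "A->I" or "In->T".
#' @export
classify_switch <- function(state1, state2) {
  ok <- (state1 %in% c("A", "I") & state2 %in% c("A", "I")) |
    (state1 %in% c("In", "T") & state2 %in% c("In", "T"))
  if (!all(ok)) stop("state pair mixes vocabularies or is unknown")
  paste0(state1, "->", state2)
}

#' State calls and switch labels for every variant and mark
#'
#' Convenience wrapper running [mark_state()] for both conditions of
#' each mark present in \code{peaks} and attaching the switch label.
#'
#' @param variants variants data frame.
#' @param peaks peaks data frame.
#' @param conditions length-2 character vector, condition 1 then 2.
#' @param marks marks to evaluate (default: those present in peaks).
#' @return data frame with variant_id, mark, state1, state2, switch.
#' @export
epi_state_table <- function(variants, peaks, conditions,
                            marks = unique(peaks$mark)) {
  stopifnot(length(conditions) == 2L)
  out <- lapply(marks, function(mk) {
    s1 <- mark_state(variants, peaks, mk, conditions[1])
    s2 <- mark_state(variants, peaks, mk, conditions[2])
    data.frame(variant_id = variants$variant_id, mark = mk,
               state1 = s1, state2 = s2,
               switch = classify_switch(s1, s2), stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Count variants per switch class for one mark
#'
#' @param states output of [epi_state_table()].
#' @param mark mark to tabulate.
#' @return named integer vector over the four switch classes of the
#'   mark's vocabulary.
#' @export
switch_class_counts <- function(states, mark) {
  vocab <- state_vocab(mark)
  classes <- as.vector(outer(vocab, vocab, function(a, b) paste0(a, "->", b)))
  counts <- setNames(integer(length(classes)), classes)
  tab <- table(states$switch[states$mark == mark])
  counts[names(tab)] <- as.integer(tab)
  counts
}

#' Select epigenetically stable variants
#'
#' A variant is epigenetically stable when its promoter mark (H3K4me3)
#' or its enhancer mark (H3K27ac) is active in both conditions (switch
#' "A->A"), so an expression change at its gene cannot be attributed to
#' a local activation change. A variant qualifying under both marks is
#' returned once, flagged "both". Optionally the repressive signals
#' (H3K27me3, DNAme) may additionally be required not to switch.
#'
#' @param states output of [epi_state_table()]; must contain H3K4me3 and
#'   H3K27ac rows for every variant.
#' @param require_repressive_stable also require In->In or T->T for any
#'   repressive mark present (default FALSE).
#' @return data frame with variant_id and qualifying_mark in
#'   {promoter, enhancer, both}.
#' @export
select_epigenetically_stable <- function(states, require_repressive_stable = FALSE) {
  need <- c("H3K4me3", "H3K27ac")
  if (!all(need %in% states$mark))
    stop("states must include H3K4me3 and H3K27ac calls")
  prom <- states$variant_id[states$mark == "H3K4me3" & states$switch == "A->A"]
  enh <- states$variant_id[states$mark == "H3K27ac" & states$switch == "A->A"]
  ids <- union(prom, enh)
  if (require_repressive_stable) {
    rep_rows <- states[states$mark %in% REPRESSIVE_MARKS, , drop = FALSE]
    if (nrow(rep_rows)) {
      unstable <- unique(rep_rows$variant_id[!rep_rows$switch %in% c("In->In", "T->T")])
      ids <- setdiff(ids, unstable)
    }
  }
  qual <- ifelse(ids %in% prom & ids %in% enh, "both",
                 ifelse(ids %in% prom, "promoter", "enhancer"))
  data.frame(variant_id = ids, qualifying_mark = qual, stringsAsFactors = FALSE)
}

#' Peak-count profile around variant sites, by switch class
#'
#' For each switch class, counts how many (variant, peak) pairs overlap
#' each \code{bin}-bp bin of the [-half_window, half_window) window
#' centered on the variant position (position coordinates, peaks in
#' their native half-open convention). Row names carry the class and
#' its variant count.
#'
#' @param variants variants data frame.
#' @param classes character vector assigning each variant a class label.
#' @param peaks peaks data frame, already filtered to one
#'   mark/condition.
#' @param half_window half-width in bp (default 2000).
#' @param bin bin width in bp (default 100).
#' @return numeric matrix, classes x bins; columns named by bin offset.
#' @export
peak_count_profile <- function(variants, classes, peaks,
                               half_window = 2000L, bin = 100L) {
  stopifnot(length(classes) == nrow(variants), half_window %% bin == 0)
  offsets <- seq(-half_window, half_window - bin, by = bin)
  ulev <- sort(unique(classes))
  mat <- matrix(0, nrow = length(ulev), ncol = length(offsets),
                dimnames = list(ulev, offsets))
  for (ch in unique(variants$chrom)) {
    p <- peaks[peaks$chrom == ch, , drop = FALSE]
    vi <- which(variants$chrom == ch)
    if (!nrow(p) || !length(vi)) next
    piv <- IRanges::IRanges(p$start, p$end - 1L)
    for (i in vi) {
      a <- variants$pos[i] + offsets
      cnt <- IRanges::countOverlaps(IRanges::IRanges(a, width = bin), piv)
      mat[classes[i], ] <- mat[classes[i], ] + cnt
    }
  }
  n_by_class <- table(factor(classes, levels = ulev))
  rownames(mat) <- sprintf("%s (%d)", ulev, as.integer(n_by_class))
  mat
}
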