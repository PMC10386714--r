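#' tRF class labels
#'
#' The exhaustive, mutually exclusive taxonomy used for retained fragments.
#' @export
TRF_CLASSES <- c("THREE_PRIME_TRF", "INT_TRF", "FIVE_PRIME_TRF",
                 "FIVE_HALF", "FIVE_TOG", "AMBIGUOUS")

#' Length of the 5'-terminal oligoguanine run
#'
#' Counts the maximal run of consecutive G starting at the first position;
#' 0 when the sequence does not start with G.
#'
#' @param seq Character vector of non-empty RNA/DNA sequences.
#' @return Integer vector of run lengths.
#' @examples
#' tog_run("GGGGGUAUAGCUCAGGGGUGAGCAUUUGACUG")  # 5
#' @export
tog_run <- function(seq) {
  if (any(is.na(seq)) || any(nchar(seq) == 0))
    stop("tog_run requires non-empty sequences")
  m <- regexpr("^G+", as_rna(seq))
  ifelse(m == 1L, attr(m, "match.length"), 0L)
}

#' Classify one fragment locus
#'
#' Applies the window rules in priority order. A fragment is 5'-anchored if
#' its start lies within 10 nt of the tRNA 5' end (`start < 10`, 0-based);
#' 5'-anchored fragments longer than 35 nt are 5' halves, those starting
#' with at least `min_tog_g` guanosines are 5'TOGs, the rest are 5' tRFs.
#' Otherwise a fragment ending within 10 nt of the tRNA 3' end
#' (`trna_len - end < 10`) is a 3' tRF, and anything else is internal.
#'
#' @param start,end 0-based half-open locus on the tRNA
#'   (`0 <= start < end <= trna_len`).
#' @param seq The fragment sequence.
#' @param trna_len Length of the source tRNA.
#' @param min_tog_g Minimum 5'-terminal G run for the 5'TOG label
#'   (default 4).
#' @param half_min_len Fragments longer than this are 5' halves
#'   (default 35; length exactly 35 falls in the short-5' group).
#' @param end_window Window size for the 5'/3' anchoring rules (default 10).
#' @return One of [TRF_CLASSES] (never `"AMBIGUOUS"`, which only arises in
#'   [classify_table()] across discordant loci).
#' @export
classify_fragment <- function(start, end, seq, trna_len,
                              min_tog_g = 4, half_min_len = 35,
                              end_window = 10) {
  if (start < 0 || end > trna_len || start >= end)
    stop("locus [", start, ", ", end, ") outside the species (length ",
         trna_len, ")")
  len <- end - start
  if (start < end_window) {
    if (len > half_min_len) return("FIVE_HALF")
    if (tog_run(seq) >= min_tog_g) return("FIVE_TOG")
    return("FIVE_PRIME_TRF")
  }
  if ((trna_len - end) < end_window) return("THREE_PRIME_TRF")
  "INT_TRF"
}

#' Classify a fragment count table
#'
#' Each row is classified through all of its loci; rows whose loci disagree
#' are labelled `AMBIGUOUS` (default) or take the majority class. Rows
#' whose length falls outside `len_range` are removed.
#'
#' @param table A `fragment_count_table` (see [count_fragments()]).
#' @param ref The [trna_reference] the loci refer to.
#' @param min_tog_g,half_min_len,end_window Passed to [classify_fragment()].
#' @param len_range Retained fragment lengths, inclusive (default
#'   `c(18, 50)`).
#' @param ambiguous_policy `"ambiguous"` (default) or `"majority"` (ties
#'   fall back to `AMBIGUOUS`).
#' @return An object of class `classified_table`: the count table plus an
#'   `info` data frame (`fragment_seq`, `length`, `tog_run`, `class`).
#' @export
classify_table <- function(table, ref, min_tog_g = 4, half_min_len = 35,
                           end_window = 10, len_range = c(18, 50),
                           ambiguous_policy = c("ambiguous", "majority")) {
  stopifnot(inherits(table, "fragment_count_table"),
            inherits(ref, "trna_reference"))
  ambiguous_policy <- match.arg(ambiguous_policy)
  seqs <- rownames(table$counts)
  len <- nchar(seqs)
  keep <- len >= len_range[1] & len <= len_range[2]
  seqs <- seqs[keep]
  counts <- table$counts[keep, , drop = FALSE]
  loci <- table$loci[keep]
  cls <- character(length(seqs))
  for (k in seq_along(seqs)) {
    l <- loci[[k]]
    trna_len <- ref$length[match(l$species_id, ref$id)]
    if (anyNA(trna_len)) stop("locus on unknown species for fragment ", seqs[k])
    per_locus <- vapply(seq_len(nrow(l)), function(j)
      classify_fragment(l$start[j], l$end[j], seqs[k], trna_len[j],
                        min_tog_g, half_min_len, end_window), "")
    u <- unique(per_locus)
    cls[k] <- if (length(u) == 1) u
    else if (ambiguous_policy == "majority") {
      tt <- sort(table(per_locus), decreasing = TRUE)
      if (length(tt) > 1 && tt[1] == tt[2]) "AMBIGUOUS" else names(tt)[1]
    } else "AMBIGUOUS"
  }
  info <- data.frame(fragment_seq = seqs, length = nchar(seqs),
                     tog_run = if (length(seqs)) tog_run(seqs) else integer(),
                     class = factor(cls, levels = TRF_CLASSES),
                     stringsAsFactors = FALSE)
  structure(list(counts = counts, loci = loci, info = info),
            class = c("classified_table", "fragment_count_table"))
}

#' Remove low-count fragments and add a pseudo-count
#'
#' Rows with fewer than `min_total` raw counts summed over all samples are
#' removed; `pseudocount` is then added to every retained cell.
#'
#' @param table A `classified_table` (or `fragment_count_table`).
#' @param min_total Minimum total raw count (default 10).
#' @param pseudocount Added to every retained cell (default 1).
#' @return The filtered table, same class as the input.
#' @export
filter_low_counts <- function(table, min_total = 10, pseudocount = 1) {
  stopifnot(inherits(table, "fragment_count_table"))
  keep <- rowSums(table$counts) >= min_total
  table$counts <- table$counts[keep, , drop = FALSE] + as.integer(pseudocount)
  table$loci <- table$loci[keep]
  if (!is.null(table$info))
    table$info <- table$info[keep, , drop = FALSE]
  table
}

#' Class composition of a classified table
#'
#' @param table A `classified_table` (non-empty).
#' @param rows Optional logical/integer/character subset of rows (e.g. the
#'   differentially abundant fragments) over which to recompute the
#'   composition.
#' @return Named numeric vector of percentages over [TRF_CLASSES], summing
#'   to 100.
#' @export
class_composition <- function(table, rows = NULL) {
  stopifnot(inherits(table, "classified_table"))
  cls <- table$info$class
  if (!is.null(rows)) {
    if (is.character(rows)) rows <- match(rows, table$info$fragment_seq)
    cls <- cls[rows]
  }
  if (length(cls) == 0) stop("composition of an empty table is undefined")
  p <- 100 * table(cls) / length(cls)
  stats::setNames(as.numeric(p), names(p))
}
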