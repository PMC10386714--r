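#' Read small-RNA reads from FASTQ
#'
#' Sequences are returned in the RNA alphabet (T transcribed to U).
#'
#' @param path FASTQ file.
#' @return Character vector of read sequences.
#' @export
read_fastq <- function(path) {
  unname(as_rna(as.character(Biostrings::readBStringSet(path, format = "fastq"))))
}

#' Write reads to FASTQ
#'
#' Sequences are written in the DNA alphabet with uniform qualities, the
#' form external aligners expect.
#'
#' @param reads Character vector of sequences (RNA or DNA).
#' @param path Output FASTQ path.
#' @param ids Optional read names; defaults to `read1 ... readN`.
#' @return Invisibly, `path`.
#' @export
write_fastq <- function(reads, path, ids = NULL) {
  if (is.null(ids)) ids <- paste0("read", seq_along(reads))
  dna <- chartr("U", "T", toupper(reads))
  x <- Biostrings::DNAStringSet(stats::setNames(dna, ids))
  qual <- Biostrings::BStringSet(vapply(nchar(dna), function(n)
    paste(rep("I", n), collapse = ""), ""))
  Biostrings::writeXStringSet(x, path, format = "fastq", qualities = qual)
  invisible(path)
}

#' Trim adapters and read ends
#'
#' Removes the 3' sequencing adapter at its first occurrence (one mismatch
#' tolerated when the matched stretch is >= 10 nt, exact otherwise), drops
#' reads shorter than `min_len` after adapter removal, then trims
#' `end_trim` nt from both ends of the survivors (dropping any read that
#' becomes empty). Reads containing non-nucleotide characters are skipped
#' with a warning tally.
#'
#' @param reads Character vector of read sequences (RNA or DNA).
#' @param adapter 3' adapter sequence.
#' @param min_len Minimum read length after adapter removal (default 23).
#' @param end_trim Bases trimmed from each end after the length filter
#'   (default 4).
#' @return Character vector of trimmed reads (RNA alphabet) with attributes
#'   `n_dropped_short`, `n_skipped_bad` and `n_adapter_trimmed`.
#' @export
preprocess_reads <- function(reads, adapter = "TGGAATTCTCGGGTGCCAAGG",
                             min_len = 23, end_trim = 4) {
  reads <- as_rna(reads)
  adapter <- as_rna(adapter)
  bad <- !is_rna_alphabet(reads)
  if (any(bad))
    warning(sum(bad), " read(s) with non-nucleotide characters skipped")
  reads <- reads[!bad]
  a_int <- utf8ToInt(adapter)
  trimmed <- character(length(reads))
  n_adapter <- 0L
  for (k in seq_along(reads)) {
    r_int <- utf8ToInt(reads[k])
    n <- length(r_int)
    cut <- n
    for (i in seq_len(n)) {
      m <- min(length(a_int), n - i + 1L)
      mm <- sum(r_int[i:(i + m - 1L)] != a_int[seq_len(m)])
      if (mm <= (m >= 10)) { cut <- i - 1L; n_adapter <- n_adapter + 1L; break }
    }
    trimmed[k] <- substr(reads[k], 1, cut)
  }
  keep <- nchar(trimmed) >= min_len
  n_short <- sum(!keep)
  out <- trimmed[keep]
  out <- substr(out, end_trim + 1, nchar(out) - end_trim)
  out <- out[nchar(out) > 0]
  structure(out,
            n_dropped_short = n_short,
            n_skipped_bad = sum(bad),
            n_adapter_trimmed = n_adapter)
}

#' Align fragments to a tRNA reference by exhaustive Hamming scan
#'
#' Every distinct read sequence is compared against every position of every
#' reference species (sense strand, no indels). All loci at the best
#' mismatch stratum `<= max_mismatches` are reported; reads hitting more
#' than `max_hits` loci are discarded entirely; unaligned reads are dropped
#' with a tally. This mirrors a `-v 2 -m 500` best-stratum short-read
#' alignment on a compact reference.
#'
#' @param reads Character vector of (preprocessed) read sequences; repeated
#'   sequences are counted, so pass reads with multiplicity.
#' @param ref A [trna_reference] (total length suited to exhaustive scan).
#' @param max_mismatches Maximum Hamming mismatches (default 2).
#' @param max_hits Maximum loci per read before the read is discarded
#'   (default 500).
#' @return An object of class `aligned_fragments`: a data frame with one
#'   row per distinct aligned sequence -- `fragment_seq`, `count` (number of
#'   reads), `n_hits`, `best_mm` -- and a list-column `loci` of data frames
#'   (`species_id`, `start`, `end`; 0-based half-open). Attributes
#'   `n_unaligned` and `n_over_max_hits` tally dropped reads.
#' @export
align_fragments <- function(reads, ref, max_mismatches = 2, max_hits = 500) {
  stopifnot(inherits(ref, "trna_reference"))
  if (nrow(ref) == 0) stop("empty reference")
  reads <- as_rna(reads)
  tab <- table(reads)
  seqs <- names(tab)
  ref_int <- lapply(ref$sequence, utf8ToInt)
  rows <- vector("list", length(seqs))
  n_unaligned <- 0L; n_over <- 0L
  for (k in seq_along(seqs)) {
    q <- utf8ToInt(seqs[k])
    m <- length(q)
    best <- max_mismatches + 1L
    loci <- list()
    for (i in seq_len(nrow(ref))) {
      s <- ref_int[[i]]
      L <- length(s)
      if (L < m) next
      for (o in 0:(L - m)) {
        mm <- sum(s[(o + 1):(o + m)] != q)
        if (mm < best) {
          best <- mm
          loci <- list(data.frame(species_id = ref$id[i], start = o,
                                  end = o + m, stringsAsFactors = FALSE))
        } else if (mm == best && mm <= max_mismatches) {
          loci[[length(loci) + 1]] <- data.frame(
            species_id = ref$id[i], start = o, end = o + m,
            stringsAsFactors = FALSE)
        }
      }
    }
    if (best > max_mismatches) {
      n_unaligned <- n_unaligned + as.integer(tab[k]); next
    }
    loci <- do.call(rbind, loci)
    if (nrow(loci) > max_hits) {
      n_over <- n_over + as.integer(tab[k]); next
    }
    rows[[k]] <- list(fragment_seq = seqs[k], count = as.integer(tab[k]),
                      n_hits = nrow(loci), best_mm = best, loci = loci)
  }
  rows <- rows[!vapply(rows, is.null, TRUE)]
  out <- data.frame(
    fragment_seq = vapply(rows, `[[`, "", "fragment_seq"),
    count = vapply(rows, `[[`, 0L, "count"),
    n_hits = vapply(rows, `[[`, 0L, "n_hits"),
    best_mm = vapply(rows, `[[`, 0L, "best_mm"),
    stringsAsFactors = FALSE)
  out$loci <- lapply(rows, `[[`, "loci")
  structure(out, n_unaligned = n_unaligned, n_over_max_hits = n_over,
            class = c("aligned_fragments", "data.frame"))
}

#' Ingest external alignments (SAM or BED) on a tRNA reference
#'
#' Accepts the output of an external aligner in place of
#' [align_fragments()]. All alignments of one read (primary plus
#' secondaries) merge into one fragment's locus set; coordinates are
#' converted to 0-based half-open. Alignments are assumed ungapped, as
#' produced by Hamming-mode short-read alignment on mature tRNAs.
#'
#' @param path SAM/BAM or 6-column BED file.
#' @param ref The [trna_reference] the file was aligned against; unknown
#'   reference names are an error listing the offenders.
#' @param format `"auto"` (by extension), `"sam"`, `"bam"` or `"bed"`.
#' @return An `aligned_fragments` object (see [align_fragments()]).
#' @export
ingest_alignments <- function(path, ref, format = c("auto", "sam", "bam", "bed")) {
  stopifnot(inherits(ref, "trna_reference"))
  format <- match.arg(format)
  if (format == "auto")
    format <- switch(tolower(tools::file_ext(path)),
                     sam = "sam", bam = "bam", bed = "bed",
                     stop("cannot infer format from extension: ", path))
  if (format == "bed") {
    gr <- rtracklayer::import(path, format = "BED")
    if (is.null(gr$name)) stop("BED file needs a name column (read id)")
    aln <- data.frame(qname = gr$name,
                      rname = as.character(GenomicRanges::seqnames(gr)),
                      start = GenomicRanges::start(gr) - 1L,
                      end = GenomicRanges::end(gr),
                      seq = NA_character_, stringsAsFactors = FALSE)
  } else {
    bam_path <- if (format == "sam")
      Rsamtools::asBam(path, tempfile(), overwrite = TRUE, indexDestination = FALSE)
    else path
    b <- Rsamtools::scanBam(bam_path, param = Rsamtools::ScanBamParam(
      what = c("qname", "flag", "rname", "pos", "seq")))[[1]]
    mapped <- !bitwAnd(b$flag, 4L)
    aln <- data.frame(qname = b$qname[mapped],
                      rname = as.character(b$rname[mapped]),
                      start = b$pos[mapped] - 1L,
                      seq = as.character(b$seq[mapped]),
                      stringsAsFactors = FALSE)
    # secondary alignments may omit SEQ; take it from the read's primary
    aln$seq[aln$seq %in% c("", "*")] <- NA_character_
    primary_seq <- tapply(aln$seq, aln$qname, function(s) s[!is.na(s)][1])
    aln$seq <- as.character(primary_seq[aln$qname])
    if (anyNA(aln$seq)) stop("read(s) without any SEQ field: ",
                             paste(unique(aln$qname[is.na(aln$seq)]), collapse = ", "))
    aln$end <- aln$start + nchar(aln$seq)
  }
  unknown <- setdiff(unique(aln$rname), ref$id)
  if (length(unknown)) stop("unknown reference name(s): ",
                            paste(unknown, collapse = ", "))
  if (is.na(aln$seq[1]) || format == "bed")
    aln$seq <- substr(ref_sequence(ref, aln$rname), aln$start + 1, aln$end)
  aln$seq <- as_rna(aln$seq)
  # merge loci per read, then collapse identical sequences to counts
  key <- paste(aln$rname, aln$start, aln$end, sep = "\r")
  per_read <- split(key, aln$qname)
  read_seq <- vapply(split(aln$seq, aln$qname), `[`, "", 1)
  rows <- list()
  for (sq in unique(read_seq)) {
    qnames <- names(read_seq)[read_seq == sq]
    loci_keys <- sort(unique(unlist(per_read[qnames])))
    parts <- strsplit(loci_keys, "\r", fixed = TRUE)
    loci <- data.frame(species_id = vapply(parts, `[`, "", 1),
                       start = as.integer(vapply(parts, `[`, "", 2)),
                       end = as.integer(vapply(parts, `[`, "", 3)),
                       stringsAsFactors = FALSE)
    rows[[length(rows) + 1]] <- list(fragment_seq = sq,
                                     count = length(qnames),
                                     n_hits = nrow(loci), loci = loci)
  }
  out <- data.frame(
    fragment_seq = vapply(rows, `[[`, "", "fragment_seq"),
    count = vapply(rows, `[[`, 0L, "count"),
    n_hits = vapply(rows, `[[`, 0L, "n_hits"),
    best_mm = NA_integer_,
    stringsAsFactors = FALSE)
  out$loci <- lapply(rows, `[[`, "loci")
  structure(out, class = c("aligned_fragments", "data.frame"))
}

#' Write alignments as SAM
#'
#' One line per locus; the first locus of each fragment is primary, the
#' rest carry the secondary flag. Each read of a fragment is emitted, so
#' the file round-trips through [ingest_alignments()].
#'
#' @param alignments An `aligned_fragments` object.
#' @param ref The [trna_reference] used for alignment (for `@SQ` headers).
#' @param path Output SAM path.
#' @return Invisibly, `path`.
#' @export
write_sam <- function(alignments, ref, path) {
  stopifnot(inherits(alignments, "aligned_fragments"),
            inherits(ref, "trna_reference"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("@HD\tVN:1.6\tSO:unknown", con)
  writeLines(sprintf("@SQ\tSN:%s\tLN:%d", ref$id, ref$length), con)
  read_no <- 0L
  for (i in seq_len(nrow(alignments))) {
    loci <- alignments$loci[[i]]
    sq <- chartr("U", "T", alignments$fragment_seq[i])
    cigar <- paste0(nchar(sq), "M")
    for (r in seq_len(alignments$count[i])) {
      read_no <- read_no + 1L
      qname <- sprintf("frag%06d", read_no)
      for (j in seq_len(nrow(loci))) {
        flag <- if (j == 1) 0L else 256L
        writeLines(paste(qname, flag, loci$species_id[j], loci$start[j] + 1L,
                         255L, cigar, "*", 0L, 0L,
                         if (j == 1) sq else "*",
                         "*", sep = "\t"), con)
      }
    }
  }
  invisible(path)
}

#' Build a fragment count table from per-sample alignments
#'
#' One row per distinct fragment sequence. With the default
#' `count_mode = "once"` each read contributes exactly 1 to its sequence's
#' count in its sample, however many loci it maps to (loci are kept as
#' annotation, unioned across samples); `"per-locus"` credits a read once
#' per locus instead.
#'
#' @param alignments Named list of `aligned_fragments`, one per sample, all
#'   against the same reference.
#' @param count_mode `"once"` (default) or `"per-locus"`.
#' @return An object of class `fragment_count_table`: a list with `counts`
#'   (fragment x sample integer matrix, rownames = fragment sequences) and
#'   `loci` (named list of per-fragment locus data frames).
#' @export
count_fragments <- function(alignments, count_mode = c("once", "per-locus")) {
  stopifnot(is.list(alignments), length(alignments) > 0,
            !is.null(names(alignments)))
  count_mode <- match.arg(count_mode)
  all_seq <- sort(unique(unlist(lapply(alignments, `[[`, "fragment_seq"))))
  counts <- matrix(0L, length(all_seq), length(alignments),
                   dimnames = list(all_seq, names(alignments)))
  loci <- stats::setNames(vector("list", length(all_seq)), all_seq)
  for (j in seq_along(alignments)) {
    a <- alignments[[j]]
    idx <- match(a$fragment_seq, all_seq)
    mult <- if (count_mode == "once") 1L else a$n_hits
    counts[idx, j] <- counts[idx, j] + a$count * mult
    for (k in seq_along(idx)) {
      cur <- loci[[idx[k]]]
      loci[[idx[k]]] <- unique(rbind(cur, a$loci[[k]]))
    }
  }
  structure(list(counts = counts, loci = loci),
            class = "fragment_count_table")
}

#' @export
print.fragment_count_table <- function(x, ...) {
  cat("fragment count table:", nrow(x$counts), "fragments x",
      ncol(x$counts), "samples\n")
  invisible(x)
}

#' Write / read a fragment count table as TSV
#'
#' Loci are serialised as `species:start-end` (0-based half-open),
#' semicolon-separated.
#'
#' @param table A `fragment_count_table`.
#' @param path TSV path.
#' @return `write_count_table` returns `path` invisibly;
#'   `read_count_table` returns a `fragment_count_table`.
#' @export
write_count_table <- function(table, path) {
  stopifnot(inherits(table, "fragment_count_table"))
  loci_str <- vapply(table$loci, function(l)
    paste(sprintf("%s:%d-%d", l$species_id, l$start, l$end), collapse = ";"), "")
  df <- data.frame(fragment_seq = rownames(table$counts), loci = loci_str,
                   table$counts, check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_count_table
#' @export
read_count_table <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  counts <- as.matrix(df[, -(1:2), drop = FALSE])
  storage.mode(counts) <- "integer"
  rownames(counts) <- df$fragment_seq
  loci <- lapply(strsplit(df$loci, ";", fixed = TRUE), function(parts) {
    m <- regmatches(parts, regexec("^(.+):(\\d+)-(\\d+)$", parts))
    data.frame(species_id = vapply(m, `[`, "", 2),
               start = as.integer(vapply(m, `[`, "", 3)),
               end = as.integer(vapply(m, `[`, "", 4)),
               stringsAsFactors = FALSE)
  })
  names(loci) <- df$fragment_seq
  structure(list(counts = counts, loci = loci),
            class = "fragment_count_table")
}
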