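#' Construct a tRNA reference
#'
#' A `trna_reference` holds mature tRNA species with their sequences and the
#' structural annotations the downstream stages use: the candidate m7G
#' guanosine in the variable loop (when annotated) and the variable-loop
#' interval. All coordinates are 0-based, half-open; user-facing reports are
#' 1-based.
#'
#' @param id Character vector of unique species identifiers.
#' @param amino_acid Three-letter amino-acid codes.
#' @param anticodon 3-mer anticodons over A/C/G/U.
#' @param sequence RNA sequences (DNA input is transcribed to U).
#' @param m7g_pos Optional 0-based index of the candidate m7G guanosine
#'   inside the variable loop; `NA` for unannotated species.
#' @param var_loop_start,var_loop_end 0-based half-open variable-loop
#'   interval within each sequence.
#' @return An object of class `trna_reference`: a data frame with columns
#'   `id`, `amino_acid`, `anticodon`, `sequence`, `length`, `m7g_pos`,
#'   `var_loop_start`, `var_loop_end`.
#' @examples
#' trna_reference("Cys-GCA-toy", "Cys", "GCA",
#'                paste(rep("GGGGGAUAGCUCAGUC", 4), collapse = ""),
#'                m7g_pos = 45, var_loop_start = 43, var_loop_end = 49)
#' @export
trna_reference <- function(id, amino_acid, anticodon, sequence,
                           m7g_pos = NA_integer_,
                           var_loop_start, var_loop_end) {
  sequence <- as_rna(as.character(sequence))
  n <- length(id)
  ref <- data.frame(
    id = as.character(id),
    amino_acid = as.character(amino_acid),
    anticodon = as_rna(as.character(anticodon)),
    sequence = sequence,
    length = nchar(sequence),
    m7g_pos = as.integer(rep_len(m7g_pos, n)),
    var_loop_start = as.integer(var_loop_start),
    var_loop_end = as.integer(var_loop_end),
    stringsAsFactors = FALSE
  )
  class(ref) <- c("trna_reference", "data.frame")
  validate_reference(ref)
}

validate_reference <- function(ref) {
  if (nrow(ref) == 0) stop("reference must contain at least one species")
  dup <- ref$id[duplicated(ref$id)]
  if (length(dup)) stop("duplicate species id(s): ", paste(unique(dup), collapse = ", "))
  bad <- !is_rna_alphabet(ref$sequence)
  if (any(bad)) stop("non-ACGU characters in sequence(s): ",
                     paste(ref$id[bad], collapse = ", "))
  if (any(ref$var_loop_start < 0 | ref$var_loop_end > ref$length |
          ref$var_loop_start >= ref$var_loop_end))
    stop("invalid variable-loop interval for: ",
         paste(ref$id[ref$var_loop_start < 0 | ref$var_loop_end > ref$length |
                      ref$var_loop_start >= ref$var_loop_end], collapse = ", "))
  ann <- !is.na(ref$m7g_pos)
  if (any(ann)) {
    base <- substr(ref$sequence[ann], ref$m7g_pos[ann] + 1, ref$m7g_pos[ann] + 1)
    not_g <- base != "G"
    if (any(not_g))
      stop("m7g_pos does not point at a G for: ",
           paste(ref$id[ann][not_g], collapse = ", "))
    outside <- ref$m7g_pos[ann] < ref$var_loop_start[ann] |
      ref$m7g_pos[ann] >= ref$var_loop_end[ann]
    if (any(outside))
      stop("m7g_pos outside the variable loop for: ",
           paste(ref$id[ann][outside], collapse = ", "))
  }
  ref
}

#' @export
print.trna_reference <- function(x, ...) {
  cat("tRNA reference with", nrow(x), "species (",
      sum(!is.na(x$m7g_pos)), "with annotated m7G site )\n")
  print.data.frame(utils::head(cbind(x[, c("id", "amino_acid", "anticodon",
                                           "length", "m7g_pos")]), 10))
  if (nrow(x) > 10) cat("...\n")
  invisible(x)
}

#' Load a tRNA reference from FASTA plus annotation table
#'
#' @param fasta_path FASTA file of mature tRNA sequences (DNA or RNA; T is
#'   transcribed to U).
#' @param annotation_path Tab-separated table with columns `id`,
#'   `amino_acid`, `anticodon`, `m7g_pos` (0-based; empty/NA when
#'   unannotated), `var_loop_start`, `var_loop_end` (0-based half-open).
#' @return A [trna_reference] object.
#' @seealso [write_reference()]
#' @export
load_reference <- function(fasta_path, annotation_path) {
  seqs <- Biostrings::readBStringSet(fasta_path)
  ids <- sub("\\s.*$", "", names(seqs))
  if (anyDuplicated(ids)) stop("duplicate FASTA id(s): ",
                               paste(unique(ids[duplicated(ids)]), collapse = ", "))
  ann <- utils::read.delim(annotation_path, stringsAsFactors = FALSE)
  need <- c("id", "amino_acid", "anticodon", "m7g_pos",
            "var_loop_start", "var_loop_end")
  if (!all(need %in% names(ann)))
    stop("annotation table must have columns: ", paste(need, collapse = ", "))
  missing <- setdiff(ids, ann$id)
  if (length(missing)) stop("species missing from annotation table: ",
                            paste(missing, collapse = ", "))
  ann <- ann[match(ids, ann$id), ]
  trna_reference(
    id = ids,
    amino_acid = ann$amino_acid,
    anticodon = ann$anticodon,
    sequence = as.character(seqs),
    m7g_pos = suppressWarnings(as.integer(ann$m7g_pos)),
    var_loop_start = ann$var_loop_start,
    var_loop_end = ann$var_loop_end
  )
}

#' Write a tRNA reference to FASTA plus annotation table
#'
#' Round-trips exactly through [load_reference()].
#'
#' @param ref A [trna_reference].
#' @param fasta_path,annotation_path Output paths.
#' @return Invisibly, `ref`.
#' @export
write_reference <- function(ref, fasta_path, annotation_path) {
  stopifnot(inherits(ref, "trna_reference"))
  seqs <- Biostrings::BStringSet(stats::setNames(ref$sequence, ref$id))
  Biostrings::writeXStringSet(seqs, fasta_path, width = 80)
  utils::write.table(
    ref[, c("id", "amino_acid", "anticodon", "m7g_pos",
            "var_loop_start", "var_loop_end")],
    annotation_path, sep = "\t", quote = FALSE, row.names = FALSE
  )
  invisible(ref)
}

#' Subset a reference to species with an annotated variable-loop guanosine
#'
#' Keeps, in their original order, the species whose candidate m7G position
#' is annotated (the "guanosine-46" set in standard tRNA numbering). An
#' empty result is allowed here, unlike the constructor.
#'
#' @param ref A [trna_reference].
#' @return A `trna_reference` (possibly with zero rows).
#' @export
g46_subset <- function(ref) {
  stopifnot(inherits(ref, "trna_reference"))
  out <- ref[!is.na(ref$m7g_pos), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("trna_reference", "data.frame")
  out
}

# Sequence lookup by species id; errors on unknown ids.
ref_sequence <- function(ref, id) {
  i <- match(id, ref$id)
  if (anyNA(i)) stop("unknown species id(s): ",
                     paste(unique(id[is.na(i)]), collapse = ", "))
  ref$sequence[i]
}
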