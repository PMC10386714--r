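# Hand-built toy fixtures shared across tests. Everything is generated in
# code; nothing is read from disk except through the package's own writers.

# A 76-nt cysteine-like species starting with 5 G and carrying a G at
# 0-based index 45 (position 46), plus an alanine-like 4G species and an
# unannotated species.
toy_sequences <- function() {
  base <- paste0(
    "GGGGG", "UAUAGCUCAGU", "GGUAGAGCAUUUGACUG",  # 5' + D-arm-ish, 33 nt
    "CAG",                                        # anticodon 34-36
    "AUCGAAUA",                                   # 44 nt so far
    "UG",                                         # variable loop lead-in
    "GUCGGGGGUUCGAAUCCCCC",                       # contains G at index 45
    "UAGCUCCCCA"                                  # 3' + CCA, total 76
  )
  stopifnot(nchar(base) == 76, substr(base, 46, 46) == "G")
  ala <- paste0("GGGG", substr(base, 5, 76))
  ala <- sub("^GGGGG", "GGGGU", ala)              # exactly 4 leading G
  stopifnot(nchar(ala) == 76, tog_run(ala) == 4, substr(ala, 46, 46) == "G")
  his <- chartr("G", "A", base)                   # no leading G, no G46
  his <- paste0(substr(his, 1, 73), "CCA")
  c(cys = base, ala = ala, his = his)
}

toy_reference <- function() {
  s <- toy_sequences()
  trna_reference(
    id = c("Cys-GCA-toy", "Ala-AGC-toy", "His-GUG-toy"),
    amino_acid = c("Cys", "Ala", "His"),
    anticodon = c("GCA", "AGC", "GUG"),
    sequence = s,
    m7g_pos = c(45L, 45L, NA_integer_),
    var_loop_start = 43L, var_loop_end = 49L
  )
}

# literal transcription of the textual classification rules, written
# independently of classify_fragment(); the windows and the 35-nt
# half boundary are applied exactly as stated.
oracle_classify <- function(start, end, seq, trna_len, min_tog_g = 4) {
  len <- end - start
  five_anchored <- start < 10            # "start site > -10 and < 10"
  three_anchored <- (trna_len - end) < 10  # "end < 10 from tRNA end site"
  if (five_anchored) {
    if (len > 35) return("FIVE_HALF")        # "5'-halves were > 35"
    ng <- 0
    for (i in seq_len(nchar(seq))) {
      if (substr(seq, i, i) == "G") ng <- ng + 1 else break
    }
    if (ng >= min_tog_g) return("FIVE_TOG")
    return("FIVE_PRIME_TRF")
  }
  if (three_anchored) return("THREE_PRIME_TRF")
  "INT_TRF"
}

# brute-force Hamming scan over every position of every species, reporting
# all loci at the best stratum; independent of align_fragments()
oracle_align <- function(read, ref, max_mm = 2) {
  hits <- data.frame(species_id = character(), start = integer(),
                     end = integer(), mm = integer(),
                     stringsAsFactors = FALSE)
  for (i in seq_len(nrow(ref))) {
    s <- strsplit(ref$sequence[i], "")[[1]]
    q <- strsplit(read, "")[[1]]
    m <- length(q)
    if (length(s) < m) next
    for (o in 0:(length(s) - m)) {
      mm <- sum(s[(o + 1):(o + m)] != q)
      if (mm <= max_mm)
        hits <- rbind(hits, data.frame(species_id = ref$id[i], start = o,
                                       end = o + m, mm = mm,
                                       stringsAsFactors = FALSE))
    }
  }
  if (nrow(hits) == 0) return(hits)
  hits[hits$mm == min(hits$mm), c("species_id", "start", "end")]
}

# tiny aligned_fragments constructor for counting tests
make_alignment <- function(seqs, counts, loci_list) {
  out <- data.frame(fragment_seq = seqs, count = as.integer(counts),
                    n_hits = vapply(loci_list, nrow, 0L),
                    best_mm = 0L, stringsAsFactors = FALSE)
  out$loci <- loci_list
  structure(out, class = c("aligned_fragments", "data.frame"))
}

locus <- function(species, start, end) {
  data.frame(species_id = species, start = as.integer(start),
             end = as.integer(end), stringsAsFactors = FALSE)
}
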