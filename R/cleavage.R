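#' Normalised cleavage (NCleavage)
#'
#' Divides each position's 5'-end read count by the total reads mapped to
#' that RNA species, per profile (species x condition x replicate). The
#' fractions of every profile sum to 1. Profiles with zero total yield an
#' all-zero vector with a warning and are excluded from site calling.
#'
#' @param profiles A `cleavage_profiles` data frame (see
#'   [simulate_cleavage_profiles()] or [read_profiles()]).
#' @return The input with an added `ncleavage` column.
#' @export
ncleavage <- function(profiles) {
  stopifnot(inherits(profiles, "data.frame"),
            all(c("species_id", "condition", "replicate", "position",
                  "count") %in% names(profiles)))
  key <- interaction(profiles$species_id, profiles$condition,
                     profiles$replicate, drop = TRUE)
  totals <- as.numeric(tapply(profiles$count, key, sum)[key])
  if (any(totals == 0))
    warning("profile(s) with zero total reads: all-zero fractions returned")
  profiles$ncleavage <- ifelse(totals > 0, profiles$count / totals, 0)
  if (!inherits(profiles, "cleavage_profiles"))
    class(profiles) <- c("cleavage_profiles", class(profiles))
  profiles
}

#' Call m7G sites from WT and KO cleavage profiles
#'
#' Computes mean NCleavage per condition and evaluates every position whose
#' inferred modified base (`position - offset` in the reference) is a
#' guanosine. A site is called when the mean WT fraction at the cleavage
#' position is at least `min_frac` and the smoothed WT/KO ratio
#' `(WT + delta)/(KO + delta)` is at least `min_ratio`, with
#' `delta = 1/mean(profile total)`. The reported site is the guanosine
#' (`position - offset`). When several sites are called for one species,
#' the one with the largest WT - KO difference is marked `top`.
#'
#' @param profiles A `cleavage_profiles` data frame containing both
#'   conditions (NCleavage is computed internally if absent).
#' @param ref The [trna_reference].
#' @param min_frac Minimum mean WT fraction at the cleavage position
#'   (default 0.05).
#' @param min_ratio Minimum smoothed WT/KO ratio (default 5).
#' @param offset Cleavage-position registration: the downstream fragment's
#'   5' end sits `offset` nt after the modified base (default 1; 0 also
#'   supported).
#' @param wt,ko Condition labels (defaults `"WT"`, `"KO"`).
#' @return A data frame of class `site_calls`: `species_id`, `site`
#'   (0-based G position; `site_1based` alongside for reports), `position`
#'   (the cleavage position inspected), `wt_mean`, `ko_mean`, `ratio`,
#'   `called`, `top`.
#' @export
call_m7g_sites <- function(profiles, ref, min_frac = 0.05, min_ratio = 5,
                           offset = 1, wt = "WT", ko = "KO") {
  stopifnot(inherits(ref, "trna_reference"))
  if (is.null(profiles$ncleavage)) profiles <- ncleavage(profiles)
  species <- intersect(ref$id, unique(profiles$species_id))
  rows <- list()
  for (sp in species) {
    p_sp <- profiles[profiles$species_id == sp, ]
    if (!all(c(wt, ko) %in% p_sp$condition))
      stop("species ", sp, " lacks replicates in one condition")
    L <- ref$length[match(sp, ref$id)]
    seq_sp <- ref$sequence[match(sp, ref$id)]
    # dense per-condition means; positions absent from a profile count as 0
    mean_frac <- function(cond) {
      sub <- p_sp[p_sp$condition == cond, ]
      n_rep <- length(unique(sub$replicate))
      agg <- tapply(sub$ncleavage, sub$position, sum) / n_rep
      dense <- numeric(L)
      dense[as.integer(names(agg)) + 1L] <- agg
      dense
    }
    wt_mean <- mean_frac(wt)
    ko_mean <- mean_frac(ko)
    delta <- 1 / mean(tapply(p_sp$count,
                             interaction(p_sp$condition, p_sp$replicate,
                                         drop = TRUE), sum))
    pos <- seq_len(L) - 1L                       # cleavage positions, 0-based
    g_site <- pos - offset
    candidate <- g_site >= 0 &
      substring(seq_sp, g_site + 1, g_site + 1) == "G"
    ratio <- (wt_mean + delta) / (ko_mean + delta)
    called <- candidate & wt_mean >= min_frac & ratio >= min_ratio
    idx <- which(candidate)
    if (!length(idx)) next
    df <- data.frame(species_id = sp, site = g_site[idx],
                     site_1based = g_site[idx] + 1L, position = pos[idx],
                     wt_mean = wt_mean[idx], ko_mean = ko_mean[idx],
                     ratio = ratio[idx], called = called[idx],
                     stringsAsFactors = FALSE)
    df$top <- FALSE
    if (any(df$called)) {
      diff <- df$wt_mean - df$ko_mean
      diff[!df$called] <- -Inf
      df$top[which.max(diff)] <- TRUE
    }
    rows[[length(rows) + 1]] <- df
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(species_id = character(), site = integer(),
               site_1based = integer(), position = integer(),
               wt_mean = numeric(), ko_mean = numeric(), ratio = numeric(),
               called = logical(), top = logical(), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  structure(out, class = c("site_calls", "data.frame"))
}

#' NCleavage matrix at the annotated cleavage positions
#'
#' For the species with an annotated variable-loop guanosine, the
#' per-replicate NCleavage value at `m7g_pos + offset`; species absent
#' from the profiles get a row of `NA` (missing, not zero).
#'
#' @param profiles A `cleavage_profiles` data frame.
#' @param ref The [trna_reference]; rows are its [g46_subset()].
#' @param offset Cleavage-position registration (default 1).
#' @return Numeric matrix, species x (condition.replicate), values in
#'   `[0, 1]` or `NA`.
#' @export
cleavage_matrix <- function(profiles, ref, offset = 1) {
  stopifnot(inherits(ref, "trna_reference"))
  if (is.null(profiles$ncleavage)) profiles <- ncleavage(profiles)
  sub_ref <- g46_subset(ref)
  cols <- unique(profiles[, c("condition", "replicate")])
  cols <- cols[order(cols$condition, cols$replicate), ]
  col_id <- paste(cols$condition, cols$replicate, sep = ".")
  mat <- matrix(NA_real_, nrow(sub_ref), nrow(cols),
                dimnames = list(sub_ref$id, col_id))
  for (i in seq_len(nrow(sub_ref))) {
    target <- sub_ref$m7g_pos[i] + offset
    for (j in seq_len(nrow(cols))) {
      v <- profiles$ncleavage[
        profiles$species_id == sub_ref$id[i] &
        profiles$condition == cols$condition[j] &
        profiles$replicate == cols$replicate[j] &
        profiles$position == target]
      if (length(v)) mat[i, j] <- v
    }
  }
  mat
}

#' Read / write cleavage profiles as TSV
#'
#' Columns: `species_id`, `condition`, `replicate`, `position` (0-based),
#' `count`.
#'
#' @param profiles A `cleavage_profiles` data frame.
#' @param path TSV path.
#' @return `write_profiles` returns `path` invisibly; `read_profiles`
#'   returns a `cleavage_profiles` data frame.
#' @export
write_profiles <- function(profiles, path) {
  utils::write.table(
    profiles[, c("species_id", "condition", "replicate", "position", "count")],
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_profiles
#' @export
read_profiles <- function(path) {
  out <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("species_id", "condition", "replicate", "position", "count")
  if (!all(need %in% names(out)))
    stop("profile table must have columns: ", paste(need, collapse = ", "))
  class(out) <- c("cleavage_profiles", "data.frame")
  out
}
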