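#' Load an expression cohort from TSV
#'
#' @param expr_path Genes x samples matrix of log2-normalised expression
#'   (first column = gene ids, header = sample ids).
#' @param label_path Two-column table (`sample`, `group`) with per-sample
#'   N/P/M labels.
#' @param name Cohort name (defaults to the expression file name).
#' @return An `expression_cohort` (list with `name`, `expr`, `groups`).
#' @export
read_cohort <- function(expr_path, label_path, name = NULL) {
  df <- utils::read.delim(expr_path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  expr <- as.matrix(df[, -1, drop = FALSE])
  rownames(expr) <- df[[1]]
  lab <- utils::read.delim(label_path, stringsAsFactors = FALSE)
  groups <- lab$group[match(colnames(expr), lab$sample)]
  if (anyNA(groups)) stop("sample(s) without a group label: ",
                          paste(colnames(expr)[is.na(groups)], collapse = ", "))
  if (sum(groups == "N") < 2) stop("cohort needs >= 2 reference (N) samples")
  structure(list(name = if (is.null(name)) basename(expr_path) else name,
                 expr = expr, groups = groups),
            class = "expression_cohort")
}

#' Tumour-class Z-score against the normal reference group
#'
#' `Z = (mean(class samples) - mean(N samples)) / sd(N samples)` with the
#' n-1 SD denominator: the number of reference standard deviations by which
#' the tumour class's mean expression departs from the reference mean.
#'
#' @param cohort An `expression_cohort`.
#' @param gene Gene id.
#' @param tumour_class `"P"` (primary) or `"M"` (metastatic).
#' @return The Z-score, or `NA` (with a warning) when the reference SD is
#'   zero, or `NA` silently when the gene or class is absent.
#' @export
cohort_zscore <- function(cohort, gene, tumour_class = c("P", "M")) {
  tumour_class <- match.arg(tumour_class)
  gi <- match(gene, rownames(cohort$expr))
  if (is.na(gi)) return(NA_real_)
  x <- cohort$expr[gi, ]
  n_ref <- x[cohort$groups == "N"]
  cls <- x[cohort$groups == tumour_class]
  if (length(cls) < 1 || length(n_ref) < 2) return(NA_real_)
  s <- stats::sd(n_ref)
  if (s == 0) {
    warning("zero reference-group SD for gene ", gene, " in ", cohort$name)
    return(NA_real_)
  }
  (mean(cls) - mean(n_ref)) / s
}

#' One-way ANOVA p-value across the cohort's groups
#'
#' Classical fixed-effects equal-variance one-way ANOVA across the N/P/M
#' groups present (groups with < 2 samples are dropped; with only two
#' groups it reduces to the equal-variance two-sample comparison).
#'
#' @param cohort An `expression_cohort`.
#' @param gene Gene id.
#' @return The p-value, or `NA` when the gene is absent or fewer than two
#'   groups remain.
#' @export
cohort_anova <- function(cohort, gene) {
  gi <- match(gene, rownames(cohort$expr))
  if (is.na(gi)) return(NA_real_)
  x <- cohort$expr[gi, ]
  g <- cohort$groups
  keep_groups <- names(which(table(g) >= 2))
  keep <- g %in% keep_groups
  if (length(unique(g[keep])) < 2) return(NA_real_)
  stats::oneway.test(x[keep] ~ factor(g[keep]), var.equal = TRUE)$p.value
}

#' Cross-cohort RNA-modifying-protein expression screen
#'
#' Per gene and cohort: tumour-class Z-scores and a one-way ANOVA p-value.
#' A gene is significant in a cohort when its ANOVA p is below `alpha`;
#' coherence is the percentage of cohorts containing the gene in which it
#' is significant. A gene is a hit when it is significant in at least
#' `min_datasets` cohorts *and* its coherence reaches `min_coherence`.
#'
#' @param cohorts List of `expression_cohort` objects.
#' @param genes Gene ids to screen (default: union over cohorts).
#' @param alpha Per-cohort significance level (default 0.05).
#' @param min_datasets Minimum number of significant cohorts (default 3).
#' @param min_coherence Minimum coherence percentage (default 75).
#' @return An object of class `screen_result`: a data frame ranked by the
#'   larger |average Z| with columns `gene`, `n_present`, `n_significant`,
#'   `coherence`, `avg_z_P`, `avg_z_M`, `hit`; per-cohort matrices (`z_P`,
#'   `z_M`, `p`, and `significant`) are attached as attributes.
#' @export
rmp_screen <- function(cohorts, genes = NULL, alpha = 0.05,
                       min_datasets = 3, min_coherence = 75) {
  stopifnot(length(cohorts) >= 1)
  if (is.null(genes))
    genes <- unique(unlist(lapply(cohorts, function(c) rownames(c$expr))))
  nm <- vapply(cohorts, `[[`, "", "name")
  z_P <- z_M <- pmat <- matrix(NA_real_, length(genes), length(cohorts),
                               dimnames = list(genes, nm))
  for (j in seq_along(cohorts)) {
    co <- cohorts[[j]]
    idx <- match(genes, rownames(co$expr))
    here <- which(!is.na(idx))
    if (!length(here)) next
    expr <- co$expr[idx[here], , drop = FALSE]
    g <- co$groups
    # vectorised Z over all genes of the cohort (same algebra as cohort_zscore)
    xn <- expr[, g == "N", drop = FALSE]
    mu_n <- rowMeans(xn)
    sd_n <- sqrt(rowSums((xn - mu_n)^2) / (ncol(xn) - 1))
    sd_n[sd_n == 0] <- NA_real_
    if (any(g == "P"))
      z_P[here, j] <- (rowMeans(expr[, g == "P", drop = FALSE]) - mu_n) / sd_n
    if (any(g == "M"))
      z_M[here, j] <- (rowMeans(expr[, g == "M", drop = FALSE]) - mu_n) / sd_n
    keep_groups <- names(which(table(g) >= 2))
    keep <- g %in% keep_groups
    if (length(unique(g[keep])) >= 2) {
      gf <- factor(g[keep])
      pmat[here, j] <- apply(expr[, keep, drop = FALSE], 1, function(x)
        stats::oneway.test(x ~ gf, var.equal = TRUE)$p.value)
    }
  }
  present <- vapply(cohorts, function(c) genes %in% rownames(c$expr),
                    logical(length(genes)))
  present <- matrix(present, nrow = length(genes))   # genes x cohorts
  sig <- !is.na(pmat) & pmat < alpha
  n_present <- rowSums(present)
  n_sig <- rowSums(sig & present)
  coherence <- ifelse(n_present > 0, 100 * n_sig / n_present, NA_real_)
  out <- data.frame(
    gene = genes,
    n_present = n_present,
    n_significant = n_sig,
    coherence = coherence,
    avg_z_P = rowMeans(z_P, na.rm = TRUE),
    avg_z_M = rowMeans(z_M, na.rm = TRUE),
    stringsAsFactors = FALSE)
  out$avg_z_P[is.nan(out$avg_z_P)] <- NA_real_
  out$avg_z_M[is.nan(out$avg_z_M)] <- NA_real_
  out$hit <- n_sig >= min_datasets & !is.na(coherence) &
    coherence >= min_coherence
  rank_z <- pmax(abs(out$avg_z_P), abs(out$avg_z_M), na.rm = TRUE)
  rank_z[is.infinite(rank_z)] <- NA_real_
  out <- out[order(-rank_z, na.last = TRUE), ]
  rownames(out) <- NULL
  structure(out, z_P = z_P, z_M = z_M, p = pmat, significant = sig,
            class = c("screen_result", "data.frame"))
}

#' PAR-CLIP read-density quantification
#'
#' Library-size (RPM) and length (RPKM) normalisation of per-gene counts,
#' with log2 IP/control enrichment on offset RPMs.
#'
#' @param counts Named numeric vector (or 2-column matrix `ip`/`control`)
#'   of per-gene read counts for the immunoprecipitated sample.
#' @param lib_sizes Library sizes (total mapped reads); one per sample
#'   column, > 0.
#' @param gene_lengths Transcript lengths in nt, > 0.
#' @param control_counts Per-gene counts of the control sample (ignored
#'   when `counts` is a matrix).
#' @param offset Offset `c` (in RPM) in
#'   `log2((RPM_IP + c)/(RPM_control + c))`; default 1.
#' @param rna_class Optional per-gene RNA class labels for the per-class
#'   median log2 RPM summary.
#' @return Data frame with `rpm_ip`, `rpm_control`, `rpkm_ip`,
#'   `rpkm_control`, `log2_enrichment`; per-class medians of the IP log2
#'   RPM are attached as attribute `class_median_log2_rpm` when
#'   `rna_class` is given.
#' @export
parclip_quant <- function(counts, lib_sizes, gene_lengths,
                          control_counts = NULL, offset = 1,
                          rna_class = NULL) {
  if (is.matrix(counts)) {
    control_counts <- counts[, 2]
    counts <- counts[, 1]
  }
  if (any(lib_sizes <= 0)) stop("library sizes must be positive")
  if (any(gene_lengths <= 0)) stop("gene length(s) must be positive")
  lib_sizes <- rep_len(lib_sizes, 2)
  rpm_ip <- 1e6 * counts / lib_sizes[1]
  rpm_ct <- 1e6 * control_counts / lib_sizes[2]
  out <- data.frame(
    gene = if (is.null(names(counts))) seq_along(counts) else names(counts),
    rpm_ip = rpm_ip,
    rpm_control = rpm_ct,
    rpkm_ip = 1e3 * rpm_ip / gene_lengths,
    rpkm_control = 1e3 * rpm_ct / gene_lengths,
    log2_enrichment = log2((rpm_ip + offset) / (rpm_ct + offset)),
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  if (!is.null(rna_class)) {
    med <- tapply(log2(rpm_ip + offset), rna_class, stats::median)
    attr(out, "class_median_log2_rpm") <- med
  }
  out
}

#' Coefficient-of-variation peak filter
#'
#' Peaks detected in fewer than two replicates (zero CPM elsewhere) are
#' removed first; surviving peaks are kept when their CV
#' (`100 * sd/mean`, n-1 SD) is below `max_cv_percent`. Peaks with zero
#' mean are removed.
#'
#' @param cpm Peaks x replicates matrix of counts-per-million.
#' @param max_cv_percent CV threshold in percent (default 30, exclusive).
#' @return The retained rows of `cpm`, with the computed CV attached as
#'   attribute `cv` (named by retained peak).
#' @export
cv_filter <- function(cpm, max_cv_percent = 30) {
  cpm <- as.matrix(cpm)
  if (ncol(cpm) < 2) stop("cv_filter needs >= 2 replicates")
  present <- rowSums(cpm > 0) >= 2
  cpm <- cpm[present, , drop = FALSE]
  mu <- rowMeans(cpm)
  cv <- ifelse(mu > 0, 100 * apply(cpm, 1, stats::sd) / mu, Inf)
  keep <- cv < max_cv_percent
  structure(cpm[keep, , drop = FALSE], cv = cv[keep])
}

#' Per-transcript fraction shares of a polysome profile
#'
#' Each transcript's abundance in each fraction is normalised by its total
#' over all analysed fractions, so shares sum to 1 per transcript.
#' Transcripts with zero total are returned as all-`NA` rows.
#'
#' @param profile A `polysome_profile` (see [simulate_polysome_profile()])
#'   or a transcripts x fractions matrix.
#' @return Matrix of shares with the same dimensions.
#' @export
polysome_proportions <- function(profile) {
  ab <- if (inherits(profile, "polysome_profile")) profile$abundance else
    as.matrix(profile)
  tot <- rowSums(ab)
  out <- sweep(ab, 1, tot, "/")
  out[tot == 0, ] <- NA_real_
  out
}

#' Polysome/non-polysome fold change per transcript
#'
#' `FC = sum(polysome shares) / sum(non-polysome shares)`. Transcripts with
#' all mass in the polysome fractions return `Inf` and are flagged in the
#' `capped` attribute; zero-total transcripts return `NA`.
#'
#' @param profile A `polysome_profile`, or a matrix together with
#'   `polysome_mask`.
#' @param polysome_mask Logical per fraction (required for plain matrices).
#' @return Named numeric vector of fold changes with attribute `capped`.
#' @export
polysome_fc <- function(profile, polysome_mask = NULL) {
  if (inherits(profile, "polysome_profile")) {
    polysome_mask <- profile$polysome_mask
    ab <- profile$abundance
  } else ab <- as.matrix(profile)
  if (is.null(polysome_mask)) stop("polysome_mask is required")
  if (!any(polysome_mask) || all(polysome_mask))
    stop("need >= 1 polysome and >= 1 non-polysome fraction")
  sh <- polysome_proportions(ab)
  poly <- rowSums(sh[, polysome_mask, drop = FALSE])
  non <- rowSums(sh[, !polysome_mask, drop = FALSE])
  fc <- poly / non
  structure(fc, capped = !is.na(fc) & is.infinite(fc))
}
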