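#' Generate a synthetic tRNA reference
#'
#' Builds random ~76-nt tRNA-like species with fixed scaffolding: an
#' anticodon placed at positions 34-36 (1-based), a terminal CCA, a
#' variable-loop interval ending 26 nt from the 3' end, and -- for the first
#' `n_m7g_targets` species -- a guanosine planted inside the variable loop
#' and recorded as the candidate m7G position (index `length - 31`, i.e.
#' position 46 of a standard 76-nt tRNA). The m7G-target species double as
#' 5'TOG sources: they start with a run of 5 (odd-numbered targets,
#' cysteine-like) or 4 (even-numbered, alanine-like) guanosines.
#'
#' @param n_species Number of species to generate.
#' @param n_m7g_targets How many of them carry an annotated m7G site
#'   (must be `<= n_species`).
#' @param length Species length in nt (default 76; must be >= 60 to host
#'   the scaffold).
#' @param seed Integer seed; the same call with the same seed returns an
#'   identical reference.
#' @return A [trna_reference].
#' @examples
#' make_trna_reference(4, 2, seed = 1)
#' @export
make_trna_reference <- function(n_species, n_m7g_targets, length = 76, seed = 1) {
  stopifnot(n_m7g_targets <= n_species, n_species >= 1)
  if (length < 60) stop("length must be >= 60 to host the tRNA scaffold")
  aa_pool <- c("Cys", "Ala", "Gly", "Glu", "Asp", "Val", "His", "Lys",
               "Phe", "Pro", "Ser", "Thr")
  with_local_seed(split_seed(seed, "reference"), {
    bases <- c("A", "C", "G", "U")
    length <- as.integer(length)
    m7g_idx <- length - 31L            # 0-based; position 46 on a 76-mer
    var_start <- m7g_idx - 2L
    var_end <- m7g_idx + 4L
    out <- vector("list", n_species)
    for (i in seq_len(n_species)) {
      s <- sample(bases, length, replace = TRUE)
      anticodon <- sample(bases, 3, replace = TRUE)
      s[34:36] <- anticodon            # 1-based 34-36
      s[(length - 2):length] <- c("C", "C", "A")
      is_target <- i <= n_m7g_targets
      if (is_target) {
        g_run <- if (i %% 2 == 1) 5L else 4L
        s[seq_len(g_run)] <- "G"
        s[g_run + 1L] <- sample(c("A", "C", "U"), 1)  # terminate the run
        s[m7g_idx + 1L] <- "G"
      }
      aa <- if (is_target) c("Cys", "Ala")[2 - i %% 2] else
        aa_pool[(i - 1) %% length(aa_pool) + 1]
      out[[i]] <- list(
        id = sprintf("%s-%s-sim%d", aa, paste(anticodon, collapse = ""), i),
        amino_acid = aa,
        anticodon = paste(anticodon, collapse = ""),
        sequence = paste(s, collapse = ""),
        m7g_pos = if (is_target) m7g_idx else NA_integer_
      )
    }
    trna_reference(
      id = vapply(out, `[[`, "", "id"),
      amino_acid = vapply(out, `[[`, "", "amino_acid"),
      anticodon = vapply(out, `[[`, "", "anticodon"),
      sequence = vapply(out, `[[`, "", "sequence"),
      m7g_pos = vapply(out, `[[`, NA_integer_, "m7g_pos"),
      var_loop_start = rep(var_start, n_species),
      var_loop_end = rep(var_end, n_species)
    )
  })
}

#' Design for a simulated small-RNA fragment experiment
#'
#' @param conditions Named integer vector of replicate counts, e.g.
#'   `c(WT = 3, KO = 3)`. Tested conditions need >= 2 replicates.
#' @param depth_per_sample Expected reads per sample.
#' @param full_length_fraction Proportion of the library that is full-length
#'   tRNA reads, in `[0, 1]`.
#' @param planted_togs Data frame with columns `species_id`, `length`
#'   (fragment length in nt, within `[18, 50]`) and `log2_excess` (planted
#'   KO/WT log2 fold change); one row per planted 5'-anchored fragment. Use
#'   [default_planted_togs()] to derive it from a reference.
#' @param planted_mean Expected WT count per planted fragment.
#' @param background_cleavage_rate Expected background fragments per nt of
#'   reference (drives how many random fragments appear).
#' @param nb_dispersion Negative-binomial overdispersion alpha
#'   (variance = mu + alpha mu^2); default 0.02, typical of near-isogenic
#'   cultured clones.
#' @param seed Integer seed.
#' @return A list of class `fragment_design`.
#' @export
fragment_design <- function(conditions = c(WT = 3, KO = 3),
                            depth_per_sample = 5e4,
                            full_length_fraction = 0.35,
                            planted_togs = NULL,
                            planted_mean = 400,
                            background_cleavage_rate = 0.5,
                            nb_dispersion = 0.02,
                            seed = 1) {
  stopifnot(full_length_fraction >= 0, full_length_fraction <= 1,
            depth_per_sample >= 0, nb_dispersion >= 0,
            all(conditions >= 2))
  if (!is.null(planted_togs)) {
    stopifnot(all(c("species_id", "length", "log2_excess") %in% names(planted_togs)))
    if (any(planted_togs$length < 18 | planted_togs$length > 50))
      stop("planted fragment lengths must lie in [18, 50]")
  }
  structure(list(conditions = conditions,
                 depth_per_sample = depth_per_sample,
                 full_length_fraction = full_length_fraction,
                 planted_togs = planted_togs,
                 planted_mean = planted_mean,
                 background_cleavage_rate = background_cleavage_rate,
                 nb_dispersion = nb_dispersion,
                 seed = seed),
            class = "fragment_design")
}

#' Default planted 5'TOG fragments for a synthetic reference
#'
#' One ~20-nt and one ~30-nt 5'-anchored fragment per m7G-target species,
#' mirroring the two fragment sizes that accumulate on loss of m7G.
#'
#' @param ref A [trna_reference].
#' @param lengths Fragment lengths to plant.
#' @param log2_excess Planted KO/WT log2 fold change.
#' @return A data frame suitable for [fragment_design()]'s `planted_togs`.
#' @export
default_planted_togs <- function(ref, lengths = c(20, 30), log2_excess = 3) {
  targets <- g46_subset(ref)
  if (nrow(targets) == 0) return(NULL)
  data.frame(
    species_id = rep(targets$id, each = length(lengths)),
    length = rep(lengths, times = nrow(targets)),
    log2_excess = log2_excess,
    stringsAsFactors = FALSE
  )
}

#' Simulate small-RNA fragment reads
#'
#' Generates per-sample read collections whose per-fragment counts are
#' negative-binomially distributed around design means. Reads are exact
#' substrings of the reference. Planted 5'TOG fragments are 5'-anchored
#' prefixes of their source species, with KO means equal to
#' `2^log2_excess` times the WT mean; background fragments and full-length
#' reads have equal means in both conditions. Library sizes vary at most
#' two-fold across samples.
#'
#' @param ref A [trna_reference].
#' @param design A [fragment_design].
#' @return A list of class `fragment_sim` with elements `reads` (named list
#'   of character vectors, one per sample), `counts` (fragment x sample
#'   integer matrix), `catalogue` (data frame: `fragment_seq`, `species_id`,
#'   `start`, `end`, `type`, `log2_excess`), `samples` (data frame with
#'   `sample`, `condition`) and the `design`.
#' @export
simulate_fragment_reads <- function(ref, design) {
  stopifnot(inherits(ref, "trna_reference"), inherits(design, "fragment_design"))
  pt <- design$planted_togs
  if (!is.null(pt)) {
    seqs <- ref_sequence(ref, pt$species_id)   # errors on unknown species
    runs <- tog_run(seqs)
    if (any(runs < 4))
      stop("TOG-source species lacking a 5'-terminal G run (>=4): ",
           paste(unique(pt$species_id[runs < 4]), collapse = ", "))
  }
  with_local_seed(split_seed(design$seed, "fragment-reads"), {
    cat_rows <- list()
    # full-length reads
    w_full <- stats::runif(nrow(ref), 0.5, 1.5)
    w_full <- w_full / sum(w_full)
    full_mass <- design$full_length_fraction * design$depth_per_sample
    for (i in seq_len(nrow(ref))) {
      cat_rows[[length(cat_rows) + 1]] <- data.frame(
        fragment_seq = ref$sequence[i], species_id = ref$id[i],
        start = 0L, end = ref$length[i], type = "full_length",
        log2_excess = 0, mu_wt = full_mass * w_full[i],
        stringsAsFactors = FALSE)
    }
    frag_mass <- (1 - design$full_length_fraction) * design$depth_per_sample
    if (frag_mass > 0) {
      # planted 5'-anchored TOG fragments
      planted_total <- 0
      if (!is.null(pt)) {
        for (i in seq_len(nrow(pt))) {
          seq_i <- ref_sequence(ref, pt$species_id[i])
          cat_rows[[length(cat_rows) + 1]] <- data.frame(
            fragment_seq = substr(seq_i, 1, pt$length[i]),
            species_id = pt$species_id[i],
            start = 0L, end = as.integer(pt$length[i]), type = "planted_tog",
            log2_excess = pt$log2_excess[i], mu_wt = design$planted_mean,
            stringsAsFactors = FALSE)
        }
        planted_total <- nrow(pt) * design$planted_mean
      }
      # background fragments: random loci, equal means across conditions
      bg_mass <- max(0, frag_mass - planted_total)
      n_bg <- stats::rpois(nrow(ref), design$background_cleavage_rate * ref$length)
      bg <- list()
      for (i in seq_len(nrow(ref))) {
        if (n_bg[i] == 0) next
        L <- ref$length[i]
        start <- sample.int(L - 18L, n_bg[i], replace = TRUE) - 1L
        len <- pmin(18L + stats::rgeom(n_bg[i], 1 / 12), 50L, L - start)
        len <- pmax(len, 18L)
        keep <- start + len <= L
        if (!any(keep)) next
        bg[[length(bg) + 1]] <- data.frame(
          fragment_seq = substring(ref$sequence[i], start[keep] + 1,
                                   start[keep] + len[keep]),
          species_id = ref$id[i], start = start[keep],
          end = start[keep] + len[keep], type = "background",
          log2_excess = 0, mu_wt = NA_real_, stringsAsFactors = FALSE)
      }
      if (length(bg)) {
        bg <- do.call(rbind, bg)
        w_bg <- stats::runif(nrow(bg), 0.2, 1.8)
        bg$mu_wt <- bg_mass * w_bg / sum(w_bg)
        cat_rows[[length(cat_rows) + 1]] <- bg
      }
    }
    catalogue <- do.call(rbind, cat_rows)
    rownames(catalogue) <- NULL

    samples <- data.frame(
      sample = unlist(lapply(names(design$conditions), function(cn)
        paste0(cn, "_", seq_len(design$conditions[[cn]])))),
      condition = rep(names(design$conditions), times = design$conditions),
      stringsAsFactors = FALSE)
    lib_factor <- stats::runif(nrow(samples), sqrt(0.5), sqrt(2))

    counts <- matrix(0L, nrow(catalogue), nrow(samples),
                     dimnames = list(NULL, samples$sample))
    for (j in seq_len(nrow(samples))) {
      excess <- if (samples$condition[j] == "KO")
        2^catalogue$log2_excess else rep(1, nrow(catalogue))
      mu <- catalogue$mu_wt * excess * lib_factor[j]
      counts[, j] <- rnbinom_mu_alpha(nrow(catalogue), mu, design$nb_dispersion)
    }
    reads <- lapply(seq_len(nrow(samples)), function(j)
      rep(catalogue$fragment_seq, counts[, j]))
    names(reads) <- samples$sample
    structure(list(reads = reads, counts = counts, catalogue = catalogue,
                   samples = samples, design = design),
              class = "fragment_sim")
  })
}

#' Design for simulated aniline-cleavage 5'-end profiles
#'
#' @param conditions Named replicate counts, e.g. `c(WT = 2, KO = 2)`.
#' @param depth_per_species Expected 5'-end count per species and replicate.
#' @param signal_fraction Fraction of 5' ends at the registered cleavage
#'   position in WT.
#' @param ko_signal_fraction Residual fraction in KO; must satisfy
#'   `0 <= ko_signal_fraction < signal_fraction <= 1`.
#' @param seed Integer seed.
#' @return A list of class `cleavage_design`.
#' @export
cleavage_design <- function(conditions = c(WT = 2, KO = 2),
                            depth_per_species = 1e4,
                            signal_fraction = 0.3,
                            ko_signal_fraction = 0.005,
                            seed = 1) {
  stopifnot(ko_signal_fraction >= 0, ko_signal_fraction < signal_fraction,
            signal_fraction <= 1)
  structure(list(conditions = conditions,
                 depth_per_species = depth_per_species,
                 signal_fraction = signal_fraction,
                 ko_signal_fraction = ko_signal_fraction,
                 seed = seed),
            class = "cleavage_design")
}

#' Simulate aniline-cleavage 5'-end count profiles
#'
#' For each species and replicate, draws a multinomial sample of
#' `depth_per_species` 5'-end positions. Annotated species concentrate
#' `signal_fraction` (WT) or `ko_signal_fraction` (KO) of the mass at the
#' registered cleavage position -- one nt downstream of the annotated m7G
#' guanosine, where aniline scission leaves the downstream fragment's 5'
#' end. Unannotated species receive uniform background only.
#'
#' @param ref A [trna_reference] (non-empty).
#' @param design A [cleavage_design].
#' @return A data frame of class `cleavage_profiles` in long format with
#'   columns `species_id`, `condition`, `replicate`, `position` (0-based)
#'   and `count`.
#' @export
simulate_cleavage_profiles <- function(ref, design) {
  stopifnot(inherits(ref, "trna_reference"), inherits(design, "cleavage_design"))
  with_local_seed(split_seed(design$seed, "cleavage-profiles"), {
    rows <- list()
    for (i in seq_len(nrow(ref))) {
      L <- ref$length[i]
      for (cn in names(design$conditions)) {
        sf <- if (is.na(ref$m7g_pos[i])) 0 else if (cn == "KO")
          design$ko_signal_fraction else design$signal_fraction
        p <- rep((1 - sf) / (L - (sf > 0)), L)
        if (sf > 0) p[ref$m7g_pos[i] + 2L] <- sf   # registered position, 1-based index
        for (r in seq_len(design$conditions[[cn]])) {
          cnt <- as.integer(stats::rmultinom(1, design$depth_per_species, p))
          rows[[length(rows) + 1]] <- data.frame(
            species_id = ref$id[i], condition = cn, replicate = r,
            position = 0:(L - 1), count = cnt, stringsAsFactors = FALSE)
        }
      }
    }
    out <- do.call(rbind, rows)
    class(out) <- c("cleavage_profiles", "data.frame")
    out
  })
}

#' Design for simulated multi-cohort expression screens
#'
#' @param n_cohorts Number of cohorts.
#' @param group_sizes Named sample counts per group, e.g.
#'   `c(N = 10, P = 10, M = 10)`; N needs >= 2 samples (the reference SD
#'   must exist).
#' @param n_genes Number of genes per cohort.
#' @param planted Data frame with columns `gene`, `effect` (shift in SD
#'   units), `classes` (string over "P"/"M" naming shifted groups) and
#'   `frac_cohorts` (fraction of cohorts carrying the effect); or `NULL`.
#' @param seed Integer seed.
#' @return A list of class `cohort_design`.
#' @export
cohort_design <- function(n_cohorts = 5,
                          group_sizes = c(N = 10, P = 10, M = 10),
                          n_genes = 1000,
                          planted = NULL,
                          seed = 1) {
  stopifnot(group_sizes[["N"]] >= 2)
  if (!is.null(planted))
    stopifnot(all(c("gene", "effect", "classes", "frac_cohorts") %in% names(planted)))
  structure(list(n_cohorts = n_cohorts, group_sizes = group_sizes,
                 n_genes = n_genes, planted = planted, seed = seed),
            class = "cohort_design")
}

#' Simulate log2 expression cohorts with group labels
#'
#' Null genes are `Normal(mu_gene, 1)` in every group (gene baselines drawn
#' once per cohort from `Normal(8, 1)`, a typical log2 microarray level);
#' planted genes are shifted by `effect` SD units in the stated groups in
#' the stated fraction of cohorts (the first
#' `round(frac_cohorts * n_cohorts)` cohorts).
#'
#' @param design A [cohort_design].
#' @return A list of `expression_cohort` objects, each a list with `name`,
#'   `expr` (genes x samples matrix) and `groups` (character vector of
#'   N/P/M labels per sample).
#' @export
simulate_expression_cohorts <- function(design) {
  stopifnot(inherits(design, "cohort_design"))
  with_local_seed(split_seed(design$seed, "expression-cohorts"), {
    genes <- sprintf("gene%04d", seq_len(design$n_genes))
    groups <- rep(names(design$group_sizes), times = design$group_sizes)
    lapply(seq_len(design$n_cohorts), function(k) {
      mu <- stats::rnorm(design$n_genes, 8, 1)
      expr <- matrix(stats::rnorm(design$n_genes * length(groups)),
                     nrow = design$n_genes) + mu
      dimnames(expr) <- list(genes, paste0("s", seq_along(groups)))
      if (!is.null(design$planted)) {
        for (i in seq_len(nrow(design$planted))) {
          pl <- design$planted[i, ]
          if (k > round(pl$frac_cohorts * design$n_cohorts)) next
          gi <- match(pl$gene, genes)
          if (is.na(gi)) stop("planted gene not in gene set: ", pl$gene)
          shifted <- groups %in% strsplit(pl$classes, "")[[1]]
          expr[gi, shifted] <- expr[gi, shifted] + pl$effect
        }
      }
      structure(list(name = paste0("cohort", k), expr = expr, groups = groups),
                class = "expression_cohort")
    })
  })
}

#' Simulate a polysome profile
#'
#' Unshifted transcripts concentrate mass in early (sub-polysomal)
#' fractions with an exponentially decaying profile; shifted transcripts
#' move `shift_mass` of their mass uniformly into the polysome fractions.
#'
#' @param n_transcripts Number of transcripts.
#' @param n_fractions Number of gradient fractions (>= 4; default 16).
#' @param shifted Character vector of transcript ids to shift (subset of
#'   `t1 ... tN`).
#' @param shift_mass Mass fraction moved into polysome fractions.
#' @param depth Multinomial depth per transcript.
#' @param polysome_fractions Indices of polysome fractions; default the
#'   second half of the gradient.
#' @param seed Integer seed.
#' @return A list of class `polysome_profile` with `abundance` (transcripts
#'   x fractions matrix) and `polysome_mask` (logical per fraction).
#' @export
simulate_polysome_profile <- function(n_transcripts, n_fractions = 16,
                                      shifted = character(),
                                      shift_mass = 0.4,
                                      depth = 1e4,
                                      polysome_fractions = NULL,
                                      seed = 1) {
  stopifnot(n_fractions >= 4)
  if (is.null(polysome_fractions))
    polysome_fractions <- seq(floor(n_fractions / 2) + 1, n_fractions)
  mask <- seq_len(n_fractions) %in% polysome_fractions
  with_local_seed(split_seed(seed, "polysome"), {
    ids <- paste0("t", seq_len(n_transcripts))
    base <- exp(-0.5 * (seq_len(n_fractions) - 1))
    base <- base / sum(base)
    ab <- t(vapply(ids, function(id) {
      p <- base
      if (id %in% shifted) {
        p <- p * (1 - shift_mass) / sum(p)
        p[mask] <- p[mask] + shift_mass / sum(mask)
      }
      as.numeric(stats::rmultinom(1, depth, p))
    }, numeric(n_fractions)))
    dimnames(ab) <- list(ids, paste0("fraction", seq_len(n_fractions)))
    structure(list(abundance = ab, polysome_mask = mask),
              class = "polysome_profile")
  })
}
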