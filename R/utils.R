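#' Derive a reproducible sub-stream seed
#'
#' One user-facing seed drives several independent simulated quantities
#' (reads, cleavage profiles, cohorts, ...). Each quantity draws from its own
#' stream, derived deterministically from the global seed and a purpose
#' label, so adding a new simulated quantity never perturbs existing ones.
#'
#' @param seed Integer global seed.
#' @param purpose Character label naming the stream.
#' @return An integer seed below 2^31.
#' @examples
#' split_seed(1, "reads")
#' @export
split_seed <- function(seed, purpose) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.character(purpose))
  s <- as.double(seed) %% 2147483647
  for (code in utf8ToInt(purpose)) {
    s <- (s * 31 + code) %% 2147483647
  }
  as.integer(s)
}

# Run expr under a local RNG state seeded with `seed`, restoring the caller's
# state afterwards.
with_local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# NB draw parameterised by mean and dispersion alpha (variance = mu + alpha mu^2).
rnbinom_mu_alpha <- function(n, mu, alpha) {
  if (alpha <= 0) return(stats::rpois(n, mu))
  stats::rnbinom(n, mu = mu, size = 1 / alpha)
}

# DNA -> RNA (and uppercase) normalisation used across all sequence input.
as_rna <- function(x) chartr("T", "U", toupper(x))

is_rna_alphabet <- function(x) !grepl("[^ACGU]", x)
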