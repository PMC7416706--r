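# Synthetic repertoire generator: clonotype tables with controlled clonal
# expansion structure, V/J usage bias, CDR3 length spectrum, programmed
# sequence convergence and longitudinal expansion/contraction dynamics.
# CDR3 sequences are unconstrained random codon strings (no V(D)J
# recombination model) — sufficient for testing counting and statistics.

# sense (non-stop) codons of the standard genetic code
sense_codons <- function() {
  bases <- c("A", "C", "G", "T")
  all <- as.vector(outer(outer(bases, bases, paste0), bases, paste0))
  setdiff(all, c("TAA", "TAG", "TGA"))
}

STOP_CODONS <- c("TAA", "TAG", "TGA")
# codon families whose third position is 4-fold degenerate: any third base
# keeps the amino acid, so a substitution there is guaranteed synonymous
FOURFOLD_PREFIXES <- c("TC", "CT", "CC", "CG", "AC", "GT", "GC", "GG")

default_v_usage <- function() {
  v <- c(TRBV27 = 18, `TRBV5-8` = 14, TRBV19 = 12, TRBV13 = 10, TRBV18 = 9,
         `TRBV6-2` = 8, `TRBV7-9` = 7, `TRBV20-1` = 6, TRBV28 = 6,
         `TRBV29-1` = 5, TRBV2 = 3, TRBV30 = 2)
  v / sum(v)
}

default_j_usage <- function() {
  j <- c(`TRBJ2-1` = 18, `TRBJ2-7` = 16, `TRBJ2-3` = 12, `TRBJ1-1` = 11,
         `TRBJ1-2` = 10, `TRBJ2-5` = 9, `TRBJ1-5` = 8, `TRBJ2-2` = 6,
         `TRBJ1-4` = 4, `TRBJ1-6` = 3, `TRBJ1-3` = 2, `TRBJ2-4` = 1)
  j / sum(j)
}

# discretized Gaussian over in-frame CDR3 nt lengths, peaked at 45 bp (the
# conventional human TRB modal length)
default_length_dist <- function() {
  len <- seq(30L, 60L, by = 3L)
  p <- stats::dnorm(len, mean = 45, sd = 6)
  stats::setNames(p / sum(p), len)
}

check_prob <- function(p, what) {
  if (any(p < 0) || abs(sum(p) - 1) > 1e-9 || is.null(names(p))) {
    stop(sprintf("%s must be a named probability vector summing to 1", what),
         call. = FALSE)
  }
}

#' Simulation parameters for a synthetic repertoire
#'
#' The stated world of the generator: clone abundances follow a power-law
#' over clone rank (p_i proportional to i^-alpha, default alpha = 1 — the
#' heavy-tailed look of real clonotype frequency plots), a lognormal, or a
#' uniform model; V/J segments and CDR3 lengths are drawn from explicit
#' usage distributions (defaults: a skewed TRBV/TRBJ panel and a length
#' spectrum peaked at 45 bp); a `convergence_rate` fraction of clones is
#' duplicated with a synonymous nucleotide variant (same amino acid,
#' substitution at a 4-fold degenerate third codon position); a
#' `nonproductive_fraction` of clones receives an in-frame stop.
#'
#' @param n_clones number of base clones (>= 1).
#' @param depth total reads allocated multinomially over clones.
#' @param abundance `"power_law"`, `"lognormal"` or `"uniform"`.
#' @param alpha power-law exponent (abundance = "power_law").
#' @param sigma lognormal sd on the log scale (abundance = "lognormal").
#' @param v_usage,j_usage named probability vectors over segment labels.
#' @param cdr3_length_dist named probability vector over nt lengths
#'   (multiples of 3 for productive clones).
#' @param convergence_rate fraction of clones duplicated with a synonymous
#'   variant, in `[0, 1]`.
#' @param nonproductive_fraction fraction of clones given an in-frame stop.
#' @param seed integer seed; every draw derives from it.
#' @return object of class `simulation_params`.
#' @export
simulation_params <- function(n_clones = 200L, depth = 50000L,
                              abundance = c("power_law", "lognormal",
                                            "uniform"),
                              alpha = 1, sigma = 1,
                              v_usage = default_v_usage(),
                              j_usage = default_j_usage(),
                              cdr3_length_dist = default_length_dist(),
                              convergence_rate = 0,
                              nonproductive_fraction = 0, seed = 1L) {
  abundance <- match.arg(abundance)
  stopifnot(n_clones >= 1L, depth >= 1L,
            convergence_rate >= 0, convergence_rate <= 1,
            nonproductive_fraction >= 0, nonproductive_fraction <= 1)
  check_prob(v_usage, "v_usage")
  check_prob(j_usage, "j_usage")
  check_prob(cdr3_length_dist, "cdr3_length_dist")
  structure(list(n_clones = as.integer(n_clones), depth = as.integer(depth),
                 abundance = abundance, alpha = alpha, sigma = sigma,
                 v_usage = v_usage, j_usage = j_usage,
                 cdr3_length_dist = cdr3_length_dist,
                 convergence_rate = convergence_rate,
                 nonproductive_fraction = nonproductive_fraction,
                 seed = as.integer(seed)),
            class = "simulation_params")
}

random_cdr3 <- function(n_codons) {
  paste(sample(sense_codons(), n_codons, replace = TRUE), collapse = "")
}

# synonymous variant: substitute the third base of the first 4-fold
# degenerate codon; NA when the sequence has none
synonymous_variant <- function(nt) {
  n3 <- nchar(nt) %/% 3L
  starts <- 3L * seq_len(n3) - 2L
  prefixes <- substring(nt, starts, starts + 1L)
  hit <- which(prefixes %in% FOURFOLD_PREFIXES)
  if (!length(hit)) return(NA_character_)
  pos <- starts[hit[1L]] + 2L
  old <- substring(nt, pos, pos)
  new <- sample(setdiff(c("A", "C", "G", "T"), old), 1L)
  paste0(substring(nt, 1L, pos - 1L), new, substring(nt, pos + 1L))
}

# Deterministic clone pool shared by all draws of a longitudinal design:
# sequences, segment calls and pre-normalisation abundance weights.
simulate_clone_pool <- function(params) {
  stopifnot(inherits(params, "simulation_params"))
  withr::with_seed(params$seed, {
    n <- params$n_clones
    weights <- switch(params$abundance,
                      power_law = seq_len(n)^(-params$alpha),
                      lognormal = exp(stats::rnorm(n, 0, params$sigma)),
                      uniform = base::rep(1, n))
    v <- sample(names(params$v_usage), n, replace = TRUE,
                prob = params$v_usage)
    j <- sample(names(params$j_usage), n, replace = TRUE,
                prob = params$j_usage)
    len <- as.integer(sample(names(params$cdr3_length_dist), n,
                             replace = TRUE,
                             prob = params$cdr3_length_dist))
    nt <- character(n)
    seen <- new.env(hash = TRUE)
    for (i in seq_len(n)) {
      repeat {
        s <- random_cdr3(len[i] %/% 3L)
        if (is.null(seen[[s]])) break
      }
      seen[[s]] <- TRUE
      nt[i] <- s
    }
    # in-frame stop for the non-productive fraction
    n_bad <- round(params$nonproductive_fraction * n)
    if (n_bad > 0L) {
      bad <- sample.int(n, n_bad)
      for (i in bad) {
        codon_idx <- sample.int(nchar(nt[i]) %/% 3L, 1L)
        pos <- 3L * codon_idx - 2L
        nt[i] <- paste0(substring(nt[i], 1L, pos - 1L),
                        sample(STOP_CODONS, 1L),
                        substring(nt[i], pos + 3L))
      }
    }
    # programmed convergence: duplicate selected productive clones with a
    # synonymous variant (new clone, same amino acid, distinct nucleotide)
    n_conv <- round(params$convergence_rate * n)
    if (n_conv > 0L) {
      productive <- which(!grepl("[*_]", translate_cdr3(nt)))
      pick <- utils::head(productive, 0L)
      if (length(productive)) {
        pick <- sample(productive, min(n_conv, length(productive)))
      }
      for (i in pick) {
        var <- synonymous_variant(nt[i])
        if (is.na(var) || !is.null(seen[[var]])) next
        seen[[var]] <- TRUE
        nt <- c(nt, var)
        v <- c(v, v[i])
        j <- c(j, j[i])
        weights <- c(weights, weights[i])
      }
    }
    list(cdr3_nt = nt, cdr3_aa = translate_cdr3(nt), v_gene = v, j_gene = j,
         weights = weights, params = params)
  })
}

# multinomial read draw from a clone pool; zero-count clones dropped
draw_reads <- function(pool, depth, seed, sample_id) {
  counts <- withr::with_seed(as.integer(seed), {
    as.vector(stats::rmultinom(1L, depth, pool$weights / sum(pool$weights)))
  })
  keep <- counts > 0L
  rec <- clonotype_records(pool$cdr3_nt[keep], pool$cdr3_aa[keep],
                           pool$v_gene[keep], pool$j_gene[keep],
                           counts[keep])
  build_repertoire(rec, key_mode = "nt+vj", sample_id = sample_id)
}

#' Simulate a clonotype repertoire
#'
#' Draws a clone pool under `params` and allocates `depth` reads
#' multinomially over the (normalised) clone abundances; clones receiving
#' zero reads are dropped. Fully reproducible from `params$seed`.
#'
#' @param params a [simulation_params()] object.
#' @param sample_id sample label for the resulting repertoire.
#' @return a `repertoire` (key mode `nt+vj`) with the generating `params`
#'   attached as attribute `sim_params`.
#' @export
simulate_repertoire <- function(params = simulation_params(),
                                sample_id = "sim") {
  pool <- simulate_clone_pool(params)
  rep <- draw_reads(pool, params$depth, derive_seeds(params$seed, 1L),
                    sample_id)
  attr(rep, "sim_params") <- params
  rep
}

#' Longitudinal simulation script
#'
#' A base clone pool plus an ordered list of timepoints, each multiplying
#' the abundance weights of selected clones by a fold change (> 1 expands,
#' < 1 contracts) before renormalising and re-drawing reads. Clone
#' identity (nucleotide sequence, V/J) is preserved across timepoints so
#' tracking and overlap analyses can follow the programmed clones.
#'
#' @param base a [simulation_params()] object.
#' @param timepoints list of `list(label =, fold =)` entries where `fold`
#'   is a named numeric vector mapping base clone index (1..n_clones) to a
#'   positive fold change; an empty `fold` leaves the timepoint at base
#'   abundances.
#' @return object of class `longitudinal_script`.
#' @export
longitudinal_script <- function(base, timepoints) {
  stopifnot(inherits(base, "simulation_params"), length(timepoints) >= 1L)
  for (tp in timepoints) {
    stopifnot(is.character(tp$label), length(tp$label) == 1L)
    fold <- tp$fold %||% numeric()
    if (length(fold)) {
      ids <- as.integer(names(fold))
      if (any(is.na(ids)) || any(ids < 1L) || any(ids > base$n_clones)) {
        stop("fold-change names must be base clone indices", call. = FALSE)
      }
      if (any(fold <= 0)) stop("fold changes must be > 0", call. = FALSE)
    }
  }
  structure(list(base = base, timepoints = timepoints),
            class = "longitudinal_script")
}

#' Simulate a longitudinal repertoire series
#'
#' @param script a [longitudinal_script()].
#' @return named list of `repertoire`s, one per timepoint, in script order;
#'   each carries attribute `expanded_ids` (the base clone indices whose
#'   weights were modified at that timepoint).
#' @export
simulate_longitudinal <- function(script) {
  stopifnot(inherits(script, "longitudinal_script"))
  pool <- simulate_clone_pool(script$base)
  seeds <- derive_seeds(script$base$seed + 1L, length(script$timepoints))
  out <- vector("list", length(script$timepoints))
  labels <- vapply(script$timepoints, function(tp) tp$label, character(1L))
  for (i in seq_along(script$timepoints)) {
    tp <- script$timepoints[[i]]
    w <- pool$weights
    fold <- tp$fold %||% numeric()
    if (length(fold)) {
      ids <- as.integer(names(fold))
      w[ids] <- w[ids] * fold
    }
    tp_pool <- pool
    tp_pool$weights <- w
    rep <- draw_reads(tp_pool, script$base$depth, seeds[i], tp$label)
    attr(rep, "expanded_ids") <- as.integer(names(fold))
    out[[i]] <- rep
  }
  stats::setNames(out, labels)
}
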