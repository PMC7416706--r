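# Independent brute-force oracles: explicit per-clone loops, no shared code
# with the implementation under test.

oracle_diversity <- function(index, counts) {
  total <- sum(counts)
  p <- counts / total
  s <- length(counts)
  H <- 0
  for (pi in p) H <- H - pi * log(pi)
  sum_p2 <- 0
  for (pi in p) sum_p2 <- sum_p2 + pi^2
  if (index == "shannon") return(H)
  if (index == "normalized_shannon") return(if (s == 1) 0 else H / log(s))
  if (index == "inverse_simpson") return(1 / sum_p2)
  if (index == "gini_simpson") return(1 - sum_p2)
  if (index == "clonality") return(if (s == 1) 1 else 1 - H / log(s))
  if (index == "chao1") {
    f1 <- 0; f2 <- 0
    for (c in counts) {
      if (c == 1) f1 <- f1 + 1
      if (c == 2) f2 <- f2 + 1
    }
    if (f2 > 0) return(s + f1^2 / (2 * f2))
    return(s + f1 * (f1 - 1) / (2 * (f2 + 1)))
  }
  if (index == "d50") {
    ps <- sort(p, decreasing = TRUE)
    acc <- 0
    for (i in seq_along(ps)) {
      acc <- acc + ps[i]
      if (acc >= 0.5) return(i)
    }
  }
  stop("unknown index")
}

# similarity over two key -> freq maps (named numeric vectors)
oracle_similarity <- function(index, fa, fb) {
  keys <- union(names(fa), names(fb))
  p <- q <- numeric(length(keys))
  for (i in seq_along(keys)) {
    k <- keys[i]
    if (k %in% names(fa)) p[i] <- fa[[k]]
    if (k %in% names(fb)) q[i] <- fb[[k]]
  }
  n_shared <- 0; n_a <- 0; n_b <- 0
  spq <- 0; sp2 <- 0; sq2 <- 0; sroot <- 0
  for (i in seq_along(keys)) {
    if (p[i] > 0) n_a <- n_a + 1
    if (q[i] > 0) n_b <- n_b + 1
    if (p[i] > 0 && q[i] > 0) n_shared <- n_shared + 1
    spq <- spq + p[i] * q[i]
    sp2 <- sp2 + p[i]^2
    sq2 <- sq2 + q[i]^2
    sroot <- sroot + sqrt(p[i] * q[i])
  }
  switch(index,
         jaccard = n_shared / (n_a + n_b - n_shared),
         overlap_coefficient = n_shared / min(n_a, n_b),
         morisita_horn = 2 * spq / (sp2 + sq2),
         bhattacharyya = sroot)
}

# per-clone scan over homeostasis bins (lower < freq <= upper)
oracle_homeostasis_mass <- function(freqs, edges) {
  lower <- c(0, edges[-length(edges)])
  mass <- numeric(length(edges))
  for (f in freqs) {
    for (b in seq_along(edges)) {
      if (f > lower[b] && f <= edges[b]) {
        mass[b] <- mass[b] + f
        break
      }
    }
  }
  mass
}

# naive O(n^3) agglomerative clustering; returns merge heights and member
# sets in merge order
oracle_agglomerate <- function(d, linkage) {
  clusters <- lapply(seq_len(nrow(d)), function(i) i)
  merges <- list()
  while (length(clusters) > 1L) {
    best <- c(NA, NA); best_h <- Inf
    for (i in seq_len(length(clusters) - 1L)) {
      for (j in seq(i + 1L, length(clusters))) {
        pair_d <- d[clusters[[i]], clusters[[j]], drop = FALSE]
        h <- switch(linkage, average = mean(pair_d),
                    complete = max(pair_d), single = min(pair_d))
        if (h < best_h - 1e-12) {
          best_h <- h
          best <- c(i, j)
        }
      }
    }
    merged <- sort(c(clusters[[best[1]]], clusters[[best[2]]]))
    merges[[length(merges) + 1L]] <-
      list(height = best_h, members = merged)
    clusters <- c(clusters[-best], list(merged))
  }
  merges
}

# independent resampling oracle: sample read indices without replacement
oracle_rarefied_shannon <- function(counts, depth, n_resamples) {
  reads <- base::rep(seq_along(counts), counts)
  vals <- numeric(n_resamples)
  for (r in seq_len(n_resamples)) {
    drawn <- table(sample(reads, depth, replace = FALSE))
    vals[r] <- oracle_diversity("shannon", as.numeric(drawn))
  }
  vals
}

# brute-force convergent-recombination degeneracy via nested loops
oracle_convergence <- function(nt_a, aa_a, nt_b, aa_b, scope = "shared_aa") {
  aas <- if (scope == "shared_aa") {
    intersect(unique(aa_a), unique(aa_b))
  } else {
    union(unique(aa_a), unique(aa_b))
  }
  res <- list()
  for (aa in sort(aas)) {
    va <- character(); vb <- character()
    for (i in seq_along(nt_a)) if (aa_a[i] == aa) va <- union(va, nt_a[i])
    for (i in seq_along(nt_b)) if (aa_b[i] == aa) vb <- union(vb, nt_b[i])
    res[[aa]] <- c(a = length(va), b = length(vb),
                   pooled = length(union(va, vb)))
  }
  res
}
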