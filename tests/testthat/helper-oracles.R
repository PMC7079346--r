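# Independent brute-force oracles. These deliberately avoid the package's
# own code paths (and, where possible, the library routines they wrap).

# connected components by explicit flood fill over an edge list
oracle_components <- function(nodes, edges_a, edges_b) {
  comp <- stats::setNames(rep(NA_integer_, length(nodes)), nodes)
  nbr <- function(v) unique(c(edges_b[edges_a == v], edges_a[edges_b == v]))
  k <- 0L
  for (v in nodes) {
    if (!is.na(comp[[v]])) next
    k <- k + 1L
    queue <- v
    while (length(queue)) {
      u <- queue[[1L]]; queue <- queue[-1L]
      if (!is.na(comp[[u]])) next
      comp[[u]] <- k
      queue <- c(queue, nbr(u))
    }
  }
  # canonical form: sorted member sets, ordered by smallest member
  cl <- unname(split(names(comp), comp))
  cl <- lapply(cl, sort)
  cl[order(vapply(cl, `[`, "", 1L))]
}

# exhaustive affine-gap global alignment score by dynamic programming
# (Gotoh three-state recursion written independently; gap of length L costs
# open + L * ext, matching the package's parameterization)
oracle_nw_score <- function(a, b, open = 10, ext = 0.5, matrix_name = "BLOSUM62") {
  data(list = matrix_name, package = "Biostrings", envir = environment())
  S <- get(matrix_name, envir = environment())
  x <- strsplit(a, "")[[1]]; y <- strsplit(b, "")[[1]]
  n <- length(x); m <- length(y)
  NEG <- -1e18
  M <- matrix(NEG, n + 1, m + 1); Ix <- M; Iy <- M
  M[1, 1] <- 0
  for (i in seq_len(n)) Ix[i + 1, 1] <- -(open + ext * i)
  for (j in seq_len(m)) Iy[1, j + 1] <- -(open + ext * j)
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      s <- S[x[i], y[j]]
      M[i + 1, j + 1] <- max(M[i, j], Ix[i, j], Iy[i, j]) + s
      Ix[i + 1, j + 1] <- max(M[i, j + 1] - open - ext,
                              Ix[i, j + 1] - ext)
      Iy[i + 1, j + 1] <- max(M[i + 1, j] - open - ext,
                              Iy[i + 1, j] - ext)
    }
  }
  max(M[n + 1, m + 1], Ix[n + 1, m + 1], Iy[n + 1, m + 1])
}

# column conservation by set algebra over per-entry property sets
oracle_score_column <- function(column, table = default_property_table()) {
  sets <- lapply(column, function(ch) {
    if (ch %in% c("-", ".", "X")) character(0)
    else names(table)[vapply(table, function(p) ch %in% p, NA)]
  })
  inter <- Reduce(intersect, sets)
  uni <- Reduce(union, sets)
  n_cons <- length(inter) + length(setdiff(names(table), uni))
  gapfree <- !any(column %in% c("-", "."))
  if (gapfree && length(unique(column)) == 1L && column[[1L]] != "X") 11L
  else as.integer(n_cons)
}

# Poisson upper tail by naive term summation (term recurrence, no ppois)
oracle_poisson_tail <- function(obs, lambda, n_terms = max(200, 5 * obs)) {
  if (obs == 0) return(1)
  # P(X >= obs) = 1 - sum_{k<obs} term_k for head; sum tail terms directly
  term <- exp(-lambda)  # k = 0
  tail_sum <- 0
  for (k in seq_len(obs + n_terms)) {
    term <- term * lambda / k
    if (k >= obs) tail_sum <- tail_sum + term
  }
  tail_sum + if (obs == 0) exp(-lambda) else 0
}

# Rand / adjusted Rand by explicit pair enumeration
oracle_rand <- function(p, o) {
  n <- length(p)
  agree <- 0; together_both <- 0; rowpairs <- 0; colpairs <- 0
  npairs <- 0
  for (i in seq_len(n - 1)) {
    for (j in seq.int(i + 1, n)) {
      npairs <- npairs + 1
      same_p <- p[i] == p[j]; same_o <- o[i] == o[j]
      if (same_p == same_o) agree <- agree + 1
      if (same_p && same_o) together_both <- together_both + 1
      if (same_p) rowpairs <- rowpairs + 1
      if (same_o) colpairs <- colpairs + 1
    }
  }
  exp_s <- rowpairs * colpairs / npairs
  denom <- (rowpairs + colpairs) / 2 - exp_s
  list(rand = agree / npairs,
       ari = if (denom == 0) 1 else (together_both - exp_s) / denom)
}

# exact two-sided rank-sum p by enumerating all group assignments
oracle_wilcoxon_exact <- function(za, zb) {
  n1 <- length(za); n2 <- length(zb)
  vals <- c(za, zb)
  r <- rank(vals)
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  combs <- utils::combn(n1 + n2, n1)
  us <- apply(combs, 2, function(idx) sum(r[idx]) - n1 * (n1 + 1) / 2)
  p <- 2 * min(mean(us <= u_obs), mean(us >= u_obs))
  min(p, 1)
}

# leftmost minimal variant representation by exhaustive search over all
# equivalent (pos, ref, alt) encodings within the window: applying the
# variant to the window fixes the mutated haplotype, and for a given
# position and ref length the alt string is then fully determined
oracle_normalize <- function(chrom, pos, ref, alt, win, win_start) {
  L <- nchar(win)
  apply_variant <- function(p, r, a) {
    i <- p - win_start + 1
    if (i < 1 || i + nchar(r) - 1 > L) return(NULL)
    if (substr(win, i, i + nchar(r) - 1) != r) return(NULL)
    paste0(substr(win, 1, i - 1), a, substr(win, i + nchar(r), L))
  }
  target <- apply_variant(pos, ref, alt)
  stopifnot(!is.null(target))
  best <- NULL
  for (p in seq(win_start, win_start + L - 1)) {
    i <- p - win_start + 1
    if (substr(win, 1, i - 1) != substr(target, 1, i - 1)) next
    for (lr in seq_len(L - i + 1)) {
      la <- nchar(target) - L + lr
      if (la < 1) next
      r <- substr(win, i, i + lr - 1)
      a <- substr(target, i, i + la - 1)
      if (identical(r, a)) next
      if (!identical(apply_variant(p, r, a), target)) next
      # parsimony first (shortest alleles), then leftmost position
      cand <- list(pos = p, ref = r, alt = a,
                   size = nchar(r) + nchar(a))
      if (is.null(best) || cand$size < best$size ||
          (cand$size == best$size && cand$pos < best$pos))
        best <- cand
    }
  }
  best
}

# deterministic tiny fixture shared across tests
toy_family <- function(seed = 1) {
  simulate_family(4, data.frame(length = c(30, 20),
                                divergence = c(0.02, 0.6)),
                  seed = seed, family_id = "TOY")
}
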