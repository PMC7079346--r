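#' Compare paralog and ortholog conservation for one gene
#'
#' Treats the two boolean conservation vectors as binary partitions of the
#' gene's residue positions and computes the Rand index, the adjusted Rand
#' index (Hubert-Arabie), and the Pearson correlation of the 0/1 vectors,
#' together with the 2x2 position counts (conserved in both, paralog only,
#' ortholog only, neither).
#'
#' If either vector has zero variance the correlation is undefined: it is
#' reported as `NA` with `pearson_defined = FALSE`; the Rand indices are
#' still computed.
#'
#' @param paralog_flags,ortholog_flags Logical (or 0/1) vectors of equal
#'   length >= 2.
#' @param gene_id Optional gene symbol carried into the result.
#' @return Object of class `conservation_comparison`: list with `gene_id`,
#'   `n`, `counts` (named both/paralog_only/ortholog_only/neither),
#'   `rand_index`, `adjusted_rand`, `pearson_r`, `pearson_defined`.
#' @examples
#' compare_conservation(c(TRUE, TRUE, FALSE, FALSE),
#'                      c(TRUE, FALSE, TRUE, FALSE))
#' @export
compare_conservation <- function(paralog_flags, ortholog_flags,
                                 gene_id = NA_character_) {
  p <- as.logical(paralog_flags); o <- as.logical(ortholog_flags)
  if (length(p) != length(o))
    stop("flag vectors differ in length (", length(p), " vs ", length(o), ")")
  n <- length(p)
  if (n < 2L) stop("need at least 2 positions")
  if (anyNA(p) || anyNA(o)) stop("flags contain NA")
  n11 <- sum(p & o); n10 <- sum(p & !o); n01 <- sum(!p & o); n00 <- sum(!p & !o)
  tab <- c(n11, n10, n01, n00)
  S <- sum(choose(tab, 2))                       # pairs together in both
  R <- choose(n11 + n10, 2) + choose(n01 + n00, 2)   # row sums (paralog)
  C <- choose(n11 + n01, 2) + choose(n10 + n00, 2)   # col sums (ortholog)
  Tn <- choose(n, 2)
  rand <- (Tn - R - C + 2 * S) / Tn
  exp_s <- R * C / Tn
  denom <- (R + C) / 2 - exp_s
  ari <- if (denom == 0) 1 else (S - exp_s) / denom
  defined <- stats::sd(p) > 0 && stats::sd(o) > 0
  r <- if (defined) stats::cor(as.numeric(p), as.numeric(o)) else NA_real_
  structure(list(gene_id = gene_id, n = n,
                 counts = c(both = n11, paralog_only = n10,
                            ortholog_only = n01, neither = n00),
                 rand_index = rand, adjusted_rand = ari,
                 pearson_r = r, pearson_defined = defined),
            class = "conservation_comparison")
}

#' @export
print.conservation_comparison <- function(x, ...) {
  cat(sprintf(
    "<conservation_comparison>%s n=%d  RI=%.4f  ARI=%.4f  r=%s\n",
    if (is.na(x$gene_id)) "" else paste0(" ", x$gene_id), x$n,
    x$rand_index, x$adjusted_rand,
    if (x$pearson_defined) sprintf("%.4f", x$pearson_r) else "undefined"))
  print(x$counts)
  invisible(x)
}
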