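#' Log-space Poisson upper tail
#'
#' `P(X >= observed | X ~ Poisson(lambda))`, computed in log space via the
#' incomplete-gamma relation underlying [stats::ppois()], so that the result
#' is meaningful far below double-precision underflow (p-values of 1e-58 and
#' far smaller arise in family burden testing). The returned `p` is
#' `exp(log p)` and underflows to 0 below ~5e-324; `log10_p` stays finite and
#' exact there and is the representation downstream code compares.
#'
#' @param observed Non-negative integer count.
#' @param lambda Expected count, > 0.
#' @return List with `p` (numeric in \[0, 1\]) and `log10_p`.
#' @examples
#' poisson_upper_tail(3, 1)$p        # 1 - e^-1 (1 + 1 + 1/2)
#' poisson_upper_tail(45, 0.96)$log10_p
#' @export
poisson_upper_tail <- function(observed, lambda) {
  stopifnot(length(observed) == 1L, length(lambda) == 1L)
  if (!is.finite(lambda) || lambda <= 0) stop("lambda must be > 0")
  if (observed < 0 || observed != round(observed))
    stop("observed must be a non-negative integer")
  if (observed == 0) return(list(p = 1, log10_p = 0))
  lp <- stats::ppois(observed - 1, lambda, lower.tail = FALSE, log.p = TRUE)
  list(p = exp(lp), log10_p = lp / log(10))
}

#' Bonferroni configuration for family burden testing
#'
#' The significance threshold is `alpha / (n_categories * n_families)`,
#' e.g. 0.05 / (5 x 2871) = 3.48e-6 for five test categories over 2871
#' sub-families.
#'
#' @param alpha Family-wise error rate (default 0.05).
#' @param n_categories Number of test categories (default 5).
#' @param n_families Number of families tested.
#' @return Object of class `multiplicity_config` with a `threshold` field.
#' @export
multiplicity_config <- function(alpha = 0.05, n_categories = 5, n_families) {
  stopifnot(alpha > 0, alpha < 1, n_categories >= 1, n_families >= 1)
  structure(list(alpha = alpha, n_categories = n_categories,
                 n_families = n_families,
                 threshold = alpha / (n_categories * n_families)),
            class = "multiplicity_config")
}

#' Remove de novo variants present in a reference panel
#'
#' Emulates the exclusion of de novo variants also observed as standing
#' variation in a large adult reference panel (ExAC-style). Records carrying
#' a genomic key (`chrom`, `pos`, `ref`, `alt`; assumed normalized, see
#' [normalize_variant()]) match on `chrom:pos:ref:alt`; records without one
#' match on `gene:aa_ref:protein_position:aa_alt`.
#'
#' @param dnms Data frame of de novo records (see [read_dnms()]).
#' @param panel Character vector of normalized keys in either format.
#' @return The filtered data frame, with an attribute `removed_per_gene`
#'   (table of removal counts).
#' @export
filter_reference_panel <- function(dnms, panel) {
  if (!length(panel) || !nrow(dnms)) {
    attr(dnms, "removed_per_gene") <- table(character(0))
    return(dnms)
  }
  keys <- dnm_keys(dnms)
  hit <- keys %in% panel
  out <- dnms[!hit, , drop = FALSE]
  attr(out, "removed_per_gene") <- table(dnms$gene[hit])
  out
}

dnm_keys <- function(dnms) {
  has_genomic <- if (all(c("chrom", "pos", "ref", "alt") %in% names(dnms)))
    !is.na(dnms$chrom) & !is.na(dnms$pos) else rep(FALSE, nrow(dnms))
  keys <- character(nrow(dnms))
  keys[has_genomic] <- paste(dnms$chrom[has_genomic], dnms$pos[has_genomic],
                             dnms$ref[has_genomic], dnms$alt[has_genomic],
                             sep = ":")
  keys[!has_genomic] <- paste(dnms$gene[!has_genomic],
                              dnms$aa_ref[!has_genomic],
                              dnms$protein_position[!has_genomic],
                              dnms$aa_alt[!has_genomic], sep = ":")
  keys
}

#' Site class of a missense de novo variant
#'
#' A missense variant is `"conserved"` when the paralog conservation flag of
#' the mutated residue is `TRUE` (para_zscore strictly > 0), otherwise
#' `"nonconserved"`. When the record carries `aa_ref`, it must match the
#' track's residue at that position; a mismatch signals isoform drift and is
#' an error.
#'
#' @param dnm One-row data frame (or list) with `gene`, `protein_position`
#'   and optionally `aa_ref`.
#' @param track The gene's [zscore_track()] result.
#' @return `"conserved"` or `"nonconserved"`.
#' @export
assign_site_class <- function(dnm, track) {
  pos <- dnm$protein_position
  if (is.na(pos) || pos < 1L || pos > nrow(track$track))
    stop("protein position ", pos, " out of range for gene ", track$gene_id,
         " (track length ", nrow(track$track), ")")
  aa <- dnm$aa_ref
  if (!is.null(aa) && !is.na(aa) && !is.na(track$track$residue[pos]) &&
      aa != track$track$residue[pos])
    stop("aa_ref mismatch for gene ", track$gene_id, " position ", pos,
         ": record says ", aa, ", track says ", track$track$residue[pos])
  if (track$track$conserved[pos]) "conserved" else "nonconserved"
}

PTV_CLASSES <- c("nonsense", "frameshift", "splice")

#' Family-wise Poisson burden tests
#'
#' For each sub-family and test category, compares the observed de novo
#' count (summed over family members) with the family expectation using the
#' log-space Poisson upper tail, and applies a Bonferroni threshold of
#' `alpha / (n_categories * n_families)`.
#'
#' Default categories: `ptv` (nonsense + frameshift + splice over the whole
#' sequence), `missense`, `missense_conserved`, `missense_nonconserved`
#' (site-class analyses), and `missense_ptv_conserved` (PTV anywhere plus
#' missense at paralog-conserved sites — the primary discovery category).
#'
#' @param expectations [expectation_df()]-format data frame with per-gene
#'   expectations; genes absent from `membership` are ignored.
#' @param dnms De novo records (see [read_dnms()]), already filtered against
#'   the reference panel. Records in genes without family membership are
#'   counted and reported in the `unassigned` attribute, not silently
#'   dropped.
#' @param membership Data frame `subfamily_id`, `gene_id` (see
#'   [write_subfamilies()]).
#' @param tracks Named list of [zscore_track()] results for site-class
#'   assignment of missense records.
#' @param config A [multiplicity_config()]; `n_families` defaults to the
#'   number of sub-families in `membership`.
#' @param categories Character vector of categories to test.
#' @return Data frame of class `burden_result`, one row per family x
#'   category, sorted by p-value: `subfamily_id`, `category`, `observed`,
#'   `expected`, `p_value`, `log10_p`, `significant`, `genes` (per-gene
#'   observed breakdown) plus one `obs_<cohort>` column per cohort present.
#' @export
family_burden_test <- function(expectations, dnms, membership,
                               tracks = list(), config = NULL,
                               categories = c("ptv", "missense",
                                              "missense_conserved",
                                              "missense_nonconserved",
                                              "missense_ptv_conserved")) {
  stopifnot(all(c("subfamily_id", "gene_id") %in% names(membership)))
  if (is.null(config))
    config <- multiplicity_config(
      n_families = length(unique(membership$subfamily_id)))
  fam_of <- stats::setNames(membership$subfamily_id, membership$gene_id)
  if (nrow(dnms)) {
    known <- dnms$gene %in% names(fam_of)
    unassigned <- dnms[!known, , drop = FALSE]
    if (nrow(unassigned))
      warning(nrow(unassigned), " de novo record(s) in genes without family ",
              "membership were set aside", call. = FALSE)
    dnms <- dnms[known, , drop = FALSE]
  } else unassigned <- dnms
  # site class per missense record (vectorized per gene; same rule as
  # assign_site_class, which remains the per-record contract)
  site <- rep(NA_character_, nrow(dnms))
  mis <- which(dnms$consequence == "missense")
  for (g in unique(dnms$gene[mis])) {
    tr <- tracks[[g]]
    if (is.null(tr)) next  # stays NA: counted in missense, not by site class
    idx <- mis[dnms$gene[mis] == g]
    pos <- dnms$protein_position[idx]
    if (anyNA(pos) || any(pos < 1L | pos > nrow(tr$track)))
      stop("protein position out of range for gene ", g,
           " (track length ", nrow(tr$track), ")")
    if ("aa_ref" %in% names(dnms)) {
      aa <- dnms$aa_ref[idx]
      res <- tr$track$residue[pos]
      bad <- !is.na(aa) & !is.na(res) & aa != res
      if (any(bad))
        stop("aa_ref mismatch for gene ", g, " position ",
             pos[which(bad)[1L]])
    }
    site[idx] <- ifelse(tr$track$conserved[pos], "conserved",
                        "nonconserved")
  }
  qualifies <- function(cat, d, s) switch(cat,
    ptv = d$consequence %in% PTV_CLASSES,
    missense = d$consequence == "missense",
    missense_conserved = d$consequence == "missense" &
      !is.na(s) & s == "conserved",
    missense_nonconserved = d$consequence == "missense" &
      !is.na(s) & s == "nonconserved",
    missense_ptv_conserved = d$consequence %in% PTV_CLASSES |
      (d$consequence == "missense" & !is.na(s) & s == "conserved"),
    synonymous = d$consequence == "synonymous",
    stop("unknown category: ", cat))
  expected_of <- function(cat, fam_tot) switch(cat,
    ptv = fam_tot[["ptv"]],
    missense = fam_tot[["missense"]],
    missense_conserved = fam_tot[["missense_conserved"]],
    missense_nonconserved = fam_tot[["missense_nonconserved"]],
    missense_ptv_conserved = fam_tot[["ptv"]] +
      fam_tot[["missense_conserved"]],
    synonymous = fam_tot[["synonymous"]])
  fams <- sort(unique(membership$subfamily_id))
  cohorts <- if (nrow(dnms) && "cohort" %in% names(dnms))
    sort(unique(dnms$cohort)) else character(0)
  rows <- list()
  for (f in fams) {
    genes <- membership$gene_id[membership$subfamily_id == f]
    edf <- expectations[expectations$gene_id %in% genes, , drop = FALSE]
    if (!nrow(edf)) {
      warning("no expectations for family ", f, "; skipped", call. = FALSE)
      next
    }
    missing_e <- setdiff(genes, edf$gene_id)
    if (length(missing_e))
      warning("family ", f, ": no expectation for gene(s) ",
              paste(missing_e, collapse = ","), call. = FALSE)
    tot <- family_expectation(edf)$totals
    d <- dnms[dnms$gene %in% genes, , drop = FALSE]
    s <- site[dnms$gene %in% genes]
    for (cat in categories) {
      q <- qualifies(cat, d, s)
      obs <- sum(q)
      lam <- expected_of(cat, tot)
      if (is.na(lam)) next  # category not computable (no tracks)
      if (lam > 0) {
        pt <- poisson_upper_tail(obs, lam)
      } else {
        pt <- list(p = if (obs == 0) 1 else NA_real_, log10_p = NA_real_)
      }
      per_gene <- table(factor(d$gene[q], levels = genes))
      gene_str <- paste(sprintf("%s(%d)", names(per_gene),
                                as.integer(per_gene)), collapse = ",")
      row <- data.frame(subfamily_id = f, category = cat,
                        observed = obs, expected = lam,
                        p_value = pt$p, log10_p = pt$log10_p,
                        significant = !is.na(pt$p) &
                          pt$p < config$threshold,
                        genes = gene_str, stringsAsFactors = FALSE)
      for (co in cohorts)
        row[[paste0("obs_", co)]] <- sum(q & d$cohort == co)
      rows[[length(rows) + 1L]] <- row
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(subfamily_id = character(), category = character(),
               observed = integer(), expected = numeric(),
               p_value = numeric(), log10_p = numeric(),
               significant = logical(), genes = character(),
               stringsAsFactors = FALSE)
  out <- out[order(out$p_value, out$subfamily_id, out$category), ]
  rownames(out) <- NULL
  attr(out, "config") <- config
  attr(out, "unassigned") <- unassigned
  class(out) <- c("burden_result", class(out))
  out
}

#' Rank-sum comparison of para_zscores between two variant classes
#'
#' Two-sided Wilcoxon/Mann-Whitney rank-sum test comparing the para_zscore
#' distributions of two variant classes (e.g. missense vs synonymous).
#' Exact enumeration is used when both samples have at most 8 observations
#' and there are no ties; otherwise the normal approximation with tie
#' correction (no continuity correction) is used.
#'
#' @param za,zb Numeric vectors of para_zscores, both non-empty.
#' @return List with `statistic` (Mann-Whitney U for the first sample),
#'   `p_value`, and `method` (`"exact"` or `"normal"`).
#' @export
class_zscore_comparison <- function(za, zb) {
  if (!length(za) || !length(zb)) stop("both samples must be non-empty")
  ties <- anyDuplicated(c(za, zb)) > 0
  exact <- length(za) <= 8 && length(zb) <= 8 && !ties
  wt <- suppressWarnings(
    stats::wilcox.test(za, zb, alternative = "two.sided", exact = exact,
                       correct = FALSE))
  list(statistic = unname(wt$statistic), p_value = min(wt$p.value, 1),
       method = if (exact) "exact" else "normal")
}

#' Flag candidate disease genes
#'
#' A gene is a plausible novel disease-gene candidate when it sits in an
#' exome-wide enriched family, carries at least one de novo variant, is
#' brain expressed (RPKM strictly > 1) and is under constraint (pLI >= 0.9
#' or missense constraint z > 3.09).
#'
#' @param annotation Data frame with columns `gene_id`, `brain_rpkm`, `pli`,
#'   `missense_constraint_z` (NA fields make the gene not evaluable).
#' @param in_enriched_family,has_dnm Logical vectors (length 1 or
#'   `nrow(annotation)`).
#' @return `annotation` with added columns `candidate` (logical; `NA` when
#'   not evaluable) and `reasons` (comma-separated reason codes).
#' @export
flag_candidate_genes <- function(annotation, in_enriched_family, has_dnm) {
  n <- nrow(annotation)
  in_enriched_family <- rep_len(in_enriched_family, n)
  has_dnm <- rep_len(has_dnm, n)
  brain <- annotation$brain_rpkm > 1
  constrained <- (!is.na(annotation$pli) & annotation$pli >= 0.9) |
    (!is.na(annotation$missense_constraint_z) &
       annotation$missense_constraint_z > 3.09)
  evaluable <- !is.na(annotation$brain_rpkm) &
    !(is.na(annotation$pli) & is.na(annotation$missense_constraint_z))
  cand <- in_enriched_family & has_dnm & brain & constrained
  cand[!evaluable] <- NA
  reasons <- vapply(seq_len(n), function(i) {
    if (!evaluable[i]) return("not_evaluable")
    r <- c(if (in_enriched_family[i]) "enriched_family",
           if (has_dnm[i]) "has_dnm",
           if (isTRUE(brain[i])) "brain_expressed",
           if (!is.na(annotation$pli[i]) && annotation$pli[i] >= 0.9)
             "pli",
           if (!is.na(annotation$missense_constraint_z[i]) &&
               annotation$missense_constraint_z[i] > 3.09) "missense_z")
    if (is.null(r)) "none" else paste(r, collapse = ",")
  }, "")
  annotation$candidate <- cand
  annotation$reasons <- reasons
  annotation
}

#' Read a de novo variant table
#'
#' Expected TSV columns: `proband_id`, `cohort`, `gene`, `consequence`
#' (synonymous/missense/nonsense/frameshift/splice), `protein_position`,
#' `aa_ref`, `aa_alt`, and optionally `chrom`, `pos`, `ref`, `alt`.
#'
#' @param path TSV path.
#' @return Data frame.
#' @export
read_dnms <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("gene", "consequence") %in% names(df)))
  df
}
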