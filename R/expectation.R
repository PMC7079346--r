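#' Trinucleotide-context mutation rate tables
#'
#' A rate table maps (trinucleotide context, alternate base at the center
#' position) to a per-site, per-generation mutation probability. A complete
#' table has 64 contexts x 3 alternates = 192 entries; incomplete tables are
#' rejected unless `fallback` supplies a default rate for missing entries.
#'
#' @param path TSV with columns `context` (e.g. `"ACA"`), `alt` (single
#'   base), `rate` (scientific notation accepted).
#' @param fallback Optional default rate for missing (context, alt) entries.
#' @return Named numeric vector of class `rate_table`; names are
#'   `"<context>><alt>"`.
#' @export
read_rate_table <- function(path, fallback = NULL) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = c(context = "character",
                                         alt = "character",
                                         rate = "numeric"))
  stopifnot(all(c("context", "alt", "rate") %in% names(df)))
  rate_table(stats::setNames(df$rate, paste0(toupper(df$context), ">",
                                             toupper(df$alt))),
             fallback = fallback)
}

#' @rdname read_rate_table
#' @param rates Named numeric vector (`"ACA>G"` style names).
#' @export
rate_table <- function(rates, fallback = NULL) {
  if (any(rates < 0)) stop("negative mutation rates")
  bases <- c("A", "C", "G", "T")
  ctx <- as.vector(outer(as.vector(outer(bases, bases, paste0)), bases,
                         paste0))
  full <- unlist(lapply(ctx, function(cc)
    paste0(cc, ">", setdiff(bases, substr(cc, 2, 2)))))
  missing <- setdiff(full, names(rates))
  if (length(missing)) {
    if (is.null(fallback))
      stop("incomplete rate table (", length(missing),
           " missing entries, e.g. ", missing[[1L]],
           ") and no fallback rate configured")
    rates[missing] <- fallback
  }
  structure(rates[full], class = "rate_table")
}

#' @rdname read_rate_table
#' @param rate Single per-site per-generation rate applied to every
#'   substitution.
#' @export
uniform_rate_table <- function(rate = 1e-8) {
  rate_table(stats::setNames(numeric(0), character(0)), fallback = rate)
}

#' Write a rate table as TSV
#' @param rates A `rate_table`.
#' @param path Output TSV (`context`, `alt`, `rate`).
#' @return `path`, invisibly.
#' @export
write_rate_table <- function(rates, path) {
  parts <- strsplit(names(rates), ">", fixed = TRUE)
  df <- data.frame(context = vapply(parts, `[`, "", 1L),
                   alt = vapply(parts, `[`, "", 2L),
                   rate = as.numeric(rates), stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Cohort specification
#'
#' @param name Cohort label (e.g. `"DD"`, `"ASD"`, `"EPI"`, `"control"`).
#' @param n_trios Positive number of sequenced trios.
#' @return Object of class `cohort_spec`.
#' @export
cohort_spec <- function(name, n_trios) {
  stopifnot(is.character(name), length(name) == 1L,
            is.numeric(n_trios), n_trios > 0)
  structure(list(name = name, n_trios = as.integer(n_trios)),
            class = "cohort_spec")
}

#' Classify a single-nucleotide substitution in a CDS
#'
#' Standard-genetic-code codon comparison. Changes at a reference stop codon
#' are labelled `stoploss` (stop to non-stop) or `stop_retained` (stop to
#' stop); they are excluded from the synonymous/missense/nonsense buckets of
#' the expectation model and reported separately.
#'
#' @param cds Coding sequence (length divisible by 3, ACGT).
#' @param position 1-based nucleotide index into `cds`.
#' @param alt Alternate base, different from the reference base.
#' @return One of `"synonymous"`, `"missense"`, `"nonsense"`, `"stoploss"`,
#'   `"stop_retained"`.
#' @examples
#' classify_substitution("ATGTGGTAA", 5, "A")  # TGG -> TAG, nonsense
#' @export
classify_substitution <- function(cds, position, alt) {
  cds <- toupper(cds); alt <- toupper(alt)
  L <- nchar(cds)
  if (L %% 3L != 0L) stop("CDS length not divisible by 3")
  if (position < 1L || position > L) stop("position out of range")
  if (!alt %in% c("A", "C", "G", "T")) stop("alt must be one of ACGT")
  ref <- substr(cds, position, position)
  if (alt == ref) stop("alt equals the reference base at position ", position)
  tab <- codon_table()
  ci <- (position - 1L) %/% 3L
  codon <- substr(cds, ci * 3L + 1L, ci * 3L + 3L)
  within <- (position - 1L) %% 3L + 1L
  mut <- codon
  substr(mut, within, within) <- alt
  aa_ref <- tab[[codon]]; aa_alt <- tab[[mut]]
  if (aa_ref == "*") {
    if (aa_alt == "*") "stop_retained" else "stoploss"
  } else if (aa_alt == "*") "nonsense"
  else if (aa_alt == aa_ref) "synonymous"
  else "missense"
}

#' Expected de novo mutation counts for one gene
#'
#' Enumerates all single-nucleotide substitutions of the gene's CDS, sums
#' the trinucleotide-context rates per consequence class, and scales by
#' `2 * n_trios` (two parental haplotypes per trio):
#' `lambda_class = 2 * n_trios * sum(rates)`.
#'
#' The frameshift expectation, which cannot be derived from a CDS alone, is
#' `frameshift_mult * lambda_nonsense` (default 1.25). The PTV expectation is
#' nonsense + frameshift (+ a caller-supplied splice expectation when
#' available). With a conservation track, the missense expectation is split
#' into conserved-site and non-conserved-site portions either proportionally
#' to the site counts (`split_mode = "proportional"`, the default) or by
#' summing missense-generating rates only over codons whose residue is
#' conserved (`split_mode = "per_site"`); the two portions always sum to the
#' missense expectation.
#'
#' Terminal CDS positions lack a trinucleotide context unless 1-base flanks
#' are supplied; they fall back to the mean rate of the table (messaged).
#' The reference stop codon is excluded from the synonymous/missense/nonsense
#' buckets and reported as `stoploss`.
#'
#' @param gene A [gene_record()] with a CDS.
#' @param rates A [rate_table()].
#' @param cohort A [cohort_spec()] (or a bare number of trios).
#' @param track Optional [zscore_track()] result for the gene; its length
#'   must equal the protein length.
#' @param flank Optional list with single bases `before` and `after` giving
#'   the genomic context flanking the CDS.
#' @param split_mode `"proportional"` or `"per_site"`.
#' @param frameshift_mult Multiplier on the nonsense expectation (>= 0).
#' @param splice_lambda Optional canonical-splice expectation to add to PTV.
#' @return Object of class `gene_expectation`; see [expectation_df()].
#' @export
gene_expectation <- function(gene, rates, cohort, track = NULL,
                             flank = NULL,
                             split_mode = c("proportional", "per_site"),
                             frameshift_mult = 1.25, splice_lambda = 0) {
  split_mode <- match.arg(split_mode)
  if (is.numeric(cohort)) cohort <- cohort_spec("cohort", cohort)
  stopifnot(inherits(gene, "gene_record"), !is.null(gene$cds_seq),
            inherits(rates, "rate_table"), frameshift_mult >= 0,
            splice_lambda >= 0)
  cds <- gene$cds_seq
  L <- nchar(cds)
  n_res <- nchar(gene$protein_seq)
  if (!is.null(track)) {
    stopifnot(inherits(track, "paralog_track"))
    if (nrow(track$track) != n_res)
      stop("track length ", nrow(track$track), " != protein length ", n_res,
           " for gene ", gene$gene_id)
  }
  bases <- c("A", "C", "G", "T")
  b <- strsplit(cds, "")[[1]]
  prev <- c(if (!is.null(flank$before)) toupper(flank$before) else NA,
            b[-L])
  nxt <- c(b[-1], if (!is.null(flank$after)) toupper(flank$after) else NA)
  ctx <- paste0(prev, b, nxt)
  no_ctx <- is.na(prev) | is.na(nxt)
  if (any(no_ctx))
    message(gene$gene_id, ": ", sum(no_ctx),
            " terminal position(s) without trinucleotide context; ",
            "using mean table rate")
  mean_rate <- mean(rates)
  # enumerate the 3 alternates per position
  pos <- rep(seq_len(L), each = 3L)
  refb <- b[pos]
  altb <- unlist(lapply(b, function(x) setdiff(bases, x)), use.names = FALSE)
  key <- paste0(ctx[pos], ">", altb)
  r <- unname(rates[key])
  r[no_ctx[pos]] <- mean_rate
  cls <- vapply(seq_along(pos), function(i)
    classify_substitution(cds, pos[i], altb[i]), "")
  sums <- vapply(c("synonymous", "missense", "nonsense", "stoploss"),
                 function(k) sum(r[cls == k]), numeric(1))
  scale <- 2 * cohort$n_trios
  lam <- scale * sums
  lam_fs <- frameshift_mult * lam[["nonsense"]]
  lam_ptv <- lam[["nonsense"]] + lam_fs + splice_lambda
  mis_cons <- NA_real_; mis_noncons <- NA_real_
  n_cons <- NA_integer_; n_noncons <- NA_integer_
  if (!is.null(track)) {
    cons <- track$track$conserved
    n_cons <- sum(cons); n_noncons <- sum(!cons)
    if (split_mode == "proportional") {
      mis_cons <- lam[["missense"]] * n_cons / n_res
    } else {
      codon_of <- (pos - 1L) %/% 3L + 1L
      mis_mask <- cls == "missense"
      on_cons <- codon_of <= n_res & cons[pmin(codon_of, n_res)]
      mis_cons <- scale * sum(r[mis_mask & on_cons])
    }
    mis_noncons <- lam[["missense"]] - mis_cons
  }
  structure(list(
    gene_id = gene$gene_id, n_trios = cohort$n_trios,
    split_mode = split_mode,
    lambda = c(synonymous = lam[["synonymous"]],
               missense = lam[["missense"]],
               nonsense = lam[["nonsense"]],
               frameshift = lam_fs,
               splice = splice_lambda,
               ptv = lam_ptv,
               stoploss = lam[["stoploss"]],
               missense_conserved = mis_cons,
               missense_nonconserved = mis_noncons),
    n_conserved_sites = n_cons, n_nonconserved_sites = n_noncons),
    class = "gene_expectation")
}

#' @export
print.gene_expectation <- function(x, ...) {
  cat(sprintf("<gene_expectation> %s (n_trios=%d, %s split)\n", x$gene_id,
              x$n_trios, x$split_mode))
  print(signif(x$lambda, 4))
  invisible(x)
}

#' Flatten gene expectations into a data frame
#'
#' One row per gene with columns `gene_id`, the per-class expectations
#' (`synonymous`, `missense`, `nonsense`, `frameshift`, `splice`, `ptv`,
#' `stoploss`, `missense_conserved`, `missense_nonconserved`) and the site
#' counts `n_conserved_sites` / `n_nonconserved_sites`. This is the format
#' consumed by [family_burden_test()] and [simulate_dnms()] and written by
#' [write_expectations()].
#'
#' @param expectations List of `gene_expectation` objects (or a single one).
#' @return Data frame.
#' @export
expectation_df <- function(expectations) {
  if (inherits(expectations, "gene_expectation"))
    expectations <- list(expectations)
  do.call(rbind, lapply(expectations, function(e) {
    data.frame(gene_id = e$gene_id, t(e$lambda),
               n_conserved_sites = e$n_conserved_sites,
               n_nonconserved_sites = e$n_nonconserved_sites,
               stringsAsFactors = FALSE)
  }))
}

#' Sum member expectations into a family-level expectation
#'
#' Component-wise sums over the family members; the per-member breakdown is
#' retained for reporting.
#'
#' @param members List of `gene_expectation` objects or an [expectation_df()]
#'   data frame.
#' @return Object of class `family_expectation`: list with `totals` (named
#'   numeric) and `members` (data frame).
#' @export
family_expectation <- function(members) {
  df <- if (is.data.frame(members)) members else expectation_df(members)
  if (anyDuplicated(df$gene_id))
    stop("duplicate gene_id in family expectation: ",
         df$gene_id[duplicated(df$gene_id)][1L])
  num <- setdiff(names(df), c("gene_id"))
  totals <- vapply(num, function(k) sum(df[[k]]), numeric(1))
  structure(list(totals = totals, members = df),
            class = "family_expectation")
}

#' Write / read per-gene expectation tables
#'
#' @param expectations List of `gene_expectation` objects or a data frame.
#' @param path TSV path.
#' @return `path` (write) or a data frame (read).
#' @export
write_expectations <- function(expectations, path) {
  df <- if (is.data.frame(expectations)) expectations
        else expectation_df(expectations)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_expectations
#' @export
read_expectations <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}
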