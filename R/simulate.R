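#' Simulate a synthetic gene family
#'
#' Generates an ancestor protein and mutates it independently into `n_genes`
#' descendants. The protein is organized in blocks, each with its own
#' per-site substitution probability (divergence), so that low-divergence
#' blocks act as conserved cores and high-divergence blocks as variable
#' linkers — the contrast the conservation scoring must detect. Replacement
#' residues are drawn uniformly from the 19 other amino acids (a deliberately
#' simple kernel; see the methods vignette). No indels are simulated, so the
#' family alignment is the stacked set of sequences. A CDS is generated for
#' every protein by drawing a random synonymous codon per residue plus a
#' random stop codon, and always back-translates to the protein.
#'
#' @param n_genes Number of descendants (>= 2).
#' @param blocks Data frame with columns `length` (>= 1) and `divergence`
#'   (in \[0, 1\]).
#' @param seed Optional integer seed; identical seeds give identical output.
#' @param family_id Id for the generated family.
#' @return Object of class `sim_family`: list with `family` (a
#'   `gene_family`), `msa` (stacked alignment), `block` (per-position block
#'   index) and `divergence` (per-position true divergence).
#' @examples
#' sim <- simulate_family(4, data.frame(length = c(30, 20),
#'                                      divergence = c(0.02, 0.6)), seed = 1)
#' @export
simulate_family <- function(n_genes = 4,
                            blocks = data.frame(length = c(60, 40),
                                                divergence = c(0.02, 0.6)),
                            seed = NULL, family_id = "SIMFAM1") {
  stopifnot(n_genes >= 2, all(blocks$length >= 1),
            all(blocks$divergence >= 0 & blocks$divergence <= 1))
  if (any(blocks$divergence < 0 | blocks$divergence > 1))
    stop("divergence must be in [0, 1]")
  if (!is.null(seed)) set.seed(seed)
  L <- sum(blocks$length)
  block_of <- rep(seq_len(nrow(blocks)), blocks$length)
  div_of <- blocks$divergence[block_of]
  ancestor <- sample(AA20, L, replace = TRUE)
  rev_code <- split(names(Biostrings::GENETIC_CODE),
                    as.character(Biostrings::GENETIC_CODE))
  stops <- rev_code[["*"]]
  members <- list()
  for (g in seq_len(n_genes)) {
    prot <- ancestor
    hit <- stats::runif(L) < div_of
    if (any(hit))
      prot[hit] <- vapply(prot[hit], function(a)
        sample(setdiff(AA20, a), 1L), "")
    cds <- paste0(paste(vapply(prot, function(a)
      sample(rev_code[[a]], 1L), ""), collapse = ""),
      sample(stops, 1L))
    id <- sprintf("%s_G%02d", family_id, g)
    members[[id]] <- gene_record(id, paste(prot, collapse = ""), cds)
  }
  fam <- structure(list(family_id = family_id, members = members),
                   class = "gene_family")
  msa <- new_msa(vapply(members, `[[`, "", "protein_seq"),
                 subfamily_id = paste0(family_id, ".1"))
  structure(list(family = fam, msa = msa, block = block_of,
                 divergence = div_of), class = "sim_family")
}

#' Build a conservation track from known site-class flags
#'
#' Convenience for simulation studies: fabricates raw scores (11 at flagged
#' sites, 0 elsewhere) and normalizes them with [zscore_track()], so the
#' track's `conserved` flags equal `flags` whenever both classes are
#' non-empty.
#'
#' @param flags Logical vector of intended conserved flags.
#' @param gene_id Gene symbol.
#' @param residues Optional residues.
#' @return A `paralog_track`.
#' @export
track_from_flags <- function(flags, gene_id = "gene", residues = NULL) {
  zscore_track(ifelse(flags, 11L, 0L), gene_id = gene_id,
               residues = residues)
}

#' Simulate a random trinucleotide-context rate table
#'
#' Rates are drawn log-normally around a typical per-site per-generation
#' substitution rate, emulating the spread of context-dependent mutabilities
#' (CpG transitions vs others) without reproducing any published table.
#'
#' @param mean_rate Geometric mean rate (default 1e-8).
#' @param sdlog Log-scale standard deviation (default 0.8).
#' @param seed Optional integer seed.
#' @return A [rate_table()].
#' @export
simulate_rate_table <- function(mean_rate = 1e-8, sdlog = 0.8, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  tab <- uniform_rate_table(mean_rate)
  rate_table(stats::setNames(
    stats::rlnorm(length(tab), meanlog = log(mean_rate), sdlog = sdlog),
    names(tab)))
}

#' Simulate de novo variant records
#'
#' Draws per-gene, per-class counts from Poisson distributions with the
#' expectations in `expectations`, multiplying the conserved-site missense
#' mean by the enrichment factor `rho` (`rho = 1` is the null). Positions
#' are drawn uniformly within the appropriate site class when the gene has a
#' track (missense), or uniformly over the protein (synonymous, nonsense);
#' frameshift and splice records carry no protein position. Cohort labels
#' are assigned proportionally to cohort sizes. Reproducible by seed.
#'
#' @param expectations [expectation_df()]-format data frame.
#' @param cohorts Named numeric vector of trio counts per cohort (labels
#'   only; the expectations are taken as given).
#' @param rho Conserved-site missense enrichment multiplier, >= 0.
#' @param tracks Named list of `paralog_track`s used to draw positions by
#'   site class.
#' @param seed Optional integer seed.
#' @return Data frame of de novo records (see [read_dnms()]).
#' @export
simulate_dnms <- function(expectations, cohorts = c(NDD = 1000), rho = 1,
                          tracks = list(), seed = NULL) {
  if (rho < 0) stop("rho must be >= 0")
  if (!is.null(seed)) set.seed(seed)
  rows <- list()
  emit <- function(gene, consequence, n, positions, aa_ref, aa_alt) {
    if (n == 0L) return()
    co <- sample(names(cohorts), n, replace = TRUE,
                 prob = cohorts / sum(cohorts))
    rows[[length(rows) + 1L]] <<- data.frame(
      proband_id = sprintf("%s_P%05d", co,
                           sample.int(1e5L, n, replace = TRUE)),
      cohort = co, gene = gene, consequence = consequence,
      protein_position = positions, aa_ref = aa_ref, aa_alt = aa_alt,
      stringsAsFactors = FALSE)
  }
  lam0 <- function(x) if (is.na(x)) 0 else x
  for (i in seq_len(nrow(expectations))) {
    e <- expectations[i, ]
    g <- e$gene_id
    tr <- tracks[[g]]
    n_res <- if (!is.null(tr)) nrow(tr$track) else NA_integer_
    draw_pos <- function(n, class) {
      if (is.null(tr)) return(rep(NA_integer_, n))
      pool <- switch(class,
        conserved = which(tr$track$conserved),
        nonconserved = which(!tr$track$conserved),
        any = seq_len(n_res))
      if (!length(pool)) return(rep(NA_integer_, n))
      pool[sample.int(length(pool), n, replace = TRUE)]
    }
    aa_at <- function(positions) {
      if (is.null(tr)) return(rep(NA_character_, length(positions)))
      ifelse(is.na(positions), NA_character_,
             tr$track$residue[positions])
    }
    alt_aa <- function(refs) vapply(refs, function(a) {
      if (is.na(a)) NA_character_ else sample(setdiff(AA20, a), 1L)
    }, "", USE.NAMES = FALSE)
    n_syn <- stats::rpois(1L, lam0(e$synonymous))
    p <- draw_pos(n_syn, "any"); a <- aa_at(p)
    emit(g, "synonymous", n_syn, p, a, a)
    n_mc <- stats::rpois(1L, rho * lam0(e$missense_conserved))
    p <- draw_pos(n_mc, "conserved"); a <- aa_at(p)
    emit(g, "missense", n_mc, p, a, alt_aa(a))
    n_mn <- stats::rpois(1L, lam0(e$missense_nonconserved))
    p <- draw_pos(n_mn, "nonconserved"); a <- aa_at(p)
    emit(g, "missense", n_mn, p, a, alt_aa(a))
    n_non <- stats::rpois(1L, lam0(e$nonsense))
    p <- draw_pos(n_non, "any"); a <- aa_at(p)
    emit(g, "nonsense", n_non, p, a, rep("*", n_non))
    n_fs <- stats::rpois(1L, lam0(e$frameshift))
    emit(g, "frameshift", n_fs, rep(NA_integer_, n_fs),
         rep(NA_character_, n_fs), rep(NA_character_, n_fs))
    n_sp <- stats::rpois(1L, lam0(e$splice))
    emit(g, "splice", n_sp, rep(NA_integer_, n_sp),
         rep(NA_character_, n_sp), rep(NA_character_, n_sp))
  }
  if (!length(rows))
    return(data.frame(proband_id = character(), cohort = character(),
                      gene = character(), consequence = character(),
                      protein_position = integer(), aa_ref = character(),
                      aa_alt = character(), stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
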