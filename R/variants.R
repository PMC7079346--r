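#' Normalize a variant to its minimal left-aligned representation
#'
#' vt-style normalization against a local reference window: shared suffix
#' bases are trimmed (left-extending with the preceding reference base
#' whenever an allele would become empty, which left-shifts indels through
#' repeat runs), then shared prefix bases are trimmed while both alleles
#' retain at least one base. The result is idempotent and is the leftmost
#' minimal representation within the window.
#'
#' @param chrom Chromosome label.
#' @param pos 1-based position of the first `ref` base.
#' @param ref,alt Non-empty allele strings (ACGT).
#' @param reference_window Local reference sequence covering the shift range.
#' @param window_start 1-based genomic position of the first base of
#'   `reference_window`.
#' @return List (class `normalized_variant`) with `chrom`, `pos`, `ref`,
#'   `alt`.
#' @examples
#' normalize_variant("1", 100, "CAC", "CGC", "ACACA", 98)
#' @export
normalize_variant <- function(chrom, pos, ref, alt, reference_window,
                              window_start = 1L) {
  ref <- toupper(ref); alt <- toupper(alt)
  win <- toupper(reference_window)
  stopifnot(nzchar(ref), nzchar(alt), pos >= window_start)
  at <- function(gpos) {
    i <- gpos - window_start + 1L
    if (i < 1L || i > nchar(win))
      stop("reference window does not cover position ", gpos)
    substr(win, i, i)
  }
  # check ref against the window
  for (k in seq_len(nchar(ref)))
    if (at(pos + k - 1L) != substr(ref, k, k))
      stop("ref allele inconsistent with reference window at position ",
           pos + k - 1L)
  repeat {
    lr <- nchar(ref); la <- nchar(alt)
    if (lr > 0 && la > 0 &&
        substr(ref, lr, lr) == substr(alt, la, la) &&
        !(lr == 1 && la == 1)) {
      ref <- substr(ref, 1L, lr - 1L)
      alt <- substr(alt, 1L, la - 1L)
      if (nchar(ref) == 0L || nchar(alt) == 0L) {
        pos <- pos - 1L
        b <- at(pos)
        ref <- paste0(b, ref); alt <- paste0(b, alt)
      }
    } else break
  }
  while (nchar(ref) >= 2L && nchar(alt) >= 2L &&
         substr(ref, 1L, 1L) == substr(alt, 1L, 1L)) {
    ref <- substr(ref, 2L, nchar(ref)); alt <- substr(alt, 2L, nchar(alt))
    pos <- pos + 1L
  }
  structure(list(chrom = chrom, pos = as.integer(pos), ref = ref, alt = alt),
            class = "normalized_variant")
}

#' Annotate de novo variants with paralog conservation
#'
#' Adds `para_zscore`, `conserved` and a `note` column to every record.
#' Missense records additionally receive a site class check via
#' [assign_site_class()] (an `aa_ref` mismatch is an error naming the gene
#' and position). Records in genes without a track are flagged `no_track`,
#' not dropped; the record count never changes.
#'
#' @param dnms De novo records (see [read_dnms()]).
#' @param tracks Named list of [zscore_track()] results.
#' @return `dnms` with added columns.
#' @export
annotate_variants <- function(dnms, tracks) {
  n <- nrow(dnms)
  z <- rep(NA_real_, n); cons <- rep(NA, n); note <- rep("", n)
  for (i in seq_len(n)) {
    tr <- tracks[[dnms$gene[i]]]
    if (is.null(tr)) { note[i] <- "no_track"; next }
    pos <- dnms$protein_position[i]
    if (is.na(pos) || pos < 1L || pos > nrow(tr$track)) {
      note[i] <- "no_position"; next
    }
    if (dnms$consequence[i] == "missense") {
      cls <- assign_site_class(dnms[i, ], tr)
      cons[i] <- cls == "conserved"
    } else {
      cons[i] <- tr$track$conserved[pos]
    }
    z[i] <- tr$track$para_zscore[pos]
  }
  dnms$para_zscore <- z
  dnms$conserved <- cons
  dnms$note <- note
  dnms
}

#' Export a per-protein conservation track with variant overlays
#'
#' One row per residue (deterministic order by position) with the residue,
#' its para_zscore (the per-gene mean sits at z = 0 by construction) and the
#' number of overlaid variants by class — the data behind lollipop-style
#' per-protein conservation plots.
#'
#' @param gene_id Gene symbol.
#' @param track The gene's [zscore_track()] result.
#' @param variants Optional de novo records for this gene with
#'   `protein_position` and `consequence`.
#' @return Data frame (class `track_export`) with columns `gene`, `position`,
#'   `residue`, `para_zscore`, `conserved`, `n_missense`, `n_ptv`,
#'   `n_synonymous`.
#' @export
export_track <- function(gene_id, track, variants = NULL) {
  df <- data.frame(gene = gene_id,
                   position = track$track$position,
                   residue = track$track$residue,
                   para_zscore = track$track$para_zscore,
                   conserved = as.integer(track$track$conserved),
                   n_missense = 0L, n_ptv = 0L, n_synonymous = 0L,
                   stringsAsFactors = FALSE)
  if (!is.null(variants) && nrow(variants)) {
    v <- variants[!is.na(variants$protein_position), , drop = FALSE]
    if (any(v$protein_position < 1L | v$protein_position > nrow(df)))
      stop("variant overlay position out of track range for gene ", gene_id)
    cls <- ifelse(v$consequence == "missense", "n_missense",
           ifelse(v$consequence %in% PTV_CLASSES, "n_ptv",
           ifelse(v$consequence == "synonymous", "n_synonymous", NA)))
    for (k in which(!is.na(cls)))
      df[v$protein_position[k], cls[k]] <- df[v$protein_position[k], cls[k]] + 1L
  }
  class(df) <- c("track_export", class(df))
  df
}

#' Write / read a track export
#'
#' @param export A [export_track()] data frame.
#' @param path TSV path. A header comment records the 1-based coordinate
#'   convention.
#' @return `path` (write) or the data frame (read).
#' @export
write_track_export <- function(export, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# coordinates: protein residue positions, 1-based", con)
  utils::write.table(export, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_track_export
#' @export
read_track_export <- function(path) {
  df <- utils::read.delim(path, comment.char = "#",
                          stringsAsFactors = FALSE)
  class(df) <- c("track_export", class(df))
  df
}
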