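#' Physico-chemical property table for column conservation
#'
#' The default table is the Livingstone & Barton physico-chemical
#' classification of the 20 amino acids into ten property sets (hydrophobic,
#' polar, small, tiny, aliphatic, aromatic, proline, positive, negative,
#' charged), as used by the AMAS conservation index. It is shipped as an
#' editable TSV (`system.file("extdata", "amas_properties.tsv", package =
#' "paralogr")`) and echoed into score outputs for provenance.
#'
#' Gaps and the unknown residue `X` carry no properties: they break every
#' "present in all" property but preserve "absent from all" ones.
#'
#' @param path TSV with columns `property` and `residues` (comma-separated
#'   amino-acid letters). Defaults to the shipped AMAS-style table.
#' @return Object of class `property_table`: named list of character vectors.
#' @export
read_property_table <- function(path = system.file("extdata",
                                                   "amas_properties.tsv",
                                                   package = "paralogr")) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("property", "residues") %in% names(df)))
  tab <- lapply(strsplit(df$residues, ","), function(x) toupper(trimws(x)))
  names(tab) <- df$property
  for (p in names(tab)) {
    bad <- setdiff(tab[[p]], AA20)
    if (length(bad))
      stop("property ", p, " lists non-canonical residue(s): ",
           paste(bad, collapse = ","))
  }
  structure(tab, class = "property_table", source = path)
}

#' @rdname read_property_table
#' @export
default_property_table <- function() read_property_table()

#' Score one alignment column
#'
#' Counts the physico-chemical properties that are uniform over the column: a
#' property is conserved when it is present in every entry or absent from
#' every entry. Gaps and `X` carry no properties. The count (0-10 with the
#' default table) is promoted to 11 for a gap-free single-residue identity
#' column, so that identity outranks mere property conservation.
#'
#' @param column Character vector of single characters (residues, `X`, or gap
#'   `-`/`.`), length >= 2.
#' @param table A [read_property_table()] object.
#' @return Integer score in \[0, 11\].
#' @export
score_column <- function(column, table = default_property_table()) {
  stopifnot(length(column) >= 2L)
  column <- toupper(column)
  bad <- setdiff(column, c(AA20, "X", GAP_CHARS))
  if (length(bad))
    stop("unknown character(s) in column: ", paste(unique(bad), collapse = ","))
  has_gap <- any(column %in% GAP_CHARS)
  res <- column[!(column %in% GAP_CHARS)]
  n_blank <- sum(column %in% GAP_CHARS) + sum(res == "X")
  score <- 0L
  for (p in table) {
    inset <- res %in% p
    present_all <- !has_gap && all(res != "X") && all(inset)
    absent_all <- !any(inset)
    if (present_all || absent_all) score <- score + 1L
  }
  if (!has_gap && length(unique(column)) == 1L && column[1L] != "X")
    score <- 11L
  score
}

#' Score every column of an alignment
#'
#' @param msa An [new_msa()] object.
#' @param table A [read_property_table()] object.
#' @return Object of class `conservation_profile` with `subfamily_id` and
#'   integer `column_scores` (one per alignment column). Invariant under
#'   permutation of row order.
#' @export
score_msa <- function(msa, table = default_property_table()) {
  mat <- do.call(rbind, strsplit(unname(msa$rows), ""))
  scores <- vapply(seq_len(ncol(mat)), function(j) {
    tryCatch(score_column(mat[, j], table),
             error = function(e) stop("column ", j, ": ",
                                      conditionMessage(e), call. = FALSE))
  }, integer(1))
  structure(list(subfamily_id = msa$subfamily_id, column_scores = scores,
                 property_table = table),
            class = "conservation_profile")
}

#' Project column scores onto one gene's residues
#'
#' Residue j of the gene receives the score of the alignment column that
#' holds its j-th non-gap character. Positions are 1-based.
#'
#' @param profile A [score_msa()] result.
#' @param msa The alignment the profile was computed from.
#' @param gene_id A row of the alignment.
#' @return Integer vector of per-residue scores (named by `gene_id`'s
#'   residues' positions).
#' @export
project_to_gene <- function(profile, msa, gene_id) {
  if (!gene_id %in% names(msa$rows))
    stop("gene ", gene_id, " is not a row of the alignment")
  chars <- strsplit(msa$rows[[gene_id]], "")[[1]]
  cols <- which(!(chars %in% GAP_CHARS))
  profile$column_scores[cols]
}

#' Per-gene paralog conservation z-scores
#'
#' Normalizes a gene's raw per-residue conservation scores into para_zscores
#' by subtracting the gene mean and dividing by the gene standard deviation
#' (sample sd, n - 1 denominator). Residues with para_zscore > 0 are flagged
#' paralog conserved (strictly positive; z = 0 is non-conserved). When the sd
#' is zero (constant track, or a single residue) every z is 0 and no residue
#' is conserved.
#'
#' @param scores Integer vector of raw per-residue scores (length >= 1).
#' @param gene_id Gene symbol.
#' @param residues Optional character vector of the gene's residues (same
#'   length), carried into the track for provenance checks.
#' @return Object of class `paralog_track`: a list with `gene_id`, `mean`,
#'   `sd`, and a data frame `$track` with columns `position`, `residue`,
#'   `score`, `para_zscore`, `conserved`.
#' @export
zscore_track <- function(scores, gene_id = "gene", residues = NULL) {
  if (length(scores) < 1L) stop("empty score track")
  m <- mean(scores)
  s <- if (length(scores) > 1L) stats::sd(scores) else 0
  z <- if (s > 0) (scores - m) / s else rep(0, length(scores))
  if (is.null(residues)) residues <- rep(NA_character_, length(scores))
  stopifnot(length(residues) == length(scores))
  structure(list(
    gene_id = gene_id, mean = m, sd = s,
    track = data.frame(position = seq_along(scores),
                       residue = residues,
                       score = as.integer(scores),
                       para_zscore = z,
                       conserved = z > 0,
                       stringsAsFactors = FALSE)),
    class = "paralog_track")
}

#' @export
print.paralog_track <- function(x, ...) {
  cat(sprintf("<paralog_track> %s: %d residues, %d conserved (mean %.2f, sd %.2f)\n",
              x$gene_id, nrow(x$track), sum(x$track$conserved), x$mean, x$sd))
  invisible(x)
}

#' Score a sub-family alignment into per-gene tracks
#'
#' Convenience wrapper: [score_msa()], then [project_to_gene()] and
#' [zscore_track()] for every row. The same code path serves ortholog
#' alignments (one target gene plus its orthologs): pass the alignment and
#' keep the target gene's track.
#'
#' @param msa An [new_msa()] object.
#' @param table A [read_property_table()] object.
#' @return Named list of `paralog_track` objects, one per row.
#' @export
score_subfamily <- function(msa, table = default_property_table()) {
  profile <- score_msa(msa, table)
  out <- lapply(names(msa$rows), function(g) {
    chars <- strsplit(msa$rows[[g]], "")[[1]]
    res <- chars[!(chars %in% GAP_CHARS)]
    zscore_track(project_to_gene(profile, msa, g), gene_id = g,
                 residues = res)
  })
  stats::setNames(out, names(msa$rows))
}

#' Write per-gene conservation tracks as TSV
#'
#' One row per residue: `gene`, `position` (1-based), `residue`,
#' `raw_score`, `para_zscore`, `conserved` (0/1). This is the distributable
#' per-gene paralog conservation annotation format.
#'
#' @param tracks Named list of `paralog_track` objects.
#' @param path Output TSV.
#' @return `path`, invisibly.
#' @export
write_tracks <- function(tracks, path) {
  df <- do.call(rbind, lapply(tracks, function(t)
    data.frame(gene = t$gene_id, position = t$track$position,
               residue = t$track$residue, raw_score = t$track$score,
               para_zscore = t$track$para_zscore,
               conserved = as.integer(t$track$conserved),
               stringsAsFactors = FALSE)))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read per-gene conservation tracks from TSV
#'
#' @param path A TSV written by [write_tracks()].
#' @return Named list of `paralog_track` objects.
#' @export
read_tracks <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("gene", "position", "raw_score", "para_zscore", "conserved")
  stopifnot(all(need %in% names(df)))
  out <- lapply(split(df, df$gene), function(d) {
    d <- d[order(d$position), ]
    t <- zscore_track(d$raw_score, gene_id = d$gene[[1L]],
                      residues = if ("residue" %in% names(d)) d$residue
                                 else NULL)
    # trust the recomputation; the file's z and flags must agree
    if (max(abs(t$track$para_zscore - d$para_zscore)) > 1e-6)
      stop("track file for gene ", d$gene[[1L]],
           " is inconsistent with its raw scores")
    t
  })
  out[order(names(out))]
}
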