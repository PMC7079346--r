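#' Construct a multiple sequence alignment object
#'
#' @param rows Named character vector of equal-length gapped sequences
#'   (names are gene ids). Gap characters are `-` or `.`.
#' @param subfamily_id Optional id carried through to profiles.
#' @return Object of class `msa` with fields `rows`, `length`.
#' @export
new_msa <- function(rows, subfamily_id = NULL) {
  stopifnot(length(rows) >= 2L, !is.null(names(rows)),
            all(nzchar(names(rows))))
  rows <- toupper(rows)
  lens <- nchar(rows)
  if (length(unique(lens)) != 1L)
    stop("alignment rows differ in length")
  structure(list(rows = rows, length = lens[[1L]],
                 subfamily_id = subfamily_id), class = "msa")
}

#' @export
print.msa <- function(x, ...) {
  cat(sprintf("<msa> %d rows x %d columns%s\n", length(x$rows), x$length,
              if (is.null(x$subfamily_id)) "" else
                paste0(" (", x$subfamily_id, ")")))
  invisible(x)
}

#' Read an aligned FASTA file as an msa
#'
#' @param path Aligned FASTA (all records equal length, gaps as `-`).
#' @param subfamily_id Optional id.
#' @return An [new_msa()] object.
#' @export
read_msa <- function(path, subfamily_id = NULL) {
  aa <- Biostrings::readAAStringSet(path)
  rows <- stats::setNames(as.character(aa), sub("\\s.*$", "", names(aa)))
  new_msa(rows, subfamily_id = subfamily_id)
}

#' Write an msa as aligned FASTA
#'
#' @param msa An `msa` object.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_msa <- function(msa, path) {
  set <- Biostrings::AAStringSet(msa$rows)
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Align a sub-family (stacking or external-aligner hook)
#'
#' The package does not bundle an aligner. Sub-families whose member proteins
#' all have equal length (e.g. output of [simulate_family()], which is
#' indel-free) can be stacked directly with `method = "stack"`. For real
#' families, `method = "external"` shells out to a command template such as
#' `"mafft --quiet {input} > {output}"`; alternatively, read a pre-computed
#' alignment with [read_msa()].
#'
#' @param subfamily A `sub_family` object.
#' @param method `"stack"` or `"external"`.
#' @param command Command template with `{input}` and `{output}` placeholders
#'   (required for `"external"`).
#' @return An [new_msa()] object.
#' @export
align_subfamily <- function(subfamily, method = c("stack", "external"),
                            command = NULL) {
  method <- match.arg(method)
  seqs <- vapply(subfamily$members, `[[`, "", "protein_seq")
  if (method == "stack") {
    if (length(unique(nchar(seqs))) != 1L)
      stop("stack alignment requires equal-length sequences; ",
           "use method = \"external\" or a pre-computed alignment")
    return(new_msa(seqs, subfamily_id = subfamily$subfamily_id))
  }
  if (is.null(command)) stop("external alignment requires a command template")
  fin <- tempfile(fileext = ".fa"); fout <- tempfile(fileext = ".fa")
  on.exit(unlink(c(fin, fout)), add = TRUE)
  write_gene_fasta(subfamily$members, fin)
  cmd <- sub("{input}", fin, sub("{output}", fout, command, fixed = TRUE),
             fixed = TRUE)
  status <- system(cmd)
  if (status != 0L || !file.exists(fout) || file.size(fout) == 0L)
    stop("external aligner failed: ", cmd)
  read_msa(fout, subfamily_id = subfamily$subfamily_id)
}
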