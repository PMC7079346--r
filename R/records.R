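#' Create a gene record
#'
#' A gene record couples a gene symbol with its protein sequence (by
#' convention the longest CCDS isoform) and, optionally, the coding sequence
#' the protein was translated from.
#'
#' @param gene_id Gene symbol (HGNC-style string).
#' @param protein_seq Amino-acid sequence, uppercase; the 20 canonical
#'   residues plus `X` are allowed.
#' @param cds_seq Optional coding sequence. Its length must be divisible by 3
#'   and its translation (standard code, trailing stop allowed) must equal
#'   `protein_seq`.
#' @return An object of class `gene_record`.
#' @examples
#' gene_record("KCNQ2x", "MATL", "ATGGCCACCCTGTAA")
#' @export
gene_record <- function(gene_id, protein_seq, cds_seq = NULL) {
  stopifnot(is.character(gene_id), length(gene_id) == 1L, nzchar(gene_id))
  protein_seq <- toupper(protein_seq)
  if (nchar(protein_seq) < 1L)
    stop("protein_seq must have length >= 1 for gene ", gene_id)
  bad <- setdiff(strsplit(protein_seq, "")[[1]], c(AA20, "X"))
  if (length(bad))
    stop("invalid residue(s) ", paste(unique(bad), collapse = ","),
         " in protein of gene ", gene_id)
  if (!is.null(cds_seq)) {
    cds_seq <- toupper(cds_seq)
    if (nchar(cds_seq) %% 3L != 0L)
      stop("cds_seq length not divisible by 3 for gene ", gene_id)
    tr <- translate_cds(cds_seq)
    if (sub("\\*$", "", tr) != protein_seq)
      stop("cds_seq does not translate to protein_seq for gene ", gene_id)
  }
  structure(list(gene_id = gene_id, protein_seq = protein_seq,
                 cds_seq = cds_seq),
            class = "gene_record")
}

#' @export
print.gene_record <- function(x, ...) {
  cat(sprintf("<gene_record> %s: %d aa%s\n", x$gene_id,
              nchar(x$protein_seq),
              if (is.null(x$cds_seq)) "" else
                sprintf(", CDS %d nt", nchar(x$cds_seq))))
  invisible(x)
}

#' Translate a coding sequence with the standard genetic code
#'
#' @param cds Nucleotide string, length divisible by 3, ACGT only.
#' @return Amino-acid string; stop codons become `*`.
#' @export
translate_cds <- function(cds) {
  cds <- toupper(cds)
  if (nchar(cds) %% 3L != 0L) stop("CDS length not divisible by 3")
  if (grepl("[^ACGT]", cds)) stop("CDS contains non-ACGT characters")
  tab <- codon_table()
  codons <- substring(cds, seq(1L, nchar(cds), 3L), seq(3L, nchar(cds), 3L))
  paste(tab[codons], collapse = "")
}

#' Read protein sequences as gene records
#'
#' Reads a FASTA file whose record ids are gene symbols. Records with empty
#' sequences or invalid characters are dropped with a warning, mirroring the
#' exclusion of genes without usable CCDS annotation.
#'
#' @param path FASTA file of protein sequences.
#' @return Named list of [gene_record()] objects.
#' @export
read_protein_fasta <- function(path) {
  aa <- Biostrings::readAAStringSet(path)
  ids <- sub("\\s.*$", "", names(aa))
  out <- list()
  for (i in seq_along(aa)) {
    rec <- tryCatch(gene_record(ids[i], as.character(aa[[i]])),
                    error = function(e) e)
    if (inherits(rec, "error")) {
      warning("dropping FASTA record '", ids[i], "': ",
              conditionMessage(rec), call. = FALSE)
    } else out[[ids[i]]] <- rec
  }
  out
}

#' Write gene records to FASTA
#'
#' @param records List of [gene_record()] objects.
#' @param path Output file.
#' @param what `"protein"` or `"cds"`.
#' @return `path`, invisibly.
#' @export
write_gene_fasta <- function(records, path, what = c("protein", "cds")) {
  what <- match.arg(what)
  seqs <- vapply(records, function(r)
    if (what == "protein") r$protein_seq else r$cds_seq %||% "", "")
  if (any(!nzchar(seqs))) stop("some records lack a ", what, " sequence")
  ids <- vapply(records, `[[`, "", "gene_id")
  set <- if (what == "protein") Biostrings::AAStringSet(seqs)
         else Biostrings::DNAStringSet(seqs)
  names(set) <- ids
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}
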