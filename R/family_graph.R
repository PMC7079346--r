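#' Clustering parameters for the alignment-similarity graph
#'
#' Sub-families are connected components of a graph in which two family
#' members are joined when their pairwise global alignment covers more than
#' `aligned_fraction_cutoff` of the longer sequence (strict inequality,
#' following the "> 80% aligned residues" rule).
#'
#' @param aligned_fraction_cutoff Fraction in (0, 1]; default 0.8.
#' @param substitution_matrix Name of the substitution matrix (default
#'   `"BLOSUM62"`).
#' @param gap_open,gap_extend Non-negative affine gap penalties (EMBOSS
#'   needle-like defaults 10 and 0.5); a gap of length L costs
#'   `gap_open + L * gap_extend`.
#' @return An object of class `clustering_params`.
#' @export
clustering_params <- function(aligned_fraction_cutoff = 0.8,
                              substitution_matrix = "BLOSUM62",
                              gap_open = 10, gap_extend = 0.5) {
  stopifnot(aligned_fraction_cutoff > 0, aligned_fraction_cutoff <= 1,
            gap_open >= 0, gap_extend >= 0, gap_extend <= gap_open)
  structure(list(aligned_fraction_cutoff = aligned_fraction_cutoff,
                 substitution_matrix = substitution_matrix,
                 gap_open = gap_open, gap_extend = gap_extend),
            class = "clustering_params")
}

#' Assemble gene families from paralog pairs
#'
#' Families are the connected components of the paralog-pair graph. Pairs
#' whose gene ids cannot be resolved in `sequences` are dropped with a
#' warning, and components reduced to a single gene are discarded (a family
#' needs at least two members).
#'
#' @param pairs Data frame with columns `gene_id_a`, `gene_id_b` and an
#'   optional `family_id` annotation column.
#' @param sequences Named list of [gene_record()] objects.
#' @return List of `gene_family` objects, each with `family_id` and a list of
#'   `members` sorted by gene id. Deterministic for identical inputs.
#' @examples
#' seqs <- list(A = gene_record("A", "MKV"), B = gene_record("B", "MKL"),
#'              C = gene_record("C", "MRL"))
#' fams <- build_families(data.frame(gene_id_a = c("A", "B"),
#'                                   gene_id_b = c("B", "C")), seqs)
#' @export
build_families <- function(pairs, sequences) {
  if (is.null(pairs) || nrow(pairs) == 0L) return(list())
  stopifnot(all(c("gene_id_a", "gene_id_b") %in% names(pairs)))
  a <- as.character(pairs$gene_id_a); b <- as.character(pairs$gene_id_b)
  known <- names(sequences)
  ok <- a %in% known & b %in% known
  if (any(!ok)) {
    miss <- setdiff(unique(c(a[!ok], b[!ok])), known)
    warning("dropping ", sum(!ok), " pair(s) with unresolvable gene id(s): ",
            paste(utils::head(miss, 10L), collapse = ","), call. = FALSE)
  }
  if ("family_id" %in% names(pairs)) {
    fid <- as.character(pairs$family_id)
    key <- paste(pmin(a, b), pmax(a, b))
    for (k in unique(key)) {
      ids <- unique(fid[key == k & !is.na(fid)])
      if (length(ids) > 1L)
        stop("contradictory family_id annotations for pair ", k, ": ",
             paste(ids, collapse = " vs "))
    }
  }
  a <- a[ok]; b <- b[ok]
  if (!length(a)) return(list())
  g <- igraph::graph_from_data_frame(
    data.frame(from = a, to = b, stringsAsFactors = FALSE),
    directed = FALSE)
  comp <- igraph::components(g)
  fams <- split(names(comp$membership), comp$membership)
  fams <- Filter(function(m) length(m) >= 2L, fams)
  fams <- lapply(fams, function(m) sort(unique(m)))
  # deterministic family ids: ordered by lexicographically smallest member
  fams <- fams[order(vapply(fams, `[`, "", 1L))]
  out <- vector("list", length(fams))
  for (i in seq_along(fams)) {
    out[[i]] <- structure(
      list(family_id = sprintf("FAM%04d", i),
           members = sequences[fams[[i]]]),
      class = "gene_family")
  }
  out
}

#' @export
print.gene_family <- function(x, ...) {
  cat(sprintf("<gene_family> %s: %d members (%s)\n", x$family_id,
              length(x$members),
              paste(utils::head(names(x$members), 6L), collapse = ", ")))
  invisible(x)
}

.check_protein_chars <- function(s, label) {
  bad <- setdiff(strsplit(toupper(s), "")[[1]], c(AA20, "X"))
  if (length(bad))
    stop("invalid character(s) ", paste(unique(bad), collapse = ","),
         " in ", label)
}

#' Global pairwise protein alignment
#'
#' Needleman-Wunsch global alignment with affine gap penalties, backed by
#' [Biostrings::pairwiseAlignment()]. Output is deterministic for identical
#' inputs and parameters; removing gaps from either row recovers the input
#' sequences.
#'
#' @param a,b Protein sequences (20 canonical residues plus `X`).
#' @param params A [clustering_params()] object.
#' @return List with gapped strings `a` and `b` (equal length) and the
#'   alignment `score`; class `pairwise_alignment`.
#' @export
global_align <- function(a, b, params = clustering_params()) {
  stopifnot(nzchar(a), nzchar(b))
  a <- toupper(a); b <- toupper(b)
  .check_protein_chars(a, "sequence a")
  .check_protein_chars(b, "sequence b")
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(a), Biostrings::AAString(b),
    type = "global",
    substitutionMatrix = params$substitution_matrix,
    gapOpening = params$gap_open, gapExtension = params$gap_extend)
  structure(list(
    a = as.character(Biostrings::alignedPattern(pa)),
    b = as.character(Biostrings::alignedSubject(pa)),
    score = Biostrings::score(pa)), class = "pairwise_alignment")
}

#' Fraction of aligned residues in a pairwise alignment
#'
#' The number of columns where both rows carry a residue, divided by the
#' length of the longer unaligned sequence. Symmetric in row order; used with
#' a strict `> cutoff` rule to build the sub-family similarity graph.
#'
#' @param alignment A `pairwise_alignment` (list with gapped rows `a`, `b`).
#' @return Fraction in \[0, 1\].
#' @export
aligned_fraction <- function(alignment) {
  ra <- strsplit(alignment$a, "")[[1]]
  rb <- strsplit(alignment$b, "")[[1]]
  if (length(ra) == 0L || length(ra) != length(rb))
    stop("invalid pairwise alignment")
  both <- sum(!(ra %in% GAP_CHARS) & !(rb %in% GAP_CHARS))
  longer <- max(sum(!(ra %in% GAP_CHARS)), sum(!(rb %in% GAP_CHARS)))
  both / longer
}

#' Split a gene family into sub-families
#'
#' All member pairs are globally aligned; an edge joins two members when
#' their [aligned_fraction()] strictly exceeds the cutoff. Sub-families are
#' the connected components with at least two members. A family may yield
#' zero sub-families.
#'
#' @param family A `gene_family` from [build_families()].
#' @param params A [clustering_params()] object.
#' @return List of `sub_family` objects (`subfamily_id`, `members`). Ids are
#'   `<family_id>.<k>` with `k` assigned in order of the lexicographically
#'   smallest member gene id.
#' @export
cluster_subfamilies <- function(family, params = clustering_params()) {
  members <- family$members
  ids <- names(members)
  stopifnot(length(ids) >= 2L)
  edges_a <- character(); edges_b <- character()
  for (i in seq_len(length(ids) - 1L)) {
    for (j in seq.int(i + 1L, length(ids))) {
      aln <- global_align(members[[i]]$protein_seq,
                          members[[j]]$protein_seq, params)
      if (aligned_fraction(aln) > params$aligned_fraction_cutoff) {
        edges_a <- c(edges_a, ids[i]); edges_b <- c(edges_b, ids[j])
      }
    }
  }
  if (!length(edges_a)) return(list())
  g <- igraph::graph_from_data_frame(
    data.frame(from = edges_a, to = edges_b, stringsAsFactors = FALSE),
    directed = FALSE, vertices = ids)
  comp <- igraph::components(g)
  cl <- Filter(function(m) length(m) >= 2L,
               split(names(comp$membership), comp$membership))
  cl <- lapply(cl, sort)
  cl <- cl[order(vapply(cl, `[`, "", 1L))]
  lapply(seq_along(cl), function(k) {
    structure(list(subfamily_id = paste0(family$family_id, ".", k),
                   members = members[cl[[k]]]),
              class = "sub_family")
  })
}

#' @export
print.sub_family <- function(x, ...) {
  cat(sprintf("<sub_family> %s: %d members (%s)\n", x$subfamily_id,
              length(x$members), paste(names(x$members), collapse = ", ")))
  invisible(x)
}

#' Read a paralog-pair table
#'
#' @param path TSV with header columns `gene_id_a`, `gene_id_b` and optional
#'   `family_id`.
#' @return Data frame.
#' @export
read_pair_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("gene_id_a", "gene_id_b") %in% names(df)))
  df
}

#' Write sub-family membership as TSV
#'
#' @param subfamilies List of `sub_family` objects.
#' @param path Output TSV (`subfamily_id`, `gene_id`).
#' @return `path`, invisibly.
#' @export
write_subfamilies <- function(subfamilies, path) {
  df <- do.call(rbind, lapply(subfamilies, function(sf)
    data.frame(subfamily_id = sf$subfamily_id, gene_id = names(sf$members),
               stringsAsFactors = FALSE)))
  if (is.null(df))
    df <- data.frame(subfamily_id = character(), gene_id = character())
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
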