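#' Per-rank percent-identity thresholds
#'
#' Classification of an amplicon to a taxonomic rank is driven by its
#' percent identity to its best reference: the deeper the rank claimed,
#' the higher the identity required. The defaults are the per-rank
#' similarity settings optimised on multi-species positive-control data
#' for this assay panel: species 97.8, genus 96.2, family 88.3,
#' order 81.21, class 80.91. Identities below the class threshold are left
#' unclassified. Boundaries are inclusive: an identity exactly equal to a
#' threshold attains that rank.
#'
#' @param species,genus,family,order,class percent-identity thresholds;
#'   must be strictly decreasing from species to class.
#' @return an object of class `rank_thresholds` (named numeric vector).
#' @export
rank_thresholds <- function(species = 97.8, genus = 96.2, family = 88.3,
                            order = 81.21, class = 80.91) {
  th <- c(species = species, genus = genus, family = family,
          order = order, class = class)
  if (any(is.na(th)) || any(th < 0 | th > 100))
    stop("thresholds must lie in [0, 100]")
  if (any(diff(th) >= 0))
    stop("thresholds must be strictly decreasing from species to class")
  structure(th, class = "rank_thresholds")
}

#' Global percent identity between two nucleotide sequences
#'
#' End-to-end (global) alignment under unit match scoring: a match scores
#' 1, a mismatch 0, and a gap column counts as a mismatch column. Among
#' alignments maximising the number of matches, one minimising the number
#' of alignment columns is used, and
#' `identity = 100 * matches / alignment columns`.
#'
#' This is a deliberately simple identity measure for toy consensus
#' sequences; it is not a k-mer database search.
#'
#' @param query,reference non-empty nucleotide strings over A/C/G/T/N
#'   (case-insensitive).
#' @return percent identity in `[0, 100]`.
#' @examples
#' percent_identity("ACGT", "ACGA")        # 75
#' percent_identity("ACGTACGT", "ACGTCGT") # 87.5
#' @export
percent_identity <- function(query, reference) {
  q <- prep_seq(query, "query")
  r <- prep_seq(reference, "reference")
  n <- length(q); m <- length(r)

  # DP over (max matches, then min columns); every transition adds one column
  M <- matrix(0L, n + 1L, m + 1L)        # best match count
  C <- matrix(0L, n + 1L, m + 1L)        # min columns given best matches
  C[1L, ] <- 0:m
  C[, 1L] <- 0:n
  for (i in seq_len(n)) {
    qi <- q[i]
    for (j in seq_len(m)) {
      diag_m <- M[i, j] + (qi == r[j])
      diag_c <- C[i, j] + 1L
      up_m <- M[i, j + 1L]; up_c <- C[i, j + 1L] + 1L
      lf_m <- M[i + 1L, j]; lf_c <- C[i + 1L, j] + 1L
      best_m <- max(diag_m, up_m, lf_m)
      best_c <- min(if (diag_m == best_m) diag_c else NA_integer_,
                    if (up_m == best_m) up_c else NA_integer_,
                    if (lf_m == best_m) lf_c else NA_integer_,
                    na.rm = TRUE)
      M[i + 1L, j + 1L] <- best_m
      C[i + 1L, j + 1L] <- best_c
    }
  }
  100 * M[n + 1L, m + 1L] / C[n + 1L, m + 1L]
}

prep_seq <- function(x, what) {
  if (!is.character(x) || length(x) != 1L || nchar(x) == 0L)
    stop(what, " must be a non-empty sequence string")
  s <- strsplit(toupper(x), "")[[1]]
  bad <- setdiff(unique(s), c("A", "C", "G", "T", "N"))
  if (length(bad))
    stop(what, " contains non-nucleotide character(s): ",
         paste(bad, collapse = ", "))
  s
}

#' Assign a taxonomic rank from a percent identity
#'
#' Returns the deepest rank whose threshold the identity meets
#' (inclusive); identities below the class threshold are `unclassified`.
#' Vectorised over `identity`.
#'
#' @param identity numeric vector of percent identities in `[0, 100]`.
#' @param thresholds a [rank_thresholds()] object.
#' @return character vector of ranks.
#' @examples
#' assign_rank(c(100, 97.8, 96.5, 80.0))
#' @export
assign_rank <- function(identity, thresholds = rank_thresholds()) {
  stopifnot(inherits(thresholds, "rank_thresholds"))
  if (any(is.na(identity) | identity < 0 | identity > 100))
    stop("identity must lie in [0, 100]")
  vapply(identity, function(id) {
    hit <- names(thresholds)[thresholds <= id]
    if (length(hit)) hit[1L] else "unclassified"
  }, character(1))
}

#' Classify annotated query sequences into tally rows
#'
#' Each query is matched to its single best-identity reference (ties
#' broken by lexicographic reference id), the reference's lineage is
#' truncated to the rank its identity supports, and the query weights
#' (read counts) are summed into tally rows. Weight is conserved: the
#' output reads sum to the input weights.
#'
#' @param queries named character vector (or `Biostrings::DNAStringSet`)
#'   of query sequences.
#' @param query_info data.frame with one row per query: `query_id`,
#'   `sample_id`, `primer_id`, `weight` (the read count the consensus
#'   represents).
#' @param references named character vector (or `DNAStringSet`) of
#'   reference sequences.
#' @param lineage data.frame with columns
#'   `ref_id class order family genus species`.
#' @param thresholds a [rank_thresholds()] object.
#' @return data.frame of tally rows: `sample_id`, `primer_id`, `taxon`,
#'   `rank`, `reads`, aggregated over queries.
#' @export
classify_sequences <- function(queries, query_info, references, lineage,
                               thresholds = rank_thresholds()) {
  queries <- as_seq_vector(queries)
  references <- as_seq_vector(references)
  if (!length(references)) stop("empty reference set")
  need <- c("ref_id", "class", "order", "family", "genus", "species")
  if (!all(need %in% names(lineage)))
    stop("lineage table needs columns: ", paste(need, collapse = ", "))
  if (!all(names(references) %in% lineage$ref_id))
    stop("reference(s) missing from lineage table: ",
         paste(setdiff(names(references), lineage$ref_id), collapse = ", "))
  stopifnot(all(c("query_id", "sample_id", "primer_id", "weight") %in%
                  names(query_info)),
            all(names(queries) %in% query_info$query_id))

  ref_order <- order(names(references))
  references <- references[ref_order]   # lexicographic tie-break by position

  rows <- lapply(names(queries), function(qid) {
    ids <- vapply(references, function(r) percent_identity(queries[[qid]], r),
                  numeric(1))
    best <- which.max(ids)              # first max = lexicographically first id
    rk <- assign_rank(ids[best], thresholds)
    lin <- lineage[lineage$ref_id == names(references)[best], , drop = FALSE]
    taxon <- if (rk == "unclassified") "unclassified" else lin[[rk]][1L]
    info <- query_info[query_info$query_id == qid, , drop = FALSE]
    data.frame(sample_id = info$sample_id[1L], primer_id = info$primer_id[1L],
               taxon = taxon, rank = rk, reads = as.integer(info$weight[1L]),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  key <- paste(out$sample_id, out$primer_id, out$taxon, out$rank, sep = "\r")
  agg <- rowsum(out$reads, key)
  first <- out[!duplicated(key), , drop = FALSE]
  first$reads <- as.integer(agg[match(unique(key), rownames(agg)), 1L])
  first <- first[order(first$sample_id, first$primer_id, first$taxon), ,
                 drop = FALSE]
  rownames(first) <- NULL
  first
}

as_seq_vector <- function(x) {
  if (inherits(x, "XStringSet")) x <- as.character(x)
  if (!is.character(x))
    stop("sequences must be a uniquely named character vector or DNAStringSet")
  if (length(x) && (is.null(names(x)) || anyDuplicated(names(x))))
    stop("sequences must be a uniquely named character vector or DNAStringSet")
  x
}

#' Read sequences from a FASTA file
#'
#' Thin wrapper over [Biostrings::readDNAStringSet()] returning a named
#' character vector (first whitespace-delimited token of each header is
#' the id).
#'
#' @param path FASTA path.
#' @return named character vector of sequences.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  out <- as.character(x)
  names(out) <- vapply(strsplit(names(x), "\\s+"), `[`, character(1), 1L)
  out
}

#' Read a reference lineage table
#'
#' TSV with columns `ref_id class order family genus species`.
#'
#' @param path TSV path.
#' @return data.frame.
#' @export
read_lineage_table <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  need <- c("ref_id", "class", "order", "family", "genus", "species")
  missing <- setdiff(need, names(df))
  if (length(missing))
    stop("lineage table is missing column(s): ", paste(missing, collapse = ", "))
  if (any(!nzchar(as.matrix(df[need]))))
    stop("lineage table has empty fields; a complete 5-rank lineage is required")
  df
}
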