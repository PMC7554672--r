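## Protein-family construction from an all-vs-all similarity search:
## thresholded single-linkage clustering of pairwise hits (the SiLiX
## criterion: identity and mutual coverage thresholds, E-value screen) and
## assembly of the genome x family occurrence matrix.

#' Default hit-filtering thresholds
#'
#' Two sequences join the same family when they share at least 35% identity,
#' the alignment covers at least 70% of *both* sequence lengths, and the hit
#' E-value is strictly below 1e-4.
#'
#' @param min_identity minimum percent identity (inclusive).
#' @param min_coverage minimum alignment coverage of both sequences
#'   (inclusive fraction).
#' @param max_evalue strict upper bound on the E-value.
#' @return list of thresholds.
#' @export
filter_thresholds <- function(min_identity = 35, min_coverage = 0.70,
                              max_evalue = 1e-4) {
  stopifnot(min_identity >= 0, min_identity <= 100,
            min_coverage > 0, min_coverage <= 1, max_evalue >= 0)
  list(min_identity = min_identity, min_coverage = min_coverage,
       max_evalue = max_evalue)
}

#' Read a pairwise hit table
#'
#' Accepts BLAST tabular output (outfmt 6: qseqid sseqid pident length
#' mismatch gapopen qstart qend sstart send evalue bitscore) or a reduced
#' 5-column table (query, subject, pident, length, evalue). Sequence lengths
#' come from a separate two-column table. Self-hits are retained in the
#' record list but never create edges downstream.
#'
#' @param path hit TSV.
#' @param lengths named integer vector of sequence lengths, or path to a
#'   two-column TSV (id, length).
#' @return data.frame with columns `query`, `subject`, `pident`, `length`,
#'   `evalue`, `qlen`, `slen`.
#' @export
read_hits <- function(path, lengths) {
  if (is.character(lengths) && length(lengths) == 1L) {
    lt <- utils::read.table(lengths, sep = "\t", header = FALSE,
                            stringsAsFactors = FALSE)
    lengths <- stats::setNames(as.integer(lt[[2L]]), as.character(lt[[1L]]))
  }
  tab <- utils::read.table(path, sep = "\t", header = FALSE,
                           stringsAsFactors = FALSE, comment.char = "#")
  if (ncol(tab) >= 12L) {
    hits <- data.frame(query = as.character(tab[[1L]]),
                       subject = as.character(tab[[2L]]),
                       pident = tab[[3L]], length = tab[[4L]],
                       evalue = tab[[11L]], stringsAsFactors = FALSE)
  } else if (ncol(tab) >= 5L) {
    hits <- data.frame(query = as.character(tab[[1L]]),
                       subject = as.character(tab[[2L]]),
                       pident = tab[[3L]], length = tab[[4L]],
                       evalue = tab[[5L]], stringsAsFactors = FALSE)
  } else {
    stop("hit table needs >= 5 columns (query, subject, pident, length, evalue)")
  }
  for (col in c("pident", "length", "evalue")) {
    v <- suppressWarnings(as.numeric(hits[[col]]))
    if (anyNA(v)) {
      stop("malformed ", col, " at line(s): ",
           paste(which(is.na(v)), collapse = ", "))
    }
    hits[[col]] <- v
  }
  if (any(hits$pident < 0 | hits$pident > 100)) stop("pident outside [0, 100]")
  ids <- unique(c(hits$query, hits$subject))
  missing <- setdiff(ids, names(lengths))
  if (length(missing)) {
    stop("missing sequence length for: ", paste(missing, collapse = ", "))
  }
  hits$qlen <- unname(lengths[hits$query])
  hits$slen <- unname(lengths[hits$subject])
  hits
}

#' Filter hits into an undirected edge list
#'
#' Keeps a hit when query != subject, `evalue < max_evalue` (strict),
#' `pident >= min_identity`, and the alignment length covers at least
#' `min_coverage` of *both* the query and the subject length. Reciprocal and
#' duplicate hits are collapsed to one undirected edge, keeping the best
#' (smallest) E-value.
#'
#' @param hits data.frame from [read_hits()].
#' @param thresholds list from [filter_thresholds()].
#' @return data.frame with columns `from`, `to`, `evalue` (one row per
#'   undirected edge, `from < to` lexicographically).
#' @export
filter_hits <- function(hits, thresholds = filter_thresholds()) {
  th <- thresholds
  keep <- hits$query != hits$subject &
    hits$evalue < th$max_evalue &
    hits$pident >= th$min_identity &
    hits$length >= th$min_coverage * hits$qlen &
    hits$length >= th$min_coverage * hits$slen
  e <- hits[keep, c("query", "subject", "evalue"), drop = FALSE]
  if (!nrow(e)) {
    return(data.frame(from = character(), to = character(),
                      evalue = numeric(), stringsAsFactors = FALSE))
  }
  from <- pmin(e$query, e$subject)
  to <- pmax(e$query, e$subject)
  key <- paste(from, to, sep = "\r")
  ord <- order(key, e$evalue)
  first <- !duplicated(key[ord])
  out <- data.frame(from = from[ord][first], to = to[ord][first],
                    evalue = e$evalue[ord][first], stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out[order(out$from, out$to), , drop = FALSE]
}

#' Cluster sequences into families by single linkage
#'
#' Families are the connected components of the filtered hit graph;
#' sequences without any surviving edge become singleton families. Family
#' identifiers are `"FAM"` plus a zero-padded rank, ranked by decreasing
#' family size with ties broken by the lexicographically smallest member.
#'
#' @param universe character vector of all sequence ids.
#' @param edges data.frame from [filter_hits()].
#' @return object of class `family_set`: `families` (named list id -> member
#'   vector) and `membership` (named character vector sequence -> family id).
#' @export
cluster_families <- function(universe, edges) {
  universe <- unique(as.character(universe))
  outside <- setdiff(unique(c(edges$from, edges$to)), universe)
  if (length(outside)) {
    stop("edge endpoint(s) outside the sequence universe: ",
         paste(outside, collapse = ", "))
  }
  g <- igraph::graph_from_data_frame(
    edges[, c("from", "to"), drop = FALSE],
    directed = FALSE, vertices = data.frame(name = universe))
  comp <- igraph::components(g)$membership
  groups <- split(names(comp), comp)
  members <- lapply(groups, function(m) sort(m))
  sizes <- lengths(members)
  smallest <- vapply(members, `[`, character(1), 1L)
  ord <- order(-sizes, smallest)
  members <- members[ord]
  width <- max(6L, nchar(length(members)))
  ids <- sprintf("FAM%0*d", width, seq_along(members))
  names(members) <- ids
  membership <- stats::setNames(rep(ids, lengths(members)),
                                unlist(members, use.names = FALSE))
  structure(list(families = members, membership = membership),
            class = "family_set")
}

#' @export
print.family_set <- function(x, ...) {
  cat("family_set:", length(x$families), "families over",
      length(x$membership), "sequences\n")
  invisible(x)
}

#' Build the genome x family occurrence matrix
#'
#' @param fams a `family_set`.
#' @param seq2genome named character vector mapping every sequence id to its
#'   genome, or path to a two-column TSV (id, genome).
#' @return integer matrix, rows = genomes, columns = families; entry (g, f)
#'   is the number of sequences of genome g in family f.
#' @export
build_occurrence_matrix <- function(fams, seq2genome) {
  if (is.character(seq2genome) && length(seq2genome) == 1L && file.exists(seq2genome)) {
    mt <- utils::read.table(seq2genome, sep = "\t", header = FALSE,
                            stringsAsFactors = FALSE)
    seq2genome <- stats::setNames(as.character(mt[[2L]]), as.character(mt[[1L]]))
  }
  seqs <- names(fams$membership)
  unmapped <- setdiff(seqs, names(seq2genome))
  if (length(unmapped)) {
    stop("unmapped sequence id(s): ", paste(unmapped, collapse = ", "))
  }
  tab <- table(genome = seq2genome[seqs], family = fams$membership[seqs])
  m <- matrix(as.integer(tab), nrow(tab), ncol(tab),
              dimnames = dimnames(tab))
  m[, order(colnames(m)), drop = FALSE]
}

#' Write / read an occurrence matrix as TSV
#'
#' @param mat integer matrix (genomes x families).
#' @param path file path.
#' @return the path (write) or the matrix (read).
#' @export
write_occurrence_matrix <- function(mat, path) {
  df <- data.frame(genome = rownames(mat), mat, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_occurrence_matrix
#' @export
read_occurrence_matrix <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                          stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  mode(m) <- "integer"
  rownames(m) <- df[[1L]]
  m
}

#' Write family membership as TSV
#'
#' @param fams a `family_set`.
#' @param path file path.
#' @export
write_families <- function(fams, path) {
  df <- data.frame(sequence = names(fams$membership),
                   family = unname(fams$membership),
                   stringsAsFactors = FALSE)
  df <- df[order(df$family, df$sequence), ]
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
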