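#' Length-filter amplicon reads
#'
#' Removes reads shorter than `min_len` base pairs, the first cleaning step
#' before clustering.  The boundary is inclusive: a read of exactly `min_len`
#' bases is retained.
#'
#' @param records A named character vector of DNA sequences or a
#'   [Biostrings::DNAStringSet].
#' @param min_len Minimum length in bp (default 100).
#' @return The retained records, same class as the input, order preserved.
#' @export
filter_by_length <- function(records, min_len = 100) {
  if (length(records) == 0) return(records)
  len <- if (methods::is(records, "XStringSet")) Biostrings::width(records)
         else nchar(records)
  records[len >= min_len]
}

#' Pairwise global-alignment identity
#'
#' Fraction of identical columns over the full global alignment of two DNA
#' sequences (end gaps penalized).  Scoring is fixed at match +1, mismatch
#' -1, gap column -2; N bases mismatch everything.  Arguments are
#' canonicalized (sorted) before aligning so the value is exactly symmetric.
#'
#' @param a,b DNA sequences (character scalars or `DNAString`s).
#' @return Identity as a fraction in \[0, 1\].
#' @export
pairwise_identity <- function(a, b) {
  a <- toupper(as.character(a)); b <- toupper(as.character(b))
  if (nchar(a) == 0 || nchar(b) == 0)
    stop("pairwise_identity: sequences must be non-empty")
  if (nchar(a) > nchar(b) || (nchar(a) == nchar(b) && a > b)) {
    tmp <- a; a <- b; b <- tmp
  }
  .nw_align(a, b)$identity
}

#' Greedy centroid clustering into MOTUs
#'
#' Deterministic greedy clustering at a fixed identity threshold.  Reads are
#' dereplicated; unique sequences are processed in order of decreasing copy
#' number (abundance of identical reads), ties broken lexicographically by
#' the smallest read id carrying the sequence.  Each sequence joins the first
#' existing centroid whose pairwise identity (see [pairwise_identity()]) is
#' at least `threshold`, otherwise it founds a new centroid.  Centroids never
#' change once founded, so the procedure is order-deterministic.
#'
#' @param records Named character vector or `DNAStringSet` of reads (ids must
#'   be unique).
#' @param threshold Identity threshold as a fraction (default 0.97).
#' @return An object of class `motu_set`: a list with
#'   \describe{
#'     \item{motus}{data.frame with `motu_id`, `representative_id`,
#'       `representative` (sequence), `size` (member reads).}
#'     \item{members}{data.frame mapping `seq_id` to `motu_id`.}
#'   }
#' @export
greedy_cluster <- function(records, threshold = 0.97) {
  seqs <- toupper(as.character(records))
  ids <- names(records)
  if (is.null(ids) || anyDuplicated(ids))
    stop("greedy_cluster: records must carry unique ids")
  if (length(seqs) == 0) {
    return(structure(list(
      motus = data.frame(motu_id = character(), representative_id = character(),
                         representative = character(), size = integer()),
      members = data.frame(seq_id = character(), motu_id = character())),
      class = "motu_set"))
  }

  # dereplicate: one row per unique sequence, keyed by smallest member id
  grp <- split(ids, seqs)
  uniq <- data.frame(seq = names(grp),
                     rep_id = vapply(grp, function(x) min(x), character(1)),
                     n = lengths(grp), stringsAsFactors = FALSE)
  uniq <- uniq[order(-uniq$n, uniq$rep_id), , drop = FALSE]

  cent_seq <- character(0); cent_len <- integer(0)
  assign_to <- integer(nrow(uniq))
  for (k in seq_len(nrow(uniq))) {
    s <- uniq$seq[k]; ls <- nchar(s)
    hit <- 0L
    for (c in seq_along(cent_seq)) {
      # identity can never exceed min(len)/max(len); skip hopeless pairs
      if (min(ls, cent_len[c]) / max(ls, cent_len[c]) < threshold) next
      if (pairwise_identity(s, cent_seq[c]) >= threshold) { hit <- c; break }
    }
    if (hit == 0L) {
      cent_seq <- c(cent_seq, s); cent_len <- c(cent_len, ls)
      hit <- length(cent_seq)
    }
    assign_to[k] <- hit
  }

  motu_id <- sprintf("MOTU%04d", seq_along(cent_seq))
  founder <- match(seq_along(cent_seq), assign_to)  # first row assigned = founder
  sizes <- vapply(seq_along(cent_seq),
                  function(c) sum(uniq$n[assign_to == c]), numeric(1))
  members <- do.call(rbind, lapply(seq_len(nrow(uniq)), function(k)
    data.frame(seq_id = grp[[uniq$seq[k]]], motu_id = motu_id[assign_to[k]],
               stringsAsFactors = FALSE)))
  rownames(members) <- NULL
  structure(list(
    motus = data.frame(motu_id = motu_id,
                       representative_id = uniq$rep_id[founder],
                       representative = cent_seq,
                       size = as.integer(sizes), stringsAsFactors = FALSE),
    members = members), class = "motu_set")
}

#' @export
print.motu_set <- function(x, ...) {
  cat("MOTU set:", nrow(x$motus), "MOTUs,", nrow(x$members), "member reads\n")
  print(head(x$motus[, c("motu_id", "representative_id", "size")]))
  invisible(x)
}

#' Samples-by-MOTUs abundance matrix
#'
#' Tallies the member reads of each MOTU per sample.  Every member read id
#' must appear in the read map; rows cover every sample in the map, so row
#' sums equal the per-sample retained read counts.
#'
#' @param motus A `motu_set` from [greedy_cluster()].
#' @param read_map data.frame with columns `seq_id` and `sample_id`.
#' @return Integer matrix, rows samples, columns MOTUs.
#' @export
build_abundance_matrix <- function(motus, read_map) {
  stopifnot(inherits(motus, "motu_set"),
            all(c("seq_id", "sample_id") %in% names(read_map)))
  samples <- sort(unique(read_map$sample_id))
  mids <- motus$motus$motu_id
  mat <- matrix(0L, nrow = length(samples), ncol = length(mids),
                dimnames = list(samples, mids))
  if (nrow(motus$members) == 0) return(mat)
  idx <- match(motus$members$seq_id, read_map$seq_id)
  if (anyNA(idx)) {
    bad <- motus$members$seq_id[which(is.na(idx))[1]]
    stop("build_abundance_matrix: read id not in read map: ", bad)
  }
  tab <- table(factor(read_map$sample_id[idx], levels = samples),
               factor(motus$members$motu_id, levels = mids))
  mat[] <- as.integer(tab)
  mat
}
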