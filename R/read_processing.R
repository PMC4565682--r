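# Raw-read cleanup: 3' adapter removal, length filtering, and collapsing to
# unique sequence tags with per-sample counts.

#' Trim the 3' adapter from reads
#'
#' Scans each read left-to-right for the first position at which a prefix of
#' the adapter (of length at least `min_overlap`) matches, allowing
#' mismatches at a rate of at most `max_mismatch_rate` of the overlap
#' length. Everything from that position to the 3' end is removed. Reads
#' with no detectable adapter are returned unchanged: exclusion is by length
#' afterwards, not by adapter presence.
#'
#' @param reads Character vector of read sequences (DNA, upper case).
#' @param adapter Adapter sequence (DNA).
#' @param min_overlap Minimum adapter prefix length to accept a hit (nt).
#' @param max_mismatch_rate Maximum fraction of mismatching bases within the
#'   overlap.
#' @return Character vector of trimmed sequences, same length/order.
#' @export
trim_adapter <- function(reads, adapter, min_overlap = 7L,
                         max_mismatch_rate = 0.1) {
  if (!nzchar(adapter)) stop2("adapter must be non-empty")
  adapter <- normalise_dna(adapter)
  n <- length(reads)
  if (n == 0L) return(character())
  out <- reads

  # Fast path: exact occurrence of the full adapter anywhere in the read.
  hit <- regexpr(adapter, reads, fixed = TRUE)
  full <- hit > 0L
  out[full] <- substr(reads[full], 1L, hit[full] - 1L)

  # Fast path: exact adapter *prefix* at the very 3' end (partial adapter
  # falling off the read). Longest overlap first so the leftmost cut wins.
  todo <- which(!full)
  na <- nchar(adapter)
  if (length(todo) && na - 1L >= min_overlap) {
    for (k in seq(na - 1L, min_overlap)) {
      if (!length(todo)) break
      pre <- substr(adapter, 1L, k)
      ends <- endsWith(out[todo], pre)
      if (any(ends)) {
        i <- todo[ends]
        out[i] <- substr(out[i], 1L, nchar(out[i]) - k)
        todo <- todo[!ends]
      }
    }
  }
  # Slow path: mismatch-tolerant scan for whatever remains untrimmed.
  if (max_mismatch_rate > 0 && length(todo)) {
    out[todo] <- vapply(reads[todo], trim_adapter_one, "",
                        adapter = adapter, min_overlap = min_overlap,
                        max_mismatch_rate = max_mismatch_rate,
                        USE.NAMES = FALSE)
  }
  out
}

# Position-by-position scan for one read; only reached when no exact hit
# exists, so the cost does not matter for simulated libraries.
trim_adapter_one <- function(read, adapter, min_overlap, max_mismatch_rate) {
  nr <- nchar(read)
  na <- nchar(adapter)
  if (nr < min_overlap) return(read)
  rb <- utf8ToInt(read)
  ab <- utf8ToInt(adapter)
  for (pos in seq_len(nr - min_overlap + 1L)) {
    len <- min(na, nr - pos + 1L)
    mm <- sum(rb[pos:(pos + len - 1L)] != ab[seq_len(len)])
    if (mm <= floor(max_mismatch_rate * len)) {
      return(substr(read, 1L, pos - 1L))
    }
  }
  read
}

#' Filter sequences by length
#'
#' Retains sequences whose length L satisfies `min_len <= L <= max_len`
#' (bounds inclusive: sequences *smaller than* `min_len` or *longer than*
#' `max_len` are excluded).
#'
#' @param x Character vector of sequences, or a collapsed tag data.frame
#'   with a `sequence` column.
#' @param min_len,max_len Inclusive length bounds in nt.
#' @return Object of the same type with out-of-range sequences removed.
#' @export
length_filter <- function(x, min_len = 18L, max_len = 25L) {
  if (is.data.frame(x)) {
    keep <- nchar(x$sequence) >= min_len & nchar(x$sequence) <= max_len
    x[keep, , drop = FALSE]
  } else {
    x[nchar(x) >= min_len & nchar(x) <= max_len]
  }
}

#' Collapse reads to unique sequence tags
#'
#' @param reads Character vector of cleaned read sequences.
#' @param sample_id Optional sample label attached to the result.
#' @return A data.frame with columns `sequence`, `count`, ordered by count
#'   descending then sequence; the counts sum to `length(reads)`.
#' @export
collapse_reads <- function(reads, sample_id = NULL) {
  if (length(reads) == 0L) {
    out <- data.frame(sequence = character(), count = integer(),
                      stringsAsFactors = FALSE)
  } else {
    tab <- table(reads)
    out <- data.frame(sequence = names(tab), count = as.integer(tab),
                      stringsAsFactors = FALSE)
    out <- out[order(-out$count, out$sequence), , drop = FALSE]
    rownames(out) <- NULL
  }
  if (!is.null(sample_id)) attr(out, "sample_id") <- sample_id
  out
}

#' Clean and collapse one sample's reads
#'
#' Convenience wrapper applying [trim_adapter()], [length_filter()] and
#' [collapse_reads()] in the pipeline order.
#'
#' @param reads Character vector of raw read sequences.
#' @param config A [load_config()] object.
#' @param sample_id Optional sample label.
#' @return A tag data.frame (see [collapse_reads()]) with attribute
#'   `lib_size` = number of cleaned reads surviving the length filter.
#' @export
process_reads <- function(reads, config = load_config(quiet = TRUE),
                          sample_id = NULL) {
  trimmed <- trim_adapter(reads, config$adapter, config$min_overlap,
                          config$max_mismatch_rate)
  kept <- length_filter(trimmed, config$min_len, config$max_len)
  tags <- collapse_reads(kept, sample_id)
  attr(tags, "lib_size") <- length(kept)
  tags
}

#' Merge per-sample tag tables into a tags-by-samples count matrix
#'
#' @param tag_list Named list of per-sample tag data.frames.
#' @return Integer matrix, unique sequences as rownames, samples as
#'   colnames, with a `lib_sizes` attribute (total cleaned reads per
#'   sample).
#' @export
tags_to_matrix <- function(tag_list) {
  stopifnot(length(tag_list) > 0L, !is.null(names(tag_list)))
  seqs <- sort(unique(unlist(lapply(tag_list, `[[`, "sequence"))))
  m <- matrix(0L, nrow = length(seqs), ncol = length(tag_list),
              dimnames = list(seqs, names(tag_list)))
  for (s in names(tag_list)) {
    tl <- tag_list[[s]]
    m[tl$sequence, s] <- tl$count
  }
  attr(m, "lib_sizes") <- vapply(
    tag_list, function(t) attr(t, "lib_size") %||% sum(t$count), 0)
  m
}
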