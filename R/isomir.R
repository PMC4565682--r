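# IsomiR-tolerant assignment of unique sequence tags to mature reference
# miRNAs. A tag is accepted as an isomiR of a mature reference if some
# ungapped placement puts both the 5' and 3' ends within +/-2 nt of the
# mature ends with at most one mismatching base. Extension bases that fall
# outside the mature sequence are compared against precursor flanking
# context when a precursor is available; without context an extension base
# is charged as a mismatch (templated and non-templated additions are then
# indistinguishable).
#
# Offset conventions (0-based, relative to the mature 5' end):
#   offset5 = tag start - mature start  (negative = 5' extension)
#   offset3 = tag end   - mature end    (positive = 3' extension)

# Build, for each mature reference, a context string `XX<mature>YY` where
# the two flanks come from the precursor (if one containing the mature
# sequence exists) and are padded with 'N' otherwise. 'N' never matches.
reference_contexts <- function(reference) {
  mat <- reference[reference$kind == "mature", , drop = FALSE]
  pre <- reference[reference$kind == "precursor", , drop = FALSE]
  ctx <- character(nrow(mat))
  for (i in seq_len(nrow(mat))) {
    m <- mat$sequence[i]
    left <- right <- ""
    j <- match(mat$ref_id[i], pre$ref_id)
    if (!is.na(j)) {
      p <- pre$sequence[j]
      at <- regexpr(m, p, fixed = TRUE)
      if (at > 0L) {
        left <- substr(p, max(1L, at - 2L), at - 1L)
        right <- substr(p, at + nchar(m), min(nchar(p), at + nchar(m) + 1L))
      }
    }
    left <- paste0(strrep("N", 2L - nchar(left)), left)
    right <- paste0(right, strrep("N", 2L - nchar(right)))
    ctx[i] <- paste0(left, m, right)
  }
  data.frame(ref_id = mat$ref_id, mature = mat$sequence,
             mature_len = nchar(mat$sequence), context = ctx,
             stringsAsFactors = FALSE)
}

#' Match one tag against one mature reference
#'
#' Considers every ungapped placement whose 5' and 3' offsets both lie
#' within `max_shift` nt of the mature ends and returns the placement with
#' the fewest mismatches, provided it does not exceed `max_mismatch`; ties
#' between placements are broken by the smaller total shift
#' `|offset5| + |offset3|`.
#'
#' @param tag Tag sequence (DNA, upper case).
#' @param mature Mature reference sequence.
#' @param context Optional 2-nt-flanked context string (see details); built
#'   from `mature` with `N` padding when omitted.
#' @param max_shift Maximum absolute end offset in nt.
#' @param max_mismatch Maximum number of mismatching bases.
#' @return A one-row data.frame `(offset5, offset3, mismatches)`, or `NULL`
#'   when no placement qualifies.
#' @export
match_tag <- function(tag, mature, context = NULL, max_shift = 2L,
                      max_mismatch = 1L) {
  if (is.null(context)) {
    context <- paste0("NN", mature, "NN")
  }
  hit <- match_tag_ints(utf8ToInt(tag), utf8ToInt(context), nchar(mature),
                        max_shift, max_mismatch)
  if (is.null(hit)) return(NULL)
  data.frame(offset5 = hit[1L], offset3 = hit[2L], mismatches = hit[3L])
}

# Integer-vector workhorse shared by match_tag() and annotate_tags().
# Context strings carry exactly 2 nt of flank padding, so max_shift > 2 is
# not supported. Returns c(offset5, offset3, mismatches) or NULL.
match_tag_ints <- function(tag_i, ctx_i, mature_len, max_shift, max_mismatch) {
  stopifnot(max_shift <= 2L)
  lt <- length(tag_i)
  best <- NULL
  n_code <- 78L  # 'N'
  for (off5 in -max_shift:max_shift) {
    off3 <- off5 + lt - mature_len
    if (abs(off3) > max_shift) next
    start <- off5 + 3L  # mature position 0 sits at context index 3
    win <- ctx_i[start:(start + lt - 1L)]
    mm <- sum(win != tag_i | win == n_code)
    if (mm <= max_mismatch) {
      shift <- abs(off5) + abs(off3)
      if (is.null(best) || mm < best[3L] ||
          (mm == best[3L] && shift < abs(best[1L]) + abs(best[2L]))) {
        best <- c(off5, off3, mm)
      }
    }
  }
  best
}

#' Annotate unique tags against a mature miRNA reference
#'
#' Each tag is matched against every mature reference under the isomiR
#' tolerance. A tag matching k references contributes its *full* count to
#' each of the k count-matrix rows (multi-mapped tags are associated with
#' all their references, not split). Tags matching nothing are returned as
#' the unannotated set. A per-reference isoform composition report (count
#' fraction of the canonical sequence vs isomiR variants) is also produced;
#' composition uses each tag's best reference under the deterministic
#' tie-break: fewest mismatches, then smallest total shift, then
#' lexicographic `ref_id`.
#'
#' @param tags Integer matrix of unique tags by samples (see
#'   [tags_to_matrix()]), or a single-sample tag data.frame.
#' @param reference A [as_reference_set()] object.
#' @param max_shift,max_mismatch IsomiR tolerance (nt, bases).
#' @return A list with elements:
#'   \describe{
#'     \item{counts}{integer matrix, mature references x samples (all
#'       references retained, including zero rows);}
#'     \item{assignments}{data.frame of every (tag, reference) assignment
#'       with offsets and mismatch count;}
#'     \item{unannotated}{the rows of `tags` assigned to no reference;}
#'     \item{composition}{per-reference canonical/variant count fractions.}
#'   }
#' @export
annotate_tags <- function(tags, reference, max_shift = 2L, max_mismatch = 1L) {
  if (is.data.frame(tags)) {
    m <- matrix(tags$count, ncol = 1L,
                dimnames = list(tags$sequence,
                                attr(tags, "sample_id") %||% "sample"))
    return(annotate_tags(m, reference, max_shift, max_mismatch))
  }
  stopifnot(is.matrix(tags))
  refs <- reference_contexts(reference)
  if (nrow(refs) == 0L) stop2("reference contains no mature sequences")

  seqs <- rownames(tags)
  ctx_ints <- lapply(refs$context, utf8ToInt)
  asg <- vector("list", length(seqs))
  for (ti in seq_along(seqs)) {
    tag_i <- utf8ToInt(seqs[ti])
    hits <- list()
    for (ri in seq_len(nrow(refs))) {
      h <- match_tag_ints(tag_i, ctx_ints[[ri]], refs$mature_len[ri],
                          max_shift, max_mismatch)
      if (!is.null(h)) hits[[length(hits) + 1L]] <- c(ri, h)
    }
    if (length(hits)) asg[[ti]] <- do.call(rbind, hits)
  }

  hit_rows <- which(!vapply(asg, is.null, TRUE))
  assignments <- if (length(hit_rows)) {
    a <- do.call(rbind, asg[hit_rows])
    data.frame(sequence = rep(seqs[hit_rows],
                              vapply(asg[hit_rows], nrow, 0L)),
               ref_id = refs$ref_id[a[, 1L]],
               offset5 = a[, 2L], offset3 = a[, 3L], mismatches = a[, 4L],
               stringsAsFactors = FALSE)
  } else {
    data.frame(sequence = character(), ref_id = character(),
               offset5 = integer(), offset3 = integer(),
               mismatches = integer(), stringsAsFactors = FALSE)
  }
  stopifnot(all(abs(assignments$offset5) <= max_shift),
            all(abs(assignments$offset3) <= max_shift),
            all(assignments$mismatches <= max_mismatch))

  counts <- matrix(0L, nrow = nrow(refs), ncol = ncol(tags),
                   dimnames = list(refs$ref_id, colnames(tags)))
  for (k in seq_len(nrow(assignments))) {
    counts[assignments$ref_id[k], ] <-
      counts[assignments$ref_id[k], ] + tags[assignments$sequence[k], ]
  }

  unannotated <- tags[setdiff(seq_along(seqs), hit_rows), , drop = FALSE]

  composition <- isoform_composition(assignments, tags)

  lengths <- refs$mature_len
  names(lengths) <- refs$ref_id
  list(counts = counts, assignments = assignments,
       unannotated = unannotated, composition = composition,
       lengths = lengths)
}

# Per-reference isoform composition, attributing each tag to its single
# best reference (deterministic tie-break) so fractions sum to 1 within a
# reference.
isoform_composition <- function(assignments, tags) {
  if (nrow(assignments) == 0L) {
    return(data.frame(ref_id = character(), canonical_fraction = numeric(),
                      variant_fraction = numeric(), n_tags = integer(),
                      stringsAsFactors = FALSE))
  }
  a <- assignments
  a$total <- rowSums(tags)[a$sequence]
  a$shift <- abs(a$offset5) + abs(a$offset3)
  ord <- order(a$sequence, a$mismatches, a$shift, a$ref_id)
  a <- a[ord, , drop = FALSE]
  best <- a[!duplicated(a$sequence), , drop = FALSE]
  best$canonical <- best$offset5 == 0L & best$offset3 == 0L &
    best$mismatches == 0L
  agg <- lapply(split(best, best$ref_id), function(b) {
    data.frame(ref_id = b$ref_id[1L],
               canonical_fraction = sum(b$total[b$canonical]) / sum(b$total),
               variant_fraction = sum(b$total[!b$canonical]) / sum(b$total),
               n_tags = nrow(b), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, agg)
  rownames(out) <- NULL
  out
}
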