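# Readers/writers for the external formats used throughout the pipeline:
# FASTA/FASTQ reads and references, TSV count matrices, sample sheets,
# CSV quantification-cycle (Cq) tables, dilution series, and the YAML run
# configuration. All downstream modules consume only the objects produced
# here.

#' Read small-RNA reads from FASTA or FASTQ
#'
#' Sequences are upper-cased and RNA `U` is mapped to `T` so that all
#' downstream matching operates in DNA space. Record order is preserved.
#' Malformed records raise an error naming the offending line rather than
#' being skipped silently.
#'
#' @param path Path to a FASTA or FASTQ file.
#' @param format One of `"auto"` (guess from the first character), `"fasta"`
#'   or `"fastq"`.
#' @return A data.frame with columns `read_id`, `sequence` and `quality`
#'   (`NA` for FASTA input).
#' @export
read_reads <- function(path, format = c("auto", "fasta", "fastq")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop2("file not found: ", path)
  if (format == "auto") {
    first <- substr(readLines(path, n = 1L), 1L, 1L)
    if (length(first) == 0L) {
      return(data.frame(read_id = character(), sequence = character(),
                        quality = character(), stringsAsFactors = FALSE))
    }
    format <- switch(first, "@" = "fastq", ">" = "fasta",
                     stop2("cannot guess format of ", path,
                           ": first character is neither '>' nor '@'"))
  }
  if (format == "fasta") read_fasta_reads(path) else read_fastq_reads(path)
}

read_fasta_reads <- function(path) {
  seqs <- tryCatch(
    Biostrings::readBStringSet(path, format = "fasta"),
    error = function(e) stop2("FASTA parse error in ", path, ": ",
                              conditionMessage(e)))
  data.frame(read_id = names(seqs),
             sequence = normalise_dna(as.character(seqs)),
             quality = NA_character_,
             stringsAsFactors = FALSE, row.names = NULL)
}

# FASTQ is read with a structural validator so that malformed records are
# reported with their line number (a contract the pipeline relies on when
# ingesting third-party files).
read_fastq_reads <- function(path) {
  lines <- readLines(path)
  n <- length(lines)
  if (n == 0L) {
    return(data.frame(read_id = character(), sequence = character(),
                      quality = character(), stringsAsFactors = FALSE))
  }
  if (n %% 4L != 0L) {
    stop2("FASTQ parse error in ", path, ": truncated record near line ", n)
  }
  idx <- seq(1L, n, by = 4L)
  bad_at <- !startsWith(lines[idx], "@")
  if (any(bad_at)) {
    stop2("FASTQ parse error in ", path, ": expected '@' header at line ",
          idx[which(bad_at)[1L]])
  }
  bad_plus <- !startsWith(lines[idx + 2L], "+")
  if (any(bad_plus)) {
    stop2("FASTQ parse error in ", path, ": expected '+' separator at line ",
          idx[which(bad_plus)[1L]] + 2L)
  }
  seqs <- lines[idx + 1L]
  quals <- lines[idx + 3L]
  bad_len <- nchar(seqs) != nchar(quals)
  if (any(bad_len)) {
    stop2("FASTQ parse error in ", path,
          ": sequence/quality length mismatch at line ",
          idx[which(bad_len)[1L]] + 1L)
  }
  data.frame(read_id = sub("^@", "", sub("\\s.*$", "", lines[idx])),
             sequence = normalise_dna(seqs),
             quality = quals,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Read a mature/precursor miRNA reference set from FASTA
#'
#' @param mature_path FASTA of mature miRNA sequences.
#' @param precursor_path Optional FASTA of precursor sequences. Precursor
#'   ids must match the mature id they contextualise.
#' @return A `reference_set` data.frame with columns `ref_id`, `sequence`,
#'   `kind`.
#' @export
read_reference <- function(mature_path, precursor_path = NULL) {
  mat <- read_fasta_reads(mature_path)
  ref <- data.frame(ref_id = mat$read_id, sequence = mat$sequence,
                    kind = "mature", stringsAsFactors = FALSE)
  if (!is.null(precursor_path)) {
    pre <- read_fasta_reads(precursor_path)
    ref <- rbind(ref, data.frame(ref_id = pre$read_id,
                                 sequence = pre$sequence,
                                 kind = "precursor",
                                 stringsAsFactors = FALSE))
  }
  as_reference_set(ref)
}

#' Construct and validate a reference set
#'
#' A reference set holds mature miRNA sequences (the annotation targets) and,
#' optionally, precursor sequences providing flanking context for templated
#' isomiR extensions.
#'
#' @param ref A data.frame with columns `ref_id`, `sequence`, `kind`
#'   (`"mature"` or `"precursor"`).
#' @return The validated data.frame with class `reference_set`.
#' @export
as_reference_set <- function(ref) {
  stopifnot(is.data.frame(ref),
            all(c("ref_id", "sequence", "kind") %in% names(ref)))
  ref$sequence <- normalise_dna(ref$sequence)
  if (!all(ref$kind %in% c("mature", "precursor"))) {
    stop2("reference kind must be 'mature' or 'precursor'")
  }
  dup <- duplicated(paste(ref$ref_id, ref$kind))
  if (any(dup)) stop2("duplicate reference ids: ",
                      paste(unique(ref$ref_id[dup]), collapse = ", "))
  lens <- nchar(ref$sequence[ref$kind == "mature"])
  if (any(lens < 16L | lens > 30L)) {
    stop2("mature reference lengths must lie in [16, 30] nt")
  }
  class(ref) <- c("reference_set", "data.frame")
  ref
}

#' Write / read a transcripts-by-samples count matrix as TSV
#'
#' The on-disk format is a plain TSV whose first column is `transcript_id`
#' followed by one integer column per sample; write/read round-trips are
#' exact.
#'
#' @param counts Integer matrix with transcript rownames and sample colnames.
#' @param path Output (input) path.
#' @return `read_count_matrix` returns the integer matrix.
#' @export
write_count_matrix <- function(counts, path) {
  stopifnot(is.matrix(counts), nrow(counts) > 0L,
            !is.null(rownames(counts)), !is.null(colnames(counts)))
  df <- data.frame(transcript_id = rownames(counts), counts,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_count_matrix
#' @export
read_count_matrix <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE,
                          stringsAsFactors = FALSE, comment.char = "#")
  if (names(df)[1L] != "transcript_id") {
    stop2("count matrix must have 'transcript_id' as its first column")
  }
  if (anyDuplicated(df$transcript_id)) {
    stop2("duplicate transcript ids in ", path)
  }
  m <- as.matrix(df[, -1L, drop = FALSE])
  if (!is.numeric(m) || any(is.na(m)) || any(m != round(m))) {
    stop2("non-integer count values in ", path)
  }
  storage.mode(m) <- "integer"
  rownames(m) <- df$transcript_id
  m
}

#' Read a sample sheet
#'
#' @param path TSV with columns `sample_id`, `group` (`control`/`case`) and
#'   optionally `fraction` (`total`/`enriched`, qPCR only) and `file_path`.
#' @return A validated data.frame.
#' @export
read_sample_sheet <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  validate_sample_sheet(df)
}

validate_sample_sheet <- function(df) {
  stopifnot(all(c("sample_id", "group") %in% names(df)))
  if (anyDuplicated(df$sample_id)) stop2("sample_ids must be unique")
  if (!all(df$group %in% c("control", "case"))) {
    stop2("group must be 'control' or 'case'")
  }
  if ("fraction" %in% names(df) &&
      !all(df$fraction %in% c("total", "enriched"))) {
    stop2("fraction must be 'total' or 'enriched'")
  }
  df
}

#' Read / write a Cq table
#'
#' A Cq table is a CSV with header
#' `sample_id,assay_id,fraction,replicate,cq`; one row per technical
#' replicate. Cq values must be strictly positive cycles.
#'
#' @param path CSV path.
#' @param cq A Cq table data.frame.
#' @return `read_cq_table` returns the validated data.frame.
#' @export
read_cq_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, comment.char = "#")
  validate_cq_table(df)
}

validate_cq_table <- function(df) {
  need <- c("sample_id", "assay_id", "fraction", "replicate", "cq")
  if (!all(need %in% names(df))) {
    stop2("Cq table must have columns ", paste(need, collapse = ", "))
  }
  if (!all(df$fraction %in% c("total", "enriched"))) {
    stop2("Cq fraction must be 'total' or 'enriched'")
  }
  if (!is.numeric(df$cq) || any(is.na(df$cq)) || any(df$cq <= 0)) {
    stop2("cq values must be positive cycles")
  }
  df
}

#' @rdname read_cq_table
#' @export
write_cq_table <- function(cq, path) {
  validate_cq_table(cq)
  utils::write.csv(cq, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a standard-curve dilution series
#'
#' @param path CSV with columns `assay_id`, `copies`, `cq` (one row per
#'   replicate measurement of one dilution point).
#' @return A validated data.frame.
#' @export
read_dilution_series <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, comment.char = "#")
  need <- c("assay_id", "copies", "cq")
  if (!all(need %in% names(df))) {
    stop2("dilution series must have columns ", paste(need, collapse = ", "))
  }
  if (any(df$copies <= 0)) stop2("dilution copies must be positive")
  df
}

# ---- Run configuration -----------------------------------------------------

config_defaults <- function() {
  list(
    adapter = "TGGAATTCTCGGGTGCCAAGG",  # Illumina TruSeq small RNA 3' adapter
    min_len = 18L,
    max_len = 25L,
    isomir_max_shift = 2L,
    isomir_max_mismatch = 1L,
    cpm_threshold = 1.0,
    cpm_min_samples = 3L,
    exclusive_min_reads = 10L,
    alpha = 0.05,
    quantile_mode = "full",
    tmm_trim_m = 0.30,
    tmm_trim_a = 0.05,
    min_overlap = 7L,
    max_mismatch_rate = 0.1,
    seed = 1L
  )
}

#' Load the run configuration
#'
#' Reads a YAML configuration file; keys not present take their documented
#' defaults. Unknown keys are rejected (anti-typo contract). Calling with
#' `path = NULL` returns the defaults.
#'
#' @param path Path to a YAML config file, or `NULL` for defaults.
#' @param quiet Suppress the effective-configuration log line.
#' @return A named list of class `run_config`.
#' @export
load_config <- function(path = NULL, quiet = FALSE) {
  cfg <- config_defaults()
  if (!is.null(path)) {
    user <- yaml::read_yaml(path)
    if (length(user)) {
      unknown <- setdiff(names(user), names(cfg))
      if (length(unknown)) {
        stop2("unknown config key(s): ", paste(unknown, collapse = ", "))
      }
      for (k in names(user)) {
        v <- user[[k]]
        if (is.numeric(cfg[[k]]) && is.numeric(v)) {
          v <- if (is.integer(cfg[[k]])) as.integer(v) else as.numeric(v)
        }
        cfg[[k]] <- v
      }
    }
  }
  if (!cfg$quantile_mode %in% c("full", "upper_quartile")) {
    stop2("quantile_mode must be 'full' or 'upper_quartile'")
  }
  class(cfg) <- "run_config"
  if (!quiet) {
    message("effective config: ",
            paste(names(cfg), vapply(cfg, format, ""), sep = "=",
                  collapse = " "))
  }
  cfg
}

#' @export
print.run_config <- function(x, ...) {
  cat("crossmir run configuration\n")
  for (k in names(x)) cat(sprintf("  %-20s %s\n", k, format(x[[k]])))
  invisible(x)
}
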