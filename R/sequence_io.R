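#' Read protein sequences from a FASTA file
#'
#' Parses a (multi-line) FASTA file into a data frame of protein records.
#' Sequences are uppercased; the header token before the first whitespace
#' becomes the record id. Sequences are not validated here; see
#' [validate_sequence()] and [load_dataset()].
#'
#' @param path Path to a FASTA file.
#' @return A data frame with columns `id` and `sequence`, one row per entry.
#' @examples
#' fa <- tempfile(fileext = ".fasta")
#' writeLines(c(">p1 description", "ACDEF", ">p2", "MKV"), fa)
#' read_fasta(fa)
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  nonblank <- which(!grepl("^\\s*$", lines))
  if (length(nonblank) == 0L) {
    warning("empty FASTA file: ", path)
    return(data.frame(id = character(), sequence = character(),
                      stringsAsFactors = FALSE))
  }
  if (!startsWith(lines[nonblank[1L]], ">")) {
    stop("malformed FASTA: sequence data before first header at line ",
         nonblank[1L], " of ", path)
  }
  set <- Biostrings::readBStringSet(path, format = "fasta")
  ids <- sub("^\\s*(\\S+).*$", "\\1", names(set))
  data.frame(id = ids, sequence = toupper(as.character(set)),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Write protein records to a FASTA file
#'
#' @param records Data frame with columns `id` and `sequence`.
#' @param path Output file path.
#' @param width Line-wrap width for sequences.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path, width = 60L) {
  set <- Biostrings::BStringSet(stats::setNames(records$sequence,
                                                records$id))
  Biostrings::writeXStringSet(set, path, format = "fasta", width = width)
  invisible(path)
}

#' Validate a protein sequence against the 20-letter standard alphabet
#'
#' Records containing ambiguous or non-standard residues (B, J, O, U, X, Z,
#' gaps, stops) are rejected outright — the deletion policy applied when the
#' training compendium was assembled — rather than masked.
#'
#' @param raw A single character string.
#' @param policy `"reject"` throws an error on invalid input;
#'   `"drop_record"` returns `NA_character_` so callers can exclude the record.
#' @return The uppercased sequence, or `NA_character_` under
#'   `policy = "drop_record"` when the sequence is invalid.
#' @export
validate_sequence <- function(raw, policy = c("reject", "drop_record")) {
  policy <- match.arg(policy)
  if (length(raw) != 1L || is.na(raw) || !nzchar(raw)) {
    if (policy == "reject") stop("empty sequence")
    return(NA_character_)
  }
  s <- toupper(raw)
  chars <- strsplit(s, "", fixed = TRUE)[[1]]
  bad <- setdiff(unique(chars), AA_ALPHABET)
  if (length(bad) > 0L) {
    if (policy == "reject") {
      stop("sequence contains non-standard residue(s): ",
           paste(bad, collapse = ", "))
    }
    return(NA_character_)
  }
  s
}

#' Load a training table of sequences and melting temperatures
#'
#' Reads a delimited table with required columns `id`, `sequence`, `tm`
#' (melting temperature, degrees Celsius) and optional columns `species` and
#' `ogt`. Rows with non-standard residues, missing/non-numeric Tm, or Tm
#' outside the plausibility window \[0, 150\] degrees C are excluded with a
#' message; sequences shorter than `min_length` are excluded because the
#' sequence-order descriptor families with default lag 30 are undefined below
#' 31 residues.
#'
#' @param path Path to a TSV (default) or CSV table; the separator is chosen
#'   from the file extension.
#' @param min_length Minimum sequence length for inclusion (default 31).
#' @param deduplicate Collapse records with identical sequences to the first
#'   occurrence (default `TRUE`).
#' @return A data frame of class `tm_dataset` with columns `id`, `sequence`,
#'   `species`, `ogt`, `tm`, and attributes `n_excluded` and `exclusions`
#'   (a per-reason count table).
#' @export
load_dataset <- function(path, min_length = 31L, deduplicate = TRUE) {
  if (!file.exists(path)) stop("dataset file not found: ", path)
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, quote = "\"",
                           comment.char = "")
  req <- c("id", "sequence", "tm")
  missing_cols <- setdiff(req, names(tab))
  if (length(missing_cols) > 0L) {
    stop("dataset is missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  if (!"species" %in% names(tab)) tab$species <- NA_character_
  if (!"ogt" %in% names(tab)) tab$ogt <- NA_real_
  tab$id <- as.character(tab$id)
  tab$tm <- suppressWarnings(as.numeric(as.character(tab$tm)))
  tab$ogt <- suppressWarnings(as.numeric(as.character(tab$ogt)))

  valid_seq <- vapply(tab$sequence, validate_sequence, character(1),
                      policy = "drop_record", USE.NAMES = FALSE)
  reasons <- rep(NA_character_, nrow(tab))
  reasons[is.na(valid_seq)] <- "non_standard_residue"
  tab$sequence <- ifelse(is.na(valid_seq), tab$sequence, valid_seq)
  bad_tm <- is.na(reasons) & (!is.finite(tab$tm) | tab$tm < 0 | tab$tm > 150)
  reasons[bad_tm] <- "invalid_tm"
  short <- is.na(reasons) & nchar(tab$sequence) < min_length
  reasons[short] <- "too_short"

  ds <- tab[is.na(reasons), c("id", "sequence", "species", "ogt", "tm")]
  if (deduplicate) {
    dup <- duplicated(ds$sequence)
    if (any(dup)) {
      reasons_dup <- sum(dup)
      ds <- ds[!dup, ]
    } else reasons_dup <- 0L
  } else reasons_dup <- 0L
  rownames(ds) <- NULL

  excl <- table(factor(reasons[!is.na(reasons)],
                       levels = c("non_standard_residue", "invalid_tm",
                                  "too_short")))
  excl <- c(excl, duplicate = reasons_dup)
  n_excl <- sum(excl)
  if (n_excl > 0L) {
    message("load_dataset: excluded ", n_excl, " of ", nrow(tab), " rows (",
            paste(sprintf("%s=%d", names(excl)[excl > 0], excl[excl > 0]),
                  collapse = ", "), ")")
  }
  structure(ds, n_excluded = n_excl, exclusions = excl,
            class = c("tm_dataset", "data.frame"))
}

#' Write a dataset to a delimited table
#'
#' Inverse of [load_dataset()]; emits the `id`, `sequence`, `species`, `ogt`,
#' `tm` columns as TSV (or CSV by extension).
#'
#' @param ds Dataset data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_dataset <- function(ds, path) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  utils::write.table(ds, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Split a dataset into training and blind test partitions
#'
#' Random, seed-reproducible partition. The blind fraction defaults to 10
#' percent, mirroring the proportion used when the reference compendium of
#' 34,913 proteins was divided (3443 blind of 34,913, about 9.9 percent).
#'
#' @param ds Dataset data frame (rows are records).
#' @param blind_fraction Proportion of records assigned to the blind set,
#'   strictly between 0 and 1.
#' @param seed Integer seed governing the draw.
#' @return A list with elements `train` and `blind`, disjoint data frames
#'   whose union is `ds`.
#' @export
split_dataset <- function(ds, blind_fraction = 0.1, seed = 1L) {
  if (!is.numeric(blind_fraction) || length(blind_fraction) != 1L ||
      blind_fraction <= 0 || blind_fraction >= 1) {
    stop("blind_fraction must lie strictly between 0 and 1")
  }
  n <- nrow(ds)
  n_blind <- round(blind_fraction * n)
  n_blind <- max(min(n_blind, n - 1L), 1L)
  idx <- withr::with_seed(as.integer(seed), sample.int(n, n_blind))
  train <- ds[-idx, , drop = FALSE]
  blind <- ds[idx, , drop = FALSE]
  rownames(train) <- NULL
  rownames(blind) <- NULL
  list(train = train, blind = blind)
}
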