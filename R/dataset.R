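#' Assemble and validate a class-labeled sequence dataset
#'
#' A dataset is an ordinary tibble with columns `seq_id`, `class` and
#' `residues`. This constructor validates the invariants every downstream
#' function relies on: unique sequence identifiers, non-empty sequences, and
#' residues drawn from the 20-letter amino-acid alphabet. Records carrying
#' non-standard residue codes (B, J, O, U, X, Z, `*`, gaps) are dropped with a
#' warning by default, or rejected outright.
#'
#' @param data A data frame with columns `seq_id`, `class`, `residues`.
#' @param nonstandard Policy for records with characters outside the standard
#'   alphabet: `"drop"` (default; remove with a warning) or `"reject"`
#'   (error naming the offending record).
#' @param min_length Minimum sequence length to retain; shorter records are
#'   dropped. Defaults to 1 (no length filter); curated compendia typically
#'   use 10.
#' @return A tibble with columns `seq_id`, `class`, `residues`.
#' @export
as_seq_dataset <- function(data, nonstandard = c("drop", "reject"),
                           min_length = 1L) {
  nonstandard <- match.arg(nonstandard)
  data <- as_tibble(data)
  required <- c("seq_id", "class", "residues")
  missing <- setdiff(required, names(data))
  if (length(missing) > 0) {
    abort(paste0("dataset is missing columns: ", paste(missing, collapse = ", ")))
  }
  data <- data[required]
  data$seq_id <- as.character(data$seq_id)
  data$class <- as.character(data$class)
  data$residues <- toupper(as.character(data$residues))

  bad <- !stringi::stri_detect_regex(data$residues, "^[ACDEFGHIKLMNPQRSTVWY]+$")
  if (any(bad)) {
    if (nonstandard == "reject") {
      abort(paste0("record(s) with non-standard residues: ",
                   paste(head(data$seq_id[bad], 5), collapse = ", ")))
    }
    warn(paste0("dropping ", sum(bad),
                " record(s) with non-standard or empty residues: ",
                paste(head(data$seq_id[bad], 5), collapse = ", ")))
    data <- data[!bad, ]
  }
  short <- nchar(data$residues) < min_length
  if (any(short)) data <- data[!short, ]
  if (anyDuplicated(data$seq_id)) {
    dup <- unique(data$seq_id[duplicated(data$seq_id)])
    abort(paste0("duplicate seq_id(s): ", paste(head(dup, 5), collapse = ", ")))
  }
  if (nrow(data) == 0) abort("dataset has no records after filtering")
  data
}

#' Read class-labeled sequences from one FASTA file per class
#'
#' Class labels come from the file grouping (the names of `paths`), never from
#' FASTA headers, whose conventions vary across source databases.
#'
#' @param paths Named character vector of FASTA paths; names are class labels.
#' @inheritParams as_seq_dataset
#' @return A tibble with columns `seq_id`, `class`, `residues`.
#' @examples
#' \dontrun{
#' data <- read_fasta_classes(c(CYT = "cyt.fasta", NUC = "nuc.fasta"))
#' }
#' @export
read_fasta_classes <- function(paths, nonstandard = c("drop", "reject"),
                               min_length = 1L) {
  if (is.null(names(paths)) || any(names(paths) == "")) {
    abort("`paths` must be a named vector: names are the class labels")
  }
  parts <- lapply(names(paths), function(label) {
    recs <- read_fasta_one(paths[[label]])
    if (nrow(recs) == 0) {
      abort(paste0("class '", label, "' has no sequences in ", paths[[label]]))
    }
    recs$class <- label
    recs
  })
  as_seq_dataset(do.call(rbind, parts), nonstandard = nonstandard,
                 min_length = min_length)
}

#' Read class-labeled sequences from one FASTA file plus a label manifest
#'
#' @param fasta Path to a FASTA file holding all sequences.
#' @param manifest A data frame (or path to a TSV) with columns `seq_id` and
#'   `class` assigning every record a class label.
#' @inheritParams as_seq_dataset
#' @return A tibble with columns `seq_id`, `class`, `residues`.
#' @export
read_fasta_manifest <- function(fasta, manifest, nonstandard = c("drop", "reject"),
                                min_length = 1L) {
  recs <- read_fasta_one(fasta)
  if (is.character(manifest)) {
    manifest <- read.delim(manifest, colClasses = "character")
  }
  manifest <- as_tibble(manifest)
  if (!all(c("seq_id", "class") %in% names(manifest))) {
    abort("manifest needs columns `seq_id` and `class`")
  }
  unlabeled <- setdiff(recs$seq_id, manifest$seq_id)
  if (length(unlabeled) > 0) {
    abort(paste0("manifest assigns no class to: ",
                 paste(head(unlabeled, 5), collapse = ", ")))
  }
  recs$class <- manifest$class[match(recs$seq_id, manifest$seq_id)]
  as_seq_dataset(recs, nonstandard = nonstandard, min_length = min_length)
}

read_fasta_one <- function(path) {
  if (!file.exists(path)) abort(paste0("FASTA file not found: ", path))
  set <- tryCatch(Biostrings::readAAStringSet(path),
                  error = function(e) {
                    abort(paste0("malformed FASTA in ", path, ": ",
                                 conditionMessage(e)))
                  })
  # keep only the first whitespace-delimited token of the header as the id
  ids <- stringi::stri_extract_first_regex(names(set), "^\\S+")
  tibble(seq_id = ids, class = NA_character_,
         residues = unname(as.character(set)))[, c("seq_id", "class", "residues")]
}

#' Read pattern-matching subjects from a FASTA file
#'
#' Unlike [read_fasta_classes()], applies no alphabet policy: masked
#' sequences (containing `X`) and other non-standard codes pass through
#' unchanged, as pattern matching operates on them literally.
#'
#' @param path Path to a FASTA file.
#' @return A tibble with columns `seq_id` and `residues`.
#' @export
read_fasta_subjects <- function(path) {
  recs <- read_fasta_one(path)
  recs$residues <- toupper(recs$residues)
  recs[c("seq_id", "residues")]
}

#' Write sequences to a FASTA file
#'
#' @param data A tibble with columns `seq_id` and a sequence column.
#' @param path Output path.
#' @param column Name of the column holding the sequence text (`"residues"`,
#'   or `"masked"` for masked output).
#' @return `path`, invisibly.
#' @export
write_fasta <- function(data, path, column = "residues") {
  if (!column %in% names(data)) abort(paste0("no column '", column, "' to write"))
  set <- Biostrings::AAStringSet(setNames(data[[column]], data$seq_id))
  Biostrings::writeXStringSet(set, filepath = path, width = 70L)
  invisible(path)
}
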