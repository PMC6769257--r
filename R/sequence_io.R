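## FASTA / label-table input-output and numeric encoding.
##
## Protein records are kept as a plain data.frame with columns
##   id        character, unique
##   sequence  character, upper-case, alphabet = 20 standard residues + X
##   group     "plant" or "nonplant"
##   label     optional factor-like character in tp_classes (NA if unknown)
##   cs        optional integer, 1-based index of the LAST residue of the
##             targeting peptide (cleavage occurs between cs and cs+1);
##             NA for noTP or unlabelled records.

#' Build a protein record table
#'
#' @param id character vector of unique identifiers.
#' @param sequence character vector of amino-acid sequences (will be
#'   upper-cased; ambiguity codes B, Z, J, U, O collapse to X).
#' @param group \code{"plant"} or \code{"nonplant"}, recycled.
#' @param label optional class labels (see \code{\link{tp_classes}}).
#' @param cs optional 1-based cleavage-site positions (last residue of the
#'   peptide); must be \code{NA} exactly for noTP / unlabelled records.
#' @return data.frame of class \code{tp_records}.
#' @export
tp_records <- function(id, sequence, group = "nonplant", label = NA_character_,
                       cs = NA_integer_) {
  df <- data.frame(id = as.character(id),
                   sequence = .normalise_sequence(as.character(sequence)),
                   group = rep_len(as.character(group), length(id)),
                   label = rep_len(as.character(label), length(id)),
                   cs = rep_len(as.integer(cs), length(id)),
                   stringsAsFactors = FALSE)
  validate_records(df)
  class(df) <- c("tp_records", "data.frame")
  df
}

#' Validate a record table
#'
#' Checks the record invariants: non-empty sequences over the allowed
#' alphabet, valid group and label values, cleavage sites present exactly
#' for the positive classes and strictly inside the sequence.
#'
#' @param records record data.frame.
#' @return the records, invisibly; errors describe the offending record.
#' @export
validate_records <- function(records) {
  stopifnot(is.data.frame(records),
            all(c("id", "sequence", "group") %in% names(records)))
  if (anyDuplicated(records$id))
    stop("duplicated record ids: ",
         paste(unique(records$id[duplicated(records$id)]), collapse = ", "))
  n <- nchar(records$sequence)
  if (any(n < 1)) stop("empty sequence for record ", records$id[which(n < 1)[1]])
  ok <- grepl(paste0("^[", paste(tp_residues, collapse = ""), "X]+$"),
              records$sequence)
  if (!all(ok)) {
    i <- which(!ok)[1]
    bad <- regmatches(records$sequence[i],
                      regexpr(paste0("[^", paste(tp_residues, collapse = ""), "X]"),
                              records$sequence[i]))
    pos <- regexpr(paste0("[^", paste(tp_residues, collapse = ""), "X]"),
                   records$sequence[i])
    stop("record ", records$id[i], ": invalid residue '", bad,
         "' at position ", as.integer(pos))
  }
  if (!all(records$group %in% c("plant", "nonplant")))
    stop("group must be 'plant' or 'nonplant'")
  if ("label" %in% names(records)) {
    lab <- records$label
    known <- is.na(lab) | lab %in% tp_classes
    if (!all(known)) stop("unknown label: ", lab[which(!known)[1]])
    cs <- if ("cs" %in% names(records)) records$cs else rep(NA_integer_, nrow(records))
    pos <- !is.na(lab) & lab %in% tp_cs_classes
    if (any(pos & is.na(cs)))
      stop("record ", records$id[which(pos & is.na(cs))[1]],
           ": positive class without a cleavage site")
    if (any(!is.na(cs) & (is.na(lab) | lab == "noTP")))
      stop("record ", records$id[which(!is.na(cs) & (is.na(lab) | lab == "noTP"))[1]],
           ": cleavage site given for a record without a targeting peptide")
    bad_cs <- pos & (records$cs < 1 | records$cs >= n)
    if (any(bad_cs))
      stop("record ", records$id[which(bad_cs)[1]],
           ": cleavage site must satisfy 1 <= cs < length")
  }
  invisible(records)
}

#' Read protein sequences from a FASTA file
#'
#' Identifiers are taken from the header up to the first whitespace;
#' sequences are upper-cased and ambiguity codes (B, Z, J, U, O) are mapped
#' to X.  Input order is preserved.
#'
#' @param path FASTA file.
#' @param group organism group assigned to every record
#'   (\code{"nonplant"} default; per-record groups can be set afterwards).
#' @return a \code{\link{tp_records}} data.frame (label and cs all NA).
#' @export
read_fasta <- function(path, group = "nonplant") {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  nonblank <- which(nzchar(trimws(lines)))
  if (length(nonblank) == 0L) stop("empty FASTA file: ", path)
  if (!startsWith(trimws(lines[nonblank[1]]), ">"))
    stop("malformed FASTA: line ", nonblank[1], " is not a header")
  hdr <- which(startsWith(trimws(lines), ">"))
  for (k in seq_along(hdr)) {
    from <- hdr[k] + 1L
    to <- if (k < length(hdr)) hdr[k + 1L] - 1L else length(lines)
    body <- paste(trimws(lines[seq2(from, to)]), collapse = "")
    if (!nzchar(body))
      stop("malformed FASTA: empty sequence for header at line ", hdr[k])
  }
  aa <- Biostrings::readAAStringSet(path)
  ids <- sub("\\s.*$", "", names(aa))
  tp_records(id = ids, sequence = as.character(aa), group = group)
}

seq2 <- function(from, to) if (from > to) integer(0) else seq(from, to)

#' Write records to a FASTA file
#'
#' @param records record data.frame.
#' @param path output file.
#' @param width line width for the sequence body.
#' @return \code{path}, invisibly.
#' @export
write_fasta <- function(records, path, width = 60L) {
  aa <- Biostrings::AAStringSet(records$sequence)
  names(aa) <- records$id
  Biostrings::writeXStringSet(aa, filepath = path, width = width)
  invisible(path)
}

#' Read / write the label sidecar table
#'
#' Tab-separated with header \code{id, label, cs}; \code{cs} empty for
#' noTP.  \code{read_labels} merges labels into an existing record table.
#'
#' @param records record data.frame (from \code{\link{read_fasta}}).
#' @param path TSV file.
#' @return \code{read_labels}: the records with label/cs filled in.
#' @export
read_labels <- function(records, path) {
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           colClasses = c("character", "character", "integer"))
  if (!all(c("id", "label", "cs") %in% names(tab)))
    stop("label table must have columns id, label, cs")
  i <- match(records$id, tab$id)
  if (anyNA(i))
    stop("no label for record ", records$id[which(is.na(i))[1]])
  records$label <- tab$label[i]
  records$cs <- as.integer(tab$cs[i])
  validate_records(records)
  records
}

#' @rdname read_labels
#' @export
write_labels <- function(records, path) {
  tab <- data.frame(id = records$id, label = records$label,
                    cs = ifelse(is.na(records$cs), "", as.character(records$cs)))
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Truncate records to their N-terminal window
#'
#' The model reads only the first \code{max_len} residues of each protein
#' (transit peptides are at most 162 residues long, so a 200-residue window
#' covers every annotated peptide).  Records whose cleavage site falls at or
#' beyond the window are flagged invalid for training via the logical
#' \code{valid} column.
#'
#' @param records record data.frame.
#' @param max_len window length (default 200).
#' @return records with truncated sequences and a \code{valid} column.
#' @export
truncate_n_terminal <- function(records, max_len = 200L) {
  stopifnot(max_len >= 1)
  records$valid <- TRUE
  long <- nchar(records$sequence) > max_len
  records$sequence[long] <- substr(records$sequence[long], 1L, max_len)
  bad <- !is.na(records$cs) & records$cs >= max_len
  records$valid[bad] <- FALSE
  records
}

#' Encode records as a padded BLOSUM62 batch
#'
#' Each residue becomes its 20-entry BLOSUM62 row (column order
#' \code{\link{tp_residues}}); \code{X} becomes the zero vector.  Sequences
#' are padded to the longest length in the batch (at most \code{max_len})
#' with zero features and a false mask.
#'
#' @param records record data.frame.
#' @param max_len maximum window length (default 200).
#' @return list with elements \code{features} (batch x L x 20 array),
#'   \code{lengths}, \code{mask} (batch x L logical), \code{group_vec}
#'   (1 = plant, 0 = nonplant), \code{class_targets} (1-based index into
#'   \code{\link{tp_classes}}, NA if unlabelled) and \code{cs_targets}
#'   (1-based position, -1 sentinel for noTP, NA if unlabelled).
#' @export
encode_batch <- function(records, max_len = 200L) {
  records <- truncate_n_terminal(records, max_len)
  n <- nrow(records)
  lens <- nchar(records$sequence)
  L <- max(lens)
  feat <- array(0, dim = c(n, L, 20L))
  mask <- matrix(FALSE, n, L)
  B <- .blosum62
  for (i in seq_len(n)) {
    chars <- strsplit(records$sequence[i], "")[[1]]
    idx <- match(chars, tp_residues)   # NA for X -> stays zero
    known <- !is.na(idx)
    if (any(known)) feat[i, which(known), ] <- B[idx[known], , drop = FALSE]
    mask[i, seq_len(lens[i])] <- TRUE
  }
  cls <- if ("label" %in% names(records)) .class_index(records$label) else rep(NA_integer_, n)
  cs <- rep(NA_integer_, n)
  if ("label" %in% names(records)) {
    cs[which(records$label == "noTP")] <- -1L
    pos <- which(!is.na(records$label) & records$label %in% tp_cs_classes)
    cs[pos] <- records$cs[pos]
  }
  list(features = feat, lengths = lens, mask = mask,
       group_vec = as.numeric(records$group == "plant"),
       class_targets = cls, cs_targets = cs,
       ids = records$id)
}
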