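## Model-introspection analyses: attention profiles, sequence-logo
## matrices, position-2 composition, arginine distances and secondary-
## structure preference profiles.
##
## Relative positions around a cleavage site use the -1/+1 convention:
## -1 is the last residue of the targeting peptide, +1 the first residue
## of the mature protein; there is no position 0.

#' Per-position maximum-attention profile
#'
#' For one prediction, the profile is the maximum over attention heads of
#' the attention weight at each position — the strength with which any
#' head looks at that residue.
#'
#' @param attention n_attn x L attention matrix (rows sum to 1).
#' @param per_head if TRUE return the full matrix instead of the
#'   per-position maximum.
#' @return numeric vector of length L (or the matrix when
#'   \code{per_head = TRUE}).
#' @export
attention_profile <- function(attention, per_head = FALSE) {
  stopifnot(is.matrix(attention))
  if (per_head) attention else apply(attention, 2, max)
}

## Map a 1-based sequence position to the relative offset around a CS.
.rel_offset <- function(pos, cs) ifelse(pos <= cs, pos - (cs + 1L), pos - cs)
## Inverse: sequence position for a relative offset (NA if outside 1..len).
.abs_pos <- function(offset, cs, len) {
  p <- ifelse(offset < 0, cs + 1L + offset, cs + offset)
  ifelse(p >= 1L & p <= len, p, NA_integer_)
}

#' Build a sequence-logo matrix
#'
#' Aggregates residues (mode \code{"frequency"}) or per-record weight
#' vectors split by residue identity (mode \code{"attention_mass"}) across
#' records, aligned either at the N terminus (offset 1 = first residue) or
#' at the cleavage site (offsets -1/+1 around the cleavage bond, no 0).
#'
#' In frequency mode each offset column sums to 1 over the records that
#' cover it; in attention-mass mode the entry for residue r at offset o is
#' the mean over covering records of the weight carried by positions
#' holding r, so the column total equals the mean weight profile at o.
#'
#' @param records record data.frame.
#' @param offsets integer vector of offsets to tabulate (positive, and for
#'   the cleavage-site anchor also negative; no 0 for that anchor).
#' @param anchor \code{"n_terminus"} or \code{"cleavage_site"}.
#' @param mode \code{"frequency"} or \code{"attention_mass"}.
#' @param weights list of per-record numeric vectors (length = sequence
#'   length), required for attention-mass mode.
#' @param cs optional vector of cleavage sites overriding
#'   \code{records$cs} (e.g. predicted ones).
#' @return list of class \code{tp_logo}: \code{values} (offsets x 20
#'   matrix), \code{support} (records covering each offset), plus the
#'   anchor/mode metadata.  Offsets covered by no record are NA and listed
#'   in \code{empty}.
#' @export
build_logo <- function(records, offsets, anchor = c("n_terminus", "cleavage_site"),
                       mode = c("frequency", "attention_mass"),
                       weights = NULL, cs = NULL) {
  anchor <- match.arg(anchor)
  mode <- match.arg(mode)
  if (anchor == "cleavage_site") {
    if (is.null(cs)) cs <- records$cs
    if (anyNA(cs)) stop("cleavage-site anchor requires a CS for every record")
    if (any(offsets == 0)) stop("no offset 0 in the -1/+1 convention")
  }
  if (mode == "attention_mass" && is.null(weights))
    stop("attention_mass mode needs per-record weight vectors")
  n <- nrow(records)
  lens <- nchar(records$sequence)
  vals <- matrix(0, length(offsets), 20,
                 dimnames = list(offsets, tp_residues))
  support <- integer(length(offsets))
  for (i in seq_len(n)) {
    chars <- strsplit(records$sequence[i], "")[[1]]
    pos <- if (anchor == "n_terminus") ifelse(offsets >= 1 & offsets <= lens[i], offsets, NA)
           else .abs_pos(offsets, cs[i], lens[i])
    for (j in seq_along(offsets)) {
      p <- pos[j]
      if (is.na(p)) next
      r <- match(chars[p], tp_residues)
      if (is.na(r)) next   # X carries no letter mass
      support[j] <- support[j] + 1L
      vals[j, r] <- vals[j, r] +
        if (mode == "frequency") 1 else weights[[i]][p]
    }
  }
  vals <- vals / ifelse(support > 0, support, NA)
  structure(list(values = vals, support = support, offsets = offsets,
                 anchor = anchor, mode = mode,
                 empty = offsets[support == 0]),
            class = "tp_logo")
}

#' Position-2 composition table
#'
#' Frequencies of the small residues A, C, G, P, S at sequence position 2
#' (directly after the initiator methionine) per class and organism group,
#' together with their sum — the fraction of chains whose methionine can
#' be excised by a methionine aminopeptidase.
#'
#' @param records labelled record data.frame (sequences of length >= 2).
#' @return data.frame with one row per (label, group) combination present.
#' @export
position2_table <- function(records) {
  stopifnot(all(nchar(records$sequence) >= 2))
  res2 <- substr(records$sequence, 2, 2)
  grp <- interaction(records$label, records$group, drop = TRUE, sep = ":")
  rows <- lapply(levels(grp), function(g) {
    sel <- grp == g
    freqs <- vapply(.small_residues, function(r) mean(res2[sel] == r), 0)
    parts <- strsplit(g, ":")[[1]]
    data.frame(label = parts[1], group = parts[2], n = sum(sel),
               t(freqs), cleavable = sum(freqs), stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Distance from the cleavage site to the nearest upstream arginine
#'
#' Scans the targeting peptide (positions 1..cs) for the arginine closest
#' to the cleavage site and returns its relative position (-1 = last
#' peptide residue), or NA when the peptide contains no arginine.
#'
#' @param sequence amino-acid string.
#' @param cs 1-based cleavage site (last peptide residue).
#' @return negative integer offset, or NA.
#' @export
nearest_upstream_arginine <- function(sequence, cs) {
  stopifnot(!is.na(cs), cs >= 1, cs <= nchar(sequence))
  chars <- strsplit(substr(sequence, 1, cs), "")[[1]]
  hits <- which(chars == "R")
  if (!length(hits)) return(NA_integer_)
  max(hits) - (cs + 1L)
}

#' Secondary-structure preference profile
#'
#' For each offset and structure class, log2 of the mean (over records)
#' conformational propensity of the residue found there, using a bundled
#' helix/sheet/turn propensity scale (Chou-Fasman); an alternative scale
#' can be supplied as a data.frame with a \code{residue} column and one
#' column per structure class.
#'
#' @param records record data.frame.
#' @param offsets,anchor,cs as in \code{\link{build_logo}}.
#' @param scale propensity table; default
#'   \code{\link{structure_propensities}()}.
#' @return matrix offsets x structure classes of log2 mean propensities;
#'   offsets with no data are NA.
#' @export
structure_preference_profile <- function(records, offsets,
                                         anchor = c("n_terminus", "cleavage_site"),
                                         cs = NULL,
                                         scale = structure_propensities()) {
  anchor <- match.arg(anchor)
  if (anchor == "cleavage_site" && is.null(cs)) cs <- records$cs
  classes <- setdiff(names(scale), "residue")
  lens <- nchar(records$sequence)
  acc <- matrix(0, length(offsets), length(classes),
                dimnames = list(offsets, classes))
  supp <- integer(length(offsets))
  for (i in seq_len(nrow(records))) {
    chars <- strsplit(records$sequence[i], "")[[1]]
    pos <- if (anchor == "n_terminus") ifelse(offsets >= 1 & offsets <= lens[i], offsets, NA)
           else .abs_pos(offsets, cs[i], lens[i])
    for (j in seq_along(offsets)) {
      p <- pos[j]
      if (is.na(p)) next
      k <- match(chars[p], scale$residue)
      if (is.na(k)) next
      supp[j] <- supp[j] + 1L
      acc[j, ] <- acc[j, ] + as.numeric(scale[k, classes])
    }
  }
  log2(acc / ifelse(supp > 0, supp, NA))
}

#' Bundled Chou-Fasman secondary-structure propensity scale
#'
#' Helix, sheet and turn conformational propensities per residue, read
#' from the package's editable TSV (inst/extdata/chou_fasman.tsv) so the
#' scale can be swapped for another published one.
#'
#' @return data.frame with columns residue, helix, sheet, turn.
#' @export
structure_propensities <- function() {
  path <- system.file("extdata", "chou_fasman.tsv", package = "targpep",
                      mustWork = TRUE)
  utils::read.delim(path, header = TRUE, sep = "\t",
                    colClasses = c("character", rep("numeric", 3)))
}
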