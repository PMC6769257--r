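## Synthetic proteins with planted targeting-peptide grammars.
##
## The generator emulates the qualitative sequence structure of the four
## targeting-peptide classes so that training, evaluation and the
## interpretability analyses are testable without any database download:
##   SP   - n-region (K/R-enriched, 1-5 aa), h-region (hydrophobic, 7-15 aa),
##          c-region (3-7 aa) ending in an A-X-A style motif with small
##          residues at -1 and -3;
##   mTP  - R/L/S-enriched, acid-depleted peptide of 15-60 aa with a single
##          arginine planted at -2, -3 or -10 relative to the cleavage site
##          (the MPP / Icp55 / MIP processing signatures) and no other
##          arginine within the last ten peptide positions;
##   cTP  - alanine at position 2 with probability p_A2 (default 0.65,
##          i.e. about two thirds), S/T-enriched acid-free core, 30-80 aa;
##   luTP - bipartite: a cTP-like stretch followed by an SP-like stretch,
##          with only the second (thylakoidal processing peptidase)
##          cleavage annotated;
##   noTP - background composition throughout.
## Mature regions are background-composition tails.  Background residue
## frequencies are uniform over the 20 standard residues by default, which
## keeps the chance floor of the classification problem analytic.

.small_residues <- c("A", "C", "G", "P", "S")
.hydrophobic <- c("L", "A", "V", "I", "F")

#' Specification of a synthetic targeting-peptide dataset
#'
#' @param n named integer vector of per-class record counts, names from
#'   \code{\link{tp_classes}}.
#' @param seed integer seed; generation is reproducible byte-for-byte.
#' @param mature_len integer range (length 2) of the mature region appended
#'   after the targeting peptide, and of the whole chain for noTP records.
#' @param p_A2 probability of alanine at position 2 in cTP and luTP records.
#' @param mtp_arg_offsets planted arginine offsets for mTPs, relative to the
#'   cleavage site (-1 = last peptide residue).
#' @param mtp_arg_weights mixture weights of the offsets.
#' @param background residue sampling weights (length 20, order
#'   \code{\link{tp_residues}}); uniform by default.
#' @return list of class \code{tp_synth_spec}.
#' @export
synth_spec <- function(n = c(noTP = 250, SP = 100, mTP = 75, cTP = 50, luTP = 25),
                       seed = 1L,
                       mature_len = c(60L, 150L),
                       p_A2 = 0.65,
                       mtp_arg_offsets = c(-2L, -3L, -10L),
                       mtp_arg_weights = c(1, 1, 1) / 3,
                       background = rep(1 / 20, 20)) {
  stopifnot(all(names(n) %in% tp_classes), all(n >= 0),
            length(mature_len) == 2, mature_len[1] <= mature_len[2],
            p_A2 >= 0, p_A2 <= 1,
            length(mtp_arg_offsets) == length(mtp_arg_weights),
            all(mtp_arg_offsets <= -1), all(mtp_arg_offsets >= -10),
            length(background) == 20, all(background >= 0))
  structure(list(n = n, seed = as.integer(seed), mature_len = as.integer(mature_len),
                 p_A2 = p_A2, mtp_arg_offsets = as.integer(mtp_arg_offsets),
                 mtp_arg_weights = mtp_arg_weights / sum(mtp_arg_weights),
                 background = background / sum(background)),
            class = "tp_synth_spec")
}

.sample_res <- function(n, weights) {
  if (n <= 0) return(character(0))
  sample(tp_residues, n, replace = TRUE, prob = weights)
}

## Class-conditional composition weights (over tp_residues order).
.weights_enriched <- function(up = character(0), w_up = 0, drop = character(0)) {
  w <- rep(1, 20)
  names(w) <- tp_residues
  w[drop] <- 0.02
  w <- w / sum(w)
  if (length(up)) {
    w <- w * (1 - w_up * length(up))
    w[up] <- w[up] + w_up
  }
  w / sum(w)
}

.mtp_weights <- .weights_enriched(up = c("R", "L", "S"), w_up = 0.12,
                                  drop = c("D", "E"))
.ctp_weights <- local({
  w <- .weights_enriched(up = c("S", "T"), w_up = 0.14, drop = character(0))
  w[c("D", "E")] <- 0            # acid-free core
  w / sum(w)
})
.nreg_weights <- .weights_enriched(up = c("K", "R"), w_up = 0.25)

## Small-residue motif position: mostly alanine.
.sample_small <- function(n) sample(.small_residues, n, replace = TRUE,
                                    prob = c(0.7, 0.05, 0.1, 0.05, 0.1))

## One SP-like stretch, excluding the initial methionine; returns the
## residue vector, whose last element is the -1 position of the cleavage.
.sp_stretch <- function() {
  nreg <- .sample_res(sample(1:5, 1), .nreg_weights)
  hreg <- sample(.hydrophobic, sample(7:15, 1), replace = TRUE)
  clen <- sample(3:7, 1)
  creg <- .sample_res(clen, .weights_enriched(up = c("S", "T", "A", "G"), w_up = 0.1))
  creg[clen] <- .sample_small(1)      # -1
  creg[clen - 2L] <- .sample_small(1) # -3
  c(nreg, hreg, creg)
}

## cTP-like stretch of total length len (including position-2 slot).
.ctp_stretch <- function(len, p_A2) {
  core <- .sample_res(len, .ctp_weights)
  w_noA <- .ctp_weights; w_noA["A"] <- 0
  core[1] <- if (stats::runif(1) < p_A2) "A" else
    .sample_res(1, w_noA / sum(w_noA))
  core
}

.mtp_peptide <- function(spec) {
  len <- sample(15:60, 1)            # includes the initial M
  body <- .sample_res(len - 1L, .mtp_weights)
  ## R-free tail window so the planted arginine is the nearest upstream one
  tail_n <- min(10L, len - 1L)
  w_noR <- .mtp_weights; w_noR["R"] <- 0; w_noR <- w_noR / sum(w_noR)
  body[(len - 1L - tail_n + 1L):(len - 1L)] <- .sample_res(tail_n, w_noR)
  off <- sample(spec$mtp_arg_offsets, 1, prob = spec$mtp_arg_weights)
  body[len - 1L + off + 1L] <- "R"   # offset -1 is the last peptide residue
  body
}

.generate_one <- function(cls, spec) {
  mature <- .sample_res(sample(spec$mature_len[1]:spec$mature_len[2], 1),
                        spec$background)
  if (cls == "noTP") {
    seqv <- c("M", mature)
    return(list(sequence = paste(seqv, collapse = ""), cs = NA_integer_))
  }
  pep <- switch(cls,
    SP = .sp_stretch(),
    mTP = .mtp_peptide(spec),
    cTP = .ctp_stretch(sample(30:80, 1) - 1L, spec$p_A2),
    luTP = c(.ctp_stretch(sample(15:40, 1) - 1L, spec$p_A2), .sp_stretch()))
  seqv <- c("M", pep, mature)
  list(sequence = paste(seqv, collapse = ""), cs = length(pep) + 1L)
}

#' Generate a labelled synthetic dataset
#'
#' Reproducible under the spec seed; every record starts with methionine;
#' cTP and luTP records are assigned to the plant group, the other classes
#' are split evenly between plant and nonplant.
#'
#' @param spec a \code{\link{synth_spec}}.
#' @return \code{\link{tp_records}} data.frame with labels and cleavage sites.
#' @export
synth_generate <- function(spec = synth_spec()) {
  stopifnot(inherits(spec, "tp_synth_spec"))
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(spec$seed)
  rows <- list()
  k <- 0L
  for (cls in tp_classes) {
    ncls <- spec$n[cls]
    if (is.na(ncls) || ncls == 0) next
    for (j in seq_len(ncls)) {
      k <- k + 1L
      g <- .generate_one(cls, spec)
      grp <- if (cls %in% c("cTP", "luTP")) "plant" else
        sample(c("plant", "nonplant"), 1)
      rows[[k]] <- data.frame(id = sprintf("%s_%04d", cls, j),
                              sequence = g$sequence, group = grp,
                              label = cls, cs = g$cs,
                              stringsAsFactors = FALSE)
    }
  }
  df <- do.call(rbind, rows)
  ## interleave classes deterministically so folds/batches are mixed
  df <- df[sample(nrow(df)), , drop = FALSE]
  rownames(df) <- NULL
  validate_records(df)
  class(df) <- c("tp_records", "data.frame")
  df
}

#' Generate a family of homologous records by point substitution
#'
#' Each copy replaces every position independently with probability
#' \code{rate} by a residue drawn from the background (which may coincide
#' with the original, as in a uniform substitution model).  Labels and
#' cleavage sites are preserved.
#'
#' @param ancestor single-row record data.frame.
#' @param n_copies number of mutated copies.
#' @param rate per-site substitution probability, in (0, 0.5).
#' @param seed integer seed.
#' @return records: the ancestor followed by its copies.
#' @export
synth_family <- function(ancestor, n_copies, rate = 0.1, seed = 1L) {
  stopifnot(nrow(ancestor) == 1, rate > 0, rate < 0.5)
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(seed)
  chars <- strsplit(ancestor$sequence, "")[[1]]
  out <- ancestor
  for (j in seq_len(n_copies)) {
    mut <- chars
    hit <- stats::runif(length(chars)) < rate
    mut[hit] <- sample(tp_residues, sum(hit), replace = TRUE)
    row <- ancestor
    row$id <- paste0(ancestor$id, "_fam", j)
    row$sequence <- paste(mut, collapse = "")
    out <- rbind(out, row)
  }
  rownames(out) <- NULL
  out
}

.save_rng <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.restore_rng <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}
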