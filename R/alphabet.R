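## Residue alphabet, class labels and the embedded BLOSUM62 matrix.

#' Amino-acid alphabet used throughout the package
#'
#' The 20 standard residues in the fixed column order used for all numeric
#' encodings (BLOSUM62 rows, one-hot blocks, logo matrices), plus the
#' placeholder \code{X} for any non-standard residue.
#'
#' @format Character vector of length 20 (\code{tp_residues}).
#' @export
tp_residues <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
                 "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

#' Peptide class labels
#'
#' Fixed class order used for probability vectors, confusion matrices and
#' count correction: \code{noTP} (no targeting peptide), \code{SP} (signal
#' peptide), \code{mTP} (mitochondrial transit peptide), \code{cTP}
#' (chloroplast transit peptide), \code{luTP} (thylakoid luminal transit
#' peptide, annotated at its second, thylakoidal-processing-peptidase
#' cleavage).
#'
#' @export
tp_classes <- c("noTP", "SP", "mTP", "cTP", "luTP")

## Classes that carry a cleavage site, in the order of the four dedicated
## attention heads.
tp_cs_classes <- c("SP", "mTP", "cTP", "luTP")

#' BLOSUM62 substitution matrix
#'
#' The standard BLOSUM62 matrix restricted to the 20 standard residues,
#' rows and columns ordered as \code{\link{tp_residues}}.  Row \code{r} is
#' the numeric encoding of residue \code{r}; \code{X} encodes as the zero
#' vector.
#'
#' @return 20 x 20 integer matrix with residue dimnames.
#' @export
tp_blosum62 <- function() .blosum62

.blosum62 <- local({
  v <- c(
    4,-1,-2,-2,0,-1,-1,0,-2,-1,-1,-1,-1,-2,-1,1,0,-3,-2,0,
    -1,5,0,-2,-3,1,0,-2,0,-3,-2,2,-1,-3,-2,-1,-1,-3,-2,-3,
    -2,0,6,1,-3,0,0,0,1,-3,-3,0,-2,-3,-2,1,0,-4,-2,-3,
    -2,-2,1,6,-3,0,2,-1,-1,-3,-4,-1,-3,-3,-1,0,-1,-4,-3,-3,
    0,-3,-3,-3,9,-3,-4,-3,-3,-1,-1,-3,-1,-2,-3,-1,-1,-2,-2,-1,
    -1,1,0,0,-3,5,2,-2,0,-3,-2,1,0,-3,-1,0,-1,-2,-1,-2,
    -1,0,0,2,-4,2,5,-2,0,-3,-3,1,-2,-3,-1,0,-1,-3,-2,-2,
    0,-2,0,-1,-3,-2,-2,6,-2,-4,-4,-2,-3,-3,-2,0,-2,-2,-3,-3,
    -2,0,1,-1,-3,0,0,-2,8,-3,-3,-1,-2,-1,-2,-1,-2,-2,2,-3,
    -1,-3,-3,-3,-1,-3,-3,-4,-3,4,2,-3,1,0,-3,-2,-1,-3,-1,3,
    -1,-2,-3,-4,-1,-2,-3,-4,-3,2,4,-2,2,0,-3,-2,-1,-2,-1,1,
    -1,2,0,-1,-3,1,1,-2,-1,-3,-2,5,-1,-3,-1,0,-1,-3,-2,-2,
    -1,-1,-2,-3,-1,0,-2,-3,-2,1,2,-1,5,0,-2,-1,-1,-1,-1,1,
    -2,-3,-3,-3,-2,-3,-3,-3,-1,0,0,-3,0,6,-4,-2,-2,1,3,-1,
    -1,-2,-2,-1,-3,-1,-1,-2,-2,-3,-3,-1,-2,-4,7,-1,-1,-4,-3,-2,
    1,-1,1,0,-1,0,0,0,-1,-2,-2,0,-1,-2,-1,4,1,-3,-2,-2,
    0,-1,0,-1,-1,-1,-1,-2,-2,-1,-1,-1,-1,-2,-1,1,5,-2,-2,0,
    -3,-3,-4,-4,-2,-2,-3,-2,-2,-3,-2,-3,-1,1,-4,-3,-2,11,2,-3,
    -2,-2,-2,-3,-2,-1,-2,-3,2,-1,-1,-2,-1,3,-3,-2,-2,2,7,-1,
    0,-3,-3,-3,-1,-2,-2,-3,-3,3,1,-2,1,-1,-2,-2,0,-3,-1,4)
  m <- matrix(as.integer(v), nrow = 20, byrow = TRUE,
              dimnames = list(tp_residues, tp_residues))
  m
})

## Ambiguity codes collapsed to X before encoding (selenocysteine and
## pyrrolysine included: their substitution scores are undefined in the
## 20-column matrix, so they encode as zeros).
.ambiguous_residues <- c("B", "Z", "J", "U", "O", "X", "*")

## Normalise a character vector of sequences: upper-case and collapse
## non-standard letters to X.  Anything outside [A-Z*] is left alone so the
## validator can report it.
.normalise_sequence <- function(x) {
  x <- toupper(x)
  for (a in .ambiguous_residues) x <- gsub(a, "X", x, fixed = TRUE)
  x
}

.class_index <- function(label) match(label, tp_classes)
.cs_head_index <- function(label) match(label, tp_cs_classes)
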