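# Shared low-level helpers: IUPAC tables, Phred codecs, Hamming distance.

IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

IUPAC_COMPLEMENT <- c(
  A = "T", C = "G", G = "C", T = "A",
  R = "Y", Y = "R", S = "S", W = "W", K = "M", M = "K",
  B = "V", V = "B", D = "H", H = "D", N = "N"
)

#' Reverse complement of a nucleotide sequence
#'
#' Handles the full IUPAC alphabet (degenerate codes are complemented to
#' their degenerate counterparts, e.g. R to Y, W to W).
#'
#' @param seq Character vector of sequences over the IUPAC alphabet.
#' @return Character vector of reverse complements.
#' @export
#' @examples
#' revcomp("ACGT")      # "ACGT"
#' revcomp("GGWACW")    # "WGTWCC"
revcomp <- function(seq) {
  stopifnot(is.character(seq))
  vapply(seq, function(s) {
    ch <- rev(strsplit(s, "", fixed = TRUE)[[1]])
    comp <- IUPAC_COMPLEMENT[ch]
    if (anyNA(comp)) {
      stop("invalid nucleotide code in sequence: ",
           paste(unique(ch[is.na(comp)]), collapse = ", "))
    }
    paste(comp, collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

# Phred+33 string <-> integer vector
phred_decode <- function(qual_string) {
  lapply(qual_string, function(q) as.integer(charToRaw(q)) - 33L)
}

phred_encode <- function(qual_int) {
  vapply(qual_int, function(q) rawToChar(as.raw(q + 33L)), character(1))
}

# mean Phred of a +33-encoded quality string (vectorised over reads)
phred_means <- function(qual_string) {
  vapply(phred_decode(qual_string), mean, numeric(1))
}

#' Hamming distance between equal-length sequences
#'
#' Number of positions at which two sequences differ (substitutions only).
#'
#' @param a,b Character scalars of equal length.
#' @return Integer distance.
#' @export
hamming <- function(a, b) {
  if (nchar(a) != nchar(b)) stop("hamming distance requires equal-length sequences")
  sum(utf8ToInt(a) != utf8ToInt(b))
}

# split sequences into an n x L character matrix (all equal length L)
seq_char_matrix <- function(seqs) {
  if (length(seqs) == 0L) return(matrix(character(0), nrow = 0, ncol = 0))
  L <- unique(nchar(seqs))
  if (length(L) != 1L) stop("sequences have mixed lengths")
  matrix(unlist(strsplit(seqs, "", fixed = TRUE), use.names = FALSE),
         nrow = length(seqs), ncol = L, byrow = TRUE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
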