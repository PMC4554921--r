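#' In silico tryptic digest
#'
#' Fully cleaves an amino acid sequence after every K or R that is not
#' followed by P (the trypsin convention, no missed cleavages) and returns
#' the peptides whose length falls within \code{[minLen, maxLen]}, in
#' sequence order. With \code{minLen = 1} and \code{maxLen = Inf} the
#' returned peptides concatenate back to the input sequence.
#'
#' @param sequence single uppercase amino acid string (letters only; the
#'   extended one-letter alphabet is accepted).
#' @param minLen,maxLen inclusive peptide length bounds retained
#'   (defaults 6 and 30).
#' @return character vector of peptides.
#' @examples
#' digestSequence("MKTAYIAKQRQISFVK", minLen = 1, maxLen = Inf)
#' @export
digestSequence <- function(sequence, minLen = 6L, maxLen = 30L) {
  if (!is.character(sequence) || length(sequence) != 1L || is.na(sequence) ||
      nchar(sequence) == 0L)
    stop("'sequence' must be a single non-empty string", call. = FALSE)
  if (grepl("[^A-Z]", sequence))
    stop("invalid residue(s) in sequence: ",
         paste(unique(strsplit(gsub("[A-Z]", "", sequence), "")[[1]]),
               collapse = ", "), call. = FALSE)
  .assertScalarNumber(minLen, "minLen", lower = 1)
  if (maxLen < minLen) stop("'maxLen' must be >= 'minLen'", call. = FALSE)
  res <- strsplit(sequence, "")[[1]]
  n <- length(res)
  # cleavage after position i when res[i] in {K,R} and res[i+1] != P
  cut <- which(res %in% c("K", "R"))
  cut <- cut[cut < n & res[pmin(cut + 1L, n)] != "P"]
  starts <- c(1L, cut + 1L)
  ends <- c(cut, n)
  peps <- substring(sequence, starts, ends)
  len <- ends - starts + 1L
  peps[len >= minLen & len <= maxLen]
}
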