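#' Convert ASCII text to a bit string
#'
#' Each character becomes its 8-bit ASCII code, most-significant bit first,
#' and the codes are concatenated. This is the first step of the degenerate
#' DNA encoding: the resulting bits are mapped to bases by [bits_to_bases()].
#'
#' @param text A character scalar containing only 7-bit ASCII characters.
#' @return A character scalar over `{0,1}` of length `8 * nchar(text)`.
#' @examples
#' text_to_bits("cty")
#' @seealso [bits_to_text()], [bits_to_bases()]
#' @export
text_to_bits <- function(text) {
  stopifnot(is.character(text), length(text) == 1L, !is.na(text))
  if (nchar(text) == 0L) return("")
  codes <- utf8ToInt(text)
  bad <- which(codes > 127L)
  if (length(bad) > 0L) {
    stop("non-ASCII character at position ", bad[1L],
         " (code point ", codes[bad[1L]], ")", call. = FALSE)
  }
  # 8 bits per character, MSB first
  bits <- vapply(codes, function(x) {
    paste(bitwAnd(bitwShiftR(x, 7:0), 1L), collapse = "")
  }, character(1L))
  paste(bits, collapse = "")
}

#' Convert a bit string back to ASCII text
#'
#' Inverse of [text_to_bits()]: consumes 8 bits per character, MSB first.
#'
#' @param bits A character scalar over `{0,1}` whose length is a multiple of 8.
#' @return A character scalar.
#' @export
bits_to_text <- function(bits) {
  v <- bit_ints(bits)
  if (length(v) == 0L) return("")
  if (length(v) %% 8L != 0L) {
    stop("bit string length ", length(v), " is not a multiple of 8", call. = FALSE)
  }
  m <- matrix(v, nrow = 8L)
  intToUtf8(as.integer(colSums(m * 2L^(7:0))))
}

# bit string -> integer vector of 0/1 (fast path via code points)
bit_ints <- function(bits) {
  stopifnot(is.character(bits), length(bits) == 1L, !is.na(bits))
  if (nchar(bits) == 0L) return(integer(0L))
  v <- utf8ToInt(bits) - 48L
  if (any(v < 0L | v > 1L)) {
    stop("bit string contains characters other than 0/1", call. = FALSE)
  }
  v
}

ints_bit <- function(v) {
  if (length(v) == 0L) return("")
  intToUtf8(v + 48L)
}

#' Encode bits as degenerate DNA bases
#'
#' Maps bit 0 to a purine (`a` or `g`) and bit 1 to a pyrimidine (`T` or `C`),
#' the choice within each pair being uniform random. Many sequences therefore
#' encode the same bits; equality of encoded payloads is decided at the bit
#' level (see [degenerate_equal()]). Purines are emitted lowercase and
#' pyrimidines uppercase; the case is presentational only.
#'
#' @param bits A character scalar over `{0,1}`.
#' @param seed Optional integer. When supplied, the base choices are drawn
#'   from a local RNG seeded with it, leaving the caller's RNG untouched;
#'   the same seed always reproduces the same sequence.
#' @return A DNA string of the same length as `bits`.
#' @examples
#' bits_to_bases(text_to_bits("cty"), seed = 1)
#' @export
bits_to_bases <- function(bits, seed = NULL) {
  v <- bit_ints(bits)
  if (length(v) == 0L) return("")
  draw <- function() stats::runif(length(v)) < 0.5
  u <- if (is.null(seed)) draw() else withr::with_seed(seed, draw())
  # index into a/g (bit 0) or T/C (bit 1)
  alphabet <- c("a", "g", "T", "C")
  intToUtf8(utf8ToInt(paste(alphabet, collapse = ""))[v * 2L + u + 1L])
}

# DNA string -> integer codes, validated; returns uppercase code points
dna_ints <- function(seq, what = "sequence") {
  stopifnot(is.character(seq), length(seq) == 1L, !is.na(seq))
  if (nchar(seq) == 0L) return(integer(0L))
  v <- utf8ToInt(toupper(seq))
  ok <- v %in% utf8ToInt("ACGT")
  if (!all(ok)) {
    stop(what, " contains a character outside {A,C,G,T} at position ",
         which(!ok)[1L], call. = FALSE)
  }
  v
}

#' Decode degenerate DNA bases to bits
#'
#' Position-wise inverse of [bits_to_bases()]: purines (`A`/`G`, any case)
#' decode to 0, pyrimidines (`T`/`C`) to 1.
#'
#' @param seq A DNA string over `{A,C,G,T}` (case-insensitive).
#' @return A character scalar over `{0,1}` of the same length.
#' @examples
#' bases_to_bits("aCCggaTTgTCCgCaggCCTTggC")
#' @export
bases_to_bits <- function(seq) {
  v <- dna_ints(seq)
  if (length(v) == 0L) return("")
  ints_bit(as.integer(v %in% utf8ToInt("TC")))
}

#' Position-wise Watson-Crick complement
#'
#' Complements each base in place (A<->T, C<->G) *without* reversing the
#' strand; this is the operation used to derive edge oligos from vertex
#' halves in the splinted-ligation model. Note the written 5'->3' antiparallel
#' complement would additionally be reversed; [reverse_complement()] provides
#' that standard operation but the pipeline does not use it. The output case
#' is regenerated as purine-lowercase / pyrimidine-uppercase.
#'
#' @param seq A DNA string (case-insensitive).
#' @return The complemented DNA string, same length and order.
#' @examples
#' dna_complement("aaTT")
#' @export
dna_complement <- function(seq) {
  dna_ints(seq)  # validate
  display_case(chartr("ACGTacgt", "TGCATGCA", seq))
}

#' Reverse complement (standard 5'->3' antiparallel read)
#'
#' @inheritParams dna_complement
#' @return The reverse-complemented DNA string.
#' @export
reverse_complement <- function(seq) {
  comp <- dna_complement(seq)
  if (nchar(comp) <= 1L) return(comp)
  intToUtf8(rev(utf8ToInt(comp)))
}

# regenerate presentational case: purines lowercase, pyrimidines uppercase
display_case <- function(seq) {
  chartr("ACGTacgt", "aCgTaCgT", seq)
}

#' Test degenerate equality of two DNA sequences
#'
#' Two sequences are degenerate-equal when they have the same length and
#' decode to the same bit string, i.e. they are interchangeable encodings of
#' the same payload under the two-bases-per-bit code.
#'
#' @param s1,s2 DNA strings (case-insensitive).
#' @return `TRUE` or `FALSE`.
#' @examples
#' degenerate_equal("aaaa", "gggg")
#' @export
degenerate_equal <- function(s1, s2) {
  nchar(s1) == nchar(s2) && identical(bases_to_bits(s1), bases_to_bits(s2))
}
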