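# The seven published vertex oligos of the two-source worked example
# (one degenerate realisation each; type/unit 4-mers are byte-exact).
published_oligos <- c(
  "start"      = "ggTaagagaTTCgaCCaCTCaCgagCCaaggTgTCTaaCagTCTgCag",
  "(cty,GZ)"   = "aCCggaTTgTCCgCaggCCTTggCTCGATGCAaTagaCCTaCgTTaCa",
  "(qa,E)"     = "gaTaagaaaTTCaagTgTTggagTTCGATGCAaaCggagagTgagTaT",
  "(qa,null)"  = "gaTaagaaaTTCaagTgTTggagTTGCATGCAaaCggagagaCagaag",
  "(cc,0)"     = "aaCgaagagCTaagCCgCCgaaTCCATGGCATgaCTgagaggTTggag",
  "(cc,null)"  = "aaCgaagagCTaagCCgCCgaaTCTGCATGCAgaCagagaggTaggag",
  "end"        = "ggTaaggaggTaggagagTaaggagCCggTgCgCCaCCTggTTggTaa"
)

published_edge_cty_qa <- "AGCTACGTTaTCTggaTgCaaTgTCTaTTCTTTaagTTCaCaaCCTCa"

published_cty_bits <- "011000110111010001111001"

published_flat_bits <- paste0(
  "00100000011100110111010001100001011100100111010001100011011101000111",
  "10010100011101011010001000000111000101100001001000000100010100100000",
  "01100011011000110011000000110000001000000010000000100000011001010110",
  "111001100100"
)

published_flat_text <- " startctyGZ qa E cc00   end"

# independent bit oracle built on base R's raw bit machinery (not the
# package's utf8 code path)
oracle_text_bits <- function(text) {
  if (nchar(text) == 0L) return("")
  bits <- rawToBits(charToRaw(text))
  m <- matrix(as.integer(bits), nrow = 8L)[8:1, , drop = FALSE]
  paste(as.vector(m), collapse = "")
}

# independent base->bit oracle: purine 0, pyrimidine 1 via lookup table
oracle_seq_bits <- function(seq) {
  x <- strsplit(toupper(seq), "")[[1]]
  paste(c(A = 0, C = 1, G = 0, T = 1)[x], collapse = "")
}

random_bits <- function(n) paste(sample(c("0", "1"), n, replace = TRUE),
                                 collapse = "")
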