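#' Physical parameters for DNA storage-density calculations
#'
#' Defaults describe the archival encoding of this package read as duplex
#' DNA: 128 payload bits carried by a 200-bp molecule (400 nucleotides
#' counting both strands), a mean nucleotide molecular weight of 330 g/mol,
#' and DNA's mass density approximated by water's (1e-3 g/mm^3). Set
#' `nt_per_duplex = 200` for single-stranded accounting.
#'
#' @param mw_per_nt Mean molecular weight of a nucleotide, g/mol.
#' @param payload_bits_per_duplex Payload bits per molecule.
#' @param nt_per_duplex Nucleotides per molecule, counting both strands.
#' @param mass_density Mass density, g/mm^3.
#' @return A `density_params` list.
#' @export
density_params <- function(mw_per_nt = 330,
                           payload_bits_per_duplex = 128,
                           nt_per_duplex = 400,
                           mass_density = 1e-3) {
  p <- list(mw_per_nt = mw_per_nt,
            payload_bits_per_duplex = payload_bits_per_duplex,
            nt_per_duplex = nt_per_duplex,
            mass_density = mass_density)
  if (any(unlist(p) <= 0)) stop("all density parameters must be positive",
                                call. = FALSE)
  structure(p, class = "density_params")
}

AVOGADRO <- 6.02214076e23

#' Storable bits per gram of DNA
#'
#' `(N_A / mw_per_nt) * payload_bits_per_duplex / nt_per_duplex`: the number
#' of nucleotides in a gram, scaled by the payload carried per nucleotide.
#' Defaults give 5.84e20 bits per gram.
#'
#' @param p A [density_params()] object.
#' @return Bits per gram (numeric scalar).
#' @examples
#' signif(bits_per_gram(), 3)
#' @export
bits_per_gram <- function(p = density_params()) {
  stopifnot(inherits(p, "density_params"))
  (AVOGADRO / p$mw_per_nt) * p$payload_bits_per_duplex / p$nt_per_duplex
}

#' Volume of DNA required to store a payload
#'
#' @param n_bits Payload size in bits.
#' @param p A [density_params()] object.
#' @return Volume in mm^3.
#' @examples
#' signif(storage_volume(petabytes_to_bits(3)), 3)
#' @export
storage_volume <- function(n_bits, p = density_params()) {
  stopifnot(n_bits >= 0)
  n_bits / bits_per_gram(p) / p$mass_density
}

#' Convert petabytes to bits
#'
#' @param pb Number of petabytes.
#' @param binary If `TRUE` (default) a petabyte is 2^50 bytes; otherwise
#'   10^15 bytes.
#' @return Number of bits.
#' @export
petabytes_to_bits <- function(pb, binary = TRUE) {
  pb * (if (binary) 2^50 else 1e15) * 8
}
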