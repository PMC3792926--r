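#' Default amplification/sequencing handles of the archival oligos
#'
#' An archival oligo is 200 nt: a 20-nt 5' handle, a 32-nt address, 128 nt
#' of data (one base per bit) and a 20-nt 3' handle. The handles are fixed
#' run-level constants framing the payload; any pair of 20-mers may be
#' substituted via the `primer5`/`primer3` arguments of [encode_stream()].
#'
#' @return A list with elements `p5` and `p3`, each a 20-nt DNA string.
#' @export
archival_primers <- function() {
  list(p5 = "ACACGACGCTCTTCCGATCT", p3 = "AGATCGGAAGAGCGTCGTGT")
}

#' Encode a byte stream as an address-tagged oligo pool
#'
#' The input bits (most-significant bit first within each byte) are split
#' into 128-bit blocks, the last block zero-padded; block `i` is prefixed
#' with its 32-bit address (a big-endian counter starting at 0), the 160
#' bits are degenerately encoded one base per bit, and the result is framed
#' by the two 20-nt handles, giving one 200-nt oligo per block.
#'
#' Each block's random base choices are drawn from a seed derived
#' deterministically from `(seed, address)`, so the pool is identical — as a
#' multiset — no matter how the blocks are partitioned into chunks for
#' conversion. `chunk_size` controls that partitioning and exists to make
#' the contract testable; it never changes the output.
#'
#' @param data A raw vector, or a character scalar taken as ASCII text.
#' @param seed Integer master seed for the degenerate encoding.
#' @param chunk_size Blocks per conversion chunk.
#' @param primer5,primer3 The 5'/3' framing handles.
#' @return An `oligo_pool` tibble with columns `address` and `seq` (200-nt
#'   strings), plus attributes recording seed, handles and payload byte
#'   length.
#' @examples
#' pool <- encode_stream(charToRaw("hello"), seed = 1)
#' nchar(pool$seq)
#' @export
encode_stream <- function(data, seed = 1L, chunk_size = 4096L,
                          primer5 = archival_primers()$p5,
                          primer3 = archival_primers()$p3) {
  if (is.character(data)) data <- charToRaw(data)
  stopifnot(is.raw(data))
  dna_ints(primer5, "primer5"); dna_ints(primer3, "primer3")
  n_bits <- 8L * length(data)
  n_blocks <- ceiling(n_bits / 128)
  if (n_blocks > 2^32) stop("address space exhausted: more than 2^32 blocks",
                            call. = FALSE)
  if (n_blocks == 0L) {
    return(empty_pool(seed, primer5, primer3, 0L))
  }
  # MSB-first bit matrix, zero-padded to a whole number of blocks
  bits <- as.integer(rawToBits(data))
  bits <- as.vector(matrix(bits, nrow = 8L)[8:1, ])
  bits <- c(bits, integer(n_blocks * 128L - n_bits))
  blocks <- matrix(bits, nrow = 128L)

  addresses <- seq_len(n_blocks) - 1
  seqs <- character(n_blocks)
  for (chunk in unname(split(addresses, addresses %/% chunk_size))) {
    seqs[chunk + 1] <- vapply(chunk, function(a) {
      payload <- c(address_bits(a), blocks[, a + 1])
      bases <- bits_to_bases(ints_bit(payload), seed = block_seed(seed, a))
      paste0(primer5, bases, primer3)
    }, character(1L))
  }

  pool <- tibble::tibble(address = addresses, seq = seqs)
  structure(pool, class = c("oligo_pool", class(pool)),
            seed = seed, primer5 = primer5, primer3 = primer3,
            n_bytes = length(data))
}

empty_pool <- function(seed, primer5, primer3, n_bytes) {
  pool <- tibble::tibble(address = double(), seq = character())
  structure(pool, class = c("oligo_pool", class(pool)),
            seed = seed, primer5 = primer5, primer3 = primer3,
            n_bytes = n_bytes)
}

# 32-bit big-endian address as 0/1 integers
address_bits <- function(a) {
  v <- integer(32L)
  for (i in 32:1) {
    v[i] <- a %% 2
    a <- a %/% 2
  }
  as.integer(v)
}

bits_address <- function(v) sum(v * 2^(31:0))

# deterministic per-block seed below 2^31, exact in double arithmetic
block_seed <- function(seed, address) {
  m <- 2147483647
  x <- (as.double(seed) %% m + as.double(address) %% m) %% m
  x <- (x * 69069 + 12345) %% m
  as.integer((x * 69069 + 1) %% m)
}

#' Decode an oligo pool back to bytes
#'
#' Order-free inverse of [encode_stream()]: each oligo's handles are
#' verified and stripped, the 32-bit address and 128 data bits are decoded,
#' blocks are sorted by address, and the data are concatenated. Addresses
#' must form a contiguous range from 0; duplicated addresses are tolerated
#' when their data bits agree. Trailing zero-padding from the final block is
#' retained — the caller trims to the known payload length (recorded on the
#' pool as the `n_bytes` attribute when it came from [encode_stream()]).
#'
#' @param pool An `oligo_pool` tibble (rows may be in any order).
#' @param primer5,primer3 The framing handles to verify and strip.
#' @return A raw vector, a multiple of 16 bytes.
#' @export
decode_pool <- function(pool, primer5 = archival_primers()$p5,
                        primer3 = archival_primers()$p3) {
  stopifnot(is.data.frame(pool), all(c("address", "seq") %in% names(pool)))
  if (nrow(pool) == 0L) return(raw(0L))
  if (any(nchar(pool$seq) != 200L)) {
    stop("archival oligos are 200 nt", call. = FALSE)
  }
  up <- toupper(pool$seq)
  if (!all(startsWith(up, toupper(primer5)) & endsWith(up, toupper(primer3)))) {
    stop("framing handles not found on every oligo", call. = FALSE)
  }
  body <- substr(pool$seq, 21L, 180L)
  bits <- lapply(body, function(s) bit_ints(bases_to_bits(s)))
  addr <- vapply(bits, function(b) bits_address(b[1:32]), double(1L))

  ord <- order(addr)
  addr <- addr[ord]
  data_bits <- lapply(bits[ord], function(b) b[33:160])
  # consistent duplicates collapse; conflicting ones are an error
  first <- !duplicated(addr)
  for (i in which(!first)) {
    j <- match(addr[i], addr)
    if (!identical(data_bits[[i]], data_bits[[j]])) {
      stop("conflicting duplicate oligos at address ", addr[i], call. = FALSE)
    }
  }
  addr_u <- addr[first]
  if (!identical(addr_u, as.double(seq_along(addr_u) - 1))) {
    missing <- setdiff(seq_len(max(addr_u) + 1) - 1, addr_u)
    stop("address gap: block(s) ", paste(utils::head(missing, 5L),
                                         collapse = ", "), " missing",
         call. = FALSE)
  }
  all_bits <- unlist(data_bits[first], use.names = FALSE)
  m <- matrix(all_bits, nrow = 8L)[8:1, , drop = FALSE]  # back to rawBits order
  packBits(as.raw(as.vector(m)), type = "raw")
}

#' Write / read an oligo pool as FASTA
#'
#' One record per oligo with the block address in the header.
#'
#' @param pool An `oligo_pool`.
#' @param path File path.
#' @return `read_pool_fasta()` returns an `oligo_pool` tibble;
#'   `write_pool_fasta()` returns `path` invisibly.
#' @export
write_pool_fasta <- function(pool, path) {
  seqinr::write.fasta(as.list(pool$seq),
                      sprintf("block_%d address=%d",
                              seq_len(nrow(pool)) - 1L, pool$address),
                      path, as.string = TRUE)
  invisible(path)
}

#' @rdname write_pool_fasta
#' @export
read_pool_fasta <- function(path) {
  fa <- seqinr::read.fasta(path, as.string = TRUE, forceDNAtolower = FALSE,
                           whole.header = TRUE)
  addr <- as.double(sub(".*address=(\\d+).*", "\\1", names(fa)))
  tibble::tibble(address = addr, seq = unname(vapply(fa, as.character,
                                                     character(1L))))
}
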