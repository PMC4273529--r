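# CRC-32 (IEEE 802.3 polynomial, reflected form) over UTF-8 bytes.
# This is the bin-assignment hash for hologram construction: deterministic
# across platforms and R sessions, unlike any randomised hashing scheme.

.crc32_table <- local({
  tab <- integer(256L)
  for (i in 0:255) {
    crc <- i
    for (j in 1:8) {
      crc <- if (bitwAnd(crc, 1L) != 0L) {
        # 0xEDB88320 as a signed 32-bit integer
        bitwXor(bitwShiftR(crc, 1L), -306674912L)
      } else {
        bitwShiftR(crc, 1L)
      }
    }
    tab[i + 1L] <- crc
  }
  tab
})

#' CRC-32 checksum of a character string
#'
#' Computes the standard CRC-32 (IEEE polynomial, as used by gzip and zlib)
#' of the UTF-8 byte representation of each input string. Holograms use
#' `crc32(key) %% L` to assign a canonical fragment key to one of `L` bins,
#' so bin assignment is reproducible across runs and platforms.
#'
#' @param x Character vector.
#' @return Numeric vector of unsigned 32-bit checksums (as doubles, since R
#'   integers cannot hold values above 2^31 - 1).
#' @examples
#' crc32("123456789") # 3421780262, the classic CRC-32 check value
#' @export
crc32 <- function(x) {
  stopifnot(is.character(x))
  vapply(x, function(s) {
    bytes <- as.integer(charToRaw(enc2utf8(s)))
    crc <- -1L
    for (b in bytes) {
      crc <- bitwXor(
        bitwShiftR(crc, 8L),
        .crc32_table[bitwAnd(bitwXor(crc, b), 255L) + 1L]
      )
    }
    v <- bitwXor(crc, -1L)
    if (v < 0L) v + 4294967296 else as.numeric(v)
  }, numeric(1), USE.NAMES = FALSE)
}
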