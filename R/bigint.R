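# Exact non-negative integer arithmetic for mapping counts.
#
# The only operation the package needs is a product of small positive
# integers (candidate-set sizes, each bounded by the atom count), but the
# result can be astronomically large -- a C60 self-pair has 60^60 possible
# mappings -- so counts are kept exactly as little-endian limb vectors in
# base 1e7. With limbs < 1e7 and multipliers <= a few hundred, every
# intermediate fits well inside the 2^53 exact-integer range of a double.

BIG_BASE <- 1e7

big_from_int <- function(x) {
  stopifnot(x >= 0, x == floor(x), x < BIG_BASE)
  structure(list(limbs = as.numeric(x)), class = "mapping_count")
}

big_mul_small <- function(big, m) {
  stopifnot(m >= 0, m == floor(m), m < BIG_BASE)
  limbs <- big$limbs
  if (m == 0) return(big_from_int(0))
  carry <- 0
  for (i in seq_along(limbs)) {
    v <- limbs[i] * m + carry
    limbs[i] <- v %% BIG_BASE
    carry <- v %/% BIG_BASE
  }
  while (carry > 0) {
    limbs <- c(limbs, carry %% BIG_BASE)
    carry <- carry %/% BIG_BASE
  }
  big$limbs <- limbs
  big
}

#' @export
as.character.mapping_count <- function(x, ...) {
  limbs <- rev(x$limbs)
  out <- c(format(limbs[1], scientific = FALSE),
           sprintf("%07.0f", limbs[-1]))
  paste(out, collapse = "")
}

#' @export
format.mapping_count <- function(x, ...) as.character(x)

#' @export
print.mapping_count <- function(x, ...) {
  cat(as.character(x), "\n")
  invisible(x)
}

#' @export
as.double.mapping_count <- function(x, ...) {
  sum(x$limbs * BIG_BASE^(seq_along(x$limbs) - 1))
}

# Number of decimal digits; used for scientific-notation display.
big_ndigits <- function(x) nchar(as.character(x))

# "4.887e+106"-style convenience form for huge counts.
big_scientific <- function(x, digits = 4) {
  s <- as.character(x)
  if (nchar(s) <= 15) return(format(as.numeric(s), scientific = FALSE))
  mant <- as.numeric(paste0(substr(s, 1, 1), ".",
                            substr(s, 2, digits + 1)))
  sprintf("%.*fe+%d", digits - 1, mant, nchar(s) - 1L)
}
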