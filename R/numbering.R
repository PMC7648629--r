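#' Tooth numbering systems
#'
#' The package indexes teeth by the Universal Tooth Numbering (UTN) system:
#' positions 1--16 run across the upper jaw from the patient's upper-right
#' third molar to the upper-left third molar, and 17--32 continue from the
#' lower-left third molar to the lower-right third molar. `utn_to_fdi()`
#' converts a UTN position to the two-digit FDI (Federation Dentaire
#' Internationale) code, whose first digit is the quadrant (1 upper right,
#' 2 upper left, 3 lower left, 4 lower right) and whose second digit counts
#' 1--8 from the central incisor out to the third molar. `fdi_to_utn()` is
#' the inverse.
#'
#' @param utn Integer vector of UTN positions in 1--32.
#' @param fdi Integer vector of FDI codes (11--18, 21--28, 31--38, 41--48).
#' @return `utn_to_fdi()` returns the FDI codes; `fdi_to_utn()` the UTN
#'   positions. Both are vectorized and form a bijection on the permanent
#'   dentition.
#' @examples
#' utn_to_fdi(1)   # 18, upper-right third molar
#' utn_to_fdi(9)   # 21, upper-left central incisor
#' fdi_to_utn(48)  # 32
#' @export
utn_to_fdi <- function(utn) {
  if (!is.numeric(utn) || anyNA(utn) || any(utn != as.integer(utn)) ||
      any(utn < 1L) || any(utn > 32L)) {
    stop("`utn` must be integer tooth positions in 1..32", call. = FALSE)
  }
  utn <- as.integer(utn)
  ifelse(utn <= 8L,  10L + (9L - utn),
  ifelse(utn <= 16L, 20L + (utn - 8L),
  ifelse(utn <= 24L, 30L + (25L - utn),
                     40L + (utn - 24L))))
}

#' @rdname utn_to_fdi
#' @export
fdi_to_utn <- function(fdi) {
  if (!is.numeric(fdi) || anyNA(fdi)) {
    stop("`fdi` must be two-digit FDI codes", call. = FALSE)
  }
  fdi <- as.integer(fdi)
  quadrant <- fdi %/% 10L
  pos <- fdi %% 10L
  if (any(quadrant < 1L) || any(quadrant > 4L) || any(pos < 1L) || any(pos > 8L)) {
    stop("`fdi` must be in {11..18, 21..28, 31..38, 41..48}", call. = FALSE)
  }
  ifelse(quadrant == 1L, 9L - pos,
  ifelse(quadrant == 2L, 8L + pos,
  ifelse(quadrant == 3L, 25L - pos,
                         24L + pos)))
}

#' @rdname utn_to_fdi
#' @param x UTN position vector.
#' @return `tooth_jaw()` returns `"upper"` for UTN 1--16, `"lower"` for
#'   17--32.
#' @export
tooth_jaw <- function(x) {
  if (any(x < 1) || any(x > 32)) stop("tooth positions must be in 1..32", call. = FALSE)
  ifelse(x <= 16, "upper", "lower")
}
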