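#' Map a fragment position onto mature-tRNA coordinates
#'
#' All coordinates are 1-based and inclusive, on the mature tRNA *including*
#' the 3' CCA. For a 3'-anchored fragment (a tRF-3) of length `frag_length`
#' on a parent of length `parent_length`, fragment position `frag_pos` sits at
#' mature position `parent_length - frag_length + frag_pos`; for a 5'-anchored
#' fragment the mature position equals the fragment position. On a canonical
#' 76-nt tRNA, position 4 of a 22-nt tRF-3b maps to mature position 58, the
#' T-loop adenosine methylated by TRMT6/61A.
#'
#' @param parent_length length of the mature tRNA in nt (including CCA).
#' @param frag_length fragment length in nt; must not exceed `parent_length`.
#' @param anchor `"3prime"` for tRF-3s/3' halves, `"5prime"` for tRF-5s/5'
#'   halves.
#' @param frag_pos 1-based position(s) on the fragment.
#' @return integer vector of 1-based mature-tRNA positions.
#' @seealso [mature_to_frag_coord()] for the inverse.
#' @examples
#' frag_to_mature_coord(76, 22, "3prime", 4)  # 58
#' @export
frag_to_mature_coord <- function(parent_length, frag_length,
                                 anchor = c("3prime", "5prime"), frag_pos) {
  anchor <- match.arg(anchor)
  parent_length <- as.integer(parent_length)
  frag_length <- as.integer(frag_length)
  frag_pos <- as.integer(frag_pos)
  if (frag_length < 1L || frag_length > parent_length)
    stop("fragment length ", frag_length, " outside 1..", parent_length)
  bad <- frag_pos < 1L | frag_pos > frag_length
  if (any(bad))
    stop("fragment position ", frag_pos[bad][1L],
         " outside 1..", frag_length)
  if (anchor == "3prime") parent_length - frag_length + frag_pos else frag_pos
}

#' Map a mature-tRNA position onto fragment coordinates
#'
#' Exact inverse of [frag_to_mature_coord()] on the positions the fragment
#' covers; returns `NA` for mature positions the fragment does not cover
#' ("outside").
#'
#' @inheritParams frag_to_mature_coord
#' @param mature_pos 1-based position(s) on the mature tRNA.
#' @return integer vector of 1-based fragment positions, `NA` where the
#'   mature position falls outside the fragment.
#' @examples
#' mature_to_frag_coord(76, 22, "3prime", 58)  # 4
#' mature_to_frag_coord(76, 22, "3prime", 54)  # NA: upstream of the fragment
#' @export
mature_to_frag_coord <- function(parent_length, frag_length,
                                 anchor = c("3prime", "5prime"), mature_pos) {
  anchor <- match.arg(anchor)
  parent_length <- as.integer(parent_length)
  frag_length <- as.integer(frag_length)
  mature_pos <- as.integer(mature_pos)
  if (frag_length < 1L || frag_length > parent_length)
    stop("fragment length ", frag_length, " outside 1..", parent_length)
  bad <- mature_pos < 1L | mature_pos > parent_length
  if (any(bad))
    stop("mature position ", mature_pos[bad][1L],
         " outside 1..", parent_length)
  fp <- if (anchor == "3prime")
    mature_pos - parent_length + frag_length
  else mature_pos
  fp[fp < 1L | fp > frag_length] <- NA_integer_
  fp
}
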