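# Substitution types are always expressed on the sense (coding) strand of the
# affected transcript and written "A>G" etc.

.BASES <- c("A", "C", "G", "T")
.BASE_COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

#' The twelve single-base substitution types
#'
#' Every ordered pair of distinct bases, written on the sense strand as
#' `"from>to"`.  Row order is alphabetical and fixed, matching the layout of
#' per-type count tables throughout the package.
#'
#' @return Character vector of length 12, e.g. `"A>C"`, `"A>G"`, ...
#' @seealso [complement_substitution()]
#' @export
#' @examples
#' substitution_types()
substitution_types <- function() {
  out <- outer(.BASES, .BASES, function(a, b) paste0(a, ">", b))
  sort(out[outer(.BASES, .BASES, "!=")])
}

#' Complement of a substitution type
#'
#' Maps a sense-strand substitution to the type it corresponds to on the
#' opposite strand: `A>G` pairs with `T>C`, and so on.  Applying the map twice
#' is the identity.
#'
#' @param s character vector of substitution types (`"from>to"`).
#' @return Character vector of the complementary types.
#' @export
#' @examples
#' complement_substitution("A>G")  # "T>C"
complement_substitution <- function(s) {
  stopifnot(is.character(s))
  from <- substr(s, 1L, 1L)
  to <- substr(s, 3L, 3L)
  bad <- !(from %in% .BASES) | !(to %in% .BASES) | substr(s, 2L, 2L) != ">" |
    from == to | nchar(s) != 3L
  if (any(bad)) {
    stop("invalid substitution type(s): ", paste(s[bad], collapse = ", "))
  }
  paste0(.BASE_COMPLEMENT[from], ">", .BASE_COMPLEMENT[to])
}

# complement of a plain base vector (character, one base per element)
.complement_bases <- function(x) {
  unname(.BASE_COMPLEMENT[x])
}

# reverse complement of a nucleotide string; Biostrings does the work
.revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

.sub_type <- function(from, to) paste0(from, ">", to)
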