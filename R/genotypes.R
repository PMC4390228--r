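# Allele multisets over {A, B}.
#
# Every genotype, haplotype tuple or gamete tuple in this package is an
# unordered multiset of A/B alleles.  Internally a multiset is encoded by
# two integers, its size and its number of B alleles (nb); the canonical
# string form sorts A before B and writes "-" for the empty (CN = 0)
# multiset.  All engine arithmetic (partitioning a parent genotype into two
# haplotypes, forming gametes, taking unions) reduces to integer arithmetic
# on (size, nb) pairs.

#' Parse multiploid genotype strings
#'
#' Converts caller-style genotype strings over the alleles `A` and `B` into
#' the package's integer multiset encoding.  Accepted forms are `"-"` or
#' `""` (null genotype, diploid copy number 0), one to four `A`/`B`
#' characters in any order (e.g. `"A"`, `"AB"`, `"ABB"`, `"ABBB"`), and
#' `"NC"` for a no-call.
#'
#' @param x Character vector of genotype strings.
#' @return A data.frame with one row per input: `size` (number of observed
#'   allele copies, `NA` for no-calls), `nb` (number of B alleles, `NA` for
#'   no-calls) and `no_call` (logical).
#' @examples
#' parse_genotype_string(c("ABB", "-", "NC", "BA"))
#' @export
parse_genotype_string <- function(x) {
  x <- toupper(trimws(as.character(x)))
  no_call <- x == "NC"
  empty <- x == "-" | x == ""
  body <- ifelse(no_call | empty, "", x)
  bad <- grepl("[^AB]", body)
  if (any(bad)) {
    stop("malformed genotype string(s): ",
         paste(unique(x[bad]), collapse = ", "),
         " (allowed: '-', 'NC', or 1-4 characters over {A,B})")
  }
  size <- nchar(body)
  if (any(size > 4L)) {
    stop("genotype string(s) longer than 4 alleles: ",
         paste(unique(x[size > 4L]), collapse = ", "))
  }
  nb <- nchar(gsub("A", "", body, fixed = TRUE))
  size[no_call] <- NA_integer_
  nb[no_call] <- NA_integer_
  data.frame(size = as.integer(size), nb = as.integer(nb), no_call = no_call)
}

#' Format an allele multiset canonically
#'
#' @param size Integer vector of multiset sizes.
#' @param nb Integer vector of B-allele counts (`nb <= size`).
#' @return Character vector with A sorted before B and `"-"` for empty
#'   multisets; `NA` sizes give `"NC"`.
#' @examples
#' format_genotype(c(3, 0, 2), c(1, 0, 2))
#' @export
format_genotype <- function(size, nb) {
  stopifnot(length(size) == length(nb))
  out <- character(length(size))
  for (i in seq_along(size)) {
    if (is.na(size[i])) {
      out[i] <- "NC"
    } else if (size[i] == 0L) {
      out[i] <- "-"
    } else {
      out[i] <- paste0(strrep("A", size[i] - nb[i]), strrep("B", nb[i]))
    }
  }
  out
}

# Range of B-allele counts available when drawing a sub-multiset of size k
# from a multiset with `size` alleles of which `nb` are B.
.sub_nb_range <- function(k, size, nb) {
  lo <- max(0L, k - (size - nb))
  hi <- min(k, nb)
  if (lo > hi) return(integer(0))
  lo:hi
}
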