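# Engine configuration.

#' Phasing engine configuration
#'
#' @param allow_nonmendelian Consider de novo deletions/duplications and
#'   uniparental iso-/heterodisomy when Mendelian transmission cannot
#'   explain a child (default `TRUE`).
#' @param cn_splits Optional named list overriding the allowed haploid
#'   copy-number splits per diploid CN, e.g.
#'   `list("3" = list(c(1, 2), c(0, 3)))`.  Defaults: CN 0 -> (0,0);
#'   1 -> (0,1); 2 -> (1,1); 3 -> (1,2); 4 -> (1,3) and (2,2).  Haploid
#'   copy numbers are capped at 3.
#' @param max_combinations Search budget: enumeration steps (phases,
#'   gametes, phase-pair x scheme combinations) beyond this cap raise an
#'   error rather than silently approximating (default `1e6`).
#' @param count_upd_as How many non-Mendelian events one uniparental
#'   disomy contributes (1, the default: one meiotic error per child; or
#'   2).
#' @param allow_multistep_dup Also enumerate two-step de novo gains
#'   (gamete cn = source cn + 2, still capped at 3); default `FALSE`,
#'   single duplications only.
#' @return A list of class `phasing_config`.
#' @export
phasing_config <- function(allow_nonmendelian = TRUE, cn_splits = NULL,
                           max_combinations = 1e6, count_upd_as = 1,
                           allow_multistep_dup = FALSE) {
  stopifnot(count_upd_as %in% c(1L, 2L), max_combinations >= 1)
  structure(list(allow_nonmendelian = isTRUE(allow_nonmendelian),
                 cn_splits = cn_splits,
                 max_combinations = max_combinations,
                 count_upd_as = as.integer(count_upd_as),
                 allow_multistep_dup = isTRUE(allow_multistep_dup)),
            class = "phasing_config")
}

# Allowed unordered (cn1, cn2) haplotype splits for a member with the
# given diploid CN, honouring the haploid cap of 3.
cn_splits_for <- function(cn, config = phasing_config()) {
  cn <- as.integer(cn)
  if (cn > 4L || cn < 0L) stop("unsupported diploid copy number: ", cn)
  ov <- config$cn_splits[[as.character(cn)]]
  if (!is.null(ov)) {
    ov <- lapply(ov, function(s) sort(as.integer(s)))
    bad <- vapply(ov, function(s) sum(s) != cn || any(s < 0L | s > 3L),
                  logical(1))
    if (any(bad)) stop("invalid cn split override for CN=", cn)
    return(unique(ov))
  }
  switch(as.character(cn),
         "0" = list(c(0L, 0L)),
         "1" = list(c(0L, 1L)),
         "2" = list(c(1L, 1L)),
         "3" = list(c(1L, 2L)),
         "4" = list(c(1L, 3L), c(2L, 2L)))
}

# expand a list of integer choice vectors into a combination matrix
# (one row per combination); zero-length list yields a single empty row.
.combo_grid <- function(choices, cap, what = "combinations") {
  n <- prod(vapply(choices, length, numeric(1)))
  if (any(vapply(choices, length, integer(1)) == 0L)) {
    return(matrix(integer(0), nrow = 0L, ncol = length(choices)))
  }
  if (n > cap) {
    stop("search budget exceeded while enumerating ", what,
         " (", format(n, big.mark = ","), " > ", format(cap, big.mark = ","),
         "); consider subsampling markers")
  }
  if (length(choices) == 0L) return(matrix(integer(0), nrow = 1L, ncol = 0L))
  m <- as.matrix(expand.grid(choices, KEEP.OUT.ATTRS = FALSE))
  dimnames(m) <- NULL
  storage.mode(m) <- "integer"
  m
}

# lexicographic <= on equal-length integer vectors
.lex_leq <- function(a, b) {
  d <- a - b
  i <- which(d != 0L)
  if (length(i) == 0L) TRUE else d[i[1]] < 0L
}
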