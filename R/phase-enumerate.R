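# Enumeration of parental haplotype partitions and gametes.
#
# A haplotype is (cn, nb): its haploid copy number and, per marker, how
# many of its cn allele copies are B.  A parent phase is an unordered pair
# of haplotypes whose per-marker multiset union reproduces the parent's
# observed genotypes.  A gamete is a haplotype tagged with the inheritance
# event that formed it.

#' Enumerate parental haplotype phases
#'
#' Enumerates all distinct unordered haplotype pairs with the allowed
#' haploid copy-number splits whose per-marker allele multisets partition
#' the parent's observed genotype multisets.  Pairs identical under
#' hap1/hap2 swap are collapsed.
#'
#' @param nb Integer vector: observed B-allele count per marker.
#' @param cn Diploid copy number of the parent (0-4; all observed genotype
#'   sizes must equal `cn`).
#' @param splits List of unordered `c(cn1, cn2)` splits to try (default:
#'   the configuration's splits for `cn`).
#' @param config A [phasing_config()].
#' @return List of phases; each phase is a list with `cn` (length-2
#'   integer) and `nb` (2 x m integer matrix, row i = haplotype i).
#' @examples
#' # one heterozygous CN=2 marker: a single phase up to swap
#' enumerate_parent_phases(nb = 1L, cn = 2L)
#' @export
enumerate_parent_phases <- function(nb, cn, splits = NULL,
                                    config = phasing_config()) {
  cn <- as.integer(cn)
  if (cn > 4L) stop("unsupported diploid copy number: ", cn)
  nb <- as.integer(nb)
  if (any(nb < 0L | nb > cn)) stop("B-allele counts incompatible with CN")
  if (is.null(splits)) splits <- cn_splits_for(cn, config)
  m <- length(nb)
  phases <- list()
  for (s in splits) {
    c1 <- min(s); c2 <- max(s)
    choices <- lapply(seq_len(m), function(j) .sub_nb_range(c1, cn, nb[j]))
    grid <- .combo_grid(choices, config$max_combinations, "parent phases")
    for (r in seq_len(nrow(grid))) {
      nb1 <- grid[r, ]
      nb2 <- nb - nb1
      if (c1 == c2 && !.lex_leq(nb1, nb2)) next
      phases[[length(phases) + 1L]] <-
        list(cn = c(c1, c2),
             nb = matrix(c(nb1, nb2), nrow = 2L, byrow = TRUE))
    }
  }
  phases
}

.gamete <- function(cn, nb, event, src) {
  list(cn = as.integer(cn), nb = as.integer(nb), event = event,
       src = sort(unique(as.integer(src))))
}

.gamete_key <- function(g) {
  paste(g$event, g$cn, paste(g$nb, collapse = ","), sep = ";")
}

#' Enumerate gametes a parent phase can form
#'
#' Mendelian gametes are the parent's two haplotypes, unmodified.  With
#' non-Mendelian events enabled, de novo deletions are every proper
#' sub-haplotype of one source haplotype (uniform copy-number reduction,
#' any per-marker sub-multiset), and de novo duplications add one extra
#' allele copy per marker drawn either from the source haplotype's own
#' alleles or from the other haplotype's alleles, with the gamete's
#' haploid copy number capped at 3.  Uniparental disomy is handled at the
#' gamete-pairing level, not here.  Gametes identical in content and event
#' are merged, accumulating their candidate source haplotypes.
#'
#' @param phase A phase from [enumerate_parent_phases()].
#' @param allow_nonmendelian Include de novo deletion/duplication gametes.
#' @param config A [phasing_config()].
#' @return List of gametes: `cn`, `nb`, `event` (`"MENDELIAN"`,
#'   `"DENOVO_DELETION"` or `"DENOVO_DUP"`), `src` (candidate source
#'   haplotype indices within the phase).
#' @export
enumerate_gametes <- function(phase, allow_nonmendelian = TRUE,
                              config = phasing_config()) {
  m <- ncol(phase$nb)
  cap <- config$max_combinations
  out <- new.env(parent = emptyenv())
  add <- function(g) {
    k <- .gamete_key(g)
    old <- out[[k]]
    if (is.null(old)) out[[k]] <- g
    else out[[k]]$src <- sort(unique(c(old$src, g$src)))
  }
  for (i in 1:2) {
    add(.gamete(phase$cn[i], phase$nb[i, ], "MENDELIAN", i))
  }
  if (allow_nonmendelian) {
    for (i in 1:2) {
      hcn <- phase$cn[i]; hnb <- phase$nb[i, ]
      # de novo deletions: any smaller haploid cn, any per-marker sub-multiset
      if (hcn >= 1L) {
        for (tgt in 0:(hcn - 1L)) {
          choices <- lapply(seq_len(m),
                            function(j) .sub_nb_range(tgt, hcn, hnb[j]))
          grid <- .combo_grid(choices, cap, "deletion gametes")
          for (r in seq_len(nrow(grid))) {
            add(.gamete(tgt, grid[r, ], "DENOVO_DELETION", i))
          }
        }
      }
      # de novo duplications: +1 copy per marker (optionally +2), from the
      # same haplotype (intra) or the other haplotype (inter)
      exts <- if (config$allow_multistep_dup) 1:2 else 1L
      for (ext in exts) {
        gcn <- hcn + ext
        if (gcn > 3L || hcn < 1L) next
        for (mode_hap in unique(c(i, 3L - i))) {
          mh_cn <- phase$cn[mode_hap]; mh_nb <- phase$nb[mode_hap, ]
          if (mh_cn < 1L) next
          choices <- lapply(seq_len(m), function(j) {
            has_a <- (mh_cn - mh_nb[j]) >= 1L
            has_b <- mh_nb[j] >= 1L
            eb <- 0:ext
            # every extra B needs a B in the mode haplotype, every extra A an A
            eb[(eb == 0L | has_b) & (eb == ext | has_a)]
          })
          grid <- .combo_grid(choices, cap, "duplication gametes")
          for (r in seq_len(nrow(grid))) {
            add(.gamete(gcn, hnb + grid[r, ], "DENOVO_DUP", i))
          }
        }
      }
    }
  }
  gs <- as.list(out)
  gs[order(names(gs))]
}
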