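# Post-phasing analytics: region grouping, transmission tallies and the
# 50:50 transmission-bias test, multiple-testing adjustment, allelic
# variability within copy-number-gain haplotypes, and dataset summaries.

.LENGTH_BINS <- c(0, 1e4, 3e4, 1e5, Inf)
.LENGTH_LABELS <- c("<10kb", "10-30kb", "30-100kb", ">100kb")

#' Assign a CNV region to carrier group A, B or C
#'
#' Group A: exactly one parent carries a CNV in the region; group B: both
#' parents are carriers; group C: no parental carrier but at least one
#' child is (putative de novo CNV).
#'
#' @param region A `cnv_region`.
#' @return `"A"`, `"B"` or `"C"`.
#' @export
assign_group <- function(region) {
  stopifnot(inherits(region, "cnv_region"))
  pa <- region$member_cn[region$father_id] != 2L
  mo <- region$member_cn[region$mother_id] != 2L
  np <- sum(pa, mo)
  if (np == 1L) return("A")
  if (np == 2L) return("B")
  if (any(region$member_cn[region$child_ids] != 2L)) return("C")
  stop("region ", region$region_id, " has no CNV carrier")
}

#' Length bin of a CNV
#'
#' Half-open bins `[0,10kb)`, `[10kb,30kb)`, `[30kb,100kb)`,
#' `[100kb,Inf)`, labelled `<10kb`, `10-30kb`, `30-100kb`, `>100kb`.
#'
#' @param length_bp Numeric vector of CNV lengths in bp.
#' @return Factor of bin labels.
#' @export
cnv_length_bin <- function(length_bp) {
  cut(length_bp, breaks = .LENGTH_BINS, labels = .LENGTH_LABELS,
      right = FALSE)
}

#' Tally transmissions of normal and CNV-carrying haplotypes
#'
#' For each unambiguously phased group-A region, counts one transmission
#' event per child from the carrier parent: the transmitted haplotype is
#' `normal` when its haploid copy number is 1 and `cnv` otherwise.
#' Children whose gamete from the carrier parent arose by a non-Mendelian
#' event are not transmissions and are skipped.  Results are stratified
#' by CNV type (deletion/duplication from the carrier's diploid CN) and
#' CNV length bin.
#'
#' @param results List of `phasing_result` objects; every element must be
#'   unambiguous and group A, otherwise an error is raised.
#' @return A list with `records` (one row per transmission) and `table`
#'   (per-bin transmitted/total counts and rates for deletions,
#'   duplications and combined, plus an `All` row).
#' @export
tally_transmissions <- function(results) {
  recs <- list()
  for (res in results) {
    stopifnot(inherits(res, "phasing_result"))
    reg <- res$region
    grp <- assign_group(reg)
    if (grp != "A") {
      stop("tally_transmissions: region ", res$region_id,
           " is group ", grp, ", only group A is analysed")
    }
    if (!res$unambiguous) {
      stop("tally_transmissions: region ", res$region_id,
           " is ambiguously phased")
    }
    carrier <- reg$carrier_parents[1]
    carrier_id <- if (carrier == "father") reg$father_id else reg$mother_id
    cnv_type <- if (reg$member_cn[carrier_id] < 2L) "deletion" else
      "duplication"
    sol <- res$solutions[[1]]
    for (cid in names(sol$schemes)) {
      sc <- sol$schemes[[cid]][[carrier]]
      if (sc$event != "MENDELIAN") next
      recs[[length(recs) + 1L]] <- data.frame(
        region_id = res$region_id, family_id = res$family_id,
        child_id = cid, carrier_parent = carrier,
        transmitted_kind = if (sc$cn == 1L) "normal" else "cnv",
        cnv_type = cnv_type,
        cnv_length = reg$end - reg$start + 1L)
    }
  }
  records <- if (length(recs)) do.call(rbind, recs) else
    data.frame(region_id = character(), family_id = character(),
               child_id = character(), carrier_parent = character(),
               transmitted_kind = character(), cnv_type = character(),
               cnv_length = integer())
  records$length_bin <- cnv_length_bin(records$cnv_length)
  tab <- do.call(rbind, lapply(c(.LENGTH_LABELS, "All"), function(bin) {
    sel <- if (bin == "All") rep(TRUE, nrow(records)) else
      records$length_bin == bin
    row <- data.frame(length_bin = bin)
    for (ty in c("deletion", "duplication", "all")) {
      s <- sel & (ty == "all" | records$cnv_type == ty)
      n_cnv <- sum(records$transmitted_kind[s] == "cnv")
      n_tot <- sum(s)
      pre <- c(deletion = "del", duplication = "dup", all = "all")[[ty]]
      row[[paste0(pre, "_cnv")]] <- n_cnv
      row[[paste0(pre, "_total")]] <- n_tot
      row[[paste0(pre, "_rate")]] <- if (n_tot) n_cnv / n_tot else NA_real_
    }
    row
  }))
  list(records = records, table = tab)
}

#' Test deviation from 50:50 transmission
#'
#' Pearson's chi-square test of the observed CNV-vs-normal transmission
#' counts against equal proportions.  By default the Yates continuity
#' correction is applied (this reproduces a goodness-of-fit test on small
#' deviations more conservatively); set `correct = FALSE` for the
#' uncorrected Pearson statistic.
#'
#' @param n_cnv,n_normal Transmission counts of CNV-carrying and normal
#'   haplotypes (total must be >= 1).
#' @param correct Apply the continuity correction (default `TRUE`).
#' @return A list with `chi_square`, `p_value`, `n` and `rate`
#'   (`n_cnv / n`).
#' @examples
#' transmission_bias_test(580, 671)$p_value  # ~ 0.011
#' @export
transmission_bias_test <- function(n_cnv, n_normal, correct = TRUE) {
  n <- n_cnv + n_normal
  if (n < 1L) stop("transmission_bias_test: zero total count")
  # small-count approximation warnings are expected for sparse bins
  ht <- if (correct) {
    suppressWarnings(stats::prop.test(n_cnv, n, p = 0.5, correct = TRUE))
  } else {
    suppressWarnings(stats::chisq.test(c(n_cnv, n_normal),
                                       p = c(0.5, 0.5)))
  }
  list(chi_square = unname(ht$statistic), p_value = unname(ht$p.value),
       n = n, rate = n_cnv / n)
}

#' Adjust per-bin p-values for multiple testing
#'
#' Bonferroni by default (conservative), with Holm or Benjamini-Hochberg
#' available; adjusted values are capped at 1.
#'
#' @param p_values Numeric vector of p-values.
#' @param m Number of tests to correct for (default `length(p_values)`).
#' @param method `"bonferroni"` (default), `"holm"` or `"BH"`.
#' @param alpha Significance level for the `significant` flags.
#' @return A list with `adjusted` and `significant`.
#' @export
multiple_testing_adjust <- function(p_values, m = length(p_values),
                                    method = "bonferroni", alpha = 0.05) {
  stopifnot(length(p_values) >= 1L, m >= length(p_values))
  adj <- stats::p.adjust(p_values, method = method, n = m)
  list(adjusted = adj, significant = adj < alpha)
}

#' Allelic variability of copy-number-gain haplotypes
#'
#' For every parental haplotype with haploid copy number >= 2 in a
#' solution, reports whether the parent's two haplotypes are
#' distinguishable by allele content at >= 1 marker (*between*-haplotype
#' informativeness) and whether the gain haplotype itself carries a
#' heterozygous allele tuple at >= 1 marker (*within*-haplotype
#' informativeness, i.e. alternative allelic copies inside the gain).
#'
#' @param solution A family solution.
#' @return A data.frame with one row per gain haplotype: `parent`, `hap`,
#'   `cn`, `has_between`, `has_within`; zero rows when no parent carries
#'   a gain haplotype.
#' @export
allelic_variability <- function(solution) {
  rows <- list()
  for (p in c("father", "mother")) {
    ph <- solution[[p]]
    for (i in 1:2) {
      if (ph$cn[i] < 2L) next
      nb_i <- ph$nb[i, ]
      has_within <- any(nb_i > 0L & nb_i < ph$cn[i])
      o <- 3L - i
      # allele *types* differ at some marker (a polymorphic marker between
      # the haplotypes); a pure copy-count difference is not informative
      ti_a <- (ph$cn[i] - nb_i) > 0L; ti_b <- nb_i > 0L
      to_a <- (ph$cn[o] - ph$nb[o, ]) > 0L; to_b <- ph$nb[o, ] > 0L
      has_between <- any(ti_a != to_a | ti_b != to_b)
      rows[[length(rows) + 1L]] <- data.frame(
        parent = p, hap = i, cn = ph$cn[i],
        has_between = has_between, has_within = has_within)
    }
  }
  if (length(rows)) do.call(rbind, rows) else
    data.frame(parent = character(), hap = integer(), cn = integer(),
               has_between = logical(), has_within = logical())
}

#' Summarize a phased dataset
#'
#' Computes per-group unambiguous phasing efficiency, the list of de novo
#' events with parent-of-origin and duplication subtype, and the
#' between/within allelic-variability percentages over gain haplotypes of
#' unambiguously phased group A and B regions.
#'
#' @param results List of `phasing_result` objects.
#' @return A list with `efficiency` (per group and overall, percentages
#'   to 1 decimal), `de_novo` (data.frame), and `allelic` (gain-haplotype
#'   counts and percentages).
#' @export
summarize_dataset <- function(results) {
  grp <- vapply(results, function(r) assign_group(r$region), character(1))
  unamb <- vapply(results, `[[`, logical(1), "unambiguous")
  eff_row <- function(sel) {
    n <- sum(sel); k <- sum(unamb[sel])
    data.frame(n_regions = n, n_unambiguous = k,
               pct = if (n) round(100 * k / n, 1) else NA_real_)
  }
  efficiency <- rbind(
    cbind(group = "all", eff_row(rep(TRUE, length(results)))),
    cbind(group = "A", eff_row(grp == "A")),
    cbind(group = "B", eff_row(grp == "B")),
    cbind(group = "C", eff_row(grp == "C")))
  dn <- list()
  gain_rows <- list()
  for (k in seq_along(results)) {
    res <- results[[k]]
    if (!res$unambiguous) next
    sol <- res$solutions[[1]]
    for (cid in names(sol$schemes)) {
      for (p in c("father", "mother")) {
        sc <- sol$schemes[[cid]][[p]]
        if (sc$event %in% c("DENOVO_DELETION", "DENOVO_DUP")) {
          dn[[length(dn) + 1L]] <- data.frame(
            family_id = res$family_id, region_id = res$region_id,
            chrom = res$region$chrom, start = res$region$start,
            end = res$region$end, child_id = cid,
            type = if (sc$event == "DENOVO_DELETION") "deletion" else
              "duplication",
            parent_of_origin =
              if (!is.null(sc$parent_origin)) sc$parent_origin else p,
            subtype = if (!is.null(sc$subtype)) sc$subtype else sc$event)
        }
      }
    }
    if (grp[k] %in% c("A", "B")) {
      av <- allelic_variability(sol)
      if (nrow(av)) gain_rows[[length(gain_rows) + 1L]] <- av
    }
  }
  de_novo <- if (length(dn)) do.call(rbind, dn) else
    data.frame(family_id = character(), region_id = character(),
               chrom = character(), start = integer(), end = integer(),
               child_id = character(), type = character(),
               parent_of_origin = character(), subtype = character())
  gains <- if (length(gain_rows)) do.call(rbind, gain_rows) else
    allelic_variability(list(father = list(cn = c(1L, 1L),
                                           nb = matrix(0L, 2, 0)),
                             mother = list(cn = c(1L, 1L),
                                           nb = matrix(0L, 2, 0)),
                             schemes = list()))
  n_gain <- nrow(gains)
  allelic <- list(
    n_gain_haplotypes = n_gain,
    n_between = sum(gains$has_between),
    n_within = sum(gains$has_within),
    pct_between = if (n_gain) round(100 * sum(gains$has_between) / n_gain,
                                    1) else NA_real_,
    pct_within = if (n_gain) round(100 * sum(gains$has_within) / n_gain,
                                   1) else NA_real_)
  list(efficiency = efficiency, de_novo = de_novo, allelic = allelic)
}
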