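# End-to-end pipeline: parse inputs, merge and filter calls, converge
# family regions, phase, and analyse.

#' Phase a family CNV dataset end to end
#'
#' Reads the genotype table, one or two callers' call sets, an optional
#' external confirmation set and the pedigree; intersects and filters
#' calls; converges family-wise CNV regions; applies marker selection and
#' phases every region.
#'
#' @param genotype_file Genotype TSV (see [read_genotype_table()]).
#' @param calls_a_file Primary caller's call TSV.
#' @param calls_b_file Optional second caller's call TSV; when given,
#'   calls are confirmed by intersection and unmatched raw calls drive
#'   the region exclusion rule.
#' @param pedigree_file PED file of nuclear families.
#' @param external_calls_file Optional external confirmation call TSV.
#' @param config A [phasing_config()].
#' @param output_dir Optional directory; when given, writes
#'   `regions.tsv`, `phasing.tsv` and `phasing.json`.
#' @param keep_going Convert per-region phasing errors (e.g. search
#'   budget) into warnings and continue (default `TRUE`).
#' @return A list with `regions`, `results`, `excluded` and `files`.
#' @export
phase_dataset <- function(genotype_file, calls_a_file, calls_b_file = NULL,
                          pedigree_file, external_calls_file = NULL,
                          config = phasing_config(), output_dir = NULL,
                          keep_going = TRUE) {
  genotypes <- read_genotype_table(genotype_file)
  calls_a <- read_cnv_calls(calls_a_file)
  families <- read_pedigree(pedigree_file)
  if (!is.null(calls_b_file)) {
    calls_b <- read_cnv_calls(calls_b_file)
    confirmed <- intersect_caller_calls(calls_a, calls_b)
    raw_index <- single_caller_raw_calls(calls_a, calls_b)
  } else {
    confirmed <- calls_a
    raw_index <- calls_a[0, , drop = FALSE]
  }
  if (!is.null(external_calls_file)) {
    external <- read_cnv_calls(external_calls_file)
    confirmed <- confirm_with_external_calls(confirmed, external)
  }
  filtered <- filter_calls(confirmed)
  regions <- converge_family_regions(filtered, raw_index, families,
                                     genotypes)
  excluded <- attr(regions, "excluded")
  regions <- lapply(regions, select_region_markers)
  results <- list()
  for (reg in regions) {
    res <- tryCatch(phase_region(reg, config = config),
                    error = function(e) {
                      if (!keep_going) stop(e)
                      warning("region ", reg$region_id, ": ",
                              conditionMessage(e), call. = FALSE)
                      NULL
                    })
    if (!is.null(res)) results[[res$region_id]] <- res
  }
  files <- NULL
  if (!is.null(output_dir)) {
    dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
    files <- c(regions = file.path(output_dir, "regions.tsv"),
               phasing_tsv = file.path(output_dir, "phasing.tsv"),
               phasing_json = file.path(output_dir, "phasing.json"))
    write_regions_tsv(regions, files[["regions"]])
    write_phasing_tsv(results, files[["phasing_tsv"]])
    write_phasing_json(results, files[["phasing_json"]])
  }
  list(regions = regions, results = results, excluded = excluded,
       files = files)
}

.solution_rows <- function(res, sol_idx) {
  sol <- res$solutions[[sol_idx]]
  reg <- res$region
  m <- ncol(sol$father$nb)
  hap_row <- function(member, role, label, cn, nb, transmitted_to, event) {
    data.frame(family_id = res$family_id, region_id = res$region_id,
               chrom = reg$chrom, start = reg$start, end = reg$end,
               solution_idx = sol_idx, n_solutions = res$n_solutions,
               member = member, role = role, hap_label = label,
               hap_cn = cn,
               hap_alleles = paste(format_genotype(rep(cn, m), nb),
                                   collapse = ","),
               transmitted_to = transmitted_to, event = event,
               score_unexplained = res$score[1],
               score_nonmendelian = res$score[2])
  }
  rows <- list()
  for (p in c("father", "mother")) {
    pid <- if (p == "father") reg$father_id else reg$mother_id
    ph <- sol[[p]]
    for (i in 1:2) {
      trans <- vapply(names(sol$schemes), function(cid) {
        sc <- sol$schemes[[cid]][[p]]
        sc$event == "MENDELIAN" && i %in% sc$src
      }, logical(1))
      rows[[length(rows) + 1L]] <-
        hap_row(pid, p, paste0("hap", i), ph$cn[i], ph$nb[i, ],
                paste(names(sol$schemes)[trans], collapse = ","),
                "PHASE")
    }
  }
  for (cid in names(sol$schemes)) {
    for (p in c("father", "mother")) {
      sc <- sol$schemes[[cid]][[p]]
      ev <- if (!is.null(sc$subtype)) sc$subtype else sc$event
      rows[[length(rows) + 1L]] <-
        hap_row(cid, "child", paste0(p, "_gamete"), sc$cn, sc$nb, "", ev)
    }
  }
  do.call(rbind, rows)
}

#' Write phasing results as a TSV table
#'
#' One row per (solution, member, haplotype/gamete).
#'
#' @param results List of `phasing_result` objects.
#' @param path Output file.
#' @return Invisibly, the data.frame written.
#' @export
write_phasing_tsv <- function(results, path) {
  rows <- list()
  for (res in results) {
    for (s in seq_along(res$solutions)) {
      rows[[length(rows) + 1L]] <- .solution_rows(res, s)
    }
  }
  df <- if (length(rows)) do.call(rbind, rows) else
    data.frame(family_id = character(), region_id = character(),
               chrom = character(), start = integer(), end = integer(),
               solution_idx = integer(), n_solutions = integer(),
               member = character(), role = character(),
               hap_label = character(), hap_cn = integer(),
               hap_alleles = character(), transmitted_to = character(),
               event = character(), score_unexplained = integer(),
               score_nonmendelian = integer())
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(df)
}

.result_to_list <- function(res) {
  sols <- lapply(res$solutions, function(sol) {
    list(father = list(cn = sol$father$cn,
                       nb = apply(sol$father$nb, 1, identity,
                                  simplify = FALSE)),
         mother = list(cn = sol$mother$cn,
                       nb = apply(sol$mother$nb, 1, identity,
                                  simplify = FALSE)),
         schemes = lapply(sol$schemes, function(pair) {
           lapply(pair, function(sc) {
             out <- list(event = sc$event, cn = sc$cn, nb = sc$nb,
                         src = sc$src)
             if (!is.null(sc$subtype)) out$subtype <- sc$subtype
             if (!is.null(sc$parent_origin)) {
               out$parent_origin <- sc$parent_origin
             }
             out
           })
         }),
         key = solution_key(sol))
  })
  list(region_id = res$region_id, family_id = res$family_id,
       chrom = res$region$chrom, start = res$region$start,
       end = res$region$end,
       member_cn = as.list(res$region$member_cn),
       group = assign_group(res$region),
       score = list(unexplained = res$score[1],
                    nonmendelian = res$score[2]),
       unambiguous = res$unambiguous, n_solutions = res$n_solutions,
       solutions = sols)
}

#' Write phasing results as JSON
#'
#' Full `phasing_result` documents, one object per region.
#'
#' @param results List of `phasing_result` objects.
#' @param path Output file.
#' @return Invisibly, `path`.
#' @export
write_phasing_json <- function(results, path) {
  docs <- lapply(unname(results), .result_to_list)
  jsonlite::write_json(docs, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Analyse phased regions
#'
#' Groups regions, tallies transmissions over the unambiguously phased
#' group-A regions, tests each length bin (and the overall counts) for
#' deviation from 50:50 transmission with multiple-testing adjustment,
#' and summarizes phasing efficiency, de novo events and allelic
#' variability.  Group-B regions are excluded from the bias analysis.
#'
#' @param results List of `phasing_result` objects.
#' @param output_dir Optional directory; writes `transmissions.tsv`,
#'   `summary.json` and `denovo.tsv`.
#' @param correct Continuity correction for the bias tests.
#' @return A list with `transmissions`, `bias_tests`, `summary`.
#' @export
analyze_results <- function(results, output_dir = NULL, correct = TRUE) {
  grp <- vapply(results, function(r) assign_group(r$region), character(1))
  unamb <- vapply(results, `[[`, logical(1), "unambiguous")
  groupA <- results[grp == "A" & unamb]
  if (length(groupA) == 0L) {
    warning("no unambiguously phased group-A regions; ",
            "transmission table is empty")
  }
  tt <- tally_transmissions(groupA)
  tab <- tt$table
  bias <- do.call(rbind, lapply(seq_len(nrow(tab)), function(r) {
    n_cnv <- tab$all_cnv[r]; n_tot <- tab$all_total[r]
    if (n_tot < 1L) {
      return(data.frame(length_bin = tab$length_bin[r],
                        chi_square = NA_real_, p_value = NA_real_))
    }
    bt <- transmission_bias_test(n_cnv, n_tot - n_cnv, correct = correct)
    data.frame(length_bin = tab$length_bin[r], chi_square = bt$chi_square,
               p_value = bt$p_value)
  }))
  tested <- !is.na(bias$p_value)
  bias$p_adjusted <- NA_real_
  bias$significant <- NA
  if (any(tested)) {
    adj <- multiple_testing_adjust(bias$p_value[tested])
    bias$p_adjusted[tested] <- adj$adjusted
    bias$significant[tested] <- adj$significant
  }
  summ <- summarize_dataset(results)
  if (!is.null(output_dir)) {
    dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.table(cbind(tab, bias[, -1, drop = FALSE]),
                       file.path(output_dir, "transmissions.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(summ$de_novo, file.path(output_dir, "denovo.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    jsonlite::write_json(list(efficiency = summ$efficiency,
                              allelic = summ$allelic),
                         file.path(output_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  list(transmissions = tt, bias_tests = bias, summary = summ)
}
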