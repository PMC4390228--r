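# Family-wise CNV regions.
#
# Filtered, confirmed calls of one family that overlap on one chromosome
# are converged into a single CNV region: the interval is the intersection
# of the carriers' calls, every family member gets a constant diploid copy
# number over the interval (2 when no call), and the per-marker multiploid
# genotypes of all members are attached.  A region is the phasing unit.

#' Raw calls supported by only one caller
#'
#' Returns the calls from either caller that no same-sample, same-type,
#' overlapping call of the other caller matches.  These unmatched raw
#' calls drive the family-region exclusion rule: a region is discarded if
#' any family member has such a call overlapping it, so that members with
#' normal diploid copy number are proven call-free in both callers.
#'
#' @param calls_a,calls_b Raw call sets from the two callers.
#' @return A data.frame of unmatched calls from both sets.
#' @export
single_caller_raw_calls <- function(calls_a, calls_b) {
  unmatched <- function(x, y) {
    if (nrow(x) == 0L) return(x)
    keep <- logical(nrow(x))
    for (i in seq_len(nrow(x))) {
      a <- x[i, ]
      keep[i] <- !any(y$sample_id == a$sample_id & y$chrom == a$chrom &
                      y$start <= a$end & y$end >= a$start &
                      .call_type(y$cn) == .call_type(a$cn))
    }
    x[keep, , drop = FALSE]
  }
  res <- rbind(unmatched(calls_a, calls_b), unmatched(calls_b, calls_a))
  rownames(res) <- NULL
  res
}

.cluster_intervals <- function(df) {
  ord <- order(df$start, df$end)
  df <- df[ord, , drop = FALSE]
  cl <- integer(nrow(df))
  cur <- 1L
  max_end <- df$end[1]
  cl[1] <- 1L
  for (i in seq_len(nrow(df))[-1]) {
    if (df$start[i] <= max_end) {
      cl[i] <- cur
      max_end <- max(max_end, df$end[i])
    } else {
      cur <- cur + 1L
      cl[i] <- cur
      max_end <- df$end[i]
    }
  }
  split(df, cl)
}

#' Converge confirmed calls into family-wise CNV regions
#'
#' Overlapping confirmed calls of one family's members are merged into one
#' region whose interval is the intersection of the contributing calls.  A
#' region is excluded when (i) any family member has a raw single-caller
#' call overlapping the interval, (ii) two or more carriers' calls were
#' intersected but fewer than 3 markers fall inside the intersection
#' ("shared" markers), (iii) a member carries overlapping calls with
#' different copy numbers (complex, mosaic-like state), or (iv) the
#' intersection of the clustered calls is empty.
#'
#' @param calls Filtered, confirmed calls ([filter_calls()] output).
#' @param raw_call_index Unmatched raw calls
#'   ([single_caller_raw_calls()] output); may have zero rows.
#' @param families Family list from [read_pedigree()].
#' @param genotypes Genotype table from [read_genotype_table()].
#' @return A list of `cnv_region` objects (see [select_region_markers()]);
#'   excluded candidate regions are reported via messages and attached as
#'   the `"excluded"` attribute.
#' @export
converge_family_regions <- function(calls, raw_call_index, families,
                                    genotypes) {
  regions <- list()
  excluded <- list()
  drop_region <- function(fid, chrom, start, end, reason) {
    message("family ", fid, " region ", chrom, ":", start, "-", end,
            " excluded: ", reason)
    excluded[[length(excluded) + 1L]] <<-
      data.frame(family_id = fid, chrom = chrom, start = start, end = end,
                 reason = reason)
  }
  for (fam in families) {
    members <- c(fam$father_id, fam$mother_id, fam$child_ids)
    fc <- calls[calls$sample_id %in% members, , drop = FALSE]
    if (nrow(fc) == 0L) next
    for (chrom in unique(fc$chrom)) {
      cc <- fc[fc$chrom == chrom, , drop = FALSE]
      for (cluster in .cluster_intervals(cc)) {
        start <- max(cluster$start)
        end <- min(cluster$end)
        if (start > end) {
          drop_region(fam$family_id, chrom, min(cluster$start),
                      max(cluster$end), "empty intersection of member calls")
          next
        }
        member_cn <- stats::setNames(rep(2L, length(members)), members)
        complex <- FALSE
        for (s in unique(cluster$sample_id)) {
          cns <- unique(cluster$cn[cluster$sample_id == s])
          if (length(cns) > 1L) complex <- TRUE else member_cn[s] <- cns
        }
        if (complex) {
          drop_region(fam$family_id, chrom, start, end,
                      "member with overlapping calls of different cn (complex)")
          next
        }
        if (nrow(raw_call_index)) {
          hit <- raw_call_index$sample_id %in% members &
            raw_call_index$chrom == chrom &
            raw_call_index$start <= end & raw_call_index$end >= start
          if (any(hit)) {
            drop_region(fam$family_id, chrom, start, end,
                        "raw single-caller call in a family member")
            next
          }
        }
        mk <- unique(genotypes[genotypes$chrom == chrom &
                               genotypes$pos >= start & genotypes$pos <= end,
                               c("marker_id", "pos")])
        mk <- mk[order(mk$pos), , drop = FALSE]
        # markers must be typed in every member
        if (nrow(mk)) {
          have <- vapply(mk$marker_id, function(m) {
            all(members %in%
                  genotypes$sample_id[genotypes$marker_id == m])
          }, logical(1))
          mk <- mk[have, , drop = FALSE]
        }
        n_carrier_calls <- length(unique(cluster$sample_id))
        if (n_carrier_calls >= 2L && nrow(mk) < 3L) {
          drop_region(fam$family_id, chrom, start, end,
                      "fewer than 3 shared markers across intersected calls")
          next
        }
        m <- nrow(mk)
        mat <- function(what) {
          x <- matrix(NA, nrow = length(members), ncol = m,
                      dimnames = list(members, mk$marker_id))
          x
        }
        size <- mat(); nb <- mat(); conf <- mat(); nocall <- mat()
        if (m) {
          g <- genotypes[genotypes$marker_id %in% mk$marker_id &
                         genotypes$sample_id %in% members, , drop = FALSE]
          idx <- cbind(match(g$sample_id, members),
                       match(g$marker_id, mk$marker_id))
          size[idx] <- g$size; nb[idx] <- g$nb
          conf[idx] <- g$confidence; nocall[idx] <- g$no_call
        }
        carrier_parents <- c("father", "mother")[
          c(member_cn[fam$father_id] != 2L, member_cn[fam$mother_id] != 2L)]
        reg <- structure(list(
          region_id = paste0(fam$family_id, "_", chrom, "_", start),
          family_id = fam$family_id, chrom = chrom,
          start = start, end = end,
          father_id = fam$father_id, mother_id = fam$mother_id,
          child_ids = fam$child_ids,
          member_cn = member_cn,
          carrier_parents = carrier_parents,
          markers = mk, size = size, nb = nb, conf = conf, nocall = nocall,
          selected = FALSE, flag = ""
        ), class = "cnv_region")
        regions[[length(regions) + 1L]] <- reg
      }
    }
  }
  attr(regions, "excluded") <-
    if (length(excluded)) do.call(rbind, excluded) else NULL
  regions
}

#' Select phasing-ready markers within a region
#'
#' Drops markers where (i) any family member has a no-call, a call
#' probability below 0.95, or a genotype whose allele count disagrees with
#' that member's regional copy number, or (ii) the union of alleles across
#' all family members contains a single allele type (monomorphic, hence
#' uninformative for phasing).  Markers outside the region interval were
#' never attached.  Remaining markers stay ordered by position.  A region
#' left with zero markers is retained but flagged `"uninformative"`:
#' phasing may still resolve it through copy numbers alone.
#'
#' @param region A `cnv_region` object.
#' @param min_confidence Call-probability threshold (default 0.95, strict).
#' @return The region with filtered marker set and `selected = TRUE`.
#' @export
select_region_markers <- function(region, min_confidence = 0.95) {
  stopifnot(inherits(region, "cnv_region"))
  m <- nrow(region$markers)
  if (m) {
    bad_quality <- apply(region$nocall, 2, any) |
      apply(region$conf < min_confidence, 2, any)
    cn_vec <- region$member_cn[rownames(region$size)]
    bad_size <- apply(region$size != cn_vec, 2, any)
    bad_quality <- bad_quality | (bad_size & !is.na(bad_size))
    bad_quality[is.na(bad_quality)] <- TRUE
    tot_b <- colSums(region$nb)
    tot_a <- colSums(region$size - region$nb)
    mono <- (tot_b == 0L) | (tot_a == 0L)
    mono[is.na(mono)] <- FALSE
    keep <- !(bad_quality | mono)
    region$markers <- region$markers[keep, , drop = FALSE]
    region$size <- region$size[, keep, drop = FALSE]
    region$nb <- region$nb[, keep, drop = FALSE]
    region$conf <- region$conf[, keep, drop = FALSE]
    region$nocall <- region$nocall[, keep, drop = FALSE]
  }
  if (nrow(region$markers) == 0L) region$flag <- "uninformative"
  region$selected <- TRUE
  region
}

#' @export
print.cnv_region <- function(x, ...) {
  cat("<cnv_region> ", x$region_id, "  ", x$chrom, ":", x$start, "-", x$end,
      "\n", sep = "")
  cat("  family ", x$family_id, ", ", length(x$child_ids), " child(ren), ",
      nrow(x$markers), " marker(s)",
      if (nzchar(x$flag)) paste0(" [", x$flag, "]"), "\n", sep = "")
  cns <- paste(names(x$member_cn), x$member_cn, sep = "=", collapse = " ")
  cat("  member CN: ", cns, "\n", sep = "")
  invisible(x)
}

#' Write converged regions as a TSV table
#'
#' @param regions List of `cnv_region` objects.
#' @param path Output file.
#' @return Invisibly, the data.frame written.
#' @export
write_regions_tsv <- function(regions, path) {
  rows <- lapply(regions, function(r) {
    grp <- tryCatch(assign_group(r), error = function(e) NA_character_)
    data.frame(
      family_id = r$family_id, chrom = r$chrom, start = r$start, end = r$end,
      members = paste(names(r$member_cn), collapse = ","),
      cns = paste(r$member_cn, collapse = ","),
      n_markers = nrow(r$markers),
      carrier_parents = paste(r$carrier_parents, collapse = ","),
      group = grp, flag = r$flag)
  })
  df <- if (length(rows)) do.call(rbind, rows) else
    data.frame(family_id = character(), chrom = character(),
               start = integer(), end = integer(), members = character(),
               cns = character(), n_markers = integer(),
               carrier_parents = character(), group = character(),
               flag = character())
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(df)
}
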